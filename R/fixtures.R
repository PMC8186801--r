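#' Generate a geometrically consistent set of synthetic imaging fixtures
#'
#' Builds, in memory (and optionally on disk as NIfTI), everything the
#' volumetric pipeline needs to run end to end with known ground truth:
#'
#' * a resting-state 4-D series in which a 9-voxel seed ROI carries a slow
#'   (below the low-pass cutoff) shared signal that reappears in a 9-voxel
#'   target ROI at a configurable correlation `rho`, on top of spatially
#'   white noise;
#' * a radial-diffusivity-like scalar map with a tract of distinct constant
#'   diffusivity, plus a smooth track probability map covering that tract;
#' * binary brain, grey-matter and white-matter masks;
#' * a task series with a boxcar activation planted at a known peak voxel.
#'
#' These fixtures emulate the geometry and signal structure the pipeline
#' operates on, not MR physics: there is no physiological noise spectrum,
#' no motion, no partial-volume structure.
#'
#' @param dim in-plane-by-slice grid (default `c(24, 24, 12)`).
#' @param n_volumes resting-state series length (default 60).
#' @param tr_s repetition time, s (default 2.8).
#' @param voxel_size_mm voxel size (default `c(2, 2, 4)` mm).
#' @param rho planted seed-target correlation in [0, 1] (default 0.9).
#' @param noise_sd white-noise SD of the resting-state series (default 1).
#' @param rd_background,rd_tract radial diffusivity off / on the tract,
#'   mm2/s (defaults 0.7e-3 and 0.5e-3).
#' @param task_amplitude boxcar activation amplitude (default 5); the task
#'   series has `task_noise_sd` white noise (default 1; set 0 for a
#'   noise-free activation).
#' @param n_task_volumes,task_block,task_cycles task design (defaults 160,
#'   16, 4).
#' @param rng_seed integer seed; the fixture set is deterministic given it.
#' @param dir optional directory; when given, all volumes are written as
#'   `.nii.gz` plus a `manifest.csv` of scalar ground truth.
#' @return A list with `rest_series`, `task_series`, `rd_map`, `track_map`,
#'   `brain_mask`, `gm_mask`, `wm_mask`, `seed`, `target`, and `manifest`
#'   (ground-truth list: `rho`, `peak_voxel`, `tract_rd`, ROI centres).
#' @export
make_image_fixtures <- function(dim = c(24, 24, 12), n_volumes = 60,
                                tr_s = 2.8, voxel_size_mm = c(2, 2, 4),
                                rho = 0.9, noise_sd = 1,
                                rd_background = 0.7e-3, rd_tract = 0.5e-3,
                                task_amplitude = 5, task_noise_sd = 1,
                                n_task_volumes = 160, task_block = 16,
                                task_cycles = 4,
                                rng_seed = 1L, dir = NULL) {
  dim <- as.integer(dim)
  if (length(dim) != 3L || any(dim[1:2] < 8L) || dim[3] < 4L)
    stop("'dim' must be three integers, at least 8 x 8 x 4")
  if (rho < 0 || rho > 1)
    stop("'rho' must lie in [0, 1]")
  .with_seed(rng_seed, {
    aff <- diag(c(voxel_size_mm, 1))
    # masks: brain = interior (1-voxel shell off), wm = central core,
    # gm = brain minus wm
    brain <- array(0, dim)
    brain[2:(dim[1] - 1), 2:(dim[2] - 1), 2:(dim[3] - 1)] <- 1
    wm <- array(0, dim)
    qx <- seq(round(dim[1] * 0.3), round(dim[1] * 0.7))
    qy <- seq(round(dim[2] * 0.3), round(dim[2] * 0.7))
    qz <- seq(max(2, round(dim[3] * 0.3)), min(dim[3] - 1,
                                               round(dim[3] * 0.7)))
    wm[qx, qy, qz] <- 1
    gm <- brain * (1 - wm)
    mk <- function(v, units) voxel_grid(v, voxel_size_mm, aff, units = units)

    # seed and target: 3x3 in-plane squares in grey matter, well separated
    zs <- 2L
    seed_c <- c(4L, 4L, zs)                       # 0-based centres
    targ_c <- c(dim[1] - 6L, dim[2] - 6L, zs)
    # 1-based slice assignment covering the 0-based 3x3 neighbourhoods
    gm[seed_c[1] + (0:2), seed_c[2] + (0:2), zs + 1L] <- 1
    gm[targ_c[1] + (0:2), targ_c[2] + (0:2), zs + 1L] <- 1
    brain <- pmax(brain, gm)
    square <- function(center)
      as.matrix(expand.grid(x = center[1] + (-1:1),
                            y = center[2] + (-1:1), z = center[3]))
    seed <- seed_roi(square(seed_c), space = "rsfmri", role = "seed")
    target <- seed_roi(square(targ_c), space = "rsfmri", role = "target")

    # slow shared signal below the 0.08 Hz cutoff, unit variance
    tt <- seq_len(n_volumes) * tr_s
    sig <- sin(2 * pi * 0.03 * tt) + 0.6 * sin(2 * pi * 0.015 * tt + 1)
    sig <- (sig - mean(sig)) / stats::sd(sig)
    rest <- array(stats::rnorm(prod(dim) * n_volumes, 0, noise_sd),
                  c(dim, n_volumes))
    plant <- function(arr, roi, tsig, keep_sd) {
      for (i in seq_len(nrow(roi$voxel_indices))) {
        v <- roi$voxel_indices[i, ] + 1L
        arr[v[1], v[2], v[3], ] <- tsig +
          keep_sd * stats::rnorm(n_volumes, 0, noise_sd)
      }
      arr
    }
    rest <- plant(rest, seed, sig, keep_sd = 0.05)
    targ_sig <- rho * sig +
      sqrt(max(0, 1 - rho^2)) * {
        e <- sin(2 * pi * 0.025 * tt + stats::runif(1, 0, 2 * pi)) +
          0.7 * sin(2 * pi * 0.045 * tt + stats::runif(1, 0, 2 * pi))
        (e - mean(e)) / stats::sd(e)
      }
    rest <- plant(rest, target, targ_sig, keep_sd = 0.05)
    rest_series <- time_series_volume(rest, tr_s, voxel_size_mm, aff)

    # tract: a line of white-matter voxels with distinct RD, covered by a
    # smooth probability map that decays off the tract axis
    rd <- array(rd_background, dim)
    zmid <- round(dim[3] / 2)
    ymid <- round(dim[2] / 2)
    track <- array(0, dim)
    for (x in qx) {
      rd[x, ymid + (-3:3), zmid] <- rd_tract
      for (dy in -3:3)
        track[x, ymid + dy, zmid] <- exp(-dy^2 / 2)
    }
    track <- track * wm                 # probability support inside WM
    track[track > 0 & track < 1e-3] <- 0
    tract_vox <- which(track > 0 & rd == rd_tract)

    # task series: boxcar activation at a known grey-matter voxel
    peak <- seed_c                                  # 0-based
    box <- rep(rep(c(0, 1), task_cycles), each = task_block)
    box <- c(box, rep(0, n_task_volumes - length(box)))
    task <- array(stats::rnorm(prod(dim) * n_task_volumes, 0, task_noise_sd),
                  c(dim, n_task_volumes))
    task[peak[1] + 1L, peak[2] + 1L, peak[3] + 1L, ] <-
      task[peak[1] + 1L, peak[2] + 1L, peak[3] + 1L, ] + task_amplitude * box
    task_series <- time_series_volume(task, tr_s, voxel_size_mm, aff)

    manifest <- list(rho = rho, peak_voxel = peak,
                     tract_rd = rd_tract,
                     tract_mean_rd = mean(rd[tract_vox]),
                     seed_center = seed_c, target_center = targ_c,
                     task_block = task_block, task_cycles = task_cycles,
                     rng_seed = rng_seed)
    out <- list(rest_series = rest_series, task_series = task_series,
                rd_map = mk(rd, "mm2/s"), track_map = mk(track, "probability"),
                brain_mask = mk(brain, "binary"), gm_mask = mk(gm, "binary"),
                wm_mask = mk(wm, "binary"),
                seed = seed, target = target, manifest = manifest)
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      vols <- c("rest_series", "task_series", "rd_map", "track_map",
                "brain_mask", "gm_mask", "wm_mask")
      for (v in vols)
        write_volume(out[[v]], file.path(dir, paste0(v, ".nii.gz")))
      scal <- manifest[c("rho", "tract_rd", "tract_mean_rd", "task_block",
                         "task_cycles", "rng_seed")]
      mf <- data.frame(key = c(names(scal), "peak_voxel", "seed_center",
                               "target_center"),
                       value = c(unlist(scal),
                                 paste(manifest$peak_voxel, collapse = " "),
                                 paste(manifest$seed_center, collapse = " "),
                                 paste(manifest$target_center, collapse = " ")))
      utils::write.csv(mf, file.path(dir, "manifest.csv"), row.names = FALSE)
    }
    out
  })
}
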