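# Frequency axis helper: cycles/unit for an n-point DFT, folded so entry k
# carries |f_k| (two-sided spectrum).
.fft_freq_abs <- function(n, delta) {
  k <- 0:(n - 1)
  pmin(k, n - k) / (n * delta)
}

#' Temporal low-pass filter (zero phase)
#'
#' Removes fluctuations above `cutoff_hz` from every voxel's time course
#' using a zero-phase frequency-domain mask with a raised-cosine rolloff
#' between 0.85 and 1.15 times the cutoff. The DC component (voxel mean) is
#' preserved exactly; the passband (below 0.8 x cutoff) is attenuated by
#' less than 5% and the stopband (above 1.25 x cutoff) by more than 90%.
#'
#' @param series a [time_series_volume()].
#' @param cutoff_hz cutoff frequency in Hz; must be below the Nyquist
#'   frequency `1 / (2 * tr_s)`. The resting-state pipeline default is
#'   0.08 Hz.
#' @return A filtered `time_series_volume`.
#' @export
lowpass_filter <- function(series, cutoff_hz = 0.08) {
  stopifnot(inherits(series, "time_series_volume"))
  nyquist <- 1 / (2 * series$tr_s)
  if (cutoff_hz >= nyquist)
    stop("cutoff (", cutoff_hz, " Hz) must be below Nyquist (",
         signif(nyquist, 4), " Hz)")
  n <- series$n_volumes
  f <- .fft_freq_abs(n, series$tr_s)
  f_lo <- 0.85 * cutoff_hz
  f_hi <- 1.15 * cutoff_hz
  gain <- ifelse(f <= f_lo, 1,
          ifelse(f >= f_hi, 0,
                 0.5 * (1 + cos(pi * (f - f_lo) / (f_hi - f_lo)))))
  dims <- dim(series$values)
  Y <- matrix(series$values, nrow = prod(dims[1:3]), ncol = n)
  spec <- stats::mvfft(t(Y)) * gain
  out <- Re(stats::mvfft(spec, inverse = TRUE)) / n
  series$values <- array(t(out), dims)
  series
}

# Apply a separable in-plane (x, y) k-space gain to every slice of a 3-D or
# 4-D array. gain_fun(n, delta) -> length-n gain over folded frequencies.
.inplane_kspace_filter <- function(values, voxel_size_mm, gain_fun) {
  dims <- dim(values)
  gx <- gain_fun(dims[1], voxel_size_mm[1])
  gy <- gain_fun(dims[2], voxel_size_mm[2])
  g2 <- outer(gx, gy)
  filt_slice <- function(sl) Re(stats::fft(stats::fft(sl) * g2,
                                           inverse = TRUE)) / length(sl)
  if (length(dims) == 3L) {
    for (z in seq_len(dims[3]))
      values[, , z] <- filt_slice(values[, , z])
  } else {
    for (t in seq_len(dims[4]))
      for (z in seq_len(dims[3]))
        values[, , z, t] <- filt_slice(values[, , z, t])
  }
  values
}

#' 2-D in-plane Hamming filter
#'
#' Apodizes the in-plane spatial-frequency spectrum of every axial slice
#' (of every volume) with a separable Hamming window whose gain is 1 at DC
#' and 0.08 at the in-plane Nyquist frequency, trading a small resolution
#' loss for improved functional contrast-to-noise. The slice mean (DC term)
#' is preserved exactly.
#'
#' @param series a `time_series_volume` (or `voxel_grid`).
#' @return The filtered object, same class as the input.
#' @export
inplane_hamming_filter <- function(series) {
  vals <- if (inherits(series, "time_series_volume") ||
              inherits(series, "voxel_grid")) series$values
          else stop("'series' must be a time_series_volume or voxel_grid")
  if (any(dim(vals)[1:2] < 4L))
    stop("in-plane dimensions must be at least 4")
  hamming_gain <- function(n, delta) {
    fr <- .fft_freq_abs(n, 1) / 0.5     # folded frequency / Nyquist, in [0,1]
    0.54 + 0.46 * cos(pi * fr)
  }
  series$values <- .inplane_kspace_filter(vals, series$voxel_size_mm,
                                          hamming_gain)
  series
}

#' 2-D in-plane Gaussian filter
#'
#' Separable in-plane Gaussian smoothing specified by its full width at half
#' maximum in mm, applied in the spatial-frequency domain (zero phase, DC
#' preserved). Used on the task-fMRI branch before the block-design GLM.
#'
#' @param series a `time_series_volume` or `voxel_grid`.
#' @param fwhm_mm full width at half maximum of the kernel, mm (default 4).
#' @return The filtered object, same class as the input.
#' @export
inplane_gaussian_filter <- function(series, fwhm_mm = 4) {
  vals <- if (inherits(series, "time_series_volume") ||
              inherits(series, "voxel_grid")) series$values
          else stop("'series' must be a time_series_volume or voxel_grid")
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  gauss_gain <- function(n, delta) {
    f <- .fft_freq_abs(n, delta)               # cycles / mm
    exp(-2 * pi^2 * sigma_mm^2 * f^2)
  }
  series$values <- .inplane_kspace_filter(vals, series$voxel_size_mm,
                                          gauss_gain)
  series
}

#' Seed reference time series
#'
#' The linearly detrended arithmetic average of the seed voxels' time
#' courses: voxels are averaged at each time point, then the least-squares
#' line is removed, leaving a zero-mean, zero-trend reference.
#'
#' @param series a `time_series_volume` (already filtered).
#' @param seed a non-empty `seed_roi` within bounds.
#' @return A list of class `reference_series` with `values`, `source_roi`
#'   and `detrended = TRUE`.
#' @export
seed_reference <- function(series, seed) {
  stopifnot(inherits(series, "time_series_volume"), inherits(seed, "seed_roi"))
  idx <- seed$voxel_indices
  dims <- dim(series$values)
  if (any(idx[, 1] >= dims[1] | idx[, 2] >= dims[2] | idx[, 3] >= dims[3]))
    stop("seed voxel outside series bounds")
  m <- apply(idx, 1L, function(v)
    series$values[v[1] + 1L, v[2] + 1L, v[3] + 1L, ])
  avg <- rowMeans(m)
  tt <- seq_along(avg)
  detrended <- stats::lm.fit(cbind(1, tt), avg)$residuals
  structure(list(values = as.numeric(detrended), source_roi = seed,
                 detrended = TRUE),
            class = "reference_series")
}

#' Whole-brain seed correlation map
#'
#' Pearson correlation between the reference time series and every in-mask
#' voxel's time course. Zero-variance voxels are recorded as r = 0 and
#' flagged; out-of-mask voxels are NA.
#'
#' @param series a `time_series_volume`.
#' @param ref a `reference_series` (or numeric vector) of matching length.
#' @param brain_mask binary `voxel_grid`.
#' @return A list of class `connectivity_map` with elements `map` (a
#'   `voxel_grid`), `stage = "r"`, `dof`, `n_flagged`.
#' @export
correlation_map <- function(series, ref, brain_mask) {
  stopifnot(inherits(series, "time_series_volume"),
            inherits(brain_mask, "voxel_grid"))
  refv <- if (inherits(ref, "reference_series")) ref$values else as.numeric(ref)
  n <- series$n_volumes
  if (length(refv) != n)
    stop("reference length (", length(refv), ") != n_volumes (", n, ")")
  if (stats::sd(refv) == 0)
    stop("reference time series has zero variance")
  dims <- dim(series$values)
  if (!all(dim(brain_mask$values) == dims[1:3]))
    stop("mask and series dimensions differ")
  inmask <- brain_mask$values > 0
  if (!any(inmask))
    stop("brain mask is empty")
  Y <- matrix(series$values, nrow = prod(dims[1:3]), ncol = n)[inmask, ,
                                                               drop = FALSE]
  sds <- apply(Y, 1L, stats::sd)
  r <- rep(0, nrow(Y))
  ok <- sds > 0
  if (any(ok))
    r[ok] <- as.numeric(stats::cor(t(Y[ok, , drop = FALSE]), refv))
  out <- array(NA_real_, dims[1:3])
  out[inmask] <- r
  structure(list(map = voxel_grid(out, series$voxel_size_mm, series$affine,
                                  units = "r"),
                 stage = "r", dof = n - 2L, n_flagged = sum(!ok)),
            class = "connectivity_map")
}

#' @export
print.connectivity_map <- function(x, ...) {
  v <- x$map$values[is.finite(x$map$values)]
  cat("<connectivity_map> stage ", x$stage, ", dof ", x$dof,
      ", in-mask range [", signif(min(v), 4), ", ", signif(max(v), 4),
      "]\n", sep = "")
  invisible(x)
}

#' Convert a correlation map to a Student's t map
#'
#' `t = r * sqrt((n_effective - 2) / (1 - r^2))`. Perfect correlations
#' (|r| = 1) map to the finite sentinel `+/- t_cap`. Low-pass filtering
#' reduces the effective temporal degrees of freedom; by default the nominal
#' number of volumes is used, and a corrected `n_effective` may be supplied —
#' the subsequent whole-brain z-normalisation removes the resulting global
#' scale either way.
#'
#' @param map a `connectivity_map` at stage `"r"`.
#' @param n_effective effective sample size, >= 3 (default: `dof + 2` of the
#'   map, i.e. the nominal volume count).
#' @param t_cap finite replacement for infinite t (default 1e6).
#' @return A `connectivity_map` at stage `"t"` with `dof = n_effective - 2`.
#' @export
r_to_t <- function(map, n_effective = NULL, t_cap = 1e6) {
  stopifnot(inherits(map, "connectivity_map"))
  if (map$stage != "r")
    stop("input map must be at stage 'r'")
  if (is.null(n_effective))
    n_effective <- map$dof + 2L
  if (n_effective < 3)
    stop("'n_effective' must be at least 3")
  r <- map$map$values
  tval <- r * sqrt((n_effective - 2) / pmax(1 - r^2, 0))
  tval[is.finite(r) & abs(r) >= 1] <- sign(r[is.finite(r) & abs(r) >= 1]) * t_cap
  tval <- pmin(pmax(tval, -t_cap), t_cap)
  map$map$values <- tval
  map$map$units <- "t"
  map$stage <- "t"
  map$dof <- as.integer(n_effective) - 2L
  map
}

#' Normalize a t map to a whole-brain z map
#'
#' Accounts for individual differences in global signal by rescaling the
#' in-mask t distribution to zero mean and unit variance:
#' `z(v) = (t(v) - mean) / sd`. The population SD convention (divide by N)
#' is the default; the sample convention is available — the two differ only
#' by a constant factor, which is irrelevant as long as one convention is
#' used consistently.
#'
#' @param map a `connectivity_map` at stage `"t"`.
#' @param brain_mask binary `voxel_grid` (default: all finite voxels).
#' @param sd_type `"population"` (divide by N) or `"sample"` (N - 1).
#' @return A `connectivity_map` at stage `"z"`; in-mask mean 0, SD 1.
#' @export
normalize_t_to_z <- function(map, brain_mask = NULL,
                             sd_type = c("population", "sample")) {
  stopifnot(inherits(map, "connectivity_map"))
  sd_type <- match.arg(sd_type)
  if (map$stage != "t")
    stop("input map must be at stage 't'")
  vals <- map$map$values
  inmask <- if (is.null(brain_mask)) is.finite(vals) else
    brain_mask$values > 0 & is.finite(vals)
  x <- vals[inmask]
  if (length(x) < 2L)
    stop("need at least 2 in-mask voxels")
  mu <- mean(x)
  s <- if (sd_type == "population") sqrt(mean((x - mu)^2)) else stats::sd(x)
  if (s == 0)
    stop("degenerate map: zero in-mask standard deviation")
  out <- array(NA_real_, dim(vals))
  out[inmask] <- (vals[inmask] - mu) / s
  map$map$values <- out
  map$map$units <- "z"
  map$stage <- "z"
  map
}

#' Extract the pathway functional connectivity value
#'
#' The arithmetic mean z over the target seed voxels (the 9-voxel target
#' ROI in the standard pipeline) of a whole-brain-normalised z map.
#'
#' @param zmap a `connectivity_map` at stage `"z"`.
#' @param target a `seed_roi`; every voxel must lie inside the normalised
#'   mask.
#' @return A single numeric fc value (z units) with attribute `n_voxels`.
#' @export
extract_fc <- function(zmap, target) {
  stopifnot(inherits(zmap, "connectivity_map"), inherits(target, "seed_roi"))
  if (zmap$stage != "z")
    stop("input map must be at stage 'z'")
  dims <- dim(zmap$map$values)
  idx <- target$voxel_indices
  if (any(idx[, 1] >= dims[1] | idx[, 2] >= dims[2] | idx[, 3] >= dims[3]))
    stop("target voxel outside map bounds")
  z <- zmap$map$values[idx + 1L]
  if (any(!is.finite(z)))
    stop("target voxel falls outside the normalised brain mask")
  structure(mean(z), n_voxels = nrow(idx))
}

#' Full seed-to-target functional connectivity pipeline
#'
#' Convenience wrapper running the standard order of operations on a raw
#' resting-state series: in-plane Hamming filter, temporal low-pass at
#' `cutoff_hz`, seed reference extraction (mean then linear detrend),
#' whole-brain correlation, conversion to t, whole-brain z-normalisation,
#' and target averaging.
#'
#' @param series raw `time_series_volume`.
#' @param seed,target `seed_roi`s (9-voxel in-plane ROIs in the standard
#'   pipeline).
#' @param brain_mask binary `voxel_grid`.
#' @param cutoff_hz temporal cutoff (default 0.08 Hz).
#' @param n_effective effective sample size for the t conversion (default:
#'   number of volumes).
#' @param spatial_filter apply the in-plane Hamming filter first (default
#'   TRUE).
#' @return A list with `fc` (numeric, z units), and the intermediate
#'   `zmap` and `ref`.
#' @export
fc_pathway <- function(series, seed, target, brain_mask, cutoff_hz = 0.08,
                       n_effective = NULL, spatial_filter = TRUE) {
  if (spatial_filter)
    series <- inplane_hamming_filter(series)
  series <- lowpass_filter(series, cutoff_hz)
  ref <- seed_reference(series, seed)
  rmap <- correlation_map(series, ref, brain_mask)
  tmap <- r_to_t(rmap, n_effective = n_effective)
  zmap <- normalize_t_to_z(tmap, brain_mask)
  list(fc = as.numeric(extract_fc(zmap, target)), zmap = zmap, ref = ref)
}
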