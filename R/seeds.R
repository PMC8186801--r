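#' Fit a block-design (boxcar) GLM to a task fMRI series
#'
#' Ordinary least squares fit, per voxel, of an intercept, a polynomial
#' drift up to `drift_order`, and a boxcar regressor encoding `n_cycles`
#' off/on cycles of `block_volumes` volumes each (off first, any remaining
#' volumes treated as rest). The t-map is the boxcar coefficient divided by
#' its standard error; a perfect noise-free fit (zero residual) is reported
#' as `+/- t_cap`.
#'
#' @param series a [time_series_volume()].
#' @param block_volumes volumes per block (one block = one off or on period).
#' @param n_cycles number of off/on cycles.
#' @param drift_order polynomial drift order (default 2; 0 = intercept only).
#' @param task_label `"left_hand"` or `"right_hand"`.
#' @param t_cap finite sentinel replacing infinite t-values (default 1e6).
#' @return A list of class `activation_map` with elements `tmap` (a
#'   `voxel_grid`, units `"t"`), `beta` (boxcar coefficients), `dof`,
#'   `design` (the design matrix) and `task_label`.
#' @export
fit_boxcar_glm <- function(series, block_volumes, n_cycles, drift_order = 2,
                           task_label = "right_hand", t_cap = 1e6) {
  stopifnot(inherits(series, "time_series_volume"))
  n <- series$n_volumes
  if (2L * block_volumes * n_cycles > n)
    stop("series too short for ", n_cycles, " off/on cycles of ",
         block_volumes, " volumes")
  box <- rep(rep(c(0, 1), n_cycles), each = block_volumes)
  box <- c(box, rep(0, n - length(box)))
  tt <- seq_len(n)
  X <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  if (drift_order >= 1)
    X <- cbind(X, stats::poly(tt, degree = drift_order))
  X <- cbind(X, boxcar = box)
  p <- ncol(X)
  if (qr(X)$rank < p)
    stop("rank-deficient design matrix (boxcar collinear with drift?)")
  dims <- dim(series$values)
  Y <- matrix(series$values, nrow = prod(dims[1:3]), ncol = n)
  fit <- stats::lm.fit(X, t(Y))
  B <- as.matrix(fit$coefficients)       # p x nvox (vector when nvox = 1)
  beta_box <- B[p, ]
  rss <- colSums(as.matrix(fit$residuals)^2)
  dof <- n - p
  sigma2 <- rss / dof
  xtxinv_pp <- chol2inv(chol(crossprod(X)))[p, p]
  se <- sqrt(sigma2 * xtxinv_pp)
  tval <- ifelse(se > 0, beta_box / se, sign(beta_box) * t_cap)
  tval <- pmin(pmax(tval, -t_cap), t_cap)
  tmap <- voxel_grid(array(tval, dims[1:3]), series$voxel_size_mm,
                     series$affine, units = "t")
  structure(list(tmap = tmap,
                 beta = array(beta_box, dims[1:3]),
                 dof = dof, design = X, task_label = task_label),
            class = "activation_map")
}

#' @export
print.activation_map <- function(x, ...) {
  cat("<activation_map> task ", x$task_label, ", dof ", x$dof,
      ", t range [", signif(min(x$tmap$values), 4), ", ",
      signif(max(x$tmap$values), 4), "]\n", sep = "")
  invisible(x)
}

#' Locate the maximally activated voxel within a search mask
#'
#' Ties are broken deterministically by lexicographic (x, y, z) order of the
#' 0-based voxel index.
#'
#' @param map an `activation_map` (or a `voxel_grid` of statistics).
#' @param search_mask binary `voxel_grid`; only voxels with mask > 0 compete.
#' @return Integer 0-based voxel index of length 3.
#' @export
peak_voxel <- function(map, search_mask) {
  grid <- if (inherits(map, "activation_map")) map$tmap else map
  stopifnot(inherits(grid, "voxel_grid"), inherits(search_mask, "voxel_grid"))
  if (!all(dim(grid$values) == dim(search_mask$values)))
    stop("map and mask dimensions differ")
  inmask <- which(search_mask$values > 0, arr.ind = TRUE)
  if (nrow(inmask) == 0L)
    stop("search mask is empty")
  vals <- grid$values[inmask]
  best <- which(vals == max(vals))
  cand <- inmask[best, , drop = FALSE] - 1L          # 0-based
  ord <- order(cand[, 1], cand[, 2], cand[, 3])
  as.integer(cand[ord[1], ])
}

#' Build a spherical ROI around a world-coordinate centre
#'
#' Includes every voxel whose centre lies within `radius_mm` of
#' `center_world_mm` (voxel centres are mapped through the grid affine).
#'
#' @param center_world_mm world coordinate (mm), length 3.
#' @param radius_mm sphere radius in mm, > 0.
#' @param grid a `voxel_grid` defining the geometry.
#' @param ... passed to [seed_roi()] (space, role, hemisphere, ...).
#' @return A `seed_roi`.
#' @export
sphere_roi <- function(center_world_mm, radius_mm, grid, ...) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (!is.numeric(radius_mm) || radius_mm <= 0)
    stop("'radius_mm' must be positive")
  dims <- dim(grid$values)
  idx <- as.matrix(expand.grid(x = 0:(dims[1] - 1), y = 0:(dims[2] - 1),
                               z = 0:(dims[3] - 1)))
  world <- t(grid$affine %*% rbind(t(idx), 1))[, 1:3, drop = FALSE]
  d2 <- (world[, 1] - center_world_mm[1])^2 +
        (world[, 2] - center_world_mm[2])^2 +
        (world[, 3] - center_world_mm[3])^2
  keep <- d2 <= radius_mm^2
  if (!any(keep))
    stop("sphere of radius ", radius_mm, " mm contains no voxel centre")
  seed_roi(idx[keep, , drop = FALSE], ...)
}

#' Build the 9-voxel in-plane square ROI around a centre voxel
#'
#' The 3x3 neighbourhood of `center` within its axial (z) slice, clipped to
#' the grid bounds and intersected with the grey-matter mask. The `eroded`
#' flag is set whenever fewer than 9 voxels survive. This replaces the
#' study-style manual erosion of seeds out of intragyral CSF with a
#' deterministic mask intersection.
#'
#' @param center 0-based voxel index, length 3; must lie inside `gm_mask`.
#' @param grid `voxel_grid` defining bounds.
#' @param gm_mask binary grey-matter `voxel_grid` (NULL = no masking).
#' @param ... passed to [seed_roi()].
#' @return A `seed_roi` of up to 9 voxels with the `eroded` flag set when
#'   clipped.
#' @export
inplane_square_roi <- function(center, grid, gm_mask = NULL, ...) {
  stopifnot(inherits(grid, "voxel_grid"))
  center <- as.integer(center)
  dims <- dim(grid$values)
  if (any(center < 0L) || any(center >= dims))
    stop("'center' outside grid bounds")
  if (!is.null(gm_mask) && gm_mask$values[t(center + 1L)] <= 0)
    stop("'center' lies outside the grey-matter mask")
  nb <- as.matrix(expand.grid(x = center[1] + (-1:1), y = center[2] + (-1:1),
                              z = center[3]))
  inb <- nb[, 1] >= 0 & nb[, 1] < dims[1] & nb[, 2] >= 0 & nb[, 2] < dims[2]
  nb <- nb[inb, , drop = FALSE]
  if (!is.null(gm_mask)) {
    keep <- gm_mask$values[nb + 1L] > 0
    nb <- nb[keep, , drop = FALSE]
  }
  if (nrow(nb) == 0L)
    stop("no voxels survive masking around the centre")
  seed_roi(nb, eroded = nrow(nb) < 9L, ...)
}

#' Find the maximally correlated voxel pair between two ROIs
#'
#' Exhaustive search over all grey-matter voxels of the two ROIs for the
#' pair of time courses with the highest Pearson correlation; used to place
#' the functional PCC/AMTL seeds. Zero-variance time courses are excluded.
#' Ties break lexicographically on the concatenated (a, b) indices.
#'
#' @param series a preprocessed (filtered) `time_series_volume`.
#' @param roi_a,roi_b `seed_roi`s (e.g. PCC sphere and AMTL mask).
#' @param gm_mask optional binary grey-matter `voxel_grid`.
#' @return A list with 0-based indices `a`, `b` and the correlation `r`.
#' @export
max_corr_pair <- function(series, roi_a, roi_b, gm_mask = NULL) {
  stopifnot(inherits(series, "time_series_volume"))
  ts_at <- function(roi) {
    idx <- roi$voxel_indices
    if (!is.null(gm_mask)) {
      keep <- gm_mask$values[idx + 1L] > 0
      idx <- idx[keep, , drop = FALSE]
    }
    if (nrow(idx) == 0L)
      stop("ROI is empty after grey-matter masking")
    m <- apply(idx, 1L, function(v) series$values[v[1] + 1L, v[2] + 1L,
                                                  v[3] + 1L, ])
    ok <- apply(m, 2L, stats::sd) > 0
    if (!any(ok))
      stop("all ROI time courses have zero variance")
    list(idx = idx[ok, , drop = FALSE], ts = m[, ok, drop = FALSE])
  }
  a <- ts_at(roi_a)
  b <- ts_at(roi_b)
  r <- stats::cor(a$ts, b$ts)
  mx <- max(r)
  hits <- which(r == mx, arr.ind = TRUE)
  key <- cbind(a$idx[hits[, 1], , drop = FALSE],
               b$idx[hits[, 2], , drop = FALSE])
  ord <- do.call(order, as.data.frame(key))
  pick <- hits[ord[1], ]
  list(a = as.integer(a$idx[pick[1], ]), b = as.integer(b$idx[pick[2], ]),
       r = mx)
}

#' Bundle a pathway's seed, target and track probability map
#'
#' @param name one of `"SMC_transcallosal"`, `"PCC_AMTL_L"`, `"PCC_AMTL_R"`.
#' @param seed,target disjoint `seed_roi`s.
#' @param track_map `voxel_grid` of track membership probabilities in [0, 1].
#' @return A list of class `pathway_spec`.
#' @export
pathway_spec <- function(name, seed, target, track_map = NULL) {
  name <- match.arg(name, c("SMC_transcallosal", "PCC_AMTL_L", "PCC_AMTL_R"))
  stopifnot(inherits(seed, "seed_roi"), inherits(target, "seed_roi"))
  both <- rbind(seed$voxel_indices, target$voxel_indices)
  if (nrow(unique(both)) < nrow(both))
    stop("seed and target ROIs must be disjoint")
  if (!is.null(track_map)) {
    stopifnot(inherits(track_map, "voxel_grid"))
    v <- track_map$values[is.finite(track_map$values)]
    if (min(v) < 0 || max(v) > 1)
      stop("track map must lie in [0, 1]")
  }
  structure(list(name = name, seed = seed, target = target,
                 track_map = track_map),
            class = "pathway_spec")
}
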