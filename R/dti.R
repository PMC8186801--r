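# Diffusion design matrix for the log-linear tensor fit: columns are
# [ln S0, Dxx, Dyy, Dzz, Dxy, Dxz, Dyz]; ln S = X theta with
# ln S = ln S0 - b g' D g.
.dti_design <- function(bvals, bvecs) {
  g <- bvecs
  cbind(1,
        -bvals * g[, 1]^2,
        -bvals * g[, 2]^2,
        -bvals * g[, 3]^2,
        -2 * bvals * g[, 1] * g[, 2],
        -2 * bvals * g[, 1] * g[, 3],
        -2 * bvals * g[, 2] * g[, 3])
}

#' Fit the diffusion tensor by log-linear least squares
#'
#' Solves, per voxel, the standard log-linearised Stejskal-Tanner model
#' `ln S = ln S0 - b g' D g` for the six unique tensor elements and `ln S0`
#' by ordinary least squares, then diagonalises the tensor. Negative
#' eigenvalues (a noise effect) are retained, not clipped, and flagged.
#'
#' @param dwi a [time_series_volume()] whose 4th axis holds the diffusion
#'   volumes.
#' @param bvals numeric b-values (s/mm2), one per volume; at least one must
#'   be 0 and at least 7 volumes are required.
#' @param bvecs n x 3 matrix of unit gradient directions (rows for b = 0
#'   volumes may be zero).
#' @param mask optional binary `voxel_grid` restricting the fit.
#' @return A list of class `tensor_field`: `eigenvalues` (4-D array, last
#'   axis the descending-sorted triple, mm2/s), `valid_mask` and
#'   `negative_flag` (`voxel_grid`s), plus geometry.
#' @export
fit_tensor_loglinear <- function(dwi, bvals, bvecs, mask = NULL) {
  stopifnot(inherits(dwi, "time_series_volume"))
  n <- dwi$n_volumes
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  if (length(bvals) != n || nrow(bvecs) != n || ncol(bvecs) != 3L)
    stop("'bvals'/'bvecs' must match the number of volumes (", n, ")")
  if (n < 7L)
    stop("at least 7 volumes are needed to fit the 7 tensor unknowns")
  if (!any(bvals == 0))
    stop("at least one b = 0 volume is required")
  dwivec <- bvals > 0
  norms <- sqrt(rowSums(bvecs[dwivec, , drop = FALSE]^2))
  if (any(abs(norms - 1) > 1e-3))
    stop("gradient directions of diffusion-weighted volumes must be unit norm")
  X <- .dti_design(bvals, bvecs)
  if (qr(X)$rank < 7L)
    stop("gradient scheme is rank deficient: cannot resolve 6 tensor elements")
  dims <- dim(dwi$values)
  nvox <- prod(dims[1:3])
  S <- matrix(dwi$values, nrow = nvox, ncol = n)
  inmask <- if (is.null(mask)) rep(TRUE, nvox) else as.vector(mask$values > 0)
  valid <- inmask & apply(S > 0, 1L, all)
  ev <- array(NA_real_, c(dims[1:3], 3L))
  neg <- array(0, dims[1:3])
  if (any(valid)) {
    Y <- t(log(S[valid, , drop = FALSE]))
    theta <- as.matrix(stats::lm.fit(X, Y)$coefficients)   # 7 x nvalid
    evs <- apply(theta, 2L, function(th) {
      D <- matrix(c(th[2], th[5], th[6],
                    th[5], th[3], th[7],
                    th[6], th[7], th[4]), 3L, 3L)
      sort(eigen(D, symmetric = TRUE, only.values = TRUE)$values,
           decreasing = TRUE)
    })
    vidx <- which(valid)
    for (k in 1:3) {
      plane <- array(NA_real_, dims[1:3])
      plane[vidx] <- evs[k, ]
      ev[, , , k] <- plane
    }
    neg[vidx] <- as.numeric(evs[3, ] < 0)
  }
  vm <- array(as.numeric(valid), dims[1:3])
  structure(list(eigenvalues = ev,
                 valid_mask = voxel_grid(vm, dwi$voxel_size_mm, dwi$affine,
                                         units = "binary"),
                 negative_flag = voxel_grid(neg, dwi$voxel_size_mm,
                                            dwi$affine, units = "binary"),
                 voxel_size_mm = dwi$voxel_size_mm, affine = dwi$affine),
            class = "tensor_field")
}

#' Forward-simulate diffusion-weighted signals from a known tensor
#'
#' Noise-free Stejskal-Tanner signal `S = S0 exp(-b g' D g)` for a single
#' tensor; the independent forward model used to validate the log-linear
#' fit by simulate-then-invert round trips.
#'
#' @param bvals,bvecs acquisition scheme as in [fit_tensor_loglinear()].
#' @param D 3x3 symmetric diffusion tensor (mm2/s).
#' @param s0 non-diffusion-weighted signal (default 1000).
#' @return Numeric signal vector, one value per volume.
#' @export
simulate_dwi_signal <- function(bvals, bvecs, D, s0 = 1000) {
  bvecs <- as.matrix(bvecs)
  D <- as.matrix(D)
  stopifnot(all(dim(D) == c(3L, 3L)))
  expo <- vapply(seq_along(bvals), function(i)
    bvals[i] * drop(bvecs[i, ] %*% D %*% bvecs[i, ]), numeric(1))
  s0 * exp(-expo)
}

#' Tensor-derived scalar maps
#'
#' From the sorted eigenvalue field: axial diffusivity `AD = lambda1`,
#' radial diffusivity `RD = (lambda2 + lambda3) / 2`, mean diffusivity
#' `MD = (lambda1 + lambda2 + lambda3) / 3`, and fractional anisotropy
#' `FA = sqrt(3/2) * ||lambda - MD|| / ||lambda||` (0 where all eigenvalues
#' vanish).
#'
#' @param field a `tensor_field`.
#' @return A list of class `scalar_maps` with `voxel_grid`s `fa`, `md`,
#'   `ad`, `rd`.
#' @export
tensor_scalars <- function(field) {
  stopifnot(inherits(field, "tensor_field"))
  d3 <- dim(field$eigenvalues)[1:3]
  l1 <- array(field$eigenvalues[, , , 1], d3)
  l2 <- array(field$eigenvalues[, , , 2], d3)
  l3 <- array(field$eigenvalues[, , , 3], d3)
  md <- (l1 + l2 + l3) / 3
  ad <- l1
  rd <- (l2 + l3) / 2
  norm2 <- l1^2 + l2^2 + l3^2
  dev2 <- (l1 - md)^2 + (l2 - md)^2 + (l3 - md)^2
  fa <- ifelse(norm2 > 0, sqrt(1.5 * dev2 / norm2), 0)
  fa[is.na(l1)] <- NA_real_
  mk <- function(v, units) voxel_grid(v, field$voxel_size_mm, field$affine,
                                      units = units)
  structure(list(fa = mk(fa, "unitless"), md = mk(md, "mm2/s"),
                 ad = mk(ad, "mm2/s"), rd = mk(rd, "mm2/s")),
            class = "scalar_maps")
}

#' Pathway-averaged diffusion measure
#'
#' Weights a scalar diffusion map by the track probability map and the
#' white-matter mask: with `normalized = TRUE` (the default) the result is
#' the weighted average
#' `<D> = sum(D w WM) / sum(w WM)`,
#' a true pathway mean that is insensitive to any uniform rescaling of the
#' track map; `normalized = FALSE` returns the literal unnormalised weighted
#' sum, which scales with tract size. Track maps supplied as visitation
#' counts (maximum > 1) are rescaled by their maximum, with a message.
#'
#' @param d_map `voxel_grid` of the diffusion scalar (e.g. RD, mm2/s).
#' @param track_map `voxel_grid` of track membership probabilities.
#' @param wm_mask binary white-matter `voxel_grid`.
#' @param normalized divide by the total weight (default TRUE).
#' @param pathway_name,subject,visit identifiers carried into the result.
#' @return A list of class `sc_value` with fields `value`, `pathway_name`,
#'   `subject`, `visit`, `normalized`.
#' @export
pathway_average <- function(d_map, track_map, wm_mask, normalized = TRUE,
                            pathway_name = "", subject = NA, visit = NA) {
  stopifnot(inherits(d_map, "voxel_grid"), inherits(track_map, "voxel_grid"),
            inherits(wm_mask, "voxel_grid"))
  if (!all(dim(d_map$values) == dim(track_map$values)) ||
      !all(dim(d_map$values) == dim(wm_mask$values)))
    stop("d_map, track_map and wm_mask must share the same grid")
  w <- track_map$values
  if (any(w < 0, na.rm = TRUE))
    stop("track map has negative weights")
  mx <- max(w, na.rm = TRUE)
  if (mx > 1) {
    message("track map looks like visitation counts (max = ", signif(mx, 4),
            "); rescaling by its maximum")
    w <- w / mx
  }
  wm <- as.numeric(wm_mask$values > 0)
  wt <- w * array(wm, dim(w))
  wt[!is.finite(wt)] <- 0
  total <- sum(wt)
  if (total <= 0)
    stop("zero total weight for pathway '", pathway_name,
         "': track map and white-matter mask do not overlap")
  d <- d_map$values
  d[!is.finite(d)] <- 0
  value <- if (normalized) sum(d * wt) / total else sum(d * wt)
  structure(list(value = value, pathway_name = pathway_name,
                 subject = subject, visit = visit, normalized = normalized),
            class = "sc_value")
}

#' @export
print.sc_value <- function(x, ...) {
  cat("<sc_value> ", format(x$value, digits = 6),
      if (nzchar(x$pathway_name)) paste0(" (", x$pathway_name, ")"),
      if (!x$normalized) " [unnormalised sum]", "\n", sep = "")
  invisible(x)
}

#' Read FSL-style bval / bvec text files
#'
#' @param bval_path one row of b-values.
#' @param bvec_path three rows (x, y, z components), one column per volume.
#' @return A list with `bvals` (numeric) and `bvecs` (n x 3 matrix).
#' @export
read_bval_bvec <- function(bval_path, bvec_path) {
  bvals <- as.numeric(scan(bval_path, quiet = TRUE))
  bv <- as.matrix(utils::read.table(bvec_path))
  if (nrow(bv) != 3L)
    stop("bvec file must have 3 rows: ", bvec_path)
  if (ncol(bv) != length(bvals))
    stop("bval / bvec volume counts differ")
  list(bvals = bvals, bvecs = t(unname(bv)))
}
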