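#' Construct a 3-D scalar volume
#'
#' A `voxel_grid` is the package's container for any single 3-D scalar field:
#' diffusivity maps, track probability maps, binary masks, z-maps. It carries
#' the voxel size, the 4x4 grid-to-world affine (NIfTI convention, 0-based
#' voxel indices) and a free-text unit label. Grids labelled `"binary"` may
#' contain only 0/1; grids labelled `"probability"` must lie in [0, 1].
#'
#' @param values numeric 3-D array.
#' @param voxel_size_mm positive length-3 numeric, voxel edge lengths in mm.
#' @param affine 4x4 grid-to-world matrix; defaults to a diagonal affine
#'   built from `voxel_size_mm`.
#' @param units unit label, e.g. `"mm2/s"`, `"z"`, `"probability"`, `"binary"`.
#' @return An object of class `voxel_grid`.
#' @examples
#' g <- voxel_grid(array(0, c(4, 4, 2)), voxel_size_mm = c(2, 2, 4))
#' dim(g$values)
#' @export
voxel_grid <- function(values, voxel_size_mm = c(1, 1, 1), affine = NULL,
                       units = "arbitrary") {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("'values' must be a 3-D array")
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) != 3L || any(!is.finite(voxel_size_mm)) ||
      any(voxel_size_mm <= 0))
    stop("'voxel_size_mm' must be three strictly positive numbers")
  if (is.null(affine))
    affine <- diag(c(voxel_size_mm, 1))
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)))
    stop("'affine' must be a 4x4 matrix")
  if (abs(det(affine)) < .Machine$double.eps)
    stop("'affine' must be invertible")
  vals <- values[is.finite(values)]
  if (identical(units, "binary") && length(vals) && !all(vals %in% c(0, 1)))
    stop("a grid labelled 'binary' may contain only 0 and 1")
  if (identical(units, "probability") && length(vals) &&
      (min(vals) < 0 || max(vals) > 1))
    stop("a grid labelled 'probability' must lie in [0, 1]")
  structure(list(values = values, voxel_size_mm = voxel_size_mm,
                 affine = affine, units = units),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat("<voxel_grid> ", paste(dim(x$values), collapse = " x "),
      " voxels, ", paste(signif(x$voxel_size_mm, 4), collapse = " x "),
      " mm, units: ", x$units, "\n", sep = "")
  invisible(x)
}

#' Construct a 4-D time-series volume
#'
#' Container for fMRI (or DWI) series: an (x, y, z, t) lattice with the
#' repetition time in seconds and the grid-to-world affine.
#'
#' @param values numeric 4-D array (x, y, z, t).
#' @param tr_s repetition time in seconds, strictly positive.
#' @param voxel_size_mm positive length-3 numeric.
#' @param affine 4x4 grid-to-world matrix (default diagonal from voxel size).
#' @return An object of class `time_series_volume` with field `n_volumes`.
#' @export
time_series_volume <- function(values, tr_s, voxel_size_mm = c(1, 1, 1),
                               affine = NULL) {
  if (!is.array(values) || length(dim(values)) != 4L)
    stop("'values' must be a 4-D array (x, y, z, t)")
  if (dim(values)[4] < 2L)
    stop("a time series needs at least 2 volumes")
  if (!is.numeric(tr_s) || length(tr_s) != 1L || !is.finite(tr_s) || tr_s <= 0)
    stop("'tr_s' must be a single positive number; supply it explicitly ",
         "when the file header carries TR = 0")
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0))
    stop("'voxel_size_mm' must be three strictly positive numbers")
  if (is.null(affine))
    affine <- diag(c(voxel_size_mm, 1))
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || abs(det(affine)) < .Machine$double.eps)
    stop("'affine' must be an invertible 4x4 matrix")
  structure(list(values = values, tr_s = tr_s, voxel_size_mm = voxel_size_mm,
                 affine = affine, n_volumes = dim(values)[4]),
            class = "time_series_volume")
}

#' @export
print.time_series_volume <- function(x, ...) {
  cat("<time_series_volume> ", paste(dim(x$values)[1:3], collapse = " x "),
      " voxels x ", x$n_volumes, " volumes, TR = ", x$tr_s, " s\n", sep = "")
  invisible(x)
}

#' Construct a seed/target region of interest
#'
#' A `seed_roi` is a set of 0-based voxel indices in a named image space.
#' The 9-voxel in-plane variant used for functional connectivity seeds is a
#' 3x3 square within a single axial slice.
#'
#' @param voxel_indices integer matrix with 3 columns (0-based x, y, z), or a
#'   length-3 vector for a single voxel.
#' @param space image-space label, one of `"rsfmri"`, `"dti"`, `"anat"`,
#'   `"task"`.
#' @param role `"seed"` or `"target"`.
#' @param hemisphere `"L"`, `"R"` or `"bilateral"`.
#' @param pathway_name pathway label.
#' @param eroded logical flag set when a 9-voxel ROI lost voxels to masking
#'   or grid bounds.
#' @return An object of class `seed_roi`.
#' @export
seed_roi <- function(voxel_indices, space = "rsfmri", role = "seed",
                     hemisphere = "bilateral", pathway_name = "",
                     eroded = FALSE) {
  if (is.null(dim(voxel_indices)))
    voxel_indices <- matrix(voxel_indices, ncol = 3, byrow = TRUE)
  voxel_indices <- as.matrix(voxel_indices)
  storage.mode(voxel_indices) <- "integer"
  if (ncol(voxel_indices) != 3L || nrow(voxel_indices) == 0L)
    stop("'voxel_indices' must be a non-empty n x 3 integer matrix")
  if (any(voxel_indices < 0L))
    stop("voxel indices are 0-based and must be non-negative")
  space <- match.arg(space, c("rsfmri", "dti", "anat", "task"))
  role <- match.arg(role, c("seed", "target"))
  hemisphere <- match.arg(hemisphere, c("L", "R", "bilateral"))
  voxel_indices <- unique(voxel_indices)
  colnames(voxel_indices) <- c("x", "y", "z")
  structure(list(voxel_indices = voxel_indices, space = space, role = role,
                 hemisphere = hemisphere, pathway_name = pathway_name,
                 eroded = isTRUE(eroded)),
            class = "seed_roi")
}

#' @export
print.seed_roi <- function(x, ...) {
  cat("<seed_roi> ", nrow(x$voxel_indices), " voxel(s) in ", x$space,
      " space, role ", x$role, ", hemisphere ", x$hemisphere,
      if (nzchar(x$pathway_name)) paste0(", pathway ", x$pathway_name),
      if (x$eroded) " [eroded]", "\n", sep = "")
  invisible(x)
}

#' Construct a world-coordinate affine between two co-registered spaces
#'
#' Stands in for the transform matrices emitted by an external affine
#' registration; the matrix maps world (mm) coordinates of the source space
#' into world coordinates of the destination space.
#'
#' @param source_space,dest_space space labels.
#' @param matrix invertible 4x4 world-to-world transform.
#' @return An object of class `affine_pair`.
#' @export
affine_pair <- function(source_space, dest_space, matrix = diag(4)) {
  matrix <- as.matrix(matrix)
  if (!all(dim(matrix) == c(4L, 4L)) || abs(det(matrix)) < .Machine$double.eps)
    stop("'matrix' must be an invertible 4x4 matrix")
  structure(list(source_space = source_space, dest_space = dest_space,
                 matrix = matrix),
            class = "affine_pair")
}

#' Read a NIfTI volume
#'
#' 3-D files return a [voxel_grid()]; 4-D files return a
#' [time_series_volume()] with the repetition time taken from the header
#' (fourth `pixdim`). A header TR of 0 — common in malformed files — must be
#' overridden via `tr_s`, otherwise an error is raised: temporal filtering
#' needs a trusted sampling rate.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @param units unit label attached to 3-D volumes.
#' @param tr_s optional repetition time (seconds) overriding the header.
#' @return A `voxel_grid` or `time_series_volume`.
#' @export
read_volume <- function(path, units = "arbitrary", tr_s = NULL) {
  if (!file.exists(path))
    stop("file not found: ", path)
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e)
                    stop("not a readable NIfTI file: ", path, " (",
                         conditionMessage(e), ")", call. = FALSE))
  dims <- dim(img)
  aff <- structure(unclass(RNifti::xform(img)),
                   imagedim = NULL, code = NULL)
  pd <- RNifti::pixdim(img)
  if (length(dims) == 3L) {
    voxel_grid(array(as.numeric(img), dim = dims),
               voxel_size_mm = abs(pd[1:3]), affine = aff, units = units)
  } else if (length(dims) == 4L) {
    # the raw header pixdim keeps a literal 0 TR (pixdim() masks it as 1)
    hdr_tr <- RNifti::niftiHeader(img)$pixdim[5]
    tr <- if (!is.null(tr_s)) tr_s else hdr_tr
    if (!is.finite(tr) || tr <= 0)
      stop("header TR is ", hdr_tr, "; supply 'tr_s' explicitly for: ", path)
    time_series_volume(array(as.numeric(img), dim = dims), tr_s = tr,
                       voxel_size_mm = abs(pd[1:3]), affine = aff)
  } else {
    stop("unsupported NIfTI dimensionality (", length(dims), "-D): ", path)
  }
}

#' Write a volume to NIfTI
#'
#' @param vol a `voxel_grid` or `time_series_volume`.
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  if (inherits(vol, "voxel_grid")) {
    img <- RNifti::asNifti(vol$values)
    RNifti::pixdim(img) <- vol$voxel_size_mm
  } else if (inherits(vol, "time_series_volume")) {
    img <- RNifti::asNifti(vol$values)
    RNifti::pixdim(img) <- c(vol$voxel_size_mm, vol$tr_s)
  } else {
    stop("'vol' must be a voxel_grid or time_series_volume")
  }
  RNifti::sform(img) <- structure(vol$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read / write a 4x4 affine as whitespace-delimited text
#'
#' @param path text file holding 4 rows of 4 numbers.
#' @return `read_affine_matrix()` returns a 4x4 matrix.
#' @export
read_affine_matrix <- function(path) {
  m <- as.matrix(utils::read.table(path))
  dimnames(m) <- NULL
  if (!all(dim(m) == c(4L, 4L)))
    stop("affine file must contain a 4x4 matrix: ", path)
  m
}

#' @rdname read_affine_matrix
#' @param matrix 4x4 matrix to write.
#' @export
write_affine_matrix <- function(matrix, path) {
  utils::write.table(matrix, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Convert an ROI to a binary mask grid, or back
#'
#' @param roi a `seed_roi`.
#' @param grid a `voxel_grid` supplying geometry.
#' @return `roi_to_mask()` returns a binary `voxel_grid`;
#'   `mask_to_roi()` returns a `seed_roi` of all voxels where the mask is
#'   non-zero.
#' @export
roi_to_mask <- function(roi, grid) {
  stopifnot(inherits(roi, "seed_roi"), inherits(grid, "voxel_grid"))
  dims <- dim(grid$values)
  idx <- roi$voxel_indices
  if (any(idx[, 1] >= dims[1] | idx[, 2] >= dims[2] | idx[, 3] >= dims[3]))
    stop("ROI voxel outside grid bounds")
  m <- array(0, dims)
  m[idx + 1L] <- 1
  voxel_grid(m, grid$voxel_size_mm, grid$affine, units = "binary")
}

#' @rdname roi_to_mask
#' @param ... passed to [seed_roi()].
#' @export
mask_to_roi <- function(grid, ...) {
  stopifnot(inherits(grid, "voxel_grid"))
  idx <- which(grid$values != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    stop("mask is empty")
  seed_roi(idx - 1L, ...)
}

#' Transfer an ROI between co-registered spaces by nearest neighbour
#'
#' Maps the centre of every source voxel through the source grid-to-world
#' affine, the world-to-world transform of `pair`, and the inverse
#' destination affine, then assigns each point to its nearest destination
#' voxel. Duplicate assignments collapse to one voxel; voxels landing outside
#' the destination grid are dropped.
#'
#' @param roi a `seed_roi` whose `space` matches `pair$source_space`.
#' @param pair an `affine_pair`.
#' @param src_grid,dest_grid `voxel_grid`s defining the two geometries.
#' @return A `seed_roi` in `pair$dest_space`.
#' @export
transfer_roi <- function(roi, pair, src_grid, dest_grid) {
  stopifnot(inherits(roi, "seed_roi"), inherits(pair, "affine_pair"),
            inherits(src_grid, "voxel_grid"), inherits(dest_grid, "voxel_grid"))
  if (!identical(roi$space, pair$source_space))
    stop("ROI space '", roi$space, "' does not match pair source space '",
         pair$source_space, "'")
  src_h <- rbind(t(roi$voxel_indices), 1)          # homogeneous, 0-based
  world <- pair$matrix %*% (src_grid$affine %*% src_h)
  dest <- solve(dest_grid$affine) %*% world
  idx <- round(t(dest[1:3, , drop = FALSE]))
  dims <- dim(dest_grid$values)
  keep <- idx[, 1] >= 0 & idx[, 1] < dims[1] &
          idx[, 2] >= 0 & idx[, 2] < dims[2] &
          idx[, 3] >= 0 & idx[, 3] < dims[3]
  idx <- idx[keep, , drop = FALSE]
  if (nrow(idx) == 0L)
    stop("all transferred voxels fall outside the destination grid")
  seed_roi(unique(idx), space = pair$dest_space, role = roi$role,
           hemisphere = roi$hemisphere, pathway_name = roi$pathway_name,
           eroded = roi$eroded)
}
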