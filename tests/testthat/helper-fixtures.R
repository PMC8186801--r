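# Small deterministic helpers shared across tests.

# 9-direction acquisition scheme (2 x b0 + 7 DWI) that resolves all six
# tensor elements.
dti_scheme <- function(b = 1000) {
  bvecs <- rbind(matrix(0, 2, 3), diag(3),
                 c(1, 1, 0) / sqrt(2), c(1, 0, 1) / sqrt(2),
                 c(0, 1, 1) / sqrt(2), c(1, -1, 0) / sqrt(2))
  list(bvals = c(0, 0, rep(b, 7)), bvecs = bvecs)
}

# Uniform DWI volume with every voxel following tensor D (noise-free).
dwi_from_tensor <- function(D, dim = c(3, 3, 2), s0 = 1000, scheme = dti_scheme()) {
  sig <- simulate_dwi_signal(scheme$bvals, scheme$bvecs, D, s0)
  arr <- array(rep(sig, each = prod(dim)), c(dim, length(sig)))
  time_series_volume(arr, tr_s = 7.8)
}

# Tiny measures table: one subject-visit per row blown into the 3-pathway
# long format with given component values.
measures_row <- function(subject, visit, fc, sc, group = NULL) {
  d <- data.frame(subject = subject, visit = visit,
                  pathway = c("SMC_transcallosal", "PCC_AMTL_L", "PCC_AMTL_R"),
                  fc = fc, sc = sc)
  if (!is.null(group)) d$group <- group
  d
}

# Constant-valued time series volume builder.
ts_from_matrix <- function(mat, tr_s = 2.8) {
  # mat: nvox x ntime; laid out on a nvox x 1 x 1 grid
  arr <- array(0, c(nrow(mat), 1, 1, ncol(mat)))
  arr[, 1, 1, ] <- mat
  time_series_volume(arr, tr_s = tr_s)
}

all_ones_mask <- function(dim, voxel = c(1, 1, 1)) {
  voxel_grid(array(1, dim), voxel, units = "binary")
}

# Replace the eigenvalue array of a tensor field (tests build fields by hand).
field_with <- function(field, ev) {
  field$eigenvalues <- ev
  field
}
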