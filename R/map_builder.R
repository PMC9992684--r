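#' Parcellate a 3-D volume into region value vectors
#'
#' Extracts, for every atlas region, the voxel values of `volume` at that
#' region's voxels. Voxel order within a region is the sorted linear
#' (column-major) index order of the label volume, which is deterministic and
#' shared by all subjects parcellated with the same atlas. Voxels outside all
#' regions are ignored.
#'
#' @param volume 3-D numeric array, same shape as the atlas label volume.
#' @param atlas a `regionage_atlas`.
#' @return named list (region id -> numeric vector of voxel values).
#' @export
parcellate_volume <- function(volume, atlas) {
  stopifnot(inherits(atlas, "regionage_atlas"))
  if (!identical(dim(volume), atlas$dim)) {
    stop(sprintf("volume shape (%s) does not match atlas shape (%s)",
                 paste(dim(volume), collapse = "x"),
                 paste(atlas$dim, collapse = "x")), call. = FALSE)
  }
  out <- lapply(atlas$voxel_indices, function(idx) as.numeric(volume[idx]))
  empty <- vapply(out, length, 1L) == 0L
  if (any(empty)) {
    stop("empty region(s) after masking: ",
         paste(names(out)[empty], collapse = ", "), call. = FALSE)
  }
  out
}

#' Fisher's z transformation of a correlation coefficient
#'
#' `z = arctanh(r)`, variance-stabilising for averaging correlations.
#' Correlations at or beyond +/-1 (numerically degenerate perfect
#' correlations) are clamped to +/-(1 - 1e-7) so the transform stays finite.
#'
#' @param r numeric vector of correlations.
#' @return Fisher-z values.
#' @export
fisher_z <- function(r) {
  if (any(!is.finite(r))) stop("non-finite correlation passed to fisher_z",
                               call. = FALSE)
  atanh(pmin(1 - 1e-7, pmax(-(1 - 1e-7), r)))
}

#' Voxel-wise average functional connectivity map
#'
#' For each voxel, the mean over all *other* voxels of the Fisher-z
#' transformed Pearson correlation between their time series. This is the
#' per-voxel summary from which FC region maps are built. A constant-in-time
#' voxel has undefined correlations; by convention they are treated as 0 and
#' a message is emitted.
#'
#' Pairwise correlations are computed in row blocks so the full voxel-pair
#' matrix is never held in memory at once.
#'
#' @param timeseries voxels x time numeric matrix (>= 2 voxels, >= 3 time
#'   points).
#' @param block_size rows per correlation block.
#' @return numeric vector, one average-connectivity value (z units) per voxel.
#' @export
build_fc_map <- function(timeseries, block_size = 2048L) {
  if (!is.matrix(timeseries)) timeseries <- as.matrix(timeseries)
  V <- nrow(timeseries); Tn <- ncol(timeseries)
  if (V < 2L) stop("need at least 2 voxels to compute connectivity", call. = FALSE)
  if (Tn < 3L) stop("need at least 3 time points", call. = FALSE)
  ctr <- timeseries - rowMeans(timeseries)
  ss <- sqrt(rowSums(ctr^2))
  const <- ss == 0
  if (any(const)) {
    message(sum(const), " constant voxel(s): correlations set to 0")
    ss[const] <- 1 # rows are all zero, correlations come out 0
  }
  Z <- ctr / ss # unit rows; crossprod gives Pearson r
  out <- numeric(V)
  for (start in seq(1L, V, by = block_size)) {
    idx <- start:min(start + block_size - 1L, V)
    r_block <- Z[idx, , drop = FALSE] %*% t(Z)
    z_block <- fisher_z(as.numeric(r_block))
    z_block <- matrix(z_block, nrow = length(idx))
    # exclude the self pair (its clamped z would otherwise inflate the mean)
    self <- cbind(seq_along(idx), idx)
    z_block[self] <- 0
    out[idx] <- rowSums(z_block) / (V - 1L)
  }
  out
}

#' Build FC region maps for a cohort from BOLD series
#'
#' Convenience wrapper over [build_fc_map()] and [parcellate_volume()]: for
#' each subject, computes the voxel-wise average-connectivity volume over all
#' labelled voxels and parcellates it with the atlas, yielding a
#' `region_maps` object in Fisher-z units.
#'
#' @param bold output of [generate_bold()] (or any list with `series`,
#'   `subject_id`).
#' @param atlas the FC `regionage_atlas`.
#' @return a `region_maps` object (no ground-truth voxel sets: `truth` holds
#'   empty sets).
#' @export
fc_maps_from_bold <- function(bold, atlas) {
  stopifnot(inherits(atlas, "regionage_atlas"))
  all_idx <- unlist(atlas$voxel_indices, use.names = FALSE)
  n <- length(bold$series)
  region_ids <- as.character(atlas$regions$region_id)
  values <- lapply(atlas$regions$n_voxels,
                   function(V) matrix(NA_real_, n, V))
  names(values) <- region_ids
  for (i in seq_len(n)) {
    fc <- build_fc_map(bold$series[[i]])
    vol <- array(0, dim = atlas$dim)
    vol[all_idx] <- fc
    parts <- parcellate_volume(vol, atlas)
    for (key in region_ids) values[[key]][i, ] <- parts[[key]]
  }
  truth <- lapply(values, function(x) integer(0))
  structure(
    list(modality = atlas$modality, atlas = atlas,
         subject_id = bold$subject_id, values = values, truth = truth,
         signal = NULL),
    class = "region_maps"
  )
}
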