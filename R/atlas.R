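#' Synthetic label atlases and atlas construction from label volumes
#'
#' An atlas pairs a 3-D integer label volume with the list of regions it
#' defines. Region voxels are stored as sorted linear (column-major) indices
#' into the volume, which fixes a deterministic voxel order for every
#' downstream map. Voxels labelled 0 belong to no region and are ignored.
#'
#' @name atlas
NULL

#' Build an atlas from a label volume
#'
#' @param labels 3-D integer array; positive values are region labels, 0 is
#'   background.
#' @param modality one of "GM", "FC", "FA".
#' @param region_names optional character vector naming the distinct labels
#'   (in increasing label order).
#' @return an object of class `regionage_atlas` with fields `modality`,
#'   `dim`, `labels`, `regions` (data frame: region_id, name, n_voxels) and
#'   `voxel_indices` (named list of sorted linear indices).
#' @export
atlas_from_labels <- function(labels, modality = c("GM", "FC", "FA"),
                              region_names = NULL) {
  modality <- match.arg(modality)
  if (length(dim(labels)) != 3L) {
    stop("label volume must be a 3-D array", call. = FALSE)
  }
  lab <- as.integer(round(labels))
  ids <- sort(unique(lab[lab > 0L]))
  if (length(ids) == 0L) {
    stop("label volume defines no regions (no positive labels)", call. = FALSE)
  }
  if (is.null(region_names)) {
    region_names <- sprintf("%s_%03d", modality, ids)
  }
  if (length(region_names) != length(ids)) {
    stop("region_names length must match the number of distinct labels",
         call. = FALSE)
  }
  voxel_indices <- lapply(ids, function(id) sort(which(lab == id)))
  names(voxel_indices) <- as.character(ids)
  structure(
    list(
      modality = modality,
      dim = dim(labels),
      labels = array(lab, dim = dim(labels)),
      regions = data.frame(region_id = ids, name = region_names,
                           n_voxels = vapply(voxel_indices, length, 1L),
                           stringsAsFactors = FALSE),
      voxel_indices = voxel_indices
    ),
    class = "regionage_atlas"
  )
}

#' Construct a synthetic block-grid atlas
#'
#' Lays out `n_regions` rectangular blocks of `voxels_per_region` voxels on a
#' regular grid, mimicking the region counts of the parcellations used for
#' each modality (90 cerebral regions for GM and FC maps, 48 white-matter
#' tracts for FA maps). Blocks are padded with background voxels when
#' `voxels_per_region` has no exact cuboid factorisation, so the volume also
#' contains unlabelled voxels, as a real atlas does.
#'
#' @param modality one of "GM", "FC", "FA".
#' @param n_regions number of regions (default 90 for GM/FC, 48 for FA).
#' @param voxels_per_region voxels per region (default 200).
#' @return a `regionage_atlas`.
#' @export
make_grid_atlas <- function(modality = c("GM", "FC", "FA"),
                            n_regions = NULL, voxels_per_region = 200L) {
  modality <- match.arg(modality)
  if (is.null(n_regions)) {
    n_regions <- if (modality == "FA") 48L else 90L
  }
  n_regions <- as.integer(n_regions)
  voxels_per_region <- as.integer(voxels_per_region)
  if (n_regions <= 0L || voxels_per_region <= 0L) {
    stop("n_regions and voxels_per_region must be positive", call. = FALSE)
  }
  # near-cubic block large enough to hold the region
  bx <- max(1L, as.integer(ceiling(voxels_per_region^(1 / 3))))
  by <- max(1L, as.integer(ceiling(sqrt(voxels_per_region / bx))))
  bz <- as.integer(ceiling(voxels_per_region / (bx * by)))
  gx <- as.integer(ceiling(sqrt(n_regions)))
  gy <- as.integer(ceiling(n_regions / gx))
  dims <- c(gx * bx, gy * by, bz)
  labels <- array(0L, dim = dims)
  k <- 0L
  for (j in seq_len(gy)) {
    for (i in seq_len(gx)) {
      k <- k + 1L
      if (k > n_regions) break
      block <- array(0L, dim = c(bx, by, bz))
      block[seq_len(voxels_per_region)] <- k
      labels[(i - 1L) * bx + seq_len(bx),
             (j - 1L) * by + seq_len(by), ] <- block
    }
  }
  atlas_from_labels(labels, modality)
}

#' @export
print.regionage_atlas <- function(x, ...) {
  cat(sprintf("<regionage_atlas> %s: %d regions, volume %s, %d labelled voxels\n",
              x$modality, nrow(x$regions),
              paste(x$dim, collapse = "x"),
              sum(x$regions$n_voxels)))
  invisible(x)
}

#' Total number of labelled voxels in an atlas
#' @param atlas a `regionage_atlas`.
#' @return integer count.
#' @export
atlas_n_voxels <- function(atlas) {
  sum(atlas$regions$n_voxels)
}
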