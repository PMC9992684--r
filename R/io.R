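#' Volume and table input/output
#'
#' Subject maps travel as 3-D NIfTI volumes plus an integer NIfTI label
#' volume per atlas; subject metadata as TSV; ground truth and feature masks
#' as JSON. All readers/writers round-trip exactly through these helpers.
#'
#' @name regionage-io
NULL

#' Write an atlas label volume as NIfTI
#' @param atlas a `regionage_atlas`.
#' @param path output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_atlas_nifti <- function(atlas, path) {
  stopifnot(inherits(atlas, "regionage_atlas"))
  RNifti::writeNifti(atlas$labels, path, datatype = "int16")
  invisible(path)
}

#' Read an atlas from a NIfTI label volume
#' @param path NIfTI file with positive integer region labels.
#' @param modality one of "GM", "FC", "FA".
#' @return a `regionage_atlas`.
#' @export
read_atlas_nifti <- function(path, modality) {
  img <- RNifti::readNifti(path)
  atlas_from_labels(array(as.integer(round(img)), dim = dim(img)), modality)
}

#' Reassemble one subject's region maps into a volume and write as NIfTI
#'
#' Inverse of parcellation for synthetic data: places each region's voxel
#' values back at the atlas voxel indices (background voxels are 0).
#'
#' @param maps a `region_maps` object.
#' @param subject_index row index of the subject within `maps`.
#' @param path output NIfTI path.
#' @return `path`, invisibly.
#' @export
write_subject_volume <- function(maps, subject_index, path) {
  stopifnot(inherits(maps, "region_maps"))
  vol <- array(0, dim = maps$atlas$dim)
  for (key in names(maps$values)) {
    vol[maps$atlas$voxel_indices[[key]]] <- maps$values[[key]][subject_index, ]
  }
  RNifti::writeNifti(vol, path, datatype = "double")
  invisible(path)
}

#' Read a subject volume and parcellate it into a region-value list
#' @param path NIfTI volume path.
#' @param atlas a `regionage_atlas`.
#' @return named list (region id -> voxel values).
#' @export
read_subject_volume <- function(path, atlas) {
  img <- RNifti::readNifti(path)
  parcellate_volume(array(as.numeric(img), dim = dim(img)), atlas)
}

#' Write the subject metadata table as TSV
#' @param subjects subject data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_subjects_tsv <- function(subjects, path) {
  utils::write.table(subjects, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a subject metadata TSV
#' @param path TSV written by [write_subjects_tsv()].
#' @return subject data frame.
#' @export
read_subjects_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Serialize feature masks to JSON
#'
#' @param masks named list (region id -> `feature_mask`).
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_masks_json <- function(masks, path) {
  payload <- lapply(masks, function(m) {
    list(selected_voxels = m$selected_voxels,
         selection_counts = m$selection_counts)
  })
  jsonlite::write_json(payload, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read feature masks from JSON
#' @param path JSON written by [write_masks_json()].
#' @return named list of `feature_mask` objects.
#' @export
read_masks_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(payload, function(m) {
    structure(list(selected_voxels = as.integer(m$selected_voxels),
                   selection_counts = as.integer(m$selection_counts)),
              class = "feature_mask")
  })
}
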