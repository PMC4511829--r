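# NIfTI and text I/O. Standard formats go through RNifti; motion traces,
# manifests and feature tables are plain whitespace/tab-delimited text.

#' NIfTI input/output
#'
#' `write_bold_nifti()` stores a 4D series with its voxel size and TR in
#' the NIfTI pixdim; `read_bold_nifti()` restores it as a [bold_series].
#' `write_atlas_nifti()` / `read_atlas_nifti()` do the same for the integer
#' label field of a [labeled_atlas], using an integer datatype on disk.
#'
#' @param series A [bold_series].
#' @param file Path (`.nii` or `.nii.gz`).
#' @return Readers return a [bold_series] / [labeled_atlas]; writers return
#'   the path invisibly.
#' @export
write_bold_nifti <- function(series, file) {
  stopifnot(inherits(series, "bold_series"))
  img <- RNifti::asNifti(series$data, reference = list(
    pixdim = c(-1, series$voxel_size, series$tr, 0, 0, 0)))
  RNifti::writeNifti(img, file)
  invisible(file)
}

#' @rdname write_bold_nifti
#' @param tr Fallback TR in seconds when the file's pixdim lacks one.
#' @export
read_bold_nifti <- function(file, tr = NULL) {
  img <- RNifti::readNifti(file)
  if (length(dim(img)) != 4L) abort("expected a 4D NIfTI volume")
  pd <- RNifti::pixdim(img)
  tr <- if (length(pd) >= 4 && pd[4] > 0) pd[4] else tr %||% 2
  bold_series(array(as.numeric(img), dim(img)), tr = tr,
              voxel_size = pd[1:3])
}

#' @rdname write_bold_nifti
#' @param atlas A [labeled_atlas].
#' @export
write_atlas_nifti <- function(atlas, file) {
  stopifnot(inherits(atlas, "labeled_atlas"))
  img <- RNifti::asNifti(atlas$labels, reference = list(
    pixdim = c(-1, atlas$voxel_size, 0, 0, 0, 0)))
  RNifti::writeNifti(img, file, datatype = "int16")
  invisible(file)
}

#' @rdname write_bold_nifti
#' @export
read_atlas_nifti <- function(file) {
  img <- RNifti::readNifti(file)
  if (length(dim(img)) != 3L) abort("expected a 3D NIfTI volume")
  structure(list(labels = array(as.integer(img), dim(img)),
                 voxel_size = RNifti::pixdim(img)[1:3]),
            class = "labeled_atlas")
}

#' Motion-trace text files
#'
#' Six-column whitespace-delimited text, one row per acquired volume:
#' translations x, y, z in mm then rotations in degrees.
#'
#' @param trace Numeric matrix with 6 columns.
#' @param file Path.
#' @export
write_motion_trace <- function(trace, file) {
  write.table(format(trace, digits = 8), file, quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' @rdname write_motion_trace
#' @export
read_motion_trace <- function(file) {
  m <- as.matrix(read.table(file, header = FALSE))
  if (ncol(m) != 6L) abort("motion trace must have 6 columns")
  colnames(m) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  m
}

#' Write a synthetic cohort to disk
#'
#' One 4D NIfTI and one motion text file per subject plus a manifest TSV
#' (`subject_id`, `group`, `truth`, `seed`). Subjects are regenerated from
#' their seeds and streamed one at a time.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in cohort$manifest$subject_id) {
    sub <- subject_data(cohort, id)
    write_bold_nifti(sub$series, file.path(dir, paste0(id, "_bold.nii.gz")))
    write_motion_trace(sub$motion, file.path(dir, paste0(id, "_motion.txt")))
  }
  manifest_path <- file.path(dir, "manifest.tsv")
  write.table(cohort$manifest, manifest_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(manifest_path)
}
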