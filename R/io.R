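## File interfaces: TSV tables with header row, NIfTI volumes (via RNifti),
## and a JSON sidecar for generator ground truth.

#' Write / read a tab-separated table
#'
#' @param x Data frame.
#' @param path File path.
#' @return `read_tsv_table` returns a data frame.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv_table
#' @export
read_tsv_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write beta patterns in the compact tabular format
#'
#' Long format: one row per (run, condition, voxel) with the hemisphere,
#' ROI and condition labels, so patterns round-trip through plain text.
#'
#' @param betas A `beta_patterns` object.
#' @param path File path.
#' @return `read_beta_table` returns a `beta_patterns`.
#' @export
write_beta_table <- function(betas, path) {
  stopifnot(inherits(betas, "beta_patterns"))
  d <- dim(betas$values)
  g <- expand.grid(run = seq_len(d[1]), cond = seq_len(d[2]),
                   voxel = seq_len(d[3]), KEEP.OUT.ATTRS = FALSE)
  out <- data.frame(roi = betas$roi_name, hemisphere = betas$hemisphere,
                    run = g$run,
                    target = betas$condition_labels$target[g$cond],
                    context = betas$condition_labels$context[g$cond],
                    voxel_id = betas$voxel_ids[g$voxel],
                    value = as.vector(betas$values))
  write_tsv_table(out, path)
}

#' @rdname write_beta_table
#' @export
read_beta_table <- function(path) {
  x <- read_tsv_table(path)
  conds <- condition_table()
  runs <- sort(unique(x$run))
  vox <- sort(unique(x$voxel_id))
  vals <- array(NA_real_, c(length(runs), nrow(conds), length(vox)))
  ci <- match(paste(x$target, x$context),
              paste(conds$target, conds$context))
  vals[cbind(match(x$run, runs), ci, match(x$voxel_id, vox))] <- x$value
  new_beta_patterns(vals, conds, x$hemisphere[1], x$roi[1], vox)
}

#' Write / read a 3-D map as NIfTI
#'
#' @param arr 3-D numeric array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param affine 4x4 voxel-to-world matrix (2 mm isotropic default).
#' @return `read_nifti_map` returns the array with the affine as attribute
#'   `affine`.
#' @export
write_nifti_map <- function(arr, path, affine = diag(c(2, 2, 2, 1))) {
  img <- RNifti::asNifti(arr)
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_nifti_map
#' @export
read_nifti_map <- function(path) {
  img <- RNifti::readNifti(path)
  out <- array(as.numeric(img), dim = dim(img))
  attr(out, "affine") <- unclass(RNifti::xform(img))
  out
}

#' Write generator ground truth as a JSON sidecar
#'
#' @param gt A [ground_truth()].
#' @param path File path.
#' @return `read_ground_truth` returns a `ground_truth`.
#' @export
write_ground_truth <- function(gt, path) {
  stopifnot(inherits(gt, "ground_truth"))
  jsonlite::write_json(unclass(gt), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(ground_truth, x)
}
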