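#' Write a volume or 4-D series as NIfTI
#'
#' @param vol 3-D or 4-D numeric array.
#' @param path Output path (.nii or .nii.gz).
#' @param voxel_size Voxel edge lengths in mm.
#' @return The path, invisibly.
#' @export
write_nifti_volume <- function(vol, path, voxel_size = c(1, 1, 1)) {
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- if (length(dim(vol)) == 4L) c(voxel_size, 1)
                         else voxel_size
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume as a plain array
#' @param path NIfTI file path.
#' @return List with \code{data} (array) and \code{voxel_size}.
#' @export
read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  vs <- RNifti::pixdim(img)
  list(data = as.array(img), voxel_size = vs[seq_len(min(3, length(vs)))])
}

#' Write a diffusion scheme as FSL-dialect bval/bvec files
#'
#' \code{bval}: one row of b-values. \code{bvec}: three rows (x, y, z
#' components), one column per volume.
#'
#' @param scheme A \code{\link{make_scheme}} scheme.
#' @param prefix Output path prefix; writes \code{<prefix>.bval} and
#'   \code{<prefix>.bvec}.
#' @return The two paths, invisibly.
#' @export
write_bval_bvec <- function(scheme, prefix) {
  bval <- paste(format(scheme$b_values, trim = TRUE), collapse = " ")
  writeLines(bval, paste0(prefix, ".bval"))
  bv <- t(scheme$directions)
  lines <- apply(bv, 1, function(r)
    paste(format(r, trim = TRUE, digits = 10), collapse = " "))
  writeLines(lines, paste0(prefix, ".bvec"))
  invisible(paste0(prefix, c(".bval", ".bvec")))
}

#' Read FSL-dialect bval/bvec files
#' @param prefix Path prefix (expects \code{<prefix>.bval}, \code{<prefix>.bvec}).
#' @return A \code{diffusion_scheme}.
#' @export
read_bval_bvec <- function(prefix) {
  b <- scan(paste0(prefix, ".bval"), quiet = TRUE)
  v <- do.call(rbind, lapply(readLines(paste0(prefix, ".bvec")), function(l)
    scan(text = l, quiet = TRUE)))
  stopifnot(nrow(v) == 3L, ncol(v) == length(b))
  scheme <- list(b_values = b, directions = t(v))
  class(scheme) <- "diffusion_scheme"
  scheme
}

#' Write a labelled connectivity matrix as TSV
#'
#' Square matrix with ROI names as header row and first column, the exchange
#' format shared by FC matrices and structural connectomes.
#'
#' @param m Matrix with dimnames.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(roi = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a labelled connectivity matrix from TSV
#' @param path TSV path written by \code{\link{write_matrix_tsv}}.
#' @return Numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write streamlines as JSON-lines
#'
#' One JSON object per line: \code{{"points": [[x,y,z], ...], "length": mm}}.
#' A plain-text alternative to binary track formats.
#'
#' @param streamlines A \code{\link{track_streamlines}} result.
#' @param path Output path (.jsonl).
#' @return The path, invisibly.
#' @export
write_streamlines_jsonl <- function(streamlines, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(streamlines$points)) {
    writeLines(jsonlite::toJSON(list(
      points = unname(streamlines$points[[k]]),
      length = streamlines$lengths[[k]]), auto_unbox = TRUE, digits = 8), con)
  }
  invisible(path)
}

#' Read streamlines from JSON-lines
#' @param path Path written by \code{\link{write_streamlines_jsonl}}.
#' @return A \code{streamline_set}.
#' @export
read_streamlines_jsonl <- function(path) {
  lines <- readLines(path)
  pts <- lapply(lines, function(l) {
    o <- jsonlite::fromJSON(l)
    matrix(o$points, ncol = 3)
  })
  lens <- vapply(lines, function(l) jsonlite::fromJSON(l)$length, numeric(1),
                 USE.NAMES = FALSE)
  structure(list(points = pts, lengths = lens), class = "streamline_set")
}

#' Write per-subject covariates as TSV
#' @param tab Data frame with subject, group and covariate columns.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_covariates_tsv <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a complete synthetic study to disk
#'
#' Serializes an atlas (NIfTI label volume + ROI table TSV), optional
#' resting-state 4-D BOLD (NIfTI + nuisance TSV), phMRI sessions (per-subject
#' ROI series TSV + covariates TSV), DWI (NIfTI + bval/bvec) and a JSON
#' ground-truth sidecar.
#'
#' @param dir Output directory (created if missing).
#' @param atlas A \code{roi_atlas}.
#' @param rest Optional \code{\link{sim_rest_bold}} result.
#' @param phmri Optional \code{\link{sim_phmri}} result.
#' @param dwi Optional list with \code{volumes} (4-D array) and
#'   \code{scheme}.
#' @param ground_truth Optional list serialized as JSON.
#' @return The directory, invisibly.
#' @export
write_study <- function(dir, atlas, rest = NULL, phmri = NULL, dwi = NULL,
                        ground_truth = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_nifti_volume(atlas$label_volume, file.path(dir, "atlas.nii.gz"),
                     atlas$voxel_size)
  utils::write.table(atlas$roi_table, file.path(dir, "atlas_rois.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(rest)) {
    if (rest$series$kind == "voxel")
      write_nifti_volume(rest$series$data, file.path(dir, "rest_bold.nii.gz"),
                         atlas$voxel_size)
    else
      write_matrix_tsv(rest$series$data, file.path(dir, "rest_roi_bold.tsv"))
    utils::write.table(rest$series$nuisance, file.path(dir, "rest_nuisance.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(phmri)) {
    pdir <- file.path(dir, "phmri")
    dir.create(pdir, showWarnings = FALSE)
    covs <- list()
    for (s in phmri$sessions) {
      m <- s$series
      rownames(m) <- paste0("roi", seq_len(nrow(m)))
      write_matrix_tsv(m, file.path(pdir, paste0(s$subject_id, ".tsv")))
      covs[[s$subject_id]] <- data.frame(subject = s$subject_id,
                                         group = s$group, t(s$covariates))
    }
    write_covariates_tsv(do.call(rbind, covs), file.path(dir, "covariates.tsv"))
  }
  if (!is.null(dwi)) {
    write_nifti_volume(dwi$volumes, file.path(dir, "dwi.nii.gz"),
                       atlas$voxel_size)
    write_bval_bvec(dwi$scheme, file.path(dir, "dwi"))
  }
  if (!is.null(ground_truth))
    jsonlite::write_json(ground_truth, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  invisible(dir)
}
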