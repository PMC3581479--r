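#' Fisher-z functional connectivity matrix
#'
#' Pairwise Pearson correlation between ROI time courses, Fisher
#' z'-transformed (\code{atanh}). Correlations are clipped at
#' \code{1 - 1e-7} in magnitude before the transform so that degenerate
#' (perfectly correlated) inputs yield a large finite z' rather than an
#' error. The diagonal is marked missing.
#'
#' @param roi_ts ROI x time matrix, or an ROI-organized
#'   \code{\link{bold_series}}.
#' @param roi_ids Optional ROI identifiers (defaults to rownames / series
#'   ids).
#' @return An object of class \code{fc_matrix}: list with \code{z}
#'   (symmetric, diagonal \code{NA}), \code{r}, \code{roi_ids} and
#'   \code{n_frames_used}. Rows/columns of constant series are \code{NA}.
#' @export
fc_matrix <- function(roi_ts, roi_ids = NULL) {
  if (inherits(roi_ts, "bold_series")) {
    roi_ids <- roi_ids %||% roi_ts$roi_ids
    roi_ts <- roi_ts$data
  }
  stopifnot(is.matrix(roi_ts))
  if (ncol(roi_ts) < 3) stop("need at least 3 frames")
  roi_ids <- roi_ids %||% rownames(roi_ts) %||% as.character(seq_len(nrow(roi_ts)))
  sds <- apply(roi_ts, 1, stats::sd)
  const <- sds == 0 | !is.finite(sds)
  if (any(const))
    warning("constant series marked missing: ",
            paste(roi_ids[const], collapse = ", "))
  r <- suppressWarnings(stats::cor(t(roi_ts)))
  r[const, ] <- NA_real_; r[, const] <- NA_real_
  z <- atanh(pmax(pmin(r, 1 - 1e-7), -1 + 1e-7))
  diag(z) <- NA_real_; diag(r) <- NA_real_
  dimnames(z) <- dimnames(r) <- list(roi_ids, roi_ids)
  structure(list(z = z, r = r, roi_ids = roi_ids,
                 n_frames_used = ncol(roi_ts)),
            class = "fc_matrix")
}

#' @export
print.fc_matrix <- function(x, ...) {
  cat("fc_matrix:", length(x$roi_ids), "ROIs,", x$n_frames_used, "frames\n")
  invisible(x)
}

#' Voxelwise seed correlation map
#'
#' Fisher-z correlation between a seed region's signal and every voxel,
#' producing a connectivity map. Constant voxels get \code{NA}.
#'
#' @param series Voxel-organized \code{\link{bold_series}}.
#' @param seed_signal Numeric vector on the same time axis.
#' @return 3-D array of z' values.
#' @export
seed_map <- function(series, seed_signal) {
  stopifnot(inherits(series, "bold_series"), series$kind == "voxel")
  if (length(seed_signal) != n_frames(series))
    stop("seed signal and series must share the time axis")
  flat <- flat_data(series)
  sds <- apply(flat, 1, stats::sd)
  r <- suppressWarnings(as.vector(stats::cor(t(flat), seed_signal)))
  r[sds == 0 | !is.finite(sds)] <- NA_real_
  z <- atanh(pmax(pmin(r, 1 - 1e-7), -1 + 1e-7))
  array(z, dim = dim(series$data)[1:3])
}

#' Average functional connectivity over homologous seeds
#'
#' Reduces a full left/right FC matrix to per-ROI-pair intra- and
#' inter-hemispheric connectivity: the intra-hemispheric value of pair (A, B)
#' averages z(A_L, B_L) and z(A_R, B_R); the inter-hemispheric value averages
#' z(A_L, B_R) and z(A_R, B_L); the inter-hemispheric diagonal holds the
#' homotopic connectivity z(A_L, A_R). Pairs involving an excluded hemisphere
#' are missing.
#'
#' @param fc An \code{\link{fc_matrix}} over bilateral gray labels.
#' @param atlas The \code{\link{make_atlas}} atlas providing homolog pairing.
#' @param included Optional named logical (by label id) marking usable ROIs.
#' @return List of class \code{homologous_fc} with matrices \code{intra} and
#'   \code{inter} (ROI-name dimnames; \code{intra} diagonal \code{NA}).
#' @export
average_homologous <- function(fc, atlas, included = NULL) {
  stopifnot(inherits(fc, "fc_matrix"))
  tab <- atlas$roi_table[atlas$roi_table$tissue == "gray", ]
  lt <- tab[tab$hemisphere == "left", ]
  nm <- lt$name
  n <- length(nm)
  zget <- function(a, b) {
    ia <- match(as.character(a), fc$roi_ids)
    ib <- match(as.character(b), fc$roi_ids)
    if (is.na(ia) || is.na(ib)) return(NA_real_)
    if (!is.null(included) &&
        !(isTRUE(included[as.character(a)]) && isTRUE(included[as.character(b)])))
      return(NA_real_)
    fc$z[ia, ib]
  }
  intra <- inter <- matrix(NA_real_, n, n, dimnames = list(nm, nm))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    al <- lt$label_id[i]; ar <- lt$homolog_label_id[i]
    bl <- lt$label_id[j]; br <- lt$homolog_label_id[j]
    if (i != j)
      intra[i, j] <- mean(c(zget(al, bl), zget(ar, br)))
    inter[i, j] <- if (i == j) zget(al, ar)
                   else mean(c(zget(al, br), zget(ar, bl)))
  }
  structure(list(intra = intra, inter = inter, roi_names = nm),
            class = "homologous_fc")
}
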