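#' Gaussian spatial smoothing of a volume or 4-D series
#'
#' Separable Gaussian convolution with kernel renormalization at the volume
#' edges, parameterized by full width at half maximum in mm
#' (\eqn{\sigma = FWHM / 2\sqrt{2\ln 2} = FWHM/2.3548}).
#'
#' @param vol 3-D or 4-D numeric array (smoothing acts on the first three
#'   dimensions).
#' @param fwhm Full width at half maximum in mm (0 = no smoothing).
#' @param voxel_size Voxel edge lengths in mm.
#' @return Smoothed array of the same shape.
#' @export
gaussian_smooth <- function(vol, fwhm, voxel_size) {
  if (fwhm < 0) stop("fwhm must be non-negative")
  if (fwhm == 0) return(vol)
  sigma_vox <- (fwhm / (2 * sqrt(2 * log(2)))) / voxel_size
  d <- dim(vol)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    n <- d[ax]
    S <- outer(seq_len(n), seq_len(n),
               function(i, j) exp(-(i - j)^2 / (2 * s^2)))
    S <- S / rowSums(S)                    # renormalize truncated kernels
    perm <- c(ax, setdiff(seq_along(d), ax))
    a <- aperm(vol, perm)
    a <- array(S %*% matrix(a, n), dim = d[perm])
    vol <- aperm(a, order(perm))
  }
  vol
}

#' Spatial smoothing and linear-drift removal
#'
#' Applies Gaussian spatial smoothing at the stated FWHM (voxel-organized
#' input only; ROI-organized series are passed through unsmoothed) and
#' removes a per-series linear trend (intercept + slope), leaving each voxel
#' or ROI series zero-mean and drift-free.
#'
#' @param series A \code{\link{bold_series}}.
#' @param fwhm Smoothing kernel FWHM in mm (default 1.0).
#' @return A preprocessed \code{bold_series}.
#' @export
preprocess <- function(series, fwhm = 1.0) {
  stopifnot(inherits(series, "bold_series"))
  if (fwhm < 0) stop("fwhm must be non-negative")
  if (series$kind == "voxel" && fwhm > 0)
    series$data <- gaussian_smooth(series$data, fwhm, series$voxel_size)
  y <- t(flat_data(series))                       # time x space
  X <- cbind(1, series$frame_times)
  res <- y - X %*% qr.coef(qr(X), y)
  replace_data(series, t(res))
}

#' Nuisance regression
#'
#' Removes non-neuronal signal contributions by ordinary least-squares
#' projection of every voxel/ROI series onto the nuisance set stored in the
#' series (global mean signal, six motion parameter traces, linear trend)
#' plus an intercept. Residuals are orthogonal to every retained regressor.
#' Collinear nuisance columns are dropped with a warning.
#'
#' @param series A \code{\link{bold_series}} with a \code{nuisance} matrix.
#' @param include Optional character/integer selection of nuisance columns
#'   (e.g. to toggle global-signal regression off).
#' @return The residual \code{bold_series}.
#' @export
regress_nuisance <- function(series, include = NULL) {
  stopifnot(inherits(series, "bold_series"))
  if (is.null(series$nuisance)) stop("series carries no nuisance regressors")
  N <- series$nuisance
  if (!is.null(include)) N <- N[, include, drop = FALSE]
  X <- cbind(intercept = 1, N)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    drop_idx <- qx$pivot[(qx$rank + 1L):ncol(X)]
    warning("dropping ", length(drop_idx), " collinear nuisance column(s): ",
            paste(colnames(X)[drop_idx], collapse = ", "))
    X <- X[, -drop_idx, drop = FALSE]
    qx <- qr(X)
  }
  y <- t(flat_data(series))
  res <- y - X %*% qr.coef(qx, y)
  replace_data(series, t(res))
}

#' Zero-phase band-pass filter
#'
#' Retains low-frequency BOLD fluctuations between \code{low} and \code{high}
#' Hz using an ideal spectral mask (exactly zero phase: passband gain 1,
#' stopband gain 0). The defaults isolate the 0.01-0.1 Hz band conventionally
#' attributed to resting-state fluctuations.
#'
#' @param series A \code{\link{bold_series}}.
#' @param low Lower passband edge in Hz (DC removed whenever \code{low > 0}).
#' @param high Upper passband edge in Hz; must not exceed Nyquist.
#' @return The filtered \code{bold_series}.
#' @export
bandpass <- function(series, low = 0.01, high = 0.1) {
  stopifnot(inherits(series, "bold_series"))
  nyq <- 1 / (2 * series$tr)
  if (low < 0 || low >= high) stop("need 0 <= low < high")
  if (high > nyq + 1e-12)
    stop("high = ", high, " Hz exceeds the Nyquist frequency ", nyq, " Hz")
  y <- t(flat_data(series))                       # time x space
  nt <- nrow(y)
  f <- (seq_len(nt) - 1) / (nt * series$tr)
  f <- pmin(f, 1 / series$tr - f)                 # two-sided frequency axis
  keep <- f >= low - 1e-12 & f <= high + 1e-12
  Y <- stats::mvfft(y)
  Y[!keep, ] <- 0
  res <- Re(stats::mvfft(Y, inverse = TRUE)) / nt
  replace_data(series, t(res))
}

#' Extract ROI-mean time series
#'
#' Averages the voxel signals within every atlas label. ROIs represented by
#' fewer than \code{min_voxels} voxels on the series grid are flagged as
#' excluded (the default of 2 mirrors dropping structures spanning less than
#' two voxels, e.g. VTA, DRN, ventral OFC and frontal cortex at typical rodent
#' fMRI resolution); empty ROIs are excluded with a warning.
#'
#' @param series Voxel-organized \code{\link{bold_series}} aligned to the
#'   atlas grid.
#' @param atlas A \code{\link{make_atlas}} result.
#' @param min_voxels Minimum voxel count for inclusion (default 2).
#' @param tissue Which ROI tissue classes to extract (default gray).
#' @return List with \code{series} (ROI-organized \code{bold_series}, one row
#'   per ROI label), \code{included} (named logical) and \code{n_voxels}
#'   (named integer).
#' @export
roi_timeseries <- function(series, atlas, min_voxels = 2L, tissue = "gray") {
  stopifnot(inherits(series, "bold_series"), series$kind == "voxel")
  if (!all(dim(series$data)[1:3] == dim(atlas$label_volume)))
    stop("atlas label volume is not aligned to the series grid")
  tab <- atlas$roi_table[atlas$roi_table$tissue %in% tissue, ]
  lab <- as.vector(atlas$label_volume)
  flat <- flat_data(series)
  nvox <- integer(nrow(tab)); ts <- matrix(NA_real_, nrow(tab), n_frames(series))
  for (i in seq_len(nrow(tab))) {
    idx <- which(lab == tab$label_id[i])
    nvox[i] <- length(idx)
    if (length(idx) == 1L) ts[i, ] <- flat[idx, ]
    else if (length(idx) > 1L) ts[i, ] <- colMeans(flat[idx, , drop = FALSE])
  }
  included <- nvox >= min_voxels
  if (any(nvox == 0L))
    warning("empty ROI(s) excluded: ",
            paste(tab$name[nvox == 0L], collapse = ", "))
  names(included) <- names(nvox) <- tab$label_id
  rownames(ts) <- tab$label_id
  out <- bold_series(ts, tr = series$tr, frame_times = series$frame_times,
                     nuisance = series$nuisance, roi_ids = tab$label_id)
  list(series = out, included = included, n_voxels = nvox)
}
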