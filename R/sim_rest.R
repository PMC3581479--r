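#' Example inter-ROI correlation structure
#'
#' Builds a valid target correlation matrix over the gray-matter labels of an
#' atlas: strong homotopic (left-right) correlation, moderate within-module
#' correlation for three contiguous blocks of ROI pairs, and a weak baseline
#' elsewhere, projected onto the positive semi-definite cone and rescaled to
#' unit diagonal.
#'
#' @param atlas A \code{\link{make_atlas}} atlas.
#' @param homotopic Homotopic correlation (default 0.6).
#' @param within Within-module correlation (default 0.35).
#' @param base Baseline correlation (default 0.1).
#' @param n_modules Number of contiguous ROI-pair modules.
#' @return Correlation matrix with gray label ids as dimnames.
#' @export
example_fc_target <- function(atlas, homotopic = 0.6, within = 0.35,
                              base = 0.1, n_modules = 3L) {
  tab <- atlas$roi_table[atlas$roi_table$tissue == "gray", ]
  labs <- tab$label_id
  n <- length(labs)
  pair <- (seq_len(n) + 1L) %/% 2L                 # pair index per label
  module <- ((pair - 1L) %% n_modules) + 1L
  fc <- matrix(base, n, n)
  fc[outer(module, module, "==")] <- within
  hom <- match(tab$homolog_label_id, labs)
  fc[cbind(seq_len(n), hom)] <- homotopic
  fc[cbind(hom, seq_len(n))] <- homotopic
  diag(fc) <- 1
  # clip negative eigenvalues, rescale to a correlation matrix
  e <- eigen(fc, symmetric = TRUE)
  fc <- e$vectors %*% (pmax(e$values, 1e-6) * t(e$vectors))
  d <- sqrt(diag(fc))
  fc <- fc / outer(d, d)
  fc <- (fc + t(fc)) / 2
  diag(fc) <- 1
  dimnames(fc) <- list(labs, labs)
  fc
}

# band-limit white noise columns with the analysis band-pass, unit variance
band_limited_noise <- function(n_frames, n_series, tr, low, high) {
  z <- matrix(stats::rnorm(n_frames * n_series), n_frames, n_series)
  f <- (seq_len(n_frames) - 1) / (n_frames * tr)
  f <- pmin(f, 1 / tr - f)
  keep <- f >= low - 1e-12 & f <= high + 1e-12
  Z <- stats::mvfft(z)
  Z[!keep, ] <- 0
  z <- Re(stats::mvfft(Z, inverse = TRUE)) / n_frames
  sweep(z, 2, apply(z, 2, stats::sd), "/")
}

#' Simulate a resting-state BOLD session
#'
#' Generates band-limited (0.01-0.1 Hz) Gaussian ROI signals whose population
#' correlation matrix equals \code{fc_target} (white noise is band-pass
#' filtered with the same filter used in analysis, then mixed through the
#' matrix square root of the target), and optionally broadcasts them into a
#' voxel volume with additive voxel noise, a global signal, six motion traces
#' and a per-voxel linear drift. All injected nuisance components are stored
#' as known regressors on the returned series.
#'
#' @param atlas A \code{\link{make_atlas}} atlas.
#' @param fc_target Target correlation matrix over the gray labels (defaults
#'   to \code{\link{example_fc_target}}); must be a valid correlation matrix.
#' @param n_frames Number of frames (default 1200).
#' @param tr Repetition time in seconds (default 0.5).
#' @param noise List of component amplitudes relative to the unit-variance
#'   ROI signals: \code{voxel} (iid voxel noise SD), \code{global} (global
#'   signal SD), \code{motion} (motion artifact SD), \code{drift} (linear
#'   drift amplitude over the full run).
#' @param band Passband of the generated fluctuations in Hz.
#' @param voxel If \code{TRUE} return a voxel-organized 4-D series; otherwise
#'   an ROI-organized series of the clean signals.
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @return List with \code{series} (a \code{\link{bold_series}}) and
#'   \code{ground_truth} (fc_target, clean ROI signals, nuisance traces and
#'   per-voxel loadings).
#' @export
sim_rest_bold <- function(atlas, fc_target = NULL, n_frames = 1200L, tr = 0.5,
                          noise = list(voxel = 1, global = 0.5, motion = 0.3,
                                       drift = 1),
                          band = c(0.01, 0.1), voxel = TRUE, seed = 1L) {
  tab <- atlas$roi_table[atlas$roi_table$tissue == "gray", ]
  labs <- tab$label_id
  if (is.null(fc_target)) fc_target <- example_fc_target(atlas)
  n_roi <- length(labs)
  stopifnot(nrow(fc_target) == n_roi)
  check_symmetric(fc_target, tol = 1e-8, what = "fc_target")
  if (max(abs(diag(fc_target) - 1)) > 1e-8)
    stop("fc_target must have unit diagonal")
  ev <- eigen(fc_target, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("fc_target is not positive semi-definite (min eigenvalue ",
         signif(min(ev), 3), "); project it to the nearest correlation ",
         "matrix first (e.g. clip negative eigenvalues and rescale, ",
         "as example_fc_target() does)")

  with_seed(seed, {
    e <- eigen(fc_target, symmetric = TRUE)
    sq <- e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
    z <- band_limited_noise(n_frames, n_roi, tr, band[1], band[2])
    roi_sig <- z %*% sq                              # time x roi
    colnames(roi_sig) <- labs
    times <- (seq_len(n_frames) - 1) * tr

    # nuisance truth: global trace, six motion traces, linear trend
    global_tr <- band_limited_noise(n_frames, 1L, tr, 0.005, 0.15)[, 1]
    motion <- apply(matrix(stats::rnorm(n_frames * 6L), n_frames, 6L), 2,
                    function(w) {
                      m <- cumsum(w); m <- m - mean(m); m / stats::sd(m)
                    })
    colnames(motion) <- paste0("motion", 1:6)
    trend <- seq(-0.5, 0.5, length.out = n_frames)
    nuis <- cbind(global = global_tr, motion, trend = trend)

    gt <- list(fc_target = fc_target, roi_signals = t(roi_sig),
               nuisance = nuis, labels = labs)

    if (!voxel) {
      ser <- bold_series(t(roi_sig), tr = tr, frame_times = times,
                         nuisance = nuis, roi_ids = labs)
      return(list(series = ser, ground_truth = gt))
    }

    d <- dim(atlas$label_volume)
    nvox <- prod(d)
    lab_flat <- as.vector(atlas$label_volume)
    brain <- lab_flat > 0
    flat <- matrix(0, nvox, n_frames)
    idx <- match(lab_flat, labs)                     # NA outside gray ROIs
    has <- !is.na(idx)
    flat[has, ] <- t(roi_sig)[idx[has], ]
    mot_load <- matrix(stats::rnorm(nvox * 6L, sd = noise$motion), nvox, 6L)
    drift_slope <- stats::rnorm(nvox, sd = noise$drift)
    flat[brain, ] <- flat[brain, ] +
      noise$global * matrix(global_tr, sum(brain), n_frames, byrow = TRUE)
    flat <- flat + mot_load %*% t(motion) +
      outer(drift_slope, trend) +
      matrix(stats::rnorm(nvox * n_frames, sd = noise$voxel), nvox, n_frames)
    gt$motion_loadings <- mot_load
    gt$drift_slopes <- drift_slope
    ser <- bold_series(array(flat, dim = c(d, n_frames)), tr = tr,
                       frame_times = times, nuisance = nuis,
                       voxel_size = atlas$voxel_size)
    list(series = ser, ground_truth = gt)
  })
}
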