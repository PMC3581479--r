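#' Construct a pharmacological MRI session
#'
#' Holds one subject's ROI x time \%BOLD series around a drug challenge,
#' the frame grid, the injection time, per-subject physiological covariates
#' (arterial CO2 tension before the scan, mean arterial blood pressure before
#' and at peak response) and the group label.
#'
#' @param series ROI x time matrix of \%BOLD change relative to baseline.
#' @param tr_min Frame spacing in minutes.
#' @param baseline_frames,post_frames Frame counts before/after injection.
#' @param covariates Named numeric vector (\code{PaCO2_before},
#'   \code{MABP_before}, \code{MABP_peak}); entries may be \code{NA}.
#' @param group Group label (e.g. "WT"/"KO").
#' @param subject_id Subject identifier.
#' @return An object of class \code{phmri_session}.
#' @export
phmri_session <- function(series, tr_min, baseline_frames, post_frames,
                          covariates = c(PaCO2_before = NA_real_,
                                         MABP_before = NA_real_,
                                         MABP_peak = NA_real_),
                          group = NA_character_, subject_id = NA_character_) {
  stopifnot(is.matrix(series),
            ncol(series) == baseline_frames + post_frames)
  structure(list(
    series = series, tr_min = tr_min,
    frame_times = (seq_len(ncol(series)) - 1) * tr_min,
    injection_time = baseline_frames * tr_min,
    baseline_frames = baseline_frames, post_frames = post_frames,
    covariates = covariates, group = group, subject_id = subject_id),
    class = "phmri_session")
}

#' @export
print.phmri_session <- function(x, ...) {
  cat("phmri_session", x$subject_id, "(", x$group, "):", nrow(x$series),
      "ROIs,", x$baseline_frames, "+", x$post_frames,
      "frames @", x$tr_min, "min\n")
  invisible(x)
}

#' Simulate a two-group pharmacological MRI study
#'
#' Each subject x ROI series is a baseline offset plus a gamma-variate
#' response \eqn{\lambda g(t - t_{inj}; \alpha, \beta)} plus additive
#' covariate effects on the post-injection frames plus stationary AR(1)
#' noise (lag-1 correlation \code{ar1_phi} on the frame grid). Subject x ROI
#' parameters are log-normal around the configured group means (mean on the
#' natural scale, so sample means converge to the configuration as n grows).
#' Defaults emulate a 20-frame (10 min) baseline followed by 80 frames
#' (40 min) after injection, with physiological covariates drawn from
#' group-typical distributions.
#'
#' @param groups Named list of two group specs, each a list with \code{mean}
#'   (named c(alpha, beta, lam)) and \code{sd_log} (between-subject SD of the
#'   log parameters).
#' @param n_subjects Integer vector of per-group subject counts.
#' @param n_rois Number of ROIs per subject.
#' @param baseline_frames,post_frames Frame counts (defaults 20 and 80).
#' @param tr_min Frame spacing in minutes (default 0.5 = 30 s).
#' @param ar1_phi Lag-1 AR(1) noise correlation, in [0, 1).
#' @param noise_sd Stationary noise SD in \%BOLD.
#' @param offset_sd SD of the per-series baseline offset.
#' @param cov_means,cov_sds Per-group named lists of covariate means/SDs.
#' @param cov_coefs Fractional modulation of the response amplitude per unit
#'   of each (centred) covariate — physiological gain effects on the
#'   hemodynamic response.
#' @param prob_missing Probability that a covariate value is missing.
#' @param seed Integer seed.
#' @return List with \code{sessions} (list of \code{\link{phmri_session}})
#'   and \code{ground_truth} (per subject x ROI parameter array, configured
#'   group means, covariate truth, noise settings).
#' @export
sim_phmri <- function(groups = list(
                        WT = list(mean = c(alpha = 3, beta = 0.25, lam = 13),
                                  sd_log = c(0.15, 0.15, 0.35)),
                        KO = list(mean = c(alpha = 3, beta = 0.25, lam = 18),
                                  sd_log = c(0.15, 0.15, 0.35))),
                      n_subjects = c(12L, 15L), n_rois = 21L,
                      baseline_frames = 20L, post_frames = 80L,
                      tr_min = 0.5, ar1_phi = 0.3, noise_sd = 0.5,
                      offset_sd = 0.2,
                      cov_means = list(
                        WT = c(PaCO2_before = 39.2, MABP_before = 118.2,
                               MABP_peak = 117.1),
                        KO = c(PaCO2_before = 34.7, MABP_before = 126.8,
                               MABP_peak = 129.2)),
                      cov_sds = list(
                        WT = c(PaCO2_before = 2.5, MABP_before = 41.8,
                               MABP_peak = 39.2),
                        KO = c(PaCO2_before = 7.3, MABP_before = 26.3,
                               MABP_peak = 25.7)),
                      cov_coefs = c(PaCO2_before = 0.005, MABP_before = 0.001,
                                    MABP_peak = 0.001),
                      prob_missing = 0, seed = 1L) {
  if (post_frames < 1L)
    stop("post_frames must be >= 1: a response is unidentifiable without post-injection frames")
  if (ar1_phi < 0 || ar1_phi >= 1) stop("ar1_phi must lie in [0, 1)")
  stopifnot(length(groups) == length(n_subjects))
  gnames <- names(groups)
  nt <- baseline_frames + post_frames
  times <- (seq_len(nt) - 1) * tr_min
  t_inj <- baseline_frames * tr_min
  cov_names <- names(cov_coefs)
  # covariate specs align with groups by position (names are informational)
  cov_grand <- Reduce(`+`, lapply(cov_means, `[`, cov_names)) / length(cov_means)

  with_seed(seed, {
    sessions <- list()
    total <- sum(n_subjects)
    params <- array(NA_real_, dim = c(total, n_rois, 3L),
                    dimnames = list(NULL, NULL, c("alpha", "beta", "lam")))
    covs <- matrix(NA_real_, total, length(cov_names),
                   dimnames = list(NULL, cov_names))
    gains <- numeric(total)
    grp <- character(total)
    s <- 0L
    for (g in seq_along(groups)) {
      spec <- groups[[g]]
      mu_log <- log(spec$mean) - spec$sd_log^2 / 2   # natural-scale mean
      for (k in seq_len(n_subjects[g])) {
        s <- s + 1L
        grp[s] <- gnames[g]
        p <- matrix(NA_real_, n_rois, 3L)
        for (j in 1:3) p[, j] <- exp(stats::rnorm(n_rois, mu_log[j], spec$sd_log[j]))
        # shape must exceed 1 for a defined peak; redraw stragglers
        while (any(p[, 1] <= 1))
          p[p[, 1] <= 1, 1] <- exp(stats::rnorm(sum(p[, 1] <= 1),
                                                mu_log[1], spec$sd_log[1]))
        params[s, , ] <- p
        gi <- min(g, length(cov_means))
        x <- stats::rnorm(length(cov_names), cov_means[[gi]][cov_names],
                          cov_sds[[min(g, length(cov_sds))]][cov_names])
        covs[s, ] <- x
        # covariates modulate the response gain multiplicatively, so they
        # shift amplitude without injecting signal the gamma model cannot
        # represent
        cov_eff <- 1 + sum(cov_coefs * (x - cov_grand[cov_names]))
        gains[s] <- cov_eff
        resp <- t(vapply(seq_len(n_rois), function(r)
          gamma_response(times - t_inj, p[r, 1], p[r, 2], p[r, 3]),
          numeric(nt)))
        resp <- resp * cov_eff
        offs <- stats::rnorm(n_rois, 0, offset_sd)
        # stationary AR(1): x_t = phi x_{t-1} + sqrt(1-phi^2) w_t
        eps <- matrix(stats::rnorm(n_rois * nt), n_rois, nt)
        if (ar1_phi > 0) {
          eps[, 1] <- eps[, 1]
          for (tt in 2:nt)
            eps[, tt] <- ar1_phi * eps[, tt - 1] +
              sqrt(1 - ar1_phi^2) * eps[, tt]
        }
        y <- resp + offs + noise_sd * eps
        cv <- stats::setNames(x, cov_names)
        if (prob_missing > 0)
          cv[stats::runif(length(cv)) < prob_missing] <- NA_real_
        sessions[[s]] <- phmri_session(
          y, tr_min = tr_min, baseline_frames = baseline_frames,
          post_frames = post_frames, covariates = cv, group = gnames[g],
          subject_id = sprintf("%s%02d", gnames[g], k))
      }
    }
    gt <- list(params = params, group = grp,
               group_means = lapply(groups, `[[`, "mean"),
               sd_log = lapply(groups, `[[`, "sd_log"),
               covariates = covs, cov_coefs = cov_coefs, cov_gain = gains,
               ar1_phi = ar1_phi, noise_sd = noise_sd)
    list(sessions = sessions, ground_truth = gt)
  })
}
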