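#' Subject-level gamma-variate fits
#'
#' Nonlinear least-squares fit of \code{offset + gamma_response(t - t_inj)}
#' to each ROI series of a session, used both as a stand-alone estimate and
#' to seed the priors of the hierarchical model. Starting values come from a
#' method-of-moments heuristic (peak location/height of the lightly smoothed
#' post-injection curve); on non-convergence the heuristic start is returned
#' and flagged.
#'
#' @param session A \code{\link{phmri_session}}.
#' @return Data frame (class \code{subject_gamma_fit}) with one row per ROI:
#'   \code{roi}, \code{offset}, \code{alpha}, \code{beta}, \code{lam},
#'   \code{converged}.
#' @export
fit_subject_gamma <- function(session) {
  stopifnot(inherits(session, "phmri_session"))
  if (session$post_frames < 10L)
    stop("need at least 10 post-injection frames to fit the response")
  tt <- session$frame_times - session$injection_time
  nroi <- nrow(session$series)
  out <- data.frame(roi = seq_len(nroi), offset = NA_real_, alpha = NA_real_,
                    beta = NA_real_, lam = NA_real_, converged = FALSE)
  for (r in seq_len(nroi)) {
    y <- session$series[r, ]
    off0 <- mean(y[tt <= 0])
    post <- which(tt > 0)
    ys <- stats::filter(y[post] - off0, rep(1 / 5, 5), sides = 2)
    ys[is.na(ys)] <- 0
    ipk <- which.max(ys)
    tpk <- max(tt[post][ipk], 2 * session$tr_min)
    a0 <- 3
    b0 <- (a0 - 1) / tpk
    amp <- max(ys)
    l0 <- amp / gamma_peak_amplitude(a0, b0)
    if (!is.finite(l0) || abs(l0) < 1e-8) l0 <- 1e-3
    dat <- data.frame(y = y, tt = tt)
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ offset + lam * stats::dgamma(tt, shape = alpha, rate = beta),
        data = dat,
        start = list(offset = off0, lam = l0, alpha = a0, beta = b0),
        # rate below ~0.02/min is indistinguishable from drift within a
        # 40-minute post-injection window, and lets lam blow up on flat data
        lower = c(-Inf, -Inf, 1.01, 0.02),
        upper = c(Inf, Inf, 50, 20),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    cf <- if (is.null(fit)) NULL else stats::coef(fit)
    # a fitted peak far beyond the observation window means the optimizer
    # slid into an unidentifiable wide/spike regime; keep the honest start
    if (!is.null(cf) &&
        is.finite(gamma_peak_time(cf["alpha"], cf["beta"])) &&
        gamma_peak_time(cf["alpha"], cf["beta"]) > 2 * max(tt)) cf <- NULL
    if (is.null(cf)) {
      out[r, 2:5] <- c(off0, a0, b0, l0)
    } else {
      out[r, 2:5] <- c(cf["offset"], cf["alpha"], cf["beta"], cf["lam"])
      out$converged[r] <- TRUE
    }
  }
  class(out) <- c("subject_gamma_fit", "data.frame")
  out
}

# exact whitening of a continuous-time AR(1) process observed at `times`
# (Markov property: rho_i = phi^(t_i - t_(i-1)))
ar1_whiten <- function(M, times, phi) {
  M <- as.matrix(M)
  if (phi == 0) return(list(M = M, logdet_half = 0))
  rho <- phi^diff(times)
  sc <- sqrt(1 - rho^2)
  W <- M
  W[-1, ] <- (M[-1, , drop = FALSE] - rho * M[-nrow(M), , drop = FALSE]) / sc
  list(M = W, logdet_half = sum(log(sc)))
}

#' Generalized least squares with continuous-time AR(1) errors
#'
#' Fits \eqn{y = X\beta + \varepsilon} with
#' \eqn{Corr(\varepsilon_i, \varepsilon_j) = \phi^{|t_i - t_j|}};
#' \eqn{\phi} is estimated by profile maximum likelihood on [0, 1) unless
#' fixed. With \code{normalize = TRUE} the response and all non-constant
#' predictors are z-scored before fitting, so coefficients are reported on
#' the normalized scale.
#'
#' @param y Response vector.
#' @param X Design matrix (include the intercept column yourself, e.g. via
#'   \code{model.matrix}); must be full rank.
#' @param frame_times Observation times (units define the scale of
#'   \eqn{\phi}).
#' @param phi Fixed AR(1) parameter, or \code{NULL} to estimate.
#' @param normalize Z-score response and non-constant predictors.
#' @return List of class \code{gls_ar1_fit}: \code{coefficients}, \code{se},
#'   \code{t}, \code{p}, \code{phi}, \code{sigma2}, \code{df_residual},
#'   \code{logLik}.
#' @export
gls_ar1 <- function(y, X, frame_times, phi = NULL, normalize = FALSE) {
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n, length(frame_times) == n)
  if (qr(X)$rank < ncol(X))
    stop("design matrix is rank-deficient (duplicated or collinear predictors)")
  if (normalize) {
    y <- as.vector(scale(y))
    for (j in seq_len(ncol(X))) {
      if (stats::sd(X[, j]) > 0) X[, j] <- as.vector(scale(X[, j]))
    }
  }
  fit_at <- function(ph) {
    wy <- ar1_whiten(y, frame_times, ph)
    wX <- ar1_whiten(X, frame_times, ph)
    qx <- qr(wX$M)
    beta <- qr.coef(qx, wy$M)
    res <- wy$M - wX$M %*% beta
    rss <- sum(res^2)
    # profile log-likelihood (sigma^2 profiled out)
    ll <- -n / 2 * log(rss / n) - wy$logdet_half
    list(beta = beta, rss = rss, ll = ll, qx = qx)
  }
  if (is.null(phi)) {
    opt <- stats::optimize(function(ph) -fit_at(ph)$ll,
                           interval = c(0, 0.999), tol = 1e-6)
    phi <- opt$minimum
    # snap to 0 when the boundary value is at least as good
    if (fit_at(0)$ll >= -opt$objective) phi <- 0
    if (phi > 0.99) warning("estimated phi near unit root (", signif(phi, 4), ")")
  }
  f <- fit_at(phi)
  p <- ncol(X)
  sigma2 <- f$rss / (n - p)
  XtXinv <- chol2inv(qr.R(f$qx))
  se <- sqrt(pmax(diag(XtXinv), 0) * sigma2)
  tval <- as.vector(f$beta) / se
  cn <- colnames(X) %||% paste0("x", seq_len(p))
  structure(list(
    coefficients = stats::setNames(as.vector(f$beta), cn),
    se = stats::setNames(se, cn), t = stats::setNames(tval, cn),
    p = stats::setNames(2 * stats::pt(-abs(tval), n - p), cn),
    phi = phi, sigma2 = sigma2, df_residual = n - p, logLik = f$ll),
    class = "gls_ar1_fit")
}

#' Voxel-level phMRI design matrix
#'
#' Columns: (1) a representative gamma-variate response curve fitted to the
#' grand-mean time course; (2) the six frame-by-frame motion parameters;
#' (3) the first \code{n_svd} left singular vectors of the matrix of
#' per-subject mean responses minus the representative curve (capturing
#' between-subject variation in response evolution). The SVD columns are
#' mutually orthonormal.
#'
#' @param series_set Subjects x time matrix of mean \%BOLD time courses.
#' @param motion Time x 6 motion-parameter matrix.
#' @param tr_min Frame spacing in minutes.
#' @param baseline_frames Frames before injection.
#' @param n_svd Number of SVD components (default 3; reduced with a warning
#'   when there are fewer subjects).
#' @return Time x (1 + 6 + n_svd) design matrix with an attribute
#'   \code{"degenerate"} flagging a near-zero residual matrix.
#' @export
build_design_matrix <- function(series_set, motion, tr_min, baseline_frames,
                                n_svd = 3L) {
  series_set <- as.matrix(series_set)
  nt <- ncol(series_set)
  ns <- nrow(series_set)
  motion <- as.matrix(motion)
  stopifnot(nrow(motion) == nt, ncol(motion) == 6L)
  if (ns < n_svd) {
    warning("fewer subjects (", ns, ") than SVD components; reducing n_svd")
    n_svd <- ns
  }
  grand <- colMeans(series_set)
  ses <- phmri_session(matrix(grand, 1), tr_min = tr_min,
                       baseline_frames = baseline_frames,
                       post_frames = nt - baseline_frames)
  fit <- fit_subject_gamma(ses)
  tt <- ses$frame_times - ses$injection_time
  rep_curve <- fit$offset[1] +
    gamma_response(tt, fit$alpha[1], fit$beta[1], fit$lam[1])
  resid <- t(series_set) - rep_curve                # time x subjects
  degenerate <- sqrt(mean(resid^2)) < 1e-8 * max(1, sqrt(mean(series_set^2)))
  if (degenerate)
    warning("per-subject responses are (near) identical; SVD columns uninformative")
  sv <- svd(resid, nu = n_svd, nv = 0)
  X <- cbind(response = rep_curve, motion, sv$u)
  colnames(X) <- c("response", paste0("motion", 1:6), paste0("svd", seq_len(n_svd)))
  attr(X, "degenerate") <- degenerate
  X
}

#' Voxel-level GLM with second-level group test
#'
#' First level: per-subject, per-voxel GLS with continuous-time AR(1) errors
#' on \code{cbind(1, design)}; the coefficient of the representative-response
#' column is kept. Second level: per-voxel linear model of these response
#' coefficients on group plus physiological covariates (missing covariates
#' imputed by group means); the group t-statistic map is returned for
#' cluster-extent correction.
#'
#' @param voxel_series List (one per subject) of voxel x time matrices.
#' @param design Shared design matrix from \code{\link{build_design_matrix}}.
#' @param groups Group label per subject (two levels).
#' @param covariates Data frame of per-subject covariates (may contain NA).
#' @param frame_times Frame times (minutes).
#' @param phi Fixed first-level AR(1) parameter, or NULL to estimate per
#'   voxel.
#' @return List with \code{coef} (subjects x voxels response coefficients),
#'   \code{t_group}, \code{p_group} (per voxel) and \code{df}.
#' @export
voxel_glm_group <- function(voxel_series, design, groups, covariates,
                            frame_times, phi = NULL) {
  ns <- length(voxel_series)
  nv <- nrow(voxel_series[[1]])
  groups <- as.factor(groups)
  stopifnot(length(groups) == ns, nlevels(groups) == 2L)
  X1 <- cbind(intercept = 1, design)
  cf <- matrix(NA_real_, ns, nv)
  for (s in seq_len(ns)) {
    ys <- voxel_series[[s]]
    for (v in seq_len(nv)) {
      f <- gls_ar1(ys[v, ], X1, frame_times, phi = phi)
      cf[s, v] <- f$coefficients["response"]
    }
  }
  covariates <- impute_group_mean(covariates, as.character(groups))
  X2 <- stats::model.matrix(~ groups + ., data = covariates)
  qx <- qr(X2)
  beta <- qr.coef(qx, cf)
  res <- cf - X2 %*% beta
  df <- ns - ncol(X2)
  sig2 <- colSums(res^2) / df
  XtXinv <- chol2inv(qr.R(qx))
  gi <- 2L                                          # group contrast column
  se <- sqrt(XtXinv[gi, gi] * sig2)
  tg <- beta[gi, ] / se
  list(coef = cf, t_group = tg,
       p_group = 2 * stats::pt(-abs(tg), df), df = df)
}

#' Linear mixed-model group test on per-ROI response summaries
#'
#' Tests an overall group difference in a per-subject x ROI summary (AUC or
#' peak amplitude) with a linear mixed model: group and physiological
#' covariates as fixed effects and a random intercept per subject capturing
#' the ROIs-per-subject structure. Missing covariates are imputed by group
#' means.
#'
#' @param tab Data frame with columns \code{subject}, \code{roi},
#'   \code{value}, \code{group} and the covariate columns.
#' @param covariate_names Covariate columns to adjust for (default the three
#'   physiological covariates).
#' @return List: \code{estimate}, \code{se}, \code{df}, \code{t}, \code{p}
#'   for the group fixed effect, plus \code{ranef_sd} and the fitted
#'   \code{model}. When the estimated random-effect SD is (near) zero the
#'   fit coincides with an ordinary regression; this is noted in
#'   \code{note}.
#' @export
mixed_model_group_test <- function(tab,
                                   covariate_names = c("PaCO2_before",
                                                       "MABP_before",
                                                       "MABP_peak")) {
  stopifnot(all(c("subject", "roi", "value", "group") %in% names(tab)))
  covariate_names <- intersect(covariate_names, names(tab))
  if (length(unique(tab$roi)) < 2L)
    stop("need at least 2 ROIs per subject")
  if (length(covariate_names)) {
    sub_tab <- unique(tab[, c("subject", "group", covariate_names)])
    sub_tab[covariate_names] <-
      impute_group_mean(sub_tab[covariate_names], sub_tab$group)
    tab <- merge(tab[, setdiff(names(tab), covariate_names)], sub_tab,
                 by = c("subject", "group"), sort = FALSE)
  }
  fml <- stats::as.formula(paste(
    "value ~ group",
    if (length(covariate_names))
      paste("+", paste(covariate_names, collapse = " + ")) else ""))
  m <- nlme::lme(fml, random = ~ 1 | subject, data = tab, method = "REML")
  tt <- summary(m)$tTable
  gi <- grep("^group", rownames(tt))[1]
  ranef_sd <- as.numeric(nlme::VarCorr(m)["(Intercept)", "StdDev"])
  note <- if (ranef_sd < 1e-6)
    "random-effect variance ~ 0; estimates coincide with ordinary regression"
  else NA_character_
  list(estimate = tt[gi, "Value"], se = tt[gi, "Std.Error"],
       df = tt[gi, "DF"], t = tt[gi, "t-value"], p = tt[gi, "p-value"],
       ranef_sd = ranef_sd, note = note, model = m)
}
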