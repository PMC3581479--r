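#' Split-chain R-hat convergence diagnostic
#'
#' Potential scale reduction factor computed after splitting each chain in
#' half (so within-chain trends inflate the statistic).
#'
#' @param draws Iterations x chains matrix of posterior draws.
#' @return R-hat (>= 1; values above ~1.1 indicate non-convergence).
#' @export
rhat <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws) %/% 2L
  if (n < 2L) return(NA_real_)
  halves <- do.call(cbind, lapply(seq_len(ncol(draws)), function(j)
    cbind(draws[seq_len(n), j], draws[n + seq_len(n), j])))
  m <- ncol(halves)
  means <- colMeans(halves)
  vars <- apply(halves, 2, stats::var)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Hierarchical Bayesian gamma-variate fit
#'
#' Fits every subject x ROI series with
#' \code{offset + lam * g(t - t_inj; alpha, beta)} where the log-parameters
#' (log alpha, log beta, log lam) are drawn from group-level normal
#' distributions — the hierarchy constrains individual fits and stabilizes
#' them in noise. Errors are stationary AR(1) on the frame grid with a
#' global lag-1 correlation \code{phi} estimated alongside the other
#' parameters (set \code{ar1 = FALSE} for iid errors). Sampling is
#' Metropolis-within-Gibbs, vectorized over all series: random-walk updates
#' for the log-parameters (componentwise plus a joint shape/rate ridge
#' move), the group-level SDs and \code{phi}; conjugate updates for offsets,
#' per-ROI noise variances and group-level means. Priors on the group-level
#' means are normal, centred on the median of initial subject-level fits
#' with SD \code{prior_sd_scale} times their IQR; group-level SDs are
#' half-normal.
#'
#' Per draw, total activation (AUC) equals the scale \code{lam} exactly
#' (gamma-density normalization) and the peak amplitude follows the closed
#' form \eqn{\lambda\beta(\alpha-1)^{\alpha-1}e^{-(\alpha-1)}/\Gamma(\alpha)}.
#' Group-level mean parameters are reported on the natural scale as
#' \eqn{\exp(\mu + \tau^2/2)} (the mean of the implied log-normal).
#'
#' @param sessions List of \code{\link{phmri_session}} objects (>= 2 subjects
#'   per group for group comparisons).
#' @param chains Number of MCMC chains (>= 3 recommended).
#' @param iter Iterations per chain (first half discarded as burn-in).
#' @param thin Keep every \code{thin}-th post-burn-in draw.
#' @param seed Integer seed.
#' @param prior_sd_scale Prior SD multiplier on the IQR of initial fits.
#' @param tau_scale Scale of the half-normal prior on group-level SDs.
#' @param fix_tau Optional fixed group-level SDs (length 3; e.g. large values
#'   to flatten the hierarchy).
#' @param ar1 Model the noise as stationary AR(1) with estimated global
#'   lag-1 correlation (default TRUE).
#' @return Object of class \code{phmri_posterior}: draws of group-level
#'   means/SDs, natural-scale group means and group differences with 95\%
#'   credible intervals, posterior-mean subject x ROI parameters with AUC
#'   and peak amplitude, the posterior mean of \code{phi}, R-hat per
#'   group-level parameter and a \code{converged} flag (any R-hat > 1.1
#'   flags the fit).
#' @export
fit_hierarchical <- function(sessions, chains = 3L, iter = 2000L, thin = 1L,
                             seed = 1L, prior_sd_scale = 10,
                             tau_scale = 1, fix_tau = NULL, ar1 = TRUE) {
  stopifnot(length(sessions) >= 1L, chains >= 1L, iter >= 20L)
  S <- length(sessions)
  R <- nrow(sessions[[1]]$series)
  tt <- sessions[[1]]$frame_times - sessions[[1]]$injection_time
  grp <- vapply(sessions, `[[`, character(1), "group")
  gf <- factor(grp, levels = unique(grp))
  G <- nlevels(gf)
  n <- S * R
  roi_of <- rep(seq_len(R), S)
  grp_of <- rep(as.integer(gf), each = R)
  Y <- do.call(rbind, lapply(sessions, `[[`, "series"))
  post <- tt > 0
  tpost <- tt[post]
  Tn <- ncol(Y); Tp <- sum(post)

  # initial subject-level fits seed both the chains and the priors
  init_fits <- lapply(sessions, fit_subject_gamma)
  est <- do.call(rbind, lapply(init_fits, function(f)
    as.matrix(f[, c("alpha", "beta", "lam")])))
  offs0 <- unlist(lapply(init_fits, `[[`, "offset"))
  clip <- cbind(pmin(pmax(est[, 1], 1.05), 45),
                pmin(pmax(est[, 2], 2e-3), 15),
                pmax(est[, 3], 1e-2))
  theta0 <- log(clip)
  m0 <- s0 <- numeric(3)
  for (k in 1:3) {
    v <- theta0[, k]
    m0[k] <- stats::median(v)
    s0[k] <- prior_sd_scale * stats::IQR(v)
    if (s0[k] <= 1e-6) s0[k] <- 1
  }

  curve_of <- function(th) {
    # n x Tp response matrix; shape/rate vectors recycle down columns
    tm <- matrix(tpost, n, Tp, byrow = TRUE)
    exp(th[, 3]) * stats::dgamma(tm, shape = exp(th[, 1]), rate = exp(th[, 2]))
  }
  resid_of <- function(resp, cc) {
    E <- Y - cc
    E[, post] <- E[, post] - resp
    E
  }
  # whitened residual sum of squares under stationary AR(1)
  ssw_of <- function(E, phi) {
    if (phi == 0) return(rowSums(E^2))
    D <- (E[, -1, drop = FALSE] - phi * E[, -Tn, drop = FALSE]) /
      sqrt(1 - phi^2)
    E[, 1]^2 + rowSums(D^2)
  }

  # initial lag-1 residual autocorrelation seeds phi
  E0 <- resid_of(curve_of(theta0), offs0)
  phi0 <- if (ar1) {
    r <- sum(E0[, -1] * E0[, -Tn]) / sum(E0^2)
    min(max(r, 0), 0.9)
  } else 0

  n_keep <- (iter - iter %/% 2L) %/% thin
  mu_draws <- array(NA_real_, c(n_keep, chains, G, 3))
  tau_draws <- array(NA_real_, c(n_keep, chains, 3))
  phi_draws <- matrix(NA_real_, n_keep, chains)
  sub_sum <- array(0, c(n, 5))                      # alpha beta lam auc peak
  n_sub <- 0L

  old_rng <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_rng))
    assign(".Random.seed", old_rng, envir = globalenv()), add = TRUE)

  for (ch in seq_len(chains)) {
    set.seed(seed + 7919L * ch)
    theta <- theta0 + matrix(stats::rnorm(3L * n, 0, 0.05), n, 3L)
    cc <- offs0 + stats::rnorm(n, 0, 0.02)
    phi <- phi0
    resp <- curve_of(theta)
    E <- resid_of(resp, cc)
    SSw <- ssw_of(E, phi)
    sigma2_r <- pmax(rowsum(SSw, roi_of)[, 1] / (S * Tn), 1e-6)
    sig_ser <- sigma2_r[roi_of]
    mu <- matrix(0, G, 3)
    for (g in seq_len(G)) for (k in 1:3)
      mu[g, k] <- mean(theta[grp_of == g, k])
    tau <- if (is.null(fix_tau))
      pmax(apply(theta, 2, stats::sd), 0.05) else fix_tau
    sc <- c(0.08, 0.08, 0.08)                       # RW proposal scales
    sc_j <- 0.15                                    # joint (log a, log b) move
    sc_phi <- 0.05
    sc_g <- matrix(0.05, 2, G)                      # group-shift move scales
    acc <- integer(4); acc_phi <- 0L; acc_g <- matrix(0L, 2, G)
    keep_i <- 0L
    burn <- iter %/% 2L

    for (it in seq_len(iter)) {
      for (k in 1:3) {
        prop <- theta[, k] + stats::rnorm(n, 0, sc[k])
        if (k == 3L) {
          resp_p <- resp * exp(prop - theta[, 3L])
        } else {
          th_p <- theta; th_p[, k] <- prop
          resp_p <- curve_of(th_p)
        }
        E_p <- E
        E_p[, post] <- E_p[, post] + (resp - resp_p)
        SSw_p <- ssw_of(E_p, phi)
        mu_k <- mu[cbind(grp_of, rep(k, n))]
        logacc <- -(SSw_p - SSw) / (2 * sig_ser) -
          ((prop - mu_k)^2 - (theta[, k] - mu_k)^2) / (2 * tau[k]^2)
        take <- log(stats::runif(n)) < logacc
        if (any(take)) {
          theta[take, k] <- prop[take]
          resp[take, ] <- resp_p[take, , drop = FALSE]
          E[take, ] <- E_p[take, , drop = FALSE]
          SSw[take] <- SSw_p[take]
        }
        acc[k] <- acc[k] + sum(take)
      }
      # joint move along the (log alpha, log beta) ridge: shape and rate are
      # strongly correlated through the peak time, so componentwise walks
      # alone mix slowly
      {
        eps <- stats::rnorm(n, 0, sc_j)
        th_p <- theta
        th_p[, 1] <- theta[, 1] + eps
        th_p[, 2] <- theta[, 2] + eps
        resp_p <- curve_of(th_p)
        E_p <- E
        E_p[, post] <- E_p[, post] + (resp - resp_p)
        SSw_p <- ssw_of(E_p, phi)
        mu1 <- mu[cbind(grp_of, rep(1L, n))]
        mu2 <- mu[cbind(grp_of, rep(2L, n))]
        logacc <- -(SSw_p - SSw) / (2 * sig_ser) -
          ((th_p[, 1] - mu1)^2 - (theta[, 1] - mu1)^2) / (2 * tau[1]^2) -
          ((th_p[, 2] - mu2)^2 - (theta[, 2] - mu2)^2) / (2 * tau[2]^2)
        take <- log(stats::runif(n)) < logacc
        if (any(take)) {
          theta[take, 1:2] <- th_p[take, 1:2]
          resp[take, ] <- resp_p[take, , drop = FALSE]
          E[take, ] <- E_p[take, , drop = FALSE]
          SSw[take] <- SSw_p[take]
        }
        acc[4] <- acc[4] + sum(take)
      }
      # collective group-shift moves: translate a group's mu and all of its
      # subject-level parameters together (within-group deviations, and so
      # the tau likelihood, are unchanged) — a hierarchical-centering move
      # that decouples group-mean mixing from subject-level mixing
      for (g in seq_len(G)) {
        idx <- which(grp_of == g)
        for (mv in 1:2) {
          del <- stats::rnorm(1, 0, sc_g[mv, g])
          th_p <- theta
          if (mv == 1L) {                           # scale shift
            th_p[idx, 3] <- theta[idx, 3] + del
            resp_p <- resp[idx, , drop = FALSE] * exp(del)
            dprior <- -((mu[g, 3] + del - m0[3])^2 -
                          (mu[g, 3] - m0[3])^2) / (2 * s0[3]^2)
          } else {                                  # shape/rate ridge shift
            th_p[idx, 1] <- theta[idx, 1] + del
            th_p[idx, 2] <- theta[idx, 2] + del
            resp_p <- curve_of(th_p)[idx, , drop = FALSE]
            dprior <- -((mu[g, 1] + del - m0[1])^2 -
                          (mu[g, 1] - m0[1])^2) / (2 * s0[1]^2) -
              ((mu[g, 2] + del - m0[2])^2 -
                 (mu[g, 2] - m0[2])^2) / (2 * s0[2]^2)
          }
          E_p <- E[idx, , drop = FALSE]
          E_p[, post] <- E_p[, post] + (resp[idx, , drop = FALSE] - resp_p)
          SSw_p <- ssw_of(E_p, phi)
          logacc <- -sum((SSw_p - SSw[idx]) / (2 * sig_ser[idx])) + dprior
          if (log(stats::runif(1)) < logacc) {
            theta <- th_p
            resp[idx, ] <- resp_p
            E[idx, ] <- E_p
            SSw[idx] <- SSw_p
            if (mv == 1L) mu[g, 3] <- mu[g, 3] + del
            else { mu[g, 1] <- mu[g, 1] + del; mu[g, 2] <- mu[g, 2] + del }
            acc_g[mv, g] <- acc_g[mv, g] + 1L
          }
        }
      }
      # conjugate offset update under the whitened model (flat prior)
      A <- Y
      A[, post] <- A[, post] - resp
      uu <- 1 + (Tn - 1) * (1 - phi) / (1 + phi)
      rdot <- A[, 1] +
        rowSums(A[, -1, drop = FALSE] - phi * A[, -Tn, drop = FALSE]) /
        (1 + phi)
      cc <- stats::rnorm(n, rdot / uu, sqrt(sig_ser / uu))
      E <- A - cc                                    # residuals on raw scale
      SSw <- ssw_of(E, phi)
      # conjugate per-ROI noise variance
      SS_r <- rowsum(SSw, roi_of)[, 1]
      sigma2_r <- 1 / stats::rgamma(R, 0.001 + S * Tn / 2,
                                    rate = 0.001 + SS_r / 2)
      sig_ser <- sigma2_r[roi_of]
      # global AR(1) correlation: random walk on [0, 0.95]
      if (ar1) {
        phi_p <- phi + stats::rnorm(1, 0, sc_phi)
        if (phi_p >= 0 && phi_p <= 0.95) {
          SSw_p <- ssw_of(E, phi_p)
          dll <- -n * (Tn - 1) / 2 *
            (log(1 - phi_p^2) - log(1 - phi^2)) -
            sum((SSw_p - SSw) / (2 * sig_ser))
          if (log(stats::runif(1)) < dll) {
            phi <- phi_p
            SSw <- SSw_p
            acc_phi <- acc_phi + 1L
          }
        }
      }
      # conjugate group-level means
      for (g in seq_len(G)) {
        idx <- grp_of == g
        ng <- sum(idx)
        for (k in 1:3) {
          prec <- 1 / s0[k]^2 + ng / tau[k]^2
          mn <- (m0[k] / s0[k]^2 + sum(theta[idx, k]) / tau[k]^2) / prec
          mu[g, k] <- stats::rnorm(1, mn, sqrt(1 / prec))
        }
      }
      # group-level SDs, half-normal prior: independence MH with the
      # likelihood-implied inverse-gamma as proposal, so the acceptance
      # ratio reduces to the prior ratio and mixing is near-perfect
      if (is.null(fix_tau)) {
        for (k in 1:3) {
          dev2 <- sum((theta[, k] - mu[cbind(grp_of, rep(k, n))])^2)
          tau_p <- sqrt(1 / stats::rgamma(1, (n - 1) / 2, rate = dev2 / 2))
          if (is.finite(tau_p) && tau_p > 0 &&
              log(stats::runif(1)) <
                -(tau_p^2 - tau[k]^2) / (2 * tau_scale^2))
            tau[k] <- tau_p
        }
      }
      # adapt proposal scales during burn-in
      if (it <= burn && it %% 50L == 0L) {
        rate <- acc / (50 * n)
        sc <- sc * exp(0.5 * (rate[1:3] - 0.3))
        sc_j <- sc_j * exp(0.5 * (rate[4] - 0.3))
        if (ar1) sc_phi <- sc_phi * exp(0.5 * (acc_phi / 50 - 0.4))
        sc_g <- sc_g * exp(0.5 * (acc_g / 50 - 0.3))
        acc <- integer(4); acc_phi <- 0L; acc_g <- matrix(0L, 2, G)
      }
      if (it > burn && (it - burn) %% thin == 0L) {
        keep_i <- keep_i + 1L
        mu_draws[keep_i, ch, , ] <- mu
        tau_draws[keep_i, ch, ] <- tau
        phi_draws[keep_i, ch] <- phi
        al <- exp(theta[, 1]); be <- exp(theta[, 2]); la <- exp(theta[, 3])
        sub_sum <- sub_sum + cbind(al, be, la, la,
                                   gamma_peak_amplitude(al, be, la))
        n_sub <- n_sub + 1L
      }
    }
  }

  # natural-scale group means exp(mu + tau^2/2) and group differences
  gm_draws <- array(NA_real_, c(n_keep, chains, G, 3))
  for (g in seq_len(G)) for (k in 1:3)
    gm_draws[, , g, k] <- exp(mu_draws[, , g, k] + tau_draws[, , k]^2 / 2)
  param_names <- c("alpha", "beta", "lam")
  group_names <- levels(gf)

  rh <- matrix(NA_real_, G + 1L, 3,
               dimnames = list(c(group_names, "tau"), param_names))
  for (k in 1:3) {
    for (g in seq_len(G)) rh[g, k] <- rhat(mu_draws[, , g, k, drop = TRUE])
    rh[G + 1L, k] <- if (is.null(fix_tau))
      rhat(tau_draws[, , k, drop = TRUE]) else NA_real_
  }
  converged <- all(rh[is.finite(rh)] < 1.1)

  group_mean <- group_sd <- matrix(NA_real_, G, 3,
                                   dimnames = list(group_names, param_names))
  for (g in seq_len(G)) for (k in 1:3) {
    v <- as.vector(gm_draws[, , g, k])
    group_mean[g, k] <- mean(v); group_sd[g, k] <- stats::sd(v)
  }
  diff_summary <- NULL
  if (G == 2L) {
    diff_summary <- data.frame(parameter = param_names, mean = NA_real_,
                               lower95 = NA_real_, upper95 = NA_real_)
    for (k in 1:3) {
      dv <- as.vector(gm_draws[, , 1, k] - gm_draws[, , 2, k])
      diff_summary$mean[k] <- mean(dv)
      diff_summary[k, c("lower95", "upper95")] <-
        stats::quantile(dv, c(0.025, 0.975))
    }
  }
  subj <- sub_sum / n_sub
  colnames(subj) <- c("alpha", "beta", "lam", "auc", "peak")
  subject_summary <- data.frame(
    subject = rep(vapply(sessions, `[[`, character(1), "subject_id"), each = R),
    group = rep(grp, each = R), roi = roi_of, subj)

  structure(list(
    mu_draws = mu_draws, tau_draws = tau_draws, group_mean_draws = gm_draws,
    group_mean = group_mean, group_sd = group_sd,
    group_difference = diff_summary, subject_summary = subject_summary,
    phi = mean(phi_draws), rhat = rh, converged = converged,
    groups = group_names, n_keep = n_keep, chains = chains),
    class = "phmri_posterior")
}

#' @export
print.phmri_posterior <- function(x, ...) {
  cat("phmri_posterior:", x$chains, "chains x", x$n_keep, "kept draws;",
      if (x$converged) "converged" else "NOT converged (R-hat > 1.1)",
      sprintf("; phi = %.3f", x$phi), "\n")
  cat("group-level means (natural scale):\n")
  print(round(x$group_mean, 4))
  if (!is.null(x$group_difference)) {
    cat("group differences (", paste(x$groups, collapse = " - "), "):\n")
    print(x$group_difference, digits = 4)
  }
  invisible(x)
}
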