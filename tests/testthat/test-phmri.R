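test_that("gamma-variate response obeys its closed-form identities", {
  expect_equal(gamma_response(0, 2, 0.5, 10), 0)
  expect_equal(gamma_response(-3, 4, 1, 5), 0)
  expect_error(gamma_response(1, -1, 1), "positive")
  expect_error(gamma_response(1, 2, 0), "positive")
  set.seed(21)
  for (i in 1:25) {
    al <- runif(1, 1.2, 8); be <- runif(1, 0.05, 2); la <- runif(1, 0.5, 30)
    # AUC equals lambda (density normalization)
    auc <- integrate(function(t) gamma_response(t, al, be, la), 0, Inf,
                     rel.tol = 1e-10)$value
    expect_equal(auc, la, tolerance = 1e-6)
    # argmax on a dense grid equals (alpha-1)/beta
    tp <- gamma_peak_time(al, be)
    grid <- seq(0, 4 * tp, length.out = 40001)
    expect_equal(grid[which.max(gamma_response(grid, al, be, la))], tp,
                 tolerance = grid[2] * 1.5)
    # peak amplitude closed form matches the grid maximum
    expect_equal(max(gamma_response(grid, al, be, la)),
                 gamma_peak_amplitude(al, be, la), tolerance = 1e-6)
  }
})

test_that("subject-level fits recover noiseless truth and absorb offsets", {
  g0 <- list(G = list(mean = c(alpha = 2.8, beta = 0.3, lam = 12),
                      sd_log = c(0.2, 0.2, 0.3)))
  sim <- sim_phmri(groups = g0, n_subjects = 2, n_rois = 4, noise_sd = 0,
                   offset_sd = 0, ar1_phi = 0,
                   cov_coefs = c(PaCO2_before = 0, MABP_before = 0,
                                 MABP_peak = 0), seed = 8)
  f <- fit_subject_gamma(sim$sessions[[1]])
  tru <- sim$ground_truth$params[1, , ]
  expect_lt(max(abs(f$alpha - tru[, 1]) / tru[, 1]), 1e-4)
  expect_lt(max(abs(f$beta - tru[, 2]) / tru[, 2]), 1e-4)
  expect_lt(max(abs(f$lam - tru[, 3]) / tru[, 3]), 1e-4)
  expect_true(all(f$converged))

  # flat noisy series: fitted response stays at the noise floor (the peak
  # amplitude is the identifiable magnitude; a wide low-rate kernel can
  # carry a loosely-determined lambda)
  set.seed(9)
  flat <- phmri_session(matrix(rnorm(200, sd = 0.2), 2), tr_min = 0.5,
                        baseline_frames = 20, post_frames = 80)
  ff <- fit_subject_gamma(flat)
  peaks <- abs(gamma_peak_amplitude(ff$alpha, ff$beta, ff$lam))
  expect_lt(max(peaks), 3 * 0.2)

  # adding a constant lands in the offset, response untouched
  s <- sim$sessions[[1]]
  s2 <- s; s2$series <- s$series + 7
  f2 <- fit_subject_gamma(s2)
  expect_equal(f2$offset, f$offset + 7, tolerance = 1e-4)
  expect_equal(f2$lam, f$lam, tolerance = 1e-4)
  expect_error(fit_subject_gamma(
    phmri_session(matrix(0, 1, 25), tr_min = 0.5, baseline_frames = 20,
                  post_frames = 5)), "post-injection")
})

test_that("GLS/AR(1) reduces to OLS, matches nlme and rejects bad designs", {
  set.seed(22)
  n <- 100
  X <- cbind(intercept = 1, x = rnorm(n), grp = rep(0:1, each = n / 2))
  tt <- seq_len(n)
  y <- as.vector(X %*% c(1, 2, 0.5)) + rnorm(n)
  g0 <- gls_ar1(y, X, tt, phi = 0)
  expect_equal(unname(g0$coefficients), unname(lm.fit(X, y)$coefficients),
               tolerance = 1e-8)
  expect_error(gls_ar1(y, cbind(X, dup = X[, 2]), tt), "rank-deficient")

  # independent oracle: nlme::gls with continuous AR(1)
  e <- as.vector(arima.sim(list(ar = 0.6), n))
  y2 <- as.vector(X %*% c(1, 2, 0.5)) + e
  fit <- gls_ar1(y2, X, tt)
  d <- data.frame(y = y2, x = X[, "x"], grp = X[, "grp"], t = tt)
  or <- nlme::gls(y ~ x + grp, data = d,
                  correlation = nlme::corCAR1(form = ~t), method = "ML")
  expect_equal(unname(fit$coefficients), unname(coef(or)), tolerance = 1e-5)
  expect_equal(fit$phi,
               as.numeric(coef(or$modelStruct$corStruct, unconstrained = FALSE)),
               tolerance = 1e-4)

  # normalized reporting: coefficients on z-scored variables
  fn <- gls_ar1(y2, X, tt, phi = 0, normalize = TRUE)
  zy <- as.vector(scale(y2)); zX <- X
  zX[, 2] <- as.vector(scale(X[, 2])); zX[, 3] <- as.vector(scale(X[, 3]))
  expect_equal(unname(fn$coefficients), unname(lm.fit(zX, zy)$coefficients),
               tolerance = 1e-8)
})

test_that("GLS/AR(1) recovers coefficients and phi across replicates", {
  set.seed(23)
  n <- 100
  X <- cbind(intercept = 1, grp = rep(0:1, each = n / 2))
  tt <- seq_len(n)
  phis <- betas <- numeric(60)
  for (i in 1:60) {
    e <- stats::filter(rnorm(n, sd = sqrt(1 - 0.25)), 0.5,
                       method = "recursive", init = rnorm(1))
    y <- as.vector(X %*% c(0, 1)) + as.vector(e)
    f <- gls_ar1(y, X, tt)
    phis[i] <- f$phi; betas[i] <- f$coefficients["grp"]
  }
  expect_lt(abs(mean(betas) - 1), 0.05 * sd(betas) + 3 * sd(betas) / sqrt(60))
  expect_gt(mean(phis), 0.4); expect_lt(mean(phis), 0.6)
})

test_that("design matrix has the three-block structure", {
  sim <- sim_phmri(n_subjects = c(4, 4), n_rois = 3, seed = 30)
  ser <- do.call(rbind, lapply(sim$sessions, function(s) colMeans(s$series)))
  set.seed(31)
  motion <- matrix(rnorm(600), 100, 6)
  X <- build_design_matrix(ser, motion, tr_min = 0.5, baseline_frames = 20)
  expect_equal(ncol(X), 10)                          # 1 + 6 + 3
  expect_equal(colnames(X)[1], "response")
  sv <- X[, c("svd1", "svd2", "svd3")]
  expect_lt(max(abs(crossprod(sv) - diag(3))), 1e-10)
  # identical noiseless subjects: degenerate residuals flagged
  g0 <- list(G = list(mean = c(alpha = 3, beta = 0.25, lam = 12),
                      sd_log = c(0, 0, 0)))
  nl <- sim_phmri(groups = g0, n_subjects = 3, n_rois = 2, noise_sd = 0,
                  offset_sd = 0, ar1_phi = 0,
                  cov_coefs = c(PaCO2_before = 0, MABP_before = 0,
                                MABP_peak = 0), seed = 12)
  ser_id <- do.call(rbind, lapply(nl$sessions, function(s) colMeans(s$series)))
  expect_warning(
    Xd <- build_design_matrix(ser_id, motion, tr_min = 0.5,
                              baseline_frames = 20),
    "identical")
  expect_true(attr(Xd, "degenerate"))
  expect_warning(
    build_design_matrix(ser[1:2, ], motion, tr_min = 0.5,
                        baseline_frames = 20), "fewer subjects")
})

test_that("voxel GLM is calibrated under the null and finds real effects", {
  set.seed(32)
  nt <- 100; tt <- (0:(nt - 1)) * 0.5
  design <- cbind(response = gamma_response(tt - 10, 3, 0.25, 1),
                  matrix(rnorm(nt * 6), nt,
                         dimnames = list(NULL, paste0("motion", 1:6))),
                  svd1 = rnorm(nt) / sqrt(nt))
  grp <- rep(c("A", "B"), each = 5)
  covs <- data.frame(PaCO2_before = rnorm(10, 37, 3),
                     MABP_before = rnorm(10, 120, 20),
                     MABP_peak = rnorm(10, 122, 20))
  nv <- 20
  pvals <- replicate(30, {
    vox <- lapply(1:10, function(s) matrix(rnorm(nv * nt), nv))
    r <- voxel_glm_group(vox, design, grp, covs, tt, phi = 0)
    r$p_group
  })
  rate <- mean(pvals < 0.05)
  expect_gt(rate, 0.02); expect_lt(rate, 0.09)
  # all-zero input gives zero coefficients
  vox0 <- lapply(1:10, function(s) matrix(0, nv, nt))
  r0 <- voxel_glm_group(vox0, design, grp, covs, tt, phi = 0)
  expect_equal(max(abs(r0$coef)), 0)
  # a 50 % lambda group difference at high SNR is detected
  hits <- replicate(10, {
    vox <- lapply(1:10, function(s) {
      lam <- if (s <= 5) 1 else 1.5
      matrix(rep(gamma_response(tt - 10, 3, 0.25, lam), nv), nv,
             byrow = TRUE) + matrix(rnorm(nv * nt, sd = 0.02), nv)
    })
    r <- voxel_glm_group(vox, design, grp, covs, tt, phi = 0)
    median(r$p_group) < 0.05                         # majority of voxels hit
  })
  expect_gte(mean(hits), 0.9)
})

test_that("mixed model is calibrated and collapses to OLS when RE = 0", {
  set.seed(33)
  nsub <- 12; nroi <- 5
  make_tab <- function(subj_sd, geff) {
    grp <- rep(c("A", "B"), each = nsub / 2)
    subj_eff <- rnorm(nsub, 0, subj_sd)
    data.frame(
      subject = rep(seq_len(nsub), each = nroi),
      roi = rep(seq_len(nroi), nsub),
      value = rep(subj_eff, each = nroi) +
        geff * rep(grp == "B", each = nroi) + rnorm(nsub * nroi, 0, 0.5),
      group = rep(grp, each = nroi),
      PaCO2_before = rep(rnorm(nsub, 37, 2), each = nroi),
      MABP_before = rep(rnorm(nsub, 120, 10), each = nroi),
      MABP_peak = rep(rnorm(nsub, 121, 10), each = nroi))
  }
  # null: the 95 % confidence interval covers zero in most replicates
  cover <- replicate(60, {
    m <- mixed_model_group_test(make_tab(1.0, 0))
    abs(m$estimate) < qt(0.975, m$df) * m$se
  })
  expect_gte(mean(cover), 0.88)
  # known effect recovered within its 95 % interval in nearly all replicates
  ok <- replicate(30, {
    m1 <- mixed_model_group_test(make_tab(0.8, 2))
    abs(m1$estimate - 2) < qt(0.975, m1$df) * m1$se
  })
  expect_gte(mean(ok), 0.85)
  # zero random-effect truth: balanced design matches plain regression
  tab0 <- make_tab(0, 1)
  m0 <- mixed_model_group_test(tab0)
  ols <- lm(value ~ group + PaCO2_before + MABP_before + MABP_peak,
            data = tab0)
  expect_equal(m0$estimate, unname(coef(ols)["groupB"]), tolerance = 1e-6)
  expect_error(mixed_model_group_test(make_tab(1, 0)[c(TRUE, rep(FALSE, 4)), ]),
               "2 ROIs")
})

test_that("missing covariates are imputed inside the mixed model", {
  set.seed(34)
  tab <- data.frame(
    subject = rep(1:6, each = 3), roi = rep(1:3, 6),
    value = rnorm(18), group = rep(c("A", "B"), each = 9),
    PaCO2_before = rep(c(35, NA, 39, 33, 36, NA), each = 3),
    MABP_before = rep(rnorm(6, 120, 5), each = 3),
    MABP_peak = rep(rnorm(6, 120, 5), each = 3))
  m <- mixed_model_group_test(tab)
  expect_true(is.finite(m$p))
})

test_that("hierarchy collapses to subject fits under a flat prior", {
  g0 <- list(G = list(mean = c(alpha = 3, beta = 0.25, lam = 14),
                      sd_log = c(0.2, 0.2, 0.2)))
  sim <- sim_phmri(groups = g0, n_subjects = 1, n_rois = 3, noise_sd = 0.2,
                   offset_sd = 0, ar1_phi = 0,
                   cov_coefs = c(PaCO2_before = 0, MABP_before = 0,
                                 MABP_peak = 0), seed = 40)
  post <- fit_hierarchical(sim$sessions, chains = 2, iter = 800, seed = 3,
                           fix_tau = c(4, 4, 4))
  nls_fit <- fit_subject_gamma(sim$sessions[[1]])
  ss <- post$subject_summary
  expect_equal(ss$alpha, nls_fit$alpha, tolerance = 0.15)
  expect_equal(ss$beta, nls_fit$beta, tolerance = 0.15)
  expect_equal(ss$lam, nls_fit$lam, tolerance = 0.15)
  # AUC of every draw equals lambda by construction; peak matches closed form
  expect_identical(ss$auc, ss$lam)
  expect_equal(ss$peak,
               gamma_peak_amplitude(ss$alpha, ss$beta, ss$lam),
               tolerance = 0.2)
})
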