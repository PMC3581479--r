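#' One- or two-sample t-test with Cohen's d
#'
#' One-sample (against zero) or pooled-variance (Student) two-sample t-test,
#' reporting Cohen's d: the mean (difference) divided by the (pooled) SD.
#' A Welch test is available via \code{var_equal = FALSE}, in which case d
#' still uses the pooled SD.
#'
#' @param a Numeric sample.
#' @param b Optional second sample; when given a two-sample test of
#'   \code{mean(a) - mean(b)} is performed.
#' @param var_equal Pool variances (default TRUE, the convention matching
#'   \code{d = t * sqrt(1/n1 + 1/n2)}).
#' @return List of class \code{test_result}: \code{statistic}, \code{df},
#'   \code{p}, \code{d}.
#' @export
t_tests <- function(a, b = NULL, var_equal = TRUE) {
  if (length(a) < 2L || (!is.null(b) && length(b) < 2L))
    stop("need at least 2 observations per sample")
  if (is.null(b)) {
    if (stats::sd(a) == 0) stop("zero variance sample")
    ht <- stats::t.test(a, mu = 0)
    d <- mean(a) / stats::sd(a)
  } else {
    if (stats::sd(a) == 0 && stats::sd(b) == 0) stop("zero variance samples")
    ht <- stats::t.test(a, b, var.equal = var_equal)
    n1 <- length(a); n2 <- length(b)
    sp <- sqrt(((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) /
                 (n1 + n2 - 2))
    d <- (mean(a) - mean(b)) / sp
  }
  structure(list(statistic = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value, d = d),
            class = "test_result")
}

#' Cohen's d from a two-sample t statistic
#'
#' \eqn{d = t \sqrt{1/n_1 + 1/n_2}} — the conversion that reproduces
#' pooled-SD effect sizes from group sizes.
#'
#' @param t t statistic.
#' @param n1,n2 Group sizes (>= 2).
#' @return Cohen's d.
#' @export
d_from_t <- function(t, n1, n2) {
  if (n1 < 2 || n2 < 2) stop("need n1, n2 >= 2")
  t * sqrt(1 / n1 + 1 / n2)
}

#' Cohen's d from a t statistic and its degrees of freedom
#'
#' \eqn{d = 2t/\sqrt{df}}, the convention common in functional-connectivity
#' tables where only df is reported.
#'
#' @param t t statistic.
#' @param df Degrees of freedom (>= 1).
#' @return Cohen's d.
#' @export
d_from_t_df <- function(t, df) {
  if (df < 1) stop("need df >= 1")
  2 * t / sqrt(df)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (q-values); monotone in the ranking of p and
#' never smaller than p. \code{NA} entries are passed through.
#'
#' @param p_values Vector of p-values in [0, 1].
#' @return Vector of q-values of the same length.
#' @export
fdr_bh <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

# label connected components (6-connectivity) of a logical 3-D array and
# return the size of the largest one
max_cluster_size <- function(mask) {
  d <- dim(mask)
  idx <- which(mask)
  if (!length(idx)) return(0L)
  lab <- integer(length(mask))
  lab[idx] <- -1L                                  # unvisited foreground
  nxy <- d[1] * d[2]
  best <- 0L
  cur <- 0L
  for (start in idx) {
    if (lab[start] != -1L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    size <- 0L
    while (length(queue)) {
      v <- queue[[length(queue)]]
      queue <- queue[-length(queue)]
      size <- size + 1L
      z <- (v - 1L) %/% nxy
      rem <- (v - 1L) %% nxy
      y <- rem %/% d[1]
      x <- rem %% d[1]
      nb <- integer(0)
      if (x > 0L) nb <- c(nb, v - 1L)
      if (x < d[1] - 1L) nb <- c(nb, v + 1L)
      if (y > 0L) nb <- c(nb, v - d[1])
      if (y < d[2] - 1L) nb <- c(nb, v + d[1])
      if (z > 0L) nb <- c(nb, v - nxy)
      if (z < d[3] - 1L) nb <- c(nb, v + nxy)
      nb <- nb[lab[nb] == -1L]
      lab[nb] <- cur
      queue <- c(queue, nb)
    }
    if (size > best) best <- size
  }
  best
}

#' Monte-Carlo cluster-extent threshold
#'
#' Estimates the minimum cluster size controlling the family-wise error of a
#' voxelwise-thresholded statistic map: Gaussian white-noise volumes are
#' smoothed to the stated FWHM, re-standardized, thresholded one-sided at
#' \code{voxel_p}, and the maximum suprathreshold cluster size
#' (face-connectivity) recorded per iteration; the cluster threshold is the
#' \code{1 - alpha} quantile of these maxima.
#'
#' @param grid_shape Volume dimensions in voxels.
#' @param voxel_size Voxel edge lengths in mm.
#' @param fwhm Smoothing FWHM in mm applied to the noise (>= 0).
#' @param voxel_p Voxelwise one-sided p threshold.
#' @param alpha Cluster-level family-wise error rate.
#' @param n_iter Monte-Carlo iterations (>= 100).
#' @param seed Integer seed.
#' @return List with \code{voxels} (minimum cluster extent in voxels),
#'   \code{mm3} (same in mm^3) and the simulated \code{max_sizes}.
#' @export
cluster_mc_threshold <- function(grid_shape, voxel_size, fwhm, voxel_p,
                                 alpha = 0.01, n_iter = 1000L, seed = 1L) {
  if (fwhm < 0) stop("fwhm must be non-negative")
  if (n_iter < 100L) stop("n_iter must be >= 100")
  stopifnot(voxel_p > 0, voxel_p <= 1, alpha > 0, alpha < 1)
  zc <- stats::qnorm(1 - voxel_p)                  # -Inf at voxel_p = 1
  maxes <- with_seed(seed, {
    vapply(seq_len(n_iter), function(i) {
      vol <- array(stats::rnorm(prod(grid_shape)), dim = grid_shape)
      if (fwhm > 0) {
        vol <- gaussian_smooth(vol, fwhm, voxel_size)
        vol <- (vol - mean(vol)) / stats::sd(vol)
      }
      max_cluster_size(vol > zc)
    }, integer(1))
  })
  k <- as.integer(ceiling(stats::quantile(maxes, 1 - alpha, type = 1)))
  list(voxels = k, mm3 = k * prod(voxel_size), max_sizes = maxes)
}

#' Group-mean imputation of covariates
#'
#' Replaces missing covariate entries by the mean of the observed values
#' within the same group; observed entries are untouched, so group means are
#' preserved exactly.
#'
#' @param covariate_table Data frame or matrix of numeric covariates.
#' @param group_labels Group label per row.
#' @return The completed table.
#' @export
impute_group_mean <- function(covariate_table, group_labels) {
  tab <- as.data.frame(covariate_table)
  stopifnot(nrow(tab) == length(group_labels))
  for (j in seq_along(tab)) {
    x <- tab[[j]]
    if (!anyNA(x)) next
    for (g in unique(group_labels)) {
      sel <- group_labels == g
      miss <- sel & is.na(x)
      if (!any(miss)) next
      obs <- x[sel & !is.na(x)]
      if (!length(obs))
        stop("covariate '", names(tab)[j], "' has no observed value in group '",
             g, "'; cannot impute")
      x[miss] <- mean(obs)
    }
    tab[[j]] <- x
  }
  tab
}
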