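#' Build a diffusion-weighting scheme
#'
#' Generates \code{n_directions} unit gradient directions spread over the
#' sphere by electrostatic repulsion of antipodal point pairs, preceded by
#' \code{n_b0} unweighted (b = 0) volumes. Defaults mirror a high-angular
#' resolution acquisition: 50 directions at b = 1250 s/mm^2 plus 2 b0 images.
#'
#' @param n_directions Number of diffusion-weighted directions (>= 6, else the
#'   tensor is not identifiable).
#' @param b b-value in s/mm^2 applied to every weighted volume.
#' @param n_b0 Number of leading b = 0 volumes.
#' @param seed Integer seed for the (randomly initialized) repulsion.
#' @param n_iter Repulsion iterations.
#' @return An object of class \code{diffusion_scheme}: list with
#'   \code{b_values} (length \code{n_b0 + n_directions}) and
#'   \code{directions} (matrix, unit rows for weighted volumes, zero rows for
#'   b0 volumes).
#' @export
make_scheme <- function(n_directions = 50L, b = 1250, n_b0 = 2L, seed = 1L,
                        n_iter = 300L) {
  if (n_directions < 6L)
    stop("n_directions must be >= 6: fewer directions leave the diffusion tensor unidentifiable")
  stopifnot(b > 0, n_b0 >= 0)
  dirs <- with_seed(seed, {
    p <- matrix(stats::rnorm(3L * n_directions), ncol = 3L)
    p <- p / sqrt(rowSums(p^2))
    step <- 0.1
    for (it in seq_len(n_iter)) {
      frc <- matrix(0, n_directions, 3L)
      for (i in seq_len(n_directions)) {
        d1 <- sweep(p, 2L, p[i, ])            # p - p_i
        d2 <- sweep(-p, 2L, p[i, ])           # -p - p_i (antipodes)
        r1 <- sqrt(rowSums(d1^2)); r2 <- sqrt(rowSums(d2^2))
        r1[i] <- Inf
        # Coulomb repulsion from both each point and its antipode
        frc[i, ] <- -colSums(d1 / (r1^3 + 1e-12)) - colSums(d2 / (r2^3 + 1e-12))
      }
      p <- p + step * frc / n_directions
      p <- p / sqrt(rowSums(p^2))
      step <- step * 0.985
    }
    p
  })
  scheme <- list(
    b_values = c(rep(0, n_b0), rep(b, n_directions)),
    directions = rbind(matrix(0, n_b0, 3L), dirs))
  class(scheme) <- "diffusion_scheme"
  scheme
}

#' Minimum pairwise angle of a direction set
#'
#' Angle between diffusion directions treating antipodal vectors as identical
#' (the relevant symmetry for diffusion weighting).
#'
#' @param directions Matrix of unit row vectors (b0 zero-rows are dropped).
#' @return Minimum pairwise angle in degrees.
#' @export
min_pairwise_angle <- function(directions) {
  d <- directions[rowSums(directions^2) > 0.5, , drop = FALSE]
  g <- abs(d %*% t(d))
  cosmax <- max(g[upper.tri(g)])
  acos(min(cosmax, 1)) * 180 / pi
}

#' @export
print.diffusion_scheme <- function(x, ...) {
  nb0 <- sum(x$b_values == 0)
  cat("diffusion_scheme:", length(x$b_values) - nb0, "weighted volumes (b =",
      max(x$b_values), "s/mm^2) +", nb0, "b0\n")
  invisible(x)
}
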