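#' Build a weighted undirected graph from a connectivity matrix
#'
#' Self-connections are always removed; by default edges with non-positive
#' weight are dropped as well, so only positive couplings enter the graph
#' (the usual convention for correlation-weighted brain graphs).
#'
#' @param matrix Square symmetric matrix of edge weights (FC z' values or
#'   structural weights). \code{NA} entries are treated as absent edges.
#' @param drop_negative Drop edges with weight <= 0 (default \code{TRUE}).
#' @return Object of class \code{weighted_graph}: list with \code{nodes} and
#'   \code{weights} (symmetric matrix, 0 = no edge, zero diagonal).
#' @export
build_graph <- function(matrix, drop_negative = TRUE) {
  w <- as.matrix(matrix)
  diag(w) <- 0
  w[is.na(w)] <- 0
  check_symmetric(w, tol = 1e-10, what = "connectivity matrix")
  if (drop_negative) w[w <= 0] <- 0
  else if (any(w < 0)) stop("negative weights present; set drop_negative = TRUE or rectify them")
  nodes <- rownames(w) %||% as.character(seq_len(nrow(w)))
  dimnames(w) <- list(nodes, nodes)
  structure(list(nodes = nodes, weights = w), class = "weighted_graph")
}

#' @export
print.weighted_graph <- function(x, ...) {
  cat("weighted_graph:", length(x$nodes), "nodes,",
      sum(x$weights[upper.tri(x$weights)] > 0), "edges\n")
  invisible(x)
}

#' Onnela weighted clustering coefficient
#'
#' Local clustering \eqn{C_i = \sum_{j,k} (\hat w_{ij}\hat w_{jk}\hat
#' w_{ik})^{1/3} / (k_i (k_i - 1))} with weights normalized by the maximum
#' weight in the graph. Nodes with degree < 2 contribute 0.
#'
#' @param g A \code{\link{build_graph}} graph.
#' @return List with \code{per_node} values and their \code{mean}.
#' @export
clustering_onnela <- function(g) {
  w <- g$weights
  if (length(g$nodes) == 0L) stop("empty graph")
  mx <- max(w)
  cpn <- stats::setNames(numeric(length(g$nodes)), g$nodes)
  if (mx > 0) {
    wh <- (w / mx)^(1 / 3)
    num <- diag(wh %*% wh %*% wh)                  # 2 * sum over triangles
    k <- rowSums(w > 0)
    ok <- k >= 2
    cpn[ok] <- num[ok] / (k[ok] * (k[ok] - 1))
  }
  list(per_node = cpn, mean = mean(cpn))
}

#' Weighted characteristic path length
#'
#' Edge length is the reciprocal weight (strong couplings are short);
#' the characteristic path length is the mean shortest-path distance over
#' all ordered node pairs. On disconnected graphs the unreachable pairs are
#' excluded from the mean and their fraction reported.
#'
#' @param g A \code{\link{build_graph}} graph.
#' @return List with \code{L}, \code{frac_unreachable} and the full
#'   \code{distances} matrix.
#' @export
char_path_length <- function(g) {
  w <- g$weights
  n <- length(g$nodes)
  adj <- ifelse(w > 0, 1 / w, 0)
  ig <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                            weighted = TRUE)
  dm <- igraph::distances(ig)
  off <- dm[row(dm) != col(dm)]
  unreach <- !is.finite(off)
  list(L = mean(off[!unreach]),
       frac_unreachable = mean(unreach),
       distances = dm)
}

surrogate_graph <- function(g, how = c("permute", "rewire")) {
  how <- match.arg(how)
  w <- g$weights
  ut <- upper.tri(w)
  vals <- w[ut]
  edges <- vals > 0
  s <- matrix(0, nrow(w), ncol(w), dimnames = dimnames(w))
  if (how == "permute") {
    # shuffle weights over the existing edge slots; topology preserved
    newvals <- vals
    newvals[edges] <- sample(vals[edges])
    s[ut] <- newvals
  } else {
    # same weights on uniformly re-drawn node pairs; density preserved
    slots <- sample(which(ut), sum(edges))
    s[slots] <- vals[edges]
  }
  s <- s + t(s)
  structure(list(nodes = g$nodes, weights = s), class = "weighted_graph")
}

#' Surrogate-normalized graph metrics and small-worldness
#'
#' Computes the mean Onnela clustering coefficient C and characteristic path
#' length L of the graph, normalizes each by its mean over
#' \code{n_surrogates} surrogate networks obtained by randomly permuting the
#' edge weights over the retained edge slots (default; \code{surrogate =
#' "rewire"} instead re-draws the edge positions), and reports small-worldness
#' \eqn{\sigma = (C/C_{surr}) / (L/L_{surr})}.
#'
#' @param g A \code{\link{build_graph}} graph.
#' @param n_surrogates Number of surrogate networks (customary choice: 1000).
#' @param seed Integer seed for the permutations.
#' @param surrogate Null model: "permute" (weight shuffle on fixed topology)
#'   or "rewire" (random edge positions, same weights).
#' @return Object of class \code{graph_metrics}: clustering, path_length,
#'   clustering_norm, path_length_norm, small_worldness, n_surrogates.
#' @export
normalize_and_smallworld <- function(g, n_surrogates = 1000L, seed = 1L,
                                     surrogate = c("permute", "rewire")) {
  surrogate <- match.arg(surrogate)
  if (n_surrogates < 1L) stop("n_surrogates must be >= 1")
  C <- clustering_onnela(g)$mean
  L <- char_path_length(g)$L
  surr <- with_seed(seed, {
    vapply(seq_len(n_surrogates), function(i) {
      s <- surrogate_graph(g, surrogate)
      c(clustering_onnela(s)$mean, char_path_length(s)$L)
    }, numeric(2))
  })
  c_norm <- C / mean(surr[1, ])
  l_norm <- L / mean(surr[2, ])
  structure(list(clustering = C, path_length = L,
                 clustering_norm = c_norm, path_length_norm = l_norm,
                 small_worldness = c_norm / l_norm,
                 n_surrogates = n_surrogates, surrogate = surrogate),
            class = "graph_metrics")
}

#' @export
print.graph_metrics <- function(x, ...) {
  cat(sprintf(
    "graph_metrics: C = %.4f, L = %.4f, C_norm = %.4f, L_norm = %.4f, sigma = %.4f (%d surrogates)\n",
    x$clustering, x$path_length, x$clustering_norm, x$path_length_norm,
    x$small_worldness, x$n_surrogates))
  invisible(x)
}
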