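# Shared fixtures: tiny atlases, bundle phantoms and brute-force oracles.

# small bilateral atlas for voxel-level pipelines
tiny_atlas <- function(n_bilateral = 4, grid = c(16, 12, 6),
                       small_rois = character(0)) {
  make_atlas(grid_shape = grid, voxel_size = c(0.5, 0.5, 0.5),
             n_bilateral = n_bilateral, small_rois = small_rois)
}

# two-ROI atlas + straight bundle along x, on a 0.25 mm grid
straight_bundle_phantom <- function(fa_inside = 0.8, fa_outside = 0.05) {
  lab <- array(0L, dim = c(24, 10, 8))
  lab[2:3, 4:6, 3:5] <- 1L
  lab[22:23, 4:6, 3:5] <- 2L
  atlas <- structure(list(
    label_volume = lab, voxel_size = c(0.25, 0.25, 0.25),
    roi_table = data.frame(
      label_id = 1:2, name = c("A", "B"), hemisphere = c("left", "right"),
      homolog_label_id = c(2L, 1L), tissue = "gray",
      stringsAsFactors = FALSE)), class = "roi_atlas")
  centerline <- cbind(seq(0.5, 5.25, length.out = 30), 1.0, 0.75)
  bundles <- list(list(start_label = 1L, end_label = 2L,
                       centerline = centerline, radius_mm = 0.3))
  ph <- sim_tensor_phantom(atlas, bundles, fa_inside = fa_inside,
                           fa_outside = fa_outside)
  list(atlas = atlas, phantom = ph, centerline_length = 5.25 - 0.5)
}

# exhaustive Onnela clustering over node triples
brute_clustering_onnela <- function(w) {
  n <- nrow(w)
  wh <- w / max(w)
  cpn <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(w[i, ] > 0)
    if (k < 2) next
    s <- 0
    for (j in seq_len(n)) for (l in seq_len(n)) {
      if (j == i || l == i || j == l) next
      s <- s + (wh[i, j] * wh[j, l] * wh[i, l])^(1 / 3)
    }
    cpn[i] <- s / (k * (k - 1))
  }
  mean(cpn)
}

# exhaustive shortest paths by simple-path enumeration (distance = 1/w)
brute_path_length <- function(w) {
  n <- nrow(w)
  best <- matrix(Inf, n, n)
  recurse <- function(path, dist) {
    i <- path[length(path)]
    s <- path[1]
    if (dist < best[s, i]) best[s, i] <<- dist
    for (j in seq_len(n)) {
      if (w[i, j] > 0 && !(j %in% path))
        recurse(c(path, j), dist + 1 / w[i, j])
    }
  }
  for (s in seq_len(n)) recurse(s, 0)
  off <- best[row(best) != col(best)]
  reach <- is.finite(off)
  list(L = mean(off[reach]), frac_unreachable = mean(!reach))
}

# random symmetric weight matrix with given edge density
random_weight_matrix <- function(n, density = 0.7) {
  w <- matrix(0, n, n)
  ut <- upper.tri(w)
  vals <- ifelse(stats::runif(sum(ut)) < density, stats::runif(sum(ut), 0.1, 1), 0)
  w[ut] <- vals
  w + t(w)
}

# direct step-up enumeration of the Benjamini-Hochberg procedure
brute_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  for (i in seq_len(n)) {
    q[o[i]] <- min(vapply(i:n, function(j) p[o[j]] * n / j, numeric(1)), 1)
  }
  q
}
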