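test_that("tensor fit inverts the noiseless forward model exactly", {
  fx <- straight_bundle_phantom()
  scheme <- make_scheme(seed = 1)
  dwi <- sim_dwi(fx$phantom$tensor_field, scheme, s0 = 1000, snr = Inf)
  tf <- fit_tensor(dwi, scheme, voxel_size = fx$atlas$voxel_size)
  expect_lt(max(abs(tf$D - fx$phantom$tensor_field$D)), 1e-9)
  # prolate eigenvalues recovered to 1e-9
  ev_true <- fx$phantom$ground_truth$eigen_inside
  inside <- fx$phantom$ground_truth$bundle_masks[[1]]
  v <- which(inside)[1]
  idx <- arrayInd(v, dim(inside))
  ev_fit <- ratconn:::tensor_eigenvalues(
    matrix(tf$D[idx[1], idx[2], idx[3], ], 1))
  expect_lt(max(abs(sort(ev_fit, decreasing = TRUE) -
                    sort(ev_true, decreasing = TRUE))), 1e-9)
  # b0-only acquisitions are rejected
  b0_scheme <- structure(list(b_values = rep(0, 8),
                              directions = matrix(0, 8, 3)),
                         class = "diffusion_scheme")
  expect_error(fit_tensor(dwi[, , , rep(1, 8)], b0_scheme), "underdetermined")
})

test_that("FA/MD follow their closed forms", {
  # isotropic: FA = 0, MD = diagonal value
  iso <- ratconn:::fa_md_from_eigenvalues(matrix(0.7e-3, 1, 3))
  expect_equal(iso$fa, 0)
  expect_equal(iso$md, 0.7e-3)
  # canonical prolate eigenvalues
  pro <- ratconn:::fa_md_from_eigenvalues(matrix(c(1.7, 0.2, 0.2) * 1e-3, 1))
  expect_equal(pro$fa, 1.5e-3 / sqrt((1.7e-3)^2 + 2 * (0.2e-3)^2),
               tolerance = 1e-12)
  expect_equal(round(pro$fa, 4), 0.8704)
  # stick limit: FA -> 1
  stick <- ratconn:::fa_md_from_eigenvalues(matrix(c(1e-3, 1e-12, 1e-12), 1))
  expect_equal(stick$fa, 1, tolerance = 1e-6)
  # zero tensor
  zero <- ratconn:::fa_md_from_eigenvalues(matrix(0, 1, 3))
  expect_equal(zero$fa, 0); expect_equal(zero$md, 0)
  # negative eigenvalues clamped and flagged
  neg <- ratconn:::fa_md_from_eigenvalues(matrix(c(1e-3, -1e-5, 1e-5), 1))
  expect_true(neg$clamped)
  # prolate_eigenvalues inverts the FA formula
  for (fa in c(0.05, 0.3, 1 / sqrt(2), 0.8, 0.95)) {
    ev <- prolate_eigenvalues(fa, 0.7e-3)
    got <- ratconn:::fa_md_from_eigenvalues(matrix(ev, 1))
    expect_equal(got$fa, fa, tolerance = 1e-9)
    expect_equal(got$md, 0.7e-3, tolerance = 1e-12)
  }
})

test_that("tractography tracks the bundle and respects its thresholds", {
  fx <- straight_bundle_phantom()
  st <- track_streamlines(fx$phantom$tensor_field, seeds_per_voxel = 4,
                          seed = 2)
  expect_gt(length(st$points), 0)
  # median length within 10 % of the centerline length
  expect_lt(abs(median(st$lengths) - fx$centerline_length),
            0.1 * fx$centerline_length)
  # no streamline turns more than 35 degrees between steps
  for (p in st$points) {
    if (nrow(p) < 3) next
    seg <- diff(p)
    seg <- seg / sqrt(rowSums(seg^2))
    turns <- acos(pmin(1, rowSums(seg[-1, , drop = FALSE] *
                                  seg[-nrow(seg), , drop = FALSE]))) * 180 / pi
    expect_lt(max(turns), 35 + 1e-6)
  }
  # at least one streamline connects the two end ROIs
  cn <- build_connectome(st, fx$atlas,
                         tensor_scalars(fx$phantom$tensor_field)$fa)
  expect_gt(cn$counts["1", "2"], 0)
  # uniform low-FA field yields no streamlines
  low <- fx$phantom$tensor_field
  low$D[] <- rep(ratconn:::prolate_tensor(c(0, 0, 1),
                                          prolate_eigenvalues(0.1, 0.7e-3)),
                 each = prod(dim(low$D)[1:3]))
  st0 <- track_streamlines(low, seeds_per_voxel = 2, seed = 1)
  expect_equal(length(st0$points), 0)
  # deterministic given seed
  st2 <- track_streamlines(fx$phantom$tensor_field, seeds_per_voxel = 4,
                           seed = 2)
  expect_identical(st$points, st2$points)
})

test_that("streamline count scales with seed density", {
  fx <- straight_bundle_phantom()
  n1 <- length(track_streamlines(fx$phantom$tensor_field,
                                 seeds_per_voxel = 2, seed = 3)$points)
  n3 <- length(track_streamlines(fx$phantom$tensor_field,
                                 seeds_per_voxel = 6, seed = 3)$points)
  expect_lt(abs(n3 / n1 - 3), 0.3)
})

test_that("connectome weighting and length filter follow the rules", {
  fx <- straight_bundle_phantom()
  fa_map <- tensor_scalars(fx$phantom$tensor_field)$fa
  # hand-built streamline with known sampled FA
  pts <- cbind(seq(0.5, 5.25, by = 0.25), 1.0, 0.75)
  sl <- structure(list(points = list(pts),
                       lengths = sum(sqrt(rowSums(diff(pts)^2)))),
                  class = "streamline_set")
  cn <- build_connectome(sl, fx$atlas, fa_map)
  fa_samples <- apply(pts, 1, function(p)
    ratconn:::interp_scalar(fa_map, fx$atlas$voxel_size, p))
  expect_equal(cn$weights["1", "2"], mean(fa_samples), tolerance = 1e-12)
  expect_equal(cn$counts["1", "2"], 1)
  # a 0.8 mm tract is excluded at the 1.0 mm minimum length
  short_pts <- cbind(seq(0.5, 1.3, by = 0.1), 1.0, 0.75)
  sl_short <- structure(list(points = list(short_pts),
                             lengths = sum(sqrt(rowSums(diff(short_pts)^2)))),
                        class = "streamline_set")
  cn_short <- build_connectome(sl_short, fx$atlas, fa_map)
  expect_equal(sum(cn_short$counts), 0)
  # endpoints outside any ROI contribute nothing
  bg_pts <- cbind(seq(1.5, 4.0, by = 0.25), 2.4, 1.9)
  sl_bg <- structure(list(points = list(bg_pts),
                          lengths = sum(sqrt(rowSums(diff(bg_pts)^2)))),
                     class = "streamline_set")
  expect_equal(sum(build_connectome(sl_bg, fx$atlas, fa_map)$counts), 0)
})

test_that("connectome feeds the graph module unchanged", {
  fx <- straight_bundle_phantom()
  st <- track_streamlines(fx$phantom$tensor_field, seeds_per_voxel = 3,
                          seed = 4)
  cn <- build_connectome(st, fx$atlas,
                         tensor_scalars(fx$phantom$tensor_field)$fa)
  g <- build_graph(cn$weights)
  expect_equal(sum(g$weights[upper.tri(g$weights)] > 0), 1)
  expect_equal(char_path_length(g)$frac_unreachable, 0)
})

test_that("white-matter FA group statistics detect a genu-style deficit", {
  set.seed(51)
  a <- make_atlas()
  d <- dim(a$label_volume)
  wm <- a$roi_table[a$roi_table$tissue == "white", ]
  genu <- wm$label_id[wm$name == "genu CC"]
  make_map <- function(shift) {
    m <- array(rnorm(prod(d), 0.5, 0.02), dim = d)
    m[a$label_volume == genu] <- m[a$label_volume == genu] + shift
    m
  }
  # constant-FA sanity: ROI mean equals the constant
  const <- array(0.5, dim = d)
  res_c <- roi_fa_stats(rep(list(const), 6), rep(c("WT", "KO"), 3), atlas = a)
  expect_equal(res_c$mean_g1, rep(0.5, 4))
  # power: genu shifted by -0.1 at within-group SD 0.05, n = 12 vs 14
  hits <- replicate(25, {
    subj_shift_wt <- rnorm(12, 0, 0.05)
    subj_shift_ko <- rnorm(14, -0.1, 0.05)
    maps <- c(lapply(subj_shift_wt, make_map), lapply(subj_shift_ko, make_map))
    res <- roi_fa_stats(maps, rep(c("WT", "KO"), c(12, 14)), atlas = a)
    res$q[res$roi == "genu CC"] < 0.05
  })
  expect_gte(mean(hits), 0.9)
  # identical groups: d near zero on average
  null_d <- replicate(20, {
    maps <- lapply(rnorm(10, 0, 0.05), make_map)
    res <- roi_fa_stats(maps, rep(c("WT", "KO"), 5), atlas = a)
    res$d[res$roi == "genu CC"]
  })
  expect_lt(abs(mean(null_d)), 0.5)
})
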