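#' Fit diffusion tensors by log-linear least squares
#'
#' Voxel-wise fit of \eqn{\ln S = \ln S_0 - b\, g^T D g} over all volumes.
#' Requires at least six non-collinear weighted volumes plus one b0 volume.
#' Non-positive signals are clamped to a small epsilon before the log and the
#' affected voxels flagged.
#'
#' @param dwi 4-D array of diffusion-weighted volumes (x, y, z, volume).
#' @param scheme The matching \code{\link{make_scheme}} scheme.
#' @param voxel_size Voxel edge lengths in mm.
#' @return A \code{tensor_field} with an extra logical \code{clamped} volume
#'   marking voxels containing clamped signals.
#' @export
fit_tensor <- function(dwi, scheme, voxel_size = c(0.25, 0.25, 0.25)) {
  d <- dim(dwi)
  stopifnot(length(d) == 4L, d[4] == length(scheme$b_values))
  b <- scheme$b_values
  g <- scheme$directions
  if (sum(b > 0) < 6L)
    stop("tensor fit is underdetermined: need >= 6 diffusion-weighted volumes")
  if (sum(b == 0) < 1L) stop("need at least one b0 volume")
  C <- cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
             2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3],
             2 * g[, 2] * g[, 3]) * b
  X <- cbind(1, -C)
  if (qr(X)$rank < 7L)
    stop("gradient directions are collinear: tensor not identifiable")
  S <- t(matrix(dwi, prod(d[1:3]), d[4]))          # volumes x voxels
  bad <- S <= 0
  if (any(bad)) S[bad] <- 1e-6 * max(S)
  theta <- qr.coef(qr(X), log(S))                  # 7 x voxels
  tf <- structure(list(
    D = array(t(theta[-1L, , drop = FALSE]), dim = c(d[1:3], 6L)),
    voxel_size = as.numeric(voxel_size),
    mask = array(TRUE, dim = d[1:3]),
    s0 = array(exp(theta[1L, ]), dim = d[1:3]),
    clamped = array(colSums(bad) > 0, dim = d[1:3])),
    class = "tensor_field")
  tf
}

# vectorized eigenvalues of symmetric 3x3 tensors (rows xx,yy,zz,xy,xz,yz),
# returned in decreasing order (trigonometric closed form)
tensor_eigenvalues <- function(Dm) {
  xx <- Dm[, 1]; yy <- Dm[, 2]; zz <- Dm[, 3]
  xy <- Dm[, 4]; xz <- Dm[, 5]; yz <- Dm[, 6]
  p1 <- xy^2 + xz^2 + yz^2
  q <- (xx + yy + zz) / 3
  p2 <- (xx - q)^2 + (yy - q)^2 + (zz - q)^2 + 2 * p1
  p <- sqrt(pmax(p2, 0) / 6)
  l1 <- l2 <- l3 <- q
  nz <- p > 0
  if (any(nz)) {
    pp <- p[nz]
    bxx <- (xx[nz] - q[nz]) / pp; byy <- (yy[nz] - q[nz]) / pp
    bzz <- (zz[nz] - q[nz]) / pp
    bxy <- xy[nz] / pp; bxz <- xz[nz] / pp; byz <- yz[nz] / pp
    detB <- bxx * (byy * bzz - byz^2) - bxy * (bxy * bzz - byz * bxz) +
      bxz * (bxy * byz - byy * bxz)
    phi <- acos(pmax(pmin(detB / 2, 1), -1)) / 3
    l1[nz] <- q[nz] + 2 * pp * cos(phi)
    l3[nz] <- q[nz] + 2 * pp * cos(phi + 2 * pi / 3)
    l2[nz] <- 3 * q[nz] - l1[nz] - l3[nz]
  }
  cbind(l1, l2, l3)
}

# FA and MD from eigenvalue rows; negative eigenvalues clamped to zero
fa_md_from_eigenvalues <- function(ev) {
  clamped <- rowSums(ev < 0) > 0
  ev <- pmax(ev, 0)
  md <- rowMeans(ev)
  num <- sqrt(rowSums((ev - md)^2))
  den <- sqrt(rowSums(ev^2))
  fa <- ifelse(den > 0, sqrt(1.5) * num / den, 0)
  list(fa = pmin(fa, 1), md = md, clamped = clamped)
}

#' FA and MD maps from a tensor field
#'
#' Mean diffusivity \eqn{(\lambda_1+\lambda_2+\lambda_3)/3} and fractional
#' anisotropy \eqn{\sqrt{3/2}\,\lVert\lambda - MD\rVert / \lVert\lambda\rVert}
#' per voxel. Negative eigenvalues (possible in noisy fits) are clamped to
#' zero and the voxel flagged.
#'
#' @param tf A \code{tensor_field}.
#' @return List with \code{fa}, \code{md} (3-D arrays) and
#'   \code{clamped} (logical 3-D array).
#' @export
tensor_scalars <- function(tf) {
  d <- dim(tf$D)[1:3]
  res <- fa_md_from_eigenvalues(tensor_eigenvalues(matrix(tf$D, prod(d), 6L)))
  list(fa = array(res$fa, d), md = array(res$md, d),
       clamped = array(res$clamped, d))
}

# trilinear interpolation of the 6 tensor components at a point in mm;
# world position of voxel index i (1-based) along an axis is (i-1)*voxel_size
interp_tensor <- function(tf, pos) {
  d <- dim(tf$D)[1:3]
  u <- pos / tf$voxel_size + 1
  if (any(u < 1) || any(u > d)) return(NULL)
  i0 <- pmin(floor(u), d - 1L); i0 <- pmax(i0, 1L)
  w <- u - i0
  out <- numeric(6L)
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wt <- (if (dx) w[1] else 1 - w[1]) *
          (if (dy) w[2] else 1 - w[2]) *
          (if (dz) w[3] else 1 - w[3])
    if (wt > 0)
      out <- out + wt * tf$D[i0[1] + dx, i0[2] + dy, i0[3] + dz, ]
  }
  out
}

# trilinear interpolation of a 3-D scalar map at a point in mm
interp_scalar <- function(map, voxel_size, pos) {
  d <- dim(map)
  u <- pos / voxel_size + 1
  if (any(u < 1) || any(u > d)) return(NA_real_)
  i0 <- pmin(floor(u), d - 1L); i0 <- pmax(i0, 1L)
  w <- u - i0
  out <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wt <- (if (dx) w[1] else 1 - w[1]) *
          (if (dy) w[2] else 1 - w[2]) *
          (if (dz) w[3] else 1 - w[3])
    if (wt > 0) out <- out + wt * map[i0[1] + dx, i0[2] + dy, i0[3] + dz]
  }
  out
}

principal_direction <- function(D6) {
  A <- matrix(c(D6[1], D6[4], D6[5],
                D6[4], D6[2], D6[6],
                D6[5], D6[6], D6[3]), 3, 3)
  eigen(A, symmetric = TRUE)$vectors[, 1]
}

fa_of_tensor6 <- function(D6) {
  fa_md_from_eigenvalues(tensor_eigenvalues(matrix(D6, 1L)))$fa
}

#' Deterministic interpolated-streamline tractography
#'
#' Seeds \code{seeds_per_voxel} uniformly placed points in every voxel whose
#' FA exceeds \code{fa_thresh} and integrates bidirectionally along the
#' principal eigenvector of the trilinearly interpolated tensor. A streamline
#' terminates when local FA drops to or below the threshold, when the turn
#' between consecutive steps exceeds \code{angle_thresh_deg}, or when it
#' leaves the volume. Defaults follow the standard deterministic protocol:
#' FA > 0.2, 35 degree angle threshold, 10 random seeds per voxel.
#'
#' @param tf A \code{tensor_field}.
#' @param fa_thresh FA threshold for seeding and propagation.
#' @param angle_thresh_deg Maximum turning angle between steps, degrees.
#' @param seeds_per_voxel Random seed points per suprathreshold voxel.
#' @param step_mm Integration step in mm.
#' @param seed Integer RNG seed (seed placement only; tracking is
#'   deterministic).
#' @param max_steps Safety cap on steps per direction.
#' @return Object of class \code{streamline_set}: list with \code{points}
#'   (list of k x 3 mm coordinate matrices) and \code{lengths} (polyline arc
#'   lengths in mm). Empty when no voxel passes the threshold.
#' @export
track_streamlines <- function(tf, fa_thresh = 0.2, angle_thresh_deg = 35,
                              seeds_per_voxel = 10L, step_mm = 0.1,
                              seed = 1L, max_steps = 2000L) {
  d <- dim(tf$D)[1:3]
  vs <- tf$voxel_size
  sc <- tensor_scalars(tf)
  seed_vox <- which(sc$fa > fa_thresh, arr.ind = TRUE)
  cos_thresh <- cos(angle_thresh_deg * pi / 180)

  walk <- function(pos, dir0) {
    pts <- list()
    pos_c <- pos; dir_c <- dir0
    for (s in seq_len(max_steps)) {
      nxt <- pos_c + step_mm * dir_c
      D6 <- interp_tensor(tf, nxt)
      if (is.null(D6)) break                        # left the volume
      if (fa_of_tensor6(D6) <= fa_thresh) break
      v <- principal_direction(D6)
      dp <- sum(v * dir_c)
      if (dp < 0) { v <- -v; dp <- -dp }
      if (dp < cos_thresh) break                    # turn too sharp
      pts[[length(pts) + 1L]] <- nxt
      pos_c <- nxt; dir_c <- v
    }
    pts
  }

  result <- if (nrow(seed_vox) == 0L) list() else with_seed(seed, {
    out <- list()
    for (i in seq_len(nrow(seed_vox))) {
      ctr <- (seed_vox[i, ] - 1) * vs
      offs <- matrix(stats::runif(3L * seeds_per_voxel, -0.5, 0.5),
                     ncol = 3L) * rep(vs, each = seeds_per_voxel)
      for (k in seq_len(seeds_per_voxel)) {
        p0 <- ctr + offs[k, ]
        D6 <- interp_tensor(tf, p0)
        if (is.null(D6) || fa_of_tensor6(D6) <= fa_thresh) next
        v0 <- principal_direction(D6)
        fwd <- walk(p0, v0)
        bwd <- walk(p0, -v0)
        pts <- c(rev(bwd), list(p0), fwd)
        if (length(pts) < 2L) next
        out[[length(out) + 1L]] <- do.call(rbind, pts)
      }
    }
    out
  })
  lens <- vapply(result, function(p)
    sum(sqrt(rowSums(diff(p)^2))), numeric(1))
  structure(list(points = result, lengths = lens,
                 voxel_size = vs, grid = d),
            class = "streamline_set")
}

#' @export
print.streamline_set <- function(x, ...) {
  cat("streamline_set:", length(x$points), "streamlines")
  if (length(x$lengths)) cat(", median length",
                             signif(stats::median(x$lengths), 3), "mm")
  cat("\n")
  invisible(x)
}

#' Build an FA-weighted structural connectome
#'
#' A streamline contributes to ROI pair (A, B) iff its two endpoint voxels
#' carry gray-matter labels A and B (A != B) and its arc length is at least
#' \code{min_length_mm} (default 1.0 mm, excluding spurious direct
#' gray-to-gray hops between neighboring areas). Edge weight is the mean FA
#' sampled (trilinearly) along all contributing tracts; by default all
#' samples are pooled, \code{per_streamline = TRUE} averages per-streamline
#' means instead.
#'
#' @param streamlines A \code{\link{track_streamlines}} result.
#' @param atlas Atlas providing gray-matter endpoint labels.
#' @param fa_map 3-D FA array on the atlas grid.
#' @param min_length_mm Minimum streamline length (default 1.0).
#' @param per_streamline Average per-streamline mean FA instead of pooling
#'   samples.
#' @return Object of class \code{connectome}: symmetric \code{weights} and
#'   \code{counts} matrices over gray label ids.
#' @export
build_connectome <- function(streamlines, atlas, fa_map, min_length_mm = 1.0,
                             per_streamline = FALSE) {
  labs <- gray_labels(atlas)
  n <- length(labs)
  vs <- atlas$voxel_size
  d <- dim(atlas$label_volume)
  weights <- counts <- matrix(0, n, n, dimnames = list(labs, labs))
  fa_sum <- fa_n <- matrix(0, n, n)
  lab_at <- function(p) {
    v <- round(p / vs) + 1L
    if (any(v < 1L) || any(v > d)) return(0L)
    atlas$label_volume[v[1], v[2], v[3]]
  }
  for (k in seq_along(streamlines$points)) {
    if (streamlines$lengths[k] < min_length_mm) next
    pts <- streamlines$points[[k]]
    la <- lab_at(pts[1, ]); lb <- lab_at(pts[nrow(pts), ])
    ia <- match(la, labs); ib <- match(lb, labs)
    if (is.na(ia) || is.na(ib) || ia == ib) next
    fa_vals <- apply(pts, 1, function(p) interp_scalar(fa_map, vs, p))
    fa_vals <- fa_vals[!is.na(fa_vals)]
    if (!length(fa_vals)) next
    i <- min(ia, ib); j <- max(ia, ib)
    counts[i, j] <- counts[i, j] + 1
    if (per_streamline) {
      fa_sum[i, j] <- fa_sum[i, j] + mean(fa_vals)
      fa_n[i, j] <- fa_n[i, j] + 1
    } else {
      fa_sum[i, j] <- fa_sum[i, j] + sum(fa_vals)
      fa_n[i, j] <- fa_n[i, j] + length(fa_vals)
    }
  }
  has <- fa_n > 0
  weights[has] <- fa_sum[has] / fa_n[has]
  weights <- weights + t(weights)
  counts <- counts + t(counts)
  structure(list(weights = weights, counts = counts, roi_ids = labs),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  ne <- sum(x$counts[upper.tri(x$counts)] > 0)
  cat("connectome:", length(x$roi_ids), "ROIs,", ne, "edges\n")
  invisible(x)
}

#' Group comparison of ROI-mean FA
#'
#' Computes per-subject mean FA within each (typically white-matter) ROI and
#' compares groups with pooled-variance two-sample t-tests,
#' Benjamini-Hochberg FDR adjustment and Cohen's d.
#'
#' @param fa_maps List of per-subject 3-D FA arrays on the atlas grid.
#' @param groups Factor/character vector of group labels (length of
#'   \code{fa_maps}); first level is the reference.
#' @param atlas Atlas whose white-matter ROIs are used by default.
#' @param masks Optional named list of logical 3-D masks overriding the
#'   atlas ROIs.
#' @return Data frame with per-ROI group means, t, df, p, FDR-adjusted q and
#'   d; ROIs with empty masks are skipped with a warning.
#' @export
roi_fa_stats <- function(fa_maps, groups, atlas = NULL, masks = NULL) {
  if (is.null(masks)) {
    tab <- atlas$roi_table[atlas$roi_table$tissue == "white", ]
    masks <- lapply(tab$label_id, function(l) atlas$label_volume == l)
    names(masks) <- tab$name
  }
  groups <- as.factor(groups)
  lv <- levels(groups)
  stopifnot(length(lv) == 2L, length(fa_maps) == length(groups))
  rows <- list()
  for (nm in names(masks)) {
    m <- masks[[nm]]
    if (!any(m)) { warning("empty mask skipped: ", nm); next }
    vals <- vapply(fa_maps, function(f) mean(f[m]), numeric(1))
    # degenerate (constant) inputs still report means, with NA statistics
    tt <- tryCatch(t_tests(vals[groups == lv[1]], vals[groups == lv[2]]),
                   error = function(e) list(statistic = NA_real_,
                                            df = NA_real_, p = NA_real_,
                                            d = NA_real_))
    rows[[nm]] <- data.frame(
      roi = nm, mean_g1 = mean(vals[groups == lv[1]]),
      mean_g2 = mean(vals[groups == lv[2]]),
      t = tt$statistic, df = tt$df, p = tt$p, d = tt$d,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$q <- fdr_bh(out$p)
  out
}
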