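#' Eigenvalues of a prolate tensor with prescribed FA and MD
#'
#' Closed-form inversion of the fractional-anisotropy formula for an
#' axially-symmetric (prolate, lambda2 = lambda3) tensor:
#' \eqn{FA = (\lambda_1-\lambda_2)/\sqrt{\lambda_1^2+2\lambda_2^2}}.
#'
#' @param fa Target fractional anisotropy in [0, 1).
#' @param md Target mean diffusivity in mm^2/s.
#' @return Numeric vector \code{c(l1, l2, l3)} with \code{l2 == l3}.
#' @export
prolate_eigenvalues <- function(fa, md = 0.7e-3) {
  stopifnot(fa >= 0, fa < 1, md > 0)
  if (abs(1 - 2 * fa^2) < 1e-9) {
    r <- (1 - fa^2) / 2
  } else {
    r <- (1 - fa * sqrt(3 - 2 * fa^2)) / (1 - 2 * fa^2)
  }
  l1 <- 3 * md / (1 + 2 * r)
  c(l1, r * l1, r * l1)
}

# symmetric tensor (xx,yy,zz,xy,xz,yz) with principal axis v
prolate_tensor <- function(v, evals) {
  v <- v / sqrt(sum(v^2))
  D <- evals[2] * diag(3) + (evals[1] - evals[2]) * tcrossprod(v)
  c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3])
}

#' Build a fiber-bundle tensor phantom
#'
#' Fills an atlas-sized grid with near-isotropic tensors
#' (\code{fa_outside}) and overwrites voxels within \code{radius_mm} of each
#' bundle centerline with prolate tensors (\code{fa_inside}) aligned to the
#' local centerline tangent. Where bundles cross, the first-listed bundle
#' wins (single-tensor model). Bundle endpoints must lie inside their
#' declared start/end ROIs and centerlines must stay inside the grid.
#'
#' @param atlas A \code{\link{make_atlas}}-style atlas (any integer label
#'   volume with \code{voxel_size} works).
#' @param bundle_spec List of bundles; each a list with \code{start_label},
#'   \code{end_label}, \code{centerline} (k x 3 matrix of mm coordinates;
#'   world position of voxel index i along an axis is \code{(i-1) *
#'   voxel_size}) and \code{radius_mm}.
#' @param fa_inside FA of bundle voxels (must exceed 0.2 so the standard
#'   tracking threshold separates bundle from background).
#' @param fa_outside FA of background voxels (must stay below 0.2).
#' @param md Mean diffusivity everywhere, mm^2/s.
#' @return List with \code{tensor_field} (class \code{tensor_field}: array
#'   \code{D} of per-voxel (xx,yy,zz,xy,xz,yz) components, \code{voxel_size},
#'   \code{mask}) and \code{ground_truth} (bundle spec, FA/MD targets,
#'   per-bundle voxel masks).
#' @export
sim_tensor_phantom <- function(atlas, bundle_spec, fa_inside = 0.8,
                               fa_outside = 0.05, md = 0.7e-3) {
  if (!(fa_inside > 0.2 && fa_outside < 0.2))
    stop("need fa_inside > 0.2 > fa_outside so the FA threshold separates bundle and background")
  d <- dim(atlas$label_volume)
  vs <- atlas$voxel_size
  extent <- (d - 1) * vs
  ev_in <- prolate_eigenvalues(fa_inside, md)
  ev_out <- prolate_eigenvalues(fa_outside, md)

  centers <- cbind(
    rep((seq_len(d[1]) - 1) * vs[1], times = d[2] * d[3]),
    rep(rep((seq_len(d[2]) - 1) * vs[2], each = d[1]), times = d[3]),
    rep((seq_len(d[3]) - 1) * vs[3], each = d[1] * d[2]))
  nvox <- nrow(centers)
  D <- matrix(rep(prolate_tensor(c(0, 0, 1), ev_out), each = nvox), nvox, 6L)
  assigned <- logical(nvox)
  bundle_masks <- vector("list", length(bundle_spec))

  for (bi in seq_along(bundle_spec)) {
    b <- bundle_spec[[bi]]
    cl <- as.matrix(b$centerline)
    if (any(cl < -1e-9) || any(sweep(cl, 2, extent) > 1e-9))
      stop("bundle ", bi, " centerline exits the grid")
    for (which_end in c(1L, nrow(cl))) {
      vox <- pmin(pmax(round(cl[which_end, ] / vs) + 1L, 1L), d)
      lab <- atlas$label_volume[vox[1], vox[2], vox[3]]
      want <- if (which_end == 1L) b$start_label else b$end_label
      if (lab != want)
        stop("bundle ", bi, " endpoint lies in label ", lab,
             " not its declared ROI ", want)
    }
    # densify the centerline and find for each voxel the nearest point
    seg <- diff(cl)
    seglen <- sqrt(rowSums(seg^2))
    npts <- pmax(2L, ceiling(seglen / (min(vs) / 2)))
    pts <- do.call(rbind, lapply(seq_len(nrow(seg)), function(k) {
      u <- seq(0, 1, length.out = npts[k])
      cbind(cl[k, 1] + u * seg[k, 1], cl[k, 2] + u * seg[k, 2],
            cl[k, 3] + u * seg[k, 3])
    }))
    tang <- do.call(rbind, lapply(seq_len(nrow(seg)), function(k)
      matrix(seg[k, ] / seglen[k], npts[k], 3L, byrow = TRUE)))
    d2 <- outer(rowSums(centers^2), rep(1, nrow(pts))) -
      2 * centers %*% t(pts) + outer(rep(1, nvox), rowSums(pts^2))
    nearest <- max.col(-d2)
    mind <- sqrt(pmax(d2[cbind(seq_len(nvox), nearest)], 0))
    inside <- mind <= b$radius_mm & !assigned
    bundle_masks[[bi]] <- array(mind <= b$radius_mm, dim = d)
    for (v in which(inside))
      D[v, ] <- prolate_tensor(tang[nearest[v], ], ev_in)
    assigned <- assigned | inside
  }

  tf <- structure(list(D = array(D, dim = c(d, 6L)), voxel_size = vs,
                       mask = array(TRUE, dim = d)),
                  class = "tensor_field")
  gt <- list(bundle_spec = bundle_spec, fa_inside = fa_inside,
             fa_outside = fa_outside, md = md, eigen_inside = ev_in,
             eigen_outside = ev_out, bundle_masks = bundle_masks)
  list(tensor_field = tf, ground_truth = gt)
}

#' Simulate diffusion-weighted volumes from a tensor field
#'
#' Forward model \eqn{S = S_0 \exp(-b\, g^T D g)} per gradient volume, with
#' optional Rician noise (magnitude-MR convention; \code{snr} is defined as
#' \eqn{S_0/\sigma} of the underlying complex Gaussian noise).
#'
#' @param tensor_field A \code{tensor_field}.
#' @param scheme A \code{\link{make_scheme}} result.
#' @param s0 Unweighted signal level (> 0).
#' @param snr Signal-to-noise ratio; \code{Inf} for noiseless data.
#' @param seed Integer seed (used only when noise is added).
#' @return 4-D array (x, y, z, volume).
#' @export
sim_dwi <- function(tensor_field, scheme, s0 = 1000, snr = Inf, seed = 1L) {
  if (s0 <= 0) stop("s0 must be positive")
  if (snr <= 0) stop("snr must be positive")
  d <- dim(tensor_field$D)[1:3]
  Dm <- matrix(tensor_field$D, prod(d), 6L)
  g <- scheme$directions
  b <- scheme$b_values
  C <- cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
             2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3],
             2 * g[, 2] * g[, 3]) * b
  S <- s0 * exp(-Dm %*% t(C))
  if (is.finite(snr)) {
    sigma <- s0 / snr
    S <- with_seed(seed, {
      n1 <- matrix(stats::rnorm(length(S), sd = sigma), nrow(S))
      n2 <- matrix(stats::rnorm(length(S), sd = sigma), nrow(S))
      sqrt((S + n1)^2 + n2^2)
    })
  }
  array(S, dim = c(d, length(b)))
}
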