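#' Canonical bilateral gray-matter ROI names
#'
#' The 23 bilaterally positioned cortical and subcortical gray-matter regions
#' used throughout the pipeline: medial prefrontal (dorsal/ventral), insular,
#' frontal, orbitofrontal (ventral/dorsal), accumbens, caudate-putamen, globus
#' pallidus, amygdala, thalamus, hippocampus (dorsal/ventral), substantia
#' nigra, dorsal raphe, ventral tegmental area and seven sensory/association
#' cortices. Mostly limbic-system regions receiving serotonergic innervation.
#'
#' @return Character vector of length 23.
#' @export
gray_roi_names <- function() {
  c("PFC (dm)", "PFC (vm)", "Ins", "FC", "OFC (v)", "OFC (d)", "NAc",
    "CPu", "GP", "Amy", "Tha", "Hip (d)", "Hip (v)", "SN", "DRN", "VTA",
    "ViC", "AuC", "TeC", "PtC", "MC", "SmC", "RsC")
}

#' White-matter ROI names
#'
#' Genu and body of the corpus callosum, anterior commissure (anterior part)
#' and internal capsule (anterior part).
#'
#' @return Character vector of length 4.
#' @export
white_roi_names <- function() {
  c("genu CC", "body CC", "anterior commissure", "internal capsule")
}

#' Build a synthetic bilateral ROI atlas
#'
#' Constructs an integer label volume containing \code{n_bilateral} pairs of
#' compact gray-matter ROIs mirrored across the mid-sagittal plane (x axis)
#' plus four midline white-matter ROIs. Gray pair \code{i} gets labels
#' \code{2i-1} (left) and \code{2i} (right); background is 0. ROIs named in
#' \code{small_rois} are placed as single-voxel regions to emulate structures
#' that span less than two voxels at the acquisition resolution and are
#' therefore excluded from resting-state analyses.
#'
#' @param grid_shape Integer vector of 3 voxel counts (x = left-right).
#' @param voxel_size Numeric vector of 3 voxel edge lengths in mm.
#' @param n_bilateral Number of bilateral gray-matter ROI pairs (default 23).
#' @param small_rois Names of ROIs rendered as single voxels per hemisphere.
#' @param seed Unused (placement is deterministic); accepted for interface
#'   uniformity with the other simulators.
#' @return An object of class \code{roi_atlas}: list with \code{label_volume}
#'   (3-D integer array), \code{voxel_size} and \code{roi_table} (data frame
#'   with \code{label_id}, \code{name}, \code{hemisphere},
#'   \code{homolog_label_id}, \code{tissue}).
#' @export
make_atlas <- function(grid_shape = c(32L, 32L, 12L),
                       voxel_size = c(0.5, 0.5, 0.5),
                       n_bilateral = 23L,
                       small_rois = c("VTA", "DRN", "OFC (v)", "FC"),
                       seed = NULL) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3, length(voxel_size) == 3,
            all(voxel_size > 0), n_bilateral >= 1)
  nx <- grid_shape[1]; ny <- grid_shape[2]; nz <- grid_shape[3]

  # hemisphere slots: 3-voxel cells with a 2x2x2 ROI block inside each
  cell <- 3L
  left_width <- nx %/% 2L - 1L          # keep >= 2 midline columns free
  n_cells <- c(left_width %/% cell, ny %/% cell, nz %/% cell)
  n_slots <- prod(pmax(n_cells, 0L))
  if (n_slots < n_bilateral || ny < 12L || nz < 2L) {
    need_x <- 2L * (cell * ceiling(n_bilateral / max(1L, (ny %/% cell) * (nz %/% cell))) + 1L) + 2L
    stop("grid too small to place ", n_bilateral,
         " bilateral ROI pairs plus 4 white-matter ROIs; ",
         "need at least c(", max(need_x, 14L), ", 12, 6) voxels")
  }

  names_pool <- if (n_bilateral == 23L) gray_roi_names()
                else paste0("ROI", seq_len(n_bilateral))
  if (n_bilateral == 23L && n_bilateral != length(names_pool))
    stop("internal: name pool mismatch")

  vol <- array(0L, dim = grid_shape)
  rows <- vector("list", 2L * n_bilateral + 4L)

  slot <- 0L
  for (zc in seq_len(n_cells[3])) for (yc in seq_len(n_cells[2])) for (xc in seq_len(n_cells[1])) {
    if (slot >= n_bilateral) break
    slot <- slot + 1L
    nm <- names_pool[slot]
    x0 <- (xc - 1L) * cell + 1L
    y0 <- (yc - 1L) * cell + 1L
    z0 <- (zc - 1L) * cell + 1L
    if (nm %in% small_rois) {
      xs <- x0; ys <- y0; zs <- z0
    } else {
      xs <- x0:(x0 + 1L); ys <- y0:(y0 + 1L); zs <- z0:(z0 + 1L)
    }
    lab_l <- 2L * slot - 1L; lab_r <- 2L * slot
    vol[xs, ys, zs] <- lab_l
    vol[nx + 1L - xs, ys, zs] <- lab_r        # mirror across midline
    rows[[2L * slot - 1L]] <- data.frame(
      label_id = lab_l, name = nm, hemisphere = "left",
      homolog_label_id = lab_r, tissue = "gray", stringsAsFactors = FALSE)
    rows[[2L * slot]] <- data.frame(
      label_id = lab_r, name = nm, hemisphere = "right",
      homolog_label_id = lab_l, tissue = "gray", stringsAsFactors = FALSE)
  }

  # midline white-matter blocks stacked along y
  wm_names <- white_roi_names()
  midx <- c(nx %/% 2L + 1L)
  if (nx %/% 2L + 1L <= nx) midx <- c(nx %/% 2L, nx %/% 2L + 1L)
  zmid <- max(1L, nz %/% 2L):min(nz, nz %/% 2L + 1L)
  for (k in seq_along(wm_names)) {
    lab <- 2L * n_bilateral + k
    ys <- (3L * (k - 1L) + 1L):(3L * (k - 1L) + 3L)
    vol[midx, ys, zmid] <- as.integer(lab)
    rows[[2L * n_bilateral + k]] <- data.frame(
      label_id = as.integer(lab), name = wm_names[k], hemisphere = NA_character_,
      homolog_label_id = NA_integer_, tissue = "white", stringsAsFactors = FALSE)
  }

  atlas <- list(label_volume = vol, voxel_size = as.numeric(voxel_size),
                roi_table = do.call(rbind, rows))
  class(atlas) <- "roi_atlas"
  atlas
}

#' Homolog label mapping of a bilateral atlas
#'
#' @param atlas A \code{roi_atlas}.
#' @return Named integer vector mapping each gray label to its contralateral
#'   homolog.
#' @export
homolog_map <- function(atlas) {
  tab <- atlas$roi_table[atlas$roi_table$tissue == "gray", ]
  stats::setNames(tab$homolog_label_id, tab$label_id)
}

#' Labels of gray-matter ROIs
#' @param atlas A \code{roi_atlas}.
#' @param hemisphere Optional filter: "left" or "right".
#' @return Integer label ids.
#' @export
gray_labels <- function(atlas, hemisphere = NULL) {
  tab <- atlas$roi_table[atlas$roi_table$tissue == "gray", ]
  if (!is.null(hemisphere)) tab <- tab[tab$hemisphere == hemisphere, ]
  tab$label_id
}

#' ROI voxel counts
#' @param atlas A \code{roi_atlas}.
#' @return Named integer vector: voxels per label id (atlas order).
#' @export
roi_voxel_counts <- function(atlas) {
  counts <- table(factor(atlas$label_volume[atlas$label_volume > 0],
                         levels = atlas$roi_table$label_id))
  stats::setNames(as.integer(counts), names(counts))
}

#' @export
print.roi_atlas <- function(x, ...) {
  tab <- x$roi_table
  cat("roi_atlas:", paste(dim(x$label_volume), collapse = " x "),
      "voxels @", paste(x$voxel_size, collapse = " x "), "mm\n")
  cat("  ", sum(tab$tissue == "gray") / 2, "bilateral gray ROI pairs,",
      sum(tab$tissue == "white"), "white-matter ROIs\n")
  invisible(x)
}
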