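#' Construct a BOLD time-series object
#'
#' Container for resting-state or pharmacological BOLD data, either
#' voxel-organized (4-D array, x/y/z/time) or ROI-organized (ROI x time
#' matrix), with the acquisition time grid and optional known nuisance
#' regressors (global mean signal, six motion parameters, linear trend).
#'
#' @param data 4-D numeric array (voxel-organized) or ROI x time matrix.
#' @param tr Repetition time in seconds.
#' @param frame_times Optional frame times (s); defaults to
#'   \code{(0:(nt-1)) * tr}. Must be strictly increasing and uniformly spaced.
#' @param nuisance Optional time x regressor matrix.
#' @param voxel_size Voxel edge lengths in mm (voxel-organized data).
#' @param roi_ids ROI identifiers for ROI-organized data.
#' @return An object of class \code{bold_series}.
#' @export
bold_series <- function(data, tr, frame_times = NULL, nuisance = NULL,
                        voxel_size = NULL, roi_ids = NULL) {
  kind <- if (is.array(data) && length(dim(data)) == 4L) "voxel"
          else if (is.matrix(data)) "roi"
          else stop("data must be a 4-D array or an ROI x time matrix")
  nt <- if (kind == "voxel") dim(data)[4] else ncol(data)
  if (is.null(frame_times)) frame_times <- (seq_len(nt) - 1) * tr
  if (length(frame_times) != nt) stop("frame_times length must match time axis")
  dt <- diff(frame_times)
  if (any(dt <= 0) || (length(dt) > 1 && max(abs(dt - dt[1])) > 1e-8 * dt[1]))
    stop("frame_times must be strictly increasing and uniformly spaced")
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (nrow(nuisance) != nt) stop("nuisance regressors must have one row per frame")
  }
  if (kind == "voxel" && is.null(voxel_size))
    stop("voxel-organized series needs voxel_size")
  if (kind == "roi" && is.null(roi_ids)) roi_ids <- seq_len(nrow(data))
  structure(list(data = data, tr = tr, frame_times = frame_times,
                 nuisance = nuisance, voxel_size = voxel_size,
                 roi_ids = roi_ids, kind = kind),
            class = "bold_series")
}

#' @export
print.bold_series <- function(x, ...) {
  if (x$kind == "voxel")
    cat("bold_series (voxel):", paste(dim(x$data)[1:3], collapse = " x "),
        "voxels,", dim(x$data)[4], "frames, TR", x$tr, "s\n")
  else
    cat("bold_series (roi):", nrow(x$data), "ROIs,", ncol(x$data),
        "frames, TR", x$tr, "s\n")
  invisible(x)
}

n_frames <- function(series) {
  if (series$kind == "voxel") dim(series$data)[4] else ncol(series$data)
}

# data as (space x time) matrix regardless of organization
flat_data <- function(series) {
  if (series$kind == "voxel") {
    d <- dim(series$data)
    matrix(series$data, prod(d[1:3]), d[4])
  } else series$data
}

replace_data <- function(series, flat) {
  if (series$kind == "voxel") {
    series$data <- array(flat, dim = dim(series$data))
  } else {
    dimnames(flat) <- dimnames(series$data)
    series$data <- flat
  }
  series
}
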