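#' ROI time-series container
#'
#' Wraps a frames x nodes matrix of region-of-interest (ROI) signal values,
#' together with node labels and the (informational) sampling interval.
#'
#' @param values Numeric matrix, frames in rows, nodes in columns.
#' @param node_labels Character vector of node labels, one per column.
#'   Defaults to the column names of `values`, or `node_001`-style labels.
#' @param tr_seconds Sampling interval (repetition time) in seconds.
#'
#' @return An object of class `roi_timeseries`.
#' @export
roi_timeseries <- function(values, node_labels = NULL, tr_seconds = 2.15) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("time-series values must be numeric")
  if (ncol(values) < 2L) stop("a time series needs at least 2 nodes")
  if (anyNA(values) || any(!is.finite(values)))
    stop("time-series values must be finite")
  if (is.null(node_labels)) node_labels <- colnames(values)
  if (is.null(node_labels))
    node_labels <- sprintf("node_%03d", seq_len(ncol(values)))
  if (length(node_labels) != ncol(values))
    stop("need exactly one label per node")
  dimnames(values) <- list(NULL, node_labels)
  structure(
    list(values = values, node_labels = node_labels,
         tr_seconds = tr_seconds),
    class = "roi_timeseries"
  )
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat(sprintf("<roi_timeseries> %d frames x %d nodes (TR = %g s)\n",
              nrow(x$values), ncol(x$values), x$tr_seconds))
  invisible(x)
}

#' @export
dim.roi_timeseries <- function(x) dim(x$values)

#' Rigid-body motion trace
#'
#' Frames x 6 matrix of head-motion parameters: three translations in mm
#' and three rotations in radians, aligned frame-by-frame with the ROI
#' time series of the same scan.
#'
#' @param values Numeric matrix with 6 columns, frames in rows. Column
#'   order is `trans_x_mm`, `trans_y_mm`, `trans_z_mm`, `rot_x_rad`,
#'   `rot_y_rad`, `rot_z_rad`.
#'
#' @return An object of class `motion_trace`.
#' @export
motion_trace <- function(values) {
  values <- as.matrix(values)
  if (ncol(values) != 6L) stop("a motion trace has exactly 6 parameters")
  if (anyNA(values) || any(!is.finite(values)))
    stop("motion parameters must be finite")
  colnames(values) <- c("trans_x_mm", "trans_y_mm", "trans_z_mm",
                        "rot_x_rad", "rot_y_rad", "rot_z_rad")
  structure(list(values = values), class = "motion_trace")
}

#' @export
print.motion_trace <- function(x, ...) {
  cat(sprintf("<motion_trace> %d frames x 6 DOF\n", nrow(x$values)))
  invisible(x)
}

#' @export
dim.motion_trace <- function(x) dim(x$values)

#' Symmetric weighted adjacency matrix
#'
#' Functional-connectivity network: a symmetric real matrix of edge
#' weights (Fisher-z transformed Pearson correlations) with an exactly
#' zero diagonal.
#'
#' @param weights Square numeric matrix; must be symmetric to within
#'   1e-12 and have all diagonal entries 0.
#' @param node_labels Optional node labels (defaults to row names).
#'
#' @return An object of class `adjacency_matrix`.
#' @export
adjacency_matrix <- function(weights, node_labels = NULL) {
  weights <- as.matrix(weights)
  n <- nrow(weights)
  if (ncol(weights) != n) stop("adjacency matrix must be square")
  if (anyNA(weights) || any(!is.finite(weights)))
    stop("adjacency weights must be finite")
  if (any(abs(weights - t(weights)) > 1e-12))
    stop("adjacency matrix must be symmetric (tolerance 1e-12)")
  if (any(diag(weights) != 0))
    stop("adjacency diagonal must be exactly zero")
  weights <- (weights + t(weights)) / 2  # exact symmetry
  if (is.null(node_labels)) node_labels <- rownames(weights)
  if (is.null(node_labels)) node_labels <- sprintf("node_%03d", seq_len(n))
  if (length(node_labels) != n) stop("need exactly one label per node")
  dimnames(weights) <- list(node_labels, node_labels)
  structure(list(weights = weights, node_labels = node_labels),
            class = "adjacency_matrix")
}

#' @export
print.adjacency_matrix <- function(x, ...) {
  w <- x$weights[upper.tri(x$weights)]
  cat(sprintf("<adjacency_matrix> %d nodes; weights in [%.3f, %.3f]\n",
              nrow(x$weights), min(w), max(w)))
  invisible(x)
}

#' @export
dim.adjacency_matrix <- function(x) dim(x$weights)

#' Plot an adjacency matrix as a heat map
#'
#' @param x An [adjacency_matrix()].
#' @param main Plot title.
#' @param ... Passed to [graphics::image()].
#' @export
plot.adjacency_matrix <- function(x, main = "Functional adjacency", ...) {
  n <- nrow(x$weights)
  graphics::image(seq_len(n), seq_len(n), t(x$weights[n:1, , drop = FALSE]),
                  xlab = "node", ylab = "node", main = main,
                  useRaster = n > 64, ...)
  invisible(x)
}

#' Discard initial volumes of a scan
#'
#' Removes the first `k` frames (scanner field-equilibration volumes)
#' from a time series or motion trace. The caller is responsible for
#' applying the same `k` to the paired object so that frames stay
#' aligned.
#'
#' @param x A [roi_timeseries()] or [motion_trace()].
#' @param k Number of initial frames to drop (default 3).
#' @return An object of the same class with `k` fewer frames.
#' @export
drop_initial_volumes <- function(x, k = 3L) {
  UseMethod("drop_initial_volumes")
}

#' @export
drop_initial_volumes.roi_timeseries <- function(x, k = 3L) {
  k <- .check_drop_k(nrow(x$values), k)
  if (k == 0L) return(x)
  roi_timeseries(x$values[-seq_len(k), , drop = FALSE],
                 node_labels = x$node_labels, tr_seconds = x$tr_seconds)
}

#' @export
drop_initial_volumes.motion_trace <- function(x, k = 3L) {
  k <- .check_drop_k(nrow(x$values), k)
  if (k == 0L) return(x)
  motion_trace(x$values[-seq_len(k), , drop = FALSE])
}

.check_drop_k <- function(frames, k) {
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 0L)
    stop("k must be a single non-negative integer")
  if (frames <= k)
    stop(sprintf("cannot drop %d initial volumes from %d frames", k, frames))
  k
}

#' Framewise displacement
#'
#' Scalar head-movement summary per frame-to-frame transition: the sum of
#' absolute translation differences plus the sum of absolute rotation
#' differences converted to arc length on a sphere of radius
#' `head_radius_mm`.
#'
#' @param motion A [motion_trace()] with at least 2 frames.
#' @param head_radius_mm Radius (mm) used to convert rotations to mm of
#'   arc displacement. Default 50.
#' @return Numeric vector of length `frames - 1`, displacement in mm.
#' @export
frame_displacement <- function(motion, head_radius_mm = 50) {
  stopifnot(inherits(motion, "motion_trace"))
  m <- motion$values
  if (nrow(m) < 2L) stop("frame displacement needs at least 2 frames")
  d <- abs(diff(m))
  d[, 4:6] <- d[, 4:6] * head_radius_mm
  unname(rowSums(d))
}

#' Motion-scrubbing frame mask
#'
#' Marks frames to retain. For every transition whose framewise
#' displacement strictly exceeds `threshold_mm`, the latter frame of the
#' transition is excluded (and optionally also the preceding frame).
#'
#' @param displacement Displacement vector from [frame_displacement()].
#' @param threshold_mm Scrub threshold in mm; exclusion requires
#'   displacement strictly greater than this value. Default 1.5.
#' @param drop_preceding Also drop the frame before a flagged transition.
#'   Default `FALSE`.
#' @return Logical vector of length `frames` (`length(displacement) + 1`);
#'   `TRUE` marks a retained frame.
#' @export
scrub_mask <- function(displacement, threshold_mm = 1.5,
                       drop_preceding = FALSE) {
  if (anyNA(displacement) || any(!is.finite(displacement)))
    stop("displacement must be finite")
  n <- length(displacement) + 1L
  keep <- rep(TRUE, n)
  bad <- which(displacement > threshold_mm)  # strict
  keep[bad + 1L] <- FALSE
  if (drop_preceding) keep[bad] <- FALSE
  keep
}

#' Average head motion covariate
#'
#' Mean absolute frame-to-frame change over the whole scan, averaged
#' across the 6 motion parameters. Rotations are converted to mm of arc
#' on a sphere of `head_radius_mm` so the six parameters are
#' commensurable.
#'
#' @inheritParams frame_displacement
#' @return Single non-negative number (mm).
#' @export
mean_motion <- function(motion, head_radius_mm = 50) {
  stopifnot(inherits(motion, "motion_trace"))
  m <- motion$values
  if (nrow(m) < 2L) stop("mean motion needs at least 2 frames")
  d <- abs(diff(m))
  d[, 4:6] <- d[, 4:6] * head_radius_mm
  mean(colMeans(d))
}

#' Pearson correlation matrix over retained frames
#'
#' @param ts A [roi_timeseries()].
#' @param mask Optional logical retained-frame mask from [scrub_mask()];
#'   `NULL` keeps all frames.
#' @return Symmetric nodes x nodes correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(ts, mask = NULL) {
  stopifnot(inherits(ts, "roi_timeseries"))
  v <- ts$values
  if (!is.null(mask)) {
    if (length(mask) != nrow(v))
      stop("mask length must equal the number of frames")
    v <- v[mask, , drop = FALSE]
  }
  if (nrow(v) < 3L)
    stop(sprintf("only %d retained frames; need at least 3 to correlate",
                 nrow(v)))
  sds <- apply(v, 2L, stats::sd)
  if (any(sds == 0))
    stop("zero-variance node(s) over retained frames: ",
         paste(ts$node_labels[sds == 0], collapse = ", "))
  r <- stats::cor(v)
  r <- (r + t(r)) / 2
  r
}

#' Fisher z-transform of a correlation matrix
#'
#' Maps off-diagonal Pearson correlations through arctanh to an
#' approximately normal scale and zeroes the diagonal, yielding the
#' weighted functional adjacency matrix.
#'
#' @param r Square symmetric correlation matrix (diagonal 1 or 0);
#'   off-diagonal entries must satisfy |r| < 1.
#' @param node_labels Optional labels (default: dimnames of `r`).
#' @return An [adjacency_matrix()] of Fisher-z weights.
#' @export
fisher_transform <- function(r, node_labels = NULL) {
  r <- as.matrix(r)
  off <- abs(r) >= 1
  diag(off) <- FALSE
  if (any(off)) {
    ij <- which(off, arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "off-diagonal |r| >= 1 between nodes %d and %d: Fisher z undefined",
      ij[1L], ij[2L]))
  }
  z <- atanh(r)
  diag(z) <- 0
  if (is.null(node_labels)) node_labels <- rownames(r)
  adjacency_matrix(z, node_labels = node_labels)
}

#' Build a scrubbed Fisher-z adjacency matrix for one scan
#'
#' Composes the full single-subject connectivity chain: discard initial
#' volumes, compute framewise displacement, scrub high-motion frames,
#' correlate the retained frames and Fisher-transform.
#'
#' @param ts A [roi_timeseries()] (raw scan, before volume discarding).
#' @param motion The paired [motion_trace()]; must have the same number
#'   of frames as `ts`.
#' @param drop_volumes Initial volumes to discard (default 3).
#' @param fd_threshold_mm Scrub threshold in mm (default 1.5, strict).
#' @param head_radius_mm Rotation-to-mm conversion radius (default 50).
#' @param drop_preceding Also scrub the frame before a flagged
#'   transition (default `FALSE`).
#' @return A list with elements `adjacency` (the [adjacency_matrix()]),
#'   `mean_motion` (motion covariate, computed on the post-discard
#'   trace), `n_frames_retained`, and `mask` (retained-frame mask after
#'   discarding).
#' @export
build_adjacency <- function(ts, motion, drop_volumes = 3L,
                            fd_threshold_mm = 1.5, head_radius_mm = 50,
                            drop_preceding = FALSE) {
  stopifnot(inherits(ts, "roi_timeseries"), inherits(motion, "motion_trace"))
  if (nrow(ts$values) != nrow(motion$values))
    stop("time series and motion trace must have equal frame counts")
  if (drop_volumes > 0L) {
    ts <- drop_initial_volumes(ts, drop_volumes)
    motion <- drop_initial_volumes(motion, drop_volumes)
  }
  fd <- frame_displacement(motion, head_radius_mm = head_radius_mm)
  mask <- scrub_mask(fd, threshold_mm = fd_threshold_mm,
                     drop_preceding = drop_preceding)
  r <- correlation_matrix(ts, mask)
  list(
    adjacency = fisher_transform(r, node_labels = ts$node_labels),
    mean_motion = mean_motion(motion, head_radius_mm = head_radius_mm),
    n_frames_retained = sum(mask),
    mask = mask
  )
}
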