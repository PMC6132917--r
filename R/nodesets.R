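#' Named node set
#'
#' An ordered set of node positions into the whole-brain atlas ordering,
#' with optional human-readable region labels. Indices are stored
#' 1-based (R convention); the on-disk JSON schema uses 0-based indices
#' and is converted on load.
#'
#' @param name Set name (e.g. `"pain"`, `"dmn"`, `"whole_brain"`).
#' @param indices Integer vector of 1-based node positions, unique, all
#'   within `[1, n_total]`.
#' @param n_total Number of nodes in the whole-brain ordering the
#'   indices refer to.
#' @param region_labels Optional character vector of region names, one
#'   per index.
#' @return An object of class `node_set`.
#' @export
node_set <- function(name, indices, n_total, region_labels = NULL) {
  indices <- as.integer(indices)
  n_total <- as.integer(n_total)
  if (anyNA(indices) || any(indices < 1L) || any(indices > n_total))
    stop(sprintf("node indices for '%s' must lie in [1, %d]", name, n_total))
  if (anyDuplicated(indices))
    stop(sprintf("duplicate node indices in set '%s'", name))
  if (!is.null(region_labels) && length(region_labels) != length(indices))
    stop("need one region label per index")
  structure(
    list(name = name, indices = indices, n_total = n_total,
         region_labels = region_labels),
    class = "node_set"
  )
}

#' @export
print.node_set <- function(x, ...) {
  cat(sprintf("<node_set> '%s': %d of %d nodes\n",
              x$name, length(x$indices), x$n_total))
  invisible(x)
}

#' @export
length.node_set <- function(x) length(x$indices)

# Cardinalities of the packaged sets; checked on every load.
.packaged_sizes <- c(pain = 16L, dmn = 58L, whole_brain = 264L)

#' Load a packaged or user-defined node set
#'
#' The three packaged sets mirror the study design: the whole brain
#' (264 atlas nodes), the default mode network (58 of those nodes), and
#' a 16-node pain network formed from the positive-weight regions of the
#' neural pain signature. The packaged pain set carries the 16 region
#' names; its concrete index assignment (and the DMN's) into the 264-node
#' ordering is a synthetic placeholder — the published atlas tables are
#' not redistributed here — so users analysing real data should supply
#' their own definition file with the true indices. All downstream
#' computation is index-set-generic, so substituting the file is the only
#' change needed.
#'
#' @param name One of `"whole_brain"`, `"dmn"`, `"pain"`, or the path to
#'   a JSON definition file with fields `name`, `n_total`,
#'   `indices` (0-based) and optionally `labels`.
#' @return A [node_set()].
#' @export
load_nodeset <- function(name) {
  packaged <- name %in% names(.packaged_sizes)
  if (packaged) {
    path <- system.file("extdata", "nodesets", paste0(name, ".json"),
                        package = "painnet", mustWork = TRUE)
  } else if (file.exists(name)) {
    path <- name
  } else {
    stop(sprintf(
      "unknown node set '%s' (not a packaged name or an existing file)",
      name))
  }
  def <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (fld in c("name", "n_total", "indices"))
    if (is.null(def[[fld]]))
      stop(sprintf("node-set file '%s' lacks required field '%s'", path, fld))
  ns <- node_set(def$name, as.integer(def$indices) + 1L, def$n_total,
                 region_labels = def$labels)
  if (packaged && length(ns) != .packaged_sizes[[def$name]])
    stop(sprintf("node set '%s' has %d indices; expected %d",
                 def$name, length(ns), .packaged_sizes[[def$name]]))
  ns
}

#' Induced subnetwork of an adjacency matrix
#'
#' Restricts the network to the nodes of a set, preserving edge weights
#' and the set's node order.
#'
#' @param adj An [adjacency_matrix()].
#' @param nodes A [node_set()] (or plain integer vector of 1-based
#'   indices) selecting the subnetwork.
#' @return An [adjacency_matrix()] over the selected nodes.
#' @export
induced_subgraph <- function(adj, nodes) {
  stopifnot(inherits(adj, "adjacency_matrix"))
  idx <- if (inherits(nodes, "node_set")) nodes$indices else as.integer(nodes)
  n <- nrow(adj$weights)
  if (any(idx < 1L) || any(idx > n))
    stop(sprintf("node index out of range for a %d-node network", n))
  adjacency_matrix(adj$weights[idx, idx, drop = FALSE],
                   node_labels = adj$node_labels[idx])
}

#' Spherical region of interest
#'
#' @param center Numeric length-3 world-space centre (mm).
#' @param radius_mm Sphere radius in mm (default 5).
#' @param label Optional ROI label.
#' @return An object of class `sphere_roi`.
#' @export
sphere_roi <- function(center, radius_mm = 5, label = NULL) {
  center <- as.numeric(center)
  if (length(center) != 3L || anyNA(center))
    stop("sphere centre must be three finite world coordinates (mm)")
  if (!is.finite(radius_mm) || radius_mm <= 0)
    stop("sphere radius must be positive")
  structure(list(center = center, radius_mm = radius_mm, label = label),
            class = "sphere_roi")
}

#' Extract sphere-ROI mean time series from a 4D NIfTI volume
#'
#' For each ROI and frame, averages the voxels whose centres (in world
#' coordinates, via the volume's affine) lie within the sphere radius of
#' the ROI centre. An optional ingestion path for preprocessed
#' standard-space data; requires the RNifti package.
#'
#' @param volume Path to a 4D NIfTI file, or an `RNifti` image object.
#' @param rois List of [sphere_roi()] objects.
#' @param tr_seconds Sampling interval recorded on the result; if `NULL`,
#'   taken from the NIfTI header.
#' @return A [roi_timeseries()], frames x ROIs.
#' @export
extract_roi_timeseries <- function(volume, rois, tr_seconds = NULL) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("extract_roi_timeseries requires the RNifti package")
  img <- if (is.character(volume)) RNifti::readNifti(volume) else volume
  dm <- dim(img)
  if (length(dm) != 4L) stop("expected a 4D volume (x, y, z, time)")
  xf <- RNifti::xform(img)
  if (is.null(tr_seconds)) {
    px <- attr(RNifti::niftiHeader(img), "pixdim")
    tr_seconds <- RNifti::niftiHeader(img)$pixdim[5L]
  }
  grid <- as.matrix(expand.grid(i = seq_len(dm[1L]), j = seq_len(dm[2L]),
                                k = seq_len(dm[3L])))
  world <- RNifti::voxelToWorld(grid, img)
  nframe <- dm[4L]
  vol <- array(img, dim = dm)
  flat <- matrix(vol, nrow = prod(dm[1:3]), ncol = nframe)
  out <- matrix(NA_real_, nrow = nframe, ncol = length(rois))
  labels <- character(length(rois))
  for (r in seq_along(rois)) {
    roi <- rois[[r]]
    stopifnot(inherits(roi, "sphere_roi"))
    labels[r] <- if (is.null(roi$label)) sprintf("roi_%02d", r) else roi$label
    d2 <- (world[, 1L] - roi$center[1L])^2 +
          (world[, 2L] - roi$center[2L])^2 +
          (world[, 3L] - roi$center[3L])^2
    inside <- d2 <= roi$radius_mm^2
    if (!any(inside))
      stop(sprintf("ROI '%s' contains no voxel centres", labels[r]))
    out[, r] <- colMeans(flat[inside, , drop = FALSE])
  }
  roi_timeseries(out, node_labels = labels, tr_seconds = tr_seconds)
}
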