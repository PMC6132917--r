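#' Convert connection weights to path lengths
#'
#' Strong functional connections are short paths: a positive weight `w`
#' becomes length `1/w`. Non-positive weights (after applying the
#' negative-weight policy) are treated as absent edges, length `Inf`.
#'
#' @param adj An [adjacency_matrix()].
#' @param negative_policy How to treat negative weights: `"zero"` drops
#'   them (absent edges, the default) or `"abs"` uses their magnitude.
#' @return Nodes x nodes symmetric length matrix, diagonal 0, absent
#'   edges `Inf`.
#' @export
to_lengths <- function(adj, negative_policy = c("zero", "abs")) {
  stopifnot(inherits(adj, "adjacency_matrix"))
  negative_policy <- match.arg(negative_policy)
  w <- adj$weights
  if (negative_policy == "abs") w <- abs(w)
  len <- ifelse(w > 0, 1 / w, Inf)
  diag(len) <- 0
  len
}

# Dijkstra from one source on a dense length matrix, tracking shortest-path
# counts (sigma) and predecessor lists for Brandes accumulation. Path-length
# ties are judged at relative tolerance `tol`. `nbrs`/`wts` are optional
# precomputed per-node neighbour indices and edge lengths.
.dijkstra_full <- function(len, s, tol = 1e-10, nbrs = NULL, wts = NULL) {
  n <- nrow(len)
  if (is.null(nbrs)) {
    nbrs <- wts <- vector("list", n)
    for (u in seq_len(n)) {
      w <- len[, u]
      nbrs[[u]] <- which(is.finite(w) & w > 0)
      wts[[u]] <- w[nbrs[[u]]]
    }
  }
  dist <- rep(Inf, n); dist[s] <- 0
  sigma <- numeric(n); sigma[s] <- 1
  visited <- logical(n)
  preds <- vector("list", n)
  ord <- integer(n); no <- 0L
  repeat {
    d <- dist; d[visited] <- Inf
    u <- which.min(d)
    if (!is.finite(d[u])) break
    visited[u] <- TRUE
    no <- no + 1L; ord[no] <- u
    keep <- !visited[nbrs[[u]]]
    nb <- nbrs[[u]][keep]
    if (length(nb)) {
      nd <- dist[u] + wts[[u]][keep]
      dv <- dist[nb]
      eps <- tol * nd
      imp <- nd < dv - eps             # covers unreached dv = Inf
      tie <- !imp & (nd - dv <= eps) & (dv - nd <= eps)
      ii <- nb[imp]
      dist[ii] <- nd[imp]
      sigma[ii] <- sigma[u]
      preds[ii] <- list(u)
      for (v in nb[tie]) {
        sigma[v] <- sigma[v] + sigma[u]
        preds[[v]] <- c(preds[[v]], u)
      }
    }
    if (no == n) break
  }
  list(dist = dist, sigma = sigma, preds = preds, order = ord[seq_len(no)])
}

# Distance-only Dijkstra; vectorised relaxation (no sigma/preds bookkeeping).
.dijkstra_dist <- function(len, s) {
  n <- nrow(len)
  dist <- rep(Inf, n); dist[s] <- 0
  visited <- logical(n)
  repeat {
    d <- dist; d[visited] <- Inf
    u <- which.min(d)
    if (!is.finite(d[u])) break
    visited[u] <- TRUE
    alt <- dist[u] + len[, u]
    upd <- alt < dist & !visited
    dist[upd] <- alt[upd]
    if (all(visited)) break
  }
  dist
}

#' All-pairs weighted shortest paths
#'
#' Runs Dijkstra's algorithm from every node of the length matrix,
#' returning minimal path lengths and the number of distinct minimal
#' paths per pair (path-length ties judged at relative tolerance 1e-10).
#'
#' @param lengths Length matrix from [to_lengths()].
#' @param tol Relative tolerance for judging two path lengths equal.
#' @return List with `distance` (nodes x nodes, `Inf` = unreachable) and
#'   `counts` (number of distinct shortest paths; 0 where unreachable).
#' @export
shortest_paths <- function(lengths, tol = 1e-10) {
  n <- nrow(lengths)
  dist <- matrix(Inf, n, n)
  counts <- matrix(0, n, n)
  for (s in seq_len(n)) {
    r <- .dijkstra_full(lengths, s, tol = tol)
    dist[s, ] <- r$dist
    cnt <- r$sigma
    cnt[!is.finite(r$dist)] <- 0
    counts[s, ] <- cnt
  }
  diag(counts) <- 0
  list(distance = dist, counts = counts)
}

#' Weighted global efficiency
#'
#' Mean over ordered node pairs of the inverse shortest-path length
#' (with `1/Inf = 0` for disconnected pairs); a measure of network
#' integration.
#'
#' @param adj An [adjacency_matrix()] with at least 2 nodes.
#' @inheritParams to_lengths
#' @return Single non-negative number.
#' @export
global_efficiency <- function(adj, negative_policy = c("zero", "abs")) {
  stopifnot(inherits(adj, "adjacency_matrix"))
  n <- nrow(adj$weights)
  if (n < 2L) stop("global efficiency needs at least 2 nodes")
  len <- to_lengths(adj, negative_policy)
  inv_sum <- 0
  for (s in seq_len(n)) {
    d <- .dijkstra_dist(len, s)
    inv <- 1 / d[-s]
    inv[!is.finite(d[-s])] <- 0
    inv_sum <- inv_sum + sum(inv)
  }
  inv_sum / (n * (n - 1))
}

#' Weighted betweenness centrality (Brandes)
#'
#' For each node, the sum over node pairs of the fraction of weighted
#' shortest paths between the pair that pass through the node. Reported
#' on the unordered-pair scale (each pair counted once), via Brandes'
#' dependency accumulation with the same path-length tie tolerance as
#' [shortest_paths()].
#'
#' @param adj An [adjacency_matrix()] with at least 3 nodes.
#' @inheritParams to_lengths
#' @param tol Relative tolerance for path-length ties.
#' @return Numeric vector of per-node centralities, named by node label.
#' @export
betweenness_centrality <- function(adj, negative_policy = c("zero", "abs"),
                                   tol = 1e-10) {
  stopifnot(inherits(adj, "adjacency_matrix"))
  n <- nrow(adj$weights)
  if (n < 3L) stop("betweenness centrality needs at least 3 nodes")
  len <- to_lengths(adj, negative_policy)
  stats::setNames(.brandes(len, tol = tol)$bc, adj$node_labels)
}

# One Brandes sweep over all sources: returns unordered-pair-scale BC and
# the all-pairs distance matrix as a by-product.
.brandes <- function(len, tol = 1e-10) {
  n <- nrow(len)
  bc <- numeric(n)
  dist <- matrix(Inf, n, n)
  nbrs <- wts <- vector("list", n)
  for (u in seq_len(n)) {
    w <- len[, u]
    nbrs[[u]] <- which(is.finite(w) & w > 0)
    wts[[u]] <- w[nbrs[[u]]]
  }
  for (s in seq_len(n)) {
    r <- .dijkstra_full(len, s, tol = tol, nbrs = nbrs, wts = wts)
    dist[s, ] <- r$dist
    delta <- numeric(n)
    for (v in rev(r$order)) {
      for (p in r$preds[[v]])
        delta[p] <- delta[p] + r$sigma[p] / r$sigma[v] * (1 + delta[v])
      if (v != s) bc[v] <- bc[v] + delta[v]
    }
  }
  list(bc = bc / 2, dist = dist)  # ordered -> unordered pairs
}

#' Per-participant z-scoring of betweenness centrality
#'
#' Centres and scales a subject's whole-brain BC vector so that network
#' averages are comparable across participants. If the scores have zero
#' spread, all z-scores are 0.
#'
#' @param bc Numeric vector of per-node BC scores (whole brain).
#' @param sd_type `"population"` (n denominator, default) or `"sample"`
#'   (n - 1 denominator).
#' @return Numeric vector of z-scores, same names as `bc`.
#' @export
zscore_bc <- function(bc, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  n <- length(bc)
  if (n < 2L) stop("z-scoring needs at least 2 nodes")
  mu <- mean(bc)
  s <- if (sd_type == "population") sqrt(mean((bc - mu)^2)) else stats::sd(bc)
  if (s == 0) return(stats::setNames(rep(0, n), names(bc)))
  (bc - mu) / s
}

#' Per-scan topology summary
#'
#' Computes the whole-brain global efficiency plus, for each named
#' subnetwork, its global efficiency and mean z-scored betweenness
#' centrality. BC is computed once on the whole-brain graph, z-scored
#' over all nodes, and then averaged within each subnetwork (so the mean
#' over the whole brain is 0 by construction and subnetwork means can be
#' nonzero). BC is not reported for the whole brain itself.
#'
#' @param adj Whole-brain [adjacency_matrix()].
#' @param nodesets List of [node_set()] subnetworks (e.g. pain, DMN).
#' @param subject_id,session Identifiers copied into the summary row.
#' @param mean_motion,n_frames_retained Optional scan-level covariates
#'   copied into the summary row.
#' @param subnetwork_ge `"induced"` (default) computes subnetwork GE on
#'   the induced subgraph, with paths confined to the subnetwork;
#'   `"restricted"` averages whole-brain inverse distances over
#'   subnetwork pairs.
#' @inheritParams to_lengths
#' @param sd_type z-score convention passed to [zscore_bc()].
#' @return One-row `data.frame`: `subject_id`, `session`,
#'   `ge_whole_brain`, then `ge_<set>` and `bc_<set>` per subnetwork,
#'   then `mean_motion`, `n_frames_retained`.
#' @export
summarize_topology <- function(adj, nodesets, subject_id = NA_character_,
                               session = NA_character_,
                               mean_motion = NA_real_,
                               n_frames_retained = NA_integer_,
                               subnetwork_ge = c("induced", "restricted"),
                               negative_policy = c("zero", "abs"),
                               sd_type = c("population", "sample")) {
  stopifnot(inherits(adj, "adjacency_matrix"))
  subnetwork_ge <- match.arg(subnetwork_ge)
  negative_policy <- match.arg(negative_policy)
  sd_type <- match.arg(sd_type)
  n <- nrow(adj$weights)

  len <- to_lengths(adj, negative_policy)
  br <- .brandes(len)
  dist <- br$dist
  inv <- 1 / dist
  inv[!is.finite(dist) | dist == 0] <- 0
  ge_pairs <- function(idx) {
    m <- inv[idx, idx, drop = FALSE]
    sum(m) / (length(idx) * (length(idx) - 1))
  }
  zbc <- zscore_bc(stats::setNames(br$bc, adj$node_labels),
                   sd_type = sd_type)

  out <- data.frame(subject_id = subject_id, session = session,
                    ge_whole_brain = ge_pairs(seq_len(n)),
                    stringsAsFactors = FALSE)
  for (ns in nodesets) {
    stopifnot(inherits(ns, "node_set"))
    if (any(ns$indices > n))
      stop(sprintf("node set '%s' indexes beyond the %d-node network",
                   ns$name, n))
    ge_sub <- if (subnetwork_ge == "induced")
      global_efficiency(induced_subgraph(adj, ns), negative_policy)
    else
      ge_pairs(ns$indices)
    out[[paste0("ge_", ns$name)]] <- ge_sub
    out[[paste0("bc_", ns$name)]] <- mean(zbc[ns$indices])
  }
  out$mean_motion <- mean_motion
  out$n_frames_retained <- n_frames_retained
  out
}
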