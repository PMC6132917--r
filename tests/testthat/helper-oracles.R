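# Independent oracles and fixture builders shared across test files.
# These deliberately avoid the package's own shortest-path code paths.

# Random symmetric positive-weight adjacency matrix with given edge density.
random_adjacency <- function(n, density = 0.6) {
  w <- matrix(0, n, n)
  npair <- n * (n - 1) / 2
  vals <- stats::runif(npair, 0.1, 1) * (stats::runif(npair) < density)
  w[upper.tri(w)] <- vals
  w <- w + t(w)
  adjacency_matrix(w)
}

# All-pairs shortest-path distances by Floyd-Warshall on a length matrix.
floyd_warshall <- function(len) {
  d <- len
  n <- nrow(d)
  for (k in seq_len(n))
    for (i in seq_len(n))
      d[i, ] <- pmin(d[i, ], d[i, k] + d[k, ])
  d
}

ge_from_dist <- function(d) {
  n <- nrow(d)
  inv <- 1 / d
  inv[!is.finite(d) | d == 0] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

# Betweenness centrality by exhaustive enumeration of all simple paths
# between every unordered pair (brute force; small n only). Ties in path
# length are judged at the same relative tolerance as the implementation.
bc_enumeration <- function(adj, tol = 1e-10) {
  len <- to_lengths(adj)
  n <- nrow(len)
  bc <- numeric(n)
  for (s in seq_len(n - 1L)) for (t in seq(s + 1L, n)) {
    plens <- numeric(0)
    pvias <- list()
    visited <- logical(n)
    rec <- function(u, d, via) {
      if (u == t) {
        plens[[length(plens) + 1L]] <<- d
        pvias[[length(pvias) + 1L]] <<- via
        return(invisible())
      }
      visited[u] <<- TRUE
      for (v in which(is.finite(len[u, ]) & len[u, ] > 0 & !visited))
        rec(v, d + len[u, v], if (v == t) via else c(via, v))
      visited[u] <<- FALSE
    }
    rec(s, 0, integer(0))
    if (!length(plens)) next
    plens <- unlist(plens)
    dmin <- min(plens)
    is_min <- abs(plens - dmin) <= tol * pmax(plens, dmin)
    sigma <- sum(is_min)
    through <- numeric(n)
    for (k in which(is_min)) {
      via <- pvias[[k]]
      through[via] <- through[via] + 1
    }
    bc <- bc + through / sigma
  }
  bc
}

# Group-term F statistic for dv ~ intercept + covariate + group (two
# groups), computed from normal equations, independent of lm().
ancova_F_oracle <- function(y, group, covariate) {
  g <- as.numeric(as.factor(group)) - 1
  X1 <- cbind(1, covariate, g)
  X0 <- cbind(1, covariate)
  rss <- function(X) {
    b <- solve(t(X) %*% X, t(X) %*% y)
    sum((y - X %*% b)^2)
  }
  r1 <- rss(X1); r0 <- rss(X0)
  df2 <- length(y) - ncol(X1)
  ((r0 - r1) / 1) / (r1 / df2)
}

# Exact two-sided Mann-Whitney p by enumerating every assignment of the
# pooled tie-free sample into the two groups.
mw_exact_oracle <- function(x, y) {
  n1 <- length(x)
  pool <- c(x, y)
  r <- rank(pool)
  U_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mid <- n1 * length(y) / 2
  combs <- utils::combn(length(pool), n1)
  Us <- apply(combs, 2L, function(idx)
    sum(r[idx]) - n1 * (n1 + 1) / 2)
  # two-sided: double the smaller tail, capped at 1 (matches wilcox.test)
  p <- 2 * min(mean(Us <= U_obs), mean(Us >= U_obs))
  min(p, 1)
}

# Small cohort design used across tests: 30-node network with an 8-node
# pain block, paper-sized groups, one seed argument.
scaled_design <- function(seed, beta_pain = 0, pain_noise_sd = 6, ...) {
  cohort_design(n_patients = 24, n_controls = 27, n_nodes = 30,
                pain_nodes = 1:8, n_frames = 199,
                beta_pain = beta_pain, pain_noise_sd = pain_noise_sd,
                seed = seed, ...)
}

# Tiny design for fast structural tests.
tiny_design <- function(seed = 1, ...) {
  args <- list(n_patients = 3, n_controls = 4, n_nodes = 12,
               pain_nodes = 1:4, n_frames = 60, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(cohort_design, args)
}
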