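# shared fixtures: tiny graphs and fast model settings

# star topology: node 1 is the hub, weights decreasing over the leaves
star_connectome <- function(n = 5, weights = NULL) {
  w <- matrix(0, n, n)
  if (is.null(weights)) weights <- seq(1, 0.2, length.out = n - 1)
  w[1, 2:n] <- weights
  w[2:n, 1] <- weights
  connectomeMatrix(w / max(w), normalized = TRUE)
}

# chain 1 - 2 - 3 with the two given weights
chain_connectome <- function(w12 = 0.2, w23 = 0.8) {
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- w12
  w[2, 3] <- w[3, 2] <- w23
  connectomeMatrix(w, normalized = FALSE)
}

# random dense small graph for oracle comparisons
random_connectome <- function(n = 8, seed = 1, density = 0.6) {
  set.seed(seed)
  w <- matrix(0, n, n)
  up <- which(upper.tri(w))
  on <- sample(up, round(density * length(up)))
  w[on] <- runif(length(on), 0.1, 1)
  w <- w + t(w)
  # ensure connectivity via a ring
  for (i in seq_len(n)) {
    j <- i %% n + 1
    if (w[i, j] == 0) w[i, j] <- w[j, i] <- runif(1, 0.1, 1)
  }
  connectomeMatrix(w, normalized = FALSE)
}

# fast integration settings for protocol tests (coarse but converged:
# RK4 at 0.05 ms resolves the fastest focus oscillations comfortably)
fast_dt <- 0.05

# ---- independent graph-metric oracles -------------------------------

# Barrat weighted clustering by exhaustive triple enumeration
oracle_clustering <- function(w) {
  n <- nrow(w)
  a <- (w > 0) * 1
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- sum(w[i, ])
    k <- sum(a[i, ])
    if (k < 2) next
    tot <- 0
    for (j in seq_len(n)) {
      for (h in seq_len(n)) {
        if (j == i || h == i || j == h) next
        tot <- tot + (w[i, j] + w[i, h]) / 2 * a[i, j] * a[i, h] * a[j, h]
      }
    }
    out[i] <- tot / (s * (k - 1))
  }
  out
}

# all-pairs shortest paths (reciprocal weights) by Floyd-Warshall
oracle_distances <- function(w) {
  n <- nrow(w)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[w > 0] <- 1 / w[w > 0]
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# betweenness from shortest-path counts (sigma recursion on the
# Floyd-Warshall distances; endpoints excluded, unordered pairs on
# symmetric graphs)
oracle_betweenness <- function(w) {
  n <- nrow(w)
  d <- oracle_distances(w)
  l <- matrix(Inf, n, n)
  l[w > 0] <- 1 / w[w > 0]
  sigma <- matrix(0, n, n)
  tol <- 1e-12
  for (j in seq_len(n)) {
    sigma[j, j] <- 1
    ord <- order(d[, j])
    for (i in ord) {
      if (i == j || !is.finite(d[i, j])) next
      for (k in seq_len(n)) {
        if (is.finite(l[i, k]) &&
            abs(l[i, k] + d[k, j] - d[i, j]) < tol) {
          sigma[i, j] <- sigma[i, j] + sigma[k, j]
        }
      }
    }
  }
  cb <- numeric(n)
  for (s in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i >= j || i == s || j == s) next
        if (!is.finite(d[i, j]) || sigma[i, j] == 0) next
        through <- if (abs(d[i, s] + d[s, j] - d[i, j]) < tol)
          sigma[i, s] * sigma[s, j] else 0
        cb[s] <- cb[s] + through / sigma[i, j]
      }
    }
  }
  cb
}
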