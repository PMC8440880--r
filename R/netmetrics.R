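#' Node strength
#'
#' Weighted node degree: row sums of the weight matrix,
#' \eqn{s_i = \sum_j w_{ij}}.
#'
#' @param conn a `connectome`.
#' @return numeric vector of per-region strengths.
#' @export
nodeStrength <- function(conn) {
  stopifnot(inherits(conn, "connectome"))
  rowSums(conn$weights)
}

#' Weighted clustering coefficient (Barrat)
#'
#' Weight-aware triangle density around each node,
#' \deqn{c_i^w = \frac{1}{s_i (k_i - 1)} \sum_{j,h}
#'   \frac{w_{ij} + w_{ih}}{2} a_{ij} a_{ih} a_{jh},}
#' where \eqn{s_i} is the node strength, \eqn{k_i} the degree and
#' \eqn{a_{ij}} the adjacency indicator. Nodes with fewer than two
#' neighbours get 0.
#'
#' @param conn a `connectome`.
#' @return numeric vector of per-region coefficients in `[0, 1]`.
#' @export
weightedClustering <- function(conn) {
  stopifnot(inherits(conn, "connectome"))
  W <- conn$weights
  A <- (W > 0) * 1
  # sum_{j,h} (w_ij + w_ih)/2 a_ij a_ih a_jh = sum_j w_ij (A A^T)_ij
  # by symmetry of the double sum under j <-> h
  num <- rowSums(W * (A %*% t(A)))
  s <- rowSums(W)
  k <- rowSums(A)
  c_w <- ifelse(k >= 2 & s > 0, num / (s * (k - 1)), 0)
  unname(c_w)
}

#' Weighted shortest path lengths
#'
#' All-pairs shortest paths under reciprocal edge lengths: an edge of
#' weight \eqn{w_{ij} > 0} has length \eqn{1/w_{ij}} (doubling every
#' weight halves every distance), absent edges are impassable. Asymmetric
#' matrices are treated as directed graphs. Disconnected pairs are
#' reported as `Inf` and excluded from the per-node averages.
#'
#' @param conn a `connectome`.
#' @return list with the full `distances` matrix, per-node average
#'   `L_i` (mean over reachable targets), the network average `L`, and
#'   `n_reachable` per node.
#' @export
weightedShortestPaths <- function(conn) {
  stopifnot(inherits(conn, "connectome"))
  g <- conn_graph(conn)
  d <- igraph::distances(g, mode = "out",
                         weights = 1 / igraph::E(g)$weight)
  diag(d) <- 0
  off <- d
  diag(off) <- NA
  reach <- is.finite(off)
  L_i <- rowMeans(ifelse(reach, off, NA), na.rm = TRUE)
  L_i[rowSums(reach, na.rm = TRUE) == 0] <- NA
  list(distances = d, L_i = unname(L_i),
       L = mean(off[is.finite(off)]),
       n_reachable = unname(rowSums(reach, na.rm = TRUE)))
}

#' Weighted betweenness centrality
#'
#' Number of all-pairs shortest paths passing through each node,
#' \eqn{c_B(s) = \sum_{i \ne j \ne s} d(i,j|s)/d(i,j)} (endpoints
#' excluded, unnormalized), with shortest paths under reciprocal-weight
#' edge lengths when `weighted = TRUE`. Pairs are unordered on symmetric
#' matrices and ordered on asymmetric ones.
#'
#' @param conn a `connectome`.
#' @param weighted use reciprocal-weight path lengths (otherwise hop
#'   counts).
#' @return numeric vector of per-region centralities.
#' @export
betweennessCentrality <- function(conn, weighted = TRUE) {
  stopifnot(inherits(conn, "connectome"))
  g <- conn_graph(conn)
  w <- if (weighted) 1 / igraph::E(g)$weight else NA
  unname(igraph::betweenness(g, weights = w))
}

conn_graph <- function(conn) {
  mode <- if (isSymmetric(conn$weights)) "undirected" else "directed"
  igraph::graph_from_adjacency_matrix(conn$weights, mode = mode,
                                      weighted = TRUE, diag = FALSE)
}

#' Per-region metric table
#'
#' Collects node strength, Barrat clustering, average shortest path
#' length and weighted betweenness centrality for every region, with the
#' network averages attached as an attribute.
#'
#' @param conn a `connectome`.
#' @return data frame with columns `area`, `label` (if available),
#'   `strength`, `clustering`, `avg_path`, `betweenness`; attribute
#'   `averages` holds the network means.
#' @export
metricTable <- function(conn) {
  stopifnot(inherits(conn, "connectome"))
  sp <- weightedShortestPaths(conn)
  out <- data.frame(area = seq_len(conn$n_regions),
                    strength = nodeStrength(conn),
                    clustering = weightedClustering(conn),
                    avg_path = sp$L_i,
                    betweenness = betweennessCentrality(conn))
  if (!is.null(conn$labels)) out$label <- conn$labels
  attr(out, "averages") <- c(S = mean(out$strength),
                             C_W = mean(out$clustering),
                             L = sp$L)
  out
}

#' Correlate excitability thresholds with node metrics
#'
#' For each node measure, reports the Pearson correlation (with two-sided
#' p value) between the per-region metric and the per-region thresholds
#' for asymptomatic and generalized seizure-like events. Strongly
#' connected, clustered and central regions need lower excitability to
#' trigger recruitment (negative correlations); long average path lengths
#' go with higher thresholds (positive correlation).
#'
#' @param threshold_map a [thresholdMap()] result (fields `eta_asy`,
#'   `eta_gen`).
#' @param metrics a [metricTable()] for the same regions.
#' @return data frame with one row per (metric, threshold) pair:
#'   `metric`, `threshold`, `r`, `p`, `n` (regions with both values
#'   defined). Degenerate (constant) metrics give `NA` correlations.
#' @export
thresholdMetricAnalysis <- function(threshold_map, metrics) {
  stopifnot(nrow(metrics) == length(threshold_map$eta_asy))
  cols <- c("strength", "clustering", "avg_path", "betweenness")
  th <- list(eta_asy = threshold_map$eta_asy,
             eta_gen = threshold_map$eta_gen)
  rows <- list()
  for (m in cols) {
    for (t in names(th)) {
      x <- metrics[[m]]
      y <- th[[t]]
      ok <- is.finite(x) & is.finite(y)
      if (sum(ok) >= 3 && stats::sd(x[ok]) > 0 && stats::sd(y[ok]) > 0) {
        ct <- stats::cor.test(x[ok], y[ok])
        rows[[length(rows) + 1]] <- data.frame(
          metric = m, threshold = t, r = unname(ct$estimate),
          p = ct$p.value, n = sum(ok))
      } else {
        rows[[length(rows) + 1]] <- data.frame(
          metric = m, threshold = t, r = NA_real_, p = NA_real_,
          n = sum(ok))
      }
    }
  }
  do.call(rbind, rows)
}

#' Topology profile along the recruitment order
#'
#' Sorts recruited regions by recruitment time and reports, per order
#' position (1 = first recruited), the average over runs of: the direct
#' connection weight to the EZ, the shortest path length to the EZ, and
#' the EZ-excluded node measures (strength, clustering, average shortest
#' path, betweenness computed on the graph with the EZ regions removed).
#'
#' @param results list of `recruitmentResult` objects (one per stimulated
#'   region / run).
#' @param conn the shared `connectome`.
#' @param ez_list list of EZ index sets, one per result (the stimulated
#'   regions).
#' @return data frame with one row per order position.
#' @export
recruitmentOrderProfile <- function(results, conn, ez_list) {
  stopifnot(inherits(conn, "connectome"),
            length(results) == length(ez_list))
  sp_full <- weightedShortestPaths(conn)$distances
  acc <- list()
  for (i in seq_along(results)) {
    res <- results[[i]]
    ez <- as.integer(ez_list[[i]])
    keep <- conn_drop(conn, ez)
    mt <- metricTable(keep$conn)
    recruited <- setdiff(res$order, ez)
    if (length(recruited) == 0) next
    pos <- seq_along(recruited)
    w_ez <- rowSums(conn$weights[recruited, ez, drop = FALSE])
    p_ez <- apply(sp_full[recruited, ez, drop = FALSE], 1, min)
    sub_idx <- match(recruited, keep$kept)
    acc[[length(acc) + 1]] <- data.frame(
      position = pos, area = recruited, weight_to_ez = w_ez,
      path_to_ez = p_ez,
      strength_excl = mt$strength[sub_idx],
      clustering_excl = mt$clustering[sub_idx],
      avg_path_excl = mt$avg_path[sub_idx],
      betweenness_excl = mt$betweenness[sub_idx],
      run = i)
  }
  if (length(acc) == 0) stop("no recruited regions in any result")
  long <- do.call(rbind, acc)
  agg <- stats::aggregate(
    long[c("weight_to_ez", "path_to_ez", "strength_excl",
           "clustering_excl", "avg_path_excl", "betweenness_excl")],
    by = list(position = long$position), FUN = mean)
  agg$n_runs <- as.vector(table(long$position)[as.character(agg$position)])
  agg
}

# remove regions from a connectome, keeping the index mapping
conn_drop <- function(conn, drop) {
  kept <- setdiff(seq_len(conn$n_regions), drop)
  w <- conn$weights[kept, kept, drop = FALSE]
  list(conn = connectomeMatrix(w, labels = conn$labels[kept],
                               normalized = FALSE),
       kept = kept)
}
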