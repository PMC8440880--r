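#' Generate a synthetic structural connectome
#'
#' Seeded generator of surrogate connectomes emulating the gross
#' statistics of diffusion-MRI structural connectivity: a square
#' nonnegative weight matrix with zero diagonal, connected topology,
#' approximately log-normal nonzero weights (few strong connections per
#' node, many weak ones) and weights normalized to `[0, 1]`. Edges are
#' first laid along a random spanning tree (guaranteeing connectivity),
#' then added between random region pairs until the requested density is
#' reached; `hub_bias > 0` biases the extra edges toward already
#' well-connected regions, producing hub-dominated topologies.
#'
#' @param n_regions number of regions, >= 2.
#' @param density fraction of off-diagonal pairs carrying a connection,
#'   in (0, 1]. The default 0.5 matches the connection density and node
#'   strength scale typical of probabilistic-tractography connectomes.
#' @param lognormal_mu,lognormal_sigma log-mean and log-sd of the raw
#'   weight distribution (the subsequent normalization preserves
#'   log-normality up to rescaling).
#' @param symmetric generate an undirected (symmetric) matrix.
#' @param hub_bias exponent in `[0, 1]` biasing edge placement toward
#'   high-degree nodes (0 = uniform).
#' @param seed integer seed; identical seeds give identical connectomes.
#' @return a normalized `connectome`.
#' @examples
#' synthConnectome(20, density = 0.3, seed = 1)
#' @export
synthConnectome <- function(n_regions = 90, density = 0.5,
                            lognormal_mu = -3, lognormal_sigma = 1,
                            symmetric = TRUE, hub_bias = 0, seed = NULL) {
  stopifnot(n_regions >= 2, hub_bias >= 0, hub_bias <= 1)
  if (density <= 0 || density > 1) stop("density must be in (0, 1]")
  n_pairs <- n_regions * (n_regions - 1) / 2
  n_edges <- round(density * n_pairs)
  if (n_edges < n_regions - 1)
    stop("density too low to connect ", n_regions, " regions (needs >= ",
         signif((n_regions - 1) / n_pairs, 3), ")")
  with_seed(seed, {
    adj <- matrix(FALSE, n_regions, n_regions)
    # random spanning tree: attach each node to a random earlier one
    perm <- sample.int(n_regions)
    for (i in 2:n_regions) {
      a <- perm[i]
      b <- perm[sample.int(i - 1, 1)]
      adj[a, b] <- adj[b, a] <- TRUE
    }
    # add edges up to target density, optionally hub-biased
    while (sum(adj[upper.tri(adj)]) < n_edges) {
      deg <- rowSums(adj)
      w <- (deg + 1)^hub_bias
      pick <- sample.int(n_regions, 2, prob = w)
      if (pick[1] != pick[2] && !adj[pick[1], pick[2]])
        adj[pick[1], pick[2]] <- adj[pick[2], pick[1]] <- TRUE
    }
    w <- matrix(0, n_regions, n_regions)
    idx <- which(upper.tri(adj) & adj)
    w[idx] <- stats::rlnorm(length(idx), lognormal_mu, lognormal_sigma)
    if (symmetric) {
      w <- w + t(w)
    } else {
      low <- which(lower.tri(adj) & adj)
      w[low] <- stats::rlnorm(length(low), lognormal_mu, lognormal_sigma)
    }
    normalizeConnectome(connectomeMatrix(w))
  })
}

#' Generate a synthetic EZ/PZ specification
#'
#' Builds a seeded epileptogenic-zone / propagation-zone fixture for a
#' connectome: the EZ regions are drawn at random, and the PZ is the set
#' of `pz_size` non-EZ regions ranked highest by the chosen rule --
#' either the strongest total connection weight to the EZ
#' (`"strongest_weight_neighbors"`) or the shortest weighted path length
#' to the EZ (`"shortest_path_neighbors"`). Both the clinician-style
#' (`pz_clin`) and SEEG-style (`pz_seeg`) fields are set to this set;
#' they can be edited independently afterwards.
#'
#' @param conn a `connectome`.
#' @param ez_size,pz_size set sizes with `ez_size + pz_size <
#'   n_regions`.
#' @param rule PZ selection rule.
#' @param seed integer seed.
#' @return an object of class `ezpzSpec` with 1-based integer sets `ez`,
#'   `pz_clin`, `pz_seeg`.
#' @export
synthEzPz <- function(conn, ez_size = 1, pz_size = 3,
                      rule = c("strongest_weight_neighbors",
                               "shortest_path_neighbors"),
                      seed = NULL) {
  stopifnot(inherits(conn, "connectome"))
  rule <- match.arg(rule)
  n <- conn$n_regions
  if (ez_size + pz_size >= n)
    stop("ez_size + pz_size must be smaller than the number of regions")
  with_seed(seed, {
    ez <- sort(sample.int(n, ez_size))
    others <- setdiff(seq_len(n), ez)
    score <- if (rule == "strongest_weight_neighbors") {
      rowSums(conn$weights[others, ez, drop = FALSE])
    } else {
      d <- weightedShortestPaths(conn)$distances
      -apply(d[others, ez, drop = FALSE], 1, min)
    }
    pz <- if (pz_size > 0)
      sort(others[order(score, decreasing = TRUE)[seq_len(pz_size)]])
    else integer(0)
    ezpzSpec(ez = ez, pz_clin = pz, pz_seeg = pz)
  })
}

#' EZ/PZ specification
#'
#' Region-index sets for the epileptogenic zone (EZ, the stimulated
#' regions), the clinician-hypothesized propagation zone (`pz_clin`) and
#' the SEEG-derived propagation zone (`pz_seeg`). The EZ must be disjoint
#' from `pz_seeg` (a region detected by the energy rule counts as PZ only
#' if it is not in the EZ).
#'
#' @param ez,pz_clin,pz_seeg 1-based integer index sets.
#' @param n_regions optional region count for range validation.
#' @return an object of class `ezpzSpec`.
#' @export
ezpzSpec <- function(ez, pz_clin = integer(0), pz_seeg = integer(0),
                     n_regions = NULL) {
  ez <- sort(unique(as.integer(ez)))
  pz_clin <- sort(unique(as.integer(pz_clin)))
  pz_seeg <- sort(unique(as.integer(pz_seeg)))
  if (length(ez) < 1 || any(ez < 1)) stop("ez must be a nonempty index set")
  if (length(intersect(ez, pz_seeg)) > 0)
    stop("ez and pz_seeg must be disjoint")
  if (!is.null(n_regions) && any(c(ez, pz_clin, pz_seeg) > n_regions))
    stop("region index out of range")
  structure(list(ez = ez, pz_clin = pz_clin, pz_seeg = pz_seeg),
            class = "ezpzSpec")
}

#' @export
print.ezpzSpec <- function(x, ...) {
  cat("EZ/PZ specification:\n")
  cat("  EZ:     ", paste(x$ez, collapse = ", "), "\n")
  cat("  PZ_clin:", paste(x$pz_clin, collapse = ", "), "\n")
  cat("  PZ_seeg:", paste(x$pz_seeg, collapse = ", "), "\n")
  invisible(x)
}

#' Read or write an EZ/PZ specification as JSON
#'
#' The JSON object has fields `ez`, `pz_clin`, `pz_seeg` holding 1-based
#' region indices.
#'
#' @param path file path.
#' @return an `ezpzSpec` (for the reader); `path` invisibly (writer).
#' @export
readEzPz <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ezpzSpec(x$ez, x$pz_clin %||% integer(0), x$pz_seeg %||% integer(0))
}

#' @rdname readEzPz
#' @param spec an `ezpzSpec`.
#' @export
writeEzPz <- function(spec, path) {
  stopifnot(inherits(spec, "ezpzSpec"))
  jsonlite::write_json(list(ez = spec$ez, pz_clin = spec$pz_clin,
                            pz_seeg = spec$pz_seeg), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
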