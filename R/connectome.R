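#' Construct a structural connectome object
#'
#' A connectome is a square nonnegative matrix of structural connection
#' weights between brain regions (typically 88 regions for the
#' Desikan-Killiany parcellation or 90 for AAL), with optional region
#' labels. Normalized connectomes have zero diagonal and weights rescaled
#' to `[0, 1]` by the maximal off-diagonal entry.
#'
#' @param weights square numeric matrix, nonnegative and finite.
#' @param labels optional character vector of region names.
#' @param normalized logical flag; validated against the matrix when
#'   `TRUE`.
#' @return an object of class `connectome`.
#' @export
connectomeMatrix <- function(weights, labels = NULL, normalized = FALSE) {
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights))
    stop("connectome matrix must be square")
  bad <- which(!is.finite(weights) | weights < 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("invalid weight at row %d, col %d (negative or non-finite)",
                 bad[1, 1], bad[1, 2]))
  if (!is.null(labels) && length(labels) != nrow(weights))
    stop("labels length must match the number of regions")
  if (normalized) {
    if (any(diag(weights) != 0))
      stop("a normalized connectome must have zero diagonal")
    if (max(weights) > 1 || (any(weights > 0) && max(weights) != 1))
      stop("a normalized nonzero connectome must have max entry 1")
  }
  structure(list(weights = unname(weights), n_regions = nrow(weights),
                 labels = labels, normalized = normalized),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  nz <- sum(x$weights > 0)
  cat("Connectome:", x$n_regions, "regions,", nz, "nonzero weights",
      if (x$normalized) "(normalized)" else "(raw)", "\n")
  cat("  density =",
      signif(nz / (x$n_regions * (x$n_regions - 1)), 3),
      ", symmetric =", isSymmetric(x$weights), "\n")
  invisible(x)
}

#' Read a connectome from a file
#'
#' Supported formats: whitespace-separated square matrix (`"matrix"`),
#' comma-separated (`"csv"`), or GraphML (`"graphml"`, via igraph, edge
#' attribute `weight`). With `format = "auto"` the format is inferred
#' from the file extension. Region labels can be supplied as a sidecar
#' text file with one name per line.
#'
#' @param path file path.
#' @param format one of `"auto"`, `"matrix"`, `"csv"`, `"graphml"`.
#' @param labels_path optional path to a label sidecar file.
#' @return a raw (unnormalized) `connectome`.
#' @export
loadConnectome <- function(path, format = c("auto", "matrix", "csv",
                                            "graphml"),
                           labels_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", graphml = "graphml", "matrix")
  }
  w <- switch(format,
    matrix = as.matrix(utils::read.table(path, header = FALSE)),
    csv = as.matrix(utils::read.csv(path, header = FALSE)),
    graphml = {
      g <- igraph::read_graph(path, format = "graphml")
      igraph::as_adjacency_matrix(g, attr = "weight", sparse = FALSE)
    })
  storage.mode(w) <- "double"
  if (nrow(w) != ncol(w))
    stop("file does not contain a square matrix: ", nrow(w), " x ", ncol(w))
  labels <- if (!is.null(labels_path)) readLines(labels_path) else {
    if (!is.null(rownames(w)) && format == "graphml") rownames(w) else NULL
  }
  connectomeMatrix(w, labels = labels, normalized = FALSE)
}

#' Write a connectome to a file
#'
#' @param conn a `connectome`.
#' @param path output file path.
#' @param format `"matrix"` (whitespace) or `"csv"`.
#' @return `path`, invisibly.
#' @export
saveConnectome <- function(conn, path, format = c("matrix", "csv")) {
  format <- match.arg(format)
  if (format == "matrix") {
    utils::write.table(conn$weights, path, row.names = FALSE,
                       col.names = FALSE)
  } else {
    utils::write.table(conn$weights, path, row.names = FALSE,
                       col.names = FALSE, sep = ",")
  }
  invisible(path)
}

#' Normalize a connectome to [0, 1]
#'
#' Zeroes the diagonal (intra-region weights are modelled separately as
#' recurrent coupling) and divides by the maximal remaining entry, so the
#' result lies in `[0, 1]` with maximum exactly 1. Idempotent and
#' invariant under global rescaling of the raw weights.
#'
#' @param conn a `connectome` with at least one positive off-diagonal
#'   entry.
#' @return a normalized `connectome`.
#' @examples
#' normalizeConnectome(connectomeMatrix(matrix(c(0, 2, 4, 0), 2)))
#' @export
normalizeConnectome <- function(conn) {
  stopifnot(inherits(conn, "connectome"))
  w <- conn$weights
  diag(w) <- 0
  m <- max(w)
  if (m == 0) stop("cannot normalize an all-zero connectome")
  connectomeMatrix(w / m, labels = conn$labels, normalized = TRUE)
}

#' Build the synaptic coupling matrix
#'
#' Converts a normalized connectome topology \eqn{\tilde J_{kl}} into
#' synaptic weights
#' \deqn{J_{kl} = \sigma \cdot \mathrm{inter} \cdot \tilde J_{kl}
#'   \ (k \ne l), \qquad J_{kk} = \sigma \cdot \mathrm{intra},}
#' i.e., strong recurrent intra-population coupling (default 20) and
#' intermediate inter-population coupling in `[0, sigma * 5]`. The global
#' factor `sigma` rescales all synapses at once (1 for the healthy-cohort
#' setting, 1.25 for the patient setting).
#'
#' @param conn a normalized `connectome`.
#' @param sigma global rescaling factor, >= 0.
#' @param intra diagonal (recurrent) weight before rescaling.
#' @param inter_scale off-diagonal multiplier before rescaling.
#' @return an object of class `coupling` with the matrix in `$J`.
#' @export
buildCoupling <- function(conn, sigma = 1, intra = 20, inter_scale = 5) {
  stopifnot(inherits(conn, "connectome"))
  if (!conn$normalized)
    stop("connectome must be normalized first (see normalizeConnectome)")
  stopifnot(is.finite(sigma), sigma >= 0)
  J <- sigma * inter_scale * conn$weights
  diag(J) <- sigma * intra
  structure(list(J = J, sigma = sigma, intra = intra,
                 inter_scale = inter_scale, n_regions = conn$n_regions),
            class = "coupling")
}

#' @export
print.coupling <- function(x, ...) {
  cat("Coupling matrix:", x$n_regions, "populations, sigma =", x$sigma,
      "\n  J_kk =", x$sigma * x$intra, ", off-diagonal in [0,",
      x$sigma * x$inter_scale, "]\n")
  invisible(x)
}

# accept a coupling object or a plain square matrix
coupling_matrix <- function(coupling) {
  if (inherits(coupling, "coupling")) coupling$J
  else if (is.matrix(coupling)) coupling
  else stop("coupling must be a coupling object or a square matrix")
}

#' Cohort presets
#'
#' Bundled parameter presets mirroring the two cohorts studied with this
#' model: `"healthy"` (AAL90 parcellation, 90 regions, sigma = 1) and
#' `"patient"` (Desikan-Killiany, 88 regions, sigma = 1.25, baseline
#' excitability -7.5).
#'
#' @param name `"healthy"` or `"patient"`.
#' @return list with `n_regions`, `sigma`, `eta_bar`, `delta`, `tau_m`,
#'   `intra`, `inter_scale`, `I_S`, `t_I`.
#' @export
networkPreset <- function(name = c("healthy", "patient")) {
  name <- match.arg(name)
  base <- list(delta = 1, tau_m = 20, intra = 20, inter_scale = 5,
               I_S = 10, t_I = 400)
  if (name == "healthy")
    c(list(n_regions = 90L, sigma = 1, eta_bar = -9.54), base)
  else
    c(list(n_regions = 88L, sigma = 1.25, eta_bar = -7.5), base)
}
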