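#' Propagation zone from signal energy
#'
#' Simulated analogue of the SEEG energy rule for identifying the
#' propagation zone: each region's voltage signal is band-pass filtered
#' (Butterworth order 4, zero-phase, 1-50 Hz by default) and its energy
#' (sum of squared samples over the analysis window) computed; a region
#' belongs to the PZ when its energy reaches at least `energy_fraction`
#' (default 30%) of the maximum energy over all regions and it is not in
#' the EZ.
#'
#' @param signals matrix of voltage signals, one column per region,
#'   uniformly sampled at `fs` Hz.
#' @param fs sampling frequency, Hz.
#' @param ez EZ region indices (always excluded from the PZ).
#' @param energy_fraction inclusion threshold as a fraction of the
#'   maximal energy.
#' @param band band-pass edges in Hz (upper edge must be below the
#'   Nyquist frequency).
#' @param order Butterworth filter order.
#' @param window optional integer range of samples to analyse (default:
#'   all).
#' @return integer vector of PZ region indices.
#' @export
pzFromEnergy <- function(signals, fs, ez, energy_fraction = 0.3,
                         band = c(1, 50), order = 4, window = NULL) {
  if (is.vector(signals)) signals <- matrix(signals, ncol = 1)
  if (nrow(signals) == 0 || ncol(signals) == 0)
    stop("empty signals")
  if (band[2] >= fs / 2)
    stop("band upper edge must be below the Nyquist frequency ", fs / 2)
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  if (is.null(window)) window <- seq_len(nrow(signals))
  energy <- apply(signals, 2, function(x) {
    xf <- signal::filtfilt(bf, x - mean(x))
    sum(xf[window]^2)
  })
  thr <- energy_fraction * max(energy)
  pz <- which(energy >= thr)
  sort(setdiff(pz, ez))
}

#' One-sided Mann-Whitney test for early PZ recruitment
#'
#' Tests whether the recruitment times of the propagation-zone regions
#' are stochastically smaller than those of the remaining recruited
#' regions (one-sided). The exact null distribution is used for group
#' sizes up to 8 without ties; otherwise the normal approximation with
#' tie correction. Unrecruited regions (`NA` times) are excluded by
#' default, or assigned the maximum rank with `unrecruited =
#' "max_rank"`.
#'
#' @param times per-region recruitment times (ms; `NA` = not recruited).
#' @param pz PZ region indices.
#' @param exclude regions dropped from both groups (typically the EZ).
#' @param unrecruited `"exclude"` or `"max_rank"`.
#' @return list with the Mann-Whitney `U` statistic (for the PZ group),
#'   one-sided `p`, group sizes `n_pz`, `n_other` and the `method`
#'   used.
#' @export
mannWhitneyPz <- function(times, pz, exclude = integer(0),
                          unrecruited = c("exclude", "max_rank")) {
  unrecruited <- match.arg(unrecruited)
  idx <- setdiff(seq_along(times), exclude)
  t_use <- times[idx]
  if (unrecruited == "max_rank") {
    worst <- if (all(is.na(t_use))) 1 else max(t_use, na.rm = TRUE) + 1
    t_use[is.na(t_use)] <- worst
  }
  is_pz <- idx %in% pz
  x <- t_use[is_pz & !is.na(t_use)]
  y <- t_use[!is_pz & !is.na(t_use)]
  if (length(x) == 0 || length(y) == 0)
    stop("both groups need at least one recruitment time")
  if (length(unique(c(x, y))) == 1) {
    # every observation tied: the test carries no information
    return(list(U = length(x) * length(y) / 2, p = 0.5,
                n_pz = length(x), n_other = length(y),
                method = "degenerate_all_tied"))
  }
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- max(length(x), length(y)) <= 8 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "less", exact = exact,
                       correct = !exact))
  p <- wt$p.value
  if (!is.finite(p)) p <- 0.5
  list(U = unname(wt$statistic), p = p, n_pz = length(x),
       n_other = length(y),
       method = if (exact) "exact" else "normal_tie_corrected")
}

#' Recruitment report for an EZ/PZ hypothesis
#'
#' Summarizes a recruitment experiment against an EZ/PZ specification:
#' the ordered recruitment list, how many PZ regions appear among the
#' first 10 recruited, quartile statistics of the recruitment times
#' (linear-interpolation quartiles, whiskers at the most extreme values
#' within 1.5 IQR of the quartiles) and one-sided Mann-Whitney tests for
#' early recruitment of `pz_clin` and `pz_seeg` (EZ regions excluded
#' from the comparison).
#'
#' @param result a `recruitmentResult`.
#' @param spec an `ezpzSpec`.
#' @return object of class `recruitmentReport`.
#' @export
recruitmentReport <- function(result, spec) {
  stopifnot(inherits(result, "recruitmentResult"),
            inherits(spec, "ezpzSpec"))
  times <- result$recruit_time
  ord <- result$order
  first10 <- utils::head(ord, 10)
  hit_stats <- function(pz) {
    if (length(pz) == 0)
      return(list(hits = 0L, fraction = NA_real_))
    hits <- length(intersect(first10, pz))
    list(hits = hits, fraction = hits / length(pz))
  }
  rec_times <- times[!is.na(times)]
  stats_block <- if (length(rec_times) > 0) {
    q <- stats::quantile(rec_times, c(0.25, 0.5, 0.75), type = 7,
                         names = FALSE)
    iqr <- q[3] - q[1]
    lo <- rec_times[rec_times >= q[1] - 1.5 * iqr]
    hi <- rec_times[rec_times <= q[3] + 1.5 * iqr]
    list(median = q[2], q1 = q[1], q3 = q[3], iqr = iqr,
         whisker_low = min(lo), whisker_high = max(hi))
  } else {
    list(median = NA_real_, q1 = NA_real_, q3 = NA_real_,
         iqr = NA_real_, whisker_low = NA_real_, whisker_high = NA_real_)
  }
  mw <- function(pz) {
    if (length(pz) == 0 || result$n_recruited == 0) return(NULL)
    tryCatch(mannWhitneyPz(times, pz, exclude = spec$ez),
             error = function(e) NULL)
  }
  structure(list(recruit_time = times, order = ord, first10 = first10,
                 classification = result$classification,
                 pz_clin = c(hit_stats(spec$pz_clin),
                             test = list(mw(spec$pz_clin))),
                 pz_seeg = c(hit_stats(spec$pz_seeg),
                             test = list(mw(spec$pz_seeg))),
                 time_stats = stats_block, spec = spec,
                 quartile_type = 7),
            class = "recruitmentReport")
}

#' @export
print.recruitmentReport <- function(x, ...) {
  cat("Recruitment report (", x$classification, ")\n", sep = "")
  st <- x$time_stats
  cat("  times: median", signif(st$median, 4), "ms, IQR [",
      signif(st$q1, 4), ",", signif(st$q3, 4), "]\n")
  f <- function(b, nm) {
    if (!is.na(b$fraction))
      cat("  ", nm, ": ", b$hits, " of the PZ in the first 10 (fraction ",
          signif(b$fraction, 3), ")",
          if (!is.null(b$test)) paste0(", one-sided p = ",
                                       signif(b$test$p, 3)),
          "\n", sep = "")
  }
  f(x$pz_clin, "PZ_clin")
  f(x$pz_seeg, "PZ_seeg")
  invisible(x)
}

#' Cohort summary across connectomes
#'
#' Aggregates recruitment reports over a cohort of connectomes: for each
#' subject, the median weighted shortest path length from all regions to
#' the EZ, summary statistics of the recruitment times, and the PZ hit
#' fractions; rows are sorted by the median shortest path to the EZ.
#' Also returns a long per-region table relating each recruitment time
#' to the region's shortest path and (log) direct weight to the EZ.
#'
#' @param reports list of `recruitmentReport` objects.
#' @param conns list of the matching `connectome` objects.
#' @param specs list of the matching `ezpzSpec` objects.
#' @param ids optional subject identifiers.
#' @return list with `summary` (one row per subject, sorted) and
#'   `per_region` (long table).
#' @export
cohortSummary <- function(reports, conns, specs, ids = NULL) {
  stopifnot(length(reports) == length(conns),
            length(conns) == length(specs))
  if (is.null(ids)) ids <- paste0("S", seq_along(reports))
  rows <- list()
  long <- list()
  for (i in seq_along(reports)) {
    rep_i <- reports[[i]]
    conn <- conns[[i]]
    ez <- specs[[i]]$ez
    d <- weightedShortestPaths(conn)$distances
    path_to_ez <- apply(d[, ez, drop = FALSE], 1, min)
    path_to_ez[ez] <- NA
    times <- rep_i$recruit_time
    rows[[i]] <- data.frame(
      id = ids[i],
      median_path_to_ez = stats::median(path_to_ez, na.rm = TRUE),
      median_time = rep_i$time_stats$median,
      q1_time = rep_i$time_stats$q1, q3_time = rep_i$time_stats$q3,
      n_recruited = sum(!is.na(times)),
      pz_clin_fraction = rep_i$pz_clin$fraction,
      pz_seeg_fraction = rep_i$pz_seeg$fraction)
    w_to_ez <- rowSums(conn$weights[, ez, drop = FALSE])
    keep <- setdiff(which(!is.na(times)), ez)
    if (length(keep) > 0)
      long[[length(long) + 1]] <- data.frame(
        id = ids[i], area = keep, time = times[keep],
        path_to_ez = path_to_ez[keep],
        log_weight_to_ez = log10(pmax(w_to_ez[keep], .Machine$double.xmin)))
  }
  summary <- do.call(rbind, rows)
  summary <- summary[order(summary$median_path_to_ez), ]
  rownames(summary) <- NULL
  list(summary = summary,
       per_region = if (length(long)) do.call(rbind, long) else NULL)
}
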