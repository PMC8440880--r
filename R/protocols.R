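#' Adiabatic up/down sweep of the excitability
#'
#' Bifurcation-diagram protocol: the network is initialized at
#' `eta_range[1]` with all rates and voltages at zero and the common
#' excitability is increased in steps of `eta_step` (default 1.5) up to
#' `eta_range[2]`; at each step the system relaxes for `settle_time`
#' (default 2000 ms) carrying the final state forward, and the
#' network-average equilibrium rate is recorded. The down sweep continues
#' from the top state stepping back down. The transition between the
#' low-activity and high-activity network states is hysteretic: the
#' up-sweep jump occurs at a larger excitability than the down-sweep
#' collapse.
#'
#' @param coupling a [buildCoupling()] object or matrix.
#' @param params a [neuralMassParams()] (its `eta_bar` is overridden by
#'   the sweep grid, applied homogeneously).
#' @param eta_range sweep limits, ms.
#' @param eta_step grid step, > 0.
#' @param settle_time relaxation time per step, ms.
#' @param direction `"both"`, `"up"` or `"down"`.
#' @param dt integration step, ms.
#' @return object of class `sweepResult`: for each direction a list with
#'   `eta`, `mean_rate` (network average, 1/ms) and `rates` (step x
#'   population matrix).
#' @export
adiabaticSweep <- function(coupling, params, eta_range = c(-50, 10),
                           eta_step = 1.5, settle_time = 2000,
                           direction = c("both", "up", "down"),
                           dt = 0.01) {
  direction <- match.arg(direction)
  stopifnot(eta_step > 0, settle_time > 0)
  J <- coupling_matrix(coupling)
  n <- params$n_pop
  eta_up <- seq(eta_range[1], eta_range[2], by = eta_step)

  run_branch <- function(etas, state) {
    rates <- matrix(NA_real_, length(etas), n)
    for (i in seq_along(etas)) {
      p <- set_eta(params, etas[i])
      traj <- tryCatch(
        integrateNetwork(p, J, state0 = state, t_span = settle_time,
                         dt = dt, record_dt = settle_time),
        error = function(e)
          stop("integration failed at eta_bar = ", etas[i], ": ",
               conditionMessage(e)))
      state <- finalState(traj)
      rates[i, ] <- state$r
    }
    list(eta = etas, mean_rate = rowMeans(rates), rates = rates,
         final = state)
  }

  out <- list()
  state0 <- list(r = rep(0, n), v = rep(0, n))
  if (direction %in% c("both", "up")) {
    up <- run_branch(eta_up, state0)
    out$up <- up[c("eta", "mean_rate", "rates")]
  }
  if (direction %in% c("both", "down")) {
    start <- if (direction == "both") up$final else {
      # reach the high-activity top state first
      run_branch(eta_range[2], state0)$final
    }
    down <- run_branch(rev(eta_up), start)
    out$down <- down[c("eta", "mean_rate", "rates")]
  }
  structure(c(out, list(direction = direction, eta_step = eta_step,
                        settle_time = settle_time)),
            class = "sweepResult")
}

#' @export
print.sweepResult <- function(x, ...) {
  cat("Adiabatic sweep (", x$direction, "), eta step ", x$eta_step,
      ", settle ", x$settle_time, " ms\n", sep = "")
  if (!is.null(x$up))
    cat("  up:  ", length(x$up$eta), "steps, final <r*> =",
        signif(x$up$mean_rate[length(x$up$eta)], 4), "\n")
  if (!is.null(x$down))
    cat("  down:", length(x$down$eta), "steps, final <r*> =",
        signif(x$down$mean_rate[length(x$down$eta)], 4), "\n")
  invisible(x)
}

#' Hysteresis boundaries of a sweep
#'
#' Estimates the up-sweep jump (largest grid excitability still in the
#' network LA state) and the down-sweep collapse (smallest grid
#' excitability still in HA) from the largest rate increments along each
#' branch.
#'
#' @param sweep a `sweepResult` with both directions.
#' @return list with `eta_HA` (up-sweep jump location) and `eta_LA`
#'   (down-sweep collapse location); hysteresis means `eta_LA < eta_HA`.
#' @export
hysteresisBounds <- function(sweep) {
  stopifnot(!is.null(sweep$up), !is.null(sweep$down))
  up <- sweep$up
  jump_up <- which.max(diff(up$mean_rate))
  down <- sweep$down
  jump_dn <- which.max(-diff(down$mean_rate))
  list(eta_HA = up$eta[jump_up + 1], eta_LA = down$eta[jump_dn])
}

#' Map of regimes over coupling strength
#'
#' Repeats the up/down sweep for a grid of global coupling factors sigma
#' and collects the network-average equilibrium rates in two (sigma x
#' eta) grids. The up grid is dominated by the low-activity state inside
#' the hysteretic band, the down grid by the high-activity state.
#'
#' @param conn a normalized `connectome`.
#' @param params a [neuralMassParams()].
#' @param sigma_range,sigma_step sigma grid (defaults `[0, 2]`, 0.05).
#' @param ... passed to [adiabaticSweep()] (`eta_range`, `eta_step`,
#'   `settle_time`, `dt`).
#' @param intra,inter_scale coupling construction constants.
#' @return list with `sigma`, `eta`, and matrices `up`, `down` of
#'   average rates (sigma x eta).
#' @export
mapOfRegimes <- function(conn, params, sigma_range = c(0, 2),
                         sigma_step = 0.05, intra = 20, inter_scale = 5,
                         ...) {
  stopifnot(inherits(conn, "connectome"))
  sigmas <- seq(sigma_range[1], sigma_range[2], by = sigma_step)
  up <- down <- NULL
  for (i in seq_along(sigmas)) {
    cpl <- buildCoupling(conn, sigma = sigmas[i], intra = intra,
                         inter_scale = inter_scale)
    sw <- adiabaticSweep(cpl, params, direction = "both", ...)
    if (is.null(up)) {
      up <- matrix(NA_real_, length(sigmas), length(sw$up$eta))
      down <- up
    }
    up[i, ] <- sw$up$mean_rate
    down[i, ] <- rev(sw$down$mean_rate)
  }
  list(sigma = sigmas, eta = sw$up$eta, up = up, down = down)
}

#' Recruitment rate criterion
#'
#' The threshold rate separating the low- and high-activity states of a
#' population. By default it is the rate of the middle (saddle)
#' equilibrium of the single population with recurrent coupling
#' `sigma * intra` at the run's excitability -- the separatrix between
#' the two basins. Where no saddle exists at that excitability, the
#' geometric mean of the LA and HA rates at the nearest bistable
#' excitability (searched on a 0.1 grid) is used instead.
#'
#' @param eta_bar excitability of the run (scalar; heterogeneous runs use
#'   the mean).
#' @param params a [neuralMassParams()].
#' @param J_self recurrent self-coupling (`sigma * intra`).
#' @param search_width how far to search for a bistable excitability.
#' @return threshold rate `r_c` in 1/ms.
#' @export
recruitmentThreshold <- function(eta_bar, params, J_self,
                                 search_width = 20) {
  saddle_rate <- function(eta) {
    fp <- singleFixedPoints(eta, params$delta, params$tau_m, J_self)
    if (nrow(fp) == 3 && any(fp$stability == "saddle"))
      fp$r[fp$stability == "saddle"][1]
    else NA_real_
  }
  rc <- saddle_rate(eta_bar)
  if (is.finite(rc)) return(rc)
  for (off in seq(0.1, search_width, by = 0.1)) {
    for (eta in c(eta_bar - off, eta_bar + off)) {
      fp <- singleFixedPoints(eta, params$delta, params$tau_m, J_self)
      if (nrow(fp) == 3) {
        stable <- sort(fp$r[fp$stability != "saddle"])
        return(sqrt(stable[1] * stable[length(stable)]))
      }
    }
  }
  stop("no bistable excitability found near eta_bar = ", eta_bar,
       "; recruitment criterion undefined")
}

#' Prepare the network low-activity state
#'
#' Relaxes the network from `(r, v) = (0, 0)` for `settle_time` and
#' verifies that every population settled below the LA/HA separatrix
#' rate. Fails when the excitability is so large that the network
#' low-activity state no longer exists (saturated-HA regime).
#'
#' @param coupling a [buildCoupling()] object or matrix.
#' @param params a [neuralMassParams()].
#' @param settle_time relaxation time, ms.
#' @param dt integration step, ms.
#' @param r_c LA/HA criterion rate; computed via
#'   [recruitmentThreshold()] when `NULL`.
#' @return list with vectors `r`, `v`.
#' @export
prepareLaState <- function(coupling, params, settle_time = 2000,
                           dt = 0.01, r_c = NULL) {
  J <- coupling_matrix(coupling)
  if (is.null(r_c))
    r_c <- recruitmentThreshold(mean(params$eta_bar), params,
                                J_self = mean(diag(J)))
  traj <- integrateNetwork(params, J, t_span = settle_time, dt = dt,
                           record_dt = settle_time)
  st <- finalState(traj)
  if (any(st$r >= r_c))
    stop("state preparation failed: ", sum(st$r >= r_c),
         " population(s) settled in the high-activity state ",
         "(eta_bar too large)")
  st
}

#' Run a stimulation experiment
#'
#' Starting from the network low-activity state, applies the rectangular
#' stimulation pulse and integrates through a pre-onset baseline, the
#' pulse, and a post-offset observation window. Time 0 is the start of
#' the trajectory; the pulse onset is at `stim$onset` (shifted to
#' `baseline` if smaller).
#'
#' @param coupling a [buildCoupling()] object or matrix.
#' @param params a [neuralMassParams()].
#' @param stim a [stimulusProtocol()].
#' @param post_window observation time after pulse offset, ms.
#' @param baseline pre-onset time, ms.
#' @param state0 initial state; computed via [prepareLaState()] when
#'   `NULL`.
#' @param dt integration step, ms.
#' @param record_dt recording interval, ms.
#' @param settle_time relaxation time for the LA preparation, ms.
#' @param r_c optional LA/HA criterion rate forwarded to the
#'   preparation.
#' @return a `massTrajectory` spanning baseline, pulse and post window.
#' @export
runStimulation <- function(coupling, params, stim, post_window = 2000,
                           baseline = 200, state0 = NULL, dt = 0.01,
                           record_dt = 0.5, settle_time = 2000,
                           r_c = NULL) {
  stopifnot(inherits(stim, "stimulusProtocol"))
  if (stim$onset < baseline)
    stim <- stimulusProtocol(stim$targets, stim$amplitude,
                             onset = baseline, duration = stim$duration)
  if (is.null(state0))
    state0 <- prepareLaState(coupling, params, settle_time = settle_time,
                             dt = dt, r_c = r_c)
  t_end <- stim$onset + stim$duration + post_window
  integrateNetwork(params, coupling, state0 = state0, t_span = t_end,
                   dt = dt, stimulus = stim, record_dt = record_dt)
}

#' Detect recruited populations in a trajectory
#'
#' A population counts as recruited when its rate at the trajectory end
#' exceeds the criterion `r_c`; its recruitment time is the first time
#' after stimulus onset at which the rate crosses `r_c` from below and
#' stays above through the trajectory end (sustained crossing, so
#' stimulus-driven transients in non-recruited populations do not
#' count). The stimulated populations themselves are the event origin,
#' not recruits in the coupling-driven sense; when they end in the
#' high-activity state their time is the first crossing after onset,
#' since their forced post-onset ringing can otherwise dip briefly
#' below `r_c` and misplace them in the order. Times are measured from
#' the stimulus onset. Classification: `"none"` (no recruitment),
#' `"asymptomatic"` (only the stimulated region), `"generalized"` (all
#' regions), else `"partial"`.
#'
#' @param traj a `massTrajectory` from [runStimulation()].
#' @param stim the applied [stimulusProtocol()] (defaults to the one
#'   stored in the trajectory).
#' @param r_c criterion rate (1/ms); computed from the trajectory's
#'   parameters when `NULL` (requires a `coupling`-diagonal argument).
#' @param J_self recurrent coupling used when deriving `r_c`.
#' @return object of class `recruitmentResult` with fields
#'   `recruit_time` (per region, ms after onset, `NA` when not
#'   recruited), `n_recruited`, `order` (region indices by ascending
#'   time), `classification` and `r_c`.
#' @export
detectRecruitments <- function(traj, stim = NULL, r_c = NULL,
                               J_self = NULL) {
  stopifnot(inherits(traj, "massTrajectory"))
  if (is.null(stim)) stim <- traj$stimulus
  if (is.null(stim)) stop("no stimulus associated with the trajectory")
  if (is.null(r_c)) {
    if (is.null(J_self))
      stop("supply r_c or J_self to derive the recruitment criterion")
    r_c <- recruitmentThreshold(mean(traj$params$eta_bar), traj$params,
                                J_self)
  }
  n <- ncol(traj$r)
  times <- traj$times
  above <- traj$r >= r_c
  end_above <- above[nrow(above), ]
  recruit_time <- rep(NA_real_, n)
  after_onset <- times >= stim$onset
  for (k in which(end_above)) {
    col <- above[, k]
    if (k %in% stim$targets) {
      # stimulated area: first crossing after onset
      idx <- which(col & after_onset)[1]
    } else {
      # last sample below criterion; recruitment at the next sample
      below <- which(!col)
      idx <- if (length(below) == 0) which(after_onset)[1]
             else min(below[length(below)] + 1L, length(times))
    }
    recruit_time[k] <- max(times[idx] - stim$onset, 0)
  }
  order_idx <- order(recruit_time, na.last = NA)
  n_rec <- sum(!is.na(recruit_time))
  classification <-
    if (n_rec == 0) "none"
    else if (n_rec == length(stim$targets) &&
             setequal(which(!is.na(recruit_time)), stim$targets))
      "asymptomatic"
    else if (n_rec == n) "generalized"
    else "partial"
  structure(list(recruit_time = recruit_time, n_recruited = n_rec,
                 order = order_idx, classification = classification,
                 r_c = r_c, stim = stim),
            class = "recruitmentResult")
}

#' @export
print.recruitmentResult <- function(x, ...) {
  cat("Recruitment:", x$n_recruited, "region(s) in HA (",
      x$classification, "), r_c =", signif(x$r_c, 4), "\n")
  if (x$n_recruited > 0) {
    k <- utils::head(x$order, 10)
    cat("  first recruited:", paste(sprintf("%d (%.0f ms)", k,
                                            x$recruit_time[k]),
                                    collapse = ", "), "\n")
  }
  invisible(x)
}

# shared machinery: one stimulation + recruitment count at a given
# excitability, reusing a prepared LA state and criterion
stim_and_count <- function(J, params, area, I_S, t_I, state0, r_c,
                           post_window, dt, record_dt) {
  stim <- stimulusProtocol(area, amplitude = I_S, onset = 0,
                           duration = t_I)
  traj <- runStimulation(J, params, stim, post_window = post_window,
                         baseline = 0, state0 = state0, dt = dt,
                         record_dt = record_dt)
  detectRecruitments(traj, stim, r_c = r_c)
}

#' Per-region excitability threshold scan
#'
#' For each target region, scans the common excitability over a grid and
#' records the number of recruited regions after a standard stimulation
#' (amplitude `I_S`, duration `t_I`). The asymptomatic threshold
#' `eta_asy(k)` is the smallest grid excitability at which at least one
#' region (the stimulated one) remains in the high-activity state; the
#' generalized threshold `eta_gen(k)` is the smallest at which all
#' regions are recruited. Grid points where the network low-activity
#' state cannot be prepared (saturated-HA regime) are flagged and
#' excluded from the threshold minimization. Thresholds are grid values,
#' not interpolated.
#'
#' @param coupling a [buildCoupling()] object.
#' @param params a [neuralMassParams()].
#' @param areas 1-based indices of regions to scan (default: all).
#' @param eta_range,eta_step scan grid (defaults `[-15, -4]`, 0.1).
#' @param I_S,t_I stimulation amplitude and duration (ms).
#' @param post_window evaluation window after pulse offset, ms.
#' @param settle_time LA preparation time, ms.
#' @param dt integration step, ms.
#' @param record_dt trajectory recording interval, ms.
#' @param progress print per-excitability progress.
#' @return object of class `thresholdMap`: `eta_asy`, `eta_gen` (per
#'   scanned area, `NA` when never attained), `n_recruited` (eta x area
#'   matrix), `saturated` (logical per eta), plus the grid.
#' @export
thresholdMap <- function(coupling, params, areas = NULL,
                         eta_range = c(-15, -4), eta_step = 0.1,
                         I_S = 10, t_I = 400, post_window = 2000,
                         settle_time = 2000, dt = 0.01, record_dt = 1,
                         progress = FALSE) {
  J <- coupling_matrix(coupling)
  n <- params$n_pop
  if (is.null(areas)) areas <- seq_len(n)
  etas <- seq(eta_range[1], eta_range[2], by = eta_step)
  counts <- matrix(NA_real_, length(etas), length(areas),
                   dimnames = list(NULL, paste0("area", areas)))
  saturated <- logical(length(etas))
  J_self <- mean(diag(J))
  for (i in seq_along(etas)) {
    p <- set_eta(params, etas[i])
    r_c <- tryCatch(recruitmentThreshold(etas[i], p, J_self),
                    error = function(e) NA_real_)
    if (!is.finite(r_c)) { saturated[i] <- TRUE; next }
    state0 <- tryCatch(
      prepareLaState(J, p, settle_time = settle_time, dt = dt, r_c = r_c),
      error = function(e) NULL)
    if (is.null(state0)) { saturated[i] <- TRUE; next }
    for (a in seq_along(areas)) {
      res <- stim_and_count(J, p, areas[a], I_S, t_I, state0, r_c,
                            post_window, dt, record_dt)
      counts[i, a] <- res$n_recruited
    }
    if (progress)
      message("eta_bar = ", etas[i], ": mean n_recruited = ",
              signif(mean(counts[i, ]), 3))
  }
  first_eta <- function(cond_col) {
    idx <- which(cond_col & !saturated)
    if (length(idx) == 0) NA_real_ else etas[min(idx)]
  }
  eta_asy <- apply(counts >= 1, 2, first_eta)
  eta_gen <- apply(counts == n, 2, first_eta)
  structure(list(eta = etas, areas = areas, n_recruited = counts,
                 saturated = saturated, eta_asy = unname(eta_asy),
                 eta_gen = unname(eta_gen)),
            class = "thresholdMap")
}

#' @export
print.thresholdMap <- function(x, ...) {
  cat("Threshold map:", length(x$areas), "area(s),",
      length(x$eta), "excitability values\n")
  cat("  mean eta_asy =", signif(mean(x$eta_asy, na.rm = TRUE), 4),
      ", mean eta_gen =", signif(mean(x$eta_gen, na.rm = TRUE), 4), "\n")
  invisible(x)
}

#' @rdname thresholdMap
#' @param area single region index (convenience wrapper returning the
#'   same structure for one area).
#' @export
thresholdScan <- function(coupling, params, area, ...) {
  thresholdMap(coupling, params, areas = area, ...)
}

#' Threshold scan with heterogeneous excitabilities
#'
#' Repeats the recruitment-count scan with per-region excitabilities
#' drawn from a Gaussian centred on each grid value (standard deviation
#' `sd`, default 0.1), averaging the recruitment counts over `reps`
#' seeded draws. With `sd = 0` this reproduces the homogeneous scan
#' exactly. Grid points where the low-activity state cannot be prepared
#' in any repetition are reported as saturated.
#'
#' @inheritParams thresholdMap
#' @param sd Gaussian standard deviation of the excitabilities.
#' @param reps number of repetitions.
#' @param seed integer seed.
#' @return list with `eta` (grid of Gaussian means), `areas`,
#'   `n_recruited` (mean over repetitions, eta x area), `saturated`
#'   (fraction of saturated repetitions per eta).
#' @export
heterogeneousScan <- function(coupling, params, areas = NULL,
                              eta_range = c(-15, -4), eta_step = 0.1,
                              sd = 0.1, reps = 10, seed = NULL,
                              I_S = 10, t_I = 400, post_window = 2000,
                              settle_time = 2000, dt = 0.01,
                              record_dt = 1) {
  stopifnot(sd >= 0, reps >= 1)
  J <- coupling_matrix(coupling)
  n <- params$n_pop
  if (is.null(areas)) areas <- seq_len(n)
  etas <- seq(eta_range[1], eta_range[2], by = eta_step)
  J_self <- mean(diag(J))
  counts <- array(NA_real_, c(length(etas), length(areas), reps))
  sat <- matrix(FALSE, length(etas), reps)
  draws <- with_seed(seed, {
    lapply(seq_len(reps), function(i)
      matrix(stats::rnorm(length(etas) * n, sd = sd), length(etas), n))
  })
  for (rep_i in seq_len(reps)) {
    for (i in seq_along(etas)) {
      eta_k <- etas[i] + if (sd > 0) draws[[rep_i]][i, ] else 0
      p <- set_eta(params, eta_k)
      r_c <- tryCatch(recruitmentThreshold(etas[i], p, J_self),
                      error = function(e) NA_real_)
      if (!is.finite(r_c)) { sat[i, rep_i] <- TRUE; next }
      state0 <- tryCatch(
        prepareLaState(J, p, settle_time = settle_time, dt = dt,
                       r_c = r_c),
        error = function(e) NULL)
      if (is.null(state0)) { sat[i, rep_i] <- TRUE; next }
      for (a in seq_along(areas)) {
        res <- stim_and_count(J, p, areas[a], I_S, t_I, state0, r_c,
                              post_window, dt, record_dt)
        counts[i, a, rep_i] <- res$n_recruited
      }
    }
  }
  list(eta = etas, areas = areas,
       n_recruited = apply(counts, c(1, 2), mean, na.rm = TRUE),
       saturated = rowMeans(sat))
}

#' Recruitment times versus stimulation amplitude
#'
#' Stimulates one region with pulses of varying amplitude (duration
#' fixed) and records the recruitment times of the first `n_first`
#' recruited regions for each amplitude. Recruitment times decrease with
#' amplitude while the recruitment order stays largely unchanged.
#'
#' @inheritParams thresholdMap
#' @param area the stimulated region.
#' @param I_S_values amplitude grid.
#' @param n_first number of order positions to report.
#' @return data frame with columns `amplitude`, `position`, `area`,
#'   `time` (ms after onset; `NA` rows record missing recruitments).
#' @export
amplitudeSweep <- function(coupling, params, area, I_S_values,
                           t_I = 400, n_first = 10, post_window = 2000,
                           settle_time = 2000, dt = 0.01,
                           record_dt = 0.5) {
  J <- coupling_matrix(coupling)
  J_self <- mean(diag(J))
  r_c <- recruitmentThreshold(mean(params$eta_bar), params, J_self)
  state0 <- prepareLaState(J, params, settle_time = settle_time, dt = dt,
                           r_c = r_c)
  rows <- list()
  for (I_S in I_S_values) {
    res <- stim_and_count(J, params, area, I_S, t_I, state0, r_c,
                          post_window, dt, record_dt)
    ord <- res$order
    for (p in seq_len(n_first)) {
      rows[[length(rows) + 1]] <- data.frame(
        amplitude = I_S, position = p,
        area = if (p <= length(ord)) ord[p] else NA_integer_,
        time = if (p <= length(ord)) res$recruit_time[ord[p]]
               else NA_real_)
    }
  }
  do.call(rbind, rows)
}

#' Recruitment times versus stimulation duration
#'
#' Companion of [amplitudeSweep()] varying the pulse duration at fixed
#' amplitude (default 15). Once the pulse outlasts the full recruitment
#' cascade, further extension leaves times and order unchanged.
#'
#' @inheritParams amplitudeSweep
#' @param t_I_values duration grid, ms.
#' @param I_S pulse amplitude.
#' @return data frame with columns `duration`, `position`, `area`,
#'   `time`.
#' @export
durationSweep <- function(coupling, params, area, t_I_values, I_S = 15,
                          n_first = 10, post_window = 2000,
                          settle_time = 2000, dt = 0.01,
                          record_dt = 0.5) {
  J <- coupling_matrix(coupling)
  J_self <- mean(diag(J))
  r_c <- recruitmentThreshold(mean(params$eta_bar), params, J_self)
  state0 <- prepareLaState(J, params, settle_time = settle_time, dt = dt,
                           r_c = r_c)
  rows <- list()
  for (t_I in t_I_values) {
    res <- if (t_I > 0)
      stim_and_count(J, params, area, I_S, t_I, state0, r_c,
                     post_window, dt, record_dt)
    else NULL
    ord <- if (is.null(res)) integer(0) else res$order
    for (p in seq_len(n_first)) {
      rows[[length(rows) + 1]] <- data.frame(
        duration = t_I, position = p,
        area = if (p <= length(ord)) ord[p] else NA_integer_,
        time = if (p <= length(ord)) res$recruit_time[ord[p]]
               else NA_real_)
    }
  }
  do.call(rbind, rows)
}
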