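#' Integrate the multipopulation neural mass model
#'
#' Deterministic fixed-step fourth-order Runge-Kutta integration of the
#' coupled mean-field equations, with an optional rectangular stimulation
#' pulse applied to a set of target populations. The default step of
#' 0.01 ms resolves the fastest damped focus oscillations (several
#' hundred Hz) with dozens of steps per period; the step is configurable
#' and halving it should leave results unchanged to high accuracy.
#'
#' @param params a [neuralMassParams()].
#' @param coupling a [buildCoupling()] object or plain square matrix.
#' @param state0 list with vectors `r`, `v` (default: all zeros).
#' @param t_span total integration time in ms (scalar) or `c(t0, t1)`.
#' @param dt integration step, ms.
#' @param stimulus a [stimulusProtocol()] or `NULL`.
#' @param record_dt recording interval, ms (rounded to a multiple of
#'   `dt`).
#' @return an object of class `massTrajectory`: list with `times` (ms),
#'   matrices `r`, `v` (time x population, rates in 1/ms) and
#'   `stimulus_trace` (applied current on the targets at the recorded
#'   times).
#' @examples
#' p <- neuralMassParams(1, eta_bar = -50)
#' tr <- integrateNetwork(p, matrix(0, 1, 1), t_span = 200, dt = 0.05)
#' @export
integrateNetwork <- function(params, coupling, state0 = NULL, t_span,
                             dt = 0.01, stimulus = NULL, record_dt = 0.5) {
  J <- coupling_matrix(coupling)
  n <- params$n_pop
  if (nrow(J) != n || ncol(J) != n)
    stop("coupling matrix dimension does not match n_pop")
  if (length(t_span) == 1) t_span <- c(0, t_span)
  if (diff(t_span) <= 0) stop("t_span must be positive")
  if (is.null(state0)) state0 <- list(r = rep(0, n), v = rep(0, n))
  if (length(state0$r) != n || length(state0$v) != n)
    stop("state0 dimension mismatch")
  if (is.null(stimulus)) {
    targets <- integer(0); amp <- 0; on <- 0; off <- 0
  } else {
    stopifnot(inherits(stimulus, "stimulusProtocol"))
    if (any(stimulus$targets > n))
      stop("stimulus target exceeds number of populations")
    targets <- stimulus$targets - 1L
    amp <- stimulus$amplitude
    on <- stimulus$onset
    off <- stimulus$onset + stimulus$duration
  }
  record_every <- max(1L, as.integer(round(record_dt / dt)))
  raw <- .rk4_network(state0$r, state0$v, params$eta_bar, params$delta,
                      params$tau_m, params$I_B, J, targets, amp, on, off,
                      t_span[1], t_span[2], dt, record_every)
  structure(list(times = raw$times, r = raw$r, v = raw$v,
                 stimulus_trace = raw$stimulus, stimulus = stimulus,
                 params = params, dt = dt),
            class = "massTrajectory")
}

#' @export
print.massTrajectory <- function(x, ...) {
  cat("Neural mass trajectory:", ncol(x$r), "population(s),",
      length(x$times), "samples over [",
      x$times[1], ",", x$times[length(x$times)], "] ms\n")
  cat("  final <r> =", signif(mean(finalState(x)$r), 4), "1/ms\n")
  invisible(x)
}

#' Final state of a trajectory
#'
#' @param traj a `massTrajectory`.
#' @return list with vectors `r`, `v` at the last recorded time.
#' @export
finalState <- function(traj) {
  i <- nrow(traj$r)
  list(r = traj$r[i, ], v = traj$v[i, ])
}

#' Simulate a finite network of QIF neurons
#'
#' Fixed-step simulation of the fully coupled microscopic QIF network
#' that the neural mass model reduces exactly as \eqn{N \to \infty}.
#' Serves as the microscopic oracle for the mean-field equations: with
#' Lorentzian excitabilities, the time-averaged population rate and mean
#' voltage of a large network converge to the stable mean-field
#' equilibrium. Between the delta-pulse synaptic kicks (accumulated over
#' a step and delivered at its end) each neuron's drift is constant, so
#' the quadratic flow is advanced with its exact closed-form solution
#' (phase rotation); spikes are exact threshold crossings, avoiding the
#' stiff-overshoot bias a naive Euler step incurs at high voltages.
#'
#' The infinite spike threshold of the ideal QIF neuron is replaced by a
#' finite `V_peak` with reset at `-V_peak`; spikes are counted at
#' threshold crossing. The time the ideal neuron would spend beyond the
#' threshold (`2 tau_m / V_peak` per spike) is restored as a refractory
#' hold, represented at `+V_peak` then `-V_peak`, which removes the
#' period-shortening bias of the truncation. The population rate is the
#' spike count per bin divided by `N` times the bin width (then
#' optionally smoothed with a rectangular kernel); the mean voltage
#' averages all neurons including the held ones, or excludes the
#' `2 tau_m / V_peak` window around each spike with
#' `refractory_mask = TRUE`.
#'
#' @param qif a [qifParams()].
#' @param duration simulation time, ms.
#' @param stimulus a [stimulusProtocol()] applied to the whole population,
#'   or `NULL`.
#' @param V0 initial voltages (default: all at the excitable rest value
#'   `-1`).
#' @param record_bin rate/voltage binning interval, ms.
#' @param smooth_ms width of the rectangular smoothing kernel for the
#'   rate, ms (0 disables smoothing).
#' @param keep_spikes store the full spike raster (memory-heavy for large
#'   `N`).
#' @param refractory_mask exclude a `2 tau_m / V_peak` window around each
#'   spike from the mean-voltage estimate.
#' @return an object of class `qifTrajectory`: `times` (bin centres, ms),
#'   `rate` (smoothed, 1/ms), `rate_raw`, `v_mean`, and optionally a
#'   `spikes` data frame.
#' @examples
#' q <- qifParams(1, eta_samples = 1, dt = 0.01)
#' sim <- qifSimulate(q, duration = 300, keep_spikes = TRUE)
#' diff(sim$spikes$time) # inter-spike intervals near pi * tau / sqrt(eta)
#' @export
qifSimulate <- function(qif, duration, stimulus = NULL, V0 = NULL,
                        record_bin = 1, smooth_ms = 10,
                        keep_spikes = FALSE, refractory_mask = FALSE) {
  stopifnot(inherits(qif, "qifParams"), duration > 0)
  if (is.null(V0)) V0 <- rep(-1, qif$N)
  if (length(V0) != qif$N) stop("V0 must have length N")
  if (is.null(stimulus)) {
    amp <- 0; on <- 0; off <- 0
  } else {
    stopifnot(inherits(stimulus, "stimulusProtocol"))
    amp <- stimulus$amplitude
    on <- stimulus$onset
    off <- stimulus$onset + stimulus$duration
  }
  raw <- .qif_simulate(V0, qif$eta_samples, qif$tau_m, qif$J, qif$I_B,
                       amp, on, off, qif$V_peak, qif$dt, duration,
                       record_bin, keep_spikes, refractory_mask)
  rate <- raw$rate
  if (smooth_ms > 0) {
    w <- max(1L, as.integer(round(smooth_ms / record_bin)))
    kern <- rep(1 / w, w)
    rate <- as.numeric(stats::filter(raw$rate, kern, sides = 2))
  }
  out <- list(times = raw$times, rate = rate, rate_raw = raw$rate,
              v_mean = raw$v_mean, V_final = raw$V_final, params = qif)
  if (keep_spikes) out$spikes <- raw$spikes
  structure(out, class = "qifTrajectory")
}

#' @export
print.qifTrajectory <- function(x, ...) {
  cat("QIF network simulation: N =", x$params$N, ",",
      length(x$times), "bins\n")
  cat("  mean rate =", signif(mean(x$rate_raw), 4), "1/ms (",
      signif(1000 * mean(x$rate_raw), 4), "Hz )\n")
  invisible(x)
}
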