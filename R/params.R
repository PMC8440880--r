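#' Parameters of the neural mass model
#'
#' Bundles the parameters of the exact QIF mean-field model: the membrane
#' time constant \eqn{\tau_m} (ms), the half-width \eqn{\Delta} of the
#' Lorentzian excitability distribution, the per-population mean
#' excitability \eqn{\bar\eta(k)} and a background DC current \eqn{I_B}.
#' All currents and voltages are dimensionless; internal time is in ms and
#' rates in 1/ms (multiply by 1000 for Hz).
#'
#' @param n_pop number of populations.
#' @param eta_bar mean excitability, scalar (recycled) or vector of length
#'   `n_pop`.
#' @param delta Lorentzian half-width at half maximum, > 0.
#' @param tau_m membrane time constant in ms, > 0.
#' @param I_B background DC current.
#' @return an object of class `neuralMassParams`.
#' @examples
#' p <- neuralMassParams(n_pop = 2, eta_bar = -9.54)
#' @export
neuralMassParams <- function(n_pop = 1, eta_bar = -5, delta = 1, tau_m = 20,
                             I_B = 0) {
  stopifnot(is.numeric(n_pop), length(n_pop) == 1, n_pop >= 1)
  n_pop <- as.integer(n_pop)
  if (!is.numeric(eta_bar) || !all(is.finite(eta_bar)))
    stop("eta_bar must be finite numeric")
  if (length(eta_bar) == 1) eta_bar <- rep(eta_bar, n_pop)
  if (length(eta_bar) != n_pop)
    stop("eta_bar must have length 1 or n_pop")
  if (!is.finite(delta) || delta <= 0) stop("delta must be > 0")
  if (!is.finite(tau_m) || tau_m <= 0) stop("tau_m must be > 0")
  if (!is.finite(I_B)) stop("I_B must be finite")
  structure(list(n_pop = n_pop, eta_bar = as.numeric(eta_bar),
                 delta = delta, tau_m = tau_m, I_B = I_B),
            class = "neuralMassParams")
}

#' @export
print.neuralMassParams <- function(x, ...) {
  cat("Neural mass parameters:", x$n_pop, "population(s)\n")
  cat("  tau_m =", x$tau_m, "ms, Delta =", x$delta, ", I_B =", x$I_B, "\n")
  if (length(unique(x$eta_bar)) == 1) {
    cat("  eta_bar =", x$eta_bar[1], "(homogeneous)\n")
  } else {
    cat("  eta_bar in [", min(x$eta_bar), ",", max(x$eta_bar),
        "] (heterogeneous)\n")
  }
  invisible(x)
}

# replace the excitability vector, keeping everything else
set_eta <- function(params, eta_bar) {
  neuralMassParams(params$n_pop, eta_bar, params$delta, params$tau_m,
                   params$I_B)
}

#' Rectangular stimulation pulse
#'
#' A step current of amplitude `amplitude` applied to the target
#' populations for `onset <= t < onset + duration`. This is the
#' perturbation used throughout the recruitment protocols (defaults:
#' amplitude 10, duration 400 ms).
#'
#' @param targets 1-based indices of the stimulated populations.
#' @param amplitude pulse amplitude (dimensionless current), >= 0.
#' @param onset pulse onset time in ms.
#' @param duration pulse duration in ms, > 0.
#' @return an object of class `stimulusProtocol`.
#' @export
stimulusProtocol <- function(targets, amplitude = 10, onset = 0,
                             duration = 400) {
  targets <- as.integer(targets)
  if (length(targets) < 1 || anyNA(targets) || any(targets < 1))
    stop("targets must be a nonempty set of positive indices")
  if (!is.finite(amplitude) || amplitude < 0)
    stop("amplitude must be >= 0")
  if (!is.finite(duration) || duration <= 0)
    stop("duration must be > 0")
  if (!is.finite(onset)) stop("onset must be finite")
  structure(list(targets = sort(unique(targets)), amplitude = amplitude,
                 onset = onset, duration = duration),
            class = "stimulusProtocol")
}

#' @export
print.stimulusProtocol <- function(x, ...) {
  cat("Rectangular pulse: I_S =", x$amplitude, "on area(s)",
      paste(x$targets, collapse = ", "), "\n")
  cat("  t in [", x$onset, ",", x$onset + x$duration, ") ms\n")
  invisible(x)
}

#' Parameters of the microscopic QIF network
#'
#' A fully coupled network (without autapses) of `N` quadratic
#' integrate-and-fire neurons with per-neuron excitabilities
#' `eta_samples`, global synaptic strength `J` and a finite numerical
#' spiking threshold `V_peak` (reset at `-V_peak`, standing in for the
#' infinite threshold of the ideal QIF neuron).
#'
#' @param N neuron count, >= 1.
#' @param eta_samples per-neuron excitabilities, length `N` (see
#'   [sampleLorentzian()]).
#' @param J synaptic strength (total coupling; each spike increments every
#'   other neuron's voltage by `J/N`).
#' @param tau_m membrane time constant, ms.
#' @param V_peak finite spike threshold, > 0.
#' @param dt Euler integration step, ms.
#' @param I_B background DC current.
#' @return an object of class `qifParams`.
#' @export
qifParams <- function(N, eta_samples, J = 0, tau_m = 20, V_peak = 100,
                      dt = 0.01, I_B = 0) {
  N <- as.integer(N)
  stopifnot(N >= 1)
  if (length(eta_samples) != N || !all(is.finite(eta_samples)))
    stop("eta_samples must be a finite vector of length N")
  if (!is.finite(V_peak) || V_peak <= 0) stop("V_peak must be > 0")
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0")
  if (!is.finite(tau_m) || tau_m <= 0) stop("tau_m must be > 0")
  structure(list(N = N, eta_samples = as.numeric(eta_samples), J = J,
                 tau_m = tau_m, V_peak = V_peak, dt = dt, I_B = I_B),
            class = "qifParams")
}

#' Sample excitabilities from a Lorentzian distribution
#'
#' The exact mean-field reduction assumes per-neuron excitabilities
#' \eqn{\eta_i} drawn from a Lorentzian (Cauchy) distribution centred at
#' \eqn{\bar\eta} with half-width \eqn{\Delta}. The deterministic scheme
#' uses the equiprobable quantiles
#' \eqn{\eta_i = \bar\eta + \Delta\,\tan(\pi (2i - N - 1) / (2(N+1)))},
#' which removes sampling noise from finite-size comparisons; the random
#' scheme draws i.i.d. Cauchy variates.
#'
#' @param eta_bar centre of the distribution.
#' @param delta half-width at half maximum, > 0.
#' @param n number of samples.
#' @param scheme `"deterministic"` quantiles or `"random"` i.i.d. draws.
#' @param seed optional integer seed for the random scheme.
#' @return numeric vector of length `n`.
#' @examples
#' sampleLorentzian(0, 1, 3) # -1 0 1
#' @export
sampleLorentzian <- function(eta_bar, delta, n,
                             scheme = c("deterministic", "random"),
                             seed = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(n >= 1, delta > 0)
  if (scheme == "deterministic") {
    i <- seq_len(n)
    eta_bar + delta * tan(pi * (2 * i - n - 1) / (2 * (n + 1)))
  } else {
    with_seed(seed, eta_bar + delta * stats::rcauchy(n))
  }
}

# evaluate `expr` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
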