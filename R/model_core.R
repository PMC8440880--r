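#' Right-hand side of the single-population neural mass model
#'
#' The exact mean-field equations for one QIF population,
#' \deqn{\tau_m \dot r = \Delta/(\tau_m \pi) + 2 r v}
#' \deqn{\tau_m \dot v = v^2 + \bar\eta + I_B + I - (\pi \tau_m r)^2
#'   + \tau_m J r,}
#' with recurrent (self) coupling `J_self` and external current `I_ext`.
#'
#' @param r,v firing rate (1/ms) and mean membrane potential.
#' @param params a [neuralMassParams()] (the first `eta_bar` entry is
#'   used).
#' @param J_self recurrent synaptic weight.
#' @param I_ext external current added to `I_B`.
#' @return list with components `dr` (1/ms^2) and `dv` (1/ms).
#' @export
massRhs <- function(r, v, params, J_self = 0, I_ext = 0) {
  if (!all(is.finite(c(r, v, J_self, I_ext))))
    stop("invalid state: non-finite input")
  if (any(r < 0)) stop("invalid state: r must be >= 0")
  tau <- params$tau_m
  eta <- params$eta_bar[1]
  dr <- (params$delta / (tau * pi) + 2 * r * v) / tau
  dv <- (v^2 + eta + params$I_B + I_ext - (pi * tau * r)^2 +
           tau * J_self * r) / tau
  list(dr = dr, dv = dv)
}

#' Right-hand side of the multipopulation neural mass model
#'
#' Per-population mean-field equations coupled through the synaptic weight
#' matrix \eqn{J_{kl}}: the coupling current on population `k` is
#' \eqn{\tau_m \sum_l J_{kl} r_l} (the diagonal carries the recurrent
#' intra-population weight). With zero off-diagonal coupling every
#' population reduces to [massRhs()].
#'
#' @param state list with numeric vectors `r` and `v` of equal length.
#' @param params a [neuralMassParams()] with matching `n_pop`.
#' @param coupling a [buildCoupling()] object or a plain square matrix.
#' @param stim_values per-population external current vector (default 0).
#' @return list of derivative vectors `dr`, `dv`.
#' @export
networkRhs <- function(state, params, coupling, stim_values = 0) {
  J <- coupling_matrix(coupling)
  n <- params$n_pop
  r <- state$r
  v <- state$v
  if (length(r) != n || length(v) != n || nrow(J) != n || ncol(J) != n)
    stop("dimension mismatch between state, parameters and coupling")
  if (!all(is.finite(r)) || !all(is.finite(v)))
    stop("invalid state: non-finite input")
  stim_values <- rep_len(stim_values, n)
  tau <- params$tau_m
  dr <- (params$delta / (tau * pi) + 2 * r * v) / tau
  dv <- (v^2 + params$eta_bar + params$I_B + stim_values -
           (pi * tau * r)^2 + tau * drop(J %*% r)) / tau
  list(dr = dr, dv = dv)
}

# Jacobian of the single-population system at (r, v)
single_jacobian <- function(r, v, tau, J_self) {
  matrix(c(2 * v / tau, -2 * pi^2 * tau * r + J_self,
           2 * r / tau, 2 * v / tau), 2, 2)
}

#' Equilibria of the single-population neural mass model
#'
#' Eliminating \eqn{v^* = -\Delta/(2\pi\tau_m r^*)} from the stationarity
#' conditions leaves the quartic
#' \deqn{-\pi^2\tau_m^2 {r^*}^4 + J \tau_m {r^*}^3 + (\bar\eta + I) {r^*}^2
#'   + \Delta^2/(4\pi^2\tau_m^2) = 0,}
#' whose positive real roots are the equilibrium firing rates. Roots are
#' found as eigenvalues of the companion matrix, classified by the
#' eigenvalues of the 2x2 Jacobian, and returned sorted by rate. The
#' system always has at least one and at most three admissible equilibria:
#' a low-activity (LA) state, a high-activity (HA) state, and in the
#' bistable window also a separating saddle.
#'
#' @param eta_bar mean excitability.
#' @param delta Lorentzian half-width, > 0.
#' @param tau_m membrane time constant, ms.
#' @param J_self recurrent coupling.
#' @param I additional constant current.
#' @return data frame of class `fixedPoints` with columns `r`, `v`,
#'   `stability`, `eig_re`, `eig_im` (eigenvalue pair; complex conjugate
#'   when `eig_im != 0`) and `degenerate`.
#' @examples
#' singleFixedPoints(-50, 1, 20, 0)
#' @export
singleFixedPoints <- function(eta_bar, delta = 1, tau_m = 20, J_self = 0,
                              I = 0) {
  stopifnot(delta > 0, tau_m > 0)
  # quartic coefficients, highest degree first
  a <- c(-pi^2 * tau_m^2, J_self * tau_m, eta_bar + I, 0,
         delta^2 / (4 * pi^2 * tau_m^2))
  comp <- matrix(0, 4, 4)
  comp[cbind(2:4, 1:3)] <- 1
  comp[1, ] <- -a[2:5] / a[1]
  roots <- eigen(comp, only.values = TRUE)$values
  r_star <- sort(Re(roots[abs(Im(roots)) < 1e-9 & Re(roots) > 1e-12]))
  # collapse numerically coincident roots (saddle-node degeneracy)
  degenerate <- FALSE
  if (length(r_star) > 1) {
    close <- diff(r_star) < 1e-9 * max(r_star)
    if (any(close)) {
      degenerate <- TRUE
      r_star <- r_star[c(TRUE, !close)]
    }
  }
  v_star <- -delta / (2 * pi * tau_m * r_star)
  res <- lapply(seq_along(r_star), function(i) {
    eig <- eigen(single_jacobian(r_star[i], v_star[i], tau_m, J_self),
                 only.values = TRUE)$values
    data.frame(r = r_star[i], v = v_star[i],
               stability = stability_label(eig),
               eig_re = Re(eig[1]), eig_im = abs(Im(eig[1])),
               degenerate = degenerate)
  })
  out <- do.call(rbind, res)
  class(out) <- c("fixedPoints", "data.frame")
  out
}

stability_label <- function(eig) {
  re <- Re(eig)
  im <- Im(eig)
  tol <- 1e-9
  if (any(abs(re) < tol)) return("degenerate")
  if (max(abs(im)) > tol) {
    if (all(re < 0)) "stable_focus" else "unstable_focus"
  } else {
    if (all(re < 0)) "stable_node"
    else if (all(re > 0)) "unstable_node"
    else "saddle"
  }
}

#' Classify the stability of a single-population equilibrium
#'
#' Evaluates the 2x2 Jacobian of the mean-field equations at
#' `(r_star, v_star)` and labels the equilibrium from its eigenvalues:
#' complex pairs give foci, real pairs nodes, real eigenvalues of opposite
#' sign a saddle; zero real parts are labelled `"degenerate"`.
#'
#' @param r_star,v_star equilibrium coordinates (must zero the
#'   right-hand side).
#' @param params a [neuralMassParams()].
#' @param J_self recurrent coupling.
#' @param I additional constant current.
#' @param tol tolerance for the equilibrium precondition.
#' @return a stability label string.
#' @export
classifyFixedPoint <- function(r_star, v_star, params, J_self = 0, I = 0,
                               tol = 1e-8) {
  d <- massRhs(r_star, v_star, params, J_self, I)
  if (max(abs(c(d$dr, d$dv))) > tol)
    stop("(r_star, v_star) is not an equilibrium of the system")
  eig <- eigen(single_jacobian(r_star, v_star, params$tau_m, J_self),
               only.values = TRUE)$values
  stability_label(eig)
}

#' Phase diagram of the single population
#'
#' Scans a grid of excitability and self-coupling values and labels each
#' cell by its attractor structure: `"LA_only"` (single stable
#' low-activity equilibrium), `"HA_focus_only"` (single stable
#' high-activity focus) or `"bistable"` (LA and HA coexisting, separated
#' by a saddle). Outside the bistable wedge the LA/HA distinction is a
#' convention; we call a single equilibrium high-activity when its focus
#' is underdamped (|Im| > |Re| of the Jacobian eigenvalues, i.e., the
#' approach is genuinely oscillatory), which reduces to the node/focus
#' boundary where the damping is weak and keeps the deep low-activity
#' region labelled LA even at very small self-coupling, where the
#' eigenvalues acquire a vanishingly small imaginary part. Cells adjacent
#' to a label change are flagged as boundary cells; cells containing a
#' degenerate (zero real part or double) root are excluded from
#' classification and marked `NA`.
#'
#' @param eta_grid,J_grid numeric vectors of grid values.
#' @param delta,tau_m model constants.
#' @return list with `eta`, `J`, a character label matrix `label`
#'   (eta x J) and a logical `boundary` matrix.
#' @export
singlePhaseDiagram <- function(eta_grid, J_grid, delta = 1, tau_m = 20) {
  stopifnot(all(is.finite(eta_grid)), all(is.finite(J_grid)))
  lab <- matrix(NA_character_, length(eta_grid), length(J_grid),
                dimnames = list(NULL, NULL))
  for (j in seq_along(J_grid)) {
    for (i in seq_along(eta_grid)) {
      fp <- singleFixedPoints(eta_grid[i], delta, tau_m, J_grid[j])
      if (any(fp$degenerate) || any(fp$stability == "degenerate")) next
      stable <- fp[fp$stability %in% c("stable_node", "stable_focus"), ]
      underdamped <- nrow(stable) == 1 &&
        stable$stability[1] == "stable_focus" &&
        stable$eig_im[1] > abs(stable$eig_re[1])
      lab[i, j] <-
        if (nrow(stable) >= 2) "bistable"
        else if (nrow(fp) == 1 && underdamped) "HA_focus_only"
        else "LA_only"
    }
  }
  boundary <- matrix(FALSE, nrow(lab), ncol(lab))
  if (nrow(lab) > 1) {
    chg <- lab[-1, , drop = FALSE] != lab[-nrow(lab), , drop = FALSE]
    chg[is.na(chg)] <- TRUE
    boundary[-1, ][chg] <- TRUE
    boundary[-nrow(lab), ][chg] <- TRUE
  }
  list(eta = eta_grid, J = J_grid, label = lab, boundary = boundary)
}
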