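test_that("single-population right-hand side matches the closed form", {
  p <- neuralMassParams(1, eta_bar = 0, delta = 1, tau_m = 20)
  d <- massRhs(0, 0, p)
  expect_equal(d$dr, 1 / (400 * pi), tolerance = 1e-12)
  expect_equal(d$dv, 0)

  # linearity in Delta at r = 0
  p2 <- neuralMassParams(1, eta_bar = 0, delta = 2, tau_m = 20)
  expect_equal(massRhs(0, 0, p2)$dr, 2 * d$dr)

  # non-finite state rejected
  expect_error(massRhs(NaN, 0, p), "non-finite")
  expect_error(massRhs(-0.1, 0, p), "r must be")
})

test_that("network RHS reduces to the single population when decoupled", {
  n <- 4
  p <- neuralMassParams(n, eta_bar = -3, delta = 1, tau_m = 20)
  J <- diag(rep(7, n))
  st <- list(r = rep(0.02, n), v = rep(-1, n))
  net <- networkRhs(st, p, J)
  single <- massRhs(0.02, -1, p, J_self = 7)
  expect_equal(net$dr, rep(single$dr, n), tolerance = 1e-12)
  expect_equal(net$dv, rep(single$dv, n), tolerance = 1e-12)
})

test_that("coupling current enters v-dot as tau * J_kl * r_l", {
  p <- neuralMassParams(2, eta_bar = -3)
  J <- matrix(c(0, 0, 5, 0), 2, 2)  # J[1,2] = 5
  st <- list(r = c(0.01, 0.05), v = c(0, 0))
  with_c <- networkRhs(st, p, J)
  without <- networkRhs(st, p, matrix(0, 2, 2))
  # tau * J_12 * r_2 = 20 * 5 * 0.05 = 5, divided by tau in dv
  expect_equal(with_c$dv[1] - without$dv[1], 5 / 20, tolerance = 1e-12)
  expect_equal(with_c$dv[2], without$dv[2])
  # all rates zero: coupling current vanishes
  st0 <- list(r = c(0, 0), v = c(0.3, -0.2))
  expect_equal(networkRhs(st0, p, J)$dv, networkRhs(st0, p, J * 0)$dv)
  expect_error(networkRhs(st, p, matrix(0, 3, 3)), "dimension")
})

test_that("fixed points zero the RHS and split by stability", {
  p <- neuralMassParams(1, eta_bar = -6, delta = 1, tau_m = 20)
  fp <- singleFixedPoints(-6, 1, 20, 20)
  expect_equal(nrow(fp), 3)
  expect_equal(fp$stability, c("stable_node", "saddle", "stable_focus"))
  for (i in seq_len(nrow(fp))) {
    d <- massRhs(fp$r[i], fp$v[i], p, J_self = 20)
    expect_lt(max(abs(c(d$dr, d$dv))), 1e-10)
  }
  # sorted ascending, v* consistent with the rate
  expect_true(all(diff(fp$r) > 0))
  expect_equal(fp$v, -1 / (2 * pi * 20 * fp$r), tolerance = 1e-12)
})

test_that("Delta -> 0 limit recovers the single-neuron firing rate", {
  fp <- singleFixedPoints(4, delta = 1e-9, tau_m = 20, J_self = 0)
  expect_equal(nrow(fp), 1)
  expect_equal(fp$r, sqrt(4) / (pi * 20), tolerance = 1e-4)
  expect_equal(fp$v, 0, tolerance = 1e-3)
})

test_that("root finder agrees with ODE relaxation across random points", {
  set.seed(42)
  p0 <- neuralMassParams(1, eta_bar = 0)
  for (rep in 1:50) {
    eta <- runif(1, -30, 8)
    J <- runif(1, 0, 25)
    fp <- singleFixedPoints(eta, 1, 20, J)
    stable <- fp[fp$stability %in% c("stable_node", "stable_focus"), ]
    # relax from a point near each stable root; must land on it
    for (i in seq_len(nrow(stable))) {
      p <- neuralMassParams(1, eta_bar = eta)
      st0 <- list(r = stable$r[i] * 1.01, v = stable$v[i])
      traj <- integrateNetwork(p, matrix(J, 1, 1), state0 = st0,
                               t_span = 4000, dt = 0.02,
                               record_dt = 4000)
      end <- finalState(traj)
      expect_lt(abs(end$r - stable$r[i]), 1e-6)
      expect_lt(abs(end$v - stable$v[i]), 1e-6)
    }
  }
})

test_that("deep-LA relaxation from rest matches the unique fixed point", {
  p <- neuralMassParams(1, eta_bar = -50)
  fp <- singleFixedPoints(-50, 1, 20, 0)
  expect_equal(nrow(fp), 1)
  traj <- integrateNetwork(p, matrix(0, 1, 1), t_span = 2000, dt = 0.02,
                           record_dt = 2000)
  end <- finalState(traj)
  expect_lt(abs(end$r - fp$r), 1e-6)
  expect_lt(abs(end$v - fp$v), 1e-6)
})

test_that("stability classification follows the Jacobian eigenvalues", {
  p <- neuralMassParams(1, eta_bar = -50)
  fp <- singleFixedPoints(-50, 1, 20, 20)
  expect_equal(classifyFixedPoint(fp$r[1], fp$v[1], p, J_self = 20),
               "stable_node")
  p2 <- neuralMassParams(1, eta_bar = -6)
  fp2 <- singleFixedPoints(-6, 1, 20, 20)
  expect_equal(classifyFixedPoint(fp2$r[2], fp2$v[2], p2, J_self = 20),
               "saddle")
  expect_equal(classifyFixedPoint(fp2$r[3], fp2$v[3], p2, J_self = 20),
               "stable_focus")
  # non-equilibrium input rejected
  expect_error(classifyFixedPoint(0.05, 1, p2, J_self = 20),
               "not an equilibrium")
})

test_that("phase diagram recovers the three regions", {
  pd <- singlePhaseDiagram(eta_grid = seq(-12, 2, by = 0.5),
                           J_grid = c(0, 5, 10, 15, 20), delta = 1,
                           tau_m = 20)
  # J = 0 slice: no bistability anywhere
  expect_false(any(pd$label[, 1] == "bistable", na.rm = TRUE))
  # J = 20 column shows all three regions
  j20 <- pd$label[, 5]
  expect_setequal(unique(stats::na.omit(j20)),
                  c("LA_only", "bistable", "HA_focus_only"))
  # contiguity along eta: LA then bistable then HA
  runs <- rle(stats::na.omit(j20))$values
  expect_equal(runs, c("LA_only", "bistable", "HA_focus_only"))
  # deep-LA column stays LA for all J
  pd2 <- singlePhaseDiagram(-50, c(0, 5, 10, 20))
  expect_true(all(pd2$label == "LA_only"))
})

test_that("trajectories preserve rate positivity and damped focus
           oscillations ring around the equilibrium", {
  # positivity: rates stay strictly positive once above zero
  p <- neuralMassParams(1, eta_bar = -9)
  traj <- integrateNetwork(p, matrix(20, 1, 1),
                           state0 = list(r = 1e-8, v = 0),
                           t_span = 500, dt = 0.02, record_dt = 0.5)
  expect_true(all(traj$r > 0))

  # HA focus: complex eigenvalues and multiple crossings of terminal v
  p6 <- neuralMassParams(1, eta_bar = -6)
  fp <- singleFixedPoints(-6, 1, 20, 20)
  ha <- fp[fp$stability == "stable_focus", ]
  expect_gt(ha$eig_im, 0)
  st0 <- list(r = ha$r * 1.3, v = ha$v)
  tr2 <- integrateNetwork(p6, matrix(20, 1, 1), state0 = st0,
                          t_span = 300, dt = 0.02, record_dt = 0.2)
  # count sign changes of (v(t) - v*) after an initial excursion
  dv <- tr2$v[, 1] - ha$v
  crossings <- sum(abs(diff(sign(dv))) > 0)
  expect_gt(crossings, 3)
})

test_that("integrator halving dt changes the LA terminal state < 1e-8", {
  p <- neuralMassParams(1, eta_bar = -50)
  run <- function(dt) finalState(integrateNetwork(
    p, matrix(0, 1, 1), t_span = 500, dt = dt, record_dt = 500))
  a <- run(0.02)
  b <- run(0.01)
  expect_lt(abs(a$r - b$r) + abs(a$v - b$v), 1e-8)
})

test_that("zero-amplitude stimulus leaves the trajectory unchanged", {
  p <- neuralMassParams(2, eta_bar = -9)
  J <- matrix(c(20, 1, 1, 20), 2, 2)
  stim <- stimulusProtocol(1, amplitude = 0, onset = 100, duration = 400)
  a <- integrateNetwork(p, J, t_span = 800, dt = 0.05, stimulus = stim)
  b <- integrateNetwork(p, J, t_span = 800, dt = 0.05)
  expect_identical(a$r, b$r)
  expect_identical(a$v, b$v)
})

test_that("integration failure names the blow-up time", {
  p <- neuralMassParams(1, eta_bar = 1e5)
  expect_error(
    integrateNetwork(p, matrix(0, 1, 1), state0 = list(r = 0, v = 1e4),
                     t_span = 100, dt = 0.5),
    "diverged.*t = ")
})

test_that("Lorentzian sampling schemes behave as documented", {
  expect_equal(sampleLorentzian(0, 1, 3), c(-1, 0, 1), tolerance = 1e-12)
  # odd N: median sample is the centre
  s <- sampleLorentzian(-7, 2, 11)
  expect_equal(s[6], -7)
  expect_equal(stats::median(s), -7)
  # random scheme reproducible under a seed
  a <- sampleLorentzian(0, 1, 100, scheme = "random", seed = 7)
  b <- sampleLorentzian(0, 1, 100, scheme = "random", seed = 7)
  expect_identical(a, b)
})
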