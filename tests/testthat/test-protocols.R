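# protocol tests run on tiny networks with dt = 0.05 ms (RK4; ~60 steps
# per fastest focus period) so the whole file stays fast

# two mutually coupled populations: recurrent 20, inter-coupling 5 * w
# (plain matrix; every protocol accepts either form)
toy2 <- function(w = 1) matrix(c(20, 5 * w, 5 * w, 20), 2)

test_that("decoupled sweep reproduces the single-population branches", {
  conn <- synthConnectome(3, density = 1, seed = 1)
  cpl <- buildCoupling(conn, sigma = 0)
  p <- neuralMassParams(3, eta_bar = -50)
  sw <- adiabaticSweep(cpl, p, eta_range = c(-30, 0), eta_step = 3,
                       settle_time = 1500, dt = fast_dt)
  for (i in seq_along(sw$up$eta)) {
    fp <- singleFixedPoints(sw$up$eta[i], 1, 20, J_self = 0)
    stable <- fp[fp$stability %in% c("stable_node", "stable_focus"), ]
    # J = 0: unique equilibrium; both sweep branches must sit on it
    expect_equal(sw$up$mean_rate[i], stable$r[1], tolerance = 1e-4)
  }
  down_rates <- rev(sw$down$mean_rate)
  expect_equal(down_rates, sw$up$mean_rate, tolerance = 1e-4)
})

test_that("up-sweep rates are non-decreasing and the coupled transition
           is hysteretic", {
  conn <- synthConnectome(10, density = 0.5, seed = 3)
  cpl <- buildCoupling(conn, sigma = 1)
  p <- neuralMassParams(10, eta_bar = -50)
  sw <- adiabaticSweep(cpl, p, eta_step = 1.5, settle_time = 1500,
                       dt = fast_dt)
  expect_true(all(diff(sw$up$mean_rate) > -1e-9))
  hb <- hysteresisBounds(sw)
  expect_lt(hb$eta_LA, hb$eta_HA)
  # up branch dominated by LA: cell-wise below the down branch
  expect_true(all(sw$up$mean_rate <=
                    rev(sw$down$mean_rate) + 1e-3))
})

test_that("map of regimes collapses to the single node at sigma = 0", {
  conn <- synthConnectome(3, density = 1, seed = 2)
  p <- neuralMassParams(3, eta_bar = -50)
  mp <- mapOfRegimes(conn, p, sigma_range = c(0, 1), sigma_step = 0.5,
                     eta_range = c(-20, -2), eta_step = 3,
                     settle_time = 1000, dt = fast_dt)
  for (i in seq_along(mp$eta)) {
    fp <- singleFixedPoints(mp$eta[i], 1, 20, J_self = 0)
    stable <- fp[fp$stability %in% c("stable_node", "stable_focus"), ]
    expect_equal(mp$up[1, i], stable$r[1], tolerance = 1e-3)
  }
  # inside the multistable band the up grid sits at or below the down grid
  expect_true(all(mp$up <= mp$down + 1e-3))
})

test_that("recruitment threshold uses the saddle and degrades
           gracefully", {
  p <- neuralMassParams(1, eta_bar = -8)
  fp <- singleFixedPoints(-8, 1, 20, 20)
  expect_equal(recruitmentThreshold(-8, p, 20),
               fp$r[fp$stability == "saddle"], tolerance = 1e-12)
  # outside the bistable window: geometric-mean fallback, still between
  # the LA and HA scales
  rc <- recruitmentThreshold(-13, p, 20)
  expect_gt(rc, 1e-3)
  expect_lt(rc, 0.1)
  expect_error(recruitmentThreshold(-8, p, J_self = 0, search_width = 1),
               "criterion undefined")
})

test_that("LA preparation succeeds in the multistable band and fails
           when only HA remains", {
  cpl <- toy2(0.3)
  p <- neuralMassParams(2, eta_bar = -9.54)
  st <- prepareLaState(cpl, p, settle_time = 1500, dt = fast_dt)
  expect_true(all(st$r < recruitmentThreshold(-9.54, p, 20)))
  p_hot <- neuralMassParams(2, eta_bar = -4)
  expect_error(prepareLaState(cpl, p_hot, settle_time = 1500,
                              dt = fast_dt),
               "high-activity")
})

test_that("stimulation below threshold relaxes back; in the multistable
           band the stimulated area stays high (asymptomatic)", {
  cpl <- toy2(0.05)  # weak inter-coupling

  # deep below the bistable window: event dies with the stimulus
  p_lo <- neuralMassParams(2, eta_bar = -12)
  stim <- stimulusProtocol(1, amplitude = 10, duration = 400)
  tr_lo <- runStimulation(cpl, p_lo, stim, post_window = 1500,
                          settle_time = 1500, dt = fast_dt)
  res_lo <- detectRecruitments(tr_lo, J_self = 20)
  expect_equal(res_lo$classification, "none")

  # inside the band: the stimulated area remains in HA after offset
  p_mid <- neuralMassParams(2, eta_bar = -9)
  tr <- runStimulation(cpl, p_mid, stim, post_window = 1500,
                       settle_time = 1500, dt = fast_dt)
  res <- detectRecruitments(tr, J_self = 20)
  expect_equal(res$classification, "asymptomatic")
  expect_equal(res$order, 1L)
  expect_equal(res$n_recruited, 1L)

  # zero amplitude: nothing happens
  stim0 <- stimulusProtocol(1, amplitude = 0.0001, duration = 400)
  tr0 <- runStimulation(cpl, p_mid, stim0, post_window = 500,
                        settle_time = 1500, dt = fast_dt)
  expect_equal(detectRecruitments(tr0, J_self = 20)$n_recruited, 0L)
})

test_that("recruitment detection returns exact times on a hand-built
           trajectory", {
  times <- seq(0, 1500, by = 1)
  n <- 4
  r_c <- 0.05
  r <- matrix(0.01, length(times), n)
  r[times >= 250, 1] <- 0.08            # sustained from 250 ms
  r[times >= 700, 2] <- 0.09            # sustained from 700 ms
  r[times >= 400 & times <= 900, 3] <- 0.07  # transient only
  stim <- stimulusProtocol(1, amplitude = 10, onset = 200,
                           duration = 400)
  traj <- structure(list(times = times, r = r,
                         v = matrix(0, length(times), n),
                         stimulus = stim,
                         params = neuralMassParams(n, -9)),
                    class = "massTrajectory")
  res <- detectRecruitments(traj, stim, r_c = r_c)
  expect_equal(res$n_recruited, 2L)
  expect_equal(res$order, c(1L, 2L))
  expect_equal(res$recruit_time[1], 50)
  expect_equal(res$recruit_time[2], 500)
  expect_true(is.na(res$recruit_time[3]))  # transient crossing ignored
  expect_equal(res$classification, "partial")

  # unstimulated trajectory: nothing recruited
  flat <- traj
  flat$r <- matrix(0.01, length(times), n)
  expect_equal(detectRecruitments(flat, stim, r_c = r_c)$classification,
               "none")
})

test_that("threshold scan orders thresholds and matches a bisection
           oracle to one grid step", {
  cpl <- toy2(1)
  p <- neuralMassParams(2, eta_bar = -9)
  step <- 0.25
  tm <- thresholdMap(cpl, p, areas = 1, eta_range = c(-11, -8.5),
                     eta_step = step, post_window = 1500,
                     settle_time = 1500, dt = fast_dt, record_dt = 1)
  expect_false(is.na(tm$eta_asy[1]))
  expect_lte(tm$eta_asy[1], tm$eta_gen[1])

  # bisection on the same criterion and machinery, different search
  count_at <- function(eta) {
    pe <- neuralMassParams(2, eta_bar = eta)
    rc <- recruitmentThreshold(eta, pe, 20)
    st <- prepareLaState(cpl, pe, settle_time = 1500, dt = fast_dt,
                         r_c = rc)
    stim <- stimulusProtocol(1, amplitude = 10, duration = 400)
    tr <- runStimulation(cpl, pe, stim, post_window = 1500, baseline = 0,
                         state0 = st, dt = fast_dt, record_dt = 1)
    detectRecruitments(tr, stim, r_c = rc)$n_recruited
  }
  bisect <- function(cond) {
    lo <- -11; hi <- -8.5
    for (it in 1:12) {
      mid <- (lo + hi) / 2
      if (cond(count_at(mid))) hi <- mid else lo <- mid
    }
    hi
  }
  asy_oracle <- bisect(function(n) n >= 1)
  gen_oracle <- bisect(function(n) n == 2)
  expect_lt(abs(tm$eta_asy[1] - asy_oracle), step + 1e-9)
  expect_lt(abs(tm$eta_gen[1] - gen_oracle), step + 1e-9)
})

test_that("heterogeneous scan reduces to the homogeneous one at sd = 0
           and is reproducible under a seed", {
  cpl <- toy2(0.3)
  p <- neuralMassParams(2, eta_bar = -9)
  grid <- c(-9.6, -9.1)
  hom <- thresholdMap(cpl, p, areas = 1, eta_range = range(grid),
                      eta_step = 0.5, post_window = 1000,
                      settle_time = 1000, dt = fast_dt, record_dt = 1)
  het0 <- heterogeneousScan(cpl, p, areas = 1, eta_range = range(grid),
                            eta_step = 0.5, sd = 0, reps = 2, seed = 1,
                            post_window = 1000, settle_time = 1000,
                            dt = fast_dt, record_dt = 1)
  expect_equal(het0$n_recruited[, 1], unname(hom$n_recruited[, 1]))

  h1 <- heterogeneousScan(cpl, p, areas = 1, eta_range = range(grid),
                          eta_step = 0.5, sd = 0.1, reps = 2, seed = 7,
                          post_window = 1000, settle_time = 1000,
                          dt = fast_dt, record_dt = 1)
  h2 <- heterogeneousScan(cpl, p, areas = 1, eta_range = range(grid),
                          eta_step = 0.5, sd = 0.1, reps = 2, seed = 7,
                          post_window = 1000, settle_time = 1000,
                          dt = fast_dt, record_dt = 1)
  expect_identical(h1$n_recruited, h2$n_recruited)
})

# hub-and-leaves coupling with moderate drives so transitions stay clean
star5 <- function(ws = c(0.5, 0.35, 0.25, 0.15)) {
  J <- diag(20, 5)
  J[2:5, 1] <- 5 * ws
  J[1, 2:5] <- 5 * ws
  J
}

test_that("first recruited area has the strongest edge to the EZ and
           amplitude only speeds recruitment up", {
  cpl <- star5()
  p <- neuralMassParams(5, eta_bar = -5.6)
  amp <- amplitudeSweep(cpl, p, area = 1, I_S_values = c(0, 10, 30),
                        t_I = 400, n_first = 5, post_window = 1500,
                        settle_time = 1500, dt = fast_dt)
  # zero amplitude recruits nothing
  expect_true(all(is.na(amp$time[amp$amplitude == 0])))
  # the EZ (hub) is first, then its strongest neighbour (area 2)
  for (I_S in c(10, 30)) {
    ord <- amp$area[amp$amplitude == I_S]
    expect_equal(ord[1], 1L)
    expect_equal(ord[2], 2L)
  }
  # per order position, times non-increasing in amplitude
  t10 <- amp$time[amp$amplitude == 10]
  t30 <- amp$time[amp$amplitude == 30]
  expect_true(all(t30 <= t10 + 1e-6, na.rm = TRUE))
})

test_that("extending the pulse beyond full recruitment leaves times
           unchanged; runs are deterministic", {
  cpl <- star5()
  p <- neuralMassParams(5, eta_bar = -5.6)
  dur <- durationSweep(cpl, p, area = 1, t_I_values = c(0, 400, 800),
                       I_S = 15, n_first = 5, post_window = 1500,
                       settle_time = 1500, dt = fast_dt)
  expect_true(all(is.na(dur$time[dur$duration == 0])))
  t400 <- dur$time[dur$duration == 400]
  t800 <- dur$time[dur$duration == 800]
  expect_true(all(abs(t800 - t400) < 1, na.rm = TRUE))

  dur2 <- durationSweep(cpl, p, area = 1, t_I_values = c(0, 400, 800),
                        I_S = 15, n_first = 5, post_window = 1500,
                        settle_time = 1500, dt = fast_dt)
  expect_identical(dur, dur2)
})
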