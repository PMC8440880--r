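test_that("energy rule applies the threshold and excludes the EZ", {
  fs <- 1000
  t <- seq(0, 2, by = 1 / fs)[-1]
  base <- sin(2 * pi * 10 * t)
  # energies 1.0, 0.31, 0.29 relative to the strongest signal
  sig <- cbind(base, sqrt(0.31) * base, sqrt(0.29) * base)
  pz <- pzFromEnergy(sig, fs, ez = 1, energy_fraction = 0.3)
  expect_equal(pz, 2)

  # EZ holding the maximum stays excluded
  pz2 <- pzFromEnergy(sig, fs, ez = c(1, 2), energy_fraction = 0.3)
  expect_length(pz2, 0)

  # all-equal energies: every non-EZ area included
  eq <- cbind(base, base, base)
  expect_equal(pzFromEnergy(eq, fs, ez = 2), c(1, 3))

  # monotone in the fraction
  expect_equal(pzFromEnergy(sig, fs, ez = 1, energy_fraction = 0),
               c(2, 3))
  expect_length(pzFromEnergy(sig, fs, ez = 1, energy_fraction = 1.1), 0)

  expect_error(pzFromEnergy(matrix(0, 0, 0), fs, 1), "empty")
  expect_error(pzFromEnergy(sig, fs, 1, band = c(1, 600)), "Nyquist")
})

test_that("band-pass rejects out-of-band components", {
  fs <- 1000
  t <- seq(0, 2, by = 1 / fs)[-1]
  inband <- sin(2 * pi * 20 * t)
  outband <- 5 * sin(2 * pi * 200 * t)  # strong but outside 1-50 Hz
  pz <- pzFromEnergy(cbind(inband, outband), fs, ez = integer(0),
                     energy_fraction = 0.3)
  expect_equal(pz, 1)
})

test_that("Mann-Whitney exact mode matches brute-force enumeration", {
  # PZ holds the 2 earliest of 10 distinct times
  times <- c(5, 10, 30, 40, 50, 60, 70, 80, 90, 100)
  res <- mannWhitneyPz(times, pz = c(1, 2))
  # exact one-sided p for the extreme ordering: 1 / choose(10, 2)
  expect_equal(res$p, 1 / 45, tolerance = 1e-12)
  expect_equal(res$method, "exact")
  expect_equal(res$U, 0)  # all PZ times precede the rest

  # brute-force enumeration over all assignments for a smaller case
  t2 <- c(12, 7, 25, 3, 18, 40)
  pz2 <- c(2, 4)
  obs <- mannWhitneyPz(t2, pz2)
  # U as the number of (pz, other) pairs with pz > other; the one-sided
  # "pz earlier" p-value is P(U_null <= U_obs)
  u_stat <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  u_obs <- u_stat(t2[pz2], t2[-pz2])
  combos <- utils::combn(6, 2)
  u_null <- apply(combos, 2, function(idx) u_stat(t2[idx], t2[-idx]))
  expect_equal(obs$p, mean(u_null <= u_obs), tolerance = 1e-12)

  # label swap with reversed alternative gives the same evidence
  rev_p <- suppressWarnings(stats::wilcox.test(
    t2[-pz2], t2[pz2], alternative = "greater", exact = TRUE))$p.value
  expect_equal(obs$p, rev_p, tolerance = 1e-12)
})

test_that("Mann-Whitney handles ties, NAs and degenerate groups", {
  # full ties: symmetric null
  res <- mannWhitneyPz(rep(100, 8), pz = 1:3)
  expect_equal(res$p, 0.5)

  # unrecruited excluded by default, or given the worst rank
  times <- c(10, 20, NA, 40, NA, 60)
  a <- mannWhitneyPz(times, pz = c(1, 2))
  expect_equal(a$n_other, 2)
  b <- mannWhitneyPz(times, pz = c(1, 2), unrecruited = "max_rank")
  expect_equal(b$n_other, 4)
  expect_lte(b$p, a$p + 1e-9)  # worst-ranked others only help the PZ

  expect_error(mannWhitneyPz(c(NA, NA, 3), pz = 1:2), "both groups")
})

test_that("recruitment reports carry quartiles, whiskers and hits", {
  res <- structure(list(
    recruit_time = c(100, 200, 300, 400, NA), n_recruited = 4,
    order = c(1, 2, 3, 4), classification = "partial", r_c = 0.02),
    class = "recruitmentResult")
  spec <- ezpzSpec(ez = 1, pz_clin = c(2, 3), pz_seeg = c(4, 5))
  rep_out <- recruitmentReport(res, spec)

  expect_equal(rep_out$time_stats$median, 250)
  expect_equal(rep_out$time_stats$q1, 175)
  expect_equal(rep_out$time_stats$q3, 325)
  # whiskers: extreme observed values within 1.5 IQR of the quartiles
  expect_equal(rep_out$time_stats$whisker_low, 100)
  expect_equal(rep_out$time_stats$whisker_high, 400)

  expect_equal(rep_out$pz_clin$hits, 2L)
  expect_equal(rep_out$pz_clin$fraction, 1)
  expect_equal(rep_out$pz_seeg$hits, 1L)  # area 5 never recruited
  expect_equal(rep_out$pz_seeg$fraction, 0.5)

  # no recruitments: empty report
  res0 <- structure(list(recruit_time = rep(NA_real_, 5),
                         n_recruited = 0, order = integer(0),
                         classification = "none", r_c = 0.02),
                    class = "recruitmentResult")
  rep0 <- recruitmentReport(res0, spec)
  expect_equal(rep0$classification, "none")
  expect_true(is.na(rep0$time_stats$median))
})

test_that("cohort summaries sort by median path to EZ and expose the
           time-path relation", {
  # two fixtures with clearly different path scales
  make_conn <- function(w12) chain_connectome(w12, w12)
  near <- make_conn(1)    # short paths to EZ
  far <- make_conn(0.1)   # ten times longer

  mk_report <- function(times) {
    res <- structure(list(recruit_time = times,
                          n_recruited = sum(!is.na(times)),
                          order = order(times, na.last = NA),
                          classification = "partial", r_c = 0.02),
                     class = "recruitmentResult")
    recruitmentReport(res, ezpzSpec(ez = 1, pz_clin = 2, pz_seeg = 2))
  }
  reports <- list(mk_report(c(NA, 50, 120)), mk_report(c(NA, 500, 1200)))
  cs <- cohortSummary(reports, list(near, far),
                      list(ezpzSpec(1, 2, 2), ezpzSpec(1, 2, 2)),
                      ids = c("near", "far"))
  expect_equal(cs$summary$id, c("near", "far"))
  expect_lt(cs$summary$median_path_to_ez[1],
            cs$summary$median_path_to_ez[2])

  # recruitment time constructed proportional to path length:
  # positive regression slope in the long table
  pr <- cs$per_region
  fit <- stats::lm(time ~ path_to_ez, data = pr)
  expect_gt(stats::coef(fit)[2], 0)
})
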