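test_that("deconvolution subtracts the 546 nm nuisance exactly", {
  tm <- seq(0, 0.05, by = 1e-4)
  pure <- 0.002 * exp(-tm / 0.15)
  drift <- 5e-4 * tm / 0.05
  t520 <- trace(tm, pure + drift, "ecs_520")
  t546 <- trace(tm, drift, "ecs_546")
  d <- deconvolve_ecs(t520, t546)
  expect_equal(d$values, pure, tolerance = 1e-12)
  expect_identical(d$channel, "ecs_corrected")
  # identical traces cancel; zero 546 passes 520 through
  expect_equal(deconvolve_ecs(t520, t520)$values, rep(0, length(tm)))
  z <- trace(tm, rep(0, length(tm)), "ecs_546")
  expect_equal(deconvolve_ecs(t520, z)$values, t520$values)
  # mismatched time bases refuse silently resampling
  t546b <- trace(tm + 5e-5, drift, "ecs_546")
  expect_error(deconvolve_ecs(t520, t546b), "alignment")
  expect_s3_class(deconvolve_ecs(t520, t546b, resample = TRUE), "trace")
})

test_that("flash amplitude reads 140 us after the flash, baseline-free", {
  truth <- wt_truth()
  te <- 0.002
  sim <- simulate_ecs_experiment(truth, "flash_psi_only",
                                 event_time_s = te)
  d <- deconvolve_ecs(sim$trace_520, sim$trace_546)
  amp <- flash_amplitude(d, te)
  expect_equal(amp, sim$truth$amplitude_at_140us, tolerance = 1e-6)
  # constant offsets do not change the amplitude
  shifted <- trace(d$time, d$values + 5, d$channel)
  expect_equal(flash_amplitude(shifted, te), amp, tolerance = 1e-9)
  # flat trace reads zero
  flat <- trace(d$time, rep(1, length(d$time)), "ecs_corrected")
  expect_equal(flash_amplitude(flat, te), 0)
  expect_error(flash_amplitude(d, 0.0599), "coverage")
})

test_that("initial slopes are exact on lines and good on exponentials", {
  tm <- seq(0, 1, by = 1e-3)
  line <- trace(tm, 2 - 0.4 * tm)
  expect_equal(initial_slope(line, 0.5, 0.1, "after"), -0.4,
               tolerance = 1e-12)
  expect_equal(initial_slope(line, 0.5, 0.1, "before"), -0.4,
               tolerance = 1e-12)
  const <- trace(tm, rep(3, length(tm)))
  expect_equal(initial_slope(const, 0.5, 0.1, "after"), 0)
  # exponential decay: window = tau/50 approximates -A/tau within 1 %
  tau <- 0.5; A <- 0.01
  dec <- trace(tm, A * exp(-tm / tau))
  s <- initial_slope(dec, 0, tau / 50, "after")
  expect_equal(s, -A / tau, tolerance = 0.01)
  expect_error(initial_slope(dec, 0, 2e-3, "after"), "resolution")
})

test_that("rates, stoichiometry and CEF fraction are exact arithmetic", {
  cal <- ecs_flash_calibration(0.01)
  expect_equal(photochemical_rate(-0.405, cal), 40.5)
  expect_equal(photochemical_rate(0, cal), 0)
  # linear in slope
  expect_equal(photochemical_rate(-0.2, cal),
               2 * photochemical_rate(-0.1, cal))
  expect_error(ecs_flash_calibration(0), "> 0")

  expect_equal(psii_psi_ratio(2, 1), 1)
  expect_equal(psii_psi_ratio(2.37, 1), 1.37)
  expect_equal(psii_psi_ratio(1, 1), 0)
  expect_error(psii_psi_ratio(0.9, 1), "inconsistency")
  # scale invariance: exact under any positive rescaling
  for (lam in c(1e-6, 0.37, 1, 12, 1e8)) {
    expect_equal(psii_psi_ratio(2.37 * lam, 1 * lam),
                 psii_psi_ratio(2.37, 1), tolerance = 1e-12)
  }

  expect_equal(cef_fraction(10, 40), 25)
  expect_equal(cef_fraction(0, 40), 0)
  expect_error(cef_fraction(41, 40), "inconsistency")
  expect_error(cef_fraction(10, 0), "rate_total")
})

test_that("the noiseless ECS chain recovers generative rates within 2 %", {
  truth <- wt_truth()
  te <- 0.002
  chain <- function(mode) {
    s <- simulate_ecs_experiment(truth, mode, event_time_s = te)
    deconvolve_ecs(s$trace_520, s$trace_546)
  }
  amp_tot <- flash_amplitude(chain("flash_total"), te)
  amp_psi <- flash_amplitude(chain("flash_psi_only"), te)
  r <- psii_psi_ratio(amp_tot, amp_psi)
  expect_equal(r, truth$r_psii_psi, tolerance = 1e-6)
  rate_psi <- photochemical_rate(
    initial_slope(chain("light_on_psi_only"), te, 5e-3, "after"),
    ecs_flash_calibration(amp_psi))
  rate_avg <- photochemical_rate(
    initial_slope(chain("light_on_total"), te, 5e-3, "after"),
    ecs_flash_calibration(amp_tot))
  rate_psii <- (rate_avg * (1 + r) - rate_psi) / r
  s <- simulate_ecs_experiment(truth, "light_on_total")
  expect_equal(rate_psi, s$truth$rate_psi, tolerance = 0.02)
  expect_equal(rate_psii, s$truth$rate_psii, tolerance = 0.02)
  # CEF share from the two off-decays
  rate_total <- photochemical_rate(
    initial_slope(chain("light_off_decay"), te, 5e-3, "after"),
    ecs_flash_calibration(amp_tot))
  rate_cef <- photochemical_rate(
    initial_slope(chain("farred_off_decay"), te, 5e-3, "after"),
    ecs_flash_calibration(amp_tot))
  expect_equal(cef_fraction(rate_cef, rate_total),
               s$truth$cef_fraction, tolerance = 0.02)
})
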