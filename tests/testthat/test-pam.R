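test_that("quenching formulas evaluate exactly", {
  expect_equal(compute_npq(2.0, 1.0), 1.0)
  expect_equal(compute_npq(1.5, 1.5), 0.0)
  expect_equal(compute_npq(2.95, 1.0), 1.95)
  expect_error(compute_npq(2, 0), "fm_prime")

  expect_equal(compute_phi_psii(1.2, 1.2), 0)
  expect_equal(compute_phi_psii(1.2, 0), 1)
  expect_equal(compute_phi_psii(1.2, 0.6), 0.5)
  neg <- compute_phi_psii(1.0, 1.1)
  expect_lt(as.numeric(neg), 0)
  expect_match(attr(neg, "findings"), "exceeds")

  expect_equal(compute_one_minus_ql(1.0, 0.25, 0.25), 0)
  expect_equal(compute_one_minus_ql(1.0, 1.0, 0.25), 1)
  expect_equal(compute_one_minus_ql(1.0, 0.5, 0.25), 2 / 3)
  expect_error(compute_one_minus_ql(1.0, 0.5, 1.0), "degenerate")

  expect_equal(compute_qt(1.0, 1.0), 0)
  expect_equal(compute_qt(1.0, 0.9), 0.1, tolerance = 1e-12)
  expect_error(compute_qt(0, 1), "fm_st1")
})

test_that("landmarks extracted from noiseless traces equal ground truth", {
  truth <- wt_truth()
  prot <- short_lc_protocol()
  sim <- simulate_pam_protocol(truth, prot, noise_sd = 0)
  lm <- extract_landmarks(sim$trace, prot)
  tl <- sim$truth$landmarks
  expect_equal(lm$fm, tl$fm, tolerance = 1e-9)
  expect_equal(lm$f0, tl$f0, tolerance = 1e-9)
  expect_equal(lm$steps$fm_prime, tl$steps$fm_prime, tolerance = 1e-9)
  expect_equal(lm$steps$fs, tl$steps$fs, tolerance = 1e-9)
  expect_equal(lm$steps$f0_prime, tl$steps$f0_prime, tolerance = 1e-9)
  expect_identical(attr(lm, "findings"), character(0))
})

test_that("missing far-red window yields NA f0_prime, not an error", {
  truth <- wt_truth()
  prot2 <- protocol(data.frame(
    start_s = c(0, 10, 10.5, 30.5, 31, 51),
    end_s = c(10, 10.5, 30.5, 31, 51, 51.5),
    kind = c("dark", "saturating_pulse", "actinic", "saturating_pulse",
             "actinic", "saturating_pulse"),
    intensity = c(0, 6000, 100, 6000, 300, 6000)))
  sim <- simulate_pam_protocol(truth, prot2, noise_sd = 0)
  lm <- extract_landmarks(sim$trace, prot2)
  expect_true(all(is.na(lm$steps$f0_prime)))
  lc <- build_light_curve(lm)
  expect_true(all(is.na(lc$one_minus_ql)))
  expect_true(length(attr(lc, "findings")) >= 2L)
  expect_false(any(is.na(lc$npq)))
})

test_that("pulses with too few samples raise a resolution error", {
  truth <- wt_truth()
  prot <- dark_pulse_protocol(pulse_s = 0.5)
  sim <- simulate_pam_protocol(truth, prot, noise_sd = 0, dt_s = 0.3)
  expect_error(extract_landmarks(sim$trace, prot), "resolution")
})

test_that("light curves order rows by intensity and track the simulator", {
  truth <- wt_truth()
  prot <- short_lc_protocol()
  sim <- simulate_pam_protocol(truth, prot, noise_sd = 0)
  lc <- build_light_curve(extract_landmarks(sim$trace, prot))
  expect_identical(nrow(lc), 6L)
  expect_true(!is.unsorted(lc$intensity))
  # NPQ non-decreasing along a monotone hyperbolic light response
  expect_true(all(diff(lc$npq) > -1e-12))
  expect_true(all(lc$phi_psii >= 0 & lc$phi_psii <= 1))
  expect_true(all(lc$one_minus_ql >= 0 & lc$one_minus_ql <= 1))
  # quenched-free truth gives a flat zero NPQ curve
  flat <- wt_truth(npq_max = 0, qz_amp = 0)
  simf <- simulate_pam_protocol(flat, prot, noise_sd = 0)
  lcf <- build_light_curve(extract_landmarks(simf$trace, prot))
  expect_equal(lcf$npq, rep(0, 6L), tolerance = 1e-9)
})

test_that("state-transition simulation and qT close the loop", {
  truth <- wt_truth(qt_amp = 0.05)
  st <- simulate_state_transition(truth)
  expect_equal(compute_qt(st$fm_st1, st$fm_st2), 0.05,
               tolerance = 1e-9)
})

test_that("NPQ kinetics decompose into qE and residual", {
  # monotone rise to 1.95, relaxation to 0.27
  tm <- seq(0, 600, by = 20)
  npq <- ifelse(tm <= 300, 1.95 * (tm / 300), NA)
  relax <- tm > 300
  npq[relax] <- 0.27 + (1.95 - 0.27) * exp(-(tm[relax] - 300) / 30)
  series <- data.frame(time_s = tm, npq = npq)
  d <- decompose_npq_kinetics(series, light_off_time_s = 300,
                              relax_read_time_s = 300)
  expect_equal(d$npq_end_light, 1.95)
  expect_equal(d$qe, 1.95 - d$npq_relaxed)
  expect_equal(d$residual, d$npq_relaxed)
  expect_equal(d$npq_relaxed, 0.27, tolerance = 1e-3)

  flat <- data.frame(time_s = tm, npq = 0)
  dflat <- decompose_npq_kinetics(flat, 300, 300)
  expect_equal(unlist(dflat), c(npq_end_light = 0, npq_relaxed = 0,
                                qe = 0, residual = 0))
  short <- data.frame(time_s = tm[tm <= 200], npq = npq[tm <= 200])
  expect_error(decompose_npq_kinetics(short, 300, 300), "coverage")
  expect_error(decompose_npq_kinetics(series, 300, 500), "coverage")
})

test_that("an end-to-end kinetics run reproduces the generative NPQ", {
  truth <- wt_truth()
  prot <- npq_kinetics_protocol(light_s = 300, dark_s = 300)
  sim <- simulate_pam_protocol(truth, prot, noise_sd = 0)
  series <- npq_time_series(sim$trace, prot)
  light_off <- max(prot$phases$end_s[prot$phases$kind == "actinic"])
  d <- decompose_npq_kinetics(series, light_off, 295)
  # end-of-light NPQ approaches the steady state from below
  expect_gt(d$npq_end_light, 0.9 * npq_steady_state(truth, 1000))
  expect_lt(d$npq_end_light, npq_steady_state(truth, 1000))
  # the residual is the slowly reversible pool, far below peak
  expect_lt(d$residual, 0.3 * d$npq_end_light)
  expect_equal(d$qe, d$npq_end_light - d$npq_relaxed)
})
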