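test_that("PAM simulator reproduces its closed-form quenching model", {
  # dark trace with a single pulse reads Fm exactly
  truth <- wt_truth()
  sim <- simulate_pam_protocol(truth, dark_pulse_protocol(), noise_sd = 0)
  expect_equal(max(sim$trace$values), truth$fm_dark, tolerance = 1e-12)
  expect_equal(sim$truth$landmarks$fm, truth$fm_dark)

  # npq_max = 0 and no slow quenching: every Fm' equals Fm
  flat <- wt_truth(npq_max = 0, qz_amp = 0)
  sim <- simulate_pam_protocol(flat, short_lc_protocol(), noise_sd = 0)
  expect_equal(sim$truth$landmarks$steps$fm_prime,
               rep(flat$fm_dark, 6L), tolerance = 1e-12)

  # with effectively instantaneous induction, the landmark NPQ at any
  # step equals the closed-form steady state at that intensity
  fast <- wt_truth(tau_npq_ind_s = 1e-3, qz_amp = 0)
  prot <- light_curve_protocol(intensities = 850, step_s = 30)
  sim <- simulate_pam_protocol(fast, prot, noise_sd = 0)
  expect_equal(sim$truth$npq,
               npq_steady_state(fast, 850, include_qz = FALSE),
               tolerance = 1e-9)
})

test_that("PAM simulator is deterministic and noise is seed-controlled", {
  truth <- wt_truth()
  prot <- dark_pulse_protocol()
  a <- simulate_pam_protocol(truth, prot, noise_sd = 0.01, seed = 42L)
  b <- simulate_pam_protocol(truth, prot, noise_sd = 0.01, seed = 42L)
  expect_identical(a$trace$values, b$trace$values)
  c <- simulate_pam_protocol(truth, prot, noise_sd = 0.01, seed = 43L)
  expect_false(identical(a$trace$values, c$trace$values))
  expect_error(
    simulate_pam_protocol(truth, protocol(data.frame(
      start_s = 0, end_s = 10, kind = "dark", intensity = 0))),
    "no saturating pulse")
})

test_that("ECS simulator obeys its closed forms", {
  truth <- wt_truth()
  te <- 0.002
  psi <- simulate_ecs_experiment(truth, "flash_psi_only",
                                 event_time_s = te)
  tot <- simulate_ecs_experiment(truth, "flash_total", event_time_s = te)
  # noiseless PSI-only amplitude 140 us after the flash
  expect_equal(psi$truth$amplitude_at_140us,
               truth$ecs_amp_one_charge *
                 exp(-140e-6 / truth$tau_atpase_s), tolerance = 1e-12)
  # total/psi-only amplitude ratio = 1 + r by construction
  expect_equal(tot$truth$amplitude_flash / psi$truth$amplitude_flash,
               1 + truth$r_psii_psi, tolerance = 1e-12)
  # 520 - 546 recovers the pure signal: at the sample right after the
  # flash the pure signal is the flash amplitude
  d <- deconvolve_ecs(tot$trace_520, tot$trace_546)
  i <- which(d$time >= te)[1L]
  expect_equal(d$values[i],
               tot$truth$amplitude_flash *
                 exp(-(d$time[i] - te) / truth$tau_atpase_s),
               tolerance = 1e-12)
  expect_error(simulate_ecs_experiment(truth, "nonsense"), "arg")
})

test_that("DCMU induction has the analytic complementary area", {
  truth <- wt_truth()
  sim <- simulate_dcmu_induction(truth, intensity = 80)
  k <- sim$truth$k
  v <- (sim$trace$values - truth$f0_dark) /
    (truth$fm_dark - truth$f0_dark)
  area <- pracma::trapz(sim$trace$time, 1 - v)
  expect_equal(area, 1 / k, tolerance = 1e-3)
  # plateau reaches fm
  expect_equal(max(sim$trace$values), truth$fm_dark, tolerance = 1e-4)
  # doubling the cross-section halves the area
  sim2 <- simulate_dcmu_induction(wt_truth(sigma_psii = 2), 80)
  v2 <- (sim2$trace$values - truth$f0_dark) /
    (truth$fm_dark - truth$f0_dark)
  expect_equal(pracma::trapz(sim2$trace$time, 1 - v2), area / 2,
               tolerance = 1e-3)
  expect_error(simulate_dcmu_induction(truth, intensity = 0), "> 0")
})

test_that("Vj series follows its exponential reoxidation law", {
  truth <- wt_truth()
  iv <- c(0.05, 4, 8, 12, 16, 20, 24)
  s <- simulate_vj_series(truth, iv, mode = "dark")
  tr <- attr(s, "truth")
  expect_equal(s$vj[1L],
               tr$v_inf + (tr$v0 - tr$v_inf) * exp(-0.05 / tr$tau),
               tolerance = 1e-12)
  # large intervals reach the reoxidized plateau
  s2 <- simulate_vj_series(truth, c(1, 50 * tr$tau), mode = "dark")
  expect_equal(s2$vj[2L], tr$v_inf, tolerance = 1e-3)
  # a nonlinear fit on the 7 noiseless points recovers tau
  fit <- minpack.lm::nlsLM(vj ~ vi + (v0 - vi) * exp(-interval_s / tau),
                           data = s,
                           start = list(vi = 0.2, v0 = 0.6, tau = 4))
  expect_equal(unname(coef(fit)[["tau"]]), tr$tau, tolerance = 1e-6)
  expect_error(simulate_vj_series(truth, numeric(0)), "empty interval")
})

test_that("TCSPC simulator is exact in total counts and seed-stable", {
  a <- c(0.6, 0.3, 0.1)
  tau <- c(0.1, 0.9, 2.0)
  h1 <- simulate_flim_decay(a, tau, n_photons = 1e5, seed = 5L)
  h2 <- simulate_flim_decay(a, tau, n_photons = 1e5, seed = 5L)
  expect_identical(h1$values, h2$values)
  expect_equal(sum(h1$values), 1e5)
  expect_true(all(h1$values == round(h1$values)))
  expect_error(simulate_flim_decay(c(0.6, 0.3, 0.2), tau), "sum to 1")

  # pure single exponential: weighted log-linear regression on the
  # noiseless histogram recovers the lifetime to well under 1 %
  h <- simulate_flim_decay(c(1, 0, 0), tau, n_photons = 1e6,
                           sample = FALSE)
  keep <- h$values > 0
  fit <- stats::lm(log(h$values[keep]) ~ h$time[keep],
                   weights = h$values[keep])
  expect_equal(-1 / unname(coef(fit)[2L]), 0.1e-9, tolerance = 0.01)
})

test_that("grana simulator matches its moments and supports >= 1 layer", {
  g <- simulate_grana_dataset(1e5, c(WT = 4.57, mut = 3.75),
                              c(WT = 500, mut = 356), width_sd = 80,
                              seed = 3L)
  expect_true(all(g$n_layers >= 1L))
  expect_true(all(g$width_nm > 0))
  expect_equal(mean(g$n_layers[g$genotype == "WT"]), 4.57,
               tolerance = 0.02 / 4.57)
  expect_equal(mean(g$n_layers[g$genotype == "mut"]), 3.75,
               tolerance = 0.02 / 3.75)
  g2 <- simulate_grana_dataset(1e3, c(WT = 4.57, mut = 3.75),
                               c(WT = 500, mut = 356), seed = 3L)
  g3 <- simulate_grana_dataset(1e3, c(WT = 4.57, mut = 3.75),
                               c(WT = 500, mut = 356), seed = 3L)
  expect_identical(g2$n_layers, g3$n_layers)
  expect_error(simulate_grana_dataset(10, c(WT = 0.9), c(WT = 500)),
               ">= 1")
})

test_that("pigment extract simulation inverts the quantification", {
  ab <- simulate_pigment_extract(10, 4)
  back <- chl_from_absorbance(ab[["a663_6"]], ab[["a646_6"]])
  expect_equal(unname(back), c(10, 4), tolerance = 1e-9)
  expect_equal(unname(simulate_pigment_extract(0, 0)), c(0, 0))
  # chlorophyll-b-free extract: absorbances solve the a-only system
  ab_a <- simulate_pigment_extract(10, 0)
  expect_equal(unname(chl_from_absorbance(ab_a[["a663_6"]],
                                          ab_a[["a646_6"]])[2L]), 0,
               tolerance = 1e-9)
  expect_error(simulate_pigment_extract(-1, 0), ">= 0")
})
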