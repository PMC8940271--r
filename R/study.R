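# End-to-end orchestration: simulate every modality for named parameter
# sets, run the full derivation chain, and compare the sets.

#' Default six-step quenching light-curve protocol
#'
#' Dark adaptation with a saturating pulse, then increasing actinic
#' steps (40, 95, 150, 380, 620, 850 umol photons m-2 s-1 by default),
#' each ending in a saturating pulse followed by a 2 s far-red window
#' that reads `F0'`.
#'
#' @param intensities Actinic step intensities.
#' @param step_s Actinic step length, seconds.
#' @param dark_s Initial dark adaptation, seconds.
#' @param pulse_s Saturating pulse length, seconds.
#' @param farred_s Far-red window length, seconds.
#' @return A [protocol()].
#' @export
light_curve_protocol <- function(intensities = c(40, 95, 150, 380, 620,
                                                 850),
                                 step_s = 300, dark_s = 60,
                                 pulse_s = 0.5, farred_s = 2) {
  rows <- list(data.frame(start_s = 0, end_s = dark_s, kind = "dark",
                          intensity = 0),
               data.frame(start_s = dark_s, end_s = dark_s + pulse_s,
                          kind = "saturating_pulse", intensity = 6000))
  t <- dark_s + pulse_s
  for (i in intensities) {
    rows <- c(rows, list(
      data.frame(start_s = t, end_s = t + step_s, kind = "actinic",
                 intensity = i),
      data.frame(start_s = t + step_s, end_s = t + step_s + pulse_s,
                 kind = "saturating_pulse", intensity = 6000),
      data.frame(start_s = t + step_s + pulse_s,
                 end_s = t + step_s + pulse_s + farred_s,
                 kind = "far_red", intensity = 20)))
    t <- t + step_s + pulse_s + farred_s
  }
  protocol(do.call(rbind, rows))
}

#' NPQ induction/relaxation protocol
#'
#' Dark adaptation and reference pulse, a single actinic phase broken
#' into pulse-terminated segments (one saturating pulse every
#' `pulse_every_s`), then a dark relaxation phase probed the same way.
#'
#' @param light_s,dark_s Length of the induction and relaxation phases.
#' @param intensity Actinic intensity, umol photons m-2 s-1.
#' @param pulse_every_s Probe pulse spacing, seconds.
#' @param pulse_s Pulse length, seconds.
#' @param dark_adapt_s Initial dark adaptation, seconds.
#' @return A [protocol()].
#' @export
npq_kinetics_protocol <- function(light_s = 600, dark_s = 600,
                                  intensity = 1000,
                                  pulse_every_s = 20, pulse_s = 0.5,
                                  dark_adapt_s = 60) {
  rows <- list(data.frame(start_s = 0, end_s = dark_adapt_s,
                          kind = "dark", intensity = 0),
               data.frame(start_s = dark_adapt_s,
                          end_s = dark_adapt_s + pulse_s,
                          kind = "saturating_pulse", intensity = 6000))
  t <- dark_adapt_s + pulse_s
  add_segments <- function(total_s, kind, inten, t) {
    n <- floor(total_s / pulse_every_s)
    for (i in seq_len(n)) {
      rows <<- c(rows, list(
        data.frame(start_s = t, end_s = t + pulse_every_s - pulse_s,
                   kind = kind, intensity = inten),
        data.frame(start_s = t + pulse_every_s - pulse_s,
                   end_s = t + pulse_every_s,
                   kind = "saturating_pulse", intensity = 6000)))
      t <- t + pulse_every_s
    }
    t
  }
  t <- add_segments(light_s, "actinic", intensity, t)
  t <- add_segments(dark_s, "dark", 0, t)
  protocol(do.call(rbind, rows))
}

#' Default wild-type-like ground truth
#'
#' @param ... Overrides passed to [simulation_ground_truth()].
#' @return A [simulation_ground_truth()].
#' @export
wt_ground_truth <- function(...) simulation_ground_truth(...)

#' Default mutant-like ground truth
#'
#' An antenna-reduced variant of [wt_ground_truth()]: PSII cross-section
#' down 25 %, PSII/PSI reaction-center ratio up 25 %, maximal NPQ down
#' 30 %, state transitions nearly abolished, faster far-red
#' plastoquinone reoxidation, and a larger fast TCSPC amplitude.
#'
#' @param ... Further overrides passed to [simulation_ground_truth()].
#' @return A [simulation_ground_truth()].
#' @export
mutant_ground_truth <- function(...) {
  wt <- wt_ground_truth()
  overrides <- list(sigma_psii = wt$sigma_psii * 0.75,
                    r_psii_psi = wt$r_psii_psi * 1.25,
                    npq_max = wt$npq_max * 0.70,
                    qt_amp = 0.01,
                    tau_pq_ox_farred_s = 0.5,
                    flim_amps = c(0.76, 0.16, 0.08))
  overrides <- utils::modifyList(overrides, list(...))
  do.call(simulation_ground_truth, overrides)
}

#' Assemble a study configuration
#'
#' @param parameter_sets Named list of [simulation_ground_truth()]
#'   objects (default: wild-type-like and mutant-like).
#' @param seed Master seed; per-set seeds are derived from it.
#' @param noise_sd PAM noise level, a.u.
#' @param ecs_noise_sd Relative ECS noise.
#' @param pam_dt_s PAM sampling interval, seconds.
#' @param lc_protocol Light-curve [protocol()].
#' @param kin_protocol NPQ-kinetics [protocol()].
#' @param flim_photons TCSPC photons per decay.
#' @param grana_n Grana measured per genotype.
#' @return A list of class `study_config`.
#' @export
study_config <- function(parameter_sets = list(
                           WT = wt_ground_truth(),
                           mutant = mutant_ground_truth()),
                         seed = 1L, noise_sd = 0.005,
                         ecs_noise_sd = 0.002, pam_dt_s = 0.02,
                         lc_protocol = light_curve_protocol(step_s = 60),
                         kin_protocol = npq_kinetics_protocol(
                           light_s = 300, dark_s = 300),
                         flim_photons = 1e6, grana_n = 200L) {
  stopifnot(length(names(parameter_sets)) == length(parameter_sets))
  structure(list(parameter_sets = parameter_sets, seed = as.integer(seed),
                 noise_sd = noise_sd, ecs_noise_sd = ecs_noise_sd,
                 pam_dt_s = pam_dt_s, lc_protocol = lc_protocol,
                 kin_protocol = kin_protocol,
                 flim_photons = flim_photons, grana_n = grana_n),
            class = "study_config")
}

# Full derivation chain for one parameter set.
.run_one_set <- function(truth, config, seed) {
  res <- list()
  record_error <- function(stage, e) {
    res$errors[[stage]] <<- conditionMessage(e)
  }

  # PAM light curve
  tryCatch({
    sim <- simulate_pam_protocol(truth, config$lc_protocol,
                                 noise_sd = config$noise_sd,
                                 seed = seed, dt_s = config$pam_dt_s)
    lmks <- extract_landmarks(sim$trace, config$lc_protocol)
    res$light_curve <- build_light_curve(lmks)
    res$landmarks <- lmks
  }, error = function(e) record_error("light_curve", e))

  # NPQ induction/relaxation kinetics
  tryCatch({
    sim <- simulate_pam_protocol(truth, config$kin_protocol,
                                 noise_sd = config$noise_sd,
                                 seed = seed + 1L,
                                 dt_s = config$pam_dt_s)
    series <- npq_time_series(sim$trace, config$kin_protocol)
    ph <- config$kin_protocol$phases
    light_off <- max(ph$end_s[ph$kind == "actinic"])
    relax_read <- min(300, max(series$time_s) - light_off)
    res$npq_kinetics <- decompose_npq_kinetics(series, light_off,
                                               relax_read)
  }, error = function(e) record_error("npq_kinetics", e))

  # state transitions
  tryCatch({
    st <- simulate_state_transition(truth)
    res$qt <- compute_qt(st$fm_st1, st$fm_st2)
  }, error = function(e) record_error("qt", e))

  # ECS chain: flashes -> stoichiometry; onsets -> per-PS rates;
  # off-decays -> total flow and CEF fraction
  tryCatch({
    ecs <- function(mode, s_off) {
      sim <- simulate_ecs_experiment(truth, mode,
                                     noise_sd = config$ecs_noise_sd,
                                     seed = seed + s_off)
      deconvolve_ecs(sim$trace_520, sim$trace_546)
    }
    te <- 0.002
    amp_tot <- flash_amplitude(ecs("flash_total", 2L), te)
    amp_psi <- flash_amplitude(ecs("flash_psi_only", 3L), te)
    r <- psii_psi_ratio(amp_tot, amp_psi)
    cal_tot <- ecs_flash_calibration(amp_tot)
    cal_psi <- ecs_flash_calibration(amp_psi)
    rate_psi <- photochemical_rate(
      initial_slope(ecs("light_on_psi_only", 4L), te, 5e-3, "after"),
      cal_psi)
    rate_avg <- photochemical_rate(
      initial_slope(ecs("light_on_total", 5L), te, 5e-3, "after"),
      cal_tot)
    rate_psii <- (rate_avg * (1 + r) - rate_psi) / r
    rate_total <- photochemical_rate(
      initial_slope(ecs("light_off_decay", 6L), te, 5e-3, "after"),
      cal_tot)
    rate_cef <- photochemical_rate(
      initial_slope(ecs("farred_off_decay", 7L), te, 5e-3, "after"),
      cal_tot)
    res$photochemistry <- list(
      rate_psii = rate_psii, rate_psi = rate_psi, r_psii_psi = r,
      cef_fraction = cef_fraction(min(rate_cef, rate_total), rate_total),
      chl_fraction_psi = chl_fraction_from_rates(rate_psi, rate_psii, r))
  }, error = function(e) record_error("photochemistry", e))

  # FLIM -> PSI chlorophyll share
  tryCatch({
    decay <- simulate_flim_decay(truth$flim_amps,
                                 truth$flim_lifetimes_ns,
                                 n_photons = config$flim_photons,
                                 seed = seed + 8L)
    fit <- fit_flim_decay(decay, truth$flim_lifetimes_ns)
    res$flim <- list(amps = fit$amps,
                     chl_fraction_psi =
                       psi_fraction_from_flim(fit$amps[1L]))
  }, error = function(e) record_error("flim", e))

  # Vj reoxidation trends
  tryCatch({
    dark <- simulate_vj_series(truth, c(0.05, 4, 8, 12, 16, 20, 24),
                               mode = "dark", seed = seed + 9L)
    fr <- simulate_vj_series(truth, c(0.05, 0.1, 0.2, 0.4, 0.8, 1.6),
                             mode = "far_red", seed = seed + 10L)
    res$vj <- list(slope_dark = fit_vj_trend(dark)$slope,
                   slope_farred = fit_vj_trend(fr)$slope)
  }, error = function(e) record_error("vj", e))

  # DCMU functional antenna size
  tryCatch({
    sim <- simulate_dcmu_induction(truth, intensity = 80,
                                   seed = seed + 11L)
    res$antenna_rate <- functional_antenna_dcmu(sim$trace,
                                                sim$truth$f0,
                                                sim$truth$fm)
  }, error = function(e) record_error("antenna", e))
  res
}

#' Run the full synthetic study
#'
#' For every named parameter set in the configuration: simulate all
#' modalities, run the complete analysis chain (light curve, NPQ
#' kinetics, qT, ECS photochemistry and chlorophyll repartition, FLIM,
#' Vj trends, DCMU antenna size), then fit the grana morphometry models
#' on a two-genotype synthetic dataset and tabulate the headline
#' contrasts between the first two parameter sets. Fully deterministic
#' given the configuration seed; any stage error is recorded per stage
#' and the bundle is still returned.
#'
#' @param config A [study_config()].
#' @return A list of class `study_report`: per-set results under
#'   `sets`, `morphometry`, and a `comparison` data.frame.
#' @export
run_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  sets <- names(config$parameter_sets)
  out <- list(sets = list())
  for (i in seq_along(sets)) {
    out$sets[[sets[i]]] <- .run_one_set(config$parameter_sets[[i]],
                                        config,
                                        config$seed + 100L * i)
  }

  # grana morphometry across the first two sets
  if (length(sets) >= 2L) {
    grana <- simulate_grana_dataset(
      n_per_group = config$grana_n,
      mean_stacks_by_group = stats::setNames(c(4.57, 3.75), sets[1:2]),
      width_mean_by_group = stats::setNames(c(500, 356), sets[1:2]),
      width_sd = 80, seed = config$seed + 1000L)
    out$morphometry <- list(
      data = grana,
      stack_model = fit_stack_count_model(grana),
      width_model = fit_width_model(grana),
      width_comparison = compare_groups(grana$width_nm, grana$genotype))

    a <- out$sets[[1L]]; b <- out$sets[[2L]]
    m <- function(x, ...) if (is.null(x)) NA_real_ else mean(x, ...)
    v <- function(x) if (is.null(x)) NA_real_ else x
    cmp <- data.frame(
      quantity = c("mean_npq", "mean_phi_psii", "mean_one_minus_ql",
                   "qt", "slope_farred_vj", "chl_fraction_psi_rates",
                   "chl_fraction_psi_flim", "antenna_rate"),
      set1 = c(m(a$light_curve$npq),
               m(a$light_curve$phi_psii),
               m(a$light_curve$one_minus_ql, na.rm = TRUE),
               v(a$qt), v(a$vj$slope_farred),
               v(a$photochemistry$chl_fraction_psi),
               v(a$flim$chl_fraction_psi), v(a$antenna_rate)),
      set2 = c(m(b$light_curve$npq),
               m(b$light_curve$phi_psii),
               m(b$light_curve$one_minus_ql, na.rm = TRUE),
               v(b$qt), v(b$vj$slope_farred),
               v(b$photochemistry$chl_fraction_psi),
               v(b$flim$chl_fraction_psi), v(b$antenna_rate)),
      stringsAsFactors = FALSE)
    names(cmp)[2:3] <- sets[1:2]
    out$comparison <- cmp
  }
  structure(out, class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d parameter sets\n", length(x$sets)))
  if (!is.null(x$comparison)) print(x$comparison)
  invisible(x)
}
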