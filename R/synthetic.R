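# Synthetic instrument traces with known ground truth.
#
# Every simulator is a pure function of (truth, protocol/arguments, seed):
# the same inputs give bit-identical outputs, and each returns the exact
# noiseless quantities needed for downstream parameter-recovery tests.

# Evaluate code with a locally seeded RNG, restoring the caller's stream.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Unit constant linking relative cross-section x intensity to a rate
# (1/s per (umol photons m-2 s-1)); only ratios matter downstream.
.KAPPA <- 1
# e- s-1 PS-1 per unit (sigma x intensity); 0.25 puts a unit-cross-section
# photosystem at 20 e- s-1 under 80 umol photons m-2 s-1.
.KAPPA_E <- 0.25
# Dark/constitutive PSII reacceptor capacity in sigma x intensity units;
# keeps the closed-center fraction light-dependent.
.KOX_DARK <- 5
# Fraction of the actinic phase used for the steady-state Fs window.
.FS_WINDOW_FRAC <- 0.05

#' Generative parameters for the synthetic phenotyping experiments
#'
#' Bundles every parameter the simulators need: relative absorption
#' cross-sections of the two photosystems, reaction-center stoichiometry,
#' dark-adapted fluorescence landmarks, the steady-state NPQ light
#' response (hyperbolic in intensity) and its induction/relaxation time
#' constants, a slowly reversible (zeaxanthin-like) quenching component,
#' the state-transition amplitude, the ECS single-charge amplitude and
#' ATPase decay constant, plastoquinone reoxidation time constants, and
#' the three fixed-lifetime fluorescence decay amplitudes.
#'
#' Defaults describe a wild-type-like Arabidopsis leaf: PSI turning over
#' twice as fast as PSII per center under the same limiting light
#' (`sigma_psi/sigma_psii = 2`), a PSII/PSI center ratio of 1.37, an
#' Fv/Fm of 0.8, a maximal NPQ of 2.2 with half-saturation at
#' 250 umol photons m-2 s-1, and TCSPC amplitudes dominated by the
#' ~100 ps PSI component.
#'
#' @param sigma_psii,sigma_psi Relative absorption cross-sections
#'   (dimensionless, wild-type PSII = 1).
#' @param r_psii_psi PSII/PSI reaction-center ratio (> 0).
#' @param fm_dark,f0_dark Dark-adapted maximal and minimal fluorescence
#'   (a.u., `f0_dark < fm_dark`).
#' @param npq_max,npq_i50,npq_hill Steady-state NPQ light response
#'   `npq_max * I^h / (i50^h + I^h)`.
#' @param tau_npq_ind_s,tau_npq_rel_s NPQ induction (light) and
#'   relaxation (dark) time constants, seconds.
#' @param qz_amp,tau_qz_s Slowly reversible quenching amplitude and its
#'   induction time constant, seconds.
#' @param qt_amp State-transition amplitude (fractional Fm drop).
#' @param ecs_amp_one_charge ECS amplitude (-dI/I) per single charge
#'   separation per photosystem-pool unit.
#' @param tau_atpase_s ECS (ATP-synthase) decay time constant, seconds.
#' @param tau_pq_ox_dark_s,tau_pq_ox_farred_s Plastoquinone reoxidation
#'   time constants in darkness and under far-red light, seconds.
#' @param flim_amps Length-3 non-negative amplitudes summing to 1.
#' @param flim_lifetimes_ns Length-3 lifetimes, nanoseconds.
#' @param seed Integer default seed for simulators.
#' @return An object of class `simulation_ground_truth` (a named list).
#' @export
simulation_ground_truth <- function(sigma_psii = 1.0,
                                    sigma_psi = 2.0,
                                    r_psii_psi = 1.37,
                                    fm_dark = 3.0,
                                    f0_dark = 0.6,
                                    npq_max = 2.2,
                                    npq_i50 = 250,
                                    npq_hill = 1.5,
                                    tau_npq_ind_s = 60,
                                    tau_npq_rel_s = 90,
                                    qz_amp = 0.3,
                                    tau_qz_s = 300,
                                    qt_amp = 0.05,
                                    ecs_amp_one_charge = 1e-3,
                                    tau_atpase_s = 0.15,
                                    tau_pq_ox_dark_s = 6,
                                    tau_pq_ox_farred_s = 0.8,
                                    flim_amps = c(0.6885, 0.2115, 0.1),
                                    flim_lifetimes_ns = c(0.1, 0.9, 2.0),
                                    seed = 1L) {
  truth <- list(sigma_psii = sigma_psii, sigma_psi = sigma_psi,
                r_psii_psi = r_psii_psi, fm_dark = fm_dark,
                f0_dark = f0_dark, npq_max = npq_max, npq_i50 = npq_i50,
                npq_hill = npq_hill, tau_npq_ind_s = tau_npq_ind_s,
                tau_npq_rel_s = tau_npq_rel_s, qz_amp = qz_amp,
                tau_qz_s = tau_qz_s, qt_amp = qt_amp,
                ecs_amp_one_charge = ecs_amp_one_charge,
                tau_atpase_s = tau_atpase_s,
                tau_pq_ox_dark_s = tau_pq_ox_dark_s,
                tau_pq_ox_farred_s = tau_pq_ox_farred_s,
                flim_amps = flim_amps,
                flim_lifetimes_ns = flim_lifetimes_ns,
                seed = as.integer(seed))
  pos <- c("sigma_psii", "sigma_psi", "r_psii_psi", "fm_dark", "f0_dark",
           "tau_npq_ind_s", "tau_npq_rel_s", "tau_qz_s",
           "ecs_amp_one_charge", "tau_atpase_s", "tau_pq_ox_dark_s",
           "tau_pq_ox_farred_s")
  for (nm in pos) {
    if (!is.numeric(truth[[nm]]) || truth[[nm]] <= 0) {
      stop("ground truth: '", nm, "' must be > 0", call. = FALSE)
    }
  }
  if (truth$f0_dark >= truth$fm_dark) {
    stop("ground truth: f0_dark must be < fm_dark", call. = FALSE)
  }
  if (truth$npq_max < 0 || truth$qz_amp < 0 || truth$qt_amp < 0) {
    stop("ground truth: quenching amplitudes must be >= 0", call. = FALSE)
  }
  if (length(flim_amps) != 3L || any(flim_amps < 0) ||
      abs(sum(flim_amps) - 1) > 1e-9) {
    stop("ground truth: flim_amps must be 3 non-negative values summing ",
         "to 1", call. = FALSE)
  }
  if (length(flim_lifetimes_ns) != 3L || any(flim_lifetimes_ns <= 0)) {
    stop("ground truth: flim_lifetimes_ns must be 3 positive values",
         call. = FALSE)
  }
  structure(truth, class = "simulation_ground_truth")
}

#' Steady-state NPQ light response
#'
#' `NPQ_ss(I) = npq_max * I^h / (i50^h + I^h)` plus the slowly reversible
#' component at its steady amplitude when `include_qz` is `TRUE`.
#'
#' @param truth A [simulation_ground_truth()].
#' @param intensity Actinic intensity, umol photons m-2 s-1.
#' @param include_qz Include the slowly reversible component?
#' @return Steady-state NPQ (dimensionless).
#' @export
npq_steady_state <- function(truth, intensity, include_qz = TRUE) {
  i <- pmax(intensity, 0)
  fast <- truth$npq_max * i^truth$npq_hill /
    (truth$npq_i50^truth$npq_hill + i^truth$npq_hill)
  fast + if (include_qz) ifelse(i > 0, truth$qz_amp, 0) else 0
}

# Fraction of closed PSII centers under actinic intensity I (lake model):
# excitation sigma_psii*I against reoxidation by PSI pull plus a
# constitutive dark capacity.
.closed_fraction <- function(truth, intensity) {
  if (intensity <= 0) return(0)
  exc <- truth$sigma_psii * intensity
  kox <- truth$sigma_psi * intensity / truth$r_psii_psi + .KOX_DARK
  exc / (exc + kox)
}

# Oxborough-Baker estimate of the light/far-red minimal fluorescence:
# F0' = F0 / (Fv/Fm + F0/Fm').
.f0_prime_ob <- function(f0, fm, fm_prime) {
  f0 / (1 - f0 / fm + f0 / fm_prime)
}

#' Simulate a PAM fluorescence protocol
#'
#' Generates the fluorescence trace a PAM fluorometer would record under
#' the given light protocol, together with the exact noiseless
#' landmarks. Within each phase, total NPQ is the sum of a fast (qE-like)
#' component relaxing first-order toward `npq_steady_state()` (time
#' constant `tau_npq_ind_s` in light, `tau_npq_rel_s` in dark/far-red)
#' and a slowly reversible component; `Fm'(t) = fm_dark / (1 + NPQ(t))`;
#' the closed-center fraction follows a lake model; `F0'` follows the
#' Oxborough-Baker relation; steady-state fluorescence is
#' `Fs = F0' + C (Fm' - F0')`. Saturating pulses are treated as
#' non-actinic probes that read `Fm'` without advancing the quenching
#' state. Gaussian noise of standard deviation `noise_sd` is added
#' pointwise.
#'
#' @param truth A [simulation_ground_truth()].
#' @param prot A [protocol()] containing at least one saturating pulse;
#'   the first pulse must sit in darkness.
#' @param noise_sd Additive Gaussian noise, a.u. (>= 0).
#' @param seed Integer seed (defaults to `truth$seed`).
#' @param dt_s Sampling interval of the generated trace, seconds.
#' @return A list with elements `trace` (a fluorescence [trace()]) and
#'   `truth`, itself a list holding the noiseless
#'   [fluorescence_landmarks()] plus per-step closed-form `npq`,
#'   `phi_psii` and `one_minus_ql`.
#' @export
simulate_pam_protocol <- function(truth, prot, noise_sd = 0,
                                  seed = truth$seed, dt_s = 0.02) {
  stopifnot(inherits(truth, "simulation_ground_truth"),
            inherits(prot, "protocol"))
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  ph <- prot$phases
  if (!any(ph$kind == "saturating_pulse")) {
    stop("configuration error: protocol has no saturating pulse",
         call. = FALSE)
  }
  t0 <- min(ph$start_s); t1 <- max(ph$end_s)
  tm <- seq(t0, t1, by = dt_s)
  if (tm[length(tm)] >= t1) tm <- tm[-length(tm)]
  f <- numeric(length(tm))

  fm0 <- truth$fm_dark; f00 <- truth$f0_dark
  nf <- 0; nz <- 0  # quenching state at the current phase start
  pulse_rows <- list()
  phase_values <- vector("list", nrow(ph))
  for (p in seq_len(nrow(ph))) {
    idx <- which(tm >= ph$start_s[p] - 1e-12 & tm < ph$end_s[p] - 1e-12)
    kind <- ph$kind[p]; inten <- ph$intensity[p]
    dt_rel <- tm[idx] - ph$start_s[p]
    dur <- ph$end_s[p] - ph$start_s[p]
    if (kind == "actinic") {
      nf_tgt <- npq_steady_state(truth, inten, include_qz = FALSE)
      nz_tgt <- truth$qz_amp
      tau_f <- truth$tau_npq_ind_s; tau_z <- truth$tau_qz_s
    } else if (kind %in% c("dark", "far_red")) {
      nf_tgt <- 0; nz_tgt <- 0
      tau_f <- truth$tau_npq_rel_s; tau_z <- 5 * truth$tau_qz_s
    } else {            # saturating pulse / flash: probe, state frozen
      nf_tgt <- nf; nz_tgt <- nz
      tau_f <- Inf; tau_z <- Inf
    }
    nf_t <- nf_tgt + (nf - nf_tgt) * exp(-dt_rel / tau_f)
    nz_t <- nz_tgt + (nz - nz_tgt) * exp(-dt_rel / tau_z)
    npq_t <- nf_t + nz_t
    fm_p <- fm0 / (1 + npq_t)
    f0_p <- .f0_prime_ob(f00, fm0, fm_p)
    vals <- switch(kind,
      actinic = {
        # lake model: steady-state Fs such that the open-center fraction
        # (1 - C) equals qL = ((Fm'-Fs)/(Fm'-F0')) * (F0'/Fs)
        cc <- .closed_fraction(truth, inten)
        fm_p * f0_p / (f0_p + (1 - cc) * (fm_p - f0_p))
      },
      saturating_pulse = fm_p,
      laser_flash = fm_p,
      f0_p)  # dark and far_red sit at the (oxidized) minimal level
    f[idx] <- vals
    phase_values[[p]] <- list(idx = idx, values = vals)
    if (kind == "saturating_pulse") {
      pulse_rows[[length(pulse_rows) + 1L]] <-
        list(phase = p, fm_prime = fm0 / (1 + nf + nz))
    }
    # advance state to the end of the phase
    nf <- nf_tgt + (nf - nf_tgt) * exp(-dur / tau_f)
    nz <- nz_tgt + (nz - nz_tgt) * exp(-dur / tau_z)
  }

  # exact noiseless landmarks, mirroring the extraction conventions
  first_pulse <- pulse_rows[[1L]]
  fp <- first_pulse$phase
  pre_dark <- which(ph$kind == "dark" & ph$end_s <= ph$start_s[fp] + 1e-12)
  f0_true <- if (length(pre_dark) > 0L) {
    stats::median(unlist(lapply(pre_dark, function(p)
      phase_values[[p]]$values)))
  } else f00
  steps <- NULL
  if (length(pulse_rows) > 1L) {
    rows <- lapply(pulse_rows[-1L], function(pr) {
      p <- pr$phase
      prev <- max(which(ph$end_s <= ph$start_s[p] + 1e-12 &
                          !(ph$kind %in% c("saturating_pulse",
                                           "laser_flash"))))
      w0 <- ph$end_s[prev] -
        .FS_WINDOW_FRAC * (ph$end_s[prev] - ph$start_s[prev])
      pv <- phase_values[[prev]]
      sel <- tm[pv$idx] >= w0 - 1e-12
      fs_true <- mean(pv$values[sel])
      nxt <- which(ph$start_s >= ph$end_s[p] - 1e-12 &
                     ph$kind == "far_red")
      f0p_true <- if (length(nxt) > 0L) {
        min(phase_values[[nxt[1L]]]$values)
      } else NA_real_
      data.frame(intensity = ph$intensity[prev], fs = fs_true,
                 fm_prime = pr$fm_prime, f0_prime = f0p_true)
    })
    steps <- do.call(rbind, rows)
  }
  lm_true <- fluorescence_landmarks(fm = first_pulse$fm_prime,
                                    f0 = f0_true, steps = steps)
  truth_out <- list(landmarks = lm_true)
  if (!is.null(steps)) {
    truth_out$npq <- (lm_true$fm - steps$fm_prime) / steps$fm_prime
    truth_out$phi_psii <- (steps$fm_prime - steps$fs) / steps$fm_prime
    truth_out$one_minus_ql <- 1 -
      ((steps$fm_prime - steps$fs) / (steps$fm_prime - steps$f0_prime)) *
      (steps$f0_prime / steps$fs)
  }
  if (noise_sd > 0) {
    f <- .with_seed(seed, f + stats::rnorm(length(f), 0, noise_sd))
  }
  list(trace = trace(tm, f, channel = "fluorescence",
                     meta = list(simulated = TRUE, noise_sd = noise_sd)),
       truth = truth_out)
}

#' Simulate a state-transition Fm pair
#'
#' Maximal fluorescence at the end of a State 1 phase and at the end of a
#' State 2 phase, where the state transition quenches Fm by the fraction
#' `qt_amp` as mobile antenna undocks from PSII.
#'
#' @param truth A [simulation_ground_truth()].
#' @param npq_background Residual NPQ present in both states (default 0).
#' @return List with `fm_st1` and `fm_st2`.
#' @export
simulate_state_transition <- function(truth, npq_background = 0) {
  fm_st1 <- truth$fm_dark / (1 + npq_background)
  list(fm_st1 = fm_st1, fm_st2 = fm_st1 * (1 - truth$qt_amp))
}

#' Simulate a dual-wavelength ECS experiment
#'
#' Generates the 520 nm and 546 nm traces of a single ECS measurement.
#' Flash modes produce a step of amplitude `ecs_amp_one_charge * (1 + r)`
#' (all centers, one charge separation per photosystem) or
#' `ecs_amp_one_charge` (PSII-inhibited leaf, PSI only) decaying with the
#' ATPase time constant. Light-on modes rise from zero with an initial
#' slope equal to `amp * (pool charge-separation rate)`; light-off and
#' far-red-off modes decay from a steady level with the matching initial
#' slope. The 546 nm channel carries a slow linear drift that is added to
#' the 520 nm channel as well, so the 520 - 546 difference recovers the
#' pure electrochromic signal exactly.
#'
#' @param truth A [simulation_ground_truth()].
#' @param mode One of `"flash_total"`, `"flash_psi_only"`,
#'   `"light_on_total"`, `"light_on_psi_only"`, `"light_off_decay"`,
#'   `"farred_off_decay"`.
#' @param noise_sd Relative (multiplicative) Gaussian noise, e.g. 0.005.
#' @param seed Integer seed.
#' @param intensity Actinic intensity (umol photons m-2 s-1) behind the
#'   light-driven modes.
#' @param intensity_farred Far-red intensity driving cyclic flow around
#'   PSI in `farred_off_decay`.
#' @param event_time_s Flash / light-transition time, seconds.
#' @param duration_s,dt_s Trace span and sampling interval, seconds.
#' @param nuisance_scale Amplitude of the 546 nm drift relative to the
#'   single-charge amplitude.
#' @return A list with `trace_520`, `trace_546` and `truth` (amplitudes,
#'   slopes and the generative rates in e- s-1 PS-1).
#' @export
simulate_ecs_experiment <- function(truth, mode, noise_sd = 0,
                                    seed = truth$seed,
                                    intensity = 80,
                                    intensity_farred = 30,
                                    event_time_s = 0.002,
                                    duration_s = 0.06, dt_s = 1e-5,
                                    nuisance_scale = 0.3) {
  stopifnot(inherits(truth, "simulation_ground_truth"))
  mode <- match.arg(mode, c("flash_total", "flash_psi_only",
                            "light_on_total", "light_on_psi_only",
                            "light_off_decay", "farred_off_decay"))
  amp <- truth$ecs_amp_one_charge
  r <- truth$r_psii_psi
  rate_psii <- .KAPPA_E * truth$sigma_psii * intensity
  rate_psi <- .KAPPA_E * truth$sigma_psi * intensity
  rate_cef <- .KAPPA_E * truth$sigma_psi * intensity_farred
  pool_total <- r * rate_psii + rate_psi    # charges/s, pools (r, 1)
  tm <- seq(0, duration_s, by = dt_s)
  te <- event_time_s
  after <- tm >= te
  steady <- 10 * amp * (1 + r)

  pure <- numeric(length(tm))
  tr_truth <- list(mode = mode, rate_psii = rate_psii, rate_psi = rate_psi,
                   r_psii_psi = r,
                   rate_avg_per_ps = pool_total / (1 + r),
                   cef_fraction = 100 * rate_cef / pool_total)
  if (mode %in% c("flash_total", "flash_psi_only")) {
    a0 <- if (mode == "flash_total") amp * (1 + r) else amp
    pure[after] <- a0 * exp(-(tm[after] - te) / truth$tau_atpase_s)
    tr_truth$amplitude_flash <- a0
    tr_truth$amplitude_at_140us <- a0 * exp(-140e-6 / truth$tau_atpase_s)
  } else if (mode %in% c("light_on_total", "light_on_psi_only")) {
    slope <- amp * if (mode == "light_on_total") pool_total else rate_psi
    s_ss <- if (mode == "light_on_total") steady else 10 * amp
    tau <- s_ss / slope
    pure[after] <- s_ss * (1 - exp(-(tm[after] - te) / tau))
    tr_truth$slope <- slope
  } else {
    slope <- amp * if (mode == "light_off_decay") pool_total else rate_cef
    tau <- steady / slope
    pure[!after] <- steady
    pure[after] <- steady * exp(-(tm[after] - te) / tau)
    tr_truth$slope <- -slope
  }

  nuisance <- nuisance_scale * amp * tm / duration_s
  v520 <- pure + nuisance
  v546 <- nuisance
  if (noise_sd > 0) {
    noise <- .with_seed(seed, stats::rnorm(2L * length(tm), 0, noise_sd))
    v520 <- v520 * (1 + noise[seq_along(tm)])
    v546 <- v546 * (1 + noise[length(tm) + seq_along(tm)])
  }
  meta <- list(simulated = TRUE, mode = mode, event_time_s = te)
  list(trace_520 = trace(tm, v520, "ecs_520", meta),
       trace_546 = trace(tm, v546, "ecs_546", meta),
       truth = tr_truth)
}

#' Simulate a DCMU fluorescence induction curve
#'
#' With the PSII acceptor side blocked, fluorescence rises from `f0_dark`
#' to `fm_dark` as `F(t) = f0 + (fm - f0)(1 - exp(-k t))` with
#' `k = sigma_psii * intensity` (in relative units): a single stable
#' charge separation per center, so the rise rate reads the functional
#' PSII antenna size.
#'
#' @param truth A [simulation_ground_truth()].
#' @param intensity Actinic intensity, umol photons m-2 s-1 (> 0).
#' @param noise_sd Additive Gaussian noise, a.u.
#' @param seed Integer seed.
#' @param n_folds Trace length in units of `1/k` (plateau coverage).
#' @param n_samples Number of samples.
#' @return A list with `trace` and `truth` (the rise rate `k`).
#' @export
simulate_dcmu_induction <- function(truth, intensity, noise_sd = 0,
                                    seed = truth$seed, n_folds = 12,
                                    n_samples = 2400L) {
  stopifnot(inherits(truth, "simulation_ground_truth"))
  if (intensity <= 0) stop("intensity must be > 0", call. = FALSE)
  k <- .KAPPA * truth$sigma_psii * intensity
  tm <- seq(0, n_folds / k, length.out = n_samples)
  f <- truth$f0_dark +
    (truth$fm_dark - truth$f0_dark) * (1 - exp(-k * tm))
  if (noise_sd > 0) {
    f <- .with_seed(seed, f + stats::rnorm(length(f), 0, noise_sd))
  }
  list(trace = trace(tm, f, "fluorescence",
                     meta = list(simulated = TRUE, dcmu = TRUE,
                                 intensity = intensity)),
       truth = list(k = k, f0 = truth$f0_dark, fm = truth$fm_dark))
}

#' Simulate a Vj pulse-train series
#'
#' Relative variable fluorescence at 3 ms (Vj) after dark or far-red
#' intervals of increasing length: `Vj(D) = v_inf + (v0 - v_inf)
#' exp(-D / tau)` with `tau` the plastoquinone reoxidation time constant
#' of the chosen mode. Far-red reoxidation is faster than dark
#' reoxidation whenever PSI pull (`sigma_psi / r_psii_psi`) exceeds the
#' dark oxidation capacity, as in the default parameter sets.
#'
#' @param truth A [simulation_ground_truth()].
#' @param intervals Strictly increasing dark/far-red intervals, seconds.
#' @param mode `"dark"` or `"far_red"`.
#' @param noise_sd Additive Gaussian noise on Vj.
#' @param seed Integer seed.
#' @param v0 Vj immediately after the previous pulse.
#' @param v_inf Fully reoxidized Vj plateau; defaults to 0.25 (dark) or
#'   0.05 (far-red).
#' @return A `vj_series` data.frame of `(interval_s, vj)` with the
#'   generative parameters attached as attribute `truth`.
#' @export
simulate_vj_series <- function(truth, intervals, mode = c("dark", "far_red"),
                               noise_sd = 0, seed = truth$seed,
                               v0 = 0.65, v_inf = NULL) {
  stopifnot(inherits(truth, "simulation_ground_truth"))
  mode <- match.arg(mode)
  if (length(intervals) == 0L) {
    stop("configuration error: empty interval list", call. = FALSE)
  }
  if (any(diff(intervals) <= 0)) {
    stop("intervals must be strictly increasing", call. = FALSE)
  }
  tau <- if (mode == "dark") truth$tau_pq_ox_dark_s else
    truth$tau_pq_ox_farred_s
  if (is.null(v_inf)) v_inf <- if (mode == "dark") 0.25 else 0.05
  vj <- v_inf + (v0 - v_inf) * exp(-intervals / tau)
  if (noise_sd > 0) {
    vj <- .with_seed(seed, vj + stats::rnorm(length(vj), 0, noise_sd))
  }
  out <- data.frame(interval_s = intervals, vj = vj)
  attr(out, "truth") <- list(tau = tau, v0 = v0, v_inf = v_inf,
                             mode = mode)
  class(out) <- c("vj_series", "data.frame")
  out
}

# Exponential decay (amplitude 1 at t = 0) convolved with a unit-area
# Gaussian instrument response of width sigma (same time units).
.exp_gauss <- function(t, tau, sigma) {
  if (sigma <= 0) return(ifelse(t >= 0, exp(-t / tau), 0))
  0.5 * exp(sigma^2 / (2 * tau^2) - t / tau) *
    pracma::erfc((sigma^2 / tau - t) / (sigma * sqrt(2)))
}

#' Simulate a TCSPC fluorescence decay histogram
#'
#' Expected counts per bin are proportional to the sum of three
#' exponentials (amplitudes `amps`, lifetimes `lifetimes_ns`), optionally
#' convolved with a Gaussian instrument response, and are either sampled
#' multinomially to exactly `n_photons` total counts or returned as the
#' rounded noiseless expectation.
#'
#' @param amps Non-negative amplitudes summing to 1 (tolerance 1e-9).
#' @param lifetimes_ns Positive lifetimes, nanoseconds.
#' @param irf_sigma_ps Gaussian IRF width, picoseconds (0 = none).
#' @param n_photons Total photon count.
#' @param bin_ps Bin width, picoseconds.
#' @param n_bins Number of bins.
#' @param seed Integer seed.
#' @param sample If `FALSE`, return the rounded noiseless expectation
#'   instead of a multinomial draw.
#' @return A `tcspc` [trace()] (time in seconds, `bin_ps` in `meta`).
#' @export
simulate_flim_decay <- function(amps, lifetimes_ns,
                                irf_sigma_ps = 0, n_photons = 1e6,
                                bin_ps = 32, n_bins = 256L, seed = 1L,
                                sample = TRUE) {
  if (length(amps) != length(lifetimes_ns)) {
    stop("amps and lifetimes_ns must have equal length", call. = FALSE)
  }
  if (any(amps < 0) || abs(sum(amps) - 1) > 1e-9) {
    stop("amps must be non-negative and sum to 1 (tolerance 1e-9)",
         call. = FALSE)
  }
  tb <- (seq_len(n_bins) - 0.5) * bin_ps   # bin centers, ps
  tau_ps <- lifetimes_ns * 1e3
  expected <- rowSums(vapply(seq_along(amps), function(i) {
    amps[i] * .exp_gauss(tb, tau_ps[i], irf_sigma_ps)
  }, numeric(length(tb))))
  p <- expected / sum(expected)
  counts <- if (sample) {
    .with_seed(seed, as.numeric(stats::rmultinom(1L, n_photons, p)))
  } else {
    round(p * n_photons)
  }
  trace(tb * 1e-12, counts, channel = "tcspc",
        meta = list(simulated = TRUE, bin_ps = bin_ps,
                    irf_sigma_ps = irf_sigma_ps))
}

#' Simulate a grana morphometry table
#'
#' Stack counts per granum are `1 + Poisson(mean - 1)` (a granum has at
#' least one layer); widths are normal, truncated at zero by redrawing.
#'
#' @param n_per_group Observations per group (scalar or one per group).
#' @param mean_stacks_by_group Named vector of mean layers per stack
#'   (all >= 1); names are the genotype labels.
#' @param width_mean_by_group Named vector of mean widths, nm.
#' @param width_sd Common width standard deviation, nm.
#' @param seed Integer seed.
#' @return A data.frame with `genotype`, `n_layers`, `width_nm`.
#' @export
simulate_grana_dataset <- function(n_per_group, mean_stacks_by_group,
                                   width_mean_by_group, width_sd = 80,
                                   seed = 1L) {
  groups <- names(mean_stacks_by_group)
  if (is.null(groups)) {
    stop("mean_stacks_by_group must be a named vector", call. = FALSE)
  }
  if (any(mean_stacks_by_group < 1)) {
    stop("mean stack counts must be >= 1 (a granum has >= 1 layer)",
         call. = FALSE)
  }
  n_per_group <- rep_len(n_per_group, length(groups))
  .with_seed(seed, {
    rows <- lapply(seq_along(groups), function(g) {
      n <- n_per_group[g]
      layers <- 1L + stats::rpois(n, mean_stacks_by_group[g] - 1)
      w <- stats::rnorm(n, width_mean_by_group[g], width_sd)
      while (any(w <= 0)) {
        bad <- w <= 0
        w[bad] <- stats::rnorm(sum(bad), width_mean_by_group[g], width_sd)
      }
      data.frame(genotype = groups[g], n_layers = layers, width_nm = w,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$genotype <- factor(out$genotype, levels = groups)
    rownames(out) <- NULL
    out
  })
}

#' Simulate absorbances of a chlorophyll extract
#'
#' Inverts the buffered 80 %-acetone two-wavelength quantification used
#' by [chl_from_absorbance()]: given true chlorophyll a and b
#' concentrations, returns the absorbances at 663.6 and 646.6 nm that
#' would be read (1 cm pathlength).
#'
#' @param chl_a,chl_b Concentrations, ug/ml (>= 0).
#' @return Named vector `c(a663_6, a646_6)`.
#' @export
simulate_pigment_extract <- function(chl_a, chl_b) {
  if (chl_a < 0 || chl_b < 0) {
    stop("concentrations must be >= 0", call. = FALSE)
  }
  a <- unname(solve(.CHL_COEF, c(chl_a, chl_b)))
  c(a663_6 = a[1L], a646_6 = a[2L])
}
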