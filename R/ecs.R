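# Electrochromic-shift analysis: dual-wavelength deconvolution, flash
# calibration, initial slopes, per-photosystem rates, stoichiometry and
# the cyclic electron flow fraction.

#' ECS single-charge flash calibration
#'
#' The ECS amplitude read 140 us after a saturating single-turnover
#' laser flash corresponds to one charge separation per photosystem and
#' calibrates slopes into e- s-1 PS-1.
#'
#' @param amp_one_charge ECS amplitude (-dI/I) per single charge
#'   separation per photosystem (> 0).
#' @param read_delay_s Delay after the flash at which the amplitude is
#'   read, seconds (default 140 us).
#' @return An object of class `ecs_flash_calibration`.
#' @export
ecs_flash_calibration <- function(amp_one_charge, read_delay_s = 140e-6) {
  if (!is.finite(amp_one_charge) || amp_one_charge <= 0) {
    stop("domain error: amp_one_charge must be > 0", call. = FALSE)
  }
  structure(list(amp_one_charge = amp_one_charge,
                 read_delay_s = read_delay_s),
            class = "ecs_flash_calibration")
}

#' Deconvolve the electrochromic signal from a 520/546 nm pair
#'
#' The 520 nm channel carries the carotenoid electrochromic bandshift
#' plus scattering/nuisance components; the 546 nm channel carries the
#' nuisance only. The pointwise difference is the pure ECS signal.
#' The two traces must share the same time base (tolerance 1e-9 s per
#' sample); no resampling is performed unless `resample = TRUE`, which
#' linearly interpolates the 546 channel onto the 520 time base.
#'
#' @param trace_520 [trace()] with channel `ecs_520`.
#' @param trace_546 [trace()] with channel `ecs_546`.
#' @param resample Allow linear-interpolated alignment of mismatched
#'   time bases (default `FALSE`).
#' @return A [trace()] with channel `ecs_corrected`.
#' @export
deconvolve_ecs <- function(trace_520, trace_546, resample = FALSE) {
  stopifnot(inherits(trace_520, "trace"), inherits(trace_546, "trace"))
  same_base <- length(trace_520$time) == length(trace_546$time) &&
    all(abs(trace_520$time - trace_546$time) <= 1e-9)
  if (!same_base) {
    if (!resample) {
      stop("alignment error: 520/546 time bases differ ",
           "(use resample = TRUE to interpolate)", call. = FALSE)
    }
    v546 <- stats::approx(trace_546$time, trace_546$values,
                          xout = trace_520$time, rule = 2L)$y
  } else {
    v546 <- trace_546$values
  }
  trace(trace_520$time, trace_520$values - v546,
        channel = "ecs_corrected",
        meta = c(trace_520$meta, list(deconvolved = TRUE)))
}

#' Flash-induced ECS amplitude
#'
#' Amplitude = value at `flash_time + read_delay` (linear interpolation
#' between samples) minus the pre-flash baseline (mean of the 1 ms
#' before the flash). Baseline subtraction makes the reading invariant
#' to constant offsets.
#'
#' @param tr An ECS [trace()] (typically `ecs_corrected`).
#' @param flash_time_s Flash time, seconds.
#' @param read_delay_s Read delay after the flash, seconds (140 us
#'   matches the single-charge calibration convention).
#' @param baseline_window_s Pre-flash baseline window, seconds.
#' @return Amplitude (-dI/I).
#' @export
flash_amplitude <- function(tr, flash_time_s, read_delay_s = 140e-6,
                            baseline_window_s = 1e-3) {
  stopifnot(inherits(tr, "trace"))
  t_read <- flash_time_s + read_delay_s
  if (tr$time[1L] > flash_time_s - baseline_window_s ||
      tr$time[length(tr$time)] < flash_time_s + 10 * read_delay_s) {
    stop("coverage error: trace does not cover the flash window",
         call. = FALSE)
  }
  base_idx <- .samples_in(tr, flash_time_s - baseline_window_s,
                          flash_time_s)
  if (length(base_idx) == 0L) {
    stop("coverage error: no pre-flash baseline samples", call. = FALSE)
  }
  .interp_at(tr, t_read) - mean(tr$values[base_idx])
}

#' Initial slope of a trace around an event
#'
#' Ordinary-least-squares slope of value versus time over a window on
#' the requested side of the event. The window must be much shorter than
#' the relaxation time constant for the initial-slope approximation.
#'
#' @param tr A [trace()].
#' @param event_time_s Event (light on/off) time, seconds.
#' @param window_s Window length, seconds.
#' @param side `"after"` (window starts at the event) or `"before"`.
#' @return Slope in signal units per second.
#' @export
initial_slope <- function(tr, event_time_s, window_s,
                          side = c("after", "before")) {
  stopifnot(inherits(tr, "trace"))
  side <- match.arg(side)
  idx <- if (side == "after") {
    .samples_in(tr, event_time_s, event_time_s + window_s)
  } else {
    .samples_in(tr, event_time_s - window_s, event_time_s)
  }
  if (length(idx) < 4L) {
    stop(sprintf("resolution error: %d samples in slope window (< 4)",
                 length(idx)), call. = FALSE)
  }
  x <- tr$time[idx]; y <- tr$values[idx]
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

#' Photochemical rate from an ECS slope
#'
#' Divides the initial ECS decay (or rise) rate by the single-charge
#' flash amplitude: `rate = |slope| / amp_one_charge`, in
#' e- s-1 PS-1. Linear in `slope`.
#'
#' @param slope ECS slope, -dI/I per second.
#' @param calibration An [ecs_flash_calibration()].
#' @return Photochemical rate, e- s-1 PS-1.
#' @export
photochemical_rate <- function(slope, calibration) {
  stopifnot(inherits(calibration, "ecs_flash_calibration"))
  abs(slope) / calibration$amp_one_charge
}

#' PSII/PSI reaction-center ratio from flash amplitudes
#'
#' A saturating single-turnover flash fires every reaction center once,
#' so the total amplitude counts PSII + PSI centers while the
#' PSII-inhibited (DCMU + hydroxylamine) amplitude counts PSI alone:
#' `r = (amp_total - amp_psi_only) / amp_psi_only`. Scale-invariant.
#'
#' @param amp_flash_total Flash amplitude with all centers active (> 0).
#' @param amp_flash_psi_only Flash amplitude with PSII inhibited (> 0).
#' @return PSII/PSI ratio (dimensionless).
#' @export
psii_psi_ratio <- function(amp_flash_total, amp_flash_psi_only) {
  if (amp_flash_total <= 0 || amp_flash_psi_only <= 0) {
    stop("domain error: flash amplitudes must be > 0", call. = FALSE)
  }
  if (amp_flash_total < amp_flash_psi_only) {
    stop("inconsistency error: total flash amplitude below PSI-only ",
         "amplitude", call. = FALSE)
  }
  (amp_flash_total - amp_flash_psi_only) / amp_flash_psi_only
}

#' Cyclic electron flow fraction
#'
#' Percentage of the total electron flow carried by cyclic flow around
#' PSI: `100 * rate_farred / rate_total`, where the far-red rate is
#' measured with PSI-only excitation.
#'
#' @param rate_farred Electron flow under far-red (PSI-only) light.
#' @param rate_total Total electron flow under actinic light (> 0).
#' @return CEF fraction, percent (0-100).
#' @export
cef_fraction <- function(rate_farred, rate_total) {
  if (rate_total <= 0) {
    stop("domain error: rate_total must be > 0", call. = FALSE)
  }
  if (rate_farred < 0 || rate_farred > rate_total) {
    stop("inconsistency error: rate_farred must lie in [0, rate_total]",
         call. = FALSE)
  }
  100 * rate_farred / rate_total
}
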