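# Partition of chlorophyll between the photosystems and functional
# PSII antenna sizing.

#' PSI share of chlorophyll from rates and stoichiometry
#'
#' Under the same limiting light, the per-photosystem photochemical rate
#' is proportional to the per-photosystem absorption cross-section, and
#' the PSII pool holds `r` centers per PSI center, so
#' `PSI/(PSI + PSII) chlorophyll = rate_psi / (rate_psi + rate_psii * r)`.
#' Strictly increasing in `rate_psi`, decreasing in `rate_psii` and `r`;
#' always in (0, 1).
#'
#' @param rate_psi PSI photochemical rate, e- s-1 PSI-1 (> 0).
#' @param rate_psii PSII photochemical rate, e- s-1 PSII-1 (> 0).
#' @param r_psii_psi PSII/PSI reaction-center ratio (> 0).
#' @return PSI chlorophyll fraction in (0, 1).
#' @examples
#' chl_fraction_from_rates(39.98, 20.25, 1.37)  # wild-type-like: 0.59
#' @export
chl_fraction_from_rates <- function(rate_psi, rate_psii, r_psii_psi) {
  if (any(c(rate_psi, rate_psii, r_psii_psi) <= 0)) {
    stop("domain error: all inputs must be > 0", call. = FALSE)
  }
  rate_psi / (rate_psi + rate_psii * r_psii_psi)
}

#' Fit a TCSPC decay with three fixed lifetimes
#'
#' Fits `F(t) = a1 exp(-t/tau1) + a2 exp(-t/tau2) + a3 exp(-t/tau3)`
#' with the lifetimes held fixed, which reduces the fit to non-negative
#' least squares on the (optionally Gaussian-IRF-convolved) exponential
#' basis. Amplitudes are normalized to sum to 1; a reduced chi-square is
#' reported under Poisson weights (`1 / max(count, 1)`).
#'
#' @param decay A `tcspc` [trace()] with at least 50 bins and total
#'   counts >= 1e4.
#' @param lifetimes_ns Fixed lifetimes, nanoseconds (default
#'   `c(0.1, 0.9, 2.0)`: PSI-, PSII- and closed-PSII-like components).
#' @param irf_sigma_ps Gaussian IRF width, picoseconds (0 = none).
#' @return An object of class `flim_fit`: `amps` (normalized),
#'   `lifetimes_ns`, `chi2_reduced`, `n_bins`, `total_counts`.
#' @export
fit_flim_decay <- function(decay, lifetimes_ns = c(0.1, 0.9, 2.0),
                           irf_sigma_ps = 0) {
  stopifnot(inherits(decay, "trace"))
  if (decay$channel != "tcspc") {
    stop("configuration error: decay must be a tcspc trace", call. = FALSE)
  }
  if (length(decay$time) < 50L) {
    stop("resolution error: need >= 50 bins", call. = FALSE)
  }
  if (sum(decay$values) < 1e4) {
    stop("degenerate-data error: need >= 1e4 total counts", call. = FALSE)
  }
  if (anyDuplicated(lifetimes_ns)) {
    stop("configuration error: duplicate lifetimes give a singular basis",
         call. = FALSE)
  }
  tb_ps <- decay$time / 1e-12
  basis <- vapply(lifetimes_ns * 1e3, function(tau)
    .exp_gauss(tb_ps, tau, irf_sigma_ps), numeric(length(tb_ps)))
  fit <- pracma::lsqnonneg(basis, decay$values)
  coef <- fit$x
  if (all(coef <= 0)) {
    stop("degenerate-data error: all-zero amplitudes", call. = FALSE)
  }
  resid <- decay$values - basis %*% coef
  w <- 1 / pmax(decay$values, 1)
  dof <- length(tb_ps) - sum(coef > 0)
  structure(list(amps = as.numeric(coef / sum(coef)),
                 lifetimes_ns = lifetimes_ns,
                 chi2_reduced = sum(w * resid^2) / dof,
                 n_bins = length(tb_ps),
                 total_counts = sum(decay$values)),
            class = "flim_fit")
}

#' @export
print.flim_fit <- function(x, ...) {
  cat(sprintf(
    "<flim_fit> a=(%s) at tau=(%s) ns, chi2_red=%.3g, %d bins, %g counts\n",
    paste(sprintf("%.4f", x$amps), collapse = ", "),
    paste(x$lifetimes_ns, collapse = ", "),
    x$chi2_reduced, x$n_bins, x$total_counts))
  invisible(x)
}

#' PSI share of chlorophyll from the fast decay amplitude
#'
#' The ~100 ps TCSPC component reports PSI-associated chlorophyll:
#' `PSI/(PSI + PSII) = c a1 / (1 - a1 + c a1)`, where `c` is a
#' setup-specific correction factor relating the photon-detection
#' efficiencies of the two pools. Strictly increasing in `a1`.
#'
#' @param a1 Amplitude of the fast (~100 ps) component, in `[0, 1]`.
#' @param c_factor Setup correction factor (> 0; default 0.49).
#' @return PSI chlorophyll fraction in `[0, 1]`.
#' @export
psi_fraction_from_flim <- function(a1, c_factor = 0.49) {
  if (any(a1 < 0 | a1 > 1)) {
    stop("domain error: a1 must lie in [0, 1]", call. = FALSE)
  }
  if (c_factor <= 0) {
    stop("domain error: c_factor must be > 0", call. = FALSE)
  }
  c_factor * a1 / (1 - a1 + c_factor * a1)
}

#' Invert the FLIM PSI-fraction relation
#'
#' Analytic inverse of [psi_fraction_from_flim()]: the `a1` that yields
#' a given PSI fraction.
#'
#' @param fraction PSI chlorophyll fraction in `[0, 1]`.
#' @param c_factor Setup correction factor (> 0).
#' @return Fast-component amplitude `a1` in `[0, 1]`.
#' @export
a1_from_psi_fraction <- function(fraction, c_factor = 0.49) {
  if (any(fraction < 0 | fraction > 1)) {
    stop("domain error: fraction must lie in [0, 1]", call. = FALSE)
  }
  fraction / (c_factor - c_factor * fraction + fraction)
}

#' Functional PSII antenna size from a DCMU induction curve
#'
#' With DCMU blocking reoxidation, the normalized variable fluorescence
#' `V(t) = (F(t) - F0) / (Fm - F0)` rises as centers close after a
#' single stable charge separation. The reciprocal of the complementary
#' area `integral of (1 - V(t)) dt` is the maximal initial excitation
#' rate of PSII, proportional to its functional antenna cross-section.
#' The finite trace is integrated trapezoidally and completed beyond its
#' end by fitting the last 10 % of samples to a single exponential and
#' integrating the tail analytically.
#'
#' @param induction A fluorescence [trace()] starting at light onset and
#'   reaching at least 99 % of `fm`.
#' @param f0,fm Dark minimal and maximal fluorescence bracketing the
#'   rise (`fm > f0`).
#' @return Maximal initial rate, 1/s.
#' @export
functional_antenna_dcmu <- function(induction, f0, fm) {
  stopifnot(inherits(induction, "trace"))
  if (fm <= f0) stop("domain error: need fm > f0", call. = FALSE)
  tm <- induction$time - induction$time[1L]
  v <- (induction$values - f0) / (fm - f0)
  n <- length(tm)
  if (max(v) < 0.99) {
    stop(sprintf(
      "coverage error: plateau not reached (max V = %.3f < 0.99; partial
 complementary area = %.4g s)",
      max(v), pracma::trapz(tm, pmax(1 - v, 0))), call. = FALSE)
  }
  area <- pracma::trapz(tm, 1 - v)
  # exponential tail beyond the trace end, from the last 10 % of samples
  tail_idx <- seq.int(max(1L, ceiling(0.9 * n)), n)
  u <- 1 - v[tail_idx]
  keep <- u > 0
  if (sum(keep) >= 3L) {
    x <- tm[tail_idx][keep]; y <- log(u[keep])
    b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    if (b < 0) {
      tau_tail <- -1 / b
      area <- area + max(1 - v[n], 0) * tau_tail
    }
  }
  1 / area
}
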