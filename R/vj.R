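# Fast fluorescence induction: Vj and plastoquinone reoxidation trends.

#' Relative variable fluorescence at 3 ms (Vj)
#'
#' `Vj = (F(3 ms) - F0) / (Fm - F0)` within a saturating pulse, where
#' `F0` is the value 50 us after pulse onset (the first reliable point
#' of fast-induction instruments, linearly interpolated) and `Fm` the
#' maximum during the pulse. Vj tracks the redox state of the
#' plastoquinone acceptor side. Invariant to scaling the whole trace by
#' a positive factor and to adding a constant offset. Set
#' `normalization = "fm"` for the plain `F(3 ms)/Fm` variant.
#'
#' @param ojip A fluorescence [trace()] covering the pulse.
#' @param pulse_start_s Pulse onset time, seconds.
#' @param pulse_duration_s Pulse length, seconds (default 0.7 s).
#' @param normalization `"variable"` (default) or `"fm"`.
#' @return Vj (dimensionless).
#' @export
compute_vj <- function(ojip, pulse_start_s, pulse_duration_s = 0.7,
                       normalization = c("variable", "fm")) {
  stopifnot(inherits(ojip, "trace"))
  normalization <- match.arg(normalization)
  idx <- .samples_in(ojip, pulse_start_s,
                     pulse_start_s + pulse_duration_s)
  if (length(idx) < 4L) {
    stop("coverage error: pulse window has fewer than 4 samples",
         call. = FALSE)
  }
  f0 <- .interp_at(ojip, pulse_start_s + 50e-6)
  fmx <- max(ojip$values[idx])
  f3 <- .interp_at(ojip, pulse_start_s + 3e-3)
  if (abs(fmx - f0) < .Machine$double.eps * 4) {
    stop("degenerate-signal error: Fm == F0 within the pulse",
         call. = FALSE)
  }
  if (normalization == "variable") (f3 - f0) / (fmx - f0) else f3 / fmx
}

#' Trend of Vj against dark/far-red interval
#'
#' Ordinary-least-squares slope of Vj against `log10(interval)` — the
#' intervals span more than two decades — plus a local-regression
#' (lowess, span 0.75) curve for display only.
#'
#' @param series Data.frame with columns `interval_s` (> 0, strictly
#'   increasing) and `vj`; at least 4 rows.
#' @return List with `slope` (per log10 s), `intercept`, and `curve`
#'   (data.frame `interval_s`, `vj_smooth`).
#' @export
fit_vj_trend <- function(series) {
  stopifnot(is.data.frame(series),
            all(c("interval_s", "vj") %in% names(series)))
  if (nrow(series) < 4L) {
    stop("need at least 4 points to fit a trend", call. = FALSE)
  }
  if (any(series$interval_s <= 0)) {
    stop("domain error: intervals must be > 0 (log undefined)",
         call. = FALSE)
  }
  x <- log10(series$interval_s)
  y <- series$vj
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  intercept <- mean(y) - slope * mean(x)
  sm <- stats::lowess(x, y, f = 0.75)
  list(slope = slope, intercept = intercept,
       curve = data.frame(interval_s = 10^sm$x, vj_smooth = sm$y))
}
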