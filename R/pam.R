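# PAM quenching analysis: landmark extraction and the derived
# NPQ / PhiPSII / 1-qL / qT parameters.

#' Fluorescence landmarks of a PAM protocol
#'
#' @param fm Dark-adapted maximal fluorescence (first saturating pulse).
#' @param f0 Dark-adapted minimal fluorescence.
#' @param steps `NULL` or a data.frame with one row per light step:
#'   `intensity` (umol photons m-2 s-1), `fs`, `fm_prime`, `f0_prime`
#'   (`NA` when no far-red window followed the step).
#' @return An object of class `fluorescence_landmarks`.
#' @export
fluorescence_landmarks <- function(fm, f0, steps = NULL) {
  if (!is.finite(fm) || fm <= 0) stop("fm must be > 0", call. = FALSE)
  if (!is.finite(f0) || f0 <= 0 || f0 >= fm) {
    stop("f0 must satisfy 0 < f0 < fm", call. = FALSE)
  }
  if (!is.null(steps)) {
    steps <- as.data.frame(steps)
    need <- c("intensity", "fs", "fm_prime", "f0_prime")
    if (!all(need %in% names(steps))) {
      stop("steps must have columns ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    rownames(steps) <- NULL
  }
  structure(list(fm = fm, f0 = f0, steps = steps),
            class = "fluorescence_landmarks")
}

#' @export
print.fluorescence_landmarks <- function(x, ...) {
  cat(sprintf("<fluorescence_landmarks> Fm=%.4g, F0=%.4g, %d steps\n",
              x$fm, x$f0, if (is.null(x$steps)) 0L else nrow(x$steps)))
  if (!is.null(x$steps)) print(x$steps)
  invisible(x)
}

#' Extract fluorescence landmarks from an annotated PAM trace
#'
#' The first saturating pulse (which must sit in darkness) gives `Fm`;
#' `F0` is the median of the dark samples preceding it. Every later
#' pulse defines a step: its intensity is that of the immediately
#' preceding non-pulse phase, `Fs` is the mean of the last 5 % of that
#' phase's samples, `Fm'` is the median of the pulse-plateau samples,
#' and `F0'` is the minimum within the far-red window following the
#' pulse (`NA` if none). Phase membership is half-open `[start, end)`.
#' No smoothing is applied.
#'
#' @param tr A fluorescence [trace()].
#' @param prot The annotating [protocol()]; the first saturating pulse
#'   must occur in darkness.
#' @param noise_tol Tolerance above `Fm` before an `Fm' > Fm` warning
#'   finding is recorded.
#' @return A [fluorescence_landmarks()]; any findings (e.g. `Fm' > Fm`)
#'   are attached as attribute `findings`.
#' @export
extract_landmarks <- function(tr, prot, noise_tol = 0.05) {
  stopifnot(inherits(tr, "trace"), inherits(prot, "protocol"))
  ph <- prot$phases
  pulses <- which(ph$kind == "saturating_pulse")
  if (length(pulses) == 0L) {
    stop("configuration error: protocol has no saturating pulse",
         call. = FALSE)
  }
  findings <- character()
  pulse_level <- function(p) {
    idx <- .samples_in(tr, ph$start_s[p], ph$end_s[p])
    if (length(idx) < 3L) {
      stop(sprintf(
        "resolution error: pulse phase %d contains %d samples (< 3)",
        p, length(idx)), call. = FALSE)
    }
    stats::median(tr$values[idx])
  }
  fp <- pulses[1L]
  fm <- pulse_level(fp)
  pre_dark <- which(ph$kind == "dark" & ph$end_s <= ph$start_s[fp] + 1e-12)
  if (length(pre_dark) == 0L) {
    stop("configuration error: first saturating pulse is not preceded ",
         "by a dark phase", call. = FALSE)
  }
  dark_idx <- unlist(lapply(pre_dark, function(p)
    .samples_in(tr, ph$start_s[p], ph$end_s[p])))
  f0 <- stats::median(tr$values[dark_idx])

  steps <- NULL
  if (length(pulses) > 1L) {
    rows <- lapply(pulses[-1L], function(p) {
      fm_prime <- pulse_level(p)
      if (fm_prime > fm + noise_tol) {
        findings <<- c(findings, sprintf(
          "Fm' (%.4g) exceeds Fm (%.4g) at pulse starting %g s",
          fm_prime, fm, ph$start_s[p]))
      }
      prev_cand <- which(ph$end_s <= ph$start_s[p] + 1e-12 &
                           !(ph$kind %in% c("saturating_pulse",
                                            "laser_flash")))
      prev <- prev_cand[which.max(ph$end_s[prev_cand])]
      w0 <- ph$end_s[prev] -
        .FS_WINDOW_FRAC * (ph$end_s[prev] - ph$start_s[prev])
      fs_idx <- .samples_in(tr, max(w0, ph$start_s[prev]), ph$end_s[prev])
      fs <- mean(tr$values[fs_idx])
      nxt <- which(ph$start_s >= ph$end_s[p] - 1e-12 &
                     ph$kind == "far_red")
      f0_prime <- if (length(nxt) > 0L) {
        fr <- nxt[which.min(ph$start_s[nxt])]
        idx <- .samples_in(tr, ph$start_s[fr], ph$end_s[fr])
        min(tr$values[idx])
      } else NA_real_
      data.frame(intensity = ph$intensity[prev], fs = fs,
                 fm_prime = fm_prime, f0_prime = f0_prime)
    })
    steps <- do.call(rbind, rows)
  }
  out <- fluorescence_landmarks(fm = fm, f0 = f0, steps = steps)
  attr(out, "findings") <- findings
  out
}

#' Non-photochemical quenching
#'
#' `NPQ = (Fm - Fm') / Fm'`.
#'
#' @param fm Dark-adapted maximal fluorescence.
#' @param fm_prime Light-acclimated maximal fluorescence (> 0).
#' @return NPQ (dimensionless).
#' @export
compute_npq <- function(fm, fm_prime) {
  if (any(fm_prime <= 0)) {
    stop("domain error: fm_prime must be > 0", call. = FALSE)
  }
  (fm - fm_prime) / fm_prime
}

#' Operating quantum yield of PSII
#'
#' `PhiPSII = (Fm' - Fs) / Fm'`. If `Fs > Fm'` the (negative) value is
#' returned and a warning finding attached as attribute `findings`.
#'
#' @param fm_prime Light-acclimated maximal fluorescence (> 0).
#' @param fs Steady-state fluorescence.
#' @return PhiPSII in `[0, 1]` for ordered landmarks.
#' @export
compute_phi_psii <- function(fm_prime, fs) {
  if (any(fm_prime <= 0)) {
    stop("domain error: fm_prime must be > 0", call. = FALSE)
  }
  phi <- (fm_prime - fs) / fm_prime
  bad <- which(fs > fm_prime)
  if (length(bad) > 0L) {
    attr(phi, "findings") <- sprintf(
      "Fs (%.4g) exceeds Fm' (%.4g): negative PhiPSII",
      fs[bad], fm_prime[bad])
  }
  phi
}

#' Fraction of closed PSII centers (1 - qL)
#'
#' `1 - qL = 1 - ((Fm' - Fs) / (Fm' - F0')) * (F0' / Fs)` under the lake
#' model of connected PSII antennae.
#'
#' @param fm_prime Light-acclimated maximal fluorescence.
#' @param fs Steady-state fluorescence (> 0).
#' @param f0_prime Far-red-oxidized minimal fluorescence
#'   (`0 < f0_prime < fm_prime`).
#' @return 1 - qL (0 when all centers are open, 1 when all are closed).
#' @export
compute_one_minus_ql <- function(fm_prime, fs, f0_prime) {
  if (any(abs(fm_prime - f0_prime) < .Machine$double.eps * 4)) {
    stop("degenerate input: fm_prime == f0_prime", call. = FALSE)
  }
  if (any(fs <= 0) || any(f0_prime <= 0)) {
    stop("domain error: fs and f0_prime must be > 0", call. = FALSE)
  }
  1 - ((fm_prime - fs) / (fm_prime - f0_prime)) * (f0_prime / fs)
}

#' Build a quenching light curve from landmarks
#'
#' Applies [compute_npq()], [compute_phi_psii()] and
#' [compute_one_minus_ql()] to every step, ordered by intensity. A step
#' without a far-red `F0'` yields `NA` for `one_minus_ql` with a
#' finding; per-step domain problems become findings attached to the
#' result, never exceptions.
#'
#' @param lm A [fluorescence_landmarks()] with at least one step.
#' @return A data.frame with columns `intensity`, `npq`, `phi_psii`,
#'   `one_minus_ql`; findings in attribute `findings`.
#' @export
build_light_curve <- function(lm) {
  stopifnot(inherits(lm, "fluorescence_landmarks"))
  if (is.null(lm$steps) || nrow(lm$steps) == 0L) {
    stop("landmarks contain no light steps", call. = FALSE)
  }
  st <- lm$steps[order(lm$steps$intensity), , drop = FALSE]
  findings <- character()
  one_row <- function(i) {
    npq <- compute_npq(lm$fm, st$fm_prime[i])
    phi <- compute_phi_psii(st$fm_prime[i], st$fs[i])
    if (!is.null(attr(phi, "findings"))) {
      findings <<- c(findings, attr(phi, "findings"))
    }
    oql <- if (is.na(st$f0_prime[i])) {
      findings <<- c(findings, sprintf(
        "step at %g umol photons m-2 s-1: no F0' (missing far-red window)",
        st$intensity[i]))
      NA_real_
    } else {
      tryCatch(compute_one_minus_ql(st$fm_prime[i], st$fs[i],
                                    st$f0_prime[i]),
               error = function(e) {
                 findings <<- c(findings, conditionMessage(e))
                 NA_real_
               })
    }
    data.frame(intensity = st$intensity[i], npq = npq,
               phi_psii = as.numeric(phi), one_minus_ql = oql)
  }
  out <- do.call(rbind, lapply(seq_len(nrow(st)), one_row))
  rownames(out) <- NULL
  attr(out, "findings") <- findings
  out
}

#' State-transition quenching qT
#'
#' `qT = (Fm_St1 - Fm_St2) / Fm_St1`, from the maximal fluorescence at
#' the end of the State 1 and State 2 light phases.
#'
#' @param fm_st1 Maximal fluorescence in State 1 (> 0).
#' @param fm_st2 Maximal fluorescence in State 2.
#' @return qT (dimensionless).
#' @export
compute_qt <- function(fm_st1, fm_st2) {
  if (any(fm_st1 <= 0)) {
    stop("domain error: fm_st1 must be > 0", call. = FALSE)
  }
  (fm_st1 - fm_st2) / fm_st1
}

#' Two-point decomposition of NPQ induction/relaxation kinetics
#'
#' From an NPQ time series spanning a light-to-dark transition, reads
#' the NPQ at the end of the light phase and after a stated relaxation
#' time, and splits the difference into a rapidly reversible (qE-like)
#' part and a residual.
#'
#' @param npq_series Data.frame with columns `time_s` and `npq`
#'   (typically one row per saturating pulse).
#' @param light_off_time_s Time at which the actinic light was switched
#'   off, seconds.
#' @param relax_read_time_s Relaxation time after light-off at which the
#'   residual NPQ is read (e.g. 300 s), seconds.
#' @param match_tol_s Maximal distance between `light_off_time_s +
#'   relax_read_time_s` and the nearest pulse, seconds.
#' @return List with `npq_end_light`, `npq_relaxed`, `qe`
#'   (= end-of-light minus relaxed) and `residual` (= relaxed).
#' @export
decompose_npq_kinetics <- function(npq_series, light_off_time_s,
                                   relax_read_time_s,
                                   match_tol_s = 30) {
  stopifnot(is.data.frame(npq_series),
            all(c("time_s", "npq") %in% names(npq_series)))
  before <- npq_series$time_s <= light_off_time_s + 1e-9
  if (!any(before)) {
    stop("coverage error: no NPQ reading at or before light-off",
         call. = FALSE)
  }
  if (max(npq_series$time_s) < light_off_time_s - 1e-9) {
    stop("coverage error: series ends before light-off", call. = FALSE)
  }
  npq_end <- npq_series$npq[max(which(before))]
  target <- light_off_time_s + relax_read_time_s
  d <- abs(npq_series$time_s - target)
  if (min(d) > match_tol_s) {
    stop(sprintf(
      "coverage error: no pulse within %g s of the relaxation read ",
      match_tol_s), call. = FALSE)
  }
  npq_rel <- npq_series$npq[which.min(d)]
  list(npq_end_light = npq_end, npq_relaxed = npq_rel,
       qe = npq_end - npq_rel, residual = npq_rel)
}

#' NPQ time series from an annotated trace
#'
#' Convenience wrapper: extracts landmarks, then returns one `(time_s,
#' npq)` row per post-dark saturating pulse, timed at the pulse start.
#'
#' @param tr A fluorescence [trace()].
#' @param prot The annotating [protocol()].
#' @return Data.frame with `time_s` and `npq`.
#' @export
npq_time_series <- function(tr, prot) {
  lm <- extract_landmarks(tr, prot)
  ph <- prot$phases
  pulses <- which(ph$kind == "saturating_pulse")
  if (length(pulses) < 2L) {
    stop("need at least one post-dark saturating pulse", call. = FALSE)
  }
  # steps are in protocol order here (extract_landmarks keeps it)
  data.frame(time_s = ph$start_s[pulses[-1L]],
             npq = compute_npq(lm$fm, lm$steps$fm_prime))
}
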