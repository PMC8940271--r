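#' Construct a single-channel trace
#'
#' A `trace` is the package's container for one time-stamped signal: a PAM
#' fluorescence record, an electrochromic-shift (ECS) record at 520 or
#' 546 nm, or a TCSPC photon-count histogram. Time is always carried in
#' seconds internally; readers convert declared ms/us/ps units on ingest.
#'
#' @param time Numeric vector of time stamps in seconds, strictly increasing.
#' @param values Numeric vector of signal values (fluorescence a.u., ECS
#'   -dI/I, or photon counts), same length as `time`.
#' @param channel One of `"fluorescence"`, `"ecs_520"`, `"ecs_546"`,
#'   `"ecs_corrected"`, `"tcspc"`.
#' @param meta Named list of free-form metadata (instrument, bin width, ...).
#' @return An object of class `trace` with elements `time`, `values`,
#'   `channel`, `meta`.
#' @examples
#' tr <- trace(c(0, 1, 2), c(1.0, 2.0, 1.5), "fluorescence")
#' @export
trace <- function(time, values, channel = "fluorescence", meta = list()) {
  channel <- match.arg(channel,
                       c("fluorescence", "ecs_520", "ecs_546",
                         "ecs_corrected", "tcspc"))
  time <- as.numeric(time)
  values <- as.numeric(values)
  if (length(time) != length(values)) {
    stop("malformed trace: length(time) != length(values)", call. = FALSE)
  }
  if (length(time) < 2L) {
    stop("malformed trace: need at least 2 samples", call. = FALSE)
  }
  if (anyNA(time) || any(!is.finite(time))) {
    stop("malformed trace: non-finite time values", call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("malformed trace: non-finite signal values", call. = FALSE)
  }
  d <- diff(time)
  if (any(d <= 0)) {
    row <- which(d <= 0)[1L] + 1L
    stop(sprintf("malformed trace: time not strictly increasing at row %d",
                 row), call. = FALSE)
  }
  if (channel == "tcspc") {
    if (any(values < 0)) {
      stop("malformed trace: tcspc counts must be non-negative",
           call. = FALSE)
    }
    if (any(abs(values - round(values)) > 1e-6)) {
      stop("malformed trace: tcspc counts must be integer", call. = FALSE)
    }
  }
  structure(list(time = time, values = values, channel = channel,
                 meta = meta),
            class = "trace")
}

#' @export
print.trace <- function(x, ...) {
  cat(sprintf("<trace> channel=%s, n=%d, span=[%g, %g] s\n",
              x$channel, length(x$time), x$time[1L],
              x$time[length(x$time)]))
  invisible(x)
}

#' Construct a light protocol
#'
#' A protocol is an ordered set of light phases annotating a trace: dark,
#' actinic light, far-red light, saturating pulses, or laser flashes, each
#' with a start/end time and an intensity in umol photons m-2 s-1 (flash
#' energy is unitless). Phase membership is half-open: a sample at a phase
#' boundary belongs to the later phase.
#'
#' @param phases A data.frame with columns `start_s`, `end_s`, `kind`
#'   (one of dark, actinic, far_red, saturating_pulse, laser_flash) and
#'   `intensity`.
#' @return An object of class `protocol` wrapping the phase table sorted
#'   by `start_s`.
#' @export
protocol <- function(phases) {
  phases <- as.data.frame(phases, stringsAsFactors = FALSE)
  required <- c("start_s", "end_s", "kind", "intensity")
  missing_cols <- setdiff(required, names(phases))
  if (length(missing_cols) > 0L) {
    stop("protocol schema error: missing columns ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  kinds <- c("dark", "actinic", "far_red", "saturating_pulse", "laser_flash")
  bad <- setdiff(unique(phases$kind), kinds)
  if (length(bad) > 0L) {
    stop("protocol schema error: unknown phase kind ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(phases$start_s >= phases$end_s)) {
    stop("protocol schema error: phase with start_s >= end_s", call. = FALSE)
  }
  if (any(phases$intensity < 0)) {
    stop("protocol schema error: negative intensity", call. = FALSE)
  }
  if (any(phases$kind == "dark" & phases$intensity != 0)) {
    stop("protocol schema error: dark phase with non-zero intensity",
         call. = FALSE)
  }
  phases <- phases[order(phases$start_s), required, drop = FALSE]
  rownames(phases) <- NULL
  structure(list(phases = phases), class = "protocol")
}

#' @export
print.protocol <- function(x, ...) {
  cat(sprintf("<protocol> %d phases, span=[%g, %g] s\n",
              nrow(x$phases), min(x$phases$start_s), max(x$phases$end_s)))
  print(x$phases)
  invisible(x)
}

# Seconds-per-unit factors accepted in trace column headers.
.time_unit_factors <- c(s = 1, ms = 1e-3, us = 1e-6, ps = 1e-12)

#' Read a trace from delimited text
#'
#' The file must be comma- or tab-delimited (auto-detected from the header
#' line) with a header naming a time column (`time_s`, `time_ms`, `time_us`
#' or `time_ps`) and one value column (any other name, e.g. `value` or
#' `counts`). Declared time units are converted to seconds on ingest.
#'
#' @param path Path to the delimited text file.
#' @param channel Channel tag for the returned trace (see [trace()]).
#' @return A [trace()].
#' @export
read_trace <- function(path, channel = "fluorescence") {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, dec = ".",
                          stringsAsFactors = FALSE)
  time_col <- grep("^time_(s|ms|us|ps)$", names(df), value = TRUE)
  if (length(time_col) != 1L) {
    stop("trace schema error: need exactly one time column named ",
         "time_s/time_ms/time_us/time_ps; found: ",
         paste(names(df), collapse = ", "), call. = FALSE)
  }
  value_col <- setdiff(names(df), time_col)
  if (length(value_col) != 1L) {
    stop("trace schema error: need exactly one value column", call. = FALSE)
  }
  unit <- sub("^time_", "", time_col)
  tm <- df[[time_col]] * .time_unit_factors[[unit]]
  trace(tm, df[[value_col]], channel = channel,
        meta = list(source = path, time_unit = unit,
                    value_column = value_col))
}

#' Write a trace to delimited text
#'
#' Writes `time_s,value` (or `time_ps,counts` for TCSPC histograms) with
#' 15 significant digits so that a read/write round trip preserves values
#' to within double serialization precision.
#'
#' @param x A [trace()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(x, path) {
  stopifnot(inherits(x, "trace"))
  if (x$channel == "tcspc") {
    header <- "time_ps,counts"
    tm <- x$time / 1e-12
  } else {
    header <- "time_s,value"
    tm <- x$time
  }
  lines <- c(header,
             paste(formatC(tm, format = "g", digits = 15),
                   formatC(x$values, format = "g", digits = 15),
                   sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Read a protocol from a YAML or JSON sidecar file
#'
#' The sidecar lists phases under a top-level `phases` key, each with
#' `start_s`, `end_s`, `kind` and `intensity`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [protocol()].
#' @export
read_protocol <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    obj <- yaml::read_yaml(path)
  }
  if (is.null(obj$phases)) {
    stop("protocol schema error: no 'phases' key in ", path, call. = FALSE)
  }
  ph <- obj$phases
  required <- c("start_s", "end_s", "kind", "intensity")
  if (!is.data.frame(ph)) {
    if (all(required %in% names(ph))) {       # column-wise layout
      ph <- as.data.frame(ph, stringsAsFactors = FALSE)
    } else {                                  # row-wise list of phases
      ph <- do.call(rbind, lapply(ph, function(p) {
        data.frame(start_s = as.numeric(p$start_s),
                   end_s = as.numeric(p$end_s),
                   kind = as.character(p$kind),
                   intensity = as.numeric(p$intensity),
                   stringsAsFactors = FALSE)
      }))
    }
  }
  protocol(ph)
}

#' Write a protocol sidecar
#'
#' @param x A [protocol()].
#' @param path Output path; format chosen by extension (`.json` or YAML
#'   otherwise).
#' @return `path`, invisibly.
#' @export
write_protocol <- function(x, path) {
  stopifnot(inherits(x, "protocol"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(phases = x$phases), path, auto_unbox = TRUE,
                         digits = NA)
  } else {
    yaml::write_yaml(list(phases = x$phases), path)
  }
  invisible(path)
}

#' Check that a protocol is consistent with a trace
#'
#' Diagnostic contract: returns a character vector of human-readable
#' findings and never throws. An empty vector means every phase lies
#' within the trace span and saturating pulses / laser flashes do not
#' overlap each other.
#'
#' @param prot A [protocol()].
#' @param tr A [trace()].
#' @return Character vector of findings (empty if consistent).
#' @export
validate_protocol <- function(prot, tr) {
  findings <- character()
  ph <- prot$phases
  t0 <- tr$time[1L]
  t1 <- tr$time[length(tr$time)]
  for (i in seq_len(nrow(ph))) {
    if (ph$start_s[i] < t0 - 1e-12 || ph$end_s[i] > t1 + 1e-12) {
      findings <- c(findings, sprintf(
        "phase %d (%s [%g, %g] s) extends outside trace span [%g, %g] s",
        i, ph$kind[i], ph$start_s[i], ph$end_s[i], t0, t1))
    }
  }
  pulses <- which(ph$kind %in% c("saturating_pulse", "laser_flash"))
  if (length(pulses) > 1L) {
    for (a in seq_along(pulses)[-length(pulses)]) {
      for (b in seq((a + 1L), length(pulses))) {
        i <- pulses[a]; j <- pulses[b]
        if (ph$start_s[j] < ph$end_s[i] && ph$start_s[i] < ph$end_s[j]) {
          findings <- c(findings, sprintf(
            "pulse phases %d and %d overlap ([%g, %g] vs [%g, %g] s)",
            i, j, ph$start_s[i], ph$end_s[i], ph$start_s[j], ph$end_s[j]))
        }
      }
    }
  }
  findings
}

#' Write an analysis report
#'
#' Serializes result records deterministically: stable key order and a
#' fixed float format, so two writes of the same records are
#' byte-identical. JSON or CSV is chosen by file extension.
#'
#' @param records A data.frame (rows = records) or a named list of scalar
#'   values.
#' @param path Output path ending in `.json` or `.csv`.
#' @return `path`, invisibly.
#' @export
write_report <- function(records, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    txt <- jsonlite::toJSON(records, auto_unbox = TRUE, digits = NA,
                            pretty = TRUE, na = "null")
    writeLines(txt, path)
  } else if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- if (is.data.frame(records)) records else
      as.data.frame(records, stringsAsFactors = FALSE)
    if (nrow(df) == 0L && length(df) == 0L) {
      writeLines("", path)
    } else {
      num <- vapply(df, is.numeric, logical(1L))
      df[num] <- lapply(df[num], function(v)
        formatC(v, format = "g", digits = 15))
      utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    }
  } else {
    stop("I/O error: report path must end in .json or .csv", call. = FALSE)
  }
  invisible(path)
}

#' Read a report written by [write_report()]
#'
#' @param path Path to a `.json` or `.csv` report.
#' @return A list (JSON) or data.frame (CSV).
#' @export
read_report <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
}

# Indices of trace samples inside [start, end): half-open phase membership.
.samples_in <- function(tr, start_s, end_s) {
  which(tr$time >= start_s - 1e-12 & tr$time < end_s - 1e-12)
}

# Linear interpolation of a trace at a single time point.
.interp_at <- function(tr, at) {
  if (at < tr$time[1L] || at > tr$time[length(tr$time)]) {
    stop(sprintf("coverage error: time %g s outside trace span", at),
         call. = FALSE)
  }
  stats::approx(tr$time, tr$values, xout = at, rule = 1L)$y
}
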