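#' Construct a flow-volume signal
#'
#' A flow-volume signal is a tibble with columns `time` (s, uniform grid),
#' `flow` (L/s, expiration positive) and `volume` (L, rises with
#' inspiration; arbitrary additive offset), carrying the sampling rate as
#' the `fs` attribute.
#'
#' @param time Numeric vector of sample times in seconds, strictly
#'   increasing with constant step `1/fs`.
#' @param flow Numeric vector of airflow in L/s. Expiration is positive,
#'   inspiration negative.
#' @param volume Numeric vector of lung volume in L, or `NULL` to integrate
#'   it from the flow (see [integrate_flow()]).
#' @param fs Sampling rate in Hz. Defaults to 200.
#'
#' @return A tibble of class `fv_signal` with columns `time`, `flow`,
#'   `volume` and attribute `fs`.
#' @export
#' @examples
#' t <- seq(0, 4, by = 1 / 200)
#' sig <- fv_signal(t, flow = -sin(pi * t / 2), fs = 200)
fv_signal <- function(time, flow, volume = NULL, fs = 200) {
  if (fs <= 0) stop("fs must be positive", call. = FALSE)
  n <- length(time)
  if (length(flow) != n) {
    stop("flow and time must have the same length", call. = FALSE)
  }
  if (anyNA(flow)) {
    stop(sprintf("NaN/NA in flow at row %d", which(is.na(flow))[1]),
         call. = FALSE)
  }
  dt <- diff(time)
  if (n > 1 && any(abs(dt - 1 / fs) > 1e-9)) {
    bad <- which(abs(dt - 1 / fs) > 1e-9)[1]
    stop(sprintf(
      "non-uniform time step: step %d is %.9f s, expected %.9f s",
      bad, dt[bad], 1 / fs), call. = FALSE)
  }
  if (is.null(volume)) {
    volume <- integrate_flow(flow, fs)
  } else if (length(volume) != n) {
    stop("volume must have the same length as time", call. = FALSE)
  }
  out <- tibble::tibble(time = as.numeric(time), flow = as.numeric(flow),
                        volume = as.numeric(volume))
  attr(out, "fs") <- fs
  class(out) <- c("fv_signal", class(out))
  out
}

#' Sampling rate of a flow-volume signal
#' @param signal An `fv_signal`.
#' @return Sampling rate in Hz.
#' @export
signal_fs <- function(signal) {
  fs <- attr(signal, "fs")
  if (is.null(fs)) stop("signal carries no fs attribute", call. = FALSE)
  fs
}

#' Integrate airflow to a volume trace
#'
#' Volume is the cumulative trapezoidal integral of `-flow`, so inspiratory
#' flow (negative by convention) raises volume. `volume[1]` is 0; the
#' absolute level is arbitrary.
#'
#' @param flow Numeric vector of airflow in L/s (expiration positive).
#' @param fs Sampling rate in Hz.
#' @return Numeric volume vector in L, same length as `flow`.
#' @export
#' @examples
#' integrate_flow(rep(-1, 401), fs = 200)[401]  # 2 L inspired in 2 s
integrate_flow <- function(flow, fs) {
  if (fs <= 0) stop("fs must be positive", call. = FALSE)
  if (anyNA(flow) || any(!is.finite(flow))) {
    stop("flow must be finite", call. = FALSE)
  }
  if (length(flow) < 2) return(rep(0, length(flow)))
  as.numeric(pracma::cumtrapz(seq_along(flow) / fs, -flow))
}

#' Read a waveform file
#'
#' Reads a delimited text file with columns `time`, `flow` and optionally
#' `volume` (comma-separated, `.` decimal, header required). When the
#' volume column is absent it is computed with [integrate_flow()].
#'
#' @param path Path to the CSV file.
#' @param fs Declared sampling rate in Hz (default 200). A time grid
#'   inconsistent with `fs` beyond 1e-9 s is an error; resampling is not
#'   supported.
#' @param invert_flow Flip the flow polarity on input, for recordings made
#'   with inspiration positive. Default `FALSE`.
#' @return An [fv_signal()].
#' @export
read_waveform <- function(path, fs = 200, invert_flow = FALSE) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("time", "flow")
  if (!all(need %in% names(df))) {
    stop("waveform file must have columns time, flow[, volume]",
         call. = FALSE)
  }
  flow <- df$flow
  if (anyNA(flow)) {
    stop(sprintf("NaN in flow at row %d of %s", which(is.na(flow))[1], path),
         call. = FALSE)
  }
  if (invert_flow) flow <- -flow
  fv_signal(df$time, flow,
            volume = if ("volume" %in% names(df)) df$volume else NULL,
            fs = fs)
}

#' Write a waveform file
#'
#' @param signal An [fv_signal()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_waveform <- function(signal, path) {
  readr::write_csv(tibble::as_tibble(signal)[, c("time", "flow", "volume")],
                   path, progress = FALSE)
  invisible(path)
}

# Canonical column order for the per-stage results table.
stage_table_cols <- c(
  "stage_label", "work_W", "VT", "fB", "VE", "TI", "TE", "VT_over_TE",
  "IC", "ERV", "IRV_paper", "EFL_present", "EFL_pct_VT", "VE_cap",
  "VE_frac_cap", "VO2", "VCO2"
)

#' Write a per-stage results table
#'
#' One row per exercise stage with fixed column names: stage_label, work_W,
#' VT, fB, VE, TI, TE, VT_over_TE, IC, ERV, IRV_paper, EFL_present,
#' EFL_pct_VT, VE_cap, VE_frac_cap, VO2, VCO2. A round-trip through
#' [read_stage_table()] preserves values to 1e-9.
#'
#' @param records Data frame of stage records (one row per stage).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_stage_table <- function(records, path) {
  if (is.null(records) || nrow(records) == 0) {
    stop("records must be non-empty", call. = FALSE)
  }
  if (anyDuplicated(records$stage_label)) {
    stop("duplicate stage_label in records", call. = FALSE)
  }
  missing_cols <- setdiff(stage_table_cols, names(records))
  for (mc in missing_cols) records[[mc]] <- NA
  readr::write_csv(records[, stage_table_cols], path, progress = FALSE)
  invisible(path)
}

#' Read a per-stage results table written by [write_stage_table()]
#' @param path CSV path.
#' @return A tibble with the stage-table columns.
#' @export
read_stage_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    stage_label = readr::col_character(),
                    EFL_present = readr::col_logical(),
                    .default = readr::col_double()))
}

#' Read a session manifest
#'
#' The manifest is a JSON file annotating one recording session:
#' `participant_id`, `visit` (1 or 2), `stage_windows` (label, t_start,
#' t_end, work_W), `ic_windows` (stage_label, t_start, t_end),
#' `fvc_windows` (phase pre/post, effort_pct, t_start, t_end) and
#' `stage_metabolics` (stage_label, VO2, VCO2). Window tables come back as
#' tibbles.
#'
#' @param path JSON path.
#' @return A list of class `session_manifest`.
#' @export
read_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_manifest(m)
}

#' Write a session manifest
#' @param manifest A `session_manifest` (or compatible list).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

validate_manifest <- function(m) {
  need <- c("participant_id", "visit", "stage_windows", "ic_windows",
            "fvc_windows", "stage_metabolics")
  missing <- setdiff(need, names(m))
  if (length(missing)) {
    stop("manifest missing field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!m$visit %in% c(1L, 2L)) stop("visit must be 1 or 2", call. = FALSE)
  for (f in c("stage_windows", "ic_windows", "fvc_windows",
              "stage_metabolics")) {
    m[[f]] <- tibble::as_tibble(m[[f]])
  }
  sw <- m$stage_windows
  if (nrow(sw) && any(sw$t_end <= sw$t_start)) {
    stop("stage window with t_end <= t_start", call. = FALSE)
  }
  class(m) <- "session_manifest"
  m
}
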