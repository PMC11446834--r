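# Session-level analysis and the two-visit study pipeline.

#' Analysis configuration
#'
#' All pipeline tunables in one validated list. Unknown keys are
#' rejected.
#'
#' @param threshold_pct EFL presence threshold, % of VT (default 5).
#' @param flow_tol Envelope slack for the overlap comparison, L/s. The
#'   pipeline default is 0.05 (the scale of flow noise and placement
#'   error on measured data); [assess_efl()] itself defaults to strict 0.
#' @param n_bins Composite tidal-curve grid points (default 101).
#' @param min_VT Artifact-breath inspired-volume floor, L (default 0.10).
#' @param hysteresis_flow Breath-boundary hysteresis, L/s (default 0.05).
#' @param mefv_smoothing Moving-average span applied to the measured MEFV
#'   envelope before differentiation (default 5; set 0 for analytic
#'   curves).
#' @param tidal_smoothing Moving-average span for tidal flow (default 0).
#' @param icc_form `"ICC2_1"` or `"ICC3_1"`.
#' @param vecap_ti_mode `"measured"` or `"fixed_fraction"`.
#' @param vecap_ti_fraction Duty cycle for the fixed-fraction mode.
#' @param tidal_window_s Tidal analysis window length, s (default 30).
#' @return A named list of class `efl_config`.
#' @export
efl_config <- function(threshold_pct = 5, flow_tol = 0.05, n_bins = 101,
                       min_VT = 0.10, hysteresis_flow = 0.05,
                       mefv_smoothing = 5, tidal_smoothing = 0,
                       icc_form = c("ICC2_1", "ICC3_1"),
                       vecap_ti_mode = c("measured", "fixed_fraction"),
                       vecap_ti_fraction = 0.45, tidal_window_s = 30) {
  cfg <- list(threshold_pct = threshold_pct, flow_tol = flow_tol,
              n_bins = n_bins, min_VT = min_VT,
              hysteresis_flow = hysteresis_flow,
              mefv_smoothing = mefv_smoothing,
              tidal_smoothing = tidal_smoothing,
              icc_form = match.arg(icc_form),
              vecap_ti_mode = match.arg(vecap_ti_mode),
              vecap_ti_fraction = vecap_ti_fraction,
              tidal_window_s = tidal_window_s)
  class(cfg) <- "efl_config"
  cfg
}

#' Extract a graded FVC maneuver from a recording window
#'
#' Takes the samples from the volume maximum (total lung capacity) to the
#' window end as the forced expiration. The volume axis is re-anchored by
#' [build_mefv()], so only relative volume matters here.
#'
#' @param signal An [fv_signal()].
#' @param t_start,t_end Window bounds, s.
#' @param phase,effort_pct Labels stored on the maneuver.
#' @return An [fvc_maneuver()] with a time column.
#' @export
extract_maneuver <- function(signal, t_start, t_end, phase = "pre",
                             effort_pct = 100) {
  seg <- slice_window(signal, c(t_start, t_end))
  i0 <- which.max(seg$volume)
  n <- nrow(seg)
  if (i0 >= n - 1) stop("no expiration found in FVC window", call. = FALSE)
  v <- seg$volume[i0:n]
  fvc_maneuver(volume_above_RV = v - v[length(v)],
               exp_flow = pmax(seg$flow[i0:n], 0),
               phase = phase, effort_pct = effort_pct,
               time = seg$time[i0:n] - seg$time[i0])
}

#' Analyze one recording session
#'
#' Runs the full per-visit pipeline: maneuver extraction and MEFV
#' envelope construction, spirometry indices and slope ratio, then per
#' stage drift correction, breath segmentation, composite averaging, IC
#' and operating lung volumes, tidal-curve placement, EFL assessment and
#' ventilatory capacity.
#'
#' @param signal An [fv_signal()] covering the whole session, or an
#'   `efl_session` from [gen_session()] (in which case `manifest` is
#'   taken from it).
#' @param manifest A `session_manifest`.
#' @param config An [efl_config()].
#' @return A list of class `efl_analysis`: `stage_table` (one row per
#'   stage), `envelope` (`mefv_curve`), `spirometry`, `SR_mean`,
#'   `placed` (named list of `placed_tidal`), `manifest`.
#' @export
analyze_session <- function(signal, manifest = NULL,
                            config = efl_config()) {
  if (inherits(signal, "efl_session")) {
    manifest <- signal$manifest
    signal <- signal$signal
  }
  if (is.null(manifest)) stop("manifest required", call. = FALSE)
  if (nrow(manifest$fvc_windows) == 0) {
    stop("manifest has no fvc_windows: cannot build the MEFV envelope",
         call. = FALSE)
  }
  mans <- purrr::pmap(manifest$fvc_windows,
                      function(phase, effort_pct, t_start, t_end) {
    extract_maneuver(signal, t_start, t_end, phase, effort_pct)
  })
  envelope <- build_mefv(mans, smoothing = config$mefv_smoothing)
  FVC <- attr(envelope, "FVC")
  spans <- vapply(mans, function(m) attr(m, "FVC_this"), numeric(1))
  spiro <- spirometry_indices(mans[[which.max(spans)]])
  SR_mean <- slope_ratio(envelope)
  metab <- manifest$stage_metabolics
  rows <- purrr::pmap(manifest$stage_windows,
                      function(label, t_start, t_end, work_W) {
    icw <- manifest$ic_windows[manifest$ic_windows$stage_label == label, ]
    if (nrow(icw) == 0) {
      stop(sprintf("no ic_window for stage %s", label), call. = FALSE)
    }
    tidal_win <- c(max(t_start, t_end - config$tidal_window_s), t_end)
    drift_win <- c(tidal_win[1], icw$t_end[1])
    dc <- correct_drift(signal, drift_win,
                        hysteresis_flow = config$hysteresis_flow)
    breaths <- segment_breaths(dc$signal, tidal_win,
                               min_VT = config$min_VT,
                               hysteresis_flow = config$hysteresis_flow)
    vent <- ventilatory_params(breaths)
    tidal <- composite_average(breaths, n_bins = config$n_bins,
                               smoothing = config$tidal_smoothing)
    ic <- measure_ic(dc$signal, c(icw$t_start[1], icw$t_end[1]), breaths)
    vols <- derive_volumes(min(ic$IC, FVC), FVC, attr(tidal, "VT"))
    placed <- place_tidal_curve(tidal, vols, envelope)
    efl <- assess_efl(placed, threshold_pct = config$threshold_pct,
                      flow_tol = config$flow_tol)
    vc <- ve_cap(envelope, attr(tidal, "VT"), vols$ERV, vent$TI,
                 ti_mode = config$vecap_ti_mode,
                 ti_fraction = config$vecap_ti_fraction)
    mrow <- metab[metab$stage_label == label, ]
    list(placed = placed, record = tibble::tibble(
      stage_label = label, work_W = work_W,
      VT = vent$VT, fB = vent$fB, VE = vent$VE, TI = vent$TI,
      TE = vent$TE, VT_over_TE = vent$VT_over_TE,
      IC = ic$IC, ERV = vols$ERV, IRV_paper = vols$IRV_paper,
      EFL_present = efl$EFL_present, EFL_pct_VT = efl$EFL_pct_VT,
      VE_cap = as.numeric(vc), VE_frac_cap = 100 * vent$VE / as.numeric(vc),
      VO2 = if (nrow(mrow)) mrow$VO2[1] else NA_real_,
      VCO2 = if (nrow(mrow)) mrow$VCO2[1] else NA_real_,
      drift_slope = dc$drift_slope))
  })
  stage_table <- dplyr::bind_rows(purrr::map(rows, "record"))
  placed <- stats::setNames(purrr::map(rows, "placed"),
                            stage_table$stage_label)
  structure(list(stage_table = stage_table, envelope = envelope,
                 spirometry = spiro, SR_mean = SR_mean, placed = placed,
                 manifest = manifest),
            class = "efl_analysis")
}

#' @export
print.efl_analysis <- function(x, ...) {
  cat("EFL session analysis:", x$manifest$participant_id, "visit",
      x$manifest$visit, "\n")
  cat(sprintf("FVC %.2f L, PEF %.2f L/s, SR %.2f\n",
              attr(x$envelope, "FVC"), attr(x$envelope, "PEF"), x$SR_mean))
  print(x$stage_table, ...)
  invisible(x)
}

#' Tidy a session analysis
#' @param x An `efl_analysis`.
#' @param ... Unused.
#' @return The per-stage results tibble.
#' @export
tidy.efl_analysis <- function(x, ...) x$stage_table

#' Glance at a session analysis
#' @param x An `efl_analysis`.
#' @param ... Unused.
#' @return One-row tibble with session-level summaries.
#' @export
glance.efl_analysis <- function(x, ...) {
  tibble::tibble(
    participant_id = x$manifest$participant_id,
    visit = x$manifest$visit,
    FVC = attr(x$envelope, "FVC"), PEF = attr(x$envelope, "PEF"),
    FEV1 = x$spirometry$FEV1, FEF25_75 = x$spirometry$FEF25_75,
    SR_mean = x$SR_mean,
    n_stages = nrow(x$stage_table),
    n_efl_stages = sum(x$stage_table$EFL_present))
}

#' Run the full two-visit pipeline
#'
#' Analyzes every session of a study, then computes between-day
#' repeatability at peak exercise (last completed stage per visit) and at
#' matched minute ventilation (stage pair above 75% of each visit's peak
#' VO2 minimizing the VE difference).
#'
#' @param study An `efl_study` from [gen_two_visit_study()], or a list of
#'   `efl_session` objects.
#' @param config An [efl_config()].
#' @param params Continuous parameters to include in the repeatability
#'   reports.
#' @return A list of class `efl_pipeline`: `stage_tables` (all stages,
#'   all sessions), `peak_pairs`, `matched_pairs` (one row per
#'   participant), `peak_report`, `matched_report` (`repeat_report`),
#'   `analyses`.
#' @export
run_pipeline <- function(study, config = efl_config(),
                         params = c("VT", "fB", "VE", "IC", "ERV",
                                    "IRV_paper", "VT_over_TE", "VE_cap",
                                    "VE_frac_cap", "EFL_pct_VT")) {
  sessions <- if (inherits(study, "efl_study")) study$sessions else study
  analyses <- purrr::map(sessions, analyze_session, config = config)
  stage_tables <- purrr::map_dfr(analyses, function(a) {
    dplyr::bind_cols(tibble::tibble(
      participant_id = a$manifest$participant_id,
      visit = a$manifest$visit), a$stage_table)
  })
  pids <- unique(stage_tables$participant_id)
  mk_pairs <- function(get_rows) {
    purrr::map_dfr(pids, function(pid) {
      v1 <- stage_tables[stage_tables$participant_id == pid &
                           stage_tables$visit == 1, ]
      v2 <- stage_tables[stage_tables$participant_id == pid &
                           stage_tables$visit == 2, ]
      if (nrow(v1) == 0 || nrow(v2) == 0) return(NULL)
      rows <- get_rows(v1, v2)
      if (is.null(rows)) return(NULL)
      r1 <- rows[[1]]; r2 <- rows[[2]]
      out <- tibble::tibble(participant_id = pid)
      for (p in params) {
        out[[paste0(p, "_1")]] <- r1[[p]]
        out[[paste0(p, "_2")]] <- r2[[p]]
      }
      out$EFL_1 <- r1$EFL_present
      out$EFL_2 <- r2$EFL_present
      out$stage_1 <- r1$stage_label
      out$stage_2 <- r2$stage_label
      out
    })
  }
  peak_pairs <- mk_pairs(function(v1, v2) {
    list(v1[nrow(v1), ], v2[nrow(v2), ])
  })
  matched_pairs <- mk_pairs(function(v1, v2) {
    m <- tryCatch(match_ve_stages(v1, v2), error = function(e) NULL)
    if (is.null(m)) return(NULL)
    list(v1[v1$stage_label == m$stage1, ][1, ],
         v2[v2$stage_label == m$stage2, ][1, ])
  })
  structure(list(
    stage_tables = stage_tables,
    peak_pairs = peak_pairs, matched_pairs = matched_pairs,
    peak_report = repeatability_report(
      dplyr::select(peak_pairs, -dplyr::starts_with("stage_"),
                    -"participant_id"),
      params = params, icc_form = config$icc_form),
    matched_report = repeatability_report(
      dplyr::select(matched_pairs, -dplyr::starts_with("stage_"),
                    -"participant_id"),
      params = params, icc_form = config$icc_form),
    analyses = analyses),
    class = "efl_pipeline")
}

#' @export
print.efl_pipeline <- function(x, ...) {
  cat("Two-visit EFL pipeline:", length(unique(
    x$stage_tables$participant_id)), "participants,",
    nrow(x$stage_tables), "stage records\n")
  cat("\nPeak-exercise repeatability:\n"); print(x$peak_report)
  cat("\nMatched-VE repeatability:\n"); print(x$matched_report)
  invisible(x)
}
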