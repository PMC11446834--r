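# EFL detection: tidal-loop placement inside the MEFV envelope, overlap
# quantification, ventilatory capacity, and matched-VE stage pairing.

#' Place a composite tidal curve inside the MEFV envelope
#'
#' The tidal curve's relative volume axis (0..VT above end-expiratory lung
#' volume) is shifted onto the absolute above-RV axis by the ERV from the
#' corresponding IC maneuver; the envelope is sampled by linear
#' interpolation at the same volumes.
#'
#' @param tidal A `tidal_fv` from [composite_average()].
#' @param vols One-row tibble from [derive_volumes()] (needs
#'   `EELV_above_RV`).
#' @param curve An `mefv_curve` from [build_mefv()].
#' @param eilv_slack Tolerated excess of end-inspiratory volume over FVC
#'   before erroring (L, default 0.05); within the slack the placement is
#'   clipped to FVC with a warning.
#' @return A `placed_tidal` tibble with columns `abs_volume` (L above
#'   RV), `exp_flow` and `envelope_flow` (L/s), plus attributes `VT`,
#'   `TI`, `TE`, `ERV`, `FVC`.
#' @export
place_tidal_curve <- function(tidal, vols, curve, eilv_slack = 0.05) {
  ERV <- vols$EELV_above_RV[1]
  if (ERV < 0) stop("negative ERV", call. = FALSE)
  FVC <- attr(curve, "FVC")
  VT <- attr(tidal, "VT")
  abs_v <- tidal$rel_volume + ERV
  over <- max(abs_v) - FVC
  if (over > eilv_slack) {
    stop(sprintf("end-inspiratory volume exceeds FVC by %.3f L", over),
         call. = FALSE)
  }
  if (over > 0) {
    warning(sprintf(
      "end-inspiratory volume exceeds FVC by %.3f L; clipping to FVC",
      over), call. = FALSE)
    abs_v <- pmin(abs_v, FVC)
  }
  out <- tibble::tibble(abs_volume = abs_v,
                        exp_flow = tidal$exp_flow,
                        envelope_flow = mefv_flow_at(curve, abs_v))
  attr(out, "VT") <- VT
  attr(out, "TI") <- attr(tidal, "TI")
  attr(out, "TE") <- attr(tidal, "TE")
  attr(out, "ERV") <- ERV
  attr(out, "FVC") <- FVC
  class(out) <- c("placed_tidal", class(out))
  out
}

#' Assess expiratory flow limitation
#'
#' A grid point is flow-limited when tidal expiratory flow meets or
#' exceeds the envelope flow at the same lung volume (within `flow_tol`).
#' The flow-limited volume is the sum of the volume-bin widths of limited
#' points (half-width bins at the grid ends, so the widths total VT), and
#' EFL is present when it covers at least `threshold_pct` of tidal volume.
#'
#' @param placed A `placed_tidal` from [place_tidal_curve()].
#' @param threshold_pct Percent of VT that must overlap for EFL to be
#'   called present (default 5).
#' @param flow_tol Slack in L/s subtracted from the envelope before the
#'   comparison (default 0, i.e. strict meets-or-exceeds).
#' @return A one-row tibble of class `efl_result`: `EFL_present`,
#'   `EFL_pct_VT`, `overlap_volume` (L).
#' @export
assess_efl <- function(placed, threshold_pct = 5, flow_tol = 0) {
  v <- placed$abs_volume
  n <- length(v)
  limited <- placed$exp_flow >= placed$envelope_flow - flow_tol
  # bin widths: trapezoid weights so widths sum to the volume span (= VT)
  dv <- diff(v)
  w <- c(dv[1] / 2, (dv[-1] + dv[-(n - 1)]) / 2, dv[n - 1] / 2)
  overlap <- sum(w[limited])
  VT <- attr(placed, "VT")
  pct <- 100 * overlap / VT
  out <- tibble::tibble(EFL_present = pct >= threshold_pct,
                        EFL_pct_VT = pct, overlap_volume = overlap)
  class(out) <- c("efl_result", class(out))
  out
}

#' Ventilatory capacity from the MEFV envelope
#'
#' The theoretical maximum minute ventilation for the current tidal-volume
#' placement: the minimal expiratory time is the volume integral of
#' 1/max_flow across the tidal range (ERV to ERV + VT; envelope flows
#' below `flow_floor` are floored to keep the integral finite), and
#' VE,CAP = 60 * VT / (TI + TE_min) using the stage's measured
#' inspiratory time.
#'
#' @param curve An `mefv_curve`.
#' @param VT Tidal volume, L.
#' @param ERV Expiratory reserve volume (= EELV above RV), L.
#' @param TI Measured inspiratory time, s. Alternatively set
#'   `ti_mode = "fixed_fraction"` to use `ti_fraction * (TI + TE_min)`
#'   implicitly, i.e. TI solved from a fixed duty cycle.
#' @param flow_floor Minimum envelope flow (L/s) used in the integral
#'   (default 0.05).
#' @param ti_mode `"measured"` (default) or `"fixed_fraction"`.
#' @param ti_fraction Duty cycle TI/TTOT used when
#'   `ti_mode = "fixed_fraction"` (default 0.45).
#' @return `VE_cap` in L/min (single number, with `TE_min` as attribute).
#' @export
ve_cap <- function(curve, VT, ERV, TI, flow_floor = 0.05,
                   ti_mode = c("measured", "fixed_fraction"),
                   ti_fraction = 0.45) {
  ti_mode <- match.arg(ti_mode)
  lo <- ERV; hi <- ERV + VT
  v <- curve$volume_above_RV
  inside <- v > lo - 1e-12 & v < hi + 1e-12
  vv <- sort(unique(c(lo, v[inside], hi)))
  fl <- mefv_flow_at(curve, vv)
  frac_zero <- mean(fl <= 1e-9)
  if (frac_zero > 0.20) {
    stop("envelope flow is zero across >20% of the tidal range; ",
         "placement inconsistent with the MEFV curve", call. = FALSE)
  }
  TE_min <- pracma::trapz(vv, 1 / pmax(fl, flow_floor))
  VE_cap <- if (ti_mode == "measured") {
    60 * VT / (TI + TE_min)
  } else {
    # TE_min is (1 - ti_fraction) of TTOT
    60 * VT / (TE_min / (1 - ti_fraction))
  }
  structure(VE_cap, TE_min = TE_min)
}

#' Pair matched-ventilation stages across two visits
#'
#' Among stages at intensities above 75% of each visit's peak oxygen
#' uptake, returns the visit-1/visit-2 stage pair with the smallest
#' absolute difference in minute ventilation. Ties break toward higher
#' work rate, then visit-1 stage order.
#'
#' @param visit1,visit2 Stage tables (one row per stage) with at least
#'   `stage_label`, `VE`, `VO2`, `work_W`.
#' @param peak_VO2_1,peak_VO2_2 Peak VO2 per visit (L/min); default the
#'   max over that visit's stages.
#' @param frac Eligibility threshold as a fraction of peak VO2
#'   (default 0.75).
#' @return A one-row tibble: `stage1`, `stage2` (labels), `VE1`, `VE2`,
#'   `dVE`.
#' @export
match_ve_stages <- function(visit1, visit2,
                            peak_VO2_1 = max(visit1$VO2, na.rm = TRUE),
                            peak_VO2_2 = max(visit2$VO2, na.rm = TRUE),
                            frac = 0.75) {
  e1 <- visit1[visit1$VO2 > frac * peak_VO2_1, , drop = FALSE]
  e2 <- visit2[visit2$VO2 > frac * peak_VO2_2, , drop = FALSE]
  if (nrow(e1) == 0 || nrow(e2) == 0) {
    stop("no stage above the peak-VO2 fraction on one of the visits",
         call. = FALSE)
  }
  grid <- tidyr::expand_grid(i = seq_len(nrow(e1)), j = seq_len(nrow(e2)))
  grid$dVE <- abs(e1$VE[grid$i] - e2$VE[grid$j])
  grid$work <- e1$work_W[grid$i] + e2$work_W[grid$j]
  grid <- grid[order(grid$dVE, -grid$work, grid$i, grid$j), ]
  best <- grid[1, ]
  tibble::tibble(stage1 = e1$stage_label[best$i],
                 stage2 = e2$stage_label[best$j],
                 VE1 = e1$VE[best$i], VE2 = e2$VE[best$j],
                 dVE = best$dVE)
}
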