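# Inspiratory capacity and operating lung volumes.

#' Measure inspiratory capacity from an IC-maneuver window
#'
#' Baseline end-expiratory volume (EEV) is the mean of the end-expiratory
#' volumes of the tidal breaths preceding the maneuver; IC is the
#' inspiratory excursion from that baseline to the extreme volume reached
#' during the maneuver. Internally inspiration raises volume, so the
#' extreme is a maximum; set `nadir = TRUE` for traces recorded with the
#' opposite polarity, where the maneuver extreme is the trace minimum.
#' Drift correction must already have been applied over the combined
#' tidal + IC window.
#'
#' @param signal A drift-corrected [fv_signal()].
#' @param ic_window Length-2 numeric `(t_start, t_end)` covering the
#'   maneuver.
#' @param baseline_breaths A `breath_table` of the preceding tidal breaths
#'   (>= 3 needed for the baseline).
#' @param nadir Logical; `TRUE` if the maneuver extreme is the volume
#'   minimum on this trace's polarity. Default `FALSE`.
#' @return A list with `IC` (L), `baseline_EEV` (L, on the trace's
#'   arbitrary offset) and `submaximal` (logical; `TRUE` flags a maneuver
#'   excursion smaller than the last tidal breath, i.e. a suspect effort).
#' @export
measure_ic <- function(signal, ic_window, baseline_breaths, nadir = FALSE) {
  if (is.null(baseline_breaths) || nrow(baseline_breaths) < 3) {
    stop("need >= 3 baseline end-expiratory points", call. = FALSE)
  }
  eev <- mean(baseline_breaths$EEV_end)
  man <- slice_window(signal, ic_window)
  extreme <- if (nadir) min(man$volume) else max(man$volume)
  IC <- abs(extreme - eev)
  last_vt <- baseline_breaths$VT_insp[nrow(baseline_breaths)]
  submax <- IC < last_vt
  if (submax) {
    warning("submaximal IC? maneuver excursion smaller than last tidal VT",
            call. = FALSE)
  }
  list(IC = IC, baseline_EEV = eev, submaximal = submax)
}

#' Derive operating lung volumes
#'
#' ERV = FVC - IC, and the corresponding tidal volume added to ERV gives
#' the quantity reported here as `IRV_paper` (= ERV + VT). Note this
#' equals end-inspiratory lung volume above residual volume (EILV), not
#' the conventional IRV = IC - VT; both aliases are returned so
#' downstream code is unambiguous.
#'
#' @param IC Inspiratory capacity, L.
#' @param FVC Forced vital capacity, L.
#' @param VT Tidal volume, L.
#' @return A one-row tibble: `IC`, `ERV`, `IRV_paper`, `EELV_above_RV`
#'   (= ERV), `EILV_above_RV` (= ERV + VT), `IRV_conventional`
#'   (= IC - VT).
#' @export
derive_volumes <- function(IC, FVC, VT) {
  if (IC <= 0 || VT <= 0) stop("IC and VT must be positive", call. = FALSE)
  if (IC > FVC + 1e-9) {
    stop("IC exceeds FVC: inconsistent volume calibration", call. = FALSE)
  }
  ERV <- FVC - IC
  if (VT > IC) {
    warning("VT exceeds IC: end-inspiratory volume above TLC",
            call. = FALSE)
  }
  tibble::tibble(IC = IC, ERV = ERV, IRV_paper = ERV + VT,
                 EELV_above_RV = ERV, EILV_above_RV = ERV + VT,
                 IRV_conventional = IC - VT)
}
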