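# MEFV envelope construction from graded FVC maneuvers, spirometry
# indices, and slope-ratio curvature.

#' Construct a graded FVC maneuver record
#'
#' A maneuver is a tibble of samples along a forced expiration, anchored at
#' total lung capacity: `volume_above_RV` starts at its maximum and falls,
#' `exp_flow` is the expiratory flow (L/s, >= 0 after onset). A `time`
#' column (s from expiratory onset) is required for spirometry indices but
#' optional for envelope construction.
#'
#' @param volume_above_RV Numeric, L above residual volume, non-increasing.
#' @param exp_flow Numeric, L/s.
#' @param phase `"pre"` or `"post"` exercise.
#' @param effort_pct Nominal effort label in percent (20-100).
#' @param time Optional numeric, s from expiratory onset.
#' @return A tibble of class `fvc_maneuver` with attributes `phase`,
#'   `effort_pct` and `FVC_this` (total volume span).
#' @export
fvc_maneuver <- function(volume_above_RV, exp_flow, phase = "pre",
                         effort_pct = 100, time = NULL) {
  stopifnot(length(volume_above_RV) == length(exp_flow))
  out <- tibble::tibble(volume_above_RV = as.numeric(volume_above_RV),
                        exp_flow = as.numeric(exp_flow))
  if (!is.null(time)) out$time <- as.numeric(time)
  attr(out, "phase") <- phase
  attr(out, "effort_pct") <- effort_pct
  attr(out, "FVC_this") <- max(volume_above_RV) - min(volume_above_RV)
  class(out) <- c("fvc_maneuver", class(out))
  out
}

#' Build the maximal expiratory flow-volume envelope
#'
#' The MEFV curve is the pointwise maximum of expiratory flow over all
#' graded FVC maneuvers, on a lung-volume grid in 0.01 L steps above
#' residual volume. Maneuvers are anchored at total lung capacity: each
#' maneuver's starting volume is aligned to the session FVC (the largest
#' volume span over the supplied maneuvers), so submaximal efforts that
#' out-flow the maximal effort at low lung volumes (reduced thoracic gas
#' compression) contribute there. Volumes covered by no maneuver get flow
#' 0 (the residual-volume endpoint).
#'
#' @param maneuvers A list of [fvc_maneuver()] objects (pre and post
#'   exercise efforts of one visit; envelopes are never merged across
#'   visits).
#' @param smoothing Optional odd moving-average span applied to the
#'   envelope after the pointwise max; 0 (default) leaves it raw.
#' @return An `mefv_curve` tibble with columns `volume_above_RV` (0 to FVC
#'   in exact 0.01 L steps) and `max_flow`, and attributes `FVC`, `PEF`
#'   and `n_maneuvers`.
#' @export
build_mefv <- function(maneuvers, smoothing = 0) {
  if (length(maneuvers) == 0) stop("no maneuvers supplied", call. = FALSE)
  if (length(maneuvers) < 8) {
    rlang::inform(paste0("fewer than 8 maneuvers supplied (",
                         length(maneuvers),
                         "); envelope may underestimate maximal flows"),
                  class = "eflkit_few_maneuvers")
  }
  spans <- vapply(maneuvers, function(m) attr(m, "FVC_this"), numeric(1))
  keep <- vapply(maneuvers, function(m) {
    any(diff(m$volume_above_RV) < 0)
  }, logical(1))
  if (!all(keep)) {
    warning(sprintf("%d maneuver(s) with no expiration excluded",
                    sum(!keep)), call. = FALSE)
    maneuvers <- maneuvers[keep]
    spans <- spans[keep]
    if (!length(maneuvers)) stop("no usable maneuvers", call. = FALSE)
  }
  FVC <- max(spans)
  grid <- seq(0, floor(FVC / 0.01 + 1e-9)) * 0.01
  max_flow <- rep(0, length(grid))
  for (m in maneuvers) {
    # anchor at TLC: shift so the maneuver's top volume sits at FVC
    v <- m$volume_above_RV - max(m$volume_above_RV) + FVC
    f <- pmax(m$exp_flow, 0)
    # enforce monotone volume for interpolation (flow vs falling volume)
    ord <- order(v)
    v <- v[ord]; f <- f[ord]
    ok <- c(TRUE, diff(v) > 1e-12)
    v <- v[ok]; f <- f[ok]
    if (length(v) < 2) next
    inside <- grid >= min(v) - 1e-12 & grid <= max(v) + 1e-12
    if (!any(inside)) next
    fi <- stats::approx(v, f, xout = grid[inside])$y
    max_flow[inside] <- pmax(max_flow[inside], fi, na.rm = TRUE)
  }
  if (smoothing >= 3) {
    k <- as.integer(smoothing); if (k %% 2 == 0) k <- k + 1L
    sm <- stats::filter(max_flow, rep(1 / k, k), sides = 2)
    max_flow <- ifelse(is.na(sm), max_flow, as.numeric(sm))
  }
  out <- tibble::tibble(volume_above_RV = grid, max_flow = max_flow)
  attr(out, "FVC") <- FVC
  attr(out, "PEF") <- max(max_flow)
  attr(out, "n_maneuvers") <- length(maneuvers)
  class(out) <- c("mefv_curve", class(out))
  out
}

#' Interpolate envelope flow at arbitrary lung volumes
#' @param curve An `mefv_curve`.
#' @param v Volumes above RV (L).
#' @return Envelope flow (L/s) at `v`; 0 outside the grid's low end,
#'   flat-extended at the top.
#' @export
mefv_flow_at <- function(curve, v) {
  stats::approx(curve$volume_above_RV, curve$max_flow, xout = v,
                rule = 2)$y
}

#' Spirometry indices from a timed FVC maneuver
#'
#' @param maneuver An [fvc_maneuver()] with a `time` column (s from
#'   expiratory onset).
#' @return A one-row tibble: `FVC` (L, total expired volume), `FEV1` (L,
#'   volume expired in the first 1.000 s, linear interpolation at t = 1),
#'   `PEF` (L/s) and `FEF25_75` (L/s, mean flow over the middle half of
#'   FVC).
#' @export
spirometry_indices <- function(maneuver) {
  if (!"time" %in% names(maneuver)) {
    stop("maneuver needs a time column for spirometry indices",
         call. = FALSE)
  }
  t <- maneuver$time - maneuver$time[1]
  if (max(t) < 1) {
    stop("maneuver shorter than 1 s: FEV1 undefined", call. = FALSE)
  }
  v0 <- maneuver$volume_above_RV[1]
  expired <- v0 - maneuver$volume_above_RV
  FVC <- max(expired)
  FEV1 <- stats::approx(t, expired, xout = 1)$y
  PEF <- max(maneuver$exp_flow)
  t25 <- stats::approx(expired, t, xout = 0.25 * FVC, ties = "ordered")$y
  t75 <- stats::approx(expired, t, xout = 0.75 * FVC, ties = "ordered")$y
  tibble::tibble(FVC = FVC, FEV1 = FEV1, PEF = PEF,
                 FEF25_75 = 0.5 * FVC / (t75 - t25))
}

#' Slope ratio of the MEFV descending limb
#'
#' The slope ratio (SR) at a point on the MEFV curve is the ratio of the
#' instantaneous tangent slope (dV'/dV, central finite difference on the
#' 0.01 L grid) to the chord slope from the point to residual volume,
#' where flow is zero (i.e. flow/volume). SR is 1 for a straight
#' descending limb through RV, above 1 for a concave (curvilinear) limb.
#' The mean is taken over the effort-independent portion, 20-80% of FVC.
#'
#' @param curve An `mefv_curve`.
#' @param lo,hi Fractions of FVC bounding the averaged region (defaults
#'   0.20 and 0.80).
#' @return `SR_mean`, a single number.
#' @export
slope_ratio <- function(curve, lo = 0.20, hi = 0.80) {
  FVC <- attr(curve, "FVC")
  v <- curve$volume_above_RV
  f <- curve$max_flow
  idx <- which(v >= lo * FVC - 1e-9 & v <= hi * FVC + 1e-9)
  if (length(idx) < 10) stop("fewer than 10 usable grid points",
                             call. = FALSE)
  n <- length(v)
  tangent <- vapply(idx, function(i) {
    if (i == 1) (f[2] - f[1]) / (v[2] - v[1])
    else if (i == n) (f[n] - f[n - 1]) / (v[n] - v[n - 1])
    else (f[i + 1] - f[i - 1]) / (v[i + 1] - v[i - 1])
  }, numeric(1))
  chord <- f[idx] / v[idx]
  use <- chord >= 0.01
  if (sum(use) < 10) stop("fewer than 10 usable grid points",
                          call. = FALSE)
  mean(tangent[use] / chord[use])
}
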