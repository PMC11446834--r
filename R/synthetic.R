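# Synthetic two-visit incremental-exercise study generator.
#
# Every session is built from a participant's "true" physiology: a
# power-law MEFV envelope flow(v) = PEF * (v/FVC)^sr_shape (so the
# slope-ratio of the descending limb equals sr_shape exactly), tidal
# breathing with half-sine inspiration and an early-peaking expiratory
# limb, linear volume drift, Gaussian flow noise, an IC maneuver at each
# stage end, and graded FVC efforts before and after exercise whose
# pointwise maximum reproduces the true envelope. EFL is induced by
# clipping the desired expiratory flow at the envelope; the clipped
# fraction of tidal volume is calibrated to a target so ground truth is
# known exactly.

# deterministic sub-seed derivation (all arithmetic < 2^53, result < 2^31)
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  h <- 0
  for (p in parts) h <- (h * 31 + (round(p * 1e6) %% 2147483647)) %% 2147483647
  as.integer(h)
}

# hash of a numeric parameter vector: keys the visit measurement-noise
# stream, so identical parameters reproduce identical recordings
param_hash <- function(x) {
  h <- 7
  for (v in x) h <- (h * 131 + (abs(round(v * 1e5)) %% 1048573)) %% 2147483647
  as.integer(h)
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  pmin(pmax(x, lo), hi)
}

true_envelope_flow <- function(v, FVC, PEF, sr_shape) {
  ifelse(v <= 0, 0, PEF * (pmax(v, 0) / FVC)^sr_shape)
}

#' Synthetic participant parameters
#'
#' Draws one participant's true physiology from priors chosen to be
#' physiologic for healthy adults (FVC ~ 4.9 +/- 1.0 L, peak tidal volume
#' ~ 49% of FVC, peak breathing frequency ~ 46/min, peak work ~ 210 W in
#' 20 W steps, end-expiratory lung volume ~ 36% of FVC at peak). The EFL
#' propensity is a latent normal truncated at zero, giving ~38% of
#' participants a positive peak overlap target.
#'
#' @param rng_seed Integer seed for this participant's parameter draw.
#' @return A list of class `participant_params`.
#' @export
participant_params <- function(rng_seed) {
  set.seed(rng_seed)
  FVC <- rtrunc_norm(1, 4.88, 0.99, 3.0, 7.5)
  PEF <- rtrunc_norm(1, 9.5, 1.3, 6.5, 13.0)
  sr_shape <- rtrunc_norm(1, 1.25, 0.2, 0.85, 1.9)
  peak_work <- round(rtrunc_norm(1, 211, 51, 100, 320) / 20) * 20
  eelv_frac_rest <- rtrunc_norm(1, 0.43, 0.04, 0.33, 0.52)
  eelv_frac_peak <- rtrunc_norm(1, 0.36, 0.04, 0.27, 0.46)
  VT_peak <- min(rtrunc_norm(1, 0.49, 0.05, 0.35, 0.60) * FVC,
                 0.92 * (1 - eelv_frac_peak) * FVC, 3.4)
  # ventilatory demand is drawn directly so VE sits near ~70% of
  # capacity, as in healthy adults; breathing frequency follows
  VE_peak <- rtrunc_norm(1, 105, 20, 65, 150)
  fB_peak <- pmin(pmax(VE_peak / VT_peak, 30), 60)
  VO2_peak <- rtrunc_norm(1, 3.35, 0.88, 1.8, 5.5)
  efl_latent <- stats::rnorm(1, -10, 48)
  list(
    FVC_true = FVC, PEF_true = PEF, sr_shape = sr_shape,
    peak_work = peak_work, VT_rest = 0.8, VT_peak = VT_peak,
    fB_rest = 14, fB_peak = fB_peak,
    eelv_frac_rest = eelv_frac_rest, eelv_frac_peak = eelv_frac_peak,
    VO2_rest = 0.35, VO2_peak = VO2_peak,
    TI_fraction = 0.45,
    drift_rate = stats::runif(1, -0.004, 0.004),
    noise_sd_flow = 0.02,
    efl_target_pct = min(max(efl_latent, 0), 60)
  ) |> structure(class = "participant_params")
}

# per-stage schedule from participant params (rest + 20 W steps)
stage_schedule <- function(p) {
  works <- c(0, seq(20, p$peak_work, by = 20))
  frac <- works / p$peak_work
  tibble::tibble(
    stage_label = c("rest", paste0("W", works[-1])),
    work_W = works,
    VT = p$VT_rest + (p$VT_peak - p$VT_rest) * frac^0.9,
    fB = p$fB_rest + (p$fB_peak - p$fB_rest) * frac^1.1,
    eelv = (p$eelv_frac_rest +
              (p$eelv_frac_peak - p$eelv_frac_rest) * frac) * p$FVC_true,
    VO2 = p$VO2_rest + (p$VO2_peak - p$VO2_rest) * frac,
    VCO2 = (p$VO2_rest + (p$VO2_peak - p$VO2_rest) * frac) *
      (0.82 + 0.30 * frac),
    # EFL builds up over the top of the ramp only
    efl_target = p$efl_target_pct * pmax(0, (frac - 0.55) / 0.45)^2
  )
}

# early-peaking expiratory flow shape on the expired-volume fraction
# axis: fast rise, gently decaying plateau, linear terminal fall. Finite
# end slopes keep the breath's expiratory time close to its volume-mean
# prediction (no heavy harmonic tails).
exp_shape <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  rise <- 0.10; fall <- 0.15
  plateau_end_val <- 0.72
  ifelse(u < rise, sin(pi / 2 * u / rise),
    ifelse(u <= 1 - fall,
      1 - (1 - plateau_end_val) * (u - rise) / (1 - fall - rise),
      plateau_end_val * (1 - u) / fall))
}

# attenuation profile of a graded effort: full envelope inside the
# effort's volume band, effort-limited near TLC, slight thoracic-gas
# compression deficit for the maximal effort at low volumes
effort_attenuation <- function(vfrac, effort_pct) {
  bands <- list(`25` = c(0.00, 0.18), `50` = c(0.12, 0.38),
                `75` = c(0.32, 0.62), `100` = c(0.55, 1.00))
  band <- bands[[as.character(effort_pct)]]
  w <- rep(1, length(vfrac))
  above <- vfrac > band[2]
  below <- vfrac < band[1]
  # above the band: effort-limited, taper toward effort_pct/100 at TLC
  if (any(above)) {
    f <- (vfrac[above] - band[2]) / max(1e-9, 1 - band[2])
    w[above] <- 1 - (1 - effort_pct / 100) * f
  }
  # below the band: gas compression deficit, taper to 0.90
  if (any(below)) {
    f <- (band[1] - vfrac[below]) / max(band[1], 1e-9)
    w[below] <- 1 - 0.10 * f
  }
  w
}

#' Generate graded FVC maneuvers and the true MEFV envelope
#'
#' Returns four timed forced expirations at nominal efforts 25/50/75/100%
#' of maximum whose pointwise flow maximum reproduces the participant's
#' true envelope (each effort attains the envelope exactly over its own
#' volume band; bands jointly cover 0..FVC). Expiration is integrated in
#' the volume domain with a 0.02 L/s terminal flow floor so every effort
#' empties to residual volume in finite time.
#'
#' @param params A [participant_params()] (or list with `FVC_true`,
#'   `PEF_true`, `sr_shape`).
#' @param phase `"pre"` or `"post"`.
#' @param fs Sampling rate, Hz.
#' @return A list: `maneuvers` (list of [fvc_maneuver()]), `true_curve`
#'   (tibble volume_above_RV/max_flow on the 0.01 L grid), `SR_true`.
#' @export
gen_mefv <- function(params, phase = "pre", fs = 200) {
  FVC <- params$FVC_true; PEF <- params$PEF_true; shp <- params$sr_shape
  grid <- seq(0, floor(FVC / 0.01 + 1e-9)) * 0.01
  true_curve <- tibble::tibble(
    volume_above_RV = grid,
    max_flow = true_envelope_flow(grid, FVC, PEF, shp))
  mans <- lapply(c(25, 50, 75, 100), function(eff) {
    vfine <- seq(FVC, 0, length.out = 3000)
    fl <- true_envelope_flow(vfine, FVC, PEF, shp) *
      effort_attenuation(vfine / FVC, eff)
    fl_t <- pmax(fl, 0.02)            # terminal floor: finite emptying time
    tt <- c(0, cumsum(-diff(vfine) / ((fl_t[-1] + fl_t[-3000]) / 2)))
    ts <- seq(0, min(max(tt), 20), by = 1 / fs)
    vs <- stats::approx(tt, vfine, xout = ts)$y
    fs_flow <- stats::approx(vfine, fl_t, xout = vs)$y
    fvc_maneuver(volume_above_RV = vs, exp_flow = fs_flow, phase = phase,
                 effort_pct = eff, time = ts)
  })
  list(maneuvers = mans, true_curve = true_curve, SR_true = shp)
}

# one tidal breath's expiratory samples, clipped at the envelope.
# Returns list(flow, vol_above_rv, TE, overlap_frac_true, c_scale)
gen_expiration <- function(VT, eelv, c_scale, env_fun, fs,
                           flow_floor = 0.05, env_margin = 1) {
  u <- seq(0, 1, length.out = 400)
  v <- eelv + VT * (1 - u)
  desired <- c_scale * exp_shape(u)
  env <- env_fun(v)
  fl <- pmax(pmin(desired, env_margin * env), flow_floor)
  tt <- VT * c(0, cumsum(diff(u) * (1 / fl[-1] + 1 / fl[-400]) / 2))
  TE <- tt[400]
  ts <- seq(1 / fs, TE, by = 1 / fs)
  u_t <- stats::approx(tt, u, xout = ts)$y
  list(flow = stats::approx(u, fl, xout = u_t)$y,
       vol = eelv + VT * (1 - u_t),
       TE = TE,
       overlap_frac = mean(fl >= env - 1e-9))
}

# calibrate the expiratory scale: either to a target clipped fraction of
# VT (EFL stages) or to a target expiratory time (free stages)
calibrate_c <- function(VT, eelv, env_fun, target_pct, TE_target,
                        env_margin = 0.92) {
  u <- seq(0, 1, length.out = 400)
  v <- eelv + VT * (1 - u)
  env <- env_fun(v)
  g <- exp_shape(u)
  if (target_pct > 0) {
    f <- function(cc) 100 * mean(cc * g >= env - 1e-9) - target_pct
    lo <- 1e-3; hi <- max(env) / max(g[g > 0]) * 4 + 10
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      if (f(mid) < 0) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  } else {
    # free breathing: desired flow capped below the envelope by the
    # margin, scale chosen to hit the target expiratory time (or as
    # close as the cap allows)
    te_of <- function(cc) {
      fl <- pmax(pmin(cc * g, env_margin * env), 0.05)
      VT * pracma::trapz(u, 1 / fl)
    }
    lo <- 1e-3; hi <- 200
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      if (te_of(mid) > TE_target) lo <- mid else hi <- mid
    }
    min((lo + hi) / 2, max(env) / max(g[g > 0]) * env_margin * 4)
  }
}

#' Generate one stage's waveform (tidal breathing + IC maneuver)
#'
#' ~31 s of tidal breathing at the stage's tidal volume and frequency,
#' followed immediately by an IC maneuver to total lung capacity and a
#' relaxed return expiration. The volume channel carries the requested
#' linear drift; the flow channel carries Gaussian noise. When the
#' stage's EFL target is positive, the desired expiratory flow is scaled
#' so that clipping at the envelope covers exactly the target fraction of
#' tidal volume.
#'
#' @param params A [participant_params()].
#' @param stage One row of the stage schedule (needs `VT`, `fB`, `eelv`,
#'   `efl_target`).
#' @param fs Sampling rate, Hz.
#' @param noise_seed Integer seed for this stage's noise stream.
#' @param tidal_dur Tidal breathing duration before the IC maneuver, s.
#' @return A list: `flow`, `volume` (clean, above-RV axis), `t` (from 0),
#'   `ic_start`, `ic_end` (s), and `truth` (one-row tibble with the
#'   ground-truth VT, fB, TI, TE, IC, EELV, EFL overlap %, expiratory
#'   scale).
#' @export
gen_stage_waveform <- function(params, stage, fs = 200, noise_seed = 1,
                               tidal_dur = 31) {
  VT <- stage$VT; fB <- stage$fB; eelv <- stage$eelv
  FVC <- params$FVC_true
  if (eelv + VT > FVC) stop("requested EELV + VT exceeds FVC", call. = FALSE)
  env_fun <- function(v) true_envelope_flow(v, FVC, params$PEF_true,
                                            params$sr_shape)
  period <- 60 / fB
  TI <- params$TI_fraction * period
  TE_target <- period - TI
  margin <- if (stage$efl_target > 0) 1 else 0.92
  cc <- calibrate_c(VT, eelv, env_fun, stage$efl_target, TE_target,
                    env_margin = margin)
  ex <- gen_expiration(VT, eelv, cc, env_fun, fs, env_margin = margin)
  # inspiratory half-sine
  nI <- max(2L, round(TI * fs))
  tI <- seq_len(nI) / fs
  A <- pi * VT / (2 * TI)
  insp_flow <- -A * sin(pi * pmin(tI, TI) / TI)
  insp_vol <- eelv + VT * (1 - cos(pi * pmin(tI, TI) / TI)) / 2
  breath_flow <- c(insp_flow, ex$flow)
  breath_vol <- c(insp_vol, ex$vol)
  nb <- ceiling(tidal_dur * fs / length(breath_flow))
  flow <- rep(breath_flow, nb)
  vol <- rep(breath_vol, nb)
  # IC maneuver: deep inspiration to TLC, then relaxed return to EELV
  IC_true <- FVC - eelv
  tIC <- 1.8
  nIC <- round(tIC * fs)
  tic <- seq_len(nIC) / fs
  ic_flow <- -pi * IC_true / (2 * tIC) * sin(pi * tic / tIC)
  ic_vol <- eelv + IC_true * (1 - cos(pi * tic / tIC)) / 2
  tRet <- 2.4
  nRet <- round(tRet * fs)
  tret <- seq_len(nRet) / fs
  ret_flow <- pi * IC_true / (2 * tRet) * sin(pi * tret / tRet)
  ret_vol <- FVC - IC_true * (1 - cos(pi * tret / tRet)) / 2
  ic_start <- length(flow) / fs
  flow <- c(flow, ic_flow, ret_flow)
  vol <- c(vol, ic_vol, ret_vol)
  set.seed(noise_seed)
  flow <- flow + stats::rnorm(length(flow), 0, params$noise_sd_flow)
  n <- length(flow)
  tt <- seq_len(n) / fs
  actual_period <- length(breath_flow) / fs
  truth <- tibble::tibble(
    VT = VT, fB = 60 / actual_period, TI = nI / fs, TE = ex$TE,
    IC = IC_true, EELV = eelv, EFL_pct = 100 * ex$overlap_frac,
    exp_scale = cc)
  list(flow = flow, volume = vol, t = tt,
       ic_start = ic_start, ic_end = n / fs, truth = truth)
}

#' Generate a complete single-visit session
#'
#' Assembles pre-exercise graded FVC maneuvers, all exercise stages (each
#' with its IC maneuver) and post-exercise maneuvers into one continuous
#' recording with a session manifest, plus the per-stage ground truth.
#' Linear volume drift is added across the whole recording.
#'
#' @param params A [participant_params()].
#' @param participant_id Character id.
#' @param visit 1 or 2.
#' @param fs Sampling rate, Hz.
#' @param noise_seed Seed for the session's measurement-noise stream; by
#'   default derived from the parameter vector, so identical parameters
#'   reproduce identical recordings.
#' @return A list of class `efl_session`: `signal` ([fv_signal()]),
#'   `manifest` (`session_manifest`), `truth` (per-stage tibble),
#'   `params`.
#' @export
gen_session <- function(params, participant_id = "P01", visit = 1,
                        fs = 200, noise_seed = NULL) {
  if (is.null(noise_seed)) {
    noise_seed <- param_hash(unlist(params[c(
      "FVC_true", "PEF_true", "sr_shape", "peak_work", "VT_peak",
      "fB_peak", "eelv_frac_rest", "eelv_frac_peak", "drift_rate",
      "efl_target_pct")]))
  }
  sched <- stage_schedule(params)
  flow <- numeric(0); vol <- numeric(0)
  stage_windows <- list(); ic_windows <- list(); fvc_windows <- list()
  truth <- list()
  t_cursor <- 0
  add_maneuvers <- function(phase, t0) {
    gm <- gen_mefv(params, phase = phase, fs = fs)
    segs <- list(); wins <- list()
    tc <- t0
    for (m in gm$maneuvers) {
      # 1.2 s inspiration from FRC to TLC, then the forced expiration
      frc <- params$eelv_frac_rest * params$FVC_true
      tin <- 1.2; nin <- round(tin * fs)
      ti <- seq_len(nin) / fs
      amp <- params$FVC_true - frc
      iflow <- -pi * amp / (2 * tin) * sin(pi * ti / tin)
      ivol <- frc + amp * (1 - cos(pi * ti / tin)) / 2
      mflow <- c(rep(0, round(0.3 * fs)), iflow, m$exp_flow)
      mvol <- c(rep(frc, round(0.3 * fs)), ivol, m$volume_above_RV)
      wins[[length(wins) + 1]] <- tibble::tibble(
        phase = phase, effort_pct = attr(m, "effort_pct"),
        t_start = tc + 0.3, t_end = tc + length(mflow) / fs)
      segs[[length(segs) + 1]] <- list(flow = mflow, vol = mvol)
      tc <- tc + length(mflow) / fs + 0.5
    }
    list(segs = segs, wins = wins, t_end = tc, true_curve = gm$true_curve)
  }
  pre <- add_maneuvers("pre", 0)
  for (s in pre$segs) {
    flow <- c(flow, s$flow, rep(0, round(0.5 * fs)))
    vol <- c(vol, s$vol, rep(s$vol[length(s$vol)], round(0.5 * fs)))
  }
  fvc_windows <- pre$wins
  t_cursor <- length(flow) / fs
  for (k in seq_len(nrow(sched))) {
    st <- sched[k, ]
    sw <- gen_stage_waveform(params, st, fs = fs,
                             noise_seed = derive_seed(noise_seed, k))
    stage_windows[[k]] <- tibble::tibble(
      label = st$stage_label, t_start = t_cursor,
      t_end = t_cursor + sw$ic_start, work_W = st$work_W)
    ic_windows[[k]] <- tibble::tibble(
      stage_label = st$stage_label, t_start = t_cursor + sw$ic_start,
      t_end = t_cursor + sw$ic_end)
    truth[[k]] <- dplyr::bind_cols(
      tibble::tibble(stage_label = st$stage_label, work_W = st$work_W),
      sw$truth)
    flow <- c(flow, sw$flow)
    vol <- c(vol, sw$volume)
    t_cursor <- length(flow) / fs
  }
  post <- add_maneuvers("post", t_cursor + 0.5)
  flow <- c(flow, rep(0, round(0.5 * fs)))
  vol <- c(vol, rep(vol[length(vol)], round(0.5 * fs)))
  for (s in post$segs) {
    flow <- c(flow, s$flow, rep(0, round(0.5 * fs)))
    vol <- c(vol, s$vol, rep(s$vol[length(s$vol)], round(0.5 * fs)))
  }
  fvc_windows <- c(fvc_windows, post$wins)
  n <- length(flow)
  tt <- (seq_len(n) - 1) / fs
  vol <- vol + params$drift_rate * tt
  manifest <- validate_manifest(list(
    participant_id = participant_id, visit = as.integer(visit),
    stage_windows = dplyr::bind_rows(stage_windows),
    ic_windows = dplyr::bind_rows(ic_windows),
    fvc_windows = dplyr::bind_rows(fvc_windows),
    stage_metabolics = tibble::tibble(
      stage_label = sched$stage_label, VO2 = sched$VO2, VCO2 = sched$VCO2)))
  structure(list(signal = fv_signal(tt, flow, volume = vol, fs = fs),
                 manifest = manifest,
                 truth = dplyr::bind_rows(truth),
                 params = params),
            class = "efl_session")
}

#' Default between-day coefficients of variation
#'
#' Percent CVs applied multiplicatively to the visit-2 parameter vector,
#' chosen to be physiologic for day-to-day variation in healthy adults
#' (a few percent for volumes and flows, more for end-expiratory volume).
#' @return Named numeric vector of percent CVs.
#' @export
default_between_day_cv <- function() {
  c(FVC_true = 1.5, PEF_true = 3, sr_shape = 5, VT_peak = 3, fB_peak = 5,
    eelv_frac_rest = 4, eelv_frac_peak = 6, VO2_peak = 5,
    efl_target_pct = 18)
}

perturb_params <- function(params, cv_map, z) {
  p2 <- params
  for (nm in names(cv_map)) {
    if (is.null(p2[[nm]])) next
    p2[[nm]] <- p2[[nm]] * (1 + cv_map[[nm]] / 100 * z[[nm]])
  }
  # keep hard constraints
  p2$VT_peak <- min(p2$VT_peak, 0.95 * (1 - p2$eelv_frac_peak) * p2$FVC_true)
  p2$efl_target_pct <- min(max(p2$efl_target_pct, 0), 60)
  p2
}

#' Generate a synthetic two-visit study
#'
#' Visit-2 parameters equal visit-1 parameters perturbed multiplicatively
#' by the between-day CVs (one standard-normal draw per parameter per
#' participant). Each visit's measurement-noise stream is keyed on its
#' realized parameter vector, so a study with all CVs zero yields two
#' byte-identical visits per participant.
#'
#' @param n_participants Number of participants (default 32).
#' @param seed Study seed.
#' @param between_day_cv Named percent-CV vector
#'   (default [default_between_day_cv()]).
#' @param fs Sampling rate, Hz.
#' @param tweak Optional `function(params, i)` applied to each
#'   participant's visit-1 parameter draw before perturbation — a hook
#'   for experiments that hold a parameter at a chosen value (for
#'   example, forcing borderline EFL propensities).
#' @return A list of class `efl_study`: `sessions` (list of
#'   `efl_session`, two per participant), `truth` (stage-level tibble
#'   with participant and visit), `config`.
#' @export
gen_two_visit_study <- function(n_participants = 32, seed = 1,
                                between_day_cv = default_between_day_cv(),
                                fs = 200, tweak = NULL) {
  sessions <- list()
  truth <- list()
  for (i in seq_len(n_participants)) {
    pid <- sprintf("P%02d", i)
    p1 <- participant_params(derive_seed(seed, i, 1))
    if (!is.null(tweak)) p1 <- tweak(p1, i)
    set.seed(derive_seed(seed, i, 2))
    z <- stats::setNames(stats::rnorm(length(between_day_cv)),
                         names(between_day_cv))
    p2 <- perturb_params(p1, between_day_cv, z)
    # visit 2 repeats the same incremental protocol
    p2$peak_work <- p1$peak_work
    s1 <- gen_session(p1, pid, visit = 1, fs = fs)
    s2 <- gen_session(p2, pid, visit = 2, fs = fs)
    sessions[[length(sessions) + 1]] <- s1
    sessions[[length(sessions) + 1]] <- s2
    truth[[length(truth) + 1]] <- dplyr::bind_cols(
      tibble::tibble(participant_id = pid, visit = 1), s1$truth)
    truth[[length(truth) + 1]] <- dplyr::bind_cols(
      tibble::tibble(participant_id = pid, visit = 2), s2$truth)
  }
  structure(list(sessions = sessions, truth = dplyr::bind_rows(truth),
                 config = list(n_participants = n_participants, seed = seed,
                               between_day_cv = between_day_cv, fs = fs)),
            class = "efl_study")
}

#' Write a synthetic study to disk
#'
#' One waveform CSV and one manifest JSON per session, plus `truth.csv`.
#' @param study An `efl_study`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (s in study$sessions) {
    base <- sprintf("%s_v%d", s$manifest$participant_id, s$manifest$visit)
    write_waveform(s$signal, file.path(dir, paste0(base, "_waveform.csv")))
    write_manifest(s$manifest, file.path(dir, paste0(base, "_manifest.json")))
  }
  readr::write_csv(study$truth, file.path(dir, "truth.csv"),
                   progress = FALSE)
  invisible(dir)
}
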