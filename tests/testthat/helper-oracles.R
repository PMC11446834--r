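# Independent oracles and small signal constructors used across tests.

# cumulative trapezoid of -flow, written as an explicit running sum
cumtrapz_oracle <- function(flow, fs) {
  v <- numeric(length(flow))
  for (k in seq_along(flow)[-1]) {
    v[k] <- v[k - 1] - (flow[k] + flow[k - 1]) / (2 * fs)
  }
  v
}

# a tidal-breathing signal from per-breath amplitudes: half-sine
# inspiration then half-sine expiration, each of duration half_period
sine_breathing_signal <- function(amplitudes, half_period = 2, fs = 200,
                                  lead_in = 0.5) {
  n_half <- round(half_period * fs)
  tt <- seq_len(n_half) / fs
  flow <- rep(0, round(lead_in * fs))
  for (A in amplitudes) {
    flow <- c(flow, -A * sin(pi * tt / half_period),
              A * sin(pi * tt / half_period))
  }
  flow <- c(flow, rep(0, round(lead_in * fs)))
  t_all <- (seq_along(flow) - 1) / fs
  fv_signal(t_all, flow, fs = fs)
}

# expiratory-limb-controlled breath: flow over the expiration follows
# shape_fun(t/TE) scaled to expire VT in TE seconds
shaped_breath_signal <- function(VT, TI, TE, shape_fun, n_breaths = 3,
                                 fs = 200, lead_in = 0.5) {
  tI <- seq_len(round(TI * fs)) / fs
  insp <- -pi * VT / (2 * TI) * sin(pi * tI / TI)
  tE <- seq_len(round(TE * fs)) / fs
  shape <- shape_fun(tE / TE)
  scale <- VT / (sum(shape) / fs)
  exp_f <- scale * shape
  flow <- c(rep(0, round(lead_in * fs)), rep(c(insp, exp_f), n_breaths),
            rep(0, round(lead_in * fs)))
  t_all <- (seq_along(flow) - 1) / fs
  fv_signal(t_all, flow, fs = fs)
}

# random piecewise-linear FVC maneuver for envelope oracle tests
random_maneuver <- function(FVC_max = 6) {
  span <- runif(1, 0.5, 1) * FVC_max
  top <- FVC_max - runif(1, 0, 0.3)
  v <- seq(top, top - span, length.out = sample(20:60, 1))
  f <- pmax(0, approx(seq(0, 1, length.out = 6),
                      runif(6, 0, 10), xout = seq(0, 1, length.out = length(v)))$y)
  fvc_maneuver(volume_above_RV = v, exp_flow = f)
}

# pointwise-max envelope oracle: loops grid points, interpolating each
# maneuver separately
mefv_oracle <- function(maneuvers, grid) {
  out <- numeric(length(grid))
  FVC <- max(vapply(maneuvers, function(m) attr(m, "FVC_this"), numeric(1)))
  for (gi in seq_along(grid)) {
    best <- 0
    for (m in maneuvers) {
      v <- m$volume_above_RV - max(m$volume_above_RV) + FVC
      ord <- order(v)
      v <- v[ord]; f <- pmax(m$exp_flow[ord], 0)
      keep <- c(TRUE, diff(v) > 1e-12)
      v <- v[keep]; f <- f[keep]
      if (grid[gi] < min(v) - 1e-12 || grid[gi] > max(v) + 1e-12) next
      fi <- approx(v, f, xout = grid[gi])$y
      if (isTRUE(fi > best)) best <- fi
    }
    out[gi] <- best
  }
  out
}

# two-sided Fisher exact p by explicit hypergeometric enumeration
fisher_oracle <- function(pos1, neg1, pos2, neg2) {
  r1 <- pos1 + neg1; r2 <- pos2 + neg2
  cpos <- pos1 + pos2; n <- r1 + r2
  support <- max(0, cpos - r2):min(r1, cpos)
  probs <- vapply(support, function(a) {
    exp(lchoose(r1, a) + lchoose(r2, cpos - a) - lchoose(n, cpos))
  }, numeric(1))
  p_obs <- probs[support == pos1]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# ICC via explicit aov mean squares and the Shrout-Fleiss formulas
icc_aov_oracle <- function(x1, x2, form = "ICC2_1") {
  n <- length(x1)
  dat <- data.frame(y = c(x1, x2),
                    subj = factor(rep(seq_len(n), 2)),
                    visit = factor(rep(1:2, each = n)))
  ms <- summary(aov(y ~ subj + visit, data = dat))[[1]][["Mean Sq"]]
  MSR <- ms[1]; MSC <- ms[2]; MSE <- ms[3]
  k <- 2
  if (form == "ICC2_1") {
    (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
  } else {
    (MSR - MSE) / (MSR + (k - 1) * MSE)
  }
}

# an analytic MEFV curve object on the 0.01 L grid
analytic_mefv <- function(FVC, flow_fun) {
  grid <- seq(0, round(FVC / 0.01)) * 0.01
  out <- tibble::tibble(volume_above_RV = grid,
                        max_flow = pmax(flow_fun(grid), 0))
  attr(out, "FVC") <- FVC
  attr(out, "PEF") <- max(out$max_flow)
  class(out) <- c("mefv_curve", class(out))
  out
}

# a hand-built placed tidal curve
manual_placed <- function(abs_volume, exp_flow, envelope_flow, VT,
                          TI = 1, TE = 1.5) {
  out <- tibble::tibble(abs_volume = abs_volume, exp_flow = exp_flow,
                        envelope_flow = envelope_flow)
  attr(out, "VT") <- VT
  attr(out, "TI") <- TI
  attr(out, "TE") <- TE
  class(out) <- c("placed_tidal", class(out))
  out
}

# build participant params with overrides, bypassing the random draw
fixed_params <- function(FVC = 5, PEF = 9, sr_shape = 1.2,
                         peak_work = 100, VT_peak = 2.4, fB_peak = 45,
                         eelv_rest = 0.43, eelv_peak = 0.36,
                         drift = 0, noise = 0, efl = 0, ti_frac = 0.45) {
  structure(list(
    FVC_true = FVC, PEF_true = PEF, sr_shape = sr_shape,
    peak_work = peak_work, VT_rest = 0.8, VT_peak = VT_peak,
    fB_rest = 14, fB_peak = fB_peak,
    eelv_frac_rest = eelv_rest, eelv_frac_peak = eelv_peak,
    VO2_rest = 0.35, VO2_peak = 3.3, TI_fraction = ti_frac,
    drift_rate = drift, noise_sd_flow = noise,
    efl_target_pct = efl), class = "participant_params")
}
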