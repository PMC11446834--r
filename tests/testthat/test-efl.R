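test_that("tidal curves are placed at the measured operating volumes", {
  env <- analytic_mefv(5, function(v) 2 * v)
  tidal <- tibble::tibble(rel_volume = seq(0, 2.4, length.out = 101),
                          exp_flow = rep(1, 101),
                          insp_flow = rep(-1, 101))
  attr(tidal, "VT") <- 2.4
  attr(tidal, "TI") <- 1; attr(tidal, "TE") <- 1.5
  class(tidal) <- c("tidal_fv", class(tidal))
  vols <- derive_volumes(IC = 3.0, FVC = 5, VT = 2.4)

  placed <- place_tidal_curve(tidal, vols, env)
  expect_equal(range(placed$abs_volume), c(2.0, 4.4))
  expect_equal(placed$envelope_flow, 2 * placed$abs_volume,
               tolerance = 1e-9)

  # EILV = FVC exactly maps the top point to TLC
  vols2 <- derive_volumes(IC = 5 - 2.6, FVC = 5, VT = 2.4)
  p2 <- place_tidal_curve(tidal, vols2, env)
  expect_equal(max(p2$abs_volume), 5)

  # small overshoot clips with a warning; a large one errors
  vols3 <- suppressWarnings(derive_volumes(IC = 2.37, FVC = 5, VT = 2.4))  # EILV 5.03
  expect_warning(p3 <- place_tidal_curve(tidal, vols3, env), "clipping")
  expect_lte(max(p3$abs_volume), 5)
  vols4 <- suppressWarnings(derive_volumes(IC = 2.0, FVC = 5, VT = 2.4))   # EILV 5.4
  expect_error(place_tidal_curve(tidal, vols4, env), "exceeds FVC")
})

test_that("EFL overlap fraction and threshold semantics", {
  n <- 101
  av <- seq(2, 4.4, length.out = n)
  envf <- 1 + 0.5 * av
  VT <- 2.4

  # everywhere 20% below the envelope: no EFL
  r0 <- assess_efl(manual_placed(av, 0.8 * envf, envf, VT))
  expect_equal(r0$EFL_pct_VT, 0)
  expect_false(r0$EFL_present)

  # clipped to the envelope over exactly the lowest 40% of VT
  lim <- av <= 2 + 0.4 * VT
  fl <- ifelse(lim, envf, 0.7 * envf)
  r40 <- assess_efl(manual_placed(av, fl, envf, VT))
  expect_equal(r40$EFL_pct_VT, 40, tolerance = 100 / (n - 1))
  expect_true(r40$EFL_present)

  # 4% overlap is nonzero but below the 5% presence threshold
  lim4 <- av <= 2 + 0.04 * VT
  r4 <- assess_efl(manual_placed(av, ifelse(lim4, envf, 0.7 * envf),
                                 envf, VT))
  expect_gt(r4$EFL_pct_VT, 0)
  expect_false(r4$EFL_present)
  expect_true(assess_efl(manual_placed(av, ifelse(lim4, envf, 0.7 * envf),
                                       envf, VT),
                         threshold_pct = 2)$EFL_present)

  # overlap volume bookkeeping
  expect_equal(r40$EFL_pct_VT, 100 * r40$overlap_volume / VT)
})

test_that("EFL is monotone in flow tolerance and tidal flow shifts", {
  set.seed(31)
  av <- seq(1.5, 4, length.out = 101)
  envf <- 2 + av
  fl <- envf * runif(101, 0.7, 1.05)
  p <- manual_placed(av, fl, envf, VT = 2.5)
  tols <- seq(0, 0.5, by = 0.05)
  pct <- vapply(tols, function(tl) assess_efl(p, flow_tol = tl)$EFL_pct_VT,
                numeric(1))
  expect_true(all(diff(pct) >= 0))
  shifted <- manual_placed(av, fl + 0.2, envf, VT = 2.5)
  expect_gte(assess_efl(shifted)$EFL_pct_VT, assess_efl(p)$EFL_pct_VT)
})

test_that("assess_efl agrees with a per-point brute-force oracle", {
  set.seed(77)
  for (rep in 1:100) {
    n <- sample(c(51, 101, 201), 1)
    VT <- runif(1, 1, 3)
    erv <- runif(1, 1, 2.5)
    av <- seq(erv, erv + VT, length.out = n)
    envf <- runif(1, 2, 6) + runif(1, 0, 2) * av
    fl <- envf * runif(n, 0.6, 1.1)
    tol <- sample(c(0, 0.05), 1)
    got <- assess_efl(manual_placed(av, fl, envf, VT), flow_tol = tol)
    # oracle: decide each point separately, accumulate its bin width
    ov <- 0
    for (i in seq_len(n)) {
      w <- if (i == 1) (av[2] - av[1]) / 2
           else if (i == n) (av[n] - av[n - 1]) / 2
           else (av[i + 1] - av[i - 1]) / 2
      if (fl[i] >= envf[i] - tol) ov <- ov + w
    }
    expect_equal(got$overlap_volume, ov, tolerance = 1e-12)
    expect_equal(got$EFL_present, 100 * ov / VT >= 5)
  }
})

test_that("ventilatory capacity follows the envelope-time integral", {
  # rectangular envelope 4 L/s: TE_min = VT/4, VE_cap = 60 VT/(TI+TE_min)
  env <- analytic_mefv(5, function(v) rep(4, length(v)))
  vc <- ve_cap(env, VT = 2, ERV = 1.5, TI = 1.0)
  expect_equal(as.numeric(vc), 80, tolerance = 0.1)
  expect_equal(attr(vc, "TE_min"), 0.5, tolerance = 1e-3)

  # doubling the envelope raises capacity
  env2 <- analytic_mefv(5, function(v) rep(8, length(v)))
  expect_gt(as.numeric(ve_cap(env2, 2, 1.5, 1)), as.numeric(vc))

  # fixed-duty-cycle mode uses TE_min / (1 - ti_fraction) as TTOT
  vcf <- ve_cap(env, VT = 2, ERV = 1.5, TI = 1,
                ti_mode = "fixed_fraction", ti_fraction = 0.5)
  expect_equal(as.numeric(vcf), 60 * 2 / (0.5 / 0.5), tolerance = 0.1)

  # a dead envelope across the tidal range is an error
  env0 <- analytic_mefv(5, function(v) ifelse(v > 3.4, 4, 0))
  expect_error(ve_cap(env0, VT = 2, ERV = 1.5, TI = 1), "zero across")
})

test_that("matched-VE stage pairing minimizes the VE difference", {
  mk <- function(labels, VE, VO2, work) {
    tibble::tibble(stage_label = labels, VE = VE, VO2 = VO2, work_W = work)
  }
  v1 <- mk(c("a", "b", "c"), c(60, 98, 110), c(2.0, 3.1, 3.4),
           c(100, 140, 160))
  v2 <- mk(c("x", "y", "z"), c(55, 101, 120), c(1.9, 3.2, 3.5),
           c(100, 140, 160))
  m <- match_ve_stages(v1, v2)
  # eligible VEs {98,110} x {101,120}: closest pair is (98, 101)
  expect_equal(c(m$VE1, m$VE2), c(98, 101))
  expect_equal(m$dVE, 3)

  # identical stage lists pair at zero difference
  m2 <- match_ve_stages(v1, v1)
  expect_equal(m2$dVE, 0)

  # a single eligible stage per visit is forced
  v3 <- mk(c("a", "b"), c(60, 130), c(1.0, 3.4), c(100, 160))
  v4 <- mk(c("x", "y"), c(55, 90), c(0.9, 3.5), c(100, 160))
  m3 <- match_ve_stages(v3, v4)
  expect_equal(c(m3$VE1, m3$VE2), c(130, 90))

  # no eligible stage errors
  expect_error(match_ve_stages(v1[1, ], v2, peak_VO2_1 = 10), "no stage")
})
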