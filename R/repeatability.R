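# Between-day agreement statistics: Cohen's kappa, ICC, within-subject
# CV, paired t, Fisher's exact, with the conventional classification
# bands (McHugh for kappa; Koo & Li for ICC).

#' 2x2 agreement table for a binary outcome measured on two visits
#'
#' @param a Both-positive count.
#' @param b Visit-1-only count.
#' @param c Visit-2-only count.
#' @param d Both-negative count.
#' @return A tibble of class `agreement_2x2`.
#' @export
agreement_table <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0) || sum(counts) == 0) {
    stop("counts must be non-negative with a positive total", call. = FALSE)
  }
  out <- tibble::tibble(a = a, b = b, c = c, d = d)
  class(out) <- c("agreement_2x2", class(out))
  out
}

#' Build the 2x2 agreement table from paired binary vectors
#' @param x1,x2 Logical vectors, one element per participant (visit 1 and
#'   visit 2 status).
#' @return An [agreement_table()].
#' @export
agreement_from_pairs <- function(x1, x2) {
  stopifnot(length(x1) == length(x2))
  agreement_table(sum(x1 & x2), sum(x1 & !x2), sum(!x1 & x2),
                  sum(!x1 & !x2))
}

#' Cohen's kappa for a 2x2 agreement table
#'
#' Chance-corrected agreement: kappa = (po - pe) / (1 - pe) with observed
#' agreement po = (a+d)/n and chance agreement pe from the marginals. The
#' p-value is the large-sample normal test of kappa = 0 using the
#' standard error under the null (Fleiss).
#'
#' @param tab An [agreement_table()].
#' @return A one-row tibble: `kappa`, `p`, `n`, `po`, `pe`,
#'   `undefined` (TRUE when a constant rater makes pe = 1).
#' @export
cohens_kappa <- function(tab) {
  a <- tab$a; b <- tab$b; c <- tab$c; d <- tab$d
  n <- a + b + c + d
  po <- (a + d) / n
  p1. <- (a + b) / n; p.1 <- (a + c) / n
  p2. <- (c + d) / n; p.2 <- (b + d) / n
  pe <- p1. * p.1 + p2. * p.2
  if (abs(1 - pe) < 1e-12) {
    return(tibble::tibble(kappa = NA_real_, p = NA_real_, n = n,
                          po = po, pe = pe, undefined = TRUE))
  }
  kappa <- (po - pe) / (1 - pe)
  # Fleiss null SE for the 2x2 case
  s <- p1. * p.1 * (p1. + p.1) + p2. * p.2 * (p2. + p.2)
  se0 <- sqrt(max(pe + pe^2 - s, 0)) / ((1 - pe) * sqrt(n))
  p <- if (se0 > 0) 2 * stats::pnorm(-abs(kappa / se0)) else NA_real_
  tibble::tibble(kappa = kappa, p = p, n = n, po = po, pe = pe,
                 undefined = FALSE)
}

#' Classify a kappa value (McHugh bands)
#'
#' none 0.00-0.20, minimal 0.21-0.39, weak 0.40-0.59, moderate 0.60-0.79,
#' strong 0.80-0.90, almost perfect > 0.90. Negative values classify as
#' "none"; exact shared endpoints go to the lower band.
#'
#' @param kappa Numeric vector.
#' @return Character vector of band labels.
#' @export
kappa_class <- function(kappa) {
  stopifnot(all(is.finite(kappa)))
  dplyr::case_when(
    kappa <= 0.20 ~ "none",
    kappa <= 0.39 + 5e-3 ~ "minimal",
    kappa <= 0.59 + 5e-3 ~ "weak",
    kappa <= 0.79 + 5e-3 ~ "moderate",
    kappa <= 0.90 ~ "strong",
    TRUE ~ "almost perfect"
  )
}

#' Intraclass correlation for paired visits
#'
#' Single-measure ICC from the two-way ANOVA mean squares of the
#' subjects-by-visits table. `"ICC2_1"` (default) is two-way random
#' effects, absolute agreement; `"ICC3_1"` is two-way mixed, consistency.
#' The 95% CI and the p-value (F test of ICC = 0) use the standard
#' F-distribution results (Shrout & Fleiss; McGraw & Wong).
#'
#' @param x1,x2 Numeric vectors of the measurement on visit 1 and 2
#'   (complete pairs, length >= 3).
#' @param form `"ICC2_1"` or `"ICC3_1"`.
#' @param conf Confidence level (default 0.95).
#' @return A one-row tibble: `icc`, `ci_lo`, `ci_hi`, `p`, `form`, `n`,
#'   `undefined` (TRUE on zero total variance).
#' @export
icc <- function(x1, x2, form = c("ICC2_1", "ICC3_1"), conf = 0.95) {
  form <- match.arg(form)
  stopifnot(length(x1) == length(x2))
  ok <- is.finite(x1) & is.finite(x2)
  x1 <- x1[ok]; x2 <- x2[ok]
  n <- length(x1)
  if (n < 3) stop("need >= 3 complete pairs", call. = FALSE)
  k <- 2
  X <- cbind(x1, x2)
  row_means <- rowMeans(X)
  col_means <- colMeans(X)
  grand <- mean(X)
  SSR <- k * sum((row_means - grand)^2)
  SSC <- n * sum((col_means - grand)^2)
  SST <- sum((X - grand)^2)
  SSE <- SST - SSR - SSC
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  if (SST < 1e-24) {
    return(tibble::tibble(icc = NA_real_, ci_lo = NA_real_,
                          ci_hi = NA_real_, p = NA_real_, form = form,
                          n = n, undefined = TRUE))
  }
  alpha <- 1 - conf
  if (form == "ICC3_1") {
    val <- (MSR - MSE) / (MSR + (k - 1) * MSE)
    Fobs <- MSR / MSE
    df1 <- n - 1; df2 <- (n - 1) * (k - 1)
    FL <- Fobs / stats::qf(1 - alpha / 2, df1, df2)
    FU <- Fobs * stats::qf(1 - alpha / 2, df2, df1)
    lo <- (FL - 1) / (FL + k - 1)
    hi <- (FU - 1) / (FU + k - 1)
    p <- stats::pf(Fobs, df1, df2, lower.tail = FALSE)
  } else {
    val <- (MSR - MSE) /
      (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
    # McGraw & Wong CI for ICC(A,1)
    Fobs <- MSR / MSE
    a_ <- k * val / (n * (1 - val))
    b_ <- 1 + k * val * (n - 1) / (n * (1 - val))
    df2 <- (a_ * MSC + b_ * MSE)^2 /
      ((a_ * MSC)^2 / (k - 1) + (b_ * MSE)^2 / ((n - 1) * (k - 1)))
    Fs <- stats::qf(1 - alpha / 2, n - 1, df2)
    Fs2 <- stats::qf(1 - alpha / 2, df2, n - 1)
    lo <- n * (MSR - Fs * MSE) /
      (Fs * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
    hi <- n * (Fs2 * MSR - MSE) /
      (k * MSC + (k * n - k - n) * MSE + n * Fs2 * MSR)
    p <- stats::pf(Fobs, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  }
  tibble::tibble(icc = val, ci_lo = lo, ci_hi = hi, p = p, form = form,
                 n = n, undefined = FALSE)
}

#' Classify an ICC value (Koo & Li bands)
#'
#' poor < 0.50, moderate 0.50-0.75, good 0.75-0.90, excellent > 0.90;
#' shared endpoints go to the lower-named band.
#'
#' @param icc Numeric vector.
#' @return Character vector of band labels.
#' @export
icc_class <- function(icc) {
  stopifnot(all(is.finite(icc)))
  dplyr::case_when(
    icc < 0.50 ~ "poor",
    icc <= 0.75 ~ "moderate",
    icc <= 0.90 ~ "good",
    TRUE ~ "excellent"
  )
}

#' Between-day within-subject coefficient of variation
#'
#' Per pair, the within-subject SD is |x1 - x2| / sqrt(2); the CV is the
#' root-mean-square of those SDs as a percentage of the grand mean.
#'
#' @param x1,x2 Numeric vectors (one element per participant).
#' @return CV in percent (single number).
#' @export
between_day_cv <- function(x1, x2) {
  stopifnot(length(x1) == length(x2), length(x1) >= 1)
  gm <- mean(c(x1, x2))
  if (gm <= 0) stop("grand mean must be positive for a CV", call. = FALSE)
  s <- abs(x1 - x2) / sqrt(2)
  100 * sqrt(mean(s^2)) / gm
}

#' Paired t-test across visits
#'
#' Thin wrapper over [stats::t.test()] with `paired = TRUE`; a zero
#' variance of the differences is flagged rather than an error.
#'
#' @param x1,x2 Numeric vectors (>= 2 complete pairs).
#' @return A one-row tibble: `t`, `p`, `df`, `mean_diff`, `undefined`.
#' @export
paired_t <- function(x1, x2) {
  stopifnot(length(x1) == length(x2), length(x1) >= 2)
  d <- x1 - x2
  if (stats::sd(d) < 1e-15) {
    return(tibble::tibble(t = if (mean(d) == 0) 0 else NA_real_,
                          p = if (mean(d) == 0) 1 else NA_real_,
                          df = length(d) - 1, mean_diff = mean(d),
                          undefined = mean(d) != 0))
  }
  tt <- stats::t.test(x1, x2, paired = TRUE)
  tibble::tibble(t = unname(tt$statistic), p = tt$p.value,
                 df = unname(tt$parameter), mean_diff = mean(d),
                 undefined = FALSE)
}

#' Fisher's exact test for visit-wise frequency counts
#'
#' Two-sided exact test on the 2x2 table (positive/negative by visit),
#' delegated to [stats::fisher.test()] (exact hypergeometric).
#'
#' @param pos1,neg1 Counts on visit 1.
#' @param pos2,neg2 Counts on visit 2.
#' @return Two-sided p-value.
#' @export
fisher_exact <- function(pos1, neg1, pos2, neg2) {
  m <- matrix(c(pos1, neg1, pos2, neg2), nrow = 2)
  stats::fisher.test(m)$p.value
}

#' Between-day repeatability report for a set of paired measurements
#'
#' For each continuous parameter: ICC with CI, p and Koo-Li class, plus
#' the between-day CV and paired t. For the binary EFL outcome: Cohen's
#' kappa with McHugh class.
#'
#' @param pairs A data frame with one row per participant and paired
#'   columns named `<param>_1` / `<param>_2` for each continuous
#'   parameter, plus optional logical `EFL_1` / `EFL_2`.
#' @param params Character vector of continuous parameter names to
#'   report (default: all with both columns present).
#' @param icc_form Passed to [icc()].
#' @return A list of class `repeat_report` with elements `continuous`
#'   (tibble: parameter, cv_pct, icc, ci, p, class) and `binary`
#'   (kappa row with class, or NULL), `n_pairs`.
#' @export
repeatability_report <- function(pairs, params = NULL,
                                 icc_form = "ICC2_1") {
  nm <- names(pairs)
  auto <- unique(sub("_[12]$", "", nm[grepl("_[12]$", nm)]))
  auto <- setdiff(auto, "EFL")
  if (is.null(params)) params <- auto
  cont <- purrr::map_dfr(params, function(p) {
    x1 <- pairs[[paste0(p, "_1")]]
    x2 <- pairs[[paste0(p, "_2")]]
    na_row <- tibble::tibble(icc = NA_real_, ci_lo = NA_real_,
                             ci_hi = NA_real_, p = NA_real_,
                             form = icc_form, n = length(x1),
                             undefined = TRUE)
    ic <- tryCatch(icc(x1, x2, form = icc_form),
                   error = function(e) na_row)
    tt <- tryCatch(paired_t(x1, x2), error = function(e) {
      tibble::tibble(t = NA_real_, p = NA_real_, df = NA_real_,
                     mean_diff = NA_real_, undefined = TRUE)
    })
    cv <- tryCatch(between_day_cv(x1, x2), error = function(e) NA_real_)
    tibble::tibble(
      parameter = p,
      cv_pct = cv,
      icc = ic$icc, icc_ci_lo = ic$ci_lo, icc_ci_hi = ic$ci_hi,
      icc_p = ic$p,
      icc_class = if (is.finite(ic$icc)) icc_class(ic$icc) else NA_character_,
      t = tt$t, t_p = tt$p)
  })
  binary <- NULL
  if (all(c("EFL_1", "EFL_2") %in% nm)) {
    tab <- agreement_from_pairs(as.logical(pairs$EFL_1),
                                as.logical(pairs$EFL_2))
    kp <- cohens_kappa(tab)
    kp$kappa_class <- if (is.finite(kp$kappa)) kappa_class(kp$kappa)
                      else NA_character_
    kp$fisher_p <- fisher_exact(tab$a + tab$b, tab$c + tab$d,
                                tab$a + tab$c, tab$b + tab$d)
    binary <- kp
  }
  structure(list(continuous = cont, binary = binary, n_pairs = nrow(pairs),
                 icc_form = icc_form),
            class = "repeat_report")
}

#' @export
print.repeat_report <- function(x, ...) {
  cat("Between-day repeatability report (", x$n_pairs, " pairs, ",
      x$icc_form, ")\n", sep = "")
  print(x$continuous, ...)
  if (!is.null(x$binary)) {
    cat("Binary EFL agreement:\n")
    print(x$binary, ...)
  }
  invisible(x)
}

#' Tidy a repeatability report
#'
#' One row per parameter (continuous parameters plus, when present, the
#' binary EFL row with the kappa in the `estimate` column).
#'
#' @param x A `repeat_report`.
#' @param ... Unused.
#' @return A tibble with columns `parameter`, `statistic_type`,
#'   `estimate`, `conf.low`, `conf.high`, `p.value`, `class`, `cv_pct`.
#' @export
tidy.repeat_report <- function(x, ...) {
  out <- dplyr::transmute(x$continuous,
    parameter = .data$parameter, statistic_type = "icc",
    estimate = .data$icc, conf.low = .data$icc_ci_lo,
    conf.high = .data$icc_ci_hi, p.value = .data$icc_p,
    class = .data$icc_class, cv_pct = .data$cv_pct)
  if (!is.null(x$binary)) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      parameter = "EFL", statistic_type = "kappa",
      estimate = x$binary$kappa, conf.low = NA_real_,
      conf.high = NA_real_, p.value = x$binary$p,
      class = x$binary$kappa_class, cv_pct = NA_real_))
  }
  out
}

#' Glance at a repeatability report
#' @param x A `repeat_report`.
#' @param ... Unused.
#' @return A one-row tibble: `n_pairs`, `n_parameters`, `icc_form`,
#'   `kappa`, `kappa_class`.
#' @export
glance.repeat_report <- function(x, ...) {
  tibble::tibble(
    n_pairs = x$n_pairs,
    n_parameters = nrow(x$continuous),
    icc_form = x$icc_form,
    kappa = if (is.null(x$binary)) NA_real_ else x$binary$kappa,
    kappa_class = if (is.null(x$binary)) NA_character_
                  else x$binary$kappa_class)
}

#' Write a repeatability report to JSON
#' @param report A `repeat_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_repeat_report <- function(report, path) {
  jsonlite::write_json(
    list(n_pairs = report$n_pairs, icc_form = report$icc_form,
         continuous = report$continuous, binary = report$binary),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}
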