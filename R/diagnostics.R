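# Diagnostic accuracy of a size classification (SGA vs AGA) for predicting
# neonatal undernutrition: 2x2 construction with an explicit exclusion audit
# trail, the accuracy battery with 95% CIs, relative risks with Katz
# intervals, and paired method comparisons.

#' A 2x2 exposure/outcome contingency table with an exclusion audit trail
#'
#' Exposure is size class (SGA = exposed, AGA = non-exposed; LGA excluded),
#' outcome is undernutrition (overnourished and out-of-coverage records
#' excluded). Counts: `tp` SGA & undernourished, `fp` SGA & normal, `fn` AGA
#' & undernourished, `tn` AGA & normal.
#'
#' @param tp,fp,fn,tn non-negative integer counts.
#' @param exposure_label,outcome_label text labels.
#' @param excluded_lga,excluded_overnourished,excluded_out_of_coverage
#'   audit counts of records removed before tabulation.
#' @return An object of class `contingency_table`.
#' @export
contingency_table <- function(tp, fp, fn, tn,
                              exposure_label = "SGA",
                              outcome_label = "undernourished",
                              excluded_lga = 0L,
                              excluded_overnourished = 0L,
                              excluded_out_of_coverage = 0L) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn,
              excluded_lga = excluded_lga,
              excluded_overnourished = excluded_overnourished,
              excluded_out_of_coverage = excluded_out_of_coverage)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("all counts must be non-negative integers", call. = FALSE)
  }
  if (tp + fp + fn + tn < 1) {
    stop("empty eligible set: no SGA/AGA records with an outcome",
         call. = FALSE)
  }
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), tn = as.integer(tn),
                 exposure_label = exposure_label,
                 outcome_label = outcome_label,
                 excluded_lga = as.integer(excluded_lga),
                 excluded_overnourished = as.integer(excluded_overnourished),
                 excluded_out_of_coverage =
                   as.integer(excluded_out_of_coverage)),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("2x2 table: %s (exposure) vs %s (outcome)\n",
              x$exposure_label, x$outcome_label))
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, byrow = TRUE,
              dimnames = list(c("exposed", "non-exposed"),
                              c("outcome+", "outcome-")))
  print(m)
  cat(sprintf("excluded: LGA %d, overnourished %d, out-of-coverage %d\n",
              x$excluded_lga, x$excluded_overnourished,
              x$excluded_out_of_coverage))
  invisible(x)
}

#' Build the exposure/outcome table from per-record classifications
#'
#' Exclusion precedence: records with a missing classification on either
#' axis are out-of-coverage; remaining LGA records are excluded from the
#' exposure groups; remaining overnourished records are excluded from the
#' outcome. `tp+fp+fn+tn` plus the three exclusion counts always equals
#' `length(size_class)`.
#'
#' @param size_class factor/character with levels SGA/AGA/LGA (NA allowed).
#' @param nutrition factor/character with levels
#'   undernourished/normal/overnourished (NA allowed).
#' @param ... labels passed to [contingency_table()].
#' @return A [contingency_table()].
#' @export
build_table <- function(size_class, nutrition, ...) {
  size_class <- as.character(size_class)
  nutrition <- as.character(nutrition)
  stopifnot(length(size_class) == length(nutrition))
  ooc <- is.na(size_class) | is.na(nutrition)
  lga <- !ooc & size_class == "LGA"
  over <- !ooc & !lga & nutrition == "overnourished"
  keep <- !ooc & !lga & !over
  sga <- size_class[keep] == "SGA"
  und <- nutrition[keep] == "undernourished"
  contingency_table(tp = sum(sga & und), fp = sum(sga & !und),
                    fn = sum(!sga & und), tn = sum(!sga & !und),
                    excluded_lga = sum(lga),
                    excluded_overnourished = sum(over),
                    excluded_out_of_coverage = sum(ooc), ...)
}

# Clopper-Pearson exact CI for x successes in n trials.
.exact_ci <- function(x, n, conf = 0.95) {
  a <- (1 - conf) / 2
  lo <- if (x == 0) 0 else stats::qbeta(a, x, n - x + 1)
  hi <- if (x == n) 1 else stats::qbeta(1 - a, x + 1, n - x)
  c(lo, hi)
}

.metric <- function(estimate, lo, hi) {
  list(estimate = estimate, ci_low = lo, ci_high = hi)
}

#' Likelihood ratios, DOR and Youden index from an operating point
#'
#' The deterministic identities linking sensitivity and specificity to the
#' positive/negative likelihood ratios, the diagnostic odds ratio
#' (`LR+ / LR-`) and the Youden index (`sens + spec - 1`). Useful for
#' reproducing a published operating point without its underlying counts.
#'
#' @param sensitivity,specificity proportions in \[0, 1\].
#' @return List with `lr_pos`, `lr_neg`, `dor`, `youden`.
#' @examples
#' operating_point_metrics(0.60, 0.7874)
#' @export
operating_point_metrics <- function(sensitivity, specificity) {
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1)
  lr_pos <- sensitivity / (1 - specificity)
  lr_neg <- (1 - sensitivity) / specificity
  list(lr_pos = lr_pos, lr_neg = lr_neg, dor = lr_pos / lr_neg,
       youden = sensitivity + specificity - 1)
}

#' Diagnostic accuracy battery for a 2x2 table
#'
#' Sensitivity, specificity, PPV and NPV (Clopper-Pearson exact 95% CIs),
#' LR+, LR-, DOR (log-normal CIs) and the Youden index (seeded multinomial
#' bootstrap CI by default, delta-method alternative). Metrics whose
#' denominator is zero are returned as `NA` and listed in the `undefined`
#' element rather than silently NaN; `continuity = TRUE` adds 0.5 to every
#' cell for the ratio metrics when any cell is zero (logged via a message).
#'
#' @param table a [contingency_table()].
#' @param conf confidence level.
#' @param youden_ci `"bootstrap"` (percentile, multinomial resampling of the
#'   table) or `"delta"` (normal approximation).
#' @param boot_reps bootstrap resamples.
#' @param boot_seed seed for the bootstrap (isolated from the global RNG).
#' @param continuity apply a +0.5 correction to ratio metrics when a zero
#'   cell makes them undefined.
#' @return An object of class `diagnostic_summary`: named list of metrics,
#'   each `list(estimate, ci_low, ci_high)`, plus `n_eligible`, `undefined`.
#' @export
diagnostic_summary <- function(table, conf = 0.95,
                               youden_ci = c("bootstrap", "delta"),
                               boot_reps = 2000L, boot_seed = 1L,
                               continuity = FALSE) {
  stopifnot(inherits(table, "contingency_table"))
  youden_ci <- match.arg(youden_ci)
  tp <- table$tp; fp <- table$fp; fn <- table$fn; tn <- table$tn
  z <- stats::qnorm(1 - (1 - conf) / 2)
  undefined <- character()
  prop <- function(x, n, name) {
    if (n == 0) { undefined <<- c(undefined, name); return(.metric(NA, NA, NA)) }
    ci <- .exact_ci(x, n, conf)
    .metric(x / n, ci[1], ci[2])
  }
  out <- list(
    sensitivity = prop(tp, tp + fn, "sensitivity"),
    specificity = prop(tn, tn + fp, "specificity"),
    ppv = prop(tp, tp + fp, "ppv"),
    npv = prop(tn, tn + fn, "npv")
  )

  ctp <- tp; cfp <- fp; cfn <- fn; ctn <- tn
  zero_cell <- any(c(tp, fp, fn, tn) == 0)
  if (continuity && zero_cell) {
    message("continuity correction applied: +0.5 to all cells for ratio metrics")
    ctp <- tp + 0.5; cfp <- fp + 0.5; cfn <- fn + 0.5; ctn <- tn + 0.5
  }
  ratio_ok <- all(c(ctp, cfp, cfn, ctn) > 0)
  logci <- function(est, se) .metric(est, est * exp(-z * se), est * exp(z * se))
  if (ratio_ok) {
    sens_c <- ctp / (ctp + cfn); spec_c <- ctn / (ctn + cfp)
    lrp <- sens_c / (1 - spec_c)
    lrn <- (1 - sens_c) / spec_c
    se_lrp <- sqrt(1 / ctp - 1 / (ctp + cfn) + 1 / cfp - 1 / (cfp + ctn))
    se_lrn <- sqrt(1 / cfn - 1 / (ctp + cfn) + 1 / ctn - 1 / (cfp + ctn))
    se_dor <- sqrt(1 / ctp + 1 / cfp + 1 / cfn + 1 / ctn)
    out$lr_pos <- logci(lrp, se_lrp)
    out$lr_neg <- logci(lrn, se_lrn)
    out$dor <- logci(lrp / lrn, se_dor)
  } else {
    undefined <- c(undefined, "lr_pos", "lr_neg", "dor")
    out$lr_pos <- out$lr_neg <- out$dor <- .metric(NA, NA, NA)
  }

  if ((tp + fn) > 0 && (tn + fp) > 0) {
    yj <- tp / (tp + fn) + tn / (tn + fp) - 1
    ci <- if (youden_ci == "delta") {
      se <- sqrt(tp * fn / (tp + fn)^3 + tn * fp / (tn + fp)^3)
      c(yj - z * se, yj + z * se)
    } else {
      .youden_boot_ci(tp, fp, fn, tn, boot_reps, boot_seed, conf)
    }
    out$youden <- .metric(yj, ci[1], ci[2])
  } else {
    undefined <- c(undefined, "youden")
    out$youden <- .metric(NA, NA, NA)
  }

  structure(c(out, list(n_eligible = tp + fp + fn + tn,
                        undefined = undefined, table = table)),
            class = "diagnostic_summary")
}

# Percentile bootstrap CI for Youden's J: resample the 2x2 as a multinomial
# over (tp, fp, fn, tn); draws with an empty margin are dropped.
.youden_boot_ci <- function(tp, fp, fn, tn, reps, seed, conf) {
  n <- tp + fp + fn + tn
  with_preserved_seed(seed, {
    draws <- stats::rmultinom(reps, n, c(tp, fp, fn, tn) / n)
    s <- draws[1, ] / (draws[1, ] + draws[3, ]) +
      draws[4, ] / (draws[4, ] + draws[2, ]) - 1
    stats::quantile(s[is.finite(s)], c((1 - conf) / 2, 1 - (1 - conf) / 2),
                    names = FALSE)
  })
}

# Run expr under a fixed seed without disturbing the caller's RNG stream.
with_preserved_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' @export
print.diagnostic_summary <- function(x, ...) {
  cat(sprintf("Diagnostic summary (%s vs %s), n eligible = %d\n",
              x$table$exposure_label, x$table$outcome_label, x$n_eligible))
  for (m in c("sensitivity", "specificity", "ppv", "npv", "lr_pos",
              "lr_neg", "dor", "youden")) {
    v <- x[[m]]
    cat(sprintf("  %-12s %8.4f (%.4f - %.4f)\n", m, v$estimate, v$ci_low,
                v$ci_high))
  }
  if (length(x$undefined)) {
    cat("  undefined:", paste(x$undefined, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Relative risk of the outcome in exposed vs non-exposed
#'
#' `RR = [tp/(tp+fp)] / [fn/(fn+tn)]` with the Katz log-method 95% CI:
#' `exp(ln RR +/- z * SE)`, `SE = sqrt(1/tp - 1/(tp+fp) + 1/fn - 1/(fn+tn))`.
#'
#' @param table a [contingency_table()].
#' @param conf confidence level.
#' @param continuity add 0.5 to every cell when a zero event count makes the
#'   log CI undefined (opt-in; logged via a message).
#' @return An object of class `risk_ratio`: list with `rr`, `ci_low`,
#'   `ci_high`, `log_se`.
#' @export
relative_risk <- function(table, conf = 0.95, continuity = FALSE) {
  stopifnot(inherits(table, "contingency_table"))
  tp <- table$tp; fp <- table$fp; fn <- table$fn; tn <- table$tn
  if (tp + fp == 0 || fn + tn == 0) {
    stop("both exposure groups must be non-empty", call. = FALSE)
  }
  if ((tp == 0 || fn == 0) && continuity) {
    message("continuity correction applied: +0.5 to all cells of the RR table")
    tp <- tp + 0.5; fp <- fp + 0.5; fn <- fn + 0.5; tn <- tn + 0.5
  }
  rr <- (tp / (tp + fp)) / (fn / (fn + tn))
  if (tp == 0 || fn == 0) {
    warning("zero events in a group; RR CI undefined (set continuity = TRUE)",
            call. = FALSE)
    se <- NA_real_; ci <- c(NA_real_, NA_real_)
  } else {
    se <- sqrt(1 / tp - 1 / (tp + fp) + 1 / fn - 1 / (fn + tn))
    z <- stats::qnorm(1 - (1 - conf) / 2)
    ci <- rr * exp(c(-z, z) * se)
  }
  structure(list(rr = rr, ci_low = ci[1], ci_high = ci[2], log_se = se),
            class = "risk_ratio")
}

#' Compare two relative risks (Altman-Bland)
#'
#' z-test on the difference of the log relative risks:
#' `ratio = exp(ln RR1 - ln RR2)`, `SE = sqrt(SE1^2 + SE2^2)`, two-sided
#' normal p. Note the test treats the two estimates as independent even when
#' they come from the same cohort, matching common published practice.
#'
#' @param rr1,rr2 [relative_risk()] results.
#' @param conf confidence level.
#' @return List with `ratio`, `ci_low`, `ci_high`, `p`.
#' @export
compare_rr <- function(rr1, rr2, conf = 0.95) {
  stopifnot(inherits(rr1, "risk_ratio"), inherits(rr2, "risk_ratio"))
  if (is.na(rr1$log_se) || is.na(rr2$log_se)) {
    stop("both RRs need defined log standard errors", call. = FALSE)
  }
  d <- log(rr1$rr) - log(rr2$rr)
  se <- sqrt(rr1$log_se^2 + rr2$log_se^2)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  list(ratio = exp(d), ci_low = exp(d - z * se), ci_high = exp(d + z * se),
       p = 2 * stats::pnorm(-abs(d / se)))
}

#' McNemar test on paired classifications
#'
#' Compares two methods' classifications of the same subjects via the
#' discordant pairs `b` (method 1 positive only) and `c` (method 2 positive
#' only). Exact binomial when `b + c < 25`, chi-square with continuity
#' correction otherwise. Restrict the input to the outcome-positive subset to
#' compare sensitivities, or the outcome-negative subset for specificities.
#'
#' @param flags1,flags2 logical vectors (positive classification by each
#'   method), or pass the discordant counts directly via `b`, `c`.
#' @param b,c discordant-pair counts (alternative to `flags1`/`flags2`).
#' @return List with `statistic` (NA for the exact test), `p`, `b`, `c`,
#'   `method`.
#' @export
mcnemar_test <- function(flags1 = NULL, flags2 = NULL, b = NULL, c = NULL) {
  if (is.null(b) || is.null(c)) {
    stopifnot(is.logical(flags1), is.logical(flags2),
              length(flags1) == length(flags2))
    keep <- !is.na(flags1) & !is.na(flags2)
    b <- sum(flags1[keep] & !flags2[keep])
    c <- sum(!flags1[keep] & flags2[keep])
  }
  nd <- b + c
  if (nd == 0) {
    warning("no discordant pairs; p = 1", call. = FALSE)
    return(list(statistic = NA_real_, p = 1, b = b, c = c,
                method = "degenerate"))
  }
  if (nd < 25) {
    p <- stats::binom.test(b, nd, 0.5)$p.value
    list(statistic = NA_real_, p = unname(p), b = b, c = c, method = "exact")
  } else {
    stat <- (abs(b - c) - 1)^2 / nd
    list(statistic = stat, p = stats::pchisq(stat, 1, lower.tail = FALSE),
         b = b, c = c, method = "chi-square (continuity corrected)")
  }
}

#' Chi-square comparison of two proportions
#'
#' Pearson chi-square (no Yates correction) on the 2x2 frequency table of
#' `k1/n1` vs `k2/n2`, treating the groups as independent. When the two
#' proportions are classifications of the SAME cohort the paired
#' [mcnemar_test()] is statistically preferable; the independent chi-square
#' is kept as the default for fidelity with common published practice. Falls
#' back to Fisher's exact test (with a warning) when an expected cell is
#' below 1.
#'
#' @param k1,n1,k2,n2 successes and totals in the two groups.
#' @return List with `chi2` (NA for the Fisher fallback), `p`.
#' @export
compare_proportions <- function(k1, n1, k2, n2) {
  stopifnot(n1 > 0, n2 > 0, k1 >= 0, k2 >= 0, k1 <= n1, k2 <= n2)
  m <- matrix(c(k1, n1 - k1, k2, n2 - k2), 2, byrow = TRUE)
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected < 1)) {
    warning("expected cell count < 1; using Fisher's exact test",
            call. = FALSE)
    return(list(chi2 = NA_real_, p = stats::fisher.test(m)$p.value))
  }
  chi2 <- sum((m - expected)^2 / expected)
  list(chi2 = chi2, p = stats::pchisq(chi2, 1, lower.tail = FALSE))
}
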