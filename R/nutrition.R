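# Neonatal nutritional status: BMI and ponderal index, centiles against
# sex- and completed-week-specific references, and the
# undernourished / normal / overnourished classification.

NUTRITION_GA_MIN <- 32L
NUTRITION_GA_MAX <- 42L

# In-code copies of the reference tables (columns: sex, ga 32..42 completed
# weeks, mean, sd). The packaged CSVs must round-trip against these exactly.
.bmi_reference_values <- function() {
  m <- c(10.44, 10.66, 10.59, 11.90, 12.39, 12.60, 13.25, 13.41, 13.67,
         13.84, 14.12)
  m_sd <- c(1.18, 1.17, 1.08, 1.45, 2.07, 1.36, 1.36, 1.17, 1.47, 1.45, 1.23)
  f <- c(10.25, 10.19, 10.77, 11.84, 12.08, 12.59, 13.18, 13.30, 13.58,
         13.82, 13.72)
  f_sd <- c(0.74, 1.02, 1.42, 2.14, 1.50, 1.59, 1.60, 1.25, 1.26, 1.30, 1.34)
  data.frame(index_kind = "BMI",
             sex = rep(c("male", "female"), each = 11L),
             ga_weeks = rep(32:42, 2L),
             mean = c(m, f), sd = c(m_sd, f_sd))
}

.pi_reference_values <- function() {
  m <- c(2.43, 2.41, 2.35, 2.54, 2.64, 2.62, 2.70, 2.69, 2.73, 2.72, 2.79)
  m_sd <- c(0.26, 0.20, 0.19, 0.28, 0.59, 0.31, 0.34, 0.25, 0.42, 0.39, 0.18)
  f <- c(2.42, 2.35, 2.42, 2.61, 2.59, 2.66, 2.74, 2.72, 2.75, 2.76, 2.78)
  f_sd <- c(0.14, 0.26, 0.30, 0.72, 0.30, 0.42, 0.46, 0.29, 0.31, 0.35, 0.30)
  data.frame(index_kind = "PI",
             sex = rep(c("male", "female"), each = 11L),
             ga_weeks = rep(32:42, 2L),
             mean = c(m, f), sd = c(m_sd, f_sd))
}

#' Neonatal nutrition reference table
#'
#' A sex-by-completed-gestational-week (32-42) table of mean and SD for a
#' neonatal anthropometric index (BMI in kg/m2, or ponderal index in
#' g/cm3 x 100). Defaults are the packaged references; user-supplied
#' replacement tables are accepted through the same schema.
#'
#' @param index_kind `"BMI"` or `"PI"`.
#' @param table optional replacement data.frame with columns `sex`,
#'   `ga_weeks` (integer completed weeks), `mean`, `sd`; when `NULL` the
#'   packaged table for `index_kind` is used.
#' @return An object of class `nutrition_reference`.
#' @export
nutrition_reference <- function(index_kind = c("BMI", "PI"), table = NULL) {
  index_kind <- match.arg(index_kind)
  if (is.null(table)) {
    table <- if (index_kind == "BMI") .bmi_reference_values()
             else .pi_reference_values()
  }
  need <- c("sex", "ga_weeks", "mean", "sd")
  miss <- setdiff(need, names(table))
  if (length(miss)) {
    stop("nutrition reference missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  table$sex <- ifelse(sex_code(table$sex) == 1L, "male", "female")
  if (any(table$mean <= 0) || any(table$sd <= 0)) {
    stop("nutrition reference means and SDs must be > 0", call. = FALSE)
  }
  if (any(table$ga_weeks != as.integer(table$ga_weeks))) {
    stop("nutrition reference gestational ages must be completed weeks",
         call. = FALSE)
  }
  structure(list(index_kind = index_kind,
                 table = table[order(table$sex, table$ga_weeks), ,
                               drop = FALSE]),
            class = "nutrition_reference")
}

#' Read a nutrition reference table from CSV
#'
#' Expected columns: `index_kind`, `sex`, `ga_weeks`, `mean`, `sd`; `#` lines
#' are comments. All rows must share one `index_kind`.
#'
#' @param path CSV path; see the packaged
#'   `extdata/neonatal_bmi_reference.csv` for the schema.
#' @return A [nutrition_reference()].
#' @export
read_nutrition_reference <- function(path) {
  tab <- utils::read.csv(path, comment.char = "#", strip.white = TRUE)
  kind <- unique(tab$index_kind)
  if (length(kind) != 1L || !kind %in% c("BMI", "PI")) {
    stop("nutrition reference CSV must have a single index_kind, BMI or PI",
         call. = FALSE)
  }
  nutrition_reference(kind, tab[, c("sex", "ga_weeks", "mean", "sd")])
}

#' Neonatal body mass index
#'
#' `BMI = weight(kg) / length(m)^2`, from birthweight in grams and birth
#' length in cm.
#'
#' @param weight birthweight in grams (> 0).
#' @param length birth length in cm (> 0).
#' @return BMI in kg/m2.
#' @export
neonatal_bmi <- function(weight, length) {
  .check_positive(weight, "weight"); .check_positive(length, "length")
  (weight / 1000) / (length / 100)^2
}

#' Neonatal (Rohrer) ponderal index
#'
#' `PI = weight(g) x 100 / length(cm)^3`.
#'
#' @inheritParams neonatal_bmi
#' @return Ponderal index in g/cm3 x 100.
#' @export
ponderal_index <- function(weight, length) {
  .check_positive(weight, "weight"); .check_positive(length, "length")
  weight * 100 / length^3
}

.check_positive <- function(x, what) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("`%s` must be finite and > 0", what), call. = FALSE)
  }
}

#' Centile of a nutrition index value against a reference
#'
#' The gestational age at birth is floored to completed weeks (obstetric
#' convention) to pick the reference row; the centile is the standard-normal
#' cumulative probability of the row z-score, times 100. Records outside the
#' 32-42 completed-week coverage get `NA` with a warning (flagged, not
#' dropped) unless `strict = TRUE`.
#'
#' @param value index value(s) (BMI or PI, matching the reference).
#' @param sex newborn sex (see [sex_code()]).
#' @param ga gestational age at birth, decimal weeks.
#' @param reference a [nutrition_reference()].
#' @param strict error (rather than warn + NA) on out-of-coverage records.
#' @return Percentile(s) in (0, 100); NA where out of coverage.
#' @export
nutrition_centile <- function(value, sex, ga,
                              reference = nutrition_reference("BMI"),
                              strict = FALSE) {
  stopifnot(inherits(reference, "nutrition_reference"))
  n <- max(length(value), length(sex), length(ga))
  value <- rep_len(value, n)
  sx <- rep_len(ifelse(sex_code(sex) == 1L, "male", "female"), n)
  wk <- floor(rep_len(ga, n))
  out_cov <- wk < NUTRITION_GA_MIN | wk > NUTRITION_GA_MAX
  if (any(out_cov)) {
    msg <- sprintf(
      "%d record(s) outside the %d-%d completed-week nutrition reference coverage",
      sum(out_cov), NUTRITION_GA_MIN, NUTRITION_GA_MAX)
    if (strict) stop(msg, call. = FALSE)
    warning(msg, "; centile set to NA", call. = FALSE)
  }
  key <- paste(sx, wk)
  ref_key <- paste(reference$table$sex, reference$table$ga_weeks)
  idx <- match(key, ref_key)
  idx[out_cov] <- NA_integer_
  mu <- reference$table$mean[idx]
  sd <- reference$table$sd[idx]
  ifelse(is.na(idx), NA_real_, stats::pnorm((value - mu) / sd) * 100)
}

#' Classify neonatal nutritional status from a centile
#'
#' Below the 10th centile: undernourished. Above the 90th: overnourished —
#' these carry an exclusion flag because overnourished newborns are removed
#' from the undernutrition diagnostics. Ties at exactly 10/90 are normal.
#' `NA` centiles (out-of-coverage) return `NA`.
#'
#' @param centile percentile(s) in (0, 100), possibly NA.
#' @return Factor with levels `undernourished`, `normal`, `overnourished`,
#'   with attribute `exclude` — a logical vector marking records excluded
#'   from diagnostics (overnourished or out-of-coverage).
#' @export
classify_nutrition <- function(centile) {
  ok <- !is.na(centile)
  if (any(centile[ok] <= 0) || any(centile[ok] >= 100)) {
    stop("`centile` must lie strictly inside (0, 100)", call. = FALSE)
  }
  out <- ifelse(centile < 10, "undernourished",
                ifelse(centile > 90, "overnourished", "normal"))
  f <- factor(out, levels = c("undernourished", "normal", "overnourished"))
  attr(f, "exclude") <- is.na(centile) | (ok & out == "overnourished")
  f
}
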