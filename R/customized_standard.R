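# Customized fetal growth standard: per-pregnancy term optimal weight from
# maternal anthropometrics and fetal sex, scaled across gestation by a
# cubic proportionality curve, with CV-based z-scores and centiles.

GA_MIN <- 20
GA_MAX <- 44

#' Coefficients of the customized term-optimal-weight model
#'
#' The customized standard predicts the ideal weight a newborn would reach at
#' 40 weeks as a linear function of maternal age (years), pregestational
#' weight (kg), maternal height (cm) and fetal sex (male = 1, female = 0).
#' Defaults are the published model estimated on the reference obstetric
#' population; the coefficient of variation `cv` converts the ratio
#' observed/ideal weight into a z-score.
#'
#' @param intercept grams.
#' @param age_coef grams per maternal year.
#' @param weight_coef grams per kg of pregestational weight.
#' @param height_coef grams per cm of maternal height.
#' @param sex_coef grams added for a male fetus.
#' @param cv coefficient of variation of weight-for-gestational-age
#'   (dimensionless, > 0).
#' @return An object of class `customized_coefficients`.
#' @examples
#' customized_coefficients()
#' @export
customized_coefficients <- function(intercept = 1407.501,
                                    age_coef = 4.087,
                                    weight_coef = 6.506,
                                    height_coef = 8.716,
                                    sex_coef = 150.375,
                                    cv = 0.12) {
  stopifnot(is.numeric(cv), length(cv) == 1L)
  if (!(cv > 0)) stop("`cv` must be > 0", call. = FALSE)
  for (nm in c("intercept", "age_coef", "weight_coef", "height_coef",
               "sex_coef")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop(sprintf("`%s` must be a finite numeric scalar", nm), call. = FALSE)
    }
  }
  structure(
    list(intercept = intercept, age_coef = age_coef,
         weight_coef = weight_coef, height_coef = height_coef,
         sex_coef = sex_coef, cv = cv),
    class = "customized_coefficients"
  )
}

#' Coefficients of the gestational-age proportionality polynomial
#'
#' Cubic polynomial giving the percentage of the 40-week weight attained at a
#' gestational age (decimal weeks): `c0 + c1*GA + c2*GA^2 + c3*GA^3`, on the
#' percent scale. The polynomial is used raw — its value at 40 weeks is close
#' to, but not renormalized to, 100%.
#'
#' @param c0,c1,c2,c3 polynomial coefficients (percent scale, GA in weeks).
#' @return An object of class `proportionality_coefficients`.
#' @export
proportionality_coefficients <- function(c0 = 299.1, c1 = -31.85,
                                         c2 = 1.094, c3 = -0.01055) {
  coefs <- c(c0 = c0, c1 = c1, c2 = c2, c3 = c3)
  if (!all(is.finite(coefs))) {
    stop("proportionality coefficients must be finite", call. = FALSE)
  }
  structure(as.list(coefs), class = "proportionality_coefficients")
}

.check_ga <- function(ga, what = "ga") {
  if (!is.numeric(ga) || any(!is.finite(ga))) {
    stop(sprintf("`%s` must be finite numeric (decimal weeks)", what),
         call. = FALSE)
  }
  bad <- ga < GA_MIN | ga > GA_MAX
  if (any(bad)) {
    stop(sprintf("`%s` outside [%d, %d] weeks: %s", what, GA_MIN, GA_MAX,
                 paste(utils::head(ga[bad], 5L), collapse = ", ")),
         call. = FALSE)
  }
  invisible(ga)
}

#' Term optimal weight for a pregnancy
#'
#' Linear prediction of the ideal 40-week weight (grams) from maternal age,
#' pregestational weight, maternal height and fetal sex. Vectorized over rows
#' of `record`.
#'
#' @param record a data.frame (or list) with columns/fields `maternal_age`
#'   (years), `pregestational_weight` (kg), `maternal_height` (cm) and `sex`
#'   (`"male"`/`"female"`, or 1/0).
#' @param coef a [customized_coefficients()] object.
#' @return Numeric vector of ideal 40-week weights in grams.
#' @export
term_optimal_weight <- function(record, coef = customized_coefficients()) {
  stopifnot(inherits(coef, "customized_coefficients"))
  need <- c("maternal_age", "pregestational_weight", "maternal_height", "sex")
  miss <- setdiff(need, names(record))
  if (length(miss)) {
    stop("missing maternal covariate(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  age <- record[["maternal_age"]]
  wt <- record[["pregestational_weight"]]
  ht <- record[["maternal_height"]]
  sx <- sex_code(record[["sex"]])
  if (any(is.na(age)) || any(is.na(wt)) || any(is.na(ht)) || any(is.na(sx))) {
    stop("maternal covariates contain missing values; no imputation is done",
         call. = FALSE)
  }
  coef$intercept + age * coef$age_coef + wt * coef$weight_coef +
    ht * coef$height_coef + sx * coef$sex_coef
}

#' Encode fetal sex as male = 1, female = 0
#'
#' Accepts `"male"`/`"female"` (case-insensitive, abbreviations `"m"`/`"f"`),
#' a factor thereof, or the integers 1/0 already in that coding.
#'
#' @param sex character, factor or 0/1 numeric.
#' @return Integer vector of 1 (male) / 0 (female); NA propagates.
#' @export
sex_code <- function(sex) {
  if (is.factor(sex)) sex <- as.character(sex)
  if (is.numeric(sex)) {
    if (any(!sex %in% c(0, 1) & !is.na(sex))) {
      stop("numeric sex must be coded 1 = male, 0 = female", call. = FALSE)
    }
    return(as.integer(sex))
  }
  s <- tolower(as.character(sex))
  out <- ifelse(s %in% c("male", "m", "1"), 1L,
                ifelse(s %in% c("female", "f", "0"), 0L, NA_integer_))
  if (any(is.na(out) & !is.na(s))) {
    stop("unrecognized sex value(s): ",
         paste(unique(s[is.na(out) & !is.na(s)]), collapse = ", "),
         call. = FALSE)
  }
  out
}

#' Proportionality fraction of the 40-week weight
#'
#' Evaluates the cubic proportionality polynomial at a gestational age in
#' decimal weeks, returning the percentage of the term (40-week) weight.
#' The raw polynomial value is returned: at 40 weeks it is ~100.3%, and this
#' slight excess is intentional (the published worked values are reproduced
#' only by the raw polynomial).
#'
#' @param ga gestational age, decimal weeks in \[20, 44\]. Vectorized.
#' @param coef a [proportionality_coefficients()] object.
#' @return Percent of the 40-week weight.
#' @examples
#' proportionality_fraction(34) # ~66.21
#' @export
proportionality_fraction <- function(ga,
                                     coef = proportionality_coefficients()) {
  stopifnot(inherits(coef, "proportionality_coefficients"))
  .check_ga(ga)
  coef$c0 + coef$c1 * ga + coef$c2 * ga^2 + coef$c3 * ga^3
}

#' Expected (ideal) weight at a gestational age under the customized standard
#'
#' Term optimal weight scaled by the proportionality fraction.
#'
#' @inheritParams term_optimal_weight
#' @param ga gestational age, decimal weeks.
#' @param prop_coef a [proportionality_coefficients()] object.
#' @return Ideal weight in grams at `ga`.
#' @export
expected_weight <- function(record, ga,
                            coef = customized_coefficients(),
                            prop_coef = proportionality_coefficients()) {
  term_optimal_weight(record, coef) *
    proportionality_fraction(ga, prop_coef) / 100
}

#' Weight z-score relative to an ideal weight
#'
#' `z = (observed/ideal - 1) / cv`: the relative deviation from the ideal
#' weight in units of the coefficient of variation.
#'
#' @param observed observed weight (grams); EFW or birthweight.
#' @param ideal ideal weight (grams), must be > 0.
#' @param cv coefficient of variation (> 0), default 0.12.
#' @return z-score(s).
#' @export
weight_zscore <- function(observed, ideal, cv = 0.12) {
  if (any(!is.finite(ideal)) || any(ideal <= 0)) {
    stop("`ideal` must be finite and > 0", call. = FALSE)
  }
  if (!is.numeric(cv) || cv <= 0) stop("`cv` must be > 0", call. = FALSE)
  (observed / ideal - 1) / cv
}

#' Centile from a z-score
#'
#' Cumulative standard-normal probability below `z`, times 100.
#'
#' @param z finite z-score(s).
#' @return Percentile in (0, 100).
#' @export
centile_from_z <- function(z) {
  if (any(!is.finite(z))) stop("`z` must be finite", call. = FALSE)
  stats::pnorm(z) * 100
}

#' Classify size-for-gestational-age from a centile
#'
#' Below the 10th centile is SGA, above the 90th is LGA, otherwise AGA.
#' Ties at exactly the 10th or 90th centile are AGA ("between the 10th and
#' 90th" read as inclusive).
#'
#' @param centile percentile in (0, 100). Vectorized.
#' @return Factor with levels `SGA`, `AGA`, `LGA`.
#' @export
classify_size <- function(centile) {
  if (any(!is.finite(centile)) || any(centile <= 0) || any(centile >= 100)) {
    stop("`centile` must lie strictly inside (0, 100)", call. = FALSE)
  }
  out <- ifelse(centile < 10, "SGA", ifelse(centile > 90, "LGA", "AGA"))
  factor(out, levels = c("SGA", "AGA", "LGA"))
}

#' Estimated fetal weight from biometry (Hadlock-type log10 regression)
#'
#' Utility only: the pipeline accepts EFW directly and never requires
#' biometry. The regression coefficients are configuration data, defaulting
#' to the widely published Hadlock model
#' `log10(EFW) = b0 + b_hc*HC + b_ac*AC + b_fl*FL + b_bpd*BPD + b_acfl*AC*FL`
#' with measurements in cm and EFW in grams.
#'
#' @param bpd,hc,ac,fl biometry in cm (biparietal diameter, head and abdominal
#'   circumference, femur length). A measurement may be omitted (NA) only if
#'   its coefficients are zero.
#' @param coef named list/vector of coefficients `b0`, `b_bpd`, `b_hc`,
#'   `b_ac`, `b_fl`, `b_acfl`; see [hadlock_coefficients()].
#' @return EFW in grams.
#' @export
hadlock_efw <- function(bpd = NA_real_, hc = NA_real_, ac = NA_real_,
                        fl = NA_real_, coef = hadlock_coefficients()) {
  coef <- as.list(coef)
  need <- c("b0", "b_bpd", "b_hc", "b_ac", "b_fl", "b_acfl")
  if (!all(need %in% names(coef))) {
    stop("hadlock coefficient table must name: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  used <- list(bpd = coef$b_bpd, hc = coef$b_hc,
               ac = c(coef$b_ac, coef$b_acfl), fl = c(coef$b_fl, coef$b_acfl))
  vals <- list(bpd = bpd, hc = hc, ac = ac, fl = fl)
  for (m in names(used)) {
    if (any(used[[m]] != 0) && any(is.na(vals[[m]]))) {
      stop(sprintf("biometry `%s` required by the coefficient table but missing",
                   m), call. = FALSE)
    }
  }
  z <- function(x) ifelse(is.na(x), 0, x) # zero-coefficient terms only
  log10efw <- coef$b0 + coef$b_bpd * z(bpd) + coef$b_hc * z(hc) +
    coef$b_ac * z(ac) + coef$b_fl * z(fl) + coef$b_acfl * z(ac) * z(fl)
  10^log10efw
}

#' Default Hadlock EFW coefficients, loadable from a config file
#'
#' Reads a `key = value` config file (one pair per line, `#` comments). The
#' packaged default is the Hadlock model using HC, AC and FL.
#'
#' @param path optional path to a coefficient config file; when `NULL` the
#'   packaged defaults are used.
#' @return Named list of coefficients.
#' @export
hadlock_coefficients <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "hadlock_coefficients.conf",
                        package = "customgrowth", mustWork = TRUE)
  }
  kv <- read_keyvalue(path)
  defaults <- list(b0 = 0, b_bpd = 0, b_hc = 0, b_ac = 0, b_fl = 0,
                   b_acfl = 0)
  for (nm in names(kv)) {
    if (!nm %in% names(defaults)) {
      stop("unknown hadlock coefficient key: ", nm, call. = FALSE)
    }
    defaults[[nm]] <- as.numeric(kv[[nm]])
  }
  defaults
}

# Parse a minimal `key = value` config file into a named character list.
read_keyvalue <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) != 2L) {
      stop("malformed config line (expected `key = value`): ", ln,
           call. = FALSE)
    }
    kv[[trimws(parts[1])]] <- trimws(parts[2])
  }
  kv
}
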