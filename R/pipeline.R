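# End-to-end orchestration: strict cohort CSV parsing, per-stratum
# classification under competing standards, nutrition status, the
# diagnostics battery, method comparisons, and tidy/Markdown reports.

COHORT_COLUMNS <- c("maternal_age", "maternal_height",
                    "pregestational_weight", "sex", "ga_scan", "efw",
                    "ga_birth", "birthweight", "birth_length")

#' Read and validate a cohort CSV
#'
#' The file must carry the documented header (columns `maternal_age`,
#' `maternal_height`, `pregestational_weight`, `sex`, `ga_scan`, `efw`,
#' `ga_birth`, `birthweight`, `birth_length`). Each row is validated:
#' physical quantities strictly positive, gestational ages within
#' \[20, 44\] weeks, sex decodable. Invalid rows are removed and returned in
#' the `rejects` attribute (row number + reason), never silently dropped.
#'
#' @param path CSV path.
#' @return data.frame of valid records, with attribute `rejects`.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, strip.white = TRUE, stringsAsFactors = FALSE)
  miss <- setdiff(COHORT_COLUMNS, names(df))
  if (length(miss)) {
    stop("cohort CSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  validate_cohort(df[, COHORT_COLUMNS])
}

#' Validate a cohort data.frame row by row
#'
#' @param df data.frame with the cohort columns.
#' @return Valid rows, with invalid ones in attribute `rejects` (columns
#'   `row`, `reason`).
#' @export
validate_cohort <- function(df) {
  reasons <- character(nrow(df))
  num_cols <- setdiff(COHORT_COLUMNS, "sex")
  for (cc in num_cols) df[[cc]] <- suppressWarnings(as.numeric(df[[cc]]))
  sx <- vapply(as.character(df$sex), function(v) {
    tryCatch(sex_code(v), error = function(e) NA_integer_)
  }, integer(1), USE.NAMES = FALSE)
  for (i in seq_len(nrow(df))) {
    probs <- character()
    for (cc in num_cols) {
      v <- df[[cc]][i]
      if (is.na(v)) probs <- c(probs, paste0(cc, " missing/non-numeric"))
      else if (v <= 0) probs <- c(probs, paste0(cc, " not > 0"))
    }
    for (cc in c("ga_scan", "ga_birth")) {
      v <- df[[cc]][i]
      if (!is.na(v) && (v < GA_MIN || v > GA_MAX)) {
        probs <- c(probs, sprintf("%s outside [%d, %d] weeks", cc, GA_MIN,
                                  GA_MAX))
      }
    }
    if (is.na(sx[i])) probs <- c(probs, "sex unrecognized")
    reasons[i] <- paste(probs, collapse = "; ")
  }
  ok <- !nzchar(reasons)
  out <- df[ok, , drop = FALSE]
  out$sex <- ifelse(sx[ok] == 1L, "male", "female")
  rownames(out) <- NULL
  attr(out, "rejects") <- data.frame(row = which(!ok),
                                     reason = reasons[!ok],
                                     stringsAsFactors = FALSE)
  out
}

#' Analysis run configuration
#'
#' @param standards named list of `growth_standard` objects to compare (the
#'   first two drive the method-comparison tests).
#' @param indices nutrition indices to run (`"BMI"`, `"PI"` or both).
#' @param strata any of `"all"`, `"term"` (birth in \[37, 42\] weeks),
#'   `"preterm"` (< 37 weeks). Births after 42 weeks are excluded with a
#'   warning (outside the nutrition references).
#' @param use_efw classify prenatally on EFW at the scan gestational age
#'   (default), or on birthweight at birth.
#' @param seed seed for the (bootstrap) confidence intervals.
#' @param youden_ci,continuity passed to [diagnostic_summary()] /
#'   [relative_risk()].
#' @return An object of class `run_config`.
#' @export
run_config <- function(standards = list(customized = customized_standard(),
                                        population =
                                          demo_population_standard()),
                       indices = c("BMI", "PI"),
                       strata = c("all", "term", "preterm"),
                       use_efw = TRUE, seed = 1L,
                       youden_ci = "bootstrap", continuity = FALSE) {
  stopifnot(length(standards) >= 1,
            all(vapply(standards, inherits, logical(1), "growth_standard")),
            length(indices) >= 1, all(indices %in% c("BMI", "PI")),
            all(strata %in% c("all", "term", "preterm")))
  if (is.null(names(standards)) || any(!nzchar(names(standards)))) {
    stop("`standards` must be a named list", call. = FALSE)
  }
  structure(list(standards = standards, indices = indices, strata = strata,
                 use_efw = use_efw, seed = seed, youden_ci = youden_ci,
                 continuity = continuity),
            class = "run_config")
}

.stratum_filter <- function(ga_birth, stratum) {
  switch(stratum,
         all = rep(TRUE, length(ga_birth)),
         term = ga_birth >= 37 & ga_birth <= 42,
         preterm = ga_birth < 37)
}

#' Run the full comparison analysis on a cohort
#'
#' For every stratum x standard x nutrition index: the SGA/AGA/LGA tally,
#' the 2x2 table against undernutrition, the diagnostic battery, and the
#' relative risk; for the first two standards additionally the Altman-Bland
#' RR comparison, McNemar tests on sensitivity and specificity, the
#' chi-square comparison of SGA and LGA frequencies, and (when exactly two
#' standards are given) the both-methods-SGA risk group. Records excluded at
#' any step are counted with a reason; per stratum,
#' analyzed + excluded = n.
#'
#' @param cohort data.frame of validated pregnancy records (see
#'   [read_cohort()]).
#' @param config a [run_config()].
#' @return An object of class `growth_report`: list with `metrics` (tidy
#'   data.frame), `classification` (size tallies), `risk` (RR rows incl.
#'   both-SGA group), `comparisons`, `exclusions` and `config`.
#' @export
run_analysis <- function(cohort, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  if (nrow(cohort) == 0) stop("empty cohort", call. = FALSE)
  post_term <- cohort$ga_birth > 42
  if (any(post_term)) {
    warning(sum(post_term), " post-term (> 42 wk) record(s) excluded",
            call. = FALSE)
  }
  w <- if (config$use_efw) cohort$efw else cohort$birthweight
  ga_class <- if (config$use_efw) cohort$ga_scan else cohort$ga_birth

  # size class per standard, nutrition status per index, computed once
  size <- lapply(config$standards, function(std) {
    classify_weight(std, w, ga_class, cohort$sex, cohort)
  })
  nut <- lapply(config$indices, function(ix) {
    ref <- nutrition_reference(ix)
    val <- if (ix == "BMI") neonatal_bmi(cohort$birthweight,
                                         cohort$birth_length)
           else ponderal_index(cohort$birthweight, cohort$birth_length)
    classify_nutrition(suppressWarnings(
      nutrition_centile(val, cohort$sex, cohort$ga_birth, ref)))
  })
  names(nut) <- config$indices

  metrics <- list(); class_rows <- list(); risk_rows <- list()
  comp_rows <- list(); excl_rows <- list()
  std_names <- names(config$standards)
  metric_names <- c("sensitivity", "specificity", "ppv", "npv", "lr_pos",
                    "lr_neg", "dor", "youden")

  for (stratum in config$strata) {
    in_str <- .stratum_filter(cohort$ga_birth, stratum) & !post_term
    n_str <- sum(in_str)
    for (s in std_names) {
      sc <- size[[s]][in_str]
      tal <- table(sc)
      class_rows[[length(class_rows) + 1L]] <- data.frame(
        stratum = stratum, standard = s,
        size_class = names(tal), n = as.integer(tal),
        pct = round(100 * as.integer(tal) / n_str, 1))
      for (ix in config$indices) {
        nu <- nut[[ix]][in_str]
        tab <- build_table(sc, nu,
                           exposure_label = paste(s, "SGA"),
                           outcome_label = paste(ix, "undernourished"))
        ds <- diagnostic_summary(tab, youden_ci = config$youden_ci,
                                 boot_seed = config$seed,
                                 continuity = config$continuity)
        for (m in metric_names) {
          metrics[[length(metrics) + 1L]] <- data.frame(
            stratum = stratum, standard = s, index = ix, metric = m,
            estimate = ds[[m]]$estimate, ci_low = ds[[m]]$ci_low,
            ci_high = ds[[m]]$ci_high, n_eligible = ds$n_eligible)
        }
        rr <- tryCatch(relative_risk(tab, continuity = config$continuity),
                       error = function(e) NULL, warning = function(w_) {
                         suppressWarnings(relative_risk(tab,
                           continuity = config$continuity))
                       })
        metrics[[length(metrics) + 1L]] <- data.frame(
          stratum = stratum, standard = s, index = ix, metric = "rr",
          estimate = if (is.null(rr)) NA_real_ else rr$rr,
          ci_low = if (is.null(rr)) NA_real_ else rr$ci_low,
          ci_high = if (is.null(rr)) NA_real_ else rr$ci_high,
          n_eligible = ds$n_eligible)
        excl_rows[[length(excl_rows) + 1L]] <- data.frame(
          stratum = stratum, standard = s, index = ix, n_stratum = n_str,
          analyzed = ds$n_eligible, excluded_lga = tab$excluded_lga,
          excluded_overnourished = tab$excluded_overnourished,
          excluded_out_of_coverage = tab$excluded_out_of_coverage)
      }
    }

    if (length(std_names) >= 2) {
      s1 <- std_names[1]; s2 <- std_names[2]
      sc1 <- size[[s1]][in_str]; sc2 <- size[[s2]][in_str]
      comp_rows[[length(comp_rows) + 1L]] <- data.frame(
        stratum = stratum, index = NA_character_,
        comparison = "sga_frequency_chi2",
        statistic = compare_proportions(sum(sc1 == "SGA"), n_str,
                                        sum(sc2 == "SGA"), n_str)$chi2,
        p = compare_proportions(sum(sc1 == "SGA"), n_str,
                                sum(sc2 == "SGA"), n_str)$p)
      comp_rows[[length(comp_rows) + 1L]] <- data.frame(
        stratum = stratum, index = NA_character_,
        comparison = "lga_frequency_chi2",
        statistic = compare_proportions(sum(sc1 == "LGA"), n_str,
                                        sum(sc2 == "LGA"), n_str)$chi2,
        p = compare_proportions(sum(sc1 == "LGA"), n_str,
                                sum(sc2 == "LGA"), n_str)$p)
      for (ix in config$indices) {
        nu <- nut[[ix]][in_str]
        eligible <- !is.na(nu) & nu != "overnourished" &
          sc1 != "LGA" & sc2 != "LGA"
        pos <- eligible & nu == "undernourished"
        neg <- eligible & nu == "normal"
        mc_se <- mcnemar_test(sc1[pos] == "SGA", sc2[pos] == "SGA")
        mc_sp <- mcnemar_test(sc1[neg] != "SGA", sc2[neg] != "SGA")
        comp_rows[[length(comp_rows) + 1L]] <- data.frame(
          stratum = stratum, index = ix, comparison = "mcnemar_sensitivity",
          statistic = mc_se$statistic, p = mc_se$p)
        comp_rows[[length(comp_rows) + 1L]] <- data.frame(
          stratum = stratum, index = ix, comparison = "mcnemar_specificity",
          statistic = mc_sp$statistic, p = mc_sp$p)
        rr1 <- .safe_rr(build_table(sc1, nu), config$continuity)
        rr2 <- .safe_rr(build_table(sc2, nu), config$continuity)
        if (!is.null(rr1) && !is.null(rr2) && !is.na(rr1$log_se) &&
            !is.na(rr2$log_se)) {
          cr <- compare_rr(rr1, rr2)
          comp_rows[[length(comp_rows) + 1L]] <- data.frame(
            stratum = stratum, index = ix, comparison = "altman_bland_rr",
            statistic = cr$ratio, p = cr$p)
        }
        # both-methods-SGA risk group (exposed: SGA by both; ref: AGA by both)
        both_class <- ifelse(sc1 == "SGA" & sc2 == "SGA", "SGA",
                             ifelse(sc1 == "AGA" & sc2 == "AGA", "AGA",
                                    "LGA"))
        rrb <- .safe_rr(build_table(both_class, nu), config$continuity)
        risk_rows[[length(risk_rows) + 1L]] <- data.frame(
          stratum = stratum, index = ix, group = "both_standards_sga",
          rr = if (is.null(rrb)) NA_real_ else rrb$rr,
          ci_low = if (is.null(rrb)) NA_real_ else rrb$ci_low,
          ci_high = if (is.null(rrb)) NA_real_ else rrb$ci_high)
      }
    }
  }

  structure(list(metrics = do.call(rbind, metrics),
                 classification = do.call(rbind, class_rows),
                 risk = if (length(risk_rows)) do.call(rbind, risk_rows),
                 comparisons = if (length(comp_rows))
                   do.call(rbind, comp_rows),
                 exclusions = do.call(rbind, excl_rows),
                 config = config, n_input = nrow(cohort),
                 n_post_term = sum(post_term)),
            class = "growth_report")
}

.safe_rr <- function(tab, continuity) {
  tryCatch(suppressWarnings(relative_risk(tab, continuity = continuity)),
           error = function(e) NULL)
}

#' Write a report bundle to disk
#'
#' Emits `metrics.csv` (tidy, one row per stratum x standard x index x
#' metric), `classification.csv`, `comparisons.csv`, `exclusions.csv`,
#' `forest_dor.csv` (forest-plot-ready DOR rows) and a human-readable
#' `report.md`.
#'
#' @param report a `growth_report` from [run_analysis()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "growth_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(metrics = file.path(out_dir, "metrics.csv"),
             classification = file.path(out_dir, "classification.csv"),
             comparisons = file.path(out_dir, "comparisons.csv"),
             exclusions = file.path(out_dir, "exclusions.csv"),
             forest = file.path(out_dir, "forest_dor.csv"),
             report = file.path(out_dir, "report.md"))
  utils::write.csv(report$metrics, paths["metrics"], row.names = FALSE)
  utils::write.csv(report$classification, paths["classification"],
                   row.names = FALSE)
  if (!is.null(report$comparisons)) {
    utils::write.csv(report$comparisons, paths["comparisons"],
                     row.names = FALSE)
  }
  utils::write.csv(report$exclusions, paths["exclusions"], row.names = FALSE)
  forest <- report$metrics[report$metrics$metric == "dor", ]
  utils::write.csv(forest, paths["forest"], row.names = FALSE)
  writeLines(format_report_md(report), paths["report"])
  invisible(paths)
}

#' Render a growth_report as Markdown
#'
#' @param report a `growth_report`.
#' @return Character vector of Markdown lines.
#' @export
format_report_md <- function(report) {
  m <- report$metrics
  lines <- c("# Growth standard comparison report", "",
             sprintf("Input records: %d (post-term excluded: %d)",
                     report$n_input, report$n_post_term), "")
  fmt <- function(e, lo, hi) {
    ifelse(is.na(e), "undefined",
           sprintf("%.2f (%.2f - %.2f)", e, lo, hi))
  }
  for (stratum in unique(m$stratum)) {
    lines <- c(lines, sprintf("## Stratum: %s", stratum), "")
    for (ix in unique(m$index)) {
      sub <- m[m$stratum == stratum & m$index == ix, ]
      stds <- unique(sub$standard)
      lines <- c(lines, sprintf("### Undernutrition by %s", ix), "",
                 paste0("| metric | ", paste(stds, collapse = " | "), " |"),
                 paste0("|---|", paste(rep("---|", length(stds)),
                                       collapse = "")))
      for (met in unique(sub$metric)) {
        cells <- vapply(stds, function(s) {
          r <- sub[sub$standard == s & sub$metric == met, ]
          fmt(r$estimate, r$ci_low, r$ci_high)
        }, character(1))
        lines <- c(lines, paste0("| ", met, " | ",
                                 paste(cells, collapse = " | "), " |"))
      }
      lines <- c(lines, "")
    }
  }
  if (!is.null(report$comparisons)) {
    lines <- c(lines, "## Method comparisons", "",
               "| stratum | index | comparison | statistic | p |",
               "|---|---|---|---|---|")
    cc <- report$comparisons
    for (i in seq_len(nrow(cc))) {
      lines <- c(lines, sprintf("| %s | %s | %s | %s | %.4g |",
                                cc$stratum[i],
                                ifelse(is.na(cc$index[i]), "-", cc$index[i]),
                                cc$comparison[i],
                                ifelse(is.na(cc$statistic[i]), "-",
                                       sprintf("%.4g", cc$statistic[i])),
                                cc$p[i]))
    }
    lines <- c(lines, "")
  }
  lines
}

#' Command-line entry point
#'
#' Verbs: `simulate` (write a synthetic cohort CSV), `classify` (per-record
#' size + nutrition classifications to CSV), `compare` / `all` (end-to-end
#' report bundle). Flags: `--input PATH`, `--out DIR`, `--n N`,
#' `--seed S`, `--index BMI|PI|both`, `--strata all,term,preterm`,
#' `--birthweight` (classify on birthweight instead of EFW),
#' `--hdp-shift X`, `--rho R`.
#'
#' @param argv character vector of arguments (verb first), e.g.
#'   `c("all", "--input", "cohort.csv", "--out", "results")`.
#' @return Integer exit code, invisibly: 0 success, 2 validation failure,
#'   3 empty analysis set.
#' @export
run_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (length(argv) == 0) {
    message("usage: customgrowth <simulate|classify|compare|all> [flags]")
    return(invisible(2L))
  }
  verb <- argv[1]
  flags <- .parse_flags(argv[-1])
  if (is.null(flags)) return(invisible(2L))
  seed <- as.integer(flags$seed %||% 1L)
  out_dir <- flags$out %||% "."
  indices <- switch(flags$index %||% "both",
                    both = c("BMI", "PI"), BMI = "BMI", PI = "PI")
  status <- tryCatch({
    if (verb == "simulate") {
      n <- as.integer(flags$n %||% 226L)
      cfg <- simulation_config(
        n = n, seed = seed,
        hdp_shift = as.numeric(flags[["hdp-shift"]] %||% 0),
        rho = as.numeric(flags$rho %||% 0.6))
      coh <- simulate_cohort(cfg)
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      utils::write.csv(coh[, COHORT_COLUMNS],
                       file.path(out_dir, "cohort.csv"), row.names = FALSE)
      message("wrote ", file.path(out_dir, "cohort.csv"))
      0L
    } else if (verb %in% c("classify", "compare", "all")) {
      if (is.null(flags$input)) {
        message("--input PATH is required"); return(invisible(2L))
      }
      coh <- read_cohort(flags$input)
      rej <- attr(coh, "rejects")
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      if (nrow(rej)) {
        utils::write.csv(rej, file.path(out_dir, "rejects.csv"),
                         row.names = FALSE)
        message(nrow(rej), " rejected row(s) written to rejects.csv")
      }
      if (nrow(coh) == 0) {
        message("no valid records"); return(invisible(3L))
      }
      cfg <- run_config(indices = indices,
                        strata = strsplit(flags$strata %||%
                                            "all,term,preterm", ",")[[1]],
                        use_efw = is.null(flags$birthweight), seed = seed)
      if (verb == "classify") {
        cls <- classify_cohort(coh, cfg)
        utils::write.csv(cls, file.path(out_dir, "classified.csv"),
                         row.names = FALSE)
        message("wrote ", file.path(out_dir, "classified.csv"))
      } else {
        rep_ <- run_analysis(coh, cfg)
        write_report(rep_, out_dir)
        message("report bundle written to ", out_dir)
      }
      0L
    } else {
      message("unknown verb: ", verb)
      2L
    }
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    2L
  })
  invisible(status)
}

#' Per-record classifications under the configured standards and indices
#'
#' @param cohort validated cohort data.frame.
#' @param config a [run_config()].
#' @return The cohort with one size-class column per standard and centile +
#'   status columns per nutrition index.
#' @export
classify_cohort <- function(cohort, config = run_config()) {
  w <- if (config$use_efw) cohort$efw else cohort$birthweight
  ga <- if (config$use_efw) cohort$ga_scan else cohort$ga_birth
  out <- cohort
  for (s in names(config$standards)) {
    out[[paste0("size_", s)]] <-
      classify_weight(config$standards[[s]], w, ga, cohort$sex, cohort)
  }
  for (ix in config$indices) {
    val <- if (ix == "BMI") neonatal_bmi(cohort$birthweight,
                                         cohort$birth_length)
           else ponderal_index(cohort$birthweight, cohort$birth_length)
    cent <- suppressWarnings(
      nutrition_centile(val, cohort$sex, cohort$ga_birth,
                        nutrition_reference(ix)))
    out[[paste0(tolower(ix), "_value")]] <- val
    out[[paste0(tolower(ix), "_centile")]] <- cent
    out[[paste0(tolower(ix), "_status")]] <-
      as.character(classify_nutrition(cent))
  }
  out
}

.parse_flags <- function(args) {
  flags <- list()
  i <- 1L
  bool_flags <- c("birthweight")
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) {
      message("unexpected argument: ", a); return(NULL)
    }
    key <- substring(a, 3)
    if (key %in% bool_flags) {
      flags[[key]] <- TRUE; i <- i + 1L
    } else {
      if (i == length(args)) { message("flag needs a value: ", a); return(NULL) }
      flags[[key]] <- args[i + 1L]; i <- i + 2L
    }
  }
  flags
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Format a count as a percentage string at printed precision
#'
#' @param k,n numerator and denominator.
#' @param digits decimal places.
#' @return Numeric percentage rounded to `digits`.
#' @export
pct <- function(k, n, digits = 1) round(100 * k / n, digits)
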