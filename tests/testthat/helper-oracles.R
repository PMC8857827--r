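# Independent oracles used across the suite: deliberately naive
# re-implementations, kept separate from the package's computation paths.

# Horner-form cubic evaluation (cross-check for proportionality_fraction).
horner_cubic <- function(ga, c0, c1, c2, c3) {
  ((c3 * ga + c2) * ga + c1) * ga + c0
}

# Brute-force filter-and-count construction of the 2x2 + exclusions.
oracle_build_table <- function(size_class, nutrition) {
  size_class <- as.character(size_class)
  nutrition <- as.character(nutrition)
  counts <- c(tp = 0L, fp = 0L, fn = 0L, tn = 0L, lga = 0L, over = 0L,
              ooc = 0L)
  for (i in seq_along(size_class)) {
    s <- size_class[i]; u <- nutrition[i]
    if (is.na(s) || is.na(u)) counts["ooc"] <- counts["ooc"] + 1L
    else if (s == "LGA") counts["lga"] <- counts["lga"] + 1L
    else if (u == "overnourished") counts["over"] <- counts["over"] + 1L
    else if (s == "SGA" && u == "undernourished") counts["tp"] <- counts["tp"] + 1L
    else if (s == "SGA") counts["fp"] <- counts["fp"] + 1L
    else if (u == "undernourished") counts["fn"] <- counts["fn"] + 1L
    else counts["tn"] <- counts["tn"] + 1L
  }
  counts
}

# Doubled binomial tail (p = 0.5 is symmetric, so this equals the exact
# two-sided McNemar p).
oracle_mcnemar_exact <- function(b, c) {
  n <- b + c
  if (n == 0) return(1)
  if (b == c) return(1)
  min(1, 2 * pbinom(min(b, c), n, 0.5))
}

# Random 2x2 with all cells positive.
random_table <- function() {
  contingency_table(sample(1:40, 1), sample(1:40, 1), sample(1:40, 1),
                    sample(1:40, 1))
}

# A tiny hand-built cohort data.frame for pipeline tests.
toy_cohort <- function(n = 60, seed = 11) {
  simulate_cohort(simulation_config(n = n, seed = seed, hdp_shift = -0.5))
}
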