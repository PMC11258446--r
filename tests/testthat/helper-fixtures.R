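# Shared small-scale fixtures, built in code at test time.

# A compact study: 4 cohorts x 200 subjects x 16 analytes, no outliers so
# sample counts are stable across tests that don't exercise outlier removal.
small_study <- function(seed = 42, outlier_fraction = 0, batch_sd = 0.15,
                        n_cohorts = 4, n_subjects = 200,
                        n_metabolites = 16, ...) {
  cfg <- sim_config(seed = seed, n_cohorts = n_cohorts,
                    n_subjects = n_subjects, n_metabolites = n_metabolites,
                    outlier_fraction = outlier_fraction,
                    batch_sd = batch_sd, missing_analytes = list(), ...)
  g <- simulate_cohorts(cfg)
  lv <- add_longitudinal_visits(g$matrix, g$pheno, cfg, g$truth)
  pheno <- simulate_survival(lv$pheno, lv$matrix, cfg)
  list(config = cfg, matrix = lv$matrix, pheno = pheno, truth = g$truth)
}

# A plain multivariate-normal analyte block wrapped as a metabolite matrix.
plain_matrix <- function(n, p, seed = 1, cohort = "cohortA") {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, sprintf("m%03d", seq_len(p))))
  data.frame(sample_id = sprintf("s%04d", seq_len(n)),
             subject_id = sprintf("s%04d", seq_len(n)),
             cohort = cohort, visit = 1L, x, stringsAsFactors = FALSE)
}

# Independent brute-force BH step-up, straight from the definition.
bh_bruteforce <- function(p) {
  m <- length(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    r <- rank(p, ties.method = "first")[i]
    cand <- vapply(seq_len(m), function(j) {
      rj <- rank(p, ties.method = "first")[j]
      if (rj >= r) m * p[j] / rj else Inf
    }, numeric(1))
    q[i] <- min(1, min(cand))
  }
  q
}

# Independent per-variable VIF via explicit regressions.
vif_bruteforce <- function(x) {
  vapply(seq_len(ncol(x)), function(j) {
    fit <- lm(x[, j] ~ x[, -j])
    1 / (1 - summary(fit)$r.squared)
  }, numeric(1))
}
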