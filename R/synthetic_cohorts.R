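#' Configuration for the multi-cohort metabolomics simulator
#'
#' Builds a fully materialized simulation configuration: every generative
#' parameter (per-analyte age slopes, hinge effects, mortality log hazard
#' ratios, latent-factor loadings, cohort batch factors, ...) is drawn once,
#' deterministically from `seed`, and stored in the returned object. The
#' defaults emulate the structure of a multi-cohort NMR metabolomics study:
#' eight cohorts with distinct age windows jointly spanning 24-86 years,
#' about 60% female, per-cohort multiplicative assay batch effects, analytes
#' with linear and hinge-shaped age trends, a sparse set of analytes driving
#' mortality (some concordant with their age trend, some opposing it),
#' analytes entirely unmeasured in some cohorts, repeat visits for a subset
#' of subjects, and a small fraction of multivariate location outliers.
#'
#' Concentrations are arbitrary units with generative residual SD ~= 1, so
#' `age_slopes` read as SD per decade and `mortality_loghr` as log hazard
#' ratio per concentration-SD. A latent subject-level "biological age"
#' offset (SD `bioage_sd` years) advances each subject's metabolome relative
#' to chronological age and drives the aging biomarkers (CRP up, eGFR down),
#' giving downstream age-adjusted association analyses a real signal.
#'
#' @param seed integer seed; fixes every parameter draw and, downstream,
#'   every data draw.
#' @param n_cohorts number of cohorts (default 8).
#' @param n_subjects subjects per cohort (scalar or vector; default 1500).
#' @param n_metabolites number of analytes (default 98).
#' @param age_ranges list of `c(lo, hi)` per cohort; defaults span 24-86.
#' @param female_frac per-cohort probability of female sex (default 0.6;
#'   one default cohort is women-only).
#' @param outlier_fraction fraction of samples replaced by multivariate
#'   location outliers, in \[0, 0.1\].
#' @param outlier_shift outlier displacement in per-analyte robust SDs
#'   (default 6).
#' @param batch_sd log-normal SD of cohort x analyte batch factors
#'   (reference cohort fixed at 1). 0 disables batch effects.
#' @param missing_analytes named list, cohort -> analyte indices entirely
#'   unmeasured in that cohort.
#' @param repeat_visit_fraction fraction of subjects given a second visit.
#' @param follow_up_gap years between visits.
#' @param censor_time administrative censoring time (years).
#' @param h0 baseline hazard (per year); `beta_age`, `beta_sex` are log
#'   hazard ratios for age (per year) and female sex.
#' @param bioage_sd SD (years) of the latent biological-age offset.
#' @param visit_sd SD of the fresh per-visit measurement noise (set 0 for
#'   noiseless repeat-visit tests).
#' @param age_slopes,nonlinear_set,nl_knot,nl_slopes,mortality_loghr
#'   optional overrides of the drawn per-analyte effect parameters.
#' @param batch_factors optional `n_cohorts x n_metabolites` matrix of
#'   multiplicative factors (rows named by cohort); overrides `batch_sd`.
#' @return An object of class `sim_config` (a list).
#' @export
sim_config <- function(seed = 1L,
                       n_cohorts = 8L,
                       n_subjects = 1500L,
                       n_metabolites = 98L,
                       age_ranges = NULL,
                       female_frac = NULL,
                       outlier_fraction = 0.01,
                       outlier_shift = 6,
                       batch_sd = 0.15,
                       missing_analytes = NULL,
                       repeat_visit_fraction = 0.1,
                       follow_up_gap = 10,
                       censor_time = 15,
                       h0 = 1e-4,
                       bioage_sd = 4,
                       visit_sd = sqrt(0.15),
                       age_slopes = NULL,
                       nonlinear_set = NULL,
                       nl_knot = 60,
                       nl_slopes = NULL,
                       mortality_loghr = NULL,
                       batch_factors = NULL) {
  p <- as.integer(n_metabolites)
  k <- as.integer(n_cohorts)
  cohorts <- sprintf("cohort%02d", seq_len(k))
  n_subjects <- rep_len(as.integer(n_subjects), k)

  if (is.null(age_ranges)) {
    base_ranges <- list(c(24, 45), c(30, 55), c(40, 70), c(45, 65),
                        c(50, 75), c(55, 80), c(60, 86), c(24, 86))
    age_ranges <- rep_len(base_ranges, k)
  }
  if (is.null(female_frac)) {
    female_frac <- rep(0.6, k)
    if (k >= 7) female_frac[7] <- 1  # a women-only screening cohort
  }
  female_frac <- rep_len(female_frac, k)

  # ethnicity mix: two Finnish-style single-ethnicity cohorts by default
  eth_mix <- rep(list(c(european = 0.8, south_asian = 0.2)), k)
  if (k >= 2) eth_mix[[1]] <- eth_mix[[2]] <- c(european = 1)

  # survival follow-up available in three mid/older cohorts
  survival_cohorts <- cohorts[intersect(c(3L, 5L, 7L), seq_len(k))]
  reference_cohort <- cohorts[min(3L, k)]

  drawn <- with_seed(child_seed(seed, 0L), {
    slopes <- rnorm(p, 0, 0.2)
    slopes[sample.int(p, max(1L, round(0.2 * p)))] <- 0
    flat <- which(abs(slopes) < 0.25)
    nlset <- sort(sample(flat, min(10L, length(flat))))
    nlsl <- rep(0.3, length(nlset)) * sample(c(1, 1, 1, -1), length(nlset),
                                             replace = TRUE)
    loghr <- numeric(p)
    n_hr <- min(12L, p)
    cand <- order(-abs(slopes))[seq_len(n_hr)]
    n_conc <- ceiling(2 * n_hr / 3)
    conc <- cand[seq_len(n_conc)]
    opp <- cand[-seq_len(n_conc)]
    sgn <- function(v) ifelse(slopes[v] == 0, 1, sign(slopes[v]))
    loghr[conc] <- sgn(conc) * runif(length(conc), 0.1, 0.3)
    loghr[opp] <- -sgn(opp) * runif(length(opp), 0.1, 0.3)
    lam <- matrix(rnorm(p * 5), p, 5)
    lam <- lam / sqrt(rowSums(lam^2)) * sqrt(0.5)  # factor variance 0.5
    list(baseline = runif(p, 2, 10),
         age_slopes = slopes, nonlinear_set = nlset, nl_slopes = nlsl,
         mortality_loghr = loghr,
         sex_effects = rnorm(p, 0, 0.2),
         bmi_effects = rnorm(p, 0, 0.1),
         eth_effects = rnorm(p, 0, 0.1),
         loadings = lam,
         rf_analytes = order(-abs(slopes))[seq_len(min(3L, p))],
         batch = if (batch_sd > 0) {
           b <- matrix(exp(rnorm(k * p, 0, batch_sd)), k, p)
           b
         } else matrix(1, k, p))
  })
  if (!is.null(age_slopes)) drawn$age_slopes <- rep_len(age_slopes, p)
  if (!is.null(nonlinear_set)) {
    drawn$nonlinear_set <- setdiff(as.integer(nonlinear_set), 0L)
    drawn$nl_slopes <- rep_len(if (is.null(nl_slopes)) 0.3 else nl_slopes,
                               length(drawn$nonlinear_set))
  } else if (!is.null(nl_slopes)) {
    drawn$nl_slopes <- rep_len(nl_slopes, length(drawn$nonlinear_set))
  }
  if (!is.null(mortality_loghr)) drawn$mortality_loghr <-
      rep_len(mortality_loghr, p)
  if (!is.null(batch_factors)) drawn$batch <- batch_factors
  if (!identical(dim(drawn$batch), c(k, p)))
    stop_metaboage("batch_factors must be n_cohorts x n_metabolites (",
                   k, " x ", p, ")")
  if (!all(is.finite(drawn$batch)) || any(drawn$batch <= 0))
    stop_metaboage("batch factors must be strictly positive and finite")
  rownames(drawn$batch) <- cohorts
  drawn$batch[reference_cohort, ] <- 1
  if (outlier_fraction < 0 || outlier_fraction > 0.1)
    stop_metaboage("outlier_fraction must lie in [0, 0.1]")
  s <- drawn$age_slopes; m <- drawn$mortality_loghr
  if (any(s != 0) && any(m != 0) &&
      !any(s != 0 & m != 0 & sign(s) != sign(m)))
    warning("no analyte opposes its age trend; opposing-direction penalty ",
            "rule will not be exercised")

  if (is.null(missing_analytes) && k >= 6) {
    missing_analytes <- list(c(5L, 6L), 5L)
    names(missing_analytes) <- cohorts[c(1L, 6L)]
  }

  cfg <- c(list(seed = as.integer(seed), n_cohorts = k, cohorts = cohorts,
                n_subjects = n_subjects, n_metabolites = p,
                analytes = sprintf("m%03d", seq_len(p)),
                age_ranges = age_ranges, female_frac = female_frac,
                eth_mix = eth_mix, survival_cohorts = survival_cohorts,
                reference_cohort = reference_cohort,
                outlier_fraction = outlier_fraction,
                outlier_shift = outlier_shift,
                missing_analytes = missing_analytes,
                repeat_visit_fraction = repeat_visit_fraction,
                follow_up_gap = follow_up_gap, censor_time = censor_time,
                h0 = h0, beta_age = 0.08, beta_sex = -0.3,
                bioage_sd = bioage_sd, nl_knot = nl_knot,
                unique_sd = sqrt(0.35), visit_sd = visit_sd,
                smoking_prev = 0.2, smoking_years = 3,
                inactive_prev = 0.35, inactive_years = 2,
                rf_shift = 0.5),
           drawn)
  class(cfg) <- "sim_config"
  cfg
}

# Expected analyte mean (pre-batch, pre-noise) for given covariates.
sim_mean <- function(config, age_eff, sex, bmi, eth_south, smoking) {
  p <- config$n_metabolites
  n <- length(age_eff)
  mu <- matrix(rep(config$baseline, each = n), n, p)
  mu <- mu + outer((age_eff - 50) / 10, config$age_slopes)
  if (length(config$nonlinear_set))
    mu[, config$nonlinear_set] <- mu[, config$nonlinear_set] +
      outer(pmax(0, age_eff - config$nl_knot) / 10, config$nl_slopes)
  mu <- mu + outer(sex, config$sex_effects)
  mu <- mu + outer((bmi - 26.5) / 5, config$bmi_effects)
  mu <- mu + outer(eth_south, config$eth_effects)
  # smokers shift along each target analyte's own aging direction
  shift <- numeric(p)
  sl <- config$age_slopes[config$rf_analytes]
  shift[config$rf_analytes] <- config$rf_shift * ifelse(sl == 0, 1, sign(sl))
  mu + outer(smoking, shift)
}

#' Generate a synthetic multi-cohort metabolomics study
#'
#' Draws subjects per cohort, builds their analyte concentrations from the
#' generative model in `config`, applies cohort batch factors, injects
#' multivariate location outliers and per-cohort missing analytes, and
#' returns the metabolite matrix, the phenotype table (survival columns
#' unset; see [simulate_survival()]) and a truth record holding every
#' generative parameter plus per-subject latent state for recovery tests
#' and longitudinal extension.
#'
#' @param config a [sim_config()].
#' @return list with elements `matrix` (metabolite matrix), `pheno`
#'   (phenotype table) and `truth` (truth record, class `sim_truth`).
#' @export
simulate_cohorts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  p <- config$n_metabolites
  with_seed(child_seed(config$seed, 1L), {
    mats <- list(); phs <- list(); subj <- list(); out_ids <- character()
    for (ci in seq_len(config$n_cohorts)) {
      ch <- config$cohorts[ci]
      n <- config$n_subjects[ci]
      rng <- config$age_ranges[[ci]]
      age <- runif(n, rng[1], rng[2])
      sex <- rbinom(n, 1, config$female_frac[ci])
      bmi <- rnorm(n, 26.5, 4)
      mix <- config$eth_mix[[ci]]
      eth <- sample(names(mix), n, replace = TRUE, prob = mix)
      smoking <- rbinom(n, 1, config$smoking_prev)
      inactive <- rbinom(n, 1, config$inactive_prev)
      d <- rnorm(n, 0, config$bioage_sd) +
        config$smoking_years * smoking + config$inactive_years * inactive
      fac <- matrix(rnorm(n * 5), n, 5)
      uniq <- matrix(rnorm(n * p, 0, config$unique_sd), n, p)
      mu <- sim_mean(config, age + d, sex, bmi,
                     as.numeric(eth == "south_asian"), smoking)
      x <- mu + fac %*% t(config$loadings) + uniq +
        matrix(rnorm(n * p, 0, config$visit_sd), n, p)
      x <- sweep(x, 2, config$batch[ch, ], "*")

      sid <- sprintf("%s_s%05d", ch, seq_len(n))
      n_out <- round(config$outlier_fraction * n)
      oidx <- integer(0)
      if (n_out > 0) {
        oidx <- sample.int(n, n_out)
        rsd <- apply(x, 2, mad)
        rsd[rsd == 0] <- 1
        for (i in oidx) {
          dir <- rnorm(p); dir <- dir / sqrt(sum(dir^2))
          x[i, ] <- x[i, ] + config$outlier_shift * dir * rsd
        }
        out_ids <- c(out_ids, paste0(sid[oidx], "_v1"))
      }
      miss <- config$missing_analytes[[ch]]
      if (length(miss)) x[, miss] <- NA_real_

      zd <- (d - mean(d)) / max(sd(d), 1e-9)
      phs[[ci]] <- data.frame(
        sample_id = paste0(sid, "_v1"), subject_id = sid, cohort = ch,
        visit = 1L, age = age, sex = sex, bmi = bmi, ethnicity = eth,
        smoking = smoking, inactive = inactive,
        obesity = as.integer(bmi > 30),
        crp = 1 + 0.05 * age + 0.8 * zd + rnorm(n, 0, 1.5),
        egfr = 120 - 0.6 * age - 4 * zd + rnorm(n, 0, 8),
        sbp = 105 + 0.5 * age + 4 * zd + rnorm(n, 0, 10),
        surv_time = NA_real_, event = NA_integer_,
        stringsAsFactors = FALSE)
      colnames(x) <- config$analytes
      mats[[ci]] <- data.frame(sample_id = paste0(sid, "_v1"),
                               subject_id = sid, cohort = ch, visit = 1L,
                               x, stringsAsFactors = FALSE)
      subj[[ci]] <- list(cohort = ch, subject_id = sid, age = age,
                         sex = sex, bmi = bmi, eth = eth, smoking = smoking,
                         inactive = inactive, d = d, factors = fac,
                         unique = uniq)
    }
    matrix_out <- do.call(rbind, mats)
    pheno_out <- do.call(rbind, phs)
    rownames(matrix_out) <- rownames(pheno_out) <- NULL
    truth <- list(config = config, outlier_sample_ids = out_ids,
                  subjects = subj)
    class(truth) <- "sim_truth"
    list(matrix = matrix_out, pheno = pheno_out, truth = truth)
  })
}

#' Attach survival outcomes to a simulated study
#'
#' Event times are exponential with subject-specific rate
#' `h0 * exp(beta_age * age + beta_sex * sex + sum_j loghr_j * z_ij)`, where
#' `z_ij` are per-cohort standardized analyte values at the first visit,
#' administratively censored at `config$censor_time`. Cohorts outside
#' `config$survival_cohorts` keep `NA` survival columns (no follow-up).
#'
#' @param pheno phenotype table from [simulate_cohorts()].
#' @param matrix matching metabolite matrix.
#' @param config the generating [sim_config()].
#' @return `pheno` with `surv_time` and `event` filled in.
#' @export
simulate_survival <- function(pheno, matrix, config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(child_seed(config$seed, 2L), {
    for (ch in config$survival_cohorts) {
      idx <- which(pheno$cohort == ch & pheno$visit == 1L)
      if (!length(idx)) next
      mi <- match(pheno$sample_id[idx], matrix$sample_id)
      z <- zscale(analyte_matrix(matrix[mi, , drop = FALSE]))
      lp <- config$beta_age * pheno$age[idx] +
        config$beta_sex * pheno$sex[idx]
      obs <- !is.na(colSums(z))   # analytes missing in this cohort drop out
      if (any(obs))
        lp <- lp + as.vector(z[, obs, drop = FALSE] %*%
                               config$mortality_loghr[obs])
      rate <- config$h0 * exp(lp)
      if (!all(is.finite(rate)))
        stop_metaboage("non-finite hazard in survival simulation")
      tt <- rexp(length(idx), rate)
      pheno$surv_time[idx] <- pmin(tt, config$censor_time)
      pheno$event[idx] <- as.integer(tt <= config$censor_time)
    }
    # repeat-visit rows inherit the subject's outcome
    rep_idx <- which(pheno$visit > 1L & pheno$cohort %in%
                       config$survival_cohorts)
    if (length(rep_idx)) {
      first <- pheno[pheno$visit == 1L, ]
      m <- match(pheno$subject_id[rep_idx], first$subject_id)
      pheno$surv_time[rep_idx] <- first$surv_time[m]
      pheno$event[rep_idx] <- first$event[m]
    }
    pheno
  })
}

#' Add second visits to a fraction of subjects
#'
#' Selected subjects receive a second sample at `age + follow_up_gap`,
#' advanced along their own generating trajectory: identical latent factors
#' and subject-unique effects, identical batch factor, fresh per-visit
#' measurement noise. No new outliers are injected.
#'
#' @param matrix,pheno outputs of [simulate_cohorts()].
#' @param config the generating [sim_config()].
#' @param truth the matching truth record (holds per-subject latent state).
#' @return list with extended `matrix` and `pheno`.
#' @export
add_longitudinal_visits <- function(matrix, pheno, config, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "sim_truth"))
  frac <- config$repeat_visit_fraction
  if (frac <= 0) return(list(matrix = matrix, pheno = pheno))
  p <- config$n_metabolites
  with_seed(child_seed(config$seed, 3L), {
    mats <- list(); phs <- list()
    for (sub in truth$subjects) {
      n <- length(sub$subject_id)
      pick <- which(runif(n) < frac)
      if (!length(pick)) next
      age2 <- sub$age[pick] + config$follow_up_gap
      mu <- sim_mean(config, age2 + sub$d[pick], sub$sex[pick],
                     sub$bmi[pick],
                     as.numeric(sub$eth[pick] == "south_asian"),
                     sub$smoking[pick])
      x <- mu + sub$factors[pick, , drop = FALSE] %*% t(config$loadings) +
        sub$unique[pick, , drop = FALSE] +
        matrix(rnorm(length(pick) * p, 0, config$visit_sd),
               length(pick), p)
      x <- sweep(x, 2, config$batch[sub$cohort, ], "*")
      miss <- config$missing_analytes[[sub$cohort]]
      if (length(miss)) x[, miss] <- NA_real_
      colnames(x) <- config$analytes
      sid <- sub$subject_id[pick]
      mats[[length(mats) + 1L]] <- data.frame(
        sample_id = paste0(sid, "_v2"), subject_id = sid,
        cohort = sub$cohort, visit = 2L, x, stringsAsFactors = FALSE)
      ph1 <- pheno[match(paste0(sid, "_v1"), pheno$sample_id), ]
      ph1$sample_id <- paste0(sid, "_v2")
      ph1$visit <- 2L
      ph1$age <- age2
      phs[[length(phs) + 1L]] <- ph1
    }
    if (!length(mats)) return(list(matrix = matrix, pheno = pheno))
    matrix2 <- rbind(matrix, do.call(rbind, mats))
    pheno2 <- rbind(pheno, do.call(rbind, phs))
    rownames(matrix2) <- rownames(pheno2) <- NULL
    list(matrix = matrix2, pheno = pheno2)
  })
}
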