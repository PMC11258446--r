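#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values: with ordered p-values `p_(1) <= ... <= p_(m)`,
#' `q_(i) = min_{j >= i} ( m * p_(j) / j )`, capped at 1. `NA` inputs are
#' propagated with a warning and do not count towards `m`.
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @return adjusted q-values, same length and order as `pvals`.
#' @export
bh_fdr <- function(pvals) {
  if (anyNA(pvals)) warning("NA p-values propagated unadjusted")
  ok <- which(!is.na(pvals))
  p <- pvals[ok]
  m <- length(p)
  q <- rep(NA_real_, length(pvals))
  if (m) {
    o <- order(p)
    adj <- rev(cummin(rev(p[o] * m / seq_len(m))))
    q[ok[o]] <- pmin(adj, 1)
  }
  q
}

#' Inverse-variance fixed-effect meta-analysis with heterogeneity
#'
#' Pools per-study effects per analyte with weights `w_i = 1 / se_i^2`:
#' `beta = sum(w b) / sum(w)`, `se = sum(w)^(-1/2)`, two-sided normal p.
#' Heterogeneity per analyte: Cochran's `Q = sum(w (b - beta)^2)` on
#' `k - 1` degrees of freedom and `I2 = max(0, (Q - df) / Q)`, labelled
#' "high" above 0.75, "low" below 0.25, "moderate" between.
#'
#' @param effects data frame of per-study effects with columns `analyte`,
#'   `cohort` (study label), `beta`, `se`, `n`.
#' @return data frame, one row per analyte: `analyte, k, beta_pooled,
#'   se_pooled, z, p, q, Q_stat, df, I2, het_label, n_total`. `q` is the
#'   BH-FDR over the analytes present.
#' @export
meta_fixed <- function(effects) {
  stopifnot(all(c("analyte", "beta", "se") %in% names(effects)))
  if (any(!is.finite(effects$se) | effects$se <= 0))
    stop_metaboage("all standard errors must be finite and positive")
  rows <- lapply(split(effects, effects$analyte), function(e) {
    w <- 1 / e$se^2
    beta <- sum(w * e$beta) / sum(w)
    se <- 1 / sqrt(sum(w))
    q_stat <- sum(w * (e$beta - beta)^2)
    k <- nrow(e)
    df <- k - 1L
    i2 <- if (df > 0 && q_stat > 1e-12) max(0, (q_stat - df) / q_stat)
          else 0
    z <- beta / se
    data.frame(analyte = e$analyte[1], k = k, beta_pooled = beta,
               se_pooled = se, z = z, p = 2 * pnorm(-abs(z)),
               Q_stat = q_stat, df = df, I2 = i2,
               het_label = if (i2 > 0.75) "high"
                           else if (i2 < 0.25) "low" else "moderate",
               n_total = sum(e$n %||% NA_real_),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$q <- bh_fdr(out$p)
  out[, c("analyte", "k", "beta_pooled", "se_pooled", "z", "p", "q",
          "Q_stat", "df", "I2", "het_label", "n_total")]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Drop covariates that are constant within the analysis sample (e.g.
# ethnicity in a single-ethnicity cohort, sex in a women-only cohort).
usable_covars <- function(df, covars) {
  covars[vapply(covars, function(v) length(unique(df[[v]])) > 1, logical(1))]
}

# One cohort's worth of age-MWAS regressions.
mwas_age_block <- function(z, ph, label, covars) {
  cv <- usable_covars(ph, covars)
  rhs <- paste(c("age", cv), collapse = " + ")
  out <- lapply(colnames(z), function(a) {
    y <- z[, a]
    if (anyNA(y) || sd(y) == 0) {
      warning("analyte ", a, " skipped in ", label,
              " (missing or constant)")
      return(NULL)
    }
    dat <- cbind(data.frame(.y = y), ph)
    fit <- lm(as.formula(paste(".y ~", rhs)), data = dat)
    sm <- summary(fit)$coefficients
    data.frame(analyte = a, cohort = label, beta = sm["age", 1],
               se = sm["age", 2], n = nrow(dat), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Metabolome-wide association study of age, stratified by cohort
#'
#' One linear model per (analyte, cohort): analyte (z-scaled within cohort
#' by default) regressed on age adjusted for sex, BMI and ethnicity.
#' Adjustment covariates constant within a cohort are dropped automatically.
#'
#' @param matrix metabolite matrix.
#' @param pheno phenotype table.
#' @param covars adjustment covariates (default sex, BMI, ethnicity).
#' @param standardize z-scale analytes per cohort so effects are SD per
#'   year (default TRUE). With FALSE, effects are concentration units per
#'   year — useful for parameter-recovery checks against a generator.
#' @return data frame of per-cohort effects (`analyte, cohort, beta, se, n`)
#'   suitable for [meta_fixed()].
#' @export
mwas_age <- function(matrix, pheno,
                     covars = c("sex", "bmi", "ethnicity"),
                     standardize = TRUE) {
  ph <- pheno[match(matrix$sample_id, pheno$sample_id), ]
  analytes <- analyte_names(matrix)
  out <- lapply(unique(matrix$cohort), function(ch) {
    idx <- which(matrix$cohort == ch)
    x <- analyte_matrix(matrix[idx, , drop = FALSE], analytes)
    if (standardize) x <- zscale(x)
    mwas_age_block(x, ph[idx, , drop = FALSE], ch, covars)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Age-group-stratified MWAS of age
#'
#' Regressions within age-group strata (treated as the studies to pool),
#' additionally adjusted for cohort. Default strata: 20-35, then 5-year
#' bands to 70, then >70. Heterogeneity of the pooled result across strata
#' (I2 from [meta_fixed()]) flags analytes whose age association is not
#' constant over the life course.
#'
#' @param matrix metabolite matrix.
#' @param pheno phenotype table.
#' @param bins ordered break points; stratum i is `[bins[i], bins[i+1])`.
#' @param covars adjustment covariates besides age and cohort.
#' @param min_n strata smaller than this are skipped with a warning.
#' @return per-stratum effects data frame (strata in the `cohort` column).
#' @export
mwas_age_stratified <- function(matrix, pheno,
                                bins = c(20, 35, 40, 45, 50, 55, 60, 65,
                                         70, Inf),
                                covars = c("sex", "bmi", "ethnicity"),
                                min_n = 30) {
  if (is.unsorted(bins, strictly = TRUE))
    stop_metaboage("bins must be strictly increasing")
  ph <- pheno[match(matrix$sample_id, pheno$sample_id), ]
  analytes <- analyte_names(matrix)
  x <- zscale(analyte_matrix(matrix, analytes))  # global scale: strata are
  # the studies, so scaling within-stratum would absorb the age signal
  lab <- cut(ph$age, bins, right = FALSE,
             labels = paste0("[", head(bins, -1), ",", bins[-1], ")"))
  out <- lapply(levels(lab), function(st) {
    idx <- which(lab == st)
    if (length(idx) < min_n) {
      if (length(idx)) warning("stratum ", st, " has n < ", min_n,
                               "; skipped")
      return(NULL)
    }
    cv <- c(covars, "cohort")
    mwas_age_block(x[idx, , drop = FALSE], ph[idx, , drop = FALSE], st, cv)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Metabolome-wide Cox regressions of all-cause mortality
#'
#' Per (analyte, cohort) Cox proportional hazards model of survival on the
#' per-cohort standardized analyte, adjusted for chronological age, sex and
#' BMI (Breslow tie handling). Cohorts without survival follow-up or
#' without events are skipped. Repeat visits are excluded (first visit per
#' subject).
#'
#' @param matrix metabolite matrix.
#' @param pheno phenotype table with `surv_time`, `event`.
#' @param covars adjustment covariates (default age, sex, BMI).
#' @return per-cohort log hazard ratios per analyte-SD
#'   (`analyte, cohort, beta, se, n, n_event`).
#' @export
mwas_mortality <- function(matrix, pheno,
                           covars = c("age", "sex", "bmi")) {
  ph <- pheno[match(matrix$sample_id, pheno$sample_id), ]
  keep <- ph$visit == 1L & !is.na(ph$surv_time) & !is.na(ph$event)
  analytes <- analyte_names(matrix)
  out <- list()
  for (ch in unique(matrix$cohort)) {
    idx <- which(keep & matrix$cohort == ch)
    if (!length(idx)) next
    phc <- ph[idx, , drop = FALSE]
    if (sum(phc$event) == 0) {
      warning("cohort ", ch, " has no events; skipped")
      next
    }
    z <- zscale(analyte_matrix(matrix[idx, , drop = FALSE], analytes))
    cv <- usable_covars(phc, covars)
    ss <- survival::Surv(phc$surv_time, phc$event)
    for (a in analytes) {
      y <- z[, a]
      if (anyNA(y) || sd(y) == 0) next
      dat <- cbind(data.frame(.a = y), phc)
      fml <- as.formula(paste("ss ~ .a +", paste(cv, collapse = " + ")))
      fit <- tryCatch(
        survival::coxph(fml, data = dat, ties = "breslow"),
        error = function(e) NULL)
      if (is.null(fit)) next
      sm <- summary(fit)$coefficients
      out[[length(out) + 1L]] <- data.frame(
        analyte = a, cohort = ch, beta = sm[".a", "coef"],
        se = sm[".a", "se(coef)"], n = nrow(dat),
        n_event = sum(phc$event), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
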