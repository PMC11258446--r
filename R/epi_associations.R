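# Build one pooled association row from per-cohort estimates.
pool_assoc <- function(effects, score_name, exposure, model_kind,
                       exp_scale = identity, p_threshold = 0.001) {
  if (is.null(effects) || !nrow(effects))
    stop_metaboage("no cohort contributed an estimate for ", exposure)
  effects$analyte <- exposure
  pooled <- meta_fixed(effects)
  est <- exp_scale(pooled$beta_pooled)
  lcl <- exp_scale(pooled$beta_pooled - qnorm(0.975) * pooled$se_pooled)
  ucl <- exp_scale(pooled$beta_pooled + qnorm(0.975) * pooled$se_pooled)
  data.frame(score = score_name, exposure = exposure, model = model_kind,
             estimate = est, se = pooled$se_pooled, lcl = lcl, ucl = ucl,
             p = pooled$p, k = pooled$k,
             sig_at_0.001 = pooled$p < p_threshold,
             stringsAsFactors = FALSE)
}

# Shared engine for the two linear association analyses.
linear_assoc <- function(scores, pheno, exposure, covars, score_name,
                         scale_exposure, drop_repeats) {
  ph <- pheno[match(names(scores), pheno$sample_id), ]
  if (drop_repeats) {
    keep <- ph$visit == 1L
    ph <- ph[keep, , drop = FALSE]
    scores <- scores[keep]
  }
  out <- list()
  for (ch in unique(ph$cohort)) {
    idx <- which(ph$cohort == ch)
    d <- ph[idx, , drop = FALSE]
    ex <- d[[exposure]]
    if (length(unique(ex)) < 2) {
      warning("exposure ", exposure, " constant in ", ch, "; skipped")
      next
    }
    s <- scores[idx]
    if (sd(s) == 0) next
    d$.score <- (s - mean(s)) / sd(s)   # score in SD units per cohort
    d$.exposure <- if (scale_exposure) (ex - mean(ex)) / sd(ex) else ex
    cv <- usable_covars(d, covars)
    fml <- as.formula(paste(".score ~ .exposure +",
                            paste(cv, collapse = " + ")))
    sm <- summary(lm(fml, data = d))$coefficients
    out[[length(out) + 1L]] <- data.frame(
      analyte = exposure, cohort = ch, beta = sm[".exposure", 1],
      se = sm[".exposure", 2], n = nrow(d), stringsAsFactors = FALSE)
  }
  pool_assoc(do.call(rbind, out), score_name, exposure, "linear")
}

#' Risk-factor associations of a metabolomic age score
#'
#' Per cohort, the score (standardized to SD units within the cohort) is
#' regressed on a binary risk factor adjusted for chronological age, sex and
#' ethnicity (constants dropped automatically); per-cohort estimates are
#' pooled by inverse-variance fixed-effect meta-analysis. Estimates read as
#' SD of score per exposure contrast. Repeat visits are excluded so each
#' subject counts once.
#'
#' @param scores numeric scores named by `sample_id`.
#' @param pheno phenotype table.
#' @param factor name of a binary column of `pheno`.
#' @param covars adjustment covariates (default age, sex, ethnicity).
#' @param score_name label for the output.
#' @param drop_repeats exclude visits > 1 (default TRUE).
#' @return one-row data frame: `score, exposure, model, estimate, se, lcl,
#'   ucl, p, k, sig_at_0.001`.
#' @export
riskfactor_assoc <- function(scores, pheno, factor,
                             covars = c("age", "sex", "ethnicity"),
                             score_name = "score", drop_repeats = TRUE) {
  linear_assoc(scores, pheno, factor, covars, score_name,
               scale_exposure = FALSE, drop_repeats = drop_repeats)
}

#' Biomarker associations of a metabolomic age score
#'
#' As [riskfactor_assoc()] but the exposure is continuous and univariate
#' scaled within each cohort, so estimates read as SD of score per SD of
#' biomarker.
#'
#' @inheritParams riskfactor_assoc
#' @param biomarker name of a continuous column of `pheno`.
#' @export
biomarker_assoc <- function(scores, pheno, biomarker,
                            covars = c("age", "sex", "ethnicity"),
                            score_name = "score", drop_repeats = TRUE) {
  linear_assoc(scores, pheno, biomarker, covars, score_name,
               scale_exposure = TRUE, drop_repeats = drop_repeats)
}

#' Cox associations of a metabolomic age score with incident events
#'
#' Per cohort with survival follow-up, a Cox proportional hazards model of
#' the event on the score (in year units, unstandardized) adjusted for
#' chronological age, sex and ethnicity; per-cohort log hazard ratios are
#' pooled by inverse-variance fixed-effect meta-analysis. Because CA is
#' adjusted for, the hazard ratio per score-year reads as the effect of a
#' year of metabolomic age acceleration. Optional age bands stratify the
#' analysis (one pooled result per band).
#'
#' @inheritParams riskfactor_assoc
#' @param age_bands optional break points, e.g. `c(-Inf, 55, 65, Inf)`.
#' @return data frame, one row per (band): `estimate` is the hazard ratio.
#' @export
cox_event_assoc <- function(scores, pheno,
                            covars = c("age", "sex", "ethnicity"),
                            score_name = "score", age_bands = NULL,
                            drop_repeats = TRUE) {
  ph <- pheno[match(names(scores), pheno$sample_id), ]
  keep <- !is.na(ph$surv_time) & !is.na(ph$event)
  if (drop_repeats) keep <- keep & ph$visit == 1L
  ph <- ph[keep, , drop = FALSE]
  scores <- scores[keep]
  if (sum(ph$event) == 0) stop_metaboage("no events in the analysis sample")
  bands <- if (is.null(age_bands)) list(all = rep(TRUE, nrow(ph)))
  else {
    lab <- cut(ph$age, age_bands, right = FALSE)
    setNames(lapply(levels(lab), function(l) !is.na(lab) & lab == l),
             levels(lab))
  }
  out <- list()
  for (bn in names(bands)) {
    sel <- bands[[bn]]
    eff <- list()
    for (ch in unique(ph$cohort[sel])) {
      idx <- which(sel & ph$cohort == ch)
      d <- ph[idx, , drop = FALSE]
      if (sum(d$event) == 0) next
      d$.score <- scores[idx]
      if (sd(d$.score) == 0) next
      cv <- usable_covars(d, covars)
      ss <- survival::Surv(d$surv_time, d$event)
      fml <- as.formula(paste("ss ~ .score +",
                              paste(cv, collapse = " + ")))
      fit <- tryCatch(survival::coxph(fml, data = d, ties = "breslow"),
                      error = function(e) NULL)
      if (is.null(fit)) next
      sm <- summary(fit)$coefficients
      eff[[length(eff) + 1L]] <- data.frame(
        analyte = bn, cohort = ch, beta = sm[".score", "coef"],
        se = sm[".score", "se(coef)"], n = nrow(d),
        stringsAsFactors = FALSE)
    }
    row <- pool_assoc(do.call(rbind, eff), score_name,
                      paste0("event", if (bn != "all") paste0("@", bn)),
                      "cox", exp_scale = exp)
    out[[length(out) + 1L]] <- row
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' BMI sensitivity adjustment
#'
#' Reruns an association analysis with extra adjustment covariates (BMI by
#' default) and returns the unadjusted and adjusted rows stacked, labelled
#' by an `adjustment` column, for attenuation comparison. Output schema is
#' otherwise identical to the base analysis.
#'
#' @param analysis one of [riskfactor_assoc()], [biomarker_assoc()],
#'   [cox_event_assoc()].
#' @param ... arguments to `analysis` (including `covars`).
#' @param extra_covars covariates added in the sensitivity run
#'   (default "bmi").
#' @return data frame with both runs and an `adjustment` column.
#' @export
sensitivity_adjust <- function(analysis, ..., extra_covars = "bmi") {
  args <- list(...)
  covars <- args$covars %||% c("age", "sex", "ethnicity")
  base <- do.call(analysis, args)
  args$covars <- unique(c(covars, extra_covars))
  adj <- do.call(analysis, args)
  base$adjustment <- "base"
  adj$adjustment <- paste0("+", paste(extra_covars, collapse = "+"))
  rbind(base, adj)
}
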