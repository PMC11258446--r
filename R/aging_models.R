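new_aging_model <- function(kind, analytes, intercept = 0,
                            coefficients = NULL, mars = NULL,
                            penalty_factors = NULL, rescale = NULL,
                            meta = list()) {
  structure(list(kind = kind, analytes = analytes, intercept = intercept,
                 coefficients = coefficients, mars = mars,
                 penalty_factors = penalty_factors, rescale = rescale,
                 meta = meta),
            class = "aging_model")
}

#' Elastic-net model of chronological age
#'
#' Penalized linear regression of age on the (pruned) analyte set with
#' mixing parameter `alpha` (default 0.5) and optional per-analyte penalty
#' multipliers; the regularization strength is chosen by internal k-fold
#' cross-validation (minimum mean-squared error by default, or the 1-SE
#' rule). Coefficients are returned on the original analyte scale.
#'
#' @param x numeric matrix, samples x analytes (named columns).
#' @param age numeric response (years).
#' @param alpha elastic-net mixing parameter (1 = lasso, 0 = ridge).
#' @param penalty_factors optional per-analyte multipliers on the penalty
#'   (0 = unshrunk). Uniform vectors reproduce the unweighted fit.
#' @param lambda optional fixed penalty, bypassing cross-validation.
#' @param nfolds internal CV folds (default 10).
#' @param one_se use the 1-SE lambda instead of the CV minimum.
#' @param seed seed for the internal CV fold split.
#' @return an `aging_model` of kind `elastic_net`.
#' @export
fit_elastic_net_age <- function(x, age, alpha = 0.5, penalty_factors = NULL,
                                lambda = NULL, nfolds = 10, one_se = FALSE,
                                seed = 1L) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (all(apply(x, 2, sd) == 0)) stop_metaboage("all predictors constant")
  pf <- if (is.null(penalty_factors)) rep(1, ncol(x)) else penalty_factors
  if (length(pf) != ncol(x))
    stop_metaboage("penalty_factors length must match ncol(x)")
  if (is.null(lambda)) {
    cvfit <- with_seed(seed, glmnet::cv.glmnet(
      x, age, alpha = alpha, penalty.factor = pf, nfolds = nfolds,
      family = "gaussian"))
    lambda <- if (one_se) cvfit$lambda.1se else cvfit$lambda.min
    fit <- cvfit$glmnet.fit
  } else {
    fit <- glmnet::glmnet(x, age, alpha = alpha, penalty.factor = pf,
                          family = "gaussian")
  }
  cf <- as.matrix(coef(fit, s = lambda, exact = TRUE, x = x, y = age,
                       alpha = alpha, penalty.factor = pf))
  new_aging_model(
    kind = if (is.null(penalty_factors)) "elastic_net" else "phenotypic",
    analytes = colnames(x), intercept = cf[1, 1],
    coefficients = setNames(cf[-1, 1], colnames(x)),
    penalty_factors = penalty_factors,
    meta = list(alpha = alpha, lambda = lambda, seed = seed))
}

#' Mortality-informed penalty factors
#'
#' Per-analyte elastic-net penalty multipliers built from the mortality
#' meta-analysis: an analyte's multiplier is its pooled mortality p-value
#' (so analytes strongly associated with mortality are barely shrunk),
#' except that analytes whose pooled age and mortality effects point in
#' opposite directions receive multiplier 1 (full shrinkage).
#'
#' @param age_meta,mort_meta [meta_fixed()] results for the age and
#'   mortality MWAS.
#' @param analytes analyte set to cover (default: all in `age_meta`).
#' @return named numeric vector in \[0, 1\].
#' @export
mortality_penalty_factors <- function(age_meta, mort_meta,
                                      analytes = age_meta$analyte) {
  ai <- match(analytes, age_meta$analyte)
  mi <- match(analytes, mort_meta$analyte)
  bad <- analytes[is.na(ai) | is.na(mi)]
  if (length(bad))
    stop_metaboage("analyte(s) missing from a meta-analysis: ",
                   paste(bad, collapse = ", "))
  v <- mort_meta$p[mi]
  opposing <- sign(age_meta$beta_pooled[ai]) !=
    sign(mort_meta$beta_pooled[mi])
  v[opposing] <- 1
  setNames(pmin(pmax(v, 0), 1), analytes)
}

#' Phenotypic-age model
#'
#' Elastic net trained on chronological age with mortality-informed penalty
#' factors from [mortality_penalty_factors()], enhancing the influence of
#' analytes closely associated with mortality while still predicting age.
#'
#' @inheritParams fit_elastic_net_age
#' @param penalty_factors per-analyte multipliers (required).
#' @return an `aging_model` of kind `phenotypic`.
#' @export
fit_phenotypic_age <- function(x, age, penalty_factors, alpha = 0.5, ...) {
  if (is.null(penalty_factors)) stop_metaboage("penalty_factors required")
  m <- fit_elastic_net_age(x, age, alpha = alpha,
                           penalty_factors = penalty_factors, ...)
  m$kind <- "phenotypic"
  m
}

#' Penalized-Cox study mortality score
#'
#' Elastic-net-penalized Cox regression (alpha 0.5) of survival on the
#' analytes plus adjustment covariates (age, sex, BMI, ethnicity, cohort).
#' Covariates carry penalty multiplier 0 so they are adjusted for but never
#' dropped; the score is the linear predictor restricted to the analyte
#' terms only, then rescaled to the mean and SD of chronological age in the
#' training sample so the score reads in years.
#'
#' @param x numeric matrix of analytes.
#' @param covars data frame with `age`, `sex` and optionally `bmi`,
#'   `ethnicity`, `cohort` columns.
#' @param surv_time,event survival outcome (years; 0/1).
#' @inheritParams fit_elastic_net_age
#' @return an `aging_model` of kind `mortality_score` with rescale
#'   parameters set.
#' @export
fit_mortality_score <- function(x, covars, surv_time, event, alpha = 0.5,
                                lambda = NULL, nfolds = 10, seed = 1L) {
  x <- as.matrix(x)
  if (sum(event) == 0) stop_metaboage("no events in training data")
  keep <- c("age", "sex", "bmi", "ethnicity", "cohort")
  cv <- covars[, intersect(keep, names(covars)), drop = FALSE]
  cv <- cv[, vapply(cv, function(v) length(unique(v)) > 1, logical(1)),
           drop = FALSE]
  cmat <- if (ncol(cv)) model.matrix(~ . - 1, data = cv) else NULL
  design <- cbind(x, cmat)
  pf <- c(rep(1, ncol(x)), rep(0, if (is.null(cmat)) 0 else ncol(cmat)))
  y <- survival::Surv(surv_time, event)
  if (is.null(lambda)) {
    cvfit <- with_seed(seed, glmnet::cv.glmnet(
      design, y, family = "cox", alpha = alpha, penalty.factor = pf,
      nfolds = nfolds))
    lambda <- cvfit$lambda.min
    fit <- cvfit$glmnet.fit
  } else {
    fit <- glmnet::glmnet(design, y, family = "cox", alpha = alpha,
                          penalty.factor = pf)
  }
  cf <- as.matrix(coef(fit, s = lambda))[, 1]
  beta <- cf[colnames(x)]
  raw <- as.vector(x %*% beta)
  if (sd(raw) == 0)
    warning("mortality score is constant on the training data")
  rescale <- list(score_mean = mean(raw), score_sd = max(sd(raw), 1e-12),
                  age_mean = mean(covars$age), age_sd = sd(covars$age))
  new_aging_model("mortality_score", analytes = colnames(x),
                  intercept = 0, coefficients = setNames(beta, colnames(x)),
                  rescale = rescale,
                  meta = list(alpha = alpha, lambda = lambda, seed = seed))
}

#' Rescale scores to age units
#'
#' Affine map sending the scores' mean/SD to the target ages' mean/SD:
#' `scores' = (scores - mean(scores)) / sd(scores) * sd(ages) + mean(ages)`.
#'
#' @param scores numeric vector with positive SD.
#' @param ages chronological ages providing the target mean and SD.
#' @return rescaled scores (years).
#' @export
rescale_to_age_units <- function(scores, ages) {
  s <- sd(scores)
  if (!is.finite(s) || s == 0)
    stop_metaboage("scores are constant; cannot rescale to age units")
  (scores - mean(scores)) / s * sd(ages) + mean(ages)
}

#' Read / write a published-score coefficient table
#'
#' CSV schema: columns `analyte, weight, transform, scaling` with
#' `transform` in `none|log` and `scaling` in `none|cohort_z`; the rescale
#' rule (`none` or `to_age_units`) travels as a `# rescale_rule:` header
#' comment line.
#'
#' @param path CSV file path.
#' @return data frame with attribute `rescale_rule`.
#' @export
read_coefficient_table <- function(path) {
  first <- readLines(path, n = 1)
  rule <- "none"
  if (grepl("^#\\s*rescale_rule:", first))
    rule <- trimws(sub("^#\\s*rescale_rule:", "", first))
  tab <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  validate_coefficient_table(tab)
  attr(tab, "rescale_rule") <- rule
  tab
}

#' @rdname read_coefficient_table
#' @param table coefficient table data frame.
#' @export
write_coefficient_table <- function(table, path) {
  validate_coefficient_table(table)
  rule <- attr(table, "rescale_rule") %||% "none"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# rescale_rule: ", rule), con)
  write.csv(table, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_coefficient_table <- function(tab) {
  need <- c("analyte", "weight", "transform", "scaling")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop_metaboage("coefficient table lacks column(s): ",
                   paste(miss, collapse = ", "))
  if (anyDuplicated(tab$analyte))
    stop_metaboage("duplicate analyte names in coefficient table")
  if (any(!is.finite(tab$weight)))
    stop_metaboage("non-finite weights in coefficient table")
  if (!all(tab$transform %in% c("none", "log")))
    stop_metaboage("transform must be 'none' or 'log'")
  if (!all(tab$scaling %in% c("none", "cohort_z")))
    stop_metaboage("scaling must be 'none' or 'cohort_z'")
  invisible(tab)
}

#' Score samples with a published coefficient table
#'
#' Per-sample weighted sum `sum_j w_j t_j(x_j)` where `t_j` applies the
#' declared transform (`log`) and then the declared scaling (`cohort_z`:
#' z-scaling within each cohort of the scoring dataset). Analytes missing in
#' some cohorts are k-NN imputed first when `impute = TRUE`; analytes absent
#' from the matrix altogether raise an error naming them. A `to_age_units`
#' rescale rule maps the score to the mean/SD of chronological age.
#'
#' @param matrix metabolite matrix.
#' @param pheno phenotype table (for cohort labels and ages).
#' @param table coefficient table (see [read_coefficient_table()]).
#' @param impute k-NN-impute analytes missing in some cohorts
#'   (default TRUE).
#' @param k neighbours for imputation.
#' @return numeric scores named by `sample_id`.
#' @export
apply_coefficient_table <- function(matrix, pheno, table, impute = TRUE,
                                    k = 10) {
  validate_coefficient_table(table)
  absent <- setdiff(table$analyte, analyte_names(matrix))
  if (length(absent))
    stop_metaboage("analyte(s) absent from the matrix: ",
                   paste(absent, collapse = ", "))
  sub <- matrix[, c(.matrix_meta_cols, table$analyte)]
  if (anyNA(sub[, table$analyte])) {
    if (!impute)
      stop_metaboage("missing values in analyte(s): ",
                     paste(table$analyte[colSums(is.na(
                       sub[, table$analyte, drop = FALSE])) > 0],
                       collapse = ", "), " and imputation is disabled")
    sub <- knn_impute(sub, k = k)
  }
  ph <- pheno[match(sub$sample_id, pheno$sample_id), ]
  score <- numeric(nrow(sub))
  for (i in seq_len(nrow(table))) {
    v <- sub[[table$analyte[i]]]
    if (table$transform[i] == "log") {
      if (any(v <= 0)) {
        eps <- min(v[v > 0]) / 2
        v <- pmax(v, eps)
      }
      v <- log(v)
    }
    if (table$scaling[i] == "cohort_z") {
      for (ch in unique(sub$cohort)) {
        j <- sub$cohort == ch
        s <- sd(v[j]); if (!is.finite(s) || s == 0) s <- 1
        v[j] <- (v[j] - mean(v[j])) / s
      }
    }
    score <- score + table$weight[i] * v
  }
  if (identical(attr(table, "rescale_rule"), "to_age_units"))
    score <- rescale_to_age_units(score, ph$age)
  setNames(score, sub$sample_id)
}

#' Predict metabolomic age from a fitted model
#'
#' Dispatches on the model kind: linear kinds evaluate
#' `intercept + x %*% coefficients`; `mars` evaluates the hinge basis;
#' models carrying rescale parameters (mortality score) are mapped to age
#' units with the parameters frozen at training time. Deterministic.
#'
#' @param model an `aging_model`.
#' @param matrix metabolite matrix or plain numeric matrix containing the
#'   model's analytes.
#' @return numeric scores (named by `sample_id` when available).
#' @export
predict_age <- function(model, matrix) {
  stopifnot(inherits(model, "aging_model"))
  if (is.data.frame(matrix) && "sample_id" %in% names(matrix)) {
    nm <- matrix$sample_id
    x <- analyte_matrix(matrix)
  } else {
    nm <- rownames(matrix)
    x <- as.matrix(matrix)
  }
  miss <- setdiff(model$analytes, colnames(x))
  if (length(miss))
    stop_metaboage("matrix lacks model analyte(s): ",
                   paste(miss, collapse = ", "))
  x <- x[, model$analytes, drop = FALSE]
  s <- if (model$kind == "mars") {
    predict(model$mars, x)
  } else {
    model$intercept + as.vector(x %*% model$coefficients)
  }
  if (!is.null(model$rescale)) {
    r <- model$rescale
    s <- (s - r$score_mean) / r$score_sd * r$age_sd + r$age_mean
  }
  setNames(s, nm)
}

#' Fit a degree-2 MARS model of chronological age
#'
#' Thin wrapper packaging [mars_fit()] as an `aging_model`.
#'
#' @param x analyte matrix; `age` response.
#' @param age numeric response (years).
#' @param ... passed to [mars_fit()].
#' @return an `aging_model` of kind `mars`.
#' @export
fit_mars_age <- function(x, age, ...) {
  m <- mars_fit(as.matrix(x), age, ...)
  new_aging_model("mars", analytes = m$var_names, mars = m,
                  meta = list())
}

#' Serialize / deserialize an aging model as JSON
#'
#' Schema-versioned; numbers at full double precision.
#'
#' @param model an `aging_model`.
#' @param path optional file path.
#' @return JSON string or path; `model_from_json` returns the model.
#' @export
model_to_json <- function(model, path = NULL) {
  obj <- list(schema = "metaboage/aging_model/1",
              kind = model$kind, analytes = model$analytes,
              intercept = model$intercept,
              coefficients = as.list(model$coefficients),
              penalty_factors = as.list(model$penalty_factors),
              rescale = model$rescale, meta = model$meta,
              mars = if (!is.null(model$mars))
                jsonlite::fromJSON(mars_to_json(model$mars),
                                   simplifyVector = FALSE))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

#' @rdname model_to_json
#' @param json JSON string or file path.
#' @export
model_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  if (!identical(obj$schema, "metaboage/aging_model/1"))
    stop_metaboage("not an aging_model JSON document")
  mars <- NULL
  if (!is.null(obj$mars))
    mars <- mars_from_json(jsonlite::toJSON(obj$mars, auto_unbox = TRUE,
                                            digits = NA, null = "null"))
  new_aging_model(
    kind = obj$kind,
    analytes = as.character(unlist(obj$analytes)),
    intercept = obj$intercept %||% 0,
    coefficients = if (length(obj$coefficients))
      unlist(obj$coefficients) else NULL,
    mars = mars,
    penalty_factors = if (length(obj$penalty_factors))
      unlist(obj$penalty_factors) else NULL,
    rescale = obj$rescale, meta = obj$meta)
}
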