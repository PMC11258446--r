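default_predict_fn <- function(model, x) {
  if (inherits(model, "aging_model")) predict_age(model, x)
  else as.vector(predict(model, x))
}

safe_cor <- function(a, b) {
  if (length(a) < 2 || sd(a) == 0 || sd(b) == 0) return(NA_real_)
  cor(a, b)
}

#' k-fold cross-validation of an age model trainer
#'
#' Folds are assigned at subject level (repeat visits of one subject never
#' straddle folds) as a deterministic function of the seed and the subject
#' list. Out-of-fold predictions are pooled and the pooled Pearson r and
#' mean absolute error are reported alongside per-fold values. Pooled r is
#' computed over the pooled predictions, not averaged over folds.
#'
#' @param trainer `function(x, y) -> model`; the model is evaluated with
#'   `predict_fn`.
#' @param x predictor matrix; `y` response (years).
#' @param y numeric response.
#' @param k number of folds (default 7).
#' @param seed fold-assignment seed.
#' @param subject_id optional subject labels (defaults to one subject per
#'   row).
#' @param predict_fn `function(model, x) -> predictions`; defaults to
#'   [predict_age()] for `aging_model`s and `predict()` otherwise.
#' @return a `cv_report`: `scheme`, `folds` (assignment), per-fold table,
#'   pooled `r` and `mae`, pooled predictions, `seed`.
#' @export
kfold_cv <- function(trainer, x, y, k = 7, seed = 1L, subject_id = NULL,
                     predict_fn = default_predict_fn) {
  x <- as.matrix(x)
  if (is.null(subject_id)) subject_id <- seq_len(nrow(x))
  subjects <- unique(subject_id)
  if (k > length(subjects))
    stop_metaboage("k exceeds the number of subjects")
  fold_of_subject <- with_seed(seed,
    setNames(sample(rep_len(seq_len(k), length(subjects))),
             as.character(subjects)))
  fold <- unname(fold_of_subject[as.character(subject_id)])
  pred <- rep(NA_real_, nrow(x))
  per_fold <- data.frame(fold = seq_len(k), n = NA_integer_,
                         r = NA_real_, mae = NA_real_)
  for (f in seq_len(k)) {
    test <- which(fold == f)
    model <- trainer(x[-test, , drop = FALSE], y[-test])
    pred[test] <- predict_fn(model, x[test, , drop = FALSE])
    per_fold$n[f] <- length(test)
    per_fold$r[f] <- safe_cor(pred[test], y[test])
    per_fold$mae[f] <- mean(abs(pred[test] - y[test]))
  }
  # a degenerate (within-fold constant) predictor has no meaningful pooled
  # correlation even though fold means differ
  degenerate <- all(tapply(pred, fold, sd) == 0)
  structure(list(scheme = "kfold", folds = fold, per_fold = per_fold,
                 r = if (degenerate) NA_real_ else safe_cor(pred, y),
                 mae = mean(abs(pred - y)),
                 predictions = pred, seed = seed),
            class = "cv_report")
}

#' Leave-one-cohort-out validation
#'
#' Each cohort is held out in turn; the model is trained on all other
#' cohorts and scored on the held-out one. Cohorts with (near-)constant age
#' (birth cohorts) report `NA` correlation but still report MAE.
#'
#' @inheritParams kfold_cv
#' @param cohorts cohort label per row of `x`.
#' @return a `cv_report` with `scheme = "loco"` and per-cohort table.
#' @export
loco_cv <- function(trainer, x, y, cohorts,
                    predict_fn = default_predict_fn) {
  x <- as.matrix(x)
  ch <- unique(cohorts)
  if (length(ch) < 2) stop_metaboage("need at least 2 cohorts")
  pred <- rep(NA_real_, nrow(x))
  per <- data.frame(cohort = ch, n = NA_integer_, r = NA_real_,
                    mae = NA_real_)
  for (i in seq_along(ch)) {
    test <- which(cohorts == ch[i])
    model <- trainer(x[-test, , drop = FALSE], y[-test])
    pred[test] <- predict_fn(model, x[test, , drop = FALSE])
    per$n[i] <- length(test)
    per$r[i] <- safe_cor(pred[test], y[test])
    per$mae[i] <- mean(abs(pred[test] - y[test]))
  }
  structure(list(scheme = "loco", folds = match(cohorts, ch),
                 per_fold = per, r = safe_cor(pred, y),
                 mae = mean(abs(pred - y)), predictions = pred,
                 seed = NA_integer_),
            class = "cv_report")
}

#' Longitudinal delta-age concordance
#'
#' For subjects with two visits, compares the change in predicted
#' metabolomic age between visits (delta predicted age) against the change
#' in chronological age (delta CA), reporting the per-subject pairs, their
#' Pearson correlation, and the median delta predicted age per integer year
#' of delta CA.
#'
#' @param model an `aging_model` (or anything `predict_fn` accepts).
#' @param matrix longitudinal metabolite matrix (visit column set).
#' @param pheno phenotype table.
#' @param predict_fn prediction function (see [kfold_cv()]).
#' @return a `delta_age_report`: `pairs` (subject, delta_ca, delta_pred),
#'   `correlation`, `by_gap` (median delta predicted per integer delta CA).
#' @export
delta_age <- function(model, matrix, pheno,
                      predict_fn = default_predict_fn) {
  ph <- pheno[match(matrix$sample_id, pheno$sample_id), ]
  tab <- table(matrix$subject_id)
  subs <- names(tab)[tab >= 2]
  if (!length(subs)) stop_metaboage("no subjects with repeat visits")
  scores <- predict_fn(model, matrix)
  rows <- lapply(subs, function(s) {
    idx <- which(matrix$subject_id == s)
    idx <- idx[order(matrix$visit[idx])]
    i1 <- idx[1]; i2 <- idx[length(idx)]
    data.frame(subject_id = s, cohort = matrix$cohort[i1],
               delta_ca = ph$age[i2] - ph$age[i1],
               delta_pred = scores[i2] - scores[i1],
               stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, rows)
  rownames(pairs) <- NULL
  gap <- round(pairs$delta_ca)
  by_gap <- aggregate(pairs$delta_pred, list(delta_ca_years = gap), median)
  names(by_gap)[2] <- "median_delta_pred"
  structure(list(pairs = pairs,
                 correlation = safe_cor(pairs$delta_ca, pairs$delta_pred),
                 by_gap = by_gap, n_subjects = nrow(pairs)),
            class = "delta_age_report")
}
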