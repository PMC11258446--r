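#' Variable-level quality control
#'
#' Excludes analytes that are frequently missing in one or more cohorts and,
#' when replicate measurements are supplied (e.g. the same samples
#' re-quantified under a second assay protocol), analytes whose replicate
#' Pearson correlation falls below `r_threshold`.
#'
#' @param matrix metabolite matrix.
#' @param replicate_matrix optional matrix with the same `sample_id`s and
#'   (a subset of) the same analyte columns, holding replicate
#'   quantifications.
#' @param missing_rule maximum tolerated fraction of missing values within
#'   any single cohort (default 0.2); an analyte exceeding it in at least
#'   one cohort where it was assayed at all is excluded, as is an analyte
#'   entirely absent from any cohort.
#' @param r_threshold replicate-correlation threshold (default 0.7).
#' @return A `qc_report` list: `retained_analytes`, `excluded_missing`,
#'   `excluded_replicate_corr` (named numeric of r values), and
#'   `outlier_samples` (empty here; see [detect_outliers()]).
#' @export
filter_variables <- function(matrix, replicate_matrix = NULL,
                             missing_rule = 0.2, r_threshold = 0.7) {
  analytes <- analyte_names(matrix)
  excluded_missing <- character()
  for (a in analytes) {
    fr <- tapply(is.na(matrix[[a]]), matrix$cohort, mean)
    if (any(fr > missing_rule)) excluded_missing <- c(excluded_missing, a)
  }
  excluded_corr <- numeric()
  if (!is.null(replicate_matrix)) {
    common <- intersect(setdiff(analytes, excluded_missing),
                        analyte_names(replicate_matrix))
    m <- match(replicate_matrix$sample_id, matrix$sample_id)
    if (anyNA(m))
      stop_metaboage("replicate_matrix has sample_ids absent from matrix")
    for (a in common) {
      r <- suppressWarnings(cor(matrix[[a]][m], replicate_matrix[[a]],
                                use = "complete.obs"))
      if (is.na(r) || r < r_threshold) {
        excluded_corr[a] <- r
      }
    }
  }
  retained <- setdiff(analytes, c(excluded_missing, names(excluded_corr)))
  if (!length(retained))
    stop_metaboage("variable QC excluded every analyte")
  structure(list(retained_analytes = retained,
                 excluded_missing = excluded_missing,
                 excluded_replicate_corr = excluded_corr,
                 outlier_samples = data.frame(sample_id = character(),
                                              weight = numeric())),
            class = "qc_report")
}

# Robust PCA score distances for one cohort block (complete analytes only).
# Median/MAD standardization, PCA retaining `var_keep` of variance,
# MAD-rescaled scores, squared distance summed over retained components.
robust_score_distance <- function(x, var_keep = 0.99) {
  med <- apply(x, 2, median)
  s <- apply(x, 2, mad)
  s[s == 0] <- 1
  z <- sweep(sweep(x, 2, med, "-"), 2, s, "/")
  pc <- prcomp(z, center = TRUE, scale. = FALSE)
  keep <- which(cumsum(pc$sdev^2) / sum(pc$sdev^2) >= var_keep)[1]
  keep <- max(1L, keep)
  sc <- pc$x[, seq_len(keep), drop = FALSE]
  smad <- apply(sc, 2, mad)
  smad[smad == 0] <- 1
  sc <- sweep(sc, 2, smad, "/")
  list(d2 = rowSums(sc^2), k = keep)
}

#' Multivariate outlier weights per cohort
#'
#' A robust-PCA weighting scheme compatible with pcout-style location
#' outlier detection: analytes are median/MAD standardized per cohort,
#' projected on principal components retaining 99% of variance, component
#' scores are MAD-rescaled, and squared score distances `d2` are calibrated
#' so that their median matches the chi-square median at the retained
#' dimension. Weights follow a translated-biweight taper between the
#' calibrated chi-square 0.5 and 0.999 quantiles (1 below, a small positive
#' floor above), so weights lie in (0, 1], are non-increasing in distance,
#' and samples with weight <= `weight_threshold` are flagged as location
#' outliers.
#'
#' @param matrix metabolite matrix.
#' @param per_cohort flag: compute weights within each cohort (default) or
#'   over the pooled data.
#' @param weight_threshold samples with weight at or below this are flagged
#'   (default 0.1; 0 flags nothing since weights are strictly positive).
#' @param var_keep fraction of variance retained by the PCA step.
#' @return A `qc_report` with `outlier_samples` (data frame of all samples
#'   with `sample_id`, `cohort`, `weight`, `distance` (calibrated squared
#'   score distance), `flagged`).
#' @export
detect_outliers <- function(matrix, per_cohort = TRUE,
                            weight_threshold = 0.1, var_keep = 0.99) {
  analytes <- analyte_names(matrix)
  groups <- if (per_cohort) split(seq_len(nrow(matrix)), matrix$cohort)
            else list(all = seq_len(nrow(matrix)))
  res <- lapply(names(groups), function(g) {
    idx <- groups[[g]]
    if (length(idx) < 20)
      stop_metaboage("cohort ", g, " has fewer than 20 samples")
    block <- matrix[idx, analytes, drop = FALSE]
    ok <- vapply(block, function(col) !anyNA(col), logical(1))
    x <- as.matrix(block[, ok, drop = FALSE])
    rd <- robust_score_distance(x, var_keep)
    d2 <- rd$d2 * qchisq(0.5, rd$k) / median(rd$d2)
    lo <- qchisq(0.5, rd$k); hi <- qchisq(0.999, rd$k)
    w <- ifelse(d2 <= lo, 1,
                ifelse(d2 >= hi, 0,
                       (1 - ((d2 - lo) / (hi - lo))^2)^2))
    w <- pmax(w, 1e-6)
    data.frame(sample_id = matrix$sample_id[idx],
               cohort = matrix$cohort[idx], weight = w, distance = d2,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[match(matrix$sample_id, out$sample_id), ]
  rownames(out) <- NULL
  out$flagged <- out$weight <= weight_threshold  # weights > 0, so 0 flags none
  if (sum(!out$flagged) < length(analytes))
    warning("fewer samples than analytes remain after outlier removal")
  structure(list(retained_analytes = analytes,
                 excluded_missing = character(),
                 excluded_replicate_corr = numeric(),
                 outlier_samples = out),
            class = "qc_report")
}

#' Drop flagged outlier samples
#'
#' @param matrix metabolite matrix.
#' @param qc a `qc_report` from [detect_outliers()].
#' @return `matrix` without flagged samples.
#' @export
remove_outliers <- function(matrix, qc) {
  bad <- qc$outlier_samples$sample_id[qc$outlier_samples$flagged]
  matrix[!matrix$sample_id %in% bad, , drop = FALSE]
}

# Demographic stratum labels used for calibration matching:
# sex x 5-year age band x BMI class x ethnicity.
calib_strata <- function(pheno) {
  band <- 5 * floor(pheno$age / 5)
  bmi_cl <- cut(pheno$bmi, c(-Inf, 25, 30, Inf),
                labels = c("lean", "over", "obese"))
  paste(pheno$sex, band, bmi_cl, pheno$ethnicity, sep = "|")
}

#' Between-cohort calibration against a reference cohort
#'
#' For every non-reference cohort, samples in demographic strata
#' (sex x 5-year age band x BMI class x ethnicity) present in both that
#' cohort and the reference are selected; per analyte, the scaling factor is
#' `median(reference matched values) / median(target matched values)` and is
#' applied multiplicatively to all samples of the target cohort. The
#' reference cohort is left untouched (factor 1).
#'
#' @param matrix metabolite matrix.
#' @param pheno phenotype table (must cover `matrix$sample_id`).
#' @param reference_cohort cohort label used as the calibration reference —
#'   conventionally a mixed-sex cohort in the middle of the age range.
#' @return list: `matrix` (calibrated) and `factors` (a
#'   `calibration_factors` object: cohort x analyte factor matrix plus
#'   per-cohort matched sample counts).
#' @export
calibrate_cohorts <- function(matrix, pheno, reference_cohort) {
  analytes <- analyte_names(matrix)
  cohorts <- unique(matrix$cohort)
  if (!reference_cohort %in% cohorts)
    stop_metaboage("reference cohort '", reference_cohort, "' not present")
  ph <- pheno[match(matrix$sample_id, pheno$sample_id), ]
  strata <- calib_strata(ph)
  ref_idx <- which(matrix$cohort == reference_cohort)
  fac <- matrix(1, length(cohorts), length(analytes),
                dimnames = list(cohorts, analytes))
  matched_n <- setNames(integer(length(cohorts)), cohorts)
  matched_n[reference_cohort] <- length(ref_idx)
  out <- matrix
  for (ch in setdiff(cohorts, reference_cohort)) {
    tgt_idx <- which(matrix$cohort == ch)
    common <- intersect(unique(strata[ref_idx]), unique(strata[tgt_idx]))
    if (!length(common))
      stop_metaboage("no demographically matched stratum between cohort '",
                     ch, "' and the reference")
    r_i <- ref_idx[strata[ref_idx] %in% common]
    t_i <- tgt_idx[strata[tgt_idx] %in% common]
    matched_n[ch] <- length(t_i)
    for (a in analytes) {
      mr <- median(matrix[[a]][r_i], na.rm = TRUE)
      mt <- median(matrix[[a]][t_i], na.rm = TRUE)
      f <- if (is.na(mr) || is.na(mt) || mt == 0) 1 else mr / mt
      if (!is.finite(f) || f <= 0) f <- 1
      fac[ch, a] <- f
      out[[a]][tgt_idx] <- matrix[[a]][tgt_idx] * f
    }
  }
  structure_factors <- structure(list(factors = fac, matched_n = matched_n,
                                      reference = reference_cohort),
                                 class = "calibration_factors")
  list(matrix = out, factors = structure_factors)
}

#' k-nearest-neighbour imputation of missing analytes
#'
#' Neighbours are found by Euclidean distance in the z-scaled space of
#' analytes observed for every sample ("complete-analyte space"); each
#' missing entry is replaced by the mean of the `k` nearest samples with
#' that analyte observed. Observed entries are untouched.
#'
#' @param matrix metabolite matrix.
#' @param k number of neighbours (default 10).
#' @return imputed metabolite matrix.
#' @export
knn_impute <- function(matrix, k = 10) {
  analytes <- analyte_names(matrix)
  x <- analyte_matrix(matrix)
  if (!anyNA(x)) return(matrix)
  if (any(rowSums(!is.na(x)) == 0))
    stop_metaboage("a sample has no observed analyte")
  complete <- analytes[colSums(is.na(x)) == 0]
  if (!length(complete))
    stop_metaboage("no analyte observed in all samples; cannot define ",
                   "neighbour space")
  bad <- analytes[colSums(!is.na(x)) == 0]
  if (length(bad))
    stop_metaboage("analyte(s) missing in every sample: ",
                   paste(bad, collapse = ", "))
  z <- zscale(x[, complete, drop = FALSE])
  # pairwise distances via the cross-product identity; fine at study scale
  sq <- rowSums(z^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(z)
  diag(d2) <- Inf
  out <- matrix
  for (a in setdiff(analytes, complete)) {
    miss <- which(is.na(x[, a]))
    obs_ok <- !is.na(x[, a])
    for (i in miss) {
      dd <- d2[i, ]
      dd[!obs_ok] <- Inf
      nb <- order(dd)[seq_len(min(k, sum(is.finite(dd))))]
      out[[a]][i] <- mean(x[nb, a])
    }
  }
  out
}

# VIFs of every column of a numeric matrix: diagonal of the inverse
# correlation matrix; falls back to per-variable R^2 when singular.
vif_values <- function(x) {
  r <- suppressWarnings(cor(x))
  v <- tryCatch(diag(solve(r)), error = function(e) NULL)
  if (!is.null(v) && all(is.finite(v)) && all(v >= 1 - 1e-8))
    return(pmax(v, 1))
  vapply(seq_len(ncol(x)), function(j) {
    fit <- lm.fit(cbind(1, x[, -j, drop = FALSE]), x[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((x[, j] - mean(x[, j]))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
}

#' Backward VIF pruning to an independent analyte set
#'
#' Iteratively removes the analyte with the largest variance inflation
#' factor (`1 / (1 - R^2)` from regressing it on all remaining analytes)
#' until every remaining VIF is below `threshold`. Perfectly collinear
#' analytes surface as infinite VIF and go first; ties on the maximum are
#' broken by column order.
#'
#' @param matrix metabolite matrix or plain numeric matrix/data frame of
#'   analytes (rows with missing values are dropped).
#' @param threshold VIF threshold (default 5).
#' @return A `vif_trace` list: `removed` (data frame of analyte and VIF at
#'   removal, in order), `retained` (analyte names), `final_vif` (named
#'   vector), `threshold`.
#' @export
vif_prune <- function(matrix, threshold = 5) {
  analytes <- if (is.data.frame(matrix) && "sample_id" %in% names(matrix))
    analyte_names(matrix) else colnames(matrix)
  x <- if (is.data.frame(matrix)) as.matrix(matrix[, analytes, drop = FALSE])
       else matrix
  x <- x[complete.cases(x), , drop = FALSE]
  if (ncol(x) < 2) stop_metaboage("need at least 2 analytes")
  if (nrow(x) <= ncol(x))
    stop_metaboage("need more samples than analytes for VIF pruning")
  removed <- data.frame(analyte = character(), vif = numeric())
  repeat {
    v <- vif_values(x)
    names(v) <- colnames(x)
    if (ncol(x) == 1 || max(v) < threshold) break
    j <- which.max(v)  # which.max returns the first maximum: tie-break
    removed <- rbind(removed,
                     data.frame(analyte = colnames(x)[j], vif = v[[j]]))
    x <- x[, -j, drop = FALSE]
  }
  v <- if (ncol(x) >= 2) setNames(vif_values(x), colnames(x))
       else setNames(1, colnames(x))
  structure(list(removed = removed, retained = colnames(x),
                 final_vif = v, threshold = threshold),
            class = "vif_trace")
}
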