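required_matrix_cols <- c("sample_id", "subject_id", "cohort", "visit")
required_pheno_cols <- c("sample_id", "age", "sex", "cohort")

# Strict CSV reader: explicit "NA" token only, decimal point only; numeric
# columns that fail to parse are reported by name.
read_strict_csv <- function(path, required, numeric_cols = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = "NA")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop_metaboage(basename(path), ": malformed header, missing column(s) ",
                   paste(miss, collapse = ", "))
  check <- numeric_cols %||% setdiff(names(df), required)
  for (cl in intersect(check, names(df))) {
    v <- df[[cl]]
    if (is.character(v)) {
      bad <- which(!is.na(v) & is.na(suppressWarnings(as.numeric(v))))
      if (length(bad))
        stop_metaboage(basename(path), ": column '", cl,
                       "' is not numeric (e.g. row ", bad[1], " = '",
                       v[bad[1]], "'); decimal commas are not accepted")
      df[[cl]] <- as.numeric(v)
    }
  }
  df
}

#' Read / write pipeline tables
#'
#' Plain CSV with a header row, `sample_id` key column and explicit `NA`
#' token; analyte and numeric phenotype columns must parse as numbers
#' (decimal-comma files are rejected, not coerced). Round trips are lossless
#' to better than 1e-12 relative error.
#'
#' @param path CSV file path.
#' @return the table (data frame).
#' @export
read_metabolite_matrix <- function(path) {
  df <- read_strict_csv(path, required_matrix_cols)
  df$visit <- as.integer(df$visit)
  df
}

#' @rdname read_metabolite_matrix
#' @param matrix,pheno tables to write.
#' @export
write_metabolite_matrix <- function(matrix, path) {
  stopifnot(all(required_matrix_cols %in% names(matrix)))
  write.csv(matrix, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname read_metabolite_matrix
#' @export
read_pheno_table <- function(path) {
  read_strict_csv(path, required_pheno_cols,
                  numeric_cols = c("age", "sex", "bmi", "surv_time",
                                   "event", "visit", "smoking", "inactive",
                                   "obesity", "crp", "egfr", "sbp"))
}

#' @rdname read_metabolite_matrix
#' @export
write_pheno_table <- function(pheno, path) {
  stopifnot(all(required_pheno_cols %in% names(pheno)))
  write.csv(pheno, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

# Truth record to JSON: generative parameters only (the per-subject latent
# state is in-memory plumbing, regenerable from the seed).
truth_to_json <- function(truth, path) {
  cfg <- truth$config
  keep <- setdiff(names(cfg), character(0))
  obj <- list(schema = "metaboage/truth/1",
              config = cfg[keep],
              outlier_sample_ids = truth$outlier_sample_ids,
              note = paste("per-subject latent state omitted;",
                           "regenerate via simulate_cohorts(config)"))
  obj$config$eth_mix <- lapply(cfg$eth_mix, as.list)
  obj$config$batch <- NULL   # large; recoverable from the seed
  obj$config$loadings <- NULL
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Pipeline configuration
#'
#' Collects every stage toggle and fixed threshold of the end-to-end run:
#' missingness rule 20%, replicate correlation 0.7, outlier weight 0.1,
#' VIF 5, elastic-net alpha 0.5, FDR 0.05, reporting p 0.001, 7 folds, the
#' nine age-group strata. One seed drives every stochastic stage.
#'
#' @param seed mandatory integer seed.
#' @param out_dir output directory.
#' @param n_cohorts,n_subjects,n_metabolites simulation scale (defaults
#'   8 x 1500 x 98; tests use smaller scales).
#' @param stages character vector of stages to run, in order, from
#'   `simulate, preprocess, mwas, fit, score, evaluate, associate`.
#' @param reference_cohort calibration reference (default: the generator's
#'   mid-age mixed-sex cohort).
#' @param missing_rule,r_threshold,outlier_weight,vif_threshold,alpha,
#'   fdr_threshold,report_p,k_folds,age_bins thresholds (documented
#'   defaults).
#' @param mars_max_terms,mars_n_knots MARS forward-pass size controls.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed, out_dir,
                            n_cohorts = 8L, n_subjects = 1500L,
                            n_metabolites = 98L,
                            stages = c("simulate", "preprocess", "mwas",
                                       "fit", "score", "evaluate",
                                       "associate"),
                            reference_cohort = NULL,
                            missing_rule = 0.2, r_threshold = 0.7,
                            outlier_weight = 0.1, vif_threshold = 5,
                            alpha = 0.5, fdr_threshold = 0.05,
                            report_p = 0.001, k_folds = 7L,
                            age_bins = c(20, 35, 40, 45, 50, 55, 60, 65,
                                         70, Inf),
                            mars_max_terms = 21L, mars_n_knots = 31L) {
  if (missing(seed)) stop_metaboage("seed is mandatory")
  stopifnot(outlier_weight >= 0, outlier_weight <= 1,
            missing_rule >= 0, missing_rule <= 1,
            alpha >= 0, alpha <= 1, vif_threshold > 1)
  structure(as.list(environment()), class = "pipeline_config")
}

stage_log <- function(log, stage, ...) {
  msg <- paste0(...)
  message("[", stage, "] ", msg)
  c(log, setNames(list(msg), paste0(stage, ".", length(log))))
}

#' Run the end-to-end pipeline
#'
#' Chains simulate -> preprocess (QC, outlier removal, calibration, VIF
#' pruning) -> MWAS meta-analysis -> model fitting (elastic net, MARS,
#' phenotypic age, mortality score) -> coefficient-table scoring -> 7-fold /
#' LOCO / delta-age evaluation -> CA-adjusted association analyses, writing
#' versioned CSV/JSON outputs plus a manifest with input hashes and
#' per-stage sample/analyte counts. A stage failure halts the run with the
#' manifest recording completed stages. Reruns with the same config are
#' byte-identical.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) the output directory; side effect: files under it.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages
  manifest <- list(package_version = "0.1.0", seed = config$seed,
                   stages_completed = character(0), counts = list())
  log <- list()
  finish <- function() {
    cfg_ser <- config
    cfg_ser$age_bins <- as.character(cfg_ser$age_bins)  # Inf-safe JSON
    manifest$config <- unclass(cfg_ser)
    files <- setdiff(list.files(config$out_dir), "manifest.json")
    manifest$hashes <- as.list(tools::md5sum(
      file.path(config$out_dir, files)))
    names(manifest$hashes) <- files
    jsonlite::write_json(manifest, file.path(config$out_dir,
                                             "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  on.exit(finish())
  pth <- function(f) file.path(config$out_dir, f)

  if ("fit" %in% stages && !"mwas" %in% stages)
    stop_metaboage("fit stage (phenotypic age) requires the mwas stage; ",
                   "enable 'mwas' or drop 'fit'")

  ## -- simulate ----------------------------------------------------------
  sim <- NULL
  if ("simulate" %in% stages) {
    sc <- sim_config(seed = config$seed, n_cohorts = config$n_cohorts,
                     n_subjects = config$n_subjects,
                     n_metabolites = config$n_metabolites)
    g <- simulate_cohorts(sc)
    lv <- add_longitudinal_visits(g$matrix, g$pheno, sc, g$truth)
    pheno <- simulate_survival(lv$pheno, lv$matrix, sc)
    sim <- list(matrix = lv$matrix, pheno = pheno, truth = g$truth,
                config = sc)
    write_metabolite_matrix(sim$matrix, pth("matrix.csv"))
    write_pheno_table(sim$pheno, pth("pheno.csv"))
    truth_to_json(sim$truth, pth("truth.json"))
    manifest$counts$simulate <- list(samples = nrow(sim$matrix),
                                     analytes = length(analyte_names(
                                       sim$matrix)))
    manifest$stages_completed <- c(manifest$stages_completed, "simulate")
  } else {
    sim <- list(matrix = read_metabolite_matrix(pth("matrix.csv")),
                pheno = read_pheno_table(pth("pheno.csv")),
                config = NULL)
  }
  mat <- sim$matrix; pheno <- sim$pheno
  reference <- config$reference_cohort %||%
    (if (!is.null(sim$config)) sim$config$reference_cohort
     else unique(mat$cohort)[1])

  ## -- preprocess --------------------------------------------------------
  pruned_analytes <- analyte_names(mat)
  if ("preprocess" %in% stages) {
    n_in <- nrow(mat); a_in <- length(analyte_names(mat))
    qc <- filter_variables(mat, missing_rule = config$missing_rule,
                           r_threshold = config$r_threshold)
    mat <- mat[, c(required_matrix_cols, qc$retained_analytes)]
    ow <- detect_outliers(mat, weight_threshold = config$outlier_weight)
    mat <- remove_outliers(mat, ow)
    pheno <- pheno[pheno$sample_id %in% mat$sample_id, ]
    cal <- calibrate_cohorts(mat, pheno, reference)
    mat <- cal$matrix
    vt <- vif_prune(mat[mat$visit == 1L, , drop = FALSE],
                    threshold = config$vif_threshold)
    pruned_analytes <- vt$retained
    jsonlite::write_json(
      list(qc = list(retained = qc$retained_analytes,
                     excluded_missing = qc$excluded_missing),
           outliers_removed = sum(ow$outlier_samples$flagged),
           calibration_factors = as.data.frame(cal$factors$factors),
           vif = list(removed = vt$removed, retained = vt$retained)),
      pth("preprocess_report.json"), auto_unbox = TRUE, digits = NA)
    write_metabolite_matrix(mat, pth("matrix_calibrated.csv"))
    manifest$counts$preprocess <- list(
      samples_in = n_in, samples_out = nrow(mat),
      analytes_in = a_in, analytes_out = length(qc$retained_analytes),
      analytes_pruned = length(pruned_analytes))
    manifest$stages_completed <- c(manifest$stages_completed, "preprocess")
  }

  ## -- mwas --------------------------------------------------------------
  age_meta <- mort_meta <- NULL
  if ("mwas" %in% stages) {
    base <- mat[mat$visit == 1L, , drop = FALSE]
    age_eff <- mwas_age(base, pheno)
    age_meta <- meta_fixed(age_eff)
    strat_eff <- mwas_age_stratified(base, pheno, bins = config$age_bins)
    strat_meta <- meta_fixed(strat_eff)
    mort_eff <- mwas_mortality(base, pheno)
    mort_meta <- meta_fixed(mort_eff)
    write.csv(age_meta, pth("mwas_age_meta.csv"), row.names = FALSE)
    write.csv(strat_meta, pth("mwas_age_stratified_meta.csv"),
              row.names = FALSE)
    write.csv(mort_meta, pth("mwas_mortality_meta.csv"), row.names = FALSE)
    manifest$counts$mwas <- list(
      age_sig = sum(age_meta$q < config$fdr_threshold, na.rm = TRUE),
      mortality_sig = sum(mort_meta$q < config$fdr_threshold,
                          na.rm = TRUE))
    manifest$stages_completed <- c(manifest$stages_completed, "mwas")
  }

  ## -- fit ---------------------------------------------------------------
  models <- list()
  if ("fit" %in% stages) {
    base <- mat[mat$visit == 1L, , drop = FALSE]
    ph <- pheno[match(base$sample_id, pheno$sample_id), ]
    x <- analyte_matrix(base, pruned_analytes)
    keep <- complete.cases(x)
    x <- x[keep, , drop = FALSE]; phk <- ph[keep, , drop = FALSE]
    models$elastic_net <- fit_elastic_net_age(
      x, phk$age, alpha = config$alpha, seed = child_seed(config$seed, 10))
    models$mars <- fit_mars_age(x, phk$age,
                                max_terms = config$mars_max_terms,
                                n_knots = config$mars_n_knots)
    pf <- mortality_penalty_factors(age_meta, mort_meta,
                                    analytes = pruned_analytes)
    models$phenotypic <- fit_phenotypic_age(
      x, phk$age, penalty_factors = pf, alpha = config$alpha,
      seed = child_seed(config$seed, 11))
    sv <- !is.na(phk$surv_time) & !is.na(phk$event)
    if (sum(phk$event[sv], na.rm = TRUE) > 0) {
      models$mortality_score <- fit_mortality_score(
        x[sv, , drop = FALSE],
        phk[sv, c("age", "sex", "bmi", "ethnicity", "cohort")],
        phk$surv_time[sv], phk$event[sv], alpha = config$alpha,
        seed = child_seed(config$seed, 12))
    }
    for (nm in names(models))
      model_to_json(models[[nm]], pth(paste0("model_", nm, ".json")))
    manifest$counts$fit <- list(models = names(models),
                                n_train = nrow(x))
    manifest$stages_completed <- c(manifest$stages_completed, "fit")
  }

  ## -- score (coefficient-table score built from the mortality MWAS) -----
  scores_tab <- NULL
  if ("score" %in% stages && !is.null(mort_meta)) {
    top <- mort_meta[order(mort_meta$p), ]
    top <- head(top[top$analyte %in% analyte_names(mat), ], 14)
    tab <- data.frame(analyte = top$analyte, weight = top$beta_pooled,
                      transform = "log", scaling = "cohort_z",
                      stringsAsFactors = FALSE)
    attr(tab, "rescale_rule") <- "to_age_units"
    write_coefficient_table(tab, pth("coefficient_table.csv"))
    sc <- apply_coefficient_table(mat, pheno, tab)
    scores_tab <- sc
    manifest$stages_completed <- c(manifest$stages_completed, "score")
  }

  ## -- evaluate ----------------------------------------------------------
  if ("evaluate" %in% stages && length(models)) {
    base <- mat[mat$visit == 1L, , drop = FALSE]
    ph <- pheno[match(base$sample_id, pheno$sample_id), ]
    x <- analyte_matrix(base, pruned_analytes)
    keep <- complete.cases(x)
    x <- x[keep, , drop = FALSE]; phk <- ph[keep, , drop = FALSE]
    trainers <- list(
      elastic_net = function(xx, yy) fit_elastic_net_age(
        xx, yy, alpha = config$alpha, seed = child_seed(config$seed, 20)),
      mars = function(xx, yy) fit_mars_age(
        xx, yy, max_terms = config$mars_max_terms,
        n_knots = config$mars_n_knots))
    evals <- list()
    for (nm in names(trainers)) {
      cvr <- kfold_cv(trainers[[nm]], x, phk$age, k = config$k_folds,
                      seed = child_seed(config$seed, 21),
                      subject_id = base$subject_id[keep])
      lcr <- loco_cv(trainers[[nm]], x, phk$age, phk$cohort)
      evals[[nm]] <- list(cv_r = cvr$r, cv_mae = cvr$mae,
                          cv_per_fold = cvr$per_fold,
                          loco_r = lcr$r, loco_mae = lcr$mae,
                          loco_per_cohort = lcr$per_fold)
    }
    if (any(mat$visit > 1L)) {
      da <- delta_age(models$elastic_net, mat[, c(required_matrix_cols,
                                                  pruned_analytes)], pheno)
      evals$delta_age <- list(correlation = da$correlation,
                              by_gap = da$by_gap,
                              n_subjects = da$n_subjects)
    }
    jsonlite::write_json(evals, pth("evaluation.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    manifest$stages_completed <- c(manifest$stages_completed, "evaluate")
  }

  ## -- associate ---------------------------------------------------------
  if ("associate" %in% stages && length(models)) {
    scores <- lapply(models, predict_age,
                     matrix = mat[, c(required_matrix_cols,
                                      pruned_analytes)])
    if (!is.null(scores_tab)) scores$coef_table <- scores_tab
    rows <- list()
    for (nm in names(scores)) {
      s <- scores[[nm]]
      for (rf in intersect(c("smoking", "inactive", "obesity"),
                           names(pheno)))
        rows[[length(rows) + 1L]] <- riskfactor_assoc(
          s, pheno, rf, score_name = nm)
      for (bm in intersect(c("crp", "egfr", "sbp"), names(pheno)))
        rows[[length(rows) + 1L]] <- biomarker_assoc(
          s, pheno, bm, score_name = nm)
      if (any(!is.na(pheno$event)) && sum(pheno$event, na.rm = TRUE) > 0) {
        s_year <- if (nm %in% c("mortality_score", "coef_table")) s
                  else rescale_to_age_units(
                    s, pheno$age[match(names(s), pheno$sample_id)])
        rows[[length(rows) + 1L]] <- cox_event_assoc(
          s_year, pheno, score_name = nm)
      }
    }
    assoc <- do.call(rbind, rows)
    rownames(assoc) <- NULL
    write.csv(assoc, pth("associations.csv"), row.names = FALSE)
    manifest$counts$associate <- list(
      rows = nrow(assoc),
      significant = sum(assoc$p < config$report_p, na.rm = TRUE))
    manifest$stages_completed <- c(manifest$stages_completed, "associate")
  }

  invisible(config$out_dir)
}

#' Command-line entry point
#'
#' `metaboage_cli(c("run", "--seed", "17", "--out", "dir"))` runs the full
#' pipeline; `simulate` runs only the generator. Installed alongside the
#' package as `exec/metaboage`.
#'
#' @param args character vector of CLI arguments (default: the command
#'   line).
#' @return exit status, invisibly.
#' @export
metaboage_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: metaboage <run|simulate> --seed <int> --out <dir>",
    "        [--cohorts n] [--subjects n] [--metabolites n]", sep = "\n")
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) && i < length(args)) args[i + 1] else default
  }
  seed <- as.integer(opt("--seed", "1"))
  out <- opt("--out", ".")
  nch <- as.integer(opt("--cohorts", "8"))
  nsub <- as.integer(opt("--subjects", "1500"))
  nmet <- as.integer(opt("--metabolites", "98"))
  if (cmd == "simulate") {
    cfg <- pipeline_config(seed = seed, out_dir = out, n_cohorts = nch,
                           n_subjects = nsub, n_metabolites = nmet,
                           stages = "simulate")
    run_pipeline(cfg)
  } else if (cmd == "run") {
    cfg <- pipeline_config(seed = seed, out_dir = out, n_cohorts = nch,
                           n_subjects = nsub, n_metabolites = nmet)
    run_pipeline(cfg)
  } else {
    message(usage)
    return(invisible(1L))
  }
  invisible(0L)
}
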