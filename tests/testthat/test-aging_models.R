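make_xy <- function(seed = 1, n = 600, p = 6, active = c(2, -1.5, 1)) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, sprintf("m%02d", 1:p)))
  y <- 50 + as.vector(x[, seq_along(active)] %*% active) + rnorm(n, 0, 2)
  list(x = x, y = y)
}

test_that("elastic net approaches OLS as the penalty vanishes", {
  d <- make_xy(seed = 1, n = 1000, p = 3)
  m <- fit_elastic_net_age(d$x, d$y, lambda = 1e-7)
  ols <- coef(lm(d$y ~ d$x))
  expect_equal(unname(m$intercept), unname(ols[1]), tolerance = 1e-3)
  expect_equal(unname(m$coefficients), unname(ols[-1]), tolerance = 1e-3)
})

test_that("penalty factor 0 leaves a coefficient unshrunk", {
  d <- make_xy(seed = 2, n = 500, p = 4)
  pf <- c(0, 1, 1, 1)
  m <- fit_elastic_net_age(d$x, d$y, penalty_factors = pf, lambda = 0.5)
  # oracle: refit with x1 free and the rest at the penalized solution's
  # values -- x1's coefficient solves the unpenalized normal equation given
  # the other fitted effects
  resid_rest <- d$y - m$intercept -
    as.vector(d$x[, -1] %*% m$coefficients[-1])
  beta1_free <- sum((d$x[, 1] - mean(d$x[, 1])) * resid_rest) /
    sum((d$x[, 1] - mean(d$x[, 1]))^2)
  expect_equal(unname(m$coefficients[1]), beta1_free, tolerance = 1e-3)
})

test_that("uniform penalty factors reproduce the unweighted fit", {
  d <- make_xy(seed = 3, n = 400, p = 5)
  m1 <- fit_elastic_net_age(d$x, d$y, lambda = 0.3)
  m2 <- fit_phenotypic_age(d$x, d$y, penalty_factors = rep(0.5, 5),
                           lambda = 0.3)
  # glmnet rescales penalty factors to mean 1, so an all-equal vector is the
  # plain fit at the same lambda
  expect_equal(m1$coefficients, m2$coefficients, tolerance = 1e-8)
  expect_equal(m2$kind, "phenotypic")
})

test_that("support recovery on sparse generating signal", {
  hits <- 0L
  for (s in 1:10) {
    slopes <- c(rep(0.5, 5), rep(0, 19))
    cfg <- sim_config(seed = 700 + s, n_cohorts = 1, n_subjects = 2500,
                      n_metabolites = 24, age_slopes = slopes,
                      nonlinear_set = 0L, batch_sd = 0, bioage_sd = 0,
                      outlier_fraction = 0, missing_analytes = list())
    g <- simulate_cohorts(cfg)
    x <- as.matrix(g$matrix[, cfg$analytes])
    m <- fit_elastic_net_age(x, g$pheno$age, seed = s, nfolds = 5)
    sel <- names(m$coefficients)[m$coefficients != 0]
    if (all(cfg$analytes[1:5] %in% sel)) hits <- hits + 1L
  }
  expect_gte(hits / 10, 0.9)
})

test_that("mortality penalty factors follow the direction rule", {
  age_meta <- data.frame(analyte = c("a", "b", "c"),
                         beta_pooled = c(0.2, 0.3, -0.1))
  mort_meta <- data.frame(analyte = c("a", "b", "c"),
                          beta_pooled = c(0.25, -0.2, -0.3),
                          p = c(0.001, 0.0001, 1))
  v <- mortality_penalty_factors(age_meta, mort_meta)
  expect_equal(unname(v["a"]), 0.001)  # concordant: barely shrunk
  expect_equal(unname(v["b"]), 1)      # opposing: fully penalized
  expect_equal(unname(v["c"]), 1)      # p = 1, concordant: boundary
  expect_error(mortality_penalty_factors(age_meta, mort_meta,
                                         analytes = c("a", "zzz")),
               "zzz")
})

test_that("phenotypic age shrinks mortality-null analytes harder", {
  wins <- 0L
  for (s in 1:10) {
    set.seed(800 + s)
    n <- 1000
    x <- matrix(rnorm(n * 4), n, 4,
                dimnames = list(NULL, paste0("m", 1:4)))
    y <- 50 + 1.2 * x[, 1] + 1.2 * x[, 2] + rnorm(n, 0, 4)
    pf <- c(0.001, 1, 1, 1)  # m1 mortality-linked, m2 mortality-null
    m <- fit_phenotypic_age(x, y, penalty_factors = pf, lambda = 0.8)
    if (abs(m$coefficients[1]) >= abs(m$coefficients[2])) wins <- wins + 1L
  }
  expect_gte(wins / 10, 0.9)
})

test_that("mortality score: recovery, analyte-only restriction, rescaling", {
  cfg <- sim_config(seed = 5, n_cohorts = 1, n_subjects = 4000,
                    n_metabolites = 6, age_slopes = 0, nonlinear_set = 0L,
                    mortality_loghr = c(0, 0.4, rep(0, 4)), batch_sd = 0,
                    bioage_sd = 0, outlier_fraction = 0,
                    missing_analytes = list(), h0 = 1e-3)
  cfg$survival_cohorts <- cfg$cohorts
  g <- simulate_cohorts(cfg)
  ph <- simulate_survival(g$pheno, g$matrix, cfg)
  x <- as.matrix(g$matrix[, cfg$analytes])
  tr <- 1:3000; te <- 3001:4000
  m <- fit_mortality_score(x[tr, ], ph[tr, c("age", "sex", "bmi",
                                             "ethnicity", "cohort")],
                           ph$surv_time[tr], ph$event[tr], seed = 1,
                           nfolds = 5)
  expect_gt(unname(m$coefficients["m002"]), 0)

  # training-score mean/SD equal training-age mean/SD to machine precision
  s_tr <- predict_age(m, x[tr, ])
  expect_equal(mean(s_tr), mean(ph$age[tr]), tolerance = 1e-12)
  expect_equal(sd(s_tr), sd(ph$age[tr]), tolerance = 1e-12)

  # held-out hazard per SD of score
  s_te <- predict_age(m, x[te, ])
  fit <- summary(survival::coxph(
    survival::Surv(ph$surv_time[te], ph$event[te]) ~ scale(s_te)))
  expect_gt(fit$conf.int[1, "exp(coef)"], 1)
  expect_lt(fit$coefficients[1, "Pr(>|z|)"], 0.001)

  expect_error(fit_mortality_score(x[1:50, ],
                                   ph[1:50, c("age", "sex")],
                                   ph$surv_time[1:50],
                                   rep(0L, 50)),
               "no events")
})

test_that("rescale_to_age_units is an exact monotone affine map", {
  set.seed(6)
  s <- rnorm(200)
  ages <- rnorm(200, 50, 10)
  r <- rescale_to_age_units(s, ages)
  expect_equal(mean(r), mean(ages), tolerance = 1e-12)
  expect_equal(sd(r), sd(ages), tolerance = 1e-12)
  expect_equal(order(r), order(s))
  expect_equal(rescale_to_age_units(r, ages), r, tolerance = 1e-12)
  expect_error(rescale_to_age_units(rep(1, 5), ages[1:5]), "constant")
})

test_that("coefficient-table scoring matches hand arithmetic", {
  # two analytes, w = (0.5, -0.5), three samples, one cohort, cohort_z
  mat <- data.frame(sample_id = c("s1", "s2", "s3"), subject_id = "x",
                    cohort = "c1", visit = 1L,
                    a1 = c(1, 2, 3), a2 = c(2, 2, 5))
  ph <- data.frame(sample_id = mat$sample_id, age = c(40, 50, 60),
                   sex = 0, cohort = "c1", ethnicity = "e")
  tab <- data.frame(analyte = c("a1", "a2"), weight = c(0.5, -0.5),
                    transform = "none", scaling = "cohort_z")
  sc <- apply_coefficient_table(mat, ph, tab)
  z1 <- (mat$a1 - mean(mat$a1)) / sd(mat$a1)
  z2 <- (mat$a2 - mean(mat$a2)) / sd(mat$a2)
  expect_equal(unname(sc), 0.5 * z1 - 0.5 * z2, tolerance = 1e-12)

  # all-zero weights + to_age_units: the constant-score error surfaces
  tab0 <- tab; tab0$weight <- 0
  attr(tab0, "rescale_rule") <- "to_age_units"
  expect_error(apply_coefficient_table(mat, ph, tab0), "constant")

  # absent analyte is named in the error
  tab2 <- rbind(tab, data.frame(analyte = "zz", weight = 1,
                                transform = "none", scaling = "none"))
  expect_error(apply_coefficient_table(mat, ph, tab2), "zz")

  # missing values are imputed on request, error otherwise
  mat$a1[2] <- NA
  expect_error(apply_coefficient_table(mat, ph, tab, impute = FALSE),
               "a1")
  sc2 <- apply_coefficient_table(mat, ph, tab, impute = TRUE, k = 2)
  expect_length(sc2, 3)
  expect_true(all(is.finite(sc2)))
})

test_that("the bundled coefficient-table template round-trips", {
  tmpl <- system.file("extdata", "synthetic_weighted_score_template.csv",
                      package = "metaboage")
  expect_true(nzchar(tmpl))
  tab <- read_coefficient_table(tmpl)
  expect_equal(nrow(tab), 14)
  expect_true(all(tab$transform == "log"))
  expect_true(all(tab$scaling == "cohort_z"))
  expect_equal(attr(tab, "rescale_rule"), "to_age_units")
  path <- withr::local_tempfile(fileext = ".csv")
  write_coefficient_table(tab, path)
  tab2 <- read_coefficient_table(path)
  expect_equal(tab2$weight, tab$weight, tolerance = 1e-12)
  expect_equal(attr(tab2, "rescale_rule"), "to_age_units")
})

test_that("predict_age is deterministic and survives JSON round trips", {
  d <- make_xy(seed = 7, n = 300, p = 4)
  m <- fit_elastic_net_age(d$x, d$y, lambda = 0.2)
  s <- predict_age(m, d$x)

  # fitted values reproduced on training data
  expect_equal(unname(s),
               m$intercept + as.vector(d$x %*% m$coefficients))
  # identical rows give identical scores
  x2 <- d$x[c(1, 1), , drop = FALSE]
  expect_equal(predict_age(m, x2)[1], predict_age(m, x2)[2])

  # JSON round trip changes nothing beyond 1e-12
  for (model in list(m, fit_mars_age(d$x, d$y, max_terms = 7,
                                     n_knots = 9))) {
    path <- withr::local_tempfile(fileext = ".json")
    model_to_json(model, path)
    m2 <- model_from_json(path)
    expect_equal(unname(predict_age(m2, d$x)), unname(predict_age(model, d$x)),
                 tolerance = 1e-12)
  }

  # trainers are seed-deterministic
  ma <- fit_elastic_net_age(d$x, d$y, seed = 11, nfolds = 5)
  mb <- fit_elastic_net_age(d$x, d$y, seed = 11, nfolds = 5)
  expect_identical(ma$coefficients, mb$coefficients)
})
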