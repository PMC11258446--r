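test_that("forward pass reproduces the linear limit and exact hinges", {
  set.seed(1)
  n <- 300
  x <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("v", 1:3)))

  # noiseless linear response: the reflected pair spans {1, x}; predictions
  # match OLS to machine-level accuracy
  y <- 1.5 + 2 * x[, 1]
  m <- mars_forward(x, y, max_terms = 5)
  ols <- fitted(lm(y ~ x[, 1]))
  expect_lt(max(abs(predict(m, x) - ols)) / diff(range(y)), 1e-6)

  # noiseless single hinge, exhaustive knots: selects the observed value
  # nearest the true knot (exhaustive-search oracle), near-zero RSS
  y2 <- pmax(0, x[, 1] - 0.5)
  m2 <- mars_forward(x, y2, knots = "all", max_terms = 5)
  cand <- sort(unique(x[, 1]))
  cand <- cand[-length(cand)]
  rss_oracle <- vapply(cand, function(t) {
    b <- cbind(1, pmax(0, x[, 1] - t), pmax(0, t - x[, 1]))
    sum(lm.fit(b, y2)$residuals^2)
  }, numeric(1))
  expect_equal(m2$terms[[2]]$knots, cand[which.min(rss_oracle)])
  expect_lt(m2$rss, 1e-10)

  # noiseless degree-2 product: an interaction term with both variables
  y3 <- pmax(0, x[, 1] - 0.2) * pmax(0, x[, 2] + 0.1)
  m3 <- mars_fit(x, y3, knots = "all", max_terms = 11)
  varsets <- lapply(m3$terms, `[[`, "vars")
  expect_true(any(vapply(varsets, function(v) setequal(v, 1:2),
                         logical(1))))
})

test_that("forward RSS is monotone non-increasing in model size", {
  set.seed(2)
  n <- 250
  x <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("v", 1:4)))
  y <- x[, 1] + pmax(0, x[, 2] - 0.3) + rnorm(n, 0, 0.5)
  sizes <- c(3, 5, 7, 9, 11)
  rss <- vapply(sizes, function(mt)
    mars_forward(x, y, max_terms = mt, n_knots = 15)$rss, numeric(1))
  expect_true(all(diff(rss) <= 1e-8))
})

test_that("backward pruning follows the GCV criterion", {
  # closed form at M = 1: GCV = (RSS/n) / (1 - 1/n)^2
  set.seed(3)
  y <- rnorm(50)
  x <- matrix(rnorm(50), 50, 1, dimnames = list(NULL, "v1"))
  m <- mars_forward(x, y, max_terms = 3, n_knots = 7)
  pruned <- mars_prune(m, x, y)
  if (length(pruned$terms) == 1) {
    rss0 <- sum((y - mean(y))^2)
    expect_equal(pruned$gcv, (rss0 / 50) / (1 - 1 / 50)^2)
  }

  # pure noise, single predictor: pruned to intercept-only in most seeds.
  # With several predictors the greedy forward search selects the best of
  # p x K candidate pairs and its spurious gain sits near the GCV cutoff
  # (penalty d = 3), so one noise pair survives in a sizeable minority of
  # runs; see the methods vignette. The >= 80% property is asserted where
  # the selection effect is small (p = 1) and a weaker floor at p = 3.
  null_rate <- function(p) {
    nulls <- 0L
    for (s in 1:20) {
      set.seed(100 + s)
      n <- 250
      xx <- matrix(rnorm(n * p), n, p,
                   dimnames = list(NULL, paste0("v", seq_len(p))))
      yy <- rnorm(n)
      pm <- mars_fit(xx, yy, max_terms = 7, n_knots = 7)
      if (length(pm$terms) == 1) nulls <- nulls + 1L
    }
    nulls / 20
  }
  expect_gte(null_rate(1), 0.8)
  expect_gte(null_rate(3), 0.5)

  # strong hinge signal: a term on the signal variable always survives
  survives <- 0L
  for (s in 1:20) {
    set.seed(200 + s)
    n <- 150
    xx <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("v", 1:3)))
    yy <- 3 * pmax(0, xx[, 1] - 0.2) + rnorm(n, 0, 0.3)
    pm <- mars_fit(xx, yy, max_terms = 9, n_knots = 15)
    vars <- unique(unlist(lapply(pm$terms, `[[`, "vars")))
    if (1L %in% vars) survives <- survives + 1L
  }
  expect_equal(survives, 20L)

  # overparameterized model is rejected
  set.seed(4)
  xs <- matrix(rnorm(12 * 2), 12, 2, dimnames = list(NULL, c("a", "b")))
  ys <- rnorm(12)
  ms <- mars_forward(xs, ys, max_terms = 11, n_knots = 5)
  if (length(ms$terms) + 1.5 * (length(ms$terms) - 1) >= 12)
    expect_error(mars_prune(ms, xs, ys), "overparameterized")
})

test_that("coefficients equal the normal-equations solution on the basis", {
  set.seed(5)
  n <- 200
  x <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("v", 1:3)))
  y <- x[, 1] - pmax(0, x[, 2] - 0.5) + rnorm(n, 0, 0.4)
  m <- mars_fit(x, y, max_terms = 9, n_knots = 15)
  b <- vapply(m$terms, metaboage:::mars_term_value, numeric(n), x = x)
  beta_oracle <- solve(crossprod(b), crossprod(b, y))
  expect_equal(m$coefficients, as.vector(beta_oracle), tolerance = 1e-8)
})

test_that("prediction is deterministic, order-invariant, and matches a
           brute-force evaluator", {
  set.seed(6)
  n <- 150
  x <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("v", 1:3)))
  y <- 2 + x[, 1] + pmax(0, x[, 2] - 0.1) + rnorm(n, 0, 0.3)
  m <- mars_fit(x, y, max_terms = 9, n_knots = 15)

  # intercept-only prediction is constant
  m0 <- m; m0$terms <- m$terms[1]; m0$coefficients <- 3.5
  expect_equal(predict(m0, x), rep(3.5, n))

  # hinge contributes exactly zero at its own knot
  tm <- Filter(function(t) length(t$vars) == 1, m$terms)[[1]]
  xa <- x[1:2, , drop = FALSE]
  xa[, tm$vars] <- tm$knots
  expect_equal(metaboage:::mars_term_value(tm, xa), c(0, 0))

  # brute-force evaluator oracle
  brute <- function(model, xx) {
    out <- numeric(nrow(xx))
    for (i in seq_along(model$terms)) {
      t <- model$terms[[i]]
      v <- rep(1, nrow(xx))
      if (length(t$vars))
        for (f in seq_along(t$vars))
          v <- v * pmax(0, t$dirs[f] * (xx[, t$vars[f]] - t$knots[f]))
      out <- out + model$coefficients[i] * v
    }
    out
  }
  xnew <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, paste0("v", 1:3)))
  expect_equal(predict(m, xnew), brute(m, xnew), tolerance = 1e-12)

  # sample-order invariance
  perm <- sample(20)
  expect_equal(predict(m, xnew[perm, ]), predict(m, xnew)[perm])
})

test_that("variable importance ranks signal strength", {
  set.seed(7)
  n <- 400
  x <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("v", 1:4)))

  # single-variable model: that variable scores 100, the rest 0
  y <- 2 * pmax(0, x[, 1] - 0.1) + rnorm(n, 0, 0.2)
  m <- mars_fit(x, y, max_terms = 7, n_knots = 15)
  vi <- mars_importance(m, x, y)
  expect_equal(unname(vi["v1"]), 100)
  expect_true(all(vi[setdiff(names(vi), "v1")] <= 1e-9))

  # two equally contributing variables: comparable scores (median over seeds)
  gaps <- vapply(1:7, function(s) {
    set.seed(400 + s)
    xx <- matrix(rnorm(350 * 3), 350, 3,
                 dimnames = list(NULL, paste0("v", 1:3)))
    yy <- xx[, 1] + xx[, 2] + rnorm(350, 0, 0.3)
    mm <- mars_fit(xx, yy, max_terms = 9, n_knots = 15)
    vv <- mars_importance(mm, xx, yy)
    abs(vv["v1"] - vv["v2"])
  }, numeric(1))
  expect_lt(median(gaps), 20)

  # generating strength orders the scores
  y3 <- 3 * x[, 1] + 0.7 * x[, 2] + rnorm(n, 0, 0.3)
  m3 <- mars_fit(x, y3, max_terms = 11, n_knots = 15)
  vi3 <- mars_importance(m3, x, y3)
  expect_gt(vi3["v1"], vi3["v2"])
  expect_gt(vi3["v2"], max(vi3[c("v3", "v4")]))
})

test_that("MARS does not overfit pathologically in the linear limit", {
  ratios <- vapply(1:10, function(s) {
    set.seed(500 + s)
    n <- 800
    x <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("v", 1:4)))
    y <- x %*% c(1, -0.5, 0.3, 0) + rnorm(n, 0, 0.5)
    tr <- 1:500; te <- 501:n
    m <- mars_fit(x[tr, ], y[tr], max_terms = 11, n_knots = 15)
    ols <- lm(y ~ ., data = data.frame(y = y[tr], x[tr, ]))
    mse_mars <- mean((predict(m, x[te, ]) - y[te])^2)
    mse_ols <- mean((predict(ols, data.frame(x[te, ])) - y[te])^2)
    mse_mars / mse_ols
  }, numeric(1))
  expect_lte(median(ratios), 1.1)
})

test_that("JSON serialization round-trips exactly", {
  set.seed(8)
  n <- 150
  x <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("v", 1:3)))
  y <- x[, 1] + pmax(0, x[, 2] - 0.4) + rnorm(n, 0, 0.3)
  m <- mars_fit(x, y, max_terms = 9, n_knots = 15)
  path <- withr::local_tempfile(fileext = ".json")
  mars_to_json(m, path)
  m2 <- mars_from_json(path)
  expect_equal(predict(m2, x), predict(m, x), tolerance = 1e-12)
  expect_identical(lapply(m2$terms, `[[`, "knots"),
                   lapply(m$terms, `[[`, "knots"))
  expect_identical(m2$coefficients, m$coefficients)
})
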