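#' @name mars_engine
#' @title Degree-2 multivariate adaptive regression splines
#'
#' @description Self-contained MARS: a greedy forward pass adds reflected
#' hinge pairs `max(0, x_v - t)` / `max(0, t - x_v)`, optionally multiplied
#' into an existing degree-1 term (never exceeding degree 2 and never
#' repeating a variable within a term); a backward pass deletes terms by
#' generalized cross-validation, `GCV = (RSS/n) / (1 - C(M)/n)^2` with cost
#' `C(M) = M + d (M - 1) / 2` and the conventional interaction penalty
#' `d = 3`. Coefficients are always the ordinary least-squares solution on
#' the selected basis.
#'
#' A term is a list of factors `(var, knot, dir)`; its value is the product
#' of `max(0, dir * (x_var - knot))` over its factors, and the empty term is
#' the intercept.
NULL

# Evaluate one hinge term over a numeric matrix.
mars_term_value <- function(term, x) {
  v <- rep(1, nrow(x))
  if (length(term$vars))
    for (f in seq_along(term$vars))
      v <- v * pmax(0, term$dirs[f] * (x[, term$vars[f]] - term$knots[f]))
  v
}

mars_basis <- function(terms, x) {
  vapply(terms, mars_term_value, numeric(nrow(x)), x = x)
}

mars_gcv <- function(rss, n, m, penalty = 3) {
  cm <- m + penalty * (m - 1) / 2
  if (cm >= n) return(Inf)
  (rss / n) / (1 - cm / n)^2
}

mars_knot_grid <- function(xv, n_knots, knots) {
  u <- sort(unique(xv))
  if (knots == "all") return(u[-length(u)])
  if (length(u) <= n_knots) return(u[-length(u)])
  qs <- quantile(xv, probs = seq_len(n_knots) / (n_knots + 1),
                 names = FALSE, type = 7)
  unique(qs)
}

#' MARS forward pass
#'
#' Greedy expansion: each step screens every (parent term, new variable,
#' candidate knot) triple — parents of degree 2 are not extended, and a
#' variable already in the parent is not reused — and adds the reflected
#' hinge pair with the largest residual-sum-of-squares reduction, computed
#' by projecting the candidate pair onto the orthogonal complement of the
#' current basis. Stops at `max_terms` total terms or when the best relative
#' RSS improvement falls below `min_improve`.
#'
#' @param x numeric matrix of predictors (columns named).
#' @param y numeric response.
#' @param max_terms maximum number of basis terms including the intercept
#'   (default 21).
#' @param n_knots candidate knots per variable, taken at equally spaced
#'   quantiles (default 31).
#' @param knots `"quantile"` (default) or `"all"` for exhaustive candidate
#'   knots at every observed value.
#' @param min_improve forward stopping threshold on relative RSS
#'   improvement (default 1e-4).
#' @param degree maximum interaction degree (1 or 2; default 2).
#' @param penalty GCV cost per extra term beyond its coefficient
#'   (default 3).
#' @return an unpruned `mars_model`.
#' @export
mars_forward <- function(x, y, max_terms = 21, n_knots = 31,
                         knots = c("quantile", "all"), min_improve = 1e-4,
                         degree = 2, penalty = 3) {
  knots <- match.arg(knots)
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  n <- nrow(x); p <- ncol(x)
  if (!all(is.finite(x))) stop_metaboage("x must be finite")
  if (n <= max_terms) stop_metaboage("need n > max_terms")
  grids <- lapply(seq_len(p), function(j)
    mars_knot_grid(x[, j], n_knots, knots))

  terms <- list(list(vars = integer(0), knots = numeric(0),
                     dirs = numeric(0)))
  b <- matrix(1, n, 1)
  repeat {
    m <- length(terms)
    if (m + 2 > max_terms) break
    qrb <- qr(b)
    qmat <- qr.Q(qrb)
    r <- as.vector(y - qmat %*% crossprod(qmat, y))
    rss <- sum(r^2)
    if (rss <= 1e-12 * max(1, sum(y^2))) break
    best <- list(gain = 0)
    for (pi in seq_along(terms)) {
      parent <- terms[[pi]]
      if (length(parent$vars) >= degree) next
      pv <- b[, pi]
      for (v in setdiff(seq_len(p), parent$vars)) {
        g <- grids[[v]]
        if (!length(g)) next
        k <- length(g)
        h_pos <- pmax(outer(x[, v], g, "-"), 0) * pv
        h_neg <- pmax(t(outer(g, x[, v], "-")), 0) * pv
        cand <- cbind(h_pos, h_neg)
        cr <- cand - qmat %*% crossprod(qmat, cand)
        c1 <- cr[, seq_len(k), drop = FALSE]
        c2 <- cr[, k + seq_len(k), drop = FALSE]
        a11 <- colSums(c1^2); a22 <- colSums(c2^2); a12 <- colSums(c1 * c2)
        b1 <- colSums(c1 * r); b2 <- colSums(c2 * r)
        det <- a11 * a22 - a12^2
        scale2 <- pmax(a11 * a22, 1e-300)
        ok2 <- det > 1e-10 * scale2
        gain2 <- ifelse(ok2,
                        (b1^2 * a22 - 2 * b1 * b2 * a12 + b2^2 * a11) / det,
                        -Inf)
        gain1 <- pmax(ifelse(a11 > 1e-10, b1^2 / a11, -Inf),
                      ifelse(a22 > 1e-10, b2^2 / a22, -Inf))
        gain <- pmax(gain2, gain1)
        j <- which.max(gain)
        if (length(j) && gain[j] > best$gain) {
          best <- list(gain = gain[j], parent = pi, var = v, knot = g[j])
        }
      }
    }
    if (is.null(best$parent) || best$gain < min_improve * rss) break
    parent <- terms[[best$parent]]
    for (dir in c(1, -1)) {
      terms[[length(terms) + 1L]] <- list(
        vars = c(parent$vars, best$var),
        knots = c(parent$knots, best$knot),
        dirs = c(parent$dirs, dir))
    }
    newb <- cbind(mars_term_value(terms[[m + 1L]], x),
                  mars_term_value(terms[[m + 2L]], x))
    b <- cbind(b, newb)
  }
  fit <- lm.fit(b, y)
  rss <- sum(fit$residuals^2)
  coefs <- fit$coefficients
  coefs[is.na(coefs)] <- 0
  model <- list(terms = terms, coefficients = unname(coefs),
                var_names = colnames(x), n_train = n,
                rss = rss, penalty = penalty,
                gcv = mars_gcv(rss, n, length(terms), penalty),
                pruned = FALSE)
  class(model) <- "mars_model"
  model
}

#' MARS backward pruning by GCV
#'
#' From the unpruned model, repeatedly deletes the non-intercept term whose
#' removal (with ordinary least-squares refit) minimizes GCV, down to the
#' intercept-only model, and returns the minimum-GCV model along the
#' deletion path (which may be the unpruned model itself).
#'
#' @param model an unpruned `mars_model`.
#' @param x,y the training data.
#' @return the pruned `mars_model`.
#' @export
mars_prune <- function(model, x, y) {
  x <- as.matrix(x)
  n <- nrow(x)
  m0 <- length(model$terms)
  if (m0 + model$penalty * (m0 - 1) / 2 >= n)
    stop_metaboage("model is overparameterized: C(M) >= n")
  b_full <- mars_basis(model$terms, x)
  active <- seq_len(m0)
  refit <- function(cols) {
    fit <- lm.fit(b_full[, cols, drop = FALSE], y)
    sum(fit$residuals^2)
  }
  best_active <- active
  best_gcv <- mars_gcv(refit(active), n, length(active), model$penalty)
  while (length(active) > 1) {
    cand_gcv <- vapply(active[-1], function(drop_i) {
      cols <- setdiff(active, drop_i)
      mars_gcv(refit(cols), n, length(cols), model$penalty)
    }, numeric(1))
    j <- which.min(cand_gcv)
    active <- setdiff(active, active[-1][j])
    if (cand_gcv[j] < best_gcv) {
      best_gcv <- cand_gcv[j]
      best_active <- active
    }
  }
  fit <- lm.fit(b_full[, best_active, drop = FALSE], y)
  coefs <- fit$coefficients
  coefs[is.na(coefs)] <- 0
  out <- model
  out$terms <- model$terms[best_active]
  out$coefficients <- unname(coefs)
  out$rss <- sum(fit$residuals^2)
  out$gcv <- best_gcv
  out$pruned <- TRUE
  out
}

#' Fit a pruned MARS model
#'
#' Convenience wrapper: [mars_forward()] followed by [mars_prune()].
#'
#' @inheritParams mars_forward
#' @param ... passed to [mars_forward()].
#' @return a pruned `mars_model`.
#' @export
mars_fit <- function(x, y, ...) {
  mars_prune(mars_forward(x, y, ...), x, y)
}

#' @export
predict.mars_model <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  need <- unique(unlist(lapply(object$terms, `[[`, "vars")))
  if (length(need) && !is.null(colnames(x)) &&
      all(object$var_names %in% colnames(x))) {
    x <- x[, object$var_names, drop = FALSE]
  } else if (ncol(x) < max(c(need, 0))) {
    stop_metaboage("newdata lacks variables used by the model")
  }
  as.vector(mars_basis(object$terms, x) %*% object$coefficients)
}

#' MARS variable importance
#'
#' For each variable appearing in the model, all terms involving it are
#' removed, the remaining basis is refit by least squares, and the increase
#' in GCV over the full model is recorded; scores are rescaled so the
#' largest is 100. Variables absent from the model score 0.
#'
#' @param model a pruned `mars_model`.
#' @param x,y the training data.
#' @return named numeric vector over all training variables.
#' @export
mars_importance <- function(model, x, y) {
  x <- as.matrix(x)
  n <- nrow(x)
  b <- mars_basis(model$terms, x)
  used <- lapply(model$terms, `[[`, "vars")
  vars <- sort(unique(unlist(used)))
  score <- setNames(numeric(length(model$var_names)), model$var_names)
  for (v in vars) {
    keep <- which(!vapply(used, function(u) v %in% u, logical(1)))
    fit <- lm.fit(b[, keep, drop = FALSE], y)
    g <- mars_gcv(sum(fit$residuals^2), n, length(keep), model$penalty)
    score[model$var_names[v]] <- max(0, g - model$gcv)
  }
  if (max(score) > 0) score <- score / max(score) * 100
  score
}

#' Serialize / deserialize a MARS model as JSON
#'
#' Numbers are written at full double precision so the round trip is exact.
#'
#' @param model a `mars_model`.
#' @param path optional file path; if `NULL`, the JSON string is returned.
#' @return `mars_to_json`: path or JSON string; `mars_from_json`: the model.
#' @export
mars_to_json <- function(model, path = NULL) {
  # doubles as %.17g strings: decimal shortest-exact, so the parse is
  # bit-identical to the original
  num <- function(v) sprintf("%.17g", v)
  obj <- list(
    schema = "metaboage/mars_model/1",
    var_names = model$var_names,
    n_train = model$n_train, rss = num(model$rss), gcv = num(model$gcv),
    penalty = model$penalty, pruned = model$pruned,
    coefficients = num(model$coefficients),
    terms = lapply(model$terms, function(t)
      list(vars = t$vars, knots = num(t$knots), dirs = t$dirs)))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                         null = "null")
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

#' @rdname mars_to_json
#' @param json JSON string or file path produced by [mars_to_json()].
#' @export
mars_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  if (!identical(obj$schema, "metaboage/mars_model/1"))
    stop_metaboage("not a mars_model JSON document")
  num <- function(v) if (is.null(v)) numeric(0) else as.numeric(unlist(v))
  model <- list(
    terms = lapply(obj$terms, function(t)
      list(vars = as.integer(unlist(t$vars)),
           knots = num(t$knots),
           dirs = num(t$dirs))),
    coefficients = num(obj$coefficients),
    var_names = as.character(unlist(obj$var_names)),
    n_train = obj$n_train, rss = num(obj$rss), gcv = num(obj$gcv),
    penalty = obj$penalty, pruned = obj$pruned)
  class(model) <- "mars_model"
  model
}
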