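# Statistical inference: canonical correlation analysis between the clinical
# and EEG variable sets with a max-statistic permutation test, and prognostic
# stepwise regression on rank-based inverse-normal transformed outcomes.

standardize_matrix <- function(m, what) {
  m <- as.matrix(m)
  if (is.null(colnames(m))) colnames(m) <- paste0(what, seq_len(ncol(m)))
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0))
    stop_eegprog("constant column(s) in %s: %s", what,
                 paste(colnames(m)[sds == 0], collapse = ", "),
                 class = "eegprog_invalid")
  scale(m)
}

# canonical correlations only (fast path for permutations)
cc_correlations <- function(xs, ys) {
  qx <- qr(xs); qy <- qr(ys)
  if (qx$rank < ncol(xs) || qy$rank < ncol(ys)) return(NULL)
  d <- svd(crossprod(qr.Q(qx), qr.Q(qy)),
           nu = 0, nv = 0)$d
  pmin(pmax(d, 0), 1)
}

#' Canonical correlation analysis of two variable sets
#'
#' Columns are standardized to zero mean and unit variance; canonical
#' weights come from the QR/SVD solution. Variates are scaled to unit
#' sample variance. Requires `n > max(p, q) + 1` and full-rank sets.
#'
#' @param x_set,y_set numeric matrices/data frames, subjects x variables.
#' @return object of class `cca_result`: `canonical_correlations`
#'   (descending), `x_weights`, `y_weights`, `x_variates`, `y_variates`,
#'   `n`; `p_values` and `loadings` are filled in by
#'   [permutation_test_cca()] and [variate_loadings()].
#' @export
fit_cca <- function(x_set, y_set) {
  xs <- standardize_matrix(x_set, "x_set")
  ys <- standardize_matrix(y_set, "y_set")
  n <- nrow(xs)
  if (nrow(ys) != n)
    stop_eegprog("x_set and y_set must have the same rows", class = "eegprog_invalid")
  if (n <= max(ncol(xs), ncol(ys)) + 1)
    stop_eegprog("need n > max(p, q) + 1 (n = %d, p = %d, q = %d)",
                 n, ncol(xs), ncol(ys), class = "eegprog_invalid")
  qx <- qr(xs); qy <- qr(ys)
  if (qx$rank < ncol(xs) || qy$rank < ncol(ys)) {
    bad <- function(qq, m) colnames(m)[qq$pivot[-seq_len(qq$rank)]]
    stop_eegprog("rank-deficient set; collinear column(s): %s",
                 paste(c(bad(qx, xs), bad(qy, ys)), collapse = ", "),
                 class = "eegprog_collinear")
  }
  k <- min(ncol(xs), ncol(ys))
  sv <- svd(crossprod(qr.Q(qx), qr.Q(qy)))
  rho <- pmin(pmax(sv$d[seq_len(k)], 0), 1)
  # weights on the standardized scale; variates have unit sample variance
  a <- backsolve(qr.R(qx), sv$u[, seq_len(k), drop = FALSE]) * sqrt(n - 1)
  b <- backsolve(qr.R(qy), sv$v[, seq_len(k), drop = FALSE]) * sqrt(n - 1)
  # undo any QR column pivoting
  a[qx$pivot, ] <- a; b[qy$pivot, ] <- b
  rownames(a) <- colnames(xs); rownames(b) <- colnames(ys)
  structure(list(canonical_correlations = rho,
                 x_weights = a, y_weights = b,
                 x_variates = xs %*% a, y_variates = ys %*% b,
                 n = n, p_values = NULL, loadings = NULL),
            class = "cca_result")
}

#' @export
print.cca_result <- function(x, ...) {
  cat("<cca_result> canonical correlations:",
      paste(sprintf("%.3f", x$canonical_correlations), collapse = ", "), "\n")
  if (!is.null(x$p_values))
    cat("  permutation p-values:",
        paste(sprintf("%.3f", x$p_values), collapse = ", "), "\n")
  invisible(x)
}

#' Max-statistic permutation test for CCA
#'
#' The rows of `x_set` are shuffled relative to `y_set` `n_perm` times; each
#' shuffle records the largest canonical correlation. The p-value of
#' observed pair `i` is the plain proportion of null maxima exceeding the
#' observed correlation (strict `>`), so p-values are non-decreasing across
#' variate pairs.
#'
#' @inheritParams fit_cca
#' @param n_perm number of permutations (default 2000).
#' @param seed integer RNG seed.
#' @return a `cca_result` with `p_values` and `null_max` attached.
#' @export
permutation_test_cca <- function(x_set, y_set, n_perm = 2000, seed = 1L) {
  res <- fit_cca(x_set, y_set)
  xs <- standardize_matrix(x_set, "x_set")
  ys <- standardize_matrix(y_set, "y_set")
  n <- nrow(xs)
  null_max <- with_seed(seed, {
    vapply(seq_len(n_perm), function(p) {
      d <- cc_correlations(xs[sample.int(n), , drop = FALSE], ys)
      if (is.null(d)) NA_real_ else max(d)
    }, numeric(1))
  })
  null_max <- null_max[!is.na(null_max)]
  res$p_values <- vapply(res$canonical_correlations,
                         function(r) mean(null_max > r), numeric(1))
  res$null_max <- null_max
  res$n_perm <- n_perm
  res
}

#' Structure loadings of the canonical variates
#'
#' Pearson correlation (with two-tailed p-value) of every original variable
#' with the *opposite* set's first canonical variate.
#'
#' @param res a fitted `cca_result`.
#' @param x_set,y_set the original variable sets.
#' @return list with data frames `x` (x variables vs first y variate) and
#'   `y` (y variables vs first x variate).
#' @export
variate_loadings <- function(res, x_set, y_set) {
  against <- function(m, variate) {
    m <- as.matrix(m)
    do.call(rbind, lapply(seq_len(ncol(m)), function(j) {
      ct <- stats::cor.test(m[, j], variate)
      data.frame(variable = colnames(m)[j], loading = unname(ct$estimate),
                 p_value = ct$p.value, stringsAsFactors = FALSE)
    }))
  }
  list(x = against(x_set, res$y_variates[, 1]),
       y = against(y_set, res$x_variates[, 1]))
}

#' Rank-based inverse normal (inverse Gaussian) transform
#'
#' Maps values to normal quantiles of their (tie-averaged) ranks:
#' `z_i = qnorm((r_i - c) / (n - 2c + 1))` with the Blom constant
#' `c = 3/8` by default.
#'
#' @param values numeric vector, `n >= 2`, no missing values.
#' @param offset rank offset constant (default Blom's 3/8).
#' @return numeric vector, strictly monotone in the input ranks.
#' @export
rank_inverse_normal <- function(values, offset = 3 / 8) {
  if (anyNA(values))
    stop_eegprog("missing values not allowed", class = "eegprog_invalid")
  n <- length(values)
  if (n < 2)
    stop_eegprog("need n >= 2", class = "eegprog_invalid")
  if (length(unique(values)) == 1)
    stop_eegprog("all values equal: no ordering information", class = "eegprog_invalid")
  r <- rank(values, ties.method = "average")
  stats::qnorm((r - offset) / (n - 2 * offset + 1))
}

#' Stepwise linear regression with p-value entry/removal
#'
#' Forward step: among candidates not in the model, add the one with the
#' smallest partial-F p-value if it is at most `entry_p`. Backward step:
#' drop any retained predictor whose p-value is at least `removal_p`
#' (largest first). Iterate until no change. Cases with missing outcome or
#' predictors are removed listwise (and logged). Standardized betas are the
#' coefficients on z-scored outcome and predictors.
#'
#' @param y numeric outcome (already transformed as desired).
#' @param candidates data frame of candidate predictor columns.
#' @param entry_p entry threshold (default 0.05).
#' @param removal_p removal threshold (default 0.10).
#' @return object of class `stepwise_result`: `selected` (entry order),
#'   `beta` (standardized), `beta_raw`, `p_values`, `r_squared`,
#'   `adj_r_squared`, `f_statistic`, `df`, `model_p`, `steps` (log),
#'   `n_used`, `dropped_cases`, `empty` flag; the model frame is kept for
#'   [r2_change()].
#' @export
stepwise_regression <- function(y, candidates, entry_p = 0.05, removal_p = 0.10) {
  candidates <- as.data.frame(candidates)
  ok <- stats::complete.cases(cbind(y, candidates))
  dropped <- which(!ok)
  y <- y[ok]
  X <- candidates[ok, , drop = FALSE]
  n <- length(y)
  steps <- character(0)
  if (length(dropped))
    steps <- sprintf("listwise deletion removed %d case(s): %s",
                     length(dropped), paste(dropped, collapse = ", "))
  fit_p <- function(vars) {
    f <- stats::lm(stats::reformulate(vars, response = "y"),
                   data = cbind(y = y, X))
    coefs <- summary(f)$coefficients
    list(fit = f, p = coefs[vars, 4])
  }
  current <- character(0)
  repeat {
    changed <- FALSE
    pool <- setdiff(names(X), current)
    if (length(pool) && n > length(current) + 2) {
      p_in <- vapply(pool, function(v) {
        cf <- summary(stats::lm(stats::reformulate(c(current, v), response = "y"),
                                data = cbind(y = y, X)))$coefficients
        cf[v, 4]
      }, numeric(1))
      if (min(p_in) <= entry_p) {
        add <- pool[which.min(p_in)]
        current <- c(current, add)
        steps <- c(steps, sprintf("enter %s (p = %.4g)", add, min(p_in)))
        changed <- TRUE
      }
    }
    while (length(current)) {
      p_cur <- fit_p(current)$p
      if (max(p_cur) >= removal_p) {
        drop <- names(which.max(p_cur))
        steps <- c(steps, sprintf("remove %s (p = %.4g)", drop, max(p_cur)))
        current <- setdiff(current, drop)
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  if (!length(current)) {
    return(structure(list(selected = character(0), beta = numeric(0),
                          beta_raw = numeric(0), p_values = numeric(0),
                          r_squared = 0, adj_r_squared = 0,
                          f_statistic = NA_real_, df = c(NA, NA),
                          model_p = NA_real_, steps = steps, n_used = n,
                          dropped_cases = dropped, empty = TRUE,
                          data = cbind(y = y, X)),
                     class = "stepwise_result"))
  }
  raw <- stats::lm(stats::reformulate(current, response = "y"),
                   data = cbind(y = y, X))
  Xz <- as.data.frame(lapply(X[current], function(v) as.numeric(scale(v))))
  names(Xz) <- current
  std <- stats::lm(stats::reformulate(current, response = "y"),
                   data = cbind(y = as.numeric(scale(y)), Xz))
  s_raw <- summary(raw)
  fstat <- s_raw$fstatistic
  structure(list(selected = current,
                 beta = stats::coef(std)[current],
                 beta_raw = stats::coef(raw)[current],
                 p_values = s_raw$coefficients[current, 4],
                 r_squared = s_raw$r.squared,
                 adj_r_squared = s_raw$adj.r.squared,
                 f_statistic = unname(fstat[1]),
                 df = unname(fstat[2:3]),
                 model_p = unname(stats::pf(fstat[1], fstat[2], fstat[3],
                                            lower.tail = FALSE)),
                 steps = steps, n_used = n, dropped_cases = dropped,
                 empty = FALSE, data = cbind(y = y, X)),
            class = "stepwise_result")
}

#' @export
print.stepwise_result <- function(x, ...) {
  if (x$empty) {
    cat("<stepwise_result> no predictor entered the model\n")
    return(invisible(x))
  }
  cat(sprintf("<stepwise_result> n = %d; adjusted R^2 = %.3f; F(%d,%d) = %.3f, p = %.4g\n",
              x$n_used, x$adj_r_squared, x$df[1], x$df[2], x$f_statistic, x$model_p))
  for (v in x$selected)
    cat(sprintf("  %s: beta = %.3f, p = %.4g\n", v, x$beta[v], x$p_values[v]))
  invisible(x)
}

#' R-squared change between a stepwise model and a nested reduction
#'
#' Both models are refit on the identical case set kept by the stepwise fit.
#'
#' @param full a `stepwise_result`.
#' @param reduced character vector, a subset of `full$selected` (possibly
#'   empty).
#' @return scalar `R^2(full) - R^2(reduced)`.
#' @export
r2_change <- function(full, reduced) {
  if (!all(reduced %in% full$selected))
    stop_eegprog("reduced set is not nested in the full model (%s)",
                 paste(setdiff(reduced, full$selected), collapse = ", "),
                 class = "eegprog_invalid")
  r2_of <- function(vars) {
    if (!length(vars)) return(0)
    f <- stats::lm(stats::reformulate(vars, response = "y"),
                   data = as.data.frame(full$data))
    summary(f)$r.squared
  }
  r2_of(full$selected) - r2_of(reduced)
}
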