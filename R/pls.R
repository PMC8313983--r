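#' Autoscale predictors and the coded class response
#'
#' Centres every predictor column to mean 0 and scales it to sample (n-1)
#' standard deviation 1; the -1/+1 coded response is treated the same way.
#' The transform is recorded so that predictions and inversion solutions can
#' be mapped back to raw variable units and coding units.
#'
#' @param data A [pls_data] object.
#' @return A list with `X` (scaled matrix), `y` (scaled coded response) and
#'   `scaling`, a `plscm_scaling` object holding `x_means`, `x_sds`,
#'   `y_mean`, `y_sd`.
#' @export
autoscale <- function(data) {
  stopifnot(inherits(data, "plscm_data"))
  x <- data$values
  mu <- colMeans(x)
  sd_ <- apply(x, 2L, stats::sd)
  if (any(sd_ <= 0)) {
    stop("constant column(s): ", paste(colnames(x)[sd_ <= 0], collapse = ", "))
  }
  y <- class_coding(data)
  ym <- mean(y); ys <- stats::sd(y)
  if (ys <= 0) stop("coded response is constant; both classes must be present")
  scaling <- structure(
    list(x_means = mu, x_sds = sd_, y_mean = ym, y_sd = ys),
    class = "plscm_scaling")
  list(X = scale_x(scaling, x), y = (y - ym) / ys, scaling = scaling)
}

#' Apply or invert the recorded autoscaling
#'
#' @param scaling A `plscm_scaling` object from [autoscale].
#' @param x Raw (for `scale_x`) or scaled (for `unscale_x`) matrix or
#'   p-vector.
#' @return Matrix (or vector) on the other scale.
#' @export
scale_x <- function(scaling, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  sweep(sweep(x, 2L, scaling$x_means, "-"), 2L, scaling$x_sds, "/")
}

#' @rdname scale_x
#' @export
unscale_x <- function(scaling, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  sweep(sweep(x, 2L, scaling$x_sds, "*"), 2L, scaling$x_means, "+")
}

#' Fit a PLS1 model by NIPALS on pre-scaled data
#'
#' One-response NIPALS with deflation of X. Besides the weights W, loadings
#' P and y-loadings Q of the factorization, the applied weights
#' R = W (P'W)^-1 are stored: scores of new data are X R, so that
#' predictions are X R Q' and the identity R'P = I underpins the algebraic
#' inversion (mapping boundary scores back through P' and returning to the
#' same prediction).
#'
#' @param X Centred/scaled predictor matrix (n x p).
#' @param y Centred/scaled response vector (length n).
#' @param a Number of latent variables, 1 <= a <= min(n - 1, p).
#' @return A `plscm_pls` list: `W`, `P` (p x a), `Q` (1 x a row vector), `R`
#'   (p x a applied weights), `T` (n x a scores), `n_lv`, `explained_var_x`,
#'   `explained_var_y`.
#' @export
fit_pls1 <- function(X, y, a) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("response length does not match rows of X")
  if (any(!is.finite(X)) || any(!is.finite(y))) stop("non-finite values in input")
  a <- as.integer(a)
  if (a < 1L || a > min(n - 1L, p)) {
    stop("number of latent variables must be in [1, ", min(n - 1L, p), "], got ", a)
  }
  ssx <- sum(X^2); ssy <- sum(y^2)
  E <- X; f <- y
  W <- P <- matrix(0, p, a)
  Tm <- matrix(0, n, a)
  q <- numeric(a)
  for (k in seq_len(a)) {
    w <- drop(crossprod(E, f))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12 * max(1, sqrt(ssx) * sqrt(ssy))) {
      stop("X deflated to numerical rank ", k - 1L,
           ": cannot extract latent variable ", k)
    }
    w <- w / nw
    t_ <- drop(E %*% w)
    tt <- sum(t_^2)
    if (tt < 1e-24) stop("degenerate score vector at latent variable ", k)
    p_ <- drop(crossprod(E, t_)) / tt
    q[k] <- sum(f * t_) / tt
    E <- E - tcrossprod(t_, p_)
    f <- f - q[k] * t_
    W[, k] <- w; P[, k] <- p_; Tm[, k] <- t_
  }
  R <- W %*% solve(crossprod(P, W))
  structure(
    list(W = W, P = P, Q = matrix(q, 1L, a), R = R, T = Tm, n_lv = a,
         explained_var_x = 1 - sum(E^2) / ssx,
         explained_var_y = 1 - sum(f^2) / ssy),
    class = "plscm_pls")
}

#' Fit a PLS-CM model with iterative outlier removal
#'
#' Fits the PLS1 model on autoscaled predictors against the -1/+1 coded
#' class, computes Hotelling T2 and Q-residual limits at `confidence`, and
#' iterates: rows that exceed BOTH limits are removed and the model (and the
#' autoscaling) is rebuilt, until no row is flagged or `max_iter` passes.
#'
#' @param data A [pls_data] object.
#' @param a Number of latent variables.
#' @param confidence Confidence level of the T2 and Q limits (default 0.95).
#' @param remove_outliers If FALSE, a single fit with no removal.
#' @param max_iter Maximum refit iterations (default 10).
#' @return A `plscm_model` object: the `plscm_pls` matrices plus `scaling`,
#'   `score_variances`, `residual_eigenvalues`, `t2_limit`, `q_limit`,
#'   `confidence`, `removed_rows` (indices into the original data),
#'   `n_retained`, `domain_ranges`, class labels and explained-variance
#'   fractions.
#' @export
fit_with_outlier_removal <- function(data, a, confidence = 0.95,
                                     remove_outliers = TRUE, max_iter = 10L) {
  stopifnot(inherits(data, "plscm_data"))
  keep <- seq_len(nrow(data$values))
  removed <- integer(0)
  for (iter in seq_len(max_iter + 1L)) {
    if (length(keep) < a + 2L) {
      stop("only ", length(keep), " rows retained; need at least ", a + 2L)
    }
    sub <- pls_data(data$values[keep, , drop = FALSE], data$class_labels[keep],
                    positive = data$positive)
    sc <- autoscale(sub)
    fit <- fit_pls1(sc$X, sc$y, a)
    model <- finalize_model(fit, sc, sub, confidence, removed)
    if (!remove_outliers || iter > max_iter) break
    t2 <- apply(fit$T, 1L, function(t_) t2_statistic(model, t_))
    qres <- apply(sc$X, 1L, function(x_) q_statistic(model, x_))
    flag <- t2 > model$t2_limit & qres > model$q_limit
    if (!any(flag)) break
    both <- table(sub$class_labels[!flag])
    if (length(both) < 2L) {
      stop("outlier removal would eliminate class '",
           setdiff(c(sub$negative, sub$positive), names(both)), "' entirely")
    }
    message("removing ", sum(flag), " outlier row(s): ",
            paste(keep[flag], collapse = ", "))
    removed <- c(removed, keep[flag])
    keep <- keep[!flag]
  }
  model
}

# Assemble the full model object from a raw fit plus scaling and limits.
finalize_model <- function(fit, sc, sub, confidence, removed) {
  q0 <- abs(fit$Q[1L, ]) < 1e-12
  if (any(q0)) {
    warning("dropping latent variable(s) ", paste(which(q0), collapse = ", "),
            " with zero y-loading; boundary normal undefined for them")
    keepk <- which(!q0)
    if (!length(keepk)) stop("all y-loadings are zero; no class signal")
    fit$W <- fit$W[, keepk, drop = FALSE]
    fit$P <- fit$P[, keepk, drop = FALSE]
    fit$Q <- fit$Q[, keepk, drop = FALSE]
    fit$T <- fit$T[, keepk, drop = FALSE]
    fit$R <- fit$W %*% solve(crossprod(fit$P, fit$W))
    fit$n_lv <- length(keepk)
  }
  n <- nrow(fit$T)
  resid <- sc$X - tcrossprod(fit$T, fit$P)
  ev <- eigen(crossprod(resid) / (n - 1L), symmetric = TRUE, only.values = TRUE)$values
  ev <- ev[ev > max(ev[1L], 0) * 1e-12]
  model <- structure(
    c(fit,
      list(X_scaled = sc$X,
           scaling = sc$scaling,
           score_variances = apply(fit$T, 2L, stats::var),
           residual_eigenvalues = ev,
           n_retained = n,
           confidence = confidence,
           removed_rows = removed,
           domain_ranges = sub$domain_ranges,
           column_names = sub$column_names,
           positive = sub$positive, negative = sub$negative,
           r2_cv = NA_real_)),
    class = c("plscm_model", "plscm_pls"))
  model$t2_limit <- t2_limit(model, confidence)
  model$q_limit <- q_limit(model, confidence)
  model
}

#' @export
print.plscm_model <- function(x, ...) {
  cat("PLS-CM model:", x$n_lv, "latent variable(s),",
      x$n_retained, "training objects (", length(x$removed_rows), "removed )\n")
  cat(sprintf("  explained variance: %.2f%% in X, %.2f%% in y\n",
              100 * x$explained_var_x, 100 * x$explained_var_y))
  if (!is.na(x$r2_cv)) cat(sprintf("  R2cv: %.2f%%\n", 100 * x$r2_cv))
  cat(sprintf("  PLSbox at %.0f%%: T2 <= %.3f, Q <= %.4g\n",
              100 * x$confidence, x$t2_limit, x$q_limit))
  invisible(x)
}

#' Predict the coded class response
#'
#' @param object A `plscm_model`.
#' @param newdata Raw p-vector or n x p matrix (original variable units).
#' @param ... Unused.
#' @return Predicted response(s) in coding units (spreading around -1
#'   and +1 for well-separated classes).
#' @export
predict.plscm_model <- function(object, newdata, ...) {
  xs <- scale_x(object$scaling, check_dim(object, newdata))
  yhat <- drop(xs %*% object$R %*% t(object$Q))
  yhat * object$scaling$y_sd + object$scaling$y_mean
}

check_dim <- function(model, x) {
  x <- if (is.null(dim(x))) matrix(x, nrow = 1L) else as.matrix(x)
  if (ncol(x) != nrow(model$R)) {
    stop("expected ", nrow(model$R), " variables, got ", ncol(x))
  }
  if (any(!is.finite(x))) stop("non-finite values in newdata")
  x
}

#' Hotelling T2 statistic and its confidence limit
#'
#' T2 of a score vector is the sum of squared scores standardized by the
#' training score variances. The limit is the usual F-based one,
#' a (n^2 - 1) / (n (n - a)) * F(a, n - a; confidence).
#'
#' @param model A `plscm_model`.
#' @param t Score a-vector.
#' @param confidence Confidence level in (0, 1).
#' @return A scalar.
#' @export
t2_statistic <- function(model, t) {
  if (any(model$score_variances <= 0)) stop("zero score variance")
  sum(t^2 / model$score_variances)
}

#' @rdname t2_statistic
#' @export
t2_limit <- function(model, confidence = model$confidence) {
  a <- model$n_lv; n <- model$n_retained
  a * (n^2 - 1) / (n * (n - a)) * stats::qf(confidence, a, n - a)
}

#' Q-residual statistic and its confidence limit
#'
#' Q is the squared norm of the part of a scaled object not reconstructed by
#' the latent variables. The limit uses the Jackson-Mudholkar approximation
#' from the residual eigenvalues, falling back to moment-matching on a
#' scaled chi-square when fewer than two residual eigenvalues remain; with
#' a = p the residual subspace is empty and the limit is 0.
#'
#' @param model A `plscm_model`.
#' @param x_scaled Autoscaled p-vector.
#' @param confidence Confidence level in (0, 1).
#' @return A scalar.
#' @export
q_statistic <- function(model, x_scaled) {
  x_scaled <- as.numeric(x_scaled)
  t_ <- drop(x_scaled %*% model$R)
  sum((x_scaled - drop(model$P %*% t_))^2)
}

#' @rdname q_statistic
#' @export
q_limit <- function(model, confidence = model$confidence) {
  ev <- model$residual_eigenvalues
  if (length(ev) == 0L) return(0)
  th1 <- sum(ev); th2 <- sum(ev^2); th3 <- sum(ev^3)
  if (length(ev) >= 2L) {
    h0 <- 1 - 2 * th1 * th3 / (3 * th2^2)
    if (is.finite(h0) && h0 != 0) {
      z <- stats::qnorm(confidence)
      lim <- th1 * (z * sqrt(2 * th2 * h0^2) / th1 +
                      1 + th2 * h0 * (h0 - 1) / th1^2)^(1 / h0)
      if (is.finite(lim) && lim > 0) return(lim)
    }
  }
  g <- th2 / th1; h <- th1^2 / th2
  g * stats::qchisq(confidence, h)
}

#' Crossvalidated choice of the number of latent variables
#'
#' Computes R2cv(a) = 1 - PRESS(a) / TSS on the coded response for
#' a = 1..a_max, refitting the autoscaling inside every fold, and selects
#' the smallest a whose R2cv is within `eps_cv` of the maximum (set
#' `rule = "max"` for the plain argmax).
#'
#' @param data A [pls_data] object.
#' @param a_max Largest number of latent variables to try.
#' @param scheme `"leave_one_out"` or `"venetian_blinds"` (every k-th row in
#'   the same split, one sample per blind).
#' @param k_splits Number of venetian-blind splits (default 10).
#' @param eps_cv Tolerance on R2cv for the parsimony rule (default 0.01).
#' @param rule `"parsimonious"` (default) or `"max"`.
#' @return A list with `table` (data frame of a, r2_cv) and `selected`.
#' @export
cross_validate <- function(data, a_max,
                           scheme = c("leave_one_out", "venetian_blinds"),
                           k_splits = 10L, eps_cv = 0.01,
                           rule = c("parsimonious", "max")) {
  stopifnot(inherits(data, "plscm_data"))
  scheme <- match.arg(scheme)
  rule <- match.arg(rule)
  n <- nrow(data$values)
  p <- ncol(data$values)
  if (a_max > min(n - 2L, p)) {
    stop("a_max must not exceed min(n - 2, p) = ", min(n - 2L, p))
  }
  folds <- if (scheme == "leave_one_out") {
    as.list(seq_len(n))
  } else {
    if (k_splits > n) stop("k_splits must not exceed n")
    split(seq_len(n), rep_len(seq_len(k_splits), n))
  }
  y <- class_coding(data)
  press <- numeric(a_max)
  ok <- FALSE
  for (fold in folds) {
    train <- setdiff(seq_len(n), fold)
    sub <- try(pls_data(data$values[train, , drop = FALSE],
                        data$class_labels[train], positive = data$positive),
               silent = TRUE)
    if (inherits(sub, "try-error")) next
    sc <- try(autoscale(sub), silent = TRUE)
    if (inherits(sc, "try-error")) next
    xs <- scale_x(sc$scaling, data$values[fold, , drop = FALSE])
    # if the fold is rank-deficient below a_max, use as many LVs as it supports
    fit <- NULL
    for (a_try in rev(seq_len(a_max))) {
      fit <- try(fit_pls1(sc$X, sc$y, a_try), silent = TRUE)
      if (!inherits(fit, "try-error")) break
    }
    if (inherits(fit, "try-error")) next
    ok <- TRUE
    for (a in seq_len(a_max)) {
      aa <- min(a, fit$n_lv)
      Ra <- fit$W[, 1:aa, drop = FALSE] %*%
        solve(crossprod(fit$P[, 1:aa, drop = FALSE], fit$W[, 1:aa, drop = FALSE]))
      yh <- drop(xs %*% Ra %*% t(fit$Q[, 1:aa, drop = FALSE])) *
        sc$scaling$y_sd + sc$scaling$y_mean
      press[a] <- press[a] + sum((y[fold] - yh)^2)
    }
  }
  if (!ok) stop("every crossvalidation fold was degenerate")
  r2 <- 1 - press / sum((y - mean(y))^2)
  selected <- if (rule == "max") which.max(r2) else {
    min(which(r2 >= max(r2) - eps_cv))
  }
  list(table = data.frame(a = seq_len(a_max), r2_cv = r2),
       selected = as.integer(selected))
}

#' Fit the full PLS-CM pipeline
#'
#' Convenience wrapper: choose the number of latent variables by
#' crossvalidation (unless given), then fit with iterative outlier removal.
#'
#' @param data A [pls_data] object.
#' @param n_lv Number of latent variables; `NULL` selects by [cross_validate].
#' @param a_max Upper bound for the crossvalidation search.
#' @param confidence PLSbox confidence (default 0.95).
#' @param ... Passed to [cross_validate].
#' @return A `plscm_model` with `r2_cv` filled in when CV was run.
#' @export
fit_plscm <- function(data, n_lv = NULL,
                      a_max = min(nrow(data$values) - 2L, ncol(data$values)),
                      confidence = 0.95, ...) {
  r2 <- NA_real_
  if (is.null(n_lv)) {
    cv <- cross_validate(data, a_max, ...)
    n_lv <- cv$selected
    r2 <- cv$table$r2_cv[n_lv]
  }
  model <- fit_with_outlier_removal(data, n_lv, confidence)
  model$r2_cv <- r2
  model
}
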