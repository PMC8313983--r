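#' Class distributions for predicted responses
#'
#' PLS-CM models each class by the probability law of its predicted
#' responses. Three families are supported: normal, triangular (often the
#' better fit for strongly skewed prediction clouds near the coding limits)
#' and the four-parameter beta (a beta law rescaled to an arbitrary bounded
#' support).
#'
#' @param mean,sd Normal parameters, `sd > 0`.
#' @param lower,mode,upper Triangular parameters with
#'   `lower <= mode <= upper` and `lower < upper`.
#' @param shape1,shape2 Positive beta shapes.
#' @return An object of class `plscm_dist` with fields `family`, `params`,
#'   `support` and (after fitting) `fit_report`.
#' @name class_distribution
NULL

#' @rdname class_distribution
#' @export
dist_normal <- function(mean, sd) {
  if (sd <= 0) stop("sd must be strictly positive")
  new_dist("normal", list(mean = mean, sd = sd),
           support = c(-Inf, Inf))
}

#' @rdname class_distribution
#' @export
dist_triangular <- function(lower, mode, upper) {
  if (!(lower <= mode && mode <= upper && lower < upper)) {
    stop("triangular requires lower <= mode <= upper and lower < upper")
  }
  new_dist("triangular", list(lower = lower, mode = mode, upper = upper),
           support = c(lower, upper))
}

#' @rdname class_distribution
#' @export
dist_beta4 <- function(shape1, shape2, lower, upper) {
  if (shape1 <= 0 || shape2 <= 0) stop("beta shapes must be positive")
  if (lower >= upper) stop("lower must be below upper")
  new_dist("beta4", list(shape1 = shape1, shape2 = shape2,
                         lower = lower, upper = upper),
           support = c(lower, upper))
}

new_dist <- function(family, params, support, fit_report = NULL) {
  structure(list(family = family, params = params, support = support,
                 fit_report = fit_report),
            class = "plscm_dist")
}

#' @export
print.plscm_dist <- function(x, ...) {
  cat("Class distribution:", x$family, "(",
      paste(names(x$params), signif(unlist(x$params), 4),
            sep = " = ", collapse = ", "), ")\n")
  if (!is.null(x$fit_report)) {
    cat("  normality battery min p =",
        signif(min(x$fit_report$normality$p_value), 3), "\n")
  }
  invisible(x)
}

#' Distribution function, quantile function, density and sampling
#'
#' `dist_cdf` clamps to 0/1 outside a bounded support; `dist_quantile`
#' requires probabilities strictly inside (0, 1) (the triangular and beta4
#' quantiles hit their support ends at 0 and 1, but the normal has none).
#'
#' @param dist A `plscm_dist` object.
#' @param x Numeric vector of evaluation points.
#' @param q Probabilities in (0, 1).
#' @param n Number of draws.
#' @return Numeric vector.
#' @export
dist_cdf <- function(dist, x) {
  p <- dist$params
  switch(dist$family,
    normal = stats::pnorm(x, p$mean, p$sd),
    triangular = {
      a <- p$lower; c_ <- p$mode; b <- p$upper
      out <- numeric(length(x))
      lo <- x <= c_ & x > a
      hi <- x > c_ & x < b
      if (c_ > a) out[lo] <- (x[lo] - a)^2 / ((b - a) * (c_ - a))
      if (c_ < b) out[hi] <- 1 - (b - x[hi])^2 / ((b - a) * (b - c_))
      out[x >= b] <- 1
      out[x <= a] <- 0
      out
    },
    beta4 = stats::pbeta(pmin(pmax((x - p$lower) / (p$upper - p$lower), 0), 1),
                         p$shape1, p$shape2),
    stop("unknown family ", dist$family))
}

#' @rdname dist_cdf
#' @export
dist_quantile <- function(dist, q) {
  if (any(q <= 0 | q >= 1)) stop("quantile probabilities must lie strictly in (0, 1)")
  p <- dist$params
  switch(dist$family,
    normal = stats::qnorm(q, p$mean, p$sd),
    triangular = {
      a <- p$lower; c_ <- p$mode; b <- p$upper
      fc <- if (c_ > a) (c_ - a) / (b - a) else 0
      ifelse(q <= fc,
             a + sqrt(q * (b - a) * (c_ - a)),
             b - sqrt((1 - q) * (b - a) * (b - c_)))
    },
    beta4 = p$lower + (p$upper - p$lower) * stats::qbeta(q, p$shape1, p$shape2),
    stop("unknown family ", dist$family))
}

#' @rdname dist_cdf
#' @export
dist_density <- function(dist, x) {
  p <- dist$params
  switch(dist$family,
    normal = stats::dnorm(x, p$mean, p$sd),
    triangular = {
      a <- p$lower; c_ <- p$mode; b <- p$upper
      out <- numeric(length(x))
      lo <- x >= a & x <= c_ & c_ > a
      hi <- x > c_ & x <= b & c_ < b
      out[lo] <- 2 * (x[lo] - a) / ((b - a) * (c_ - a))
      out[hi] <- 2 * (b - x[hi]) / ((b - a) * (b - c_))
      if (c_ == a) out[x == a] <- 2 / (b - a)
      out
    },
    beta4 = stats::dbeta((x - p$lower) / (p$upper - p$lower),
                         p$shape1, p$shape2) / (p$upper - p$lower),
    stop("unknown family ", dist$family))
}

#' @rdname dist_cdf
#' @export
dist_random <- function(dist, n) {
  dist_quantile(dist, stats::runif(n))
}

# Effective bracketing interval for root finding on CDFs.
dist_bracket <- function(dist) {
  if (dist$family == "normal") {
    dist$params$mean + c(-12, 12) * dist$params$sd
  } else {
    dist$support
  }
}

#' D'Agostino K-squared omnibus normality test
#'
#' Combines the transformed sample skewness and kurtosis into a statistic
#' that is approximately chi-square with 2 degrees of freedom under
#' normality.
#'
#' @param x Numeric sample, n >= 8.
#' @return List with `statistic` and `p_value`.
#' @export
dagostino_k2 <- function(x) {
  n <- length(x)
  if (n < 8L) stop("D'Agostino's test needs at least 8 observations")
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  # skewness component
  b1 <- m3 / m2^1.5
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(w2))
  alpha <- sqrt(2 / (w2 - 1))
  ya <- y / alpha
  z1 <- delta * log(ya + sqrt(ya^2 + 1))
  # kurtosis component
  b2 <- m4 / m2^2
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xx <- (b2 - eb2) / sqrt(vb2)
  sb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  aa <- 6 + 8 / sb1 * (2 / sb1 + sqrt(1 + 4 / sb1^2))
  denom <- 1 + xx * sqrt(2 / (aa - 4))
  term2 <- sign(denom) * abs((1 - 2 / aa) / abs(denom))^(1 / 3)
  z2 <- ((1 - 2 / (9 * aa)) - term2) / sqrt(2 / (9 * aa))
  k2 <- z1^2 + z2^2
  list(statistic = k2, p_value = stats::pchisq(k2, 2, lower.tail = FALSE))
}

#' Fit a probability distribution to one class's predicted responses
#'
#' Runs a normality battery (Shapiro-Wilk, Anderson-Darling, D'Agostino
#' K-squared). If the smallest p-value is at least `p_threshold` the normal
#' with maximum-likelihood parameters is returned; otherwise a triangular
#' and a four-parameter beta distribution are fitted by maximum likelihood
#' and the family with the larger log-likelihood wins (ties favour the
#' triangular, which has one parameter fewer).
#'
#' @param preds Numeric vector of predicted responses for one class. At
#'   least 8 values are needed to run the battery; with 4-7 values a plain
#'   normal ML fit is returned with a warning.
#' @param p_threshold Battery acceptance level (default 0.10): normality is
#'   retained when no test rejects below it.
#' @param support `"expanded"` (default) anchors the triangular/beta4
#'   support at the sample range widened by `expand` of the span on each
#'   side; `"sample"` uses the exact sample range.
#' @param expand Relative widening of the support (default 0.01).
#' @return A `plscm_dist` whose `fit_report` holds the battery p-values and
#'   the per-family log-likelihoods considered.
#' @export
fit_predicted_distribution <- function(preds, p_threshold = 0.10,
                                       support = c("expanded", "sample"),
                                       expand = 0.01) {
  support <- match.arg(support)
  preds <- as.numeric(preds)
  if (length(preds) < 4L) stop("need at least 4 predicted responses")
  if (diff(range(preds)) <= 0) stop("degenerate predictions: all values equal")
  mle_normal <- dist_normal(mean(preds), sqrt(mean((preds - mean(preds))^2)))
  if (length(preds) < 8L) {
    warning("fewer than 8 values: returning a normal ML fit without normality testing")
    mle_normal$fit_report <- list(normality = NULL, logliks = NULL)
    return(mle_normal)
  }
  battery <- data.frame(
    test = c("shapiro_wilk", "anderson_darling", "dagostino_k2"),
    p_value = c(stats::shapiro.test(preds)$p.value,
                nortest::ad.test(preds)$p.value,
                dagostino_k2(preds)$p_value))
  if (min(battery$p_value) >= p_threshold) {
    mle_normal$fit_report <- list(
      normality = battery,
      logliks = c(normal = sum(stats::dnorm(preds, mle_normal$params$mean,
                                            mle_normal$params$sd, log = TRUE))))
    return(mle_normal)
  }
  expand_eff <- if (support == "expanded") expand else 0
  tri <- fit_triangular_ml(preds, expand = expand_eff)
  bet <- fit_beta4_ml(preds, expand = max(expand_eff, 1e-6))
  lls <- c(triangular = dist_loglik(tri, preds), beta4 = dist_loglik(bet, preds))
  # >= breaks ties toward the 3-parameter triangular
  chosen <- if (lls["triangular"] >= lls["beta4"]) tri else bet
  chosen$fit_report <- list(normality = battery, logliks = lls)
  chosen
}

#' Log-likelihood of a sample under a class distribution
#'
#' @param dist A `plscm_dist`.
#' @param x Numeric sample.
#' @return Scalar log-likelihood (-Inf when any point has zero density).
#' @export
dist_loglik <- function(dist, x) {
  d <- dist_density(dist, x)
  if (any(d <= 0)) return(-Inf)
  sum(log(d))
}

# Triangular maximum likelihood. The likelihood is non-smooth in the mode
# (the MLE mode sits at a sample point), so the mode is profiled over the
# order statistics while (lower, upper) move on a grid anchored at the
# expanded sample range, followed by Nelder-Mead refinement of the bounds.
fit_triangular_ml <- function(x, expand = 0.01, grid_n = 7L) {
  r <- range(x); span <- diff(r)
  modes <- sort(unique(stats::quantile(x, seq(0, 1, length.out = min(101L, length(x))),
                                       names = FALSE, type = 1L)))
  prof <- function(a, b) {
    cand <- modes[modes > a & modes < b]
    if (!length(cand)) cand <- (a + b) / 2
    ll <- vapply(cand, function(c_) {
      dist_loglik(dist_triangular(a, c_, b), x)
    }, numeric(1))
    k <- which.max(ll)
    c(ll = ll[k], mode = cand[k])
  }
  offs <- span * exp(seq(log(max(expand, 1e-4)), log(0.5), length.out = grid_n))
  best <- NULL
  for (da in offs) for (db in offs) {
    pr <- prof(r[1] - da, r[2] + db)
    if (is.null(best) || pr["ll"] > best$ll) {
      best <- list(ll = pr["ll"], a = r[1] - da, b = r[2] + db, mode = pr["mode"])
    }
  }
  # refine bounds; log-offset parametrization keeps a < min(x) < max(x) < b
  obj <- function(u) -prof(r[1] - exp(u[1]), r[2] + exp(u[2]))["ll"]
  opt <- stats::optim(log(c(r[1] - best$a, best$b - r[2])), obj,
                      method = "Nelder-Mead",
                      control = list(maxit = 200L, reltol = 1e-10))
  a <- r[1] - exp(opt$par[1]); b <- r[2] + exp(opt$par[2])
  pr <- prof(a, b)
  dist_triangular(a, pr["mode"], b)
}

# Four-parameter beta by ML with the support fixed at the (expanded) sample
# range; shapes optimized on the log scale from moment-matching starts.
fit_beta4_ml <- function(x, expand = 0.01) {
  r <- range(x); span <- diff(r)
  lo <- r[1] - expand * span; up <- r[2] + expand * span
  z <- (x - lo) / (up - lo)
  m <- mean(z); v <- stats::var(z)
  k <- max(m * (1 - m) / v - 1, 0.1)
  start <- log(c(max(m * k, 0.05), max((1 - m) * k, 0.05)))
  nll <- function(ls) {
    -sum(stats::dbeta(z, exp(ls[1]), exp(ls[2]), log = TRUE))
  }
  opt <- stats::optim(start, nll, method = "Nelder-Mead",
                      control = list(maxit = 500L, reltol = 1e-10))
  dist_beta4(exp(opt$par[1]), exp(opt$par[2]), lo, up)
}
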