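test_that("autoscale centres and scales both blocks and round-trips exactly", {
  d <- pls_data(cbind(a = c(1, 2, 3, 4), b = c(10, 30, 20, 40)),
                c("A", "A", "B", "B"))
  sc <- autoscale(d)
  expect_equal(unname(colMeans(sc$X)), c(0, 0))
  expect_equal(unname(apply(sc$X, 2, sd)), c(1, 1))
  expect_equal(class_coding(d), c(-1, -1, 1, 1))
  expect_equal(mean(sc$y), 0)
  expect_lt(max(abs(unscale_x(sc$scaling, sc$X) - d$values)), 1e-10)
  # sample-sd convention on consecutive integers
  expect_equal(sc$scaling$x_sds[["a"]], sd(1:4))
})

test_that("degenerate inputs are rejected with informative errors", {
  expect_error(pls_data(cbind(c(1, 1, 1, 1), c(1, 2, 3, 4)), c("A", "A", "B", "B")),
               "constant column")
  expect_error(pls_data(cbind(1:4, 4:1), c("A", "A", "A", "A")), "two class labels")
  expect_error(pls_data(cbind(c(1, NA, 3, 4), 1:4), c("A", "A", "B", "B")),
               "missing")
  expect_error(fit_pls1(matrix(rnorm(20), 10, 2), rnorm(10), 5),
               "latent variables")
  expect_error(fit_pls1(matrix(c(NA, rnorm(19)), 10, 2), rnorm(10), 1),
               "non-finite")
})

test_that("PLS1 with all latent variables reproduces least squares", {
  # p = 1 reduces to univariate OLS
  set.seed(5)
  x <- drop(scale(rnorm(12)))
  y <- drop(scale(2 * x + rnorm(12, sd = 0.3)))
  fit <- fit_pls1(matrix(x), y, 1)
  expect_equal(drop(matrix(x) %*% fit$R %*% t(fit$Q)),
               as.numeric(fitted(lm(y ~ x - 1))), tolerance = 1e-10)
  # full-rank multivariate instances against lm()
  for (seed in c(11, 12, 13)) {
    inst <- random_instance(seed)
    fit <- fit_pls1(inst$X, inst$y, 4)
    pls_pred <- drop(inst$X %*% fit$R %*% t(fit$Q))
    ols_pred <- unname(fitted(lm(inst$y ~ inst$X - 1)))
    expect_lt(max(abs(pls_pred - ols_pred)), 1e-8)
  }
})

test_that("orthonormal X with y equal to its first column is fit exactly on one LV", {
  set.seed(17)
  X <- qr.Q(qr(matrix(rnorm(40), 10, 4)))
  y <- X[, 1]
  fit <- fit_pls1(X, y, 1)
  expect_lt(max(abs(drop(X %*% fit$R %*% t(fit$Q)) - y)), 1e-10)
  expect_equal(abs(drop(fit$W)), c(1, 0, 0, 0), tolerance = 1e-10)
  # the response is exhausted after one component: no second LV exists
  expect_error(fit_pls1(X, y, 2), "rank")
})

test_that("applied weights satisfy R'P = I and scores T = X R", {
  m <- std_model()
  expect_lt(max(abs(crossprod(m$R, m$P) - diag(m$n_lv))), 1e-8)
  expect_lt(max(abs(m$X_scaled %*% m$R - m$T)), 1e-8)
})

test_that("predictions behave as the affine map the model stores", {
  m <- std_model()
  d <- std_data()
  # training centroid maps to the coded-response mean
  expect_equal(drop(predict(m, m$scaling$x_means)), m$scaling$y_mean,
               tolerance = 1e-10)
  # training rows reproduce T Q' unscaled
  keep <- setdiff(seq_len(nrow(d$values)), m$removed_rows)
  expect_lt(max(abs(predict(m, d$values[keep, ]) -
                      (drop(m$T %*% t(m$Q)) * m$scaling$y_sd + m$scaling$y_mean))),
            1e-10)
  # linearity in any direction
  set.seed(9)
  x0 <- d$values[1, ]; v <- rnorm(6); delta <- 0.37
  gain <- delta * drop((v / m$scaling$x_sds) %*% m$R %*% t(m$Q)) * m$scaling$y_sd
  expect_equal(drop(predict(m, x0 + delta * v)) - drop(predict(m, x0)), gain,
               tolerance = 1e-10)
  expect_error(predict(m, 1:3), "variables")
})

test_that("predictions are invariant to training-row order", {
  d <- std_data()
  set.seed(77)
  perm <- sample(nrow(d$values))
  dp <- pls_data(d$values[perm, ], d$class_labels[perm], positive = d$positive)
  m1 <- suppressMessages(fit_with_outlier_removal(d, 2))
  m2 <- suppressMessages(fit_with_outlier_removal(dp, 2))
  probe <- generate_two_class(n_per_class = 5, p = 6, seed = 999)$values
  expect_equal(predict(m1, probe), predict(m2, probe), tolerance = 1e-8)
})

test_that("crossvalidation recovers an exactly linear coded response", {
  # coded class is an exact linear function of a rank-2 predictor block
  set.seed(21)
  n <- 40
  t1 <- rep(c(-1, 1), each = n / 2)
  t2 <- rnorm(n)
  d1 <- c(1, 1, 0, 0) / sqrt(2); d2 <- c(0, 0, 1, 1) / sqrt(2)
  X <- outer(t1, d1) + outer(t2, d2) + matrix(rnorm(n * 4, sd = 1e-8), n, 4)
  d <- pls_data(X, ifelse(t1 < 0, "A", "B"))
  cv <- cross_validate(d, 4)
  expect_gte(cv$table$r2_cv[2], 0.999)
  expect_true(all(cv$table$r2_cv <= 1))
  expect_lte(cv$selected, 2)
})

test_that("crossvalidation schemes and selection rules are honoured", {
  d <- std_data()
  cv_loo <- cross_validate(d, 3, scheme = "leave_one_out")
  cv_vb <- cross_validate(d, 3, scheme = "venetian_blinds", k_splits = 10)
  expect_equal(nrow(cv_loo$table), 3)
  expect_true(all(cv_vb$table$r2_cv <= 1))
  # both should find the rank-one class signal with few LVs
  expect_gte(cv_loo$table$r2_cv[cv_loo$selected], 0.85)
  expect_lte(cross_validate(d, 3, rule = "max")$selected, 3)
  expect_error(cross_validate(d, 10), "a_max")
})

test_that("T2 and Q statistics match their definitions and direct oracles", {
  m <- std_model()
  a <- m$n_lv
  expect_equal(t2_statistic(m, rep(0, a)), 0)
  expect_equal(t2_statistic(m, sqrt(m$score_variances)), a)
  expect_gt(t2_limit(m, 0.99), t2_limit(m, 0.95))
  expect_gt(q_limit(m, 0.99), q_limit(m, 0.95))
  # Q equals the squared norm of the reconstruction residual, independently
  set.seed(3)
  xs <- rnorm(6)
  t_ <- drop(xs %*% m$R)
  expect_equal(q_statistic(m, xs), sum((xs - drop(m$P %*% t_))^2),
               tolerance = 1e-12)
  # points in the span of P have zero residual
  expect_lt(q_statistic(m, drop(m$P %*% c(0.3, -1.2))), 1e-10)
})

test_that("Q vanishes identically when all latent variables are kept", {
  d <- generate_two_class(n_per_class = 10, p = 4, delta = 5, seed = 31)
  m <- suppressMessages(fit_with_outlier_removal(d, 4, remove_outliers = FALSE))
  set.seed(4)
  for (i in 1:5) expect_lt(q_statistic(m, rnorm(4)), 1e-16)
  expect_equal(q_limit(m), 0)
})

test_that("outlier removal flags only gross outliers and reaches a fixed point", {
  d <- std_data()
  m <- suppressMessages(fit_with_outlier_removal(d, 2))
  # clean synthetic data: at most a stray row or two at the 95% limits
  expect_lte(length(m$removed_rows), 3)
  # plant a gross outlier: 20 sds off in two variables (opposite signs, so
  # it leaves the latent plane as well as the score ellipse)
  vals <- d$values
  vals[7, 1:2] <- vals[7, 1:2] + c(20, -20) * apply(d$values[, 1:2], 2, sd)
  dd <- pls_data(vals, d$class_labels)
  m2 <- suppressMessages(fit_with_outlier_removal(dd, 2))
  expect_true(7 %in% m2$removed_rows)
  # fixed point: no retained row exceeds both limits
  t2 <- apply(m2$T, 1, function(t_) t2_statistic(m2, t_))
  qq <- apply(m2$X_scaled, 1, function(x_) q_statistic(m2, x_))
  expect_false(any(t2 > m2$t2_limit & qq > m2$q_limit))
})

test_that("fit_plscm wires crossvalidated selection into the final model", {
  d <- std_data()
  m <- suppressMessages(fit_plscm(d, a_max = 3))
  expect_s3_class(m, "plscm_model")
  expect_false(is.na(m$r2_cv))
  expect_gte(m$explained_var_y, 0.5)
})
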