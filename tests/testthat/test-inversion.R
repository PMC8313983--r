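test_that("minimum-norm boundary scores solve t Q' = y with least norm", {
  expect_equal(min_norm_score_solution(c(1, 0), 0.5), c(0.5, 0))
  expect_equal(min_norm_score_solution(c(3, 4), 5), c(0.6, 0.8))
  expect_equal(min_norm_score_solution(c(3, 4), 0), c(0, 0))
  expect_error(min_norm_score_solution(c(0, 0), 1), "zero")
})

test_that("latent null bases are orthonormal complements of Q", {
  b <- latent_null_basis(c(3, 4))
  expect_equal(dim(b), c(1L, 2L))
  expect_equal(abs(b), matrix(c(0.8, 0.6), 1), tolerance = 1e-12)
  expect_gt(b[1, 1], 0)  # sign convention
  expect_equal(nrow(latent_null_basis(2.5)), 0)
  set.seed(8)
  q <- rnorm(3)
  b3 <- latent_null_basis(q)
  expect_equal(tcrossprod(b3), diag(2), tolerance = 1e-10)
  expect_lt(max(abs(b3 %*% q)), 1e-10)
})

test_that("scores map back to input space as an affine image of the centroid", {
  m <- std_model()
  expect_equal(unname(scores_to_input(m, rep(0, m$n_lv))),
               unname(m$scaling$x_means), tolerance = 1e-12)
  set.seed(12)
  t1 <- rnorm(m$n_lv); t2 <- rnorm(m$n_lv)
  mu <- m$scaling$x_means
  expect_equal(scores_to_input(m, t1 + t2) - mu,
               (scores_to_input(m, t1) - mu) + (scores_to_input(m, t2) - mu),
               tolerance = 1e-10)
})

test_that("every latent boundary score maps to an object predicting y_d", {
  m <- std_model(); sp <- std_spec()
  inv <- invert_threshold(m, sp)
  set.seed(14)
  for (i in 1:50) {
    t_ <- inv$t_d + drop(rnorm(nrow(inv$latent_null_basis)) %*% inv$latent_null_basis)
    expect_equal(drop(predict(m, scores_to_input(m, t_))), sp$y_d,
                 tolerance = 1e-6)
  }
})

test_that("W-null directions are invisible to the model", {
  m <- std_model()
  wb <- w_null_basis(m)
  p <- nrow(m$R)
  expect_equal(dim(wb), c(p - m$n_lv, p))
  expect_lt(max(abs(wb %*% m$R)), 1e-8)
  expect_equal(tcrossprod(wb), diag(p - m$n_lv), tolerance = 1e-10)
  # adding a W-null direction (in raw increments) leaves the prediction at y_d
  sp <- std_spec()
  inv <- invert_threshold(m, sp)
  for (delta in c(-1, 1)) {
    x <- inv$x_hat_d + delta * wb[1, ] * m$scaling$x_sds
    expect_equal(drop(predict(m, x)), sp$y_d, tolerance = 1e-6)
  }
  # but it does change the Q-residual
  xs0 <- drop(scale_x(m$scaling, inv$x_hat_d))
  expect_gt(q_statistic(m, xs0 + wb[1, ]), q_statistic(m, xs0) + 0.5)
})

test_that("null-space dimensions audit: a-1 latent, p-a W, p-1 input", {
  for (cfg in list(c(p = 6, a = 2), c(p = 6, a = 3), c(p = 2, a = 1))) {
    d <- generate_two_class(n_per_class = 30, p = cfg["p"], delta = 5,
                            seed = 200 + cfg["a"])
    m <- suppressMessages(fit_with_outlier_removal(d, cfg["a"],
                                                   remove_outliers = FALSE))
    expect_equal(nrow(latent_null_basis(m$Q)), unname(cfg["a"]) - 1)
    expect_equal(nrow(w_null_basis(m)), unname(cfg["p"] - cfg["a"]))
    inb <- input_null_basis(m)
    expect_equal(nrow(inb), unname(cfg["p"]) - 1)
    expect_lt(max(abs(inb %*% m$R %*% t(m$Q))), 1e-8)
    expect_equal(tcrossprod(inb), diag(nrow(inb)), tolerance = 1e-8)
  }
})

test_that("feasibility combines the PLSbox with inclusive domain bounds", {
  m <- std_model(); d <- std_data()
  # medoid of the training cloud is comfortably feasible
  keep <- setdiff(seq_len(nrow(d$values)), m$removed_rows)
  med <- apply(d$values[keep, ], 2, median)
  fl <- is_feasible(m, med)
  expect_true(fl$in_plsbox && fl$in_domain)
  # ten times the range of every variable: far outside the domain
  far <- m$domain_ranges["max", ] + 10 * diff(m$domain_ranges)
  expect_false(is_feasible(m, far)$in_domain)
  # a point just above one column's max: still in the PLSbox, but outside D
  # (start from a training row attaining a column max while interior to the box)
  j <- which(vapply(seq_len(6), function(jj) {
    x <- d$values[keep[which.max(d$values[keep, jj])], ]
    fl <- is_feasible(m, x)
    fl$in_plsbox && fl$in_domain
  }, logical(1)))[1]
  bump <- d$values[keep[which.max(d$values[keep, j])], ]
  bump[j] <- bump[j] + 1e-3 * diff(m$domain_ranges)[1, j]
  fl2 <- is_feasible(m, bump)
  expect_true(fl2$in_plsbox)
  expect_false(fl2$in_domain)
  # boundary of the domain itself is inclusive
  edge <- med; edge[2] <- m$domain_ranges["max", 2]
  expect_true(is_feasible(m, edge)$in_domain)
})

test_that("boundary sampling is seeded, on-target and convex-closed", {
  m <- std_model(); sp <- std_spec()
  b1 <- sample_boundary(m, sp, n_points = 15, seed = 3)
  b2 <- sample_boundary(m, sp, n_points = 15, seed = 3)
  b3 <- sample_boundary(m, sp, n_points = 15, seed = 4)
  expect_identical(b1$points, b2$points)
  expect_false(isTRUE(all.equal(b1$points, b3$points)))
  expect_gte(sum(b1$feasible), 15)
  expect_lt(max(abs(b1$predictions - sp$y_d)), 1e-6)
  # any convex combination of feasible boundary points stays on the boundary
  ij <- which(b1$feasible)[1:2]
  mix <- 0.3 * b1$points[ij[1], ] + 0.7 * b1$points[ij[2], ]
  expect_equal(drop(predict(m, mix)), sp$y_d, tolerance = 1e-6)
})

test_that("an unreachable threshold yields a warning and an empty feasible set", {
  m <- std_model()
  # a threshold far beyond the coding range cannot be met inside the domain
  expect_warning(b <- sample_boundary(m, 30, n_points = 2, seed = 5),
                 "no feasible")
  expect_equal(sum(b$feasible), 0)
  expect_lt(max(abs(b$predictions - 30)), 1e-6)
})
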