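#' Minimum-norm score solution of the boundary equation
#'
#' All score vectors predicting a (scaled) target y satisfy t Q' = y; the
#' minimum-norm particular solution is y Q / ||Q||^2.
#'
#' @param Q y-loadings, a row vector (1 x a) or plain numeric vector.
#' @param y_d_scaled Target response in scaled units.
#' @return Score a-vector.
#' @export
min_norm_score_solution <- function(Q, y_d_scaled) {
  q <- as.numeric(Q)
  nq2 <- sum(q^2)
  if (nq2 <= 0) stop("Q is zero: the boundary equation has no normal direction")
  y_d_scaled * q / nq2
}

#' Orthonormal basis of the latent null space
#'
#' The latent boundary hyperplane {t : t Q' = y} is a translate of the
#' (a - 1)-dimensional null space {t0 : t0 Q' = 0}.
#'
#' @param Q y-loadings (1 x a or numeric vector).
#' @return (a - 1) x a matrix with orthonormal rows, each orthogonal to Q;
#'   a 0 x a matrix when a = 1.
#' @export
latent_null_basis <- function(Q) {
  q <- as.numeric(Q)
  a <- length(q)
  if (sum(q^2) <= 0) stop("Q is zero")
  if (a == 1L) return(matrix(numeric(0), 0L, 1L))
  sv <- svd(matrix(q, 1L, a), nv = a)
  fix_signs(t(sv$v[, 2:a, drop = FALSE]))
}

# Reproducible sign convention: first entry of each row with |.| > tol
# is made positive.
fix_signs <- function(m, tol = 1e-12) {
  for (i in seq_len(nrow(m))) {
    j <- which(abs(m[i, ]) > tol)[1L]
    if (!is.na(j) && m[i, j] < 0) m[i, ] <- -m[i, ]
  }
  m
}

#' Map scores to an input-space point
#'
#' Projects a score vector back through the X-loadings (x = t P' in scaled
#' units) and returns the point in raw variable units. Because R'P = I, the
#' prediction of the resulting point equals t Q' exactly, so boundary scores
#' map to boundary objects.
#'
#' @param model A `plscm_model`.
#' @param t Score a-vector (or m x a matrix of score rows).
#' @return p-vector (or m x p matrix) in raw units.
#' @export
scores_to_input <- function(model, t) {
  t <- if (is.null(dim(t))) matrix(t, nrow = 1L) else as.matrix(t)
  if (ncol(t) != model$n_lv) stop("expected ", model$n_lv, " score columns")
  out <- unscale_x(model$scaling, t %*% t(model$P))
  if (nrow(out) == 1L) drop(out) else out
}

#' Orthonormal basis of the W-null space
#'
#' Directions in (scaled) input space with zero projection on the applied
#' weights: adding them to any point changes neither its scores nor its
#' prediction, only its Q-residual. Dimension p - a (empty when a = p).
#'
#' @param model A `plscm_model`.
#' @return (p - a) x p matrix with orthonormal rows v satisfying v R = 0.
#' @export
w_null_basis <- function(model) {
  p <- nrow(model$R); a <- model$n_lv
  if (a >= p) return(matrix(numeric(0), 0L, p))
  sv <- svd(model$R, nu = p)
  fix_signs(t(sv$u[, (a + 1L):p, drop = FALSE]))
}

#' Orthonormal basis of the full input-space null space
#'
#' The kernel of the prediction map x -> x R Q' has dimension p - 1: the
#' union of the latent null space mapped through P' (dimension a - 1) and
#' the W-null space (dimension p - a), re-orthonormalized.
#'
#' @param model A `plscm_model`.
#' @return (p - 1) x p matrix with orthonormal rows v with v R Q' = 0.
#' @export
input_null_basis <- function(model) {
  p <- nrow(model$R)
  lat <- latent_null_basis(model$Q)
  stacked <- rbind(lat %*% t(model$P), w_null_basis(model))
  sv <- svd(stacked)
  r <- sum(sv$d > max(sv$d[1L], 1) * 1e-10)
  if (r != p - 1L) {
    stop("degenerate model: input null space has rank ", r,
         " instead of ", p - 1L)
  }
  fix_signs(t(sv$v[, seq_len(r), drop = FALSE]))
}

#' Feasibility of a point: PLSbox and domain membership
#'
#' A solution of the inversion is only valid when it lies inside the model's
#' region of applicability (T2 and Q-residual below their confidence limits,
#' the "PLSbox") and inside the domain D given by the training range of
#' every variable (inclusive bounds).
#'
#' @param model A `plscm_model`.
#' @param x_raw p-vector in raw units.
#' @param domain 2 x p matrix of per-column min/max (default: training
#'   ranges stored in the model).
#' @param confidence Confidence level for the PLSbox limits (default: the
#'   model's).
#' @return List with logical `in_plsbox` and `in_domain`.
#' @export
is_feasible <- function(model, x_raw, domain = model$domain_ranges,
                        confidence = model$confidence) {
  x_raw <- as.numeric(x_raw)
  xs <- drop(scale_x(model$scaling, x_raw))
  t_ <- drop(xs %*% model$R)
  in_box <- t2_statistic(model, t_) <= t2_limit(model, confidence) &&
    q_statistic(model, xs) <= q_limit(model, confidence)
  in_dom <- all(x_raw >= domain["min", ] & x_raw <= domain["max", ])
  list(in_plsbox = in_box, in_domain = in_dom)
}

#' Algebraic inversion of the model at a decision threshold
#'
#' Characterizes the class-model boundary for a threshold y_d in coding
#' units: the minimum-norm boundary scores, the latent and W null-space
#' bases, the full input null basis, and the particular boundary object in
#' raw units.
#'
#' @param model A `plscm_model`.
#' @param y_d Decision threshold in coding units (a number or a
#'   `plscm_spec`).
#' @return A `plscm_inversion` list: `y_d`, `y_d_scaled`, `t_d`,
#'   `latent_null_basis`, `x_hat_d` (raw units), `w_null_basis`,
#'   `input_null_basis`, `feasibility` of `x_hat_d`.
#' @export
invert_threshold <- function(model, y_d) {
  if (inherits(y_d, "plscm_spec")) y_d <- y_d$y_d
  ys <- (y_d - model$scaling$y_mean) / model$scaling$y_sd
  t_d <- min_norm_score_solution(model$Q, ys)
  x_hat_d <- scores_to_input(model, t_d)
  structure(
    list(y_d = y_d, y_d_scaled = ys, t_d = t_d,
         latent_null_basis = latent_null_basis(model$Q),
         x_hat_d = x_hat_d,
         w_null_basis = w_null_basis(model),
         input_null_basis = input_null_basis(model),
         feasibility = is_feasible(model, x_hat_d)),
    class = "plscm_inversion")
}

#' @export
print.plscm_inversion <- function(x, ...) {
  cat(sprintf("Boundary at y_d = %.4f: null dims %d (latent) + %d (W) = %d (input)\n",
              x$y_d, nrow(x$latent_null_basis), nrow(x$w_null_basis),
              nrow(x$input_null_basis)))
  invisible(x)
}

#' Sample boundary objects at a decision threshold
#'
#' Draws null-space coefficients uniformly inside a box scaled to
#' `box_scale` times the range of the training projections on each null
#' direction, adds them to the minimum-norm boundary solution, maps to the
#' input space and screens each point against the PLSbox and the domain.
#' Batches are drawn until `n_points` feasible points are collected or 100
#' times `n_points` draws are spent (then a warning is issued and whatever
#' was drawn is returned, possibly with an empty feasible set).
#'
#' @param model A `plscm_model`.
#' @param class_spec A `plscm_spec` or a numeric threshold in coding units.
#' @param n_points Number of feasible boundary points wanted (default 50,
#'   enough to trace the boundary without cluttering a plot).
#' @param seed Integer seed; same seed, same sample.
#' @param box_scale Scale factor on the training projection ranges
#'   (default 1).
#' @return A `plscm_boundary` list: `y_d`, `points` (rows in raw units),
#'   `scores`, `predictions` (coding units), `in_plsbox`, `in_domain`,
#'   `feasible`.
#' @export
sample_boundary <- function(model, class_spec, n_points = 50L, seed = 1L,
                            box_scale = 1) {
  if (n_points < 1L) stop("n_points must be at least 1")
  inv <- invert_threshold(model, class_spec)
  set.seed(as.integer(seed))
  lat <- inv$latent_null_basis
  wnb <- inv$w_null_basis
  lat_rng <- if (nrow(lat)) apply(model$T %*% t(lat), 2L, range)
  w_rng <- if (nrow(wnb)) apply(model$X_scaled %*% t(wnb), 2L, range)
  xs_d <- drop(scale_x(model$scaling, inv$x_hat_d))
  draw_batch <- function(m) {
    xs <- matrix(rep(xs_d, each = m), m)
    if (nrow(lat)) {
      cl <- sapply(seq_len(nrow(lat)), function(j)
        stats::runif(m, box_scale * lat_rng[1L, j], box_scale * lat_rng[2L, j]))
      xs <- xs + matrix(cl, m) %*% (lat %*% t(model$P))
    }
    if (nrow(wnb)) {
      cw <- sapply(seq_len(nrow(wnb)), function(j)
        stats::runif(m, box_scale * w_rng[1L, j], box_scale * w_rng[2L, j]))
      xs <- xs + matrix(cw, m) %*% wnb
    }
    xs
  }
  collected <- NULL
  n_feasible <- 0L
  budget <- 100L * n_points
  while (n_feasible < n_points && budget > 0L) {
    m <- min(max(n_points, 2L * (n_points - n_feasible)), budget)
    budget <- budget - m
    xs <- draw_batch(m)
    raw <- unscale_x(model$scaling, xs)
    flags <- t(apply(raw, 1L, function(x_) unlist(is_feasible(model, x_))))
    batch <- list(xs = xs, raw = raw, flags = flags)
    collected <- if (is.null(collected)) batch else {
      list(xs = rbind(collected$xs, xs), raw = rbind(collected$raw, raw),
           flags = rbind(collected$flags, flags))
    }
    n_feasible <- sum(collected$flags[, 1L] & collected$flags[, 2L])
  }
  feasible <- collected$flags[, "in_plsbox"] & collected$flags[, "in_domain"]
  if (!any(feasible)) {
    warning("no feasible boundary point found after ", 100L * n_points,
            " draws; returning the infeasible sample")
  } else {
    # keep all draws up to the one that completes the feasible quota
    last <- which(cumsum(feasible) == min(n_points, sum(feasible)))[1L]
    collected$xs <- collected$xs[seq_len(last), , drop = FALSE]
    collected$raw <- collected$raw[seq_len(last), , drop = FALSE]
    collected$flags <- collected$flags[seq_len(last), , drop = FALSE]
    feasible <- feasible[seq_len(last)]
  }
  scores <- collected$xs %*% model$R
  preds <- drop(collected$xs %*% model$R %*% t(model$Q)) *
    model$scaling$y_sd + model$scaling$y_mean
  colnames(collected$raw) <- model$column_names
  structure(
    list(y_d = inv$y_d, points = collected$raw, scores = scores,
         predictions = preds,
         in_plsbox = unname(collected$flags[, "in_plsbox"]),
         in_domain = unname(collected$flags[, "in_domain"]),
         feasible = unname(feasible)),
    class = "plscm_boundary")
}

#' @export
print.plscm_boundary <- function(x, ...) {
  cat(sprintf("Boundary sample at y_d = %.4f: %d points, %d feasible\n",
              x$y_d, nrow(x$points), sum(x$feasible)))
  invisible(x)
}

#' @export
as.data.frame.plscm_boundary <- function(x, ...) {
  cbind(as.data.frame(x$points),
        prediction = x$predictions,
        in_plsbox = x$in_plsbox, in_domain = x$in_domain,
        feasible = x$feasible)
}
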