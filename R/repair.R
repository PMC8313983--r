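#' Normal direction to the boundary hyperplane in latent space
#'
#' The boundary {t : t Q' = y_d} has normal Q'; normalized, and oriented so
#' that moving along it increases the predicted response (toward the class
#' coded +1).
#'
#' @param Q y-loadings (1 x a or numeric vector).
#' @return Unit a-vector.
#' @export
latent_normal_direction <- function(Q) {
  q <- as.numeric(Q)
  nq <- sqrt(sum(q^2))
  if (nq <= 0) stop("Q is zero: no normal direction")
  q / nq
}

#' Normal direction to the boundary hyperplane in input space
#'
#' The prediction map in scaled input space is x -> x R Q', so the director
#' vector orthogonal to the global null space is R Q' (normalized, in
#' scaled units). Moving one scaled unit along it raises the scaled
#' prediction by ||R Q'||.
#'
#' @param model A `plscm_model`.
#' @return Unit p-vector in scaled units.
#' @export
input_normal_direction <- function(model) {
  g <- drop(model$R %*% t(model$Q))
  ng <- sqrt(sum(g^2))
  if (ng <= 0) stop("degenerate model: R Q' is zero")
  g / ng
}

#' Repair trajectory: move a rejected object into the class-model
#'
#' Starting from an object, takes `n_steps` equally spaced steps (in scaled
#' units, so steps are comparable across variables of different magnitude)
#' along the input-space normal direction, the straight line that crosses
#' the class-model boundary orthogonally. Each computed point gets its
#' prediction, feasibility against the PLSbox and domain, and a status.
#'
#' With `step_size = "auto"` the step is 2 (y_d - yhat0) (in scaled
#' response units) / (n_steps ||R Q'||), so a rejected start crosses the
#' boundary near the middle of the trajectory.
#'
#' @param model A `plscm_model`.
#' @param class_spec A `plscm_spec` or numeric threshold in coding units.
#' @param x_start Starting p-vector in raw units.
#' @param n_steps Number of steps beyond the start (default 10).
#' @param step_size `"auto"` or a step length in scaled units.
#' @return A `plscm_trajectory` list: `points` ((n_steps + 1) x p, raw
#'   units, first row = start), `predictions` (coding units), `status`
#'   (`"rejected"`, `"accepted"` or `"infeasible"` per point),
#'   `direction_raw` (raw-unit increments of one unit scaled step),
#'   `step_size`, `start_point`, `y_d`.
#' @export
repair_trajectory <- function(model, class_spec, x_start, n_steps = 10L,
                              step_size = "auto") {
  if (inherits(class_spec, "plscm_spec")) class_spec <- class_spec$y_d
  y_d <- class_spec
  if (n_steps < 1L) stop("n_steps must be at least 1")
  x_start <- as.numeric(check_dim(model, x_start))
  u <- input_normal_direction(model)
  grad <- sqrt(sum(drop(model$R %*% t(model$Q))^2))
  ys <- model$scaling
  yhat0 <- drop(predict(model, x_start))
  deficit_scaled <- (y_d - yhat0) / ys$y_sd
  if (yhat0 >= y_d) {
    warning("start is already accepted (prediction ", signif(yhat0, 4),
            " >= y_d ", signif(y_d, 4), "); trajectory produced anyway")
  }
  if (identical(step_size, "auto")) {
    step_size <- 2 * deficit_scaled / (n_steps * grad)
  }
  if (!is.finite(step_size)) stop("degenerate step size")
  xs0 <- drop(scale_x(ys, x_start))
  k <- 0:n_steps
  xs <- outer(rep(1, length(k)), xs0) + outer(k * step_size, u)
  raw <- unscale_x(ys, xs)
  colnames(raw) <- model$column_names
  preds <- predict(model, raw)
  status <- vapply(seq_along(k), function(i) {
    fl <- is_feasible(model, raw[i, ])
    if (!fl$in_plsbox || !fl$in_domain) "infeasible"
    else if (preds[i] >= y_d) "accepted" else "rejected"
  }, character(1))
  structure(
    list(points = raw, predictions = preds, status = status,
         direction_raw = u * ys$x_sds, step_size = step_size,
         start_point = x_start, y_d = y_d),
    class = "plscm_trajectory")
}

#' @export
print.plscm_trajectory <- function(x, ...) {
  cat(sprintf("Repair trajectory: %d points, step %.4g (scaled), y_d = %.4f\n",
              nrow(x$points), x$step_size, x$y_d))
  print(table(factor(x$status, levels = c("rejected", "accepted", "infeasible"))))
  invisible(x)
}

#' @export
as.data.frame.plscm_trajectory <- function(x, ...) {
  cbind(data.frame(status = x$status, prediction = x$predictions),
        as.data.frame(x$points))
}

#' Classify an object with a class-model
#'
#' Hard constraints first: objects outside the PLSbox or the domain D are
#' aliens for which the class-model makes no statement. Otherwise the
#' object is inside the class-model exactly when its prediction reaches the
#' decision threshold (ties accepted).
#'
#' @param model A `plscm_model`.
#' @param class_spec A `plscm_spec` or numeric threshold in coding units.
#' @param x_raw p-vector in raw units.
#' @return `"inside"`, `"outside"` or `"not_applicable"`.
#' @export
classify_object <- function(model, class_spec, x_raw) {
  if (inherits(class_spec, "plscm_spec")) class_spec <- class_spec$y_d
  fl <- is_feasible(model, x_raw)
  if (!fl$in_plsbox || !fl$in_domain) return("not_applicable")
  if (drop(predict(model, x_raw)) >= class_spec) "inside" else "outside"
}
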