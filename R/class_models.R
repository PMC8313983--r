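#' Decision thresholds from the fitted class distributions
#'
#' The class-model of the positive class (coded +1) is the half-line of
#' predicted responses above a decision threshold y_d. Given the fitted
#' distribution F_B of the modelled class's predictions, a prescribed
#' sensitivity s fixes the threshold through P(X_B <= y_c) = 1 - s; the
#' specificity against the other class is then P(X_A <= y_c) under its
#' fitted distribution F_A.
#'
#' @param dist_B Fitted distribution of the modelled (+1) class predictions.
#' @param dist_A Fitted distribution of the other (-1) class predictions.
#' @param s Target sensitivity, strictly in (0, 1).
#' @param y_c Decision threshold in coding units.
#' @return `threshold_for_sensitivity`: the threshold y_c (the 1 - s
#'   quantile of `dist_B`). `sensitivity_at_threshold` and
#'   `specificity_at_threshold`: probabilities in `[0, 1]`.
#' @export
threshold_for_sensitivity <- function(dist_B, s) {
  if (length(s) != 1L || s <= 0 || s >= 1) {
    stop("sensitivity must lie strictly in (0, 1); the threshold is unbounded at 0 or 1")
  }
  dist_quantile(dist_B, 1 - s)
}

#' @rdname threshold_for_sensitivity
#' @export
sensitivity_at_threshold <- function(dist_B, y_c) {
  1 - dist_cdf(dist_B, y_c)
}

#' @rdname threshold_for_sensitivity
#' @export
specificity_at_threshold <- function(dist_A, y_c) {
  dist_cdf(dist_A, y_c)
}

#' Build a class-model specification at a given threshold
#'
#' @param y_d Decision threshold in coding units.
#' @param dist_A,dist_B Fitted class distributions (negative, positive).
#' @param modelled_class Label of the modelled class (informational).
#' @return A `plscm_spec` object: `y_d`, `sensitivity`, `specificity`,
#'   `alpha` (= 1 - sensitivity), `beta` (= 1 - specificity) and the two
#'   distributions.
#' @export
class_model_spec <- function(y_d, dist_A, dist_B, modelled_class = "B") {
  s <- sensitivity_at_threshold(dist_B, y_d)
  sp <- specificity_at_threshold(dist_A, y_d)
  structure(
    list(modelled_class = modelled_class, y_d = y_d,
         sensitivity = s, specificity = sp,
         alpha = 1 - s, beta = 1 - sp,
         dist_A = dist_A, dist_B = dist_B),
    class = "plscm_spec")
}

#' @export
print.plscm_spec <- function(x, ...) {
  cat(sprintf(
    "Class-model of class %s: y_d = %.4f, sensitivity = %.3f, specificity = %.3f\n",
    x$modelled_class, x$y_d, x$sensitivity, x$specificity))
  invisible(x)
}

#' Balanced decision threshold (sensitivity = specificity)
#'
#' Finds by bisection the threshold at which the class-model accepts its own
#' objects and rejects the others with the same probability, i.e. the root
#' of F_A(y) - (1 - F_B(y)).
#'
#' @param dist_A,dist_B Fitted class distributions (negative, positive).
#' @param tol Bisection tolerance on the threshold (default 1e-12), tight
#'   enough that |sensitivity - specificity| <= 1e-9 at the solution.
#' @return A `plscm_spec` at the balanced threshold.
#' @export
balanced_threshold <- function(dist_A, dist_B, tol = 1e-12) {
  g <- function(y) specificity_at_threshold(dist_A, y) -
    sensitivity_at_threshold(dist_B, y)
  lo <- min(dist_bracket(dist_A)[1], dist_bracket(dist_B)[1])
  hi <- max(dist_bracket(dist_A)[2], dist_bracket(dist_B)[2])
  glo <- g(lo); ghi <- g(hi)
  if (glo * ghi > 0) {
    stop("no balanced threshold: specificity - sensitivity has sign ",
         sign(glo), " across [", signif(lo, 4), ", ", signif(hi, 4),
         "]; the operating curves do not cross (classes completely ",
         "separated or inverted)")
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    gm <- g(mid)
    if (gm == 0) { lo <- hi <- mid; break }
    if (glo * gm < 0) hi <- mid else { lo <- mid; glo <- gm }
  }
  class_model_spec((lo + hi) / 2, dist_A, dist_B)
}

#' Operating characteristic curve over a threshold grid
#'
#' @param dist_A,dist_B Fitted class distributions (negative, positive).
#' @param grid Ascending vector of thresholds.
#' @return A data frame of class `plscm_oc` with columns `threshold`,
#'   `sensitivity` (nonincreasing) and `specificity` (nondecreasing).
#' @export
oc_curve <- function(dist_A, dist_B, grid) {
  if (!length(grid)) stop("threshold grid is empty")
  if (is.unsorted(grid)) stop("threshold grid must be sorted ascending")
  out <- data.frame(threshold = grid,
                    sensitivity = sensitivity_at_threshold(dist_B, grid),
                    specificity = specificity_at_threshold(dist_A, grid))
  class(out) <- c("plscm_oc", "data.frame")
  out
}

#' Fit class distributions from a model and build a class-model
#'
#' Convenience pipeline: predict the training rows, split the predictions by
#' class, fit a distribution to each, and return the balanced class-model
#' (or the one at a prescribed sensitivity).
#'
#' @param model A `plscm_model`.
#' @param data The [pls_data] the model was fitted on.
#' @param sensitivity Either `"balanced"` (default) or a value in (0, 1).
#' @param ... Passed to [fit_predicted_distribution].
#' @return A `plscm_spec`.
#' @export
build_class_model <- function(model, data, sensitivity = "balanced", ...) {
  stopifnot(inherits(model, "plscm_model"), inherits(data, "plscm_data"))
  keep <- setdiff(seq_len(nrow(data$values)), model$removed_rows)
  preds <- predict(model, data$values[keep, , drop = FALSE])
  cls <- data$class_labels[keep]
  dist_A <- fit_predicted_distribution(preds[cls == data$negative], ...)
  dist_B <- fit_predicted_distribution(preds[cls == data$positive], ...)
  if (identical(sensitivity, "balanced")) {
    balanced_threshold(dist_A, dist_B)
  } else {
    class_model_spec(threshold_for_sensitivity(dist_B, sensitivity),
                     dist_A, dist_B, modelled_class = data$positive)
  }
}
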