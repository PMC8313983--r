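#' Serialize a fitted model to JSON and back
#'
#' Writes every matrix as nested arrays (row-major) together with the
#' scaling, limits and metadata, under a `format_version` field, so a fit
#' can be archived or exchanged without R serialization.
#'
#' @param model A `plscm_model`.
#' @param path Output file; if `NULL`, the JSON string is returned.
#' @return `model_to_json`: `path` (or the JSON string) invisibly.
#'   `model_from_json`: the restored `plscm_model`.
#' @export
model_to_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "plscm_model"))
  payload <- list(
    format_version = "1.0",
    n_lv = model$n_lv,
    W = model$W, P = model$P, Q = model$Q, R = model$R,
    T = model$T, X_scaled = model$X_scaled,
    scaling = unclass(model$scaling),
    score_variances = model$score_variances,
    residual_eigenvalues = model$residual_eigenvalues,
    n_retained = model$n_retained,
    confidence = model$confidence,
    t2_limit = model$t2_limit, q_limit = model$q_limit,
    removed_rows = model$removed_rows,
    domain_ranges = model$domain_ranges,
    column_names = model$column_names,
    positive = model$positive, negative = model$negative,
    explained_var_x = model$explained_var_x,
    explained_var_y = model$explained_var_y,
    r2_cv = model$r2_cv)
  js <- jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE, na = "null")
  if (is.null(path)) return(invisible(as.character(js)))
  writeLines(js, path)
  invisible(path)
}

#' @rdname model_to_json
#' @export
model_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  if (is.null(obj$format_version)) stop("not a serialized model: no format_version")
  mat <- function(m) matrix(as.numeric(m), nrow = nrow(m))
  model <- list(
    W = mat(obj$W), P = mat(obj$P),
    Q = matrix(as.numeric(obj$Q), nrow = 1L),
    R = mat(obj$R), T = mat(obj$T), X_scaled = mat(obj$X_scaled),
    n_lv = as.integer(obj$n_lv),
    explained_var_x = obj$explained_var_x,
    explained_var_y = obj$explained_var_y,
    scaling = structure(obj$scaling, class = "plscm_scaling"),
    score_variances = as.numeric(obj$score_variances),
    residual_eigenvalues = as.numeric(obj$residual_eigenvalues),
    n_retained = as.integer(obj$n_retained),
    confidence = obj$confidence,
    t2_limit = obj$t2_limit, q_limit = obj$q_limit,
    removed_rows = as.integer(obj$removed_rows),
    domain_ranges = {
      d <- mat(obj$domain_ranges); rownames(d) <- c("min", "max")
      colnames(d) <- obj$column_names; d
    },
    column_names = obj$column_names,
    positive = obj$positive, negative = obj$negative,
    r2_cv = if (is.null(obj$r2_cv)) NA_real_ else obj$r2_cv)
  structure(model, class = c("plscm_model", "plscm_pls"))
}
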