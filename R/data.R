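#' Two-class training data for PLS class-modelling
#'
#' Bundles the predictor matrix, the binary class labels and the per-column
#' training ranges that later define the hard domain constraint on inversion
#' solutions.
#'
#' @param x Numeric matrix or data frame, n objects by p predictor variables.
#' @param class Length-n vector with exactly two distinct labels.
#' @param positive Label of the class coded +1 (the modelled class). Defaults
#'   to the last label in sort order so that labels `c("A", "B")` code B as +1.
#'
#' @return An object of class `plscm_data` with elements `values` (numeric
#'   matrix), `class_labels` (character), `positive`/`negative` (the two
#'   labels), `column_names`, and `domain_ranges` (2 x p matrix of training
#'   minima and maxima).
#'
#' @details At least 4 rows and 2 columns are required, both classes must be
#'   present, missing values are rejected, and every column must have a
#'   strictly positive range (a constant column carries no scaling
#'   information and would make autoscaling undefined).
#' @export
pls_data <- function(x, class, positive = NULL) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("predictor matrix must be numeric")
  n <- nrow(x); p <- ncol(x)
  if (n < 4L) stop("need at least 4 objects, got ", n)
  if (p < 2L) stop("need at least 2 predictor variables, got ", p)
  if (anyNA(x) || any(!is.finite(x))) stop("predictor matrix contains missing or non-finite values")
  class <- as.character(class)
  if (length(class) != n) stop("class vector length ", length(class), " does not match ", n, " rows")
  lev <- sort(unique(class))
  if (length(lev) != 2L) stop("exactly two class labels required, found: ", paste(lev, collapse = ", "))
  if (is.null(positive)) positive <- lev[2L]
  if (!positive %in% lev) stop("positive label '", positive, "' not among the class labels")
  negative <- setdiff(lev, positive)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(p))
  rng <- apply(x, 2L, range)
  rownames(rng) <- c("min", "max")
  const <- rng["max", ] - rng["min", ] <= 0
  if (any(const)) {
    stop("constant column(s): ", paste(colnames(x)[const], collapse = ", "))
  }
  structure(
    list(values = x, class_labels = class,
         positive = positive, negative = negative,
         column_names = colnames(x), domain_ranges = rng),
    class = "plscm_data")
}

#' @export
print.plscm_data <- function(x, ...) {
  tab <- table(x$class_labels)
  cat("PLS-CM data:", nrow(x$values), "objects x", ncol(x$values), "variables\n")
  cat("  classes: ", x$negative, " (coded -1, n=", tab[[x$negative]], "), ",
      x$positive, " (coded +1, n=", tab[[x$positive]], ")\n", sep = "")
  invisible(x)
}

#' Coded class response
#'
#' @param data A [pls_data] object.
#' @return Numeric vector of -1 (negative class) and +1 (positive class).
#' @export
class_coding <- function(data) {
  stopifnot(inherits(data, "plscm_data"))
  ifelse(data$class_labels == data$positive, 1, -1)
}

#' Simulate two classes separated along a linear direction
#'
#' Generates the kind of data PLS-CM is designed for: two Gaussian clouds in
#' p dimensions whose means differ by `delta` noise-standard-deviation units
#' along a single direction. Class structure is therefore rank one and a
#' one-latent-variable model recovers it; larger `delta` gives better
#' separated predicted responses.
#'
#' @param n_per_class Objects per class (>= 4). Default 200.
#' @param p Number of predictor variables (>= 2). Default 6.
#' @param delta Distance between the class means along `effect_direction`, in
#'   units of `noise_sd`. Default 6 (well-separated but overlapping classes,
#'   comparable to a class-model with sensitivity/specificity in the high
#'   0.9s).
#' @param noise_sd Isotropic noise standard deviation. Default 1.
#' @param effect_direction Unit p-vector along which the classes separate;
#'   default is the diagonal direction `rep(1, p) / sqrt(p)`.
#' @param seed Integer seed; the output is a deterministic function of it.
#' @param labels Two labels, negative class first. Default `c("A", "B")`.
#'
#' @return A [pls_data] object with `n_per_class` rows of each class, class A
#'   centred at `-(delta/2) * effect_direction` and class B at
#'   `+(delta/2) * effect_direction`.
#' @export
generate_two_class <- function(n_per_class = 200L, p = 6L, delta = 6,
                               noise_sd = 1, effect_direction = NULL,
                               seed = 1L, labels = c("A", "B")) {
  if (n_per_class < 4L) stop("n_per_class must be at least 4")
  if (p < 2L) stop("p must be at least 2")
  if (delta < 0) stop("delta must be nonnegative")
  if (noise_sd <= 0) stop("noise_sd must be strictly positive")
  if (is.null(effect_direction)) effect_direction <- rep(1, p) / sqrt(p)
  if (length(effect_direction) != p) stop("effect_direction must have length p")
  nrm <- sqrt(sum(effect_direction^2))
  if (nrm <= 0) stop("effect_direction must be nonzero")
  effect_direction <- effect_direction / nrm
  set.seed(as.integer(seed))
  n <- 2L * as.integer(n_per_class)
  z <- rep(c(-1, 1), each = n_per_class)
  x <- outer(z * delta / 2, effect_direction) +
    matrix(stats::rnorm(n * p, sd = noise_sd), n, p)
  colnames(x) <- paste0("x", seq_len(p))
  pls_data(x, rep(labels, each = n_per_class), positive = labels[2L])
}

#' Read a two-class dataset from CSV
#'
#' Expects a comma-separated file with a header row, "." decimal marks, one
#' class column and numeric predictors in all other columns.
#'
#' @param path Path to the CSV file.
#' @param class_column Name of the class column.
#' @param positive Label of the modelled (+1) class; default last in sort
#'   order.
#' @return A [pls_data] object.
#' @export
read_dataset <- function(path, class_column = "class", positive = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!class_column %in% names(df)) {
    stop("class column '", class_column, "' not found; columns: ",
         paste(names(df), collapse = ", "))
  }
  cls <- as.character(df[[class_column]])
  pred <- df[setdiff(names(df), class_column)]
  for (j in names(pred)) {
    v <- pred[[j]]
    bad <- which(is.na(v) | (is.character(v) & !nzchar(trimws(v))))
    if (is.character(v)) {
      vn <- suppressWarnings(as.numeric(v))
      bad <- union(bad, which(is.na(vn) & !is.na(v)))
      v <- vn
    }
    if (length(bad)) {
      stop("non-numeric or blank value in column '", j, "', row ", bad[1L])
    }
    pred[[j]] <- v
  }
  blank <- which(is.na(cls) | !nzchar(trimws(cls)))
  if (length(blank)) stop("blank class label in row ", blank[1L])
  pls_data(as.matrix(pred), cls, positive = positive)
}

#' Write boundary points, trajectories or OC curves to CSV
#'
#' Plain CSV writer (no row names, "." decimal) so results round-trip through
#' [utils::read.csv] exactly at double precision.
#'
#' @param results Data frame or matrix.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(results, path) {
  utils::write.csv(as.data.frame(results), path, row.names = FALSE)
  invisible(path)
}
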