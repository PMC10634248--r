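# Two-class linear discriminant analysis and the repeated stratified
# two-fold cross-validation protocol used for accuracy reporting and as the
# genetic-algorithm fitness.

#' Fit a two-class linear discriminant model
#'
#' Classic Fisher/Gaussian LDA: the discriminant direction is
#' `w = S^-1 (mu1 - mu0)` with `S` the pooled within-class covariance,
#' ridge-stabilised by adding `ridge * trace(S)/p` to the diagonal.  A
#' point `x` is assigned to class 1 iff `w'x > w'(mu0 + mu1)/2 -
#' log(pi1/pi0)`; exact ties go to class 0.
#'
#' @param x numeric matrix, patients x markers (no missing values).
#' @param y logical labels (`TRUE` = class 1); both classes need >= 2 rows.
#' @param priors `"empirical"` (class frequencies) or `"equal"`.
#' @param ridge relative ridge added to the pooled covariance diagonal.
#' @return An object of class `lda_model` with elements `mu0`, `mu1`, `S`,
#'   `w`, `threshold`, `priors`, `markers`.
#' @export
fit_lda <- function(x, y, priors = c("empirical", "equal"), ridge = 1e-6) {
  priors <- match.arg(priors)
  x <- as.matrix(x)
  stopifnot(is.logical(y), length(y) == nrow(x), !anyNA(x))
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 < 2 || n0 < 2) stop2("both classes need at least 2 rows")
  p <- ncol(x)
  x1 <- x[y, , drop = FALSE]; x0 <- x[!y, , drop = FALSE]
  mu1 <- colMeans(x1); mu0 <- colMeans(x0)
  S <- ((n1 - 1) * stats::cov(x1) + (n0 - 1) * stats::cov(x0)) / (n1 + n0 - 2)
  S <- S + diag(ridge * sum(diag(S)) / p, p)
  w <- tryCatch(solve(S, mu1 - mu0), error = function(e)
    stop2("pooled covariance is singular even after ridge ", ridge,
          "; increase `ridge`"))
  pi1 <- if (priors == "empirical") n1 / (n1 + n0) else 0.5
  threshold <- sum(w * (mu0 + mu1)) / 2 - log(pi1 / (1 - pi1))
  structure(list(mu0 = mu0, mu1 = mu1, S = S, w = w, threshold = threshold,
                 priors = c(p0 = 1 - pi1, p1 = pi1),
                 markers = colnames(x)),
            class = "lda_model")
}

#' Predict class membership from a fitted LDA model
#'
#' @param object an `lda_model` from [fit_lda()].
#' @param newdata numeric matrix whose columns match the model's markers.
#' @param ... unused.
#' @return Logical vector: `TRUE` for class 1.  Boundary points classify to
#'   class 0.
#' @export
predict.lda_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(colnames(newdata)) && !is.null(object$markers)) {
    if (!identical(colnames(newdata), object$markers)) {
      stop2("column names of `newdata` do not match the fitted markers")
    }
  } else if (ncol(newdata) != length(object$w)) {
    stop2("`newdata` has ", ncol(newdata), " columns; model expects ",
          length(object$w))
  }
  as.vector(newdata %*% object$w > object$threshold)
}

# Stratified fold assignment: within each class, a random permutation dealt
# round-robin into n_folds folds.
.stratified_folds <- function(y, n_folds) {
  fold <- integer(length(y))
  for (cls in c(TRUE, FALSE)) {
    idx <- which(y == cls)
    fold[idx[sample.int(length(idx))]] <-
      rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' Repeated stratified k-fold cross-validation of LDA
#'
#' For each repeat a stratified random partition into `n_folds` folds is
#' drawn; each fold is predicted by a model fitted on the remaining folds,
#' so every patient is predicted exactly once per repeat.  Accuracy is the
#' pooled correct fraction over all patients of a repeat; sensitivity and
#' specificity are the correct fractions among class-1 and class-0 patients.
#' Reported rates are means over repeats.
#'
#' @inheritParams fit_lda
#' @param n_repeats number of random repartitions (default 30).
#' @param n_folds folds per repeat (default 2).
#' @param seed integer seed; the evaluation is deterministic given
#'   `(x, y, seed)`.
#' @return A list of class `cv_report`: `accuracy`, `accuracy_sd`,
#'   `sensitivity`, `specificity`, `per_repeat` (data.frame), `n_repeats`,
#'   `n_folds`, `seed`.
#' @export
cv_evaluate <- function(x, y, n_repeats = 30L, n_folds = 2L, seed = 1L,
                        priors = "empirical", ridge = 1e-6) {
  x <- as.matrix(x)
  stopifnot(is.logical(y), length(y) == nrow(x))
  if (sum(y) < 2 * n_folds || sum(!y) < 2 * n_folds) {
    stop2("each class needs at least 2 rows per fold for stratified CV")
  }
  per <- with_seed(seed, {
    t(vapply(seq_len(n_repeats), function(r) {
      fold <- .stratified_folds(y, n_folds)
      pred <- logical(length(y))
      for (f in seq_len(n_folds)) {
        test <- fold == f
        model <- fit_lda(x[!test, , drop = FALSE], y[!test],
                         priors = priors, ridge = ridge)
        pred[test] <- predict(model, x[test, , drop = FALSE])
      }
      ok <- pred == y
      c(accuracy = mean(ok),
        sensitivity = mean(ok[y]),
        specificity = mean(ok[!y]))
    }, numeric(3)))
  })
  per <- as.data.frame(per)
  structure(list(accuracy = mean(per$accuracy),
                 accuracy_sd = stats::sd(per$accuracy),
                 sensitivity = mean(per$sensitivity),
                 specificity = mean(per$specificity),
                 per_repeat = per,
                 n_repeats = n_repeats, n_folds = n_folds, seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf(paste0("<cv_report> %dx%d-fold CV: accuracy %.3f (sd %.3f), ",
                     "sensitivity %.3f, specificity %.3f\n"),
              x$n_repeats, x$n_folds, x$accuracy, x$accuracy_sd,
              x$sensitivity, x$specificity))
  invisible(x)
}
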