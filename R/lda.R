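# Linear discriminant analysis written from first principles.
#
# Shared-covariance Gaussian model: pooled within-class covariance with
# divisor N - K, linear discriminant scores
#   delta_k(x) = x' Sigma^-1 mu_k - 1/2 mu_k' Sigma^-1 mu_k + log pi_k,
# posteriors by softmax of the scores (exact under the shared-covariance
# model), and canonical axes from the generalized eigenproblem of
# between-class vs pooled within-class scatter, solved symmetrically via a
# Cholesky whitening of the within matrix.

#' Fit a linear discriminant model
#'
#' @param x numeric matrix or data frame (samples x features), typically
#'   min-max scaled first (see [fit_scaler()]).
#' @param labels class label per row; at least 2 classes, each with at
#'   least 2 samples, and more samples than classes overall.
#' @param priors `"proportional"` (class frequencies, the default) or
#'   `"uniform"`.
#' @return an object of class `lda_fit`: `class_labels` (sorted), `means`
#'   (K x p class means), `pooled_cov` (within-class covariance, divisor
#'   N - K), `priors`, `axes` (p x m discriminant directions,
#'   m = min(K - 1, p)) with `eigenvalues` (nonincreasing), `xbar` (grand
#'   mean), and `lambda` (ridge actually added, 0 when the within matrix
#'   was well conditioned).
#' @examples
#' x <- rbind(matrix(rnorm(40), 20), matrix(rnorm(40, 3), 20))
#' fit <- fit_lda(x, rep(c("a", "b"), each = 20))
#' predict(fit, x)$class
#' @export
fit_lda <- function(x, labels, priors = c("proportional", "uniform")) {
  priors <- match.arg(priors)
  x <- as_feature_matrix(x)
  labels <- as.character(labels)
  if (length(labels) != nrow(x)) stopf("'labels' must match rows of 'x'")
  if (any(!is.finite(x))) stopf("'x' must be finite")
  classes <- sort(unique(labels))
  K <- length(classes)
  N <- nrow(x)
  p <- ncol(x)
  if (K < 2) stopf("need at least 2 classes")
  if (N <= K) stopf("need more samples (%d) than classes (%d)", N, K)
  nk <- vapply(classes, function(k) sum(labels == k), numeric(1))
  small <- classes[nk < 2]
  if (length(small)) {
    stopf("class(es) with fewer than 2 samples: %s",
          paste(small, collapse = ", "))
  }

  means <- matrix(0, K, p, dimnames = list(classes, colnames(x)))
  for (k in classes) {
    means[k, ] <- colMeans(x[labels == k, , drop = FALSE])
  }

  W <- matrix(0, p, p)
  for (k in classes) {
    xk <- sweep(x[labels == k, , drop = FALSE], 2, means[k, ])
    W <- W + crossprod(xk)
  }
  W <- W / (N - K)
  W <- (W + t(W)) / 2

  # ridge stabilization when the pooled covariance is near-singular (small
  # per-class n, e.g. triplicate sites, invites this)
  ev <- eigen(W, symmetric = TRUE, only.values = TRUE)$values
  lambda <- 0
  if (min(ev) <= 0 || max(ev) / min(ev) > 1e10) {
    lambda <- max(1e-8 * sum(diag(W)) / p, 1e-12)
    W <- W + diag(lambda, p)
  }

  pri <- if (priors == "proportional") nk / N else rep(1 / K, K)
  names(pri) <- classes

  xbar <- colMeans(x)
  B <- matrix(0, p, p)
  for (i in seq_along(classes)) {
    d <- means[i, ] - xbar
    B <- B + nk[i] * tcrossprod(d)
  }
  B <- B / (K - 1)

  # symmetric generalized eigenproblem: W = U'U, M = U^-T B U^-1
  U <- chol(W)
  Ui <- backsolve(U, diag(p))
  M <- t(Ui) %*% B %*% Ui
  M <- (M + t(M)) / 2
  eg <- eigen(M, symmetric = TRUE)
  m <- min(K - 1, p)
  axes <- Ui %*% eg$vectors[, seq_len(m), drop = FALSE]
  colnames(axes) <- paste0("LD", seq_len(m))
  rownames(axes) <- colnames(x)

  Sigma_inv <- chol2inv(U)

  structure(
    list(
      class_labels = classes, means = means, pooled_cov = W,
      priors = pri, axes = axes, eigenvalues = eg$values[seq_len(m)],
      xbar = xbar, lambda = lambda, Sigma_inv = Sigma_inv, n = N,
      counts = stats::setNames(nk, classes), priors_mode = priors
    ),
    class = "lda_fit"
  )
}

#' @export
print.lda_fit <- function(x, ...) {
  cat(sprintf(
    "<lda_fit> %d classes, %d features, %d discriminant axes (%s priors)\n",
    length(x$class_labels), ncol(x$means), ncol(x$axes), x$priors_mode))
  cat("Classes:", paste(x$class_labels, collapse = ", "), "\n")
  cat("Axis eigenvalues:", paste(signif(x$eigenvalues, 4), collapse = ", "),
      "\n")
  if (x$lambda > 0) cat(sprintf("Ridge applied: lambda = %.3g\n", x$lambda))
  invisible(x)
}

#' Classify samples with a fitted LDA model
#'
#' Labels are the argmax of the linear discriminant scores; posteriors are
#' the softmax of the scores. Exact score ties are broken toward the
#' earliest class in `class_labels` and counted in the `n_ties` field
#' (with a message when any occur).
#'
#' @param object an [lda_fit] model.
#' @param newdata matrix or data frame with the model's features.
#' @param ... unused.
#' @return list with `class` (character vector), `posterior` (rows sum to
#'   1), `scores` (discriminant score per class), `n_ties`.
#' @export
predict.lda_fit <- function(object, newdata, ...) {
  x <- as_feature_matrix(newdata)
  p <- ncol(object$means)
  if (ncol(x) != p) {
    stopf("dimension mismatch: model has %d features, data has %d",
          p, ncol(x))
  }
  if (valid_names(colnames(x)) && valid_names(colnames(object$means)) &&
      setequal(colnames(x), colnames(object$means))) {
    x <- x[, colnames(object$means), drop = FALSE]
  }
  A <- object$Sigma_inv %*% t(object$means)          # p x K
  const <- -0.5 * colSums(t(object$means) * A) + log(object$priors)
  scores <- x %*% A + matrix(const, nrow(x), length(const), byrow = TRUE)
  colnames(scores) <- object$class_labels

  top <- apply(scores, 1, max)
  is_tie <- apply(scores, 1, function(s) {
    sum(abs(s - max(s)) <= 1e-10 * max(1, abs(max(s)))) > 1
  })
  n_ties <- sum(is_tie)
  if (n_ties > 0) {
    message(sprintf(
      "%d tied discriminant score(s); broke toward the earliest class",
      n_ties))
  }
  # earliest-listed class among (tolerance-)tied maxima
  cls <- object$class_labels[apply(scores, 1, function(s) {
    which(abs(s - max(s)) <= 1e-10 * max(1, abs(max(s))))[1]
  })]

  shifted <- exp(scores - top)
  posterior <- shifted / rowSums(shifted)

  list(class = cls, posterior = posterior, scores = scores, n_ties = n_ties)
}

#' Project samples onto the discriminant axes
#'
#' Centers on the training grand mean and projects onto the canonical
#' axes; the coordinates behind an LDA score plot. The grand mean itself
#' maps to the origin.
#'
#' @param model an [lda_fit].
#' @param x matrix or data frame in the model's feature space.
#' @return matrix of LD coordinates (samples x axes).
#' @export
lda_project <- function(model, x) {
  if (!inherits(model, "lda_fit")) stopf("'model' must be an lda_fit")
  x <- as_feature_matrix(x)
  if (ncol(x) != length(model$xbar)) {
    stopf("dimension mismatch: model has %d features, data has %d",
          length(model$xbar), ncol(x))
  }
  sweep(x, 2, model$xbar) %*% model$axes
}

# ---- confusion matrices ---------------------------------------------------

#' Build a confusion matrix
#'
#' Counts with rows = true class and columns = predicted class, over the
#' union (or a supplied ordering) of class labels.
#'
#' @param true,predicted character vectors of equal length.
#' @param classes optional ordered class labels; defaults to the sorted
#'   union of those observed.
#' @return a `confusion_matrix` (integer matrix subclass).
#' @export
confusion_matrix <- function(true, predicted, classes = NULL) {
  if (length(true) != length(predicted)) {
    stopf("'true' and 'predicted' must have equal length")
  }
  if (is.null(classes)) classes <- sort(unique(c(true, predicted)))
  extra <- setdiff(unique(c(true, predicted)), classes)
  if (length(extra)) {
    stopf("labels outside 'classes': %s", paste(extra, collapse = ", "))
  }
  m <- table(factor(true, levels = classes),
             factor(predicted, levels = classes))
  m <- matrix(as.integer(m), nrow = length(classes),
              dimnames = list(classes, classes))
  structure(m, class = c("confusion_matrix", class(m)))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("LOOCV confusion matrix (rows = true, columns = predicted)\n")
  print(unclass(x))
  r <- prediction_rates(x)
  cat("Per-class prediction (%):",
      paste(names(r$per_class), sprintf("%.1f", r$per_class),
            collapse = ", "), "\n")
  cat(sprintf("Overall: %.2f%%\n", r$overall))
  invisible(x)
}

#' Export a confusion matrix in the report-table layout
#'
#' One row per true class: the class label, the K predicted-class counts,
#' then the per-class `Prediction (%)` rounded half-up to one decimal.
#'
#' @param cm a [confusion_matrix].
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_confusion_csv <- function(cm, path) {
  r <- prediction_rates(cm)
  df <- data.frame(Region = rownames(cm), unclass(cm),
                   check.names = FALSE, stringsAsFactors = FALSE)
  df[["Prediction (%)"]] <- unname(r$per_class)
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

# ---- leave-one-out cross-validation ---------------------------------------

#' Leave-one-out cross-validation of min-max-scaled LDA
#'
#' For each sample, fits the model on the remaining samples and predicts
#' the held-out one; predictions are pooled into a confusion matrix. Under
#' the default `scaling = "prefit"` the min-max scaler is fit once on the
#' full table before the loop (normalization first, then internally
#' cross-validated LDA); `"per_fold"` refits the scaler inside every fold,
#' the strictly leakage-free variant.
#'
#' @param x raw (unscaled) feature matrix or data frame.
#' @param labels class label per row; every class needs >= 3 samples so
#'   each fold keeps >= 2 per class.
#' @param priors passed to [fit_lda()].
#' @param scaling `"prefit"` or `"per_fold"`.
#' @return an object of class `loocv_result`: `confusion`
#'   (a [confusion_matrix]), `predictions` (data frame with `index`,
#'   `true`, `predicted`, `correct`), plus the `scaling`/`priors` used.
#' @export
loocv <- function(x, labels, priors = c("proportional", "uniform"),
                  scaling = c("prefit", "per_fold")) {
  priors <- match.arg(priors)
  scaling <- match.arg(scaling)
  x <- as_feature_matrix(x)
  labels <- as.character(labels)
  if (length(labels) != nrow(x)) stopf("'labels' must match rows of 'x'")
  nk <- table(labels)
  small <- names(nk)[nk < 3]
  if (length(small)) {
    stopf("LOOCV needs >= 3 samples per class; too few in: %s",
          paste(small, collapse = ", "))
  }
  n <- nrow(x)
  classes <- sort(unique(labels))
  if (scaling == "prefit") {
    xs <- apply_scaler(fit_scaler(x), x, warn = FALSE)
  }
  predicted <- character(n)
  for (i in seq_len(n)) {
    if (scaling == "prefit") {
      train <- xs[-i, , drop = FALSE]
      test <- xs[i, , drop = FALSE]
    } else {
      sc <- fit_scaler(x[-i, , drop = FALSE])
      train <- apply_scaler(sc, x[-i, , drop = FALSE], warn = FALSE)
      test <- apply_scaler(sc, x[i, , drop = FALSE], warn = FALSE)
    }
    fit <- fit_lda(train, labels[-i], priors = priors)
    predicted[i] <- suppressMessages(predict(fit, test)$class)
  }
  structure(
    list(
      confusion = confusion_matrix(labels, predicted, classes),
      predictions = data.frame(
        index = seq_len(n), true = labels, predicted = predicted,
        correct = labels == predicted, stringsAsFactors = FALSE
      ),
      scaling = scaling, priors = priors
    ),
    class = "loocv_result"
  )
}

#' @export
print.loocv_result <- function(x, ...) {
  cat(sprintf("Leave-one-out cross-validation (%s scaling, %s priors)\n",
              x$scaling, x$priors))
  print(x$confusion)
  invisible(x)
}
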