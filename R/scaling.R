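# Min-max feature scaling: x' = (x - min(A)) / (max(A) - min(A)) per
# feature A, fit on a training table and applied to any table with the
# same features.

as_feature_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) x <- matrix(x, ncol = 1)
  storage.mode(x) <- "double"
  x
}

#' Fit a min-max scaler
#'
#' Records the per-feature minimum and maximum of a training matrix, so
#' that [apply_scaler()] can map values into \[0, 1\] over the training
#' range.
#'
#' @param x numeric matrix or data frame (samples x features), all values
#'   finite.
#' @return an object of class `minmax_scaler` with fields `min`, `max`,
#'   `features`.
#' @export
fit_scaler <- function(x) {
  x <- as_feature_matrix(x)
  if (nrow(x) < 1 || ncol(x) < 1) stopf("need at least one sample and feature")
  bad <- which(!is.finite(x), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    cn <- colnames(x)
    stopf("non-finite value at row %d, column %s",
          bad[1, 1],
          if (is.null(cn)) as.character(bad[1, 2]) else cn[bad[1, 2]])
  }
  structure(
    list(
      min = apply(x, 2, min),
      max = apply(x, 2, max),
      features = colnames(x)
    ),
    class = "minmax_scaler"
  )
}

#' Apply a fitted min-max scaler
#'
#' Maps each feature through `(x - min) / (max - min)` using the training
#' range stored in `params`. Values inside the training range land in
#' \[0, 1\]; held-out values outside it are returned as computed (and
#' counted in a warning). Degenerate features with `max == min` carry no
#' discriminant information and are mapped to 0, with a warning.
#'
#' @param params a [fit_scaler()] result.
#' @param x matrix or data frame whose columns match (by name, when named)
#'   the features the scaler was fit on.
#' @param warn emit warnings for out-of-range values and degenerate
#'   features? Set `FALSE` for silent use inside cross-validation loops.
#' @return scaled numeric matrix of the same shape.
#' @export
apply_scaler <- function(params, x, warn = TRUE) {
  if (!inherits(params, "minmax_scaler")) {
    stopf("'params' must come from fit_scaler()")
  }
  x <- as_feature_matrix(x)
  if (ncol(x) != length(params$min)) {
    stopf("feature mismatch: scaler has %d features, data has %d columns",
          length(params$min), ncol(x))
  }
  if (valid_names(params$features) && valid_names(colnames(x))) {
    if (!setequal(colnames(x), params$features)) {
      stopf("feature mismatch: data columns {%s} vs scaler features {%s}",
            paste(colnames(x), collapse = ", "),
            paste(params$features, collapse = ", "))
    }
    x <- x[, params$features, drop = FALSE]
  }
  rng <- params$max - params$min
  degenerate <- rng == 0
  rng[degenerate] <- 1 # placeholder; degenerate columns are zeroed below
  scaled <- sweep(sweep(x, 2, params$min, "-"), 2, rng, "/")
  scaled[, degenerate] <- 0
  if (warn) {
    if (any(degenerate)) {
      nm <- params$features %||% as.character(seq_along(params$min))
      warnf("%d degenerate (constant) feature(s) mapped to 0: %s",
            sum(degenerate), paste(nm[degenerate], collapse = ", "))
    }
    n_out <- sum(scaled[, !degenerate, drop = FALSE] < 0 |
                   scaled[, !degenerate, drop = FALSE] > 1)
    if (n_out > 0) {
      warnf("%d value(s) fall outside the training range (scaled outside [0, 1])",
            n_out)
    }
  }
  scaled
}

#' @export
print.minmax_scaler <- function(x, ...) {
  cat(sprintf("<minmax_scaler> %d feature(s)\n", length(x$min)))
  df <- data.frame(min = x$min, max = x$max)
  rownames(df) <- x$features %||% paste0("V", seq_along(x$min))
  print(df)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize scaling parameters to JSON
#'
#' Round-trippable provenance record of a fitted scaler, for embedding in
#' run reports.
#'
#' @param params a [fit_scaler()] result.
#' @param json a JSON string from `scaler_to_json`.
#' @return `scaler_to_json` returns a JSON string; `scaler_from_json` the
#'   reconstructed `minmax_scaler`.
#' @export
scaler_to_json <- function(params) {
  jsonlite::toJSON(
    list(min = as.list(stats::setNames(params$min, params$features)),
         max = as.list(stats::setNames(params$max, params$features))),
    auto_unbox = TRUE, digits = NA
  )
}

#' @rdname scaler_to_json
#' @export
scaler_from_json <- function(json) {
  p <- jsonlite::fromJSON(json)
  structure(
    list(min = unlist(p$min), max = unlist(p$max), features = names(p$min)),
    class = "minmax_scaler"
  )
}
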