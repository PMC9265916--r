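# Shared generators for the test suite. All randomness is seeded locally.

# Two Gaussian classes separated by `gap` pooled SDs along every feature.
make_two_class_data <- function(n_per = 20, gap = 10, p = 2, seed = 1,
                                labels = c("a", "b")) {
  set.seed(seed)
  x <- rbind(
    matrix(rnorm(n_per * p, 0, 1), n_per, p),
    matrix(rnorm(n_per * p, gap, 1), n_per, p)
  )
  colnames(x) <- paste0("f", seq_len(p))
  list(x = x, labels = rep(labels, each = n_per))
}

# Independent oracle for LDA class assignment: evaluates the full
# shared-covariance Gaussian log-posterior via the quadratic form
# log pi_k - (x - mu_k)' Sigma^-1 (x - mu_k) / 2 computed with solve(),
# rather than the linear discriminant-score route the package uses.
oracle_predict <- function(x, labels, newdata,
                           priors = c("proportional", "uniform")) {
  priors <- match.arg(priors)
  x <- as.matrix(x); newdata <- as.matrix(newdata)
  classes <- sort(unique(labels))
  K <- length(classes); N <- nrow(x); p <- ncol(x)
  mus <- lapply(classes, function(k) colMeans(x[labels == k, , drop = FALSE]))
  W <- Reduce(`+`, lapply(seq_len(K), function(i) {
    xk <- sweep(x[labels == classes[i], , drop = FALSE], 2, mus[[i]])
    crossprod(xk)
  })) / (N - K)
  pri <- if (priors == "proportional") {
    sapply(classes, function(k) mean(labels == k))
  } else rep(1 / K, K)
  lp <- sapply(seq_len(K), function(i) {
    d <- sweep(newdata, 2, mus[[i]])
    log(pri[i]) - 0.5 * rowSums((d %*% solve(W)) * d)
  })
  lp <- matrix(lp, nrow = nrow(newdata))
  classes[apply(lp, 1, which.max)]
}

# A random named FA quantity vector over the 15-FA panel.
random_fa_raw <- function(seed = 1) {
  set.seed(seed)
  stats::setNames(runif(15, 0.1, 10), fa_names())
}
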