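test_that("well-separated classes are learned perfectly", {
  d <- make_two_class_data(n_per = 20, gap = 10, p = 2, seed = 1)
  fit <- fit_lda(d$x, d$labels)
  expect_identical(predict(fit, d$x)$class, d$labels)
  expect_identical(ncol(fit$axes), 1L) # min(K-1, p) = 1
})

test_that("axis count follows min(K-1, p)", {
  set.seed(2)
  x4 <- matrix(rnorm(80), ncol = 2)
  l4 <- rep(c("a", "b", "c", "d"), each = 10)
  expect_identical(ncol(fit_lda(x4, l4)$axes), 2L) # K = 4, p = 2 -> 2 axes

  x1 <- matrix(rnorm(20), ncol = 1)
  l1 <- rep(c("a", "b"), each = 10)
  fit1 <- fit_lda(x1, l1)
  expect_identical(ncol(fit1$axes), 1L)
  # single feature: the axis is the feature up to scale
  expect_true(abs(fit1$axes[1, 1]) > 0)
})

test_that("predictions match the quadratic-form Gaussian oracle", {
  # small random instances, exact agreement with an independent oracle
  for (i in 1:30) {
    set.seed(i)
    K <- sample(2:3, 1)
    p <- sample(1:3, 1)
    # keep N - K comfortably above p so the oracle's solve() is well posed
    n_per <- p + sample(2:4, 1)
    n <- K * n_per
    x <- matrix(rnorm(n * p, sd = 2), n, p) +
      rep(seq_len(K) * 2, each = n_per)
    labels <- rep(letters[seq_len(K)], each = n_per)
    for (pm in c("proportional", "uniform")) {
      fit <- fit_lda(x, labels, priors = pm)
      set.seed(1000 + i)
      new <- matrix(rnorm(5 * p, mean = mean(x), sd = 3), ncol = p)
      expect_identical(
        suppressMessages(predict(fit, new)$class),
        oracle_predict(x, labels, new, priors = pm)
      )
    }
  }
})

test_that("discriminant scores match the direct formula on a toy set", {
  set.seed(5)
  x <- matrix(rnorm(12), 6, 2)
  labels <- rep(c("a", "b"), each = 3)
  fit <- fit_lda(x, labels)
  pr <- predict(fit, x)
  # direct delta_k(x) = x' S^-1 mu_k - mu_k' S^-1 mu_k / 2 + log pi_k
  Sinv <- solve(fit$pooled_cov)
  for (k in 1:2) {
    mu <- fit$means[k, ]
    manual <- x %*% Sinv %*% mu -
      0.5 * drop(t(mu) %*% Sinv %*% mu) + log(fit$priors[k])
    expect_equal(unname(pr$scores[, k]), drop(manual), tolerance = 1e-8)
  }
})

test_that("posteriors are proper and class means sit where they should", {
  set.seed(6)
  d <- make_two_class_data(n_per = 15, gap = 3, p = 3, seed = 6)
  fit <- fit_lda(d$x, d$labels)
  pr <- predict(fit, matrix(rnorm(30), ncol = 3))
  expect_true(all(abs(rowSums(pr$posterior) - 1) < 1e-12))
  # a point at a class mean with uniform priors is assigned to that class
  fitu <- fit_lda(d$x, d$labels, priors = "uniform")
  expect_identical(predict(fitu, fit$means)$class, fit$class_labels)
})

test_that("exact ties break toward the earliest class and are counted", {
  # two symmetric classes; the midpoint is exactly equidistant
  x <- rbind(c(-1, 0), c(-2, 0), c(-1, 1), c(1, 0), c(2, 0), c(1, 1))
  labels <- rep(c("a", "b"), each = 3)
  fit <- fit_lda(x, labels, priors = "uniform")
  mid <- matrix(c(0, 0.5), 1) # on the symmetry axis
  expect_message(pr <- predict(fit, mid), "tied")
  expect_identical(pr$class, "a")
  expect_identical(pr$n_ties, 1L)
})

test_that("projection centers on the grand mean and orders axis variance", {
  set.seed(8)
  x <- matrix(rnorm(120), ncol = 3)
  labels <- rep(c("a", "b", "c", "d"), each = 10)
  x <- x + outer(as.integer(factor(labels)), c(2, 0.5, 0))
  fit <- fit_lda(x, labels)
  expect_equal(drop(lda_project(fit, matrix(fit$xbar, 1))),
               rep(0, ncol(fit$axes)), tolerance = 1e-12,
               ignore_attr = TRUE)
  # between-class variance nonincreasing across axes
  proj_means <- lda_project(fit, fit$means)
  bvar <- apply(proj_means, 2, stats::var)
  expect_true(all(diff(bvar) <= 1e-8))
  expect_true(all(diff(fit$eigenvalues) <= 1e-8))
  expect_error(lda_project(fit, matrix(1, 1, 2)), "dimension mismatch")
})

test_that("fit preconditions are enforced", {
  set.seed(9)
  x <- matrix(rnorm(10), 5, 2)
  expect_error(fit_lda(x, c("a", "a", "a", "a", "b")), "fewer than 2")
  expect_error(fit_lda(x[1:3, ], c("a", "a", "b")), "fewer than 2")
  expect_error(fit_lda(matrix(rnorm(4), 2), c("a", "b")), "more samples")
  expect_error(predict(fit_lda(x, rep(c("a", "b"), c(2, 3))),
                       matrix(1, 1, 3)),
               "dimension mismatch")
})

test_that("ridge stabilization engages on singular pooled covariance", {
  # a duplicated feature makes the within matrix exactly singular
  set.seed(10)
  z <- rnorm(12)
  x <- cbind(z, z, rnorm(12))
  labels <- rep(c("a", "b"), each = 6)
  fit <- fit_lda(x, labels)
  expect_gt(fit$lambda, 0)
  expect_identical(length(suppressMessages(predict(fit, x)$class)), 12L)
})

test_that("LOOCV conserves counts and is permutation invariant", {
  d <- make_two_class_data(n_per = 12, gap = 2, p = 2, seed = 11)
  r <- loocv(d$x, d$labels)
  cm <- r$confusion
  expect_equal(rowSums(cm), c(a = 12, b = 12), ignore_attr = TRUE)
  expect_identical(sum(cm), 24L)

  set.seed(12)
  perm <- sample(24)
  r2 <- loocv(d$x[perm, ], d$labels[perm])
  expect_identical(unclass(r2$confusion), unclass(cm))
})

test_that("LOOCV separates what is separable and enforces preconditions", {
  d <- make_two_class_data(n_per = 20, gap = 10, p = 2, seed = 13)
  cm <- loocv(d$x, d$labels)$confusion
  expect_identical(unname(diag(unclass(cm))), c(20L, 20L))

  expect_error(loocv(d$x[1:22, ], rep(c("a", "b"), c(20, 2))),
               "too few in: b")
})

test_that("LOOCV accuracy increases with class separation", {
  gaps <- c(0, 1, 3, 10)
  acc <- vapply(gaps, function(g) {
    d <- make_two_class_data(n_per = 15, gap = g, p = 2, seed = 99)
    sum(diag(unclass(loocv(d$x, d$labels)$confusion))) / 30
  }, numeric(1))
  expect_true(all(diff(acc) >= 0))
  expect_gt(acc[4], 0.95)
})

test_that("fit and predictions agree with an independent reference (MASS)", {
  s <- generate_samples(builtin_fixtures("korea_table1"), seed = 17)
  x <- as.matrix(s[, c("d13C", "d15N")])
  xs <- apply_scaler(fit_scaler(x), x, warn = FALSE)
  fit <- fit_lda(xs, s$region)
  ref <- MASS::lda(xs, grouping = s$region)
  expect_equal(fit$means[rownames(ref$means), ], ref$means,
               tolerance = 1e-6)
  expect_identical(suppressMessages(predict(fit, xs)$class),
                   as.character(predict(ref)$class))
})

test_that("confusion matrices validate and export in the report layout", {
  cm <- confusion_matrix(c("a", "a", "b"), c("a", "b", "b"))
  expect_equal(unclass(cm),
               matrix(c(1L, 0L, 1L, 1L), 2,
                      dimnames = list(c("a", "b"), c("a", "b"))),
               ignore_attr = FALSE)
  expect_error(confusion_matrix("a", c("a", "b")), "equal length")
  expect_error(confusion_matrix("a", "b", classes = "a"), "outside")

  path <- withr::local_tempfile(fileext = ".csv")
  write_confusion_csv(builtin_confusion("dual_isotope_regions"), path)
  out <- utils::read.csv(path, check.names = FALSE)
  expect_identical(names(out),
                   c("Region", "CC", "GN", "JB", "JN", "Prediction (%)"))
  expect_equal(out[["Prediction (%)"]], c(84.0, 73.1, 60.0, 53.8))
})
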