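test_that("prediction rates reproduce report arithmetic and invariances", {
  cm <- builtin_confusion("dual_isotope_regions")
  r <- prediction_rates(cm)
  expect_equal(unname(r$per_class["CC"]), 84.0) # 21 of 25
  expect_equal(r$overall, trunc_decimals(100 * 69 / 102, 2))

  ident <- confusion_matrix(rep(c("a", "b", "c"), 5),
                            rep(c("a", "b", "c"), 5))
  ri <- prediction_rates(ident)
  expect_true(all(ri$per_class == 100))
  expect_equal(ri$overall, 100)

  # invariant under simultaneous row/column class permutation
  m <- unclass(cm)
  perm <- c(3, 1, 4, 2)
  r2 <- prediction_rates(m[perm, perm])
  expect_equal(sort(r2$per_class), sort(r$per_class))
  expect_equal(r2$overall, r$overall)

  expect_error(prediction_rates(matrix(0L, 2, 2)), "empty")
  expect_error(prediction_rates(matrix(1, 2, 3)), "square")
})

test_that("pooled prediction rate matches the stepwise totals", {
  expect_equal(pooled_prediction_rate(c(4, 98, 1), c(15, 102, 16)), 77.44)
  expect_equal(pooled_prediction_rate(c(3, 51, 2), c(3, 51, 3)), 98.24)
  expect_equal(pooled_prediction_rate(c(3, 51, 3), c(3, 51, 3)), 100)
  expect_error(pooled_prediction_rate(c(5, 1), c(4, 1)), "correct <= totals")
})

test_that("routing escalates weak classes, subsamples per site, validates tau", {
  s <- generate_samples(builtin_fixtures("korea_table1"), seed = 0)
  res <- loocv(s[, c("d13C", "d15N")], s$region)

  # with tau = 100 every imperfect region routes; k = 3 over 17 sites -> 51
  routed <- route_unauthenticated(res, s, policy = "site_rate_below",
                                  tau = 100, subsample_k = 3)
  all_routed <- attr(routed, "all_routed")
  rates <- prediction_rates(res$confusion)$per_class_raw
  expect_true(all(rates < 100)) # no region is perfect on this draw
  expect_length(all_routed, 102)
  expect_length(routed, 51)
  expect_true(all(table(s$site_id[match(routed, s$sample_id)]) == 3))
  # deterministic: first three by sample_id at each site
  expect_true(all(grepl("-0[123]$", routed)))

  # threshold tau only routes classes below it
  weakest <- names(which.min(rates))
  routed_lo <- route_unauthenticated(res, s, tau = min(rates) + 0.1)
  expect_setequal(unique(s$region[match(routed_lo, s$sample_id)]), weakest)

  # the stricter reading: exactly the misclassified individuals
  routed_mis <- route_unauthenticated(res, s, policy = "sample_misclassified")
  expect_length(routed_mis, sum(!res$predictions$correct))

  expect_error(route_unauthenticated(res, s, tau = 0), "\\(0, 100\\]")
  expect_error(route_unauthenticated(res, s, tau = 101), "\\(0, 100\\]")
  # k above a site's routed count takes all, with a notice
  expect_message(
    route_unauthenticated(res, s, tau = 100, subsample_k = 99),
    "taking all"
  )
})

test_that("a perfectly separated tier 1 short-circuits the rest", {
  set.seed(30)
  specs <- lapply(1:2, function(k) {
    site_spec(paste0("S", k, "-1"), paste0("R", k), "X", 10,
              gaussian_features = list(
                easy = c(10 * k, 0.1), extra = c(0, 1)
              ))
  })
  s <- generate_samples(specs, seed = 30)
  tiers <- list(cascade_tier("t1", "easy"), cascade_tier("t2", "extra"))
  cr <- run_cascade(s, tiers, tau = 100, label = "region")
  expect_named(cr$tiers, "t1")
  expect_true(all(cr$ledger$status == "authenticated"))
  expect_true(all(cr$ledger$final_label == cr$ledger$true))
})

test_that("cascade ledger partitions every input exactly once", {
  full <- merge_specs(
    merge_specs(builtin_fixtures("korea_table1"),
                builtin_fixtures("csia_table4")),
    builtin_fixtures("fa_profiles_synthetic")
  )
  s <- generate_samples(full, seed = 0)
  for (mode in c("stepwise", "parallel")) {
    cr <- run_cascade(s, policy = "site_rate_below", tau = 100,
                      subsample_k = 3, mode = mode)
    led <- cr$ledger
    expect_identical(nrow(led), nrow(s))
    expect_identical(sort(led$sample_id), sort(s$sample_id))
    expect_false(any(is.na(led$final_label)))
    expect_false(anyDuplicated(led$sample_id) > 0)
    # evaluated cohorts are nonincreasing across tiers
    sizes <- vapply(cr$tiers, function(tr) tr$n, numeric(1))
    expect_true(all(diff(sizes) <= 0))
    # tier-2+ cohort is the routed triplicate subsample
    if (length(cr$tiers) > 1) expect_identical(unname(sizes[2]), 51)
  }
  # parallel mode evaluates every tier on the same 51
  crp <- run_cascade(s, tau = 100, subsample_k = 3, mode = "parallel")
  expect_identical(names(crp$tiers),
                   c("dual_isotope", "fa_profile", "csia_fa"))
  expect_identical(unname(vapply(crp$tiers, function(tr) tr$n, numeric(1))),
                   c(102, 51, 51))
  summ <- cascade_summary(crp)
  expect_identical(summ$class, c("CC", "GN", "JB", "JN"))
  expect_identical(sum(summ$dual_isotope_n), 102L)
  expect_identical(sum(summ$fa_profile_n), 51L)
  totals <- attr(summ, "totals")
  expect_identical(names(totals),
                   c("dual_isotope", "fa_profile", "csia_fa"))
  expect_true(all(totals >= 0 & totals <= 100))
})

test_that("missing later-tier features are reported by sample and feature", {
  s <- generate_samples(builtin_fixtures("korea_table1"), seed = 1)
  tiers <- list(cascade_tier("t1", c("d13C", "d15N")),
                cascade_tier("t2", "16:0"))
  expect_error(run_cascade(s, tiers), "absent from the data")

  s2 <- s
  s2[["16:0"]] <- 20
  s2[["16:0"]][5] <- NA
  expect_error(
    run_cascade(s2, tiers, policy = "site_rate_below", tau = 100),
    "sample CC-1-05 is missing feature 16:0"
  )
})

test_that("an informative added feature block does not hurt accuracy", {
  # paired over seeds: base features vs base + a 2-pooled-SD block
  diffs <- vapply(1:10, function(seed) {
    set.seed(seed)
    n_per <- 12
    base <- rbind(matrix(rnorm(n_per * 2), n_per),
                  matrix(rnorm(n_per * 2), n_per)) # uninformative base
    info <- c(rnorm(n_per, 0), rnorm(n_per, 2))    # 2-SD gap block
    labels <- rep(c("a", "b"), each = n_per)
    acc <- function(x) {
      sum(diag(unclass(loocv(x, labels)$confusion))) / (2 * n_per)
    }
    acc(cbind(base, info)) - acc(base)
  }, numeric(1))
  expect_gt(mean(diffs), -0.02)
})
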