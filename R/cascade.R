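# The stepwise authentication cascade: evaluate a cheap tier on everything,
# route what it fails to authenticate to richer (costlier) feature tiers,
# and report each tier's confusion and prediction rates.

#' Define a cascade tier
#'
#' @param name tier name; the three canonical tiers are `"dual_isotope"`
#'   (bulk d13C + d15N), `"fa_profile"` (15-FA relative composition) and
#'   `"csia_fa"` (d13C of individual FAs), but any name is accepted.
#' @param features ordered feature (column) names this tier classifies on.
#' @param priors,scaling passed to [loocv()].
#' @return an object of class `cascade_tier`.
#' @export
cascade_tier <- function(name, features,
                         priors = c("proportional", "uniform"),
                         scaling = c("prefit", "per_fold")) {
  if (!is.character(name) || length(name) != 1 || !nzchar(name)) {
    stopf("'name' must be a non-empty string")
  }
  if (!is.character(features) || length(features) == 0) {
    stopf("tier %s: 'features' must be a non-empty character vector", name)
  }
  structure(
    list(name = name, features = features,
         priors = match.arg(priors), scaling = match.arg(scaling)),
    class = "cascade_tier"
  )
}

# The three canonical tiers over the built-in feature naming.
#' Canonical tier definitions
#'
#' Convenience constructors for the three assay tiers over the column
#' names produced by [generate_samples()].
#' @return a list of three [cascade_tier] objects: dual isotopes, FA
#'   profile, compound-specific d13C-FA.
#' @export
default_tiers <- function() {
  list(
    cascade_tier("dual_isotope", c("d13C", "d15N")),
    cascade_tier("fa_profile", fa_names()),
    cascade_tier("csia_fa", .CSIA_FEATURES)
  )
}

#' Per-class and overall prediction rates of a confusion matrix
#'
#' Per-class rate = 100 x diagonal / row sum, rounded half-up to one
#' decimal. Overall rate = 100 x trace / total, truncated at two decimals
#' — the convention of the reference report tables (e.g. 56/57 -> 98.24).
#' Unrounded values are returned alongside.
#'
#' @param cm a [confusion_matrix] (or plain square count matrix).
#' @return list with `per_class` (named, 1 decimal), `overall`
#'   (2 decimals), `per_class_raw`, `overall_raw`.
#' @export
prediction_rates <- function(cm) {
  m <- unclass(cm)
  if (!is.matrix(m) || nrow(m) != ncol(m) || nrow(m) == 0) {
    stopf("'cm' must be a non-empty square count matrix")
  }
  if (sum(m) == 0) stopf("empty confusion matrix: no samples counted")
  rs <- rowSums(m)
  per_raw <- ifelse(rs > 0, 100 * diag(m) / rs, NA_real_)
  names(per_raw) <- rownames(m)
  overall_raw <- 100 * sum(diag(m)) / sum(m)
  list(
    per_class = round_half_up(per_raw, 1),
    overall = trunc_decimals(overall_raw, 2),
    per_class_raw = per_raw,
    overall_raw = overall_raw
  )
}

#' Pooled prediction rate from per-group counts
#'
#' The "Total (Cross-Val)%" arithmetic: 100 x sum(correct) / sum(cohort),
#' truncated at two decimals.
#'
#' @param correct correctly classified count per group.
#' @param totals cohort size per group.
#' @return pooled percentage (2 decimals).
#' @export
pooled_prediction_rate <- function(correct, totals) {
  if (length(correct) != length(totals)) {
    stopf("'correct' and 'totals' must have equal length")
  }
  if (any(correct > totals) || any(correct < 0) || any(totals < 0)) {
    stopf("counts must satisfy 0 <= correct <= totals")
  }
  if (sum(totals) == 0) stopf("empty cohort")
  trunc_decimals(100 * sum(correct) / sum(totals), 2)
}

#' Select the samples a tier failed to authenticate
#'
#' Two routing readings of "unclassified samples" are supported:
#' `"site_rate_below"` escalates every sample of all sites whose class's
#' per-class LOOCV prediction rate is below `tau` percent (with
#' `tau = 100`, any class that is not perfectly predicted routes — the
#' whole-region triplicate design); `"sample_misclassified"` escalates
#' exactly the individually misclassified samples. With `subsample_k` set,
#' only the first `k` samples per site (by `sample_id` order) are retained
#' for the next tier — `k = 3` reproduces a triplicate design.
#'
#' @param result a [loocv()] result for the current tier.
#' @param samples the data frame the tier was evaluated on (row-aligned
#'   with `result`), with `sample_id` and `site_id` columns.
#' @param policy `"site_rate_below"` or `"sample_misclassified"`.
#' @param tau routing threshold in percent, in (0, 100]; only used by
#'   `"site_rate_below"`.
#' @param subsample_k optional per-site retention count.
#' @param label column of `samples` holding the true class
#'   (default `"region"`).
#' @return character vector of retained routed `sample_id`s, with
#'   attribute `all_routed` (the routed set before subsampling).
#' @export
route_unauthenticated <- function(result, samples,
                                  policy = c("site_rate_below",
                                             "sample_misclassified"),
                                  tau = 100, subsample_k = NULL,
                                  label = "region") {
  policy <- match.arg(policy)
  if (!inherits(result, "loocv_result")) {
    stopf("'result' must come from loocv()")
  }
  if (nrow(samples) != nrow(result$predictions)) {
    stopf("'samples' must be row-aligned with the LOOCV result")
  }
  if (policy == "site_rate_below") {
    if (!is.numeric(tau) || length(tau) != 1 || tau <= 0 || tau > 100) {
      stopf("'tau' must lie in (0, 100]")
    }
    rates <- prediction_rates(result$confusion)$per_class_raw
    weak <- names(rates)[rates < tau]
    routed <- samples$sample_id[samples[[label]] %in% weak]
  } else {
    routed <- samples$sample_id[!result$predictions$correct]
  }
  retained <- routed
  if (!is.null(subsample_k) && length(routed)) {
    k <- as.integer(subsample_k)
    if (is.na(k) || k < 1) stopf("'subsample_k' must be a positive integer")
    site_of <- samples$site_id[match(routed, samples$sample_id)]
    kept <- unlist(lapply(split(routed, site_of), function(ids) {
      ids <- sort(ids)
      if (length(ids) < k) {
        message(sprintf(
          "site %s has only %d routed sample(s) (< k = %d); taking all",
          site_of[match(ids[1], routed)], length(ids), k))
        ids
      } else {
        ids[seq_len(k)]
      }
    }), use.names = FALSE)
    retained <- routed[routed %in% kept]
  }
  attr(retained, "all_routed") <- routed
  retained
}

tier_features_check <- function(samples, tier) {
  missing_cols <- setdiff(tier$features, names(samples))
  if (length(missing_cols)) {
    stopf("tier %s: feature column(s) absent from the data: %s",
          tier$name, paste(missing_cols, collapse = ", "))
  }
  x <- as.matrix(samples[, tier$features, drop = FALSE])
  bad <- which(!is.finite(x), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stopf("tier %s: sample %s is missing feature %s",
          tier$name, samples$sample_id[bad[1, 1]],
          tier$features[bad[1, 2]])
  }
  x
}

#' Run the stepwise authentication cascade
#'
#' Evaluates tier 1 on all samples by LOOCV, routes the unauthenticated
#' material (per `policy`) to tier 2, and so on; samples authenticated at
#' a tier keep that tier's LOOCV-predicted label, the last tier's
#' predictions are final, and every input sample ends with exactly one
#' final label. A tier that authenticates everything short-circuits the
#' rest.
#'
#' In `mode = "parallel"`, tiers after the first are each evaluated
#' independently on the same routed subsample from tier 1 (the fixed
#' triplicate cohort design) rather than nested; the routing ledger then
#' reports the last tier as final.
#'
#' @param samples wide data frame from [generate_samples()] /
#'   [read_samples_csv()].
#' @param tiers ordered list of [cascade_tier]s (default [default_tiers()]
#'   trimmed to the features present).
#' @param policy,tau,subsample_k routing controls, see
#'   [route_unauthenticated()].
#' @param label column holding the true class (`"region"` or `"country"`).
#' @param mode `"stepwise"` (nested routing) or `"parallel"` (fixed
#'   subsample re-evaluated by every later tier).
#' @return an object of class `cascade_result`: per-tier records (`name`,
#'   `n`, `confusion`, `rates`, `loocv`), a `ledger` data frame
#'   (`sample_id`, `true`, `tier`, `status`, `final_label`), and the
#'   routing controls used. Ledger `status` is `"authenticated"` (kept its
#'   tier label), `"subsampled_out"` (site routed but sample not retained;
#'   keeps the tier label), or `"final_tier"`.
#' @export
run_cascade <- function(samples, tiers = NULL,
                        policy = c("site_rate_below", "sample_misclassified"),
                        tau = 100, subsample_k = NULL, label = "region",
                        mode = c("stepwise", "parallel")) {
  policy <- match.arg(policy)
  mode <- match.arg(mode)
  if (is.null(tiers)) {
    tiers <- Filter(function(t) all(t$features %in% names(samples)),
                    default_tiers())
  }
  if (inherits(tiers, "cascade_tier")) tiers <- list(tiers)
  if (length(tiers) == 0) stopf("need at least one tier")
  if (!all(vapply(tiers, inherits, logical(1), "cascade_tier"))) {
    stopf("'tiers' must be cascade_tier objects")
  }
  if (!label %in% names(samples)) stopf("label column '%s' not found", label)
  if (anyDuplicated(samples$sample_id)) stopf("duplicate sample_id values")

  ledger <- data.frame(
    sample_id = samples$sample_id, true = samples[[label]],
    tier = NA_character_, status = NA_character_,
    final_label = NA_character_, stringsAsFactors = FALSE
  )
  finalize <- function(ids, tier_name, status, labels_for) {
    i <- match(ids, ledger$sample_id)
    ledger$tier[i] <<- tier_name
    ledger$status[i] <<- status
    ledger$final_label[i] <<- labels_for
  }

  tier_records <- list()
  cohort <- samples
  for (t in seq_along(tiers)) {
    tier <- tiers[[t]]
    x <- tier_features_check(cohort, tier)
    res <- loocv(x, cohort[[label]], priors = tier$priors,
                 scaling = tier$scaling)
    rates <- prediction_rates(res$confusion)
    tier_records[[tier$name]] <- list(
      name = tier$name, n = nrow(cohort), confusion = res$confusion,
      rates = rates, loocv = res
    )
    last <- t == length(tiers)
    if (last) {
      finalize(cohort$sample_id, tier$name, "final_tier",
               res$predictions$predicted)
      break
    }
    retained <- route_unauthenticated(res, cohort, policy = policy,
                                      tau = tau, subsample_k = subsample_k,
                                      label = label)
    all_routed <- attr(retained, "all_routed")
    kept_here <- setdiff(cohort$sample_id, all_routed)
    finalize(kept_here, tier$name, "authenticated",
             res$predictions$predicted[match(kept_here, cohort$sample_id)])
    dropped <- setdiff(all_routed, retained)
    if (length(dropped)) {
      finalize(dropped, tier$name, "subsampled_out",
               res$predictions$predicted[match(dropped, cohort$sample_id)])
    }
    if (length(retained) == 0) break # tier authenticated everything
    if (mode == "stepwise") {
      cohort <- samples[match(retained, samples$sample_id), , drop = FALSE]
    } else {
      # parallel: every later tier re-evaluates the same tier-1 subsample
      sub <- samples[match(retained, samples$sample_id), , drop = FALSE]
      for (t2 in seq(t + 1, length(tiers))) {
        tier2 <- tiers[[t2]]
        x2 <- tier_features_check(sub, tier2)
        res2 <- loocv(x2, sub[[label]], priors = tier2$priors,
                      scaling = tier2$scaling)
        tier_records[[tier2$name]] <- list(
          name = tier2$name, n = nrow(sub), confusion = res2$confusion,
          rates = prediction_rates(res2$confusion), loocv = res2
        )
        if (t2 == length(tiers)) {
          finalize(sub$sample_id, tier2$name, "final_tier",
                   res2$predictions$predicted)
        }
      }
      break
    }
  }

  structure(
    list(tiers = tier_records, ledger = ledger, policy = policy, tau = tau,
         subsample_k = subsample_k, label = label, mode = mode),
    class = "cascade_result"
  )
}

#' @export
print.cascade_result <- function(x, ...) {
  cat(sprintf("<cascade_result> %s mode, policy %s (tau = %s, k = %s)\n",
              x$mode, x$policy, format(x$tau),
              if (is.null(x$subsample_k)) "none" else x$subsample_k))
  for (tr in x$tiers) {
    cat(sprintf("-- tier %s: n = %d, overall %.2f%%\n",
                tr$name, tr$n, tr$rates$overall))
  }
  cat(sprintf("%d samples finalized across %d evaluated tier(s)\n",
              sum(!is.na(x$ledger$final_label)), length(x$tiers)))
  invisible(x)
}

#' Per-class stepwise summary table
#'
#' One row per true class with, for every evaluated tier, the cohort size
#' and the LOOCV-correct count, plus a pooled "Total (Cross-Val) %" row
#' computed with [pooled_prediction_rate()] — the layout of a stepwise
#' per-country report.
#'
#' @param result a [run_cascade()] result.
#' @return data frame; one `<tier>_n` and `<tier>_correct` column pair per
#'   tier, with attribute `totals` holding the pooled percentage per tier.
#' @export
cascade_summary <- function(result) {
  if (!inherits(result, "cascade_result")) {
    stopf("'result' must come from run_cascade()")
  }
  classes <- sort(unique(result$ledger$true))
  out <- data.frame(class = classes, stringsAsFactors = FALSE)
  totals <- numeric(0)
  for (tr in result$tiers) {
    cm <- unclass(tr$confusion)
    present <- rownames(cm)
    ncol_n <- stats::setNames(rep(0L, length(classes)), classes)
    ncor <- ncol_n
    ncol_n[present] <- as.integer(rowSums(cm))
    ncor[present] <- as.integer(diag(cm))
    out[[paste0(tr$name, "_n")]] <- unname(ncol_n)
    out[[paste0(tr$name, "_correct")]] <- unname(ncor)
    totals[tr$name] <- pooled_prediction_rate(ncor, ncol_n)
  }
  attr(out, "totals") <- totals
  out
}
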