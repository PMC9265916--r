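# Seeded synthetic-sample generation from site specs, plus CSV / config
# serialization of the wide per-sample table.

# Dirichlet draws via normalized gamma variates; alpha = dispersion * mean
# composition, so E[draw] = mean composition and larger dispersion means
# tighter compositional noise.
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)),
              nrow = n, ncol = k)
  sweep(g, 1, rowSums(g), "/")
}

#' Generate synthetic per-sample measurements
#'
#' Draws `n` clams per site from each [site_spec]: Gaussian features
#' independently per feature from the site's (mean, sd); 15-FA compositions
#' from a Dirichlet centred on the site's mean composition with
#' concentration `fa_dispersion`, rescaled to percent. The same seed always
#' reproduces the same table; the caller's RNG state is left untouched.
#'
#' Features are drawn independently within a site: only marginal site
#' moments are public, so no assay covariance is (or can be) emulated.
#'
#' @param specs a list of [site_spec] objects (or a single one).
#' @param seed integer RNG seed.
#' @return data frame with columns `sample_id`, `site_id`, `region`,
#'   `country`, one column per Gaussian feature, and — where specs carry a
#'   composition — one percent column per FA (each row's 15 FA values sum
#'   to 100).
#' @examples
#' head(generate_samples(builtin_fixtures("korea_table1"), seed = 1))
#' @export
generate_samples <- function(specs, seed = 0) {
  if (inherits(specs, "site_spec")) specs <- list(specs)
  if (!is.list(specs) || length(specs) == 0) {
    stopf("'specs' must be a non-empty list of site_spec objects")
  }
  if (!all(vapply(specs, inherits, logical(1), "site_spec"))) {
    stopf("every element of 'specs' must be a site_spec")
  }
  gauss_feats <- unique(unlist(lapply(specs, function(s) {
    names(s$gaussian_features)
  })))
  has_fa <- any(vapply(specs, function(s) !is.null(s$fa_composition),
                       logical(1)))
  fa_feats <- if (has_fa) .FA_NAMES else character(0)

  with_seed(seed, {
    blocks <- lapply(specs, function(s) {
      n <- s$n
      df <- data.frame(
        sample_id = sprintf("%s-%02d", s$site_id, seq_len(n)),
        site_id = s$site_id, region = s$region, country = s$country,
        stringsAsFactors = FALSE
      )
      for (f in gauss_feats) {
        ms <- s$gaussian_features[[f]]
        df[[f]] <- if (is.null(ms)) NA_real_ else {
          stats::rnorm(n, mean = ms["mean"], sd = ms["sd"])
        }
      }
      if (has_fa) {
        if (is.null(s$fa_composition)) {
          for (f in fa_feats) df[[f]] <- NA_real_
        } else {
          comp <- s$fa_composition[.FA_NAMES]
          comp[is.na(comp)] <- 0
          draws <- 100 * rdirichlet(n, s$fa_dispersion * comp)
          for (j in seq_along(fa_feats)) df[[fa_feats[j]]] <- draws[, j]
        }
      }
      df
    })
    out <- do.call(rbind, blocks)
    rownames(out) <- NULL
    out
  })
}

#' Write / read the wide per-sample CSV
#'
#' One row per clam: `sample_id`, `site_id`, `region`, `country`, then the
#' feature columns (UTF-8, `.` decimal separator, ASCII hyphen-minus for
#' negative values).
#'
#' @param samples data frame as produced by [generate_samples()].
#' @param path file path.
#' @return `write_samples_csv` returns `path` invisibly; `read_samples_csv`
#'   returns the data frame with feature column names intact.
#' @export
write_samples_csv <- function(samples, path) {
  utils::write.csv(samples, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_samples_csv
#' @export
read_samples_csv <- function(path) {
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                  fileEncoding = "UTF-8")
}

# ---- spec (de)serialization ----------------------------------------------

spec_to_list <- function(s) {
  out <- list(
    site_id = s$site_id, region = s$region, country = s$country, n = s$n,
    gaussian_features = lapply(s$gaussian_features, function(ms) {
      list(mean = unname(ms["mean"]), sd = unname(ms["sd"]))
    })
  )
  if (!is.null(s$fa_composition)) {
    out$fa_composition <- as.list(s$fa_composition)
    out$fa_dispersion <- s$fa_dispersion
  }
  out
}

spec_from_list <- function(x) {
  site_spec(
    site_id = x$site_id, region = x$region, country = x$country, n = x$n,
    gaussian_features = lapply(x$gaussian_features, function(ms) {
      c(ms$mean, ms$sd)
    }),
    fa_composition = if (!is.null(x$fa_composition)) {
      unlist(x$fa_composition)
    },
    fa_dispersion = x$fa_dispersion
  )
}

#' Serialize site specs to a JSON or YAML config
#'
#' The config schema mirrors the [site_spec] fields (`site_id`, `region`,
#' `country`, `n`, `gaussian_features` as `{mean, sd}` maps, optional
#' `fa_composition` fractions and `fa_dispersion`). Format is chosen by the
#' file extension: `.json`, or `.yml`/`.yaml` (requires the yaml package).
#'
#' @param specs list of [site_spec].
#' @param path config file path.
#' @return `specs_to_config` returns `path` invisibly; `specs_from_config`
#'   returns a list of [site_spec].
#' @export
specs_to_config <- function(specs, path) {
  if (inherits(specs, "site_spec")) specs <- list(specs)
  payload <- lapply(specs, spec_to_list)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stopf("the 'yaml' package is required for YAML configs")
    }
    writeLines(yaml::as.yaml(payload), path)
  } else {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' @rdname specs_to_config
#' @export
specs_from_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  payload <- if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stopf("the 'yaml' package is required for YAML configs")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = FALSE)
  }
  lapply(payload, spec_from_list)
}
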