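# Site-level reference fixtures and their constructor.
#
# The study's raw per-sample measurements were never deposited; what is
# public is site-level summary structure: per-site mean +/- SD of bulk
# d13C/d15N for 17 Korean sites (with per-site n), per-site mean +/- SD of
# d13C for 6 individual fatty acids (3 clams per site), and country-level
# bulk isotope summaries for China, DPR Korea and Korea. Those summaries
# are carried here verbatim as `site_spec` objects; the 15-FA compositional
# profiles are NOT public and the "fa_profiles_synthetic" set is a
# constructed stand-in (see its docs).

#' Construct a site specification
#'
#' A `site_spec` holds everything the synthetic-sample generator needs for
#' one collection site: its labels, its sample count, per-feature Gaussian
#' moments, and (optionally) a mean fatty-acid composition with a Dirichlet
#' concentration controlling compositional noise.
#'
#' @param site_id short site label, e.g. `"CC-1"`.
#' @param region region code (`"CC"`, `"JB"`, `"JN"`, `"GN"`, `"CHN"`,
#'   `"NK"` in the built-in fixtures; any label is accepted).
#' @param country country code (`"KOR"`, `"CHN"`, `"NK"` in the built-ins).
#' @param n number of clams sampled at the site (>= 1).
#' @param gaussian_features named list; each element is `c(mean, sd)` in
#'   feature units (per mil for isotope features). `sd` must be >= 0.
#' @param fa_composition optional named vector of 15 FA mean relative
#'   abundances as fractions summing to 1.
#' @param fa_dispersion positive Dirichlet concentration scalar for
#'   compositional noise (larger = tighter around `fa_composition`);
#'   required when `fa_composition` is given.
#' @return an object of class `site_spec`.
#' @export
site_spec <- function(site_id, region, country, n, gaussian_features = list(),
                      fa_composition = NULL, fa_dispersion = NULL) {
  if (!is.character(site_id) || length(site_id) != 1 || !nzchar(site_id)) {
    stopf("'site_id' must be a non-empty string")
  }
  n <- as.integer(n)
  if (is.na(n) || n < 1) stopf("site %s: 'n' must be an integer >= 1", site_id)
  if (length(gaussian_features)) {
    if (is.null(names(gaussian_features)) ||
        any(!nzchar(names(gaussian_features)))) {
      stopf("site %s: 'gaussian_features' must be a named list", site_id)
    }
    for (f in names(gaussian_features)) {
      ms <- gaussian_features[[f]]
      if (length(ms) != 2 || any(!is.finite(ms))) {
        stopf("site %s, feature %s: expected c(mean, sd)", site_id, f)
      }
      if (ms[2] < 0) stopf("site %s, feature %s: sd must be >= 0", site_id, f)
      gaussian_features[[f]] <- stats::setNames(as.numeric(ms), c("mean", "sd"))
    }
  }
  if (!is.null(fa_composition)) {
    if (is.null(names(fa_composition))) {
      stopf("site %s: 'fa_composition' must be named", site_id)
    }
    if (any(fa_composition < 0)) {
      stopf("site %s: FA composition must be nonnegative", site_id)
    }
    if (abs(sum(fa_composition) - 1) > 1e-9) {
      stopf("site %s: FA composition must sum to 1 (got %.12f)",
            site_id, sum(fa_composition))
    }
    if (is.null(fa_dispersion) || !is.finite(fa_dispersion) ||
        fa_dispersion <= 0) {
      stopf("site %s: 'fa_dispersion' must be a positive scalar", site_id)
    }
  }
  structure(
    list(
      site_id = site_id, region = region, country = country, n = n,
      gaussian_features = gaussian_features,
      fa_composition = fa_composition,
      fa_dispersion = if (is.null(fa_composition)) NULL else fa_dispersion
    ),
    class = "site_spec"
  )
}

#' @export
print.site_spec <- function(x, ...) {
  cat(sprintf("<site_spec> %s (%s/%s), n = %d\n",
              x$site_id, x$region, x$country, x$n))
  for (f in names(x$gaussian_features)) {
    ms <- x$gaussian_features[[f]]
    cat(sprintf("  %-12s %8.2f +/- %.2f\n", f, ms["mean"], ms["sd"]))
  }
  if (!is.null(x$fa_composition)) {
    cat(sprintf("  15-FA composition (dispersion %.0f)\n", x$fa_dispersion))
  }
  invisible(x)
}

# ---- raw fixture tables ---------------------------------------------------
# Bulk isotopes of Korean sites: region, site, d13C mean/sd, d15N mean/sd, n.
.KOREA_BULK <- data.frame(
  region = rep(c("CC", "JB", "JN", "GN"), c(5, 4, 4, 4)),
  site_id = c("CC-1", "CC-2", "CC-3", "CC-4", "CC-5",
              "JB-1", "JB-2", "JB-3", "JB-4",
              "JN-1", "JN-2", "JN-3", "JN-4",
              "GN-1", "GN-2", "GN-3", "GN-4"),
  d13C = c(-18.0, -18.3, -18.4, -17.6, -17.5,
           -17.1, -16.6, -17.4, -16.4,
           -16.5, -17.1, -16.9, -16.9,
           -16.8, -15.7, -16.3, -15.8),
  d13C_sd = c(0.2, 0.3, 0.1, 0.4, 0.3,
              0.1, 0.3, 0.1, 0.4,
              0.3, 0.1, 0.2, 0.2,
              0.3, 0.1, 0.1, 0.2),
  d15N = c(8.9, 6.8, 6.4, 9.1, 8.6,
           9.6, 9.1, 10.0, 8.7,
           7.7, 10.0, 9.0, 9.1,
           8.8, 10.6, 9.8, 11.0),
  d15N_sd = c(0.2, 0.3, 0.4, 0.2, 0.4,
              0.4, 0.3, 0.3, 0.4,
              0.1, 0.2, 0.1, 0.1,
              0.2, 0.2, 0.2, 0.1),
  n = c(5, 5, 5, 5, 5,
        10, 5, 5, 5,
        10, 3, 3, 10,
        8, 10, 3, 5),
  stringsAsFactors = FALSE
)

# d13C of six individual fatty acids per Korean site (mean, sd); three
# clams per site (17 x 3 = 51).
.CSIA_FEATURES <- c("d13C_16:0", "d13C_18:0", "d13C_18:1n-7",
                    "d13C_18:1n-9", "d13C_20:1n-7", "d13C_20:1n-9")
.KOREA_CSIA_MEAN <- matrix(c(
  -23.1, -24.6, -20.9, -15.2, -22.9, -21.0,
  -24.4, -25.3, -22.5, -15.6, -25.0, -22.4,
  -24.4, -25.3, -22.2, -15.5, -24.6, -21.3,
  -25.0, -25.3, -21.1, -18.5, -20.7, -19.9,
  -24.9, -25.0, -20.2, -17.9, -20.6, -20.4,
  -20.4, -24.5, -20.6, -15.6, -21.0, -20.9,
  -21.9, -21.4, -21.4, -15.0, -21.1, -21.6,
  -26.8, -26.1, -24.5, -19.6, -24.8, -21.7,
  -23.5, -21.2, -21.2, -17.5, -21.5, -23.6,
  -22.2, -19.8, -20.7, -16.8, -20.6, -21.3,
  -23.2, -19.8, -22.0, -18.0, -21.5, -23.1,
  -23.4, -21.2, -22.6, -18.0, -20.9, -23.3,
  -23.5, -20.6, -22.1, -18.0, -21.8, -23.4,
  -24.5, -24.2, -27.1, -19.5, -26.1, -23.6,
  -21.6, -22.1, -25.6, -17.8, -24.6, -18.0,
  -21.9, -22.2, -25.5, -17.8, -24.8, -18.0,
  -22.0, -22.2, -25.7, -17.8, -24.8, -18.1
), nrow = 17, byrow = TRUE,
  dimnames = list(.KOREA_BULK$site_id, .CSIA_FEATURES))
.KOREA_CSIA_SD <- matrix(c(
  0.4, 0.4, 0.8, 0.7, 0.5, 0.7,
  0.4, 0.4, 0.4, 0.5, 0.3, 0.3,
  0.4, 0.4, 0.3, 0.4, 0.3, 0.5,
  0.5, 0.3, 0.7, 0.5, 0.5, 0.3,
  0.4, 0.3, 0.4, 0.4, 0.6, 0.5,
  0.5, 0.4, 0.5, 0.5, 0.4, 0.4,
  0.4, 0.8, 0.5, 0.7, 0.9, 0.5,
  0.4, 0.8, 0.7, 0.5, 0.6, 0.6,
  0.4, 0.3, 0.4, 0.5, 0.4, 0.5,
  0.4, 0.3, 0.5, 0.5, 0.5, 0.5,
  0.3, 0.4, 0.5, 0.4, 0.5, 0.5,
  0.4, 0.6, 0.5, 0.4, 0.6, 0.4,
  0.3, 0.5, 0.6, 0.4, 0.4, 0.5,
  0.6, 0.6, 0.7, 0.6, 0.5, 0.6,
  0.5, 0.3, 0.6, 0.6, 0.5, 0.6,
  0.3, 0.4, 0.6, 0.3, 0.3, 0.5,
  0.5, 0.7, 0.5, 0.4, 0.5, 0.3
), nrow = 17, byrow = TRUE,
  dimnames = list(.KOREA_BULK$site_id, .CSIA_FEATURES))

# Country-level bulk isotopes: China (Dalian), DPR Korea, Korea pooled.
.COUNTRIES_BULK <- data.frame(
  site_id = c("CHN", "NK", "KOR"),
  region = c("CHN", "NK", "KOR"),
  country = c("CHN", "NK", "KOR"),
  d13C = c(-17.58, -17.69, -16.94),
  d13C_sd = c(0.39, 0.38, 0.79),
  d15N = c(9.67, 8.95, 9.01),
  d15N_sd = c(0.72, 0.24, 1.18),
  n = c(15, 16, 102),
  stringsAsFactors = FALSE
)

# Constructed region-level 15-FA mean compositions (percent), chosen to obey
# the reported compositional envelope (SFA within 26.20-65.48 %, PUFA within
# 10.23-32.33 % of total FAs), 16:0 and 18:0 dominant among SFAs, EPA/DHA
# dominant among PUFAs, and DHA/EPA > 1 only in GN (dinoflagellate-leaning
# diet there). These are synthetic: the study's per-site abundances are not
# public.
.FA_REGION_BASE <- list(
  CC = c(3.0, 1.0, 27.0, 1.5, 12.5,  9.0, 5.0, 4.0, 4.5, 4.5,
         1.5, 1.0, 2.5, 14.0, 9.0),
  JB = c(3.5, 1.5, 32.0, 2.5, 15.5,  6.0, 6.5, 3.5, 4.5, 4.5,
         1.5, 1.0, 2.0, 9.0, 6.5),
  JN = c(2.5, 1.0, 24.0, 1.5, 11.0,  7.0, 6.0, 6.0, 6.5, 6.5,
         2.0, 1.5, 2.5, 12.0, 10.0),
  GN = c(2.0, 0.8, 23.0, 1.2, 11.0,  5.0, 4.0, 9.0, 6.0, 6.0,
         2.0, 1.5, 2.5, 10.0, 16.0)
)

.korea_table1_specs <- function() {
  lapply(seq_len(nrow(.KOREA_BULK)), function(i) {
    r <- .KOREA_BULK[i, ]
    site_spec(
      site_id = r$site_id, region = r$region, country = "KOR", n = r$n,
      gaussian_features = list(
        d13C = c(r$d13C, r$d13C_sd),
        d15N = c(r$d15N, r$d15N_sd)
      )
    )
  })
}

.csia_table4_specs <- function() {
  lapply(seq_len(nrow(.KOREA_BULK)), function(i) {
    sid <- .KOREA_BULK$site_id[i]
    gf <- lapply(.CSIA_FEATURES, function(f) {
      c(.KOREA_CSIA_MEAN[sid, f], .KOREA_CSIA_SD[sid, f])
    })
    names(gf) <- .CSIA_FEATURES
    site_spec(site_id = sid, region = .KOREA_BULK$region[i],
              country = "KOR", n = 3L, gaussian_features = gf)
  })
}

.countries_table6_specs <- function() {
  lapply(seq_len(nrow(.COUNTRIES_BULK)), function(i) {
    r <- .COUNTRIES_BULK[i, ]
    site_spec(
      site_id = r$site_id, region = r$region, country = r$country, n = r$n,
      gaussian_features = list(
        d13C = c(r$d13C, r$d13C_sd),
        d15N = c(r$d15N, r$d15N_sd)
      )
    )
  })
}

.fa_profiles_synthetic_specs <- function() {
  lapply(seq_len(nrow(.KOREA_BULK)), function(i) {
    sid <- .KOREA_BULK$site_id[i]
    region <- .KOREA_BULK$region[i]
    base <- .FA_REGION_BASE[[region]]
    names(base) <- .FA_NAMES
    # small within-region site-to-site shift: trade 16:0 against 18:0 so
    # class totals (and the compositional envelope) are untouched
    k <- as.integer(sub(".*-", "", sid))
    shift <- 0.6 * (k - 2.5)
    base["16:0"] <- base["16:0"] + shift
    base["18:0"] <- base["18:0"] - shift
    site_spec(site_id = sid, region = region, country = "KOR", n = 3L,
              fa_composition = base / sum(base), fa_dispersion = 1200)
  })
}

#' Built-in site-level fixtures
#'
#' Returns the reference `site_spec` sets that drive the synthetic-sample
#' generator:
#'
#' * `"korea_table1"` — 17 Korean sites (regions CC, JB, JN, GN; total
#'   n = 102) with bulk `d13C`/`d15N` mean and SD per site.
#' * `"csia_table4"` — the same 17 sites with mean and SD of `d13C` for six
#'   individual fatty acids (16:0, 18:0, 18:1n-7, 18:1n-9, 20:1n-7,
#'   20:1n-9), three clams per site.
#' * `"countries_table6"` — country-level bulk `d13C`/`d15N` for China
#'   (n = 15), DPR Korea (n = 16) and Korea (n = 102).
#' * `"fa_profiles_synthetic"` — constructed (not measured) 15-FA mean
#'   compositions for the 17 Korean sites, three clams per site, obeying
#'   the reported compositional envelope; see the package vignette.
#'
#' @param name one of the four fixture-set names above.
#' @return list of [site_spec] objects.
#' @examples
#' specs <- builtin_fixtures("korea_table1")
#' sum(vapply(specs, function(s) s$n, integer(1))) # 102 clams
#' @export
builtin_fixtures <- function(name = c("korea_table1", "csia_table4",
                                      "countries_table6",
                                      "fa_profiles_synthetic")) {
  if (length(name) != 1 && !identical(name, eval(formals()$name))) {
    stopf("'name' must be a single fixture name")
  }
  name <- match.arg(name)
  switch(name,
    korea_table1 = .korea_table1_specs(),
    csia_table4 = .csia_table4_specs(),
    countries_table6 = .countries_table6_specs(),
    fa_profiles_synthetic = .fa_profiles_synthetic_specs()
  )
}

#' Merge two site-spec lists by site
#'
#' Combines feature sets of specs that describe the same sites, so one
#' generator call can emit every tier's features for a sample. Gaussian
#' features are unioned (conflicting duplicate definitions are an error);
#' FA composition fields are taken from whichever side defines them. Sample
#' counts come from `x`.
#'
#' @param x,y lists of [site_spec]; every `site_id` in `y` must appear in
#'   `x`.
#' @return list of merged [site_spec] objects, in the order of `x`.
#' @export
merge_specs <- function(x, y) {
  ids_x <- vapply(x, function(s) s$site_id, character(1))
  ids_y <- vapply(y, function(s) s$site_id, character(1))
  if (!all(ids_y %in% ids_x)) {
    stopf("sites in 'y' missing from 'x': %s",
          paste(setdiff(ids_y, ids_x), collapse = ", "))
  }
  lapply(x, function(s) {
    j <- match(s$site_id, ids_y)
    if (is.na(j)) return(s)
    o <- y[[j]]
    shared <- intersect(names(s$gaussian_features), names(o$gaussian_features))
    for (f in shared) {
      if (!isTRUE(all.equal(s$gaussian_features[[f]],
                            o$gaussian_features[[f]]))) {
        stopf("site %s: conflicting definitions of feature %s", s$site_id, f)
      }
    }
    site_spec(
      site_id = s$site_id, region = s$region, country = s$country, n = s$n,
      gaussian_features = c(
        s$gaussian_features,
        o$gaussian_features[setdiff(names(o$gaussian_features),
                                    names(s$gaussian_features))]
      ),
      fa_composition = if (!is.null(s$fa_composition)) s$fa_composition
                       else o$fa_composition,
      fa_dispersion = if (!is.null(s$fa_composition)) s$fa_dispersion
                      else o$fa_dispersion
    )
  })
}

#' Sample-size-weighted regional means of a fixture feature
#'
#' Aggregates per-site fixture means to region (or country) level, weighting
#' each site by its sample count — the arithmetic behind the "Average" rows
#' of the site summary tables.
#'
#' @param specs list of [site_spec].
#' @param feature a Gaussian feature name, e.g. `"d13C"`.
#' @param by `"region"` or `"country"`.
#' @return named numeric vector of weighted means (unrounded).
#' @export
fixture_region_means <- function(specs, feature, by = c("region", "country")) {
  by <- match.arg(by)
  has <- vapply(specs, function(s) feature %in% names(s$gaussian_features),
                logical(1))
  if (!any(has)) stopf("no spec defines feature %s", feature)
  specs <- specs[has]
  g <- vapply(specs, function(s) s[[by]], character(1))
  m <- vapply(specs, function(s) s$gaussian_features[[feature]][["mean"]],
              numeric(1))
  n <- vapply(specs, function(s) s$n, integer(1))
  vapply(split(seq_along(m), g)[unique(g)],
         function(i) stats::weighted.mean(m[i], n[i]), numeric(1))
}

# ---- published classification outcomes (report arithmetic inputs) --------

.REGION_ORDER <- c("CC", "GN", "JB", "JN")

.PRINTED_CONFUSIONS <- list(
  # LOOCV counts, rows = true region, columns = predicted region
  dual_isotope_regions = matrix(
    c(21, 0, 3, 1,
      0, 19, 2, 5,
      0, 2, 15, 8,
      0, 0, 12, 14),
    nrow = 4, byrow = TRUE,
    dimnames = list(.REGION_ORDER, .REGION_ORDER)
  ),
  fa_profile_regions = matrix(
    c(15, 0, 0, 0,
      0, 12, 0, 0,
      0, 0, 12, 0,
      0, 0, 0, 12),
    nrow = 4, byrow = TRUE,
    dimnames = list(.REGION_ORDER, .REGION_ORDER)
  ),
  csia_regions = matrix(
    c(14, 0, 1, 0,
      0, 12, 0, 0,
      1, 0, 7, 4,
      0, 0, 0, 12),
    nrow = 4, byrow = TRUE,
    dimnames = list(.REGION_ORDER, .REGION_ORDER)
  )
)

#' Published LOOCV confusion counts
#'
#' The reference classification outcomes of the three single-tier analyses
#' on the Korean regions, as counts (rows = true region, columns =
#' LOOCV-predicted region): the dual-isotope tier (n = 102), the FA-profile
#' tier on the 51 escalated triplicates, and the compound-specific
#' delta13C-FA tier on the same 51. These are inputs for report arithmetic
#' ([prediction_rates()]), not outputs of this package's classifier.
#'
#' @param name `"dual_isotope_regions"`, `"fa_profile_regions"` or
#'   `"csia_regions"`.
#' @return a [confusion_matrix] object.
#' @export
builtin_confusion <- function(name = c("dual_isotope_regions",
                                       "fa_profile_regions",
                                       "csia_regions")) {
  name <- match.arg(name)
  m <- .PRINTED_CONFUSIONS[[name]]
  structure(m, class = c("confusion_matrix", class(m)))
}

#' Published stepwise per-country outcomes
#'
#' Per-country cohort sizes and LOOCV-correct counts of the three-country
#' stepwise analysis: the dual-isotope tier on all 133 clams, then the
#' FA-profile and delta13C-FA tiers each on the 57-clam subsample (51
#' Korean triplicates + 3 Chinese + 3 DPR Korean). Pooled totals follow
#' with [pooled_prediction_rate()].
#'
#' @return data frame with columns `country`, `tier`, `cohort_n`,
#'   `correct`.
#' @export
builtin_stepwise_counts <- function() {
  data.frame(
    country = rep(c("CHN", "KOR", "NK"), times = 3),
    tier = rep(c("dual_isotope", "fa_profile", "csia_fa"), each = 3),
    cohort_n = c(15, 102, 16, 3, 51, 3, 3, 51, 3),
    correct = c(4, 98, 1, 3, 51, 2, 3, 51, 3),
    stringsAsFactors = FALSE
  )
}
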