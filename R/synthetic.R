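#' Scenario configuration for the synthetic-data generators
#'
#' Bundles every knob the generators need. Defaults emulate the scale of a
#' national electrofishing survey reduced to desk size: 26 species (the
#' paper-scale pool), 300 sites monitored over 5 years in 4 watersheds,
#' lognormal densities, and land-use effects expressed directly on the
#' community-index scale.
#'
#' @param n_species number of species.
#' @param n_sites number of sampling sites.
#' @param n_years number of sampled years per site.
#' @param n_watersheds number of watershed blocks.
#' @param trait_schema named counts of trait columns per kind.
#' @param missingness per-cell missingness probability for trait tables.
#' @param sigma_site standard deviation of the site random intercept, on
#'   the community-index scale.
#' @param sigma_resid occasion-level residual standard deviation, on the
#'   community-index scale.
#' @param landuse_variant classification variant for generated land use.
#' @param class_effects named numeric shifts of the expected community
#'   index per land-use class relative to the reference (index units);
#'   default all zero.
#' @param landuse_proportions class probabilities for land-use assignment;
#'   default uniform over the variant's classes.
#' @param density_meanlog,density_sdlog lognormal parameters of species
#'   baseline densities.
#' @param density_noise_sdlog lognormal sd of per-occasion multiplicative
#'   density noise.
#' @param year0 first survey year.
#' @param seed integer seed recorded in every generated output.
#' @return list of class `scenario_config`.
#' @export
scenario_config <- function(n_species = 26L, n_sites = 300L, n_years = 5L,
                            n_watersheds = 4L,
                            trait_schema = c(quantitative = 3L, ordinal = 2L,
                                             nominal = 1L, binary = 1L),
                            missingness = 0,
                            sigma_site = 0.004, sigma_resid = 0.006,
                            landuse_variant = "ONEMA7",
                            class_effects = NULL,
                            landuse_proportions = NULL,
                            density_meanlog = 2, density_sdlog = 1,
                            density_noise_sdlog = 0.2,
                            year0 = 2000L, seed = 1L) {
  classes <- landuse_variants()[[landuse_variant]]
  if (is.null(classes)) stop("unknown land-use variant: ", landuse_variant)
  if (is.null(class_effects)) {
    class_effects <- stats::setNames(rep(0, length(classes)), classes)
  } else {
    bad <- setdiff(names(class_effects), classes)
    if (length(bad)) stop("effect(s) for unknown class(es): ", paste(bad, collapse = ", "))
    full <- stats::setNames(rep(0, length(classes)), classes)
    full[names(class_effects)] <- class_effects
    class_effects <- full
  }
  if (is.null(landuse_proportions)) {
    landuse_proportions <- stats::setNames(rep(1 / length(classes), length(classes)), classes)
  }
  stopifnot(n_species >= 2L, n_sites >= 2L, n_years >= 1L, n_watersheds >= 1L,
            missingness >= 0, missingness < 1,
            sigma_site >= 0, sigma_resid >= 0)
  structure(list(n_species = n_species, n_sites = n_sites, n_years = n_years,
                 n_watersheds = n_watersheds, trait_schema = trait_schema,
                 missingness = missingness, sigma_site = sigma_site,
                 sigma_resid = sigma_resid, landuse_variant = landuse_variant,
                 class_effects = class_effects,
                 landuse_proportions = landuse_proportions,
                 density_meanlog = density_meanlog, density_sdlog = density_sdlog,
                 density_noise_sdlog = density_noise_sdlog,
                 year0 = year0, seed = seed),
            class = "scenario_config")
}

.species_ids <- function(n) sprintf("sp%02d", seq_len(n))
.site_ids <- function(n) sprintf("site%04d", seq_len(n))

#' Generate a mixed-type trait table
#'
#' Quantitative traits are standard normal, ordinal traits discrete uniform
#' on 1..5, nominal traits uniform over three states, binary traits
#' Bernoulli(0.5). Missing cells are drawn uniformly at the configured
#' rate, re-drawn if a column would lose all its values.
#'
#' @param cfg a [scenario_config()] (fields `n_species`, `trait_schema`,
#'   `missingness`, `seed` are used).
#' @return a [trait_table()].
#' @export
gen_trait_table <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  schema <- cfg$trait_schema
  if (sum(schema) == 0L) stop("trait schema declares zero traits")
  n <- cfg$n_species
  set.seed(cfg$seed)
  cols <- list()
  kinds <- character()
  for (kind in names(schema)) {
    for (j in seq_len(schema[[kind]])) {
      nm <- paste0(substr(kind, 1, 4), j)
      cols[[nm]] <- switch(kind,
        quantitative = stats::rnorm(n),
        ordinal = sample.int(5L, n, replace = TRUE),
        nominal = sample(c("s1", "s2", "s3"), n, replace = TRUE),
        binary = as.character(stats::rbinom(n, 1L, 0.5)),
        stop("unknown trait kind: ", kind))
      kinds[nm] <- kind
    }
  }
  df <- as.data.frame(cols, stringsAsFactors = FALSE)
  if (cfg$missingness > 0) {
    for (j in seq_along(df)) {
      repeat {
        mask <- stats::runif(n) < cfg$missingness
        if (!all(mask)) break
      }
      df[[j]][mask] <- NA
    }
  }
  df$species_id <- .species_ids(n)
  trait_table(df, kinds = kinds)
}

#' Generate a random ultrametric tree
#'
#' Sequential random coalescence ([ape::rcoal()]): lineages merge pairwise
#' at random until a single root remains, so every tip sits at the same
#' depth by construction.
#'
#' @param n_tips number of tips (>= 2).
#' @param seed integer seed.
#' @return ultrametric `phylo` tree with tips `sp01`, `sp02`, ...
#' @export
gen_ultrametric_tree <- function(n_tips, seed = 1L) {
  if (n_tips < 2L) stop("need at least 2 tips")
  set.seed(seed)
  ape::rcoal(n_tips, tip.label = .species_ids(n_tips))
}

#' Generate a per-site land-use table
#'
#' Multinomial assignment over the variant's classes; the reference class
#' is guaranteed non-empty (the first site is recoded if necessary).
#'
#' @param site_ids character site ids.
#' @param variant classification variant name.
#' @param proportions class probabilities (named over the variant's
#'   classes, summing to 1); default uniform.
#' @param seed integer seed.
#' @param reference reference class to keep non-empty.
#' @return a [landuse_table()].
#' @export
gen_landuse <- function(site_ids, variant = "ONEMA7", proportions = NULL,
                        seed = 1L, reference = "Forest") {
  classes <- landuse_variants()[[variant]]
  if (is.null(classes)) stop("unknown land-use variant: ", variant)
  if (is.null(proportions)) {
    proportions <- stats::setNames(rep(1 / length(classes), length(classes)), classes)
  }
  if (!setequal(names(proportions), classes)) {
    stop("proportions must be named over the variant's classes")
  }
  proportions <- proportions[classes]
  if (abs(sum(proportions) - 1) > 1e-8) stop("proportions must sum to 1")
  set.seed(seed)
  cls <- sample(classes, length(site_ids), replace = TRUE, prob = proportions)
  if (!reference %in% cls) cls[1L] <- reference
  landuse_table(data.frame(site_id = site_ids, class = cls,
                           stringsAsFactors = FALSE),
                variant = variant, reference = reference)
}

#' Generate a survey table with a controlled land-use effect
#'
#' Simulates occasion-level species densities whose community-weighted
#' index carries a configured shift per land-use class. Species baseline
#' densities are lognormal; for each occasion a target index is drawn as
#' `mu0 + effect(class) + site intercept + residual` (site intercepts
#' `N(0, sigma_site^2)`, residuals `N(0, sigma_resid^2)`), where `mu0` is
#' the baseline-weighted mean score, and the species density profile is
#' exponentially tilted along the score vector until its weighted mean
#' matches the target. Independent lognormal noise then perturbs each
#' density, so realized indices scatter around the target. Sites are laid
#' out in watershed blocks along the x axis.
#'
#' @param cfg a [scenario_config()].
#' @param scores a [species_scores()] vector (one score per species; ids
#'   must match the config's species count).
#' @param landuse a [landuse_table()] covering the config's sites;
#'   generated from the config when `NULL`.
#' @return list with `survey` (site, year, species, density), `context`
#'   (a [site_context()]), `landuse`, and `expected` (per-site expected
#'   index before noise).
#' @export
gen_survey <- function(cfg, scores, landuse = NULL) {
  stopifnot(inherits(cfg, "scenario_config"), inherits(scores, "species_scores"))
  n_sp <- length(scores)
  if (n_sp != cfg$n_species) stop("score vector length differs from config n_species")
  X <- as.numeric(scores)
  rng <- range(X)
  if (diff(rng) <= 0) stop("scores are constant; no index gradient is expressible")

  set.seed(cfg$seed + 1L)
  site_ids <- .site_ids(cfg$n_sites)
  if (is.null(landuse)) {
    landuse <- gen_landuse(site_ids, variant = cfg$landuse_variant,
                           proportions = cfg$landuse_proportions,
                           seed = cfg$seed + 2L)
  }
  unknown <- setdiff(site_ids, landuse$site_id)
  if (length(unknown)) stop("land-use table misses generated site(s)")

  b <- stats::rlnorm(n_sp, cfg$density_meanlog, cfg$density_sdlog)
  mu0 <- sum(b * X) / sum(b)
  effects <- cfg$class_effects
  lo <- rng[1L] + 0.02 * diff(rng)
  hi <- rng[2L] - 0.02 * diff(rng)
  if (any(mu0 + effects < rng[1L] | mu0 + effects > rng[2L])) {
    stop("class effect(s) push the target index outside the score range")
  }

  ws <- sprintf("W%d", 1L + (seq_len(cfg$n_sites) - 1L) %% cfg$n_watersheds)
  x <- (match(ws, sort(unique(ws))) - 1L) / max(1L, cfg$n_watersheds) +
    stats::runif(cfg$n_sites, 0, 1 / max(1L, cfg$n_watersheds))
  y <- stats::runif(cfg$n_sites)
  ctx <- site_context(data.frame(site_id = site_ids, x = x, y = y,
                                 watershed = ws, stringsAsFactors = FALSE))

  u <- stats::rnorm(cfg$n_sites, 0, cfg$sigma_site)
  site_class <- as.character(landuse$class[match(site_ids, landuse$site_id)])
  site_target <- mu0 + effects[site_class] + u

  tilt_weights <- function(target) {
    f <- function(theta) {
      w <- b * exp(theta * (X - mean(X)))
      sum(w * X) / sum(w) - target
    }
    lo_t <- -1
    hi_t <- 1
    while (f(lo_t) > 0) lo_t <- lo_t * 2
    while (f(hi_t) < 0) hi_t <- hi_t * 2
    theta <- stats::uniroot(f, c(lo_t, hi_t), tol = 1e-10)$root
    b * exp(theta * (X - mean(X)))
  }

  years <- cfg$year0 + seq_len(cfg$n_years) - 1L
  n_occ <- cfg$n_sites * cfg$n_years
  dens <- matrix(NA_real_, n_occ, n_sp)
  occ_site <- integer(n_occ)
  occ_year <- integer(n_occ)
  k <- 0L
  for (s in seq_len(cfg$n_sites)) {
    for (yr in years) {
      k <- k + 1L
      tau <- min(max(site_target[s] + stats::rnorm(1L, 0, cfg$sigma_resid), lo), hi)
      w <- tilt_weights(tau)
      dens[k, ] <- w * stats::rlnorm(n_sp, -cfg$density_noise_sdlog^2 / 2,
                                     cfg$density_noise_sdlog)
      occ_site[k] <- s
      occ_year[k] <- yr
    }
  }
  survey <- data.frame(
    site_id = rep(site_ids[occ_site], each = n_sp),
    year = rep(occ_year, each = n_sp),
    species_id = rep(names(scores), times = n_occ),
    density = as.vector(t(dens)),
    stringsAsFactors = FALSE
  )
  list(survey = survey, context = ctx, landuse = landuse,
       expected = data.frame(site_id = site_ids, class = site_class,
                             expected_index = as.numeric(site_target),
                             stringsAsFactors = FALSE),
       mu0 = mu0, seed = cfg$seed)
}

#' Generate an abiotic site table
#'
#' Correlated river-position variables: an upstream-downstream position
#' drives temperature sum, longitudinal gradient, log elevation and slope
#' with independent noise, emulating the headwater-to-lowland structure of
#' national survey networks.
#'
#' @param n_sites number of sites.
#' @param seed integer seed.
#' @return data.frame with `site_id` and the four abiotic variables.
#' @export
gen_abiotic <- function(n_sites, seed = 1L) {
  set.seed(seed)
  pos <- stats::runif(n_sites)  # 0 = headwater, 1 = lowland
  data.frame(
    site_id = .site_ids(n_sites),
    temperature_sum = 60 + 40 * pos + stats::rnorm(n_sites, 0, 5),
    longitudinal_gradient = pos + stats::rnorm(n_sites, 0, 0.05),
    log_elevation = log(1500) - 2.5 * pos + stats::rnorm(n_sites, 0, 0.3),
    slope = exp(1.5 - 3 * pos + stats::rnorm(n_sites, 0, 0.4)),
    stringsAsFactors = FALSE
  )
}
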