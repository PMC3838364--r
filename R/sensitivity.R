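#' Land-use classification variants
#'
#' Class vocabularies for the three nested land-cover groupings used to test
#' indicator reproducibility, each ordered along the artificialization
#' gradient from the natural reference ("Forest") to the most artificial
#' class. `CLC5` has 5 classes, `EUROWATER6` adds "Intensive Urban",
#' `ONEMA7` further adds "Intensive Farming".
#'
#' @return named list of ordered class vectors.
#' @export
landuse_variants <- function() {
  list(
    CLC5 = c("Forest", "Meadow", "Farming", "Mix", "Urban"),
    EUROWATER6 = c("Forest", "Meadow", "Farming", "Mix", "Urban", "Intensive Urban"),
    ONEMA7 = c("Forest", "Meadow", "Farming", "Intensive Farming", "Mix",
               "Urban", "Intensive Urban")
  )
}

#' Construct a per-site land-use table
#'
#' @param df data.frame with columns `site_id` and `class`.
#' @param variant one of `"CLC5"`, `"EUROWATER6"`, `"ONEMA7"`.
#' @param reference natural reference class (default `"Forest"`).
#' @return data.frame of class `landuse_table`, `class` as a factor with
#'   the reference as first level and the variant's gradient order after.
#' @export
landuse_table <- function(df, variant = c("ONEMA7", "CLC5", "EUROWATER6"),
                          reference = "Forest") {
  variant <- match.arg(variant)
  classes <- landuse_variants()[[variant]]
  stopifnot(all(c("site_id", "class") %in% names(df)))
  if (anyDuplicated(df$site_id)) stop("duplicate site ids in land-use table")
  bad <- setdiff(unique(as.character(df$class)), classes)
  if (length(bad)) {
    stop("class(es) not in variant ", variant, ": ", paste(bad, collapse = ", "))
  }
  if (!reference %in% classes) stop("reference class not in variant")
  if (!reference %in% df$class) stop("reference class '", reference, "' has no sites")
  lev <- c(reference, setdiff(classes, reference))
  out <- data.frame(site_id = as.character(df$site_id),
                    class = factor(as.character(df$class), levels = lev),
                    stringsAsFactors = FALSE)
  structure(out, class = c("landuse_table", "data.frame"),
            variant = variant, reference = reference, gradient = classes)
}

#' Construct a site context table
#'
#' @param df data.frame with columns `site_id`, `x`, `y`, `watershed` and
#'   optionally `region` (used by region-exclusion reruns; defaults to the
#'   watershed label).
#' @return data.frame of class `site_context`.
#' @export
site_context <- function(df) {
  need <- c("site_id", "x", "y", "watershed")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("site context missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$site_id)) stop("duplicate site ids in site context")
  if (any(!is.finite(df$x)) || any(!is.finite(df$y))) stop("coordinates must be finite")
  out <- data.frame(site_id = as.character(df$site_id), x = df$x, y = df$y,
                    watershed = as.character(df$watershed),
                    region = if ("region" %in% names(df)) as.character(df$region)
                             else as.character(df$watershed),
                    stringsAsFactors = FALSE)
  structure(out, class = c("site_context", "data.frame"))
}

# fixed-effect vocabulary for the spatio-temporal models
.fixed_vocab <- c("year", "x", "y", "watershed", "landuse",
                  "year:x", "year:y", "year:watershed")

#' Assemble a model design for a community index series
#'
#' Joins the index series to site coordinates, watershed labels and
#' (optionally) land-use classes, centers the year, and records the
#' requested fixed effects. The response is the index value; the model
#' always carries a random intercept per site.
#'
#' @param series a [community_index()] result.
#' @param ctx a [site_context()].
#' @param lu optional [landuse_table()].
#' @param fixed character vector of fixed-effect terms from the vocabulary
#'   `year, x, y, watershed, landuse, year:x, year:y, year:watershed`.
#' @return list of class `index_design` with `data` (model frame) and
#'   `fixed`; `n_fixed_cols` counts non-intercept design columns.
#' @export
build_design <- function(series, ctx, lu = NULL, fixed = c("year", "x", "y")) {
  stopifnot(inherits(series, "community_index_series") || is.data.frame(series))
  if (anyDuplicated(fixed)) {
    stop("duplicate fixed effect(s): ", paste(unique(fixed[duplicated(fixed)]), collapse = ", "))
  }
  bad <- setdiff(fixed, .fixed_vocab)
  if (length(bad)) stop("unknown fixed effect(s): ", paste(bad, collapse = ", "))
  if ("landuse" %in% fixed && is.null(lu)) stop("fixed effects include landuse but no land-use table given")

  df <- as.data.frame(series)
  df <- df[is.finite(df$index), , drop = FALSE]
  unknown <- setdiff(unique(df$site_id), ctx$site_id)
  if (length(unknown)) stop("site(s) missing from context: ", paste(unknown, collapse = ", "))
  i <- match(df$site_id, ctx$site_id)
  df$x <- ctx$x[i]
  df$y <- ctx$y[i]
  df$watershed <- factor(ctx$watershed[i])
  df$region <- ctx$region[i]
  if (!is.null(lu)) {
    unknown <- setdiff(unique(df$site_id), lu$site_id)
    if (length(unknown)) stop("site(s) missing from land-use table: ", paste(unknown, collapse = ", "))
    df$landuse <- droplevels(lu$class[match(df$site_id, lu$site_id)])
  }
  df$year_c <- df$year - mean(df$year)
  df$site <- factor(df$site_id)

  mm <- stats::model.matrix(stats::reformulate(.term_map(fixed)), df)
  structure(list(data = df, fixed = fixed,
                 n_fixed_cols = ncol(mm) - 1L,
                 lu_attrs = if (is.null(lu)) NULL else attributes(lu)[c("variant", "reference", "gradient")]),
            class = "index_design")
}

.term_map <- function(fixed) {
  map <- c(year = "year_c", x = "x", y = "y", watershed = "watershed",
           landuse = "landuse", `year:x` = "year_c:x", `year:y` = "year_c:y",
           `year:watershed` = "year_c:watershed")
  unname(map[fixed])
}

#' Fit the spatio-temporal mixed model of a design
#'
#' Linear model for the community index with the design's fixed effects and
#' a random intercept per sampling site, fitted with [lmerTest::lmer()]
#' (Satterthwaite t-tests). Fits are by maximum likelihood when `REML =
#' FALSE` (for AIC comparison across fixed-effect sets) and by REML for
#' final coefficients. When the random-intercept variance collapses to the
#' boundary the model falls back to ordinary least squares with a warning.
#'
#' @param design a [build_design()] result.
#' @param REML logical (default `FALSE`).
#' @return list of class `mixed_fit`: `coefficients` (term, estimate, se,
#'   t, p), `aic`, `n_obs`, `n_par`, `singular`, `fixed`, `model`.
#' @export
fit_mixed <- function(design, REML = FALSE) {
  stopifnot(inherits(design, "index_design"))
  df <- design$data
  if (nlevels(droplevels(df$site)) < 2L) stop("need at least 2 sites")
  rhs <- .term_map(design$fixed)

  mm <- stats::model.matrix(stats::reformulate(rhs), df)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    aliased <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1L):ncol(mm)]]
    stop("rank-deficient design; aliased column(s): ", paste(aliased, collapse = ", "))
  }

  form <- stats::as.formula(paste("index ~", paste(rhs, collapse = " + "), "+ (1 | site)"))
  fit <- suppressMessages(lmerTest::lmer(form, data = df, REML = REML))
  singular <- lme4::isSingular(fit, tol = 1e-5)
  if (singular) {
    warning("random-intercept variance at the boundary; falling back to least squares")
    lmfit <- stats::lm(stats::reformulate(rhs, response = "index"), data = df)
    cf <- summary(lmfit)$coefficients
    coefs <- data.frame(term = rownames(cf), estimate = cf[, 1L], se = cf[, 2L],
                        t = cf[, 3L], p = cf[, 4L], row.names = NULL,
                        stringsAsFactors = FALSE)
    return(structure(list(coefficients = coefs, aic = stats::AIC(lmfit),
                          n_obs = nrow(df), n_par = length(stats::coef(lmfit)) + 1L,
                          singular = TRUE, fixed = design$fixed, model = lmfit),
                     class = "mixed_fit"))
  }
  cf <- stats::coef(summary(fit))
  coefs <- data.frame(term = rownames(cf), estimate = cf[, "Estimate"],
                      se = cf[, "Std. Error"], t = cf[, "t value"],
                      p = cf[, "Pr(>|t|)"], row.names = NULL,
                      stringsAsFactors = FALSE)
  structure(list(coefficients = coefs, aic = stats::AIC(fit), n_obs = nrow(df),
                 n_par = length(cf[, 1L]) + 2L, singular = FALSE,
                 fixed = design$fixed, model = fit),
            class = "mixed_fit")
}

#' Select the best candidate model by AIC
#'
#' @param fits list of [fit_mixed()] results fitted by ML on identical rows.
#' @return the minimal-AIC fit; exact ties go to the model with fewer
#'   parameters.
#' @export
aic_select <- function(fits) {
  if (!length(fits)) stop("need at least one candidate")
  stopifnot(all(vapply(fits, inherits, TRUE, "mixed_fit")))
  n_obs <- vapply(fits, `[[`, 0, "n_obs")
  if (length(unique(n_obs)) != 1L) stop("candidates fitted on differing row sets")
  aic <- vapply(fits, `[[`, 0, "aic")
  npar <- vapply(fits, `[[`, 0, "n_par")
  best <- which(aic <= min(aic) + 1e-8)
  best <- best[order(npar[best])][1L]
  fits[[best]]
}

#' Benjamini-Yekutieli FDR adjustment
#'
#' Step-up false-discovery-rate control valid under arbitrary dependence:
#' the Benjamini-Hochberg rule inflated by the harmonic constant
#' `c(m) = sum_{j=1..m} 1/j`.
#'
#' @param pvals raw p-values in \[0, 1\].
#' @return adjusted p-values in input order.
#' @examples
#' by_fdr(c(0.01, 0.02, 0.03))  # all 0.055
#' @export
by_fdr <- function(pvals) {
  pvals <- as.numeric(pvals)
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BY")
}

# default AIC candidate sets: year always present, spatial vocabulary
# {x+y, watershed, x+y+watershed}, each with and without year interactions
.default_candidates <- function(with_watershed = TRUE) {
  cands <- list(
    c("year", "x", "y"),
    c("year", "x", "y", "year:x", "year:y")
  )
  if (with_watershed) {
    cands <- c(cands, list(
      c("year", "watershed"),
      c("year", "watershed", "year:watershed"),
      c("year", "x", "y", "watershed"),
      c("year", "x", "y", "watershed", "year:x", "year:y", "year:watershed")
    ))
  }
  cands
}

#' Land-use sensitivity of a community index
#'
#' The indicator-evaluation pipeline: AIC-selects the spatio-temporal base
#' model (ML fits over the candidate fixed-effect sets), adds the
#' reference-coded land-use classes, refits by REML, tests every
#' non-reference class against the natural reference with
#' Benjamini-Yekutieli FDR control, and reports the adjusted R-squared of
#' the identical fixed-effects model refit without the random intercept as
#' an R-squared proxy.
#'
#' @param series a [community_index()] result.
#' @param ctx a [site_context()].
#' @param lu a [landuse_table()].
#' @param exclude_region optional region label(s); sites in these regions
#'   are dropped before fitting (outlier-region rerun).
#' @param candidates optional list of fixed-effect sets for the AIC search;
#'   defaults to the year x {x+y, watershed, both} x {+/- interactions}
#'   vocabulary.
#' @param alpha significance level applied to BY-adjusted p-values.
#' @return list of class `sensitivity_result`: `table` (class, estimate,
#'   t, p, p_by, significant; reference row has estimate 0), `model_terms`,
#'   `r2_proxy`, `n_obs`, `n_sites`, `variant`, `singular`.
#' @export
landuse_sensitivity <- function(series, ctx, lu, exclude_region = NULL,
                                candidates = NULL, alpha = 0.05) {
  stopifnot(inherits(lu, "landuse_table"))
  if (!is.null(exclude_region)) {
    drop_sites <- ctx$site_id[ctx$region %in% exclude_region]
    series <- series[!(series$site_id %in% drop_sites), , drop = FALSE]
    class(series) <- c("community_index_series", "data.frame")
    if (!nrow(series)) stop("region exclusion removed every observation")
  }
  if (is.null(candidates)) {
    n_ws <- length(unique(ctx$watershed[ctx$site_id %in% series$site_id]))
    candidates <- .default_candidates(with_watershed = n_ws >= 2L)
  }
  if (anyDuplicated(vapply(candidates, paste, "", collapse = "+"))) {
    stop("duplicate candidate fixed-effect sets")
  }

  fits <- lapply(candidates, function(fx) {
    fit_mixed(build_design(series, ctx, lu = NULL, fixed = fx), REML = FALSE)
  })
  base <- aic_select(fits)

  full_fixed <- c(base$fixed, "landuse")
  design <- build_design(series, ctx, lu = lu, fixed = full_fixed)
  final <- withCallingHandlers(
    fit_mixed(design, REML = TRUE),
    warning = function(w) {
      if (grepl("boundary", conditionMessage(w))) invokeRestart("muffleWarning")
    })

  reference <- attr(lu, "reference")
  present <- levels(droplevels(design$data$landuse))
  cls <- setdiff(present, reference)
  terms <- paste0("landuse", cls)
  cf <- final$coefficients
  row_i <- match(terms, cf$term)
  if (anyNA(row_i)) stop("internal: land-use coefficient(s) missing from fit")
  p_by <- by_fdr(cf$p[row_i])
  tab <- data.frame(
    class = c(reference, cls),
    estimate = c(0, cf$estimate[row_i]),
    t = c(NA, cf$t[row_i]),
    p = c(NA, cf$p[row_i]),
    p_by = c(NA, p_by),
    stringsAsFactors = FALSE
  )
  tab$significant <- !is.na(tab$p_by) & tab$p_by < alpha
  # gradient order for reporting
  tab <- tab[order(match(tab$class, attr(lu, "gradient"))), , drop = FALSE]
  rownames(tab) <- NULL

  lmfit <- stats::lm(stats::reformulate(.term_map(full_fixed), response = "index"),
                     data = design$data)
  structure(list(table = tab, model_terms = full_fixed,
                 r2_proxy = summary(lmfit)$adj.r.squared,
                 n_obs = final$n_obs,
                 n_sites = nlevels(droplevels(design$data$site)),
                 variant = attr(lu, "variant"), reference = reference,
                 alpha = alpha, singular = final$singular, fit = final),
            class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat("Land-use sensitivity (", x$variant, "), model: index ~ ",
      paste(x$model_terms, collapse = " + "), " + (1|site)\n", sep = "")
  cat("n =", x$n_obs, "occasions across", x$n_sites, "sites; R2 proxy =",
      signif(x$r2_proxy, 3), "\n")
  print(x$table, digits = 4)
  invisible(x)
}

#' Robustness of a sensitivity result across land-use classifications
#'
#' Reruns [landuse_sensitivity()] under each classification variant and
#' applies a sign-agreement rule: the index is flagged robust when every
#' variant yields at least one significant class effect and all significant
#' effects, across all variants, share the same sign.
#'
#' @param series,ctx as in [landuse_sensitivity()].
#' @param variants named list of two or more [landuse_table()]s covering
#'   the same sites.
#' @param ... passed to [landuse_sensitivity()].
#' @return list of class `robustness_report`: `results` per variant,
#'   `signs` (signs of significant effects per variant), `robust` (logical,
#'   `NA` when fewer than 2 variants are supplied).
#' @export
classification_robustness <- function(series, ctx, variants, ...) {
  stopifnot(is.list(variants), length(variants) >= 1L)
  site_sets <- lapply(variants, function(v) sort(unique(v$site_id)))
  if (length(unique(vapply(site_sets, paste, "", collapse = ","))) != 1L) {
    stop("land-use variants cover differing site sets")
  }
  results <- lapply(variants, function(v) landuse_sensitivity(series, ctx, v, ...))
  signs <- lapply(results, function(r) {
    sig <- r$table[r$table$significant %in% TRUE, , drop = FALSE]
    stats::setNames(sign(sig$estimate), sig$class)
  })
  robust <- if (length(variants) < 2L) {
    NA
  } else {
    all_signs <- unlist(signs, use.names = FALSE)
    all(lengths(signs) > 0L) && length(unique(all_signs)) == 1L
  }
  structure(list(results = results, signs = signs, robust = robust),
            class = "robustness_report")
}

#' Per-watershed consistency of a land-use response
#'
#' Refits the land-use model within each watershed (reduced fixed effects:
#' year, coordinates, land use) and summarizes coefficient signs by class.
#' Watersheds with fewer sites than `min_sites`, or without the reference
#' class, are skipped with a warning.
#'
#' @param series,ctx,lu as in [landuse_sensitivity()].
#' @param min_sites minimum number of sites per watershed (default 10).
#' @param ... passed to [landuse_sensitivity()].
#' @return list of class `watershed_report`: `results` per watershed,
#'   `sign_matrix` (class x watershed), `consistent` (per class: do all
#'   watershed estimates share one sign?), `skipped`.
#' @export
watershed_consistency <- function(series, ctx, lu, min_sites = 10L, ...) {
  ws <- sort(unique(ctx$watershed[ctx$site_id %in% series$site_id]))
  if (length(ws) < 2L) stop("need at least 2 watersheds")
  results <- list()
  skipped <- character()
  for (w in ws) {
    sites_w <- ctx$site_id[ctx$watershed == w]
    sub <- series[series$site_id %in% sites_w, , drop = FALSE]
    class(sub) <- c("community_index_series", "data.frame")
    n_sites <- length(unique(sub$site_id))
    lu_w <- lu[lu$site_id %in% sites_w, , drop = FALSE]
    if (n_sites < min_sites || !(attr(lu, "reference") %in% lu_w$class)) {
      warning("watershed '", w, "' skipped (", n_sites, " sites)")
      skipped <- c(skipped, w)
      next
    }
    lu_sub <- landuse_table(lu_w, variant = attr(lu, "variant"),
                            reference = attr(lu, "reference"))
    results[[w]] <- landuse_sensitivity(sub, ctx, lu_sub,
                                        candidates = list(c("year", "x", "y")), ...)
  }
  if (!length(results)) stop("no watershed met the minimum size")
  classes <- setdiff(attr(lu, "gradient"), attr(lu, "reference"))
  sign_matrix <- sapply(results, function(r) {
    s <- stats::setNames(sign(r$table$estimate), r$table$class)
    s[classes]
  })
  if (is.null(dim(sign_matrix))) sign_matrix <- matrix(sign_matrix, ncol = length(results),
                                                       dimnames = list(classes, names(results)))
  rownames(sign_matrix) <- classes
  consistent <- apply(sign_matrix, 1L, function(s) {
    s <- s[!is.na(s)]
    length(s) > 0L && length(unique(s)) == 1L
  })
  structure(list(results = results, sign_matrix = sign_matrix,
                 consistent = consistent, skipped = skipped),
            class = "watershed_report")
}

#' Write a sensitivity table as CSV
#' @param res a [landuse_sensitivity()] result.
#' @param path output path.
#' @export
write_sensitivity_csv <- function(res, path) {
  stopifnot(inherits(res, "sensitivity_result"))
  utils::write.csv(res$table, path, row.names = FALSE)
  invisible(path)
}
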