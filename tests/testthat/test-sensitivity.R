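# small direct builder for model-level tests: index series + context with
# known structure, no generator involved
make_series <- function(n_sites, n_years, f = function(df) 0, sigma_site = 0,
                        sigma = 0.01, seed = 1, n_watersheds = 2) {
  set.seed(seed)
  sites <- sprintf("m%03d", seq_len(n_sites))
  ctx <- site_context(data.frame(
    site_id = sites, x = runif(n_sites), y = runif(n_sites),
    watershed = sprintf("W%d", 1 + (seq_len(n_sites) - 1) %% n_watersheds)))
  u <- rnorm(n_sites, 0, sigma_site)
  df <- expand.grid(site_id = sites, year = 2000L + seq_len(n_years) - 1L,
                    stringsAsFactors = FALSE)
  i <- match(df$site_id, sites)
  df$x <- ctx$x[i]
  df$y <- ctx$y[i]
  df$watershed <- ctx$watershed[i]
  df$index <- 0.5 + f(df) + u[i] + rnorm(nrow(df), 0, sigma)
  ser <- data.frame(site_id = df$site_id, year = df$year, index = df$index,
                    coverage = 1, flag = "ok", stringsAsFactors = FALSE)
  class(ser) <- c("community_index_series", "data.frame")
  list(series = ser, ctx = ctx)
}

test_that("design assembly counts reference-coded columns and rejects bad specs", {
  d <- make_series(20, 3)
  des <- build_design(d$series, d$ctx,
                      fixed = c("year", "x", "y", "year:x", "year:y"))
  expect_equal(des$n_fixed_cols, 5L)  # year, x, y and the two interactions

  lu <- gen_landuse(unique(d$series$site_id), variant = "CLC5", seed = 2)
  des2 <- build_design(d$series, d$ctx, lu = lu, fixed = c("year", "landuse"))
  expect_equal(des2$n_fixed_cols, 1L + 4L)  # 5 classes, Forest dropped

  expect_error(build_design(d$series, d$ctx, fixed = c("year", "year", "x")),
               "duplicate fixed effect")
  expect_error(build_design(d$series, d$ctx, fixed = c("year", "altitude")),
               "unknown fixed effect")
  bad_ctx <- d$ctx[-1, ]
  class(bad_ctx) <- class(d$ctx)
  expect_error(build_design(d$series, bad_ctx), "missing from context")
})

test_that("land-use tables validate class vocabulary and reference", {
  df <- data.frame(site_id = c("a", "b"), class = c("Forest", "Urban"))
  lu <- landuse_table(df, variant = "CLC5")
  expect_identical(levels(lu$class)[1], "Forest")
  expect_error(landuse_table(data.frame(site_id = "a", class = "Quarry"),
                             variant = "CLC5"), "not in variant")
  expect_error(landuse_table(data.frame(site_id = "a", class = "Urban"),
                             variant = "CLC5"), "no sites")
})

test_that("mixed fit collapses to least squares when site variance is zero", {
  d <- make_series(40, 4, f = function(df) 0.3 * df$x - 0.1 * df$y,
                   sigma_site = 0, sigma = 0.02, seed = 5)
  des <- build_design(d$series, d$ctx, fixed = c("year", "x", "y"))
  fit <- suppressWarnings(fit_mixed(des, REML = TRUE))
  ols <- lm(index ~ year_c + x + y, data = des$data)
  expect_true(fit$singular)
  expect_equal(fit$coefficients$estimate,
               unname(coef(ols)[fit$coefficients$term]), tolerance = 1e-6)
})

test_that("mixed fit recovers a known slope across seeded replicates", {
  hits <- 0L
  n_rep <- 40L
  for (r in seq_len(n_rep)) {
    d <- make_series(120, 4, f = function(df) 0.2 * df$x,
                     sigma_site = 0.05, sigma = 0.05, seed = 900 + r)
    des <- build_design(d$series, d$ctx, fixed = c("x"))
    fit <- suppressWarnings(fit_mixed(des, REML = TRUE))
    row <- fit$coefficients[fit$coefficients$term == "x", ]
    if (abs(row$estimate - 0.2) <= 3 * row$se) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("mixed fit rejects degenerate designs", {
  d <- make_series(30, 3)
  d$ctx$y <- d$ctx$x  # aliased coordinate
  des <- build_design(d$series, d$ctx, fixed = c("year", "x", "y"))
  expect_error(fit_mixed(des), "aliased")

  one <- d$series[d$series$site_id == "m001", ]
  class(one) <- class(d$series)
  des1 <- build_design(one, d$ctx, fixed = c("year"))
  expect_error(fit_mixed(des1), "at least 2 sites")
})

test_that("AIC selection prefers the generating model and breaks ties to parsimony", {
  d <- make_series(50, 3, f = function(df) 0)
  des <- build_design(d$series, d$ctx, fixed = c("year", "x"))
  fit <- suppressWarnings(fit_mixed(des))
  expect_identical(aic_select(list(fit)), fit)

  # exact tie by duplication: the smaller model wins
  fit_big <- suppressWarnings(fit_mixed(build_design(d$series, d$ctx,
                                                     fixed = c("year", "x", "y"))))
  fit_tie <- fit_big
  fit_tie$n_par <- fit_big$n_par - 1L
  expect_identical(aic_select(list(fit_big, fit_tie)), fit_tie)

  fit_other <- fit
  fit_other$n_obs <- fit$n_obs - 1L
  expect_error(aic_select(list(fit, fit_other)), "differing row sets")

  # the watershed model is selected when a watershed effect generates the data
  wins <- 0L
  n_rep <- 50L
  for (r in seq_len(n_rep)) {
    d2 <- make_series(60, 3, seed = 700 + r, sigma_site = 0.02, sigma = 0.03,
                      f = function(df) ifelse(df$watershed == "W1", 0.08, -0.08),
                      n_watersheds = 2)
    f_xy <- suppressWarnings(fit_mixed(build_design(d2$series, d2$ctx,
                                                    fixed = c("year", "x", "y"))))
    f_ws <- suppressWarnings(fit_mixed(build_design(d2$series, d2$ctx,
                                                    fixed = c("year", "watershed"))))
    if (identical(aic_select(list(f_xy, f_ws)), f_ws)) wins <- wins + 1L
  }
  expect_gte(wins / n_rep, 0.9)
})

test_that("BY adjustment matches the hand-worked step-up rule and dominates BH", {
  expect_equal(by_fdr(0.04), 0.04)
  expect_equal(by_fdr(c(0.01, 0.02, 0.03)), rep(0.055, 3))
  set.seed(17)
  for (r in 1:20) {
    p <- runif(sample(2:12, 1))
    adj <- by_fdr(p)
    expect_true(all(adj >= p.adjust(p, "BH") - 1e-15))
    expect_true(all(adj <= 1))
    expect_true(all(diff(adj[order(p)]) >= -1e-15))  # monotone in sorted order
  }
  expect_error(by_fdr(c(0.2, 1.3)), "\\[0, 1\\]")
})

test_that("region exclusion equals fitting on the complement", {
  res_all <- run_pipeline_once(seed = 11, effects = c(Urban = -0.02))
  sc <- sim_scores()
  cfg <- scenario_config(seed = 11, class_effects = c(Urban = -0.02))
  dat <- gen_survey(cfg, sc)
  ser <- community_index(dat$survey, sc)
  res_excl <- landuse_sensitivity(ser, dat$context, dat$landuse,
                                  exclude_region = "W3")
  keep <- dat$context$site_id[dat$context$watershed != "W3"]
  sub <- ser[ser$site_id %in% keep, ]
  class(sub) <- class(ser)
  res_manual <- landuse_sensitivity(sub, dat$context, dat$landuse)
  expect_equal(res_excl$table, res_manual$table, tolerance = 1e-12)
  expect_equal(res_excl$r2_proxy, res_manual$r2_proxy, tolerance = 1e-12)
  # reference-class coefficient is structurally zero everywhere
  expect_equal(res_all$table$estimate[res_all$table$class == "Forest"], 0)
  expect_true(all(is.na(res_all$table$p_by) |
                    res_all$table$p_by >= res_all$table$p))
})

test_that("classification robustness flags sign conflicts and degenerate input", {
  # direct construction: index responds + to Urban, - to Farming; a variant
  # merging them must break the sign agreement
  set.seed(23)
  n_sites <- 160
  sites <- sprintf("m%03d", seq_len(n_sites))
  cls7 <- sample(c("Forest", "Meadow", "Farming", "Urban"), n_sites, TRUE)
  eff <- c(Forest = 0, Meadow = 0, Farming = -0.05, Urban = 0.05)
  ctx <- site_context(data.frame(site_id = sites, x = runif(n_sites),
                                 y = runif(n_sites),
                                 watershed = rep(c("W1", "W2"), length.out = n_sites)))
  u <- rnorm(n_sites, 0, 0.02)
  df <- expand.grid(site_id = sites, year = 2000:2002, stringsAsFactors = FALSE)
  df$index <- 0.5 + eff[cls7[match(df$site_id, sites)]] + u[match(df$site_id, sites)] +
    rnorm(nrow(df), 0, 0.01)
  ser <- data.frame(site_id = df$site_id, year = df$year, index = df$index,
                    coverage = 1, flag = "ok")
  class(ser) <- c("community_index_series", "data.frame")

  lu_fine <- landuse_table(data.frame(site_id = sites, class = cls7), "CLC5")
  merged <- ifelse(cls7 %in% c("Farming", "Urban"), "Mix", cls7)
  merged[match(c("Farming", "Urban"), cls7)] <- c("Farming", "Urban") # keep levels present
  lu_coarse <- landuse_table(data.frame(site_id = sites, class = merged), "CLC5")

  rep_conflict <- classification_robustness(ser, ctx,
                                            list(fine = lu_fine, coarse = lu_coarse))
  expect_false(rep_conflict$robust)

  rep_one <- classification_robustness(ser, ctx, list(fine = lu_fine))
  expect_true(is.na(rep_one$robust))

  bad <- lu_fine[-1, ]
  class(bad) <- class(lu_fine)
  attributes(bad)[c("variant", "reference", "gradient")] <-
    attributes(lu_fine)[c("variant", "reference", "gradient")]
  expect_error(classification_robustness(ser, ctx, list(lu_fine, bad)),
               "differing site sets")
})

test_that("watershed consistency detects homogeneous and reversed effects", {
  build_ws_data <- function(reverse_in = NULL) {
    set.seed(29)
    n_sites <- 240
    sites <- sprintf("m%03d", seq_len(n_sites))
    ws <- rep(sprintf("W%d", 1:4), length.out = n_sites)
    cls <- sample(c("Forest", "Meadow", "Farming", "Mix", "Urban"), n_sites, TRUE)
    eff <- c(Forest = 0, Meadow = -0.01, Farming = -0.03, Mix = -0.04, Urban = -0.06)
    sgn <- ifelse(ws %in% reverse_in, -1, 1)
    ctx <- site_context(data.frame(site_id = sites, x = runif(n_sites),
                                   y = runif(n_sites), watershed = ws))
    u <- rnorm(n_sites, 0, 0.02)
    df <- expand.grid(site_id = sites, year = 2000:2002, stringsAsFactors = FALSE)
    i <- match(df$site_id, sites)
    df$index <- 0.5 + sgn[i] * eff[cls[i]] + u[i] + rnorm(nrow(df), 0, 0.01)
    ser <- data.frame(site_id = df$site_id, year = df$year, index = df$index,
                      coverage = 1, flag = "ok")
    class(ser) <- c("community_index_series", "data.frame")
    list(ser = ser, ctx = ctx,
         lu = landuse_table(data.frame(site_id = sites, class = cls), "CLC5"))
  }

  hom <- build_ws_data()
  rep_hom <- suppressWarnings(watershed_consistency(hom$ser, hom$ctx, hom$lu))
  expect_true(all(rep_hom$consistent))
  expect_true(all(rep_hom$sign_matrix["Urban", ] == -1))

  rev <- build_ws_data(reverse_in = "W2")
  rep_rev <- suppressWarnings(watershed_consistency(rev$ser, rev$ctx, rev$lu))
  expect_false(all(rep_rev$consistent))

  # a watershed below the minimum size is logged and absent from the summary
  small <- hom
  drop_sites <- small$ctx$site_id[small$ctx$watershed == "W4"][-(1:3)]
  small$ser <- small$ser[!small$ser$site_id %in% drop_sites, ]
  class(small$ser) <- c("community_index_series", "data.frame")
  expect_warning(rep_small <- watershed_consistency(small$ser, small$ctx, small$lu,
                                                    min_sites = 10),
                 "W4.*skipped")
  expect_false("W4" %in% colnames(rep_small$sign_matrix))
  expect_identical(rep_small$skipped, "W4")
})
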