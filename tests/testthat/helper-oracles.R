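# Independent oracles and fixture builders shared across the test files.

# Brute-force Gower coefficient: explicit double loop over species pairs and
# traits, independent of the vectorized implementation.
gower_brute <- function(df, kinds, weights = NULL) {
  n <- nrow(df)
  m <- ncol(df)
  if (is.null(weights)) weights <- rep(1, m)
  cols <- lapply(seq_len(m), function(j) {
    v <- df[[j]]
    if (kinds[[j]] == "ordinal") v <- rank(v, na.last = "keep")
    v
  })
  rngs <- vapply(seq_len(m), function(j) {
    if (kinds[[j]] %in% c("quantitative", "ordinal")) {
      diff(range(cols[[j]], na.rm = TRUE))
    } else NA_real_
  }, 0)
  d <- matrix(0, n, n, dimnames = list(rownames(df), rownames(df)))
  for (i in seq_len(n)) for (l in seq_len(n)) {
    if (i == l) next
    num <- 0
    den <- 0
    for (j in seq_len(m)) {
      a <- cols[[j]][i]
      b <- cols[[j]][l]
      if (is.na(a) || is.na(b)) next
      s <- if (kinds[[j]] %in% c("quantitative", "ordinal")) {
        if (rngs[j] == 0) 0 else abs(a - b) / rngs[j]
      } else {
        as.numeric(a != b)
      }
      num <- num + weights[j] * s
      den <- den + weights[j]
    }
    d[i, l] <- num / den
  }
  d
}

# Projected-gradient maximizer of p' D p on the probability simplex, written
# from scratch (own simplex projection) as the oracle for QE originality.
qe_pg_oracle <- function(d, iters = 200000L, tol = 1e-13) {
  n <- nrow(d)
  proj <- function(v) {
    u <- sort(v, decreasing = TRUE)
    cs <- cumsum(u) - 1
    rho <- max(which(u > cs / seq_len(n)))
    pmax(v - cs[rho] / rho, 0)
  }
  p <- rep(1 / n, n)
  step <- 1 / (2 * max(abs(eigen(d, symmetric = TRUE, only.values = TRUE)$values)))
  for (i in seq_len(iters)) {
    p_new <- proj(p + step * 2 * as.numeric(d %*% p))
    if (max(abs(p_new - p)) < tol) {
      p <- p_new
      break
    }
    p <- p_new
  }
  p
}

# Random mixed-type trait data.frame (with optional missing cells) for
# property tests; returns a ready trait_table.
rand_trait_table <- function(n_species, seed, n_quant = 2L, n_ord = 2L,
                             n_nom = 1L, n_bin = 1L, missing_rate = 0) {
  set.seed(seed)
  df <- data.frame(row.names = sprintf("s%02d", seq_len(n_species)))
  kinds <- character()
  for (j in seq_len(n_quant)) {
    df[[paste0("q", j)]] <- rnorm(n_species)
    kinds[paste0("q", j)] <- "quantitative"
  }
  for (j in seq_len(n_ord)) {
    df[[paste0("o", j)]] <- sample.int(5L, n_species, replace = TRUE)
    kinds[paste0("o", j)] <- "ordinal"
  }
  for (j in seq_len(n_nom)) {
    df[[paste0("n", j)]] <- sample(c("u", "v", "w"), n_species, replace = TRUE)
    kinds[paste0("n", j)] <- "nominal"
  }
  for (j in seq_len(n_bin)) {
    df[[paste0("b", j)]] <- as.character(rbinom(n_species, 1L, 0.5))
    kinds[paste0("b", j)] <- "binary"
  }
  if (missing_rate > 0) {
    for (j in seq_along(df)) {
      mask <- runif(n_species) < missing_rate
      # keep each row and column comparable: never blank a whole column
      if (all(mask)) mask[1L] <- FALSE
      df[[j]][mask] <- NA
    }
  }
  trait_table(df, kinds = kinds)
}

# Small survey + habitat fixture: k classes, one site per class, one year,
# species density matrix given as species x class.
survey_from_class_matrix <- function(mat) {
  k <- ncol(mat)
  sites <- sprintf("h%02d", seq_len(k))
  rows <- expand.grid(species_id = rownames(mat), site_idx = seq_len(k),
                      stringsAsFactors = FALSE)
  data.frame(site_id = sites[rows$site_idx], year = 2000L,
             species_id = rows$species_id,
             density = mat[cbind(match(rows$species_id, rownames(mat)),
                                 rows$site_idx)],
             stringsAsFactors = FALSE)
}

class_assignment <- function(k) {
  data.frame(site_id = sprintf("h%02d", seq_len(k)), class = seq_len(k),
             stringsAsFactors = FALSE)
}

# Shared scores for the simulation tests: raw equal-splits SOI on a fixed
# synthetic trait table (raw scale, so index shifts of a few 0.01 fit).
sim_scores <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tt <- gen_trait_table(scenario_config(seed = 7L))
      cache <<- soi_from_traits(tt, trait_set = "niche", proportions = FALSE)
    }
    cache
  }
})

# One pipeline replicate: generate survey under `effects`, aggregate, run
# the land-use sensitivity model; returns the sensitivity_result.
run_pipeline_once <- function(seed, effects = NULL, ...) {
  sc <- sim_scores()
  cfg <- scenario_config(seed = seed, class_effects = effects)
  dat <- gen_survey(cfg, sc)
  ser <- community_index(dat$survey, sc)
  landuse_sensitivity(ser, dat$context, dat$landuse, ...)
}
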