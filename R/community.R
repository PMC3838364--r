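#' Community-weighted index per sampling occasion
#'
#' Aggregates per-species scores into an occasion-level community index:
#' for occasion `t`, `index_t = sum_i a_it * X_i / sum_i a_it`, the
#' density-weighted mean of the species scores `X_i` over the species
#' recorded at `t`. With originality scores this is the Community
#' Originality Index (COI); with specialization scores the Community
#' Specialization Index (CSI).
#'
#' Species without a score are dropped from both numerator and denominator;
#' the fraction of total density carried by scored species is reported as
#' `coverage`. Occasions under `min_coverage` are flagged, not dropped;
#' occasions with no scored density get an `NA` index and the flag
#' `"undefined"`.
#'
#' @param survey data.frame with columns `site_id`, `year`, `species_id`,
#'   `density`.
#' @param scores a [species_scores()] vector.
#' @param min_coverage coverage threshold below which an occasion is
#'   flagged (default 0.5).
#' @return data.frame of class `community_index_series` with columns
#'   `site_id`, `year`, `index`, `coverage`, `flag`; metric and trait-set
#'   tags inherited from `scores`.
#' @examples
#' sv <- data.frame(site_id = "s1", year = 2000,
#'                  species_id = c("a", "b"), density = c(30, 10))
#' sc <- species_scores(c(a = 0.2, b = 0.8), metric = "equal_splits")
#' community_index(sv, sc)$index  # 0.35
#' @export
community_index <- function(survey, scores, min_coverage = 0.5) {
  validate_survey(survey)
  stopifnot(inherits(scores, "species_scores"))
  if (!length(scores)) stop("score vector is empty")

  sp <- as.character(survey$species_id)
  unscored <- setdiff(unique(sp), names(scores))
  x <- scores[sp]

  key <- paste(survey$site_id, survey$year, sep = "\r")
  tot <- tapply(survey$density, key, sum)
  sc_mask <- !is.na(x)
  num <- tapply(survey$density * ifelse(sc_mask, as.numeric(x), 0), key, sum)
  den <- tapply(survey$density * sc_mask, key, sum)

  occ <- unique(survey[c("site_id", "year")])
  okey <- paste(occ$site_id, occ$year, sep = "\r")
  index <- as.numeric(num[okey] / den[okey])
  coverage <- as.numeric(den[okey] / tot[okey])
  index[den[okey] == 0] <- NA_real_

  flag <- rep("ok", nrow(occ))
  flag[coverage < min_coverage] <- "low_coverage"
  flag[den[okey] == 0] <- "undefined"
  if (any(flag == "undefined")) {
    warning(sum(flag == "undefined"), " occasion(s) with zero scored density")
  }
  mean_cov <- sum(den) / sum(tot)
  if (length(unscored) && mean_cov < min_coverage) {
    warning("species without scores exceed the coverage threshold: ",
            paste(unscored, collapse = ", "))
  }

  out <- data.frame(site_id = as.character(occ$site_id), year = occ$year,
                    index = index, coverage = coverage, flag = flag,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("community_index_series", "data.frame"),
            metric = attr(scores, "metric"), trait_set = attr(scores, "trait_set"))
}

#' Write a community index series as long-format CSV
#' @param series a [community_index()] result.
#' @param path output path.
#' @export
write_series_csv <- function(series, path) {
  df <- as.data.frame(series)
  df$metric <- attr(series, "metric")
  df$trait_set <- attr(series, "trait_set")
  utils::write.csv(df[c("site_id", "year", "metric", "trait_set",
                        "index", "coverage", "flag")], path, row.names = FALSE)
  invisible(path)
}

#' Read a community index series written by [write_series_csv()]
#' @param path input path.
#' @return `community_index_series` data.frame.
#' @export
read_series_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  structure(df[c("site_id", "year", "index", "coverage", "flag")],
            class = c("community_index_series", "data.frame"),
            metric = df$metric[1L], trait_set = df$trait_set[1L])
}
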