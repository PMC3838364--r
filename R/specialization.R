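#' Balanced habitat classes from abiotic site variables
#'
#' Partitions sites into `k` habitat classes of approximately equal size
#' from four abiotic variables (temperature sum over January-June,
#' longitudinal gradient, log elevation, slope). Variables are standardized,
#' sites clustered by k-means, and members of over-full clusters are then
#' reassigned to their nearest under-full centroid until no class exceeds
#' `ceiling(n / k) + slack` sites. Equal class sizes correct the geographic
#' over-sampling of headwater sites that would otherwise bias
#' density-per-habitat profiles.
#'
#' @param abiotic data.frame with columns `site_id`, `temperature_sum`,
#'   `longitudinal_gradient`, `log_elevation`, `slope`; unique sites, no
#'   missing values.
#' @param k number of classes (default 7).
#' @param slack allowed excess over the equal-share class size (default 0).
#' @param seed integer seed (k-means initialization).
#' @return data.frame of class `habitat_assignment` with columns `site_id`,
#'   `class` (integer 1..k); attributes record method, k, slack and seed.
#' @export
balanced_habitat_classes <- function(abiotic, k = 7L, slack = 0L, seed = 1L) {
  vars <- c("temperature_sum", "longitudinal_gradient", "log_elevation", "slope")
  miss <- setdiff(c("site_id", vars), names(abiotic))
  if (length(miss)) stop("abiotic table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(abiotic$site_id)) stop("duplicate site ids in abiotic table")
  if (anyNA(abiotic[vars])) stop("missing values in abiotic variables")
  n <- nrow(abiotic)
  if (n < k) stop("need at least k = ", k, " sites, got ", n)
  sds <- vapply(abiotic[vars], stats::sd, 0)
  if (any(sds == 0)) {
    stop("constant abiotic variable(s): ", paste(vars[sds == 0], collapse = ", "))
  }
  Z <- scale(as.matrix(abiotic[vars]))

  set.seed(seed)
  km <- stats::kmeans(Z, centers = k, nstart = 10L, iter.max = 100L)
  cls <- km$cluster
  centers <- km$centers
  cap <- ceiling(n / k) + slack

  # distance of every site to every centroid, for nearest-centroid reassignment
  d2 <- vapply(seq_len(k), function(j) {
    rowSums((Z - matrix(centers[j, ], n, 4L, byrow = TRUE))^2)
  }, numeric(n))

  repeat {
    sizes <- tabulate(cls, nbins = k)
    over <- which(sizes > cap)
    if (!length(over)) break
    under <- which(sizes < cap)
    cand_sites <- which(cls %in% over)
    # move the site closest to some under-full centroid
    sub <- d2[cand_sites, under, drop = FALSE]
    idx <- arrayInd(which.min(sub), dim(sub))
    cls[cand_sites[idx[1L]]] <- under[idx[2L]]
  }

  out <- data.frame(site_id = as.character(abiotic$site_id), class = cls,
                    stringsAsFactors = FALSE)
  structure(out, class = c("habitat_assignment", "data.frame"),
            method = "kmeans+capacity", k = k, slack = slack, seed = seed)
}

#' Species Specialization Index (SSI)
#'
#' For every species, the coefficient of variation (standard deviation over
#' mean) of its average density across habitat classes. A species equally
#' dense in every habitat scores 0 (perfect generalist); a species confined
#' to a single one of `k` classes scores `sqrt(k)` with the sample-sd
#' convention. Class averages are taken over all sampling occasions in a
#' class, counting occasions where the species was not recorded as zero
#' density.
#'
#' @param survey data.frame with columns `site_id`, `year`, `species_id`,
#'   `density` (>= 0); one row per (site, year, species).
#' @param assignment a [balanced_habitat_classes()] result (or any
#'   data.frame with `site_id`, `class`) covering every surveyed site.
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`.
#' @return [species_scores()] with metric `"ssi"`. Species with zero total
#'   density are dropped with a warning.
#' @export
ssi <- function(survey, assignment, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  validate_survey(survey)
  if (anyDuplicated(assignment$site_id)) stop("duplicate site ids in assignment")
  cls_of <- stats::setNames(assignment$class, as.character(assignment$site_id))
  sites <- unique(as.character(survey$site_id))
  unknown <- setdiff(sites, names(cls_of))
  if (length(unknown)) {
    stop("surveyed site(s) without habitat class: ", paste(unknown, collapse = ", "))
  }

  occ <- unique(survey[c("site_id", "year")])
  occ_class <- cls_of[as.character(occ$site_id)]
  n_per_class <- table(occ_class)
  classes <- names(n_per_class)
  if (length(classes) < 2L) stop("fewer than 2 habitat classes represented")

  surv_class <- cls_of[as.character(survey$site_id)]
  # summed density per species x class; divide by occasion count so absent
  # occasions count as zeros in the class average
  tot <- tapply(survey$density,
                list(factor(as.character(survey$species_id)),
                     factor(surv_class, levels = classes)),
                sum, default = 0)
  means <- sweep(tot, 2L, as.numeric(n_per_class), `/`)

  zero <- rowSums(means) == 0
  if (any(zero)) {
    warning("species with zero total density excluded: ",
            paste(rownames(means)[zero], collapse = ", "))
    means <- means[!zero, , drop = FALSE]
  }
  if (!nrow(means)) stop("no species with positive density")

  denom <- if (sd_type == "sample") ncol(means) - 1L else ncol(means)
  sds <- sqrt(rowSums((means - rowMeans(means))^2) / denom)
  vals <- sds / rowMeans(means)
  species_scores(vals, rownames(means), metric = "ssi", trait_set = "custom")
}

validate_survey <- function(survey) {
  need <- c("site_id", "year", "species_id", "density")
  miss <- setdiff(need, names(survey))
  if (length(miss)) stop("survey table missing column(s): ", paste(miss, collapse = ", "))
  if (!nrow(survey)) stop("survey table is empty")
  if (any(!is.finite(survey$density)) || any(survey$density < 0)) {
    stop("densities must be finite and >= 0")
  }
  key <- paste(survey$site_id, survey$year, survey$species_id, sep = "\r")
  if (anyDuplicated(key)) stop("duplicate (site, year, species) rows in survey")
  invisible(survey)
}
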