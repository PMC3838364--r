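#' Construct a per-species score vector
#'
#' Light container for per-species originality (SOI) or specialization (SSI)
#' values: a named numeric vector tagged with the metric that produced it,
#' the trait set it summarizes, and whether it has been normalized to
#' proportions.
#'
#' @param values non-negative numeric values.
#' @param species_ids character ids, one per value (default `names(values)`).
#' @param metric one of `"equal_splits"`, `"qe"`, `"ssi"`.
#' @param trait_set free-form tag (e.g. `"life_history"`, `"niche"`,
#'   `"phylogeny"`, `"custom"`).
#' @param normalized logical; if `TRUE` the values must sum to 1.
#' @return named numeric vector of class `species_scores`.
#' @export
species_scores <- function(values, species_ids = names(values),
                           metric = c("equal_splits", "qe", "ssi"),
                           trait_set = "custom", normalized = FALSE) {
  metric <- match.arg(metric)
  species_ids <- species_ids  # force before names are stripped
  values <- as.numeric(values)
  if (is.null(species_ids) || length(species_ids) != length(values)) {
    stop("need one species id per value")
  }
  if (anyDuplicated(species_ids)) stop("duplicate species ids in score vector")
  if (any(!is.finite(values)) || any(values < 0)) stop("scores must be finite and >= 0")
  if (normalized && abs(sum(values) - 1) > 1e-9) {
    stop("normalized scores must sum to 1")
  }
  structure(stats::setNames(values, species_ids), class = "species_scores",
            metric = metric, trait_set = trait_set, normalized = normalized)
}

#' @export
print.species_scores <- function(x, ...) {
  cat("species_scores [metric=", attr(x, "metric"),
      ", trait_set=", attr(x, "trait_set"),
      ", normalized=", attr(x, "normalized"), "]\n", sep = "")
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' Equal-splits originality of every tip
#'
#' Each branch's length is attributed to its descendant tips, divided
#' equally among the daughter branches at every split below it, so a tip
#' subtending long, rarely shared branches scores high. Scores sum to the
#' total branch length of the tree. Polytomies divide by the actual child
#' count; a root with a single child passes its edge along undivided (with a
#' warning).
#'
#' @param tree rooted `phylo` tree with branch lengths, at least 2 tips.
#' @param trait_set tag recorded on the output.
#' @return [species_scores()] with metric `"equal_splits"`, in branch-length
#'   units.
#' @examples
#' tr <- read_newick("((A:1,B:1):2,C:3);")
#' equal_splits(tr)  # A = 2, B = 2, C = 3
#' @export
equal_splits <- function(tree, trait_set = "custom") {
  stopifnot(inherits(tree, "phylo"))
  # trees are treated as rooted at their structural root node; a basal
  # polytomy (e.g. a star dendrogram) is a legitimate rooted split here
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    stop("tree has missing branch lengths")
  }
  ntip <- ape::Ntip(tree)
  if (ntip < 2L) stop("tree must have at least 2 tips")
  tree <- stats::reorder(tree, "cladewise")
  nnode <- ntip + tree$Nnode
  nchild <- tabulate(tree$edge[, 1L], nbins = nnode)
  if (any(nchild[tree$edge[, 1L]] == 1L)) {
    warning("node(s) with a single child: their edges pass along undivided")
  }
  # acc[v]: branch length accumulated on the root->v path, already divided at
  # every split strictly below each contributing edge
  acc <- numeric(nnode)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1L]
    ch <- tree$edge[e, 2L]
    acc[ch] <- acc[p] / nchild[p] + tree$edge.length[e]
  }
  species_scores(acc[seq_len(ntip)], tree$tip.label,
                 metric = "equal_splits", trait_set = trait_set)
}

#' Rao quadratic-entropy originality weights
#'
#' Finds the species weights `p` on the probability simplex maximizing
#' Rao's quadratic entropy `p' D p` for a dissimilarity matrix `D`
#' (tree inputs go through [cophenetic_matrix()] first). Species carrying
#' rare, distant trait combinations receive large weights; redundant species
#' may receive weight zero. For ultrametric `D` (UPGMA output, Gower via
#' clustering) the entropy is concave on the simplex and the maximizer
#' unique.
#'
#' Instances with up to `exact_n` species are solved by exhaustive
#' active-set enumeration (every support set, equality-constrained solve,
#' KKT screen); larger instances by projected-gradient ascent with a final
#' KKT verification.
#'
#' @param d symmetric non-negative labelled dissimilarity matrix with zero
#'   diagonal.
#' @param trait_set tag recorded on the output.
#' @param tol tolerance on the KKT stationarity residual.
#' @param exact_n largest size solved by exhaustive enumeration.
#' @return normalized [species_scores()] with metric `"qe"`; attribute
#'   `"qe"` holds the achieved quadratic entropy.
#' @export
qe_originality <- function(d, trait_set = "custom", tol = 1e-10, exact_n = 12L) {
  validate_distance_matrix(d)
  n <- nrow(d)
  if (n < 2L) stop("need at least 2 species")
  if (all(d == 0)) stop("no originality signal: all dissimilarities are zero")
  ids <- rownames(d)

  qe_of <- function(p) as.numeric(p %*% d %*% p)

  if (n <= exact_n) {
    best_p <- NULL
    best_f <- -Inf
    for (mask in seq_len(2L^n - 1L)) {
      S <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) != 0L)
      if (length(S) < 2L) next
      dS <- d[S, S, drop = FALSE]
      x <- tryCatch(solve(dS, rep(1, length(S))), error = function(e) NULL)
      if (is.null(x)) next
      sx <- sum(x)
      if (abs(sx) < 1e-14) next
      pS <- x / sx
      if (any(pS < -1e-10)) next
      pS <- pmax(pS, 0)
      pS <- pS / sum(pS)
      p <- numeric(n)
      p[S] <- pS
      f <- qe_of(p)
      g <- as.numeric(d %*% p)
      if (max(g) > f + 1e-8 * max(1, f)) next  # KKT: no excluded species can improve
      if (f > best_f + 1e-12) {
        best_f <- f
        best_p <- p
      }
    }
    if (is.null(best_p)) stop("QE maximization failed: no KKT point found")
    p <- best_p
  } else {
    p <- rep(1 / n, n)
    L <- 2 * max(abs(eigen(d, symmetric = TRUE, only.values = TRUE)$values))
    step <- 1 / L
    for (it in seq_len(200000L)) {
      g <- 2 * as.numeric(d %*% p)
      p_new <- .project_simplex(p + step * g)
      mu <- qe_of(p_new)
      gr <- as.numeric(d %*% p_new)
      res <- max(c(gr[p_new > 1e-12] - mu, mu - gr[p_new > 1e-12],
                   gr - mu))
      p <- p_new
      if (res < tol * max(1, mu)) break
    }
  }
  out <- species_scores(p, ids, metric = "qe", trait_set = trait_set,
                        normalized = TRUE)
  attr(out, "qe") <- qe_of(p)
  out
}

# Euclidean projection onto the probability simplex (Duchi et al. 2008)
.project_simplex <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u - (css - 1) / seq_along(u) > 0))
  theta <- (css[rho] - 1) / rho
  pmax(v - theta, 0)
}

#' Normalize scores to proportions
#'
#' Divides each score by the total so species values sum to one, making
#' indices computed from different trait sets comparable.
#'
#' @param s a [species_scores()] vector with positive total.
#' @return normalized [species_scores()].
#' @export
as_proportions <- function(s) {
  stopifnot(inherits(s, "species_scores"))
  tot <- sum(s)
  if (tot <= 0) stop("cannot normalize an all-zero score vector")
  species_scores(as.numeric(s) / tot, names(s),
                 metric = attr(s, "metric"), trait_set = attr(s, "trait_set"),
                 normalized = TRUE)
}

#' Species originality from a trait table
#'
#' Convenience chain: Gower dissimilarity, UPGMA dendrogram, then the chosen
#' originality metric (equal-splits on the tree; QE on its cophenetic
#' distances).
#'
#' @param tt a [trait_table()].
#' @param metric `"equal_splits"` (default) or `"qe"`.
#' @param trait_set tag recorded on the output.
#' @param proportions normalize the result with [as_proportions()]?
#' @param weights optional Gower trait weights.
#' @return [species_scores()].
#' @export
soi_from_traits <- function(tt, metric = c("equal_splits", "qe"),
                            trait_set = "custom", proportions = TRUE,
                            weights = NULL) {
  metric <- match.arg(metric)
  d <- gower_distance(tt, weights = weights)
  tr <- upgma(d)
  s <- if (metric == "equal_splits") {
    equal_splits(tr, trait_set = trait_set)
  } else {
    qe_originality(cophenetic_matrix(tr), trait_set = trait_set)
  }
  if (proportions) as_proportions(s) else s
}

#' Sensitivity of originality scores to species additions
#'
#' Measures how stable per-species originality is when the species pool
#' grows: for each replicate, a random subset of the extra species is added
#' to the base table, originality is recomputed on both tables, and the
#' extended-set scores of the shared species are regressed on the base
#' scores. The coefficient of determination is reported on a 0-100 scale.
#'
#' @param base [trait_table()] of the core species set.
#' @param extended [trait_table()] containing all base species plus at least
#'   one extra, with the same trait schema.
#' @param metric `"equal_splits"` or `"qe"`.
#' @param n_reps number of random-subset replicates.
#' @param seed integer seed.
#' @return list of class `addition_sensitivity` with `per_rep` (data.frame
#'   of rep, n_added, r2) and `mean_r2`.
#' @export
species_addition_sensitivity <- function(base, extended,
                                         metric = c("equal_splits", "qe"),
                                         n_reps = 50, seed = 1) {
  metric <- match.arg(metric)
  stopifnot(inherits(base, "trait_table"), inherits(extended, "trait_table"))
  if (!identical(sort(names(base$kinds)), sort(names(extended$kinds))) ||
      !identical(base$kinds[sort(names(base$kinds))],
                 extended$kinds[sort(names(extended$kinds))])) {
    stop("trait schema mismatch between base and extended tables")
  }
  base_ids <- rownames(base$data)
  ext_ids <- rownames(extended$data)
  if (!all(base_ids %in% ext_ids)) stop("extended table must contain all base species")
  extras <- setdiff(ext_ids, base_ids)
  if (!length(extras)) stop("extended table adds no species")

  s_base <- soi_from_traits(base, metric = metric, proportions = TRUE)
  set.seed(seed)
  per_rep <- data.frame(rep = seq_len(n_reps), n_added = NA_integer_, r2 = NA_real_)
  for (r in seq_len(n_reps)) {
    k <- sample.int(length(extras), 1L)
    add <- sample(extras, k)
    keep <- c(base_ids, add)
    sub <- trait_table(
      cbind(extended$data[keep, , drop = FALSE],
            species_id = keep),
      kinds = extended$kinds
    )
    s_ext <- soi_from_traits(sub, metric = metric, proportions = TRUE)
    per_rep$n_added[r] <- k
    per_rep$r2[r] <- r2_percent(as.numeric(s_base[base_ids]),
                                as.numeric(s_ext[base_ids]))
  }
  structure(list(per_rep = per_rep, mean_r2 = mean(per_rep$r2),
                 metric = metric, seed = seed),
            class = "addition_sensitivity")
}

#' Coefficient of determination on a 0-100 scale
#'
#' Simple least-squares fit of `y` on `x`; returns 100 * R-squared.
#' @param x,y numeric vectors of equal length.
#' @export
r2_percent <- function(x, y) {
  fit <- stats::lm(y ~ x)
  100 * summary(fit)$r.squared
}

#' Write species scores as labelled CSV with metadata header
#' @param s a [species_scores()].
#' @param path output path.
#' @export
write_scores_csv <- function(s, path) {
  stopifnot(inherits(s, "species_scores"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# metric=", attr(s, "metric")),
               paste0("# trait_set=", attr(s, "trait_set")),
               paste0("# normalized=", tolower(as.character(attr(s, "normalized"))))),
             con)
  utils::write.csv(data.frame(species_id = names(s),
                              value = sprintf("%.17g", as.numeric(s))),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read species scores written by [write_scores_csv()]
#' @param path input path.
#' @return [species_scores()].
#' @export
read_scores_csv <- function(path) {
  ln <- readLines(path)
  meta_ln <- grep("^#", ln, value = TRUE)
  meta <- list(metric = "equal_splits", trait_set = "custom", normalized = "false")
  for (m in meta_ln) {
    kv <- strsplit(sub("^#\\s*", "", m), "=", fixed = TRUE)[[1L]]
    if (length(kv) == 2L) meta[[trimws(kv[1L])]] <- trimws(kv[2L])
  }
  df <- utils::read.csv(textConnection(ln[!startsWith(ln, "#")]),
                        stringsAsFactors = FALSE)
  species_scores(df$value, df$species_id, metric = meta$metric,
                 trait_set = meta$trait_set,
                 normalized = identical(tolower(meta$normalized), "true"))
}
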