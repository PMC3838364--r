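#' Construct a mixed-type trait table
#'
#' A trait table couples a species-by-trait data frame with a declared
#' statistical kind for every trait column. Kinds drive how the Gower
#' dissimilarity treats each column: `quantitative` and `ordinal` traits are
#' range-normalized (ordinal after conversion to ranks), `nominal` and
#' `binary` traits contribute a simple matching distance.
#'
#' @param data data.frame of trait values; species identifiers either as row
#'   names or in a column named `species_id`.
#' @param kinds named character vector mapping every trait column to one of
#'   `"quantitative"`, `"ordinal"`, `"nominal"`, `"binary"`.
#' @return An object of class `trait_table` with elements `data` (trait
#'   columns only, species ids as row names) and `kinds`.
#' @examples
#' tt <- trait_table(
#'   data.frame(species_id = c("a", "b"), len = c(1, 2), mig = c(0, 1)),
#'   kinds = c(len = "quantitative", mig = "binary")
#' )
#' @export
trait_table <- function(data, kinds) {
  stopifnot(is.data.frame(data))
  if ("species_id" %in% names(data)) {
    ids <- as.character(data$species_id)
    data <- data[, setdiff(names(data), "species_id"), drop = FALSE]
  } else {
    ids <- rownames(data)
  }
  if (is.null(ids) || !length(ids) || any(!nzchar(ids))) {
    stop("trait table needs species identifiers (row names or a 'species_id' column)")
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate species id(s): ", paste(dup, collapse = ", "))
  }
  if (ncol(data) == 0L) stop("trait table has no trait columns")
  kinds <- unlist(kinds)
  valid_kinds <- c("quantitative", "ordinal", "nominal", "binary")
  undeclared <- setdiff(names(data), names(kinds))
  if (length(undeclared)) {
    stop("trait column(s) without a declared kind: ", paste(undeclared, collapse = ", "))
  }
  kinds <- kinds[names(data)]
  bad <- !kinds %in% valid_kinds
  if (any(bad)) {
    stop("invalid trait kind(s): ", paste(unique(kinds[bad]), collapse = ", "))
  }
  for (j in names(data)) {
    v <- data[[j]]
    if (all(is.na(v))) stop("trait column '", j, "' has no non-missing values")
    if (kinds[[j]] %in% c("quantitative", "ordinal")) {
      vn <- suppressWarnings(as.numeric(as.character(v)))
      if (any(is.na(vn) & !is.na(v))) {
        stop("trait column '", j, "' declared ", kinds[[j]],
             " but is not coercible to numbers")
      }
      data[[j]] <- vn
    } else {
      data[[j]] <- as.character(v)
    }
  }
  rownames(data) <- ids
  structure(list(data = data, kinds = kinds), class = "trait_table")
}

#' @export
print.trait_table <- function(x, ...) {
  cat("trait_table:", nrow(x$data), "species x", ncol(x$data), "traits\n")
  cat("kinds:", paste(names(x$kinds), x$kinds, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Read a trait table from delimited text
#'
#' @param path path to a CSV/TSV file with a header row; the species id is
#'   taken from a `species_id` column, or from the first column otherwise.
#' @param schema named character vector or list mapping trait columns to
#'   kinds, or the path to a sidecar file of `name=kind` lines.
#' @param missing_token string marking missing cells (default `"NA"`).
#' @param sep field delimiter; `NULL` (default) auto-detects comma vs tab
#'   from the header line.
#' @return A [trait_table()].
#' @export
read_trait_table <- function(path, schema, missing_token = "NA", sep = NULL) {
  if (is.character(schema) && length(schema) == 1L && file.exists(schema)) {
    schema <- read_trait_schema(schema)
  }
  if (is.null(sep)) {
    hdr <- readLines(path, n = 1L)
    sep <- if (grepl("\t", hdr)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep, na.strings = missing_token,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  idcol <- if ("species_id" %in% names(df)) "species_id" else names(df)[1L]
  ids <- df[[idcol]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) stop("duplicate species id(s): ", paste(dup, collapse = ", "))
  df <- df[, setdiff(names(df), idcol), drop = FALSE]
  df$species_id <- ids
  trait_table(df, kinds = schema)
}

#' Read a `name=kind` trait schema file
#'
#' Blank lines and lines starting with `#` are ignored.
#' @param path path to the schema file.
#' @return named character vector of trait kinds.
#' @export
read_trait_schema <- function(path) {
  ln <- readLines(path)
  ln <- trimws(ln)
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  parts <- strsplit(ln, "=", fixed = TRUE)
  if (any(lengths(parts) != 2L)) stop("schema lines must be 'name=kind'")
  stats::setNames(trimws(vapply(parts, `[`, "", 2L)),
                  trimws(vapply(parts, `[`, "", 1L)))
}

#' Gower dissimilarity for mixed-type trait tables
#'
#' Computes the Gower (1971) coefficient: quantitative and ordinal traits
#' (ordinal taken as ranks) contribute `|x_i - x_j| / range`, nominal and
#' binary traits contribute 0/1 matching, missing values are handled by
#' pairwise deletion, and per-trait contributions are averaged with the
#' supplied weights over the traits comparable for each pair.
#'
#' Ranges are the observed ranges over non-missing values. A quantitative or
#' ordinal trait with zero observed range contributes 0 dissimilarity (with a
#' warning); a species pair sharing no comparable trait is an error.
#'
#' @param tt a [trait_table()].
#' @param weights optional positive per-trait weights (named or in column
#'   order); default all 1.
#' @return symmetric numeric matrix with zero diagonal and entries in
#'   \[0, 1\], species ids as dimnames.
#' @examples
#' tt <- trait_table(
#'   data.frame(species_id = c("a", "b"), q = c(5, 10), b = c("1", "0")),
#'   kinds = c(q = "quantitative", b = "binary")
#' )
#' gower_distance(tt)  # (|5-10|/5 handled by observed range)
#' @export
gower_distance <- function(tt, weights = NULL) {
  stopifnot(inherits(tt, "trait_table"))
  X <- tt$data
  kinds <- tt$kinds
  n <- nrow(X)
  m <- ncol(X)
  ids <- rownames(X)
  if (is.null(weights)) {
    weights <- rep(1, m)
  } else {
    if (!is.null(names(weights))) {
      miss <- setdiff(names(X), names(weights))
      if (length(miss)) stop("weights missing for trait(s): ", paste(miss, collapse = ", "))
      weights <- weights[names(X)]
    }
    if (length(weights) != m) stop("need one weight per trait")
    if (any(!is.finite(weights) | weights <= 0)) stop("weights must be positive and finite")
  }

  num <- matrix(0, n, n)
  den <- matrix(0, n, n)
  for (j in seq_len(m)) {
    v <- X[[j]]
    ok <- !is.na(v)
    if (kinds[[j]] %in% c("quantitative", "ordinal")) {
      x <- if (kinds[[j]] == "ordinal") rank(v, na.last = "keep") else v
      rng <- diff(range(x, na.rm = TRUE))
      if (rng == 0) {
        warning("trait '", names(X)[j], "' has zero range; it contributes 0 dissimilarity")
        s <- matrix(0, n, n)
      } else {
        s <- abs(outer(x, x, `-`)) / rng
      }
    } else {
      s <- 1 - outer(v, v, `==`)
      mode(s) <- "numeric"
    }
    delta <- outer(ok, ok, `&`)
    s[!delta] <- 0
    num <- num + weights[j] * s
    den <- den + weights[j] * delta
  }
  off <- upper.tri(den)
  if (any(den[off] == 0)) {
    idx <- which(den == 0 & upper.tri(den), arr.ind = TRUE)[1L, ]
    stop("species pair with no comparable trait: ", ids[idx[1L]], " / ", ids[idx[2L]])
  }
  d <- num / den
  diag(d) <- 0
  dimnames(d) <- list(ids, ids)
  d
}

#' Write a labelled square distance matrix as CSV
#' @param d symmetric labelled matrix.
#' @param path output file path.
#' @export
write_distance_csv <- function(d, path) {
  utils::write.csv(as.data.frame(d), path, row.names = TRUE)
  invisible(path)
}

#' Read a labelled square distance matrix from CSV
#' @param path CSV written by [write_distance_csv()].
#' @return symmetric labelled matrix.
#' @export
read_distance_csv <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  d <- as.matrix(df)
  colnames(d) <- rownames(d)
  validate_distance_matrix(d)
  d
}

# shared distance-matrix validation used by clustering and QE originality
validate_distance_matrix <- function(d, require_unit = FALSE) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (is.null(rownames(d))) stop("distance matrix must be labelled")
  if (any(!is.finite(d))) stop("distance matrix has undefined entries")
  if (any(abs(d - t(d)) > 1e-12)) stop("distance matrix must be symmetric")
  if (any(diag(d) != 0)) stop("distance matrix diagonal must be zero")
  if (any(d < 0)) stop("distance matrix entries must be non-negative")
  if (require_unit && any(d > 1 + 1e-12)) stop("distances exceed 1")
  invisible(d)
}
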