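#' Construct a site-level community matrix
#'
#' A `community_matrix` holds one site's years-by-taxa table of integer
#' abundances: the unit on which all temporal beta-diversity statistics
#' are computed.  Rows are consecutive calendar years, columns are taxa
#' recorded at least once at the site.
#'
#' Invariants enforced here and assumed everywhere downstream:
#' counts are non-negative integers; at least two years; years strictly
#' increasing and consecutive (gaps break the consecutive-pair logic and
#' are an error); no duplicated taxon names; every taxon column has at
#' least one non-zero entry (all-zero columns are dropped with a warning,
#' since site statistics are defined on the site's own taxon list).
#'
#' @param counts numeric matrix of non-negative integer abundances,
#'   years in rows, taxa in columns.
#' @param site_id scalar site identifier.
#' @param years integer vector of calendar years, one per row; defaults
#'   to the matrix rownames.
#' @param taxa character vector of taxon identifiers, one per column;
#'   defaults to the matrix colnames.
#'
#' @return An object of class `community_matrix`: an integer matrix with
#'   years as rownames, taxa as colnames and a `site_id` attribute.
#'
#' @examples
#' m <- community_matrix(rbind(c(2, 1), c(4, 0)), site_id = "A",
#'                       years = 2000:2001, taxa = c("t1", "t2"))
#' alpha_richness(m)
#' gamma_richness(m)
#' @export
community_matrix <- function(counts, site_id, years = NULL, taxa = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  years <- years %||% as.integer(rownames(counts))
  taxa <- taxa %||% colnames(counts)
  if (is.null(years) || anyNA(years)) {
    rlang::abort("`years` must be supplied (or present as rownames)")
  }
  if (is.null(taxa)) {
    rlang::abort("`taxa` must be supplied (or present as colnames)")
  }
  years <- as.integer(years)
  storage.mode(counts) <- "double"
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    bad <- which(is.na(counts) | counts < 0 | counts != round(counts),
                 arr.ind = TRUE)[1, , drop = TRUE]
    rlang::abort(sprintf(
      "counts must be non-negative integers; offending cell: year %s, taxon '%s'",
      years[bad[["row"]]], taxa[bad[["col"]]]))
  }
  storage.mode(counts) <- "integer"
  if (length(years) < 2L) {
    rlang::abort(sprintf("site '%s': need at least 2 years", site_id))
  }
  if (is.unsorted(years, strictly = TRUE)) {
    rlang::abort(sprintf("site '%s': years must be strictly increasing", site_id))
  }
  if (any(diff(years) != 1L)) {
    gap <- years[which(diff(years) != 1L)[1L]]
    rlang::abort(sprintf(
      "site '%s': years must be consecutive; gap after %d (consecutive-pair analysis needs contiguous years)",
      site_id, gap))
  }
  if (anyDuplicated(taxa)) {
    rlang::abort(sprintf("site '%s': duplicated taxon identifiers: %s",
                         site_id, paste(unique(taxa[duplicated(taxa)]), collapse = ", ")))
  }
  empty <- colSums(counts) == 0L
  if (any(empty)) {
    rlang::warn(sprintf(
      "site '%s': dropping %d all-zero taxon column(s): %s",
      site_id, sum(empty), paste(taxa[empty], collapse = ", ")))
    counts <- counts[, !empty, drop = FALSE]
    taxa <- taxa[!empty]
  }
  if (ncol(counts) == 0L) {
    rlang::abort(sprintf("site '%s': no taxon was ever recorded", site_id))
  }
  # canonical lexicographic taxon order, so row-order of the source file
  # never leaks into results
  ord <- order(taxa, method = "radix")
  counts <- counts[, ord, drop = FALSE]
  dimnames(counts) <- list(as.character(years), taxa[ord])
  structure(counts, site_id = as.character(site_id),
            class = c("community_matrix", "matrix", "array"))
}

#' @export
print.community_matrix <- function(x, ...) {
  cat(sprintf("<community_matrix> site '%s': %d years (%s-%s), %d taxa\n",
              site_id(x), nrow(x), rownames(x)[1L], rownames(x)[nrow(x)],
              ncol(x)))
  cat(sprintf("  per-year richness (alpha): %s\n",
              paste(alpha_richness(x), collapse = " ")))
  cat(sprintf("  total richness (gamma): %d\n", gamma_richness(x)))
  invisible(x)
}

#' Site identifier, per-year richness and total richness
#'
#' `site_id()` returns the site label; `alpha_richness()` the number of
#' taxa with non-zero abundance in each year (temporal alpha diversity);
#' `gamma_richness()` the number of taxa recorded at least once across
#' all years (temporal gamma diversity).
#'
#' @param x a [community_matrix()].
#' @return `site_id()` a string; `alpha_richness()` a named integer
#'   vector (one per year); `gamma_richness()` a single integer.
#' @export
site_id <- function(x) attr(x, "site_id")

#' @rdname site_id
#' @export
alpha_richness <- function(x) {
  stopifnot(inherits(x, "community_matrix"))
  r <- rowSums(x > 0)
  storage.mode(r) <- "integer"
  r
}

#' @rdname site_id
#' @export
gamma_richness <- function(x) {
  stopifnot(inherits(x, "community_matrix"))
  sum(colSums(x > 0) > 0)
}

#' Years covered by a community matrix
#' @param x a [community_matrix()].
#' @return integer vector of calendar years.
#' @export
community_years <- function(x) as.integer(rownames(x))

#' Summarize a set of community matrices as a tibble
#'
#' One row per site with its year span, temporal alpha diversity (mean
#' per-year richness) and temporal gamma diversity (total richness).
#'
#' @param matrices list of [community_matrix()] objects.
#' @return tibble with columns `site`, `n_years`, `first_year`,
#'   `last_year`, `alpha_mean`, `gamma`.
#' @export
community_summary <- function(matrices) {
  stopifnot(is.list(matrices))
  purrr::map_dfr(matrices, function(m) {
    yrs <- community_years(m)
    tibble::tibble(site = site_id(m), n_years = length(yrs),
                   first_year = min(yrs), last_year = max(yrs),
                   alpha_mean = mean(alpha_richness(m)),
                   gamma = gamma_richness(m))
  })
}
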