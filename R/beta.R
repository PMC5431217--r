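#' Log(x + 1) transform of a community matrix
#'
#' Abundances are transformed cell-wise to `log(x + 1)` before any
#' dissimilarity is computed, damping the influence of highly abundant
#' taxa.  The logarithm base matters for Bray-Curtis (the index is not
#' base-invariant), so it is an explicit argument; natural log is the
#' default.
#'
#' @param x a [community_matrix()] or non-negative numeric matrix.
#' @param base logarithm base (`exp(1)`, `10` or `2`).
#' @return numeric matrix of the same shape; zeros stay zero.
#' @export
log_transform <- function(x, base = exp(1)) {
  m <- unclass(x)
  storage.mode(m) <- "double"
  if (any(m < 0)) rlang::abort("abundances must be non-negative")
  log1p(m) / log(base)
}

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' `sum(|x - y|) / sum(x + y)` over taxa: 0 for identical vectors, 1
#' when no abundance is shared.
#'
#' @param x,y non-negative numeric vectors of equal length.
#' @return dissimilarity in `[0, 1]`.
#' @examples
#' bray_curtis(c(2, 2), c(1, 3))  # 0.25
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) rlang::abort("vectors must have equal length")
  if (any(x < 0) || any(y < 0)) rlang::abort("entries must be non-negative")
  tot <- sum(x) + sum(y)
  if (tot == 0) {
    rlang::abort("Bray-Curtis is undefined for two all-zero vectors (empty year?)")
  }
  sum(abs(x - y)) / tot
}

# consecutive-pair Bray-Curtis values for an already log-transformed
# matrix; the vectorized hot path shared with the null engine
consecutive_bc <- function(m) {
  n <- nrow(m)
  a <- m[-n, , drop = FALSE]
  b <- m[-1L, , drop = FALSE]
  num <- rowSums(abs(a - b))
  den <- rowSums(a + b)
  num / den
}

#' Consecutive-year Bray-Curtis dissimilarities for one site
#'
#' Applies the log(x + 1) transform once, then computes Bray-Curtis
#' between every adjacent pair of years.  The mean of these pair values
#' is the site's observed temporal beta diversity (beta_obs); with 14
#' years there are 13 pairs.
#'
#' @param matrix a [community_matrix()].
#' @param log_base logarithm base for the abundance transform.
#' @return tibble with one row per consecutive pair: `site`,
#'   `year_from`, `year_to`, `dissimilarity`.
#' @seealso [beta_observed()] for the per-site summary.
#' @export
consecutive_dissimilarities <- function(matrix, log_base = exp(1)) {
  stopifnot(inherits(matrix, "community_matrix"))
  yrs <- community_years(matrix)
  empty <- rowSums(matrix) == 0L
  if (any(empty)) {
    rlang::abort(sprintf("site '%s': year %d has zero total abundance",
                         site_id(matrix), yrs[which(empty)[1L]]))
  }
  vals <- consecutive_bc(log_transform(matrix, base = log_base))
  tibble::tibble(site = site_id(matrix),
                 year_from = yrs[-length(yrs)],
                 year_to = yrs[-1L],
                 dissimilarity = unname(vals))
}

#' Observed temporal beta diversity per site
#'
#' Summarizes consecutive-pair dissimilarities to one row per site:
#' `beta_obs` (the mean pair dissimilarity) and `beta_obs_sd` (standard
#' deviation over the pair values).  With a single pair the SD is
#' reported as 0 and flagged (`sd_degenerate`), keeping the table
#' rectangular.
#'
#' @param matrices list of [community_matrix()] objects (or one).
#' @inheritParams consecutive_dissimilarities
#' @return tibble with columns `site`, `n_pairs`, `beta_obs`,
#'   `beta_obs_sd`, `sd_degenerate`.
#' @export
beta_observed <- function(matrices, log_base = exp(1)) {
  if (inherits(matrices, "community_matrix")) matrices <- list(matrices)
  purrr::map_dfr(matrices, function(m) {
    d <- consecutive_dissimilarities(m, log_base = log_base)
    n <- nrow(d)
    tibble::tibble(site = site_id(m), n_pairs = n,
                   beta_obs = mean(d$dissimilarity),
                   beta_obs_sd = if (n > 1L) stats::sd(d$dissimilarity) else 0,
                   sd_degenerate = n < 2L)
  })
}

#' Dissimilarity-by-lag profile and the size of the one-year step
#'
#' Temporal autocorrelation makes consecutive years more similar than
#' distant ones.  This diagnostic computes Bray-Curtis for all
#' `choose(n_years, 2)` year pairs, groups them by year separation
#' (lag), smooths mean dissimilarity against lag with a locally weighted
#' running line ([stats::lowess()]), and reports `lag1_effect`: the
#' smoothed plateau value at the largest lags minus the smoothed value
#' at lag 1, clamped below at 0.  A small value means one-year-apart
#' communities are barely more similar than distant ones, i.e. the
#' consecutive-pair design is not dominated by autocorrelation.
#'
#' @param matrix a [community_matrix()] with at least 3 years.
#' @param smoother_span `lowess` span (fraction of points in each local
#'   fit).
#' @inheritParams consecutive_dissimilarities
#' @return object of class `lag_profile`: a tibble with per-lag columns
#'   `lag`, `n_pairs`, `mean_dissimilarity`, `smoothed`, and attribute
#'   `lag1_effect`.
#' @export
lag_profile <- function(matrix, smoother_span = 2 / 3, log_base = exp(1)) {
  stopifnot(inherits(matrix, "community_matrix"))
  n <- nrow(matrix)
  if (n < 3L) rlang::abort("lag profile needs at least 3 years")
  m <- log_transform(matrix, base = log_base)
  pairs <- utils::combn(n, 2L)
  d <- apply(pairs, 2L, function(ij) bray_curtis(m[ij[1L], ], m[ij[2L], ]))
  lag <- pairs[2L, ] - pairs[1L, ]
  prof <- tibble::tibble(lag = lag, dissimilarity = d) |>
    dplyr::group_by(.data$lag) |>
    dplyr::summarise(n_pairs = dplyr::n(),
                     mean_dissimilarity = mean(.data$dissimilarity),
                     .groups = "drop") |>
    dplyr::arrange(.data$lag)
  if (nrow(prof) > 2L) {
    sm <- stats::lowess(prof$lag, prof$mean_dissimilarity, f = smoother_span)
    prof$smoothed <- sm$y[match(prof$lag, sm$x)]
  } else {
    prof$smoothed <- prof$mean_dissimilarity
  }
  # plateau: smoothed mean over the top third of lags (at least one lag)
  plateau_lags <- prof$lag >= stats::quantile(prof$lag, 2 / 3)
  effect <- max(0, mean(prof$smoothed[plateau_lags]) - prof$smoothed[1L])
  structure(prof, lag1_effect = effect, site_id = site_id(matrix),
            class = c("lag_profile", class(prof)))
}

#' @export
print.lag_profile <- function(x, ...) {
  cat(sprintf("<lag_profile> site '%s': lag-1 effect %.4f\n",
              attr(x, "site_id"), attr(x, "lag1_effect")))
  NextMethod()
}

#' @rdname lag_profile
#' @param profile a `lag_profile` object.
#' @return `lag1_effect()`: the scalar lag-1 autocorrelation effect.
#' @export
lag1_effect <- function(profile) attr(profile, "lag1_effect")
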