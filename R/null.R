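#' Randomize a binary occurrence matrix with fixed marginals (curveball)
#'
#' Shuffles species presences so that per-year richness (row sums),
#' per-taxon occurrence frequency (column sums), total fill and hence
#' site gamma diversity are all retained.  Implemented as the curveball
#' trade algorithm: repeatedly pick two random rows and redistribute the
#' presences they do not share between them.  At stationarity the chain
#' samples uniformly from the set of all binary matrices with the given
#' margins.
#'
#' @param presence binary (0/1 or logical) matrix with no all-zero row.
#' @param trades number of attempted trades (>= 0).
#' @return binary integer matrix of the same shape and margins.
#' @seealso [null_distribution()] for the full quantitative null.
#' @export
binary_randomize <- function(presence, trades) {
  pres <- check_presence(presence)
  if (length(trades) != 1L || is.na(trades) || trades < 0) {
    rlang::abort("`trades` must be a single non-negative integer")
  }
  rows_idx <- apply(pres, 1L, function(r) which(r > 0L), simplify = FALSE)
  rows_idx <- curveball_trades(rows_idx, as.integer(trades))
  out <- matrix(0L, nrow(pres), ncol(pres), dimnames = dimnames(pres))
  out[cbind(rep(seq_len(nrow(pres)), lengths(rows_idx)),
            unlist(rows_idx, use.names = FALSE))] <- 1L
  out
}

check_presence <- function(presence) {
  if (!is.matrix(presence)) rlang::abort("`presence` must be a matrix")
  pres <- unclass(presence)
  storage.mode(pres) <- "integer"
  if (anyNA(pres) || !all(pres %in% c(0L, 1L))) {
    rlang::abort("`presence` must be binary (0/1)")
  }
  if (any(rowSums(pres) == 0L)) {
    rlang::abort("`presence` must have no all-zero rows")
  }
  pres
}

# curveball trades on a list of per-row presence column indices
curveball_trades <- function(rows_idx, n_trades) {
  nr <- length(rows_idx)
  if (nr < 2L) return(rows_idx)
  for (t in seq_len(n_trades)) {
    ab <- sample.int(nr, 2L)
    a <- rows_idx[[ab[1L]]]
    b <- rows_idx[[ab[2L]]]
    in_b <- a %in% b
    in_a <- b %in% a
    only_a <- a[!in_b]
    only_b <- b[!in_a]
    la <- length(only_a)
    if (la > 0L && length(only_b) > 0L) {
      pool <- c(only_a, only_b)       # all distinct by construction
      keep <- sample.int(length(pool), la)
      rows_idx[[ab[1L]]] <- c(a[in_b], pool[keep])
      rows_idx[[ab[2L]]] <- c(b[in_a], pool[-keep])
    }
  }
  rows_idx
}

# default trade counts: enough mixing for the matrix's number of years
default_burn_in <- function(n_rows) as.integer(ceiling(10 * n_rows * log(n_rows + 1)))
default_thin <- function(n_rows) as.integer(2L * n_rows)

#' Distribute individuals over the non-zero cells of a null matrix
#'
#' Given a randomized presence structure and the observed per-year
#' totals, re-allocates individuals so that every present taxon gets at
#' least one individual and year totals are preserved exactly
#' (`"multinomial_min1"`, the default): each presence cell receives 1
#' individual and the remaining `N_i - k_i` are distributed
#' multinomially with equal cell probabilities.  The alternative
#' `"shuffle_nonzero"` permutes the observed non-zero abundance values
#' across all presence cells of the matrix; it preserves the abundance
#' multiset and fill but not row totals, and warns accordingly.
#'
#' @param row_totals integer vector of per-row individual totals.
#' @param presence binary matrix (rows x taxa).
#' @param scheme allocation scheme, `"multinomial_min1"` or
#'   `"shuffle_nonzero"`.
#' @param values observed non-zero abundance values (required for
#'   `"shuffle_nonzero"`; length must equal the matrix fill).
#' @return integer matrix: positive entries exactly on the presence
#'   cells; under `"multinomial_min1"` row sums equal `row_totals`.
#' @export
allocate_abundances <- function(row_totals, presence,
                                scheme = c("multinomial_min1", "shuffle_nonzero"),
                                values = NULL) {
  scheme <- match.arg(scheme)
  pres <- check_presence(presence)
  nr <- nrow(pres)
  if (length(row_totals) != nr) {
    rlang::abort("`row_totals` must have one entry per row of `presence`")
  }
  out <- matrix(0L, nr, ncol(pres), dimnames = dimnames(pres))
  if (scheme == "multinomial_min1") {
    for (i in seq_len(nr)) {
      cells <- which(pres[i, ] > 0L)
      k <- length(cells)
      if (row_totals[i] < k) {
        rlang::abort(sprintf(
          "row %d: total %d is smaller than its %d presences (cannot give every present taxon >= 1 individual)",
          i, row_totals[i], k))
      }
      extra <- stats::rmultinom(1L, row_totals[i] - k, rep.int(1, k))[, 1L]
      out[i, cells] <- 1L + extra
    }
  } else {
    fill <- sum(pres)
    if (is.null(values) || length(values) != fill) {
      rlang::abort("`shuffle_nonzero` needs `values` with one observed non-zero abundance per presence cell")
    }
    rlang::warn("allocation scheme 'shuffle_nonzero' does not preserve per-year totals")
    idx <- which(t(pres) > 0L)        # row-major order of presence cells
    out_t <- matrix(0L, ncol(pres), nr)
    out_t[idx] <- as.integer(sample(values))
    out <- t(out_t)
    dimnames(out) <- dimnames(pres)
  }
  out
}

#' Null distribution of temporal beta diversity for one site
#'
#' Runs the quantitative null model: the binary occurrence structure is
#' randomized by curveball trades (a burn-in on the first iteration,
#' thinning trades between subsequent ones, so iterations form a
#' well-mixed chain), individuals are re-allocated over the non-zero
#' cells, abundances are log(x + 1)-transformed and the mean
#' consecutive-year Bray-Curtis dissimilarity is recorded.  Over
#' `n_iter` iterations this yields the expected temporal beta diversity
#' `beta_exp` (mean) and its standard deviation, from which the
#' departure statistic is `beta_dep = (beta_obs - beta_exp) / SD
#' beta_exp`.
#'
#' Every null matrix preserves, relative to the observed one: per-year
#' richness, per-taxon occurrence frequency, total fill, the set of
#' non-zero taxa (gamma) and (under `"multinomial_min1"`) per-year
#' abundance totals.
#'
#' @param matrix a [community_matrix()].
#' @param n_iter number of null iterations (default 1000).
#' @param allocation_scheme see [allocate_abundances()].
#' @param burn_in_trades curveball trades before the first iteration;
#'   default `ceiling(10 * n_years * log(n_years + 1))`.
#' @param thin_trades trades between successive iterations; default
#'   `2 * n_years`.
#' @param seed optional integer seed giving a self-contained RNG stream;
#'   with `NULL` the caller's stream is used.
#' @param log_base logarithm base for the abundance transform.
#' @param keep_iterations keep the per-iteration mean dissimilarities
#'   (attribute `per_iteration_means`).
#' @param check_conservation assert the marginal-preservation contract
#'   on every iteration (slower; used in tests).
#' @return one-row tibble: `site`, `n_pairs`, `beta_obs`,
#'   `beta_exp_mean`, `beta_exp_sd`, `beta_dep`, `n_iter`,
#'   `degenerate_null`.  `beta_exp_sd` uses the n-1 denominator over the
#'   iteration means.
#' @export
null_distribution <- function(matrix, n_iter = 1000L,
                              allocation_scheme = c("multinomial_min1", "shuffle_nonzero"),
                              burn_in_trades = NULL, thin_trades = NULL,
                              seed = NULL, log_base = exp(1),
                              keep_iterations = FALSE,
                              check_conservation = FALSE) {
  stopifnot(inherits(matrix, "community_matrix"))
  allocation_scheme <- match.arg(allocation_scheme)
  if (n_iter < 1L) rlang::abort("`n_iter` must be >= 1")
  run <- function() {
    null_distribution_impl(matrix, n_iter, allocation_scheme,
                           burn_in_trades, thin_trades, log_base,
                           keep_iterations, check_conservation)
  }
  if (!is.null(seed)) with_seed(seed, run()) else run()
}

null_distribution_impl <- function(matrix, n_iter, allocation_scheme,
                                   burn_in_trades, thin_trades, log_base,
                                   keep_iterations, check_conservation) {
  nr <- nrow(matrix)
  burn_in <- burn_in_trades %||% default_burn_in(nr)
  thin <- thin_trades %||% default_thin(nr)
  pres <- (unclass(matrix) > 0L) * 1L
  totals <- rowSums(matrix)
  if (any(totals == 0)) {
    rlang::abort(sprintf("site '%s': a year has zero total abundance", site_id(matrix)))
  }
  obs_values <- as.integer(t(matrix))[which(t(pres) > 0L)]
  rows_idx <- apply(pres, 1L, function(r) which(r > 0L), simplify = FALSE)
  log_den <- log(log_base)
  iter_means <- numeric(n_iter)
  nc <- ncol(matrix)
  row_rep <- function(ri) rep(seq_len(nr), lengths(ri))
  for (it in seq_len(n_iter)) {
    rows_idx <- curveball_trades(rows_idx, if (it == 1L) burn_in else thin)
    m <- matrix(0L, nr, nc)
    m[cbind(row_rep(rows_idx), unlist(rows_idx, use.names = FALSE))] <- 1L
    null_counts <- if (allocation_scheme == "multinomial_min1") {
      allocate_abundances(totals, m, "multinomial_min1")
    } else {
      suppressWarnings(allocate_abundances(totals, m, "shuffle_nonzero",
                                           values = obs_values))
    }
    if (check_conservation) {
      assert_null_conservation(matrix, pres, null_counts, allocation_scheme)
    }
    iter_means[it] <- mean(consecutive_bc(log1p(null_counts) / log_den))
  }
  beta_obs <- mean(consecutive_bc(log_transform(matrix, base = log_base)))
  exp_mean <- mean(iter_means)
  exp_sd <- if (n_iter > 1L) stats::sd(iter_means) else 0
  degenerate <- exp_sd == 0
  out <- tibble::tibble(site = site_id(matrix), n_pairs = nr - 1L,
                        beta_obs = beta_obs, beta_exp_mean = exp_mean,
                        beta_exp_sd = exp_sd,
                        beta_dep = beta_departure(beta_obs, exp_mean, exp_sd),
                        n_iter = as.integer(n_iter),
                        degenerate_null = degenerate)
  if (keep_iterations) attr(out, "per_iteration_means") <- iter_means
  out
}

# marginal-preservation contract, asserted per iteration in test mode
assert_null_conservation <- function(observed, pres, null_counts, scheme) {
  null_pres <- (null_counts > 0L) * 1L
  stopifnot(all(rowSums(null_pres) == rowSums(pres)),
            all(colSums(null_pres) == colSums(pres)),
            sum(null_pres) == sum(pres),
            all(colSums(null_counts) == 0 | colSums(observed) > 0))
  if (scheme == "multinomial_min1") {
    stopifnot(all(rowSums(null_counts) == rowSums(observed)))
  }
}

#' Departure of observed beta diversity from the null expectation
#'
#' The standardized effect size `(beta_obs - beta_exp_mean) /
#' beta_exp_sd`: the number of null standard deviations the observed
#' mean dissimilarity lies from the chance expectation.  Negative
#' values mean consecutive-year communities are less dissimilar (more
#' stable) than expected by chance.  A degenerate null (`beta_exp_sd ==
#' 0`) returns 0.
#'
#' @param beta_obs observed mean consecutive-pair dissimilarity.
#' @param beta_exp_mean,beta_exp_sd mean and SD of the null iteration
#'   means.
#' @return the effect size (vectorized).
#' @examples
#' beta_departure(0.25, 0.30, 0.025)  # -2
#' @export
beta_departure <- function(beta_obs, beta_exp_mean, beta_exp_sd) {
  if (any(beta_exp_sd < 0)) rlang::abort("`beta_exp_sd` must be >= 0")
  ifelse(beta_exp_sd == 0, 0, (beta_obs - beta_exp_mean) / beta_exp_sd)
}

#' Classify a site's stability from its null departure
#'
#' A community is read as more stable than expected by chance when
#' `beta_dep` falls strictly below the threshold (default -2, i.e. two
#' null SDs below the expectation).
#'
#' @param beta_dep departure statistic (vectorized).
#' @param threshold classification threshold (strict `<`).
#' @return factor with levels `more_stable_than_chance`,
#'   `indistinguishable`.
#' @export
classify_stability <- function(beta_dep, threshold = -2) {
  if (anyNA(beta_dep) || any(!is.finite(beta_dep))) {
    rlang::abort("`beta_dep` must be finite")
  }
  factor(ifelse(beta_dep < threshold, "more_stable_than_chance",
                "indistinguishable"),
         levels = c("more_stable_than_chance", "indistinguishable"))
}

#' Null-model departure for every site of a study
#'
#' Maps [null_distribution()] over a list of community matrices.  Each
#' site gets an independent RNG substream derived from `seed` and a hash
#' of its identifier, so results do not depend on the order in which
#' sites are processed.
#'
#' @param matrices list of [community_matrix()] objects.
#' @param seed master integer seed.
#' @inheritParams null_distribution
#' @param stability_threshold threshold passed to [classify_stability()].
#' @return tibble with one row per site: the [null_distribution()]
#'   columns plus `stability`.
#' @export
null_beta <- function(matrices, n_iter = 1000L, seed = 1L,
                      allocation_scheme = "multinomial_min1",
                      burn_in_trades = NULL, thin_trades = NULL,
                      log_base = exp(1), stability_threshold = -2) {
  if (inherits(matrices, "community_matrix")) matrices <- list(matrices)
  purrr::map_dfr(matrices, function(m) {
    null_distribution(m, n_iter = n_iter,
                      allocation_scheme = allocation_scheme,
                      burn_in_trades = burn_in_trades,
                      thin_trades = thin_trades,
                      seed = site_seed(seed, site_id(m)),
                      log_base = log_base)
  }) |>
    dplyr::mutate(stability = classify_stability(.data$beta_dep,
                                                 stability_threshold))
}
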