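#' Z-score the columns of a data frame
#'
#' Centers each numeric column to mean 0 and scales to standard
#' deviation 1 (n-1 denominator).  Regressions on z-scored response and
#' predictors yield standardized coefficients directly.
#'
#' @param data data frame; non-numeric columns are passed through.
#' @return tibble of the same shape.
#' @export
standardize <- function(data) {
  data <- tibble::as_tibble(data)
  num <- vapply(data, is.numeric, logical(1L))
  for (col in names(data)[num]) {
    s <- stats::sd(data[[col]])
    if (is.na(s) || s == 0) {
      rlang::abort(sprintf("cannot standardize zero-variance column `%s`", col))
    }
    data[[col]] <- (data[[col]] - mean(data[[col]])) / s
  }
  data
}

# small-sample-corrected AIC from the Gaussian profile log-likelihood;
# k counts slopes + intercept + residual variance
aicc_from_rss <- function(rss, n, n_slopes) {
  k <- n_slopes + 2
  if (n - k - 1 <= 0) {
    rlang::abort(sprintf(
      "AICc undefined: n = %d too small for a model with %d slopes", n, n_slopes))
  }
  loglik <- -n / 2 * (log(2 * pi) + log(rss / n) + 1)
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Exhaustive-subset OLS with AICc multimodel inference
#'
#' Fits ordinary least squares for every subset of the predictors
#' (including the intercept-only model; 6 predictors give 2^6 = 64
#' candidates) on z-scored response and predictors, so coefficients are
#' standardized.  Models are ranked by AICc (parameter count k = number
#' of slopes + intercept + residual variance); `delta` is the AICc
#' difference to the best model and Akaike weights are
#' `exp(-delta/2)` renormalized over all candidates.
#'
#' @param data data frame holding response and predictors, one row per
#'   site.
#' @param response name of the response column.
#' @param predictors names of the predictor columns (default the six
#'   canonical covariates, see [read_environment()]).
#' @return object of class `beta_model_set`: tibble with one row per
#'   model (`model`, `n_slopes`, one standardized-coefficient column
#'   per predictor, `rss`, `adj_r2`, `aicc`, `delta`, `weight`) plus
#'   attributes `response` and `n`.  Use [tidy()][tidy.beta_model_set],
#'   [glance()][glance.beta_model_set], [variable_importance()],
#'   [best_models()] and [autoplot()][autoplot.beta_model_set] on it.
#' @export
fit_all_subsets <- function(data, response, predictors = env_predictors()) {
  data <- tibble::as_tibble(data)
  miss <- setdiff(c(response, predictors), names(data))
  if (length(miss) > 0L) {
    rlang::abort(sprintf("column(s) not in data: %s", paste(miss, collapse = ", ")))
  }
  n <- nrow(data)
  p_max <- length(predictors)
  if (n <= p_max + 3) {
    rlang::abort(sprintf(
      "need more sites (%d) than %d for AICc on the largest model", n, p_max + 3))
  }
  z <- standardize(data[c(response, predictors)])
  X <- as.matrix(z[predictors])
  if (qr(X)$rank < p_max) {
    rlang::abort(sprintf("collinear predictors among: %s",
                         paste(predictors, collapse = ", ")))
  }
  y <- z[[response]]
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), p_max))
  names(subsets) <- predictors
  rows <- purrr::map(seq_len(nrow(subsets)), function(i) {
    incl <- predictors[unlist(subsets[i, ])]
    p <- length(incl)
    fit <- if (p == 0L) {
      stats::lm(y ~ 1)
    } else {
      stats::lm(y ~ ., data = tibble::as_tibble(z[c(response, incl)]) |>
                  stats::setNames(c("y", incl)))
    }
    rss <- sum(stats::residuals(fit)^2)
    r2 <- 1 - rss / sum((y - mean(y))^2)
    coefs <- stats::setNames(rep(NA_real_, p_max), predictors)
    if (p > 0L) coefs[incl] <- stats::coef(fit)[incl]
    dplyr::bind_cols(
      tibble::tibble(model = if (p == 0L) "(intercept only)" else paste(incl, collapse = " + "),
                     n_slopes = p),
      tibble::as_tibble(as.list(coefs)),
      tibble::tibble(rss = rss,
                     adj_r2 = 1 - (1 - r2) * (n - 1) / (n - p - 1),
                     aicc = aicc_from_rss(rss, n, p)))
  })
  models <- dplyr::bind_rows(rows) |>
    dplyr::mutate(delta = .data$aicc - min(.data$aicc),
                  weight = exp(-.data$delta / 2) / sum(exp(-(.data$aicc - min(.data$aicc)) / 2))) |>
    dplyr::arrange(.data$delta)
  structure(models, response = response, n = n, predictors = predictors,
            class = c("beta_model_set", class(models)))
}

#' @export
print.beta_model_set <- function(x, ...) {
  cat(sprintf("<beta_model_set> response '%s': %d candidate models on %d sites\n",
              attr(x, "response"), nrow(x), attr(x, "n")))
  cat("Best models (delta AICc < 2):\n")
  print(tibble::as_tibble(best_models(x)), ...)
  invisible(x)
}

#' Broom-style accessors for an all-subsets model set
#'
#' `tidy()` returns one row per model and included term with its
#' standardized coefficient; `glance()` one row per model with fit and
#' ranking statistics.
#'
#' @param x a `beta_model_set` from [fit_all_subsets()].
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.beta_model_set <- function(x, ...) {
  preds <- attr(x, "predictors")
  tibble::as_tibble(x) |>
    dplyr::select("model", dplyr::all_of(preds)) |>
    tidyr::pivot_longer(dplyr::all_of(preds), names_to = "term",
                        values_to = "estimate") |>
    dplyr::filter(!is.na(.data$estimate))
}

#' @rdname tidy.beta_model_set
#' @export
glance.beta_model_set <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::select("model", "n_slopes", "rss", "adj_r2", "aicc", "delta",
                  "weight")
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")

#' Per-variable importance as summed Akaike weights
#'
#' A variable's importance is the sum of the Akaike weights of all
#' candidate models that contain it (with 6 predictors, 32 of the 64
#' models).  Variables at or above `threshold` (default 0.80) are
#' flagged `important`.
#'
#' @param result a `beta_model_set`.
#' @param threshold importance cut-off for the flag.
#' @return tibble with columns `variable`, `importance`, `important`,
#'   sorted by decreasing importance.
#' @export
variable_importance <- function(result, threshold = 0.80) {
  stopifnot(inherits(result, "beta_model_set"))
  preds <- attr(result, "predictors")
  purrr::map_dfr(preds, function(v) {
    tibble::tibble(variable = v,
                   importance = sum(result$weight[!is.na(result[[v]])]))
  }) |>
    dplyr::mutate(important = .data$importance >= threshold) |>
    dplyr::arrange(dplyr::desc(.data$importance))
}

#' Models with equal support (delta AICc below a threshold)
#'
#' Models within `delta_threshold` AICc units of the best model are
#' interpreted as having equal support; the default threshold is 2.
#' The comparison is strict `<`, so the threshold must be positive (the
#' best model itself has delta 0).
#'
#' @param result a `beta_model_set`.
#' @param delta_threshold positive delta-AICc cut-off.
#' @return tibble of the qualifying models sorted by delta, with their
#'   standardized coefficients, `adj_r2`, `delta` and `weight`.
#' @export
best_models <- function(result, delta_threshold = 2) {
  stopifnot(inherits(result, "beta_model_set"))
  if (delta_threshold <= 0) {
    rlang::abort("`delta_threshold` must be > 0 (the best model has delta 0)")
  }
  preds <- attr(result, "predictors")
  tibble::as_tibble(result) |>
    dplyr::filter(.data$delta < delta_threshold) |>
    dplyr::arrange(.data$delta) |>
    dplyr::select("model", dplyr::all_of(preds), "adj_r2", "delta", "weight")
}
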