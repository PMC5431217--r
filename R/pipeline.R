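#' Run the full temporal beta-diversity analysis
#'
#' End-to-end pipeline: observed consecutive-year Bray-Curtis
#' dissimilarity per site ([beta_observed()]), the quantitative null
#' model and departure statistic ([null_beta()]), and exhaustive-subset
#' AICc model selection ([fit_all_subsets()]) run twice - once with the
#' observed beta diversity and once with the null departure as response
#' - so the importance tables can be read side by side to separate
#' stochastic from deterministic drivers.
#'
#' @param matrices list of [community_matrix()] objects.
#' @param environment environment tibble (see [read_environment()]);
#'   gamma is computed from `matrices`.
#' @param n_iter null-model iterations per site (default 1000).
#' @param seed master seed for the null model.
#' @param log_base logarithm base for the abundance transform.
#' @param allocation_scheme see [allocate_abundances()].
#' @param stability_threshold beta_dep threshold for
#'   [classify_stability()].
#' @return object of class `betadep_analysis`: list with `beta` (per
#'   site: observed beta, null expectation, beta_dep, stability class,
#'   alpha, gamma), `environment` (with gamma), `models_obs` and
#'   `models_dep` ([fit_all_subsets()] results), `null_config` and
#'   `log_base`.
#' @export
temporal_beta_analysis <- function(matrices, environment, n_iter = 1000L,
                                   seed = 1L, log_base = exp(1),
                                   allocation_scheme = "multinomial_min1",
                                   stability_threshold = -2) {
  env <- assemble_environment(environment, matrices)
  obs <- beta_observed(matrices, log_base = log_base)
  nul <- null_beta(matrices, n_iter = n_iter, seed = seed,
                   allocation_scheme = allocation_scheme,
                   log_base = log_base,
                   stability_threshold = stability_threshold)
  beta <- obs |>
    dplyr::left_join(dplyr::select(nul, !"beta_obs" & !"n_pairs"),
                     by = "site") |>
    dplyr::left_join(community_summary(matrices), by = "site")
  model_data <- beta |>
    dplyr::select("site", "beta_obs", "beta_dep") |>
    dplyr::left_join(env, by = "site")
  structure(list(
    beta = beta,
    environment = env,
    models_obs = fit_all_subsets(model_data, "beta_obs"),
    models_dep = fit_all_subsets(model_data, "beta_dep"),
    null_config = list(n_iter = as.integer(n_iter), seed = as.integer(seed),
                       allocation_scheme = allocation_scheme,
                       stability_threshold = stability_threshold),
    log_base = log_base),
    class = "betadep_analysis")
}

#' @export
print.betadep_analysis <- function(x, ...) {
  b <- x$beta
  cat(sprintf("<betadep_analysis> %d sites, %d null iterations\n",
              nrow(b), x$null_config$n_iter))
  cat(sprintf("  beta_obs: mean %.3f, range %.3f-%.3f\n",
              mean(b$beta_obs), min(b$beta_obs), max(b$beta_obs)))
  cat(sprintf("  beta_dep: range %.3f-%.3f; %d/%d sites more stable than chance\n",
              min(b$beta_dep), max(b$beta_dep),
              sum(b$stability == "more_stable_than_chance"), nrow(b)))
  io <- variable_importance(x$models_obs)
  id <- variable_importance(x$models_dep)
  cat(sprintf("  top importance, beta_obs response: %s (%.2f)\n",
              io$variable[1L], io$importance[1L]))
  cat(sprintf("  top importance, beta_dep response: %s (%.2f)\n",
              id$variable[1L], id$importance[1L]))
  invisible(x)
}
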