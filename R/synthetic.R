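#' Configuration for the synthetic study generator
#'
#' Parameters of a stochastic multi-year community generator emulating a
#' set of riffle-dwelling invertebrate communities censused once a year:
#' a regional taxon pool, site pools of 50-81 taxa, per-year richness
#' around 25-40, right-skewed abundances with year-to-year persistence,
#' and six site covariates of which exactly two causally influence
#' community variability - through two deliberately different channels:
#'
#' * the *bryophyte-like* covariate (V1) acts species-identity-
#'   dependently: each taxon carries a fixed stabilizer trait, and at
#'   high-V1 sites persisting taxa repeat their abundances more
#'   faithfully from year to year, more so for high-trait taxa (a
#'   deterministic, niche-like channel the null model is blind to in
#'   the observed data but erases in its randomizations);
#' * the *connectivity-like* covariate (V2) acts identity-free: it
#'   raises every taxon's persistence equally (mass-effect rescue) and
#'   scales the uniform immigration rate, changing how much occupancy
#'   turns over but never which taxa are favoured (a stochastic
#'   channel).
#'
#' Consequently the expected analysis outcome is that V2 explains
#' observed beta diversity while only V1 explains the null departure
#' beta_dep - the contrast the full pipeline is designed to detect.
#'
#' @param n_sites number of sites (default 23).
#' @param n_years number of consecutive years (default 14).
#' @param pool_size regional taxon pool size (default 129).
#' @param site_gamma_range inclusive range the per-site pool size is
#'   drawn from (default 50-81).
#' @param target_alpha range of per-site target mean annual richness;
#'   used for feasibility checks (default 25-40; realized alpha follows
#'   from the persistence/immigration balance).
#' @param persistence_base probability a present taxon persists to the
#'   next year at a covariate-neutral site (default 0.62).
#' @param stabilizer_effect logit-scale strength with which V1 (through
#'   the per-taxon trait) raises the AR(1) coefficient of persisting
#'   taxa's log abundances - the identity-dependent channel (default
#'   1.3).
#' @param immigration_base expected identity-free colonizations per year
#'   at a covariate-neutral site with a reference-size pool (default
#'   25; the per-taxon annual colonization probability is
#'   `immigration_base * exp(immigration_effect * V2) /
#'   mean(site_gamma_range)`, capped at 0.95 - a fixed reference
#'   denominator, so immigration pressure reflects the surrounding
#'   network rather than the size of the site's own pool).
#' @param connectivity_effect logit-scale strength with which V2 raises
#'   every taxon's persistence equally (mass-effect rescue) - the
#'   identity-free channel driving observed turnover (default 0.5).
#' @param immigration_effect log-scale strength with which V2 scales the
#'   identity-free immigration rate (default 0.25; immigration pushes
#'   the null departure towards zero while rescue pulls it down, and at
#'   this ratio the two leaks into beta_dep roughly cancel, keeping the
#'   connectivity channel orthogonal to the departure response).
#' @param trait_mean,trait_sd distribution of the per-taxon stabilizer
#'   trait (default mean 1, sd 0.5; the positive mean makes the
#'   vegetation channel monotone in V1 while the spread keeps it
#'   species-identity-dependent).
#' @param abundance_meanlog,abundance_sdlog log-normal abundance
#'   parameters for colonizing taxa (default 1.2 and 1: median count 3,
#'   strongly right-skewed).
#' @param abundance_rho baseline AR(1) autocorrelation of log abundance
#'   for persisting taxa (default 0.55; V1 moves it per taxon on the
#'   logit scale).
#' @param site_noise_sd SD of site-level logit noise on the
#'   abundance-stability intercept: between-site heterogeneity in
#'   stability not explained by any covariate (default 0.5).
#' @param turnover_noise_sd SD of site-level logit noise on the
#'   persistence intercept: unexplained heterogeneity in turnover
#'   (default 0.1).
#' @param noise_sd measurement noise SD added to the standard-normal
#'   covariate latents before they are expressed in natural units
#'   (default 0.2).
#' @param seed integer master seed.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_sites = 23L, n_years = 14L, pool_size = 129L,
                             site_gamma_range = c(50L, 81L),
                             target_alpha = c(25L, 40L),
                             persistence_base = 0.62,
                             stabilizer_effect = 1.3,
                             immigration_base = 25,
                             connectivity_effect = 0.5,
                             immigration_effect = 0.25,
                             trait_mean = 1, trait_sd = 0.5,
                             abundance_meanlog = 1.2, abundance_sdlog = 1,
                             abundance_rho = 0.55,
                             site_noise_sd = 0.5, turnover_noise_sd = 0.1,
                             noise_sd = 0.2, seed = 1L) {
  cfg <- list(n_sites = as.integer(n_sites), n_years = as.integer(n_years),
              pool_size = as.integer(pool_size),
              site_gamma_range = as.integer(site_gamma_range),
              target_alpha = as.integer(target_alpha),
              persistence_base = persistence_base,
              stabilizer_effect = stabilizer_effect,
              immigration_base = immigration_base,
              connectivity_effect = connectivity_effect,
              immigration_effect = immigration_effect,
              trait_mean = trait_mean, trait_sd = trait_sd,
              abundance_meanlog = abundance_meanlog,
              abundance_sdlog = abundance_sdlog,
              abundance_rho = abundance_rho,
              site_noise_sd = site_noise_sd,
              turnover_noise_sd = turnover_noise_sd,
              noise_sd = noise_sd, seed = as.integer(seed))
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  with(cfg, {
    stopifnot(n_sites >= 1L, n_years >= 2L,
              length(site_gamma_range) == 2L,
              site_gamma_range[1L] <= site_gamma_range[2L],
              length(target_alpha) == 2L,
              target_alpha[1L] <= target_alpha[2L],
              persistence_base > 0, persistence_base <= 1,
              immigration_base > 0, abundance_rho > 0, abundance_rho < 1,
              site_noise_sd >= 0, turnover_noise_sd >= 0, noise_sd >= 0)
    if (pool_size < site_gamma_range[2L]) {
      rlang::abort("`pool_size` must be at least the upper gamma bound")
    }
    if (target_alpha[2L] > site_gamma_range[1L]) {
      rlang::abort("infeasible alpha/gamma combination: target alpha can exceed the smallest site pool")
    }
  })
  invisible(cfg)
}

pool_taxon_names <- function(pool_size) {
  sprintf("taxon_%03d", seq_len(pool_size))
}

# simulate one site's occupancy/abundance dynamics; latents and traits
# come from the caller so taxon identity is shared across sites.
#
# Two causal channels, kept deliberately orthogonal:
#  * connectivity (v2), identity-free: shifts every taxon's persistence
#    odds equally (mass-effect rescue) and scales the uniform
#    immigration rate - it changes how much occupancy turns over, but
#    not which taxa turn over;
#  * vegetation (v1), identity-dependent: sets the AR(1) coefficient of
#    each persisting taxon's log abundance through that taxon's fixed
#    stabilizer trait (refugia steady populations, more so for some
#    taxa than others) - it changes how faithfully abundances repeat
#    between years, a structure the null model destroys.
simulate_site_matrix <- function(cfg, site_name, pool_idx, traits, v1, v2,
                                 years) {
  g <- length(pool_idx)
  z <- traits[pool_idx]
  p_pers <- stats::plogis(stats::qlogis(cfg$persistence_base) +
                            cfg$connectivity_effect * v2 +
                            stats::rnorm(1L, 0, cfg$turnover_noise_sd))
  # reference pool size, not the site's own: immigration pressure is a
  # property of the surrounding network, so the per-taxon colonization
  # probability must not covary with how many taxa the site pool holds
  g_ref <- mean(cfg$site_gamma_range)
  lambda <- min(0.95, cfg$immigration_base *
                  exp(cfg$immigration_effect * v2) / g_ref)
  rho_taxon <- stats::plogis(stats::qlogis(cfg$abundance_rho) +
                               cfg$stabilizer_effect * v1 * z +
                               stats::rnorm(1L, 0, cfg$site_noise_sd))
  p0 <- lambda / (lambda + (1 - p_pers))
  ny <- cfg$n_years
  occ <- matrix(FALSE, ny, g)
  la <- matrix(NA_real_, ny, g)    # log abundance where occupied
  occ[1L, ] <- stats::runif(g) < p0
  if (!any(occ[1L, ])) occ[1L, sample.int(g, 1L)] <- TRUE
  la[1L, occ[1L, ]] <- stats::rnorm(sum(occ[1L, ]), cfg$abundance_meanlog,
                                    cfg$abundance_sdlog)
  for (y in 2:ny) {
    stay <- occ[y - 1L, ] & stats::runif(g) < p_pers
    come <- !occ[y - 1L, ] & stats::runif(g) < lambda
    occ[y, ] <- stay | come
    if (!any(occ[y, ])) {          # avoid an empty census year
      keep <- sample(which(occ[y - 1L, ]), 1L)
      occ[y, keep] <- TRUE
      stay[keep] <- TRUE
    }
    rho <- rho_taxon[stay]
    la[y, stay] <- cfg$abundance_meanlog +
      rho * (la[y - 1L, stay] - cfg$abundance_meanlog) +
      sqrt(1 - rho^2) * cfg$abundance_sdlog * stats::rnorm(sum(stay))
    la[y, come] <- stats::rnorm(sum(come), cfg$abundance_meanlog,
                                cfg$abundance_sdlog)
  }
  counts <- matrix(0L, ny, g)
  counts[occ] <- pmax(1L, as.integer(round(exp(la[occ]))))
  seen <- colSums(counts) > 0L
  community_matrix(counts[, seen, drop = FALSE], site_id = site_name,
                   years = years,
                   taxa = pool_taxon_names(cfg$pool_size)[pool_idx][seen])
}

# express covariate latents (true + measurement noise) in natural units
covariates_natural <- function(lat_noisy) {
  tibble::tibble(
    site = lat_noisy$site,
    bmi = pmin(100, pmax(0, 15 + 6 * lat_noisy$v3)),
    bryophytes = pmin(100, pmax(0, 40 + 15 * lat_noisy$v1)),
    simpson = 1 + exp(log(2.5) + 0.3 * lat_noisy$v4),
    temperature = 8 + 1.5 * lat_noisy$v5,
    connectivity = exp(log(800) + 0.6 * lat_noisy$v2))
}

#' Generate one synthetic site
#'
#' Simulates a single site under a [synthetic_config()]: the site pool
#' is drawn from the regional pool, year-1 occupancy starts at the
#' site's stationary occupancy, and occupancy then evolves by
#' trait-dependent persistence and identity-free immigration, with
#' AR(1)-autocorrelated log-normal abundances for persisting taxa.
#'
#' @param cfg a [synthetic_config()].
#' @param site_index integer site number (also seeds the site's RNG
#'   substream together with `cfg$seed`).
#' @param traits optional fixed per-taxon trait vector of length
#'   `cfg$pool_size`; drawn from the config seed when `NULL` (as
#'   [generate_dataset()] does once for all sites).
#' @param latents optional named list with standard-normal covariate
#'   latents `v1` .. `v5`; drawn when `NULL`.
#' @return list with elements `matrix` (a [community_matrix()]),
#'   `environment` (one-row tibble of covariates in natural units) and
#'   `latents` (one-row tibble of the true covariate latents).
#' @export
generate_site <- function(cfg, site_index, traits = NULL, latents = NULL) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (is.null(traits)) {
    traits <- with_seed(site_seed(cfg$seed, "traits"),
                        stats::rnorm(cfg$pool_size, cfg$trait_mean, cfg$trait_sd))
  }
  site_name <- sprintf("site_%02d", site_index)
  with_seed(site_seed(cfg$seed, site_name), {
    if (is.null(latents)) {
      latents <- as.list(stats::setNames(stats::rnorm(5L), paste0("v", 1:5)))
    }
    g <- sample(seq(cfg$site_gamma_range[1L], cfg$site_gamma_range[2L]), 1L)
    pool_idx <- sort(sample.int(cfg$pool_size, g))
    years <- seq(2000L, length.out = cfg$n_years)
    m <- simulate_site_matrix(cfg, site_name, pool_idx, traits,
                              latents$v1, latents$v2, years)
    lat <- tibble::as_tibble(latents) |>
      dplyr::mutate(site = site_name, .before = 1L)
    noisy <- lat
    for (v in paste0("v", 1:5)) {
      noisy[[v]] <- noisy[[v]] + stats::rnorm(1L, 0, cfg$noise_sd)
    }
    list(matrix = m, environment = covariates_natural(noisy), latents = lat)
  })
}

#' Generate a full synthetic study dataset
#'
#' Draws the shared per-taxon stabilizer traits once, then simulates
#' `cfg$n_sites` sites on independent RNG substreams (so the dataset is
#' bit-identical for a given seed regardless of evaluation order).  The
#' environment table carries the five measured covariates in natural
#' units; temporal gamma diversity is added downstream from the
#' community matrices by [assemble_environment()].
#'
#' @param cfg a [synthetic_config()].
#' @return object of class `study_dataset`: list with `matrices` (named
#'   list of [community_matrix()]), `environment` (tibble), `latents`
#'   (tibble of true covariate values, for diagnostics) and `config`.
#' @export
generate_dataset <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  traits <- with_seed(site_seed(cfg$seed, "traits"),
                      stats::rnorm(cfg$pool_size, cfg$trait_mean, cfg$trait_sd))
  sites <- purrr::map(seq_len(cfg$n_sites), function(i) {
    generate_site(cfg, i, traits = traits)
  })
  matrices <- purrr::map(sites, "matrix")
  names(matrices) <- purrr::map_chr(matrices, site_id)
  structure(list(matrices = matrices,
                 environment = purrr::map_dfr(sites, "environment"),
                 latents = purrr::map_dfr(sites, "latents"),
                 config = cfg),
            class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  cs <- community_summary(x$matrices)
  cat(sprintf("<study_dataset> %d sites x %d years, regional pool %d taxa\n",
              length(x$matrices), x$config$n_years, x$config$pool_size))
  cat(sprintf("  alpha (mean per-year richness): mean %.1f, range %.1f-%.1f\n",
              mean(cs$alpha_mean), min(cs$alpha_mean), max(cs$alpha_mean)))
  cat(sprintf("  gamma (total richness): mean %.1f, range %d-%d\n",
              mean(cs$gamma), min(cs$gamma), max(cs$gamma)))
  invisible(x)
}

#' Write a synthetic dataset to the long community / environment files
#'
#' Emits the same TSV formats the readers consume
#' (`community_long.tsv`, `environment.tsv`), so the whole IO path can
#' be exercised end to end.
#'
#' @param dataset a `study_dataset` from [generate_dataset()].
#' @param out_dir output directory, created if needed.
#' @return invisibly, the two file paths.
#' @export
write_dataset <- function(dataset, out_dir) {
  stopifnot(inherits(dataset, "study_dataset"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  comm <- file.path(out_dir, "community_long.tsv")
  env <- file.path(out_dir, "environment.tsv")
  readr::write_tsv(community_to_long(dataset$matrices), comm)
  readr::write_tsv(dataset$environment, env)
  invisible(c(community = comm, environment = env))
}
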