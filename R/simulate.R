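# Stable sub-seeding: one RNG stream per generated artifact so regenerating
# one table does not shift the others. Offsets are fixed per artifact name.
.sub_seed <- function(seed, what) {
  offs <- c(pool = 101L, design = 211L, counts = 307L, environment = 401L,
            pipeline = 503L, rarefaction = 601L)
  if (!what %in% names(offs)) stop("unknown RNG stream: ", what)
  (as.integer(seed) %% 1000000L) * 1009L + offs[[what]]
}

#' Configuration of the synthetic study generator
#'
#' Bundles the design sizes, species-abundance-distribution parameters,
#' count overdispersion, and the forest-type and site-condition effect sizes
#' the generator plants in the data. Defaults emulate the field design:
#' 8 sites (4 loamy, 4 sandy) x 5 forest types, a ~26-species pool with a
#' strongly dominated lognormal abundance distribution, ~34 individuals
#' expected per beech core, a 2.2-fold abundance increase in spruce,
#' depletion of euedaphic species in Douglas fir (factor 0.4), half-strength
#' effects in the conifer-beech mixtures, and sparser, more parthenogenetic
#' communities at sandy sites.
#'
#' @param n_sites Number of sites (default 8).
#' @param n_loamy Number of loamy sites; the remainder are sandy (default 4).
#' @param forest_types Forest-type levels planted at every site.
#' @param n_species_pool Species-pool size (default 26).
#' @param sad_lognormal_mu,sad_lognormal_sigma Parameters of the lognormal
#'   species abundance distribution on the log scale.
#' @param nb_dispersion Negative-binomial size parameter for per-species
#'   counts (smaller = more overdispersed).
#' @param baseline_total_per_core Expected individuals per core in beech on
#'   a loamy site.
#' @param effect_spruce_abundance Multiplier on total expected abundance in
#'   spruce monoculture.
#' @param effect_douglas_euedaphic Multiplier (< 1) on euedaphic expected
#'   counts in Douglas fir monoculture.
#' @param mixture_attenuation Fraction of each pure-conifer effect applied
#'   in the corresponding conifer-beech mixture.
#' @param effect_sandy_richness Per-species retention probability of the
#'   species pool at sandy sites (thinning).
#' @param effect_sandy_sexual Multiplier (< 1) on sexual-species expected
#'   abundance at sandy sites.
#' @param layer_allocation Named list mapping life form to a probability
#'   vector over (litter, soil_0_5, soil_5_10).
#' @param seed Master seed; per-artifact streams are derived from it.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_sites = 8L,
                             n_loamy = 4L,
                             forest_types = colltraits::forest_types,
                             n_species_pool = 26L,
                             sad_lognormal_mu = 0,
                             sad_lognormal_sigma = 1.5,
                             nb_dispersion = 5,
                             baseline_total_per_core = 34,
                             effect_spruce_abundance = 2.2,
                             effect_douglas_euedaphic = 0.4,
                             mixture_attenuation = 0.5,
                             effect_sandy_richness = 0.7,
                             effect_sandy_sexual = 0.35,
                             layer_allocation = list(
                               epedaphic  = c(litter = 0.80, soil_0_5 = 0.15, soil_5_10 = 0.05),
                               hemiedaphic = c(litter = 0.45, soil_0_5 = 0.40, soil_5_10 = 0.15),
                               euedaphic  = c(litter = 0.10, soil_0_5 = 0.45, soil_5_10 = 0.45)),
                             seed = 1L) {
  cfg <- as.list(environment())
  if (cfg$n_loamy > cfg$n_sites) stop("n_loamy must be <= n_sites")
  if (cfg$n_species_pool < 3L) stop("species pool must have >= 3 species")
  mult <- c(cfg$effect_spruce_abundance, cfg$effect_douglas_euedaphic,
            cfg$mixture_attenuation, cfg$effect_sandy_richness,
            cfg$effect_sandy_sexual, cfg$nb_dispersion,
            cfg$baseline_total_per_core)
  if (any(mult <= 0)) stop("all effect multipliers and rates must be > 0")
  for (lf in names(cfg$layer_allocation)) {
    p <- cfg$layer_allocation[[lf]]
    if (abs(sum(p) - 1) > 1e-8 || any(p < 0))
      stop("layer_allocation for ", lf, " is not a probability vector")
  }
  class(cfg) <- "generator_config"
  cfg
}

# probabilities coupling traits to life form; euedaphic species are blind,
# unpigmented, short-furca, short-antenna; epedaphic the opposite extreme
.lf_probs <- c(epedaphic = 1 / 3, hemiedaphic = 1 / 3, euedaphic = 1 / 3)

#' Generate a species pool with coupled traits
#'
#' Draws `n_species_pool` species with life forms in roughly equal shares
#' and trait values coupled to life form: euedaphic (true soil-living)
#' species are unpigmented with no ocelli and reduced furca and antennae;
#' epedaphic (surface-living) species are at the opposite extreme. About 80%
#' of species are Arthropleona. Trophic guild and reproductive mode are
#' correlated with life form but overlap deliberately.
#'
#' @param config A [generator_config()].
#' @param seed Optional override of the config's master seed.
#' @return A validated trait table (see [validate_trait_table()]).
#' @export
generate_species_pool <- function(config = generator_config(), seed = config$seed) {
  n <- config$n_species_pool
  if (n < 3L) stop("species pool must have >= 3 species (FD undefined below)")
  withr::with_seed(.sub_seed(seed, "pool"), {
    lf <- sample(names(.lf_probs), n, replace = TRUE, prob = .lf_probs)
    guild_p <- list(epedaphic  = c(D = 0.60, I = 0.25, II = 0.15),
                    hemiedaphic = c(D = 0.30, I = 0.50, II = 0.20),
                    euedaphic  = c(D = 0.15, I = 0.60, II = 0.25))
    partheno_p <- c(epedaphic = 0.2, hemiedaphic = 0.4, euedaphic = 0.7)
    guild <- vapply(lf, function(l)
      sample(names(guild_p[[l]]), 1L, prob = guild_p[[l]]), character(1))
    repro <- ifelse(stats::runif(n) < partheno_p[lf], "parthenogenetic", "sexual")
    pig <- ifelse(lf == "euedaphic", 0,
                  ifelse(lf == "hemiedaphic", stats::runif(n, 0.2, 0.7),
                         stats::runif(n, 0.6, 1.0)))
    oce <- ifelse(lf == "euedaphic", 0L,
                  ifelse(lf == "hemiedaphic",
                         sample(2:6, n, replace = TRUE),
                         sample(6:8, n, replace = TRUE)))
    furca <- ifelse(lf == "euedaphic", stats::runif(n, 0.0, 0.3),
                    ifelse(lf == "hemiedaphic", stats::runif(n, 0.3, 0.8),
                           stats::runif(n, 0.7, 1.5)))
    ant <- ifelse(lf == "euedaphic", stats::runif(n, 0.10, 0.30),
                  ifelse(lf == "hemiedaphic", stats::runif(n, 0.25, 0.50),
                         stats::runif(n, 0.40, 0.80)))
    len <- pmin(pmax(stats::rlnorm(n, log(1.2), 0.6), 0.2), 5)
    grp <- ifelse(stats::runif(n) < 0.8, "arthropleona", "symphypleona")
    data.frame(species_id = sprintf("sp%02d", seq_len(n)),
               body_length_mm = len, allometry_group = grp, life_form = lf,
               trophic_guild = guild, reproduction = repro,
               pigmentation = pig, n_ocelli = as.integer(oce),
               furca_size = furca, antenna_body_ratio = ant,
               stringsAsFactors = FALSE, row.names = NULL)
  }) |> validate_trait_table()
}

#' Generate the plot design
#'
#' `n_sites` sites each containing every forest type once. The first
#' `n_loamy` sites are loamy at lower (southern) latitudes, the remainder
#' sandy at higher latitudes; mean annual temperature is drawn near
#' 281-283 K, slightly cooler in the north.
#'
#' @inheritParams generate_species_pool
#' @return A validated plot-design table.
#' @export
generate_design <- function(config = generator_config(), seed = config$seed) {
  withr::with_seed(.sub_seed(seed, "design"), {
    ns <- config$n_sites
    loamy <- seq_len(config$n_loamy)
    lat_site <- ifelse(seq_len(ns) %in% loamy,
                       stats::runif(ns, 51.66, 51.77),
                       stats::runif(ns, 52.62, 53.20))
    mat_site <- 282.4 - 0.35 * (lat_site - 51.7) + stats::rnorm(ns, 0, 0.25)
    d <- expand.grid(site_id = seq_len(ns),
                     forest_type = config$forest_types,
                     stringsAsFactors = FALSE)
    d <- d[order(d$site_id, match(d$forest_type, config$forest_types)), ]
    d$plot_id <- sprintf("s%02d_%s", d$site_id, d$forest_type)
    d$site_condition <- ifelse(d$site_id %in% loamy, "loamy", "sandy")
    d$latitude <- lat_site[d$site_id]
    d$mat <- mat_site[d$site_id]
    rownames(d) <- NULL
    d[, .schema$plot_design]
  }) |> validate_plot_design()
}

# expected per-species counts for one plot, before NB noise
.expected_counts <- function(plot, rel_abund, pool, config, site_keep) {
  ft <- plot$forest_type
  lam <- config$baseline_total_per_core * rel_abund
  att <- config$mixture_attenuation
  tot_mult <- switch(ft,
                     spruce = config$effect_spruce_abundance,
                     spruce_beech = 1 + (config$effect_spruce_abundance - 1) * att,
                     1)
  eu_mult <- switch(ft,
                    douglas = config$effect_douglas_euedaphic,
                    douglas_beech = 1 - (1 - config$effect_douglas_euedaphic) * att,
                    1)
  lam <- lam * tot_mult
  lam[pool$life_form == "euedaphic"] <- lam[pool$life_form == "euedaphic"] * eu_mult
  if (plot$site_condition == "sandy") {
    lam[pool$reproduction == "sexual"] <-
      lam[pool$reproduction == "sexual"] * config$effect_sandy_sexual
    lam <- lam * site_keep
  }
  lam
}

#' Generate layered counts for a design and species pool
#'
#' Per plot, species expected counts follow the lognormal species abundance
#' distribution scaled by the configured forest-type and site-condition
#' effects; realised counts are negative-binomial (overdispersed), and each
#' species' individuals are allocated multinomially to the three layers
#' according to its life form.
#'
#' @param design Plot design table.
#' @param pool Species trait table.
#' @inheritParams generate_species_pool
#' @return A validated layered-counts table (only positive counts stored).
#' @export
generate_layered_counts <- function(design, pool, config = generator_config(),
                                    seed = config$seed) {
  design <- validate_plot_design(design)
  pool <- validate_trait_table(pool)
  withr::with_seed(.sub_seed(seed, "counts"), {
    n_sp <- nrow(pool)
    rel <- stats::rlnorm(n_sp, config$sad_lognormal_mu, config$sad_lognormal_sigma)
    rel <- rel / sum(rel)
    # site-level pool thinning at sandy sites
    keep <- lapply(seq_len(config$n_sites), function(s)
      as.numeric(stats::runif(n_sp) < config$effect_sandy_richness))
    rows <- vector("list", nrow(design) * n_sp)
    k <- 0L
    for (i in seq_len(nrow(design))) {
      plot <- design[i, ]
      lam <- .expected_counts(plot, rel, pool, config, keep[[plot$site_id]])
      cnt <- stats::rnbinom(n_sp, size = config$nb_dispersion, mu = lam)
      for (j in which(cnt > 0L)) {
        p <- config$layer_allocation[[pool$life_form[j]]]
        lay <- stats::rmultinom(1L, cnt[j], p)[, 1L]
        pos <- which(lay > 0L)
        k <- k + 1L
        rows[[k]] <- data.frame(plot_id = plot$plot_id,
                                layer = soil_layers[pos],
                                species_id = pool$species_id[j],
                                count = as.integer(lay[pos]),
                                stringsAsFactors = FALSE)
      }
    }
    out <- if (k > 0L) do.call(rbind, rows[seq_len(k)]) else
      data.frame(plot_id = character(), layer = character(),
                 species_id = character(), count = integer())
    .sort_rows(out)
  }) |> validate_layered_counts()
}

#' Generate a plot environment table
#'
#' Site-condition-specific means plus noise: litter sodium and microbial
#' biomass are elevated at loamy sites, root carbon increases with latitude,
#' and the remaining litter and microbial variables differ moderately
#' between loamy and sandy sites.
#'
#' @param design Plot design table.
#' @param seed Integer seed.
#' @return A validated environment table.
#' @export
generate_environment <- function(design, seed = 1L) {
  design <- validate_plot_design(design)
  withr::with_seed(.sub_seed(seed, "environment"), {
    n <- nrow(design)
    loam <- design$site_condition == "loamy"
    rn <- function(mu_loamy, mu_sandy, sd)
      ifelse(loam, mu_loamy, mu_sandy) + stats::rnorm(n, 0, sd)
    data.frame(
      plot_id = design$plot_id,
      root_C = 430 + 12 * (design$latitude - 51.7) + stats::rnorm(n, 0, 8),
      root_N = rn(11, 9, 1.2),
      litter_mass = rn(520, 610, 60),
      litter_N = rn(14, 12, 1.5),
      litter_P = rn(0.9, 0.7, 0.12),
      litter_K = rn(2.4, 1.8, 0.35),
      litter_Ca = rn(8.5, 5.5, 1.1),
      litter_Na = rn(0.22, 0.11, 0.03),
      litter_pH = rn(4.6, 3.9, 0.25),
      microbial_biomass = rn(16, 10, 2.2),
      pct_fungi = rn(28, 34, 4),
      pct_bacteria = rn(52, 46, 4),
      latitude = design$latitude,
      stringsAsFactors = FALSE)
  }) |> validate_environment_table()
}

#' Simulate a complete study data set
#'
#' Convenience wrapper producing the four tables (trait pool, design,
#' layered counts, environment) from one configuration and master seed.
#'
#' @inheritParams generate_species_pool
#' @return List with elements `pool`, `design`, `counts`, `environment`,
#'   `config`, `seed`.
#' @export
simulate_study <- function(config = generator_config(), seed = config$seed) {
  pool <- generate_species_pool(config, seed)
  design <- generate_design(config, seed)
  counts <- generate_layered_counts(design, pool, config, seed)
  env <- generate_environment(design, seed)
  list(pool = pool, design = design, counts = counts, environment = env,
       config = config, seed = seed)
}
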