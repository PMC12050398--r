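#' Pipeline configuration
#'
#' Either paths to the four input tables or a [generator_config()] to
#' simulate them; plus the knobs shared by the stages. Can also be read
#' from a YAML file with [read_pipeline_config()].
#'
#' @param inputs Named list of paths (`counts`, `traits`, `design`,
#'   `environment`) or `NULL` to simulate.
#' @param simulate A [generator_config()] (ignored when `inputs` given).
#' @param core_diameter_m Corer diameter in metres.
#' @param layer_coding Layer surface-affinity coding.
#' @param pca_transform Species-matrix transformation before PCA.
#' @param n_perm Permutations for PERMANOVA / envfit / betadisper.
#' @param n_boot Bootstrap resamples for rarefaction bands.
#' @param seed Master seed.
#' @param outdir Output directory.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(inputs = NULL,
                            simulate = generator_config(),
                            core_diameter_m = 0.05,
                            layer_coding = default_layer_coding,
                            pca_transform = "hellinger",
                            n_perm = 999L,
                            n_boot = 200L,
                            seed = 1L,
                            outdir = tempfile("colltraits_run_")) {
  if (!is.null(inputs)) {
    need <- c("counts", "traits", "design", "environment")
    miss <- setdiff(need, names(inputs))
    if (length(miss) > 0L)
      stop("inputs must name paths for: ", paste(miss, collapse = ", "))
    simulate <- NULL
  }
  cfg <- list(inputs = inputs, simulate = simulate,
              core_diameter_m = core_diameter_m, layer_coding = layer_coding,
              pca_transform = pca_transform, n_perm = as.integer(n_perm),
              n_boot = as.integer(n_boot), seed = as.integer(seed),
              outdir = outdir)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the [pipeline_config()]
#'   arguments (generator settings under `simulate:`).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- setdiff(names(formals(pipeline_config)), c("simulate", "layer_coding"))
  bad <- setdiff(names(y), c(known, "simulate", "layer_coding"))
  if (length(bad) > 0L)
    stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  args <- y[intersect(names(y), known)]
  if (!is.null(y$simulate))
    args$simulate <- do.call(generator_config, y$simulate)
  if (!is.null(y$layer_coding))
    args$layer_coding <- unlist(y$layer_coding)
  do.call(pipeline_config, args)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

.write_tsv <- function(x, dir, name) {
  p <- file.path(dir, paste0(name, ".tsv"))
  utils::write.table(as.data.frame(x), p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  p
}

#' Run the full analysis pipeline
#'
#' Executes, in order: data acquisition (load or simulate), layer pooling
#' and density conversion, plot energetics, trait standardization / CWM /
#' composition metrics, functional diversity and rarefaction, ordination
#' with environmental vectors, PERMANOVA and dispersion tests, and the
#' mixed-model contrasts for the headline responses. Every intermediate
#' table is written to `config$outdir` as TSV and listed, with an MD5
#' content hash, in the returned JSON manifest.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the manifest list (also written to
#'   `manifest.json` in the output directory).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  add <- function(x, name) files[[name]] <<- .write_tsv(x, config$outdir, name)

  dat <- .stage("inputs", {
    if (!is.null(config$inputs)) {
      for (nm in names(config$inputs))
        if (!file.exists(config$inputs[[nm]]))
          stop("missing input file for '", nm, "': ", config$inputs[[nm]])
      list(pool = read_trait_table(config$inputs$traits),
           design = read_plot_design(config$inputs$design),
           counts = read_layered_counts(config$inputs$counts),
           environment = read_environment_table(config$inputs$environment))
    } else {
      simulate_study(config$simulate, seed = config$seed)
    }
  })
  add(dat$counts, "layered_counts"); add(dat$pool, "trait_table")
  add(dat$design, "plot_design"); add(dat$environment, "environment")

  comm <- .stage("densities", {
    pooled <- pool_layers(dat$counts, plots = dat$design$plot_id,
                          species = dat$pool$species_id)
    counts_to_density(pooled, config$core_diameter_m)
  })
  add(data.frame(plot_id = rownames(comm), comm, check.names = FALSE), "community_density")

  energ <- .stage("energetics", plot_energetics(comm, dat$pool, dat$design))
  add(energ, "energetics")

  tr <- .stage("traits", {
    vs <- vertical_scores(dat$counts, config$layer_coding)
    std <- suppressWarnings(build_trait_matrix(dat$pool, vs))
    # species never captured anywhere have no vertical score and an all-zero
    # column; they cannot contribute to any CWM
    cw <- cwm(comm[, colnames(comm) %in% rownames(std), drop = FALSE], std)
    list(vscores = vs, std = std, cwm = cw,
         guilds = composition_proportions(comm, dat$pool, "trophic_guild"),
         life_forms = composition_proportions(comm, dat$pool, "life_form"),
         repro = composition_proportions(comm, dat$pool, "reproduction"))
  })
  add(data.frame(species_id = names(tr$vscores), vertical_score = tr$vscores),
      "vertical_scores")
  add(data.frame(species_id = rownames(tr$std), tr$std, check.names = FALSE),
      "standardized_traits")
  add(data.frame(plot_id = rownames(tr$cwm), tr$cwm, check.names = FALSE), "cwm")
  add(data.frame(plot_id = rownames(tr$guilds), tr$guilds, check.names = FALSE),
      "guild_proportions")
  add(data.frame(plot_id = rownames(tr$life_forms), tr$life_forms,
                 check.names = FALSE), "life_form_proportions")

  div <- .stage("diversity", {
    space <- functional_space(gower_distance(tr$std))
    present <- intersect(colnames(comm), rownames(space$points))
    feve <- apply(comm[, present, drop = FALSE], 1L, function(r)
      functional_evenness(space, r))
    fdiv <- apply(comm[, present, drop = FALSE], 1L, function(r)
      functional_divergence(space, r))
    pooled_counts <- pool_layers(dat$counts, plots = dat$design$plot_id,
                                 species = dat$pool$species_id)
    gamma_curves <- lapply(split(seq_len(nrow(pooled_counts)),
                                 dat$design$forest_type[
                                   match(rownames(pooled_counts),
                                         dat$design$plot_id)]),
                           function(rows) rarefy_extrapolate(
                             colSums(pooled_counts[rows, , drop = FALSE]),
                             n_boot = config$n_boot, seed = config$seed))
    list(metrics = data.frame(plot_id = rownames(comm),
                              richness = richness_per_plot(comm),
                              feve = as.numeric(feve), fdiv = as.numeric(fdiv),
                              row.names = NULL),
         turnover = turnover_vs_reference(comm, dat$design),
         gamma = gamma_curves)
  })
  add(div$metrics, "diversity_metrics")
  add(div$turnover, "turnover_vs_beech")
  add(do.call(rbind, lapply(names(div$gamma), function(ft)
    cbind(forest_type = ft, div$gamma[[ft]]))), "rarefaction_gamma")

  ord <- .stage("ordination", {
    sp_f <- filter_rare_species(comm)
    sp_pca <- pca_ordination(transform_community(sp_f, config$pca_transform))
    cwm_pca <- pca_ordination(tr$cwm, scale = FALSE)
    env_f <- collinearity_filter(dat$environment, r_max = 0.8)
    list(species = sp_pca, traits = cwm_pca,
         env_species = fit_env_vectors(sp_pca, env_f, config$n_perm, config$seed),
         env_traits = fit_env_vectors(cwm_pca, env_f, config$n_perm, config$seed))
  })
  add(data.frame(plot_id = rownames(ord$species$scores),
                 ord$species$scores[, 1:2]), "pca_species_scores")
  add(data.frame(plot_id = rownames(ord$traits$scores),
                 ord$traits$scores[, 1:2]), "pca_traits_scores")
  add(ord$env_species, "envfit_species"); add(ord$env_traits, "envfit_traits")

  perma <- .stage("permanova", {
    des <- dat$design[match(rownames(comm), dat$design$plot_id), ]
    sp_f <- filter_rare_species(comm)
    d_sp <- bray_curtis(sp_f[rowSums(sp_f) > 0, , drop = FALSE])
    des_sp <- des[rowSums(sp_f) > 0, , drop = FALSE]
    d_tr <- bray_curtis(tr$cwm)
    des_tr <- des[match(rownames(tr$cwm), des$plot_id), ]
    list(species = permanova(d_sp, des_sp, n_perm = config$n_perm,
                             seed = config$seed),
         traits = permanova(d_tr, des_tr, n_perm = config$n_perm,
                            seed = config$seed),
         betadisper = dispersion_homogeneity(d_sp, des_sp$forest_type,
                                             config$n_perm, config$seed))
  })
  add(as.data.frame(perma$species), "permanova_species")
  add(as.data.frame(perma$traits), "permanova_traits")
  add(data.frame(F = perma$betadisper$F, p = perma$betadisper$p), "betadisper")

  models <- .stage("models", {
    dd <- merge(merge(dat$design, energ, by = "plot_id"),
                div$metrics, by = "plot_id")
    specs <- list(abundance = c("abundance_ind_m2", "log1p"),
                  biomass = c("biomass_mg_m2", "log1p"),
                  metabolism = c("metabolism_J_m2_h", "log1p"),
                  richness = c("richness", "sqrt"),
                  feve = c("feve", "none"),
                  fdiv = c("fdiv", "none"))
    out <- lapply(names(specs), function(nm) {
      s <- specs[[nm]]
      keep <- !is.na(dd[[s[1]]])
      fit <- fit_lmm(dd[keep, ], s[1], transform = s[2])
      mc <- marginal_means_and_contrasts(fit)
      cols <- c("contrast", "estimate", "SE", "df", "lower.CL", "upper.CL",
                "t.ratio", "p.value")
      cbind(response = nm, transform = s[2],
            mc$contrasts[, intersect(cols, names(mc$contrasts))])
    })
    do.call(rbind, out)
  })
  add(models, "lmm_contrasts")

  manifest <- list(
    package = "colltraits",
    version = as.character(utils::packageVersion("colltraits")),
    seed = config$seed,
    n_plots = nrow(dat$design),
    n_layer_samples = nrow(dat$design) * length(soil_layers),
    n_species = nrow(dat$pool),
    outputs = lapply(files, function(p)
      list(path = basename(p), md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
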