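#' Allometric length-mass coefficients
#'
#' Coefficients of the power equations converting Collembola body length
#' (mm) to dry mass (ug): `DW = a * L^b` for Arthropleona and
#' `DW = a * (0.83 * L)^b` for Symphypleona, and `FM = c * DW^d` converting
#' dry to fresh mass (ug).
#'
#' @return Named list with `a`, `b` per allometry group, the Symphypleona
#'   length factor, and the fresh-mass coefficients `c`, `d`.
#' @export
allometry_coefficients <- function() {
  list(arthropleona = c(a = 5.6, b = 2.693),
       symphypleona = c(a = 57.8, b = 2.954),
       symphypleona_length_factor = 0.83,
       fresh = c(c = 4.08, d = 1.02))
}

#' Metabolic-rate constants
#'
#' Constants of the mass- and temperature-dependent individual metabolic
#' rate `I = i0 * M^alpha * exp(-E / (k * T))` with `I` in J/h, `M` fresh
#' mass in mg and `T` in Kelvin: normalization `i0`, allometric exponent
#' `alpha`, activation energy `E` (eV) and the Boltzmann constant `k`
#' (eV/K).
#'
#' @return Named list of the four constants.
#' @export
metabolic_constants <- function() {
  list(i0 = 3477995118, alpha = 0.759, E = 0.657, k = 8.62e-5)
}

#' Dry mass from body length
#'
#' @param length_mm Body length(s) in millimetres, > 0.
#' @param group Allometry group per length: `"arthropleona"` or
#'   `"symphypleona"` (recycled if length 1).
#' @return Dry mass in micrograms.
#' @export
dry_mass_ug <- function(length_mm, group) {
  if (any(!is.finite(length_mm)) || any(length_mm <= 0))
    stop("body length must be positive and finite", call. = FALSE)
  group <- rep_len(as.character(group), length(length_mm))
  bad <- setdiff(unique(group), c("arthropleona", "symphypleona"))
  if (length(bad) > 0L)
    stop("unknown allometry group: ", paste(bad, collapse = ", "), call. = FALSE)
  co <- allometry_coefficients()
  L <- ifelse(group == "symphypleona",
              co$symphypleona_length_factor * length_mm, length_mm)
  a <- ifelse(group == "symphypleona", co$symphypleona["a"], co$arthropleona["a"])
  b <- ifelse(group == "symphypleona", co$symphypleona["b"], co$arthropleona["b"])
  unname(a * L^b)
}

#' Fresh mass from dry mass
#'
#' @param dw_ug Dry mass in micrograms, >= 0.
#' @return Fresh mass in micrograms, `FM = 4.08 * DW^1.02` (0 maps to 0).
#' @export
fresh_mass_ug <- function(dw_ug) {
  if (any(!is.finite(dw_ug)) || any(dw_ug < 0))
    stop("dry mass must be non-negative and finite", call. = FALSE)
  co <- allometry_coefficients()$fresh
  unname(co["c"] * dw_ug^co["d"])
}

#' Individual metabolic rate
#'
#' Mass- and temperature-dependent metabolic rate
#' `I = i0 * M^alpha * exp(-E / (k * T))` in joules per hour. Note the unit
#' contract: `M` is fresh mass in milligrams (fresh mass computed in
#' micrograms must be divided by 1000 first).
#'
#' @param fresh_mass_mg Fresh mass in milligrams, > 0.
#' @param temperature_K Temperature in Kelvin, > 0.
#' @return Metabolic rate in J/h.
#' @export
metabolic_rate_J_per_h <- function(fresh_mass_mg, temperature_K) {
  if (any(!is.finite(fresh_mass_mg)) || any(fresh_mass_mg <= 0))
    stop("fresh mass (mg) must be positive", call. = FALSE)
  if (any(!is.finite(temperature_K)) || any(temperature_K <= 0))
    stop("temperature (K) must be positive", call. = FALSE)
  mc <- metabolic_constants()
  mc$i0 * fresh_mass_mg^mc$alpha * exp(-mc$E / (mc$k * temperature_K))
}

#' Plot-level biomass and community metabolism
#'
#' For each plot, fresh biomass (mg per m^2) is the density-weighted sum of
#' per-individual fresh mass, and community metabolism (J per m^2 per hour)
#' is the sum of individual metabolic rates at the plot's mean annual
#' temperature. Each species' individuals share the species-level adult
#' body length from the trait table.
#'
#' @param community Plot-by-species density matrix (individuals per m^2).
#' @param traits Trait table covering every species in the matrix.
#' @param design Plot design table supplying `mat` (Kelvin) per plot.
#' @return Data frame with `plot_id`, `abundance_ind_m2`,
#'   `biomass_mg_m2`, `metabolism_J_m2_h`.
#' @export
plot_energetics <- function(community, traits, design) {
  traits <- validate_trait_table(traits)
  design <- validate_plot_design(design)
  sp <- colnames(community)
  miss <- setdiff(sp, traits$species_id)
  if (length(miss) > 0L)
    stop("species missing from trait table: ", paste(miss, collapse = ", "),
         call. = FALSE)
  miss <- setdiff(rownames(community), design$plot_id)
  if (length(miss) > 0L)
    stop("plots missing from design: ", paste(miss, collapse = ", "),
         call. = FALSE)
  tr <- traits[match(sp, traits$species_id), ]
  fm_mg <- fresh_mass_ug(dry_mass_ug(tr$body_length_mm, tr$allometry_group)) / 1000
  mat <- design$mat[match(rownames(community), design$plot_id)]
  biomass <- as.vector(community %*% fm_mg)
  # per-individual rate depends on plot temperature, species mass
  rate <- outer(mat, fm_mg, function(TT, M) metabolic_rate_J_per_h(M, TT))
  metab <- rowSums(community * rate)
  data.frame(plot_id = rownames(community),
             abundance_ind_m2 = rowSums(community),
             biomass_mg_m2 = biomass,
             metabolism_J_m2_h = unname(metab),
             stringsAsFactors = FALSE, row.names = NULL)
}
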