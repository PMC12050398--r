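#' Default surface-affinity coding of the core layers
#'
#' Numeric values assigned to the three layers when computing species
#' vertical-distribution scores: higher = closer to the surface, so that
#' larger scores mean more surface-living.
#'
#' @format Named numeric vector over the three layers.
#' @export
default_layer_coding <- c(litter = 1, soil_0_5 = 0.5, soil_5_10 = 0)

#' Standardize a trait table to the [0, 1] trait matrix
#'
#' Numeric traits are min-max scaled to `[0, 1]` (a constant column maps to
#' all zeros rather than being dropped, so column sets stay stable across
#' data sets); each categorical trait is expanded to 0/1 indicator columns
#' named `trait.level` whose rowwise sum is 1.
#'
#' @param traits Data frame with a `species_id` column plus trait columns.
#' @param numeric Names of numeric trait columns to scale.
#' @param categorical Names of categorical trait columns to expand.
#' @return Numeric matrix (species x trait columns) with attribute
#'   `blocks`: a named list mapping each source trait to its output
#'   column(s), used for Gower weighting and provenance.
#' @export
standardize_traits <- function(traits,
                               numeric = c("body_length_mm", "pigmentation",
                                           "n_ocelli", "furca_size",
                                           "antenna_body_ratio"),
                               categorical = c("reproduction", "trophic_guild")) {
  stopifnot(nrow(traits) >= 1L, "species_id" %in% names(traits))
  numeric <- intersect(numeric, names(traits))
  categorical <- intersect(categorical, names(traits))
  if (length(numeric) + length(categorical) == 0L)
    stop("no trait columns to standardize", call. = FALSE)
  cols <- list(); blocks <- list()
  for (v in numeric) {
    x <- as.numeric(traits[[v]])
    if (any(is.na(x))) stop("missing values in numeric trait ", v, call. = FALSE)
    r <- range(x)
    cols[[v]] <- if (r[2] > r[1]) (x - r[1]) / (r[2] - r[1]) else rep(0, length(x))
    blocks[[v]] <- v
  }
  for (v in categorical) {
    f <- factor(as.character(traits[[v]]))
    if (any(is.na(f))) stop("missing values in categorical trait ", v, call. = FALSE)
    ind <- stats::model.matrix(~ f - 1)
    nm <- paste(v, levels(f), sep = ".")
    for (j in seq_along(nm)) cols[[nm[j]]] <- ind[, j]
    blocks[[v]] <- nm
  }
  m <- do.call(cbind, cols)
  rownames(m) <- as.character(traits$species_id)
  attr(m, "blocks") <- blocks
  m
}

#' Community-weighted mean trait profile
#'
#' `CWM_t = sum_i p_i * x_it` per plot and trait column, with `p_i` the
#' relative abundance of species `i` in the plot. Plots with zero total
#' abundance are excluded from the result and flagged in the `excluded`
#' attribute.
#'
#' @param community Plot-by-species abundance or density matrix.
#' @param std Standardized trait matrix from [standardize_traits()] (rows
#'   must cover the community's species).
#' @return Plot-by-trait-column matrix of community-weighted means, with
#'   attributes `excluded` (zero-total plot ids) and `blocks`.
#' @export
cwm <- function(community, std) {
  sp <- colnames(community)
  miss <- setdiff(sp, rownames(std))
  if (length(miss) > 0L)
    stop("species missing from trait matrix: ", paste(miss, collapse = ", "),
         call. = FALSE)
  x <- std[sp, , drop = FALSE]
  tot <- rowSums(community)
  excluded <- rownames(community)[tot == 0]
  keep <- tot > 0
  p <- community[keep, , drop = FALSE] / tot[keep]
  out <- p %*% x
  attr(out, "excluded") <- excluded
  attr(out, "blocks") <- attr(std, "blocks")
  out
}

#' Species vertical-distribution (surface affinity) scores
#'
#' Abundance-weighted mean of the numeric layer coding, aggregated over all
#' plots before weighting: `score(sp) = sum_l coding(l) * n(sp, l) / n(sp)`.
#' With the default coding higher values mean more surface-living. Species
#' with zero total count are absent from the result.
#'
#' @param counts Layered-counts table.
#' @param layer_coding Named numeric vector assigning one value per layer.
#' @return Named numeric vector of scores, attribute `coding` records the
#'   layer values used.
#' @export
vertical_scores <- function(counts, layer_coding = default_layer_coding) {
  counts <- validate_layered_counts(as.data.frame(counts))
  if (!all(soil_layers %in% names(layer_coding)))
    stop("layer_coding must assign a value to every layer", call. = FALSE)
  n_sl <- tapply(counts$count, list(counts$species_id, as.character(counts$layer)),
                 sum, default = 0)
  n_sl <- n_sl[rowSums(n_sl) > 0, soil_layers[soil_layers %in% colnames(n_sl)],
               drop = FALSE]
  w <- layer_coding[colnames(n_sl)]
  s <- as.vector(n_sl %*% w) / rowSums(n_sl)
  names(s) <- rownames(n_sl)
  attr(s, "coding") <- layer_coding
  s
}

#' Abundance-weighted composition proportions
#'
#' Per-plot proportions of individuals in each category of a species-level
#' grouping trait (trophic guild, life form, or reproductive mode);
#' proportions sum to 1 per plot. Zero-total plots are excluded and
#' flagged.
#'
#' @param community Plot-by-species abundance or density matrix.
#' @param traits Trait table.
#' @param by One of `"trophic_guild"`, `"life_form"`, `"reproduction"`.
#' @return Plot-by-category matrix of proportions, attribute `excluded`.
#' @export
composition_proportions <- function(community, traits,
                                    by = c("trophic_guild", "life_form",
                                           "reproduction")) {
  by <- match.arg(by)
  traits <- validate_trait_table(traits)
  sp <- colnames(community)
  miss <- setdiff(sp, traits$species_id)
  if (length(miss) > 0L)
    stop("species without a ", by, " category: ", paste(miss, collapse = ", "),
         call. = FALSE)
  g <- factor(traits[[by]][match(sp, traits$species_id)])
  agg <- t(apply(community, 1L, function(r) tapply(r, g, sum, default = 0)))
  colnames(agg) <- levels(g)
  tot <- rowSums(agg)
  excluded <- rownames(agg)[tot == 0]
  out <- agg[tot > 0, , drop = FALSE] / tot[tot > 0]
  attr(out, "excluded") <- excluded
  out
}

#' Assemble the standardized trait matrix used for CWM and trait space
#'
#' Merges the study-measured vertical-distribution score into the trait
#' table and standardizes the full trait set: body length, pigmentation,
#' number of ocelli, furcal size, antenna/body ratio, vertical score
#' (numeric, min-max scaled) plus reproduction and trophic guild
#' (indicators). Species without a vertical score (never captured) are
#' dropped with a warning.
#'
#' @param traits Trait table.
#' @param vscores Named vector from [vertical_scores()].
#' @return Standardized trait matrix (see [standardize_traits()]).
#' @export
build_trait_matrix <- function(traits, vscores) {
  traits <- validate_trait_table(traits)
  keep <- traits$species_id %in% names(vscores)
  if (!all(keep)) {
    warning("dropping species never captured (no vertical score): ",
            paste(traits$species_id[!keep], collapse = ", "))
    traits <- traits[keep, , drop = FALSE]
  }
  traits$vertical_score <- as.numeric(vscores[traits$species_id])
  standardize_traits(traits,
                     numeric = c("body_length_mm", "pigmentation", "n_ocelli",
                                 "furca_size", "antenna_body_ratio",
                                 "vertical_score"),
                     categorical = c("reproduction", "trophic_guild"))
}
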