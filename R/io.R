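#' @keywords internal
"_PACKAGE"

#' Soil layers of a split core
#'
#' The fixed three-level vocabulary for the depth layers into which each
#' soil core is separated: litter, 0-5 cm mineral soil, and 5-10 cm
#' mineral soil.
#'
#' @format Character vector of length 3.
#' @export
soil_layers <- c("litter", "soil_0_5", "soil_5_10")

#' Forest-type levels of the study design
#'
#' European beech is the reference level; the conifer monocultures and the
#' two conifer-beech mixtures follow.
#'
#' @format Character vector of length 5.
#' @export
forest_types <- c("beech", "douglas", "spruce", "douglas_beech", "spruce_beech")

# required columns per table type
.schema <- list(
  layered_counts    = c("plot_id", "layer", "species_id", "count"),
  trait_table       = c("species_id", "body_length_mm", "allometry_group",
                        "life_form", "trophic_guild", "reproduction",
                        "pigmentation", "n_ocelli", "furca_size",
                        "antenna_body_ratio"),
  plot_design       = c("plot_id", "site_id", "site_condition", "forest_type",
                        "latitude", "mat"),
  environment_table = c("plot_id", "root_C", "root_N", "litter_mass",
                        "litter_N", "litter_P", "litter_K", "litter_Ca",
                        "litter_Na", "litter_pH", "microbial_biomass",
                        "pct_fungi", "pct_bacteria", "latitude")
)

.read_delim_auto <- function(path) {
  stopifnot(file.exists(path))
  sep <- if (grepl("\\.tsv$|\\.tab$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE, fileEncoding = "UTF-8")
}

.write_delim_auto <- function(x, path) {
  sep <- if (grepl("\\.tsv$|\\.tab$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(x, path, sep = sep, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

.check_columns <- function(x, what) {
  need <- .schema[[what]]
  miss <- setdiff(need, names(x))
  if (length(miss) > 0L)
    stop(sprintf("%s: missing required column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  x[, c(need, setdiff(names(x), need)), drop = FALSE]
}

#' Validate a layered-counts table
#'
#' Checks the schema of a long-format table of per-core individual counts:
#' one row per (plot, layer, species) with a non-negative integer count and
#' layers drawn from [soil_layers].
#'
#' @param x Data frame with columns `plot_id`, `layer`, `species_id`, `count`.
#' @return The validated data frame (invisibly classed `layered_counts`).
#' @export
validate_layered_counts <- function(x) {
  x <- .check_columns(x, "layered_counts")
  bad <- setdiff(unique(as.character(x$layer)), soil_layers)
  if (length(bad) > 0L)
    stop("unknown layer label(s): ", paste(bad, collapse = ", "),
         " (expected ", paste(soil_layers, collapse = ", "), ")", call. = FALSE)
  if (any(is.na(x$count)) || any(x$count < 0))
    stop("counts must be non-negative and non-missing", call. = FALSE)
  if (any(x$count != round(x$count)))
    stop("counts must be whole numbers of individuals", call. = FALSE)
  key <- paste(x$plot_id, x$layer, x$species_id, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicated (plot, layer, species) rows", call. = FALSE)
  x$layer <- factor(as.character(x$layer), levels = soil_layers)
  class(x) <- c("layered_counts", "data.frame")
  x
}

#' Validate a species trait table
#'
#' One row per species, with body length in mm, allometry group
#' (arthropleona/symphypleona), life form, trophic guild (D, I, II),
#' reproductive mode, and the morphological traits.
#'
#' @param x Data frame following the trait-table schema.
#' @return The validated data frame.
#' @export
validate_trait_table <- function(x) {
  x <- .check_columns(x, "trait_table")
  if (anyDuplicated(x$species_id)) stop("duplicated species_id", call. = FALSE)
  if (any(x$body_length_mm <= 0)) stop("body_length_mm must be > 0", call. = FALSE)
  chk <- function(col, lv) {
    bad <- setdiff(unique(as.character(x[[col]])), lv)
    if (length(bad) > 0L)
      stop(sprintf("%s: unknown level(s) %s", col, paste(bad, collapse = ", ")),
           call. = FALSE)
  }
  chk("allometry_group", c("arthropleona", "symphypleona"))
  chk("life_form", c("epedaphic", "hemiedaphic", "euedaphic"))
  chk("trophic_guild", c("D", "I", "II"))
  chk("reproduction", c("sexual", "parthenogenetic"))
  x
}

#' Validate a plot design table
#'
#' @param x Data frame with plot, site, site condition, forest type, latitude
#'   and mean annual temperature (Kelvin).
#' @return The validated data frame.
#' @export
validate_plot_design <- function(x) {
  x <- .check_columns(x, "plot_design")
  if (anyDuplicated(x$plot_id)) stop("duplicated plot_id", call. = FALSE)
  bad <- setdiff(unique(as.character(x$forest_type)), forest_types)
  if (length(bad) > 0L)
    stop("unknown forest_type level(s): ", paste(bad, collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(as.character(x$site_condition)), c("loamy", "sandy"))
  if (length(bad) > 0L)
    stop("unknown site_condition level(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (any(x$mat <= 250))
    stop("mat must be in Kelvin (> 250 K); got values <= 250", call. = FALSE)
  key <- paste(x$site_id, x$forest_type)
  if (anyDuplicated(key))
    stop("a site contains the same forest type more than once", call. = FALSE)
  x
}

#' Validate a plot environment table
#' @param x Data frame following the environment-table schema.
#' @return The validated data frame.
#' @export
validate_environment_table <- function(x) {
  x <- .check_columns(x, "environment_table")
  if (anyDuplicated(x$plot_id)) stop("duplicated plot_id", call. = FALSE)
  x
}

.sort_rows <- function(x) {
  ord_cols <- intersect(c("plot_id", "layer", "species_id"), names(x))
  if (length(ord_cols) > 0L)
    x <- x[do.call(order, lapply(ord_cols, function(cc) as.character(x[[cc]]))), ,
           drop = FALSE]
  rownames(x) <- NULL
  x
}

#' Read / write the tabular interchange formats
#'
#' Delimited-text readers and writers for the four table types. The
#' separator is auto-detected from the extension (`.tsv`/`.tab`/`.txt` are
#' tab-separated, everything else comma-separated); files are UTF-8 with a
#' single header row. Writers emit a deterministic column order and rows
#' sorted by (plot, layer, species).
#'
#' @param path File path.
#' @param x Table to write.
#' @return Readers return the validated data frame; writers return the path
#'   invisibly.
#' @export
read_layered_counts <- function(path) validate_layered_counts(.read_delim_auto(path))

#' @rdname read_layered_counts
#' @export
write_layered_counts <- function(x, path) {
  x <- validate_layered_counts(as.data.frame(x))
  x$layer <- as.character(x$layer)
  .write_delim_auto(.sort_rows(x), path)
}

#' @rdname read_layered_counts
#' @export
read_trait_table <- function(path) validate_trait_table(.read_delim_auto(path))

#' @rdname read_layered_counts
#' @export
write_trait_table <- function(x, path) {
  .write_delim_auto(.sort_rows(validate_trait_table(x)), path)
}

#' @rdname read_layered_counts
#' @export
read_plot_design <- function(path) validate_plot_design(.read_delim_auto(path))

#' @rdname read_layered_counts
#' @export
write_plot_design <- function(x, path) {
  .write_delim_auto(.sort_rows(validate_plot_design(x)), path)
}

#' @rdname read_layered_counts
#' @export
read_environment_table <- function(path) validate_environment_table(.read_delim_auto(path))

#' @rdname read_layered_counts
#' @export
write_environment_table <- function(x, path) {
  .write_delim_auto(.sort_rows(validate_environment_table(x)), path)
}

#' Pool layered counts into a plot-by-species matrix
#'
#' Sums counts over the three core layers to give one row per plot. Plot
#' and species universes default to those present in the data; passing the
#' design's plot ids and the trait table's species ids keeps plots with a
#' core but zero animals as all-zero rows.
#'
#' @param counts A layered-counts table.
#' @param plots Optional character vector of plot ids to include (all-zero
#'   rows are kept for plots without captures).
#' @param species Optional character vector of species ids for the columns.
#' @return Numeric matrix (plots x species) of raw pooled counts, with
#'   attribute `units = "count"`.
#' @export
pool_layers <- function(counts, plots = NULL, species = NULL) {
  counts <- validate_layered_counts(as.data.frame(counts))
  if (is.null(plots)) plots <- sort(unique(as.character(counts$plot_id)))
  if (is.null(species)) species <- sort(unique(as.character(counts$species_id)))
  m <- matrix(0, nrow = length(plots), ncol = length(species),
              dimnames = list(plots, species))
  if (nrow(counts) > 0L) {
    keep <- counts$plot_id %in% plots & counts$species_id %in% species
    cc <- counts[keep, , drop = FALSE]
    if (nrow(cc) > 0L) {
      idx <- cbind(match(as.character(cc$plot_id), plots),
                   match(as.character(cc$species_id), species))
      for (i in seq_len(nrow(cc))) m[idx[i, 1L], idx[i, 2L]] <-
          m[idx[i, 1L], idx[i, 2L]] + cc$count[i]
    }
  }
  attr(m, "units") <- "count"
  m
}

#' Convert pooled core counts to areal densities
#'
#' Divides counts by the area of the circular soil corer,
#' `pi * (d / 2)^2`. For the study's 5-cm corer one individual per core is
#' ~509.3 individuals per square metre.
#'
#' @param pooled Plot-by-species matrix of raw counts (from [pool_layers()]).
#' @param core_diameter_m Corer diameter in metres (default 0.05).
#' @return Matrix of densities in individuals per m^2, `units = "ind_m2"`.
#' @export
counts_to_density <- function(pooled, core_diameter_m = 0.05) {
  if (!is.numeric(core_diameter_m) || length(core_diameter_m) != 1L ||
      core_diameter_m <= 0)
    stop("core_diameter_m must be a single positive number", call. = FALSE)
  if (identical(attr(pooled, "units"), "ind_m2"))
    stop("input already holds densities", call. = FALSE)
  out <- pooled / (pi * (core_diameter_m / 2)^2)
  attr(out, "units") <- "ind_m2"
  out
}
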