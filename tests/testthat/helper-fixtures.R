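# Small in-code fixtures shared across test files.

`%||%` <- function(a, b) if (is.null(a)) b else a

# four-species trait table with hand-set values covering both allometry
# groups, all life forms and guilds
toy_traits <- function() {
  data.frame(
    species_id = c("spA", "spB", "spC", "spD"),
    body_length_mm = c(1.0, 2.0, 0.5, 1.5),
    allometry_group = c("arthropleona", "arthropleona", "symphypleona",
                        "arthropleona"),
    life_form = c("epedaphic", "hemiedaphic", "euedaphic", "hemiedaphic"),
    trophic_guild = c("D", "I", "II", "I"),
    reproduction = c("sexual", "parthenogenetic", "parthenogenetic", "sexual"),
    pigmentation = c(1.0, 0.5, 0.0, 0.4),
    n_ocelli = c(8L, 4L, 0L, 6L),
    furca_size = c(1.2, 0.6, 0.1, 0.8),
    antenna_body_ratio = c(0.6, 0.35, 0.15, 0.4),
    stringsAsFactors = FALSE)
}

toy_design <- function() {
  data.frame(plot_id = c("p1", "p2", "p3", "p4"),
             site_id = c(1L, 1L, 2L, 2L),
             site_condition = c("loamy", "loamy", "sandy", "sandy"),
             forest_type = c("beech", "spruce", "beech", "douglas"),
             latitude = c(51.7, 51.7, 52.9, 52.9),
             mat = c(282, 282, 281.5, 281.5),
             stringsAsFactors = FALSE)
}

toy_counts <- function() {
  data.frame(
    plot_id = c("p1", "p1", "p1", "p2", "p2", "p3", "p4", "p4"),
    layer = c("litter", "soil_0_5", "litter", "litter", "soil_5_10",
              "soil_0_5", "litter", "soil_5_10"),
    species_id = c("spA", "spA", "spB", "spB", "spC", "spC", "spD", "spD"),
    count = c(2L, 1L, 4L, 3L, 2L, 5L, 1L, 1L),
    stringsAsFactors = FALSE)
}

# random plot-by-species abundance matrix (integer counts, some zeros)
random_community <- function(n_plots, n_species, seed, max_count = 20L) {
  withr::with_seed(seed, {
    m <- matrix(rpois(n_plots * n_species, lambda = 3) *
                  rbinom(n_plots * n_species, 1, 0.7),
                n_plots, n_species,
                dimnames = list(sprintf("plot%02d", seq_len(n_plots)),
                                sprintf("sp%02d", seq_len(n_species))))
    # ensure no all-zero rows
    for (i in which(rowSums(m) == 0)) m[i, sample.int(n_species, 1L)] <- 1L
    m
  })
}

# random standardized-style trait matrix with a block attribute
random_points <- function(n, k, seed) {
  withr::with_seed(seed, {
    p <- matrix(runif(n * k), n, k,
                dimnames = list(sprintf("sp%02d", seq_len(n)), NULL))
    p
  })
}
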