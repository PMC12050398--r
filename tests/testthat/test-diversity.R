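test_that("Gower distance matches hand-computed mixed-trait values", {
  tr <- data.frame(species_id = c("a", "b", "c"),
                   v = c(0, 0.5, 1) * 10 + 2,   # min-max scales to 0, 0.5, 1
                   g = c("x", "y", "x"))
  std <- standardize_traits(tr, numeric = "v", categorical = "g")
  d <- as.matrix(gower_distance(std))
  expect_equal(d["a", "b"], (0.5 + 1) / 2)
  expect_equal(d["a", "c"], (1.0 + 0) / 2)
  expect_equal(d["b", "c"], (0.5 + 1) / 2)
  expect_equal(diag(d), c(a = 0, b = 0, c = 0))
  # identical rows at distance 0; maximal difference in every trait at 1
  tr2 <- data.frame(species_id = c("a", "b"), v = c(0, 1), g = c("x", "y"))
  d2 <- as.matrix(gower_distance(standardize_traits(tr2, "v", "g")))
  expect_equal(d2["a", "b"], 1)
})

test_that("Gower distance agrees with cluster::daisy on numeric traits", {
  skip_if_not_installed("cluster")
  tr <- data.frame(species_id = sprintf("s%d", 1:6),
                   a = runif(6), b = runif(6), c = runif(6))
  std <- standardize_traits(tr, numeric = c("a", "b", "c"), categorical = NULL)
  ours <- as.matrix(gower_distance(std))
  ref <- as.matrix(cluster::daisy(as.data.frame(std[, c("a", "b", "c")]),
                                  metric = "gower"))
  expect_equal(unname(ours), unname(ref), tolerance = 1e-10)
})

test_that("principal-coordinates embedding reconstructs Euclidean input", {
  pts <- random_points(7, 3, seed = 4)
  sp <- functional_space(stats::dist(pts))
  expect_equal(as.matrix(stats::dist(sp$points)), as.matrix(stats::dist(pts)),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(sp$eig > 0))
  # three equidistant species form an equilateral triangle
  d3 <- stats::as.dist(matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3,
                              dimnames = list(letters[1:3], letters[1:3])))
  tri <- functional_space(d3)
  expect_equal(unname(as.matrix(stats::dist(tri$points))[upper.tri(diag(3))]),
               rep(1, 3), tolerance = 1e-8)
  # duplicated species map to coincident points
  d4 <- stats::dist(pts[c(1, 1, 2, 3), ])
  sp4 <- functional_space(d4)
  expect_equal(unname(sp4$points[1, ]), unname(sp4$points[2, ]),
               tolerance = 1e-8)
})

# exhaustive spanning-tree oracle: FEve recomputed from the minimum spanning
# tree found by enumerating all 16 labelled spanning trees of K4
feve_bruteforce_4 <- function(pts, ab) {
  stopifnot(nrow(pts) == 4L)
  D <- as.matrix(stats::dist(pts))
  edges <- t(combn(4, 2))
  best <- NULL; best_w <- Inf
  for (idx in combn(6, 3, simplify = FALSE)) {
    e <- edges[idx, , drop = FALSE]
    # connected iff all 4 nodes reachable from node 1
    reach <- 1L
    repeat {
      nxt <- unique(c(e[e[, 1] %in% reach, 2], e[e[, 2] %in% reach, 1]))
      new <- union(reach, nxt)
      if (length(new) == length(reach)) break
      reach <- new
    }
    if (length(reach) < 4L) next
    w <- sum(D[e])
    if (w < best_w) { best_w <- w; best <- e }
  }
  wrel <- ab / sum(ab)
  ew <- D[best] / (wrel[best[, 1]] + wrel[best[, 2]])
  pew <- ew / sum(ew)
  ref <- 1 / 3
  (sum(pmin(pew, ref)) - ref) / (1 - ref)
}

test_that("functional evenness matches brute-force MST oracle on toys", {
  for (s in 1:10) {
    pts <- random_points(4, 2, seed = 200 + s)
    ab <- withr::with_seed(300 + s, runif(4, 0.5, 5))
    names(ab) <- rownames(pts)
    expect_equal(functional_evenness(pts, ab), feve_bruteforce_4(pts, ab),
                 tolerance = 1e-10)
  }
})

test_that("functional evenness is 1 for even line configurations", {
  pts <- matrix(0:4, 5, 1, dimnames = list(paste0("s", 1:5), NULL))
  ab <- setNames(rep(2, 5), rownames(pts))
  expect_equal(functional_evenness(pts, ab), 1, tolerance = 1e-10)
})

test_that("functional evenness is undefined below 3 species", {
  pts <- random_points(4, 2, seed = 1)
  ab <- setNames(c(1, 2, 0, 0), rownames(pts))
  out <- functional_evenness(pts, ab)
  expect_true(is.na(out))
  expect_match(attr(out, "reason"), "3 species")
})

test_that("convex-hull vertex detection agrees with chull and geometry facts", {
  # planar configurations embedded in 3-D exercise the Frank-Wolfe path
  for (s in 1:8) {
    pts2 <- random_points(10, 2, seed = 400 + s)
    v2 <- hull_vertices(pts2)
    pts3 <- cbind(pts2, 0.31 * pts2[, 1] - 0.17 * pts2[, 2])  # affine plane in 3-D
    expect_equal(hull_vertices(pts3), v2)
  }
  # the centroid of a point cloud is never a vertex; axis extremes always are
  pts <- random_points(12, 4, seed = 77)
  pts <- rbind(pts, centroid = colMeans(pts))
  v <- hull_vertices(pts)
  expect_false(13L %in% v)
  for (j in 1:4) {
    expect_true(which.max(pts[, j]) %in% v)
    expect_true(which.min(pts[, j]) %in% v)
  }
})

test_that("functional divergence matches a step-by-step geometry oracle", {
  # square with all species on the hull, equidistant from the centre
  sq <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1), 4, 2, byrow = TRUE,
               dimnames = list(paste0("s", 1:4), NULL))
  ab <- setNames(c(1, 1, 1, 5), rownames(sq))
  expect_equal(functional_divergence(sq, ab), 1, tolerance = 1e-10)
  # triangle plus interior point: independent arithmetic oracle
  pts <- matrix(c(0, 0, 2, 0, 0, 2, 0.5, 0.5), 4, 2, byrow = TRUE,
                dimnames = list(paste0("s", 1:4), NULL))
  ab <- setNames(c(1, 2, 3, 4), rownames(pts))
  G <- colMeans(pts[1:3, ])                       # hull vertices are the triangle
  di <- sqrt(rowSums(sweep(pts, 2, G)^2))
  w <- ab / sum(ab); dbar <- mean(di)
  oracle <- (sum(w * (di - dbar)) + dbar) / (sum(w * abs(di - dbar)) + dbar)
  expect_equal(functional_divergence(pts, ab), oracle, tolerance = 1e-10)
  # abundance concentrated on the most distant species pushes FDiv above 0.5
  far <- matrix(c(0, 0, 0.1, 0, 0, 0.1, 3, 3), 4, 2, byrow = TRUE,
                dimnames = list(paste0("s", 1:4), NULL))
  ab2 <- setNames(c(1, 1, 1, 50), rownames(far))
  expect_gt(functional_divergence(far, ab2), 0.5)
})

test_that("FEve and FDiv stay within [0, 1] over many random communities", {
  pool <- generate_species_pool(generator_config(n_species_pool = 15L), seed = 6L)
  space <- functional_space(gower_distance(standardize_traits(pool)))
  n_bad <- 0L
  for (s in 1:1000) {
    ab <- withr::with_seed(1000 + s, {
      k <- sample(3:15, 1L)
      sp <- sample(pool$species_id, k)
      setNames(rexp(k) + 0.01, sp)
    })
    fe <- functional_evenness(space, ab)
    fd <- functional_divergence(space, ab)
    if (!is.na(fe) && (fe < -1e-10 || fe > 1 + 1e-10)) n_bad <- n_bad + 1L
    if (!is.na(fd) && (fd < -1e-10 || fd > 1 + 1e-10)) n_bad <- n_bad + 1L
  }
  expect_equal(n_bad, 0L)
})

test_that("richness and turnover are simple exact counts", {
  comm <- matrix(c(5, 0, 1, 0, 0, 0), 2, 3, byrow = TRUE,
                 dimnames = list(c("p1", "p2"), c("A", "B", "C")))
  expect_equal(unname(richness_per_plot(comm)), c(2L, 0L))
  expect_equal(richness_per_plot(comm * 509.296), richness_per_plot(comm))

  comm <- matrix(c(2, 1, 0, 0,   # beech plot: pool {A, B}
                   0, 3, 2, 1),  # other plot: {B, C, D}
                 2, 4, byrow = TRUE,
                 dimnames = list(c("p1", "p2"), c("A", "B", "C", "D")))
  des <- data.frame(plot_id = c("p1", "p2"), site_id = 1:2,
                    site_condition = "loamy",
                    forest_type = c("beech", "douglas"),
                    latitude = 51.7, mat = 282)
  out <- turnover_vs_reference(comm, des)
  expect_equal(out$new_species[out$plot_id == "p1"], 0L)
  expect_equal(out$shared_with_reference[out$plot_id == "p2"], 1L)
  expect_equal(out$new_species[out$plot_id == "p2"], 2L)
  expect_error(turnover_vs_reference(comm, des, reference_type = "spruce"),
               "no plots")
})

test_that("rarefaction matches hypergeometric arithmetic and endpoints", {
  out <- rarefy_extrapolate(c(2, 2), m_grid = c(1, 2, 4), n_boot = 10)
  expect_equal(out$S_est[out$m == 1], 1)
  expect_equal(out$S_est[out$m == 2], 5 / 3)   # 2 - 2*C(2,2)/C(4,2)
  expect_equal(out$S_est[out$m == 4], 2)       # S(N) = S_obs
  ab <- c(10, 5, 3, 1, 1)
  out <- rarefy_extrapolate(ab, m_grid = c(1, sum(ab)), n_boot = 10)
  expect_equal(out$S_est, c(1, 5))
  expect_error(rarefy_extrapolate(c(0, 0)), "no individuals")
})

test_that("rarefaction interpolation agrees with vegan::rarefy", {
  ab <- c(12, 7, 5, 2, 1, 1, 1)
  m <- c(2, 5, 10, 20)
  out <- rarefy_extrapolate(ab, m_grid = m, n_boot = 10)
  expect_equal(out$S_est, as.numeric(vegan::rarefy(ab, m)), tolerance = 1e-10)
})

test_that("exact rarefaction matches Monte-Carlo subsampling within 3 SE", {
  ab <- c(9, 6, 3, 2, 1)
  m <- 8
  exact <- rarefy_extrapolate(ab, m_grid = m, n_boot = 10)$S_est
  draws <- withr::with_seed(99L, {
    ids <- rep(seq_along(ab), ab)
    replicate(10000, length(unique(sample(ids, m))))
  })
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(exact - mean(draws)), 3 * se)
})

test_that("rarefaction curves are monotone, concave, Chao1-bounded", {
  for (s in 1:20) {
    ab <- withr::with_seed(500 + s, rpois(12, 4) + rbinom(12, 1, 0.3))
    ab <- ab[ab > 0]
    if (sum(ab) < 2 || length(ab) < 2) next
    out <- rarefy_extrapolate(ab, m_grid = seq_len(2 * sum(ab)), n_boot = 5,
                              seed = s)
    expect_true(all(diff(out$S_est) > -1e-10))
    expect_true(all(diff(diff(out$S_est[out$type == "rarefied"])) < 1e-8))
    expect_gte(chao1(ab), sum(ab > 0))
    expect_gte(attr(out, "chao1") + 1e-10, max(out$S_est) - 1e-8)
    # extrapolation asymptote is Chao1
    far <- rarefy_extrapolate(ab, m_grid = sum(ab) * 2000, n_boot = 5)
    expect_equal(far$S_est, attr(far, "chao1"), tolerance = 1e-4)
  }
})
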