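test_that("Bray-Curtis matches hand values and rejects empty samples", {
  x <- rbind(a = c(2, 1), b = c(1, 2), c = c(2, 1))
  d <- as.matrix(bray_curtis(x))
  expect_equal(d["a", "b"], 1 / 3)    # (1 + 1) / 6
  expect_equal(d["a", "c"], 0)
  disjoint <- rbind(a = c(3, 0), b = c(0, 5))
  expect_equal(as.matrix(bray_curtis(disjoint))["a", "b"], 1)
  bad <- rbind(a = c(1, 1), empty = c(0, 0))
  expect_error(bray_curtis(bad), "empty")
})

test_that("rare-species filter drops single-plot occupants", {
  m <- matrix(0, 5, 5, dimnames = list(paste0("p", 1:5), paste0("s", 1:5)))
  m[1, 1] <- 3                      # occupancy 1 -> dropped
  m[2, 2] <- 1                      # occupancy 1 -> dropped
  m[1:2, 3] <- 1                    # occupancy 2 -> kept
  m[1:3, 4] <- 2                    # occupancy 3 -> kept
  m[, 5] <- 1                       # occupancy 5 -> kept
  out <- filter_rare_species(m)
  expect_equal(colnames(out), c("s3", "s4", "s5"))
  expect_setequal(attr(out, "dropped"), c("s1", "s2"))
})

test_that("PCA reconstructs, explains, and has a stable sign convention", {
  # two variables on a line: one axis carries all variance
  x <- cbind(a = 1:6, b = 2 * (1:6) + 3)
  ord <- pca_ordination(x)
  expect_equal(ord$explained[1], 1, tolerance = 1e-12)
  # reconstruction from all axes returns the centered data
  y <- matrix(rnorm(60), 10, 6)
  colnames(y) <- paste0("v", 1:6)
  ord <- pca_ordination(y)
  rec <- ord$scores %*% t(ord$loadings)
  expect_equal(rec, scale(y, scale = FALSE), tolerance = 1e-8,
               ignore_attr = TRUE)
  # per-axis largest-magnitude loading is positive, deterministically
  expect_true(all(apply(ord$loadings, 2, function(v) v[which.max(abs(v))] > 0)))
  expect_equal(pca_ordination(y)$scores, ord$scores)
  expect_error(pca_ordination(matrix(1, 4, 3)), "constant")
})

test_that("collinearity filter applies the greedy worst-pair rule", {
  set.seed(31)
  base <- rnorm(30)
  env <- data.frame(plot_id = sprintf("p%02d", 1:30),
                    a = base, b = base,                 # r = 1 pair
                    c = rnorm(30))
  out <- collinearity_filter(env)
  expect_length(attr(out, "dropped"), 1L)
  expect_true(attr(out, "dropped") %in% c("a", "b"))
  # all below the threshold: unchanged
  env2 <- data.frame(a = rnorm(30), b = rnorm(30), c = rnorm(30))
  expect_length(attr(collinearity_filter(env2), "dropped"), 0L)
  # three variables, one r ~ 0.9 pair: the pair member more correlated with
  # the rest is removed, two survive
  u <- rnorm(200)
  env3 <- data.frame(x = u, y = u + rnorm(200, 0, 0.3), z = rnorm(200))
  out3 <- collinearity_filter(env3)
  expect_equal(sum(c("x", "y", "z") %in% names(out3)), 2L)
})

test_that("environmental vectors recover an axis-aligned variable", {
  sim <- simulate_study(generator_config(seed = 21L))
  comm <- counts_to_density(pool_layers(sim$counts, sim$design$plot_id,
                                        sim$pool$species_id))
  ord <- pca_ordination(transform_community(filter_rare_species(comm)))
  env <- data.frame(plot_id = rownames(ord$scores),
                    onaxis = ord$scores[, 1],
                    noise = withr::with_seed(5, rnorm(nrow(ord$scores))),
                    flat = 1)
  out <- fit_env_vectors(ord, env, n_perm = 199, seed = 3)
  expect_equal(out$r2[out$variable == "onaxis"], 1, tolerance = 1e-8)
  expect_equal(abs(out$axis1[out$variable == "onaxis"]), 1, tolerance = 1e-6)
  expect_lt(out$p[out$variable == "onaxis"], 0.05)
  expect_equal(attr(out, "skipped"), "flat")
})

test_that("PERMANOVA agrees with vegan::adonis2 on SS, df and pseudo-F", {
  sim <- simulate_study(generator_config(seed = 13L))
  comm <- counts_to_density(pool_layers(sim$counts, sim$design$plot_id,
                                        sim$pool$species_id))
  comm <- filter_rare_species(comm)
  keep <- rowSums(comm) > 0
  d <- bray_curtis(comm[keep, ])
  des <- sim$design[match(rownames(comm)[keep], sim$design$plot_id), ]
  ours <- permanova(d, des, ~ forest_type * site_condition, n_perm = 99,
                    seed = 1)
  ref <- vegan::adonis2(d ~ forest_type * site_condition, data = des,
                        permutations = 99, by = "terms")
  expect_equal(ours$SS[1:4], ref$SumOfSqs[1:4], tolerance = 1e-8)
  expect_equal(ours$df[1:4], ref$Df[1:4])
  expect_equal(ours$pseudo_F[1:3], ref$F[1:3], tolerance = 1e-8)
  # the study design yields residual df 30 and site-condition df 1
  expect_equal(ours$df[ours$term == "residual"], 30L)
  expect_equal(ours$df[ours$term == "site_condition"], 1L)
})

test_that("PERMANOVA sequential SS decomposition sums to the total", {
  for (s in 1:5) {
    comm <- random_community(12, 8, seed = 600 + s)
    des <- data.frame(forest_type = rep(c("beech", "spruce", "douglas"), 4),
                      site_condition = rep(c("loamy", "sandy"), each = 6))
    out <- permanova(bray_curtis(comm), des, ~ forest_type * site_condition,
                     n_perm = 19, seed = s)
    expect_equal(sum(out$SS[out$term != "total"]),
                 out$SS[out$term == "total"], tolerance = 1e-8)
    expect_true(all(out$p[1:3] > 0))
  }
})

test_that("PERMANOVA exact p on a 6-sample toy by full enumeration", {
  # two groups of internally identical samples at maximal dissimilarity:
  # p must equal the share of the 720 label permutations whose pseudo-F
  # is at least as extreme, computed here from the group-assignment count
  comm <- rbind(matrix(rep(c(5, 0), each = 3), 3, 2),
                matrix(rep(c(0, 7), each = 3), 3, 2))
  rownames(comm) <- paste0("p", 1:6); colnames(comm) <- c("sA", "sB")
  des <- data.frame(forest_type = rep(c("beech", "spruce"), each = 3))
  perms <- as.matrix(expand.grid(rep(list(1:6), 6)))
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == 6L), ]
  expect_equal(nrow(perms), 720L)
  out <- permanova(bray_curtis(comm), des, ~ forest_type,
                   permutations = perms)
  # 3!*3!*2 = 72 permutations reproduce the two-block split exactly; only
  # those attain the maximal pseudo-F
  expect_equal(out$p[1], (1 + 72) / (1 + 720))
})

test_that("PERMANOVA is invariant to consistent sample reordering", {
  comm <- random_community(12, 6, seed = 71)
  des <- data.frame(forest_type = rep(c("beech", "spruce", "douglas"), 4))
  d <- bray_curtis(comm)
  out1 <- permanova(d, des, ~ forest_type, n_perm = 49, seed = 2)
  ord <- sample(12)
  d2 <- stats::as.dist(as.matrix(d)[ord, ord])
  out2 <- permanova(d2, des[ord, , drop = FALSE], ~ forest_type,
                    n_perm = 49, seed = 2)
  expect_equal(out1$pseudo_F[1], out2$pseudo_F[1], tolerance = 1e-10)
  expect_equal(out1$SS, out2$SS, tolerance = 1e-10)
})

test_that("PERMANOVA type-I error is nominal under the null", {
  # 500 null data sets, alpha = 0.05: rejection rate within the binomial CI
  n_rej <- 0L
  for (s in 1:500) {
    comm <- random_community(12, 6, seed = 3000 + s)
    des <- data.frame(forest_type = rep(c("beech", "spruce", "douglas"), 4))
    out <- permanova(bray_curtis(comm), des, ~ forest_type, n_perm = 199,
                     seed = s)
    if (out$p[1] <= 0.05) n_rej <- n_rej + 1L
  }
  ci <- 0.05 + c(-1, 1) * 1.96 * sqrt(0.05 * 0.95 / 500)
  expect_gte(n_rej / 500, ci[1])
  expect_lte(n_rej / 500, ci[2])
})

test_that("dispersion homogeneity flags unequal spread and not equal spread", {
  withr::with_seed(8L, {
    tight <- matrix(rep(c(5, 5, 5, 0, 0), each = 8), 8, 5) +
      matrix(rnorm(40, 0, 0.01), 8, 5)
    spread <- matrix(rep(c(5, 5, 5, 0, 0), each = 8), 8, 5) +
      matrix(rnorm(40, 0, 2), 8, 5)
  })
  x <- abs(rbind(tight, spread))
  rownames(x) <- paste0("p", 1:16)
  out <- dispersion_homogeneity(bray_curtis(x),
                                rep(c("a", "b"), each = 8),
                                n_perm = 999, seed = 4)
  expect_lt(out$p, 0.05)
  expect_true(all(out$distances >= 0))
  # size-1 groups are excluded with a warning
  expect_warning(
    dispersion_homogeneity(bray_curtis(x), c(rep(c("a", "b"), each = 7),
                                             "c", "d"),
                           n_perm = 99, seed = 1),
    "size 1")
})
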