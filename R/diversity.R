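#' Gower distance between species in mixed trait space
#'
#' Distance in `[0, 1]` over a standardized trait matrix, with equal weight
#' per source trait: numeric traits (already scaled to `[0, 1]`) contribute
#' their absolute difference; a categorical trait contributes 1 on mismatch,
#' its indicator columns sharing the trait's weight.
#'
#' @param std Standardized trait matrix from [standardize_traits()].
#' @return `dist` object over species.
#' @export
gower_distance <- function(std) {
  if (nrow(std) < 2L) stop("need >= 2 species", call. = FALSE)
  blocks <- attr(std, "blocks")
  if (is.null(blocks)) stop("no trait block mapping on input", call. = FALSE)
  n <- nrow(std)
  acc <- matrix(0, n, n)
  for (b in blocks) {
    x <- std[, b, drop = FALSE]
    # L1 distance over an indicator block is 2 on mismatch, halve it;
    # a single numeric column is its plain absolute difference
    d <- as.matrix(stats::dist(x, method = "manhattan"))
    if (length(b) > 1L) d <- d / 2
    acc <- acc + d
  }
  acc <- acc / length(blocks)
  dimnames(acc) <- list(rownames(std), rownames(std))
  stats::as.dist(acc)
}

#' Principal-coordinates trait space
#'
#' Embeds species into a low-dimensional Euclidean space from the Gower
#' distance matrix via classical multidimensional scaling (eigendecomposition
#' of the double-centered squared-distance matrix); axes with non-positive
#' eigenvalues are dropped.
#'
#' @param d `dist` object (e.g. from [gower_distance()]).
#' @param eig_tol Relative tolerance below which an eigenvalue counts as 0.
#' @return List of class `functional_space`: `points` (species x axes),
#'   `eig` (retained eigenvalues), `n_axes`.
#' @export
functional_space <- function(d, eig_tol = 1e-8) {
  n <- attr(d, "Size")
  # negative eigenvalues are expected for non-Euclidean (e.g. Gower)
  # distances; those axes are dropped below, so silence cmdscale's warning
  fit <- suppressWarnings(stats::cmdscale(d, k = max(1L, n - 1L), eig = TRUE))
  eig <- fit$eig
  keep <- which(eig > eig_tol * max(abs(eig)))
  pts <- fit$points[, keep, drop = FALSE]
  rownames(pts) <- attr(d, "Labels")
  structure(list(points = pts, eig = eig[keep], n_axes = length(keep)),
            class = "functional_space")
}

.space_points <- function(space) {
  if (inherits(space, "functional_space")) space$points else as.matrix(space)
}

# minimum spanning tree edges of a point configuration, via vegan
.mst_edges <- function(pts) {
  d <- stats::dist(pts)
  tr <- vegan::spantree(d)
  cbind(from = 2:nrow(pts), to = tr$kid, w = tr$dist)
}

#' Functional evenness (FEve)
#'
#' Regularity of the abundance distribution along the minimum spanning tree
#' of the community's species in trait space. Branch weights
#' `EW_l = dist(i, j) / (w_i + w_j)` (relative abundances `w`) are
#' normalized to `PEW_l` and compared with the even reference `1/(S-1)`:
#' `FEve = (sum_l min(PEW_l, 1/(S-1)) - 1/(S-1)) / (1 - 1/(S-1))`.
#' Undefined (NA with a reason attribute) for fewer than 3 species with
#' positive abundance.
#'
#' @param space `functional_space` (global trait space) or a point matrix.
#' @param abundances Named abundance vector; names match space rows.
#' @return FEve in `[0, 1]`, or `NA` with attribute `reason`.
#' @export
functional_evenness <- function(space, abundances) {
  pts <- .space_points(space)
  ab <- abundances[abundances > 0]
  if (length(ab) < 3L)
    return(structure(NA_real_, reason = "fewer than 3 species present"))
  if (!all(names(ab) %in% rownames(pts)))
    stop("abundance names not all present in trait space", call. = FALSE)
  p <- pts[names(ab), , drop = FALSE]
  w <- ab / sum(ab)
  S <- length(ab)
  ed <- .mst_edges(p)
  ew <- ed[, "w"] / (w[ed[, "from"]] + w[ed[, "to"]])
  if (sum(ew) == 0)
    return(structure(NA_real_, reason = "all species coincident in trait space"))
  pew <- ew / sum(ew)
  ref <- 1 / (S - 1)
  unname((sum(pmin(pew, ref)) - ref) / (1 - ref))
}

# convex-hull membership test: is the squared distance from x to the hull
# of the columns of A above thr2? Away-step Frank-Wolfe (linear convergence)
# with duality-gap certificates: f < thr2 proves membership, f - gap > thr2
# proves x is outside (gap bounds f - f*).
.is_hull_vertex_point <- function(A, x, thr2, max_iter = 5000L) {
  m <- ncol(A)
  lam <- rep(1 / m, m)
  r <- as.vector(A %*% lam) - x
  f <- sum(r^2)
  for (it in seq_len(max_iter)) {
    if (f < thr2) return(FALSE)
    g <- as.vector(2 * crossprod(A, r))
    s <- which.min(g)
    gap_fw <- sum(g * lam) - g[s]
    if (f - gap_fw > thr2) return(TRUE)
    if (gap_fw < 1e-16) break
    act <- which(lam > 0)
    v <- act[which.max(g[act])]
    gap_aw <- g[v] - sum(g * lam)
    if (gap_fw >= gap_aw) {            # Frank-Wolfe step toward vertex s
      d_vec <- A[, s] - as.vector(A %*% lam)
      gmax <- 1
    } else {                           # away step from active vertex v
      d_vec <- as.vector(A %*% lam) - A[, v]
      gmax <- lam[v] / (1 - lam[v] + 1e-300)
    }
    denom <- sum(d_vec^2)
    if (denom <= 0) break
    step <- min(max(-sum(r * d_vec) / denom, 0), gmax)
    if (step <= 0) break
    if (gap_fw >= gap_aw) {
      lam <- (1 - step) * lam
      lam[s] <- lam[s] + step
    } else {
      lam <- (1 + step) * lam
      lam[v] <- lam[v] - step
      lam[lam < 0] <- 0
    }
    r <- as.vector(A %*% lam) - x
    f <- sum(r^2)
  }
  f > thr2
}

#' Convex-hull vertex species of a point configuration
#'
#' In one dimension the extremes, in two `grDevices::chull()`, in higher
#' dimensions each point is tested for membership in the convex hull of the
#' others (Frank-Wolfe projection); points whose distance to that hull
#' exceeds a small tolerance are vertices.
#'
#' @param pts Numeric matrix (points x axes).
#' @param tol Distance tolerance for the membership test.
#' @return Integer indices of the vertex points.
#' @export
hull_vertices <- function(pts, tol = 1e-6) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  if (n <= ncol(pts) + 1L) return(seq_len(n))
  if (ncol(pts) == 1L)
    return(unique(c(which.min(pts[, 1]), which.max(pts[, 1]))))
  if (ncol(pts) == 2L) return(sort(grDevices::chull(pts)))
  scale <- max(stats::dist(pts))
  if (scale == 0) return(seq_len(n))
  sort(which(vapply(seq_len(n), function(i)
    .is_hull_vertex_point(t(pts[-i, , drop = FALSE]), pts[i, ],
                          (tol * scale)^2),
    logical(1))))
}

#' Functional divergence (FDiv)
#'
#' Abundance-weighted divergence of species from the gravity center `G` of
#' the convex-hull vertex species in trait space. With `d_i` the distance
#' of species `i` to `G`, `dbar` their unweighted mean,
#' `Dd = sum_i w_i (d_i - dbar)` and `D|d| = sum_i w_i |d_i - dbar|`:
#' `FDiv = (Dd + dbar) / (D|d| + dbar)`. For more than `max_axes` retained
#' axes the hull (and distances) use the first `max_axes` principal axes.
#'
#' @param space `functional_space` or point matrix.
#' @param abundances Named abundance vector.
#' @param max_axes Axis cap for the convex-hull computation (default 8).
#' @return FDiv in `[0, 1]`, or `NA` with attribute `reason`.
#' @export
functional_divergence <- function(space, abundances, max_axes = 8L) {
  pts <- .space_points(space)
  ab <- abundances[abundances > 0]
  if (length(ab) < 3L)
    return(structure(NA_real_, reason = "fewer than 3 species present"))
  if (!all(names(ab) %in% rownames(pts)))
    stop("abundance names not all present in trait space", call. = FALSE)
  p <- pts[names(ab), seq_len(min(ncol(pts), max_axes)), drop = FALSE]
  if (max(stats::dist(p)) == 0)
    return(structure(NA_real_, reason = "all species coincident in trait space"))
  w <- ab / sum(ab)
  v <- hull_vertices(p)
  G <- colMeans(p[v, , drop = FALSE])
  di <- sqrt(rowSums(sweep(p, 2L, G)^2))
  dbar <- mean(di)
  Dd <- sum(w * (di - dbar))
  Dabs <- sum(w * abs(di - dbar))
  unname((Dd + dbar) / (Dabs + dbar))
}

#' Species richness per plot
#'
#' Number of species with positive abundance in each row; zero for empty
#' plots and invariant to density scaling.
#'
#' @param community Plot-by-species matrix.
#' @return Named integer vector.
#' @export
richness_per_plot <- function(community) {
  out <- as.integer(rowSums(community > 0))
  names(out) <- rownames(community)
  out
}

#' Species turnover against a reference forest type
#'
#' The reference pool is the union of species observed in any plot of the
#' reference forest type. For each plot, `shared_with_reference` counts its
#' species inside the pool and `new_species` those outside it.
#'
#' @param community Plot-by-species matrix.
#' @param design Plot design table.
#' @param reference_type Reference forest type (default `"beech"`).
#' @return Data frame with `plot_id`, `forest_type`, `shared_with_reference`,
#'   `new_species`.
#' @export
turnover_vs_reference <- function(community, design, reference_type = "beech") {
  design <- validate_plot_design(design)
  ft <- design$forest_type[match(rownames(community), design$plot_id)]
  ref_rows <- which(ft == reference_type)
  if (length(ref_rows) == 0L)
    stop("no plots of reference type '", reference_type, "'", call. = FALSE)
  pool <- colnames(community)[colSums(community[ref_rows, , drop = FALSE] > 0) > 0]
  present <- community > 0
  shared <- rowSums(present[, colnames(community) %in% pool, drop = FALSE])
  new <- rowSums(present[, !colnames(community) %in% pool, drop = FALSE])
  data.frame(plot_id = rownames(community), forest_type = ft,
             shared_with_reference = as.integer(shared),
             new_species = as.integer(new),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Chao1 richness estimator
#'
#' `S_obs + f1^2 / (2 f2)`, or the bias-corrected `S_obs + f1 (f1 - 1) / 2`
#' when no doubletons exist; never below the observed richness.
#'
#' @param abund Vector of species abundances (individual counts).
#' @return Chao1 estimate.
#' @export
chao1 <- function(abund) {
  abund <- abund[abund > 0]
  S <- length(abund)
  f1 <- sum(abund == 1); f2 <- sum(abund == 2)
  f0 <- if (f2 > 0) f1^2 / (2 * f2) else f1 * (f1 - 1) / 2
  S + f0
}

#' Individual-based rarefaction and Chao1-anchored extrapolation
#'
#' For `m <= N` the exact hypergeometric estimator
#' `S(m) = S_obs - sum_i C(N - N_i, m) / C(N, m)`; beyond the sample size
#' the curve is extrapolated toward the Chao1 asymptote:
#' `S(N + m*) = S_obs + f0 * (1 - (1 - f1 / (N f0 + f1))^m*)`. 95%
#' confidence bands come from a seeded multinomial bootstrap over
#' individuals.
#'
#' @param abund Species abundance vector (pooled individual counts).
#' @param m_grid Individual counts at which to evaluate; default ~40 knots
#'   from 1 to `2N`.
#' @param n_boot Bootstrap resamples for the bands (default 200).
#' @param seed Integer seed for the bootstrap.
#' @return Data frame `m`, `S_est`, `lower`, `upper`, `type`
#'   (rarefied/extrapolated), with attributes `S_obs`, `N`, `f1`, `f2`,
#'   `chao1`.
#' @export
rarefy_extrapolate <- function(abund, m_grid = NULL, n_boot = 200L, seed = 1L) {
  abund <- abund[abund > 0]
  N <- sum(abund)
  if (N < 1) stop("no individuals to rarefy", call. = FALSE)
  if (is.null(m_grid))
    m_grid <- unique(pmax(1, round(seq(1, 2 * N, length.out = 40))))
  est_curve <- function(a) {
    a <- a[a > 0]
    Ntot <- sum(a); S <- length(a)
    vapply(m_grid, function(m) {
      if (m <= Ntot) {
        S - sum(exp(lchoose(Ntot - a, m) - lchoose(Ntot, m)))
      } else {
        f1 <- sum(a == 1); f2 <- sum(a == 2)
        f0 <- if (f2 > 0) f1^2 / (2 * f2) else f1 * (f1 - 1) / 2
        if (f0 == 0 || f1 == 0) S
        else S + f0 * (1 - (1 - f1 / (Ntot * f0 + f1))^(m - Ntot))
      }
    }, numeric(1))
  }
  S_est <- est_curve(abund)
  boot <- withr::with_seed(.sub_seed(seed, "rarefaction"), {
    p <- abund / N
    replicate(n_boot, est_curve(as.vector(stats::rmultinom(1L, N, p))))
  })
  boot <- matrix(boot, nrow = length(m_grid))
  ci <- apply(boot, 1L, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
  out <- data.frame(m = m_grid, S_est = S_est,
                    lower = ci[1L, ], upper = ci[2L, ],
                    type = ifelse(m_grid <= N, "rarefied", "extrapolated"),
                    stringsAsFactors = FALSE)
  attr(out, "S_obs") <- length(abund); attr(out, "N") <- N
  attr(out, "f1") <- sum(abund == 1); attr(out, "f2") <- sum(abund == 2)
  attr(out, "chao1") <- chao1(abund)
  out
}
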