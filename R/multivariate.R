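#' Bray-Curtis dissimilarity
#'
#' `BC(x, y) = sum |x - y| / sum (x + y)` between community rows; symmetric,
#' zero on the diagonal, in `[0, 1]` for non-negative data. All-zero rows
#' are rejected by name since their dissimilarity is undefined.
#'
#' @param x Plot-by-species abundance or density matrix.
#' @return `dist` object.
#' @export
bray_curtis <- function(x) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("negative abundances", call. = FALSE)
  zero <- rownames(x)[rowSums(x) == 0]
  if (length(zero) > 0L)
    stop("all-zero sample(s): ", paste(zero, collapse = ", "), call. = FALSE)
  vegan::vegdist(x, method = "bray")
}

#' Drop species occurring in at most one plot
#'
#' Occupancy filter applied before the multivariate analyses of species
#' composition: only species present in more than one plot are kept.
#'
#' @param x Plot-by-species matrix.
#' @return Filtered matrix; attribute `dropped` names the removed species.
#' @export
filter_rare_species <- function(x) {
  occ <- colSums(x > 0)
  dropped <- colnames(x)[occ <= 1]
  out <- x[, occ > 1, drop = FALSE]
  attr(out, "units") <- attr(x, "units")
  attr(out, "dropped") <- dropped
  out
}

#' Community matrix transformations for ordination
#'
#' @param x Plot-by-species matrix.
#' @param method `"hellinger"` (square root of relative abundance, via
#'   [vegan::decostand()]), `"log1p"`, or `"none"`.
#' @return Transformed matrix; attribute `transform` records the choice.
#' @export
transform_community <- function(x, method = c("hellinger", "log1p", "none")) {
  method <- match.arg(method)
  out <- switch(method,
                hellinger = vegan::decostand(as.matrix(x), "hellinger"),
                log1p = log1p(as.matrix(x)),
                none = as.matrix(x))
  attr(out, "transform") <- method
  out
}

#' Principal components analysis
#'
#' Eigendecomposition of the covariance (or correlation, if `scale`) matrix
#' of the column-centered data, with a deterministic sign convention: on
#' each axis the largest-magnitude loading is positive.
#'
#' @param x Samples-by-variables matrix.
#' @param center,scale Passed to the decomposition (defaults TRUE, FALSE).
#' @return List of class `ordination`: `scores`, `loadings`, `explained`
#'   (variance proportions), `center`, `scale`, `transform`.
#' @export
pca_ordination <- function(x, center = TRUE, scale = FALSE) {
  x <- as.matrix(x)
  if (nrow(x) < 2L || ncol(x) < 2L) stop("need >= 2 samples and >= 2 variables")
  sds <- apply(x, 2L, stats::sd)
  if (all(sds == 0)) stop("constant matrix: no variance to decompose")
  if (scale && any(sds == 0))
    stop("cannot scale zero-variance column(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  fit <- stats::prcomp(x, center = center, scale. = scale)
  flip <- apply(fit$rotation, 2L, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  scores <- sweep(fit$x, 2L, flip, `*`)
  loadings <- sweep(fit$rotation, 2L, flip, `*`)
  structure(list(scores = scores, loadings = loadings,
                 explained = fit$sdev^2 / sum(fit$sdev^2),
                 center = center, scale = scale,
                 transform = attr(x, "transform")),
            class = "ordination")
}

#' Greedy collinearity filter on environmental variables
#'
#' While any pair of numeric variables has `|Pearson r| >= r_max`, the
#' member of the most correlated pair with the larger mean absolute
#' correlation to all other variables is dropped.
#'
#' @param env Environment table (non-numeric columns are carried through).
#' @param r_max Correlation threshold (default 0.8).
#' @return Filtered table; attribute `dropped` names removed variables.
#' @export
collinearity_filter <- function(env, r_max = 0.8) {
  num <- names(env)[vapply(env, is.numeric, logical(1))]
  keep <- num
  dropped <- character()
  repeat {
    if (length(keep) < 2L) break
    r <- abs(stats::cor(as.matrix(env[, keep, drop = FALSE])))
    diag(r) <- 0
    if (max(r, na.rm = TRUE) < r_max) break
    idx <- which(r == max(r, na.rm = TRUE), arr.ind = TRUE)[1L, ]
    pair <- keep[idx]
    mean_abs <- colMeans(r)[pair]
    worst <- pair[which.max(mean_abs)]
    dropped <- c(dropped, worst)
    keep <- setdiff(keep, worst)
  }
  out <- env[, c(setdiff(names(env), num), keep), drop = FALSE]
  attr(out, "dropped") <- dropped
  out
}

#' Fit environmental vectors onto an ordination
#'
#' Least-squares fit of each standardized environmental variable onto the
#' first two ordination axes (vegan's `envfit`), with permutation p-values.
#' Zero-variance variables are reported as missing with a reason.
#'
#' @param ord `ordination` object from [pca_ordination()].
#' @param env Environment table aligned with the ordination samples
#'   (a `plot_id` column, if present, is matched against score rownames).
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @return Data frame: variable, axis-1/axis-2 direction cosines, `r2`,
#'   `p`; attribute `skipped` lists zero-variance variables.
#' @export
fit_env_vectors <- function(ord, env, n_perm = 999L, seed = 1L) {
  sc <- ord$scores[, 1:2, drop = FALSE]
  if ("plot_id" %in% names(env)) {
    if (!all(rownames(sc) %in% env$plot_id))
      stop("environment table does not cover all ordination samples")
    env <- env[match(rownames(sc), env$plot_id), , drop = FALSE]
  }
  num <- env[, vapply(env, is.numeric, logical(1)), drop = FALSE]
  if (nrow(num) != nrow(sc)) stop("environment rows must match ordination samples")
  sds <- apply(num, 2L, stats::sd)
  skipped <- names(num)[sds == 0]
  num <- num[, sds > 0, drop = FALSE]
  z <- scale(as.matrix(num))
  fit <- withr::with_seed(as.integer(seed),
                          vegan::envfit(sc, as.data.frame(z),
                                        permutations = n_perm))
  out <- data.frame(variable = rownames(fit$vectors$arrows),
                    axis1 = fit$vectors$arrows[, 1L],
                    axis2 = fit$vectors$arrows[, 2L],
                    r2 = fit$vectors$r,
                    p = fit$vectors$pvals,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "skipped") <- skipped
  out
}

# Gower-centered inner-product matrix of a distance object
.gower_center <- function(d) {
  A <- -0.5 * as.matrix(d)^2
  n <- nrow(A)
  J <- diag(n) - matrix(1 / n, n, n)
  J %*% A %*% J
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Distance-based partitioning of a dissimilarity matrix by the terms of a
#' design formula, with sequential (type-I) sums of squares in formula
#' order: for each term the hat-matrix increment against the
#' Gower-centered inner-product matrix gives its SS, and
#' `pseudo-F = (SS_term / df_term) / (SS_residual / df_residual)`.
#' P-values use free permutation of sample labels with the add-one rule
#' `p = (1 + #(F* >= F)) / (1 + n_perm)`, so they are never zero.
#'
#' @param d `dist` object.
#' @param data Data frame of design variables aligned with `d`'s samples.
#' @param formula Right-hand-side formula of terms, e.g.
#'   `~ forest_type * site_condition`.
#' @param n_perm Number of random permutations (default 999).
#' @param seed Integer seed for the permutation stream.
#' @param permutations Optional integer matrix of explicit permutations
#'   (rows = permutations), e.g. all `n!` arrangements for an exact test;
#'   overrides `n_perm`/`seed`. The identity row, if present, is counted
#'   like any other.
#' @return Data frame of class `permanova`: term, df, SS, R2, pseudo-F, p;
#'   attributes `n_perm` and `seed`.
#' @export
permanova <- function(d, data, formula = ~ forest_type * site_condition,
                      n_perm = 999L, seed = 1L, permutations = NULL) {
  G <- .gower_center(d)
  n <- nrow(G)
  if (nrow(data) != n) stop("design rows must match distance matrix", call. = FALSE)
  trm <- stats::terms(formula)
  labels <- attr(trm, "term.labels")
  if (length(labels) == 0L) stop("formula has no terms", call. = FALSE)
  hats <- vector("list", length(labels))
  prev_rank <- 1L
  X_prev <- matrix(1, n, 1L)
  H_prev <- X_prev %*% solve(crossprod(X_prev)) %*% t(X_prev)
  dfs <- integer(length(labels))
  for (k in seq_along(labels)) {
    f_k <- stats::reformulate(labels[seq_len(k)])
    X <- stats::model.matrix(f_k, data = data)
    qrX <- qr(X)
    if (qrX$rank <= prev_rank)
      stop("rank-deficient design at term ", labels[k], call. = FALSE)
    Q <- qr.Q(qrX)[, seq_len(qrX$rank), drop = FALSE]
    H <- tcrossprod(Q)
    hats[[k]] <- H - H_prev
    dfs[k] <- qrX$rank - prev_rank
    H_prev <- H; prev_rank <- qrX$rank
  }
  H_full <- H_prev
  df_res <- n - prev_rank
  R <- diag(n) - H_full
  # clamp roundoff negatives so perfect separation yields F = Inf, not noise
  ss_of <- function(Gm) {
    s <- c(vapply(hats, function(H) sum(H * Gm), numeric(1)), sum(R * Gm))
    tol <- 1e-10 * max(abs(s), 1e-300)
    s[abs(s) < tol] <- 0
    s
  }
  ss <- ss_of(G)
  SS_terms <- ss[seq_along(labels)]
  SS_res <- ss[length(ss)]
  SS_tot <- sum(diag(G))
  Fstat <- (SS_terms / dfs) / (SS_res / df_res)
  stat_fun <- function(Gm) {
    s <- ss_of(Gm)
    (s[seq_along(labels)] / dfs) / (s[length(s)] / df_res)
  }
  if (is.null(permutations)) {
    perms <- withr::with_seed(as.integer(seed),
                              t(replicate(n_perm, sample.int(n))))
  } else {
    perms <- as.matrix(permutations)
    if (ncol(perms) != n) stop("permutation matrix must have n columns")
  }
  ge <- rep(0L, length(labels))
  for (i in seq_len(nrow(perms))) {
    p <- perms[i, ]
    hit <- stat_fun(G[p, p]) >= Fstat - 1e-12
    hit[is.na(hit)] <- FALSE
    ge <- ge + hit
  }
  pval <- (1 + ge) / (1 + nrow(perms))
  out <- data.frame(term = c(labels, "residual", "total"),
                    df = c(dfs, df_res, n - 1L),
                    SS = c(SS_terms, SS_res, SS_tot),
                    R2 = c(SS_terms, SS_res, SS_tot) / SS_tot,
                    pseudo_F = c(Fstat, NA, NA),
                    p = c(pval, NA, NA),
                    stringsAsFactors = FALSE)
  attr(out, "n_perm") <- nrow(perms)
  attr(out, "seed") <- seed
  class(out) <- c("permanova", "data.frame")
  out
}

#' Homogeneity of multivariate dispersion (beta-diversity)
#'
#' Per-sample distances to group centroids in principal-coordinates space
#' (vegan's `betadisper`, negative eigenvalues handled there), tested by a
#' permutation F-test. Groups of size 1 are excluded with a warning.
#'
#' @param d `dist` object.
#' @param groups Factor of group labels aligned with `d`'s samples.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @return List: `F`, `p`, `distances` (per-sample distance to centroid),
#'   `groups`, `excluded`.
#' @export
dispersion_homogeneity <- function(d, groups, n_perm = 999L, seed = 1L) {
  groups <- factor(groups)
  n <- attr(d, "Size")
  if (length(groups) != n) stop("groups must match distance matrix", call. = FALSE)
  sizes <- table(groups)
  excluded <- names(sizes)[sizes < 2]
  if (length(excluded) > 0L) {
    warning("excluding group(s) of size 1: ", paste(excluded, collapse = ", "))
    keep <- !(groups %in% excluded)
    d <- stats::as.dist(as.matrix(d)[keep, keep])
    groups <- droplevels(groups[keep])
  }
  if (nlevels(groups) < 2L) stop("need >= 2 groups", call. = FALSE)
  bd <- vegan::betadisper(d, groups)
  pt <- withr::with_seed(as.integer(seed),
                         vegan::permutest(bd, permutations = n_perm))
  list(F = unname(pt$tab$F[1L]), p = unname(pt$tab[1L, "Pr(>F)"]),
       distances = bd$distances, groups = groups, excluded = excluded)
}
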