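#' Transform a response variable
#'
#' Elementwise `none`, `log`, `log1p` or `sqrt` transform, with domain
#' checks: `log` requires strictly positive values (use `"log1p"`
#' explicitly for data with zeros), `sqrt` non-negative ones. The choice is
#' recorded in the `transform` attribute for provenance.
#'
#' @param values Numeric vector.
#' @param kind One of `"none"`, `"log"`, `"log1p"`, `"sqrt"`.
#' @return Transformed vector with attribute `transform`.
#' @export
transform_response <- function(values, kind = c("none", "log", "log1p", "sqrt")) {
  kind <- match.arg(kind)
  out <- switch(kind,
                none = values,
                log = {
                  if (any(values <= 0))
                    stop("log transform requires positive values; ",
                         "use kind = \"log1p\" for data with zeros", call. = FALSE)
                  log(values)
                },
                log1p = {
                  if (any(values < 0)) stop("log1p requires values >= -0", call. = FALSE)
                  log1p(values)
                },
                sqrt = {
                  if (any(values < 0))
                    stop("sqrt transform requires non-negative values", call. = FALSE)
                  sqrt(values)
                })
  attr(out, "transform") <- kind
  out
}

#' Fit the study's linear mixed-effects model
#'
#' REML fit of `response ~ forest_type * site_condition + (1 | site_id)`
#' with the reference forest type as first factor level. A singular fit
#' (site variance estimated at the boundary 0) triggers a warning but is
#' returned as-is.
#'
#' @param data Data frame with the response plus `forest_type`,
#'   `site_condition`, `site_id` columns (typically a plot design table
#'   joined with a per-plot metric).
#' @param response Name of the response column.
#' @param transform Response transform (see [transform_response()]).
#' @param reference Reference forest-type level (default `"beech"`).
#' @return `lmerModLmerTest` fit with attributes `response`, `transform`,
#'   `reference`.
#' @export
fit_lmm <- function(data, response, transform = "none", reference = "beech") {
  stopifnot(all(c(response, "forest_type", "site_condition", "site_id") %in%
                  names(data)))
  if (length(unique(data$site_id)) < 2L) stop("need >= 2 sites", call. = FALSE)
  d <- data
  d$.y <- as.numeric(transform_response(d[[response]], transform))
  d$forest_type <- stats::relevel(factor(d$forest_type), ref = reference)
  d$site_condition <- factor(d$site_condition)
  d$site_id <- factor(d$site_id)
  fit <- lmerTest::lmer(.y ~ forest_type * site_condition + (1 | site_id),
                        data = d, REML = TRUE)
  if (lme4::isSingular(fit, tol = 1e-5))
    warning("singular fit: site variance estimated at the boundary (0)")
  attr(fit, "response") <- response
  attr(fit, "transform") <- transform
  attr(fit, "reference") <- reference
  fit
}

#' Extract the random-effect and residual variance components
#'
#' @param fit Fit from [fit_lmm()].
#' @return Named numeric vector `c(site, residual)`.
#' @export
variance_components <- function(fit) {
  vc <- as.data.frame(lme4::VarCorr(fit))
  c(site = vc$vcov[vc$grp == "site_id"], residual = vc$vcov[vc$grp == "Residual"])
}

# containment (between-within) denominator df: observations minus groups
# minus the rank of the within-group fixed-effect columns
.containment_df <- function(fit) {
  X <- lme4::getME(fit, "X")
  g <- lme4::getME(fit, "flist")[[1L]]
  P <- stats::model.matrix(~ g - 1)
  Pg <- P %*% solve(crossprod(P)) %*% t(P)
  within_rank <- qr(X - Pg %*% X)$rank
  nrow(X) - nlevels(g) - within_rank
}

#' Marginal means and contrasts against the reference forest type
#'
#' Estimated marginal means per forest type (averaged over site condition)
#' with 95% CI, and treatment-vs-reference contrasts with no multiplicity
#' adjustment. Default degrees of freedom follow the containment
#' (between-within) rule for within-site effects; `"satterthwaite"`
#' switches to lmerTest's approximation. If the model response was log (or
#' log1p) transformed, back-transformed means and CI are appended.
#'
#' @param fit Fit from [fit_lmm()].
#' @param df_method `"containment"` (default) or `"satterthwaite"`.
#' @return List of data frames `means` and `contrasts`.
#' @export
marginal_means_and_contrasts <- function(fit,
                                         df_method = c("containment",
                                                       "satterthwaite")) {
  df_method <- match.arg(df_method)
  mode <- if (df_method == "satterthwaite") "satterthwaite" else "asymptotic"
  emm <- emmeans::emmeans(fit, "forest_type", lmer.df = mode)
  con <- emmeans::contrast(emm, method = "trt.vs.ctrl", ref = 1, adjust = "none")
  if (df_method == "containment") {
    dfc <- .containment_df(fit)
    emm <- update(emm, df = dfc)
    con <- update(con, df = dfc)
  }
  ms <- as.data.frame(summary(emm, infer = c(TRUE, FALSE)))
  cs <- as.data.frame(summary(con, infer = c(TRUE, TRUE)))
  names(ms)[names(ms) == "emmean"] <- "estimate"
  tr <- attr(fit, "transform")
  if (!is.null(tr) && tr %in% c("log", "log1p")) {
    back <- function(x) if (tr == "log") exp(x) else expm1(x)
    ms$response_mean <- back(ms$estimate)
    ms$response_lower <- back(ms$lower.CL)
    ms$response_upper <- back(ms$upper.CL)
    cs$response_ratio <- exp(cs$estimate)  # ratio scale for log contrasts
  }
  list(means = ms, contrasts = cs)
}
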