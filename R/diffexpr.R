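#' Differential-expression configuration
#'
#' Threshold set for the hierarchical differential-expression procedure.
#' Defaults match the main single-cell comparisons (fold-change 1.5,
#' FDR 0.05, F-stage prefilter at adjusted p < 0.2); checkpoint-therapy
#' comparisons use `fc_threshold = 1.25`, marker derivation uses
#' `p_adjust_threshold = 0.1`.
#'
#' @param fc_threshold Linear fold-change cutoff (> 1); applied on the log2
#'   scale as |log2 FC| >= log2(fc_threshold).
#' @param p_adjust_threshold BH-adjusted p cutoff for pairwise calls.
#' @param f_prefilter_threshold BH-adjusted p cutoff for the moderated-F
#'   prefilter stage.
#' @param trend Model the prior variance as a smooth function of mean
#'   expression (default `TRUE`).
#' @return A `deg_config` list.
#' @export
deg_config <- function(fc_threshold = 1.5, p_adjust_threshold = 0.05,
                       f_prefilter_threshold = 0.2, trend = TRUE) {
  if (!is.numeric(fc_threshold) || fc_threshold <= 1) {
    abort("`fc_threshold` must exceed 1 (linear scale).")
  }
  for (p in c(p_adjust_threshold, f_prefilter_threshold)) {
    if (!is.numeric(p) || p <= 0 || p > 1) abort("p thresholds must lie in (0, 1].")
  }
  structure(list(fc_threshold = fc_threshold,
                 p_adjust_threshold = p_adjust_threshold,
                 f_prefilter_threshold = f_prefilter_threshold,
                 trend = isTRUE(trend)),
            class = "deg_config")
}

# Newton inversion of the trigamma function (solves trigamma(x) = y).
trigamma_inverse <- function(y) {
  out <- y
  out[y > 1e7] <- 1 / sqrt(y[y > 1e7])
  out[y < 1e-6] <- 1 / y[y < 1e-6]
  mid <- y <= 1e7 & y >= 1e-6
  x <- 0.5 + 1 / y[mid]
  if (length(x)) {
    for (i in seq_len(50)) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / y[mid]) / psigamma(x, deriv = 2)
      x <- x + dif
      if (max(-dif / x) < 1e-10) break
    }
  }
  out[mid] <- x
  out
}

# Moment-matching fit of a scaled-F distribution to sample variances:
# s2_g ~ s0^2 * F(df1, d0). Works on log variances; when a covariate is
# given, log s0^2 is a lowess-smooth function of it (span 0.5).
fit_f_dist <- function(s2, df1, covariate = NULL, span = 0.5) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2) {
    # Degenerate input: no information to pool; fall back to no shrinkage.
    return(list(df_prior = 0, s2_prior = rep(mean(s2), length(s2))))
  }
  z <- log(s2[ok])
  e <- z - digamma(df1 / 2) + log(df1 / 2)
  if (is.null(covariate)) {
    etrend_all <- rep(mean(e), length(s2))
    resid <- e - mean(e)
  } else {
    lo <- lowess(covariate[ok], e, f = span)
    etrend_all <- stats::approx(lo$x, lo$y, xout = covariate, rule = 2,
                                ties = mean)$y
    resid <- e - etrend_all[ok]
  }
  evar <- var(resid) - trigamma(df1 / 2)
  if (is.finite(evar) && evar > 0) {
    df_prior <- 2 * trigamma_inverse(evar)
    s2_prior <- exp(etrend_all + digamma(df_prior / 2) - log(df_prior / 2))
  } else {
    df_prior <- Inf
    s2_prior <- exp(etrend_all)
  }
  list(df_prior = df_prior, s2_prior = s2_prior)
}

#' Empirical-Bayes moderated linear-model fit
#'
#' Fits a one-way group-means model to each gene of a log2-scale expression
#' matrix, then shrinks per-gene residual variances toward a pooled prior
#' by empirical Bayes. The prior degrees of freedom `d0` and prior variance
#' `s0^2` are estimated by moment-matching the marginal distribution of the
#' log sample variances to a scaled F distribution; with `trend = TRUE`,
#' `s0^2` is a lowess-smooth function of each gene's mean expression.
#' Posterior variances are `(d0 s0^2 + df s^2) / (d0 + df)`.
#'
#' Genes with zero residual variance are assigned the prior variance
#' directly so downstream statistics stay defined.
#'
#' @param normexpr Genes x cells matrix on a log2 scale (or an
#'   [expr_matrix()] with a `normexpr` layer).
#' @param groups Factor (or vector) of group labels, one per cell; every
#'   group needs >= 2 cells.
#' @param trend Fit an expression-dependent prior variance.
#' @param d0_override Optional fixed prior df (e.g. 0 disables shrinkage,
#'   `Inf` forces full shrinkage); mainly for diagnostics.
#' @return A `moderated_fit` object: group means, residual variances `s2`
#'   and df, prior (`d0`, `s0_2`), posterior variances `s2_post`, and mean
#'   expression `amean`.
#' @export
moderated_fit <- function(normexpr, groups, trend = FALSE, d0_override = NULL) {
  x <- if (inherits(normexpr, "expr_matrix")) get_layer(normexpr, "normexpr") else as.matrix(normexpr)
  groups <- factor(groups)
  if (length(groups) != ncol(x)) abort("`groups` must have one label per cell.")
  if (nlevels(groups) < 2) abort("Need at least two groups.")
  n_g <- table(groups)
  if (any(n_g < 2)) {
    abort(sprintf("Group(s) with fewer than 2 cells: %s",
                  paste(names(n_g)[n_g < 2], collapse = ", ")))
  }
  k <- nlevels(groups)
  N <- ncol(x)
  group_means <- t(rowsum(t(x), groups) / as.vector(n_g))
  df_resid <- N - k
  rss <- rowSums(x^2) - group_means^2 %*% as.vector(n_g)
  s2 <- pmax(as.vector(rss) / df_resid, 0)  # guard tiny negative round-off
  amean <- rowMeans(x)

  prior <- fit_f_dist(s2, df_resid, covariate = if (trend) amean else NULL)
  d0 <- d0_override %||% prior$df_prior
  s0_2 <- prior$s2_prior
  s2_post <- if (is.infinite(d0)) s0_2 else (d0 * s0_2 + df_resid * s2) / (d0 + df_resid)
  zero_var <- s2 == 0
  if (any(zero_var) && d0 == 0) s2_post[zero_var] <- s0_2[zero_var]

  structure(
    list(group_means = group_means, n_per_group = as.vector(n_g),
         group_levels = levels(groups), s2 = s2, df_resid = df_resid,
         d0 = d0, s0_2 = s0_2, s2_post = s2_post, amean = amean,
         # total df for the reference distributions, bounded by the pooled
         # residual df actually observed (an estimated prior cannot carry
         # more information than the data it was estimated from)
         df_total = min(d0 + df_resid, nrow(x) * df_resid),
         genes = rownames(x), trend = trend),
    class = "moderated_fit"
  )
}

#' @export
print.moderated_fit <- function(x, ...) {
  cat(sprintf(
    "<moderated_fit> %d genes, groups: %s; residual df %d, prior df %.2f%s\n",
    length(x$genes), paste(x$group_levels, collapse = "/"),
    x$df_resid, x$d0, if (x$trend) " (trended prior)" else ""))
  invisible(x)
}

#' Moderated t-test between two groups
#'
#' Computes, per gene, `t = (mean_A - mean_B) / sqrt(s2_post (1/n_A +
#' 1/n_B))` with `d0 + df` total degrees of freedom, two-sided p values and
#' BH adjustment across genes. The log2 fold-change is the difference of
#' group means (the data are already log2-scale).
#'
#' @param fit A [moderated_fit()].
#' @param contrast Length-2 character vector `c(A, B)` of group levels
#'   (A vs B); A == B is allowed and gives the degenerate all-zero contrast.
#' @param genes Optional subset of genes to test (BH is computed within this
#'   set).
#' @return A tibble: `gene`, `contrast`, `log2_fc`, `t`, `p_value`,
#'   `adj_p_value`, `mean_expr`.
#' @export
moderated_t_test <- function(fit, contrast, genes = NULL) {
  stopifnot(inherits(fit, "moderated_fit"))
  if (length(contrast) != 2) abort("`contrast` must name two groups.")
  missing <- setdiff(contrast, fit$group_levels)
  if (length(missing)) abort(sprintf("Unknown group(s): %s",
                                     paste(missing, collapse = ", ")))
  idx <- if (is.null(genes)) seq_along(fit$genes) else match(genes, fit$genes)
  if (anyNA(idx)) abort("Some requested genes are absent from the fit.")
  ia <- match(contrast[1], fit$group_levels)
  ib <- match(contrast[2], fit$group_levels)
  delta <- fit$group_means[idx, ia] - fit$group_means[idx, ib]
  if (contrast[1] == contrast[2]) delta <- rep(0, length(idx))
  vfac <- 1 / fit$n_per_group[ia] + 1 / fit$n_per_group[ib]
  se <- sqrt(fit$s2_post[idx] * vfac)
  tstat <- ifelse(se > 0, delta / se, ifelse(delta == 0, 0, sign(delta) * Inf))
  p <- 2 * pt(-abs(tstat), df = fit$df_total)
  tibble(
    gene = fit$genes[idx],
    contrast = paste(contrast[1], "vs", contrast[2]),
    log2_fc = unname(delta), t = unname(tstat),
    p_value = unname(p), adj_p_value = bh_adjust(unname(p)),
    mean_expr = unname(fit$amean[idx])
  )
}

#' Moderated F-test across all groups
#'
#' Per-gene moderated F statistic for any difference among group means,
#' using the posterior variance in the denominator and `d0 + df` denominator
#' degrees of freedom.
#'
#' @inheritParams moderated_t_test
#' @return A tibble: `gene`, `f`, `p_value`, `adj_p_value`.
#' @export
moderated_f_test <- function(fit) {
  stopifnot(inherits(fit, "moderated_fit"))
  n_g <- fit$n_per_group
  N <- sum(n_g)
  k <- length(n_g)
  mbar <- as.vector(fit$group_means %*% n_g) / N
  between_ss <- as.vector((fit$group_means - mbar)^2 %*% n_g)
  fstat <- (between_ss / (k - 1)) / fit$s2_post
  fstat[fit$s2_post == 0 & between_ss == 0] <- 0
  p <- pf(fstat, df1 = k - 1, df2 = fit$df_total, lower.tail = FALSE)
  tibble(gene = fit$genes, f = unname(fstat), p_value = unname(p),
         adj_p_value = bh_adjust(unname(p)))
}

#' Hierarchical F-then-pairwise differential expression
#'
#' Stage 1 screens genes with a moderated F test across all groups, keeping
#' those with BH-adjusted p below `config$f_prefilter_threshold`. Stage 2
#' runs pairwise moderated t-tests on the surviving genes only; BH is then
#' re-computed jointly over all contrasts with the full testing universe
#' (genes x contrasts) as the adjustment denominator, so neither the
#' stage-1 selection nor the multiplicity of contrasts inflates the
#' false-discovery rate of the reported calls (adjusting within the
#' survivor set of a single contrast would cap error control at the
#' stage-1 threshold rather than the nominal level). A gene is significant
#' when its adjusted p is below `config$p_adjust_threshold` and its |log2
#' fold-change| is at least `log2(config$fc_threshold)`.
#'
#' @inheritParams moderated_fit
#' @param config A [deg_config()].
#' @param contrasts Optional list of length-2 character vectors; defaults to
#'   all pairs of group levels.
#' @return A tibble of stage-2 results with a `significant` flag; the
#'   stage-1 table is attached as attribute `"f_stage"`.
#' @export
hierarchical_deg <- function(normexpr, groups, config = deg_config(),
                             contrasts = NULL) {
  stopifnot(inherits(config, "deg_config"))
  fit <- moderated_fit(normexpr, groups, trend = config$trend)
  fres <- moderated_f_test(fit)
  survivors <- fres$gene[fres$adj_p_value < config$f_prefilter_threshold]
  if (!length(survivors)) {
    warn("No gene passes the F-stage prefilter; returning an empty result.")
    out <- tibble(gene = character(), contrast = character(),
                  log2_fc = double(), t = double(), p_value = double(),
                  adj_p_value = double(), mean_expr = double(),
                  significant = logical())
    attr(out, "f_stage") <- fres
    return(out)
  }
  contrasts <- contrasts %||% utils::combn(fit$group_levels, 2, simplify = FALSE)
  n_universe <- length(fit$genes) * length(contrasts)
  out <- purrr::map_dfr(contrasts, function(ct) {
    moderated_t_test(fit, ct, genes = survivors)
  })
  out$adj_p_value <- p.adjust(out$p_value, method = "BH", n = n_universe)
  out <- mutate(out,
                significant = .data$adj_p_value < config$p_adjust_threshold &
                  abs(.data$log2_fc) >= log2(config$fc_threshold))
  attr(out, "f_stage") <- fres
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Validates that the inputs are probabilities and applies the BH step-up
#' adjustment (`adj_(i) = min_{j >= i} p_(j) m / j`, capped at 1), returned
#' in the original order.
#'
#' @param p_values Numeric vector of p values in \[0, 1\].
#' @return Adjusted p values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values)) abort("`p_values` must be numeric.")
  bad <- !is.na(p_values) & (p_values < 0 | p_values > 1)
  if (any(bad)) abort("p values must lie in [0, 1].")
  p.adjust(p_values, method = "BH")
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.moderated_fit <- function(x, ...) {
  means <- as_tibble(x$group_means)
  names(means) <- paste0("mean_", x$group_levels)
  dplyr::bind_cols(
    tibble(gene = x$genes, mean_expr = unname(x$amean),
           s2 = unname(x$s2), s2_prior = unname(x$s0_2),
           s2_post = unname(x$s2_post)),
    means
  )
}

#' @exportS3Method generics::glance
glance.moderated_fit <- function(x, ...) {
  tibble(n_genes = length(x$genes), n_groups = length(x$group_levels),
         df_resid = x$df_resid, d0 = x$d0,
         s2_prior_median = median(x$s0_2), trend = x$trend)
}
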