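#' Kendall correlation matrix over marker genes
#'
#' Pairwise Kendall tau-b (tie-corrected) between marker genes across a
#' cohort's samples, with two-sided p values from the tie-adjusted normal
#' approximation. Markers absent from the cohort are dropped with a
#' warning; constant genes get tau 0 with a flag.
#'
#' @param cohort A [bulk_cohort()].
#' @param markers Character vector of gene symbols (default: MAIT signature
#'   plus pan-T and NK markers).
#' @return A `kendall_report`: list with `tau` and `p` matrices, `markers`,
#'   and `constant` (logical per marker).
#' @export
kendall_matrix <- function(cohort, markers = NULL) {
  stopifnot(inherits(cohort, "bulk_cohort"))
  gs <- mait_gene_sets()
  markers <- markers %||% unique(c(gs$mait_signature, gs$pan_t_genes, gs$nk_genes))
  if (nrow(cohort$expr) < 10) abort("Need at least 10 samples.")
  missing <- setdiff(markers, colnames(cohort$expr))
  if (length(missing)) {
    warn(sprintf("Marker(s) absent from cohort, dropped: %s",
                 paste(missing, collapse = ", ")))
    markers <- setdiff(markers, missing)
  }
  if (length(markers) < 2) abort("Fewer than two markers available.")
  m <- cohort$expr[, markers, drop = FALSE]
  constant <- apply(m, 2, function(v) length(unique(v)) == 1)
  k <- length(markers)
  tau <- diag(1, k); p <- matrix(0, k, k)
  dimnames(tau) <- dimnames(p) <- list(markers, markers)
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      if (constant[i] || constant[j]) {
        tau[i, j] <- tau[j, i] <- 0
        p[i, j] <- p[j, i] <- 1
      } else {
        ct <- suppressWarnings(
          cor.test(m[, i], m[, j], method = "kendall", exact = FALSE)
        )
        tau[i, j] <- tau[j, i] <- unname(ct$estimate)
        p[i, j] <- p[j, i] <- ct$p.value
      }
    }
  }
  structure(list(tau = tau, p = p, markers = markers, constant = constant),
            class = "kendall_report")
}

#' @export
print.kendall_report <- function(x, ...) {
  cat(sprintf("<kendall_report> %d markers; %d constant\n",
              length(x$markers), sum(x$constant)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.kendall_report <- function(x, ...) {
  pairs <- which(upper.tri(x$tau), arr.ind = TRUE)
  tibble(gene1 = x$markers[pairs[, 1]], gene2 = x$markers[pairs[, 2]],
         tau = x$tau[pairs], p_value = x$p[pairs])
}

# Positive, significant correlation between two genes in a report.
is_correlated <- function(report, g1, g2, alpha) {
  report$tau[g1, g2] > 0 & report$p[g1, g2] < alpha
}

#' Rule-based trimming of a bulk-cohort MAIT signature
#'
#' Retains only signature genes whose bulk expression behaves like a MAIT /
#' T-cell transcript, per three rules evaluated against the *current*
#' retained set ("correlated" = Kendall tau > 0 with p < `alpha`):
#' (1) correlated with the anchor gene (SLC4A10), anchor exempt;
#' (2) correlated with all, or all but one, other retained genes;
#' (3) correlated with at least two pan-T-cell markers.
#' The worst violator (most rules broken; ties broken by smallest tau with
#' the anchor) is removed and the rules re-evaluated until a fixed point is
#' reached. A cohort is `eligible` for survival analysis only if at least
#' `min_genes` genes remain.
#'
#' @param report A [kendall_matrix()] result containing signature, pan-T
#'   (and typically NK) markers.
#' @param signature Genes to trim (default: 11-gene MAIT signature).
#' @param anchor Anchor gene (default `"SLC4A10"`); must be in the report.
#' @param pan_t_genes Pan-T markers (default CD3D/CD3E/CD3G).
#' @param alpha Significance cutoff for "correlated" (default 0.05).
#' @param min_genes Eligibility threshold (default 5).
#' @param cancer Optional cohort label carried into the output.
#' @return A `trimmed_signature`: list with `cancer`, `retained`,
#'   `removed` (tibble of gene + rules violated at removal), `eligible`.
#' @export
trim_signature <- function(report, signature = NULL, anchor = "SLC4A10",
                           pan_t_genes = NULL, alpha = 0.05,
                           min_genes = 5, cancer = NA_character_) {
  stopifnot(inherits(report, "kendall_report"))
  gs <- mait_gene_sets()
  signature <- as_signature(signature %||% gs$mait_signature)$genes
  pan_t_genes <- pan_t_genes %||% gs$pan_t_genes
  if (!anchor %in% report$markers) {
    abort(sprintf("Anchor gene '%s' is absent from the correlation report.", anchor))
  }
  retained <- intersect(signature, report$markers)
  pan_t <- intersect(pan_t_genes, report$markers)
  removed <- tibble(gene = character(), rules_violated = character())

  violations <- function(g, retained) {
    v <- character()
    if (g != anchor) {
      anchor_ok <- anchor %in% retained && is_correlated(report, g, anchor, alpha)
      if (!anchor_ok) v <- c(v, "anchor")
    }
    others <- setdiff(retained, g)
    n_uncorr <- sum(!vapply(others, function(o)
      is_correlated(report, g, o, alpha), logical(1)))
    if (n_uncorr >= 2) v <- c(v, "block")
    n_pant <- sum(vapply(pan_t, function(o)
      is_correlated(report, g, o, alpha), logical(1)))
    if (n_pant < 2) v <- c(v, "pan_t")
    v
  }

  for (iter in seq_len(length(retained))) {
    viol <- lapply(retained, violations, retained = retained)
    n_viol <- lengths(viol)
    if (all(n_viol == 0)) break
    worst <- which(n_viol == max(n_viol))
    if (length(worst) > 1) {
      anchor_tau <- report$tau[retained[worst], anchor]
      worst <- worst[which.min(anchor_tau)]
    }
    removed <- bind_rows(removed, tibble(
      gene = retained[worst],
      rules_violated = paste(viol[[worst]], collapse = "+")
    ))
    retained <- retained[-worst]
    if (!length(retained)) break
  }
  structure(list(cancer = cancer, retained = retained, removed = removed,
                 eligible = length(retained) >= min_genes,
                 anchor = anchor, alpha = alpha),
            class = "trimmed_signature")
}

#' @export
print.trimmed_signature <- function(x, ...) {
  cat(sprintf("<trimmed_signature>%s %d/%d genes retained (%seligible)\n",
              if (is.na(x$cancer)) "" else paste0(" [", x$cancer, "]"),
              length(x$retained),
              length(x$retained) + nrow(x$removed),
              if (x$eligible) "" else "NOT "))
  if (length(x$retained)) cat("  retained:", paste(x$retained, collapse = ", "), "\n")
  if (nrow(x$removed)) {
    cat("  removed: ", paste(sprintf("%s (%s)", x$removed$gene,
                                     x$removed$rules_violated), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Per-sample MAIT, T-cell and residual MAIT scores in a bulk cohort
#'
#' The MAIT score is the mean of per-gene z-scores (over samples) of the
#' retained signature genes; the T-cell score is computed likewise from the
#' pan-T markers. The residual MAIT score removes the T-cell component by
#' ordinary least squares: the residual of regressing the MAIT score on the
#' T score (intercept included), hence exactly orthogonal to the T score.
#'
#' @param cohort A [bulk_cohort()].
#' @param trimmed A `trimmed_signature` (must be eligible) or a character
#'   vector of genes.
#' @param pan_t_genes Pan-T markers (default CD3D/CD3E/CD3G).
#' @return A tibble: `sample_id`, `mait_score`, `t_score`,
#'   `resid_mait_score`.
#' @export
score_bulk <- function(cohort, trimmed, pan_t_genes = NULL) {
  stopifnot(inherits(cohort, "bulk_cohort"))
  pan_t_genes <- pan_t_genes %||% mait_gene_sets()$pan_t_genes
  genes <- if (inherits(trimmed, "trimmed_signature")) {
    if (!trimmed$eligible) {
      abort("Trimmed signature is not eligible (fewer than the minimum genes).")
    }
    trimmed$retained
  } else as_signature(trimmed)$genes
  zmean <- function(gset) {
    gset <- intersect(gset, colnames(cohort$expr))
    if (!length(gset)) abort("None of the requested genes are in the cohort.")
    sub <- cohort$expr[, gset, drop = FALSE]
    sdv <- apply(sub, 2, sd)
    z <- sweep(sub, 2, colMeans(sub), "-")
    z <- sweep(z, 2, ifelse(sdv > 0, sdv, 1), "/")
    z[, sdv == 0] <- 0
    rowMeans(z)
  }
  mait <- zmean(genes)
  tsc <- zmean(pan_t_genes)
  if (sd(tsc) == 0) {
    warn("T-cell score is constant; residualization skipped.")
    res <- mait
  } else {
    res <- unname(resid(lm(mait ~ tsc)))
  }
  tibble(sample_id = rownames(cohort$expr), mait_score = unname(mait),
         t_score = unname(tsc), resid_mait_score = res)
}

#' Survival association of a per-sample score
#'
#' Stratifies samples at the 33rd/67th percentiles of the score into
#' low/middle/high groups (linear-interpolation quantiles; boundary samples
#' go to the lower stratum) and fits a univariate Cox proportional-hazards
#' model of high vs low (middle excluded; Efron tie handling), plus a
#' Kaplan-Meier / log-rank comparison of the two groups. With
#' `mode = "continuous"` the Cox model instead uses the standardized score
#' on all samples; the tertile KM/log-rank is still reported.
#'
#' @param scores Data frame with `sample_id` and the score column.
#' @param cohort A [bulk_cohort()] supplying the endpoints.
#' @param endpoint `"os"` or `"pfs"`.
#' @param mode `"tertile"` (default) or `"continuous"`.
#' @param score_col Which score column to use (default
#'   `"resid_mait_score"`).
#' @param min_samples Minimum samples with non-missing endpoint (default
#'   30).
#' @return A `mait_survfit`: list with `summary` (one-row tibble: hazard
#'   ratio, CI, Wald and log-rank p, group sizes), `cox` (the coxph fit),
#'   `km` (survfit object for high/low) and `data`.
#' @export
survival_test <- function(scores, cohort, endpoint = c("os", "pfs"),
                          mode = c("tertile", "continuous"),
                          score_col = "resid_mait_score", min_samples = 30) {
  endpoint <- match.arg(endpoint)
  mode <- match.arg(mode)
  stopifnot(inherits(cohort, "bulk_cohort"))
  scores <- as_tibble(scores)
  if (!score_col %in% names(scores)) {
    abort(sprintf("Column '%s' not found in `scores`.", score_col))
  }
  tcol <- paste0(endpoint, "_time"); ecol <- paste0(endpoint, "_event")
  df <- inner_join(scores, cohort$clinical, by = "sample_id") |>
    rename(time = dplyr::all_of(tcol), event = dplyr::all_of(ecol)) |>
    dplyr::filter(!is.na(.data$time), !is.na(.data$event))
  if (nrow(df) < min_samples) {
    abort(sprintf("Only %d samples with non-missing %s endpoint (need >= %d).",
                  nrow(df), toupper(endpoint), min_samples))
  }
  s <- df[[score_col]]
  qs <- quantile(s, c(1/3, 2/3), type = 7)
  df$group <- factor(ifelse(s <= qs[1], "low",
                            ifelse(s <= qs[2], "middle", "high")),
                     levels = c("low", "middle", "high"))
  hl <- dplyr::filter(df, .data$group != "middle") |>
    mutate(group = droplevels(.data$group))

  zero_events <- with(hl, tapply(event, group, sum)) == 0
  flagged <- any(zero_events)
  if (flagged) warn("A stratum has zero events; the hazard ratio is unstable.")

  cox <- if (mode == "tertile") {
    survival::coxph(survival::Surv(time, event) ~ group, data = hl,
                    ties = "efron")
  } else {
    survival::coxph(survival::Surv(time, event) ~ I(scale(df[[score_col]])[, 1]),
                    data = df, ties = "efron")
  }
  cs <- summary(cox)
  km <- survival::survfit(survival::Surv(time, event) ~ group, data = hl)
  lr <- survival::survdiff(survival::Surv(time, event) ~ group, data = hl)
  lr_p <- pchisq(lr$chisq, df = length(lr$n) - 1, lower.tail = FALSE)

  summary_tbl <- tibble(
    cancer = NA_character_, endpoint = toupper(endpoint), mode = mode,
    hazard_ratio = unname(cs$conf.int[1, "exp(coef)"]),
    hr_lower = unname(cs$conf.int[1, "lower .95"]),
    hr_upper = unname(cs$conf.int[1, "upper .95"]),
    log_hr = unname(cs$coefficients[1, "coef"]),
    log_hr_se = unname(cs$coefficients[1, "se(coef)"]),
    wald_p = unname(cs$coefficients[1, "Pr(>|z|)"]),
    logrank_p = lr_p, logrank_chisq = unname(lr$chisq),
    n_low = sum(df$group == "low"), n_middle = sum(df$group == "middle"),
    n_high = sum(df$group == "high"), hr_flagged = flagged
  )
  structure(list(summary = summary_tbl, cox = cox, km = km, data = df),
            class = "mait_survfit")
}

#' @export
print.mait_survfit <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<mait_survfit> %s (%s): HR %.3f [%.3f, %.3f], Wald p %.3g, log-rank p %.3g\n",
    s$endpoint, s$mode, s$hazard_ratio, s$hr_lower, s$hr_upper,
    s$wald_p, s$logrank_p))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.mait_survfit <- function(x, ...) x$summary

#' @exportS3Method generics::glance
glance.mait_survfit <- function(x, ...) {
  tibble(n = nrow(x$data), n_events = sum(x$data$event),
         concordance = unname(x$cox$concordance["concordance"]))
}

#' Association between MR1 expression and the MAIT score
#'
#' Pearson correlation (two-sided) between log2(TPM+1) expression of MR1 —
#' the antigen-presenting molecule restricting MAIT cells — and the
#' residual MAIT score.
#'
#' @param cohort A [bulk_cohort()] containing an `MR1` column.
#' @param scores Output of [score_bulk()].
#' @param score_col Score column (default `"resid_mait_score"`).
#' @return A one-row tibble: `r`, `p_value`, `n`.
#' @export
mr1_association <- function(cohort, scores, score_col = "resid_mait_score") {
  stopifnot(inherits(cohort, "bulk_cohort"))
  if (!"MR1" %in% colnames(cohort$expr)) abort("MR1 is absent from the cohort.")
  scores <- as_tibble(scores)
  mr1 <- cohort$expr[scores$sample_id, "MR1"]
  ct <- cor.test(mr1, scores[[score_col]])
  tibble(r = unname(ct$estimate), p_value = ct$p.value, n = nrow(scores))
}
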