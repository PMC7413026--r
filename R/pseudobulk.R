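#' Pre-filter a signature by detection rate
#'
#' Drops signature genes detected (count > 0) in fewer than `min_expr_frac`
#' of cells — lowly expressed genes only add noise to pseudo-bulk scores.
#'
#' @param x An [expr_matrix()] with a counts layer.
#' @param signature A [signature_def()] or character vector.
#' @param min_expr_frac Minimum detection fraction (default 0.01).
#' @return A reduced [signature_def()]; removed genes are attached as
#'   attribute `"removed"`.
#' @export
prefilter_signature <- function(x, signature, min_expr_frac = 0.01) {
  counts <- get_layer(x, "counts")
  assert_prob(min_expr_frac, "min_expr_frac")
  sig <- as_signature(signature)
  present <- intersect(sig$genes, rownames(counts))
  det <- rowMeans(counts[present, , drop = FALSE] > 0)
  keep <- present[det >= min_expr_frac]
  removed <- setdiff(sig$genes, keep)
  if (!length(keep)) {
    abort("All signature genes fall below the detection threshold.")
  }
  if (length(removed)) {
    message(sprintf("Pre-filter removed %d gene(s): %s",
                    length(removed), paste(removed, collapse = ", ")))
  }
  out <- signature_def(sig$name, keep, provenance = sig$provenance)
  attr(out, "removed") <- removed
  out
}

#' Simulate pseudo-bulk samples from annotated single cells
#'
#' Each pseudo-bulk sample draws `n` cells from the dataset without
#' replacement (samples are independent, so different samples may overlap),
#' sums their raw counts per gene, records the true subset composition of
#' the draw, normalizes the summed profile to log2(CPM + 1), and scores the
#' signature. `n` is either fixed or drawn uniformly from an integer range
#' per sample.
#'
#' @param x An [expr_matrix()] with a counts layer.
#' @param annotations Per-cell annotations with `subset`.
#' @param signature Signature to score (apply [prefilter_signature()]
#'   first if desired).
#' @param n_samples Number of pseudo-bulk samples.
#' @param n_cells Either a single integer or a length-2 range `c(lo, hi)`.
#' @param seed Integer seed (required).
#' @param score_method `"mean"` (default): plain mean of the normalized
#'   expression of the signature genes, per sample; `"zmean"`: mean of
#'   per-gene z-scores across samples.
#' @return A list of class `pseudobulk_set`: `samples` (tibble with
#'   `sample_id`, `n_cells`, one `frac_*` column per subset, `mait_score`),
#'   `normexpr` (genes x samples matrix), `counts` (genes x samples summed
#'   counts) and `members` (list of drawn cell ids).
#' @export
make_pseudobulk <- function(x, annotations, signature,
                            n_samples = 300, n_cells = 3000, seed,
                            score_method = c("mean", "zmean")) {
  score_method <- match.arg(score_method)
  counts <- get_layer(x, "counts")
  ann <- as_tibble(annotations)
  if (n_samples < 2) abort("`n_samples` must be at least 2.")
  if (!length(n_cells) %in% 1:2 || any(n_cells < 1)) {
    abort("`n_cells` must be a positive integer or an integer range c(lo, hi).")
  }
  if (max(n_cells) > ncol(counts)) {
    abort(sprintf("Requested up to %d cells but only %d are available.",
                  max(n_cells), ncol(counts)))
  }
  subsets <- ann$subset[match(colnames(counts), ann$cell_id)]
  if (anyNA(subsets)) abort("Every cell needs a subset annotation.")
  subset_levels_here <- sort(unique(subsets))

  with_seed(seed, {
    ns <- if (length(n_cells) == 2) {
      n_cells[1] + sample.int(n_cells[2] - n_cells[1] + 1L, n_samples,
                              replace = TRUE) - 1L
    } else rep(as.integer(n_cells), n_samples)
    members <- lapply(ns, function(n) sample(colnames(counts), n))
    summed <- vapply(members, function(cells) {
      rowSums(counts[, cells, drop = FALSE])
    }, numeric(nrow(counts)))
    colnames(summed) <- sprintf("pb_%04d", seq_len(n_samples))
    fracs <- matrix(unlist(lapply(members, function(cells) {
      tab <- table(factor(subsets[match(cells, colnames(counts))],
                          levels = subset_levels_here))
      as.vector(tab) / length(cells)
    })), nrow = n_samples, byrow = TRUE,
    dimnames = list(NULL, paste0("frac_", subset_levels_here)))

    norm <- normalize_log_cpm(summed)
    sig <- as_signature(signature)
    present <- intersect(sig$genes, rownames(norm))
    if (!length(present)) abort("No signature gene present in the matrix.")
    score <- if (score_method == "mean") {
      colMeans(norm[present, , drop = FALSE])
    } else {
      score_module(expr_matrix(normexpr = norm), present)$score
    }
    samples <- dplyr::bind_cols(
      tibble(sample_id = colnames(summed), n_cells = ns),
      as_tibble(fracs),
      tibble(mait_score = unname(score))
    )
    structure(list(samples = samples, normexpr = norm, counts = summed,
                   members = members, signature = present),
              class = "pseudobulk_set")
  })
}

#' @export
print.pseudobulk_set <- function(x, ...) {
  cat(sprintf("<pseudobulk_set> %d samples, %d genes; signature: %s\n",
              nrow(x$samples), nrow(x$counts),
              paste(x$signature, collapse = ", ")))
  invisible(x)
}

#' Evaluate signature scores against true subset fractions
#'
#' Removes outlier scores — samples whose signature score lies more than
#' `outlier_mad_k` raw median absolute deviations from the median — then
#' computes Pearson correlations (with two-sided p values) between the
#' score and each subset's true fraction across the surviving samples.
#'
#' @param samples The `samples` tibble of a [make_pseudobulk()] result (or
#'   the result itself); needs `mait_score` and `frac_*` columns.
#' @param outlier_mad_k MAD multiplier (default 3); the MAD is unscaled (no
#'   1.4826 consistency factor).
#' @return A tibble with one row per subset (`subset`, `r`, `p_value`,
#'   `n_used`); removed sample ids are attached as attribute `"outliers"`.
#' @export
evaluate_scores <- function(samples, outlier_mad_k = 3) {
  if (inherits(samples, "pseudobulk_set")) samples <- samples$samples
  samples <- as_tibble(samples)
  score <- samples$mait_score
  dev <- abs(score - median(score))
  madv <- median(dev)
  if (madv == 0 && any(dev > 0)) {
    warn("MAD of scores is zero with non-constant scores; skipping outlier removal.")
    keep <- rep(TRUE, length(score))
  } else {
    keep <- dev <= outlier_mad_k * madv
  }
  if (sum(keep) < 3) abort("Fewer than 3 samples remain after outlier removal.")
  kept <- samples[keep, ]
  frac_cols <- grep("^frac_", names(samples), value = TRUE)
  out <- purrr::map_dfr(frac_cols, function(col) {
    if (sd(kept[[col]]) == 0 || sd(kept$mait_score) == 0) {
      # a constant fraction (or score) has no defined correlation
      return(tibble(subset = sub("^frac_", "", col), r = NA_real_,
                    p_value = NA_real_, n_used = nrow(kept)))
    }
    ct <- cor.test(kept$mait_score, kept[[col]])
    tibble(subset = sub("^frac_", "", col),
           r = unname(ct$estimate), p_value = ct$p.value,
           n_used = nrow(kept))
  })
  attr(out, "outliers") <- samples$sample_id[!keep]
  out
}
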