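#' Per-cell module score
#'
#' Scores a gene set per cell as the mean of per-gene z-scores: each
#' signature gene's log2-scale expression is centered and scaled across
#' cells, and the z-scores of the genes present are averaged within each
#' cell. Genes with zero variance contribute 0; signature genes absent from
#' the matrix are dropped (an error is raised if none remain). The score is
#' invariant under per-gene affine rescaling of the input.
#'
#' @param x An [expr_matrix()] with a `normexpr` layer (or a genes x cells
#'   log2-scale matrix).
#' @param signature A [signature_def()] or character vector of gene symbols.
#' @return A tibble with `cell_id` and `score`; the genes actually used are
#'   attached as attribute `"genes_used"`.
#' @export
score_module <- function(x, signature) {
  m <- if (inherits(x, "expr_matrix")) get_layer(x, "normexpr") else as.matrix(x)
  sig <- as_signature(signature)
  present <- intersect(sig$genes, rownames(m))
  if (!length(present)) {
    abort(sprintf("No signature gene found in the matrix; missing: %s",
                  paste(sig$genes, collapse = ", ")))
  }
  sub <- m[present, , drop = FALSE]
  mu <- rowMeans(sub)
  sdv <- apply(sub, 1, sd)
  z <- (sub - mu) / ifelse(sdv > 0, sdv, 1)
  z[sdv == 0, ] <- 0
  out <- tibble(cell_id = colnames(m), score = unname(colMeans(z)))
  attr(out, "genes_used") <- present
  out
}

#' Rank-based comparison of module scores between two groups
#'
#' Two-sample Wilcoxon rank-sum test on per-cell scores, two-sided. Exact
#' enumeration is used for small untied samples (both n <= 25), the
#' tie-corrected normal approximation otherwise.
#'
#' @param scores Data frame with columns `cell_id` and `score` (e.g. from
#'   [score_module()]).
#' @param group_labels Vector of two-level group labels, either named by
#'   cell id or aligned with `scores` rows.
#' @return A one-row tibble: group ns, medians, rank-sum statistic `W`, and
#'   two-sided `p_value`.
#' @export
compare_scores <- function(scores, group_labels) {
  scores <- as_tibble(scores)
  if (!is.null(names(group_labels))) {
    group_labels <- group_labels[scores$cell_id]
  }
  if (length(group_labels) != nrow(scores)) {
    abort("`group_labels` must align with `scores` (by position or cell id).")
  }
  g <- factor(group_labels)
  if (nlevels(g) != 2) abort("Exactly two groups are required.")
  xs <- split(scores$score, g)
  if (any(lengths(xs) == 0)) abort("Both groups must be non-empty.")
  exact <- all(lengths(xs) <= 25) && !any(duplicated(scores$score))
  wt <- suppressWarnings(
    wilcox.test(xs[[1]], xs[[2]], exact = exact, correct = !exact)
  )
  tibble(group1 = levels(g)[1], group2 = levels(g)[2],
         n1 = lengths(xs)[[1]], n2 = lengths(xs)[[2]],
         median1 = median(xs[[1]]), median2 = median(xs[[2]]),
         W = unname(wt$statistic), p_value = wt$p.value)
}

#' Consensus MAIT signature across tissue-by-cancer strata
#'
#' Within every stratum (cancer x tissue), a gene qualifies iff it is
#' significantly *higher* in MAIT cells than in each comparator subset
#' present (pairwise moderated t-test; BH-adjusted p < `p_threshold` and
#' fold-change >= `fc_threshold`). The consensus signature is the strict
#' intersection of the qualifying sets across all strata, so adding a
#' stratum can only shrink or preserve it.
#'
#' Tissue strata with fewer than `merge_threshold` MAIT cells are merged
#' into the same cancer's tumor stratum before testing (low-power strata
#' carry too few MAIT cells to test on their own); a stratum with no MAIT
#' cells at all is an error.
#'
#' @param x An [expr_matrix()] with a `normexpr` layer covering all cells.
#' @param annotations Per-cell annotations with `subset`, `tissue` and a
#'   cancer column.
#' @param cancer_col Name of the annotation column holding the cancer label
#'   (default `"cancer"`).
#' @param comparators Subsets MAIT cells are tested against (default CD8,
#'   CD4, Treg; only those present in a stratum are used, and at least one
#'   must be).
#' @param p_threshold,fc_threshold Qualification cutoffs (defaults 0.1 and
#'   1.5).
#' @param merge_threshold Minimum MAIT cells per tissue stratum before
#'   merging into the cancer's tumor stratum (default 20).
#' @param trend Trended prior in the moderated fits (default `TRUE`).
#' @return A [signature_def()] (provenance `"derived"`) with attributes
#'   `"per_stratum"` (named list of qualifying gene sets) and `"n_strata"`
#'   (number of intersected sets).
#' @export
derive_consensus_signature <- function(x, annotations, cancer_col = "cancer",
                                       comparators = c("CD8", "CD4", "Treg"),
                                       p_threshold = 0.1, fc_threshold = 1.5,
                                       merge_threshold = 20, trend = TRUE) {
  ann <- as_tibble(annotations)
  if (!cancer_col %in% names(ann)) {
    abort(sprintf("Column '%s' not found in annotations.", cancer_col))
  }
  m <- get_layer(x, "normexpr")
  ann <- dplyr::filter(ann, .data$subset %in% c("MAIT", comparators))
  ann$.cancer <- ann[[cancer_col]]

  # Merge low-MAIT tissue strata into the cancer's tumor stratum.
  mait_n <- ann |>
    dplyr::filter(.data$subset == "MAIT") |>
    count(.data$.cancer, .data$tissue, name = "n_mait")
  strata0 <- dplyr::distinct(ann, .data$.cancer, .data$tissue) |>
    left_join(mait_n, by = c(".cancer", "tissue")) |>
    mutate(n_mait = tidyr::replace_na(.data$n_mait, 0L))
  if (any(strata0$n_mait == 0)) {
    bad <- strata0[strata0$n_mait == 0, ]
    abort(sprintf("Stratum without MAIT cells: %s",
                  paste(bad$.cancer, bad$tissue, sep = "/", collapse = ", ")))
  }
  strata0$merged_tissue <- ifelse(strata0$n_mait < merge_threshold,
                                  "tumor", strata0$tissue)
  ann <- left_join(ann, select(strata0, ".cancer", "tissue", "merged_tissue"),
                   by = c(".cancer", "tissue"))

  strata <- dplyr::distinct(ann, .data$.cancer, .data$merged_tissue)
  per_stratum <- purrr::pmap(strata, function(.cancer, merged_tissue) {
    cells <- ann$cell_id[ann$.cancer == .cancer &
                           ann$merged_tissue == merged_tissue]
    sub_ann <- ann[match(cells, ann$cell_id), ]
    present <- intersect(comparators, unique(sub_ann$subset))
    if (!length(present)) {
      abort(sprintf("Stratum %s/%s has no comparator subset.",
                    .cancer, merged_tissue))
    }
    fit <- moderated_fit(m[, cells, drop = FALSE], sub_ann$subset, trend = trend)
    sets <- lapply(present, function(cmp) {
      res <- moderated_t_test(fit, c("MAIT", cmp))
      res$gene[res$adj_p_value < p_threshold &
                 res$log2_fc >= log2(fc_threshold)]
    })
    Reduce(intersect, sets)
  })
  names(per_stratum) <- paste(strata$.cancer, strata$merged_tissue, sep = "/")
  consensus <- Reduce(intersect, per_stratum)
  if (!length(consensus)) {
    warn("No gene qualifies in every stratum; the consensus signature is empty.")
    out <- structure(list(name = "consensus_mait", genes = character(),
                          provenance = "derived"), class = "signature_def")
  } else {
    out <- signature_def("consensus_mait", consensus, provenance = "derived")
  }
  attr(out, "per_stratum") <- per_stratum
  attr(out, "n_strata") <- length(per_stratum)
  out
}

#' Gene-by-subset marker specificity table
#'
#' Tests each signature gene for elevated expression in a reference subset
#' relative to every other subset (one moderated t-test per gene x
#' comparator pair), the bookkeeping used when validating a signature
#' against sorted lymphocyte populations — e.g. 11 genes x 6 comparator
#' cell types = 66 comparisons.
#'
#' @param x An [expr_matrix()] with a `normexpr` layer.
#' @param annotations Per-cell/sample annotations with `subset` labels (any
#'   character labels allowed here).
#' @param signature Genes to test.
#' @param reference Reference subset (default `"MAIT"`).
#' @param trend Trended prior (default `TRUE`).
#' @return A tibble with one row per gene x comparator subset: `log2_fc`,
#'   `t`, `p_value`, and `higher_in_reference` (p < 0.05 and positive
#'   fold-change).
#' @export
marker_specificity <- function(x, annotations, signature,
                               reference = "MAIT", trend = TRUE) {
  ann <- as_tibble(annotations)
  m <- get_layer(x, "normexpr")
  sig <- as_signature(signature)
  present <- intersect(sig$genes, rownames(m))
  if (!length(present)) abort("No signature gene present in the matrix.")
  groups <- ann$subset[match(colnames(m), ann$cell_id)]
  fit <- moderated_fit(m, groups, trend = trend)
  others <- setdiff(unique(groups), reference)
  purrr::map_dfr(others, function(cmp) {
    res <- moderated_t_test(fit, c(reference, cmp), genes = present)
    mutate(res, comparator = cmp,
           higher_in_reference = .data$p_value < 0.05 & .data$log2_fc > 0)
  }) |>
    select("gene", "comparator", "log2_fc", "t", "p_value",
           "higher_in_reference")
}
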