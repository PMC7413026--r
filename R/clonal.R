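#' Tissue preference as observed/expected ratios
#'
#' For each patient, cross-tabulates cells by tissue and subset and
#' computes, per cell of the table, the ratio of the observed count to the
#' expected count under independence (row total x column total / grand
#' total) — the chi-square expected value. A ratio above 1 marks
#' enrichment of a subset in a tissue; proportional margins give ratios of
#' exactly 1 everywhere.
#'
#' Patients sampled in a single tissue carry no distributional information
#' and are excluded with a warning.
#'
#' @param annotations Per-cell annotations with `patient_id`, `subset` and
#'   the grouping column.
#' @param group_by Column crossing `subset` in the contingency table
#'   (default `"tissue"`; use `"treatment"` for pre/post designs).
#' @return A tibble with `patient_id`, the grouping column, `subset`,
#'   `observed`, `expected` and `roe`.
#' @export
compute_roe <- function(annotations, group_by = "tissue") {
  ann <- as_tibble(annotations)
  if (!group_by %in% names(ann)) abort(sprintf("Column '%s' not found.", group_by))
  counts <- ann |>
    count(.data$patient_id, .group = .data[[group_by]], .data$subset,
          name = "observed")
  ok_patients <- counts |>
    group_by(.data$patient_id) |>
    summarise(n_levels = dplyr::n_distinct(.data$.group), .groups = "drop")
  excluded <- ok_patients$patient_id[ok_patients$n_levels < 2]
  if (length(excluded)) {
    warn(sprintf("Excluding patient(s) with a single '%s' level: %s",
                 group_by, paste(excluded, collapse = ", ")))
  }
  counts <- dplyr::filter(counts, !.data$patient_id %in% excluded)
  out <- counts |>
    tidyr::complete(.data$patient_id, .data$.group, .data$subset,
                    fill = list(observed = 0L)) |>
    group_by(.data$patient_id) |>
    mutate(expected = {
      tot <- sum(.data$observed)
      row_tot <- stats::ave(.data$observed, .data$.group, FUN = sum)
      col_tot <- stats::ave(.data$observed, .data$subset, FUN = sum)
      row_tot * col_tot / tot
    }) |>
    ungroup() |>
    # cells from tissues/subsets a patient was never sampled in stay out
    dplyr::filter(.data$expected > 0) |>
    mutate(roe = .data$observed / .data$expected)
  names(out)[names(out) == ".group"] <- group_by
  out
}

#' Compare per-patient observed/expected ratios between two groups
#'
#' Two-sided unpaired Welch t-test on per-patient ratios of one subset
#' between two levels of the grouping column (e.g. tumor vs normal).
#'
#' @param roe Output of [compute_roe()].
#' @param subset Subset whose ratios are compared (default `"MAIT"`).
#' @param levels Length-2 character vector of group levels; defaults to the
#'   first two present.
#' @param group_by Name of the grouping column in `roe`.
#' @param var_equal Assume equal variances (default `FALSE`, Welch).
#' @return A one-row tibble with group means, t statistic, df and p value.
#' @export
compare_roe <- function(roe, subset = "MAIT", levels = NULL,
                        group_by = "tissue", var_equal = FALSE) {
  df <- dplyr::filter(as_tibble(roe), .data$subset == !!subset)
  levels <- levels %||% utils::head(unique(df[[group_by]]), 2)
  if (length(levels) != 2) abort("`levels` must name exactly two groups.")
  x <- df$roe[df[[group_by]] == levels[1]]
  y <- df$roe[df[[group_by]] == levels[2]]
  if (length(x) < 2 || length(y) < 2) {
    abort("Need at least two patients per group for a t-test.")
  }
  tt <- t.test(x, y, var.equal = var_equal)
  tibble(subset = subset, group1 = levels[1], group2 = levels[2],
         mean1 = mean(x), mean2 = mean(y), n1 = length(x), n2 = length(y),
         statistic = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value)
}

#' Clonotype sharing across tissue compartments
#'
#' Assigns every clonal clonotype (>= 2 cells) the exact set of tissues its
#' member cells occupy, encoded as a combination label over B(lood),
#' N(ormal) and T(umor) — e.g. `"BNT"` for clones spanning all three.
#' Non-clonal (singleton) clonotypes are tallied separately per tissue.
#'
#' @param clonotypes Clonotype table from [build_clonotypes()].
#' @param annotations Per-cell annotations with `tissue`.
#' @param group_vars Optional annotation columns (e.g. a cancer label) to
#'   stratify by.
#' @return A tibble with the grouping columns plus `combination`, `clonal`,
#'   `n_clonotypes` and `mean_cells_per_clonotype`.
#' @export
summarize_sharing <- function(clonotypes, annotations, group_vars = NULL) {
  ann <- as_tibble(annotations)
  initials <- c(blood = "B", normal = "N", tumor = "T")
  members <- clonotype_members(clonotypes) |>
    left_join(ann[, c("cell_id", "tissue", group_vars)], by = "cell_id")
  if (any(is.na(members$tissue))) abort("Some clonotype members lack tissue annotations.")
  members |>
    group_by(across(dplyr::all_of(c(group_vars, "clonotype_id")))) |>
    summarise(
      combination = paste(initials[sort(unique(.data$tissue))], collapse = ""),
      n_cells = dplyr::n(), .groups = "drop"
    ) |>
    mutate(clonal = .data$n_cells >= 2) |>
    group_by(across(dplyr::all_of(c(group_vars, "clonal", "combination")))) |>
    summarise(n_clonotypes = dplyr::n(),
              mean_cells_per_clonotype = mean(.data$n_cells),
              .groups = "drop") |>
    arrange(dplyr::desc(.data$clonal), .data$combination)
}

#' Pre/post-treatment clone dynamics
#'
#' For each patient with at least `min_cells` clonotype-member cells in both
#' pre- and post-treatment samples, tests every clonotype for a significant
#' change in its proportion with a two-sided Fisher exact test on the 2x2
#' table `[[pre_count, pre_total - pre_count], [post_count, post_total -
#' post_count]]`, adjusts p values by Benjamini-Hochberg within patient,
#' and assigns a fate: `pre_only` / `post_only` for clones seen on one side
#' only, `expanded` / `depleted` for significant proportional increases /
#' decreases (q < `alpha`), and `stable` otherwise.
#'
#' @param clonotypes Clonotype table from [build_clonotypes()].
#' @param annotations Per-cell annotations with `patient_id` and
#'   `treatment` (`"pre"`/`"post"`).
#' @param alpha FDR threshold for the expanded/depleted calls (default
#'   0.05).
#' @param min_cells Minimum pre and post totals per patient (default 10);
#'   patients under the bar are skipped with a warning.
#' @return A tibble with `patient_id`, `clonotype_id`, `pre_count`,
#'   `post_count`, `pre_total`, `post_total`, `p_value`, `q_value`, `fate`.
#' @export
classify_clone_dynamics <- function(clonotypes, annotations,
                                    alpha = 0.05, min_cells = 10) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must lie in (0, 1).")
  }
  ann <- as_tibble(annotations)
  members <- clonotype_members(clonotypes) |>
    left_join(ann[, c("cell_id", "patient_id", "treatment")], by = "cell_id") |>
    dplyr::filter(.data$treatment %in% c("pre", "post"))
  if (!nrow(members)) return(tibble())
  totals <- members |>
    count(.data$patient_id, .data$treatment) |>
    tidyr::pivot_wider(names_from = "treatment", values_from = "n",
                       values_fill = 0L)
  for (col in c("pre", "post")) if (!col %in% names(totals)) totals[[col]] <- 0L
  skipped <- totals$patient_id[totals$pre < min_cells | totals$post < min_cells]
  if (length(skipped)) {
    warn(sprintf("Skipping patient(s) with < %d cells pre or post: %s",
                 min_cells, paste(skipped, collapse = ", ")))
  }
  counts <- members |>
    dplyr::filter(!.data$patient_id %in% skipped) |>
    count(.data$patient_id, .data$clonotype_id, .data$treatment) |>
    tidyr::pivot_wider(names_from = "treatment", values_from = "n",
                       values_fill = 0L)
  for (col in c("pre", "post")) if (!col %in% names(counts)) counts[[col]] <- 0L
  if (!nrow(counts)) return(tibble())
  counts |>
    rename(pre_count = "pre", post_count = "post") |>
    left_join(select(totals, "patient_id", pre_total = "pre", post_total = "post"),
              by = "patient_id") |>
    mutate(p_value = purrr::pmap_dbl(
      list(.data$pre_count, .data$post_count, .data$pre_total, .data$post_total),
      function(a, b, nt, mt) {
        fisher.test(matrix(c(a, nt - a, b, mt - b), nrow = 2,
                           byrow = TRUE))$p.value
      })) |>
    group_by(.data$patient_id) |>
    mutate(q_value = p.adjust(.data$p_value, method = "BH")) |>
    ungroup() |>
    mutate(fate = dplyr::case_when(
      .data$post_count == 0 & .data$pre_count > 0 ~ "pre_only",
      .data$pre_count == 0 & .data$post_count > 0 ~ "post_only",
      .data$q_value < alpha &
        .data$post_count / .data$post_total >
        .data$pre_count / .data$pre_total ~ "expanded",
      .data$q_value < alpha &
        .data$post_count / .data$post_total <
        .data$pre_count / .data$pre_total ~ "depleted",
      TRUE ~ "stable"
    )) |>
    arrange(.data$patient_id, dplyr::desc(.data$pre_count + .data$post_count))
}
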