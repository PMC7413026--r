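#' @importFrom ggplot2 ggplot aes geom_point geom_col geom_boxplot
#'   geom_hline geom_step facet_wrap labs theme_bw scale_y_log10 autoplot
#'   geom_jitter position_dodge geom_abline
NULL

#' @export
ggplot2::autoplot

#' Plot per-patient tissue-preference ratios
#'
#' Dot plot of observed/expected ratios per patient, faceted by subset,
#' with the neutral line at 1.
#'
#' @param roe Output of [compute_roe()].
#' @param subsets Subsets to show (default `"MAIT"`).
#' @param group_by Grouping column used in [compute_roe()].
#' @return A ggplot object.
#' @export
plot_roe <- function(roe, subsets = "MAIT", group_by = "tissue") {
  df <- dplyr::filter(as_tibble(roe), .data$subset %in% subsets)
  ggplot(df, aes(x = .data[[group_by]], y = .data$roe)) +
    geom_jitter(width = 0.1, height = 0, alpha = 0.7) +
    geom_hline(yintercept = 1, linetype = "dashed") +
    facet_wrap(~subset) +
    labs(x = NULL, y = "observed / expected cells") +
    theme_bw()
}

#' Volcano plot of differential-expression results
#'
#' @param deg A tibble from [hierarchical_deg()] or [moderated_t_test()].
#' @param fc_threshold,p_threshold Guide lines (defaults 1.5 and 0.05 on
#'   the adjusted p).
#' @return A ggplot object.
#' @export
plot_volcano <- function(deg, fc_threshold = 1.5, p_threshold = 0.05) {
  df <- as_tibble(deg) |>
    mutate(status = dplyr::case_when(
      .data$adj_p_value < p_threshold &
        abs(.data$log2_fc) >= log2(fc_threshold) ~ "significant",
      .data$adj_p_value < 2 * p_threshold ~ "borderline",
      TRUE ~ "ns"
    ))
  ggplot(df, aes(x = .data$log2_fc, y = -log10(.data$p_value),
                 colour = .data$status)) +
    geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(values = c(significant = "red3",
                                            borderline = "salmon",
                                            ns = "grey60")) +
    facet_wrap(~contrast) +
    labs(x = "log2 fold-change", y = "-log10 p") +
    theme_bw()
}

#' Bar plot of TRAJ / TRBV segment usage
#'
#' @param usage Output of [vj_usage()].
#' @param group_by Stratum column to facet by (default `"tissue"`).
#' @return A ggplot object.
#' @export
plot_vj_usage <- function(usage, group_by = "tissue") {
  ggplot(as_tibble(usage),
         aes(x = .data$segment, y = .data$freq, fill = .data[[group_by]])) +
    geom_col(position = position_dodge(preserve = "single")) +
    facet_wrap(~segment_class, scales = "free_x") +
    labs(x = NULL, y = "frequency among MAIT cells") +
    theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Clone-dynamics scatter (pre vs post proportions)
#'
#' @param dynamics Output of [classify_clone_dynamics()].
#' @return A ggplot object with clones coloured by fate on log-scaled
#'   per-mille proportions.
#' @export
plot_clone_dynamics <- function(dynamics) {
  df <- as_tibble(dynamics) |>
    mutate(pre_prop = (.data$pre_count + 0.5) / .data$pre_total,
           post_prop = (.data$post_count + 0.5) / .data$post_total)
  ggplot(df, aes(x = .data$pre_prop, y = .data$post_prop,
                 colour = .data$fate, shape = .data$patient_id)) +
    geom_point(size = 2, alpha = 0.8) +
    geom_abline(linetype = "dashed", colour = "grey50") +
    scale_y_log10() + ggplot2::scale_x_log10() +
    labs(x = "pre-treatment proportion", y = "post-treatment proportion") +
    theme_bw()
}

#' @describeIn evaluate_scores Scatter of signature score against the true
#'   MAIT fraction of each pseudo-bulk sample.
#' @param object A `pseudobulk_set`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.pseudobulk_set <- function(object, ...) {
  ggplot(object$samples, aes(x = .data$frac_MAIT, y = .data$mait_score)) +
    geom_point(alpha = 0.6) +
    labs(x = "true MAIT fraction", y = "MAIT signature score") +
    theme_bw()
}

#' @describeIn survival_test Kaplan-Meier curves for the low/high score
#'   strata.
#' @param object A `mait_survfit`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.mait_survfit <- function(object, ...) {
  km <- object$km
  df <- tibble(
    time = km$time,
    surv = km$surv,
    group = rep(sub("^group=", "", names(km$strata)), km$strata)
  )
  df0 <- tibble(time = 0, surv = 1, group = unique(df$group))
  ggplot(bind_rows(df0, df), aes(x = .data$time, y = .data$surv,
                                 colour = .data$group)) +
    geom_step() +
    labs(x = "time (days)", y = "survival probability",
         subtitle = sprintf("log-rank p = %.3g", object$summary$logrank_p)) +
    theme_bw()
}
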