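mait_j_segments <- c("TRAJ33", "TRAJ12", "TRAJ20")

# Defining chain per cell and locus: the lexicographically smallest
# (v_gene, j_gene, cdr3_nt) among that cell's productive chains.
# Deterministic tie-break for cells expressing multiple chains.
defining_chains <- function(contigs) {
  contigs |>
    dplyr::filter(.data$productive) |>
    mutate(v_gene = strip_allele(.data$v_gene),
           j_gene = strip_allele(.data$j_gene)) |>
    arrange(.data$cell_id, .data$locus, .data$v_gene, .data$j_gene, .data$cdr3_nt) |>
    dplyr::distinct(.data$cell_id, .data$locus, .keep_all = TRUE)
}

#' Classify MAIT cells from TCR contigs
#'
#' A cell is analysis-eligible if it has at least one productive TRA and one
#' productive TRB chain. An eligible cell is called MAIT iff any of its
#' productive TRA chains uses TRAV1-2 joined to TRAJ33, TRAJ12 or TRAJ20 —
#' the canonical semi-invariant MAIT TCR alpha chain. All other eligible
#' cells keep their annotated subset (or `"unassigned"`).
#'
#' Allele suffixes (`*01`) are stripped before segment comparison. The
#' classification is deterministic and independent of row order.
#'
#' @param contigs Contig data frame (see [read_tcr_contigs()]).
#' @param annotations Optional per-cell annotations supplying non-MAIT
#'   subset labels.
#' @return A tibble with columns `cell_id`, `eligible`, `mait`, `subset`.
#'   Ineligible cells are flagged `eligible = FALSE` and `subset =
#'   "unassigned"`; they should be excluded from downstream repertoire
#'   analyses.
#' @export
classify_mait <- function(contigs, annotations = NULL) {
  contigs <- validate_contigs(contigs)
  per_cell <- contigs |>
    group_by(.data$cell_id) |>
    summarise(
      has_tra = any(.data$productive & .data$locus == "TRA"),
      has_trb = any(.data$productive & .data$locus == "TRB"),
      mait = any(.data$productive & .data$locus == "TRA" &
                   strip_allele(.data$v_gene) == "TRAV1-2" &
                   strip_allele(.data$j_gene) %in% mait_j_segments),
      .groups = "drop"
    ) |>
    mutate(eligible = .data$has_tra & .data$has_trb,
           mait = .data$mait & .data$eligible) |>
    select("cell_id", "eligible", "mait")
  if (!is.null(annotations)) {
    ann <- as_tibble(annotations) |> select("cell_id", annotated = "subset")
    per_cell <- left_join(per_cell, ann, by = "cell_id")
  } else {
    per_cell$annotated <- NA_character_
  }
  per_cell |>
    mutate(subset = dplyr::case_when(
      !.data$eligible ~ "unassigned",
      .data$mait ~ "MAIT",
      is.na(.data$annotated) ~ "unassigned",
      TRUE ~ .data$annotated
    )) |>
    select("cell_id", "eligible", "mait", "subset") |>
    arrange(.data$cell_id)
}

#' Build clonotypes from TCR contigs
#'
#' Two grouping modes are supported:
#' \describe{
#'   \item{`"exact_pair"`}{Cells share a clonotype iff their defining
#'     (alpha, beta) chain pairs — V gene, J gene and CDR3 nucleotide
#'     sequence — are identical. For cells with multiple productive chains
#'     the lexicographically smallest chain per locus defines the pair.}
#'   \item{`"shared_chain"`}{Cells are merged (transitively) whenever they
#'     share at least one productive TRA and at least one productive TRB
#'     CDR3 nucleotide sequence each.}
#' }
#' `exact_pair` refines `shared_chain`: every exact-pair clone lies inside
#' one shared-chain clone. Only eligible cells (productive alpha-beta pair)
#' are clustered. A clonotype is "clonal" iff it has at least two members.
#'
#' @param contigs Contig data frame.
#' @param mode `"exact_pair"` (default) or `"shared_chain"`.
#' @return A tibble with one row per clonotype: `clonotype_id`, defining
#'   alpha/beta fields (`alpha_v`, `alpha_j`, `alpha_cdr3_nt`, `beta_v`,
#'   `beta_j`, `beta_cdr3_nt`), `n_cells`, `clonal`, and a `cell_ids`
#'   list-column.
#' @export
build_clonotypes <- function(contigs, mode = c("exact_pair", "shared_chain")) {
  mode <- match.arg(mode)
  contigs <- validate_contigs(contigs)
  flags <- classify_mait(contigs)
  eligible <- flags$cell_id[flags$eligible]
  if (!length(eligible)) {
    return(tibble(clonotype_id = character(), alpha_v = character(),
                  alpha_j = character(), alpha_cdr3_nt = character(),
                  beta_v = character(), beta_j = character(),
                  beta_cdr3_nt = character(), n_cells = integer(),
                  clonal = logical(), cell_ids = list()))
  }
  def <- defining_chains(dplyr::filter(contigs, .data$cell_id %in% eligible)) |>
    tidyr::pivot_wider(
      id_cols = "cell_id", names_from = "locus",
      values_from = c("v_gene", "j_gene", "cdr3_nt")
    ) |>
    rename(alpha_v = "v_gene_TRA", alpha_j = "j_gene_TRA",
           alpha_cdr3_nt = "cdr3_nt_TRA", beta_v = "v_gene_TRB",
           beta_j = "j_gene_TRB", beta_cdr3_nt = "cdr3_nt_TRB")

  if (mode == "exact_pair") {
    membership <- def |>
      group_by(.data$alpha_v, .data$alpha_j, .data$alpha_cdr3_nt,
               .data$beta_v, .data$beta_j, .data$beta_cdr3_nt) |>
      mutate(.grp = dplyr::cur_group_id()) |>
      ungroup()
  } else {
    prod <- dplyr::filter(contigs, .data$cell_id %in% eligible, .data$productive)
    pair_edges <- function(locus) {
      chains <- prod |>
        dplyr::filter(.data$locus == !!locus) |>
        dplyr::distinct(.data$cell_id, .data$cdr3_nt)
      inner_join(chains, chains, by = "cdr3_nt",
                 relationship = "many-to-many") |>
        dplyr::filter(.data$cell_id.x < .data$cell_id.y) |>
        dplyr::distinct(.data$cell_id.x, .data$cell_id.y)
    }
    edges <- inner_join(pair_edges("TRA"), pair_edges("TRB"),
                        by = c("cell_id.x", "cell_id.y"))
    g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = data.frame(name = eligible))
    comp <- igraph::components(g)$membership
    membership <- def |> mutate(.grp = unname(comp[.data$cell_id]))
  }

  membership |>
    group_by(.data$.grp) |>
    summarise(
      alpha_v = .data$alpha_v[order(.data$alpha_cdr3_nt)[1]],
      alpha_j = .data$alpha_j[order(.data$alpha_cdr3_nt)[1]],
      alpha_cdr3_nt = min(.data$alpha_cdr3_nt),
      beta_v = .data$beta_v[order(.data$beta_cdr3_nt)[1]],
      beta_j = .data$beta_j[order(.data$beta_cdr3_nt)[1]],
      beta_cdr3_nt = min(.data$beta_cdr3_nt),
      n_cells = dplyr::n(), cell_ids = list(sort(.data$cell_id)),
      .groups = "drop"
    ) |>
    arrange(dplyr::desc(.data$n_cells), .data$alpha_cdr3_nt, .data$beta_cdr3_nt) |>
    mutate(clonotype_id = sprintf("clone_%04d", dplyr::row_number()),
           clonal = .data$n_cells >= 2L) |>
    select("clonotype_id", "alpha_v", "alpha_j", "alpha_cdr3_nt",
           "beta_v", "beta_j", "beta_cdr3_nt", "n_cells", "clonal", "cell_ids")
}

# Long (cell_id, clonotype_id) mapping from a clonotype table.
clonotype_members <- function(clonotypes) {
  tidyr::unnest(select(clonotypes, "clonotype_id", "cell_ids"),
                cols = "cell_ids") |>
    rename(cell_id = "cell_ids")
}

#' Summarize TRAJ and TRBV segment usage of MAIT cells
#'
#' Counts each MAIT cell once, using its defining alpha chain's J segment
#' and defining beta chain's V segment, within strata defined by annotation
#' columns (default: tissue). Frequencies sum to one per stratum and
#' segment class.
#'
#' @param contigs Contig data frame.
#' @param annotations Per-cell annotations providing the stratifying
#'   columns.
#' @param group_vars Character vector of annotation columns defining the
#'   strata (default `"tissue"`).
#' @return A tibble with the stratum columns plus `segment_class`
#'   (`"TRAJ"`/`"TRBV"`), `segment`, `n` and `freq`.
#' @export
vj_usage <- function(contigs, annotations, group_vars = "tissue") {
  contigs <- validate_contigs(contigs)
  flags <- classify_mait(contigs, annotations)
  mait_cells <- flags$cell_id[flags$mait]
  ann <- as_tibble(annotations)
  strata_all <- dplyr::distinct(ann[, group_vars, drop = FALSE])
  if (!length(mait_cells)) {
    warn("No MAIT cells; returning an empty usage table.")
    return(tibble())
  }
  # The MAIT-defining alpha chain (TRAV1-2) supplies the J segment; the
  # defining beta chain supplies the V segment.
  prod <- dplyr::filter(contigs, .data$cell_id %in% mait_cells, .data$productive) |>
    mutate(v_gene = strip_allele(.data$v_gene), j_gene = strip_allele(.data$j_gene))
  alpha <- prod |>
    dplyr::filter(.data$locus == "TRA", .data$v_gene == "TRAV1-2",
                  .data$j_gene %in% mait_j_segments) |>
    arrange(.data$cell_id, .data$j_gene, .data$cdr3_nt) |>
    dplyr::distinct(.data$cell_id, .keep_all = TRUE) |>
    mutate(segment_class = "TRAJ", segment = .data$j_gene)
  beta <- defining_chains(prod) |>
    dplyr::filter(.data$locus == "TRB") |>
    mutate(segment_class = "TRBV", segment = .data$v_gene)
  usage <- bind_rows(select(alpha, "cell_id", "segment_class", "segment"),
                     select(beta, "cell_id", "segment_class", "segment")) |>
    left_join(ann[, c("cell_id", group_vars)], by = "cell_id") |>
    group_by(across(dplyr::all_of(c(group_vars, "segment_class", "segment")))) |>
    summarise(n = dplyr::n(), .groups = "drop_last") |>
    mutate(freq = .data$n / sum(.data$n)) |>
    ungroup()
  covered <- dplyr::distinct(usage[, group_vars, drop = FALSE])
  n_missing <- nrow(dplyr::anti_join(strata_all, covered, by = group_vars))
  if (n_missing > 0) {
    warn(sprintf("%d stratum/strata contain no MAIT cells and are omitted.", n_missing))
  }
  usage
}
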