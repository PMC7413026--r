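#' Quality-control filtering of cells
#'
#' Removes cells whose library size, detected-gene count or mitochondrial
#' fraction falls outside the given bounds. Following the usual droplet
#' conventions, a cell is kept iff
#' `min_umi <= UMI <= max_umi`, `min_genes <= genes <= max_genes` and
#' `mito fraction <= max_mito_frac`; i.e. "< 1200 UMI" removes cells
#' strictly below 1200.
#'
#' @param x An [expr_matrix()] with a counts layer.
#' @param annotations Per-cell annotation data frame (subset along with the
#'   cells); optional.
#' @param min_umi,max_umi Library-size bounds (total counts per cell).
#' @param min_genes,max_genes Bounds on the number of genes with count > 0.
#' @param max_mito_frac Maximum tolerated fraction of counts from
#'   mitochondrial genes.
#' @param mito_prefix Gene-symbol prefix identifying mitochondrial genes.
#' @return A list with elements `matrix` (filtered `expr_matrix`),
#'   `annotations` (filtered tibble or `NULL`) and `removed` (tibble of
#'   dropped cells with per-cell QC metrics).
#' @export
qc_filter_cells <- function(x, annotations = NULL,
                            min_umi = 1200, max_umi = 25000,
                            min_genes = 600, max_genes = 4000,
                            max_mito_frac = 0.10, mito_prefix = "MT-") {
  counts <- get_layer(x, "counts")
  if (min_umi > max_umi) abort("`min_umi` exceeds `max_umi`.")
  if (min_genes > max_genes) abort("`min_genes` exceeds `max_genes`.")
  assert_prob(max_mito_frac, "max_mito_frac")

  libsize <- colSums(counts)
  ngenes <- colSums(counts > 0)
  mito <- startsWith(rownames(counts), mito_prefix)
  mito_frac <- if (any(mito)) {
    colSums(counts[mito, , drop = FALSE]) / pmax(libsize, 1)
  } else rep(0, ncol(counts))

  keep <- libsize >= min_umi & libsize <= max_umi &
    ngenes >= min_genes & ngenes <= max_genes &
    mito_frac <= max_mito_frac

  metrics <- tibble(
    cell_id = colnames(counts), total_umi = unname(libsize),
    n_genes = unname(ngenes), mito_frac = unname(mito_frac),
    kept = unname(keep)
  )
  kept_cells <- colnames(counts)[keep]
  out_ann <- NULL
  if (!is.null(annotations)) {
    out_ann <- dplyr::filter(as_tibble(annotations), .data$cell_id %in% kept_cells)
  }
  list(
    matrix = subset_expr(x, cells = kept_cells),
    annotations = out_ann,
    removed = dplyr::filter(metrics, !.data$kept)
  )
}

#' Remove genes with low average count
#'
#' @param x An [expr_matrix()] with a counts layer.
#' @param min_mean_count Keep genes whose mean count across cells is at
#'   least this value (default 0.01).
#' @return A filtered `expr_matrix`.
#' @export
filter_low_genes <- function(x, min_mean_count = 0.01) {
  counts <- get_layer(x, "counts")
  keep <- rowMeans(counts) >= min_mean_count
  if (!any(keep)) {
    warn("No gene passes the mean-count filter; returning an empty matrix.")
  }
  take <- function(m) if (is.null(m)) NULL else m[keep, , drop = FALSE]
  out <- x
  out$counts <- take(x$counts)
  out$normexpr <- take(x$normexpr)
  out$gene_ids <- x$gene_ids[keep]
  out
}

#' Library-size normalization to log2(CPM + 1)
#'
#' Each gene's count is divided by the cell's library size, multiplied by
#' 1e6, incremented by one, and log2-transformed — an expression measure
#' analogous to log2(TPM + 1) for UMI data (no gene-length correction).
#'
#' @param x An [expr_matrix()] with a counts layer, or a genes x cells
#'   counts matrix.
#' @return For an `expr_matrix`, the same object with the `normexpr` layer
#'   populated; for a bare matrix, the normalized matrix.
#' @export
normalize_log_cpm <- function(x) {
  counts <- if (inherits(x, "expr_matrix")) get_layer(x, "counts") else as.matrix(x)
  libsize <- colSums(counts)
  if (any(libsize == 0)) {
    abort(sprintf("Zero library size for cell(s): %s",
                  paste(colnames(counts)[libsize == 0], collapse = ", ")))
  }
  norm <- log2(sweep(counts, 2, libsize, "/") * 1e6 + 1)
  if (inherits(x, "expr_matrix")) {
    x$normexpr <- norm
    x
  } else {
    norm
  }
}
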