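#' Read an expression matrix from disk
#'
#' Two plain-text layouts are supported:
#' \describe{
#'   \item{`"tsv"`}{Dense TSV/CSV with genes as rows, cells as columns, and
#'     gene symbols in the first column.}
#'   \item{`"mtx"`}{MatrixMarket triplet file plus two single-column sidecar
#'     files listing gene symbols and cell ids (in matrix order).}
#' }
#'
#' @param path Path to the TSV/CSV file, or to the `.mtx` file.
#' @param format `"tsv"` or `"mtx"`.
#' @param layer Which layer the file holds: `"counts"` or `"normexpr"`.
#' @param genes_path,cells_path Sidecar paths (mtx only); default to
#'   `<path>.genes.txt` / `<path>.cells.txt` next to the matrix.
#' @return An [expr_matrix()].
#' @export
read_expression <- function(path, format = c("tsv", "mtx"),
                            layer = c("counts", "normexpr"),
                            genes_path = NULL, cells_path = NULL) {
  format <- match.arg(format)
  layer <- match.arg(layer)
  if (format == "tsv") {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE,
                            sep = if (grepl("\\.csv$", path)) "," else "\t")
    if (ncol(df) < 2) abort(sprintf("'%s': expected a gene column plus >=1 cell column.", path))
    genes <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(m)) {
      bad <- which(!apply(df[, -1, drop = FALSE], 2, is.numeric))[1]
      abort(sprintf("'%s': non-numeric values in column %d.", path, bad + 1L))
    }
    rownames(m) <- genes
  } else {
    genes_path <- genes_path %||% paste0(path, ".genes.txt")
    cells_path <- cells_path %||% paste0(path, ".cells.txt")
    sp <- Matrix::readMM(path)
    genes <- readLines(genes_path)
    cells <- readLines(cells_path)
    if (nrow(sp) != length(genes) || ncol(sp) != length(cells)) {
      abort(sprintf(
        "'%s': matrix is %d x %d but sidecars list %d genes and %d cells.",
        path, nrow(sp), ncol(sp), length(genes), length(cells)))
    }
    m <- as.matrix(sp)
    dimnames(m) <- list(genes, cells)
  }
  if (layer == "counts") expr_matrix(counts = m) else expr_matrix(normexpr = m)
}

#' Write an expression matrix to disk
#'
#' @param x An [expr_matrix()].
#' @param path Output path (`.tsv` or `.mtx`).
#' @inheritParams read_expression
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, format = c("tsv", "mtx"),
                             layer = c("counts", "normexpr")) {
  format <- match.arg(format)
  layer <- match.arg(layer)
  m <- get_layer(x, layer)
  if (format == "tsv") {
    df <- data.frame(gene = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE, doDiag = FALSE), path)
    writeLines(rownames(m), paste0(path, ".genes.txt"))
    writeLines(colnames(m), paste0(path, ".cells.txt"))
  }
  invisible(path)
}

tissue_levels <- c("blood", "normal", "tumor")
subset_levels <- c("MAIT", "CD8", "CD4", "Treg", "other", "unassigned")
treatment_levels <- c("pre", "post", "not_applicable")

#' Read / validate per-cell annotations
#'
#' Annotations are a TSV with header columns `cell_id`, `patient_id`,
#' `tissue` (blood/normal/tumor), `subset` (MAIT/CD8/CD4/Treg/other/
#' unassigned) and `treatment` (pre/post/not_applicable). Extra columns are
#' kept.
#'
#' @param path TSV path.
#' @return A tibble, validated by [validate_annotations()].
#' @export
read_cell_annotations <- function(path) {
  ann <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_annotations(ann)
}

#' @rdname read_cell_annotations
#' @param annotations A data frame of per-cell annotations.
#' @export
validate_annotations <- function(annotations) {
  ann <- as_tibble(annotations)
  need <- c("cell_id", "patient_id", "tissue", "subset", "treatment")
  missing <- setdiff(need, names(ann))
  if (length(missing)) abort(sprintf("Annotation columns missing: %s",
                                     paste(missing, collapse = ", ")))
  if (anyDuplicated(ann$cell_id)) abort("Each cell_id must appear exactly once.")
  chk <- function(col, levels) {
    bad <- setdiff(unique(ann[[col]]), levels)
    if (length(bad)) abort(sprintf("Invalid %s value(s): %s",
                                   col, paste(bad, collapse = ", ")))
  }
  chk("tissue", tissue_levels)
  chk("subset", subset_levels)
  chk("treatment", treatment_levels)
  ann
}

#' Read TCR contig records
#'
#' Expects a TSV compatible with common `filtered_contig_annotations`
#' exports, with columns `cell_id`, `locus` (TRA/TRB), `v_gene`, `j_gene`,
#' `cdr3_nt`, `cdr3_aa`, `productive` (logical or "true"/"false").
#'
#' @param path TSV path.
#' @return A tibble of contigs (one row per chain).
#' @export
read_tcr_contigs <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_contigs(df)
}

#' @rdname read_tcr_contigs
#' @param contigs A data frame of contig records.
#' @export
validate_contigs <- function(contigs) {
  df <- as_tibble(contigs)
  need <- c("cell_id", "locus", "v_gene", "j_gene", "cdr3_nt", "productive")
  missing <- setdiff(need, names(df))
  if (length(missing)) abort(sprintf("Contig columns missing: %s",
                                     paste(missing, collapse = ", ")))
  if (!"cdr3_aa" %in% names(df)) df$cdr3_aa <- NA_character_
  if (is.character(df$productive)) {
    df$productive <- tolower(df$productive) %in% c("true", "t", "yes", "1")
  }
  bad <- setdiff(unique(df$locus), c("TRA", "TRB"))
  if (length(bad)) abort(sprintf("Invalid locus value(s): %s",
                                 paste(bad, collapse = ", ")))
  # locus must agree with the V-segment prefix when one is recorded
  vpref <- substr(strip_allele(df$v_gene), 1, 3)
  mism <- !is.na(df$v_gene) & vpref %in% c("TRA", "TRB") & vpref != df$locus
  if (any(mism)) {
    abort(sprintf("%d contig(s) have a v_gene inconsistent with their locus (e.g. %s on %s).",
                  sum(mism), df$v_gene[mism][1], df$locus[mism][1]))
  }
  df
}

#' Read / write a bulk expression + survival cohort
#'
#' A cohort couples a sample x gene log2(TPM+1) matrix with per-sample
#' survival endpoints: `os_time`, `os_event`, `pfs_time`, `pfs_event`
#' (times in days, events 0/1).
#'
#' @param expr_path TSV with `sample_id` in the first column and genes as
#'   the remaining columns.
#' @param clinical_path TSV with columns `sample_id`, `os_time`, `os_event`,
#'   `pfs_time`, `pfs_event`.
#' @return A `bulk_cohort`: list with `expr` (samples x genes matrix) and
#'   `clinical` (tibble).
#' @export
read_bulk_cohort <- function(expr_path, clinical_path) {
  edf <- utils::read.delim(expr_path, check.names = FALSE, stringsAsFactors = FALSE)
  expr <- as.matrix(edf[, -1, drop = FALSE])
  rownames(expr) <- edf[[1]]
  clinical <- readr::read_tsv(clinical_path, show_col_types = FALSE, progress = FALSE)
  bulk_cohort(expr, clinical)
}

#' @rdname read_bulk_cohort
#' @param expr Samples x genes numeric matrix (log2(TPM+1)), rownames =
#'   sample ids.
#' @param clinical Data frame of survival endpoints.
#' @export
bulk_cohort <- function(expr, clinical) {
  clinical <- as_tibble(clinical)
  need <- c("sample_id", "os_time", "os_event", "pfs_time", "pfs_event")
  missing <- setdiff(need, names(clinical))
  if (length(missing)) abort(sprintf("Clinical columns missing: %s",
                                     paste(missing, collapse = ", ")))
  if (!setequal(rownames(expr), clinical$sample_id)) {
    abort("Expression rownames and clinical sample_id must match.")
  }
  expr <- expr[clinical$sample_id, , drop = FALSE]
  if (any(!is.finite(expr))) abort("Bulk expression must be finite.")
  for (col in c("os_time", "pfs_time")) {
    if (any(clinical[[col]] < 0, na.rm = TRUE))
      abort(sprintf("`%s` must be non-negative.", col))
  }
  for (col in c("os_event", "pfs_event")) {
    if (!all(clinical[[col]] %in% c(0, 1, NA)))
      abort(sprintf("`%s` must be 0/1.", col))
  }
  structure(list(expr = expr, clinical = clinical), class = "bulk_cohort")
}

#' @export
print.bulk_cohort <- function(x, ...) {
  cat(sprintf("<bulk_cohort> %d samples x %d genes; OS events: %d; PFS events: %d\n",
              nrow(x$expr), ncol(x$expr),
              sum(x$clinical$os_event, na.rm = TRUE),
              sum(x$clinical$pfs_event, na.rm = TRUE)))
  invisible(x)
}

#' @rdname read_bulk_cohort
#' @param cohort A `bulk_cohort`.
#' @param dir Output directory.
#' @param prefix File name prefix.
#' @export
write_bulk_cohort <- function(cohort, dir, prefix = "cohort") {
  stopifnot(inherits(cohort, "bulk_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  expr_path <- file.path(dir, paste0(prefix, "_expr.tsv"))
  clin_path <- file.path(dir, paste0(prefix, "_clinical.tsv"))
  df <- data.frame(sample_id = rownames(cohort$expr), cohort$expr,
                   check.names = FALSE)
  utils::write.table(df, expr_path, sep = "\t", quote = FALSE, row.names = FALSE)
  readr::write_tsv(cohort$clinical, clin_path, progress = FALSE)
  invisible(c(expr = expr_path, clinical = clin_path))
}
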