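#' Gene-by-cell expression container
#'
#' A light container holding one or both layers of a genes x cells matrix:
#' `counts` (non-negative integers, UMI or read counts) and `normexpr`
#' (normalized expression on a log2(x + 1) scale, e.g. log2(TPM + 1) or
#' log2(CPM + 1)). Row names are gene symbols, column names are cell ids;
#' both must be unique.
#'
#' @param counts Optional genes x cells matrix of non-negative counts.
#' @param normexpr Optional genes x cells matrix of log2-scale expression.
#' @param gene_ids,cell_ids Optional character vectors overriding dimnames.
#'
#' @return An object of class `expr_matrix` with elements `counts`,
#'   `normexpr`, `gene_ids`, `cell_ids`.
#' @examples
#' m <- matrix(rpois(6, 5), 3, 2,
#'             dimnames = list(c("CD3D", "KLRB1", "GZMB"), c("c1", "c2")))
#' em <- expr_matrix(counts = m)
#' dim(em)
#' @export
expr_matrix <- function(counts = NULL, normexpr = NULL,
                        gene_ids = NULL, cell_ids = NULL) {
  if (is.null(counts) && is.null(normexpr)) {
    abort("At least one of `counts` or `normexpr` must be supplied.")
  }
  fix <- function(m) {
    if (is.null(m)) return(NULL)
    m <- as.matrix(m)
    if (!is.null(gene_ids)) rownames(m) <- gene_ids
    if (!is.null(cell_ids)) colnames(m) <- cell_ids
    if (is.null(rownames(m)) || is.null(colnames(m))) {
      abort("Expression matrices need gene (row) and cell (column) names.")
    }
    m
  }
  counts <- fix(counts)
  normexpr <- fix(normexpr)
  ref <- counts %||% normexpr
  if (anyDuplicated(rownames(ref))) {
    abort(sprintf("Duplicate gene symbols: %s",
                  paste(unique(rownames(ref)[duplicated(rownames(ref))]),
                        collapse = ", ")))
  }
  if (anyDuplicated(colnames(ref))) abort("Duplicate cell ids.")
  if (!is.null(counts)) {
    if (any(counts < 0)) abort("Counts must be non-negative.")
    if (any(is.na(counts))) abort("Counts must not contain NA.")
  }
  if (!is.null(counts) && !is.null(normexpr)) {
    if (!identical(dim(counts), dim(normexpr)) ||
        !identical(dimnames(counts), dimnames(normexpr))) {
      abort("`counts` and `normexpr` layers must share dimensions and names.")
    }
  }
  structure(
    list(counts = counts, normexpr = normexpr,
         gene_ids = rownames(ref), cell_ids = colnames(ref)),
    class = "expr_matrix"
  )
}

#' @export
dim.expr_matrix <- function(x) {
  c(length(x$gene_ids), length(x$cell_ids))
}

#' @export
print.expr_matrix <- function(x, ...) {
  layers <- c(if (!is.null(x$counts)) "counts",
              if (!is.null(x$normexpr)) "normexpr")
  cat(sprintf("<expr_matrix> %d genes x %d cells; layers: %s\n",
              length(x$gene_ids), length(x$cell_ids),
              paste(layers, collapse = ", ")))
  invisible(x)
}

#' Subset an expression container by genes and/or cells
#'
#' @param x An [expr_matrix()].
#' @param genes,cells Character vectors (or logical/integer indices) of
#'   genes / cells to keep; `NULL` keeps all.
#' @return An `expr_matrix` restricted to the requested rows/columns.
#' @export
subset_expr <- function(x, genes = NULL, cells = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  gi <- genes %||% x$gene_ids
  ci <- cells %||% x$cell_ids
  if (is.character(gi)) {
    missing <- setdiff(gi, x$gene_ids)
    if (length(missing)) abort(sprintf("Genes not present: %s",
                                       paste(missing, collapse = ", ")))
  }
  take <- function(m) if (is.null(m)) NULL else m[gi, ci, drop = FALSE]
  expr_matrix(counts = take(x$counts), normexpr = take(x$normexpr))
}

# Internal: fetch a layer or fail with a clear message.
get_layer <- function(x, layer = c("normexpr", "counts")) {
  layer <- match.arg(layer)
  m <- x[[layer]]
  if (is.null(m)) abort(sprintf("Layer '%s' is absent from this expr_matrix.", layer))
  m
}
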