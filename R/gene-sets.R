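#' Default immune gene-set catalog
#'
#' Curated marker lists used throughout the pipeline: T-cell
#' activation/function genes, exhaustion (checkpoint/dysfunction) genes,
#' the eleven-gene consensus MAIT signature, pan-T-cell markers and NK-cell
#' markers. Extra user-defined sets can be appended.
#'
#' @param ... Named character vectors to append to (or override in) the
#'   catalog.
#' @return A named list of character vectors of gene symbols.
#' @examples
#' mait_gene_sets()$mait_signature
#' @export
mait_gene_sets <- function(...) {
  defaults <- list(
    activation_genes = c("CD69", "CD38", "HLA-DRA", "IL2RA", "TNFRSF9",
                         "TNF", "GNLY", "IFNG", "GZMB", "GZMA", "GZMH"),
    exhaustion_genes = c("PDCD1", "CTLA4", "TIGIT", "CXCL13", "ENTPD1",
                         "LAG3", "ITGAE", "LAYN"),
    mait_signature = c("SLC4A10", "KLRB1", "ME1", "TMIGD2", "IL23R",
                       "NCR3", "LST1", "COLQ", "RORC", "ZBTB16", "TLE1"),
    pan_t_genes = c("CD3D", "CD3E", "CD3G"),
    nk_genes = c("XCL2", "PRF1", "KLRF1", "KLRD1", "IL2RB", "CD244", "CD160")
  )
  extra <- list(...)
  if (length(extra)) {
    if (is.null(names(extra)) || any(names(extra) == "")) {
      abort("Extra gene sets must be named.")
    }
    defaults[names(extra)] <- extra
  }
  lapply(defaults, function(g) {
    if (anyDuplicated(g)) abort("Gene sets must not contain duplicates.")
    as.character(g)
  })
}

#' Define a named gene signature
#'
#' @param name Signature name.
#' @param genes Character vector of unique gene symbols.
#' @param provenance One of `"paper_default"`, `"derived"`, `"user"`.
#' @return A `signature_def` object (named list).
#' @export
signature_def <- function(name, genes,
                          provenance = c("user", "paper_default", "derived")) {
  provenance <- match.arg(provenance)
  genes <- as.character(genes)
  if (!length(genes)) abort("A signature must contain at least one gene.")
  if (anyDuplicated(genes)) abort("Signature genes must be unique.")
  structure(list(name = name, genes = genes, provenance = provenance),
            class = "signature_def")
}

#' @export
print.signature_def <- function(x, ...) {
  cat(sprintf("<signature_def> '%s' (%s): %d genes\n  %s\n",
              x$name, x$provenance, length(x$genes),
              paste(x$genes, collapse = ", ")))
  invisible(x)
}

# Accept either a signature_def or a bare character vector of genes.
as_signature <- function(x, name = "signature") {
  if (inherits(x, "signature_def")) return(x)
  signature_def(name, x)
}

#' Read / write gene sets as YAML
#'
#' YAML files map set names to lists of gene symbols.
#'
#' @param path File path.
#' @param sets Named list of character vectors.
#' @return `read_gene_sets()` returns a named list of character vectors.
#' @export
read_gene_sets <- function(path) {
  sets <- yaml::read_yaml(path)
  if (!is.list(sets) || is.null(names(sets))) {
    abort(sprintf("'%s' must be a YAML mapping of set name -> gene list.", path))
  }
  lapply(sets, as.character)
}

#' @rdname read_gene_sets
#' @export
write_gene_sets <- function(sets, path) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  yaml::write_yaml(lapply(sets, as.list), path)
  invisible(path)
}
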