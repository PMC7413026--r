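#' @importFrom rlang %||% abort warn .data
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join inner_join bind_rows n count rename distinct pull across
#' @importFrom tibble tibble as_tibble
#' @importFrom stats median mad sd var quantile lowess p.adjust pt pf pnorm
#'   pchisq fisher.test wilcox.test t.test cor cor.test lm resid rnbinom
#'   rnorm runif rexp rgamma rbinom model.matrix setNames uniroot
NULL

# Explicit-seed policy: every randomized entry point funnels through here.
check_seed <- function(seed) {
  if (is.null(seed) || length(seed) != 1L || is.na(seed) ||
      !is.numeric(seed) || seed != as.integer(seed)) {
    abort("`seed` must be a single integer; randomized operations never run unseeded.")
  }
  as.integer(seed)
}

with_seed <- function(seed, code) {
  seed <- check_seed(seed)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must lie in [0, 1].", name))
  }
  invisible(x)
}

# Strip IMGT allele suffixes so "TRAV1-2*01" and "TRAV1-2" compare equal.
strip_allele <- function(x) sub("\\*.*$", "", x)
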