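# Independent brute-force oracles. These are deliberately naive
# implementations written straight from the definitions; they never call
# the code paths they are used to check.

# Benjamini-Hochberg step-up, straight from the definition.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- p[o] * m / seq_len(m)
  # enforce monotonicity from the largest p downwards
  for (i in seq(m - 1, 1)) {
    if (i >= 1 && m > 1) adj_sorted[i] <- min(adj_sorted[i], adj_sorted[i + 1])
  }
  out <- numeric(m)
  out[o] <- pmin(adj_sorted, 1)
  out
}

# Two-sided Fisher exact p for a 2x2 table [[a, b], [c, d]] by summing
# hypergeometric probabilities not exceeding that of the observed table.
fisher_oracle <- function(a, b, c, d) {
  m <- a + b      # row 1 total
  n <- c + d      # row 2 total
  k <- a + c      # column 1 total
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Kendall tau-b by O(n^2) pair enumeration with tie correction.
kendall_oracle <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      dx <- sign(x[i] - x[j]); dy <- sign(y[i] - y[j])
      if (dx == 0 && dy == 0) next
      if (dx == 0) tx <- tx + 1
      else if (dy == 0) ty <- ty + 1
      else if (dx == dy) conc <- conc + 1
      else disc <- disc + 1
    }
  }
  (conc - disc) / sqrt((conc + disc + tx) * (conc + disc + ty))
}

# Deterministic unique CDR3 strings for fixtures.
random_nt <- function(i) sprintf("NT%04d", i)

# Tiny deterministic expression fixture: counts for 4 genes x 3 cells.
tiny_counts <- function() {
  matrix(c(0, 1, 2, 3,
           4, 0, 6, 2,
           1, 1, 1, 1),
         nrow = 4,
         dimnames = list(c("MT-CO1", "CD3D", "KLRB1", "GZMB"),
                         c("c1", "c2", "c3")))
}

# Contig table builder for readable TCR fixtures.
contig_row <- function(cell, locus, v, j, nt, productive = TRUE) {
  tibble::tibble(cell_id = cell, locus = locus, v_gene = v, j_gene = j,
                 cdr3_nt = nt, cdr3_aa = NA_character_,
                 productive = productive)
}

# An eligible cell with one alpha and one beta chain.
simple_cell <- function(cell, av = "TRAV1-2", aj = "TRAJ33", ant = "AAA",
                        bv = "TRBV6-1", bj = "TRBJ1-1", bnt = "CCC",
                        a_prod = TRUE, b_prod = TRUE) {
  dplyr::bind_rows(
    contig_row(cell, "TRA", av, aj, ant, a_prod),
    contig_row(cell, "TRB", bv, bj, bnt, b_prod)
  )
}
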