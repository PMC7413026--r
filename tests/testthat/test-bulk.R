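# Build a bulk_cohort from a samples x genes matrix with dummy endpoints.
cohort_from <- function(expr, os_time = NULL, os_event = NULL) {
  n <- nrow(expr)
  clin <- tibble::tibble(
    sample_id = rownames(expr),
    os_time = os_time %||% rep(100, n),
    os_event = os_event %||% rep(1, n),
    pfs_time = os_time %||% rep(50, n),
    pfs_event = os_event %||% rep(1, n)
  )
  bulk_cohort(expr, clin)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("Kendall tau-b matches pair enumeration on tied fixtures", {
  set.seed(61)
  # deterministic tied fixture
  x <- c(1, 2, 2, 3, 4, 4, 4, 5, 1, 3, 2, 5)
  y <- c(2, 1, 3, 3, 5, 4, 6, 7, 2, 2, 4, 6)
  expr <- cbind(gA = x, gB = y, gC = rnorm(12))
  rownames(expr) <- sprintf("s%02d", 1:12)
  rep_ <- kendall_matrix(cohort_from(expr), markers = c("gA", "gB", "gC"))
  expect_equal(rep_$tau["gA", "gB"], kendall_oracle(x, y), tolerance = 1e-12)
  # random fixtures with heavy ties, n <= 30
  for (i in 1:50) {
    n <- sample(5:30, 1)
    a <- sample(1:5, n, replace = TRUE) + rnorm(n, 0, 0.01 * (i %% 2))
    b <- sample(1:5, n, replace = TRUE)
    expr2 <- cbind(gA = a, gB = b)
    rownames(expr2) <- sprintf("s%02d", 1:n)
    if (n < 10) next
    r2 <- kendall_matrix(cohort_from(expr2), markers = c("gA", "gB"))
    expect_equal(r2$tau["gA", "gB"], kendall_oracle(a, b), tolerance = 1e-12)
  }
})

test_that("perfect concordance and reversal give tau of +1 / -1", {
  x <- 1:12
  expr <- cbind(up = x, down = rev(x), noise = rnorm(12))
  rownames(expr) <- sprintf("s%02d", 1:12)
  rep_ <- kendall_matrix(cohort_from(expr), markers = c("up", "down", "noise"))
  expect_equal(rep_$tau["up", "down"], -1)
  expect_equal(rep_$tau["up", "up"], 1)
  # constant gene flagged, tau recorded as zero
  expr2 <- cbind(expr, flat = rep(3, 12))
  rownames(expr2) <- rownames(expr)
  expect_warning(r2 <- kendall_matrix(cohort_from(expr2),
                                      markers = c("up", "flat", "missing")),
                 "absent")
  expect_true(r2$constant["flat"])
  expect_equal(r2$tau["up", "flat"], 0)
})

# Construct a kendall_report directly for rule tests.
fake_report <- function(markers, tau, p) {
  structure(list(tau = tau, p = p, markers = markers,
                 constant = setNames(rep(FALSE, length(markers)), markers)),
            class = "kendall_report")
}

all_good_report <- function(genes, pan_t = c("CD3D", "CD3E", "CD3G")) {
  mk <- c(genes, pan_t)
  k <- length(mk)
  tau <- matrix(0.5, k, k, dimnames = list(mk, mk)); diag(tau) <- 1
  p <- matrix(1e-6, k, k, dimnames = list(mk, mk)); diag(p) <- 0
  fake_report(mk, tau, p)
}

test_that("trimming retains everything when all pairs correlate", {
  sig <- mait_gene_sets()$mait_signature
  tr <- trim_signature(all_good_report(sig))
  expect_setequal(tr$retained, sig)
  expect_true(tr$eligible)
  expect_identical(nrow(tr$removed), 0L)
})

test_that("a gene uncorrelated with the anchor is removed under rule one", {
  sig <- mait_gene_sets()$mait_signature
  rep_ <- all_good_report(sig)
  rep_$tau["KLRB1", "SLC4A10"] <- rep_$tau["SLC4A10", "KLRB1"] <- -0.2
  tr <- trim_signature(rep_)
  expect_false("KLRB1" %in% tr$retained)
  expect_match(tr$removed$rules_violated[tr$removed$gene == "KLRB1"], "anchor")
  expect_true(tr$eligible)
})

test_that("genes missing pan-T support are removed; under five genes is ineligible", {
  sig <- mait_gene_sets()$mait_signature
  rep_ <- all_good_report(sig)
  drop <- c("ME1", "RORC", "ZBTB16", "TLE1", "LST1", "COLQ", "TMIGD2")
  for (g in drop) {
    rep_$p[g, c("CD3D", "CD3E", "CD3G")] <- 0.9
    rep_$p[c("CD3D", "CD3E", "CD3G"), g] <- 0.9
  }
  tr <- trim_signature(rep_)
  expect_setequal(tr$retained, setdiff(sig, drop))
  expect_false(tr$eligible)   # 4 genes < 5
  expect_identical(length(tr$retained), 4L)
})

test_that("trimming reaches a fixed point and is idempotent", {
  bc <- generate_bulk_cohort(bulk_sim_config(seed = 62, n_samples = 150))
  rep_ <- kendall_matrix(bc$cohort)
  tr <- trim_signature(rep_)
  # re-trim with the retained set as input: nothing else is removed
  tr2 <- trim_signature(rep_, signature = tr$retained)
  expect_identical(tr2$retained, tr$retained)
  expect_identical(nrow(tr2$removed), 0L)
  expect_lte(nrow(tr$removed) + length(tr$retained), 11)
  expect_error(trim_signature(rep_, anchor = "NOPE"), "absent")
})

test_that("bulk scores are z-means and residuals are orthogonal to T scores", {
  set.seed(63)
  n <- 40
  genes <- c(mait_gene_sets()$mait_signature, "CD3D", "CD3E", "CD3G", "MR1")
  expr <- matrix(rnorm(n * length(genes), 5), n,
                 dimnames = list(sprintf("s%02d", 1:n), genes))
  co <- cohort_from(expr)
  sb <- score_bulk(co, mait_gene_sets()$mait_signature)
  # z-mean construction
  z <- scale(expr[, mait_gene_sets()$mait_signature])
  expect_equal(sb$mait_score, unname(rowMeans(z)), tolerance = 1e-12)
  expect_lt(abs(cor(sb$resid_mait_score, sb$t_score)), 1e-10)

  # MAIT score identical to T score -> residuals all zero
  co2 <- cohort_from(expr)
  sb2 <- score_bulk(co2, c("CD3D", "CD3E", "CD3G"))
  expect_equal(sb2$resid_mait_score, rep(0, n), tolerance = 1e-10)
})

test_that("residuals match the hand-solved simple regression on 5 samples", {
  x <- c(-1, -0.5, 0, 0.5, 1)        # T score
  y <- c(0.2, 0.1, 0.4, 0.9, 0.9)    # MAIT score
  beta <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  alpha <- mean(y) - beta * mean(x)
  resid_hand <- y - (alpha + beta * x)
  expect_equal(unname(resid(lm(y ~ x))), resid_hand, tolerance = 1e-12)
  # the same arithmetic drives score_bulk's residualization on real scores
  bc <- generate_bulk_cohort(bulk_sim_config(seed = 64, n_samples = 100))
  sb <- score_bulk(bc$cohort, mait_gene_sets()$mait_signature)
  fit <- lm(sb$mait_score ~ sb$t_score)
  expect_equal(sb$resid_mait_score, unname(resid(fit)), tolerance = 1e-10)
})

test_that("tertile stratification splits at the 33rd/67th percentiles", {
  bc <- generate_bulk_cohort(bulk_sim_config(seed = 65, n_samples = 300))
  sb <- score_bulk(bc$cohort, mait_gene_sets()$mait_signature)
  sv <- survival_test(sb, bc$cohort, "os")
  s <- sv$summary
  expect_identical(s$n_low + s$n_middle + s$n_high, 300L)
  qs <- quantile(sb$resid_mait_score, c(1/3, 2/3), type = 7)
  expect_identical(s$n_low, sum(sb$resid_mait_score <= qs[1]))
  expect_true(s$hr_lower <= s$hazard_ratio && s$hazard_ratio <= s$hr_upper)
  # planted positive hazard: high-score group fares worse
  expect_gt(s$hazard_ratio, 1)
  expect_lt(s$wald_p, 0.05)
})

test_that("identical survival in both strata gives a null log-rank statistic", {
  n <- 63
  expr <- matrix(rnorm(n * 14, 5), n,
                 dimnames = list(sprintf("s%02d", 1:n),
                                 c(mait_gene_sets()$mait_signature,
                                   "CD3D", "CD3E", "CD3G")))
  # every score stratum sees the same multiset of event times
  score <- rep(1:3, each = n / 3)      # low/middle/high by construction
  times <- rep(rep(c(10, 20, 30), each = n / 9), 3)
  co <- cohort_from(expr, os_time = times, os_event = rep(1, n))
  sc <- tibble::tibble(sample_id = rownames(expr), resid_mait_score = score)
  sv <- survival_test(sc, co, "os")
  expect_lt(sv$summary$logrank_chisq, 1e-10)
  expect_equal(sv$summary$hazard_ratio, 1, tolerance = 1e-6)
})

test_that("continuous-mode Cox recovers a planted log hazard ratio", {
  bc <- generate_bulk_cohort(bulk_sim_config(seed = 66))
  truth_scores <- tibble::tibble(sample_id = bc$truth$sample_id,
                                 resid_mait_score = bc$truth$mait_z)
  sv <- survival_test(truth_scores, bc$cohort, "os", mode = "continuous")
  expect_lt(abs(sv$summary$log_hr - 0.5), 0.15)
  expect_true(all(c("log_hr", "log_hr_se", "hazard_ratio") %in%
                    names(tidy(sv))))
})

test_that("MR1 association recovers planted and degenerate relationships", {
  bc <- generate_bulk_cohort(bulk_sim_config(seed = 67))
  sb <- score_bulk(bc$cohort, mait_gene_sets()$mait_signature)
  res <- mr1_association(bc$cohort, sb)
  expect_gt(res$r, 0.2)
  expect_lt(res$p_value, 0.001)

  # MR1 an exact affine function of the score -> r = 1
  expr <- bc$cohort$expr
  expr[, "MR1"] <- 2 * sb$resid_mait_score[match(rownames(expr), sb$sample_id)] + 3
  co2 <- bulk_cohort(expr, bc$cohort$clinical)
  expect_equal(mr1_association(co2, sb)$r, 1, tolerance = 1e-12)

  # 6-sample fixture vs the textbook formula
  mr1 <- c(1, 3, 2, 5, 4, 6); sc <- c(0.2, 0.5, 0.1, 0.9, 0.8, 1.2)
  r_hand <- sum((mr1 - mean(mr1)) * (sc - mean(sc))) /
    sqrt(sum((mr1 - mean(mr1))^2) * sum((sc - mean(sc))^2))
  e2 <- matrix(rnorm(6 * 11, 5), 6,
               dimnames = list(sprintf("s%d", 1:6),
                               mait_gene_sets()$mait_signature))
  e2 <- cbind(e2, MR1 = mr1)
  co3 <- cohort_from(e2)
  sc3 <- tibble::tibble(sample_id = rownames(e2), resid_mait_score = sc)
  expect_equal(mr1_association(co3, sc3)$r, r_hand, tolerance = 1e-12)
  expect_error(mr1_association(cohort_from(e2[, 1:11]), sc3), "MR1")
})
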