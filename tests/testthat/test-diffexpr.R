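sim_matrix <- function(n_genes, n_per_group, k = 2, delta = NULL, sd = 1,
                       mean0 = 5) {
  n <- n_per_group * k
  x <- matrix(rnorm(n_genes * n, mean0, sd), n_genes, n,
              dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                              sprintf("c%04d", seq_len(n))))
  groups <- rep(LETTERS[seq_len(k)], each = n_per_group)
  if (!is.null(delta)) {
    de <- seq_along(delta)
    x[de, groups == "A"] <- x[de, groups == "A"] + delta
  }
  list(x = x, groups = groups)
}

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.07, 5)), rep(0.07, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  set.seed(31)
  for (i in 1:200) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
  # adjusted p never drops below raw p
  p <- runif(100)
  expect_true(all(bh_adjust(p) >= p))
})

test_that("moderated t matches the closed-form formula on a fixed dataset", {
  x <- matrix(c(1, 2, 3, 4, 5, 7,
                2, 2, 2, 5, 5, 5), nrow = 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"), paste0("c", 1:6)))
  grp <- rep(c("A", "B"), each = 3)
  fit <- moderated_fit(x, grp)
  res <- moderated_t_test(fit, c("B", "A"))
  # hand computation for g1: means 2 and 16/3; pooled s2 from the fit,
  # shrunk toward the prior; t = delta / sqrt(s2_post * (1/3 + 1/3))
  delta <- mean(x[1, 4:6]) - mean(x[1, 1:3])
  t_hand <- delta / sqrt(fit$s2_post[1] * (2 / 3))
  expect_equal(res$t[res$gene == "g1"], unname(t_hand), tolerance = 1e-10)
  expect_equal(res$log2_fc[res$gene == "g1"], delta)
  # p from the t distribution on d0 + df degrees of freedom
  expect_equal(res$p_value[res$gene == "g1"],
               2 * pt(-abs(t_hand), fit$df_total), tolerance = 1e-12)
})

test_that("d0 = 0 reduces to the ordinary equal-variance two-sample t-test", {
  set.seed(7)
  sm <- sim_matrix(300, 10)
  fit <- moderated_fit(sm$x, sm$groups, d0_override = 0)
  res <- moderated_t_test(fit, c("A", "B"))
  for (g in sample(rownames(sm$x), 50)) {
    tt <- t.test(sm$x[g, sm$groups == "A"], sm$x[g, sm$groups == "B"],
                 var.equal = TRUE)
    expect_equal(res$t[res$gene == g], unname(tt$statistic), tolerance = 1e-8)
    expect_equal(res$p_value[res$gene == g], tt$p.value, tolerance = 1e-8)
  }
})

test_that("d0 = Inf forces full shrinkage to the prior variance", {
  set.seed(8)
  sm <- sim_matrix(100, 5)
  fit <- moderated_fit(sm$x, sm$groups, d0_override = Inf)
  expect_equal(fit$s2_post, fit$s0_2)
})

test_that("posterior variances lie between the sample and prior variances", {
  set.seed(9)
  sm <- sim_matrix(500, 6, k = 3)
  fit <- moderated_fit(sm$x, sm$groups)
  lo <- pmin(fit$s2, fit$s0_2); hi <- pmax(fit$s2, fit$s0_2)
  expect_true(all(fit$s2_post >= lo - 1e-12 & fit$s2_post <= hi + 1e-12))
  expect_true(fit$d0 >= 0)
})

test_that("prior moment-matching recovers planted (d0, s0^2) within 20%", {
  set.seed(10)
  d0_true <- 8; s0_true <- 1.3; df1 <- 18
  s2 <- s0_true * stats::rf(2000, df1, d0_true)
  prior <- maitsig:::fit_f_dist(s2, df1)
  expect_lt(abs(prior$df_prior - d0_true) / d0_true, 0.2)
  expect_lt(abs(prior$s2_prior[1] - s0_true) / s0_true, 0.2)
})

test_that("the fit agrees with the limma reference implementation", {
  skip_if_not_installed("limma")
  set.seed(12)
  sm <- sim_matrix(400, 15, k = 3, delta = rep(1, 30))
  fit <- moderated_fit(sm$x, sm$groups, trend = FALSE)
  design <- stats::model.matrix(~0 + sm$groups)
  colnames(design) <- levels(factor(sm$groups))
  lf <- limma::lmFit(sm$x, design)
  ct <- limma::contrasts.fit(lf, limma::makeContrasts(A - B, levels = design))
  eb <- limma::eBayes(ct, trend = FALSE)
  expect_equal(fit$d0, eb$df.prior, tolerance = 1e-8)
  expect_equal(unname(fit$s0_2[1]), eb$s2.prior[1], tolerance = 1e-8)
  mine <- moderated_t_test(fit, c("A", "B"))
  expect_equal(mine$t, unname(eb$t[, 1]), tolerance = 1e-10)
  expect_equal(mine$p_value, unname(eb$p.value[, 1]), tolerance = 1e-10)
  # moderated F for group equality: F over the non-intercept coefficients
  eb2 <- limma::eBayes(limma::lmFit(sm$x, stats::model.matrix(~factor(sm$groups))))
  tt <- limma::topTable(eb2, coef = 2:3, number = Inf, sort.by = "none")
  fres <- moderated_f_test(fit)
  expect_equal(fres$f, tt$F, tolerance = 1e-10)
  # topTable recomputes the F p with an uncapped total df; near-identical
  expect_equal(fres$p_value, tt$P.Value, tolerance = 1e-3)
  # trended prior on genuinely heteroskedastic data: the smoothers differ
  # slightly, so agreement is checked loosely
  v <- sqrt(seq(0.4, 2.5, length.out = 400))
  xh <- matrix(rnorm(400 * 45, 0, rep(v, 45)), 400, 45) +
    seq(2, 9, length.out = 400)
  dimnames(xh) <- dimnames(sm$x)
  fit_tr <- moderated_fit(xh, sm$groups, trend = TRUE)
  lfh <- limma::lmFit(xh, design)
  cth <- limma::contrasts.fit(lfh, limma::makeContrasts(A - B, levels = design))
  eb_tr <- limma::eBayes(cth, trend = TRUE)
  # the smooth trend absorbs the variance dispersion: both estimators
  # push the prior df to infinity (full shrinkage to the trend line)
  expect_identical(is.infinite(fit_tr$d0), is.infinite(eb_tr$df.prior))
  expect_gt(cor(fit_tr$s0_2, eb_tr$s2.prior), 0.98)
  mine_tr <- moderated_t_test(fit_tr, c("A", "B"))
  expect_gt(cor(mine_tr$t, unname(eb_tr$t[, 1])), 0.999)
})

test_that("hierarchical procedure screens with F then tests survivors only", {
  set.seed(13)
  sm <- sim_matrix(800, 50, k = 2, delta = rep(1, 40))
  res <- hierarchical_deg(sm$x, sm$groups, deg_config(trend = TRUE))
  fstage <- attr(res, "f_stage")
  survivors <- fstage$gene[fstage$adj_p_value < 0.2]
  expect_true(all(res$gene %in% survivors))

  planted <- rownames(sm$x)[1:40]
  called <- unique(res$gene[res$significant])
  sens <- length(intersect(called, planted)) / length(planted)
  fdr <- if (length(called)) length(setdiff(called, planted)) / length(called) else 0
  expect_gte(sens, 0.8)
  expect_lte(fdr, 0.1)

  # disabling the prefilter reproduces plain pairwise testing
  res_all <- hierarchical_deg(sm$x, sm$groups,
                              deg_config(f_prefilter_threshold = 1, trend = TRUE))
  expect_identical(sort(unique(res_all$gene)), sort(rownames(sm$x)))
})

test_that("degenerate inputs are handled explicitly", {
  set.seed(14)
  sm <- sim_matrix(50, 10)
  expect_error(moderated_fit(sm$x, rep("A", 20)), "two groups")
  expect_error(moderated_fit(sm$x, c(rep("A", 19), "B")), "fewer than 2")
  # self-contrast: all zero fold-changes
  fit <- moderated_fit(sm$x, sm$groups)
  res <- moderated_t_test(fit, c("A", "A"))
  expect_true(all(res$log2_fc == 0) && all(res$t == 0) && all(res$p_value == 1))
  # identical group means -> t = 0, p = 1
  x <- matrix(rep(c(1, 2, 3, 1, 2, 3), each = 2), nrow = 2)
  dimnames(x) <- list(c("g1", "g2"), paste0("c", 1:6))
  fit2 <- moderated_fit(x, rep(c("A", "B"), each = 3))
  res2 <- moderated_t_test(fit2, c("A", "B"))
  expect_true(all(abs(res2$t) < 1e-12))
  # zero-variance genes do not produce NaN statistics
  xz <- rbind(const = rep(5, 20), var = rnorm(20))
  colnames(xz) <- paste0("c", 1:20)
  fitz <- moderated_fit(xz, rep(c("A", "B"), each = 10))
  resz <- moderated_t_test(fitz, c("A", "B"))
  expect_false(any(is.nan(resz$t)))
  # no survivor: empty result with a warning
  set.seed(15)
  null_sm <- sim_matrix(100, 5, k = 2)
  expect_warning(
    empty <- hierarchical_deg(null_sm$x, null_sm$groups,
                              deg_config(f_prefilter_threshold = 0.0001,
                                         trend = FALSE)),
    "No gene")
  expect_identical(nrow(empty), 0L)
})
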