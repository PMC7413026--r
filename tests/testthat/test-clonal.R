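make_ann <- function(patient, tissue, subset, n) {
  tibble::tibble(patient_id = patient, tissue = tissue, subset = subset) |>
    tidyr::uncount(n) |>
    dplyr::mutate(cell_id = sprintf("%s_%s_%s_%03d", patient, tissue, subset,
                                    dplyr::row_number()),
                  treatment = "not_applicable")
}

test_that("observed/expected ratios match the chi-square expected counts", {
  # 2x2 table [[30,10],[10,30]]: expected (1,1) = 40*40/80 = 20 -> 1.5
  ann <- dplyr::bind_rows(
    make_ann("p1", "blood", "MAIT", 30), make_ann("p1", "blood", "CD8", 10),
    make_ann("p1", "tumor", "MAIT", 10), make_ann("p1", "tumor", "CD8", 30)
  )
  roe <- compute_roe(ann)
  r11 <- roe[roe$tissue == "blood" & roe$subset == "MAIT", ]
  expect_equal(r11$expected, 20)
  expect_equal(r11$roe, 1.5)
  # the observed-minus-expected deviations cancel within patient
  expect_equal(sum(roe$observed - roe$expected), 0)
})

test_that("proportional margins give ratios of one, absence gives zero", {
  prop <- dplyr::bind_rows(
    make_ann("p1", "blood", "MAIT", 10), make_ann("p1", "blood", "CD8", 30),
    make_ann("p1", "tumor", "MAIT", 20), make_ann("p1", "tumor", "CD8", 60)
  )
  expect_true(all(abs(compute_roe(prop)$roe - 1) < 1e-12))

  absent <- dplyr::bind_rows(
    make_ann("p1", "blood", "MAIT", 5), make_ann("p1", "blood", "CD8", 20),
    make_ann("p1", "tumor", "CD8", 25)
  )
  roe <- compute_roe(absent)
  expect_equal(roe$roe[roe$tissue == "tumor" & roe$subset == "MAIT"], 0)
})

test_that("single-tissue patients are excluded and group comparison runs", {
  ann <- dplyr::bind_rows(
    make_ann("p1", "blood", "MAIT", 10), make_ann("p1", "tumor", "MAIT", 5),
    make_ann("p1", "blood", "CD8", 30), make_ann("p1", "tumor", "CD8", 40),
    make_ann("p2", "blood", "MAIT", 8), make_ann("p2", "tumor", "MAIT", 9),
    make_ann("p2", "blood", "CD8", 25), make_ann("p2", "tumor", "CD8", 30),
    make_ann("p3", "blood", "MAIT", 7)  # single tissue -> excluded
  )
  expect_warning(roe <- compute_roe(ann), "p3")
  expect_false("p3" %in% roe$patient_id)
  cmp <- compare_roe(roe, levels = c("blood", "tumor"))
  expect_identical(cmp$n1, 2L)
  expect_true(cmp$p_value > 0 && cmp$p_value <= 1)
})

test_that("clonotype sharing maps clones to exact tissue combinations", {
  # clone1 in blood+tumor, clone2 in all three, singletons everywhere
  contigs <- dplyr::bind_rows(
    simple_cell("c1", ant = "AAA", bnt = "X1"),
    simple_cell("c2", ant = "AAA", bnt = "X1"),
    simple_cell("c3", ant = "GGG", bnt = "X2"),
    simple_cell("c4", ant = "GGG", bnt = "X2"),
    simple_cell("c5", ant = "GGG", bnt = "X2"),
    simple_cell("s1", ant = "T10", bnt = "Y1"),
    simple_cell("s2", ant = "T11", bnt = "Y2")
  )
  ann <- tibble::tibble(
    cell_id = paste0(c("c", "c", "c", "c", "c", "s", "s"),
                     c(1, 2, 3, 4, 5, 1, 2)),
    patient_id = "p1",
    tissue = c("blood", "tumor", "blood", "normal", "tumor", "blood", "tumor"),
    subset = "MAIT", treatment = "not_applicable"
  )
  sh <- summarize_sharing(build_clonotypes(contigs), ann)
  clonal <- sh[sh$clonal, ]
  expect_setequal(clonal$combination, c("BT", "BNT"))
  expect_identical(clonal$n_clonotypes[clonal$combination == "BNT"], 1L)
  expect_equal(clonal$mean_cells_per_clonotype[clonal$combination == "BNT"], 3)
  # non-clonal singletons tallied per tissue
  expect_identical(sum(sh$n_clonotypes[!sh$clonal]), 2L)
  # clonal combination counts partition the clonal clonotypes
  expect_identical(sum(clonal$n_clonotypes),
                   sum(build_clonotypes(contigs)$clonal))
})

test_that("all-singleton repertoires have empty clonal bins", {
  contigs <- dplyr::bind_rows(lapply(1:4, function(i) {
    simple_cell(paste0("c", i), ant = random_nt(i), bnt = random_nt(i + 100))
  }))
  ann <- tibble::tibble(cell_id = paste0("c", 1:4), patient_id = "p1",
                        tissue = "blood", subset = "MAIT",
                        treatment = "not_applicable")
  sh <- summarize_sharing(build_clonotypes(contigs), ann)
  expect_false(any(sh$clonal))
})

dyn_fixture <- function(clone_sizes_pre, clone_sizes_post, patient = "p1") {
  # builds contigs + annotations where clone i has the given pre/post counts
  rows <- list(); anns <- list(); cell <- 0
  for (i in seq_along(clone_sizes_pre)) {
    for (tr in c("pre", "post")) {
      n <- if (tr == "pre") clone_sizes_pre[i] else clone_sizes_post[i]
      if (n == 0) next
      for (k in seq_len(n)) {
        cell <- cell + 1
        id <- sprintf("%s_c%04d", patient, cell)
        rows[[length(rows) + 1]] <- simple_cell(id, ant = random_nt(i),
                                                bnt = random_nt(i + 1000))
        anns[[length(anns) + 1]] <- tibble::tibble(
          cell_id = id, patient_id = patient, tissue = "tumor",
          subset = "MAIT", treatment = tr)
      }
    }
  }
  list(contigs = dplyr::bind_rows(rows), ann = dplyr::bind_rows(anns))
}

test_that("clone dynamics assigns the documented fates", {
  # clone1 stable (same proportion), clone2 pre-only, clone3 post-only,
  # clone4 expanded (1/100 -> 50/100 within patient totals)
  fx <- dyn_fixture(clone_sizes_pre = c(30, 7, 0, 1, 62),
                    clone_sizes_post = c(30, 0, 7, 50, 13))
  cl <- build_clonotypes(fx$contigs)
  dyn <- classify_clone_dynamics(cl, fx$ann, alpha = 0.05, min_cells = 10)
  fate_of <- function(pre, post) dyn$fate[dyn$pre_count == pre & dyn$post_count == post]
  expect_identical(fate_of(30, 30), "stable")
  expect_identical(fate_of(7, 0), "pre_only")
  expect_identical(fate_of(0, 7), "post_only")
  expect_identical(fate_of(1, 50), "expanded")
  expect_identical(fate_of(62, 13), "depleted")
  # identical proportions: Fisher p = 1
  expect_equal(dyn$p_value[dyn$pre_count == 30], 1)
  # totals recorded per patient
  expect_true(all(dyn$pre_total == 100 & dyn$post_total == 100))
})

test_that("swapping pre and post mirrors the directional fates", {
  fx <- dyn_fixture(clone_sizes_pre = c(30, 7, 0, 1, 62),
                    clone_sizes_post = c(30, 0, 7, 50, 13))
  fx_sw <- fx
  fx_sw$ann$treatment <- c(pre = "post", post = "pre")[fx$ann$treatment]
  cl <- build_clonotypes(fx$contigs)
  dyn <- classify_clone_dynamics(cl, fx$ann)
  dyn_sw <- classify_clone_dynamics(cl, fx_sw$ann)
  key <- paste(dyn$pre_count + dyn$post_count)
  swap_map <- c(pre_only = "post_only", post_only = "pre_only",
                expanded = "depleted", depleted = "expanded",
                stable = "stable")
  merged <- dplyr::inner_join(dyn, dyn_sw, by = "clonotype_id")
  expect_identical(unname(swap_map[merged$fate.x]), merged$fate.y)
  expect_equal(merged$p_value.x, merged$p_value.y)
})

test_that("patients under the cell minimum are skipped and alpha is validated", {
  fx <- dyn_fixture(clone_sizes_pre = c(4, 2), clone_sizes_post = c(3, 3))
  cl <- build_clonotypes(fx$contigs)
  expect_warning(dyn <- classify_clone_dynamics(cl, fx$ann, min_cells = 10),
                 "Skipping")
  expect_identical(nrow(dyn), 0L)
  expect_error(classify_clone_dynamics(cl, fx$ann, alpha = 2), "alpha")
})

test_that("Fisher p values match hypergeometric enumeration on random tables", {
  set.seed(202)
  for (rep in 1:1000) {
    pre_total <- sample(2:50, 1)
    post_total <- sample(2:50, 1)
    a <- sample(0:pre_total, 1)
    b <- sample(0:post_total, 1)
    p_pkg <- fisher.test(matrix(c(a, pre_total - a, b, post_total - b),
                                nrow = 2, byrow = TRUE))$p.value
    p_oracle <- fisher_oracle(a, pre_total - a, b, post_total - b)
    expect_equal(p_pkg, p_oracle, tolerance = 1e-10)
  }
})
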