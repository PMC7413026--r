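# Dirichlet draws via normalized gammas.
rdirichlet <- function(n, alpha) {
  g <- matrix(rgamma(n * length(alpha), shape = alpha), nrow = n, byrow = TRUE)
  sw <- g / rowSums(g)
  colnames(sw) <- names(alpha)
  sw
}

random_seq <- function(n, len, alphabet = c("A", "C", "G", "T")) {
  vapply(seq_len(n), function(i) {
    paste(sample(alphabet, len, replace = TRUE), collapse = "")
  }, character(1))
}

#' Configuration for the synthetic single-cell generator
#'
#' Defaults emulate the structure of the cancer T-cell atlases the pipeline
#' targets: several patients sampled in blood / normal tissue / tumor, a
#' minority MAIT population defined by a planted semi-invariant TCR alpha
#' chain, geometric clone sizes (most clonotypes singletons), planted MAIT
#' marker genes, and negative-binomial UMI-like counts (or log-normal
#' TPM-like values).
#'
#' @param seed Integer seed (required; generation never runs unseeded).
#' @param cancers Character vector of cancer labels (one dataset spans all).
#' @param patients Patients per cancer.
#' @param tissues Tissue compartments to sample.
#' @param cells_per_tissue Cells per patient per tissue (ignored when
#'   `cells_per_subset` is given).
#' @param mait_freq Named per-tissue MAIT frequency.
#' @param subset_props Proportions of CD8/CD4/Treg among non-MAIT cells.
#' @param cells_per_subset Optional fixed design: cells per subset per
#'   patient-tissue (single integer), overriding the frequency model.
#' @param n_background Background (non-marker) genes.
#' @param mait_marker_lfc Planted log2 effect of the MAIT signature genes
#'   in MAIT cells (default 2; these genes are near-exclusive to MAIT cells
#'   in real repertoires).
#' @param decoys_per_stratum Stratum-specific decoy markers per
#'   cancer-tissue stratum (elevated in that stratum's MAIT cells only).
#' @param decoy_lfc Planted log2 effect of decoys (defaults to
#'   `mait_marker_lfc`).
#' @param noise `"umi"` (negative binomial, dispersion `nb_dispersion`) or
#'   `"tpm"` (log-normal on the log2 scale, sd `tpm_sigma`).
#' @param nb_dispersion,tpm_sigma Noise parameters (defaults 0.3 and 0.5,
#'   mirroring droplet vs full-length platforms).
#' @param clone_geom_p Geometric parameter of MAIT clone sizes (default
#'   0.6: most clonotypes are singletons).
#' @param traj_probs Usage probabilities of TRAJ33/12/20 among synthetic
#'   MAIT alpha chains (default 0.85/0.10/0.05, TRAJ33-dominant).
#' @param treatment Simulate pre/post-treatment sampling with clonal
#'   expansion (tumor compartment only).
#' @param expanded_clones_per_patient,expansion_factor Treatment model:
#'   clones whose post-treatment sampling weight is multiplied.
#' @return A `sc_sim_config` list.
#' @export
sc_sim_config <- function(seed,
                          cancers = "cancer1",
                          patients = 4,
                          tissues = c("blood", "normal", "tumor"),
                          cells_per_tissue = 300,
                          mait_freq = c(blood = 0.05, normal = 0.10, tumor = 0.05),
                          subset_props = c(CD8 = 0.45, CD4 = 0.35, Treg = 0.20),
                          cells_per_subset = NULL,
                          n_background = 200,
                          mait_marker_lfc = 2,
                          decoys_per_stratum = 0,
                          decoy_lfc = NULL,
                          noise = c("umi", "tpm"),
                          nb_dispersion = 0.3,
                          tpm_sigma = 0.5,
                          clone_geom_p = 0.6,
                          traj_probs = c(TRAJ33 = 0.85, TRAJ12 = 0.10, TRAJ20 = 0.05),
                          treatment = FALSE,
                          expanded_clones_per_patient = 1,
                          expansion_factor = 6) {
  noise <- match.arg(noise)
  seed <- check_seed(seed)
  assert_prob(mait_freq[tissues], "mait_freq")
  assert_prob(clone_geom_p, "clone_geom_p")
  if (!is.null(cells_per_subset) && cells_per_subset < 1) {
    abort("`cells_per_subset` must be positive.")
  }
  if (all(mait_freq[tissues] == 0) && is.null(cells_per_subset)) {
    abort("The clonal model needs MAIT cells; all configured MAIT frequencies are zero.")
  }
  structure(as.list(environment()), class = "sc_sim_config")
}

# Geometric clone sizes (>= 1) covering n cells; the last clone is trimmed.
draw_clone_sizes <- function(n, p) {
  sizes <- integer(0)
  while (sum(sizes) < n) {
    sizes <- c(sizes, stats::rgeom(max(16, n %/% 2), p) + 1L)
  }
  cum <- cumsum(sizes)
  k <- which(cum >= n)[1]
  sizes <- sizes[seq_len(k)]
  sizes[k] <- sizes[k] - (cum[k] - n)
  sizes[sizes > 0]
}

#' Generate a synthetic single-cell TCR + expression dataset
#'
#' Emits a counts (and log2-CPM) expression matrix, per-cell annotations,
#' TCR contig records and ground-truth tables. MAIT cells carry a
#' productive TRAV1-2 alpha chain joined to TRAJ33/12/20 and elevated
#' planted marker genes; non-MAIT cells carry other V/J combinations
#' (including TRAV1-2 with non-MAIT J segments, and MAIT-J segments with
#' other V genes, as negative controls). MAIT clonotype memberships follow
#' a geometric size distribution within patient, so larger clones span
#' tissue compartments.
#'
#' @param config An [sc_sim_config()].
#' @return A list: `matrix` ([expr_matrix()] with `counts` and `normexpr`),
#'   `annotations` (tibble; includes a `cancer` column), `contigs`
#'   (tibble), and `truth` (list with `markers`, `decoys`, `clones`,
#'   `config`).
#' @export
generate_sc_dataset <- function(config) {
  stopifnot(inherits(config, "sc_sim_config"))
  gs <- mait_gene_sets()
  with_seed(config$seed, {
    strata <- expand.grid(cancer = config$cancers, tissue = config$tissues,
                          stringsAsFactors = FALSE)
    n_decoys <- config$decoys_per_stratum * nrow(strata)
    decoy_genes <- if (n_decoys) sprintf("DECOY_%03d", seq_len(n_decoys)) else character()
    decoy_map <- if (n_decoys) {
      tibble(gene = decoy_genes,
             cancer = rep(strata$cancer, each = config$decoys_per_stratum),
             tissue = rep(strata$tissue, each = config$decoys_per_stratum))
    } else tibble(gene = character(), cancer = character(), tissue = character())
    bg_genes <- sprintf("BG_%04d", seq_len(config$n_background))
    genes <- c(gs$mait_signature, gs$pan_t_genes, gs$nk_genes,
               decoy_genes, bg_genes)

    base_mean <- setNames(exp(rnorm(length(genes), log(2), 1)), genes)
    base_mean[gs$mait_signature] <- exp(rnorm(11, log(3), 0.5))
    base_mean[decoy_genes] <- exp(rnorm(n_decoys, log(3), 0.5))
    base_mean[gs$pan_t_genes] <- 30    # pan-T: high in every T cell
    base_mean[gs$nk_genes] <- 0.3      # NK markers: low in T cells

    # --- cell frame -------------------------------------------------------
    subsets_nonmait <- names(config$subset_props)
    cells <- purrr::pmap_dfr(
      expand.grid(cancer = config$cancers,
                  patient = seq_len(config$patients),
                  tissue = config$tissues, stringsAsFactors = FALSE),
      function(cancer, patient, tissue) {
        if (!is.null(config$cells_per_subset)) {
          subset <- rep(c("MAIT", subsets_nonmait),
                        each = config$cells_per_subset)
        } else {
          n <- config$cells_per_tissue
          p_mait <- config$mait_freq[[tissue]]
          probs <- c(p_mait, (1 - p_mait) * config$subset_props /
                       sum(config$subset_props))
          subset <- sample(c("MAIT", subsets_nonmait), n, replace = TRUE,
                           prob = probs)
        }
        tibble(cancer = cancer,
               patient_id = sprintf("%s_p%02d", cancer, patient),
               tissue = tissue, subset = subset)
      }) |>
      mutate(cell_id = sprintf("cell_%06d", dplyr::row_number()),
             treatment = "not_applicable")

    # --- treatment labels (tumor compartment) -----------------------------
    if (config$treatment) {
      tum <- cells$tissue == "tumor"
      cells$treatment[tum] <- sample(c("pre", "post"), sum(tum), replace = TRUE)
    }

    # --- expression -------------------------------------------------------
    mu <- matrix(base_mean, nrow = length(genes), ncol = nrow(cells),
                 dimnames = list(genes, cells$cell_id))
    is_mait <- cells$subset == "MAIT"
    mu[gs$mait_signature, is_mait] <-
      mu[gs$mait_signature, is_mait] * 2^config$mait_marker_lfc
    if (n_decoys) {
      dlfc <- config$decoy_lfc %||% config$mait_marker_lfc
      for (r in seq_len(nrow(decoy_map))) {
        sel <- is_mait & cells$cancer == decoy_map$cancer[r] &
          cells$tissue == decoy_map$tissue[r]
        mu[decoy_map$gene[r], sel] <- mu[decoy_map$gene[r], sel] * 2^dlfc
      }
    }
    size_factor <- exp(rnorm(nrow(cells), 0, 0.3))
    mu <- sweep(mu, 2, size_factor, "*")
    if (config$noise == "umi") {
      counts <- matrix(rnbinom(length(mu), mu = mu,
                               size = 1 / config$nb_dispersion),
                       nrow = nrow(mu), dimnames = dimnames(mu))
    } else {
      # TPM-like: log-normal around the rate, rounded to pseudo-counts
      counts <- matrix(round(mu * 2^rnorm(length(mu), 0, config$tpm_sigma)),
                       nrow = nrow(mu), dimnames = dimnames(mu))
    }
    # guard: normalization requires non-empty cells
    empty <- colSums(counts) == 0
    if (any(empty)) counts[1, empty] <- 1
    mat <- normalize_log_cpm(expr_matrix(counts = counts))

    # --- TCR --------------------------------------------------------------
    trav_pool <- c("TRAV8-1", "TRAV12-1", "TRAV13-1", "TRAV21", "TRAV29",
                   "TRAV38-2", "TRAV1-2")
    traj_pool <- c("TRAJ58", "TRAJ10", "TRAJ42", "TRAJ49", "TRAJ33")
    trbv_pool <- c("TRBV6-1", "TRBV20-1", "TRBV19", "TRBV4-2", "TRBV9",
                   "TRBV11-2", "TRBV27", "TRBV28", "TRBV5-1")
    mait_trbv_probs <- c(0.28, 0.25, 0.12, 0.10, 0.07, 0.07, 0.05, 0.03, 0.03)

    contigs <- list(); clone_rows <- list()
    for (pid in unique(cells$patient_id)) {
      idx <- which(cells$patient_id == pid & is_mait)
      if (length(idx)) {
        sizes <- draw_clone_sizes(length(idx), config$clone_geom_p)
        clone_ids <- sprintf("%s_mait_clone%03d", pid, seq_along(sizes))
        assign_weights <- rep(1, length(sizes))
        if (config$treatment && length(sizes) > 1) {
          expanded <- order(sizes, decreasing = TRUE)[
            seq_len(min(config$expanded_clones_per_patient, length(sizes)))]
        } else expanded <- integer(0)
        # draw per-cell clone membership; post-treatment cells favor
        # expanded clones
        base_w <- rep(sizes, times = 1)
        cell_clone <- integer(length(idx))
        is_post <- cells$treatment[idx] == "post"
        w_pre <- base_w
        w_post <- base_w
        w_post[expanded] <- w_post[expanded] * config$expansion_factor
        cell_clone[!is_post] <- sample(seq_along(sizes), sum(!is_post),
                                       replace = TRUE, prob = w_pre)
        if (any(is_post)) {
          cell_clone[is_post] <- sample(seq_along(sizes), sum(is_post),
                                        replace = TRUE, prob = w_post)
        }
        # clone-level chains
        cj <- sample(names(config$traj_probs), length(sizes), replace = TRUE,
                     prob = config$traj_probs)
        ca <- random_seq(length(sizes), 18)
        cbv <- sample(trbv_pool, length(sizes), replace = TRUE,
                      prob = mait_trbv_probs)
        cb <- random_seq(length(sizes), 21)
        contigs[[length(contigs) + 1]] <- tibble(
          cell_id = rep(cells$cell_id[idx], 2),
          locus = rep(c("TRA", "TRB"), each = length(idx)),
          v_gene = c(rep("TRAV1-2", length(idx)), cbv[cell_clone]),
          j_gene = c(cj[cell_clone], rep("TRBJ2-6", length(idx))),
          cdr3_nt = c(ca[cell_clone], cb[cell_clone]),
          cdr3_aa = NA_character_, productive = TRUE
        )
        clone_rows[[length(clone_rows) + 1]] <- tibble(
          cell_id = cells$cell_id[idx],
          true_clone = clone_ids[cell_clone],
          expanded = cell_clone %in% expanded
        )
      }
      # non-MAIT cells: unique chains per cell; TRAV1-2 appears with
      # non-MAIT J segments only (negative controls for the classifier)
      idx2 <- which(cells$patient_id == pid & !is_mait)
      if (length(idx2)) {
        av <- sample(trav_pool, length(idx2), replace = TRUE)
        aj <- ifelse(av == "TRAV1-2",
                     sample(setdiff(traj_pool, "TRAJ33"), length(idx2), replace = TRUE),
                     sample(traj_pool, length(idx2), replace = TRUE))
        contigs[[length(contigs) + 1]] <- tibble(
          cell_id = rep(cells$cell_id[idx2], 2),
          locus = rep(c("TRA", "TRB"), each = length(idx2)),
          v_gene = c(av, sample(trbv_pool, length(idx2), replace = TRUE)),
          j_gene = c(aj, rep("TRBJ1-1", length(idx2))),
          cdr3_nt = c(random_seq(length(idx2), 18), random_seq(length(idx2), 21)),
          cdr3_aa = NA_character_, productive = TRUE
        )
        clone_rows[[length(clone_rows) + 1]] <- tibble(
          cell_id = cells$cell_id[idx2],
          true_clone = paste0(cells$cell_id[idx2], "_single"),
          expanded = FALSE
        )
      }
    }

    annotations <- cells |>
      select("cell_id", "patient_id", "cancer", "tissue", "subset", "treatment")
    list(
      matrix = mat,
      annotations = annotations,
      contigs = bind_rows(contigs) |> arrange(.data$cell_id, .data$locus),
      truth = list(markers = gs$mait_signature, decoys = decoy_map,
                   clones = bind_rows(clone_rows), config = config)
    )
  })
}

#' Configuration for the synthetic bulk survival cohort
#'
#' Samples are cell mixtures: subset fractions drawn from a Dirichlet
#' (tumor/stroma in `other`), expression as the fraction-weighted mixture
#' of subset profiles with log-normal noise on the log2(TPM + 1) scale, and
#' survival times from an exponential hazard scaled by
#' `exp(beta x standardized true MAIT fraction)` with independent
#' exponential censoring calibrated to the requested censoring fraction.
#'
#' @param seed Integer seed (required).
#' @param n_samples Cohort size.
#' @param dirichlet_alpha Dirichlet concentration per subset.
#' @param n_background Background genes.
#' @param mait_marker_lfc Planted log2 elevation of MAIT signature genes in
#'   the MAIT profile (default 5: these genes are near-exclusive to MAIT
#'   cells, so their bulk signal scales with MAIT content).
#' @param immune_load_sigma SD (log scale) of the per-sample immune-load
#'   factor multiplying all T/NK subset fractions before renormalization
#'   (default 0.8). Tumors differ strongly in overall lymphocyte
#'   infiltration (leukocyte fractions span roughly 5-50%), which is what
#'   couples pan-T and MAIT marker levels in real cohorts.
#' @param mr1_coupling Linear coupling of MR1 expression to the MAIT
#'   fraction (0 disables the planted association).
#' @param beta Planted log-hazard per SD of true MAIT fraction.
#' @param baseline_hazard Events per day at the cohort mean (default
#'   1/1500).
#' @param censoring Target censored fraction in \[0, 1) (default 0.3).
#' @param noise_sigma SD of log-normal noise on log2(TPM+1) (default 0.5).
#' @return A `bulk_sim_config` list.
#' @export
bulk_sim_config <- function(seed,
                            n_samples = 600,
                            dirichlet_alpha = c(MAIT = 1.5, CD8 = 8, CD4 = 8,
                                                Treg = 3, NK = 2, other = 18),
                            n_background = 100,
                            immune_load_sigma = 0.8,
                            mait_marker_lfc = 5,
                            mr1_coupling = 10,
                            beta = 0.5,
                            baseline_hazard = 1 / 1500,
                            censoring = 0.3,
                            noise_sigma = 0.5) {
  seed <- check_seed(seed)
  if (censoring < 0 || censoring >= 1) abort("`censoring` must lie in [0, 1).")
  if (n_samples < 2) abort("`n_samples` must be at least 2.")
  structure(as.list(environment()), class = "bulk_sim_config")
}

# Exponential censoring rate such that the expected censored fraction over
# the realized hazards equals `target`.
solve_censor_rate <- function(rates, target) {
  if (target == 0) return(0)
  f <- function(rc) mean(rc / (rc + rates)) - target
  uniroot(f, lower = min(rates) * 1e-6, upper = max(rates) * 1e6,
          tol = 1e-12)$root
}

#' Generate a synthetic bulk cohort with survival endpoints
#'
#' @param config A [bulk_sim_config()].
#' @return A list: `cohort` (a [bulk_cohort()]) and `truth` (tibble of
#'   per-sample subset fractions and the standardized MAIT fraction
#'   `mait_z` driving the hazard, plus the config).
#' @export
generate_bulk_cohort <- function(config) {
  stopifnot(inherits(config, "bulk_sim_config"))
  gs <- mait_gene_sets()
  with_seed(config$seed, {
    subsets <- names(config$dirichlet_alpha)
    fr <- rdirichlet(config$n_samples, config$dirichlet_alpha)
    # shared immune-load factor: scales lymphocyte fractions jointly
    lymph <- setdiff(subsets, "other")
    if (config$immune_load_sigma > 0 && length(lymph)) {
      load <- exp(rnorm(config$n_samples, 0, config$immune_load_sigma))
      fr[, lymph] <- fr[, lymph] * load
      fr <- fr / rowSums(fr)
    }
    bg <- sprintf("BG_%04d", seq_len(config$n_background))
    genes <- c(gs$mait_signature, gs$pan_t_genes, gs$nk_genes, "MR1", bg)

    # subset profiles on a linear TPM scale
    base <- setNames(exp(rnorm(length(genes), log(20), 1)), genes)
    prof <- matrix(base, nrow = length(genes), ncol = length(subsets),
                   dimnames = list(genes, subsets))
    prof[, "other"] <- prof[, "other"] * exp(rnorm(length(genes), 0, 0.2))
    t_subsets <- intersect(c("MAIT", "CD8", "CD4", "Treg"), subsets)
    # MAIT markers: moderate background level (these genes are detectable
    # in bulk tumors) sharply elevated in the MAIT profile
    marker_base <- exp(rnorm(11, log(4), 0.5))
    prof[gs$mait_signature, ] <- marker_base
    prof[gs$mait_signature, "MAIT"] <- marker_base * 2^config$mait_marker_lfc
    prof[gs$pan_t_genes, ] <- 1
    prof[gs$pan_t_genes, t_subsets] <- base[gs$pan_t_genes] * 5
    prof[gs$nk_genes, ] <- 1
    if ("NK" %in% subsets) prof[gs$nk_genes, "NK"] <- base[gs$nk_genes] * 5

    tpm <- fr %*% t(prof)                       # samples x genes
    mait_f <- fr[, "MAIT"]
    tpm[, "MR1"] <- tpm[, "MR1"] * (1 + config$mr1_coupling * mait_f)
    expr <- log2(tpm + 1) +
      matrix(rnorm(length(tpm), 0, config$noise_sigma), nrow = nrow(tpm))
    rownames(expr) <- sprintf("s_%04d", seq_len(config$n_samples))

    mait_z <- if (sd(mait_f) > 0) as.vector(scale(mait_f)) else rep(0, length(mait_f))
    rates <- config$baseline_hazard * exp(config$beta * mait_z)
    draw_endpoint <- function(rate_scale) {
      tt <- rexp(config$n_samples, rates * rate_scale)
      rc <- solve_censor_rate(rates * rate_scale, config$censoring)
      cc <- if (rc > 0) rexp(config$n_samples, rc) else rep(Inf, config$n_samples)
      list(time = round(pmin(tt, cc), 1), event = as.integer(tt <= cc))
    }
    os <- draw_endpoint(1)
    pfs <- draw_endpoint(2)  # progression precedes death on average
    clinical <- tibble(
      sample_id = rownames(expr),
      os_time = os$time, os_event = os$event,
      pfs_time = pfs$time, pfs_event = pfs$event
    )
    truth <- dplyr::bind_cols(
      tibble(sample_id = rownames(expr)),
      as_tibble(fr), tibble(mait_z = mait_z)
    )
    list(cohort = bulk_cohort(expr, clinical),
         truth = truth, config = config)
  })
}
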