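#' Configuration of a simulation study of accuracy erosion
#'
#' Describes the full experiment: a base reference population, descendant
#' target populations separated by one to many generations of random
#' mating, and replicated phenotypes over a grid of heritabilities. The
#' defaults are a desk-scale version of a large livestock-style design
#' (they run in minutes; all sizes are configurable upward).
#'
#' @param n_reference size of the base (phenotyped) reference population;
#'   intermediate generations are bred at this size too.
#' @param n_target size of each target population, sampled from the
#'   generations in `target_generations`.
#' @param target_generations generation gaps at which target populations
#'   are taken (default 1, 5, 10).
#' @param h2_grid true heritabilities for the replicated phenotypes.
#' @param sigma2_y phenotypic variance (default 100).
#' @param n_snps,n_chromosomes,map_length,ld_decay,freq_range founder
#'   simulator settings, see [ld_model()].
#' @param n_qtl causal variants per trait (drawn once per study).
#' @param n_replicates phenotype replicates per heritability.
#' @param matrices relationship matrices to analyse, subset of
#'   `c("A", "G", "H")`.
#' @param genotyped_fraction_ref fraction of the reference population
#'   treated as genotyped when building H (targets are always genotyped).
#' @param a_max_depth pedigree depth for A, see [build_A()].
#' @param h_blend_beta blending weight for H, see [build_H()].
#' @param igc_h2_grid heritability grid of the simulated-phenotype IGC.
#' @param igc_reps_per_h2 phenotype replicates per heritability inside the
#'   simulated-phenotype IGC; at desk scale a single replicate leaves the
#'   slope with a Monte-Carlo SD of ~0.03, so the study averages several.
#' @param seed integer seed driving the whole study.
#' @return An object of class `study_config`.
#' @export
study_config <- function(n_reference = 1000, n_target = 300,
                         target_generations = c(1, 5, 10),
                         h2_grid = seq(0.05, 0.95, by = 0.1),
                         sigma2_y = 100, n_snps = 5000, n_chromosomes = 10,
                         map_length = 100, ld_decay = 5,
                         freq_range = c(0.05, 0.95), n_qtl = 500,
                         n_replicates = 100, matrices = "G",
                         genotyped_fraction_ref = 0.25, a_max_depth = 3,
                         h_blend_beta = 0.95,
                         igc_h2_grid = seq(0.1, 0.9, by = 0.1),
                         igc_reps_per_h2 = 5, seed = 1) {
  stopifnot(n_reference >= 30, n_target >= 10, all(target_generations >= 1),
            all(h2_grid > 0 & h2_grid < 1), sigma2_y > 0, n_replicates >= 1,
            all(matrices %in% c("A", "G", "H")),
            genotyped_fraction_ref > 0, genotyped_fraction_ref <= 1)
  if (n_qtl > n_snps) stop("n_qtl exceeds n_snps")
  structure(as.list(environment()), class = "study_config")
}

## fast eigen-space version of expected_R_gblup; algebraically identical to
## the dense formula (asserted in the tests):
## diag term_i = rowSums(B21^2 * s2g / (lam * s2g + s2e))
.gblup_expect_eig <- function(lam, B21sq, s2g, s2e, h2_hat) {
  d <- drop(B21sq %*% (s2g / (lam * s2g + s2e)))
  sqrt(h2_hat) / nrow(B21sq) * sum(sqrt(pmax(d, 0)))
}

#' Run the accuracy-erosion simulation study
#'
#' Simulates one base population and its descendant generations, computes
#' the index of genetic correlation per (matrix, generation gap) by both
#' estimators where genotypes allow, then replicates phenotypes across the
#' heritability grid: each replicate is analysed by REML, BLUP breeding
#' values and target predictions, realized accuracies, the erosion
#' expectation and the GBLUP reference expectation.
#'
#' @param config a [study_config()].
#' @param out_dir optional directory; when given, writes `records.csv`,
#'   `summary.csv`, `igc.json` and `provenance.json`.
#' @return List with `records` (one row per replicate x heritability x
#'   generation x matrix), `summary` (cell means and SDs), `igc` (per
#'   matrix and generation: both estimators, the GBLUP comparator, and the
#'   value used), and the `config`.
#' @export
run_study <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  set.seed(config$seed)
  model <- ld_model(config$n_snps, config$n_chromosomes, config$map_length,
                    config$ld_decay, config$freq_range)

  ## --- population: base + generations of random mating, no selection
  pop <- simulate_founders(model, config$n_reference)
  ref_geno <- pop$geno
  targets <- list()
  for (gen in seq_len(max(config$target_generations))) {
    pop <- advance_generation(pop, config$n_reference)
    if (gen %in% config$target_generations) {
      ids <- sample(sample_ids(pop$geno), config$n_target)
      targets[[as.character(gen)]] <- subset_samples(pop$geno, ids)
    }
  }
  ped <- pop$ped

  all_dos <- do.call(rbind, c(list(ref_geno$dosages),
                              lapply(targets, function(g) g$dosages)))
  combined <- geno_matrix(all_dos, ref_geno$chrom, ref_geno$pos_cM)
  ref_ids <- sample_ids(ref_geno)
  qtl_ids <- sample(variant_ids(combined), config$n_qtl)

  ## --- relationship matrices over reference + all targets
  W_list <- list()
  if (any(c("G", "H") %in% config$matrices)) {
    Mc <- center_scale(combined)          # combined allele frequencies
    G_all <- build_G(Mc)
  }
  if ("G" %in% config$matrices) W_list$G <- G_all
  if (any(c("A", "H") %in% config$matrices))
    A_all <- build_A(ped, ids = rownames(all_dos), max_depth = config$a_max_depth)
  if ("A" %in% config$matrices) W_list$A <- A_all
  if ("H" %in% config$matrices) {
    gt_ids <- c(sample(ref_ids, round(config$genotyped_fraction_ref *
                                        length(ref_ids))),
                unlist(lapply(targets, sample_ids), use.names = FALSE))
    W_list$H <- build_H(A_all, G_all[gt_ids, gt_ids], gt_ids,
                        config$h_blend_beta)
  }

  ## --- IGC per matrix kind and generation gap
  igc_rows <- list()
  records <- list()
  caches <- list()
  for (kind in names(W_list)) {
    W <- W_list[[kind]]
    for (gen in config$target_generations) {
      tar_ids <- sample_ids(targets[[as.character(gen)]])
      split <- population_partition(ref_ids, tar_ids)

      r_svd_val <- NA_real_
      if (kind == "G") {
        p1 <- allele_freqs(ref_geno)
        p2 <- allele_freqs(targets[[as.character(gen)]])
        poly <- p1 > 0 & p1 < 1 & p2 > 0 & p2 < 1
        M1 <- center_scale(ref_geno$dosages[, poly, drop = FALSE])
        M2 <- center_scale(targets[[as.character(gen)]]$dosages[, poly, drop = FALSE])
        r_svd_val <- igc_svd(M1, M2)$r
      }
      r_sim <- igc_simphen(W, split, h2_grid = config$igc_h2_grid,
                           sigma2_y = config$sigma2_y,
                           reps_per_h2 = config$igc_reps_per_h2,
                           geno = if (kind == "G") combined else NULL,
                           n_qtl = if (kind == "G") config$n_qtl else NULL)$r
      blocks <- partition_W(W, split)
      eig <- eigen(blocks$W11, symmetric = TRUE)
      lam <- pmax(eig$values, 0)
      B21 <- blocks$W21 %*% eig$vectors
      r_gb <- mean(sqrt(pmax(drop((B21^2) %*%
                                    (1 / pmax(lam, 1e-10 * max(lam)))), 0)))
      r_used <- if (kind == "G") r_svd_val else r_sim
      igc_rows[[length(igc_rows) + 1L]] <-
        data.frame(matrix = kind, generation_gap = gen, r_svd = r_svd_val,
                   r_simphen = r_sim, r_gblup = r_gb, r_used = r_used)

      ## cache what the replicate loop needs
      caches[[kind]][[as.character(gen)]] <-
        list(eig = eig, lam = lam, B21 = B21, B21sq = B21^2,
             tar_ids = tar_ids, r_used = r_used)
    }
  }

  ## --- replicated phenotypes: REML, BLUP, accuracies, expectations
  for (rep_i in seq_len(config$n_replicates)) {
    for (h2 in config$h2_grid) {
      trait <- simulate_trait(combined,
                              trait_config(h2, config$sigma2_y, qtl_ids = qtl_ids))
      y1 <- trait$y[ref_ids]
      for (kind in names(W_list)) {
        first <- TRUE
        for (gen in config$target_generations) {
          cache <- caches[[kind]][[as.character(gen)]]
          if (first) {  # REML and reference accuracy shared across gaps
            vc <- estimate_reml(y1, eig = cache$eig)
            yt <- drop(crossprod(cache$eig$vectors, y1))
            bv1 <- .blup_eig(yt, cache$eig, NULL, vc$sigma2_g, vc$sigma2_e)
            rho_raw <- stats::cor(bv1$g_hat_ref, y1)
            rho_hat <- rho_cap(rho_raw, vc$h2)
            first <- FALSE
          }
          g2 <- drop(cache$B21 %*% (vc$sigma2_g * yt /
                                      (cache$lam * vc$sigma2_g + vc$sigma2_e)))
          R <- stats::cor(g2, trait$y[cache$tar_ids])
          records[[length(records) + 1L]] <- data.frame(
            replicate = rep_i, matrix = kind, generation_gap = gen,
            h2_true = h2, h2_hat = vc$h2, rho_hat = rho_hat,
            R_realized = R,
            expected_R_erosion = expected_R_erosion(rho_hat, cache$r_used),
            expected_R_gblup = .gblup_expect_eig(cache$lam, cache$B21sq,
                                                 vc$sigma2_g, vc$sigma2_e,
                                                 vc$h2),
            r_used = cache$r_used)
        }
      }
    }
  }
  records <- do.call(rbind, records)
  igc <- do.call(rbind, igc_rows)

  agg <- function(f) stats::aggregate(
    records[c("h2_hat", "rho_hat", "R_realized", "expected_R_erosion",
              "expected_R_gblup")],
    records[c("matrix", "generation_gap", "h2_true")], f)
  means <- agg(mean); sds <- agg(stats::sd)
  names(sds)[-(1:3)] <- paste0(names(sds)[-(1:3)], "_sd")
  summary_df <- merge(means, sds, by = c("matrix", "generation_gap", "h2_true"))
  summary_df <- summary_df[order(summary_df$matrix, summary_df$generation_gap,
                                 summary_df$h2_true), ]

  out <- list(records = records, summary = summary_df, igc = igc,
              config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(records, file.path(out_dir, "records.csv"), row.names = FALSE)
    utils::write.csv(summary_df, file.path(out_dir, "summary.csv"), row.names = FALSE)
    jsonlite::write_json(igc, file.path(out_dir, "igc.json"), digits = NA)
    cfg_file <- tempfile()
    writeLines(deparse(unclass(config)), cfg_file)
    jsonlite::write_json(
      list(seed = config$seed,
           config = unclass(config),
           config_hash = unname(tools::md5sum(cfg_file)),
           package_version = as.character(utils::packageVersion("breedacc")),
           r_version = R.version.string),
      file.path(out_dir, "provenance.json"), auto_unbox = TRUE, digits = NA)
    unlink(cfg_file)
  }
  out
}
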