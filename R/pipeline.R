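# End-to-end orchestration: simulate -> within-lineage DE -> orthogroup
# convergence -> GO enrichment -> co-expression network -> ordination, with
# deterministic outputs and a run manifest.

#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end run. A single seed governs all
#' stochastic stages; stage s draws its own seed as `seed + 1000 * s`, so
#' stages are reproducible independently of one another.
#'
#' @param out_dir output directory (created if missing).
#' @param seed master integer seed (mandatory).
#' @param alpha DE significance threshold on the q-value (default 0.05).
#' @param min_cpm,min_samples expression filter (defaults 2 and 3).
#' @param beta soft-thresholding power, `"auto"` (scale-free criterion) or
#'   an integer.
#' @param min_module_size minimum co-expression module size (default 30).
#' @param merge_cor eigengene correlation above which modules merge
#'   (default 0.9).
#' @param module_p module-trait correlation retention threshold
#'   (default 0.01).
#' @param min_k minimum lineage count for the shared DE set (default 3).
#' @param fixed_dispersion dispersion for lineages without replicates
#'   (default 0.1).
#' @param wgcna_top_genes number of highest-SD genes entering the network
#'   (default 1500).
#' @param mds_top_genes number of highest-SD genes for MDS (default 10000,
#'   capped at the feature count).
#' @param sim a [multilineage_config()]; defaults to the study-design
#'   defaults seeded from `seed`.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed, alpha = 0.05, min_cpm = 2,
                            min_samples = 3, beta = "auto",
                            min_module_size = 30, merge_cor = 0.9,
                            module_p = 0.01, min_k = 3,
                            fixed_dispersion = 0.1, wgcna_top_genes = 1500,
                            mds_top_genes = 10000, sim = NULL) {
  assert_that(!missing(seed), "seed is mandatory")
  assert_that(alpha > 0 && alpha <= 1, "alpha must lie in (0, 1]")
  assert_that(merge_cor > 0 && merge_cor < 1, "merge_cor must lie in (0, 1)")
  assert_that(module_p > 0 && module_p < 1, "module_p must lie in (0, 1)")
  if (is.null(sim)) sim <- multilineage_config(seed = as.integer(seed) + 1000L)
  assert_that(min_k >= 2 && min_k <= sim$n_lineages,
              "min_k must lie in [2, n_lineages]")
  structure(list(out_dir = out_dir, seed = as.integer(seed), alpha = alpha,
                 min_cpm = min_cpm, min_samples = min_samples, beta = beta,
                 min_module_size = min_module_size, merge_cor = merge_cor,
                 module_p = module_p, min_k = min_k,
                 fixed_dispersion = fixed_dispersion,
                 wgcna_top_genes = wgcna_top_genes,
                 mds_top_genes = mds_top_genes, sim = sim),
            class = "pipeline_config")
}

#' Run the full comparative analysis pipeline
#'
#' Executes, in dependency order: (1) multi-lineage count simulation;
#' (2) within-lineage gene-level DE for the focal (first) lineage;
#' (3) MDS of the focal lineage's samples; (4) orthogroup aggregation,
#' universal-expression retention, per-lineage DE and directional
#' intersection analysis; (5) GO over-representation of the focal up/down
#' sets and of orthogroups shared in `>= min_k` lineages, against planted
#' annotations; (6) co-expression network analysis of the focal lineage;
#' (7) cross-population profile clustering and joint orthogroup MDS. All
#' tables are written to `out_dir` as TSV and a manifest records the seed,
#' a hash of the configuration, per-stage row counts and output checksums;
#' reruns with the same configuration are bit-identical.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) list with all stage objects plus `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(config$out_dir, f)
  counts_of_stage <- list()

  # stage 1: simulate
  sim <- simulate_multilineage(config$sim)
  for (sp in names(sim$count_matrices)) {
    write_count_matrix(sim$count_matrices[[sp]],
                       path(sprintf("counts_%s.csv", sp)))
  }
  write_sample_sheet(sim$sample_sheet, path("samples.tsv"))
  write_orthogroup_map(sim$orthogroup_map, path("orthogroups.tsv"))
  counts_of_stage$simulate <- length(sim$count_matrices)

  # stage 2: focal-lineage gene-level DE
  focal <- names(sim$count_matrices)[1L]
  de <- run_de(sim$count_matrices[[focal]], sim$sample_sheet,
               alpha = config$alpha, min_cpm = config$min_cpm,
               min_samples = config$min_samples,
               fixed_dispersion = config$fixed_dispersion)
  write_table(de, path("de_focal.tsv"))
  counts_of_stage$de_focal <- nrow(de)

  # stage 3: focal MDS on the highest-SD genes
  Yf <- sim$count_matrices[[focal]]$counts[de$feature_id, , drop = FALSE]
  norm_f <- tmm_factors(Yf)
  expr_f <- expression_transform(Yf, norm = norm_f)
  mds_f <- expression_mds(expr_f, top = min(config$mds_top_genes, nrow(expr_f)))
  sheet_f <- as.data.frame(sim$sample_sheet)
  sheet_f <- sheet_f[match(rownames(mds_f$points), sheet_f$sample_id), ]
  write_table(data.frame(sample_id = rownames(mds_f$points),
                         mds_f$points, habitat = sheet_f$habitat,
                         species = sheet_f$species, check.names = FALSE),
              path("mds_focal.tsv"))
  counts_of_stage$mds_focal <- nrow(mds_f$points)

  # stage 4: orthogroup convergence
  ortho <- aggregate_to_orthogroups(sim$count_matrices, sim$orthogroup_map)
  retained <- filter_universal_expressed(ortho)
  ortho_r <- subset_orthogroups(ortho, retained)
  de_lineages <- per_lineage_de(ortho_r, sim$sample_sheet,
                                alpha = config$alpha,
                                fixed_dispersion = config$fixed_dispersion)
  report <- intersect_directional(de_lineages)
  write_table(convergence_table(report), path("convergence.tsv"))
  shared <- shared_in_at_least(report, config$min_k)
  counts_of_stage$retained_orthogroups <- length(retained)
  counts_of_stage$shared_min_k <- length(shared)

  # stage 5: GO enrichment against planted annotations
  go_gene <- simulate_go_annotation(de$feature_id,
                                    de$feature_id[de$direction == "up"],
                                    seed = config$seed + 5000L)
  enr_up <- hypergeom_enrichment(de$feature_id[de$direction == "up"],
                                 de$feature_id, go_gene$annotation)
  enr_down <- hypergeom_enrichment(de$feature_id[de$direction == "down"],
                                   de$feature_id, go_gene$annotation)
  write_table(enr_up, path("enrichment_up.tsv"))
  write_table(enr_down, path("enrichment_down.tsv"))
  if (length(shared) >= 2L) {
    go_og <- simulate_go_annotation(retained, shared,
                                    seed = config$seed + 5001L)
    enr_shared <- hypergeom_enrichment(shared, retained, go_og$annotation)
    write_table(enr_shared, path("enrichment_shared.tsv"))
  } else {
    enr_shared <- NULL
  }
  counts_of_stage$enrichment_up <- nrow(enr_up)

  # stage 6: co-expression network on the focal lineage
  net_genes <- top_sd_genes(expr_f, k = min(config$wgcna_top_genes,
                                            nrow(expr_f)))
  expr_net <- expr_f[net_genes, , drop = FALSE]
  if (identical(config$beta, "auto")) {
    scan <- soft_threshold_scan(expr_net)
    beta <- scan$selected
    write_table(scan$scan, path("beta_scan.tsv"))
  } else {
    scan <- NULL
    beta <- as.numeric(config$beta)
  }
  A <- adjacency_matrix(expr_net, beta)
  tom <- tom_similarity(A)
  modules <- cut_modules(1 - tom, min_module_size = config$min_module_size)
  modules <- refine_modules_kme(expr_net, modules)
  modules <- merge_modules(expr_net, modules, cor_threshold = config$merge_cor)
  trait <- as.numeric(sheet_f$habitat[match(colnames(expr_net),
                                            sheet_f$sample_id)] == "SW")
  if (any(modules$labels > 0)) {
    mt <- module_trait_correlation(modules$eigengenes, trait,
                                   p_threshold = config$module_p)
    write_table(mt, path("module_trait.tsv"))
    write_table(data.frame(module = rownames(modules$eigengenes),
                           modules$eigengenes, check.names = FALSE),
                path("eigengenes.tsv"))
  } else {
    mt <- NULL
  }
  k_in <- intramodular_connectivity(A, modules$labels)
  write_table(data.frame(gene_id = names(modules$labels),
                         module = unname(modules$labels),
                         intramodular_k = unname(k_in)),
              path("modules.tsv"))
  counts_of_stage$modules <- length(unique(modules$labels[modules$labels > 0]))

  # stage 7: cross-population ordination
  profiles <- population_mean_profiles(ortho_r, sim$sample_sheet)
  pop_clust <- population_profile_clustering(profiles)
  writeLines(pop_clust$newick, path("population_tree.nwk"))
  write_table(data.frame(population = rownames(pop_clust$similarity),
                         pop_clust$similarity, check.names = FALSE),
              path("population_similarity.tsv"))
  counts_of_stage$populations <- ncol(profiles)

  # manifest: versions, seed, config hash, stage row counts, checksums
  cfg_hash <- md5_of_string(paste(deparse(config[setdiff(names(config),
                                                         "out_dir")]),
                                  collapse = "\n"))
  outputs <- sort(setdiff(list.files(config$out_dir), "manifest.tsv"))
  sums <- tools::md5sum(file.path(config$out_dir, outputs))
  manifest <- data.frame(
    key = c("package_version", "seed", "config_md5",
            paste0("n_", names(counts_of_stage)),
            paste0("md5_", outputs)),
    value = c(as.character(utils::packageVersion("orthoconverge")),
              as.character(config$seed), cfg_hash,
              as.character(unlist(counts_of_stage)), unname(sums)),
    stringsAsFactors = FALSE)
  write_table(manifest, path("manifest.tsv"))

  invisible(list(sim = sim, de_focal = de, mds_focal = mds_f,
                 ortho = ortho_r, retained = retained,
                 de_lineages = de_lineages, report = report,
                 shared = shared, enrichment_up = enr_up,
                 enrichment_down = enr_down, enrichment_shared = enr_shared,
                 beta = beta, beta_scan = scan, modules = modules,
                 module_trait = mt, population_clustering = pop_clust,
                 manifest = manifest))
}
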