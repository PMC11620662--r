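test_that("simulator output is reproducible and self-consistent", {
  cfg <- multilineage_config(seed = 301, n_orthogroups = 120,
                             samples_per_habitat = c(3, 2))
  sim1 <- simulate_multilineage(cfg)
  sim2 <- simulate_multilineage(cfg)
  expect_identical(sim1$count_matrices$lineage01$counts,
                   sim2$count_matrices$lineage01$counts)
  expect_identical(sim1$truth$lfc, sim2$truth$lfc)

  # the generator does not disturb the session RNG stream
  set.seed(99); before <- runif(3)
  set.seed(99); invisible(simulate_multilineage(cfg)); after <- runif(3)
  expect_identical(before, after)

  # emitted tables are readable by the io module without modification
  td <- withr::local_tempdir()
  write_count_matrix(sim1$count_matrices$lineage01,
                     file.path(td, "c.csv"))
  back <- read_count_matrix(file.path(td, "c.csv"), "lineage01")
  expect_identical(back$counts, sim1$count_matrices$lineage01$counts)
  write_sample_sheet(sim1$sample_sheet, file.path(td, "s.tsv"))
  expect_identical(read_sample_sheet(file.path(td, "s.tsv"))$sample_id,
                   sim1$sample_sheet$sample_id)
  write_orthogroup_map(sim1$orthogroup_map, file.path(td, "og.tsv"))
  og <- read_orthogroup_map(file.path(td, "og.tsv"),
                            attr(sim1$orthogroup_map, "species"))
  expect_identical(unclass(og)[], unclass(sim1$orthogroup_map)[])

  # truth is consistent with the emitted matrices
  g <- sim1$truth$genes
  expect_setequal(g$gene_id[g$species == "lineage01"],
                  sim1$count_matrices$lineage01$feature_ids)
  # convergent orthogroups carry one sign across lineages; divergent >= 2
  lfc <- sim1$truth$lfc
  cls <- sim1$truth$classes
  conv <- lfc[cls == "convergent", , drop = FALSE]
  expect_true(all(apply(sign(conv), 1, function(s) length(unique(s)) == 1)))
  dive <- lfc[cls == "divergent", , drop = FALSE]
  expect_true(all(apply(sign(dive), 1,
                        function(s) all(s != 0) && length(unique(s)) > 1)))
  expect_true(all(lfc[cls == "null", ] == 0))
  expect_true(all(rowSums(lfc[cls == "lineage_specific", , drop = FALSE] != 0) == 1))
})

test_that("paralog-free simulation makes orthogroup counts equal gene counts", {
  cfg <- multilineage_config(seed = 311, n_orthogroups = 80,
                             samples_per_habitat = c(3, 3),
                             paralog_rate = 0)
  sim <- simulate_multilineage(cfg)
  # every orthogroup has exactly one gene per species
  expect_true(all(vapply(sim$orthogroup_map,
                         function(r) all(lengths(r) == 1), logical(1))))
  oc <- aggregate_to_orthogroups(sim$count_matrices, sim$orthogroup_map)
  for (sp in names(sim$count_matrices)) {
    Y <- sim$count_matrices[[sp]]$counts
    og_of <- vapply(sim$orthogroup_map, function(r) r[[sp]], character(1))
    expect_identical(unname(oc$counts[[sp]][names(og_of), ]),
                     unname(Y[og_of, ]))
  }
})

test_that("simulated counts match the NB mean-variance law", {
  # many i.i.d. replicates of a few null orthogroups: moments must match
  cfg <- multilineage_config(seed = 321, n_orthogroups = 12,
                             n_lineages = 2,
                             samples_per_habitat = 400,
                             paralog_rate = 0,
                             prop_effects = c(convergent = 0, divergent = 0,
                                              lineage_specific = 0, null = 1),
                             lib_size_sdlog = 1e-6)
  sim <- simulate_multilineage(cfg)
  Y <- sim$count_matrices$lineage01$counts
  L <- mean(sim$truth$lib_sizes$lineage01)
  for (g in rownames(Y)) {
    y <- Y[g, ]
    m <- mean(y)
    if (m < 20) next                    # skip low counts (noisy moments)
    phi_true <- cfg$phi0 + cfg$phi_slope / m
    v_expect <- m + phi_true * m^2
    # 800 draws: variance ratio should sit near 1
    expect_gt(var(y) / v_expect, 0.7)
    expect_lt(var(y) / v_expect, 1.4)
  }
})

test_that("planted-module generator has the stated latent structure", {
  sim <- simulate_modules(seed = 331)
  expect_identical(dim(sim$expr), c(440L, 40L))
  expect_identical(sum(sim$labels == 0), 200L)
  # loadings near 1 drive within-module correlation toward 1
  sim_hi <- simulate_modules(module_sizes = 30, loading_range = c(0.99, 0.995),
                             n_noise = 0, trait_effect = 0, seed = 332)
  cc <- cor(t(sim_hi$expr))
  expect_gt(min(abs(cc[upper.tri(cc)])), 0.95)
  # with no trait effect the trait correlation is null-distributed
  mt_p <- vapply(1:20, function(s) {
    sm <- simulate_modules(n_samples = 30, module_sizes = c(40),
                           n_noise = 0, trait_effect = 0, seed = 400 + s)
    E <- module_eigengenes(sm$expr, sm$labels)
    module_trait_correlation(E, sm$trait)$p
  }, numeric(1))
  expect_gt(ks.test(mt_p, "punif")$p.value, 0.01)
})

test_that("planted GO annotation is null without a rate difference", {
  genes <- sprintf("g%04d", 1:1500)
  target <- genes[1:100]
  # equal rates: forced via planted_rate barely above base (null in effect)
  sim <- simulate_go_annotation(genes, target, base_rate = 0.05,
                                planted_rate = 0.0500001, n_terms = 40,
                                seed = 341)
  res <- hypergeom_enrichment(target, genes, sim$annotation)
  expect_gt(min(res$q), 0.05)
  # annotation covers only background genes
  expect_true(all(names(sim$annotation$gene2terms) %in% genes))
})
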