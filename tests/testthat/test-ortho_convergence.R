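make_toy_ortho <- function() {
  Y1 <- matrix(c(7, 2,   3, 0,   4, 5,  1, 1), 4, 2, byrow = TRUE,
               dimnames = list(c("a1", "b1", "b2", "x1"), c("s1", "s2")))
  Y2 <- matrix(c(6, 6,   2, 3,   0, 9), 3, 2, byrow = TRUE,
               dimnames = list(c("a2", "b3", "z1"), c("t1", "t2")))
  cms <- list(sp1 = count_matrix(Y1, "sp1"), sp2 = count_matrix(Y2, "sp2"))
  tf <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(c("Orthogroup\tsp1\tsp2",
               "OGa\ta1\ta2",
               "OGb\tb1,b2\tb3",
               "OGc\tmissing_gene\t"), tf)
  map <- read_orthogroup_map(tf, c("sp1", "sp2"))
  list(cms = cms, map = map)
}

test_that("orthogroup aggregation sums paralogs and conserves totals", {
  toy <- make_toy_ortho()
  oc <- aggregate_to_orthogroups(toy$cms, toy$map)
  # 1:1 ortholog passes through
  expect_equal(unname(oc$counts$sp1["OGa", ]), c(7, 2))
  # paralogs sum
  expect_equal(unname(oc$counts$sp1["OGb", ]), c(3 + 4, 0 + 5))
  # mapped-but-absent gene contributes zero and is logged
  expect_equal(unname(oc$counts$sp1["OGc", ]), c(0, 0))
  expect_identical(oc$provenance$sp1$mapped_missing, "missing_gene")
  # unmapped matrix genes are dropped and logged
  expect_identical(oc$provenance$sp1$unmapped, "x1")
  # per-sample totals over mapped genes are conserved exactly
  mapped <- c("a1", "b1", "b2")
  expect_identical(colSums(oc$counts$sp1),
                   colSums(toy$cms$sp1$counts[mapped, ]))
  expect_error(aggregate_to_orthogroups(toy$cms["sp1"], toy$map), "sp2")
})

test_that("universal-expression retention keeps complete, always-positive orthogroups", {
  toy <- make_toy_ortho()
  oc <- aggregate_to_orthogroups(toy$cms, toy$map)
  kept <- filter_universal_expressed(oc)
  # OGa and OGb are complete and positive in every cell; OGc is absent
  # from sp2 and has an all-zero row in sp1
  expect_setequal(kept, c("OGa", "OGb"))
  # idempotent under subsetting
  oc2 <- subset_orthogroups(oc, kept)
  expect_identical(filter_universal_expressed(oc2), kept)

  # a single zero cell in one individual removes the orthogroup
  oc$counts$sp2["OGa", "t2"] <- 0
  expect_setequal(filter_universal_expressed(oc), "OGb")
})

test_that("directional intersections match set algebra on the worked example", {
  mk <- function(up, down, all_feats = c(letters, "x", "y")) {
    feats <- unique(c(up, down, all_feats))
    data.frame(feature_id = feats,
               direction = ifelse(feats %in% up, "up",
                                  ifelse(feats %in% down, "down", "ns")),
               stringsAsFactors = FALSE)
  }
  tabs <- list(L1 = mk(up = c("a", "b"), down = "x"),
               L2 = mk(up = c("b", "c"), down = c("x", "y")))
  rep2 <- intersect_directional(tabs)
  s <- rep2$subsets[["L1+L2"]]
  expect_identical(s$shared_up, "b")
  expect_identical(s$shared_down, "x")
  expect_identical(s$shared_any, c("b", "x"))
  expect_identical(shared_in_at_least(rep2, 2), c("b", "x"))

  # disjoint DE sets yield empty intersections
  tabs2 <- list(L1 = mk(up = "a", down = "b"), L2 = mk(up = "c", down = "d"))
  s2 <- intersect_directional(tabs2)$subsets[["L1+L2"]]
  expect_length(s2$shared_any, 0)
})

test_that("intersection report matches the brute-force membership oracle", {
  set.seed(101)
  feats <- sprintf("f%02d", 1:40)
  lineages <- c("A", "B", "C", "D")
  for (rep_i in 1:25) {
    up <- list(); down <- list()
    tabs <- list()
    for (l in lineages) {
      st <- sample(c("up", "down", "ns"), length(feats), replace = TRUE,
                   prob = c(0.3, 0.3, 0.4))
      up[[l]] <- feats[st == "up"]
      down[[l]] <- feats[st == "down"]
      tabs[[l]] <- data.frame(feature_id = feats, direction = st,
                              stringsAsFactors = FALSE)
    }
    report <- intersect_directional(tabs)
    expect_length(report$subsets, 11L)  # all subsets of size >= 2 of 4
    for (lab in names(report$subsets)) {
      s <- report$subsets[[lab]]
      oracle <- intersect_oracle(up, down, s$lineages, lineages)
      expect_identical(s$shared_up, oracle$shared_up)
      expect_identical(s$shared_down, oracle$shared_down)
      expect_identical(s$shared_any, oracle$shared_any)
      expect_identical(s$exclusive_any, oracle$exclusive_any)
      # structural invariants
      expect_length(intersect(s$shared_up, s$shared_down), 0)
      expect_true(all(c(s$shared_up, s$shared_down) %in% s$shared_any))
    }
    # monotonicity: adding a lineage can only shrink the shared set
    expect_true(all(shared_in_at_least(report, 4) %in%
                      shared_in_at_least(report, 3)))
    expect_true(all(shared_in_at_least(report, 3) %in%
                      shared_in_at_least(report, 2)))
  }
})

test_that("per-lineage DE runs on a common universe with the no-replicate fallback", {
  cfg <- multilineage_config(seed = 5, n_orthogroups = 150,
                             samples_per_habitat = c(4, 4, 4, 1),
                             prop_effects = c(convergent = 0.2, divergent = 0,
                                              lineage_specific = 0, null = 0.8),
                             lfc_range = c(2, 2.5))
  sim <- simulate_multilineage(cfg)
  oc <- aggregate_to_orthogroups(sim$count_matrices, sim$orthogroup_map)
  kept <- filter_universal_expressed(oc)
  ocr <- subset_orthogroups(oc, kept)
  expect_warning(
    de_l <- per_lineage_de(ocr, sim$sample_sheet),
    "fixed dispersion"
  )
  # identical universe across lineages
  ids <- lapply(de_l, function(d) sort(d$feature_id))
  expect_true(all(vapply(ids, identical, logical(1), ids[[1]])))
  # significant calls on convergent orthogroups match the planted sign
  conv <- names(sim$truth$classes)[sim$truth$classes == "convergent"]
  for (sp in names(de_l)[1:3]) {
    d <- de_l[[sp]]
    sig <- d[d$feature_id %in% conv & d$direction != "ns", ]
    if (nrow(sig) > 0) {
      expect_true(all(sign(sig$logFC) ==
                        sign(sim$truth$lfc[sig$feature_id, sp])))
    }
  }
})
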