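mk_annotation <- function(genes, term_of) {
  sets <- lapply(genes, function(g) character(0))
  names(sets) <- genes
  for (tm in names(term_of)) {
    for (g in term_of[[tm]]) sets[[g]] <- c(sets[[g]], tm)
  }
  go_annotation(sets)
}

test_that("hypergeometric p matches the exact combinatorial value", {
  # N = 10, B = 5, n = 4, b = 4: p = C(5,4) C(5,0) / C(10,4) = 5/210
  genes <- sprintf("g%02d", 1:10)
  ann <- mk_annotation(genes, list("GO:1" = genes[1:5],
                                   "GO:2" = genes))   # GO:2 keeps all annotated
  res <- hypergeom_enrichment(genes[1:4], genes, ann)
  row <- res[res$term == "GO:1", ]
  expect_equal(row$p, 5 / 210, tolerance = 1e-12)
  expect_equal(row$fold, (4 / 4) / (5 / 10))
  expect_identical(c(row$b, row$n, row$B, row$N), c(4L, 4L, 5L, 10L))

  # degenerate universe: target = background gives fold 1, p 1
  res2 <- hypergeom_enrichment(genes, genes, ann)
  expect_equal(res2$fold, rep(1, nrow(res2)))
  expect_equal(res2$p, rep(1, nrow(res2)))
})

test_that("hypergeometric tail equals enumeration and the Fisher tail", {
  set.seed(181)
  for (i in 1:15) {
    N <- sample(6:12, 1)
    B <- sample(2:(N - 1), 1)
    n <- sample(2:(N - 1), 1)
    genes <- sprintf("g%02d", seq_len(N))
    ann <- mk_annotation(genes, list("GO:t" = genes[seq_len(B)],
                                     "GO:bg" = genes))
    target <- genes[sample(N, n)]
    res <- hypergeom_enrichment(target, genes, ann, min_b = 1)
    b <- sum(target %in% genes[seq_len(B)])
    if (b >= 1) {
      p_pkg <- res$p[res$term == "GO:t"]
      expect_equal(p_pkg, hyper_enum_oracle(b, B, N, n), tolerance = 1e-10)
      tab <- matrix(c(b, B - b, n - b, N - B - n + b), 2)
      expect_equal(p_pkg, fisher.test(tab, alternative = "greater")$p.value,
                   tolerance = 1e-10)
    }
  }
})

test_that("p is monotone nonincreasing in b and min_b filters terms", {
  genes <- sprintf("g%03d", 1:100)
  ps <- vapply(2:19, function(b) {
    ann <- mk_annotation(genes, list("GO:t" = genes[1:40], "GO:bg" = genes))
    target <- c(genes[1:b], genes[41:(60 - b)])
    hypergeom_enrichment(target, genes, ann)$p[1]
  }, numeric(1))
  expect_true(all(diff(ps) <= 1e-12))

  ann <- mk_annotation(genes, list("GO:rare" = genes[1], "GO:bg" = genes))
  res <- hypergeom_enrichment(genes[1:10], genes, ann)
  expect_false("GO:rare" %in% res$term)   # b = 1 < min_b
})

test_that("planted term is the top hit at the stated rates", {
  genes <- sprintf("g%04d", 1:5000)
  target <- genes[1:200]
  sim <- simulate_go_annotation(genes, target, seed = 191)
  res <- hypergeom_enrichment(target, genes, sim$annotation)
  expect_identical(res$term[1], sim$planted)
  expect_lt(res$q[1], 0.05)
  # no other term reaches the planted term's significance
  expect_gt(res$p[2] / res$p[1], 10)
})

test_that("annotation propagation closes over ancestors and is idempotent", {
  ann <- go_annotation(list(g1 = "GO:child", g2 = "GO:parent", g3 = character(0)))
  edges <- data.frame(child = "GO:child", parent = "GO:parent")
  out <- propagate_annotations(ann, edges)
  expect_setequal(out$gene2terms$g1, c("GO:child", "GO:parent"))
  expect_identical(out$gene2terms$g3, character(0))

  # no edges: identity
  expect_identical(propagate_annotations(ann, NULL)$gene2terms, ann$gene2terms)

  # idempotence on random DAGs (terms t1..t9, edges only low -> high)
  set.seed(201)
  for (i in 1:5) {
    terms <- sprintf("t%d", 1:9)
    e <- subset(expand.grid(child = terms, parent = terms,
                            stringsAsFactors = FALSE),
                match(child, terms) < match(parent, terms))
    e <- e[sample(nrow(e), 10), ]
    ann_r <- go_annotation(list(gA = sample(terms, 3), gB = sample(terms, 2)))
    once <- propagate_annotations(ann_r, e)
    twice <- propagate_annotations(once, e)
    expect_identical(twice$gene2terms, once$gene2terms)
  }

  # cycles are rejected
  cyc <- data.frame(child = c("a", "b"), parent = c("b", "a"))
  ann_c <- go_annotation(list(g = "a"))
  expect_error(propagate_annotations(ann_c, cyc), "cycle")
})
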