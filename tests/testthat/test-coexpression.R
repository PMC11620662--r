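test_that("expression transform drops constant genes and ignores depth", {
  set.seed(111)
  Y <- random_counts(200, 6, seed = 111)
  Y["g0001", ] <- 0                       # all-zero -> constant after log
  norm <- tmm_factors(Y)
  expr <- expression_transform(Y, norm)
  expect_true("g0001" %in% attr(expr, "dropped"))
  expect_identical(dim(expr), c(199L, 6L))

  # doubling all counts of one sample shifts its log2-cpm only through the
  # prior term: for well-expressed genes the column is essentially unchanged
  Y2 <- Y; Y2[, 3] <- Y[, 3] * 2
  e1 <- cpm(Y, log = TRUE)
  e2 <- cpm(Y2, log = TRUE)
  big <- Y[, 3] > 50
  expect_lt(max(abs(e1[big, 3] - e2[big, 3])), 0.02)
  expect_error(expression_transform(Y[, 1:2]), "three samples")
})

test_that("sample dendrogram merges duplicates first with monotone heights", {
  set.seed(121)
  expr <- matrix(rnorm(50 * 5), 50, 5,
                 dimnames = list(sprintf("g%02d", 1:50), sprintf("s%d", 1:5)))
  expr <- cbind(expr, s6 = expr[, "s2"])   # duplicated sample
  tree <- sample_dendrogram(expr)
  expect_identical(length(tree$height), 5L)          # n - 1 merges
  expect_true(!is.unsorted(tree$height))             # monotone agglomeration
  expect_equal(tree$height[1], 0)                    # duplicates merge at 0
  first <- sort(tree$labels[abs(tree$merge[1, ])])
  expect_identical(first, c("s2", "s6"))
})

test_that("soft-threshold scan obeys its structural invariants", {
  set.seed(131)
  # perfectly correlated genes: adjacency is all 1 regardless of beta
  base <- rnorm(20)
  expr <- outer(rep(1, 30), base) * rep(c(1, 2), 15) + 5
  rownames(expr) <- sprintf("g%02d", 1:30)
  colnames(expr) <- sprintf("s%02d", 1:20)
  A <- adjacency_matrix(expr, 6)
  expect_equal(max(abs(A - 1)), 0, tolerance = 1e-12)
  expect_equal(unname(rowSums(A) - 1), rep(29, 30))

  sim <- simulate_modules(seed = 17)
  scan <- suppressWarnings(soft_threshold_scan(sim$expr))
  # mean connectivity strictly decreases with the power
  expect_true(all(diff(scan$scan$mean_k) < 0))
  # selection is deterministic across reruns
  scan2 <- suppressWarnings(soft_threshold_scan(sim$expr))
  expect_identical(scan$selected, scan2$selected)
  expect_equal(scan$scan, scan2$scan)
})

test_that("TOM matches the triple-loop oracle and its closed-form identities", {
  set.seed(141)
  # random symmetric adjacency in [0,1]
  n <- 50
  R <- matrix(runif(n * n), n, n)
  A <- (R + t(R)) / 2
  diag(A) <- 1
  expect_equal(unname(tom_similarity(A)), tom_oracle(A), tolerance = 1e-12)

  # empty graph: TOM off-diagonal is 0
  A0 <- diag(n)
  T0 <- tom_similarity(A0)
  expect_equal(max(abs(T0[upper.tri(T0)])), 0)
  # complete graph: TOM is 1 everywhere
  A1 <- matrix(1, n, n)
  expect_equal(unname(tom_similarity(A1)), matrix(1, n, n))

  # bounds and symmetry on a realistic network
  sim <- simulate_modules(n_samples = 20, module_sizes = c(25, 20),
                          n_noise = 15, seed = 19)
  At <- adjacency_matrix(sim$expr, 6)
  Tt <- tom_similarity(At)
  expect_true(isSymmetric(unname(Tt), tol = 1e-12))
  expect_true(all(Tt >= -1e-12 & Tt <= 1 + 1e-12))
  expect_equal(unname(diag(Tt)), rep(1, nrow(Tt)))
  expect_error(tom_similarity(matrix(c(1, 0.5, 0.2, 1), 2)), "symmetric")
})

test_that("module extraction resolves planted block structure", {
  # two perfectly separated blocks of 50 genes
  set.seed(151)
  e1 <- rnorm(30); e2 <- rnorm(30)
  expr <- rbind(outer(seq(1, 2, length.out = 50), e1),
                outer(seq(1, 2, length.out = 50), e2))
  expr <- expr + matrix(rnorm(100 * 30, sd = 1e-4), 100, 30)
  rownames(expr) <- sprintf("g%03d", 1:100)
  colnames(expr) <- sprintf("s%02d", 1:30)
  tom <- tom_similarity(adjacency_matrix(expr, 6))
  # clean block structure tolerates a cut just below the final merge
  mod <- cut_modules(1 - tom, cut_quantile = 0.99)
  expect_identical(sort(as.integer(table(mod$labels[mod$labels > 0]))),
                   c(50L, 50L))
  # labels ordered by size with id tie-break: both size 50, module 1 holds g001
  expect_identical(unname(mod$labels["g001"]), 1L)

  # min size above the gene count leaves everything unassigned
  expect_warning(mod0 <- cut_modules(1 - tom, min_module_size = 1000),
                 "unassigned")
  expect_true(all(mod0$labels == 0))
})

test_that("eigengenes equal the leading principal component", {
  set.seed(161)
  # module of identical genes: eigengene correlates perfectly with each
  expr <- outer(rep(1, 10), rnorm(12)) + 3
  expr <- expr * seq(1, 3, length.out = 10)
  rownames(expr) <- sprintf("g%02d", 1:10)
  colnames(expr) <- sprintf("s%02d", 1:12)
  labels <- setNames(rep(1L, 10), rownames(expr))
  E <- module_eigengenes(expr, labels)
  for (g in rownames(expr)) {
    expect_equal(abs(cor(E[1, ], expr[g, ])), 1, tolerance = 1e-10)
  }
  expect_equal(sum(E[1, ]^2), 1)          # unit norm over samples

  # permutation invariance (sign fixed by the mean-expression convention)
  perm <- sample(rownames(expr))
  E2 <- module_eigengenes(expr[perm, ], labels[perm])
  expect_equal(E2, E, tolerance = 1e-10)

  # variance explained matches an independent eigendecomposition
  sim <- simulate_modules(n_samples = 25, module_sizes = c(40),
                          n_noise = 0, seed = 23)
  Em <- module_eigengenes(sim$expr, sim$labels)
  Z <- t(scale(t(sim$expr)))
  ev <- eigen(crossprod(Z), symmetric = TRUE)$values
  expect_equal(unname(attr(Em, "var_explained")["ME1"]), ev[1] / sum(ev),
               tolerance = 1e-10)
})

test_that("module merging reunites over-split modules and stops below threshold", {
  set.seed(171)
  n <- 36
  e <- rnorm(n)
  # one true module artificially split in two: both halves load on e at 0.95
  mk <- function(m, id0) {
    rho <- rep(0.95, m)
    X <- rho %o% e + sqrt(1 - rho^2) *
      matrix(rnorm(m * n), m, n)
    rownames(X) <- sprintf("g%03d", id0 + seq_len(m))
    X
  }
  expr <- rbind(mk(40, 0), mk(40, 40))
  colnames(expr) <- sprintf("s%02d", 1:n)
  labels <- setNames(rep(c(1L, 2L), each = 40), rownames(expr))
  merged <- merge_modules(expr, labels)
  expect_identical(length(unique(merged$labels[merged$labels > 0])), 1L)
  expect_identical(length(merged$merge_history), 1L)
  expect_identical(unname(merged$merge_history[[1]]), c(2L, 1L))

  # independent modules stay separate
  e2 <- rnorm(n)
  expr2 <- rbind(mk(40, 0), {
    X <- rep(0.95, 40) %o% e2 +
      sqrt(1 - 0.95^2) * matrix(rnorm(40 * n), 40, n)
    rownames(X) <- sprintf("g%03d", 40 + 1:40); X
  })
  colnames(expr2) <- sprintf("s%02d", 1:n)
  merged2 <- merge_modules(expr2, labels)
  expect_identical(length(unique(merged2$labels[merged2$labels > 0])), 2L)
  expect_length(merged2$merge_history, 0)
})

test_that("module-trait correlation uses the Student-t law", {
  E <- matrix(rnorm(24), 2, 12,
              dimnames = list(c("ME1", "ME2"), sprintf("s%02d", 1:12)))
  trait <- rep(0:1, 6)
  mt <- module_trait_correlation(E, trait)
  # matches an independent evaluation via cor.test
  for (i in 1:2) {
    ref <- cor.test(E[i, ], trait)
    expect_equal(mt$r[i], unname(ref$estimate), tolerance = 1e-12)
    expect_equal(mt$p[i], ref$p.value, tolerance = 1e-10)
  }
  # closed-form edge cases: r = 0 -> p = 1; |r| = 1 -> p = 0
  E2 <- rbind(ME1 = rep(c(1, -1), 6),              # exactly orthogonal
              ME2 = rep(0:1, each = 6))            # exactly the trait
  mt2 <- module_trait_correlation(E2, rep(0:1, each = 6))
  expect_equal(mt2$r[mt2$module == "ME1"], 0)
  expect_equal(mt2$p[mt2$module == "ME1"], 1)
  expect_equal(mt2$p[mt2$module == "ME2"], 0)
  expect_error(module_trait_correlation(E2, rep(1, 12)), "constant")
})

test_that("planted modules are recovered end-to-end with the trait module on top", {
  sim <- simulate_modules(seed = 29)
  scan <- suppressWarnings(soft_threshold_scan(sim$expr))
  tom <- tom_similarity(adjacency_matrix(sim$expr, scan$selected))
  mod <- cut_modules(1 - tom)
  mod <- refine_modules_kme(sim$expr, mod)
  mod <- merge_modules(sim$expr, mod)
  ari <- mclust::adjustedRandIndex(mod$labels, sim$labels)
  expect_gte(ari, 0.9)
  mt <- module_trait_correlation(mod$eigengenes, sim$trait)
  top <- which.max(abs(mt$r))
  # the trait-driven planted module carries the strongest correlation
  top_genes <- names(mod$labels)[mod$labels ==
                                   as.integer(sub("ME", "", mt$module[top]))]
  expect_gt(mean(grepl("^mod1_", top_genes)), 0.9)
  expect_lt(mt$p[top], 0.01)

  # whole-pipeline determinism: identical inputs give identical outputs
  mod_b <- merge_modules(sim$expr, refine_modules_kme(
    sim$expr, cut_modules(1 - tom)))
  expect_identical(mod$labels, mod_b$labels)
  expect_equal(mod$eigengenes, mod_b$eigengenes, tolerance = 0)
})
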