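# Low-dimensional visualization stages: top-variance gene selection,
# classical (Torgerson) multidimensional scaling of samples, and
# cross-population expression-profile clustering.

#' Select the genes with the highest expression standard deviation
#'
#' Ranks features by the standard deviation of their (log2-cpm) expression
#' across all samples, descending, with ties broken by feature id, and
#' returns the top `k`. When `k` exceeds the feature count, all features are
#' returned with a warning.
#'
#' @param expr genes x samples expression matrix (log2-cpm).
#' @param k number of genes to keep (default 10000).
#' @return character vector of selected feature ids.
#' @export
top_sd_genes <- function(expr, k = 10000) {
  s <- apply(expr, 1L, stats::sd)
  if (k > nrow(expr)) {
    warning(sprintf("k (%d) exceeds feature count (%d); returning all",
                    k, nrow(expr)))
    k <- nrow(expr)
  }
  ord <- order(-s, rownames(expr))
  rownames(expr)[ord[seq_len(k)]]
}

#' Classical multidimensional scaling (Torgerson scaling)
#'
#' Double-centers the squared distance matrix, `B = -1/2 * J * D^2 * J` with
#' `J = I - 11'/n`, and embeds the points on the top `k` eigenvectors of `B`
#' scaled by the square roots of their eigenvalues. Axes are ordered by
#' decreasing eigenvalue; each axis' sign is fixed so its largest-magnitude
#' coordinate is positive. Negative eigenvalues are reported but never used
#' for axes.
#'
#' @param D symmetric non-negative distance matrix with zero diagonal.
#' @param k number of output axes (default 2).
#' @return object of class `mds_result`: list with `points` (samples x k),
#'   `eigenvalues` (all n of them), and `prop_dispersion` (per-axis share of
#'   the positive eigenvalue total).
#' @export
classical_mds <- function(D, k = 2) {
  D <- as.matrix(D)
  assert_that(isSymmetric(unname(D), tol = 1e-8), "distance matrix must be symmetric")
  assert_that(all(D >= 0) && all(abs(diag(D)) < 1e-12),
              "distances must be non-negative with zero diagonal")
  n <- nrow(D)
  assert_that(k >= 1 && k <= n - 1, "k must lie in [1, n-1]")
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (D^2) %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  ev <- e$values
  pos <- pmax(ev[seq_len(k)], 0)
  pts <- e$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(pos), k, k)
  # deterministic axis orientation
  for (j in seq_len(k)) {
    i_max <- which.max(abs(pts[, j]))
    if (pts[i_max, j] < 0) pts[, j] <- -pts[, j]
  }
  rownames(pts) <- rownames(D)
  colnames(pts) <- paste0("axis", seq_len(k))
  structure(list(points = pts, eigenvalues = ev,
                 prop_dispersion = pos / sum(pmax(ev, 0))),
            class = "mds_result")
}

#' @export
print.mds_result <- function(x, ...) {
  cat(sprintf("mds_result: %d samples on %d axes (dispersion: %s)\n",
              nrow(x$points), ncol(x$points),
              paste(sprintf("%.1f%%", 100 * x$prop_dispersion), collapse = ", ")))
  invisible(x)
}

#' MDS of samples from an expression matrix
#'
#' Convenience wrapper: selects the `top` highest-SD genes, computes
#' Euclidean distances between sample profiles, and runs [classical_mds()].
#'
#' @param expr genes x samples expression matrix (log2-cpm).
#' @param top number of highest-SD genes to use (default 10000).
#' @param k number of axes (default 2).
#' @return an `mds_result`.
#' @export
expression_mds <- function(expr, top = 10000, k = 2) {
  sel <- top_sd_genes(expr, k = top)
  D <- as.matrix(stats::dist(t(expr[sel, , drop = FALSE])))
  classical_mds(D, k = k)
}

#' Mean expression profiles per population
#'
#' Averages log2-cpm over the individuals of each species-by-habitat
#' population, on a common orthogroup universe.
#'
#' @param ortho an `ortho_counts` object (retention-filtered).
#' @param sheet a `sample_sheet` covering all samples.
#' @return orthogroups x populations matrix; population names are
#'   `<species>_<habitat>`.
#' @export
population_mean_profiles <- function(ortho, sheet) {
  stopifnot(inherits(ortho, "ortho_counts"))
  sheet <- as.data.frame(sheet)
  cols <- list()
  for (s in names(ortho$counts)) {
    M <- ortho$counts[[s]]
    norm <- tmm_factors(M)
    expr <- cpm(M, norm = norm, log = TRUE)
    sub <- sheet[sheet$species == s, , drop = FALSE]
    for (h in c("FW", "SW")) {
      ids <- intersect(colnames(M), sub$sample_id[sub$habitat == h])
      if (length(ids) == 0L) next
      cols[[paste(s, h, sep = "_")]] <- rowMeans(expr[, ids, drop = FALSE])
    }
  }
  do.call(cbind, cols)
}

#' Cluster population expression profiles
#'
#' Computes the Pearson-correlation distance (`1 - r`) between population
#' mean profiles and clusters the populations by average linkage. Related
#' lineages are expected to pair together when lineage divergence dominates
#' habitat effects.
#'
#' @param profiles features x populations matrix of mean expression (e.g.
#'   from [population_mean_profiles()]).
#' @return list with `tree` (hclust over populations), `similarity`
#'   (correlation matrix), `newick` (the tree in Newick format, via ape).
#' @export
population_profile_clustering <- function(profiles) {
  assert_that(ncol(profiles) >= 3L, "need at least three populations")
  R <- stats::cor(profiles)
  tree <- stats::hclust(stats::as.dist(1 - R), method = "average")
  list(tree = tree, similarity = R,
       newick = ape::write.tree(ape::as.phylo(tree)))
}
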