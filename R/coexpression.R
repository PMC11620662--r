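# Weighted co-expression network core: expression transform, soft-threshold
# selection by the scale-free topology criterion, adjacency, topological
# overlap, module extraction from the gene dendrogram, eigengenes, module
# merging, and module-trait correlation.

#' Expression transform for network analysis
#'
#' Produces the log2-cpm matrix used for co-expression work:
#' `log2(cpm + 0.5)` on TMM-effective library sizes, a standard
#' variance-stabilizing choice for NB counts. Genes with zero variance
#' across samples are dropped (their correlations are undefined) and
#' recorded in the `dropped` attribute.
#'
#' @param counts count matrix or [count_matrix()], already
#'   expression-filtered.
#' @param norm optional `norm_factors`; computed by [tmm_factors()] when
#'   NULL.
#' @param prior prior count on the cpm scale (default 0.5).
#' @return genes x samples numeric matrix with attribute `dropped`.
#' @export
expression_transform <- function(counts, norm = NULL, prior = 0.5) {
  Y <- counts_of(counts)
  assert_that(ncol(Y) >= 3L, "need at least three samples for correlation work")
  if (is.null(norm)) norm <- tmm_factors(Y)
  expr <- cpm(Y, norm = norm, log = TRUE, prior = prior)
  v <- apply(expr, 1L, stats::var)
  dropped <- rownames(expr)[v <= 0]
  expr <- expr[v > 0, , drop = FALSE]
  attr(expr, "dropped") <- dropped
  expr
}

#' Hierarchical clustering of samples
#'
#' Average-linkage agglomeration on Euclidean distances between sample
#' expression profiles; samples are ordered lexicographically before
#' clustering so that distance ties resolve deterministically.
#'
#' @param expr genes x samples expression matrix.
#' @return an [stats::hclust] tree over samples.
#' @export
sample_dendrogram <- function(expr) {
  assert_that(ncol(expr) >= 3L, "need at least three samples")
  ord <- order(colnames(expr))
  stats::hclust(stats::dist(t(expr[, ord, drop = FALSE])), method = "average")
}

#' Soft-threshold (power) scan under the scale-free topology criterion
#'
#' For each candidate power beta, forms the unsigned weighted adjacency
#' `A = |cor|^beta`, computes connectivities `k_i = sum_{j != i} A_ij`, bins
#' `log10(k)` into `n_bins` equal-width bins, and regresses log10 bin
#' frequency on the mean log10 connectivity per bin. The signed fit index is
#' `-sign(slope) * R^2`, positive when the connectivity distribution decays
#' as in a scale-free network. The selected power is the smallest candidate
#' whose signed R-squared reaches `r2_target` (retaining the highest
#' possible mean connectivity); if none reaches it, the candidate with the
#' best fit is chosen with a warning.
#'
#' @param expr genes x samples expression matrix.
#' @param powers increasing candidate powers (default 1:20).
#' @param r2_target scale-free fit target (default 0.80).
#' @param n_bins connectivity histogram bins (default 10).
#' @return object of class `soft_threshold_scan`: data.frame `scan` with
#'   columns `power`, `sft_r2`, `slope`, `mean_k`, `median_k`, plus
#'   `selected` (the chosen power).
#' @export
soft_threshold_scan <- function(expr, powers = 1:20, r2_target = 0.80,
                                n_bins = 10) {
  assert_that(ncol(expr) >= 3L, "need at least three samples")
  assert_that(all(diff(powers) > 0), "powers must be strictly increasing")
  C <- abs(stats::cor(t(expr)))
  diag(C) <- 0
  rows <- lapply(powers, function(b) {
    k <- rowSums(C^b)
    fit <- scale_free_fit(k, n_bins)
    data.frame(power = b, sft_r2 = fit["sft_r2"], slope = fit["slope"],
               mean_k = mean(k), median_k = stats::median(k))
  })
  scan <- do.call(rbind, rows)
  rownames(scan) <- NULL
  ok <- which(scan$sft_r2 >= r2_target)
  if (length(ok) > 0L) {
    selected <- scan$power[ok[1L]]
  } else {
    warning("no candidate power reaches the scale-free fit target; using best fit")
    selected <- scan$power[which.max(scan$sft_r2)]
  }
  structure(list(scan = scan, selected = selected, r2_target = r2_target),
            class = "soft_threshold_scan")
}

# signed scale-free model fit: regress log10(freq) on binned log10(k)
scale_free_fit <- function(k, n_bins) {
  k <- k[k > 0]
  if (length(k) < 2L || diff(range(log10(k))) == 0) {
    return(c(sft_r2 = 0, slope = 0))
  }
  lk <- log10(k)
  br <- seq(min(lk), max(lk), length.out = n_bins + 1L)
  bin <- cut(lk, breaks = br, include.lowest = TRUE)
  freq <- tapply(lk, bin, length)
  xk <- tapply(lk, bin, mean)
  keep <- !is.na(freq) & freq > 0
  if (sum(keep) < 3L) return(c(sft_r2 = 0, slope = 0))
  fit <- stats::lm(log10(freq[keep]) ~ xk[keep])
  r2 <- summary(fit)$r.squared
  slope <- stats::coef(fit)[[2L]]
  c(sft_r2 = -sign(slope) * r2, slope = slope)
}

#' @export
print.soft_threshold_scan <- function(x, ...) {
  cat(sprintf("soft_threshold_scan: selected power %d (target R^2 = %g)\n",
              x$selected, x$r2_target))
  print(x$scan, row.names = FALSE, digits = 3, ...)
  invisible(x)
}

#' Unsigned weighted adjacency
#'
#' `A_ij = |pearson(x_i, x_j)|^beta`, with unit diagonal.
#'
#' @param expr genes x samples expression matrix.
#' @param beta soft-thresholding power (>= 1).
#' @return symmetric genes x genes adjacency matrix in `[0, 1]`.
#' @export
adjacency_matrix <- function(expr, beta) {
  assert_that(beta >= 1, "beta must be >= 1")
  A <- abs(stats::cor(t(expr)))^beta
  diag(A) <- 1
  A
}

#' Topological overlap similarity
#'
#' `TOM_ij = (L_ij + A_ij) / (min(k_i, k_j) + 1 - A_ij)` for `i != j`, where
#' `L_ij = sum_{u != i,j} A_iu A_uj` counts shared neighbours and
#' `k_i = sum_{j != i} A_ij` is the connectivity; `TOM_ii = 1`. The
#' clustering dissimilarity is `1 - TOM`.
#'
#' @param A symmetric adjacency matrix with unit diagonal.
#' @return symmetric TOM matrix with unit diagonal, entries in `[0, 1]`.
#' @export
tom_similarity <- function(A) {
  assert_that(isSymmetric(unname(A), tol = 1e-12), "adjacency must be symmetric")
  diag(A) <- 1
  L <- A %*% A - 2 * A        # removes the u = i and u = j terms (A_ii = 1)
  k <- rowSums(A) - 1
  denom <- outer(k, k, pmin) + 1 - A
  tom <- (L + A) / denom
  diag(tom) <- 1
  dimnames(tom) <- dimnames(A)
  tom
}

#' Extract modules from the gene dendrogram
#'
#' Clusters genes by average linkage on the TOM dissimilarity, cuts the tree
#' at the `cut_quantile` quantile of its merge heights, and keeps connected
#' subtrees with at least `min_module_size` leaves as modules. Modules are
#' labeled 1, 2, ... by decreasing size (ties broken by smallest member gene
#' id); all remaining genes are labeled 0 (unassigned).
#'
#' The cut height defaults to the median merge height: on topological
#' overlap dendrograms the informative within-module merges occupy the lower
#' half of the height distribution while unstructured genes chain together
#' just below the maximum, so a high cut fuses everything into one cluster.
#' The median yields tight module cores; [refine_modules_kme()] then
#' recruits the remaining members by module membership.
#'
#' @param dissimilarity symmetric gene dissimilarity matrix (`1 - TOM`).
#' @param min_module_size minimum module size (default 30).
#' @param cut_quantile quantile of merge heights at which to cut
#'   (default 0.5).
#' @return object of class `module_assignment`: list with `labels` (named
#'   integer vector, 0 = unassigned), `tree` (the hclust object),
#'   `cut_height`, and `merge_history` (empty until [merge_modules()]).
#' @export
cut_modules <- function(dissimilarity, min_module_size = 30,
                        cut_quantile = 0.5) {
  d <- as.matrix(dissimilarity)
  assert_that(isSymmetric(unname(d), tol = 1e-8), "dissimilarity must be symmetric")
  tree <- stats::hclust(stats::as.dist(d), method = "average")
  h_star <- stats::quantile(tree$height, probs = cut_quantile, names = FALSE)
  raw <- stats::cutree(tree, h = h_star)
  labels <- relabel_modules(raw, min_module_size)
  structure(list(labels = labels, tree = tree, cut_height = h_star,
                 merge_history = list()),
            class = "module_assignment")
}

# size-filter raw cluster ids and relabel 1.. by decreasing size
# (ties by smallest member gene id); everything else becomes 0
relabel_modules <- function(raw, min_module_size) {
  tab <- table(raw)
  big <- names(tab)[tab >= min_module_size]
  if (length(big) == 0L) {
    warning("no cluster reaches the minimum module size; all genes unassigned")
    return(stats::setNames(rep(0L, length(raw)), names(raw)))
  }
  first_gene <- vapply(big, function(cl) min(names(raw)[raw == cl]), character(1))
  ord <- order(-tab[big], first_gene)
  labels <- rep(0L, length(raw))
  names(labels) <- names(raw)
  for (i in seq_along(ord)) {
    labels[raw == big[ord[i]]] <- i
  }
  labels
}

#' Refine module assignments by module membership (kME)
#'
#' Reassigns every gene to the module whose eigengene it correlates with
#' most strongly (its module membership, kME), provided `|kME| >= kme_min`;
#' genes below the threshold become unassigned. This recruits true members
#' missed by the core cut and evicts weakly connected genes. Modules left
#' with fewer than two members are dissolved. Deterministic.
#'
#' @param expr genes x samples expression matrix.
#' @param assignment a `module_assignment` (or named label vector) holding
#'   the module cores.
#' @param kme_min minimum absolute eigengene correlation for membership
#'   (default 0.5, the conventional module-membership cutoff).
#' @return the assignment with refined `labels`.
#' @export
refine_modules_kme <- function(expr, assignment, kme_min = 0.5) {
  labels <- if (inherits(assignment, "module_assignment")) {
    assignment$labels
  } else {
    assignment
  }
  if (!any(labels > 0)) return(assignment)
  E <- module_eigengenes(expr, labels)
  mods <- as.integer(sub("^ME", "", rownames(E)))
  K <- stats::cor(t(expr), t(E))          # genes x modules
  best <- max.col(abs(K), ties.method = "first")
  val <- abs(K)[cbind(seq_len(nrow(K)), best)]
  new <- ifelse(val >= kme_min, mods[best], 0L)
  names(new) <- rownames(expr)
  for (m in unique(new[new > 0])) {
    if (sum(new == m) < 2L) new[new == m] <- 0L
  }
  if (inherits(assignment, "module_assignment")) {
    assignment$labels <- new
    assignment
  } else {
    new
  }
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of its
#' standardized expression: each member gene is z-scored across samples and
#' the module's first right singular vector (unit norm over samples) is
#' taken, with sign fixed so that its correlation with the module's mean
#' z-scored expression is non-negative. Zero-variance genes are dropped from
#' the decomposition.
#'
#' @param expr genes x samples expression matrix.
#' @param labels named integer module labels (0 = unassigned, ignored).
#' @return modules x samples eigengene matrix with rownames `ME<label>`;
#'   attribute `var_explained` gives the leading eigenvalue share per
#'   module.
#' @export
module_eigengenes <- function(expr, labels) {
  mods <- sort(unique(labels[labels > 0]))
  assert_that(length(mods) > 0L, "no assigned modules")
  E <- matrix(NA_real_, length(mods), ncol(expr),
              dimnames = list(paste0("ME", mods), colnames(expr)))
  ve <- stats::setNames(numeric(length(mods)), paste0("ME", mods))
  for (i in seq_along(mods)) {
    genes <- names(labels)[labels == mods[i]]
    Z <- expr[genes, , drop = FALSE]
    v <- apply(Z, 1L, stats::var)
    Z <- Z[v > 0, , drop = FALSE]
    assert_that(nrow(Z) >= 2L, "module %d has fewer than two variable genes",
                mods[i])
    Z <- t(scale(t(Z)))                       # z-score genes across samples
    sv <- svd(Z, nu = 0, nv = 1)
    e <- sv$v[, 1L]
    if (stats::cor(e, colMeans(Z)) < 0) e <- -e
    E[i, ] <- e
    ve[i] <- sv$d[1L]^2 / sum(sv$d^2)
  }
  attr(E, "var_explained") <- ve
  E
}

#' Merge highly correlated modules
#'
#' Iteratively merges the module pair whose eigengenes are most strongly
#' Pearson-correlated, as long as that correlation exceeds `cor_threshold`;
#' the merged module keeps the lower label number and eigengenes are
#' recomputed after every merge. Deterministic.
#'
#' @param expr genes x samples expression matrix.
#' @param assignment a `module_assignment` (or named label vector).
#' @param cor_threshold eigengene correlation above which modules merge
#'   (default 0.9).
#' @return a `module_assignment` with updated `labels`, `eigengenes`, and
#'   `merge_history` (list of `c(from, into)` pairs).
#' @export
merge_modules <- function(expr, assignment, cor_threshold = 0.9) {
  labels <- if (inherits(assignment, "module_assignment")) {
    assignment$labels
  } else {
    assignment
  }
  history <- list()
  repeat {
    mods <- sort(unique(labels[labels > 0]))
    if (length(mods) < 2L) break
    E <- module_eigengenes(expr, labels)
    R <- stats::cor(t(E))
    diag(R) <- -Inf
    best <- which(R == max(R), arr.ind = TRUE)[1L, ]
    if (R[best[1L], best[2L]] <= cor_threshold) break
    pair <- sort(mods[c(best[1L], best[2L])])
    labels[labels == pair[2L]] <- pair[1L]
    history[[length(history) + 1L]] <- c(from = pair[2L], into = pair[1L])
  }
  out <- if (inherits(assignment, "module_assignment")) assignment else {
    structure(list(labels = NULL, tree = NULL, cut_height = NA_real_,
                   merge_history = list()), class = "module_assignment")
  }
  out$labels <- labels
  out$merge_history <- c(out$merge_history, history)
  out$eigengenes <- if (any(labels > 0)) module_eigengenes(expr, labels) else NULL
  out
}

#' @export
print.module_assignment <- function(x, ...) {
  tab <- table(x$labels[x$labels > 0])
  cat(sprintf("module_assignment: %d modules over %d genes (%d unassigned)\n",
              length(tab), length(x$labels), sum(x$labels == 0)))
  if (length(tab) > 0L) print(tab)
  invisible(x)
}

#' Module-trait correlation
#'
#' Pearson correlation between each module eigengene and a sample trait
#' (habitat coded freshwater = 0, saltwater = 1), with the Student-t
#' p-value `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` degrees of
#' freedom. Modules with `p < p_threshold` are flagged significant.
#'
#' @param eigengenes modules x samples eigengene matrix.
#' @param trait numeric trait vector over samples (not constant).
#' @param p_threshold retention threshold (default 0.01).
#' @return data.frame with `module`, `r`, `p`, `significant`.
#' @export
module_trait_correlation <- function(eigengenes, trait, p_threshold = 0.01) {
  n <- ncol(eigengenes)
  assert_that(n >= 3L, "need at least three samples")
  assert_that(length(trait) == n, "trait length must match samples")
  assert_that(stats::var(trait) > 0, "trait is constant")
  r <- as.vector(stats::cor(t(eigengenes), trait))
  p <- cor_pvalue_student(r, n)
  data.frame(module = rownames(eigengenes), r = r, p = p,
             significant = p < p_threshold,
             stringsAsFactors = FALSE, row.names = NULL)
}

# two-sided Student-t p-value for a Pearson correlation on n samples
cor_pvalue_student <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  t <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, 0))
  2 * stats::pt(abs(t), df = n - 2, lower.tail = FALSE)
}

#' Intramodular connectivity
#'
#' Per-gene sum of adjacency to other genes of the same module.
#'
#' @param A adjacency matrix.
#' @param labels named module labels.
#' @return named numeric vector.
#' @export
intramodular_connectivity <- function(A, labels) {
  k <- stats::setNames(numeric(length(labels)), names(labels))
  for (m in unique(labels[labels > 0])) {
    genes <- names(labels)[labels == m]
    sub <- A[genes, genes, drop = FALSE]
    k[genes] <- rowSums(sub) - 1
  }
  k
}
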