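# Library-size scaling: counts per million and TMM normalization factors.

#' Counts per million
#'
#' Scales each count by its sample's effective library size:
#' `cpm_gi = y_gi / (N_i * f_i) * 1e6`. With `log = TRUE` the prior count is
#' added on the cpm scale before taking log2, so an observed zero maps to
#' `log2(prior)`.
#'
#' @param counts numeric matrix of counts (features x samples) or a
#'   [count_matrix()].
#' @param norm optional `norm_factors` object from [tmm_factors()]; when NULL,
#'   all scaling factors are 1 and library sizes are column sums.
#' @param log logical; return log2(cpm + prior)?
#' @param prior prior count added on the cpm scale before log2 (default 0.5).
#' @return numeric matrix of (log-)cpm values, same dimnames as `counts`.
#' @export
cpm <- function(counts, norm = NULL, log = FALSE, prior = 0.5) {
  y <- counts_of(counts)
  eff <- effective_lib_sizes(y, norm)
  assert_that(all(eff > 0), "zero effective library size")
  out <- sweep(y, 2L, eff / 1e6, "/")
  if (log) out <- log2(out + prior)
  out
}

counts_of <- function(x) {
  if (inherits(x, "count_matrix")) x$counts else {
    assert_that(is.matrix(x) && is.numeric(x), "counts must be a numeric matrix")
    x
  }
}

effective_lib_sizes <- function(y, norm = NULL) {
  if (is.null(norm)) return(colSums(y))
  stopifnot(inherits(norm, "norm_factors"))
  assert_that(length(norm$lib_size) == ncol(y),
              "norm factors do not match number of samples")
  norm$lib_size * norm$factor
}

#' Expression filter: minimum cpm in a minimum number of individuals
#'
#' Retains feature g iff `cpm_gi >= min_cpm` in at least `min_samples`
#' individuals, with cpm computed on raw library sizes (all scaling factors
#' fixed at 1, since the filter precedes normalization in the workflow).
#' Feature order is preserved.
#'
#' @param counts count matrix or [count_matrix()].
#' @param min_cpm minimum counts-per-million (default 2).
#' @param min_samples minimum number of individuals meeting `min_cpm`
#'   (default 3).
#' @return character vector of retained feature ids.
#' @export
filter_by_expression <- function(counts, min_cpm = 2, min_samples = 3) {
  y <- counts_of(counts)
  assert_that(min_samples <= ncol(y),
              "min_samples (%d) exceeds number of samples (%d)",
              min_samples, ncol(y))
  cp <- cpm(y, norm = NULL, log = FALSE)
  keep <- rowSums(cp >= min_cpm) >= min_samples
  rownames(y)[keep]
}

#' TMM normalization factors (trimmed mean of M-values)
#'
#' Computes between-sample scaling factors from doubly trimmed,
#' precision-weighted log count ratios against a reference sample. The
#' reference is the sample whose 75th-percentile cpm lies closest to the mean
#' of all samples' 75th-percentile cpms. For each sample, over genes positive
#' in both the sample and the reference, the log-ratio `M` and log-abundance
#' `A` are doubly trimmed (`trim_M` fraction from each tail of M, `trim_A`
#' from each tail of A) and the factor is `2^(weighted mean of M)` with
#' inverse-variance (delta-method binomial) weights. Factors are rescaled so
#' their geometric mean is exactly 1.
#'
#' @param counts count matrix or [count_matrix()]; needs >= 2 samples, each
#'   with at least one positive count.
#' @param trim_M two-sided trim fraction for log-ratios (default 0.30).
#' @param trim_A two-sided trim fraction for log-abundances (default 0.05).
#' @return object of class `norm_factors`: list with `lib_size` (column
#'   sums), `factor` (scaling factors, geometric mean 1), `effective`
#'   (their product), `ref_sample`.
#' @export
tmm_factors <- function(counts, trim_M = 0.30, trim_A = 0.05) {
  y <- counts_of(counts)
  assert_that(ncol(y) >= 2L, "TMM requires at least two samples")
  N <- colSums(y)
  assert_that(all(N > 0), "every sample needs at least one positive count")

  q75 <- apply(cpm(y), 2L, stats::quantile, probs = 0.75, names = FALSE)
  ref <- which.min(abs(q75 - mean(q75)))

  f <- vapply(seq_len(ncol(y)), function(s) {
    if (s == ref) return(1)
    tmm_pair_factor(y[, s], y[, ref], N[s], N[ref], trim_M, trim_A)
  }, numeric(1))

  f <- f / exp(mean(log(f)))
  structure(list(lib_size = N, factor = f, effective = N * f,
                 ref_sample = colnames(y)[ref]),
            class = "norm_factors")
}

# single-sample-vs-reference trimmed weighted mean of M values
tmm_pair_factor <- function(ys, yr, Ns, Nr, trim_M, trim_A) {
  pos <- ys > 0 & yr > 0
  ys <- ys[pos]; yr <- yr[pos]
  n <- length(ys)
  if (n == 0L) {
    warning("no genes positive in both sample and reference; factor set to 1")
    return(1)
  }
  M <- log2((ys / Ns) / (yr / Nr))
  A <- 0.5 * log2((ys / Ns) * (yr / Nr))
  w <- 1 / ((Ns - ys) / (Ns * ys) + (Nr - yr) / (Nr * yr))

  rk_M <- rank(M, ties.method = "first")
  rk_A <- rank(A, ties.method = "first")
  cut_M <- floor(n * trim_M)
  cut_A <- floor(n * trim_A)
  keep <- rk_M > cut_M & rk_M <= n - cut_M & rk_A > cut_A & rk_A <= n - cut_A
  if (sum(keep) < 10L) {
    warning(sprintf("fewer than 10 genes survive TMM trimming (%d); factor set to 1",
                    sum(keep)))
    return(1)
  }
  2^(sum(w[keep] * M[keep]) / sum(w[keep]))
}

#' @export
print.norm_factors <- function(x, ...) {
  cat(sprintf("norm_factors for %d samples (reference: %s)\n",
              length(x$factor), x$ref_sample))
  print(data.frame(lib_size = x$lib_size, factor = x$factor), ...)
  invisible(x)
}
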