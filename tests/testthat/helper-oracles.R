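# Independent straight-line oracles used to check the package's
# implementations. These are deliberately naive (direct-definition, loops,
# enumeration) and share no code with the package internals.

# O(m^2) direct-definition Benjamini-Hochberg step-up: q_(i) is the minimum
# over j >= i (in sorted-p order) of p_(j) * m / j, capped at 1.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    vals <- numeric(0)
    for (j in i:m) {
      vals <- c(vals, p[ord[j]] * m / j)
    }
    q[ord[i]] <- min(1, min(vals))
  }
  q
}

# straight-line TMM: doubly trimmed, precision-weighted mean of M values
# against a given reference column, then geometric-mean-1 rescaling
tmm_oracle <- function(Y, trim_M = 0.30, trim_A = 0.05) {
  N <- colSums(Y)
  cpm0 <- sweep(Y, 2, N, "/") * 1e6
  q75 <- apply(cpm0, 2, quantile, probs = 0.75, names = FALSE)
  r <- which.min(abs(q75 - mean(q75)))
  f <- rep(1, ncol(Y))
  for (s in seq_len(ncol(Y))) {
    if (s == r) next
    keep0 <- Y[, s] > 0 & Y[, r] > 0
    ys <- Y[keep0, s]; yr <- Y[keep0, r]
    M <- log2((ys / N[s]) / (yr / N[r]))
    A <- 0.5 * log2((ys / N[s]) * (yr / N[r]))
    w <- 1 / ((N[s] - ys) / (N[s] * ys) + (N[r] - yr) / (N[r] * yr))
    n <- length(M)
    rkM <- rank(M, ties.method = "first")
    rkA <- rank(A, ties.method = "first")
    keep <- rkM > floor(n * trim_M) & rkM <= n - floor(n * trim_M) &
      rkA > floor(n * trim_A) & rkA <= n - floor(n * trim_A)
    f[s] <- 2^(sum(w[keep] * M[keep]) / sum(w[keep]))
  }
  f / exp(mean(log(f)))
}

# naive triple-loop topological overlap
tom_oracle <- function(A) {
  n <- nrow(A)
  k <- rowSums(A) - diag(A)
  out <- matrix(1, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      L <- 0
      for (u in seq_len(n)) {
        if (u != i && u != j) L <- L + A[i, u] * A[u, j]
      }
      out[i, j] <- (L + A[i, j]) / (min(k[i], k[j]) + 1 - A[i, j])
    }
  }
  out
}

# exact hypergeometric upper tail by enumerating all C(N, n) target draws
hyper_enum_oracle <- function(b, B, N, n) {
  draws <- combn(N, n)
  in_term <- seq_len(N) <= B   # first B universe elements carry the term
  hits <- apply(draws, 2, function(cols) sum(in_term[cols]))
  mean(hits >= b)
}

# brute-force directional intersection over per-feature membership patterns
intersect_oracle <- function(up, down, subset_lineages, all_lineages) {
  feats <- unique(c(unlist(up), unlist(down)))
  res <- list(shared_up = character(0), shared_down = character(0),
              shared_any = character(0), exclusive_any = character(0))
  for (f in feats) {
    st <- vapply(all_lineages, function(l) {
      if (f %in% up[[l]]) "up" else if (f %in% down[[l]]) "down" else "ns"
    }, character(1))
    in_s <- st[subset_lineages]
    if (all(in_s == "up")) res$shared_up <- c(res$shared_up, f)
    if (all(in_s == "down")) res$shared_down <- c(res$shared_down, f)
    if (all(in_s != "ns")) {
      res$shared_any <- c(res$shared_any, f)
      de_set <- names(st)[st != "ns"]
      if (setequal(de_set, subset_lineages)) {
        res$exclusive_any <- c(res$exclusive_any, f)
      }
    }
  }
  lapply(res, sort)
}

# random count matrix fixture
random_counts <- function(G, S, mu_log_mean = 4, phi = 0.1, seed = 1) {
  set.seed(seed)
  mu <- exp(rnorm(G, mu_log_mean, 1))
  Y <- matrix(rnbinom(G * S, mu = rep(mu, S), size = 1 / phi), G, S,
              dimnames = list(sprintf("g%04d", seq_len(G)),
                              sprintf("s%02d", seq_len(S))))
  Y
}

two_group_sheet <- function(Y, species = "sp") {
  data.frame(sample_id = colnames(Y), species = species,
             habitat = rep(c("FW", "SW"), each = ncol(Y) / 2),
             stringsAsFactors = FALSE)
}
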