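# Negative binomial GLM machinery: log-likelihood, Fisher-scoring fits,
# Cox-Reid adjusted profile likelihood dispersion estimation, and the
# likelihood-ratio test. Parameterization throughout: var = mu + phi * mu^2,
# i.e. size = 1/phi, with phi = 0 the Poisson limit.

#' Negative binomial log-likelihood
#'
#' Log pmf of the NB distribution parameterized by mean `mu` and dispersion
#' `phi` (variance `mu + phi*mu^2`); `phi = 0` is evaluated as the Poisson
#' limit. Vectorized over its arguments.
#'
#' @param y non-negative integer counts.
#' @param mu positive means.
#' @param phi non-negative dispersions.
#' @return numeric vector of log-likelihood contributions.
#' @export
nb_loglik <- function(y, mu, phi) {
  assert_that(all(y == round(y)) && all(y >= 0),
              "y must contain non-negative integers")
  assert_that(all(mu > 0), "mu must be positive")
  assert_that(all(phi >= 0), "phi must be non-negative")
  n <- max(length(y), length(mu), length(phi))
  y <- rep_len(y, n); mu <- rep_len(mu, n); phi <- rep_len(phi, n)
  out <- numeric(n)
  pois <- phi == 0
  if (any(pois)) out[pois] <- stats::dpois(y[pois], mu[pois], log = TRUE)
  if (any(!pois)) {
    out[!pois] <- stats::dnbinom(y[!pois], size = 1 / phi[!pois],
                                 mu = mu[!pois], log = TRUE)
  }
  out
}

# NB log-likelihood for a count matrix Y (features x samples) against fitted
# means MU with per-feature dispersion phi (scalar or length-nrow vector).
# Returns the per-feature row sums.
nb_loglik_rows <- function(Y, MU, phi) {
  phi <- rep_len(phi, nrow(Y))
  ll <- matrix(0, nrow(Y), ncol(Y))
  pois <- phi == 0
  if (any(pois)) {
    ll[pois, ] <- stats::dpois(Y[pois, , drop = FALSE],
                               MU[pois, , drop = FALSE], log = TRUE)
  }
  if (any(!pois)) {
    ll[!pois, ] <- stats::dnbinom(Y[!pois, , drop = FALSE],
                                  size = 1 / phi[!pois],
                                  mu = MU[!pois, , drop = FALSE], log = TRUE)
  }
  rowSums(ll)
}

#' Fit a negative binomial GLM to one feature
#'
#' Maximizes the NB log-likelihood of `log mu_i = x_i' beta + o_i` by Fisher
#' scoring with step halving, declaring convergence when `max|delta beta| <
#' 1e-8` (at most 50 iterations). The deviance is twice the gap to the
#' saturated model. An all-zero response under an intercept-only model gets
#' its coefficient floored (fitted mean 1e-8 of the effective library size)
#' and is flagged.
#'
#' @param y integer count vector for one feature.
#' @param X design matrix (samples x coefficients), full column rank.
#' @param offsets per-sample offsets, normally `log(N_i * f_i)`.
#' @param phi scalar NB dispersion held fixed during the fit.
#' @return list with `coefficients`, `fitted`, `deviance`, `loglik`,
#'   `iterations`, `converged`, `flagged`.
#' @export
fit_nb_glm <- function(y, X, offsets = rep(0, length(y)), phi = 0) {
  X <- as.matrix(X)
  assert_that(nrow(X) == length(y), "design rows must match length(y)")
  assert_that(qr(X)$rank == ncol(X), "design matrix is rank-deficient")
  assert_that(all(y == round(y)) && all(y >= 0),
              "y must contain non-negative integers")

  flagged <- FALSE
  if (all(y == 0) && ncol(X) == 1L && all(X == X[1L, 1L])) {
    beta <- log(1e-8) / X[1L, 1L]
    mu <- as.vector(exp(X %*% beta + offsets))
    warning("all-zero feature: coefficient floored")
    return(list(coefficients = beta, fitted = mu,
                deviance = 2 * (nb_saturated_loglik(y, phi) -
                                  sum(nb_loglik(y, mu, phi))),
                loglik = sum(nb_loglik(y, mu, phi)),
                iterations = 0L, converged = TRUE, flagged = TRUE))
  }

  # initialize from a least-squares fit on the log scale
  z <- log(pmax(y, 0.125)) - offsets
  beta <- qr.solve(X, z)
  mu <- as.vector(exp(X %*% beta + offsets))
  ll <- sum(nb_loglik(y, mu, phi))
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(50L)) {
    w <- mu / (1 + phi * mu)                     # Fisher weights
    score <- crossprod(X, (y - mu) / (1 + phi * mu))
    info <- crossprod(X, X * w)
    delta <- solve(info, score)
    # step-halving keeps the likelihood non-decreasing
    step <- 1
    repeat {
      beta_new <- beta + step * delta
      mu_new <- as.vector(exp(X %*% beta_new + offsets))
      ll_new <- sum(nb_loglik(y, pmax(mu_new, 1e-300), phi))
      if (ll_new >= ll - 1e-12 || step < 1e-8) break
      step <- step / 2
    }
    moved <- max(abs(step * delta))
    beta <- beta_new; mu <- mu_new; ll <- ll_new
    if (moved < 1e-8) { converged <- TRUE; break }
  }
  list(coefficients = as.vector(beta), fitted = mu,
       deviance = 2 * (nb_saturated_loglik(y, phi) - ll),
       loglik = ll, iterations = iter, converged = converged,
       flagged = flagged)
}

# saturated NB log-likelihood (mu = y; zero counts contribute 0)
nb_saturated_loglik <- function(y, phi) {
  pos <- y > 0
  if (!any(pos)) return(0)
  sum(nb_loglik(y[pos], y[pos], phi))
}

# ---- vectorized one-way (group) fits ---------------------------------------
# For a one-way layout the NB MLE decomposes into one scalar log-mean per
# group per feature, solved by vectorized Fisher scoring across all features.

# Coerce a design specification to a group factor when it describes a one-way
# layout (a factor/character vector, or a matrix whose distinct rows span its
# column rank). Returns NULL otherwise.
design_as_groups <- function(design, n_samples) {
  if (is.factor(design) || is.character(design)) {
    g <- factor(design)
    assert_that(length(g) == n_samples, "design length must match samples")
    return(g)
  }
  X <- as.matrix(design)
  assert_that(nrow(X) == n_samples, "design rows must match samples")
  patt <- apply(X, 1L, paste, collapse = "\r")
  g <- factor(patt, levels = unique(patt))
  if (nlevels(g) == ncol(X) && qr(X)$rank == ncol(X)) g else NULL
}

# Fit per-group log-means for every feature at once.
# Y: features x samples; groups: factor over samples; eff: effective library
# sizes; phi: scalar or per-feature vector. Returns list(B, MU, loglik, adj)
# where adj is the Cox-Reid 0.5*log det(X'WX) term in group-means coding.
nb_group_fit <- function(Y, groups, eff, phi, cr_adjust = FALSE) {
  G <- nrow(Y); S <- ncol(Y)
  phi <- rep_len(phi, G)
  lev <- levels(groups)
  B <- matrix(NA_real_, G, length(lev), dimnames = list(rownames(Y), lev))
  MU <- matrix(NA_real_, G, S, dimnames = dimnames(Y))
  adj <- if (cr_adjust) numeric(G) else NULL
  for (k in seq_along(lev)) {
    idx <- which(groups == lev[k])
    Yk <- Y[, idx, drop = FALSE]
    ek <- eff[idx]
    tot <- rowSums(Yk)
    zero <- tot == 0
    b <- log(pmax(tot, 1e-8)) - log(sum(ek))
    # Fisher scoring on the scalar group mean; exact at phi = 0 immediately
    for (it in seq_len(50L)) {
      MUk <- exp(outer(b, log(ek), "+"))
      denom <- 1 + MUk * phi
      score <- rowSums((Yk - MUk) / denom)
      info <- rowSums(MUk / denom)
      delta <- score / pmax(info, 1e-300)
      delta <- pmin(pmax(delta, -5), 5)
      b <- b + delta
      if (max(abs(delta)) < 1e-10) break
    }
    b[zero] <- log(1e-8)   # floor: fitted mean 1e-8 of effective library
    B[, k] <- b
    MUk <- exp(outer(b, log(ek), "+"))
    MU[, idx] <- MUk
    if (cr_adjust) {
      w <- MUk / (1 + MUk * phi)
      adj <- adj + 0.5 * log(pmax(rowSums(w), 1e-300))
    }
  }
  list(B = B, MU = MU, loglik = nb_loglik_rows(Y, MU, phi), adj = adj)
}

# Cox-Reid adjusted profile log-likelihood per feature at dispersion phi
# (scalar or per-feature vector).
nb_apl <- function(Y, groups, eff, phi) {
  fit <- nb_group_fit(Y, groups, eff, phi, cr_adjust = TRUE)
  fit$loglik - fit$adj
}

# ---- dispersion estimation -------------------------------------------------

#' Estimate common and tagwise NB dispersions
#'
#' Empirical-Bayes dispersion estimation from Cox-Reid adjusted profile
#' likelihoods (APL). The common dispersion maximizes the summed APL over a
#' 21-point log-spaced grid refined by golden-section search. The tagwise
#' dispersion of feature g maximizes the weighted-likelihood objective
#' `APL_g(phi) + w0 * mean-APL(phi)` with prior weight
#' `w0 = prior_df / residual_df`, shrinking per-feature estimates toward the
#' value supported by all features jointly. No abundance trend is fitted.
#'
#' @param counts count matrix or [count_matrix()] (features x samples).
#' @param design group factor, or a one-way design matrix (e.g. intercept +
#'   habitat indicator).
#' @param norm optional `norm_factors`; defaults to column-sum library sizes.
#' @param prior_df prior degrees of freedom for tagwise shrinkage
#'   (default 10).
#' @param grid_range search bounds for phi (default `c(1e-4, 4)`).
#' @param grid_points number of log-spaced grid points (default 21).
#' @return object of class `dispersion_estimates`: list with `common`,
#'   `tagwise` (named per feature), `prior_df`, `w0`, `grid_range`.
#' @export
estimate_dispersion <- function(counts, design, norm = NULL, prior_df = 10,
                                grid_range = c(1e-4, 4), grid_points = 21L) {
  Y <- counts_of(counts)
  eff <- effective_lib_sizes(Y, norm)
  groups <- design_as_groups(design, ncol(Y))
  assert_that(!is.null(groups),
              "dispersion estimation supports one-way group designs only")
  G <- nrow(Y)
  res_df <- ncol(Y) - nlevels(groups)

  lgrid <- seq(log(grid_range[1L]), log(grid_range[2L]),
               length.out = grid_points)
  APL <- vapply(lgrid, function(lp) nb_apl(Y, groups, eff, exp(lp)),
                numeric(G))           # G x grid_points

  if (res_df < 1L) {
    warning("no residual degrees of freedom; tagwise dispersion set to common")
    tot <- colSums(APL)
    common <- exp(golden_max(function(lp) sum(nb_apl(Y, groups, eff, exp(lp))),
                             lgrid, which.max(tot)))
    tw <- rep(common, G)
    names(tw) <- rownames(Y)
    return(structure(list(common = common, tagwise = tw, prior_df = prior_df,
                          w0 = Inf, grid_range = grid_range),
                     class = "dispersion_estimates"))
  }

  # common dispersion: maximize the APL sum
  tot <- colSums(APL)
  i_best <- which.max(tot)
  if (i_best %in% c(1L, grid_points)) {
    warning("common dispersion at grid boundary; possible dispersion outside search bounds")
  }
  common <- exp(golden_max(function(lp) sum(nb_apl(Y, groups, eff, exp(lp))),
                           lgrid, i_best))

  # tagwise: APL_g + w0 * mean APL, mean interpolated from the grid
  w0 <- prior_df / res_df
  abar <- colMeans(APL)
  abar_fun <- stats::splinefun(lgrid, abar, method = "natural")
  obj_grid <- APL + matrix(w0 * abar, G, grid_points, byrow = TRUE)
  j_best <- max.col(obj_grid, ties.method = "first")
  lo <- lgrid[pmax(j_best - 1L, 1L)]
  hi <- lgrid[pmin(j_best + 1L, grid_points)]
  # vectorized ternary search per feature
  for (it in seq_len(40L)) {
    m1 <- lo + (hi - lo) / 3
    m2 <- hi - (hi - lo) / 3
    f1 <- nb_apl(Y, groups, eff, exp(m1)) + w0 * abar_fun(m1)
    f2 <- nb_apl(Y, groups, eff, exp(m2)) + w0 * abar_fun(m2)
    take_lo <- f1 < f2
    lo <- ifelse(take_lo, m1, lo)
    hi <- ifelse(take_lo, hi, m2)
    if (max(hi - lo) < 1e-4) break
  }
  tw <- exp((lo + hi) / 2)
  names(tw) <- rownames(Y)
  structure(list(common = common, tagwise = tw, prior_df = prior_df,
                 w0 = w0, grid_range = grid_range),
            class = "dispersion_estimates")
}

# golden-section refinement of a grid maximum (on the transformed axis)
golden_max <- function(f, grid, i_best) {
  lo <- grid[max(i_best - 1L, 1L)]
  hi <- grid[min(i_best + 1L, length(grid))]
  gr <- (sqrt(5) - 1) / 2
  x1 <- hi - gr * (hi - lo); x2 <- lo + gr * (hi - lo)
  f1 <- f(x1); f2 <- f(x2)
  while (hi - lo > 1e-5) {
    if (f1 < f2) {
      lo <- x1; x1 <- x2; f1 <- f2
      x2 <- lo + gr * (hi - lo); f2 <- f(x2)
    } else {
      hi <- x2; x2 <- x1; f2 <- f1
      x1 <- hi - gr * (hi - lo); f1 <- f(x1)
    }
  }
  (lo + hi) / 2
}

#' @export
print.dispersion_estimates <- function(x, ...) {
  cat(sprintf("dispersion_estimates: common = %.4g; tagwise over %d features (median %.4g); prior_df = %g\n",
              x$common, length(x$tagwise), stats::median(x$tagwise), x$prior_df))
  invisible(x)
}

# ---- likelihood-ratio test -------------------------------------------------

#' Negative binomial GLM likelihood-ratio test
#'
#' Per-feature likelihood-ratio test of a full one-way design against a
#' nested reduced design, with the tagwise dispersion held fixed across both
#' fits. `LR = 2 * (loglik_full - loglik_reduced)` is referred to a
#' chi-squared distribution with degrees of freedom equal to the difference
#' in design ranks. Tiny negative LR values (above `-1e-8`) are clipped to
#' zero; larger negatives signal a convergence failure and raise an error.
#'
#' @param counts count matrix or [count_matrix()].
#' @param design_full group factor or one-way design matrix.
#' @param design_reduced nested reduced design (often intercept-only).
#' @param norm optional `norm_factors`.
#' @param dispersions `dispersion_estimates`, or a numeric dispersion
#'   (scalar or per-feature) used for every fit.
#' @return data.frame with `feature_id`, `LR`, `df`, `PValue`.
#' @export
nb_lrt <- function(counts, design_full, design_reduced, norm = NULL,
                   dispersions) {
  Y <- counts_of(counts)
  eff <- effective_lib_sizes(Y, norm)
  gf <- design_as_groups(design_full, ncol(Y))
  gr <- design_as_groups(design_reduced, ncol(Y))
  assert_that(!is.null(gf) && !is.null(gr),
              "nb_lrt supports one-way group designs only")
  # nesting: reduced groups must be a coarsening of full groups
  assert_that(all(tapply(as.integer(gr), gf, function(v) length(unique(v))) == 1L),
              "reduced design is not nested in the full design")
  df <- nlevels(gf) - nlevels(gr)
  assert_that(df >= 1L, "full design adds no parameters over the reduced design")

  phi <- if (inherits(dispersions, "dispersion_estimates")) {
    dispersions$tagwise
  } else {
    rep_len(dispersions, nrow(Y))
  }
  ll_full <- nb_group_fit(Y, gf, eff, phi)$loglik
  ll_red <- nb_group_fit(Y, gr, eff, phi)$loglik
  LR <- 2 * (ll_full - ll_red)
  assert_that(all(LR > -1e-8),
              "negative likelihood ratio beyond tolerance: convergence failure")
  LR <- pmax(LR, 0)
  data.frame(feature_id = rownames(Y), LR = LR, df = df,
             PValue = stats::pchisq(LR, df = df, lower.tail = FALSE),
             stringsAsFactors = FALSE, row.names = NULL)
}
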