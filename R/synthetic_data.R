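# Seeded generators for multi-lineage NB count data with planted convergent,
# divergent, lineage-specific and null effects, planted co-expression
# modules, and planted GO enrichment. Every pipeline stage is testable
# against the emitted ground truth without external downloads.

#' Configuration for the multi-lineage count simulator
#'
#' Defaults emulate the comparative study design: four independent lineages,
#' each sampled as a freshwater/saltwater ecotype pair with 6, 5, 3 and 1
#' individuals per habitat respectively (the last lineage exercising the
#' no-replicate edge case), a shared orthogroup universe with occasional
#' paralogs, and lineage (phylogenetic) expression offsets that are larger
#' than habitat effects.
#'
#' @param n_lineages number of lineages (default 4).
#' @param samples_per_habitat individuals per habitat per lineage, recycled
#'   to `n_lineages` (default `c(6, 5, 3, 1)`).
#' @param n_orthogroups number of orthogroups (default 2000).
#' @param paralog_rate Poisson rate of extra per-species gene copies per
#'   orthogroup (default 0.2).
#' @param baseline_log2_mean,baseline_log2_sd log2 relative-abundance
#'   distribution of orthogroup baselines (defaults 3 and 2).
#' @param lineage_offset_sd SD of per-lineage log2 expression offsets
#'   (default 1.5, so that phylogenetic divergence dominates habitat
#'   effects, as observed in cross-lineage expression data).
#' @param phi0 asymptotic NB dispersion (default 0.05).
#' @param phi_slope dispersion inflation at low counts, `phi = phi0 +
#'   phi_slope / mu` (default 2).
#' @param prop_effects named proportions of orthogroup effect classes
#'   `convergent`, `divergent`, `lineage_specific`, `null`; must sum to 1
#'   (defaults 0.05 / 0.05 / 0.10 / 0.80).
#' @param lfc_range range of |log2 fold change| for non-null effects
#'   (default `c(1, 3)`).
#' @param lib_size_meanlog,lib_size_sdlog lognormal library-size parameters
#'   (defaults `log(5e6)` and 0.2).
#' @param seed mandatory integer seed.
#' @return a validated `sim_config` list.
#' @export
multilineage_config <- function(n_lineages = 4,
                                samples_per_habitat = c(6, 5, 3, 1),
                                n_orthogroups = 2000,
                                paralog_rate = 0.2,
                                baseline_log2_mean = 3,
                                baseline_log2_sd = 2,
                                lineage_offset_sd = 1.5,
                                phi0 = 0.05,
                                phi_slope = 2,
                                prop_effects = c(convergent = 0.05,
                                                 divergent = 0.05,
                                                 lineage_specific = 0.10,
                                                 null = 0.80),
                                lfc_range = c(1, 3),
                                lib_size_meanlog = log(5e6),
                                lib_size_sdlog = 0.2,
                                seed) {
  assert_that(!missing(seed), "seed is mandatory")
  need <- c("convergent", "divergent", "lineage_specific", "null")
  assert_that(all(need %in% names(prop_effects)),
              "prop_effects needs: %s", paste(need, collapse = ", "))
  assert_that(abs(sum(prop_effects) - 1) < 1e-8, "effect proportions must sum to 1")
  assert_that(all(prop_effects >= 0), "effect proportions must be non-negative")
  assert_that(phi0 > 0 && phi_slope >= 0 && baseline_log2_sd > 0 &&
                lineage_offset_sd >= 0 && lib_size_sdlog > 0,
              "scale parameters must be positive")
  assert_that(n_lineages >= 2, "need at least two lineages")
  cfg <- list(n_lineages = n_lineages,
              samples_per_habitat = rep_len(samples_per_habitat, n_lineages),
              n_orthogroups = n_orthogroups,
              paralog_rate = paralog_rate,
              baseline_log2_mean = baseline_log2_mean,
              baseline_log2_sd = baseline_log2_sd,
              lineage_offset_sd = lineage_offset_sd,
              phi0 = phi0, phi_slope = phi_slope,
              prop_effects = prop_effects[need],
              lfc_range = lfc_range,
              lib_size_meanlog = lib_size_meanlog,
              lib_size_sdlog = lib_size_sdlog,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate multi-lineage gill count data with planted effects
#'
#' Draws, per orthogroup, a shared baseline log2 relative abundance and a
#' per-lineage offset; splits each orthogroup's abundance across
#' `1 + Poisson(paralog_rate)` per-species gene copies by a symmetric
#' Dirichlet(1); and samples counts `y ~ NB(mu, phi)` with
#' `mu = L_i * p_g * 2^(LFC * I[saltwater])` and `phi = phi0 +
#' phi_slope / mu`. Effect classes: convergent orthogroups carry the same
#' log2 fold change sign in every lineage, divergent ones are DE in every
#' lineage with at least two sign patterns, lineage-specific ones are DE in
#' a single lineage, and null ones in none. Fully seeded and reproducible.
#'
#' @param config a [multilineage_config()].
#' @return list with `count_matrices` (named list of [count_matrix()]),
#'   `sample_sheet`, `orthogroup_map`, and `truth` (list with `classes`,
#'   `lfc` orthogroup x lineage matrix, `genes` data.frame, `lib_sizes`).
#' @export
simulate_multilineage <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    nL <- config$n_lineages
    nOG <- config$n_orthogroups
    species <- sprintf("lineage%02d", seq_len(nL))
    og_ids <- sprintf("OG%05d", seq_len(nOG))

    # effect classes in fixed proportions, shuffled across orthogroups
    n_per <- round(config$prop_effects * nOG)
    n_per["null"] <- nOG - sum(n_per[c("convergent", "divergent",
                                       "lineage_specific")])
    classes <- sample(rep(names(n_per), times = n_per))
    names(classes) <- og_ids

    # true log2 fold changes per orthogroup and lineage
    mag <- matrix(stats::runif(nOG * nL, config$lfc_range[1L],
                               config$lfc_range[2L]), nOG, nL)
    lfc <- matrix(0, nOG, nL, dimnames = list(og_ids, species))
    conv <- classes == "convergent"
    if (any(conv)) {
      s <- sample(c(-1, 1), sum(conv), replace = TRUE)
      lfc[conv, ] <- s * mag[conv, 1L]   # same sign and size in all lineages
    }
    dive <- classes == "divergent"
    if (any(dive)) {
      s <- matrix(sample(c(-1, 1), sum(dive) * nL, replace = TRUE),
                  sum(dive), nL)
      uniform <- abs(rowSums(s)) == nL   # force >= 2 sign patterns
      if (any(uniform)) {
        flip <- sample.int(nL, sum(uniform), replace = TRUE)
        s[cbind(which(uniform), flip)] <- -s[cbind(which(uniform), flip)]
      }
      lfc[dive, ] <- s * mag[dive, , drop = FALSE]
    }
    lsp <- classes == "lineage_specific"
    if (any(lsp)) {
      pick <- sample.int(nL, sum(lsp), replace = TRUE)
      sgn <- sample(c(-1, 1), sum(lsp), replace = TRUE)
      lfc[cbind(which(lsp), pick)] <- sgn * mag[cbind(which(lsp), pick)]
    }

    baseline <- stats::rnorm(nOG, config$baseline_log2_mean,
                             config$baseline_log2_sd)
    offsets <- matrix(stats::rnorm(nOG * nL, 0, config$lineage_offset_sd),
                      nOG, nL)

    count_matrices <- list()
    map_rows <- lapply(og_ids, function(og) stats::setNames(
      vector("list", nL), species))
    names(map_rows) <- og_ids
    sheet_rows <- list()
    gene_rows <- list()
    lib_sizes <- list()

    for (l in seq_len(nL)) {
      sp <- species[l]
      n_h <- config$samples_per_habitat[l]
      sample_ids <- c(sprintf("%s_FW_%d", sp, seq_len(n_h)),
                      sprintf("%s_SW_%d", sp, seq_len(n_h)))
      habitat <- rep(c("FW", "SW"), each = n_h)
      sheet_rows[[sp]] <- data.frame(sample_id = sample_ids, species = sp,
                                     habitat = habitat,
                                     stringsAsFactors = FALSE)
      L <- round(stats::rlnorm(2 * n_h, config$lib_size_meanlog,
                               config$lib_size_sdlog))
      lib_sizes[[sp]] <- stats::setNames(L, sample_ids)

      n_copies <- 1L + stats::rpois(nOG, config$paralog_rate)
      gene_og <- rep(seq_len(nOG), n_copies)
      copy_idx <- sequence(n_copies)
      gene_ids <- sprintf("%s_%s_c%d", sp, og_ids[gene_og], copy_idx)
      # symmetric Dirichlet(1) split of the orthogroup abundance
      gam <- stats::rexp(length(gene_og))
      tot <- rowsum(gam, gene_og)[, 1L]
      split_frac <- gam / tot[gene_og]
      rel <- 2^(baseline[gene_og] + offsets[gene_og, l]) * split_frac
      p <- rel / sum(rel)

      MU <- outer(p, L) * 2^(lfc[gene_og, l] %o% as.numeric(habitat == "SW"))
      PHI <- config$phi0 + config$phi_slope / MU
      Ycnt <- matrix(stats::rnbinom(length(MU), mu = MU, size = 1 / PHI),
                     nrow(MU), ncol(MU),
                     dimnames = list(gene_ids, sample_ids))
      count_matrices[[sp]] <- count_matrix(Ycnt, species = sp)

      for (i in seq_len(nOG)) map_rows[[i]][[sp]] <- character(0)
      sp_genes <- split(gene_ids, og_ids[gene_og])
      for (og in names(sp_genes)) map_rows[[og]][[sp]] <- sp_genes[[og]]
      gene_rows[[sp]] <- data.frame(gene_id = gene_ids, species = sp,
                                    orthogroup = og_ids[gene_og],
                                    stringsAsFactors = FALSE)
    }

    map <- structure(map_rows, species = species, class = "orthogroup_map")
    sheet <- sample_sheet(do.call(rbind, c(sheet_rows,
                                           list(make.row.names = FALSE))))
    truth <- list(classes = classes, lfc = lfc,
                  genes = do.call(rbind, c(gene_rows,
                                           list(make.row.names = FALSE))),
                  lib_sizes = lib_sizes)
    list(count_matrices = count_matrices, sample_sheet = sheet,
         orthogroup_map = map, truth = truth)
  })
}

#' Simulate expression data with planted co-expression modules
#'
#' Each module m has a latent per-sample eigengene `e_m ~ N(0, 1)`; member
#' gene g is `x_g = rho_g * e_m + sqrt(1 - rho_g^2) * noise` with loading
#' `rho_g` drawn uniformly from `loading_range`. When `trait_effect > 0`,
#' module 1's eigengene is tied to the binary habitat trait (freshwater = 0,
#' saltwater = 1): `e_1 = standardize(trait_effect * trait + N(0, 1))`.
#' Noise genes are pure standard normal.
#'
#' @param n_samples number of samples (default 40; half FW, half SW).
#' @param module_sizes integer sizes of the planted modules (default
#'   `c(100, 80, 60)`).
#' @param loading_range range of gene loadings in (0, 1) (default
#'   `c(0.7, 0.9)`).
#' @param trait_effect strength of the trait's drive on module 1
#'   (default 2).
#' @param n_noise number of unstructured genes (default 200).
#' @param seed mandatory integer seed.
#' @return list with `expr` (genes x samples), `labels` (named truth
#'   labels, 0 for noise genes), `trait` (0/1 vector over samples).
#' @export
simulate_modules <- function(n_samples = 40, module_sizes = c(100, 80, 60),
                             loading_range = c(0.7, 0.9), trait_effect = 2,
                             n_noise = 200, seed) {
  assert_that(!missing(seed), "seed is mandatory")
  assert_that(all(loading_range > 0 & loading_range < 1),
              "loadings must lie in (0, 1)")
  with_seed(seed, {
    n_half <- floor(n_samples / 2)
    trait <- c(rep(0, n_samples - n_half), rep(1, n_half))
    sample_ids <- sprintf("s%02d_%s", seq_len(n_samples),
                          ifelse(trait == 0, "FW", "SW"))
    M <- length(module_sizes)
    E <- matrix(stats::rnorm(M * n_samples), M, n_samples)
    if (trait_effect != 0) {
      E[1L, ] <- trait_effect * trait + stats::rnorm(n_samples)
    }
    E <- t(scale(t(E)))   # unit-variance latent eigengenes

    genes <- list()
    labels <- integer(0)
    for (m in seq_len(M)) {
      rho <- stats::runif(module_sizes[m], loading_range[1L], loading_range[2L])
      X <- rho %o% E[m, ] +
        sqrt(1 - rho^2) * matrix(stats::rnorm(module_sizes[m] * n_samples),
                                 module_sizes[m], n_samples)
      rownames(X) <- sprintf("mod%d_g%03d", m, seq_len(module_sizes[m]))
      genes[[m]] <- X
      labels <- c(labels, stats::setNames(rep(m, module_sizes[m]), rownames(X)))
    }
    if (n_noise > 0) {
      X <- matrix(stats::rnorm(n_noise * n_samples), n_noise, n_samples)
      rownames(X) <- sprintf("noise_g%03d", seq_len(n_noise))
      genes[[M + 1L]] <- X
      labels <- c(labels, stats::setNames(rep(0L, n_noise), rownames(X)))
    }
    expr <- do.call(rbind, genes)
    colnames(expr) <- sample_ids
    list(expr = expr, labels = labels, trait = trait)
  })
}

#' Simulate a GO annotation with planted enrichment
#'
#' Every background gene receives every term independently at `base_rate`;
#' for the `n_planted` planted terms, target genes receive the term at
#' `planted_rate` instead, creating true over-representation.
#'
#' @param background character vector of universe gene ids.
#' @param target character vector of target gene ids (subset of
#'   background).
#' @param n_terms number of GO terms (default 50).
#' @param base_rate background annotation rate (default 0.05).
#' @param planted_rate annotation rate of planted terms within the target
#'   (default 0.4; must exceed `base_rate`).
#' @param n_planted number of planted terms (default 1).
#' @param seed mandatory integer seed.
#' @return list with `annotation` (a [go_annotation()]) and `planted`
#'   (character vector of planted term ids).
#' @export
simulate_go_annotation <- function(background, target, n_terms = 50,
                                   base_rate = 0.05, planted_rate = 0.4,
                                   n_planted = 1, seed) {
  assert_that(!missing(seed), "seed is mandatory")
  assert_that(all(target %in% background), "target must be a subset of background")
  assert_that(planted_rate > base_rate, "planted_rate must exceed base_rate")
  with_seed(seed, {
    terms <- sprintf("GO:%07d", seq_len(n_terms))
    planted <- terms[seq_len(n_planted)]
    is_target <- background %in% target
    sets <- lapply(seq_along(background), function(i) character(0))
    names(sets) <- background
    for (tm in terms) {
      rate <- rep(base_rate, length(background))
      if (tm %in% planted) rate[is_target] <- planted_rate
      hit <- stats::runif(length(background)) < rate
      for (g in which(hit)) sets[[g]] <- c(sets[[g]], tm)
    }
    list(annotation = go_annotation(sets), planted = planted)
  })
}
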