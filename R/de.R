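# Differential expression driver: filter -> TMM -> dispersion -> two-group
# NB GLM (saltwater vs freshwater) -> LRT -> Benjamini-Hochberg.

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment: with p-values sorted ascending,
#' `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1 and returned in input
#' order. Missing p-values propagate as missing and are excluded from `m`.
#'
#' @param pvals numeric vector of p-values in `[0, 1]` (NA/NaN allowed).
#' @return numeric vector of q-values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  ok <- !is.na(pvals)
  assert_that(all(pvals[ok] >= 0 & pvals[ok] <= 1), "p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(pvals))
  p <- pvals[ok]
  m <- length(p)
  if (m > 0L) {
    ord <- order(p)
    q <- pmin(1, rev(cummin(rev(p[ord] * m / seq_len(m)))))
    tmp <- numeric(m)
    tmp[ord] <- q
    out[ok] <- tmp
  }
  out
}

#' Two-group differential expression for one species
#'
#' Runs the full within-species pipeline comparing saltwater against
#' freshwater individuals: expression filtering ([filter_by_expression()]),
#' TMM normalization ([tmm_factors()]), empirical-Bayes dispersion estimation
#' ([estimate_dispersion()]), per-feature negative binomial GLM
#' likelihood-ratio tests ([nb_lrt()]), and Benjamini-Hochberg adjustment.
#' Log2 fold changes are reported for saltwater relative to freshwater, so a
#' positive value means higher expression in the saltwater ecotype.
#'
#' When either habitat has fewer than two individuals the dispersion cannot
#' be estimated from replicates; a configured fixed dispersion
#' (`fixed_dispersion`, default 0.1) is used instead with a prominent
#' warning.
#'
#' @param counts a [count_matrix()] (or plain matrix) for one species.
#' @param sheet a `sample_sheet` covering the matrix's samples; only the
#'   matching species' rows are used when `counts` is a [count_matrix()].
#' @param alpha significance threshold on the q-value (default 0.05).
#' @param min_cpm,min_samples expression filter parameters (defaults 2 and 3).
#' @param prior_df prior degrees of freedom for tagwise dispersion.
#' @param fixed_dispersion dispersion used when replicates are insufficient.
#' @param filter logical; apply the expression filter (TRUE for gene-level
#'   analyses; orthogroup-level analyses apply their own retention filter).
#' @return data.frame of class `de_result` with columns `feature_id`,
#'   `logFC`, `logCPM`, `LR`, `PValue`, `FDR`, `direction`, sorted by FDR
#'   then p-value then feature id.
#' @export
run_de <- function(counts, sheet, alpha = 0.05, min_cpm = 2, min_samples = 3,
                   prior_df = 10, fixed_dispersion = 0.1, filter = TRUE) {
  cm_species <- if (inherits(counts, "count_matrix")) counts$species else NA
  Y <- counts_of(counts)
  sheet <- as.data.frame(sheet)
  if (!is.na(cm_species) && cm_species %in% sheet$species) {
    sheet <- sheet[sheet$species == cm_species, , drop = FALSE]
  }
  missing <- setdiff(colnames(Y), sheet$sample_id)
  assert_that(length(missing) == 0L,
              "samples absent from the sample sheet: %s",
              paste(missing, collapse = ", "))
  sheet <- sheet[match(colnames(Y), sheet$sample_id), , drop = FALSE]
  habitat <- factor(sheet$habitat, levels = c("FW", "SW"))
  n_fw <- sum(habitat == "FW"); n_sw <- sum(habitat == "SW")
  assert_that(n_fw >= 1L && n_sw >= 1L,
              "both habitats must be present (FW: %d, SW: %d)", n_fw, n_sw)

  if (filter) {
    keep <- filter_by_expression(Y, min_cpm = min_cpm, min_samples = min_samples)
    Y <- Y[keep, , drop = FALSE]
  }
  assert_that(nrow(Y) > 0L, "no features retained after filtering")

  norm <- tmm_factors(Y)

  if (min(n_fw, n_sw) < 2L) {
    warning(sprintf(paste(
      "a habitat has a single individual (FW: %d, SW: %d);",
      "dispersion cannot be estimated from replicates -",
      "using fixed dispersion %g"), n_fw, n_sw, fixed_dispersion))
    disp <- structure(list(common = fixed_dispersion,
                           tagwise = stats::setNames(rep(fixed_dispersion, nrow(Y)),
                                                     rownames(Y)),
                           prior_df = prior_df, w0 = NA_real_,
                           grid_range = c(NA_real_, NA_real_)),
                      class = "dispersion_estimates")
  } else {
    if (min(n_fw, n_sw) == ncol(Y) - 1L && ncol(Y) <= 3L) {
      warning("very few replicates per habitat; dispersion estimates are weakly informed")
    }
    disp <- estimate_dispersion(Y, habitat, norm = norm, prior_df = prior_df)
  }

  eff <- effective_lib_sizes(Y, norm)
  fit <- nb_group_fit(Y, habitat, eff, disp$tagwise)
  logFC <- (fit$B[, "SW"] - fit$B[, "FW"]) / log(2)
  logCPM <- rowMeans(cpm(Y, norm = norm, log = TRUE))

  lrt <- nb_lrt(Y, habitat, rep("all", ncol(Y)), norm = norm,
                dispersions = disp)
  q <- bh_adjust(lrt$PValue)
  direction <- ifelse(q < alpha, ifelse(logFC > 0, "up", "down"), "ns")

  out <- data.frame(feature_id = rownames(Y), logFC = unname(logFC),
                    logCPM = unname(logCPM), LR = lrt$LR,
                    PValue = lrt$PValue, FDR = q, direction = direction,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$FDR, out$PValue, out$feature_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  attr(out, "dispersion") <- disp
  class(out) <- c("de_result", "data.frame")
  out
}

#' Summarize a differential expression table
#' @param object a `de_result`.
#' @param ... unused.
#' @return invisible named vector with retained/up/down counts.
#' @export
summary.de_result <- function(object, ...) {
  n_up <- sum(object$direction == "up")
  n_down <- sum(object$direction == "down")
  cat(sprintf("%d features tested: %d significant (%d up, %d down) at alpha = %g\n",
              nrow(object), n_up + n_down, n_up, n_down,
              attr(object, "alpha")))
  invisible(c(tested = nrow(object), up = n_up, down = n_down))
}
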