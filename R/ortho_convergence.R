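# Cross-lineage comparative stage: orthogroup count aggregation, the
# universal-expression retention filter, per-lineage DE, and directional
# intersection analysis of convergent expression.

#' Aggregate gene counts to orthogroup counts
#'
#' For every species, sums the counts of all member genes of each orthogroup
#' into an orthogroup-by-sample matrix, so expression becomes comparable
#' across species with different gene complements. Genes mapped in an
#' orthogroup but absent from the species' count matrix contribute zero;
#' genes not assigned to any orthogroup are dropped. Both events are counted
#' in the returned provenance.
#'
#' @param count_matrices named list of [count_matrix()] objects, one per
#'   species; names must cover every species in `map`.
#' @param map an `orthogroup_map` from [read_orthogroup_map()].
#' @return object of class `ortho_counts`: list with `orthogroup_ids`
#'   (shared ordering), `counts` (named list of orthogroup x sample
#'   matrices), `map`, and `provenance` (per species: genes summed, mapped
#'   genes missing from the matrix, matrix genes not in any orthogroup).
#' @export
aggregate_to_orthogroups <- function(count_matrices, map) {
  stopifnot(inherits(map, "orthogroup_map"))
  species <- attr(map, "species")
  missing_sp <- setdiff(species, names(count_matrices))
  assert_that(length(missing_sp) == 0L,
              "species in orthogroup map missing from inputs: %s",
              paste(missing_sp, collapse = ", "))
  og_ids <- names(map)
  counts <- list()
  provenance <- list()
  for (s in species) {
    cm <- count_matrices[[s]]
    Y <- counts_of(cm)
    member <- lapply(map, `[[`, s)
    genes <- unlist(member, use.names = FALSE)
    og_of_gene <- rep(og_ids, lengths(member))
    in_matrix <- genes %in% rownames(Y)
    M <- matrix(0, length(og_ids), ncol(Y),
                dimnames = list(og_ids, colnames(Y)))
    if (any(in_matrix)) {
      sub <- Y[genes[in_matrix], , drop = FALSE]
      rs <- rowsum(sub, group = og_of_gene[in_matrix])
      M[rownames(rs), ] <- rs
    }
    counts[[s]] <- M
    provenance[[s]] <- list(
      genes_summed = sum(in_matrix),
      mapped_missing = genes[!in_matrix],
      unmapped = setdiff(rownames(Y), genes)
    )
  }
  structure(list(orthogroup_ids = og_ids, counts = counts, map = map,
                 provenance = provenance),
            class = "ortho_counts")
}

#' @export
print.ortho_counts <- function(x, ...) {
  cat(sprintf("ortho_counts: %d orthogroups x %d species (%s)\n",
              length(x$orthogroup_ids), length(x$counts),
              paste(names(x$counts), collapse = ", ")))
  invisible(x)
}

#' Universal-expression retention filter
#'
#' Keeps an orthogroup iff it has at least one member gene in every species
#' and its summed count is positive in every individual of every species
#' (cpm > 0 per individual is equivalent to raw count > 0 for positive
#' library sizes).
#'
#' @param ortho an `ortho_counts` object.
#' @return character vector of retained orthogroup ids (order preserved).
#' @export
filter_universal_expressed <- function(ortho) {
  stopifnot(inherits(ortho, "ortho_counts"))
  species <- names(ortho$counts)
  present <- Reduce(`&`, lapply(species, function(s) {
    lengths(lapply(ortho$map, `[[`, s)) > 0
  }))
  expressed <- Reduce(`&`, lapply(ortho$counts, function(M) {
    rowSums(M > 0) == ncol(M)
  }))
  ortho$orthogroup_ids[present & expressed]
}

#' Subset an `ortho_counts` object to a set of orthogroups
#' @param ortho an `ortho_counts` object.
#' @param ids orthogroup ids to keep.
#' @return a reduced `ortho_counts` object.
#' @export
subset_orthogroups <- function(ortho, ids) {
  stopifnot(inherits(ortho, "ortho_counts"))
  assert_that(all(ids %in% ortho$orthogroup_ids), "unknown orthogroup id(s)")
  ortho$orthogroup_ids <- ids
  ortho$counts <- lapply(ortho$counts, function(M) M[ids, , drop = FALSE])
  ortho$map <- structure(ortho$map[ids], species = attr(ortho$map, "species"),
                         class = "orthogroup_map")
  ortho
}

#' Per-lineage differential expression on retained orthogroups
#'
#' Runs the saltwater-vs-freshwater NB GLM pipeline of [run_de()]
#' independently for every species on the common retained orthogroup
#' universe (no further expression filter is applied beyond the universal
#' retention filter). Lineages with a single individual per habitat fall
#' back to the configured fixed dispersion, with a warning.
#'
#' @param ortho an `ortho_counts` object, already retention-filtered.
#' @param sheet a `sample_sheet` covering every species' samples.
#' @param alpha q-value significance threshold (default 0.05).
#' @param fixed_dispersion dispersion for lineages without replicates
#'   (default 0.1).
#' @param prior_df prior degrees of freedom for tagwise shrinkage.
#' @return named list of `de_result` tables, one per species, all over the
#'   identical orthogroup universe.
#' @export
per_lineage_de <- function(ortho, sheet, alpha = 0.05, fixed_dispersion = 0.1,
                           prior_df = 10) {
  stopifnot(inherits(ortho, "ortho_counts"))
  sheet <- as.data.frame(sheet)
  out <- lapply(names(ortho$counts), function(s) {
    sub <- sheet[sheet$species == s, , drop = FALSE]
    run_de(count_matrix(ortho$counts[[s]], species = s), sub, alpha = alpha,
           prior_df = prior_df, fixed_dispersion = fixed_dispersion,
           filter = FALSE)
  })
  names(out) <- names(ortho$counts)
  out
}

#' Directional intersections of per-lineage DE results
#'
#' For every subset S of two or more lineages, intersects the significantly
#' upregulated and downregulated feature sets: `shared_up(S)` holds features
#' upregulated (saltwater relative to freshwater) in every lineage of S,
#' `shared_down(S)` the downregulated analogue, and `shared_any(S)` features
#' differentially expressed in every lineage of S regardless of sign
#' agreement. Inclusive counts describe features DE in at least the lineages
#' of S; the exclusive region removes features that also belong to the
#' `shared_any` set of any strict superset, i.e. features DE in exactly the
#' lineages of S (the Venn-diagram regions).
#'
#' @param de_tables named list of `de_result` tables (>= 2 lineages) flagged
#'   at their alpha.
#' @return object of class `convergence_report`: list with `lineages`,
#'   `subsets` (list keyed by subset label `"a+b"`, each holding `lineages`,
#'   `shared_up`, `shared_down`, `shared_any`, `exclusive_up`,
#'   `exclusive_down`, `exclusive_any`), and `summary` (data.frame with
#'   inclusive and exclusive counts per subset).
#' @export
intersect_directional <- function(de_tables) {
  assert_that(length(de_tables) >= 2L, "need at least two lineages")
  lineages <- names(de_tables)
  assert_that(!is.null(lineages) && !anyDuplicated(lineages),
              "lineage labels must be unique and named")
  up <- lapply(de_tables, function(d) d$feature_id[d$direction == "up"])
  down <- lapply(de_tables, function(d) d$feature_id[d$direction == "down"])
  de_any <- Map(union, up, down)

  n <- length(lineages)
  subset_idx <- unlist(lapply(2:n, function(k) {
    asplit(utils::combn(n, k), 2L)
  }), recursive = FALSE)

  inter <- function(sets, idx) Reduce(intersect, sets[idx])
  subsets <- lapply(subset_idx, function(idx) {
    list(lineages = lineages[idx],
         shared_up = sort(inter(up, idx)),
         shared_down = sort(inter(down, idx)),
         shared_any = sort(inter(de_any, idx)))
  })
  names(subsets) <- vapply(subset_idx, function(idx) {
    paste(lineages[idx], collapse = "+")
  }, character(1))

  # exclusive regions: remove membership in any strict superset's shared_any
  sizes <- lengths(subset_idx)
  for (i in seq_along(subsets)) {
    idx <- subset_idx[[i]]
    super_any <- character(0)
    for (j in seq_along(subsets)) {
      if (sizes[j] > sizes[i] && all(idx %in% subset_idx[[j]])) {
        super_any <- union(super_any, subsets[[j]]$shared_any)
      }
    }
    subsets[[i]]$exclusive_up <- setdiff(subsets[[i]]$shared_up, super_any)
    subsets[[i]]$exclusive_down <- setdiff(subsets[[i]]$shared_down, super_any)
    subsets[[i]]$exclusive_any <- setdiff(subsets[[i]]$shared_any, super_any)
  }

  summary <- do.call(rbind, lapply(names(subsets), function(lab) {
    s <- subsets[[lab]]
    data.frame(subset = lab, n_lineages = length(s$lineages),
               n_up = length(s$shared_up), n_down = length(s$shared_down),
               n_any = length(s$shared_any),
               n_up_excl = length(s$exclusive_up),
               n_down_excl = length(s$exclusive_down),
               n_any_excl = length(s$exclusive_any),
               stringsAsFactors = FALSE)
  }))
  structure(list(lineages = lineages, subsets = subsets, summary = summary),
            class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, ...) {
  cat(sprintf("convergence_report over %d lineages (%s)\n",
              length(x$lineages), paste(x$lineages, collapse = ", ")))
  print(x$summary, row.names = FALSE, ...)
  invisible(x)
}

#' Features differentially expressed in at least k lineages
#'
#' Selector over a [intersect_directional()] report: features DE in any
#' direction in `k` or more lineages, the target set for downstream GO
#' over-representation.
#'
#' @param report a `convergence_report`.
#' @param k minimum number of lineages (between 2 and the lineage count).
#' @return sorted character vector of feature ids.
#' @export
shared_in_at_least <- function(report, k) {
  stopifnot(inherits(report, "convergence_report"))
  n <- length(report$lineages)
  assert_that(k >= 2L && k <= n, "k must lie in [2, %d]", n)
  hits <- unique(unlist(lapply(report$subsets, function(s) {
    if (length(s$lineages) >= k) s$shared_any else character(0)
  })))
  sort(hits)
}

#' Flatten a convergence report to a writable table
#'
#' @param report a `convergence_report`.
#' @return data.frame with one row per subset and mode (inclusive /
#'   exclusive), with semicolon-joined feature id lists.
#' @export
convergence_table <- function(report) {
  stopifnot(inherits(report, "convergence_report"))
  rows <- lapply(names(report$subsets), function(lab) {
    s <- report$subsets[[lab]]
    data.frame(
      subset = lab, n_lineages = length(s$lineages),
      mode = c("inclusive", "exclusive"),
      n_any = c(length(s$shared_any), length(s$exclusive_any)),
      n_up = c(length(s$shared_up), length(s$exclusive_up)),
      n_down = c(length(s$shared_down), length(s$exclusive_down)),
      feature_ids = c(paste(s$shared_any, collapse = ";"),
                      paste(s$exclusive_any, collapse = ";")),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
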