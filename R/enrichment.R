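# GO term over-representation by the hypergeometric tail, applied to
# up/down-regulated gene sets and to orthogroups shared across lineages.

#' Hypergeometric GO over-representation
#'
#' Tests each GO term for over-representation in a target gene set against a
#' background universe. By default the universe is restricted to annotated
#' genes (those carrying at least one term); set `universe = "all"` to use
#' every background gene as the denominator. For a term carried by `B` of
#' `N` universe genes and `b` of the `n` target genes, the p-value is the
#' upper hypergeometric tail `P(X >= b)`, fold enrichment is
#' `(b/n) / (B/N)`, and q-values are Benjamini-Hochberg across all tested
#' terms. Terms observed in fewer than `min_b` target genes are skipped.
#'
#' @param target character vector of target gene ids (subset of
#'   `background`).
#' @param background character vector of universe gene ids.
#' @param annotation a [go_annotation()] keyed by background gene ids.
#' @param min_b minimum target count for a term to be tested (default 2).
#' @param universe `"annotated"` (default) or `"all"`.
#' @return data.frame of class `enrichment_result` with columns `term`,
#'   `name`, `b`, `n`, `B`, `N`, `fold`, `p`, `q`, sorted by p then term.
#' @export
hypergeom_enrichment <- function(target, background, annotation, min_b = 2,
                                 universe = c("annotated", "all")) {
  universe <- match.arg(universe)
  stopifnot(inherits(annotation, "go_annotation"))
  assert_that(all(target %in% background), "target must be a subset of background")
  g2t <- annotation$gene2terms
  annotated <- names(g2t)[lengths(g2t) > 0]
  bg <- if (universe == "annotated") intersect(background, annotated) else background
  tg <- intersect(target, bg)
  empty <- data.frame(term = character(0), name = character(0),
                      b = integer(0), n = integer(0), B = integer(0),
                      N = integer(0), fold = numeric(0), p = numeric(0),
                      q = numeric(0), stringsAsFactors = FALSE)
  if (length(tg) == 0L) {
    warning("no annotated target genes; empty enrichment table")
    class(empty) <- c("enrichment_result", "data.frame")
    return(empty)
  }
  N <- length(bg); n <- length(tg)
  term_bg <- table(unlist(g2t[intersect(bg, annotated)], use.names = FALSE))
  term_tg <- table(unlist(g2t[intersect(tg, annotated)], use.names = FALSE))
  terms <- names(term_tg)[term_tg >= min_b]
  if (length(terms) == 0L) {
    class(empty) <- c("enrichment_result", "data.frame")
    return(empty)
  }
  b <- as.integer(term_tg[terms])
  B <- as.integer(term_bg[terms])
  p <- stats::phyper(b - 1, B, N - B, n, lower.tail = FALSE)
  nm <- annotation$term_names[terms]
  nm[is.na(nm)] <- ""
  out <- data.frame(term = terms, name = unname(nm), b = b, n = n, B = B,
                    N = N, fold = (b / n) / (B / N), p = p,
                    q = bh_adjust(p), stringsAsFactors = FALSE)
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' True-path propagation of GO annotations
#'
#' Closes every gene's term set under the ancestor relation given by a flat
#' child-to-parent edge list; idempotent. Cycles in the edge list are an
#' error.
#'
#' @param annotation a [go_annotation()].
#' @param parent_edges optional data.frame with columns `child`, `parent`;
#'   defaults to the edges stored in `annotation`.
#' @return a [go_annotation()] with propagated term sets.
#' @export
propagate_annotations <- function(annotation, parent_edges = NULL) {
  stopifnot(inherits(annotation, "go_annotation"))
  edges <- if (is.null(parent_edges)) annotation$parent_edges else parent_edges
  if (is.null(edges) || nrow(edges) == 0L) return(annotation)
  parents <- split(edges$parent, edges$child)
  anc_cache <- new.env(parent = emptyenv())
  ancestors <- function(term, path = character(0)) {
    if (term %in% path) format_error("cycle in parent edges at term %s", term)
    if (exists(term, envir = anc_cache, inherits = FALSE)) {
      return(get(term, envir = anc_cache))
    }
    ps <- parents[[term]]
    out <- character(0)
    for (p in ps) out <- union(out, c(p, ancestors(p, c(path, term))))
    anc_cache[[term]] <- out
    out
  }
  annotation$gene2terms <- lapply(annotation$gene2terms, function(terms) {
    sort(unique(c(terms, unlist(lapply(terms, ancestors)))))
  })
  annotation
}
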