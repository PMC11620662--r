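# Readers and writers for every external table the pipeline touches.
# All downstream modules operate on the in-memory types constructed here.

#' Construct a validated count matrix
#'
#' The universal input object: an integer gene-by-sample count matrix for one
#' species, with unique ordered feature and sample identifiers.
#'
#' @param counts integer matrix, features in rows, samples in columns, with
#'   rownames (feature ids) and colnames (sample ids).
#' @param species species label attached to the matrix.
#' @return object of class `count_matrix`: a list with elements `counts`,
#'   `feature_ids`, `sample_ids`, `species`.
#' @export
count_matrix <- function(counts, species = "species") {
  assert_that(is.matrix(counts), "counts must be a matrix")
  fid <- rownames(counts)
  sid <- colnames(counts)
  assert_that(!is.null(fid) && !is.null(sid),
              "counts must have feature rownames and sample colnames")
  dup <- fid[duplicated(fid)]
  assert_that(length(dup) == 0L, "duplicate feature id(s): %s",
              paste(unique(dup), collapse = ", "))
  dup <- sid[duplicated(sid)]
  assert_that(length(dup) == 0L, "duplicate sample id(s): %s",
              paste(unique(dup), collapse = ", "))
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    format_error("non-integer or negative count at row '%s', column '%s'",
                 fid[bad[1L, 1L]], sid[bad[1L, 2L]])
  }
  storage.mode(counts) <- "double"  # exact for counts < 2^53
  structure(
    list(counts = counts, feature_ids = fid, sample_ids = sid,
         species = as.character(species)),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d features x %d samples (species: %s)\n",
              length(x$feature_ids), length(x$sample_ids), x$species))
  invisible(x)
}

#' Read a gene count matrix from CSV
#'
#' Expects a comma-separated file whose first column holds gene ids and whose
#' remaining columns hold non-negative integer counts, one column per sample,
#' with sample ids in the header (the dialect emitted by transcript
#' quantification pipelines). Fractional values are rejected, not rounded: the
#' downstream negative binomial model assumes true read counts.
#'
#' @param path path to the CSV file.
#' @param species_label species name to attach.
#' @return a [count_matrix()].
#' @export
read_count_matrix <- function(path, species_label = "species") {
  assert_that(file.exists(path), "file not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character")
  assert_that(ncol(df) >= 2L, "count CSV needs a gene id column plus >=1 sample")
  fid <- df[[1L]]
  mat <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(mat), nrow = nrow(mat),
                                 dimnames = list(fid, colnames(mat))))
  bad <- which(is.na(num) & !is.na(mat), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    format_error("non-numeric count at row '%s', column '%s' in %s",
                 fid[bad[1L, 1L]], colnames(num)[bad[1L, 2L]], path)
  }
  count_matrix(num, species = species_label)
}

#' Write a count matrix to CSV
#'
#' Inverse of [read_count_matrix()]; emits `gene_id` as the first column.
#'
#' @param cm a [count_matrix()].
#' @param path output path.
#' @export
write_count_matrix <- function(cm, path) {
  stopifnot(inherits(cm, "count_matrix"))
  df <- data.frame(gene_id = cm$feature_ids,
                   as.data.frame(cm$counts, check.names = FALSE),
                   check.names = FALSE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  lines <- c(paste(colnames(df), collapse = ","),
             do.call(paste, c(lapply(df, function(col) {
               if (is.numeric(col)) format(col, trim = TRUE, scientific = FALSE) else as.character(col)
             }), sep = ",")))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a sample sheet
#'
#' Tab-separated with header `sample_id`, `species`, `habitat`; habitat must
#' be `FW` (freshwater) or `SW` (saltwater). Additional columns are kept as
#' covariates.
#'
#' @param path path to the TSV file.
#' @return data.frame of class `sample_sheet`.
#' @export
read_sample_sheet <- function(path) {
  assert_that(file.exists(path), "file not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  sample_sheet(df)
}

#' Construct a validated sample sheet
#'
#' @param df data.frame with columns `sample_id`, `species`, `habitat`.
#' @return the validated data.frame, classed `sample_sheet`.
#' @export
sample_sheet <- function(df) {
  need <- c("sample_id", "species", "habitat")
  assert_that(all(need %in% colnames(df)),
              "sample sheet requires columns: %s", paste(need, collapse = ", "))
  dup <- df$sample_id[duplicated(df$sample_id)]
  assert_that(length(dup) == 0L, "duplicate sample id(s): %s",
              paste(unique(dup), collapse = ", "))
  bad <- setdiff(unique(df$habitat), c("FW", "SW"))
  assert_that(length(bad) == 0L,
              "habitat must be 'FW' or 'SW'; found: %s", paste(bad, collapse = ", "))
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' Write a sample sheet to TSV
#' @param sheet a `sample_sheet` data.frame.
#' @param path output path.
#' @export
write_sample_sheet <- function(sheet, path) {
  write_tsv_file(as.data.frame(sheet), path)
}

#' Read an orthogroup membership table
#'
#' Tab-separated with header `Orthogroup` followed by one column per species;
#' each cell is a comma-separated gene list (with or without a space after the
#' comma) and an empty cell means the orthogroup is absent from that species.
#' This is the dialect produced by standard orthology inference tools.
#'
#' @param path path to the TSV file.
#' @param species_names character vector of expected species; header species
#'   outside this set are an error (a missing species column means that
#'   species is absent from the analysis — fail fast rather than fabricate
#'   empty lists).
#' @return object of class `orthogroup_map`: named list (orthogroup id) of
#'   named lists (species) of character gene id vectors; attribute `species`.
#' @export
read_orthogroup_map <- function(path, species_names) {
  assert_that(file.exists(path), "file not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  assert_that(colnames(df)[1L] == "Orthogroup",
              "first column of orthogroup table must be 'Orthogroup'")
  sp <- colnames(df)[-1L]
  extra <- setdiff(sp, species_names)
  assert_that(length(extra) == 0L,
              "species in header not in species_names: %s",
              paste(extra, collapse = ", "))
  orthogroup_map_from_lists(df$Orthogroup, df[, sp, drop = FALSE])
}

orthogroup_map_from_lists <- function(og_ids, cells) {
  sp <- colnames(cells)
  dup <- og_ids[duplicated(og_ids)]
  assert_that(length(dup) == 0L, "duplicate orthogroup id(s): %s",
              paste(unique(dup), collapse = ", "))
  per_sp <- lapply(cells, function(col) {
    lapply(col, function(cell) {
      if (is.na(cell) || !nzchar(cell)) character(0)
      else trimws(strsplit(cell, ",", fixed = TRUE)[[1L]])
    })
  })
  # a gene may belong to at most one orthogroup within a species
  for (s in sp) {
    genes <- unlist(per_sp[[s]], use.names = FALSE)
    dup <- genes[duplicated(genes)]
    assert_that(length(dup) == 0L,
                "gene(s) listed under multiple orthogroups for species %s: %s",
                s, paste(unique(dup), collapse = ", "))
  }
  m <- lapply(seq_along(og_ids), function(i) {
    stats::setNames(lapply(per_sp, `[[`, i), sp)
  })
  names(m) <- og_ids
  structure(m, species = sp, class = "orthogroup_map")
}

#' Write an orthogroup map to TSV
#' @param map an `orthogroup_map`.
#' @param path output path.
#' @export
write_orthogroup_map <- function(map, path) {
  sp <- attr(map, "species")
  cells <- vapply(map, function(row) {
    vapply(sp, function(s) paste(row[[s]], collapse = ", "), character(1))
  }, character(length(sp)))
  cells <- if (length(sp) == 1L) matrix(cells, nrow = 1L) else cells
  df <- data.frame(Orthogroup = names(map),
                   t(cells), check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("Orthogroup", sp)
  write_tsv_file(df, path)
}

#' Read a gene-to-GO-term annotation map
#'
#' Tab-separated with header `gene_id` and a second column of comma-separated
#' GO identifiers; genes are keyed strictly by the count-matrix feature id.
#' An optional flat child-parent edge table supports true-path propagation.
#'
#' @param path path to the gene-to-term TSV.
#' @param parents_path optional path to a two-column `child`/`parent` TSV.
#' @return object of class `go_annotation`: list with `gene2terms` (named
#'   list of character term sets), `term_names` (named character, possibly
#'   empty), `parent_edges` (two-column data.frame or NULL).
#' @export
read_go_map <- function(path, parents_path = NULL) {
  assert_that(file.exists(path), "file not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  assert_that(ncol(df) >= 2L, "GO map needs gene_id and term columns")
  terms <- lapply(df[[2L]], function(cell) {
    if (is.na(cell) || !nzchar(cell)) character(0)
    else unique(trimws(strsplit(cell, ",", fixed = TRUE)[[1L]]))
  })
  names(terms) <- df[[1L]]
  edges <- NULL
  if (!is.null(parents_path)) {
    edges <- utils::read.delim(parents_path, stringsAsFactors = FALSE,
                               colClasses = "character")
    assert_that(ncol(edges) >= 2L, "parent edge table needs child and parent columns")
    colnames(edges)[1:2] <- c("child", "parent")
    assert_that(!any(edges$child == edges$parent), "self-parent edge detected")
  }
  go_annotation(terms, parent_edges = edges)
}

#' Construct a GO annotation object
#' @param gene2terms named list mapping gene id to a character vector of terms.
#' @param term_names optional named character vector of term descriptions.
#' @param parent_edges optional data.frame with columns `child`, `parent`.
#' @return a `go_annotation` object.
#' @export
go_annotation <- function(gene2terms, term_names = character(0),
                          parent_edges = NULL) {
  assert_that(is.list(gene2terms), "gene2terms must be a named list")
  if (!is.null(parent_edges)) {
    assert_that(!any(parent_edges$child == parent_edges$parent),
                "self-parent edge detected")
  }
  structure(list(gene2terms = gene2terms,
                 term_names = term_names,
                 parent_edges = parent_edges),
            class = "go_annotation")
}

#' Write a gene-to-GO map to TSV
#' @param annotation a `go_annotation`.
#' @param path output path.
#' @export
write_go_map <- function(annotation, path) {
  g2t <- annotation$gene2terms
  df <- data.frame(gene_id = names(g2t),
                   go_ids = vapply(g2t, paste, character(1), collapse = ","),
                   stringsAsFactors = FALSE)
  write_tsv_file(df, path)
}

#' Write any result data.frame to TSV
#'
#' Deterministic column order (as given) and stable row order; UTF-8, LF.
#'
#' @param result a data.frame.
#' @param path output path.
#' @export
write_table <- function(result, path) {
  write_tsv_file(as.data.frame(result), path)
}
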