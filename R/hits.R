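#' Hit tables of pairwise local alignments
#'
#' A hit table holds the pairwise local alignments of one query search as a
#' `data.frame` with columns `query_id`, `subject_id`, `subject_species`,
#' `e_value`, `percent_identity`, `query_start`, `query_end`,
#' `aligned_query`, `aligned_subject`.  Rows are kept sorted by ascending
#' E-value, ties broken by descending percent identity then subject id.
#' Coordinates are 1-based inclusive on the unaligned query, the BLAST
#' tabular convention; the ungapped `aligned_query` of every row must equal
#' the corresponding query substring.
#'
#' @param df Data frame with the columns above.
#' @param query Query sequence record (one-row sequence `data.frame` or a
#'   list with `id` and `residues`).
#' @param oversized Logical flag: the producing search would have exceeded
#'   its `max_hits` budget before truncation.
#' @return The sorted, validated hit table with attributes `query_id`,
#'   `query_len` and `oversized`.
#' @export
hit_table <- function(df, query, oversized = FALSE) {
  cols <- c("query_id", "subject_id", "subject_species", "e_value",
            "percent_identity", "query_start", "query_end",
            "aligned_query", "aligned_subject")
  if (is.null(df) || nrow(df) == 0L) {
    df <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
    df$e_value <- numeric(0); df$percent_identity <- numeric(0)
    df$query_start <- integer(0); df$query_end <- integer(0)
  }
  stopifnot(all(cols %in% names(df)))
  df <- df[, cols]
  query_len <- nchar(query$residues)
  if (nrow(df)) {
    if (any(df$e_value < 0)) stop("negative E-value in hit table")
    if (any(df$percent_identity < 0 | df$percent_identity > 100)) {
      stop("percent_identity outside [0, 100]")
    }
    if (any(nchar(df$aligned_query) != nchar(df$aligned_subject))) {
      stop("aligned_query and aligned_subject differ in length")
    }
    if (any(df$query_end > query_len)) {
      stop("query_end exceeds query length ", query_len)
    }
    ungapped <- gsub("-", "", df$aligned_query, fixed = TRUE)
    expect <- substr(rep(query$residues, nrow(df)), df$query_start, df$query_end)
    bad <- ungapped != expect
    if (any(bad)) {
      stop("aligned query string of subject ", df$subject_id[bad][[1L]],
           " is inconsistent with the query sequence")
    }
    df <- df[order(df$e_value, -df$percent_identity, df$subject_id), ]
  }
  rownames(df) <- NULL
  structure(df, query_id = query$id, query_len = query_len,
            oversized = isTRUE(oversized),
            class = c("remort_hits", "data.frame"))
}

#' @export
print.remort_hits <- function(x, ...) {
  cat("Hit table for query '", attr(x, "query_id"), "' (length ",
      attr(x, "query_len"), "): ", nrow(x), " alignments",
      if (attr(x, "oversized")) " [oversized]", "\n", sep = "")
  NextMethod()
}

#' Keep the best HSP per subject
#'
#' Collapses a hit table to one row per subject, keeping the first row in
#' table order (i.e. the lowest-E-value local alignment).
#'
#' @param hits A hit table.
#' @return The deduplicated hit table.
#' @export
best_hsp_per_subject <- function(hits) {
  keep <- !duplicated(hits$subject_id)
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  attributes(out)[c("query_id", "query_len", "oversized", "class")] <-
    attributes(hits)[c("query_id", "query_len", "oversized", "class")]
  out
}

## Default column order of the canonical BLAST+ tabular dialect:
## -outfmt "6 qseqid sseqid pident evalue qstart qend qseq sseq staxids"
BLAST_COLUMNS <- c("qseqid", "sseqid", "pident", "evalue",
                   "qstart", "qend", "qseq", "sseq", "staxids")

#' Read BLAST+ tabular search results
#'
#' Ingests the output of an external relaxed BLAST search.  The file must
#' carry the aligned sequence strings (`qseq`, `sseq`) -- without them the
#' conservation profiles cannot be built -- and is validated against the
#' query sequence.
#'
#' @param path Path to a BLAST+ tabular (`-outfmt 6`) file.
#' @param query Query sequence record (`id`, `species`, `residues`).
#' @param species_map Optional data frame from [read_species_map()] mapping
#'   subject accessions to species; when absent, the `staxids` column is
#'   used verbatim as the species label.
#' @param columns Character vector naming the file's columns, in order.
#' @return A hit table (see [hit_table()]).
#' @export
read_blast_tabular <- function(path, query, species_map = NULL,
                               columns = BLAST_COLUMNS) {
  need <- c("qseqid", "sseqid", "pident", "evalue", "qstart", "qend",
            "qseq", "sseq")
  missing_cols <- setdiff(need, columns)
  if (length(missing_cols)) {
    stop("BLAST tabular input lacks column(s) ",
         paste(missing_cols, collapse = ", "),
         "; rerun blastp with -outfmt \"6 ",
         paste(BLAST_COLUMNS, collapse = " "), "\"")
  }
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "#")
  if (ncol(tab) != length(columns)) {
    stop("expected ", length(columns), " columns (",
         paste(columns, collapse = " "), "), found ", ncol(tab))
  }
  names(tab) <- columns
  if (!all(tab$qseqid == query$id)) {
    stop("file contains hits for query '", setdiff(tab$qseqid, query$id)[[1L]],
         "', not '", query$id, "' (single-query files only)")
  }
  if (!is.null(species_map)) {
    idx <- match(tab$sseqid, species_map$accession)
    if (anyNA(idx)) {
      stop("species unresolved for subject ", tab$sseqid[is.na(idx)][[1L]])
    }
    species <- species_map$species[idx]
  } else if ("staxids" %in% columns) {
    species <- as.character(tab$staxids)
  } else {
    stop("no species map given and no staxids column present")
  }
  df <- data.frame(query_id = tab$qseqid, subject_id = tab$sseqid,
                   subject_species = species, e_value = as.numeric(tab$evalue),
                   percent_identity = as.numeric(tab$pident),
                   query_start = as.integer(tab$qstart),
                   query_end = as.integer(tab$qend),
                   aligned_query = toupper(tab$qseq),
                   aligned_subject = toupper(tab$sseq),
                   stringsAsFactors = FALSE)
  hit_table(df, query)
}
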