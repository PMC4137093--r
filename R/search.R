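#' Search configuration
#'
#' Parameters of the relaxed similarity search.  The defaults are the
#' pipeline's operating point: an E-value threshold of 100 (relaxed enough
#' to admit remote family members that score far below significance) and a
#' 1500-hit budget -- a search that would exceed it indicates a large
#' multi-branching family for which phylogenetic methods are the better
#' tool, and the pipeline stops.
#'
#' @param e_threshold Positive E-value cutoff (default 100).
#' @param max_hits Positive integer hit budget (default 1500).
#' @param matrix Substitution matrix name (currently `"BLOSUM62"`).
#' @param gap_open,gap_extend Affine gap penalties (default 11 / 1).
#' @param lambda Bits-per-score-unit scaling of the internal backend's
#'   E-value proxy (default 0.267).
#' @return A `search_config` list.
#' @export
search_config <- function(e_threshold = 100, max_hits = 1500,
                          matrix = "BLOSUM62", gap_open = 11, gap_extend = 1,
                          lambda = 0.267) {
  stopifnot(e_threshold > 0, max_hits >= 1)
  structure(list(e_threshold = e_threshold, max_hits = as.integer(max_hits),
                 matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend, lambda = lambda),
            class = "search_config")
}

resolve_matrix <- function(config) {
  if (!identical(config$matrix, "BLOSUM62")) {
    stop("unsupported substitution matrix: ", config$matrix)
  }
  blosum62()
}

#' Smith-Waterman local alignment of two protein sequences
#'
#' Affine-gap Smith-Waterman (via Biostrings) with a Karlin-Altschul-shaped
#' E-value proxy `E = m * n * 2^(-lambda * s)` for raw score `s` and
#' sequence lengths `m`, `n`.  The proxy is a strictly monotone transform of
#' the score, sufficient for the pipeline, whose rules depend only on
#' E-value order plus two absolute cutoffs (both configurable).
#'
#' @param a Query sequence record (`id`, `species`, `residues`).
#' @param b Subject sequence record.
#' @param config A [search_config()].
#' @return A one-row hit-table `data.frame`, or `NULL` when the best local
#'   score is not positive.
#' @export
sw_align <- function(a, b, config = search_config()) {
  out <- sw_align_many(a, list(b), config)
  if (nrow(out) == 0L) NULL else out
}

## Vectorized core: one query against a list/data.frame of subjects.
sw_align_many <- function(query, subjects, config = search_config()) {
  if (is.data.frame(subjects)) {
    subj_ids <- subjects$id; subj_species <- subjects$species
    subj_res <- subjects$residues
  } else {
    subj_ids <- vapply(subjects, `[[`, character(1), "id")
    subj_species <- vapply(subjects, `[[`, character(1), "species")
    subj_res <- vapply(subjects, `[[`, character(1), "residues")
  }
  if (!nzchar(query$residues) || any(!nzchar(subj_res))) {
    stop("empty sequence passed to the aligner")
  }
  mat <- resolve_matrix(config)
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAStringSet(subj_res),
    subject = Biostrings::AAString(query$residues),
    type = "local", substitutionMatrix = mat,
    gapOpening = config$gap_open, gapExtension = config$gap_extend)
  s <- Biostrings::score(pa)
  m <- nchar(query$residues)
  n <- nchar(subj_res)
  e <- m * n * 2^(-config$lambda * s)
  keep <- s > 0
  df <- data.frame(
    query_id = query$id,
    subject_id = subj_ids,
    subject_species = subj_species,
    e_value = e,
    percent_identity = Biostrings::pid(pa),
    query_start = BiocGenerics::start(Biostrings::subject(pa)),
    query_end = BiocGenerics::end(Biostrings::subject(pa)),
    aligned_query = as.character(Biostrings::subject(pa)),
    aligned_subject = as.character(Biostrings::pattern(pa)),
    score = s,
    stringsAsFactors = FALSE)
  df[keep, , drop = FALSE]
}

#' Search backends
#'
#' A backend holds named sequence databases and answers
#' [backend_search()] queries with deterministic, sorted hit tables.  Three
#' implementations: `internal_backend()` (the bundled Smith-Waterman
#' aligner, no external dependency), `blast_backend()` (wraps the `blastp`
#' executable), and `fixture_backend()` (canned results for tests).
#'
#' @param databases Named list of sequence `data.frame`s (see [seq_db()]).
#' @return A backend object.
#' @rdname search_backend
#' @export
internal_backend <- function(databases) {
  stopifnot(is.list(databases), !is.null(names(databases)))
  databases <- lapply(databases, validate_seq_db)
  structure(list(databases = databases),
            class = c("internal_backend", "search_backend"))
}

#' @param tables For `fixture_backend()`: either a named list of hit-table
#'   `data.frame`s keyed `"<query_id>::<db_id>"`, or the path of a JSON file
#'   holding the same mapping (an object of row-lists).
#' @param databases Named list of sequence databases (fixture backends need
#'   them to look up candidate sequences and species).
#' @rdname search_backend
#' @export
fixture_backend <- function(tables, databases = list()) {
  if (is.character(tables) && length(tables) == 1L) {
    raw <- jsonlite::read_json(tables, simplifyVector = TRUE)
    tables <- lapply(raw, as.data.frame, stringsAsFactors = FALSE)
  }
  stopifnot(is.list(tables))
  databases <- lapply(databases, validate_seq_db)
  structure(list(tables = tables, databases = databases),
            class = c("fixture_backend", "search_backend"))
}

#' @param db_paths For `blast_backend()`: named character vector of FASTA
#'   paths, one per database id.
#' @param species_maps Named list of species maps ([read_species_map()]),
#'   parallel to `db_paths`.
#' @rdname search_backend
#' @export
blast_backend <- function(db_paths, species_maps = list()) {
  stopifnot(is.character(db_paths), !is.null(names(db_paths)))
  databases <- lapply(names(db_paths), function(db_id) {
    read_fasta(db_paths[[db_id]], species_from = if (db_id %in% names(species_maps))
      "sidecar" else "header",
      species_map = species_maps[[db_id]])
  })
  names(databases) <- names(db_paths)
  structure(list(db_paths = db_paths, databases = databases,
                 species_maps = species_maps),
            class = c("blast_backend", "search_backend"))
}

#' Run a search against a registered database
#'
#' All subjects with `E <= e_threshold`, sorted by ascending E-value (ties:
#' descending percent identity, then subject id), truncated to
#' `config$max_hits`.  A search that would exceed the budget before
#' truncation is flagged `oversized` so the pipeline can stop.
#'
#' @param backend A backend object.
#' @param query Query sequence record.
#' @param db_id Registered database id.
#' @param config A [search_config()].
#' @return A hit table.
#' @export
backend_search <- function(backend, query, db_id, config = search_config()) {
  UseMethod("backend_search")
}

get_database <- function(backend, db_id) {
  if (!db_id %in% names(backend$databases)) {
    stop("unknown database id '", db_id, "'; registered: ",
         paste(names(backend$databases), collapse = ", "))
  }
  backend$databases[[db_id]]
}

#' @export
backend_search.internal_backend <- function(backend, query, db_id,
                                            config = search_config()) {
  db <- get_database(backend, db_id)
  db <- db[order(db$id), , drop = FALSE]  # invariance to record order
  df <- sw_align_many(query, db, config)
  df <- df[df$e_value <= config$e_threshold, , drop = FALSE]
  oversized <- nrow(df) > config$max_hits
  if (oversized) {
    df <- df[order(df$e_value, -df$percent_identity, df$subject_id), ]
    df <- df[seq_len(config$max_hits), , drop = FALSE]
  }
  hit_table(df, query, oversized = oversized)
}

#' @export
backend_search.fixture_backend <- function(backend, query, db_id,
                                           config = search_config()) {
  key <- paste0(query$id, "::", db_id)
  tab <- backend$tables[[key]]
  if (is.null(tab)) {
    stop("fixture backend has no canned results for ", key)
  }
  tab <- tab[tab$e_value <= config$e_threshold, , drop = FALSE]
  oversized <- nrow(tab) > config$max_hits
  if (oversized) tab <- tab[seq_len(config$max_hits), , drop = FALSE]
  hit_table(tab, query, oversized = oversized)
}

#' @export
backend_search.blast_backend <- function(backend, query, db_id,
                                         config = search_config()) {
  if (!nzchar(Sys.which("blastp"))) {
    stop("blastp not found; use backend=internal")
  }
  db_path <- backend$db_paths[[db_id]]
  if (is.null(db_path)) stop("unknown database id '", db_id, "'")
  qfile <- tempfile(fileext = ".fa")
  on.exit(unlink(qfile), add = TRUE)
  writeLines(c(paste0(">", query$id, " ", query$species), query$residues), qfile)
  outfile <- tempfile(fileext = ".tsv")
  on.exit(unlink(outfile), add = TRUE)
  args <- blastp_args(qfile, db_path, outfile, config)
  status <- system2("blastp", shQuote(args))
  if (status != 0L) stop("blastp exited with status ", status)
  sm <- backend$species_maps[[db_id]]
  if (is.null(sm)) {
    db <- backend$databases[[db_id]]
    sm <- data.frame(accession = db$id, species = db$species)
  }
  cols <- setdiff(BLAST_COLUMNS, "staxids")
  hits <- read_blast_tabular(outfile, query, species_map = sm, columns = cols)
  oversized <- nrow(hits) > config$max_hits
  if (oversized) {
    hits <- hit_table(hits[seq_len(config$max_hits), ], query, oversized = TRUE)
  }
  hits
}

## blastp argument vector; split out so tests can inspect the command.
blastp_args <- function(query_path, db_path, out_path, config) {
  c("-query", query_path, "-subject", db_path,
    "-evalue", format(config$e_threshold, scientific = FALSE),
    "-outfmt", paste0("6 ", paste(setdiff(BLAST_COLUMNS, "staxids"),
                                  collapse = " ")),
    "-out", out_path)
}
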