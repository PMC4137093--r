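#' Sequence records and FASTA input
#'
#' A sequence database in remort is a plain `data.frame` with one row per
#' protein and columns `id` (accession, unique), `species` (species name)
#' and `residues` (upper-case amino acids, 20 standard letters plus `X`).
#'
#' @param id,species,residues Character vectors of equal length.
#' @return A validated sequence `data.frame`.
#' @export
seq_db <- function(id, species, residues) {
  db <- data.frame(id = as.character(id), species = as.character(species),
                   residues = toupper(as.character(residues)),
                   stringsAsFactors = FALSE)
  validate_seq_db(db)
}

validate_seq_db <- function(db) {
  stopifnot(is.data.frame(db), all(c("id", "species", "residues") %in% names(db)))
  if (nrow(db) == 0L) stop("sequence database is empty")
  dup <- db$id[duplicated(db$id)]
  if (length(dup)) stop("duplicate id ", dup[[1L]])
  if (any(!nzchar(db$residues))) {
    stop("empty residues for id ", db$id[!nzchar(db$residues)][[1L]])
  }
  bad <- grepl(paste0("[^", paste(AA20, collapse = ""), "X]"), db$residues)
  if (any(bad)) {
    stop("non-amino-acid characters in sequence ", db$id[bad][[1L]])
  }
  rownames(db) <- NULL
  db
}

#' Read a protein FASTA file into a sequence database
#'
#' Species are resolved either from a header token (the second
#' whitespace-separated word of the description line, the convention used by
#' the bundled generator) or from a sidecar species map
#' (see [read_species_map()]).  `*` stop characters are stripped and
#' residues upper-cased.
#'
#' @param path Path to a FASTA file of protein sequences.
#' @param species_from `"header"` or `"sidecar"`.
#' @param species_map Data frame from [read_species_map()]; required when
#'   `species_from = "sidecar"`.
#' @return A sequence `data.frame` (see [seq_db()]), in file order.
#' @export
read_fasta <- function(path, species_from = c("header", "sidecar"),
                       species_map = NULL) {
  species_from <- match.arg(species_from)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  headers <- names(set)
  tokens <- strsplit(headers, "[ \t]+")
  ids <- vapply(tokens, `[[`, character(1), 1L)
  if (species_from == "header") {
    species <- vapply(tokens, function(tk) {
      if (length(tk) < 2L) NA_character_ else tk[[2L]]
    }, character(1))
    if (anyNA(species)) {
      stop("species unresolved for ", ids[is.na(species)][[1L]],
           ": no species token in header and no sidecar map given")
    }
  } else {
    if (is.null(species_map)) stop("species_from = 'sidecar' requires species_map")
    idx <- match(ids, species_map$accession)
    if (anyNA(idx)) {
      stop("species unresolved for ", ids[is.na(idx)][[1L]],
           ": accession missing from the species map")
    }
    species <- species_map$species[idx]
  }
  residues <- gsub("\\*", "", toupper(as.character(set)))
  seq_db(ids, species, residues)
}

#' Read a species sidecar map
#'
#' Tab-separated file with columns `accession`, `species` and optionally
#' `phylum` (no header line).
#'
#' @param path Path to the TSV file.
#' @return A data frame with columns `accession`, `species`, `phylum`.
#' @export
read_species_map <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "")
  if (ncol(tab) < 2L) stop("species map needs at least accession<TAB>species")
  names(tab)[1:2] <- c("accession", "species")
  if (ncol(tab) >= 3L) names(tab)[3L] <- "phylum" else tab$phylum <- NA_character_
  tab[, c("accession", "species", "phylum")]
}

#' Write a sequence database as FASTA
#'
#' Headers are `>id species`, the dialect [read_fasta()] parses by default.
#'
#' @param db A sequence `data.frame`.
#' @param path Output path.
#' @export
write_fasta <- function(db, path) {
  db <- validate_seq_db(db)
  lines <- as.vector(rbind(paste0(">", db$id, " ", db$species), db$residues))
  writeLines(lines, path)
  invisible(path)
}
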