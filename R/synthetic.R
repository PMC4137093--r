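#' Specification of a synthetic protein family
#'
#' Describes a ground-truth test world for the pipeline: an orthologous
#' family sharing a short conserved motif embedded at variable positions in
#' otherwise random sequence, per-species paralogs whose copy of the motif
#' is scrambled (so they still attain alignments and exercise the rejection
#' path), and unrelated decoys that reach only weak, high-E-value
#' alignments to the query.  Defaults model the regime the pipeline is
#' built for: a short (150-residue) protein with one remotely conserved
#' 20-residue pattern, one ortholog per species across 20 species, three
#' paralogs per species and 50 decoys.
#'
#' @param n_species Number of species, each contributing one true ortholog
#'   (the first species' ortholog is the query).
#' @param motif Conserved residue pattern (default a fixed 20-mer rich in
#'   rare residues, where conservation is most informative).
#' @param motif_identity Per-position probability that a motif position is
#'   left intact in an ortholog (mutated positions are redrawn from the
#'   background).
#' @param background_len Total sequence length (motif embedded within).
#' @param n_paralogs_per_species Paralogs per species (scrambled motif).
#' @param n_decoys Unrelated random sequences.
#' @param seed Integer seed; the world is a pure function of the spec.
#' @return A `family_spec` list.
#' @export
family_spec <- function(n_species = 20, motif = "WCHKRFDPEQYMGNWLSTCV",
                        motif_identity = 0.8, background_len = 150,
                        n_paralogs_per_species = 3, n_decoys = 50,
                        seed = 1) {
  stopifnot(n_species >= 1, nzchar(motif), motif_identity >= 0,
            motif_identity <= 1, n_paralogs_per_species >= 0, n_decoys >= 0)
  if (nchar(motif) > background_len) {
    stop("motif (", nchar(motif), " aa) longer than background_len (",
         background_len, ")")
  }
  if (grepl(paste0("[^", paste(AA20, collapse = ""), "]"), motif)) {
    stop("motif must use the 20 standard residues")
  }
  structure(list(n_species = as.integer(n_species), motif = motif,
                 motif_identity = motif_identity,
                 background_len = as.integer(background_len),
                 n_paralogs_per_species = as.integer(n_paralogs_per_species),
                 n_decoys = as.integer(n_decoys), seed = as.integer(seed)),
            class = "family_spec")
}

#' Generate a synthetic family world
#'
#' Deterministic under the spec's seed.  Background residues are drawn from
#' Robinson-Robinson frequencies (so log-rarity position weights are
#' meaningful); each ortholog embeds the motif at a random position with
#' per-position mutation probability `1 - motif_identity`; paralogs embed a
#' scrambled permutation of the motif; decoys are pure background.
#'
#' @param spec A [family_spec()].
#' @return A list with `db` (sequence `data.frame`; the query is the first
#'   row, id `orth_s01`), `query_id`, `truth` (character vector of true
#'   ortholog ids, query included), `species_map`, and `motif_positions`
#'   (named list of `c(start, end)` per ortholog).
#' @export
generate_family <- function(spec) {
  stopifnot(inherits(spec, "family_spec"))
  with_private_seed(spec$seed, {
    draw_bg <- function(len) {
      paste(sample(AA20, len, replace = TRUE, prob = ROBINSON_FREQS),
            collapse = "")
    }
    motif_chars <- strsplit(spec$motif, "")[[1L]]
    mlen <- length(motif_chars)
    embed <- function(motif_vec) {
      start <- sample.int(spec$background_len - mlen + 1L, 1L)
      bg <- strsplit(draw_bg(spec$background_len), "")[[1L]]
      bg[start:(start + mlen - 1L)] <- motif_vec
      list(seq = paste(bg, collapse = ""), start = start, end = start + mlen - 1L)
    }
    mutate_motif <- function() {
      keep <- stats::runif(mlen) < spec$motif_identity
      out <- motif_chars
      n_mut <- sum(!keep)
      if (n_mut) {
        out[!keep] <- sample(AA20, n_mut, replace = TRUE, prob = ROBINSON_FREQS)
      }
      out
    }
    species <- sprintf("species_%02d", seq_len(spec$n_species))
    ids <- character(0); specs <- character(0); seqs <- character(0)
    motif_positions <- list()
    for (si in seq_len(spec$n_species)) {
      oid <- sprintf("orth_s%02d", si)
      emb <- embed(if (si == 1L) motif_chars else mutate_motif())
      ids <- c(ids, oid); specs <- c(specs, species[[si]])
      seqs <- c(seqs, emb$seq)
      motif_positions[[oid]] <- c(start = emb$start, end = emb$end)
      for (pi in seq_len(spec$n_paralogs_per_species)) {
        pid <- sprintf("para_s%02d_%d", si, pi)
        pemb <- embed(sample(motif_chars))
        ids <- c(ids, pid); specs <- c(specs, species[[si]])
        seqs <- c(seqs, pemb$seq)
      }
    }
    if (spec$n_decoys > 0L) {
      for (di in seq_len(spec$n_decoys)) {
        ids <- c(ids, sprintf("decoy_%03d", di))
        specs <- c(specs, sprintf("species_%02d",
                                  ((di - 1L) %% spec$n_species) + 1L))
        seqs <- c(seqs, draw_bg(spec$background_len))
      }
    }
    db <- seq_db(ids, specs, seqs)
    truth <- sprintf("orth_s%02d", seq_len(spec$n_species))
    species_map <- data.frame(accession = ids, species = specs,
                              phylum = "synthetic", stringsAsFactors = FALSE)
    list(db = db, query_id = "orth_s01", truth = truth,
         species_map = species_map, motif_positions = motif_positions,
         spec = spec)
  })
}

#' Planted conservation support of a generated ortholog
#'
#' The query positions occupied by the embedded motif -- the support the
#' clustering stage should recover as the family consensus.
#'
#' @param world Result of [generate_family()].
#' @param id Ortholog id generated by the spec.
#' @return Integer vector of 1-based query positions.
#' @export
expected_profile <- function(world, id) {
  pos <- world$motif_positions[[id]]
  if (is.null(pos)) stop("unknown ortholog id '", id, "'")
  seq.int(pos[["start"]], pos[["end"]])
}

#' Write a synthetic world to disk
#'
#' FASTA database (+ `>id species` headers), species sidecar TSV and a
#' ground-truth JSON, the inputs a pipeline run needs.
#'
#' @param world Result of [generate_family()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "database.fa")
  write_fasta(world$db, fasta)
  smap <- file.path(dir, "species.tsv")
  utils::write.table(world$species_map, smap, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  truth <- file.path(dir, "truth.json")
  jsonlite::write_json(list(query_id = world$query_id, truth = world$truth,
                            motif_positions = world$motif_positions),
                       truth, auto_unbox = TRUE, digits = NA)
  invisible(c(fasta = fasta, species = smap, truth = truth))
}
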