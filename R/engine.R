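#' Engine parameters
#'
#' Decision constants of the reciprocal-verification engine:
#'
#' * `identity_select` -- hits with *more than* this percent identity to the
#'   query are initial candidates regardless of their cluster (default 80).
#' * `strict_e` -- below this E-value to the query the strict reciprocal
#'   best-hit rule applies: the candidate's top reciprocal hit in the query
#'   species must be the query itself (default 1e-5).
#' * `reject_fraction` -- a candidate is rejected when *more than* this
#'   fraction of the current verified orthologs reject it as an RBH
#'   (default 1/3).
#' * `acceptable_ranks` -- reciprocal ranks (within the ortholog's species)
#'   counted as "acceptable": for weak-similarity relationships the second
#'   or third hit in a species may well be the true ortholog (default 2:3).
#' * `multi_support_select` -- a subject found as an RBH by *more than* this
#'   many verified orthologs is selected as a candidate (default 2).
#'
#' @param identity_select,strict_e,reject_fraction,acceptable_ranks,multi_support_select
#'   See above.
#' @return An `engine_params` list.
#' @export
engine_params <- function(identity_select = 80, strict_e = 1e-5,
                          reject_fraction = 1 / 3, acceptable_ranks = 2:3,
                          multi_support_select = 2) {
  stopifnot(identity_select > 0, strict_e > 0,
            reject_fraction > 0, reject_fraction < 1,
            all(acceptable_ranks >= 2), multi_support_select >= 1)
  structure(list(identity_select = identity_select, strict_e = strict_e,
                 reject_fraction = reject_fraction,
                 acceptable_ranks = as.integer(acceptable_ranks),
                 multi_support_select = as.integer(multi_support_select)),
            class = "engine_params")
}

#' Initial orthology candidates
#'
#' Union of (a) hits with more than `identity_select` percent identity to
#' the query (strictly greater) and (b) all members of the query's cluster.
#' The query itself is not a candidate.
#'
#' @param hits Query hit table.
#' @param clusters A `cluster_set` whose leaves include the query.
#' @param query_id Query id.
#' @param params [engine_params()].
#' @return Character vector of subject ids.
#' @export
initial_candidates <- function(hits, clusters, query_id,
                               params = engine_params()) {
  qc <- clusters$assignments[query_id]
  if (is.na(qc)) stop("query cluster not found: '", query_id,
                      "' is not a leaf of the clustering")
  in_cluster <- names(clusters$assignments)[clusters$assignments == qc]
  high_id <- unique(hits$subject_id[hits$percent_identity > params$identity_select])
  setdiff(union(high_id, in_cluster), query_id)
}

#' Expand the candidate set
#'
#' Adds (a) every co-member of any selected protein's cluster and (b) every
#' subject found as an RBH by more than `multi_support_select` verified
#' orthologs.
#'
#' @param selected Character vector of currently selected subject ids.
#' @param clusters A `cluster_set`.
#' @param rbh_counts Named integer vector: subject id -> number of verified
#'   orthologs whose reciprocal search finds it as the best hit in its
#'   species.
#' @param params [engine_params()].
#' @return The expanded selected set (character vector).
#' @export
expand_candidates <- function(selected, clusters, rbh_counts = integer(0),
                              params = engine_params()) {
  cluster_ids <- unique(clusters$assignments[intersect(selected,
                                                       names(clusters$assignments))])
  co_members <- names(clusters$assignments)[clusters$assignments %in% cluster_ids]
  multi <- names(rbh_counts)[rbh_counts > params$multi_support_select]
  union(selected, union(co_members, multi))
}

#' Reciprocal report for one candidate
#'
#' Given the candidate's reciprocal search results, computes for each
#' verified ortholog `o` (in species `s`) the rank of `o` among the
#' candidate's hits restricted to species `s`, and the relation:
#' `best` (rank 1), `acceptable` (rank in `acceptable_ranks`), else
#' `rejected` (including absent).
#'
#' @param search_hits The candidate's reciprocal search hit table.
#' @param verified Data frame with columns `id`, `species`: the current
#'   verified orthologs (the query included).
#' @param params [engine_params()].
#' @return Data frame with columns `ortholog_id`, `species`, `rank`,
#'   `relation`.
#' @export
reciprocal_report <- function(search_hits, verified, params = engine_params()) {
  hits <- best_hsp_per_subject(search_hits)
  ranks <- vapply(seq_len(nrow(verified)), function(i) {
    same <- hits$subject_id[hits$subject_species == verified$species[[i]]]
    r <- match(verified$id[[i]], same)
    if (is.na(r)) NA_integer_ else as.integer(r)
  }, integer(1))
  relation <- ifelse(is.na(ranks), "rejected",
                     ifelse(ranks == 1L, "best",
                            ifelse(ranks %in% params$acceptable_ranks,
                                   "acceptable", "rejected")))
  data.frame(ortholog_id = verified$id, species = verified$species,
             rank = ranks, relation = relation, stringsAsFactors = FALSE)
}

#' Decide on one orthology candidate
#'
#' For candidates with a statistically reliable E-value to the query
#' (`e_value_to_query < strict_e`) the strict RBH rule applies: verified iff
#' the relation to the query is `best`.  Otherwise the rejection vote
#' applies: rejected iff the rejecting fraction of the current verified set
#' strictly exceeds `reject_fraction`, else (provisionally) verified.
#'
#' @param report Data frame from [reciprocal_report()] covering all current
#'   verified orthologs.
#' @param e_value_to_query Candidate's E-value in the original query search.
#' @param query_id Query id.
#' @param params [engine_params()].
#' @return List with `verified` (logical), `rule` (which rule fired) and the
#'   vote counts.
#' @export
decide_candidate <- function(report, e_value_to_query, query_id,
                             params = engine_params()) {
  if (nrow(report) == 0L) stop("empty verified set: nothing to decide against")
  n_verified <- nrow(report)
  rejectors <- report$ortholog_id[report$relation == "rejected"]
  if (e_value_to_query < params$strict_e) {
    rel_q <- report$relation[report$ortholog_id == query_id]
    if (!length(rel_q)) stop("strict-RBH decision requires the query in the report")
    ok <- rel_q[[1L]] == "best"
    return(list(verified = ok, rule = "strict_rbh",
                n_verified = n_verified, n_rejectors = length(rejectors)))
  }
  frac <- length(rejectors) / n_verified
  ok <- !(frac > params$reject_fraction)
  list(verified = ok, rule = "rejection_vote",
       n_verified = n_verified, n_rejectors = length(rejectors))
}

#' Run the iterative reciprocal-verification engine
#'
#' Starting from the initial candidates (more than 80% identity, or in the
#' query's cluster), the engine loops: each pending candidate -- in
#' deterministic order of ascending E-value to the query, then id -- is
#' submitted to a reciprocal search against the source database, its
#' relations to the current verified set are computed, and
#' [decide_candidate()] verifies or rejects it.  Newly verified orthologs
#' immediately join the verified set.  After each pass the candidate set is
#' expanded (cluster co-members; subjects found as RBH by more than two
#' verified orthologs) and the loop repeats until no new candidates appear.
#' Candidates are bounded by the subjects of the initial search, so the loop
#' terminates.
#'
#' The final output drops every verified candidate supported by the query
#' alone: a candidate's supporters are the final verified orthologs whose
#' relation in the candidate's reciprocal search is `best` or `acceptable`,
#' and at least one supporter other than the query is required.
#'
#' @param query Query sequence record.
#' @param hits Query hit table (from [backend_search()] or
#'   [read_blast_tabular()]).
#' @param clusters A `cluster_set` over the hit subjects plus the query.
#' @param backend A search backend holding `source_db`.
#' @param source_db Database id to run reciprocal searches against.
#' @param config [search_config()] for the reciprocal searches.
#' @param params [engine_params()].
#' @return List with `verified` (data.frame id/species/e_value, query
#'   excluded), `reports` (per-candidate reciprocal reports), `searches`
#'   (per-candidate reciprocal hit tables), `audit` (data.frame of decisions)
#'   and `statuses` (named character vector).
#' @export
run_engine <- function(query, hits, clusters, backend, source_db,
                       config = search_config(), params = engine_params()) {
  if (isTRUE(attr(hits, "oversized"))) {
    stop("initial search oversized (> ", config$max_hits, " hits): the family ",
         "has enough sequence similarity for phylogenetic methods; ",
         "aborting the remote-orthology engine")
  }
  db <- get_database(backend, source_db)
  uniq <- best_hsp_per_subject(hits)
  e_to_query <- setNames(uniq$e_value, uniq$subject_id)
  species_of <- setNames(uniq$subject_species, uniq$subject_id)
  species_of[query$id] <- query$species
  universe <- setdiff(uniq$subject_id, query$id)

  selected <- intersect(
    expand_candidates(initial_candidates(hits, clusters, query$id, params),
                      clusters, params = params),
    universe)
  statuses <- setNames(rep("pending", length(universe)), universe)
  statuses[selected] <- "selected"
  verified_ids <- query$id
  searches <- list()
  reports <- list()
  audit <- list()
  note <- function(...) audit[[length(audit) + 1L]] <<- list(...)

  decided <- character(0)
  repeat {
    pending <- setdiff(selected, decided)
    if (!length(pending)) break
    pending <- pending[order(e_to_query[pending], pending)]
    for (cand in pending) {
      decided <- c(decided, cand)
      row <- db[db$id == cand, ]
      if (nrow(row) == 0L) {
        statuses[cand] <- "pending"
        note(candidate = cand, rule = "search_failed",
             detail = "sequence missing from source database")
        next
      }
      cand_rec <- as.list(row[1L, ])
      res <- tryCatch(backend_search(backend, cand_rec, source_db, config),
                      error = function(e) e)
      if (inherits(res, "error")) {
        statuses[cand] <- "pending"
        note(candidate = cand, rule = "search_failed",
             detail = conditionMessage(res))
        next
      }
      searches[[cand]] <- res
      vdf <- data.frame(id = verified_ids,
                        species = unname(species_of[verified_ids]),
                        stringsAsFactors = FALSE)
      rep_df <- reciprocal_report(res, vdf, params)
      reports[[cand]] <- rep_df
      dec <- decide_candidate(rep_df, e_to_query[[cand]], query$id, params)
      statuses[cand] <- if (dec$verified) "verified" else "rejected"
      note(candidate = cand, rule = dec$rule, verified = dec$verified,
           e_value = unname(e_to_query[[cand]]),
           n_verified = dec$n_verified, n_rejectors = dec$n_rejectors)
      if (dec$verified) verified_ids <- c(verified_ids, cand)
    }
    ## expansion: cluster co-members of the selected set, plus subjects
    ## found as best-in-their-species by > multi_support_select verified
    ## orthologs
    rbh_counts <- rbh_support_counts(searches,
                                     intersect(verified_ids, names(searches)),
                                     universe)
    grown <- intersect(
      expand_candidates(selected, clusters, rbh_counts, params), universe)
    new <- setdiff(grown, selected)
    if (!length(new)) break
    statuses[new] <- "selected"
    for (s in new) note(candidate = s, rule = "expanded",
                        n_rbh_support = unname(rbh_counts[s]))
    selected <- grown
  }

  ## query-alone exclusion, evaluated against the final verified set
  final <- setdiff(verified_ids, query$id)
  keep <- vapply(final, function(cand) {
    rep_all <- reciprocal_report(
      searches[[cand]],
      data.frame(id = verified_ids, species = unname(species_of[verified_ids]),
                 stringsAsFactors = FALSE),
      params)
    sup <- rep_all$ortholog_id[rep_all$relation %in% c("best", "acceptable")]
    sup <- setdiff(sup, cand)
    length(setdiff(sup, query$id)) > 0L
  }, logical(1))
  for (cand in final[!keep]) {
    statuses[cand] <- "excluded_query_only"
    note(candidate = cand, rule = "query_alone_exclusion", verified = FALSE)
  }
  final <- final[keep]

  verified_df <- data.frame(id = final, species = unname(species_of[final]),
                            e_value = unname(e_to_query[final]),
                            stringsAsFactors = FALSE)
  verified_df <- verified_df[order(verified_df$e_value, verified_df$id), ]
  rownames(verified_df) <- NULL
  audit_df <- do.call(rbind, lapply(audit, function(x) {
    data.frame(candidate = x$candidate, rule = x$rule,
               verified = if (is.null(x$verified)) NA else x$verified,
               detail = if (is.null(x$detail)) NA_character_ else x$detail,
               n_verified = if (is.null(x$n_verified)) NA_integer_ else x$n_verified,
               n_rejectors = if (is.null(x$n_rejectors)) NA_integer_ else x$n_rejectors,
               stringsAsFactors = FALSE)
  }))
  if (is.null(audit_df)) {
    audit_df <- data.frame(candidate = character(0), rule = character(0),
                           verified = logical(0), detail = character(0),
                           n_verified = integer(0), n_rejectors = integer(0))
  }
  list(verified = verified_df, reports = reports, searches = searches,
       audit = audit_df, statuses = statuses)
}

## For each subject in `universe`, the number of verified orthologs whose
## stored reciprocal search ranks it first within the subject's species.
rbh_support_counts <- function(searches, verified_with_search, universe) {
  counts <- setNames(integer(length(universe)), universe)
  for (o in verified_with_search) {
    hits <- best_hsp_per_subject(searches[[o]])
    if (nrow(hits) == 0L) next
    tops <- hits$subject_id[!duplicated(hits$subject_species)]
    tops <- intersect(tops, universe)
    counts[tops] <- counts[tops] + 1L
  }
  counts
}

#' Write an engine audit log as line-oriented JSON
#'
#' @param audit The `audit` data frame of a [run_engine()] result.
#' @param path Output path (one JSON object per line).
#' @export
write_audit_jsonl <- function(audit, path) {
  lines <- vapply(seq_len(nrow(audit)), function(i) {
    row <- as.list(audit[i, ])
    row <- row[!vapply(row, function(v) is.na(v) || is.null(v), logical(1))]
    as.character(jsonlite::toJSON(row, auto_unbox = TRUE, digits = NA))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
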