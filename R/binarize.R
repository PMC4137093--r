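#' Binarize one alignment against the query
#'
#' Transforms a pairwise local alignment into a 0/1 conservation profile
#' over the full query length: position `p` is 1 iff it lies inside the
#' aligned region, neither column is a gap, and the two residues are
#' identical or conserved (positive substitution-matrix score).  Gap columns
#' in the aligned query consume no query position; `X` residues never count
#' as identical or conserved.
#'
#' @param aln One alignment: a list or one-row data frame with fields
#'   `aligned_query`, `aligned_subject`, `query_start`, `query_end`.
#' @param query_len Full (unaligned) query length; all profiles of a run
#'   share this length.
#' @param matrix Symmetric substitution matrix (default [blosum62()]).
#' @return Integer 0/1 vector of length `query_len`.
#' @export
binarize <- function(aln, query_len, matrix = blosum62()) {
  qs <- as.integer(aln$query_start)
  qe <- as.integer(aln$query_end)
  if (qe > query_len) {
    stop("query_end (", qe, ") exceeds query length (", query_len, ")")
  }
  qchars <- strsplit(aln$aligned_query, "")[[1L]]
  schars <- strsplit(aln$aligned_subject, "")[[1L]]
  if (length(qchars) != length(schars)) {
    stop("aligned strings differ in length")
  }
  bits <- integer(query_len)
  pos <- qs
  for (i in seq_along(qchars)) {
    q <- qchars[[i]]
    if (q == "-") next
    s <- schars[[i]]
    if (s != "-" && q %in% AA20 && s %in% AA20 &&
        (q == s || matrix[q, s] > 0)) {
      bits[pos] <- 1L
    }
    pos <- pos + 1L
  }
  if (pos - 1L != qe) {
    stop("ungapped aligned_query does not span query_start..query_end")
  }
  bits
}

#' Conservation profiles for all hits of a search
#'
#' Keeps the lowest-E-value HSP per subject (one profile per subject keeps
#' the cluster consensus well defined) and binarizes each against the query.
#'
#' @param hits A hit table.
#' @param query Query sequence record.
#' @param matrix Substitution matrix, default [blosum62()].
#' @param include_query Prepend the query's own profile (its full-length
#'   self-alignment), so the query is a leaf of the clustering.
#' @return Integer 0/1 matrix, one row per subject (row names are ids),
#'   `ncol` = query length.
#' @export
alignment_profiles <- function(hits, query, matrix = blosum62(),
                               include_query = TRUE) {
  hits <- best_hsp_per_subject(hits)
  query_len <- nchar(query$residues)
  rows <- list()
  if (include_query) {
    self <- list(aligned_query = query$residues,
                 aligned_subject = query$residues,
                 query_start = 1L, query_end = query_len)
    rows[[query$id]] <- binarize(self, query_len, matrix)
  }
  for (i in seq_len(nrow(hits))) {
    sid <- hits$subject_id[[i]]
    if (!is.null(rows[[sid]])) next  # query also present as a database hit
    rows[[sid]] <- binarize(hits[i, ], query_len, matrix)
  }
  mat <- do.call(rbind, rows)
  rownames(mat) <- names(rows)
  mat
}
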