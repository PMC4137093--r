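#' Per-residue weights for profile similarity
#'
#' Rare residues carry more evolutionary signal when they stay conserved, so
#' positions are weighted by the query residue they carry.  Two schemes:
#'
#' * `"log_rarity"` (default): `w(a) = -log2 f(a)` with Robinson-Robinson
#'   background frequencies `f` -- the information content of observing
#'   residue `a`, so tryptophan (f = 0.0133) weighs about 2.4x leucine
#'   (f = 0.0902).
#' * `"optima"`: diagonal weights of the OPTIMA substitution matrix, read
#'   from a user-supplied two-column table (`residue<TAB>weight`); the
#'   package does not bundle these values.
#'
#' @param scheme `"log_rarity"` or `"optima"`.
#' @param table For `scheme = "optima"`: path to the weights table.
#' @return Named positive numeric vector over the 20 standard residues.
#' @export
residue_weights <- function(scheme = c("log_rarity", "optima"), table = NULL) {
  scheme <- match.arg(scheme)
  if (scheme == "log_rarity") {
    w <- -log2(ROBINSON_FREQS)
  } else {
    if (is.null(table)) {
      table <- system.file("extdata", "optima_weights.tsv", package = "remort")
    }
    if (is.null(table) || !nzchar(table) || !file.exists(table)) {
      stop("weights table not found: scheme 'optima' needs a residue<TAB>weight ",
           "table (the OPTIMA diagonal values are not bundled); ",
           "use scheme = 'log_rarity' or supply `table`")
    }
    tab <- utils::read.table(table, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)
    w <- setNames(as.numeric(tab[[2L]]), toupper(tab[[1L]]))
    missing_aa <- setdiff(AA20, names(w))
    if (length(missing_aa)) {
      stop("weights table lacks residue(s) ", paste(missing_aa, collapse = ", "))
    }
    w <- w[AA20]
  }
  if (any(!is.finite(w)) || any(w <= 0)) stop("all residue weights must be positive")
  w
}

## Position weights along a query sequence: w(q_p) for each position p.
## Non-standard residues (X) get weight 0 so they contribute to neither the
## intersection nor the union of a weighted-Jaccard comparison.
position_weights <- function(query_residues, weights) {
  chars <- strsplit(query_residues, "")[[1L]]
  w <- unname(weights[chars])
  w[is.na(w)] <- 0
  w
}
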