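#' Weighted similarity of two conservation profiles
#'
#' Weighted Jaccard similarity over conserved positions:
#' `S = sum_p w(q_p) p_i[p] p_j[p] / sum_p w(q_p) max(p_i[p], p_j[p])`,
#' where `w(q_p)` is the weight of the query residue at position `p`.
#' `S = 0` when the denominator is 0 (disjoint or empty supports give 0;
#' identical non-empty supports give 1).
#'
#' @param p_i,p_j Equal-length 0/1 profiles.
#' @param query Query sequence record (`residues` supplies the weights), or
#'   `NULL` to pass precomputed position weights via `pw`.
#' @param weights Residue weights from [residue_weights()].
#' @param pw Optional precomputed position-weight vector (overrides
#'   `query`/`weights`).
#' @return Similarity in `[0, 1]`.
#' @export
profile_similarity <- function(p_i, p_j, query = NULL,
                               weights = residue_weights(), pw = NULL) {
  if (length(p_i) != length(p_j)) {
    stop("profile length mismatch: ", length(p_i), " vs ", length(p_j))
  }
  if (is.null(pw)) pw <- position_weights(query$residues, weights)
  if (length(pw) != length(p_i)) stop("position weights do not match profile length")
  denom <- sum(pw * pmax(p_i, p_j))
  if (denom == 0) return(0)
  sum(pw * p_i * p_j) / denom
}

#' Consensus-linkage hierarchical clustering of conservation profiles
#'
#' Agglomerative clustering with distance `d = 1 - S` (weighted Jaccard
#' similarity, [profile_similarity()]).  Unlike classical average linkage,
#' the distance between two clusters is computed between their *conserved
#' consensus* vectors -- the elementwise AND of the member profiles -- so a
#' cluster is represented by the positions conserved in every member, the
#' family-specific pattern the pipeline is after.  Ties in the minimum
#' distance are broken by the lexicographically smallest pair of cluster
#' representative ids (a representative is the smallest member id), making
#' runs bit-reproducible.
#'
#' @param profiles 0/1 matrix, one row per profile, row names are ids.
#' @param query Query sequence record.
#' @param weights Residue weights, default [residue_weights()].
#' @return An object of class `consensus_dendrogram`: list with `merge`
#'   (m x 2, `hclust` convention: negative = leaf index, positive = earlier
#'   merge), `height` (the actual merge distances, which may invert --
#'   consensus linkage, like centroid linkage, is not monotone), `labels`,
#'   and `consensus` (m x L matrix of post-merge consensus vectors).
#' @export
consensus_linkage <- function(profiles, query, weights = residue_weights()) {
  n <- nrow(profiles)
  if (is.null(n) || n < 2L) stop("consensus_linkage needs at least 2 profiles")
  labels <- rownames(profiles)
  if (is.null(labels) || anyNA(labels) || any(duplicated(labels))) {
    stop("profiles must carry unique row-name ids")
  }
  pw <- position_weights(query$residues, weights)
  if (length(pw) != ncol(profiles)) {
    stop("profile length (", ncol(profiles), ") does not match query length (",
         length(pw), ")")
  }

  ## Active cluster state; node encodes hclust merge ids.
  cons <- profiles * 1            # consensus vectors (rows)
  rep_id <- labels                # representative = smallest member id
  node <- -seq_len(n)
  active <- rep(TRUE, n)

  sim <- function(a, b) {
    denom <- sum(pw * pmax(a, b))
    if (denom == 0) 0 else sum(pw * a * b) / denom
  }
  ## distance matrix over active clusters
  D <- matrix(NA_real_, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      D[i, j] <- D[j, i] <- 1 - sim(cons[i, ], cons[j, ])
    }
  }

  m <- n - 1L
  merge <- matrix(0L, m, 2L)
  height <- numeric(m)
  consensus <- matrix(0L, m, ncol(profiles))
  slots <- seq_len(n)

  for (step in seq_len(m)) {
    act <- slots[active]
    ## minimum distance among active pairs
    dmin <- Inf
    best <- NULL
    for (ii in seq_len(length(act) - 1L)) {
      for (jj in seq(ii + 1L, length(act))) {
        i <- act[[ii]]; j <- act[[jj]]
        d <- D[i, j]
        if (d < dmin - 1e-12) {
          dmin <- d; best <- c(i, j)
        } else if (abs(d - dmin) <= 1e-12) {
          ## tie: smallest lexicographic (sorted) representative pair
          cand <- sort(c(rep_id[[i]], rep_id[[j]]))
          cur <- sort(c(rep_id[[best[[1L]]]], rep_id[[best[[2L]]]]))
          if (cand[[1L]] < cur[[1L]] ||
              (cand[[1L]] == cur[[1L]] && cand[[2L]] < cur[[2L]])) {
            best <- c(i, j)
          }
        }
      }
    }
    i <- best[[1L]]; j <- best[[2L]]
    ## record merge in hclust convention, smaller node code first
    pair <- sort(c(node[[i]], node[[j]]))
    merge[step, ] <- pair
    height[[step]] <- D[i, j]
    newcons <- cons[i, ] & cons[j, ]
    consensus[step, ] <- as.integer(newcons)
    ## collapse j into i
    cons[i, ] <- as.numeric(newcons)
    rep_id[[i]] <- min(rep_id[[i]], rep_id[[j]])
    node[[i]] <- step
    active[[j]] <- FALSE
    for (k in slots[active]) {
      if (k != i) D[i, k] <- D[k, i] <- 1 - sim(cons[i, ], cons[k, ])
    }
  }
  structure(list(merge = merge, height = height, labels = labels,
                 consensus = consensus),
            class = "consensus_dendrogram")
}

#' @export
print.consensus_dendrogram <- function(x, ...) {
  cat("Consensus-linkage dendrogram over", length(x$labels), "profiles;",
      nrow(x$merge), "merges, height range [",
      format(min(x$height), digits = 4), ",",
      format(max(x$height), digits = 4), "]\n")
  invisible(x)
}

#' Cut a dendrogram at the climbing-rate knee of an exponential fit
#'
#' The sorted merge heights of a family dendrogram typically follow an
#' exponential curve: a long flat stretch (mutually similar alignments)
#' followed by a steep climb (merges joining unrelated clusters).  The cut
#' is placed where the climbing rate turns from flat to steep: fit
#' `y = a exp(b x)` by least squares on the log-transformed sorted heights
#' (ranks `x = 1..m`; heights below `eps = 1e-9` are clamped to `eps`), and
#' take the first rank `x*` at which the fitted instantaneous slope
#' `a b exp(b x)` exceeds the mean slope `(y_m - y_1)/(m - 1)`; if the
#' fitted slope never catches the mean slope the acceleration point lies
#' beyond the last rank and `x* = m`.  The cut height is the fitted value
#' `a exp(b x*)`; clusters are the connected components over merges with
#' height strictly below it.
#'
#' Exact-zero heights (identical profiles) would act as unbounded levers on
#' the log-scale fit; they are clamped to half the smallest positive height
#' before fitting, which preserves the flatness signal without distorting
#' the slope.
#'
#' Degenerate cases (fewer than 3 merges, all heights equal, or a flat /
#' non-increasing fit) return a single cluster.
#'
#' @param dend A `consensus_dendrogram`.
#' @return An object of class `cluster_set`: list with `assignments` (named
#'   integer vector, leaf id -> cluster index), `clusters` (list of id
#'   character vectors), `cut_height`, and the fit coefficients `a`, `b`.
#' @export
cut_dendrogram <- function(dend) {
  m <- length(dend$height)
  n <- length(dend$labels)
  single <- function(cut_height = Inf, a = NA_real_, b = NA_real_) {
    structure(list(assignments = setNames(rep(1L, n), dend$labels),
                   clusters = list(dend$labels),
                   cut_height = cut_height, a = a, b = b),
              class = "cluster_set")
  }
  if (m < 3L) return(single())
  y <- sort(dend$height)
  if (max(y) - min(y) < 1e-12) return(single())
  pos <- y[y > 1e-9]
  if (!length(pos)) return(single())
  eps <- max(1e-9, min(pos) / 2)
  x <- seq_len(m)
  fit <- stats::lm(log(pmax(y, eps)) ~ x)
  a <- exp(stats::coef(fit)[[1L]])
  b <- stats::coef(fit)[[2L]]
  mean_slope <- (y[[m]] - y[[1L]]) / (m - 1L)
  if (!is.finite(b) || b <= 0 || mean_slope <= 0) return(single())
  slope <- a * b * exp(b * x)
  knee <- which(slope > mean_slope)
  ## when the fitted slope never catches the mean slope the acceleration
  ## point lies beyond the last rank: cut at the top of the fitted curve
  x_star <- if (length(knee)) knee[[1L]] else m
  cut_height <- a * exp(b * x_star)
  components_below(dend, cut_height, a = a, b = b)
}

## Connected components over merges with height < cut_height (union-find).
components_below <- function(dend, cut_height, a = NA_real_, b = NA_real_) {
  n <- length(dend$labels)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[[i]] != i) {
      parent[[i]] <<- parent[[parent[[i]]]]
      i <- parent[[i]]
    }
    i
  }
  ## leaves reachable under each merge node
  merge_members <- vector("list", nrow(dend$merge))
  members_of <- function(code) {
    if (code < 0L) -code else merge_members[[code]]
  }
  for (s in seq_len(nrow(dend$merge))) {
    mem <- c(members_of(dend$merge[s, 1L]), members_of(dend$merge[s, 2L]))
    merge_members[[s]] <- mem
    if (dend$height[[s]] < cut_height) {
      r <- find(mem[[1L]])
      for (i in mem[-1L]) parent[[find(i)]] <- r
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  ids <- match(roots, unique(roots))
  assignments <- setNames(ids, dend$labels)
  clusters <- split(dend$labels, ids)
  names(clusters) <- NULL
  structure(list(assignments = assignments, clusters = clusters,
                 cut_height = cut_height, a = a, b = b),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  sizes <- lengths(x$clusters)
  cat("Cluster set:", length(x$clusters), "clusters (sizes",
      paste(sort(sizes, decreasing = TRUE), collapse = ", "),
      ") cut at height", format(x$cut_height, digits = 4), "\n")
  invisible(x)
}

#' Write dendrogram merges and cluster assignments as TSV (diagnostics)
#'
#' @param dend A `consensus_dendrogram`.
#' @param clusters A `cluster_set`.
#' @param merges_path,assignments_path Output paths.
#' @export
write_clustering_tsv <- function(dend, clusters, merges_path, assignments_path) {
  name_of <- function(codes) {
    vapply(codes, function(code) {
      if (code < 0L) dend$labels[[-code]] else paste0("merge_", code)
    }, character(1))
  }
  merges <- data.frame(left = name_of(dend$merge[, 1L]),
                       right = name_of(dend$merge[, 2L]),
                       height = dend$height)
  utils::write.table(merges, merges_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  assign_df <- data.frame(id = names(clusters$assignments),
                          cluster = unname(clusters$assignments))
  assign_df <- assign_df[order(assign_df$id), ]
  utils::write.table(assign_df, assignments_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(NULL)
}
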