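## Independent oracles and fixture builders used across the test files.
## Each oracle re-derives the quantity it checks from first principles,
## sharing no code path with the implementation.

## --- naive affine-gap Smith-Waterman (pure R, O(mn) DP) -----------------
## Gap of length L costs gap_open + L * gap_extend.
naive_sw_score <- function(a, b, matrix = remort::blosum62(),
                           gap_open = 11, gap_extend = 1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  m <- length(A); n <- length(B)
  M <- matrix(0, m + 1, n + 1)   # best ending in a match/mismatch
  X <- matrix(-Inf, m + 1, n + 1) # gap in B (A consumed)
  Y <- matrix(-Inf, m + 1, n + 1) # gap in A (B consumed)
  best <- 0
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      sub <- matrix[A[i], B[j]]
      M[i + 1, j + 1] <- max(0, M[i, j], X[i, j], Y[i, j]) + sub
      X[i + 1, j + 1] <- max(M[i, j + 1] - gap_open - gap_extend,
                             X[i, j + 1] - gap_extend)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - gap_open - gap_extend,
                             Y[i + 1, j] - gap_extend)
      best <- max(best, M[i + 1, j + 1])
    }
  }
  best
}

## --- brute-force consensus-linkage agglomerator -------------------------
## Recomputes AND-consensus and weighted-Jaccard distance from scratch at
## every step, tracking clusters as plain member lists.
brute_consensus_linkage <- function(profiles, pw) {
  jac <- function(x, y) {
    den <- sum(pw * pmax(x, y))
    if (den == 0) 0 else sum(pw * x * y) / den
  }
  clusters <- lapply(seq_len(nrow(profiles)), function(i) rownames(profiles)[i])
  heights <- numeric(0)
  merge_sets <- list()
  while (length(clusters) > 1L) {
    k <- length(clusters)
    cons <- lapply(clusters, function(mem) {
      v <- rep(1L, ncol(profiles))
      for (id in mem) v <- v & profiles[id, ]
      as.integer(v)
    })
    dmin <- Inf; pick <- NULL
    for (i in seq_len(k - 1L)) {
      for (j in seq(i + 1L, k)) {
        d <- 1 - jac(cons[[i]], cons[[j]])
        if (d < dmin - 1e-12) {
          dmin <- d; pick <- c(i, j)
        } else if (abs(d - dmin) <= 1e-12) {
          cand <- sort(c(min(clusters[[i]]), min(clusters[[j]])))
          cur <- sort(c(min(clusters[[pick[1]]]), min(clusters[[pick[2]]])))
          if (cand[1] < cur[1] || (cand[1] == cur[1] && cand[2] < cur[2])) {
            pick <- c(i, j)
          }
        }
      }
    }
    d_pick <- 1 - jac(cons[[pick[1]]], cons[[pick[2]]])
    heights <- c(heights, d_pick)
    merged <- sort(c(clusters[[pick[1]]], clusters[[pick[2]]]))
    merge_sets[[length(merge_sets) + 1L]] <- merged
    clusters <- c(clusters[-pick], list(merged))
  }
  list(heights = heights, merge_sets = merge_sets)
}

## Member sets per merge of a consensus_dendrogram, for comparison with the
## brute-force agglomerator.
dend_merge_sets <- function(dend) {
  sets <- vector("list", nrow(dend$merge))
  members <- function(code) {
    if (code < 0) dend$labels[-code] else sets[[code]]
  }
  for (s in seq_len(nrow(dend$merge))) {
    sets[[s]] <- sort(c(members(dend$merge[s, 1]), members(dend$merge[s, 2])))
  }
  sets
}

## --- random profile sets -------------------------------------------------
random_profiles <- function(n, L, seed, p_on = 0.3) {
  set.seed(seed)
  mat <- matrix(as.integer(runif(n * L) < p_on), n, L)
  rownames(mat) <- sprintf("p%02d", seq_len(n))
  mat
}

## Random query of given length (uniform residues).
random_query <- function(L, seed) {
  set.seed(seed)
  list(id = "query", species = "qsp",
       residues = paste(sample(c("A","R","N","D","C","Q","E","G","H","I",
                                 "L","K","M","F","P","S","T","W","Y","V"),
                               L, replace = TRUE), collapse = ""))
}

## --- planted 3-cluster profile sets (cleanly separated supports) ---------
## Disjoint 20-position supports with light jitter (~2% dropout, one stray
## bit) keep within-group merge heights well below the between-group
## distance of 1, the "cleanly separated" regime the cut is probed in.
planted_three_clusters <- function(seed, per_cluster = 5, L = 100) {
  set.seed(seed)
  supports <- list(1:20, 35:54, 70:89)
  rows <- list()
  for (g in 1:3) {
    for (r in seq_len(per_cluster)) {
      v <- integer(L)
      on <- supports[[g]][runif(20) > 0.02]  # drop ~2% of the support
      v[on] <- 1L
      noise <- sample(setdiff(seq_len(L), supports[[g]]), 1)
      v[noise] <- 1L
      rows[[sprintf("g%d_m%02d", g, r)]] <- v
    }
  }
  mat <- do.call(rbind, rows)
  rownames(mat) <- names(rows)
  list(profiles = mat,
       truth = rep(1:3, each = per_cluster))
}

## --- dense eigen-decomposition centrality oracle -------------------------
## Principal eigenvector of the weighted adjacency, per connected
## component, oriented non-negative and L2-normalised.
eigen_centrality_oracle <- function(net) {
  ids <- net$nodes$id
  n <- length(ids)
  W <- matrix(0, n, n, dimnames = list(ids, ids))
  if (nrow(net$edges)) {
    for (k in seq_len(nrow(net$edges))) {
      i <- match(net$edges$node_a[k], ids)
      j <- match(net$edges$node_b[k], ids)
      W[i, j] <- W[j, i] <- net$edges$weight[k]
    }
  }
  ## components via matrix powers of the boolean adjacency
  reach <- (W > 0) | diag(n) > 0
  for (k in seq_len(n)) reach <- reach | (reach %*% reach) > 0
  comp <- integer(n); cur <- 0
  for (i in seq_len(n)) {
    if (comp[i] == 0) {
      cur <- cur + 1
      comp[reach[i, ]] <- cur
    }
  }
  scores <- stats::setNames(numeric(n), ids)
  for (c0 in unique(comp)) {
    idx <- which(comp == c0)
    if (length(idx) == 1) { scores[idx] <- 1; next }
    eg <- eigen(W[idx, idx], symmetric = TRUE)
    v <- eg$vectors[, which.max(eg$values)]
    if (sum(v) < 0) v <- -v
    scores[idx] <- abs(v) / sqrt(sum(v^2))
  }
  scores
}

## Random typed orthology network on <= max_nodes nodes.
random_network <- function(seed, max_nodes = 8) {
  set.seed(seed)
  n <- sample(2:max_nodes, 1)
  ids <- sprintf("n%02d", seq_len(n))
  types <- c("bb", "ba", "aa", "b", "a")
  wts <- c(bb = 1, ba = 0.5, aa = 0.25, b = 0.125, a = 0.0625)
  edges <- list()
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (runif(1) < 0.5) {
        ty <- sample(types, 1)
        edges[[length(edges) + 1L]] <-
          data.frame(node_a = ids[i], node_b = ids[j], etype = ty,
                     weight = unname(wts[ty]), stringsAsFactors = FALSE)
      }
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(node_a = character(0), node_b = character(0),
               etype = character(0), weight = numeric(0))
  structure(list(nodes = data.frame(id = ids,
                                    species = paste0("sp", seq_len(n)),
                                    e_value = runif(n),
                                    stringsAsFactors = FALSE),
                 edges = edges),
            class = "orthology_network")
}

## --- misc ---------------------------------------------------------------
## A one-row alignment record for binarize()/hit-table tests.
aln_row <- function(aligned_query, aligned_subject, query_start, query_end,
                    subject_id = "s1", subject_species = "sp1",
                    e_value = 1, percent_identity = 50, query_id = "q1") {
  data.frame(query_id = query_id, subject_id = subject_id,
             subject_species = subject_species, e_value = e_value,
             percent_identity = percent_identity,
             query_start = as.integer(query_start),
             query_end = as.integer(query_end),
             aligned_query = aligned_query, aligned_subject = aligned_subject,
             stringsAsFactors = FALSE)
}
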