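## Fixed edge weights of the typed orthology network.  These constants carry
## the published score semantics and are deliberately not configurable.
EDGE_WEIGHTS <- c(bb = 1, ba = 0.5, aa = 0.25, b = 0.125, a = 0.0625)

#' Classify an orthology-network edge from its two directed relations
#'
#' Verified orthologs are connected by typed edges reflecting how each finds
#' the other in its reciprocal search: best-best (`bb`), best-acceptable
#' (`ba`), acceptable-acceptable (`aa`), and the one-sided types `b` and `a`
#' where only one of the two proteins finds the other.  Weights descend
#' bb = 1, ba = 0.5, aa = 0.25, b = 0.125, a = 0.0625.
#'
#' @param rel_ab Relation of `b` in `a`'s search: `"best"`, `"acceptable"`
#'   or `"none"`.
#' @param rel_ba Relation of `a` in `b`'s search.
#' @return A list with `etype` and `weight`, or `NULL` when neither finds
#'   the other.
#' @export
classify_edge <- function(rel_ab, rel_ba) {
  stopifnot(rel_ab %in% c("best", "acceptable", "none"),
            rel_ba %in% c("best", "acceptable", "none"))
  pair <- sort(c(rel_ab, rel_ba))
  etype <- if (all(pair == c("best", "best"))) "bb"
    else if (all(pair == c("acceptable", "best"))) "ba"
    else if (all(pair == c("acceptable", "acceptable"))) "aa"
    else if (all(pair == c("best", "none"))) "b"
    else if (all(pair == c("acceptable", "none"))) "a"
    else return(NULL)
  list(etype = etype, weight = unname(EDGE_WEIGHTS[[etype]]))
}

## Directed relation of `target` in a search hit table, mapped to
## best/acceptable/none (ranks beyond the acceptable window count as none).
directed_relation <- function(search_hits, target_id, target_species, params) {
  hits <- best_hsp_per_subject(search_hits)
  same <- hits$subject_id[hits$subject_species == target_species]
  r <- match(target_id, same)
  if (is.na(r)) "none"
  else if (r == 1L) "best"
  else if (r %in% params$acceptable_ranks) "acceptable"
  else "none"
}

#' Build the typed orthology network
#'
#' Nodes are the query plus the verified orthologs; each unordered pair is
#' connected by the edge [classify_edge()] derives from the two directed
#' relations (each node's reciprocal search ranking the other within its
#' species; the query's "search" is the original relaxed search).
#'
#' @param query Query sequence record.
#' @param engine_result Result of [run_engine()].
#' @param hits The original query hit table.
#' @param params [engine_params()].
#' @return An `orthology_network`: list with `nodes` (data.frame `id`,
#'   `species`, `e_value`) and `edges` (data.frame `node_a`, `node_b`,
#'   `etype`, `weight`).
#' @export
build_network <- function(query, engine_result, hits, params = engine_params()) {
  verified <- engine_result$verified
  nodes <- rbind(
    data.frame(id = query$id, species = query$species, e_value = 0,
               stringsAsFactors = FALSE),
    verified[, c("id", "species", "e_value")])
  nodes <- nodes[order(nodes$id), ]
  rownames(nodes) <- NULL
  searches <- engine_result$searches
  searches[[query$id]] <- hits
  edges <- list()
  n <- nrow(nodes)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        a <- nodes$id[[i]]; b <- nodes$id[[j]]
        rel_ab <- if (is.null(searches[[a]])) "none" else
          directed_relation(searches[[a]], b, nodes$species[[j]], params)
        rel_ba <- if (is.null(searches[[b]])) "none" else
          directed_relation(searches[[b]], a, nodes$species[[i]], params)
        cls <- classify_edge(rel_ab, rel_ba)
        if (!is.null(cls)) {
          edges[[length(edges) + 1L]] <-
            data.frame(node_a = a, node_b = b, etype = cls$etype,
                       weight = cls$weight, stringsAsFactors = FALSE)
        }
      }
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(node_a = character(0), node_b = character(0),
               etype = character(0), weight = numeric(0))
  structure(list(nodes = nodes, edges = edges), class = "orthology_network")
}

#' @export
print.orthology_network <- function(x, ...) {
  cat("Orthology network:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  if (nrow(x$edges)) print(table(x$edges$etype))
  invisible(x)
}

#' Eigenvector-centrality network scores
#'
#' Scores every node by the principal eigenvector of the edge-weighted
#' adjacency matrix, computed per connected component by power iteration
#' from a uniform positive start, L2-normalising each step, until the
#' maximum per-node change falls below `tol` (default 1e-10) or 1000
#' iterations (then an error naming the component).  The iteration runs on
#' `W + I`, which has the same principal eigenvector as `W` but converges
#' on bipartite components where plain power iteration oscillates.  Scores
#' are non-negative with unit Euclidean norm per component; an isolated
#' node scores 1 by that convention.  This E-value-independent score
#' measures how central a protein is to the group of collected orthologs;
#' it must never be used to *exclude* candidates (low scores are expected
#' for true members attached to only a few family members).
#'
#' @param net An `orthology_network`.
#' @param tol Convergence tolerance (max per-node change).
#' @param max_iter Iteration cap.
#' @return Named numeric vector of scores, one per node.
#' @export
network_centrality <- function(net, tol = 1e-10, max_iter = 1000L) {
  ids <- net$nodes$id
  n <- length(ids)
  if (n == 0L) stop("empty network")
  W <- matrix(0, n, n, dimnames = list(ids, ids))
  if (nrow(net$edges)) {
    ia <- match(net$edges$node_a, ids)
    ib <- match(net$edges$node_b, ids)
    for (k in seq_along(ia)) {
      W[ia[[k]], ib[[k]]] <- W[ib[[k]], ia[[k]]] <- net$edges$weight[[k]]
    }
  }
  comp <- graph_components(W > 0)
  scores <- setNames(numeric(n), ids)
  for (cid in unique(comp)) {
    idx <- which(comp == cid)
    if (length(idx) == 1L) {
      scores[idx] <- 1
      next
    }
    A <- W[idx, idx, drop = FALSE]
    x <- rep(1 / sqrt(length(idx)), length(idx))
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      xn <- A %*% x + x
      xn <- as.vector(xn / sqrt(sum(xn^2)))
      if (max(abs(xn - x)) < tol) {
        x <- xn; converged <- TRUE; break
      }
      x <- xn
    }
    if (!converged) {
      stop("centrality power iteration did not converge for the component ",
           "containing ", ids[idx][[1L]])
    }
    scores[idx] <- pmax(x, 0)
  }
  scores
}

#' Export the scored network as Cytoscape SIF plus node attributes
#'
#' Writes `node_a<TAB>etype<TAB>node_b` SIF lines and a node-attribute TSV
#' with columns `id`, `species`, `e_value`, `network_score`; both sorted by
#' id so repeated runs are byte-identical.
#'
#' @param net An `orthology_network`.
#' @param scores Scores from [network_centrality()].
#' @param path_sif,path_attr Output paths.
#' @export
export_sif <- function(net, scores, path_sif, path_attr) {
  edges <- net$edges
  if (nrow(edges)) {
    swap <- edges$node_a > edges$node_b
    tmp <- edges$node_a[swap]
    edges$node_a[swap] <- edges$node_b[swap]
    edges$node_b[swap] <- tmp
    edges <- edges[order(edges$node_a, edges$node_b), ]
    sif <- paste(edges$node_a, edges$etype, edges$node_b, sep = "\t")
  } else {
    sif <- character(0)
  }
  ## isolated nodes appear as bare node lines so the SIF reconstructs the
  ## full node set
  linked <- unique(c(edges$node_a, edges$node_b))
  isolated <- sort(setdiff(net$nodes$id, linked))
  writeLines(c(sif, isolated), path_sif)
  attr_df <- net$nodes
  attr_df$network_score <- unname(scores[attr_df$id])
  attr_df <- attr_df[order(attr_df$id),
                     c("id", "species", "e_value", "network_score")]
  utils::write.table(attr_df, path_attr, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(NULL)
}

#' Read a SIF + attribute file pair back into a scored network
#'
#' @param path_sif,path_attr Paths written by [export_sif()].
#' @return A list with an `orthology_network` (`net`) and `scores`.
#' @export
read_sif_network <- function(path_sif, path_attr) {
  lines <- readLines(path_sif)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t")
  is_edge <- lengths(parts) == 3L
  edges <- if (any(is_edge)) {
    data.frame(node_a = vapply(parts[is_edge], `[[`, character(1), 1L),
               etype = vapply(parts[is_edge], `[[`, character(1), 2L),
               node_b = vapply(parts[is_edge], `[[`, character(1), 3L),
               stringsAsFactors = FALSE)
  } else {
    data.frame(node_a = character(0), etype = character(0),
               node_b = character(0))
  }
  edges$weight <- unname(EDGE_WEIGHTS[edges$etype])
  attr_df <- utils::read.table(path_attr, sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE)
  net <- structure(list(
    nodes = attr_df[, c("id", "species", "e_value")],
    edges = edges[, c("node_a", "node_b", "etype", "weight")]),
    class = "orthology_network")
  list(net = net, scores = setNames(attr_df$network_score, attr_df$id))
}

#' Ranked result table
#'
#' One row per network node with id, species, network score and E-value,
#' sorted by descending score; ties broken by ascending E-value, then id.
#'
#' @param net An `orthology_network`.
#' @param scores Scores from [network_centrality()].
#' @return A data frame with columns `id`, `species`, `network_score`,
#'   `e_value`.
#' @export
rank_results <- function(net, scores) {
  df <- net$nodes
  if (nrow(df) == 0L) {
    return(data.frame(id = character(0), species = character(0),
                      network_score = numeric(0), e_value = numeric(0)))
  }
  df$network_score <- unname(scores[df$id])
  df <- df[order(-df$network_score, df$e_value, df$id),
           c("id", "species", "network_score", "e_value")]
  rownames(df) <- NULL
  df
}

## Connected components of a logical adjacency matrix (BFS).
graph_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[[s]] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[[s]] <- cur
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}
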