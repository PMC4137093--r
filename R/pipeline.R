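#' Pipeline run configuration
#'
#' Bundles every tunable of an end-to-end run.  Defaults are the method's
#' published operating point: relaxed E-threshold 100, strict-RBH E-value
#' 1e-5, rejection fraction 1/3, identity selection above 80%, 1500-hit
#' budget, log-rarity residue weights.
#'
#' @param query_path Path to a single-record query FASTA (or `NULL` when a
#'   `query` record is passed to [run_pipeline()] directly).
#' @param db_path Path to the database FASTA (or `NULL` with an in-memory
#'   `db`).
#' @param species_path Optional species sidecar TSV for query/database.
#' @param backend One of `"internal"`, `"blast"`, `"fixture"`.
#' @param fixture_path JSON of canned hit tables for the fixture backend.
#' @param search [search_config()].
#' @param engine [engine_params()].
#' @param weight_scheme `"log_rarity"` or `"optima"`.
#' @param weight_table Optional weights table path for `"optima"`.
#' @param out_dir Output directory (`NULL`: no files written).
#' @param seed Integer seed recorded in the manifest (the internal pipeline
#'   is deterministic; the seed matters for synthetic-world generation).
#' @return A `run_config` list.
#' @export
run_config <- function(query_path = NULL, db_path = NULL, species_path = NULL,
                       backend = c("internal", "blast", "fixture"),
                       fixture_path = NULL,
                       search = search_config(), engine = engine_params(),
                       weight_scheme = "log_rarity", weight_table = NULL,
                       out_dir = NULL, seed = 1L) {
  backend <- match.arg(backend)
  structure(list(query_path = query_path, db_path = db_path,
                 species_path = species_path, backend = backend,
                 fixture_path = fixture_path, search = search,
                 engine = engine, weight_scheme = weight_scheme,
                 weight_table = weight_table, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full remote-orthology pipeline
#'
#' Search, binarize, cluster, cut, verify, score, export: the end-to-end
#' workflow.  Stages run in order and any stage error aborts with the stage
#' name and cause.  With an `out_dir`, writes `results.tsv`, `network.sif`,
#' `network_attributes.tsv`, `audit.jsonl`, `merges.tsv`, `clusters.tsv`
#' and `manifest.json`; all outputs are deterministic functions of the
#' config (internal/fixture backends).
#'
#' @param config A [run_config()].
#' @param query Optional in-memory query record (overrides `query_path`).
#' @param db Optional in-memory sequence database (overrides `db_path`).
#' @return A result bundle: list with `results` (ranked table), `verified`,
#'   `network`, `scores`, `clusters`, `dendrogram`, `hits`, `engine`
#'   (full engine output) and `manifest`.
#' @export
run_pipeline <- function(config = run_config(), query = NULL, db = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  inputs <- stage("load", {
    smap <- if (!is.null(config$species_path)) {
      read_species_map(config$species_path)
    } else NULL
    if (is.null(db) && !is.null(config$db_path)) {
      db <- read_fasta(config$db_path,
                       species_from = if (is.null(smap)) "header" else "sidecar",
                       species_map = smap)
    }
    if (is.null(query) && !is.null(config$query_path)) {
      q <- read_fasta(config$query_path,
                      species_from = if (is.null(smap)) "header" else "sidecar",
                      species_map = smap)
      if (nrow(q) != 1L) stop("query FASTA must hold exactly one record")
      query <- as.list(q[1L, ])
    }
    if (is.null(query)) stop("no query given")
    if (is.data.frame(query)) query <- as.list(query[1L, ])
    if (is.null(db) && config$backend != "fixture") stop("no database given")
    list(query = query, db = db, smap = smap)
  })
  query <- inputs$query

  backend <- stage("search", {
    switch(config$backend,
      internal = internal_backend(list(main = inputs$db)),
      fixture = {
        if (is.null(config$fixture_path)) stop("fixture backend needs fixture_path")
        fixture_backend(config$fixture_path,
                        databases = if (is.null(inputs$db)) list() else
                          list(main = inputs$db))
      },
      blast = {
        if (!nzchar(Sys.which("blastp"))) stop("blastp not found; use backend=internal")
        blast_backend(c(main = config$db_path),
                      species_maps = if (is.null(inputs$smap)) list() else
                        list(main = inputs$smap))
      })
  })
  hits <- stage("search", backend_search(backend, query, "main", config$search))
  if (isTRUE(attr(hits, "oversized"))) {
    stop("pipeline stage 'search' failed: more than ", config$search$max_hits,
         " hits; the family is similar enough for phylogenetic methods",
         call. = FALSE)
  }

  weights <- stage("weights", residue_weights(config$weight_scheme,
                                              table = config$weight_table))
  profiles <- stage("binarize", alignment_profiles(hits, query))

  clustering <- stage("cluster", {
    if (nrow(profiles) < 2L) {
      list(dend = NULL,
           clusters = structure(list(
             assignments = setNames(rep(1L, nrow(profiles)),
                                    rownames(profiles)),
             clusters = list(rownames(profiles)),
             cut_height = Inf, a = NA_real_, b = NA_real_),
             class = "cluster_set"))
    } else {
      dend <- consensus_linkage(profiles, query, weights)
      list(dend = dend, clusters = cut_dendrogram(dend))
    }
  })

  engine <- stage("engine", run_engine(query, hits, clustering$clusters,
                                       backend, "main",
                                       config = config$search,
                                       params = config$engine))

  net <- stage("network", build_network(query, engine, hits, config$engine))
  scores <- stage("network", network_centrality(net))
  results <- stage("network", rank_results(net, scores))

  manifest <- list(
    query_id = query$id, backend = config$backend, seed = config$seed,
    package_version = as.character(utils::packageVersion("remort")),
    e_threshold = config$search$e_threshold,
    max_hits = config$search$max_hits,
    strict_e = config$engine$strict_e,
    reject_fraction = config$engine$reject_fraction,
    identity_select = config$engine$identity_select,
    weight_scheme = config$weight_scheme,
    counts = list(
      hits = nrow(hits),
      profiles = nrow(profiles),
      clusters = length(clustering$clusters$clusters),
      candidates_searched = length(engine$searches),
      verified = nrow(engine$verified)))

  bundle <- list(results = results, verified = engine$verified, network = net,
                 scores = scores, clusters = clustering$clusters,
                 dendrogram = clustering$dend, hits = hits, engine = engine,
                 manifest = manifest)

  if (!is.null(config$out_dir)) {
    stage("export", {
      dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
      p <- function(f) file.path(config$out_dir, f)
      utils::write.table(results, p("results.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
      export_sif(net, scores, p("network.sif"), p("network_attributes.tsv"))
      write_audit_jsonl(engine$audit, p("audit.jsonl"))
      if (!is.null(clustering$dend)) {
        write_clustering_tsv(clustering$dend, clustering$clusters,
                             p("merges.tsv"), p("clusters.tsv"))
      }
      jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
    })
  }
  bundle
}

#' Evaluate predictions against ground truth
#'
#' Standard confusion-matrix metrics for a synthetic-world run:
#' recall = TP/(TP+FN), precision = TP/(TP+FP),
#' accuracy = (TP+TN)/(TP+TN+FP+FN) and F1 = 2PR/(P+R).  True negatives
#' are the non-truth subjects of the initial hit table that were not
#' reported.  With no true positives, precision (and F1) are reported as 0
#' with `degenerate = TRUE`.
#'
#' @param predicted Character vector of reported ortholog ids (the query
#'   itself is ignored).
#' @param truth Character vector of true ortholog ids.
#' @param universe Character vector of all subjects considered (initial hit
#'   table subjects); used for the true-negative count.
#' @param query_id Optional query id to drop from all three sets.
#' @return List with `tp`, `fp`, `fn`, `tn`, `recall`, `precision`,
#'   `accuracy`, `f1`, `degenerate`.
#' @export
evaluate_predictions <- function(predicted, truth, universe = NULL,
                                 query_id = NULL) {
  if (length(truth) == 0L) stop("empty truth set")
  if (!is.null(query_id)) {
    predicted <- setdiff(predicted, query_id)
    truth <- setdiff(truth, query_id)
    universe <- setdiff(universe, query_id)
  }
  if (length(truth) == 0L) stop("empty truth set after removing the query")
  tp <- length(intersect(predicted, truth))
  fp <- length(setdiff(predicted, truth))
  fn <- length(setdiff(truth, predicted))
  tn <- if (is.null(universe)) NA_integer_ else
    length(setdiff(setdiff(universe, truth), predicted))
  recall <- tp / (tp + fn)
  degenerate <- (tp + fp) == 0L
  precision <- if (degenerate) 0 else tp / (tp + fp)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  accuracy <- if (is.na(tn)) NA_real_ else (tp + tn) / (tp + tn + fp + fn)
  list(tp = tp, fp = fp, fn = fn, tn = tn, recall = recall,
       precision = precision, accuracy = accuracy, f1 = f1,
       degenerate = degenerate)
}
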