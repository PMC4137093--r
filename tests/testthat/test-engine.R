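## Shared fixture world: query q (sp1) with candidates A, B, D in its
## cluster, E and F reachable only through multi-ortholog RBH support.
## Sequences are all identical 8-mers; the canned tables drive every
## decision, which keeps the expected outcomes hand-derivable.
engine_world <- function() {
  res <- "MKVLWAAK"
  ids <- c("q", "A", "B", "D", "E", "F", "X")
  sps <- c("sp1", "sp2", "sp3", "sp4", "sp5", "sp6", "sp2")
  db <- seq_db(ids, sps, rep(res, length(ids)))
  row <- function(sid, sp, e) {
    aln_row("MKV", "MKV", 1, 3, subject_id = sid, subject_species = sp,
            e_value = e)
  }
  tables <- list(
    "q::main" = rbind(row("A", "sp2", 1e-3), row("B", "sp3", 2e-3),
                      row("D", "sp4", 1e-2), row("E", "sp5", 50),
                      row("F", "sp6", 60)),
    "A::main" = rbind(row("q", "sp1", 1e-3), row("B", "sp3", 1e-3),
                      row("D", "sp4", 1e-2), row("E", "sp5", 50),
                      row("F", "sp6", 60)),
    "B::main" = rbind(row("q", "sp1", 1e-3), row("A", "sp2", 1e-3),
                      row("E", "sp5", 50), row("F", "sp6", 60)),
    "D::main" = rbind(row("q", "sp1", 1e-3), row("X", "sp2", 1e-3),
                      row("A", "sp2", 2e-3), row("E", "sp5", 50)),
    "E::main" = rbind(row("q", "sp1", 1e-3), row("A", "sp2", 2e-3),
                      row("B", "sp3", 2e-3)))
  clusters <- structure(list(
    assignments = c(q = 1L, A = 1L, B = 1L, D = 1L, E = 2L, F = 3L),
    clusters = list(c("q", "A", "B", "D"), "E", "F"),
    cut_height = 0.5, a = NA_real_, b = NA_real_), class = "cluster_set")
  query <- list(id = "q", species = "sp1", residues = res)
  backend <- fixture_backend(tables, databases = list(main = db))
  hits <- backend_search(backend, query, "main")
  list(query = query, db = db, backend = backend, hits = hits,
       clusters = clusters)
}

test_that("initial candidate selection applies the strict >80% identity rule and the query cluster", {
  w <- engine_world()
  hits <- w$hits
  hits$percent_identity <- c(12, 12, 12, 80.0, 80.1)[match(hits$subject_id,
                                                           c("A", "B", "D", "E", "F"))]
  cand <- initial_candidates(hits, w$clusters, "q")
  expect_true(all(c("A", "B", "D") %in% cand))  # query cluster, any identity
  expect_true("F" %in% cand)                    # 80.1% > 80
  expect_false("E" %in% cand)                   # 80.0% is not > 80
  expect_false("q" %in% cand)

  bad <- w$clusters
  bad$assignments <- bad$assignments[names(bad$assignments) != "q"]
  expect_error(initial_candidates(hits, bad, "q"), "query cluster not found")
})

test_that("candidate expansion adds cluster co-members and >2-supporter subjects", {
  w <- engine_world()
  out <- expand_candidates("A", w$clusters,
                           rbh_counts = c(E = 3L, F = 2L))
  expect_true(all(c("q", "A", "B", "D") %in% out))  # A's whole cluster
  expect_true("E" %in% out)    # found as RBH by 3 > 2 verified orthologs
  expect_false("F" %in% out)   # 2 is not more than 2
})

test_that("reciprocal reports rank verified orthologs within their species", {
  w <- engine_world()
  d_search <- backend_search(w$backend, list(id = "D", species = "sp4",
                                             residues = "MKVLWAAK"), "main")
  verified <- data.frame(id = c("q", "A", "B"),
                         species = c("sp1", "sp2", "sp3"))
  rep_df <- reciprocal_report(d_search, verified)
  expect_equal(rep_df$relation[rep_df$ortholog_id == "q"], "best")
  ## A is second in sp2 behind X: acceptable
  expect_equal(rep_df$rank[rep_df$ortholog_id == "A"], 2L)
  expect_equal(rep_df$relation[rep_df$ortholog_id == "A"], "acceptable")
  ## B absent from D's hits: rejected
  expect_equal(rep_df$relation[rep_df$ortholog_id == "B"], "rejected")
})

test_that("decision rules: strict RBH below 1e-5, rejection vote above it", {
  mk_report <- function(relations) {
    data.frame(ortholog_id = c("q", paste0("o", seq_along(relations)[-1])),
               species = paste0("sp", seq_along(relations)),
               rank = NA_integer_, relation = relations)
  }
  ## strict RBH: reciprocal top hit in the query species is not the query
  dec <- decide_candidate(mk_report("acceptable"), 1e-8, "q")
  expect_false(dec$verified)
  expect_equal(dec$rule, "strict_rbh")
  expect_true(decide_candidate(mk_report("best"), 1e-8, "q")$verified)
  ## the same non-best relation is tolerated at weak E-value
  expect_true(decide_candidate(mk_report("acceptable"), 1, "q")$verified)

  ## rejection vote boundary: 2 of 6 (33.3%) retained, 3 of 6 rejected
  rels6 <- c("best", "best", "best", "best", "rejected", "rejected")
  expect_true(decide_candidate(mk_report(rels6), 1, "q")$verified)
  rels6b <- c("best", "best", "best", "rejected", "rejected", "rejected")
  expect_false(decide_candidate(mk_report(rels6b), 1, "q")$verified)

  ## monotone in rejections: adding a rejector never flips rejected->verified
  for (k in 0:5) {
    rels <- c(rep("best", 6 - k), rep("rejected", k))
    ver_k <- decide_candidate(mk_report(rels), 1, "q")$verified
    if (k < 5) {
      rels2 <- c(rep("best", 5 - k), rep("rejected", k + 1))
      ver_k1 <- decide_candidate(mk_report(rels2), 1, "q")$verified
      expect_true(ver_k | !ver_k1)
    }
  }
  expect_error(decide_candidate(mk_report("best")[0, ], 1, "q"),
               "empty verified")
})

test_that("run_engine verifies the planted family, expands by RBH support, and audits", {
  w <- engine_world()
  res <- run_engine(w$query, w$hits, w$clusters, w$backend, "main")
  expect_setequal(res$verified$id, c("A", "B", "D", "E"))
  ## E was reached only through >2-supporter expansion
  exp_row <- res$audit[res$audit$rule == "expanded", ]
  expect_true("E" %in% exp_row$candidate)
  ## F had only 2 supporters: never selected
  expect_equal(unname(res$statuses[["F"]]), "pending")
  expect_false("F" %in% names(res$searches))
  ## every decision is logged with its rule
  expect_true(all(c("A", "B", "D", "E") %in%
                    res$audit$candidate[res$audit$rule == "rejection_vote"]))
})

test_that("orthologs supported by the query alone are dropped from the final output", {
  res8 <- "MKVLWAAK"
  db <- seq_db(c("q", "D"), c("sp1", "sp4"), rep(res8, 2))
  row <- function(sid, sp, e) aln_row("MKV", "MKV", 1, 3, subject_id = sid,
                                      subject_species = sp, e_value = e)
  backend <- fixture_backend(
    list("q::main" = row("D", "sp4", 1e-2),
         "D::main" = row("q", "sp1", 1e-2)),
    databases = list(main = db))
  clusters <- structure(list(assignments = c(q = 1L, D = 1L),
                             clusters = list(c("q", "D")),
                             cut_height = 0.5, a = NA_real_, b = NA_real_),
                        class = "cluster_set")
  query <- list(id = "q", species = "sp1", residues = res8)
  hits <- backend_search(backend, query, "main")
  res <- run_engine(query, hits, clusters, backend, "main")
  ## D is a clean reciprocal best hit of the query -- but of the query alone
  expect_equal(nrow(res$verified), 0L)
  expect_equal(unname(res$statuses[["D"]]), "excluded_query_only")
  expect_true("query_alone_exclusion" %in% res$audit$rule)
})

test_that("run_engine is deterministic, terminates on empty rounds, rejects oversized input", {
  w <- engine_world()
  r1 <- run_engine(w$query, w$hits, w$clusters, w$backend, "main")
  ## permuting the canned row order changes nothing: tables are re-sorted
  perm_tables <- lapply(w$backend$tables, function(t) t[rev(seq_len(nrow(t))), ])
  backend2 <- fixture_backend(perm_tables, databases = list(main = w$db))
  hits2 <- backend_search(backend2, w$query, "main")
  r2 <- run_engine(w$query, hits2, w$clusters, backend2, "main")
  expect_equal(r1$verified, r2$verified)
  expect_equal(r1$audit, r2$audit)

  ## no candidate passes round 1: engine stops with an empty verified set
  res8 <- "MKVLWAAK"
  db <- seq_db(c("q", "D"), c("sp1", "sp4"), rep(res8, 2))
  backend3 <- fixture_backend(
    list("q::main" = aln_row("MKV", "MKV", 1, 3, subject_id = "D",
                             subject_species = "sp4", e_value = 1),
         "D::main" = aln_row("MKV", "MKV", 1, 3, subject_id = "D",
                             subject_species = "sp4", e_value = 1e-4)),
    databases = list(main = db))
  clusters <- structure(list(assignments = c(q = 1L, D = 1L),
                             clusters = list(c("q", "D")),
                             cut_height = 0.5, a = NA_real_, b = NA_real_),
                        class = "cluster_set")
  query <- list(id = "q", species = "sp1", residues = res8)
  hits3 <- backend_search(backend3, query, "main")
  res3 <- run_engine(query, hits3, clusters, backend3, "main")
  expect_equal(nrow(res3$verified), 0L)
  expect_equal(unname(res3$statuses[["D"]]), "rejected")

  ## an oversized initial search aborts with the phylogenetics recommendation
  over <- hit_table(as.data.frame(w$hits), w$query, oversized = TRUE)
  expect_error(run_engine(w$query, over, w$clusters, w$backend, "main"),
               "phylogenetic")
})
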