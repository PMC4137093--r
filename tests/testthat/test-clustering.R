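test_that("residue weights are positive, rarity-monotone, and schemes validated", {
  w <- residue_weights("log_rarity")
  expect_length(w, 20)
  expect_true(all(w > 0))
  expect_gt(w[["W"]], w[["L"]])  # rarer residue weighs more
  expect_gt(w[["C"]], w[["A"]])
  expect_error(residue_weights("optima"), "weights table not found")

  tab <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(names(w), rep(2, 20), sep = "\t"), tab)
  wo <- residue_weights("optima", table = tab)
  expect_true(all(wo == 2))
})

test_that("profile similarity is a weighted Jaccard with the stated properties", {
  query <- list(id = "q", species = "s", residues = "WL")
  w <- c(setNames(rep(1, 20), names(residue_weights())))
  w[["W"]] <- 4.4; w[["L"]] <- 1.2
  ## hand-computed from the formula: shared W position over union {W, L}
  expect_equal(profile_similarity(c(1, 1), c(1, 0), query, w), 4.4 / 5.6)

  wlr <- residue_weights()
  q10 <- random_query(10, seed = 3)
  expect_equal(profile_similarity(rep(1, 10), rep(1, 10), q10, wlr), 1)
  expect_equal(profile_similarity(c(1,1,0,0,0,0,0,0,0,0),
                                  c(0,0,1,1,0,0,0,0,0,0), q10, wlr), 0)
  expect_equal(profile_similarity(rep(0, 10), rep(0, 10), q10, wlr), 0)
  expect_error(profile_similarity(c(1, 0), c(1, 0, 1), query, w), "mismatch")

  ## symmetry, bounds, identity-iff-equal-support; brute-force position loop
  for (seed in 1:10) {
    p <- random_profiles(2, 30, seed = seed, p_on = 0.4)
    qq <- random_query(30, seed = seed + 100)
    pw <- unname(vapply(strsplit(qq$residues, "")[[1]],
                        function(ch) wlr[[ch]], numeric(1)))
    s_ij <- profile_similarity(p[1, ], p[2, ], qq, wlr)
    s_ji <- profile_similarity(p[2, ], p[1, ], qq, wlr)
    expect_identical(s_ij, s_ji)
    expect_gte(s_ij, 0); expect_lte(s_ij, 1)
    num <- 0; den <- 0
    for (k in 1:30) {
      num <- num + pw[k] * p[1, k] * p[2, k]
      den <- den + pw[k] * max(p[1, k], p[2, k])
    }
    expect_equal(s_ij, unname(if (den == 0) 0 else num / den))
    expect_equal(s_ij == 1, all(p[1, ] == p[2, ]) && sum(p[1, ]) > 0)
  }
})

test_that("consensus linkage merges identical profiles at zero and disjoint groups at one", {
  query <- random_query(12, seed = 1)
  ident <- rbind(a = rep(c(1L, 0L), 6), b = rep(c(1L, 0L), 6),
                 c = rep(c(1L, 0L), 6))
  d <- consensus_linkage(ident, query)
  expect_equal(d$height, c(0, 0))

  two_groups <- rbind(a1 = c(rep(1L, 6), rep(0L, 6)),
                      a2 = c(rep(1L, 6), rep(0L, 6)),
                      b1 = c(rep(0L, 6), rep(1L, 6)),
                      b2 = c(rep(0L, 6), rep(1L, 6)))
  d2 <- consensus_linkage(two_groups, query)
  expect_equal(sort(d2$height), c(0, 0, 1))
  expect_error(consensus_linkage(ident[1, , drop = FALSE], query), "at least 2")
})

test_that("consensus linkage matches the brute-force agglomerator on random sets", {
  wlr <- residue_weights()
  for (seed in 0:9) {
    n <- 4 + (seed %% 7)
    prof <- random_profiles(n, 40, seed = seed)
    query <- random_query(40, seed = seed + 500)
    pw <- vapply(strsplit(query$residues, "")[[1]], function(ch) wlr[[ch]],
                 numeric(1))
    dend <- consensus_linkage(prof, query, wlr)
    oracle <- brute_consensus_linkage(prof, pw)
    expect_equal(dend$height, oracle$heights, tolerance = 1e-12)
    expect_equal(dend_merge_sets(dend), oracle$merge_sets)
  }
})

test_that("consensus vectors shrink monotonically up the tree", {
  for (seed in 0:4) {
    prof <- random_profiles(8, 40, seed = seed, p_on = 0.5)
    query <- random_query(40, seed = seed + 900)
    dend <- consensus_linkage(prof, query)
    child_cons <- function(code) {
      if (code < 0) prof[-code, ] else dend$consensus[code, ]
    }
    for (s in seq_len(nrow(dend$merge))) {
      parent <- dend$consensus[s, ]
      for (code in dend$merge[s, ]) {
        expect_true(all(parent <= child_cons(code)))
      }
    }
  }
})

test_that("consensus linkage reduces to average linkage on identical-member groups", {
  ## Within a group of identical profiles the consensus equals each member,
  ## so within-group merges and the first cross-group comparison coincide
  ## with classical average linkage (all pairwise distances are equal
  ## there).  The reduction is exact as long as merged consensus vectors do
  ## not shrink the comparison: two groups, or groups with mutually
  ## disjoint supports (where every cross distance is 1 either way).
  wlr <- residue_weights()
  avg_linkage <- function(prof, query) {
    n <- nrow(prof)
    dmat <- matrix(0, n, n, dimnames = list(rownames(prof), rownames(prof)))
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      dmat[i, j] <- dmat[j, i] <-
        1 - profile_similarity(prof[i, ], prof[j, ], query, wlr)
    }
    stats::hclust(stats::as.dist(dmat), method = "average")
  }

  ## two groups of identical profiles, arbitrary overlap
  query <- random_query(30, seed = 7)
  base <- random_profiles(2, 30, seed = 7, p_on = 0.4)
  prof2 <- rbind(a1 = base[1, ], a2 = base[1, ], a3 = base[1, ],
                 b1 = base[2, ], b2 = base[2, ])
  dend2 <- consensus_linkage(prof2, query)
  expect_equal(sort(dend2$height), sort(avg_linkage(prof2, query)$height),
               tolerance = 1e-12)

  ## three groups with disjoint supports (cross distances all 1)
  g <- function(lo) { v <- integer(30); v[lo:(lo + 7)] <- 1L; v }
  prof3 <- rbind(a1 = g(1), a2 = g(1), b1 = g(11), b2 = g(11),
                 c1 = g(21), c2 = g(21))
  dend3 <- consensus_linkage(prof3, query)
  expect_equal(sort(dend3$height), sort(avg_linkage(prof3, query)$height),
               tolerance = 1e-12)
})

test_that("cut_dendrogram splits flat-then-steep height profiles and honours degeneracies", {
  query <- random_query(60, seed = 21)
  ## two tight groups with disjoint supports plus one stray profile: within
  ## merges at ~0, cross merges near 1
  prof <- rbind(
    a1 = c(rep(1L, 20), rep(0L, 40)), a2 = c(rep(1L, 20), rep(0L, 40)),
    a3 = c(rep(1L, 20), rep(0L, 40)),
    b1 = c(rep(0L, 30), rep(1L, 20), rep(0L, 10)),
    b2 = c(rep(0L, 30), rep(1L, 20), rep(0L, 10)),
    b3 = c(rep(0L, 30), rep(1L, 20), rep(0L, 10)),
    s1 = c(rep(0L, 55), rep(1L, 5)))
  dend <- consensus_linkage(prof, query)
  cs <- cut_dendrogram(dend)
  expect_gte(length(cs$clusters), 2)
  ## every pair merged at height 0 shares a cluster
  expect_equal(cs$assignments[["a1"]], cs$assignments[["a2"]])
  expect_equal(cs$assignments[["a1"]], cs$assignments[["a3"]])
  expect_equal(cs$assignments[["b1"]], cs$assignments[["b2"]])
  ## partition covers all leaves, no empty cluster
  expect_setequal(unlist(cs$clusters), rownames(prof))
  expect_true(all(lengths(cs$clusters) > 0))

  ## all heights equal -> one cluster, no fit attempted
  flat <- structure(list(merge = rbind(c(-1L, -2L), c(-3L, 1L), c(-4L, 2L)),
                         height = c(0.5, 0.5, 0.5),
                         labels = c("a", "b", "c", "d"),
                         consensus = matrix(0L, 3, 4)),
                    class = "consensus_dendrogram")
  expect_length(cut_dendrogram(flat)$clusters, 1)

  ## fewer than 3 merges -> single cluster
  tiny <- structure(list(merge = rbind(c(-1L, -2L)), height = 0.4,
                         labels = c("a", "b"), consensus = matrix(0L, 1, 4)),
                    class = "consensus_dendrogram")
  expect_length(cut_dendrogram(tiny)$clusters, 1)
})

test_that("cut_dendrogram recovers planted clusters", {
  planted <- planted_three_clusters(seed = 7)
  query <- random_query(100, seed = 7)
  dend <- consensus_linkage(planted$profiles, query)
  cs <- cut_dendrogram(dend)
  expect_length(cs$clusters, 3)
  ## recovered partition equals the planted one
  expect_equal(length(unique(paste(planted$truth,
                                   cs$assignments[rownames(planted$profiles)]))),
               3)
})
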