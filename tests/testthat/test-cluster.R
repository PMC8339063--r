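test_that("identical trimmed sequences are grouped with membership conserved", {
  g <- group_identical(c("AAA", "AAA", "AAA", "CCC"))
  expect_length(g$seqs, 2L)
  expect_equal(lengths(g$members), c(AAA = 3L, CCC = 1L))
  expect_equal(group_identical(character())$seqs, character())
  set.seed(5)
  x <- sample(sprintf("S%04d", 1:9000), 10000, replace = TRUE)
  g2 <- group_identical(x)
  expect_equal(length(g2$seqs), length(unique(x)))
  expect_equal(sum(lengths(g2$members)), 10000L)
})

test_that("nearest-neighbor pre-clustering merges, retires and records", {
  # two points within threshold -> one pre-cluster of 2
  pts <- rbind(c(0, 0), c(1, 0))
  expect_equal(nn_precluster(pts, thr = 2), list(c(1L, 2L)))
  # isolated far point -> nothing
  pts <- rbind(c(0, 0), c(100, 0))
  expect_equal(nn_precluster(pts, thr = 2), list())
  # collinear chain reachable only through the centroid
  A <- c(0, 0); B <- c(2, 0); C <- c(3.2, 0)
  # d2(A,B) = 4 <= 5; d2(mid(A,B), C) = 4.84 <= 5; d2(A,C) = 10.24 > 5
  pre <- nn_precluster(rbind(A, B, C), thr = 5)
  expect_equal(pre, list(c(1L, 2L, 3L)))
  # single row or empty input
  expect_equal(nn_precluster(rbind(c(0, 0)), thr = 1), list())
})

test_that("far points retire only themselves, not their nearest neighbor", {
  # dense pair plus one far outlier whose NN is inside the pair
  pts <- rbind(c(100, 0), c(0, 0), c(1, 0))
  pre <- nn_precluster(pts, thr = 2)
  expect_equal(pre, list(c(2L, 3L)))
})

test_that("V-gene splitting follows graph components with fallback scoring", {
  sc <- vgene_scorer()
  expect_equal(sc("TRBV12-3*01", "TRBV12-3"), 4)
  expect_equal(sc("TRBV12-3", "TRBV9"), 0)
  # all same allele -> one group
  expect_equal(split_by_vgene(list("TRBV9", "TRBV9", "TRBV9"), sc, 3.7),
               list(1:3))
  # two incompatible families -> two groups
  out <- split_by_vgene(list("TRBV9", "TRBV9", "TRBV5-1", "TRBV5-1"), sc, 3.7)
  expect_equal(out, list(c(1L, 2L), c(3L, 4L)))
  # singleton components are dropped
  out <- split_by_vgene(list("TRBV9", "TRBV9", "TRBV5-1"), sc, 3.7)
  expect_equal(out, list(c(1L, 2L)))
  # table-driven chain a-b-c linked through b (depth-first transitivity)
  tab <- data.frame(allele_1 = c("a", "b", "a"), allele_2 = c("b", "c", "c"),
                    score = c(4, 4, 1))
  sct <- vgene_scorer(tab)
  expect_equal(split_by_vgene(list("a", "b", "c"), sct, 3.7), list(1:3))
  # unseen pair falls back with a message, once
  expect_message(sct("a", "zz"), "fallback")
})

test_that("k-mer index connects one-substitution neighbors and not others", {
  # 11-mer: 7 windows x 5 masked variants before dedup
  s <- "SLAPGATNEKL"
  keys <- character(0)
  for (p in 1:7) {
    w <- substr(s, p, p + 4)
    for (q in 1:5) { k <- w; substr(k, q, q) <- "?"; keys <- c(keys, k) }
  }
  expect_length(keys, 35L)
  # one substitution inside a shared window -> edge
  e <- build_kmer_graph(c("SLAPGATNEKL", "SLAPGATNEKI"))
  expect_equal(nrow(e), 1L)
  # hamming distance >= 2 in every window, no identical window -> no edge
  e2 <- build_kmer_graph(c("AAAAAAAAAA", "CCAACCAACC"))
  expect_equal(nrow(e2), 0L)
  expect_error(build_kmer_graph(c("AAAA", "CCCC")), ">= kmer_len")
})

test_that("capped ungapped score: identity 4, symmetry, worked example", {
  expect_equal(sw_score_ungapped("SLAPG", "SLAPG"), 4)
  expect_equal(sw_score_ungapped("SLAPG", "SLAPA"), 3.2)  # BLOSUM62(G,A) = 0
  set.seed(13)
  for (i in 1:20) {
    a <- random_trimmed(8); b <- random_trimmed(8)
    expect_equal(sw_score_ungapped(a, b), sw_score_ungapped(b, a))
    expect_lte(sw_score_ungapped(a, b), 4)
  }
  expect_error(sw_score_ungapped("SLAPG", "SLAP"), "equal length")
})

test_that("final clusters keep only score-qualified components of size >= 2", {
  seqs <- c("SLAPGATNEKL", "SLAPGATNEKI", "WWCCWWCCWWC")
  out <- finalize_clusters(seqs, list(1:3), thr_s = 3.3)
  expect_equal(out, list(c(1L, 2L)))
  out2 <- finalize_clusters(seqs, list(1:3), thr_s = 4.0)
  expect_equal(out2, list())
})

test_that("pipeline end-to-end: worked micro-examples", {
  # 20 copies of one CDR3 plus one unrelated sequence: no cluster
  rec <- tcr_records(c(rep("CASSLAPGATNEKLFF", 20), "CAWWCCWWCCWWCCF"),
                     v_gene = "TRBV9")
  cs <- suppressWarnings(cluster_repertoire(rec))
  expect_equal(nrow(cs$members), 0L)
  # conservative one-substitution pair, same V gene: one cluster of 2
  rec2 <- tcr_records(c("CASSLAPGATNEKLFF", "CASSLAPGATNDKLFF"),
                      v_gene = "TRBV9")
  cs2 <- cluster_repertoire(rec2)
  expect_equal(nrow(cs2$members), 2L)
  expect_equal(length(unique(cs2$members$cluster_id)), 1L)
  # same pair with incompatible V genes: no cluster
  rec3 <- tcr_records(c("CASSLAPGATNEKLFF", "CASSLAPGATNDKLFF"),
                      v_gene = c("TRBV9", "TRBV5-1"))
  cs3 <- suppressWarnings(cluster_repertoire(rec3))
  expect_equal(nrow(cs3$members), 0L)
  # ... but clusters with V filtering off
  cs4 <- cluster_repertoire(rec3, clustering_params(use_vgene = FALSE))
  expect_equal(nrow(cs4$members), 2L)
})

test_that("pipeline conserves membership, length homogeneity and determinism", {
  rep1 <- generate_repertoire(synthetic_spec(seed = 3L, n_background = 400L,
                                             n_groups = 8L))
  cs_a <- suppressMessages(cluster_repertoire(rep1))
  cs_b <- suppressMessages(cluster_repertoire(rep1))
  expect_identical(cs_a$members, cs_b$members)
  m <- cs_a$members
  # no record in more than one cluster
  expect_false(any(duplicated(m$record_id)))
  # all members of a cluster share trimmed length
  lens <- tapply(nchar(m$trimmed), m$cluster_id, function(x) length(unique(x)))
  expect_true(all(lens == 1L))
  # every cluster has at least two distinct trimmed sequences
  nseq <- tapply(m$trimmed, m$cluster_id, function(x) length(unique(x)))
  expect_true(all(nseq >= 2L))
  # soundness audit: qualifying edges connect every cluster
  aud <- audit_clusters(cs_a)
  expect_true(all(aud$connected))
  expect_true(all(aud$length_ok))
  expect_true(all(aud$min_edge_score >= cs_a$params$thr_s))
})

test_that("all records filtered out yields an empty set with a warning", {
  rec <- tcr_records("CASSF")
  expect_warning(cs <- suppressMessages(cluster_repertoire(rec)),
                 "filtered out")
  expect_equal(nrow(cs$members), 0L)
})
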