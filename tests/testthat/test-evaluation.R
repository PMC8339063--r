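test_that("cluster purity is the modal label fraction", {
  expect_equal(cluster_purity(c("A", "A", "A")), 1)
  expect_equal(cluster_purity(c("A", "A", "B", "B")), 0.5)
  expect_equal(cluster_purity(c("A", "A", "A", "B")), 0.75)
  expect_error(cluster_purity(c("A", NA)), "unlabeled")
  expect_error(cluster_purity(character()), "empty")
})

test_that("pure-cluster fraction and retention follow their definitions", {
  out <- pure_cluster_metrics(list(rep("A", 3), rep("B", 4),
                                   c("A", "A", "B", "C", "C")),
                              total_tcrs = 20)
  expect_equal(out$fraction, 2 / 3)
  expect_equal(out$retention, 7 / 20)
  both <- pure_cluster_metrics(list(rep("A", 2), rep("B", 2)), 4)
  expect_equal(both$fraction, 1)
  none <- pure_cluster_metrics(list(c("A", "B"), c("A", "B")), 4)
  expect_equal(none$fraction, 0)
  expect_equal(none$retention, 0)
  expect_true(is.na(pure_cluster_metrics(list(), 10)$fraction))
})

test_that("per-cluster NMI: perfect capture 1, random labels near 0", {
  # one cluster holds every TCR of label A; others hold B and C
  out <- mean_cluster_nmi(list(rep("A", 5), rep("B", 4), rep("C", 6)))
  expect_equal(out$per_cluster_nmi, rep(1, 3))
  expect_equal(out$mean_nmi, 1)
  # random labels over many clusters: mean NMI near zero
  set.seed(99)
  labs <- sample(LETTERS[1:10], 10000, replace = TRUE)
  clusters <- split(labs, rep(1:100, each = 100))
  out2 <- mean_cluster_nmi(unname(clusters))
  expect_lt(out2$mean_nmi, 0.02)
  # degenerate single label: pure -> 1
  out3 <- mean_cluster_nmi(list(c("A", "A"), c("A", "A", "A")))
  expect_equal(out3$per_cluster_nmi, c(1, 1))
  # partition NMI of a partition against itself is 1
  expect_equal(partition_nmi(c(1, 1, 2, 2, 3), c("x", "x", "y", "y", "z")), 1)
})

test_that("mean per-cluster NMI matches a direct contingency oracle", {
  # oracle: explicit 2x2 contingency of cluster membership vs carrying the
  # cluster's dominant label
  cl <- list(c("A", "A", "B"), c("B", "B"), c("A", "C"))
  out <- mean_cluster_nmi(cl)
  all_labs <- unlist(cl)
  n <- length(all_labs)
  ora <- function(idx, modal) {
    ind <- rep(FALSE, n); ind[idx] <- TRUE
    y <- all_labs == modal
    p <- table(ind, y) / n
    px <- rowSums(p); py <- colSums(p)
    mi <- sum(ifelse(p > 0, p * log(p / outer(px, py)), 0))
    hx <- -sum(px[px > 0] * log(px[px > 0]))
    hy <- -sum(py[py > 0] * log(py[py > 0]))
    2 * mi / (hx + hy)
  }
  expect_equal(out$per_cluster_nmi[1], ora(1:3, "A"))
  expect_equal(out$per_cluster_nmi[2], ora(4:5, "B"))
  expect_equal(out$per_cluster_nmi[3], ora(6:7, "A"))
})

test_that("spike-in counting identities hold on constructed cases", {
  # training family with background copies: background calls become FP
  train <- tcr_records(c("CASSLAPGATNEKLFF", "CASSLAPGATNDKLFF"),
                       v_gene = "TRBV9", label = "E1")
  test <- tcr_records("CASSLAPGATNEKLYF", v_gene = "TRBV9", label = "E1")
  # the first background record is byte-identical to a training CDR3
  backg <- tcr_records(c("CASSLAPGATNEKLFF", "CAWWCCWWCCWWCCF"),
                       v_gene = c("TRBV9", "TRBV2"))
  out <- spike_in_experiment(train, test, backg)
  expect_equal(unname(out$counts["FP"]), 1L)
  expect_equal(out$specificity, 0.5)
  expect_equal(out$sensitivity, 1)
  expect_equal(out$ppv, 0.5)
  expect_equal(out$counts[["TP"]] / (out$counts[["TP"]] + out$counts[["FN"]]),
               out$sensitivity)
  # training TCRs that cluster with nothing: sensitivity 0, specificity 1
  train2 <- tcr_records("CAFFKKFFKKFFKKF", v_gene = "TRBV19", label = "E9")
  out2 <- suppressWarnings(spike_in_experiment(train2, test, backg))
  expect_equal(out2$sensitivity, 0)
  expect_equal(out2$specificity, 1)
  # overlap between train and test is rejected
  expect_error(spike_in_experiment(train, train, backg), "overlap")
})

test_that("class fractions follow the sample-span filter and normalize", {
  # toy merged set: one good cluster with 3 COVID / 2 HC / 1 cancer
  # reference TCRs plus the query's own, one promiscuous cluster excluded
  mk <- function(cluster_id, sample_id, origin) {
    data.frame(cluster_id = cluster_id, cdr3 = "CASSLAPGATNEKLFF",
               trimmed = "SLAPGATNEKL", v_gene = "TRBV9",
               sample_id = sample_id, origin = origin, label = NA,
               record_id = paste0(origin, ":", seq_along(sample_id), ":",
                                  cluster_id),
               stringsAsFactors = FALSE)
  }
  members <- rbind(
    mk(1L, c("Q", "c1", "c2", "c3", "h1", "h2", "k1"),
       c("query", rep("reference", 6))),
    mk(2L, c("Q", sprintf("s%03d", 1:101)), c("query", rep("reference", 101))))
  cs <- structure(list(members = members, params = clustering_params(),
                       embedding_hash = "x", n_input = nrow(members),
                       n_excluded = 0L), class = "tcr_cluster_set")
  cls <- c(c1 = "COVID", c2 = "COVID", c3 = "COVID", h1 = "HC", h2 = "HC",
           k1 = "cancer")
  fr <- class_fractions(cs, "Q", cls)
  expect_equal(sum(fr), 1)
  expect_equal(unname(fr["COVID"]), 0.5)
  expect_equal(unname(fr["HC"]), 1 / 3, tolerance = 1e-12)
  expect_equal(unname(fr["cancer"]), 1 / 6, tolerance = 1e-12)
  # all co-clustered reference TCRs from one class
  one <- structure(list(members = mk(1L, c("Q", "h1", "h2"),
                                     c("query", "reference", "reference")),
                        params = clustering_params(), embedding_hash = "x",
                        n_input = 3L, n_excluded = 0L),
                   class = "tcr_cluster_set")
  fr2 <- class_fractions(one, "Q", cls, classes = c("COVID", "HC", "cancer"))
  expect_equal(unname(fr2), c(0, 1, 0))
  # no co-clustered reference TCRs: all-missing with a message
  lone <- structure(list(members = mk(1L, c("Q", "Q"), c("query", "query")),
                         params = clustering_params(), embedding_hash = "x",
                         n_input = 2L, n_excluded = 0L),
                    class = "tcr_cluster_set")
  expect_message(fr3 <- class_fractions(lone, "Q", cls), "no co-clustered")
  expect_true(all(is.na(fr3)))
})

test_that("difference-of-fractions scores and ROC behave canonically", {
  expect_equal(pairwise_disease_score(0.4, 0.4), 0)
  expect_equal(pairwise_disease_score(0.7, 0.1), 0.6)
  expect_true(is.na(pairwise_disease_score(NA_real_, 0.1)))
  labs <- rep(c(0, 1), each = 50)
  out <- roc_with_bootstrap(labs, labs, n_boot = 100L, seed = 1L)
  expect_equal(unname(out["auc"]), 1)
  set.seed(2)
  sc <- rnorm(1000)
  labs2 <- rep(c(0, 1), 500)
  mid <- roc_with_bootstrap(sc, labs2, n_boot = 200L, seed = 1L)
  expect_lt(abs(mid["auc"] - 0.5), 0.06)
  expect_true(mid["ci_low"] <= mid["auc"] && mid["auc"] <= mid["ci_high"])
  rev <- roc_with_bootstrap(-sc, labs2, n_boot = 200L, seed = 1L)
  expect_equal(unname(rev["auc"]), 1 - unname(mid["auc"]))
  expect_error(roc_with_bootstrap(sc, rep(1, 1000)), "two classes")
})

test_that("sample sharing matrix floors weak correlations and zero rows", {
  mk <- function(cluster_id, sample_id) {
    data.frame(cluster_id = cluster_id, cdr3 = "X", trimmed = "X",
               v_gene = NA, sample_id = sample_id, origin = "input",
               label = NA, record_id = paste0(cluster_id, ":", sample_id,
                                              ":", seq_along(sample_id)),
               stringsAsFactors = FALSE)
  }
  members <- rbind(mk(1L, c("A", "A", "B")), mk(2L, c("A", "B", "B")),
                   mk(3L, c("C", "C")))
  cs <- structure(list(members = members, params = clustering_params(),
                       embedding_hash = "x", n_input = 8L, n_excluded = 0L),
                  class = "tcr_cluster_set")
  S <- sample_sharing_matrix(cs)
  expect_true(isSymmetric(S))
  # A and B share clusters 1 and 2 identically
  expect_gt(S["A", "B"], 0.4)
  expect_error(sample_sharing_matrix(
    structure(list(members = mk(1L, c("A", "A"))), class = "tcr_cluster_set")),
    "2 samples")
})
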