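#' Purity of a single cluster
#'
#' Fraction of members carrying the most common label (e.g. the dominant
#' epitope). A pure cluster has purity 1.
#'
#' @param labels Character vector of member labels (no `NA`).
#' @return Numeric in `[0, 1]`.
#' @export
cluster_purity <- function(labels) {
  if (length(labels) == 0L) stop("empty cluster")
  if (anyNA(labels)) stop("unlabeled cluster member")
  max(table(labels)) / length(labels)
}

#' Pure-cluster fraction and retention
#'
#' `fraction` is the number of pure clusters (purity exactly 1) divided by
#' the number of clusters; `retention` is the number of TCRs inside pure
#' clusters divided by `total_tcrs`, the size of the full labeled test set
#' (conventionally after dropping epitopes represented by a single TCR).
#'
#' @param cluster_labels List of per-cluster label vectors.
#' @param total_tcrs Denominator for retention.
#' @return List with `fraction` (NA if there are no clusters), `retention`,
#'   and `per_cluster_purity`.
#' @export
pure_cluster_metrics <- function(cluster_labels, total_tcrs) {
  if (length(cluster_labels) == 0L) {
    return(list(fraction = NA_real_, retention = 0, per_cluster_purity = numeric(0)))
  }
  pur <- vapply(cluster_labels, cluster_purity, numeric(1))
  pure <- pur == 1
  list(fraction = mean(pure),
       retention = sum(lengths(cluster_labels)[pure]) / total_tcrs,
       per_cluster_purity = pur)
}

.entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Per-cluster normalized mutual information, averaged
#'
#' For each cluster, computes the NMI (twice the mutual information divided
#' by the sum of entropies) between two binary variables over the set of all
#' clustered TCRs: membership in that cluster, and carrying the cluster's
#' dominant (modal) label. A cluster holding exactly the TCRs of one antigen
#' and nothing else therefore scores 1 — the two indicators are then
#' deterministic functions of each other. The arithmetic mean over clusters
#' is returned. If the label indicator is degenerate (every clustered TCR
#' carries the modal label), the per-cluster NMI is defined as 1 for a pure
#' cluster and 0 otherwise.
#'
#' @param cluster_labels List of per-cluster label vectors (over clustered
#'   TCRs only).
#' @return List with `mean_nmi` and `per_cluster_nmi`.
#' @export
mean_cluster_nmi <- function(cluster_labels) {
  if (length(cluster_labels) == 0L) {
    return(list(mean_nmi = NA_real_, per_cluster_nmi = numeric(0)))
  }
  all_labels <- unlist(cluster_labels, use.names = FALSE)
  n <- length(all_labels)
  sizes <- lengths(cluster_labels)
  starts <- cumsum(c(0L, sizes[-length(sizes)]))
  nmi <- vapply(seq_along(cluster_labels), function(ci) {
    ind <- rep(FALSE, n)
    ind[starts[ci] + seq_len(sizes[ci])] <- TRUE
    modal <- names(which.max(table(cluster_labels[[ci]])))
    y <- all_labels == modal
    hy <- .entropy(table(y) / n)
    if (hy == 0) {
      return(as.numeric(cluster_purity(cluster_labels[[ci]]) == 1))
    }
    hx <- .entropy(table(ind) / n)
    joint <- table(ind, y) / n
    mi <- 0
    px <- rowSums(joint); py <- colSums(joint)
    for (i in seq_len(nrow(joint))) for (j in seq_len(ncol(joint))) {
      if (joint[i, j] > 0) {
        mi <- mi + joint[i, j] * log(joint[i, j] / (px[i] * py[j]))
      }
    }
    if (hx + hy == 0) return(1)
    2 * mi / (hx + hy)
  }, numeric(1))
  list(mean_nmi = mean(nmi), per_cluster_nmi = nmi)
}

#' Global-partition normalized mutual information
#'
#' NMI between the full cluster assignment and the labels over clustered
#' TCRs; provided alongside the per-cluster average for comparison.
#'
#' @param assignment Cluster id per clustered TCR.
#' @param labels Label per clustered TCR.
#' @return Numeric in `[0, 1]`.
#' @export
partition_nmi <- function(assignment, labels) {
  n <- length(labels)
  stopifnot(length(assignment) == n, n > 0)
  joint <- table(assignment, labels) / n
  px <- rowSums(joint); py <- colSums(joint)
  hx <- .entropy(px); hy <- .entropy(py)
  mi <- 0
  for (i in seq_len(nrow(joint))) for (j in seq_len(ncol(joint))) {
    if (joint[i, j] > 0) mi <- mi + joint[i, j] * log(joint[i, j] / (px[i] * py[j]))
  }
  if (hx + hy == 0) return(1)
  unname(2 * mi / (hx + hy))
}

#' In silico spike-in retrieval experiment
#'
#' Emulates mixing held-out antigen-specific TCRs into a background
#' repertoire: the union of training, testing and background records is
#' clustered; every cluster containing at least one training TCR marks its
#' non-training members as positive calls. True positives are positive calls
#' from the test set, false positives are positive calls from the
#' background. Sensitivity is TP over the test-set size and specificity TN
#' over the background size.
#'
#' @param train,test Labeled record `data.frame`s; they must not overlap (by
#'   CDR3 + V gene).
#' @param background Unlabeled background records.
#' @param params,emb,vgene_table Passed to [cluster_repertoire()].
#' @return List with `sensitivity`, `specificity`, `ppv`, `counts` (named TP
#'   / FP / TN / FN), and the underlying `cluster_set`.
#' @export
spike_in_experiment <- function(train, test, background,
                                params = clustering_params(),
                                emb = default_embedding(),
                                vgene_table = NULL) {
  key <- function(df) paste(df$cdr3, df$v_gene)
  if (length(intersect(key(train), key(test)))) {
    stop("train and test sets overlap")
  }
  train$origin <- "train"; test$origin <- "test"; background$origin <- "background"
  common <- Reduce(intersect, list(names(train), names(test), names(background)))
  pool <- rbind(test[, common, drop = FALSE],
                background[, common, drop = FALSE],
                train[, common, drop = FALSE])
  pool$record_id <- paste0(pool$origin, ":", seq_len(nrow(pool)))
  cs <- cluster_repertoire(pool, params, emb, vgene_table, origin = "mixed")
  m <- cs$members
  pos_ids <- character(0)
  for (cid in unique(m$cluster_id)) {
    blk <- m[m$cluster_id == cid, , drop = FALSE]
    if (any(blk$origin == "train")) {
      pos_ids <- c(pos_ids, blk$record_id[blk$origin != "train"])
    }
  }
  tp <- sum(startsWith(pos_ids, "test:"))
  fp <- sum(startsWith(pos_ids, "background:"))
  fn <- nrow(test) - tp
  tn <- nrow(background) - fp
  list(sensitivity = tp / nrow(test),
       specificity = tn / nrow(background),
       ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       counts = c(TP = tp, FP = fp, TN = tn, FN = fn),
       cluster_set = cs)
}

#' Reference class fractions for one query sample
#'
#' Given a merged cluster set from [query_reference()], drops clusters
#' spanning more than `max_samples` distinct samples (promiscuous
#' "small-world" clusters), then, over the remaining clusters that contain
#' TCRs of the query sample, counts the co-clustered reference TCRs by class
#' and normalizes to fractions (summing to 1 when any reference TCR is
#' co-clustered).
#'
#' @param merged `tcr_cluster_set` whose members carry `origin`
#'   (`reference` / `query`) and `sample_id`.
#' @param query_sample Sample id of the query sample.
#' @param ref_class_of Named character vector: reference `sample_id` ->
#'   class.
#' @param max_samples Sample-span cutoff (default 100).
#' @param classes Optional class universe for zero-filled output.
#' @return Named numeric vector of fractions (all `NA` when no reference TCR
#'   is co-clustered).
#' @export
class_fractions <- function(merged, query_sample, ref_class_of,
                            max_samples = 100L, classes = NULL) {
  m <- merged$members
  span <- tapply(m$sample_id, m$cluster_id, function(s) length(unique(s)))
  keep_ids <- as.integer(names(span)[span <= max_samples])
  m <- m[m$cluster_id %in% keep_ids, , drop = FALSE]
  with_query <- unique(m$cluster_id[m$origin == "query" &
                                      m$sample_id == query_sample])
  co <- m[m$cluster_id %in% with_query & m$origin == "reference", , drop = FALSE]
  cls <- ref_class_of[co$sample_id]
  if (is.null(classes)) classes <- sort(unique(ref_class_of))
  if (nrow(co) == 0L || all(is.na(cls))) {
    message("no co-clustered reference TCRs for sample ", query_sample)
    return(stats::setNames(rep(NA_real_, length(classes)), classes))
  }
  counts <- table(factor(cls, levels = classes))
  stats::setNames(as.vector(counts) / sum(counts), classes)
}

#' Difference-of-fractions disease score
#'
#' Pairwise single-number predictor for separating two disease classes:
#' the difference of their class fractions.
#'
#' @param fraction_a,fraction_b Class fractions.
#' @return `fraction_a - fraction_b` (`NA` if either is missing).
#' @export
pairwise_disease_score <- function(fraction_a, fraction_b) {
  fraction_a - fraction_b
}

#' ROC AUC with stratified bootstrap confidence interval
#'
#' Empirical AUC via pROC, with a `n_boot`-replicate stratified bootstrap
#' 95% confidence interval. The score direction is fixed (higher score ->
#' second level), so reversing the sign of the scores maps AUC to 1 - AUC.
#'
#' @param scores Numeric predictor.
#' @param labels Binary labels (two distinct values; the higher/second factor
#'   level is the positive class).
#' @param n_boot Bootstrap replicates (default 2000).
#' @param seed Integer seed for the bootstrap.
#' @return Named numeric vector `c(auc, ci_low, ci_high)`.
#' @export
roc_with_bootstrap <- function(scores, labels, n_boot = 2000L, seed = 1L) {
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) != 2L) {
    stop("labels must contain exactly two classes")
  }
  set.seed(seed)
  r <- pROC::roc(response = labels, predictor = scores, quiet = TRUE,
                 direction = "<", levels = levels(droplevels(labels)))
  ci <- suppressWarnings(pROC::ci.auc(r, method = "bootstrap", boot.n = n_boot,
                                      boot.stratified = TRUE))
  c(auc = as.numeric(pROC::auc(r)), ci_low = unname(ci[1L]),
    ci_high = unname(ci[3L]))
}

#' Sample-wise sharing correlation matrix
#'
#' Counts, for every pair of samples, the number of co-clustered TCR pairs
#' (one member from each sample in the same cluster), computes the Spearman
#' correlation matrix of the per-sample count profiles, and zeroes entries
#' at or below `corr_floor`. Undefined correlations (constant profiles) are
#' set to 0.
#'
#' @param cs `tcr_cluster_set`.
#' @param corr_floor Correlation floor (entries `<=` it become 0; default
#'   0.4).
#' @return Symmetric numeric matrix over sample ids.
#' @export
sample_sharing_matrix <- function(cs, corr_floor = 0.4) {
  m <- cs$members
  samples <- sort(unique(m$sample_id))
  if (length(samples) < 2L) stop("need at least 2 samples")
  C <- matrix(0, length(samples), length(samples),
              dimnames = list(samples, samples))
  for (cid in unique(m$cluster_id)) {
    tab <- table(factor(m$sample_id[m$cluster_id == cid], levels = samples))
    v <- as.vector(tab)
    contrib <- outer(v, v)
    diag(contrib) <- v * (v - 1) / 2
    C <- C + contrib
  }
  S <- suppressWarnings(stats::cor(C, method = "spearman"))
  S[is.na(S)] <- 0
  S[S <= corr_floor] <- 0
  S
}
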