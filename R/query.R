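#' Build a clustered reference bundle
#'
#' Clusters a reference repertoire once and caches everything needed to
#' query new samples against it without re-clustering: the validated
#' records, the cluster set, the encoded coordinates of every unique trimmed
#' sequence, and the parameters used.
#'
#' @inheritParams cluster_repertoire
#' @return Object of class `reference_bundle`: list with `records` (validated
#'   reference records with `trimmed` and `record_id`), `clusters`
#'   (`tcr_cluster_set`), `encoded` (per trimmed length, coordinate matrix of
#'   unique sequences), `params`, `embedding_hash`.
#' @export
make_reference_bundle <- function(records, params = clustering_params(),
                                  emb = default_embedding(),
                                  vgene_table = NULL) {
  cs <- cluster_repertoire(records, params, emb, vgene_table,
                           origin = "reference")
  records$record_id <- paste0("reference:", seq_len(nrow(records)))
  trimmed <- trim_cdr3(records$cdr3, params$clip_n, params$clip_c)
  keep <- !is.na(trimmed)
  rec <- records[keep, , drop = FALSE]
  rec$trimmed <- trimmed[keep]
  rec$origin <- "reference"
  transform <- if (params$encoder == "g6") build_transform(6L, emb$dim) else NULL
  useqs <- unique(rec$trimmed)
  encoded <- lapply(split(useqs, nchar(useqs)), function(s) {
    encode_matrix(s, emb, transform)
  })
  structure(list(records = rec, clusters = cs, encoded = encoded,
                 params = params, embedding_hash = embedding_hash(emb)),
            class = "reference_bundle")
}

#' @export
print.reference_bundle <- function(x, ...) {
  cat("Reference bundle:", nrow(x$records), "record(s),",
      length(unique(x$clusters$members$cluster_id)), "cluster(s)\n")
  invisible(x)
}

#' Select reference candidates near a set of query sequences
#'
#' For every query sequence, finds all reference sequences of the same
#' trimmed length within squared distance `thr`, and returns the query
#' records plus the matching reference records (each reference record at
#' most once). This is the candidate set on which the query clustering runs;
#' it can optionally be materialized to a TSV file.
#'
#' @param ref `reference_bundle`.
#' @param query_records Query record `data.frame`.
#' @param thr Squared-distance cutoff (defaults to the bundle's `thr`).
#' @param emb Embedding; must hash-match the bundle.
#' @param tmp_file Optional path: write the candidate records as TSV
#'   (`tmp_query.txt` by convention), or `NULL` to keep in memory only.
#' @return Candidate record `data.frame` with `origin` in
#'   `{"query", "reference"}` and `trimmed` filled in.
#' @export
select_candidates <- function(ref, query_records, thr = ref$params$thr,
                              emb = default_embedding(), tmp_file = NULL) {
  if (!identical(embedding_hash(emb), ref$embedding_hash)) {
    stop("embedding hash mismatch between reference bundle and query; ",
         "coordinates are not comparable")
  }
  p <- ref$params
  query_records$record_id <- paste0("query:", seq_len(nrow(query_records)))
  trimmed <- trim_cdr3(query_records$cdr3, p$clip_n, p$clip_c)
  keep <- !is.na(trimmed)
  q <- query_records[keep, , drop = FALSE]
  q$trimmed <- trimmed[keep]
  q$origin <- "query"
  transform <- if (p$encoder == "g6") build_transform(6L, emb$dim) else NULL

  hit_seqs <- character(0)
  for (L in intersect(unique(nchar(q$trimmed)), names(ref$encoded))) {
    Rm <- ref$encoded[[as.character(L)]]
    qs <- unique(q$trimmed[nchar(q$trimmed) == as.integer(L)])
    Qm <- encode_matrix(qs, emb, transform)
    d2 <- outer(rowSums(Qm^2), rowSums(Rm^2), "+") - 2 * tcrossprod(Qm, Rm)
    near <- which(colSums(d2 <= thr) > 0L)
    hit_seqs <- c(hit_seqs, rownames(Rm)[near])
  }
  refsel <- ref$records[ref$records$trimmed %in% hit_seqs, , drop = FALSE]
  common <- intersect(names(q), names(refsel))
  cand <- rbind(q[, common, drop = FALSE], refsel[, common, drop = FALSE])
  rownames(cand) <- NULL
  if (!is.null(tmp_file)) {
    utils::write.table(cand, tmp_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  cand
}

#' Query new TCR samples against a clustered reference
#'
#' Runs the full clustering pipeline on the candidate set from
#' [select_candidates()] and merges the result into the reference clusters:
#' any candidate cluster sharing at least one reference sequence with an
#' existing reference cluster is unioned with it (a candidate cluster
#' bridging several reference clusters unions all of them; such multi-way
#' merges are listed in the `merges` element). Candidate clusters with no
#' reference-cluster overlap are appended as new clusters. Reference clusters
#' never lose members.
#'
#' @param ref `reference_bundle`.
#' @param query_records Query record `data.frame`.
#' @param params Parameters for the candidate clustering (defaults to the
#'   bundle's).
#' @param emb Embedding; must hash-match the bundle.
#' @param vgene_table Optional V-gene score table.
#' @param tmp_file Optional candidate-file path passed to
#'   [select_candidates()].
#' @return `tcr_cluster_set` over reference and query records (member
#'   `origin` distinguishes them), with an extra element `merges`: a list of
#'   integer vectors of reference cluster ids unioned by one query cluster.
#' @export
query_reference <- function(ref, query_records, params = ref$params,
                            emb = default_embedding(), vgene_table = NULL,
                            tmp_file = NULL) {
  if (nrow(query_records) == 0L) {
    out <- ref$clusters
    out$merges <- list()
    return(out)
  }
  cand <- select_candidates(ref, query_records, params$thr, emb, tmp_file)
  ccs <- cluster_repertoire(cand, params, emb, vgene_table, origin = "candidate")
  # candidate records already carry origin/record_id; cluster_repertoire kept them
  cm <- ccs$members
  refm <- ref$clusters$members
  ref_ids <- sort(unique(refm$cluster_id))

  # map: reference record_id -> reference cluster id
  ref_cl_of <- stats::setNames(refm$cluster_id, refm$record_id)

  merged <- list()
  merges <- list()
  new_clusters <- list()
  absorbed <- stats::setNames(vector("list", length(ref_ids)),
                              as.character(ref_ids))
  for (cid in unique(cm$cluster_id)) {
    block <- cm[cm$cluster_id == cid, , drop = FALSE]
    overlap <- unique(ref_cl_of[block$record_id[block$origin == "reference"]])
    overlap <- overlap[!is.na(overlap)]
    if (length(overlap) == 0L) {
      new_clusters[[length(new_clusters) + 1L]] <- block
    } else {
      if (length(overlap) > 1L) {
        merges[[length(merges) + 1L]] <- sort(as.integer(overlap))
      }
      key <- as.character(min(overlap))
      absorbed[[key]] <- rbind(absorbed[[key]], block)
      # a bridge to several reference clusters redirects the others
      for (o in setdiff(as.character(overlap), key)) {
        absorbed[[key]] <- rbind(absorbed[[key]], absorbed[[o]])
        absorbed[[o]] <- NULL
        ref_ids_redirect <- refm$cluster_id == as.integer(o)
        refm$cluster_id[ref_ids_redirect] <- as.integer(key)
      }
    }
  }

  out_rows <- list()
  next_id <- 0L
  for (cid in sort(unique(refm$cluster_id))) {
    next_id <- next_id + 1L
    block <- refm[refm$cluster_id == cid, , drop = FALSE]
    extra <- absorbed[[as.character(cid)]]
    if (!is.null(extra)) {
      extra <- extra[!extra$record_id %in% block$record_id, , drop = FALSE]
      common <- intersect(names(block), names(extra))
      block <- rbind(block[, common, drop = FALSE], extra[, common, drop = FALSE])
    }
    block$cluster_id <- next_id
    out_rows[[length(out_rows) + 1L]] <- block
  }
  for (block in new_clusters) {
    next_id <- next_id + 1L
    block$cluster_id <- next_id
    out_rows[[length(out_rows) + 1L]] <- block
  }
  members <- do.call(rbind, out_rows)
  out <- .new_cluster_set(members, params, emb,
                          nrow(ref$records) + nrow(query_records),
                          0L)
  out$merges <- merges
  out
}
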