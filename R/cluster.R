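#' Group identical trimmed CDR3 sequences
#'
#' Clustering operates on unique trimmed sequences; identical CDR3s (possibly
#' observed in many samples) are collapsed into one group up front and
#' expanded back into the final clusters afterwards.
#'
#' @param trimmed Character vector of trimmed CDR3s (no `NA`).
#' @return List with `seqs` (unique trimmed sequences, in first-appearance
#'   order) and `members` (list of integer vectors: for each unique sequence,
#'   the indices of the input records carrying it).
#' @export
group_identical <- function(trimmed) {
  if (length(trimmed) == 0L) {
    return(list(seqs = character(), members = list()))
  }
  f <- factor(trimmed, levels = unique(trimmed))
  list(seqs = levels(f),
       members = split(seq_along(trimmed), f))
}

#' Nearest-neighbor centroid pre-clustering
#'
#' Iteratively agglomerates encoded points: in each pass every active point
#' is visited in index order together with its nearest neighbor (computed at
#' the start of the pass). If their squared distance is within `thr` the two
#' points are replaced by the centroid of their constituent sequences (the
#' size-weighted mean, which for two original points is simply the midpoint)
#' carrying the union of their members; otherwise the visited point is
#' retired, and any retired point
#' that is a centroid of two or more sequences is recorded as a pre-cluster.
#' A point is retired only on the evidence of its own nearest-neighbor
#' distance: a far-away point must not knock out its (possibly
#' well-connected) nearest neighbor. Points whose snapshot neighbor was
#' already consumed earlier in the pass stay active for the next pass. Iteration stops when no active points
#' remain, a full pass removes none, or `max_iter` passes have run; active
#' centroids of two or more sequences surviving at that point are also
#' recorded. Single-sequence retirees yield nothing.
#'
#' @param points Numeric matrix, one encoded sequence per row (all the same
#'   trimmed length).
#' @param thr Squared-distance merge cutoff.
#' @param max_iter Maximum number of passes.
#' @return List of integer vectors: each pre-cluster as row indices into
#'   `points`.
#' @export
nn_precluster <- function(points, thr, max_iter = 20L) {
  n <- nrow(points)
  if (is.null(n) || n == 0L) return(list())
  if (n == 1L) return(list())
  coords <- points
  members <- as.list(seq_len(n))
  preclusters <- list()
  record <- function(m) {
    if (length(m) >= 2L) preclusters[[length(preclusters) + 1L]] <<- sort(m)
  }
  for (pass in seq_len(max_iter)) {
    m <- nrow(coords)
    if (m <= 1L) break
    sq <- rowSums(coords^2)
    D <- outer(sq, sq, "+") - 2 * tcrossprod(coords)
    D[D < 0] <- 0
    diag(D) <- Inf
    nn <- apply(D, 1L, which.min)  # ties: lowest index
    alive <- rep(TRUE, m)
    new_coords <- list()
    new_members <- list()
    removed <- 0L
    for (i in seq_len(m)) {
      if (!alive[i]) next
      j <- nn[i]
      if (!alive[j]) next  # neighbor consumed this pass; revisit next pass
      if (D[i, j] <= thr) {
        ni <- length(members[[i]]); nj <- length(members[[j]])
        new_coords[[length(new_coords) + 1L]] <-
          (ni * coords[i, ] + nj * coords[j, ]) / (ni + nj)
        new_members[[length(new_members) + 1L]] <- c(members[[i]], members[[j]])
        alive[i] <- FALSE; alive[j] <- FALSE
        removed <- removed + 2L
      } else {
        alive[i] <- FALSE
        record(members[[i]])
        removed <- removed + 1L
      }
    }
    keep <- which(alive)
    coords <- rbind(coords[keep, , drop = FALSE],
                    do.call(rbind, c(new_coords, list(NULL))))
    members <- c(members[keep], new_members)
    if (removed == 0L) break
    if (nrow(coords) == 0L) break
  }
  for (m in members) record(m)
  preclusters
}

#' V-gene compatibility scorer
#'
#' Returns a function scoring two sets of TRBV allele names. If a score table
#' is supplied (symmetric long format, see [read_vgene_table()]), the score
#' of two sets is the maximum table score over cross pairs; pairs absent from
#' the table fall back to the default rule, with one message per unseen pair.
#' The fallback rule scores 4 when the gene names match after stripping the
#' allele suffix (`"TRBV12-3*01"` -> `"TRBV12-3"`) and 0 otherwise, so the
#' default cutoff `thr_v = 3.7` requires an exact gene match.
#'
#' @param table Optional `data.frame` with columns `allele_1`, `allele_2`,
#'   `score`.
#' @return Function `(a, b) -> numeric` over character vectors of alleles.
#' @export
vgene_scorer <- function(table = NULL) {
  strip <- function(x) sub("\\*.*$", "", x)
  fallback <- function(a, b) ifelse(strip(a) == strip(b), 4, 0)
  if (is.null(table)) {
    return(function(a, b) {
      max(outer(a, b, fallback))
    })
  }
  env <- new.env(parent = emptyenv())
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
  for (i in seq_len(nrow(table))) {
    assign(key(table$allele_1[i], table$allele_2[i]),
           as.numeric(table$score[i]), envir = env)
  }
  warned <- new.env(parent = emptyenv())
  function(a, b) {
    best <- -Inf
    for (x in a) for (y in b) {
      k <- key(x, y)
      v <- if (exists(k, envir = env, inherits = FALSE)) {
        get(k, envir = env)
      } else {
        if (!exists(k, envir = warned, inherits = FALSE)) {
          assign(k, TRUE, envir = warned)
          message("V-gene pair not in score table, using fallback: ", k)
        }
        fallback(x, y)
      }
      if (v > best) best <- v
    }
    best
  }
}

#' Split a pre-cluster by V-gene compatibility
#'
#' Builds a graph over the member unique-sequence groups with an edge
#' wherever the V-gene score of two groups reaches `thr_v`, and returns its
#' connected components. Each component becomes a smaller pre-cluster;
#' singleton components are dropped (they can never form a cluster of two
#' distinct sequences).
#'
#' @param vsets List of character vectors: the V genes observed for each
#'   member group.
#' @param scorer Function from [vgene_scorer()].
#' @param thr_v Score cutoff.
#' @return List of integer vectors (indices into `vsets`), each of length
#'   >= 2.
#' @export
split_by_vgene <- function(vsets, scorer = vgene_scorer(), thr_v = 3.7) {
  n <- length(vsets)
  if (n == 0L) return(list())
  if (n == 1L) return(list())
  from <- integer(0); to <- integer(0)
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      if (scorer(vsets[[i]], vsets[[j]]) >= thr_v) {
        from <- c(from, i); to <- c(to, j)
      }
    }
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(from)) g <- igraph::add_edges(g, rbind(from, to))
  comp <- igraph::components(g)$membership
  out <- split(seq_len(n), comp)
  out <- out[lengths(out) >= 2L]
  names(out) <- NULL
  lapply(out, as.integer)
}

#' Candidate-pair graph from a one-mismatch k-mer index
#'
#' Indexes every consecutive k-mer of every sequence under `kmer_len` masked
#' variants (each position wildcarded in turn), so two sequences sharing a
#' k-mer window with at most one substitution share at least one index key.
#' An edge joins any two sequences sharing a key; the edge list is
#' deduplicated.
#'
#' @param seqs Character vector of equal-length trimmed sequences (length >=
#'   `kmer_len` each).
#' @param kmer_len k-mer size (default 5).
#' @return Integer matrix with columns `i`, `j` (`i < j`), one row per edge.
#' @export
build_kmer_graph <- function(seqs, kmer_len = 5L) {
  n <- length(seqs)
  empty <- matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("i", "j")))
  if (n < 2L) return(empty)
  if (any(nchar(seqs) < kmer_len)) stop("all sequences must be >= kmer_len")
  index <- new.env(parent = emptyenv(), size = 4L * n)
  for (s in seq_len(n)) {
    L <- nchar(seqs[s])
    for (p in seq_len(L - kmer_len + 1L)) {
      w <- substr(seqs[s], p, p + kmer_len - 1L)
      for (q in seq_len(kmer_len)) {
        key <- w
        substr(key, q, q) <- "?"
        prev <- index[[key]]
        index[[key]] <- c(prev, s)
      }
    }
  }
  pairs <- list()
  for (key in ls(index)) {
    hits <- unique(index[[key]])
    if (length(hits) >= 2L) {
      cmb <- utils::combn(sort(hits), 2L)
      pairs[[length(pairs) + 1L]] <- t(cmb)
    }
  }
  if (length(pairs) == 0L) return(empty)
  out <- unique(do.call(rbind, pairs))
  colnames(out) <- c("i", "j")
  out
}

.capped_b62 <- function() {
  if (is.null(.tcriso_env$capped_b62)) {
    .tcriso_env$capped_b62 <- pmin(blosum62(), 4L)
  }
  .tcriso_env$capped_b62
}

#' Normalized ungapped alignment score
#'
#' Positional BLOSUM62 score of two equal-length sequences, with each
#' positional score capped at 4, divided by the length. The cap makes a
#' self-comparison score exactly 4.0 (mirroring the zero diagonal of the
#' dissimilarity matrix `4 - BLOSUM62`), so scores live in `(-Inf, 4]` and
#' the cluster cutoff `thr_s` is a per-residue similarity requirement.
#' Gapped alignment is not supported; unequal lengths are an error.
#'
#' @param s1,s2 Equal-length amino-acid strings.
#' @return Numeric score, at most 4.
#' @export
#' @examples
#' sw_score_ungapped("SLAPG", "SLAPG")  # 4
#' sw_score_ungapped("SLAPG", "SLAPA")  # 3.2
sw_score_ungapped <- function(s1, s2) {
  if (nchar(s1) != nchar(s2)) {
    stop("sequences must have equal length (no gap support)")
  }
  a <- strsplit(s1, "", fixed = TRUE)[[1]]
  b <- strsplit(s2, "", fixed = TRUE)[[1]]
  bm <- .capped_b62()
  sum(bm[cbind(a, b)]) / nchar(s1)
}

# vectorized scorer over an index-pair matrix (equal-length seqs)
.score_pairs <- function(seqs, pairs) {
  if (nrow(pairs) == 0L) return(numeric(0))
  L <- nchar(seqs[1L])
  bm <- .capped_b62()
  chars <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                  nrow = length(seqs), byrow = TRUE)
  sc <- numeric(nrow(pairs))
  for (p in seq_len(L)) {
    sc <- sc + bm[cbind(chars[pairs[, 1L], p], chars[pairs[, 2L], p])]
  }
  sc / L
}

#' Final cluster formation by alignment-filtered components
#'
#' Within each candidate group, scores every k-mer-graph edge with
#' [sw_score_ungapped()], drops edges below `thr_s`, and reports the
#' connected components with at least two distinct sequences as final
#' clusters.
#'
#' @param seqs Character vector of all unique trimmed sequences (one length).
#' @param groups List of integer vectors (indices into `seqs`), e.g. from
#'   [split_by_vgene()].
#' @param thr_s Normalized score cutoff.
#' @param kmer_len k-mer size for the candidate index.
#' @return List of integer vectors: final clusters as indices into `seqs`.
#' @export
finalize_clusters <- function(seqs, groups, thr_s, kmer_len = 5L) {
  clusters <- list()
  for (grp in groups) {
    if (length(grp) < 2L) next
    sub <- seqs[grp]
    edges <- build_kmer_graph(sub, kmer_len)
    if (nrow(edges) == 0L) next
    sc <- .score_pairs(sub, edges)
    keep <- edges[sc >= thr_s, , drop = FALSE]
    if (nrow(keep) == 0L) next
    g <- igraph::make_empty_graph(length(grp), directed = FALSE)
    g <- igraph::add_edges(g, t(keep))
    comp <- igraph::components(g)$membership
    for (cc in split(seq_along(grp), comp)) {
      if (length(cc) >= 2L) {
        clusters[[length(clusters) + 1L]] <- grp[cc]
      }
    }
  }
  clusters
}

#' Cluster a TCR repertoire
#'
#' Full pipeline: trim and validate CDR3s, collapse identical trimmed
#' sequences, encode each trimmed length separately and pre-cluster by
#' nearest-neighbor centroid agglomeration, split pre-clusters by V-gene
#' compatibility, then filter k-mer candidate edges by ungapped alignment
#' score and emit connected components of at least two distinct sequences as
#' final clusters. Identical-sequence groups are expanded back to all their
#' records in the output. The run is deterministic given the input order,
#' parameters and embedding.
#'
#' @param records Record `data.frame` (see [tcr_records()] or
#'   [read_repertoire()]).
#' @param params [clustering_params()].
#' @param emb `aa_embedding` (default the shipped cache).
#' @param vgene_table Optional V-gene score table (`data.frame` with columns
#'   `allele_1`, `allele_2`, `score`).
#' @param origin Origin tag stored with every member (default `"input"`).
#' @return Object of class `tcr_cluster_set`: list with `members` (data.frame
#'   of clustered records: `cluster_id`, `cdr3`, `trimmed`, `v_gene`,
#'   `sample_id`, `origin`, `label`, `record_id`), `params`,
#'   `embedding_hash`, `n_input`, `n_excluded`.
#' @export
cluster_repertoire <- function(records, params = clustering_params(),
                               emb = default_embedding(),
                               vgene_table = NULL, origin = "input") {
  stopifnot(is.data.frame(records))
  if (!"record_id" %in% names(records)) {
    records$record_id <- if (nrow(records)) {
      paste0(origin, ":", seq_len(nrow(records)))
    } else character(0)
  }
  if (!"origin" %in% names(records)) records$origin <- origin
  if (!"label" %in% names(records)) records$label <- NA_character_
  if (!"sample_id" %in% names(records)) records$sample_id <- "S1"
  if (!"v_gene" %in% names(records)) records$v_gene <- NA_character_

  trimmed <- trim_cdr3(records$cdr3, params$clip_n, params$clip_c)
  excl <- attr(trimmed, "exclusions")
  keep <- !is.na(trimmed)
  if (sum(excl) > 0L) {
    message("excluded ", excl[["nonstandard"]], " record(s) with non-standard ",
            "residues and ", excl[["too_short"]], " too short after trimming")
  }
  rec <- records[keep, , drop = FALSE]
  rec$trimmed <- trimmed[keep]
  if (nrow(rec) == 0L) {
    warning("all records were filtered out; returning empty cluster set")
    return(.new_cluster_set(rec[0, ], params, emb, nrow(records), sum(excl)))
  }

  grp <- group_identical(rec$trimmed)
  useqs <- grp$seqs
  umembers <- grp$members
  uvsets <- lapply(umembers, function(ix) {
    v <- unique(rec$v_gene[ix])
    v[!is.na(v)]
  })
  scorer <- vgene_scorer(vgene_table)

  transform <- if (params$encoder == "g6") build_transform(6L, emb$dim) else NULL
  lens <- nchar(useqs)
  cluster_members <- list()
  for (L in sort(unique(lens))) {
    idx <- which(lens == L)
    if (length(idx) < 2L) next
    X <- encode_matrix(useqs[idx], emb, transform)
    pre <- nn_precluster(X, params$thr, params$max_iter)
    if (length(pre) == 0L) next
    for (pc in pre) {
      gidx <- idx[pc]  # global unique-seq indices in this pre-cluster
      groups <- if (params$use_vgene) {
        vs <- uvsets[gidx]
        # groups with no V information cannot be matched; treat missing V as
        # its own pseudo-allele so they only cluster together
        vs <- lapply(vs, function(v) if (length(v) == 0L) "V?" else v)
        lapply(split_by_vgene(vs, scorer, params$thr_v),
               function(cc) gidx[cc])
      } else {
        list(gidx)
      }
      fin <- finalize_clusters(useqs, groups, params$thr_s, params$kmer_len)
      cluster_members <- c(cluster_members, fin)
    }
  }

  if (length(cluster_members) == 0L) {
    return(.new_cluster_set(rec[0, ], params, emb, nrow(records), sum(excl)))
  }
  rows <- list()
  for (ci in seq_along(cluster_members)) {
    recidx <- unlist(umembers[cluster_members[[ci]]], use.names = FALSE)
    block <- rec[recidx, , drop = FALSE]
    block$cluster_id <- ci
    rows[[ci]] <- block
  }
  out <- do.call(rbind, rows)
  .new_cluster_set(out, params, emb, nrow(records), sum(excl))
}

.new_cluster_set <- function(members, params, emb, n_input, n_excluded) {
  cols <- c("cluster_id", "cdr3", "trimmed", "v_gene", "sample_id",
            "origin", "label", "record_id")
  for (cn in setdiff(cols, names(members))) {
    members[[cn]] <- if (cn == "cluster_id") integer(0) else character(0)
  }
  members <- members[, cols, drop = FALSE]
  rownames(members) <- NULL
  structure(list(members = members, params = params,
                 embedding_hash = embedding_hash(emb),
                 n_input = n_input, n_excluded = n_excluded),
            class = "tcr_cluster_set")
}

#' @export
print.tcr_cluster_set <- function(x, ...) {
  nc <- length(unique(x$members$cluster_id))
  cat("TCR cluster set:", nc, "cluster(s),", nrow(x$members),
      "clustered record(s) of", x$n_input, "input record(s)\n")
  invisible(x)
}

#' Post-hoc soundness audit of a cluster set
#'
#' Re-examines every final cluster: all members must share one trimmed
#' length; the graph over its unique sequences restricted to k-mer candidate
#' edges with alignment score >= `thr_s` and V-gene score >= `thr_v` must
#' connect the whole cluster.
#'
#' @param cs `tcr_cluster_set`.
#' @param vgene_table Optional V-gene score table used at clustering time.
#' @return `data.frame` with one row per cluster: `cluster_id`, `n_records`,
#'   `n_seqs`, `length_ok`, `min_edge_score` (minimum retained-edge score),
#'   `connected`.
#' @export
audit_clusters <- function(cs, vgene_table = NULL) {
  p <- cs$params
  scorer <- vgene_scorer(vgene_table)
  res <- lapply(split(cs$members, cs$members$cluster_id), function(m) {
    seqs <- unique(m$trimmed)
    length_ok <- length(unique(nchar(seqs))) == 1L
    edges <- build_kmer_graph(seqs, p$kmer_len)
    ok_edge <- rep(FALSE, nrow(edges))
    if (nrow(edges)) {
      sc <- .score_pairs(seqs, edges)
      vs <- lapply(seqs, function(s) {
        v <- unique(m$v_gene[m$trimmed == s]); v <- v[!is.na(v)]
        if (length(v) == 0L) "V?" else v
      })
      vok <- vapply(seq_len(nrow(edges)), function(e) {
        scorer(vs[[edges[e, 1L]]], vs[[edges[e, 2L]]]) >= p$thr_v
      }, logical(1))
      ok_edge <- sc >= p$thr_s & (vok | !p$use_vgene)
    }
    keep <- edges[ok_edge, , drop = FALSE]
    connected <- FALSE
    min_score <- NA_real_
    if (nrow(keep)) {
      g <- igraph::make_empty_graph(length(seqs), directed = FALSE)
      g <- igraph::add_edges(g, t(keep))
      connected <- igraph::components(g)$no == 1L
      min_score <- min(.score_pairs(seqs, keep))
    }
    data.frame(cluster_id = m$cluster_id[1L], n_records = nrow(m),
               n_seqs = length(seqs), length_ok = length_ok,
               min_edge_score = min_score,
               connected = connected)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
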