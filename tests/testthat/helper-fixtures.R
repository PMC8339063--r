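# Shared fixtures: embedding/transform are loaded once; the brute-force
# pair oracle is independent of the clustering path (direct all-pairs
# scoring over record pairs).

emb16 <- default_embedding()
g6 <- build_transform(6L, emb16$dim)

random_trimmed <- function(len, rng = NULL) {
  paste(sample(AA_ALPHABET20, len, replace = TRUE), collapse = "")
}

# all record pairs with equal trimmed length, matching V gene (allele
# suffix stripped) and capped normalized score >= thr_s
brute_force_pairs <- function(records, params) {
  trimmed <- trim_cdr3(records$cdr3, params$clip_n, params$clip_c)
  keep <- which(!is.na(trimmed))
  bm <- pmin(blosum62(), 4)
  out <- list()
  for (L in unique(nchar(trimmed[keep]))) {
    ix <- keep[nchar(trimmed[keep]) == L]
    s <- trimmed[ix]
    v <- sub("\\*.*$", "", records$v_gene[ix])
    n <- length(ix)
    if (n < 2) next
    chars <- matrix(unlist(strsplit(s, "", fixed = TRUE)), nrow = n, byrow = TRUE)
    S <- matrix(0, n, n)
    for (p in seq_len(L)) S <- S + matrix(bm[chars[, p], chars[, p]], n, n)
    S <- S / L
    hit <- which(S >= params$thr_s & outer(v, v, "==") & upper.tri(S),
                 arr.ind = TRUE)
    if (nrow(hit)) out[[as.character(L)]] <- cbind(ix[hit[, 1]], ix[hit[, 2]])
  }
  do.call(rbind, c(out, list(matrix(integer(0), ncol = 2))))
}

# fraction of oracle pairs co-clustered in a cluster set (records indexed
# by "r:<i>" record ids)
pair_recall <- function(records, cs, params) {
  bp <- brute_force_pairs(records, params)
  if (nrow(bp) == 0) return(NA_real_)
  m <- cs$members
  clu <- rep(NA_integer_, nrow(records))
  clu[as.integer(sub(".*:", "", m$record_id))] <- m$cluster_id
  mean(!is.na(clu[bp[, 1]]) & !is.na(clu[bp[, 2]]) &
         clu[bp[, 1]] == clu[bp[, 2]])
}
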