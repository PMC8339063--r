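#' Embed the 20 amino acids into Euclidean space by non-metric MDS
#'
#' Finds 20 coordinate vectors `beta_i` in `R^dim` whose pairwise Euclidean
#' distances approximate the dissimilarities `M[i, j] = 4 - BLOSUM62[i, j]`.
#' Non-metric (Kruskal) MDS is used so that dimensions above the classical
#' limit of 13 can be explored; the default `dim = 16` maximizes downstream
#' concordance between encoded-sequence distances and alignment scores.
#'
#' Because a non-metric solution is only defined up to a global scale, the
#' converged configuration is rescaled by the least-squares factor
#' `sum(d * M) / sum(d^2)` so that fitted distances live on the scale of `M`
#' itself. This makes `||beta_i - beta_j|| ~ M[i, j]` an approximate equality,
#' which is what gives the squared-distance clustering cutoff (`thr`, default
#' 10) its meaning.
#'
#' The optimization is fully deterministic given `(M, dim, seed)`: the initial
#' configuration is the classical-MDS solution padded with seeded
#' small-variance Gaussian columns.
#'
#' @param M Dissimilarity matrix from [build_dissimilarity_matrix()].
#' @param dim Embedding dimension `r` (default 16; a warning is issued outside
#'   13..19).
#' @param seed Integer seed for the initialization padding.
#' @param maxit Maximum isoMDS iterations.
#' @param stress_fail Stress (percent) above which the fit is treated as
#'   non-converged and an error is raised.
#' @return Object of class `aa_embedding`: list with `vectors` (20 x dim
#'   matrix, rows named by residue), `dim`, `seed`, `stress` (final Kruskal
#'   stress, percent), `scale` (calibration factor applied).
#' @export
embed_amino_acids <- function(M = build_dissimilarity_matrix(), dim = 16L,
                              seed = 42L, maxit = 200L, stress_fail = 20) {
  dim <- as.integer(dim)
  if (dim < 2L || dim > 19L) {
    if (dim < 2L) stop("embedding dimension must be >= 2")
  }
  if (dim < 13L || dim > 19L) {
    warning("embedding dimension ", dim, " is outside the recommended 13..19")
  }
  Mm <- unclass(as.matrix(M))
  d <- stats::as.dist(Mm)
  n <- nrow(Mm)
  ncl <- mds_embedding_rank(Mm)
  init <- suppressWarnings(stats::cmdscale(d, k = min(dim, ncl)))
  if (ncol(init) < dim) {
    set.seed(seed)
    init <- cbind(init, matrix(stats::rnorm(n * (dim - ncol(init)), sd = 1e-2),
                               n, dim - ncol(init)))
  } else {
    init <- init[, seq_len(dim), drop = FALSE]
  }
  fit <- MASS::isoMDS(d, y = init, k = dim, maxit = maxit, trace = FALSE)
  if (fit$stress > stress_fail) {
    stop("non-metric MDS did not converge after ", maxit,
         " iterations; final stress = ", format(fit$stress))
  }
  pts <- fit$points
  dd <- stats::dist(pts)
  sc <- sum(dd * d) / sum(dd^2)
  pts <- pts * sc
  rownames(pts) <- rownames(Mm)
  structure(list(vectors = pts, dim = dim, seed = as.integer(seed),
                 stress = fit$stress, scale = sc),
            class = "aa_embedding")
}

#' @export
print.aa_embedding <- function(x, ...) {
  cat("Amino-acid embedding: 20 x", x$dim, "(seed", x$seed,
      ", stress", format(x$stress, digits = 4), ")\n")
  invisible(x)
}

#' Write / read an embedding cache file
#'
#' The cache is a plain-text table: a header comment recording the dimension,
#' seed, stress and provenance, then one row per amino acid (letter followed
#' by `dim` tab-separated reals at full double precision). A cache written and
#' re-read reproduces the embedding bit-identically, which pins down all
#' downstream coordinates across machines.
#'
#' @param emb `aa_embedding` object.
#' @param path File path.
#' @return `write_embedding` returns `path` invisibly; `read_embedding`
#'   returns an `aa_embedding`.
#' @export
write_embedding <- function(emb, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# aa_embedding dim=%d seed=%d stress=%s scale=%s matrix=4-BLOSUM62",
                     emb$dim, emb$seed,
                     format(emb$stress, digits = 17),
                     format(emb$scale, digits = 17)), con)
  for (i in seq_len(nrow(emb$vectors))) {
    writeLines(paste(c(rownames(emb$vectors)[i],
                       format(emb$vectors[i, ], digits = 17)),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_embedding
#' @export
read_embedding <- function(path) {
  lines <- readLines(path)
  hdr <- lines[[1]]
  getf <- function(key) {
    m <- regmatches(hdr, regexpr(paste0(key, "=[^ ]+"), hdr))
    sub(paste0(key, "="), "", m)
  }
  body <- lines[-1]
  parts <- strsplit(body, "\t", fixed = TRUE)
  letters <- vapply(parts, `[`, character(1), 1)
  vecs <- t(vapply(parts, function(p) as.numeric(p[-1]),
                   numeric(length(parts[[1]]) - 1)))
  rownames(vecs) <- letters
  vecs <- vecs[AA_ALPHABET20, , drop = FALSE]
  structure(list(vectors = vecs, dim = ncol(vecs),
                 seed = as.integer(getf("seed")),
                 stress = as.numeric(getf("stress")),
                 scale = as.numeric(getf("scale"))),
            class = "aa_embedding")
}

.tcriso_env <- new.env(parent = emptyenv())

#' Default shipped amino-acid embedding
#'
#' Loads (and memoizes) the embedding cache shipped with the package
#' (`4 - BLOSUM62`, `dim = 16`, `seed = 42`). All clustering defaults assume
#' this embedding; results are reproducible across machines because the
#' coordinates are read from the cached text file rather than refit.
#'
#' @return `aa_embedding` object.
#' @export
default_embedding <- function() {
  if (is.null(.tcriso_env$default_embedding)) {
    path <- system.file("extdata", "aa_embedding_blosum62_r16.tsv",
                        package = "tcriso", mustWork = TRUE)
    .tcriso_env$default_embedding <- read_embedding(path)
  }
  .tcriso_env$default_embedding
}

#' Content fingerprint of an embedding
#'
#' 32-bit polynomial rolling hash of the formatted coordinate values, used
#' to refuse comparisons between coordinates produced under different
#' embeddings (e.g. reference vs query in [query_reference()]).
#'
#' @param emb `aa_embedding`.
#' @return Character scalar, 8 hex digits.
#' @export
embedding_hash <- function(emb) {
  txt <- paste(format(emb$vectors, digits = 12), collapse = ",")
  bytes <- utf8ToInt(txt)
  h <- 5381
  for (b in bytes) {
    h <- (h * 33 + b) %% 4294967296  # exact in doubles: 33 * 2^32 < 2^53
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
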