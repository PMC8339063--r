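#' Build the amino-acid dissimilarity matrix from a substitution table
#'
#' Converts a similarity (log-odds) substitution matrix `s` into the
#' dissimilarity matrix used for embedding: `M[i, j] = 4 - s[i, j]` for
#' `i != j`, with the diagonal set exactly to 0. With BLOSUM62 this yields a
#' symmetric non-negative matrix that violates the triangle inequality for
#' some residue triples, so no exact Euclidean realization exists; the
#' multidimensional-scaling embedding in [embed_amino_acids()] is therefore
#' only approximately isometric.
#'
#' @param substitution_table 20x20 symmetric integer similarity matrix with
#'   dimnames covering the 20 standard amino acids (default [blosum62()]).
#' @return Object of class `aa_dissimilarity`: a 20x20 numeric matrix in
#'   [AA_ALPHABET20] order with attribute `alphabet`.
#' @export
#' @examples
#' M <- build_dissimilarity_matrix()
#' M["A", "R"]  # 4 - (-1) = 5
build_dissimilarity_matrix <- function(substitution_table = blosum62()) {
  s <- substitution_table
  if (is.null(dimnames(s)) || is.null(rownames(s))) {
    stop("substitution table must carry amino-acid dimnames")
  }
  extra <- setdiff(rownames(s), AA_ALPHABET20)
  if (length(extra) > 0 && !all(AA_ALPHABET20 %in% rownames(s))) {
    stop("non-standard alphabet symbol in substitution table: ",
         paste(extra, collapse = ", "))
  }
  missing <- setdiff(AA_ALPHABET20, rownames(s))
  if (length(missing) > 0) {
    stop("substitution table missing amino acid(s): ",
         paste(missing, collapse = ", "))
  }
  s <- s[AA_ALPHABET20, AA_ALPHABET20]
  if (!isTRUE(all.equal(s, t(s), check.attributes = FALSE))) {
    stop("substitution table must be symmetric")
  }
  M <- 4 - s
  diag(M) <- 0
  storage.mode(M) <- "double"
  structure(M, alphabet = AA_ALPHABET20, class = c("aa_dissimilarity", "matrix"))
}

#' Embedding dimension implied by classical multidimensional scaling
#'
#' Counts the positive eigenvalues of the classical-MDS Gram matrix
#' `B = -1/2 * J (M o M) J` with `J = I - (1/n) 11'` (`o` is the elementwise
#' product, i.e. squared dissimilarities are double-centered). For a matrix of
#' exact Euclidean distances this equals the dimension of the generating
#' configuration; for a non-Euclidean dissimilarity such as 4 - BLOSUM62 it is
#' the maximal dimension classical MDS can use (13).
#'
#' @param M Dissimilarity matrix from [build_dissimilarity_matrix()], or any
#'   symmetric dissimilarity matrix.
#' @param tol Relative eigenvalue tolerance: eigenvalues greater than
#'   `tol * max(eigenvalue)` are counted. Default `1e-8`.
#' @return Integer count of positive eigenvalues.
#' @export
mds_embedding_rank <- function(M, tol = 1e-8) {
  M <- unclass(as.matrix(M))
  n <- nrow(M)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (M * M) %*% J
  ev <- eigen((B + t(B)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (max(ev) <= 0) return(0L)
  sum(ev > tol * max(ev))
}
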