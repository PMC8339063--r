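#' Trim CDR3 sequences to their hypervariable core
#'
#' Removes `clip_n` leading and `clip_c` trailing residues from each CDR3.
#' The clipped flanks (the conserved C..F junction anatomy) carry little
#' antigen information; the defaults (3 and 2) leave, for a length-16 CDR3,
#' an 11-residue core. Sequences containing characters outside the 20
#' standard amino-acid letters, or whose trimmed core is shorter than
#' `min_len` (the k-mer indexing step needs at least 5 residues), are
#' returned as `NA` and tallied in the `exclusions` attribute.
#'
#' @param seq Character vector of CDR3 amino-acid sequences.
#' @param clip_n Residues clipped from the N-terminus (default 3).
#' @param clip_c Residues clipped from the C-terminus (default 2).
#' @param min_len Minimum acceptable trimmed length (default 5).
#' @return Character vector of trimmed sequences (`NA` where excluded), with
#'   attribute `exclusions`: named integer vector
#'   `c(nonstandard = ..., too_short = ...)`.
#' @export
#' @examples
#' trim_cdr3("CASSLAPGATNEKLFF")  # "SLAPGATNEKL"
trim_cdr3 <- function(seq, clip_n = 3L, clip_c = 2L, min_len = 5L) {
  if (clip_n < 0L || clip_c < 0L) stop("clip values must be >= 0")
  ok_chars <- grepl(paste0("^[", paste(AA_ALPHABET20, collapse = ""), "]+$"),
                    seq)
  ok_chars[is.na(seq)] <- FALSE
  n <- nchar(seq)
  out <- rep(NA_character_, length(seq))
  long_enough <- !is.na(seq) & (n - clip_n - clip_c) >= min_len
  sel <- ok_chars & long_enough
  out[sel] <- substr(seq[sel], clip_n + 1L, n[sel] - clip_c)
  structure(out,
            exclusions = c(nonstandard = sum(!ok_chars),
                           too_short = sum(ok_chars & !long_enough)))
}

.residue_rows <- function(trimmed, emb) {
  idx <- match(strsplit(trimmed, "", fixed = TRUE)[[1]],
               rownames(emb$vectors))
  if (anyNA(idx)) {
    bad <- strsplit(trimmed, "", fixed = TRUE)[[1]][is.na(idx)]
    stop("residue absent from embedding: ", paste(unique(bad), collapse = ", "))
  }
  idx
}

#' Encode a trimmed CDR3 as Euclidean coordinates (cyclic-group encoder)
#'
#' Applies the operator product over residues: the coordinate vector is
#' `x = sum_{l=1..k} Omega^l * lift(beta[residue at position k-l+1])`, i.e.
#' the C-terminal residue receives `Omega^1` and operators accumulate
#' right-to-left. Because `Omega^l` on a lifted vector just relocates its
#' `r`-block, the sum is evaluated by block accumulation with positions
#' assigned to blocks by `l mod order`; this is exactly the matrix product
#' definition (asserted in the test-suite) but O(k r) instead of O(k (or)^2).
#'
#' @param trimmed Trimmed CDR3 string (see [trim_cdr3()]).
#' @param emb `aa_embedding` (default [default_embedding()]).
#' @param transform `cyclic_transform` from [build_transform()]; its
#'   `base_dim` must equal `emb$dim`.
#' @return Numeric vector of length `transform$order * emb$dim` (96 at
#'   defaults).
#' @export
encode_cdr3 <- function(trimmed, emb = default_embedding(),
                        transform = build_transform(6L, emb$dim)) {
  if (transform$base_dim != emb$dim) {
    stop("transform base_dim (", transform$base_dim,
         ") does not match embedding dim (", emb$dim, ")")
  }
  k <- nchar(trimmed)
  if (is.na(trimmed) || k < 1L) stop("trimmed sequence must have length >= 1")
  r <- emb$dim
  ord <- transform$order
  x <- numeric(ord * r)
  rows <- .residue_rows(trimmed, emb)
  for (l in seq_len(k)) {
    b <- transform$block_cycle[((l - 1L) %% ord) + 1L]
    cols <- (b - 1L) * r + seq_len(r)
    x[cols] <- x[cols] + emb$vectors[rows[k - l + 1L], ]
  }
  x
}

#' Encode a trimmed CDR3 by stacking embedding vectors
#'
#' The naive isometric representation: concatenate the residue embedding
#' vectors in sequence order, `x = (beta_1', beta_2', ..., beta_k')'`. The
#' dimension is `k * r` and therefore varies with trimmed length. For pairs
#' whose mismatch positions are never separated by a multiple of the
#' cyclic-group order, stacked and cyclic-group squared distances coincide.
#'
#' @inheritParams encode_cdr3
#' @return Numeric vector of length `nchar(trimmed) * emb$dim`.
#' @export
encode_stacked <- function(trimmed, emb = default_embedding()) {
  k <- nchar(trimmed)
  if (is.na(trimmed) || k < 1L) stop("trimmed sequence must have length >= 1")
  rows <- .residue_rows(trimmed, emb)
  as.vector(t(emb$vectors[rows, , drop = FALSE]))
}

#' Encode many equal-length trimmed sequences at once
#'
#' Vectorized encoder used by the clustering engine. All sequences must share
#' one trimmed length.
#'
#' @param trimmed Character vector of trimmed sequences of equal length.
#' @param emb `aa_embedding`.
#' @param transform `cyclic_transform`, or `NULL` for the stacked encoder.
#' @return Numeric matrix, one row per sequence.
#' @export
encode_matrix <- function(trimmed, emb = default_embedding(),
                          transform = build_transform(6L, emb$dim)) {
  k <- unique(nchar(trimmed))
  if (length(k) != 1L) stop("all sequences must share one trimmed length")
  n <- length(trimmed)
  r <- emb$dim
  chars <- matrix(unlist(strsplit(trimmed, "", fixed = TRUE), use.names = FALSE),
                  nrow = n, byrow = TRUE)
  idx <- matrix(match(chars, rownames(emb$vectors)), nrow = n)
  if (anyNA(idx)) stop("residue absent from embedding")
  if (is.null(transform)) {
    X <- matrix(0, n, k * r)
    for (p in seq_len(k)) {
      X[, (p - 1L) * r + seq_len(r)] <- emb$vectors[idx[, p], , drop = FALSE]
    }
  } else {
    ord <- transform$order
    X <- matrix(0, n, ord * r)
    for (l in seq_len(k)) {
      b <- transform$block_cycle[((l - 1L) %% ord) + 1L]
      cols <- (b - 1L) * r + seq_len(r)
      X[, cols] <- X[, cols] + emb$vectors[idx[, k - l + 1L], , drop = FALSE]
    }
  }
  rownames(X) <- trimmed
  X
}

#' Probability that a two-mismatch comparison violates the non-identity
#' condition
#'
#' The cyclic-group encoder is exactly isometric for two mismatches unless
#' their positions are separated by exactly the transform period (6 at
#' defaults), in which case a cross term survives. This function enumerates
#' all unordered position pairs of the trimmed core of a CDR3 of length
#' `full_len` and returns the fraction whose separation equals `period`.
#'
#' @param full_len Full (untrimmed) CDR3 length.
#' @param period Transform order (default 6).
#' @param clip_n,clip_c Trimming convention (defaults 3 and 2).
#' @return Fraction in `[0, 1]`.
#' @export
#' @examples
#' nic_violation_probability(16)  # 5/55
nic_violation_probability <- function(full_len, period = 6L,
                                      clip_n = 3L, clip_c = 2L) {
  if (period < 2L) stop("period must be >= 2")
  L <- full_len - clip_n - clip_c
  if (L < 2L) stop("effective trimmed length < 2; nothing to enumerate")
  pairs <- utils::combn(seq_len(L), 2L)
  viol <- sum(pairs[2L, ] - pairs[1L, ] == period)
  viol / ncol(pairs)
}
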