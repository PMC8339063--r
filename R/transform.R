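#' Cyclic-group block transformation matrix
#'
#' Builds the orthogonal block-permutation matrix `Omega` representing the
#' generator of the cyclic group of the given order, acting on lifted
#' embedding vectors in `R^(order * base_dim)`:
#'
#' * order 2: `[0 I; I 0]` over `r`-blocks,
#' * order 3: `[0 0 I; I 0 0; 0 I 0]` over `r`-blocks,
#' * order 6: `Omega_2` blocks arranged in the order-3 pattern (the order-6
#'   group factorizes as the product of its order-2 and order-3 subgroups).
#'
#' The resulting matrix is a permutation of `r`-dimensional sub-blocks, hence
#' exactly orthogonal, with `Omega^order = I` and no smaller power equal to
#' the identity. Powers of `Omega` applied to lifted vectors simply relocate
#' the `r`-block, which is what makes cross terms between distinct sequence
#' positions vanish (until the position separation hits a multiple of the
#' order).
#'
#' @param order Group order: 2, 3 or 6 (default 6).
#' @param base_dim Embedding dimension `r` per block (default 16).
#' @return Object of class `cyclic_transform`: list with `matrix`
#'   (`order*r x order*r`), `order`, `base_dim`, and `block_cycle` (the block
#'   index that receives a lifted vector under `Omega^l`, `l = 1..order`).
#' @export
build_transform <- function(order = 6L, base_dim = 16L) {
  order <- as.integer(order)
  r <- as.integer(base_dim)
  if (!order %in% c(2L, 3L, 6L)) {
    stop("unsupported cyclic-group order: ", order, " (use 2, 3 or 6)")
  }
  blk <- function(pattern, cell) {
    # pattern: 0/1 matrix over cells; cell: the sub-matrix standing for 1
    n <- nrow(pattern); m <- nrow(cell)
    out <- matrix(0, n * m, n * m)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (pattern[i, j] != 0) {
        out[(i - 1) * m + seq_len(m), (j - 1) * m + seq_len(m)] <- cell
      }
    }
    out
  }
  p3 <- rbind(c(0, 0, 1), c(1, 0, 0), c(0, 1, 0))
  omega <- switch(as.character(order),
    "2" = blk(rbind(c(0, 1), c(1, 0)), diag(r)),
    "3" = blk(p3, diag(r)),
    "6" = blk(p3, blk(rbind(c(0, 1), c(1, 0)), diag(r))))
  # permutation of r-blocks: Omega sends block j to block perm[j]
  nb <- order
  perm <- integer(nb)
  for (j in seq_len(nb)) {
    col <- (j - 1) * r + 1
    perm[j] <- (which(omega[, col] != 0)[1] - 1) %/% r + 1
  }
  cycle <- integer(order)
  b <- 1L
  for (l in seq_len(order)) {
    b <- perm[b]
    cycle[l] <- b
  }
  structure(list(matrix = omega, order = order, base_dim = r,
                 block_cycle = cycle),
            class = "cyclic_transform")
}

#' @export
print.cyclic_transform <- function(x, ...) {
  cat("Cyclic-group transform: order", x$order, ", base dim", x$base_dim,
      "->", x$order * x$base_dim, "coordinates\n")
  invisible(x)
}

#' Lift an embedding vector into the transform space
#'
#' Pads an `r`-dimensional embedding vector with zeros to dimension
#' `order * r`: the first `r` entries are `beta`, the rest 0. Lifted vectors
#' occupy the first block, so `u' Omega^p v = 0` for lifted `u`, `v` and any
#' power `p` that is not a multiple of the order.
#'
#' @param beta Numeric vector of length `r`.
#' @param order Cyclic-group order.
#' @return Numeric vector of length `order * length(beta)`.
#' @export
lift_vector <- function(beta, order = 6L) {
  c(beta, numeric((order - 1L) * length(beta)))
}
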