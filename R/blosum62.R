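#' Standard amino-acid alphabet
#'
#' The 20 standard amino acids in the conventional substitution-matrix order
#' (A, R, N, D, ...). All embeddings, dissimilarity matrices and encoders in
#' this package index residues in this order.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                   "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# BLOSUM62 log-odds similarity scores for the 20 standard amino acids
# (half-bit units, Henikoff & Henikoff). Bundled as a constant so that all
# downstream results are reproducible without external files.
.blosum62_values <- c(
   4, -1, -2, -2,  0, -1, -1,  0, -2, -1, -1, -1, -1, -2, -1,  1,  0, -3, -2,  0,
  -1,  5,  0, -2, -3,  1,  0, -2,  0, -3, -2,  2, -1, -3, -2, -1, -1, -3, -2, -3,
  -2,  0,  6,  1, -3,  0,  0,  0,  1, -3, -3,  0, -2, -3, -2,  1,  0, -4, -2, -3,
  -2, -2,  1,  6, -3,  0,  2, -1, -1, -3, -4, -1, -3, -3, -1,  0, -1, -4, -3, -3,
   0, -3, -3, -3,  9, -3, -4, -3, -3, -1, -1, -3, -1, -2, -3, -1, -1, -2, -2, -1,
  -1,  1,  0,  0, -3,  5,  2, -2,  0, -3, -2,  1,  0, -3, -1,  0, -1, -2, -1, -2,
  -1,  0,  0,  2, -4,  2,  5, -2,  0, -3, -3,  1, -2, -3, -1,  0, -1, -3, -2, -2,
   0, -2,  0, -1, -3, -2, -2,  6, -2, -4, -4, -2, -3, -3, -2,  0, -2, -2, -3, -3,
  -2,  0,  1, -1, -3,  0,  0, -2,  8, -3, -3, -1, -2, -1, -2, -1, -2, -2,  2, -3,
  -1, -3, -3, -3, -1, -3, -3, -4, -3,  4,  2, -3,  1,  0, -3, -2, -1, -3, -1,  3,
  -1, -2, -3, -4, -1, -2, -3, -4, -3,  2,  4, -2,  2,  0, -3, -2, -1, -2, -1,  1,
  -1,  2,  0, -1, -3,  1,  1, -2, -1, -3, -2,  5, -1, -3, -1,  0, -1, -3, -2, -2,
  -1, -1, -2, -3, -1,  0, -2, -3, -2,  1,  2, -1,  5,  0, -2, -1, -1, -1, -1,  1,
  -2, -3, -3, -3, -2, -3, -3, -3, -1,  0,  0, -3,  0,  6, -4, -2, -2,  1,  3, -1,
  -1, -2, -2, -1, -3, -1, -1, -2, -2, -3, -3, -1, -2, -4,  7, -1, -1, -4, -3, -2,
   1, -1,  1,  0, -1,  0,  0,  0, -1, -2, -2,  0, -1, -2, -1,  4,  1, -3, -2, -2,
   0, -1,  0, -1, -1, -1, -1, -2, -2, -1, -1, -1, -1, -2, -1,  1,  5, -2, -2,  0,
  -3, -3, -4, -4, -2, -2, -3, -2, -2, -3, -2, -3, -1,  1, -4, -3, -2, 11,  2, -3,
  -2, -2, -2, -3, -2, -1, -2, -3,  2, -1, -1, -2, -1,  3, -3, -2, -2,  2,  7, -1,
   0, -3, -3, -3, -1, -2, -2, -3, -3,  3,  1, -2,  1, -1, -2, -2,  0, -3, -1,  4)

#' BLOSUM62 substitution matrix
#'
#' Returns the standard BLOSUM62 similarity matrix restricted to the 20
#' standard amino acids, in [AA_ALPHABET20] order.
#'
#' @return Integer 20x20 matrix with dimnames set to the amino-acid letters.
#' @export
#' @examples
#' blosum62()["A", "R"]  # -1
blosum62 <- function() {
  m <- matrix(as.integer(.blosum62_values), nrow = 20, byrow = TRUE,
              dimnames = list(AA_ALPHABET20, AA_ALPHABET20))
  m
}

#' Read a substitution matrix in NCBI text format
#'
#' Parses a whitespace-delimited scoring matrix as distributed by NCBI
#' (comment lines starting with `#`, a header row of residue letters, one
#' labelled row per residue). Columns beyond the 20 standard amino acids
#' (B, Z, X, *) are dropped.
#'
#' @param path Path to the matrix file.
#' @return Integer matrix over the 20 standard amino acids.
#' @export
read_substitution_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  header <- strsplit(trimws(lines[[1]]), "\\s+")[[1]]
  body <- lines[-1]
  rows <- lapply(body, function(x) strsplit(trimws(x), "\\s+")[[1]])
  labels <- vapply(rows, `[`, character(1), 1)
  vals <- t(vapply(rows, function(r) as.numeric(r[-1]), numeric(length(header))))
  dimnames(vals) <- list(labels, header)
  keep <- intersect(AA_ALPHABET20, intersect(labels, header))
  if (length(keep) < 20) {
    stop("substitution matrix does not cover the 20 standard amino acids; ",
         "missing: ", paste(setdiff(AA_ALPHABET20, keep), collapse = ", "))
  }
  out <- vals[AA_ALPHABET20, AA_ALPHABET20]
  storage.mode(out) <- "integer"
  out
}
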