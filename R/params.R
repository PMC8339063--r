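#' Clustering parameters
#'
#' Bundles the tunable thresholds of the clustering pipeline.
#'
#' @param thr Squared Euclidean distance cutoff for the nearest-neighbor
#'   pre-clustering pass (`-t`). The encoding distances are calibrated to the
#'   `4 - BLOSUM62` dissimilarity scale, so `thr = 10` (the default) admits
#'   merges up to roughly one strongly conservative substitution step.
#' @param thr_s Normalized ungapped alignment-score cutoff (`-S`), in
#'   `(0, 4]`; a self-comparison scores exactly 4. Default 3.3.
#' @param thr_v V-gene alignment-score cutoff (`-G`). With the fallback
#'   scorer (no table supplied) a same-gene match scores 4 and anything else
#'   0, so the default 3.7 requires an exact gene match (allele suffixes
#'   ignored).
#' @param kmer_len k-mer length for the alignment-candidate index (default 5).
#' @param max_iter Cap on nearest-neighbor centroid passes (default 20).
#' @param clip_n,clip_c CDR3 trimming (defaults 3 and 2, see [trim_cdr3()]).
#' @param use_vgene Apply V-gene compatibility filtering (default TRUE).
#' @param encoder `"g6"` for the cyclic-group encoder (fixed 96-dim at
#'   defaults) or `"stacked"` for concatenated embedding vectors.
#' @return Object of class `clustering_params`.
#' @export
clustering_params <- function(thr = 10, thr_s = 3.3, thr_v = 3.7,
                              kmer_len = 5L, max_iter = 20L,
                              clip_n = 3L, clip_c = 2L,
                              use_vgene = TRUE, encoder = c("g6", "stacked")) {
  encoder <- match.arg(encoder)
  if (thr <= 0) stop("thr must be > 0")
  if (thr_s <= 0 || thr_s > 4) stop("thr_s must be in (0, 4]")
  if (kmer_len < 3L) stop("kmer_len must be >= 3")
  structure(list(thr = thr, thr_s = thr_s, thr_v = thr_v,
                 kmer_len = as.integer(kmer_len),
                 max_iter = as.integer(max_iter),
                 clip_n = as.integer(clip_n), clip_c = as.integer(clip_c),
                 use_vgene = isTRUE(use_vgene), encoder = encoder),
            class = "clustering_params")
}

#' @export
print.clustering_params <- function(x, ...) {
  cat(sprintf("Clustering params: -t %g  -S %g  -G %g  kmer %d  clip %d/%d  encoder %s  vgene %s\n",
              x$thr, x$thr_s, x$thr_v, x$kmer_len, x$clip_n, x$clip_c,
              x$encoder, if (x$use_vgene) "on" else "off"))
  invisible(x)
}

#' Construct a TCR record table
#'
#' Normalizes a set of CDR3 observations into the record `data.frame` used by
#' the clustering engine: columns `cdr3`, `v_gene`, `sample_id`, `frequency`,
#' `count`, `label`. Any of the optional fields may be `NA`.
#'
#' @param cdr3 Character vector of CDR3 amino-acid sequences.
#' @param v_gene TRBV gene/allele names (recycled; `NA` allowed when V-gene
#'   filtering is disabled).
#' @param sample_id Sample identifiers (recycled).
#' @param frequency Optional clone frequencies in `[0, 1]`.
#' @param count Optional read/template counts.
#' @param label Optional class or antigen tags.
#' @return `data.frame` of TCR records.
#' @export
tcr_records <- function(cdr3, v_gene = NA_character_,
                        sample_id = "S1", frequency = NA_real_,
                        count = NA_integer_, label = NA_character_) {
  if (length(cdr3) == 0L) {
    return(data.frame(cdr3 = character(), v_gene = character(),
                      sample_id = character(), frequency = numeric(),
                      count = integer(), label = character(),
                      stringsAsFactors = FALSE))
  }
  if (any(!nzchar(cdr3), na.rm = TRUE)) stop("cdr3 must be non-empty")
  data.frame(cdr3 = as.character(cdr3),
             v_gene = rep_len(as.character(v_gene), length(cdr3)),
             sample_id = rep_len(as.character(sample_id), length(cdr3)),
             frequency = rep_len(as.numeric(frequency), length(cdr3)),
             count = rep_len(as.integer(count), length(cdr3)),
             label = rep_len(as.character(label), length(cdr3)),
             stringsAsFactors = FALSE)
}
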