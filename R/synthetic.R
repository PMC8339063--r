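# Average amino-acid composition of the UniProtKB/Swiss-Prot database
# (release-average values, fraction of residues). Fixed so that synthetic
# repertoires are deterministic; realism of the marginal composition is
# secondary to reproducibility.
.aa_background_freq <- c(
  A = 0.0826, R = 0.0553, N = 0.0406, D = 0.0546, C = 0.0137,
  Q = 0.0393, E = 0.0674, G = 0.0708, H = 0.0227, I = 0.0593,
  L = 0.0965, K = 0.0582, M = 0.0241, F = 0.0386, P = 0.0472,
  S = 0.0660, T = 0.0535, W = 0.0110, Y = 0.0292, V = 0.0687)

# Canonical strongly conservative substitution pairs (D/E, Q/E, R/K, F/Y,
# I/V). Planted antigen-group members vary from their motif center only
# within these pairs: this is the regime in which co-specific TCRs are
# observed to differ, and the regime the default distance cutoff captures.
.conservative_partners <- list(
  D = "E", E = c("D", "Q"), Q = "E", R = "K", K = "R",
  F = "Y", Y = "F", I = "V", V = "I")

.default_v_pool <- c("TRBV2", "TRBV4-1", "TRBV5-1", "TRBV6-2", "TRBV7-9",
                     "TRBV9", "TRBV11-2", "TRBV12-3", "TRBV19", "TRBV20-1",
                     "TRBV28", "TRBV30")

#' Synthetic repertoire specification
#'
#' Parameters of the planted-structure generator. Defaults define the
#' package's standard simulation conditions: 2,000 background clonotypes and
#' 20 antigen-specific groups of 10 members, each member at most one
#' strongly conservative substitution away from its group's motif center.
#'
#' @param n_background Number of background clonotypes.
#' @param n_groups Number of planted antigen-specific groups.
#' @param group_size Members per group (>= 2).
#' @param max_mutations Maximum substitutions of a member from its motif
#'   center (drawn uniformly from `0..max_mutations`).
#' @param length_range Full CDR3 length range, inclusive (default 12..17).
#' @param v_gene_pool TRBV gene names sampled for background records and
#'   assigned per group.
#' @param seed Integer seed; identical seeds give identical output.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_background = 2000L, n_groups = 20L,
                           group_size = 10L, max_mutations = 1L,
                           length_range = c(12L, 17L),
                           v_gene_pool = .default_v_pool,
                           seed = 0L) {
  stopifnot(n_background >= 0L, n_groups >= 0L, max_mutations >= 0L,
            length_range[1L] >= 10L, length_range[2L] >= length_range[1L])
  structure(list(n_background = as.integer(n_background),
                 n_groups = as.integer(n_groups),
                 group_size = as.integer(group_size),
                 max_mutations = as.integer(max_mutations),
                 length_range = as.integer(length_range),
                 v_gene_pool = v_gene_pool,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

.random_cdr3 <- function(len) {
  core <- sample(names(.aa_background_freq), len - 4L, replace = TRUE,
                 prob = .aa_background_freq)
  paste0("CAS", paste(core, collapse = ""), "F")
}

#' Generate background clonotypes
#'
#' Draws CDR3s residue-wise from a fixed average amino-acid composition,
#' with the junction anatomy mimicked by a constant `CAS` prefix and `F`
#' suffix; V genes are uniform over the pool. Lengths are uniform over
#' `length_range`.
#'
#' @param spec [synthetic_spec()].
#' @param sample_id Sample id for the records.
#' @return Record `data.frame`.
#' @export
generate_background <- function(spec = synthetic_spec(), sample_id = "background") {
  set.seed(spec$seed + 1L)
  n <- spec$n_background
  lens <- sample(seq(spec$length_range[1L], spec$length_range[2L]), n,
                 replace = TRUE)
  cdr3 <- vapply(lens, .random_cdr3, character(1))
  tcr_records(cdr3 = cdr3,
              v_gene = sample(spec$v_gene_pool, n, replace = TRUE),
              sample_id = sample_id)
}

.mutate_member <- function(center, n_mut, clip_n = 3L, clip_c = 2L) {
  chars <- strsplit(center, "", fixed = TRUE)[[1]]
  L <- length(chars)
  interior <- seq(clip_n + 1L, L - clip_c)
  mutable <- interior[chars[interior] %in% names(.conservative_partners)]
  n_mut <- min(n_mut, length(mutable))
  if (n_mut > 0L) {
    pos <- mutable[sample.int(length(mutable), n_mut)]
    for (p in pos) {
      alt <- .conservative_partners[[chars[p]]]
      chars[p] <- if (length(alt) == 1L) alt else sample(alt, 1L)
    }
  }
  paste(chars, collapse = "")
}

#' Generate planted antigen-specific groups
#'
#' Each group gets a random motif-center CDR3 and one V gene; members are
#' the center with up to `max_mutations` strongly conservative substitutions
#' (BLOSUM62 >= 2) at interior (non-clipped) positions, so that the planted
#' pairs remain recoverable at the default clustering thresholds. Members
#' share the group label `G<i>` and the group's V gene.
#'
#' @param spec [synthetic_spec()].
#' @param sample_id Sample id for the records.
#' @return Labeled record `data.frame`.
#' @export
generate_antigen_groups <- function(spec = synthetic_spec(),
                                    sample_id = "planted") {
  if (spec$n_groups > 0L && spec$group_size < 2L) {
    stop("group_size must be >= 2")
  }
  set.seed(spec$seed + 2L)
  rows <- vector("list", spec$n_groups)
  for (g in seq_len(spec$n_groups)) {
    len <- sample(seq(spec$length_range[1L], spec$length_range[2L]), 1L)
    center <- .random_cdr3(len)
    vg <- sample(spec$v_gene_pool, 1L)
    members <- vapply(seq_len(spec$group_size), function(i) {
      .mutate_member(center, sample(0:spec$max_mutations, 1L))
    }, character(1))
    rows[[g]] <- tcr_records(cdr3 = members, v_gene = vg,
                             sample_id = sample_id,
                             label = sprintf("G%02d", g))
  }
  do.call(rbind, rows)
}

#' Generate a full synthetic repertoire
#'
#' Planted antigen groups followed by background records (planted records
#' first, so that the deterministic index order of the pre-clustering pass
#' visits them first).
#'
#' @param spec [synthetic_spec()].
#' @param sample_id Sample id for the records.
#' @return Record `data.frame` with `label` set for planted records and `NA`
#'   for background.
#' @export
generate_repertoire <- function(spec = synthetic_spec(), sample_id = "sim") {
  rbind(generate_antigen_groups(spec, sample_id),
        generate_background(spec, sample_id))
}

#' Generate a spike-in experiment design
#'
#' Splits every planted group into disjoint training and testing subsets at
#' `train_frac` (groups too small to place at least one member on each side
#' are skipped with a warning) and pairs them with an independent
#' background.
#'
#' @param spec [synthetic_spec()].
#' @param train_frac Fraction of each group assigned to training (default
#'   0.8).
#' @return List with record `data.frame`s `train`, `test`, `background`.
#' @export
generate_spike_in <- function(spec = synthetic_spec(), train_frac = 0.8) {
  if (train_frac <= 0 || train_frac >= 1) stop("train_frac must be in (0, 1)")
  groups <- generate_antigen_groups(spec)
  background <- generate_background(spec)
  set.seed(spec$seed + 3L)
  train <- list(); test <- list()
  for (g in unique(groups$label)) {
    blk <- groups[groups$label == g, , drop = FALSE]
    n <- nrow(blk)
    n_train <- round(train_frac * n)
    if (n_train < 1L || n_train >= n) {
      warning("group ", g, " too small to split; skipped")
      next
    }
    blk <- blk[sample(n), , drop = FALSE]
    take <- seq_len(n_train)
    train[[g]] <- blk[take, , drop = FALSE]
    held <- blk[-take, , drop = FALSE]
    # identical CDR3s must not straddle the split (train/test disjointness)
    test[[g]] <- held[!held$cdr3 %in% blk$cdr3[take], , drop = FALSE]
  }
  list(train = do.call(rbind, train),
       test = do.call(rbind, test),
       background = background)
}
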