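.cdr3_synonyms <- c("cdr3", "aminoAcid", "amino_acid", "cdr3aa", "CDR3.aa",
                    "junction_aa", "cdr3_amino_acid", "CDR3")
.vgene_synonyms <- c("v_gene", "vGeneName", "v_call", "V", "vMaxResolved",
                     "v_gene_name")
.sample_synonyms <- c("sample_id", "sample", "sample_name")
.freq_synonyms <- c("frequency", "frequencyCount", "freq")
.count_synonyms <- c("count", "templates", "reads", "duplicate_count")
.label_synonyms <- c("label", "antigen", "epitope", "class")

.resolve_col <- function(headers, synonyms) {
  hit <- intersect(synonyms, headers)
  if (length(hit) == 0L) return(NA_character_)
  hit[[1L]]
}

#' Read a TCR repertoire table
#'
#' Reads a TSV clonotype table in immunoSEQ/immuneACCESS, AIRR or minimal
#' dialect. Column names are resolved through synonym lists (CDR3:
#' `aminoAcid`, `cdr3aa`, `CDR3.aa`, `junction_aa`, ...; V gene: `vGeneName`,
#' `v_call`, `V`, ...). Rows whose CDR3 cannot be parsed (empty, `NA`, or
#' containing characters outside the 20 standard amino-acid letters, such as
#' `*`, `X` or `_`) are counted and skipped with a message, never silently
#' dropped; the skip count is attached as attribute `n_skipped`. Row order
#' is preserved.
#'
#' @param path Path to a tab-separated file with a header line.
#' @param sample_id Sample identifier to assign when the file has no sample
#'   column (default: file name without extension).
#' @return Record `data.frame` as from [tcr_records()].
#' @export
read_repertoire <- function(path, sample_id = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE, comment.char = "#")
  cn <- names(df)
  ccol <- .resolve_col(cn, .cdr3_synonyms)
  if (is.na(ccol)) {
    stop("no CDR3 column found; detected headers: ",
         paste(cn, collapse = ", "))
  }
  vcol <- .resolve_col(cn, .vgene_synonyms)
  scol <- .resolve_col(cn, .sample_synonyms)
  fcol <- .resolve_col(cn, .freq_synonyms)
  ncol_ <- .resolve_col(cn, .count_synonyms)
  lcol <- .resolve_col(cn, .label_synonyms)

  cdr3 <- as.character(df[[ccol]])
  bad <- is.na(cdr3) | !nzchar(cdr3) |
    !grepl(paste0("^[", paste(AA_ALPHABET20, collapse = ""), "]+$"), cdr3)
  if (any(bad)) {
    message("skipped ", sum(bad), " row(s) with unparseable CDR3 in ", path)
  }
  df <- df[!bad, , drop = FALSE]
  cdr3 <- cdr3[!bad]
  if (is.null(sample_id)) {
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  }
  out <- tcr_records(
    cdr3 = cdr3,
    v_gene = if (!is.na(vcol)) as.character(df[[vcol]]) else NA_character_,
    sample_id = if (!is.na(scol)) as.character(df[[scol]]) else sample_id,
    frequency = if (!is.na(fcol)) as.numeric(df[[fcol]]) else NA_real_,
    count = if (!is.na(ncol_)) as.integer(df[[ncol_]]) else NA_integer_,
    label = if (!is.na(lcol)) as.character(df[[lcol]]) else NA_character_)
  attr(out, "n_skipped") <- sum(bad)
  out
}

#' Write / read a cluster set as TSV
#'
#' The cluster file is tab-separated with columns `cluster_id`, `CDR3`,
#' `V_gene`, `sample_id`, `origin`, `label`, `record_id`, preceded by comment
#' lines (`#`) recording the package version, the `-t`/`-S`/`-G` thresholds,
#' trimming, encoder and the embedding cache hash. `read_clusters()` restores
#' the set including its parameters, so `read_clusters(write_clusters(x))`
#' round-trips.
#'
#' @param cs `tcr_cluster_set`.
#' @param path Output file path.
#' @return `write_clusters` returns `path` invisibly; `read_clusters` returns
#'   a `tcr_cluster_set`.
#' @export
write_clusters <- function(cs, path) {
  p <- cs$params
  hdr <- c(
    paste0("# tcriso cluster file v", as.character(utils::packageVersion("tcriso"))),
    sprintf("# params t=%.17g S=%.17g G=%.17g kmer=%d clip=%d/%d encoder=%s vgene=%d maxiter=%d",
            p$thr, p$thr_s, p$thr_v, p$kmer_len, p$clip_n, p$clip_c,
            p$encoder, as.integer(p$use_vgene), p$max_iter),
    sprintf("# embedding %s", cs$embedding_hash),
    sprintf("# n_input=%d n_excluded=%d", cs$n_input, cs$n_excluded))
  m <- cs$members
  tab <- data.frame(cluster_id = m$cluster_id, CDR3 = m$cdr3,
                    V_gene = m$v_gene, sample_id = m$sample_id,
                    origin = m$origin, label = m$label,
                    record_id = m$record_id, stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(names(tab), collapse = "\t"), con)
  if (nrow(tab)) {
    writeLines(do.call(paste, c(lapply(tab, as.character), sep = "\t")), con)
  }
  invisible(path)
}

#' @rdname write_clusters
#' @export
read_clusters <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  pl <- hdr[grepl("^# params ", hdr)]
  if (length(pl) != 1L) stop("malformed cluster file header: ", path)
  getv <- function(key, ln) {
    m <- regmatches(ln, regexpr(paste0(key, "=[^ ]+"), ln))
    sub(paste0(key, "="), "", m)
  }
  params <- clustering_params(
    thr = as.numeric(getv("t", pl)), thr_s = as.numeric(getv("S", pl)),
    thr_v = as.numeric(getv("G", pl)), kmer_len = as.integer(getv("kmer", pl)),
    max_iter = as.integer(getv("maxiter", pl)),
    clip_n = as.integer(strsplit(getv("clip", pl), "/")[[1]][1]),
    clip_c = as.integer(strsplit(getv("clip", pl), "/")[[1]][2]),
    use_vgene = getv("vgene", pl) == "1", encoder = getv("encoder", pl))
  nl <- hdr[grepl("^# n_input=", hdr)]
  n_input <- if (length(nl)) as.integer(getv("n_input", nl)) else NA_integer_
  n_excl <- if (length(nl)) as.integer(getv("n_excluded", nl)) else NA_integer_
  ehash <- sub("^# embedding ", "", hdr[grepl("^# embedding ", hdr)])

  tab <- utils::read.delim(text = paste(body, collapse = "\n"),
                           stringsAsFactors = FALSE)
  members <- data.frame(cluster_id = as.integer(tab$cluster_id),
                        cdr3 = as.character(tab$CDR3),
                        trimmed = trim_cdr3(as.character(tab$CDR3),
                                            params$clip_n, params$clip_c),
                        v_gene = as.character(tab$V_gene),
                        sample_id = as.character(tab$sample_id),
                        origin = as.character(tab$origin),
                        label = as.character(tab$label),
                        record_id = as.character(tab$record_id),
                        stringsAsFactors = FALSE)
  attr(members$trimmed, "exclusions") <- NULL
  cs <- structure(list(members = members, params = params,
                       embedding_hash = ehash,
                       n_input = n_input, n_excluded = n_excl),
                  class = "tcr_cluster_set")
  cs
}

#' Read a V-gene pair score table
#'
#' Expects a TSV with columns `allele_1`, `allele_2`, `score` (symmetric;
#' each unordered pair listed once is sufficient).
#'
#' @param path File path.
#' @return `data.frame` usable as the `table` argument of [vgene_scorer()].
#' @export
read_vgene_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("allele_1", "allele_2", "score")
  if (!all(need %in% names(df))) {
    stop("V-gene score table must have columns: ", paste(need, collapse = ", "))
  }
  df[, need]
}
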