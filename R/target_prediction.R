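#' Scan a target sequence for canonical miRNA seed-match sites
#'
#' Every occurrence of the seed-core match (reverse complement of miRNA
#' positions 2-7) anchors one site, classified by its extensions: a match to
#' position 8 on the 5' side plus an adenosine opposite miRNA position 1
#' makes an 8mer; position-8 match alone a 7mer-m8; the adenosine alone a
#' 7mer-A1; neither a 6mer. Each core occurrence yields exactly one site of
#' its maximal class, so sub-patterns of a stronger site are never reported
#' separately. Overlapping cores at different offsets are all reported.
#' T and U are interchangeable in both sequences.
#'
#' @param mirna_seq miRNA sequence (>= 8 nt).
#' @param target_seq target sequence (>= 6 nt).
#' @return data.frame with columns `start`, `end` (0-based half-open on the
#'   target sense strand) and `site_class`.
#' @export
seed_match_sites <- function(mirna_seq, target_seq) {
  check_alphabet <- function(s, what) {
    bad <- regexpr("[^ACGUT]", toupper(s))
    if (bad != -1L)
      stop(sprintf("non-nucleotide character '%s' in %s at position %d",
                   substr(s, bad, bad), what, bad - 1L), call. = FALSE)
  }
  check_alphabet(mirna_seq, "miRNA sequence")
  check_alphabet(target_seq, "target sequence")
  if (nchar(mirna_seq) < 8L) stop("miRNA sequence must be >= 8 nt", call. = FALSE)
  if (nchar(target_seq) < 6L) stop("target sequence must be >= 6 nt", call. = FALSE)
  t <- rna_of(target_seq)
  pats <- seed_patterns(mirna_seq)
  comp_m8 <- substr(pats$rc7, 1L, 1L)
  n <- nchar(t)
  starts1 <- which(substring(t, seq_len(n - 5L), seq_len(n - 5L) + 5L) == pats$rc6)
  if (!length(starts1))
    return(data.frame(start = integer(0), end = integer(0),
                      site_class = character(0), stringsAsFactors = FALSE))
  m8_ok <- starts1 > 1L & substring(t, starts1 - 1L, starts1 - 1L) == comp_m8
  a1_ok <- starts1 + 6L <= n & substring(t, starts1 + 6L, starts1 + 6L) == "A"
  site_class <- ifelse(m8_ok & a1_ok, "8mer",
                ifelse(m8_ok, "7mer-m8",
                ifelse(a1_ok, "7mer-A1", "6mer")))
  start0 <- ifelse(m8_ok, starts1 - 2L, starts1 - 1L)        # 0-based
  end0 <- ifelse(a1_ok, starts1 + 6L, starts1 + 5L)          # half-open
  data.frame(start = as.integer(start0), end = as.integer(end0),
             site_class = site_class, stringsAsFactors = FALSE)
}

#' Predict miRNA targets by seed matching
#'
#' Scans every miRNA against every target sequence and reports one row per
#' (miRNA, target) pair with at least one canonical site, annotated with the
#' best site class found (8mer > 7mer-m8 > 7mer-A1 > 6mer).
#'
#' @param mirna_fasta,target_fasta named character vectors of sequences, or
#'   paths to FASTA files.
#' @param target_class `"lncRNA"` or `"mRNA"`.
#' @return a target-table data.frame (source tag `"seedmatch"`).
#' @export
predict_targets <- function(mirna_fasta, target_fasta,
                            target_class = c("lncRNA", "mRNA")) {
  target_class <- match.arg(target_class)
  load_seqs <- function(x, what) {
    if (is.character(x) && length(x) == 1L && is.null(names(x)) && file.exists(x))
      x <- read_fasta(x)
    if (!length(x)) stop("empty ", what, " FASTA input", call. = FALSE)
    if (is.null(names(x)) || anyDuplicated(names(x)) ||
        any(is.na(names(x)) | !nzchar(names(x))))
      stop(what, " sequences need unique ids", call. = FALSE)
    x
  }
  mirnas <- load_seqs(mirna_fasta, "miRNA")
  targets <- load_seqs(target_fasta, "target")
  rows <- list()
  for (m in names(mirnas)) {
    for (g in names(targets)) {
      sites <- seed_match_sites(mirnas[[m]], targets[[g]])
      if (!nrow(sites)) next
      best <- SITE_CLASSES[min(match(sites$site_class, SITE_CLASSES))]
      rows[[length(rows) + 1L]] <- data.frame(
        mirna_id = m, target_id = g, target_class = target_class,
        site_class = best, source = "seedmatch", stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty_target_table())
  do.call(rbind, rows)
}

#' Intersect target tables from multiple prediction sources
#'
#' Keeps the (miRNA, target) pairs present in every input table, mirroring
#' the consensus-of-tools step; annotation columns are carried from the
#' first table. Output is sorted by miRNA id then target id and tagged
#' `source = "intersection"`.
#'
#' @param ... two or more target-table data.frames (or one list of them).
#' @return a target-table data.frame.
#' @export
intersect_targets <- function(...) {
  tables <- list(...)
  if (length(tables) == 1L && is.list(tables[[1L]]) &&
      !is.data.frame(tables[[1L]]))
    tables <- tables[[1L]]
  if (length(tables) < 2L)
    stop("intersect_targets needs at least 2 target tables", call. = FALSE)
  keys <- lapply(tables, function(t) unique(paste(t$mirna_id, t$target_id,
                                                  sep = "\r")))
  shared <- Reduce(intersect, keys)
  first <- tables[[1L]]
  out <- first[paste(first$mirna_id, first$target_id, sep = "\r") %in% shared, ,
               drop = FALSE]
  out <- out[!duplicated(out[, c("mirna_id", "target_id")]), , drop = FALSE]
  if (!nrow(out)) {
    warning("target tables have no pairs in common")
    return(empty_target_table())
  }
  out$source <- "intersection"
  out <- out[order(out$mirna_id, out$target_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
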