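#' @keywords internal
"_PACKAGE"

COMPARTMENTS <- c("Cytoplasm", "Nucleus", "Ribosome", "Exosome")

#' Construct a validated expression matrix
#'
#' A thin, validated container for gene x sample abundance tables (FPKM for
#' lncRNA/mRNA, TPM for miRNA). Rows are genes, columns are samples.
#'
#' @param values numeric matrix with gene ids as rownames and sample ids as
#'   colnames; all values must be finite and non-negative.
#' @param gene_class one of `"lncRNA"`, `"miRNA"`, `"mRNA"`.
#' @return a numeric matrix of class `expr_matrix` carrying a `gene_class`
#'   attribute.
#' @export
expression_matrix <- function(values, gene_class = c("lncRNA", "miRNA", "mRNA")) {
  gene_class <- match.arg(gene_class)
  if (!is.matrix(values) || !is.numeric(values))
    stop("expression values must be a numeric matrix", call. = FALSE)
  if (nrow(values) < 1L)
    stop("expression matrix must have at least one gene row", call. = FALSE)
  if (ncol(values) < 2L)
    stop("expression matrix must have at least two sample columns", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix requires gene ids (rownames) and sample ids (colnames)",
         call. = FALSE)
  dup_g <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_g))
    stop("duplicate gene id(s): ", paste(dup_g, collapse = ", "), call. = FALSE)
  dup_s <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_s))
    stop("duplicate sample id(s): ", paste(dup_s, collapse = ", "), call. = FALSE)
  bad <- which(!is.finite(values) | values < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "invalid expression value at gene '%s', sample '%s' (must be finite and >= 0)",
      rownames(values)[bad[1L, 1L]], colnames(values)[bad[1L, 2L]]), call. = FALSE)
  }
  structure(values, gene_class = gene_class, class = c("expr_matrix", class(values)))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %s: %d genes x %d samples\n",
              attr(x, "gene_class"), nrow(x), ncol(x)))
  invisible(x)
}

gene_class_of <- function(x) attr(x, "gene_class")

#' Read an expression matrix from TSV
#'
#' Expects a tab-separated file with a header row; column 1 holds gene ids,
#' remaining columns are samples. Values must parse as finite non-negative
#' numbers; duplicated ids and silent coercions are rejected.
#'
#' @param path file path.
#' @inheritParams expression_matrix
#' @return an [expression_matrix()].
#' @export
read_expression_matrix <- function(path, gene_class = c("lncRNA", "miRNA", "mRNA")) {
  gene_class <- match.arg(gene_class)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", quote = "")
  if (ncol(df) < 3L)
    stop("expression TSV needs a gene id column plus >= 2 sample columns: ", path,
         call. = FALSE)
  ids <- df[[1L]]
  vals <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(vals), nrow = nrow(vals),
                                 dimnames = list(ids, colnames(vals))))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric expression value '%s' at gene '%s', sample '%s'",
                 vals[bad[1L, 1L], bad[1L, 2L]], ids[bad[1L, 1L]],
                 colnames(vals)[bad[1L, 2L]]), call. = FALSE)
  expression_matrix(num, gene_class)
}

#' Write an expression matrix to TSV
#'
#' @param x an [expression_matrix()] (or plain named matrix).
#' @param path output file path.
#' @param id_col name for the gene-id column.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path, id_col = "gene_id") {
  m <- unclass(x)
  chr <- matrix(sprintf("%.17g", m), nrow = nrow(m), dimnames = dimnames(m))
  df <- data.frame(rownames(m), as.data.frame(chr), check.names = FALSE)
  names(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a sample design
#'
#' Maps each sample to a developmental stage and replicate index and fixes
#' the stage order used by time-course operations.
#'
#' @param sample_id character vector of unique sample ids.
#' @param stage character vector, one stage label per sample.
#' @param replicate integer replicate index per sample (default: running
#'   count within stage).
#' @param stage_order order of stages along the time course (default: order
#'   of first appearance).
#' @return a data.frame of class `sample_design` with attribute `stage_order`.
#' @export
sample_design <- function(sample_id, stage, replicate = NULL, stage_order = NULL) {
  if (anyDuplicated(sample_id))
    stop("duplicate sample id(s) in design", call. = FALSE)
  if (length(stage) != length(sample_id))
    stop("stage and sample_id lengths differ", call. = FALSE)
  if (is.null(stage_order)) stage_order <- unique(stage)
  if (!all(stage %in% stage_order))
    stop("stage label(s) outside stage_order: ",
         paste(setdiff(stage, stage_order), collapse = ", "), call. = FALSE)
  if (length(stage_order) < 2L)
    stop("design needs at least two stages", call. = FALSE)
  if (is.null(replicate))
    replicate <- stats::ave(seq_along(stage), stage, FUN = seq_along)
  df <- data.frame(sample_id = as.character(sample_id),
                   stage = as.character(stage),
                   replicate = as.integer(replicate),
                   stringsAsFactors = FALSE)
  structure(df, stage_order = as.character(stage_order),
            class = c("sample_design", "data.frame"))
}

stage_order_of <- function(design) attr(design, "stage_order")

#' Derive a sample design from "STAGE_rep" sample ids
#'
#' @param sample_ids character vector such as `c("E8_1","E8_2",...)`.
#' @param stage_order optional explicit stage order.
#' @return a [sample_design()].
#' @export
design_from_sample_ids <- function(sample_ids, stage_order = NULL) {
  parts <- regmatches(sample_ids, regexpr("_[0-9]+$", sample_ids))
  if (length(parts) != length(sample_ids))
    stop("sample ids must follow the 'STAGE_rep' convention", call. = FALSE)
  stage <- sub("_[0-9]+$", "", sample_ids)
  rep_i <- as.integer(sub("^_", "", parts))
  sample_design(sample_ids, stage, rep_i, stage_order)
}

#' Read / write a sample design TSV (sample_id, stage, replicate)
#' @param path file path.
#' @param stage_order optional explicit stage order.
#' @return a [sample_design()].
#' @export
read_sample_design <- function(path, stage_order = NULL) {
  df <- utils::read.delim(path, sep = "\t", colClasses = "character", quote = "")
  need <- c("sample_id", "stage")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("design TSV missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  rep_i <- if ("replicate" %in% names(df)) as.integer(df$replicate) else NULL
  sample_design(df$sample_id, df$stage, rep_i, stage_order)
}

#' @rdname read_sample_design
#' @param design a [sample_design()].
#' @export
write_sample_design <- function(design, path) {
  utils::write.table(as.data.frame(design), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

check_design_covers <- function(design, expr) {
  missing <- setdiff(colnames(expr), design$sample_id)
  if (length(missing))
    stop("sample(s) absent from design: ", paste(missing, collapse = ", "),
         call. = FALSE)
  tab <- table(design$stage[design$sample_id %in% colnames(expr)])
  if (any(tab < 2L))
    stop("every stage needs >= 2 replicates for testing; offending stage(s): ",
         paste(names(tab)[tab < 2L], collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

empty_target_table <- function() {
  data.frame(mirna_id = character(0), target_id = character(0),
             target_class = character(0), site_class = character(0),
             source = character(0), stringsAsFactors = FALSE)
}

as_target_table <- function(df) {
  if (!"target_class" %in% names(df))
    df[["target_class"]] <- rep(NA_character_, nrow(df))
  if (!"site_class" %in% names(df))
    df[["site_class"]] <- rep("external", nrow(df))
  if (!"source" %in% names(df))
    df[["source"]] <- rep("external", nrow(df))
  df <- df[, c("mirna_id", "target_id", "target_class", "site_class", "source")]
  df[] <- lapply(df, as.character)
  dup <- duplicated(df[, c("mirna_id", "target_id", "source")])
  df <- df[!dup, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read a miRNA target table from TSV
#'
#' Mandatory columns `mirna_id` and `target_id`; optional `target_class`
#' (lncRNA/mRNA), `site_class`, and `source`. Duplicate (miRNA, target)
#' pairs within one source are dropped.
#'
#' @param path file path.
#' @return a target-table data.frame.
#' @export
read_target_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", colClasses = "character", quote = "")
  miss <- setdiff(c("mirna_id", "target_id"), names(df))
  if (length(miss))
    stop("target table missing mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  as_target_table(df)
}

#' @rdname read_target_table
#' @param table a target-table data.frame.
#' @export
write_target_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a lncRNA subcellular localization table
#'
#' Two-column TSV (`lnc_id`, `compartment`). Compartment labels are matched
#' case-insensitively against the fixed vocabulary Cytoplasm, Nucleus,
#' Ribosome, Exosome and normalized.
#'
#' @param path file path.
#' @return data.frame with columns `lnc_id`, `compartment`.
#' @export
read_localization_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", colClasses = "character", quote = "")
  miss <- setdiff(c("lnc_id", "compartment"), names(df))
  if (length(miss))
    stop("localization table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(df$lnc_id))
    stop("duplicate lncRNA id(s) in localization table: ",
         paste(unique(df$lnc_id[duplicated(df$lnc_id)]), collapse = ", "),
         call. = FALSE)
  idx <- match(tolower(df$compartment), tolower(COMPARTMENTS))
  if (anyNA(idx))
    stop("unknown compartment label(s): ",
         paste(unique(df$compartment[is.na(idx)]), collapse = ", "),
         "; expected one of ", paste(COMPARTMENTS, collapse = ", "), call. = FALSE)
  df$compartment <- COMPARTMENTS[idx]
  df[, c("lnc_id", "compartment")]
}

#' @rdname read_localization_table
#' @param table localization data.frame.
#' @export
write_localization_table <- function(table, path) {
  utils::write.table(table[, c("lnc_id", "compartment")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read GMT-like annotation sets
#'
#' Each line: set id, description, then one member gene id per further
#' tab-separated field. Empty sets are rejected.
#'
#' @param path file path.
#' @return named list of character vectors with a `descriptions` attribute.
#' @export
read_annotation_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(ids))
    stop("duplicate set id(s) in annotation file", call. = FALSE)
  if (any(lengths(fields) < 3L))
    stop("empty annotation set(s): ",
         paste(ids[lengths(fields) < 3L], collapse = ", "), call. = FALSE)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- ids
  attr(sets, "descriptions") <- stats::setNames(vapply(fields, `[[`, "", 2L), ids)
  sets
}

#' Read / write FASTA as a named character vector
#'
#' Thin wrappers over Biostrings; sequences are returned uppercase.
#'
#' @param path file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  stats::setNames(toupper(as.character(ss)), names(ss))
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = 60L)
  invisible(path)
}

#' Export a gene network
#'
#' Writes the typed lncRNA/miRNA/mRNA graph with node `type` and `degree`
#' attributes and edge `kind` attributes (sponge: lncRNA-miRNA; target:
#' miRNA-mRNA). GML and GraphML are produced via igraph for Gephi
#' compatibility; `edge_tsv` is a plain three-column table.
#'
#' @param net a [gene_network()].
#' @param path output file path.
#' @param format one of `"gml"`, `"graphml"`, `"edge_tsv"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("gml", "graphml", "edge_tsv")) {
  format <- match.arg(format)
  if (nrow(net$nodes) == 0L || nrow(net$edges) == 0L)
    stop("empty network", call. = FALSE)
  if (format == "edge_tsv") {
    utils::write.table(net$edges[, c("from", "to", "kind")], path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  deg <- node_degrees(net)
  g <- igraph::graph_from_data_frame(
    net$edges[, c("from", "to", "kind")], directed = FALSE,
    vertices = data.frame(name = net$nodes$id, type = net$nodes$type,
                          degree = as.integer(deg[net$nodes$id])))
  igraph::write_graph(g, path, format = format)
  if (format == "gml") {
    # igraph stamps the Creator line with the current time; pin it so
    # identical runs yield byte-identical exports
    lines <- readLines(path)
    lines[1L] <- sub('^Creator ".*"$', 'Creator "cernakit"', lines[1L])
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read an edge TSV written by [write_network()]
#' @param path file path.
#' @return data.frame with columns `from`, `to`, `kind`.
#' @export
read_edge_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", colClasses = "character", quote = "")
}
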