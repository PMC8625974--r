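check_cor_input <- function(x, y) {
  if (length(x) != length(y)) stop("vectors differ in length", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 paired samples", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("correlation input must be finite", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant vector: correlation undefined", call. = FALSE)
}

#' Pearson correlation coefficient
#'
#' @param x,y numeric vectors of equal length (>= 3), non-constant.
#' @return correlation in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  check_cor_input(x, y)
  dx <- x - mean(x)
  dy <- y - mean(y)
  r <- sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
  max(-1, min(1, r))
}

#' Spearman rank correlation coefficient
#'
#' Pearson correlation of mean ranks (ties receive their average rank);
#' exactly +/-1 for strictly monotone relations.
#'
#' @inheritParams pearson_r
#' @return correlation in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  check_cor_input(x, y)
  pearson_r(rank(x, ties.method = "average"), rank(y, ties.method = "average"))
}

#' Upper-tail hypergeometric probability P(X >= k)
#'
#' For X ~ Hypergeometric(N, K, n) (k shared elements between a set of size
#' K and a set of size n drawn from a universe of size N):
#' sum over i = k..min(K, n) of C(K,i) C(N-K, n-i) / C(N, n), evaluated with
#' log-gamma binomials for numerical stability. This is the shared-sponge
#' significance test: the chance that two genes share at least k miRNA
#' partners by luck given their individual partner counts.
#'
#' @param k observed shared count.
#' @param K,n the two set sizes.
#' @param N universe size.
#' @return tail probability in `[0, 1]`.
#' @export
hypergeom_sf <- function(k, K, n, N) {
  v <- c(k = k, K = K, n = n, N = N)
  if (any(v != floor(v)) || any(v < 0))
    stop("hypergeometric parameters must be non-negative integers", call. = FALSE)
  if (K > N || n > N || k > min(K, n))
    stop(sprintf("inconsistent hypergeometric parameters k=%d K=%d n=%d N=%d",
                 k, K, n, N), call. = FALSE)
  i <- seq.int(max(k, 0L), min(K, n))
  if (!length(i)) return(0)
  terms <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  min(1, sum(exp(terms)))
}

#' Anti-correlation filter for miRNA-ceRNA target pairs
#'
#' For every predicted (miRNA, target) pair, computes Spearman's rho between
#' the miRNA and target expression profiles over all samples and keeps pairs
#' with `rho < threshold_neg` (strict). Pairs whose gene has a constant
#' profile are skipped with a warning.
#'
#' @param targets a target-table data.frame.
#' @param mirna_expr,partner_expr [expression_matrix()] objects sharing the
#'   same sample columns.
#' @param threshold_neg strict retention threshold (default -0.85).
#' @return data.frame `mirna_id`, `partner_id`, `partner_class`, `rho`,
#'   sorted by miRNA id then partner id.
#' @export
filter_mirna_cerna_pairs <- function(targets, mirna_expr, partner_expr,
                                     threshold_neg = -0.85) {
  if (!setequal(colnames(mirna_expr), colnames(partner_expr)))
    stop("expression matrices must share the same sample columns", call. = FALSE)
  samp <- colnames(mirna_expr)
  partner_class <- gene_class_of(partner_expr)
  if (!nrow(targets))
    return(data.frame(mirna_id = character(0), partner_id = character(0),
                      partner_class = character(0), rho = numeric(0)))
  miss_m <- setdiff(unique(targets$mirna_id), rownames(mirna_expr))
  if (length(miss_m))
    stop("miRNA id(s) missing from expression matrix: ",
         paste(miss_m, collapse = ", "), call. = FALSE)
  miss_t <- setdiff(unique(targets$target_id), rownames(partner_expr))
  if (length(miss_t))
    stop("target id(s) missing from expression matrix: ",
         paste(miss_t, collapse = ", "), call. = FALSE)
  rho <- rep(NA_real_, nrow(targets))
  skipped <- character(0)
  for (i in seq_len(nrow(targets))) {
    x <- unclass(mirna_expr)[targets$mirna_id[i], samp]
    y <- unclass(partner_expr)[targets$target_id[i], samp]
    r <- tryCatch(spearman_rho(x, y), error = function(e) NA_real_)
    if (is.na(r))
      skipped <- c(skipped, paste0(targets$mirna_id[i], "~", targets$target_id[i]))
    rho[i] <- r
  }
  if (length(skipped))
    warning("skipped pair(s) with constant expression: ",
            paste(skipped, collapse = ", "))
  keep <- !is.na(rho) & rho < threshold_neg
  out <- data.frame(mirna_id = targets$mirna_id[keep],
                    partner_id = targets$target_id[keep],
                    partner_class = rep(partner_class, sum(keep)),
                    rho = rho[keep], stringsAsFactors = FALSE)
  out <- out[order(out$mirna_id, out$partner_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Candidate ceRNA pairs sharing at least one sponged miRNA
#'
#' Pairs every lncRNA with every mRNA whose post-filter miRNA partner sets
#' intersect. The hypergeometric counts are conditioned on the same filtered
#' pair sets that define the overlap: K and n are the lncRNA's and mRNA's
#' retained partner counts, and N is the number of distinct miRNAs in any
#' retained pair.
#'
#' @param lnc_pairs,mrna_pairs outputs of [filter_mirna_cerna_pairs()] for
#'   lncRNA and mRNA partners respectively.
#' @return data.frame `lnc_id`, `mrna_id`, `shared_mirnas` (list column),
#'   `k`, `K`, `n`, `N`.
#' @export
candidate_cerna_pairs <- function(lnc_pairs, mrna_pairs) {
  lnc_sets <- split(lnc_pairs$mirna_id, lnc_pairs$partner_id)
  mrna_sets <- split(mrna_pairs$mirna_id, mrna_pairs$partner_id)
  N <- length(unique(c(lnc_pairs$mirna_id, mrna_pairs$mirna_id)))
  rows <- list()
  for (l in sort(names(lnc_sets))) {
    for (g in sort(names(mrna_sets))) {
      shared <- sort(intersect(lnc_sets[[l]], mrna_sets[[g]]))
      if (!length(shared)) next
      rows[[length(rows) + 1L]] <- data.frame(
        lnc_id = l, mrna_id = g, shared_mirnas = I(list(shared)),
        k = length(shared), K = length(unique(lnc_sets[[l]])),
        n = length(unique(mrna_sets[[g]])), N = N, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(lnc_id = character(0), mrna_id = character(0),
                      shared_mirnas = I(list()), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assemble the ceRNA network from candidate pairs
#'
#' Applies the three remaining gates to [candidate_cerna_pairs()] output:
#' Pearson co-expression `pcc > threshold_pos` (strict; computed on
#' `log2(x + pseudocount)` by default), shared-sponge significance
#' `p_sponge < alpha` (strict, [hypergeom_sf()]), and cytoplasmic
#' localization of the lncRNA. Each surviving pair is expanded into one
#' lncRNA-miRNA-mRNA triplet per shared miRNA, and a typed [gene_network()]
#' with sponge (lncRNA-miRNA) and target (miRNA-mRNA) edges is assembled.
#'
#' @param candidates output of [candidate_cerna_pairs()].
#' @param lnc_expr,mrna_expr [expression_matrix()] objects.
#' @param localization localization data.frame (`lnc_id`, `compartment`).
#' @param threshold_pos strict Pearson threshold (default 0.9).
#' @param alpha strict sponge-test threshold (default 0.05).
#' @param keep_unlocalized keep lncRNAs absent from the localization table
#'   (default FALSE: excluded with a warning).
#' @param log_transform correlate on log2(x + pseudocount) (default TRUE).
#' @param pseudocount pseudocount for the log transform.
#' @param adjust_sponge apply BH across sponge p-values before gating
#'   (default FALSE: raw p < alpha, as in the source procedure).
#' @return list with `pairs` (retained, with pcc and p_sponge), `triplets`,
#'   `network` (a [gene_network()]), `all_candidates` (annotated, ungated),
#'   and `funnel` (named survivor counts).
#' @export
build_cerna_network <- function(candidates, lnc_expr, mrna_expr, localization,
                                threshold_pos = 0.9, alpha = 0.05,
                                keep_unlocalized = FALSE, log_transform = TRUE,
                                pseudocount = 1, adjust_sponge = FALSE) {
  if (!setequal(colnames(lnc_expr), colnames(mrna_expr)))
    stop("expression matrices must share the same sample columns", call. = FALSE)
  samp <- colnames(lnc_expr)
  cand <- candidates
  tf <- if (log_transform) function(v) log2(v + pseudocount) else identity
  if (nrow(cand)) {
    cand$pcc <- vapply(seq_len(nrow(cand)), function(i) {
      x <- tf(unclass(lnc_expr)[cand$lnc_id[i], samp])
      y <- tf(unclass(mrna_expr)[cand$mrna_id[i], samp])
      tryCatch(pearson_r(x, y), error = function(e) NA_real_)
    }, numeric(1))
    cand$p_sponge <- vapply(seq_len(nrow(cand)), function(i)
      hypergeom_sf(cand$k[i], cand$K[i], cand$n[i], cand$N[i]), numeric(1))
    if (adjust_sponge) cand$p_sponge <- bh_adjust(cand$p_sponge)
  } else {
    cand$pcc <- numeric(0)
    cand$p_sponge <- numeric(0)
  }
  coexp <- cand[!is.na(cand$pcc) & cand$pcc > threshold_pos, , drop = FALSE]
  sig <- coexp[coexp$p_sponge < alpha, , drop = FALSE]
  loc <- stats::setNames(localization$compartment, localization$lnc_id)
  known <- sig$lnc_id %in% names(loc)
  if (any(!known) && !keep_unlocalized)
    warning("excluding lncRNA(s) with no localization annotation: ",
            paste(unique(sig$lnc_id[!known]), collapse = ", "))
  cyto <- ifelse(known, tolower(loc[sig$lnc_id]) == "cytoplasm",
                 keep_unlocalized)
  final <- sig[cyto, , drop = FALSE]
  rownames(final) <- NULL
  triplets <- if (nrow(final)) {
    reps <- lengths(final$shared_mirnas)
    data.frame(lnc_id = rep(final$lnc_id, reps),
               mirna_id = unlist(final$shared_mirnas),
               mrna_id = rep(final$mrna_id, reps), stringsAsFactors = FALSE)
  } else {
    data.frame(lnc_id = character(0), mirna_id = character(0),
               mrna_id = character(0), stringsAsFactors = FALSE)
  }
  rownames(triplets) <- NULL
  net <- gene_network(triplets)
  funnel <- c(candidate_pairs = nrow(cand), coexpressed = nrow(coexp),
              sponge_significant = nrow(sig), localized = nrow(final),
              triplets = nrow(triplets))
  list(pairs = final, triplets = triplets, network = net,
       all_candidates = cand, funnel = funnel)
}
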