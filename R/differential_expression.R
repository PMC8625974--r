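#' Log2 fold change with pseudocount
#'
#' `log2((mean_b + pseudocount) / (mean_a + pseudocount))`; antisymmetric
#' under swapping the two groups.
#'
#' @param mean_a,mean_b non-negative group mean abundances.
#' @param pseudocount positive abundance added to both means.
#' @return log2 ratio (B over A).
#' @export
log2_fold_change <- function(mean_a, mean_b, pseudocount = 1) {
  if (any(pseudocount <= 0)) stop("pseudocount must be > 0", call. = FALSE)
  if (any(mean_a < 0) || any(mean_b < 0))
    stop("group means must be >= 0", call. = FALSE)
  log2((mean_b + pseudocount) / (mean_a + pseudocount))
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Standard step-up: sort p ascending, q_i = min over j >= i of
#' p_j * m / j, clipped at 1, returned in the input order.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return vector of FDR-adjusted values, same order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  m <- length(p_values)
  ord <- order(p_values)
  scaled <- p_values[ord] * m / seq_len(m)
  q <- rev(cummin(rev(scaled)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[ord] <- q
  out
}

# Welch two-sample t-test on pre-transformed values. Degenerate zero-variance
# groups are resolved analytically (equal means -> p = 1, else p = 0) so
# noise-free synthetic data remains testable.
welch_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- stats::var(a); vb <- stats::var(b)
  se2 <- va / na + vb / nb
  d <- mean(b) - mean(a)
  if (se2 == 0) return(if (d == 0) 1 else 0)
  t <- d / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  2 * stats::pt(-abs(t), df)
}

DE_TESTS <- list(welch_log = function(a, b, pseudocount) {
  welch_p(log2(a + pseudocount), log2(b + pseudocount))
})

#' Pairwise comparison plan over ordered stages
#'
#' Enumerates every stage pair (A before B in `stage_order`) in the
#' conventional order: all comparisons of the first stage against each later
#' stage, then the second, and so on (for E8, E13, D1, D10 this is E8 vs
#' E13, E8 vs D1, E8 vs D10, E13 vs D1, E13 vs D10, D1 vs D10).
#'
#' @param stage_order ordered character vector of stage labels.
#' @return data.frame with columns `stage_a`, `stage_b`, `label`.
#' @export
comparison_plan <- function(stage_order) {
  if (length(stage_order) < 2L || anyDuplicated(stage_order))
    stop("stage_order must hold >= 2 unique stages", call. = FALSE)
  idx <- utils::combn(length(stage_order), 2L)
  data.frame(stage_a = stage_order[idx[1L, ]], stage_b = stage_order[idx[2L, ]],
             label = paste(stage_order[idx[1L, ]], "vs", stage_order[idx[2L, ]],
                           sep = "_"),
             stringsAsFactors = FALSE)
}

#' Differential expression test for one stage comparison
#'
#' For every gene, tests group B against group A with the configured
#' two-sample test on `log2(x + pseudocount)` (default: Welch's t-test, a
#' documented stand-in for count-model DE on abundance data), adjusts
#' p-values with [bh_adjust()] within the comparison, and flags genes
#' passing the strict thresholds `fdr < fdr_threshold` and
#' `|log2fc| > lfc_threshold`.
#'
#' @param expr an [expression_matrix()].
#' @param design a [sample_design()] covering the matrix samples.
#' @param comparison length-2 character vector `c(stage_a, stage_b)`.
#' @param fdr_threshold,lfc_threshold strict DE thresholds.
#' @param pseudocount abundance pseudocount for the log transform and fold
#'   change.
#' @param method name of the registered test (currently `"welch_log"`).
#' @return data.frame with one row per gene: `gene_id`, `comparison`,
#'   `mean_a`, `mean_b`, `log2fc`, `p_value`, `fdr`, `is_de`.
#' @export
de_test <- function(expr, design, comparison, fdr_threshold = 0.05,
                    lfc_threshold = 1, pseudocount = 1, method = "welch_log") {
  test_fun <- DE_TESTS[[method]]
  if (is.null(test_fun)) stop("unknown DE test method: ", method, call. = FALSE)
  if (length(comparison) != 2L || comparison[1L] == comparison[2L])
    stop("comparison must name two distinct stages", call. = FALSE)
  miss <- setdiff(comparison, design$stage)
  if (length(miss))
    stop("stage(s) absent from design: ", paste(miss, collapse = ", "),
         call. = FALSE)
  check_design_covers(design, expr)
  cols_a <- design$sample_id[design$stage == comparison[1L]]
  cols_b <- design$sample_id[design$stage == comparison[2L]]
  cols_a <- intersect(cols_a, colnames(expr))
  cols_b <- intersect(cols_b, colnames(expr))
  if (length(cols_a) < 2L || length(cols_b) < 2L)
    stop("insufficient replication: both stages need >= 2 samples", call. = FALSE)
  a <- unclass(expr)[, cols_a, drop = FALSE]
  b <- unclass(expr)[, cols_b, drop = FALSE]
  mean_a <- rowMeans(a)
  mean_b <- rowMeans(b)
  lfc <- log2_fold_change(mean_a, mean_b, pseudocount)
  p <- vapply(seq_len(nrow(a)),
              function(i) test_fun(a[i, ], b[i, ], pseudocount), numeric(1))
  fdr <- bh_adjust(p)
  data.frame(gene_id = rownames(expr),
             comparison = paste(comparison[1L], comparison[2L], sep = "_vs_"),
             mean_a = mean_a, mean_b = mean_b, log2fc = lfc,
             p_value = p, fdr = fdr,
             is_de = fdr < fdr_threshold & abs(lfc) > lfc_threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Run every comparison in a plan
#'
#' @inheritParams de_test
#' @param plan a [comparison_plan()] data.frame.
#' @param ... forwarded to [de_test()].
#' @return named list of per-comparison [de_test()] data.frames.
#' @export
de_test_all <- function(expr, design, plan = comparison_plan(stage_order_of(design)),
                        ...) {
  res <- lapply(seq_len(nrow(plan)), function(i)
    de_test(expr, design, c(plan$stage_a[i], plan$stage_b[i]), ...))
  names(res) <- plan$label
  res
}

#' Pool differentially expressed genes across comparisons
#'
#' Union of gene ids flagged `is_de` in any comparison; the pooled "all DE"
#' gene set that seeds network construction.
#'
#' @param results list of [de_test()] data.frames.
#' @return character vector of unique DE gene ids.
#' @export
pool_de_genes <- function(results) {
  if (!length(results)) stop("no DE results supplied", call. = FALSE)
  ids <- unique(unlist(lapply(results, function(r) r$gene_id[r$is_de])))
  if (!length(ids)) warning("no differentially expressed genes in any comparison")
  ids
}
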