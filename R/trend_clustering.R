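lex_order <- function(mat) do.call(order, as.data.frame(mat))

#' Enumerate candidate trend profiles
#'
#' All integer profiles of length `T` starting at 0 whose successive
#' changes are bounded by `c` in absolute value — `(2c+1)^(T-1)` step
#' sequences — minus the all-flat profile, in deterministic lexicographic
#' order of the value vectors.
#'
#' @param T number of timepoints (>= 2).
#' @param c unit-change bound (>= 1).
#' @return integer matrix, one profile per row.
#' @export
enumerate_candidate_profiles <- function(T, c = 1L) {
  if (T < 2L) stop("need at least 2 timepoints", call. = FALSE)
  if (c < 1L) stop("unit-change bound c must be >= 1", call. = FALSE)
  steps <- expand.grid(rep(list(seq.int(-c, c)), T - 1L))
  vals <- cbind(0L, t(apply(as.matrix(steps), 1L, cumsum)))
  if (T == 2L) vals <- cbind(0L, as.matrix(steps))
  vals <- vals[rowSums(vals != 0L) > 0L, , drop = FALSE]
  vals <- vals[lex_order(vals), , drop = FALSE]
  dimnames(vals) <- NULL
  storage.mode(vals) <- "integer"
  vals
}

profile_cor_dist <- function(a, b) 1 - pearson_r(a, b)

#' Select distinct model profiles by greedy farthest-point sampling
#'
#' Starting from the most-decreasing candidate, repeatedly adds the
#' candidate maximizing the minimum correlation distance
#' `d = 1 - Pearson(values)` to the already-selected set (ties broken by
#' lexicographically smallest value vector). The selected set is re-indexed
#' 0..m-1 by ascending lexicographic order, so the monotone-decreasing
#' profile gets id 0 and the monotone-increasing one id m-1.
#'
#' @param candidates matrix from [enumerate_candidate_profiles()].
#' @param m number of model profiles.
#' @return integer matrix with rownames "0".."m-1", one profile per row.
#' @export
select_model_profiles <- function(candidates, m) {
  nc <- nrow(candidates)
  if (m > nc) stop("m exceeds the number of candidate profiles", call. = FALSE)
  ord <- lex_order(candidates)
  candidates <- candidates[ord, , drop = FALSE]  # lexicographic; row 1 = most decreasing
  selected <- 1L
  if (m > 1L) {
    d <- matrix(NA_real_, nc, nc)
    for (i in seq_len(nc)) for (j in seq_len(nc))
      if (i < j) d[i, j] <- d[j, i] <- profile_cor_dist(candidates[i, ],
                                                        candidates[j, ])
    diag(d) <- 0
    mind <- d[, 1L]
    while (length(selected) < m) {
      mind[selected] <- -Inf
      best <- which(mind == max(mind))[1L]  # candidates are in lex order: ties
      selected <- c(selected, best)         # resolve to the lex-smallest vector
      mind <- pmin(mind, d[, best])
    }
  }
  chosen <- candidates[sort(selected), , drop = FALSE]
  chosen <- chosen[lex_order(chosen), , drop = FALSE]
  rownames(chosen) <- as.character(seq_len(nrow(chosen)) - 1L)
  chosen
}

stage_means <- function(expr, design) {
  stages <- stage_order_of(design)
  idx <- lapply(stages, function(s)
    intersect(design$sample_id[design$stage == s], colnames(expr)))
  if (any(lengths(idx) == 0L))
    stop("design stage(s) with no samples in the matrix", call. = FALSE)
  means <- vapply(idx, function(cols)
    rowMeans(unclass(expr)[, cols, drop = FALSE]), numeric(nrow(expr)))
  if (nrow(expr) == 1L) means <- matrix(means, nrow = 1L)
  dimnames(means) <- list(rownames(expr), stages)
  means
}

assign_one <- function(v, profiles) {
  if (stats::sd(v) == 0) return(c(NA_integer_, NA_real_))
  d <- vapply(seq_len(nrow(profiles)), function(j)
    profile_cor_dist(v, profiles[j, ]), numeric(1))
  best <- which.min(d)  # ties resolve to the lower profile id
  c(best - 1L, d[best])
}

#' Assign genes to model profiles by correlation distance
#'
#' Computes per-gene stage means in stage order and assigns each gene to
#' the profile minimizing `d = 1 - Pearson(stage means, profile values)`
#' (ties to the lower profile id). Genes with constant stage means are
#' excluded from assignment.
#'
#' @param expr an [expression_matrix()].
#' @param design a [sample_design()] whose stage count matches the profile
#'   length.
#' @param profiles matrix from [select_model_profiles()].
#' @return list of class `profile_assignment`: `assignments` (gene_id,
#'   profile_id, distance; NA profile for excluded genes), `profiles`, and
#'   per-profile `counts` (observed o_j).
#' @export
assign_genes <- function(expr, design, profiles) {
  stages <- stage_order_of(design)
  if (length(stages) != ncol(profiles))
    stop(sprintf("profiles have %d timepoints but the design has %d stages",
                 ncol(profiles), length(stages)), call. = FALSE)
  sm <- stage_means(expr, design)
  res <- t(apply(sm, 1L, assign_one, profiles = profiles))
  assignments <- data.frame(gene_id = rownames(expr),
                            profile_id = as.integer(res[, 1L]),
                            distance = res[, 2L],
                            row.names = NULL, stringsAsFactors = FALSE)
  excluded <- sum(is.na(assignments$profile_id))
  if (excluded)
    message(excluded, " gene(s) with constant stage means excluded from ",
            "profile assignment")
  counts <- table(factor(assignments$profile_id,
                         levels = seq_len(nrow(profiles)) - 1L))
  structure(list(assignments = assignments, profiles = profiles,
                 counts = stats::setNames(as.integer(counts), names(counts)),
                 stage_means = sm),
            class = "profile_assignment")
}

permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- permutations(n - 1L)
  out <- matrix(0L, 0L, n)
  for (i in seq_len(n))
    out <- rbind(out, cbind(i, sub + (sub >= i)))
  unname(out)
}

#' Permutation significance of profile occupancy
#'
#' Exact null: for every assignable gene, all `T!` orderings of its stage
#' means are assigned to profiles; the expected count e_j of profile j is
#' the total across genes divided by `T!`. The observed count o_j is then
#' compared with a binomial tail, p_j = P(Binomial(G, e_j / G) >= o_j)
#' where G is the assignable gene count; a profile is significant when
#' `p_j < alpha` (strict).
#'
#' @param assignment a `profile_assignment` from [assign_genes()].
#' @param alpha significance threshold (default 0.05).
#' @return data.frame `profile_id`, `observed`, `expected`, `p`,
#'   `significant`.
#' @export
profile_significance <- function(assignment, alpha = 0.05) {
  profiles <- assignment$profiles
  Tn <- ncol(profiles)
  if (Tn > 7L) stop("exact permutation null supported for T <= 7", call. = FALSE)
  perms <- permutations(Tn)
  sm <- assignment$stage_means
  assignable <- !is.na(assignment$assignments$profile_id)
  G <- sum(assignable)
  null_counts <- numeric(nrow(profiles))
  for (g in which(assignable)) {
    v <- sm[g, ]
    for (r in seq_len(nrow(perms))) {
      a <- assign_one(v[perms[r, ]], profiles)
      if (!is.na(a[1L])) null_counts[a[1L] + 1L] <- null_counts[a[1L] + 1L] + 1L
    }
  }
  expected <- null_counts / nrow(perms)
  observed <- assignment$counts
  p <- vapply(seq_along(expected), function(j) {
    if (G == 0L) return(1)
    stats::pbinom(observed[j] - 1L, G, expected[j] / G, lower.tail = FALSE)
  }, numeric(1))
  data.frame(profile_id = seq_along(expected) - 1L,
             observed = as.integer(observed), expected = expected, p = p,
             significant = p < alpha, row.names = NULL)
}

#' Classify profiles as increasing, decreasing, or complex
#'
#' By the sign of the final value: positive net change is increasing,
#' negative decreasing, zero complex.
#'
#' @param profiles matrix from [select_model_profiles()].
#' @param ids integer profile ids to classify (default: all).
#' @return named character vector keyed by profile id.
#' @export
classify_profiles <- function(profiles, ids = seq_len(nrow(profiles)) - 1L) {
  bad <- setdiff(ids, seq_len(nrow(profiles)) - 1L)
  if (length(bad))
    stop("unknown profile id(s): ", paste(bad, collapse = ", "), call. = FALSE)
  last <- profiles[ids + 1L, ncol(profiles)]
  stats::setNames(ifelse(last > 0L, "increasing",
                  ifelse(last < 0L, "decreasing", "complex")),
                  as.character(ids))
}
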