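test_that("correlations reproduce hand-derived values and extremes", {
  expect_identical(spearman_rho(c(1, 2, 3, 4), c(8, 6, 4, 2)), -1)
  expect_equal(spearman_rho(c(1, 2, 3), c(2, 1, 3)), 0.5)
  expect_identical(spearman_rho(c(1, 2, 2, 3), c(3, 2, 2, 1)), -1)  # tied ranks
  expect_identical(pearson_r(1:10, 2 * (1:10) + 3), 1)
  expect_identical(pearson_r(1:10, -(1:10)), -1)
  expect_equal(pearson_r(c(1, 2, 3), c(1, 3, 2)), 0.5)
})

test_that("correlations agree with stats::cor on random and tied inputs", {
  set.seed(21)
  for (i in 1:300) {
    n <- sample(c(5, 12, 30), 1)
    tied <- i %% 3 == 0
    x <- if (tied) sample(1:4, n, replace = TRUE) + 0 else stats::rnorm(n)
    y <- if (tied) sample(1:4, n, replace = TRUE) + 0 else stats::rnorm(n)
    if (stats::sd(x) == 0 || stats::sd(y) == 0) next
    expect_equal(pearson_r(x, y), stats::cor(x, y), tolerance = 1e-10)
    expect_equal(spearman_rho(x, y), stats::cor(x, y, method = "spearman"),
                 tolerance = 1e-10)
  }
})

test_that("degenerate correlation input raises errors", {
  expect_error(spearman_rho(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pearson_r(c(1, 2, 3), c(5, 5, 5)), "constant")
  expect_error(pearson_r(1:3, 1:4), "length")
  expect_error(pearson_r(c(1, 2), c(3, 4)), "3")
  expect_error(pearson_r(c(1, 2, NA), c(1, 2, 3)), "finite")
})

test_that("hypergeom_sf matches hand enumeration and boundary identities", {
  expect_equal(hypergeom_sf(3, 4, 5, 10), 66 / 252, tolerance = 1e-12)
  expect_equal(hypergeom_sf(0, 3, 4, 9), 1)
  expect_equal(hypergeom_sf(5, 5, 5, 5), 1)
  expect_equal(hypergeom_sf(1, 1, 1, 1), 1)
  expect_error(hypergeom_sf(4, 3, 5, 10), "inconsistent")
  expect_error(hypergeom_sf(1, 5, 3, 4), "inconsistent")
  expect_error(hypergeom_sf(0.5, 2, 2, 4), "integer")
})

test_that("hypergeom_sf agrees with stats::phyper everywhere sampled", {
  set.seed(3)
  for (i in 1:200) {
    N <- sample(2:500, 1)
    K <- sample(0:N, 1)
    n <- sample(0:N, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(hypergeom_sf(k, K, n, N),
                 stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("p_sponge is non-increasing in k at fixed (K, n, N)", {
  for (c_ in list(c(6, 8, 20), c(3, 3, 12), c(10, 5, 40))) {
    p <- vapply(0:min(c_[1], c_[2]), function(k)
      hypergeom_sf(k, c_[1], c_[2], c_[3]), numeric(1))
    expect_true(all(diff(p) <= 1e-15))
  }
})

test_that("anti-correlation filter retains exactly the strict passers", {
  samples <- paste0("s", 1:12)
  up <- 2^(seq(0, 5.5, 0.5))
  mk <- function(rows, class) expression_matrix(
    matrix(unlist(rows), nrow = length(rows), byrow = TRUE,
           dimnames = list(names(rows), samples)), class)
  mir <- mk(list(m_perf = up, m_null = c(5, 3, 8, 2, 9, 4, 7, 1, 6, 8, 2, 5),
                 m_const = rep(2, 12)), "miRNA")
  lnc <- mk(list(l_anti = rev(up), l_null = c(2, 8, 3, 7, 1, 9, 4, 6, 5, 3, 8, 1)),
            "lncRNA")
  targets <- data.frame(
    mirna_id = c("m_perf", "m_perf", "m_null", "m_const"),
    target_id = c("l_anti", "l_null", "l_anti", "l_anti"),
    target_class = "lncRNA", site_class = "6mer", source = "t")
  expect_warning(pairs <- filter_mirna_cerna_pairs(targets, mir, lnc),
                 "constant")
  expect_identical(pairs$mirna_id, "m_perf")
  expect_identical(pairs$partner_id, "l_anti")
  expect_equal(pairs$rho, -1)

  # boundary: rho exactly at the threshold is dropped (strict <)
  expect_equal(nrow(filter_mirna_cerna_pairs(
    targets[1, ], mir, lnc, threshold_neg = -1)), 0)
  missing <- targets; missing$mirna_id[1] <- "m_ghost"
  expect_error(filter_mirna_cerna_pairs(missing, mir, lnc), "m_ghost")
})

test_that("candidate pairing intersects partner sets with the C2 counting", {
  lp <- data.frame(mirna_id = c("m1", "m2", "m4"),
                   partner_id = c("L1", "L1", "L2"),
                   partner_class = "lncRNA", rho = -0.9)
  mp <- data.frame(mirna_id = c("m2", "m3", "m3"),
                   partner_id = c("G1", "G1", "G2"),
                   partner_class = "mRNA", rho = -0.9)
  cands <- candidate_cerna_pairs(lp, mp)
  expect_equal(nrow(cands), 1)
  expect_identical(cands$lnc_id, "L1")
  expect_identical(cands$mrna_id, "G1")
  expect_identical(cands$shared_mirnas[[1]], "m2")
  expect_equal(cands[, c("k", "K", "n", "N")],
               data.frame(k = 1L, K = 2L, n = 2L, N = 4L), ignore_attr = TRUE)

  none <- candidate_cerna_pairs(lp[3, ], mp)
  expect_equal(nrow(none), 0)

  same <- data.frame(mirna_id = c("m1", "m2", "m3"), partner_id = "X",
                     partner_class = "lncRNA", rho = -0.9)
  same2 <- transform(same, partner_id = "Y", partner_class = "mRNA")
  expect_equal(candidate_cerna_pairs(same, same2)$k, 3L)
})

test_that("build_cerna_network applies co-expression, sponge, and localization gates", {
  ds <- small_sim(seed = 4, noise_sd = 0)
  tl <- predict_targets(ds$mirna_fasta, ds$lnc_fasta, "lncRNA")
  tm <- predict_targets(ds$mirna_fasta, ds$mrna_fasta, "mRNA")
  lp <- filter_mirna_cerna_pairs(tl, ds$mirna_expr, ds$lnc_expr)
  mp <- filter_mirna_cerna_pairs(tm, ds$mirna_expr, ds$mrna_expr)
  cands <- candidate_cerna_pairs(lp, mp)
  res <- build_cerna_network(cands, ds$lnc_expr, ds$mrna_expr, ds$localization)
  expect_setequal(triplet_key(res$triplets), triplet_key(ds$truth_triplets))
  expect_true(all(res$pairs$pcc > 0.9))
  expect_true(all(res$pairs$p_sponge < 0.05))
  # each retained pair expands into one triplet per shared miRNA
  expect_equal(sum(lengths(res$pairs$shared_mirnas)), nrow(res$triplets))

  # relabeling a truth lncRNA to Nucleus removes its triplets
  loc2 <- ds$localization
  victim <- ds$truth_triplets$lnc_id[1]
  loc2$compartment[loc2$lnc_id == victim] <- "Nucleus"
  res2 <- build_cerna_network(cands, ds$lnc_expr, ds$mrna_expr, loc2)
  expect_false(victim %in% res2$triplets$lnc_id)
  expect_lt(nrow(res2$triplets), nrow(res$triplets))

  # unlocalized lncRNAs are excluded with a warning unless kept explicitly
  loc3 <- ds$localization[ds$localization$lnc_id != victim, ]
  expect_warning(res3 <- build_cerna_network(cands, ds$lnc_expr, ds$mrna_expr,
                                             loc3), victim)
  expect_false(victim %in% res3$triplets$lnc_id)
  res4 <- build_cerna_network(cands, ds$lnc_expr, ds$mrna_expr, loc3,
                              keep_unlocalized = TRUE)
  expect_true(victim %in% res4$triplets$lnc_id)
})

test_that("a forced single-miRNA overlap is not significant (k=K=n=N=1)", {
  samples <- paste0("s", 1:12)
  up <- 2^(seq(0, 5.5, 0.5))
  lnc <- expression_matrix(matrix(rev(up), 1, dimnames = list("L1", samples)),
                           "lncRNA")
  mrna <- expression_matrix(matrix(rev(up) * 2, 1, dimnames = list("G1", samples)),
                            "mRNA")
  cands <- candidate_cerna_pairs(
    data.frame(mirna_id = "m1", partner_id = "L1", partner_class = "lncRNA",
               rho = -1),
    data.frame(mirna_id = "m1", partner_id = "G1", partner_class = "mRNA",
               rho = -1))
  expect_equal(cands$N, 1L)
  res <- build_cerna_network(cands, lnc, mrna,
                             data.frame(lnc_id = "L1", compartment = "Cytoplasm"))
  expect_equal(res$all_candidates$p_sponge, 1)
  expect_equal(nrow(res$triplets), 0)
  expect_equal(unname(res$funnel["coexpressed"]), 1L)
})

test_that("funnel survivor counts never increase along the pipeline", {
  ds <- small_sim(seed = 2)
  tl <- predict_targets(ds$mirna_fasta, ds$lnc_fasta, "lncRNA")
  tm <- predict_targets(ds$mirna_fasta, ds$mrna_fasta, "mRNA")
  lp <- filter_mirna_cerna_pairs(tl, ds$mirna_expr, ds$lnc_expr)
  mp <- filter_mirna_cerna_pairs(tm, ds$mirna_expr, ds$mrna_expr)
  expect_lte(nrow(lp), nrow(tl))
  expect_lte(nrow(mp), nrow(tm))
  res <- build_cerna_network(candidate_cerna_pairs(lp, mp), ds$lnc_expr,
                             ds$mrna_expr, ds$localization)
  f <- res$funnel
  expect_true(all(diff(f[c("candidate_pairs", "coexpressed",
                           "sponge_significant", "localized")]) <= 0))
})

test_that("retained edges are invariant to input row order", {
  ds <- small_sim(seed = 5)
  tl <- predict_targets(ds$mirna_fasta, ds$lnc_fasta, "lncRNA")
  tm <- predict_targets(ds$mirna_fasta, ds$mrna_fasta, "mRNA")
  run <- function(lnc, mir, mrna, tlo, tmo) {
    lp <- filter_mirna_cerna_pairs(tlo, mir, lnc)
    mp <- filter_mirna_cerna_pairs(tmo, mir, mrna)
    res <- build_cerna_network(candidate_cerna_pairs(lp, mp), lnc, mrna,
                               ds$localization)
    sort(paste(res$network$edges$from, res$network$edges$to))
  }
  base <- run(ds$lnc_expr, ds$mirna_expr, ds$mrna_expr, tl, tm)
  set.seed(9)
  shuffle <- function(m, class) expression_matrix(
    unclass(m)[sample(nrow(m)), , drop = FALSE], class)
  perm <- run(shuffle(ds$lnc_expr, "lncRNA"), shuffle(ds$mirna_expr, "miRNA"),
              shuffle(ds$mrna_expr, "mRNA"), tl[sample(nrow(tl)), ],
              tm[sample(nrow(tm)), ])
  expect_identical(base, perm)
})
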