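test_that("invalid configurations fail naming the offending field", {
  expect_error(sim_config(n_triplets = 50, n_lnc = 10, n_mirna = 10, n_mrna = 10),
               "n_triplets")
  expect_error(sim_config(noise_sd = -1), "noise_sd")
  expect_error(sim_config(frac_cytoplasmic = 1.2), "frac_cytoplasmic")
  expect_error(sim_config(stages = "E8"), "stages")
  expect_error(sim_config(reps_per_stage = 1), "reps_per_stage")
  expect_error(sim_config(base_abundance_range = c(-5, 10)),
               "base_abundance_range")
})

test_that("simulated matrices have the configured shape and shared samples", {
  ds <- simulate_timecourse(sim_config(n_lnc = 50, n_mirna = 20, n_mrna = 100,
                                       n_triplets = 6, mirnas_per_pair = 1,
                                       seed = 4))
  expect_equal(dim(ds$lnc_expr), c(50, 12))
  expect_equal(dim(ds$mirna_expr), c(20, 12))
  expect_equal(dim(ds$mrna_expr), c(100, 12))
  expect_identical(colnames(ds$lnc_expr), colnames(ds$mirna_expr))
  expect_identical(colnames(ds$lnc_expr), colnames(ds$mrna_expr))
  expect_identical(colnames(ds$lnc_expr), ds$design$sample_id)
  expect_equal(nrow(ds$truth_triplets), 6)
})

test_that("noise-free planted pairs hit the correlation extremes exactly", {
  ds <- small_sim(seed = 5, noise_sd = 0)
  for (i in seq_len(nrow(ds$truth_triplets))) {
    t <- ds$truth_triplets[i, ]
    m <- unclass(ds$mirna_expr)[t$mirna_id, ]
    expect_identical(spearman_rho(m, unclass(ds$lnc_expr)[t$lnc_id, ]), -1)
    expect_identical(spearman_rho(m, unclass(ds$mrna_expr)[t$mrna_id, ]), -1)
    expect_gte(pearson_r(unclass(ds$lnc_expr)[t$lnc_id, ],
                         unclass(ds$mrna_expr)[t$mrna_id, ]), 0.99)
  }
})

test_that("truth lncRNAs are cytoplasmic and planted sites occur in both partners", {
  ds <- small_sim(seed = 1)
  loc <- stats::setNames(ds$localization$compartment, ds$localization$lnc_id)
  expect_true(all(loc[unique(ds$truth_triplets$lnc_id)] == "Cytoplasm"))
  for (i in seq_len(nrow(ds$truth_triplets))) {
    t <- ds$truth_triplets[i, ]
    expect_gte(nrow(seed_match_sites(ds$mirna_fasta[[t$mirna_id]],
                                     ds$lnc_fasta[[t$lnc_id]])), 1)
    expect_gte(nrow(seed_match_sites(ds$mirna_fasta[[t$mirna_id]],
                                     ds$mrna_fasta[[t$mrna_id]])), 1)
  }
})

test_that("every planted site is recovered at its offset with its class, and no others", {
  ds <- small_sim(seed = 1)
  planted <- paste(ds$site_table$mirna_id, ds$site_table$target_id)
  all_fa <- c(ds$lnc_fasta, ds$mrna_fasta)
  for (m in names(ds$mirna_fasta)) {
    for (g in names(all_fa)) {
      hits <- seed_match_sites(ds$mirna_fasta[[m]], all_fa[[g]])
      row <- ds$site_table[ds$site_table$mirna_id == m &
                           ds$site_table$target_id == g, ]
      if (nrow(row)) {
        expect_equal(nrow(hits), 1)
        expect_identical(hits$site_class, row$site_class)
        expect_equal(hits$start, row$position)
      } else {
        expect_equal(nrow(hits), 0)
      }
    }
  }
})

test_that("identical seeds reproduce byte-identical datasets", {
  cfg <- sim_config(n_lnc = 10, n_mirna = 8, n_mrna = 12, n_triplets = 4,
                    mirnas_per_pair = 2, seed = 42)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- write_dataset(simulate_timecourse(cfg), d1)
  m2 <- write_dataset(simulate_timecourse(cfg), d2)
  expect_identical(basename(m1), basename(m2))
  for (f in basename(m1))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
})

test_that("plant_seed_sites writes the canonical pattern for each class", {
  mir <- "UGGAAUGUAAAGAAGUAUGUAU"
  polyc <- strrep("C", 30)
  p8 <- plant_seed_sites(mir, polyc, "8mer", 10)
  expect_identical(substr(p8, 11, 18), "ACAUUCCA")
  expect_identical(substr(p8, 1, 10), strrep("C", 10))
  expect_identical(substr(p8, 19, 30), strrep("C", 12))
  p6 <- plant_seed_sites(mir, polyc, "6mer", 10)
  expect_identical(substr(p6, 11, 16), "CAUUCC")
  dna <- plant_seed_sites(mir, strrep("T", 30), "7mer-m8", 3)
  expect_identical(substr(dna, 4, 10), "ACATTCC")
  expect_error(plant_seed_sites(mir, polyc, "8mer", 25), "out of range")
  expect_error(plant_seed_sites("UGGAAUG", polyc, "8mer", 0), ">= 8")
})

test_that("plant-then-scan round-trips recover the planted class and offset", {
  set.seed(31)
  for (cls in c("8mer", "7mer-m8", "7mer-A1", "6mer")) {
    mt <- neutral_plant_mir_target(60)
    mir <- mt$mir
    pos <- 17
    planted <- plant_seed_sites(mir, mt$target, cls, pos)
    hits <- seed_match_sites(mir, planted)
    expect_equal(nrow(hits), 1, label = cls)
    expect_identical(hits$site_class, cls)
    expect_equal(hits$start, pos)
  }
})

test_that("decoy pairs rarely exceed the correlation gates", {
  bad <- 0L; total <- 0L
  for (seed in 1:3) {
    ds <- small_sim(seed = seed)
    decoy_l <- setdiff(rownames(ds$lnc_expr), ds$truth_triplets$lnc_id)
    decoy_m <- setdiff(rownames(ds$mirna_expr), ds$truth_triplets$mirna_id)
    for (l in decoy_l) for (m in decoy_m) {
      r <- spearman_rho(unclass(ds$mirna_expr)[m, ], unclass(ds$lnc_expr)[l, ])
      total <- total + 1L
      if (abs(r) > 0.85) bad <- bad + 1L
    }
  }
  expect_lt(bad / total, 0.05)
})

test_that("write_dataset writes the declared manifest and round-trips", {
  ds <- small_sim(seed = 1)
  dir <- withr::local_tempdir()
  manifest <- write_dataset(ds, dir)
  expect_true(all(file.exists(manifest)))
  back <- read_expression_matrix(manifest[["lnc_expr"]], "lncRNA")
  expect_identical(unclass(back)[, ], unclass(ds$lnc_expr)[, ])
  expect_identical(read_fasta(manifest[["mirna_fasta"]]),
                   chartr("T", "U", ds$mirna_fasta))
  loc <- read_localization_table(manifest[["localization"]])
  expect_identical(loc, ds$localization, ignore_attr = TRUE)
  ds_broken <- ds
  ds_broken$lnc_expr <- ds$lnc_expr[0, , drop = FALSE]
  expect_error(write_dataset(ds_broken, dir), "empty dataset")
})
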