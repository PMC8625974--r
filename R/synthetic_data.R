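SITE_CLASSES <- c("8mer", "7mer-m8", "7mer-A1", "6mer")

rna_of <- function(s) chartr("Tt", "Uu", toupper(s))
dna_of <- function(s) chartr("Uu", "Tt", toupper(s))

revcomp <- function(s, alphabet = c("RNA", "DNA")) {
  alphabet <- match.arg(alphabet)
  s <- toupper(s)
  comp <- if (alphabet == "RNA") chartr("ACGUT", "UGCAA", s) else chartr("ACGUT", "TGCTA", s)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1L]]), collapse = "")
}

# Seed-derived match patterns on the target sense strand (RNA alphabet):
# rc6 = reverse complement of miRNA positions 2-7 (the seed core match),
# rc7 = reverse complement of positions 2-8 = comp(m8) followed by rc6.
seed_patterns <- function(mirna_seq) {
  m <- rna_of(mirna_seq)
  if (nchar(m) < 8L) stop("miRNA sequence must be >= 8 nt", call. = FALSE)
  list(rc6 = revcomp(substr(m, 2L, 7L), "RNA"),
       rc7 = revcomp(substr(m, 2L, 8L), "RNA"))
}

site_pattern <- function(mirna_seq, site_class) {
  p <- seed_patterns(mirna_seq)
  switch(site_class,
         "8mer"    = paste0(p$rc7, "A"),
         "7mer-m8" = p$rc7,
         "7mer-A1" = paste0(p$rc6, "A"),
         "6mer"    = p$rc6,
         stop("unknown site class: ", site_class, call. = FALSE))
}

#' Simulation configuration
#'
#' Describes the synthetic staged expression world: planted ceRNA triplets
#' (miRNA with a monotone increasing stage trend; its partnered lncRNA and
#' mRNA with the mirrored decreasing trend) plus structureless decoys.
#' Planted miRNAs are grouped `mirnas_per_pair` per lncRNA-mRNA pair so the
#' shared-sponge hypergeometric test sees overlaps with k > 1.
#'
#' @param n_lnc,n_mirna,n_mrna gene counts per class.
#' @param n_triplets number of planted (lncRNA, miRNA, mRNA) truth triplets.
#' @param stages ordered stage labels.
#' @param reps_per_stage biological replicates per stage.
#' @param noise_sd standard deviation of multiplicative noise in log2 units.
#' @param base_abundance_range min/max baseline abundance (FPKM/TPM-like).
#' @param frac_cytoplasmic fraction of decoy lncRNAs labeled Cytoplasm
#'   (planted lncRNAs are always cytoplasmic).
#' @param mirnas_per_pair planted miRNAs shared by each lncRNA-mRNA pair.
#' @param stage_fold per-stage geometric fold change of planted trends.
#' @param seed integer RNG seed.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_lnc = 40L, n_mirna = 40L, n_mrna = 80L,
                       n_triplets = 30L,
                       stages = c("E8", "E13", "D1", "D10"),
                       reps_per_stage = 3L, noise_sd = 0.25,
                       base_abundance_range = c(20, 200),
                       frac_cytoplasmic = 0.75,
                       mirnas_per_pair = 3L, stage_fold = 3,
                       seed = 1L) {
  cfg <- list(n_lnc = as.integer(n_lnc), n_mirna = as.integer(n_mirna),
              n_mrna = as.integer(n_mrna), n_triplets = as.integer(n_triplets),
              stages = as.character(stages),
              reps_per_stage = as.integer(reps_per_stage),
              noise_sd = as.numeric(noise_sd),
              base_abundance_range = as.numeric(base_abundance_range),
              frac_cytoplasmic = as.numeric(frac_cytoplasmic),
              mirnas_per_pair = as.integer(mirnas_per_pair),
              stage_fold = as.numeric(stage_fold),
              seed = as.integer(seed))
  bad <- function(field, why) stop(sprintf("invalid sim_config field '%s': %s",
                                           field, why), call. = FALSE)
  for (f in c("n_lnc", "n_mirna", "n_mrna"))
    if (cfg[[f]] < 1L) bad(f, "must be >= 1")
  if (cfg$n_triplets < 1L) bad("n_triplets", "must be >= 1")
  if (cfg$n_triplets > min(cfg$n_lnc, cfg$n_mirna, cfg$n_mrna))
    bad("n_triplets", "exceeds min(n_lnc, n_mirna, n_mrna)")
  if (length(cfg$stages) < 2L) bad("stages", "needs >= 2 stage labels")
  if (anyDuplicated(cfg$stages)) bad("stages", "labels must be unique")
  if (cfg$reps_per_stage < 2L) bad("reps_per_stage", "needs >= 2 replicates")
  if (is.na(cfg$noise_sd) || cfg$noise_sd < 0) bad("noise_sd", "must be >= 0")
  if (length(cfg$base_abundance_range) != 2L ||
      any(cfg$base_abundance_range <= 0) ||
      diff(cfg$base_abundance_range) < 0)
    bad("base_abundance_range", "must be positive (min, max)")
  if (cfg$frac_cytoplasmic < 0 || cfg$frac_cytoplasmic > 1)
    bad("frac_cytoplasmic", "must lie in [0, 1]")
  if (cfg$mirnas_per_pair < 1L) bad("mirnas_per_pair", "must be >= 1")
  if (cfg$stage_fold <= 1) bad("stage_fold", "must exceed 1")
  structure(cfg, class = "sim_config")
}

#' Plant a canonical miRNA seed site into a target sequence
#'
#' Overwrites `target_seq` at a 0-based `position` with the canonical site
#' for `site_class`: the reverse complement of miRNA positions 2-7 (6mer,
#' 7mer-A1) or 2-8 (7mer-m8, 8mer), with an A opposite miRNA position 1 for
#' the A1-anchored classes. The rest of the sequence is unchanged; the
#' planted pattern is written in the target's own alphabet (T if the target
#' contains T, U otherwise).
#'
#' @param mirna_seq miRNA sequence (RNA or DNA letters, length >= 8).
#' @param target_seq target sequence.
#' @param site_class one of `"8mer"`, `"7mer-m8"`, `"7mer-A1"`, `"6mer"`.
#' @param position 0-based offset of the site start on the target.
#' @return the modified target sequence.
#' @export
plant_seed_sites <- function(mirna_seq, target_seq,
                             site_class = c("8mer", "7mer-m8", "7mer-A1", "6mer"),
                             position) {
  site_class <- match.arg(site_class)
  pat <- site_pattern(mirna_seq, site_class)
  is_dna <- grepl("T", toupper(target_seq), fixed = TRUE)
  if (is_dna) pat <- dna_of(pat)
  len <- nchar(pat)
  if (position < 0L || position + len > nchar(target_seq))
    stop(sprintf("site position %d out of range for target of length %d",
                 position, nchar(target_seq)), call. = FALSE)
  substr(target_seq, position + 1L, position + len) <- pat
  target_seq
}

# Footprint of the full potential 8mer around a planted core, used both to
# protect planted sites during background screening and to pin their flanks.
core_start_of <- function(site_class, position) {
  if (site_class %in% c("8mer", "7mer-m8")) position + 1L else position
}

random_seq <- function(n, letters) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

# Generate miRNA sequences whose seed-core match patterns are pairwise
# distinct and cannot be embedded in one another's planted-site footprints
# (shifted by one base in either direction, with arbitrary flanks), so
# background screening can always succeed without touching planted windows.
gen_mirnas <- function(n, len = 22L) {
  seqs <- character(n)
  cores <- character(0)
  compatible <- function(cand) {
    head5 <- substr(cand, 1L, 5L); tail5 <- substr(cand, 2L, 6L)
    if (head5 == tail5) return(FALSE)  # self-periodic core
    for (a in cores) {
      if (cand == a || tail5 == substr(a, 1L, 5L) || head5 == substr(a, 2L, 6L))
        return(FALSE)
    }
    TRUE
  }
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in 1:1000) {
      s <- random_seq(len, c("A", "C", "G", "U"))
      core <- seed_patterns(s)$rc6
      if (compatible(core)) { ok <- TRUE; break }
    }
    if (!ok) stop("could not draw a compatible miRNA seed set", call. = FALSE)
    seqs[i] <- s
    cores <- c(cores, core)
  }
  seqs
}

# Remove every accidental seed-core match from a target sequence, leaving
# the deliberately planted windows untouched. planted: data.frame with
# columns mirna (index into rc6_dna), core_start (0-based), protect_from,
# protect_to (0-based inclusive footprint).
scrub_background <- function(seq, rc6_dna, planted) {
  protected <- integer(0)
  if (nrow(planted))
    protected <- unlist(Map(seq.int, planted$protect_from, planted$protect_to))
  for (iter in 1:500) {
    hits <- NULL
    n <- nchar(seq)
    wins <- substring(seq, seq_len(n - 5L), seq_len(n - 5L) + 5L)
    for (j in seq_along(rc6_dna)) {
      starts0 <- which(wins == rc6_dna[j]) - 1L  # overlapping occurrences
      if (!length(starts0)) next
      ok <- planted$core_start[planted$mirna == j]
      spurious <- setdiff(starts0, ok)
      if (length(spurious))
        hits <- rbind(hits, data.frame(start = spurious, mirna = j))
    }
    if (is.null(hits)) return(seq)
    h <- hits[order(hits$start), , drop = FALSE][1L, ]
    window <- seq.int(h$start, h$start + 5L)
    mutable <- setdiff(window, protected)
    if (!length(mutable))
      stop("unscrubbable seed collision inside a planted site", call. = FALSE)
    pos <- mutable[1L]
    old <- substr(seq, pos + 1L, pos + 1L)
    substr(seq, pos + 1L, pos + 1L) <-
      sample(setdiff(c("A", "C", "G", "T"), old), 1L)
  }
  stop("background screening did not converge", call. = FALSE)
}

build_target_seq <- function(len, mir_idx, mirna_seqs, classes, slots, rc6_dna) {
  if (length(slots) && max(slots) + 8L > len)
    stop("too many planted sites for target length ", len, call. = FALSE)
  for (attempt in 1:50) {
    seq <- random_seq(len, c("A", "C", "G", "T"))
    planted <- data.frame(mirna = integer(0), core_start = integer(0),
                          protect_from = integer(0), protect_to = integer(0))
    ok <- TRUE
    for (i in seq_along(mir_idx)) {
      cls <- classes[i]
      pos <- slots[i]
      seq <- plant_seed_sites(mirna_seqs[mir_idx[i]], seq, cls, pos)
      core <- core_start_of(cls, pos)
      # pin the flanks so the planted class is exactly what is recovered:
      # no accidental m8 extension and no accidental A1 adenosine
      p <- seed_patterns(mirna_seqs[mir_idx[i]])
      m8_dna <- dna_of(substr(p$rc7, 1L, 1L))
      if (!cls %in% c("8mer", "7mer-m8") && core >= 1L) {
        choices <- setdiff(c("C", "G", "T"), m8_dna)
        substr(seq, core, core) <- choices[1L]  # 1-based = core-1 in 0-based
      }
      if (!cls %in% c("8mer", "7mer-A1") && core + 6L < nchar(seq)) {
        substr(seq, core + 7L, core + 7L) <- "C"  # 0-based core+6
      }
      planted <- rbind(planted, data.frame(
        mirna = mir_idx[i], core_start = core,
        protect_from = max(0L, core - 1L),
        protect_to = min(nchar(seq) - 1L, core + 6L)))
    }
    res <- tryCatch(scrub_background(seq, rc6_dna, planted),
                    error = function(e) NULL)
    if (!is.null(res)) return(res)
  }
  stop("could not construct a clean target sequence", call. = FALSE)
}

#' Simulate a staged ceRNA expression time course with planted triplets
#'
#' Planted miRNAs follow a monotone increasing geometric stage trend; their
#' partnered lncRNAs and mRNAs follow the mirrored decreasing trend (high in
#' the embryo, downregulated after hatch), scaled by a per-gene baseline.
#' Decoy genes get a stage-independent baseline. Multiplicative log-normal
#' noise (`noise_sd`, log2 units) is applied per observation, so with
#' `noise_sd = 0` every planted miRNA-target pair has Spearman rho exactly
#' -1 and every planted lncRNA-mRNA pair has Pearson r of 1 over all
#' samples. Sequences carry planted canonical seed sites for every truth
#' triplet and are screened so no seed-core match exists anywhere else.
#'
#' @param config a [sim_config()].
#' @return a list of class `synthetic_dataset` with expression matrices,
#'   the sample design, truth triplets, planted site table, localization
#'   table, and FASTA sequence vectors.
#' @export
simulate_timecourse <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  set.seed(config$seed)
  S <- length(config$stages)
  reps <- config$reps_per_stage
  samples <- as.vector(t(outer(config$stages, seq_len(reps), paste, sep = "_")))
  design <- design_from_sample_ids(samples, stage_order = config$stages)
  stage_idx <- rep(seq_len(S), each = reps)

  n_pairs <- ceiling(config$n_triplets / config$mirnas_per_pair)
  lnc_ids <- sprintf("LNC%03d", seq_len(config$n_lnc))
  mir_ids <- sprintf("MIR%03d", seq_len(config$n_mirna))
  mrna_ids <- sprintf("MRNA%03d", seq_len(config$n_mrna))
  pair_of_mir <- ceiling(seq_len(config$n_triplets) / config$mirnas_per_pair)
  truth <- data.frame(lnc_id = lnc_ids[pair_of_mir],
                      mirna_id = mir_ids[seq_len(config$n_triplets)],
                      mrna_id = mrna_ids[pair_of_mir],
                      stringsAsFactors = FALSE)

  down <- config$stage_fold^(S - seq_len(S))   # high early, low late
  up <- config$stage_fold^(seq_len(S) - 1L)    # miRNA trend, mirrored
  draw_base <- function(n) stats::runif(n, config$base_abundance_range[1L],
                                        config$base_abundance_range[2L])
  make_matrix <- function(ids, planted, trend) {
    base <- draw_base(length(ids))
    mu <- matrix(base, nrow = length(ids), ncol = length(samples))
    if (length(planted))
      mu[planted, ] <- outer(base[planted], rep(1, length(samples))) *
        matrix(trend[stage_idx], nrow = length(planted),
               ncol = length(samples), byrow = TRUE)
    noise <- matrix(2^stats::rnorm(length(mu), 0, config$noise_sd), nrow = nrow(mu))
    vals <- mu * noise
    dimnames(vals) <- list(ids, samples)
    vals
  }
  lnc_vals <- make_matrix(lnc_ids, seq_len(n_pairs), down)
  mir_vals <- make_matrix(mir_ids, seq_len(config$n_triplets), up)
  mrna_vals <- make_matrix(mrna_ids, seq_len(n_pairs), down)

  compartment <- rep("Cytoplasm", config$n_lnc)
  decoy_lnc <- setdiff(seq_len(config$n_lnc), seq_len(n_pairs))
  if (length(decoy_lnc)) {
    cyto <- stats::runif(length(decoy_lnc)) < config$frac_cytoplasmic
    other <- sample(c("Nucleus", "Ribosome", "Exosome"), length(decoy_lnc),
                    replace = TRUE)
    compartment[decoy_lnc] <- ifelse(cyto, "Cytoplasm", other)
  }
  localization <- data.frame(lnc_id = lnc_ids, compartment = compartment,
                             stringsAsFactors = FALSE)

  mirna_seqs <- stats::setNames(gen_mirnas(config$n_mirna), mir_ids)
  rc6_dna <- vapply(mirna_seqs, function(s) dna_of(seed_patterns(s)$rc6), "")
  site_rows <- list()
  gen_targets <- function(ids, len, planted_pairs) {
    seqs <- character(length(ids))
    for (i in seq_along(ids)) {
      mir_idx <- which(planted_pairs == i)
      classes <- SITE_CLASSES[(mir_idx - 1L) %% length(SITE_CLASSES) + 1L]
      slots <- 20L + (seq_along(mir_idx) - 1L) * 40L
      seqs[i] <- build_target_seq(len, mir_idx, mirna_seqs, classes, slots,
                                  rc6_dna)
      if (length(mir_idx))
        site_rows[[length(site_rows) + 1L]] <<- data.frame(
          mirna_id = mir_ids[mir_idx], target_id = ids[i],
          site_class = classes, position = slots, stringsAsFactors = FALSE)
    }
    stats::setNames(seqs, ids)
  }
  planted_lnc <- ifelse(pair_of_mir <= config$n_lnc, pair_of_mir, NA_integer_)
  lnc_pairs_vec <- rep(NA_integer_, config$n_mirna)
  lnc_pairs_vec[seq_len(config$n_triplets)] <- planted_lnc
  lnc_seqs <- gen_targets(lnc_ids, 400L, lnc_pairs_vec)
  mrna_seqs <- gen_targets(mrna_ids, 300L, lnc_pairs_vec)
  site_table <- do.call(rbind, site_rows)

  structure(list(
    lnc_expr = expression_matrix(lnc_vals, "lncRNA"),
    mirna_expr = expression_matrix(mir_vals, "miRNA"),
    mrna_expr = expression_matrix(mrna_vals, "mRNA"),
    design = design,
    truth_triplets = truth,
    site_table = site_table,
    localization = localization,
    mirna_fasta = mirna_seqs,
    lnc_fasta = lnc_seqs,
    mrna_fasta = mrna_seqs,
    config = config), class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_dataset> %d lncRNA, %d miRNA, %d mRNA x %d ",
                     "samples; %d truth triplets\n"),
              nrow(x$lnc_expr), nrow(x$mirna_expr), nrow(x$mrna_expr),
              ncol(x$lnc_expr), nrow(x$truth_triplets)))
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Emits TSV expression matrices, the sample design, FASTA sequences, the
#' truth-triplet table, and the localization table; reading back via the io
#' readers reproduces the values at full precision.
#'
#' @param ds a `synthetic_dataset`.
#' @param out_dir output directory (created if absent).
#' @return named character vector: the manifest of written files.
#' @export
write_dataset <- function(ds, out_dir) {
  if (!inherits(ds, "synthetic_dataset"))
    stop("ds must be a synthetic_dataset", call. = FALSE)
  if (nrow(ds$lnc_expr) == 0L || nrow(ds$mirna_expr) == 0L ||
      nrow(ds$mrna_expr) == 0L)
    stop("empty dataset: expression matrices have no genes", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  manifest <- c(
    lnc_expr = write_expression_matrix(ds$lnc_expr, p("lnc_expr.tsv")),
    mirna_expr = write_expression_matrix(ds$mirna_expr, p("mirna_expr.tsv")),
    mrna_expr = write_expression_matrix(ds$mrna_expr, p("mrna_expr.tsv")),
    design = write_sample_design(ds$design, p("design.tsv")),
    mirna_fasta = write_fasta(ds$mirna_fasta, p("mirna.fa")),
    lnc_fasta = write_fasta(ds$lnc_fasta, p("lnc.fa")),
    mrna_fasta = write_fasta(ds$mrna_fasta, p("mrna.fa")),
    truth = {
      utils::write.table(ds$truth_triplets, p("truth_triplets.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      p("truth_triplets.tsv")
    },
    localization = write_localization_table(ds$localization, p("localization.tsv")))
  manifest
}
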