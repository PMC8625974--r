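#' Pipeline run configuration
#'
#' Collects every input path and threshold of the simulate -> DE -> targets
#' -> network -> hubs -> trends pipeline. Either `simulate` (a [sim_config()]
#' argument list) or the full set of input paths must be given. All
#' thresholds default to the printed values of the source procedure:
#' FDR < 0.05, |log2FC| > 1, Spearman rho < -0.85, PCC > 0.9, sponge
#' p < 0.05, top 5 hubs.
#'
#' @param simulate NULL, or a list of [sim_config()] arguments; when set,
#'   inputs are generated instead of read.
#' @param inputs named list of paths: `lnc_expr`, `mirna_expr`, `mrna_expr`,
#'   `design`, `mirna_fasta`, `lnc_fasta`, `mrna_fasta`, `localization`,
#'   optionally `targets_lnc` / `targets_mrna` (>= 2 paths each for
#'   intersection).
#' @param fdr,lfc,pseudocount DE gate parameters.
#' @param rho_threshold strict Spearman anti-correlation gate (negative).
#' @param pcc_threshold strict Pearson co-expression gate.
#' @param alpha_sponge strict sponge-test threshold.
#' @param keep_unlocalized keep lncRNAs without localization annotation.
#' @param top_k hub count.
#' @param stem_c,stem_m,stem_alpha trend-clustering parameters (unit-change
#'   bound, model profile count, profile significance threshold).
#' @param seed integer RNG seed.
#' @param out_dir output directory.
#' @return list of class `run_config`.
#' @export
run_config <- function(simulate = list(), inputs = list(),
                       fdr = 0.05, lfc = 1, pseudocount = 1,
                       rho_threshold = -0.85, pcc_threshold = 0.9,
                       alpha_sponge = 0.05, keep_unlocalized = FALSE,
                       top_k = 5L, stem_c = 1L, stem_m = 20L,
                       stem_alpha = 0.05, seed = 1L, out_dir = NULL) {
  cfg <- list(simulate = simulate, inputs = inputs, fdr = fdr, lfc = lfc,
              pseudocount = pseudocount, rho_threshold = rho_threshold,
              pcc_threshold = pcc_threshold, alpha_sponge = alpha_sponge,
              keep_unlocalized = isTRUE(keep_unlocalized),
              top_k = as.integer(top_k), stem_c = as.integer(stem_c),
              stem_m = as.integer(stem_m), stem_alpha = stem_alpha,
              seed = as.integer(seed), out_dir = out_dir)
  structure(cfg, class = "run_config")
}

#' Read a JSON run configuration
#' @param path JSON file with [run_config()] fields.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  do.call(run_config, vals)
}

#' Validate a run configuration
#'
#' @param config a [run_config()].
#' @return character vector of issues; empty when the config is runnable.
#' @export
validate_config <- function(config) {
  issues <- character(0)
  add <- function(msg) issues <<- c(issues, msg)
  in_range <- function(x, lo, hi) is.numeric(x) && length(x) == 1L &&
    is.finite(x) && x > lo && x <= hi
  if (!in_range(config$fdr, 0, 1)) add("fdr: must lie in (0, 1]")
  if (!is.numeric(config$lfc) || config$lfc < 0) add("lfc: must be >= 0")
  if (!is.numeric(config$pseudocount) || config$pseudocount <= 0)
    add("pseudocount: must be > 0")
  if (!is.numeric(config$rho_threshold) || config$rho_threshold >= 0 ||
      config$rho_threshold < -1)
    add("rho_threshold: must be negative (anti-correlation gate), in [-1, 0)")
  if (!in_range(config$pcc_threshold, 0, 1))
    add("pcc_threshold: must lie in (0, 1]")
  if (!in_range(config$alpha_sponge, 0, 1))
    add("alpha_sponge: must lie in (0, 1]")
  if (config$top_k < 1L) add("top_k: must be >= 1")
  if (config$stem_c < 1L) add("stem_c: must be >= 1")
  if (config$stem_m < 2L) add("stem_m: must be >= 2")
  if (!in_range(config$stem_alpha, 0, 1)) add("stem_alpha: must lie in (0, 1]")
  simulated <- length(config$simulate) > 0L ||
    identical(config$simulate, list())
  if (length(config$inputs)) {
    need <- c("lnc_expr", "mirna_expr", "mrna_expr", "design",
              "mirna_fasta", "lnc_fasta", "mrna_fasta")
    miss <- setdiff(need, names(config$inputs))
    if (length(miss))
      add(paste0("inputs: missing ", paste(miss, collapse = ", "),
                 "; provide the path(s) or use simulate"))
    for (f in intersect(need, names(config$inputs)))
      if (!file.exists(config$inputs[[f]]))
        add(paste0("inputs$", f, ": file not found: ", config$inputs[[f]]))
    if (is.null(config$inputs$localization) && !config$keep_unlocalized)
      add(paste0("inputs$localization: required unless keep_unlocalized is ",
                 "set; provide a localization TSV"))
  } else if (!simulated) {
    add("either simulate or inputs must be provided")
  }
  issues
}

flatten_pairs <- function(pairs) {
  out <- pairs
  out$shared_mirnas <- vapply(pairs$shared_mirnas, paste, "", collapse = ",")
  out
}

#' Run the full ceRNA inference pipeline
#'
#' Executes, in flowchart order: input loading (or simulation), per-class
#' differential expression over every pairwise stage comparison with pooled
#' DE gating, seed-match target prediction (or intersection of supplied
#' target tables) restricted to DE genes, Spearman anti-correlation
#' filtering, candidate pairing with the hypergeometric shared-sponge test,
#' Pearson co-expression and cytoplasmic-localization gating, triplet
#' expansion, hub-lncRNA ranking, and trend-profile clustering of the
#' network mRNAs. Every intermediate table is written under
#' `config$out_dir` (if set) together with a machine-readable JSON report.
#'
#' @param config a [run_config()].
#' @return the run report: a list with `funnel` (named survivor counts),
#'   `hubs`, `trend` (significance table and categories), `outputs` (file
#'   manifest), `config` echo, and `seed`.
#' @export
run_pipeline <- function(config = run_config()) {
  issues <- validate_config(config)
  if (length(issues))
    stop("invalid run configuration:\n  - ", paste(issues, collapse = "\n  - "),
         call. = FALSE)
  set.seed(config$seed)

  # --- stage: inputs ---------------------------------------------------
  if (length(config$inputs)) {
    lnc <- read_expression_matrix(config$inputs$lnc_expr, "lncRNA")
    mir <- read_expression_matrix(config$inputs$mirna_expr, "miRNA")
    mrna <- read_expression_matrix(config$inputs$mrna_expr, "mRNA")
    design <- read_sample_design(config$inputs$design)
    mirna_fa <- read_fasta(config$inputs$mirna_fasta)
    lnc_fa <- read_fasta(config$inputs$lnc_fasta)
    mrna_fa <- read_fasta(config$inputs$mrna_fasta)
    localization <- if (!is.null(config$inputs$localization))
      read_localization_table(config$inputs$localization)
    else data.frame(lnc_id = character(0), compartment = character(0))
  } else {
    sim_args <- config$simulate
    if (is.null(sim_args$seed)) sim_args$seed <- config$seed
    ds <- simulate_timecourse(do.call(sim_config, sim_args))
    lnc <- ds$lnc_expr; mir <- ds$mirna_expr; mrna <- ds$mrna_expr
    design <- ds$design
    mirna_fa <- ds$mirna_fasta; lnc_fa <- ds$lnc_fasta; mrna_fa <- ds$mrna_fasta
    localization <- ds$localization
  }

  # --- stage: differential expression ----------------------------------
  plan <- comparison_plan(stage_order_of(design))
  de_args <- list(fdr_threshold = config$fdr, lfc_threshold = config$lfc,
                  pseudocount = config$pseudocount)
  de <- lapply(list(lncRNA = lnc, miRNA = mir, mRNA = mrna), function(m)
    do.call(de_test_all, c(list(m, design, plan), de_args)))
  de_ids <- suppressWarnings(lapply(de, pool_de_genes))

  # --- stage: target prediction ----------------------------------------
  get_targets <- function(paths, fasta, class) {
    if (!is.null(paths) && length(paths) >= 2L)
      intersect_targets(lapply(paths, read_target_table))
    else predict_targets(mirna_fa[names(mirna_fa) %in% de_ids$miRNA],
                         fasta[names(fasta) %in% de_ids[[class]]],
                         target_class = class)
  }
  if (!length(de_ids$miRNA) || !length(de_ids$lncRNA) || !length(de_ids$mRNA))
    stop("pipeline stage 'differential_expression': a gene class has no DE ",
         "genes; nothing to build a network from", call. = FALSE)
  targets_lnc <- get_targets(config$inputs$targets_lnc, lnc_fa, "lncRNA")
  targets_mrna <- get_targets(config$inputs$targets_mrna, mrna_fa, "mRNA")
  keep_de <- function(t, ids) t[t$mirna_id %in% de_ids$miRNA &
                                t$target_id %in% ids, , drop = FALSE]
  targets_lnc <- keep_de(targets_lnc, de_ids$lncRNA)
  targets_mrna <- keep_de(targets_mrna, de_ids$mRNA)

  # --- stage: correlation gating and network assembly ------------------
  lnc_pairs <- filter_mirna_cerna_pairs(targets_lnc, mir, lnc,
                                        config$rho_threshold)
  mrna_pairs <- filter_mirna_cerna_pairs(targets_mrna, mir, mrna,
                                         config$rho_threshold)
  cands <- candidate_cerna_pairs(lnc_pairs, mrna_pairs)
  net_res <- build_cerna_network(cands, lnc, mrna, localization,
                                 threshold_pos = config$pcc_threshold,
                                 alpha = config$alpha_sponge,
                                 keep_unlocalized = config$keep_unlocalized,
                                 pseudocount = config$pseudocount)

  # --- stage: hubs and trends ------------------------------------------
  hubs <- if (nrow(net_res$network$nodes))
    suppressWarnings(hub_lncrnas(net_res$network, config$top_k))
  else character(0)
  net_mrnas <- unique(net_res$triplets$mrna_id)
  trend <- NULL
  if (length(net_mrnas) >= 1L) {
    profiles <- select_model_profiles(
      enumerate_candidate_profiles(length(stage_order_of(design)),
                                   config$stem_c), config$stem_m)
    sub <- expression_matrix(unclass(mrna)[net_mrnas, , drop = FALSE], "mRNA")
    assignment <- suppressMessages(assign_genes(sub, design, profiles))
    sig <- profile_significance(assignment, config$stem_alpha)
    categories <- classify_profiles(profiles,
                                    sig$profile_id[sig$significant])
    trend <- list(profiles = profiles, assignment = assignment,
                  significance = sig, categories = categories)
  }

  funnel <- c(targets_lnc = nrow(targets_lnc), targets_mrna = nrow(targets_mrna),
              corr_lnc = nrow(lnc_pairs), corr_mrna = nrow(mrna_pairs),
              net_res$funnel)
  report <- list(
    package_version = as.character(utils::packageVersion("cernakit")),
    seed = config$seed,
    n_de = lengths(de_ids),
    funnel = funnel,
    hubs = hubs,
    significant_profiles = if (is.null(trend)) integer(0) else
      trend$significance$profile_id[trend$significance$significant],
    profile_categories = if (is.null(trend)) character(0) else trend$categories,
    thresholds = config[c("fdr", "lfc", "rho_threshold", "pcc_threshold",
                          "alpha_sponge", "top_k", "stem_c", "stem_m",
                          "stem_alpha")])

  outputs <- character(0)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(config$out_dir, f)
    emit <- function(df, f) {
      utils::write.table(df, p(f), sep = "\t", quote = FALSE, row.names = FALSE)
      outputs <<- c(outputs, p(f))
    }
    for (cls in names(de))
      emit(do.call(rbind, c(de[[cls]], make.row.names = FALSE)),
           paste0("de_", cls, ".tsv"))
    emit(data.frame(gene_id = unlist(de_ids, use.names = FALSE),
                    gene_class = rep(names(de_ids), lengths(de_ids))),
         "de_pooled.tsv")
    emit(targets_lnc, "targets_lnc.tsv")
    emit(targets_mrna, "targets_mrna.tsv")
    emit(lnc_pairs, "pairs_mirna_lnc.tsv")
    emit(mrna_pairs, "pairs_mirna_mrna.tsv")
    emit(flatten_pairs(net_res$all_candidates), "cerna_candidates.tsv")
    emit(flatten_pairs(net_res$pairs), "cerna_pairs.tsv")
    emit(net_res$triplets, "cerna_triplets.tsv")
    if (nrow(net_res$network$edges)) {
      write_network(net_res$network, p("network.gml"), "gml")
      write_network(net_res$network, p("network_edges.tsv"), "edge_tsv")
      outputs <- c(outputs, p("network.gml"), p("network_edges.tsv"))
    }
    emit(data.frame(rank = seq_along(hubs), lnc_id = hubs), "hubs.tsv")
    if (!is.null(trend)) {
      emit(data.frame(profile_id = rownames(trend$profiles),
                      values = apply(trend$profiles, 1L, paste, collapse = ",")),
           "trend_profiles.tsv")
      emit(trend$assignment$assignments, "trend_assignments.tsv")
      emit(trend$significance, "trend_significance.tsv")
    }
    report$outputs <- basename(outputs)  # relative: byte-identical across dirs
    jsonlite::write_json(report, p("report.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    report$outputs <- c(outputs, p("report.json"))
  }

  c(report, list(de = de, targets = list(lncRNA = targets_lnc,
                                         mRNA = targets_mrna),
                 pairs = list(lncRNA = lnc_pairs, mRNA = mrna_pairs),
                 network = net_res, trend = trend))
}
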