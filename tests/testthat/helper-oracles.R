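# Independent oracle implementations used to cross-check the package's own
# routines. These deliberately take different computational routes.

# Literal Benjamini-Hochberg step-up, as written on paper: sort ascending,
# q_(i) = min over j >= i of p_(j) * m / j, clip at 1, restore input order.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[ord] <- q
  out
}

# Exhaustive hypergeometric tail: enumerate every n-subset of 1..N and count
# how many share >= k elements with 1..K.
oracle_hyper_enum <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  overlap <- colSums(draws <= K)
  mean(overlap >= k)
}

# Brute-force seed-site scanner: tests every target offset against the full
# literal pattern of each site class, then keeps the maximal class per seed
# core occurrence.
oracle_seed_scan <- function(mirna_seq, target_seq) {
  to_rna <- function(s) chartr("Tt", "Uu", toupper(s))
  rc <- function(s) {
    comp <- chartr("ACGU", "UGCA", s)
    paste(rev(strsplit(comp, "")[[1]]), collapse = "")
  }
  m <- to_rna(mirna_seq)
  t <- to_rna(target_seq)
  rc6 <- rc(substr(m, 2, 7))
  rc7 <- rc(substr(m, 2, 8))
  pats <- list("8mer" = paste0(rc7, "A"), "7mer-m8" = rc7,
               "7mer-A1" = paste0(rc6, "A"), "6mer" = rc6)
  found <- list()
  for (cls in names(pats)) {
    pat <- pats[[cls]]
    L <- nchar(pat)
    for (i in 0:(nchar(t) - L)) {
      if (substr(t, i + 1, i + L) == pat) {
        core <- if (cls %in% c("8mer", "7mer-m8")) i + 1 else i
        found[[length(found) + 1]] <- data.frame(
          core = core, start = i, end = i + L, site_class = cls,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(found))
    return(data.frame(start = integer(0), end = integer(0),
                      site_class = character(0), stringsAsFactors = FALSE))
  df <- do.call(rbind, found)
  rank <- match(df$site_class, c("8mer", "7mer-m8", "7mer-A1", "6mer"))
  best <- do.call(rbind, lapply(split(df, df$core), function(d)
    d[which.min(match(d$site_class, c("8mer", "7mer-m8", "7mer-A1", "6mer"))), ]))
  best <- best[order(best$core), c("start", "end", "site_class")]
  rownames(best) <- NULL
  best
}

random_nt <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# A homogeneous target background that cannot extend a planted site: its
# letter is neither A (no accidental A1 anchor) nor the complement of miRNA
# position 8 (no accidental m8 extension), and the miRNA is redrawn if its
# seed core is a homopolymer of that letter.
neutral_plant_mir_target <- function(len = 60) {
  repeat {
    mir <- random_nt(22, c("A", "C", "G", "U"))
    comp_m8 <- chartr("ACGU", "TGCA", substr(mir, 8, 8))
    letter <- setdiff(c("C", "G", "T"), comp_m8)[1]
    core_rna <- substr(mir, 2, 7)
    core_match <- paste(rev(strsplit(chartr("ACGU", "TGCA", core_rna),
                                     "")[[1]]), collapse = "")
    if (core_match != strrep(letter, 6))
      return(list(mir = mir, target = strrep(letter, len)))
  }
}

triplet_key <- function(df) paste(df$lnc_id, df$mirna_id, df$mrna_id)

# Small synthetic dataset reused across tests (cached per session).
small_sim <- local({
  cache <- new.env()
  function(seed = 1, noise_sd = 0.25) {
    key <- paste0("s", seed, "_", noise_sd)
    if (is.null(cache[[key]]))
      cache[[key]] <- simulate_timecourse(sim_config(
        n_lnc = 12, n_mirna = 12, n_mrna = 20, n_triplets = 8,
        mirnas_per_pair = 4, noise_sd = noise_sd, seed = seed))
    cache[[key]]
  }
})
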