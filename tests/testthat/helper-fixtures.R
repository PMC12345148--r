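# Fixtures are built in code. Two cached simulations back most tests: a
# small colony for fast checks and the full default study conditions for the
# recovery/concordance suites. Independent brute-force oracles live here too
# and deliberately share no code with the package internals they check.

.fixture_cache <- new.env(parent = emptyenv())

small_sim_config <- function(seed = 42) {
  sim_config(
    contig_lengths = c(cA = 30000L, cB = 20000L),
    n_genes = 16, n_snps = 40, n_shared_sites = 120,
    doublehet_excess = 0.5, seed = seed
  )
}

# small simulated colony: genome, truth, pileups, mask, per-animal calls
small_study <- function() {
  if (!is.null(.fixture_cache$small)) return(.fixture_cache$small)
  cfg <- small_sim_config()
  genome <- simulate_genome(cfg)
  truth <- plant_truth(cfg, genome)
  pile <- simulate_pileups(genome, truth, cfg)
  mask <- call_exome_snps(pile$dna)
  calls <- call_edit_sites(pile$rna, mask = mask,
                           features = genome$features,
                           genome = genome$sequence) |>
    dplyr::left_join(pile$samples[, c("sample_id", "genotype")],
                     by = "sample_id")
  .fixture_cache$small <- list(cfg = cfg, genome = genome, truth = truth,
                               pile = pile, mask = mask, calls = calls)
  .fixture_cache$small
}

# the full default study conditions, written to disk and run end to end
default_study <- function() {
  if (!is.null(.fixture_cache$default)) return(.fixture_cache$default)
  cfg <- sim_config()
  dir <- file.path(tempdir(), "editomer_default_study")
  study <- simulate_study(cfg, dir)
  report <- run_pipeline(study$config, verbose = FALSE)
  .fixture_cache$default <- list(cfg = cfg, study = study, report = report)
  .fixture_cache$default
}

# one pileup record
pu_row <- function(contig, pos, ref, nA = 0, nC = 0, nG = 0, nT = 0,
                   sample_id = "s1") {
  tibble::tibble(contig = contig, pos = as.integer(pos), ref = ref,
                 nA = as.integer(nA), nC = as.integer(nC),
                 nG = as.integer(nG), nT = as.integer(nT),
                 depth = as.integer(nA + nC + nG + nT),
                 sample_id = sample_id)
}

# --- independent oracles -------------------------------------------------

# per-animal detection probability by direct double summation over depth and
# variant reads (dbinom/dpois only; no shared code with the package)
oracle_detection_prob <- function(f, depth_mean, error_rate,
                                  min_depth = 10, min_variant_reads = 3,
                                  lo = 0.05, hi = 0.95,
                                  complex_fraction = 0.05) {
  p <- f * (1 - error_rate) + (1 - f) * error_rate / 3
  e3 <- error_rate / 3
  total <- 0
  z <- 1 - dpois(0, depth_mean)
  for (d in 1:(depth_mean + 12 * ceiling(sqrt(depth_mean)) + 20)) {
    if (d < min_depth) next
    wd <- dpois(d, depth_mean) / z
    pd <- 0
    for (k in 0:d) {
      if (k < min_variant_reads) next
      if (k / d < lo || k / d > hi) next
      pd <- pd + dbinom(k, d, p)
    }
    cthr <- max(1, ceiling(complex_fraction * d))
    p_one <- sum(dbinom(cthr:d, d, e3))
    total <- total + wd * pd * (1 - p_one)^2
  }
  total
}

# naive per-record edit caller: a position-by-position loop over plain
# column vectors, with a linear scan over gene spans for strand context
oracle_call_edits <- function(pileups, mask_positions, unassessable,
                              spans, min_depth = 10, min_variant_reads = 3,
                              lo = 0.05, hi = 0.95, complex_fraction = 0.05,
                              drop_unassessable = TRUE) {
  p <- as.list(pileups)
  keep <- logical(nrow(pileups))
  change <- character(nrow(pileups))
  vr_out <- integer(nrow(pileups))
  for (i in seq_len(nrow(pileups))) {
    key <- paste(p$contig[i], p$pos[i])
    if (key %in% mask_positions) next
    if (drop_unassessable && key %in% unassessable) next
    strands <- character(0)
    for (j in seq_len(nrow(spans))) {
      if (spans$contig[j] == p$contig[i] && p$pos[i] >= spans$start[j] &&
          p$pos[i] <= spans$end[j]) {
        strands <- c(strands, spans$strand[j])
      }
    }
    if (p$ref[i] == "A" && (length(strands) == 0 || "+" %in% strands)) {
      vr <- p$nG[i]; third <- max(p$nC[i], p$nT[i]); ch <- "A>G"
    } else if (p$ref[i] == "T" &&
               (length(strands) == 0 || "-" %in% strands)) {
      vr <- p$nC[i]; third <- max(p$nA[i], p$nG[i]); ch <- "T>C"
    } else next
    if (p$depth[i] < min_depth) next
    if (vr < min_variant_reads) next
    ef <- vr / p$depth[i]
    if (ef < lo || ef > hi) next
    if (third / p$depth[i] >= complex_fraction) next
    keep[i] <- TRUE; change[i] <- ch; vr_out[i] <- vr
  }
  data.frame(contig = p$contig[keep], pos = p$pos[keep],
             change = change[keep], sample_id = p$sample_id[keep],
             variant_reads = vr_out[keep], stringsAsFactors = FALSE)
}

# exhaustive Venn partition by membership signatures
oracle_venn_counts <- function(sets) {
  universe <- unique(unlist(sets))
  sig <- vapply(universe, function(el) {
    paste(names(sets)[vapply(sets, function(s) el %in% s, logical(1))],
          collapse = "&")
  }, character(1))
  table(sig)
}

# linear-scan feature assignment with the 3'UTR-first precedence
oracle_assign <- function(sites, features, repeats) {
  prec <- c("three_prime_utr", "five_prime_utr", "cds", "intron")
  feature_class <- character(nrow(sites))
  gene_id <- rep(NA_character_, nrow(sites))
  repeat_class <- rep(NA_character_, nrow(sites))
  for (i in seq_len(nrow(sites))) {
    best <- Inf; best_gene <- NA_character_
    for (j in seq_len(nrow(features))) {
      if (features$contig[j] == sites$contig[i] &&
          sites$pos[i] >= features$start[j] &&
          sites$pos[i] <= features$end[j]) {
        rank <- match(features$class[j], prec)
        if (rank < best ||
            (rank == best && features$gene_id[j] < best_gene)) {
          best <- rank; best_gene <- features$gene_id[j]
        }
      }
    }
    feature_class[i] <- if (is.finite(best)) prec[best] else "intergenic"
    gene_id[i] <- if (is.finite(best)) best_gene else NA_character_
    bw <- Inf; bc <- NA_character_
    for (j in seq_len(nrow(repeats))) {
      if (repeats$contig[j] == sites$contig[i] &&
          sites$pos[i] >= repeats$start[j] &&
          sites$pos[i] <= repeats$end[j]) {
        w <- repeats$end[j] - repeats$start[j] + 1
        if (w < bw || (w == bw && repeats$class[j] < bc)) {
          bw <- w; bc <- repeats$class[j]
        }
      }
    }
    repeat_class[i] <- bc
  }
  data.frame(feature_class = feature_class, gene_id = gene_id,
             repeat_class = repeat_class, stringsAsFactors = FALSE)
}

# two-sided Fisher p by explicit enumeration of all tables with the
# observed margins, using choose() directly
oracle_fisher_p <- function(tab) {
  m <- sum(tab[1, ]); n_ <- sum(tab[2, ]); k <- sum(tab[, 1])
  prob_of <- function(a) {
    choose(m, a) * choose(n_, k - a) / choose(m + n_, k)
  }
  p_obs <- prob_of(tab[1, 1])
  total <- 0
  for (a in max(0, k - n_):min(k, m)) {
    pa <- prob_of(a)
    if (pa <= p_obs * (1 + 1e-7)) total <- total + pa
  }
  min(1, total)
}

# Benjamini-Hochberg step-up, written out longhand
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (i in n:1) {
    val <- min(prev, p[o[i]] * n / i)
    adj[o[i]] <- val
    prev <- val
  }
  adj
}
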