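# The synthetic-data generator: construction contracts, determinism,
# ground-truth invariants, and the binomial detection oracle.

test_that("config validation rejects impossible study designs", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(editing_fraction_range = c(0, 0.5)),
               class = "editomer_config_error")
  expect_error(sim_config(placement_weights = c(intergenic = 0.7,
                                                cds = 0.7)),
               class = "editomer_config_error")
  expect_error(sim_config(placement_weights = c(promoter = 1)),
               class = "editomer_config_error")
  expect_error(sim_config(isg_multipliers = c(WT = 1)),
               class = "editomer_config_error")
})

test_that("an empty genome request yields sequence but no annotation", {
  cfg <- sim_config(contig_lengths = c(solo = 5000L), n_genes = 0,
                    repeat_density = c(SINE = 0, LINE = 0,
                                       DNA_transposon = 0,
                                       other_retrotransposon = 0),
                    n_snps = 0, n_shared_sites = 0, doublehet_excess = 0)
  g <- simulate_genome(cfg)
  expect_equal(nchar(g$sequence[["solo"]]), 5000L)
  expect_equal(nrow(g$features), 0)
  expect_equal(nrow(g$repeats), 0)
})

test_that("gene loci tile with the 5'UTR-CDS/intron-3'UTR structure", {
  cfg <- sim_config(contig_lengths = c(c1 = 20000L), n_genes = 2,
                    exons_per_gene = 3, n_snps = 0, n_shared_sites = 0,
                    doublehet_excess = 0)
  g <- simulate_genome(cfg)
  expect_setequal(unique(g$features$gene_id), c("g001", "g002"))
  for (gid in c("g001", "g002")) {
    f <- g$features[g$features$gene_id == gid, ]
    expect_equal(sum(f$class == "five_prime_utr"), 1)
    expect_equal(sum(f$class == "three_prime_utr"), 1)
    expect_equal(sum(f$class == "cds"), 3)
    expect_equal(sum(f$class == "intron"), 2)
    expect_length(unique(f$strand), 1)
    # non-overlapping blocks within the gene
    o <- order(f$start)
    expect_true(all(f$start[o][-1] > f$end[o][-length(o)]))
  }
  expect_true(all(g$features$start >= 1 & g$features$end <= 20000))
})

test_that("a contig too small for its genes raises a sizing error", {
  cfg <- sim_config(contig_lengths = c(tiny = 2000L), n_genes = 5,
                    n_snps = 0, n_shared_sites = 0, doublehet_excess = 0)
  expect_error(simulate_genome(cfg), class = "editomer_sizing_error",
               regexp = "tiny")
})

test_that("the same seed reproduces byte-identical genome and features", {
  cfg <- small_sim_config()
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  expect_identical(g1$sequence, g2$sequence)
  expect_identical(g1$features, g2$features)
  expect_identical(g1$repeats, g2$repeats)
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_genome_fasta(g1$sequence, f1)
  write_genome_fasta(g2$sequence, f2)
  expect_identical(readLines(f1), readLines(f2))
  tr1 <- plant_truth(cfg, g1)
  tr2 <- plant_truth(cfg, g2)
  expect_identical(tr1$edit_sites, tr2$edit_sites)
  p1 <- simulate_pileups(g1, tr1, cfg)
  p2 <- simulate_pileups(g2, tr2, cfg)
  expect_identical(p1$rna, p2$rna)
  expect_identical(p1$dna, p2$dna)
})

test_that("planted truth respects strand, separation and placement rules", {
  s <- small_study()
  es <- s$truth$edit_sites
  # every edit site sits on an adenosine of its assigned strand
  expect_true(all(es$ref[es$strand == "+"] == "A"))
  expect_true(all(es$ref[es$strand == "-"] == "T"))
  chars <- lapply(s$genome$sequence, function(x) strsplit(x, "")[[1]])
  expect_true(all(mapply(function(ct, p, r) chars[[ct]][p] == r,
                         es$contig, es$pos, es$ref)))
  # SNPs and edit sites never coincide
  expect_length(intersect(paste(es$contig, es$pos),
                          paste(s$truth$snps$contig, s$truth$snps$pos)), 0)
  # zygosity mix as configured
  expect_equal(sum(s$truth$snps$zygosity == "het"),
               round(s$cfg$n_snps * s$cfg$snp_het_fraction))
})

test_that("degenerate placement weights put every site in that class", {
  cfg <- sim_config(contig_lengths = c(c1 = 30000L), n_genes = 10,
                    n_snps = 0, n_shared_sites = 10, doublehet_excess = 0,
                    placement_weights = c(three_prime_utr = 1),
                    seed = 5)
  g <- simulate_genome(cfg)
  tr <- plant_truth(cfg, g)
  expect_equal(nrow(tr$edit_sites), 10)
  utr3 <- g$features[g$features$class == "three_prime_utr", ]
  inside <- vapply(seq_len(nrow(tr$edit_sites)), function(i) {
    any(utr3$contig == tr$edit_sites$contig[i] &
          utr3$start <= tr$edit_sites$pos[i] &
          utr3$end >= tr$edit_sites$pos[i])
  }, logical(1))
  expect_true(all(inside))
  expect_true(all(tr$edit_sites$feature_class == "three_prime_utr"))
})

test_that("the DoubleHet-unique quota is exact and exclusive", {
  cfg <- sim_config(contig_lengths = c(c1 = 50000L), n_genes = 10,
                    n_snps = 0, n_shared_sites = 100,
                    doublehet_excess = 0.4, seed = 3)
  g <- simulate_genome(cfg)
  tr <- plant_truth(cfg, g)
  expect_equal(nrow(tr$edit_sites), 140)
  expect_equal(sum(!is.na(tr$edit_sites$unique_to)), 40)
  expect_true(all(stats::na.omit(tr$edit_sites$unique_to) == "DoubleHet"))
})

test_that("impossible placement demands raise a placement error", {
  cfg <- sim_config(contig_lengths = c(c1 = 5000L), n_genes = 2,
                    n_snps = 0, n_shared_sites = 2000,
                    doublehet_excess = 0,
                    placement_weights = c(five_prime_utr = 1))
  g <- simulate_genome(cfg)
  expect_error(plant_truth(cfg, g), class = "editomer_placement_error",
               regexp = "five_prime_utr")
})

test_that("detection probabilities match an independent binomial-sum oracle", {
  for (f in c(0.1, 0.3, 0.5, 0.8)) {
    expect_equal(detection_probability(f, depth_mean = 50,
                                       error_rate = 0.005),
                 oracle_detection_prob(f, 50, 0.005), tolerance = 1e-10)
  }
  # and the analytic expected consensus count is the oracle's fourth power
  s <- small_study()
  es <- s$truth$edit_sites
  shared <- es[is.na(es$unique_to), ]
  expect_equal(
    s$truth$expected$expected_consensus_sites[
      s$truth$expected$genotype == "WT"],
    sum(vapply(shared$fraction, oracle_detection_prob, numeric(1),
               depth_mean = s$cfg$rna_depth_mean,
               error_rate = s$cfg$error_rate)^4),
    tolerance = 1e-8
  )
})

test_that("zero-noise pileups contain only reference and planted signal", {
  cfg <- sim_config(contig_lengths = c(c1 = 4000L), n_genes = 1,
                    n_snps = 0, n_shared_sites = 0, doublehet_excess = 0,
                    error_rate = 0, animals_per_genotype = 1,
                    repeat_density = c(SINE = 0, LINE = 0,
                                       DNA_transposon = 0,
                                       other_retrotransposon = 0))
  g <- simulate_genome(cfg)
  tr <- plant_truth(cfg, g)
  pl <- simulate_pileups(g, tr, cfg)
  ref_count <- with(pl$rna, ifelse(ref == "A", nA, ifelse(ref == "C", nC,
                             ifelse(ref == "G", nG, nT))))
  expect_true(all(ref_count == pl$rna$depth))
  expect_true(all(pl$rna$depth >= 1))
})

test_that("DNA pileups reflect zygosity and never editing", {
  s <- small_study()
  dna <- s$pile$dna
  hom <- s$truth$snps[s$truth$snps$zygosity == "hom", ]
  rows <- dplyr::inner_join(dna, hom, by = c("contig", "pos"))
  alt_n <- with(rows, ifelse(alt == "A", nA, ifelse(alt == "C", nC,
                       ifelse(alt == "G", nG, nT))))
  # homozygous alternate: essentially every read carries the alternate
  expect_true(all(alt_n / rows$depth > 0.9))
  # DNA shows no signal at planted edit sites beyond the error rate
  es_rows <- dplyr::inner_join(dna, s$truth$edit_sites,
                               by = c("contig", "pos"))
  var_n <- with(es_rows, ifelse(ref.x == "A", nG, nC))
  expect_lt(mean(var_n / es_rows$depth), 0.01)
})

test_that("planted editing fractions are recovered at high depth", {
  cfg <- sim_config(contig_lengths = c(c1 = 300L), n_genes = 0,
                    n_snps = 0, n_shared_sites = 1, doublehet_excess = 0,
                    editing_fraction_range = c(0.499999, 0.500001),
                    placement_weights = c(intergenic = 1),
                    rna_depth_mean = 1000, animals_per_genotype = 25,
                    repeat_density = c(SINE = 0, LINE = 0,
                                       DNA_transposon = 0,
                                       other_retrotransposon = 0),
                    seed = 9)
  g <- simulate_genome(cfg)
  tr <- plant_truth(cfg, g)
  pl <- simulate_pileups(g, tr, cfg)
  site <- tr$edit_sites[1, ]
  rows <- pl$rna[pl$rna$pos == site$pos & pl$rna$contig == site$contig, ]
  var_n <- if (site$ref == "A") rows$nG else rows$nC
  p_g <- 0.5 * (1 - cfg$error_rate) + 0.5 * cfg$error_rate / 3
  se <- sqrt(p_g * (1 - p_g) / sum(rows$depth))
  expect_lt(abs(sum(var_n) / sum(rows$depth) - p_g), 3 * se)
})
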