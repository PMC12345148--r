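# Germline masking and per-animal edit calling: threshold rules, strand
# soundness, mask behaviour, and equivalence with a naive per-record oracle.

features_1gene <- function(strand, contig = "c1", start = 100, end = 500,
                           gene_id = "gX") {
  tibble::tibble(contig = contig, start = as.integer(start),
                 end = as.integer(end), strand = strand, gene_id = gene_id,
                 class = "cds")
}

test_that("exome SNP calling follows the depth and fraction thresholds", {
  dna <- dplyr::bind_rows(
    pu_row("c1", 10, "A", nA = 20, nG = 20, sample_id = "dna"),  # het
    pu_row("c1", 20, "A", nA = 40, sample_id = "dna"),           # clean
    pu_row("c1", 30, "C", nC = 2, nT = 2, sample_id = "dna"),    # shallow
    pu_row("c1", 40, "G", nG = 36, nA = 4, sample_id = "dna")    # 10% alt
  )
  m <- call_exome_snps(dna, min_depth = 10, min_alt_fraction = 0.1)
  expect_equal(m$mask$pos, c(10L, 40L))
  expect_equal(m$mask$alt[m$mask$pos == 10], "G")
  expect_equal(m$unassessable$pos, 30L)
  expect_true(all(m$mask$provenance == "exome"))
})

test_that("unsorted DNA pileups are rejected with the offending position", {
  dna <- dplyr::bind_rows(pu_row("c1", 20, "A", nA = 30),
                          pu_row("c1", 10, "A", nA = 30))
  expect_error(call_exome_snps(dna), class = "editomer_order_error",
               regexp = "10")
})

test_that("known-variant merging is an idempotent union with provenance", {
  dna <- pu_row("c1", 10, "A", nA = 20, nG = 20, sample_id = "dna")
  m <- call_exome_snps(dna)
  merged <- merge_known_variants(m, tibble::tibble(contig = "c1",
                                                   pos = c(10L, 99L)))
  expect_equal(merged$mask$pos, c(10L, 99L))
  expect_equal(merged$mask$provenance, c("both", "supplied"))
  again <- merge_known_variants(merged, tibble::tibble(contig = "c1",
                                                       pos = c(10L, 99L)))
  expect_equal(again$mask, merged$mask)
  # union size matches a set oracle on random instances
  set.seed(1)
  for (i in 1:5) {
    a <- sample(1:200, 60); b <- sample(1:200, 60)
    ma <- merge_known_variants(NULL, tibble::tibble(contig = "z", pos = a))
    mu <- merge_known_variants(ma, tibble::tibble(contig = "z", pos = b))
    expect_equal(nrow(mu$mask), length(union(a, b)))
  }
  expect_error(merge_known_variants(m, tibble::tibble(contig = "c1",
                                                      pos = c(1.5))),
               class = "editomer_parse_error")
})

test_that("calls obey arithmetic and strand-consistency rules", {
  feats <- dplyr::bind_rows(features_1gene("+", gene_id = "gP"),
                            features_1gene("-", start = 600, end = 900,
                                           gene_id = "gM"))
  pu <- dplyr::bind_rows(
    pu_row("c1", 150, "A", nA = 14, nG = 6),        # + gene: A>G, 0.30
    pu_row("c1", 650, "T", nT = 21, nC = 9),        # - gene: T>C, 0.30
    pu_row("c1", 700, "A", nA = 14, nG = 6),        # A>G in - gene: blocked
    pu_row("c1", 950, "T", nT = 21, nC = 9),        # intergenic T>C
    pu_row("c1", 960, "G", nG = 14, nA = 6)         # ref G never eligible
  )
  calls <- call_edit_sites(pu, features = feats)
  expect_equal(nrow(calls), 3)
  c150 <- calls[calls$pos == 150, ]
  expect_equal(c150$change, "A>G")
  expect_equal(c150$strand, "+")
  expect_equal(c150$editing_fraction, 0.3)
  expect_equal(c150$gene_id, "gP")
  c650 <- calls[calls$pos == 650, ]
  expect_equal(c650$change, "T>C")
  expect_equal(c650$strand, "-")
  c950 <- calls[calls$pos == 950, ]
  expect_equal(c950$strand, "unstranded")
  expect_true(is.na(c950$gene_id))
})

test_that("masked and unassessable positions yield no calls", {
  pu <- dplyr::bind_rows(
    pu_row("c1", 10, "A", nA = 10, nG = 10),
    pu_row("c1", 20, "A", nA = 10, nG = 10),
    pu_row("c1", 30, "A", nA = 10, nG = 10)
  )
  mask <- editomer:::new_snp_mask(
    tibble::tibble(contig = "c1", pos = 10L, ref = "A", alt = "G",
                   provenance = "exome"),
    tibble::tibble(contig = "c1", pos = 20L)
  )
  got <- call_edit_sites(pu, mask = mask)
  expect_equal(got$pos, 30L)
  kept <- call_edit_sites(pu, mask = mask, drop_unassessable = FALSE)
  expect_setequal(kept$pos, c(20L, 30L))
  flagged <- call_edit_sites(pu, mask = mask, keep_filtered = TRUE)
  expect_equal(flagged$filter_flags[flagged$pos == 10], "snp_mask")
  expect_equal(flagged$filter_flags[flagged$pos == 20], "unassessable_dna")
})

test_that("depth, variant-read, fraction-window and complex filters apply", {
  pu <- dplyr::bind_rows(
    pu_row("c1", 10, "A", nA = 4, nG = 4),            # depth 8 < 10
    pu_row("c1", 20, "A", nA = 18, nG = 2),           # 2 variant reads
    pu_row("c1", 30, "A", nA = 98, nG = 2),           # fraction 0.02
    pu_row("c1", 40, "A", nG = 40),                   # fraction 1 > 0.95
    pu_row("c1", 50, "A", nA = 12, nG = 6, nT = 2),   # complex (nT 10%)
    pu_row("c1", 60, "A", nA = 14, nG = 6)            # clean call
  )
  calls <- call_edit_sites(pu)
  expect_equal(calls$pos, 60L)
  flagged <- call_edit_sites(pu, keep_filtered = TRUE)
  expect_equal(flagged$filter_flags[flagged$pos == 50], "complex")
  # a retained call has an empty flag set
  expect_equal(flagged$filter_flags[flagged$pos == 60], "")
})

test_that("a pileup/genome reference disagreement is a hard error", {
  genome <- c(c1 = paste(rep("C", 100), collapse = ""))
  pu <- pu_row("c1", 5, "A", nA = 14, nG = 6)
  expect_error(call_edit_sites(pu, genome = genome),
               class = "editomer_reference_mismatch", regexp = "c1:5")
})

test_that("calling matches a naive per-record oracle on a simulated colony", {
  s <- small_study()
  # one animal's pileup restricted to candidate-bearing records keeps the
  # quadratic oracle tractable while exercising every rule
  rna <- s$pile$rna
  pu <- rna[rna$sample_id == "WT_1" &
              ((rna$ref == "A" & rna$nG > 0) |
                 (rna$ref == "T" & rna$nC > 0)), ]
  spans <- s$genome$features |>
    dplyr::group_by(contig, gene_id, strand) |>
    dplyr::summarise(start = min(start), end = max(end), .groups = "drop")
  expected <- oracle_call_edits(
    pu,
    mask_positions = paste(s$mask$mask$contig, s$mask$mask$pos),
    unassessable = paste(s$mask$unassessable$contig,
                         s$mask$unassessable$pos),
    spans = spans
  )
  got <- call_edit_sites(pu, mask = s$mask, features = s$genome$features,
                         genome = s$genome$sequence)
  expect_equal(nrow(got), nrow(expected))
  expect_setequal(paste(got$contig, got$pos, got$change),
                  paste(expected$contig, expected$pos, expected$change))
  # and under a second threshold setting
  expected2 <- oracle_call_edits(
    pu, mask_positions = paste(s$mask$mask$contig, s$mask$mask$pos),
    unassessable = character(0), spans = spans,
    min_depth = 20, min_variant_reads = 5, lo = 0.1, hi = 0.9,
    drop_unassessable = FALSE
  )
  got2 <- call_edit_sites(pu, mask = s$mask, features = s$genome$features,
                          min_depth = 20, min_variant_reads = 5,
                          fraction_range = c(0.1, 0.9),
                          drop_unassessable = FALSE)
  expect_setequal(paste(got2$contig, got2$pos, got2$change),
                  paste(expected2$contig, expected2$pos, expected2$change))
})

test_that("tightening thresholds never increases the number of calls", {
  s <- small_study()
  pu <- s$pile$rna[s$pile$rna$sample_id == "DoubleHet_2", ]
  base <- nrow(call_edit_sites(pu, mask = s$mask,
                               features = s$genome$features))
  for (md in c(15, 25, 40)) {
    expect_lte(nrow(call_edit_sites(pu, mask = s$mask,
                                    features = s$genome$features,
                                    min_depth = md)), base)
  }
  prev <- base
  for (mv in c(4, 6, 10)) {
    cur <- nrow(call_edit_sites(pu, mask = s$mask,
                                features = s$genome$features,
                                min_variant_reads = mv))
    expect_lte(cur, prev)
    prev <- cur
  }
})

test_that("no calls arise at planted SNP positions with adequate DNA depth", {
  s <- small_study()
  assessable_snps <- dplyr::anti_join(s$truth$snps, s$mask$unassessable,
                                      by = c("contig", "pos"))
  hits <- dplyr::semi_join(s$calls, assessable_snps,
                           by = c("contig", "pos"))
  expect_equal(nrow(hits), 0)
})

test_that("call output is sorted by sample then position", {
  s <- small_study()
  cl <- s$calls
  o <- order(cl$sample_id, cl$contig, cl$pos)
  expect_identical(cl$pos, cl$pos[o])
})
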