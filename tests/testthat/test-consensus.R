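# Replicate-consensus rules and cross-genotype set comparison.

fake_calls <- function(...) {
  # list of per-animal site vectors "contig:pos:change"
  per <- list(...)
  dplyr::bind_rows(lapply(seq_along(per), function(i) {
    parts <- strsplit(per[[i]], ":", fixed = TRUE)
    tibble::tibble(
      contig = vapply(parts, `[`, character(1), 1),
      pos = as.integer(vapply(parts, `[`, character(1), 2)),
      change = vapply(parts, `[`, character(1), 3),
      sample_id = paste0("a", i)
    )
  }))
}

test_that("a site must be edited in all animals to reach consensus", {
  calls <- fake_calls(
    c("c:10:A>G", "c:20:A>G"),
    c("c:10:A>G", "c:20:A>G"),
    c("c:10:A>G", "c:20:A>G"),
    c("c:10:A>G")                # animal 4 lacks site 20
  )
  cs <- consensus_sites(calls)
  expect_equal(cs$pos, 10L)
  # k-of-n generalisation
  cs3 <- consensus_sites(calls, n_required = 3)
  expect_setequal(cs3$pos, c(10L, 20L))
  expect_error(consensus_sites(calls, n_required = 5),
               class = "editomer_parameter_error")
  # opposite-orientation events at one coordinate are distinct sites
  two <- fake_calls(c("c:30:A>G", "c:30:T>C"), c("c:30:A>G"))
  expect_equal(consensus_sites(two)$change, "A>G")
})

test_that("consensus sites equal a brute-force intersection on random sets", {
  set.seed(7)
  for (rep in 1:5) {
    per <- lapply(1:4, function(i) {
      sprintf("c:%d:A>G", sample(1:80, 30))
    })
    calls <- do.call(fake_calls, per)
    got <- consensus_sites(calls)
    want <- Reduce(intersect, per)
    expect_setequal(sprintf("c:%d:A>G", got$pos), want)
  }
})

test_that("gene consensus allows editing anywhere in the gene", {
  feats <- tibble::tibble(
    contig = "c", start = c(1L, 101L), end = c(100L, 200L),
    strand = "+", gene_id = c("gA", "gB"), class = "cds"
  )
  # gA edited at site 10 in animals 1-2 and site 90 in animals 3-4
  calls <- fake_calls(c("c:10:A>G"), c("c:10:A>G"),
                      c("c:90:A>G"), c("c:90:A>G"))
  cg <- consensus_genes(calls, feats)
  expect_equal(cg$gene_id, "gA")
  # ...while neither site reaches site-level consensus
  expect_equal(nrow(consensus_sites(calls)), 0)
  # a gene edited in only 3 of 4 animals is excluded
  calls3 <- fake_calls(c("c:10:A>G"), c("c:20:A>G"), c("c:30:A>G"),
                       c("c:150:A>G"))
  expect_equal(nrow(consensus_genes(calls3, feats)), 0)
  # unknown gene ids in calls are a consistency error
  bad <- dplyr::mutate(calls, gene_id = "ghost")
  expect_error(consensus_genes(bad, feats),
               class = "editomer_consistency_error")
})

test_that("genes of consensus sites are always a subset of consensus genes", {
  set.seed(11)
  feats <- tibble::tibble(
    contig = "c", start = seq(1L, 901L, by = 100L),
    end = seq(100L, 1000L, by = 100L), strand = "+",
    gene_id = sprintf("g%02d", 1:10), class = "cds"
  )
  for (rep in 1:5) {
    per <- lapply(1:4, function(i) sprintf("c:%d:A>G", sample(1:1000, 120)))
    calls <- do.call(fake_calls, per)
    cs <- consensus_sites(calls)
    cg <- consensus_genes(calls, feats)
    genes_of_sites <- unique(feats$gene_id[
      vapply(cs$pos, function(p) which(feats$start <= p & feats$end >= p)[1],
             integer(1))])
    expect_true(all(stats::na.omit(genes_of_sites) %in% cg$gene_id))
  }
})

test_that("Venn cells partition the union and match exhaustive enumeration", {
  set.seed(3)
  for (rep in 1:5) {
    sets <- lapply(setNames(1:4, c("WT", "Adar_het", "RdRp_tg",
                                   "DoubleHet")), function(i) {
      as.character(sample(1:60, sample(10:40, 1)))
    })
    vp <- venn_partition(sets)
    expect_equal(nrow(vp), 15)
    # disjoint cells covering the union
    all_members <- unlist(vp$members)
    expect_equal(anyDuplicated(all_members), 0)
    expect_setequal(all_members, unique(unlist(sets)))
    # counts equal the signature-table oracle
    want <- oracle_venn_counts(sets)
    got <- setNames(vp$n, vp$cell)
    for (cell in names(want)) {
      expect_equal(unname(got[cell]), unname(as.integer(want[cell])))
    }
    expect_equal(sum(vp$n[!vp$cell %in% names(want)]), 0)
  }
})

test_that("Venn partitioning is invariant under set relabeling", {
  sets <- list(A = c("x", "y", "z"), B = c("y"), C = c("z", "w"),
               D = character(0))
  vp1 <- venn_partition(sets)
  vp2 <- venn_partition(rev(sets))
  for (i in seq_len(nrow(vp1))) {
    lab <- sort(vp1$labels[[i]])
    match2 <- which(vapply(vp2$labels, function(l)
      identical(sort(l), lab), logical(1)))
    expect_equal(vp2$n[match2], vp1$n[i])
  }
  expect_error(venn_partition(list(A = 1, A = 2)),
               class = "editomer_parameter_error")
})

test_that("degenerate set configurations give the expected cells", {
  same <- list(a = letters[1:5], b = letters[1:5], c = letters[1:5],
               d = letters[1:5])
  vp <- venn_partition(same)
  expect_equal(vp$n[vp$degree == 4], 5)
  expect_equal(sum(vp$n[vp$degree < 4]), 0)
  expect_true(all(lengths(unique_sets(vp)) == 0))
  disj <- list(a = letters[1:3], b = letters[4:6], c = letters[7:9],
               d = letters[10:12])
  vd <- venn_partition(disj)
  expect_true(all(vd$n[vd$degree == 1] == 3))
  expect_true(all(vd$n[vd$degree > 1] == 0))
  expect_equal(unique_sets(vd)[["a"]], letters[1:3])
})

test_that("percent change is plain arithmetic on the baseline", {
  counts <- tibble::tibble(genotype = c("WT", "Adar_het", "DoubleHet"),
                           n = c(1000, 1000, 1600))
  pc <- percent_change(counts)
  expect_equal(pc$percent_change[pc$genotype == "DoubleHet"], 60)
  expect_equal(pc$percent_change[pc$genotype == "Adar_het"], 0)
  expect_error(percent_change(tibble::tibble(genotype = "WT", n = 0)),
               class = "editomer_undefined_change")
  expect_error(percent_change(counts, baseline = "missing"),
               class = "editomer_parameter_error")
})
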