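# Simulated RNA and DNA base-count pileups with a truncated-Poisson coverage
# model and symmetric substitution errors (rate e/3 to each non-template base).

# slot of base j for template base t: 0 when j == t, otherwise the rank of
# j among the three non-template bases in alphabetical order
ERROR_SLOT <- local({
  m <- matrix(0L, 4, 4, dimnames = list(BASES, BASES))
  for (t in 1:4) m[t, -t] <- 1:3
  m
})

# multinomial error split by sequential binomial thinning: each of the three
# non-template bases receives errors at rate e/3
split_errors <- function(m, error_rate) {
  e3 <- error_rate / 3
  b1 <- rbinom(length(m), m, e3)
  b2 <- rbinom(length(m), m - b1, e3 / (1 - e3))
  b3 <- rbinom(length(m), m - b1 - b2, e3 / (1 - 2 * e3))
  list(keep = m - b1 - b2 - b3, err = list(b1, b2, b3))
}

# add a template class (template base tb, read counts m) into 4 count vectors
add_template <- function(acc, tb_col, m, error_rate) {
  sp <- split_errors(m, error_rate)
  for (j in 1:4) {
    slot <- ERROR_SLOT[cbind(tb_col, j)]
    acc[[j]] <- acc[[j]] + (slot == 0L) * sp$keep +
      (slot == 1L) * sp$err[[1]] + (slot == 2L) * sp$err[[2]] +
      (slot == 3L) * sp$err[[3]]
  }
  acc
}

# one pileup over the whole genome for one sample.
# special: tibble(contig, pos, alt, alt_frac, exact) — positions where a
# second template allele is present; exact=TRUE means alt template count is
# depth * alt_frac deterministically (homozygous), otherwise Binomial.
build_pileup <- function(chars, lens, depth_mean, error_rate, special,
                         sample_id) {
  per_contig <- lapply(names(lens), function(ct) {
    L <- lens[[ct]]
    depth <- rpois_trunc1(L, depth_mean)
    ref <- chars[[ct]]
    ref_col <- match(ref, BASES)
    acc <- add_template(list(integer(L), integer(L), integer(L), integer(L)),
                        ref_col, depth, error_rate)
    sp <- special[special$contig == ct, , drop = FALSE]
    if (nrow(sp) > 0) {
      i <- sp$pos
      d <- depth[i]
      t_alt <- as.integer(ifelse(sp$exact, round(d * sp$alt_frac),
                                 rbinom(nrow(sp), d, sp$alt_frac)))
      sub <- add_template(list(integer(nrow(sp)), integer(nrow(sp)),
                               integer(nrow(sp)), integer(nrow(sp))),
                          ref_col[i], d - t_alt, error_rate)
      sub <- add_template(sub, match(sp$alt, BASES), t_alt, error_rate)
      for (j in 1:4) acc[[j]][i] <- sub[[j]]
    }
    tibble(contig = ct, pos = seq_len(L), ref = ref,
           nA = as.integer(acc[[1]]), nC = as.integer(acc[[2]]),
           nG = as.integer(acc[[3]]), nT = as.integer(acc[[4]]),
           depth = depth, sample_id = sample_id)
  })
  bind_rows(per_contig)
}

#' Simulate per-animal RNA pileups and a pooled DNA (exome) pileup
#'
#' For every animal, per-site RNA depth is Poisson(`rna_depth_mean`)
#' truncated at >= 1. At planted edit sites applicable to the animal's
#' genotype the variant template (G on a plus-strand adenosine, C on a
#' minus-strand one) is carried by `Binomial(depth, fraction)` reads; at
#' germline SNP positions the alternate allele is carried at its zygosity
#' fraction (0.5 heterozygous, 1 homozygous) in both RNA and DNA; everywhere
#' else non-reference counts arise only from the symmetric error model. The
#' pooled DNA pileup reflects zygosity and never editing. The simulated DNA
#' evidence covers the whole toy genome so that intergenic sites are
#' assessable for germline variation.
#'
#' @param genome A [simulate_genome()] result.
#' @param truth A [plant_truth()] result.
#' @param config The [sim_config()] used for both.
#' @return A `sim_pileups` list: `rna` (tibble with columns `contig`, `pos`,
#'   `ref`, `nA`, `nC`, `nG`, `nT`, `depth`, `sample_id`, sorted by position
#'   within each sample), `dna` (same shape, `sample_id = "exome_pool"`) and
#'   `samples` (tibble: `sample_id`, `animal`, `genotype`).
#' @export
simulate_pileups <- function(genome, truth, config) {
  stopifnot(inherits(genome, "sim_genome"), inherits(truth, "sim_truth"),
            inherits(config, "sim_config"))
  chars <- genome_chars(genome$sequence)
  lens <- genome$contig_lengths

  snp_special <- tibble(
    contig = truth$snps$contig, pos = truth$snps$pos, alt = truth$snps$alt,
    alt_frac = ifelse(truth$snps$zygosity == "hom", 1, 0.5),
    exact = truth$snps$zygosity == "hom"
  )

  set.seed(config$seed + 500L)
  dna <- build_pileup(chars, lens, config$dna_depth_mean, config$error_rate,
                      snp_special, "exome_pool")

  samples <- tidyr::expand_grid(genotype = config$genotypes,
                                animal = seq_len(config$animals_per_genotype)) |>
    mutate(sample_id = paste(.data$genotype, .data$animal, sep = "_")) |>
    select("sample_id", "animal", "genotype")

  es <- truth$edit_sites
  rna <- purrr::map_dfr(seq_len(nrow(samples)), function(i) {
    g <- samples$genotype[i]
    app <- es[is.na(es$unique_to) | es$unique_to == g, , drop = FALSE]
    edit_special <- tibble(
      contig = app$contig, pos = app$pos,
      alt = as.character(ifelse(app$ref == "A", "G", "C")),
      alt_frac = app$fraction, exact = logical(nrow(app))
    )
    set.seed(config$seed + 1000L + i)
    build_pileup(chars, lens, config$rna_depth_mean, config$error_rate,
                 bind_rows(snp_special, edit_special), samples$sample_id[i])
  })

  structure(list(rna = rna, dna = dna, samples = samples),
            class = "sim_pileups")
}

#' Simulate a gene-level expression count table
#'
#' Per-gene baseline means are log-normal; ISG transcripts are scaled by the
#' configured per-genotype multipliers; counts are negative-binomial with the
#' configured dispersion. This feeds the minimal differential-expression
#' plumbing ([minimal_deg_call()]) so the ISG summary logic can be exercised
#' end to end; it is independent of the pileup coverage model.
#'
#' @inheritParams simulate_pileups
#' @return Long tibble: `gene_id`, `sample_id`, `genotype`, `count`.
#' @export
simulate_expression <- function(genome, truth, config) {
  stopifnot(inherits(genome, "sim_genome"), inherits(truth, "sim_truth"),
            inherits(config, "sim_config"))
  set.seed(config$seed + 5000L)
  gene_ids <- sort(unique(genome$features$gene_id))
  base <- rlnorm(length(gene_ids), log(config$expression_base_mean), 1)
  is_isg <- gene_ids %in% truth$isg_genes
  samples <- tidyr::expand_grid(genotype = config$genotypes,
                                animal = seq_len(config$animals_per_genotype))
  purrr::map_dfr(seq_len(nrow(samples)), function(i) {
    g <- samples$genotype[i]
    mult <- ifelse(is_isg, config$isg_multipliers[[g]], 1)
    tibble(
      gene_id = gene_ids,
      sample_id = paste(g, samples$animal[i], sep = "_"),
      genotype = g,
      count = rnbinom(length(gene_ids), mu = base * mult,
                      size = config$expression_dispersion)
    )
  })
}
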