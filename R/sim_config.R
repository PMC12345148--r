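#' Configuration for the synthetic editome study
#'
#' Bundles every tunable of the synthetic-data generator: the toy genome
#' (contig lengths, gene structure, repeat densities), the colony (germline
#' SNP count and zygosity mix), the editing regime (a shared site pool edited
#' in all four genotypes plus a pool unique to the double heterozygote, sized
#' by `doublehet_excess`), sequencing (coverage means, per-base error rate)
#' and the interferon-stimulated-gene (ISG) expression regime.
#'
#' Defaults emulate a four-genotype x four-animal design in which the double
#' heterozygote carries a unique edit-site pool sized for a 50-65% excess of
#' detectable consensus sites over the other genotypes, planted sites
#' concentrate in intergenic regions and 3'UTRs, and ISG expression in the
#' double heterozygote is four-fold that of the RdRp transgenic.
#'
#' @param contig_lengths Named integer vector of contig lengths (bp).
#' @param n_genes Total genes tiled across contigs (proportional to length).
#' @param exons_per_gene Integer vector of admissible CDS exon counts;
#'   each gene draws uniformly from it.
#' @param utr5_length,cds_exon_length,intron_length,utr3_length Lengths (bp)
#'   of the fixed per-gene feature blocks.
#' @param repeat_density Named vector, elements per Mb for the four repeat
#'   classes `SINE`, `LINE`, `DNA_transposon`, `other_retrotransposon`.
#' @param genotypes Genotype labels; default `WT`, `Adar_het`, `RdRp_tg`,
#'   `DoubleHet`.
#' @param animals_per_genotype Replicate animals per genotype (default 4).
#' @param n_snps Germline colony SNPs planted uniformly over the genome.
#' @param snp_het_fraction Fraction of SNPs that are heterozygous (rest
#'   homozygous alternate).
#' @param n_shared_sites Edit sites edited in every genotype.
#' @param doublehet_excess Size of the DoubleHet-unique site pool as a
#'   fraction of `n_shared_sites` (default 0.575, the midpoint of a 50-65%
#'   excess window).
#' @param editing_fraction_range Per-site editing fraction is drawn uniformly
#'   from this open interval.
#' @param placement_weights Named weights (summing to 1) over
#'   `intergenic`, `three_prime_utr`, `cds`, `intron`, `five_prime_utr`
#'   governing where edit sites are planted.
#' @param rna_depth_mean,dna_depth_mean Mean per-site coverage; depth is
#'   Poisson(mean) truncated at >= 1.
#' @param error_rate Per-base sequencing error rate; a read shows each of the
#'   three non-template bases with probability `error_rate / 3`.
#' @param isg_fraction Fraction of genes flagged as ISGs.
#' @param isg_multipliers Named per-genotype expression multipliers applied
#'   to ISG transcripts.
#' @param expression_base_mean Log-normal location (on the count scale) of
#'   per-gene baseline expression.
#' @param expression_dispersion Negative-binomial size parameter for counts.
#' @param seed Integer seed; all randomness flows from it (per-stage and
#'   per-animal substreams use fixed offsets).
#'
#' @return A `sim_config` object (validated named list).
#' @examples
#' cfg <- sim_config(contig_lengths = c(chr = 50000), n_genes = 10,
#'                   n_shared_sites = 50, n_snps = 20)
#' cfg$n_unique_sites
#' @export
sim_config <- function(contig_lengths = c(chrS1 = 250000L, chrS2 = 250000L),
                       n_genes = 200,
                       exons_per_gene = 2:3,
                       utr5_length = 100,
                       cds_exon_length = 200,
                       intron_length = 300,
                       utr3_length = 300,
                       repeat_density = c(SINE = 120, LINE = 60,
                                          DNA_transposon = 30,
                                          other_retrotransposon = 30),
                       genotypes = GENOTYPES,
                       animals_per_genotype = 4,
                       n_snps = 200,
                       snp_het_fraction = 0.5,
                       n_shared_sites = 1000,
                       doublehet_excess = 0.575,
                       editing_fraction_range = c(0.2, 0.8),
                       placement_weights = c(intergenic = 0.5,
                                             three_prime_utr = 0.3,
                                             cds = 0.1, intron = 0.1,
                                             five_prime_utr = 0),
                       rna_depth_mean = 50,
                       dna_depth_mean = 40,
                       error_rate = 0.005,
                       isg_fraction = 0.2,
                       isg_multipliers = c(WT = 1, Adar_het = 1,
                                           RdRp_tg = 2, DoubleHet = 8),
                       expression_base_mean = 200,
                       expression_dispersion = 10,
                       seed = 20260101L) {
  cfg <- list(
    contig_lengths = contig_lengths, n_genes = as.integer(n_genes),
    exons_per_gene = as.integer(exons_per_gene),
    utr5_length = as.integer(utr5_length),
    cds_exon_length = as.integer(cds_exon_length),
    intron_length = as.integer(intron_length),
    utr3_length = as.integer(utr3_length),
    repeat_density = repeat_density,
    genotypes = genotypes,
    animals_per_genotype = as.integer(animals_per_genotype),
    n_snps = as.integer(n_snps), snp_het_fraction = snp_het_fraction,
    n_shared_sites = as.integer(n_shared_sites),
    doublehet_excess = doublehet_excess,
    n_unique_sites = as.integer(round(n_shared_sites * doublehet_excess)),
    editing_fraction_range = editing_fraction_range,
    placement_weights = placement_weights,
    rna_depth_mean = rna_depth_mean, dna_depth_mean = dna_depth_mean,
    error_rate = error_rate,
    isg_fraction = isg_fraction, isg_multipliers = isg_multipliers,
    expression_base_mean = expression_base_mean,
    expression_dispersion = expression_dispersion,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  bad <- function(msg) stop_editomer(msg, "editomer_config_error")
  if (is.null(names(cfg$contig_lengths)) || any(names(cfg$contig_lengths) == ""))
    bad("contig_lengths must be a named vector")
  counts <- c(cfg$contig_lengths, cfg$n_genes, cfg$n_snps,
              cfg$n_shared_sites, cfg$n_unique_sites,
              cfg$animals_per_genotype, cfg$repeat_density)
  if (any(counts < 0)) bad("all counts must be >= 0")
  fr <- cfg$editing_fraction_range
  if (length(fr) != 2 || fr[1] <= 0 || fr[2] >= 1 || fr[1] > fr[2])
    bad("editing_fraction_range must lie inside (0, 1)")
  w <- cfg$placement_weights
  if (any(w < 0) || abs(sum(w) - 1) > 1e-8)
    bad("placement_weights must be non-negative and sum to 1")
  miss <- setdiff(names(w), SITE_CLASSES)
  if (length(miss) > 0)
    bad(paste("unknown placement class:", paste(miss, collapse = ", ")))
  if (anyDuplicated(cfg$genotypes) > 0) bad("genotype labels must be unique")
  if (!all(cfg$genotypes %in% names(cfg$isg_multipliers)))
    bad("isg_multipliers must name every genotype")
  if (cfg$error_rate < 0 || cfg$error_rate >= 1)
    bad("error_rate must be in [0, 1)")
  if (cfg$isg_fraction < 0 || cfg$isg_fraction > 1)
    bad("isg_fraction must be in [0, 1]")
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  genome: %d contig(s), %s bp; %d genes\n",
              length(x$contig_lengths),
              format(sum(x$contig_lengths), big.mark = ","), x$n_genes))
  cat(sprintf("  design: %d genotypes x %d animals\n",
              length(x$genotypes), x$animals_per_genotype))
  cat(sprintf("  editing: %d shared + %d DoubleHet-unique sites, f in [%.2f, %.2f]\n",
              x$n_shared_sites, x$n_unique_sites,
              x$editing_fraction_range[1], x$editing_fraction_range[2]))
  cat(sprintf("  coverage: RNA %.0fx, DNA %.0fx, error %.4g; seed %d\n",
              x$rna_depth_mean, x$dna_depth_mean, x$error_rate, x$seed))
  invisible(x)
}
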