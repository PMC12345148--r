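#' Simulate a complete study on disk
#'
#' Generates the toy genome, annotation, ground truth, per-animal RNA
#' pileups, pooled exome pileup, ISG list, expression counts and a DEG table
#' (from [minimal_deg_call()], each non-baseline genotype versus `WT`),
#' writes everything in the pipeline's interchange formats, and returns a
#' ready-to-run [pipeline_config()] together with the ground truth.
#'
#' @param config A [sim_config()].
#' @param dir Directory to write into (created if needed).
#' @param out_dir Pipeline output directory (defaults to `dir`/results).
#' @return List: `config` (a `pipeline_config`), `truth` (`sim_truth`),
#'   `genome` (`sim_genome`), `samples` (sample tibble) and `paths`.
#' @export
simulate_study <- function(config, dir, out_dir = file.path(dir, "results")) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "pileups"), showWarnings = FALSE)

  genome <- simulate_genome(config)
  truth <- plant_truth(config, genome)
  pile <- simulate_pileups(genome, truth, config)
  expr <- simulate_expression(genome, truth, config)

  paths <- list(
    genome_fasta = file.path(dir, "genome.fa"),
    features_bed = file.path(dir, "features.bed"),
    repeats_bed = file.path(dir, "repeats.bed"),
    sample_sheet = file.path(dir, "sample_sheet.tsv"),
    dna_pileup = file.path(dir, "pileups", "exome_pool.tsv"),
    isg_list = file.path(dir, "isg_list.txt"),
    deg_table = file.path(dir, "deg_table.tsv"),
    truth_sites = file.path(dir, "truth_sites.tsv"),
    truth_snps = file.path(dir, "truth_snps.tsv"),
    truth_json = file.path(dir, "truth.json"),
    expression = file.path(dir, "expression_counts.tsv")
  )
  write_genome_fasta(genome$sequence, paths$genome_fasta)
  write_features_bed(genome$features, paths$features_bed)
  write_repeats_bed(genome$repeats, paths$repeats_bed)
  write_pileups(pile$dna, paths$dna_pileup)

  sheet <- pile$samples |>
    mutate(rna_pileup = file.path(dir, "pileups",
                                  paste0(.data$sample_id, ".tsv")))
  for (i in seq_len(nrow(sheet))) {
    write_pileups(pile$rna[pile$rna$sample_id == sheet$sample_id[i], ],
                  sheet$rna_pileup[i])
  }
  readr::write_tsv(sheet, paths$sample_sheet)
  readr::write_lines(truth$isg_genes, paths$isg_list)
  readr::write_tsv(truth$edit_sites, paths$truth_sites)
  readr::write_tsv(truth$snps, paths$truth_snps)
  jsonlite::write_json(list(expected = truth$expected,
                            n_isg = length(truth$isg_genes)),
                       paths$truth_json, auto_unbox = TRUE, digits = NA)
  readr::write_tsv(expr, paths$expression)

  counts <- expr |>
    tidyr::pivot_wider(id_cols = "gene_id", names_from = "sample_id",
                       values_from = "count")
  mat <- as.matrix(counts[, -1])
  rownames(mat) <- counts$gene_id
  sample_geno <- setNames(pile$samples$genotype, pile$samples$sample_id)
  baseline <- config$genotypes[1]
  deg <- purrr::map_dfr(setdiff(config$genotypes, baseline), function(g) {
    keep <- colnames(mat)[sample_geno[colnames(mat)] %in% c(g, baseline)]
    sub <- mat[, keep, drop = FALSE]
    grp <- factor(sample_geno[keep], levels = c(g, baseline))
    minimal_deg_call(sub, grp) |>
      select("gene_id", "log2_fc", adj_p = "adj_p", "contrast")
  })
  readr::write_tsv(deg, paths$deg_table)

  pcfg <- pipeline_config(
    genome_fasta = paths$genome_fasta, features_bed = paths$features_bed,
    repeats_bed = paths$repeats_bed, sample_sheet = paths$sample_sheet,
    dna_pileups = paths$dna_pileup, isg_list = paths$isg_list,
    deg_table = paths$deg_table, out_dir = out_dir,
    genotypes = config$genotypes, baseline = config$genotypes[1],
    seed = config$seed
  )
  list(config = pcfg, truth = truth, genome = genome,
       samples = pile$samples, paths = paths)
}
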