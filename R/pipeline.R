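# End-to-end orchestration: simulate -> mask -> call -> consensus ->
# annotate -> compare -> report, file-based and reproducible.

#' Declarative configuration of a pipeline run
#'
#' @param genome_fasta,features_bed,repeats_bed Reference genome and
#'   annotation paths (BED files are 0-based half-open on disk).
#' @param sample_sheet TSV path with `sample_id`, `animal`, `genotype`,
#'   `rna_pileup` columns.
#' @param dna_pileups Character vector of DNA (exome) pileup TSV paths.
#' @param isg_list Optional path, one ISG gene id per line.
#' @param deg_table Optional DEG TSV (`gene_id`, `log2_fc`, `adj_p`,
#'   `contrast`).
#' @param known_variants Optional known-variant VCF merged into the mask.
#' @param out_dir Output directory (created if needed).
#' @param genotypes Declared genotype labels; sample-sheet genotypes must
#'   come from this set.
#' @param baseline Baseline genotype for percent changes (default `"WT"`).
#' @param thresholds Named list overriding any of: `min_dna_depth`,
#'   `min_alt_fraction`, `min_depth`, `min_variant_reads`, `fraction_range`,
#'   `drop_unassessable`, `complex_fraction`, `lfc_cut`, `p_cut`.
#' @param seed Integer seed recorded in the manifest (the pipeline itself is
#'   deterministic; the seed is forwarded to any simulation step).
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(genome_fasta, features_bed, repeats_bed,
                            sample_sheet, dna_pileups,
                            isg_list = NULL, deg_table = NULL,
                            known_variants = NULL,
                            out_dir = tempfile("editomer_run_"),
                            genotypes = GENOTYPES, baseline = "WT",
                            thresholds = list(), seed = 1L) {
  defaults <- list(min_dna_depth = 10, min_alt_fraction = 0.1,
                   min_depth = 10, min_variant_reads = 3,
                   fraction_range = c(0.05, 0.95),
                   drop_unassessable = TRUE, complex_fraction = 0.05,
                   lfc_cut = 1, p_cut = 0.05)
  unknown <- setdiff(names(thresholds), names(defaults))
  if (length(unknown) > 0) {
    stop_editomer(paste("unknown threshold(s):",
                        paste(unknown, collapse = ", ")),
                  "editomer_config_error")
  }
  cfg <- list(
    genome_fasta = genome_fasta, features_bed = features_bed,
    repeats_bed = repeats_bed, sample_sheet = sample_sheet,
    dna_pileups = dna_pileups, isg_list = isg_list, deg_table = deg_table,
    known_variants = known_variants, out_dir = out_dir,
    genotypes = genotypes, baseline = baseline,
    thresholds = modifyList(defaults, thresholds), seed = as.integer(seed)
  )
  class(cfg) <- "pipeline_config"
  cfg
}

#' Serialise a pipeline configuration to YAML (lossless round trip)
#'
#' @param config A [pipeline_config()].
#' @param path YAML path.
#' @return `read_pipeline_config()` returns the `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$dna_pileups <- as.character(x$dna_pileups)
  x$genotypes <- as.character(x$genotypes)
  x$thresholds$fraction_range <- as.numeric(x$thresholds$fraction_range)
  x$seed <- as.integer(x$seed)
  class(x) <- "pipeline_config"
  x
}

#' Validate pipeline inputs without mutating anything
#'
#' Checks file existence, FASTA/BED/VCF well-formedness, pileup sortedness
#' and sample-sheet completeness. Issues are returned, not thrown.
#'
#' @param config A [pipeline_config()].
#' @return Tibble of issues: `severity` (`"error"`), `item`, `message`;
#'   zero rows when everything is well-formed.
#' @export
validate_inputs <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  issues <- list()
  note <- function(item, message) {
    issues[[length(issues) + 1L]] <<- tibble(severity = "error",
                                             item = item, message = message)
  }
  need <- c(genome_fasta = config$genome_fasta,
            features_bed = config$features_bed,
            repeats_bed = config$repeats_bed,
            sample_sheet = config$sample_sheet)
  for (i in seq_along(need)) {
    if (is.null(need[[i]]) || !file.exists(need[[i]])) {
      note(names(need)[i], sprintf("missing input file: %s",
                                   need[[i]] %||% "<unset>"))
    }
  }
  if (length(config$dna_pileups) == 0) {
    note("dna_pileups", "no DNA pileup supplied")
  }
  for (p in config$dna_pileups) {
    if (!file.exists(p)) note("dna_pileups", sprintf("missing input file: %s", p))
  }
  for (p in c(config$isg_list, config$deg_table, config$known_variants)) {
    if (!is.null(p) && !file.exists(p)) {
      note("optional_input", sprintf("missing input file: %s", p))
    }
  }

  if (!is.null(config$genome_fasta) && file.exists(config$genome_fasta)) {
    first <- tryCatch(readr::read_lines(config$genome_fasta, n_max = 1),
                      error = function(e) "")
    g <- tryCatch(read_genome_fasta(config$genome_fasta),
                  error = function(e) NULL)
    if (length(first) == 0 || !startsWith(first[1], ">") || is.null(g) ||
        length(g) == 0 || any(nchar(g) == 0)) {
      note("genome_fasta", sprintf("FASTA file %s is not well-formed",
                                   config$genome_fasta))
    }
  }
  check_bed <- function(path, reader, item) {
    if (is.null(path) || !file.exists(path)) return()
    df <- tryCatch(reader(path), error = function(e) NULL)
    if (is.null(df) || any(df$start < 1) || any(df$end < df$start)) {
      note(item, sprintf("BED file %s is not well-formed", path))
    }
  }
  check_bed(config$features_bed, read_features_bed, "features_bed")
  check_bed(config$repeats_bed, read_repeats_bed, "repeats_bed")

  sheet <- NULL
  if (!is.null(config$sample_sheet) && file.exists(config$sample_sheet)) {
    sheet <- tryCatch(read_sample_sheet(config$sample_sheet),
                      error = function(e) {
                        note("sample_sheet", conditionMessage(e))
                        NULL
                      })
  }
  if (!is.null(sheet)) {
    if (nrow(sheet) == 0) note("sample_sheet", "sample sheet has no samples")
    if (anyDuplicated(sheet$sample_id) > 0) {
      note("sample_sheet", "duplicate sample_id in sample sheet")
    }
    bad_g <- setdiff(unique(sheet$genotype), config$genotypes)
    if (length(bad_g) > 0) {
      note("sample_sheet",
           sprintf("genotype label(s) not in the declared set: %s",
                   paste(bad_g, collapse = ", ")))
    }
    for (i in seq_len(nrow(sheet))) {
      if (is.na(sheet$rna_pileup[i]) || !file.exists(sheet$rna_pileup[i])) {
        note("sample_sheet",
             sprintf("sample '%s' has no readable pileup: %s",
                     sheet$sample_id[i], sheet$rna_pileup[i]))
      }
    }
  }
  pileup_paths <- c(config$dna_pileups,
                    if (!is.null(sheet)) sheet$rna_pileup)
  for (p in pileup_paths) {
    if (is.null(p) || is.na(p) || !file.exists(p)) next
    ok <- tryCatch({ read_pileups(p); TRUE },
                   error = function(e) {
                     note("pileup", conditionMessage(e))
                     FALSE
                   })
  }
  if (!is.null(config$known_variants) && file.exists(config$known_variants)) {
    tryCatch(read_mask_vcf(config$known_variants),
             error = function(e) note("known_variants", conditionMessage(e)))
  }
  if (length(issues) == 0) {
    tibble(severity = character(), item = character(), message = character())
  } else {
    bind_rows(issues)
  }
}

#' Run the full editome comparison pipeline
#'
#' Orchestrates germline masking, per-animal edit calling, all-replicate
#' consensus at site and gene level, feature/repeat annotation, four-way
#' Venn partitioning, unique sets, percent changes versus the baseline
#' genotype, and (when an ISG list is supplied) the ISG proportion test and
#' DEG summary. Artifacts (per-animal call VCF/TSV, consensus tables,
#' summaries, Venn cells, report and manifest JSON) are written under
#' `config$out_dir`. Rerunning with an identical configuration reproduces
#' identical outputs.
#'
#' @param config A [pipeline_config()]; inputs are validated first and any
#'   issue aborts the run before computation.
#' @param verbose Log stage boundaries with record counts.
#' @return An `editome_report` (list of tibbles; see [tidy.editome_report()]).
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  issues <- validate_inputs(config)
  if (nrow(issues) > 0) {
    stop_editomer(
      paste0("input validation failed:\n",
             paste(sprintf("- [%s] %s", issues$item, issues$message),
                   collapse = "\n")),
      "editomer_validation_error"
    )
  }
  th <- config$thresholds
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(config$out_dir, "calls"), showWarnings = FALSE)

  genome <- read_genome_fasta(config$genome_fasta)
  features <- read_features_bed(config$features_bed)
  repeats <- read_repeats_bed(config$repeats_bed)
  sheet <- read_sample_sheet(config$sample_sheet)
  contig_lengths <- setNames(nchar(genome), names(genome))

  dna <- bind_rows(lapply(config$dna_pileups, read_pileups))
  mask <- call_exome_snps(dna, min_depth = th$min_dna_depth,
                          min_alt_fraction = th$min_alt_fraction)
  if (!is.null(config$known_variants)) {
    mask <- merge_known_variants(mask,
                                 read_mask_vcf(config$known_variants)$mask)
  }
  say("masking: %d DNA records -> %d masked, %d unassessable positions",
      nrow(dna), nrow(mask$mask), nrow(mask$unassessable))
  write_mask_vcf(mask, file.path(config$out_dir, "mask.vcf"))

  calls <- purrr::map_dfr(seq_len(nrow(sheet)), function(i) {
    pu <- read_pileups(sheet$rna_pileup[i])
    cl <- call_edit_sites(pu, mask = mask, features = features,
                          genome = genome,
                          min_depth = th$min_depth,
                          min_variant_reads = th$min_variant_reads,
                          fraction_range = th$fraction_range,
                          drop_unassessable = th$drop_unassessable,
                          complex_fraction = th$complex_fraction)
    say("calling %s: %d pileup records -> %d passing calls",
        sheet$sample_id[i], nrow(pu), nrow(cl))
    write_calls_vcf(cl, file.path(config$out_dir, "calls",
                                  paste0(sheet$sample_id[i], ".vcf")))
    readr::write_tsv(cl, file.path(config$out_dir, "calls",
                                   paste0(sheet$sample_id[i], ".tsv")))
    cl
  })
  calls <- calls |>
    left_join(sheet[, c("sample_id", "genotype")], by = "sample_id")

  genotypes <- intersect(config$genotypes, unique(sheet$genotype))
  cons_sites <- purrr::map_dfr(genotypes, function(g) {
    gc <- calls |> filter(.data$genotype == g)
    consensus_sites(gc, animals = sheet$sample_id[sheet$genotype == g]) |>
      mutate(genotype = g)
  })
  cons_genes <- purrr::map_dfr(genotypes, function(g) {
    gc <- calls |> filter(.data$genotype == g)
    consensus_genes(gc, features,
                    animals = sheet$sample_id[sheet$genotype == g]) |>
      mutate(genotype = g)
  })
  say("consensus: %d site rows, %d gene rows across %d genotypes",
      nrow(cons_sites), nrow(cons_genes), length(genotypes))

  assignments <- assign_features(cons_sites, features, repeats,
                                 contig_lengths = contig_lengths)
  summary <- distribution_summary(assignments)

  site_sets <- lapply(setNames(genotypes, genotypes), function(g) {
    s <- cons_sites |> filter(.data$genotype == g)
    site_key(s$contig, s$pos, s$change)
  })
  gene_sets <- lapply(setNames(genotypes, genotypes), function(g) {
    cons_genes$gene_id[cons_genes$genotype == g]
  })
  venn_sites <- venn_partition(site_sets)
  venn_genes <- venn_partition(gene_sets)
  uniq_sites <- unique_sets(venn_sites)
  uniq_genes <- unique_sets(venn_genes)

  counts <- tibble(
    genotype = genotypes,
    n_sites = vapply(site_sets, length, integer(1)),
    n_genes = vapply(gene_sets, length, integer(1)),
    n_unique_sites = vapply(genotypes, function(g)
      length(uniq_sites[[g]] %||% character(0)), integer(1)),
    n_unique_genes = vapply(genotypes, function(g)
      length(uniq_genes[[g]] %||% character(0)), integer(1))
  )
  pct <- if (config$baseline %in% genotypes) {
    percent_change(counts |> select("genotype", n = "n_sites"),
                   baseline = config$baseline)
  } else NULL

  isg <- NULL
  deg_summary <- NULL
  if (!is.null(config$isg_list)) {
    isgs <- read_isg_list(config$isg_list)
    flagged <- assignments |>
      mutate(key = site_key(.data$contig, .data$pos, .data$change)) |>
      group_by(.data$genotype) |>
      mutate(unique_site = .data$key %in%
               (uniq_sites[[.data$genotype[1]]] %||% character(0))) |>
      ungroup()
    isg <- isg_edit_proportion(flagged, isgs)
    if (!is.null(config$deg_table)) {
      deg <- readr::read_tsv(config$deg_table, progress = FALSE,
                             col_types = readr::cols())
      deg_summary <- deg_isg_summary(deg, isgs, lfc_cut = th$lfc_cut,
                                     p_cut = th$p_cut)
    }
  }

  hashable <- unclass(config)
  hashable$out_dir <- NULL
  manifest <- list(
    package = "editomer",
    version = as.character(utils::packageVersion("editomer")),
    config_hash = rlang::hash(hashable),
    seed = config$seed,
    n_samples = nrow(sheet),
    genotypes = genotypes
  )

  report <- structure(list(
    counts = counts, consensus_sites = cons_sites,
    consensus_genes = cons_genes, assignments = assignments,
    summary = summary, venn_sites = venn_sites, venn_genes = venn_genes,
    unique_sites = uniq_sites, unique_genes = uniq_genes,
    percent_change = pct, isg = isg, deg_summary = deg_summary,
    mask = mask, calls = calls, manifest = manifest,
    out_dir = config$out_dir
  ), class = "editome_report")
  write_report_files(report)
  say("report written to %s", config$out_dir)
  report
}

venn_table <- function(vp) {
  tibble(cell = vp$cell, degree = vp$degree, n = vp$n)
}

write_report_files <- function(report) {
  out <- report$out_dir
  readr::write_tsv(report$consensus_sites,
                   file.path(out, "consensus_sites.tsv"))
  readr::write_tsv(report$consensus_genes,
                   file.path(out, "consensus_genes.tsv"))
  readr::write_tsv(report$summary$features,
                   file.path(out, "feature_summary.tsv"))
  readr::write_tsv(report$summary$repeats,
                   file.path(out, "repeat_summary.tsv"))
  readr::write_tsv(venn_table(report$venn_sites),
                   file.path(out, "venn_sites.tsv"))
  readr::write_tsv(venn_table(report$venn_genes),
                   file.path(out, "venn_genes.tsv"))
  readr::write_tsv(report$counts, file.path(out, "counts.tsv"))
  if (!is.null(report$percent_change)) {
    readr::write_tsv(report$percent_change,
                     file.path(out, "percent_change.tsv"))
  }
  if (!is.null(report$isg)) {
    jsonlite::write_json(report$isg, file.path(out, "isg_enrichment.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(report$deg_summary)) {
    readr::write_tsv(report$deg_summary, file.path(out, "deg_summary.tsv"))
  }
  payload <- list(
    counts = report$counts,
    percent_change = report$percent_change,
    venn_sites = venn_table(report$venn_sites),
    venn_genes = venn_table(report$venn_genes),
    feature_summary = report$summary$features |>
      mutate(feature_class = as.character(.data$feature_class)),
    repeat_summary = report$summary$repeats,
    isg = report$isg
  )
  jsonlite::write_json(payload, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(report$manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(report)
}

#' @export
print.editome_report <- function(x, ...) {
  cat("<editome_report>\n")
  print(x$counts)
  if (!is.null(x$percent_change)) print(x$percent_change)
  invisible(x)
}
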