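#' Simulate a toy genome with gene and repeat annotation
#'
#' Draws a random nucleotide sequence per contig and tiles non-overlapping
#' gene loci with a 5'UTR - CDS(/intron) - 3'UTR structure on randomly
#' assigned strands; repeat elements (SINE, LINE, DNA transposon, other
#' retrotransposon) are placed independently and may overlap gene features,
#' as in real genomes.
#'
#' @param config A [sim_config()].
#' @return A `sim_genome` list with elements `sequence` (named character
#'   vector, one string per contig), `features` (tibble: `contig`, `start`,
#'   `end` 1-based inclusive, `strand`, `gene_id`, `class`), `repeats`
#'   (tibble: `contig`, `start`, `end`, `class`) and `contig_lengths`.
#' @examples
#' g <- simulate_genome(sim_config(contig_lengths = c(chr = 20000),
#'                                 n_genes = 4, n_snps = 0,
#'                                 n_shared_sites = 0))
#' table(g$features$class)
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  lens <- config$contig_lengths
  sequence <- vapply(lens, function(L) {
    paste(sample(BASES, L, replace = TRUE), collapse = "")
  }, character(1))
  names(sequence) <- names(lens)

  # distribute genes over contigs proportionally to length (largest remainder)
  n_per_contig <- integer(length(lens))
  if (config$n_genes > 0) {
    exact <- config$n_genes * lens / sum(lens)
    n_per_contig <- floor(exact)
    rem <- config$n_genes - sum(n_per_contig)
    if (rem > 0) {
      ord <- order(exact - n_per_contig, decreasing = TRUE)
      n_per_contig[ord[seq_len(rem)]] <- n_per_contig[ord[seq_len(rem)]] + 1L
    }
  }

  feat <- list()
  gene_counter <- 0L
  min_gap <- 50L
  for (ci in seq_along(lens)) {
    ng <- n_per_contig[ci]
    if (ng == 0) next
    contig <- names(lens)[ci]
    n_ex <- if (length(config$exons_per_gene) == 1) {
      rep(config$exons_per_gene, ng)
    } else {
      sample(config$exons_per_gene, ng, replace = TRUE)
    }
    glen <- config$utr5_length + n_ex * config$cds_exon_length +
      (n_ex - 1L) * config$intron_length + config$utr3_length
    slack <- lens[ci] - sum(glen) - (ng + 1L) * min_gap
    if (slack < 0) {
      stop_editomer(
        sprintf("contig '%s' (%d bp) is too small to hold %d gene(s)",
                contig, lens[ci], ng),
        "editomer_sizing_error"
      )
    }
    extra <- as.vector(rmultinom(1, slack, rep(1, ng + 1L)))
    gaps <- min_gap + extra
    strand <- sample(c("+", "-"), ng, replace = TRUE)
    pos <- 1L
    for (gi in seq_len(ng)) {
      pos <- pos + gaps[gi]
      gene_counter <- gene_counter + 1L
      gid <- sprintf("g%03d", gene_counter)
      # blocks in transcription order; reversed physically on minus strand
      classes <- c("five_prime_utr",
                   head(rep(c("cds", "intron"), n_ex[gi]), 2L * n_ex[gi] - 1L),
                   "three_prime_utr")
      blen <- ifelse(classes == "five_prime_utr", config$utr5_length,
              ifelse(classes == "three_prime_utr", config$utr3_length,
              ifelse(classes == "cds", config$cds_exon_length,
                     config$intron_length)))
      if (strand[gi] == "-") {
        classes <- rev(classes)
        blen <- rev(blen)
      }
      ends <- pos - 1L + cumsum(blen)
      starts <- ends - blen + 1L
      feat[[length(feat) + 1L]] <- tibble(
        contig = contig, start = as.integer(starts), end = as.integer(ends),
        strand = strand[gi], gene_id = gid, class = classes
      )
      pos <- pos + sum(blen)
    }
  }
  features <- if (length(feat) > 0) bind_rows(feat) else {
    tibble(contig = character(), start = integer(), end = integer(),
           strand = character(), gene_id = character(), class = character())
  }

  rep_len_range <- list(SINE = c(150, 300), LINE = c(500, 1500),
                        DNA_transposon = c(200, 800),
                        other_retrotransposon = c(200, 1000))
  reps <- list()
  for (ci in seq_along(lens)) {
    contig <- names(lens)[ci]
    for (cls in names(config$repeat_density)) {
      nr <- rpois(1, config$repeat_density[[cls]] * lens[ci] / 1e6)
      if (nr == 0) next
      rl <- round(runif(nr, rep_len_range[[cls]][1], rep_len_range[[cls]][2]))
      rl <- pmin(rl, lens[ci])
      st <- floor(runif(nr, 1, lens[ci] - rl + 1))
      reps[[length(reps) + 1L]] <- tibble(
        contig = contig, start = as.integer(st),
        end = as.integer(st + rl - 1L), class = cls
      )
    }
  }
  repeats <- if (length(reps) > 0) {
    bind_rows(reps) |> arrange(.data$contig, .data$start, .data$end)
  } else {
    tibble(contig = character(), start = integer(), end = integer(),
           class = character())
  }

  structure(list(sequence = sequence, features = features, repeats = repeats,
                 contig_lengths = lens),
            class = "sim_genome")
}

#' @export
print.sim_genome <- function(x, ...) {
  cat(sprintf("<sim_genome> %d contig(s), %s bp, %d genes, %d repeat elements\n",
              length(x$sequence), format(sum(x$contig_lengths), big.mark = ","),
              dplyr::n_distinct(x$features$gene_id), nrow(x$repeats)))
  invisible(x)
}
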