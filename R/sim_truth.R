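# Ground-truth planting and the closed-form binomial detection oracle.

#' Closed-form per-animal detection probability for an edited site
#'
#' Probability that a site with true editing fraction `fraction` yields a
#' passing call in one animal under the default caller thresholds, with
#' sequencing depth Poisson(`depth_mean`) truncated at >= 1 and the symmetric
#' substitution error model (each non-template base at rate `error_rate / 3`).
#' The variant-read probability per read is
#' `f * (1 - e) + (1 - f) * e / 3`; detection requires depth >= `min_depth`,
#' variant reads >= `min_variant_reads`, an observed fraction inside
#' `fraction_range`, and survival of the complex-site filter (each of the
#' two non-variant non-reference bases accumulates errors at rate
#' `error_rate / 3`, and a site is discarded when either reaches
#' `complex_fraction` of reads).
#'
#' @param fraction True editing fraction(s), vectorised.
#' @param depth_mean Mean RNA depth (truncated-Poisson coverage model).
#' @param error_rate Per-base sequencing error rate.
#' @param min_depth,min_variant_reads,fraction_range,complex_fraction Caller
#'   thresholds.
#' @return Numeric vector of detection probabilities.
#' @examples
#' detection_probability(0.3, depth_mean = 50)
#' @export
detection_probability <- function(fraction, depth_mean = 50,
                                  error_rate = 0.005,
                                  min_depth = 10, min_variant_reads = 3,
                                  fraction_range = c(0.05, 0.95),
                                  complex_fraction = 0.05) {
  e <- error_rate
  p <- fraction * (1 - e) + (1 - fraction) * e / 3
  vapply(p, call_probability_given_p, numeric(1),
         depth_mean = depth_mean, min_depth = min_depth,
         min_variant_reads = min_variant_reads,
         fraction_range = fraction_range, error_rate = e,
         complex_fraction = complex_fraction)
}

#' Closed-form false-positive probability at an unedited eligible position
#'
#' Probability that sequencing error alone produces a passing call at a
#' position with no editing and no germline variant, under the same coverage
#' and error model as [detection_probability()]. Because the complex-site
#' filter can only remove candidate calls, this is a (tight) upper bound on
#' the realised per-position false-positive rate.
#'
#' @inheritParams detection_probability
#' @return A single probability.
#' @export
false_positive_probability <- function(depth_mean = 50, error_rate = 0.005,
                                       min_depth = 10, min_variant_reads = 3,
                                       fraction_range = c(0.05, 0.95)) {
  call_probability_given_p(error_rate / 3, depth_mean, min_depth,
                           min_variant_reads, fraction_range,
                           error_rate = 0, complex_fraction = 1)
}

# P(call) for per-read variant probability p, marginalised over truncated
# Poisson depth. The complex filter is folded in as an independent factor
# per depth: each of the two non-variant non-reference bases carries errors
# at error_rate/3 (complex_fraction = 1 disables the correction).
call_probability_given_p <- function(p, depth_mean, min_depth,
                                     min_variant_reads, fraction_range,
                                     error_rate = 0, complex_fraction = 1) {
  d_hi <- qpois(1 - 1e-13, depth_mean)
  d <- seq.int(max(1L, min_depth), d_hi)
  if (length(d) == 0) return(0)
  w <- dpois(d, depth_mean) / (1 - dpois(0, depth_mean))
  k_min <- pmax(min_variant_reads, ceiling(fraction_range[1] * d))
  k_max <- pmin(d, floor(fraction_range[2] * d))
  pr <- ifelse(k_min > k_max, 0,
               pbinom(k_max, d, p) - pbinom(k_min - 1, d, p))
  if (complex_fraction < 1) {
    c_min <- pmax(1, ceiling(complex_fraction * d))
    p_one <- 1 - pbinom(c_min - 1, d, error_rate / 3)
    pr <- pr * (1 - p_one)^2
  }
  sum(w * pr)
}

# repeat class at point positions: overlap against repeat intervals,
# ties broken by smallest interval then alphabetical class
repeat_class_at <- function(sites, repeats) {
  out <- rep(NA_character_, nrow(sites))
  hits <- overlap_points(sites, repeats)
  if (nrow(hits) == 0) return(out)
  hits <- hits |>
    mutate(width = repeats$end[.data$row_feature] -
             repeats$start[.data$row_feature] + 1L,
           class = repeats$class[.data$row_feature]) |>
    arrange(.data$row_site, .data$width, .data$class) |>
    distinct(.data$row_site, .keep_all = TRUE)
  out[hits$row_site] <- hits$class
  out
}

#' Plant ground truth: germline SNPs and genotype-dependent edit sites
#'
#' Plants colony germline SNPs uniformly over the genome, then plants edit
#' sites on strand-appropriate adenosines (reference A inside plus-strand
#' features or intergenic space; reference T where the adenosine lies on the
#' minus strand) according to the configured feature-placement weights. A
#' shared pool is edited in every genotype; a unique pool is edited only in
#' the double heterozygote. Expected per-genotype consensus site and gene
#' counts are computed analytically from [detection_probability()] and stored
#' as the oracle for parameter-recovery tests.
#'
#' @param config A [sim_config()].
#' @param genome A [simulate_genome()] result.
#' @return A `sim_truth` list: `snps` (tibble: `contig`, `pos`, `ref`, `alt`,
#'   `zygosity`), `edit_sites` (tibble: `site_id`, `contig`, `pos`, `strand`,
#'   `ref`, `gene_id`, `feature_class`, `repeat_class`, `unique_to`,
#'   `fraction`, `detect_prob`), `isg_genes` (character), and `expected`
#'   (tibble of analytic per-genotype consensus counts).
#' @export
plant_truth <- function(config, genome) {
  stopifnot(inherits(config, "sim_config"), inherits(genome, "sim_genome"))
  set.seed(config$seed + 1L)
  chars <- genome_chars(genome$sequence)
  lens <- genome$contig_lengths
  offsets <- c(0, cumsum(as.numeric(lens)))[seq_along(lens)]
  names(offsets) <- names(lens)

  # --- germline SNPs, uniform over the genome ---
  snps <- tibble(contig = character(), pos = integer(), ref = character(),
                 alt = character(), zygosity = character())
  if (config$n_snps > 0) {
    gidx <- sort(sample.int(sum(lens), config$n_snps))
    ci <- findInterval(gidx, cumsum(as.numeric(lens)) + 1) + 1L
    contig <- names(lens)[ci]
    pos <- as.integer(gidx - offsets[contig])
    ref <- base_at(chars, contig, pos)
    alt <- vapply(ref, function(b) sample(BASES[BASES != b], 1), character(1))
    n_het <- round(config$n_snps * config$snp_het_fraction)
    zyg <- sample(rep(c("het", "hom"),
                      c(n_het, config$n_snps - n_het)))
    snps <- tibble(contig = contig, pos = pos, ref = unname(ref),
                   alt = unname(alt), zygosity = zyg)
  }
  snp_keys <- paste(snps$contig, snps$pos)

  # --- candidate adenosine positions per feature class ---
  features <- genome$features
  candidates <- edit_candidates(chars, lens, features)
  candidates <- candidates[!(paste(candidates$contig, candidates$pos) %in%
                               snp_keys), , drop = FALSE]

  n_total <- config$n_shared_sites + config$n_unique_sites
  w <- config$placement_weights[config$placement_weights > 0]
  sites <- tibble(site_id = character(), contig = character(),
                  pos = integer(), strand = character(), ref = character(),
                  gene_id = character(), feature_class = character(),
                  repeat_class = character(), unique_to = character(),
                  fraction = numeric(), detect_prob = numeric())
  if (n_total > 0) {
    n_class <- as.vector(rmultinom(1, n_total, w))
    names(n_class) <- names(w)
    picked <- list()
    for (cls in names(w)) {
      pool <- candidates[candidates$feature_class == cls, , drop = FALSE]
      if (nrow(pool) < n_class[[cls]]) {
        stop_editomer(
          sprintf("insufficient adenosines in feature class '%s' (%d needed, %d available)",
                  cls, n_class[[cls]], nrow(pool)),
          "editomer_placement_error"
        )
      }
      picked[[cls]] <- pool[sample.int(nrow(pool), n_class[[cls]]), ,
                            drop = FALSE]
    }
    sites <- bind_rows(picked) |> arrange(.data$contig, .data$pos)
    uniq <- rep(NA_character_, n_total)
    if (config$n_unique_sites > 0) {
      uniq[sample.int(n_total, config$n_unique_sites)] <- "DoubleHet"
    }
    sites$unique_to <- uniq
    sites$fraction <- runif(n_total, config$editing_fraction_range[1],
                            config$editing_fraction_range[2])
    sites$repeat_class <- repeat_class_at(sites, genome$repeats)
    sites$site_id <- sprintf("s%05d", seq_len(n_total))
    sites$detect_prob <- detection_probability(
      sites$fraction, config$rna_depth_mean, config$error_rate)
    sites <- sites |>
      select("site_id", "contig", "pos", "strand", "ref", "gene_id",
             "feature_class", "repeat_class", "unique_to", "fraction",
             "detect_prob")
  }

  # --- ISG membership ---
  gene_ids <- sort(unique(features$gene_id))
  n_isg <- round(length(gene_ids) * config$isg_fraction)
  isg_genes <- sort(sample(gene_ids, n_isg))

  # --- analytic expected consensus counts ---
  A <- config$animals_per_genotype
  expected <- purrr::map_dfr(config$genotypes, function(g) {
    app <- sites[is.na(sites$unique_to) | sites$unique_to == g, , drop = FALSE]
    exp_sites <- sum(app$detect_prob^A)
    genic <- app[!is.na(app$gene_id), , drop = FALSE]
    exp_genes <- if (nrow(genic) == 0) 0 else {
      genic |>
        group_by(.data$gene_id) |>
        summarise(p_animal = 1 - prod(1 - .data$detect_prob),
                  .groups = "drop") |>
        summarise(e = sum(.data$p_animal^A)) |>
        pull(.data$e)
    }
    tibble(genotype = g, expected_consensus_sites = exp_sites,
           expected_consensus_genes = exp_genes)
  })

  structure(list(snps = snps, edit_sites = sites, isg_genes = isg_genes,
                 expected = expected),
            class = "sim_truth")
}

# enumerate strand-appropriate adenosine positions per feature class,
# including intergenic space (either strand)
edit_candidates <- function(chars, lens, features) {
  out <- list()
  if (nrow(features) > 0) {
    for (i in seq_len(nrow(features))) {
      f <- features[i, ]
      target <- if (f$strand == "+") "A" else "T"
      span <- f$start:f$end
      hit <- span[chars[[f$contig]][span] == target]
      if (length(hit) > 0) {
        out[[length(out) + 1L]] <- tibble(
          contig = f$contig, pos = as.integer(hit), strand = f$strand,
          ref = target, gene_id = f$gene_id, feature_class = f$class
        )
      }
    }
  }
  for (ct in names(lens)) {
    covered <- rep(FALSE, lens[[ct]])
    ff <- features[features$contig == ct, , drop = FALSE]
    for (i in seq_len(nrow(ff))) covered[ff$start[i]:ff$end[i]] <- TRUE
    open <- which(!covered)
    b <- chars[[ct]][open]
    keep <- b %in% c("A", "T")
    if (any(keep)) {
      out[[length(out) + 1L]] <- tibble(
        contig = ct, pos = as.integer(open[keep]),
        strand = ifelse(b[keep] == "A", "+", "-"), ref = b[keep],
        gene_id = NA_character_, feature_class = "intergenic"
      )
    }
  }
  bind_rows(out)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("<sim_truth> %d SNPs, %d edit sites (%d DoubleHet-unique), %d ISGs\n",
              nrow(x$snps), nrow(x$edit_sites),
              sum(!is.na(x$edit_sites$unique_to)), length(x$isg_genes)))
  print(x$expected)
  invisible(x)
}
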