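# Per-animal A-to-I edit calling from RNA pileups.

#' Call candidate A-to-I edit sites from per-animal RNA pileups
#'
#' Inosine is read as guanosine, so edits appear as A>G mismatches on the
#' transcribed strand (T>C in reference coordinates when the edited
#' adenosine lies on the minus strand). Inside a gene of known strand only
#' the strand-consistent change is eligible; intergenic positions accept
#' either orientation and are reported as `unstranded`. Positions in the
#' germline mask are excluded, as are (by default) positions whose DNA
#' evidence was too shallow to assess. A passing call requires
#' depth >= `min_depth`, variant reads >= `min_variant_reads`, an editing
#' fraction inside `fraction_range`, and no third base at or above
#' `complex_fraction` of reads (such positions are flagged complex and
#' dropped as likely unmasked variants or artifacts).
#'
#' @param rna_pileups Pileup tibble (`contig`, `pos`, `ref`, `nA`, `nC`,
#'   `nG`, `nT`, `depth`, `sample_id`), position-sorted within each sample.
#' @param mask A `snp_mask` from [call_exome_snps()] /
#'   [merge_known_variants()], or `NULL` for no masking.
#' @param features Gene-feature tibble (as from [simulate_genome()] or
#'   [read_features_bed()]); used for gene strand context. `NULL` treats all
#'   positions as intergenic.
#' @param genome Optional named character vector of contig sequences; when
#'   supplied, pileup reference bases are checked against it and a mismatch
#'   is an error naming the position.
#' @param min_depth,min_variant_reads,fraction_range Call thresholds
#'   (defaults 10, 3, `c(0.05, 0.95)`).
#' @param drop_unassessable Drop positions with unassessable DNA evidence
#'   (default `TRUE`, conservative).
#' @param complex_fraction Third-base fraction at or above which a position
#'   is flagged complex (default 0.05).
#' @param keep_filtered Return all candidate positions (variant reads >= 1)
#'   with a `filter_flags` column (comma-joined, empty for passing calls)
#'   instead of passing calls only.
#' @return Tibble of calls: `contig`, `pos`, `strand` (`+`, `-` or
#'   `unstranded`), `change` (`A>G`/`T>C`), `ref`, `depth`, `variant_reads`,
#'   `editing_fraction`, `gene_id`, `sample_id`, sorted by sample then
#'   position.
#' @export
call_edit_sites <- function(rna_pileups, mask = NULL, features = NULL,
                            genome = NULL,
                            min_depth = 10, min_variant_reads = 3,
                            fraction_range = c(0.05, 0.95),
                            drop_unassessable = TRUE,
                            complex_fraction = 0.05,
                            keep_filtered = FALSE) {
  assert_columns(rna_pileups, c("contig", "pos", "ref", "nA", "nC", "nG",
                                "nT", "depth", "sample_id"), "RNA pileup")
  check_sorted_pileup(rna_pileups, "RNA pileup")
  df <- rna_pileups

  if (!is.null(genome)) {
    chars <- genome_chars(genome)
    expected <- base_at(chars, df$contig, df$pos)
    bad <- which(df$ref != expected)
    if (length(bad) > 0) {
      stop_editomer(
        sprintf("pileup reference base '%s' disagrees with genome base '%s' at %s:%d",
                df$ref[bad[1]], expected[bad[1]], df$contig[bad[1]],
                df$pos[bad[1]]),
        "editomer_reference_mismatch"
      )
    }
  }

  # gene strand context from full gene spans (flat vectors; the grouped
  # aggregation is the hot path on whole-genome pileups)
  n <- nrow(df)
  has_gene <- has_plus <- has_minus <- logical(n)
  gene_plus <- gene_minus <- rep(NA_character_, n)
  if (!is.null(features) && nrow(features) > 0) {
    spans <- gene_spans(features)
    hits <- overlap_points(df[, c("contig", "pos")], spans)
    if (nrow(hits) > 0) {
      hs <- spans$strand[hits$row_feature]
      hg <- spans$gene_id[hits$row_feature]
      has_gene[unique(hits$row_site)] <- TRUE
      for (s in c("+", "-")) {
        i <- which(hs == s)
        if (length(i) == 0) next
        ord <- i[order(hits$row_site[i], hg[i])]
        keep <- ord[!duplicated(hits$row_site[ord])]
        if (s == "+") {
          has_plus[hits$row_site[keep]] <- TRUE
          gene_plus[hits$row_site[keep]] <- hg[keep]
        } else {
          has_minus[hits$row_site[keep]] <- TRUE
          gene_minus[hits$row_site[keep]] <- hg[keep]
        }
      }
    }
  }

  idx_f <- which(df$ref == "A" & (!has_gene | has_plus) & df$nG >= 1)
  idx_r <- which(df$ref == "T" & (!has_gene | has_minus) & df$nC >= 1)
  cand <- df[c(idx_f, idx_r), ]
  cand$change <- rep(c("A>G", "T>C"), c(length(idx_f), length(idx_r)))
  cand$strand <- c(ifelse(has_plus[idx_f], "+", "unstranded"),
                   ifelse(has_minus[idx_r], "-", "unstranded"))
  cand$gene_id <- c(gene_plus[idx_f], gene_minus[idx_r])
  cand$variant_reads <- c(df$nG[idx_f], df$nC[idx_r])
  cand$third_base <- c(pmax(df$nC[idx_f], df$nT[idx_f]),
                       pmax(df$nA[idx_r], df$nG[idx_r]))
  cand$editing_fraction <- cand$variant_reads / cand$depth

  mask_pos <- if (is.null(mask)) {
    tibble(contig = character(), pos = integer())
  } else mask$mask[, c("contig", "pos")]
  unass_pos <- if (is.null(mask) || !drop_unassessable) {
    tibble(contig = character(), pos = integer())
  } else mask$unassessable[, c("contig", "pos")]

  key <- paste(cand$contig, cand$pos)
  flags <- list(
    snp_mask = key %in% paste(mask_pos$contig, mask_pos$pos),
    unassessable_dna = key %in% paste(unass_pos$contig, unass_pos$pos),
    low_depth = cand$depth < min_depth,
    few_variant_reads = cand$variant_reads < min_variant_reads,
    fraction_outside = cand$editing_fraction < fraction_range[1] |
      cand$editing_fraction > fraction_range[2],
    complex = cand$third_base / cand$depth >= complex_fraction
  )
  flag_str <- rep("", nrow(cand))
  for (nm in names(flags)) {
    f <- which(flags[[nm]])
    flag_str[f] <- ifelse(flag_str[f] == "", nm,
                          paste(flag_str[f], nm, sep = ","))
  }
  cand$filter_flags <- flag_str

  out_cols <- c("contig", "pos", "strand", "change", "ref", "depth",
                "variant_reads", "editing_fraction", "gene_id", "sample_id")
  if (keep_filtered) {
    cand |>
      select(all_of(c(out_cols, "filter_flags"))) |>
      arrange(.data$sample_id, .data$contig, .data$pos)
  } else {
    cand |>
      filter(.data$filter_flags == "") |>
      select(all_of(out_cols)) |>
      arrange(.data$sample_id, .data$contig, .data$pos)
  }
}

#' Enumerate positions eligible for an editing call
#'
#' Lists every genomic position at which an A>G (plus-strand adenosine) or
#' T>C (minus-strand adenosine) call is possible under the strand rules used
#' by [call_edit_sites()]: reference A inside plus-strand genes or
#' intergenic space, reference T inside minus-strand genes or intergenic
#' space. Useful as the denominator for empirical false-positive rates.
#'
#' @param genome Named character vector of contig sequences.
#' @param features Gene-feature tibble or `NULL`.
#' @return Tibble: `contig`, `pos`, `change`.
#' @export
eligible_positions <- function(genome, features = NULL) {
  chars <- genome_chars(genome)
  spans <- if (is.null(features)) NULL else gene_spans(features)
  out <- list()
  for (ct in names(genome)) {
    L <- nchar(genome[[ct]])
    b <- chars[[ct]]
    in_plus <- in_minus <- in_gene <- rep(FALSE, L)
    if (!is.null(spans)) {
      sp <- spans[spans$contig == ct, , drop = FALSE]
      for (i in seq_len(nrow(sp))) {
        idx <- sp$start[i]:sp$end[i]
        in_gene[idx] <- TRUE
        if (sp$strand[i] == "+") in_plus[idx] <- TRUE else in_minus[idx] <- TRUE
      }
    }
    fwd <- which(b == "A" & (!in_gene | in_plus))
    rev_ <- which(b == "T" & (!in_gene | in_minus))
    out[[length(out) + 1L]] <- bind_rows(
      tibble(contig = ct, pos = fwd, change = "A>G"),
      tibble(contig = ct, pos = rev_, change = "T>C")
    )
  }
  bind_rows(out) |> arrange(.data$contig, .data$pos)
}
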