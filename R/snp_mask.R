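# Germline masking from whole-exome pileup evidence.

new_snp_mask <- function(mask, unassessable) {
  structure(list(mask = mask, unassessable = unassessable),
            class = "snp_mask")
}

#' Call germline variant positions from DNA (exome) pileups
#'
#' A position enters the mask iff its DNA depth is at least `min_depth` and
#' any non-reference base reaches `min_alt_fraction` of reads (default 0.1,
#' permissive on purpose: masking is conservative). Positions whose DNA depth
#' never reaches `min_depth` are recorded separately as unassessable so that
#' downstream edit calling can (by default) drop them. With several DNA
#' samples, a position is masked if any sample shows the variant at adequate
#' depth, and unassessable only if no sample reaches `min_depth`.
#'
#' @param dna_pileups Pileup tibble (`contig`, `pos`, `ref`, `nA`, `nC`,
#'   `nG`, `nT`, `depth`, `sample_id`), sorted by position within each
#'   sample; unsorted input is an error naming the offending position.
#' @param min_depth Minimum DNA depth to assess a position (default 10).
#' @param min_alt_fraction Minimum non-reference fraction to mask (default 0.1).
#' @return A `snp_mask` object: `$mask` (tibble `contig`, `pos`, `ref`,
#'   `alt`, `provenance`) and `$unassessable` (tibble `contig`, `pos`).
#' @export
call_exome_snps <- function(dna_pileups, min_depth = 10,
                            min_alt_fraction = 0.1) {
  assert_columns(dna_pileups, c("contig", "pos", "ref", "nA", "nC", "nG",
                                "nT", "depth"), "DNA pileup")
  check_sorted_pileup(dna_pileups, "DNA pileup")
  counts <- as.matrix(dna_pileups[, c("nA", "nC", "nG", "nT")])
  ref_col <- match(dna_pileups$ref, BASES)
  alt_counts <- counts
  alt_counts[cbind(seq_len(nrow(counts)), ref_col)] <- -1L
  top_alt_count <- do.call(pmax, as.data.frame(alt_counts))
  top_alt <- BASES[max.col(alt_counts, ties.method = "first")]
  df <- dna_pileups |>
    mutate(alt = top_alt,
           alt_frac = ifelse(.data$depth > 0, top_alt_count / .data$depth, 0),
           qualifies = .data$depth >= min_depth &
             .data$alt_frac >= min_alt_fraction)
  # best qualifying row per position (vectorised; positions are unique when
  # a single pooled DNA sample is supplied)
  mask <- df |>
    filter(.data$qualifies) |>
    arrange(.data$contig, .data$pos, dplyr::desc(.data$alt_frac)) |>
    distinct(.data$contig, .data$pos, .keep_all = TRUE) |>
    mutate(provenance = "exome") |>
    select("contig", "pos", "ref", "alt", "provenance")
  deep <- df |>
    filter(.data$depth >= min_depth) |>
    distinct(.data$contig, .data$pos)
  unassessable <- df |>
    distinct(.data$contig, .data$pos) |>
    anti_join(deep, by = c("contig", "pos")) |>
    arrange(.data$contig, .data$pos)
  new_snp_mask(mask, unassessable)
}

#' Merge a supplied known-variant list into a SNP mask
#'
#' Union of positions; provenance per entry becomes `"exome"`, `"supplied"`
#' or `"both"`. Idempotent: merging the same list twice changes nothing.
#'
#' @param mask A `snp_mask` (e.g. from [call_exome_snps()]), or `NULL` to
#'   build a mask from the list alone.
#' @param known Tibble with columns `contig` and `pos` (extra columns such
#'   as `ref`/`alt` are carried through when present).
#' @return A `snp_mask`.
#' @export
merge_known_variants <- function(mask, known) {
  if (is.null(mask)) {
    mask <- new_snp_mask(
      tibble(contig = character(), pos = integer(), ref = NA_character_,
             alt = NA_character_, provenance = character()),
      tibble(contig = character(), pos = integer())
    )
  }
  stopifnot(inherits(mask, "snp_mask"))
  assert_columns(known, c("contig", "pos"), "known-variant list")
  bad <- which(!is.finite(known$pos) | known$pos < 1 |
                 known$pos != as.integer(known$pos) |
                 is.na(known$contig) | known$contig == "")
  if (length(bad) > 0) {
    stop_editomer(sprintf("malformed known-variant record at line %d", bad[1]),
                  "editomer_parse_error")
  }
  known <- known |>
    distinct(.data$contig, .data$pos, .keep_all = TRUE) |>
    mutate(pos = as.integer(.data$pos),
           ref = if ("ref" %in% names(known)) .data$ref else NA_character_,
           alt = if ("alt" %in% names(known)) .data$alt else NA_character_,
           provenance = "supplied") |>
    select("contig", "pos", "ref", "alt", "provenance")
  merged <- bind_rows(mask$mask, known) |>
    group_by(.data$contig, .data$pos) |>
    summarise(
      ref = first(.data$ref[!is.na(.data$ref)], default = NA_character_),
      alt = first(.data$alt[!is.na(.data$alt)], default = NA_character_),
      provenance = combine_provenance(.data$provenance),
      .groups = "drop"
    ) |>
    arrange(.data$contig, .data$pos)
  new_snp_mask(merged, mask$unassessable)
}

combine_provenance <- function(p) {
  has_ex <- any(p %in% c("exome", "both"))
  has_sup <- any(p %in% c("supplied", "both"))
  if (has_ex && has_sup) "both" else p[1]
}

#' @export
print.snp_mask <- function(x, ...) {
  cat(sprintf("<snp_mask> %d masked position(s) (%s), %d unassessable\n",
              nrow(x$mask),
              paste(sprintf("%s: %d", names(table(x$mask$provenance)),
                            table(x$mask$provenance)), collapse = ", "),
              nrow(x$unassessable)))
  invisible(x)
}
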