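# Replicate-consensus rules: a site counts only if the identical site
# (coordinate + change) is edited in all replicate animals of a genotype; a
# gene counts if every animal carries at least one passing call anywhere in
# its full span (UTRs, exons and introns).

#' Consensus edited sites across replicate animals
#'
#' A site is keyed by (`contig`, `pos`, `change`), so opposite-orientation
#' events at one coordinate are distinct sites. Under the default
#' `n_required` (all animals) this is the exact intersection of the
#' per-animal site sets; a k-of-n generalisation is available but the
#' all-animals rule is the default.
#'
#' @param calls Call tibble from [call_edit_sites()] (one genotype's
#'   animals), with `sample_id` identifying the animal.
#' @param animals Character vector of the animals that must support a site;
#'   defaults to every `sample_id` present in `calls`.
#' @param n_required Number of supporting animals required; default
#'   `length(animals)`. Must not exceed the animal count.
#' @return Tibble: `contig`, `pos`, `change`, `n_animals`.
#' @export
consensus_sites <- function(calls, animals = NULL, n_required = NULL) {
  assert_columns(calls, c("contig", "pos", "change", "sample_id"), "calls")
  animals <- animals %||% sort(unique(calls$sample_id))
  if (length(animals) < 1) {
    stop_editomer("consensus requires at least one animal",
                  "editomer_parameter_error")
  }
  n_required <- n_required %||% length(animals)
  if (n_required > length(animals)) {
    stop_editomer(
      sprintf("n_required (%d) exceeds the number of animals (%d)",
              n_required, length(animals)),
      "editomer_parameter_error"
    )
  }
  calls |>
    filter(.data$sample_id %in% animals) |>
    distinct(.data$sample_id, .data$contig, .data$pos, .data$change) |>
    count(.data$contig, .data$pos, .data$change, name = "n_animals") |>
    filter(.data$n_animals >= n_required) |>
    arrange(.data$contig, .data$pos, .data$change)
}

#' Consensus edited genes across replicate animals
#'
#' A gene is included iff every required animal has at least one passing
#' call at any position within the gene's full annotated span (editing can
#' occur anywhere in the gene, and need not be at the same site in each
#' animal). A call inside two overlapping genes credits both genes.
#'
#' @inheritParams consensus_sites
#' @param features Gene-feature tibble; gene spans are its per-gene extents.
#' @return Tibble: `gene_id`, `n_animals`.
#' @export
consensus_genes <- function(calls, features, animals = NULL,
                            n_required = NULL) {
  assert_columns(calls, c("contig", "pos", "sample_id"), "calls")
  animals <- animals %||% sort(unique(calls$sample_id))
  if (length(animals) < 1) {
    stop_editomer("consensus requires at least one animal",
                  "editomer_parameter_error")
  }
  n_required <- n_required %||% length(animals)
  if (n_required > length(animals)) {
    stop_editomer(
      sprintf("n_required (%d) exceeds the number of animals (%d)",
              n_required, length(animals)),
      "editomer_parameter_error"
    )
  }
  if ("gene_id" %in% names(calls)) {
    unknown <- setdiff(stats::na.omit(unique(calls$gene_id)),
                       unique(features$gene_id))
    if (length(unknown) > 0) {
      stop_editomer(
        sprintf("gene id(s) in calls absent from the feature table: %s",
                paste(head(unknown, 3), collapse = ", ")),
        "editomer_consistency_error"
      )
    }
  }
  calls <- calls |> filter(.data$sample_id %in% animals)
  spans <- gene_spans(features)
  hits <- overlap_points(calls[, c("contig", "pos")], spans)
  if (nrow(hits) == 0) return(tibble(gene_id = character(),
                                     n_animals = integer()))
  hits |>
    mutate(gene_id = spans$gene_id[.data$row_feature],
           sample_id = calls$sample_id[.data$row_site]) |>
    distinct(.data$gene_id, .data$sample_id) |>
    count(.data$gene_id, name = "n_animals") |>
    filter(.data$n_animals >= n_required) |>
    arrange(.data$gene_id)
}

#' Percent change in counts relative to a baseline genotype
#'
#' `100 * (n_g - n_baseline) / n_baseline` for every genotype.
#'
#' @param counts Tibble with columns `genotype` and `n`, or a named numeric
#'   vector.
#' @param baseline Baseline genotype label (default `"WT"`); its count must
#'   be positive.
#' @return Tibble: `genotype`, `n`, `percent_change`.
#' @export
percent_change <- function(counts, baseline = "WT") {
  if (!is.data.frame(counts)) {
    counts <- tibble(genotype = names(counts), n = as.numeric(counts))
  }
  assert_columns(counts, c("genotype", "n"), "counts")
  if (!baseline %in% counts$genotype) {
    stop_editomer(sprintf("baseline genotype '%s' not present", baseline),
                  "editomer_parameter_error")
  }
  b <- counts$n[counts$genotype == baseline][1]
  if (!is.finite(b) || b <= 0) {
    stop_editomer("percent change is undefined for a zero baseline count",
                  "editomer_undefined_change")
  }
  counts |> mutate(percent_change = 100 * (.data$n - b) / b)
}
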