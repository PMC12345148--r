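# Genomic-feature and repeat-class annotation of edit sites.

#' Assign each site to one feature class and (optionally) one repeat class
#'
#' When a site overlaps one or more gene features its class is chosen by the
#' fixed precedence 3'UTR > 5'UTR > CDS (exon) > intron — any base annotated
#' as UTR is reported as UTR — otherwise the site is intergenic and carries
#' no gene id. The repeat class is assigned independently by overlap (a site
#' can be, say, intron + SINE); ties among overlapping repeats are broken by
#' the smallest interval, then alphabetical class.
#'
#' @param sites Tibble with at least `contig` and `pos`.
#' @param features Gene-feature tibble (`contig`, `start`, `end`, `strand`,
#'   `gene_id`, `class`).
#' @param repeats Repeat tibble (`contig`, `start`, `end`, `class`) or `NULL`.
#' @param contig_lengths Optional named vector; when supplied, a site beyond
#'   its contig's bounds is a coordinate error.
#' @return `sites` with `feature_class`, `gene_id` (NA when intergenic) and
#'   `repeat_class` (NA when outside all repeats) columns added.
#' @export
assign_features <- function(sites, features, repeats = NULL,
                            contig_lengths = NULL) {
  assert_columns(sites, c("contig", "pos"), "sites")
  if (!is.null(contig_lengths)) {
    bad <- which(sites$pos < 1 | sites$pos > contig_lengths[sites$contig] |
                   !(sites$contig %in% names(contig_lengths)))
    if (length(bad) > 0) {
      stop_editomer(
        sprintf("site %s:%d is outside contig bounds",
                sites$contig[bad[1]], sites$pos[bad[1]]),
        "editomer_coordinate_error"
      )
    }
  }
  sites$feature_class <- "intergenic"
  sites$gene_id <- NA_character_
  hits <- overlap_points(sites, features)
  if (nrow(hits) > 0) {
    best <- hits |>
      mutate(class = features$class[.data$row_feature],
             gene_id = features$gene_id[.data$row_feature],
             prec = match(.data$class, FEATURE_PRECEDENCE)) |>
      arrange(.data$row_site, .data$prec, .data$gene_id) |>
      distinct(.data$row_site, .keep_all = TRUE)
    sites$feature_class[best$row_site] <- best$class
    sites$gene_id[best$row_site] <- best$gene_id
  }
  sites$repeat_class <- if (is.null(repeats)) NA_character_ else {
    repeat_class_at(sites, repeats)
  }
  sites
}

#' Per-genotype distribution of edit sites over feature and repeat classes
#'
#' Counts and proportions of consensus sites per feature class (proportions
#' sum to 1 within each genotype) and per repeat class, plus totals of
#' edited sites and of distinct edited genes among the assignments.
#'
#' @param assignments Tibble from [assign_features()] with an additional
#'   `genotype` column.
#' @return An `editome_summary` list of tibbles: `features` (`genotype`,
#'   `feature_class`, `n`, `prop`), `repeats` (`genotype`, `repeat_class`,
#'   `n`, `prop` of all sites), `totals` (`genotype`, `n_sites`, `n_genes`).
#' @export
distribution_summary <- function(assignments) {
  assert_columns(assignments, c("genotype", "feature_class"), "assignments")
  genotypes <- unique(assignments$genotype)
  features <- assignments |>
    count(.data$genotype, .data$feature_class) |>
    tidyr::complete(genotype = genotypes,
                    feature_class = SITE_CLASSES,
                    fill = list(n = 0L)) |>
    group_by(.data$genotype) |>
    mutate(prop = if (sum(.data$n) > 0) .data$n / sum(.data$n) else 0) |>
    ungroup() |>
    mutate(feature_class = factor(.data$feature_class,
                                  levels = SITE_CLASSES)) |>
    arrange(.data$genotype, .data$feature_class)
  totals <- assignments |>
    group_by(.data$genotype) |>
    summarise(n_sites = n(),
              n_genes = n_distinct(.data$gene_id[!is.na(.data$gene_id)]),
              .groups = "drop")
  repeats <- assignments |>
    filter(!is.na(.data$repeat_class)) |>
    count(.data$genotype, .data$repeat_class) |>
    tidyr::complete(genotype = genotypes,
                    repeat_class = REPEAT_CLASSES,
                    fill = list(n = 0L)) |>
    left_join(totals, by = "genotype") |>
    mutate(prop = ifelse(.data$n_sites > 0, .data$n / .data$n_sites, 0)) |>
    select("genotype", "repeat_class", "n", "prop")
  structure(list(features = features, repeats = repeats, totals = totals),
            class = "editome_summary")
}

#' @export
print.editome_summary <- function(x, ...) {
  cat("<editome_summary>\n")
  print(x$totals)
  print(tidyr::pivot_wider(x$features |> select(-"n"),
                           names_from = "feature_class",
                           values_from = "prop"))
  invisible(x)
}
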