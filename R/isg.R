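# ISG classification, DEG summaries, and the exact proportion test for
# uniquely edited sites falling within interferon-stimulated-gene RNAs.

#' Summarise differentially expressed genes against an ISG list
#'
#' Counts, per contrast and direction (up/down), the genes passing the fold
#' change and adjusted-p thresholds and how many of them are known ISGs.
#'
#' @param deg DEG tibble: `gene_id`, `log2_fc`, `adj_p`, `contrast`. Gene
#'   ids must be unique within a contrast.
#' @param isgs Character vector of ISG gene ids.
#' @param lfc_cut Minimum `|log2_fc|` (default 1).
#' @param p_cut Maximum adjusted p (default 0.05).
#' @return Tibble: `contrast`, `direction`, `n_deg`, `n_isg`, `fraction`.
#' @examples
#' deg <- tibble::tibble(gene_id = paste0("g", 1:4),
#'                       log2_fc = c(2, -3, 1.5, 0.1),
#'                       adj_p = c(0.01, 0.02, 0.3, 0.01),
#'                       contrast = "mut_vs_wt")
#' deg_isg_summary(deg, isgs = c("g1", "g3"))
#' @export
deg_isg_summary <- function(deg, isgs, lfc_cut = 1, p_cut = 0.05) {
  assert_columns(deg, c("gene_id", "log2_fc", "adj_p", "contrast"),
                 "DEG table")
  dup <- deg |> count(.data$contrast, .data$gene_id) |> filter(n > 1)
  if (nrow(dup) > 0) {
    stop_editomer(
      sprintf("duplicated gene id '%s' within contrast '%s'",
              dup$gene_id[1], dup$contrast[1]),
      "editomer_input_error"
    )
  }
  contrasts <- unique(deg$contrast)
  deg |>
    filter(abs(.data$log2_fc) >= lfc_cut, .data$adj_p < p_cut) |>
    mutate(direction = as.character(ifelse(.data$log2_fc > 0,
                                           "up", "down"))) |>
    group_by(.data$contrast, .data$direction) |>
    summarise(n_deg = n(), n_isg = sum(.data$gene_id %in% isgs),
              .groups = "drop") |>
    tidyr::complete(contrast = contrasts, direction = c("up", "down"),
                    fill = list(n_deg = 0L, n_isg = 0L)) |>
    mutate(fraction = ifelse(.data$n_deg > 0, .data$n_isg / .data$n_deg,
                             NA_real_))
}

#' Log-transform an expression matrix with a pseudocount
#'
#' Elementwise `log(x + pseudocount)`; with the default pseudocount of 1 a
#' zero maps to 0 in any base. Used to put FPKM-style values on a
#' visualisation-friendly scale.
#'
#' @param x Non-negative numeric matrix (or vector).
#' @param pseudocount Added before the log (default 1).
#' @param base Log base (default natural).
#' @return Transformed object of the same shape.
#' @export
log_transform_matrix <- function(x, pseudocount = 1, base = exp(1)) {
  if (any(x < 0, na.rm = TRUE)) {
    stop_editomer("expression values must be non-negative",
                  "editomer_domain_error")
  }
  log(x + pseudocount, base = base)
}

#' Two-sided Fisher exact test by hypergeometric enumeration
#'
#' For a 2x2 table with fixed margins, sums the probabilities of all tables
#' whose hypergeometric probability does not exceed that of the observed
#' table (with the customary relative tolerance on the comparison). Reports
#' the sample odds ratio, with the Haldane-Anscombe (+0.5) correction also
#' emitted for degenerate margins.
#'
#' @param tab 2x2 integer matrix or equivalent.
#' @return List: `p_value`, `odds_ratio` (may be `Inf`), `odds_ratio_haldane`.
#' @examples
#' fisher_exact_2x2(matrix(c(10, 10, 10, 10), 2))
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- matrix(as.numeric(tab), 2, 2)
  if (any(tab < 0) || any(tab != round(tab))) {
    stop_editomer("table entries must be non-negative integers",
                  "editomer_input_error")
  }
  a <- tab[1, 1]
  m <- sum(tab[1, ])   # row 1 total
  n_ <- sum(tab[2, ])  # row 2 total
  k <- sum(tab[, 1])   # column 1 total
  support <- max(0, k - n_):min(k, m)
  d <- dhyper(support, m, n_, k)
  p_obs <- dhyper(a, m, n_, k)
  p <- sum(d[d <= p_obs * (1 + 1e-7)])
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  or_h <- ((tab[1, 1] + 0.5) * (tab[2, 2] + 0.5)) /
    ((tab[1, 2] + 0.5) * (tab[2, 1] + 0.5))
  list(p_value = min(1, p), odds_ratio = or, odds_ratio_haldane = or_h)
}

#' Are uniquely edited sites enriched in ISG transcripts?
#'
#' For each genotype, builds the 2x2 table (site within an ISG RNA vs within
#' another gene) x (site unique to the genotype vs shared), over the
#' genotype's genic consensus sites, and reports the ISG proportion among
#' unique sites, the odds ratio, and the two-sided Fisher exact p computed
#' by hypergeometric enumeration ([fisher_exact_2x2()]). Intergenic sites
#' carry no transcript and are excluded.
#'
#' @param sites Tibble with `genotype`, `gene_id`, and logical `unique_site`
#'   (TRUE when the site belongs only to that genotype's consensus set).
#' @param isgs Character vector of ISG gene ids (non-empty).
#' @return An `isg_enrichment` tibble: `genotype`, `n_unique`, `n_shared`,
#'   `isg_unique`, `isg_shared`, `prop_unique_isg`, `prop_shared_isg`,
#'   `odds_ratio`, `odds_ratio_haldane`, `p_value`.
#' @export
isg_edit_proportion <- function(sites, isgs) {
  assert_columns(sites, c("genotype", "gene_id", "unique_site"), "sites")
  if (length(isgs) == 0) {
    stop_editomer("ISG list must be non-empty", "editomer_input_error")
  }
  genic <- sites |> filter(!is.na(.data$gene_id))
  if (nrow(genic) == 0) {
    stop_editomer("no genic sites: the ISG proportion is undefined",
                  "editomer_undefined_proportion")
  }
  out <- genic |>
    mutate(in_isg = .data$gene_id %in% isgs) |>
    group_by(.data$genotype) |>
    summarise(
      n_unique = sum(.data$unique_site),
      n_shared = sum(!.data$unique_site),
      isg_unique = sum(.data$unique_site & .data$in_isg),
      isg_shared = sum(!.data$unique_site & .data$in_isg),
      .groups = "drop"
    ) |>
    mutate(
      prop_unique_isg = ifelse(.data$n_unique > 0,
                               .data$isg_unique / .data$n_unique, NA_real_),
      prop_shared_isg = ifelse(.data$n_shared > 0,
                               .data$isg_shared / .data$n_shared, NA_real_)
    )
  tests <- purrr::pmap_dfr(
    out[, c("n_unique", "n_shared", "isg_unique", "isg_shared")],
    function(n_unique, n_shared, isg_unique, isg_shared) {
      tab <- matrix(c(isg_unique, isg_shared,
                      n_unique - isg_unique, n_shared - isg_shared),
                    nrow = 2, byrow = TRUE)
      ft <- fisher_exact_2x2(tab)
      tibble(odds_ratio = ft$odds_ratio,
             odds_ratio_haldane = ft$odds_ratio_haldane,
             p_value = ft$p_value)
    }
  )
  out <- bind_cols(out, tests)
  class(out) <- c("isg_enrichment", class(out))
  out
}

#' Minimal differential-expression caller (plumbing)
#'
#' Per-gene log2 fold change of group means (with one pseudocount) and an
#' exact two-sample Wilcoxon rank test, Benjamini-Hochberg adjusted. This is
#' a deliberately simple stand-in so the synthetic pipeline runs end to end;
#' it is not a replacement for a dedicated count-model DE method, and with
#' few replicates the rank test's attainable p-values are coarse.
#'
#' @param counts Numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns.
#' @param groups Character/factor of length `ncol(counts)` with exactly two
#'   levels; each group needs at least two samples. The contrast is
#'   `first_level_vs_second_level` with fold change of the first over the
#'   second.
#' @return DEG tibble: `gene_id`, `log2_fc`, `p_value`, `adj_p`, `contrast`.
#' @export
minimal_deg_call <- function(counts, groups) {
  counts <- as.matrix(counts)
  lv <- if (is.factor(groups)) levels(droplevels(groups)) else
    unique(as.character(groups))
  groups <- as.character(groups)
  if (length(lv) != 2) {
    stop_editomer("groups must have exactly two levels",
                  "editomer_parameter_error")
  }
  if (any(table(groups) < 2)) {
    stop_editomer("each group needs at least two samples",
                  "editomer_parameter_error")
  }
  a <- counts[, groups == lv[1], drop = FALSE]
  b <- counts[, groups == lv[2], drop = FALSE]
  lfc <- log2((rowMeans(a) + 1) / (rowMeans(b) + 1))
  p <- vapply(seq_len(nrow(counts)), function(i) {
    suppressWarnings(wilcox.test(a[i, ], b[i, ], exact = TRUE)$p.value)
  }, numeric(1))
  tibble(
    gene_id = rownames(counts) %||% as.character(seq_len(nrow(counts))),
    log2_fc = unname(lfc),
    p_value = p,
    adj_p = p.adjust(p, method = "BH"),
    contrast = paste(lv[1], lv[2], sep = "_vs_")
  )
}

#' Read an ISG list (one gene id per line)
#'
#' @param path Plain-text file, one gene id per line; blank lines and lines
#'   starting with `#` are ignored.
#' @return Character vector of unique gene ids.
#' @export
read_isg_list <- function(path) {
  x <- readr::read_lines(path)
  x <- trimws(x)
  unique(x[x != "" & !startsWith(x, "#")])
}
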