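# broom-style tidiers for the result objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an editome report
#'
#' One row per genotype with consensus and unique-set counts and the percent
#' change in site counts versus the baseline.
#'
#' @param x An `editome_report` from [run_pipeline()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.editome_report <- function(x, ...) {
  out <- x$counts
  if (!is.null(x$percent_change)) {
    out <- out |>
      left_join(x$percent_change |> select("genotype", "percent_change"),
                by = "genotype")
  }
  out
}

#' Glance at an editome report
#'
#' A one-row summary: totals, the genotype with the most uniquely edited
#' sites, and (when computed) that genotype's percent change and ISG
#' proportion-test p-value.
#'
#' @inheritParams tidy.editome_report
#' @return A one-row tibble.
#' @export
glance.editome_report <- function(x, ...) {
  top <- x$counts$genotype[which.max(x$counts$n_unique_sites)]
  pc <- if (!is.null(x$percent_change)) {
    x$percent_change$percent_change[x$percent_change$genotype == top][1]
  } else NA_real_
  pv <- if (!is.null(x$isg)) {
    x$isg$p_value[x$isg$genotype == top][1]
  } else NA_real_
  tibble(
    n_genotypes = nrow(x$counts),
    total_consensus_sites = sum(x$counts$n_sites),
    total_consensus_genes = sum(x$counts$n_genes),
    top_unique_genotype = top,
    top_unique_sites = max(x$counts$n_unique_sites),
    top_percent_change = pc,
    top_isg_p = pv
  )
}

#' Tidy / glance methods for the ISG enrichment result
#'
#' `tidy()` returns the per-genotype table (it already is tidy); `glance()`
#' reports the number of genotypes tested and the smallest p-value.
#'
#' @param x An `isg_enrichment` from [isg_edit_proportion()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.isg_enrichment <- function(x, ...) {
  as_tibble(x)
}

#' @rdname tidy.isg_enrichment
#' @export
glance.isg_enrichment <- function(x, ...) {
  tibble(n_genotypes = nrow(x), min_p_value = min(x$p_value, na.rm = TRUE))
}
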