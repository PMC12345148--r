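# Four-way (generally k-way) Venn partitioning of consensus sets.

#' Partition labeled sets into exclusive Venn cells
#'
#' Every element of the union is assigned to exactly one of the 2^k - 1
#' nonempty-label cells (the cell naming exactly the sets that contain it),
#' so cells are pairwise disjoint and their union is the union of the
#' inputs. All cells are reported, including empty ones.
#'
#' @param sets Named list of character vectors (typically one consensus
#'   gene or site set per genotype). Names must be unique and non-empty.
#' @return A `venn_partition` tibble: `cell` (labels joined by `&`),
#'   `labels` (list of member set names), `degree`, `n`, `members`
#'   (list-column of elements).
#' @examples
#' venn_partition(list(A = c("x", "y"), B = c("y", "z")))
#' @export
venn_partition <- function(sets) {
  if (is.null(names(sets)) || any(names(sets) == "") ||
      anyDuplicated(names(sets)) > 0) {
    stop_editomer("sets must have unique non-empty names",
                  "editomer_parameter_error")
  }
  labels <- names(sets)
  sets <- lapply(sets, function(s) unique(as.character(s)))
  universe <- sort(unique(unlist(sets, use.names = FALSE)))
  memb <- vapply(sets, function(s) universe %in% s,
                 logical(length(universe)))
  if (length(universe) == 1) memb <- matrix(memb, nrow = 1,
                                            dimnames = list(NULL, labels))
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(labels)))[-1, ,
                                                                   drop = FALSE]
  names(combos) <- labels
  sig <- if (length(universe) > 0) {
    apply(memb, 1, function(r) paste(labels[r], collapse = "&"))
  } else character(0)
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    in_cell <- as.logical(combos[i, ])
    cell <- paste(labels[in_cell], collapse = "&")
    el <- universe[sig == cell]
    tibble(cell = cell, labels = list(labels[in_cell]),
           degree = sum(in_cell), n = length(el), members = list(el))
  })
  out <- bind_rows(rows) |> arrange(.data$degree, .data$cell)
  class(out) <- c("venn_partition", class(out))
  out
}

#' Uniquely edited elements per set
#'
#' The singleton Venn cells: elements belonging to exactly one input set.
#' In the four-genotype comparison these are the uniquely edited genes or
#' sites of each genotype.
#'
#' @param partition A [venn_partition()] result.
#' @return Named list (one entry per input set) of unique-element vectors.
#' @export
unique_sets <- function(partition) {
  stopifnot(inherits(partition, "venn_partition"))
  singles <- partition[partition$degree == 1, ]
  setNames(singles$members, singles$cell)
}
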