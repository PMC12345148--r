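# Shared internal helpers: site keys, validation, truncated-Poisson draws.

GENOTYPES <- c("WT", "Adar_het", "RdRp_tg", "DoubleHet")

FEATURE_CLASSES <- c("five_prime_utr", "cds", "intron", "three_prime_utr")
SITE_CLASSES <- c("three_prime_utr", "five_prime_utr", "cds", "intron", "intergenic")
REPEAT_CLASSES <- c("SINE", "LINE", "DNA_transposon", "other_retrotransposon")

# precedence used when a site overlaps several gene features (3'UTR first)
FEATURE_PRECEDENCE <- c("three_prime_utr", "five_prime_utr", "cds", "intron")

BASES <- c("A", "C", "G", "T")

site_key <- function(contig, pos, change) {
  paste(contig, pos, change, sep = ":")
}

other_bases <- function(ref) {
  lapply(ref, function(b) BASES[BASES != b])
}

stop_editomer <- function(msg, class) {
  abort(msg, class = c(class, "editomer_error"))
}

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop_editomer(
      sprintf("%s is missing required column(s): %s", what,
              paste(missing, collapse = ", ")),
      "editomer_input_error"
    )
  }
  invisible(df)
}

# Poisson truncated at >= 1, by inverse-CDF so draws stay within the main
# RNG stream.
rpois_trunc1 <- function(n, lambda) {
  if (n == 0L) return(integer(0))
  p0 <- dpois(0, lambda)
  u <- runif(n, min = p0, max = 1)
  qpois(u, lambda)
}

# Check that pileup-style records are sorted by position within each
# (sample_id, contig) block and that contig blocks are contiguous.
# Returns NULL if sorted, otherwise a description of the first offence.
first_sort_offence <- function(df) {
  ids <- if ("sample_id" %in% names(df)) df$sample_id else rep("", nrow(df))
  blocks <- paste(ids, df$contig, sep = "\r")
  r <- rle(blocks)
  if (anyDuplicated(r$values) > 0) {
    dup <- r$values[duplicated(r$values)][1]
    i <- which(blocks == dup)
    i <- i[which(diff(i) > 1)[1] + 1L]
    return(sprintf("contig block for '%s' at record %d is not contiguous",
                   df$contig[i], i))
  }
  ends <- cumsum(r$lengths)
  starts <- c(1L, head(ends, -1) + 1L)
  for (b in seq_along(starts)) {
    p <- df$pos[starts[b]:ends[b]]
    bad <- which(diff(p) <= 0)
    if (length(bad) > 0) {
      i <- starts[b] + bad[1]
      return(sprintf("position %d on contig '%s' (record %d) is out of order",
                     df$pos[i], df$contig[i], i))
    }
  }
  NULL
}

check_sorted_pileup <- function(df, what = "pileup") {
  off <- first_sort_offence(df)
  if (!is.null(off)) {
    stop_editomer(sprintf("%s is not sorted: %s", what, off),
                  "editomer_order_error")
  }
  invisible(df)
}

# split genome strings into per-contig character vectors, memo-free
genome_chars <- function(genome) {
  lapply(genome, function(s) strsplit(s, "", fixed = TRUE)[[1]])
}

# base at (contig, pos) given the per-contig character list
base_at <- function(chars, contig, pos) {
  out <- character(length(contig))
  for (ct in unique(contig)) {
    i <- contig == ct
    out[i] <- chars[[ct]][pos[i]]
  }
  out
}

# gene spans (full interval incl. introns) from a gene-feature table
gene_spans <- function(features) {
  if (nrow(features) == 0) {
    return(tibble(contig = character(), start = integer(), end = integer(),
                  strand = character(), gene_id = character()))
  }
  features |>
    group_by(.data$contig, .data$gene_id, .data$strand) |>
    summarise(start = min(.data$start), end = max(.data$end),
              .groups = "drop") |>
    select("contig", "start", "end", "strand", "gene_id") |>
    arrange(.data$contig, .data$start)
}

# overlap of point positions against an interval tibble; returns a tibble
# of (row_site, row_feature) index pairs (1-based into each input)
overlap_points <- function(sites, intervals) {
  if (nrow(sites) == 0 || nrow(intervals) == 0) {
    return(tibble(row_site = integer(), row_feature = integer()))
  }
  q <- GenomicRanges::GRanges(sites$contig,
                              IRanges::IRanges(sites$pos, sites$pos))
  s <- GenomicRanges::GRanges(intervals$contig,
                              IRanges::IRanges(intervals$start, intervals$end))
  h <- GenomicRanges::findOverlaps(q, s, ignore.strand = TRUE)
  tibble(row_site = S4Vectors::queryHits(h),
         row_feature = S4Vectors::subjectHits(h))
}
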