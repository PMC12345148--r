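# Interchange formats. Coordinates are 1-based inclusive everywhere inside
# the package; BED files are 0-based half-open and converted exactly once at
# read/write time.

#' Convert between BED (0-based half-open) and internal (1-based inclusive)
#'
#' `bed_to_internal()` maps a BED interval `[start0, end0)` to
#' `[start0 + 1, end0]`; `internal_to_bed()` inverts it. The pair is
#' lossless by construction and round-trip tested.
#'
#' @param start0,end0 BED coordinates.
#' @param start,end Internal coordinates.
#' @return Two-column tibble of converted coordinates.
#' @export
bed_to_internal <- function(start0, end0) {
  tibble(start = as.integer(start0 + 1L), end = as.integer(end0))
}

#' @rdname bed_to_internal
#' @export
internal_to_bed <- function(start, end) {
  tibble(start0 = as.integer(start - 1L), end0 = as.integer(end))
}

#' Read and write genomes as FASTA
#'
#' Thin wrappers over Biostrings that exchange a named character vector of
#' contig sequences.
#'
#' @param genome Named character vector of sequences.
#' @param path FASTA file path.
#' @return `read_genome_fasta()` returns a named character vector.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

pileup_cols <- readr::cols(
  contig = readr::col_character(), pos = readr::col_integer(),
  ref = readr::col_character(), nA = readr::col_integer(),
  nC = readr::col_integer(), nG = readr::col_integer(),
  nT = readr::col_integer(), depth = readr::col_integer(),
  sample_id = readr::col_character()
)

#' Read and write base-count pileups as TSV
#'
#' Columns: `contig`, `pos` (1-based), `ref`, `nA`, `nC`, `nG`, `nT`,
#' `depth`, `sample_id`. On read, `depth` must equal the four base counts
#' summed and records must be position-sorted within each sample; violations
#' raise errors naming the first offending record.
#'
#' @param pileups Pileup tibble.
#' @param path TSV path.
#' @return `read_pileups()` returns the validated tibble.
#' @export
write_pileups <- function(pileups, path) {
  readr::write_tsv(pileups[, names(pileup_cols$cols)], path)
  invisible(path)
}

#' @rdname write_pileups
#' @export
read_pileups <- function(path) {
  df <- readr::read_tsv(path, col_types = pileup_cols, progress = FALSE)
  bad <- which(df$depth != df$nA + df$nC + df$nG + df$nT | df$pos < 1)
  if (length(bad) > 0) {
    stop_editomer(
      sprintf("invalid pileup record at line %d of %s", bad[1] + 1L, path),
      "editomer_parse_error"
    )
  }
  check_sorted_pileup(df, sprintf("pileup file %s", path))
  df
}

#' Read and write feature and repeat annotation as BED
#'
#' Six-column BED, 0-based half-open. For gene features the name column is
#' `gene_id|feature_class` and column 6 is the strand; for repeats the name
#' is the repeat class and the strand is `.`.
#'
#' @param features Gene-feature tibble (`contig`, `start`, `end`, `strand`,
#'   `gene_id`, `class`; 1-based inclusive).
#' @param repeats Repeat tibble (`contig`, `start`, `end`, `class`).
#' @param path BED path.
#' @return Readers return the corresponding internal tibble.
#' @export
write_features_bed <- function(features, path) {
  conv <- internal_to_bed(features$start, features$end)
  readr::write_tsv(
    tibble(contig = features$contig, start = conv$start0, end = conv$end0,
           name = paste(features$gene_id, features$class, sep = "|"),
           score = 0L, strand = features$strand),
    path, col_names = FALSE
  )
  invisible(path)
}

bed6_cols <- readr::cols(
  contig = readr::col_character(), start = readr::col_integer(),
  end = readr::col_integer(), name = readr::col_character(),
  score = readr::col_integer(), strand = readr::col_character()
)

read_bed6 <- function(path) {
  readr::read_tsv(path, col_names = names(bed6_cols$cols),
                  col_types = bed6_cols, progress = FALSE)
}

#' @rdname write_features_bed
#' @export
read_features_bed <- function(path) {
  df <- read_bed6(path)
  conv <- bed_to_internal(df$start, df$end)
  parts <- strsplit(df$name, "|", fixed = TRUE)
  bad <- which(lengths(parts) != 2)
  if (length(bad) > 0) {
    stop_editomer(
      sprintf("malformed feature name '%s' at line %d of %s (expected gene_id|class)",
              df$name[bad[1]], bad[1], path),
      "editomer_parse_error"
    )
  }
  tibble(contig = df$contig, start = conv$start, end = conv$end,
         strand = df$strand,
         gene_id = vapply(parts, `[`, character(1), 1),
         class = vapply(parts, `[`, character(1), 2))
}

#' @rdname write_features_bed
#' @export
write_repeats_bed <- function(repeats, path) {
  conv <- internal_to_bed(repeats$start, repeats$end)
  readr::write_tsv(
    tibble(contig = repeats$contig, start = conv$start0, end = conv$end0,
           name = repeats$class, score = 0L, strand = "."),
    path, col_names = FALSE
  )
  invisible(path)
}

#' @rdname write_features_bed
#' @export
read_repeats_bed <- function(path) {
  df <- read_bed6(path)
  conv <- bed_to_internal(df$start, df$end)
  tibble(contig = df$contig, start = conv$start, end = conv$end,
         class = df$name)
}

vcf_header <- function(info_lines) {
  c("##fileformat=VCFv4.2",
    info_lines,
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t"))
}

read_vcf_body <- function(path) {
  lines <- readr::read_lines(path)
  body <- lines[!startsWith(lines, "#") & lines != ""]
  if (length(body) == 0) {
    return(tibble(CHROM = character(), POS = integer(), ID = character(),
                  REF = character(), ALT = character(), QUAL = character(),
                  FILTER = character(), INFO = character()))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 8)
  if (length(bad) > 0) {
    stop_editomer(sprintf("malformed VCF record at data line %d of %s",
                          bad[1], path),
                  "editomer_parse_error")
  }
  m <- do.call(rbind, parts)
  tibble(CHROM = m[, 1], POS = as.integer(m[, 2]), ID = m[, 3],
         REF = m[, 4], ALT = m[, 5], QUAL = m[, 6], FILTER = m[, 7],
         INFO = m[, 8])
}

info_field <- function(info, key) {
  hit <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]*"), info))
  out <- rep(NA_character_, length(info))
  found <- lengths(regmatches(info, gregexpr(paste0("(^|;)", key, "="),
                                             info))) > 0
  out[found] <- sub(paste0("^.*", key, "="), "", hit)
  out
}

#' Read and write a SNP mask as minimal VCF
#'
#' `CHROM POS ID REF ALT QUAL FILTER INFO` with provenance carried in
#' `INFO/ORIGIN` (`exome`, `supplied` or `both`). Unassessable positions are
#' not part of the VCF and are restored empty on read.
#'
#' @param mask A `snp_mask`.
#' @param path VCF path.
#' @return `read_mask_vcf()` returns a `snp_mask` (empty unassessable set).
#' @export
write_mask_vcf <- function(mask, path) {
  stopifnot(inherits(mask, "snp_mask"))
  m <- mask$mask
  header <- vcf_header(
    '##INFO=<ID=ORIGIN,Number=1,Type=String,Description="Mask provenance">')
  rows <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\tORIGIN=%s",
                  m$contig, m$pos,
                  ifelse(is.na(m$ref), "N", m$ref),
                  ifelse(is.na(m$alt), ".", m$alt),
                  m$provenance)
  readr::write_lines(c(header, rows), path)
  invisible(path)
}

#' @rdname write_mask_vcf
#' @export
read_mask_vcf <- function(path) {
  df <- read_vcf_body(path)
  new_snp_mask(
    tibble(contig = df$CHROM, pos = df$POS,
           ref = ifelse(df$REF == "N", NA_character_, df$REF),
           alt = ifelse(df$ALT == ".", NA_character_, df$ALT),
           provenance = info_field(df$INFO, "ORIGIN")),
    tibble(contig = character(), pos = integer())
  )
}

#' Read and write per-animal edit calls as minimal VCF
#'
#' One file per animal. `ALT` is `G` (A>G) or `C` (T>C); `INFO` carries
#' `DP` (depth), `VR` (variant reads), `STRAND` (`+`, `-` or `.` for
#' unstranded), `GENE` (`.` when intergenic) and `SAMPLE`. The editing
#' fraction is recomputed from `VR/DP` on read, so the round trip is exact.
#'
#' @param calls Call tibble from [call_edit_sites()] (single sample).
#' @param path VCF path.
#' @return `read_calls_vcf()` returns the call tibble.
#' @export
write_calls_vcf <- function(calls, path) {
  header <- vcf_header(c(
    '##INFO=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##INFO=<ID=VR,Number=1,Type=Integer,Description="Variant reads">',
    '##INFO=<ID=STRAND,Number=1,Type=String,Description="Transcript strand">',
    '##INFO=<ID=GENE,Number=1,Type=String,Description="Containing gene">',
    '##INFO=<ID=SAMPLE,Number=1,Type=String,Description="Animal">'))
  rows <- sprintf(
    "%s\t%d\t.\t%s\t%s\t.\t.\tDP=%d;VR=%d;STRAND=%s;GENE=%s;SAMPLE=%s",
    calls$contig, calls$pos, calls$ref,
    ifelse(calls$change == "A>G", "G", "C"),
    calls$depth, calls$variant_reads,
    ifelse(calls$strand == "unstranded", ".", calls$strand),
    ifelse(is.na(calls$gene_id), ".", calls$gene_id),
    calls$sample_id)
  readr::write_lines(c(header, rows), path)
  invisible(path)
}

#' @rdname write_calls_vcf
#' @export
read_calls_vcf <- function(path) {
  df <- read_vcf_body(path)
  strand <- info_field(df$INFO, "STRAND")
  gene <- info_field(df$INFO, "GENE")
  depth <- as.integer(info_field(df$INFO, "DP"))
  vr <- as.integer(info_field(df$INFO, "VR"))
  tibble(
    contig = df$CHROM, pos = df$POS,
    strand = ifelse(strand == ".", "unstranded", strand),
    change = ifelse(df$ALT == "G", "A>G", "T>C"),
    ref = df$REF, depth = depth, variant_reads = vr,
    editing_fraction = ifelse(depth > 0, vr / depth, NA_real_),
    gene_id = ifelse(gene == ".", NA_character_, gene),
    sample_id = info_field(df$INFO, "SAMPLE")
  )
}

#' Read a sample sheet
#'
#' TSV with columns `sample_id`, `animal`, `genotype` and `rna_pileup`
#' (path to the sample's RNA pileup TSV).
#'
#' @param path TSV path.
#' @return Tibble.
#' @export
read_sample_sheet <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  assert_columns(df, c("sample_id", "animal", "genotype", "rna_pileup"),
                 "sample sheet")
  df
}
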