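#' Read a bedGraph track
#'
#' Parses a 4-column bedGraph (via rtracklayer) into the 0-based half-open
#' tibble representation used by the scoring functions.
#'
#' @param path Path to an uncompressed bedGraph file.
#' @return Tibble with columns `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    value = as.numeric(gr$score)
  )
}

#' Write a bedGraph track
#'
#' @param track Tibble with columns `chrom`, `start`, `end`, `value`
#'   (0-based half-open).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  gr <- GenomicRanges::GRanges(track$chrom,
                               IRanges::IRanges(track$start + 1L, track$end),
                               score = track$value)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a BED interval file
#'
#' Reads the first 3+ columns of a BED file (0-based half-open), e.g. a
#' gene exclusion list.
#'
#' @param path Path to an uncompressed BED file.
#' @return Tibble with `chrom`, `start`, `end` and, when present, `name`,
#'   `score`, `strand`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
  if (!is.null(gr$name)) out$name <- gr$name
  if (!is.null(gr$score)) out$score <- as.numeric(gr$score)
  st <- as.character(GenomicRanges::strand(gr))
  if (any(st != "*")) out$strand <- st
  out
}

#' Write intervals as BED
#'
#' Writes `chrom`, `start`, `end` plus optional `name`/`score`/`strand`
#' columns (sites tables work directly: `site_id` is used as the name and
#' `strand` is kept).
#'
#' @param x Tibble with at least `chrom`, `start`, `end`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  name <- if ("name" %in% names(x)) x$name else
    if ("site_id" %in% names(x)) x$site_id else "."
  score <- if ("score" %in% names(x)) x$score else 0
  strand <- if ("strand" %in% names(x)) x$strand else "."
  df <- data.frame(x$chrom, x$start, x$end, name, score, strand)
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}

#' Read/write the package's tabular artifacts
#'
#' Plain TSV round-trip for sites, types, candidates, edits, feature
#' matrices and association results. `write_chromoff_tsv()` drops list
#' columns and writes a header; `read_chromoff_tsv()` restores column types
#' from the data.
#'
#' @param x A tibble.
#' @param path File path.
#' @return The tibble (read) or `path` invisibly (write).
#' @export
write_chromoff_tsv <- function(x, path) {
  x <- x[, !vapply(x, is.list, logical(1)), drop = FALSE]
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname write_chromoff_tsv
#' @export
read_chromoff_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Read a gene score table
#'
#' TSV with columns `chrom`, `start`, `end`, `gene_id`, `score` (0-based
#' half-open intervals), e.g. per-gene FPKM values.
#'
#' @param path Path to the TSV.
#' @return Tibble with those columns.
#' @export
read_gene_table <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("chrom", "start", "end", "gene_id", "score") %in% names(out)))
  out
}

#' Write simulated variant calls as a tumor-normal VCF
#'
#' Emits a minimal VCFv4.2 with two genotype columns (control, editor) so
#' the somatic-style filter path in [load_filtered_variants()] is exercised:
#' `FILTER=PASS` records with `GT:AF:DP` fields and the allele fraction on
#' the editor sample.
#'
#' @param variants Tibble with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`, `allele_fraction`.
#' @param path Output path.
#' @param normal_name,tumor_name Sample column names.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path, normal_name = "control",
                      tumor_name = "editor") {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=chromoff-simulator",
    "##FILTER=<ID=PASS,Description=\"All filters passed\">",
    "##INFO=<ID=SOMATIC,Number=0,Type=Flag,Description=\"Somatic event\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AF,Number=A,Type=Float,Description=\"Allele fraction\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", normal_name, tumor_name, sep = "\t")
  )
  rows <- character(0)
  if (nrow(variants) > 0) {
    v <- variants %>% arrange(.data$chrom, .data$pos)
    rows <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tSOMATIC\tGT:AF:DP\t0/0:0.00:40\t0/1:%.4f:40",
                    v$chrom, v$pos, v$ref, v$alt, v$allele_fraction)
  }
  writeLines(c(header, rows), path)
  invisible(path)
}
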