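#' Names of the thirteen chromatin-context features
#'
#' Four histone marks (H3K9me3, H3K4me1, H3K36me3, H3K27ac), DNA
#' methylation, seven accessibility/occupancy signals (ATAC, DNase, RNAP2,
#' TCF27, ELK4, TCF7L2, TRIM28), and expression (FPKM).
#'
#' @return Character vector of length 13.
#' @export
chromatin_feature_names <- function() {
  c("H3K9me3", "H3K4me1", "H3K36me3", "H3K27ac", "DNA_methylation",
    "ATAC", "DNase", "RNAP2", "TCF27", "ELK4", "TCF7L2", "TRIM28", "FPKM")
}

# the 11 features scored as coverage-weighted interval tracks
interval_feature_names <- function() {
  setdiff(chromatin_feature_names(), c("DNA_methylation", "FPKM"))
}

#' Build the 50-bp scoring window around each site
#'
#' The scoring window is the site sequence plus 15 bp upstream and 12 bp
#' downstream. Upstream/downstream are strand-aware: upstream is 5' of
#' position 1 of the targeted-strand sequence, so a minus-strand site's
#' upstream flank lies at higher genomic coordinates. Windows are clipped at
#' contig edges when lengths are supplied; `win_len` records the actual
#' width.
#'
#' @param sites Site tibble with `chrom`, `start`, `end`, `strand`.
#' @param genome_lengths Optional named vector of chromosome lengths for
#'   edge clipping (see [genome_lengths()]).
#' @param upstream,downstream Flank widths in bp (defaults 15 and 12; with a
#'   23-bp site the window is 50 bp).
#' @param strand_aware If `FALSE`, upstream is always the lower-coordinate
#'   side regardless of strand.
#' @return `sites` with `win_start`, `win_end` (0-based half-open) and
#'   `win_len` columns added.
#' @export
make_window <- function(sites, genome_lengths = NULL, upstream = 15L,
                        downstream = 12L, strand_aware = TRUE) {
  plus <- if (strand_aware) sites$strand == "+" else rep(TRUE, nrow(sites))
  ws <- ifelse(plus, sites$start - upstream, sites$start - downstream)
  we <- ifelse(plus, sites$end + downstream, sites$end + upstream)
  ws <- pmax(ws, 0L)
  if (!is.null(genome_lengths)) {
    we <- pmin(we, as.integer(genome_lengths[sites$chrom]))
  }
  sites %>%
    mutate(win_start = as.integer(ws), win_end = as.integer(we),
           win_len = .data$win_end - .data$win_start)
}

windows_to_granges <- function(windows) {
  GenomicRanges::GRanges(windows$chrom,
                         IRanges::IRanges(windows$win_start + 1L,
                                          windows$win_end))
}

#' Score windows against an interval signal track
#'
#' Coverage-weighted mean of track values over each window. In `"zero"`
#' mode (the bedGraph convention: absent signal is zero) uncovered bases
#' contribute value 0 with full weight, so the score is
#' `sum(value * overlap_bp) / win_len`; in `"exclude"` mode the mean is over
#' covered bases only. Windows with no overlapping interval score 0.
#'
#' @param windows Tibble from [make_window()].
#' @param track Track tibble with columns `chrom`, `start`, `end` (0-based
#'   half-open) and `value` (see [read_bedgraph()]).
#' @param uncovered `"zero"` (default) or `"exclude"`.
#' @return Numeric vector of scores, one per window.
#' @export
score_interval_track <- function(windows, track,
                                 uncovered = c("zero", "exclude")) {
  uncovered <- match.arg(uncovered)
  n <- nrow(windows)
  num <- numeric(n)
  cov <- numeric(n)
  if (nrow(track) > 0) {
    win_gr <- windows_to_granges(windows)
    trk_gr <- GenomicRanges::GRanges(track$chrom,
                                     IRanges::IRanges(track$start + 1L,
                                                      track$end))
    ov <- GenomicRanges::findOverlaps(win_gr, trk_gr)
    if (length(ov) > 0) {
      wi <- S4Vectors::queryHits(ov)
      ti <- S4Vectors::subjectHits(ov)
      olap <- pmin(windows$win_end[wi], track$end[ti]) -
        pmax(windows$win_start[wi], track$start[ti])
      num <- num + as.numeric(tapply(olap * track$value[ti],
                                     factor(wi, levels = seq_len(n)),
                                     sum, default = 0))
      cov <- cov + as.numeric(tapply(olap, factor(wi, levels = seq_len(n)),
                                     sum, default = 0))
    }
  }
  if (uncovered == "zero") {
    ifelse(windows$win_len > 0, num / windows$win_len, 0)
  } else {
    ifelse(cov > 0, num / cov, 0)
  }
}

#' Count methylation records in each window
#'
#' DNA methylation is scored as the number of methylation-site records whose
#' position falls inside the window (half-open: a record exactly at
#' `win_start` counts, one at `win_end` does not).
#'
#' @param windows Tibble from [make_window()].
#' @param track Tibble of point records with columns `chrom`, `start`
#'   (0-based position; an `end` column is ignored).
#' @return Integer vector of counts.
#' @export
score_methylation <- function(windows, track) {
  n <- nrow(windows)
  if (nrow(track) == 0) return(integer(n))
  win_gr <- windows_to_granges(windows)
  pt_gr <- GenomicRanges::GRanges(track$chrom,
                                  IRanges::IRanges(track$start + 1L,
                                                   track$start + 1L))
  GenomicRanges::countOverlaps(win_gr, pt_gr)
}

#' Score windows by expression of overlapping genes
#'
#' Mean expression score (e.g. FPKM) of all genes whose interval overlaps
#' the window; windows overlapping no gene score 0. The aggregation across
#' multiple overlapping genes is configurable.
#'
#' @param windows Tibble from [make_window()].
#' @param gene_table Tibble with columns `chrom`, `start`, `end` (0-based
#'   half-open), `gene_id`, `score`.
#' @param multi_gene Aggregation over overlapping genes: `"mean"` (default),
#'   `"max"`, or `"sum"`.
#' @return Numeric vector of scores.
#' @export
score_expression <- function(windows, gene_table,
                             multi_gene = c("mean", "max", "sum")) {
  multi_gene <- match.arg(multi_gene)
  n <- nrow(windows)
  out <- numeric(n)
  if (nrow(gene_table) == 0) return(out)
  win_gr <- windows_to_granges(windows)
  gene_gr <- GenomicRanges::GRanges(gene_table$chrom,
                                    IRanges::IRanges(gene_table$start + 1L,
                                                     gene_table$end))
  ov <- GenomicRanges::findOverlaps(win_gr, gene_gr)
  if (length(ov) == 0) return(out)
  agg <- tapply(gene_table$score[S4Vectors::subjectHits(ov)],
                factor(S4Vectors::queryHits(ov), levels = seq_len(n)),
                switch(multi_gene, mean = mean, max = max, sum = sum))
  hit <- !is.na(agg)
  out[hit] <- as.numeric(agg[hit])
  out
}

#' Score sites on all supplied chromatin features
#'
#' Builds the 50-bp window for each site and scores every supplied feature:
#' interval tracks by coverage-weighted mean ([score_interval_track()]),
#' methylation by record count ([score_methylation()]), expression by mean
#' overlapping-gene score ([score_expression()]). A feature whose track is
#' not supplied is absent from the output (never silently zero).
#'
#' @param sites Site tibble.
#' @param tracks Named list of interval-track tibbles (names from
#'   [chromatin_feature_names()], excluding `DNA_methylation`/`FPKM`).
#' @param methylation Optional methylation point-record tibble.
#' @param genes Optional gene score table for the `FPKM` feature.
#' @param genome_lengths Optional chromosome lengths for window clipping.
#' @param uncovered,multi_gene,strand_aware Passed to the scorers /
#'   [make_window()].
#' @return Tibble with `site_id` and one numeric column per scored feature;
#'   scoring modes are recorded in the `scoring_modes` attribute.
#' @export
score_sites <- function(sites, tracks = list(), methylation = NULL,
                        genes = NULL, genome_lengths = NULL,
                        uncovered = "zero", multi_gene = "mean",
                        strand_aware = TRUE) {
  if (length(tracks) > 0 && is.null(names(tracks))) {
    stop("`tracks` must be a named list", call. = FALSE)
  }
  win <- make_window(sites, genome_lengths = genome_lengths,
                     strand_aware = strand_aware)
  out <- tibble(site_id = sites$site_id)
  for (nm in names(tracks)) {
    out[[nm]] <- score_interval_track(win, tracks[[nm]], uncovered = uncovered)
  }
  if (!is.null(methylation)) {
    out[["DNA_methylation"]] <- score_methylation(win, methylation)
  }
  if (!is.null(genes)) {
    out[["FPKM"]] <- score_expression(win, genes, multi_gene = multi_gene)
  }
  attr(out, "scoring_modes") <- list(
    uncovered = uncovered, multi_gene = multi_gene,
    strand_aware = strand_aware, upstream = 15L, downstream = 12L
  )
  out
}
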