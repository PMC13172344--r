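#' Build a genome index from named sequences
#'
#' A genome index is a named character vector of chromosome sequences with
#' case preserved (lowercase marks soft-masked repeats, as in UCSC/Ensembl
#' FASTA). The alphabet is restricted to `A`, `C`, `G`, `T`, `N` in either
#' case.
#'
#' @param sequences Named character vector or named list of single strings,
#'   one per chromosome.
#' @return A named character vector of class `genome_index` with a `lengths`
#'   attribute (named integer vector of chromosome lengths in bp).
#' @examples
#' genome_index(c(chr1 = "ACGTacgtNNN"))
#' @export
genome_index <- function(sequences) {
  if (is.list(sequences)) sequences <- vapply(sequences, paste0, character(1))
  if (is.null(names(sequences)) || any(!nzchar(names(sequences)))) {
    stop("all sequences must be named by chromosome", call. = FALSE)
  }
  if (anyDuplicated(names(sequences))) {
    stop("duplicated chromosome names", call. = FALSE)
  }
  bad <- !grepl("^[ACGTNacgtn]*$", sequences)
  if (any(bad)) {
    stop("sequences contain characters outside {A,C,G,T,N}: ",
         paste(names(sequences)[bad], collapse = ", "), call. = FALSE)
  }
  structure(
    as.character(sequences),
    names = names(sequences),
    lengths = setNames(nchar(sequences), names(sequences)),
    class = c("genome_index", "character")
  )
}

#' @export
print.genome_index <- function(x, ...) {
  cat("<genome_index> ", length(x), " sequence(s), ",
      format(sum(attr(x, "lengths")), big.mark = ","), " bp total\n", sep = "")
  for (nm in head(names(x), 10)) {
    cat("  ", nm, ": ", format(attr(x, "lengths")[[nm]], big.mark = ","),
        " bp\n", sep = "")
  }
  if (length(x) > 10) cat("  ...\n")
  invisible(x)
}

#' Chromosome lengths of a genome index
#'
#' @param genome A [genome_index()] (or named character vector of sequences).
#' @return Named integer vector of lengths in bp.
#' @export
genome_lengths <- function(genome) {
  lens <- attr(genome, "lengths")
  if (is.null(lens)) lens <- setNames(nchar(genome), names(genome))
  lens
}

#' Read a genome from FASTA
#'
#' Reads a (multi-record, possibly soft-masked) FASTA file preserving case,
#' so downstream filters can distinguish soft-masked lowercase bases.
#'
#' @param path Path to an uncompressed FASTA file.
#' @return A [genome_index()].
#' @export
read_genome <- function(path) {
  recs <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE,
                             seqonly = FALSE)
  genome_index(setNames(unlist(recs), names(recs)))
}

#' Write a genome to FASTA
#'
#' @param genome A [genome_index()] or named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  seqinr::write.fasta(as.list(unclass(genome)), names = names(genome),
                      file.out = path, as.string = TRUE, nbchar = 70)
  invisible(path)
}

#' Reverse complement a whole genome
#'
#' Utility used mainly by the strand-symmetry property tests: every
#' chromosome is reverse-complemented in place (names kept).
#'
#' @param genome A [genome_index()].
#' @return A [genome_index()] of the reverse-complemented sequences.
#' @export
revcomp_genome <- function(genome) {
  genome_index(setNames(revcomp(as.character(genome)), names(genome)))
}
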