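DNA_BASES <- c("A", "C", "G", "T")

# IUPAC nucleotide codes -> the set of bases each one matches
IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement. Case is preserved (soft-masked lowercase
#' stays lowercase); `N`/`n` maps to itself.
#'
#' @param x Character vector of DNA strings.
#' @return Character vector of the same length.
#' @examples
#' revcomp(c("ACGT", "aacgGG"))
#' @export
revcomp <- function(x) {
  flipped <- vapply(
    strsplit(x, NULL),
    function(s) paste(rev(s), collapse = ""),
    character(1)
  )
  chartr("ACGTacgt", "TGCAtgca", flipped)
}

#' GC content of DNA strings
#'
#' @param x Character vector of DNA strings (case-insensitive).
#' @return Numeric vector of GC fractions in `[0, 1]`.
#' @examples
#' gc_content("ACGT")
#' @export
gc_content <- function(x) {
  stringr::str_count(x, "[GCgc]") / nchar(x)
}

#' Round half away from zero
#'
#' Base [round()] rounds half to even; printed percentages in this package
#' use conventional half-up rounding (e.g. `21/32` as a percentage is
#' `65.63`, not `65.62`).
#'
#' @param x Numeric vector (non-negative in all package uses).
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# percent, rounded half-up to 2 decimals, as printed in reports
percent2 <- function(num, denom) {
  if (denom == 0) return(NA_real_)
  round_half_up(100 * num / denom, 2)
}

# encode an upper-case DNA string as integers 1..4, NA for anything else
encode_dna <- function(seq) {
  match(strsplit(toupper(seq), NULL)[[1]], DNA_BASES)
}

assert_dna <- function(x, len = NULL, arg = deparse(substitute(x))) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be a single DNA string", arg), call. = FALSE)
  }
  if (!grepl("^[ACGTacgt]+$", x)) {
    stop(sprintf("`%s` must contain only A/C/G/T", arg), call. = FALSE)
  }
  if (!is.null(len) && nchar(x) != len) {
    stop(sprintf("`%s` must be %d nt long (got %d)", arg, len, nchar(x)),
         call. = FALSE)
  }
  invisible(toupper(x))
}

validate_iupac <- function(pattern) {
  chars <- strsplit(toupper(pattern), NULL)[[1]]
  bad <- setdiff(chars, names(IUPAC_CODES))
  if (length(bad) > 0) {
    stop("invalid IUPAC code(s) in PAM pattern: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  chars
}

# stable site identifier used across all tables
site_id_of <- function(chrom, start, end, strand) {
  sprintf("%s:%d-%d:%s", chrom, start, end, strand)
}

# count of occurrences of each query string among genome windows of the same
# width, both strands (forward windows + their reverse complements). Window
# width must be odd so no window can equal its own reverse complement.
count_genome_occurrences <- function(genome, queries, width) {
  stopifnot(width %% 2 == 1)
  counts <- setNames(integer(length(queries)), queries)
  rc_queries <- revcomp(queries)
  for (seq in genome) {
    s <- toupper(seq)
    L <- nchar(s)
    if (L < width) next
    wins <- substring(s, 1:(L - width + 1), width:L)
    tab <- table(wins)
    fwd <- tab[queries]
    rev <- tab[rc_queries]
    fwd[is.na(fwd)] <- 0L
    rev[is.na(rev)] <- 0L
    counts <- counts + as.integer(fwd) + as.integer(rev)
  }
  counts
}
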