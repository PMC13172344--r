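#' Enumerate potential off-target sites for a target sequence
#'
#' Finds every genomic window, on both strands, whose Hamming distance to
#' `target23` (mismatches counted across all positions, PAM included) is at
#' most `max_mismatches`. The on-target locus itself is returned as a
#' 0-mismatch site; windows containing `N` are excluded. The scan is a
#' direct vectorised Hamming comparison at every window, so the result is
#' exhaustive and exact.
#'
#' @param genome A [genome_index()].
#' @param target23 Target sequence (protospacer + PAM, conventionally 23 nt)
#'   over `A`/`C`/`G`/`T`.
#' @param max_mismatches Maximum Hamming distance (default 9).
#' @param expected_length Guard on `nchar(target23)` (default 23; set `NULL`
#'   for non-standard protospacer/PAM geometries).
#' @return Tibble with columns `site_id`, `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, `site23` (targeted-strand orientation),
#'   `mismatch_count`, `mismatch_positions` (comma-joined 1-based positions),
#'   `pam_class` (`"NGG"` iff the last two bases are `GG`).
#' @examples
#' g <- genome_index(c(chr = "TTTTACGTACGTACGTACGTACGTAGGTTTT"))
#' enumerate_offtargets(g, "ACGTACGTACGTACGTACGTAGG", max_mismatches = 2)
#' @export
enumerate_offtargets <- function(genome, target23, max_mismatches = 9L,
                                 expected_length = 23L) {
  target23 <- assert_dna(target23, len = expected_length)
  tl <- nchar(target23)
  if (max_mismatches >= tl) {
    warning("max_mismatches >= target length: every window matches",
            call. = FALSE)
  }
  tvec <- encode_dna(target23)
  out <- list()
  for (chrom in names(genome)) {
    s <- toupper(genome[[chrom]])
    L <- nchar(s)
    if (L < tl) next
    for (strand in c("+", "-")) {
      scanned <- if (strand == "+") s else revcomp(s)
      hit <- hamming_hits(scanned, tvec, max_mismatches)
      if (length(hit$pos) == 0) next
      j <- hit$pos
      site23 <- substring(scanned, j, j + tl - 1L)
      start <- if (strand == "+") j - 1L else L - j - tl + 1L
      mmpos <- mismatch_positions(site23, target23)
      out[[length(out) + 1L]] <- tibble(
        chrom = chrom, start = start, end = start + tl, strand = strand,
        site23 = site23,
        mismatch_count = hit$mm,
        mismatch_positions = mmpos,
        pam_class = ifelse(substr(site23, tl - 1L, tl) == "GG",
                           "NGG", "non-NGG")
      )
    }
  }
  if (length(out) == 0) {
    res <- tibble(
      chrom = character(), start = integer(), end = integer(),
      strand = character(), site23 = character(), mismatch_count = integer(),
      mismatch_positions = character(), pam_class = character()
    )
  } else {
    res <- bind_rows(out) %>% arrange(.data$chrom, .data$start, .data$strand)
  }
  res %>%
    mutate(site_id = site_id_of(.data$chrom, .data$start, .data$end,
                                .data$strand),
           .before = 1)
}

# vectorised Hamming scan of one oriented sequence: returns 1-based window
# starts and mismatch counts for windows within max_mm of the encoded target
hamming_hits <- function(seq_up, tvec, max_mm) {
  tl <- length(tvec)
  enc <- encode_dna(seq_up)
  L <- length(enc)
  nw <- L - tl + 1L
  if (nw < 1L) return(list(pos = integer(0), mm = integer(0)))
  mm <- integer(nw)
  hasN <- logical(nw)
  for (k in seq_len(tl)) {
    v <- enc[k:(nw + k - 1L)]
    bad <- is.na(v)
    mm <- mm + ifelse(bad, 1L, as.integer(v != tvec[k]))
    hasN <- hasN | bad
  }
  keep <- !hasN & mm <= max_mm
  list(pos = which(keep), mm = mm[keep])
}

# comma-joined 1-based mismatch positions for each site sequence
mismatch_positions <- function(site_seqs, target) {
  tchars <- strsplit(target, NULL)[[1]]
  vapply(strsplit(site_seqs, NULL), function(sc) {
    paste(which(sc != tchars), collapse = ",")
  }, character(1))
}

parse_mismatch_positions <- function(x) {
  lapply(strsplit(x, ","), function(p) as.integer(p[nzchar(p)]))
}

#' Group sequence-identical sites into off-target types
#'
#' All sites sharing an identical observed sequence form one off-target
#' "type": within a type the sequence is constant and only genomic location
#' (hence chromatin context) varies. Type ids are assigned by lexicographic
#' order of the shared sequence, so they are deterministic for a given site
#' set.
#'
#' @param sites Site tibble from [enumerate_offtargets()].
#' @return `sites` with a `type_id` column added.
#' @seealso [offtarget_types()] for the per-type summary table.
#' @export
assign_types <- function(sites) {
  seqs <- sort(unique(sites$site23))
  ids <- setNames(sprintf("type_%04d", seq_along(seqs)), seqs)
  sites %>% mutate(type_id = unname(ids[.data$site23]))
}

#' Per-type summary of off-target sites
#'
#' @param sites Site tibble with `type_id` (see [assign_types()]); if a
#'   `callable` column is present, per-type callable counts are included.
#' @return Tibble with `type_id`, `sequence`, `n_sites` (and `n_callable`).
#' @export
offtarget_types <- function(sites) {
  stopifnot("type_id" %in% names(sites))
  out <- sites %>%
    group_by(.data$type_id) %>%
    summarise(sequence = .data$site23[1], n_sites = dplyr::n(),
              .groups = "drop")
  if ("callable" %in% names(sites)) {
    ncall <- sites %>%
      group_by(.data$type_id) %>%
      summarise(n_callable = sum(.data$callable), .groups = "drop")
    out <- left_join(out, ncall, by = "type_id")
  }
  arrange(out, .data$type_id)
}

#' Flag sites whose sequence context is unique (callable)
#'
#' A site is callable when its sequence plus `flank` bp of genomic context
#' on each side occurs exactly once in the genome (both strands searched) --
#' a proxy for short-read mappability, so that variants at the site can be
#' confidently assigned to that locus. Sites too close to a contig edge for
#' full flanks are not callable.
#'
#' @param sites Site tibble from [enumerate_offtargets()].
#' @param genome The [genome_index()] the sites came from.
#' @param flank Flank width in bp (default 27, i.e. a 77-bp context for a
#'   23-bp site).
#' @return `sites` with a logical `callable` column added. Invariant to
#'   genome record order.
#' @export
flag_callable <- function(sites, genome, flank = 27L) {
  stopifnot(flank >= 0)
  if (nrow(sites) == 0) return(sites %>% mutate(callable = logical()))
  widths <- unique(sites$end - sites$start)
  stopifnot(length(widths) == 1)
  w <- widths + 2L * flank
  lens <- genome_lengths(genome)
  cs <- sites$start - flank
  ce <- sites$end + flank
  in_bounds <- cs >= 0 & ce <= lens[sites$chrom]
  context <- rep(NA_character_, nrow(sites))
  idx <- which(in_bounds)
  if (length(idx) > 0) {
    context[idx] <- toupper(substring(genome[sites$chrom[idx]],
                                      cs[idx] + 1L, ce[idx]))
  }
  callable <- rep(FALSE, nrow(sites))
  if (length(idx) > 0) {
    occ <- count_genome_occurrences(genome, unique(context[idx]), w)
    callable[idx] <- occ[context[idx]] == 1L
  }
  sites %>% mutate(callable = callable)
}
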