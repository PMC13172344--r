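#' Configuration for the protospacer scan
#'
#' Bundles every tunable of the candidate-protospacer screen. Defaults follow
#' the published screen: `NGG` PAM, 20-nt protospacer, GC in `[0.40, 0.80)`,
#' at most 14 perfect copies of the 23-mer per chromosome, an editing window
#' at protospacer positions 4-8 that must contain both an A and a C, and a
#' pool of more than 5000 potential off-target sites.
#'
#' @param pam_pattern IUPAC PAM pattern 3' of the protospacer (default
#'   `"NGG"`).
#' @param protospacer_length Protospacer length in bp (default 20).
#' @param gc_min,gc_max GC-fraction bounds on the protospacer; a candidate
#'   passes when `gc_min <= GC < gc_max`.
#' @param max_perfect_copies_per_chrom Reject candidates whose full
#'   protospacer+PAM sequence has more than this many perfect copies (both
#'   strands, the candidate itself included) on any single chromosome.
#' @param exclusion_intervals Optional tibble/data frame with columns
#'   `chrom`, `start`, `end` (0-based half-open) of intervals, e.g. lethal or
#'   cell-cycle genes, that protospacers must not overlap. `NULL` disables
#'   the filter.
#' @param edit_window_start 1-based start of the editing window within the
#'   protospacer.
#' @param edit_window_width Editing-window width in bp.
#' @param min_offtarget_pool Candidates must have strictly more than this
#'   many potential off-target sites.
#' @param top_n Number of top-ranked candidates to keep.
#' @param max_mismatches Maximum Hamming distance (over the full
#'   protospacer+PAM) for a locus to count as a potential off-target site.
#' @param flank Flank width in bp on each side of a site used for the
#'   callability (context-uniqueness) check.
#' @return A list of class `scan_config`.
#' @export
scan_config <- function(pam_pattern = "NGG",
                        protospacer_length = 20L,
                        gc_min = 0.40, gc_max = 0.80,
                        max_perfect_copies_per_chrom = 14L,
                        exclusion_intervals = NULL,
                        edit_window_start = 4L,
                        edit_window_width = 5L,
                        min_offtarget_pool = 5000L,
                        top_n = 3000L,
                        max_mismatches = 9L,
                        flank = 27L) {
  validate_iupac(pam_pattern)
  stopifnot(
    protospacer_length >= 1,
    gc_min >= 0, gc_min < gc_max, gc_max <= 1,
    max_perfect_copies_per_chrom >= 1,
    edit_window_start >= 1,
    edit_window_width >= 1,
    edit_window_start + edit_window_width - 1 <= protospacer_length,
    min_offtarget_pool >= 0,
    top_n >= 1,
    max_mismatches >= 0,
    flank >= 0
  )
  if (!is.null(exclusion_intervals)) {
    stopifnot(all(c("chrom", "start", "end") %in% names(exclusion_intervals)))
  }
  structure(
    list(
      pam_pattern = toupper(pam_pattern),
      protospacer_length = as.integer(protospacer_length),
      gc_min = gc_min, gc_max = gc_max,
      max_perfect_copies_per_chrom = as.integer(max_perfect_copies_per_chrom),
      exclusion_intervals = exclusion_intervals,
      edit_window_start = as.integer(edit_window_start),
      edit_window_width = as.integer(edit_window_width),
      min_offtarget_pool = as.integer(min_offtarget_pool),
      top_n = as.integer(top_n),
      max_mismatches = as.integer(max_mismatches),
      flank = as.integer(flank)
    ),
    class = "scan_config"
  )
}

target_length <- function(config) {
  config$protospacer_length + nchar(config$pam_pattern)
}

# scan one strand of one chromosome; seq_up is the upper-case sequence being
# scanned 5'->3' (the chromosome itself or its reverse complement)
scan_strand <- function(seq_up, config) {
  plen <- config$protospacer_length
  pam <- validate_iupac(config$pam_pattern)
  tl <- plen + length(pam)
  L <- nchar(seq_up)
  if (L < tl) return(integer(0))
  chars <- strsplit(seq_up, NULL)[[1]]
  nw <- L - tl + 1L
  # windows containing anything outside A/C/G/T are uncallable -> discarded
  bad <- !(chars %in% DNA_BASES)
  cb <- c(0L, cumsum(bad))
  clean <- (cb[(1:nw) + tl] - cb[1:nw]) == 0L
  ok <- clean
  for (k in seq_along(pam)) {
    allowed <- IUPAC_CODES[[pam[k]]]
    ok <- ok & (chars[(plen + k - 1L) + (1:nw)] %in% allowed)
  }
  which(ok)
}

#' Scan a genome for PAM-adjacent protospacer candidates
#'
#' Finds every position, on both strands, where a full-length protospacer
#' lies immediately 5' of a PAM-matching motif. Reverse-strand hits are
#' reported in genomic coordinates with strand `"-"` and sequences in
#' targeted-strand (protospacer 5'->3') orientation. Windows containing `N`
#' are discarded. This is step 1 of the eight-step screen; [apply_filters()]
#' applies steps 2-8.
#'
#' @param genome A [genome_index()].
#' @param config A [scan_config()].
#' @return Tibble of pre-filter candidates with columns `chrom`, `start`,
#'   `end` (0-based half-open, spanning protospacer+PAM), `strand`,
#'   `protospacer`, `pam`, `target23`, `gc`. Coordinates always refer to the
#'   forward genomic strand.
#' @examples
#' g <- genome_index(c(chr = "CCCACGTACGTACGTACGTACGTAGGCCC"))
#' scan_pam_sites(g, scan_config())
#' @export
scan_pam_sites <- function(genome, config = scan_config()) {
  if (length(genome) == 0) stop("empty genome", call. = FALSE)
  tl <- target_length(config)
  plen <- config$protospacer_length
  out <- list()
  for (chrom in names(genome)) {
    s <- toupper(genome[[chrom]])
    L <- nchar(s)
    if (L < tl) {
      message("skipping ", chrom, ": shorter than ", tl, " bp")
      next
    }
    # forward strand
    i <- scan_strand(s, config)
    if (length(i) > 0) {
      t23 <- substring(s, i, i + tl - 1L)
      out[[length(out) + 1L]] <- tibble(
        chrom = chrom, start = i - 1L, end = i + tl - 1L, strand = "+",
        protospacer = substr(t23, 1L, plen),
        pam = substr(t23, plen + 1L, tl),
        target23 = t23
      )
    }
    # reverse strand: scan the reverse complement, map back to genomic coords
    rc <- revcomp(s)
    j <- scan_strand(rc, config)
    if (length(j) > 0) {
      t23 <- substring(rc, j, j + tl - 1L)
      out[[length(out) + 1L]] <- tibble(
        chrom = chrom, start = L - j - tl + 1L, end = L - j + 1L, strand = "-",
        protospacer = substr(t23, 1L, plen),
        pam = substr(t23, plen + 1L, tl),
        target23 = t23
      )
    }
  }
  if (length(out) == 0) {
    return(tibble(
      chrom = character(), start = integer(), end = integer(),
      strand = character(), protospacer = character(), pam = character(),
      target23 = character(), gc = numeric()
    ))
  }
  bind_rows(out) %>%
    mutate(gc = gc_content(.data$protospacer)) %>%
    arrange(.data$chrom, .data$start, .data$strand)
}

# per-chromosome perfect-copy counts (both strands) for a set of 23-mers
perfect_copy_max <- function(genome, queries, width) {
  mx <- setNames(integer(length(queries)), queries)
  rc_q <- revcomp(queries)
  for (seq in genome) {
    s <- toupper(seq)
    L <- nchar(s)
    if (L < width) next
    tab <- table(substring(s, 1:(L - width + 1), width:L))
    fwd <- tab[queries]; rev <- tab[rc_q]
    fwd[is.na(fwd)] <- 0L; rev[is.na(rev)] <- 0L
    mx <- pmax(mx, as.integer(fwd) + as.integer(rev))
  }
  mx
}

# does the protospacer contain a simple repeat: a run of 4 identical bases,
# or 3 consecutive tandem copies of any 2-mer or 3-mer unit
has_simple_repeat <- function(proto) {
  grepl("([ACGT])\\1{3}", proto) |
    grepl("([ACGT]{2})\\1{2}", proto) |
    grepl("([ACGT]{3})\\1{2}", proto)
}

# genomic interval of the protospacer 20-mer within the 23-mer window
protospacer_interval <- function(start, end, strand, plen, pam_len) {
  p_start <- ifelse(strand == "+", start, start + pam_len)
  list(start = p_start, end = p_start + plen)
}

#' Apply the eight-step candidate filters
#'
#' Applies steps 2-8 of the candidate-protospacer screen to scanned
#' candidates (step 1 is the PAM scan itself):
#' \enumerate{
#'   \item PAM match (done by [scan_pam_sites()]);
#'   \item `gc_min <= GC < gc_max` on the protospacer;
#'   \item reject candidates whose whole protospacer+PAM is soft-masked
#'     (every base lowercase in the source FASTA);
#'   \item reject candidates with more than `max_perfect_copies_per_chrom`
#'     perfect copies of the protospacer+PAM on any one chromosome (both
#'     strands; the candidate is one of its own copies);
#'   \item reject candidates whose protospacer overlaps an exclusion
#'     interval (e.g. lethal / cell-cycle genes);
#'   \item reject simple repeats: any run of 4 identical bases, or 3
#'     consecutive tandem copies of a 2-mer or 3-mer unit, in the
#'     protospacer;
#'   \item require at least one `A` and at least one `C` inside the editing
#'     window;
#'   \item require strictly more than `min_offtarget_pool` potential
#'     off-target sites.
#' }
#' Each rejected candidate records the first failing step in `filter_trace`;
#' survivors record `"pass"`. The result set is independent of candidate
#' order.
#'
#' @param candidates Tibble from [scan_pam_sites()].
#' @param genome The [genome_index()] the candidates came from (case
#'   preserved; needed for the soft-mask and copy-count checks).
#' @param config A [scan_config()].
#' @param pools Named integer vector mapping each candidate's `target23`
#'   sequence to its potential off-target pool size (from
#'   [enumerate_offtargets()]), or a tibble with columns `target23`,
#'   `pool_size`. Required unless `steps` excludes step 8.
#' @param steps Integer vector of steps to apply (default `2:8`); mainly for
#'   testing individual filters.
#' @param keep_rejected If `TRUE`, return all candidates with logical `pass`
#'   and `filter_trace` columns instead of survivors only.
#' @return Tibble of surviving candidates (columns of `candidates` plus
#'   `pool_size` and `filter_trace`), with an attribute `filter_summary`: a
#'   tibble of per-step rejection counts.
#' @export
apply_filters <- function(candidates, genome, config = scan_config(),
                          pools = NULL, steps = 2:8,
                          keep_rejected = FALSE) {
  if (nrow(candidates) == 0) {
    out <- candidates %>% mutate(pool_size = integer(), filter_trace = character())
    attr(out, "filter_summary") <- tibble(step = character(), n_rejected = integer())
    return(out)
  }
  plen <- config$protospacer_length
  pam_len <- nchar(config$pam_pattern)
  tl <- plen + pam_len
  step_labels <- c(
    `2` = "gc_content", `3` = "soft_masked", `4` = "perfect_copies",
    `5` = "gene_exclusion", `6` = "simple_repeat", `7` = "edit_window",
    `8` = "pool_size"
  )
  fail <- rep(NA_character_, nrow(candidates))
  mark <- function(bad, label) fail <<- ifelse(is.na(fail) & bad, label, fail)

  if (2 %in% steps) {
    mark(!(candidates$gc >= config$gc_min & candidates$gc < config$gc_max),
         "gc_content")
  }
  if (3 %in% steps) {
    raw <- substring(genome[candidates$chrom], candidates$start + 1L,
                     candidates$end)
    mark(grepl("^[acgtn]+$", raw), "soft_masked")
  }
  if (4 %in% steps) {
    uniq <- unique(candidates$target23)
    mx <- perfect_copy_max(genome, uniq, tl)
    mark(as.integer(mx[candidates$target23]) >
           config$max_perfect_copies_per_chrom, "perfect_copies")
  }
  if (5 %in% steps && !is.null(config$exclusion_intervals)) {
    excl <- config$exclusion_intervals
    pint <- protospacer_interval(candidates$start, candidates$end,
                                 candidates$strand, plen, pam_len)
    cand_gr <- GenomicRanges::GRanges(
      candidates$chrom, IRanges::IRanges(pint$start + 1L, pint$end))
    excl_gr <- GenomicRanges::GRanges(
      excl$chrom, IRanges::IRanges(excl$start + 1L, excl$end))
    hits <- GenomicRanges::countOverlaps(cand_gr, excl_gr)
    mark(hits > 0, "gene_exclusion")
  }
  if (6 %in% steps) {
    mark(has_simple_repeat(candidates$protospacer), "simple_repeat")
  }
  if (7 %in% steps) {
    win <- substr(candidates$protospacer, config$edit_window_start,
                  config$edit_window_start + config$edit_window_width - 1L)
    mark(!(grepl("A", win) & grepl("C", win)), "edit_window")
  }
  pool_size <- rep(NA_integer_, nrow(candidates))
  if (8 %in% steps) {
    if (is.null(pools)) {
      stop("`pools` is required for the off-target pool-size filter (step 8)",
           call. = FALSE)
    }
    if (is.data.frame(pools)) {
      pools <- setNames(as.integer(pools$pool_size), pools$target23)
    }
    missing <- setdiff(unique(candidates$target23[is.na(fail)]), names(pools))
    if (length(missing) > 0) {
      stop("no off-target pool supplied for candidate sequence(s): ",
           paste(head(missing, 3), collapse = ", "),
           if (length(missing) > 3) " ...", call. = FALSE)
    }
    pool_size <- as.integer(pools[candidates$target23])
    mark(!is.na(pool_size) & pool_size <= config$min_offtarget_pool,
         "pool_size")
  }

  res <- candidates %>%
    mutate(pool_size = pool_size,
           pass = is.na(fail),
           filter_trace = ifelse(is.na(fail), "pass", fail))
  summary <- res %>%
    filter(!.data$pass) %>%
    count(step = .data$filter_trace, name = "n_rejected") %>%
    arrange(match(.data$step, step_labels))
  out <- if (keep_rejected) res else res %>% filter(.data$pass) %>% select(-"pass")
  attr(out, "filter_summary") <- summary
  out
}

#' Rank surviving candidates by callable off-target pool
#'
#' Sorts survivors by descending `callable_pool_size`, breaking ties
#' deterministically by `(chrom, start, strand)`, and keeps the first
#' `top_n`.
#'
#' @param survivors Tibble with a `callable_pool_size` column.
#' @param top_n Number of candidates to keep (fewer survivors returns all).
#' @return Ranked tibble with a `rank` column.
#' @export
rank_candidates <- function(survivors, top_n = 3000L) {
  stopifnot("callable_pool_size" %in% names(survivors), top_n >= 1)
  survivors %>%
    arrange(desc(.data$callable_pool_size), .data$chrom, .data$start,
            .data$strand) %>%
    slice_head(n = as.integer(top_n)) %>%
    mutate(rank = row_number())
}

#' Full candidate-protospacer screen
#'
#' Convenience pipeline for small genomes: scans PAM sites, applies the cheap
#' filters (steps 2-7), enumerates off-target pools for the remaining
#' candidates, applies the pool-size filter (step 8), flags callable sites,
#' and ranks by callable pool size. Intended for toy/simulated genomes; each
#' surviving candidate costs one genome-wide enumeration.
#'
#' @inheritParams apply_filters
#' @return Ranked survivor tibble (see [rank_candidates()]) with
#'   `pool_size` and `callable_pool_size` columns; per-step rejection counts
#'   in the `filter_summary` attribute.
#' @export
scan_protospacers <- function(genome, config = scan_config()) {
  cands <- scan_pam_sites(genome, config)
  pre <- apply_filters(cands, genome, config, steps = 2:7)
  if (nrow(pre) == 0) {
    out <- pre %>% mutate(callable_pool_size = integer(), rank = integer())
    attr(out, "filter_summary") <- attr(pre, "filter_summary")
    return(out)
  }
  uniq <- unique(pre$target23)
  pool_size <- integer(length(uniq))
  callable_size <- integer(length(uniq))
  for (k in seq_along(uniq)) {
    sites <- enumerate_offtargets(genome, uniq[k],
                                  max_mismatches = config$max_mismatches,
                                  expected_length = target_length(config))
    sites <- flag_callable(sites, genome, flank = config$flank)
    pool_size[k] <- nrow(sites)
    callable_size[k] <- sum(sites$callable)
  }
  names(pool_size) <- uniq
  names(callable_size) <- uniq
  post <- apply_filters(pre %>% select(-"pool_size", -"filter_trace"),
                        genome, config, pools = pool_size, steps = 8)
  post <- post %>%
    mutate(callable_pool_size = as.integer(callable_size[.data$target23]))
  out <- rank_candidates(post, config$top_n)
  attr(out, "filter_summary") <- bind_rows(attr(pre, "filter_summary"),
                                           attr(post, "filter_summary"))
  out
}
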