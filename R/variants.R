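#' Load and re-filter somatic variant calls
#'
#' Reads a (tumor-normal style) VCF and applies the defensive filters used
#' after somatic calling: keep `FILTER == PASS` records, split multi-allelic
#' records per ALT, re-enforce a minimum tumor allele fraction, and drop
#' clustered records when any `region_window`-bp window holds more than
#' `max_events_in_region` of them. Variant calling itself happens upstream
#' (the package consumes called VCFs); these thresholds mirror the
#' FilterMutectCalls settings `--min-allele-fraction 0.01
#' --max-events-in-region 5`.
#'
#' @param path Path to an uncompressed VCF (v4.x) with a FILTER column.
#' @param min_allele_fraction Minimum tumor-sample allele fraction.
#' @param max_events_in_region Maximum records tolerated in any
#'   `region_window`-bp window; windows exceeding it have all their records
#'   dropped.
#' @param region_window Window width in bp for the clustered-events rule.
#' @param tumor_sample Name of the tumor genotype column; default is the
#'   last sample in the VCF.
#' @return Tibble with columns `chrom`, `pos` (1-based), `ref`, `alt`,
#'   `allele_fraction`, `sample_id`.
#' @export
load_filtered_variants <- function(path,
                                   min_allele_fraction = 0.01,
                                   max_events_in_region = 5L,
                                   region_window = 50L,
                                   tumor_sample = NULL) {
  v <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("malformed VCF '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(tibble(chrom = character(), pos = integer(), ref = character(),
                  alt = character(), allele_fraction = numeric(),
                  sample_id = character()))
  }
  samples <- colnames(v@gt)[-1]
  if (is.null(tumor_sample)) tumor_sample <- samples[length(samples)]
  if (!tumor_sample %in% samples) {
    stop("tumor sample '", tumor_sample, "' not in VCF", call. = FALSE)
  }
  af_chr <- vcfR::extract.gt(v, element = "AF")[, tumor_sample]

  rec <- tibble(
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    filter = fix$FILTER, af = unname(af_chr)
  ) %>%
    filter(.data$filter == "PASS")
  # split multi-allelic records per ALT (AF is per-allele, comma-joined)
  rec <- rec %>%
    mutate(alt = strsplit(.data$alt, ","),
           af = strsplit(ifelse(is.na(.data$af), "", .data$af), ",")) %>%
    mutate(af = purrr::map2(.data$af, .data$alt,
                            ~ rep_len(as.numeric(.x), length(.y)))) %>%
    tidyr::unnest(c("alt", "af"))
  rec <- rec %>% filter(!is.na(.data$af), .data$af >= min_allele_fraction)

  # clustered-events rule: anchor a window at each record; if the window
  # holds more than the allowed number of records, drop them all
  rec <- rec %>% arrange(.data$chrom, .data$pos)
  drop <- logical(nrow(rec))
  for (ch in unique(rec$chrom)) {
    idx <- which(rec$chrom == ch)
    pos <- rec$pos[idx]
    hi <- findInterval(pos + region_window - 1L, pos)
    for (i in seq_along(pos)) {
      if (hi[i] - i + 1L > max_events_in_region) drop[idx[i:hi[i]]] <- TRUE
    }
  }
  rec %>%
    filter(!drop) %>%
    transmute(chrom = .data$chrom, pos = .data$pos, ref = .data$ref,
              alt = .data$alt, allele_fraction = .data$af,
              sample_id = tumor_sample)
}

#' Classify variants as SNV or InDel and decompose base changes
#'
#' Length-preserving substitutions are classified `SNV` and decomposed into
#' per-position base changes; this covers single-base substitutions and the
#' run substitutions (e.g. `AA>GG`, `CCC>TTT` and their reverse complements)
#' that variant callers sometimes emit as multi-base records even though
#' they are single-nucleotide mutations at each position. Length-changing
#' variants are `InDel`.
#'
#' @param ref,alt Character vectors of reference and alternate alleles
#'   (`A`/`C`/`G`/`T` only).
#' @return Tibble with one row per variant: `ref`, `alt`, `variant_class`,
#'   and a `changes` list-column of tibbles (`offset` 0-based within REF,
#'   `from`, `to`) for SNVs (empty for InDels).
#' @examples
#' classify_variant(c("A", "AA", "A"), c("G", "GG", "AG"))
#' @export
classify_variant <- function(ref, alt) {
  stopifnot(length(ref) == length(alt))
  if (any(!grepl("^[ACGTacgt]+$", c(ref, alt)))) {
    stop("alleles must be non-empty A/C/G/T strings", call. = FALSE)
  }
  ref <- toupper(ref); alt <- toupper(alt)
  cls <- ifelse(nchar(ref) == nchar(alt), "SNV", "InDel")
  changes <- purrr::pmap(list(ref, alt, cls), function(r, a, cl) {
    if (cl != "SNV") {
      return(tibble(offset = integer(), from = character(), to = character()))
    }
    rc <- strsplit(r, NULL)[[1]]
    ac <- strsplit(a, NULL)[[1]]
    d <- which(rc != ac)
    tibble(offset = d - 1L, from = rc[d], to = ac[d])
  })
  tibble(ref = ref, alt = alt, variant_class = cls, changes = changes)
}

#' Assign variants to off-target sites and split on/off-target
#'
#' A variant is assigned to every site whose window contains its reference
#' position (by default the site's own bases; optionally the full 50-bp
#' context window). Sites with zero mismatches and an NGG PAM are the
#' on-target loci: their edits are labelled `on_target = TRUE` and excluded
#' from off-target tallies downstream.
#'
#' @param variants Tibble from [load_filtered_variants()] (or with columns
#'   `chrom`, `pos`, `ref`, `alt`, `allele_fraction`, `sample_id`).
#' @param sites Site tibble from [enumerate_offtargets()] (+
#'   [assign_types()] if type ids are wanted on the calls).
#' @param extend_window If `TRUE`, assign within the 50-bp context window
#'   (`upstream`/`downstream` around the site) instead of the site itself.
#' @param upstream,downstream Context extension in bp when
#'   `extend_window = TRUE`.
#' @return Edit-call tibble: one row per (variant, site, base change) for
#'   SNVs and one per (variant, site) for InDels, with columns `site_id`,
#'   `type_id` (if present), `chrom`, `pos`, `variant_class`, `from_base`,
#'   `to_base` (reference-strand bases; `NA` for InDels),
#'   `allele_fraction`, `sample_id`, `on_target`. Variants on chromosomes
#'   with no sites are ignored.
#' @export
assign_edits_to_sites <- function(variants, sites, extend_window = FALSE,
                                  upstream = 15L, downstream = 12L) {
  empty <- tibble(
    site_id = character(), type_id = character(), chrom = character(),
    pos = integer(), variant_class = character(), from_base = character(),
    to_base = character(), allele_fraction = numeric(),
    sample_id = character(), on_target = logical()
  )
  if (!"type_id" %in% names(sites)) empty$type_id <- NULL
  if (nrow(variants) == 0 || nrow(sites) == 0) return(empty)

  ws <- sites$start
  we <- sites$end
  if (extend_window) {
    win <- make_window(sites, upstream = upstream, downstream = downstream)
    ws <- win$win_start
    we <- win$win_end
  }
  site_gr <- GenomicRanges::GRanges(sites$chrom, IRanges::IRanges(ws + 1L, we))
  var_gr <- GenomicRanges::GRanges(variants$chrom,
                                   IRanges::IRanges(variants$pos, variants$pos))
  ov <- GenomicRanges::findOverlaps(var_gr, site_gr)
  if (length(ov) == 0) return(empty)
  vi <- S4Vectors::queryHits(ov)
  si <- S4Vectors::subjectHits(ov)

  cls <- classify_variant(variants$ref[vi], variants$alt[vi])
  base <- tibble(
    site_id = sites$site_id[si],
    chrom = variants$chrom[vi],
    pos = variants$pos[vi],
    variant_class = cls$variant_class,
    changes = cls$changes,
    allele_fraction = variants$allele_fraction[vi],
    sample_id = variants$sample_id[vi],
    on_target = sites$mismatch_count[si] == 0 & sites$pam_class[si] == "NGG"
  )
  if ("type_id" %in% names(sites)) {
    base <- base %>% mutate(type_id = sites$type_id[si], .after = "site_id")
  }
  snv <- base %>%
    filter(.data$variant_class == "SNV") %>%
    tidyr::unnest("changes") %>%
    mutate(pos = .data$pos + .data$offset, from_base = .data$from,
           to_base = .data$to) %>%
    select(-"offset", -"from", -"to")
  indel <- base %>%
    filter(.data$variant_class == "InDel") %>%
    select(-"changes") %>%
    mutate(from_base = NA_character_, to_base = NA_character_)
  bind_rows(snv, indel) %>% arrange(.data$chrom, .data$pos, .data$site_id)
}

#' Summarise off-target edit calls
#'
#' Computes the per-editor characterisation statistics from edit calls and
#' the site pool: off-target edit and type counts, the 4x4 From->To mutation
#' matrix over SNV base changes (reference-strand bases, zero diagonal),
#' per-PAM-class editing frequency (edited / potential sites, as a percent
#' rounded half-up to 2 decimals), the mismatch-count histogram of edited
#' sites, and the per-position mismatch frequency among edited sites.
#' On-target calls are excluded from every tally.
#'
#' @param edit_calls Tibble from [assign_edits_to_sites()].
#' @param sites The full site pool the calls were assigned against.
#' @return A list of class `edit_summary` with elements `n_offtarget_edits`
#'   (distinct edited site x sample pairs), `n_offtarget_sites`,
#'   `n_offtarget_types`, `mutation_matrix`, `pam_table`,
#'   `mismatch_histogram`, `position_profile`.
#' @export
summarize_edits <- function(edit_calls, sites) {
  off <- edit_calls %>% filter(!.data$on_target)
  off_sites <- sites %>%
    filter(!(.data$mismatch_count == 0 & .data$pam_class == "NGG"))

  mut <- matrix(0L, 4, 4, dimnames = list(From = DNA_BASES, To = DNA_BASES))
  snv <- off %>% filter(.data$variant_class == "SNV")
  if (nrow(snv) > 0) {
    tab <- table(factor(snv$from_base, DNA_BASES),
                 factor(snv$to_base, DNA_BASES))
    mut[] <- as.integer(tab)
  }
  diag(mut) <- 0L

  edited_sites <- distinct(off, .data$site_id)
  edited_info <- off_sites %>% filter(.data$site_id %in% edited_sites$site_id)

  pam_table <- off_sites %>%
    group_by(pam_class = .data$pam_class) %>%
    summarise(n_potential = dplyr::n(),
              n_edited = sum(.data$site_id %in% edited_sites$site_id),
              .groups = "drop") %>%
    mutate(editing_frequency_pct =
             purrr::map2_dbl(.data$n_edited, .data$n_potential, percent2))

  mism_hist <- edited_info %>%
    count(mismatch_count = .data$mismatch_count, name = "n_sites")

  tl <- if (nrow(sites) > 0) nchar(sites$site23[1]) else 23L
  pos_freq <- numeric(tl)
  if (nrow(edited_info) > 0) {
    plist <- parse_mismatch_positions(edited_info$mismatch_positions)
    tabp <- tabulate(unlist(plist), nbins = tl)
    pos_freq <- tabp / nrow(edited_info)
  }

  structure(
    list(
      n_offtarget_edits = nrow(distinct(off, .data$site_id, .data$sample_id)),
      n_offtarget_sites = nrow(edited_sites),
      n_offtarget_types = if ("type_id" %in% names(off)) {
        dplyr::n_distinct(off$type_id)
      } else NA_integer_,
      mutation_matrix = mut,
      pam_table = pam_table,
      mismatch_histogram = mism_hist,
      position_profile = tibble(position = seq_len(tl),
                                mismatch_frequency = pos_freq)
    ),
    class = "edit_summary"
  )
}

#' @export
print.edit_summary <- function(x, ...) {
  cat("<edit_summary>\n")
  cat("  off-target edits (site x sample): ", x$n_offtarget_edits, "\n",
      sep = "")
  cat("  edited off-target sites: ", x$n_offtarget_sites,
      "  types: ", x$n_offtarget_types, "\n", sep = "")
  cat("  PAM classes:\n")
  print(as.data.frame(x$pam_table), row.names = FALSE)
  invisible(x)
}

#' Per-PAM-class editing frequency table
#'
#' Standalone form of the PAM bias computation in [summarize_edits()]:
#' within each PAM class, editing frequency = edited sites / potential
#' sites, reported as a percent rounded half-up to two decimals.
#'
#' @param sites Site tibble with `site_id` and `pam_class` columns
#'   (on-target rows should already be excluded or absent).
#' @param edited_site_ids Character vector of edited `site_id`s.
#' @return Tibble with `pam_class`, `n_potential`, `n_edited`,
#'   `editing_frequency_pct`.
#' @export
pam_frequency_table <- function(sites, edited_site_ids) {
  sites %>%
    group_by(pam_class = .data$pam_class) %>%
    summarise(n_potential = dplyr::n(),
              n_edited = sum(.data$site_id %in% edited_site_ids),
              .groups = "drop") %>%
    mutate(editing_frequency_pct =
             purrr::map2_dbl(.data$n_edited, .data$n_potential, percent2))
}

#' Pairwise overlap of edited off-target site sets
#'
#' Venn-style comparison of edited-site sets across editors: intersection,
#' union, Jaccard index, and the percentage of each editor's edited sites
#' unique to it relative to the other.
#'
#' @param edit_sets Named list of edit-call tibbles (one per editor; from
#'   [assign_edits_to_sites()]) or of character vectors of edited site ids.
#' @return Tibble with one row per unordered editor pair.
#' @export
edited_set_overlap <- function(edit_sets) {
  stopifnot(length(edit_sets) >= 2, !is.null(names(edit_sets)))
  ids <- lapply(edit_sets, function(x) {
    if (is.data.frame(x)) {
      unique(x$site_id[!x$on_target])
    } else unique(as.character(x))
  })
  pairs <- combn(names(ids), 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(p) {
    a <- ids[[p[1]]]; b <- ids[[p[2]]]
    inter <- length(intersect(a, b))
    tibble(
      editor_a = p[1], editor_b = p[2],
      n_a = length(a), n_b = length(b),
      n_intersect = inter, n_union = length(union(a, b)),
      jaccard = if (length(union(a, b)) > 0) inter / length(union(a, b)) else NA_real_,
      pct_unique_a = percent2(length(a) - inter, length(a)),
      pct_unique_b = percent2(length(b) - inter, length(b))
    )
  })
}
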