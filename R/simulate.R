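#' Configuration for the synthetic off-target study generator
#'
#' Defines a toy study: a random genome with planted repeat families (one
#' target sequence per family, copies at chosen mismatch distances on random
#' strands with unique random flanks), chromatin feature tracks whose
#' per-site values follow a per-feature baseline + effect model, and edits
#' realised per replicate from a logistic model on mismatch burden and
#' chromatin scores. Everything is deterministic under `seed`.
#'
#' @param seed Integer seed (mandatory).
#' @param genome_length Genome length in bp (single chromosome `"chr1"`).
#' @param family_sizes Integer vector: total planted sites per repeat
#'   family. Each family is one target sequence whose planted sites are
#'   grouped into `types_per_family` distinct variant sequences ("types");
#'   copies of the same type are sequence-identical but placed at different
#'   loci, mirroring the endogenous repeat structure the analysis exploits.
#' @param types_per_family Number of distinct variant sequences per family
#'   (recycled across families; default 6). Ignored for a family when
#'   `type_copies` is supplied.
#' @param mismatch_spectrum Optional list (one element per family) of
#'   integer vectors, one mismatch count per type; `NULL` makes the first
#'   type the 0-mismatch target itself and draws the rest uniformly from
#'   `mismatch_range`.
#' @param type_copies Optional list (one element per family) of integer
#'   vectors giving the number of planted copies of each type; `NULL`
#'   splits `family_sizes` as evenly as possible.
#' @param mismatch_range Range mismatch counts are drawn from when
#'   `mismatch_spectrum` is `NULL` (default `1:4`).
#' @param flank_uniqueness Verify planted flanks are globally unique and
#'   re-place colliding sites (default `TRUE`).
#' @param track_effects Named list per chromatin feature: `list(baseline=,
#'   sd=)` for the per-site value model `baseline + sd * z`, `z ~ N(0,1)`.
#'   Defaults cover all 13 features with modest baselines.
#' @param edit_model List with `intercept`, `mismatch` (additive log-odds
#'   per mismatch), and `features`: named numeric of per-feature log-odds
#'   per standard deviation (features are standardised across sites before
#'   entering the model).
#' @param editor_mode Substitution signature of simulated edits: `"CBE"`
#'   (C->T on the targeted strand), `"ABE"` (A->G), or `"unbiased"`.
#' @param n_replicates Number of replicate samples / VCFs (default 3).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed,
                       genome_length = 100000L,
                       family_sizes = c(60L, 60L),
                       types_per_family = 6L,
                       mismatch_spectrum = NULL,
                       type_copies = NULL,
                       mismatch_range = 1:4,
                       flank_uniqueness = TRUE,
                       track_effects = default_track_effects(),
                       edit_model = list(intercept = -1.5, mismatch = -0.6,
                                         features = c(DNase = 1.2,
                                                      ATAC = 0.8,
                                                      H3K9me3 = -0.8)),
                       editor_mode = c("unbiased", "CBE", "ABE"),
                       n_replicates = 3L) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  editor_mode <- match.arg(editor_mode)
  stopifnot(genome_length > 0, n_replicates >= 1)
  if (!is.null(type_copies)) {
    nfam <- length(type_copies)
    types_per_family <- lengths(type_copies)
    family_sizes <- vapply(type_copies, sum, numeric(1))
  } else {
    nfam <- length(family_sizes)
    types_per_family <- rep_len(as.integer(types_per_family), nfam)
  }
  stopifnot(all(family_sizes >= 1))
  if (!is.null(mismatch_spectrum)) {
    stopifnot(length(mismatch_spectrum) == nfam,
              all(lengths(mismatch_spectrum) == types_per_family))
  }
  stopifnot(all(names(edit_model$features) %in% chromatin_feature_names()))
  structure(
    list(seed = as.integer(seed), genome_length = as.integer(genome_length),
         family_sizes = as.integer(family_sizes),
         types_per_family = types_per_family,
         mismatch_spectrum = mismatch_spectrum,
         type_copies = type_copies,
         mismatch_range = mismatch_range,
         flank_uniqueness = flank_uniqueness,
         track_effects = track_effects, edit_model = edit_model,
         editor_mode = editor_mode, n_replicates = as.integer(n_replicates)),
    class = "sim_config"
  )
}

#' @rdname sim_config
#' @export
default_track_effects <- function() {
  eff <- list(
    H3K9me3 = list(baseline = 1.0, sd = 1.0),
    H3K4me1 = list(baseline = 1.0, sd = 1.0),
    H3K36me3 = list(baseline = 1.0, sd = 1.0),
    H3K27ac = list(baseline = 1.0, sd = 1.0),
    DNA_methylation = list(baseline = 3.0, sd = 1.5),
    ATAC = list(baseline = 2.0, sd = 1.0),
    DNase = list(baseline = 2.0, sd = 1.0),
    RNAP2 = list(baseline = 1.0, sd = 1.0),
    TCF27 = list(baseline = 0.5, sd = 0.5),
    ELK4 = list(baseline = 0.5, sd = 0.5),
    TCF7L2 = list(baseline = 0.5, sd = 0.5),
    TRIM28 = list(baseline = 0.5, sd = 0.5),
    FPKM = list(baseline = 5.0, sd = 3.0)
  )
  stopifnot(identical(names(eff), chromatin_feature_names()))
  eff
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# draw a family target: 20-mer + NGG PAM that passes the GC, simple-repeat
# and editing-window filters, so planted on-targets are scan-eligible
draw_target23 <- function(config = scan_config()) {
  for (tries in 1:200) {
    proto <- random_dna(20L)
    gc <- gc_content(proto)
    win <- substr(proto, config$edit_window_start,
                  config$edit_window_start + config$edit_window_width - 1L)
    if (gc >= config$gc_min && gc < config$gc_max &&
        !has_simple_repeat(proto) &&
        grepl("A", win) && grepl("C", win)) {
      return(paste0(proto, sample(DNA_BASES, 1), "GG"))
    }
  }
  stop("could not draw a filter-passing target in 200 tries", call. = FALSE)
}

mutate_target <- function(target23, n_mm) {
  if (n_mm == 0) return(target23)
  chars <- strsplit(target23, NULL)[[1]]
  pos <- sample(length(chars), n_mm)
  for (p in pos) chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1)
  paste(chars, collapse = "")
}

#' Simulate a genome with planted off-target families
#'
#' Generates a random background genome and plants, for each family, copies
#' of a scan-eligible target sequence at the configured mismatch distances,
#' on random strands, at well-separated loci. With `flank_uniqueness` the
#' planted context (site + 27-bp flanks) is checked for global uniqueness
#' and colliding sites are re-drawn, so the callability ground truth is
#' exact.
#'
#' @param config A [sim_config()].
#' @return List with `genome` (a [genome_index()]) and `truth`: one row per
#'   planted site (`family`, `family_type`, `target23`, `chrom`, `start`,
#'   `end`, `strand`, `site_id`, `planted_seq` in targeted-strand
#'   orientation, `mismatch_count`). All copies of one `family_type` share
#'   `planted_seq`, so they form one off-target type downstream.
#' @export
simulate_genome <- function(config) {
  withr::with_seed(config$seed, {
    L <- config$genome_length
    total <- sum(config$family_sizes)
    slot <- 160L  # per-site footprint: 23-mer + flanks + spacing
    margin <- 60L
    if (total * slot > L - 2L * margin) {
      stop("genome_length too small to host ", total,
           " planted sites (need >= ", total * slot + 2L * margin, " bp)",
           call. = FALSE)
    }
    bg <- sample(DNA_BASES, L, replace = TRUE)

    starts0 <- margin + floor((L - 2L * margin - 23L) *
                                (seq_len(total) - 0.5) / total)
    nfam <- length(config$family_sizes)
    targets <- vapply(seq_len(nfam), function(i) draw_target23(), character(1))

    # per family: distinct variant sequences (types), each planted in
    # several sequence-identical copies at separate loci
    plan <- purrr::map_dfr(seq_len(nfam), function(i) {
      ntype <- config$types_per_family[i]
      mm <- if (!is.null(config$mismatch_spectrum)) {
        as.integer(config$mismatch_spectrum[[i]])
      } else {
        c(0L, sample(config$mismatch_range, ntype - 1L, replace = TRUE))
      }
      copies <- if (!is.null(config$type_copies)) {
        as.integer(config$type_copies[[i]])
      } else {
        diff(round(seq(0, config$family_sizes[i], length.out = ntype + 1L)))
      }
      seqs <- character(ntype)
      for (k in seq_len(ntype)) {
        for (try in 1:100) {
          s <- mutate_target(targets[i], mm[k])
          if (!s %in% seqs[seq_len(k - 1L)]) break
        }
        seqs[k] <- s
      }
      tibble(family = i, family_type = rep(seq_len(ntype), copies),
             planted_seq = rep(seqs, copies),
             mismatch_count = rep(mm, copies))
    })
    stopifnot(nrow(plan) == total)
    plan <- plan[sample.int(total), ]  # interleave families along the genome
    strand <- sample(c("+", "-"), total, replace = TRUE)

    rows <- vector("list", total)
    for (i in seq_len(total)) {
      seq23 <- plan$planted_seq[i]
      genomic <- if (strand[i] == "+") seq23 else revcomp(seq23)
      s0 <- starts0[i]
      bg[(s0 + 1):(s0 + 23)] <- strsplit(genomic, NULL)[[1]]
      rows[[i]] <- tibble(
        family = plan$family[i], family_type = plan$family_type[i],
        target23 = targets[plan$family[i]],
        chrom = "chr1", start = s0, end = s0 + 23L, strand = strand[i],
        planted_seq = seq23, mismatch_count = plan$mismatch_count[i]
      )
    }
    genome <- genome_index(c(chr1 = paste(bg, collapse = "")))
    truth <- bind_rows(rows) %>%
      mutate(site_id = site_id_of(.data$chrom, .data$start, .data$end,
                                  .data$strand))

    if (config$flank_uniqueness) {
      # re-randomise flanks of any context that collides (rare)
      for (pass in 1:3) {
        chk <- flag_callable(truth, genome, flank = 27L)
        bad <- which(!chk$callable)
        if (length(bad) == 0) break
        s <- strsplit(genome[["chr1"]], NULL)[[1]]
        for (i in bad) {
          fl <- truth$start[i] - 27L
          fr <- truth$end[i] + 27L
          if (fl >= 0) s[(fl + 1):truth$start[i]] <-
              sample(DNA_BASES, 27L, replace = TRUE)
          if (fr <= L) s[(truth$end[i] + 1):fr] <-
              sample(DNA_BASES, 27L, replace = TRUE)
        }
        genome <- genome_index(c(chr1 = paste(s, collapse = "")))
      }
    }
    list(genome = genome, truth = truth)
  })
}

#' Simulate chromatin feature tracks for planted sites
#'
#' Draws a per-site value for each of the 13 chromatin features from the
#' configured baseline + sd model and materialises them as valid track
#' files: 11 interval (bedGraph-style) tracks whose intervals exactly cover
#' each site's 50-bp window (background intervals at the baseline
#' elsewhere), DNA methylation as point records (the per-site value is a
#' count), and FPKM as one gene interval per site. Site windows therefore
#' score back to the drawn values exactly.
#'
#' @param config A [sim_config()].
#' @param sim Output of [simulate_genome()].
#' @return List with `tracks` (named list of 11 interval tibbles),
#'   `methylation`, `genes`, and `site_values`: tibble of the drawn
#'   per-site feature values (ground truth).
#' @export
simulate_tracks <- function(config, sim) {
  withr::with_seed(config$seed + 1L, {
    truth <- sim$truth
    lens <- genome_lengths(sim$genome)
    win <- make_window(truth, genome_lengths = lens)
    n <- nrow(truth)
    vals <- tibble(site_id = truth$site_id)
    for (f in chromatin_feature_names()) {
      eff <- config$track_effects[[f]]
      v <- eff$baseline + eff$sd * rnorm(n)
      if (f == "DNA_methylation") v <- pmax(0L, round(v))
      if (f == "FPKM") v <- pmax(0, v)
      vals[[f]] <- v
    }

    ord <- order(win$win_start)
    tracks <- list()
    for (f in interval_feature_names()) {
      site_iv <- tibble(chrom = win$chrom[ord], start = win$win_start[ord],
                        end = win$win_end[ord], value = vals[[f]][ord])
      gaps <- tibble(
        chrom = "chr1",
        start = c(0L, site_iv$end),
        end = c(site_iv$start, lens[["chr1"]])
      ) %>% filter(.data$end > .data$start)
      gaps$value <- config$track_effects[[f]]$baseline
      tracks[[f]] <- bind_rows(site_iv, gaps) %>%
        arrange(.data$chrom, .data$start)
    }

    meth <- purrr::map_dfr(seq_len(n), function(i) {
      k <- min(vals$DNA_methylation[i], win$win_len[i])
      if (k == 0) return(tibble(chrom = character(), start = integer()))
      tibble(chrom = win$chrom[i],
             start = as.integer(win$win_start[i] +
                                  sort(sample(win$win_len[i], k))) - 1L)
    })

    genes <- tibble(
      chrom = win$chrom[ord], start = win$win_start[ord],
      end = win$win_end[ord],
      gene_id = sprintf("gene_%04d", seq_len(n)),
      score = vals$FPKM[ord]
    )
    list(tracks = tracks, methylation = meth, genes = genes,
         site_values = vals)
  })
}

#' Simulate edits at planted sites
#'
#' Computes each site's edit probability from the logistic model
#' `plogis(intercept + mismatch * mm + sum(beta_f * z_f))` (features
#' standardised across sites), realises edited flags per replicate, and
#' emits the edits as SNVs with the configured editor signature (`CBE`:
#' C->T on the targeted strand, `ABE`: A->G, `unbiased`: random
#' substitution) and allele fractions `>= 0.01`.
#'
#' @param config A [sim_config()].
#' @param sim Output of [simulate_genome()].
#' @param tracks Output of [simulate_tracks()].
#' @return List with `truth` (per site: `edit_prob` and logical
#'   `edited_rep1..K`, plus `edited_any`) and `vcfs`: list of per-replicate
#'   variant tibbles (`chrom`, `pos` 1-based, `ref`, `alt`,
#'   `allele_fraction`) ready for [write_vcf()].
#' @export
simulate_edits <- function(config, sim, tracks) {
  withr::with_seed(config$seed + 2L, {
    truth <- sim$truth
    vals <- tracks$site_values
    em <- config$edit_model
    eta <- em$intercept + em$mismatch * truth$mismatch_count
    for (f in names(em$features)) {
      v <- vals[[f]]
      z <- if (sd(v) > 0) (v - mean(v)) / sd(v) else v * 0
      eta <- eta + em$features[[f]] * z
    }
    p <- plogis(eta)

    n <- nrow(truth)
    flags <- matrix(FALSE, n, config$n_replicates)
    vcfs <- vector("list", config$n_replicates)
    for (r in seq_len(config$n_replicates)) {
      flags[, r] <- runif(n) < p
      idx <- which(flags[, r])
      if (length(idx) == 0) {
        vcfs[[r]] <- tibble(chrom = character(), pos = integer(),
                            ref = character(), alt = character(),
                            allele_fraction = numeric())
        next
      }
      rows <- purrr::map_dfr(idx, function(i) {
        simulate_one_edit(truth[i, ], config$editor_mode)
      })
      rows$allele_fraction <- round(runif(nrow(rows), 0.05, 0.6), 4)
      vcfs[[r]] <- rows %>% arrange(.data$chrom, .data$pos)
    }
    colnames(flags) <- sprintf("edited_rep%d", seq_len(config$n_replicates))
    truth_out <- truth %>%
      mutate(edit_prob = p) %>%
      dplyr::bind_cols(as_tibble(flags)) %>%
      mutate(edited_any = rowSums(flags) > 0)
    list(truth = truth_out, vcfs = vcfs)
  })
}

# pick the edited base within one site's 23-mer per the editor signature;
# returns reference-strand REF/ALT at a 1-based genomic position
simulate_one_edit <- function(site, mode) {
  chars <- strsplit(site$planted_seq, NULL)[[1]]
  want <- switch(mode, CBE = "C", ABE = "A", unbiased = NA_character_)
  cand <- if (is.na(want)) seq_along(chars) else which(chars == want)
  if (length(cand) == 0) cand <- seq_along(chars)  # fall back: any base
  pos_in_site <- if (length(cand) == 1) cand else sample(cand, 1)
  from_t <- chars[pos_in_site]
  to_t <- switch(mode,
                 CBE = if (from_t == "C") "T" else
                   sample(setdiff(DNA_BASES, from_t), 1),
                 ABE = if (from_t == "A") "G" else
                   sample(setdiff(DNA_BASES, from_t), 1),
                 unbiased = sample(setdiff(DNA_BASES, from_t), 1))
  if (site$strand == "+") {
    pos1 <- site$start + pos_in_site
    ref <- from_t; alt <- to_t
  } else {
    pos1 <- site$end - pos_in_site + 1L
    ref <- revcomp(from_t); alt <- revcomp(to_t)
  }
  tibble(chrom = site$chrom, pos = as.integer(pos1), ref = ref, alt = alt)
}

#' Run the whole simulator
#'
#' Convenience wrapper: [simulate_genome()] then [simulate_tracks()] then
#' [simulate_edits()].
#'
#' @param config A [sim_config()].
#' @return List with `config`, `genome`, `truth` (including feature values,
#'   edit probabilities and realised flags), `tracks`, `methylation`,
#'   `genes`, `site_values`, `vcfs`.
#' @export
simulate_offtarget_study <- function(config) {
  g <- simulate_genome(config)
  trk <- simulate_tracks(config, g)
  ed <- simulate_edits(config, g, trk)
  truth <- ed$truth %>%
    left_join(trk$site_values, by = "site_id")
  list(config = config, genome = g$genome, truth = truth,
       tracks = trk$tracks, methylation = trk$methylation,
       genes = trk$genes, site_values = trk$site_values, vcfs = ed$vcfs)
}

#' Write a simulated study to disk
#'
#' Materialises every artifact in its standard format: genome FASTA, 11
#' bedGraph tracks, methylation bedGraph (count as the value), gene score
#' TSV, one VCF per replicate, and the truth table TSV.
#'
#' @param sim Output of [simulate_offtarget_study()].
#' @param dir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(genome = file.path(dir, "genome.fa"))
  write_genome(sim$genome, paths$genome)
  for (f in names(sim$tracks)) {
    paths[[f]] <- file.path(dir, paste0(tolower(f), ".bedgraph"))
    write_bedgraph(sim$tracks[[f]], paths[[f]])
  }
  paths$methylation <- file.path(dir, "methylation.bedgraph")
  write_bedgraph(sim$methylation %>%
                   mutate(end = .data$start + 1L, value = 1),
                 paths$methylation)
  paths$genes <- file.path(dir, "genes.tsv")
  write_chromoff_tsv(sim$genes, paths$genes)
  for (r in seq_along(sim$vcfs)) {
    paths[[paste0("vcf_rep", r)]] <- file.path(dir, sprintf("edits_rep%d.vcf", r))
    write_vcf(sim$vcfs[[r]], paths[[paste0("vcf_rep", r)]],
              tumor_name = sprintf("editor_rep%d", r))
  }
  paths$truth <- file.path(dir, "truth.tsv")
  write_chromoff_tsv(sim$truth, paths$truth)
  invisible(paths)
}
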