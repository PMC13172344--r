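test_that("PAM scan finds the constructed forward protospacer", {
  g <- genome_index(c(chr = "CCCACGTACGTACGTACGTACGTAGGCCC"))
  hits <- scan_pam_sites(g, scan_config())
  fwd <- hits[hits$strand == "+", ]
  expect_equal(nrow(fwd), 1)
  expect_equal(fwd$protospacer, "ACGTACGTACGTACGTACGT")
  expect_equal(fwd$pam, "AGG")
  expect_equal(fwd$target23, paste0(fwd$protospacer, fwd$pam))
  expect_equal(fwd$start, 3L)
  expect_equal(fwd$end, 26L)
})

test_that("a homopolymer genome yields no candidates and short contigs skip", {
  g <- genome_index(c(chr = strrep("A", 500)))
  expect_equal(nrow(scan_pam_sites(g, scan_config())), 0)
  g2 <- genome_index(c(tiny = "ACGTACGT", ok = strrep("ACG", 30)))
  expect_message(scan_pam_sites(g2, scan_config()), "skipping tiny")
})

test_that("scan agrees with a naive per-position oracle on a random genome", {
  g <- random_genome(10000, seed = 101)
  hits <- scan_pam_sites(g, scan_config())
  expect_equal(nrow(hits), oracle_scan_count(g))
  # windows containing N are discarded
  s <- as.character(g[["chr1"]])
  substr(s, 5001, 5001) <- "N"
  gN <- genome_index(c(chr1 = s))
  hitsN <- scan_pam_sites(gN, scan_config())
  expect_equal(nrow(hitsN), oracle_scan_count(gN))
  expect_lt(nrow(hitsN), nrow(hits))
})

test_that("strand symmetry: reverse-complementing the genome mirrors hits", {
  g <- random_genome(4000, seed = 7)
  cfg <- scan_config()
  a <- scan_pam_sites(g, cfg)
  b <- scan_pam_sites(revcomp_genome(g), cfg)
  L <- unname(genome_lengths(g))
  mirrored <- tibble::tibble(
    start = L - b$end, end = L - b$start,
    strand = ifelse(b$strand == "+", "-", "+"),
    target23 = b$target23
  )
  key <- function(d) sort(paste(d$start, d$end, d$strand, d$target23))
  expect_identical(key(a), key(mirrored))
})

test_that("each filter step rejects its fixture and passes a clean one", {
  cfg <- scan_config(min_offtarget_pool = 5)
  good23 <- "GACTGACCTGATCGATGCATCGG"  # GC 0.55, no repeat, A+C in window 4-8
  make_cand <- function(t23, gc = NULL) {
    tibble::tibble(
      chrom = "chr1", start = 100L, end = 123L, strand = "+",
      protospacer = substr(t23, 1, 20), pam = substr(t23, 21, 23),
      target23 = t23, gc = if (is.null(gc)) gc_content(substr(t23, 1, 20)) else gc
    )
  }
  g_plain <- plant_sites(good23, 1, 3000, seed = 5, strands = "+")$genome
  cand_at <- function(genome, t23) {
    hits <- scan_pam_sites(genome, cfg)
    hits[hits$target23 == t23, ]
  }

  # step 2: GC bounds (40% <= GC < 80%), both tails
  low_gc <- make_cand("AATTAATTAATTAGCGCGCCCGG")   # GC 7/20 = 0.35
  expect_equal(gc_content(low_gc$protospacer), 0.35)
  out <- apply_filters(low_gc, g_plain, cfg, steps = 2, keep_rejected = TRUE)
  expect_equal(out$filter_trace, "gc_content")
  hi_gc <- make_cand("GGCCGGCCGTGCGGCCGGCCCGG")   # GC 19/20 = 0.95
  out <- apply_filters(hi_gc, g_plain, cfg, steps = 2, keep_rejected = TRUE)
  expect_equal(out$filter_trace, "gc_content")
  out <- apply_filters(make_cand(good23), g_plain, cfg, steps = 2)
  expect_equal(out$filter_trace, "pass")

  # step 3: completely soft-masked 23-mer rejected, partial masking passes
  masked <- plant_sites(tolower(good23), 1, 3000, seed = 5, strands = "+")
  cand <- tibble::tibble(chrom = "chr1", start = masked$start,
                         end = masked$start + 23L, strand = "+",
                         protospacer = substr(good23, 1, 20),
                         pam = substr(good23, 21, 23), target23 = good23,
                         gc = gc_content(substr(good23, 1, 20)))
  out <- apply_filters(cand, masked$genome, cfg, steps = 3,
                       keep_rejected = TRUE)
  expect_equal(out$filter_trace, "soft_masked")
  partial <- masked$genome
  s <- as.character(partial[["chr1"]])
  substr(s, masked$start + 1, masked$start + 1) <- toupper(substr(s, masked$start + 1, masked$start + 1))
  partial <- genome_index(c(chr1 = s))
  out <- apply_filters(cand, partial, cfg, steps = 3)
  expect_equal(out$filter_trace, "pass")

  # step 4: more than 14 perfect copies on one chromosome
  many <- plant_sites(good23, 15, 6000, seed = 9, strands = rep("+", 15))
  cand15 <- cand_at(many$genome, good23)
  expect_gte(nrow(cand15), 15)
  out <- apply_filters(cand15, many$genome, cfg, steps = 4,
                       keep_rejected = TRUE)
  expect_true(all(out$filter_trace == "perfect_copies"))
  few <- plant_sites(good23, 14, 6000, seed = 9, strands = rep("+", 14))
  out <- apply_filters(cand_at(few$genome, good23), few$genome, cfg, steps = 4)
  expect_true(all(out$filter_trace == "pass"))

  # step 5: overlap with an exclusion interval (protospacer interval only)
  cfg_ex <- scan_config(exclusion_intervals =
                          tibble::tibble(chrom = "chr1", start = 110L, end = 130L))
  out <- apply_filters(make_cand(good23), g_plain, cfg_ex, steps = 5,
                       keep_rejected = TRUE)
  expect_equal(out$filter_trace, "gene_exclusion")
  cfg_far <- scan_config(exclusion_intervals =
                           tibble::tibble(chrom = "chr1", start = 500L, end = 600L))
  out <- apply_filters(make_cand(good23), g_plain, cfg_far, steps = 5)
  expect_equal(out$filter_trace, "pass")

  # step 6: the documented simple-repeat rule instances
  run4 <- make_cand("AAAAGCGCGCGCGCGCGCGCCGG")
  expect_equal(apply_filters(run4, g_plain, cfg, steps = 6,
                             keep_rejected = TRUE)$filter_trace,
               "simple_repeat")
  tandem2 <- make_cand("ACACACGTGATCGTACGTGCCGG")   # AC x3
  expect_equal(apply_filters(tandem2, g_plain, cfg, steps = 6,
                             keep_rejected = TRUE)$filter_trace,
               "simple_repeat")
  tandem3 <- make_cand("ACGACGACGTTGCATGCTACCGG")   # ACG x3
  expect_equal(apply_filters(tandem3, g_plain, cfg, steps = 6,
                             keep_rejected = TRUE)$filter_trace,
               "simple_repeat")
  expect_equal(apply_filters(make_cand(good23), g_plain, cfg,
                             steps = 6)$filter_trace, "pass")

  # step 7: editing window (positions 4-8) must contain A and C
  noA <- make_cand("GTTCTCGTGATCGATGCATCCGG")  # window "CTCGT": C but no A
  expect_equal(apply_filters(noA, g_plain, cfg, steps = 7,
                             keep_rejected = TRUE)$filter_trace, "edit_window")
  expect_equal(substr(good23, 4, 8), "TGACC")
  expect_equal(apply_filters(make_cand(good23), g_plain, cfg,
                             steps = 7)$filter_trace, "pass")

  # step 8: pool must exceed the threshold; missing pool is an error
  pools <- c(2000L, 20L)
  names(pools) <- c(good23, "AATTAATTAATTAGCGCGCCCGG")
  both <- dplyr::bind_rows(make_cand(good23), low_gc)
  cfg8 <- scan_config(min_offtarget_pool = 100)
  out <- apply_filters(both, g_plain, cfg8, pools = pools, steps = 8,
                       keep_rejected = TRUE)
  expect_equal(out$filter_trace, c("pass", "pool_size"))
  expect_error(apply_filters(make_cand(good23), g_plain, cfg8,
                             pools = c(XYZ = 5L), steps = 8),
               "no off-target pool")
})

test_that("filters are order-independent and idempotent on survivors", {
  g <- random_genome(6000, seed = 23)
  cfg <- scan_config()
  cands <- scan_pam_sites(g, cfg)
  surv <- apply_filters(cands, g, cfg, steps = 2:7)
  shuffled <- cands[withr::with_seed(1, sample(nrow(cands))), ]
  surv2 <- apply_filters(shuffled, g, cfg, steps = 2:7)
  key <- function(d) sort(paste(d$chrom, d$start, d$strand))
  expect_identical(key(surv), key(surv2))
  # each survivor passes every individual step standalone
  for (st in 2:7) {
    alone <- apply_filters(surv %>% dplyr::select(-pool_size, -filter_trace),
                           g, cfg, steps = st, keep_rejected = TRUE)
    expect_true(all(alone$pass), info = paste("step", st))
  }
})

test_that("ranking sorts by callable pool with deterministic tie-break", {
  surv <- tibble::tibble(
    chrom = c("chr2", "chr1", "chr1"), start = c(5L, 9L, 2L),
    strand = c("+", "+", "+"),
    callable_pool_size = c(5L, 50L, 7L)
  )
  r <- rank_candidates(surv, top_n = 2)
  expect_equal(r$callable_pool_size, c(50L, 7L))
  expect_equal(r$rank, 1:2)
  # ties broken by (chrom, start, strand), stable across shuffles
  tied <- tibble::tibble(
    chrom = c("chr2", "chr1", "chr1"), start = c(1L, 9L, 2L),
    strand = c("+", "-", "+"),
    callable_pool_size = c(10L, 10L, 10L)
  )
  r1 <- rank_candidates(tied, top_n = 3)
  r2 <- rank_candidates(tied[c(3, 1, 2), ], top_n = 3)
  expect_identical(r1, r2)
  expect_equal(r1$chrom, c("chr1", "chr1", "chr2"))
  expect_equal(r1$start, c(2L, 9L, 1L))
  # fewer survivors than top_n returns all
  expect_equal(nrow(rank_candidates(tied, top_n = 10)), 3)
})

test_that("planted pools decide survival through the composite screen", {
  # one family of 15 identical planted targets, another with 3 copies: with
  # min_offtarget_pool = 5 only the large family's candidates survive.
  # t_big carries no GG/CC away from its PAM and is planted inside A/T-only
  # flanks, so the family contributes no other PAM-bearing window whose
  # shifted copies could form a surviving pool of their own.
  t_big <- "GACTGATCTGATCGATGCATCGG"
  t_small <- "TGCACTTGATCCGTAGCTAGAGG"
  bg <- withr::with_seed(31, sample(c("A", "C", "G", "T"), 9000, replace = TRUE))
  at_flank <- function(n) sample(c("A", "T"), n, replace = TRUE)
  starts_big <- 100 + (0:14) * 400
  starts_small <- 6400 + (0:2) * 400
  withr::with_seed(32, {
    for (s0 in starts_big) {
      bg[(s0 - 7):(s0 + 31)] <- c(at_flank(8), strsplit(t_big, NULL)[[1]],
                                  at_flank(8))
    }
  })
  for (s0 in starts_small) {
    bg[(s0 + 1):(s0 + 23)] <- strsplit(t_small, NULL)[[1]]
  }
  g <- genome_index(c(chr1 = paste(bg, collapse = "")))
  cfg <- scan_config(min_offtarget_pool = 5, max_mismatches = 3,
                     max_perfect_copies_per_chrom = 100, top_n = 100)
  out <- scan_protospacers(g, cfg)
  expect_setequal(out$target23, t_big)
  expect_equal(sort(out$start), starts_big)
  expect_equal(nrow(out), 15)
  expect_true(all(out$pool_size >= 15))
  expect_true(all(out$callable_pool_size <= out$pool_size))
})
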