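write_test_vcf <- function(variants, path) {
  write_vcf(variants, path)
  path
}

test_that("variant loading enforces PASS, allele fraction and clustering", {
  path <- withr::local_tempfile(fileext = ".vcf")
  vars <- tibble::tibble(
    chrom = "chr1",
    pos = c(100L, 300L, 500L),
    ref = c("A", "C", "G"), alt = c("G", "T", "A"),
    allele_fraction = c(0.5, 0.005, 0.2)
  )
  write_test_vcf(vars, path)
  got <- load_filtered_variants(path)
  # AF 0.005 dropped, isolated PASS records retained
  expect_equal(got$pos, c(100L, 500L))
  expect_equal(got$allele_fraction, c(0.5, 0.2))
  expect_equal(got$sample_id, rep("editor", 2))

  # a non-PASS record is dropped
  lines <- readLines(path)
  lines[length(lines)] <- sub("\tPASS\t", "\tclustered_events\t",
                              lines[length(lines)])
  writeLines(lines, path)
  got2 <- load_filtered_variants(path)
  expect_equal(got2$pos, 100L)
})

test_that("six variants within 40 bp are all dropped by the region rule", {
  path <- withr::local_tempfile(fileext = ".vcf")
  clustered <- tibble::tibble(
    chrom = "chr1", pos = c(1000L, 1008L, 1016L, 1024L, 1032L, 1040L),
    ref = "A", alt = "G", allele_fraction = 0.3
  )
  lone <- tibble::tibble(chrom = "chr1", pos = 5000L, ref = "C", alt = "T",
                         allele_fraction = 0.3)
  write_test_vcf(dplyr::bind_rows(clustered, lone), path)
  got <- load_filtered_variants(path, max_events_in_region = 5,
                                region_window = 50)
  expect_equal(got$pos, 5000L)
  # five events in the window survive
  write_test_vcf(dplyr::bind_rows(clustered[1:5, ], lone), path)
  got5 <- load_filtered_variants(path, max_events_in_region = 5,
                                 region_window = 50)
  expect_equal(nrow(got5), 6)
})

test_that("multi-allelic records are split per ALT with per-allele AF", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FILTER=<ID=PASS,Description=\"ok\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    "##FORMAT=<ID=AF,Number=A,Type=Float,Description=\"af\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tcontrol\teditor",
    "chr1\t100\t.\tA\tG,T\t.\tPASS\t.\tGT:AF\t0/0:0,0\t0/1:0.30,0.002"
  ), path)
  got <- load_filtered_variants(path)
  expect_equal(nrow(got), 1)
  expect_equal(got$alt, "G")
  expect_equal(got$allele_fraction, 0.30)
})

test_that("variant classification follows the run-substitution rule", {
  one <- classify_variant("A", "G")
  expect_equal(one$variant_class, "SNV")
  expect_equal(one$changes[[1]]$from, "A")
  expect_equal(one$changes[[1]]$to, "G")

  # AA>GG is an SNV with two A->G base changes, not an InDel
  run2 <- classify_variant("AA", "GG")
  expect_equal(run2$variant_class, "SNV")
  expect_equal(run2$changes[[1]]$from, c("A", "A"))
  expect_equal(run2$changes[[1]]$to, c("G", "G"))
  expect_equal(run2$changes[[1]]$offset, c(0L, 1L))
  run3 <- classify_variant("CCC", "TTT")
  expect_equal(run3$changes[[1]]$offset, 0:2)

  expect_equal(classify_variant("A", "AG")$variant_class, "InDel")
  expect_equal(classify_variant("ATT", "A")$variant_class, "InDel")
  expect_error(classify_variant("A", "X"), "A/C/G/T")
})

test_that("edits assign to containing sites and on-target is excluded", {
  target <- random_target(81)
  tch <- strsplit(target, NULL)[[1]]
  mm3 <- tch
  mm3[c(2, 9, 15)] <- vapply(mm3[c(2, 9, 15)],
                             function(b) setdiff(c("A", "C", "G", "T"), b)[1],
                             character(1))
  # force an NGG on-target so the exclusion path is exercised
  on_seq <- paste(c(tch[1:21], "G", "G"), collapse = "")
  off_seq <- paste(mm3, collapse = "")
  sites <- tibble::tibble(
    site_id = c("on", "off"), chrom = "chr1",
    start = c(100L, 500L), end = c(123L, 523L), strand = "+",
    site23 = c(on_seq, off_seq),
    mismatch_count = c(0L, 3L),
    mismatch_positions = c("", "2,9,15"),
    pam_class = c("NGG", ifelse(substr(off_seq, 22, 23) == "GG",
                                "NGG", "non-NGG"))
  )
  variants <- tibble::tibble(
    chrom = "chr1", pos = c(110L, 510L, 900L),
    ref = c("A", "C", "G"), alt = c("G", "A", "T"),
    allele_fraction = 0.4, sample_id = "rep1"
  )
  edits <- assign_edits_to_sites(variants, sites)
  expect_equal(nrow(edits), 2)  # variant at 900 hits no site
  expect_true(edits$on_target[edits$site_id == "on"])
  expect_false(edits$on_target[edits$site_id == "off"])
  sm <- summarize_edits(edits, sites)
  expect_equal(sm$n_offtarget_edits, 1)
  expect_equal(sm$n_offtarget_sites, 1)
  # From/To are reference-strand bases
  expect_equal(edits$from_base[edits$site_id == "off"], "C")
  expect_equal(edits$to_base[edits$site_id == "off"], "A")
})

test_that("edit summary matrices and PAM frequencies are correct", {
  sites <- tibble::tibble(
    site_id = sprintf("s%02d", 1:10), chrom = "chr1",
    start = seq(0L, 900L, by = 100L), end = seq(23L, 923L, by = 100L),
    strand = "+",
    site23 = rep(random_target(91), 10),
    mismatch_count = c(0L, rep(2L, 5), rep(4L, 4)),
    mismatch_positions = c("", rep("3,7", 5), rep("1,5,9,21", 4)),
    pam_class = c("NGG", rep("NGG", 4), rep("non-NGG", 5))
  )
  edits <- tibble::tibble(
    site_id = c("s02", "s03", "s07", "s07"),
    chrom = "chr1", pos = c(101L, 201L, 601L, 602L),
    variant_class = c("SNV", "SNV", "SNV", "InDel"),
    from_base = c("A", "A", "G", NA), to_base = c("G", "C", "A", NA),
    allele_fraction = 0.2,
    sample_id = c("rep1", "rep1", "rep1", "rep2"),
    on_target = FALSE
  )
  sm <- summarize_edits(edits, sites)
  expect_equal(sum(sm$mutation_matrix), 3)
  expect_equal(sm$mutation_matrix["A", "G"], 1L)
  expect_equal(sm$mutation_matrix["A", "C"], 1L)
  expect_equal(sm$mutation_matrix["G", "A"], 1L)
  expect_true(all(diag(sm$mutation_matrix) == 0))
  pam <- sm$pam_table
  # 9 potential off-target sites: 4 NGG (2 edited), 5 non-NGG (1 edited)
  expect_equal(pam$n_potential[pam$pam_class == "NGG"], 4L)
  expect_equal(pam$n_edited[pam$pam_class == "NGG"], 2L)
  expect_equal(pam$editing_frequency_pct[pam$pam_class == "NGG"], 50)
  expect_equal(pam$n_edited[pam$pam_class == "non-NGG"], 1L)
  expect_equal(pam$editing_frequency_pct[pam$pam_class == "non-NGG"], 20)
  # mismatch histogram and positional profile over edited sites
  expect_equal(sm$mismatch_histogram$n_sites[sm$mismatch_histogram$mismatch_count == 2], 2L)
  expect_equal(sm$mismatch_histogram$n_sites[sm$mismatch_histogram$mismatch_count == 4], 1L)
  prof <- sm$position_profile
  expect_equal(prof$mismatch_frequency[prof$position == 3], 2 / 3)
  expect_equal(prof$mismatch_frequency[prof$position == 1], 1 / 3)
  # the edited site x sample count tallies both replicates
  expect_equal(sm$n_offtarget_edits, 4)
  expect_equal(sm$n_offtarget_sites, 3)
})

test_that("an empty edit set yields all-zero summaries", {
  sites <- tibble::tibble(
    site_id = "s1", chrom = "chr1", start = 0L, end = 23L, strand = "+",
    site23 = random_target(95), mismatch_count = 2L,
    mismatch_positions = "1,2", pam_class = "non-NGG"
  )
  edits <- assign_edits_to_sites(
    tibble::tibble(chrom = character(), pos = integer(), ref = character(),
                   alt = character(), allele_fraction = numeric(),
                   sample_id = character()),
    sites)
  sm <- summarize_edits(edits, sites)
  expect_equal(sm$n_offtarget_edits, 0)
  expect_true(all(sm$mutation_matrix == 0))
  expect_equal(sm$pam_table$n_edited, 0L)
})

test_that("pairwise edited-set overlap reports unique percentages", {
  sets <- list(
    Cas9 = c("a", "b", "c", "d"),
    BE = c("c", "d", "e", "f", "g", "h")
  )
  ov <- edited_set_overlap(sets)
  expect_equal(ov$n_intersect, 2)
  expect_equal(ov$n_union, 8)
  expect_equal(ov$pct_unique_a, 50)
  expect_equal(ov$pct_unique_b, round_half_up(100 * 4 / 6, 2))
})
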