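# Independent oracles and fixture builders used across the suite.

random_genome <- function(len, seed, name = "chr1") {
  withr::with_seed(seed, {
    genome_index(setNames(
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
      name))
  })
}

random_target <- function(seed, len = 23) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), len,
                                      replace = TRUE), collapse = ""))
}

# brute-force Hamming enumeration oracle via Biostrings (independent of the
# package's vectorised scan): every window on both strands within max_mm
oracle_enumerate <- function(genome, target23, max_mm) {
  out <- list()
  for (chrom in names(genome)) {
    subj <- Biostrings::DNAString(toupper(genome[[chrom]]))
    L <- length(subj)
    fwd <- Biostrings::matchPattern(Biostrings::DNAString(target23), subj,
                                    max.mismatch = max_mm, fixed = TRUE)
    if (length(fwd) > 0) {
      out[[length(out) + 1L]] <- tibble::tibble(
        chrom = chrom, start = Biostrings::start(fwd) - 1L, strand = "+")
    }
    rc <- Biostrings::reverseComplement(Biostrings::DNAString(target23))
    rev <- Biostrings::matchPattern(rc, subj, max.mismatch = max_mm,
                                    fixed = TRUE)
    if (length(rev) > 0) {
      out[[length(out) + 1L]] <- tibble::tibble(
        chrom = chrom, start = Biostrings::start(rev) - 1L, strand = "-")
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          strand = character()))
  }
  dplyr::arrange(dplyr::bind_rows(out), chrom, start, strand)
}

# per-position naive PAM scan oracle (string comparison at every offset)
oracle_scan_count <- function(genome, pam = "NGG", plen = 20) {
  iup <- list(A = "A", C = "C", G = "G", T = "T", N = c("A", "C", "G", "T"),
              R = c("A", "G"), Y = c("C", "T"))
  pamc <- strsplit(pam, NULL)[[1]]
  tl <- plen + length(pamc)
  n <- 0L
  for (chrom in names(genome)) {
    for (s in c(toupper(genome[[chrom]]), revcomp(toupper(genome[[chrom]])))) {
      L <- nchar(s)
      if (L < tl) next
      for (i in 1:(L - tl + 1)) {
        w <- substr(s, i, i + tl - 1)
        if (grepl("[^ACGT]", w)) next
        pam_ok <- TRUE
        for (k in seq_along(pamc)) {
          if (!substr(w, plen + k, plen + k) %in% iup[[pamc[k]]]) {
            pam_ok <- FALSE
            break
          }
        }
        if (pam_ok) n <- n + 1L
      }
    }
  }
  n
}

# full permutation oracle for the two-sided rank-sum p-value, computed from
# Mann-Whitney U on the raw values (independent of the package's rank DP)
oracle_rank_sum_p <- function(x, y) {
  v <- c(x, y)
  n1 <- length(x)
  n <- length(v)
  u_of <- function(idx) {
    xs <- v[idx]
    ys <- v[-idx]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  mu <- n1 * (n - n1) / 2
  obs <- abs(u_of(seq_len(n1)) - mu)
  devs <- apply(utils::combn(n, n1), 2, function(i) abs(u_of(i) - mu))
  mean(devs >= obs - 1e-12)
}

# plant `copies` exact copies of seq23 (targeted-strand orientation) into a
# random background at spaced loci; returns genome + planted coordinates
plant_sites <- function(seq23, copies, len, seed, strands = NULL) {
  withr::with_seed(seed, {
    bg <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    slot <- floor((len - 120) / copies)
    stopifnot(slot >= nchar(seq23) + 80)
    starts <- 60 + (seq_len(copies) - 1L) * slot
    if (is.null(strands)) strands <- sample(c("+", "-"), copies, replace = TRUE)
    for (i in seq_len(copies)) {
      s <- if (strands[i] == "+") seq23 else revcomp(seq23)
      bg[(starts[i] + 1):(starts[i] + nchar(seq23))] <- strsplit(s, NULL)[[1]]
    }
    list(genome = genome_index(c(chr1 = paste(bg, collapse = ""))),
         start = starts, strand = strands)
  })
}
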