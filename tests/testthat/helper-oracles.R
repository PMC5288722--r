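# Test helpers: random sequence generators and independent oracles.

rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_positions <- function(seq, positions, to = "N") {
  ch <- strsplit(seq, "")[[1]]
  ch[positions] <- to
  paste(ch, collapse = "")
}

substitute_bases <- function(seq, positions) {
  ch <- strsplit(seq, "")[[1]]
  for (i in positions) {
    ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  }
  paste(ch, collapse = "")
}

insert_at <- function(seq, pos, insertion) {
  paste0(substr(seq, 1, pos), insertion, substr(seq, pos + 1, nchar(seq)))
}

# Brute-force trimming oracle: direct scan of every window, no prefix sums.
trim_oracle <- function(seq, t = sip_thresholds()) {
  ch <- strsplit(seq, "")[[1]]
  amb <- !(ch %in% c("A", "C", "G", "T"))
  n <- length(ch)
  wc <- function(i0) sum(amb[(i0 + 1):min(n, i0 + t$qc_window)])
  cap <- floor(t$max_5prime_trim_fraction * n)
  start <- cap
  for (i in 0:cap) {
    if (i == n) break
    if (wc(i) <= t$max_ambiguities_5prime) { start <- i; break }
  }
  end <- n
  from <- start + t$three_prime_scan_offset
  if (from < n) {
    for (i in from:(n - 1)) {
      if (wc(i) > t$three_prime_ambiguity_limit) { end <- i; break }
    }
  }
  list(start = start, end = max(end, start))
}

# Independent local-alignment score oracle: full Smith-Waterman on every
# subject, both query strands, via Biostrings (match 2 / mismatch -3 /
# gap of length L costs 5 + 2L).
sw_score_oracle <- function(query, subjects) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = TRUE)
  one <- function(q, s) {
    Biostrings::score(Biostrings::pairwiseAlignment(
      q, s, type = "local", substitutionMatrix = mat,
      gapOpening = 5, gapExtension = 2))
  }
  vapply(subjects, function(s) {
    max(one(query, s), one(revcomp(query), s))
  }, numeric(1))
}

# Brute-force phasing oracle: generate-and-test. For every candidate
# offset d, enumerate all assignments of the two-base forward positions to
# allele A (allele B is then forced), and keep pairs whose superposition
# reproduces both observed reads exactly. Returns solutions grouped by d.
bf_phase_solutions <- function(forward_mix, reverse_mix, max_d = 10) {
  Fm <- seq_to_masks(forward_mix)
  M <- length(Fm)
  sols <- list()
  bits_of <- function(m) {
    b <- c(1L, 2L, 4L, 8L)
    b[bitwAnd(m, b) > 0L]
  }
  char_of <- c("A", "C", NA, "G", NA, NA, NA, "T")
  for (d in 0:max_d) {
    la <- M - d
    if (la < 1) next
    tail_ok <- TRUE
    if (d > 0) {
      for (i in (la + 1):M) {
        if (length(bits_of(Fm[i])) != 1L) { tail_ok <- FALSE; break }
      }
    }
    if (!tail_ok) next
    two <- which(vapply(seq_len(la),
                        function(i) length(bits_of(Fm[i])) == 2L,
                        logical(1)))
    if (any(vapply(seq_len(M), function(i) length(bits_of(Fm[i])) > 2L,
                   logical(1)))) next
    k <- length(two)
    for (code in 0:(2^k - 1)) {
      amask <- integer(la); bmask <- integer(M)
      ok <- TRUE
      for (i in seq_len(la)) {
        bs <- bits_of(Fm[i])
        if (length(bs) == 1L) { amask[i] <- bs; bmask[i] <- bs }
      }
      if (k > 0) {
        picks <- bitwAnd(code %/% (2^(seq_len(k) - 1)), 1L)
        for (j in seq_len(k)) {
          i <- two[j]
          bs <- bits_of(Fm[i])
          amask[i] <- bs[1 + picks[j]]
          bmask[i] <- bs[2 - picks[j]]
        }
      }
      if (d > 0) for (i in (la + 1):M) bmask[i] <- bits_of(Fm[i])
      a <- paste(char_of[amask], collapse = "")
      b <- paste(char_of[bmask], collapse = "")
      sp <- superpose_alleles(a, b)
      if (identical(sp$forward, forward_mix) &&
          identical(sp$reverse, reverse_mix)) {
        # canonical order: shorter allele first; lexicographic at d = 0
        pair <- if (nchar(a) == nchar(b)) sort(c(a, b)) else c(a, b)
        key <- paste(pair, collapse = "|")
        sols[[key]] <- list(a = pair[1], b = pair[2], d = d)
      }
    }
  }
  sols
}

# deterministic random reference sequence for simulation tests
.spongeid_test_refseq <- function(cfg, len, seed) {
  withr::with_seed(seed, rand_seq(len))
}

# small FASTA/manifest writer for read-pair loading tests
write_test_fasta <- function(records, path) {
  lines <- unlist(purrr::imap(records, function(s, id) c(paste0(">", id), s)))
  writeLines(lines, path)
  path
}
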