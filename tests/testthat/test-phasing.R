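test_that("superposing two alleles yields the documented mixture reads", {
  sp <- superpose_alleles("ACGTACGT", "ACGGTACGT")
  expect_equal(sp$forward, "ACGKWMSKT")
  expect_equal(nchar(sp$reverse), 9L)
  # homozygous superposition is just the sequence and its reverse complement
  s <- rand_seq(40)
  sp0 <- superpose_alleles(s, s)
  expect_equal(sp0$forward, s)
  expect_equal(sp0$reverse, revcomp(s))
})

test_that("heterozygosity classes separate clean, point and length-variant pairs", {
  s <- rand_seq(120)
  expect_equal(classify_heterozygosity(s, revcomp(s))$class, "homozygous")

  # single substitution: one mixed code, reverse-complement consistent
  set.seed(5)
  a <- rand_seq(120)
  b <- substitute_bases(a, 60)
  sp <- superpose_alleles(a, b)
  cl <- classify_heterozygosity(sp$forward, sp$reverse)
  expect_equal(cl$class, "point_het")
  expect_true(cl$rc_consistent)

  # allele pair differing by an interior indel: mixed tail to the 3' end
  b2 <- insert_at(a, 60, "G")
  sp2 <- superpose_alleles(a, b2)
  expect_equal(classify_heterozygosity(sp2$forward, sp2$reverse)$class,
               "length_variant_het")

  # N-type base-call ambiguity is not mixture evidence
  noisy <- mutate_positions(s, 110:120)
  expect_equal(classify_heterozygosity(noisy, revcomp(s))$class,
               "homozygous")
})

test_that("phasing recovers the planted allele pair", {
  sp <- superpose_alleles("ACGTACGT", "ACGGTACGT")
  ph <- phase_alleles(sp$forward, sp$reverse)
  expect_setequal(c(ph$allele_a, ph$allele_b), c("ACGTACGT", "ACGGTACGT"))
  expect_equal(ph$offset_d, 1L)
  expect_equal(ph$indel_position, 3L)

  # d = 0 with a single mixed position reduces to two alleles one apart
  set.seed(9)
  a <- rand_seq(30)
  b <- substitute_bases(a, 15)
  sp0 <- superpose_alleles(a, b)
  ph0 <- phase_alleles(sp0$forward, sp0$reverse)
  expect_equal(ph0$offset_d, 0L)
  expect_setequal(c(ph0$allele_a, ph0$allele_b), c(a, b))

  # inconsistent mixtures are unphaseable, not silently resolved
  expect_error(phase_alleles("RRAAAAAAAA", revcomp("AAAAAAAAAA")),
               class = "spongeid_unphaseable_error")
})

test_that("phasing round-trips on random indel heterozygotes", {
  set.seed(17)
  for (i in 1:100) {
    la <- sample(50:70, 1)
    a <- rand_seq(la)
    d <- sample(1:3, 1)
    b <- insert_at(a, sample(10:(la - 10), 1), rand_seq(d))
    sp <- superpose_alleles(a, b)
    ph <- tryCatch(phase_alleles(sp$forward, sp$reverse),
                   error = function(e) e)
    # ambiguous instances are surfaced, never mis-phased
    if (inherits(ph, "spongeid_phase_ambiguity_error")) next
    expect_false(inherits(ph, "error"))
    sp2 <- superpose_alleles(ph$allele_a, ph$allele_b)
    expect_identical(sp2, sp)
    expect_setequal(c(ph$allele_a, ph$allele_b), c(a, b))
  }
})

test_that("phasing matches the brute-force oracle on small alleles", {
  set.seed(29)
  for (i in 1:60) {
    la <- sample(6:11, 1)
    a <- rand_seq(la)
    d <- sample(0:2, 1)
    b <- if (d == 0) substitute_bases(a, sample(la, 1))
         else insert_at(a, sample(2:(la - 2), 1), rand_seq(d))
    sp <- superpose_alleles(a, b)
    oracle <- bf_phase_solutions(sp$forward, sp$reverse)
    ds <- unique(vapply(oracle, function(s) s$d, numeric(1)))
    ph <- tryCatch(phase_alleles(sp$forward, sp$reverse),
                   error = function(e) e)
    if (length(ds) > 1) {
      expect_s3_class(ph, "spongeid_phase_ambiguity_error")
    } else {
      expect_false(inherits(ph, "error"), label = paste("case", i))
      # the chosen pair is the oracle's lexicographically smallest solution
      keys <- unname(sort(vapply(oracle, function(s) paste(s$a, s$b),
                                 character(1))))
      expect_equal(paste(ph$allele_a, ph$allele_b), keys[1])
    }
  }
})

test_that("consensus merges overlapping reads and flags disagreements", {
  s <- rand_seq(150)
  cons <- build_consensus(s, revcomp(s))
  expect_equal(cons$sequence, s)
  expect_equal(cons$pct_agreement, 100)

  # one disagreement in a 100-base overlap: union code, 99% agreement
  f <- strrep("A", 100)
  r_seq <- mutate_positions(strrep("A", 100), 50, to = "G")
  cons2 <- build_consensus(f, revcomp(r_seq))
  expect_equal(cons2$overlap_len, 100L)
  expect_equal(cons2$pct_agreement, 99)
  expect_equal(substr(cons2$sequence, 50, 50), "R")

  # a base resolves a compatible ambiguity to the more specific call
  f3 <- paste0(strrep("A", 30), "R", strrep("A", 30))
  r3 <- paste0(strrep("A", 30), "A", strrep("A", 30))
  cons3 <- build_consensus(f3, revcomp(r3))
  expect_false(grepl("R", cons3$sequence))

  expect_error(build_consensus(strrep("A", 60), strrep("C", 60)),
               class = "spongeid_consensus_error")
})

test_that("replicate deduplication keeps one concordant representative", {
  s <- rand_seq(300)
  recs <- tibble::tibble(id = c("c", "a", "b"), sequence = s)
  kept <- dedupe_replicates(recs)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$id, "a") # equal lengths: smallest id

  # high but imperfect identity: the longest replicate is representative
  set.seed(31)
  s2 <- rand_seq(600)
  r2 <- tibble::tibble(
    id = c("x", "y", "z"),
    sequence = c(s2, substitute_bases(s2, 10), paste0(s2, "AC")))
  kept2 <- dedupe_replicates(r2)
  expect_equal(kept2$id, "z")

  # divergent replicates are kept separate with a discordance warning
  r3 <- tibble::tibble(id = c("p", "q"),
                       sequence = c(s, substitute_bases(s, 1:60)))
  expect_warning(out <- dedupe_replicates(r3),
                 class = "spongeid_replicate_discordance")
  expect_equal(nrow(out), 2L)

  expect_error(dedupe_replicates(tibble::tibble(id = character(),
                                                sequence = character())),
               class = "spongeid_dedupe_error")
})
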