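make_tax <- function(acc, phylum = "Porifera", order = "Simorder",
                     family = "Simfamily", genus = "Simgenus",
                     species = NA) {
  tibble::tibble(accession = acc, phylum = phylum, order = order,
                 family = family, genus = genus, species = species)
}

test_that("reference databases index clean words and record total length", {
  th <- sip_thresholds(word_size = 4)
  seqs <- tibble::tibble(accession = c("A1", "A2", "A3"),
                         sequence = c("ACGTACG", "TTTTACGT", "GGGCCCAA"))
  db <- build_reference_db(seqs, make_tax(seqs$accession), "COI", th)
  # every clean 4-mer of every record is indexed
  for (i in seq_len(3)) {
    s <- seqs$sequence[i]
    for (j in 1:(nchar(s) - 3)) {
      w <- substr(s, j, j + 3)
      expect_true(i %in% db$index[[w]], info = w)
    }
  }
  expect_equal(db$m, sum(nchar(seqs$sequence)))

  expect_error(
    build_reference_db(tibble::tibble(accession = "X", sequence = "ACG"),
                       make_tax("X"), "COI", th),
    class = "spongeid_refdb_error")
  expect_error(
    build_reference_db(
      tibble::tibble(accession = c("A", "A"),
                     sequence = c("ACGTACGT", "ACGTACGT")),
      make_tax(c("A", "A")), "COI", th),
    class = "spongeid_refdb_error")
  expect_error(
    build_reference_db(tibble::tibble(accession = "B",
                                      sequence = "ACGTACGT"),
                       make_tax("C"), "COI", th),
    class = "spongeid_refdb_error")
  # a rank beneath an empty rank violates the lineage invariant
  bad_tax <- make_tax("D", family = NA, genus = "Genus")
  expect_error(
    build_reference_db(tibble::tibble(accession = "D",
                                      sequence = "ACGTACGT"),
                       bad_tax, "COI", th),
    class = "spongeid_lineage_error")
  # database length of a larger simulated set is the sum of lengths
  cfg <- simulation_config(seed = 4)
  ref <- simulate_reference_db(cfg, "COI")
  db2 <- build_reference_db(ref$sequences, ref$taxonomy, "COI")
  expect_equal(db2$m, sum(nchar(ref$sequences$sequence)))
})

test_that("bit scores follow the Karlin-Altschul transform", {
  lambda <- 0.625; K <- 0.41
  expect_equal(karlin_altschul_bits(200, lambda, K),
               (lambda * 200 - log(K)) / log(2), tolerance = 1e-12)
  expect_equal(round(karlin_altschul_bits(200, lambda, K), 1), 181.6)
  # zero of the formula at S = ln(K) / lambda
  expect_equal(karlin_altschul_bits(log(K) / lambda, lambda, K), 0)
  # strictly increasing in S
  s <- 1:50
  expect_true(all(diff(karlin_altschul_bits(s, lambda, K)) > 0))
  expect_error(karlin_altschul_bits(10, -1, K), class = "spongeid_ka_error")
  expect_error(karlin_altschul_bits(10, lambda, 0),
               class = "spongeid_ka_error")
})

test_that("identity queries hit their own reference at 100/100", {
  set.seed(41)
  seqs <- tibble::tibble(accession = sprintf("R%02d", 1:6),
                         sequence = replicate(6, rand_seq(300)))
  db <- build_reference_db(seqs, make_tax(seqs$accession), "COI")
  q <- seqs$sequence[3]
  hits <- local_search(q, db)
  expect_equal(hits$accession[1], "R03")
  expect_equal(hits$pct_identity[1], 100)
  expect_equal(hits$query_coverage_pct[1], 100)
  expect_equal(hits$bit_score[1],
               karlin_altschul_bits(2L * 300L))
  # E-value is strictly decreasing in bit score for fixed m, n
  if (nrow(hits) > 1) {
    expect_true(all(diff(hits$bit_score) <= 0))
    expect_true(all(diff(hits$evalue) >= 0))
  }
  # ~2 substitutions per 100 bases gives ~98% identity
  q2 <- substitute_bases(seqs$sequence[3], sample(20:280, 6))
  h2 <- local_search(q2, db)
  expect_equal(h2$accession[1], "R03")
  expect_equal(h2$pct_identity[1], 98, tolerance = 0.01)
  # no shared word, no hits; reverse-complement queries hit on minus strand
  expect_equal(nrow(local_search(strrep("AC", 20), db)), 0L)
  h3 <- local_search(revcomp(q), db)
  expect_equal(h3$accession[1], "R03")
  expect_equal(h3$strand[1], "-")
  expect_equal(h3$raw_score[1], hits$raw_score[1])
})

test_that("top-hit raw scores equal the full Smith-Waterman optimum", {
  set.seed(43)
  th <- sip_thresholds(word_size = 5)
  for (case in 1:20) {
    subs <- replicate(sample(3:8, 1),
                      rand_seq(sample(60:200, 1)))
    acc <- sprintf("S%02d", seq_along(subs))
    db <- build_reference_db(tibble::tibble(accession = acc,
                                            sequence = subs),
                             make_tax(acc), "COI", th)
    src <- sample(subs, 1)
    q <- substr(src, 1, sample(40:nchar(src), 1))
    q <- substitute_bases(q, sample(nchar(q), max(1, nchar(q) %/% 20)))
    if (runif(1) < 0.3) q <- revcomp(q)
    hits <- local_search(q, db, th)
    if (nrow(hits) == 0) next
    expect_equal(hits$raw_score[1], max(sw_score_oracle(q, subs)),
                 info = paste("case", case))
  }
})

test_that("hit sorting is total and repeated searches are identical", {
  set.seed(47)
  cfg <- simulation_config(seed = 6, n_orders = 2, species_per_genus = 2)
  ref <- simulate_reference_db(cfg, "ITS")
  db <- build_reference_db(ref$sequences, ref$taxonomy, "ITS")
  q <- substitute_bases(ref$sequences$sequence[2], sample(600, 12))
  h1 <- local_search(q, db)
  h2 <- local_search(q, db)
  expect_identical(h1, h2)
  expect_false(is.unsorted(-h1$bit_score))
})

test_that("phylum screen returns the top hit's phylum", {
  cfg <- simulation_config(seed = 8)
  ref <- simulate_reference_db(cfg, "COI")
  db <- build_reference_db(ref$sequences, ref$taxonomy, "COI")
  target <- ref$taxonomy$accession[ref$taxonomy$phylum == "Porifera"][1]
  decoy <- ref$taxonomy$accession[ref$taxonomy$phylum != "Porifera"][1]
  sq <- function(a) ref$sequences$sequence[ref$sequences$accession == a]
  set.seed(51)
  expect_equal(phylum_screen(substitute_bases(sq(target), 1:5), db),
               "Porifera")
  expect_equal(phylum_screen(substitute_bases(sq(decoy), 1:5), db),
               "Chordata")
  expect_true(is.na(phylum_screen(strrep("AC", 30), db)))
})

test_that("tabular hit files round-trip through write and parse", {
  set.seed(53)
  seqs <- tibble::tibble(accession = c("K1", "K2"),
                         sequence = replicate(2, rand_seq(250)))
  db <- build_reference_db(seqs, make_tax(c("K1", "K2")), "28S")
  q <- substitute_bases(seqs$sequence[1], sample(250, 5))
  hits <- local_search(q, db, query_id = "QX")
  qlens <- tibble::tibble(query_id = "QX", length = nchar(q))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tabular_hits(hits, path)
  back <- parse_tabular_hits(path, qlens)
  carried <- c("query_id", "accession", "bit_score", "evalue",
               "pct_identity", "query_coverage_pct", "qstart", "qend",
               "sstart", "send", "strand", "phylum", "order", "family",
               "genus", "species")
  expect_equal(as.data.frame(back[carried]),
               as.data.frame(hits[carried]), tolerance = 1e-12)

  # reversed query coordinates are normalized with a strand flag
  row <- paste(c("QX", "K9", "97.5", "100", "2", "0",
                 "120", "21", "5", "104", "1e-50", "180.3"),
               collapse = "\t")
  p2 <- withr::local_tempfile()
  writeLines(row, p2)
  h <- parse_tabular_hits(p2, qlens)
  expect_equal(h$strand, "-")
  expect_equal(h$qstart, 20L)
  expect_equal(h$qend, 120L)
  expect_equal(h$query_coverage_pct, 100 * 100 / nchar(q))

  # 13-column rows populate the lineage
  row13 <- paste(row, "Porifera;Suberitida;Suberitidae;Suberites;aurantiacus",
                 sep = "\t")
  writeLines(row13, p2)
  h13 <- parse_tabular_hits(p2, qlens)
  expect_equal(h13$genus, "Suberites")

  writeLines("too\tfew\tcolumns", p2)
  expect_error(parse_tabular_hits(p2, qlens), regexp = "line 1",
               class = "spongeid_tabular_error")
  writeLines(sub("^QX", "QZ", row), p2)
  expect_error(parse_tabular_hits(p2, qlens),
               class = "spongeid_tabular_error")
})
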