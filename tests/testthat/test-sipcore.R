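mk_hit <- function(accession, bit, evalue = 1e-50, pident = 98, cov = 96,
                   phylum = "Porifera", order = "Suberitida",
                   family = "Suberitidae", genus = "Suberites",
                   species = NA_character_, query_id = "Q") {
  tibble::tibble(query_id = query_id, accession = accession,
                 raw_score = NA_integer_, bit_score = bit, evalue = evalue,
                 pct_identity = pident, query_coverage_pct = cov,
                 qstart = 0L, qend = 100L, sstart = 0L, send = 100L,
                 strand = "+", phylum = phylum, order = order,
                 family = family, genus = genus, species = species)
}

mk_locus_result <- function(locus, bit, pident = 98, cov = 95,
                            genus = "Suberites", species = NA_character_,
                            valid = TRUE, reason = NA_character_) {
  tibble::tibble(specimen_id = "SP", locus = locus, valid = valid,
                 reason = reason, accession = paste0(locus, "-acc"),
                 bit_score = bit, evalue = NA_real_, pct_identity = pident,
                 query_coverage_pct = cov, phylum = "Porifera",
                 order = "Suberitida", family = "Suberitidae",
                 genus = genus, species = species,
                 warnings = list(character(0)))
}

test_that("locus selection filters coverage and breaks ties deterministically", {
  sel <- select_locus_hit(mk_hit("AC1", 500, cov = 96), locus = "COI")
  expect_true(sel$valid)
  expect_equal(sel$accession, "AC1")

  low <- dplyr::bind_rows(mk_hit("AC1", 500, cov = 30),
                          mk_hit("AC2", 400, cov = 49.9))
  sel_low <- select_locus_hit(low, locus = "COI")
  expect_false(sel_low$valid)
  expect_equal(sel_low$reason, "low_coverage")

  empty <- select_locus_hit(mk_hit("x", 1)[0, ], locus = "COI")
  expect_equal(empty$reason, "no_hits")

  # a low-coverage leader must not outrank a qualifying hit
  mixed <- sort_hits(dplyr::bind_rows(mk_hit("BIG", 900, cov = 20),
                                      mk_hit("OK", 500, cov = 80)))
  expect_equal(select_locus_hit(mixed, locus = "COI")$accession, "OK")

  # full tie on bit, evalue, identity and coverage: lower accession wins
  tie <- sort_hits(dplyr::bind_rows(mk_hit("ZZZ", 500), mk_hit("AAA", 500)))
  expect_equal(select_locus_hit(tie, locus = "COI")$accession, "AAA")
})

test_that("the top-20 scan warns but never alters the selection", {
  hits <- sort_hits(dplyr::bind_rows(
    mk_hit("H01", 800, genus = "Suberites"),
    mk_hit("H02", 790, genus = "Rhizaxinella"),
    mk_hit("H03", 780, genus = "Rhizaxinella"),
    mk_hit("H04", 770, genus = "Rhizaxinella",
           phylum = "Chordata", order = "DecoyOrder", family = "DecoyFam")))
  sel <- select_locus_hit(hits, locus = "COI")
  w <- sel$warnings[[1]]
  expect_length(w, 2L)
  expect_match(w[1], "phyla")
  expect_match(w[2], "dominates")
  # non-interference: selection identical to the warning-free prefix run
  sel_clean <- select_locus_hit(hits[1, ], locus = "COI")
  expect_equal(sel$accession, sel_clean$accession)
  expect_equal(sel$bit_score, sel_clean$bit_score)
  expect_equal(sel$genus, sel_clean$genus)
})

test_that("arbitration picks the highest bit score across loci", {
  # worked example: 28S bit 975 beats COI bit 608
  d1 <- arbitrate(sama_locus_results("SAMA S1981"), "SAMA S1981")
  expect_equal(d1$chosen_locus, "28S")
  expect_equal(d1$bit_score, 975)
  expect_equal(d1$genus, "Suberites")
  expect_equal(d1$species, "aurantiacus")

  # worked example: COI bit 1010 beats 28S bit 642
  d2 <- arbitrate(sama_locus_results("SAMA S1962"), "SAMA S1962")
  expect_equal(d2$chosen_locus, "COI")
  expect_equal(d2$bit_score, 1010)
  expect_equal(d2$species, "robusta")

  # a single valid locus is chosen regardless of its bit score
  only_its <- mk_locus_result("ITS", 120)
  d3 <- arbitrate(dplyr::bind_rows(
    only_its, mk_locus_result("COI", NA, valid = FALSE, reason = "short")))
  expect_equal(d3$chosen_locus, "ITS")
  expect_equal(d3$status, "identified")

  # no valid locus: unidentified with the dominant reason
  d4 <- arbitrate(dplyr::bind_rows(
    mk_locus_result("COI", NA, valid = FALSE, reason = "low_coverage"),
    mk_locus_result("28S", NA, valid = FALSE, reason = "low_coverage"),
    mk_locus_result("ITS", NA, valid = FALSE, reason = "short")))
  expect_equal(d4$status, "unidentified")
  expect_equal(d4$reason, "low_coverage")

  # exact bit ties: higher identity, then coverage, then COI > 28S > ITS
  t1 <- arbitrate(dplyr::bind_rows(mk_locus_result("ITS", 500, pident = 99),
                                   mk_locus_result("28S", 500, pident = 97)))
  expect_equal(t1$chosen_locus, "ITS")
  t2 <- arbitrate(dplyr::bind_rows(mk_locus_result("ITS", 500),
                                   mk_locus_result("28S", 500)))
  expect_equal(t2$chosen_locus, "28S")
})

test_that("arbitration satisfies the argmax and ablation properties", {
  set.seed(61)
  for (i in 1:50) {
    n <- sample(2:3, 1)
    loci <- sample(c("COI", "28S", "ITS"), n)
    res <- dplyr::bind_rows(lapply(loci, function(l) {
      mk_locus_result(l, bit = sample(200:1200, 1),
                      pident = sample(85:100, 1))
    }))
    d <- arbitrate(res)
    expect_equal(d$bit_score, max(res$bit_score))
    # removing a non-chosen locus never changes the decision
    others <- res[res$locus != d$chosen_locus, ]
    if (nrow(others) > 0) {
      drop_one <- res[res$locus != others$locus[1], ]
      expect_equal(arbitrate(drop_one)$chosen_locus, d$chosen_locus)
      # removing the chosen locus yields the runner-up
      runner <- arbitrate(others)
      expect_equal(runner$bit_score, max(others$bit_score))
    }
  }
})

test_that("lineage match level is the deepest shared rank", {
  full <- lineage("Porifera", "Suberitida", "Suberitidae", "Suberites",
                  "aurantiacus")
  expect_equal(lineage_match_level(full, full), "species")
  fam <- lineage("Porifera", "Suberitida", "Suberitidae", "Rhizaxinella")
  expect_equal(lineage_match_level(full, fam), "family")
  a <- lineage("Porifera", "Poecilosclerida", "Tedaniidae", "Tedania")
  b <- lineage("Porifera", "Poecilosclerida", "Desmacididae", "Desmapsamma")
  expect_equal(lineage_match_level(a, b), "order")
  expect_equal(lineage_match_level(a, lineage("Porifera", "Clionaida")),
               "none")
  expect_error(lineage_match_level(a, lineage("Porifera")),
               class = "spongeid_lineage_error")
  # symmetric; blanking a rank can only shallow the match
  set.seed(67)
  orders <- c("Suberitida", "Clionaida")
  for (i in 1:40) {
    l1 <- lineage("Porifera", sample(orders, 1), "FamA",
                  sample(c("G1", "G2"), 1), sample(c("s1", NA), 1))
    l2 <- lineage("Porifera", sample(orders, 1), "FamA",
                  sample(c("G1", "G2"), 1), sample(c("s1", NA), 1))
    m12 <- lineage_match_level(l1, l2)
    expect_equal(m12, lineage_match_level(l2, l1))
    blanked <- l1
    blanked[c("genus", "species")] <- NA
    depth <- function(x) match(x, c("none", "order", "family", "genus",
                                    "species"))
    expect_lte(depth(lineage_match_level(blanked, l2)), depth(m12))
  }
})

test_that("concordance summary counts any-two-loci agreement", {
  lin <- function(sp, locus, order, family = "Fam", genus = "Gen") {
    tibble::tibble(specimen_id = sp, locus = locus, phylum = "Porifera",
                   order = order, family = family, genus = genus,
                   species = NA_character_)
  }
  # planted: SP1 agrees at genus (2 loci), SP2 only at order, SP3 nowhere
  tbl <- dplyr::bind_rows(
    lin("SP1", "COI", "O1"), lin("SP1", "28S", "O1"),
    lin("SP2", "COI", "O2", family = "FamA", genus = "GenA"),
    lin("SP2", "ITS", "O2", family = "FamB", genus = "GenB"),
    lin("SP3", "COI", "O3"), lin("SP3", "28S", "O4",
                                 family = "FamX", genus = "GenX"))
  cs <- concordance_summary(tbl)
  expect_equal(cs$matches[cs$level == "genus"], 1L)
  expect_equal(cs$matches[cs$level == "order"], 2L)
  expect_equal(cs$fraction[cs$level == "order"], "2/3")
  expect_equal(cs$percent[cs$level == "order"], 67L)

  # all identical lineages: 100% everywhere
  same <- dplyr::bind_rows(lin("SP1", "COI", "O"), lin("SP1", "28S", "O"),
                           lin("SP2", "COI", "O"), lin("SP2", "ITS", "O"))
  cs2 <- concordance_summary(same)
  expect_true(all(cs2$percent == 100L))

  expect_error(concordance_summary(lin("SP1", "COI", "O1")),
               class = "spongeid_concordance_error")
})
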