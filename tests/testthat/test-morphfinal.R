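test_that("category assignment reproduces every published case-study row", {
  m <- sama_morphology()
  d <- sama_decisions()
  cats <- assign_category(m, d)
  # exact partition: one category per specimen
  expect_equal(nrow(cats), 34L)
  expect_true(all(cats$category %in% c("I", "II", "III", "IV", "V")))
  joined <- dplyr::inner_join(
    cats, dplyr::select(m, "specimen_id", "published_category"),
    by = "specimen_id")
  expect_equal(joined$category, joined$published_category)
  counts <- table(cats$category)
  expect_equal(as.integer(counts[c("I", "II", "III", "IV", "V")]),
               c(9L, 7L, 8L, 3L, 7L))
  # spot checks: genus agreement, revision, and order-level disagreement
  one <- function(id) cats$category[cats$specimen_id == id]
  expect_equal(one("SAMA S1962"), "I")
  expect_equal(one("SAMA S1985"), "V")
  expect_equal(one("SAMA S1961"), "IV")
  # revised specimens still carry their post-revision match level
  expect_equal(cats$match_level[cats$specimen_id == "SAMA S1985"], "genus")
  expect_error(assign_category(m[1, ], d[0, ]),
               class = "spongeid_category_error")
})

test_that("final identities follow the three reconciliation rules", {
  m <- sama_morphology()
  d <- sama_decisions()
  cats <- assign_category(m, d)
  fin <- finalize(cats, d, m)
  pick <- function(id) fin[fin$specimen_id == id, ]
  # genus match: molecular identity, rule 1
  expect_equal(pick("SAMA S1964")$source, "SIP")
  expect_equal(pick("SAMA S1964")$rule_fired, "1")
  # order match at 99% similarity: molecular identity via the 98% rule
  expect_equal(pick("SAMA S1963")$source, "SIP")
  expect_equal(pick("SAMA S1963")$rule_fired, "3a")
  # no order match at 93%: morphology stands
  expect_equal(pick("SAMA S1968")$source, "morphology")
  expect_equal(pick("SAMA S1968")$rule_fired, "3b")
  expect_equal(pick("SAMA S1968")$order, "Tetractinellida")
  # similar-morphology family/order match: molecular identity, rule 2
  expect_equal(pick("SAMA S1989")$rule_fired, "2")
  # an unidentified specimen falls back to morphology with a note
  d2 <- d
  d2$status[d2$specimen_id == "SAMA S1963"] <- "unidentified"
  fin2 <- finalize(cats, d2, m)
  row <- fin2[fin2$specimen_id == "SAMA S1963", ]
  expect_equal(row$source, "morphology")
  expect_equal(row$note, "no molecular identity")
})

test_that("raising similarity never flips a final identity away from SIP", {
  m <- sama_morphology()
  d <- sama_decisions()
  cats <- assign_category(m, d)
  rank_src <- function(fin) ifelse(fin$source == "SIP", 1L, 0L)
  base <- finalize(cats, d, m)
  for (bump in c(0, 2, 5, 10)) {
    d2 <- d
    d2$pct_identity <- pmin(100, d2$pct_identity + bump)
    fin2 <- finalize(cats, d2, m)
    expect_true(all(rank_src(fin2) >= rank_src(base)))
    base_bumped <- base # keep comparing against the unbumped run
  }
})

test_that("matching rates round half up and co-report the fraction", {
  expect_equal(matching_rate(17, 18), 94L)
  expect_equal(matching_rate(6, 18), 33L)
  expect_equal(matching_rate(0, 7), 0L)
  expect_equal(matching_rate(1, 200), 1L) # 0.5 rounds up
  for (t in 1:12) {
    for (msel in 0:t) {
      r <- matching_rate(msel, t)
      expect_gte(r, 0L); expect_lte(r, 100L)
      expect_equal(r == 100L, msel == t)
    }
  }
  expect_error(matching_rate(5, 0))
})

test_that("the matching-rate report reproduces planted cohorts", {
  lin_cols <- function(order, family, genus) {
    list(phylum = "Porifera", order = order, family = family, genus = genus,
         species = NA_character_)
  }
  lr_row <- function(sp, locus, order, family, genus, pid = 99) {
    tibble::tibble(specimen_id = sp, locus = locus, valid = TRUE,
                   pct_identity = pid, phylum = "Porifera", order = order,
                   family = family, genus = genus,
                   species = NA_character_)
  }
  morph_row <- function(sp, order, family, genus) {
    tibble::tibble(specimen_id = sp,
                   reexamined_phylum = "Porifera", reexamined_order = order,
                   reexamined_family = family, reexamined_genus = genus,
                   reexamined_species = NA_character_)
  }
  dec_row <- function(sp, locus, order, family, genus) {
    tibble::tibble(specimen_id = sp, status = "identified",
                   chosen_locus = locus, phylum = "Porifera", order = order,
                   family = family, genus = genus, species = NA_character_)
  }
  # single specimen, full agreement everywhere: 1/1 = 100 at all levels
  lr <- dplyr::bind_rows(lr_row("S1", "COI", "O", "F", "G"),
                         lr_row("S1", "28S", "O", "F", "G"))
  rep1 <- summarize_matching(lr, morph_row("S1", "O", "F", "G"),
                             dec_row("S1", "28S", "O", "F", "G"))
  expect_true(all(rep1$percent[rep1$total > 0] == 100L))
  expect_equal(
    rep1$fraction[rep1$comparison == "both_loci_vs_morphology" &
                    rep1$level == "genus"], "1/1")

  # planted disagreement: COI matches morphology at genus, 28S only at order
  lr2 <- dplyr::bind_rows(lr_row("S1", "COI", "O", "F", "G"),
                          lr_row("S1", "28S", "O", "F2", "G2"),
                          lr_row("S2", "COI", "O", "F", "G"),
                          lr_row("S2", "28S", "O", "F", "G"))
  morph2 <- dplyr::bind_rows(morph_row("S1", "O", "F", "G"),
                             morph_row("S2", "O", "F", "G"))
  dec2 <- dplyr::bind_rows(dec_row("S1", "COI", "O", "F", "G"),
                           dec_row("S2", "28S", "O", "F", "G"))
  rep2 <- summarize_matching(lr2, morph2, dec2)
  cell <- function(comp, lv, col) {
    rep2[[col]][rep2$comparison == comp & rep2$level == lv &
                  (rep2$group %in% c("COI+28S", "chosen", "pairs", "COI"))][1]
  }
  # both loci agree with morphology at genus only for S2
  expect_equal(cell("both_loci_vs_morphology", "genus", "matches"), 1L)
  expect_equal(cell("both_loci_vs_morphology", "order", "matches"), 2L)
  # the chosen locus matches morphology at genus for both specimens
  expect_equal(cell("inferring_locus_vs_morphology", "genus", "matches"), 2L)
  # any-two-loci agreement at genus holds only for S2
  expect_equal(cell("any_two_loci", "genus", "matches"), 1L)
  # single-locus (COI) vs morphology: both specimens match at genus
  expect_equal(cell("single_locus_vs_morphology", "genus", "matches"), 2L)
})
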