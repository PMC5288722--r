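# Reconciling molecular identities with re-examined morphology.
#
# Specimens are first partitioned into agreement categories:
#   I   re-examined morphology matches the molecular identity at genus level
#   II  family/order match where the taxa share highly similar morphology
#       (a curator-supplied judgement, e.g. families differing only in the
#       surface arrangement of spicules)
#   III family/order match without that similarity
#   IV  no match even at order level
#   V   the initial morphological identification was revised on
#       re-examination (any rank changed, including refinements)
# and the final identity then follows three rules: genus-level agreement or
# the similar-morphology judgement accepts the molecular identity; failing
# both, it is accepted only at >= 98% sequence similarity, otherwise the
# re-examined morphological identity stands.

.rank_cols <- function(prefix) paste0(prefix, "_", .LINEAGE_RANKS)

.pick_lineage <- function(row, prefix) {
  v <- vapply(.rank_cols(prefix), function(cn) {
    val <- row[[cn]]
    if (is.null(val)) NA_character_ else as.character(val)
  }, character(1))
  v <- .canon_text(v)
  names(v) <- .LINEAGE_RANKS
  v
}

# TRUE when the initial and re-examined lineages differ at any rank
# (set-vs-empty counts as a difference: a refinement is a revision)
.lineage_revised <- function(row) {
  a <- .pick_lineage(row, "initial")
  b <- .pick_lineage(row, "reexamined")
  any((is.na(a) != is.na(b)) |
        (!is.na(a) & !is.na(b) & tolower(a) != tolower(b)))
}

#' Assign morphology/molecular agreement categories
#'
#' Joins morphological records with molecular decisions by `specimen_id`
#' and assigns each specimen one of categories I-V (see the module notes
#' above). The match level between the re-examined morphological lineage
#' and the molecular lineage is reported for every specimen, including the
#' revised (category V) ones.
#'
#' @param morph A tibble with `specimen_id`, `initial_*` and `reexamined_*`
#'   lineage columns (`*` in phylum, order, family, genus, species) and a
#'   logical `similar_morphology` column.
#' @param decisions A decision tibble from [arbitrate()] (identified rows).
#' @return A tibble: `specimen_id`, `category` (`"I"`..`"V"`),
#'   `match_level`.
#' @export
assign_category <- function(morph, decisions) {
  df <- dplyr::inner_join(morph, decisions, by = "specimen_id")
  if (nrow(df) < nrow(morph)) {
    missing <- setdiff(morph$specimen_id, df$specimen_id)
    rlang::abort(sprintf("no molecular decision for specimen(s): %s",
                         paste(missing, collapse = ", ")),
                 class = "spongeid_category_error")
  }
  purrr::map_dfr(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    reex <- .pick_lineage(row, "reexamined")
    sip <- lineage(row$phylum, row$order, row$family, row$genus, row$species)
    lvl <- lineage_match_level(reex, sip)
    depth <- .match_depth(lvl)
    cat <- if (.lineage_revised(row)) {
      "V"
    } else if (depth >= .match_depth("genus")) {
      "I"
    } else if (depth >= .match_depth("family") ||
               depth >= .match_depth("order")) {
      if (isTRUE(row$similar_morphology)) "II" else "III"
    } else {
      "IV"
    }
    tibble::tibble(specimen_id = row$specimen_id, category = cat,
                   match_level = lvl)
  })
}

#' Final identity: molecular inference versus re-examined morphology
#'
#' Applies the three final-identification rules to each categorized
#' specimen: (1) a genus-level match accepts the molecular identity;
#' (2) a family/order match between taxa with highly similar morphology
#' accepts the molecular identity; (3) otherwise the molecular identity is
#' accepted only when its sequence similarity meets
#' `final_similarity_threshold_pct` (rule 3a), else the re-examined
#' morphological identity is final (rule 3b). Specimens without a molecular
#' identity fall to morphology under rule 3b.
#'
#' @param categories Output of [assign_category()].
#' @param decisions Decision tibble from [arbitrate()].
#' @param morph Morphology tibble (see [assign_category()]).
#' @param thresholds A [sip_thresholds()] object.
#' @return A tibble: `specimen_id`, `category`, `match_level`, `source`
#'   (`"SIP"` or `"morphology"`), `rule_fired` (`"1"`, `"2"`, `"3a"`,
#'   `"3b"`), `pct_identity`, and the final lineage ranks.
#' @export
finalize <- function(categories, decisions, morph,
                     thresholds = sip_thresholds()) {
  t <- thresholds
  df <- categories |>
    dplyr::inner_join(decisions, by = "specimen_id") |>
    dplyr::inner_join(morph, by = "specimen_id")
  purrr::map_dfr(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    depth <- .match_depth(row$match_level)
    unidentified <- !identical(row$status, "identified")
    if (unidentified) {
      source <- "morphology"; rule <- "3b"
    } else if (depth >= .match_depth("genus")) {
      source <- "SIP"; rule <- "1"
    } else if (depth >= .match_depth("order") &&
               isTRUE(row$similar_morphology)) {
      source <- "SIP"; rule <- "2"
    } else if (!is.na(row$pct_identity) &&
               row$pct_identity >= t$final_similarity_threshold_pct) {
      source <- "SIP"; rule <- "3a"
    } else {
      source <- "morphology"; rule <- "3b"
    }
    lin <- if (source == "SIP") {
      c(phylum = row$phylum, order = row$order, family = row$family,
        genus = row$genus, species = row$species)
    } else {
      .pick_lineage(row, "reexamined")
    }
    tibble::tibble(
      specimen_id = row$specimen_id, category = row$category,
      match_level = row$match_level, source = source, rule_fired = rule,
      pct_identity = row$pct_identity,
      note = if (unidentified) "no molecular identity" else NA_character_,
      phylum = lin[["phylum"]], order = lin[["order"]],
      family = lin[["family"]], genus = lin[["genus"]],
      species = lin[["species"]])
  })
}

#' Integer matching percentage, round half up
#'
#' `100 * matches / total` rounded half up to the nearest integer; reported
#' summaries always carry the exact `matches/total` fraction alongside
#' because printed percentages alone are ambiguous under mixed rounding
#' conventions.
#'
#' @param matches,total Non-negative counts, `matches <= total`,
#'   `total > 0`.
#' @return Integer percent in 0..100.
#' @export
#' @examples
#' matching_rate(17, 18) # 94
matching_rate <- function(matches, total) {
  stopifnot(total > 0, matches >= 0, matches <= total)
  as.integer(floor(100 * matches / total + 0.5))
}

# deepest level at which a locus lineage matches the re-examined morphology
.morph_match_depth <- function(locus_row, morph_row) {
  reex <- .pick_lineage(morph_row, "reexamined")
  .match_depth(lineage_match_level(locus_row, reex))
}

#' Matching-rate report across marker/morphology comparison classes
#'
#' Builds the standard comparison table of a multilocus identification
#' study: (a) specimens with both COI and 28S identities, both matching
#' the re-examined morphology; (b) the inferring (arbitration-chosen) locus
#' versus morphology over the same specimens; (c) any two loci matching
#' each other (specimens with two or more valid loci); (d) each single
#' locus versus morphology; (e) among the single-locus matches, the subset
#' whose similarity meets the 98% threshold. Counts, `matches/total`
#' fractions and round-half-up percentages are reported at the genus,
#' family and order levels.
#'
#' @param locus_results A tibble with `specimen_id`, `locus`, `valid`,
#'   lineage ranks and `pct_identity` (one row per specimen-locus).
#' @param morph Morphology tibble with `reexamined_*` lineage columns.
#' @param decisions Decision tibble from [arbitrate()].
#' @param thresholds A [sip_thresholds()] object.
#' @return A tibble: `comparison`, `group`, `level`, `matches`, `total`,
#'   `fraction`, `percent`.
#' @export
summarize_matching <- function(locus_results, morph, decisions,
                               thresholds = sip_thresholds()) {
  t <- thresholds
  lr <- dplyr::filter(locus_results, .data$valid)
  levels <- c("genus", "family", "order")
  morph_by_id <- split(morph, morph$specimen_id)
  depth_vs_morph <- function(rows) {
    vapply(seq_len(nrow(rows)), function(i) {
      m <- morph_by_id[[rows$specimen_id[i]]]
      if (is.null(m)) return(-1)
      .morph_match_depth(rows[i, ], m[1, ])
    }, numeric(1))
  }
  row_out <- function(comparison, group, lv, m, n) {
    tibble::tibble(comparison = comparison, group = group, level = lv,
                   matches = m, total = n,
                   fraction = if (n > 0) sprintf("%d/%d", m, n) else "-",
                   percent = if (n > 0) matching_rate(m, n) else NA_integer_)
  }
  out <- list()

  # (a, b) specimens with both COI and 28S
  both_ids <- intersect(lr$specimen_id[lr$locus == "COI"],
                        lr$specimen_id[lr$locus == "28S"])
  if (length(both_ids) > 0) {
    coi <- lr[lr$locus == "COI" & lr$specimen_id %in% both_ids, ]
    s28 <- lr[lr$locus == "28S" & lr$specimen_id %in% both_ids, ]
    coi <- coi[order(coi$specimen_id), ]; s28 <- s28[order(s28$specimen_id), ]
    d_coi <- depth_vs_morph(coi); d_28 <- depth_vs_morph(s28)
    d_both <- pmin(d_coi, d_28)
    dec <- decisions[match(sort(both_ids), decisions$specimen_id), ]
    d_inf <- depth_vs_morph(dec)
    for (lv in levels) {
      out[[length(out) + 1L]] <- row_out(
        "both_loci_vs_morphology", "COI+28S", lv,
        sum(d_both >= .match_depth(lv)), length(both_ids))
      out[[length(out) + 1L]] <- row_out(
        "inferring_locus_vs_morphology", "chosen", lv,
        sum(d_inf >= .match_depth(lv)), length(both_ids))
    }
  }

  # (c) any two loci matching each other
  multi <- lr |> dplyr::count(.data$specimen_id) |>
    dplyr::filter(.data$n >= 2L)
  if (nrow(multi) > 0) {
    conc <- concordance_summary(dplyr::semi_join(lr, multi,
                                                 by = "specimen_id"))
    for (i in seq_len(nrow(conc))) {
      out[[length(out) + 1L]] <- row_out(
        "any_two_loci", "pairs", conc$level[i], conc$matches[i],
        conc$total[i])
    }
  }

  # (d, e) single locus vs morphology, and its >= 98% similarity subset
  for (loc in .SIP_LOCI) {
    rows <- lr[lr$locus == loc, ]
    if (nrow(rows) == 0L) next
    d <- depth_vs_morph(rows)
    hi <- !is.na(rows$pct_identity) &
      rows$pct_identity >= t$final_similarity_threshold_pct
    for (lv in levels) {
      matched <- d >= .match_depth(lv)
      out[[length(out) + 1L]] <- row_out(
        "single_locus_vs_morphology", loc, lv, sum(matched), nrow(rows))
      out[[length(out) + 1L]] <- row_out(
        "high_similarity_subset", loc, lv, sum(matched & hi), sum(matched))
    }
  }
  dplyr::bind_rows(out)
}
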