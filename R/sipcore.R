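# Per-locus best-hit selection, cross-locus arbitration and multilocus
# concordance: the decision core of the identification protocol. The bit
# score is the arbitration statistic throughout because it is normalized
# with respect to the scoring system and therefore comparable across
# searches and across loci; E-values saturate at 0 for strong nucleotide
# hits and cannot discriminate them.

#' Build a lineage record
#'
#' @param phylum,order,family,genus,species Rank names (character or `NA`),
#'   filled from the highest rank down: a rank may not be set beneath an
#'   empty one.
#' @return A named character vector of the five ranks.
#' @export
lineage <- function(phylum = NA, order = NA, family = NA, genus = NA,
                    species = NA) {
  v <- .canon_text(c(phylum = phylum, order = order, family = family,
                     genus = genus, species = species))
  names(v) <- .LINEAGE_RANKS
  if (any(cumsum(is.na(v)) > 0 & !is.na(v))) {
    rlang::abort("a lineage rank may not be set beneath an empty rank",
                 class = "spongeid_lineage_error")
  }
  v
}

.as_lineage <- function(x) {
  if (is.data.frame(x)) x <- as.list(x[1, , drop = FALSE])
  v <- vapply(.LINEAGE_RANKS,
              function(r) {
                val <- if (is.list(x)) x[[r]] else unname(x[r])
                if (is.null(val) || length(val) == 0L) NA_character_
                else as.character(val)
              }, character(1))
  v <- .canon_text(v)
  names(v) <- .LINEAGE_RANKS
  v
}

#' Deepest taxonomic rank at which two lineages agree
#'
#' Compares two lineages rank by rank (case-insensitively, after whitespace
#' canonicalization) and returns the deepest rank at which both carry equal
#' non-empty values: one of `"species"`, `"genus"`, `"family"`, `"order"`,
#' or `"none"`. A rank missing on either side cannot match. Both lineages
#' must have their order set.
#'
#' @param a,b Lineages: named vectors from [lineage()], lists, or one-row
#'   data frames with rank columns.
#' @return A single string.
#' @export
#' @examples
#' lineage_match_level(
#'   lineage("Porifera", "Poecilosclerida", "Tedaniidae", "Tedania"),
#'   lineage("Porifera", "Poecilosclerida", "Desmacididae", "Desmapsamma"))
lineage_match_level <- function(a, b) {
  va <- .as_lineage(a); vb <- .as_lineage(b)
  if (is.na(va[["order"]]) || is.na(vb[["order"]])) {
    rlang::abort("both lineages must have their order set",
                 class = "spongeid_lineage_error")
  }
  for (r in rev(.LINEAGE_RANKS[-1])) { # species, genus, family, order
    x <- va[[r]]; y <- vb[[r]]
    if (!is.na(x) && !is.na(y) && tolower(x) == tolower(y)) return(r)
  }
  "none"
}

# rank depth helper: species deepest
.match_depth <- function(level) {
  match(level, c("none", "order", "family", "genus", "species")) - 1L
}

#' Select the identity hit for a single locus
#'
#' Drops hits under the minimum query coverage ("Coverage Region" rule),
#' then selects the best remaining hit by bit score with ties broken by
#' E-value, percent identity, coverage, then accession. The leading
#' `min(top_n_scan, n)` hits are scanned for anomalies -- more than one
#' phylum present, or a best-hit genus that occurs only once while another
#' genus dominates the list -- which are recorded as advisory warnings and
#' never change the selection.
#'
#' @param hits A hit tibble (as from [local_search()] or
#'   [parse_tabular_hits()]).
#' @param thresholds A [sip_thresholds()] object (`min_coverage_pct`,
#'   `top_n_scan`).
#' @param locus Locus label recorded in the result.
#' @return A one-row tibble: `locus`, `valid`, `reason` (`NA`, `no_hits` or
#'   `low_coverage`), `accession`, `bit_score`, `evalue`, `pct_identity`,
#'   `query_coverage_pct`, lineage ranks, and a `warnings` list-column.
#' @export
select_locus_hit <- function(hits, thresholds = sip_thresholds(),
                             locus = NA_character_) {
  t <- thresholds
  invalid <- function(reason) tibble::tibble(
    locus = locus, valid = FALSE, reason = reason,
    accession = NA_character_, bit_score = NA_real_, evalue = NA_real_,
    pct_identity = NA_real_, query_coverage_pct = NA_real_,
    phylum = NA_character_, order = NA_character_, family = NA_character_,
    genus = NA_character_, species = NA_character_,
    warnings = list(character(0)))
  if (nrow(hits) == 0L) return(invalid("no_hits"))
  kept <- dplyr::filter(hits, .data$query_coverage_pct >= t$min_coverage_pct)
  if (nrow(kept) == 0L) return(invalid("low_coverage"))
  kept <- dplyr::arrange(kept, dplyr::desc(.data$bit_score), .data$evalue,
                         dplyr::desc(.data$pct_identity),
                         dplyr::desc(.data$query_coverage_pct),
                         .data$accession)
  best <- kept[1, ]
  top <- kept[seq_len(min(t$top_n_scan, nrow(kept))), ]
  warnings <- character(0)
  phyla <- unique(stats::na.omit(top$phylum))
  if (length(phyla) > 1L) {
    warnings <- c(warnings, sprintf("multiple phyla in top %d hits: %s",
                                    nrow(top), paste(phyla, collapse = ", ")))
  }
  genera <- stats::na.omit(top$genus)
  if (!is.na(best$genus) && length(genera) > 1L) {
    counts <- table(genera)
    best_n <- counts[[best$genus]]
    others <- counts[names(counts) != best$genus]
    if (best_n == 1L && length(others) > 0 && max(others) >= 2L) {
      dom <- names(others)[which.max(others)]
      warnings <- c(warnings, sprintf(
        "best-hit genus '%s' occurs once in the top %d while '%s' dominates (%d hits)",
        best$genus, nrow(top), dom, max(others)))
    }
  }
  tibble::tibble(
    locus = locus, valid = TRUE, reason = NA_character_,
    accession = best$accession, bit_score = best$bit_score,
    evalue = best$evalue, pct_identity = best$pct_identity,
    query_coverage_pct = best$query_coverage_pct,
    phylum = best$phylum, order = best$order, family = best$family,
    genus = best$genus, species = best$species,
    warnings = list(warnings))
}

#' Arbitrate across loci: the highest bit score wins
#'
#' Given the per-locus selection results of one specimen, the valid locus
#' with the highest bit score provides the final molecular identity. Exact
#' bit ties are broken by higher percent identity, then higher coverage,
#' then locus priority `COI > 28S > ITS`. With no valid locus the specimen
#' is `unidentified`, carrying the dominant exclusion reason.
#'
#' @param locus_results A tibble of [select_locus_hit()] rows
#'   (0-3 loci of one specimen).
#' @param specimen_id Id recorded in the decision.
#' @return A one-row tibble: `specimen_id`, `status` (`identified` or
#'   `unidentified`), `reason`, `chosen_locus`, `bit_score`,
#'   `pct_identity`, `query_coverage_pct`, `accession`, lineage ranks.
#' @export
arbitrate <- function(locus_results, specimen_id = NA_character_) {
  valid <- dplyr::filter(locus_results, .data$valid)
  if (nrow(valid) == 0L) {
    reasons <- locus_results$reason
    reason <- if (length(reasons) == 0L) "no_data" else {
      tab <- sort(table(reasons), decreasing = TRUE)
      names(tab)[1]
    }
    return(tibble::tibble(
      specimen_id = specimen_id, status = "unidentified", reason = reason,
      chosen_locus = NA_character_, bit_score = NA_real_,
      pct_identity = NA_real_, query_coverage_pct = NA_real_,
      accession = NA_character_,
      phylum = NA_character_, order = NA_character_,
      family = NA_character_, genus = NA_character_,
      species = NA_character_))
  }
  valid <- valid |>
    dplyr::mutate(.prio = match(.data$locus, .SIP_LOCI)) |>
    dplyr::arrange(dplyr::desc(.data$bit_score),
                   dplyr::desc(.data$pct_identity),
                   dplyr::desc(.data$query_coverage_pct), .data$.prio)
  best <- valid[1, ]
  tibble::tibble(
    specimen_id = specimen_id, status = "identified", reason = NA_character_,
    chosen_locus = best$locus, bit_score = best$bit_score,
    pct_identity = best$pct_identity,
    query_coverage_pct = best$query_coverage_pct,
    accession = best$accession,
    phylum = best$phylum, order = best$order, family = best$family,
    genus = best$genus, species = best$species)
}

#' Multilocus concordance of per-locus identities
#'
#' For every specimen with at least two valid locus identities, checks
#' whether any two loci agree at the genus, family and order levels, and
#' summarises counts, `matches/total` fractions and integer percentages
#' (round half up).
#'
#' @param locus_lineages A tibble with columns `specimen_id`, `locus` and
#'   the lineage ranks (one row per valid specimen-locus identity).
#' @return A tibble with columns `level`, `matches`, `total`, `fraction`,
#'   `percent`.
#' @export
concordance_summary <- function(locus_lineages) {
  by_spec <- split(locus_lineages, locus_lineages$specimen_id)
  by_spec <- Filter(function(d) nrow(d) >= 2L, by_spec)
  if (length(by_spec) == 0L) {
    rlang::abort("need at least one specimen with two or more valid loci",
                 class = "spongeid_concordance_error")
  }
  levels <- c("genus", "family", "order")
  best_pair_depth <- vapply(by_spec, function(d) {
    pairs <- utils::combn(nrow(d), 2)
    max(apply(pairs, 2, function(ij) {
      .match_depth(lineage_match_level(d[ij[1], ], d[ij[2], ]))
    }))
  }, numeric(1))
  total <- length(by_spec)
  purrr::map_dfr(levels, function(lv) {
    m <- sum(best_pair_depth >= .match_depth(lv))
    tibble::tibble(level = lv, matches = m, total = total,
                   fraction = sprintf("%d/%d", m, total),
                   percent = matching_rate(m, total))
  })
}
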