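# End-to-end orchestration: qc -> phase -> consensus -> search -> select ->
# arbitrate -> finalize -> summarize. Stage failures abort only the
# affected specimen x locus, never the run; every exclusion is logged with
# its stage and a machine-readable reason.

#' Run the full multilocus identification pipeline
#'
#' Takes a read-pair table, per-locus reference databases and (optionally)
#' morphological records, and carries every specimen through trimming,
#' validity filtering, heterozygosity handling (consensus for homozygous /
#' point-heterozygous pairs, allele deconvolution for length-variant
#' heterozygotes), local similarity search, per-locus best-hit selection,
#' cross-locus arbitration, and -- when morphology is supplied --
#' categorization, final-identity rules and matching-rate summaries.
#'
#' @param pairs A tibble with `specimen_id`, `locus`, `forward_seq`,
#'   `reverse_seq` (see [load_read_pairs()]).
#' @param references Named list (by locus) of [build_reference_db()]
#'   objects, or of `list(sequences, taxonomy)` pairs to build them from.
#' @param morph Optional morphology tibble (see [assign_category()]).
#' @param thresholds A [sip_thresholds()] object.
#' @return An object of class `sip_run`: a list with tibbles `qc`,
#'   `locus_results`, `decisions`, `exclusions`, and (with morphology)
#'   `categories`, `finals`, `summary`.
#' @export
run_sip_pipeline <- function(pairs, references, morph = NULL,
                             thresholds = sip_thresholds()) {
  t <- thresholds
  dbs <- purrr::imap(references, function(ref, locus) {
    if (inherits(ref, "sip_reference_db")) ref
    else build_reference_db(ref$sequences, ref$taxonomy, locus, t)
  })
  if (nrow(pairs) == 0L) {
    return(structure(list(
      qc = tibble::tibble(), locus_results = tibble::tibble(),
      decisions = tibble::tibble(), exclusions = .empty_exclusions(),
      categories = NULL, finals = NULL, summary = NULL, thresholds = t),
      class = "sip_run"))
  }
  missing_db <- setdiff(unique(pairs$locus), names(dbs))
  if (length(missing_db) > 0) {
    rlang::abort(sprintf("no reference database for locus: %s",
                         paste(missing_db, collapse = ", ")),
                 class = "spongeid_pipeline_error")
  }
  screens <- purrr::map(dbs, function(db) {
    function(q) phylum_screen(q, db, t)
  })
  qc <- qc_read_pairs(pairs, screens, t)
  exclusions <- list()
  note_exclusion <- function(specimen, locus, stage, reason) {
    exclusions[[length(exclusions) + 1L]] <<- tibble::tibble(
      specimen_id = specimen, locus = locus, stage = stage, reason = reason)
  }
  locus_rows <- list()
  for (i in seq_len(nrow(qc))) {
    row <- qc[i, ]
    # heterozygosity is judged on the raw encoded reads: ambiguity trimming
    # would truncate the superposed tail that length-variant phasing needs
    cls <- classify_heterozygosity(row$forward_seq, row$reverse_seq, t)
    query <- NULL
    if (cls$class == "length_variant_het") {
      # validity on the untrimmed mixture reads (length + taxon screen)
      if (nchar(row$forward_seq) < t$min_valid_length ||
          nchar(row$reverse_seq) < t$min_valid_length) {
        note_exclusion(row$specimen_id, row$locus, "qc", "short")
        next
      }
      ph <- tryCatch(
        phase_alleles(row$forward_seq, row$reverse_seq, t),
        error = function(e) e)
      if (inherits(ph, "error")) {
        note_exclusion(row$specimen_id, row$locus, "phase", "unphaseable")
        next
      }
      screen <- phylum_screen(ph$allele_a, dbs[[row$locus]], t)
      if (is.na(screen) || !identical(screen, t$target_phylum)) {
        note_exclusion(row$specimen_id, row$locus, "qc", "non_target")
        next
      }
      query <- ph$allele_a
    } else {
      if (row$verdict != "valid") {
        note_exclusion(row$specimen_id, row$locus, "qc", row$reason)
        next
      }
      cons <- tryCatch(
        build_consensus(row$forward_trimmed, row$reverse_trimmed, t),
        error = function(e) e)
      if (inherits(cons, "error")) {
        note_exclusion(row$specimen_id, row$locus, "consensus",
                       "no_consensus")
        next
      }
      query <- cons$sequence
    }
    hits <- local_search(query, dbs[[row$locus]], t,
                         query_id = row$specimen_id)
    sel <- select_locus_hit(hits, t, locus = row$locus)
    sel$specimen_id <- row$specimen_id
    sel$het_class <- cls$class
    locus_rows[[length(locus_rows) + 1L]] <- sel
    if (!sel$valid) {
      note_exclusion(row$specimen_id, row$locus, "select", sel$reason)
    }
  }
  locus_results <- if (length(locus_rows)) dplyr::bind_rows(locus_rows)
                   else tibble::tibble()
  all_specimens <- unique(pairs$specimen_id)
  decisions <- purrr::map_dfr(all_specimens, function(sp) {
    lr <- if (nrow(locus_results))
      dplyr::filter(locus_results, .data$specimen_id == sp)
    else tibble::tibble()
    if (nrow(lr) == 0L) {
      ex <- dplyr::bind_rows(exclusions)
      reasons <- ex$reason[ex$specimen_id == sp]
      return(tibble::tibble(
        specimen_id = sp, status = "unidentified",
        reason = if (length(reasons)) names(sort(table(reasons),
                                                 decreasing = TRUE))[1]
                 else "no_data",
        chosen_locus = NA_character_, bit_score = NA_real_,
        pct_identity = NA_real_, query_coverage_pct = NA_real_,
        accession = NA_character_, phylum = NA_character_,
        order = NA_character_, family = NA_character_,
        genus = NA_character_, species = NA_character_))
    }
    arbitrate(lr, specimen_id = sp)
  })
  categories <- finals <- summary <- NULL
  if (!is.null(morph)) {
    identified <- dplyr::filter(decisions, .data$status == "identified")
    categorizable <- dplyr::semi_join(morph, identified, by = "specimen_id")
    if (nrow(categorizable) > 0) {
      categories <- assign_category(categorizable, identified)
      finals <- finalize(categories, identified, categorizable, t)
      valid_lr <- dplyr::filter(locus_results, .data$valid)
      summary <- summarize_matching(valid_lr, categorizable, identified, t)
    }
  }
  structure(list(
    qc = qc, locus_results = locus_results, decisions = decisions,
    exclusions = if (length(exclusions)) dplyr::bind_rows(exclusions)
                 else .empty_exclusions(),
    categories = categories, finals = finals, summary = summary,
    thresholds = t),
    class = "sip_run")
}

.empty_exclusions <- function() {
  tibble::tibble(specimen_id = character(), locus = character(),
                 stage = character(), reason = character())
}

#' @export
print.sip_run <- function(x, ...) {
  n_spec <- if (nrow(x$decisions)) length(unique(x$decisions$specimen_id))
            else 0L
  n_id <- if (nrow(x$decisions)) sum(x$decisions$status == "identified")
          else 0L
  cat(sprintf("<sip_run> %d specimens: %d identified, %d exclusions logged\n",
              n_spec, n_id, nrow(x$exclusions)))
  invisible(x)
}

#' Tidy the per-specimen decisions of a pipeline run
#'
#' @param x A `sip_run` object.
#' @param ... Unused.
#' @return The decision tibble (one row per specimen).
#' @exportS3Method generics::tidy
tidy.sip_run <- function(x, ...) x$decisions

#' One-row summary of a pipeline run
#'
#' @param x A `sip_run` object.
#' @param ... Unused.
#' @return A one-row tibble: specimens, identified, unidentified,
#'   exclusions, loci searched.
#' @exportS3Method generics::glance
glance.sip_run <- function(x, ...) {
  tibble::tibble(
    n_specimens = if (nrow(x$decisions))
      length(unique(x$decisions$specimen_id)) else 0L,
    n_identified = if (nrow(x$decisions))
      sum(x$decisions$status == "identified") else 0L,
    n_unidentified = if (nrow(x$decisions))
      sum(x$decisions$status != "identified") else 0L,
    n_exclusions = nrow(x$exclusions),
    n_locus_results = if (is.null(x$locus_results)) 0L
                      else nrow(x$locus_results))
}

#' Plot per-locus bit scores of a pipeline run
#'
#' Bars of the selected bit score per specimen and locus, with the
#' arbitration-chosen locus highlighted; the cross-locus winner is simply
#' the tallest bar of each specimen.
#'
#' @param object A `sip_run` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.sip_run <- function(object, ...) {
  lr <- dplyr::filter(object$locus_results, .data$valid)
  if (nrow(lr) == 0L) {
    rlang::abort("no valid locus results to plot",
                 class = "spongeid_plot_error")
  }
  chosen <- object$decisions |>
    dplyr::filter(.data$status == "identified") |>
    dplyr::select("specimen_id", "chosen_locus")
  lr <- lr |>
    dplyr::left_join(chosen, by = "specimen_id") |>
    dplyr::mutate(chosen = .data$locus == .data$chosen_locus)
  ggplot2::ggplot(lr, ggplot2::aes(x = .data$specimen_id,
                                   y = .data$bit_score,
                                   fill = .data$locus,
                                   alpha = .data$chosen)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.4),
                                guide = "none") +
    ggplot2::labs(x = NULL, y = "bit score", fill = "locus",
                  title = "Per-locus bit scores (chosen locus opaque)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60,
                                                       hjust = 1))
}

#' Plot a matching-rate summary
#'
#' @param summary A tibble from [summarize_matching()] or
#'   [concordance_summary()].
#' @return A ggplot object.
#' @export
plot_matching_rates <- function(summary) {
  if (!"comparison" %in% names(summary)) summary$comparison <- "concordance"
  if (!"group" %in% names(summary)) summary$group <- ""
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = factor(.data$level,
                                          c("genus", "family", "order")),
                               y = .data$percent,
                               fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(ggplot2::vars(.data$comparison)) +
    ggplot2::labs(x = "taxonomic level", y = "matching rate (%)",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
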