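#' Load paired forward/reverse Sanger reads from FASTA plus a manifest
#'
#' Reads a multi-record FASTA and a tab-separated manifest mapping each FASTA
#' record id to its specimen, locus and read direction, and assembles one row
#' per specimen-locus read pair. Sequences are upper-cased and `U` is mapped
#' to `T`; any character outside the IUPAC nucleotide alphabet is an error.
#'
#' @param fasta Path to a FASTA file (wrapped or unwrapped records).
#' @param manifest Path to a TSV with columns `record_id`, `specimen_id`,
#'   `locus` (one of `COI`, `28S`, `ITS`) and `direction` (`F` or `R`), or a
#'   data frame with those columns.
#' @return A tibble with columns `specimen_id`, `locus`, `forward_seq`,
#'   `reverse_seq`.
#' @export
load_read_pairs <- function(fasta, manifest) {
  # read as raw strings: the IUPAC validation below gives positional
  # errors instead of silently dropping unexpected letters, and RNA-style
  # U is mapped to T first
  seqs <- Biostrings::readBStringSet(fasta)
  recs <- tibble::tibble(
    record_id = names(seqs),
    seq = unname(toupper(chartr("Uu", "Tt", as.character(seqs))))
  )
  # validate alphabet with positional error messages
  purrr::walk2(recs$seq, recs$record_id, function(s, id) {
    tryCatch(seq_to_masks(s), error = function(e) {
      rlang::abort(sprintf("record '%s': %s", id, conditionMessage(e)),
                   class = "spongeid_alphabet_error")
    })
  })
  if (is.character(manifest)) {
    manifest <- readr::read_tsv(manifest, show_col_types = FALSE,
                                progress = FALSE)
  }
  manifest <- tibble::as_tibble(manifest)
  needed <- c("record_id", "specimen_id", "locus", "direction")
  if (!all(needed %in% names(manifest))) {
    rlang::abort(paste("manifest must have columns:",
                       paste(needed, collapse = ", ")),
                 class = "spongeid_manifest_error")
  }
  missing <- setdiff(recs$record_id, manifest$record_id)
  if (length(missing) > 0) {
    rlang::abort(sprintf("FASTA records absent from manifest: %s",
                         paste(missing, collapse = ", ")),
                 class = "spongeid_manifest_error")
  }
  df <- dplyr::inner_join(recs, manifest, by = "record_id")
  if (!all(df$direction %in% c("F", "R"))) {
    rlang::abort("manifest direction must be 'F' or 'R'",
                 class = "spongeid_manifest_error")
  }
  wide <- df |>
    dplyr::group_by(.data$specimen_id, .data$locus) |>
    dplyr::summarise(
      n_fwd = sum(.data$direction == "F"),
      n_rev = sum(.data$direction == "R"),
      forward_seq = if (any(.data$direction == "F"))
        .data$seq[.data$direction == "F"][1] else NA_character_,
      reverse_seq = if (any(.data$direction == "R"))
        .data$seq[.data$direction == "R"][1] else NA_character_,
      .groups = "drop"
    )
  bad <- dplyr::filter(wide, .data$n_fwd != 1L | .data$n_rev != 1L)
  if (nrow(bad) > 0) {
    b <- bad[1, ]
    side <- if (b$n_fwd == 0L) "forward" else if (b$n_rev == 0L) "reverse"
            else "duplicate"
    rlang::abort(sprintf(
      "specimen '%s' locus '%s': missing or duplicated mate (%s); each specimen x locus needs exactly one F and one R record",
      b$specimen_id, b$locus, side),
      class = "spongeid_orphan_error")
  }
  dplyr::select(wide, "specimen_id", "locus", "forward_seq", "reverse_seq")
}

#' Trim a Sanger read by windowed ambiguity content
#'
#' Implements the two-sided trimming rule used for direct Sanger reads:
#' the 5' trim advances to the first position whose `qc_window`-base window
#' contains no ambiguity (any non-ACGT character), but never beyond
#' `floor(max_5prime_trim_fraction * length)`; the 3' scan then starts
#' `three_prime_scan_offset` bases after the 5' trim and cuts at the start
#' of the first window containing more than `three_prime_ambiguity_limit`
#' ambiguities. Windows truncated by the end of the read are evaluated over
#' the available bases with unscaled thresholds.
#'
#' @param seq A single IUPAC nucleotide string.
#' @param thresholds A [sip_thresholds()] object.
#' @return A list with `start` (0-based inclusive) and `end` (0-based
#'   exclusive); the kept read is `substr(seq, start + 1, end)`. The window
#'   may be empty when the 5' cap forces the start past a dirty region.
#' @export
#' @examples
#' trim_read(strrep("A", 400)) # clean read: list(start = 0, end = 400)
trim_read <- function(seq, thresholds = sip_thresholds()) {
  t <- thresholds
  masks <- seq_to_masks(seq)
  n <- length(masks)
  stopifnot(n >= 1L)
  amb <- as.integer(.mask_is_ambiguous(masks))
  # cumulative ambiguity counts; window [i, i+w) count via prefix sums
  cs <- c(0L, cumsum(amb))
  win_count <- function(i0) { # i0 0-based window start
    hi <- min(n, i0 + t$qc_window)
    cs[hi + 1L] - cs[i0 + 1L]
  }
  cap <- floor(t$max_5prime_trim_fraction * n)
  start <- cap
  for (i in 0:cap) {
    if (i == n) break
    if (win_count(i) <= t$max_ambiguities_5prime) { start <- i; break }
  }
  start <- min(start, n)
  scan_from <- start + t$three_prime_scan_offset
  end <- n
  if (scan_from < n) {
    for (i in scan_from:(n - 1L)) {
      if (win_count(i) > t$three_prime_ambiguity_limit) { end <- i; break }
    }
  }
  list(start = as.integer(start), end = as.integer(max(end, start)))
}

#' Trim every read of a pair table
#'
#' Applies [trim_read()] to the forward and reverse read of each pair (each
#' in its own reading orientation) and appends the trim coordinates and the
#' trimmed sequences.
#'
#' @param pairs A tibble as returned by [load_read_pairs()].
#' @param thresholds A [sip_thresholds()] object.
#' @return `pairs` with added columns `fwd_trim_start`, `fwd_trim_end`,
#'   `rev_trim_start`, `rev_trim_end`, `forward_trimmed`, `reverse_trimmed`.
#' @export
trim_read_pairs <- function(pairs, thresholds = sip_thresholds()) {
  tf <- purrr::map(pairs$forward_seq, trim_read, thresholds = thresholds)
  tr <- purrr::map(pairs$reverse_seq, trim_read, thresholds = thresholds)
  pairs |>
    dplyr::mutate(
      fwd_trim_start = purrr::map_int(tf, "start"),
      fwd_trim_end = purrr::map_int(tf, "end"),
      rev_trim_start = purrr::map_int(tr, "start"),
      rev_trim_end = purrr::map_int(tr, "end"),
      forward_trimmed = substr(.data$forward_seq, .data$fwd_trim_start + 1L,
                               .data$fwd_trim_end),
      reverse_trimmed = substr(.data$reverse_seq, .data$rev_trim_start + 1L,
                               .data$rev_trim_end)
    )
}

#' Validity filter for a trimmed read pair
#'
#' A pair is excluded when either trimmed read is shorter than
#' `min_valid_length` (reason `"short"`), or when either read's best-hit
#' phylum differs from the expected target phylum (reason `"non_target"`);
#' otherwise it is valid. The short-length check runs first. A failure
#' inside the taxon screen itself propagates as an error, distinct from an
#' exclusion verdict.
#'
#' @param forward_trimmed,reverse_trimmed Trimmed read sequences.
#' @param taxon_screen Function mapping a sequence to its best-hit phylum
#'   (or `NA` when there are no hits); see [phylum_screen()].
#' @param thresholds A [sip_thresholds()] object.
#' @return A list with `verdict` (`"valid"` or `"excluded"`) and `reason`
#'   (`NA`, `"short"` or `"non_target"`).
#' @export
validity_filter <- function(forward_trimmed, reverse_trimmed, taxon_screen,
                            thresholds = sip_thresholds()) {
  t <- thresholds
  if (nchar(forward_trimmed) < t$min_valid_length ||
      nchar(reverse_trimmed) < t$min_valid_length) {
    return(list(verdict = "excluded", reason = "short"))
  }
  screen_one <- function(s) {
    ph <- tryCatch(taxon_screen(s), error = function(e) {
      rlang::abort(paste("taxon screen failed:", conditionMessage(e)),
                   class = "spongeid_screen_error")
    })
    ph
  }
  for (s in c(forward_trimmed, reverse_trimmed)) {
    ph <- screen_one(s)
    if (is.na(ph) || !identical(ph, t$target_phylum)) {
      return(list(verdict = "excluded", reason = "non_target"))
    }
  }
  list(verdict = "valid", reason = NA_character_)
}

#' QC a cohort of read pairs: trim, screen and filter
#'
#' Convenience wrapper chaining [trim_read_pairs()] and [validity_filter()]
#' over a pair table, producing the QC report used by the pipeline.
#'
#' @param pairs A tibble as returned by [load_read_pairs()].
#' @param taxon_screen Function mapping a sequence to its best-hit phylum,
#'   or a named list of such functions keyed by locus.
#' @param thresholds A [sip_thresholds()] object.
#' @return The trimmed pair table with `verdict` and `reason` columns.
#' @export
qc_read_pairs <- function(pairs, taxon_screen,
                          thresholds = sip_thresholds()) {
  trimmed <- trim_read_pairs(pairs, thresholds)
  pick_screen <- function(locus) {
    if (is.function(taxon_screen)) return(taxon_screen)
    fn <- taxon_screen[[locus]]
    if (is.null(fn)) {
      rlang::abort(sprintf("no taxon screen supplied for locus '%s'", locus),
                   class = "spongeid_screen_error")
    }
    fn
  }
  res <- purrr::pmap(
    list(trimmed$forward_trimmed, trimmed$reverse_trimmed, trimmed$locus),
    function(f, r, loc) validity_filter(f, r, pick_screen(loc), thresholds)
  )
  trimmed |>
    dplyr::mutate(
      verdict = purrr::map_chr(res, "verdict"),
      reason = purrr::map_chr(res, "reason")
    )
}
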