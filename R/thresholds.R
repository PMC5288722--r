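#' Pipeline thresholds and scoring parameters
#'
#' Bundle of every tunable cut-off used across QC, phasing, search and final
#' identification. Defaults reproduce the protocol's published settings:
#' a 5' trim capped at 25% of the read that advances until the first 50-base
#' window holds zero ambiguities; a 3' scan starting 100 bases after the 5'
#' trim that cuts at the first 50-base window holding two or more ambiguities;
#' exclusion of trimmed reads under 200 bp or of non-target phyla; hits under
#' 50% query coverage dropped; a top-20 hit sanity scan; replicate
#' deduplication at >99% identity; and the 98% similarity rule for accepting
#' a molecular identity over a conflicting morphological one.
#'
#' @param max_5prime_trim_fraction Cap on the 5' trim as a fraction of read
#'   length (default 0.25).
#' @param qc_window Window width in bases for both trim scans (default 50).
#' @param max_ambiguities_5prime Maximum ambiguities tolerated in the 5'
#'   window ("less than 1", i.e. 0).
#' @param three_prime_scan_offset Bases after the 5' trim at which the 3'
#'   scan starts (default 100).
#' @param three_prime_ambiguity_limit The 3' window must contain more than
#'   this many ambiguities to trigger a cut (default 1, i.e. cut at >= 2).
#' @param min_valid_length Minimum trimmed read length in bp (default 200).
#' @param min_coverage_pct Minimum query coverage % for a usable hit
#'   (default 50).
#' @param final_similarity_threshold_pct Similarity % at or above which a
#'   molecular identity overrides a conflicting morphological one
#'   (default 98).
#' @param classify_similarity_note_pct Similarity % used when summarising
#'   how many specimens are classifiable (default 90).
#' @param top_n_scan Number of leading hits examined by the advisory sanity
#'   scan (default 20).
#' @param duplicate_identity_pct Pairwise identity % above which replicate
#'   consensus sequences are treated as duplicates (default 99).
#' @param ka_lambda,ka_K Karlin-Altschul parameters of the scoring system
#'   (defaults 0.625 and 0.41, the standard values for +2/-3 nucleotide
#'   scoring).
#' @param match,mismatch Alignment match/mismatch scores (defaults +2 / -3).
#' @param gap_open,gap_extend Affine gap penalties, given as positive costs;
#'   a gap of length L costs `gap_open + gap_extend * L` (defaults 5 and 2).
#' @param word_size Seed word length for the local search index (default 11).
#' @param min_overlap Minimum forward/reverse overlap in bases for a
#'   consensus (default 20).
#' @param min_agreement_pct Minimum % agreement in the overlap for a
#'   consensus (default 90).
#' @param point_het_max Maximum number of isolated mixed bases still called
#'   a point heterozygote (default 1).
#' @param run_min Minimum number of mixed positions for the length-variant
#'   superposition signature (default 5).
#' @param tail_window Distance (bases) from the 3' end within which the last
#'   mixed position must fall for the length-variant signature (default 10).
#' @param max_offset Largest allele length difference |d| tried during
#'   phasing (default 10).
#' @param target_phylum Expected phylum for the validity screen
#'   (default "Porifera").
#'
#' @return A named list with class `sip_thresholds`.
#' @export
#' @examples
#' t <- sip_thresholds()
#' t$min_valid_length
sip_thresholds <- function(max_5prime_trim_fraction = 0.25,
                           qc_window = 50L,
                           max_ambiguities_5prime = 0L,
                           three_prime_scan_offset = 100L,
                           three_prime_ambiguity_limit = 1L,
                           min_valid_length = 200L,
                           min_coverage_pct = 50,
                           final_similarity_threshold_pct = 98,
                           classify_similarity_note_pct = 90,
                           top_n_scan = 20L,
                           duplicate_identity_pct = 99,
                           ka_lambda = 0.625,
                           ka_K = 0.41,
                           match = 2L,
                           mismatch = -3L,
                           gap_open = 5L,
                           gap_extend = 2L,
                           word_size = 11L,
                           min_overlap = 20L,
                           min_agreement_pct = 90,
                           point_het_max = 1L,
                           run_min = 5L,
                           tail_window = 10L,
                           max_offset = 10L,
                           target_phylum = "Porifera") {
  t <- list(
    max_5prime_trim_fraction = max_5prime_trim_fraction,
    qc_window = as.integer(qc_window),
    max_ambiguities_5prime = as.integer(max_ambiguities_5prime),
    three_prime_scan_offset = as.integer(three_prime_scan_offset),
    three_prime_ambiguity_limit = as.integer(three_prime_ambiguity_limit),
    min_valid_length = as.integer(min_valid_length),
    min_coverage_pct = min_coverage_pct,
    final_similarity_threshold_pct = final_similarity_threshold_pct,
    classify_similarity_note_pct = classify_similarity_note_pct,
    top_n_scan = as.integer(top_n_scan),
    duplicate_identity_pct = duplicate_identity_pct,
    ka_lambda = ka_lambda,
    ka_K = ka_K,
    match = as.integer(match),
    mismatch = as.integer(mismatch),
    gap_open = as.integer(gap_open),
    gap_extend = as.integer(gap_extend),
    word_size = as.integer(word_size),
    min_overlap = as.integer(min_overlap),
    min_agreement_pct = min_agreement_pct,
    point_het_max = as.integer(point_het_max),
    run_min = as.integer(run_min),
    tail_window = as.integer(tail_window),
    max_offset = as.integer(max_offset),
    target_phylum = target_phylum
  )
  stopifnot(
    t$max_5prime_trim_fraction > 0, t$max_5prime_trim_fraction <= 1,
    t$qc_window > 0L, t$max_ambiguities_5prime >= 0L,
    t$three_prime_scan_offset >= 0L, t$three_prime_ambiguity_limit >= 0L,
    t$min_valid_length > 0L,
    t$min_coverage_pct > 0, t$min_coverage_pct <= 100,
    t$final_similarity_threshold_pct > 0,
    t$final_similarity_threshold_pct <= 100,
    t$top_n_scan > 0L, t$duplicate_identity_pct > 0,
    t$ka_lambda > 0, t$ka_K > 0, t$ka_K <= 1,
    t$word_size > 0L, t$run_min > 0L, t$max_offset >= 0L
  )
  structure(t, class = "sip_thresholds")
}

#' @export
print.sip_thresholds <- function(x, ...) {
  cat("<sip_thresholds>\n")
  for (nm in names(x)) cat(sprintf("  %-32s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

# loci in arbitration-priority order (used for cross-locus tie-breaks)
.SIP_LOCI <- c("COI", "28S", "ITS")
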