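# IUPAC nucleotide codes handled as 4-bit masks: A=1, C=2, G=4, T=8.
# A mask is "ambiguous" when it encodes more than one base; '-' is never a
# legal input character (gaps are an error upstream, not an ambiguity).

.IUPAC_CHARS <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  R = 5L,  # A/G
  Y = 10L, # C/T
  S = 6L,  # C/G
  W = 9L,  # A/T
  K = 12L, # G/T
  M = 3L,  # A/C
  B = 14L, D = 13L, H = 11L, V = 7L,
  N = 15L
)

.MASK_TO_CHAR <- {
  x <- character(15)
  x[.IUPAC_CHARS] <- names(.IUPAC_CHARS)
  x
}

#' Convert an IUPAC nucleotide string to a vector of base-set bit masks
#'
#' Each character becomes an integer mask over \{A=1, C=2, G=4, T=8\};
#' e.g. `R` (A/G) maps to 5. Lowercase input is accepted and `U` is read
#' as `T`. Used internally by every sequence operation; exported because
#' test fixtures and extensions need the same encoding.
#'
#' @param seq A single IUPAC nucleotide string.
#' @return Integer vector of masks, one per base.
#' @seealso [masks_to_seq()], [revcomp()]
#' @export
#' @examples
#' seq_to_masks("ACGRN")
seq_to_masks <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L, !is.na(seq))
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  chars[chars == "U"] <- "T"
  masks <- unname(.IUPAC_CHARS[chars])
  if (anyNA(masks)) {
    bad <- which(is.na(masks))[1]
    rlang::abort(
      sprintf("non-IUPAC character '%s' at position %d", chars[bad], bad),
      class = "spongeid_alphabet_error"
    )
  }
  masks
}

#' Convert a vector of base-set bit masks back to an IUPAC string
#'
#' Inverse of [seq_to_masks()].
#'
#' @param masks Integer vector of masks in 1..15.
#' @return A single IUPAC nucleotide string.
#' @export
masks_to_seq <- function(masks) {
  stopifnot(all(masks >= 1L & masks <= 15L))
  paste(.MASK_TO_CHAR[masks], collapse = "")
}

# complement of a mask: reverse the A<->T, C<->G bits
.comp_mask <- function(m) {
  ((m %% 2L) * 8L) +            # A -> T
    (bitwAnd(m, 2L) * 2L) +     # C -> G
    (bitwAnd(m, 4L) %/% 2L) +   # G -> C
    (bitwAnd(m, 8L) %/% 8L)     # T -> A
}

#' Reverse-complement an IUPAC nucleotide string
#'
#' Ambiguity codes are complemented set-wise (`R` -> `Y`, `K` -> `M`,
#' `N` -> `N`, ...).
#'
#' @param seq A single IUPAC nucleotide string.
#' @return The reverse complement as a string.
#' @export
#' @examples
#' revcomp("ACGR") # "YCGT"
revcomp <- function(seq) {
  if (nchar(seq) == 0L) return(seq)
  masks_to_seq(rev(.comp_mask(seq_to_masks(seq))))
}

#' Count base-call ambiguities in a sequence
#'
#' An ambiguity is any character outside `A`, `C`, `G`, `T` (the definition
#' used by the trimming rules). Gap characters are rejected, not counted.
#'
#' @param seq A single IUPAC nucleotide string.
#' @return Integer count of ambiguous positions.
#' @export
count_ambiguities <- function(seq) {
  if (nchar(seq) == 0L) return(0L)
  sum(.mask_is_ambiguous(seq_to_masks(seq)))
}

.mask_is_ambiguous <- function(masks) {
  !(masks %in% c(1L, 2L, 4L, 8L))
}

# number of bases in each mask's set
.mask_size <- function(m) {
  (m %% 2L) + (bitwAnd(m, 2L) %/% 2L) + (bitwAnd(m, 4L) %/% 4L) +
    (bitwAnd(m, 8L) %/% 8L)
}

#' Encode secondary sequencing peaks as IUPAC mixed-base codes
#'
#' Positions flagged as carrying a secondary peak are rewritten to the
#' two-base IUPAC code of \{primary base, secondary base\}; all other
#' positions are returned unchanged. This is how double peaks in a Sanger
#' trace are represented once chromatograms have been base-called.
#'
#' @param seq A single nucleotide string (the primary base calls).
#' @param secondary Character vector the same length as `seq` (or a named
#'   subset via `positions`): the secondary base observed at each flagged
#'   position, `NA` where there is no secondary peak.
#' @return The IUPAC-encoded string.
#' @export
#' @examples
#' encode_mixed_bases("ACGT", c("G", NA, NA, NA)) # "RCGT"
encode_mixed_bases <- function(seq, secondary) {
  masks <- seq_to_masks(seq)
  if (length(secondary) != length(masks)) {
    rlang::abort("secondary-peak vector length must equal sequence length",
                 class = "spongeid_peak_error")
  }
  flagged <- which(!is.na(secondary))
  for (i in flagged) {
    sec <- .IUPAC_CHARS[[toupper(secondary[i])]]
    if (is.null(sec)) {
      rlang::abort(sprintf("invalid secondary base '%s' at position %d",
                           secondary[i], i),
                   class = "spongeid_peak_error")
    }
    if (bitwAnd(masks[i], sec) == sec && .mask_size(sec) == 1L &&
        masks[i] == sec) {
      rlang::abort(sprintf(
        "secondary base at position %d equals the primary call (not a mixture)", i),
        class = "spongeid_peak_error")
    }
    masks[i] <- bitwOr(masks[i], sec)
  }
  masks_to_seq(masks)
}
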