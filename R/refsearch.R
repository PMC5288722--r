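# Taxonomy-annotated reference database and local similarity search.
#
# The search emulates a nucleotide BLAST workflow self-containedly: exact
# word seeding selects candidate subjects, each candidate is then aligned
# with an exact affine-gap local alignment (both query strands), and raw
# scores are converted to bit scores and E-values with the Karlin-Altschul
# parameters of the scoring system.

.LINEAGE_RANKS <- c("phylum", "order", "family", "genus", "species")

.canon_text <- function(x) {
  x <- stringr::str_squish(as.character(x))
  x[is.na(x) | x == ""] <- NA_character_
  x
}

.check_lineage_tbl <- function(tax) {
  for (r in seq_along(.LINEAGE_RANKS)[-1]) {
    lower <- tax[[.LINEAGE_RANKS[r]]]
    higher <- tax[[.LINEAGE_RANKS[r - 1]]]
    bad <- !is.na(lower) & is.na(higher)
    if (any(bad)) {
      rlang::abort(sprintf(
        "lineage rank '%s' set while '%s' is empty (accession %s)",
        .LINEAGE_RANKS[r], .LINEAGE_RANKS[r - 1],
        tax$accession[which(bad)[1]]),
        class = "spongeid_lineage_error")
    }
  }
  invisible(tax)
}

#' Build a taxonomy-annotated reference database for one locus
#'
#' Indexes reference sequences with an exact k-mer word index (words
#' containing ambiguity codes are skipped) and attaches a lineage
#' (phylum, order, family, genus, species) to every accession. The summed
#' database length is recorded for E-value computation.
#'
#' @param sequences A tibble with columns `accession` and `sequence`, or the
#'   path to a FASTA file whose record ids are accessions.
#' @param taxonomy A tibble (or TSV path) with columns `accession`,
#'   `phylum`, `order`, and optionally `family`, `genus`, `species`. Every
#'   accession in `sequences` must appear; lower ranks may be empty but a
#'   rank may not be set beneath an empty one.
#' @param locus Locus label (`COI`, `28S` or `ITS`).
#' @param thresholds A [sip_thresholds()] object (`word_size`).
#' @return An object of class `sip_reference_db`.
#' @export
build_reference_db <- function(sequences, taxonomy, locus,
                               thresholds = sip_thresholds()) {
  t <- thresholds
  if (is.character(sequences)) {
    ss <- Biostrings::readDNAStringSet(sequences)
    sequences <- tibble::tibble(accession = names(ss),
                                sequence = as.character(ss))
  }
  sequences <- tibble::as_tibble(sequences)
  sequences$sequence <- toupper(chartr("Uu", "Tt", sequences$sequence))
  if (anyDuplicated(sequences$accession)) {
    dup <- sequences$accession[duplicated(sequences$accession)][1]
    rlang::abort(sprintf("duplicate accession '%s'", dup),
                 class = "spongeid_refdb_error")
  }
  short <- nchar(sequences$sequence) < t$word_size
  if (any(short)) {
    rlang::abort(sprintf(
      "record '%s' is shorter than word_size (%d); cannot be indexed",
      sequences$accession[which(short)[1]], t$word_size),
      class = "spongeid_refdb_error")
  }
  if (is.character(taxonomy)) {
    taxonomy <- readr::read_tsv(taxonomy, show_col_types = FALSE,
                                progress = FALSE)
  }
  taxonomy <- tibble::as_tibble(taxonomy)
  for (r in .LINEAGE_RANKS) {
    if (!r %in% names(taxonomy)) taxonomy[[r]] <- NA_character_
    taxonomy[[r]] <- .canon_text(taxonomy[[r]])
  }
  missing <- setdiff(sequences$accession, taxonomy$accession)
  if (length(missing) > 0) {
    rlang::abort(sprintf("accession '%s' has no taxonomy row", missing[1]),
                 class = "spongeid_refdb_error")
  }
  taxonomy <- taxonomy[match(sequences$accession, taxonomy$accession), ]
  if (any(is.na(taxonomy$phylum) | is.na(taxonomy$order))) {
    rlang::abort("every reference needs at least phylum and order",
                 class = "spongeid_refdb_error")
  }
  .check_lineage_tbl(taxonomy)
  records <- dplyr::bind_cols(
    sequences,
    dplyr::select(taxonomy, dplyr::all_of(.LINEAGE_RANKS))
  )
  index <- new.env(parent = emptyenv(), hash = TRUE)
  for (i in seq_len(nrow(records))) {
    for (w in .clean_words(records$sequence[i], t$word_size)) {
      index[[w]] <- c(index[[w]], i)
    }
  }
  structure(
    list(records = records, index = index, locus = locus,
         word_size = t$word_size, m = sum(nchar(records$sequence)),
         masks = lapply(records$sequence, seq_to_masks)),
    class = "sip_reference_db")
}

# unique words of width w made only of A/C/G/T
.clean_words <- function(seq, w) {
  n <- nchar(seq)
  if (n < w) return(character(0))
  starts <- seq_len(n - w + 1L)
  words <- substring(seq, starts, starts + w - 1L)
  unique(words[!grepl("[^ACGT]", words)])
}

#' @export
print.sip_reference_db <- function(x, ...) {
  cat(sprintf("<sip_reference_db> locus %s: %d records, %d total bases, word size %d\n",
              x$locus, nrow(x$records), x$m, x$word_size))
  invisible(x)
}

#' Karlin-Altschul bit score of a raw alignment score
#'
#' Normalizes a raw local-alignment score with respect to the scoring
#' system: `bits = (lambda * S - ln K) / ln 2`. Bit scores from different
#' searches (and loci) are thereby comparable, which is what makes them the
#' arbitration statistic of the identification protocol.
#'
#' @param S Integer raw score(s).
#' @param lambda,K Karlin-Altschul parameters (`lambda > 0`, `0 < K <= 1`).
#' @return Bit score(s).
#' @export
#' @examples
#' karlin_altschul_bits(200, 0.625, 0.41)
karlin_altschul_bits <- function(S, lambda = 0.625, K = 0.41) {
  if (lambda <= 0 || K <= 0) {
    rlang::abort("lambda and K must be positive",
                 class = "spongeid_ka_error")
  }
  (lambda * S - log(K)) / log(2)
}

#' Search a query against a reference database
#'
#' Exact-word seeding selects candidate subjects (both query strands); each
#' candidate is aligned with an exact affine-gap local alignment and the
#' best local alignment per subject is reported with its raw score, bit
#' score, E-value (`m * n * 2^-bits`), percent identity, query coverage and
#' subject lineage. Hits are sorted by bit score (desc), then E-value
#' (asc), then accession (asc); repeated runs give byte-identical tables.
#'
#' @param query A single IUPAC nucleotide string.
#' @param db A [build_reference_db()] object.
#' @param thresholds A [sip_thresholds()] object (scoring and `ka_*`).
#' @param query_id Id recorded in the `query_id` column (default "query").
#' @return A tibble of hits (possibly empty) with columns `query_id`,
#'   `accession`, `raw_score`, `bit_score`, `evalue`, `pct_identity`,
#'   `query_coverage_pct`, `qstart`, `qend`, `sstart`, `send` (0-based
#'   half-open), `strand`, and the lineage ranks.
#' @export
local_search <- function(query, db, thresholds = sip_thresholds(),
                         query_id = "query") {
  t <- thresholds
  stopifnot(inherits(db, "sip_reference_db"))
  query <- toupper(chartr("Uu", "Tt", query))
  n <- nchar(query)
  if (n < db$word_size) {
    rlang::abort("query shorter than the database word size",
                 class = "spongeid_search_error")
  }
  if (nrow(db$records) == 0L) return(.empty_hits())
  strands <- list(
    `+` = query,
    `-` = revcomp(query)
  )
  cand <- lapply(strands, function(q) {
    words <- .clean_words(q, db$word_size)
    found <- unlist(lapply(words, function(w) db$index[[w]]), use.names = FALSE)
    sort(unique(found))
  })
  rows <- list()
  subjects <- sort(unique(c(cand[["+"]], cand[["-"]])))
  qmasks <- lapply(strands, seq_to_masks)
  for (si in subjects) {
    smask <- db$masks[[si]]
    best <- NULL
    for (strand in c("+", "-")) {
      if (!si %in% cand[[strand]]) next
      qmask <- qmasks[[strand]]
      a <- .sw_align_cpp(qmask, smask, t$match, t$mismatch,
                         t$gap_open, t$gap_extend)
      if (a$score <= 0) next
      a$strand <- strand
      if (is.null(best) || a$score > best$score) best <- a
    }
    if (is.null(best)) next
    # report query coordinates on the given (plus) orientation
    if (best$strand == "-") {
      qs <- n - best$qend; qe <- n - best$qstart
    } else {
      qs <- best$qstart; qe <- best$qend
    }
    bits <- karlin_altschul_bits(best$score, t$ka_lambda, t$ka_K)
    rec <- db$records[si, ]
    rows[[length(rows) + 1L]] <- tibble::tibble(
      query_id = query_id,
      accession = rec$accession,
      raw_score = as.integer(best$score),
      bit_score = bits,
      evalue = db$m * n * 2^(-bits),
      pct_identity = 100 * best$matches / best$align_len,
      query_coverage_pct = 100 * (best$qend - best$qstart) / n,
      qstart = as.integer(qs), qend = as.integer(qe),
      sstart = as.integer(best$sstart), send = as.integer(best$send),
      strand = best$strand,
      phylum = rec$phylum, order = rec$order, family = rec$family,
      genus = rec$genus, species = rec$species
    )
  }
  if (length(rows) == 0L) return(.empty_hits())
  sort_hits(dplyr::bind_rows(rows))
}

.empty_hits <- function() {
  tibble::tibble(
    query_id = character(), accession = character(),
    raw_score = integer(), bit_score = numeric(), evalue = numeric(),
    pct_identity = numeric(), query_coverage_pct = numeric(),
    qstart = integer(), qend = integer(),
    sstart = integer(), send = integer(), strand = character(),
    phylum = character(), order = character(), family = character(),
    genus = character(), species = character()
  )
}

#' Sort a hit table into the canonical order
#'
#' Bit score descending, then E-value ascending, then accession ascending
#' (within each query id). The order is total, so repeated runs are
#' byte-identical.
#'
#' @param hits A hit tibble.
#' @return The sorted tibble.
#' @export
sort_hits <- function(hits) {
  dplyr::arrange(hits, .data$query_id, dplyr::desc(.data$bit_score),
                 .data$evalue, .data$accession)
}

#' Best-hit phylum of a query
#'
#' Runs [local_search()] and returns the subject phylum of the top hit, or
#' `NA` when there are no hits. This is the taxon screen used by the
#' validity filter to drop contaminant (non-target) reads.
#'
#' @inheritParams local_search
#' @return A phylum string or `NA_character_`.
#' @export
phylum_screen <- function(query, db, thresholds = sip_thresholds()) {
  hits <- local_search(query, db, thresholds)
  if (nrow(hits) == 0L) NA_character_ else hits$phylum[1]
}

#' Read externally produced tabular hits (12-column format)
#'
#' Parses the standard 12-column tabular hit format (`qseqid sseqid pident
#' length mismatch gapopen qstart qend sstart send evalue bitscore`),
#' optionally followed by a 13th column holding the subject lineage as
#' `phylum;order;family;genus;species`. Input coordinates are 1-based
#' inclusive; they are converted to the package's 0-based half-open
#' convention, reversed spans are normalized with a strand flag, and query
#' coverage is computed from a supplied query-length table. Rows are
#' re-sorted into the canonical hit order.
#'
#' @param path Path to the tabular file (no header).
#' @param query_lengths A tibble with columns `query_id` and `length`.
#' @return A hit tibble as from [local_search()] (`raw_score` is `NA`: the
#'   raw score is not part of the tabular format).
#' @export
parse_tabular_hits <- function(path, query_lengths) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(.empty_hits())
  rows <- purrr::imap(lines, function(line, lineno) {
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (!length(f) %in% c(12L, 13L)) {
      rlang::abort(sprintf("line %d: expected 12 or 13 columns, found %d",
                           lineno, length(f)),
                   class = "spongeid_tabular_error")
    }
    num <- suppressWarnings(as.numeric(f[3:12]))
    if (anyNA(num)) {
      rlang::abort(sprintf("line %d: malformed numeric field", lineno),
                   class = "spongeid_tabular_error")
    }
    qlen <- query_lengths$length[match(f[1], query_lengths$query_id)]
    if (is.na(qlen)) {
      rlang::abort(sprintf("line %d: unknown query id '%s'", lineno, f[1]),
                   class = "spongeid_tabular_error")
    }
    qs <- num[5]; qe <- num[6]; ss <- num[7]; se <- num[8]
    strand <- "+"
    if (qs > qe) { tmp <- qs; qs <- qe; qe <- tmp; strand <- "-" }
    if (ss > se) { tmp <- ss; ss <- se; se <- tmp; strand <- "-" }
    lin <- rep(NA_character_, 5)
    if (length(f) == 13L) {
      parts <- .canon_text(strsplit(f[13], ";", fixed = TRUE)[[1]])
      lin[seq_along(parts)] <- parts
    }
    tibble::tibble(
      query_id = f[1], accession = f[2],
      raw_score = NA_integer_,
      bit_score = num[10], evalue = num[9],
      pct_identity = num[1],
      query_coverage_pct = 100 * (qe - qs + 1) / qlen,
      qstart = as.integer(qs - 1), qend = as.integer(qe),
      sstart = as.integer(ss - 1), send = as.integer(se),
      strand = strand,
      phylum = lin[1], order = lin[2], family = lin[3],
      genus = lin[4], species = lin[5]
    )
  })
  sort_hits(dplyr::bind_rows(rows))
}

#' Write a hit table in the 12(+1)-column tabular format
#'
#' Inverse of [parse_tabular_hits()]: internal 0-based half-open spans are
#' written back as 1-based inclusive coordinates (reversed for minus-strand
#' hits), with the lineage joined by `;` as an optional 13th column.
#'
#' @param hits A hit tibble.
#' @param path Output path.
#' @param lineage Write the 13th lineage column (default TRUE).
#' @return `path`, invisibly.
#' @export
write_tabular_hits <- function(hits, path, lineage = TRUE) {
  lines <- purrr::pmap_chr(hits, function(...) {
    h <- list(...)
    qs <- h$qstart + 1L; qe <- h$qend
    ss <- h$sstart + 1L; se <- h$send
    if (identical(h$strand, "-")) { tmp <- qs; qs <- qe; qe <- tmp }
    base <- paste(
      h$query_id, h$accession,
      sprintf("%.17g", h$pct_identity),
      h$qend - h$qstart, # alignment length proxy: query span
      0L, 0L,
      qs, qe, ss, se,
      sprintf("%.17g", h$evalue),
      sprintf("%.17g", h$bit_score),
      sep = "\t")
    if (lineage) {
      lin <- paste(dplyr::coalesce(c(h$phylum, h$order, h$family,
                                     h$genus, h$species), ""),
                   collapse = ";")
      base <- paste(base, lin, sep = "\t")
    }
    base
  })
  readr::write_lines(lines, path)
  invisible(path)
}
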