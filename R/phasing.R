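# Heterozygote handling for direct Sanger reads.
#
# A diploid template whose two alleles differ by an indel produces, in a
# direct Sanger read, a clean signal up to the indel and a superposition of
# the two frame-shifted alleles after it. With IUPAC-encoded reads this
# appears as a dense patch of mixed bases running to the 3' end of the read.
# The forward read shows the superposition anchored at the 5' end of the
# amplicon; the reverse read shows it anchored at the 3' end, which is what
# makes the two alleles recoverable.

#' Superpose two alleles into the forward/reverse mixture reads they produce
#'
#' Ground-truth model for direct sequencing of a diploid template: at every
#' position the observed call is the IUPAC union of the bases the two
#' alleles place there, with the forward read anchored at the 5' end and the
#' reverse read (returned in its own reading orientation) anchored at the
#' 3' end. Both reads span `max(nchar(a), nchar(b))` bases.
#'
#' @param allele_a,allele_b Plain `ACGT` allele strings.
#' @return A list with `forward` and `reverse` IUPAC strings.
#' @export
#' @examples
#' superpose_alleles("ACGTACGT", "ACGGTACGT")$forward # "ACGKWMSKT"
superpose_alleles <- function(allele_a, allele_b) {
  ma <- seq_to_masks(allele_a)
  mb <- seq_to_masks(allele_b)
  la <- length(ma); lb <- length(mb); M <- max(la, lb)
  fwd <- integer(M); rev3 <- integer(M)
  for (i in seq_len(M)) {
    f <- 0L
    if (i <= la) f <- bitwOr(f, ma[i])
    if (i <= lb) f <- bitwOr(f, mb[i])
    fwd[i] <- f
    r <- 0L
    if (i <= la) r <- bitwOr(r, ma[la - i + 1L])
    if (i <= lb) r <- bitwOr(r, mb[lb - i + 1L])
    rev3[i] <- r
  }
  list(forward = masks_to_seq(fwd),
       reverse = masks_to_seq(.comp_mask(rev3)))
}

#' Classify the heterozygosity of an IUPAC-encoded read pair
#'
#' Three mutually exclusive classes: `homozygous` (no mixed base in either
#' read), `length_variant_het` (either read carries the superposition
#' signature of two frame-shifted alleles: at least `run_min` mixed
#' positions with the last one within `tail_window` bases of its 3' end),
#' and `point_het` otherwise (isolated mixed bases, e.g. a SNP under a
#' single double peak). For point heterozygotes the mixed codes of the two
#' reads are checked for reverse-complement consistency and the result is
#' reported as `rc_consistent`.
#'
#' @param forward_seq,reverse_seq IUPAC-encoded trimmed reads (each in its
#'   own reading orientation).
#' @param thresholds A [sip_thresholds()] object (`run_min`, `tail_window`,
#'   `point_het_max`).
#' @return A list with `class`, `n_mixed_fwd`, `n_mixed_rev`,
#'   `rc_consistent` (NA unless `point_het`).
#' @export
classify_heterozygosity <- function(forward_seq, reverse_seq,
                                    thresholds = sip_thresholds()) {
  t <- thresholds
  fm <- seq_to_masks(forward_seq)
  rm <- seq_to_masks(reverse_seq)
  # double peaks are two-base codes; N-type base-call ambiguities are not
  # mixture evidence and are ignored here
  mixed_f <- which(.mask_size(fm) == 2L)
  mixed_r <- which(.mask_size(rm) == 2L)
  tail_sig <- function(mixed, n) {
    length(mixed) >= t$run_min &&
      (n - max(mixed)) < t$tail_window
  }
  cls <- if (length(mixed_f) == 0L && length(mixed_r) == 0L) {
    "homozygous"
  } else if (tail_sig(mixed_f, length(fm)) || tail_sig(mixed_r, length(rm))) {
    "length_variant_het"
  } else {
    "point_het"
  }
  rc <- NA
  if (cls == "point_het") {
    # complement the reverse read's mixed codes and compare code multisets
    f_codes <- sort(fm[mixed_f])
    r_codes <- sort(.comp_mask(rm[mixed_r]))
    rc <- identical(f_codes, r_codes) &&
      length(mixed_f) <= t$point_het_max &&
      length(mixed_r) <= t$point_het_max
  }
  list(class = cls,
       n_mixed_fwd = length(mixed_f),
       n_mixed_rev = length(mixed_r),
       rc_consistent = rc)
}

# Solve one candidate offset d (allele B longer than A by d >= 0).
# Fm: forward union masks; Tm: 3'-anchored union masks (complemented reverse
# read, NOT reversed). Returns list of solutions (each list(a=, b=) mask
# vectors), canonicalized and truncated to at most `cap` solutions.
.phase_solve_d <- function(Fm, Tm, d, cap = 16L) {
  M <- length(Fm)
  la <- M - d
  if (la < 1L) return(list())
  lb <- M
  # candidate sets
  ca <- rep(15L, la)
  cb <- rep(15L, lb)
  ok <- TRUE
  # pair constraints: list of (ai, bi, S) with |S| == 2
  pairs <- list()
  add_single <- function(cand, idx, S) {
    v <- bitwAnd(cand[idx], S)
    cand[idx] <- v
    cand
  }
  # forward constraints
  for (i in seq_len(M)) {
    S <- Fm[i]
    if (.mask_size(S) > 2L) return(list())
    if (i <= la) {
      ca <- add_single(ca, i, S)
      cb <- add_single(cb, i, S)
      if (.mask_size(S) == 2L) pairs[[length(pairs) + 1L]] <- c(i, i, S)
    } else {
      if (.mask_size(S) != 1L) return(list())
      cb <- add_single(cb, i, S)
    }
  }
  # reverse constraints: position j pairs A[la-j+1] with B[lb-j+1]
  for (j in seq_len(M)) {
    S <- Tm[j]
    if (.mask_size(S) > 2L) return(list())
    bi <- lb - j + 1L
    if (j <= la) {
      ai <- la - j + 1L
      ca <- add_single(ca, ai, S)
      cb <- add_single(cb, bi, S)
      if (.mask_size(S) == 2L) pairs[[length(pairs) + 1L]] <- c(ai, bi, S)
    } else {
      if (.mask_size(S) != 1L) return(list())
      cb <- add_single(cb, bi, S)
    }
  }
  if (any(ca == 0L) || any(cb == 0L)) return(list())
  # propagate the exclusive-pair constraints to a fixpoint: for {x, y} = S
  # with |S| = 2, x and y take distinct values covering S
  repeat {
    changed <- FALSE
    for (p in pairs) {
      ai <- p[1]; bi <- p[2]; S <- p[3]
      av <- ca[ai]; bv <- cb[bi]
      if (.mask_size(av) == 1L) {
        nb <- bitwAnd(bv, bitwAnd(S, bitwNot(av)))
        if (nb != bv) { cb[bi] <- nb; changed <- TRUE }
      }
      if (.mask_size(cb[bi]) == 1L) {
        na_ <- bitwAnd(ca[ai], bitwAnd(S, bitwNot(cb[bi])))
        if (na_ != ca[ai]) { ca[ai] <- na_; changed <- TRUE }
      }
    }
    if (any(ca == 0L) || any(cb == 0L)) return(list())
    if (!changed) break
  }
  # unresolved variables sit in chains linked by pair constraints; each
  # connected component has at most two consistent assignments
  unresolved_a <- which(.mask_size(ca) > 1L)
  unresolved_b <- which(.mask_size(cb) > 1L)
  if (length(unresolved_a) == 0L && length(unresolved_b) == 0L) {
    return(list(list(a = ca, b = cb)))
  }
  # component discovery over variable ids: a-vars 1..la, b-vars la+1..la+lb
  nvar <- la + lb
  adj <- vector("list", nvar)
  for (k in seq_along(pairs)) {
    p <- pairs[[k]]
    u <- p[1]; v <- la + p[2]
    adj[[u]] <- c(adj[[u]], k)
    adj[[v]] <- c(adj[[v]], k)
  }
  var_cand <- c(ca, cb)
  comp <- rep(0L, nvar)
  ncomp <- 0L
  for (v0 in c(unresolved_a, la + unresolved_b)) {
    if (comp[v0] != 0L) next
    ncomp <- ncomp + 1L
    queue <- v0
    comp[v0] <- ncomp
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (k in adj[[v]]) {
        p <- pairs[[k]]
        others <- c(p[1], la + p[2])
        for (w in others) {
          if (comp[w] == 0L && .mask_size(var_cand[w]) > 1L) {
            comp[w] <- ncomp
            queue <- c(queue, w)
          }
        }
      }
    }
  }
  # per component, try the (at most 2) assignments of a root variable and
  # propagate within the component
  solve_component <- function(cid) {
    vars <- which(comp == cid)
    root <- vars[1]
    root_opts <- .mask_bits(var_cand[root])
    sols <- list()
    for (val in root_opts) {
      assign <- var_cand
      assign[root] <- val
      stack <- root
      consistent <- TRUE
      while (length(stack) && consistent) {
        v <- stack[1]; stack <- stack[-1]
        for (k in adj[[v]]) {
          p <- pairs[[k]]
          u <- p[1]; w <- la + p[2]; S <- p[3]
          for (pairvar in list(c(u, w), c(w, u))) {
            x <- pairvar[1]; y <- pairvar[2]
            if (.mask_size(assign[x]) == 1L) {
              forced <- bitwAnd(assign[y], bitwAnd(S, bitwNot(assign[x])))
              if (forced == 0L) { consistent <- FALSE; break }
              if (forced != assign[y]) {
                assign[y] <- forced
                if (.mask_size(forced) == 1L) stack <- c(stack, y)
              }
            }
          }
          if (!consistent) break
        }
      }
      if (consistent && all(.mask_size(assign[vars]) == 1L)) {
        sols[[length(sols) + 1L]] <- assign[vars]
      }
    }
    list(vars = vars, sols = sols)
  }
  comps <- lapply(seq_len(ncomp), solve_component)
  if (any(vapply(comps, function(cc) length(cc$sols) == 0L, logical(1)))) {
    return(list())
  }
  # cartesian product over components (capped)
  sol_counts <- vapply(comps, function(cc) length(cc$sols), integer(1))
  total <- prod(sol_counts)
  if (total > cap) total <- cap
  grids <- expand.grid(lapply(sol_counts, seq_len))[seq_len(total), ,
                                                    drop = FALSE]
  out <- list()
  for (r in seq_len(nrow(grids))) {
    assign <- var_cand
    for (ci in seq_len(ncomp)) {
      cc <- comps[[ci]]
      assign[cc$vars] <- cc$sols[[grids[r, ci]]]
    }
    out[[length(out) + 1L]] <- list(a = assign[seq_len(la)],
                                    b = assign[la + seq_len(lb)])
  }
  out
}

.mask_bits <- function(m) {
  bits <- c(1L, 2L, 4L, 8L)
  bits[bitwAnd(m, bits) > 0L]
}

# canonical ordering of a solved pair: lexicographically smallest allele
# string first (alleles of different length keep the shorter first)
.canon_pair <- function(sol) {
  a <- masks_to_seq(sol$a)
  b <- masks_to_seq(sol$b)
  if (nchar(a) == nchar(b) && b < a) list(a = b, b = a) else list(a = a, b = b)
}

#' Phase a length-variant heterozygote into its two alleles
#'
#' Reconstructs the two allele sequences from the IUPAC mixture reads
#' produced by direct sequencing of a diploid template whose alleles differ
#' by an indel. Candidate allele length differences `d = 0..max_offset` are
#' tried; for each, the forward read constrains the alleles from the 5' end
#' and the (reverse-complemented) reverse read constrains them from the 3'
#' end, and the unique joint assignment is recovered by constraint
#' propagation. Solutions at more than one distinct `|d|` raise an ambiguity
#' error listing all of them; no solution at any `d` raises an unphaseable
#' error; multiple assignments at a single `|d|` (e.g. unlinked substitution
#' phase ambiguity at `d = 0`) resolve deterministically to the
#' lexicographically smallest `allele_a`.
#'
#' @param forward_mix,reverse_mix IUPAC mixture reads (reverse in its own
#'   reading orientation); every position must encode one or two bases.
#' @param thresholds A [sip_thresholds()] object (`max_offset`).
#' @return A list with `allele_a`, `allele_b` (plain `ACGT` strings,
#'   `allele_a` the shorter or lexicographically smaller), `offset_d`
#'   (`nchar(allele_b) - nchar(allele_a)`), `indel_position` (0-based index
#'   of the first divergent position in `allele_a`, `NA` when `d = 0`), and
#'   `n_solutions` (assignments found at the accepted `d`).
#' @export
#' @examples
#' sp <- superpose_alleles("ACGTACGT", "ACGGTACGT")
#' phase_alleles(sp$forward, sp$reverse)
phase_alleles <- function(forward_mix, reverse_mix,
                          thresholds = sip_thresholds()) {
  Fm <- seq_to_masks(forward_mix)
  Rv <- seq_to_masks(reverse_mix)
  if (any(.mask_size(Fm) > 2L) || any(.mask_size(Rv) > 2L)) {
    rlang::abort("mixture positions must encode one or two bases",
                 class = "spongeid_phase_error")
  }
  if (length(Fm) != length(Rv)) {
    rlang::abort(
      "forward and reverse mixture reads must span the same template length",
      class = "spongeid_phase_error")
  }
  Tm <- .comp_mask(Rv) # 3'-anchored superposition, 3' -> 5'
  by_d <- list()
  for (d in 0:thresholds$max_offset) {
    sols <- .phase_solve_d(Fm, Tm, d)
    if (length(sols) > 0L) by_d[[as.character(d)]] <- sols
  }
  if (length(by_d) == 0L) {
    rlang::abort("no allele pair is consistent with both mixture reads",
                 class = "spongeid_unphaseable_error")
  }
  if (length(by_d) > 1L) {
    all_sols <- purrr::imap(by_d, function(sols, d) {
      purrr::map(sols, function(s) {
        cp <- .canon_pair(s)
        sprintf("d=%s: %s / %s", d, cp$a, cp$b)
      })
    })
    rlang::abort(
      paste0("multiple consistent allele pairs at distinct offsets:\n",
             paste(unlist(all_sols), collapse = "\n")),
      class = "spongeid_phase_ambiguity_error")
  }
  d <- as.integer(names(by_d)[1])
  sols <- purrr::map(by_d[[1]], .canon_pair)
  keys <- vapply(sols, function(s) paste(s$a, s$b), character(1))
  sols <- sols[!duplicated(keys)]
  ord <- order(vapply(sols, function(s) s$a, character(1)),
               vapply(sols, function(s) s$b, character(1)))
  best <- sols[[ord[1]]]
  indel <- NA_integer_
  if (d > 0L) {
    ach <- strsplit(best$a, "")[[1]]
    bch <- strsplit(best$b, "")[[1]]
    la <- length(ach)
    div <- which(ach != bch[seq_len(la)])
    indel <- if (length(div)) div[1] - 1L else la
  }
  list(allele_a = best$a, allele_b = best$b,
       offset_d = nchar(best$b) - nchar(best$a),
       indel_position = indel,
       n_solutions = length(sols))
}

#' Build the forward/reverse consensus of a read pair
#'
#' The reverse read is reverse-complemented (IUPAC-aware) and slid along the
#' forward read without gaps; the offset maximizing the number of matching
#' positions (two codes match when their base sets intersect) is taken. In
#' the overlap the consensus stores the intersection of the two codes when
#' non-empty (a plain base resolves a compatible ambiguity to the more
#' specific call) and the union when the reads disagree. Outside the overlap
#' the covering read is copied.
#'
#' @param fwd,rev Trimmed IUPAC reads (reverse in its own orientation).
#' @param thresholds A [sip_thresholds()] object (`min_overlap`,
#'   `min_agreement_pct`).
#' @return A list with `sequence`, `overlap_len`, `pct_agreement`, `offset`
#'   (position of the reverse-complemented read relative to the forward
#'   read; may be negative).
#' @export
build_consensus <- function(fwd, rev, thresholds = sip_thresholds()) {
  t <- thresholds
  f <- seq_to_masks(fwd)
  r <- rev(.comp_mask(seq_to_masks(rev))) # reverse-complemented masks
  nf <- length(f); nr <- length(r)
  best <- NULL
  for (s in (-(nr - 1L)):(nf - 1L)) {
    lo <- max(0L, s)              # overlap start on forward coords (0-based)
    hi <- min(nf, s + nr)
    ov <- hi - lo
    if (ov < t$min_overlap) next
    fi <- (lo + 1L):hi
    ri <- (lo - s + 1L):(hi - s)
    m <- sum(bitwAnd(f[fi], r[ri]) > 0L)
    cand <- list(s = s, ov = ov, matches = m)
    if (is.null(best) || m > best$matches ||
        (m == best$matches && ov > best$ov) ||
        (m == best$matches && ov == best$ov && abs(s) < abs(best$s))) {
      best <- cand
    }
  }
  if (is.null(best)) {
    rlang::abort("no overlap of at least min_overlap bases",
                 class = "spongeid_consensus_error")
  }
  pct <- 100 * best$matches / best$ov
  if (pct < t$min_agreement_pct) {
    rlang::abort(sprintf(
      "best overlap agreement %.1f%% is below min_agreement_pct (%s%%)",
      pct, t$min_agreement_pct),
      class = "spongeid_consensus_error")
  }
  s <- best$s
  span_lo <- min(0L, s); span_hi <- max(nf, s + nr)
  cons <- integer(span_hi - span_lo)
  for (p in seq_along(cons)) {
    pos <- span_lo + p - 1L  # forward 0-based coordinate
    fv <- if (pos >= 0L && pos < nf) f[pos + 1L] else 0L
    rv <- if (pos >= s && pos < s + nr) r[pos - s + 1L] else 0L
    v <- if (fv > 0L && rv > 0L) {
      ix <- bitwAnd(fv, rv)
      if (ix > 0L) ix else bitwOr(fv, rv)
    } else bitwOr(fv, rv)
    cons[p] <- v
  }
  list(sequence = masks_to_seq(cons),
       overlap_len = best$ov,
       pct_agreement = pct,
       offset = s)
}

#' Deduplicate replicate consensus sequences of one nominal species
#'
#' Verifies that all pairwise identities (global alignment) exceed
#' `duplicate_identity_pct` and keeps a single representative: the longest
#' sequence, ties broken by lexicographically smallest id. Below-threshold
#' pairs trigger a replicate-discordance warning and all records are kept.
#'
#' @param records A tibble with columns `id` and `sequence` (one nominal
#'   species worth of replicates).
#' @param thresholds A [sip_thresholds()] object (`duplicate_identity_pct`).
#' @return A tibble: one representative row when concordant, all rows (with
#'   a warning) when not.
#' @export
dedupe_replicates <- function(records, thresholds = sip_thresholds()) {
  if (nrow(records) == 0L) {
    rlang::abort("no replicate records supplied",
                 class = "spongeid_dedupe_error")
  }
  if (nrow(records) == 1L) return(records)
  n <- nrow(records)
  idx <- utils::combn(n, 2)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = 0,
                                                  baseOnly = FALSE)
  pid <- apply(idx, 2, function(ij) {
    aln <- Biostrings::pairwiseAlignment(
      records$sequence[ij[1]], records$sequence[ij[2]],
      type = "global", substitutionMatrix = mat,
      gapOpening = 0, gapExtension = 1)
    Biostrings::pid(aln)
  })
  if (any(pid <= thresholds$duplicate_identity_pct)) {
    rlang::warn(sprintf(
      "replicate discordance: minimum pairwise identity %.1f%% <= %s%%; records kept separate",
      min(pid), thresholds$duplicate_identity_pct),
      class = "spongeid_replicate_discordance")
    return(records)
  }
  records |>
    dplyr::arrange(dplyr::desc(nchar(.data$sequence)), .data$id) |>
    dplyr::slice(1L)
}
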