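---
title: "Multilocus barcode identification of sponges: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilocus barcode identification of sponges: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spongeid)
```

## The problem

Sponges (phylum Porifera) are notoriously hard to identify from morphology
alone: the usable characters are few (spicule size, shape and arrangement),
several families overlap in them, and misidentifications propagate into the
very reference databases that molecular identification depends on. No single
DNA barcode resolves all sponge taxa either — the mitochondrial COI barcode
evolves slowly in sponges, the nuclear 28S rRNA (D3–D5) region resolves many
groups well but has patchy database coverage, and the fast-evolving ITS
region is informative but poorly represented in public databases.

`spongeid` implements a complete multilocus identification protocol around
these three markers. The design rests on three ideas:

1. **Bit score as the arbitration statistic.** A raw local-alignment score
   depends on the scoring system; the Karlin–Altschul transform
   $\mathrm{bits} = (\lambda S - \ln K)/\ln 2$ normalizes it so that scores
   from different searches — and, crucially, from *different loci* — are
   comparable. E-values saturate at 0 for strong nucleotide hits and cannot
   rank them; percent similarity is not linear in evolutionary distance.
   Within each locus the top hit by bit score is the locus identity; across
   loci the highest bit score wins.
2. **Guarded inputs.** Direct Sanger reads are trimmed by windowed ambiguity
   content, screened against the reference database to drop non-target
   (contaminant) reads, and excluded when under 200 bp or when the best hit
   covers less than half the query ("coverage region" rule).
3. **Reconciliation with morphology.** Molecular and re-examined
   morphological identities are compared rank by rank; a small rule engine
   decides which one becomes the final identity, with a 98% sequence
   similarity threshold as the tie-breaker when the two disagree above the
   genus level.

## Pipeline stages and their parameters

### Trimming (`trim_read`)

Both reads of a pair are trimmed in their own reading orientation:

* 5' end: advance the start until the first `qc_window` (50-base) window
  contains zero ambiguities (any non-ACGT code), but never trim more than
  `max_5prime_trim_fraction` (25%) of the read. If no clean window exists
  before the cap, the cap position is used.
* 3' end: starting `three_prime_scan_offset` (100) bases after the 5' trim,
  cut at the first 50-base window containing more than
  `three_prime_ambiguity_limit` (1) ambiguities, scanning 5'→3'.

Design notes, where the underlying convention was genuinely open:

* "Less than 1 ambiguity" is read as exactly zero; "more than 1" as two or
  more — the literal arithmetic reading of the trimming settings.
* Windows truncated by the end of the read are evaluated over the available
  bases with thresholds unscaled; the simplest consistent rule.
* The 25% cap applies to the 5' trim only and is computed from the raw read
  length; the 3' scan direction is 5'→3' from `start + 100`. Both choices
  are documented here because the alternative readings are defensible.
* A `-` character is an error, not an ambiguity: gaps cannot occur in a
  base-called read.

One property worth stating precisely: inserting extra ambiguities can never
move the 5' start earlier, and — *for a fixed 5' start* — can never move
the 3' end later. The unconditional version of the second claim is false
under this (or any offset-anchored) rule: extra 5' ambiguities can push the
start, and with it the scan origin, past a dirty window. The property suite
therefore tests the conditional form.

### Validity filter (`validity_filter`)

A pair is excluded when either trimmed read is shorter than
`min_valid_length` (200 bp; checked first) or when either read's best-hit
phylum is not the expected target (`Porifera` by default). The taxon screen
is a callback — normally `phylum_screen()` over the locus database — and a
*failure* of the screen is an error, deliberately distinct from an
exclusion verdict.

### Heterozygotes (`classify_heterozygosity`, `phase_alleles`)

Direct sequencing of a diploid template yields three signal classes:
homozygous pairs; point heterozygotes (isolated double peaks, encoded as
two-base IUPAC codes); and length-variant heterozygotes, where the two
alleles differ by an indel and the trace downstream of it is a superposition
of two frame-shifted allele signals.

The classifier operates on the IUPAC-encoded text, since chromatograms are
out of scope: a read shows the length-variant signature when it carries at
least `run_min` (5) mixed positions and the last one lies within
`tail_window` (10) bases of its 3' end. A strictly contiguous mixed run is
*not* required — two alleles shifted by one base still agree at roughly a
quarter of downstream positions, so the genuine superposition signal is
dense but gappy. `N`-type base-call ambiguities are never mixture evidence;
only two-base codes are. Classification happens on the raw encoded reads,
before ambiguity trimming, because the trimmer would otherwise truncate the
very tail that phasing needs.

Phasing enumerates candidate allele-length differences `d` up to
`max_offset` (10). For each `d` the forward read constrains the allele pair
from the 5' end and the reverse read from the 3' end; each observed
position is either a singleton (both alleles agree) or an unordered
two-base set (the alleles differ), and constraint propagation threads the
two sequences through both reads simultaneously. Semantics of the outcome:

* no consistent pair at any `d` — an `unphaseable` error;
* consistent pairs at more than one distinct `|d|` — an ambiguity error
  that lists every solution (the tool refuses to choose silently);
* several assignments at a single `|d|` (e.g. two unlinked substitutions at
  `d = 0`, whose phase is genuinely unknowable from a single amplicon) —
  the lexicographically smallest `allele_a` is chosen deterministically so
  that runs are reproducible, and `n_solutions` records the multiplicity.

The test suite checks phasing two ways: a round trip (superpose → phase →
superposition is reproduced exactly) on random indel heterozygotes, and
equivalence with a brute-force generate-and-test oracle on alleles of up to
12 bases, including the tie-break.

### Consensus and replicates (`build_consensus`, `dedupe_replicates`)

The reverse read is reverse-complemented (IUPAC-aware) and slid along the
forward read without gaps; the offset maximizing the number of matching
positions wins, with ties broken toward longer overlap and then smaller
shift. Two codes match when their base sets intersect; the consensus stores
the intersection (a plain base sharpens a compatible ambiguity) or, on
disagreement, the union code. A consensus requires `min_overlap` (20) bases
of overlap at `min_agreement_pct` (90%) agreement.

Replicate consensus sequences of one nominal species must exceed
`duplicate_identity_pct` (99%) pairwise global-alignment identity; the
longest is kept (ties: smallest id). Discordant replicates are kept
separate with a warning — a disagreement among replicates is a biological
red flag, not something to average away.

### Search (`build_reference_db`, `local_search`)

The reference database holds per-locus sequences with five-rank lineages
(phylum → species, no rank beneath an empty one) and an exact k-mer index
(`word_size` 11). A query is searched on both strands; subjects sharing at
least one clean word are aligned with an exact affine-gap Smith–Waterman
(Rcpp) under `match +2 / mismatch −3 / gap open 5 / gap extend 2`, one best
local alignment per subject. Ambiguity codes match when the base sets
intersect, and score as a mismatch otherwise. Raw scores become bit scores
via λ = 0.625, K = 0.41 (the standard constants for this scoring system;
they are configuration, not estimated) and E-values via
$E = m\,n\,2^{-\mathrm{bits}}$ with `m` the summed database length.

Running the exact DP on word-filtered candidates — rather than a banded
heuristic extension — keeps the engine simple and makes a strong guarantee
testable: the top hit's raw score equals the full Smith–Waterman optimum
over the whole database whenever word seeding finds the subject. The
property suite verifies this against an independent implementation
(`Biostrings::pairwiseAlignment`) on hundreds of seeded cases.

Externally produced hits in the standard 12-column tabular dialect (with an
optional 13th lineage column) can substitute for the built-in engine via
`parse_tabular_hits()`; coordinates are converted between the 1-based
inclusive file convention and the package's 0-based half-open intervals,
and `parse_tabular_hits(write_tabular_hits(h))` round-trips.

### Selection and arbitration (`select_locus_hit`, `arbitrate`)

Hits under `min_coverage_pct` (50%) query coverage are dropped; the best
remaining hit is chosen by bit score, with the deterministic tie-break
chain E-value → percent identity → coverage → accession. The leading
`top_n_scan` (20) hits are scanned for anomalies — multiple phyla, or a
best-hit genus occurring once while another genus dominates — and these are
attached as *advisory warnings only*: the protocol says to consider the top
of the list for possible errors but prescribes no decision rule, so the
scan must never alter the selection (a tested invariant).

Across loci the valid locus with the highest bit score wins. Bit ties never
occurred in the study data; they resolve by identity, then coverage, then
the fixed priority COI > 28S > ITS, purely for reproducibility. Species
rank is reported only when the winning hit carries a species name;
otherwise the identity stops at genus (as with hits like "*Tethya* sp.").
Note the documented length bias: loci are weighted equally in the sense
that raw bit maxima are compared directly, and longer amplicons can reach
higher bit scores.

### Categories and final identities (`assign_category`, `finalize`)

Against the re-examined morphology, each specimen falls in exactly one
category: **V** when re-examination changed the initial classification at
any rank (including pure refinements, e.g. an order-level name resolved to
a genus); otherwise **I** for a genus-or-deeper match with the molecular
identity, **II** for a family/order match between taxa the curator flagged
as highly similar, **III** for a family/order match without that flag, and
**IV** for no order-level match. Two points were genuinely open:

* The similar-morphology judgement is curator *input*, not computed — it
  encodes expert knowledge (e.g. two families differing only in the surface
  arrangement of spicules) that no lineage comparison can supply.
* Category III is "family or order match without the flag" rather than
  "order match only": the study itself contains a family-level match
  without the flag, and the broader reading keeps I–V a true partition.

Final identities then follow three rules: (1) genus-level agreement → the
molecular identity; (2) family/order agreement plus the similar-morphology
flag → the molecular identity; (3) otherwise the molecular identity is
accepted only at `final_similarity_threshold_pct` (98%) or better (rule
3a), else the re-examined morphological identity stands (3b). Specimens
without a molecular identity fall to morphology with a note. Raising a
specimen's similarity can move its final identity from morphology to
molecular but never the reverse (a tested monotonicity).

Reported percentages use round-half-up and always carry the exact
`matches/total` fraction alongside, because printed percentages alone are
ambiguous across rounding conventions.

## The synthetic-data generator

`simulation_config()` / `simulate_reference_db()` build a reference
database as a taxonomy-shaped tree: one random root per order, genus
representatives at 10% substitution divergence, species at a further 2%,
plus independent random decoys under a non-target phylum so the screen has
something to catch. Divergence is substitution-only, keeping identity
arithmetic exact for tests; indels appear only inside the heterozygote
simulation. `simulate_specimen()` mutates a reference at 1% into a specimen
template, reads it from both ends at 90% template coverage, and appends a
dirty `N`-bearing tail (30 bases at 50% density) to exercise the trimmer;
heterozygous specimens superpose a second allele (one substitution, or an
interior insertion for the length-variant class). `make_cohort_fixture()`
assembles whole cohorts with controlled defect counts — its default
emulates a 31-pair amplicon batch losing one pair to a contaminant forward
read and one to a 170-bp forward read — and emits ground-truth labels next
to every artifact. All generation runs on one seeded stream per call;
identical seeds give byte-identical files, and the caller's RNG state is
untouched.

What the simulator does *not* emulate: chromatogram-level noise (quality
scores, dye blobs, mobility shifts), PCR chimeras and heteroduplexes,
within-specimen paralogy of the rRNA arrays, and the deeply uneven taxon
coverage of real public databases. Passing tests therefore demonstrate the
correctness of the decision logic and the alignment engine under the stated
noise model, not robustness to every artefact of real trace data.

## Numerical choices and problem sizes

Alignment scores are integers throughout; bit scores and E-values are
doubles computed in closed form, so test comparisons are exact or at
`1e-12`. Hit ordering is total (bit ↓, E-value ↑, accession ↑), making
repeated runs byte-identical. The test suite sizes were chosen to exercise
the combinatorics while keeping a full run in a few minutes on one core:
1000 phasing oracle cases on alleles ≤ 12, 200 search-vs-Smith–Waterman
cases on databases of up to 10 subjects of ≤ 200 bases, 1000 trimming
oracle cases, 200 arbitration ablation cases, and a 31-pair cohort for the
end-to-end validity-filter count.

## Known limitations

* Phasing assumes both reads span the same template interval (full-length
  mixture reads); partially overlapping mixture reads are not threaded.
* One best local alignment per subject; multi-HSP score summing is not
  implemented.
* Karlin–Altschul parameters are fixed constants for the default scoring;
  gapped-parameter estimation and composition-based statistics are out of
  scope.
* Phylogenetic-tree validation of identities (building per-query trees) is
  outside the package; the arbitration rests on bit scores alone.
* The bundled case-study tables encode the published per-specimen outcomes,
  including one voucher number that differs between two source tables; the
  tables are worked-example data, not a nomenclaturally validated taxonomy.
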