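# Seeded simulators for every input the pipeline consumes: reference
# databases with a taxonomic hierarchy and non-target decoys, specimen read
# pairs (optionally heterozygous), and whole cohorts with controlled defect
# profiles. Divergence between reference taxa is substitution-only so that
# identity arithmetic stays exact; indels occur only inside the
# heterozygote simulation. All randomness flows through one seeded stream
# per call and the caller's RNG state is left untouched.

.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister")
  force(expr)
}

.random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitution-only mutation at the given per-base rate
.mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(ch)) < rate)
  for (i in hit) {
    ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  }
  paste(ch, collapse = "")
}

#' Simulation settings for synthetic references, specimens and cohorts
#'
#' @param seed Integer seed; a fixed seed gives byte-identical outputs.
#' @param n_orders,genera_per_order,species_per_genus Shape of the
#'   simulated target-phylum taxonomy (one family per genus).
#' @param n_decoys Number of non-target-phylum decoy references.
#' @param locus_lengths Named locus lengths in bases.
#' @param between_genus_divergence,within_genus_divergence Substitution
#'   fractions applied when deriving genus and species sequences.
#' @param specimen_mutation_rate Per-base substitution rate from reference
#'   to specimen template.
#' @param read_fraction Fraction of the template covered by each read
#'   (from opposite ends; 0.9 leaves a generous overlap).
#' @param tail_noise_len,tail_noise_rate Length of the simulated dirty read
#'   tail and the per-base probability of an `N` inside it.
#' @param target_phylum,decoy_phylum Phylum labels for references/decoys.
#' @return A list of class `sip_sim_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_orders = 4L,
                              genera_per_order = 2L,
                              species_per_genus = 4L,
                              n_decoys = 5L,
                              locus_lengths = c(COI = 680L, `28S` = 1000L,
                                                ITS = 600L),
                              between_genus_divergence = 0.10,
                              within_genus_divergence = 0.02,
                              specimen_mutation_rate = 0.01,
                              read_fraction = 0.9,
                              tail_noise_len = 30L,
                              tail_noise_rate = 0.5,
                              target_phylum = "Porifera",
                              decoy_phylum = "Chordata") {
  stopifnot(between_genus_divergence >= 0, between_genus_divergence <= 0.5,
            within_genus_divergence >= 0, within_genus_divergence <= 0.5,
            specimen_mutation_rate >= 0, read_fraction > 0.5,
            read_fraction <= 1)
  structure(as.list(environment()), class = "sip_sim_config")
}

#' Simulate a taxonomy-annotated reference database for one locus
#'
#' A root sequence is drawn per simulated order; genus representatives
#' diverge from it by `between_genus_divergence` substitutions and species
#' by a further `within_genus_divergence`. Non-target decoy references
#' (independent random sequences under `decoy_phylum`) are appended so that
#' the phylum screen has something to catch.
#'
#' @param cfg A [simulation_config()].
#' @param locus Locus to simulate (`names(cfg$locus_lengths)`).
#' @return A list with `sequences` (accession, sequence), `taxonomy`
#'   (accession + lineage ranks), ready for [build_reference_db()].
#' @export
simulate_reference_db <- function(cfg, locus = "COI") {
  stopifnot(inherits(cfg, "sip_sim_config"),
            locus %in% names(cfg$locus_lengths))
  len <- as.integer(cfg$locus_lengths[[locus]])
  .with_seed(cfg$seed + match(locus, names(cfg$locus_lengths)), {
    seqs <- list(); tax <- list()
    acc_i <- 0L
    for (o in seq_len(cfg$n_orders)) {
      root <- .random_seq(len)
      for (g in seq_len(cfg$genera_per_order)) {
        genus_seq <- .mutate_seq(root, cfg$between_genus_divergence)
        for (s in seq_len(cfg$species_per_genus)) {
          acc_i <- acc_i + 1L
          acc <- sprintf("SIM%04d", acc_i)
          seqs[[acc]] <- .mutate_seq(genus_seq, cfg$within_genus_divergence)
          tax[[acc]] <- tibble::tibble(
            accession = acc, phylum = cfg$target_phylum,
            order = sprintf("Simorder%d", o),
            family = sprintf("Simfamily%d_%d", o, g),
            genus = sprintf("Simgenus%d_%d", o, g),
            species = sprintf("simspecies%d_%d_%d", o, g, s))
        }
      }
    }
    for (k in seq_len(cfg$n_decoys)) {
      acc_i <- acc_i + 1L
      acc <- sprintf("SIM%04d", acc_i)
      seqs[[acc]] <- .random_seq(len)
      tax[[acc]] <- tibble::tibble(
        accession = acc, phylum = cfg$decoy_phylum,
        order = "Decoyorder", family = "Decoyfamily",
        genus = "Decoygenus", species = sprintf("decoyspecies%d", k))
    }
    list(
      sequences = tibble::tibble(accession = names(seqs),
                                 sequence = unlist(seqs, use.names = FALSE)),
      taxonomy = dplyr::bind_rows(tax)
    )
  })
}

.add_tail_noise <- function(seq, noise_len, rate) {
  n <- nchar(seq)
  if (noise_len <= 0 || rate <= 0 || n <= noise_len) return(seq)
  ch <- strsplit(seq, "")[[1]]
  zone <- (n - noise_len + 1L):n
  hit <- zone[stats::runif(length(zone)) < rate]
  ch[hit] <- "N"
  paste(ch, collapse = "")
}

#' Simulate a specimen read pair from a reference sequence
#'
#' The specimen template is the reference mutated at
#' `specimen_mutation_rate`; the forward read covers the template's 5' side
#' and the reverse read (returned in its own orientation) its 3' side, each
#' spanning `read_fraction` of the template, with a dirty `N`-bearing tail
#' appended to mimic the degrading end of a Sanger trace. `het = "point"`
#' superposes a second allele differing by one substitution; `het =
#' "length_variant"` superposes an allele carrying an insertion of
#' `indel_len` bases at an interior position (full-length clean reads, the
#' regime in which deconvolution is attempted).
#'
#' @param cfg A [simulation_config()].
#' @param ref_seq Reference sequence string.
#' @param specimen_id Id for the returned row.
#' @param het One of `"none"`, `"point"`, `"length_variant"`.
#' @param indel_len Insertion length for length-variant heterozygotes.
#' @param seed Stream seed for this specimen.
#' @return A one-row tibble: `specimen_id`, `forward_seq`, `reverse_seq`,
#'   `het_truth`, plus `allele_a`/`allele_b` (the simulated truth, `NA`
#'   when homozygous).
#' @export
simulate_specimen <- function(cfg, ref_seq, specimen_id = "SP1",
                              het = c("none", "point", "length_variant"),
                              indel_len = 1L, seed = cfg$seed) {
  het <- match.arg(het)
  .with_seed(seed, {
    template <- .mutate_seq(ref_seq, cfg$specimen_mutation_rate)
    L <- nchar(template)
    if (het == "none") {
      rl <- ceiling(cfg$read_fraction * L)
      fwd <- substr(template, 1L, rl)
      rev <- revcomp(substr(template, L - rl + 1L, L))
      fwd <- .add_tail_noise(fwd, cfg$tail_noise_len, cfg$tail_noise_rate)
      rev <- .add_tail_noise(rev, cfg$tail_noise_len, cfg$tail_noise_rate)
      return(tibble::tibble(specimen_id = specimen_id, forward_seq = fwd,
                            reverse_seq = rev, het_truth = "homozygous",
                            allele_a = NA_character_,
                            allele_b = NA_character_))
    }
    if (het == "point") {
      pos <- sample(seq(10L, L - 10L), 1)
      ch <- strsplit(template, "")[[1]]
      alt <- ch
      alt[pos] <- sample(setdiff(c("A", "C", "G", "T"), ch[pos]), 1)
      other <- paste(alt, collapse = "")
      sp <- superpose_alleles(template, other)
      truth <- "point_het"
      pair <- sort(c(template, other))
    } else {
      # insertion at an interior position, away from both read ends so the
      # superposition signature is visible in both reads
      pos <- sample(seq(floor(L * 0.3), floor(L * 0.7)), 1)
      ins <- .random_seq(indel_len)
      other <- paste0(substr(template, 1, pos), ins,
                      substr(template, pos + 1L, L))
      sp <- superpose_alleles(template, other)
      truth <- "length_variant_het"
      pair <- c(template, other) # allele_a the shorter
    }
    tibble::tibble(specimen_id = specimen_id, forward_seq = sp$forward,
                   reverse_seq = sp$reverse, het_truth = truth,
                   allele_a = pair[1], allele_b = pair[2])
  })
}

#' Simulate a sequencing cohort with a controlled defect profile
#'
#' Generates `n_pairs` specimen read pairs for one locus from a simulated
#' reference database and injects the requested defects at seeded
#' positions: `n_non_target` pairs get a forward read derived from a decoy
#' (non-target phylum) reference, and `n_short` pairs get a forward read
#' truncated to `short_len` bases. The default profile mirrors a typical
#' direct-sequencing cohort in which a batch of 31 amplicon pairs loses one
#' pair to a contaminant forward read and one to a 170-bp forward read.
#'
#' @param seed Integer seed.
#' @param n_pairs Number of read pairs.
#' @param n_non_target,n_short Defect counts.
#' @param short_len Length of the truncated forward read(s).
#' @param locus Simulated locus.
#' @param cfg Optional [simulation_config()] (its seed is overridden).
#' @return A list with `pairs` (specimen_id, locus, forward_seq,
#'   reverse_seq), `reference` (sequences + taxonomy), and `truth`
#'   (specimen_id, defect, accession).
#' @export
make_cohort_fixture <- function(seed = 1L, n_pairs = 31L,
                                n_non_target = 1L, n_short = 1L,
                                short_len = 170L, locus = "COI",
                                cfg = NULL) {
  if (is.null(cfg)) cfg <- simulation_config(seed = seed)
  cfg$seed <- as.integer(seed)
  ref <- simulate_reference_db(cfg, locus)
  target_acc <- ref$taxonomy$accession[ref$taxonomy$phylum ==
                                         cfg$target_phylum]
  decoy_acc <- ref$taxonomy$accession[ref$taxonomy$phylum !=
                                        cfg$target_phylum]
  if (n_pairs > 0 && length(target_acc) == 0L) {
    rlang::abort("no target references simulated",
                 class = "spongeid_sim_error")
  }
  .with_seed(cfg$seed + 1000L, {
    use_acc <- sample(target_acc, n_pairs, replace =
                        n_pairs > length(target_acc))
    rows <- list(); truth <- list()
    defect_ids <- if (n_pairs > 0) {
      sample(n_pairs, min(n_pairs, n_non_target + n_short))
    } else integer(0)
    nt_ids <- utils::head(defect_ids, n_non_target)
    sh_ids <- utils::head(setdiff(defect_ids, nt_ids), n_short)
    for (i in seq_len(n_pairs)) {
      id <- sprintf("SYN%03d", i)
      ref_seq <- ref$sequences$sequence[ref$sequences$accession == use_acc[i]]
      sp <- simulate_specimen(cfg, ref_seq, id, het = "none",
                              seed = cfg$seed + 2000L + i)
      defect <- "none"
      if (i %in% nt_ids) {
        defect <- "non_target"
        dec_acc <- decoy_acc[1L + (match(i, nt_ids) - 1L) %% length(decoy_acc)]
        dec_seq <- ref$sequences$sequence[ref$sequences$accession == dec_acc]
        dsp <- simulate_specimen(cfg, dec_seq, id, het = "none",
                                 seed = cfg$seed + 3000L + i)
        sp$forward_seq <- dsp$forward_seq
      } else if (i %in% sh_ids) {
        defect <- "short_read"
        sp$forward_seq <- substr(sp$forward_seq, 1L, short_len)
      }
      rows[[i]] <- tibble::tibble(specimen_id = id, locus = locus,
                                  forward_seq = sp$forward_seq,
                                  reverse_seq = sp$reverse_seq)
      truth[[i]] <- tibble::tibble(specimen_id = id, defect = defect,
                                   accession = use_acc[i])
    }
    list(pairs = dplyr::bind_rows(rows), reference = ref,
         truth = dplyr::bind_rows(truth))
  })
}

#' Write a simulated cohort to FASTA/TSV files
#'
#' Emits the same dialects the pipeline consumes: a reads FASTA plus
#' manifest TSV (for [load_read_pairs()]), the reference FASTA and taxonomy
#' TSV (for [build_reference_db()]), and the ground-truth TSV.
#'
#' @param cohort Output of [make_cohort_fixture()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_files <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- cohort$pairs
  reads <- Biostrings::DNAStringSet(c(
    stats::setNames(p$forward_seq, paste0(p$specimen_id, "_", p$locus, "_F")),
    stats::setNames(p$reverse_seq, paste0(p$specimen_id, "_", p$locus, "_R"))
  ))
  Biostrings::writeXStringSet(reads, file.path(dir, "reads.fasta"))
  manifest <- dplyr::bind_rows(
    tibble::tibble(record_id = paste0(p$specimen_id, "_", p$locus, "_F"),
                   specimen_id = p$specimen_id, locus = p$locus,
                   direction = "F"),
    tibble::tibble(record_id = paste0(p$specimen_id, "_", p$locus, "_R"),
                   specimen_id = p$specimen_id, locus = p$locus,
                   direction = "R"))
  readr::write_tsv(manifest, file.path(dir, "manifest.tsv"), progress = FALSE)
  refs <- Biostrings::DNAStringSet(stats::setNames(
    cohort$reference$sequences$sequence,
    cohort$reference$sequences$accession))
  Biostrings::writeXStringSet(refs, file.path(dir, "reference.fasta"))
  readr::write_tsv(cohort$reference$taxonomy,
                   file.path(dir, "taxonomy.tsv"), progress = FALSE)
  readr::write_tsv(cohort$truth, file.path(dir, "truth.tsv"),
                   progress = FALSE)
  invisible(dir)
}
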