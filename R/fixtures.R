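# Synthetic mock communities with known ground truth.
#
# These generators exist so every pipeline stage is testable without any
# download: genomes embed known primer-flanked operons at known coordinates,
# and the truth table records exactly what in-silico PCR should recover.

#' Specification of a synthetic mock community
#'
#' @param n_genomes Number of genomes.
#' @param operons_per_genome Integer vector of rRNA-operon copy numbers,
#'   recycled to `n_genomes`. Copies of an operon within a genome may
#'   diverge, yielding several ASVs per genome (the "amplitype").
#' @param asv_core_length Length (bp) of the random core between the primer
#'   footprints.
#' @param intra_genome_divergence Per-base substitution probability applied
#'   to the core of operon copies 2..k relative to copy 1. In `[0, 0.2]`.
#' @param intergenic_length Length (bp) of random spacer between operons.
#' @param seed Integer seed; a fixed seed gives byte-identical fixtures.
#' @return A `hifisim_community_spec` list.
#' @export
mock_community_spec <- function(n_genomes = 3,
                                operons_per_genome = 3,
                                asv_core_length = 300,
                                intra_genome_divergence = 0.02,
                                intergenic_length = 400,
                                seed = 1L) {
  operons_per_genome <- rep_len(as.integer(operons_per_genome), n_genomes)
  stopifnot(
    n_genomes >= 1,
    all(operons_per_genome >= 1),
    intra_genome_divergence >= 0, intra_genome_divergence <= 0.2,
    asv_core_length > 0, intergenic_length > 0
  )
  structure(
    list(n_genomes = as.integer(n_genomes),
         operons_per_genome = operons_per_genome,
         asv_core_length = as.integer(asv_core_length),
         intra_genome_divergence = intra_genome_divergence,
         intergenic_length = as.integer(intergenic_length),
         seed = as.integer(seed)),
    class = "hifisim_community_spec"
  )
}

#' Generate one mock genome with embedded amplicons and its truth table
#'
#' The genome is random intergenic spacer interleaved with operon copies.
#' Each operon is a concrete realization of the forward primer, a random
#' core, and the reverse complement of a realization of the reverse primer;
#' degenerate primer positions are instantiated per operon so extraction
#' must genuinely handle IUPAC matching. Copies 2..k carry substitutions in
#' the core at rate `intra_genome_divergence` relative to copy 1.
#'
#' @param spec A [mock_community_spec()].
#' @param genome_index Which genome of the community to generate (1-based).
#' @param fwd_primer,rev_primer IUPAC primer strings.
#' @param minus_strand_prob Probability that an operon is embedded on the
#'   reverse strand (default 0: forward only).
#' @return A list with `genome` (one-row tibble: `id`, `seq`, `description`)
#'   and `truth` (tibble: `genome_id`, `start`, `end`, `strand`,
#'   `product_seq`, `insert_seq`; 0-based half-open coordinates on the
#'   forward strand; `product_seq` is primer-inclusive in amplicon
#'   orientation).
#' @export
generate_mock_genome <- function(spec, genome_index, fwd_primer, rev_primer,
                                 minus_strand_prob = 0) {
  stopifnot(inherits(spec, "hifisim_community_spec"),
            genome_index >= 1, genome_index <= spec$n_genomes)
  fwd_primer <- toupper(fwd_primer); rev_primer <- toupper(rev_primer)
  .check_iupac(c(fwd_primer, rev_primer), "primer")
  if (spec$asv_core_length < nchar(fwd_primer) + nchar(rev_primer) + 10) {
    stop("asv_core_length must be at least combined primer length + 10",
         call. = FALSE)
  }
  k <- spec$operons_per_genome[[genome_index]]
  gid <- paste0("g", genome_index)
  .with_seed(.substream(spec$seed, paste0("genome", genome_index)), {
    base_core <- .random_dna(spec$asv_core_length)
    # primers are realized once per genome, so copies at zero divergence
    # are identical; realizations still differ across genomes, exercising
    # IUPAC matching at extraction
    fwd_real <- realize_iupac(fwd_primer)
    rev_real <- realize_iupac(rev_primer)
    operons <- character(k)
    for (i in seq_len(k)) {
      core <- base_core
      if (i > 1 && spec$intra_genome_divergence > 0) {
        chars <- strsplit(core, "", fixed = TRUE)[[1]]
        hit <- which(runif(length(chars)) < spec$intra_genome_divergence)
        for (j in hit) {
          chars[j] <- sample(setdiff(c("A", "C", "G", "T"), chars[j]), 1)
        }
        core <- paste(chars, collapse = "")
      }
      operons[i] <- paste0(fwd_real, core,
                           reverse_complement(rev_real))
    }
    strands <- ifelse(runif(k) < minus_strand_prob, "-", "+")
    pieces <- character(2 * k + 1)
    starts <- integer(k); ends <- integer(k)
    pos <- 0L
    for (i in seq_len(k)) {
      spacer <- .random_dna(spec$intergenic_length)
      pieces[2 * i - 1] <- spacer
      pos <- pos + nchar(spacer)
      embedded <- if (strands[i] == "+") operons[i] else
        reverse_complement(operons[i])
      pieces[2 * i] <- embedded
      starts[i] <- pos
      pos <- pos + nchar(embedded)
      ends[i] <- pos
    }
    pieces[2 * k + 1] <- .random_dna(spec$intergenic_length)
    genome_seq <- paste(pieces, collapse = "")
    insert <- substr(operons, nchar(fwd_primer) + 1,
                     nchar(operons) - nchar(rev_primer))
    list(
      genome = tibble::tibble(
        id = gid, seq = genome_seq,
        description = sprintf("synthetic mock genome, %d operon copies", k)
      ),
      truth = tibble::tibble(
        genome_id = gid, start = starts, end = ends, strand = strands,
        product_seq = operons, insert_seq = insert
      )
    )
  })
}

#' Generate a whole mock community
#'
#' @inheritParams generate_mock_genome
#' @return A list with `genomes` (tibble of FASTA-ready records) and
#'   `truth` (row-bound truth tables from [generate_mock_genome()]).
#' @export
generate_mock_community <- function(spec, fwd_primer, rev_primer,
                                    minus_strand_prob = 0) {
  out <- purrr::map(seq_len(spec$n_genomes), function(i) {
    generate_mock_genome(spec, i, fwd_primer, rev_primer, minus_strand_prob)
  })
  list(
    genomes = purrr::list_rbind(purrr::map(out, "genome")),
    truth = purrr::list_rbind(purrr::map(out, "truth"))
  )
}

#' Generate a dual-barcode table for n samples
#'
#' Barcode pairs are random, distinct across samples, and concrete DNA
#' (16 bp by default, the usual PacBio barcode length).
#'
#' @param n_samples Number of samples.
#' @param barcode_length Barcode length in bp.
#' @param seed Integer seed.
#' @return Tibble with `sample_id`, `fwd_barcode`, `rev_barcode`.
#' @export
generate_barcode_table <- function(n_samples, barcode_length = 16L, seed = 1L) {
  stopifnot(n_samples >= 1, barcode_length >= 4)
  .with_seed(.substream(seed, "barcodes"), {
    draw <- function(n) vapply(seq_len(n), function(i) .random_dna(barcode_length),
                               character(1))
    fwd <- draw(n_samples); rev <- draw(n_samples)
    while (anyDuplicated(paste(fwd, rev))) {
      i <- which(duplicated(paste(fwd, rev)))
      fwd[i] <- draw(length(i)); rev[i] <- draw(length(i))
    }
    validate_barcodes(tibble::tibble(
      sample_id = paste0("S", seq_len(n_samples)),
      fwd_barcode = fwd, rev_barcode = rev
    ))
  })
}

#' Generate a synthetic empirical pass-number histogram
#'
#' Draws pass numbers from a truncated, discretized lognormal and tabulates
#' them, producing the TSV-shaped histogram a real instrument run would
#' yield. Stand-in for extraction from a real sequencing run.
#'
#' @param n_draws Number of molecules to draw.
#' @param meanlog,sdlog Lognormal parameters on the log scale.
#' @param np_min,np_max Truncation range (inclusive).
#' @param seed Integer seed.
#' @return Tibble with `np`, `count`; counts sum to `n_draws`.
#' @export
generate_empirical_np_table <- function(n_draws, meanlog = 2.3, sdlog = 0.5,
                                        np_min = 2L, np_max = 59L, seed = 1L) {
  stopifnot(n_draws > 0)
  dist <- np_lognormal(meanlog = meanlog, sdlog = sdlog,
                       np_min = np_min, np_max = np_max)
  draws <- sample_np(dist, n_draws, seed = .substream(seed, "np_table"))
  tab <- table(draws)
  tibble::tibble(np = as.integer(names(tab)), count = as.numeric(tab))
}
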