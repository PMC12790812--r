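# In-silico PCR: locate degenerate-primer binding sites on both strands and
# extract amplicons with copy numbers and amplitype patterns.

#' Match a degenerate primer against a genome window
#'
#' Position i mismatches iff the window base is not in the degeneracy set
#' of the primer base; an N in the genome matches nothing except a primer
#' N (which is a wildcard).
#'
#' @param primer IUPAC primer string.
#' @param window Genome window of the same length (may be a character
#'   vector of windows).
#' @param max_mismatch Mismatch budget.
#' @return Tibble with `matches` (logical) and `n_mismatch` (integer), one
#'   row per window.
#' @export
iupac_match <- function(primer, window, max_mismatch = 0L) {
  primer <- toupper(primer); window <- toupper(window)
  .check_iupac(primer, "primer")
  if (any(nchar(window) != nchar(primer))) {
    stop("window length must equal primer length", call. = FALSE)
  }
  pchars <- strsplit(primer, "", fixed = TRUE)[[1]]
  mm <- vapply(window, function(w) {
    wchars <- strsplit(w, "", fixed = TRUE)[[1]]
    sum(vapply(seq_along(pchars), function(i) {
      !(wchars[i] %in% .iupac_sets[[pchars[i]]])
    }, logical(1)))
  }, integer(1), USE.NAMES = FALSE)
  tibble::tibble(matches = mm <= max_mismatch, n_mismatch = mm)
}

# Vectorized scan of one strand: all 0-based offsets where `primer` matches
# within the budget, plus the mismatch count at each.
#' @noRd
.scan_primer <- function(genome_chars, primer, max_mismatch) {
  m <- nchar(primer)
  n <- length(genome_chars)
  if (n < m) {
    return(tibble::tibble(start = integer(0), mismatches = integer(0)))
  }
  pchars <- strsplit(toupper(primer), "", fixed = TRUE)[[1]]
  n_off <- n - m + 1L
  mm <- integer(n_off)
  for (j in seq_len(m)) {
    ok <- genome_chars[j:(j + n_off - 1L)] %in% .iupac_sets[[pchars[j]]]
    mm <- mm + !ok
  }
  hit <- which(mm <= max_mismatch)
  tibble::tibble(start = hit - 1L, mismatches = mm[hit])
}

#' @noRd
.extract_one_strand <- function(genome_seq, fwd_primer, rev_primer,
                                max_mismatch, min_len, max_len) {
  chars <- strsplit(genome_seq, "", fixed = TRUE)[[1]]
  f_len <- nchar(fwd_primer); r_len <- nchar(rev_primer)
  fwd_sites <- .scan_primer(chars, fwd_primer, max_mismatch)
  rev_sites <- .scan_primer(chars, reverse_complement(rev_primer),
                            max_mismatch)
  if (nrow(fwd_sites) == 0 || nrow(rev_sites) == 0) {
    return(tibble::tibble(start = integer(0), end = integer(0),
                          fwd_mismatches = integer(0),
                          rev_mismatches = integer(0),
                          product_seq = character(0)))
  }
  # all (fwd site, downstream reverse site) pairs within the length window;
  # nested/overlapping products are all reported
  pairs <- tidyr::expand_grid(fi = seq_len(nrow(fwd_sites)),
                              ri = seq_len(nrow(rev_sites)))
  s <- fwd_sites$start[pairs$fi]
  e <- rev_sites$start[pairs$ri] + r_len
  len <- e - s
  keep <- (rev_sites$start[pairs$ri] >= s + f_len) &
    len >= min_len & len <= max_len
  pairs <- pairs[keep, ]; s <- s[keep]; e <- e[keep]
  tibble::tibble(
    start = s, end = e,
    fwd_mismatches = fwd_sites$mismatches[pairs$fi],
    rev_mismatches = rev_sites$mismatches[pairs$ri],
    product_seq = substring(genome_seq, s + 1L, e)
  )
}

#' Extract amplicons from genomes by in-silico PCR
#'
#' Finds every pairing of a forward-primer site with a downstream
#' reverse-primer site (as its reverse complement) on the plus strand, and
#' the symmetric pairings on the minus strand. Products are reported 5'->3'
#' from the forward primer; minus-strand products carry plus-strand
#' coordinates with `strand == "-"`. Identical product sequences within a
#' genome collapse into one ASV (`asv_id = <genome>.asv<k>`, numbered by
#' first occurrence along the genome).
#'
#' The stored `insert_seq` is the primer-exclusive insert used for template
#' building; `product_seq` (primer-inclusive) is what the length window
#' applies to.
#'
#' @param genomes Tibble with `id`, `seq` (e.g. from [read_fasta()]).
#' @param fwd_primer,rev_primer IUPAC primer strings.
#' @param max_mismatch Per-primer mismatch budget (default 2).
#' @param min_len,max_len Product length window (primer-inclusive);
#'   defaults impose no filter.
#' @return Tibble with one row per amplicon: `genome_id`, `asv_id`,
#'   `start`, `end` (0-based half-open), `strand`, `fwd_mismatches`,
#'   `rev_mismatches`, `product_seq`, `insert_seq`.
#' @export
extract_amplicons <- function(genomes, fwd_primer, rev_primer,
                              max_mismatch = 2L, min_len = 0, max_len = Inf) {
  stopifnot(all(c("id", "seq") %in% names(genomes)), min_len <= max_len)
  fwd_primer <- toupper(fwd_primer); rev_primer <- toupper(rev_primer)
  .check_iupac(c(fwd_primer, rev_primer), "primer")
  f_len <- nchar(fwd_primer); r_len <- nchar(rev_primer)
  per_genome <- purrr::map(seq_len(nrow(genomes)), function(g) {
    gseq <- toupper(genomes$seq[[g]])
    glen <- nchar(gseq)
    plus <- .extract_one_strand(gseq, fwd_primer, rev_primer,
                                max_mismatch, min_len, max_len)
    plus$strand <- rep("+", nrow(plus))
    minus <- .extract_one_strand(reverse_complement(gseq), fwd_primer,
                                 rev_primer, max_mismatch, min_len, max_len)
    if (nrow(minus) > 0) {
      # map coordinates on the reverse strand back to plus-strand space
      tmp_start <- glen - minus$end
      minus$end <- glen - minus$start
      minus$start <- tmp_start
      minus$strand <- "-"
    } else {
      minus$strand <- character(0)
    }
    amp <- dplyr::bind_rows(plus, minus)
    if (nrow(amp) == 0) return(amp)
    amp$genome_id <- genomes$id[[g]]
    amp <- dplyr::arrange(amp, .data$start, .data$end, .data$strand)
    amp$insert_seq <- substr(amp$product_seq, f_len + 1L,
                             nchar(amp$product_seq) - r_len)
    asv_key <- match(amp$product_seq, unique(amp$product_seq))
    amp$asv_id <- paste0(genomes$id[[g]], ".asv", asv_key)
    amp
  })
  out <- purrr::list_rbind(per_genome)
  if (nrow(out) == 0) {
    return(tibble::tibble(genome_id = character(0), asv_id = character(0),
                          start = integer(0), end = integer(0),
                          strand = character(0), fwd_mismatches = integer(0),
                          rev_mismatches = integer(0),
                          product_seq = character(0),
                          insert_seq = character(0)))
  }
  out[, c("genome_id", "asv_id", "start", "end", "strand",
          "fwd_mismatches", "rev_mismatches", "product_seq", "insert_seq")]
}

#' Collapse amplicons into the per-genome ASV catalog
#'
#' @param amplicons Tibble from [extract_amplicons()].
#' @return Tibble with one row per unique ASV: `asv_id`, `genome_id`,
#'   `insert_seq`, `product_seq`, `multiplicity`. Multiplicities within a
#'   genome sum to its amplicon count.
#' @export
asv_catalog <- function(amplicons) {
  if (nrow(amplicons) == 0) {
    return(tibble::tibble(asv_id = character(0), genome_id = character(0),
                          insert_seq = character(0),
                          product_seq = character(0),
                          multiplicity = integer(0)))
  }
  out <- dplyr::summarise(
    dplyr::group_by(amplicons, .data$genome_id, .data$asv_id),
    insert_seq = .data$insert_seq[[1]],
    product_seq = .data$product_seq[[1]],
    multiplicity = dplyr::n(),
    .groups = "drop"
  )
  dplyr::arrange(out, .data$genome_id, .data$asv_id)[
    , c("asv_id", "genome_id", "insert_seq", "product_seq", "multiplicity")]
}

#' Amplitype signature of each genome
#'
#' The multiset of unique-ASV multiplicities, sorted descending and joined
#' with `+` (e.g. a genome with ASVs of multiplicity 3, 2 and 1 has
#' amplitype `"3+2+1"`).
#'
#' @param amplicons Tibble from [extract_amplicons()] (or an
#'   [asv_catalog()]).
#' @return Tibble with `genome_id`, `amplitype`.
#' @export
amplitype <- function(amplicons) {
  if (nrow(amplicons) == 0) {
    return(tibble::tibble(genome_id = character(0), amplitype = character(0)))
  }
  catalog <- if ("multiplicity" %in% names(amplicons)) amplicons else
    asv_catalog(amplicons)
  dplyr::summarise(
    dplyr::group_by(catalog, .data$genome_id),
    amplitype = paste(sort(.data$multiplicity, decreasing = TRUE),
                      collapse = "+"),
    .groups = "drop"
  )
}
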