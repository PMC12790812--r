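# IUPAC nucleotide primitives shared by every stage of the simulator.

#' @noRd
.iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"),
  # N in a primer is a wildcard; it also matches a literal N in the genome.
  N = c("A", "C", "G", "T", "N")
)

.iupac_alphabet <- names(.iupac_sets)

#' @noRd
.complement_map <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", V = "B", D = "H", H = "D", N = "N"
)

#' @noRd
.check_iupac <- function(seq, what = "sequence") {
  bad <- setdiff(unique(strsplit(paste(seq, collapse = ""), "", fixed = TRUE)[[1]]),
                 .iupac_alphabet)
  if (length(bad) > 0) {
    stop(sprintf("%s contains non-IUPAC DNA characters: %s",
                 what, paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(seq)
}

#' Reverse complement of DNA sequences with IUPAC degeneracies
#'
#' Complements every base (including degeneracy codes, e.g. R <-> Y,
#' M <-> K, B <-> V) and reverses the string. Only DNA is accepted:
#' `U` or any non-IUPAC character is an error.
#'
#' @param seq Character vector of DNA strings (IUPAC alphabet, any case).
#' @return Character vector of reverse complements, upper-cased.
#' @examples
#' reverse_complement("ACGT")
#' reverse_complement("AGRGTTYGATYMTGGCTCAG")
#' @export
reverse_complement <- function(seq) {
  if (length(seq) == 0) return(character(0))
  seq <- toupper(seq)
  .check_iupac(seq)
  comp <- chartr(paste(names(.complement_map), collapse = ""),
                 paste(unname(.complement_map), collapse = ""),
                 seq)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Instantiate degenerate IUPAC positions to concrete bases
#'
#' Each degenerate position is replaced by a base drawn uniformly from its
#' degeneracy set (N draws from A/C/G/T). Uses the current RNG stream.
#'
#' @param seq A single IUPAC DNA string.
#' @return A concrete DNA string over A/C/G/T.
#' @export
realize_iupac <- function(seq) {
  stopifnot(length(seq) == 1)
  seq <- toupper(seq)
  .check_iupac(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  out <- vapply(chars, function(ch) {
    set <- setdiff(.iupac_sets[[ch]], "N")
    if (length(set) == 1) set else sample(set, 1)
  }, character(1), USE.NAMES = FALSE)
  paste(out, collapse = "")
}

#' @noRd
.phred_to_string <- function(q) {
  rawToChar(as.raw(pmin(as.integer(q), 93L) + 33L))
}

#' @noRd
.string_to_phred <- function(s) {
  as.integer(charToRaw(s)) - 33L
}

# Deterministic substream seeds: run seed -> stage/unit seed, so adding
# samples or ZMWs never perturbs earlier units' draws and per-unit work can
# be distributed across workers without changing results.
#' @noRd
.substream <- function(seed, key) {
  m <- 2147483647
  h <- 0
  for (k in utf8ToInt(as.character(key))) h <- (h * 131 + k) %% m
  as.integer((((seed %% m) * 48271) %% m + h) %% m)
}

# Evaluate code under a temporary RNG seed, restoring the caller's stream.
#' @noRd
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' @noRd
.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
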