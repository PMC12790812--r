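# Shared fixture builders. Primers are the full-length 16S pair used
# throughout: 27F / 1492R.
FWD_PRIMER <- "AGRGTTYGATYMTGGCTCAG"
REV_PRIMER <- "RGYTACCTTGTTACGACTT"

# A small community with known truth; product length = core + both primers.
make_community <- function(n_genomes = 2, operons = 3, core = 120,
                           divergence = 0.02, seed = 11,
                           minus_strand_prob = 0) {
  spec <- mock_community_spec(
    n_genomes = n_genomes, operons_per_genome = operons,
    asv_core_length = core, intra_genome_divergence = divergence,
    intergenic_length = 150, seed = seed
  )
  cm <- generate_mock_community(spec, FWD_PRIMER, REV_PRIMER,
                                minus_strand_prob = minus_strand_prob)
  cm$spec <- spec
  cm$product_len <- core + nchar(FWD_PRIMER) + nchar(REV_PRIMER)
  cm
}

# Independent per-character IUPAC matcher used as an oracle against the
# production scanner.
oracle_scan <- function(genome, primer, max_mismatch) {
  sets <- list(A = "A", C = "C", G = "G", T = "T",
               R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"),
               W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
               B = c("C", "G", "T"), D = c("A", "G", "T"),
               H = c("A", "C", "T"), V = c("A", "C", "G"),
               N = c("A", "C", "G", "T", "N"))
  g <- strsplit(genome, "")[[1]]
  p <- strsplit(primer, "")[[1]]
  m <- length(p)
  hits <- integer(0); mms <- integer(0)
  for (s in seq_len(length(g) - m + 1)) {
    mm <- 0
    for (j in seq_len(m)) {
      if (!(g[s + j - 1] %in% sets[[p[j]]])) mm <- mm + 1
    }
    if (mm <= max_mismatch) { hits <- c(hits, s - 1L); mms <- c(mms, mm) }
  }
  list(start = hits, mismatches = mms)
}

# Independent quadratic-DP Levenshtein oracle (unit costs).
oracle_levenshtein <- function(a, b) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  prev <- 0:m
  for (i in seq_len(n)) {
    cur <- numeric(m + 1); cur[1] <- i
    for (j in seq_len(m)) {
      cur[j + 1] <- min(prev[j] + (x[i] != y[j]), prev[j + 1] + 1, cur[j] + 1)
    }
    prev <- cur
  }
  prev[m + 1]
}
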