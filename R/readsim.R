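# Subread simulation and CCS-style consensus calling.
#
# Each molecule (ZMW) is read in np alternating-strand passes. Every pass
# walks the template base by base: with probability `accuracy` the base is
# emitted faithfully; otherwise an error type is chosen by the
# substitution:insertion:deletion weight ratio. An insertion emits a
# uniform random base and re-processes the current template base (so
# insertion run lengths are geometric); a deletion skips the base.

#' Subread error model
#'
#' @param accuracy Per-base probability of no error, in (0, 1]. Default
#'   0.65, the calibrated single-pass accuracy typical of CCS subreads.
#' @param error_ratio Non-negative weights for
#'   substitution : insertion : deletion, normalized internally. Default
#'   `c(6, 55, 39)`, the published PacBio RSII error-type ratio.
#' @param homopolymer_multiplier Multiplier (>= 1) applied to the ins+del
#'   weight mass inside homopolymer runs of length >= 3, renormalized
#'   per position. Default 1 (off).
#' @return A `hifisim_error_model` object.
#' @export
error_model <- function(accuracy = 0.65, error_ratio = c(6, 55, 39),
                        homopolymer_multiplier = 1) {
  stopifnot(accuracy > 0, accuracy <= 1, length(error_ratio) == 3,
            all(error_ratio >= 0), sum(error_ratio) > 0,
            homopolymer_multiplier >= 1)
  structure(
    list(accuracy = accuracy,
         weights = error_ratio / sum(error_ratio),
         homopolymer_multiplier = homopolymer_multiplier),
    class = "hifisim_error_model"
  )
}

#' @export
print.hifisim_error_model <- function(x, ...) {
  cat(sprintf(
    "<hifisim error model: accuracy %.3f, sub:ins:del = %.3f:%.3f:%.3f>\n",
    x$accuracy, x$weights[1], x$weights[2], x$weights[3]))
  invisible(x)
}

# Positions inside homopolymer runs of length >= 3 (logical vector).
#' @noRd
.homopolymer_mask <- function(chars) {
  r <- rle(chars)
  rep(r$lengths >= 3, r$lengths)
}

# Core error-injection walk over one concrete template string, using the
# current RNG stream. Returns the mutated sequence plus exact edit counts.
#' @noRd
.mutate_seq <- function(seq, model) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  acc <- model$accuracy
  w <- matrix(model$weights, nrow = n, ncol = 3, byrow = TRUE)
  if (model$homopolymer_multiplier > 1) {
    hp <- .homopolymer_mask(chars)
    w[hp, 2:3] <- w[hp, 2:3] * model$homopolymer_multiplier
    w <- w / rowSums(w)
  }
  p_err <- 1 - acc
  p_ins <- p_err * w[, 2]
  n_ins <- rgeom(n, prob = 1 - p_ins)
  # resolution of each template base, conditional on no further insertion
  u <- runif(n) * (1 - p_ins)
  res <- integer(n) # 0 match, 1 sub, 2 del
  res[u >= acc] <- 1L
  res[u >= acc + p_err * w[, 1]] <- 2L
  bases <- c("A", "C", "G", "T")
  out_main <- chars
  subs <- which(res == 1L)
  if (length(subs) > 0) {
    idx <- match(chars[subs], bases)
    shift <- sample.int(3, length(subs), replace = TRUE)
    out_main[subs] <- bases[((idx - 1L + shift) %% 4L) + 1L]
  }
  keep <- res != 2L
  total_ins <- sum(n_ins)
  ins_chars <- if (total_ins > 0) sample(bases, total_ins, replace = TRUE)
               else character(0)
  ins_pos <- rep.int(seq_len(n), n_ins)
  all_pos <- c(ins_pos, seq_len(n)[keep])
  all_pri <- c(rep.int(0L, total_ins), rep.int(1L, sum(keep)))
  all_chr <- c(ins_chars, out_main[keep])
  ord <- order(all_pos, all_pri)
  list(seq = paste(all_chr[ord], collapse = ""),
       n_match = sum(res == 0L), n_sub = sum(res == 1L),
       n_ins = total_ins, n_del = sum(res == 2L))
}

#' Simulate one subread pass over a template
#'
#' For the minus strand the walk operates on the reverse complement of the
#' template, so errors accrue in read orientation.
#'
#' @param template_seq Concrete DNA template string.
#' @param model An [error_model()].
#' @param strand `"+"` or `"-"`.
#' @param seed Optional integer seed.
#' @return One-row tibble with `strand`, `seq`, and exact injected-error
#'   counts `n_match`, `n_sub`, `n_ins`, `n_del`.
#' @export
mutate_pass <- function(template_seq, model = error_model(),
                        strand = c("+", "-"), seed = NULL) {
  strand <- match.arg(strand)
  stopifnot(nzchar(template_seq))
  walk_seq <- if (strand == "-") reverse_complement(template_seq) else
    toupper(template_seq)
  m <- .with_seed(seed, .mutate_seq(walk_seq, model))
  tibble::tibble(strand = strand, seq = m$seq, n_match = m$n_match,
                 n_sub = m$n_sub, n_ins = m$n_ins, n_del = m$n_del)
}

#' Simulate all passes of one ZMW
#'
#' Passes 1..np alternate strand (+, -, +, ...), each independently
#' mutated.
#'
#' @param template_seq Concrete DNA template string.
#' @param np Number of passes (>= 1).
#' @param model An [error_model()].
#' @param seed Optional integer seed.
#' @return Tibble of subreads with `pass_index`, `strand`, `seq` and error
#'   counts.
#' @export
simulate_zmw <- function(template_seq, np, model = error_model(),
                         seed = NULL) {
  if (np < 1) stop("np must be >= 1", call. = FALSE)
  .with_seed(seed, {
    out <- purrr::list_rbind(purrr::map(seq_len(np), function(i) {
      strand <- if (i %% 2 == 1) "+" else "-"
      mutate_pass(template_seq, model, strand)
    }))
    out$pass_index <- seq_len(np)
    out[, c("pass_index", "strand", "seq",
            "n_match", "n_sub", "n_ins", "n_del")]
  })
}

#' Call a CCS-style consensus from the subreads of one ZMW
#'
#' Subreads are oriented to the plus strand; the backbone is the medoid
#' (by edit distance) of up to `medoid_cap` evenly spaced subreads; every
#' subread is globally aligned to the backbone and each column (including
#' insertion columns observed in at least half the subreads) is called by
#' plurality vote. Per-base quality is
#' `min(qcap, round(-10 log10(max(eps, 1 - k/n))))` with k votes for the
#' winning symbol among n subreads. A single-subread ZMW returns that
#' subread with the fixed single-coverage quality, since agreement is
#' undefined at n = 1.
#'
#' @param subreads Tibble from [simulate_zmw()] (needs `strand`, `seq`).
#' @param template_length_hint Unused by the caller-facing algorithm;
#'   retained for interface symmetry with pipeline bookkeeping.
#' @param single_pass_qual Phred quality assigned when only one subread is
#'   available (default 20).
#' @param medoid_cap Number of evenly spaced subreads among which the
#'   backbone medoid is chosen (default 5).
#' @param eps,qcap Quality floor / cap (defaults 1e-10 and 93, the FASTQ
#'   `~` ceiling).
#' @return A list with `seq` (consensus string) and `qual` (integer Phred
#'   vector, same length).
#' @export
consensus <- function(subreads, template_length_hint = NULL,
                      single_pass_qual = 20L, medoid_cap = 5L,
                      eps = 1e-10, qcap = 93L) {
  stopifnot(nrow(subreads) >= 1,
            all(c("strand", "seq") %in% names(subreads)))
  seqs <- ifelse(subreads$strand == "-", reverse_complement(subreads$seq),
                 subreads$seq)
  if (length(seqs) == 1) {
    return(list(seq = seqs[[1]],
                qual = rep(as.integer(single_pass_qual), nchar(seqs[[1]]))))
  }
  cand <- unique(round(seq(1, length(seqs), length.out = min(length(seqs),
                                                             medoid_cap))))
  d <- adist(seqs[cand])
  backbone <- cand[which.min(rowSums(d))]
  .ccs_consensus(seqs, backbone, eps, as.integer(qcap))
}

#' Simulate the full read set for a list of templates
#'
#' One ZMW per template copy; the pass number is sampled per ZMW; each ZMW
#' uses a seed derived from the run seed and its global index, so results
#' are identical for any worker count and adding molecules never perturbs
#' earlier ones.
#'
#' @param templates Tibble from [assign_templates()] (`template_id`,
#'   `sample_id`, `genome_id`, `asv_id`, `seq`, `copies`).
#' @param np_dist A `hifisim_np` pass-number distribution.
#' @param model An [error_model()].
#' @param seed Integer run seed.
#' @param workers Number of parallel workers (forked; results are
#'   worker-count-invariant).
#' @param movie Movie name used in read ids; default derived from the
#'   seed.
#' @param single_pass_qual Passed to [consensus()].
#' @return Tibble of reads: `read_id` (`<movie>/<zmw>/ccs`), `sample_id`,
#'   `genome_id`, `asv_id`, `template_id`, `np`, `seq`, `qual` (Phred+33
#'   string), `template_len`.
#' @export
simulate_reads <- function(templates, np_dist = np_lognormal(),
                           model = error_model(), seed = 1L, workers = 1L,
                           movie = NULL, single_pass_qual = 20L) {
  stopifnot(nrow(templates) >= 1, inherits(np_dist, "hifisim_np"))
  if (is.null(movie)) {
    movie <- sprintf("m%06d_000000_000000", seed %% 1000000L)
  }
  idx <- rep.int(seq_len(nrow(templates)), templates$copies)
  n_zmw <- length(idx)
  one_zmw <- function(z) {
    t_row <- idx[[z]]
    .with_seed(.substream(seed, paste0("zmw", z)), {
      np <- sample_np(np_dist, 1)
      subreads <- simulate_zmw(templates$seq[[t_row]], np, model)
      cons <- consensus(subreads, single_pass_qual = single_pass_qual)
      tibble::tibble(
        read_id = sprintf("%s/%d/ccs", movie, z),
        sample_id = templates$sample_id[[t_row]],
        genome_id = templates$genome_id[[t_row]],
        asv_id = templates$asv_id[[t_row]],
        template_id = templates$template_id[[t_row]],
        np = as.integer(np),
        seq = cons$seq,
        qual = .phred_to_string(cons$qual),
        template_len = nchar(templates$seq[[t_row]])
      )
    })
  }
  res <- if (workers > 1L) {
    parallel::mclapply(seq_len(n_zmw), one_zmw, mc.cores = workers)
  } else {
    lapply(seq_len(n_zmw), one_zmw)
  }
  purrr::list_rbind(res)
}
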