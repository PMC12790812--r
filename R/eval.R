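# Evaluation metrics and the subread-accuracy calibration loop:
# edit-distance profiles against the reference ASVs, misassignment,
# expected-vs-observed abundance correlation, positional error profiles,
# and KL-divergence grid search over subread accuracy.

#' Nearest reference ASV by global edit distance
#'
#' Global (end-to-end, unit-cost Levenshtein) distance of every read to
#' every reference; ties broken by lexicographically smallest `asv_id`.
#'
#' @param reads Tibble with `read_id`, `seq` (or a character vector of
#'   sequences).
#' @param references Tibble with `asv_id`, `seq`.
#' @return Tibble with `read_id`, `min_edit_distance`, `nearest_asv_id`.
#' @export
nearest_reference <- function(reads, references) {
  if (is.character(reads)) {
    reads <- tibble::tibble(read_id = paste0("read", seq_along(reads)),
                            seq = reads)
  }
  stopifnot(nrow(references) >= 1,
            all(c("asv_id", "seq") %in% names(references)))
  references <- dplyr::arrange(references, .data$asv_id)
  d <- adist(reads$seq, references$seq)
  j <- apply(d, 1, which.min)
  tibble::tibble(
    read_id = reads$read_id,
    min_edit_distance = d[cbind(seq_len(nrow(d)), j)],
    nearest_asv_id = references$asv_id[j]
  )
}

#' Fraction of reads nearest to a wrong reference
#'
#' A read is correctly assigned when its true source ASV is among the
#' references at minimum distance (ties that include the truth count as
#' correct).
#'
#' @param reads Tibble with `seq` and true `asv_id`.
#' @param references Tibble with `asv_id`, `seq`.
#' @return Fraction misassigned, in `[0, 1]`.
#' @export
misassignment_rate <- function(reads, references) {
  stopifnot(all(c("seq", "asv_id") %in% names(reads)), nrow(reads) >= 1)
  d <- adist(reads$seq, references$seq)
  mis <- vapply(seq_len(nrow(d)), function(i) {
    best <- references$asv_id[d[i, ] == min(d[i, ])]
    !(reads$asv_id[[i]] %in% best)
  }, logical(1))
  mean(mis)
}

#' Kullback-Leibler divergence between two histograms
#'
#' `sum(p * log(p / q))` in nats over bins where `p > 0`. The histograms
#' must share their binning; `q` must be smoothed (see
#' [smooth_histogram()]) so it has no zero bin where `p > 0`.
#'
#' @param p,q Non-negative numeric vectors of equal length (normalized to
#'   sum 1; normalization is applied defensively).
#' @return Non-negative divergence in nats; 0 iff `p == q`.
#' @export
kl_divergence <- function(p, q) {
  if (length(p) != length(q)) stop("histogram bin mismatch", call. = FALSE)
  stopifnot(all(p >= 0), all(q >= 0), sum(p) > 0, sum(q) > 0)
  p <- p / sum(p); q <- q / sum(q)
  if (any(q == 0 & p > 0)) {
    stop("q has a zero bin where p > 0; smooth q first (smooth_histogram)",
         call. = FALSE)
  }
  keep <- p > 0
  sum(p[keep] * log(p[keep] / q[keep]))
}

#' Add-mass smoothing for a histogram
#'
#' @param q Non-negative numeric vector.
#' @param eps Mass added to every bin before renormalization.
#' @return Smoothed, normalized histogram with all bins > 0.
#' @export
smooth_histogram <- function(q, eps = 1e-9) {
  q <- q / sum(q) + eps
  q / sum(q)
}

# Unit-width bins over [0, d_max] plus one overflow bin.
#' @noRd
.hist_from_distances <- function(d, d_max) {
  counts <- tabulate(pmin(d, d_max + 1L) + 1L, nbins = d_max + 2L)
  as.numeric(counts)
}

#' Edit-distance profile of a read set against reference ASVs
#'
#' Reads outside the `[min_len, max_len]` length window are excluded
#' before any distance is computed, mirroring how evaluation metrics are
#' length-filtered in practice.
#'
#' @param reads Tibble with `read_id`, `seq` (extra provenance columns are
#'   carried through).
#' @param references Tibble with `asv_id`, `seq`.
#' @param min_len,max_len Read length window (defaults: no filter).
#' @param d_max Histogram upper edge; distances above it land in an
#'   overflow bin. Default: the maximum observed distance.
#' @return A `hifisim_edit_profile` object: list with `per_read` (tibble),
#'   `histogram` (tibble `distance`, `count`, `proportion`; the overflow
#'   bin is labelled `> d_max`), `n_input`, `n_filtered`, `min_len`,
#'   `max_len`, `d_max`.
#' @export
edit_distance_profile <- function(reads, references, min_len = 0,
                                  max_len = Inf, d_max = NULL) {
  stopifnot(all(c("read_id", "seq") %in% names(reads)))
  n_input <- nrow(reads)
  len <- nchar(reads$seq)
  reads <- reads[len >= min_len & len <= max_len, ]
  if (nrow(reads) == 0) stop("no reads within the length window", call. = FALSE)
  nn <- nearest_reference(reads, references)
  per_read <- dplyr::left_join(reads[, intersect(
    c("read_id", "sample_id", "genome_id", "asv_id", "np", "seq"),
    names(reads))], nn, by = "read_id")
  if (is.null(d_max)) d_max <- max(nn$min_edit_distance)
  counts <- .hist_from_distances(nn$min_edit_distance, d_max)
  structure(
    list(
      per_read = per_read,
      histogram = tibble::tibble(
        distance = c(as.character(0:d_max), paste0("> ", d_max)),
        count = counts,
        proportion = counts / sum(counts)
      ),
      n_input = n_input, n_filtered = n_input - nrow(reads),
      min_len = min_len, max_len = max_len, d_max = as.integer(d_max)
    ),
    class = "hifisim_edit_profile"
  )
}

#' @method tidy hifisim_edit_profile
#' @export
tidy.hifisim_edit_profile <- function(x, ...) x$histogram

#' @method glance hifisim_edit_profile
#' @export
glance.hifisim_edit_profile <- function(x, ...) {
  tibble::tibble(
    n_reads = nrow(x$per_read), n_filtered = x$n_filtered,
    median_distance = median(x$per_read$min_edit_distance),
    mean_distance = mean(x$per_read$min_edit_distance),
    d_max = x$d_max
  )
}

#' @export
print.hifisim_edit_profile <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<hifisim edit-distance profile: %d reads (%d length-filtered), median distance %.1f>\n",
    g$n_reads, g$n_filtered, g$median_distance))
  invisible(x)
}

#' @method autoplot hifisim_edit_profile
#' @export
autoplot.hifisim_edit_profile <- function(object, ...) {
  df <- object$per_read
  if ("genome_id" %in% names(df)) {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$genome_id,
                                     y = .data$min_edit_distance)) +
      ggplot2::geom_violin(fill = "steelblue", alpha = 0.6, scale = "width") +
      ggplot2::labs(x = NULL, y = "edit distance to nearest reference ASV") +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                         hjust = 1))
  } else {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$min_edit_distance)) +
      ggplot2::geom_histogram(binwidth = 1, fill = "steelblue") +
      ggplot2::labs(x = "edit distance to nearest reference ASV",
                    y = "reads") +
      ggplot2::theme_minimal()
  }
}

#' Calibrate the subread accuracy by KL-divergence grid search
#'
#' For each accuracy on the grid, a read set is simulated with an
#' otherwise-fixed configuration, its edit-distance histogram is binned
#' identically to the target, and `KL(target || simulated)` is computed
#' with the simulated histogram smoothed; the accuracy minimizing the
#' divergence wins (ties go to the lower accuracy).
#'
#' @param target_distances Integer vector of edit distances from the
#'   target (e.g. real) read set, or a pre-binned histogram (named use
#'   requires `d_max`).
#' @param sim_factory Function `(accuracy, seed) -> integer distances`
#'   running the simulation at that accuracy.
#' @param accuracy_grid Numeric vector of accuracies in (0, 1].
#' @param seed Integer seed; each grid point gets a derived stream.
#' @param d_max Histogram upper edge (default: max of target distances).
#' @param eps Smoothing mass for the simulated histogram.
#' @return A `hifisim_calibration` object with `best_accuracy` and a
#'   `results` tibble (`accuracy`, `kl`).
#' @export
calibrate_accuracy <- function(target_distances, sim_factory, accuracy_grid,
                               seed = 1L, d_max = NULL, eps = 1e-9) {
  stopifnot(length(accuracy_grid) >= 1,
            all(accuracy_grid > 0), all(accuracy_grid <= 1))
  if (is.null(d_max)) d_max <- max(target_distances)
  p <- .hist_from_distances(as.integer(target_distances), d_max)
  accuracy_grid <- sort(accuracy_grid)
  kl <- vapply(seq_along(accuracy_grid), function(i) {
    sim_d <- sim_factory(accuracy_grid[[i]],
                         .substream(seed, paste0("calib", i)))
    q <- smooth_histogram(.hist_from_distances(as.integer(sim_d), d_max),
                          eps)
    kl_divergence(p, q)
  }, numeric(1))
  structure(
    list(best_accuracy = accuracy_grid[[which.min(kl)]],
         results = tibble::tibble(accuracy = accuracy_grid, kl = kl),
         d_max = as.integer(d_max)),
    class = "hifisim_calibration"
  )
}

#' @method tidy hifisim_calibration
#' @export
tidy.hifisim_calibration <- function(x, ...) x$results

#' @method glance hifisim_calibration
#' @export
glance.hifisim_calibration <- function(x, ...) {
  tibble::tibble(best_accuracy = x$best_accuracy,
                 min_kl = min(x$results$kl),
                 n_grid = nrow(x$results))
}

#' @export
print.hifisim_calibration <- function(x, ...) {
  cat(sprintf("<hifisim calibration: best accuracy %.3f over %d grid points>\n",
              x$best_accuracy, nrow(x$results)))
  invisible(x)
}

#' @method autoplot hifisim_calibration
#' @export
autoplot.hifisim_calibration <- function(object, ...) {
  ggplot2::ggplot(object$results,
                  ggplot2::aes(x = .data$accuracy, y = .data$kl)) +
    ggplot2::geom_line(color = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$best_accuracy,
                        linetype = "dashed", color = "firebrick") +
    ggplot2::labs(x = "subread accuracy",
                  y = "KL(target || simulated) [nats]") +
    ggplot2::theme_minimal()
}

#' Squared Pearson correlation between expected and observed abundances
#'
#' @param expected,observed Numeric vectors of equal length (>= 3).
#' @param log10 Correlate on the log10 scale (a pseudocount may be needed
#'   for zero counts).
#' @param pseudocount Added before the log transform when `log10 = TRUE`.
#' @return R^2 in `[0, 1]`.
#' @export
abundance_r2 <- function(expected, observed, log10 = FALSE,
                         pseudocount = 0) {
  if (length(expected) != length(observed) || length(expected) < 3) {
    stop("expected and observed must have equal length >= 3", call. = FALSE)
  }
  if (log10) {
    expected <- base::log10(expected + pseudocount)
    observed <- base::log10(observed + pseudocount)
  }
  if (stats::sd(expected) == 0 || stats::sd(observed) == 0) {
    stop("zero variance in expected or observed", call. = FALSE)
  }
  unname(cor(expected, observed)^2)
}

#' Positional error profile of reads against their true source sequences
#'
#' Each read is globally aligned (unit costs) to the sequence it was
#' simulated from; every alignment column is classified as match,
#' substitution, insertion (base absent from the reference) or deletion
#' (base absent from the read), and per-column proportions are tallied
#' along the alignment coordinate.
#'
#' @param reads Tibble with `seq` and a key column joining to `truth`
#'   (default `template_id`).
#' @param truth Tibble with the key column and `seq` of the true source.
#' @param by Name of the join key (default `"template_id"`).
#' @return A `hifisim_pos_profile` object: tibble of `position`, `n`,
#'   `match`, `substitution`, `insertion`, `deletion` proportions (summing
#'   to 1 per position).
#' @export
positional_error_profile <- function(reads, truth, by = "template_id") {
  stopifnot("seq" %in% names(reads), all(c(by, "seq") %in% names(truth)),
            nrow(reads) >= 1)
  ref_seq <- truth$seq[match(reads[[by]], truth[[by]])]
  if (anyNA(ref_seq)) stop("read(s) with no matching truth record",
                           call. = FALSE)
  max_len <- 0L
  cls <- vector("list", nrow(reads))
  for (i in seq_len(nrow(reads))) {
    al <- .nw_align(ref_seq[[i]], reads$seq[[i]])
    r <- strsplit(al$ref, "", fixed = TRUE)[[1]]
    q <- strsplit(al$qry, "", fixed = TRUE)[[1]]
    k <- ifelse(r == "-", 3L, ifelse(q == "-", 4L, ifelse(r == q, 1L, 2L)))
    cls[[i]] <- k
    max_len <- max(max_len, length(k))
  }
  counts <- matrix(0, nrow = max_len, ncol = 4)
  for (k in cls) {
    idx <- cbind(seq_along(k), k)
    for (j in seq_along(k)) counts[j, k[j]] <- counts[j, k[j]] + 1
  }
  n <- rowSums(counts)
  out <- tibble::tibble(
    position = seq_len(max_len), n = as.integer(n),
    match = counts[, 1] / n, substitution = counts[, 2] / n,
    insertion = counts[, 3] / n, deletion = counts[, 4] / n
  )
  structure(list(profile = out), class = "hifisim_pos_profile")
}

#' @method tidy hifisim_pos_profile
#' @export
tidy.hifisim_pos_profile <- function(x, ...) x$profile

#' @method glance hifisim_pos_profile
#' @export
glance.hifisim_pos_profile <- function(x, ...) {
  p <- x$profile
  tibble::tibble(
    n_positions = nrow(p),
    mean_match = mean(p$match), mean_substitution = mean(p$substitution),
    mean_insertion = mean(p$insertion), mean_deletion = mean(p$deletion)
  )
}

#' @export
print.hifisim_pos_profile <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<hifisim positional error profile: %d columns, mean match %.3f>\n",
    g$n_positions, g$mean_match))
  invisible(x)
}

#' @method autoplot hifisim_pos_profile
#' @export
autoplot.hifisim_pos_profile <- function(object, ...) {
  long <- tidyr::pivot_longer(object$profile,
                              c("match", "substitution", "insertion",
                                "deletion"),
                              names_to = "class", values_to = "proportion")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$position,
                                     y = .data$proportion,
                                     color = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "alignment position", y = "proportion") +
    ggplot2::theme_minimal()
}
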