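# Pass-number (np) distributions: the number of polymerase passes per
# molecule, which drives consensus read accuracy. Supports empirical
# histograms extracted from real runs and fitted lognormals, both truncated
# to [np_min, np_max] (defaults 2-59).

#' Pass-number distribution constructors
#'
#' `np_empirical()` builds a distribution from a histogram tibble
#' (`np`, `count`); rows outside `[np_min, np_max]` are dropped and the
#' remainder renormalized. `np_lognormal()` parameterizes a lognormal on
#' the log scale; sampling discretizes by rounding to the nearest integer
#' and rejects values outside the range.
#'
#' @param tbl Tibble with columns `np` (integers) and `count` (>= 0).
#' @param np_min,np_max Inclusive truncation range; `np_min >= 1`.
#' @return A `hifisim_np` object.
#' @export
np_empirical <- function(tbl, np_min = 2L, np_max = 59L) {
  stopifnot(all(c("np", "count") %in% names(tbl)),
            np_min >= 1, np_max >= np_min, all(tbl$count >= 0))
  keep <- tbl$np >= np_min & tbl$np <= np_max & tbl$count > 0
  if (!any(keep)) {
    stop("no pass-number rows within [np_min, np_max]", call. = FALSE)
  }
  tbl <- tbl[keep, ]
  agg <- tapply(tbl$count, tbl$np, sum)
  support <- as.integer(names(agg))
  probs <- as.numeric(agg) / sum(agg)
  structure(
    list(kind = "empirical", support = support, probabilities = probs,
         np_min = as.integer(np_min), np_max = as.integer(np_max)),
    class = "hifisim_np"
  )
}

#' @rdname np_empirical
#' @param meanlog,sdlog Mean and standard deviation of `log(np)`;
#'   `sdlog >= 0` (0 is the degenerate point mass at `round(exp(meanlog))`).
#' @export
np_lognormal <- function(meanlog = 2.3, sdlog = 0.5,
                         np_min = 2L, np_max = 59L) {
  stopifnot(is.finite(meanlog), sdlog >= 0, np_min >= 1, np_max >= np_min)
  structure(
    list(kind = "lognormal", meanlog = meanlog, sdlog = sdlog,
         np_min = as.integer(np_min), np_max = as.integer(np_max)),
    class = "hifisim_np"
  )
}

#' Load an empirical pass-number distribution from a TSV histogram
#'
#' @param path TSV with header `np`, `count`.
#' @inheritParams np_empirical
#' @return A `hifisim_np` object.
#' @export
load_empirical_np <- function(path, np_min = 2L, np_max = 59L) {
  np_empirical(read_np_table(path), np_min = np_min, np_max = np_max)
}

#' Fit a lognormal pass-number distribution
#'
#' Maximum-likelihood fit of the un-truncated lognormal: `meanlog` and
#' `sdlog` are the mean and *population* standard deviation (divisor n,
#' not n-1) of `log(np)`.
#'
#' @param np_samples Integer vector of observed pass numbers (all > 0,
#'   length >= 2).
#' @inheritParams np_empirical
#' @return A `hifisim_np` lognormal object with the fitted parameters.
#' @export
fit_np_lognormal <- function(np_samples, np_min = 2L, np_max = 59L) {
  if (length(np_samples) < 2) stop("need at least 2 samples", call. = FALSE)
  if (any(np_samples <= 0)) stop("pass numbers must be positive", call. = FALSE)
  lx <- log(np_samples)
  mu <- mean(lx)
  sigma <- sqrt(mean((lx - mu)^2))
  np_lognormal(meanlog = mu, sdlog = sigma, np_min = np_min, np_max = np_max)
}

#' Sample pass numbers from a distribution
#'
#' All draws are integers within `[np_min, np_max]`. Empirical: categorical
#' sampling over the support. Lognormal: draw, round to nearest integer
#' (R's round-half-to-even), redraw while out of range.
#'
#' @param dist A `hifisim_np` object.
#' @param n Number of draws (>= 0).
#' @param seed Optional integer seed (restores the caller's RNG stream).
#' @return Integer vector of length `n`.
#' @export
sample_np <- function(dist, n, seed = NULL) {
  stopifnot(inherits(dist, "hifisim_np"), n >= 0)
  if (n == 0) return(integer(0))
  .with_seed(seed, {
    if (dist$kind == "empirical") {
      if (length(dist$support) == 1) {
        rep(dist$support, n)
      } else {
        sample(dist$support, n, replace = TRUE, prob = dist$probabilities)
      }
    } else {
      if (dist$sdlog == 0) {
        v <- as.integer(round(exp(dist$meanlog)))
        if (v < dist$np_min || v > dist$np_max) {
          stop("degenerate lognormal mass lies outside [np_min, np_max]",
               call. = FALSE)
        }
        return(rep(v, n))
      }
      out <- integer(0)
      tries <- 0L
      while (length(out) < n) {
        draw <- as.integer(round(rlnorm(max(n, 1000L), dist$meanlog,
                                        dist$sdlog)))
        draw <- draw[draw >= dist$np_min & draw <= dist$np_max]
        out <- c(out, draw)
        tries <- tries + 1L
        if (tries > 1000L) {
          stop("lognormal has (near-)zero mass within [np_min, np_max]",
               call. = FALSE)
        }
      }
      out[seq_len(n)]
    }
  })
}

#' @method tidy hifisim_np
#' @export
tidy.hifisim_np <- function(x, ...) {
  if (x$kind == "empirical") {
    tibble::tibble(np = x$support, probability = x$probabilities)
  } else {
    support <- seq(x$np_min, x$np_max)
    if (x$sdlog == 0) {
      p <- as.numeric(support == as.integer(round(exp(x$meanlog))))
    } else {
      # mass of the rounded lognormal landing on each integer, renormalized
      # over the truncation range (sampling uses rejection, so this is the
      # exact sampled pmf)
      p <- plnorm(support + 0.5, x$meanlog, x$sdlog) -
        plnorm(support - 0.5, x$meanlog, x$sdlog)
    }
    if (sum(p) == 0) stop("no lognormal mass within range", call. = FALSE)
    tibble::tibble(np = as.integer(support), probability = p / sum(p))
  }
}

#' @method glance hifisim_np
#' @export
glance.hifisim_np <- function(x, ...) {
  pmf <- tidy(x)
  tibble::tibble(
    kind = x$kind,
    np_min = x$np_min, np_max = x$np_max,
    mean_np = sum(pmf$np * pmf$probability),
    meanlog = if (x$kind == "lognormal") x$meanlog else NA_real_,
    sdlog = if (x$kind == "lognormal") x$sdlog else NA_real_
  )
}

#' @export
print.hifisim_np <- function(x, ...) {
  cat(sprintf("<hifisim pass-number distribution: %s, range [%d, %d]>\n",
              x$kind, x$np_min, x$np_max))
  if (x$kind == "lognormal") {
    cat(sprintf("  meanlog = %.4g, sdlog = %.4g\n", x$meanlog, x$sdlog))
  } else {
    cat(sprintf("  %d support points\n", length(x$support)))
  }
  invisible(x)
}

#' @method autoplot hifisim_np
#' @export
autoplot.hifisim_np <- function(object, ...) {
  pmf <- tidy(object)
  ggplot2::ggplot(pmf, ggplot2::aes(x = .data$np, y = .data$probability)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "pass number (np)", y = "probability",
                  title = sprintf("Pass-number distribution (%s)", object$kind)) +
    ggplot2::theme_minimal()
}
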