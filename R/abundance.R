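# Genome-level abundance simulation: molarity distributions, an
# intensity -> variability (CV^2) model with the NA -> 0 edge case, two-stage
# (biological Gamma + technical multinomial) count realization, and
# copy-number-aware expansion to ASV-level expected intensities.

#' Sample genome molarities from a named distribution
#'
#' @param n_genomes Number of genomes (>= 1).
#' @param dist One of `"uniform"`, `"lognormal"`, `"powerlaw"`,
#'   `"empirical"`.
#' @param params Named list of distribution parameters: lognormal takes
#'   `meanlog` (0) and `sdlog` (1); powerlaw takes `alpha` (1) and assigns
#'   rank^(-alpha) by genome order; empirical takes `profile`, a
#'   non-negative vector of length `n_genomes`.
#' @param seed Optional integer seed.
#' @return Non-negative numeric vector of length `n_genomes` summing to 1.
#' @export
sample_genome_molarity <- function(n_genomes,
                                   dist = c("uniform", "lognormal",
                                            "powerlaw", "empirical"),
                                   params = list(), seed = NULL) {
  stopifnot(n_genomes >= 1)
  dist <- match.arg(dist)
  w <- .with_seed(seed, switch(
    dist,
    uniform = rep(1, n_genomes),
    lognormal = {
      meanlog <- params$meanlog %||% 0
      sdlog <- params$sdlog %||% 1
      exp(rnorm(n_genomes, meanlog, sdlog))
    },
    powerlaw = {
      alpha <- params$alpha %||% 1
      seq_len(n_genomes)^(-alpha)
    },
    empirical = {
      profile <- params$profile
      if (is.null(profile) || length(profile) != n_genomes) {
        stop("empirical profile must have length n_genomes", call. = FALSE)
      }
      if (any(profile < 0)) stop("negative abundance in profile", call. = FALSE)
      as.numeric(profile)
    }
  ))
  w / sum(w)
}

#' Intensity -> variability model
#'
#' Predicts the squared coefficient of variation (CV^2) of a feature's
#' abundance across replicate samples as a linear function of
#' log10(intensity), with noise around the mean curve. Draws that fall at
#' or below zero are returned as 0, i.e. "no biological variability" - the
#' behaviour real count-matrix parameter estimation shows when its
#' dispersion estimate is unavailable (NA) for a feature.
#'
#' The default coefficients give the canonical overdispersion shape (CV^2
#' decreasing with intensity, roughly 0.05 at intensity 0.5 up to 0.5 at
#' intensity 1e-4); all three parameters are user-settable and
#' [fit_variability_model()] estimates them from any (intensity, CV^2)
#' table.
#'
#' @param dispersion_slope,dispersion_intercept Mean curve
#'   `CV^2 = intercept + slope * log10(intensity)` (raw scale, so the
#'   prediction can go negative at high intensity, triggering the 0 rule).
#' @param nb_size Size parameter controlling sampling noise around the mean
#'   curve: draws are Normal(mu, mu/sqrt(nb_size)); `Inf` means no noise.
#' @return A `hifisim_variability` object.
#' @export
variability_model <- function(dispersion_slope = -0.12,
                              dispersion_intercept = 0.013,
                              nb_size = 25) {
  stopifnot(is.finite(dispersion_slope), is.finite(dispersion_intercept),
            nb_size > 0)
  structure(
    list(dispersion_slope = dispersion_slope,
         dispersion_intercept = dispersion_intercept,
         nb_size = nb_size),
    class = "hifisim_variability"
  )
}

#' @method tidy hifisim_variability
#' @export
tidy.hifisim_variability <- function(x, ...) {
  tibble::tibble(
    term = c("dispersion_intercept", "dispersion_slope", "nb_size"),
    estimate = c(x$dispersion_intercept, x$dispersion_slope, x$nb_size)
  )
}

#' @export
print.hifisim_variability <- function(x, ...) {
  cat(sprintf(
    "<hifisim variability model: CV2 = %.4g %+.4g * log10(intensity), nb_size = %.4g>\n",
    x$dispersion_intercept, x$dispersion_slope, x$nb_size))
  invisible(x)
}

#' Fit a variability model from an (intensity, CV^2) table
#'
#' Least-squares fit of the mean curve on log10(intensity); `nb_size` is
#' estimated by moments from the residual variance.
#'
#' @param data Tibble/data frame with columns `intensity` (> 0) and `cv2`.
#' @return A `hifisim_variability` object.
#' @export
fit_variability_model <- function(data) {
  stopifnot(all(c("intensity", "cv2") %in% names(data)),
            all(data$intensity > 0), nrow(data) >= 3)
  fit <- lm(cv2 ~ I(log10(intensity)), data = data)
  mu <- pmax(fitted(fit), 0)
  rv <- mean(resid(fit)^2)
  nb_size <- if (rv > 0 && any(mu > 0)) mean(mu[mu > 0]^2) / rv else Inf
  variability_model(dispersion_slope = unname(coef(fit)[2]),
                    dispersion_intercept = unname(coef(fit)[1]),
                    nb_size = nb_size)
}

#' Draw per-feature CV^2 values from a variability model
#'
#' @param intensity Positive numeric vector of expected relative abundances.
#' @param model A [variability_model()].
#' @param seed Optional integer seed.
#' @return Numeric vector of CV^2 draws, >= 0; draws that would be negative
#'   (or whose predicted mean is <= 0) are returned as 0.
#' @export
predict_variability <- function(intensity, model = variability_model(),
                                seed = NULL) {
  stopifnot(inherits(model, "hifisim_variability"))
  if (any(intensity <= 0)) stop("intensity must be positive", call. = FALSE)
  mu <- model$dispersion_intercept +
    model$dispersion_slope * log10(intensity)
  .with_seed(seed, {
    draw <- if (is.infinite(model$nb_size)) mu else
      rnorm(length(mu), mean = mu, sd = abs(mu) / sqrt(model$nb_size))
    pmax(draw, 0)
  })
}

#' Build a genome x sample abundance table
#'
#' One community molarity vector is drawn and shared across samples (the
#' samples are replicates of the same community); per-cell variability is
#' drawn from the model, either independently per genome x sample
#' (`variability_per = "cell"`) or once per genome (`"feature"`).
#'
#' @param genome_ids Character vector of genome ids.
#' @param sample_ids Character vector of sample ids.
#' @inheritParams sample_genome_molarity
#' @param model A [variability_model()].
#' @param variability_per `"cell"` or `"feature"`.
#' @param seed Integer seed.
#' @return Tibble with `genome_id`, `sample_id`, `intensity`, `cv2`;
#'   intensities sum to 1 within each sample.
#' @export
build_abundance_matrix <- function(genome_ids, sample_ids,
                                   dist = "uniform", params = list(),
                                   model = variability_model(),
                                   variability_per = c("cell", "feature"),
                                   seed = 1L) {
  variability_per <- match.arg(variability_per)
  n_g <- length(genome_ids)
  molarity <- sample_genome_molarity(n_g, dist, params,
                                     seed = .substream(seed, "molarity"))
  if (any(molarity == 0)) {
    # keep intensities strictly positive for the variability model
    molarity <- molarity + 1e-12
    molarity <- molarity / sum(molarity)
  }
  out <- tidyr::expand_grid(sample_id = sample_ids, genome_id = genome_ids)
  out$intensity <- rep(molarity, times = length(sample_ids))
  if (variability_per == "feature") {
    cv2 <- predict_variability(molarity, model,
                               seed = .substream(seed, "variability"))
    out$cv2 <- rep(cv2, times = length(sample_ids))
  } else {
    out$cv2 <- unlist(lapply(seq_along(sample_ids), function(j) {
      predict_variability(molarity, model,
                          seed = .substream(seed, paste0("variability", j)))
    }))
  }
  out[, c("genome_id", "sample_id", "intensity", "cv2")]
}

#' Expand genome-level abundances to ASV level using operon copy numbers
#'
#' Each ASV's expected weight is its genome's intensity times the ASV's
#' copy multiplicity within that genome; weights are renormalized over all
#' ASVs within each sample. Genomes with no extracted ASV contribute
#' nothing (with a warning).
#'
#' @param abundance Genome-level tibble from [build_abundance_matrix()].
#' @param catalog ASV catalog from [asv_catalog()] (columns `asv_id`,
#'   `genome_id`, `multiplicity`).
#' @return Tibble with `asv_id`, `genome_id`, `sample_id`, `intensity`,
#'   `cv2`; intensities sum to 1 per sample.
#' @export
expand_to_asv <- function(abundance, catalog) {
  stopifnot(all(c("genome_id", "sample_id", "intensity") %in% names(abundance)),
            all(c("asv_id", "genome_id", "multiplicity") %in% names(catalog)))
  missing <- setdiff(unique(abundance$genome_id), unique(catalog$genome_id))
  if (length(missing) > 0) {
    warning(sprintf("genome(s) with no extracted amplicons dropped: %s",
                    paste(missing, collapse = ", ")), call. = FALSE)
  }
  out <- dplyr::inner_join(abundance,
                           catalog[, c("asv_id", "genome_id", "multiplicity")],
                           by = "genome_id", relationship = "many-to-many")
  out <- dplyr::mutate(out, weight = .data$intensity * .data$multiplicity)
  out <- dplyr::mutate(dplyr::group_by(out, .data$sample_id),
                       intensity = .data$weight / sum(.data$weight))
  out <- dplyr::ungroup(out)
  cols <- c("asv_id", "genome_id", "sample_id", "intensity")
  if ("cv2" %in% names(out)) cols <- c(cols, "cv2")
  dplyr::arrange(out[, cols], .data$sample_id, .data$genome_id, .data$asv_id)
}

#' Realize integer counts for one sample
#'
#' Two-stage sampling: a biological stage draws each feature's realized
#' intensity from a Gamma with mean `intensity` and squared coefficient of
#' variation `variability` (a variability of 0 uses the intensity as-is,
#' so replicates are identical before technical sampling); a technical
#' stage draws `depth` reads by multinomial sampling over the renormalized
#' stage-1 intensities.
#'
#' @param intensity Non-negative vector summing to 1.
#' @param variability CV^2 vector of the same length (>= 0).
#' @param depth Total reads for the sample (>= 1).
#' @param seed Optional integer seed.
#' @return Integer count vector summing to `depth`.
#' @export
simulate_sample_counts <- function(intensity, variability, depth,
                                   seed = NULL) {
  stopifnot(length(intensity) == length(variability), depth >= 1,
            all(intensity >= 0), all(variability >= 0))
  if (abs(sum(intensity) - 1) > 1e-6) {
    stop("intensities must sum to 1", call. = FALSE)
  }
  .with_seed(seed, {
    lambda <- intensity
    noisy <- variability > 0 & intensity > 0
    if (any(noisy)) {
      shape <- 1 / variability[noisy]
      lambda[noisy] <- rgamma(sum(noisy), shape = shape,
                              scale = intensity[noisy] * variability[noisy])
    }
    if (sum(lambda) == 0) lambda <- intensity
    as.integer(rmultinom(1, size = depth, prob = lambda / sum(lambda)))
  })
}

#' Simulate the full ASV x sample count table
#'
#' @param asv_abundance ASV-level tibble from [expand_to_asv()].
#' @param depth Reads per sample.
#' @param seed Integer seed; each sample gets its own derived stream.
#' @return Tibble with `asv_id`, `genome_id`, `sample_id`, `intensity`
#'   (expected), `count` (realized); counts sum to `depth` per sample.
#' @export
simulate_counts <- function(asv_abundance, depth, seed = 1L) {
  stopifnot(all(c("asv_id", "sample_id", "intensity") %in%
                  names(asv_abundance)))
  split_tbl <- split(asv_abundance, asv_abundance$sample_id)
  out <- purrr::list_rbind(purrr::map(split_tbl, function(tbl) {
    cv2 <- if ("cv2" %in% names(tbl)) tbl$cv2 else rep(0, nrow(tbl))
    tbl$count <- simulate_sample_counts(
      tbl$intensity, cv2, depth,
      seed = .substream(seed, paste0("counts_", tbl$sample_id[[1]]))
    )
    tbl
  }))
  dplyr::arrange(out, .data$sample_id, .data$genome_id, .data$asv_id)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
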