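test_that("molarity distributions normalize as specified", {
  # even design: n genomes at equal abundance
  expect_equal(sample_genome_molarity(8, "uniform"), rep(0.125, 8))
  expect_equal(sample_genome_molarity(3, "empirical",
                                      list(profile = c(2, 1, 1))),
               c(0.5, 0.25, 0.25))
  # harmonic normalization of rank^-1
  expect_equal(sample_genome_molarity(3, "powerlaw", list(alpha = 1)),
               c(1, 1 / 2, 1 / 3) / (1 + 1 / 2 + 1 / 3),
               tolerance = 1e-12)
  ln <- sample_genome_molarity(50, "lognormal",
                               list(meanlog = 0, sdlog = 1), seed = 2)
  expect_equal(sum(ln), 1)
  expect_true(all(ln > 0))
  expect_error(sample_genome_molarity(3, "empirical", list(profile = 1:2)),
               "length")
})

test_that("variability draws follow the mean curve and map negatives to zero", {
  # model whose mean curve is negative everywhere: every draw comes back 0,
  # i.e. identical replicates (the NA -> 0 emulation)
  neg <- variability_model(dispersion_slope = 0, dispersion_intercept = -1,
                           nb_size = 1e6)
  expect_equal(predict_variability(c(0.01, 0.5), neg, seed = 1), c(0, 0))

  # no-noise limit returns the mean curve exactly
  exact <- variability_model(dispersion_slope = -0.12,
                             dispersion_intercept = 0.013, nb_size = Inf)
  i <- c(1e-4, 1e-2)
  expect_equal(predict_variability(i, exact),
               0.013 - 0.12 * log10(i))

  # Monte-Carlo: sample mean of draws tracks the model mean within 4 sigma
  m <- variability_model(nb_size = 25)
  mu <- 0.013 - 0.12 * log10(1e-3)
  draws <- predict_variability(rep(1e-3, 1e4), m, seed = 8)
  se <- (mu / sqrt(25)) / sqrt(1e4)
  expect_lt(abs(mean(draws) - mu), 4 * se)
  expect_true(all(draws >= 0))
  expect_error(predict_variability(0, m), "positive")
})

test_that("two-stage count sampling conserves depth and matches the binomial law", {
  counts <- simulate_sample_counts(c(0.2, 0.3, 0.5), c(0.1, 0, 0.4),
                                   depth = 500, seed = 3)
  expect_equal(sum(counts), 500)
  expect_true(all(counts >= 0))

  # pure technical sampling, two equal features: counts ~ Binomial(10, 0.5);
  # compare the realized PMF to the closed form by chi-square
  reps <- 10000
  first <- vapply(seq_len(reps), function(i) {
    simulate_sample_counts(c(0.5, 0.5), c(0, 0), depth = 10)[1]
  }, integer(1))
  obs <- tabulate(first + 1L, nbins = 11)
  expected_p <- dbinom(0:10, 10, 0.5)
  chi <- suppressWarnings(stats::chisq.test(obs, p = expected_p))
  expect_gt(chi$p.value, 0.001)

  # zero variability, large depth: frequencies converge on the intensities
  intens <- c(0.4, 0.35, 0.15, 0.1)
  big <- simulate_sample_counts(intens, rep(0, 4), depth = 2e5, seed = 5)
  expect_lt(sum(abs(big / 2e5 - intens)), 0.02)
})

test_that("zero-variability biological stage is deterministic", {
  ab <- tibble::tibble(
    genome_id = rep(c("g1", "g2"), each = 2),
    sample_id = rep(c("S1", "S2"), 2),
    intensity = rep(c(0.7, 0.3), each = 2),
    cv2 = 0
  )
  cat1 <- tibble::tibble(asv_id = c("g1.asv1", "g2.asv1"),
                         genome_id = c("g1", "g2"), multiplicity = c(1L, 1L))
  a <- simulate_counts(expand_to_asv(ab, cat1), depth = 100, seed = 9)
  b <- simulate_counts(expand_to_asv(ab, cat1), depth = 100, seed = 9)
  expect_identical(a$count, b$count)
})

test_that("copy-number expansion weights ASVs by multiplicity and renormalizes", {
  ab <- tibble::tibble(genome_id = c("g1", "g2"), sample_id = "S1",
                       intensity = c(0.5, 0.5), cv2 = 0)
  # 3 identical copies aggregate into one ASV with weight 3m
  cat3 <- tibble::tibble(asv_id = c("g1.asv1", "g2.asv1"),
                         genome_id = c("g1", "g2"),
                         multiplicity = c(3L, 1L))
  out <- expand_to_asv(ab, cat3)
  expect_equal(out$intensity[out$asv_id == "g1.asv1"], 3 / 4)

  # 4 unique copies vs 2 unique copies: summed genome masses stay 2:1... 1:1
  cat42 <- tibble::tibble(
    asv_id = c(paste0("g1.asv", 1:4), paste0("g2.asv", 1:2)),
    genome_id = c(rep("g1", 4), rep("g2", 2)),
    multiplicity = 1L
  )
  out2 <- expand_to_asv(ab, cat42)
  mass <- tapply(out2$intensity, out2$genome_id, sum)
  expect_equal(unname(mass["g1"] / mass["g2"]), (0.5 * 4) / (0.5 * 2))
  expect_equal(sum(out2$intensity), 1)

  # genome with no amplicons contributes nothing, with a warning
  ab3 <- tibble::tibble(genome_id = c("g1", "g2", "g3"), sample_id = "S1",
                        intensity = c(0.5, 0.25, 0.25), cv2 = 0)
  expect_warning(out3 <- expand_to_asv(ab3, cat3), "g3")
  expect_false("g3" %in% out3$genome_id)
  expect_equal(sum(out3$intensity), 1)
})

test_that("expected ASV intensities are recovered from simulated counts", {
  # staggered 20-genome community, realistic depth, replicate samples
  genome_ids <- paste0("g", 1:20)
  sample_ids <- paste0("S", 1:8)
  ab <- build_abundance_matrix(genome_ids, sample_ids,
                               dist = "powerlaw", params = list(alpha = 1),
                               seed = 17)
  catalog <- tibble::tibble(
    asv_id = paste0(genome_ids, ".asv1"), genome_id = genome_ids,
    multiplicity = rep(c(1L, 2L, 3L, 4L), 5)
  )
  asv_ab <- expand_to_asv(ab, catalog)
  counts <- simulate_counts(asv_ab, depth = 13000, seed = 17)
  per_sample <- split(counts, counts$sample_id)
  for (tbl in per_sample) expect_equal(sum(tbl$count), 13000)
  mean_freq <- tapply(counts$count / 13000, counts$asv_id, mean)
  expected <- tapply(asv_ab$intensity, asv_ab$asv_id, mean)
  expect_gt(abundance_r2(as.numeric(expected[names(mean_freq)]),
                         as.numeric(mean_freq)), 0.95)
})

test_that("fit_variability_model recovers a known mean curve", {
  set.seed(12)
  intensity <- 10^runif(400, -4, -0.5)
  mu <- 0.05 - 0.1 * log10(intensity)
  cv2 <- mu + rnorm(400, 0, 0.02)
  fit <- fit_variability_model(tibble::tibble(intensity = intensity,
                                              cv2 = cv2))
  expect_equal(fit$dispersion_slope, -0.1, tolerance = 0.05)
  expect_equal(fit$dispersion_intercept, 0.05, tolerance = 0.05)
})
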