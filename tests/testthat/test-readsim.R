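test_that("a perfect-accuracy pass reproduces the template (or its RC)", {
  tpl <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  m <- error_model(accuracy = 1)
  plus <- mutate_pass(tpl, m, "+", seed = 1)
  expect_equal(plus$seq, tpl)
  expect_equal(plus$n_sub + plus$n_ins + plus$n_del, 0L)
  minus <- mutate_pass(tpl, m, "-", seed = 1)
  expect_equal(minus$seq, reverse_complement(tpl))
})

test_that("injected error composition and identity track the model", {
  set.seed(2)
  tpl <- paste(sample(c("A", "C", "G", "T"), 2e5, TRUE), collapse = "")
  sub <- mutate_pass(tpl, error_model(), "+", seed = 2)
  visits <- sub$n_match + sub$n_sub + sub$n_ins + sub$n_del
  errors <- sub$n_sub + sub$n_ins + sub$n_del
  # identity per emitted alignment column ~ accuracy
  expect_lt(abs(sub$n_match / visits - 0.65),
            4 * sqrt(0.65 * 0.35 / visits))
  # error-type shares ~ normalized 6:55:39
  expect_lt(abs(sub$n_ins / errors - 0.55), 4 * sqrt(0.55 * 0.45 / errors))
  expect_lt(abs(sub$n_del / errors - 0.39), 4 * sqrt(0.39 * 0.61 / errors))
})

test_that("ZMW passes alternate strands and are seed-reproducible", {
  tpl <- paste(sample(c("A", "C", "G", "T"), 150, TRUE), collapse = "")
  z <- simulate_zmw(tpl, 5, error_model(), seed = 3)
  expect_equal(z$strand, c("+", "-", "+", "-", "+"))
  expect_equal(z$pass_index, 1:5)
  z2 <- simulate_zmw(tpl, 5, error_model(), seed = 3)
  expect_identical(z, z2)
  expect_error(simulate_zmw(tpl, 0, error_model()), "np")
})

test_that("homopolymer multiplier raises indel rates inside runs", {
  tpl <- paste0(strrep("ACGT", 500), strrep("A", 2000))
  m_on <- error_model(accuracy = 0.9, homopolymer_multiplier = 3)
  base <- mutate_pass(tpl, error_model(accuracy = 0.9), "+", seed = 4)
  boosted <- mutate_pass(tpl, m_on, "+", seed = 4)
  expect_gt(boosted$n_ins + boosted$n_del, base$n_ins + base$n_del)
})

test_that("consensus of identical subreads is exact with capped quality", {
  tpl <- paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = "")
  subreads <- simulate_zmw(tpl, 7, error_model(accuracy = 1), seed = 5)
  cc <- consensus(subreads)
  expect_equal(cc$seq, tpl)
  expect_equal(cc$qual, rep(93L, 120))
})

test_that("a single subread is returned plus-oriented at the floor quality", {
  tpl <- paste(sample(c("A", "C", "G", "T"), 80, TRUE), collapse = "")
  one_minus <- mutate_pass(tpl, error_model(accuracy = 1), "-", seed = 6)
  one_minus$pass_index <- 1L
  cc <- consensus(one_minus, single_pass_qual = 20L)
  expect_equal(cc$seq, tpl)
  expect_equal(cc$qual, rep(20L, 80))
})

test_that("consensus error decreases with pass number (paired sign test)", {
  tpl <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  m <- error_model()
  n_pairs <- 40
  d3 <- integer(n_pairs); d15 <- integer(n_pairs)
  for (i in seq_len(n_pairs)) {
    d3[i] <- adist(consensus(simulate_zmw(tpl, 3, m, seed = 1000 + i))$seq,
                   tpl)
    d15[i] <- adist(consensus(simulate_zmw(tpl, 15, m, seed = 2000 + i))$seq,
                    tpl)
  }
  expect_lte(median(d15), median(d3))
  informative <- sum(d3 != d15)
  p <- stats::binom.test(sum(d15 < d3), informative,
                         alternative = "greater")$p.value
  expect_lt(p, 0.01)
})

test_that("simulate_reads emits one read per molecule with full provenance", {
  templates <- tibble::tibble(
    template_id = paste0("S1_g1.asv", 1:3),
    sample_id = "S1", genome_id = "g1",
    asv_id = paste0("g1.asv", 1:3),
    seq = vapply(1:3, function(i)
      paste(sample(c("A", "C", "G", "T"), 150, TRUE), collapse = ""),
      character(1)),
    copies = c(1L, 2L, 1L)
  )
  reads <- simulate_reads(templates, np_lognormal(), error_model(), seed = 10)
  expect_equal(nrow(reads), 4)
  expect_true(all(reads$np >= 2 & reads$np <= 59))
  expect_true(all(nchar(reads$seq) == nchar(reads$qual)))
  expect_match(reads$read_id, "^m\\d+_000000_000000/\\d+/ccs$")
  # byte-identical rerun
  again <- simulate_reads(templates, np_lognormal(), error_model(), seed = 10)
  expect_identical(reads, again)
})
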