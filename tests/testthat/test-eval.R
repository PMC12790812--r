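test_that("nearest_reference finds exact and near matches with stable ties", {
  refs <- tibble::tibble(asv_id = c("b", "a"),
                         seq = c("ACGTACGTAC", "ACGTACGTTT"))
  hit <- nearest_reference("ACGTACGTAC", refs)
  expect_equal(hit$min_edit_distance, 0)
  expect_equal(hit$nearest_asv_id, "b")
  # one deletion
  del <- nearest_reference("ACGTACGAC", refs)
  expect_equal(del$min_edit_distance, 1)
  # equidistant read: the lexicographically smallest asv_id wins
  tie <- nearest_reference("ACGTACGTAT", refs)
  expect_equal(tie$nearest_asv_id, "a")
  expect_error(nearest_reference("ACGT", refs[0, ]), "references|>= 1")
})

test_that("nearest_reference distances equal a quadratic-DP oracle", {
  set.seed(13)
  refs <- tibble::tibble(
    asv_id = paste0("r", 1:5),
    seq = vapply(1:5, function(i)
      paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = ""),
      character(1))
  )
  for (i in 1:20) {
    read <- paste(sample(c("A", "C", "G", "T"), sample(40:80, 1), TRUE),
                  collapse = "")
    got <- nearest_reference(read, refs)
    want <- min(vapply(refs$seq, oracle_levenshtein, numeric(1), a = read))
    expect_equal(got$min_edit_distance, want)
  }
})

test_that("misassignment is zero for error-free reads and honors ties", {
  refs <- tibble::tibble(asv_id = c("a", "b"),
                         seq = c(strrep("ACGT", 10), strrep("GGCA", 10)))
  reads <- tibble::tibble(asv_id = c("a", "b"), seq = refs$seq)
  expect_equal(misassignment_rate(reads, refs), 0)
  # identical references: a tie that includes the truth counts as correct
  twins <- tibble::tibble(asv_id = c("a", "b"), seq = rep(refs$seq[1], 2))
  expect_equal(
    misassignment_rate(tibble::tibble(asv_id = "a", seq = refs$seq[1]),
                       twins), 0)
  wrong <- tibble::tibble(asv_id = "b", seq = refs$seq[1])
  expect_equal(misassignment_rate(wrong, refs), 1)
})

test_that("KL divergence matches the closed form and rejects unsmoothed zeros", {
  expect_equal(kl_divergence(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(kl_divergence(c(0.5, 0.5), c(0.25, 0.75)),
               0.5 * log(2) + 0.5 * log(2 / 3))
  expect_equal(kl_divergence(c(0.5, 0.5), c(0.25, 0.75)), 0.1438410,
               tolerance = 1e-6)
  expect_error(kl_divergence(c(0.5, 0.5), c(0, 1)), "smooth")
  expect_error(kl_divergence(c(0.5, 0.5), c(0.3, 0.3, 0.4)), "mismatch")
  expect_gte(kl_divergence(c(0.9, 0.1), smooth_histogram(c(0.1, 0.9))), 0)
})

test_that("abundance R^2 is affine-invariant and matches the closed form", {
  expect_equal(abundance_r2(c(1, 2, 3), c(1, 2, 3)), 1.0)
  expect_equal(abundance_r2(c(1, 2, 3), 2 * c(1, 2, 3) + 1), 1.0)
  expect_equal(abundance_r2(c(1, 2, 3), c(1, 2, 4)), 27 / 28)
  expect_equal(abundance_r2(c(1, 2, 3), c(1, 2, 4)), 0.9642857,
               tolerance = 1e-6)
  expect_error(abundance_r2(c(1, 1, 1), c(1, 2, 3)), "variance")
  expect_error(abundance_r2(1:2, 1:2), "length")
})

test_that("positional error profile classifies columns correctly", {
  truth <- tibble::tibble(template_id = "t1", seq = strrep("ACGT", 10))
  perfect <- tibble::tibble(template_id = "t1", seq = truth$seq)
  prof <- positional_error_profile(perfect, truth)
  expect_true(all(tidy(prof)$match == 1))
  expect_true(all(abs(rowSums(tidy(prof)[, c("match", "substitution",
                                             "insertion", "deletion")]) - 1)
                  < 1e-12))

  # a single deletion at position 10 shows up as a deletion column there
  delseq <- paste0(substr(truth$seq, 1, 9), substr(truth$seq, 11, 40))
  prof_d <- positional_error_profile(
    tibble::tibble(template_id = "t1", seq = delseq), truth)
  tp <- tidy(prof_d)
  expect_equal(sum(tp$deletion), 1)
  expect_equal(tp$position[tp$deletion == 1], 10)
})

test_that("uniform error model leaves no positional trend", {
  set.seed(23)
  tpl <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  truth <- tibble::tibble(template_id = "t1", seq = tpl)
  reads <- purrr::map(1:60, function(i) {
    mutate_pass(tpl, error_model(accuracy = 0.9), "+")$seq
  })
  prof <- positional_error_profile(
    tibble::tibble(template_id = "t1", seq = unlist(reads)), truth)
  tp <- tidy(prof)
  # regression of error proportion on position: slope compatible with 0
  tp$err <- 1 - tp$match
  # end columns are covered by few alignments; keep well-covered ones
  tp <- tp[tp$n >= 30, ]
  fit <- summary(lm(err ~ position, data = tp))
  slope <- fit$coefficients["position", ]
  expect_lt(abs(slope["Estimate"]), 4 * slope["Std. Error"] + 1e-4)
})

test_that("calibration returns the only grid point, and the max on degenerate targets", {
  fake_factory <- function(accuracy, seed) {
    # deterministic fake: mean distance decreases as accuracy rises
    rep(round((1 - accuracy) * 20), 200)
  }
  one <- calibrate_accuracy(rep(3, 100), fake_factory, 0.8, seed = 1)
  expect_equal(one$best_accuracy, 0.8)
  # all-zero target: the highest accuracy matches best
  zero <- calibrate_accuracy(rep(0, 100), fake_factory,
                             c(0.8, 0.9, 1.0), seed = 1)
  expect_equal(zero$best_accuracy, 1.0)
  expect_equal(nrow(tidy(zero)), 3)
})

test_that("edit-distance profiles length-filter before computing distances", {
  refs <- tibble::tibble(asv_id = "a", seq = strrep("ACGT", 25))
  reads <- tibble::tibble(
    read_id = c("r1", "r2", "r3"),
    seq = c(strrep("ACGT", 25), strrep("ACGT", 5), strrep("ACGT", 50))
  )
  prof <- edit_distance_profile(reads, refs, min_len = 50, max_len = 150)
  expect_equal(nrow(prof$per_read), 1)
  expect_equal(prof$n_filtered, 2)
  expect_equal(glance(prof)$median_distance, 0)
  expect_error(edit_distance_profile(reads, refs, min_len = 1000), "window")
})
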