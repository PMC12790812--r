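test_that("IUPAC matching expands degeneracy sets per base", {
  hit <- iupac_match("AGRGTTYGATYMTGGCTCAG", "AGAGTTTGATCATGGCTCAG", 0)
  expect_true(hit$matches)
  expect_equal(hit$n_mismatch, 0L)
  expect_equal(iupac_match("ACGT", "ACGT", 0)$n_mismatch, 0L)
  one <- iupac_match("ACGT", "ACGA", 0)
  expect_false(one$matches)
  expect_equal(one$n_mismatch, 1L)
  # genome N matches nothing except primer N
  expect_equal(iupac_match("ACGT", "ACGN", 0)$n_mismatch, 1L)
  expect_equal(iupac_match("ACGN", "ACGN", 0)$n_mismatch, 0L)
  expect_error(iupac_match("ACGT", "ACG", 0), "length")
})

test_that("extraction recovers the fixture truth table exactly", {
  cm <- make_community(n_genomes = 2, operons = 3, divergence = 0.02,
                       seed = 41)
  amp <- extract_amplicons(cm$genomes, FWD_PRIMER, REV_PRIMER,
                           max_mismatch = 0, max_len = cm$product_len + 50)
  expect_equal(nrow(amp), nrow(cm$truth))
  amp_o <- amp[order(amp$genome_id, amp$start), ]
  truth_o <- cm$truth[order(cm$truth$genome_id, cm$truth$start), ]
  expect_equal(amp_o$start, truth_o$start)
  expect_equal(amp_o$end, truth_o$end)
  expect_equal(amp_o$strand, truth_o$strand)
  expect_equal(amp_o$product_seq, truth_o$product_seq)
  expect_equal(amp_o$insert_seq, truth_o$insert_seq)
})

test_that("identical copies collapse into one ASV; diverged copies stay apart", {
  same <- make_community(n_genomes = 1, operons = 3, divergence = 0, seed = 6)
  amp <- extract_amplicons(same$genomes, FWD_PRIMER, REV_PRIMER,
                           max_mismatch = 0, max_len = same$product_len + 50)
  cat1 <- asv_catalog(amp)
  expect_equal(nrow(amp), 3)
  expect_equal(nrow(cat1), 1)
  expect_equal(cat1$multiplicity, 3L)
  expect_equal(amplitype(amp)$amplitype, "3")

  div <- make_community(n_genomes = 1, operons = 2, divergence = 0.02,
                        core = 1000, seed = 6)
  amp2 <- extract_amplicons(div$genomes, FWD_PRIMER, REV_PRIMER,
                            max_mismatch = 0, max_len = div$product_len + 50)
  expect_equal(asv_catalog(amp2)$multiplicity, c(1L, 1L))
  expect_equal(amplitype(amp2)$amplitype, "1+1")
})

test_that("amplitype signature sorts multiplicities descending", {
  catalog <- tibble::tibble(
    genome_id = "g1", asv_id = paste0("g1.asv", 1:3),
    multiplicity = c(1L, 3L, 2L)
  )
  expect_equal(amplitype(catalog)$amplitype, "3+2+1")
  expect_equal(nrow(amplitype(catalog[0, ])), 0)
})

test_that("a forward site without a reverse partner yields nothing", {
  genome <- tibble::tibble(
    id = "g1",
    seq = paste0(strrep("T", 50), "AGAGTTTGATCATGGCTCAG", strrep("T", 50))
  )
  amp <- extract_amplicons(genome, FWD_PRIMER, REV_PRIMER, max_mismatch = 0)
  expect_equal(nrow(amp), 0)
})

test_that("strand symmetry: the reverse-complemented genome gives the same ASVs", {
  cm <- make_community(n_genomes = 2, operons = 2, seed = 51,
                       minus_strand_prob = 0.5)
  amp_f <- extract_amplicons(cm$genomes, FWD_PRIMER, REV_PRIMER,
                             max_mismatch = 0, max_len = cm$product_len + 50)
  rc <- cm$genomes
  rc$seq <- reverse_complement(rc$seq)
  amp_r <- extract_amplicons(rc, FWD_PRIMER, REV_PRIMER,
                             max_mismatch = 0, max_len = cm$product_len + 50)
  expect_equal(sort(amp_f$product_seq), sort(amp_r$product_seq))
  expect_equal(nrow(amp_f), nrow(amp_r))
})

test_that("production scanner agrees with a naive per-offset oracle", {
  set.seed(61)
  for (i in 1:5) {
    g <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")
    # implant two fuzzy primer sites
    site <- realize_iupac(FWD_PRIMER)
    substr(g, 300, 299 + nchar(site)) <- site
    site2 <- realize_iupac(FWD_PRIMER)
    substr(site2, 5, 5) <- "T" # may or may not add a mismatch
    substr(g, 1200, 1199 + nchar(site2)) <- site2
    for (mm in c(0, 2)) {
      got <- hifisim:::.scan_primer(strsplit(g, "")[[1]], FWD_PRIMER, mm)
      want <- oracle_scan(g, FWD_PRIMER, mm)
      expect_equal(got$start, want$start)
      expect_equal(got$mismatches, want$mismatches)
    }
  }
})

test_that("length window keeps cross-operon products out (or in when asked)", {
  cm <- make_community(n_genomes = 1, operons = 3, divergence = 0, seed = 71)
  narrow <- extract_amplicons(cm$genomes, FWD_PRIMER, REV_PRIMER,
                              max_mismatch = 0,
                              max_len = cm$product_len + 50)
  expect_equal(nrow(narrow), 3)
  # with no window, every fwd site pairs with every downstream rev site:
  # 3 + 2 + 1 nested/spanning products
  all_pairs <- extract_amplicons(cm$genomes, FWD_PRIMER, REV_PRIMER,
                                 max_mismatch = 0)
  expect_equal(nrow(all_pairs), 6)
})
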