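test_that("simulation is byte-identical under a fixed seed", {
  lib <- synthetic_library(blocks_per_cycle = c(4, 4), seed = 3)
  dir <- withr::local_tempdir()
  f1 <- file.path(dir, "a.fastq"); f2 <- file.path(dir, "b.fastq")
  s1 <- simulate_selection(lib, n_reads = 200, fastq = f1, seed = 5)
  s2 <- simulate_selection(lib, n_reads = 200, fastq = f2, seed = 5)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_selection(lib, n_reads = 200, fastq = NULL, seed = 6)
  expect_false(identical(s1$truth$compound_id, s3$truth$compound_id))
})

test_that("zero-error simulation decodes losslessly to the planted truth", {
  lib <- synthetic_library(blocks_per_cycle = c(6, 6, 6), tag_length = 8,
                           umi_length = 10, seed = 7)
  dir <- withr::local_tempdir()
  fq <- file.path(dir, "clean.fastq.gz")
  sim <- simulate_selection(lib, n_reads = 400, sub_rate = 0, indel_rate = 0,
                            fastq = fq, seed = 11)
  sel <- toy_selection(lib, fq)
  run <- run_decoding(sel)
  expect_equal(glance(run)$decoded_fraction, 1)
  # raw cube counts equal the sampled multinomial counts exactly
  truth_counts <- table(sim$truth$compound_id)
  cube <- run$cube
  expect_equal(sort(cube$raw_target), sort(as.integer(truth_counts)))
  expect_equal(cube$raw_target[match(names(truth_counts), cube$compound_id)],
               as.integer(truth_counts))
  # unique UMIs per molecule: UMI count equals raw count
  expect_true(all(cube$umi_target <= cube$raw_target))
})

test_that("per-compound counts under uniform weights fit a multinomial draw", {
  lib <- synthetic_library(blocks_per_cycle = c(5, 5), seed = 19)
  sim <- simulate_selection(lib, n_reads = 20000, sub_rate = 0, indel_rate = 0,
                            fastq = NULL, seed = 23)
  counts <- table(factor(sim$truth$compound_id, levels = compound_ids(lib)))
  gof <- stats::chisq.test(as.integer(counts), p = rep(1 / 25, 25))
  expect_gt(gof$p.value, 0.001)
})

test_that("planted enrichment weights have the closed-form hit share", {
  lib <- synthetic_library(blocks_per_cycle = c(6, 6, 6), seed = 1)
  w <- planted_enrichment_weights(lib, hit_fraction = 0.05, fold = 10, seed = 4)
  expect_equal(sum(w$weight), 1)
  h <- mean(w$is_hit)
  expect_equal(sum(w$weight[w$is_hit]), 10 * h / (10 * h + 1 - h), tolerance = 1e-10)
  # fold = 1 degenerates to uniform
  w1 <- planted_enrichment_weights(lib, hit_fraction = 0.05, fold = 1, seed = 4)
  expect_true(all(abs(w1$weight - 1 / nrow(w1)) < 1e-12))
  # simulated hit share matches expectation
  sim <- simulate_selection(lib, weights = w[, c("compound_id", "weight")],
                            n_reads = 20000, sub_rate = 0, fastq = NULL, seed = 8)
  got <- mean(sim$truth$compound_id %in% w$compound_id[w$is_hit])
  expect_equal(got, sum(w$weight[w$is_hit]), tolerance = 0.02)
})

test_that("decode rate is monotonically non-increasing in the substitution rate", {
  lib <- synthetic_library(blocks_per_cycle = c(6, 6, 6), tag_length = 8,
                           umi_length = 10, seed = 7)
  dir <- withr::local_tempdir()
  rates <- c(0, 0.005, 0.02, 0.05)
  decoded <- vapply(seq_along(rates), function(i) {
    fq <- file.path(dir, paste0("r", i, ".fastq"))
    simulate_selection(lib, n_reads = 1500, sub_rate = rates[i], indel_rate = 0,
                       fastq = fq, seed = 100 + i)
    glance(run_decoding(toy_selection(lib, fq)))$decoded_fraction
  }, numeric(1))
  expect_equal(decoded[1], 1)
  expect_true(all(diff(decoded) <= 0))
})

test_that("every read is accounted for: correct, flagged, or counted miscall", {
  lib <- synthetic_library(blocks_per_cycle = c(6, 6, 6), tag_length = 8,
                           umi_length = 10, seed = 7)
  dir <- withr::local_tempdir()
  fq <- file.path(dir, "err.fastq")
  sim <- simulate_selection(lib, n_reads = 2000, sub_rate = 0.02, indel_rate = 0.002,
                            fastq = fq, seed = 31)
  sel <- toy_selection(lib, fq)
  out <- decode_reads(as.character(Biostrings::readDNAStringSet(fq, format = "fastq")),
                      sel, read_ids = sim$truth$read_id)
  joined <- dplyr::left_join(out, sim$truth, by = "read_id", suffix = c("", ".true"))
  correct <- sum(joined$status == "decoded" &
                   joined$compound_id == joined$compound_id.true)
  miscall <- sum(joined$status == "decoded" &
                   joined$compound_id != joined$compound_id.true)
  flagged <- sum(joined$status != "decoded")
  expect_equal(correct + miscall + flagged, nrow(sim$truth))
  # silent miscalls exist in principle but must be rare at 2% error
  expect_lt(miscall / nrow(sim$truth), 0.02)
})
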