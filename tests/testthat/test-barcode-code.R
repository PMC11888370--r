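test_that("code construction satisfies the distance certificates at every length", {
  for (n in 7:16) {
    code <- build_code(n)
    expect_equal(code$k, n - 3)
    expect_equal(ncol(code$H), n)
    expect_true(all(colSums(code$H != 0) > 0))
    # sphere-packing sanity: capacity within the Hamming bound
    expect_lte(4^(n - 3), 4^n / (1 + 3 * n))

    pc <- build_code(n, parity = TRUE)
    expect_equal(pc$k, n - 4)
    expect_equal(pc$d, 4)
  }
  expect_error(build_code(6), "between 7 and 16")
  expect_error(build_code(17), "between 7 and 16")
})

test_that("construction is deterministic and the zero message encodes to all-A", {
  a <- build_code(9); b <- build_code(9)
  expect_identical(a$H, b$H)
  expect_equal(encode(a, rep(0, a$k)), strrep("A", 9))
  expect_error(encode(a, rep(0, 3)), "length")
})

test_that("every codeword satisfies the parity checks and pairwise distance >= 3 (n=7)", {
  code <- build_code(7)
  cw <- delcube:::all_codewords(code)
  expect_equal(ncol(cw), 256)
  expect_true(all(delcube:::gf4_matmul(code$H, cw) == 0))
  seqs <- delcube:::gf4_to_seqs(cw)
  expect_false(anyDuplicated(seqs) > 0)  # encode injective
  expect_gte(delcube:::min_pairwise_distance(seqs), 3)
})

test_that("exhaustive single-substitution correction recovers every codeword (n=7)", {
  code <- build_code(7)
  cw <- delcube:::all_codewords(code)
  seqs <- delcube:::gf4_to_seqs(cw)
  expect_true(all(decode_tags(code, seqs)$status == "valid"))
  for (p in 1:7) {
    for (a in 1:3) {
      corrupted <- cw
      corrupted[p, ] <- delcube:::gf4_add(corrupted[p, ], a)
      res <- decode_tags(code, delcube:::gf4_to_seqs(corrupted))
      expect_true(all(res$status == "corrected"))
      expect_equal(res$codeword, seqs)
      expect_true(all(res$error_position == p))
      expect_true(all(res$error_magnitude == a))
    }
  }
})

test_that("parity mode corrects singles and never silently miscorrects doubles (n=8)", {
  code <- build_code(8, parity = TRUE)
  expect_equal(4^code$k, 256)
  cw <- delcube:::all_codewords(code)
  seqs <- delcube:::gf4_to_seqs(cw)
  expect_gte(delcube:::min_pairwise_distance(seqs), 4)

  for (p in 1:8) {
    for (a in 1:3) {
      corrupted <- cw
      corrupted[p, ] <- delcube:::gf4_add(corrupted[p, ], a)
      res <- decode_tags(code, delcube:::gf4_to_seqs(corrupted))
      expect_true(all(res$status == "corrected" & res$codeword == seqs))
    }
  }
  # all 252 double corruptions of all 256 codewords: flagged, never rewritten
  for (p in 1:7) {
    for (q in (p + 1):8) {
      for (a in 1:3) {
        for (b in 1:3) {
          corrupted <- cw
          corrupted[p, ] <- delcube:::gf4_add(corrupted[p, ], a)
          corrupted[q, ] <- delcube:::gf4_add(corrupted[q, ], b)
          res <- decode_tags(code, delcube:::gf4_to_seqs(corrupted))
          expect_true(all(res$status %in% c("detected_uncorrectable", "invalid")))
        }
      }
    }
  }
})

test_that("encode/decode round-trips over sampled messages at longer lengths", {
  for (spec in list(list(n = 12, parity = FALSE), list(n = 13, parity = TRUE))) {
    code <- build_code(spec$n, spec$parity)
    msgs <- withr::with_seed(1, matrix(sample(0:3, code$k * 200, replace = TRUE), nrow = code$k))
    seqs <- delcube:::gf4_to_seqs(delcube:::encode_matrix(code, msgs))
    expect_true(all(decode_tags(code, seqs)$status == "valid"))
    corrupted <- vapply(seqs, function(s) withr::with_seed(nchar(s) + utf8ToInt(substr(s, 1, 1)), corrupt_tag(s, 1)), character(1), USE.NAMES = FALSE)
    res <- decode_tags(code, corrupted)
    fixable <- corrupted != seqs
    expect_true(all(res$status[fixable] == "corrected" & res$codeword[fixable] == seqs[fixable]))
  }
})

test_that("generate_barcode_set gives distinct, distant, seed-reproducible sets", {
  set <- generate_barcode_set(8, 96, seed = 42)
  expect_equal(nrow(set), 96)
  expect_false(anyDuplicated(set$barcode) > 0)
  expect_gte(delcube:::min_pairwise_distance(set$barcode), 3)
  expect_identical(set, generate_barcode_set(8, 96, seed = 42))
  expect_false(identical(set, generate_barcode_set(8, 96, seed = 43)))

  pset <- generate_barcode_set(9, 50, parity = TRUE, seed = 1)
  expect_gte(delcube:::min_pairwise_distance(pset$barcode), 4)

  expect_equal(nrow(generate_barcode_set(7, 1, seed = 1)), 1)
  expect_error(generate_barcode_set(7, 257, seed = 1), "256")
})

test_that("lookup decoder corrects unique neighbours and rejects ambiguous ones", {
  ld <- build_lookup_decoder(c("AAAA", "TTTT"))
  res <- decode_lookup(ld, c("AAAT", "AAAA", "GGCC"))
  expect_equal(res$status, c("corrected", "valid", "invalid"))
  expect_equal(res$codeword, c("AAAA", "AAAA", NA))

  # neighbour claimed by both tags decodes to invalid
  ld2 <- build_lookup_decoder(c("AAAA", "AAAT"))
  expect_equal(decode_lookup(ld2, "AAAC")$status, "invalid")
  # a tag is never reinterpreted as a neighbour of another tag
  expect_equal(decode_lookup(ld2, "AAAT")$status, "valid")

  expect_error(build_lookup_decoder(c("AAAA", "AAAA")), "duplicate")
  expect_error(build_lookup_decoder(c("AAAA", "TTT")), "length")
})

test_that("lookup and Hamming decoders agree on a Hamming codeword subset", {
  code <- build_code(7)
  tags <- generate_barcode_set(7, 40, seed = 9)$barcode
  ld <- build_lookup_decoder(tags)
  obs <- withr::with_seed(11, unlist(lapply(tags, function(t) {
    c(t, vapply(1:3, function(i) corrupt_tag(t, 1), character(1)))
  })))
  hres <- decode_tags(code, obs)
  lres <- decode_lookup(ld, obs)
  # where the Hamming decoder lands on a tag in the set, both must agree
  in_set <- hres$codeword %in% tags
  expect_equal(lres$status[in_set], hres$status[in_set])
  expect_equal(lres$codeword[in_set], hres$codeword[in_set])
  # corrections to codewords outside the 40-tag subset are invalid for lookup
  expect_true(all(lres$status[!in_set] == "invalid"))
})
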