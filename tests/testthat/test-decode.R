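# shared fixture: one small selection with errors, decoded once
fx <- local({
  lib <- synthetic_library(blocks_per_cycle = c(6, 6, 6), tag_length = 8,
                           umi_length = 10, seed = 7)
  dir <- tempfile("decode-fixture-")
  dir.create(dir)
  fq <- file.path(dir, "reads.fastq.gz")
  sim <- simulate_selection(lib, n_reads = 3000, sub_rate = 0.005, indel_rate = 0.001,
                            fastq = fq, seed = 42)
  sel <- toy_selection(lib, fq)
  run <- run_decoding(sel)
  list(lib = lib, dir = dir, fq = fq, sim = sim, sel = sel, run = run)
})

test_that("per-read outcomes behave as planted: clean, correctable, uncorrectable", {
  lib <- fx$lib
  sel <- fx$sel
  tagB <- lib$bb_sets$B$blocks$dna_tag
  mk_read <- function(a = 1, b = 1, c = 1, corrupt_cycle = NULL, k = 1) {
    tags <- list(A = lib$bb_sets$A$blocks$dna_tag[a],
                 B = tagB[b],
                 C = lib$bb_sets$C$blocks$dna_tag[c])
    if (!is.null(corrupt_cycle)) {
      tags[[corrupt_cycle]] <- corrupt_tag(tags[[corrupt_cycle]], k)
    }
    delcube:::.render_barcode(lib, tags, "ACGTACGTAC")
  }
  withr::local_seed(55)

  clean <- decode_read(mk_read(), sel)
  expect_equal(clean$status, "decoded")
  expect_equal(clean$compound_id, paste(lib$library_id, "A001", "B001", "C001", sep = "-"))
  expect_equal(clean$umi, "ACGTACGTAC")
  expect_equal(clean$corrected_tags, 0)

  one_sub <- decode_read(mk_read(corrupt_cycle = "B", k = 1), sel)
  expect_equal(one_sub$status, "decoded")
  expect_equal(one_sub$compound_id, clean$compound_id)
  expect_equal(one_sub$corrected_tags, 1)

  # 2 substitutions in a distance-3 tag: flagged or (rarely) miscalled,
  # never crashes; here check the flagged path dominates over 30 trials
  res <- vapply(1:30, function(i) decode_read(mk_read(corrupt_cycle = "B", k = 2), sel)$status,
                character(1))
  expect_gt(mean(res == "bb_tag_invalid"), 0.5)
  one <- decode_read(mk_read(corrupt_cycle = "B", k = 2), sel)
  if (one$status == "bb_tag_invalid") expect_equal(one$failed_cycle, "B")

  # reverse-complemented reads decode identically
  rc <- decode_read(delcube:::revcomp(mk_read()), sel)
  expect_equal(rc$compound_id, clean$compound_id)

  # random sequence: no library match
  expect_equal(decode_read(random_read(70), sel)$status, "no_library_match")
})

test_that("read conservation holds and the cube matches its invariants", {
  run <- fx$run
  tl <- tidy(run)
  expect_equal(sum(tl$n), nrow(fx$sim$truth))
  expect_equal(sum(tl$proportion), 1)
  cube <- run$cube
  # raw counts over compounds = decoded reads
  expect_equal(sum(cube$raw_target), tl$n[tl$status == "decoded"])
  expect_true(all(cube$umi_target <= cube$raw_target))
  expect_false(is.unsorted(cube$compound_id))
})

test_that("any 4-way shard split merges to the bit-identical single-pass cube", {
  lib <- fx$lib; sel <- fx$sel
  reads <- as.character(Biostrings::readDNAStringSet(fx$fq, format = "fastq"))
  ids <- fx$sim$truth$read_id
  shard_of <- withr::with_seed(17, sample(rep(1:4, length.out = length(reads))))
  states <- lapply(1:4, function(s) {
    out <- decode_reads(reads[shard_of == s], sel, ids[shard_of == s])
    delcube:::.outcomes_to_state(out, "target", sel$selection_id)
  })
  dir <- withr::local_tempdir()
  paths <- vapply(1:4, function(s) {
    p <- file.path(dir, paste0("shard", s, ".json"))
    save_umi_state(states[[s]], p)
    p
  }, character(1))
  merged <- merge_umi_states(paths)
  cube_merged <- build_cube(merged, sel)
  f1 <- file.path(dir, "merged.csv"); f2 <- file.path(dir, "single.csv")
  write_cube(cube_merged, f1)
  write_cube(fx$run$cube, f2)
  expect_identical(readLines(f1), readLines(f2))

  # merge algebra: identity and commutativity
  expect_equal(merge_umi_states(list(states[[1]]))$records, states[[1]]$records)
  ab <- merge_umi_states(list(states[[1]], states[[2]]))
  ba <- merge_umi_states(list(states[[2]], states[[1]]))
  expect_equal(ab$records, ba$records)

  # states from different selections refuse to merge
  other <- delcube:::new_umi_state("other_selection")
  expect_error(merge_umi_states(list(states[[1]], other)), "different selections")
})

test_that("UMI state round-trips through JSON", {
  st <- fx$run$umi_state
  p <- file.path(withr::local_tempdir(), "state.json")
  save_umi_state(st, p)
  back <- load_umi_state(p)
  expect_equal(back$selection_id, st$selection_id)
  expect_equal(tibble::as_tibble(back$records), tibble::as_tibble(st$records))
})

test_that("cube CSV output is deterministic, sparse-by-zero and round-trips", {
  lib <- fx$lib
  rec <- tibble::tibble(
    condition = c("c1", "c1", "c1", "c2"),
    library_id = lib$library_id,
    compound_id = paste(lib$library_id, c("A001-B001-C001", "A001-B001-C001",
                                          "A002-B002-C002", "A003-B003-C003"), sep = "-"),
    umi = c("AAAA", "CCCC", "AAAA", "GGGG"),
    reads = c(2L, 1L, 5L, 4L))
  sel2 <- new_selection_spec("s2", stats::setNames(list(lib), lib$library_id),
                             tibble::tibble(condition = c("c1", "c2"), replicate = "1",
                                            read_file = c("x", "y")))
  cube <- build_cube(delcube:::new_umi_state("s2", rec), sel2)
  expect_equal(nrow(cube), 3)
  expect_equal(ncol(cube), 2 + 3 + 2 * 2)  # keys + cycles + (raw,umi) x 2 conditions
  # compound seen only in c1 has zero counts in c2
  r1 <- cube[cube$compound_id == paste(lib$library_id, "A001-B001-C001", sep = "-"), ]
  expect_equal(r1$raw_c1, 3L); expect_equal(r1$umi_c1, 2L)
  expect_equal(r1$raw_c2, 0L); expect_equal(r1$umi_c2, 0L)
  p <- file.path(withr::local_tempdir(), "cube.csv")
  write_cube(cube, p)
  back <- read_cube(p)
  expect_equal(as.data.frame(back), as.data.frame(cube))
})

test_that("cluster1 UMI mode merges single-substitution UMI neighbours", {
  lib <- fx$lib
  rec <- tibble::tibble(
    condition = "c1", library_id = lib$library_id,
    compound_id = paste(lib$library_id, "A001-B001-C001", sep = "-"),
    umi = c("AAAA", "AAAT", "GGGG"), reads = c(10L, 1L, 3L))
  sel2 <- new_selection_spec("s2", stats::setNames(list(lib), lib$library_id),
                             tibble::tibble(condition = "c1", replicate = "1", read_file = "x"))
  st <- delcube:::new_umi_state("s2", rec)
  expect_equal(build_cube(st, sel2, umi_mode = "exact")$umi_c1, 3L)
  expect_equal(build_cube(st, sel2, umi_mode = "cluster1")$umi_c1, 2L)
})

test_that("report proportions sum to one and small libraries pool under 1%", {
  s <- decode_summary(fx$run$report)
  expect_equal(sum(s$status_proportions$proportion), 1, tolerance = 1e-9)
  expect_equal(s$library_shares$share, 1)

  # synthetic two-library share table: 99.5% / 0.5% pools the second
  tally <- tibble::tibble(condition = "t", status = "decoded",
                          library_id = c("L1", "L2"), n = c(995L, 5L))
  cube <- tibble::tibble(compound_id = c("L1-A001", "L2-A001"),
                         library_id = c("L1", "L2"),
                         bb_A = "A001", umi_t = c(995L, 5L), raw_t = c(995L, 5L))
  rep2 <- delcube:::new_decode_report("x", tally, cube)
  s2 <- decode_summary(rep2)
  expect_setequal(s2$library_shares$library_id, c("L1", "other"))
  expect_equal(s2$library_shares$share[s2$library_shares$library_id == "other"], 0.005)

  p <- withr::local_tempdir()
  out <- build_report(fx$run$report, json = file.path(p, "r.json"),
                      html = file.path(p, "r.html"))
  expect_true(file.exists(file.path(p, "r.json")))
  expect_true(file.exists(file.path(p, "r.html")))
  js <- jsonlite::fromJSON(file.path(p, "r.json"))
  expect_equal(js$total_reads, 3000)
})

test_that("an empty FASTQ gives an empty cube and a zero-read report", {
  lib <- fx$lib
  dir <- withr::local_tempdir()
  fq <- file.path(dir, "empty.fastq")
  writeLines(character(0), fq)
  run <- run_decoding(toy_selection(lib, fq))
  expect_equal(nrow(run$cube), 0)
  expect_equal(decode_summary(run$report)$total_reads, 0)
  expect_error(run_decoding(toy_selection(lib, file.path(dir, "missing.fastq"))),
               "not found")
})
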