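toy_cube <- function() {
  # 2x2x2 library, two conditions, hand-set counts
  grid <- expand.grid(C = c("C001", "C002"), B = c("B001", "B002"),
                      A = c("A001", "A002"), stringsAsFactors = FALSE)[, 3:1]
  cube <- tibble::tibble(
    compound_id = paste("L", grid$A, grid$B, grid$C, sep = "-"),
    library_id = "L",
    bb_A = grid$A, bb_B = grid$B, bb_C = grid$C,
    raw_target = c(10L, 4L, 6L, 2L, 8L, 1L, 3L, 6L),
    umi_target = c(9L, 4L, 5L, 2L, 7L, 1L, 3L, 5L),
    raw_ntc = c(2L, 3L, 1L, 4L, 2L, 2L, 3L, 3L),
    umi_ntc = c(2L, 3L, 1L, 4L, 2L, 2L, 3L, 3L))
  cube[order(cube$compound_id), ]
}

test_that("sampling depth is reads over diversity, linear and guarded", {
  cube <- toy_cube()
  expect_equal(sampling_depth(cube, "target", 1000), sum(cube$raw_target) / 1000)
  expect_equal(sampling_depth(cube[0, ], "target", 10), 0)
  d1 <- sampling_depth(cube, "target", 8)
  cube2 <- cube
  cube2$raw_target <- cube2$raw_target * 2L
  expect_equal(sampling_depth(cube2, "target", 8), 2 * d1)
  expect_error(sampling_depth(cube, "target", 0), "positive")
})

test_that("normalized counts are counts-per-million and sum to 1e6", {
  expect_equal(normalized_count(5, 1e6), 5)
  expect_equal(normalized_count(0, 100), 0)
  cnt <- c(3, 7, 90)
  expect_equal(sum(normalized_count(cnt, sum(cnt))), 1e6)
  expect_error(normalized_count(1, 0), "positive")
})

test_that("the binomial z-score matches direct evaluation and a Monte-Carlo null", {
  expect_equal(zscore(10, 1000, 0.01), 0)
  expect_equal(zscore(30, 1000, 0.01), 6.357, tolerance = 1e-3 / 6.357)
  # strictly increasing in count
  z <- zscore(0:50, 1000, 0.01)
  expect_true(all(diff(z) > 0))
  # Monte-Carlo: under the null, z has mean ~0 and sd ~1
  draws <- withr::with_seed(1, stats::rbinom(20000, 1000, 0.01))
  zs <- zscore(draws, 1000, 0.01)
  expect_lt(abs(mean(zs)), 0.05)
  expect_lt(abs(stats::sd(zs) - 1), 0.05)
  expect_error(zscore(1, 100, 0), "null_proportion")
})

test_that("the control-referenced z is zero at equal proportions", {
  expect_equal(zscore_vs_control(30, 1000, 60, 2000), 0)
  expect_gt(zscore_vs_control(50, 1000, 20, 1000), 0)
  expect_equal(zscore_vs_control(50, 1000, 20, 1000),
               -zscore_vs_control(20, 1000, 50, 1000))
})

test_that("the MLE enrichment ratio matches the estimator and its interval covers", {
  expect_equal(mle_ratio(10, 1000, 10, 1000)$ratio, 1)
  r <- mle_ratio(20, 1000, 2, 1000)
  expect_equal(r$ratio, 8.2, tolerance = 0.1 / 8.2)
  expect_gt(r$ci_low, 1)
  # reciprocity
  fwd <- mle_ratio(17, 900, 5, 1100)
  rev <- mle_ratio(5, 1100, 17, 900)
  expect_equal(fwd$ratio, 1 / rev$ratio)
  expect_equal(fwd$ci_low, 1 / rev$ci_high)
  # the point estimate sits inside the interval across a grid incl. zeros
  grid <- expand.grid(ct = c(0, 1, 5, 50), cc = c(0, 1, 5, 50))
  res <- mle_ratio(grid$ct, 500, grid$cc, 800)
  expect_true(all(res$ci_low <= res$ratio & res$ratio <= res$ci_high))
})

test_that("the conditional-binomial interval has near-nominal coverage", {
  # parametric check: true rates 8 per 1000 (target) vs 4 per 1000 (control)
  true_ratio <- 2
  covered <- withr::with_seed(99, {
    ct <- stats::rpois(4000, 8); cc <- stats::rpois(4000, 4)
    ci <- mle_ratio(ct, 1000, cc, 1000, alpha = 0.05)
    mean(ci$ci_low <= true_ratio & true_ratio <= ci$ci_high)
  })
  expect_gte(covered, 0.95 - 0.02)
})

test_that("compute_enrichment is permutation-equivariant and control-aware", {
  cube <- toy_cube()
  enr <- compute_enrichment(cube, "target", control = "ntc", library_size = 8)
  expect_s3_class(enr, "enrichment_table")
  expect_true(all(c("nsc", "zscore", "zscore_vs_control", "mle_ratio") %in% names(enr)))
  expect_true(all(enr$mle_ratio_ci_low <= enr$mle_ratio &
                    enr$mle_ratio <= enr$mle_ratio_ci_high))
  expect_true(all(enr$nsc >= 0))
  perm <- withr::with_seed(2, sample(nrow(cube)))
  enr_p <- compute_enrichment(cube[perm, ], "target", control = "ntc", library_size = 8)
  m <- match(enr$compound_id, enr_p$compound_id)
  expect_equal(enr_p$zscore[m], enr$zscore)
  expect_equal(enr_p$mle_ratio[m], enr$mle_ratio)
})

test_that("synthon aggregation conserves counts at every level", {
  cube <- toy_cube()
  di <- aggregate_synthons(cube, c("A", "B"))
  expect_equal(nrow(di), 4)
  expect_equal(sum(di$raw_target), sum(cube$raw_target))
  expect_equal(sum(di$umi_ntc), sum(cube$umi_ntc))
  # each disynthon row sums its two compound rows
  r <- di[di$bb_A == "A001" & di$bb_B == "B001", ]
  expect_equal(r$raw_target, 10L + 4L)
  mono <- aggregate_synthons(cube, "B")
  expect_equal(nrow(mono), 2)
  expect_equal(sum(mono$raw_target), sum(cube$raw_target))
  expect_error(aggregate_synthons(cube, c("A", "B", "C")), "proper subset")
  expect_error(aggregate_synthons(cube, "Z"), "unknown cycle")
  # metrics run on the aggregated table with synthon keys
  enr <- compute_enrichment(di, "target", control = "ntc", library_size = nrow(di))
  expect_equal(nrow(enr), 4)
  expect_true("synthon_key" %in% names(enr))
})

test_that("replicate overlap partitions passing keys into Venn regions", {
  mk <- function(ids, z) tibble::tibble(compound_id = ids, zscore = z)
  ids <- sprintf("L-%03d", 1:40)
  # identical tables: everything in the triple region
  t1 <- mk(ids, rep(c(5, 0), each = 20))
  ov <- replicate_overlap(list(r1 = t1, r2 = t1, r3 = t1), "zscore", 3)
  expect_equal(sum(ov$n_keys), 20)
  expect_equal(ov$n_keys[ov$members == "r1+r2+r3"], 20)
  expect_true(all(ov$n_keys[ov$degree < 3] == 0))

  # disjoint passing sets: only singleton regions
  z1 <- ifelse(seq_along(ids) <= 5, 5, 0)
  z2 <- ifelse(seq_along(ids) %in% 6:10, 5, 0)
  ov2 <- replicate_overlap(list(a = mk(ids, z1), b = mk(ids, z2)), "zscore", 3)
  expect_equal(ov2$n_keys[ov2$members == "a"], 5)
  expect_equal(ov2$n_keys[ov2$members == "b"], 5)
  expect_equal(ov2$n_keys[ov2$members == "a+b"], 0)

  # planted: 10 common + 5 unique per replicate
  common <- seq_len(10)
  uniq <- list(11:15, 16:20, 21:25)
  tabs <- lapply(1:3, function(r) {
    z <- rep(0, 40); z[common] <- 9; z[uniq[[r]]] <- 9
    mk(ids, z)
  })
  names(tabs) <- paste0("rep", 1:3)
  ov3 <- replicate_overlap(tabs, "zscore", 5)
  expect_equal(ov3$n_keys[ov3$members == "rep1+rep2+rep3"], 10)
  expect_true(all(ov3$n_keys[ov3$degree == 2] == 0))
  expect_true(all(ov3$n_keys[ov3$degree == 1] == 5))
  # regions partition the union
  expect_equal(sum(ov3$n_keys), 25)

  expect_error(replicate_overlap(list(mk(ids, 0), mk(rev(ids)[1:10], 0)), "zscore", 1),
               "key spaces")
})

test_that("planted enrichment is recovered by the z-score at depth >= 10", {
  lib <- synthetic_library(blocks_per_cycle = c(6, 6, 6), seed = 3)
  w <- planted_enrichment_weights(lib, hit_fraction = 0.01, fold = 10, seed = 12)
  sim <- simulate_selection(lib, weights = w[, c("compound_id", "weight")],
                            n_reads = 2500, sub_rate = 0, fastq = NULL, seed = 13)
  counts <- table(factor(sim$truth$compound_id, levels = w$compound_id))
  z <- zscore(as.integer(counts), sum(counts), 1 / nrow(w))
  planted <- w$is_hit
  expect_gt(stats::median(z[planted]), stats::quantile(z[!planted], 0.99))
})

test_that("the balanced baseline model beats the dummy only when signal exists", {
  withr::local_seed(8)
  n <- 160
  x <- as.data.frame(matrix(stats::rnorm(n * 5), n, 5))
  # separable labels from one feature; imbalanced 120/40
  y_sep <- x[[1]] > stats::quantile(x[[1]], 0.75)
  ev <- balance_and_evaluate(x, y_sep, folds = 5, seed = 2)
  g <- glance(ev)
  expect_equal(g$n_balanced, 2 * min(table(y_sep)))
  expect_gt(g$model_accuracy, 0.9)
  expect_lt(abs(g$dummy_accuracy - 0.5), 0.15)

  # labels independent of features: model within noise of the dummy
  y_null <- withr::with_seed(3, sample(y_sep))
  ev0 <- balance_and_evaluate(x, y_null, folds = 5, seed = 2)
  expect_lt(abs(glance(ev0)$model_accuracy - 0.5), 0.2)

  expect_error(balance_and_evaluate(x, rep(TRUE, n)), "2 classes")

  # pluggable classifier contract
  nearest_mean <- list(
    fit = function(x, y) lapply(split(x, y), colMeans),
    predict = function(model, x) {
      d <- vapply(model, function(mu) rowSums(sweep(as.matrix(x), 2, mu)^2), numeric(nrow(x)))
      colnames(d)[max.col(-d)]
    })
  ev2 <- balance_and_evaluate(x, y_sep, folds = 3, seed = 4, classifier = nearest_mean)
  expect_gt(glance(ev2)$model_accuracy, 0.7)
})
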