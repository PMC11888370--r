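#' NGS sampling depth of a selection condition
#'
#' Total raw reads for a condition divided by the library diversity: the
#' average number of reads available per library member, the first-order
#' gauge of whether a selection was sequenced deeply enough for its
#' counts to be interpretable.
#'
#' @param cube A `cube_table`.
#' @param condition Condition name (a `raw_<condition>` column must exist).
#' @param library_size Library diversity (number of possible compounds).
#' @return Reads per compound (a single number).
#' @export
sampling_depth <- function(cube, condition, library_size) {
  if (library_size <= 0) stop("library_size must be positive")
  col <- paste0("raw_", condition)
  if (!col %in% names(cube)) stop("no raw counts for condition \"", condition, "\"")
  sum(cube[[col]]) / library_size
}

#' Normalized sequence count (counts per million)
#'
#' @param count Raw or UMI-corrected count(s).
#' @param condition_total Total counts in the condition.
#' @return `count * 1e6 / condition_total`.
#' @export
normalized_count <- function(count, condition_total) {
  if (any(condition_total <= 0)) stop("condition_total must be positive")
  count * 1e6 / condition_total
}

#' Binomial z-score of a compound count against a null proportion
#'
#' Under the null that a compound is sampled with probability `p0` (by
#' default `1/library_size`, i.e. no enrichment relative to a uniform
#' pool), the observed count among `n` condition reads is
#' Binomial(`n`, `p0`); the z-score is the count's standardised deviation
#' `(count - n*p0) / sqrt(n*p0*(1-p0))`.
#'
#' @param count Observed count(s).
#' @param condition_total Total counts `n` in the condition.
#' @param null_proportion Null sampling probability `p0`, in (0, 1).
#' @return z-score(s).
#' @export
zscore <- function(count, condition_total, null_proportion) {
  if (any(null_proportion <= 0 | null_proportion >= 1)) {
    stop("null_proportion must be in (0, 1)")
  }
  if (any(condition_total <= 0)) stop("condition_total must be positive")
  mu <- condition_total * null_proportion
  (count - mu) / sqrt(mu * (1 - null_proportion))
}

#' Two-proportion z-score of target vs control counts
#'
#' Pooled two-proportion z: compares a compound's sampling proportion in
#' the target condition against a control (e.g. a no-target-control arm).
#' Zero when the two proportions are equal.
#'
#' @param count_target,total_target Compound count and condition total in
#'   the target arm.
#' @param count_control,total_control Same for the control arm.
#' @return z-score(s).
#' @export
zscore_vs_control <- function(count_target, total_target, count_control, total_control) {
  if (any(total_target <= 0) || any(total_control <= 0)) stop("totals must be positive")
  p1 <- count_target / total_target
  p2 <- count_control / total_control
  pool <- (count_target + count_control) / (total_target + total_control)
  se <- sqrt(pool * (1 - pool) * (1 / total_target + 1 / total_control))
  out <- (p1 - p2) / se
  out[se == 0] <- 0
  out
}

#' Maximum-likelihood enrichment ratio with confidence interval
#'
#' Models target and control counts as Poisson with rates proportional to
#' the condition totals; the enrichment ratio estimate is the rate ratio
#' with a half-count pseudocount,
#' `((count_target + 1/2)/total_target) / ((count_control + 1/2)/total_control)`.
#' The interval comes from the conditional-binomial construction: given
#' the summed count, the target count is Binomial with success probability
#' determined by the rate ratio, so a Clopper-Pearson interval for that
#' probability transforms into an exact interval for the ratio.
#'
#' @param count_target,total_target,count_control,total_control Counts and
#'   condition totals (vectorised).
#' @param alpha Interval level is `1 - alpha`.
#' @return A tibble with `ratio`, `ci_low`, `ci_high`.
#' @export
mle_ratio <- function(count_target, total_target, count_control, total_control,
                      alpha = 0.05) {
  if (any(total_target <= 0) || any(total_control <= 0)) stop("totals must be positive")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  k <- max(length(count_target), length(count_control))
  ct <- rep_len(count_target, k); cc <- rep_len(count_control, k)
  Nt <- rep_len(total_target, k); Nc <- rep_len(total_control, k)

  ratio <- ((ct + 0.5) / Nt) / ((cc + 0.5) / Nc)
  m <- ct + cc
  # Clopper-Pearson bounds for p = P(count lands in target | total m)
  p_lo <- ifelse(ct == 0, 0, stats::qbeta(alpha / 2, ct, m - ct + 1))
  p_hi <- ifelse(ct == m, 1, stats::qbeta(1 - alpha / 2, ct + 1, m - ct))
  odds <- function(p) ifelse(p >= 1, Inf, p / (1 - p))
  tibble::tibble(ratio = ratio,
                 ci_low = odds(p_lo) * Nc / Nt,
                 ci_high = odds(p_hi) * Nc / Nt)
}

# ---- enrichment driver ----------------------------------------------------

#' Compute per-compound enrichment metrics from a cube table
#'
#' Applies the metric suite to one condition of a cube (UMI-corrected
#' counts by default; raw counts via `counts = "raw"`).  When a control
#' condition is given, control-referenced metrics
#' (`zscore_vs_control`, `mle_ratio` and its interval) are included.
#'
#' @param cube A `cube_table` (or any tibble with the cube columns).
#' @param condition Target condition name.
#' @param control Optional control (e.g. NTC) condition name.
#' @param library_size Library diversity; defaults to the number of rows
#'   in the cube (appropriate when the cube covers the library).
#' @param counts `"umi"` or `"raw"`.
#' @param alpha Interval level for [mle_ratio()].
#' @return An `enrichment_table` tibble: key columns plus `count`,
#'   `sampling_depth`, `nsc`, `zscore`, and the control-referenced columns
#'   when `control` is given.
#' @export
compute_enrichment <- function(cube, condition, control = NULL,
                               library_size = NULL, counts = c("umi", "raw"),
                               alpha = 0.05) {
  counts <- match.arg(counts)
  col <- paste0(counts, "_", condition)
  if (!col %in% names(cube)) stop("no ", counts, " counts for condition \"", condition, "\"")
  library_size <- library_size %||% nrow(cube)
  key_cols <- intersect(c("compound_id", "synthon_key", "library_id",
                          grep("^bb_", names(cube), value = TRUE)), names(cube))
  out <- tibble::as_tibble(cube)[, key_cols]
  out$condition <- condition
  cnt <- cube[[col]]
  total <- sum(cnt)
  out$count <- cnt
  out$sampling_depth <- sum(cube[[paste0("raw_", condition)]] %||% cnt) / library_size
  out$nsc <- normalized_count(cnt, total)
  out$zscore <- zscore(cnt, total, 1 / library_size)
  if (!is.null(control)) {
    ccol <- paste0(counts, "_", control)
    if (!ccol %in% names(cube)) stop("no ", counts, " counts for condition \"", control, "\"")
    ctl <- cube[[ccol]]
    ctotal <- sum(ctl)
    out$zscore_vs_control <- zscore_vs_control(cnt, total, ctl, ctotal)
    mr <- mle_ratio(cnt, total, ctl, ctotal, alpha)
    out$mle_ratio <- mr$ratio
    out$mle_ratio_ci_low <- mr$ci_low
    out$mle_ratio_ci_high <- mr$ci_high
  }
  structure(out, class = c("enrichment_table", class(out)))
}

# ---- synthon aggregation --------------------------------------------------

#' Aggregate a cube to mono- or disynthon level
#'
#' Sums raw and UMI counts over all completions of the free cycles,
#' keeping the chosen cycles fixed: fixing one cycle of a three-cycle
#' library gives monosynthons, fixing two gives disynthons.  Counts are
#' conserved: every synthon row is the sum of its compound rows.
#'
#' @param cube A `cube_table`.
#' @param fixed_cycles Character vector of cycle labels to fix, e.g.
#'   `c("A", "B")`; must be a proper subset of the library's cycles.
#' @return A `cube_table`-like tibble keyed by `synthon_key` with the
#'   fixed cycles' `bb_*` columns and the summed count columns.
#' @export
aggregate_synthons <- function(cube, fixed_cycles) {
  cycle_cols <- grep("^bb_", names(cube), value = TRUE)
  all_cycles <- sub("^bb_", "", cycle_cols)
  if (!all(fixed_cycles %in% all_cycles)) {
    stop("unknown cycle(s): ", paste(setdiff(fixed_cycles, all_cycles), collapse = ", "))
  }
  if (length(fixed_cycles) >= length(all_cycles)) {
    stop("fixing all ", length(all_cycles), " cycles is the compound level; fix a proper subset")
  }
  if (length(fixed_cycles) < 1) stop("fix at least one cycle")
  fixed_cols <- paste0("bb_", fixed_cycles)
  count_cols <- grep("^(raw|umi)_", names(cube), value = TRUE)
  agg <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(cube),
                    dplyr::across(dplyr::all_of(c("library_id", fixed_cols)))),
    dplyr::across(dplyr::all_of(count_cols), sum), .groups = "drop")
  agg$synthon_key <- do.call(paste, c(list(agg$library_id),
                                      lapply(fixed_cols, function(cc) agg[[cc]]),
                                      list(sep = "-")))
  agg <- agg[order(agg$synthon_key),
             c("synthon_key", "library_id", fixed_cols, count_cols)]
  structure(agg, class = c("cube_table", class(tibble::tibble())),
            conditions = attr(cube, "conditions"), cycle_cols = fixed_cols)
}

# ---- replicate overlap ----------------------------------------------------

#' Reproducibility of enrichment calls across replicate selections
#'
#' Given per-replicate enrichment tables over the same key space and a
#' user-chosen threshold on a metric, counts for every subset of
#' replicates the keys that pass the threshold in exactly that subset --
#' the region counts of the replicate Venn diagram.  The regions partition
#' the union of passing keys.
#'
#' @param tables Named list (>= 2) of enrichment tables sharing a key
#'   column.
#' @param metric Metric column to threshold, e.g. `"zscore"`.
#' @param threshold Keys with `metric > threshold` pass.
#' @param key Key column name (default `compound_id`, falling back to
#'   `synthon_key`).
#' @return A tibble with `members` (replicate names, `+`-joined), `degree`
#'   and `n_keys`, one row per non-empty region possibility.
#' @export
replicate_overlap <- function(tables, metric, threshold, key = NULL) {
  stopifnot(length(tables) >= 2)
  if (is.null(names(tables)) || any(names(tables) == "")) {
    names(tables) <- paste0("rep", seq_along(tables))
  }
  key <- key %||% (if ("compound_id" %in% names(tables[[1]])) "compound_id" else "synthon_key")
  keyspace <- lapply(tables, function(t) sort(t[[key]]))
  for (i in seq_along(tables)[-1]) {
    if (!identical(keyspace[[1]], keyspace[[i]])) {
      stop("tables have mismatched key spaces (", names(tables)[1], " vs ",
           names(tables)[i], ")")
    }
  }
  passing <- lapply(tables, function(t) t[[key]][t[[metric]] > threshold])
  union_keys <- unique(unlist(passing))
  pattern <- if (length(union_keys) == 0) character(0) else {
    membership <- vapply(passing, function(p) union_keys %in% p,
                         logical(length(union_keys)))
    if (length(union_keys) == 1) membership <- matrix(membership, nrow = 1)
    apply(membership, 1, function(r) paste(names(tables)[r], collapse = "+"))
  }
  reps <- names(tables)
  regions <- unlist(lapply(seq_along(reps), function(k) {
    utils::combn(reps, k, paste, collapse = "+")
  }))
  tibble::tibble(members = regions,
                 degree = lengths(strsplit(regions, "+", fixed = TRUE)),
                 n_keys = vapply(regions, function(r) sum(pattern == r), integer(1),
                                 USE.NAMES = FALSE))
}

# ---- baseline ML evaluation ----------------------------------------------

#' Balance a labelled set and evaluate a baseline classifier against a dummy
#'
#' Undersamples the majority class to the minority size (seeded), then
#' runs k-fold cross-validation of a pluggable classifier and of a
#' majority-class dummy on the balanced set.  On balanced two-class data
#' the dummy sits near 0.5 accuracy, so the gap between the classifier and
#' the dummy measures whether the labels carry a learnable signal -- a
#' quality-control diagnostic as much as a model.
#'
#' The classifier is abstract: a list with `fit(x, y)` returning a model
#' and `predict(model, x)` returning class labels.  The default uses a
#' random forest when the `randomForest` package is installed.
#'
#' @param features Data frame or matrix of per-compound feature vectors
#'   (e.g. fingerprints).
#' @param labels Logical or two-level factor, one per row of `features`.
#' @param folds Number of cross-validation folds.
#' @param seed Integer seed for balancing and fold assignment.
#' @param classifier Optional list(fit=, predict=); see Details.
#' @return An `ml_eval` object: tibble of per-fold accuracies for model
#'   and dummy plus a `glance()`-able summary.
#' @export
balance_and_evaluate <- function(features, labels, folds = 5, seed = 1L,
                                 classifier = NULL) {
  features <- as.data.frame(features)
  y <- as.factor(labels)
  if (nlevels(y) != 2) stop("labels must have exactly 2 classes, got ", nlevels(y))
  if (min(table(y)) < folds) stop("minority class smaller than the number of folds")
  classifier <- classifier %||% .default_classifier()

  with_seed(seed, {
    # undersample the majority class
    n_min <- min(table(y))
    keep <- unlist(lapply(levels(y), function(lv) {
      idx <- which(y == lv)
      if (length(idx) > n_min) sample(idx, n_min) else idx
    }))
    keep <- sample(keep)  # shuffle before fold assignment
    xb <- features[keep, , drop = FALSE]
    yb <- droplevels(y[keep])
    fold <- rep_len(seq_len(folds), length(keep))

    res <- lapply(seq_len(folds), function(f) {
      tr <- fold != f; te <- !tr
      fit <- classifier$fit(xb[tr, , drop = FALSE], yb[tr])
      pred <- classifier$predict(fit, xb[te, , drop = FALSE])
      maj <- names(which.max(table(yb[tr])))
      tibble::tibble(fold = f,
                     model_accuracy = mean(as.character(pred) == as.character(yb[te])),
                     dummy_accuracy = mean(maj == as.character(yb[te])))
    })
    out <- dplyr::bind_rows(res)
    structure(list(folds = out, n_balanced = length(keep), classes = levels(yb)),
              class = "ml_eval")
  })
}

.default_classifier <- function() {
  if (!requireNamespace("randomForest", quietly = TRUE)) {
    stop("install the randomForest package or supply a classifier = list(fit=, predict=)")
  }
  list(
    fit = function(x, y) randomForest::randomForest(x, y),
    predict = function(model, x) stats::predict(model, x)
  )
}

#' @export
print.ml_eval <- function(x, ...) {
  cat(sprintf("<ml_eval> %d folds on %d balanced samples: model %.3f vs dummy %.3f\n",
              nrow(x$folds), x$n_balanced,
              mean(x$folds$model_accuracy), mean(x$folds$dummy_accuracy)))
  invisible(x)
}
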