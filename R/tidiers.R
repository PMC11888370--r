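#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a quaternary code: its parity-check matrix in long form
#'
#' @param x A `quaternary_code`.
#' @param ... Unused.
#' @return A tibble with `row`, `position`, `value` over GF(4).
#' @export
tidy.quaternary_code <- function(x, ...) {
  tibble::tibble(row = rep(seq_len(nrow(x$H)), ncol(x$H)),
                 position = rep(seq_len(ncol(x$H)), each = nrow(x$H)),
                 value = as.integer(x$H))
}

#' @rdname tidy.quaternary_code
#' @return For `glance()`: a one-row tibble with `n`, `k`, `codewords`,
#'   `min_distance`, `parity`.
#' @export
glance.quaternary_code <- function(x, ...) {
  tibble::tibble(n = x$n, k = x$k, codewords = 4^x$k,
                 min_distance = x$d, parity = x$parity)
}

#' Tidy a library specification: one row per building block
#'
#' @param x A `library_spec`.
#' @param ... Unused.
#' @return A tibble with `cycle`, `bb_id`, `dna_tag`, `smiles`.
#' @export
tidy.library_spec <- function(x, ...) {
  dplyr::bind_rows(lapply(x$bb_sets, function(s) {
    dplyr::mutate(s$blocks, cycle = s$cycle_label, .before = 1)
  }))
}

#' @rdname tidy.library_spec
#' @export
glance.library_spec <- function(x, ...) {
  sizes <- vapply(x$bb_sets, function(s) nrow(s$blocks), integer(1))
  tibble::tibble(library_id = x$library_id, n_cycles = length(sizes),
                 n_compounds = prod(sizes),
                 tag_length = x$bb_sets[[1]]$tag_length,
                 barcode_length = sum(x$schema$length),
                 error_correction_mode = x$error_correction_mode)
}

#' Tidy a decoding run: per-condition outcome tallies
#'
#' @param x A `decode_run` or `decode_report`.
#' @param ... Unused.
#' @return A tibble with `condition`, `status`, `n`, `proportion`.
#' @export
tidy.decode_report <- function(x, ...) {
  per <- dplyr::summarise(dplyr::group_by(x$tally, .data$condition, .data$status),
                          n = sum(.data$n), .groups = "drop_last")
  dplyr::ungroup(dplyr::mutate(per, proportion = .data$n / sum(.data$n)))
}

#' @rdname tidy.decode_report
#' @export
tidy.decode_run <- function(x, ...) tidy.decode_report(x$report, ...)

#' @rdname tidy.decode_report
#' @export
glance.decode_report <- function(x, ...) {
  s <- decode_summary(x)
  tibble::tibble(total_reads = s$total_reads, decoded_fraction = s$decoded_fraction,
                 n_compounds = nrow(x$cube))
}

#' @rdname tidy.decode_report
#' @export
glance.decode_run <- function(x, ...) glance.decode_report(x$report, ...)

#' Tidy a baseline-ML evaluation: per-fold accuracies
#'
#' @param x An `ml_eval` from [balance_and_evaluate()].
#' @param ... Unused.
#' @return A tibble with `fold`, `model_accuracy`, `dummy_accuracy`.
#' @export
tidy.ml_eval <- function(x, ...) x$folds

#' @rdname tidy.ml_eval
#' @export
glance.ml_eval <- function(x, ...) {
  tibble::tibble(model_accuracy = mean(x$folds$model_accuracy),
                 dummy_accuracy = mean(x$folds$dummy_accuracy),
                 accuracy_gap = mean(x$folds$model_accuracy - x$folds$dummy_accuracy),
                 folds = nrow(x$folds), n_balanced = x$n_balanced)
}
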