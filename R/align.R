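#' Semi-global alignment of a barcode pattern against a read
#'
#' Aligns the full `reference` pattern against a substring of each read
#' (free end gaps on the read only), with affine gap costs and a scoring
#' matrix in which the wildcard `N` scores 0 against every base, so that
#' constant regions anchor the alignment while variable regions neither
#' attract nor repel it.  Defaults: match +1, mismatch -1, gap open -2,
#' gap extend -1.
#'
#' An alignment whose error count (mismatches at non-wildcard positions
#' plus gap bases) exceeds `max_error_rate * nchar(reference)` is rejected;
#' absence of a hit is a value, not an error.  Ties are broken toward the
#' leftmost read start, then the fewest errors.
#'
#' @param reads Character vector of reads (ACGT).
#' @param reference The pattern, ACGT plus `N` wildcards.
#' @param max_error_rate Maximum tolerated errors per reference base,
#'   in `[0, 0.5)`.
#' @param match,mismatch,gap_open,gap_extend Scoring parameters.
#' @param sections Optional tibble with `name`, `start`, `end` (0-based
#'   half-open reference coordinates) whose read spans and substrings are
#'   recovered from the traceback.
#' @return A tibble with one row per read: `score`, `read_start`,
#'   `read_end` (0-based half-open), `errors`, `hit` (logical), and, for
#'   each requested section, `<name>` (extracted read substring) plus
#'   `<name>_start`/`<name>_end` span columns.
#' @export
semi_global_align <- function(reads, reference, max_error_rate = 0.1,
                              match = 1, mismatch = -1,
                              gap_open = -2, gap_extend = -1,
                              sections = NULL) {
  stopifnot(nchar(reference) > 0, max_error_rate >= 0, max_error_rate < 0.5)
  if (is.null(sections)) {
    sections <- tibble::tibble(name = character(0), start = integer(0), end = integer(0))
  }
  res <- cpp_semi_global(as.character(reads), reference, match, mismatch,
                         gap_open, gap_extend,
                         as.integer(sections$start), as.integer(sections$end))
  out <- tibble::tibble(score = res$score, read_start = res$read_start,
                        read_end = res$read_end, errors = res$errors)
  out$hit <- !is.na(out$errors) & out$errors <= max_error_rate * nchar(reference)
  for (s in seq_len(nrow(sections))) {
    out[[sections$name[s]]] <- res$sections[, s]
    out[[paste0(sections$name[s], "_start")]] <- res$section_start[, s]
    out[[paste0(sections$name[s], "_end")]] <- res$section_end[, s]
  }
  out
}

#' Match a read against the libraries of a selection
#'
#' Aligns each library's demultiplexing tag against the read in both
#' orientations and returns the library with the fewest alignment errors
#' within tolerance, or `NA` if none qualifies.
#'
#' @param reads Character vector of reads.
#' @param libraries Named list of `library_spec`s.
#' @param max_error_rate Tolerated errors per tag base.
#' @return A tibble with `library_id` (`NA` = no match) and `orientation`
#'   (`"fwd"` or `"rev"`; the orientation in which the tag matched best).
#' @export
match_library <- function(reads, libraries, max_error_rate = 0.1) {
  n <- length(reads)
  best_err <- rep(Inf, n)
  best_lib <- rep(NA_character_, n)
  best_ori <- rep(NA_character_, n)
  rc <- revcomp(reads)
  for (id in names(libraries)) {
    tag <- libraries[[id]]$library_tag
    for (ori in c("fwd", "rev")) {
      r <- if (ori == "fwd") reads else rc
      al <- semi_global_align(r, tag, max_error_rate)
      better <- al$hit & (al$errors < best_err)
      best_err[better] <- al$errors[better]
      best_lib[better] <- id
      best_ori[better] <- ori
    }
  }
  tibble::tibble(library_id = best_lib, orientation = best_ori, errors = best_err)
}

#' Align reads to a library's full barcode schema
#'
#' Builds the schema's reference string (constant sections verbatim,
#' `N` wildcards at building-block tag, UMI and index positions), aligns
#' it semi-globally against each read, and recovers the read span of every
#' schema section from the traceback.
#'
#' @param reads Character vector of reads, already in the library's
#'   orientation.
#' @param spec A `library_spec`.
#' @param max_error_rate Tolerated errors per reference base.
#' @return As [semi_global_align()], with one substring/span column group
#'   per schema section.
#' @export
align_schema <- function(reads, spec, max_error_rate = 0.1) {
  ref <- schema_reference(spec$schema)
  sc <- schema_coords(spec$schema)
  semi_global_align(reads, ref, max_error_rate,
                    sections = sc[, c("name", "start", "end")])
}
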