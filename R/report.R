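new_decode_report <- function(selection_id, tally, cube) {
  structure(list(selection_id = selection_id, tally = tally, cube = cube),
            class = "decode_report")
}

#' @export
print.decode_report <- function(x, ...) {
  s <- decode_summary(x)
  cat(sprintf("<decode_report> selection %s: %d reads, %.1f%% decoded\n",
              x$selection_id, s$total_reads, 100 * s$decoded_fraction))
  invisible(x)
}

#' Summarise a decoding run
#'
#' Failure-cause proportions (summing to 1 over all reads) and per-library
#' shares of UMI-corrected counts, with libraries below the 1% cutoff
#' pooled into `"other"` -- the numbers behind the decoding report's pie
#' charts.
#'
#' @param report A `decode_report` from [run_decoding()].
#' @param library_share_cutoff Pooling threshold for small libraries.
#' @return A list with `total_reads`, `decoded_fraction`,
#'   `status_proportions` (tibble `status`, `n`, `proportion`) and
#'   `library_shares` (tibble `library_id`, `umi_count`, `share`).
#' @export
decode_summary <- function(report, library_share_cutoff = 0.01) {
  tl <- dplyr::summarise(dplyr::group_by(report$tally, .data$status),
                         n = sum(.data$n), .groups = "drop")
  total <- sum(tl$n)
  tl$proportion <- if (total > 0) tl$n / total else rep(0, nrow(tl))
  decoded <- sum(tl$n[tl$status == "decoded"])

  cube <- report$cube
  umi_cols <- grep("^umi_", names(cube), value = TRUE)
  shares <- tibble::tibble(library_id = character(), umi_count = numeric(), share = numeric())
  if (nrow(cube) > 0 && length(umi_cols) > 0) {
    per_lib <- dplyr::summarise(
      dplyr::group_by(cube, .data$library_id),
      umi_count = sum(dplyr::pick(dplyr::all_of(umi_cols))), .groups = "drop")
    tot <- sum(per_lib$umi_count)
    per_lib$share <- if (tot > 0) per_lib$umi_count / tot else 0
    small <- per_lib$share < library_share_cutoff
    if (any(small) && any(!small)) {
      pooled <- tibble::tibble(library_id = "other",
                               umi_count = sum(per_lib$umi_count[small]),
                               share = sum(per_lib$share[small]))
      per_lib <- dplyr::bind_rows(per_lib[!small, ], pooled)
    }
    shares <- dplyr::arrange(per_lib, dplyr::desc(.data$share))
  }
  list(total_reads = total,
       decoded_fraction = if (total > 0) decoded / total else 0,
       status_proportions = dplyr::arrange(tl, dplyr::desc(.data$n)),
       library_shares = shares)
}

#' Write the decoding report to JSON and HTML
#'
#' The machine-readable JSON carries the full summary; the HTML is a
#' small self-contained page with the status breakdown and library shares.
#'
#' @param report A `decode_report`.
#' @param json Output JSON path, or `NULL` to skip.
#' @param html Output HTML path, or `NULL` to skip.
#' @return The [decode_summary()] list, invisibly.
#' @export
build_report <- function(report, json = NULL, html = NULL) {
  s <- decode_summary(report)
  if (!is.null(json)) {
    jsonlite::write_json(list(selection_id = report$selection_id,
                              total_reads = s$total_reads,
                              decoded_fraction = s$decoded_fraction,
                              status_proportions = s$status_proportions,
                              library_shares = s$library_shares,
                              per_condition = report$tally),
                         json, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(html)) {
    row <- function(...) paste0("<tr>", paste0("<td>", c(...), "</td>", collapse = ""), "</tr>")
    stat_rows <- paste(mapply(row, s$status_proportions$status,
                              s$status_proportions$n,
                              sprintf("%.2f%%", 100 * s$status_proportions$proportion)),
                       collapse = "\n")
    lib_rows <- if (nrow(s$library_shares)) {
      paste(mapply(row, s$library_shares$library_id, s$library_shares$umi_count,
                   sprintf("%.2f%%", 100 * s$library_shares$share)), collapse = "\n")
    } else ""
    writeLines(c(
      "<!DOCTYPE html><html><head><meta charset='utf-8'>",
      sprintf("<title>Decoding report: %s</title></head><body>", report$selection_id),
      sprintf("<h1>Decoding report &mdash; %s</h1>", report$selection_id),
      sprintf("<p>%d reads, %.2f%% decoded.</p>", s$total_reads, 100 * s$decoded_fraction),
      "<h2>Outcome breakdown</h2>",
      "<table border='1'><tr><th>status</th><th>reads</th><th>proportion</th></tr>",
      stat_rows, "</table>",
      "<h2>Library shares (UMI-corrected counts, &lt;1% pooled)</h2>",
      "<table border='1'><tr><th>library</th><th>UMI count</th><th>share</th></tr>",
      lib_rows, "</table>",
      "</body></html>"), html)
  }
  invisible(s)
}
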