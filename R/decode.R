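#' Decode a batch of reads against a selection
#'
#' The per-read pipeline: library demultiplexing (semi-global alignment of
#' each library tag, both orientations), schema alignment (wildcard
#' reference, per-section span recovery), per-cycle building-block tag
#' decoding (Hamming syndrome correction, hash-map lookup, or exact match,
#' per the library's `error_correction_mode`), then UMI extraction.  The
#' first failing stage determines the outcome status; every read gets
#' exactly one status.
#'
#' @param reads Character vector of reads.
#' @param selection A `selection_spec`.
#' @param read_ids Optional read identifiers.
#' @return A tibble with one row per read: `read_id`, `status` (one of
#'   `decoded`, `no_library_match`, `schema_align_failed`, `bb_tag_invalid`,
#'   `umi_missing`), `library_id`, `compound_id`, `umi` (set iff decoded),
#'   `failed_cycle` (set iff `bb_tag_invalid`), `corrected_tags`.
#' @export
decode_reads <- function(reads, selection, read_ids = NULL) {
  stopifnot(inherits(selection, "selection_spec"))
  n <- length(reads)
  if (is.null(read_ids)) read_ids <- sprintf("read_%06d", seq_len(n))
  out <- tibble::tibble(read_id = read_ids,
                        status = rep("no_library_match", n),
                        library_id = NA_character_,
                        compound_id = NA_character_,
                        umi = NA_character_,
                        failed_cycle = NA_character_,
                        corrected_tags = NA_integer_)
  if (n == 0) return(out)

  ds <- selection$decode_settings
  lm <- match_library(reads, selection$libraries, ds$library_error_rate)

  for (id in names(selection$libraries)) {
    spec <- selection$libraries[[id]]
    idx <- which(!is.na(lm$library_id) & lm$library_id == id)
    if (!length(idx)) next
    oriented <- ifelse(lm$orientation[idx] == "rev", revcomp(reads[idx]), reads[idx])
    al <- align_schema(oriented, spec, ds$schema_error_rate)

    ok <- al$hit
    out$library_id[idx] <- id
    out$status[idx[!ok]] <- "schema_align_failed"
    if (!any(ok)) next
    sub <- idx[ok]

    cycles <- names(spec$bb_sets)
    bb_calls <- matrix(NA_character_, length(sub), length(cycles),
                       dimnames = list(NULL, cycles))
    corrected <- integer(length(sub))
    failed <- rep(NA_character_, length(sub))
    for (cy in cycles) {
      sec_name <- spec$schema$name[spec$schema$kind == "bb_tag" &
                                     !is.na(spec$schema$cycle) & spec$schema$cycle == cy]
      obs <- al[[sec_name]][ok]
      dec <- spec$decoders[[cy]]
      want_len <- spec$bb_sets[[cy]]$tag_length
      len_ok <- !is.na(obs) & nchar(obs) == want_len & !grepl("[^ACGT]", obs)
      status <- rep("invalid", length(obs))
      codeword <- rep(NA_character_, length(obs))
      if (any(len_ok)) {
        res <- switch(dec$mode,
          hamming = decode_tags(dec$code, obs[len_ok])[, c("status", "codeword")],
          lookup = decode_lookup(dec$decoder, obs[len_ok])[, c("status", "codeword")],
          none = {
            hit <- obs[len_ok] %in% dec$tags
            tibble::tibble(status = ifelse(hit, "valid", "invalid"),
                           codeword = ifelse(hit, obs[len_ok], NA_character_))
          })
        status[len_ok] <- res$status
        codeword[len_ok] <- res$codeword
      }
      # a corrected/valid codeword must be one of this cycle's tags
      bb <- spec$bb_sets[[cy]]$blocks$bb_id[match(codeword, dec$tags)]
      good <- status %in% c("valid", "corrected") & !is.na(bb)
      bb_calls[good, cy] <- bb[good]
      corrected <- corrected + (good & status == "corrected")
      failed[is.na(failed) & !good] <- cy
    }

    called <- is.na(failed)
    out$status[sub[!called]] <- "bb_tag_invalid"
    out$failed_cycle[sub[!called]] <- failed[!called]
    out$corrected_tags[sub] <- corrected

    # UMI extraction
    has_umi <- any(spec$schema$kind == "umi")
    if (has_umi) {
      umi_name <- spec$schema$name[spec$schema$kind == "umi"][1]
      umi_len <- spec$schema$length[spec$schema$kind == "umi"][1]
      umi <- al[[umi_name]][ok]
      umi_ok <- !is.na(umi) & nchar(umi) > 0 & nchar(umi) >= umi_len - 2 &
        nchar(umi) <= umi_len + 2 & !grepl("[^ACGT]", umi)
    } else {
      umi <- rep(NA_character_, length(sub))
      umi_ok <- rep(TRUE, length(sub))
    }
    out$status[sub[called & !umi_ok]] <- "umi_missing"

    done <- called & umi_ok
    if (any(done)) {
      ids <- apply(bb_calls[done, , drop = FALSE], 1, paste, collapse = "-")
      out$status[sub[done]] <- "decoded"
      out$compound_id[sub[done]] <- paste(id, ids, sep = "-")
      out$umi[sub[done]] <- umi[done]
    }
  }
  out
}

#' Decode a single read
#'
#' Convenience wrapper over [decode_reads()] for one read.
#'
#' @param read A single read string.
#' @param selection A `selection_spec`.
#' @return A one-row tibble; see [decode_reads()].
#' @export
decode_read <- function(read, selection) {
  decode_reads(read, selection, read_ids = "read_000001")
}

# ---- UMI state ------------------------------------------------------------

new_umi_state <- function(selection_id, records = NULL) {
  if (is.null(records)) {
    records <- tibble::tibble(condition = character(), library_id = character(),
                              compound_id = character(), umi = character(),
                              reads = integer())
  }
  structure(list(selection_id = selection_id, records = records), class = "umi_state")
}

#' @export
print.umi_state <- function(x, ...) {
  cat(sprintf("<umi_state> selection %s: %d (condition, compound, UMI) records, %d reads\n",
              x$selection_id, nrow(x$records), sum(x$records$reads)))
  invisible(x)
}

#' Save decoder UMI state as JSON
#'
#' Decoding shards of a read set independently requires coordinating
#' UMI-corrected counts across shards: each decoder saves its UMI state
#' (the set of observed UMIs per condition and compound, with raw read
#' tallies) and the states are merged afterwards.
#'
#' @param state A `umi_state`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
save_umi_state <- function(state, path) {
  stopifnot(inherits(state, "umi_state"))
  jsonlite::write_json(list(selection_id = state$selection_id,
                            records = state$records),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a UMI state JSON
#' @param path Path written by [save_umi_state()].
#' @return A `umi_state`.
#' @export
load_umi_state <- function(path) {
  x <- jsonlite::fromJSON(path)
  rec <- tibble::as_tibble(x$records)
  rec$reads <- as.integer(rec$reads)
  new_umi_state(x$selection_id, rec)
}

#' Merge UMI states from parallel decoding shards
#'
#' Raw counts add; UMI sets union.  The merge is associative and
#' commutative, so any partition of the reads decoded independently and
#' merged gives the same state as a single pass.  States from different
#' selections (mismatched `selection_id`) refuse to merge.
#'
#' @param states A list of `umi_state` objects, or paths to saved states.
#' @return The merged `umi_state`.
#' @export
merge_umi_states <- function(states) {
  states <- lapply(states, function(s) if (is.character(s)) load_umi_state(s) else s)
  stopifnot(length(states) >= 1)
  ids <- unique(vapply(states, `[[`, character(1), "selection_id"))
  if (length(ids) != 1) {
    stop("cannot merge UMI states from different selections: ", paste(ids, collapse = ", "))
  }
  rec <- dplyr::bind_rows(lapply(states, `[[`, "records"))
  rec <- dplyr::summarise(
    dplyr::group_by(rec, .data$condition, .data$library_id, .data$compound_id, .data$umi),
    reads = sum(.data$reads), .groups = "drop")
  rec <- dplyr::arrange(rec, .data$condition, .data$compound_id, .data$umi)
  new_umi_state(ids, rec)
}

# outcomes tibble (+condition) -> umi_state records
.outcomes_to_state <- function(outcomes, condition, selection_id) {
  dec <- outcomes[outcomes$status == "decoded", ]
  if (nrow(dec) == 0) return(new_umi_state(selection_id))
  dec$umi[is.na(dec$umi)] <- ""   # libraries without a UMI section
  rec <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(condition = condition,
                                   library_id = dec$library_id,
                                   compound_id = dec$compound_id,
                                   umi = dec$umi),
                    .data$condition, .data$library_id, .data$compound_id, .data$umi),
    reads = dplyr::n(), .groups = "drop")
  new_umi_state(selection_id, rec)
}

# greedy Hamming-1 UMI clustering: descending read count, ties by UMI string
.cluster1_count <- function(umis, reads) {
  o <- order(-reads, umis)
  umis <- umis[o]
  accepted <- character(0)
  for (u in umis) {
    if (length(accepted) == 0 ||
        !any(nchar(accepted) == nchar(u) & hamming(rep(u, length(accepted)), accepted) <= 1)) {
      accepted <- c(accepted, u)
    }
  }
  length(accepted)
}

# ---- cube -----------------------------------------------------------------

#' Build the per-compound count ("cube") table from UMI state
#'
#' One row per decoded compound: the compound id, library, per-cycle
#' building-block ids, then per condition a raw read count and a
#' UMI-corrected count (number of distinct UMIs; with `umi_mode =
#' "cluster1"`, UMIs within Hamming distance 1 are first merged greedily by
#' descending read count).  Compounds absent from a condition get zero
#' counts there.
#'
#' @param state A `umi_state`.
#' @param selection The `selection_spec` the state came from (supplies the
#'   cycle structure and condition list).
#' @param umi_mode `"exact"` or `"cluster1"`; defaults to the selection's
#'   decode settings.
#' @return A `cube_table` tibble, sorted by `compound_id`.
#' @export
build_cube <- function(state, selection, umi_mode = NULL) {
  stopifnot(inherits(state, "umi_state"), inherits(selection, "selection_spec"))
  umi_mode <- umi_mode %||% selection$decode_settings$umi_mode
  conditions <- unique(selection$conditions$condition)
  rec <- state$records
  cycles_by_lib <- lapply(selection$libraries, function(s) names(s$bb_sets))
  max_cycles <- max(vapply(cycles_by_lib, length, integer(1)))
  cycle_cols <- paste0("bb_", LETTERS[seq_len(max_cycles)])

  if (nrow(rec) == 0) {
    empty <- tibble::tibble(compound_id = character(), library_id = character())
    for (cc in cycle_cols) empty[[cc]] <- character()
    for (co in conditions) {
      empty[[paste0("raw_", co)]] <- integer()
      empty[[paste0("umi_", co)]] <- integer()
    }
    return(structure(empty, class = c("cube_table", class(empty)),
                     conditions = conditions, cycle_cols = cycle_cols))
  }

  per <- dplyr::summarise(
    dplyr::group_by(rec, .data$condition, .data$library_id, .data$compound_id),
    raw = sum(.data$reads),
    umi = if (all(.data$umi == "")) sum(.data$reads)
          else if (umi_mode == "cluster1") .cluster1_count(.data$umi, .data$reads)
          else dplyr::n_distinct(.data$umi),
    .groups = "drop")

  wide <- tidyr::pivot_wider(per, names_from = "condition",
                             values_from = c("raw", "umi"),
                             names_glue = "{.value}_{condition}",
                             values_fill = 0L)
  for (co in conditions) {
    for (p in c("raw_", "umi_")) {
      if (!paste0(p, co) %in% names(wide)) wide[[paste0(p, co)]] <- 0L
    }
  }
  # per-cycle building-block ids from the compound id
  bb <- strsplit(wide$compound_id, "-", fixed = TRUE)
  for (i in seq_len(max_cycles)) {
    wide[[cycle_cols[i]]] <- vapply(bb, function(p) {
      if (length(p) >= i + 1) p[i + 1] else NA_character_
    }, character(1))
  }
  count_cols <- as.vector(t(outer(c("raw_", "umi_"), conditions, paste0)))
  wide <- wide[order(wide$compound_id),
               c("compound_id", "library_id", cycle_cols, count_cols)]
  structure(wide, class = c("cube_table", class(tibble::tibble())),
            conditions = conditions, cycle_cols = cycle_cols)
}

#' Write a cube table to CSV
#'
#' Deterministic bytes: rows sorted by `compound_id`, fixed column order
#' (`compound_id`, `library_id`, per-cycle block ids, then per-condition
#' `raw_*` and `umi_*` counts).
#'
#' @param cube A `cube_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path) {
  readr::write_csv(as.data.frame(cube), path, progress = FALSE)
  invisible(path)
}

#' Read a cube CSV
#'
#' Accepts any CSV with the documented cube columns, whether written by
#' [write_cube()] or produced elsewhere.
#'
#' @param path Path to the CSV.
#' @return A `cube_table` tibble.
#' @export
read_cube <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  conditions <- unique(sub("^raw_", "", grep("^raw_", names(x), value = TRUE)))
  cycle_cols <- grep("^bb_", names(x), value = TRUE)
  structure(x, class = c("cube_table", class(x)),
            conditions = conditions, cycle_cols = cycle_cols)
}

# ---- full run -------------------------------------------------------------

#' Decode a full selection: FASTQ reads to cube, report and UMI state
#'
#' Streams every read file of the selection, decodes reads in batches,
#' tallies outcome statuses per condition (read conservation: the status
#' counts always sum to the number of input reads), and assembles the
#' count cube and the mergeable UMI state.
#'
#' @param selection A `selection_spec`.
#' @param batch_size Reads per decoding batch.
#' @param verbose Emit progress lines to stderr.
#' @return A list of class `decode_run` with elements `cube`
#'   (`cube_table`), `report` (`decode_report`: per-condition status
#'   tallies and per-library UMI shares) and `umi_state`.
#' @export
run_decoding <- function(selection, batch_size = 20000L, verbose = FALSE) {
  stopifnot(inherits(selection, "selection_spec"))
  tallies <- list()
  state <- new_umi_state(selection$selection_id)
  for (i in seq_len(nrow(selection$conditions))) {
    cond <- selection$conditions$condition[i]
    path <- selection$conditions$read_file[i]
    if (!file.exists(path)) {
      stop("read file not found: ", path, " (condition ", cond, ")")
    }
    reads_set <- tryCatch(
      Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = FALSE),
      error = function(e) stop("failed to read FASTQ ", path, ": ", conditionMessage(e)))
    nm <- names(reads_set)
    reads <- as.character(reads_set)
    total <- length(reads)
    if (verbose) message(sprintf("[%s] %s: %d reads", cond, basename(path), total))
    done <- 0L
    while (done < total) {
      take <- seq(done + 1L, min(done + batch_size, total))
      out <- decode_reads(reads[take], selection, read_ids = nm[take])
      tallies[[length(tallies) + 1]] <- dplyr::count(
        tibble::tibble(condition = cond, status = out$status,
                       library_id = out$library_id),
        .data$condition, .data$status, .data$library_id, name = "n")
      state <- merge_umi_states(list(state, .outcomes_to_state(out, cond, selection$selection_id)))
      done <- done + length(take)
    }
    if (total == 0) {
      tallies[[length(tallies) + 1]] <- tibble::tibble(condition = cond,
                                                       status = character(),
                                                       library_id = character(),
                                                       n = integer())
    }
  }
  tally <- dplyr::summarise(
    dplyr::group_by(dplyr::bind_rows(tallies), .data$condition, .data$status, .data$library_id),
    n = sum(.data$n), .groups = "drop")
  cube <- build_cube(state, selection)
  report <- new_decode_report(selection$selection_id, tally, cube)
  structure(list(cube = cube, report = report, umi_state = state), class = "decode_run")
}

#' @export
print.decode_run <- function(x, ...) {
  print(x$report)
  invisible(x)
}
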