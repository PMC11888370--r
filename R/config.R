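#' Suggest the closest valid key for a misspelled one
#'
#' Configuration validation does not just reject unknown keys -- it points
#' at the nearest known key when one is plausibly intended.  "Plausibly"
#' means Levenshtein edit distance at most 2; anything further away returns
#' `NULL` rather than an absurd suggestion.  Ties are broken
#' lexicographically.
#'
#' @param bad_key The unrecognised key.
#' @param valid_keys Non-empty character vector of known keys.
#' @return The suggested key, or `NULL` if nothing is within distance 2.
#' @examples
#' suggest_key("umo", c("umi", "index"))
#' @export
suggest_key <- function(bad_key, valid_keys) {
  stopifnot(is.character(bad_key), length(bad_key) == 1, length(valid_keys) > 0)
  d <- utils::adist(bad_key, valid_keys)[1, ]
  best <- min(d)
  if (best > 2) return(NULL)
  sort(valid_keys[d == best])[1]
}

.config_stop <- function(file, where, msg, suggestion = NULL) {
  full <- sprintf("%s (in %s, %s)", msg, file, where)
  if (!is.null(suggestion)) full <- paste0(full, sprintf("; did you mean \"%s\"?", suggestion))
  rlang::abort(full, class = "delcube_config_error")
}

.check_keys <- function(x, valid, required, file, where) {
  for (k in setdiff(names(x), valid)) {
    .config_stop(file, where, sprintf("unknown key \"%s\"", k), suggest_key(k, valid))
  }
  for (k in setdiff(required, names(x))) {
    .config_stop(file, where, sprintf("missing required key \"%s\"", k))
  }
  invisible(TRUE)
}

# ---- building-block files -------------------------------------------------

#' Read a building-block table
#'
#' Building blocks come as CSV or TSV (delimiter inferred from the file
#' extension) with a header row; required columns `id` and `tag`, optional
#' `smiles`.  Tags must be uppercase ACGT, non-empty, all the same length,
#' and distinct; ids must be distinct.  Row order is preserved.
#'
#' @param path Path to the `.csv` or `.tsv` file.
#' @param cycle_label Label of the synthesis cycle this set encodes
#'   (e.g. `"A"`).
#' @return A `building_block_set`: list with `cycle_label`, `tag_length`,
#'   and `blocks` (a tibble with `bb_id`, `dna_tag`, `smiles`).
#' @export
load_building_blocks <- function(path, cycle_label = "A") {
  if (!file.exists(path)) {
    rlang::abort(paste0("building-block file not found: ", path), class = "delcube_config_error")
  }
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  tab <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  for (k in setdiff(names(tab), c("id", "tag", "smiles"))) {
    .config_stop(path, "header", sprintf("unknown column \"%s\"", k),
                 suggest_key(k, c("id", "tag", "smiles")))
  }
  for (k in setdiff(c("id", "tag"), names(tab))) {
    .config_stop(path, "header", sprintf("missing required column \"%s\"", k))
  }
  if (nrow(tab) == 0) .config_stop(path, "body", "no building blocks")
  bad <- which(is.na(tab$tag) | tab$tag == "" | grepl("[^ACGT]", tab$tag))
  if (length(bad)) {
    row <- bad[1]
    ch <- regmatches(tab$tag[row], regexpr("[^ACGT]", tab$tag[row]))
    detail <- if (length(ch) && nzchar(ch)) sprintf("invalid character \"%s\" in tag \"%s\"", ch, tab$tag[row])
              else "empty tag"
    .config_stop(path, paste0("row ", row), detail)
  }
  if (length(unique(nchar(tab$tag))) != 1) {
    lens <- nchar(tab$tag)
    row <- which(lens != lens[1])[1]
    .config_stop(path, paste0("row ", row),
                 sprintf("tag length %d differs from the set's length %d", lens[row], lens[1]))
  }
  if (anyDuplicated(tab$tag)) {
    row <- which(duplicated(tab$tag))[1]
    .config_stop(path, paste0("row ", row), sprintf("duplicate tag \"%s\"", tab$tag[row]))
  }
  if (anyDuplicated(tab$id)) {
    row <- which(duplicated(tab$id))[1]
    .config_stop(path, paste0("row ", row), sprintf("duplicate id \"%s\"", tab$id[row]))
  }
  blocks <- tibble::tibble(bb_id = tab$id, dna_tag = tab$tag,
                           smiles = if ("smiles" %in% names(tab)) tab$smiles else NA_character_)
  structure(list(cycle_label = cycle_label, tag_length = nchar(blocks$dna_tag[1]),
                 blocks = blocks),
            class = "building_block_set")
}

# ---- barcode schema -------------------------------------------------------

.SECTION_KINDS <- c("constant", "bb_tag", "umi", "index")

new_barcode_schema <- function(sections, file = "<in-memory>") {
  stopifnot(is.data.frame(sections))
  sections <- tibble::as_tibble(sections)
  if (!"sequence" %in% names(sections)) sections$sequence <- NA_character_
  if (!"cycle" %in% names(sections)) sections$cycle <- NA_character_
  for (i in seq_len(nrow(sections))) {
    s <- sections[i, ]
    where <- sprintf("barcode_schema section %d (\"%s\")", i, s$name)
    if (!s$kind %in% .SECTION_KINDS) {
      .config_stop(file, where, sprintf("unknown section kind \"%s\"", s$kind),
                   suggest_key(s$kind, .SECTION_KINDS))
    }
    if (is.na(s$length) || s$length <= 0) .config_stop(file, where, "section length must be positive")
    if (s$kind == "constant") {
      if (is.na(s$sequence) || grepl("[^ACGT]", s$sequence)) {
        .config_stop(file, where, "constant section needs an ACGT sequence")
      }
      if (nchar(s$sequence) != s$length) {
        .config_stop(file, where, sprintf("sequence length %d != declared length %d",
                                          nchar(s$sequence), s$length))
      }
    }
    if (s$kind == "bb_tag" && (is.na(s$cycle) || s$cycle == "")) {
      .config_stop(file, where, "bb_tag section needs a cycle label")
    }
  }
  if (anyDuplicated(sections$name)) {
    .config_stop(file, "barcode_schema", "duplicate section names")
  }
  dup <- sections$cycle[sections$kind == "bb_tag"]
  if (anyDuplicated(dup)) {
    .config_stop(file, "barcode_schema",
                 sprintf("more than one bb_tag section for cycle \"%s\"", dup[duplicated(dup)][1]))
  }
  structure(sections, class = c("barcode_schema", class(sections)))
}

# full reference string with N at variable (bb_tag / umi) positions
schema_reference <- function(schema, wildcard_index = TRUE) {
  paste(vapply(seq_len(nrow(schema)), function(i) {
    s <- schema[i, ]
    if (s$kind == "constant") s$sequence
    else if (s$kind == "index" && !wildcard_index) s$sequence
    else strrep("N", s$length)
  }, character(1)), collapse = "")
}

# 0-based half-open section coordinates within the reference
schema_coords <- function(schema) {
  ends <- cumsum(schema$length)
  tibble::tibble(name = schema$name, kind = schema$kind, cycle = schema$cycle,
                 start = c(0L, utils::head(ends, -1)), end = as.integer(ends))
}

# ---- library JSON ---------------------------------------------------------

.LIBRARY_KEYS <- c("library_id", "library_tag", "error_correction_mode",
                   "barcode_schema", "building_blocks", "reaction_scheme")
.SECTION_KEYS <- c("name", "kind", "length", "sequence", "cycle")

#' Load and cross-validate a library definition
#'
#' A library is defined by a small JSON file: its id, the demultiplexing
#' tag, the ordered barcode schema (sections are a list, so barcode order
#' is explicit), references to the per-cycle building-block CSV/TSV files
#' (paths resolved relative to the JSON file), the reaction scheme, and the
#' tag error-correction mode (`"hamming"`, `"lookup"` or `"none"`).
#' Every cross-check failure is reported with the file, the offending
#' field or row, and -- for misspelled keys -- a suggested correction.
#'
#' @param path Path to the library JSON file.
#' @return A `library_spec` object.
#' @seealso [write_library()] for the inverse, [load_selection()] for
#'   selection experiments.
#' @export
load_library <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("library file not found: ", path), class = "delcube_config_error")
  }
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  .check_keys(x, .LIBRARY_KEYS,
              c("library_id", "library_tag", "barcode_schema", "building_blocks"),
              path, "top level")
  mode <- x$error_correction_mode %||% "none"
  if (!mode %in% c("hamming", "lookup", "none")) {
    .config_stop(path, "error_correction_mode",
                 sprintf("unknown mode \"%s\"", mode),
                 suggest_key(mode, c("hamming", "lookup", "none")))
  }
  if (grepl("[^ACGT]", x$library_tag)) {
    .config_stop(path, "library_tag", sprintf("tag \"%s\" contains non-ACGT characters", x$library_tag))
  }

  secs <- lapply(seq_along(x$barcode_schema), function(i) {
    s <- x$barcode_schema[[i]]
    .check_keys(s, .SECTION_KEYS, c("name", "kind", "length"),
                path, sprintf("barcode_schema section %d", i))
    tibble::tibble(name = s$name, kind = s$kind, length = as.integer(s$length),
                   sequence = s$sequence %||% NA_character_,
                   cycle = s$cycle %||% NA_character_)
  })
  schema <- new_barcode_schema(dplyr::bind_rows(secs), file = path)

  bb_sets <- list()
  for (i in seq_along(x$building_blocks)) {
    b <- x$building_blocks[[i]]
    .check_keys(b, c("cycle", "file"), c("cycle", "file"),
                path, sprintf("building_blocks entry %d", i))
    bb_path <- b$file
    if (!file.exists(bb_path)) bb_path <- file.path(dirname(path), b$file)
    bb_sets[[b$cycle]] <- load_building_blocks(bb_path, b$cycle)
  }

  new_library_spec(
    library_id = x$library_id,
    library_tag = x$library_tag,
    schema = schema,
    bb_sets = bb_sets,
    reaction_scheme = unlist(x$reaction_scheme) %||% character(0),
    error_correction_mode = mode,
    file = path
  )
}

#' Construct a library specification from its parts
#'
#' The programmatic counterpart of [load_library()]; used by the built-in
#' synthetic library generator and by tests.  All cross-invariants are
#' checked: every cycle in the schema has a building-block set, tag lengths
#' match the schema's bb_tag section lengths, and in `hamming` mode the
#' tags must actually be codewords of the matching quaternary code.
#'
#' @param library_id,library_tag,schema,bb_sets,reaction_scheme,error_correction_mode
#'   Fields of the specification; see [load_library()].
#' @param file Label used in error messages.
#' @return A `library_spec` object.
#' @export
new_library_spec <- function(library_id, library_tag, schema, bb_sets,
                             reaction_scheme = character(0),
                             error_correction_mode = "none",
                             file = "<in-memory>") {
  cycles <- schema$cycle[schema$kind == "bb_tag"]
  for (cy in cycles) {
    if (!cy %in% names(bb_sets)) {
      .config_stop(file, "building_blocks", sprintf("no building-block set for cycle \"%s\"", cy))
    }
    want <- schema$length[schema$kind == "bb_tag" & schema$cycle == cy]
    got <- bb_sets[[cy]]$tag_length
    if (got != want) {
      .config_stop(file, sprintf("cycle \"%s\"", cy),
                   sprintf("building-block tag length %d does not match schema bb_tag length %d",
                           got, want))
    }
  }
  extra <- setdiff(names(bb_sets), cycles)
  if (length(extra)) {
    .config_stop(file, "building_blocks",
                 sprintf("building-block set \"%s\" has no bb_tag section in the schema", extra[1]))
  }

  spec <- structure(
    list(library_id = library_id, library_tag = library_tag, schema = schema,
         bb_sets = bb_sets[cycles], reaction_scheme = reaction_scheme,
         error_correction_mode = error_correction_mode),
    class = "library_spec"
  )
  spec$decoders <- .build_tag_decoders(spec, file)
  spec
}

# one decoder per cycle, according to the error-correction mode
.build_tag_decoders <- function(spec, file = "<in-memory>") {
  lapply(spec$bb_sets, function(set) {
    tags <- set$blocks$dna_tag
    if (spec$error_correction_mode == "hamming") {
      code <- build_code(set$tag_length)
      chk <- decode_tags(code, tags)
      if (!all(chk$status == "valid")) {
        bad <- which(chk$status != "valid")[1]
        .config_stop(file, sprintf("cycle \"%s\" row %d", set$cycle_label, bad),
                     sprintf("tag \"%s\" is not a codeword of the length-%d quaternary Hamming code",
                             tags[bad], set$tag_length))
      }
      list(mode = "hamming", code = code, tags = tags)
    } else if (spec$error_correction_mode == "lookup") {
      list(mode = "lookup", decoder = build_lookup_decoder(tags), tags = tags)
    } else {
      list(mode = "none", tags = tags)
    }
  })
}

#' @export
print.library_spec <- function(x, ...) {
  sizes <- vapply(x$bb_sets, function(s) nrow(s$blocks), integer(1))
  cat(sprintf("<library_spec> %s: %d cycles (%s), %s compounds, %s correction\n",
              x$library_id, length(x$bb_sets),
              paste(sprintf("%s=%d", names(sizes), sizes), collapse = ", "),
              format(prod(sizes), big.mark = ","), x$error_correction_mode))
  invisible(x)
}

#' Write a library specification back to JSON (plus block CSVs)
#'
#' Serialises a `library_spec` so that [load_library()] on the result
#' round-trips to an equivalent specification.  Building-block sets are
#' written as `bb_<cycle>.csv` next to the JSON file.
#'
#' @param spec A `library_spec`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_library <- function(spec, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  bb_entries <- list()
  for (cy in names(spec$bb_sets)) {
    f <- sprintf("bb_%s.csv", cy)
    blocks <- spec$bb_sets[[cy]]$blocks
    out <- data.frame(id = blocks$bb_id, tag = blocks$dna_tag)
    if (!all(is.na(blocks$smiles))) out$smiles <- blocks$smiles
    readr::write_csv(out, file.path(dirname(path), f))
    bb_entries[[length(bb_entries) + 1]] <- list(cycle = cy, file = f)
  }
  secs <- lapply(seq_len(nrow(spec$schema)), function(i) {
    s <- spec$schema[i, ]
    out <- list(name = s$name, kind = s$kind, length = s$length)
    if (!is.na(s$sequence)) out$sequence <- s$sequence
    if (!is.na(s$cycle)) out$cycle <- s$cycle
    out
  })
  x <- list(library_id = spec$library_id, library_tag = spec$library_tag,
            error_correction_mode = spec$error_correction_mode,
            barcode_schema = secs, building_blocks = bb_entries)
  if (length(spec$reaction_scheme)) x$reaction_scheme <- as.list(spec$reaction_scheme)
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

# ---- selection YAML -------------------------------------------------------

.SELECTION_KEYS <- c("selection_id", "libraries", "conditions", "decode_settings")
.CONDITION_KEYS <- c("name", "replicate", "read_files")
.DECODE_KEYS <- c("library_error_rate", "schema_error_rate", "umi_mode")

#' Load a selection-experiment definition
#'
#' A selection experiment names the libraries screened, the FASTQ read
#' files per condition/replicate, and the decoding settings, in a short
#' YAML file.  Library references are resolved against `library_registry`
#' (a named list of `library_spec`s or a character vector of library JSON
#' paths); unknown ids get a nearest-match suggestion.  Libraries whose
#' demultiplexing tags are within the configured error tolerance of each
#' other cannot be told apart and raise an ambiguity error.
#'
#' @param path Path to the YAML file.
#' @param library_registry Named list of `library_spec` objects, or paths
#'   to library JSON files.
#' @return A `selection_spec` object.
#' @export
load_selection <- function(path, library_registry) {
  if (!file.exists(path)) {
    rlang::abort(paste0("selection file not found: ", path), class = "delcube_config_error")
  }
  x <- yaml::read_yaml(path)
  .check_keys(x, .SELECTION_KEYS, c("selection_id", "libraries", "conditions"), path, "top level")

  if (is.character(library_registry)) {
    library_registry <- lapply(library_registry, load_library)
    names(library_registry) <- vapply(library_registry, `[[`, character(1), "library_id")
  }
  libs <- list()
  for (id in unlist(x$libraries)) {
    if (!id %in% names(library_registry)) {
      .config_stop(path, "libraries", sprintf("unknown library id \"%s\"", id),
                   suggest_key(id, names(library_registry)))
    }
    libs[[id]] <- library_registry[[id]]
  }
  if (length(libs) == 0) .config_stop(path, "libraries", "at least one library is required")

  ds <- x$decode_settings %||% list()
  .check_keys(ds, .DECODE_KEYS, character(0), path, "decode_settings")
  settings <- list(
    library_error_rate = ds$library_error_rate %||% 0.1,
    schema_error_rate = ds$schema_error_rate %||% 0.1,
    umi_mode = ds$umi_mode %||% "exact"
  )
  for (k in c("library_error_rate", "schema_error_rate")) {
    v <- settings[[k]]
    if (!is.numeric(v) || v < 0 || v >= 0.5) {
      .config_stop(path, paste0("decode_settings.", k),
                   sprintf("error rate must be in [0, 0.5), got %s", v))
    }
  }
  if (!settings$umi_mode %in% c("exact", "cluster1")) {
    .config_stop(path, "decode_settings.umi_mode",
                 sprintf("unknown umi_mode \"%s\"", settings$umi_mode),
                 suggest_key(settings$umi_mode, c("exact", "cluster1")))
  }

  conds <- list()
  for (i in seq_along(x$conditions)) {
    co <- x$conditions[[i]]
    .check_keys(co, .CONDITION_KEYS, c("name", "read_files"), path,
                sprintf("conditions entry %d", i))
    files <- unlist(co$read_files)
    resolved <- vapply(files, function(f) {
      if (file.exists(f)) f else file.path(dirname(path), f)
    }, character(1))
    conds[[i]] <- tibble::tibble(condition = co$name,
                                 replicate = as.character(co$replicate %||% "1"),
                                 read_file = unname(resolved))
  }
  conditions <- dplyr::bind_rows(conds)
  if (nrow(conditions) == 0) .config_stop(path, "conditions", "at least one read file is required")

  new_selection_spec(x$selection_id, libs, conditions, settings, file = path)
}

#' Construct a selection specification from its parts
#'
#' @param selection_id Identifier embedded in UMI-state files so shards
#'   from different selections cannot be merged by accident.
#' @param libraries Named list of `library_spec`s.
#' @param conditions Tibble with columns `condition`, `replicate`,
#'   `read_file`.
#' @param decode_settings List with `library_error_rate`,
#'   `schema_error_rate`, `umi_mode`.
#' @param file Label used in error messages.
#' @return A `selection_spec` object.
#' @export
new_selection_spec <- function(selection_id, libraries, conditions,
                               decode_settings = list(library_error_rate = 0.1,
                                                      schema_error_rate = 0.1,
                                                      umi_mode = "exact"),
                               file = "<in-memory>") {
  # ambiguity: two library tags within the error tolerance of each other
  ids <- names(libraries)
  if (length(ids) >= 2) {
    for (a in seq_len(length(ids) - 1)) {
      for (b in (a + 1):length(ids)) {
        ta <- libraries[[a]]$library_tag; tb <- libraries[[b]]$library_tag
        tol <- floor(decode_settings$library_error_rate * max(nchar(ta), nchar(tb)))
        if (utils::adist(ta, tb) <= tol) {
          .config_stop(file, "libraries",
                       sprintf("library tags of \"%s\" and \"%s\" are within the error tolerance (%d edits) of each other; reads cannot be demultiplexed unambiguously",
                               ids[a], ids[b], tol))
        }
      }
    }
  }
  structure(list(selection_id = selection_id, libraries = libraries,
                 conditions = tibble::as_tibble(conditions),
                 decode_settings = decode_settings),
            class = "selection_spec")
}

#' @export
print.selection_spec <- function(x, ...) {
  cat(sprintf("<selection_spec> %s: %d libraries, %d read files over %d conditions\n",
              x$selection_id, length(x$libraries), nrow(x$conditions),
              dplyr::n_distinct(x$conditions$condition)))
  invisible(x)
}
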