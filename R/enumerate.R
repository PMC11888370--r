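# Chemistry (reaction application, canonical SMILES, descriptors) is
# delegated to RDKit through a batch subprocess; the `python` interpreter
# is located once per session (option delcube.python overrides).

.chem_python <- function() {
  opt <- getOption("delcube.python")
  if (!is.null(opt)) return(opt)
  py <- Sys.which("python")
  if (py == "") py <- Sys.which("python3")
  if (py == "") stop("no `python` interpreter on PATH; the enumeration module needs one with RDKit")
  unname(py)
}

.chem_call <- function(req) {
  script <- system.file("python", "chem_backend.py", package = "delcube")
  if (script == "") {  # running from a source checkout
    script <- file.path("inst", "python", "chem_backend.py")
  }
  fin <- tempfile(fileext = ".json"); fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)))
  jsonlite::write_json(req, fin, auto_unbox = TRUE, digits = NA, null = "null")
  status <- system2(.chem_python(), c(script, fin, fout), stdout = TRUE, stderr = TRUE)
  if (!file.exists(fout)) {
    stop("chemistry backend failed: ", paste(status, collapse = "\n"))
  }
  res <- jsonlite::fromJSON(fout, simplifyVector = FALSE)
  if (!is.null(res$fatal)) stop(res$fatal)
  res
}

#' Canonicalize SMILES strings
#'
#' @param smiles Character vector.
#' @return Character vector of canonical SMILES (`NA` where unparsable).
#' @export
canonical_smiles <- function(smiles) {
  if (length(smiles) == 0) return(character(0))
  res <- .chem_call(list(op = "canonicalize", smiles = as.list(smiles)))
  vapply(res, function(r) r$smiles %||% NA_character_, character(1))
}

# apply one two-reactant transform to vectors of (lhs, rhs) SMILES
.react_batch <- function(lhs, rhs, smirks) {
  if (length(lhs) == 0) {
    return(tibble::tibble(smiles = character(), n_products = integer(), error = character()))
  }
  tasks <- lapply(seq_along(lhs), function(i) list(lhs = lhs[i], rhs = rhs[i], smirks = smirks))
  res <- .chem_call(list(op = "react", tasks = tasks))
  tibble::tibble(
    smiles = vapply(res, function(r) r$smiles %||% NA_character_, character(1)),
    n_products = vapply(res, function(r) as.integer(r$n_products %||% 0L), integer(1)),
    error = vapply(res, function(r) r$error %||% NA_character_, character(1)))
}

# ---- compound ids ---------------------------------------------------------

#' Parse a compound identifier
#'
#' Compound ids have the form `LIB-A001-B002-C003`: the library id
#' followed by one building-block id per cycle, in cycle order.
#'
#' @param spec A `library_spec`.
#' @param compound_id The identifier string.
#' @return Named character vector of building-block ids, one per cycle.
#' @export
parse_compound_id <- function(spec, compound_id) {
  cycles <- names(spec$bb_sets)
  prefix <- paste0(spec$library_id, "-")
  if (!startsWith(compound_id, prefix)) {
    stop("compound id \"", compound_id, "\" does not belong to library ", spec$library_id)
  }
  parts <- strsplit(sub(prefix, "", compound_id, fixed = TRUE), "-", fixed = TRUE)[[1]]
  if (length(parts) != length(cycles)) {
    stop("compound id \"", compound_id, "\" has ", length(parts),
         " building blocks; library ", spec$library_id, " has ", length(cycles), " cycles")
  }
  names(parts) <- cycles
  for (cy in cycles) {
    if (!parts[[cy]] %in% spec$bb_sets[[cy]]$blocks$bb_id) {
      stop("unknown building block \"", parts[[cy]], "\" in cycle ", cy,
           " of library ", spec$library_id)
    }
  }
  parts
}

.bb_smiles <- function(spec, cycle, bb_ids) {
  blocks <- spec$bb_sets[[cycle]]$blocks
  smi <- blocks$smiles[match(bb_ids, blocks$bb_id)]
  missing <- bb_ids[is.na(smi) | smi == ""]
  if (length(missing)) {
    stop("building block(s) without SMILES in cycle ", cycle, ": ",
         paste(unique(missing), collapse = ", "))
  }
  smi
}

.check_scheme <- function(spec) {
  n_steps <- length(spec$bb_sets) - 1L
  if (length(spec$reaction_scheme) != n_steps) {
    stop("library ", spec$library_id, " needs a linear reaction scheme with ",
         n_steps, " transform(s) (one per joining step), got ",
         length(spec$reaction_scheme))
  }
}

# core: enumerate the products for a table of per-cycle bb ids
.enumerate_rows <- function(spec, bb_tab) {
  .check_scheme(spec)
  cycles <- names(spec$bb_sets)
  running <- .bb_smiles(spec, cycles[1], bb_tab[[1]])
  failure <- rep(NA_character_, nrow(bb_tab))
  multi <- rep(FALSE, nrow(bb_tab))
  for (step in seq_along(spec$reaction_scheme)) {
    rhs <- .bb_smiles(spec, cycles[step + 1], bb_tab[[step + 1]])
    todo <- which(is.na(failure))
    if (length(todo)) {
      # deduplicate identical (intermediate, block) reactions
      key <- paste(running[todo], rhs[todo], sep = "\r")
      uniq <- !duplicated(key)
      res <- .react_batch(running[todo][uniq], rhs[todo][uniq], spec$reaction_scheme[step])
      res <- res[match(key, key[uniq]), ]
      running[todo] <- res$smiles
      failure[todo][!is.na(res$error)] <- res$error[!is.na(res$error)]
      multi[todo] <- multi[todo] | res$n_products > 1
    }
  }
  if (length(spec$reaction_scheme) == 0) {
    # single-cycle library: canonicalize the block itself
    running <- canonical_smiles(running)
  }
  if (any(multi, na.rm = TRUE)) {
    warning(sum(multi, na.rm = TRUE), " compound(s) gave multiple reaction products; ",
            "kept the first in canonical order")
  }
  running[!is.na(failure)] <- NA_character_
  tibble::tibble(smiles = running, failure_reason = failure)
}

# ---- public enumeration API ----------------------------------------------

#' Enumerate one compound on demand
#'
#' Applies the library's reaction scheme step by step: the first transform
#' joins the cycle-A and cycle-B blocks, each further transform joins the
#' running intermediate with the next cycle's block.  A block that does
#' not match its transform yields a failure marker in `failure_reason`,
#' not an error; the special transform string `"identity"` keeps the
#' intermediate unchanged.
#'
#' @param spec A `library_spec` whose blocks carry SMILES.
#' @param compound_id A compound identifier (see [parse_compound_id()]).
#' @return A one-row tibble: `compound_id`, one `bb_*` column per cycle,
#'   `smiles` (canonical, `NA` on failure), `failure_reason`.
#' @examples
#' \dontrun{
#' enumerate_compound(lib, "TOY-A001-B002")
#' }
#' @export
enumerate_compound <- function(spec, compound_id) {
  bb <- parse_compound_id(spec, compound_id)
  bb_tab <- tibble::as_tibble(as.list(bb))
  res <- .enumerate_rows(spec, bb_tab)
  out <- tibble::tibble(compound_id = compound_id)
  for (cy in names(spec$bb_sets)) out[[paste0("bb_", cy)]] <- bb[[cy]]
  out$smiles <- res$smiles
  out$failure_reason <- res$failure_reason
  out
}

#' Enumerate a whole library
#'
#' Yields the full Cartesian product of the cycles' building blocks, in
#' deterministic lexicographic cycle-index order (last cycle fastest); the
#' row count always equals the product of the cycle sizes, with per-row
#' failures recorded in `failure_reason` rather than dropped.
#'
#' @param spec A `library_spec` whose blocks carry SMILES.
#' @param descriptors Optional character vector of descriptor names to
#'   compute for each successful structure (see [compute_properties()]).
#' @return A tibble: `compound_id`, `bb_*` per cycle, `smiles`,
#'   `failure_reason`, plus any requested descriptor columns.
#' @export
enumerate_library <- function(spec, descriptors = NULL) {
  cycles <- names(spec$bb_sets)
  ids <- lapply(spec$bb_sets, function(s) s$blocks$bb_id)
  grid <- expand.grid(rev(ids), stringsAsFactors = FALSE)[, rev(seq_along(ids)), drop = FALSE]
  names(grid) <- cycles
  grid <- tibble::as_tibble(grid)
  res <- .enumerate_rows(spec, grid)
  out <- tibble::tibble(compound_id = do.call(paste, c(list(spec$library_id), grid, list(sep = "-"))))
  for (cy in cycles) out[[paste0("bb_", cy)]] <- grid[[cy]]
  out$smiles <- res$smiles
  out$failure_reason <- res$failure_reason
  if (!is.null(descriptors) && length(descriptors)) {
    out <- compute_properties(out, descriptors)
  }
  out
}

#' Compute physicochemical descriptors for enumerated compounds
#'
#' @param compounds A tibble with a `smiles` column (e.g. from
#'   [enumerate_library()]).
#' @param descriptors Character vector of descriptor names: `mw`,
#'   `heavy_atoms`, `ring_count`, `logp`, `tpsa`, `hbd`, `hba`.  Unknown
#'   names are an error.  An empty vector returns the input unchanged.
#' @return The input with one numeric column per descriptor appended.
#' @export
compute_properties <- function(compounds, descriptors) {
  stopifnot("smiles" %in% names(compounds))
  if (length(descriptors) == 0) return(compounds)
  ok <- which(!is.na(compounds$smiles))
  for (d in descriptors) compounds[[d]] <- NA_real_
  if (length(ok)) {
    res <- .chem_call(list(op = "descriptors",
                           smiles = as.list(compounds$smiles[ok]),
                           descriptors = as.list(descriptors)))
    for (d in descriptors) {
      compounds[[d]][ok] <- vapply(res, function(r) {
        v <- r[[d]]
        if (is.null(v)) NA_real_ else as.numeric(v)
      }, numeric(1))
    }
  }
  compounds
}
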