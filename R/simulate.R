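#' Build a synthetic DEL for testing and simulation
#'
#' Constructs a fully specified split-and-pool library in memory: constant
#' primer regions, a demultiplexing tag, one error-correcting (or random)
#' building-block tag section per cycle, and a UMI section.  Cycle tags are
#' drawn from a quaternary Hamming code via [generate_barcode_set()], so
#' the library exercises the same error-correction machinery as a real
#' Hamming-encoded DEL.  Everything is deterministic given `seed`.
#'
#' @param library_id Identifier for the library.
#' @param blocks_per_cycle Integer vector, number of building blocks in
#'   each cycle (its length sets the number of cycles; cycles are labelled
#'   A, B, C, ...).
#' @param tag_length Building-block tag length in bp (7-16).
#' @param umi_length UMI length in bp (0 disables the UMI section).
#' @param library_tag_length Length of the demultiplexing tag.
#' @param error_correction_mode `"hamming"`, `"lookup"` or `"none"`.
#' @param parity Use parity (distance-4) codes for the cycle tags.
#' @param smiles Optional list (one character vector per cycle) of
#'   building-block SMILES.
#' @param seed Integer seed.
#' @return A `library_spec`.
#' @examples
#' lib <- synthetic_library(blocks_per_cycle = c(4, 4), seed = 1)
#' lib
#' @export
synthetic_library <- function(library_id = "SYN001",
                              blocks_per_cycle = c(24, 24, 24),
                              tag_length = 8,
                              umi_length = 10,
                              library_tag_length = 10,
                              error_correction_mode = "hamming",
                              parity = FALSE,
                              smiles = NULL,
                              seed = 1L) {
  n_cycles <- length(blocks_per_cycle)
  cycles <- LETTERS[seq_len(n_cycles)]
  with_seed(seed, {
    library_tag <- random_dna(1, library_tag_length)
    p5 <- random_dna(1, 12)
    p3 <- random_dna(1, 12)
    bb_sets <- list()
    for (i in seq_len(n_cycles)) {
      tags <- if (error_correction_mode == "hamming") {
        generate_barcode_set(tag_length, blocks_per_cycle[i], parity = parity,
                             seed = sample.int(1e6, 1))$barcode
      } else {
        # rejection-sample distinct random tags
        out <- character(0)
        while (length(out) < blocks_per_cycle[i]) {
          out <- unique(c(out, random_dna(blocks_per_cycle[i], tag_length)))
        }
        out[seq_len(blocks_per_cycle[i])]
      }
      blocks <- tibble::tibble(
        bb_id = sprintf("%s%03d", cycles[i], seq_len(blocks_per_cycle[i])),
        dna_tag = tags,
        smiles = if (is.null(smiles)) NA_character_ else smiles[[i]]
      )
      bb_sets[[cycles[i]]] <- structure(
        list(cycle_label = cycles[i], tag_length = tag_length, blocks = blocks),
        class = "building_block_set")
    }
    secs <- list(tibble::tibble(name = "primer5", kind = "constant", length = 12L,
                                sequence = p5, cycle = NA_character_),
                 tibble::tibble(name = "library", kind = "constant",
                                length = nchar(library_tag),
                                sequence = library_tag, cycle = NA_character_))
    for (cy in cycles) {
      secs[[length(secs) + 1]] <- tibble::tibble(name = paste0("bb_", cy), kind = "bb_tag",
                                                 length = as.integer(tag_length),
                                                 sequence = NA_character_, cycle = cy)
    }
    if (umi_length > 0) {
      secs[[length(secs) + 1]] <- tibble::tibble(name = "umi", kind = "umi",
                                                 length = as.integer(umi_length),
                                                 sequence = NA_character_, cycle = NA_character_)
    }
    secs[[length(secs) + 1]] <- tibble::tibble(name = "primer3", kind = "constant", length = 12L,
                                               sequence = p3, cycle = NA_character_)
    schema <- new_barcode_schema(dplyr::bind_rows(secs))
    new_library_spec(library_id, library_tag, schema, bb_sets,
                     error_correction_mode = error_correction_mode)
  })
}

#' All compound identifiers of a library
#'
#' Compound ids render the per-cycle building-block choice as
#' `LIB-A001-B002-...`, one id per element of the Cartesian product of the
#' cycles' block sets, in lexicographic cycle-index order (last cycle
#' fastest).
#'
#' @param spec A `library_spec`.
#' @return Character vector of length `prod(cycle sizes)`.
#' @export
compound_ids <- function(spec) {
  ids <- lapply(spec$bb_sets, function(s) s$blocks$bb_id)
  grid <- expand.grid(rev(ids), stringsAsFactors = FALSE)[, rev(seq_along(ids)), drop = FALSE]
  do.call(paste, c(list(spec$library_id), grid, list(sep = "-")))
}

#' Sampling weights with a planted enriched set
#'
#' Uniform background weights over all compounds of a library, with a
#' random `hit_fraction` of compounds up-weighted `fold`-fold (then
#' renormalised) -- the ground truth for testing enrichment recovery.
#' The expected share of reads drawn from the hit set is
#' `fold*h / (fold*h + 1 - h)` for hit fraction `h`.
#'
#' @param spec A `library_spec`.
#' @param hit_fraction Fraction of compounds in the enriched set (0-1).
#' @param fold Sampling weight multiplier for hits (>= 1).
#' @param seed Integer seed choosing the hit set.
#' @return A tibble with `compound_id`, `weight`, `is_hit`.
#' @export
planted_enrichment_weights <- function(spec, hit_fraction, fold, seed = 1L) {
  stopifnot(hit_fraction > 0, hit_fraction < 1, fold >= 1)
  ids <- compound_ids(spec)
  n <- length(ids)
  with_seed(seed, {
    hits <- sample.int(n, max(1L, round(hit_fraction * n)))
    w <- rep(1, n)
    w[hits] <- fold
    tibble::tibble(compound_id = ids, weight = w / sum(w),
                   is_hit = seq_len(n) %in% hits)
  })
}

# render the exact barcode of one compound (no errors), with a given UMI
.render_barcode <- function(spec, bb_tags, umi) {
  sc <- schema_coords(spec$schema)
  parts <- character(nrow(sc))
  bb_i <- 1L
  for (i in seq_len(nrow(sc))) {
    parts[i] <- switch(sc$kind[i],
      constant = spec$schema$sequence[i],
      bb_tag = { t <- bb_tags[[sc$cycle[i]]]; t },
      umi = umi,
      index = strrep("A", spec$schema$length[i])
    )
  }
  paste(parts, collapse = "")
}

# vectorised error injection: i.i.d. substitutions and single-base indels
.inject_errors <- function(seqs, sub_rate, indel_rate) {
  n_sub <- integer(length(seqs)); n_indel <- integer(length(seqs))
  if (sub_rate > 0 || indel_rate > 0) {
    for (i in seq_along(seqs)) {
      v <- strsplit(seqs[i], "")[[1]]
      if (sub_rate > 0) {
        hit <- which(stats::runif(length(v)) < sub_rate)
        for (p in hit) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
        n_sub[i] <- length(hit)
      }
      if (indel_rate > 0) {
        hit <- which(stats::runif(length(v)) < indel_rate)
        # process right-to-left so positions stay valid
        for (p in rev(hit)) {
          if (stats::runif(1) < 0.5 && length(v) > 1) {
            v <- v[-p]
          } else {
            v <- append(v, sample(c("A", "C", "G", "T"), 1), after = p)
          }
        }
        n_indel[i] <- length(hit)
      }
      if (n_sub[i] || n_indel[i]) seqs[i] <- paste(v, collapse = "")
    }
  }
  list(seqs = seqs, n_sub = n_sub, n_indel = n_indel)
}

#' Simulate a DEL selection sequencing run with full ground truth
#'
#' Draws `n_reads` compounds from `weights` (multinomial), renders each
#' compound's barcode with a uniformly random UMI, adds 0-10 random flank
#' bases on each side, injects i.i.d. per-base substitutions and
#' single-base indels, reverse-complements roughly half of the reads, and
#' writes a FASTQ file.  The returned truth table records, per read, the
#' compound, the UMI and the injected error counts -- the ground truth every
#' decoder test is scored against.  Fully reproducible from `seed`.
#'
#' The error model is deliberately simple (uniform substitutions, single
#' base indels); it is not a sequencer-realistic profile.
#'
#' @param spec A `library_spec`.
#' @param weights Tibble with `compound_id` and `weight` (a probability
#'   distribution over the library's compounds), e.g. from
#'   [planted_enrichment_weights()]; `NULL` for uniform.
#' @param n_reads Number of reads to simulate.
#' @param sub_rate Per-base substitution probability (0-0.2).
#' @param indel_rate Per-base indel probability (0-0.2).
#' @param fastq Output FASTQ path (`.gz` supported); `NULL` to skip writing.
#' @param seed Integer seed.
#' @return A list with `fastq` (the path), `truth` (per-read tibble:
#'   `read_id`, `library_id`, `compound_id`, `umi`, `n_sub`, `n_indel`,
#'   `revcomp`) and `weights` (the sampling distribution used).
#' @export
simulate_selection <- function(spec, weights = NULL, n_reads = 1000,
                               sub_rate = 0.005, indel_rate = 0.001,
                               fastq = tempfile(fileext = ".fastq.gz"),
                               seed = 1L) {
  stopifnot(inherits(spec, "library_spec"),
            sub_rate >= 0, sub_rate <= 0.2, indel_rate >= 0, indel_rate <= 0.2)
  all_ids <- compound_ids(spec)
  if (is.null(weights)) {
    weights <- tibble::tibble(compound_id = all_ids, weight = 1 / length(all_ids))
  }
  if (!setequal(weights$compound_id, all_ids)) {
    stop("weights must cover exactly the compounds of ", spec$library_id)
  }
  if (abs(sum(weights$weight) - 1) > 1e-8) stop("weights must sum to 1")

  umi_len <- sum(spec$schema$length[spec$schema$kind == "umi"])
  tag_tab <- lapply(spec$bb_sets, function(s) stats::setNames(s$blocks$dna_tag, s$blocks$bb_id))
  cycles <- names(spec$bb_sets)

  with_seed(seed, {
    draw <- sample(weights$compound_id, n_reads, replace = TRUE, prob = weights$weight)
    umis <- if (umi_len > 0) random_dna(n_reads, umi_len) else rep("", n_reads)

    # compound id -> per-cycle tags; parse ids back into bb ids
    parts <- strsplit(draw, "-", fixed = TRUE)
    barcodes <- vapply(seq_len(n_reads), function(i) {
      bb <- parts[[i]][-1]
      names(bb) <- cycles
      tags <- lapply(cycles, function(cy) unname(tag_tab[[cy]][bb[[cy]]]))
      names(tags) <- cycles
      .render_barcode(spec, tags, umis[i])
    }, character(1))

    flank_l <- random_dna(n_reads, sample(0:10, n_reads, replace = TRUE))
    flank_r <- random_dna(n_reads, sample(0:10, n_reads, replace = TRUE))
    reads <- paste0(flank_l, barcodes, flank_r)
    err <- .inject_errors(reads, sub_rate, indel_rate)
    reads <- err$seqs
    rc <- stats::runif(n_reads) < 0.5
    reads[rc] <- revcomp(reads[rc])

    read_id <- sprintf("sim_%06d", seq_len(n_reads))
    truth <- tibble::tibble(read_id = read_id, library_id = spec$library_id,
                            compound_id = draw, umi = umis,
                            n_sub = err$n_sub, n_indel = err$n_indel, revcomp = rc)
    if (!is.null(fastq)) {
      x <- Biostrings::DNAStringSet(reads)
      names(x) <- read_id
      qual <- Biostrings::BStringSet(vapply(nchar(reads), strrep, character(1), x = "I"))
      Biostrings::writeXStringSet(x, fastq, format = "fastq", compress = grepl("\\.gz$", fastq),
                                  qualities = qual)
    }
    list(fastq = fastq, truth = truth, weights = weights)
  })
}
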