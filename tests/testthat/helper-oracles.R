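# Independent oracles and small fixture builders used across the suite.
# The alignment oracle is a deliberately plain Gotoh DP kept separate from
# the package's aligner: it computes only the optimal score.

# Semi-global (pattern-global, read-local) affine-gap score.
# match/mismatch on bases, 'N' in the pattern scores 0 against anything.
oracle_semi_global_score <- function(read, pattern,
                                     match = 1, mismatch = -1,
                                     gap_open = -2, gap_ext = -1) {
  p <- strsplit(pattern, "")[[1]]
  r <- strsplit(read, "")[[1]]
  m <- length(p); n <- length(r)
  NEG <- -1e18
  # matrices indexed [i+1, j+1] for pattern prefix i, read prefix j
  M <- matrix(NEG, m + 1, n + 1)  # p[i] aligned to r[j]
  X <- matrix(NEG, m + 1, n + 1)  # r[j] inserted (gap in pattern)
  Y <- matrix(NEG, m + 1, n + 1)  # p[i] deleted (gap in read)
  for (i in 1:m) {
    for (j in 0:n) {
      if (j > 0) {
        s <- if (p[i] == "N") 0 else if (p[i] == r[j]) match else mismatch
        prev <- if (i == 1) 0 else max(M[i, j], X[i, j], Y[i, j])
        M[i + 1, j + 1] <- s + prev
        X[i + 1, j + 1] <- max(M[i + 1, j] + gap_open,
                               X[i + 1, j] + gap_ext,
                               Y[i + 1, j] + gap_open)
      }
      Y[i + 1, j + 1] <- if (i == 1) gap_open else
        max(M[i, j + 1] + gap_open, X[i, j + 1] + gap_open, Y[i, j + 1] + gap_ext)
    }
  }
  max(M[m + 1, ], Y[m + 1, ])
}

# Levenshtein distance by textbook DP (oracle for suggest_key)
oracle_edit_distance <- function(a, b) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  d <- matrix(0L, length(a) + 1, length(b) + 1)
  d[, 1] <- 0:length(a); d[1, ] <- 0:length(b)
  for (i in seq_along(a)) {
    for (j in seq_along(b)) {
      d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L,
                             d[i, j] + (a[i] != b[j]))
    }
  }
  d[length(a) + 1, length(b) + 1]
}

# substitute `k` random positions of a DNA string with different bases
corrupt_tag <- function(tag, k) {
  v <- strsplit(tag, "")[[1]]
  pos <- sample(length(v), k)
  for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
  paste(v, collapse = "")
}

random_read <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# tiny in-memory selection over one synthetic library
toy_selection <- function(lib, fastq, condition = "target") {
  new_selection_spec(
    paste0("sel_", lib$library_id),
    stats::setNames(list(lib), lib$library_id),
    tibble::tibble(condition = condition, replicate = "1", read_file = fastq))
}

# path to the installed 2-cycle amide toy library
toylib_path <- function() {
  system.file("extdata", "toylib", "toylib.json", package = "delcube")
}

# a 3-cycle library with SMILES for enumeration tests: acids x diamines x
# acids, joined by two amide couplings
smiles_library <- function(per_cycle = 3, seed = 5) {
  acids <- paste0("C", vapply(seq_len(per_cycle), function(k) strrep("C", k), ""), "(=O)O")
  diamines <- paste0("NCC", vapply(seq_len(per_cycle), function(k) strrep("C", k), ""), "N")
  acids2 <- paste0("OC(=O)", vapply(seq_len(per_cycle), function(k) strrep("C", k), ""), "C")
  lib <- synthetic_library("CHEM", blocks_per_cycle = rep(per_cycle, 3),
                           tag_length = 8, umi_length = 6,
                           error_correction_mode = "none", seed = seed,
                           smiles = list(acids, diamines, acids2))
  lib$reaction_scheme <- c(
    "[C:1](=[O:2])[OH].[NX3;H2:3]>>[C:1](=[O:2])[N:3]",
    "[NX3;H2:1].[C:2](=[O:3])[OH]>>[C:2](=[O:3])[N:1]")
  lib
}
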