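`%||%` <- function(x, y) if (is.null(x)) y else x

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# reverse complement for plain character vectors
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Hamming distance between two equal-length strings, vectorised over pairs
hamming <- function(a, b) {
  stopifnot(all(nchar(a) == nchar(b)))
  mapply(function(x, y) {
    sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
  }, a, b, USE.NAMES = FALSE)
}

# minimum pairwise Hamming distance of a set of equal-length strings
min_pairwise_distance <- function(tags) {
  M <- seqs_to_gf4(tags, nchar(tags[1]))
  N <- ncol(M)
  best <- nchar(tags[1])
  for (i in seq_len(N - 1)) {
    d <- colSums(M[, (i + 1):N, drop = FALSE] != M[, i])
    best <- min(best, d)
  }
  best
}

random_dna <- function(n_strings, len) {
  if (length(len) == 1) len <- rep(len, n_strings)
  vapply(seq_len(n_strings), function(i) {
    paste(sample(c("A", "C", "G", "T"), len[i], replace = TRUE), collapse = "")
  }, character(1))
}
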