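#' Quaternary Hamming codes for DNA barcodes
#'
#' DNA barcodes map naturally onto the four-element field GF(4), so a
#' Hamming code over GF(4) gives barcode sets in which every pair of
#' barcodes differs at three or more positions: any single substitution
#' can be corrected from the syndrome alone.  `build_code()` constructs a
#' shortened GF(4) Hamming code of length `n` (7 to 16 bp) with minimum
#' Hamming distance 3, or, in parity mode, an extended code of minimum
#' distance 4 that additionally detects (but cannot correct) double
#' substitutions.
#'
#' The parity-check matrix of the distance-3 code uses the lexicographically
#' ordered projective representatives of GF(4)^3 (each nonzero vector scaled
#' so its first nonzero entry is 1), shortened to the first `n` columns.  In
#' parity mode the 4-row parity-check matrix takes its columns from the
#' elliptic quadric of PG(3,4) -- an ovoid of 17 points with no three
#' collinear -- in lexicographic order, so no three columns are linearly
#' dependent: the certificate that the minimum distance is at least 4, valid
#' for every length up to 16.  Both certificates (no column a scalar
#' multiple of another; no three columns dependent) are re-verified at
#' build time.
#'
#' Symbols map to bases as A=0, C=1, G=2, T=3.
#'
#' @param n Barcode length in base pairs; 7 to 16.
#' @param parity Logical; extend to minimum distance 4 (costs one more
#'   check symbol, so the message dimension drops from `n - 3` to `n - 4`).
#' @return An object of class `quaternary_code` with elements `n`, `k`
#'   (message dimension), `parity`, `d` (guaranteed minimum distance), and
#'   the parity-check matrix `H` (integer matrix over GF(4)).
#' @examples
#' code <- build_code(7)
#' code$k          # 4 message symbols -> 256 codewords
#' encode(code, c(0, 0, 0, 0))
#' @export
build_code <- function(n, parity = FALSE) {
  if (!is.numeric(n) || length(n) != 1 || n != round(n) || n < 7 || n > 16) {
    stop("barcode length `n` must be an integer between 7 and 16, got ", n)
  }
  n <- as.integer(n)
  if (parity) {
    H <- .parity_check_extended(n)
    d <- 4L
  } else {
    pts <- .gf4_projective_points(3L)
    H <- pts[, seq_len(n), drop = FALSE]
    d <- 3L
  }
  r <- nrow(H)
  if (gf4_rank(H) != r) stop("internal error: parity-check matrix is rank-deficient")
  .check_distance_certificate(H, d)

  k <- n - r
  # systematic structure: pivot (check) positions P and free (message)
  # positions F with c[P] = M %*% c[F]  (char 2, so signs vanish)
  piv <- .gf4_pivot_columns(H)
  free <- setdiff(seq_len(n), piv)
  M <- gf4_matmul(gf4_solve(H[, piv, drop = FALSE]), H[, free, drop = FALSE])

  syn <- .syndrome_table(H)
  structure(
    list(n = n, k = k, parity = parity, d = d, H = H,
         pivot = piv, free = free, M = M,
         syndrome_pos = syn$pos, syndrome_mag = syn$mag,
         symbol_map = c(A = 0L, C = 1L, G = 2L, T = 3L)),
    class = "quaternary_code"
  )
}

#' @export
print.quaternary_code <- function(x, ...) {
  cat(sprintf(
    "<quaternary_code> n = %d bp, k = %d (%s codewords), min distance >= %d%s\n",
    x$n, x$k, format(4^x$k, big.mark = ","), x$d,
    if (x$parity) " (parity mode)" else ""
  ))
  invisible(x)
}

# projective representatives of GF(4)^r \ {0}: first nonzero entry 1,
# ordered lexicographically; returned as an r x (4^r - 1)/3 integer matrix
.gf4_projective_points <- function(r) {
  grid <- as.matrix(expand.grid(rep(list(0:3), r))[, r:1, drop = FALSE])
  storage.mode(grid) <- "integer"
  keep <- apply(grid, 1, function(v) {
    nz <- which(v != 0L)
    length(nz) > 0L && v[nz[1]] == 1L
  })
  pts <- grid[keep, , drop = FALSE]
  ord <- do.call(order, as.data.frame(pts))
  t(pts[ord, , drop = FALSE])
}

# Greedy deterministic construction of a 4-row parity-check matrix whose
# columns are pairwise independent and no three linearly dependent
# (=> minimum distance 4).  Data columns are the distance-3 projective
# points with an appended 1 (the overall-sum row), taken in lexicographic
# order, skipping any column that would create a dependent triple with the
# columns already kept; the pure parity column e4 closes the matrix.
# Distance-4 parity-check matrix: columns are points of the elliptic
# quadric x1*x2 + x3^2 + x3*x4 + w*x4^2 = 0 in PG(3,4).  The quadric is an
# ovoid (17 points, no three collinear), so any three columns are linearly
# independent, which certifies minimum distance 4 for every shortening to
# n <= 16 columns.  Points are taken in lexicographic order.
.parity_check_extended <- function(n) {
  w <- 2L  # a primitive element of GF(4)
  # the point (0,1,0,0) plus the 16 affine points (1, f(z,t), z, t) = 17
  pts <- list(c(0L, 1L, 0L, 0L))
  for (z in 0:3) {
    for (t in 0:3) {
      f <- gf4_add(gf4_add(gf4_mul(z, z), gf4_mul(z, t)), gf4_mul(w, gf4_mul(t, t)))
      pts <- c(pts, list(c(1L, f, z, t)))
    }
  }
  ord <- do.call(order, as.data.frame(do.call(rbind, pts)))
  pts <- pts[ord]
  # ensure the selected columns span GF(4)^4: greedily take a rank-4 basis
  # first, then fill with the remaining points in lexicographic order
  basis <- integer(0)
  for (j in seq_along(pts)) {
    if (length(basis) == 4L) break
    cand <- c(basis, j)
    if (gf4_rank(do.call(cbind, pts[cand])) == length(cand)) basis <- cand
  }
  sel <- c(basis, setdiff(seq_along(pts), basis))[seq_len(n)]
  do.call(cbind, pts[sort(sel)])
}

# direct verification of the distance certificate on H
.check_distance_certificate <- function(H, d) {
  n <- ncol(H)
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      if (gf4_rank(H[, c(a, b), drop = FALSE]) < 2L) {
        stop("distance certificate failed: columns ", a, " and ", b, " are dependent")
      }
    }
  }
  if (d >= 4) {
    for (a in seq_len(n - 2)) {
      for (b in (a + 1):(n - 1)) {
        for (cc in (b + 1):n) {
          if (gf4_rank(H[, c(a, b, cc), drop = FALSE]) < 3L) {
            stop("distance certificate failed: columns ", a, ", ", b, ", ", cc,
                 " are linearly dependent")
          }
        }
      }
    }
  }
  invisible(TRUE)
}

.gf4_pivot_columns <- function(H) {
  A <- H
  piv <- integer(0)
  row <- 1L
  for (col in seq_len(ncol(A))) {
    if (row > nrow(A)) break
    p <- which(A[row:nrow(A), col] != 0L)[1]
    if (is.na(p)) next
    p <- p + row - 1L
    if (p != row) A[c(row, p), ] <- A[c(p, row), ]
    A[row, ] <- gf4_scale(gf4_inv(A[row, col]), A[row, ])
    for (r in seq_len(nrow(A))) {
      if (r != row && A[r, col] != 0L) {
        A[r, ] <- gf4_add(A[r, ], gf4_scale(A[r, col], A[row, ]))
      }
    }
    piv <- c(piv, col)
    row <- row + 1L
  }
  piv
}

# map every correctable syndrome (alpha * column j) to (j, alpha); keys are
# base-4 strings of the syndrome.  Distinct by the distance certificate.
.syndrome_table <- function(H) {
  n <- ncol(H)
  keys <- character(0); pos <- integer(0); mag <- integer(0)
  for (j in seq_len(n)) {
    for (al in 1:3) {
      s <- gf4_scale(al, H[, j])
      keys <- c(keys, paste(s, collapse = ""))
      pos <- c(pos, j)
      mag <- c(mag, al)
    }
  }
  if (anyDuplicated(keys)) stop("internal error: duplicate correctable syndromes")
  names(pos) <- keys
  names(mag) <- keys
  list(pos = pos, mag = mag)
}

# ---- symbol/string conversions -------------------------------------------

.BASES <- c("A", "C", "G", "T")

# character vector of equal-length sequences -> integer matrix (len x N)
seqs_to_gf4 <- function(x, len = NULL) {
  if (length(x) == 0) return(matrix(integer(0), nrow = len %||% 0, ncol = 0))
  if (is.null(len)) len <- nchar(x[1])
  v <- match(unlist(strsplit(x, "", fixed = TRUE)), .BASES) - 1L
  if (anyNA(v)) stop("sequence contains characters outside ACGT")
  matrix(v, nrow = len)
}

gf4_to_seqs <- function(m) {
  if (is.null(dim(m))) m <- matrix(m, ncol = 1)
  apply(m, 2, function(v) paste(.BASES[v + 1L], collapse = ""))
}

# ---- encoding -------------------------------------------------------------

#' Encode a message as an error-correcting DNA barcode
#'
#' Maps a message of `k = code$k` GF(4) symbols (integers 0-3) to its
#' `n`-bp codeword.  The codeword `c` satisfies `H %*% c = 0` over GF(4);
#' the all-zero message encodes to the all-`A` barcode.
#'
#' @param code A [build_code()] object.
#' @param message Integer vector of length `code$k` with values in 0:3.
#' @return A nucleotide string of length `code$n`.
#' @export
encode <- function(code, message) {
  stopifnot(inherits(code, "quaternary_code"))
  if (length(message) != code$k) {
    stop("message must have length k = ", code$k, ", got ", length(message))
  }
  if (!all(message %in% 0:3)) stop("message symbols must be integers in 0..3")
  gf4_to_seqs(encode_matrix(code, matrix(as.integer(message), ncol = 1)))
}

# vectorised encoder: messages as k x N matrix -> codeword matrix n x N
encode_matrix <- function(code, messages) {
  stopifnot(nrow(messages) == code$k)
  N <- ncol(messages)
  cw <- matrix(0L, code$n, N)
  cw[code$free, ] <- messages
  if (length(code$pivot)) {
    cw[code$pivot, ] <- gf4_matmul(code$M, messages)
  }
  cw
}

# all 4^k codewords as an n x 4^k matrix (use only for small k)
all_codewords <- function(code) {
  k <- code$k
  msgs <- t(as.matrix(expand.grid(rep(list(0:3), k))[, k:1, drop = FALSE]))
  storage.mode(msgs) <- "integer"
  encode_matrix(code, msgs)
}

# ---- decoding -------------------------------------------------------------

#' Decode an observed DNA tag with single-substitution correction
#'
#' Computes the syndrome of the observed tag against the code's
#' parity-check matrix.  A zero syndrome means the tag is a codeword
#' (`valid`); a syndrome equal to a scalar multiple of column *j* means a
#' single substitution at position *j*, which is corrected (`corrected`).
#' Any other nonzero syndrome cannot come from a single substitution: in
#' parity mode (distance 4) it is reported as `detected_uncorrectable`
#' (at least two substitutions, never silently miscorrected), otherwise as
#' `invalid`.
#'
#' @param code A [build_code()] object.
#' @param observed A nucleotide string of length `code$n` (ACGT).
#' @return A list with `status` (one of `"valid"`, `"corrected"`,
#'   `"detected_uncorrectable"`, `"invalid"`), `codeword` (the decoded
#'   barcode, or `NA` if not decodable), `error_position` and
#'   `error_magnitude` (set when `status == "corrected"`).
#' @export
decode_tag <- function(code, observed) {
  stopifnot(inherits(code, "quaternary_code"), is.character(observed), length(observed) == 1)
  if (nchar(observed) != code$n) {
    stop("observed tag has length ", nchar(observed), ", expected ", code$n)
  }
  res <- decode_tags(code, observed)
  list(status = res$status, codeword = res$codeword,
       error_position = res$error_position, error_magnitude = res$error_magnitude)
}

#' Decode many observed tags at once
#'
#' Vectorised form of [decode_tag()]; the workhorse used by the read
#' decoder.
#'
#' @inheritParams decode_tag
#' @param observed Character vector of `n`-bp tags.
#' @return A tibble with one row per tag: `observed`, `status`, `codeword`,
#'   `error_position`, `error_magnitude`.
#' @export
decode_tags <- function(code, observed) {
  N <- length(observed)
  if (N == 0) {
    return(tibble::tibble(observed = character(), status = character(),
                          codeword = character(), error_position = integer(),
                          error_magnitude = integer()))
  }
  C <- seqs_to_gf4(observed, code$n)
  S <- gf4_matmul(code$H, C)
  keys <- apply(S, 2, paste, collapse = "")
  zero_key <- strrep("0", nrow(code$H))

  status <- rep(if (code$parity) "detected_uncorrectable" else "invalid", N)
  codeword <- rep(NA_character_, N)
  err_pos <- rep(NA_integer_, N)
  err_mag <- rep(NA_integer_, N)

  ok <- keys == zero_key
  status[ok] <- "valid"
  codeword[ok] <- observed[ok]

  hit <- match(keys, names(code$syndrome_pos))
  corr <- !ok & !is.na(hit)
  if (any(corr)) {
    idx <- which(corr)
    pos <- unname(code$syndrome_pos[hit[idx]])
    mag <- unname(code$syndrome_mag[hit[idx]])
    Cc <- C[, idx, drop = FALSE]
    Cc[cbind(pos, seq_along(idx))] <- gf4_add(Cc[cbind(pos, seq_along(idx))], mag)
    status[idx] <- "corrected"
    codeword[idx] <- gf4_to_seqs(Cc)
    err_pos[idx] <- pos
    err_mag[idx] <- mag
  }
  tibble::tibble(observed = observed, status = status, codeword = codeword,
                 error_position = err_pos, error_magnitude = err_mag)
}

# ---- barcode set generation ----------------------------------------------

#' Generate a set of mutually distant DNA barcodes
#'
#' Samples `count` distinct codewords from a quaternary Hamming code, so
#' every pair of returned barcodes has Hamming distance at least 3 (4 in
#' parity mode).  Sampling is without replacement and fully determined by
#' `seed`.  No GC-content or homopolymer filtering is applied.
#'
#' @param n Barcode length in bp (7-16).
#' @param count Number of barcodes; at most `4^k` for the chosen code.
#' @param parity Logical; request minimum distance 4.
#' @param seed Integer seed controlling the sample.
#' @return A tibble with columns `index` and `barcode`.
#' @examples
#' generate_barcode_set(8, 96, seed = 1)
#' @export
generate_barcode_set <- function(n, count, parity = FALSE, seed = 1L) {
  code <- build_code(n, parity)
  capacity <- 4^code$k
  if (count > capacity) {
    stop("requested ", count, " barcodes but a length-", n,
         if (parity) " parity" else "", " code has capacity ", format(capacity, scientific = FALSE))
  }
  msgs <- with_seed(seed, {
    seen <- new.env(parent = emptyenv())
    out <- matrix(0L, code$k, 0L)
    while (ncol(out) < count) {
      need <- count - ncol(out)
      draw <- matrix(sample(0:3, code$k * max(need * 2L, 16L), replace = TRUE), nrow = code$k)
      keys <- apply(draw, 2, paste, collapse = "")
      fresh <- !duplicated(keys) & !vapply(keys, function(k) exists(k, seen), logical(1))
      draw <- draw[, fresh, drop = FALSE]
      keys <- keys[fresh]
      take <- seq_len(min(ncol(draw), need))
      for (k in keys[take]) assign(k, TRUE, seen)
      out <- cbind(out, draw[, take, drop = FALSE])
    }
    out
  })
  tibble::tibble(index = seq_len(count), barcode = gf4_to_seqs(encode_matrix(code, msgs)))
}

# ---- lookup decoder for unstructured tag sets -----------------------------

#' Build a hash-map decoder for an arbitrary tag set
#'
#' Many DELs use barcode sets that were generated randomly rather than from
#' a single Hamming code.  For those, decoding falls back to an associative
#' lookup: each exact tag decodes to itself, and a single-substitution
#' neighbour decodes to a tag *iff* exactly one tag claims it and the
#' neighbour is not itself a tag.  Neighbours claimed by two or more tags
#' are ambiguous and decode as invalid.
#'
#' @param tags Character vector of distinct, equal-length ACGT tags.
#' @return An object of class `lookup_decoder`.
#' @export
build_lookup_decoder <- function(tags) {
  if (length(tags) == 0) stop("empty tag set")
  len <- nchar(tags[1])
  if (!all(nchar(tags) == len)) stop("tags must all have the same length")
  if (anyDuplicated(tags)) stop("duplicate tags: ", paste(unique(tags[duplicated(tags)]), collapse = ", "))
  M <- seqs_to_gf4(tags, len)

  # enumerate all 1-substitution neighbours of every tag
  nb_key <- character(0); nb_tag <- integer(0)
  for (i in seq_along(tags)) {
    v <- M[, i]
    for (p in seq_len(len)) {
      for (b in setdiff(0:3, v[p])) {
        w <- v; w[p] <- b
        nb_key <- c(nb_key, paste(.BASES[w + 1L], collapse = ""))
        nb_tag <- c(nb_tag, i)
      }
    }
  }
  claims <- table(nb_key)
  unique_nb <- names(claims)[claims == 1L]
  unique_nb <- setdiff(unique_nb, tags)   # a tag is never reinterpreted
  keep <- nb_key %in% unique_nb
  map <- nb_tag[keep]
  names(map) <- nb_key[keep]
  structure(list(tags = tags, length = len, neighbour_map = map),
            class = "lookup_decoder")
}

#' Decode observed tags against a lookup decoder
#'
#' @param decoder A [build_lookup_decoder()] object.
#' @param observed Character vector of tags (same length as the decoder's).
#' @return A tibble with `observed`, `status` (`valid`, `corrected`,
#'   `invalid`) and `codeword`.
#' @export
decode_lookup <- function(decoder, observed) {
  stopifnot(inherits(decoder, "lookup_decoder"))
  status <- rep("invalid", length(observed))
  codeword <- rep(NA_character_, length(observed))
  exact <- match(observed, decoder$tags)
  status[!is.na(exact)] <- "valid"
  codeword[!is.na(exact)] <- observed[!is.na(exact)]
  rest <- which(is.na(exact))
  nb <- match(observed[rest], names(decoder$neighbour_map))
  hit <- rest[!is.na(nb)]
  status[hit] <- "corrected"
  codeword[hit] <- decoder$tags[decoder$neighbour_map[nb[!is.na(nb)]]]
  tibble::tibble(observed = observed, status = status, codeword = codeword)
}
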