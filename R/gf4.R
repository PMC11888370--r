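# Arithmetic over GF(4) = {0, 1, w, w^2}, encoded as integers 0..3 with
# 1 = 1, 2 = w, 3 = w^2.  Characteristic 2: addition is bitwise XOR of the
# 2-bit representations.  The nonzero elements form a cyclic group of order 3.

# multiplication table, row/col indexed by value + 1
.gf4_mult_table <- matrix(
  c(0L, 0L, 0L, 0L,
    0L, 1L, 2L, 3L,
    0L, 2L, 3L, 1L,
    0L, 3L, 1L, 2L),
  nrow = 4, byrow = TRUE
)

# multiplicative inverses of 1, 2, 3
.gf4_inv <- c(1L, 3L, 2L)

gf4_add <- function(a, b) {
  r <- bitwXor(a, b)
  if (!is.null(dim(a))) dim(r) <- dim(a) else if (!is.null(dim(b))) dim(r) <- dim(b)
  r
}

gf4_mul <- function(a, b) {
  .gf4_mult_table[cbind(a + 1L, b + 1L)]
}

# scalar * vector, vectorised over the vector
gf4_scale <- function(alpha, v) .gf4_mult_table[alpha + 1L, v + 1L]

gf4_inv <- function(a) {
  if (any(a == 0L)) stop("0 has no inverse in GF(4)")
  .gf4_inv[a]
}

# matrix product over GF(4): A (r x m) %*% B (m x c)
gf4_matmul <- function(A, B) {
  r <- nrow(A); m <- ncol(A); cc <- ncol(B)
  out <- matrix(0L, r, cc)
  for (t in seq_len(m)) {
    out <- gf4_add(out, outer(A[, t], B[t, ], gf4_mul))
  }
  out
}

# Invert a square matrix over GF(4) by Gauss-Jordan elimination.
gf4_solve <- function(A) {
  n <- nrow(A)
  aug <- cbind(A, diag(n) * 0L + diag(n))
  storage.mode(aug) <- "integer"
  for (col in seq_len(n)) {
    piv <- which(aug[col:n, col] != 0L)[1]
    if (is.na(piv)) stop("matrix is singular over GF(4)")
    piv <- piv + col - 1L
    if (piv != col) aug[c(col, piv), ] <- aug[c(piv, col), ]
    aug[col, ] <- gf4_scale(gf4_inv(aug[col, col]), aug[col, ])
    for (r in seq_len(n)) {
      if (r != col && aug[r, col] != 0L) {
        aug[r, ] <- gf4_add(aug[r, ], gf4_scale(aug[r, col], aug[col, ]))
      }
    }
  }
  aug[, (n + 1L):(2L * n), drop = FALSE]
}

# rank over GF(4)
gf4_rank <- function(A) {
  A <- as.matrix(A); storage.mode(A) <- "integer"
  rank <- 0L
  row <- 1L
  for (col in seq_len(ncol(A))) {
    if (row > nrow(A)) break
    piv <- which(A[row:nrow(A), col] != 0L)[1]
    if (is.na(piv)) next
    piv <- piv + row - 1L
    if (piv != row) A[c(row, piv), ] <- A[c(piv, row), ]
    A[row, ] <- gf4_scale(gf4_inv(A[row, col]), A[row, ])
    for (r in seq_len(nrow(A))) {
      if (r != row && A[r, col] != 0L) {
        A[r, ] <- gf4_add(A[r, ], gf4_scale(A[r, col], A[row, ]))
      }
    }
    row <- row + 1L
    rank <- rank + 1L
  }
  rank
}
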