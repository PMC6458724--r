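#' Classical LCS prefix score table
#'
#' Computes the full (m+1) x (n+1) table R whose cell (i, j) holds the LCS
#' length of the prefixes `A[1..i]` and `B[1..j]`:
#' \deqn{R[i,j] = 0 \textrm{ if } i = 0 \textrm{ or } j = 0;\quad
#'       R[i-1,j-1] + 1 \textrm{ if } A[i] = B[j];\quad
#'       \max(R[i-1,j], R[i,j-1]) \textrm{ otherwise.}}
#' The answer is the corner cell R[m, n]. This is the reference
#' implementation against which the row-wise kernels are validated.
#'
#' @param A,B Character strings.
#' @return Integer matrix with `m + 1` rows and `n + 1` columns; row i and
#'   column j of the recurrence live at matrix index `[i + 1, j + 1]`.
#' @seealso [lcs_length()] for the two-row length-only variant.
#' @export
lcs_table <- function(A, B) {
  stopifnot(is.character(A), length(A) == 1L, is.character(B), length(B) == 1L)
  cpp_lcs_table(A, B)
}

#' LCS length (classical recurrence, two-row storage)
#'
#' Same recurrence as [lcs_table()], but keeps only the current and the
#' previous score row, so working storage is proportional to `n` rather than
#' `m * n`.
#'
#' @param A,B Character strings.
#' @return The LCS length, a nonnegative integer.
#' @export
lcs_length <- function(A, B) {
  stopifnot(is.character(A), length(A) == 1L, is.character(B), length(B) == 1L)
  cpp_lcs_length_classic(A, B)
}

#' Brute-force LCS length by exhaustive enumeration
#'
#' Independent test oracle: enumerates every subsequence of the shorter
#' string (in decreasing length order) and returns the length of the first
#' one that is also a subsequence of the longer string. Exponential in the
#' shorter length, hence capped at 15.
#'
#' @param A,B Character strings with `min(nchar(A), nchar(B)) <= 15`.
#' @return The LCS length.
#' @export
brute_force_lcs <- function(A, B) {
  stopifnot(is.character(A), length(A) == 1L, is.character(B), length(B) == 1L)
  if (nchar(A) > nchar(B)) { tmp <- A; A <- B; B <- tmp }
  k <- nchar(A)
  if (k > 15L)
    abort_size(sprintf("brute force requires min sequence length <= 15, got %d", k))
  if (k == 0L || nchar(B) == 0L) return(0L)
  sa <- utf8ToInt(A)
  tb <- utf8ToInt(B)
  masks <- 0:(2L^k - 1L)
  bits <- outer(masks, 0:(k - 1L), function(m, b) bitwAnd(bitwShiftR(m, b), 1L))
  ord <- order(rowSums(bits), decreasing = TRUE)
  for (r in ord) {
    sub <- sa[bits[r, ] == 1L]
    if (is_subsequence_int(sub, tb)) return(length(sub))
  }
  0L
}

# greedy subsequence test on integer code vectors
is_subsequence_int <- function(sub, seq) {
  if (length(sub) == 0L) return(TRUE)
  if (length(sub) > length(seq)) return(FALSE)
  pos <- 0L
  nseq <- length(seq)
  for (ch in sub) {
    pos <- pos + 1L
    while (pos <= nseq && seq[pos] != ch) pos <- pos + 1L
    if (pos > nseq) return(FALSE)
  }
  TRUE
}

#' Recover one longest common subsequence from a score table
#'
#' Walks the table produced by [lcs_table()] from the corner back to the
#' origin. Ties are broken deterministically: at each cell, take the
#' diagonal move when the characters match and it explains the score,
#' otherwise move up (decrement i) when that preserves the score, otherwise
#' move left.
#'
#' @param table Integer matrix from `lcs_table(A, B)`.
#' @param A,B The sequences the table was built from.
#' @return A common subsequence of `A` and `B` of maximal length (possibly
#'   the empty string).
#' @export
lcs_traceback <- function(table, A, B) {
  m <- nchar(A); n <- nchar(B)
  if (!is.matrix(table) || nrow(table) != m + 1L || ncol(table) != n + 1L)
    abort_contract(sprintf(
      "table dimensions (%d x %d) do not match sequences (%d x %d)",
      nrow(table), ncol(table), m + 1L, n + 1L))
  if (m == 0L || n == 0L) return("")
  a <- strsplit(A, "", fixed = TRUE)[[1]]
  b <- strsplit(B, "", fixed = TRUE)[[1]]
  out <- character(0)
  i <- m; j <- n
  while (i > 0L && j > 0L) {
    if (a[i] == b[j] && table[i + 1L, j + 1L] == table[i, j] + 1L) {
      out <- c(a[i], out)
      i <- i - 1L; j <- j - 1L
    } else if (table[i, j + 1L] == table[i + 1L, j + 1L]) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  paste(out, collapse = "")
}
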