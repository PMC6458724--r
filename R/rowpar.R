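#' Execution policy for work-shared row evaluation
#'
#' Describes how the elements of one score row (and the rows of the P table)
#' are shared among workers: worker count, scheduling strategy and chunk
#' size, mirroring the static/dynamic/guided work-sharing schedules of
#' OpenMP-style parallel-for loops. The computed LCS length is a pure
#' function of the sequences: every policy yields the identical result, the
#' policy only affects how the order-independent per-element work is
#' distributed.
#'
#' @param workers Positive integer number of workers. The default is the
#'   number of available processors capped at 16, the tuned optimum for this
#'   algorithm family on shared-memory CPUs.
#' @param schedule One of `"static"`, `"dynamic"`, `"guided"`.
#' @param chunk Positive integer chunk size, or `"auto"` (static: even split
#'   of `ceiling(n / workers)`; dynamic/guided: implementation default).
#' @return An object of class `execution_policy`.
#' @export
execution_policy <- function(workers = default_workers(),
                             schedule = c("static", "dynamic", "guided"),
                             chunk = "auto") {
  if (!is_count(workers, min = 1L))
    abort_contract("workers must be a positive integer")
  schedule <- tryCatch(match.arg(schedule),
                       error = function(e)
                         abort_contract("schedule must be static, dynamic or guided"))
  if (!(identical(chunk, "auto") || is_count(chunk, min = 1L)))
    abort_contract("chunk must be a positive integer or \"auto\"")
  structure(
    list(workers = as.integer(workers), schedule = schedule,
         chunk = if (identical(chunk, "auto")) "auto" else as.integer(chunk)),
    class = "execution_policy"
  )
}

#' @rdname execution_policy
#' @export
default_workers <- function() {
  nc <- tryCatch(parallel::detectCores(logical = TRUE), error = function(e) 1L)
  if (is.na(nc) || nc < 1L) nc <- 1L
  min(nc, 16L)
}

#' @export
print.execution_policy <- function(x, ...) {
  cat(sprintf("<execution_policy> workers=%d schedule=%s chunk=%s\n",
              x$workers, x$schedule, as.character(x$chunk)))
  invisible(x)
}

as_policy <- function(policy) {
  if (is.null(policy)) return(execution_policy())
  if (!inherits(policy, "execution_policy"))
    abort_contract("policy must be created with execution_policy()")
  policy
}

schedule_code <- function(schedule) {
  switch(schedule, static = 1L, dynamic = 2L, guided = 3L,
         abort_contract("unknown schedule"))
}

chunk_code <- function(chunk) if (identical(chunk, "auto")) 0L else as.integer(chunk)

#' Build the last-occurrence (P) table
#'
#' For each alphabet rank c and column j in `0..n`, the P table records where
#' the character `C[c]` last occurs in `B[1..j]` (1-based). Two storage
#' variants are supported:
#' \describe{
#'   \item{`v2_direct`}{`P[c, j] = occ(c, j)`, the last occurrence position
#'     itself, with 0 meaning "no occurrence". Used by the two-branch
#'     version-2 row kernel.}
#'   \item{`v1_offset`}{`P[c, j] = occ(c, j) - 1`, with -1 as the
#'     "no occurrence" sentinel (0 would be ambiguous with an occurrence at
#'     position 1). Used by the three-branch version-1 row kernel.}
#' }
#' Rows of P are mutually independent and are computed under the given
#' work-sharing policy; the result is identical for every policy.
#'
#' @param B Character string (the second sequence).
#' @param alphabet An [build_alphabet()] result covering every character of `B`.
#' @param variant `"v2_direct"` or `"v1_offset"`.
#' @param policy An [execution_policy()]; default policy if `NULL`.
#' @return Object of class `occurrence_table`: list with `variant`,
#'   `alphabet`, and integer matrix `P` (`|C|` rows, `n + 1` columns; column
#'   names `j0..jn`, row names the alphabet characters).
#' @export
build_occurrence_table <- function(B, alphabet,
                                   variant = c("v2_direct", "v1_offset"),
                                   policy = NULL) {
  variant <- match.arg(variant)
  if (!inherits(alphabet, "lcs_alphabet"))
    abort_contract("alphabet must be an lcs_alphabet")
  stopifnot(is.character(B), length(B) == 1L)
  if (nzchar(B)) {
    bchars <- unique(strsplit(B, "", fixed = TRUE)[[1]])
    missing <- setdiff(bchars, alphabet$chars)
    if (length(missing) > 0L)
      abort_contract(sprintf("character '%s' of B has no rank in the alphabet",
                             missing[1]))
  }
  policy <- as_policy(policy)
  P <- cpp_occurrence_table(B, alphabet$symbols,
                            offset = (variant == "v1_offset"),
                            workers = policy$workers,
                            schedule = schedule_code(policy$schedule),
                            chunk = chunk_code(policy$chunk))
  dimnames(P) <- list(alphabet$chars, paste0("j", 0:nchar(B)))
  structure(list(variant = variant, alphabet = alphabet, P = P),
            class = "occurrence_table")
}

#' @export
print.occurrence_table <- function(x, ...) {
  cat(sprintf("<occurrence_table> variant=%s, %d x %d\n",
              x$variant, nrow(x$P), ncol(x$P)))
  invisible(x)
}

#' Version-1 row update (three data branches)
#'
#' Computes score row i from row i - 1 using the offset-stored occurrence
#' table. Each output element j is decided by one of three branches: a
#' direct character match `A[i] == B[j]` (diagonal + 1), an earlier
#' occurrence of `A[i]` in `B[1..j]` (`max(prev[j], prev[occ - 1] + 1)`), or
#' no occurrence at all (carry `prev[j]` down). Elements depend only on the
#' previous row, so they may be computed in any order.
#'
#' @param prev Integer vector of length n + 1: score row i - 1 (column 0
#'   first).
#' @param i Row index in `1..m`.
#' @param A,B The sequences.
#' @param alphabet Joint alphabet of `A` and `B`.
#' @param P An `occurrence_table` with variant `v1_offset` built from `B`.
#' @return Integer vector of length n + 1: score row i.
#' @export
row_update_v1 <- function(prev, i, A, B, alphabet, P) {
  if (!inherits(P, "occurrence_table") || P$variant != "v1_offset")
    abort_contract("P must be an occurrence_table with variant v1_offset")
  n <- nchar(B)
  if (length(prev) != n + 1L)
    abort_contract(sprintf("prev must have n + 1 = %d elements", n + 1L))
  if (!is_count(i, min = 1L) || i > nchar(A))
    abort_contract("row index i must be in 1..m")
  ai <- substr(A, i, i)
  c <- alphabet_rank(alphabet, ai)
  cpp_row_update_v1(as.integer(prev), ai, B, P$P[c, ])
}

#' Version-2 row update (two data branches, branch-reduced)
#'
#' The branch-reduced kernel: consumes only the alphabet rank `c` of the
#' current character and the direct-stored occurrence table, never comparing
#' sequence characters. Each element j is `prev[j]` when `P[c, j] = 0` and
#' `max(prev[j], prev[P[c, j] - 1] + 1)` otherwise, which yields exactly the
#' classical score row.
#'
#' @param prev Integer vector of length n + 1: score row i - 1.
#' @param c Alphabet rank (1-based) of the current character of `A`.
#' @param P An `occurrence_table` with variant `v2_direct` built from `B`.
#' @param n Column count (length of `B`).
#' @return Integer vector of length n + 1: score row i.
#' @export
row_update_v2 <- function(prev, c, P, n) {
  if (!inherits(P, "occurrence_table") || P$variant != "v2_direct")
    abort_contract("P must be an occurrence_table with variant v2_direct")
  if (!is_count(c, min = 1L) || c > nrow(P$P))
    abort_contract(sprintf("alphabet rank c = %s out of range 1..%d",
                           as.character(c), nrow(P$P)))
  if (ncol(P$P) != n + 1L)
    abort_contract("P column count does not match n + 1")
  if (length(prev) != n + 1L)
    abort_contract(sprintf("prev must have n + 1 = %d elements", n + 1L))
  cpp_row_update_v2(as.integer(prev), P$P[c, ])
}

#' LCS length via row-wise-independent kernels
#'
#' Builds the joint alphabet and the P table for the chosen version, then
#' sweeps the score rows top to bottom keeping only two rows, evaluating the
#' elements of each row under the work-sharing policy. Returns exactly
#' [lcs_length()] for every input, version and policy; peak working storage
#' is two rows plus the `|C| x (n + 1)` P table.
#'
#' @param A,B Character strings.
#' @param version `"v2"` (branch-reduced, the default) or `"v1"`.
#' @param policy An [execution_policy()]; default policy if `NULL`.
#' @return The LCS length, a nonnegative integer.
#' @export
lcs_length_rowwise <- function(A, B, version = c("v2", "v1"), policy = NULL) {
  version <- tryCatch(match.arg(version),
                      error = function(e) abort_contract("version must be v1 or v2"))
  stopifnot(is.character(A), length(A) == 1L, is.character(B), length(B) == 1L)
  policy <- as_policy(policy)
  if (!nzchar(A) || !nzchar(B)) return(0L)
  alphabet <- build_alphabet(A, B)
  cpp_lcs_length_rowwise(A, B, alphabet$symbols,
                         version = if (version == "v1") 1L else 2L,
                         workers = policy$workers,
                         schedule = schedule_code(policy$schedule),
                         chunk = chunk_code(policy$chunk))
}

#' Partition loop iterations into scheduled chunks
#'
#' Models how `1..n` loop iterations are carved into contiguous chunks under
#' a work-sharing policy. `static` assigns fixed-size chunks round-robin to
#' workers (chunk `"auto"` = `ceiling(n / workers)`); `dynamic` uses
#' fixed-size chunks claimed by the next free worker at run time (so no
#' worker is pre-assigned); `guided` shrinks chunk sizes proportionally to
#' the remaining work, with the configured chunk as a floor.
#'
#' @param n Number of iterations (>= 0).
#' @param policy An [execution_policy()].
#' @return A data frame with columns `start`, `end`, `worker` (integer; `NA`
#'   for schedules where assignment happens at run time), whose ranges are
#'   disjoint, contiguous, ascending and cover `1..n` exactly. Zero rows when
#'   `n = 0`.
#' @export
partition <- function(n, policy = NULL) {
  if (!is_count(n, min = 0L)) abort_contract("n must be a nonnegative integer")
  policy <- as_policy(policy)
  n <- as.integer(n)
  empty <- data.frame(start = integer(0), end = integer(0), worker = integer(0))
  if (n == 0L) return(empty)
  w <- policy$workers
  if (policy$schedule == "guided") {
    floor_chunk <- if (identical(policy$chunk, "auto")) 1L else policy$chunk
    starts <- integer(0); ends <- integer(0)
    nxt <- 1L
    while (nxt <= n) {
      remaining <- n - nxt + 1L
      size <- max(as.integer(ceiling(remaining / w)), floor_chunk)
      size <- min(size, remaining)
      starts <- c(starts, nxt); ends <- c(ends, nxt + size - 1L)
      nxt <- nxt + size
    }
    return(data.frame(start = starts, end = ends,
                      worker = rep(NA_integer_, length(starts))))
  }
  k <- if (identical(policy$chunk, "auto")) as.integer(ceiling(n / w))
       else policy$chunk
  starts <- seq.int(1L, n, by = k)
  ends <- pmin(starts + k - 1L, n)
  worker <- if (policy$schedule == "static")
    as.integer((seq_along(starts) - 1L) %% w + 1L)
  else
    rep(NA_integer_, length(starts))
  data.frame(start = as.integer(starts), end = as.integer(ends), worker = worker)
}
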