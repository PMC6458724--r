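# independent oracles and small generators shared across test files;
# these deliberately avoid the package's kernels and RNG plumbing

rand_string <- function(len, chars = c("A", "C", "G", "T")) {
  if (len == 0L) return("")
  paste(sample(chars, len, replace = TRUE), collapse = "")
}

alphabet_pool <- function(size) {
  # alphabet sizes used across the oracle suites: 1, 2, 4, 8 symbols
  c("A", "AC", "ACGT", "ACGTNRYK")[[match(size, c(1L, 2L, 4L, 8L))]]
}

# brute-force last-occurrence scan: largest p in 1..j with B[p] == ch, else 0
oracle_last_occ <- function(B, ch, j) {
  bs <- strsplit(B, "", fixed = TRUE)[[1]]
  hits <- which(bs[seq_len(j)] == ch)
  if (length(hits) == 0L) 0L else max(hits)
}

# character-level subsequence predicate (greedy, independent of the package)
is_subseq_chr <- function(sub, s) {
  if (!nzchar(sub)) return(TRUE)
  a <- strsplit(sub, "", fixed = TRUE)[[1]]
  b <- strsplit(s, "", fixed = TRUE)[[1]]
  i <- 0L
  for (ch in a) {
    repeat {
      i <- i + 1L
      if (i > length(b)) return(FALSE)
      if (b[i] == ch) break
    }
  }
  TRUE
}

random_pair <- function(max_len, chars = c("A", "C", "G", "T"), min_len = 0L) {
  list(A = rand_string(sample(min_len:max_len, 1L), chars),
       B = rand_string(sample(min_len:max_len, 1L), chars))
}

all_policies <- function(workers = c(1L, 2L, 4L, 8L),
                         schedules = c("static", "dynamic", "guided"),
                         chunks = list(1L, 16L, "auto")) {
  out <- list()
  for (w in workers) for (s in schedules) for (k in chunks)
    out[[length(out) + 1L]] <- execution_policy(w, s, k)
  out
}
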