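test_that("occurrence table matches worked examples for both variants", {
  a <- build_alphabet("ACGT", "AGT")
  P2 <- build_occurrence_table("AGT", a, "v2_direct")
  expect_equal(unname(P2$P["G", ]), c(0L, 0L, 2L, 2L))
  P1 <- build_occurrence_table("AGT", a, "v1_offset")
  expect_equal(unname(P1$P["G", ]), c(-1L, -1L, 1L, 1L))
  # column j = 0 base case, every row
  expect_true(all(P2$P[, 1] == 0L))
  expect_true(all(P1$P[, 1] == -1L))
})

test_that("occurrence table equals the brute-force last-occurrence scan", {
  set.seed(31)
  for (i in 1:40) {
    chars <- strsplit(alphabet_pool(sample(c(1L, 2L, 4L, 8L), 1)), "")[[1]]
    B <- rand_string(sample(1:24, 1), chars)
    a <- build_alphabet(B, rand_string(sample(0:5, 1), chars))
    P2 <- build_occurrence_table(B, a, "v2_direct")$P
    P1 <- build_occurrence_table(B, a, "v1_offset")$P
    for (c in seq_along(a$chars)) {
      occ <- vapply(0:nchar(B), function(j)
        if (j == 0L) 0L else oracle_last_occ(B, a$chars[c], j), integer(1))
      expect_equal(unname(P2[c, ]), occ)
      expect_equal(unname(P1[c, ]), occ - 1L)
      # monotone, bounded by j
      expect_true(all(diff(P2[c, ]) >= 0L))
      expect_true(all(P2[c, ] <= 0:nchar(B)))
    }
  }
})

test_that("occurrence table rejects characters of B outside the alphabet", {
  a <- build_alphabet("ACGT", "ACGT")
  expect_error(build_occurrence_table("ACGN", a, "v2_direct"),
               class = "rowlcs_contract_error")
})

test_that("occurrence table output is policy-independent", {
  set.seed(37)
  B <- rand_string(300L)
  a <- build_alphabet(B, "")
  ref <- build_occurrence_table(B, a, "v2_direct")$P
  for (pol in all_policies(workers = c(2L, 8L), chunks = list(1L, "auto")))
    expect_identical(build_occurrence_table(B, a, "v2_direct", pol)$P, ref)
})

test_that("row updates match worked examples", {
  a <- build_alphabet("ACGT", "AGT")
  P1 <- build_occurrence_table("AGT", a, "v1_offset")
  P2 <- build_occurrence_table("AGT", a, "v2_direct")
  zero <- rep(0L, 4L)
  expect_equal(row_update_v1(zero, 1L, "ACGT", "AGT", a, P1), c(0L, 1L, 1L, 1L))
  expect_equal(row_update_v2(zero, alphabet_rank(a, "A"), P2, 3L),
               c(0L, 1L, 1L, 1L))
  # row i = 4 (character T), prev frozen from the classical table
  expect_equal(row_update_v2(c(0L, 1L, 2L, 2L), alphabet_rank(a, "T"), P2, 3L),
               c(0L, 1L, 2L, 3L))
  # full sweep reaches the LCS length 3
  prev <- zero
  for (i in 1:4) prev <- row_update_v1(prev, i, "ACGT", "AGT", a, P1)
  expect_equal(prev[4], 3L)
})

test_that("a character absent from B carries the previous row down (v1)", {
  a <- build_alphabet("ACGTN", "ACGT")
  B <- "ACGT"
  P1 <- build_occurrence_table(B, a, "v1_offset")
  prev <- c(0L, 1L, 1L, 2L, 2L)
  expect_equal(row_update_v1(prev, 5L, "ACGTN", B, a, P1), prev)
  # and in v2 an all-zero P row does the same
  P2 <- build_occurrence_table(B, a, "v2_direct")
  expect_equal(row_update_v2(prev, alphabet_rank(a, "N"), P2, 4L), prev)
})

test_that("every row of both kernels equals the classical table row", {
  set.seed(41)
  for (rep in 1:20) {
    chars <- strsplit(alphabet_pool(sample(c(2L, 4L, 8L), 1)), "")[[1]]
    A <- rand_string(sample(1:32, 1), chars)
    B <- rand_string(sample(1:32, 1), chars)
    a <- build_alphabet(A, B)
    P1 <- build_occurrence_table(B, a, "v1_offset")
    P2 <- build_occurrence_table(B, a, "v2_direct")
    R <- lcs_table(A, B)
    prev1 <- prev2 <- rep(0L, nchar(B) + 1L)
    for (i in seq_len(nchar(A))) {
      c <- alphabet_rank(a, substr(A, i, i))
      prev1 <- row_update_v1(prev1, i, A, B, a, P1)
      prev2 <- row_update_v2(prev2, c, P2, nchar(B))
      expect_equal(prev1, unname(R[i + 1L, ]))
      expect_equal(prev2, prev1)
    }
  }
})

test_that("row update contract errors", {
  a <- build_alphabet("ACGT", "AGT")
  P1 <- build_occurrence_table("AGT", a, "v1_offset")
  P2 <- build_occurrence_table("AGT", a, "v2_direct")
  expect_error(row_update_v1(rep(0L, 3L), 1L, "ACGT", "AGT", a, P1),
               class = "rowlcs_contract_error") # prev length != n + 1
  expect_error(row_update_v1(rep(0L, 4L), 1L, "ACGT", "AGT", a, P2),
               class = "rowlcs_contract_error") # wrong variant
  expect_error(row_update_v2(rep(0L, 4L), 5L, P2, 3L),
               class = "rowlcs_contract_error") # rank out of range
  expect_error(row_update_v2(rep(0L, 4L), 0L, P2, 3L),
               class = "rowlcs_contract_error")
})

test_that("lcs_length_rowwise matches the classical length on worked cases", {
  expect_equal(lcs_length_rowwise("ACGT", "AGT", "v2",
                                  execution_policy(1L)), 3L)
  expect_equal(lcs_length_rowwise("AGCAT", "GAC", "v1",
                                  execution_policy(4L, "static", 2L)), 2L)
  expect_equal(lcs_length_rowwise("", "ACGT", "v1"), 0L)
  expect_equal(lcs_length_rowwise("", "ACGT", "v2"), 0L)
  expect_error(lcs_length_rowwise("A", "A", "v3"), class = "rowlcs_contract_error")
  expect_error(lcs_length_rowwise("A", "A", "v2", policy = list(workers = 2)),
               class = "rowlcs_contract_error")
})

test_that("execution_policy validates its fields", {
  p <- execution_policy()
  expect_s3_class(p, "execution_policy")
  expect_lte(p$workers, 16L) # default capped at 16
  expect_equal(p$schedule, "static")
  expect_equal(p$chunk, "auto")
  expect_error(execution_policy(0L), class = "rowlcs_contract_error")
  expect_error(execution_policy(2L, "fastest"), class = "rowlcs_contract_error")
  expect_error(execution_policy(2L, "static", 0L), class = "rowlcs_contract_error")
})

test_that("partition matches worked examples", {
  p <- partition(10L, execution_policy(3L, "static", 4L))
  expect_equal(p$start, c(1L, 5L, 9L))
  expect_equal(p$end, c(4L, 8L, 10L))
  expect_equal(p$worker, c(1L, 2L, 3L))
  expect_equal(nrow(partition(0L, execution_policy(2L, "dynamic"))), 0L)
  p <- partition(7L, execution_policy(2L, "static", "auto"))
  expect_equal(p$start, c(1L, 5L))
  expect_equal(p$end, c(4L, 7L))
})

test_that("partition always yields a disjoint exact cover of 1..n", {
  set.seed(47)
  for (rep in 1:60) {
    n <- sample(0:200, 1)
    pol <- execution_policy(sample(1:8, 1),
                            sample(c("static", "dynamic", "guided"), 1),
                            sample(list(1L, 3L, 16L, "auto"), 1)[[1]])
    p <- partition(n, pol)
    covered <- unlist(Map(seq.int, p$start, p$end), use.names = FALSE)
    if (n == 0L) expect_equal(length(covered), 0L)
    else expect_equal(covered, 1:n) # contiguous, ascending, disjoint, exact
    if (nrow(p) > 0L) {
      expect_true(all(p$end >= p$start))
      if (pol$schedule == "static")
        expect_true(all(p$worker >= 1L & p$worker <= pol$workers))
      # guided chunks never shrink below the configured floor except the tail
      if (pol$schedule == "guided" && !identical(pol$chunk, "auto") && nrow(p) > 1L)
        expect_true(all((p$end - p$start + 1L)[-nrow(p)] >= pol$chunk))
    }
  }
})
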