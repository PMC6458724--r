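# Expected values below marked "frozen" were computed once with
# brute_force_lcs (exhaustive enumeration) and checked by hand.

test_that("lcs_table matches the prefix recurrence on worked cases", {
  R <- lcs_table("A", "A")
  expect_equal(R[2, 2], 1L)
  expect_true(all(lcs_table("", "ACGT") == 0L))
  R <- lcs_table("AGCAT", "GAC")
  expect_equal(dim(R), c(6L, 4L))
  expect_equal(R[6, 4], 2L) # frozen: brute-force enumeration gives 2
  expect_true(all(R[1, ] == 0L) && all(R[, 1] == 0L))
})

test_that("lcs_table satisfies the score-table invariants on random pairs", {
  set.seed(101)
  for (i in 1:30) {
    p <- random_pair(25L)
    R <- lcs_table(p$A, p$B)
    m <- nchar(p$A); n <- nchar(p$B)
    # stepwise monotone in both directions, steps of at most 1
    if (n > 0) {
      dcol <- R[, -1, drop = FALSE] - R[, -(n + 1), drop = FALSE]
      expect_true(all(dcol %in% 0:1))
    }
    if (m > 0) {
      drow <- R[-1, , drop = FALSE] - R[-(m + 1), , drop = FALSE]
      expect_true(all(drow %in% 0:1))
    }
    expect_true(all(R <= outer(0:m, 0:n, pmin)))
    expect_equal(R[m + 1, n + 1], lcs_length(p$A, p$B))
  }
})

test_that("lcs_length equals the brute-force oracle and obeys edge cases", {
  expect_equal(lcs_length("ACGT", "ACGT"), 4L)
  expect_equal(lcs_length("AGCAT", "GAC"), 2L)
  expect_equal(lcs_length("AAAA", ""), 0L)
  set.seed(7)
  for (i in 1:60) {
    chars <- strsplit(alphabet_pool(sample(c(1L, 2L, 4L, 8L), 1)), "")[[1]]
    A <- rand_string(sample(0:12, 1), chars)
    B <- rand_string(sample(0:20, 1), chars)
    expect_equal(lcs_length(A, B), brute_force_lcs(A, B),
                 info = sprintf("A=%s B=%s", A, B))
  }
})

test_that("brute_force_lcs handles edges and enforces its size cap", {
  expect_equal(brute_force_lcs("AGCAT", "GAC"), 2L)
  expect_equal(brute_force_lcs("AB", "BA"), 1L)
  expect_equal(brute_force_lcs("", "X"), 0L)
  expect_error(brute_force_lcs(strrep("A", 16), strrep("A", 20)),
               class = "rowlcs_size_error")
})

test_that("lcs_traceback returns a maximal common subsequence, deterministically", {
  expect_equal(lcs_traceback(lcs_table("ACGT", "AGT"), "ACGT", "AGT"), "AGT")
  expect_equal(lcs_traceback(lcs_table("", ""), "", ""), "")
  expect_equal(lcs_traceback(lcs_table("AC", "GT"), "AC", "GT"), "")
  expect_error(lcs_traceback(lcs_table("AC", "GT"), "ACGT", "GT"),
               class = "rowlcs_contract_error")
  set.seed(13)
  for (i in 1:40) {
    p <- random_pair(18L)
    R <- lcs_table(p$A, p$B)
    s <- lcs_traceback(R, p$A, p$B)
    expect_true(is_subseq_chr(s, p$A))
    expect_true(is_subseq_chr(s, p$B))
    expect_equal(nchar(s), R[nchar(p$A) + 1, nchar(p$B) + 1])
    expect_identical(s, lcs_traceback(R, p$A, p$B)) # deterministic tie rule
  }
})

test_that("metamorphic laws: symmetry, identity, bounds, suffix, concatenation", {
  set.seed(23)
  for (i in 1:60) {
    p <- random_pair(24L)
    l <- lcs_length(p$A, p$B)
    expect_equal(l, lcs_length(p$B, p$A))
    expect_gte(l, 0L)
    expect_lte(l, min(nchar(p$A), nchar(p$B)))
    expect_equal(lcs_length(p$A, p$A), nchar(p$A))
    S <- rand_string(sample(0:8, 1))
    expect_equal(lcs_length(paste0(p$A, S), paste0(p$B, S)), l + nchar(S))
    q <- random_pair(24L)
    expect_gte(lcs_length(paste0(p$A, q$A), paste0(p$B, q$B)),
               l + lcs_length(q$A, q$B))
  }
})
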