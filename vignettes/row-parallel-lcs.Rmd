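---
title: "Row-parallel computation of the longest common subsequence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Row-parallel computation of the longest common subsequence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rowlcs)
```

## The problem

A *subsequence* of a string is obtained by deleting zero or more characters
without reordering; unlike a substring it need not be contiguous. The
*longest common subsequence* (LCS) of two strings `A[1..m]` and `B[1..n]` is
a maximum-length string that is a subsequence of both. In comparative
genomics the LCS length is a simple, gap-tolerant similarity measure between
two DNA sequences, and the quadratic dynamic program that computes it is a
model problem for parallelising dependency-laden table computations.

## The classical recurrence and why it resists parallelism

The textbook dynamic program fills an `(m+1) x (n+1)` score table `R` where
`R[i,j]` is the LCS length of the prefixes `A[1..i]` and `B[1..j]`:

* `R[i,j] = 0` when `i = 0` or `j = 0`;
* `R[i,j] = R[i-1,j-1] + 1` when `A[i] = B[j]`;
* `R[i,j] = max(R[i-1,j], R[i,j-1])` otherwise.

The answer is `R[m,n]`. The `R[i,j-1]` term chains every cell of a row to
its left neighbour, so a row cannot be computed concurrently as written.
`lcs_table()` implements this recurrence exactly (it is the package's
reference implementation and the ground truth for all tests);
`lcs_length()` is the same recurrence with only two rows of storage.

## Removing the within-row dependency: the occurrence table

The within-row coupling exists only to propagate the position of the most
recent match. That information can be precomputed. Define, for each
character `C[c]` of the joint alphabet `C` (the deduplicated, code-sorted
union of the characters of `A` and `B`),

```
occ(c, j) = the largest position p in 1..j with B[p] = C[c], or 0 if none.
```

Each row of this *occurrence table* P depends only on `B` and one
character, so all `|C|` rows are mutually independent and are themselves
computed under the work-sharing policy. With `p = occ(rank(A[i]), j)` the
score row becomes, for `j = 1..n`:

```
R[i,j] = R[i-1,j]                              if p = 0
R[i,j] = max(R[i-1,j], R[i-1,p-1] + 1)         otherwise
```

Every element of row `i` now depends only on row `i-1` and on P — the cells
of a row can be computed in any order or concurrently, and only two score
rows plus the `|C| x (n+1)` table P (for DNA, `|C| <= ~5`, i.e. O(n)
memory) need to be held.

## The two kernel versions

The package implements two historically distinct forms of this kernel:

* **Version 1** (`row_update_v1()`, three data branches): tests the direct
  character match `A[i] == B[j]` first (diagonal + 1), then distinguishes
  "an occurrence exists at or before j" from "none". Its P variant
  (`v1_offset`) stores `occ - 1`, the table index actually dereferenced.
* **Version 2** (`row_update_v2()`, two data branches, "branch-reduced"):
  never compares sequence characters; it consumes only the alphabet rank of
  `A[i]` and the direct-stored table (`v2_direct`, storing `occ` itself)
  and folds the match case into the general `max`. This is the form that
  favours architectures with expensive branching; on CPUs with good branch
  prediction version 1 tends to run faster despite the extra branch, which
  is why the benchmark harness keeps both.

Both kernels produce, row by row, exactly the classical table; the test
suite asserts this per-row ("row oracle") and end-to-end on hundreds of
seeded instances, including agreement with an exhaustive brute-force
enumeration (`brute_force_lcs()`) whenever the shorter input has at most
12-15 characters.

### Index conventions and the -1 sentinel

All contracts are stated 1-based with a sentinel row/column 0, and
`occ(c, j)` is "last occurrence *at or before* j". This is the one
resolution under which the two-branch kernel reproduces the classical
table, which the oracle tests enforce. The `v1_offset` variant needs `-1`
(not 0) as its "no occurrence" sentinel because under 1-based indexing the
stored value 0 would be ambiguous with a genuine occurrence at position 1.

## Execution policies

`execution_policy(workers, schedule, chunk)` describes how the `n`
elements of a row (and the `|C|` rows of P) are shared among workers:

* `workers` — positive integer; the default is the number of available
  processors capped at 16, the empirically tuned optimum for this kernel
  family on shared-memory CPUs.
* `schedule` — `static` (fixed chunks assigned round-robin up front),
  `dynamic` (fixed chunks claimed by the next free worker) or `guided`
  (chunks shrink proportionally to the remaining work). Default `static`.
* `chunk` — iterations per assignment; `"auto"` (default) means an even
  split of `ceiling(n / workers)` for static and the implementation default
  otherwise.

Crucially, the policy is a *contract about order-independence*, not about
the result: `lcs_length_rowwise()` is a pure function of `(A, B)` and the
acceptance suite quantifies this over 36 policy combinations. The compiled
kernels use OpenMP work-sharing loops when the toolchain provides OpenMP
(`has_openmp()`), and fall back to an equivalent sequential loop otherwise
— a conformant executor, since per-element results never depend on
evaluation order. `partition()` exposes the chunking arithmetic itself as
an inspectable, tested object.

## The synthetic generator: what it emulates and what it does not

`generate_dna()` emulates the simulated inputs of the experiments this
package models: uniformly random sequences over `ACGT` at lengths from 128
to 32,768 bases. The RNG is pinned explicitly (Mersenne-Twister, rejection
sampling, inversion) so a `(length, seed, alphabet)` triple reproduces
byte-identical output across platforms, and the caller's RNG state is left
untouched. Uniform composition is an assumption: real genomes have GC
bias, repeats and long-range structure that the generator deliberately does
not model, so a green test establishes algorithmic correctness and scaling
behaviour on unstructured input, not biological realism. Real sequences
enter through `read_fasta()` instead (non-ACGT characters such as `N` are
retained under the default permissive sanitization, since the algorithms
are alphabet-agnostic; `strict` rejects them).

`generate_planted_pair()` additionally embeds one random string of length
`plant_length` as a (generally non-contiguous) subsequence of both outputs:
plant positions are a sorted sample without replacement, every other
position is filled uniformly. The plant is therefore provably a common
subsequence, giving each fixture a known lower bound `LCS(A,B) >=
plant_length` that tests can assert without trusting the implementation
under test.

## The benchmark harness

`run_benchmark()` times each `(algorithm, policy)` pair on one sequence
pair; the timed region is alphabet construction + P construction + the
score loop, excluding file I/O, because P construction is an intrinsic part
of both row-wise algorithms. The aggregate statistic is the minimum over
repeats (least scheduling noise), with the mean also reported.
`compute_speedups()` derives the two standard ratios: *relative* speedup
(same algorithm at one worker ÷ this record) and *absolute* speedup (best
sequential algorithm ÷ this record); a missing baseline yields `NA`.
Wall-clock numbers are machine-dependent by nature — the harness reproduces
the *design* of tuning and comparison experiments (which configurations are
pitted against each other), and its tests assert structure and
cross-algorithm agreement of the computed lengths, never absolute times.

## Numerical and design choices

* **Alphabet order**: `build_alphabet()` sorts symbols by character code.
  Any fixed order would do; sorting makes P tables reproducible.
* **Traceback tie rule** (`lcs_traceback()`): prefer the diagonal move on a
  match, else up, else left — one deterministic witness among the possibly
  many optimal subsequences.
* **Timing floor**: sub-resolution timings are clamped to 1 ns so the
  "all wall times positive" invariant holds for microsecond-scale runs.
* **Empty sequences** are legal everywhere and give LCS 0.
* **Brute-force cap**: `brute_force_lcs()` refuses shorter-string lengths
  above 15 (2^15 subsequences); it enumerates in decreasing-length order
  and stops at the first hit.
* **Degenerate policies**: `partition(0, ...)` is an empty cover; guided
  partitions respect the configured chunk as a floor except for the final
  remainder chunk.

## Known limitations

* Length only by default: the memory-light kernels do not keep enough state
  to reconstruct a witness subsequence; `lcs_traceback()` requires the full
  `lcs_table()`, i.e. O(mn) memory, and is intended for short inputs.
* No distributed-memory (message-passing) driver: for this algorithm the
  per-row scatter/gather synchronisation costs are known to dominate, so
  only the shared-memory work-sharing model is provided.
* No bit-parallel or anti-diagonal LCS algorithms, multi-sequence LCS, or
  IUPAC ambiguity expansion.
* Speedups from `workers > 1` depend on the host toolchain providing
  OpenMP and on actual core availability; correctness does not.

## A worked example

```{r example}
a <- generate_dna(2048, seed = 1)
b <- generate_dna(2048, seed = 2)
lcs_length(a$residues, b$residues)
lcs_length_rowwise(a$residues, b$residues, "v2",
                   execution_policy(4, "static", "auto"))
```

Both calls print the same length, as they must for every policy; at this
length a uniform random DNA pair has an LCS close to 0.65 of its length,
the expected density for a four-letter alphabet.
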