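// Dynamic-programming kernels for LCS length computation.
//
// Conventions (all 1-based on the sequence side, matching the R API):
//   R[i,j]   = LCS length of prefixes A[1..i], B[1..j]; sentinel row/col 0.
//   occ(c,j) = largest p in [1..j] with B[p] == C[c], or 0 if none.
//   P tables: v2_direct stores occ(c,j); v1_offset stores occ(c,j) - 1 with
//             -1 as the "no occurrence" sentinel (0 would be ambiguous with
//             an occurrence at position 1 under 1-based indexing).
//
// The row kernels are written so that every output element j depends only on
// the previous row, the P table and the current character rank: elements of a
// row may be computed in any order or concurrently, which is what the OpenMP
// work-sharing pragmas below exploit. Without OpenMP the pragmas are inert
// and the kernels run sequentially with identical results.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <algorithm>
#ifdef _OPENMP
#include <omp.h>
#endif

using namespace Rcpp;

// schedule codes shared with the R wrappers: 1 static, 2 dynamic, 3 guided
static void set_omp_policy(int workers, int schedule, int chunk) {
#ifdef _OPENMP
  omp_set_num_threads(workers > 0 ? workers : 1);
  omp_sched_t kind = omp_sched_static;
  if (schedule == 2) kind = omp_sched_dynamic;
  else if (schedule == 3) kind = omp_sched_guided;
  // chunk <= 0 means "auto": the implementation default (for static this is
  // an even split of ceiling(n/workers), matching the partition() contract)
  omp_set_schedule(kind, chunk > 0 ? chunk : 0);
#else
  (void)workers; (void)schedule; (void)chunk;
#endif
}

// [[Rcpp::export]]
IntegerMatrix cpp_lcs_table(const std::string& A, const std::string& B) {
  const int m = (int)A.size(), n = (int)B.size();
  IntegerMatrix R(m + 1, n + 1); // zero-initialised: base cases i=0 or j=0
  for (int i = 1; i <= m; ++i) {
    const char a = A[i - 1];
    for (int j = 1; j <= n; ++j) {
      if (a == B[j - 1])
        R(i, j) = R(i - 1, j - 1) + 1;
      else
        R(i, j) = std::max(R(i - 1, j), R(i, j - 1));
    }
  }
  return R;
}

// [[Rcpp::export]]
int cpp_lcs_length_classic(const std::string& A, const std::string& B) {
  const int m = (int)A.size(), n = (int)B.size();
  if (m == 0 || n == 0) return 0;
  std::vector<int> prev(n + 1, 0), cur(n + 1, 0);
  for (int i = 1; i <= m; ++i) {
    const char a = A[i - 1];
    cur[0] = 0;
    for (int j = 1; j <= n; ++j) {
      if (a == B[j - 1])
        cur[j] = prev[j - 1] + 1;
      else
        cur[j] = std::max(prev[j], cur[j - 1]);
    }
    std::swap(prev, cur);
  }
  return prev[n];
}

// last-occurrence table over |C| rows and n+1 columns; rows are mutually
// independent so the outer loop is work-shared
// [[Rcpp::export]]
IntegerMatrix cpp_occurrence_table(const std::string& B,
                                   const std::string& symbols,
                                   bool offset,
                                   int workers, int schedule, int chunk) {
  const int n = (int)B.size(), k = (int)symbols.size();
  IntegerMatrix P(k, n + 1);
  int* p = INTEGER(P);
  set_omp_policy(workers, schedule, chunk);
#ifdef _OPENMP
#pragma omp parallel for schedule(runtime)
#endif
  for (int c = 0; c < k; ++c) {
    const char ch = symbols[c];
    int last = offset ? -1 : 0;
    p[c] = last; // column j = 0
    for (int j = 1; j <= n; ++j) {
      if (B[j - 1] == ch) last = offset ? j - 1 : j;
      p[(size_t)j * k + c] = last;
    }
  }
  return P;
}

// Version 1 row kernel: three data branches, with an explicit character match
// test against B[j]. prow is the v1_offset P row for the rank of A[i].
// [[Rcpp::export]]
IntegerVector cpp_row_update_v1(const IntegerVector& prev,
                                const std::string& ai,
                                const std::string& B,
                                const IntegerVector& prow) {
  const int n = (int)B.size();
  if ((int)prev.size() != n + 1 || (int)prow.size() != n + 1)
    stop("row length mismatch: expected n + 1 = %d elements", n + 1);
  const char a = ai.empty() ? '\0' : ai[0];
  IntegerVector out(n + 1);
  const int* pv = INTEGER(prev);
  const int* pr = INTEGER(prow);
  int* po = INTEGER(out);
  po[0] = 0;
  for (int j = 1; j <= n; ++j) {
    if (a == B[j - 1])
      po[j] = pv[j - 1] + 1;          // match: diagonal + 1
    else if (pr[j] == -1)
      po[j] = pv[j];                  // no occurrence at or before j
    else
      po[j] = std::max(pv[j], pv[pr[j]] + 1); // prev[occ - 1] + 1
  }
  return out;
}

// Version 2 row kernel: two data branches, driven purely by the v2_direct
// P row (no character comparison).
// [[Rcpp::export]]
IntegerVector cpp_row_update_v2(const IntegerVector& prev,
                                const IntegerVector& prow) {
  const int n = (int)prow.size() - 1;
  if ((int)prev.size() != n + 1)
    stop("row length mismatch: expected n + 1 = %d elements", n + 1);
  IntegerVector out(n + 1);
  const int* pv = INTEGER(prev);
  const int* pr = INTEGER(prow);
  int* po = INTEGER(out);
  po[0] = 0;
  for (int j = 1; j <= n; ++j) {
    const int p = pr[j];
    po[j] = (p == 0) ? pv[j] : std::max(pv[j], pv[p - 1] + 1);
  }
  return out;
}

// Two-row driver over the row-wise-independent kernels. version: 1 or 2.
// Peak working storage: two score rows plus the |C| x (n+1) P table.
// [[Rcpp::export]]
int cpp_lcs_length_rowwise(const std::string& A, const std::string& B,
                           const std::string& symbols, int version,
                           int workers, int schedule, int chunk) {
  const int m = (int)A.size(), n = (int)B.size();
  if (m == 0 || n == 0) return 0;
  const int k = (int)symbols.size();

  std::array<int, 256> rank;
  rank.fill(-1);
  for (int c = 0; c < k; ++c) rank[(unsigned char)symbols[c]] = c;
  for (int i = 0; i < m; ++i)
    if (rank[(unsigned char)A[i]] < 0)
      stop("character '%c' of A has no rank in the alphabet", A[i]);
  for (int j = 0; j < n; ++j)
    if (rank[(unsigned char)B[j]] < 0)
      stop("character '%c' of B has no rank in the alphabet", B[j]);

  const bool offset = (version == 1);
  set_omp_policy(workers, schedule, chunk);

  // P table, row-parallel (each row independent)
  std::vector<int> P((size_t)k * (n + 1));
#ifdef _OPENMP
#pragma omp parallel for schedule(runtime)
#endif
  for (int c = 0; c < k; ++c) {
    const char ch = symbols[c];
    int* row = &P[(size_t)c * (n + 1)];
    int last = offset ? -1 : 0;
    row[0] = last;
    for (int j = 1; j <= n; ++j) {
      if (B[j - 1] == ch) last = offset ? j - 1 : j;
      row[j] = last;
    }
  }

  std::vector<int> prev(n + 1, 0), cur(n + 1, 0);
  for (int i = 1; i <= m; ++i) {
    const int c = rank[(unsigned char)A[i - 1]];
    const int* prow = &P[(size_t)c * (n + 1)];
    const char a = A[i - 1];
    int* pc = cur.data();
    const int* pv = prev.data();
    pc[0] = 0;
    if (version == 1) {
#ifdef _OPENMP
#pragma omp parallel for schedule(runtime)
#endif
      for (int j = 1; j <= n; ++j) {
        if (a == B[j - 1])
          pc[j] = pv[j - 1] + 1;
        else if (prow[j] == -1)
          pc[j] = pv[j];
        else
          pc[j] = std::max(pv[j], pv[prow[j]] + 1);
      }
    } else {
#ifdef _OPENMP
#pragma omp parallel for schedule(runtime)
#endif
      for (int j = 1; j <= n; ++j) {
        const int p = prow[j];
        pc[j] = (p == 0) ? pv[j] : std::max(pv[j], pv[p - 1] + 1);
      }
    }
    std::swap(prev, cur);
  }
  return prev[n];
}

// [[Rcpp::export]]
bool cpp_has_openmp() {
#ifdef _OPENMP
  return true;
#else
  return false;
#endif
}
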