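#include <Rcpp.h>
#include <string>
#include <vector>
#include <cstring>
using namespace Rcpp;

// 3' adapter occurrence search with cutadapt-style semantics.
//
// An occurrence of the adapter A (length m) in read T (length n) is a pair
// (s, j): the alignment starts after s read bases and covers the adapter
// prefix A[0..j). Either j == m (the full adapter occurs internally; the
// aligned read segment may end anywhere) or the aligned segment ends at the
// read's 3' end (a truncated adapter running off the read). The error count
// e(s, j) is the unit-cost edit distance (substitutions and indels) between
// A[0..j) and the aligned read segment, minimized over segment lengths where
// these are free. An occurrence qualifies when e <= max_error_rate * j and
// j >= min_overlap. Among qualifying occurrences the longest adapter match j
// wins, ties broken by the leftmost start s. The read is trimmed to its
// first s bases.
//
// Full-adapter starts are found for all s in one O(n*m) pass by running a
// free-start semi-global DP on the reversed strings: with A' = rev(A),
// T' = rev(T), the best-fit distance of A over segments of T starting at
// position s equals D'[m][n - s], where D'[j][i] is the minimum edit
// distance of A'[0..j) against any suffix of T'[0..i).

static inline double full_occurrence_cost(const char* a, int m,
                                          const char* t, int n,
                                          std::vector<int>& prev,
                                          std::vector<int>& curr,
                                          std::vector<int>& out_cost) {
  // out_cost[s] = min over t of edit(A, T[s..s+t)) for s in [0, n)
  // computed on reversed strings; returns nothing of interest directly.
  for (int i = 0; i <= n; ++i) prev[i] = 0;  // row j = 0: free start
  for (int j = 1; j <= m; ++j) {
    char aj = a[m - j];  // reversed adapter
    curr[0] = j;
    for (int i = 1; i <= n; ++i) {
      char ti = t[n - i];  // reversed read
      int diag = prev[i - 1] + (aj == ti ? 0 : 1);
      int up = prev[i] + 1;
      int left = curr[i - 1] + 1;
      int c = diag < up ? diag : up;
      if (left < c) c = left;
      curr[i] = c;
    }
    std::swap(prev, curr);
  }
  // prev now holds D'[m][i]; D'[m][n - s] = cost of best full occurrence at s
  for (int s = 0; s < n; ++s) out_cost[s] = prev[n - s];
  return 0.0;
}

// Edit distance between A[0..j) and T[s..n) (both segments fixed).
static inline int segment_edit(const char* a, int j, const char* t, int len,
                               std::vector<int>& prev, std::vector<int>& curr) {
  for (int i = 0; i <= len; ++i) prev[i] = i;
  for (int r = 1; r <= j; ++r) {
    curr[0] = r;
    for (int i = 1; i <= len; ++i) {
      int diag = prev[i - 1] + (a[r - 1] == t[i - 1] ? 0 : 1);
      int up = prev[i] + 1;
      int left = curr[i - 1] + 1;
      int c = diag < up ? diag : up;
      if (left < c) c = left;
      curr[i] = c;
    }
    std::swap(prev, curr);
  }
  return prev[len];
}

// For each read, the number of 5' bases kept after trimming, or -1 when no
// qualifying adapter occurrence exists (read kept untrimmed).
// [[Rcpp::export]]
IntegerVector trim_positions_cpp(CharacterVector reads, std::string adapter,
                                 double max_error_rate, int min_overlap) {
  int m = (int) adapter.size();
  const char* a = adapter.c_str();
  int nr = reads.size();
  IntegerVector res(nr);
  std::vector<int> prev, curr, full_cost, endcost;

  for (int r = 0; r < nr; ++r) {
    const char* t = CHAR(STRING_ELT(reads, r));
    int n = (int) std::strlen(t);
    if ((int) prev.size() < n + 1) {
      prev.resize(n + 1);
      curr.resize(n + 1);
    }
    if ((int) full_cost.size() < n) full_cost.resize(n);

    int best = -1;
    // Full-adapter occurrences (j = m): leftmost qualifying start.
    if (m >= min_overlap && n >= 1) {
      full_occurrence_cost(a, m, t, n, prev, curr, full_cost);
      for (int s = 0; s < n; ++s) {
        if ((double) full_cost[s] <= max_error_rate * (double) m) {
          best = s;
          break;
        }
      }
    }
    // Truncated 3'-end occurrences, longest j first. One forward
    // free-start DP gives, for every adapter prefix length j, the minimum
    // error count over all starts of aligning A[0..j) to a read suffix
    // ending at the 3' end; a prefix length qualifies iff that minimum
    // does. The leftmost qualifying start for the winning j is then found
    // among the few starts compatible with the error budget (each indel
    // costs one error, so |segment length - j| <= e_max).
    if (best < 0 && m - 1 >= min_overlap) {
      if ((int) endcost.size() < m + 1) endcost.resize(m + 1);
      for (int i = 0; i <= n; ++i) prev[i] = 0;
      endcost[0] = 0;
      for (int j = 1; j <= m; ++j) {
        char aj = a[j - 1];
        curr[0] = j;
        for (int i = 1; i <= n; ++i) {
          int diag = prev[i - 1] + (aj == t[i - 1] ? 0 : 1);
          int up = prev[i] + 1;
          int left = curr[i - 1] + 1;
          int c = diag < up ? diag : up;
          if (left < c) c = left;
          curr[i] = c;
        }
        endcost[j] = curr[n];
        std::swap(prev, curr);
      }
      for (int j = m - 1; j >= min_overlap && best < 0; --j) {
        if ((double) endcost[j] > max_error_rate * (double) j) continue;
        int emax = (int) (max_error_rate * (double) j + 1e-9);
        int s_lo = n - j - emax, s_hi = n - j + emax;
        if (s_lo < 0) s_lo = 0;
        if (s_hi > n - 1) s_hi = n - 1;
        for (int s = s_lo; s <= s_hi; ++s) {
          int e = segment_edit(a, j, t + s, n - s, prev, curr);
          if ((double) e <= max_error_rate * (double) j) {
            best = s;
            break;  // smallest s for this j
          }
        }
      }
    }
    res[r] = best;
  }
  return res;
}
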