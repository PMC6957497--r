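#include <Rcpp.h>
using namespace Rcpp;

// Mendelian consistency of diploid ancestry dosages in a pedigree.
//
// A dosage configuration is consistent iff there is an assignment of ordered
// ancestry-allele pairs (paternal, maternal) to every individual such that
// each pair sums to the individual's dosage and every non-founder receives
// one allele carried by its father and one carried by its mother.  Decided by
// depth-first genotype elimination over individuals listed parents-first;
// with two allele states the search space per individual is at most 4 ordered
// pairs, so the DFS with transmission pruning is fast even for n = 20.

static bool dfs_assign(int i, int n, const int *dos,
                       const int *father, const int *mother,
                       int *a1, int *a2) {
  if (i == n) return true;
  int d = dos[i];
  int cand[4][2];
  int nc = 0;
  if (d == NA_INTEGER) {
    cand[0][0] = 0; cand[0][1] = 0;
    cand[1][0] = 0; cand[1][1] = 1;
    cand[2][0] = 1; cand[2][1] = 0;
    cand[3][0] = 1; cand[3][1] = 1;
    nc = 4;
  } else if (d == 0) {
    cand[0][0] = 0; cand[0][1] = 0; nc = 1;
  } else if (d == 2) {
    cand[0][0] = 1; cand[0][1] = 1; nc = 1;
  } else {
    cand[0][0] = 0; cand[0][1] = 1;
    cand[1][0] = 1; cand[1][1] = 0;
    nc = 2;
  }
  for (int c = 0; c < nc; ++c) {
    int p = cand[c][0], q = cand[c][1];
    if (father[i] > 0) {
      int f = father[i] - 1;
      if (p != a1[f] && p != a2[f]) continue;
    }
    if (mother[i] > 0) {
      int m = mother[i] - 1;
      if (q != a1[m] && q != a2[m]) continue;
    }
    a1[i] = p; a2[i] = q;
    if (dfs_assign(i + 1, n, dos, father, mother, a1, a2)) return true;
  }
  return false;
}

// dos: n x L integer matrix (individuals in rows, parents before children);
// father, mother: 1-based row index of each parent, 0 if absent.
// Returns one logical per column.
// [[Rcpp::export(name = ".consistent_loci_cpp")]]
LogicalVector consistent_loci_cpp(IntegerMatrix dos,
                                  IntegerVector father,
                                  IntegerVector mother) {
  int n = dos.nrow(), L = dos.ncol();
  if (father.size() != n || mother.size() != n)
    stop("parent index length must equal the number of individuals");
  for (int i = 0; i < n; ++i) {
    if (father[i] < 0 || father[i] > n || mother[i] < 0 || mother[i] > n)
      stop("parent index out of range");
    if (father[i] > i || mother[i] > i)
      stop("individuals must be ordered parents-first");
  }
  LogicalVector out(L);
  std::vector<int> col(n), a1(n), a2(n);
  for (int t = 0; t < L; ++t) {
    for (int i = 0; i < n; ++i) {
      int v = dos(i, t);
      if (v != NA_INTEGER && (v < 0 || v > 2))
        stop("dosage out of {0,1,2} at row %d, column %d", i + 1, t + 1);
      col[i] = v;
    }
    out[t] = dfs_assign(0, n, col.data(), &father[0], &mother[0],
                        a1.data(), a2.data());
  }
  return out;
}
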