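// Core extension and filtering routines.
//
// Sequences arrive as integer code vectors: 1..S for in-alphabet symbols,
// 0 for the sentinel (ambiguity codes etc.).  The sentinel never matches
// anything, including itself, so N-runs always burn mismatch budget.
// All positions at this interface are 1-based, matching the R wrappers.

#include <Rcpp.h>
#include <vector>
#include <algorithm>

using namespace Rcpp;

static inline bool sym_eq(int a, int b) { return a == b && a != 0; }

// Longest exact common extension of x[i..] vs y[j..]; i in [1, n+1].
static int lcp0_raw(const int* x, int n, int i, const int* y, int m, int j) {
    int cap = std::min(n - i + 1, m - j + 1);
    const int* xp = x + (i - 1);
    const int* yp = y + (j - 1);
    int l = 0;
    while (l < cap && sym_eq(xp[l], yp[l])) ++l;
    return l;
}

// As lcp0_raw but indices beyond one-past-end contribute 0 (used where the
// carry/verify formulas reference positions past a sequence end).
static inline int lcp0_clamped(const int* x, int n, int i,
                               const int* y, int m, int j) {
    if (i > n || j > m) return 0;
    return lcp0_raw(x, n, i, y, m, j);
}

// Longest common extension with at most k mismatches (k+1 jump-extensions,
// fused into a single scan: each mismatch consumes one unit of budget).
static int lcpk_raw(const int* x, int n, int i, const int* y, int m, int j,
                    int k) {
    int cap = std::min(n - i + 1, m - j + 1);
    const int* xp = x + (i - 1);
    const int* yp = y + (j - 1);
    int l = 0, mis = 0;
    while (l < cap) {
        if (!sym_eq(xp[l], yp[l])) {
            if (mis == k) break;
            ++mis;
        }
        ++l;
    }
    return l;
}

static void full_sweep_raw(const int* x, int n, int i, const int* y, int m,
                           int k, int& best, std::vector<int>& ties) {
    best = 0;
    ties.clear();
    for (int j = 1; j <= m; ++j) {
        int l = lcpk_raw(x, n, i, y, m, j, k);
        if (l > best) {
            best = l;
            ties.clear();
            ties.push_back(j);
        } else if (l == best) {
            ties.push_back(j);
        }
    }
}

// Per-symbol occurrence lists over y (symbol code -> sorted positions),
// the compiled counterpart of the per-symbol bit masks.
static void build_pos_lists(const int* y, int m, int nsym,
                            std::vector<std::vector<int> >& pos) {
    pos.assign(nsym + 1, std::vector<int>());
    for (int r = 1; r <= m; ++r)
        if (y[r - 1] >= 1 && y[r - 1] <= nsym) pos[y[r - 1]].push_back(r);
}

struct StepCounters {
    double pairs_examined;   // pairs on which a jump-extension / lcp_k ran
    double accepted;         // verifications accepted (new best or tie)
    StepCounters() : pairs_examined(0.0), accepted(0.0) {}
};

// One step of the filtered algorithm: from (i, L, ties) for suffix i,
// compute (L', ties') for suffix i+1.  `exact` enables the L-1
// tie-completion pass; `segment_filter` enables the optional whole-segment
// pre-filter (must not change results).
//
// Exactness requires one departure from the pure carry/shift scheme: the
// shift r -> r+1 can never propose y-position 1, whose extension is
// unconstrained by step i, so pair (i+1, 1) is always evaluated directly.
static void step_raw(const int* x, int n, const int* y, int m, int k,
                     int i, int L, const std::vector<int>& ties,
                     bool exact, bool segment_filter,
                     const std::vector<std::vector<int> >& pos_lists,
                     int nsym,
                     int& L_out, std::vector<int>& ties_out,
                     std::vector<char>& carried, std::vector<char>& intie,
                     StepCounters& st) {
    // ---- carry-over from step-i ties ----
    int Lmax = -1;
    ties_out.clear();
    bool any = false;
    std::fill(carried.begin(), carried.end(), 0);
    std::fill(intie.begin(), intie.end(), 0);

    for (size_t t = 0; t < ties.size(); ++t) {
        int j = ties[t];
        if (j + 1 > m) continue;
        any = true;
        carried[j + 1] = 1;
        int c;
        bool end_hit = (i + L - 1 == n) || (j + L - 1 == m);
        if (end_hit) {
            // the (k+1)-th mismatch the carry formulas presuppose does not
            // exist: recompute directly
            c = lcpk_raw(x, n, i + 1, y, m, j + 1, k);
            st.pairs_examined += 1;
        } else if (sym_eq(x[i - 1], y[j - 1])) {
            c = L - 1;                               // Case 1
        } else {
            c = L + lcp0_raw(x, n, i + L + 1, y, m, j + L + 1);  // Case 2
            st.pairs_examined += 1;
        }
        if (c > Lmax) {
            Lmax = c;
            ties_out.clear();
            ties_out.push_back(j + 1);
        } else if (c == Lmax) {
            ties_out.push_back(j + 1);
        }
    }

    if (!any) {
        // degenerate carry (all step-i ties at j == m): full re-sweep
        full_sweep_raw(x, n, i + 1, y, m, k, L_out, ties_out);
        st.pairs_examined += m;
        return;
    }
    for (size_t t = 0; t < ties_out.size(); ++t) intie[ties_out[t]] = 1;

    // ---- direct check of y-position 1 (never reachable by the shift) ----
    {
        int v1 = lcpk_raw(x, n, i + 1, y, m, 1, k);
        st.pairs_examined += 1;
        if (v1 > Lmax) {
            for (size_t t = 0; t < ties_out.size(); ++t) intie[ties_out[t]] = 0;
            Lmax = v1;
            ties_out.clear();
            ties_out.push_back(1);
            intie[1] = 1;
        } else if (v1 == Lmax) {
            ties_out.push_back(1);
            intie[1] = 1;
        }
    }

    // ---- filtered candidate scan ----
    // filter (a): y_r must NOT match x_i; filter (b): y_{r+L} must match
    // x_{i+L} (anchor fixed from the step-i L even as Lmax grows).
    int xi = x[i - 1];
    bool have_anchor = (i + L <= n);

    // candidate r values, ascending
    const std::vector<int>* anchor_pos = NULL;
    if (have_anchor) {
        int a = x[i + L - 1];
        if (a >= 1 && a <= nsym) anchor_pos = &pos_lists[a];
        // sentinel anchor: matches nothing -> empty candidate set
    }

    // iterate candidates
    int idx = 0;
    int n_candidates = have_anchor ? (anchor_pos ? (int)anchor_pos->size() : 0)
                                   : m;
    for (;;) {
        int r;
        if (have_anchor) {
            if (idx >= n_candidates) break;
            r = (*anchor_pos)[idx++] - L;   // y_{r+L} matches the anchor
            if (r < 1) continue;
        } else {
            if (++idx > m) break;           // no anchor: all r, filter (a) only
            r = idx;
        }
        if (r + 1 > m) continue;
        if (sym_eq(y[r - 1], xi)) continue;             // filter (a)
        if (carried[r + 1] || intie[r + 1]) continue;   // already processed

        if (segment_filter && Lmax > L) {
            // a match of length >= Lmax forces y[r+L..r+Lmax-1] to equal
            // x[i+L..i+Lmax-1] position-wise
            if (i + Lmax - 1 > n || r + Lmax - 1 > m) continue;
            bool ok = true;
            for (int off = L; off < Lmax; ++off)
                if (!sym_eq(x[i + off - 1], y[r + off - 1])) { ok = false; break; }
            if (!ok) continue;
        }

        int c = L + lcp0_clamped(x, n, i + L + 1, y, m, r + L + 1);
        if (c < Lmax) continue;             // cannot improve: no extension run
        int Ltrue = lcpk_raw(x, n, i + 1, y, m, r + 1, k);
        st.pairs_examined += 1;
        if (Ltrue != c) continue;           // hidden mismatch before offset L
        if (c > Lmax) {
            for (size_t t = 0; t < ties_out.size(); ++t) intie[ties_out[t]] = 0;
            Lmax = c;
            ties_out.clear();
            ties_out.push_back(r + 1);
            intie[r + 1] = 1;
        } else {
            ties_out.push_back(r + 1);
            intie[r + 1] = 1;
        }
        st.accepted += 1;
    }

    // ---- L-1 tie-completion pass (exact mode only) ----
    if (exact && Lmax == L - 1) {
        for (int r = 1; r + 1 <= m; ++r) {
            if (sym_eq(y[r - 1], xi)) continue;         // filter (a) is sound
            if (carried[r + 1] || intie[r + 1]) continue;
            int Ltrue = lcpk_raw(x, n, i + 1, y, m, r + 1, k);
            st.pairs_examined += 1;
            if (Ltrue == Lmax) {
                ties_out.push_back(r + 1);
                intie[r + 1] = 1;
            }
        }
    }

    std::sort(ties_out.begin(), ties_out.end());
    L_out = Lmax;
}

// ---------------------------------------------------------------- exports

static void check_pos(int i, int n, const char* what) {
    if (i < 1 || i > n + 1)
        stop("position %s = %d out of range [1, %d]", what, i, n + 1);
}

// [[Rcpp::export]]
int lcp0_cpp(IntegerVector x, int i, IntegerVector y, int j) {
    check_pos(i, x.size(), "i");
    check_pos(j, y.size(), "j");
    return lcp0_raw(x.begin(), x.size(), i, y.begin(), y.size(), j);
}

// [[Rcpp::export]]
int lcpk_cpp(IntegerVector x, int i, IntegerVector y, int j, int k) {
    if (k < 0) stop("mismatch budget k must be non-negative");
    check_pos(i, x.size(), "i");
    check_pos(j, y.size(), "j");
    return lcpk_raw(x.begin(), x.size(), i, y.begin(), y.size(), j, k);
}

// [[Rcpp::export]]
List full_sweep_cpp(IntegerVector x, int i, IntegerVector y, int k) {
    if (k < 0) stop("mismatch budget k must be non-negative");
    check_pos(i, x.size(), "i");
    int best;
    std::vector<int> ties;
    full_sweep_raw(x.begin(), x.size(), i, y.begin(), y.size(), k, best, ties);
    return List::create(_["best"] = best, _["ties"] = wrap(ties));
}

// [[Rcpp::export]]
List carry_over_cpp(IntegerVector x, IntegerVector y, int k, int i, int L,
                    IntegerVector ties) {
    int n = x.size(), m = y.size();
    const int* xp = x.begin();
    const int* yp = y.begin();
    int Lmax = -1;
    double pairs = 0;
    std::vector<int> out;
    bool any = false;
    for (int t = 0; t < ties.size(); ++t) {
        int j = ties[t];
        if (j + 1 > m) continue;
        any = true;
        int c;
        bool end_hit = (i + L - 1 == n) || (j + L - 1 == m);
        if (end_hit) {
            c = lcpk_raw(xp, n, i + 1, yp, m, j + 1, k);
            pairs += 1;
        } else if (sym_eq(xp[i - 1], yp[j - 1])) {
            c = L - 1;
        } else {
            c = L + lcp0_raw(xp, n, i + L + 1, yp, m, j + L + 1);
            pairs += 1;
        }
        if (c > Lmax) { Lmax = c; out.clear(); out.push_back(j + 1); }
        else if (c == Lmax) out.push_back(j + 1);
    }
    return List::create(_["ok"] = any, _["L_max"] = Lmax,
                        _["ties"] = wrap(out), _["pairs_examined"] = pairs);
}

// [[Rcpp::export]]
List step_cpp(IntegerVector x, IntegerVector y, int k, int i, int L,
              IntegerVector ties, bool exact, bool segment_filter, int nsym) {
    int n = x.size(), m = y.size();
    if (i + 1 > n) stop("step would move past the end of x");
    std::vector<std::vector<int> > pos_lists;
    build_pos_lists(y.begin(), m, nsym, pos_lists);
    std::vector<int> tv(ties.begin(), ties.end());
    std::vector<int> ties_out;
    std::vector<char> carried(m + 2, 0), intie(m + 2, 0);
    StepCounters st;
    int L_out;
    step_raw(x.begin(), n, y.begin(), m, k, i, L, tv, exact, segment_filter,
             pos_lists, nsym, L_out, ties_out, carried, intie, st);
    return List::create(_["i"] = i + 1, _["L"] = L_out,
                        _["ties"] = wrap(ties_out),
                        _["pairs_examined"] = st.pairs_examined,
                        _["accepted"] = st.accepted);
}

// [[Rcpp::export]]
List maxcor_cpp(IntegerVector x, IntegerVector y, int k, bool exact,
                bool segment_filter, int nsym) {
    int n = x.size(), m = y.size();
    if (n < 1 || m < 1) stop("sequences entering comparison must be non-empty");
    if (k < 0) stop("mismatch budget k must be non-negative");
    const int* xp = x.begin();
    const int* yp = y.begin();

    std::vector<std::vector<int> > pos_lists;
    build_pos_lists(yp, m, nsym, pos_lists);

    IntegerVector values(n), best_j(n);
    StepCounters st;

    int L;
    std::vector<int> ties;
    full_sweep_raw(xp, n, 1, yp, m, k, L, ties);
    st.pairs_examined += m;
    values[0] = L;
    best_j[0] = ties.empty() ? NA_INTEGER : ties.front();

    std::vector<int> ties_next;
    std::vector<char> carried(m + 2, 0), intie(m + 2, 0);
    for (int i = 1; i <= n - 1; ++i) {
        int L_out;
        step_raw(xp, n, yp, m, k, i, L, ties, exact, segment_filter,
                 pos_lists, nsym, L_out, ties_next, carried, intie, st);
        L = L_out;
        ties.swap(ties_next);
        values[i] = L;
        best_j[i] = ties.empty() ? NA_INTEGER : ties.front();
        if ((i & 1023) == 0) Rcpp::checkUserInterrupt();
    }

    return List::create(_["values"] = values, _["best_j"] = best_j,
                        _["pairs_examined"] = st.pairs_examined,
                        _["accepted"] = st.accepted);
}

// [[Rcpp::export]]
List naive_maxcor_cpp(IntegerVector x, IntegerVector y, int k) {
    int n = x.size(), m = y.size();
    if (n < 1 || m < 1) stop("sequences entering comparison must be non-empty");
    if (k < 0) stop("mismatch budget k must be non-negative");
    IntegerVector values(n), best_j(n);
    const int* xp = x.begin();
    const int* yp = y.begin();
    for (int i = 1; i <= n; ++i) {
        int best = 0, bj = 1;
        for (int j = 1; j <= m; ++j) {
            int l = lcpk_raw(xp, n, i, yp, m, j, k);
            if (l > best) { best = l; bj = j; }
        }
        values[i - 1] = best;
        best_j[i - 1] = bj;
        if ((i & 255) == 0) Rcpp::checkUserInterrupt();
    }
    return List::create(_["values"] = values, _["best_j"] = best_j);
}

// kmacs-style greedy: seed with the longest exact match, then extend the
// exact-match tie set with k mismatches.  A lower bound on the true value.
// [[Rcpp::export]]
List greedy_maxcor_cpp(IntegerVector x, IntegerVector y, int k) {
    int n = x.size(), m = y.size();
    if (n < 1 || m < 1) stop("sequences entering comparison must be non-empty");
    if (k < 0) stop("mismatch budget k must be non-negative");
    IntegerVector values(n), best_j(n);
    const int* xp = x.begin();
    const int* yp = y.begin();
    std::vector<int> Z;
    for (int i = 1; i <= n; ++i) {
        int l0 = -1;
        Z.clear();
        for (int j = 1; j <= m; ++j) {
            int l = lcp0_raw(xp, n, i, yp, m, j);
            if (l > l0) { l0 = l; Z.clear(); Z.push_back(j); }
            else if (l == l0) Z.push_back(j);
        }
        int best = 0, bj = Z.empty() ? NA_INTEGER : Z.front();
        for (size_t t = 0; t < Z.size(); ++t) {
            int l = lcpk_raw(xp, n, i, yp, m, Z[t], k);
            if (l > best) { best = l; bj = Z[t]; }
        }
        values[i - 1] = best;
        best_j[i - 1] = bj;
        if ((i & 255) == 0) Rcpp::checkUserInterrupt();
    }
    return List::create(_["values"] = values, _["best_j"] = best_j);
}
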