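#include <Rcpp.h>
using namespace Rcpp;

// Greedy left-to-right bout scan over a per-minute activity sequence.
// A candidate opens at the first unconsumed active minute s; inactive
// minutes are absorbed while the cumulative interruption count stays
// <= max_int; the candidate closes at the last active minute seen before
// the interruption budget would be exceeded (or end of sequence). The
// candidate is kept iff its span (end - start + 1) >= min_dur; a kept
// bout consumes its span and scanning resumes after it, otherwise the
// scan resumes at the next active minute after s.
static void greedy_scan(const std::vector<int>& a, int min_dur, int max_int,
                        std::vector<std::pair<int,int> >& bouts) {
    const int n = (int)a.size();
    int i = 0;
    while (i < n) {
        if (!a[i]) { ++i; continue; }
        int interruptions = 0, last_active = i, j = i + 1;
        while (j < n) {
            if (a[j]) { last_active = j; }
            else {
                if (interruptions + 1 > max_int) break;
                ++interruptions;
            }
            ++j;
        }
        // retreat: trailing absorbed interruptions are not part of the bout
        int span = last_active - i + 1;
        if (span >= min_dur) {
            bouts.push_back(std::make_pair(i, last_active));
            i = last_active + 1;
        } else {
            ++i; // next candidate start is the next active minute after i
        }
    }
}

// Independent reference: identical consumption semantics, but each
// candidate's end is found by explicit enumeration of feasible windows
// (active endpoints, interior inactive count <= max_int), taking the
// maximal feasible end, rather than by the single-pass counter.
static void oracle_scan(const std::vector<int>& a, int min_dur, int max_int,
                        std::vector<std::pair<int,int> >& bouts) {
    const int n = (int)a.size();
    int i = 0;
    while (i < n) {
        if (!a[i]) { ++i; continue; }
        int best_e = -1, inactive = 0;
        for (int e = i; e < n; ++e) {
            if (e > i) inactive += (a[e - 1] ? 0 : 1);
            if (inactive > max_int) break;
            if (a[e]) best_e = e;
        }
        if (best_e >= 0 && best_e - i + 1 >= min_dur) {
            bouts.push_back(std::make_pair(i, best_e));
            i = best_e + 1;
        } else {
            ++i;
        }
    }
}

static IntegerMatrix to_matrix(const std::vector<std::pair<int,int> >& bouts) {
    IntegerMatrix m((int)bouts.size(), 2);
    for (size_t k = 0; k < bouts.size(); ++k) {
        m(k, 0) = bouts[k].first + 1;  // 1-based for R
        m(k, 1) = bouts[k].second + 1;
    }
    colnames(m) = CharacterVector::create("start", "end");
    return m;
}

static std::vector<int> as_vec(const LogicalVector& active) {
    std::vector<int> a(active.size());
    for (int i = 0; i < active.size(); ++i) a[i] = (active[i] == TRUE) ? 1 : 0;
    return a;
}

// [[Rcpp::export(name = ".bout_spans_greedy")]]
IntegerMatrix bout_spans_greedy(LogicalVector active, int min_dur, int max_int) {
    std::vector<std::pair<int,int> > bouts;
    std::vector<int> a = as_vec(active);
    greedy_scan(a, min_dur, max_int, bouts);
    return to_matrix(bouts);
}

// [[Rcpp::export(name = ".bout_spans_oracle")]]
IntegerMatrix bout_spans_oracle(LogicalVector active, int min_dur, int max_int) {
    std::vector<std::pair<int,int> > bouts;
    std::vector<int> a = as_vec(active);
    oracle_scan(a, min_dur, max_int, bouts);
    return to_matrix(bouts);
}

static int in_bout_active(const std::vector<int>& a,
                          const std::vector<std::pair<int,int> >& bouts) {
    int tot = 0;
    for (size_t k = 0; k < bouts.size(); ++k)
        for (int j = bouts[k].first; j <= bouts[k].second; ++j) tot += a[j];
    return tot;
}

// Exhaustively compare greedy vs oracle total in-bout active minutes over
// all 2^len binary sequences. Returns c(n_sequences, n_mismatches,
// first_mismatch_mask) with mask -1 when none.
// [[Rcpp::export(name = ".bout_exhaustive_check")]]
IntegerVector bout_exhaustive_check(int len, int min_dur, int max_int) {
    if (len < 1 || len > 24) stop("len must be in 1..24");
    const long total = 1L << len;
    long mismatches = 0, first = -1;
    std::vector<int> a(len);
    std::vector<std::pair<int,int> > b1, b2;
    for (long mask = 0; mask < total; ++mask) {
        for (int i = 0; i < len; ++i) a[i] = (mask >> i) & 1L;
        b1.clear(); b2.clear();
        greedy_scan(a, min_dur, max_int, b1);
        oracle_scan(a, min_dur, max_int, b2);
        if (in_bout_active(a, b1) != in_bout_active(a, b2)) {
            if (first < 0) first = mask;
            ++mismatches;
        }
        if ((mask & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
    }
    return IntegerVector::create((int)total, (int)mismatches, (int)first);
}

// Compare greedy vs oracle on each row of a 0/1 matrix; returns the number
// of rows where total in-bout active minutes disagree.
// [[Rcpp::export(name = ".bout_batch_check")]]
int bout_batch_check(IntegerMatrix seqs, int min_dur, int max_int) {
    int bad = 0;
    std::vector<int> a(seqs.ncol());
    std::vector<std::pair<int,int> > b1, b2;
    for (int r = 0; r < seqs.nrow(); ++r) {
        for (int j = 0; j < seqs.ncol(); ++j) a[j] = seqs(r, j) ? 1 : 0;
        b1.clear(); b2.clear();
        greedy_scan(a, min_dur, max_int, b1);
        oracle_scan(a, min_dur, max_int, b2);
        if (in_bout_active(a, b1) != in_bout_active(a, b2)) ++bad;
        if ((r & 0x3FF) == 0) Rcpp::checkUserInterrupt();
    }
    return bad;
}
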