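#include <Rcpp.h>
using namespace Rcpp;

// Low-level ungapped sequence scans shared by the merging, clustering,
// repeat-detection and protospacer stages. All matching in this package is
// substitution-only (Hamming); 'N' never matches anything, including itself.

static inline bool base_eq(char a, char b) {
  return a == b && a != 'N';
}

// Best suffix(r1)/prefix(r2) overlap among lengths in [min_ov, max_ov].
// Minimizes the mismatch fraction; ties broken by the longer overlap.
// Returns c(overlap_length, mismatches); c(-1, -1) when no candidate length
// exists (reads shorter than min_ov).
// [[Rcpp::export]]
IntegerVector cpp_best_overlap(std::string r1, std::string r2,
                               int min_ov, int max_ov) {
  int n1 = (int) r1.size(), n2 = (int) r2.size();
  int hi = std::min(std::min(n1, n2), max_ov);
  int best_L = -1, best_mm = -1;
  for (int L = min_ov; L <= hi; ++L) {
    int mm = 0, off = n1 - L;
    for (int i = 0; i < L; ++i)
      if (!base_eq(r1[off + i], r2[i])) ++mm;
    if (best_L < 0 ||
        (long) mm * best_L < (long) best_mm * L ||
        ((long) mm * best_L == (long) best_mm * L && L > best_L)) {
      best_L = L; best_mm = mm;
    }
  }
  return IntegerVector::create(best_L, best_mm);
}

// Consensus merge of a pair at a fixed overlap length. At disagreeing
// positions the higher-quality base wins (tie -> r1); kept quality is the
// max of the two at every overlap column.
// [[Rcpp::export]]
List cpp_merge_at(std::string r1, std::string r2,
                  IntegerVector q1, IntegerVector q2, int L) {
  int n1 = (int) r1.size(), n2 = (int) r2.size();
  int off = n1 - L;
  std::string out = r1.substr(0, off);
  out.reserve(n1 + n2 - L);
  IntegerVector qual(n1 + n2 - L);
  for (int i = 0; i < off; ++i) qual[i] = q1[i];
  for (int i = 0; i < L; ++i) {
    char b1 = r1[off + i], b2 = r2[i];
    int  qa = q1[off + i], qb = q2[i];
    out.push_back(b1 == b2 ? b1 : (qb > qa ? b2 : b1));
    qual[off + i] = std::max(qa, qb);
  }
  out.append(r2.substr(L));
  for (int i = L; i < n2; ++i) qual[n1 + i - L] = q2[i];
  return List::create(_["sequence"] = out, _["qualities"] = qual);
}

// Hamming distance between motif and every window of seq; empty vector when
// motif is longer than seq.
// [[Rcpp::export]]
IntegerVector cpp_hamming_scan(std::string seq, std::string motif) {
  int n = (int) seq.size(), m = (int) motif.size();
  if (m == 0 || m > n) return IntegerVector(0);
  IntegerVector out(n - m + 1);
  for (int s = 0; s <= n - m; ++s) {
    int mm = 0;
    for (int i = 0; i < m; ++i)
      if (!base_eq(seq[s + i], motif[i])) ++mm;
    out[s] = mm;
  }
  return out;
}

// [[Rcpp::export]]
int cpp_hamming(std::string a, std::string b) {
  if (a.size() != b.size()) return -1;
  int mm = 0;
  for (size_t i = 0; i < a.size(); ++i)
    if (!base_eq(a[i], b[i])) ++mm;
  return mm;
}

// Best ungapped offset alignment of b against a over every relative offset
// d in [-(nb-1), na-1] (d = position of b's first base in a's coordinates).
// Maximizes matches; ties -> longer overlap, then smaller offset.
// Returns c(matches, overlap_length, offset).
// [[Rcpp::export]]
IntegerVector cpp_best_offset(std::string a, std::string b) {
  int na = (int) a.size(), nb = (int) b.size();
  int best_m = -1, best_ov = -1, best_d = 0;
  for (int d = -(nb - 1); d <= na - 1; ++d) {
    int lo = std::max(0, d), hi = std::min(na, d + nb);
    int ov = hi - lo;
    if (ov <= 0) continue;
    int m = 0;
    for (int i = lo; i < hi; ++i)
      if (base_eq(a[i], b[i - d])) ++m;
    if (m > best_m || (m == best_m && ov > best_ov)) {
      best_m = m; best_ov = ov; best_d = d;
    }
  }
  return IntegerVector::create(best_m, best_ov, best_d);
}

// Early-bailing membership test used inside greedy clustering: does any
// ungapped offset give coverage >= min_cov (aligned columns relative to the
// LONGER sequence, so clusters correspond to whole array types) and
// identity >= min_id over the overlap?
// [[Rcpp::export]]
bool cpp_cluster_hit(std::string rep, std::string seq,
                     double min_id, double min_cov) {
  int na = (int) rep.size(), nb = (int) seq.size();
  int longer = std::max(na, nb);
  int min_ov = (int) std::ceil(min_cov * longer - 1e-9);
  if (min_ov < 1) min_ov = 1;
  for (int d = -(nb - 1); d <= na - 1; ++d) {
    int lo = std::max(0, d), hi = std::min(na, d + nb);
    int ov = hi - lo;
    if (ov < min_ov) continue;
    int allowed = (int) std::floor((1.0 - min_id) * ov + 1e-9);
    int mm = 0;
    bool ok = true;
    for (int i = lo; i < hi; ++i) {
      if (!base_eq(rep[i], seq[i - d])) {
        if (++mm > allowed) { ok = false; break; }
      }
    }
    if (ok) return true;
  }
  return false;
}

// Exact check that the BEST ungapped alignment (max matches; ties -> longer
// overlap) reaches both thresholds. Offsets are visited in decreasing
// overlap order so the scan can stop once no remaining overlap can beat the
// best match count (matches <= overlap).
// [[Rcpp::export]]
bool cpp_best_offset_qualifies(std::string a, std::string b,
                               double min_id, double min_cov) {
  int na = (int) a.size(), nb = (int) b.size();
  int longer = std::max(na, nb);
  std::vector<int> offs;
  offs.reserve(na + nb - 1);
  for (int d = -(nb - 1); d <= na - 1; ++d) offs.push_back(d);
  std::stable_sort(offs.begin(), offs.end(), [&](int d1, int d2) {
    int ov1 = std::min(na, d1 + nb) - std::max(0, d1);
    int ov2 = std::min(na, d2 + nb) - std::max(0, d2);
    return ov1 > ov2;
  });
  int best_m = -1, best_ov = -1;
  for (int d : offs) {
    int lo = std::max(0, d), hi = std::min(na, d + nb);
    int ov = hi - lo;
    if (ov <= 0 || ov <= best_m) break;  // later overlaps only shrink
    int m = 0;
    for (int i = lo; i < hi; ++i)
      if (base_eq(a[i], b[i - d])) ++m;
    if (m > best_m || (m == best_m && ov > best_ov)) {
      best_m = m; best_ov = ov;
    }
  }
  if (best_ov <= 0) return false;
  double identity = (double) best_m / best_ov;
  double coverage = (double) best_ov / longer;
  return identity >= min_id - 1e-12 && coverage >= min_cov - 1e-12;
}

// Exhaustive ungapped scan of a query against one reference strand; returns
// mismatch count at every offset (thin alias of cpp_hamming_scan kept for
// the protospacer stage's readability).
// [[Rcpp::export]]
IntegerVector cpp_query_scan(std::string ref, std::string query) {
  return cpp_hamming_scan(ref, query);
}
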