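#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// Local alignment primitives shared by ANI, read recruitment and protein
// clustering. Scoring is identity-based (match +1, mismatch -1, linear gap
// -2); identity_pct = 100 * matches / alignment columns (gaps included).
// Wildcard bases (N for nucleotide, X for protein) never count as matches.

static const int MATCH = 1;
static const int MISMATCH = -1;
static const int GAP = -2;

static inline bool is_wild(char c) {
  return c == 'N' || c == 'n' || c == 'X' || c == 'x';
}

static inline int sub_score(char a, char b) {
  if (is_wild(a) || is_wild(b)) return MISMATCH;
  return (a == b) ? MATCH : MISMATCH;
}

struct AlnResult {
  bool found;
  int score, matches, columns;
  int qstart, qend, tstart, tend; // 0-based half-open
  AlnResult() : found(false), score(0), matches(0), columns(0),
                qstart(0), qend(0), tstart(0), tend(0) {}
};

// Full Smith-Waterman with traceback. dir codes: 0 stop, 1 diag, 2 up
// (consume query), 3 left (consume target).
static AlnResult sw_full(const std::string& a, const std::string& b) {
  const int la = a.size(), lb = b.size();
  AlnResult res;
  if (la == 0 || lb == 0) return res;
  std::vector<int> prev(lb + 1, 0), cur(lb + 1, 0);
  std::vector<uint8_t> dir((size_t)(la + 1) * (lb + 1), 0);
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= la; ++i) {
    cur[0] = 0;
    for (int j = 1; j <= lb; ++j) {
      int d = prev[j - 1] + sub_score(a[i - 1], b[j - 1]);
      int u = prev[j] + GAP;
      int l = cur[j - 1] + GAP;
      int h = d; uint8_t dd = 1;
      if (u > h) { h = u; dd = 2; }
      if (l > h) { h = l; dd = 3; }
      if (h <= 0) { h = 0; dd = 0; }
      cur[j] = h;
      dir[(size_t)i * (lb + 1) + j] = dd;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(prev, cur);
  }
  if (best <= 0) return res;
  int i = bi, j = bj, matches = 0, columns = 0;
  while (i > 0 && j > 0) {
    uint8_t dd = dir[(size_t)i * (lb + 1) + j];
    if (dd == 0) break;
    ++columns;
    if (dd == 1) {
      if (!is_wild(a[i - 1]) && !is_wild(b[j - 1]) && a[i - 1] == b[j - 1]) ++matches;
      --i; --j;
    } else if (dd == 2) { --i; }
    else { --j; }
  }
  res.found = true; res.score = best; res.matches = matches; res.columns = columns;
  res.qstart = i; res.qend = bi; res.tstart = j; res.tend = bj;
  return res;
}

// Banded Smith-Waterman around the main diagonal (offset range covers the
// length difference plus `band` on each side). Used for near-global protein
// identity where indels are rare.
static AlnResult sw_banded(const std::string& a, const std::string& b, int band) {
  const int la = a.size(), lb = b.size();
  AlnResult res;
  if (la == 0 || lb == 0) return res;
  const int dlo = std::min(0, lb - la) - band;
  const int dhi = std::max(0, lb - la) + band;
  const int W = dhi - dlo + 1;
  const int NEG = -1000000000;
  std::vector<int> prev(W, 0), cur(W, 0);
  std::vector<uint8_t> dir((size_t)(la + 1) * W, 0);
  int best = 0, bi = 0, bk = 0;
  for (int k = 0; k < W; ++k) {
    int j = 0 + dlo + k;
    prev[k] = (j >= 0 && j <= lb) ? 0 : NEG;
  }
  for (int i = 1; i <= la; ++i) {
    for (int k = 0; k < W; ++k) {
      int j = i + dlo + k;
      if (j < 0 || j > lb) { cur[k] = NEG; continue; }
      if (j == 0) { cur[k] = 0; dir[(size_t)i * W + k] = 0; continue; }
      // diag: (i-1, j-1) -> same k in prev row
      int d = (prev[k] <= NEG / 2) ? NEG : prev[k] + sub_score(a[i - 1], b[j - 1]);
      // up: (i-1, j) -> k+1 in prev row
      int u = (k + 1 < W && prev[k + 1] > NEG / 2) ? prev[k + 1] + GAP : NEG;
      // left: (i, j-1) -> k-1 in cur row
      int l = (k - 1 >= 0 && cur[k - 1] > NEG / 2) ? cur[k - 1] + GAP : NEG;
      int h = d; uint8_t dd = 1;
      if (u > h) { h = u; dd = 2; }
      if (l > h) { h = l; dd = 3; }
      if (h <= 0) { h = 0; dd = 0; }
      cur[k] = h;
      dir[(size_t)i * W + k] = dd;
      if (h > best) { best = h; bi = i; bk = k; }
    }
    std::swap(prev, cur);
  }
  if (best <= 0) return res;
  int i = bi, k = bk, matches = 0, columns = 0;
  while (i > 0) {
    int j = i + dlo + k;
    if (j <= 0) break;
    uint8_t dd = dir[(size_t)i * W + k];
    if (dd == 0) break;
    ++columns;
    if (dd == 1) {
      if (!is_wild(a[i - 1]) && !is_wild(b[j - 1]) && a[i - 1] == b[j - 1]) ++matches;
      --i; // k unchanged (diag keeps offset)
    } else if (dd == 2) { --i; ++k; }
    else { --k; }
  }
  res.found = true; res.score = best; res.matches = matches; res.columns = columns;
  res.qstart = i; res.qend = bi;
  res.tstart = i + dlo + k; res.tend = bi + dlo + bk;
  return res;
}

// Banded "fit" alignment: the whole of `a` (the shorter sequence) is
// aligned into `b` with free leading/trailing gaps in `b` (cd-hit-style
// global identity). Used for protein clustering, where sub-50% identities
// must still yield full-length alignments.
static AlnResult sw_fit_banded(const std::string& a, const std::string& b,
                               int band) {
  const int la = a.size(), lb = b.size();
  AlnResult res;
  if (la == 0 || lb == 0) return res;
  const int dlo = std::min(0, lb - la) - band;
  const int dhi = std::max(0, lb - la) + band;
  const int W = dhi - dlo + 1;
  const int NEG = -1000000000;
  std::vector<int> prev(W, NEG), cur(W, NEG);
  std::vector<uint8_t> dir((size_t)(la + 1) * W, 0);
  for (int k = 0; k < W; ++k) {
    int j = 0 + dlo + k;
    if (j >= 0 && j <= lb) prev[k] = 0; // free leading gap in b
  }
  for (int i = 1; i <= la; ++i) {
    for (int k = 0; k < W; ++k) {
      int j = i + dlo + k;
      cur[k] = NEG;
      if (j < 0 || j > lb) continue;
      int d = NEG, u = NEG, l = NEG;
      if (prev[k] > NEG / 2 && j >= 1)
        d = prev[k] + sub_score(a[i - 1], b[j - 1]);
      if (k + 1 < W && prev[k + 1] > NEG / 2) u = prev[k + 1] + GAP;
      if (k - 1 >= 0 && cur[k - 1] > NEG / 2 && j >= 1) l = cur[k - 1] + GAP;
      int h = d; uint8_t dd = 1;
      if (u > h) { h = u; dd = 2; }
      if (l > h) { h = l; dd = 3; }
      if (h <= NEG / 2) continue;
      cur[k] = h;
      dir[(size_t)i * W + k] = dd;
    }
    std::swap(prev, cur);
  }
  int best = NEG, bk = -1;
  for (int k = 0; k < W; ++k) {
    int j = la + dlo + k;
    if (j < 0 || j > lb) continue;
    if (prev[k] > best) { best = prev[k]; bk = k; }
  }
  if (bk < 0) return res;
  int i = la, k = bk, matches = 0, columns = 0;
  while (i > 0) {
    uint8_t dd = dir[(size_t)i * W + k];
    if (dd == 0) break;
    ++columns;
    if (dd == 1) {
      int j = i + dlo + k;
      if (!is_wild(a[i - 1]) && !is_wild(b[j - 1]) && a[i - 1] == b[j - 1])
        ++matches;
      --i;
    } else if (dd == 2) { --i; ++k; }
    else { --k; }
  }
  res.found = true; res.score = best; res.matches = matches;
  res.columns = columns;
  res.qstart = i; res.qend = la;
  res.tstart = i + dlo + k; res.tend = la + dlo + bk;
  return res;
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'T': return 'A';
    case 'C': return 'G'; case 'G': return 'C';
    case 'a': return 't'; case 't': return 'a';
    case 'c': return 'g'; case 'g': return 'c';
    default: return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp_base(c);
  return r;
}

// FNV-1a hash of k bytes; windows containing wildcards are skipped.
static inline bool kmer_hash(const std::string& s, int pos, int k, uint64_t& out) {
  uint64_t h = 1469598103934665603ULL;
  for (int i = 0; i < k; ++i) {
    char c = s[pos + i];
    if (is_wild(c)) return false;
    h ^= (uint64_t)(unsigned char)c;
    h *= 1099511628211ULL;
  }
  out = h;
  return true;
}

typedef std::unordered_map<uint64_t, std::vector<int> > SeedIndex;

static SeedIndex build_index(const std::string& t, int k) {
  SeedIndex idx;
  const int lt = t.size();
  idx.reserve(lt > k ? (size_t)(lt - k + 1) : 1);
  for (int p = 0; p + k <= lt; ++p) {
    uint64_t h;
    if (kmer_hash(t, p, k, h)) idx[h].push_back(p);
  }
  return idx;
}

// Seeded best local alignment of query against target (one strand).
// Diagonal voting -> up to max_cand candidate windows -> SW per window.
static AlnResult seeded_align_one(const std::string& q, const std::string& t,
                                  const SeedIndex& idx, int k, int band,
                                  int max_cand) {
  AlnResult best;
  const int lq = q.size(), lt = t.size();
  if (lq < k) return best;
  std::unordered_map<int, int> votes;
  for (int p = 0; p + k <= lq; ++p) {
    uint64_t h;
    if (!kmer_hash(q, p, k, h)) continue;
    SeedIndex::const_iterator it = idx.find(h);
    if (it == idx.end()) continue;
    if ((int)it->second.size() > 64) continue; // repeat-heavy seed, skip
    for (int tp : it->second) votes[tp - p] += 1;
  }
  if (votes.empty()) return best;
  std::vector<std::pair<int, int> > dv(votes.begin(), votes.end());
  std::sort(dv.begin(), dv.end(), [](const std::pair<int,int>& x,
                                     const std::pair<int,int>& y) {
    if (x.second != y.second) return x.second > y.second;
    return x.first < y.first;
  });
  std::vector<int> chosen;
  int vote_floor = std::max(1, dv[0].second / 8);
  for (auto& pr : dv) {
    if (pr.second < vote_floor) break;
    bool near = false;
    for (int c : chosen) if (std::abs(pr.first - c) <= band) { near = true; break; }
    if (near) continue;
    chosen.push_back(pr.first);
    if ((int)chosen.size() >= max_cand) break;
  }
  for (int d : chosen) {
    // clip query and target to the diagonal stripe so the band stays tight
    int qs = std::max(0, -d - band);
    int qe = std::min(lq, lt - d + band);
    if (qe - qs < k) continue;
    int ws = std::max(0, d + qs - band);
    int we = std::min(lt, d + qe + band);
    if (we - ws < k) continue;
    AlnResult r = sw_banded(q.substr(qs, qe - qs), t.substr(ws, we - ws),
                            band);
    if (!r.found) continue;
    r.qstart += qs; r.qend += qs;
    r.tstart += ws; r.tend += ws;
    if (!best.found || r.score > best.score ||
        (r.score == best.score && r.tstart < best.tstart)) best = r;
  }
  return best;
}

// [[Rcpp::export(name = ".cpp_sw_pair")]]
List cpp_sw_pair(std::string a, std::string b) {
  AlnResult r = sw_full(a, b);
  return List::create(_["found"] = r.found, _["score"] = r.score,
                      _["matches"] = r.matches, _["columns"] = r.columns,
                      _["qstart"] = r.qstart, _["qend"] = r.qend,
                      _["tstart"] = r.tstart, _["tend"] = r.tend);
}

// [[Rcpp::export(name = ".cpp_local_align")]]
List cpp_local_align(std::string a, std::string b, int k, int band,
                     double full_dp_limit) {
  AlnResult r;
  double cells = (double)a.size() * (double)b.size();
  if (cells <= full_dp_limit) {
    r = sw_full(a, b);
  } else {
    SeedIndex idx = build_index(b, k);
    r = seeded_align_one(a, b, idx, k, band, 8);
  }
  return List::create(_["found"] = r.found, _["score"] = r.score,
                      _["matches"] = r.matches, _["columns"] = r.columns,
                      _["qstart"] = r.qstart, _["qend"] = r.qend,
                      _["tstart"] = r.tstart, _["tend"] = r.tend);
}

// Map many queries against one target; best single hit per query, both
// strands optional. Tie-break: higher score, then lower target start, then
// '+' strand. Coordinates 0-based half-open on the original query/target.
// [[Rcpp::export(name = ".cpp_map_reads")]]
DataFrame cpp_map_reads(CharacterVector queries, std::string target,
                        int k, int band, int min_len, double min_identity,
                        bool both_strands, int max_cand) {
  SeedIndex idx = build_index(target, k);
  const int n = queries.size();
  LogicalVector found(n);
  IntegerVector qstart(n), qend(n), tstart(n), tend(n), matches(n), columns(n), score(n);
  CharacterVector strand(n);
  NumericVector identity(n);
  for (int i = 0; i < n; ++i) {
    std::string q = as<std::string>(queries[i]);
    AlnResult fw = seeded_align_one(q, target, idx, k, band, max_cand);
    AlnResult rv;
    bool use_rev = false;
    if (both_strands) {
      std::string qr = revcomp(q);
      rv = seeded_align_one(qr, target, idx, k, band, max_cand);
      if (rv.found && (!fw.found || rv.score > fw.score ||
                       (rv.score == fw.score && rv.tstart < fw.tstart)))
        use_rev = true;
    }
    AlnResult r = use_rev ? rv : fw;
    bool ok = r.found && r.columns >= min_len &&
              (100.0 * r.matches / std::max(1, r.columns)) >= min_identity;
    found[i] = ok;
    if (ok) {
      int lq = q.size();
      if (use_rev) { // flip query span back to original orientation
        int qs = lq - r.qend, qe = lq - r.qstart;
        qstart[i] = qs; qend[i] = qe;
      } else {
        qstart[i] = r.qstart; qend[i] = r.qend;
      }
      tstart[i] = r.tstart; tend[i] = r.tend;
      matches[i] = r.matches; columns[i] = r.columns; score[i] = r.score;
      strand[i] = use_rev ? "-" : "+";
      identity[i] = 100.0 * r.matches / r.columns;
    } else {
      qstart[i] = NA_INTEGER; qend[i] = NA_INTEGER;
      tstart[i] = NA_INTEGER; tend[i] = NA_INTEGER;
      matches[i] = NA_INTEGER; columns[i] = NA_INTEGER; score[i] = NA_INTEGER;
      strand[i] = NA_STRING; identity[i] = NA_REAL;
    }
  }
  return DataFrame::create(_["found"] = found, _["qstart"] = qstart,
                           _["qend"] = qend, _["tstart"] = tstart,
                           _["tend"] = tend, _["strand"] = strand,
                           _["matches"] = matches, _["columns"] = columns,
                           _["score"] = score, _["identity"] = identity,
                           _["stringsAsFactors"] = false);
}

// sorted (hash, position) pairs of all k-mers of a sequence
typedef std::vector<std::pair<uint64_t, int> > KposVec;

static KposVec kmer_positions(const std::string& s, int k) {
  KposVec v;
  for (int p = 0; p + k <= (int)s.size(); ++p) {
    uint64_t h;
    if (kmer_hash(s, p, k, h)) v.push_back(std::make_pair(h, p));
  }
  std::sort(v.begin(), v.end());
  return v;
}

// best diagonal (offset of `s` inside `l`) by shared-k-mer voting; returns
// false when the two sequences share no k-mer at all
static bool best_offset(const KposVec& ks, const KposVec& kl, int& diag_out) {
  std::unordered_map<int, int> votes;
  size_t i = 0, j = 0;
  while (i < ks.size() && j < kl.size()) {
    if (ks[i].first < kl[j].first) ++i;
    else if (kl[j].first < ks[i].first) ++j;
    else {
      size_t i2 = i, j2 = j;
      while (i2 < ks.size() && ks[i2].first == ks[i].first) ++i2;
      while (j2 < kl.size() && kl[j2].first == kl[j].first) ++j2;
      if ((i2 - i) * (j2 - j) <= 256) {
        for (size_t a = i; a < i2; ++a)
          for (size_t b = j; b < j2; ++b)
            votes[kl[b].second - ks[a].second] += 1;
      }
      i = i2; j = j2;
    }
  }
  if (votes.empty()) return false;
  int best_d = 0, best_v = -1;
  for (auto& pr : votes) {
    if (pr.second > best_v || (pr.second == best_v && pr.first < best_d)) {
      best_v = pr.second; best_d = pr.first;
    }
  }
  // word filter: a qualifying alignment leaves >= 2 shared k-mers on its
  // diagonal except for very short sequences
  int need = std::min(2, (int)std::min(ks.size(), kl.size()));
  if (best_v < need) return false;
  diag_out = best_d;
  return true;
}

// cd-hit style pair decision: fit the shorter sequence into the longer in
// a narrow band around the best shared-k-mer diagonal; identity = matches /
// alignment columns (gaps included). Pairs without any shared k-mer cannot
// qualify.
static bool pair_passes(const std::string& a, const std::string& b,
                        const KposVec& ka, const KposVec& kb,
                        double id_thr, double cov_thr, int band,
                        double& id_out, double& cov_out) {
  const bool a_short = a.size() <= b.size();
  const std::string& s = a_short ? a : b;
  const std::string& l = a_short ? b : a;
  const KposVec& ks = a_short ? ka : kb;
  const KposVec& kl = a_short ? kb : ka;
  int diag;
  if (!best_offset(ks, kl, diag)) return false;
  const int la = s.size(), lb = l.size();
  int ws = std::max(0, std::min(diag - band, lb - la));
  int we = std::min(lb, std::max(diag + la + band, la));
  if (we <= ws) return false;
  AlnResult r = sw_fit_banded(s, l.substr(ws, we - ws), band);
  if (!r.found || r.columns == 0) return false;
  int span = r.qend - r.qstart;
  id_out = 100.0 * r.matches / r.columns;
  cov_out = (double)span / la;
  return id_out >= id_thr && cov_out >= cov_thr;
}

// Greedy length-descending clustering (cd-hit style): sequences must be
// supplied sorted by decreasing length; each sequence joins the best-scoring
// existing representative meeting the identity/coverage thresholds, else
// founds a new cluster. Returns 1-based cluster ids.
// [[Rcpp::export(name = ".cpp_cluster_greedy")]]
IntegerVector cpp_cluster_greedy(CharacterVector seqs, double id_thr,
                                 double cov_thr, int k, int band) {
  const int n = seqs.size();
  std::vector<std::string> ss(n);
  std::vector<KposVec> km(n);
  for (int i = 0; i < n; ++i) {
    ss[i] = as<std::string>(seqs[i]);
    km[i] = kmer_positions(ss[i], k);
  }
  IntegerVector cl(n);
  std::vector<int> reps;
  for (int i = 0; i < n; ++i) {
    int best_rep = -1; double best_id = -1;
    for (size_t rI = 0; rI < reps.size(); ++rI) {
      int r = reps[rI];
      double idv, covv;
      if (pair_passes(ss[i], ss[r], km[i], km[r], id_thr, cov_thr, band,
                      idv, covv)) {
        if (idv > best_id) { best_id = idv; best_rep = r; }
      }
    }
    if (best_rep >= 0) cl[i] = cl[best_rep];
    else { reps.push_back(i); cl[i] = reps.size(); }
  }
  return cl;
}

// All-vs-all qualifying pairs (for single-linkage ortholog families).
// Returns 1-based index pairs with identity and coverage.
// [[Rcpp::export(name = ".cpp_all_hits")]]
DataFrame cpp_all_hits(CharacterVector seqs, double id_thr, double cov_thr,
                       int k, int band) {
  const int n = seqs.size();
  std::vector<std::string> ss(n);
  std::vector<KposVec> km(n);
  for (int i = 0; i < n; ++i) {
    ss[i] = as<std::string>(seqs[i]);
    km[i] = kmer_positions(ss[i], k);
  }
  std::vector<int> ii, jj; std::vector<double> idv, covv;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double idx_, cov_;
      if (pair_passes(ss[i], ss[j], km[i], km[j], id_thr, cov_thr, band,
                      idx_, cov_)) {
        ii.push_back(i + 1); jj.push_back(j + 1);
        idv.push_back(idx_); covv.push_back(cov_);
      }
    }
  }
  return DataFrame::create(_["i"] = ii, _["j"] = jj, _["identity"] = idv,
                           _["coverage"] = covv);
}

// [[Rcpp::export(name = ".cpp_fit_pair")]]
List cpp_fit_pair(std::string a, std::string b, int band) {
  KposVec ka = kmer_positions(a, 3), kb = kmer_positions(b, 3);
  double idv = NA_REAL, cov = NA_REAL;
  bool ok = pair_passes(a, b, ka, kb, 0.0, 0.0, band, idv, cov);
  return List::create(_["found"] = ok, _["identity"] = idv,
                      _["coverage"] = cov);
}

// [[Rcpp::export(name = ".cpp_revcomp")]]
std::string cpp_revcomp(std::string s) { return revcomp(s); }
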