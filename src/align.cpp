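#include <Rcpp.h>
#include <cmath>
#include <string>
#include <vector>
using namespace Rcpp;

// Global (end-to-end) alignment with unit costs: match 0, mismatch 1,
// gap 1. Ties broken deterministically: diagonal > up (gap in query) >
// left (gap in reference).
static int nw_core(const std::string& ref, const std::string& qry,
                   std::string& out_ref, std::string& out_qry) {
  const int n = (int)ref.size(), m = (int)qry.size();
  std::vector<int> prev(m + 1), cur(m + 1);
  std::vector<unsigned char> tb((size_t)(n + 1) * (m + 1));
  for (int j = 0; j <= m; ++j) { prev[j] = j; tb[j] = 'L'; }
  for (int i = 1; i <= n; ++i) {
    cur[0] = i;
    tb[(size_t)i * (m + 1)] = 'U';
    for (int j = 1; j <= m; ++j) {
      int diag = prev[j - 1] + (ref[i - 1] == qry[j - 1] ? 0 : 1);
      int up = prev[j] + 1;
      int left = cur[j - 1] + 1;
      int best = diag; unsigned char t = 'D';
      if (up < best) { best = up; t = 'U'; }
      if (left < best) { best = left; t = 'L'; }
      cur[j] = best;
      tb[(size_t)i * (m + 1) + j] = t;
    }
    std::swap(prev, cur);
  }
  int dist = prev[m];
  std::string ra, rb;
  ra.reserve(n + m); rb.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    unsigned char t = tb[(size_t)i * (m + 1) + j];
    if (t == 'D') { ra.push_back(ref[i - 1]); rb.push_back(qry[j - 1]); --i; --j; }
    else if (t == 'U') { ra.push_back(ref[i - 1]); rb.push_back('-'); --i; }
    else { ra.push_back('-'); rb.push_back(qry[j - 1]); --j; }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  out_ref = ra; out_qry = rb;
  return dist;
}

// [[Rcpp::export(name = ".nw_align")]]
List nw_align_cpp(std::string ref, std::string qry) {
  std::string ar, aq;
  int d = nw_core(ref, qry, ar, aq);
  return List::create(_["ref"] = ar, _["qry"] = aq, _["distance"] = d);
}

// Counts of match/substitution/insertion/deletion columns of the global
// alignment of qry to ref (insertion = base in qry absent from ref).
// [[Rcpp::export(name = ".align_stats")]]
IntegerVector align_stats_cpp(std::string ref, std::string qry) {
  std::string ar, aq;
  nw_core(ref, qry, ar, aq);
  int match = 0, sub = 0, ins = 0, del = 0;
  for (size_t c = 0; c < ar.size(); ++c) {
    if (ar[c] == '-') ++ins;
    else if (aq[c] == '-') ++del;
    else if (ar[c] == aq[c]) ++match;
    else ++sub;
  }
  return IntegerVector::create(_["match"] = match, _["sub"] = sub,
                               _["ins"] = ins, _["del"] = del);
}

static inline int sym_index(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1; case 'G': return 2;
    case 'T': return 3; case 'N': return 4; default: return 5; // gap/other
  }
}

static inline int phred_from_votes(int k, int n, double eps, int qcap) {
  double err = 1.0 - (double)k / (double)n;
  if (err < eps) err = eps;
  int q = (int)std::lround(-10.0 * std::log10(err));
  if (q > qcap) q = qcap;
  if (q < 0) q = 0;
  return q;
}

// Backbone-based plurality consensus of subreads from one ZMW, all
// oriented to the + strand. Per backbone column the plurality symbol among
// {A,C,G,T,N,-} wins (ties prefer a base over a gap, then alphabetical);
// insertion columns between backbone positions are included only when
// observed in at least half the subreads, with ties resolved toward the
// gap. Per-base quality is -10*log10(max(eps, 1 - k/n)) capped at qcap,
// where k of n subreads vote for the winning symbol.
// [[Rcpp::export(name = ".ccs_consensus")]]
List ccs_consensus_cpp(CharacterVector subreads, int backbone,
                       double eps = 1e-10, int qcap = 93) {
  const int n = subreads.size();
  if (n < 1) stop("empty subread list");
  std::string bb = as<std::string>(subreads[backbone - 1]);
  const int L = (int)bb.size();
  // per subread: aligned base (or gap) at each backbone position, and
  // inserted bases at each junction (before backbone position p; p in 0..L)
  std::vector<std::string> bbv(n);
  std::vector<std::vector<std::string> > insv(n);
  for (int s = 0; s < n; ++s) {
    std::string ar, aq;
    nw_core(bb, as<std::string>(subreads[s]), ar, aq);
    std::string col(L, '-');
    std::vector<std::string> jins(L + 1);
    int p = 0;
    for (size_t c = 0; c < ar.size(); ++c) {
      if (ar[c] != '-') { col[p] = aq[c]; ++p; }
      else jins[p].push_back(aq[c]);
    }
    bbv[s] = col;
    insv[s] = jins;
  }
  std::string cons;
  std::vector<int> quals;
  cons.reserve(L + L / 4);
  quals.reserve(L + L / 4);
  const char symbols[6] = {'A', 'C', 'G', 'T', 'N', '-'};
  for (int p = 0; p <= L; ++p) {
    // insertion columns at junction p
    size_t maxk = 0;
    for (int s = 0; s < n; ++s)
      if (insv[s][p].size() > maxk) maxk = insv[s][p].size();
    for (size_t k = 0; k < maxk; ++k) {
      int covered = 0;
      int counts[6] = {0, 0, 0, 0, 0, 0};
      for (int s = 0; s < n; ++s) {
        if (insv[s][p].size() > k) {
          ++covered;
          ++counts[sym_index(insv[s][p][k])];
        } else {
          ++counts[5];
        }
      }
      if (2 * covered < n) continue; // column observed in < half the subreads
      int best = 5; // start from gap; a base must strictly beat it
      for (int b = 0; b < 5; ++b)
        if (counts[b] > counts[best]) best = b;
      if (best == 5) continue; // gap wins (ties included): emit nothing
      cons.push_back(symbols[best]);
      quals.push_back(phred_from_votes(counts[best], n, eps, qcap));
    }
    if (p == L) break;
    // backbone column p
    int counts[6] = {0, 0, 0, 0, 0, 0};
    for (int s = 0; s < n; ++s) ++counts[sym_index(bbv[s][p])];
    int best = 0;
    for (int b = 1; b < 6; ++b)
      if (counts[b] > counts[best]) best = b; // ties prefer earlier: base, A<C<G<T
    if (best == 5) continue; // deletion consensus
    cons.push_back(symbols[best]);
    quals.push_back(phred_from_votes(counts[best], n, eps, qcap));
  }
  return List::create(_["seq"] = cons, _["qual"] = wrap(quals));
}
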