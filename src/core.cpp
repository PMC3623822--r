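// Compiled core: truncated-trie construction and the bounded inexact search.
// Codes: 0 sentinel, 1..4 = ACGT, 5 record separator, 6 ambiguous read base.
// Rows are 0-based over n+1 BWT rows; Occ(c, y) counts c in bwt[0..y].

#include <Rcpp.h>
#include <array>
#include <map>
#include <string>
#include <vector>

using namespace Rcpp;

namespace {

struct FMC {
  const int* bwt;
  int n;          // text length; n+1 rows
  const int* C;   // length 7, C[code] = # characters < code in text+sentinel
  const int* bk;  // Occ buckets, 7 x (nb+1), column-major
  int bsize;

  int occ(int c, int y) const {
    if (y < 0) return 0;
    int j = (y + 1) / bsize;
    int cnt = bk[j * 7 + c];
    for (int t = j * bsize; t <= y; ++t)
      if (bwt[t] == c) ++cnt;
    return cnt;
  }
  void ext(int k, int l, int c, int& k2, int& l2) const {
    k2 = C[c] + occ(c, k - 1);
    l2 = C[c] + occ(c, l) - 1;
  }
};

FMC make_fm(const IntegerVector& bwt, const IntegerVector& C,
            const IntegerMatrix& bk, int bsize) {
  FMC f;
  f.bwt = bwt.begin();
  f.n = bwt.size() - 1;
  f.C = C.begin();
  f.bk = bk.begin();
  f.bsize = bsize;
  return f;
}

}  // namespace

// Breadth-first construction of the frequency-truncated trie over the
// reversed reference.  A node reached by edge labels c1..cd (backward-search
// consumption order) caches the SA interval of the query string cd..c1 on the
// forward index; its frequency (interval width) equals the occurrence count
// of c1..cd in the reversed reference.  Construction aborts with
// exceeded = TRUE as soon as the non-root node count would pass node_budget.
// [[Rcpp::export]]
List build_trie_cpp(IntegerVector bwt, IntegerVector C, IntegerMatrix occ_buckets,
                    int bucket_size, int epsilon, double node_budget,
                    int max_depth) {
  FMC fm = make_fm(bwt, C, occ_buckets, bucket_size);
  std::vector<int> ch;  // stride 4, 1-based child ids, 0 = absent
  std::vector<int> kv, lv, dv, pv, ev;
  ch.assign(4, 0);
  kv.push_back(0); lv.push_back(fm.n);
  dv.push_back(0); pv.push_back(0); ev.push_back(0);
  bool exceeded = false;

  for (size_t node = 0; node < kv.size() && !exceeded; ++node) {
    if (dv[node] >= max_depth) continue;
    for (int c = 1; c <= 4; ++c) {
      int k2, l2;
      fm.ext(kv[node], lv[node], c, k2, l2);
      if (k2 > l2 || l2 - k2 + 1 < epsilon) continue;
      if (static_cast<double>(kv.size()) > node_budget) {  // non-root count after push
        exceeded = true;
        break;
      }
      ch[node * 4 + (c - 1)] = static_cast<int>(kv.size()) + 1;
      kv.push_back(k2); lv.push_back(l2);
      dv.push_back(dv[node] + 1);
      pv.push_back(static_cast<int>(node) + 1);
      ev.push_back(c);
      ch.insert(ch.end(), 4, 0);
    }
  }

  int nn = static_cast<int>(kv.size());
  IntegerMatrix children(nn, 4);
  for (int i = 0; i < nn; ++i)
    for (int c = 0; c < 4; ++c) children(i, c) = ch[i * 4 + c];
  return List::create(_["children"] = children,
                      _["k"] = wrap(kv), _["l"] = wrap(lv),
                      _["depth"] = wrap(dv), _["parent"] = wrap(pv),
                      _["edge"] = wrap(ev),
                      _["exceeded"] = exceeded);
}

namespace {

struct Hit {
  int k, l, nd;
  std::string script;
};

class Searcher {
 public:
  FMC fm;
  const int* W;
  int m;
  const int* D;
  int z, max_ext, max_opens, seed_len, seed_max_diff;
  const int* tch;  // trie children, nn x 4 column-major, 1-based ids
  const int* tk;
  const int* tl;
  int tnn;
  bool use_trie;
  long steps = 0, step_cap = 0;
  bool capped = false;

  std::map<std::pair<int, int>, size_t> seen;
  std::vector<Hit> hits;
  std::string path;

  void record(int k, int l, int nd) {
    auto key = std::make_pair(k, l);
    std::string script(path.rbegin(), path.rend());
    auto it = seen.find(key);
    if (it == seen.end()) {
      seen[key] = hits.size();
      hits.push_back({k, l, nd, script});
    } else if (nd < hits[it->second].nd) {
      hits[it->second] = {k, l, nd, script};
    }
  }

  // One backward step: cached trie edge while available, FM extension after
  // falling off the trie (t2 = -1 marks permanent FM mode for the branch).
  void stepc(int t, int k, int l, int c, int& t2, int& k2, int& l2) {
    if (use_trie && t >= 0) {
      int child = tch[(c - 1) * tnn + t];
      if (child > 0) {
        t2 = child - 1;
        k2 = tk[child - 1];
        l2 = tl[child - 1];
        return;
      }
    }
    t2 = -1;
    fm.ext(k, l, c, k2, l2);
  }

  // lastop: 0 match/sub, 1 deletion (reference consumed), 2 insertion.
  // opens: gap opens consumed so far (capped at max_opens).
  void rec(int i, int k, int l, int zrem, int t, int lastop, int run, int sd,
           int opens) {
    if (capped) return;
    if (++steps > step_cap) { capped = true; return; }
    if (i < 0) {
      record(k, l, z - zrem);
      return;
    }
    if (D[i] > zrem) return;  // lower bound on remaining prefix cost
    bool inseed = seed_len > 0 && i >= m - seed_len;
    int b = W[i];
    int ks[5], ls[5], ts[5];
    for (int c = 1; c <= 4; ++c) stepc(t, k, l, c, ts[c], ks[c], ls[c]);

    // 1. match
    if (b >= 1 && b <= 4 && ks[b] <= ls[b]) {
      path.push_back('M');
      rec(i - 1, ks[b], ls[b], zrem, ts[b], 0, 0, sd, opens);
      path.pop_back();
    }
    // 2. substitution
    if (zrem >= 1 && (!inseed || sd < seed_max_diff)) {
      for (int c = 1; c <= 4; ++c) {
        if (c == b || ks[c] > ls[c]) continue;
        path.push_back('X');
        rec(i - 1, ks[c], ls[c], zrem - 1, ts[c], 0, 0,
            sd + (inseed ? 1 : 0), opens);
        path.pop_back();
      }
    }
    // 3. deletion from the read (a reference base with no read base):
    //    gap open costs 1; up to max_ext consecutive extensions cost 0.
    {
      bool free_ext = (lastop == 1 && run < max_ext);
      int cost = free_ext ? 0 : 1;
      bool ok = free_ext || (opens < max_opens && zrem >= 1 &&
                             (!inseed || sd < seed_max_diff));
      if (ok) {
        for (int c = 1; c <= 4; ++c) {
          if (ks[c] > ls[c]) continue;
          path.push_back('D');
          rec(i, ks[c], ls[c], zrem - cost, ts[c], 1,
              free_ext ? run + 1 : 0, sd + ((cost && inseed) ? 1 : 0),
              opens + (free_ext ? 0 : 1));
          path.pop_back();
        }
      }
    }
    // 4. insertion in the read (read base consumed, no reference base)
    {
      bool free_ext = (lastop == 2 && run < max_ext);
      int cost = free_ext ? 0 : 1;
      bool ok = free_ext || (opens < max_opens && zrem >= 1 &&
                             (!inseed || sd < seed_max_diff));
      if (ok) {
        path.push_back('I');
        rec(i - 1, k, l, zrem - cost, t, 2,
            free_ext ? run + 1 : 0, sd + ((cost && inseed) ? 1 : 0),
            opens + (free_ext ? 0 : 1));
        path.pop_back();
      }
    }
  }
};

}  // namespace

// Depth-first bounded inexact search from the read end toward the start.
// Branch order: match > substitution > deletion > insertion.  A branch is cut
// whenever D[i] (lower bound on the cost of aligning W[0..i]) exceeds the
// remaining difference budget.  Returns deduplicated SA intervals with the
// charged difference count and a per-column edit script (left-to-right over
// M/X/I/D columns).
// [[Rcpp::export]]
List inexact_search_cpp(IntegerVector bwt, IntegerVector C, IntegerMatrix occ_buckets,
                        int bucket_size, IntegerVector W, IntegerVector D, int z,
                        int max_gap_opens, int max_gap_extensions,
                        int seed_length, int seed_max_diff,
                        IntegerMatrix trie_children, IntegerVector trie_k,
                        IntegerVector trie_l, bool use_trie, double max_steps) {
  Searcher s;
  s.fm = make_fm(bwt, C, occ_buckets, bucket_size);
  s.W = W.begin();
  s.m = W.size();
  s.D = D.begin();
  s.z = z;
  s.max_ext = max_gap_extensions;
  s.max_opens = max_gap_opens;
  s.seed_len = seed_length;
  s.seed_max_diff = seed_max_diff;
  s.tch = trie_children.begin();
  s.tk = trie_k.begin();
  s.tl = trie_l.begin();
  s.tnn = trie_children.nrow();
  s.use_trie = use_trie && s.tnn > 0;
  s.step_cap = static_cast<long>(max_steps);

  if (s.m > 0) s.rec(s.m - 1, 0, s.fm.n, z, s.use_trie ? 0 : -1, 0, 0, 0, 0);
  if (s.capped) stop("inexact search exceeded max_steps; raise search_params(max_steps=)");

  int nh = static_cast<int>(s.hits.size());
  IntegerVector hk(nh), hl(nh), hd(nh);
  CharacterVector hs(nh);
  for (int i = 0; i < nh; ++i) {
    hk[i] = s.hits[i].k;
    hl[i] = s.hits[i].l;
    hd[i] = s.hits[i].nd;
    hs[i] = s.hits[i].script;
  }
  return List::create(_["k"] = hk, _["l"] = hl, _["ndiff"] = hd,
                      _["script"] = hs);
}
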