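// Core primitives for abundance-biased codon diversification:
//  - exact-repeat scanner (k-mer seeded, leftmost-maximal runs)
//  - Boltzmann repeat-interaction objective in log space
//  - longest common substring / maximal exact matches / dot plot
//  - greedy + simulated-annealing synonymous-codon search
#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <string>
#include <vector>

using namespace Rcpp;

static const double LN10 = 2.302585092994046;
// log10 floor standing in for the -Inf sentinel during annealing arithmetic
static const double E_SENTINEL = -9999.0;

static inline int b2i(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
  }
  return -1;
}

static std::vector<uint8_t> encode_dna(const std::string& s) {
  std::vector<uint8_t> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    int b = b2i(s[i]);
    if (b < 0)
      stop("non-ACGT character '%c' at position %d", s[i], (int)(i + 1));
    v[i] = (uint8_t)b;
  }
  return v;
}

// Online log-sum-exp accumulator (natural log).
struct LogSum {
  double mx, s;
  LogSum() : mx(R_NegInf), s(0.0) {}
  void add(double e) {
    if (!R_FINITE(mx) && s == 0.0) {
      mx = e;
      s = 1.0;
      return;
    }
    if (e > mx) {
      s = s * std::exp(mx - e) + 1.0;
      mx = e;
    } else {
      s += std::exp(e - mx);
    }
  }
  double value() const { return (s > 0.0) ? mx + std::log(s) : R_NegInf; }
};

// Versioned k-mer bucket table; reused across evaluations so a full rescore
// of a ~1.5 kb construct costs O(n) with no clearing or allocation.
struct RunScanner {
  int k;               // seed length actually indexed (<= min_match)
  size_t tsize;
  std::vector<int32_t> head;
  std::vector<uint32_t> stamp;
  std::vector<int32_t> nxt;
  uint32_t ver;

  RunScanner() : k(0), tsize(0), ver(0) {}

  void init(int seed_k, int nmax) {
    k = seed_k;
    tsize = (size_t)1 << (2 * k);
    head.assign(tsize, -1);
    stamp.assign(tsize, 0);
    nxt.assign((size_t)nmax, -1);
    ver = 0;
  }

  // Enumerate maximal exact repeats (x < y, length >= min_match) of C[0..n)
  // whose later copy intersects [ctx, n).  Each maximal run is reported once
  // (its first k-mer pair fails the left-extension test).
  template <typename F>
  void scan(const std::vector<uint8_t>& C, int n, int ctx, int min_match, F&& fn) {
    if (n < k) return;
    ++ver;
    uint32_t mask = (uint32_t)(tsize - 1);
    uint32_t code = 0;
    for (int i = 0; i < n; ++i) {
      code = ((code << 2) | C[i]) & mask;
      if (i < k - 1) continue;
      int s = i - k + 1;
      if (stamp[code] == ver) {
        for (int j = head[code]; j >= 0; j = nxt[j]) {
          if (j > 0 && s > 0 && C[j - 1] == C[s - 1]) continue;  // not run start
          int l = k;
          while (s + l < n && C[j + l] == C[s + l]) ++l;
          if (l >= min_match && s + l > ctx) fn(j, s, l);
        }
      } else {
        stamp[code] = ver;
        head[code] = -1;
      }
      nxt[s] = head[code];
      head[code] = s;
    }
  }
};

static inline int seed_k_for(int min_match) {
  int k = min_match;
  if (k > 10) k = 10;  // keep the bucket table small; runs are filtered on length
  if (k < 2) k = 2;
  return k;
}

struct ScoreResult {
  double log10_f;
  int max_run;
  long n_runs;
  // dominant (largest Boltzmann weight) repeat, for targeted search moves
  int dom_x, dom_y, dom_l;
};

// Objective: log10 sum over maximal exact repeats r of exp(-dG(r)/RT),
// dG(r) = nearest-neighbor stack sum over the matched run.
static ScoreResult score_runs(const std::vector<uint8_t>& C, int n, int ctx,
                              const double* stacks, double rt, double init_dg,
                              int min_match, RunScanner& sc,
                              std::vector<double>& ps) {
  ps.resize((size_t)std::max(n, 1));
  ps[0] = 0.0;
  for (int i = 0; i + 1 < n; ++i)
    ps[i + 1] = ps[i] + stacks[C[i] * 4 + C[i + 1]];
  LogSum ls;
  int maxrun = 0;
  long nruns = 0;
  double dom_e = R_NegInf;
  int dx = -1, dy = -1, dl = 0;
  sc.scan(C, n, ctx, min_match, [&](int x, int y, int l) {
    double dg = init_dg + ps[x + l - 1] - ps[x];
    double e = -dg / rt;
    ls.add(e);
    if (e > dom_e) {
      dom_e = e;
      dx = x;
      dy = y;
      dl = l;
    }
    if (l > maxrun) maxrun = l;
    ++nruns;
  });
  ScoreResult r;
  r.log10_f = ls.value() / LN10;  // -Inf when no run qualifies
  r.max_run = maxrun;
  r.n_runs = nruns;
  r.dom_x = dx;
  r.dom_y = dy;
  r.dom_l = dl;
  return r;
}

// [[Rcpp::export]]
List cpp_objective(std::string seq, std::string context, NumericVector stacks,
                   double rt, double init_dg, int min_match) {
  std::string full = context + seq;
  std::vector<uint8_t> C = encode_dna(full);
  int n = (int)C.size();
  int ctx = (int)context.size();
  RunScanner sc;
  sc.init(seed_k_for(min_match), std::max(n, 1));
  std::vector<double> ps;
  ScoreResult r = score_runs(C, n, ctx, REAL(stacks), rt, init_dg, min_match, sc, ps);
  return List::create(_["log10_f"] = r.log10_f, _["max_run"] = r.max_run,
                      _["n_runs"] = (double)r.n_runs);
}

// All maximal exact repeats (for reports); same semantics as the scorer.
// [[Rcpp::export]]
DataFrame cpp_self_runs(std::string seq, std::string context, int min_match) {
  std::string full = context + seq;
  std::vector<uint8_t> C = encode_dna(full);
  int n = (int)C.size();
  int ctx = (int)context.size();
  RunScanner sc;
  sc.init(seed_k_for(min_match), std::max(n, 1));
  std::vector<int> xs, ys, ls;
  sc.scan(C, n, ctx, min_match, [&](int x, int y, int l) {
    xs.push_back(x);
    ys.push_back(y);
    ls.push_back(l);
  });
  return DataFrame::create(_["pos_a"] = xs, _["pos_b"] = ys, _["length"] = ls);
}

// [[Rcpp::export]]
List cpp_lcs(std::string a, std::string b) {
  std::vector<uint8_t> A = encode_dna(a), B = encode_dna(b);
  int n = (int)A.size(), m = (int)B.size();
  int best = 0, ba = 0, bb = 0;
  for (int d = -(n - 1); d < m; ++d) {
    int i = d < 0 ? -d : 0;
    int j = d < 0 ? 0 : d;
    int run = 0;
    while (i < n && j < m) {
      if (A[i] == B[j]) {
        ++run;
        if (run > best) {
          best = run;
          ba = i - run + 1;
          bb = j - run + 1;
        }
      } else {
        run = 0;
      }
      ++i;
      ++j;
    }
  }
  return List::create(_["pos_a"] = ba, _["pos_b"] = bb, _["length"] = best);
}

// Maximal exact matches between two strings: maximal equal runs per diagonal.
// [[Rcpp::export]]
DataFrame cpp_mems(std::string a, std::string b, int min_len) {
  std::vector<uint8_t> A = encode_dna(a), B = encode_dna(b);
  int n = (int)A.size(), m = (int)B.size();
  std::vector<int> pa, pb, ln;
  for (int d = -(n - 1); d < m; ++d) {
    int i = d < 0 ? -d : 0;
    int j = d < 0 ? 0 : d;
    int run = 0;
    while (i < n && j < m) {
      if (A[i] == B[j]) {
        ++run;
      } else if (run > 0) {
        if (run >= min_len) {
          pa.push_back(i - run);
          pb.push_back(j - run);
          ln.push_back(run);
        }
        run = 0;
      }
      ++i;
      ++j;
    }
    if (run >= min_len) {
      pa.push_back(i - run);
      pb.push_back(j - run);
      ln.push_back(run);
    }
  }
  return DataFrame::create(_["pos_a"] = pa, _["pos_b"] = pb, _["length"] = ln);
}

// Every (i, j) with a[i:i+k] == b[j:j+k]; derived from diagonal runs.
// [[Rcpp::export]]
DataFrame cpp_dotplot(std::string a, std::string b, int k) {
  std::vector<uint8_t> A = encode_dna(a), B = encode_dna(b);
  int n = (int)A.size(), m = (int)B.size();
  std::vector<int> pa, pb;
  for (int d = -(n - 1); d < m; ++d) {
    int i = d < 0 ? -d : 0;
    int j = d < 0 ? 0 : d;
    int run = 0;
    while (i < n && j < m) {
      if (A[i] == B[j]) {
        ++run;
        if (run >= k) {
          pa.push_back(i - k + 1);
          pb.push_back(j - k + 1);
        }
      } else {
        run = 0;
      }
      ++i;
      ++j;
    }
  }
  return DataFrame::create(_["pos_a"] = pa, _["pos_b"] = pb);
}

// Duplex dG between two equal-length windows: locate the longest exact shared
// substring (ties: most negative dG); if shorter than min_match return NA.
// [[Rcpp::export]]
List cpp_duplex(std::string win_a, std::string win_b, NumericVector stacks,
                int min_match) {
  std::vector<uint8_t> A = encode_dna(win_a), B = encode_dna(win_b);
  int n = (int)A.size(), m = (int)B.size();
  const double* st = REAL(stacks);
  int best = 0;
  double bestdg = R_PosInf;
  for (int d = -(n - 1); d < m; ++d) {
    int i = d < 0 ? -d : 0;
    int j = d < 0 ? 0 : d;
    int run = 0;
    double dg = 0.0;
    while (i < n && j < m) {
      if (A[i] == B[j]) {
        if (run > 0) dg += st[A[i - 1] * 4 + A[i]];
        ++run;
        if (run > best || (run == best && dg < bestdg)) {
          best = run;
          bestdg = dg;
        }
      } else {
        run = 0;
        dg = 0.0;
      }
      ++i;
      ++j;
    }
  }
  if (best < min_match)
    return List::create(_["length"] = best, _["delta_g"] = R_NilValue);
  return List::create(_["length"] = best, _["delta_g"] = bestdg);
}

// ---------------------------------------------------------------------------
// Diversification search
// ---------------------------------------------------------------------------

struct Xoshiro {
  // mt19937 with hand-rolled draws so results are identical on any platform
  std::vector<uint32_t> dummy;
};

struct MT {
  uint32_t state[624];
  int idx;
  explicit MT(uint32_t seed) {
    state[0] = seed;
    for (int i = 1; i < 624; ++i)
      state[i] = 1812433253u * (state[i - 1] ^ (state[i - 1] >> 30)) + (uint32_t)i;
    idx = 624;
  }
  uint32_t next() {
    if (idx >= 624) {
      for (int i = 0; i < 624; ++i) {
        uint32_t y = (state[i] & 0x80000000u) | (state[(i + 1) % 624] & 0x7fffffffu);
        state[i] = state[(i + 397) % 624] ^ (y >> 1);
        if (y & 1u) state[i] ^= 2567483615u;
      }
      idx = 0;
    }
    uint32_t y = state[idx++];
    y ^= y >> 11;
    y ^= (y << 7) & 2636928640u;
    y ^= (y << 15) & 4022730752u;
    y ^= y >> 18;
    return y;
  }
  double unif() { return next() * 2.3283064365386963e-10; }  // [0, 1)
  int below(int m) { return (int)(next() % (uint32_t)m); }
};

static inline void place_codon(std::vector<uint8_t>& C, int pos, int code) {
  C[pos] = (uint8_t)((code >> 4) & 3);
  C[pos + 1] = (uint8_t)((code >> 2) & 3);
  C[pos + 2] = (uint8_t)(code & 3);
}

// Is any motif placed with start in [from, to] (clipped) fully inside
// C[0..built) while extending past the context (occurrences wholly inside the
// fixed context predate the design and are ignored)?
static int motif_hit(const std::vector<uint8_t>& C, int built, int ctx,
                     const std::vector<std::vector<uint8_t> >& motifs,
                     int from, int to, int* hit_pos) {
  for (size_t mi = 0; mi < motifs.size(); ++mi) {
    const std::vector<uint8_t>& M = motifs[mi];
    int L = (int)M.size();
    int lo = from - L + 1;
    if (lo < 0) lo = 0;
    int hi = to;
    if (hi > built - L) hi = built - L;
    for (int s = lo; s <= hi; ++s) {
      if (s + L <= ctx) continue;
      bool ok = true;
      for (int t = 0; t < L; ++t) {
        if (C[s + t] != M[t]) {
          ok = false;
          break;
        }
      }
      if (ok) {
        if (hit_pos) *hit_pos = s;
        return (int)mi;
      }
    }
  }
  return -1;
}

// [[Rcpp::export]]
List cpp_diversify(std::string context, List allowed, List fracs,
                   CharacterVector motifs, CharacterVector motif_names,
                   NumericVector stacks, double rt,
                   double init_dg, int min_match, std::string fixed_suffix,
                   int budget, int seed, int restarts, double t_start,
                   double t_end) {
  int P = allowed.size();
  if (P < 1) stop("empty protein");
  int ctx = (int)context.size();
  int suf = (int)fixed_suffix.size();
  int n = ctx + 3 * P + suf;

  std::vector<uint8_t> C(n, 0);
  {
    std::vector<uint8_t> cv = encode_dna(context);
    for (int i = 0; i < ctx; ++i) C[i] = cv[i];
    std::vector<uint8_t> sv = encode_dna(fixed_suffix);
    for (int i = 0; i < suf; ++i) C[ctx + 3 * P + i] = sv[i];
  }

  std::vector<std::vector<int> > cand(P);
  std::vector<std::vector<double> > cfrac(P);
  for (int t = 0; t < P; ++t) {
    IntegerVector cv = allowed[t];
    NumericVector fv = fracs[t];
    if (cv.size() < 1) stop("no allowed codon for residue %d", t + 1);
    cand[t].assign(cv.begin(), cv.end());
    cfrac[t].assign(fv.begin(), fv.end());
  }

  std::vector<std::vector<uint8_t> > mots;
  int maxmot = 0;
  for (int i = 0; i < motifs.size(); ++i) {
    std::string m = as<std::string>(motifs[i]);
    mots.push_back(encode_dna(m));
    if ((int)m.size() > maxmot) maxmot = (int)m.size();
  }

  RunScanner sc;
  sc.init(seed_k_for(min_match), n);
  std::vector<double> ps;

  // ---- greedy construction with bounded backtracking over motif conflicts
  std::vector<std::vector<int> > order(P);   // candidate order per slot
  std::vector<int> pick(P, -1);              // index into order
  long backtracks = 0;
  const long max_backtracks = 20000;
  int t = 0;
  int last_block_motif = -1, last_block_pos = -1;
  while (t < P) {
    int pos = ctx + 3 * t;
    int built = ctx + 3 * (t + 1) + (t == P - 1 ? suf : 0);
    if (pick[t] < 0) {
      // rank candidates by (objective asc, family fraction desc, codon asc)
      int nc = (int)cand[t].size();
      std::vector<double> sc_val(nc);
      for (int c = 0; c < nc; ++c) {
        place_codon(C, pos, cand[t][c]);
        ScoreResult r = score_runs(C, built, ctx, REAL(stacks), rt, init_dg, min_match, sc, ps);
        sc_val[c] = R_FINITE(r.log10_f) ? r.log10_f : E_SENTINEL;
      }
      std::vector<int> ord(nc);
      for (int c = 0; c < nc; ++c) ord[c] = c;
      std::sort(ord.begin(), ord.end(), [&](int u, int v) {
        if (sc_val[u] != sc_val[v]) return sc_val[u] < sc_val[v];
        if (cfrac[t][u] != cfrac[t][v]) return cfrac[t][u] > cfrac[t][v];
        return cand[t][u] < cand[t][v];
      });
      order[t] = ord;
      pick[t] = 0;
    }
    bool placed = false;
    while (pick[t] < (int)order[t].size()) {
      int code = cand[t][order[t][pick[t]]];
      place_codon(C, pos, code);
      int hp = -1;
      int hm = motif_hit(C, built, ctx, mots, pos - maxmot + 1,
                         pos + 2 + (t == P - 1 ? suf : 0), &hp);
      if (hm < 0) {
        placed = true;
        break;
      }
      last_block_motif = hm;
      last_block_pos = hp;
      ++pick[t];
    }
    if (placed) {
      ++t;
    } else {
      pick[t] = -1;
      --t;
      if (t < 0 || ++backtracks > max_backtracks) {
        std::string nm = "?";
        if (last_block_motif >= 0 && last_block_motif < motifs.size()) {
          nm = (last_block_motif < motif_names.size())
                   ? as<std::string>(motif_names[last_block_motif])
                   : as<std::string>(motifs[last_block_motif]);
        }
        stop("infeasible: forbidden motif '%s' unavoidable near position %d",
             nm.c_str(), last_block_pos + 1);
      }
      ++pick[t];
    }
  }

  ScoreResult cur = score_runs(C, n, ctx, REAL(stacks), rt, init_dg, min_match, sc, ps);
  double e_cur = R_FINITE(cur.log10_f) ? cur.log10_f : E_SENTINEL;
  std::vector<uint8_t> best = C;
  double e_best = e_cur;
  int best_maxrun = cur.max_run;

  // ---- simulated annealing refinement with targeted moves
  // Half of the proposals mutate a codon inside the current dominant repeat
  // (the term that owns the log-sum), which is the move that can actually
  // lower the objective; the rest explore uniformly.
  MT rng((uint32_t)seed);
  long used = 0;
  if (budget > 0 && P >= 1) {
    if (restarts < 1) restarts = 1;
    long per = budget / restarts;
    if (per < 1) per = 1;
    for (int ph = 0; ph < restarts && used < budget; ++ph) {
      // each phase restarts the cooling schedule from the best solution so far
      C = best;
      cur = score_runs(C, n, ctx, REAL(stacks), rt, init_dg, min_match, sc, ps);
      e_cur = R_FINITE(cur.log10_f) ? cur.log10_f : E_SENTINEL;
      double cool = (per > 1) ? std::pow(t_end / t_start, 1.0 / (double)(per - 1)) : 1.0;
      double T = t_start;
      for (long it = 0; it < per && used < budget; ++it, ++used, T *= cool) {
        int slot = -1;
        // targeted proposal: a designable position inside the dominant repeat
        if (cur.dom_l > 0 && (rng.next() & 1u)) {
          int off = rng.below(cur.dom_l);
          int p = (rng.next() & 1u) ? cur.dom_y + off : cur.dom_x + off;
          if (p < ctx) p = cur.dom_y + off;          // context copy is fixed
          if (p >= ctx && p < ctx + 3 * P) slot = (p - ctx) / 3;
        }
        if (slot < 0) slot = rng.below(P);
        int nc = (int)cand[slot].size();
        if (nc < 2) continue;
        int pos = ctx + 3 * slot;
        int old0 = C[pos], old1 = C[pos + 1], old2 = C[pos + 2];
        int oldcode = (old0 << 4) | (old1 << 2) | old2;
        int code = cand[slot][rng.below(nc)];
        if (code == oldcode) continue;
        place_codon(C, pos, code);
        if (motif_hit(C, n, ctx, mots, pos - maxmot + 1, pos + 2, 0) >= 0) {
          C[pos] = (uint8_t)old0;
          C[pos + 1] = (uint8_t)old1;
          C[pos + 2] = (uint8_t)old2;
          continue;
        }
        ScoreResult nw = score_runs(C, n, ctx, REAL(stacks), rt, init_dg, min_match, sc, ps);
        double e_new = R_FINITE(nw.log10_f) ? nw.log10_f : E_SENTINEL;
        bool acc = (e_new <= e_cur) ||
                   (rng.unif() < std::exp((e_cur - e_new) / T));
        if (acc) {
          e_cur = e_new;
          cur = nw;
          if (e_new < e_best) {
            e_best = e_new;
            best = C;
            best_maxrun = nw.max_run;
          }
        } else {
          C[pos] = (uint8_t)old0;
          C[pos + 1] = (uint8_t)old1;
          C[pos + 2] = (uint8_t)old2;
        }
      }
    }
  }

  static const char* b2c = "ACGT";
  std::string out(3 * P + suf, 'A');
  for (int i = 0; i < 3 * P + suf; ++i) out[i] = b2c[best[ctx + i]];
  double log10f = (e_best <= E_SENTINEL) ? R_NegInf : e_best;
  return List::create(_["seq"] = out, _["log10_f"] = log10f,
                      _["max_run"] = best_maxrun, _["iterations"] = (double)used);
}
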