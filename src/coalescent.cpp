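// Ancestral recombination graph simulator for a single [0,1) region.
//
// Time is measured backward from the present in units of 4*N0 generations,
// where N0 is the present-day (island) effective size. Rates follow the ms
// conventions: pairwise coalescence at 2/f in a deme of relative size f,
// per-lineage recombination at rho * integral of the local intensity over the
// lineage's ancestral-material span, per-lineage mutation at theta * material
// length, infinite-sites placement. A hard complete sweep is simulated as a
// structured coalescent conditioned on a (deterministic) allele-frequency
// trajectory supplied from R as a piecewise-constant backward grid: lineages
// carry the allelic class at the selected site, coalesce only within class at
// rates inversely proportional to the class frequency, and recombination
// between a lineage's material and the selected site re-draws its class from
// the current frequency.

#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

typedef uint64_t mask_t;

struct Seg {
  double l, r;
  mask_t d;  // descendant sample set; never 0 and never the full set
};

struct Lin {
  std::vector<Seg> segs;
  double mlen;  // cached total material length
  int deme;     // 0 = island / single population, 1 = continent
  int cls;      // 0 = ancestral background, 1 = beneficial; valid in sweep phase
};

struct Mut {
  double pos;
  mask_t d;
};

static const double TINF = 1e300;

static double seg_len(const std::vector<Seg>& s) {
  double t = 0;
  for (const Seg& x : s) t += x.r - x.l;
  return t;
}

// --- recombination map: breaks[0]=0 < ... < breaks[m]=1, intensity lam[i] on
// [breaks[i], breaks[i+1]) ---
struct RecMap {
  std::vector<double> br, lam, cum;
  void init(const NumericVector& b, const NumericVector& l) {
    br.assign(b.begin(), b.end());
    lam.assign(l.begin(), l.end());
    cum.assign(br.size(), 0.0);
    for (size_t i = 1; i < br.size(); ++i)
      cum[i] = cum[i - 1] + lam[i - 1] * (br[i] - br[i - 1]);
  }
  double at(double x) const {
    if (x <= 0) return 0;
    if (x >= 1) return cum.back();
    size_t i = std::upper_bound(br.begin(), br.end(), x) - br.begin() - 1;
    return cum[i] + lam[i] * (x - br[i]);
  }
  bool uniform() const { return lam.size() == 1; }
  double weight(double a, double b) const {
    if (uniform()) return (b - a) * lam[0];
    return at(b) - at(a);
  }
  double inv(double c) const {
    size_t i = std::upper_bound(cum.begin(), cum.end(), c) - cum.begin();
    if (i == 0) i = 1;
    if (i >= br.size()) i = br.size() - 1;
    double x = br[i - 1] + (c - cum[i - 1]) / lam[i - 1];
    if (x < 0) x = 0;
    if (x > 1) x = 1;
    return x;
  }
  double draw(double a, double b) const {  // breakpoint in (a,b) by intensity
    if (uniform()) return a + unif_rand() * (b - a);
    double ca = at(a), cb = at(b);
    return inv(ca + unif_rand() * (cb - ca));
  }
};

static std::vector<Seg> merge_segs(const std::vector<Seg>& A,
                                   const std::vector<Seg>& B, mask_t full) {
  std::vector<Seg> out;
  size_t ia = 0, ib = 0;
  double cur = 2.0;
  if (!A.empty()) cur = std::min(cur, A[0].l);
  if (!B.empty()) cur = std::min(cur, B[0].l);
  while (true) {
    while (ia < A.size() && A[ia].r <= cur) ++ia;
    while (ib < B.size() && B[ib].r <= cur) ++ib;
    if (ia >= A.size() && ib >= B.size()) break;
    double aL = ia < A.size() ? A[ia].l : 2.0, aR = ia < A.size() ? A[ia].r : 2.0;
    double bL = ib < B.size() ? B[ib].l : 2.0, bR = ib < B.size() ? B[ib].r : 2.0;
    double start = cur;
    double low = std::min(aL, bL);
    if (start < low) start = low;
    bool inA = (aL <= start && start < aR);
    bool inB = (bL <= start && start < bR);
    double end = 2.0;
    end = std::min(end, inA ? aR : aL);
    end = std::min(end, inB ? bR : bL);
    mask_t d = (inA ? A[ia].d : 0) | (inB ? B[ib].d : 0);
    if (d != 0 && d != full) {
      if (!out.empty() && out.back().r == start && out.back().d == d)
        out.back().r = end;
      else
        out.push_back({start, end, d});
    }
    cur = end;
  }
  return out;
}

static void split_segs(const std::vector<Seg>& S, double x,
                       std::vector<Seg>& L, std::vector<Seg>& R) {
  L.clear(); R.clear();
  for (const Seg& s : S) {
    if (s.r <= x) L.push_back(s);
    else if (s.l >= x) R.push_back(s);
    else { L.push_back({s.l, x, s.d}); R.push_back({x, s.r, s.d}); }
  }
}

// boundary-event schedule
struct BEvent {
  double t;
  int type;     // 0 = size change, 1 = join, 2 = sweep fixation (enter sweep),
                // 3 = sweep grid step, 4 = sweep origin (leave sweep)
  double val;   // new size for type 0; frequency for type 3
  int idx;
};

// [[Rcpp::export(name = ".sim_coalescent_cpp")]]
List sim_coalescent_cpp(int n, double theta, double rho,
                        NumericVector hot_breaks, NumericVector hot_lam,
                        NumericMatrix epochs,        // cols: time, size
                        double mig_rate,             // per-lineage, <0 disables
                        double cont_size, double join_time,
                        bool has_sweep, double sweep_pos,
                        double sweep_end, double sweep_dur,
                        NumericVector traj_freq,     // backward grid, piecewise const
                        int nreps) {
  if (n < 2 || n > 64) stop("sample size must be between 2 and 64");
  mask_t full = (n == 64) ? ~(mask_t)0 : (((mask_t)1 << n) - 1);
  RecMap rmap; rmap.init(hot_breaks, hot_lam);
  bool two_demes = (mig_rate >= 0);

  // static boundary schedule (shared across replicates)
  std::vector<BEvent> sched;
  for (int i = 0; i < epochs.nrow(); ++i)
    sched.push_back({epochs(i, 0), 0, epochs(i, 1), i});
  if (two_demes && join_time >= 0) sched.push_back({join_time, 1, 0, 0});
  int G = traj_freq.size();
  if (has_sweep) {
    sched.push_back({sweep_end, 2, 0, 0});
    for (int j = 1; j < G; ++j)
      sched.push_back({sweep_end + sweep_dur * j / G, 3, traj_freq[j], j});
    sched.push_back({sweep_end + sweep_dur, 4, 0, 0});
  }
  std::sort(sched.begin(), sched.end(),
            [](const BEvent& a, const BEvent& b) {
              return a.t < b.t || (a.t == b.t && a.type < b.type);
            });

  List reps(nreps);
  for (int rep = 0; rep < nreps; ++rep) {
    std::vector<Lin> lins(n);
    for (int i = 0; i < n; ++i) {
      lins[i].segs = {{0.0, 1.0, (mask_t)1 << i}};
      lins[i].mlen = 1.0;
      lins[i].deme = 0;
      lins[i].cls = 0;
    }
    std::vector<Mut> muts;
    double t = 0.0;
    double fsz[2] = {1.0, cont_size};
    bool in_sweep = false, joined = false;
    double x = 1.0;                 // sweep-allele frequency (backward)
    size_t bptr = 0;
    long long guard = 0;
    std::vector<double> w;

    while (lins.size() > 1) {
      if (++guard > 200000000LL) stop("event limit exceeded");
      // per-iteration rates
      int k0B = 0, k0b = 0, k1 = 0;
      double wrec = 0, mtot = 0;
      w.resize(lins.size());
      for (size_t i = 0; i < lins.size(); ++i) {
        Lin& L = lins[i];
        mtot += L.mlen;
        double a = L.segs.front().l, b = L.segs.back().r;
        if (in_sweep && L.deme == 0) {
          a = std::min(a, sweep_pos); b = std::max(b, sweep_pos);
        }
        w[i] = rho > 0 ? rho * rmap.weight(a, b) : 0.0;
        wrec += w[i];
        if (L.deme == 1) ++k1;
        else if (in_sweep && L.cls == 1) ++k0B;
        else ++k0b;
      }
      double rc0B = 0, rc0b = 0, rc1 = 0, rmig = 0;
      if (in_sweep) {
        rc0B = (double)k0B * (k0B - 1) / (x * fsz[0]);
        rc0b = (double)k0b * (k0b - 1) / ((1.0 - x) * fsz[0]);
      } else {
        rc0b = (double)(k0B + k0b) * (k0B + k0b - 1) / fsz[0];
      }
      if (two_demes && !joined) {
        rc1 = (double)k1 * (k1 - 1) / fsz[1];
        rmig = mig_rate * (in_sweep ? k0b : (k0B + k0b));
      } else if (two_demes) {
        rc1 = (double)k1 * (k1 - 1) / fsz[1];
      }
      double total = rc0B + rc0b + rc1 + wrec + rmig;

      double tb = bptr < sched.size() ? sched[bptr].t : TINF;
      double wait = total > 0 ? exp_rand() / total : TINF;
      double dt = std::min(wait, tb - t);
      if (dt == TINF) stop("internal: no events possible");

      // mutations over the elapsed interval
      if (theta > 0 && dt > 0 && mtot > 0) {
        int nm = (int)R::rpois(theta * dt * mtot);
        for (int m = 0; m < nm; ++m) {
          double u = unif_rand() * mtot;
          size_t i = 0;
          while (i + 1 < lins.size() && u > lins[i].mlen) { u -= lins[i].mlen; ++i; }
          double v = unif_rand() * lins[i].mlen;
          for (const Seg& s : lins[i].segs) {
            double len = s.r - s.l;
            if (v <= len) { muts.push_back({s.l + v, s.d}); break; }
            v -= len;
          }
        }
      }

      if (tb - t <= wait) {  // boundary first
        t = tb;
        const BEvent& be = sched[bptr++];
        switch (be.type) {
          case 0: fsz[0] = be.val; if (two_demes) fsz[1] = be.val; break;
          case 1:
            joined = true;
            for (Lin& L : lins) L.deme = 1;
            break;
          case 2:
            in_sweep = true;
            x = traj_freq[0];
            for (Lin& L : lins) L.cls = (L.deme == 0) ? 1 : 0;
            break;
          case 3: x = be.val; break;
          case 4: {
            in_sweep = false;
            // all beneficial-class lineages descend from the single origin
            std::vector<size_t> bidx;
            for (size_t i = 0; i < lins.size(); ++i)
              if (lins[i].deme == 0 && lins[i].cls == 1) bidx.push_back(i);
            if (bidx.size() > 1) {
              std::vector<Seg> acc = lins[bidx[0]].segs;
              for (size_t j = 1; j < bidx.size(); ++j)
                acc = merge_segs(acc, lins[bidx[j]].segs, full);
              lins[bidx[0]].segs = acc;
              lins[bidx[0]].mlen = seg_len(acc);
              lins[bidx[0]].cls = 0;
              for (size_t j = bidx.size(); j-- > 1;)
                lins.erase(lins.begin() + bidx[j]);
              if (lins[bidx[0]].segs.empty()) lins.erase(lins.begin() + bidx[0]);
            } else if (bidx.size() == 1) {
              lins[bidx[0]].cls = 0;
            }
            break;
          }
        }
        continue;
      }

      t += wait;
      double u = unif_rand() * total;
      if (u < rc0B + rc0b + rc1) {
        // a coalescence in one of the three groups
        int deme, cls;
        if (u < rc0B) { deme = 0; cls = 1; }
        else if (u < rc0B + rc0b) { deme = 0; cls = 0; }
        else { deme = 1; cls = -1; }
        std::vector<size_t> idx;
        for (size_t i = 0; i < lins.size(); ++i) {
          const Lin& L = lins[i];
          if (deme == 1) { if (L.deme == 1) idx.push_back(i); }
          else if (L.deme == 0 &&
                   (!in_sweep || L.cls == cls)) idx.push_back(i);
        }
        if (idx.size() < 2) continue;  // raced with a boundary; redraw
        size_t a = idx[(size_t)(unif_rand() * idx.size())];
        size_t b;
        do { b = idx[(size_t)(unif_rand() * idx.size())]; } while (b == a);
        if (a > b) std::swap(a, b);
        lins[a].segs = merge_segs(lins[a].segs, lins[b].segs, full);
        lins[a].mlen = seg_len(lins[a].segs);
        lins.erase(lins.begin() + b);
        if (lins[a].segs.empty()) lins.erase(lins.begin() + a);
      } else if (u < rc0B + rc0b + rc1 + wrec) {
        // recombination
        double v = u - (rc0B + rc0b + rc1);
        size_t i = 0;
        while (i + 1 < lins.size() && v > w[i]) { v -= w[i]; ++i; }
        Lin& L = lins[i];
        double a = L.segs.front().l, b = L.segs.back().r;
        double lo = a, hi = b;
        if (in_sweep && L.deme == 0) {
          lo = std::min(a, sweep_pos); hi = std::max(b, sweep_pos);
        }
        double bp = rmap.draw(lo, hi);
        if (bp > a && bp < b) {
          std::vector<Seg> SL, SR;
          split_segs(L.segs, bp, SL, SR);
          if (SL.empty() || SR.empty()) continue;  // breakpoint grazed an edge
          Lin NL; NL.deme = L.deme; NL.cls = L.cls;
          if (in_sweep && L.deme == 0) {
            int away_cls = (unif_rand() < x) ? 1 : 0;
            if (sweep_pos >= bp) {  // right piece stays linked to the site
              NL.segs = SL; NL.cls = away_cls;
              L.segs = SR;
            } else {
              NL.segs = SR; NL.cls = away_cls;
              L.segs = SL;
            }
          } else {
            NL.segs = SR;
            L.segs = SL;
          }
          L.mlen = seg_len(L.segs);
          NL.mlen = seg_len(NL.segs);
          lins.push_back(NL);
        } else if (in_sweep && L.deme == 0) {
          // breakpoint between the material and the selected site:
          // the whole lineage hops onto a random background
          L.cls = (unif_rand() < x) ? 1 : 0;
        }
      } else {
        // migration: island (background class during the sweep) -> continent
        std::vector<size_t> idx;
        for (size_t i = 0; i < lins.size(); ++i)
          if (lins[i].deme == 0 && (!in_sweep || lins[i].cls == 0))
            idx.push_back(i);
        if (idx.empty()) continue;
        lins[idx[(size_t)(unif_rand() * idx.size())]].deme = 1;
      }
    }

    std::sort(muts.begin(), muts.end(),
              [](const Mut& a, const Mut& b) { return a.pos < b.pos; });
    int T = muts.size();
    NumericVector pos(T);
    IntegerMatrix haps(n, T);
    for (int j = 0; j < T; ++j) {
      pos[j] = muts[j].pos;
      for (int i = 0; i < n; ++i)
        haps(i, j) = (muts[j].d >> i) & 1 ? 1 : 0;
    }
    reps[rep] = List::create(Named("positions") = pos, Named("haplotypes") = haps);
  }
  return reps;
}
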