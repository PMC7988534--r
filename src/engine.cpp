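// Event-driven (discontinuous) molecular dynamics core.
//
// Beads move ballistically between analytically predicted discontinuity
// crossings: hard cores, square-well edges, bond walls, directional
// hydrogen-bond wells, Andersen-thermostat ghost collisions and cell-list
// crossings.  Scheduling uses the classic one-slot-per-particle scheme:
// every rescan of a bead pushes only its earliest candidate event; stale
// events (per-bead counter mismatch) trigger a rescan when popped.  Units:
// lengths in Angstrom, energies in eps_HB, masses in Da; the time unit tau
// follows from these.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <unordered_set>
#include <cmath>
#include <cstdint>
#include <random>
#include <limits>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

enum EvKind {
  EV_CORE = 0, EV_WELL_IN = 1, EV_WELL_OUT = 2, EV_WALL_IN = 3,
  EV_WALL_OUT = 4, EV_HB_FORM = 5, EV_HB_BREAK = 6, EV_CELL = 7,
  EV_GHOST = 8, EV_SNAP = 9, EV_NONE = 10
};

struct Ev {
  double t;
  int kind;
  int i, j;           // participants; j < 0 for single-bead/global events
  int owner;          // slot ownership: bit 1 = bead i's slot, bit 2 = j's
  std::uint64_t ci, cj;
};

struct EvCmp {
  bool operator()(const Ev& a, const Ev& b) const {
    if (a.t != b.t) return a.t > b.t;
    if (a.kind != b.kind) return a.kind > b.kind;
    if (a.i != b.i) return a.i > b.i;
    return a.j > b.j;
  }
};

// stable roots of |d + v t| = R
static inline double rootInward(double a, double b, double c2, double R2) {
  if (b >= 0.0 || a <= 0.0) return INF;
  double disc = b * b - a * (c2 - R2);
  if (disc <= 0.0) return INF;
  return (c2 - R2) / (-b + std::sqrt(disc));
}
static inline double rootOutward(double a, double b, double c2, double R2) {
  if (a <= 0.0) return INF;
  double disc = b * b + a * (R2 - c2);
  if (disc < 0.0) return INF;
  return (-b + std::sqrt(disc)) / a;
}

// pair interaction modes
enum PairMode { PM_NONE, PM_WALL, PM_CORE, PM_SW, PM_HB };

struct Engine {
  int n;                 // beads
  int mchain;            // beads per chain
  double L;              // box edge
  std::vector<double> pos, vel;   // 3n, positions at per-bead time t0
  std::vector<double> t0;
  std::vector<std::uint64_t> cc;  // per-bead event counters
  std::vector<int> chain, resi, type, res20;
  std::vector<double> radius, mass;
  std::vector<int> aux1, aux2;    // auxiliary beads for HB directionality

  // same-chain exclusion tables (local index pairs)
  std::vector<int> excl;          // mchain*mchain codes
  std::vector<double> wmin, wmax;
  std::vector<std::vector<int>> near_partners;  // per local bead

  // sidechain square wells (20x20)
  std::vector<double> sww, swd;
  double hbW, hbCore, hbDepth, hbAux, coreScale;
  int hbMinSep;

  // dynamic interaction state
  std::vector<int> hbp;           // hydrogen-bond partner bead (or -1)
  std::unordered_set<long long> wellSet;
  double PE;

  // cells
  bool useCells;
  int nc;
  double cellw;
  std::vector<int> cellOf;                 // flat cell index per bead
  std::vector<std::vector<int>> cells;

  std::priority_queue<Ev, std::vector<Ev>, EvCmp> q;
  double clock_;
  std::mt19937_64 rng;
  std::normal_distribution<double> gauss;

  double tstar, ghostRate;
  double Eref, maxEdrift, maxPEerr, maxOverlap;
  long long nAudit;
  bool err;
  std::string errMsg;

  std::vector<char> touched;
  std::uint64_t touchGen;
  std::vector<std::uint64_t> touchStamp;

  long long evCount[11];
  long long nPush, nPop, nScan, nPredict;

  // ---- geometry helpers ----
  inline double mind(double d) const {
    // branchy minimum image: positions stay within ~1.5 L of the primary
    // box (cell crossings re-wrap), so one fold almost always suffices
    double hl = 0.5 * L;
    while (d > hl) d -= L;
    while (d < -hl) d += L;
    return d;
  }
  inline void posAt(int i, double t, double* out) const {
    double dt = t - t0[i];
    out[0] = pos[3 * i] + vel[3 * i] * dt;
    out[1] = pos[3 * i + 1] + vel[3 * i + 1] * dt;
    out[2] = pos[3 * i + 2] + vel[3 * i + 2] * dt;
  }
  inline void advance(int i, double t) {
    double dt = t - t0[i];
    pos[3 * i] += vel[3 * i] * dt;
    pos[3 * i + 1] += vel[3 * i + 1] * dt;
    pos[3 * i + 2] += vel[3 * i + 2] * dt;
    t0[i] = t;
  }
  inline double dist2At(int i, int j, double t) const {
    double pi[3], pj[3];
    posAt(i, t, pi); posAt(j, t, pj);
    double s = 0;
    for (int k = 0; k < 3; ++k) { double d = mind(pj[k] - pi[k]); s += d * d; }
    return s;
  }
  inline long long pairKey(int i, int j) const {
    int a = i < j ? i : j, b = i < j ? j : i;
    return (long long)a * (long long)n + b;
  }

  struct PInfo {
    int mode;
    double core, well, depth, wlo, whi;
    int nh, co;  // for HB pairs
  };

  PInfo pairInfo(int i, int j) const {
    PInfo p; p.mode = PM_CORE; p.core = radius[i] + radius[j];
    p.well = 0; p.depth = 0; p.wlo = 0; p.whi = 0; p.nh = -1; p.co = -1;
    bool same = chain[i] == chain[j];
    if (same) {
      int li = i - chain[i] * mchain, lj = j - chain[j] * mchain;
      int code = excl[li * mchain + lj];
      if (code == 1) {
        p.mode = PM_WALL;
        p.wlo = wmin[li * mchain + lj];
        p.whi = wmax[li * mchain + lj];
        return p;
      }
      if (code == 2) { p.core *= coreScale; return p; }
    }
    int sep = std::abs(resi[i] - resi[j]);
    bool eligible = !same || sep >= hbMinSep;
    if (eligible) {
      if ((type[i] == 0 && type[j] == 2) || (type[i] == 2 && type[j] == 0)) {
        p.mode = PM_HB;
        p.core = hbCore; p.well = hbW; p.depth = hbDepth;
        p.nh = type[i] == 0 ? i : j;
        p.co = type[i] == 0 ? j : i;
        return p;
      }
      if (type[i] == 3 && type[j] == 3) {
        double d = swd[res20[i] * 20 + res20[j]];
        if (d > 0) {
          p.mode = PM_SW;
          p.well = sww[res20[i] * 20 + res20[j]];
          p.depth = d;
          return p;
        }
      }
    }
    return p;
  }

  // earliest discontinuity of a pair, relative to absolute time tnow
  bool predictPair(int i, int j, double tnow, Ev& out) {
    nPredict++;
    PInfo p = pairInfo(i, j);
    double pi[3], pj[3];
    posAt(i, tnow, pi); posAt(j, tnow, pj);
    double d[3], v[3];
    for (int k = 0; k < 3; ++k) {
      d[k] = mind(pj[k] - pi[k]);
      v[k] = vel[3 * j + k] - vel[3 * i + k];
    }
    double a = v[0] * v[0] + v[1] * v[1] + v[2] * v[2];
    double b = d[0] * v[0] + d[1] * v[1] + d[2] * v[2];
    double c2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
    double t = INF; int kind = EV_NONE;
    if (p.mode == PM_WALL) {
      double lo2 = p.wlo * p.wlo, hi2 = p.whi * p.whi;
      double tin;
      if (c2 <= lo2) tin = (b < 0) ? 0.0 : INF;
      else tin = rootInward(a, b, c2, lo2);
      double tout;
      if (c2 >= hi2 && b > 0) tout = 0.0;
      else tout = rootOutward(a, b, c2, hi2);
      if (tin < tout) { t = tin; kind = EV_WALL_IN; }
      else { t = tout; kind = EV_WALL_OUT; }
    } else if (p.mode == PM_CORE) {
      double R2 = p.core * p.core;
      if (c2 <= R2) { if (b < 0) { t = 0.0; kind = EV_CORE; } }
      else { t = rootInward(a, b, c2, R2); kind = EV_CORE; }
    } else if (p.mode == PM_SW) {
      double R2 = p.core * p.core, W2 = p.well * p.well;
      bool occ = wellSet.count(pairKey(i, j)) > 0;
      if (occ) {
        double tc;
        if (c2 <= R2) tc = (b < 0) ? 0.0 : INF;
        else tc = rootInward(a, b, c2, R2);
        double tw;
        if (c2 >= W2 && b > 0) tw = 0.0;
        else tw = rootOutward(a, b, c2, W2);
        if (tc < tw) { t = tc; kind = EV_CORE; }
        else { t = tw; kind = EV_WELL_OUT; }
      } else {
        t = rootInward(a, b, c2, W2);
        kind = EV_WELL_IN;
      }
    } else if (p.mode == PM_HB) {
      double R2 = p.core * p.core, W2 = p.well * p.well;
      bool bonded = hbp[p.nh] == p.co;
      if (bonded) {
        double tc;
        if (c2 <= R2) tc = (b < 0) ? 0.0 : INF;
        else tc = rootInward(a, b, c2, R2);
        double tw;
        if (c2 >= W2 && b > 0) tw = 0.0;
        else tw = rootOutward(a, b, c2, W2);
        if (tc < tw) { t = tc; kind = EV_CORE; }
        else { t = tw; kind = EV_HB_BREAK; }
      } else if (c2 > W2 * (1.0 + 1e-9)) {
        bool bothFree = hbp[p.nh] < 0 && hbp[p.co] < 0;
        if (bothFree) { t = rootInward(a, b, c2, W2); kind = EV_HB_FORM; }
        else { t = rootInward(a, b, c2, R2); kind = EV_CORE; }
      } else {
        // inside the well but unbonded (failed or ineligible formation)
        if (c2 <= R2) { if (b < 0) { t = 0.0; kind = EV_CORE; } }
        else { t = rootInward(a, b, c2, R2); kind = EV_CORE; }
      }
    }
    if (!(t < INF)) return false;
    out.t = tnow + t; out.kind = kind; out.i = i; out.j = j;
    out.ci = cc[i]; out.cj = cc[j];
    return true;
  }

  // ---- cells ----
  inline int cellIndex(double x, double y, double z) const {
    int cx = (int)std::floor(x / cellw), cy = (int)std::floor(y / cellw),
        cz = (int)std::floor(z / cellw);
    cx = ((cx % nc) + nc) % nc; cy = ((cy % nc) + nc) % nc;
    cz = ((cz % nc) + nc) % nc;
    return (cx * nc + cy) * nc + cz;
  }
  void cellInsert(int i) {
    double p[3] = {pos[3 * i], pos[3 * i + 1], pos[3 * i + 2]};
    // nudge along velocity so beads sitting exactly on a boundary land on
    // the side they are moving toward
    int ci = cellIndex(p[0] + 1e-9 * sgn(vel[3 * i]),
                       p[1] + 1e-9 * sgn(vel[3 * i + 1]),
                       p[2] + 1e-9 * sgn(vel[3 * i + 2]));
    cellOf[i] = ci;
    cells[ci].push_back(i);
  }
  static inline double sgn(double x) { return x > 0 ? 1.0 : (x < 0 ? -1.0 : 0.0); }
  void cellRemove(int i) {
    std::vector<int>& v = cells[cellOf[i]];
    for (size_t k = 0; k < v.size(); ++k)
      if (v[k] == i) { v[k] = v.back(); v.pop_back(); break; }
  }
  // earliest cell-boundary crossing for bead i (absolute time)
  bool predictCell(int i, double tnow, Ev& out) {
    if (!useCells) return false;
    double p[3]; posAt(i, tnow, p);
    int ci = cellOf[i];
    int cz = ci % nc, cy = (ci / nc) % nc, cx = ci / (nc * nc);
    int cidx[3] = {cx, cy, cz};
    double tmin = INF;
    for (int k = 0; k < 3; ++k) {
      double v = vel[3 * i + k];
      if (v == 0) continue;
      // unwrapped coordinate consistent with the stored cell
      double x = p[k] - L * std::floor(p[k] / L);
      double lo = cidx[k] * cellw, hi = (cidx[k] + 1) * cellw;
      // x should be within [lo,hi]; tolerate wrap mismatches
      if (x < lo - 0.5 * L) x += L;
      if (x > hi + 0.5 * L) x -= L;
      double tc = v > 0 ? (hi - x) / v : (lo - x) / v;
      if (tc < 0) tc = 0;
      if (tc < tmin) tmin = tc;
    }
    if (!(tmin < INF)) return false;
    out.t = tnow + tmin; out.kind = EV_CELL; out.i = i; out.j = -1;
    out.ci = cc[i]; out.cj = 0;
    return true;
  }

  // ---- rescans (one-slot scheduling) ----
  // the earliest candidate event of bead i (its prospective slot event)
  Ev computeBest(int i, double tnow) {
    nScan++;
    Ev best; best.t = INF; best.kind = EV_NONE;
    Ev cand;
    if (predictCell(i, tnow, cand)) best = cand;
    touchGen++;
    // near partners (walls & scaled cores) are always candidates
    int base = chain[i] * mchain, li = i - base;
    for (int lj : near_partners[li]) {
      int j = base + lj;
      touchStamp[j] = touchGen;
      if (predictPair(i, j, tnow, cand) && cand.t < best.t) best = cand;
    }
    if (useCells) {
      int ci = cellOf[i];
      int cz = ci % nc, cy = (ci / nc) % nc, cx = ci / (nc * nc);
      for (int dx = -1; dx <= 1; ++dx)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dz = -1; dz <= 1; ++dz) {
            int cxx = (cx + dx + nc) % nc, cyy = (cy + dy + nc) % nc,
                czz = (cz + dz + nc) % nc;
            const std::vector<int>& cv = cells[(cxx * nc + cyy) * nc + czz];
            for (int j : cv) {
              if (j == i || touchStamp[j] == touchGen) continue;
              touchStamp[j] = touchGen;
              if (predictPair(i, j, tnow, cand) && cand.t < best.t) best = cand;
            }
          }
    } else {
      for (int j = 0; j < n; ++j) {
        if (j == i || touchStamp[j] == touchGen) continue;
        if (predictPair(i, j, tnow, cand) && cand.t < best.t) best = cand;
      }
    }
    return best;
  }

  void rescan(int i, double tnow) {
    Ev best = computeBest(i, tnow);
    if (best.kind != EV_NONE) { best.owner = 1; q.push(best); nPush++; }
  }

  // rescan both members of a pair after a bump; a shared earliest event is
  // pushed once, owning both slots
  void rescanPair(int i, int j, double tnow) {
    Ev a = computeBest(i, tnow);
    Ev b = computeBest(j, tnow);
    bool same = a.kind != EV_NONE && a.kind == b.kind && a.t == b.t &&
      a.i == b.j && a.j == b.i;
    if (same) {
      a.owner = 3;
      q.push(a); nPush++;
      return;
    }
    if (a.kind != EV_NONE) { a.owner = 1; q.push(a); nPush++; }
    if (b.kind != EV_NONE) { b.owner = 1; q.push(b); nPush++; }
  }

  // ---- event execution ----
  void applyRadial(int i, int j, const double* nhat, double dvr) {
    double mu = mass[i] * mass[j] / (mass[i] + mass[j]);
    for (int k = 0; k < 3; ++k) {
      vel[3 * i + k] -= (mu / mass[i]) * dvr * nhat[k];
      vel[3 * j + k] += (mu / mass[j]) * dvr * nhat[k];
    }
  }

  // relative geometry at the (already advanced) event time
  void relNow(int i, int j, double* nhat, double& vr) {
    double d[3];
    double r = 0;
    for (int k = 0; k < 3; ++k) {
      d[k] = mind(pos[3 * j + k] - pos[3 * i + k]);
      r += d[k] * d[k];
    }
    r = std::sqrt(r);
    vr = 0;
    for (int k = 0; k < 3; ++k) {
      nhat[k] = d[k] / r;
      vr += (vel[3 * j + k] - vel[3 * i + k]) * nhat[k];
    }
  }

  bool auxOK(int nh, int co, double t) {
    // all auxiliary beads must lie beyond hbAux from the partner bead
    int aux_nh[2] = {aux1[nh], aux2[nh]};
    int aux_co[2] = {aux1[co], aux2[co]};
    double pco[3], pnh[3];
    posAt(co, t, pco); posAt(nh, t, pnh);
    double A2 = hbAux * hbAux;
    for (int a : aux_nh) {
      if (a < 0) continue;
      double pa[3]; posAt(a, t, pa);
      double s = 0;
      for (int k = 0; k < 3; ++k) { double d = mind(pco[k] - pa[k]); s += d * d; }
      if (s <= A2) return false;
    }
    for (int a : aux_co) {
      if (a < 0) continue;
      double pa[3]; posAt(a, t, pa);
      double s = 0;
      for (int k = 0; k < 3; ++k) { double d = mind(pnh[k] - pa[k]); s += d * d; }
      if (s <= A2) return false;
    }
    return true;
  }

  void bump(int i) { cc[i]++; }

  void execPair(const Ev& e) {
    int i = e.i, j = e.j;
    advance(i, e.t); advance(j, e.t);
    PInfo p = pairInfo(i, j);
    double nhat[3], vr;
    relNow(i, j, nhat, vr);
    double mu = mass[i] * mass[j] / (mass[i] + mass[j]);
    bool changed = false;
    switch (e.kind) {
    case EV_CORE: case EV_WALL_IN:
      if (vr < 0) { applyRadial(i, j, nhat, -2 * vr); changed = true; }
      break;
    case EV_WALL_OUT:
      if (vr > 0) { applyRadial(i, j, nhat, -2 * vr); changed = true; }
      break;
    case EV_WELL_IN:
      if (vr < 0) {
        double vr2 = -std::sqrt(vr * vr + 2 * p.depth / mu);
        applyRadial(i, j, nhat, vr2 - vr);
        PE -= p.depth;
        wellSet.insert(pairKey(i, j));
        changed = true;
      }
      break;
    case EV_WELL_OUT:
      if (vr > 0) {
        if (0.5 * mu * vr * vr > p.depth) {
          double vr2 = std::sqrt(vr * vr - 2 * p.depth / mu);
          applyRadial(i, j, nhat, vr2 - vr);
          PE += p.depth;
          wellSet.erase(pairKey(i, j));
        } else {
          applyRadial(i, j, nhat, -2 * vr);
        }
        changed = true;
      }
      break;
    case EV_HB_FORM: {
      bool ok = vr < 0 && hbp[p.nh] < 0 && hbp[p.co] < 0 &&
        auxOK(p.nh, p.co, e.t);
      if (ok) {
        double vr2 = -std::sqrt(vr * vr + 2 * p.depth / mu);
        applyRadial(i, j, nhat, vr2 - vr);
        PE -= p.depth;
        hbp[p.nh] = p.co; hbp[p.co] = p.nh;
        changed = true;
      } else {
        // pass through: no impulse; keep the pair scheduled
        Ev nxt;
        if (predictPair(i, j, e.t, nxt)) { nxt.owner = 3; q.push(nxt); }
      }
      break;
    }
    case EV_HB_BREAK:
      if (vr > 0) {
        if (0.5 * mu * vr * vr > p.depth) {
          double vr2 = std::sqrt(vr * vr - 2 * p.depth / mu);
          applyRadial(i, j, nhat, vr2 - vr);
          PE += p.depth;
          hbp[p.nh] = -1; hbp[p.co] = -1;
        } else {
          applyRadial(i, j, nhat, -2 * vr);
        }
        changed = true;
      }
      break;
    }
    if (changed) {
      bump(i); bump(j);
      rescanPair(i, j, e.t);
    } else if (e.kind != EV_HB_FORM) {
      // wrong-sign no-op (numerically possible): keep the pair alive
      Ev nxt;
      if (predictPair(i, j, e.t, nxt)) { nxt.owner = 3; q.push(nxt); }
    }
  }

  void execCell(const Ev& e) {
    int i = e.i;
    advance(i, e.t);
    // re-wrap into the primary box
    for (int k = 0; k < 3; ++k) {
      double x = pos[3 * i + k];
      pos[3 * i + k] = x - L * std::floor(x / L);
    }
    cellRemove(i);
    cellInsert(i);
    bump(i);
    rescan(i, e.t);
  }

  void execGhost(const Ev& e) {
    std::uniform_int_distribution<int> pick(0, n - 1);
    int i = pick(rng);
    advance(i, e.t);
    double ke0 = 0, ke1 = 0;
    for (int k = 0; k < 3; ++k) ke0 += vel[3 * i + k] * vel[3 * i + k];
    double sd = std::sqrt(tstar / mass[i]);
    for (int k = 0; k < 3; ++k) vel[3 * i + k] = sd * gauss(rng);
    for (int k = 0; k < 3; ++k) ke1 += vel[3 * i + k] * vel[3 * i + k];
    Eref += 0.5 * mass[i] * (ke1 - ke0);
    bump(i);
    rescan(i, e.t);
    scheduleGhost(e.t);
  }

  void scheduleGhost(double tnow) {
    if (ghostRate <= 0) return;
    std::exponential_distribution<double> ex(ghostRate * n);
    Ev g; g.t = tnow + ex(rng); g.kind = EV_GHOST; g.i = -1; g.j = -1;
    g.ci = 0; g.cj = 0;
    q.push(g);
  }

  double kinetic() const {
    double ke = 0;
    for (int i = 0; i < n; ++i) {
      double s = 0;
      for (int k = 0; k < 3; ++k) s += vel[3 * i + k] * vel[3 * i + k];
      ke += 0.5 * mass[i] * s;
    }
    return ke;
  }

  // from-scratch audit of the bookkept potential energy and overlaps
  void audit(double tnow) {
    double pe = 0;
    double worst = 0;
    for (int i = 0; i < n; ++i) {
      for (int j = i + 1; j < n; ++j) {
        PInfo p = pairInfo(i, j);
        double c2 = dist2At(i, j, tnow);
        if (p.mode == PM_SW) {
          if (wellSet.count(pairKey(i, j))) pe -= p.depth;
          double ov = p.core - std::sqrt(c2);
          if (ov > worst) worst = ov;
        } else if (p.mode == PM_HB) {
          if (hbp[p.nh] == p.co) pe -= p.depth;
          double ov = p.core - std::sqrt(c2);
          if (ov > worst) worst = ov;
        } else if (p.mode == PM_CORE) {
          double ov = p.core - std::sqrt(c2);
          if (ov > worst) worst = ov;
        } else if (p.mode == PM_WALL) {
          double r = std::sqrt(c2);
          double ov = std::max(p.wlo - r, r - p.whi);
          if (ov > worst) worst = ov;
        }
      }
    }
    double dPE = std::fabs(pe - PE);
    if (dPE > maxPEerr) maxPEerr = dPE;
    if (worst > maxOverlap) maxOverlap = worst;
    double E = kinetic() + PE;
    double dE = std::fabs(E - Eref);
    if (dE > maxEdrift) maxEdrift = dE;
    nAudit++;
  }
};

// [[Rcpp::export]]
List engine_run_cpp(NumericMatrix pos0, NumericMatrix vel0, double box,
                    IntegerVector chain, IntegerVector resi,
                    IntegerVector type, IntegerVector res20,
                    NumericVector radius, NumericVector mass,
                    IntegerVector aux1, IntegerVector aux2,
                    int mchain,
                    IntegerMatrix excl_code, NumericMatrix wall_min,
                    NumericMatrix wall_max,
                    NumericMatrix sw_width, NumericMatrix sw_depth,
                    double hb_width, double hb_core, double hb_depth,
                    double hb_aux, int hb_min_sep, double core_scale,
                    IntegerMatrix hb_init,
                    double tstar, double ghost_rate,
                    double max_events, double max_time,
                    double snap_interval, double audit_interval,
                    int seed) {
  Engine E;
  E.n = pos0.nrow();
  E.mchain = mchain;
  E.L = box;
  E.pos.resize(3 * E.n); E.vel.resize(3 * E.n);
  for (int i = 0; i < E.n; ++i)
    for (int k = 0; k < 3; ++k) {
      double x = pos0(i, k);
      if (k >= 0) x = x - box * std::floor(x / box);
      E.pos[3 * i + k] = x;
      E.vel[3 * i + k] = vel0(i, k);
    }
  E.t0.assign(E.n, 0.0);
  E.cc.assign(E.n, 0);
  E.chain.assign(chain.begin(), chain.end());
  E.resi.assign(resi.begin(), resi.end());
  E.type.assign(type.begin(), type.end());
  E.res20.assign(res20.begin(), res20.end());
  E.radius.assign(radius.begin(), radius.end());
  E.mass.assign(mass.begin(), mass.end());
  E.aux1.assign(aux1.begin(), aux1.end());
  E.aux2.assign(aux2.begin(), aux2.end());
  E.excl.resize(mchain * mchain);
  E.wmin.resize(mchain * mchain);
  E.wmax.resize(mchain * mchain);
  E.near_partners.assign(mchain, std::vector<int>());
  for (int a = 0; a < mchain; ++a)
    for (int b = 0; b < mchain; ++b) {
      E.excl[a * mchain + b] = excl_code(a, b);
      E.wmin[a * mchain + b] = wall_min(a, b);
      E.wmax[a * mchain + b] = wall_max(a, b);
      if (a != b && excl_code(a, b) > 0) E.near_partners[a].push_back(b);
    }
  E.sww.resize(400); E.swd.resize(400);
  for (int a = 0; a < 20; ++a)
    for (int b = 0; b < 20; ++b) {
      E.sww[a * 20 + b] = sw_width(a, b);
      E.swd[a * 20 + b] = sw_depth(a, b);
    }
  E.hbW = hb_width; E.hbCore = hb_core; E.hbDepth = hb_depth;
  E.hbAux = hb_aux; E.hbMinSep = hb_min_sep; E.coreScale = core_scale;
  E.hbp.assign(E.n, -1);
  E.PE = 0;
  E.clock_ = 0;
  E.rng.seed((std::uint64_t)seed);
  E.gauss = std::normal_distribution<double>(0.0, 1.0);
  E.tstar = tstar; E.ghostRate = ghost_rate;
  E.maxEdrift = 0; E.maxPEerr = 0; E.maxOverlap = 0; E.nAudit = 0;
  E.err = false;
  E.touchStamp.assign(E.n, 0);
  E.touchGen = 0;
  for (int k = 0; k < 11; ++k) E.evCount[k] = 0;
  E.nPush = E.nPop = E.nScan = E.nPredict = 0;

  // interaction range governs the cell size
  double rmax = hb_width;
  for (int a = 0; a < 400; ++a) rmax = std::max(rmax, E.sww[a]);
  for (int a = 0; a < mchain * mchain; ++a) rmax = std::max(rmax, E.wmax[a]);
  int nc = (int)std::floor(box / rmax);
  E.useCells = nc >= 4;
  if (E.useCells) {
    E.nc = nc;
    E.cellw = box / nc;
    E.cells.assign(nc * nc * nc, std::vector<int>());
    E.cellOf.assign(E.n, 0);
    for (int i = 0; i < E.n; ++i) E.cellInsert(i);
  }

  // initial hydrogen bonds (fixtures)
  for (int r = 0; r < hb_init.nrow(); ++r) {
    int nh = hb_init(r, 0), co = hb_init(r, 1);
    E.hbp[nh] = co; E.hbp[co] = nh;
    E.PE -= hb_depth;
  }
  // initial sidechain well occupancy from geometry
  for (int i = 0; i < E.n; ++i)
    for (int j = i + 1; j < E.n; ++j) {
      Engine::PInfo p = E.pairInfo(i, j);
      if (p.mode != PM_SW) continue;
      if (E.dist2At(i, j, 0.0) < p.well * p.well) {
        E.wellSet.insert(E.pairKey(i, j));
        E.PE -= p.depth;
      }
    }
  E.Eref = E.kinetic() + E.PE;

  // initial schedule
  for (int i = 0; i < E.n; ++i) E.rescan(i, 0.0);
  E.scheduleGhost(0.0);
  double next_snap = 0.0;
  if (snap_interval > 0) {
    Ev s; s.t = 0.0; s.kind = EV_SNAP; s.i = -1; s.j = -1; s.ci = 0; s.cj = 0;
    E.q.push(s);
  }

  // outputs
  std::vector<double> snapT, snapPE, snapKE;
  std::vector<double> snapPos;
  std::vector<std::vector<int>> snapHB;
  long long executed = 0;
  long long max_ev = (long long)max_events;

  auto recordSnap = [&](double t) {
    snapT.push_back(t);
    snapPE.push_back(E.PE);
    snapKE.push_back(E.kinetic());
    for (int i = 0; i < E.n; ++i) {
      double p[3]; E.posAt(i, t, p);
      for (int k = 0; k < 3; ++k) {
        double x = p[k] - box * std::floor(p[k] / box);
        snapPos.push_back(x);
      }
    }
    std::vector<int> hb;
    for (int i = 0; i < E.n; ++i)
      if (E.type[i] == 0 && E.hbp[i] >= 0) { hb.push_back(i); hb.push_back(E.hbp[i]); }
    snapHB.push_back(hb);
  };

  long long sinceAudit = 0;
  while (executed < max_ev && !E.err) {
    if (E.q.empty()) break;
    Ev e = E.q.top(); E.q.pop(); E.nPop++;
    if (e.t > max_time) { E.clock_ = max_time; break; }
    // staleness
    if (e.kind <= EV_HB_BREAK) {
      bool iok = E.cc[e.i] == e.ci, jok = E.cc[e.j] == e.cj;
      if (!iok || !jok) {
        // rescan any participant whose slot this event occupied
        if (iok && (e.owner & 1)) E.rescan(e.i, E.clock_);
        if (jok && (e.owner & 2)) E.rescan(e.j, E.clock_);
        continue;
      }
    } else if (e.kind == EV_CELL) {
      if (E.cc[e.i] != e.ci) continue;
    }
    if (e.t < E.clock_ - 1e-9) {
      E.err = true;
      E.errMsg = "event time regression (calendar corruption)";
      break;
    }
    E.clock_ = std::max(E.clock_, e.t);
    switch (e.kind) {
    case EV_SNAP:
      recordSnap(e.t);
      next_snap += snap_interval;
      {
        Ev s; s.t = next_snap; s.kind = EV_SNAP; s.i = -1; s.j = -1;
        s.ci = 0; s.cj = 0;
        E.q.push(s);
      }
      break;
    case EV_GHOST:
      E.execGhost(e);
      E.evCount[EV_GHOST]++;
      executed++;
      sinceAudit++;
      break;
    case EV_CELL:
      E.execCell(e);
      E.evCount[EV_CELL]++;
      executed++;
      sinceAudit++;
      break;
    default:
      E.execPair(e);
      E.evCount[e.kind]++;
      executed++;
      sinceAudit++;
    }
    if (audit_interval > 0 && sinceAudit >= (long long)audit_interval) {
      E.audit(E.clock_);
      sinceAudit = 0;
    }
    if ((executed & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
  }
  if (audit_interval > 0) E.audit(E.clock_);

  // final state
  NumericMatrix fpos(E.n, 3), fvel(E.n, 3);
  for (int i = 0; i < E.n; ++i) {
    double p[3]; E.posAt(i, E.clock_, p);
    for (int k = 0; k < 3; ++k) {
      fpos(i, k) = p[k] - box * std::floor(p[k] / box);
      fvel(i, k) = E.vel[3 * i + k];
    }
  }
  std::vector<int> fhb;
  for (int i = 0; i < E.n; ++i)
    if (E.type[i] == 0 && E.hbp[i] >= 0) { fhb.push_back(i); fhb.push_back(E.hbp[i]); }
  IntegerMatrix fhbm(fhb.size() / 2, 2);
  for (size_t r = 0; r < fhb.size() / 2; ++r) {
    fhbm(r, 0) = fhb[2 * r]; fhbm(r, 1) = fhb[2 * r + 1];
  }

  int nsnap = snapT.size();
  List snaps(nsnap);
  for (int s = 0; s < nsnap; ++s) {
    NumericMatrix sp(E.n, 3);
    for (int i = 0; i < E.n; ++i)
      for (int k = 0; k < 3; ++k)
        sp(i, k) = snapPos[(size_t)s * 3 * E.n + 3 * i + k];
    IntegerMatrix shb(snapHB[s].size() / 2, 2);
    for (size_t r = 0; r < snapHB[s].size() / 2; ++r) {
      shb(r, 0) = snapHB[s][2 * r]; shb(r, 1) = snapHB[s][2 * r + 1];
    }
    snaps[s] = List::create(_["positions"] = sp, _["hbonds"] = shb,
                            _["time"] = snapT[s], _["potential_energy"] = snapPE[s],
                            _["kinetic_energy"] = snapKE[s]);
  }
  std::vector<std::string> kindNames = {
    "core_collision", "well_entry", "well_exit", "bond_inner", "bond_outer",
    "hb_form", "hb_break", "cell_crossing", "ghost", "snapshot", "none"};
  IntegerVector counts(9);
  CharacterVector cn(9);
  for (int k = 0; k < 9; ++k) { counts[k] = E.evCount[k]; cn[k] = kindNames[k]; }
  counts.names() = cn;
  return List::create(
    _["n_events"] = (double)executed,
    _["clock"] = E.clock_,
    _["times"] = snapT,
    _["potential_energy"] = snapPE,
    _["kinetic_energy"] = snapKE,
    _["snapshots"] = snaps,
    _["final_positions"] = fpos,
    _["final_velocities"] = fvel,
    _["final_hbonds"] = fhbm,
    _["final_potential_energy"] = E.PE,
    _["n_wells"] = (double)E.wellSet.size(),
    _["event_counts"] = counts,
    _["max_energy_drift"] = E.maxEdrift,
    _["max_pe_error"] = E.maxPEerr,
    _["max_overlap"] = E.maxOverlap,
    _["n_audits"] = (double)E.nAudit,
    _["n_push"] = (double)E.nPush, _["n_pop"] = (double)E.nPop,
    _["n_scan"] = (double)E.nScan, _["n_predict"] = (double)E.nPredict,
    _["error"] = E.err,
    _["error_message"] = E.errMsg);
}

// Standalone two-bead event prediction through the same root machinery as
// the engine (used for oracle comparisons): a single pair with a hard core
// and optionally a square well.
// [[Rcpp::export]]
List pair_event_cpp(NumericVector ri, NumericVector vi,
                    NumericVector rj, NumericVector vj,
                    double core, double well, double depth,
                    bool occupied, double box) {
  double d[3], v[3];
  for (int k = 0; k < 3; ++k) {
    double dd = rj[k] - ri[k];
    if (box > 0) dd -= box * std::nearbyint(dd / box);
    d[k] = dd;
    v[k] = vj[k] - vi[k];
  }
  double a = v[0]*v[0] + v[1]*v[1] + v[2]*v[2];
  double b = d[0]*v[0] + d[1]*v[1] + d[2]*v[2];
  double c2 = d[0]*d[0] + d[1]*d[1] + d[2]*d[2];
  double t = INF;
  std::string kind = "none";
  double R2 = core * core;
  if (well > 0 && depth > 0) {
    double W2 = well * well;
    if (occupied) {
      double tc = (c2 <= R2) ? (b < 0 ? 0.0 : INF) : rootInward(a, b, c2, R2);
      double tw = (c2 >= W2 && b > 0) ? 0.0 : rootOutward(a, b, c2, W2);
      if (tc < tw) { t = tc; kind = "core_collision"; }
      else { t = tw; kind = "well_exit"; }
    } else {
      t = rootInward(a, b, c2, W2);
      kind = "well_entry";
    }
  } else {
    t = (c2 <= R2) ? (b < 0 ? 0.0 : INF) : rootInward(a, b, c2, R2);
    kind = "core_collision";
  }
  if (!(t < INF)) return List::create(_["kind"] = "none", _["time"] = NA_REAL);
  return List::create(_["kind"] = kind, _["time"] = t);
}
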