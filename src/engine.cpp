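// Core vertex-dynamics engine: energy/forces of the 2D apical network,
// explicit Euler integration, T1/T2 topological surgery, cell division,
// and the per-cell cycle clocks.  All geometry is in nondimensional units
// (preferred cell area = 1).  Loops are counter-clockwise; vertex and cell
// indices are 0-based internally, 1-based at the R interface.

#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <chrono>

using namespace Rcpp;

namespace {

struct Params {
  double lam[2];      // line tension, [normal, abnormal]
  double gam[2];      // perimeter elasticity
  double mu;          // interfacial contractility factor (>= 1)
  double theta_t1;    // absolute T1 length threshold
  double theta_t2;    // absolute T2 area threshold
  double dt;
  double b;           // mitotic target-area growth rate
  double tau[2];      // cycle duration, may be Inf
  double jitter;      // +/- fractional jitter on the cycle threshold
  double delta_a;     // adder increment
  int    rule;        // 0 doubling, 1 adder
  int    orient;      // 0 random, 1 long axis
  double new_edge_factor; // post-T1 edge length / theta_t1
  double tm_cap;      // cap on mitotic time in the target area (stability guard)
  double step_clamp;  // max vertex displacement per Euler step (stability guard)
};

Params readParams(const List& p) {
  Params q;
  q.lam[0] = as<double>(p["lambda_normal"]);
  q.lam[1] = as<double>(p["lambda_abnormal"]);
  q.gam[0] = as<double>(p["gamma_normal"]);
  q.gam[1] = as<double>(p["gamma_abnormal"]);
  q.mu = as<double>(p["mu"]);
  q.theta_t1 = as<double>(p["theta_t1"]);
  q.theta_t2 = as<double>(p["theta_t2"]);
  q.dt = as<double>(p["dt"]);
  q.b = as<double>(p["b"]);
  q.tau[0] = as<double>(p["tau_normal"]);
  q.tau[1] = as<double>(p["tau_abnormal"]);
  q.jitter = as<double>(p["jitter"]);
  q.delta_a = as<double>(p["delta_a"]);
  q.rule = as<int>(p["rule"]);
  q.orient = as<int>(p["orient"]);
  q.new_edge_factor = as<double>(p["new_edge_factor"]);
  q.tm_cap = as<double>(p["tm_cap"]);
  q.step_clamp = as<double>(p["step_clamp"]);
  return q;
}

struct Edge { int a, b, c1, c2; };

struct Engine {
  std::vector<double> vx, vy;
  std::vector<char> vfix;
  std::vector< std::vector<int> > loops;
  std::vector<char> alive;
  std::vector<int> cid, ctype, phase;
  std::vector<double> clk, thr, t_ent, a_ent, a_birth;
  int next_cid;
  Params P;
  bool active;        // interfacial contractility on?
  double t;

  std::vector<double> carea, cperim, fx, fy;
  std::vector<Edge> edges;
  std::vector< std::vector<int> > v2c;
  bool topo_dirty;

  std::vector<double> ev_t;
  std::vector<int> ev_kind, ev_cell;  // kind: 1 T1, 2 T2, 3 division
  std::vector<double> ev_x, ev_y;

  // ---- construction from / export to R ----------------------------------
  void fromList(const List& m) {
    NumericMatrix V = m["vertices"];
    int nv = V.nrow();
    vx.resize(nv); vy.resize(nv);
    for (int i = 0; i < nv; ++i) { vx[i] = V(i, 0); vy[i] = V(i, 1); }
    LogicalVector fx_ = m["fixed"];
    vfix.resize(nv);
    for (int i = 0; i < nv; ++i) vfix[i] = fx_[i] ? 1 : 0;
    List cl = m["cells"];
    int nc = cl.size();
    loops.resize(nc);
    for (int c = 0; c < nc; ++c) {
      IntegerVector lv = cl[c];
      loops[c].assign(lv.begin(), lv.end());
      for (int& v : loops[c]) --v;  // to 0-based
    }
    alive.assign(nc, 1);
    IntegerVector id = m["cell_id"], ty = m["type"], ph = m["phase"];
    cid.assign(id.begin(), id.end());
    ctype.assign(ty.begin(), ty.end());
    phase.assign(ph.begin(), ph.end());
    NumericVector ck = m["clock"], th = m["threshold"], te = m["t_entry"],
                  ae = m["a_entry"], ab = m["area_birth"];
    clk.assign(ck.begin(), ck.end());
    thr.assign(th.begin(), th.end());
    t_ent.assign(te.begin(), te.end());
    a_ent.assign(ae.begin(), ae.end());
    a_birth.assign(ab.begin(), ab.end());
    next_cid = 0;
    for (int c = 0; c < nc; ++c) next_cid = std::max(next_cid, cid[c] + 1);
    topo_dirty = true;
  }

  List toList() const {
    // compact: keep vertices referenced by live cells, keep live cells
    int nv = vx.size();
    std::vector<int> vmap(nv, -1);
    int nv2 = 0;
    for (size_t c = 0; c < loops.size(); ++c)
      if (alive[c])
        for (int v : loops[c])
          if (vmap[v] < 0) vmap[v] = nv2++;
    NumericMatrix V(nv2, 2);
    LogicalVector fx_(nv2);
    for (int i = 0; i < nv; ++i)
      if (vmap[i] >= 0) {
        V(vmap[i], 0) = vx[i]; V(vmap[i], 1) = vy[i];
        fx_[vmap[i]] = vfix[i] != 0;
      }
    int nc2 = 0;
    for (size_t c = 0; c < loops.size(); ++c) if (alive[c]) ++nc2;
    List cl(nc2);
    IntegerVector id(nc2), ty(nc2), ph(nc2);
    NumericVector ck(nc2), th(nc2), te(nc2), ae(nc2), ab(nc2);
    int j = 0;
    for (size_t c = 0; c < loops.size(); ++c) {
      if (!alive[c]) continue;
      IntegerVector lv(loops[c].size());
      for (size_t i = 0; i < loops[c].size(); ++i) lv[i] = vmap[loops[c][i]] + 1;
      cl[j] = lv;
      id[j] = cid[c]; ty[j] = ctype[c]; ph[j] = phase[c];
      ck[j] = clk[c]; th[j] = thr[c]; te[j] = t_ent[c];
      ae[j] = a_ent[c]; ab[j] = a_birth[c];
      ++j;
    }
    return List::create(
      _["vertices"] = V, _["fixed"] = fx_, _["cells"] = cl,
      _["cell_id"] = id, _["type"] = ty, _["phase"] = ph,
      _["clock"] = ck, _["threshold"] = th, _["t_entry"] = te,
      _["a_entry"] = ae, _["area_birth"] = ab);
  }

  // ---- derived topology --------------------------------------------------
  void ensureTopo() {
    if (!topo_dirty) return;
    edges.clear();
    int nv = vx.size();
    v2c.assign(nv, std::vector<int>());
    std::unordered_map<uint64_t, int> emap;
    emap.reserve(loops.size() * 4);
    for (size_t c = 0; c < loops.size(); ++c) {
      if (!alive[c]) continue;
      const std::vector<int>& L = loops[c];
      int m = L.size();
      for (int i = 0; i < m; ++i) {
        int a = L[i], b = L[(i + 1) % m];
        uint64_t key = a < b
          ? (uint64_t)a * 0x100000000ULL + (uint64_t)b
          : (uint64_t)b * 0x100000000ULL + (uint64_t)a;
        auto it = emap.find(key);
        if (it == emap.end()) {
          emap[key] = edges.size();
          edges.push_back({std::min(a, b), std::max(a, b), (int)c, -1});
        } else {
          edges[it->second].c2 = (int)c;
        }
        if (std::find(v2c[a].begin(), v2c[a].end(), (int)c) == v2c[a].end())
          v2c[a].push_back((int)c);
      }
    }
    topo_dirty = false;
  }

  double polyArea(const std::vector<int>& L) const {
    double A = 0;
    int m = L.size();
    for (int i = 0; i < m; ++i) {
      int a = L[i], b = L[(i + 1) % m];
      A += vx[a] * vy[b] - vx[b] * vy[a];
    }
    return 0.5 * A;
  }

  void centroid(const std::vector<int>& L, double& cx, double& cy) const {
    // area centroid of the polygon
    double A = 0, sx = 0, sy = 0;
    int m = L.size();
    for (int i = 0; i < m; ++i) {
      int a = L[i], b = L[(i + 1) % m];
      double w = vx[a] * vy[b] - vx[b] * vy[a];
      A += w; sx += (vx[a] + vx[b]) * w; sy += (vy[a] + vy[b]) * w;
    }
    A *= 0.5;
    if (std::fabs(A) < 1e-14) {  // degenerate: vertex mean
      sx = sy = 0;
      for (int v : L) { sx += vx[v]; sy += vy[v]; }
      cx = sx / m; cy = sy / m; return;
    }
    cx = sx / (6 * A); cy = sy / (6 * A);
  }

  void computeGeometry() {
    int nc = loops.size();
    carea.assign(nc, 0.0); cperim.assign(nc, 0.0);
    for (int c = 0; c < nc; ++c) {
      if (!alive[c]) continue;
      const std::vector<int>& L = loops[c];
      int m = L.size();
      double A = 0, Lp = 0;
      for (int i = 0; i < m; ++i) {
        int a = L[i], b = L[(i + 1) % m];
        A += vx[a] * vy[b] - vx[b] * vy[a];
        double dx = vx[b] - vx[a], dy = vy[b] - vy[a];
        Lp += std::sqrt(dx * dx + dy * dy);
      }
      carea[c] = 0.5 * A;
      cperim[c] = Lp;
    }
  }

  double targetArea(int c) const {
    if (phase[c] != 1) return 1.0;
    double tm = t - t_ent[c];
    if (tm < 0) tm = 0;
    if (tm > P.tm_cap) tm = P.tm_cap;
    return 1.0 + P.b * tm;
  }

  double edgeLambda(const Edge& e) const {
    if (e.c2 < 0) return P.lam[ctype[e.c1]];
    int t1 = ctype[e.c1], t2 = ctype[e.c2];
    if (t1 == t2) return P.lam[t1];
    double base = 0.5 * (P.lam[0] + P.lam[1]);
    return active ? P.mu * base : base;
  }

  double totalEnergy() {
    ensureTopo(); computeGeometry();
    double U = 0;
    for (size_t c = 0; c < loops.size(); ++c) {
      if (!alive[c]) continue;
      double da = carea[c] - targetArea(c);
      U += 0.5 * da * da + 0.5 * P.gam[ctype[c]] * cperim[c] * cperim[c];
    }
    for (const Edge& e : edges) {
      double dx = vx[e.b] - vx[e.a], dy = vy[e.b] - vy[e.a];
      U += edgeLambda(e) * std::sqrt(dx * dx + dy * dy);
    }
    return U;
  }

  void computeForces() {
    int nv = vx.size();
    fx.assign(nv, 0.0); fy.assign(nv, 0.0);
    for (size_t c = 0; c < loops.size(); ++c) {
      if (!alive[c]) continue;
      const std::vector<int>& L = loops[c];
      int m = L.size();
      double Aerr = carea[c] - targetArea(c);
      double gL = P.gam[ctype[c]] * cperim[c];
      for (int i = 0; i < m; ++i) {
        int v = L[i], p = L[(i + m - 1) % m], n = L[(i + 1) % m];
        // area term: dA/dx_i = (y_n - y_p)/2, dA/dy_i = (x_p - x_n)/2
        fx[v] -= Aerr * 0.5 * (vy[n] - vy[p]);
        fy[v] -= Aerr * 0.5 * (vx[p] - vx[n]);
        // perimeter term
        double dxp = vx[v] - vx[p], dyp = vy[v] - vy[p];
        double dxn = vx[v] - vx[n], dyn = vy[v] - vy[n];
        double lp = std::sqrt(dxp * dxp + dyp * dyp);
        double ln = std::sqrt(dxn * dxn + dyn * dyn);
        if (lp > 1e-14) { fx[v] -= gL * dxp / lp; fy[v] -= gL * dyp / lp; }
        if (ln > 1e-14) { fx[v] -= gL * dxn / ln; fy[v] -= gL * dyn / ln; }
      }
    }
    for (const Edge& e : edges) {
      double dx = vx[e.b] - vx[e.a], dy = vy[e.b] - vy[e.a];
      double len = std::sqrt(dx * dx + dy * dy);
      if (len < 1e-14) continue;
      double lam = edgeLambda(e);
      double ux = lam * dx / len, uy = lam * dy / len;
      fx[e.a] += ux; fy[e.a] += uy;
      fx[e.b] -= ux; fy[e.b] -= uy;
    }
    for (int i = 0; i < nv; ++i)
      if (vfix[i]) { fx[i] = 0; fy[i] = 0; }
  }

  void eulerMove() {
    int nv = vx.size();
    double c2 = P.step_clamp * P.step_clamp;
    for (int i = 0; i < nv; ++i) {
      if (vfix[i]) continue;
      double dx = P.dt * fx[i], dy = P.dt * fy[i];
      double d2 = dx * dx + dy * dy;
      if (d2 > c2) {  // clamp pathological force spikes
        double s = P.step_clamp / std::sqrt(d2);
        dx *= s; dy *= s;
      }
      vx[i] += dx;
      vy[i] += dy;
    }
  }

  // ---- cell cycle --------------------------------------------------------
  double drawThreshold(int type) const {
    double tau = P.tau[type];
    if (!std::isfinite(tau)) return R_PosInf;
    return tau * (1.0 + P.jitter * (2.0 * unif_rand() - 1.0));
  }

  void advanceCycle() {
    for (size_t c = 0; c < loops.size(); ++c) {
      if (!alive[c]) continue;
      clk[c] += P.dt;
      if (phase[c] == 0 && clk[c] >= thr[c]) {
        phase[c] = 1;
        t_ent[c] = t;
        a_ent[c] = carea[c];
      }
    }
  }

  bool divisionReady(int c) const {
    if (!alive[c] || phase[c] != 1) return false;
    // rule 0: doubling, preferred-area baseline (A >= 2)
    // rule 1: adder (A >= A_entry + delta_a)
    // rule 2: doubling, entry-area baseline (A >= 2 A_entry)
    if (P.rule == 1) return carea[c] >= a_ent[c] + P.delta_a;
    if (P.rule == 2) return carea[c] >= 2.0 * a_ent[c];
    return carea[c] >= 2.0;
  }

  // ---- topological surgery ----------------------------------------------
  bool inLoop(int c, int v) const {
    return std::find(loops[c].begin(), loops[c].end(), v) != loops[c].end();
  }

  // T1 reconnection of interior edge (a,b); returns false if skipped
  bool tryT1(int a, int b) {
    ensureTopo();
    if (vfix[a] || vfix[b]) return false;
    // locate the edge
    int P_ = -1, Q_ = -1;
    for (const Edge& e : edges)
      if ((e.a == std::min(a, b)) && (e.b == std::max(a, b))) {
        P_ = e.c1; Q_ = e.c2; break;
      }
    if (P_ < 0 || Q_ < 0) return false;
    if ((int)loops[P_].size() < 4 || (int)loops[Q_].size() < 4) return false;
    if (v2c[a].size() != 3 || v2c[b].size() != 3) return false;
    int R_ = -1, S_ = -1;
    for (int c : v2c[a]) if (c != P_ && c != Q_) R_ = c;
    for (int c : v2c[b]) if (c != P_ && c != Q_) S_ = c;
    if (R_ < 0 || S_ < 0 || R_ == S_) return false;
    if (inLoop(R_, b) || inLoop(S_, a)) return false;

    // ensure a belongs to P_'s loop order such that P_ keeps a, Q_ keeps b
    double mx = 0.5 * (vx[a] + vx[b]), my = 0.5 * (vy[a] + vy[b]);
    double ex = vx[b] - vx[a], ey = vy[b] - vy[a];
    double len = std::sqrt(ex * ex + ey * ey);
    if (len < 1e-14) { ex = 1; ey = 0; } else { ex /= len; ey /= len; }
    double px = -ey, py = ex;  // perpendicular
    double cxP, cyP;
    centroid(loops[P_], cxP, cyP);
    double s = (px * (cxP - mx) + py * (cyP - my)) >= 0 ? 1.0 : -1.0;
    double half = 0.5 * P.new_edge_factor * P.theta_t1;

    // surgery on the loops
    auto eraseV = [&](int c, int v) {
      auto& L = loops[c];
      L.erase(std::remove(L.begin(), L.end(), v), L.end());
    };
    // R_: insert b next to a, on the Q_ side
    auto insertAdj = [&](int c, int anchor, int newcomer, int sideCell) -> bool {
      auto& L = loops[c];
      int m = L.size();
      int ia = -1;
      for (int i = 0; i < m; ++i) if (L[i] == anchor) { ia = i; break; }
      if (ia < 0) return false;
      int prev = L[(ia + m - 1) % m], nxt = L[(ia + 1) % m];
      bool prevSide = inLoop(sideCell, prev);
      bool nxtSide = inLoop(sideCell, nxt);
      if (prevSide == nxtSide) return false;  // ambiguous; bail out
      if (prevSide) L.insert(L.begin() + ia, newcomer);        // prev, new, anchor
      else L.insert(L.begin() + ia + 1, newcomer);             // anchor, new, next
      return true;
    };

    // check insertability before mutating anything
    std::vector<int> saveR = loops[R_], saveS = loops[S_];
    if (!insertAdj(R_, a, b, Q_)) { loops[R_] = saveR; return false; }
    if (!insertAdj(S_, b, a, P_)) { loops[R_] = saveR; loops[S_] = saveS; return false; }
    eraseV(P_, b);
    eraseV(Q_, a);
    vx[a] = mx + s * half * px; vy[a] = my + s * half * py;
    vx[b] = mx - s * half * px; vy[b] = my - s * half * py;
    topo_dirty = true;
    ev_t.push_back(t); ev_kind.push_back(1); ev_cell.push_back(cid[P_]);
    ev_x.push_back(mx); ev_y.push_back(my);
    return true;
  }

  // T2 removal: merge the vertices of a group of cells (usually one) into a
  // single vertex.  Returns -2 on success, -1 on hard failure, or the index
  // of a blocking neighbour (one that would be pinched below 3 vertices).
  int tryT2Group(const std::vector<int>& group) {
    ensureTopo();
    std::vector<char> inG(loops.size(), 0);
    for (int c : group) inG[c] = 1;
    std::vector<int> V;
    for (int c : group)
      for (int v : loops[c])
        if (std::find(V.begin(), V.end(), v) == V.end()) V.push_back(v);
    int nfix = 0, fixv = -1;
    for (int v : V) if (vfix[v]) { ++nfix; fixv = v; }
    if (nfix > 1) return -1;
    int keep = nfix == 1 ? fixv : V[0];
    double cx = 0, cy = 0, atot = 0;
    for (int c : group) {
      double x, y;
      centroid(loops[c], x, y);
      double a = std::max(polyArea(loops[c]), 1e-12);
      cx += a * x; cy += a * y; atot += a;
    }
    cx /= atot; cy /= atot;

    std::vector<int> nbs;
    for (int v : V)
      for (int d : v2c[v])
        if (!inG[d] && alive[d] &&
            std::find(nbs.begin(), nbs.end(), d) == nbs.end())
          nbs.push_back(d);
    if (nbs.empty()) return -1;   // would delete the whole tissue

    auto member = [&](int v) {
      return std::find(V.begin(), V.end(), v) != V.end();
    };
    std::vector< std::vector<int> > newloops(nbs.size());
    for (size_t i = 0; i < nbs.size(); ++i) {
      std::vector<int> L;
      for (int v : loops[nbs[i]]) L.push_back(member(v) ? keep : v);
      std::vector<int> D;
      int m = L.size();
      for (int j = 0; j < m; ++j)
        if (L[j] != L[(j + 1) % m]) D.push_back(L[j]);
      if ((int)D.size() < 3) return nbs[i];
      std::vector<int> S = D;
      std::sort(S.begin(), S.end());
      if (std::adjacent_find(S.begin(), S.end()) != S.end()) return nbs[i];
      newloops[i] = D;
    }
    for (size_t i = 0; i < nbs.size(); ++i) loops[nbs[i]] = newloops[i];
    if (nfix == 0) { vx[keep] = cx; vy[keep] = cy; }
    for (int c : group) {
      alive[c] = 0;
      ev_t.push_back(t); ev_kind.push_back(2); ev_cell.push_back(cid[c]);
      ev_x.push_back(cx); ev_y.push_back(cy);
    }
    topo_dirty = true;
    return -2;
  }

  // single-cell entry point with a cascading fallback: a removal blocked by
  // a neighbour that is itself below the T2 threshold removes the pair (and
  // so on, up to 8 cells) as one unit, so that collapsed clusters cannot
  // deadlock as zero-area "zombie" cells
  bool tryT2(int c) {
    std::vector<int> group{c};
    for (int attempt = 0; attempt < 8; ++attempt) {
      int r = tryT2Group(group);
      if (r == -2) return true;
      if (r == -1) return false;
      computeGeometry();
      if (carea[r] < 2.0 * P.theta_t2 &&
          std::find(group.begin(), group.end(), r) == group.end())
        group.push_back(r);
      else
        return false;
    }
    return false;
  }

  // rosette resolution: a vertex where more than three cells meet (created
  // by T2 merges or coincident events) is split into two vertices joined by
  // a short edge, partitioning the incident edges by an angular cut.  This
  // is the inverse-T1 generalization standard in vertex-model codes; without
  // it T2 merges accumulate unresolvable high-degree fans.
  bool trySplitRosette(int v) {
    ensureTopo();
    if ((int)v2c[v].size() <= 3 || vfix[v]) return false;
    // unique neighbour vertices along incident edges
    std::vector<int> nbrs;
    for (int c : v2c[v]) {
      const std::vector<int>& L = loops[c];
      int m = L.size();
      for (int i = 0; i < m; ++i)
        if (L[i] == v) {
          int p = L[(i + m - 1) % m], n = L[(i + 1) % m];
          if (std::find(nbrs.begin(), nbrs.end(), p) == nbrs.end())
            nbrs.push_back(p);
          if (std::find(nbrs.begin(), nbrs.end(), n) == nbrs.end())
            nbrs.push_back(n);
        }
    }
    // interior rosettes only: every incident edge must have two cells
    for (int w : nbrs) {
      int cnt = 0;
      for (int c : v2c[v]) {
        const std::vector<int>& L = loops[c];
        int m = L.size();
        for (int i = 0; i < m; ++i)
          if ((L[i] == v && L[(i + 1) % m] == w) ||
              (L[i] == w && L[(i + 1) % m] == v)) { ++cnt; break; }
      }
      if (cnt != 2) return false;
    }
    // balanced contiguous angular partition: sort the incident edges by
    // angle, cut at the widest gap and again half-way round, so each side
    // receives at least two edges and the vertex degree strictly decreases
    int m_e = nbrs.size();
    std::vector< std::pair<double, int> > av(m_e);
    for (int i = 0; i < m_e; ++i)
      av[i] = { std::atan2(vy[nbrs[i]] - vy[v], vx[nbrs[i]] - vx[v]), nbrs[i] };
    std::sort(av.begin(), av.end());
    int cut = 0;
    double best_gap = -1;
    for (int i = 0; i < m_e; ++i) {
      double nexta = i + 1 < m_e ? av[i + 1].first : av[0].first + 2 * M_PI;
      if (nexta - av[i].first > best_gap) { best_gap = nexta - av[i].first; cut = i; }
    }
    // side A: the m_e/2 edges following the cut (cyclically)
    std::vector<char> sideA_of(vx.size() + 1, 0);
    std::vector<char> isA(m_e, 0);
    for (int j = 1; j <= m_e / 2; ++j) isA[(cut + j) % m_e] = 1;
    auto sideOf = [&](int w) {
      for (int i = 0; i < m_e; ++i)
        if (av[i].second == w) return isA[i] != 0;
      return false;
    };
    int nA = 0, nB = 0;
    for (int w : nbrs) (sideOf(w) ? nA : nB)++;
    if (nA == 0 || nB == 0) return false;
    // mean pull directions of the two groups
    double mAx = 0, mAy = 0, mBx = 0, mBy = 0;
    for (int w : nbrs) {
      double dx = vx[w] - vx[v], dy = vy[w] - vy[v];
      double len = std::sqrt(dx * dx + dy * dy);
      if (len < 1e-14) continue;
      if (sideOf(w)) { mAx += dx / len; mAy += dy / len; }
      else { mBx += dx / len; mBy += dy / len; }
    }
    double lA = std::sqrt(mAx * mAx + mAy * mAy);
    double lB = std::sqrt(mBx * mBx + mBy * mBy);
    if (lA < 1e-12 || lB < 1e-12) return false;
    double delta = 0.75 * P.theta_t1;
    double v0x = vx[v], v0y = vy[v];
    int vB = vx.size();
    vx.push_back(v0x + delta * mBx / lB);
    vy.push_back(v0y + delta * mBy / lB);
    vfix.push_back(0);
    vx[v] = v0x + delta * mAx / lA;
    vy[v] = v0y + delta * mAy / lA;

    std::vector<int> cells = v2c[v];
    for (int c : cells) {
      std::vector<int>& L = loops[c];
      int m = L.size();
      int i = -1;
      for (int j = 0; j < m; ++j) if (L[j] == v) { i = j; break; }
      int pv = L[(i + m - 1) % m], nv = L[(i + 1) % m];
      bool sp = sideOf(pv), sn = sideOf(nv);
      if (sp == sn) {
        if (!sp) L[i] = vB;            // whole cell on the B side
      } else {
        // spanning cell: gets both vertices, ordered p-side first
        int first = sp ? v : vB, second = sn ? v : vB;
        L[i] = first;
        L.insert(L.begin() + i + 1, second);
      }
    }
    topo_dirty = true;
    ev_t.push_back(t); ev_kind.push_back(1); ev_cell.push_back(-1);
    ev_x.push_back(v0x); ev_y.push_back(v0y);
    return true;
  }

  // last-resort removal for degenerate (essentially zero-area or inverted)
  // cells whose regular T2 stays blocked: merge the cell into one vertex and
  // iron out any pinched loop patterns this creates.  Pure mesh repair; only
  // reached when the regular pathway cannot fire.
  void mergeVertexInto(int x, int keep) {
    for (size_t c = 0; c < loops.size(); ++c) {
      if (!alive[c]) continue;
      bool touched = false;
      for (int& v : loops[c]) if (v == x) { v = keep; touched = true; }
      if (!touched) continue;
      std::vector<int> D;
      int m = loops[c].size();
      for (int j = 0; j < m; ++j)
        if (loops[c][j] != loops[c][(j + 1) % m]) D.push_back(loops[c][j]);
      loops[c] = D;
      std::vector<int> S = D;
      std::sort(S.begin(), S.end());
      bool dup = std::adjacent_find(S.begin(), S.end()) != S.end();
      if ((int)D.size() < 3 || dup) {
        if ((int)D.size() < 3 && !dup) {
          alive[c] = 0;
          ev_t.push_back(t); ev_kind.push_back(2); ev_cell.push_back(cid[c]);
          ev_x.push_back(vx[keep]); ev_y.push_back(vy[keep]);
        }
      }
    }
  }

  void forceRemove(int c) {
    std::vector<int> V;
    for (int v : loops[c])
      if (std::find(V.begin(), V.end(), v) == V.end()) V.push_back(v);
    int keep = V[0];
    for (int v : V) if (vfix[v]) keep = v;
    double cx, cy;
    centroid(loops[c], cx, cy);
    if (!vfix[keep]) { vx[keep] = cx; vy[keep] = cy; }
    alive[c] = 0;
    ev_t.push_back(t); ev_kind.push_back(2); ev_cell.push_back(cid[c]);
    ev_x.push_back(cx); ev_y.push_back(cy);
    for (int v : V) if (v != keep) mergeVertexInto(v, keep);
    // iron out non-consecutive repeats of keep: merge the shorter arc away
    for (int guard = 0; guard < 32; ++guard) {
      bool dirty = false;
      for (size_t cc = 0; cc < loops.size() && !dirty; ++cc) {
        if (!alive[cc]) continue;
        std::vector<int>& L = loops[cc];
        int m = L.size();
        std::vector<int> pos;
        for (int j = 0; j < m; ++j) if (L[j] == keep) pos.push_back(j);
        if (pos.size() < 2) continue;
        // arc between first two occurrences (exclusive)
        int arc1 = pos[1] - pos[0] - 1;
        int arc2 = m - 2 - arc1;
        if (arc1 <= arc2) {
          for (int j = pos[0] + 1; j < pos[1]; ++j)
            mergeVertexInto(L[j], keep);
        } else {
          for (int j = pos[1] + 1; j < m + pos[0]; ++j)
            mergeVertexInto(L[j % m], keep);
        }
        dirty = true;
      }
      if (!dirty) break;
    }
    topo_dirty = true;
  }

  // division of cell c along a line through its centroid at `angle`
  bool tryDivide(int c, double angle) {
    ensureTopo();
    const std::vector<int> V = loops[c];
    int m = V.size();
    double cx, cy;
    centroid(V, cx, cy);
    double dx = std::cos(angle), dy = std::sin(angle);
    std::vector<double> s(m);
    for (int i = 0; i < m; ++i) {
      double sx = dx * (vy[V[i]] - cy) - dy * (vx[V[i]] - cx);
      if (std::fabs(sx) < 1e-12) return false;  // vertex on the line; resample
      s[i] = sx;
    }
    std::vector<int> hits;
    for (int i = 0; i < m; ++i)
      if (s[i] * s[(i + 1) % m] < 0) hits.push_back(i);
    if (hits.size() != 2) return false;
    int j1 = hits[0], j2 = hits[1];
    auto cut = [&](int j, double& wx, double& wy) {
      int a = V[j], b = V[(j + 1) % m];
      double tt = s[j] / (s[j] - s[(j + 1) % m]);
      if (tt < 1e-6 || tt > 1 - 1e-6) return false;
      wx = vx[a] + tt * (vx[b] - vx[a]);
      wy = vy[a] + tt * (vy[b] - vy[a]);
      return true;
    };
    double w1x, w1y, w2x, w2y;
    if (!cut(j1, w1x, w1y) || !cut(j2, w2x, w2y)) return false;

    int w1 = vx.size(), w2 = w1 + 1;
    vx.push_back(w1x); vy.push_back(w1y);
    vx.push_back(w2x); vy.push_back(w2y);
    vfix.push_back(vfix[V[j1]] && vfix[V[(j1 + 1) % m]]);
    vfix.push_back(vfix[V[j2]] && vfix[V[(j2 + 1) % m]]);

    // daughters (both CCW since the mother is)
    std::vector<int> d1, d2;
    d1.push_back(w1);
    for (int i = j1 + 1; i <= j2; ++i) d1.push_back(V[i]);
    d1.push_back(w2);
    d2.push_back(w2);
    for (int i = j2 + 1; i < m; ++i) d2.push_back(V[i]);
    for (int i = 0; i <= j1; ++i) d2.push_back(V[i]);
    d2.push_back(w1);

    // insert the new vertices into the loops of the two edge-neighbours
    auto patchNeighbour = [&](int j, int w) {
      int a = V[j], b = V[(j + 1) % m];
      int other = -1;
      for (int cc : v2c[a])
        if (cc != c && alive[cc] && inLoop(cc, b)) {
          // confirm (b, a) consecutive in cc
          auto& L = loops[cc];
          int mm = L.size();
          for (int i = 0; i < mm; ++i)
            if (L[i] == b && L[(i + 1) % mm] == a) { other = cc; break; }
          if (other >= 0) break;
        }
      if (other >= 0) {
        auto& L = loops[other];
        int mm = L.size();
        for (int i = 0; i < mm; ++i)
          if (L[i] == b && L[(i + 1) % mm] == a) {
            L.insert(L.begin() + i + 1, w);
            break;
          }
      }
    };
    patchNeighbour(j1, w1);
    patchNeighbour(j2, w2);

    // mother slot -> daughter 1; append daughter 2
    int ty = ctype[c];
    loops[c] = d1;
    cid[c] = next_cid++;
    phase[c] = 0; clk[c] = 0; t_ent[c] = -1; a_ent[c] = -1;
    thr[c] = drawThreshold(ty);
    a_birth[c] = polyArea(d1);
    loops.push_back(d2);
    alive.push_back(1);
    cid.push_back(next_cid++);
    ctype.push_back(ty);
    phase.push_back(0);
    clk.push_back(0);
    thr.push_back(drawThreshold(ty));
    t_ent.push_back(-1);
    a_ent.push_back(-1);
    a_birth.push_back(polyArea(d2));
    topo_dirty = true;
    ev_t.push_back(t); ev_kind.push_back(3); ev_cell.push_back(cid[c]);
    ev_x.push_back(cx); ev_y.push_back(cy);
    return true;
  }

  double divisionAngle(int c) {
    if (P.orient == 1) {
      // perpendicular to the long axis of the vertex second-moment tensor
      const std::vector<int>& V = loops[c];
      double cx = 0, cy = 0;
      for (int v : V) { cx += vx[v]; cy += vy[v]; }
      cx /= V.size(); cy /= V.size();
      double sxx = 0, syy = 0, sxy = 0;
      for (int v : V) {
        double ddx = vx[v] - cx, ddy = vy[v] - cy;
        sxx += ddx * ddx; syy += ddy * ddy; sxy += ddx * ddy;
      }
      double phi = 0.5 * std::atan2(2 * sxy, sxx - syy);
      return phi + M_PI / 2;
    }
    return unif_rand() * M_PI;
  }

  // one resolution pass: T1 (shortest first), then T2 (smallest first),
  // then division triggers; re-scan after every applied event, cap 10
  int resolveEvents(bool divisionsOn, int maxIter, bool geometryFresh) {
    int applied = 0;
    for (int iter = 0; iter < maxIter; ++iter) {
      ensureTopo();
      if (!geometryFresh || iter > 0) computeGeometry();
      geometryFresh = false;
      bool done = false;

      // rosette resolution first: keep junctions three-way
      for (size_t v = 0; v < vx.size() && !done; ++v)
        if ((int)v2c[v].size() > 3 && trySplitRosette((int)v)) done = true;

      // T1 candidates
      std::vector< std::pair<double, int> > cand;
      for (size_t i = 0; i < edges.size(); ++i) {
        const Edge& e = edges[i];
        if (e.c2 < 0) continue;
        double ddx = vx[e.b] - vx[e.a], ddy = vy[e.b] - vy[e.a];
        double len = std::sqrt(ddx * ddx + ddy * ddy);
        if (len < P.theta_t1) cand.push_back({len, (int)i});
      }
      std::sort(cand.begin(), cand.end());
      for (auto& pr : cand) {
        const Edge e = edges[pr.second];
        if (tryT1(e.a, e.b)) { done = true; break; }
      }
      if (!done) {
        std::vector< std::pair<double, int> > t2c;
        for (size_t c = 0; c < loops.size(); ++c)
          if (alive[c] && carea[c] < P.theta_t2)
            t2c.push_back({carea[c], (int)c});
        std::sort(t2c.begin(), t2c.end());
        for (auto& pr : t2c)
          if (tryT2(pr.second)) { done = true; break; }
        if (!done)
          for (auto& pr : t2c)
            if (pr.first < 0.25 * P.theta_t2) {
              forceRemove(pr.second);
              done = true;
              break;
            }
      }
      if (!done && divisionsOn) {
        for (size_t c = 0; c < loops.size(); ++c) {
          if (!divisionReady(c)) continue;
          bool ok = false;
          for (int attempt = 0; attempt < 16 && !ok; ++attempt) {
            double ang = divisionAngle(c);
            if (P.orient == 1 && attempt > 0)
              ang += (unif_rand() - 0.5) * 0.5;
            ok = tryDivide(c, ang);
          }
          if (ok) { done = true; break; }
          phase[c] = 1;  // stays mitotic; retried next step
        }
      }
      if (!done) break;
      ++applied;
    }
    return applied;
  }

  int countType(int ty) const {
    int n = 0;
    for (size_t c = 0; c < loops.size(); ++c)
      if (alive[c] && ctype[c] == ty) ++n;
    return n;
  }

  double meanAreaType(int ty) {
    double s = 0; int n = 0;
    for (size_t c = 0; c < loops.size(); ++c)
      if (alive[c] && ctype[c] == ty) { s += carea[c]; ++n; }
    return n ? s / n : NA_REAL;
  }
};

Engine makeEngine(const List& mesh, const List& params, double t_now,
                  bool active) {
  Engine E;
  E.fromList(mesh);
  E.P = readParams(params);
  E.t = t_now;
  E.active = active;
  return E;
}

}  // namespace

// [[Rcpp::export]]
double vm_energy(List mesh, List params, double t_now = 0,
                 bool contractility_active = true) {
  Engine E = makeEngine(mesh, params, t_now, contractility_active);
  return E.totalEnergy();
}

// [[Rcpp::export]]
NumericMatrix vm_forces(List mesh, List params, double t_now = 0,
                        bool contractility_active = true) {
  Engine E = makeEngine(mesh, params, t_now, contractility_active);
  E.ensureTopo();
  E.computeGeometry();
  E.computeForces();
  int nv = E.vx.size();
  NumericMatrix F(nv, 2);
  for (int i = 0; i < nv; ++i) { F(i, 0) = E.fx[i]; F(i, 1) = E.fy[i]; }
  return F;
}

// [[Rcpp::export]]
List vm_cell_metrics(List mesh) {
  Engine E;
  E.fromList(mesh);
  E.computeGeometry();
  int nc = E.loops.size();
  NumericVector A(nc), L(nc), cx(nc), cy(nc);
  IntegerVector ns(nc);
  for (int c = 0; c < nc; ++c) {
    A[c] = E.carea[c]; L[c] = E.cperim[c];
    double x, y;
    E.centroid(E.loops[c], x, y);
    cx[c] = x; cy[c] = y;
    ns[c] = E.loops[c].size();
  }
  return List::create(_["area"] = A, _["perimeter"] = L,
                      _["cx"] = cx, _["cy"] = cy, _["n_sides"] = ns);
}

// [[Rcpp::export]]
List vm_euler_steps(List mesh, List params, int n_steps, double t_now = 0,
                    bool contractility_active = true) {
  // pure gradient-descent steps, no topological events, no cycle progression
  Engine E = makeEngine(mesh, params, t_now, contractility_active);
  for (int k = 0; k < n_steps; ++k) {
    E.ensureTopo();
    E.computeGeometry();
    E.computeForces();
    E.eulerMove();
    E.t += E.P.dt;
  }
  return List::create(_["mesh"] = E.toList(), _["t"] = E.t);
}

// [[Rcpp::export]]
List vm_apply_t1(List mesh, List params, int v1, int v2, double t_now = 0) {
  Engine E = makeEngine(mesh, params, t_now, true);
  bool ok = E.tryT1(v1 - 1, v2 - 1);
  return List::create(_["mesh"] = E.toList(), _["applied"] = ok);
}

// [[Rcpp::export]]
List vm_apply_t2(List mesh, List params, int cell, double t_now = 0) {
  Engine E = makeEngine(mesh, params, t_now, true);
  E.ensureTopo();
  bool ok = E.tryT2(cell - 1);
  return List::create(_["mesh"] = E.toList(), _["applied"] = ok);
}

// [[Rcpp::export]]
List vm_divide_cell(List mesh, List params, int cell, double angle,
                    double t_now = 0) {
  Engine E = makeEngine(mesh, params, t_now, true);
  E.ensureTopo();
  E.computeGeometry();
  bool ok = E.tryDivide(cell - 1, angle);
  return List::create(_["mesh"] = E.toList(), _["applied"] = ok);
}

// [[Rcpp::export]]
List vm_resolve_events(List mesh, List params, double t_now = 0,
                       bool divisions_on = true, int max_iter = 10,
                       bool contractility_active = true) {
  Engine E = makeEngine(mesh, params, t_now, contractility_active);
  int n = E.resolveEvents(divisions_on, max_iter, false);
  DataFrame ev = DataFrame::create(
    _["time"] = NumericVector(E.ev_t.begin(), E.ev_t.end()),
    _["kind"] = IntegerVector(E.ev_kind.begin(), E.ev_kind.end()),
    _["cell_id"] = IntegerVector(E.ev_cell.begin(), E.ev_cell.end()),
    _["x"] = NumericVector(E.ev_x.begin(), E.ev_x.end()),
    _["y"] = NumericVector(E.ev_y.begin(), E.ev_y.end()));
  return List::create(_["mesh"] = E.toList(), _["n_applied"] = n,
                      _["events"] = ev);
}

// [[Rcpp::export]]
List vm_run(List mesh, List params, List control) {
  Engine E = makeEngine(mesh, params, as<double>(control["t0"]),
                        as<bool>(control["active"]));
  double t_end = as<double>(control["t_end"]);
  int sample_every = as<int>(control["sample_every"]);
  int activate_at_N = as<int>(control["activate_at_N"]);
  bool divisions_on = as<bool>(control["divisions"]);
  bool stop_on_extinct = as<bool>(control["stop_on_extinct"]);
  int bailout_n = as<int>(control["bailout_n"]);
  bool record_energy = as<bool>(control["record_energy"]);
  int max_iter = as<int>(control["max_event_iter"]);

  long n_steps = (long)std::ceil((t_end - E.t) / E.P.dt - 1e-9);
  if (n_steps < 0) n_steps = 0;

  std::vector<double> s_t, s_area_abn, s_area_nrm, s_energy;
  std::vector<int> s_nabn, s_nnrm;
  double onset_time = NA_REAL, a0 = NA_REAL;
  int status = 0;
  double t_extinct = NA_REAL;

  auto sample = [&]() {
    s_t.push_back(E.t);
    int na = E.countType(1), nn = E.countType(0);
    s_nabn.push_back(na);
    s_nnrm.push_back(nn);
    double sa = 0, sn = 0;
    for (size_t c = 0; c < E.loops.size(); ++c) {
      if (!E.alive[c]) continue;
      if (E.ctype[c] == 1) sa += E.carea[c]; else sn += E.carea[c];
    }
    s_area_abn.push_back(sa);
    s_area_nrm.push_back(sn);
    if (record_energy) s_energy.push_back(E.totalEnergy());
  };

  E.ensureTopo();
  E.computeGeometry();
  sample();

  for (long step = 0; step < n_steps; ++step) {
    E.ensureTopo();
    E.computeGeometry();
    if (activate_at_N > 0 && !E.active &&
        E.countType(1) >= activate_at_N) {
      E.active = true;
      onset_time = E.t;
      a0 = E.meanAreaType(1);
    }
    E.computeForces();
    E.eulerMove();
    E.t += E.P.dt;
    E.ensureTopo();
    E.computeGeometry();
    E.advanceCycle();
    E.resolveEvents(divisions_on, max_iter, true);
    if (E.topo_dirty) { E.ensureTopo(); E.computeGeometry(); }

    int na = E.countType(1);
    if ((step + 1) % sample_every == 0 || step == n_steps - 1) sample();
    if (na == 0 && stop_on_extinct) {
      status = 1;
      t_extinct = E.t;
      if ((step + 1) % sample_every != 0 && step != n_steps - 1) sample();
      break;
    }
    if (bailout_n > 0 && na >= bailout_n) {
      status = 2;
      if ((step + 1) % sample_every != 0 && step != n_steps - 1) sample();
      break;
    }
    if (step % 20000 == 0) Rcpp::checkUserInterrupt();
  }

  DataFrame samples = DataFrame::create(
    _["t"] = NumericVector(s_t.begin(), s_t.end()),
    _["n_abnormal"] = IntegerVector(s_nabn.begin(), s_nabn.end()),
    _["n_normal"] = IntegerVector(s_nnrm.begin(), s_nnrm.end()),
    _["area_abnormal"] = NumericVector(s_area_abn.begin(), s_area_abn.end()),
    _["area_normal"] = NumericVector(s_area_nrm.begin(), s_area_nrm.end()));
  NumericVector en;
  if (record_energy) en = NumericVector(s_energy.begin(), s_energy.end());
  DataFrame ev = DataFrame::create(
    _["time"] = NumericVector(E.ev_t.begin(), E.ev_t.end()),
    _["kind"] = IntegerVector(E.ev_kind.begin(), E.ev_kind.end()),
    _["cell_id"] = IntegerVector(E.ev_cell.begin(), E.ev_cell.end()),
    _["x"] = NumericVector(E.ev_x.begin(), E.ev_x.end()),
    _["y"] = NumericVector(E.ev_y.begin(), E.ev_y.end()));
  return List::create(
    _["mesh"] = E.toList(), _["samples"] = samples, _["events"] = ev,
    _["energy"] = en, _["t_final"] = E.t, _["status"] = status,
    _["onset_time"] = onset_time, _["a0"] = a0,
    _["t_extinct"] = t_extinct,
    _["contractility_active"] = E.active);
}

// [[Rcpp::export]]
void vm_bench(List mesh, List params, int n) {  // TEMP scratch benchmark
  Engine E = makeEngine(mesh, params, 0.0, true);
  E.ensureTopo();
  auto t0 = std::chrono::high_resolution_clock::now();
  for (int i = 0; i < n; ++i) E.computeGeometry();
  auto t1 = std::chrono::high_resolution_clock::now();
  for (int i = 0; i < n; ++i) E.computeForces();
  auto t2 = std::chrono::high_resolution_clock::now();
  for (int i = 0; i < n; ++i) E.eulerMove();
  auto t3 = std::chrono::high_resolution_clock::now();
  auto us = [&](std::chrono::high_resolution_clock::time_point a,
                std::chrono::high_resolution_clock::time_point b) {
    return std::chrono::duration_cast<std::chrono::nanoseconds>(b - a).count() / 1e3 / n;
  };
  Rprintf("geometry %.2f us, forces %.2f us, euler %.2f us\n",
          us(t0, t1), us(t1, t2), us(t2, t3));
}
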