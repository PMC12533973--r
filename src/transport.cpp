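// Lagrangian embolus transport core: analytic in-segment velocity field with
// junction blending, modified Maxey-Riley forcing (Stokes drag, added mass,
// undisturbed-flow force, Saffman-type shear-gradient lift), wall collisions
// with impact-Stokes-dependent lubricated restitution, and the explicit Euler
// batch integrator. Units: mm, mm/s, s; conversions to SI are local.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

struct V3 {
  double x, y, z;
  V3(double a = 0, double b = 0, double c = 0) : x(a), y(b), z(c) {}
};
static inline V3 operator+(V3 a, V3 b) { return V3(a.x + b.x, a.y + b.y, a.z + b.z); }
static inline V3 operator-(V3 a, V3 b) { return V3(a.x - b.x, a.y - b.y, a.z - b.z); }
static inline V3 operator*(double s, V3 a) { return V3(s * a.x, s * a.y, s * a.z); }
static inline double dot(V3 a, V3 b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
static inline V3 cross(V3 a, V3 b) {
  return V3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
static inline double norm3(V3 a) { return std::sqrt(dot(a, a)); }

struct Seg {
  V3 p0, ez;
  double L, r0, r1;
  bool sten;
  double sc, shalf, fth;
  bool occluded;
  int prox, dist;
  int outlet;  // 0 = interior segment, else 1-based outlet index
};

// lumen radius and its first two axial derivatives at arc length s
static inline void radius_at(const Seg& sg, double s, double& R, double& dR,
                             double& d2R) {
  double slope = (sg.r1 - sg.r0) / sg.L;
  double Rb = sg.r0 + slope * s, dRb = slope;
  R = Rb; dR = dRb; d2R = 0.0;
  if (sg.sten) {
    double u = (s - sg.sc) / sg.shalf;
    if (u > -1.0 && u < 1.0) {
      double c = std::cos(M_PI * u), sn = std::sin(M_PI * u);
      double m = 1.0 - (1.0 - sg.fth) * 0.5 * (1.0 + c);
      double dm = (1.0 - sg.fth) * 0.5 * M_PI / sg.shalf * sn;
      double d2m = (1.0 - sg.fth) * 0.5 * M_PI * M_PI / (sg.shalf * sg.shalf) * c;
      R = Rb * m;
      dR = dRb * m + Rb * dm;
      d2R = 2.0 * dRb * dm + Rb * d2m;
    }
  }
}

// Interior junction: within a sphere of radius rJ around the node the field
// switches to a mass-conserving potential flow of softened point
// sources/sinks located at the segment ports, with strengths equal to the
// instantaneous signed segment flows. This routes emboli across branch
// points in proportion to the flow split.
struct NodeJ {
  V3 pos;
  double rJ;
  bool active;
  std::vector<int> segs;
  std::vector<double> sign;  // +1: positive segment flow enters the node
  std::vector<V3> port;
  std::vector<double> eps2;
};

struct Net {
  std::vector<Seg> segs;
  std::vector<std::vector<int> > cand;  // segment -> blend/transition candidates
  std::vector<NodeJ> nodes;
  int inlet_seg;
};

static Net parse_net(const List& nl) {
  Net net;
  NumericMatrix p0 = nl["p0"], p1 = nl["p1"];
  NumericVector r0 = nl["r0"], r1 = nl["r1"], sc = nl["sc"], shalf = nl["shalf"],
                fth = nl["fth"];
  IntegerVector sten = nl["sten"], occ = nl["occluded"], prox = nl["prox"],
                dist = nl["dist"], outlet = nl["outlet"];
  int nseg = p0.nrow();
  int nnode = as<int>(nl["nnode"]);
  net.inlet_seg = as<int>(nl["inlet_seg"]);
  net.segs.resize(nseg);
  std::vector<std::vector<int> > adj(nnode);
  for (int i = 0; i < nseg; i++) {
    Seg& s = net.segs[i];
    s.p0 = V3(p0(i, 0), p0(i, 1), p0(i, 2));
    V3 d = V3(p1(i, 0), p1(i, 1), p1(i, 2)) - s.p0;
    s.L = norm3(d);
    s.ez = (1.0 / s.L) * d;
    s.r0 = r0[i]; s.r1 = r1[i];
    s.sten = sten[i] != 0; s.sc = sc[i]; s.shalf = shalf[i]; s.fth = fth[i];
    s.occluded = occ[i] != 0;
    s.prox = prox[i]; s.dist = dist[i]; s.outlet = outlet[i];
    adj[s.prox].push_back(i);
    adj[s.dist].push_back(i);
  }
  net.cand.resize(nseg);
  for (int i = 0; i < nseg; i++) {
    if (net.segs[i].occluded) continue;
    std::vector<int>& c = net.cand[i];
    c.push_back(i);
    const int nodes[2] = {net.segs[i].prox, net.segs[i].dist};
    for (int k = 0; k < 2; k++)
      for (size_t m = 0; m < adj[nodes[k]].size(); m++) {
        int j = adj[nodes[k]][m];
        if (j == i || net.segs[j].occluded) continue;
        bool seen = false;
        for (size_t q = 0; q < c.size(); q++) if (c[q] == j) seen = true;
        if (!seen) c.push_back(j);
      }
  }
  net.nodes.resize(nnode);
  for (int nd = 0; nd < nnode; nd++) {
    NodeJ& J = net.nodes[nd];
    J.active = false;
    double maxR = 0, minL = 1e30;
    V3 psum;
    for (size_t m = 0; m < adj[nd].size(); m++) {
      int j = adj[nd][m];
      const Seg& sg = net.segs[j];
      if (sg.occluded) continue;
      bool at_dist = (sg.dist == nd);
      double Rend, dum1, dum2;
      radius_at(sg, at_dist ? sg.L : 0.0, Rend, dum1, dum2);
      J.segs.push_back(j);
      J.sign.push_back(at_dist ? 1.0 : -1.0);
      psum = psum + (at_dist ? sg.p0 + sg.L * sg.ez : sg.p0);
      if (Rend > maxR) maxR = Rend;
      if (sg.L < minL) minL = sg.L;
    }
    if (J.segs.size() < 2) continue;
    J.active = true;
    J.pos = (1.0 / J.segs.size()) * psum;
    J.rJ = std::min(1.5 * maxR, 0.4 * minL);
    // the sphere must cover the end cap of a terminating parent that has no
    // comparable-radius continuation, or a stagnation crescent forms there
    double runmatched = 0;
    for (size_t m = 0; m < J.segs.size(); m++) {
      const Seg& sm = net.segs[J.segs[m]];
      double Rm, d1, d2;
      radius_at(sm, sm.dist == nd ? sm.L : 0.0, Rm, d1, d2);
      bool matched = false;
      for (size_t q = 0; q < J.segs.size(); q++) {
        if (q == m) continue;
        const Seg& sq = net.segs[J.segs[q]];
        double Rq;
        radius_at(sq, sq.dist == nd ? sq.L : 0.0, Rq, d1, d2);
        if (Rq >= 0.8 * Rm) { matched = true; break; }
      }
      if (!matched && Rm > runmatched) runmatched = Rm;
    }
    if (J.rJ < 1.05 * runmatched) J.rJ = 1.05 * runmatched;
    for (size_t m = 0; m < J.segs.size(); m++) {
      const Seg& sg = net.segs[J.segs[m]];
      bool at_dist = (sg.dist == nd);
      V3 end = at_dist ? sg.p0 + sg.L * sg.ez : sg.p0;
      V3 dir = at_dist ? -1.0 * sg.ez : sg.ez;  // away from node into segment
      double Rend0, dd1, dd2;
      radius_at(sg, at_dist ? sg.L : 0.0, Rend0, dd1, dd2);
      // port singularity sits outside the junction sphere, one branch radius
      // beyond the surface, so no stagnation trap forms at a strong sink
      double dport = std::min(J.rJ + Rend0, 0.9 * sg.L);
      J.port.push_back(end + dport * dir);
      double Rend, dum1, dum2;
      radius_at(sg, at_dist ? sg.L : 0.0, Rend, dum1, dum2);
      double eps = 1.0 * Rend;
      J.eps2.push_back(eps * eps);
    }
  }
  return net;
}


struct Flow {
  double T, dtq;
  int nt, nseg;
  const double* Q;
  const double* dQdt;
};

static Flow parse_flow(const List& fl, NumericMatrix& Qm, NumericMatrix& Dm) {
  Flow f;
  f.T = as<double>(fl["T"]);
  Qm = as<NumericMatrix>(fl["Q"]);
  Dm = as<NumericMatrix>(fl["dQdt"]);
  f.nt = Qm.ncol(); f.nseg = Qm.nrow();
  f.dtq = f.T / f.nt;
  f.Q = REAL(Qm); f.dQdt = REAL(Dm);
  return f;
}

// periodic linear interpolation of segment flow (this realizes the
// stitched-cycle extension of the periodic solution)
static inline void flow_at(const Flow& f, int seg, double t, double& Q,
                           double& Qd) {
  double tt = t - f.T * std::floor(t / f.T);
  double x = tt / f.dtq;
  int i0 = (int)std::floor(x);
  double fr = x - i0;
  i0 = i0 % f.nt;
  int i1 = (i0 + 1) % f.nt;
  Q = f.Q[seg + (size_t)f.nseg * i0] * (1 - fr) + f.Q[seg + (size_t)f.nseg * i1] * fr;
  Qd = f.dQdt[seg + (size_t)f.nseg * i0] * (1 - fr) + f.dQdt[seg + (size_t)f.nseg * i1] * fr;
}

struct Loc {
  int seg;
  double sraw, s, rho, depth, dcap, R, dR, d2R;
  V3 er;    // perpendicular radial unit (zero on axis)
  V3 ncap;  // capsule surface normal (outward)
  bool found;
};

static Loc locate_seg(const Seg& sg, const V3& x) {
  Loc lc;
  lc.sraw = dot(x - sg.p0, sg.ez);
  lc.s = lc.sraw < 0 ? 0 : (lc.sraw > sg.L ? sg.L : lc.sraw);
  V3 rel = x - (sg.p0 + lc.s * sg.ez);
  lc.dcap = norm3(rel);
  V3 perp = x - (sg.p0 + lc.sraw * sg.ez);
  lc.rho = norm3(perp);
  radius_at(sg, lc.s, lc.R, lc.dR, lc.d2R);
  lc.depth = lc.R - lc.dcap;
  lc.er = lc.rho > 1e-12 ? (1.0 / lc.rho) * perp : V3(0, 0, 0);
  lc.ncap = lc.dcap > 1e-12 ? (1.0 / lc.dcap) * rel : lc.er;
  lc.found = true;
  return lc;
}

static Loc locate(const Net& net, const V3& x, int hint) {
  const std::vector<int>& cc = net.cand[hint];
  Loc best; best.found = false; best.depth = -1e30; best.seg = hint;
  for (size_t k = 0; k < cc.size(); k++) {
    const Seg& sg = net.segs[cc[k]];
    Loc lc = locate_seg(sg, x);
    lc.seg = cc[k];
    if (lc.depth > best.depth) best = lc;
  }
  if (best.depth < -1.0) {  // far outside candidates: global fallback
    for (size_t j = 0; j < net.segs.size(); j++) {
      if (net.segs[j].occluded) continue;
      Loc lc = locate_seg(net.segs[j], x);
      lc.seg = (int)j;
      if (lc.depth > best.depth) best = lc;
    }
  }
  return best;
}

// single-segment Poiseuille field (axial + continuity radial component);
// c = 2*Q[mm^3/s]/pi. Fills u and, if grad != null, the velocity gradient.
static void seg_field(const Seg& sg, const Loc& lc, double c, V3& u,
                      double* grad) {
  double R = lc.R;
  if (R <= 1e-9 || lc.rho >= R) { u = V3(); if (grad) for (int i = 0; i < 9; i++) grad[i] = 0; return; }
  double rho = lc.rho;
  double iR2 = 1.0 / (R * R), iR3 = iR2 / R, iR4 = iR3 / R, iR5 = iR4 / R,
         iR6 = iR5 / R;
  double uz = c * (iR2 - rho * rho * iR4);
  double ur = c * lc.dR * (rho * iR3 - rho * rho * rho * iR5);
  u = uz * sg.ez + ur * lc.er;
  if (!grad) return;
  double duz_dr = -2.0 * c * rho * iR4;
  double duz_ds = c * lc.dR * (-2.0 * iR3 + 4.0 * rho * rho * iR5);
  double dur_dr = c * lc.dR * (iR3 - 3.0 * rho * rho * iR5);
  double dur_ds = c * (lc.d2R * (rho * iR3 - rho * rho * rho * iR5) +
                       lc.dR * lc.dR * (-3.0 * rho * iR4 + 5.0 * rho * rho * rho * iR6));
  double ur_over_rho = c * lc.dR * (iR3 - rho * rho * iR5);
  V3 er = lc.er, ez = sg.ez;
  V3 ephi = cross(ez, er);
  // grad[3*i+j] = du_i/dx_j
  double e1[3] = {ez.x, ez.y, ez.z};
  double e2[3] = {er.x, er.y, er.z};
  double e3[3] = {ephi.x, ephi.y, ephi.z};
  bool on_axis = rho <= 1e-12;
  for (int i = 0; i < 3; i++)
    for (int j = 0; j < 3; j++) {
      double g = e1[i] * (duz_ds * e1[j] + duz_dr * e2[j]) +
                 e2[i] * (dur_ds * e1[j] + dur_dr * e2[j]);
      if (!on_axis) g += ur_over_rho * e3[i] * e3[j];
      grad[3 * i + j] = g;
    }
}

struct FieldOut {
  V3 u, udot;
  double grad[9];
  Loc loc;
  double wsum;
  double depth;   // effective containment depth (capsule or junction sphere)
  V3 ncap;        // effective outward wall normal
  double junction_w;
};

// softened point-source potential-flow field of one junction
static void junction_field(const Net& net, const Flow& flow, const NodeJ& J,
                           const V3& x, double t, V3& u, V3& udot,
                           double* grad) {
  u = V3(); udot = V3();
  if (grad) for (int i = 0; i < 9; i++) grad[i] = 0;
  for (size_t m = 0; m < J.segs.size(); m++) {
    double Q, Qd;
    flow_at(flow, J.segs[m], t, Q, Qd);
    double q = 1000.0 * J.sign[m] * Q / (4.0 * M_PI);    // mm^3/s source
    double qd = 1000.0 * J.sign[m] * Qd / (4.0 * M_PI);
    V3 r = x - J.port[m];
    double r2 = dot(r, r) + J.eps2[m];
    double ir3 = 1.0 / (r2 * std::sqrt(r2));
    u = u + (q * ir3) * r;
    udot = udot + (qd * ir3) * r;
    if (grad) {
      double ir5 = ir3 / r2;
      double rr[3] = {r.x, r.y, r.z};
      for (int i = 0; i < 3; i++)
        for (int j = 0; j < 3; j++)
          grad[3 * i + j] += q * ((i == j ? ir3 : 0.0) -
                                  3.0 * rr[i] * rr[j] * ir5);
    }
  }
}

// blended field: capsule-containment-depth^2 weights over candidate segments,
// with a potential-flow junction zone near interior nodes
static void eval_field(const Net& net, const Flow& flow, const V3& x, double t,
                       int hint, bool want_grad, FieldOut& out) {
  Loc best = locate(net, x, hint);
  out.loc = best;
  out.u = V3(); out.udot = V3();
  for (int i = 0; i < 9; i++) out.grad[i] = 0;
  out.wsum = 0;
  const std::vector<int>& cc = net.cand[best.seg];
  double g[9];
  for (size_t k = 0; k < cc.size(); k++) {
    const Seg& sg = net.segs[cc[k]];
    Loc lc = locate_seg(sg, x);
    if (lc.depth <= 0) continue;
    // fade the extrapolated field over one radius of axial overshoot past
    // the segment end (the junction field takes over there)
    double o = std::fabs(lc.sraw - lc.s);
    double att = lc.R > 0 ? 1.0 - o / lc.R : 0.0;
    if (att <= 0) continue;
    double w = lc.depth * lc.depth * att * att;
    double Q, Qd;
    flow_at(flow, cc[k], t, Q, Qd);
    double c = att * 2.0 * 1000.0 * Q / M_PI;
    double cd = att * 2.0 * 1000.0 * Qd / M_PI;
    V3 u, ud;
    seg_field(sg, lc, c, u, want_grad ? g : (double*)0);
    seg_field(sg, lc, cd, ud, (double*)0);
    out.u = out.u + w * u;
    out.udot = out.udot + w * ud;
    if (want_grad) for (int i = 0; i < 9; i++) out.grad[i] += w * g[i];
    out.wsum += w;
  }
  if (out.wsum > 0) {
    double iw = 1.0 / out.wsum;
    out.u = iw * out.u; out.udot = iw * out.udot;
    for (int i = 0; i < 9; i++) out.grad[i] *= iw;
  }
  out.depth = best.depth;
  out.ncap = best.ncap;
  out.junction_w = 0;
  // junction zone of the nearer active node of the host segment
  const Seg& bs = net.segs[best.seg];
  const int nds[2] = {bs.prox, bs.dist};
  double lam = 0; const NodeJ* Jbest = 0; double dbest = 0;
  for (int k = 0; k < 2; k++) {
    const NodeJ& J = net.nodes[nds[k]];
    if (!J.active) continue;
    V3 rel = x - J.pos;
    double d = norm3(rel);
    if (d >= J.rJ) continue;
    double l = (J.rJ - d) / (0.05 * J.rJ);  // thin transition shell
    if (l > 1) l = 1;
    if (l > lam) { lam = l; Jbest = &J; dbest = d; }
  }
  if (Jbest) {
    V3 uj, udj;
    double gj[9];
    junction_field(net, flow, *Jbest, x, t, uj, udj,
                   want_grad ? gj : (double*)0);
    out.u = lam * uj + (1 - lam) * out.u;
    out.udot = lam * udj + (1 - lam) * out.udot;
    if (want_grad)
      for (int i = 0; i < 9; i++)
        out.grad[i] = lam * gj[i] + (1 - lam) * out.grad[i];
    out.junction_w = lam;
    double sdepth = Jbest->rJ - dbest;
    if (sdepth > out.depth) {
      out.depth = sdepth;
      out.ncap = dbest > 1e-12 ? (1.0 / dbest) * (x - Jbest->pos) : out.ncap;
    }
  }
}

// containment query: capsule depth of the best host segment, overridden by
// the junction sphere when that is deeper
struct Contain {
  Loc loc;
  double depth;
  V3 n;  // outward
};

static Contain containment(const Net& net, const V3& x, int hint) {
  Contain c;
  c.loc = locate(net, x, hint);
  c.depth = c.loc.depth;
  c.n = c.loc.ncap;
  const Seg& bs = net.segs[c.loc.seg];
  const int nds[2] = {bs.prox, bs.dist};
  for (int k = 0; k < 2; k++) {
    const NodeJ& J = net.nodes[nds[k]];
    if (!J.active) continue;
    V3 rel = x - J.pos;
    double d = norm3(rel);
    double sdepth = J.rJ - d;
    if (sdepth > c.depth) {
      c.depth = sdepth;
      c.n = d > 1e-12 ? (1.0 / d) * rel : c.n;
    }
  }
  return c;
}

struct Props {
  double d_mm, rho_p, Cm, e0, Stc, Cl;
  bool lift_on, drag_on, flow_force_on;
};

static Props parse_props(const List& pl) {
  Props p;
  p.d_mm = as<double>(pl["diameter_um"]) * 1e-3;
  p.rho_p = as<double>(pl["density"]) * 1000.0;
  p.Cm = as<double>(pl["added_mass"]);
  p.e0 = as<double>(pl["restitution"]);
  p.Stc = as<double>(pl["critical_stokes"]);
  p.Cl = as<double>(pl["lift_coefficient"]);
  p.lift_on = as<bool>(pl["lift"]);
  p.drag_on = as<bool>(pl["drag"]);
  p.flow_force_on = as<bool>(pl["flow_force"]);
  return p;
}

struct Fluid { double mu, rho_f; };  // Pa s, kg/m^3
static Fluid parse_fluid(const List& fl) {
  Fluid f;
  f.mu = as<double>(fl["viscosity"]) * 1e-3;
  f.rho_f = as<double>(fl["density"]) * 1000.0;
  return f;
}

// modified Maxey-Riley acceleration (per unit effective particle mass)
static void accel(const FieldOut& fo, const V3& v, const Props& pp,
                  const Fluid& ff, V3& a_total, V3& a_drag, V3& a_flow,
                  V3& a_lift) {
  double d_m = pp.d_mm * 1e-3;
  double denom = pp.rho_p + pp.Cm * ff.rho_f;
  double tau = pp.rho_p * d_m * d_m / (18.0 * ff.mu);
  V3 slip = fo.u - v;
  a_drag = pp.drag_on ? (pp.rho_p / denom / tau) * slip : V3();
  V3 Dudt(fo.udot.x + fo.grad[0] * fo.u.x + fo.grad[1] * fo.u.y + fo.grad[2] * fo.u.z,
          fo.udot.y + fo.grad[3] * fo.u.x + fo.grad[4] * fo.u.y + fo.grad[5] * fo.u.z,
          fo.udot.z + fo.grad[6] * fo.u.x + fo.grad[7] * fo.u.y + fo.grad[8] * fo.u.z);
  a_flow = pp.flow_force_on ? ((1.0 + pp.Cm) * ff.rho_f / denom) * Dudt : V3();
  a_lift = V3();
  if (pp.lift_on) {
    V3 om(fo.grad[7] - fo.grad[5], fo.grad[2] - fo.grad[6], fo.grad[3] - fo.grad[1]);
    double nom = norm3(om);
    if (nom > 1e-8) {
      V3 slip_SI = 1e-3 * slip;
      V3 F = (pp.Cl * d_m * d_m * std::sqrt(ff.mu * ff.rho_f / nom)) *
             cross(slip_SI, om);
      double m_eff = M_PI / 6.0 * d_m * d_m * d_m * denom;
      a_lift = (1e3 / m_eff) * F;
    }
  }
  a_total = a_drag + a_flow + a_lift;
}

// lubricated wall collision: effective restitution e0*max(0, 1 - Stc/Stn)
static double effective_restitution(double vn_mm_s, const Props& pp,
                                    const Fluid& ff) {
  if (vn_mm_s <= 0) return 0.0;
  double Stn = pp.rho_p * (pp.d_mm * 1e-3) * (vn_mm_s * 1e-3) / (9.0 * ff.mu);
  if (Stn <= pp.Stc) return 0.0;
  return pp.e0 * (1.0 - pp.Stc / Stn);
}

// [[Rcpp::export]]
List locate_cpp(List net_list, NumericVector x, int hint) {
  Net net = parse_net(net_list);
  Loc lc = locate(net, V3(x[0], x[1], x[2]), hint);
  return List::create(_["segment"] = lc.seg + 1, _["s"] = lc.s,
                      _["s_raw"] = lc.sraw, _["rho"] = lc.rho,
                      _["radius"] = lc.R, _["wall_distance"] = lc.depth,
                      _["normal"] = NumericVector::create(-lc.ncap.x, -lc.ncap.y, -lc.ncap.z),
                      _["inside"] = lc.depth > 0);
}

// [[Rcpp::export]]
List field_eval_cpp(List net_list, List flow_list, NumericVector x, double t,
                    int hint) {
  Net net = parse_net(net_list);
  NumericMatrix Qm, Dm;
  Flow flow = parse_flow(flow_list, Qm, Dm);
  FieldOut fo;
  eval_field(net, flow, V3(x[0], x[1], x[2]), t, hint, true, fo);
  NumericMatrix g(3, 3);
  for (int i = 0; i < 3; i++)
    for (int j = 0; j < 3; j++) g(i, j) = fo.grad[3 * i + j];
  return List::create(
      _["u"] = NumericVector::create(fo.u.x, fo.u.y, fo.u.z),
      _["dudt"] = NumericVector::create(fo.udot.x, fo.udot.y, fo.udot.z),
      _["grad"] = g, _["segment"] = fo.loc.seg + 1, _["s"] = fo.loc.s,
      _["rho"] = fo.loc.rho, _["wall_distance"] = fo.loc.depth,
      _["junction_w"] = fo.junction_w,
      _["inside"] = fo.loc.depth > 0);
}

// [[Rcpp::export]]
List accel_cpp(List net_list, List flow_list, NumericVector x, NumericVector v,
               double t, List props, List fluid, int hint) {
  Net net = parse_net(net_list);
  NumericMatrix Qm, Dm;
  Flow flow = parse_flow(flow_list, Qm, Dm);
  Props pp = parse_props(props);
  Fluid ff = parse_fluid(fluid);
  FieldOut fo;
  eval_field(net, flow, V3(x[0], x[1], x[2]), t, hint, true, fo);
  if (fo.loc.depth <= 0) stop("query point outside the lumen");
  V3 at, ad, af, al;
  accel(fo, V3(v[0], v[1], v[2]), pp, ff, at, ad, af, al);
  return List::create(
      _["total"] = NumericVector::create(at.x, at.y, at.z),
      _["drag"] = NumericVector::create(ad.x, ad.y, ad.z),
      _["flow_force"] = NumericVector::create(af.x, af.y, af.z),
      _["lift"] = NumericVector::create(al.x, al.y, al.z));
}

// [[Rcpp::export]]
List collide_cpp(NumericVector v, NumericVector wall_normal, List props,
                 List fluid) {
  Props pp = parse_props(props);
  Fluid ff = parse_fluid(fluid);
  V3 vv(v[0], v[1], v[2]);
  V3 n(wall_normal[0], wall_normal[1], wall_normal[2]);  // into the lumen
  double inn = norm3(n);
  if (inn <= 0) stop("zero wall normal");
  n = (1.0 / inn) * n;
  double vn = -dot(vv, n);  // speed toward the wall
  if (vn <= 0)
    return List::create(_["velocity"] = v, _["collided"] = false,
                        _["restitution"] = NA_REAL);
  double e = effective_restitution(vn, pp, ff);
  V3 vout = vv + (1.0 + e) * vn * n;
  return List::create(
      _["velocity"] = NumericVector::create(vout.x, vout.y, vout.z),
      _["collided"] = true, _["restitution"] = e);
}

// [[Rcpp::export]]
List integrate_batch_cpp(List net_list, List flow_list, NumericMatrix X0,
                         NumericMatrix V0, NumericVector t0, IntegerVector seg0,
                         List props, List fluid, double dt, double t_end,
                         int record_every = 0, int max_visited = 64) {
  Net net = parse_net(net_list);
  NumericMatrix Qm, Dm;
  Flow flow = parse_flow(flow_list, Qm, Dm);
  Props pp = parse_props(props);
  Fluid ff = parse_fluid(fluid);
  double a_emb = pp.d_mm / 2.0;

  int n = X0.nrow();
  IntegerVector status(n), outlet(n), collisions(n), steps(n);
  NumericVector exit_time(n, NA_REAL), t_final(n);
  NumericMatrix Xf(n, 3), Vf(n, 3);
  List visited_out(n), traj_out(record_every > 0 ? n : 0);

  for (int p = 0; p < n; p++) {
    V3 x(X0(p, 0), X0(p, 1), X0(p, 2));
    V3 v(V0(p, 0), V0(p, 1), V0(p, 2));
    double t = t0[p];
    int hint = seg0[p] - 1;
    std::vector<int> visited;
    visited.push_back(hint);
    std::vector<double> traj;
    int ncol = 0, st = 0, out = 0, nstep = 0;
    double texit = NA_REAL;
    FieldOut fo;
    while (t < t_end) {
      eval_field(net, flow, x, t, hint, true, fo);
      V3 at, ad, af, al;
      accel(fo, v, pp, ff, at, ad, af, al);
      x = x + dt * v;
      v = v + dt * at;
      t += dt;
      nstep++;
      Contain cn = containment(net, x, fo.loc.seg);
      Loc& lc = cn.loc;
      hint = lc.seg;
      if (visited.back() != lc.seg && (int)visited.size() < max_visited)
        visited.push_back(lc.seg);
      const Seg& sg = net.segs[lc.seg];
      if (sg.outlet > 0 && lc.sraw >= sg.L) {
        st = 1; out = sg.outlet; texit = t;
        break;
      }
      if (lc.seg == net.inlet_seg && lc.sraw < 0) {
        // inlet face: reflect back into the root (no upstream exit)
        x = x - (lc.sraw - 1e-3) * sg.ez;
        double vax = dot(v, sg.ez);
        if (vax < 0) v = v - vax * sg.ez;
        cn = containment(net, x, lc.seg);
      }
      if (cn.depth < a_emb) {
        V3 nwall = cn.n;  // outward
        double vn = dot(v, nwall);
        if (vn > 0) {
          double e = effective_restitution(vn, pp, ff);
          v = v - (1.0 + e) * vn * nwall;
          ncol++;
        }
        // project the centre back to the wall-offset surface
        x = x + (a_emb - cn.depth) * (-1.0 * nwall);
      }
      if (record_every > 0 && nstep % record_every == 0 &&
          traj.size() < 80000) {
        traj.push_back(t); traj.push_back(x.x); traj.push_back(x.y);
        traj.push_back(x.z);
      }
      if (nstep % 20000 == 0) Rcpp::checkUserInterrupt();
    }
    status[p] = st; outlet[p] = out; collisions[p] = ncol; steps[p] = nstep;
    exit_time[p] = texit; t_final[p] = t;
    Xf(p, 0) = x.x; Xf(p, 1) = x.y; Xf(p, 2) = x.z;
    Vf(p, 0) = v.x; Vf(p, 1) = v.y; Vf(p, 2) = v.z;
    IntegerVector vis(visited.size());
    for (size_t k = 0; k < visited.size(); k++) vis[k] = visited[k] + 1;
    visited_out[p] = vis;
    if (record_every > 0) {
      int np = traj.size() / 4;
      NumericMatrix tm(np, 4);
      for (int k = 0; k < np; k++)
        for (int c2 = 0; c2 < 4; c2++) tm(k, c2) = traj[4 * k + c2];
      traj_out[p] = tm;
    }
  }
  List res = List::create(
      _["status"] = status, _["outlet"] = outlet, _["exit_time"] = exit_time,
      _["t_final"] = t_final, _["position"] = Xf, _["velocity"] = Vf,
      _["collisions"] = collisions, _["steps"] = steps,
      _["visited"] = visited_out);
  if (record_every > 0) res["trajectory"] = traj_out;
  return res;
}
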