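// Lattice kernel for the extended Cellular Potts model.
//
// A cell is a 4-connected set of occupied sites on a rectangular grid,
// restricted to an adhesive mask.  Elementary Metropolis moves add or remove
// single boundary sites under
//
//     H = kappa_A * A^2 + kappa_P * P^2 - sum_x eps(x)
//
// with A the contact area (um^2), P the contour length (um) counted over
// exposed 4-neighbour edges, and eps(x) a per-site polarization field.
// After every Monte Carlo step (MCS) sites are classified by the balance of
// accepted protrusion/retraction events within a signaling radius R and the
// field relaxes exponentially towards eps0 +/- deps/2 (or eps0 when neutral).
//
// All randomness comes from R's RNG so set.seed() gives bit-identical runs.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Params {
  double kappa_A, kappa_P, eps0, deps, mu, R, kT, mcs_minutes, h;
};

Params read_params(const List& par) {
  Params p;
  p.kappa_A = as<double>(par["kappa_A"]);
  p.kappa_P = as<double>(par["kappa_P"]);
  p.eps0 = as<double>(par["eps0"]);
  p.deps = as<double>(par["delta_eps"]);
  p.mu = as<double>(par["mu"]);
  p.R = as<double>(par["signaling_R"]);
  p.kT = as<double>(par["kT"]);
  p.mcs_minutes = as<double>(par["mcs_minutes"]);
  p.h = as<double>(par["spacing"]);
  return p;
}

struct Lattice {
  int nx, ny, n;
  double h;
  std::vector<uint8_t> mask, occ;
  std::vector<double> eps;
  std::vector<int8_t> label;       // event label this MCS: +1 protruded, -1 retracted
  std::vector<int> labeled;        // sites carrying a label
  std::vector<int> occ_list;       // indices of occupied sites
  std::vector<int> pos;            // position in occ_list, -1 if empty
  long A;                          // occupied site count
  long P;                          // exposed edge count
  double eps_sum;                  // sum of eps over occupied sites
  double sum_i;                    // sum of long-axis indices (for COM)

  void init(const LogicalMatrix& m) {
    nx = m.nrow(); ny = m.ncol(); n = nx * ny; h = 0;
    mask.assign(n, 0);
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) mask[i + nx * j] = m(i, j) ? 1 : 0;
    occ.assign(n, 0);
    eps.assign(n, 0.0);
    label.assign(n, 0);
    pos.assign(n, -1);
    occ_list.clear(); labeled.clear();
    A = 0; P = 0; eps_sum = 0; sum_i = 0;
  }

  inline int ix(int idx) const { return idx % nx; }
  inline int iy(int idx) const { return idx / nx; }

  // neighbour in direction d (0:+x 1:-x 2:+y 3:-y), -1 if off-grid
  inline int nbr(int idx, int d) const {
    int i = ix(idx), j = iy(idx);
    switch (d) {
      case 0: return (i + 1 < nx) ? idx + 1 : -1;
      case 1: return (i > 0) ? idx - 1 : -1;
      case 2: return (j + 1 < ny) ? idx + nx : -1;
      default: return (j > 0) ? idx - nx : -1;
    }
  }

  inline int occ_nbrs(int idx) const {
    int c = 0;
    for (int d = 0; d < 4; ++d) {
      int nb = nbr(idx, d);
      if (nb >= 0 && occ[nb]) ++c;
    }
    return c;
  }

  void seed_site(int idx, double e) {   // used when building initial state
    occ[idx] = 1;
    pos[idx] = (int)occ_list.size();
    occ_list.push_back(idx);
    eps[idx] = e;
    eps_sum += e;
    sum_i += ix(idx);
    ++A;
    P += 4 - 2 * occ_nbrs(idx);
  }

  inline double dH_add(int idx, double e, const Params& p) const {
    long dE = 4 - 2 * occ_nbrs(idx);
    double h2 = h * h, h4 = h2 * h2;
    double dA = p.kappa_A * h4 * (double)(2 * A + 1);
    double dP = p.kappa_P * h2 * (double)(dE * (2 * P + dE));
    return dA + dP - e;
  }

  inline double dH_remove(int idx, const Params& p) const {
    long dE = 2 * occ_nbrs(idx) - 4;
    double h2 = h * h, h4 = h2 * h2;
    double dA = -p.kappa_A * h4 * (double)(2 * A - 1);
    double dP = p.kappa_P * h2 * (double)(dE * (2 * P + dE));
    return dA + dP + eps[idx];
  }

  void add(int idx, double e) {
    P += 4 - 2 * occ_nbrs(idx);
    occ[idx] = 1;
    pos[idx] = (int)occ_list.size();
    occ_list.push_back(idx);
    eps[idx] = e;
    eps_sum += e;
    sum_i += ix(idx);
    ++A;
  }

  void remove(int idx) {
    P += 2 * occ_nbrs(idx) - 4;
    occ[idx] = 0;
    int pi = pos[idx], last = occ_list.back();
    occ_list[pi] = last; pos[last] = pi;
    occ_list.pop_back(); pos[idx] = -1;
    eps_sum -= eps[idx];
    sum_i -= ix(idx);
    --A;
  }

  // Would removing idx keep the remaining occupied neighbours locally
  // 4-connected within the 3x3 neighbourhood?  Conservative articulation
  // check: global connectivity can only be broken through local paths.
  bool removable(int idx) const {
    if (A <= 1) return false;
    int i0 = ix(idx), j0 = iy(idx);
    bool nb[3][3];
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        int i = i0 + di, j = j0 + dj;
        nb[di + 1][dj + 1] = (i >= 0 && i < nx && j >= 0 && j < ny) &&
                             occ[i + nx * j] && !(di == 0 && dj == 0);
      }
    // 4-neighbours of idx that are occupied must form one component
    int comp[3][3]; for (int a = 0; a < 3; ++a) for (int b = 0; b < 3; ++b) comp[a][b] = -1;
    int stack[9]; int nfour = 0, first = -1;
    const int fdi[4] = {1, -1, 0, 0}, fdj[4] = {0, 0, 1, -1};
    for (int d = 0; d < 4; ++d)
      if (nb[fdi[d] + 1][fdj[d] + 1]) { ++nfour; first = d; }
    if (nfour <= 1) return true;
    // BFS from the first occupied 4-neighbour, moving 4-adjacently inside 3x3
    int top = 0;
    int si = fdi[first] + 1, sj = fdj[first] + 1;
    comp[si][sj] = 0; stack[top++] = si * 3 + sj;
    while (top > 0) {
      int c = stack[--top]; int a = c / 3, b = c % 3;
      const int ddi[4] = {1, -1, 0, 0}, ddj[4] = {0, 0, 1, -1};
      for (int d = 0; d < 4; ++d) {
        int na = a + ddi[d], nbj = b + ddj[d];
        if (na < 0 || na > 2 || nbj < 0 || nbj > 2) continue;
        if (na == 1 && nbj == 1) continue;          // removed centre blocks paths
        if (nb[na][nbj] && comp[na][nbj] < 0) { comp[na][nbj] = 0; stack[top++] = na * 3 + nbj; }
      }
    }
    for (int d = 0; d < 4; ++d) {
      int a = fdi[d] + 1, b = fdj[d] + 1;
      if (nb[a][b] && comp[a][b] < 0) return false;
    }
    return true;
  }

  int boundary_count() const {
    int b = 0;
    for (size_t k = 0; k < occ_list.size(); ++k)
      if (occ_nbrs(occ_list[k]) < 4) ++b;
    return b;
  }

  double hamiltonian(const Params& p) const {
    double h2 = h * h;
    return p.kappa_A * (double)A * (double)A * h2 * h2 +
           p.kappa_P * (double)P * (double)P * h2 - eps_sum;
  }

  void clear_labels() {
    for (size_t k = 0; k < labeled.size(); ++k) label[labeled[k]] = 0;
    labeled.clear();
  }
};

void build_from_matrices(Lattice& L, const LogicalMatrix& mask,
                         const LogicalMatrix& occ, const NumericMatrix& eps,
                         double h) {
  L.init(mask);
  L.h = h;
  for (int j = 0; j < L.ny; ++j)
    for (int i = 0; i < L.nx; ++i)
      if (occ(i, j)) L.seed_site(i + L.nx * j, eps(i, j));
}

// offsets within Euclidean distance R (in um, spacing h)
std::vector<std::pair<int,int> > disc_offsets(double R, double h) {
  std::vector<std::pair<int,int> > off;
  int m = (int)std::floor(R / h);
  for (int dj = -m; dj <= m; ++dj)
    for (int di = -m; di <= m; ++di)
      if ((di * di + dj * dj) * h * h <= R * R + 1e-12)
        off.push_back(std::make_pair(di, dj));
  return off;
}

// Single Metropolis attempt.  Returns: 0 no-op, +1 protrusion accepted,
// -1 retraction accepted; fills dH/site/type when a candidate was evaluated.
int attempt(Lattice& L, const Params& p, int& site_out, int& type_out,
            double& dH_out, bool& evaluated) {
  evaluated = false; site_out = -1; type_out = 0; dH_out = NA_REAL;
  int s = L.occ_list[(int)std::floor(unif_rand() * L.A)];
  int d = (int)std::floor(unif_rand() * 4.0);
  int nb = L.nbr(s, d);
  bool protrude = unif_rand() < 0.5;
  if (nb >= 0 && L.occ[nb]) return 0;
  if (protrude) {
    if (nb < 0 || !L.mask[nb]) { // hard confinement: acceptance zero
      evaluated = true; site_out = nb; type_out = 1; dH_out = R_PosInf;
      return 0;
    }
    double dH = L.dH_add(nb, L.eps[s], p);
    evaluated = true; site_out = nb; type_out = 1; dH_out = dH;
    if (dH <= 0 || unif_rand() < std::exp(-dH / p.kT)) {
      L.add(nb, L.eps[s]);
      if (L.label[nb] == 0) L.labeled.push_back(nb);
      L.label[nb] = 1;
      return 1;
    }
    return 0;
  } else {
    if (L.A <= 1 || !L.removable(s)) return 0;
    double dH = L.dH_remove(s, p);
    evaluated = true; site_out = s; type_out = -1; dH_out = dH;
    if (dH <= 0 || unif_rand() < std::exp(-dH / p.kT)) {
      L.remove(s);
      if (L.label[s] == 0) L.labeled.push_back(s);
      L.label[s] = -1;
      return -1;
    }
    return 0;
  }
}

// classification + exponential field relaxation, applied once per MCS
void relax_field(Lattice& L, const Params& p,
                 const std::vector<std::pair<int,int> >& off,
                 std::vector<int>& pcnt, std::vector<int>& rcnt,
                 std::vector<int>& touched) {
  for (size_t k = 0; k < touched.size(); ++k) {
    pcnt[touched[k]] = 0; rcnt[touched[k]] = 0;
  }
  touched.clear();
  for (size_t k = 0; k < L.labeled.size(); ++k) {
    int e = L.labeled[k];
    int ei = L.ix(e), ej = L.iy(e);
    int8_t lab = L.label[e];
    for (size_t q = 0; q < off.size(); ++q) {
      int i = ei + off[q].first, j = ej + off[q].second;
      if (i < 0 || i >= L.nx || j < 0 || j >= L.ny) continue;
      int t = i + L.nx * j;
      if (pcnt[t] == 0 && rcnt[t] == 0) touched.push_back(t);
      if (lab > 0) ++pcnt[t]; else ++rcnt[t];
    }
  }
  double f = std::exp(-p.mu * p.mcs_minutes);
  double lo = p.eps0 - p.deps / 2.0, hi = p.eps0 + p.deps / 2.0;
  for (size_t k = 0; k < L.occ_list.size(); ++k) {
    int s = L.occ_list[k];
    double tgt = p.eps0;
    if (pcnt[s] > rcnt[s]) tgt = hi;
    else if (rcnt[s] > pcnt[s]) tgt = lo;
    double e = tgt + (L.eps[s] - tgt) * f;
    if (e < lo) e = lo; else if (e > hi) e = hi;
    L.eps_sum += e - L.eps[s];
    L.eps[s] = e;
  }
}

LogicalMatrix occ_out(const Lattice& L) {
  LogicalMatrix m(L.nx, L.ny);
  for (int j = 0; j < L.ny; ++j)
    for (int i = 0; i < L.nx; ++i) m(i, j) = L.occ[i + L.nx * j] != 0;
  return m;
}

NumericMatrix eps_out(const Lattice& L) {
  NumericMatrix m(L.nx, L.ny);
  for (int j = 0; j < L.ny; ++j)
    for (int i = 0; i < L.nx; ++i)
      m(i, j) = L.occ[i + L.nx * j] ? L.eps[i + L.nx * j] : NA_REAL;
  return m;
}

IntegerMatrix label_out(const Lattice& L) {
  IntegerMatrix m(L.nx, L.ny);
  for (int j = 0; j < L.ny; ++j)
    for (int i = 0; i < L.nx; ++i) m(i, j) = L.label[i + L.nx * j];
  return m;
}

} // namespace

// [[Rcpp::export]]
double cpp_hamiltonian(LogicalMatrix mask, LogicalMatrix occ,
                       NumericMatrix eps, List par) {
  Params p = read_params(par);
  Lattice L; build_from_matrices(L, mask, occ, eps, p.h);
  return L.hamiltonian(p);
}

// [[Rcpp::export]]
List cpp_single_attempt(LogicalMatrix mask, LogicalMatrix occ,
                        NumericMatrix eps, List par) {
  Params p = read_params(par);
  Lattice L; build_from_matrices(L, mask, occ, eps, p.h);
  RNGScope scope;
  int site, type; double dH; bool eval;
  int res = attempt(L, p, site, type, dH, eval);
  int si = NA_INTEGER, sj = NA_INTEGER;
  if (site >= 0) { si = L.ix(site) + 1; sj = L.iy(site) + 1; }
  return List::create(
    _["occ"] = occ_out(L), _["eps"] = eps_out(L), _["label"] = label_out(L),
    _["accepted"] = res != 0, _["evaluated"] = eval,
    _["type"] = type, _["i"] = si, _["j"] = sj, _["dH"] = dH);
}

// Run one full MCS on the given state; returns updated state, event labels
// before field relaxation, and the summed incremental dH of accepted moves.
// [[Rcpp::export]]
List cpp_run_mcs(LogicalMatrix mask, LogicalMatrix occ, NumericMatrix eps,
                 List par, bool relax = true) {
  Params p = read_params(par);
  Lattice L; build_from_matrices(L, mask, occ, eps, p.h);
  RNGScope scope;
  std::vector<std::pair<int,int> > off = disc_offsets(p.R, p.h);
  std::vector<int> pcnt(L.n, 0), rcnt(L.n, 0), touched;
  int B = L.boundary_count();
  double dH_sum = 0; int n_acc = 0, n_att = 0;
  for (int k = 0; k < B; ++k) {
    int site, type; double dH; bool eval;
    int res = attempt(L, p, site, type, dH, eval);
    if (eval) ++n_att;
    if (res != 0) { dH_sum += dH; ++n_acc; }
  }
  IntegerMatrix labels = label_out(L);
  if (relax) relax_field(L, p, off, pcnt, rcnt, touched);
  return List::create(
    _["occ"] = occ_out(L), _["eps"] = eps_out(L), _["label"] = labels,
    _["dH_sum"] = dH_sum, _["n_accepted"] = n_acc, _["n_evaluated"] = n_att,
    _["n_attempts"] = B);
}

// Full simulation loop.  Samples the centre-of-mass koor (um from lane
// centre) every `sampling` minutes after a burn-in window.
// [[Rcpp::export]]
List cpp_run_simulation(LogicalMatrix mask, LogicalMatrix occ0,
                        NumericMatrix eps0m, List par, double duration,
                        double sampling, double burn_in,
                        bool record_fields, bool record_shapes,
                        bool check_bounds) {
  Params p = read_params(par);
  Lattice L; build_from_matrices(L, mask, occ0, eps0m, p.h);
  RNGScope scope;
  std::vector<std::pair<int,int> > off = disc_offsets(p.R, p.h);
  std::vector<int> pcnt(L.n, 0), rcnt(L.n, 0), touched;

  double lane_centre = L.nx * p.h / 2.0;
  long n_samples = (long)std::floor(duration / sampling + 1e-9) + 1;
  NumericVector t_out(n_samples), koor(n_samples), area(n_samples),
      perim(n_samples), width_lead(n_samples), width_trail(n_samples);
  NumericVector field_stack;
  if (record_fields) {
    field_stack = NumericVector(Dimension(L.nx, L.ny, n_samples));
    std::fill(field_stack.begin(), field_stack.end(), NA_REAL);
  }
  List shapes(record_shapes ? n_samples : 0);

  long total_mcs = (long)std::ceil((burn_in + duration) / p.mcs_minutes);
  long acc = 0, att = 0;
  double lo = p.eps0 - p.deps / 2.0, hi = p.eps0 + p.deps / 2.0;
  double prev_koor = NA_REAL;
  long isample = 0;
  double next_t = 0.0;   // simulation time past burn-in for next sample

  // helper lambda: record one sample
  auto record = [&](double tnow) {
    double com = (L.sum_i / (double)L.A + 0.5) * p.h - lane_centre;
    t_out[isample] = tnow;
    koor[isample] = com;
    area[isample] = (double)L.A * p.h * p.h;
    perim[isample] = (double)L.P * p.h;
    // width of leading/trailing halves relative to motion since last sample
    double dir = 0;
    if (isample > 0 && !ISNA(prev_koor)) dir = com - prev_koor;
    double wl = NA_REAL, wt = NA_REAL;
    if (dir != 0) {
      double sgn = dir > 0 ? 1.0 : -1.0;
      double com_i = L.sum_i / (double)L.A;
      long nl = 0, nt = 0; int li_min = L.nx, li_max = -1, ti_min = L.nx, ti_max = -1;
      for (size_t k = 0; k < L.occ_list.size(); ++k) {
        int i = L.ix(L.occ_list[k]);
        if (sgn * (i - com_i) > 0) {
          ++nl; if (i < li_min) li_min = i; if (i > li_max) li_max = i;
        } else {
          ++nt; if (i < ti_min) ti_min = i; if (i > ti_max) ti_max = i;
        }
      }
      if (nl > 0 && li_max >= li_min) wl = (double)nl / (li_max - li_min + 1) * p.h;
      if (nt > 0 && ti_max >= ti_min) wt = (double)nt / (ti_max - ti_min + 1) * p.h;
    }
    width_lead[isample] = wl; width_trail[isample] = wt;
    if (record_fields) {
      for (int j = 0; j < L.ny; ++j)
        for (int i = 0; i < L.nx; ++i)
          field_stack[i + L.nx * j + L.nx * L.ny * isample] =
            L.occ[i + L.nx * j] ? L.eps[i + L.nx * j] : NA_REAL;
    }
    if (record_shapes) shapes[isample] = occ_out(L);
    prev_koor = com;
    ++isample;
  };

  double t = -burn_in;
  bool recorded0 = false;
  if (burn_in <= 1e-9) { record(0.0); recorded0 = true; next_t = sampling; }
  for (long step = 0; step < total_mcs && isample < n_samples; ++step) {
    int B = L.boundary_count();
    for (int k = 0; k < B; ++k) {
      int site, type; double dH; bool eval;
      int res = attempt(L, p, site, type, dH, eval);
      if (eval) ++att;
      if (res != 0) ++acc;
    }
    relax_field(L, p, off, pcnt, rcnt, touched);
    L.clear_labels();
    if (check_bounds) {
      for (size_t k = 0; k < L.occ_list.size(); ++k) {
        double e = L.eps[L.occ_list[k]];
        if (e < lo - 1e-9 || e > hi + 1e-9)
          stop("polarization field left its bounds");
      }
    }
    if (L.A == 0) stop("cell extinction: pathological parameters");
    t += p.mcs_minutes;
    if (!recorded0 && t >= -1e-9) { record(0.0); recorded0 = true; next_t = sampling; }
    else if (recorded0) {
      while (isample < n_samples && t >= next_t - 1e-9) {
        record(next_t);
        next_t += sampling;
      }
    }
    if (step % 256 == 0) Rcpp::checkUserInterrupt();
  }
  // pad any unrecorded trailing samples (shouldn't happen)
  while (isample < n_samples) { record(next_t); next_t += sampling; }

  List out = List::create(
    _["time"] = t_out, _["koor"] = koor, _["area"] = area, _["perimeter"] = perim,
    _["width_lead"] = width_lead, _["width_trail"] = width_trail,
    _["occ"] = occ_out(L), _["eps"] = eps_out(L),
    _["acceptance_rate"] = att > 0 ? (double)acc / att : NA_REAL);
  if (record_fields) out["field_series"] = field_stack;
  if (record_shapes) out["shape_series"] = shapes;
  return out;
}
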