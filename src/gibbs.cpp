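// Gibbs sampler and sufficient statistics for the multilevel ALAAM.
//
// The model state is a pair of binary vectors: y over households (level A)
// and Y over regions (level B).  Effects are encoded as (code, col) pairs;
// static effects read a pre-computed node covariate column (degree, triangle
// count, same/cross-region degree, any household or region covariate),
// dynamic effects depend on the outcome of adjacent nodes.  The sampler
// maintains the statistic vector incrementally via change statistics.

#include <Rcpp.h>
using namespace Rcpp;

enum EffectCode {
  H_STATIC = 1,     // sum_h y_h * hstat(h, col)
  H_CONT_SAME = 2,  // sum over same-region ties of y_h y_h'
  H_CONT_CROSS = 3, // sum over cross-region ties of y_h y_h'
  H_CONT_POOR = 4,  // sum over ties of y_h y_h' 1{both in poorest quintile}
  R_STATIC = 5,     // sum_v Y_v * rstat(v, col)
  RR_CONT = 6,      // sum over region meta-ties of Y_v Y_v'
  CROSS_LEVEL = 7,  // sum_v Y_v * (number of y=1 households in v)
  MICRO_MACRO = 8   // sum_v Y_v * (within-v ties with both endpoints y=1)
};

struct Model {
  IntegerVector nb_idx, nb_ptr;   // household adjacency, CSR, 0-based
  LogicalVector nb_same;          // aligned with nb_idx: neighbour in same region
  IntegerVector region;           // household -> region, 0-based
  IntegerVector rnb_idx, rnb_ptr; // region meta adjacency, CSR
  IntegerVector rh_idx, rh_ptr;   // households per region, CSR
  NumericMatrix hstat, rstat;     // static effect columns
  IntegerVector code, col;        // effect table (col 0-based)
  IntegerVector poorest;          // 0/1 per household
  int N, R, P;
};

static Model unpack(const List& m) {
  Model md;
  md.nb_idx = m["nb_idx"]; md.nb_ptr = m["nb_ptr"]; md.nb_same = m["nb_same"];
  md.region = m["region"];
  md.rnb_idx = m["rnb_idx"]; md.rnb_ptr = m["rnb_ptr"];
  md.rh_idx = m["rh_idx"]; md.rh_ptr = m["rh_ptr"];
  md.hstat = as<NumericMatrix>(m["hstat"]);
  md.rstat = as<NumericMatrix>(m["rstat"]);
  md.code = m["code"]; md.col = m["col"];
  md.poorest = m["poorest"];
  md.N = md.nb_ptr.size() - 1;
  md.R = md.rh_ptr.size() - 1;
  md.P = md.code.size();
  return md;
}

// within-region concordant tie count incident to household h (y = current state)
static inline int same_y1(const Model& md, const IntegerVector& y, int h) {
  int c = 0;
  for (int k = md.nb_ptr[h]; k < md.nb_ptr[h + 1]; ++k)
    if (md.nb_same[k] && y[md.nb_idx[k]]) ++c;
  return c;
}

// change statistics for flipping household h from 0 to 1
static void dz_house(const Model& md, const IntegerVector& y,
                     const IntegerVector& Y, int h, NumericVector& dz) {
  int c_same = 0, c_cross = 0, c_poor = 0;
  for (int k = md.nb_ptr[h]; k < md.nb_ptr[h + 1]; ++k) {
    int j = md.nb_idx[k];
    if (y[j]) {
      if (md.nb_same[k]) ++c_same; else ++c_cross;
      if (md.poorest[h] && md.poorest[j]) ++c_poor;
    }
  }
  int v = md.region[h];
  for (int p = 0; p < md.P; ++p) {
    switch (md.code[p]) {
    case H_STATIC:    dz[p] = md.hstat(h, md.col[p]); break;
    case H_CONT_SAME: dz[p] = c_same; break;
    case H_CONT_CROSS:dz[p] = c_cross; break;
    case H_CONT_POOR: dz[p] = c_poor; break;
    case CROSS_LEVEL: dz[p] = Y[v]; break;
    case MICRO_MACRO: dz[p] = Y[v] ? c_same : 0.0; break;
    default:          dz[p] = 0.0;
    }
  }
}

// change statistics for flipping region v from 0 to 1
static void dz_region(const Model& md, const IntegerVector& y,
                      const IntegerVector& Y, int v, NumericVector& dz) {
  bool need_rr = false, need_cl = false, need_mm = false;
  for (int p = 0; p < md.P; ++p) {
    if (md.code[p] == RR_CONT) need_rr = true;
    else if (md.code[p] == CROSS_LEVEL) need_cl = true;
    else if (md.code[p] == MICRO_MACRO) need_mm = true;
  }
  int rr = 0, ysum = 0; double conc = 0.0;
  if (need_rr)
    for (int k = md.rnb_ptr[v]; k < md.rnb_ptr[v + 1]; ++k)
      if (Y[md.rnb_idx[k]]) ++rr;
  if (need_cl || need_mm) {
    for (int k = md.rh_ptr[v]; k < md.rh_ptr[v + 1]; ++k) {
      int h = md.rh_idx[k];
      if (y[h]) {
        ++ysum;
        if (need_mm) conc += same_y1(md, y, h);
      }
    }
    conc *= 0.5; // each within-region concordant tie counted from both ends
  }
  for (int p = 0; p < md.P; ++p) {
    switch (md.code[p]) {
    case R_STATIC:    dz[p] = md.rstat(v, md.col[p]); break;
    case RR_CONT:     dz[p] = rr; break;
    case CROSS_LEVEL: dz[p] = ysum; break;
    case MICRO_MACRO: dz[p] = conc; break;
    default:          dz[p] = 0.0;
    }
  }
}

static NumericVector full_stats(const Model& md, const IntegerVector& y,
                                const IntegerVector& Y) {
  NumericVector z(md.P);
  for (int p = 0; p < md.P; ++p) {
    double s = 0.0;
    switch (md.code[p]) {
    case H_STATIC:
      for (int h = 0; h < md.N; ++h) if (y[h]) s += md.hstat(h, md.col[p]);
      break;
    case H_CONT_SAME: case H_CONT_CROSS: case H_CONT_POOR:
      for (int h = 0; h < md.N; ++h) {
        if (!y[h]) continue;
        for (int k = md.nb_ptr[h]; k < md.nb_ptr[h + 1]; ++k) {
          int j = md.nb_idx[k];
          if (j <= h || !y[j]) continue;
          if (md.code[p] == H_CONT_SAME && md.nb_same[k]) s += 1.0;
          else if (md.code[p] == H_CONT_CROSS && !md.nb_same[k]) s += 1.0;
          else if (md.code[p] == H_CONT_POOR && md.poorest[h] && md.poorest[j]) s += 1.0;
        }
      }
      break;
    case R_STATIC:
      for (int v = 0; v < md.R; ++v) if (Y[v]) s += md.rstat(v, md.col[p]);
      break;
    case RR_CONT:
      for (int v = 0; v < md.R; ++v) {
        if (!Y[v]) continue;
        for (int k = md.rnb_ptr[v]; k < md.rnb_ptr[v + 1]; ++k)
          if (md.rnb_idx[k] > v && Y[md.rnb_idx[k]]) s += 1.0;
      }
      break;
    case CROSS_LEVEL:
      for (int v = 0; v < md.R; ++v) {
        if (!Y[v]) continue;
        for (int k = md.rh_ptr[v]; k < md.rh_ptr[v + 1]; ++k)
          if (y[md.rh_idx[k]]) s += 1.0;
      }
      break;
    case MICRO_MACRO:
      for (int v = 0; v < md.R; ++v) {
        if (!Y[v]) continue;
        double c = 0.0;
        for (int k = md.rh_ptr[v]; k < md.rh_ptr[v + 1]; ++k) {
          int h = md.rh_idx[k];
          if (y[h]) c += same_y1(md, y, h);
        }
        s += 0.5 * c;
      }
      break;
    }
    z[p] = s;
  }
  return z;
}

// [[Rcpp::export]]
NumericVector alaam_stats_cpp(List model, IntegerVector y, IntegerVector Y) {
  Model md = unpack(model);
  return full_stats(md, y, Y);
}

// [[Rcpp::export]]
NumericVector alaam_changestat_cpp(List model, IntegerVector y, IntegerVector Y,
                                   int node, bool household) {
  Model md = unpack(model);
  NumericVector dz(md.P);
  if (household) dz_house(md, y, Y, node, dz); else dz_region(md, y, Y, node, dz);
  return dz;
}

// Gibbs sampler.  update_h / update_r are 0-based indices of free nodes
// (clamped nodes are simply omitted).  Draws are recorded every `thin`
// sweeps after `n_burn` sweeps; uses R's RNG so set.seed() governs it.
// [[Rcpp::export]]
List alaam_gibbs_cpp(List model, NumericVector theta,
                     IntegerVector y0, IntegerVector Y0,
                     IntegerVector update_h, IntegerVector update_r,
                     int n_burn, int n_keep, int thin, bool return_states) {
  Model md = unpack(model);
  IntegerVector y = clone(y0), Y = clone(Y0);
  int nh = update_h.size(), nr = update_r.size(), M = nh + nr;
  NumericVector dz(md.P);
  NumericVector z = full_stats(md, y, Y);
  NumericMatrix stats(n_keep, md.P);
  IntegerMatrix ys, Ys;
  if (return_states) { ys = IntegerMatrix(n_keep, md.N); Ys = IntegerMatrix(n_keep, md.R); }

  std::vector<int> order(M);
  for (int i = 0; i < M; ++i) order[i] = i;

  int total_sweeps = n_burn + (n_keep > 0 ? n_keep * thin : 0);
  int kept = 0;
  for (int s = 0; s < total_sweeps; ++s) {
    // Fisher-Yates shuffle of the combined household+region update order
    for (int i = M - 1; i > 0; --i) {
      int j = (int)std::floor(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(order[i], order[j]);
    }
    for (int i = 0; i < M; ++i) {
      int o = order[i];
      bool is_h = o < nh;
      int node = is_h ? update_h[o] : update_r[o - nh];
      if (is_h) dz_house(md, y, Y, node, dz); else dz_region(md, y, Y, node, dz);
      double eta = 0.0;
      for (int p = 0; p < md.P; ++p) eta += theta[p] * dz[p];
      int cur = is_h ? y[node] : Y[node];
      int nv = (unif_rand() < 1.0 / (1.0 + std::exp(-eta))) ? 1 : 0;
      if (nv != cur) {
        double d = nv - cur;
        for (int p = 0; p < md.P; ++p) z[p] += d * dz[p];
        if (is_h) y[node] = nv; else Y[node] = nv;
      }
    }
    if (s >= n_burn && n_keep > 0 && (s - n_burn + 1) % thin == 0 && kept < n_keep) {
      for (int p = 0; p < md.P; ++p) stats(kept, p) = z[p];
      if (return_states) {
        for (int h = 0; h < md.N; ++h) ys(kept, h) = y[h];
        for (int v = 0; v < md.R; ++v) Ys(kept, v) = Y[v];
      }
      ++kept;
    }
  }
  List out = List::create(_["stats"] = stats, _["y"] = y, _["Y"] = Y);
  if (return_states) { out["y_draws"] = ys; out["Y_draws"] = Ys; }
  return out;
}
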