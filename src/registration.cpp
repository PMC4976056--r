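// Registration core: KD-tree nearest-neighbour search, closed-form rigid
// estimators, and the two ICP inner loops (point-to-point, point-to-plane).
// Kept in C++ because the all-vs-all comparison matrix runs thousands of
// ICP iterations per mesh pair.

#include <RcppArmadillo.h>
#include <algorithm>
#include <cmath>
#include <vector>

// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

// Simple 3-D KD-tree over mesh vertices.  Median split on the widest axis,
// (1+eps)-approximate pruning; eps = 0 gives the exact nearest vertex.
class KDTree {
public:
  explicit KDTree(const arma::mat& pts, int leaf = 12)
      : data_(pts), n_(static_cast<int>(pts.n_rows)), leaf_(leaf) {
    idx_.resize(n_);
    for (int i = 0; i < n_; ++i) idx_[i] = i;
    if (n_ > 0) build(0, n_);
  }

  // Returns 0-based index of an (approximately) nearest point, sets dist.
  int nearest(const double* q, double eps, double& dist) const {
    int best = -1;
    double best_d2 = std::numeric_limits<double>::infinity();
    const double inv = 1.0 / ((1.0 + eps) * (1.0 + eps));
    search(0, q, inv, best, best_d2);
    dist = std::sqrt(best_d2);
    return best;
  }

private:
  arma::mat data_;
  int n_, leaf_;
  std::vector<int> idx_;
  std::vector<int> left_, right_, start_, end_, axis_;
  std::vector<double> split_;

  double coord(int i, int d) const { return data_(i, d); }

  int build(int s, int e) {
    const int node = static_cast<int>(left_.size());
    left_.push_back(-1);
    right_.push_back(-1);
    start_.push_back(s);
    end_.push_back(e);
    axis_.push_back(-1);
    split_.push_back(0.0);
    if (e - s <= leaf_) return node;

    double lo[3], hi[3];
    for (int d = 0; d < 3; ++d) {
      lo[d] = std::numeric_limits<double>::infinity();
      hi[d] = -lo[d];
    }
    for (int i = s; i < e; ++i)
      for (int d = 0; d < 3; ++d) {
        const double v = coord(idx_[i], d);
        if (v < lo[d]) lo[d] = v;
        if (v > hi[d]) hi[d] = v;
      }
    int ax = 0;
    double w = hi[0] - lo[0];
    for (int d = 1; d < 3; ++d)
      if (hi[d] - lo[d] > w) {
        w = hi[d] - lo[d];
        ax = d;
      }
    if (w <= 0.0) return node;  // all points coincide: stay a leaf

    const int mid = (s + e) / 2;
    std::nth_element(idx_.begin() + s, idx_.begin() + mid, idx_.begin() + e,
                     [&](int a, int b) { return coord(a, ax) < coord(b, ax); });
    axis_[node] = ax;
    split_[node] = coord(idx_[mid], ax);
    const int l = build(s, mid);
    left_[node] = l;
    const int r = build(mid, e);
    right_[node] = r;
    return node;
  }

  void search(int node, const double* q, double inv, int& best,
              double& best_d2) const {
    if (left_[node] < 0) {
      for (int i = start_[node]; i < end_[node]; ++i) {
        const int j = idx_[i];
        double d2 = 0.0;
        for (int d = 0; d < 3; ++d) {
          const double t = q[d] - coord(j, d);
          d2 += t * t;
        }
        if (d2 < best_d2) {
          best_d2 = d2;
          best = j;
        }
      }
      return;
    }
    const int ax = axis_[node];
    const double diff = q[ax] - split_[node];
    const int near = diff < 0.0 ? left_[node] : right_[node];
    const int far = diff < 0.0 ? right_[node] : left_[node];
    search(near, q, inv, best, best_d2);
    // visit the far side only if the splitting plane could hold a point
    // closer than best/(1+eps)
    if (diff * diff < best_d2 * inv) search(far, q, inv, best, best_d2);
  }
};

arma::mat skew(const arma::vec& w) {
  arma::mat K(3, 3, arma::fill::zeros);
  K(0, 1) = -w(2); K(0, 2) =  w(1);
  K(1, 0) =  w(2); K(1, 2) = -w(0);
  K(2, 0) = -w(1); K(2, 1) =  w(0);
  return K;
}

// Rodrigues exponential map so(3) -> SO(3)
arma::mat expmap(const arma::vec& w) {
  const double th = arma::norm(w);
  const arma::mat I = arma::eye(3, 3);
  if (th < 1e-12) return I + skew(w);
  const arma::mat K = skew(w / th);
  return I + std::sin(th) * K + (1.0 - std::cos(th)) * (K * K);
}

// Project a near-rotation onto SO(3) (polar decomposition via SVD).
arma::mat orthonormalize(const arma::mat& R) {
  arma::mat U, V;
  arma::vec s;
  arma::svd(U, s, V, R);
  arma::mat D = arma::eye(3, 3);
  if (arma::det(U * V.t()) < 0.0) D(2, 2) = -1.0;
  return U * D * V.t();
}

// Least-squares rigid transform S -> T (Kabsch/Umeyama, reflection-guarded).
void rigid_from_corr(const arma::mat& S, const arma::mat& T,
                     const arma::vec* w, arma::mat& R, arma::vec& t) {
  arma::rowvec cs, ct;
  arma::mat H;
  if (w) {
    const double sw = arma::accu(*w);
    cs = (w->t() * S) / sw;
    ct = (w->t() * T) / sw;
    arma::mat Sc = S.each_row() - cs;
    arma::mat Tc = T.each_row() - ct;
    Sc.each_col() %= arma::sqrt(*w);
    Tc.each_col() %= arma::sqrt(*w);
    H = Sc.t() * Tc;
  } else {
    cs = arma::mean(S, 0);
    ct = arma::mean(T, 0);
    H = (S.each_row() - cs).t() * (T.each_row() - ct);
  }
  arma::mat U, V;
  arma::vec s;
  arma::svd(U, s, V, H);
  arma::mat D = arma::eye(3, 3);
  if (arma::det(V * U.t()) < 0.0) D(2, 2) = -1.0;
  R = V * D * U.t();
  t = ct.t() - R * cs.t();
}

}  // namespace

// Nearest-neighbour query of `query` points against `target` points.
// eps > 0 gives (1+eps)-approximate answers.  When cos_min > -1 and both
// normal sets are supplied, a correspondence is flagged rejected when the
// normal angle exceeds the compatibility threshold.
// [[Rcpp::export]]
List cpp_nn(const arma::mat& target, const arma::mat& query, double eps,
            Nullable<NumericMatrix> target_normals = R_NilValue,
            Nullable<NumericMatrix> query_normals = R_NilValue,
            double cos_min = -2.0) {
  const int m = static_cast<int>(query.n_rows);
  IntegerVector idx(m);
  NumericVector dist(m);
  LogicalVector accepted(m, true);
  if (target.n_rows == 0 || m == 0)
    return List::create(_["index"] = IntegerVector(0),
                        _["distance"] = NumericVector(0),
                        _["accepted"] = LogicalVector(0));
  KDTree tree(target);
  arma::mat tn, qn;
  const bool check = cos_min > -1.5 && target_normals.isNotNull() &&
                     query_normals.isNotNull();
  if (check) {
    tn = as<arma::mat>(target_normals.get());
    qn = as<arma::mat>(query_normals.get());
  }
  for (int i = 0; i < m; ++i) {
    const double q[3] = {query(i, 0), query(i, 1), query(i, 2)};
    double d;
    const int j = tree.nearest(q, eps, d);
    idx[i] = j + 1;
    dist[i] = d;
    if (check) {
      const double dot = tn(j, 0) * qn(i, 0) + tn(j, 1) * qn(i, 1) +
                         tn(j, 2) * qn(i, 2);
      const double nq = qn(i, 0) * qn(i, 0) + qn(i, 1) * qn(i, 1) +
                        qn(i, 2) * qn(i, 2);
      // vertices without a usable normal are not subjected to the test
      if (nq > 0.25) accepted[i] = dot >= cos_min;
    }
  }
  return List::create(_["index"] = idx, _["distance"] = dist,
                      _["accepted"] = accepted);
}

// [[Rcpp::export]]
List cpp_estimate_p2p(const arma::mat& src, const arma::mat& tgt,
                      Nullable<NumericVector> weights = R_NilValue) {
  arma::mat R;
  arma::vec t;
  if (weights.isNotNull()) {
    arma::vec w = as<arma::vec>(weights.get());
    rigid_from_corr(src, tgt, &w, R, t);
  } else {
    rigid_from_corr(src, tgt, nullptr, R, t);
  }
  return List::create(_["R"] = R, _["t"] = t);
}

// One linearised point-to-plane solve.  Returns the rigid update together
// with the singular values and right singular vectors of the 6-column
// Jacobian so the caller can diagnose unconstrained motions.
// [[Rcpp::export]]
List cpp_estimate_p2pl(const arma::mat& src, const arma::mat& tgt,
                       const arma::mat& nrm, double sv_rel_tol = 1e-9) {
  const int m = static_cast<int>(src.n_rows);
  arma::mat A(m, 6);
  arma::vec b(m);
  for (int i = 0; i < m; ++i) {
    const arma::vec p = src.row(i).t();
    const arma::vec q = tgt.row(i).t();
    const arma::vec n = nrm.row(i).t();
    const arma::vec c = arma::cross(p, n);
    A(i, 0) = c(0); A(i, 1) = c(1); A(i, 2) = c(2);
    A(i, 3) = n(0); A(i, 4) = n(1); A(i, 5) = n(2);
    b(i) = -arma::dot(p - q, n);
  }
  arma::mat U, V;
  arma::vec s;
  arma::svd_econ(U, s, V, A);
  const double smax = s.max();
  arma::vec x(6, arma::fill::zeros);
  for (arma::uword k = 0; k < s.n_elem; ++k) {
    if (smax > 0.0 && s(k) > sv_rel_tol * smax)
      x += (arma::dot(U.col(k), b) / s(k)) * V.col(k);
  }
  const arma::mat R = orthonormalize(expmap(x.subvec(0, 2)));
  return List::create(_["R"] = R, _["t"] = x.subvec(3, 5),
                      _["omega"] = x.subvec(0, 2),
                      _["singular_values"] = s, _["V"] = V);
}

// Point-to-point ICP.  Re-estimates the absolute transform from the original
// source coordinates each iteration.  trace[k] is the RMS of the NN distances
// evaluated under the transform entering iteration k; with eps = 0 it is
// nonincreasing.
// [[Rcpp::export]]
List cpp_icp_p2p(const arma::mat& src, const arma::mat& tgt,
                 const arma::mat& R0, const arma::vec& t0, int max_iter,
                 double tol, double eps) {
  KDTree tree(tgt);
  const int n = static_cast<int>(src.n_rows);
  arma::mat R = R0;
  arma::vec t = t0;
  arma::mat matched(n, 3);
  std::vector<double> trace;
  trace.reserve(max_iter + 1);
  bool converged = false;
  int updates = 0;
  double prev = std::numeric_limits<double>::infinity();
  for (int it = 0; it <= max_iter; ++it) {
    arma::mat cur = src * R.t();
    cur.each_row() += t.t();
    double ss = 0.0;
    for (int i = 0; i < n; ++i) {
      const double q[3] = {cur(i, 0), cur(i, 1), cur(i, 2)};
      double d;
      const int j = tree.nearest(q, eps, d);
      matched.row(i) = tgt.row(j);
      ss += d * d;
    }
    const double rms = std::sqrt(ss / n);
    trace.push_back(rms);
    if (std::fabs(prev - rms) < tol) {
      converged = true;
      break;
    }
    prev = rms;
    if (it == max_iter) break;
    rigid_from_corr(src, matched, nullptr, R, t);
    ++updates;
  }
  return List::create(_["R"] = R, _["t"] = t, _["trace"] = wrap(trace),
                      _["iterations"] = updates, _["converged"] = converged,
                      _["rms"] = trace.back());
}

// Point-to-plane ICP with exact NN, normal-compatibility rejection and
// optional overlap trimming (keep the best `overlap` fraction of accepted
// residuals each iteration).  Starts from (R0, t0) and returns the composed
// absolute transform.
// [[Rcpp::export]]
List cpp_icp_p2pl(const arma::mat& src, const arma::mat& src_n,
                  const arma::mat& tgt, const arma::mat& tgt_n,
                  const arma::mat& R0, const arma::vec& t0, int max_iter,
                  double tol, double cos_min, double overlap,
                  double sv_rel_tol = 1e-9) {
  KDTree tree(tgt);
  const int n = static_cast<int>(src.n_rows);
  arma::mat R = R0;
  arma::vec t = t0;
  std::vector<double> trace;
  trace.reserve(max_iter + 1);
  bool converged = false, failed = false;
  int updates = 0, n_accepted = 0;
  double prev = std::numeric_limits<double>::infinity();

  std::vector<int> ai, aj;
  std::vector<double> ad;
  ai.reserve(n); aj.reserve(n); ad.reserve(n);

  for (int it = 0; it <= max_iter; ++it) {
    arma::mat cur = src * R.t();
    cur.each_row() += t.t();
    arma::mat curn = src_n * R.t();
    ai.clear(); aj.clear(); ad.clear();
    for (int i = 0; i < n; ++i) {
      const double q[3] = {cur(i, 0), cur(i, 1), cur(i, 2)};
      double d;
      const int j = tree.nearest(q, 0.0, d);
      const double nq = curn(i, 0) * curn(i, 0) + curn(i, 1) * curn(i, 1) +
                        curn(i, 2) * curn(i, 2);
      bool ok = true;
      if (nq > 0.25) {
        const double dot = curn(i, 0) * tgt_n(j, 0) +
                           curn(i, 1) * tgt_n(j, 1) +
                           curn(i, 2) * tgt_n(j, 2);
        ok = dot >= cos_min;
      }
      if (ok) {
        ai.push_back(i);
        aj.push_back(j);
        ad.push_back(d);
      }
    }
    int m = static_cast<int>(ai.size());
    if (m < 6) {
      failed = true;
      break;
    }
    // overlap trimming: keep the best fraction of residuals
    std::vector<int> ord(m);
    for (int k = 0; k < m; ++k) ord[k] = k;
    if (overlap < 1.0) {
      int keep = std::max(6, static_cast<int>(std::floor(overlap * m)));
      if (keep < m) {
        std::nth_element(ord.begin(), ord.begin() + keep, ord.end(),
                         [&](int a, int b) { return ad[a] < ad[b]; });
        ord.resize(keep);
        m = keep;
      }
    }
    double ss = 0.0;
    for (int k = 0; k < m; ++k) ss += ad[ord[k]] * ad[ord[k]];
    const double rms = std::sqrt(ss / m);
    trace.push_back(rms);
    n_accepted = m;
    if (std::fabs(prev - rms) < tol) {
      converged = true;
      break;
    }
    prev = rms;
    if (it == max_iter) break;

    arma::mat A(m, 6);
    arma::vec b(m);
    for (int k = 0; k < m; ++k) {
      const int i = ai[ord[k]], j = aj[ord[k]];
      const arma::vec p = cur.row(i).t();
      const arma::vec qv = tgt.row(j).t();
      const arma::vec nv = tgt_n.row(j).t();
      const arma::vec c = arma::cross(p, nv);
      A(k, 0) = c(0); A(k, 1) = c(1); A(k, 2) = c(2);
      A(k, 3) = nv(0); A(k, 4) = nv(1); A(k, 5) = nv(2);
      b(k) = -arma::dot(p - qv, nv);
    }
    arma::mat U, V;
    arma::vec s;
    arma::svd_econ(U, s, V, A);
    const double smax = s.max();
    arma::vec x(6, arma::fill::zeros);
    for (arma::uword k = 0; k < s.n_elem; ++k) {
      if (smax > 0.0 && s(k) > sv_rel_tol * smax)
        x += (arma::dot(U.col(k), b) / s(k)) * V.col(k);
    }
    const arma::mat Rd = orthonormalize(expmap(x.subvec(0, 2)));
    R = orthonormalize(Rd * R);
    t = Rd * t + x.subvec(3, 5);
    ++updates;
  }
  if (trace.empty()) trace.push_back(NA_REAL);
  return List::create(_["R"] = R, _["t"] = t, _["trace"] = wrap(trace),
                      _["iterations"] = updates, _["converged"] = converged,
                      _["failed"] = failed, _["n_accepted"] = n_accepted,
                      _["rms"] = trace.back());
}

// Symmetric RMS of exact nearest-neighbour distances: squared NN distances
// are pooled over both directions (a -> b and b -> a) before the mean.
// [[Rcpp::export]]
double cpp_symmetric_rms(const arma::mat& a, const arma::mat& b) {
  KDTree ta(a), tb(b);
  const int na = static_cast<int>(a.n_rows), nb = static_cast<int>(b.n_rows);
  double ss = 0.0;
  for (int i = 0; i < na; ++i) {
    const double q[3] = {a(i, 0), a(i, 1), a(i, 2)};
    double d;
    tb.nearest(q, 0.0, d);
    ss += d * d;
  }
  for (int i = 0; i < nb; ++i) {
    const double q[3] = {b(i, 0), b(i, 1), b(i, 2)};
    double d;
    ta.nearest(q, 0.0, d);
    ss += d * d;
  }
  return std::sqrt(ss / (na + nb));
}

// Directed NN distance summaries used by the alternative value metrics.
// [[Rcpp::export]]
NumericVector cpp_nn_dists(const arma::mat& target, const arma::mat& query) {
  KDTree tree(target);
  const int m = static_cast<int>(query.n_rows);
  NumericVector out(m);
  for (int i = 0; i < m; ++i) {
    const double q[3] = {query(i, 0), query(i, 1), query(i, 2)};
    double d;
    tree.nearest(q, 0.0, d);
    out[i] = d;
  }
  return out;
}

namespace {

// Squared distance from point p to triangle (a, b, c): barycentric
// projection onto the plane, clamped to the nearest edge when outside.
double point_tri_d2(const double* p, const arma::rowvec& a,
                    const arma::rowvec& b, const arma::rowvec& c) {
  const arma::rowvec pv(std::vector<double>{p[0], p[1], p[2]});
  const arma::rowvec ab = b - a, ac = c - a, ap = pv - a;
  const double d1 = arma::dot(ab, ap), d2 = arma::dot(ac, ap);
  if (d1 <= 0.0 && d2 <= 0.0) return arma::dot(ap, ap);
  const arma::rowvec bp = pv - b;
  const double d3 = arma::dot(ab, bp), d4 = arma::dot(ac, bp);
  if (d3 >= 0.0 && d4 <= d3) return arma::dot(bp, bp);
  const double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    const double v = d1 / (d1 - d3);
    const arma::rowvec d = ap - v * ab;
    return arma::dot(d, d);
  }
  const arma::rowvec cp = pv - c;
  const double d5 = arma::dot(ab, cp), d6 = arma::dot(ac, cp);
  if (d6 >= 0.0 && d5 <= d6) return arma::dot(cp, cp);
  const double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    const double w = d2 / (d2 - d6);
    const arma::rowvec d = ap - w * ac;
    return arma::dot(d, d);
  }
  const double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    const double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    const arma::rowvec d = bp - w * (c - b);
    return arma::dot(d, d);
  }
  const double denom = 1.0 / (va + vb + vc);
  const double v = vb * denom, w = vc * denom;
  const arma::rowvec d = ap - v * ab - w * ac;
  return arma::dot(d, d);
}

// All points of `tree`'s data within radius r of q (0-based indices).
void gather_radius(const arma::mat& pts, const double* q, double r,
                   std::vector<int>& out) {
  const double r2 = r * r;
  const int n = static_cast<int>(pts.n_rows);
  for (int i = 0; i < n; ++i) {
    double d2 = 0.0;
    for (int d = 0; d < 3; ++d) {
      const double t = q[d] - pts(i, d);
      d2 += t * t;
    }
    if (d2 <= r2) out.push_back(i);
  }
}

}  // namespace

// Exact point-to-surface distances: for each query point, the distance to
// the nearest point on any triangle of the mesh (vertices V, 1-based faces
// F).  The nearest-vertex distance is an upper bound; only triangles whose
// centroid lies within bound + max circumradius can beat it.
// [[Rcpp::export]]
NumericVector cpp_surface_dists(const arma::mat& V, const arma::imat& F,
                                const arma::mat& query) {
  const int nf = static_cast<int>(F.n_rows);
  const int m = static_cast<int>(query.n_rows);
  arma::mat cent(nf, 3);
  double rmax = 0.0;
  arma::vec rad(nf);
  for (int f = 0; f < nf; ++f) {
    const arma::rowvec a = V.row(F(f, 0) - 1);
    const arma::rowvec b = V.row(F(f, 1) - 1);
    const arma::rowvec c = V.row(F(f, 2) - 1);
    cent.row(f) = (a + b + c) / 3.0;
    const double r = std::sqrt(std::max({
        arma::dot(a - cent.row(f), a - cent.row(f)),
        arma::dot(b - cent.row(f), b - cent.row(f)),
        arma::dot(c - cent.row(f), c - cent.row(f))}));
    rad(f) = r;
    if (r > rmax) rmax = r;
  }
  KDTree vtree(V), ctree(cent);
  NumericVector out(m);
  std::vector<int> cand;
  for (int i = 0; i < m; ++i) {
    const double q[3] = {query(i, 0), query(i, 1), query(i, 2)};
    double dv;
    vtree.nearest(q, 0.0, dv);  // upper bound on the surface distance
    double best2 = dv * dv;
    cand.clear();
    gather_radius(cent, q, dv + rmax, cand);
    for (int k : cand) {
      const int f = k;
      // centroid-based lower bound for this triangle
      double cd2 = 0.0;
      for (int d = 0; d < 3; ++d) {
        const double t = q[d] - cent(f, d);
        cd2 += t * t;
      }
      const double lb = std::sqrt(cd2) - rad(f);
      if (lb > 0.0 && lb * lb >= best2) continue;
      const double d2 = point_tri_d2(q, V.row(F(f, 0) - 1),
                                     V.row(F(f, 1) - 1), V.row(F(f, 2) - 1));
      if (d2 < best2) best2 = d2;
    }
    out[i] = std::sqrt(best2);
  }
  return out;
}
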