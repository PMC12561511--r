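// Computational kernels for spinereg: brute-force neighborhood search,
// farthest point sampling, surface-variation curvature, Kabsch/RANSAC
// rigid pose estimation, point-to-point ICP and voxel downsampling.
// Clouds here are small (10^3-10^4 points), so O(n*m) search beats
// building spatial indices.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Uniform-grid spatial index: cells of edge h in an unordered map.
// Clouds here are surface samplings, so occupied cells are sparse.
struct Grid {
  double h;
  arma::rowvec mn;
  std::unordered_map<long long, std::vector<int>> cells;

  Grid(const arma::mat& pts, double cell) : h(cell) {
    mn = arma::min(pts, 0);
    for (arma::uword i = 0; i < pts.n_rows; ++i) {
      cells[key_of(pts(i,0), pts(i,1), pts(i,2))].push_back(i);
    }
  }
  long long key_of(double x, double y, double z) const {
    long long ix = (long long)std::floor((x - mn(0)) / h);
    long long iy = (long long)std::floor((y - mn(1)) / h);
    long long iz = (long long)std::floor((z - mn(2)) / h);
    return ((ix + 1048576LL) << 42) | ((iy + 1048576LL) << 21) |
           (iz + 1048576LL);
  }
  // indices of all points within Chebyshev ring `s` of the query cell
  void ring(double x, double y, double z, int s,
            std::vector<int>& out) const {
    long long ix = (long long)std::floor((x - mn(0)) / h);
    long long iy = (long long)std::floor((y - mn(1)) / h);
    long long iz = (long long)std::floor((z - mn(2)) / h);
    for (long long dx = -s; dx <= s; ++dx) {
      for (long long dy = -s; dy <= s; ++dy) {
        for (long long dz = -s; dz <= s; ++dz) {
          if (std::max({std::llabs(dx), std::llabs(dy), std::llabs(dz)}) != s)
            continue;
          long long key = ((ix + dx + 1048576LL) << 42) |
                          ((iy + dy + 1048576LL) << 21) |
                          (iz + dz + 1048576LL);
          auto it = cells.find(key);
          if (it != cells.end()) {
            out.insert(out.end(), it->second.begin(), it->second.end());
          }
        }
      }
    }
  }
};

static double cloud_cell_size(const arma::mat& pts) {
  arma::rowvec ext = arma::max(pts, 0) - arma::min(pts, 0);
  double diag = arma::norm(ext, 2);
  if (diag <= 0) diag = 1.0;
  // surface samplings: aim for a handful of points per occupied cell
  double h = diag / std::max(8.0, std::cbrt((double)pts.n_rows) * 4.0);
  return std::max(h, 1e-6);
}

// Greedy max-min farthest point sampling. Ties broken by lowest index.
// Returns 1-based indices in selection order.
// [[Rcpp::export]]
IntegerVector fps_cpp(const arma::mat& pts, int k, int seed_index) {
  const int n = pts.n_rows;
  if (k < 1 || k > n) stop("fps: k must be in [1, n]");
  if (seed_index < 1 || seed_index > n) stop("fps: seed_index out of range");
  IntegerVector out(k);
  arma::vec mind(n);
  mind.fill(arma::datum::inf);
  int cur = seed_index - 1;
  out[0] = cur + 1;
  for (int s = 1; s < k; ++s) {
    // update min distance to the selected set with the latest pick
    for (int i = 0; i < n; ++i) {
      double d = arma::norm(pts.row(i) - pts.row(cur), 2);
      if (d < mind[i]) mind[i] = d;
    }
    mind[cur] = -1.0;  // selected points can never win again
    int best = -1;
    double bestd = -1.0;
    for (int i = 0; i < n; ++i) {
      if (mind[i] > bestd) { bestd = mind[i]; best = i; }
    }
    cur = best;
    out[s] = cur + 1;
    mind[cur] = -1.0;
  }
  return out;
}

// For each query row: indices (1-based) of reference points within radius,
// sorted by distance (ties by index), truncated to max_k when max_k > 0.
// [[Rcpp::export]]
List radius_groups_cpp(const arma::mat& query, const arma::mat& ref,
                       double radius, int max_k) {
  const int nq = query.n_rows;
  const double r2 = radius * radius;
  Grid grid(ref, radius);
  List idx_out(nq), dist_out(nq);
  std::vector<std::pair<double,int>> hits;
  std::vector<int> cand;
  for (int i = 0; i < nq; ++i) {
    hits.clear();
    cand.clear();
    for (int s = 0; s <= 1; ++s) {
      grid.ring(query(i,0), query(i,1), query(i,2), s, cand);
    }
    for (int j : cand) {
      double d2 = 0.0;
      for (int c = 0; c < 3; ++c) {
        double t = query(i, c) - ref(j, c);
        d2 += t * t;
      }
      if (d2 <= r2) hits.push_back(std::make_pair(d2, j));
    }
    std::sort(hits.begin(), hits.end());
    int m = hits.size();
    if (max_k > 0 && m > max_k) m = max_k;
    IntegerVector ii(m);
    NumericVector dd(m);
    for (int t = 0; t < m; ++t) {
      ii[t] = hits[t].second + 1;
      dd[t] = std::sqrt(hits[t].first);
    }
    idx_out[i] = ii;
    dist_out[i] = dd;
  }
  return List::create(_["index"] = idx_out, _["dist"] = dist_out);
}

// k nearest reference points per query row (query may equal ref; set
// exclude_self to skip the zero-distance identical index).
// [[Rcpp::export]]
List knn_cpp(const arma::mat& query, const arma::mat& ref, int k,
             bool exclude_self) {
  const int nq = query.n_rows, nr = ref.n_rows;
  if (k > nr - (exclude_self ? 1 : 0)) stop("knn: k larger than reference");
  IntegerMatrix idx(nq, k);
  NumericMatrix dist(nq, k);
  double h = cloud_cell_size(ref);
  Grid grid(ref, h);
  arma::rowvec ext = arma::max(ref, 0) - arma::min(ref, 0);
  int max_ring = (int)std::ceil(arma::norm(ext, 2) / h) + 2;
  std::vector<std::pair<double,int>> hits;
  std::vector<int> cand;
  for (int i = 0; i < nq; ++i) {
    hits.clear();
    const int need = k + (exclude_self ? 1 : 0);
    bool done = false;
    for (int s = 0; s <= max_ring; ++s) {
      // queries far outside the reference extent would walk many empty
      // rings; brute force is cheaper there
      if (s >= 8 && hits.empty()) break;
      cand.clear();
      grid.ring(query(i,0), query(i,1), query(i,2), s, cand);
      for (int j : cand) {
        double d2 = 0.0;
        for (int c = 0; c < 3; ++c) {
          double t = query(i, c) - ref(j, c);
          d2 += t * t;
        }
        hits.push_back(std::make_pair(d2, j));
      }
      if ((int)hits.size() >= need) {
        std::sort(hits.begin(), hits.end());
        // points in unexplored cells are at least s*h away
        double bound = (double)s * h;
        if (std::sqrt(hits[need - 1].first) <= bound) { done = true; break; }
      }
    }
    if (!done) {
      hits.clear();
      for (int j = 0; j < nr; ++j) {
        double d2 = 0.0;
        for (int c = 0; c < 3; ++c) {
          double t = query(i, c) - ref(j, c);
          d2 += t * t;
        }
        hits.push_back(std::make_pair(d2, j));
      }
    }
    std::sort(hits.begin(), hits.end());
    int kept = 0;
    for (size_t q = 0; q < hits.size() && kept < k; ++q) {
      if (exclude_self && hits[q].second == i) continue;
      idx(i, kept) = hits[q].second + 1;
      dist(i, kept) = std::sqrt(hits[q].first);
      ++kept;
    }
    if (kept < k) stop("knn: grid search exhausted before k neighbors");
  }
  return List::create(_["index"] = idx, _["dist"] = dist);
}

// Surface-variation curvature sigma = lambda_min / (l1 + l2 + l3) from the
// covariance (about the neighborhood centroid) of all points within
// `radius` of each point, the point itself included. Neighborhoods with
// fewer than min_neighbors points get sigma = 0 and are counted.
// [[Rcpp::export]]
List curvature_cpp(const arma::mat& pts, double radius, int min_neighbors) {
  const int n = pts.n_rows;
  const double r2 = radius * radius;
  Grid grid(pts, radius);
  NumericVector sigma(n);
  int degenerate = 0;
  std::vector<int> nb, cand;
  for (int i = 0; i < n; ++i) {
    nb.clear();
    cand.clear();
    for (int s = 0; s <= 1; ++s) {
      grid.ring(pts(i,0), pts(i,1), pts(i,2), s, cand);
    }
    for (int j : cand) {
      double d2 = 0.0;
      for (int c = 0; c < 3; ++c) {
        double t = pts(i, c) - pts(j, c);
        d2 += t * t;
      }
      if (d2 <= r2) nb.push_back(j);
    }
    const int m = nb.size();
    if (m < min_neighbors) {
      sigma[i] = 0.0;
      ++degenerate;
      continue;
    }
    arma::mat P(m, 3);
    for (int t = 0; t < m; ++t) P.row(t) = pts.row(nb[t]);
    arma::rowvec mu = arma::mean(P, 0);
    P.each_row() -= mu;
    arma::mat C = P.t() * P;  // unnormalized scatter; sigma is a ratio
    arma::vec ev;
    arma::eig_sym(ev, C);     // ascending
    double s = arma::accu(ev);
    sigma[i] = (s > 0.0) ? ev(0) / s : 0.0;
    if (sigma[i] < 0.0) sigma[i] = 0.0;
    if (sigma[i] > 1.0 / 3.0) sigma[i] = 1.0 / 3.0;
  }
  return List::create(_["sigma"] = sigma, _["n_degenerate"] = degenerate);
}

static void kabsch_fit(const arma::mat& src, const arma::mat& tgt,
                       arma::mat& R, arma::vec& t) {
  arma::rowvec cs = arma::mean(src, 0), ct = arma::mean(tgt, 0);
  arma::mat S = src.each_row() - cs;
  arma::mat T = tgt.each_row() - ct;
  arma::mat H = S.t() * T;  // 3x3 cross-covariance
  arma::mat U, V;
  arma::vec sv;
  arma::svd(U, sv, V, H);
  arma::mat D = arma::eye(3, 3);
  D(2, 2) = arma::det(V * U.t());  // reflection guard
  R = V * D * U.t();
  t = ct.t() - R * cs.t();
}

static void kabsch_fit_w(const arma::mat& src, const arma::mat& tgt,
                         const arma::vec& w, arma::mat& R, arma::vec& t) {
  double sw = arma::accu(w);
  arma::rowvec cs = (w.t() * src) / sw;
  arma::rowvec ct = (w.t() * tgt) / sw;
  arma::mat S = src.each_row() - cs;
  arma::mat T = tgt.each_row() - ct;
  S.each_col() %= w;
  arma::mat H = S.t() * T;
  arma::mat U, V;
  arma::vec sv;
  arma::svd(U, sv, V, H);
  arma::mat D = arma::eye(3, 3);
  D(2, 2) = arma::det(V * U.t());
  R = V * D * U.t();
  t = ct.t() - R * cs.t();
}

// Least-squares rigid transform (R, t) mapping src onto tgt.
// [[Rcpp::export]]
List kabsch_cpp(const arma::mat& src, const arma::mat& tgt) {
  if (src.n_rows != tgt.n_rows || src.n_rows < 3)
    stop("kabsch: need >= 3 paired points");
  arma::mat R;
  arma::vec t;
  kabsch_fit(src, tgt, R, t);
  return List::create(_["rotation"] = R, _["translation"] = t);
}

// RANSAC over putative correspondences: minimal 3-point hypotheses scored
// by inlier count (residual <= thresh), best hypothesis refit on its
// inliers by Kabsch. Deterministic given seed.
// [[Rcpp::export]]
List ransac_cpp(const arma::mat& src, const arma::mat& tgt, int iters,
                double thresh, unsigned int seed) {
  const int n = src.n_rows;
  if (n < 3) stop("ransac: need >= 3 correspondences");
  std::mt19937 rng(seed);
  std::uniform_int_distribution<int> pick(0, n - 1);
  arma::mat bestR = arma::eye(3, 3);
  arma::vec bestt = arma::zeros(3);
  int best_count = -1;
  arma::mat R;
  arma::vec t;
  arma::mat s3(3, 3), t3(3, 3);
  for (int it = 0; it < iters; ++it) {
    int a = pick(rng), b = pick(rng), c = pick(rng);
    if (a == b || a == c || b == c) continue;
    s3.row(0) = src.row(a); s3.row(1) = src.row(b); s3.row(2) = src.row(c);
    t3.row(0) = tgt.row(a); t3.row(1) = tgt.row(b); t3.row(2) = tgt.row(c);
    // degenerate (near-collinear) minimal samples give unstable poses
    arma::rowvec e1 = s3.row(1) - s3.row(0), e2 = s3.row(2) - s3.row(0);
    arma::rowvec cr = arma::cross(e1, e2);
    if (arma::norm(cr, 2) < 1e-8) continue;
    kabsch_fit(s3, t3, R, t);
    int count = 0;
    for (int i = 0; i < n; ++i) {
      arma::vec p = R * src.row(i).t() + t;
      if (arma::norm(p - tgt.row(i).t(), 2) <= thresh) ++count;
    }
    if (count > best_count) {
      best_count = count;
      bestR = R;
      bestt = t;
    }
  }
  if (best_count < 3) {
    return List::create(_["ok"] = false, _["rotation"] = bestR,
                        _["translation"] = bestt, _["inliers"] = IntegerVector(0),
                        _["inlier_count"] = 0);
  }
  // iterated refit on the consensus set: refit, recount, repeat;
  // stabilizes the pose when several near-tie consensus sets exist
  for (int round = 0; round < 3; ++round) {
    std::vector<int> in;
    for (int i = 0; i < n; ++i) {
      arma::vec p = bestR * src.row(i).t() + bestt;
      if (arma::norm(p - tgt.row(i).t(), 2) <= thresh) in.push_back(i);
    }
    if (in.size() < 3) break;
    arma::mat si(in.size(), 3), ti(in.size(), 3);
    for (size_t i = 0; i < in.size(); ++i) {
      si.row(i) = src.row(in[i]);
      ti.row(i) = tgt.row(in[i]);
    }
    kabsch_fit(si, ti, bestR, bestt);
  }
  IntegerVector inliers;
  int count = 0;
  std::vector<int> in2;
  for (int i = 0; i < n; ++i) {
    arma::vec p = bestR * src.row(i).t() + bestt;
    if (arma::norm(p - tgt.row(i).t(), 2) <= thresh) { ++count; in2.push_back(i + 1); }
  }
  inliers = wrap(in2);
  return List::create(_["ok"] = true, _["rotation"] = bestR,
                      _["translation"] = bestt, _["inliers"] = inliers,
                      _["inlier_count"] = count);
}

// Point-to-point ICP from an initial pose. Each iteration matches every
// transformed source point to its nearest target point, drops pairs
// beyond max_corr, and re-estimates the cumulative transform on the
// matched original coordinates. Stops when the mean matched residual
// changes by less than tol.
// [[Rcpp::export]]
List icp_cpp(const arma::mat& src, const arma::mat& tgt,
             const arma::mat& R0, const arma::vec& t0,
             int max_iters, double tol, double max_corr, double trim,
             bool symmetric, bool robust) {
  const int n = src.n_rows, m = tgt.n_rows;
  arma::mat R = R0;
  arma::vec t = t0;
  std::vector<double> residuals;
  bool converged = false, any_corr = false;
  double prev = arma::datum::inf;
  for (int it = 0; it < max_iters; ++it) {
    arma::mat cur = src * R.t();
    cur.each_row() += t.t();
    // only target points near the moved source can participate
    arma::rowvec lo = arma::min(cur, 0) - max_corr;
    arma::rowvec hi = arma::max(cur, 0) + max_corr;
    std::vector<int> cand;
    for (int j = 0; j < m; ++j) {
      if (tgt(j,0) >= lo(0) && tgt(j,0) <= hi(0) &&
          tgt(j,1) >= lo(1) && tgt(j,1) <= hi(1) &&
          tgt(j,2) >= lo(2) && tgt(j,2) <= hi(2)) cand.push_back(j);
    }
    std::vector<int> si, ti;
    std::vector<double> di;
    for (int i = 0; i < n; ++i) {
      double bd2 = arma::datum::inf;
      int bj = -1;
      for (int j : cand) {
        double d2 = 0.0;
        for (int c = 0; c < 3; ++c) {
          double d = cur(i, c) - tgt(j, c);
          d2 += d * d;
        }
        if (d2 < bd2) { bd2 = d2; bj = j; }
      }
      double d = std::sqrt(bd2);
      if (d <= max_corr) {
        si.push_back(i);
        ti.push_back(bj);
        di.push_back(d);
      }
    }
    if (symmetric && di.size() >= 3) {
      // reverse direction: nearest moved-source point per candidate
      // target point; symmetrizing the correspondence set cancels most
      // of the nearest-sample quantization bias of point-to-point ICP.
      // The source covers only part of the target, so reverse pairs are
      // gated by the forward residual scale — otherwise every target
      // point near the patch (including uncovered surface) would drag
      // the fit.
      std::vector<double> dsort(di);
      std::nth_element(dsort.begin(), dsort.begin() + dsort.size() / 2,
                       dsort.end());
      double rev_thresh = std::min(max_corr, 3.0 * dsort[dsort.size() / 2]);
      for (int j : cand) {
        double bd2 = arma::datum::inf;
        int bi = -1;
        for (int i = 0; i < n; ++i) {
          double d2 = 0.0;
          for (int c = 0; c < 3; ++c) {
            double d = cur(i, c) - tgt(j, c);
            d2 += d * d;
          }
          if (d2 < bd2) { bd2 = d2; bi = i; }
        }
        double d = std::sqrt(bd2);
        if (d <= rev_thresh) {
          si.push_back(bi);
          ti.push_back(j);
          di.push_back(d);
        }
      }
    }
    if (si.size() < 3) break;  // no usable correspondences at this pose
    // trimmed variant: keep the closest fraction of matches, which
    // suppresses the boundary pull of partially overlapping patches
    if (trim < 1.0 && (int)si.size() > 3) {
      int keep = std::max(3, (int)std::floor(trim * si.size()));
      std::vector<int> ord(si.size());
      for (size_t q = 0; q < ord.size(); ++q) ord[q] = q;
      std::stable_sort(ord.begin(), ord.end(),
                       [&](int a, int b) { return di[a] < di[b]; });
      std::vector<int> si2, ti2;
      std::vector<double> di2;
      for (int q = 0; q < keep; ++q) {
        si2.push_back(si[ord[q]]);
        ti2.push_back(ti[ord[q]]);
        di2.push_back(di[ord[q]]);
      }
      si.swap(si2); ti.swap(ti2); di.swap(di2);
    }
    any_corr = true;
    double res = 0.0;
    for (double d : di) res += d;
    res /= si.size();
    residuals.push_back(res);
    if (std::abs(prev - res) < tol) { converged = true; break; }
    prev = res;
    arma::mat S(si.size(), 3), T(si.size(), 3);
    for (size_t q = 0; q < si.size(); ++q) {
      S.row(q) = src.row(si[q]);
      T.row(q) = tgt.row(ti[q]);
    }
    if (robust) {
      // Welsch-weighted re-estimation: scale from the median residual;
      // smoothly downweights boundary and cross-source mismatches
      std::vector<double> dsort(di);
      std::nth_element(dsort.begin(), dsort.begin() + dsort.size() / 2,
                       dsort.end());
      double sigma = std::max(1e-9, 2.0 * dsort[dsort.size() / 2]);
      arma::vec w(si.size());
      for (size_t q = 0; q < si.size(); ++q) {
        double z = di[q] / sigma;
        w(q) = std::exp(-z * z);
      }
      kabsch_fit_w(S, T, w, R, t);
    } else {
      kabsch_fit(S, T, R, t);
    }
  }
  return List::create(_["rotation"] = R, _["translation"] = t,
                      _["converged"] = converged,
                      _["had_correspondences"] = any_corr,
                      _["residuals"] = wrap(residuals));
}

// Voxel-grid downsampling: one representative per occupied voxel, the
// point closest to the voxel centroid (ties by lowest index). Returns
// sorted 1-based indices into pts.
// [[Rcpp::export]]
IntegerVector voxel_downsample_cpp(const arma::mat& pts, double voxel) {
  const int n = pts.n_rows;
  if (voxel <= 0) stop("voxel size must be > 0");
  arma::rowvec mn = arma::min(pts, 0);
  std::map<std::tuple<long,long,long>, std::vector<int>> cells;
  for (int i = 0; i < n; ++i) {
    long ix = (long)std::floor((pts(i,0) - mn(0)) / voxel);
    long iy = (long)std::floor((pts(i,1) - mn(1)) / voxel);
    long iz = (long)std::floor((pts(i,2) - mn(2)) / voxel);
    cells[std::make_tuple(ix, iy, iz)].push_back(i);
  }
  std::vector<int> keep;
  keep.reserve(cells.size());
  for (auto& kv : cells) {
    double cx = mn(0) + (std::get<0>(kv.first) + 0.5) * voxel;
    double cy = mn(1) + (std::get<1>(kv.first) + 0.5) * voxel;
    double cz = mn(2) + (std::get<2>(kv.first) + 0.5) * voxel;
    int best = -1;
    double bd = arma::datum::inf;
    for (int i : kv.second) {
      double dx = pts(i,0) - cx, dy = pts(i,1) - cy, dz = pts(i,2) - cz;
      double d2 = dx*dx + dy*dy + dz*dz;
      if (d2 < bd - 1e-15 || best < 0) { bd = d2; best = i; }
    }
    keep.push_back(best + 1);
  }
  std::sort(keep.begin(), keep.end());
  return wrap(keep);
}

// Column-wise max within groups of rows, with 1-based argmax row indices.
// `group` holds 1-based group ids per row of H; ngroups is the number of
// groups. Every group must own at least one row.
// [[Rcpp::export]]
List group_max_cpp(const arma::mat& H, const IntegerVector& group,
                   int ngroups) {
  const int S = H.n_rows, C = H.n_cols;
  arma::mat out(ngroups, C);
  out.fill(-arma::datum::inf);
  IntegerMatrix arg(ngroups, C);
  for (int i = 0; i < S; ++i) {
    int g = group[i] - 1;
    for (int c = 0; c < C; ++c) {
      if (H(i, c) > out(g, c)) {
        out(g, c) = H(i, c);
        arg(g, c) = i + 1;
      }
    }
  }
  return List::create(_["max"] = out, _["argmax"] = arg);
}
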