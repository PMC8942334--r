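// Low-level kernels for Calpha structure alignment:
//  - afp_scan: all gapless fragment-pair windows with superposition RMSD
//    below a cutoff, plus each window's rigid transform
//  - chain_afps: monotone dynamic-programming chaining of those windows,
//    optionally allowing a limited number of rigid-block changes (twists)
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

// Minimal-RMSD statistics for one window from accumulated sums.
// Returns squared deviation sum (E) and, if rot != nullptr, the proper
// rotation mapping centred A onto centred B.
double window_msd(const arma::vec &Sa, const arma::vec &Sb,
                  double Saa, double Sbb, const arma::mat &Sab,
                  int L, arma::mat *rot) {
  arma::vec ca = Sa / L, cb = Sb / L;
  // covariance C = sum a b^T - L ca cb^T  (a rows of A, b rows of B)
  arma::mat C = Sab - L * (ca * cb.t());
  double E0 = (Saa - L * arma::dot(ca, ca)) + (Sbb - L * arma::dot(cb, cb));
  arma::mat U, V;
  arma::vec s;
  if (!arma::svd(U, s, V, C)) return -1.0;
  double sgn = (arma::det(V * U.t()) < 0.0) ? -1.0 : 1.0;
  double D = s(0) + s(1) + sgn * s(2);
  double msd = (E0 - 2.0 * D) / L;
  if (msd < 0) msd = 0;
  if (rot) {
    arma::mat Dm = arma::eye(3, 3);
    Dm(2, 2) = sgn;
    *rot = V * Dm * U.t();  // b ~ rot * a (centred)
  }
  return msd;
}

}  // namespace

// [[Rcpp::export(name = ".afp_scan_cpp")]]
List afp_scan_cpp(const arma::mat &A, const arma::mat &B, int L,
                  double rmsd_max, int thin = 1) {
  const int n = A.n_rows, m = B.n_rows;
  std::vector<int> vi, vj;
  std::vector<double> vr;
  std::vector<double> vrot;  // 9 per AFP, row-major
  std::vector<double> vca, vcb;

  struct Hit { int i; double rmsd; arma::mat R; arma::vec ca, cb; };
  std::vector<Hit> run;  // current same-diagonal run of passing windows

  auto emit = [&](const Hit &h, int d) {
    vi.push_back(h.i);
    vj.push_back(h.i + d);
    vr.push_back(h.rmsd);
    for (int r = 0; r < 3; ++r)
      for (int c = 0; c < 3; ++c) vrot.push_back(h.R(r, c));
    for (int r = 0; r < 3; ++r) vca.push_back(h.ca(r));
    for (int r = 0; r < 3; ++r) vcb.push_back(h.cb(r));
  };
  // thin long same-diagonal runs to every `thin`-th window plus both run
  // ends; window unions still cover every residue of the run
  auto flush_run = [&](int d) {
    const int R = (int)run.size();
    for (int q = 0; q < R; ++q)
      if (q == 0 || q == R - 1 || (thin <= 1) || (q % thin == 0))
        emit(run[q], d);
    run.clear();
  };

  // iterate diagonals d = j - i
  for (int d = -(n - L); d <= (m - L); ++d) {
    int i0 = std::max(0, -d);
    int i1 = std::min(n - L, m - L - d);
    if (i1 < i0) continue;
    // sliding sums over window starting at i (A rows i..i+L-1, B rows i+d..)
    arma::vec Sa(3, arma::fill::zeros), Sb(3, arma::fill::zeros);
    arma::mat Sab(3, 3, arma::fill::zeros);
    double Saa = 0, Sbb = 0;
    for (int k = 0; k < L; ++k) {
      arma::vec a = A.row(i0 + k).t(), b = B.row(i0 + d + k).t();
      Sa += a; Sb += b; Saa += arma::dot(a, a); Sbb += arma::dot(b, b);
      Sab += a * b.t();
    }
    for (int i = i0; i <= i1; ++i) {
      arma::mat R;
      double msd = window_msd(Sa, Sb, Saa, Sbb, Sab, L, &R);
      if (msd >= 0 && std::sqrt(msd) <= rmsd_max) {
        run.push_back({i, std::sqrt(msd), R, Sa / L, Sb / L});
      } else if (!run.empty()) flush_run(d);
      if (i < i1) {  // slide: drop row i, add row i+L
        arma::vec a0 = A.row(i).t(), b0 = B.row(i + d).t();
        arma::vec a1 = A.row(i + L).t(), b1 = B.row(i + d + L).t();
        Sa += a1 - a0; Sb += b1 - b0;
        Saa += arma::dot(a1, a1) - arma::dot(a0, a0);
        Sbb += arma::dot(b1, b1) - arma::dot(b0, b0);
        Sab += a1 * b1.t() - a0 * b0.t();
      }
    }
    if (!run.empty()) flush_run(d);
  }

  const int K = (int)vi.size();
  IntegerVector oi(K), oj(K);
  NumericVector orms(K);
  NumericMatrix orot(K, 9), oca(K, 3), ocb(K, 3);
  for (int k = 0; k < K; ++k) {
    oi[k] = vi[k]; oj[k] = vj[k]; orms[k] = vr[k];
    for (int c = 0; c < 9; ++c) orot(k, c) = vrot[9 * k + c];
    for (int c = 0; c < 3; ++c) { oca(k, c) = vca[3 * k + c]; ocb(k, c) = vcb[3 * k + c]; }
  }
  return List::create(_["i"] = oi, _["j"] = oj, _["rmsd"] = orms,
                      _["rot"] = orot, _["ca"] = oca, _["cb"] = ocb);
}

// [[Rcpp::export(name = ".chain_afps_cpp")]]
List chain_afps_cpp(const IntegerVector &ai, const IntegerVector &aj,
                    const NumericVector &w, const NumericMatrix &rot,
                    const NumericMatrix &ca, const NumericMatrix &cb,
                    int L, int gap_max, double twist_penalty, int max_twists,
                    double rot_tol_deg, double trans_tol) {
  const int m = ai.size();
  if (m == 0)
    return List::create(_["chain"] = IntegerVector(0),
                        _["twist_before"] = LogicalVector(0),
                        _["score"] = 0.0);

  // sort by (i, j)
  std::vector<int> ord(m);
  for (int k = 0; k < m; ++k) ord[k] = k;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (ai[a] != ai[b]) return ai[a] < ai[b];
    return aj[a] < aj[b];
  });

  // row index: i -> sorted (j, id)
  int imax = 0;
  for (int k = 0; k < m; ++k) imax = std::max(imax, ai[k]);
  std::vector<std::vector<std::pair<int, int>>> rows(imax + 1);
  for (int k = 0; k < m; ++k) rows[ai[k]].push_back({aj[k], k});
  for (auto &r : rows) std::sort(r.begin(), r.end());

  const int T = max_twists;
  const double NEG = -1e18;
  // best[k * (T+1) + t]
  std::vector<double> best((size_t)m * (T + 1), NEG);
  std::vector<int> prevk((size_t)m * (T + 1), -1), prevt((size_t)m * (T + 1), -1);
  const double cos_tol = std::cos(rot_tol_deg * M_PI / 180.0);

  auto compatible = [&](int p, int k) {
    // rotation agreement
    double tr = 0;
    for (int r = 0; r < 3; ++r)
      for (int c = 0; c < 3; ++c) tr += rot(p, 3 * r + c) * rot(k, 3 * r + c);
    // trace(Rp^T Rk); cos(theta) = (tr-1)/2
    if ((tr - 1.0) / 2.0 < cos_tol) return false;
    // translation agreement: map k's A-centroid through p's transform
    double y[3], dd = 0;
    for (int r = 0; r < 3; ++r) {
      y[r] = cb(p, r);
      for (int c = 0; c < 3; ++c) y[r] += rot(p, 3 * r + c) * (ca(k, c) - ca(p, c));
      double e = y[r] - cb(k, r);
      dd += e * e;
    }
    return dd <= trans_tol * trans_tol;
  };

  double best_final = NEG;
  int best_k = -1, best_t = -1;

  for (int idx = 0; idx < m; ++idx) {
    int k = ord[idx];
    int ik = ai[k], jk = aj[k];
    for (int t = 0; t <= T; ++t) best[(size_t)k * (T + 1) + t] = NEG;
    best[(size_t)k * (T + 1) + 0] = w[k];  // chain starts here

    // non-overlapping predecessors
    int ilo = std::max(0, ik - L - gap_max), ihi = ik - L;
    for (int ip = ilo; ip <= ihi && ip <= imax; ++ip) {
      if (ip < 0) continue;
      const auto &r = rows[ip];
      int jlo = jk - L - gap_max, jhi = jk - L;
      auto it = std::lower_bound(r.begin(), r.end(), std::make_pair(jlo, -1));
      for (; it != r.end() && it->first <= jhi; ++it) {
        int p = it->second;
        bool comp = compatible(p, k);
        for (int t = 0; t <= T; ++t) {
          double bp = best[(size_t)p * (T + 1) + t];
          if (bp <= NEG / 2) continue;
          if (comp) {
            double cand = bp + w[k];
            if (cand > best[(size_t)k * (T + 1) + t]) {
              best[(size_t)k * (T + 1) + t] = cand;
              prevk[(size_t)k * (T + 1) + t] = p;
              prevt[(size_t)k * (T + 1) + t] = t;
            }
          } else if (t < T) {
            double cand = bp + w[k] - twist_penalty;
            if (cand > best[(size_t)k * (T + 1) + t + 1]) {
              best[(size_t)k * (T + 1) + t + 1] = cand;
              prevk[(size_t)k * (T + 1) + t + 1] = p;
              prevt[(size_t)k * (T + 1) + t + 1] = t;
            }
          }
        }
      }
    }
    // same-diagonal overlapping predecessors (always same block)
    for (int delta = 1; delta < L; ++delta) {
      int ip = ik - delta, jp = jk - delta;
      if (ip < 0 || ip > imax) continue;
      const auto &r = rows[ip];
      auto it = std::lower_bound(r.begin(), r.end(), std::make_pair(jp, -1));
      if (it == r.end() || it->first != jp) continue;
      int p = it->second;
      if (!compatible(p, k)) continue;
      double gain = w[k] * ((double)delta / L);
      for (int t = 0; t <= T; ++t) {
        double bp = best[(size_t)p * (T + 1) + t];
        if (bp <= NEG / 2) continue;
        double cand = bp + gain;
        if (cand > best[(size_t)k * (T + 1) + t]) {
          best[(size_t)k * (T + 1) + t] = cand;
          prevk[(size_t)k * (T + 1) + t] = p;
          prevt[(size_t)k * (T + 1) + t] = t;
        }
      }
    }
    for (int t = 0; t <= T; ++t) {
      double b = best[(size_t)k * (T + 1) + t];
      if (b > best_final) { best_final = b; best_k = k; best_t = t; }
    }
  }

  // backtrack
  std::vector<int> chain;
  std::vector<int> twists;
  int k = best_k, t = best_t;
  while (k >= 0) {
    chain.push_back(k);
    int pk = prevk[(size_t)k * (T + 1) + t];
    int pt = prevt[(size_t)k * (T + 1) + t];
    twists.push_back(pk >= 0 && pt != t ? 1 : 0);
    k = pk;
    t = (pt >= 0) ? pt : t;
  }
  std::reverse(chain.begin(), chain.end());
  std::reverse(twists.begin(), twists.end());

  IntegerVector och(chain.size());
  LogicalVector otw(chain.size());
  for (size_t q = 0; q < chain.size(); ++q) {
    och[q] = chain[q] + 1;  // 1-based for R
    otw[q] = twists[q] == 1;
  }
  return List::create(_["chain"] = och, _["twist_before"] = otw,
                      _["score"] = best_final);
}
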