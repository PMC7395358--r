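// Nested adaptive Gauss-Hermite quadrature for multilevel logistic
// likelihoods: individuals in households in clusters, one Q-variate normal
// random intercept per cluster and one per household (independent across
// levels).  Q = 1 gives the per-outcome model; Q = 3 the simultaneous one.
//
// Both integrals are adapted at the conditional mode with the conditional
// curvature; the same construction is used for every Q so that with
// diagonal covariance blocks the Q-variate likelihood factorises exactly
// into the univariate ones (tensor-product grids, coordinate-decoupled
// Newton steps).
//
// Hot paths use fixed-size stack arrays (Q <= 3) rather than dynamic
// matrices; the per-cluster cost is linear in households x individuals x
// quadrature points.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const int QMAX = 3;

static inline double log1pexp_(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

namespace {

// lower Cholesky of a Q x Q SPD matrix (row-major storage); returns false
// if a pivot is non-positive
inline bool chol_small(int Q, const double* M, double* L) {
  for (int i = 0; i < Q; ++i) {
    for (int j = 0; j <= i; ++j) {
      double s = M[i * QMAX + j];
      for (int k = 0; k < j; ++k) s -= L[i * QMAX + k] * L[j * QMAX + k];
      if (i == j) {
        if (s <= 0.0) return false;
        L[i * QMAX + i] = std::sqrt(s);
      } else {
        L[i * QMAX + j] = s / L[j * QMAX + j];
      }
    }
  }
  return true;
}

// solve L L' x = b in place (b overwritten with x)
inline void chol_solve(int Q, const double* L, double* b) {
  for (int i = 0; i < Q; ++i) {
    double s = b[i];
    for (int k = 0; k < i; ++k) s -= L[i * QMAX + k] * b[k];
    b[i] = s / L[i * QMAX + i];
  }
  for (int i = Q - 1; i >= 0; --i) {
    double s = b[i];
    for (int k = i + 1; k < Q; ++k) s -= L[k * QMAX + i] * b[k];
    b[i] = s / L[i * QMAX + i];
  }
}

// x = L^{-T} z (backward substitution with the transpose)
inline void backsolve_t(int Q, const double* L, const double* z, double* x) {
  for (int i = Q - 1; i >= 0; --i) {
    double s = z[i];
    for (int k = i + 1; k < Q; ++k) s -= L[k * QMAX + i] * x[k];
    x[i] = s / L[i * QMAX + i];
  }
}

inline void matvec(int Q, const double* M, const double* v, double* out) {
  for (int i = 0; i < Q; ++i) {
    double s = 0.0;
    for (int j = 0; j < Q; ++j) s += M[i * QMAX + j] * v[j];
    out[i] = s;
  }
}

inline double quadform(int Q, const double* M, const double* v) {
  double s = 0.0;
  for (int i = 0; i < Q; ++i)
    for (int j = 0; j < Q; ++j) s += v[i] * M[i * QMAX + j] * v[j];
  return s;
}

struct LevelPrec {          // precision of one random-effect level
  bool present = false;
  double Si[QMAX * QMAX];   // inverse covariance (row-major, QMAX stride)
  double cst = 0.0;         // log-normalizing constant of the prior
};

class NestedLik {
public:
  NestedLik(const mat& eta, const imat& Y,
            const ivec& hh_ptr, const ivec& cl_ptr,
            const mat& Lc, const mat& Lh,
            const vec& gh_x, const vec& gh_w)
    : hh_ptr_(hh_ptr), cl_ptr_(cl_ptr) {
    Q_ = static_cast<int>(eta.n_cols);
    n_ = static_cast<int>(eta.n_rows);
    if (Q_ > QMAX) Rcpp::stop("at most %d outcomes supported", QMAX);
    eta_ = eta.memptr();
    Y_ = Y.memptr();
    init_level(lev_c_, Lc);
    init_level(lev_h_, Lh);
    build_grid(gh_x, gh_w);
    int H = static_cast<int>(hh_ptr.n_elem) - 1;
    vhat_.assign(static_cast<size_t>(H) * QMAX, 0.0);
    uhat_.assign(static_cast<size_t>(cl_ptr.n_elem - 1) * QMAX, 0.0);
  }

  // optional persistent mode state (C x Q and H x Q), warm-starting the
  // Newton searches across likelihood evaluations during optimization
  void load_state(const Rcpp::NumericMatrix& um,
                  const Rcpp::NumericMatrix& vm) {
    int C = static_cast<int>(cl_ptr_.n_elem) - 1;
    int H = static_cast<int>(hh_ptr_.n_elem) - 1;
    if (um.nrow() == C && um.ncol() == Q_)
      for (int c = 0; c < C; ++c)
        for (int q = 0; q < Q_; ++q)
          uhat_[static_cast<size_t>(c) * QMAX + q] = um(c, q);
    if (vm.nrow() == H && vm.ncol() == Q_)
      for (int h = 0; h < H; ++h)
        for (int q = 0; q < Q_; ++q)
          vhat_[static_cast<size_t>(h) * QMAX + q] = vm(h, q);
  }

  void save_state(Rcpp::NumericMatrix& um, Rcpp::NumericMatrix& vm) const {
    int C = static_cast<int>(cl_ptr_.n_elem) - 1;
    int H = static_cast<int>(hh_ptr_.n_elem) - 1;
    if (um.nrow() == C && um.ncol() == Q_)
      for (int c = 0; c < C; ++c)
        for (int q = 0; q < Q_; ++q)
          um(c, q) = uhat_[static_cast<size_t>(c) * QMAX + q];
    if (vm.nrow() == H && vm.ncol() == Q_)
      for (int h = 0; h < H; ++h)
        for (int q = 0; q < Q_; ++q)
          vm(h, q) = vhat_[static_cast<size_t>(h) * QMAX + q];
  }

  double loglik() {
    int C = static_cast<int>(cl_ptr_.n_elem) - 1;
    double total = 0.0;
    for (int c = 0; c < C; ++c) total += cluster_loglik(c);
    return total;
  }

private:
  int Q_, n_;
  const double* eta_;   // column-major n x Q
  const int* Y_;
  const ivec& hh_ptr_;
  const ivec& cl_ptr_;
  LevelPrec lev_c_, lev_h_;
  std::vector<double> Z_;     // K x Q node coordinates (node-major)
  std::vector<double> logw_;  // K modified log-weights
  int K_ = 1;
  std::vector<double> vhat_;  // warm-started household modes (H x QMAX)
  std::vector<double> uhat_;  // warm-started cluster modes (C x QMAX)
  std::vector<double> Gk_;    // outer-node values, size K

  void init_level(LevelPrec& lev, const mat& L) {
    if (L.n_rows == 0) return;
    if (static_cast<int>(L.n_rows) != Q_)
      Rcpp::stop("covariance factor dimension does not match outcomes");
    lev.present = true;
    mat S = L * L.t();
    mat Si = inv_sympd(S);
    for (int i = 0; i < Q_; ++i)
      for (int j = 0; j < Q_; ++j)
        lev.Si[i * QMAX + j] = Si(i, j);
    lev.cst = -0.5 * Q_ * std::log(2.0 * datum::pi) -
      accu(log(L.diag()));
  }

  void build_grid(const vec& gh_x, const vec& gh_w) {
    int k = static_cast<int>(gh_x.n_elem);
    K_ = 1;
    for (int q = 0; q < Q_; ++q) K_ *= k;
    Z_.resize(static_cast<size_t>(K_) * Q_);
    logw_.resize(K_);
    Gk_.resize(K_);
    for (int idx = 0; idx < K_; ++idx) {
      int rem = idx;
      double lw = 0.0;
      for (int q = 0; q < Q_; ++q) {
        int j = rem % k;
        rem /= k;
        double z = gh_x(j);
        Z_[static_cast<size_t>(idx) * Q_ + q] = z;
        lw += std::log(gh_w(j)) + z * z;
      }
      logw_[idx] = lw;
    }
  }

  // Bernoulli log-likelihood of household rows [r0, r1) at offset shift;
  // accumulates residual r and information d per outcome when not null
  inline double bern(int r0, int r1, const double* shift,
                     double* r, double* d) const {
    double ll = 0.0;
    if (r) for (int q = 0; q < Q_; ++q) { r[q] = 0.0; d[q] = 0.0; }
    for (int q = 0; q < Q_; ++q) {
      const double* ecol = eta_ + static_cast<size_t>(q) * n_;
      const int* ycol = Y_ + static_cast<size_t>(q) * n_;
      const double sh = shift[q];
      for (int i = r0; i < r1; ++i) {
        double e = ecol[i] + sh;
        double y = static_cast<double>(ycol[i]);
        if (e > 35.0) {
          ll += y * e - e;
          if (r) r[q] += y - 1.0;
        } else if (e < -35.0) {
          double ex = std::exp(e);
          ll += y * e - ex;
          if (r) { r[q] += y - ex; d[q] += ex; }
        } else {
          double ex = std::exp(e);
          ll += y * e - std::log1p(ex);
          if (r) {
            double p = ex / (1.0 + ex);
            r[q] += y - p;
            d[q] += p * (1.0 - p);
          }
        }
      }
    }
    return ll;
  }

  // integrand log-density for household h at effect v, cluster offset u;
  // fills full gradient wrt v (grad) and Bernoulli information (d)
  inline double inner_l(int h, const double* u, const double* v,
                        double* grad, double* d) const {
    double shift[QMAX];
    for (int q = 0; q < Q_; ++q) shift[q] = u[q] + v[q];
    double lb = bern(hh_ptr_(h), hh_ptr_(h + 1), shift, grad, d);
    double lq = lev_h_.cst - 0.5 * quadform(Q_, lev_h_.Si, v);
    if (grad) {
      double sv[QMAX];
      matvec(Q_, lev_h_.Si, v, sv);
      for (int q = 0; q < Q_; ++q) grad[q] -= sv[q];
    }
    return lq + lb;
  }

  // log of the household-level integral at cluster offset u, plus (when
  // need_grad) its gradient g and Hessian Hg with respect to u
  double inner(int h, const double* u, bool need_grad,
               double* g, double* Hg) {
    if (!lev_h_.present) {
      double r[QMAX], d[QMAX];
      double ll = bern(hh_ptr_(h), hh_ptr_(h + 1), u,
                       need_grad ? r : nullptr, need_grad ? d : nullptr);
      if (need_grad) {
        for (int q = 0; q < Q_; ++q) {
          g[q] = r[q];
          for (int j = 0; j < Q_; ++j) Hg[q * QMAX + j] = 0.0;
          Hg[q * QMAX + q] = -d[q];
        }
      }
      return ll;
    }

    double* vh = &vhat_[static_cast<size_t>(h) * QMAX];
    double v[QMAX], grad[QMAX], d[QMAX];
    for (int q = 0; q < Q_; ++q) v[q] = vh[q];
    double l = inner_l(h, u, v, grad, d);
    double Hm[QMAX * QMAX], L[QMAX * QMAX];
    for (int it = 0; it < 50; ++it) {
      for (int i = 0; i < Q_; ++i)
        for (int j = 0; j < Q_; ++j)
          Hm[i * QMAX + j] = lev_h_.Si[i * QMAX + j];
      for (int q = 0; q < Q_; ++q) Hm[q * QMAX + q] += d[q];
      if (!chol_small(Q_, Hm, L)) break;
      double step[QMAX];
      for (int q = 0; q < Q_; ++q) step[q] = grad[q];
      chol_solve(Q_, L, step);
      double vnew[QMAX], lnew;
      int halvings = 0;
      while (true) {
        for (int q = 0; q < Q_; ++q) vnew[q] = v[q] + step[q];
        lnew = inner_l(h, u, vnew, grad, d);
        if (lnew >= l - 1e-12 || halvings >= 30) break;
        for (int q = 0; q < Q_; ++q) step[q] *= 0.5;
        ++halvings;
      }
      double mx = 0.0;
      for (int q = 0; q < Q_; ++q) mx = std::max(mx, std::fabs(step[q]));
      for (int q = 0; q < Q_; ++q) v[q] = vnew[q];
      l = lnew;
      if (mx < 1e-10) break;
    }
    for (int q = 0; q < Q_; ++q) vh[q] = v[q];

    // curvature at the mode
    for (int i = 0; i < Q_; ++i)
      for (int j = 0; j < Q_; ++j)
        Hm[i * QMAX + j] = lev_h_.Si[i * QMAX + j];
    for (int q = 0; q < Q_; ++q) Hm[q * QMAX + q] += d[q];
    if (!chol_small(Q_, Hm, L)) {
      for (int q = 0; q < Q_; ++q) Hm[q * QMAX + q] += 1e-8;
      chol_small(Q_, Hm, L);
    }
    double logdetA = 0.0;
    for (int q = 0; q < Q_; ++q) logdetA -= std::log(L[q * QMAX + q]);
    const double sqrt2 = std::sqrt(2.0);

    // quadrature over the adapted grid
    double lref = l;
    double s = 0.0;
    double m1[QMAX], M2[QMAX * QMAX];
    if (need_grad) {
      for (int q = 0; q < Q_; ++q) m1[q] = 0.0;
      for (int q = 0; q < Q_ * QMAX; ++q) M2[q] = 0.0;
    }
    double off[QMAX], vk[QMAX], rk[QMAX], dk[QMAX];
    for (int kk = 0; kk < K_; ++kk) {
      const double* z = &Z_[static_cast<size_t>(kk) * Q_];
      backsolve_t(Q_, L, z, off);
      for (int q = 0; q < Q_; ++q) vk[q] = v[q] + sqrt2 * off[q];
      double lv = inner_l(h, u, vk, need_grad ? rk : nullptr,
                          need_grad ? dk : nullptr);
      double w = std::exp(logw_[kk] + lv - lref);
      s += w;
      if (need_grad) {
        // Bernoulli residual (gradient wrt u): add back the prior term
        double sv[QMAX];
        matvec(Q_, lev_h_.Si, vk, sv);
        for (int q = 0; q < Q_; ++q) rk[q] += sv[q];
        for (int i = 0; i < Q_; ++i) {
          m1[i] += w * rk[i];
          for (int j = 0; j < Q_; ++j)
            M2[i * QMAX + j] += w * rk[i] * rk[j];
          M2[i * QMAX + i] -= w * dk[i];
        }
      }
    }
    double logJ = lref + std::log(s) + 0.5 * Q_ * std::log(2.0) + logdetA;
    if (need_grad) {
      for (int i = 0; i < Q_; ++i) m1[i] /= s;
      for (int i = 0; i < Q_ * QMAX; ++i) M2[i] /= s;
      for (int i = 0; i < Q_; ++i) {
        g[i] = m1[i];
        for (int j = 0; j < Q_; ++j)
          Hg[i * QMAX + j] = M2[i * QMAX + j] - m1[i] * m1[j];
      }
      if (K_ == 1) {
        // a single node cannot estimate the posterior variance term, so
        // use the implicit-function curvature of the Laplace integral:
        // d2 logJ / du2 = -D + D (Sih + D)^{-1} D, with D the Bernoulli
        // information at the conditional mode (d, L already there)
        double Kin[QMAX * QMAX];
        for (int j = 0; j < Q_; ++j) {
          double e[QMAX] = {0.0, 0.0, 0.0};
          e[j] = 1.0;
          chol_solve(Q_, L, e);
          for (int i = 0; i < Q_; ++i) Kin[i * QMAX + j] = e[i];
        }
        for (int i = 0; i < Q_; ++i)
          for (int j = 0; j < Q_; ++j)
            Hg[i * QMAX + j] = d[i] * Kin[i * QMAX + j] * d[j] -
              (i == j ? d[i] : 0.0);
      }
    }
    return logJ;
  }

  // G(u) = log phi(u; Sigma_c) + sum_h log J_h(u)
  double outer_G(int c, const double* u, bool need_grad,
                 double* grad, double* hess) {
    double G = 0.0;
    if (need_grad) {
      for (int q = 0; q < Q_; ++q) grad[q] = 0.0;
      for (int q = 0; q < Q_ * QMAX; ++q) hess[q] = 0.0;
    }
    double g[QMAX], Hg[QMAX * QMAX];
    for (int h = cl_ptr_(c); h < cl_ptr_(c + 1); ++h) {
      G += inner(h, u, need_grad, g, Hg);
      if (need_grad) {
        for (int i = 0; i < Q_; ++i) {
          grad[i] += g[i];
          for (int j = 0; j < Q_; ++j)
            hess[i * QMAX + j] += Hg[i * QMAX + j];
        }
      }
    }
    if (lev_c_.present) {
      G += lev_c_.cst - 0.5 * quadform(Q_, lev_c_.Si, u);
      if (need_grad) {
        double su[QMAX];
        matvec(Q_, lev_c_.Si, u, su);
        for (int i = 0; i < Q_; ++i) {
          grad[i] -= su[i];
          for (int j = 0; j < Q_; ++j)
            hess[i * QMAX + j] -= lev_c_.Si[i * QMAX + j];
        }
      }
    }
    return G;
  }

  double cluster_loglik(int c) {
    double u[QMAX] = {0.0, 0.0, 0.0};
    if (!lev_c_.present) return outer_G(c, u, false, nullptr, nullptr);
    for (int q = 0; q < Q_; ++q)
      u[q] = uhat_[static_cast<size_t>(c) * QMAX + q];

    double grad[QMAX], hess[QMAX * QMAX];
    double gnew[QMAX], hnew[QMAX * QMAX];
    double Hm[QMAX * QMAX], L[QMAX * QMAX];
    double G = outer_G(c, u, true, grad, hess);
    for (int it = 0; it < 50; ++it) {
      for (int i = 0; i < Q_ * QMAX; ++i) Hm[i] = -hess[i];
      if (!chol_small(Q_, Hm, L)) {
        for (int q = 0; q < Q_; ++q) Hm[q * QMAX + q] += 1e-6;
        if (!chol_small(Q_, Hm, L)) break;
      }
      double step[QMAX];
      for (int q = 0; q < Q_; ++q) step[q] = grad[q];
      chol_solve(Q_, L, step);
      // the outer gradient is the envelope derivative (it drops the
      // log-determinant terms), so tiny merit decreases near the root are
      // expected: damp only while the step is macroscopic
      double unew[QMAX], Gnew;
      int halvings = 0;
      while (true) {
        for (int q = 0; q < Q_; ++q) unew[q] = u[q] + step[q];
        Gnew = outer_G(c, unew, true, gnew, hnew);
        double smax = 0.0;
        for (int q = 0; q < Q_; ++q) smax = std::max(smax, std::fabs(step[q]));
        if (smax < 1e-2 || Gnew >= G - 1e-12 || halvings >= 30) break;
        for (int q = 0; q < Q_; ++q) step[q] *= 0.5;
        ++halvings;
      }
      double mx = 0.0;
      for (int q = 0; q < Q_; ++q) mx = std::max(mx, std::fabs(step[q]));
      for (int q = 0; q < Q_; ++q) u[q] = unew[q];
      G = Gnew;
      for (int q = 0; q < Q_; ++q) grad[q] = gnew[q];
      for (int q = 0; q < Q_ * QMAX; ++q) hess[q] = hnew[q];
      if (mx < 1e-8) break;
    }
    for (int q = 0; q < Q_; ++q)
      uhat_[static_cast<size_t>(c) * QMAX + q] = u[q];

    for (int i = 0; i < Q_ * QMAX; ++i) Hm[i] = -hess[i];
    if (!chol_small(Q_, Hm, L)) {
      for (int q = 0; q < Q_; ++q) Hm[q * QMAX + q] += 1e-8;
      chol_small(Q_, Hm, L);
    }
    double logdetA = 0.0;
    for (int q = 0; q < Q_; ++q) logdetA -= std::log(L[q * QMAX + q]);
    const double sqrt2 = std::sqrt(2.0);

    double Gmax = G;
    double off[QMAX], uk[QMAX];
    for (int kk = 0; kk < K_; ++kk) {
      const double* z = &Z_[static_cast<size_t>(kk) * Q_];
      double zmax = 0.0;
      for (int q = 0; q < Q_; ++q) zmax = std::max(zmax, std::fabs(z[q]));
      if (zmax < 1e-12) { Gk_[kk] = G; continue; }  // centre node
      backsolve_t(Q_, L, z, off);
      for (int q = 0; q < Q_; ++q) uk[q] = u[q] + sqrt2 * off[q];
      Gk_[kk] = outer_G(c, uk, false, nullptr, nullptr);
      if (Gk_[kk] > Gmax) Gmax = Gk_[kk];
    }
    double s = 0.0;
    for (int kk = 0; kk < K_; ++kk)
      s += std::exp(logw_[kk] + Gk_[kk] - Gmax);
    return Gmax + std::log(s) + 0.5 * Q_ * std::log(2.0) + logdetA;
  }
};

}  // namespace

//' @noRd
// [[Rcpp::export(name = ".nested_aghq_loglik")]]
double nested_aghq_loglik(const arma::mat& eta, const arma::imat& Y,
                          const arma::ivec& hh_ptr, const arma::ivec& cl_ptr,
                          const arma::mat& Lc, const arma::mat& Lh,
                          const arma::vec& gh_x, const arma::vec& gh_w,
                          Rcpp::Nullable<Rcpp::NumericMatrix> umode =
                            R_NilValue,
                          Rcpp::Nullable<Rcpp::NumericMatrix> vmode =
                            R_NilValue) {
  if (eta.n_rows != Y.n_rows || eta.n_cols != Y.n_cols)
    Rcpp::stop("eta and Y must have matching dimensions");
  NestedLik lik(eta, Y, hh_ptr, cl_ptr, Lc, Lh, gh_x, gh_w);
  bool has_state = umode.isNotNull() && vmode.isNotNull();
  Rcpp::NumericMatrix um, vm;
  if (has_state) {
    um = umode.get();
    vm = vmode.get();
    lik.load_state(um, vm);
  }
  double ll = lik.loglik();
  if (has_state) lik.save_state(um, vm);
  return ll;
}
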