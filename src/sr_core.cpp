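// Core numerical kernels: error-constrained L1 sparse coding by lasso
// homotopy over the Gram matrix, rank-1 SVD atom updates (K-SVD), a full
// dictionary-update sweep, and the scatter-add used by patch aggregation.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Leading singular triplet of E, via the eigendecomposition of the smaller
// Gram matrix. Returns u (unit left vector), v (row = s * right vector), s.
// Sign canonicalized: first entry of u with |u_i| > 1e-10 is positive.
static void rank1_svd(const mat& E, vec& u, rowvec& v, double& s) {
  if (E.n_cols >= E.n_rows) {
    mat M = E * E.t();
    vec eval; mat evec;
    eig_sym(eval, evec, M);
    s = std::sqrt(std::max(eval(eval.n_elem - 1), 0.0));
    u = evec.col(evec.n_cols - 1);
    v = u.t() * E;
  } else {
    mat M = E.t() * E;
    vec eval; mat evec;
    eig_sym(eval, evec, M);
    s = std::sqrt(std::max(eval(eval.n_elem - 1), 0.0));
    vec v1 = evec.col(evec.n_cols - 1);
    if (s > 0) {
      u = E * v1 / s;
      double un = norm(u);
      if (un > 0) u /= un;
    } else {
      u = zeros<vec>(E.n_rows);
      u(0) = 1.0;
    }
    v = s * v1.t();
  }
  for (uword i = 0; i < u.n_elem; ++i) {
    if (std::abs(u(i)) > 1e-10) {
      if (u(i) < 0) { u = -u; v = -v; }
      break;
    }
  }
}

// [[Rcpp::export]]
Rcpp::List sr_rank1_cpp(const arma::mat& E) {
  vec u; rowvec v; double s;
  rank1_svd(E, u, v, s);
  return Rcpp::List::create(Rcpp::Named("u") = u,
                            Rcpp::Named("v") = v,
                            Rcpp::Named("s") = s);
}

// In-place Cholesky solve of the na x na SPD system for two right-hand
// sides, on stack buffers (hot path: na <= SMALL_NA). Returns false if the
// factorization breaks down.
#define SMALL_NA 16
static bool chol_solve2(double* gaa, int na, double* rhs1, double* rhs2) {
  double L[SMALL_NA * SMALL_NA];
  for (int j = 0; j < na; ++j) {
    double d = gaa[j + j * na];
    for (int t = 0; t < j; ++t) d -= L[j + t * na] * L[j + t * na];
    if (d <= 1e-13) return false;
    double lj = std::sqrt(d);
    L[j + j * na] = lj;
    for (int i = j + 1; i < na; ++i) {
      double s = gaa[i + j * na];
      for (int t = 0; t < j; ++t) s -= L[i + t * na] * L[j + t * na];
      L[i + j * na] = s / lj;
    }
  }
  for (int pass = 0; pass < 2; ++pass) {
    double* x = pass == 0 ? rhs1 : rhs2;
    for (int i = 0; i < na; ++i) {
      double s = x[i];
      for (int t = 0; t < i; ++t) s -= L[i + t * na] * x[t];
      x[i] = s / L[i + i * na];
    }
    for (int i = na - 1; i >= 0; --i) {
      double s = x[i];
      for (int t = i + 1; t < na; ++t) s -= L[t + i * na] * x[t];
      x[i] = s / L[i + i * na];
    }
  }
  return true;
}

static mat solve_small(const mat& GAA, const mat& rhs) {
  mat out;
  bool ok = solve(out, GAA, rhs, solve_opts::no_approx);
  if (!ok) {
    mat Gr = GAA + 1e-12 * trace(GAA) / GAA.n_rows * eye(GAA.n_rows, GAA.n_rows);
    out = solve(Gr, rhs);
  }
  return out;
}

// Error-constrained minimum-L1 coding of the columns of X over dictionary D:
//   min ||a||_1  s.t.  ||x - D a||_2^2 <= budget
// solved exactly by lasso homotopy in the regularization parameter lambda,
// using only the Gram matrix G = D'D and correlations b = D'x. Within an
// active segment beta(lambda) = u - lambda * v with G_AA u = b_A,
// G_AA v = s_A, and the residual obeys r2(lambda) = (yy - b_A'u) +
// lambda^2 * (s_A'v), so the budget crossing is available in closed form.
// max_nnz > 0 caps the support: once reached, no further atoms join and the
// path continues (shrinkage towards the active-set least squares solution)
// until the budget is met or the path ends; infeasibility is flagged.
// [[Rcpp::export]]
Rcpp::List sr_lasso_batch_cpp(const arma::mat& D, const arma::mat& X,
                              double budget, int max_nnz,
                              bool dense_out) {
  const uword k = D.n_cols, P = X.n_cols;
  mat G = D.t() * D;
  mat B = D.t() * X;

  std::vector<double> t_val;
  std::vector<int> t_row, t_col;
  mat Adense;
  if (dense_out) Adense.zeros(k, P);
  vec resid(P, fill::zeros);
  Rcpp::IntegerVector feas(P);

  const double zero_tol = 1e-12;

  // per-patch work buffers, allocated once
  vec Gu(k), Gv(k);
  std::vector<char> is_act_buf(k, 0);

  for (uword p = 0; p < P; ++p) {
    vec b = B.col(p);
    double yy = dot(X.col(p), X.col(p));
    double eps_abs = budget + zero_tol * std::max(1.0, yy);
    if (yy <= eps_abs) {            // zero vector already feasible
      resid(p) = std::sqrt(std::max(yy, 0.0));
      feas(p) = 1;
      continue;
    }

    std::vector<uword> act;
    std::vector<double> sgn;
    uword j0 = index_max(abs(b));
    double lam = std::abs(b(j0));
    act.push_back(j0);
    sgn.push_back(b(j0) >= 0 ? 1.0 : -1.0);
    const double tol_ev = 1e-12 * lam;

    vec beta;                        // solution on the active set
    bool feasible = false;
    double r2_final = yy;
    const int max_events = 8 * (int)k + 100;

    double ubuf[SMALL_NA], vbuf[SMALL_NA];

    for (int ev = 0; ev < max_events; ++ev) {
      uword na = act.size();
      vec u, v;
      double r0, svv;
      bool fast_done = false;
      if (na <= SMALL_NA) {
        double gaa[SMALL_NA * SMALL_NA];
        for (uword i = 0; i < na; ++i) {
          ubuf[i] = b(act[i]);
          vbuf[i] = sgn[i];
          for (uword j = 0; j <= i; ++j) {
            double g = G(act[i], act[j]);
            gaa[i + j * na] = g; gaa[j + i * na] = g;
          }
        }
        if (chol_solve2(gaa, (int)na, ubuf, vbuf)) {
          u = vec(ubuf, na); v = vec(vbuf, na);
          fast_done = true;
        }
      }
      if (!fast_done) {
        vec bA(na), sA(na);
        mat GAA(na, na);
        for (uword i = 0; i < na; ++i) {
          bA(i) = b(act[i]);
          sA(i) = sgn[i];
          for (uword j = 0; j <= i; ++j) {
            double g = G(act[i], act[j]);
            GAA(i, j) = g; GAA(j, i) = g;
          }
        }
        mat sol = solve_small(GAA, join_rows(bA, sA));
        u = sol.col(0); v = sol.col(1);
      }
      r0 = yy;
      svv = 0.0;
      for (uword i = 0; i < na; ++i) {
        r0 -= b(act[i]) * u(i);
        svv += sgn[i] * v(i);
      }

      // next path event strictly below current lambda
      double lam_next = 0.0;
      int etype = 0;                 // 0 none, 1 drop, 2 add
      uword eidx = 0;
      double easign = 1.0;
      for (uword i = 0; i < na; ++i) {
        if (std::abs(v(i)) > 0) {
          double l = u(i) / v(i);
          if (l > tol_ev && l < lam - tol_ev && l > lam_next) {
            lam_next = l; etype = 1; eidx = i;
          }
        }
      }
      bool capped = (max_nnz > 0 && (int)na >= max_nnz);
      if (!capped) {
        // c_j(lambda) = m_j + lambda * t_j for inactive j
        double* gu = Gu.memptr();
        double* gv = Gv.memptr();
        std::fill(gu, gu + k, 0.0);
        std::fill(gv, gv + k, 0.0);
        for (uword i = 0; i < na; ++i) {
          const double* gc = G.colptr(act[i]);
          const double ui = u(i), vi = v(i);
          for (uword j = 0; j < k; ++j) {
            gu[j] += gc[j] * ui;
            gv[j] += gc[j] * vi;
          }
        }
        for (uword i = 0; i < na; ++i) is_act_buf[act[i]] = 1;
        const double* bp = b.memptr();
        for (uword j = 0; j < k; ++j) {
          if (is_act_buf[j]) continue;
          double m = bp[j] - gu[j], t = gv[j];
          double d1 = 1.0 - t;
          if (std::abs(d1) > 1e-14) {
            double l = m / d1;
            if (l > tol_ev && l < lam - tol_ev && l > lam_next) {
              lam_next = l; etype = 2; eidx = j; easign = 1.0;
            }
          }
          double d2 = 1.0 + t;
          if (std::abs(d2) > 1e-14) {
            double l = -m / d2;
            if (l > tol_ev && l < lam - tol_ev && l > lam_next) {
              lam_next = l; etype = 2; eidx = j; easign = -1.0;
            }
          }
        }
        for (uword i = 0; i < na; ++i) is_act_buf[act[i]] = 0;
      }

      // budget crossing inside (lam_next, lam]?
      if (r0 <= eps_abs) {
        double lam_star = 0.0;
        if (svv > 0 && budget > r0)
          lam_star = std::sqrt((budget - r0) / svv);
        if (lam_star >= lam_next - 1e-15) {
          beta = u - lam_star * v;
          feasible = true;
          r2_final = r0 + lam_star * lam_star * svv;
          break;
        }
      }

      if (etype == 0) {              // path exhausted: LS on active set
        beta = u;
        r2_final = std::max(r0, 0.0);
        feasible = (r2_final <= eps_abs);
        break;
      }
      if (etype == 1) {
        act.erase(act.begin() + eidx);
        sgn.erase(sgn.begin() + eidx);
        if (act.empty()) {           // degenerate; restart from max corr
          uword jn = index_max(abs(b));
          act.push_back(jn);
          sgn.push_back(b(jn) >= 0 ? 1.0 : -1.0);
        }
      } else {
        act.push_back(eidx);
        sgn.push_back(easign);
      }
      lam = lam_next;
      if (ev == max_events - 1) {    // safety: use current LS solution
        uword na2 = act.size();
        vec bA2(na2); mat GAA2(na2, na2);
        for (uword i = 0; i < na2; ++i) {
          bA2(i) = b(act[i]);
          for (uword j = 0; j <= i; ++j) {
            double g = G(act[i], act[j]);
            GAA2(i, j) = g; GAA2(j, i) = g;
          }
        }
        beta = solve_small(GAA2, bA2);
        r2_final = yy - dot(bA2, beta);
        feasible = (r2_final <= eps_abs);
      }
    }

    feas(p) = feasible ? 1 : 0;
    // store coefficients and recompute the exact residual norm (active
    // columns only)
    vec r = X.col(p);
    for (uword i = 0; i < act.size() && i < (uword)beta.n_elem; ++i)
      if (beta(i) != 0.0) r -= D.col(act[i]) * beta(i);
    resid(p) = norm(r);
    if (dense_out) {
      double* ac = Adense.colptr(p);
      for (uword i = 0; i < act.size() && i < (uword)beta.n_elem; ++i)
        ac[act[i]] = beta(i);
    } else {
      for (uword i = 0; i < act.size() && i < (uword)beta.n_elem; ++i) {
        if (beta(i) != 0.0) {
          t_row.push_back((int)act[i] + 1);
          t_col.push_back((int)p + 1);
          t_val.push_back(beta(i));
        }
      }
    }
  }

  if (dense_out) {
    return Rcpp::List::create(Rcpp::Named("A") = Adense,
                              Rcpp::Named("resid") = resid,
                              Rcpp::Named("feasible") = feas);
  }
  return Rcpp::List::create(Rcpp::Named("i") = t_row,
                            Rcpp::Named("j") = t_col,
                            Rcpp::Named("x") = t_val,
                            Rcpp::Named("resid") = resid,
                            Rcpp::Named("feasible") = feas);
}

// One full K-SVD dictionary-update sweep. Atoms are updated sequentially in
// ascending index order by the rank-1 SVD of the restricted residual. The
// representation error ||X - D A||_F^2 is recorded AFTER the sweep and
// BEFORE dictionary maintenance (replacement of unused atoms and of atoms
// nearly duplicating another atom by the worst-represented patches).
// [[Rcpp::export]]
Rcpp::List sr_ksvd_sweep_cpp(arma::mat D, arma::mat A, const arma::mat& X,
                             double dedup_thresh, bool maintain) {
  const uword k = D.n_cols;
  const uword P = A.n_cols;
  mat R = X - D * A;

  // usage lists from one cache-friendly pass over A's columns; the support
  // pattern is unchanged by the value updates below
  std::vector<std::vector<uword>> using_p(k);
  for (uword p = 0; p < P; ++p) {
    const double* ap = A.colptr(p);
    for (uword m = 0; m < k; ++m)
      if (ap[m] != 0.0) using_p[m].push_back(p);
  }

  for (uword m = 0; m < k; ++m) {
    if (using_p[m].empty()) continue;
    uvec use(using_p[m].size());
    for (uword t = 0; t < use.n_elem; ++t) use(t) = using_p[m][t];
    mat E = R.cols(use);
    rowvec coef(use.n_elem);
    for (uword t = 0; t < use.n_elem; ++t) coef(t) = A(m, use(t));
    E += D.col(m) * coef;
    vec u; rowvec v; double s;
    rank1_svd(E, u, v, s);
    if (!(s > 0)) continue;
    D.col(m) = u;
    R.cols(use) = E - u * v;
    for (uword t = 0; t < use.n_elem; ++t) A(m, use(t)) = v(t);
  }

  double err = accu(square(R));

  int replaced = 0;
  if (maintain) {
    rowvec rn = sum(square(R), 0);
    mat Gd = D.t() * D;
    uvec ord = sort_index(rn.t(), "descend");
    uword next = 0;
    for (uword m = 0; m < k; ++m) {
      uvec use(using_p[m].size());
      for (uword t = 0; t < use.n_elem; ++t) use(t) = using_p[m][t];
      bool dup = false;
      for (uword j = 0; j < k && !dup; ++j)
        if (j != m && std::abs(Gd(j, m)) > dedup_thresh) dup = true;
      if (use.n_elem > 0 && !dup) continue;
      if (use.n_elem > 0 && dup) {
        // return this atom's contribution to the residual, zero its codes
        rowvec coef(use.n_elem);
        for (uword t = 0; t < use.n_elem; ++t) coef(t) = A(m, use(t));
        R.cols(use) += D.col(m) * coef;
        for (uword t = 0; t < use.n_elem; ++t) A(m, use(t)) = 0.0;
      }
      while (next < ord.n_elem && norm(X.col(ord(next))) < 1e-12) ++next;
      if (next >= ord.n_elem) break;
      vec pcol = X.col(ord(next)); ++next;
      pcol /= norm(pcol);
      for (uword i = 0; i < pcol.n_elem; ++i) {
        if (std::abs(pcol(i)) > 1e-10) {
          if (pcol(i) < 0) pcol = -pcol;
          break;
        }
      }
      D.col(m) = pcol;
      vec g = D.t() * pcol;
      Gd.col(m) = g;
      Gd.row(m) = g.t();
      Gd(m, m) = 1.0;
      ++replaced;
    }
  }

  return Rcpp::List::create(Rcpp::Named("D") = D,
                            Rcpp::Named("A") = A,
                            Rcpp::Named("err") = err,
                            Rcpp::Named("replaced") = replaced);
}

// Scatter-add of patch values back onto a pixel grid. idx is 1-based and of
// the same shape as values; returns the per-pixel accumulated sums.
// [[Rcpp::export]]
arma::vec sr_scatter_add_cpp(const arma::mat& values, const arma::umat& idx,
                             int npix) {
  vec out(npix, fill::zeros);
  for (uword j = 0; j < values.n_cols; ++j)
    for (uword i = 0; i < values.n_rows; ++i)
      out(idx(i, j) - 1) += values(i, j);
  return out;
}
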