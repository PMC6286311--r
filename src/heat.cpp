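// Explicit forward-time centered-space integrator for
//   dT/dt = D lap(T) - lambda (T - T_amb) + S(x, t)
// on a regular grid with Dirichlet (ambient) boundary. The source S is a
// precomputed stamp (deg C per s over the spot footprint) translated along a
// per-step center trajectory; steps with a negative center row are source-off.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// alpha = D dt / h^2; lambda_dt = lambda * dt; stamp holds the degC/s source
// density; centers is nsteps x 2 (0-based stamp top-left, row < 0 => off).
// [[Rcpp::export]]
Rcpp::List heat_run_cpp(const arma::mat& T0, const double ambient,
                        const double alpha, const double lambda_dt,
                        const double dt, const arma::mat& stamp,
                        const arma::imat& centers, const int snap_every,
                        const int probe_i, const int probe_j,
                        const int profile_i) {
  const int nr = T0.n_rows, nc = T0.n_cols;
  const int nsteps = centers.n_rows;
  const int sh = stamp.n_rows, sw = stamp.n_cols;
  mat T = T0, Tn = T0;

  const int nsnap = nsteps / snap_every + 1;
  cube snaps(nr, nc, nsnap);
  vec snap_t(nsnap);
  int isnap = 0;
  snaps.slice(isnap) = T; snap_t(isnap++) = 0.0;

  vec probe(nsteps + 1);
  probe(0) = T(probe_i, probe_j);
  mat profile(nsteps + 1, nc);
  profile.row(0) = T.row(profile_i);
  mat maxfield = T;

  for (int s = 0; s < nsteps; ++s) {
    // interior FTCS update (pointer loop: the scheme is memory-bound)
    for (int j = 1; j < nc - 1; ++j) {
      const double* tc = T.colptr(j);
      const double* tl = T.colptr(j - 1);
      const double* tr = T.colptr(j + 1);
      double* out = Tn.colptr(j);
      for (int i = 1; i < nr - 1; ++i) {
        const double c = tc[i];
        out[i] = c + alpha * (tc[i - 1] + tc[i + 1] + tl[i] + tr[i] - 4.0 * c)
                   - lambda_dt * (c - ambient);
      }
    }
    // source stamp
    const int ci = centers(s, 0), cj = centers(s, 1);
    if (ci >= 0) {
      const int i0 = std::max(ci, 1), j0 = std::max(cj, 1);
      const int i1 = std::min(ci + sh - 1, nr - 2), j1 = std::min(cj + sw - 1, nc - 2);
      if (i1 >= i0 && j1 >= j0)
        Tn.submat(i0, j0, i1, j1) +=
          dt * stamp.submat(i0 - ci, j0 - cj, i1 - ci, j1 - cj);
    }
    std::swap(T, Tn);
    {
      double* mf = maxfield.memptr();
      const double* tp = T.memptr();
      const uword ne = T.n_elem;
      for (uword k = 0; k < ne; ++k) if (tp[k] > mf[k]) mf[k] = tp[k];
    }
    probe(s + 1) = T(probe_i, probe_j);
    profile.row(s + 1) = T.row(profile_i);
    if ((s + 1) % snap_every == 0 && isnap < nsnap) {
      snaps.slice(isnap) = T;
      snap_t(isnap++) = (s + 1) * dt;
    }
  }
  if (isnap < nsnap) { snaps.slice(isnap) = T; snap_t(isnap++) = nsteps * dt; }
  snaps = snaps.slices(0, isnap - 1);
  return Rcpp::List::create(
    Rcpp::Named("final") = T,
    Rcpp::Named("snapshots") = snaps,
    Rcpp::Named("snapshot_t") = snap_t.subvec(0, isnap - 1),
    Rcpp::Named("probe") = probe,
    Rcpp::Named("profile") = profile,
    Rcpp::Named("maxfield") = maxfield);
}
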