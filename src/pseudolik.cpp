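#include <Rcpp.h>
using namespace Rcpp;

// Pairwise exponential-family model over genotype levels {0,1,2} per SNP:
//   P(g) ~ exp( sum_i h_i(g_i) + sum_{i<j} J_ij(g_i, g_j) )
// with the baseline level 0 carrying no parameters: h_i(0) = 0 and
// J_ij(a,b) = 0 whenever a = 0 or b = 0.  Free parameters: 2 per SNP
// (h_i(1), h_i(2)) and 4 per pair (J_ij(a,b), a,b in {1,2}).
//
// Parameter packing (0-based within the vector):
//   theta[2*i + (a-1)]                 : field h_i(a),  i = 0..m-1, a in {1,2}
//   theta[2*m + 4*p + 2*(a-1) + (b-1)] : coupling J_p(a,b) for pair p
// Pairs are given by 0-based index vectors pi < pj.
//
// Pseudo-likelihood objective (to be maximized):
//   sum_rows sum_i log P(g_i | g_{-i}) - lambda * sum_p ||J_p||_F^2
// Missing entries (NA): a missing g_i drops that row's i-th conditional; a
// missing g_j drops the (i,j) term from SNP i's conditional.

static inline bool is_obs(int g) { return g != NA_INTEGER && g >= 0; }

// Returns objective value and (optionally) gradient.
// [[Rcpp::export]]
List plik_value_grad(NumericVector theta, IntegerMatrix X,
                     IntegerVector pi, IntegerVector pj,
                     double lambda, bool want_grad) {
  const int n = X.nrow(), m = X.ncol(), P = pi.size();
  const double *th = theta.begin();
  const double *J = th + 2 * m;
  NumericVector grad(want_grad ? theta.size() : 0);
  double *gf = want_grad ? grad.begin() : nullptr;
  double *gJ = want_grad ? gf + 2 * m : nullptr;

  std::vector<double> z1(m), z2(m), p1(m), p2(m);
  std::vector<int> g(m);
  double obj = 0.0;

  for (int r = 0; r < n; ++r) {
    for (int i = 0; i < m; ++i) {
      g[i] = X(r, i);
      z1[i] = th[2 * i];
      z2[i] = th[2 * i + 1];
    }
    // accumulate coupling contributions to each conditional's logits
    for (int p = 0; p < P; ++p) {
      const int i = pi[p], j = pj[p];
      const int a = g[i], b = g[j];
      const double *Jp = J + 4 * p; // order: (1,1),(1,2),(2,1),(2,2)
      if (is_obs(b) && b > 0) {     // conditional of i given g_j = b
        z1[i] += Jp[b - 1];         // J(1,b)
        z2[i] += Jp[2 + (b - 1)];   // J(2,b)
      }
      if (is_obs(a) && a > 0) {     // conditional of j given g_i = a
        z1[j] += Jp[2 * (a - 1)];     // J(a,1)
        z2[j] += Jp[2 * (a - 1) + 1]; // J(a,2)
      }
    }
    for (int i = 0; i < m; ++i) {
      if (!is_obs(g[i])) { p1[i] = p2[i] = 0.0; continue; }
      // log-sum-exp over states {0,1,2} with z0 = 0
      double zm = 0.0;
      if (z1[i] > zm) zm = z1[i];
      if (z2[i] > zm) zm = z2[i];
      const double e0 = std::exp(-zm), e1 = std::exp(z1[i] - zm),
                   e2 = std::exp(z2[i] - zm);
      const double Z = e0 + e1 + e2;
      const double zi = (g[i] == 0) ? 0.0 : (g[i] == 1 ? z1[i] : z2[i]);
      obj += zi - (zm + std::log(Z));
      p1[i] = e1 / Z;
      p2[i] = e2 / Z;
      if (want_grad) {
        gf[2 * i] += (g[i] == 1 ? 1.0 : 0.0) - p1[i];
        gf[2 * i + 1] += (g[i] == 2 ? 1.0 : 0.0) - p2[i];
      }
    }
    if (want_grad) {
      for (int p = 0; p < P; ++p) {
        const int i = pi[p], j = pj[p];
        const int a = g[i], b = g[j];
        double *Gp = gJ + 4 * p;
        if (is_obs(a) && is_obs(b)) {
          if (b > 0) { // d/dJ(a',b) of i's conditional
            Gp[(b - 1)] += (a == 1 ? 1.0 : 0.0) - p1[i];
            Gp[2 + (b - 1)] += (a == 2 ? 1.0 : 0.0) - p2[i];
          }
          if (a > 0) { // d/dJ(a,b') of j's conditional
            Gp[2 * (a - 1)] += (b == 1 ? 1.0 : 0.0) - p1[j];
            Gp[2 * (a - 1) + 1] += (b == 2 ? 1.0 : 0.0) - p2[j];
          }
        }
      }
    }
  }

  double pen = 0.0;
  for (int p = 0; p < 4 * P; ++p) pen += J[p] * J[p];
  obj -= lambda * pen;
  if (want_grad)
    for (int p = 0; p < 4 * P; ++p) gJ[p] -= 2.0 * lambda * J[p];

  if (want_grad) return List::create(_["value"] = obj, _["grad"] = grad);
  return List::create(_["value"] = obj);
}

// Gibbs sampler for the same model: one independent chain per individual,
// systematic scan over SNPs, `sweeps` burn-in sweeps, final state returned.
// U is a pre-drawn n x (sweeps*m) matrix of uniforms so that sampling is
// driven entirely by R's RNG (seed reproducibility, bit-identical).
// [[Rcpp::export]]
IntegerMatrix gibbs_sample_cpp(int n, int m, NumericVector theta,
                               IntegerVector pi, IntegerVector pj,
                               IntegerMatrix init, NumericMatrix U,
                               int sweeps) {
  const int P = pi.size();
  const double *th = theta.begin();
  const double *J = th + 2 * m;
  IntegerMatrix G = clone(init);
  // adjacency: for each SNP, list of (pair index, role) with role 0 if SNP is
  // the first member of the pair
  std::vector<std::vector<std::pair<int, int> > > adj(m);
  for (int p = 0; p < P; ++p) {
    adj[pi[p]].push_back(std::make_pair(p, 0));
    adj[pj[p]].push_back(std::make_pair(p, 1));
  }
  for (int s = 0; s < sweeps; ++s) {
    for (int i = 0; i < m; ++i) {
      const int ucol = s * m + i;
      for (int r = 0; r < n; ++r) {
        double z1 = th[2 * i], z2 = th[2 * i + 1];
        for (size_t k = 0; k < adj[i].size(); ++k) {
          const int p = adj[i][k].first;
          const int other = adj[i][k].second == 0 ? pj[p] : pi[p];
          const int b = G(r, other);
          if (b == 0) continue;
          const double *Jp = J + 4 * p;
          if (adj[i][k].second == 0) { // J(a, b)
            z1 += Jp[(b - 1)];
            z2 += Jp[2 + (b - 1)];
          } else {                     // J(b, a)
            z1 += Jp[2 * (b - 1)];
            z2 += Jp[2 * (b - 1) + 1];
          }
        }
        double zm = 0.0;
        if (z1 > zm) zm = z1;
        if (z2 > zm) zm = z2;
        const double e0 = std::exp(-zm), e1 = std::exp(z1 - zm),
                     e2 = std::exp(z2 - zm);
        const double Z = e0 + e1 + e2;
        const double u = U(r, ucol) * Z;
        G(r, i) = (u < e0) ? 0 : (u < e0 + e1 ? 1 : 2);
      }
    }
  }
  return G;
}
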