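#include <Rcpp.h>
using namespace Rcpp;

// Collapsed Gibbs sampler for microbial source tracking.
//
// Each read of the sink sample carries a latent source assignment
// z in {1..V known sources, V+1 = Unknown}. Known-source taxon
// distributions are fixed from the rarefied source table with
// pseudo-count alpha1; the Unknown source's distribution is estimated
// from its currently assigned reads with pseudo-count alpha2. The
// mixing proportions have a flat Dirichlet(tau) prior.
//
// sink: taxon index (0-based) of each read, length N
// source_counts: V x T matrix of rarefied known-source counts
// Returns a draws x (V+1) matrix of mixing-proportion samples.
// [[Rcpp::export]]
NumericMatrix gibbs_sourcetrack(IntegerVector sink, IntegerMatrix source_counts,
                                double alpha1, double alpha2, double tau,
                                int restarts, int burn_in, int draws,
                                int thinning) {
  const int N = sink.size();
  const int V = source_counts.nrow();
  const int T = source_counts.ncol();
  const int S = V + 1;

  // fixed known-source log-free probabilities phi_v(t)
  NumericMatrix phi(V, T);
  for (int v = 0; v < V; ++v) {
    double tot = 0.0;
    for (int t = 0; t < T; ++t) tot += source_counts(v, t);
    for (int t = 0; t < T; ++t)
      phi(v, t) = (source_counts(v, t) + alpha1) / (tot + alpha1 * T);
  }

  NumericMatrix out(restarts * draws, S);
  std::vector<int> z(N);
  std::vector<double> n_v(S);
  std::vector<double> c_unk(T);
  std::vector<double> prob(S);

  int row = 0;
  for (int r = 0; r < restarts; ++r) {
    // random initial assignments
    std::fill(n_v.begin(), n_v.end(), 0.0);
    std::fill(c_unk.begin(), c_unk.end(), 0.0);
    for (int i = 0; i < N; ++i) {
      int zi = (int)(unif_rand() * S);
      if (zi >= S) zi = S - 1;
      z[i] = zi;
      n_v[zi] += 1.0;
      if (zi == V) c_unk[sink[i]] += 1.0;
    }
    double c_unk_tot = n_v[V];

    const int sweeps = burn_in + draws * thinning;
    for (int sweep = 0; sweep < sweeps; ++sweep) {
      for (int i = 0; i < N; ++i) {
        const int t = sink[i];
        const int zi = z[i];
        n_v[zi] -= 1.0;
        if (zi == V) { c_unk[t] -= 1.0; c_unk_tot -= 1.0; }

        double tot = 0.0;
        for (int v = 0; v < V; ++v) {
          prob[v] = phi(v, t) * (n_v[v] + tau);
          tot += prob[v];
        }
        prob[V] = (c_unk[t] + alpha2) / (c_unk_tot + alpha2 * T) *
                  (n_v[V] + tau);
        tot += prob[V];

        double u = unif_rand() * tot;
        int znew = 0;
        double acc = prob[0];
        while (u > acc && znew < S - 1) { ++znew; acc += prob[znew]; }

        z[i] = znew;
        n_v[znew] += 1.0;
        if (znew == V) { c_unk[t] += 1.0; c_unk_tot += 1.0; }
      }
      if (sweep >= burn_in && (sweep - burn_in + 1) % thinning == 0) {
        for (int v = 0; v < S; ++v) out(row, v) = n_v[v] / N;
        ++row;
      }
    }
  }
  return out;
}
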