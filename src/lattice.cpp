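#include <Rcpp.h>
using namespace Rcpp;

// Metropolis dynamics for the 2D Ising lattice with periodic boundaries.
// One sweep = L*L single-site update attempts at uniformly random sites.
// Uses R's RNG (unif_rand) so results are reproducible via set.seed().

static inline int rand_index(int L) {
  int i = (int)(unif_rand() * L);
  return i == L ? L - 1 : i;  // guard against unif_rand() returning 1.0
}

// [[Rcpp::export]]
List cpp_simulate_lattice(IntegerMatrix spins0,
                          NumericVector T_sweep,
                          NumericVector H_sweep,
                          int record_every,
                          int track_i,
                          int track_j) {
  IntegerMatrix spins = clone(spins0);
  const int L = spins.nrow();
  const int n_sweeps = T_sweep.size();
  const int n_rec = n_sweeps / record_every;
  const bool track = track_i >= 1 && track_j >= 1;

  NumericVector mag(n_rec);
  IntegerVector site(track ? n_rec : 0);

  long msum = 0;
  for (int i = 0; i < L; ++i)
    for (int j = 0; j < L; ++j) msum += spins(i, j);

  for (int s = 0; s < n_sweeps; ++s) {
    const double T = T_sweep[s], H = H_sweep[s];
    for (int a = 0; a < L * L; ++a) {
      const int i = rand_index(L);
      const int j = rand_index(L);
      const int S = spins(i, j);
      const int NB = spins((i + 1) % L, j) + spins((i + L - 1) % L, j) +
                     spins(i, (j + 1) % L) + spins(i, (j + L - 1) % L);
      const double Ediff = 2.0 * S * (NB - H);
      // Ediff <= 0 accepted without consuming a random number
      const bool flip = (Ediff <= 0.0) || (unif_rand() < std::exp(-Ediff / T));
      if (flip) {
        spins(i, j) = -S;
        msum -= 2 * S;
      }
    }
    if ((s + 1) % record_every == 0) {
      const int k = (s + 1) / record_every - 1;
      mag[k] = (double)msum / (double)(L * L);
      if (track) site[k] = spins(track_i - 1, track_j - 1);
    }
  }

  return List::create(_["magnetization"] = mag,
                      _["site_spin"] = site,
                      _["spins"] = spins);
}
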