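#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <cmath>
using namespace Rcpp;

// -------------------------------------------------------------------------
// Deterministic, platform-independent RNG (xoshiro256++, seeded by splitmix64)
// used for the per-step membrane voltage noise. Seeded from a double-precision
// integer passed from R so trials are reproducible in isolation.
// -------------------------------------------------------------------------
namespace {

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    // splitmix64 expansion of the seed
    uint64_t z = seed;
    for (int i = 0; i < 4; ++i) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      s[i] = t ^ (t >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t;    s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {  // uniform in [0, 1)
    return (next() >> 11) * 0x1.0p-53;
  }
};

// One receptor update step. The transmitter signal [T] is piecewise constant
// (1 during a pulse, 0 otherwise) and pulses are aligned with the step grid,
// so the linear kinetics dr/dt = alpha*[T]*(1-r) - beta*r integrate exactly:
//   pulse:   r <- rinf + (r - rinf) * exp(-(alpha+beta)*dt),  rinf = a/(a+b)
//   decay:   r <- r * exp(-beta*dt)
inline double receptor_step(double r, bool pulse, double edec, double epul,
                            double rinf) {
  if (pulse) return rinf + (r - rinf) * epul;
  return r * edec;
}

}  // namespace

// [[Rcpp::export(name = ".receptor_trace_cpp")]]
NumericVector receptor_trace_cpp(IntegerVector pulse_start_steps, int n_steps,
                                 double dt_ms, double alpha, double beta,
                                 double tau_ms) {
  int pulse_steps = std::max(1, (int) std::lround(tau_ms / dt_ms));
  double edec = std::exp(-beta * dt_ms);
  double epul = std::exp(-(alpha + beta) * dt_ms);
  double rinf = alpha / (alpha + beta);
  NumericVector out(n_steps);
  double r = 0.0;
  int remain = 0;
  std::vector<char> is_start(n_steps, 0);
  for (int k = 0; k < pulse_start_steps.size(); ++k) {
    int s = pulse_start_steps[k];
    if (s >= 0 && s < n_steps) is_start[s] = 1;
  }
  for (int t = 0; t < n_steps; ++t) {
    if (is_start[t]) remain = pulse_steps;
    r = receptor_step(r, remain > 0, edec, epul, rinf);
    if (remain > 0) --remain;
    out[t] = r;
  }
  return out;
}

// -------------------------------------------------------------------------
// Full network trial.
//
// The lateral weight matrix is never materialized. With neuron i at pixel
// p(i) and channel c(i),
//   W[i,j] = Slat * (Sd * Wd[p(i),p(j)] + Sa * Wa[c(i),c(j)])   (i != j)
// so the lateral conductance sum over presynaptic receptor fractions r_j is
//   g_i = Slat*Sd*L[p(i)] + Slat*Sa*(Wa %*% cs)[c(i)] - Wself*r_i
// with  L = Wd %*% spix,  spix[p] = sum of r_j over neurons at pixel p,
//       cs[c] = sum of r_j over neurons in channel c,
//       Wself = Slat*(Sd + Sa)   (removes the zero-diagonal term).
// Outside transmitter pulses every r_j decays by the same factor, so spix,
// cs and L are maintained incrementally with sparse corrections from the
// (few) neurons currently inside a pulse; the cached sums are recomputed
// from scratch periodically to eliminate rounding drift.
// -------------------------------------------------------------------------

// [[Rcpp::export(name = ".run_trial_cpp")]]
List run_trial_cpp(LogicalMatrix ext_spikes,      // N x total bins (0.5 ms)
                   NumericMatrix Wd,              // P x P distance weights
                   NumericMatrix Wa,              // K x K angle weights
                   IntegerVector pix_of,          // N, 0-based pixel index
                   IntegerVector ch_of,           // N, 0-based channel index
                   double Sd, double Sa, double Slat, double Sext,
                   double a, double b, double c_reset, double d_inc,
                   double v_thresh, double S_eps, double E_rev,
                   double alpha, double beta, double tau_ms,
                   double dt_ms, double transient_ms, double duration_ms,
                   double bin_ms, double runaway_rate_hz, double seed) {
  const int N = ext_spikes.nrow();
  const int P = Wd.nrow();
  const int K = Wa.nrow();
  const int steps_per_bin = (int) std::lround(bin_ms / dt_ms);
  const int total_bins = (int) std::lround((transient_ms + duration_ms) / bin_ms);
  const int transient_bins = (int) std::lround(transient_ms / bin_ms);
  const int analysis_bins = total_bins - transient_bins;
  const int total_steps = total_bins * steps_per_bin;
  const int pulse_steps = std::max(1, (int) std::lround(tau_ms / dt_ms));

  if (ext_spikes.ncol() < total_bins)
    stop("external input covers %d bins but %d are required",
         ext_spikes.ncol(), total_bins);

  const double edec = std::exp(-beta * dt_ms);
  const double epul = std::exp(-(alpha + beta) * dt_ms);
  const double rinf = alpha / (alpha + beta);
  const double Wself = Slat * (Sd + Sa);

  Xoshiro rng((uint64_t) seed);

  std::vector<double> v(N, -65.0), u(N), rl(N, 0.0), re(N, 0.0);
  for (int i = 0; i < N; ++i) u[i] = b * v[i];
  std::vector<int> pl(N, 0), pe(N, 0);          // pulse steps remaining
  std::vector<int> lat_active, ext_active;      // indices with pulses running
  lat_active.reserve(256); ext_active.reserve(256);

  std::vector<double> spix(P, 0.0), L(P, 0.0), cs(K, 0.0), wacs(K, 0.0);

  LogicalMatrix out(N, analysis_bins);

  const double* wd = REAL(Wd);  // column-major P x P, symmetric
  const int* pix = INTEGER(pix_of);
  const int* ch = INTEGER(ch_of);
  const int* extsp = LOGICAL(ext_spikes);
  int* outp = LOGICAL(out);
  for (int step = 0; step < total_steps; ++step) {
    const int bin = step / steps_per_bin;
    // external Poisson spikes trigger transmitter pulses at the bin start
    if (step % steps_per_bin == 0) {
      const int* colb = extsp + (size_t) bin * N;
      for (int i = 0; i < N; ++i) {
        if (colb[i]) {
          if (pe[i] == 0) ext_active.push_back(i);
          pe[i] = pulse_steps;
        }
      }
    }

    for (int c = 0; c < K; ++c) {
      double acc = 0.0;
      for (int c2 = 0; c2 < K; ++c2) acc += Wa(c, c2) * cs[c2];
      wacs[c] = acc;
    }

    // membrane update (forward Euler) and spike detection
    double* vv = v.data();
    double* uu = u.data();
    const double* rlp = rl.data();
    const double* rep = re.data();
    for (int i = 0; i < N; ++i) {
      const double vi = vv[i];
      const double g_lat =
          Slat * (Sd * L[pix[i]] + Sa * wacs[ch[i]]) - Wself * rlp[i];
      const double I = (vi - E_rev) * (g_lat + rep[i] * Sext);
      const double eps = (rng.unif() - 0.5) * S_eps;
      const double vnew =
          vi + dt_ms * (0.04 * vi * vi + 5.0 * vi + 140.0 - uu[i] - I + eps);
      uu[i] += dt_ms * a * (b * vi - uu[i]);
      if (!(vnew > -1e6 && vnew < 1e6))
        stop("integration diverged at step %d (t = %.3f ms), neuron %d",
             step, step * dt_ms, i + 1);
      if (vnew >= v_thresh) {
        vv[i] = c_reset;
        uu[i] += d_inc;
        if (bin >= transient_bins)
          outp[(size_t) (bin - transient_bins) * N + i] = 1;
        if (pl[i] == 0) lat_active.push_back(i);
        pl[i] = pulse_steps;  // transmitter pulse restarts at the spike
      } else {
        vv[i] = vnew;
      }
    }

    // receptor kinetics: exact exponential update.
    // Pulsing neurons first (corrections against the common decay factor).
    size_t na = lat_active.size();
    for (size_t k = 0; k < na; ) {
      const int j = lat_active[k];
      const double rold = rl[j];
      const double rnew = receptor_step(rold, true, edec, epul, rinf);
      const double delta = rnew - rold * edec;  // surplus over plain decay
      rl[j] = rnew / edec;  // pre-compensate for the global decay below
      const int pj = pix_of[j];
      spix[pj] += delta / edec;
      cs[ch_of[j]] += delta / edec;
      const double* col = wd + (size_t) pj * P;
      const double dd = delta / edec;
      for (int p = 0; p < P; ++p) L[p] += dd * col[p];
      if (--pl[j] == 0) {
        lat_active[k] = lat_active.back();
        lat_active.pop_back();
        --na;
      } else {
        ++k;
      }
    }
    // flush-to-zero at 1e-30: exponential decay would otherwise park most
    // receptor fractions in the subnormal range (orders of magnitude slower
    // multiplies); physically 1e-30 is indistinguishable from silence
    for (int i = 0; i < N; ++i) {
      const double t = rl[i] * edec;
      rl[i] = (t < 1e-30) ? 0.0 : t;
    }
    for (int p = 0; p < P; ++p) {
      const double t1 = spix[p] * edec, t2 = L[p] * edec;
      spix[p] = (t1 < 1e-30) ? 0.0 : t1;
      L[p] = (t2 < 1e-30) ? 0.0 : t2;
    }
    for (int c = 0; c < K; ++c) {
      const double t = cs[c] * edec;
      cs[c] = (t < 1e-30) ? 0.0 : t;
    }

    na = ext_active.size();
    for (size_t k = 0; k < na; ) {
      const int j = ext_active[k];
      re[j] = receptor_step(re[j], true, edec, epul, rinf) / edec;
      if (--pe[j] == 0) {
        ext_active[k] = ext_active.back();
        ext_active.pop_back();
        --na;
      } else {
        ++k;
      }
    }
    for (int i = 0; i < N; ++i) {
      const double t = re[i] * edec;
      re[i] = (t < 1e-30) ? 0.0 : t;
    }

    // periodic exact recompute of the cached sums (rounding-drift control)
    if ((step + 1) % 20000 == 0) {
      std::fill(spix.begin(), spix.end(), 0.0);
      std::fill(cs.begin(), cs.end(), 0.0);
      for (int i = 0; i < N; ++i) {
        spix[pix_of[i]] += rl[i];
        cs[ch_of[i]] += rl[i];
      }
      for (int p = 0; p < P; ++p) {
        double acc = 0.0;
        const double* col = wd + (size_t) p * P;
        for (int q = 0; q < P; ++q) acc += col[q] * spix[q];
        L[p] = acc;
      }
    }
  }

  // per-neuron firing rates over the analysis window (transient excluded)
  NumericVector rates(N);
  long analysed = 0;
  for (int i = 0; i < N; ++i) {
    int ci = 0;
    for (int t = 0; t < analysis_bins; ++t) if (out(i, t)) ++ci;
    rates[i] = 1000.0 * ci / duration_ms;
    analysed += ci;
  }
  const double mean_rate = 1000.0 * analysed / (duration_ms * N);
  const bool runaway = mean_rate > runaway_rate_hz;

  return List::create(_["spikes"] = out, _["rates"] = rates,
                      _["mean_rate_hz"] = mean_rate, _["runaway"] = runaway);
}
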