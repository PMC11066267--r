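#include <Rcpp.h>
using namespace Rcpp;

// Advance the electrical state of the whole population by `n_steps` steps of
// params$dt (1 ms). Structural state is frozen during a chunk; the R side
// calls this between plasticity updates and stimulus-window boundaries so
// that `stim` is constant over the chunk.
//
// Conventions:
//  * v, u, ca, fired are mutated in place (the caller owns fresh copies).
//  * `fired` on entry holds the spikes of the step *before* the chunk;
//    spikes at step t drive synaptic input at t + 1 (one-step delay).
//  * csr_* encode the synapse table grouped by source neuron, 0-based.
//  * `bins` is an n x nbins spike-count matrix indexed by the global
//    0-based step (step0) divided by bin_steps; mutated in place.
//  * Background draws use R's RNG so that a run is reproducible from
//    set.seed() across the R/C++ boundary, one N(mu, sigma) draw per
//    neuron per step in neuron order (dead neurons included, so the
//    stream layout does not depend on lesions).
//
// Returns the recorded raster for neurons with record = TRUE as a list of
// two integer vectors (step, id), steps 1-based.
// [[Rcpp::export]]
List step_chunk_cpp(NumericVector v, NumericVector u, NumericVector ca,
                    LogicalVector fired,
                    IntegerVector csr_ptr, IntegerVector csr_tgt,
                    NumericVector csr_w,
                    NumericVector stim, LogicalVector alive,
                    IntegerMatrix bins,
                    int step0, int n_steps, int bin_steps,
                    LogicalVector record,
                    double a, double b, double c, double d,
                    double k0, double k1, double k2,
                    double mu_bg, double sigma_bg, double k_cond,
                    double tau_ca, double beta_ca)
{
    const int n = v.size();
    std::vector<double> isyn(n);
    std::vector<int> spk_step, spk_id;
    bool any_record = false;
    for (int j = 0; j < n; ++j) if (record[j]) { any_record = true; break; }

    RNGScope rng;

    for (int s = 0; s < n_steps; ++s) {
        const int global = step0 + s;          // 0-based
        const int bin = global / bin_steps;

        std::fill(isyn.begin(), isyn.end(), 0.0);
        for (int i = 0; i < n; ++i) {
            if (!fired[i]) continue;
            for (int e = csr_ptr[i]; e < csr_ptr[i + 1]; ++e)
                isyn[csr_tgt[e]] += k_cond * csr_w[e];
        }

        for (int j = 0; j < n; ++j) {
            const double bg = R::rnorm(mu_bg, sigma_bg);
            if (!alive[j]) { fired[j] = FALSE; continue; }
            const double I = isyn[j] + bg + stim[j];
            double vj = v[j], uj = u[j];
            vj += 0.5 * (k2 * vj * vj + k1 * vj + k0 - uj + I);
            vj += 0.5 * (k2 * vj * vj + k1 * vj + k0 - uj + I);
            uj += a * (b * vj - uj);
            bool f = false;
            if (vj >= 30.0) { f = true; vj = c; uj += d; }
            v[j] = vj; u[j] = uj;
            ca[j] += -ca[j] / tau_ca + (f ? beta_ca : 0.0);
            fired[j] = f;
            if (f) {
                bins(j, bin) += 1;
                if (any_record && record[j]) {
                    spk_step.push_back(global + 1);
                    spk_id.push_back(j + 1);
                }
            }
        }
    }

    return List::create(_["step"] = wrap(spk_step), _["id"] = wrap(spk_id));
}
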