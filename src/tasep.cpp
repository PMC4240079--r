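#include <Rcpp.h>
#include <deque>
using namespace Rcpp;

// Continuous-time (Gillespie) TASEP with extended particles.
//
// State: P-site codon index (0-based) of every ribosome on the mRNA,
// ordered 5'->3'. A ribosome whose P-site is at codon j occupies codons
// [j, j+ell-1]; it hops j -> j+1 at rate 1/dwell[j] (divided by
// pause_factor while paused) provided the ribosome ahead has P-site
// > j+ell. Initiation places a P-site at codon 0 at rate init_rate when
// codons [0, ell-1] are free. A ribosome decoding the last codon
// terminates at its hop rate. Pausing is redrawn at every decoding step
// with probability pause_prob.
//
// RC is accumulated as time-integrated P-site occupancy after burn_in.
// Optional snapshot mode additionally counts P-site positions at
// `snapshots` evenly spaced times in (burn_in, horizon].
//
// Uses R's RNG so set.seed() in R controls reproducibility.

// [[Rcpp::export]]
List tasep_gene_cpp(NumericVector dwell,
                    double init_rate,
                    int ell,
                    double pause_prob,
                    double pause_factor,
                    double horizon,
                    double burn_in,
                    int snapshots) {
    const int J = dwell.size();
    NumericVector occ(J);
    IntegerVector snap(J);

    std::deque<int> pos;      // P-site positions, front = most downstream
    std::deque<double> rate;  // current hop rate of each ribosome

    long completions = 0;
    double t = 0.0;
    double snap_dt = snapshots > 0 ? (horizon - burn_in) / snapshots : 0.0;
    double next_snap = snapshots > 0 ? burn_in + snap_dt : R_PosInf;
    int snaps_done = 0;

    std::vector<double> rates;
    while (t < horizon) {
        const size_t n = pos.size();
        rates.assign(n + 1, 0.0);
        double total = 0.0;
        for (size_t i = 0; i < n; ++i) {
            bool free_ahead = (i == 0) || (pos[i - 1] - pos[i] > ell);
            if (free_ahead) rates[i] = rate[i];
            total += rates[i];
        }
        bool can_init = (n == 0) || (pos.back() >= ell);
        if (can_init) {
            rates[n] = init_rate;
            total += init_rate;
        }
        if (total <= 0.0) break;  // empty lattice, no initiation

        double dt = R::exp_rand() / total;
        double t_new = std::min(t + dt, horizon);

        // time-integrated occupancy after burn_in
        double w = t_new - std::max(t, burn_in);
        if (w > 0.0)
            for (size_t i = 0; i < n; ++i) occ[pos[i]] += w;

        // snapshots falling inside (t, t_new]
        while (snaps_done < snapshots && next_snap <= t_new) {
            for (size_t i = 0; i < n; ++i) snap[pos[i]] += 1;
            ++snaps_done;
            next_snap += snap_dt;
        }

        if (t + dt >= horizon) break;
        t += dt;

        // choose event
        double u = R::unif_rand() * total;
        size_t k = 0;
        double acc = rates[0];
        while (u > acc && k < n) { ++k; acc += rates[k]; }

        if (k == n) {
            // initiation at codon 0
            pos.push_back(0);
            double r = 1.0 / dwell[0];
            if (pause_prob > 0.0 && R::unif_rand() < pause_prob)
                r /= pause_factor;
            rate.push_back(r);
        } else if (pos[k] == J - 1) {
            // termination
            pos.erase(pos.begin() + k);
            rate.erase(rate.begin() + k);
            ++completions;
        } else {
            int j = ++pos[k];
            double r = 1.0 / dwell[j];
            if (pause_prob > 0.0 && R::unif_rand() < pause_prob)
                r /= pause_factor;
            rate[k] = r;
        }
    }

    return List::create(_["occupancy"] = occ,
                        _["snapshot"] = snap,
                        _["completions"] = (double) completions);
}
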