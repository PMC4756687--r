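#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Mirror (symmetric, edge-repeating) index, total for any integer shift.
static inline int mir(int i, int n) {
    int p = ((i % (2 * n)) + 2 * n) % (2 * n);
    return (p < n) ? p : (2 * n - 1 - p);
}

// One SRF layer: sample stochastic edges from `state`, compute normalized
// smoothness weights, and take a single synchronous gradient step on the
// total energy  sum (t - obs)^2 + lambda * sum_edges w (t_i - t_j)^2.
//
// This mirrors the pure-R engine (sample_edges -> compute_weights ->
// gradient_step) operation for operation, consuming random numbers in the
// identical order: for each offset (rows of `offsets`, in order), one
// uniform draw per site in column-major order, drawn whether or not the
// partner site lies inside the image.
//
// Returns the updated state plus the total energy before and after the
// step (both evaluated with the sampled weights and `obs` as observation).
// [[Rcpp::export(name = ".srf_layer_cpp")]]
List srf_layer_cpp(NumericMatrix state, NumericMatrix obs,
                   IntegerMatrix offsets, int region,
                   double q, double sigma, double lambda, double step) {
    const int h = state.nrow(), w = state.ncol();
    const int M = h * w;
    const int K = offsets.nrow();
    const int r2 = (region - 1) / 2;
    const double inv_patch = 1.0 / (double)(region * region);

    const double *S = state.begin();
    const double *O = obs.begin();

    // Per-offset raw weights (0 where no edge); column-major within offset.
    std::vector< std::vector<double> > W((size_t)K);

    const int he = h + 2 * r2, we = w + 2 * r2;
    std::vector<double> Dsq((size_t)he * we);
    std::vector<double> V((size_t)h * we);
    std::vector<double> dmap((size_t)M);

    RNGScope scope;

    for (int k = 0; k < K; ++k) {
        const int dr = offsets(k, 0), dc = offsets(k, 1);
        W[(size_t)k].assign((size_t)M, 0.0);
        double *Wk = W[(size_t)k].data();

        // Squared differences on the extended (mirror-padded) grid.
        for (int xe = 0; xe < we; ++xe) {
            const int x = xe - r2;
            const int mx = mir(x, w), mxd = mir(x + dc, w);
            for (int ye = 0; ye < he; ++ye) {
                const int y = ye - r2;
                const double d = S[mir(y, h) + (size_t)h * mx]
                               - S[mir(y + dr, h) + (size_t)h * mxd];
                Dsq[(size_t)ye + (size_t)he * xe] = d * d;
            }
        }
        // Vertical then horizontal box sums over the region window.
        for (int xe = 0; xe < we; ++xe) {
            for (int y = 0; y < h; ++y) {
                double acc = 0.0;
                for (int pr = 0; pr < region; ++pr)
                    acc += Dsq[(size_t)(y + pr) + (size_t)he * xe];
                V[(size_t)y + (size_t)h * xe] = acc;
            }
        }
        for (int c = 0; c < w; ++c) {
            for (int r = 0; r < h; ++r) {
                double acc = 0.0;
                for (int pc = 0; pc < region; ++pc)
                    acc += V[(size_t)r + (size_t)h * (c + pc)];
                dmap[(size_t)r + (size_t)h * c] = std::sqrt(acc) * inv_patch;
            }
        }
        // Edge sampling and raw weights; one uniform per site, always drawn.
        for (int c = 0; c < w; ++c) {
            const bool cok = (c + dc >= 0) && (c + dc < w);
            for (int r = 0; r < h; ++r) {
                const double u = unif_rand();
                if (!cok || r + dr < 0 || r + dr >= h) continue;
                const double d = dmap[(size_t)r + (size_t)h * c];
                if (u < std::exp(-d / q))
                    Wk[(size_t)r + (size_t)h * c] = std::exp(-(d * d) / (sigma * sigma));
            }
        }
    }

    // Incident raw-degree sums: i-endpoint contributions for all offsets,
    // then j-endpoint contributions (same order as the R engine).
    std::vector<double> Z((size_t)M, 0.0);
    for (int k = 0; k < K; ++k) {
        const double *Wk = W[(size_t)k].data();
        for (int s = 0; s < M; ++s) Z[(size_t)s] += Wk[(size_t)s];
    }
    for (int k = 0; k < K; ++k) {
        const int dr = offsets(k, 0), dc = offsets(k, 1);
        const double *Wk = W[(size_t)k].data();
        for (int c = 0; c < w; ++c) {
            if (c + dc < 0 || c + dc >= w) continue;
            for (int r = 0; r < h; ++r) {
                if (r + dr < 0 || r + dr >= h) continue;
                Z[(size_t)(r + dr) + (size_t)h * (c + dc)] += Wk[(size_t)r + (size_t)h * c];
            }
        }
    }
    // Symmetric per-site normalization w / (2 max(Z_i, Z_j)).
    for (int k = 0; k < K; ++k) {
        const int dr = offsets(k, 0), dc = offsets(k, 1);
        double *Wk = W[(size_t)k].data();
        for (int c = 0; c < w; ++c) {
            if (c + dc < 0 || c + dc >= w) continue;
            for (int r = 0; r < h; ++r) {
                const size_t si = (size_t)r + (size_t)h * c;
                if (Wk[si] <= 0.0) continue;
                const size_t sj = (size_t)(r + dr) + (size_t)h * (c + dc);
                const double zmax = (Z[si] > Z[sj]) ? Z[si] : Z[sj];
                Wk[si] /= 2.0 * zmax;
            }
        }
    }

    // Energy before the step and the full gradient.
    long double unary_pre = 0.0L, pair_pre = 0.0L;
    for (int s = 0; s < M; ++s) {
        const double d = S[(size_t)s] - O[(size_t)s];
        unary_pre += (long double)(d * d);
    }
    NumericMatrix grad(h, w);
    double *G = grad.begin();
    for (int s = 0; s < M; ++s) G[(size_t)s] = 2.0 * (S[(size_t)s] - O[(size_t)s]);
    for (int k = 0; k < K; ++k) {
        const int dr = offsets(k, 0), dc = offsets(k, 1);
        const double *Wk = W[(size_t)k].data();
        for (int c = 0; c < w; ++c) {
            if (c + dc < 0 || c + dc >= w) continue;
            for (int r = 0; r < h; ++r) {
                if (r + dr < 0 || r + dr >= h) continue;
                const size_t si = (size_t)r + (size_t)h * c;
                const size_t sj = (size_t)(r + dr) + (size_t)h * (c + dc);
                const double diff = S[si] - S[sj];
                pair_pre += (long double)(Wk[si] * diff * diff);
                const double contrib = 2.0 * lambda * Wk[si] * diff;
                G[si] += contrib;
                G[sj] -= contrib;
            }
        }
    }

    NumericMatrix out(h, w);
    double *T1 = out.begin();
    for (int s = 0; s < M; ++s) T1[(size_t)s] = S[(size_t)s] - step * G[(size_t)s];

    long double unary_post = 0.0L, pair_post = 0.0L;
    for (int s = 0; s < M; ++s) {
        const double d = T1[(size_t)s] - O[(size_t)s];
        unary_post += (long double)(d * d);
    }
    for (int k = 0; k < K; ++k) {
        const int dr = offsets(k, 0), dc = offsets(k, 1);
        const double *Wk = W[(size_t)k].data();
        for (int c = 0; c < w; ++c) {
            if (c + dc < 0 || c + dc >= w) continue;
            for (int r = 0; r < h; ++r) {
                if (r + dr < 0 || r + dr >= h) continue;
                const size_t si = (size_t)r + (size_t)h * c;
                const size_t sj = (size_t)(r + dr) + (size_t)h * (c + dc);
                const double diff = T1[si] - T1[sj];
                pair_post += (long double)(Wk[si] * diff * diff);
            }
        }
    }

    return List::create(
        Named("state") = out,
        Named("energy_pre") = (double)(unary_pre + (long double)lambda * pair_pre),
        Named("energy_post") = (double)(unary_post + (long double)lambda * pair_post));
}
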