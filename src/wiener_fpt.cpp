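#include <Rcpp.h>
using namespace Rcpp;

// Two-boundary Wiener first-passage-time density at the LOWER boundary,
// diffusion coefficient fixed at 1.  Dual-series evaluation: the density in
// normalized time tau = t / a^2 (unit boundary, zero drift, relative start w)
// is computed with either the small-time or the large-time expansion,
// whichever needs fewer terms for truncation error < eps, then rescaled by
// the drift/boundary factor exp(-v*a*w - v^2 t / 2) / a^2.

static const double EPS_TRUNC = 1e-7; // series truncation error

// log of the normalized (a=1, v=0) lower-boundary density at tau, start w.
static double wfpt_norm_logdens(double tau, double w) {
    if (!(tau > 0.0)) return R_NegInf;

    // number of terms required by each expansion (Navarro & Fuss 2009)
    double ks, kl;
    if (2.0 * std::sqrt(2.0 * M_PI * tau) * EPS_TRUNC < 1.0) {
        ks = 2.0 + std::sqrt(-2.0 * tau *
                             std::log(2.0 * std::sqrt(2.0 * M_PI * tau) * EPS_TRUNC));
        ks = std::max(ks, std::sqrt(tau) + 1.0);
    } else {
        ks = 2.0;
    }
    if (M_PI * tau * EPS_TRUNC < 1.0) {
        kl = std::sqrt(-2.0 * std::log(M_PI * tau * EPS_TRUNC) / (M_PI * M_PI * tau));
        kl = std::max(kl, 1.0 / (M_PI * std::sqrt(tau)));
    } else {
        kl = 1.0 / (M_PI * std::sqrt(tau));
    }

    double p = 0.0;
    if (ks < kl) {
        // small-time expansion, terms k = -K..K around the images of w
        int K = (int)std::ceil(ks);
        int lo = -(int)std::floor((K - 1.0) / 2.0);
        int hi = (int)std::ceil((K - 1.0) / 2.0);
        for (int k = lo; k <= hi; ++k) {
            double x = w + 2.0 * k;
            p += x * std::exp(-x * x / (2.0 * tau));
        }
        p /= std::sqrt(2.0 * M_PI * tau * tau * tau);
    } else {
        // large-time (spectral) expansion
        int K = (int)std::ceil(kl);
        for (int k = 1; k <= K; ++k) {
            p += k * std::exp(-k * k * M_PI * M_PI * tau / 2.0) *
                 std::sin(k * M_PI * w);
        }
        p *= M_PI;
    }
    if (!(p > 0.0)) return R_NegInf; // far-tail cancellation guard
    return std::log(p);
}

// [[Rcpp::export]]
NumericVector wfpt_logdens_cpp(NumericVector t, NumericVector v,
                               NumericVector a, NumericVector w) {
    R_xlen_t n = t.size();
    if (v.size() != n || a.size() != n || w.size() != n)
        stop("wfpt_logdens_cpp: argument lengths differ");
    NumericVector out(n);
    for (R_xlen_t i = 0; i < n; ++i) {
        double ti = t[i];
        if (!R_finite(ti) || ti <= 0.0) { out[i] = R_NegInf; continue; }
        double ai = a[i], wi = w[i], vi = v[i];
        double tau = ti / (ai * ai);
        double ld = wfpt_norm_logdens(tau, wi);
        if (ld == R_NegInf) { out[i] = R_NegInf; continue; }
        out[i] = ld - vi * ai * wi - vi * vi * ti / 2.0 - 2.0 * std::log(ai);
    }
    return out;
}

// Euler-Maruyama simulation of the diffusion to first passage; used as an
// independent oracle for the series density and the exact sampler.
// Returns a matrix [rt, upper] where upper is 1 if the upper boundary was hit.
// [[Rcpp::export]]
NumericMatrix wiener_euler_cpp(int n, double v, double a, double z,
                               double t0, double dt, double tmax) {
    NumericMatrix out(n, 2);
    double sdt = std::sqrt(dt);
    for (int i = 0; i < n; ++i) {
        double x = z * a;
        double t = 0.0;
        int upper = -1;
        while (t < tmax) {
            x += v * dt + sdt * R::norm_rand();
            t += dt;
            if (x >= a) { upper = 1; break; }
            if (x <= 0.0) { upper = 0; break; }
        }
        if (upper < 0) { // censored: restart the trial (mass ~ e^{-lambda tmax})
            i--; continue;
        }
        out(i, 0) = t0 + t;
        out(i, 1) = upper;
    }
    return out;
}
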