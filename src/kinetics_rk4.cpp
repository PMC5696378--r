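#include <Rcpp.h>
using namespace Rcpp;

// Fixed-step classical Runge-Kutta (RK4) for the two proximity-ligation
// kinetic systems, state (omega, x, y, z).
//
// one-step:  domega = -(p1+p2) omega ; dy = p1 omega^2 ; dz = p2 beta omega
// two-step:  domega = -2 p0 omega ; dx = 2 p0 omega - (p1+p2) x ;
//            dy = p1 x omega ; dz = p2 x beta

struct Params { double beta, p0, p1, p2; };

static inline void rhs_one(const double* s, double* d, const Params& P) {
    d[0] = -(P.p1 + P.p2) * s[0];
    d[1] = 0.0;
    d[2] = P.p1 * s[0] * s[0];
    d[3] = P.p2 * P.beta * s[0];
}

static inline void rhs_two(const double* s, double* d, const Params& P) {
    d[0] = -2.0 * P.p0 * s[0];
    d[1] = 2.0 * P.p0 * s[0] - (P.p1 + P.p2) * s[1];
    d[2] = P.p1 * s[1] * s[0];
    d[3] = P.p2 * s[1] * P.beta;
}

// model: 1 = one-step, 2 = two-step.
// Returns an (n_steps + 1) x 5 matrix: t, omega, x, y, z.
// [[Rcpp::export(name = ".rk4_kinetics_cpp")]]
NumericMatrix rk4_kinetics_cpp(double N, double beta, double p0, double p1,
                               double p2, int model, double t_end,
                               int n_steps) {
    if (!R_finite(N) || !R_finite(beta) || !R_finite(p0) || !R_finite(p1) ||
        !R_finite(p2))
        stop("non-finite kinetics parameters");
    if (t_end <= 0) stop("t_end must be > 0");
    if (n_steps < 2) stop("n_steps must be >= 2");
    Params P = {beta, p0, p1, p2};
    double h = t_end / n_steps;
    double s[4] = {2.0 * N, 0.0, 0.0, 0.0};
    NumericMatrix out(n_steps + 1, 5);
    out(0, 0) = 0.0;
    out(0, 1) = s[0];
    out(0, 2) = s[1];
    out(0, 3) = s[2];
    out(0, 4) = s[3];
    double k1[4], k2[4], k3[4], k4[4], tmp[4];
    for (int i = 1; i <= n_steps; ++i) {
        if (model == 1) rhs_one(s, k1, P); else rhs_two(s, k1, P);
        for (int j = 0; j < 4; ++j) tmp[j] = s[j] + 0.5 * h * k1[j];
        if (model == 1) rhs_one(tmp, k2, P); else rhs_two(tmp, k2, P);
        for (int j = 0; j < 4; ++j) tmp[j] = s[j] + 0.5 * h * k2[j];
        if (model == 1) rhs_one(tmp, k3, P); else rhs_two(tmp, k3, P);
        for (int j = 0; j < 4; ++j) tmp[j] = s[j] + h * k3[j];
        if (model == 1) rhs_one(tmp, k4, P); else rhs_two(tmp, k4, P);
        for (int j = 0; j < 4; ++j)
            s[j] += h / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
        out(i, 0) = i * h;
        out(i, 1) = s[0];
        out(i, 2) = s[1];
        out(i, 3) = s[2];
        out(i, 4) = s[3];
    }
    return out;
}
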