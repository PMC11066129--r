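#include <Rcpp.h>
#include <cmath>

// Coupled mass-action occupancy model for a two-isoform competition ChIP
// experiment. State y = (theta_A, theta_B): fractional occupancy of the
// constitutive (A, Myc) and induced competitor (B, HA) isoform at one site.
//
//   dtheta_A/dt = kon (1 - theta_A - theta_B) - koff theta_A
//   dtheta_B/dt = kon h(t) (1 - theta_A - theta_B) - koff theta_B
//
// kon = k_a * c_A (effective on-rate, /min), koff = k_d (/min) and
// h(t) = c_B(t)/c_A is the Hill induction curve of the competitor.
// Initial condition: pre-induction steady state theta_A(0) = kon/(kon+koff),
// theta_B(0) = 0.
//
// Integrator: adaptive exponential-midpoint stepping. For a frozen
// induction level h the system is linear, y' = M y + c with
// M = -koff I - kon N, where N = (1,h)^T (1,1) is rank one, so one step of
// size dt has the closed form
//
//   y(t+dt) = y_ss + e^{-koff dt} (I + f N) (y - y_ss),
//   f = (e^{-kon (1+h) dt} - 1) / (1+h),
//
// with y_ss the steady state at the frozen h. Freezing h at the step
// midpoint gives a second-order method whose only error source is the slow
// variation of the induction curve; step-doubling with local extrapolation
// supplies the error estimate and adaptivity. The scheme is A-stable, so
// arbitrarily large on-rates (fast equilibration) cost nothing extra --
// unlike an explicit Runge-Kutta scheme, whose stability limit makes the
// large-kon corner of the fit parameter box prohibitively slow.

static inline double hill_c(double t, double xp, double th, double n) {
    if (t <= 0.0) return 0.0;
    double r = std::pow(t / th, n);
    return xp * r / (1.0 + r);
}

// One exact step at induction level frozen at the step midpoint.
static inline void expm_step(const double y[2], double t, double dt,
                             double kon, double koff,
                             double xp, double th, double n,
                             double out[2]) {
    double h = hill_c(t + dt / 2.0, xp, th, n);
    double tau = 1.0 + h;
    double s_ss = kon * tau / (koff + kon * tau);
    double scale = kon * (1.0 - s_ss) / koff;
    double yss0 = scale, yss1 = scale * h;
    double d0 = y[0] - yss0, d1 = y[1] - yss1;
    double f = std::expm1(-kon * tau * dt) / tau;
    double dsum = d0 + d1;
    double damp = std::exp(-koff * dt);
    out[0] = yss0 + damp * (d0 + f * dsum);
    out[1] = yss1 + damp * (d1 + f * dsum * h);
}

//' Integrate the competition turnover ODEs (compiled adaptive stepper)
//'
//' Adaptive exponential-midpoint integrator with step-doubling error
//' control, used by [solve_model()]. Exposed at the R level only for
//' testing; use [solve_model()] in package code.
//'
//' @param kon effective on-rate k_a c_A (per minute)
//' @param koff off-rate k_d (per minute)
//' @param xp,th_ind,n_hill Hill induction parameters (plateau, half-time
//'   in minutes, coefficient)
//' @param times strictly increasing evaluation times (minutes); first
//'   element must be 0
//' @param rtol,atol relative / absolute step-error tolerances
//' @return numeric matrix with one row per time and columns
//'   \code{theta_A}, \code{theta_B}
//' @keywords internal
// [[Rcpp::export]]
Rcpp::NumericMatrix cc_integrate(double kon, double koff,
                                 double xp, double th_ind, double n_hill,
                                 Rcpp::NumericVector times,
                                 double rtol = 1e-8, double atol = 1e-10) {
    const int nt = times.size();
    if (nt < 1 || times[0] != 0.0)
        Rcpp::stop("`times` must start at 0");
    if (!(kon > 0) || !(koff > 0) || !std::isfinite(kon) || !std::isfinite(koff))
        Rcpp::stop("non-finite or non-positive rate constants (kon=%g, koff=%g)",
                   kon, koff);

    Rcpp::NumericMatrix out(nt, 2);
    double y[2] = {kon / (kon + koff), 0.0};
    out(0, 0) = y[0];
    out(0, 1) = y[1];

    double t = 0.0;
    double dt = 0.1;
    double y_full[2], y_half[2], y_two[2];
    int next_out = 1;
    long steps = 0;
    const long max_steps = 20000000L;

    while (next_out < nt) {
        if (++steps > max_steps)
            Rcpp::stop("ODE integration exceeded step budget (kon=%g, koff=%g)",
                       kon, koff);
        double t_target = times[next_out];
        double dt_try = dt;
        bool clipped = false;
        if (t + dt_try >= t_target) {
            dt_try = t_target - t;
            clipped = true;
        }
        expm_step(y, t, dt_try, kon, koff, xp, th_ind, n_hill, y_full);
        expm_step(y, t, dt_try / 2.0, kon, koff, xp, th_ind, n_hill, y_half);
        expm_step(y_half, t + dt_try / 2.0, dt_try / 2.0, kon, koff,
                  xp, th_ind, n_hill, y_two);

        double err = 0.0;
        for (int i = 0; i < 2; ++i) {
            double sc = atol + rtol * std::max(std::fabs(y[i]),
                                               std::fabs(y_two[i]));
            double r = (y_full[i] - y_two[i]) / sc;
            err += r * r;
        }
        err = std::sqrt(err / 2.0);

        if (err <= 1.0 || dt_try <= 1e-12) {
            t = clipped ? t_target : t + dt_try;
            // local extrapolation of the step-doubled solution
            y[0] = (4.0 * y_two[0] - y_full[0]) / 3.0;
            y[1] = (4.0 * y_two[1] - y_full[1]) / 3.0;
            if (clipped) {
                out(next_out, 0) = y[0];
                out(next_out, 1) = y[1];
                ++next_out;
            }
        }
        double fac = (err > 0) ? 0.9 * std::pow(err, -1.0 / 3.0) : 5.0;
        if (fac < 0.2) fac = 0.2;
        if (fac > 5.0) fac = 5.0;
        // resume from the pre-clipping step size after hitting an output time
        dt = (clipped && err <= 1.0 ? dt : dt_try) * fac;
        if (dt < 1e-12) dt = 1e-12;
    }

    Rcpp::colnames(out) = Rcpp::CharacterVector::create("theta_A", "theta_B");
    return out;
}
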