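#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Analytic deposit of the ramp-rate pulse
//   alpha * wdot(k/fs - t_arr),  wdot(t) = 2*pi*f0*cos(2*pi*f0*t) on [0, T)
// into buf, where buf[m] holds grid sample k = kb0 + m.  Evaluation is
// exact at every grid time (no interpolation).  When fs/f0 is an integer P
// the samples repeat with period P, so a P-entry cosine table turns the
// inner loop into cyclic adds; otherwise a cos/sin rotation recurrence is
// used (one sincos call per deposit either way).
struct wdot_pulse {
    double f0, T, fs, w, dph, cd, sd;
    int period;                 // fs/f0 if integer, else 0
    int nmax;                   // samples spanning the support
    std::vector<double> table;  // scratch for the periodic case
    wdot_pulse(double f0_, double T_, double fs_)
        : f0(f0_), T(T_), fs(fs_) {
        w = 2.0 * M_PI * f0;
        dph = w / fs;
        cd = std::cos(dph); sd = std::sin(dph);
        double p = fs / f0;
        period = (std::abs(p - std::round(p)) < 1e-9 && p <= 4096)
                 ? (int)std::round(p) : 0;
        if (period) table.resize(period);
        nmax = (int)std::ceil(T * fs) + 2;
    }
};

static inline void deposit_wdot(std::vector<double> &buf, int kb0, int kb1,
                                double alpha, double t_arr, wdot_pulse &P) {
    int ks = (int)std::ceil(t_arr * P.fs);
    if ((double)ks / P.fs < t_arr) ks++;             // guard fp round-down
    int ke = (int)std::ceil((t_arr + P.T) * P.fs) - 1;
    if (ks < kb0) ks = kb0;
    if (ke > kb1) ke = kb1;
    if (ks > ke) return;
    double ph = P.w * ((double)ks / P.fs - t_arr);
    double c0 = std::cos(ph), s0 = std::sin(ph);
    const double a = alpha * P.w;
    double *b = buf.data() + (ks - kb0);
    const int n = ke - ks + 1;
    if (P.period) {
        // phase advances by exactly 2*pi/period per sample: tabulate one
        // period, then add cyclically
        const int p = P.period;
        double *tab = P.table.data();
        double c = c0, s = s0;
        int m = n < p ? n : p;
        for (int j = 0; j < m; ++j) {
            tab[j] = a * c;
            double c1 = c * P.cd - s * P.sd;
            s = s * P.cd + c * P.sd;
            c = c1;
        }
        int j = 0;
        for (int k = 0; k < n; ++k) {
            b[k] += tab[j];
            if (++j == p) j = 0;
        }
    } else {
        for (int k = 0; k < n; ++k) {
            b[k] += a * c0;
            double c1 = c0 * P.cd - s0 * P.sd;
            s0 = s0 * P.cd + c0 * P.sd;
            c0 = c1;
        }
    }
}

// Pulse-echo RF synthesis for one transmit event.
//
// For every scatterer the transmit-summed intermediate pressure
//   sum_i apod_i * pT(elem_i -> scatterer, t + tau_i)
// is evaluated on the global sample grid k/fs by quadrature of the
// Rayleigh integral with analytic time evaluation, then convolved
// (discrete approximation of the continuous convolution, step 1/fs) with
// the per-channel receive intermediate pR(elem_j -> scatterer, t +
// tau_rx_j), scaled by a_s / (2 rho0 c^2), and accumulated into the
// channel trace.  The outer time derivative is applied once per trace by
// the caller, after superposition.
//
// scat: N x 3 positions (m); elem_tx/elem_rx: element centers (rows, m);
// quad: Q x 3 (dx, dy, weight_m2) node offsets on the element face;
// k0_out: global index of the first output sample (t0 = k0_out / fs).
// Output: nt x Mrx matrix (time down the rows).
// [[Rcpp::export]]
NumericMatrix rf_event_cpp(NumericMatrix scat, NumericVector amp,
                           NumericMatrix elem_tx, NumericVector tau_tx,
                           NumericVector apod_tx,
                           NumericMatrix elem_rx, NumericVector tau_rx,
                           NumericMatrix quad,
                           double f0_tx, double T_tx,
                           double f0_rx, double T_rx,
                           double fs, int k0_out, int nt,
                           double c, double rho0) {
    const int N = scat.nrow();
    const int Mt = elem_tx.nrow();
    const int Mr = elem_rx.nrow();
    const int Q = quad.nrow();
    NumericMatrix out(nt, Mr);
    double *outp = REAL(out);

    // local copies: tight loops must not go through Rcpp accessors
    std::vector<double> sx(N), sy(N), sz(N), am(N);
    for (int n = 0; n < N; ++n) {
        sx[n] = scat(n, 0); sy[n] = scat(n, 1); sz[n] = scat(n, 2);
        am[n] = amp[n];
    }
    std::vector<double> txx(Mt), txy(Mt), txz(Mt), txt(Mt), txa(Mt);
    for (int i = 0; i < Mt; ++i) {
        txx[i] = elem_tx(i, 0); txy[i] = elem_tx(i, 1); txz[i] = elem_tx(i, 2);
        txt[i] = tau_tx[i]; txa[i] = apod_tx[i];
    }
    std::vector<double> rxx(Mr), rxy(Mr), rxz(Mr), rxt(Mr);
    for (int j = 0; j < Mr; ++j) {
        rxx[j] = elem_rx(j, 0); rxy[j] = elem_rx(j, 1); rxz[j] = elem_rx(j, 2);
        rxt[j] = tau_rx[j];
    }
    std::vector<double> qx(Q), qy(Q), qw(Q);
    for (int q = 0; q < Q; ++q) {
        qx[q] = quad(q, 0); qy[q] = quad(q, 1); qw[q] = quad(q, 2);
    }

    wdot_pulse Ptx(f0_tx, T_tx, fs), Prx(f0_rx, T_rx, fs);
    const double inv2pc = rho0 / (2.0 * M_PI);
    const double scale0 = 1.0 / (2.0 * rho0 * c * c) / fs;

    std::vector<double> ta(Mt * Q), al(Mt * Q);
    std::vector<double> td(Q), ad(Q);
    std::vector<double> tsum, prx;

    for (int n = 0; n < N; ++n) {
        if (am[n] == 0.0) continue;
        const double px = sx[n], py = sy[n], pz = sz[n];

        // transmit terms: arrival times and Rayleigh amplitudes
        double tmin = R_PosInf, tmax = R_NegInf;
        int nterm = 0;
        for (int i = 0; i < Mt; ++i) {
            if (txa[i] == 0.0) continue;
            const double ex = txx[i], ey = txy[i], ez = txz[i];
            const double w0 = txa[i] * inv2pc;
            for (int q = 0; q < Q; ++q, ++nterm) {
                const double dx = px - (ex + qx[q]);
                const double dy = py - (ey + qy[q]);
                const double dz = pz - ez;
                const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
                const double t = d / c + txt[i];
                ta[nterm] = t;
                al[nterm] = w0 * qw[q] / d;
                if (t < tmin) tmin = t;
                if (t > tmax) tmax = t;
            }
        }
        if (nterm == 0) continue;

        const int kt0 = (int)std::floor(tmin * fs);
        const int kt1 = (int)std::ceil((tmax + T_tx) * fs);
        const int Lt = kt1 - kt0 + 1;
        tsum.assign(Lt, 0.0);
        for (int m = 0; m < nterm; ++m)
            deposit_wdot(tsum, kt0, kt1, al[m], ta[m], Ptx);

        const double sc = scale0 * am[n];
        for (int j = 0; j < Mr; ++j) {
            const double ex = rxx[j], ey = rxy[j], ez = rxz[j];
            double rmin = R_PosInf, rmax = R_NegInf;
            for (int q = 0; q < Q; ++q) {
                const double dx = px - (ex + qx[q]);
                const double dy = py - (ey + qy[q]);
                const double dz = pz - ez;
                const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
                const double t = d / c + rxt[j];
                td[q] = t;
                ad[q] = inv2pc * qw[q] / d;
                if (t < rmin) rmin = t;
                if (t > rmax) rmax = t;
            }
            const int kr0 = (int)std::floor(rmin * fs);
            const int kr1 = (int)std::ceil((rmax + T_rx) * fs);
            const int Lr = kr1 - kr0 + 1;
            prx.assign(Lr, 0.0);
            for (int q = 0; q < Q; ++q)
                deposit_wdot(prx, kr0, kr1, ad[q], td[q], Prx);

            // accumulate conv(tsum, prx) into channel j
            double *col = outp + (size_t)j * nt;
            const int base0 = kt0 + kr0 - k0_out;
            const double *ts = tsum.data();
            for (int r = 0; r < Lr; ++r) {
                const double g = sc * prx[r];
                if (g == 0.0) continue;
                int base = base0 + r;
                int m0 = 0, m1 = Lt - 1;
                if (base + m0 < 0) m0 = -base;
                if (base + m1 > nt - 1) m1 = nt - 1 - base;
                double *cb = col + base;
                for (int m = m0; m <= m1; ++m)
                    cb[m] += g * ts[m];
            }
        }
        if ((n & 1023) == 0) Rcpp::checkUserInterrupt();
    }
    return out;
}
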