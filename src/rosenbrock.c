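/* Stiff relaxation of mass-action networks to steady state, and the
 * going-up/coming-down stimulus sweep, implemented in C so that a
 * Latin-hypercube scan over thousands of parameter sets stays cheap.
 *
 * Integrator: two-stage L-stable Rosenbrock (ROS2, gamma = 1 + 1/sqrt(2)),
 *   (I - g h J) k1 = f(x)
 *   (I - g h J) k2 = f(x + h k1) - 2 k1
 *   x+ = x + h (3/2 k1 + 1/2 k2)
 * with the embedded first-order solution x + h k1 providing the local error
 * estimate (h/2)|k1 + k2|. The Jacobian is assembled analytically from the
 * reaction list. A converged state is polished by Newton iteration on the
 * steady-state system with conservation laws substituted for the equations
 * of designated species (the plain Jacobian is singular along conservation
 * directions).
 */

#include <R.h>
#include <Rinternals.h>
#include <math.h>
#include <string.h>

#define MAXN 16

typedef struct {
    int ns, nr;
    const double *stoich;   /* ns x nr, column major */
    const int *r1, *r2;     /* 0-based reactant indices, -1 = none */
    const double *rate;
} network;

static void derivs(const network *net, const double *x, double *f)
{
    int i, j;
    for (i = 0; i < net->ns; i++) f[i] = 0.0;
    for (j = 0; j < net->nr; j++) {
        double flux = net->rate[j];
        if (net->r1[j] >= 0) flux *= x[net->r1[j]];
        if (net->r2[j] >= 0) flux *= x[net->r2[j]];
        if (flux != 0.0) {
            const double *col = net->stoich + (size_t)j * net->ns;
            for (i = 0; i < net->ns; i++)
                if (col[i] != 0.0) f[i] += col[i] * flux;
        }
    }
}

/* J[i][k] = d f_i / d x_k, column major in jac (ns x ns) */
static void jacobian(const network *net, const double *x, double *jac)
{
    int i, j, ns = net->ns;
    memset(jac, 0, sizeof(double) * ns * ns);
    for (j = 0; j < net->nr; j++) {
        int a = net->r1[j], b = net->r2[j];
        const double *col = net->stoich + (size_t)j * ns;
        if (a < 0) continue;            /* zero-order: no state dependence */
        if (b < 0) {                    /* unimolecular */
            double d = net->rate[j];
            for (i = 0; i < ns; i++)
                if (col[i] != 0.0) jac[a * ns + i] += col[i] * d;
        } else if (a == b) {            /* 2 X -> ... */
            double d = 2.0 * net->rate[j] * x[a];
            for (i = 0; i < ns; i++)
                if (col[i] != 0.0) jac[a * ns + i] += col[i] * d;
        } else {
            double da = net->rate[j] * x[b], db = net->rate[j] * x[a];
            for (i = 0; i < ns; i++)
                if (col[i] != 0.0) {
                    jac[a * ns + i] += col[i] * da;
                    jac[b * ns + i] += col[i] * db;
                }
        }
    }
}

/* LU with partial pivoting; A column-major n x n. Returns 0 on success. */
static int lu_factor(double *A, int *piv, int n)
{
    int i, j, k;
    for (k = 0; k < n; k++) {
        int p = k;
        double amax = fabs(A[k * n + k]);
        for (i = k + 1; i < n; i++) {
            double v = fabs(A[k * n + i]);
            if (v > amax) { amax = v; p = i; }
        }
        if (!(amax > 0.0) || !R_FINITE(amax)) return 1;
        piv[k] = p;
        if (p != k)
            for (j = 0; j < n; j++) {
                double tmp = A[j * n + k];
                A[j * n + k] = A[j * n + p];
                A[j * n + p] = tmp;
            }
        for (i = k + 1; i < n; i++) {
            A[k * n + i] /= A[k * n + k];
            double m = A[k * n + i];
            if (m != 0.0)
                for (j = k + 1; j < n; j++)
                    A[j * n + i] -= m * A[j * n + k];
        }
    }
    return 0;
}

static void lu_solve(const double *A, const int *piv, int n, double *b)
{
    int i, j;
    for (i = 0; i < n; i++) {
        if (piv[i] != i) {
            double tmp = b[i]; b[i] = b[piv[i]]; b[piv[i]] = tmp;
        }
        for (j = 0; j < i; j++) b[i] -= A[j * n + i] * b[j];
    }
    for (i = n - 1; i >= 0; i--) {
        for (j = i + 1; j < n; j++) b[i] -= A[j * n + i] * b[j];
        b[i] /= A[i * n + i];
    }
}

typedef struct {
    double rtol, atol, ss_tol, t_min, t_max, h0;
    int max_steps;
    int newton_gate;   /* require a verified nearby equilibrium to converge */
} solver_opts;

static double state_rate(const network *net, const double *x, double *f)
{
    derivs(net, x, f);
    double rate = 0.0;
    for (int i = 0; i < net->ns; i++) {
        double sc = fabs(x[i]); if (sc < 1e-6) sc = 1e-6;
        double r = fabs(f[i]) / sc;
        if (r > rate) rate = r;
    }
    return rate;
}

/* Newton polish on f = 0 with conservation rows substituted.
 * law: nl x ns (column major), targets: nl, rows[l]: species row replaced.
 * Returns the post-polish relative rate, so the caller can tell a true
 * equilibrium from a slow transit (e.g. a saddle-node ghost), where no
 * nearby equilibrium exists and the polish bails out. */
static double polish(const network *net, int nl, const double *law,
                     const double *targets, const int *rows, double *x)
{
    int ns = net->ns, piv[MAXN], it, i, l;
    double f[MAXN], g[MAXN], J[MAXN * MAXN], M[MAXN * MAXN], xs[MAXN];
    memcpy(xs, x, sizeof(double) * ns);
    for (it = 0; it < 8; it++) {
        derivs(net, x, f);
        jacobian(net, x, J);
        memcpy(M, J, sizeof(double) * ns * ns);
        memcpy(g, f, sizeof(double) * ns);
        for (l = 0; l < nl; l++) {
            int r = rows[l];
            double resid = -targets[l];
            for (i = 0; i < ns; i++) {
                M[i * ns + r] = law[i * nl + l];
                resid += law[i * nl + l] * x[i];
            }
            g[r] = resid;
        }
        if (lu_factor(M, piv, ns)) { memcpy(x, xs, sizeof(double) * ns); return state_rate(net, x, f); }
        lu_solve(M, piv, ns, g);
        double dn = 0.0, xn = 1.0;
        for (i = 0; i < ns; i++) {
            if (fabs(g[i]) > dn) dn = fabs(g[i]);
            if (fabs(x[i]) > xn) xn = fabs(x[i]);
        }
        if (!R_FINITE(dn) || dn > 1e-2 * xn) {   /* polish would jump: bail */
            memcpy(x, xs, sizeof(double) * ns);
            return state_rate(net, x, f);
        }
        for (i = 0; i < ns; i++) {
            x[i] -= g[i];
            if (x[i] < 0.0) x[i] = 0.0;
        }
        if (dn < 1e-13 * xn) break;
    }
    for (i = 0; i < ns; i++)
        if (!R_FINITE(x[i]) || x[i] < 0.0) { memcpy(x, xs, sizeof(double) * ns); break; }
    return state_rate(net, x, f);
}

/* Relax x (in place) to steady state. Returns 1 if converged. */
static int relax(const network *net, double *x, const solver_opts *o,
                 int nl, const double *law, const double *targets, const int *rows)
{
    const double gam = 1.0 + 1.0 / sqrt(2.0);
    int ns = net->ns, piv[MAXN], i, step;
    double f0[MAXN], f1[MAXN], k1[MAXN], k2[MAXN], xt[MAXN], xn[MAXN];
    double A[MAXN * MAXN], J[MAXN * MAXN];
    double t = 0.0, h = o->h0;
    int converged = 0, f0_fresh = 0;
    double attempt_gate = 1e300;

    for (step = 0; step < o->max_steps && !converged; step++) {
        /* convergence judged on the current derivative before stepping; a
         * state that is already steady converges without integrating */
        if (!f0_fresh) derivs(net, x, f0);
        f0_fresh = 0;
        double rate = 0.0;
        for (i = 0; i < ns; i++) {
            double sc = fabs(x[i]); if (sc < 1e-6) sc = 1e-6;
            double r = fabs(f0[i]) / sc;
            if (r > rate) rate = r;
        }
        if (rate < o->ss_tol && rate < attempt_gate &&
            (t >= o->t_min || step == 0)) {
            /* candidate steady state: accept only if Newton lands on a true
             * nearby equilibrium; a slow transit (saddle-node ghost) has no
             * equilibrium nearby and integration must continue */
            double xp[MAXN];
            memcpy(xp, x, sizeof(double) * ns);
            double post = (nl > 0) ? polish(net, nl, law, targets, rows, xp)
                                   : rate;
            if (!o->newton_gate) { converged = 1; break; }
            if (post < 1e-9) {
                memcpy(x, xp, sizeof(double) * ns);
                converged = 1;
                break;
            }
            attempt_gate = rate * 0.3;   /* retry once the rate drops further */
            f0_fresh = 1;
        }
        if (t >= o->t_max) break;
        if (h > o->t_max - t) h = o->t_max - t;
        jacobian(net, x, J);
        for (i = 0; i < ns * ns; i++) A[i] = -gam * h * J[i];
        for (i = 0; i < ns; i++) A[i * ns + i] += 1.0;
        if (lu_factor(A, piv, ns)) { h *= 0.25; continue; }
        memcpy(k1, f0, sizeof(double) * ns);
        lu_solve(A, piv, ns, k1);
        for (i = 0; i < ns; i++) xt[i] = x[i] + h * k1[i];
        derivs(net, xt, f1);
        for (i = 0; i < ns; i++) k2[i] = f1[i] - 2.0 * k1[i];
        lu_solve(A, piv, ns, k2);
        double ratio = 0.0;
        int bad = 0;
        for (i = 0; i < ns; i++) {
            xn[i] = x[i] + h * (1.5 * k1[i] + 0.5 * k2[i]);
            if (!R_FINITE(xn[i])) { bad = 1; break; }
            double est = 0.5 * h * fabs(k1[i] + k2[i]);
            double sc = o->atol + o->rtol * fmax(fabs(x[i]), fabs(xn[i]));
            double r = est / sc;
            if (r > ratio) ratio = r;
        }
        if (bad || !R_FINITE(ratio)) { h *= 0.25; f0_fresh = 1; if (h < 1e-300) break; continue; }
        if (ratio <= 1.0) {
            for (i = 0; i < ns; i++) x[i] = (xn[i] < 0.0) ? 0.0 : xn[i];
            t += h;
            double fac = (ratio > 0.0) ? 0.9 / sqrt(ratio) : 5.0;
            if (fac > 5.0) fac = 5.0;
            if (fac < 0.2) fac = 0.2;
            h *= fac;
        } else {
            f0_fresh = 1;
            double fac = 0.9 / sqrt(ratio);
            if (fac < 0.1) fac = 0.1;
            h *= fac;
            if (h < 1e-300) break;
        }
    }
    return converged;
}

typedef struct {
    int nl, stim_law;           /* stimulus law index (0-based) */
    const double *law;          /* nl x ns column major */
    const int *adjust;          /* per-law residual-absorbing species */
    const int *enz_drain;       /* species drained (in order) when the kinase
                                   total decreases; paired with release[] which
                                   is -1 for free enzyme, else the substrate
                                   species receiving the freed partner */
    const int *enz_release;
    int n_drain;
} sweep_meta;

static void set_targets(const sweep_meta *m, const double *base, double stim,
                        double *targets)
{
    for (int l = 0; l < m->nl; l++)
        targets[l] = (l == m->stim_law) ? stim : base[l];
}

/* move the kinase conservation law of state x to the value `total` */
static void set_enzyme_total(const network *net, const sweep_meta *m,
                             double *x, double total)
{
    int ns = net->ns, i;
    double cur = 0.0;
    for (i = 0; i < ns; i++) cur += m->law[i * m->nl + m->stim_law] * x[i];
    double delta = total - cur;
    if (delta >= 0.0) {
        x[m->enz_drain[0]] += delta;    /* add as free cytosolic kinase */
        return;
    }
    for (i = 0; i < m->n_drain && delta < 0.0; i++) {
        int s = m->enz_drain[i];
        double take = fmin(x[s], -delta);
        x[s] -= take;
        delta += take;
        if (m->enz_release[i] >= 0) x[m->enz_release[i]] += take;
    }
}

static void project_laws(const network *net, const sweep_meta *m,
                         const double *targets, double *x)
{
    for (int l = 0; l < m->nl; l++) {
        double v = 0.0;
        for (int i = 0; i < net->ns; i++) v += m->law[i * m->nl + l] * x[i];
        int s = m->adjust[l];
        x[s] += targets[l] - v;
        if (x[s] < 0.0) x[s] = 0.0;
    }
}

static void perturb(const network *net, double *x, double eps)
{
    for (int i = 0; i < net->ns; i++) if (x[i] > 0.0) x[i] *= (1.0 + eps);
}

static network unpack_network(SEXP stoich, SEXP r1, SEXP r2, SEXP rates)
{
    network net;
    net.ns = nrows(stoich);
    net.nr = ncols(stoich);
    net.stoich = REAL(stoich);
    net.r1 = INTEGER(r1);
    net.r2 = INTEGER(r2);
    net.rate = REAL(rates);
    return net;
}

static solver_opts unpack_opts(SEXP opts)
{
    const double *o = REAL(opts);
    solver_opts s;
    s.rtol = o[0]; s.atol = o[1]; s.ss_tol = o[2];
    s.t_min = o[3]; s.t_max = o[4]; s.h0 = o[5];
    s.max_steps = (int) o[6];
    s.newton_gate = (length(opts) > 7) ? (int) o[7] : 1;
    return s;
}

/* single relaxation: returns list(state, converged) */
SEXP C_relax(SEXP stoich, SEXP r1, SEXP r2, SEXP rates, SEXP x0, SEXP opts,
             SEXP law, SEXP targets, SEXP polish_rows)
{
    network net = unpack_network(stoich, r1, r2, rates);
    solver_opts o = unpack_opts(opts);
    if (net.ns > MAXN) error("too many species for the compiled solver");
    double x[MAXN];
    memcpy(x, REAL(x0), sizeof(double) * net.ns);
    int nl = length(targets);
    int conv = relax(&net, x, &o, nl, REAL(law), REAL(targets),
                     INTEGER(polish_rows));
    SEXP out = PROTECT(allocVector(VECSXP, 2));
    SEXP st = PROTECT(allocVector(REALSXP, net.ns));
    memcpy(REAL(st), x, sizeof(double) * net.ns);
    SET_VECTOR_ELT(out, 0, st);
    SET_VECTOR_ELT(out, 1, ScalarInteger(conv));
    UNPROTECT(2);
    return out;
}

/* full going-up/coming-down sweep for one parameter set */
SEXP C_sweep(SEXP stoich, SEXP r1, SEXP r2, SEXP rates, SEXP x0, SEXP stim,
             SEXP opts, SEXP law, SEXP law_base, SEXP stim_law, SEXP adjust,
             SEXP enz_drain, SEXP enz_release, SEXP resp, SEXP perturb_eps)
{
    network net = unpack_network(stoich, r1, r2, rates);
    solver_opts o = unpack_opts(opts);
    if (net.ns > MAXN) error("too many species for the compiled solver");
    int nstim = length(stim);
    const double *sv = REAL(stim);
    sweep_meta m;
    m.nl = length(law_base);
    m.stim_law = asInteger(stim_law) - 1;
    m.law = REAL(law);
    m.adjust = INTEGER(adjust);
    m.enz_drain = INTEGER(enz_drain);
    m.enz_release = INTEGER(enz_release);
    m.n_drain = length(enz_drain);
    int iresp = asInteger(resp) - 1;
    double eps = asReal(perturb_eps);

    SEXP up = PROTECT(allocVector(REALSXP, nstim));
    SEXP down = PROTECT(allocVector(REALSXP, nstim));
    SEXP cup = PROTECT(allocVector(INTSXP, nstim));
    SEXP cdown = PROTECT(allocVector(INTSXP, nstim));

    double x[MAXN], targets[8];
    memcpy(x, REAL(x0), sizeof(double) * net.ns);
    int k;
    for (k = 0; k < nstim; k++) {
        if (k > 0) {
            perturb(&net, x, eps);
            set_enzyme_total(&net, &m, x, sv[k]);
        }
        set_targets(&m, REAL(law_base), sv[k], targets);
        project_laws(&net, &m, targets, x);
        INTEGER(cup)[k] = relax(&net, x, &o, m.nl, m.law, targets, m.adjust);
        REAL(up)[k] = x[iresp];
    }
    for (k = nstim - 1; k >= 0; k--) {
        perturb(&net, x, eps);
        set_enzyme_total(&net, &m, x, sv[k]);
        set_targets(&m, REAL(law_base), sv[k], targets);
        project_laws(&net, &m, targets, x);
        INTEGER(cdown)[k] = relax(&net, x, &o, m.nl, m.law, targets, m.adjust);
        REAL(down)[k] = x[iresp];
    }
    SEXP out = PROTECT(allocVector(VECSXP, 4));
    SET_VECTOR_ELT(out, 0, up);
    SET_VECTOR_ELT(out, 1, down);
    SET_VECTOR_ELT(out, 2, cup);
    SET_VECTOR_ELT(out, 3, cdown);
    UNPROTECT(5);
    return out;
}

#include <R_ext/Rdynload.h>

static const R_CallMethodDef CallEntries[] = {
    {"C_relax", (DL_FUNC) &C_relax, 9},
    {"C_sweep", (DL_FUNC) &C_sweep, 15},
    {NULL, NULL, 0}
};

void R_init_compswitch(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
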