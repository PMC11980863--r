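#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// HKY transition probabilities, generator normalised to mean rate 1.
// States in order A, C, G, T; P is row-major 4x4.
static void hky_pmatrix(const double *f, double kappa, double t, double *P) {
  const double piA = f[0], piC = f[1], piG = f[2], piT = f[3];
  const double piR = piA + piG, piY = piC + piT;
  const double beta = 1.0 / (2.0 * kappa * (piA * piG + piC * piT) + 2.0 * piR * piY);
  const double e2 = std::exp(-beta * t);
  const double eR = std::exp(-beta * t * (piR * kappa + piY));
  const double eY = std::exp(-beta * t * (piY * kappa + piR));
  const double grp[4] = {piR, piY, piR, piY};
  const double egrp[4] = {eR, eY, eR, eY};
  for (int i = 0; i < 4; ++i) {
    for (int j = 0; j < 4; ++j) {
      double v;
      if (i == j) {
        v = f[j] + f[j] * (1.0 / grp[j] - 1.0) * e2 +
            ((grp[j] - f[j]) / grp[j]) * egrp[j];
      } else if ((i % 2) == (j % 2)) {  // same group (A,G) or (C,T)
        v = f[j] + f[j] * (1.0 / grp[j] - 1.0) * e2 - (f[j] / grp[j]) * egrp[j];
      } else {
        v = f[j] * (1.0 - e2);
      }
      P[4 * i + j] = v;
    }
  }
}

// Felsenstein pruning log-likelihood for each partition of a dated tree.
//
// edge: 2n-2 x 2 (parent, child), 1-based node ids, rows in postorder
//       (each child's subtree rows precede the row leading to the child).
// ages: node ages, years BP, length 2n-1.
// part_tips: per partition an IntegerMatrix (n_tip x n_pattern) of state
//       codes 0=A,1=C,2=G,3=T,4=fully ambiguous (N or '-').
// part_rates/part_catweights: site-rate mixture per partition.
// Branch distance = clock_rate * rel_rate * category_rate * duration.
// [[Rcpp::export(name = ".prune_loglik")]]
NumericVector prune_loglik(IntegerMatrix edge, NumericVector ages, int n_tip,
                           List part_tips, List part_weights, List part_freqs,
                           NumericVector kappa, List part_rates,
                           List part_catweights, double clock_rate,
                           NumericVector rel_rate) {
  const int n_part = part_tips.size();
  const int n_edge = edge.nrow();
  const int n_node = 2 * n_tip - 1;
  NumericVector out(n_part);

  std::vector<double> dur(n_edge);
  for (int e = 0; e < n_edge; ++e) {
    dur[e] = ages[edge(e, 0) - 1] - ages[edge(e, 1) - 1];
    if (dur[e] < 0) stop("negative branch duration");
  }

  for (int p = 0; p < n_part; ++p) {
    IntegerMatrix tips = part_tips[p];
    NumericVector w = part_weights[p];
    NumericVector fr = part_freqs[p];
    NumericVector rates = part_rates[p];
    NumericVector cw = part_catweights[p];
    const int npat = tips.ncol();
    const int ncat = rates.size();
    if (npat == 0) { out[p] = 0.0; continue; }
    double f[4] = {fr[0], fr[1], fr[2], fr[3]};

    // per-category log site likelihoods; internal-node partials only
    // (tip children are folded in directly from their state codes)
    std::vector<double> catll(static_cast<size_t>(ncat) * npat);
    std::vector<double> partial(static_cast<size_t>(n_tip - 1) * npat * 4);
    std::vector<double> scaler(npat);
    std::vector<double> P(static_cast<size_t>(n_edge) * 16);
    const int *tipc = &tips(0, 0);  // column-major n_tip x npat

    for (int c = 0; c < ncat; ++c) {
      const double r = clock_rate * rel_rate[p] * rates[c];
      for (int e = 0; e < n_edge; ++e)
        hky_pmatrix(f, kappa[p], r * dur[e], &P[16 * e]);

      std::fill(partial.begin(), partial.end(), 1.0);
      std::fill(scaler.begin(), scaler.end(), 0.0);

      for (int e = 0; e < n_edge; ++e) {
        const int par = edge(e, 0) - 1, ch = edge(e, 1) - 1;
        double *pp = &partial[(static_cast<size_t>(par - n_tip) * npat) * 4];
        const double *Pe = &P[16 * e];
        if (ch < n_tip) {
          double rowsum[4];
          for (int i = 0; i < 4; ++i)
            rowsum[i] = Pe[4 * i] + Pe[4 * i + 1] + Pe[4 * i + 2] + Pe[4 * i + 3];
          for (int s = 0; s < npat; ++s) {
            const int code = tipc[static_cast<size_t>(s) * n_tip + ch];
            double *ps = pp + 4 * s;
            if (code >= 4) {
              ps[0] *= rowsum[0]; ps[1] *= rowsum[1];
              ps[2] *= rowsum[2]; ps[3] *= rowsum[3];
            } else {
              ps[0] *= Pe[code]; ps[1] *= Pe[4 + code];
              ps[2] *= Pe[8 + code]; ps[3] *= Pe[12 + code];
            }
          }
        } else {
          double *pc = &partial[(static_cast<size_t>(ch - n_tip) * npat) * 4];
          for (int s = 0; s < npat; ++s) {
            double *cs = pc + 4 * s;
            // rescale the completed internal partial before consuming it
            double m = cs[0];
            if (cs[1] > m) m = cs[1];
            if (cs[2] > m) m = cs[2];
            if (cs[3] > m) m = cs[3];
            if (m > 0) {
              cs[0] /= m; cs[1] /= m; cs[2] /= m; cs[3] /= m;
              scaler[s] += std::log(m);
            } else {
              // site impossible under this rate category (e.g. a variable
              // site in the invariant class): category likelihood is 0
              scaler[s] = -std::numeric_limits<double>::infinity();
            }
            double *ps = pp + 4 * s;
            for (int i = 0; i < 4; ++i) {
              const double *row = Pe + 4 * i;
              ps[i] *= row[0] * cs[0] + row[1] * cs[1] +
                       row[2] * cs[2] + row[3] * cs[3];
            }
          }
        }
      }

      const double *proot = &partial[0];  // root is node n_tip (0-based)
      for (int s = 0; s < npat; ++s) {
        const double *ps = proot + 4 * s;
        double lik = f[0] * ps[0] + f[1] * ps[1] + f[2] * ps[2] + f[3] * ps[3];
        catll[static_cast<size_t>(c) * npat + s] =
            (lik > 0 ? std::log(lik) : -std::numeric_limits<double>::infinity()) +
            scaler[s];
      }
    }

    // mix over categories per pattern (log-sum-exp), then weight patterns
    double ll = 0.0;
    for (int s = 0; s < npat; ++s) {
      double mx = -std::numeric_limits<double>::infinity();
      for (int c = 0; c < ncat; ++c) {
        double v = std::log(cw[c]) + catll[static_cast<size_t>(c) * npat + s];
        if (v > mx) mx = v;
      }
      double acc = 0.0;
      if (std::isfinite(mx)) {
        for (int c = 0; c < ncat; ++c)
          acc += std::exp(std::log(cw[c]) +
                          catll[static_cast<size_t>(c) * npat + s] - mx);
      }
      ll += w[s] * (mx + std::log(acc));
    }
    out[p] = ll;
  }
  return out;
}
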