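#include <Rcpp.h>
using namespace Rcpp;

// Lifetime evaluation of one association set on a compiled network.
//
// Matrices are target-row / source-column: entry (i, j) describes the
// connection j -> i. Amag holds magnitudes of standard-source
// connections, Asgn their signs; Msig holds signed modulatory-source
// weights; P marks plastic entries (a subset of Amag's support).
//
// RNG: consumes R's global RNG in a fixed order -- one uniform per
// plastic entry in column-major order for the lifetime reset, then one
// uniform per softmax selection. The pure-R reference engine consumes
// the stream identically, so the two engines agree bitwise under the
// same seed.
//
// actions: 1-based correct action per stimulus.
// Input layout (n_in lines): [stimulus one-hot | pos | neg | feedback
// one-hot], or the 9-line variant [stimulus | signed reward |
// feedback] when n_in == n_stim + 1 + n_act.
// [[Rcpp::export]]
List eval_set_cpp(NumericMatrix Amag_in, NumericMatrix Asgn,
                  NumericMatrix Msig, LogicalMatrix P,
                  NumericVector bias,
                  IntegerVector input_idx, IntegerVector output_idx,
                  IntegerVector actions,
                  int episodes, int steps,
                  double lambda, double eta, double wmax,
                  double tau, double reward, bool learn) {
  const int n = Amag_in.nrow();
  const int n_in = input_idx.size();
  const int n_out = output_idx.size();
  const int n_stim = actions.size();
  NumericMatrix Amag = clone(Amag_in);

  std::vector<bool> is_input(n, false);
  for (int k = 0; k < n_in; ++k) is_input[input_idx[k] - 1] = true;

  // lifetime reset of plastic magnitudes, column-major
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < n; ++i)
      if (P(i, j)) Amag(i, j) = wmax * unif_rand();

  std::vector<double> o(n, 0.0), newo(n, 0.0), m(n, 0.0);
  std::vector<double> invec(n_in, 0.0), out(n_out, 0.0), prob(n_out, 0.0);
  const bool collapsed = (n_in == n_stim + 1 + n_out);

  LogicalVector flags(n_stim);
  IntegerVector chosen_v(n_stim);
  NumericVector descriptor(n_stim * n_out);

  for (int ep = 0; ep < episodes; ++ep) {
    for (int a = 0; a < n_stim; ++a) {
      for (int phase = 0; phase < 2; ++phase) {
        // build the clamped input for this phase
        std::fill(invec.begin(), invec.end(), 0.0);
        invec[a] = 1.0;
        int chosen = -1;
        if (phase == 1) {
          // softmax selection from the stimulus-phase outputs
          double mx = out[0];
          for (int k = 1; k < n_out; ++k) if (out[k] > mx) mx = out[k];
          double tot = 0.0;
          for (int k = 0; k < n_out; ++k) {
            prob[k] = std::exp((out[k] - mx) / tau);
            tot += prob[k];
          }
          double u = unif_rand() * tot, cum = 0.0;
          chosen = n_out - 1;
          for (int k = 0; k < n_out; ++k) {
            cum += prob[k];
            if (u < cum) { chosen = k; break; }
          }
          bool correct = (chosen + 1 == actions[a]);
          if (collapsed) {
            invec[n_stim] = (correct ? 1.0 : -1.0) * reward;
            invec[n_stim + 1 + chosen] = 1.0;
          } else {
            invec[n_stim + (correct ? 0 : 1)] = reward;
            invec[n_stim + 2 + chosen] = 1.0;
          }
          if (ep == episodes - 1) {
            flags[a] = correct;
            chosen_v[a] = chosen + 1;
            for (int k = 0; k < n_out; ++k)
              descriptor[a * n_out + k] = out[k];
          }
        }
        // clamp before propagation: the inputs are part of the state
        // the first step reads
        for (int k = 0; k < n_in; ++k) o[input_idx[k] - 1] = invec[k];
        for (int t = 0; t < steps; ++t) {
          for (int i = 0; i < n; ++i) {
            double drive = bias[i], mi = 0.0;
            for (int j = 0; j < n; ++j) {
              drive += Asgn(i, j) * Amag(i, j) * o[j];
              mi += Msig(i, j) * o[j];
            }
            newo[i] = 1.0 / (1.0 + std::exp(-lambda * drive));
            m[i] = mi;
          }
          for (int k = 0; k < n_in; ++k) newo[input_idx[k] - 1] = invec[k];
          o = newo;
          if (learn) {
            for (int j = 0; j < n; ++j)
              for (int i = 0; i < n; ++i)
                if (P(i, j)) {
                  double w = Amag(i, j) + eta * std::tanh(m[i]) * o[i] * o[j];
                  Amag(i, j) = std::min(std::max(w, 0.0), wmax);
                }
          }
        }
        if (phase == 0)
          for (int k = 0; k < n_out; ++k) out[k] = o[output_idx[k] - 1];
      }
    }
  }
  return List::create(_["correct"] = flags, _["chosen"] = chosen_v,
                      _["descriptor"] = descriptor, _["Amag"] = Amag);
}
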