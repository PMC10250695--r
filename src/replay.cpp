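#include <Rcpp.h>
using namespace Rcpp;

// Session replay for likelihood evaluation. Mirrors the R learner
// primitives exactly (tested for agreement); exists because multi-restart
// Nelder-Mead fitting evaluates the likelihood tens of thousands of times.
//
// trials: n x 8 integer matrix, columns
//   0 s1, 1 a1, 2 s2, 3 a2, 4 s3, 5 specific (0/1), 6 goal color code
//   (0 none, 1 yellow, 2 red, 3 blue), 7 missing (0/1)
// reward: paid coins per trial
// succ: 2*(1+n2) x 2, row = state*2 + action, 0-based candidate state ids
// term_value / term_color: per terminal (state id - n2 - 1 in 0-based C++)
// kind: 0 = model-free SARSA, 1 = model-based planner
// rate: alpha (MF) or eta (MB); tau: inverse temperature

static inline double chosen_prob2(double qa, double qb, int chosen,
                                  double tau) {
  // softmax over two actions, overflow-safe
  double d = tau * ((chosen == 0) ? (qb - qa) : (qa - qb));
  return 1.0 / (1.0 + std::exp(d));
}

// [[Rcpp::export]]
List cpp_session_nll(IntegerMatrix trials, NumericVector reward,
                     IntegerMatrix succ, NumericVector term_value,
                     IntegerVector term_color, int n2, int n3, int kind,
                     double rate, double tau) {
  const int n = trials.nrow();
  const int nchoice = n2 + 1;
  const double floor_p = 1e-12;

  std::vector<double> Q(nchoice * 2, 0.0);       // MF Q or MB planned Q
  std::vector<double> T(nchoice * 2, 0.5);       // P(likely); unlikely = 1-T
  std::vector<double> rterm(n3), v2(n2);

  NumericMatrix probs(n, 2);
  NumericVector trial_lik(n);
  std::fill(probs.begin(), probs.end(), NA_REAL);
  std::fill(trial_lik.begin(), trial_lik.end(), NA_REAL);
  double nll = 0.0;

  for (int t = 0; t < n; ++t) {
    if (trials(t, 7) == 1) continue;             // missing: no choices made
    const int s1 = trials(t, 0), a1 = trials(t, 1), s2 = trials(t, 2),
              a2 = trials(t, 3), s3 = trials(t, 4);
    const int specific = trials(t, 5), goal = trials(t, 6);

    if (kind == 1) {
      // backward planning at trial start under the current goal
      for (int j = 0; j < n3; ++j) {
        rterm[j] = (specific && term_color[j] != goal) ? 0.0 : term_value[j];
      }
      for (int s = 1; s <= n2; ++s) {
        for (int a = 0; a < 2; ++a) {
          const int row = s * 2 + a;
          const double p = T[row];
          Q[row] = p * rterm[succ(row, 0) - n2 - 1] +
                   (1.0 - p) * rterm[succ(row, 1) - n2 - 1];
        }
        v2[s - 1] = std::max(Q[s * 2], Q[s * 2 + 1]);
      }
      for (int a = 0; a < 2; ++a) {
        const double p = T[a];
        Q[a] = p * v2[succ(a, 0) - 1] + (1.0 - p) * v2[succ(a, 1) - 1];
      }
    }

    double p1 = chosen_prob2(Q[s1 * 2], Q[s1 * 2 + 1], a1, tau);
    double p2 = chosen_prob2(Q[s2 * 2], Q[s2 * 2 + 1], a2, tau);
    probs(t, 0) = p1;
    probs(t, 1) = p2;
    trial_lik[t] = p1 * p2;
    nll -= std::log(std::max(p1, floor_p)) + std::log(std::max(p2, floor_p));

    if (kind == 0) {
      // SARSA: intermediate reward 0, bootstrap from the chosen a2;
      // terminal reward = paid coins, bootstrap 0
      const int r1 = s1 * 2 + a1, r2 = s2 * 2 + a2;
      Q[r1] += rate * (0.0 + Q[r2] - Q[r1]);
      Q[r2] += rate * (reward[t] + 0.0 - Q[r2]);
    } else {
      // state-prediction-error updates of both observed transitions
      const int r1 = s1 * 2 + a1, r2 = s2 * 2 + a2;
      double obs1 = (succ(r1, 0) == s2) ? 1.0 : 0.0;
      T[r1] = T[r1] * (1.0 - rate) + rate * obs1;
      double obs2 = (succ(r2, 0) == s3) ? 1.0 : 0.0;
      T[r2] = T[r2] * (1.0 - rate) + rate * obs2;
    }
  }

  return List::create(_["nll"] = nll, _["decision_prob"] = probs,
                      _["trial_likelihood"] = trial_lik);
}
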