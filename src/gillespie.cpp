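#include <Rcpp.h>
using namespace Rcpp;

// Exact (Gillespie) simulation of the one-species birth-death chain with
// rates B(n) = lambda_bar * n * (1 - n/N) (clipped at 0) and D(n) = mu * n.
// Uses R's RNG so results are reproducible under set.seed(). Population
// sizes are recorded at the requested (sorted, nonnegative) sample times;
// the full event list is returned only when keep_events is true.
//
// [[Rcpp::export(name = ".gillespie_invader")]]
List gillespie_invader(double lambda_bar, double mu, double N, int n0,
                       double t_end, NumericVector sample_times,
                       bool keep_events) {
  RNGScope scope;
  const int ns = sample_times.size();
  IntegerVector sampled(ns);
  std::vector<double> ev_t;
  std::vector<int> ev_n;
  double t = 0.0;
  long long n = n0;
  int si = 0;
  if (keep_events) { ev_t.push_back(0.0); ev_n.push_back(n0); }

  while (true) {
    double nb = (double)n;
    double B = lambda_bar * nb * (1.0 - nb / N);
    if (B < 0.0) B = 0.0;
    double D = mu * nb;
    double R = B + D;
    double t_next;
    if (n == 0 || R <= 0.0) {
      t_next = R_PosInf;  // absorbed or frozen: no further events
    } else {
      t_next = t + exp_rand() / R;
    }
    double t_stop = (t_next < t_end) ? t_next : t_end;
    while (si < ns && sample_times[si] <= t_stop &&
           (sample_times[si] < t_next || t_next >= t_end)) {
      // record state before the next event fires
      if (sample_times[si] >= t) sampled[si] = (int)n;
      si++;
    }
    if (t_next >= t_end) break;
    t = t_next;
    if (unif_rand() * R < B) n++; else n--;
    if (keep_events) { ev_t.push_back(t); ev_n.push_back((int)n); }
    if (n == 0) {
      // absorbing: remaining sample times read 0
      while (si < ns) { sampled[si] = 0; si++; }
      break;
    }
  }
  while (si < ns) { sampled[si] = (int)n; si++; }

  List out = List::create(
    _["sampled"] = sampled,
    _["extinct"] = (n == 0),
    _["final_size"] = (int)n,
    _["n_events"] = (int)(keep_events ? (ev_t.size() - 1) : 0));
  if (keep_events) {
    out["event_times"] = NumericVector(ev_t.begin(), ev_t.end());
    out["event_sizes"] = IntegerVector(ev_n.begin(), ev_n.end());
  }
  return out;
}

// Exact joint simulation of the two-species competitive birth-death chain:
//   B_I = lambda_I nI (1 - (nI + aIR nR)/N_I),  D_I = mu_I nI
//   B_R = lambda_R nR (1 - (nR + aRI nI)/N_R),  D_R = mu_R nR
// with negative propensities clipped to 0.
//
// [[Rcpp::export(name = ".gillespie_pair")]]
List gillespie_pair(double lambda_I, double mu_I, double N_I, double aIR,
                    double lambda_R, double mu_R, double N_R, double aRI,
                    int nI0, int nR0, double t_end,
                    NumericVector sample_times, bool keep_events) {
  RNGScope scope;
  const int ns = sample_times.size();
  IntegerVector samp_I(ns), samp_R(ns);
  std::vector<double> ev_t;
  std::vector<int> ev_I, ev_R;
  double t = 0.0;
  long long nI = nI0, nR = nR0;
  int si = 0;
  if (keep_events) { ev_t.push_back(0.0); ev_I.push_back(nI0); ev_R.push_back(nR0); }

  while (true) {
    double bI = lambda_I * (double)nI * (1.0 - ((double)nI + aIR * (double)nR) / N_I);
    if (bI < 0.0) bI = 0.0;
    double dI = mu_I * (double)nI;
    double bR = lambda_R * (double)nR * (1.0 - ((double)nR + aRI * (double)nI) / N_R);
    if (bR < 0.0) bR = 0.0;
    double dR = mu_R * (double)nR;
    double R = bI + dI + bR + dR;
    double t_next = (R <= 0.0) ? R_PosInf : t + exp_rand() / R;
    double t_stop = (t_next < t_end) ? t_next : t_end;
    while (si < ns && sample_times[si] <= t_stop &&
           (sample_times[si] < t_next || t_next >= t_end)) {
      if (sample_times[si] >= t) { samp_I[si] = (int)nI; samp_R[si] = (int)nR; }
      si++;
    }
    if (t_next >= t_end) break;
    t = t_next;
    double u = unif_rand() * R;
    if (u < bI) nI++;
    else if (u < bI + dI) nI--;
    else if (u < bI + dI + bR) nR++;
    else nR--;
    if (keep_events) { ev_t.push_back(t); ev_I.push_back((int)nI); ev_R.push_back((int)nR); }
  }
  while (si < ns) { samp_I[si] = (int)nI; samp_R[si] = (int)nR; si++; }

  List out = List::create(
    _["sampled_I"] = samp_I,
    _["sampled_R"] = samp_R,
    _["extinct"] = (nI == 0),
    _["final_I"] = (int)nI,
    _["final_R"] = (int)nR,
    _["n_events"] = (int)(keep_events ? (ev_t.size() - 1) : 0));
  if (keep_events) {
    out["event_times"] = NumericVector(ev_t.begin(), ev_t.end());
    out["event_sizes_I"] = IntegerVector(ev_I.begin(), ev_I.end());
    out["event_sizes_R"] = IntegerVector(ev_R.begin(), ev_R.end());
  }
  return out;
}
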