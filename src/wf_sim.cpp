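#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Weighted interlocutor choice: neighbour m of speaker n is picked with
// probability proportional to 1 + s * x[m].
static inline int pick_neighbor(const std::vector<int>& nb,
                                const std::vector<double>& x, double s) {
  const int z = (int)nb.size();
  if (s == 0.0) {
    int k = (int)(unif_rand() * z);
    if (k >= z) k = z - 1;
    return nb[k];
  }
  double tot = 0.0;
  for (int k = 0; k < z; ++k) tot += 1.0 + s * x[nb[k]];
  double u = unif_rand() * tot, acc = 0.0;
  for (int k = 0; k < z; ++k) {
    acc += 1.0 + s * x[nb[k]];
    if (u <= acc) return nb[k];
  }
  return nb[z - 1];
}

// Event-driven Wright-Fisher dynamics on a fixed social network.  Updates
// occur at total rate N * rate (asynchronous exponential clocks); in an
// update, speaker n hears neighbour m and replaces a fraction eps of its
// stored experience with the perceived variant.  Absorption is declared
// when the population mean frequency leaves [tol, 1 - tol].
// [[Rcpp::export(".wf_simulate_cpp")]]
List wf_simulate_cpp(List adj, double eps, double s, double eta, double rate,
                     std::string x0_mode, double x0_value, int n_reps,
                     double tol, double max_events, bool record,
                     int record_every) {
  RNGScope scope;
  const int N = adj.size();
  std::vector<std::vector<int> > nbrs(N);
  for (int i = 0; i < N; ++i) {
    IntegerVector v = adj[i];
    nbrs[i].assign(v.begin(), v.end());
  }
  IntegerVector status_out(n_reps);
  NumericVector time_out(n_reps), events_out(n_reps);
  std::vector<double> traj_t, traj_x;
  const double total_rate = (double)N * rate;

  for (int rep = 0; rep < n_reps; ++rep) {
    std::vector<double> x(N, 0.0);
    double S = 0.0;
    if (x0_mode == "single") {
      int seedn = (int)(unif_rand() * N);
      if (seedn >= N) seedn = N - 1;
      x[seedn] = x0_value;
      S = x0_value;
    } else {
      for (int i = 0; i < N; ++i) x[i] = x0_value;
      S = x0_value * (double)N;
    }
    double t = 0.0;
    long long ev = 0;
    int status = -1;  // -1 running, 0 lost, 1 fixed
    if (S <= tol * N) status = 0;
    else if (S >= (1.0 - tol) * N) status = 1;
    if (record && rep == 0) { traj_t.push_back(0.0); traj_x.push_back(S / N); }

    while (status < 0 && (double)ev < max_events) {
      t += R::rexp(1.0) / total_rate;
      int n = (int)(unif_rand() * N);
      if (n >= N) n = N - 1;
      if (!nbrs[n].empty()) {
        int m = pick_neighbor(nbrs[n], x, s);
        double xm = x[m];
        double pperc = xm + (1.0 - xm) * eta;
        double tau = (unif_rand() < pperc) ? 1.0 : 0.0;
        double xn2 = (1.0 - eps) * x[n] + eps * tau;
        S += xn2 - x[n];
        x[n] = xn2;
      }
      ++ev;
      if (ev % 4000000LL == 0LL) {  // curb floating drift of the running sum
        S = 0.0;
        for (int i = 0; i < N; ++i) S += x[i];
      }
      if (record && rep == 0 && ev % record_every == 0LL) {
        traj_t.push_back(t);
        traj_x.push_back(S / N);
      }
      if (S <= tol * N) status = 0;
      else if (S >= (1.0 - tol) * N) status = 1;
    }
    status_out[rep] = status;
    time_out[rep] = t;
    events_out[rep] = (double)ev;
  }
  List out = List::create(_["status"] = status_out, _["time"] = time_out,
                          _["events"] = events_out);
  if (record) {
    out["traj_time"] = NumericVector(traj_t.begin(), traj_t.end());
    out["traj_freq"] = NumericVector(traj_x.begin(), traj_x.end());
  }
  return out;
}
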