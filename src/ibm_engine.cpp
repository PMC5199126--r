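// Within-cycle event loop of the genotype-structured individual-based model.
//
// Cells with identical genotype (same lineage entry) divide synchronously:
// a genotype of count n doubles to 2n at its next division time. After each
// division event, a random number of the n just-divided daughter cells is
// converted into new single-cell genotypes by the active mutation model.
// The cycle stops at the first division event at which the total population
// reaches 2^M * N; simultaneous events are processed in genotype-id order
// and the stop condition is checked after each genotype's doubling.
//
// All randomness goes through R's RNG so runs are reproducible from
// set.seed(); with mutations disabled the event sequence is identical to
// the pure-R reference engine.

#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

namespace {

struct Ev {
  double t;
  int id;
};
struct EvCmp {
  bool operator()(const Ev& a, const Ev& b) const {
    if (a.t != b.t) return a.t > b.t;
    return a.id > b.id;
  }
};

struct Pop {
  std::vector<double> count, lag, tau;
  std::vector<int> mask;
};

// gamma draw bridged to the dimensionless raw coefficient s_r; the raw draw
// is a doubling-time change in minutes, truncation handled downstream
inline double draw_sr(double shape, double scale, double Twt) {
  double raw = R::rgamma(shape, scale);
  if (raw >= Twt) return R_PosInf;
  return raw / (Twt - raw);
}

inline double dT_wt_of(double sr, double Twt, double TwtN) {
  double raw = (sr == R_PosInf) ? Twt : Twt * sr / (sr + 1.0);
  return std::min(raw, Twt - TwtN);
}

inline double dL_wt_of(double sr, double tau_carrier, double M, double Lwt,
                       double LwtN) {
  if (sr == R_PosInf) return Lwt - LwtN;
  return std::min(sr * M * tau_carrier, Lwt - LwtN);
}

}  // namespace

// [[Rcpp::export(name = ".ibm_advance_cycle_cpp")]]
List ibm_advance_cycle_cpp(NumericVector count0, NumericVector lag0,
                           NumericVector tau0, IntegerVector mask0,
                           double target_total, int model, List pars) {
  const int n_in = count0.size();
  Pop pop;
  pop.count.assign(count0.begin(), count0.end());
  pop.lag.assign(lag0.begin(), lag0.end());
  pop.tau.assign(tau0.begin(), tau0.end());
  pop.mask.assign(mask0.begin(), mask0.end());

  // DFE model parameters
  double p_aff = 0, z = 0, shape = 2, scale = 33, Twt = 162, TwtN = 126,
         Lwt = 805, LwtN = 271, Mdoub = 5;
  int variant = 2;
  // targeted model parameters
  std::vector<double> p_ch, ch_lag, ch_tau;
  if (model == 1) {
    p_aff = as<double>(pars["p_affect"]);
    z = as<double>(pars["z"]);
    shape = as<double>(pars["shape"]);
    scale = as<double>(pars["scale"]);
    Twt = as<double>(pars["T_wt"]);
    TwtN = as<double>(pars["T_wt_N"]);
    Lwt = as<double>(pars["L_wt"]);
    LwtN = as<double>(pars["L_wt_N"]);
    Mdoub = as<double>(pars["M"]);
    variant = as<int>(pars["variant"]);
  }
  std::vector<double> ch_score;
  if (model == 2) {
    NumericVector p = pars["p_channel"], cl = pars["channel_lag"],
                  ct = pars["channel_doubling"], cs = pars["channel_score"];
    p_ch.assign(p.begin(), p.end());
    ch_lag.assign(cl.begin(), cl.end());
    ch_tau.assign(ct.begin(), ct.end());
    ch_score.assign(cs.begin(), cs.end());
  }

  std::priority_queue<Ev, std::vector<Ev>, EvCmp> q;
  double total = 0;
  for (int i = 0; i < n_in; ++i) {
    total += pop.count[i];
    if (pop.count[i] > 0) q.push({pop.lag[i] + pop.tau[i], i});
  }
  if (total <= 0) stop("population is empty");
  if (total >= target_total)
    stop("population already at or above the cycle target");

  double t_end = 0;
  long n_events = 0;
  const size_t max_genotypes = 20000000;

  while (true) {
    if (q.empty()) stop("no dividing genotypes left before the cycle target");
    Ev e = q.top();
    q.pop();
    const int i = e.id;
    const double t = e.t;
    const double n = pop.count[i];
    ++n_events;
    if (n <= 0) continue;  // lineage emptied by mutation since scheduling
    pop.count[i] = 2.0 * n;
    total += n;
    t_end = t;

    if (model == 1 && p_aff > 0) {
      // only fitness-affecting mutations change the phenotype and therefore
      // need a new lineage; neutral mutations leave the carrier unchanged
      double nm = R::rbinom(n, p_aff);
      if (nm > 0) {
        pop.count[i] -= nm;
        for (int k = 0; k < (int)nm; ++k) {
          double newlag = pop.lag[i], newtau = pop.tau[i];
          if (variant == 1 || variant == 2) {
            const bool ben = unif_rand() < z;
            const double sr = draw_sr(shape, scale, Twt);
            const double dTwt = dT_wt_of(sr, Twt, TwtN);
            if (ben) {
              newtau -= dTwt * (newtau - TwtN) / (Twt - TwtN);
              if (variant == 2) {
                const double dLwt = dL_wt_of(sr, pop.tau[i], Mdoub, Lwt, LwtN);
                newlag -= dLwt * (newlag - LwtN) / (Lwt - LwtN);
              }
            } else {
              newtau += std::min(dTwt, Twt - newtau);
              if (variant == 2) {
                const double dLwt = dL_wt_of(sr, pop.tau[i], Mdoub, Lwt, LwtN);
                newlag += std::min(dLwt, Lwt - newlag);
              }
            }
          } else {  // M3: independent sign and magnitude per component
            const bool benT = unif_rand() < z;
            const double srT = draw_sr(shape, scale, Twt);
            const double dTwt = dT_wt_of(srT, Twt, TwtN);
            if (benT)
              newtau -= dTwt * (newtau - TwtN) / (Twt - TwtN);
            else
              newtau += std::min(dTwt, Twt - newtau);
            const bool benL = unif_rand() < z;
            const double srL = draw_sr(shape, scale, Twt);
            const double dLwt = dL_wt_of(srL, pop.tau[i], Mdoub, Lwt, LwtN);
            if (benL)
              newlag -= dLwt * (newlag - LwtN) / (Lwt - LwtN);
            else
              newlag += std::min(dLwt, Lwt - newlag);
          }
          newtau = std::min(std::max(newtau, TwtN), Twt);
          newlag = std::min(std::max(newlag, LwtN), Lwt);
          pop.count.push_back(1.0);
          pop.lag.push_back(newlag);
          pop.tau.push_back(newtau);
          pop.mask.push_back(0);
          q.push({t + newtau, (int)pop.count.size() - 1});
        }
        if (pop.count.size() > max_genotypes) stop("too many genotypes");
      }
    } else if (model == 2) {
      double avail = n;
      for (size_t c = 0; c < p_ch.size() && avail > 0; ++c) {
        if (p_ch[c] <= 0) continue;
        double nm = R::rbinom(avail, p_ch[c]);
        if (nm <= 0) continue;
        nm = std::min(nm, avail);
        avail -= nm;
        pop.count[i] -= nm;
        const int newmask = pop.mask[i] | (1 << c);
        // complete negative epistasis: phenotype of the fittest carried
        // allele (highest selection coefficient against the founder; ties
        // by smaller doubling time, then smaller lag)
        double best_tau = R_PosInf, best_lag = R_PosInf;
        double best_score = R_NegInf;
        for (size_t b = 0; b < p_ch.size(); ++b) {
          if (newmask & (1 << b)) {
            if (ch_score[b] > best_score ||
                (ch_score[b] == best_score &&
                 (ch_tau[b] < best_tau ||
                  (ch_tau[b] == best_tau && ch_lag[b] < best_lag)))) {
              best_score = ch_score[b];
              best_tau = ch_tau[b];
              best_lag = ch_lag[b];
            }
          }
        }
        for (int k = 0; k < (int)nm; ++k) {
          pop.count.push_back(1.0);
          pop.lag.push_back(best_lag);
          pop.tau.push_back(best_tau);
          pop.mask.push_back(newmask);
          q.push({t + best_tau, (int)pop.count.size() - 1});
        }
        if (pop.count.size() > max_genotypes) stop("too many genotypes");
      }
    }

    q.push({t + pop.tau[i], i});
    if (total >= target_total) break;
  }

  return List::create(_["count"] = wrap(pop.count), _["lag"] = wrap(pop.lag),
                      _["doubling_time"] = wrap(pop.tau),
                      _["mask"] = wrap(pop.mask), _["t_end"] = t_end,
                      _["n_events"] = (double)n_events);
}
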