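// Annual-cycle core of the Markov cohort model. Semantics:
//  - all flows computed simultaneously on start-of-cycle occupancy,
//    per-cell competing-risk normalization when total exit probability
//    would exceed 1;
//  - then ageing (age 100 absorbs), births into age 0, subthreshold
//    entry/exit bookkeeping at the eligibility boundaries, and net
//    migration applied proportionally to compartment occupancy with
//    outflows clipped at the available population.
// Event tallies are indexed by start-of-year age.

#include <Rcpp.h>
using namespace Rcpp;

static const int NA_ = 101;  // ages 0..100
static const int NS_ = 2;    // female, male

// [[Rcpp::export]]
List markov_engine_cpp(NumericMatrix S0, NumericMatrix U0, NumericMatrix D0,
                       NumericMatrix p_inc_S0, NumericMatrix p_inc_U0,
                       NumericMatrix p_sui0, NumericMatrix p_sui_D0,
                       NumericMatrix p_oth, NumericMatrix p_rem,
                       NumericMatrix inc_r, NumericMatrix sui_r,
                       NumericMatrix mig0, NumericVector f_vec,
                       double cov_base, double rr_inc, double rr_sui,
                       double mult, double dmult, LogicalVector elig,
                       int a_entry, int a_exit, double sub_frac,
                       NumericVector newborns, int horizon, bool active,
                       bool indicated, bool keep_trace) {
  std::vector<double> S(S0.begin(), S0.end());
  std::vector<double> U(U0.begin(), U0.end());
  std::vector<double> D(D0.begin(), D0.end());
  std::vector<double> dead_s(NA_ * NS_, 0.0), dead_o(NA_ * NS_, 0.0);
  std::vector<double> Sn(NA_ * NS_), Un(NA_ * NS_), Dn(NA_ * NS_);

  NumericVector incident_total(horizon), suicide_total(horizon),
      other_total(horizon), prevalent_cases(horizon), alive_total(horizon),
      eligible_pop(horizon);
  NumericMatrix suicides_by_age(horizon, NA_);

  const int ny = horizon + 1;
  NumericVector occ_S, occ_U, occ_D, occ_ds, occ_do, ev_inc, ev_sui, ev_oth,
      ev_mig;
  if (keep_trace) {
    occ_S = NumericVector(ny * NA_ * NS_);
    occ_U = NumericVector(ny * NA_ * NS_);
    occ_D = NumericVector(ny * NA_ * NS_);
    occ_ds = NumericVector(ny * NA_ * NS_);
    occ_do = NumericVector(ny * NA_ * NS_);
    ev_inc = NumericVector(horizon * NA_ * NS_);
    ev_sui = NumericVector(horizon * NA_ * NS_);
    ev_oth = NumericVector(horizon * NA_ * NS_);
    ev_mig = NumericVector(horizon * NA_ * NS_);
    for (int c = 0; c < NA_ * NS_; ++c) {
      int a = c % NA_, s = c / NA_;
      occ_S[0 + ny * (a + NA_ * s)] = S[c];
      occ_U[0 + ny * (a + NA_ * s)] = U[c];
      occ_D[0 + ny * (a + NA_ * s)] = D[c];
    }
  }
  bool normalized = false, clipped = false;

  for (int t = 0; t < horizon; ++t) {
    double f = f_vec[t];
    double covf = 0.0, rri = 1.0, rrs = 1.0;
    bool treat = active && f > 0.0;
    if (treat) {
      covf = f * cov_base;
      rri = 1.0 - covf * (1.0 - rr_inc);
      rrs = 1.0 - covf * (1.0 - rr_sui);
    }
    double prev_t = 0.0, alive_t = 0.0, elig_t = 0.0, inc_t = 0.0,
           sui_t = 0.0, oth_t = 0.0;

    for (int s = 0; s < NS_; ++s) {
      for (int a = 0; a < NA_; ++a) {
        int c = a + NA_ * s;
        double Sc = S[c], Uc = U[c], Dc = D[c];
        prev_t += Dc;
        alive_t += Sc + Uc + Dc;
        if (elig[a]) elig_t += Sc + Uc + Dc;

        double pSi = p_inc_S0[c], pUi = p_inc_U0[c];
        double pSs = p_sui0[c], pUs = p_sui0[c], pDs = p_sui_D0[c];
        double po = p_oth[c], pr = p_rem[c];
        if (treat && elig[a]) {
          pUi = 1.0 - std::exp(-inc_r[c] * mult * rri);
          pUs = 1.0 - std::exp(-sui_r[c] * rrs);
          if (!indicated) {
            pSi = 1.0 - std::exp(-inc_r[c] * rri);
            pSs = pUs;
            pDs = 1.0 - std::exp(-sui_r[c] * dmult * rrs);
          }
        }
        // competing-risk normalization, per alive compartment
        double eS = pSi + pSs + po;
        if (eS > 1.0) { pSi /= eS; pSs /= eS; normalized = true; }
        double poS = eS > 1.0 ? po / eS : po;
        double eU = pUi + pUs + po;
        if (eU > 1.0) { pUi /= eU; pUs /= eU; normalized = true; }
        double poU = eU > 1.0 ? po / eU : po;
        double eD = pr + pDs + po;
        if (eD > 1.0) { pr /= eD; pDs /= eD; normalized = true; }
        double poD = eD > 1.0 ? po / eD : po;

        double inc_S = Sc * pSi, sui_S = Sc * pSs, oth_S = Sc * poS;
        double inc_U = Uc * pUi, sui_U = Uc * pUs, oth_U = Uc * poU;
        double rem_D = Dc * pr, sui_D = Dc * pDs, oth_D = Dc * poD;

        double pool = Sc + Uc;
        double rem_to_U = pool > 0.0 ? rem_D * (Uc / pool) : 0.0;
        double rem_to_S = rem_D - rem_to_U;

        double incident = inc_S + inc_U;
        double suicides = sui_S + sui_U + sui_D;
        double others = oth_S + oth_U + oth_D;
        inc_t += incident;
        sui_t += suicides;
        oth_t += others;
        suicides_by_age(t, a) += suicides;
        dead_s[c] += suicides;
        dead_o[c] += others;
        if (keep_trace) {
          ev_inc[t + horizon * (a + NA_ * s)] += incident;
          ev_sui[t + horizon * (a + NA_ * s)] += suicides;
          ev_oth[t + horizon * (a + NA_ * s)] += others;
        }
        Sn[c] = Sc - inc_S - sui_S - oth_S + rem_to_S;
        Un[c] = Uc - inc_U - sui_U - oth_U + rem_to_U;
        Dn[c] = Dc + inc_S + inc_U - rem_D - sui_D - oth_D;
      }
    }
    prevalent_cases[t] = prev_t;
    alive_total[t] = alive_t;
    eligible_pop[t] = elig_t;
    incident_total[t] = inc_t;
    suicide_total[t] = sui_t;
    other_total[t] = oth_t;

    // ageing: shift up one age, 100+ absorbs, births enter at age 0
    for (int s = 0; s < NS_; ++s) {
      int off = NA_ * s;
      double s100 = Sn[off + 99] + Sn[off + 100];
      double u100 = Un[off + 99] + Un[off + 100];
      double d100 = Dn[off + 99] + Dn[off + 100];
      for (int a = 99; a >= 1; --a) {
        S[off + a] = Sn[off + a - 1];
        U[off + a] = Un[off + a - 1];
        D[off + a] = Dn[off + a - 1];
      }
      S[off + 100] = s100; U[off + 100] = u100; D[off + 100] = d100;
      S[off] = newborns[s]; U[off] = 0.0; D[off] = 0.0;

      // subthreshold split for the cohort entering eligibility
      double move = sub_frac * S[off + a_entry];
      S[off + a_entry] -= move;
      U[off + a_entry] += move;
      if (a_exit < NA_) {  // cohort ageing out of eligibility
        S[off + a_exit] += U[off + a_exit];
        U[off + a_exit] = 0.0;
      }
    }

    // net migration, proportional to compartment occupancy
    for (int c = 0; c < NA_ * NS_; ++c) {
      double m = mig0[c];
      if (m == 0.0) { if (keep_trace) { int a = c % NA_, s = c / NA_;
                        ev_mig[t + horizon * (a + NA_ * s)] = 0.0; } continue; }
      double tot = S[c] + U[c] + D[c];
      if (m < -tot) { m = -tot; clipped = true; }
      if (tot > 0.0) {
        S[c] += m * (S[c] / tot);
        U[c] += m * (U[c] / tot);
        D[c] += m * (D[c] / tot);
      } else if (m > 0.0) {
        S[c] += m;  // inflow into an empty cell joins the at-risk state
      }
      if (keep_trace) {
        int a = c % NA_, s = c / NA_;
        ev_mig[t + horizon * (a + NA_ * s)] = m;
      }
    }

    if (keep_trace) {
      for (int c = 0; c < NA_ * NS_; ++c) {
        int a = c % NA_, s = c / NA_;
        int idx = (t + 1) + ny * (a + NA_ * s);
        occ_S[idx] = S[c]; occ_U[idx] = U[c]; occ_D[idx] = D[c];
        occ_ds[idx] = dead_s[c]; occ_do[idx] = dead_o[c];
      }
    }
  }

  List out = List::create(
      _["incident_total"] = incident_total,
      _["suicide_total"] = suicide_total,
      _["other_total"] = other_total,
      _["prevalent_cases"] = prevalent_cases,
      _["alive_total"] = alive_total,
      _["eligible_pop"] = eligible_pop,
      _["suicides_by_age"] = suicides_by_age,
      _["normalized"] = normalized,
      _["clipped"] = clipped);
  if (keep_trace) {
    out["occ_S"] = occ_S; out["occ_U"] = occ_U; out["occ_D"] = occ_D;
    out["occ_dead_suicide"] = occ_ds; out["occ_dead_other"] = occ_do;
    out["ev_incident"] = ev_inc; out["ev_suicide"] = ev_sui;
    out["ev_other"] = ev_oth; out["ev_migrants"] = ev_mig;
  }
  return out;
}
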