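// Production engine for the fishery self-governance model.
//
// This is a line-by-line mirror of the pure-R reference engine in
// R/engine_r.R: it consumes R's global RNG stream in the identical order and
// reproduces R's floating-point semantics (long-double accumulation where
// the reference uses sum()), so both engines yield bit-identical
// trajectories from the same seed.  See engine_r.R for the documented RNG
// consumption contract; any behavioural change must be made in both files.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

struct Config {
  int n_fishers;
  double reliability_mean, reliability_sd;
  double skills_mean, skills_sd;
  double initial_loyalty_mean, initial_loyalty_sd;
  double initial_capital, loyalty_half_saturation;
  double K, r, q, N0;
  int regime;                       // 0 det, 1 stochastic, 2 seasonal
  double stochastic_cv, seasonal_amplitude;
  double price, fishing_cost, beach_price_fraction;
  double loyalty_growth, coop_rate_fraction, loyalty_decay;
  double membership_fee, contribution_rate, capital_threshold;
  int min_size;
  double known_fraction;
  int cheat_variant;                // 0 corrected, 1 as_printed
  bool cheating_enabled, entry_enabled;
  double buyer_endowment;
  int entry_members;
  double market_share;
  int n_init_buyers, n_init_coops, years;
};

struct State {
  Config cfg;
  std::vector<double> rel, skl, loyalty, capital;
  std::vector<int> org;             // 0 = inactive, else 1-based org id
  std::vector<bool> patron;
  std::vector<int> cheats;

  std::vector<int> o_kind;          // 1 pc, 2 coop
  std::vector<bool> o_alive;
  std::vector<double> o_capital;
  std::vector<int> o_entry_year, o_patron;
  std::vector<std::vector<int> > o_known;   // 1-based fisher ids
  std::vector<double> delivered;

  double N;
  int day;
  double money_in, money_out, write_off;

  std::vector<double> daily;        // row-major, 17 cols
  std::vector<double> census;      // 8 cols
  std::vector<double> events;      // 7 cols
};

const int NDAILY = 17, NCENSUS = 8, NEVENTS = 7;

// partial Fisher-Yates, one uniform per pick; pool holds 1-based ids
std::vector<int> fy_sample(std::vector<int> pool, int m) {
  int n = (int)pool.size();
  if (m > n) m = n;
  std::vector<int> out;
  out.reserve(m);
  for (int k = 1; k <= m; ++k) {
    int j = k + (int)std::floor(unif_rand() * (double)(n - k + 1));
    if (j > n) j = n;
    std::swap(pool[k - 1], pool[j - 1]);
    out.push_back(pool[k - 1]);
  }
  return out;
}

std::vector<int> inactive_ids(const State& S) {
  std::vector<int> out;
  for (int i = 0; i < S.cfg.n_fishers; ++i)
    if (S.org[i] == 0) out.push_back(i + 1);
  return out;
}

std::vector<int> members_of(const State& S, int oid) {   // oid 1-based
  std::vector<int> out;
  for (int i = 0; i < S.cfg.n_fishers; ++i)
    if (S.org[i] == oid && !S.patron[i]) out.push_back(i + 1);
  return out;
}

void log_event(State& S, int year, int org_id, int kind, int event,
               int reason = 0, int age = -1, int founder = 0) {
  double row[NEVENTS] = {(double)year, (double)org_id, (double)kind,
                         (double)event, (double)reason, (double)age,
                         (double)founder};
  S.events.insert(S.events.end(), row, row + NEVENTS);
}

int add_buyer(State& S, int founder, int year) {
  const Config& c = S.cfg;
  int oid = (int)S.o_kind.size() + 1;
  double cap = c.buyer_endowment;
  S.money_in += c.buyer_endowment;
  if (founder > 0) {
    cap += S.capital[founder - 1];
    S.capital[founder - 1] = 0;
    S.patron[founder - 1] = true;
    S.org[founder - 1] = oid;
  }
  S.o_kind.push_back(1);
  S.o_alive.push_back(true);
  S.o_capital.push_back(cap);
  S.o_entry_year.push_back(year);
  S.o_patron.push_back(founder);
  int nk = (int)std::lround(c.known_fraction * (double)c.n_fishers);
  std::vector<int> all(c.n_fishers);
  for (int i = 0; i < c.n_fishers; ++i) all[i] = i + 1;
  S.o_known.push_back(fy_sample(all, nk));
  std::vector<int> members = fy_sample(inactive_ids(S), c.entry_members);
  for (size_t k = 0; k < members.size(); ++k) {
    S.org[members[k] - 1] = oid;
    S.loyalty[members[k] - 1] = 0;
  }
  return oid;
}

int add_coop(State& S, int year) {
  const Config& c = S.cfg;
  int oid = (int)S.o_kind.size() + 1;
  S.o_kind.push_back(2);
  S.o_alive.push_back(true);
  S.o_capital.push_back(0.0);
  S.o_entry_year.push_back(year);
  S.o_patron.push_back(0);
  S.o_known.push_back(std::vector<int>());
  std::vector<int> members = fy_sample(inactive_ids(S), c.entry_members);
  for (size_t k = 0; k < members.size(); ++k) {
    S.org[members[k] - 1] = oid;
    double l = R::rnorm(c.initial_loyalty_mean, c.initial_loyalty_sd);
    S.loyalty[members[k] - 1] = l > 0 ? l : 0;
  }
  return oid;
}

void annual_entry(State& S, int year) {
  const Config& c = S.cfg;
  std::vector<int> pool = inactive_ids(S);
  if ((int)pool.size() >= c.entry_members + 1) {
    int founder = pool[0];
    double best = S.capital[pool[0] - 1];
    for (size_t k = 1; k < pool.size(); ++k)
      if (S.capital[pool[k] - 1] > best) {          // strict: first max wins
        best = S.capital[pool[k] - 1];
        founder = pool[k];
      }
    int oid = add_buyer(S, founder, year);
    log_event(S, year, oid, 1, 1, 0, -1, founder);
  } else {
    log_event(S, year, 0, 1, 3);
  }
  pool = inactive_ids(S);
  if ((int)pool.size() >= c.entry_members) {
    int oid = add_coop(S, year);
    log_event(S, year, oid, 2, 1);
  } else {
    log_event(S, year, 0, 2, 3);
  }
}

bool under_supplied(const State& S, int oid) {
  long double acc = 0.0L;
  for (int i = 0; i < S.cfg.n_fishers; ++i)
    if (S.org[i] == oid && !S.patron[i]) acc += S.skl[i];
  double s = (double)acc;
  return S.cfg.q * S.N * s < S.cfg.market_share;
}

void select_crews(State& S) {
  std::vector<int> buyers;
  for (size_t o = 0; o < S.o_kind.size(); ++o)
    if (S.o_alive[o] && S.o_kind[o] == 1) buyers.push_back((int)o + 1);
  if (buyers.empty()) return;
  while (true) {
    // round A: each under-supplied buyer signs its best-known inactive fisher
    for (size_t bi = 0; bi < buyers.size(); ++bi) {
      int b = buyers[bi];
      if (!under_supplied(S, b)) continue;
      const std::vector<int>& known = S.o_known[b - 1];
      std::vector<int> cand;
      for (size_t k = 0; k < known.size(); ++k)
        if (S.org[known[k] - 1] == 0) cand.push_back(known[k]);
      if (cand.empty()) continue;
      std::sort(cand.begin(), cand.end());
      int pick = cand[0];
      double best = S.rel[cand[0] - 1] * S.skl[cand[0] - 1];
      for (size_t k = 1; k < cand.size(); ++k) {
        double sc = S.rel[cand[k] - 1] * S.skl[cand[k] - 1];
        if (sc > best) { best = sc; pick = cand[k]; }
      }
      S.org[pick - 1] = b;
      S.loyalty[pick - 1] = 0;
    }
    std::vector<int> und;
    for (size_t bi = 0; bi < buyers.size(); ++bi)
      if (under_supplied(S, buyers[bi])) und.push_back(buyers[bi]);
    std::vector<int> pool = inactive_ids(S);
    if (und.empty() || pool.empty()) break;
    // round B: random inactive fisher approaches a random needy buyer
    int fi = 1 + (int)std::floor(unif_rand() * (double)pool.size());
    if (fi > (int)pool.size()) fi = (int)pool.size();
    int bj = 1 + (int)std::floor(unif_rand() * (double)und.size());
    if (bj > (int)und.size()) bj = (int)und.size();
    int f = pool[fi - 1], b = und[bj - 1];
    S.org[f - 1] = b;
    S.loyalty[f - 1] = 0;
    bool any_under = false;
    for (size_t bi = 0; bi < buyers.size(); ++bi)
      if (under_supplied(S, buyers[bi])) { any_under = true; break; }
    if (!any_under || inactive_ids(S).empty()) break;
  }
}

void renew_contracts(State& S, int oid) {
  std::vector<int> mem = members_of(S, oid);
  int k = (int)mem.size();
  if (k == 0) return;
  double avg = S.delivered[oid - 1] / (double)k;
  if (avg <= 0) return;
  while (k > 0 && (double)k * avg > S.cfg.market_share + avg) {
    mem = members_of(S, oid);
    int drop = mem[0];
    double worst = S.loyalty[mem[0] - 1];
    for (size_t j = 1; j < mem.size(); ++j)
      if (S.loyalty[mem[j] - 1] < worst) {          // strict: first min wins
        worst = S.loyalty[mem[j] - 1];
        drop = mem[j];
      }
    S.org[drop - 1] = 0;
    S.loyalty[drop - 1] = 0;
    --k;
  }
}

void expel_member(State& S, int oid) {
  std::vector<int> mem = members_of(S, oid);
  for (size_t j = 0; j < mem.size(); ++j)
    if (S.loyalty[mem[j] - 1] <= 0) {
      S.org[mem[j] - 1] = 0;
      S.loyalty[mem[j] - 1] = 0;
    }
}

void dissolve_org(State& S, int oid, int year, int reason) {
  std::vector<int> mem = members_of(S, oid);
  double residual = S.o_capital[oid - 1];
  if (S.o_kind[oid - 1] == 2 && residual > 0 && !mem.empty()) {
    double each = residual / (double)mem.size();
    for (size_t j = 0; j < mem.size(); ++j)
      S.capital[mem[j] - 1] = S.capital[mem[j] - 1] + each;
    residual = 0;
  }
  S.write_off += residual;
  for (size_t j = 0; j < mem.size(); ++j) {
    S.org[mem[j] - 1] = 0;
    S.loyalty[mem[j] - 1] = 0;
  }
  int p = S.o_patron[oid - 1];
  if (p > 0) {
    S.patron[p - 1] = false;
    S.org[p - 1] = 0;
  }
  S.o_alive[oid - 1] = false;
  S.o_capital[oid - 1] = 0;
  log_event(S, year, oid, S.o_kind[oid - 1], 2, reason,
            year - S.o_entry_year[oid - 1]);
}

void dissolution_check(State& S, int year) {
  for (size_t o = 0; o < S.o_kind.size(); ++o) {
    if (!S.o_alive[o]) continue;
    int oid = (int)o + 1;
    if (S.o_kind[o] == 1) {
      if (S.o_capital[o] < 0) dissolve_org(S, oid, year, 1);
    } else {
      std::vector<int> mem = members_of(S, oid);
      // co-op capital is the members' aggregate: pot + sum of member capital
      long double mcap = 0.0L;
      for (size_t j = 0; j < mem.size(); ++j) mcap += S.capital[mem[j] - 1];
      if (S.o_capital[o] + (double)mcap < 0) {
        dissolve_org(S, oid, year, 1);
      } else {
        long double acc = 0.0L;
        for (size_t j = 0; j < mem.size(); ++j) acc += S.loyalty[mem[j] - 1];
        if ((double)acc <= 0) dissolve_org(S, oid, year, 2);
        else if ((int)mem.size() < S.cfg.min_size)
          dissolve_org(S, oid, year, 3);
      }
    }
  }
}

void record_day(State& S, int day, int year, double harvest) {
  const Config& c = S.cfg;
  int npc = 0, nco = 0, npat = 0;
  long double rel_pc = 0.0L, rel_co = 0.0L;
  for (int i = 0; i < c.n_fishers; ++i) {
    if (S.patron[i]) { ++npat; continue; }
    if (S.org[i] > 0) {
      if (S.o_kind[S.org[i] - 1] == 1) { ++npc; rel_pc += S.rel[i]; }
      else { ++nco; rel_co += S.rel[i]; }
    }
  }
  int nb = 0, nc2 = 0;
  long double ocap = 0.0L;
  for (size_t o = 0; o < S.o_kind.size(); ++o)
    if (S.o_alive[o]) {
      if (S.o_kind[o] == 1) ++nb; else ++nc2;
      ocap += S.o_capital[o];
    }
  long double fcap = 0.0L;
  for (int i = 0; i < c.n_fishers; ++i) fcap += S.capital[i];
  double* row = &S.daily[(size_t)day * NDAILY];
  row[0] = day; row[1] = year; row[2] = S.N; row[3] = harvest;
  row[4] = npc; row[5] = nco; row[6] = npat;
  row[7] = c.n_fishers - npc - nco - npat;
  row[8] = nb; row[9] = nc2;
  row[10] = S.money_in; row[11] = S.money_out; row[12] = S.write_off;
  row[13] = (double)fcap; row[14] = (double)ocap;
  row[15] = npc > 0 ? (double)rel_pc / (double)npc : R_NaN;
  row[16] = nco > 0 ? (double)rel_co / (double)nco : R_NaN;
}

void record_census(State& S, int year) {
  for (size_t o = 0; o < S.o_kind.size(); ++o) {
    if (!S.o_alive[o]) continue;
    std::vector<int> mem = members_of(S, (int)o + 1);
    long double loy = 0.0L, mcap = 0.0L;
    for (size_t j = 0; j < mem.size(); ++j) {
      loy += S.loyalty[mem[j] - 1];
      mcap += S.capital[mem[j] - 1];
    }
    double cap_tot = S.o_capital[o] +
      (S.o_kind[o] == 2 ? (double)mcap : 0.0);
    double row[NCENSUS] = {(double)year, (double)(o + 1), (double)S.o_kind[o],
                           (double)(year - S.o_entry_year[o]),
                           S.o_capital[o], cap_tot, (double)loy,
                           (double)mem.size()};
    S.census.insert(S.census.end(), row, row + NCENSUS);
  }
}

void step_day(State& S) {
  const Config& c = S.cfg;
  int day = S.day;
  int year = day / 365;
  int doy = day % 365;

  if (doy == 0 && c.entry_enabled) annual_entry(S, year);
  S.delivered.assign(S.o_kind.size(), 0.0);

  select_crews(S);

  // loans
  for (size_t o = 0; o < S.o_kind.size(); ++o) {
    if (!S.o_alive[o]) continue;
    int nb = (int)members_of(S, (int)o + 1).size();
    S.o_capital[o] = S.o_capital[o] - c.fishing_cost * (double)nb;
    S.money_out += c.fishing_cost * (double)nb;
  }

  // fishing
  double factor = 1.0;
  if (c.regime == 1) {
    double sdlog = std::sqrt(std::log(1 + c.stochastic_cv * c.stochastic_cv));
    factor = std::exp(R::rnorm(-0.5 * sdlog * sdlog, sdlog));
  }
  std::vector<int> af;
  for (int i = 0; i < c.n_fishers; ++i)
    if (S.org[i] > 0 && !S.patron[i]) af.push_back(i + 1);
  std::vector<double> catchv(af.size());
  long double acc = 0.0L;
  for (size_t k = 0; k < af.size(); ++k) {
    catchv[k] = c.q * S.skl[af[k] - 1] * S.N * factor;
    acc += catchv[k];
  }
  double s = (double)acc;
  if (s > S.N && s > 0) {
    double scale = S.N / s;
    for (size_t k = 0; k < af.size(); ++k) catchv[k] = catchv[k] * scale;
  }
  acc = 0.0L;
  for (size_t k = 0; k < af.size(); ++k) acc += catchv[k];
  double harvest = (double)acc;

  // cheating decisions
  std::vector<bool> cheat(af.size(), false);
  if (c.cheating_enabled && !af.empty()) {
    double h = c.loyalty_half_saturation;
    for (size_t k = 0; k < af.size(); ++k) {
      int i = af[k];
      double a = unif_rand();
      double b = unif_rand();
      double idx = S.loyalty[i - 1] / (S.loyalty[i - 1] + h);
      bool gate = c.cheat_variant == 1 ? (S.rel[i - 1] > a)
                                       : (S.rel[i - 1] < a);
      cheat[k] = gate && idx < b;
    }
  }

  // settlement and loyalty
  double p = c.price, phi = c.beach_price_fraction, cost = c.fishing_cost;
  double g_coop = c.loyalty_growth * c.coop_rate_fraction;
  double d_pc = c.loyalty_decay;
  double d_coop = c.loyalty_decay * c.coop_rate_fraction;
  for (size_t k = 0; k < af.size(); ++k) {
    int i = af[k];
    int home = S.org[i - 1];
    double ci = catchv[k];
    if (cheat[k]) {
      std::vector<int> others;
      for (size_t o = 0; o < S.o_kind.size(); ++o)
        if (S.o_alive[o] && (int)o + 1 != home) others.push_back((int)o + 1);
      if (!others.empty()) {
        int oi = 1 + (int)std::floor(unif_rand() * (double)others.size());
        if (oi > (int)others.size()) oi = (int)others.size();
        int tgt = others[oi - 1];
        S.o_capital[tgt - 1] = S.o_capital[tgt - 1] + (1 - phi) * p * ci;
        S.money_in += p * ci;
      } else {
        S.money_in += phi * p * ci;
      }
      S.capital[i - 1] = S.capital[i - 1] + phi * p * ci;
      double di = S.o_kind[home - 1] == 2 ? d_coop : d_pc;
      double l = S.loyalty[i - 1] - di;
      S.loyalty[i - 1] = l > 0 ? l : 0;
      S.cheats[i - 1] += 1;
    } else if (S.o_kind[home - 1] == 1) {
      double value = p * ci;
      double beach = phi * value;
      double repay = std::min(cost, beach);
      S.capital[i - 1] = S.capital[i - 1] + beach - repay;
      S.o_capital[home - 1] = S.o_capital[home - 1] + (1 - phi) * value + repay;
      S.money_in += value;
      S.delivered[home - 1] += ci;
      S.loyalty[i - 1] = S.loyalty[i - 1] + c.loyalty_growth;
    } else {
      double value = p * ci;
      double repay = std::min(cost, value);
      S.capital[i - 1] = S.capital[i - 1] + value - repay - c.membership_fee;
      S.o_capital[home - 1] = S.o_capital[home - 1] + repay + c.membership_fee;
      if (S.capital[i - 1] > c.capital_threshold) {
        double contrib = c.contribution_rate * S.capital[i - 1];
        S.capital[i - 1] = S.capital[i - 1] - contrib;
        S.o_capital[home - 1] = S.o_capital[home - 1] + contrib;
      }
      S.money_in += value;
      S.delivered[home - 1] += ci;
      S.loyalty[i - 1] = S.loyalty[i - 1] + g_coop;
    }
  }

  // renewal, expulsion, dissolution
  for (size_t o = 0; o < S.o_kind.size(); ++o)
    if (S.o_alive[o] && S.o_kind[o] == 1) renew_contracts(S, (int)o + 1);
  for (size_t o = 0; o < S.o_kind.size(); ++o)
    if (S.o_alive[o] && S.o_kind[o] == 2) expel_member(S, (int)o + 1);
  dissolution_check(S, year);

  // stock update
  double amp = c.regime == 2 ? c.seasonal_amplitude : 0.0;
  double Kt = c.K * (1 + amp * std::sin(2 * M_PI * (double)doy / 365));
  double Nn = S.N + c.r * S.N * (1 - S.N / Kt) - harvest;
  S.N = Nn > 0 ? Nn : 0;

  record_day(S, day, year, harvest);
  if (doy == 364) record_census(S, year);
  S.money_in = 0; S.money_out = 0; S.write_off = 0;
  S.day = day + 1;
}

Config parse_config(const List& cfg) {
  Config c;
  c.n_fishers = as<int>(cfg["n_fishers"]);
  c.reliability_mean = as<double>(cfg["reliability_mean"]);
  c.reliability_sd = as<double>(cfg["reliability_sd"]);
  c.skills_mean = as<double>(cfg["skills_mean"]);
  c.skills_sd = as<double>(cfg["skills_sd"]);
  c.initial_loyalty_mean = as<double>(cfg["initial_loyalty_mean"]);
  c.initial_loyalty_sd = as<double>(cfg["initial_loyalty_sd"]);
  c.initial_capital = as<double>(cfg["initial_capital"]);
  c.loyalty_half_saturation = as<double>(cfg["loyalty_half_saturation"]);
  c.K = as<double>(cfg["K"]);
  c.r = as<double>(cfg["r"]);
  c.q = as<double>(cfg["q"]);
  c.N0 = as<double>(cfg["N0"]);
  std::string reg = as<std::string>(cfg["regime"]);
  c.regime = reg == "stochastic" ? 1 : (reg == "seasonal" ? 2 : 0);
  c.stochastic_cv = as<double>(cfg["stochastic_cv"]);
  c.seasonal_amplitude = as<double>(cfg["seasonal_amplitude"]);
  c.price = as<double>(cfg["price"]);
  c.fishing_cost = as<double>(cfg["fishing_cost"]);
  c.beach_price_fraction = as<double>(cfg["beach_price_fraction"]);
  c.loyalty_growth = as<double>(cfg["loyalty_growth"]);
  c.coop_rate_fraction = as<double>(cfg["coop_rate_fraction"]);
  c.loyalty_decay = as<double>(cfg["loyalty_decay"]);
  c.membership_fee = as<double>(cfg["membership_fee"]);
  c.contribution_rate = as<double>(cfg["contribution_rate"]);
  c.capital_threshold = as<double>(cfg["capital_threshold"]);
  c.min_size = as<int>(cfg["min_size"]);
  c.known_fraction = as<double>(cfg["known_fraction"]);
  c.cheat_variant =
    as<std::string>(cfg["cheat_rule_variant"]) == "as_printed" ? 1 : 0;
  c.cheating_enabled = as<bool>(cfg["cheating_enabled"]);
  c.entry_enabled = as<bool>(cfg["entry_enabled"]);
  c.buyer_endowment = as<double>(cfg["buyer_endowment"]);
  c.entry_members = as<int>(cfg["entry_members"]);
  c.market_share = as<double>(cfg["market_share"]);
  c.n_init_buyers = as<int>(cfg["n_init_buyers"]);
  c.n_init_coops = as<int>(cfg["n_init_coops"]);
  c.years = as<int>(cfg["years"]);
  return c;
}

} // namespace

// [[Rcpp::export(name = ".run_engine_cpp")]]
List run_engine_cpp(List cfg_list) {
  Config c = parse_config(cfg_list);
  State S;
  S.cfg = c;
  int n = c.n_fishers;
  S.rel.resize(n); S.skl.resize(n);
  for (int i = 0; i < n; ++i) {
    double x = R::rnorm(c.reliability_mean, c.reliability_sd);
    S.rel[i] = x < 0 ? 0 : (x > 1 ? 1 : x);
  }
  for (int i = 0; i < n; ++i) {
    double x = R::rnorm(c.skills_mean, c.skills_sd);
    S.skl[i] = x < 0 ? 0 : x;
  }
  S.loyalty.assign(n, 0.0);
  S.capital.assign(n, c.initial_capital);
  S.org.assign(n, 0);
  S.patron.assign(n, false);
  S.cheats.assign(n, 0);
  S.N = c.N0;
  S.day = 0;
  S.money_in = 0; S.money_out = 0; S.write_off = 0;
  int total = 365 * c.years;
  S.daily.assign((size_t)total * NDAILY, NA_REAL);
  for (int i = 0; i < c.n_init_buyers; ++i) add_buyer(S, 0, 0);
  for (int i = 0; i < c.n_init_coops; ++i) add_coop(S, 0);

  for (int d = 0; d < total; ++d) {
    step_day(S);
    if (d % 3650 == 0) Rcpp::checkUserInterrupt();
  }

  // row-major scratch -> column-major R matrices
  NumericMatrix daily(total, NDAILY);
  for (int i = 0; i < total; ++i)
    for (int j = 0; j < NDAILY; ++j)
      daily(i, j) = S.daily[(size_t)i * NDAILY + j];
  int ncr = (int)S.census.size() / NCENSUS;
  NumericMatrix census(ncr, NCENSUS);
  for (int i = 0; i < ncr; ++i)
    for (int j = 0; j < NCENSUS; ++j)
      census(i, j) = S.census[(size_t)i * NCENSUS + j];
  int ner = (int)S.events.size() / NEVENTS;
  NumericMatrix events(ner, NEVENTS);
  for (int i = 0; i < ner; ++i)
    for (int j = 0; j < NEVENTS; ++j)
      events(i, j) = S.events[(size_t)i * NEVENTS + j];

  return List::create(_["daily"] = daily, _["census"] = census,
                      _["events"] = events);
}
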