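#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Discrete-event engine for the signal-traffic model.
//
// Dynamics:
//  - External arrivals: one network-global Poisson process with rate
//    `rate_ext`; each arrival draws a uniform source and a uniform
//    destination != source, and the unit enters the source node under the
//    same buffer rules as an internal arrival.
//  - Each node is a single server with exponential(mu) service times and a
//    LIFO (last-come-first-served), non-preemptive queue of capacity K.
//  - Push-out buffer: an arrival at a node with a full queue is accepted
//    and the *oldest* queued unit is ejected and dropped (with K = 0 the
//    arriving unit is itself the only queue candidate and is lost).
//  - On service completion the unit hops instantaneously to a uniformly
//    random out-neighbour; landing on its destination removes it from the
//    network immediately (no queueing at the destination).
//  - All randomness comes from R's RNG stream via inverse-transform
//    sampling: exponential variates are -log(U)/rate, discrete choices are
//    floor(U * k). Seeding with set.seed in R gives bit-identical traces.
//
// Trace: one record per unit (source, destination, creation time, status,
// final time) and one segment per node visit (arrival, service start,
// departure; service start is NA if the unit was ejected while queued,
// both are NA-truncated if still present at t_end).

struct CompEvent {
  double t;
  int node;
  long token;
};
struct CompLater {
  bool operator()(const CompEvent &a, const CompEvent &b) const {
    return a.t > b.t;
  }
};

static inline double rexp_inv(double rate) {
  double u;
  do { u = unif_rand(); } while (u <= 0.0);
  return -std::log(u) / rate;
}

static inline int runif_int(int k) {
  int j = (int)(unif_rand() * k);
  return (j >= k) ? (k - 1) : j;
}

// [[Rcpp::export]]
List cpp_simulate(List adj, double rate_ext, double mu, int K, double t_end) {
  const int n = adj.size();
  std::vector<std::vector<int>> nbr(n);
  for (int i = 0; i < n; ++i) nbr[i] = as<std::vector<int>>(adj[i]);

  // unit records
  std::vector<int> u_src, u_dst, u_status;     // status: 0 in_network, 1 delivered, 2 dropped
  std::vector<double> u_created, u_final;
  std::vector<int> u_open;                     // open segment index per unit
  // segments
  std::vector<int> s_uid, s_node;
  std::vector<double> s_arr, s_start, s_dep;

  // node state
  std::vector<int> serving(n, -1);
  std::vector<std::vector<int>> queue_(n);     // back = newest, front = oldest
  std::vector<long> token(n, 0);
  std::priority_queue<CompEvent, std::vector<CompEvent>, CompLater> comps;

  auto schedule = [&](int i, double t) {
    ++token[i];
    comps.push(CompEvent{t + rexp_inv(mu), i, token[i]});
  };

  auto open_segment = [&](int u, int node, double t) {
    u_open[u] = (int)s_uid.size();
    s_uid.push_back(u);
    s_node.push_back(node);
    s_arr.push_back(t);
    s_start.push_back(NA_REAL);
    s_dep.push_back(NA_REAL);
  };

  // arrival of unit u at node j (j != destination, guaranteed by caller)
  auto handle_arrival = [&](int j, int u, double t) {
    open_segment(u, j, t);
    if (serving[j] < 0) {
      serving[j] = u;
      s_start[u_open[u]] = t;
      schedule(j, t);
    } else {
      queue_[j].push_back(u);
      if ((int)queue_[j].size() > K) {
        const int old = queue_[j].front();
        queue_[j].erase(queue_[j].begin());
        s_dep[u_open[old]] = t;
        u_status[old] = 2;
        u_final[old] = t;
      }
    }
  };

  double t_arr = (rate_ext > 0.0) ? rexp_inv(rate_ext) : R_PosInf;

  while (true) {
    // next valid completion
    double t_comp = R_PosInf;
    while (!comps.empty()) {
      const CompEvent &e = comps.top();
      if (e.token == token[e.node] && serving[e.node] >= 0) {
        t_comp = e.t;
        break;
      }
      comps.pop();
    }
    const double t_next = (t_arr < t_comp) ? t_arr : t_comp;
    if (t_next > t_end) break;

    if (t_arr <= t_comp) {
      // external arrival: new unit, uniform source, uniform dest != source
      const int s = runif_int(n);
      int d = runif_int(n - 1);
      if (d >= s) ++d;
      const int u = (int)u_src.size();
      u_src.push_back(s);
      u_dst.push_back(d);
      u_status.push_back(0);
      u_created.push_back(t_arr);
      u_final.push_back(NA_REAL);
      u_open.push_back(-1);
      handle_arrival(s, u, t_arr);
      t_arr += rexp_inv(rate_ext);
    } else {
      const CompEvent e = comps.top();
      comps.pop();
      const int i = e.node;
      const double t = e.t;
      const int u = serving[i];
      s_dep[u_open[u]] = t;
      const std::vector<int> &out = nbr[i];
      const int j = out[runif_int((int)out.size())];
      if (j == u_dst[u]) {
        u_status[u] = 1;
        u_final[u] = t;
      } else {
        handle_arrival(j, u, t);
      }
      if (!queue_[i].empty()) {
        const int v = queue_[i].back();
        queue_[i].pop_back();
        serving[i] = v;
        s_start[u_open[v]] = t;
        schedule(i, t);
      } else {
        serving[i] = -1;
        ++token[i];  // invalidate any stale completion
      }
    }
  }

  const int nu = (int)u_src.size();
  IntegerVector uid(nu), usrc(nu), udst(nu), ustat(nu);
  NumericVector ucre(nu), ufin(nu);
  for (int u = 0; u < nu; ++u) {
    uid[u] = u + 1;
    usrc[u] = u_src[u] + 1;
    udst[u] = u_dst[u] + 1;
    ustat[u] = u_status[u];
    ucre[u] = u_created[u];
    ufin[u] = u_final[u];
  }
  const int ns = (int)s_uid.size();
  IntegerVector suid(ns), snode(ns);
  NumericVector sarr(ns), sstart(ns), sdep(ns);
  for (int k = 0; k < ns; ++k) {
    suid[k] = s_uid[k] + 1;
    snode[k] = s_node[k] + 1;
    sarr[k] = s_arr[k];
    sstart[k] = s_start[k];
    sdep[k] = s_dep[k];
  }
  return List::create(
    _["units"] = DataFrame::create(
      _["uid"] = uid, _["source"] = usrc, _["destination"] = udst,
      _["t_created"] = ucre, _["status"] = ustat, _["t_final"] = ufin),
    _["segments"] = DataFrame::create(
      _["uid"] = suid, _["node"] = snode, _["t_arrive"] = sarr,
      _["t_service_start"] = sstart, _["t_depart"] = sdep));
}
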