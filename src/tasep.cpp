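// Event-driven (Gillespie) simulation of the homogeneous l-TASEP with
// extended particles (ribosomes of footprint `ell` codons) and optional
// two-state (telegraph) bursty initiation.
//
// Occupancy convention: tau[i] = 1 marks the trailing (5') edge of a
// ribosome whose footprint covers sites i .. i+ell-1.  A hop i -> i+1
// therefore requires site i+ell to be free (or to lie past the lattice
// end), initiation requires sites 0 .. ell-1 to be free, and termination
// is the hop off site L-1, at the same rate as elongation.
//
// The pending-event set is a binary min-heap keyed on absolute event time.
// Each ribosome has at most one pending move, scheduled at the moment the
// move becomes enabled; in the l-TASEP an enabled move can never become
// disabled again, so no event in the heap is ever invalid except pending
// initiations, which are invalidated lazily (sequence counter) when the
// gene switches off or when run-off purges them.
//
// All exponential waiting times are drawn from R's RNG so that set.seed()
// in R makes every simulation reproducible.

#include <Rcpp.h>
#include <queue>
#include <vector>

using namespace Rcpp;

namespace {

struct Event {
  double time;
  int code;  // -2 toggle, -1 initiation, 0..L-1 move of ribosome at site code
  long seq;  // initiation sequence number (lazy invalidation)
};

struct EventLater {
  bool operator()(const Event& a, const Event& b) const { return a.time > b.time; }
};

inline double rexp_rate(double rate) { return ::exp_rand() / rate; }

class LTasep {
 public:
  int L, ell;
  double alpha, lam, k_on, k_off;  // k_on: inactive->active, k_off: active->inactive
  bool telegraph;
  bool runoff;  // initiation disabled

  std::vector<int> tau;
  int G;         // gene state (1 = active)
  double t;

  long n_init, n_elong, n_term, n_toggle;

  LTasep(int L_, int ell_, double alpha_, double lam_, bool telegraph_,
         double k_on_, double k_off_)
      : L(L_), ell(ell_), alpha(alpha_), lam(lam_), k_on(k_on_), k_off(k_off_),
        telegraph(telegraph_), runoff(false), tau(L_, 0), G(1), t(0.0),
        n_init(0), n_elong(0), n_term(0), n_toggle(0),
        init_seq(0), init_pending(false) {}

  // Rebuild the event set from the occupancy state alone.  Valid because all
  // waiting times are exponential (memoryless).
  void reset_events(const std::vector<int>& tau0, int G0, bool runoff_mode) {
    tau = tau0;
    G = G0;
    runoff = runoff_mode;
    t = 0.0;
    heap = Heap();
    init_pending = false;
    for (int i = 0; i < L; ++i) {
      if (tau[i] == 1 && move_enabled(i)) schedule_move(i);
    }
    maybe_schedule_init();
    if (telegraph && !runoff) schedule_toggle();
  }

  void purge_initiation() { init_pending = false; }

  int n_ribosomes() const {
    int n = 0;
    for (int i = 0; i < L; ++i) n += tau[i];
    return n;
  }

  // Execute one valid event; returns false if no event remains.
  bool step() {
    for (;;) {
      if (heap.empty()) return false;
      Event ev = heap.top();
      heap.pop();
      if (ev.code == -1) {
        if (runoff || !init_pending || ev.seq != init_seq) continue;  // stale
        t = ev.time;
        init_pending = false;
        tau[0] = 1;
        ++n_init;
        if (move_enabled(0)) schedule_move(0);
        return true;
      }
      if (ev.code == -2) {
        t = ev.time;
        G = 1 - G;
        ++n_toggle;
        schedule_toggle();
        if (G == 1) {
          maybe_schedule_init();
        } else {
          init_pending = false;  // cancel any armed initiation
        }
        return true;
      }
      // ribosome move
      int i = ev.code;
      t = ev.time;
      if (i == L - 1) {  // termination: leave the lattice
        tau[L - 1] = 0;
        ++n_term;
        if (L - ell - 1 >= 0 && tau[L - ell - 1] == 1) schedule_move(L - ell - 1);
        return true;
      }
      tau[i] = 0;
      tau[i + 1] = 1;
      ++n_elong;
      if (i == ell - 1) maybe_schedule_init();            // entrance cleared
      if (i > ell - 1 && tau[i - ell] == 1) schedule_move(i - ell);  // follower freed
      if (move_enabled(i + 1)) schedule_move(i + 1);
      return true;
    }
  }

  // Process all events up to t_target (exclusive of later ones).
  // Returns false once no events remain.
  bool advance_until(double t_target) {
    for (;;) {
      skip_stale();
      if (heap.empty()) return false;
      if (heap.top().time > t_target) return true;
      step();
    }
  }

  bool has_events() {
    skip_stale();
    return !heap.empty();
  }

 private:
  typedef std::priority_queue<Event, std::vector<Event>, EventLater> Heap;
  Heap heap;
  long init_seq;
  bool init_pending;

  bool move_enabled(int i) const {
    return (i + ell >= L) || (tau[i + ell] == 0);
  }

  bool front_clear() const {
    for (int i = 0; i < ell; ++i)
      if (tau[i]) return false;
    return true;
  }

  void schedule_move(int i) {
    Event ev = {t + rexp_rate(lam), i, 0};
    heap.push(ev);
  }

  void schedule_toggle() {
    double rate = (G == 1) ? k_off : k_on;
    Event ev = {t + rexp_rate(rate), -2, 0};
    heap.push(ev);
  }

  void maybe_schedule_init() {
    if (runoff || alpha <= 0.0 || init_pending) return;
    if (telegraph && G == 0) return;
    if (!front_clear()) return;
    Event ev = {t + rexp_rate(alpha), -1, ++init_seq};
    heap.push(ev);
    init_pending = true;
  }

  void skip_stale() {
    while (!heap.empty()) {
      const Event& ev = heap.top();
      if (ev.code == -1 && (runoff || !init_pending || ev.seq != init_seq)) {
        heap.pop();
      } else {
        break;
      }
    }
  }
};

}  // namespace

// Record the state every dt from t = 0 to n_frames-1 frames.  In run-off
// mode recording stops after the first frame with an empty lattice.
static List record_frames(LTasep& sim, int n_frames, double dt,
                          const NumericVector& w, bool keep_occupancy,
                          bool stop_when_empty) {
  int L = sim.L;
  std::vector<double> times, nepi;
  std::vector<int> nrib, gene;
  IntegerMatrix occ;
  std::vector<int> occ_rows;
  if (keep_occupancy) occ = IntegerMatrix(n_frames, L);

  int f = 0;
  for (; f < n_frames; ++f) {
    double t_target = f * dt;
    sim.advance_until(t_target);
    times.push_back(t_target);
    int n = sim.n_ribosomes();
    nrib.push_back(n);
    gene.push_back(sim.G);
    double e = 0.0;
    for (int i = 0; i < L; ++i)
      if (sim.tau[i]) e += w[i];
    nepi.push_back(e);
    if (keep_occupancy) {
      for (int i = 0; i < L; ++i) occ(f, i) = sim.tau[i];
      occ_rows.push_back(f);
    }
    if (stop_when_empty && n == 0) {
      ++f;
      break;
    }
  }

  List out = List::create(
      _["times"] = wrap(times), _["n_ribosomes"] = wrap(nrib),
      _["n_epitopes"] = wrap(nepi), _["gene_state"] = wrap(gene));
  if (keep_occupancy) {
    IntegerMatrix occ_trim(f, L);
    for (int r = 0; r < f; ++r)
      for (int i = 0; i < L; ++i) occ_trim(r, i) = occ(r, i);
    out["occupancy"] = occ_trim;
  }
  return out;
}

// Event-count burn-in followed by a deterministic settling time.  The state
// at the n-th event epoch follows the embedded jump chain, whose stationary
// law over-weights high-activity (high-N) states; advancing a further fixed
// 2*L/lam seconds (complete lattice turnover) restores time-stationary
// sampling.
static void burn_in_and_settle(LTasep& sim, int burn_in) {
  for (int k = 0; k < burn_in; ++k)
    if (!sim.step()) break;
  sim.advance_until(sim.t + 2.0 * sim.L / sim.lam);
}

// [[Rcpp::export]]
List tasep_sim_cpp(int L, int ell, double alpha, double lam, bool telegraph,
                   double k_on, double k_off, int burn_in, double duration,
                   double dt, NumericVector w, bool runoff,
                   bool keep_occupancy) {
  LTasep sim(L, ell, alpha, lam, telegraph, k_on, k_off);
  std::vector<int> empty(L, 0);
  sim.reset_events(empty, 1, false);
  burn_in_and_settle(sim, burn_in);

  if (runoff) {
    std::vector<int> tau0 = sim.tau;
    int G0 = sim.G;
    sim.reset_events(tau0, G0, true);
  } else {
    sim.t = 0.0;  // measure recorded time from the end of burn-in
    std::vector<int> tau0 = sim.tau;
    sim.reset_events(tau0, sim.G, false);
  }

  int n_frames = (int)std::floor(duration / dt + 1e-9) + 1;
  List frames = record_frames(sim, n_frames, dt, w, keep_occupancy, runoff);
  frames["counts"] = IntegerVector::create(
      _["initiations"] = (int)sim.n_init, _["elongations"] = (int)sim.n_elong,
      _["terminations"] = (int)sim.n_term, _["toggles"] = (int)sim.n_toggle);
  return frames;
}

// Ensemble of run-off traces sharing one steady-state burn-in; between
// traces the steady-state process advances `decorrelate` events before the
// state is copied and run off with initiation disabled.
// [[Rcpp::export]]
List runoff_ensemble_cpp(int L, int ell, double alpha, double lam,
                         bool telegraph, double k_on, double k_off,
                         int burn_in, int decorrelate, int n_traces,
                         double duration, double dt, NumericVector w) {
  LTasep ss(L, ell, alpha, lam, telegraph, k_on, k_off);
  std::vector<int> empty(L, 0);
  ss.reset_events(empty, 1, false);
  burn_in_and_settle(ss, burn_in);

  int n_frames = (int)std::floor(duration / dt + 1e-9) + 1;
  List out(n_traces);
  for (int r = 0; r < n_traces; ++r) {
    LTasep ro(L, ell, alpha, lam, false, 0.0, 0.0);
    ro.reset_events(ss.tau, 1, true);
    out[r] = record_frames(ro, n_frames, dt, w, false, true);
    burn_in_and_settle(ss, decorrelate);
  }
  return out;
}

// Ensemble of steady-state traces (initiation active), same decorrelation
// scheme; used for burst/density analyses.
// [[Rcpp::export]]
List steady_ensemble_cpp(int L, int ell, double alpha, double lam,
                         bool telegraph, double k_on, double k_off,
                         int burn_in, int decorrelate, int n_traces,
                         double duration, double dt, NumericVector w) {
  LTasep ss(L, ell, alpha, lam, telegraph, k_on, k_off);
  std::vector<int> empty(L, 0);
  ss.reset_events(empty, 1, false);
  burn_in_and_settle(ss, burn_in);

  int n_frames = (int)std::floor(duration / dt + 1e-9) + 1;
  List out(n_traces);
  for (int r = 0; r < n_traces; ++r) {
    std::vector<int> tau0 = ss.tau;
    ss.reset_events(tau0, ss.G, false);
    out[r] = record_frames(ss, n_frames, dt, w, false, false);
    burn_in_and_settle(ss, decorrelate);
  }
  return out;
}
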