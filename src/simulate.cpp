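#include <Rcpp.h>
#include <unordered_set>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Hybrid eco-evolutionary simulator of CRISPR host-phage coevolution.
//
// Deterministic part: Lotka-Volterra-like strain dynamics integrated with
// fixed-step RK4. With m_ik = 1 if host i carries a spacer matching a
// protospacer of virus k, and effective susceptibility
//   s_ik = (1 - m_ik) + m_ik * f,
// the rates are
//   dN_i/dt = r N_i (1 - sumN/K) - (1-q) phi N_i sum_k V_k s_ik
//   dV_k/dt = beta (1-q) phi V_k sum_i N_i s_ik - phi V_k sumN - m_v V_k
// (every adsorption removes a virion; only vulnerable, non-acquiring hosts
// are lysed and produce a burst).
//
// Stochastic part, per step dt (volume fixed at 1 mL so densities are
// expected individual counts):
//   spacer acquisition: total rate q phi sumN sumV; each event picks host i
//     prop. to N_i, virus k prop. to V_k, copies a uniformly chosen
//     protospacer allele of k to the leader end of i's locus (trailer-end
//     spacer dropped when the locus holds S spacers; no-op when the allele
//     is already present) and moves one founder individual to the new or
//     existing strain;
//   protospacer escape mutation: rate per virus
//     mu P beta (1-q) phi V_k sum_i N_i s_ik; each event replaces one
//     uniformly chosen position with a globally novel allele
//     (infinite-alleles, no back mutation) and seeds the mutant with one
//     founder individual taken from the parent.
// Strains below the density cutoff are pruned (swap-remove; ids are never
// reused). Viral strain counts can reach thousands, so the susceptibility
// matrix is kept flat and contiguous for vectorized row sweeps.

struct Params {
  int S, P;
  double q, mu, r, K, phi, beta, m_v, f, dt, cutoff, t_end, record_every;
  double init_host, init_virus;
};

class Sim {
public:
  Params pm;
  std::vector<std::vector<int> > hostLocus; // leader end first
  std::vector<std::unordered_set<int> > hostSet;
  std::vector<int> hostId;
  std::vector<double> N;
  std::vector<std::vector<int> > virusProto; // length P
  std::vector<int> virusId;
  std::vector<double> V;
  // susceptibility matrix, row-major with padded column capacity
  std::vector<double> s;
  size_t cap = 64;
  int nextHostId = 1, nextVirusId = 1, nextAllele = 1;
  // archives of every strain ever created (filtered to recorded ids)
  std::vector<int> archHostId; std::vector<std::vector<int> > archHostLocus;
  std::vector<int> archVirusId; std::vector<std::vector<int> > archVirusProto;
  long nAcq = 0, nAcqNoop = 0, nMut = 0, nNegClip = 0;
  // scratch
  std::vector<double> n1, v1, kn1, kv1, kn2, kv2, kn3, kv3, kn4, kv4, prod,
      lam;

  double susceptibility(const std::unordered_set<int>& g,
                        const std::vector<int>& h) const {
    for (int a : h) if (g.count(a)) return pm.f;
    return 1.0;
  }

  void growCap() {
    size_t newcap = cap * 2;
    std::vector<double> s2(N.size() * newcap, 0.0);
    for (size_t i = 0; i < N.size(); ++i)
      std::copy(s.begin() + i * cap, s.begin() + i * cap + V.size(),
                s2.begin() + i * newcap);
    s = std::move(s2);
    cap = newcap;
  }

  void addHost(std::vector<int> locus, double dens) {
    hostSet.emplace_back(locus.begin(), locus.end());
    s.resize((N.size() + 1) * cap, 0.0);
    double* row = &s[N.size() * cap];
    for (size_t k = 0; k < V.size(); ++k)
      row[k] = susceptibility(hostSet.back(), virusProto[k]);
    hostId.push_back(nextHostId);
    archHostId.push_back(nextHostId);
    archHostLocus.push_back(locus);
    hostLocus.push_back(std::move(locus));
    N.push_back(dens);
    ++nextHostId;
  }

  void addVirus(std::vector<int> proto, double dens) {
    if (V.size() == cap) growCap();
    for (size_t i = 0; i < N.size(); ++i)
      s[i * cap + V.size()] = susceptibility(hostSet[i], proto);
    virusId.push_back(nextVirusId);
    archVirusId.push_back(nextVirusId);
    archVirusProto.push_back(proto);
    virusProto.push_back(std::move(proto));
    V.push_back(dens);
    ++nextVirusId;
  }

  void derivs(const std::vector<double>& n, const std::vector<double>& v,
              std::vector<double>& dn, std::vector<double>& dv) {
    const size_t nh = n.size(), nv = v.size();
    double sumN = 0.0;
    for (size_t i = 0; i < nh; ++i) sumN += n[i];
    prod.assign(nv, 0.0);
    const double hostLoss = (1.0 - pm.q) * pm.phi;
    for (size_t i = 0; i < nh; ++i) {
      const double* row = &s[i * cap];
      const double* vv = v.data();
      double inf = 0.0;
#pragma omp simd reduction(+ : inf)
      for (size_t k = 0; k < nv; ++k) inf += vv[k] * row[k];
      dn[i] = pm.r * n[i] * (1.0 - sumN / pm.K) - hostLoss * n[i] * inf;
      const double ni = n[i];
      double* pr = prod.data();
#pragma omp simd
      for (size_t k = 0; k < nv; ++k) pr[k] += ni * row[k];
    }
    const double gain = pm.beta * (1.0 - pm.q) * pm.phi;
    for (size_t k = 0; k < nv; ++k)
      dv[k] = gain * v[k] * prod[k] - pm.phi * v[k] * sumN - pm.m_v * v[k];
  }

  void rk4() {
    const size_t nh = N.size(), nv = V.size();
    n1.resize(nh); kn1.resize(nh); kn2.resize(nh); kn3.resize(nh);
    kn4.resize(nh);
    v1.resize(nv); kv1.resize(nv); kv2.resize(nv); kv3.resize(nv);
    kv4.resize(nv);
    const double h = pm.dt;
    derivs(N, V, kn1, kv1);
    for (size_t i = 0; i < nh; ++i) n1[i] = N[i] + 0.5 * h * kn1[i];
    for (size_t k = 0; k < nv; ++k) v1[k] = V[k] + 0.5 * h * kv1[k];
    derivs(n1, v1, kn2, kv2);
    for (size_t i = 0; i < nh; ++i) n1[i] = N[i] + 0.5 * h * kn2[i];
    for (size_t k = 0; k < nv; ++k) v1[k] = V[k] + 0.5 * h * kv2[k];
    derivs(n1, v1, kn3, kv3);
    for (size_t i = 0; i < nh; ++i) n1[i] = N[i] + h * kn3[i];
    for (size_t k = 0; k < nv; ++k) v1[k] = V[k] + h * kv3[k];
    derivs(n1, v1, kn4, kv4);
    for (size_t i = 0; i < nh; ++i) {
      N[i] += h / 6.0 * (kn1[i] + 2.0 * kn2[i] + 2.0 * kn3[i] + kn4[i]);
      if (N[i] < 0) { N[i] = 0.0; ++nNegClip; }
    }
    for (size_t k = 0; k < nv; ++k) {
      V[k] += h / 6.0 * (kv1[k] + 2.0 * kv2[k] + 2.0 * kv3[k] + kv4[k]);
      if (V[k] < 0) { V[k] = 0.0; ++nNegClip; }
    }
  }

  static size_t sampleIdx(const std::vector<double>& w, double total) {
    double u = unif_rand() * total, c = 0.0;
    for (size_t i = 0; i < w.size(); ++i) {
      c += w[i];
      if (u <= c) return i;
    }
    return w.size() - 1;
  }

  void acquisitionEvents() {
    if (pm.q <= 0.0) return;
    double sumN = 0.0, sumV = 0.0;
    for (double x : N) sumN += x;
    for (double x : V) sumV += x;
    double lamTot = pm.q * pm.phi * pm.dt * sumN * sumV;
    if (lamTot <= 0.0) return;
    int ne = (int) R::rpois(lamTot);
    for (int e = 0; e < ne; ++e) {
      size_t i = sampleIdx(N, sumN);
      size_t k = sampleIdx(V, sumV);
      if (N[i] <= 0.0 || V[k] <= 0.0) continue;
      int pos = (int) std::floor(unif_rand() * pm.P);
      if (pos >= pm.P) pos = pm.P - 1;
      int allele = virusProto[k][pos];
      if (hostSet[i].count(allele)) { ++nAcqNoop; continue; }
      std::vector<int> locus;
      locus.reserve(pm.S);
      locus.push_back(allele);
      for (int a : hostLocus[i])
        if ((int) locus.size() < pm.S) locus.push_back(a);
      double founder = N[i] < 1.0 ? N[i] : 1.0;
      long target = -1; // merge into an identical existing locus
      for (size_t j = 0; j < hostLocus.size(); ++j)
        if (hostLocus[j] == locus) { target = (long) j; break; }
      N[i] -= founder;
      if (target >= 0) N[target] += founder;
      else addHost(std::move(locus), founder);
      ++nAcq;
    }
  }

  void mutationEvents() {
    if (pm.mu <= 0.0) return;
    const size_t nh = N.size(), nv = V.size();
    lam.assign(nv, 0.0);
    for (size_t i = 0; i < nh; ++i) {
      const double* row = &s[i * cap];
      const double ni = N[i];
      double* lm = lam.data();
#pragma omp simd
      for (size_t k = 0; k < nv; ++k) lm[k] += ni * row[k];
    }
    const double c0 = pm.mu * pm.P * pm.beta * (1.0 - pm.q) * pm.phi * pm.dt;
    double tot = 0.0;
    for (size_t k = 0; k < nv; ++k) {
      lam[k] *= c0 * V[k];
      tot += lam[k];
    }
    if (tot <= 0.0) return;
    int ne = (int) R::rpois(tot);
    for (int e = 0; e < ne; ++e) {
      size_t k = sampleIdx(lam, tot);
      if (V[k] <= 0.0) continue;
      int pos = (int) std::floor(unif_rand() * pm.P);
      if (pos >= pm.P) pos = pm.P - 1;
      std::vector<int> proto = virusProto[k];
      proto[pos] = nextAllele++;
      double founder = V[k] < 1.0 ? V[k] : 1.0;
      V[k] -= founder;
      addVirus(std::move(proto), founder);
      ++nMut;
    }
  }

  void prune() {
    for (size_t i = 0; i < N.size();) {
      if (N[i] < pm.cutoff) {
        size_t lastI = N.size() - 1;
        if (i != lastI) {
          N[i] = N[lastI]; hostId[i] = hostId[lastI];
          hostLocus[i] = std::move(hostLocus[lastI]);
          hostSet[i] = std::move(hostSet[lastI]);
          std::copy(s.begin() + lastI * cap,
                    s.begin() + lastI * cap + V.size(),
                    s.begin() + i * cap);
        }
        N.pop_back(); hostId.pop_back(); hostLocus.pop_back();
        hostSet.pop_back();
        s.resize(N.size() * cap);
      } else {
        ++i;
      }
    }
    for (size_t k = 0; k < V.size();) {
      if (V[k] < pm.cutoff) {
        size_t lastK = V.size() - 1;
        if (k != lastK) {
          V[k] = V[lastK]; virusId[k] = virusId[lastK];
          virusProto[k] = std::move(virusProto[lastK]);
          for (size_t i = 0; i < N.size(); ++i)
            s[i * cap + k] = s[i * cap + lastK];
        }
        V.pop_back(); virusId.pop_back(); virusProto.pop_back();
      } else {
        ++k;
      }
    }
  }
};

// [[Rcpp::export]]
List run_coevolution_cpp(List params) {
  Params pm;
  pm.S = as<int>(params["S"]); pm.P = as<int>(params["P"]);
  pm.q = as<double>(params["q"]); pm.mu = as<double>(params["mu"]);
  pm.r = as<double>(params["r"]); pm.K = as<double>(params["K"]);
  pm.phi = as<double>(params["phi"]); pm.beta = as<double>(params["beta"]);
  pm.m_v = as<double>(params["m_v"]); pm.f = as<double>(params["f"]);
  pm.dt = as<double>(params["dt"]); pm.cutoff = as<double>(params["cutoff"]);
  pm.t_end = as<double>(params["t_end"]);
  pm.record_every = as<double>(params["record_every"]);
  pm.init_host = as<double>(params["init_host"]);
  pm.init_virus = as<double>(params["init_virus"]);

  Sim sim; sim.pm = pm;
  sim.addHost(std::vector<int>(), pm.init_host); // naive host, empty locus
  std::vector<int> anc(pm.P);
  for (int p = 0; p < pm.P; ++p) anc[p] = sim.nextAllele++;
  sim.addVirus(std::move(anc), pm.init_virus);

  const long nsteps = (long) std::ceil(pm.t_end / pm.dt - 1e-9);
  const long stride = std::max(1L, (long) std::lround(pm.record_every / pm.dt));

  std::vector<double> recT, recHtot, recVtot;
  std::vector<int> recMinLocus;
  std::vector<std::vector<int> > recHid, recVid;
  std::vector<std::vector<double> > recHden, recVden;
  std::unordered_set<int> seenH, seenV;

  auto record = [&](double t) {
    recT.push_back(t);
    double sn = 0.0, sv = 0.0;
    int ml = sim.N.empty() ? 0 : pm.S;
    for (size_t i = 0; i < sim.N.size(); ++i) {
      sn += sim.N[i];
      if ((int) sim.hostLocus[i].size() < ml) ml = sim.hostLocus[i].size();
      seenH.insert(sim.hostId[i]);
    }
    for (size_t k = 0; k < sim.V.size(); ++k) {
      sv += sim.V[k];
      seenV.insert(sim.virusId[k]);
    }
    recHtot.push_back(sn); recVtot.push_back(sv); recMinLocus.push_back(ml);
    recHid.emplace_back(sim.hostId.begin(), sim.hostId.end());
    recVid.emplace_back(sim.virusId.begin(), sim.virusId.end());
    recHden.emplace_back(sim.N.begin(), sim.N.end());
    recVden.emplace_back(sim.V.begin(), sim.V.end());
  };

  record(0.0);
  std::string outcome = "completed";
  double t = 0.0;
  for (long step = 1; step <= nsteps; ++step) {
    sim.rk4();
    sim.acquisitionEvents();
    sim.mutationEvents();
    sim.prune();
    t = step * pm.dt;
    bool atRec = (step % stride == 0) || step == nsteps;
    double sumN = 0.0, sumV = 0.0;
    for (double x : sim.N) sumN += x;
    for (double x : sim.V) sumV += x;
    bool vExt = sumV < pm.cutoff, hExt = sumN < pm.cutoff;
    if (atRec || vExt || hExt) record(t);
    if (vExt) { outcome = "viral_extinction"; break; }
    if (hExt) { outcome = "host_extinction"; break; }
    if (step % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  // registries restricted to strains that appear in some snapshot
  std::vector<int> regHid, regVid;
  List regHloc, regVproto;
  {
    std::vector<IntegerVector> hl, vp;
    for (size_t a = 0; a < sim.archHostId.size(); ++a)
      if (seenH.count(sim.archHostId[a])) {
        regHid.push_back(sim.archHostId[a]);
        hl.push_back(IntegerVector(sim.archHostLocus[a].begin(),
                                   sim.archHostLocus[a].end()));
      }
    for (size_t a = 0; a < sim.archVirusId.size(); ++a)
      if (seenV.count(sim.archVirusId[a])) {
        regVid.push_back(sim.archVirusId[a]);
        vp.push_back(IntegerVector(sim.archVirusProto[a].begin(),
                                   sim.archVirusProto[a].end()));
      }
    regHloc = wrap(hl); regVproto = wrap(vp);
  }

  const size_t nrec = recHid.size();
  List snapsH(nrec), snapsV(nrec), snapsHd(nrec), snapsVd(nrec);
  for (size_t m = 0; m < nrec; ++m) {
    snapsH[m] = IntegerVector(recHid[m].begin(), recHid[m].end());
    snapsV[m] = IntegerVector(recVid[m].begin(), recVid[m].end());
    snapsHd[m] = NumericVector(recHden[m].begin(), recHden[m].end());
    snapsVd[m] = NumericVector(recVden[m].begin(), recVden[m].end());
  }

  return List::create(
      _["times"] = NumericVector(recT.begin(), recT.end()),
      _["host_total"] = NumericVector(recHtot.begin(), recHtot.end()),
      _["viral_total"] = NumericVector(recVtot.begin(), recVtot.end()),
      _["min_locus"] = IntegerVector(recMinLocus.begin(), recMinLocus.end()),
      _["host_ids"] = snapsH, _["host_densities"] = snapsHd,
      _["virus_ids"] = snapsV, _["virus_densities"] = snapsVd,
      _["host_registry_id"] = IntegerVector(regHid.begin(), regHid.end()),
      _["host_registry_spacers"] = regHloc,
      _["virus_registry_id"] = IntegerVector(regVid.begin(), regVid.end()),
      _["virus_registry_protospacers"] = regVproto,
      _["outcome"] = outcome,
      _["end_time"] = t,
      _["n_acquisitions"] = (double) sim.nAcq,
      _["n_acquisition_noops"] = (double) sim.nAcqNoop,
      _["n_mutations"] = (double) sim.nMut,
      _["n_negative_clips"] = (double) sim.nNegClip);
}
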