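#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Event kinds (order matters: it is the channel enumeration order and is
// mirrored exactly by the pure-R reference engine).
enum EventKind {
  CANCER_BIRTH = 0,      // clonal/mutant resolved at draw time
  CANCER_DEATH_NATURAL = 1,
  CANCER_DEATH_COMPETITION = 2,
  CANCER_DEATH_EXCESS_BRC = 3,
  CANCER_DEATH_THERAPY = 4,
  CANCER_SWITCH = 5,
  TCELL_BIRTH = 6,
  TCELL_DEATH = 7,
  CYTOKINE_DECAY = 8,
  MUTANT_BIRTH = 9       // tally only; drawn inside CANCER_BIRTH
};

// Exact SSA for the tumour/T-cell/cytokine jump process.
//
// Channel enumeration per iteration, in canonical trait order (phenotypes,
// then T-cells, then cytokines); interaction sums exclude the focal
// individual's own 1/K contribution. Two uniforms are consumed per
// iteration (waiting time, channel); a cancer birth consumes one more when
// the mutation probability is positive, and a further one to draw the
// mutant destination. Traits flagged `frozen` contribute to interaction
// sums at their fixed counts but generate no events and never change.
//
// [[Rcpp::export]]
List ssa_run_cpp(List model, NumericVector init, double t0, double tMax,
                 double recordDt,
                 NumericVector schedTimes, IntegerVector schedTrait,
                 NumericVector schedCount,
                 LogicalVector frozen,
                 bool stopTumourExtinct,
                 IntegerVector thresholdGroup, double thresholdCount,
                 double maxEvents) {
  const int nP = as<int>(model["nP"]);
  const int nZ = as<int>(model["nZ"]);
  const int nW = as<int>(model["nW"]);
  const int nT = nP + nZ + nW;
  const NumericVector b = model["b"], d = model["d"];
  const NumericMatrix C = model["C"], Cb = model["Cb"], Tkill = model["Tkill"];
  const NumericVector killBurst = model["killBurst"];   // dim nP x nZ x nW
  const NumericMatrix Snat = model["Snat"];
  const NumericVector Scyt = model["Scyt"];             // dim nW x nP x nP
  const NumericVector muP = model["muP"];
  const NumericMatrix mlaw = model["mlaw"];
  const NumericVector bT = model["bT"], dT = model["dT"];
  const NumericMatrix Tprod = model["Tprod"], repBurst = model["repBurst"];
  const NumericVector dW = model["dW"];
  const double K = as<double>(model["K"]);

  std::vector<double> n(nT);
  for (int i = 0; i < nT; ++i) n[i] = init[i];

  // channel buffers
  std::vector<double> cum; cum.reserve(4 * nT * nT);
  std::vector<int> ckind, cactor, ctarget;
  ckind.reserve(4 * nT * nT); cactor.reserve(4 * nT * nT); ctarget.reserve(4 * nT * nT);

  std::vector<double> recT, recMut;
  std::vector<double> recX;
  double cumMut = 0.0;
  std::vector<double> evCount(10, 0.0);

  double t = t0;
  double gridNext = t0 + recordDt;
  int schedIdx = 0;
  const int nSched = schedTimes.size();
  std::string stopReason = "t_max";
  double nEvents = 0.0;
  const bool useThreshold = thresholdGroup.size() > 0;

  RNGScope scope;

  auto record = [&](double tt) {
    recT.push_back(tt);
    for (int i = 0; i < nT; ++i) recX.push_back(n[i]);
    recMut.push_back(cumMut);
  };
  // record state (constant on [t, tNew)) at all grid points in (t, tNew]
  auto recordUpTo = [&](double tNew) {
    while (gridNext <= tNew + 1e-12 && gridNext <= tMax + 1e-12) {
      record(gridNext);
      gridNext += recordDt;
    }
  };

  record(t0);

  // apply injections scheduled at exactly t0 or earlier
  while (schedIdx < nSched && schedTimes[schedIdx] <= t0) {
    n[schedTrait[schedIdx]] += schedCount[schedIdx];
    ++schedIdx;
  }

  while (true) {
    if (nEvents >= maxEvents) { stopReason = "max_events"; break; }
    if (((long long)nEvents & 0xFFFF) == 0) Rcpp::checkUserInterrupt();

    // ---- build channels ----
    cum.clear(); ckind.clear(); cactor.clear(); ctarget.clear();
    double total = 0.0;
    for (int i = 0; i < nP; ++i) {
      const double ni = n[i];
      if (ni <= 0 || frozen[i]) continue;
      double Sb = 0.0, Sd = 0.0;
      for (int j = 0; j < nP; ++j) {
        const double nuj = (n[j] - (j == i ? 1.0 : 0.0)) / K;
        Sb += Cb(i, j) * nuj;
        Sd += C(i, j) * nuj;
      }
      double Beff = b[i] - Sb, Dbrc = 0.0;
      if (Beff < 0) { Dbrc = -Beff; Beff = 0.0; }
      total += ni * Beff; cum.push_back(total); ckind.push_back(CANCER_BIRTH); cactor.push_back(i); ctarget.push_back(-1);
      total += ni * d[i]; cum.push_back(total); ckind.push_back(CANCER_DEATH_NATURAL); cactor.push_back(i); ctarget.push_back(-1);
      total += ni * Sd; cum.push_back(total); ckind.push_back(CANCER_DEATH_COMPETITION); cactor.push_back(i); ctarget.push_back(-1);
      total += ni * Dbrc; cum.push_back(total); ckind.push_back(CANCER_DEATH_EXCESS_BRC); cactor.push_back(i); ctarget.push_back(-1);
      for (int z = 0; z < nZ; ++z) {
        total += ni * Tkill(i, z) * (n[nP + z] / K);
        cum.push_back(total); ckind.push_back(CANCER_DEATH_THERAPY); cactor.push_back(i); ctarget.push_back(z);
      }
      for (int j = 0; j < nP; ++j) {
        if (j == i) continue;
        double sr = Snat(i, j);
        for (int w = 0; w < nW; ++w) {
          sr += Scyt[w + nW * (i + nP * j)] * (n[nP + nZ + w] / K);
        }
        if (sr > 0) {
          total += ni * sr;
          cum.push_back(total); ckind.push_back(CANCER_SWITCH); cactor.push_back(i); ctarget.push_back(j);
        }
      }
    }
    for (int z = 0; z < nZ; ++z) {
      const double nz = n[nP + z];
      if (nz <= 0 || frozen[nP + z]) continue;
      double prey = bT[z];
      for (int p = 0; p < nP; ++p) prey += Tprod(z, p) * (n[p] / K);
      total += nz * prey; cum.push_back(total); ckind.push_back(TCELL_BIRTH); cactor.push_back(z); ctarget.push_back(-1);
      total += nz * dT[z]; cum.push_back(total); ckind.push_back(TCELL_DEATH); cactor.push_back(z); ctarget.push_back(-1);
    }
    for (int w = 0; w < nW; ++w) {
      const double nw = n[nP + nZ + w];
      if (nw <= 0 || frozen[nP + nZ + w]) continue;
      total += nw * dW[w]; cum.push_back(total); ckind.push_back(CYTOKINE_DECAY); cactor.push_back(w); ctarget.push_back(-1);
    }

    if (total <= 0.0) {
      double popTotal = 0.0;
      for (int i = 0; i < nT; ++i) popTotal += n[i];
      if (schedIdx < nSched && schedTimes[schedIdx] <= tMax) {
        // nothing can happen until the next injection
        double tInj = schedTimes[schedIdx];
        recordUpTo(tInj);
        t = tInj;
        while (schedIdx < nSched && schedTimes[schedIdx] <= t) {
          n[schedTrait[schedIdx]] += schedCount[schedIdx];
          ++schedIdx;
        }
        continue;
      }
      if (popTotal == 0.0) { stopReason = "all_extinct"; break; }
      recordUpTo(tMax);
      t = tMax;
      stopReason = "t_max";
      break;
    }

    const double u1 = unif_rand();
    const double dt = -std::log(u1) / total;
    const double u2 = unif_rand();
    double tNew = t + dt;

    if (schedIdx < nSched && schedTimes[schedIdx] <= tNew && schedTimes[schedIdx] <= tMax) {
      // clip at the injection time; drawn event is discarded (memorylessness)
      double tInj = schedTimes[schedIdx];
      recordUpTo(tInj);
      t = tInj;
      while (schedIdx < nSched && schedTimes[schedIdx] <= t) {
        n[schedTrait[schedIdx]] += schedCount[schedIdx];
        ++schedIdx;
      }
      continue;
    }
    if (tNew > tMax) {
      recordUpTo(tMax);
      t = tMax;
      stopReason = "t_max";
      break;
    }
    recordUpTo(tNew);
    t = tNew;

    // ---- choose channel ----
    const double target = u2 * total;
    int lo = 0, hi = (int)cum.size() - 1;
    while (lo < hi) {
      int mid = (lo + hi) / 2;
      if (cum[mid] >= target) hi = mid; else lo = mid + 1;
    }
    const int k = lo;
    const int kind = ckind[k], actor = cactor[k], tgt = ctarget[k];

    // ---- apply ----
    switch (kind) {
    case CANCER_BIRTH: {
      bool mutant = false;
      if (muP[actor] > 0) {
        const double u3 = unif_rand();
        mutant = (u3 < muP[actor]);
      }
      if (mutant) {
        const double u4 = unif_rand();
        double acc = 0.0; int dest = -1;
        for (int j = 0; j < nP; ++j) {
          acc += mlaw(actor, j);
          if (u4 < acc) { dest = j; break; }
        }
        if (dest < 0) dest = actor; // defensive: degenerate law row
        cumMut += 1.0;
        evCount[MUTANT_BIRTH] += 1.0;
        if (!frozen[dest]) n[dest] += 1.0;
      } else {
        n[actor] += 1.0;
      }
      evCount[CANCER_BIRTH] += 1.0;
      break;
    }
    case CANCER_DEATH_NATURAL:
    case CANCER_DEATH_COMPETITION:
    case CANCER_DEATH_EXCESS_BRC:
      n[actor] -= 1.0;
      evCount[kind] += 1.0;
      break;
    case CANCER_DEATH_THERAPY: {
      n[actor] -= 1.0;
      for (int w = 0; w < nW; ++w) {
        const int wi = nP + nZ + w;
        if (!frozen[wi]) n[wi] += killBurst[actor + nP * (tgt + nZ * w)];
      }
      evCount[CANCER_DEATH_THERAPY] += 1.0;
      break;
    }
    case CANCER_SWITCH:
      n[actor] -= 1.0;
      n[tgt] += 1.0;
      evCount[CANCER_SWITCH] += 1.0;
      break;
    case TCELL_BIRTH: {
      n[nP + actor] += 1.0;
      for (int w = 0; w < nW; ++w) {
        const int wi = nP + nZ + w;
        if (!frozen[wi]) n[wi] += repBurst(actor, w);
      }
      evCount[TCELL_BIRTH] += 1.0;
      break;
    }
    case TCELL_DEATH:
      n[nP + actor] -= 1.0;
      evCount[TCELL_DEATH] += 1.0;
      break;
    case CYTOKINE_DECAY:
      n[nP + nZ + actor] -= 1.0;
      evCount[CYTOKINE_DECAY] += 1.0;
      break;
    }
    nEvents += 1.0;

    // ---- stop rules ----
    if (useThreshold) {
      double g = 0.0;
      for (int q = 0; q < thresholdGroup.size(); ++q) g += n[thresholdGroup[q]];
      if (g >= thresholdCount) { stopReason = "threshold"; break; }
      if (g <= 0.0) { stopReason = "group_extinct"; break; }
    }
    double popTotal = 0.0;
    for (int i = 0; i < nT; ++i) popTotal += n[i];
    if (popTotal == 0.0) {
      if (schedIdx < nSched && schedTimes[schedIdx] <= tMax) continue;
      stopReason = "all_extinct";
      break;
    }
    if (stopTumourExtinct) {
      double canc = 0.0;
      for (int i = 0; i < nP; ++i) canc += n[i];
      if (canc == 0.0) { stopReason = "tumour_extinct"; break; }
    }
  }

  // final record at stop time (if not already on the last grid point)
  if (recT.empty() || recT.back() < t - 1e-12) record(t);

  const int nRec = (int)recT.size();
  NumericMatrix X(nRec, nT);
  for (int r = 0; r < nRec; ++r) {
    for (int i = 0; i < nT; ++i) X(r, i) = recX[(size_t)r * nT + i];
  }
  NumericVector finalN(nT);
  for (int i = 0; i < nT; ++i) finalN[i] = n[i];

  return List::create(
    _["times"] = NumericVector(recT.begin(), recT.end()),
    _["counts"] = X,
    _["cumMutations"] = NumericVector(recMut.begin(), recMut.end()),
    _["stopReason"] = stopReason,
    _["eventCounts"] = NumericVector(evCount.begin(), evCount.end()),
    _["nEvents"] = nEvents,
    _["finalTime"] = t,
    _["finalCounts"] = finalN
  );
}
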