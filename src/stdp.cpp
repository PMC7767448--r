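#include <Rcpp.h>
using namespace Rcpp;

// Reservoir dynamics with nearest-spike additive STDP on a fixed directed
// edge list. Time is discrete (one step per input sample); spikes propagate
// with a one-step axonal delay.
//
// Input neurons are spike sources: they transfer the encoded spike train of
// their channel directly into the model, emitting one event per encoded
// spike with its polarity (+1/-1); a negative event delivers -w along each
// outgoing edge. All other neurons are leaky integrate-and-fire: membrane
// u <- u*leak + sum(incoming w * event sign); a neuron fires (emits a +1
// event) when u > fireThreshold, then resets and enters a refractory period
// during which input is ignored.
//
// STDP (applied at every emission, nearest-spike pairing):
//   pre emitted dt steps before this post event -> dw = +aPlus  * exp(-dt/tau)
//   post emitted dt steps before this pre event -> dw = -aMinus * exp(-dt/tau)
// A counterpart spike is paired only if it is newer than the emitting
// neuron's own previous spike, so each spike enters at most one pair per
// role and per edge. Excitatory weights are clipped to [0, wMax];
// inhibitory edges mirror the rule on the magnitude, clipped to [-wMax, 0].
//
// [[Rcpp::export]]
List stdp_run_cpp(IntegerVector pre, IntegerVector post, NumericVector w0,
                  LogicalVector inhib, IntegerMatrix spikes,
                  IntegerVector inputNeurons, int nNeurons,
                  double leak, double fireThreshold, int refractorySteps,
                  double aPlus, double aMinus, double tauMs, double wMax,
                  int passes) {
  const int nEdges = pre.size();
  const int nChan = spikes.nrow();
  const int nT = spikes.ncol();

  // CSR-style adjacency over the edge list, by pre (out) and by post (in)
  std::vector<int> outStart(nNeurons + 1, 0), inStart(nNeurons + 1, 0);
  for (int e = 0; e < nEdges; ++e) {
    outStart[pre[e] + 1]++;
    inStart[post[e] + 1]++;
  }
  for (int i = 0; i < nNeurons; ++i) {
    outStart[i + 1] += outStart[i];
    inStart[i + 1] += inStart[i];
  }
  std::vector<int> outEdge(nEdges), inEdge(nEdges);
  {
    std::vector<int> oc(outStart.begin(), outStart.end() - 1),
        ic(inStart.begin(), inStart.end() - 1);
    for (int e = 0; e < nEdges; ++e) {
      outEdge[oc[pre[e]]++] = e;
      inEdge[ic[post[e]]++] = e;
    }
  }

  std::vector<int> channelOf(nNeurons, -1);
  for (int ch = 0; ch < nChan; ++ch) channelOf[inputNeurons[ch]] = ch;

  NumericVector w = clone(w0);
  std::vector<double> u(nNeurons, 0.0), drive(nNeurons, 0.0);
  std::vector<int> refr(nNeurons, 0), lastFire(nNeurons, -1);
  std::vector<int> prevEmit, prevSign, emitNow, emitSign;
  std::vector<int> logNeuron, logT, logPol;

  for (int pass = 0; pass < passes; ++pass) {
    std::fill(u.begin(), u.end(), 0.0);
    std::fill(refr.begin(), refr.end(), 0);
    std::fill(lastFire.begin(), lastFire.end(), -1);
    prevEmit.clear();
    prevSign.clear();

    for (int t = 0; t < nT; ++t) {
      std::fill(drive.begin(), drive.end(), 0.0);
      for (size_t k = 0; k < prevEmit.size(); ++k) {
        const int i = prevEmit[k];
        const double s = prevSign[k];
        for (int p = outStart[i]; p < outStart[i + 1]; ++p) {
          const int e = outEdge[p];
          drive[post[e]] += s * w[e];
        }
      }

      emitNow.clear();
      emitSign.clear();
      for (int i = 0; i < nNeurons; ++i) {
        if (channelOf[i] >= 0) {
          const int s = spikes(channelOf[i], t);
          if (s != 0) {
            emitNow.push_back(i);
            emitSign.push_back(s);
            logNeuron.push_back(i + 1);
            logT.push_back(t);
            logPol.push_back(s);
          }
          continue;
        }
        if (refr[i] > 0) {
          refr[i]--;
          u[i] = 0.0;
          continue;
        }
        u[i] = u[i] * leak + drive[i];
        if (u[i] > fireThreshold) {
          emitNow.push_back(i);
          emitSign.push_back(1);
          logNeuron.push_back(i + 1);
          logT.push_back(t);
          logPol.push_back(drive[i] >= 0 ? 1 : -1);
        }
      }

      if (aPlus != 0.0 || aMinus != 0.0) {
        for (size_t k = 0; k < emitNow.size(); ++k) {
          const int i = emitNow[k];
          const int own = lastFire[i];  // this neuron's previous spike
          // potentiate incoming edges whose pre emitted before this event
          for (int p = inStart[i]; p < inStart[i + 1]; ++p) {
            const int e = inEdge[p];
            const int lf = lastFire[pre[e]];
            if (lf >= 0 && t - lf >= 1 && lf > own) {
              const double dw = aPlus * std::exp(-(double)(t - lf) / tauMs);
              if (inhib[e]) {
                w[e] -= dw;
                if (w[e] < -wMax) w[e] = -wMax;
              } else {
                w[e] += dw;
                if (w[e] > wMax) w[e] = wMax;
              }
            }
          }
          // depress outgoing edges whose post emitted before this event
          for (int p = outStart[i]; p < outStart[i + 1]; ++p) {
            const int e = outEdge[p];
            const int lf = lastFire[post[e]];
            if (lf >= 0 && t - lf >= 1 && lf > own) {
              const double dw = aMinus * std::exp(-(double)(t - lf) / tauMs);
              if (inhib[e]) {
                w[e] += dw;
                if (w[e] > 0) w[e] = 0;
              } else {
                w[e] -= dw;
                if (w[e] < 0) w[e] = 0;
              }
            }
          }
        }
      }

      for (size_t k = 0; k < emitNow.size(); ++k) {
        const int i = emitNow[k];
        if (channelOf[i] < 0) {
          u[i] = 0.0;
          refr[i] = refractorySteps;
        }
        lastFire[i] = t;
      }
      prevEmit = emitNow;
      prevSign = emitSign;
    }
  }

  return List::create(_["w"] = w,
                      _["neuron"] = wrap(logNeuron),
                      _["t"] = wrap(logT),
                      _["polarity"] = wrap(logPol));
}
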