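// Inner loop of the two-phase Hebbian development procedure.
//
// The R side precomputes, per development direction, the per-channel
// geniculate waveforms already filtered by the cortical time constant
// (HfL/HfR, one stimulus period sampled at N points) and the inhibitory
// drive term onto excitatory cells for every stimulus condition (ITmL,
// ITmR for monocular phase-1 stimulation; ITb for the binocular phase-2
// direction x offset set, computed with unit inhibitory-to-excitatory
// modulation so it scales linearly with m_ie). The loop maintains the
// per-eye modulated input numerators
//   F_eye[dir] = (A_eye % M_eye) * Hf_eye[dir]          (n_exc x N)
// and mass D_eye = rowsum(A_eye % M_eye), so a change of one channel's
// modulation column is a rank-1 update; the caches are rebuilt from m
// every refresh_every cycles to cancel floating-point drift. The
// excitatory potential for a stimulus is
//   p_exc = k_gc * (F_L + shift(F_R)) / (D_L + D_R) - m_ie * IT
// and the response is the F1 amplitude (or, optionally, the peak) of the
// rectified impulse rate.
//
// Interocular offsets enter as integer circular shifts of the right-eye
// waveform columns, exact because the offset grid is aligned with the
// time grid.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

namespace {

struct EvalCtx {
  const cube &FL, &FR, &ITmL, &ITmR, &ITb;
  const vec &DL, &DR;
  const std::vector<uvec> &shift_idx;
  double k_gc, k_rect, p_rest;
  int n_dir, n_off, N, measure;
  mat P, E;
  vec cosv, sinv, resp, cpart, spart;

  EvalCtx(const cube &FL_, const cube &FR_, const cube &ITmL_,
          const cube &ITmR_, const cube &ITb_, const vec &DL_,
          const vec &DR_, const std::vector<uvec> &shift_idx_, double k_gc_,
          double k_rect_, double p_rest_, int n_dir_, int n_off_,
          int measure_)
      : FL(FL_), FR(FR_), ITmL(ITmL_), ITmR(ITmR_), ITb(ITb_), DL(DL_),
        DR(DR_), shift_idx(shift_idx_), k_gc(k_gc_), k_rect(k_rect_),
        p_rest(p_rest_), n_dir(n_dir_), n_off(n_off_), N(FL_.n_cols),
        measure(measure_) {
    const uword nx = FL.n_rows;
    P.set_size(nx, N);
    E.set_size(nx, N);
    cosv.set_size(N);
    sinv.set_size(N);
    for (int k = 0; k < N; ++k) {
      cosv[k] = std::cos(2.0 * datum::pi * k / N);
      sinv[k] = std::sin(2.0 * datum::pi * k / N);
    }
    resp.set_size(nx);
    cpart.set_size(nx);
    spart.set_size(nx);
  }

  void accum_resp(const mat &IT, double m_ie, const vec &invD) {
    E = P;
    E.each_col() %= invD;
    E -= m_ie * IT;
    if (measure == 0) {  // F1 amplitude of impulse rate
      E = clamp(E, 0.0, datum::inf);
      cpart = E * cosv;
      spart = E * sinv;
      vec f1 = (2.0 * k_rect / N) * sqrt(cpart % cpart + spart % spart);
      resp = arma::max(resp, f1);
    } else if (measure == 1) {
      // peak response: the maximum of the generator potential over the
      // cycle (proportional to peak impulse rate whenever the neuron
      // fires, and a graded measure of peak depolarisation below
      // threshold)
      resp = arma::max(resp, arma::max(E, 1));
    } else {  // F1 amplitude of the generator potential
      cpart = E * cosv;
      spart = E * sinv;
      resp = arma::max(resp, (2.0 / N) * sqrt(cpart % cpart + spart % spart));
    }
  }

  // phase 1: monocular stimulation of eye_stim (0 = L, 1 = R); the
  // unstimulated eye's channels rest at p_rest and contribute a constant
  vec eval_mono(int eye_stim, double m_ie) {
    vec invD = k_gc / (DL + DR);
    resp.zeros();
    for (int d = 0; d < n_dir; ++d) {
      if (eye_stim == 0) {
        P = FL.slice(d);
        P.each_col() += p_rest * DR;
        accum_resp(ITmL.slice(d), m_ie, invD);
      } else {
        P = FR.slice(d);
        P.each_col() += p_rest * DL;
        accum_resp(ITmR.slice(d), m_ie, invD);
      }
    }
    return resp;
  }

  // phase 2: binocular stimulation, max over directions x offsets
  vec eval_bino(double m_ie) {
    vec invD = k_gc / (DL + DR);
    resp.zeros();
    for (int d = 0; d < n_dir; ++d) {
      for (int o = 0; o < n_off; ++o) {
        P = FL.slice(d) + FR.slice(d).cols(shift_idx[o]);
        accum_resp(ITb.slice(d * n_off + o), m_ie, invD);
      }
    }
    return resp;
  }
};

}  // namespace

// [[Rcpp::export]]
Rcpp::List dev_loop(
    arma::mat m, const arma::mat &A, const arma::ivec &eye,
    const arma::uvec &local, const arma::cube &HfL, const arma::cube &HfR,
    const arma::cube &ITmL, const arma::cube &ITmR, const arma::cube &ITb,
    const arma::ivec &shifts, arma::mat best, const arma::ivec &sel,
    int phase, const arma::vec &mie, double k_gc, double k_rect,
    double p_rest, double dm, int measure, int baseline, int norm_frozen,
    int refresh_every, int log_every, const arma::uvec &idxL,
    const arma::uvec &idxR, int cycle0) {
  const int n_dir = HfL.n_slices;
  const int n_off = shifts.n_elem;
  const int N = HfL.n_cols;
  const uword n_cycles = sel.n_elem;
  const uword nx = m.n_rows;

  std::vector<uvec> shift_idx(n_off);
  for (int o = 0; o < n_off; ++o) {
    uvec ix(N);
    long s = shifts[o] % N;
    for (int k = 0; k < N; ++k) ix[k] = (uword)(((k - s) % N + N) % N);
    shift_idx[o] = ix;
  }

  const mat AL = A.cols(idxL);
  const mat AR = A.cols(idxR);

  // build the numerator caches from the current modulation state
  cube FL(nx, N, n_dir), FR(nx, N, n_dir);
  vec DL, DR;
  auto refresh = [&]() {
    mat WL = AL % m.cols(idxL);
    mat WR = AR % m.cols(idxR);
    for (int d = 0; d < n_dir; ++d) {
      FL.slice(d) = WL * HfL.slice(d);
      FR.slice(d) = WR * HfR.slice(d);
    }
    DL = sum(WL, 1);
    DR = sum(WR, 1);
  };
  refresh();

  EvalCtx ctx(FL, FR, ITmL, ITmR, ITb, DL, DR, shift_idx, k_gc, k_rect,
              p_rest, n_dir, n_off, measure);

  // best: one baseline column per stimulus condition (phase 1: column 0
  // for left-eye, column 1 for right-eye stimulation; phase 2: column 0
  // for the binocular ensemble). Sentinel best < 0 means no cached
  // previous-cycle response yet; evaluate the ensemble on the incoming
  // state.
  if (best.min() < 0) {
    double m_ie0 = mie.n_elem ? mie[0] : 1.0;
    if (phase == 1) {
      best.col(0) = ctx.eval_mono(0, m_ie0);
      best.col(1) = ctx.eval_mono(1, m_ie0);
    } else {
      best.col(0) = ctx.eval_bino(m_ie0);
      best.col(1).zeros();
    }
  }

  const int n_log = log_every > 0 ? (int)(n_cycles / log_every) + 2 : 1;
  mat log_mat(n_log, 4, fill::zeros);
  int log_row = 0;

  vec acol, mcol, dplus, dadj, mnew;
  for (uword c = 0; c < n_cycles; ++c) {
    const int k = sel[c];
    const int e = eye[k];
    const uword j = local[k];
    acol = A.col(k);
    mcol = m.col(k);
    dplus = clamp(mcol + dm, 0.0, 2.0) - mcol;

    vec resp0;
    if (baseline == 0) {
      resp0 = (phase == 1) ? ctx.eval_mono(e, mie[c]) : ctx.eval_bino(mie[c]);
    }

    vec upd = dplus % acol;
    if (e == 0) {
      for (int d = 0; d < n_dir; ++d) FL.slice(d) += upd * HfL.slice(d).row(j);
      if (!norm_frozen) DL += upd;
    } else {
      for (int d = 0; d < n_dir; ++d) FR.slice(d) += upd * HfR.slice(d).row(j);
      if (!norm_frozen) DR += upd;
    }
    m.col(k) = mcol + dplus;

    // with frozen normalisation the provisional response is evaluated
    // with the pre-increment weight normaliser: the accept test isolates
    // the channel's own contribution, renormalisation following only
    // after the decision
    vec resp = (phase == 1) ? ctx.eval_mono(e, mie[c]) : ctx.eval_bino(mie[c]);

    const uword bcol = (phase == 1) ? (uword)e : 0;
    vec base;
    if (baseline == 0) {
      // within-cycle comparison: the baseline is the same ensemble
      // evaluated on the incoming state (resp0, computed above before the
      // tentative update was applied)
      base = resp0;
    } else {
      base = best.col(bcol);
    }
    // a tie means the increment had no measurable effect (typically a
    // silent neuron): revert it without the penalty decrement
    uvec rej = find(resp < base);
    uvec tie = find(resp == base);
    uvec acc = find(resp > base);
    if (baseline == 1) {
      best.col(bcol) = resp;  // previous-cycle measured response
    } else if (baseline == 2) {
      vec bc = best.col(bcol);
      bc.elem(acc) = resp.elem(acc);
      best.col(bcol) = bc;  // running maximum, updated on acceptance
    } else {
      best.col(bcol) = resp;  // reporting only
    }

    if (rej.n_elem + tie.n_elem > 0) {
      mnew = m.col(k);
      vec target = clamp(mcol - dm, 0.0, 2.0);
      dadj = zeros<vec>(nx);
      dadj.elem(rej) = target.elem(rej) - mnew.elem(rej);
      dadj.elem(tie) = mcol.elem(tie) - mnew.elem(tie);
      vec upd2 = dadj % acol;
      if (e == 0) {
        for (int d = 0; d < n_dir; ++d)
          FL.slice(d) += upd2 * HfL.slice(d).row(j);
        if (!norm_frozen) DL += upd2;
      } else {
        for (int d = 0; d < n_dir; ++d)
          FR.slice(d) += upd2 * HfR.slice(d).row(j);
        if (!norm_frozen) DR += upd2;
      }
      m.col(k) = mnew + dadj;
    }
    if (norm_frozen) {
      vec dnet = (m.col(k) - mcol) % acol;
      if (e == 0) DL += dnet; else DR += dnet;
    }

    if (log_every > 0 && ((c + 1) % log_every == 0 || c + 1 == n_cycles) &&
        log_row < n_log) {
      log_mat(log_row, 0) = cycle0 + c + 1;
      log_mat(log_row, 1) = (phase == 1) ? mean(mean(best)) : mean(best.col(0));
      log_mat(log_row, 2) = best.max();
      log_mat(log_row, 3) = (double)acc.n_elem / nx;
      ++log_row;
    }

    // periodic full recompute cancels floating-point drift of the rank-1
    // updates; boundaries align with checkpoint segments so interrupted
    // and straight runs stay bit-identical
    if (refresh_every > 0 && (c + 1) % (uword)refresh_every == 0) refresh();

    if ((c & 255) == 0) Rcpp::checkUserInterrupt();
  }

  return Rcpp::List::create(
      Rcpp::Named("m") = m, Rcpp::Named("best") = best,
      Rcpp::Named("log") =
          log_row > 0 ? log_mat.rows(0, log_row - 1) : mat(0, 4));
}
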