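#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Reservation-based SOM training.
//
// neurons: M x C matrix (C = N*N cells, cell k = x + y*N in column k).
// items:   M x T matrix of membership vectors (all entries >= 0).
// alphas, radii: per-epoch schedules (length = number of epochs).
// n:       grid side N.
//
// Each epoch clears all reservations, visits the items in a freshly
// shuffled order (Fisher-Yates driven by R's RNG so runs reproduce under
// set.seed), lets each item reserve the unreserved neuron with minimal
// metric cosine distance (ties -> smallest row-major index), and trains
// every neuron within the Chebyshev radius of the reserved cell (reserved
// or not) with the convex rule q <- q + alpha (t - q).
//
// The update rule is affine in the fixed item vectors, so the trainer
// never touches the M-dimensional neurons in its hot loops. It maintains
//   D[j,k]    = <t_j, q_k>          (updated D <- (1-a) D + a G[,i]),
//   qnorm2[k] = |q_k|^2             (closed-form update via D[i,k]),
// and represents each neuron as q_k = a_k q0_k + s_k sum_j B[j,k] t_j,
// where an update only rescales a_k, s_k and bumps B[i,k] (O(1) amortized;
// s_k is renormalized into B before it underflows). The full neuron field
// is reconstructed once after the last epoch.
//
// Minimizing acos(dot/(|q||t|))/pi equals maximizing dot/|q| (|t| is a
// common positive factor and all vectors are non-negative), so the scan
// compares dot^2/|q|^2 and never evaluates acos or sqrt. The degenerate
// conventions d(0,0)=0 and d(0,p!=0)=1 map to +Inf and -1. Strict '>'
// over ascending k keeps the smallest row-major index on ties, exactly as
// the distance form would.
//
// Returns the trained neurons and the final epoch's reservation map
// (0-based cell index per item).
// prev0[t] (0-based cell, or -1) seeds each item's standing position: an
// item keeps its current cell whenever that cell exactly ties the scan's
// best similarity. Trained fields contain exact plateaus (cells updated
// purely toward one item are exactly parallel to it), and without this
// stickiness the assignment inside a plateau would depend on the epoch's
// shuffle order, defeating layout preservation across warm starts.
// [[Rcpp::export]]
List rsom_train_cpp(NumericMatrix neurons, NumericMatrix items,
                    NumericVector alphas, IntegerVector radii, int n,
                    IntegerVector prev0) {
  const int M = neurons.nrow();
  const int C = neurons.ncol();
  const int T = items.ncol();
  const int E = alphas.size();
  if (items.nrow() != M) stop("item dimension does not match grid dimension");
  if (T > C) stop("more items than grid cells");
  if (radii.size() != E) stop("alpha/radius schedules differ in length");

  const double *q0 = REAL(neurons);
  const double *tp = REAL(items);

  // item Gram matrix and squared norms (fixed for the whole run)
  std::vector<double> G((size_t)T * T), tnorm2(T);
  for (int i = 0; i < T; ++i) {
    const double *ti = tp + (size_t)i * M;
    for (int j = 0; j <= i; ++j) {
      const double *tj = tp + (size_t)j * M;
      double s = 0.0;
      for (int m = 0; m < M; ++m) s += ti[m] * tj[m];
      G[(size_t)i * T + j] = G[(size_t)j * T + i] = s;
    }
    tnorm2[i] = G[(size_t)i * T + i];
  }

  // D[j + k*T] = <t_j, q_k>; qnorm2[k] = |q_k|^2
  std::vector<double> D((size_t)T * C), qnorm2(C);
  for (int k = 0; k < C; ++k) {
    const double *qv = q0 + (size_t)k * M;
    double s = 0.0;
    for (int m = 0; m < M; ++m) s += qv[m] * qv[m];
    qnorm2[k] = s;
    for (int j = 0; j < T; ++j) {
      const double *tj = tp + (size_t)j * M;
      double d = 0.0;
      for (int m = 0; m < M; ++m) d += tj[m] * qv[m];
      D[(size_t)k * T + j] = d;
    }
  }

  // lazy neuron representation: q_k = a[k] q0_k + s[k] sum_j B[j,k] t_j
  std::vector<double> a(C, 1.0), s(C, 1.0), B((size_t)T * C, 0.0);

  // Standing positions carried in from a previous layout (warm starts);
  // fixed for the whole run. Within-run epochs use the plain smallest-index
  // tie rule: epoch-to-epoch contention around shared plateaus is what lets
  // similar (e.g. dominance-weighted) items coalesce.
  std::vector<int> order(T), assign(T, -1), sticky(T, -1);
  if (prev0.size() == T) {
    for (int t = 0; t < T; ++t) {
      if (prev0[t] >= 0 && prev0[t] < C) sticky[t] = assign[t] = prev0[t];
    }
  }
  std::vector<char> reserved(C, 0);

  // Reconstruct neuron k from its lazy representation.
  std::vector<double> qtmp(M > 0 ? M : 1);
  auto reconstruct = [&](int k, double *qv) {
    const double *q0v = q0 + (size_t)k * M;
    const double ak = a[k];
    for (int m = 0; m < M; ++m) qv[m] = ak * q0v[m];
    const double *bcol = &B[(size_t)k * T];
    for (int j = 0; j < T; ++j) {
      const double c = s[k] * bcol[j];
      if (c != 0.0) {
        const double *tj = tp + (size_t)j * M;
        for (int m = 0; m < M; ++m) qv[m] += c * tj[m];
      }
    }
  };

  // Recompute D and qnorm2 exactly from the reconstructed field. The
  // incremental updates drift at the last few bits over thousands of
  // epochs; on cosine plateaus (exact ties) that drift would make the
  // final reservations disagree with the returned field, breaking
  // warm-start reproducibility. Resyncing periodically and right before
  // the final epoch keeps them consistent.
  auto resync = [&]() {
    for (int k = 0; k < C; ++k) {
      reconstruct(k, qtmp.data());
      double sn = 0.0;
      for (int m = 0; m < M; ++m) sn += qtmp[m] * qtmp[m];
      qnorm2[k] = sn;
      double *dcol = &D[(size_t)k * T];
      for (int j = 0; j < T; ++j) {
        const double *tj = tp + (size_t)j * M;
        double d = 0.0;
        for (int m = 0; m < M; ++m) d += tj[m] * qtmp[m];
        dcol[j] = d;
      }
    }
  };

  RNGScope rng_scope;

  for (int e = 0; e < E; ++e) {
    const double alpha = alphas[e];
    const double keep = 1.0 - alpha;
    const int rad = radii[e];

    if (e == E - 1 && E > 1) resync();

    std::fill(reserved.begin(), reserved.end(), 0);
    for (int t = 0; t < T; ++t) order[t] = t;
    for (int t = T - 1; t > 0; --t) {  // Fisher-Yates via R's RNG
      int j = (int)std::floor(unif_rand() * (t + 1));
      if (j > t) j = t;
      std::swap(order[t], order[j]);
    }

    for (int oi = 0; oi < T; ++oi) {
      const int it = order[oi];
      const double tn2 = tnorm2[it];

      // best = argmax dot^2/|q|^2, compared by cross-multiplication so the
      // scan stays division-free; sim classes: +Inf (both zero), finite
      // ratio, -1 (exactly one zero vector).
      int best = -1;
      double best_num = -1.0, best_den = 1.0;  // ratio -1
      bool best_inf = false;
      for (int k = 0; k < C; ++k) {
        if (reserved[k]) continue;
        const double qn = qnorm2[k];
        if (qn <= 0.0) {
          if (tn2 == 0.0 && !best_inf) {  // d(0,0)=0 beats everything
            best = k; best_inf = true;
          } else if (best < 0) {          // d(0,p!=0)=1, ratio -1
            best = k;
          }
          continue;
        }
        if (best_inf) continue;
        double num, den;
        if (tn2 == 0.0) {
          num = -1.0; den = 1.0;
        } else {
          const double dot = D[(size_t)k * T + it];
          num = dot * dot; den = qn;
        }
        if (best < 0 || num * best_den > best_num * den) {
          best = k; best_num = num; best_den = den;
        }
      }
      // sticky ties with hysteresis: the item's carried-in standing cell
      // keeps it unless the scan's best is better by more than a 1e-12
      // relative margin. Plateau cells agree only to the last few ulps
      // (different update histories round differently), so exact equality
      // would not recognize them as the ties they mathematically are.
      const int pv = sticky[it];
      if (pv >= 0 && pv != best && !reserved[pv]) {
        const double qn = qnorm2[pv];
        bool tie;
        if (best_inf) {
          tie = (qn <= 0.0 && tn2 == 0.0);
        } else if (qn <= 0.0 || tn2 == 0.0) {
          tie = (best_num == -1.0 && best_den == 1.0);
        } else {
          const double dot = D[(size_t)pv * T + it];
          tie = (dot * dot * best_den >= best_num * qn * (1.0 - 1e-12));
        }
        if (tie) best = pv;
      }
      reserved[best] = 1;
      assign[it] = best;

      if (alpha > 0.0) {
        const int bx = best % n, by = best / n;
        const int x0 = std::max(0, bx - rad), x1 = std::min(n - 1, bx + rad);
        const int y0 = std::max(0, by - rad), y1 = std::min(n - 1, by + rad);
        const double *__restrict gcol = &G[(size_t)it * T];
        for (int y = y0; y <= y1; ++y) {
          for (int x = x0; x <= x1; ++x) {
            const int k = x + y * n;
            double *__restrict dcol = &D[(size_t)k * T];
            const double dti = dcol[it];
            qnorm2[k] = keep * keep * qnorm2[k] +
              2.0 * alpha * keep * dti + alpha * alpha * tn2;
            for (int j = 0; j < T; ++j) {
              dcol[j] = keep * dcol[j] + alpha * gcol[j];
            }
            double *bcol = &B[(size_t)k * T];
            if (alpha == 1.0) {
              a[k] = 0.0;
              s[k] = 1.0;
              for (int j = 0; j < T; ++j) bcol[j] = 0.0;
              bcol[it] = 1.0;
            } else {
              a[k] *= keep;
              s[k] *= keep;
              bcol[it] += alpha / s[k];
              if (s[k] < 1e-200) {  // fold the scale in before underflow
                for (int j = 0; j < T; ++j) bcol[j] *= s[k];
                s[k] = 1.0;  // a[k] decays separately (0 underflow is fine)
              }
            }
          }
        }
      }
    }

    if ((e & 1023) == 0) Rcpp::checkUserInterrupt();
  }

  // reconstruct the neuron field once
  NumericMatrix q(M, C);
  double *qp = REAL(q);
  for (int k = 0; k < C; ++k) reconstruct(k, qp + (size_t)k * M);

  IntegerVector res(T);
  for (int t = 0; t < T; ++t) res[t] = assign[t];
  return List::create(_["neurons"] = q, _["reservations"] = res);
}
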