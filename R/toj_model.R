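# Internal unit convention: SOAs are in milliseconds, so encoding rates
# (v_p, v_r, C) are events per millisecond. Reported capacities multiply by
# 1000 to give Hz; see hz() / per_ms().

#' Convert a per-millisecond rate to Hertz
#'
#' Attentional capacity is carried internally in events per millisecond
#' (matching SOAs in ms) and reported in Hz.
#'
#' @param rate_per_ms numeric rate(s) in events/ms.
#' @return numeric rate(s) in Hz.
#' @export
hz <- function(rate_per_ms) 1000 * rate_per_ms

#' Convert a rate in Hertz to events per millisecond
#'
#' @param rate_hz numeric rate(s) in Hz.
#' @return numeric rate(s) in events/ms.
#' @export
per_ms <- function(rate_hz) rate_hz / 1000

#' Split attentional capacity into race rates
#'
#' The fixed-capacity race assigns the probe the rate \eqn{v_p = C w} and the
#' reference \eqn{v_r = C (1 - w)}, so the two rates always sum to the
#' capacity C and the probe's share of the total rate equals its attentional
#' weight.
#'
#' @param C attentional capacity, events per millisecond, > 0.
#' @param w attentional weight of the probe, in (0, 1).
#' @return list with numeric components `v_p` and `v_r`.
#' @examples
#' reparameterize(0.1, 0.6)  # v_p = 0.06, v_r = 0.04
#' @export
reparameterize <- function(C, w) {
  stopifnot(is.numeric(C), is.numeric(w))
  if (any(!is.finite(C)) || any(C <= 0)) stop("C must be finite and > 0")
  if (any(!is.finite(w)) || any(w <= 0) || any(w >= 1)) {
    stop("w must lie strictly in (0, 1)")
  }
  list(v_p = C * w, v_r = C * (1 - w))
}

#' Recover capacity and weight from race rates
#'
#' Algebraic inverse of [reparameterize()]: \eqn{C = v_p + v_r},
#' \eqn{w = v_p / (v_p + v_r)}.
#'
#' @param v_p,v_r encoding rates of probe and reference, events/ms, > 0.
#' @return list with numeric components `C` and `w`.
#' @export
attention_from_rates <- function(v_p, v_r) {
  if (any(!is.finite(v_p)) || any(v_p <= 0) ||
      any(!is.finite(v_r)) || any(v_r <= 0)) {
    stop("rates must be finite and > 0")
  }
  list(C = v_p + v_r, w = v_p / (v_p + v_r))
}

#' Probability that the probe is judged to flicker first
#'
#' Closed-form psychometric function of the TVA exponential race. With
#' encoding times exponentially distributed at rates `v_p` (probe) and `v_r`
#' (reference), and the onsets separated by the stimulus-onset asynchrony
#' (negative SOA: probe leads; positive: reference leads), the probe is
#' encoded first with probability
#' \deqn{P = 1 - e^{-v_p |SOA|} + e^{-v_p |SOA|} \frac{v_p}{v_p + v_r}
#'   \quad (SOA < 0)}
#' \deqn{P = e^{-v_r |SOA|} \frac{v_p}{v_p + v_r} \quad (SOA \ge 0)}
#' The first branch sums the probability that the probe finishes during its
#' head start and the complementary event in which both race together and the
#' probe wins by the Luce choice ratio; the second branch is the mirror case
#' in which the reference must still be racing when the probe starts.
#'
#' @param v_p,v_r encoding rates in events/ms, > 0. Recycled against `soa`.
#' @param soa signed stimulus-onset asynchrony in ms; negative = probe leads.
#' @return numeric vector of probabilities, strictly inside (0, 1) for finite
#'   inputs.
#' @examples
#' p_probe_first(0.05, 0.05, 0)     # 0.5: equal rates, simultaneous onset
#' p_probe_first(0.05, 0.05, -100)  # 1 - exp(-5)/2
#' @export
p_probe_first <- function(v_p, v_r, soa) {
  if (any(!is.finite(v_p)) || any(v_p <= 0) ||
      any(!is.finite(v_r)) || any(v_r <= 0)) {
    stop("rates must be finite and > 0")
  }
  if (any(!is.finite(soa))) stop("soa must be finite")
  n <- max(length(v_p), length(v_r), length(soa))
  v_p <- rep_len(v_p, n); v_r <- rep_len(v_r, n); soa <- rep_len(soa, n)
  luce <- v_p / (v_p + v_r)
  a <- abs(soa)
  ifelse(soa < 0,
         1 - exp(-v_p * a) + exp(-v_p * a) * luce,
         exp(-v_r * a) * luce)
}

#' Probe-first probability parameterized by capacity and weight
#'
#' Convenience wrapper substituting \eqn{v_p = C w}, \eqn{v_r = C(1-w)} into
#' [p_probe_first()].
#'
#' @inheritParams reparameterize
#' @param soa signed SOA in ms.
#' @return numeric vector of probabilities.
#' @export
p_probe_first_cw <- function(C, w, soa) {
  v <- reparameterize(C, w)
  p_probe_first(v$v_p, v$v_r, soa)
}

# clamp probabilities away from 0/1 before taking logs so extreme parameter
# proposals during optimization/sampling cannot produce -Inf
.clamp_p <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)

#' Binomial log-likelihood of TOJ counts under the race model
#'
#' Sums, over SOA cells, the binomial log-mass of the observed probe-first
#' counts with success probability given by the closed-form race model.
#'
#' @param counts data frame with columns `soa` (ms), `n_trials`,
#'   `k_probe_first`.
#' @param C capacity in events/ms.
#' @param w probe weight in (0, 1).
#' @return scalar log-likelihood; 0 for an empty table or all-zero `n_trials`.
#' @export
toj_log_likelihood <- function(counts, C, w) {
  stopifnot(is.data.frame(counts),
            all(c("soa", "n_trials", "k_probe_first") %in% names(counts)))
  if (nrow(counts) == 0L) return(0)
  if (any(counts$n_trials < 0)) stop("n_trials must be non-negative")
  if (any(counts$k_probe_first < 0) ||
      any(counts$k_probe_first > counts$n_trials)) {
    stop("k_probe_first must lie in [0, n_trials]")
  }
  p <- .clamp_p(p_probe_first_cw(C, w, counts$soa))
  sum(stats::dbinom(counts$k_probe_first, counts$n_trials, p, log = TRUE))
}
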