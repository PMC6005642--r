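#' History-dependent observation process pairs
#'
#' A process pair represents the two random processes an observer must
#' distinguish: the sequence of observations generated when the correct
#' opinion is 0 versus 1. The processes may have memory — the distribution
#' of the next observation can depend on everything seen so far — which is
#' exactly the situation of two multi-valued biased coins whose bias
#' changes with wear.
#'
#' @param next_dist `function(hypothesis, history)` returning the
#'   probability vector of the next observation; `hypothesis` is 0 or 1
#'   and `history` an integer vector of past outcomes (1-based indices,
#'   possibly empty).
#' @param n_outcomes number of possible outcomes per observation.
#' @param outcomes optional outcome labels.
#' @return an object of class `process_pair`.
#' @export
process_pair <- function(next_dist, n_outcomes, outcomes = NULL) {
  stopifnot(is.function(next_dist), n_outcomes >= 2)
  if (is.null(outcomes)) outcomes <- paste0("o", seq_len(n_outcomes))
  structure(list(next_dist = next_dist, k = as.integer(n_outcomes),
                 outcomes = outcomes),
            class = "process_pair")
}

#' Memoryless process pair
#'
#' @param p0,p1 probability vectors over a common outcome set; every
#'   observation is an independent draw from `p0` (hypothesis 0) or `p1`.
#' @return a `process_pair`.
#' @export
memoryless_pair <- function(p0, p1) {
  stopifnot(length(p0) == length(p1))
  process_pair(function(hyp, history) if (hyp == 0L) p0 else p1,
               length(p0))
}

dist_checked <- function(pair, hyp, history) {
  p <- pair$next_dist(hyp, history)
  if (length(p) != pair$k || abs(sum(p) - 1) > 1e-12 || any(p < 0)) {
    stop("next_dist returned an invalid distribution")
  }
  p
}

guard_horizon <- function(pair, t) {
  if (pair$k^t > 1e6) {
    stop("horizon too large for exhaustive enumeration (k^t > 1e6)")
  }
}

#' l1 distance between two probability vectors
#'
#' The per-step process gap: the sum of absolute differences between the
#' two hypotheses' next-outcome probabilities given a common history.
#'
#' @param p0,p1 equal-length probability vectors.
#' @return a number in \[0, 2\].
#' @examples
#' l1_gap(c(0.51, 0.49), c(0.43, 0.57))  # 0.16
#' @export
l1_gap <- function(p0, p1) {
  if (length(p0) != length(p1)) stop("probability vectors differ in length")
  sum(abs(p0 - p1))
}

# Depth-first walk over all histories reachable (positive probability under
# either hypothesis) up to length `t`, invoking visit(history, p0_reach,
# p1_reach, d0, d1) with the reach probabilities of the history and the two
# conditional next-outcome distributions at it.
walk_histories <- function(pair, t, visit) {
  recurse <- function(history, r0, r1) {
    d0 <- dist_checked(pair, 0L, history)
    d1 <- dist_checked(pair, 1L, history)
    visit(history, r0, r1, d0, d1)
    if (length(history) < t - 1L) {
      for (o in seq_len(pair$k)) {
        n0 <- r0 * d0[o]
        n1 <- r1 * d1[o]
        if (n0 > 0 || n1 > 0) recurse(c(history, o), n0, n1)
      }
    }
  }
  if (t >= 1L) recurse(integer(0), 1, 1)
  invisible(NULL)
}

#' Extract the (eps, delta) difficulty parameters of a process pair
#'
#' `eps` is the maximum, over all histories of length < t reachable with
#' positive probability under either hypothesis, of the l1 distance
#' between the two conditional next-outcome distributions; it measures how
#' far apart the processes can ever drift in one step. `delta` is the
#' minimum conditional probability of any outcome over both hypotheses and
#' all reachable histories; it lower-bounds the probability of attaining
#' any observation. `eps_linf` additionally reports the per-outcome
#' (max-abs) version of the gap.
#'
#' @param pair a `process_pair`.
#' @param t horizon (number of observations analysed exhaustively; the
#'   enumeration guard requires `k^t <= 1e6`).
#' @return list of class `pair_params` with `eps`, `eps_linf`, `delta`,
#'   `t`.
#' @export
pair_params <- function(pair, t) {
  guard_horizon(pair, t)
  eps <- 0; eps_linf <- 0; delta <- 1
  walk_histories(pair, t, function(history, r0, r1, d0, d1) {
    eps <<- max(eps, sum(abs(d0 - d1)))
    eps_linf <<- max(eps_linf, max(abs(d0 - d1)))
    delta <<- min(delta, d0, d1)
  })
  structure(list(eps = eps, eps_linf = eps_linf, delta = delta, t = t),
            class = "pair_params")
}

#' Chain-rule KL divergence between observation sequences
#'
#' Computes `KL(P0(<=t) || P1(<=t))` — the divergence between the two
#' processes' joint distributions over the first t observations — via the
#' chain rule: the sum over steps of the expectation, under hypothesis 0,
#' of the conditional KL between the next-outcome distributions given the
#' history. Returned in nats. `Inf` when some outcome has positive
#' probability under hypothesis 0 but zero under hypothesis 1 at a
#' P0-reachable history.
#'
#' @inheritParams pair_params
#' @return KL divergence in nats.
#' @export
chain_rule_kl <- function(pair, t) {
  guard_horizon(pair, t)
  total <- 0
  walk_histories(pair, t, function(history, r0, r1, d0, d1) {
    if (r0 <= 0) return(invisible(NULL))
    pos <- d0 > 0
    if (any(pos & d1 == 0)) {
      total <<- Inf
    } else if (is.finite(total)) {
      total <<- total + r0 * sum(d0[pos] * log(d0[pos] / d1[pos]))
    }
  })
  total
}

#' Brute-force KL divergence over full length-t sequences
#'
#' Independent verification oracle for [chain_rule_kl()]: explicitly
#' enumerates all k^t observation sequences, builds both joint
#' distributions, and sums `p0 * log(p0 / p1)`.
#'
#' @inheritParams pair_params
#' @return KL divergence in nats.
#' @export
joint_kl_oracle <- function(pair, t) {
  guard_horizon(pair, t)
  total <- 0
  recurse <- function(history, p0, p1) {
    if (length(history) == t) {
      if (p0 > 0) {
        if (p1 == 0) total <<- Inf
        else if (is.finite(total)) total <<- total + p0 * log(p0 / p1)
      }
      return(invisible(NULL))
    }
    d0 <- dist_checked(pair, 0L, history)
    d1 <- dist_checked(pair, 1L, history)
    for (o in seq_len(pair$k)) {
      if (p0 * d0[o] > 0 || p1 * d1[o] > 0) {
        recurse(c(history, o), p0 * d0[o], p1 * d1[o])
      }
    }
  }
  recurse(integer(0), 1, 1)
  total
}

#' Budget bound on the chain-rule KL divergence
#'
#' After t observations of a process pair with difficulty parameters
#' (eps, delta), the joint KL divergence can grow at most linearly:
#' `KL(P0(<=t) || P1(<=t)) <= t * eps^2 / delta`. The constant 1 follows
#' from the per-step bound KL <= chi-square <= (l1 gap)^2 / (min prob).
#' This is the mechanism behind slow spreading: per-step information gain
#' is quadratic in the tiny gap eps, inflated only by 1/delta.
#'
#' @param t number of observations.
#' @param params a `pair_params` (or any list with `eps` and `delta`).
#' @return the bound in nats (`Inf` when `delta` = 0).
#' @export
kl_budget_bound <- function(t, params) {
  if (params$delta <= 0) return(Inf)
  t * params$eps^2 / params$delta
}

#' Lower bounds on distinguishing error from a KL budget
#'
#' Two standard lower bounds on the error probability of any rule that
#' must decide between the hypotheses from observations whose joint
#' distributions are KL nats apart (uniform prior): the Pinsker-based
#' bound `(1 - sqrt(KL/2)) / 2` and the Bretagnolle-Huber bound
#' `exp(-KL) / 4`. Both certify that a small KL budget forces the error to
#' stay near 1/2; Bretagnolle-Huber stays informative for large KL.
#'
#' @param kl KL divergence in nats (>= 0).
#' @return list with `pinsker_based` and `bretagnolle_huber`.
#' @examples
#' error_lower_bounds(0)  # indistinguishable: error at least 1/2
#' @export
error_lower_bounds <- function(kl) {
  stopifnot(kl >= 0)
  list(pinsker_based = max(0, (1 - sqrt(kl / 2)) / 2),
       bretagnolle_huber = exp(-kl) / 4)
}

#' Exact Bayes error of the optimal distinguisher
#'
#' Enumerates all length-t observation sequences and computes the minimal
#' achievable error probability of any decision rule:
#' `sum over sequences of min(prior * p1, (1 - prior) * p0)`.
#'
#' @inheritParams pair_params
#' @param prior prior probability of hypothesis 1.
#' @return the Bayes error probability.
#' @export
bayes_error_oracle <- function(pair, t, prior = 0.5) {
  guard_horizon(pair, t)
  stopifnot(prior >= 0, prior <= 1)
  total <- 0
  recurse <- function(history, p0, p1) {
    if (length(history) == t) {
      total <<- total + min(prior * p1, (1 - prior) * p0)
      return(invisible(NULL))
    }
    d0 <- dist_checked(pair, 0L, history)
    d1 <- dist_checked(pair, 1L, history)
    for (o in seq_len(pair$k)) {
      if (p0 * d0[o] > 0 || p1 * d1[o] > 0) {
        recurse(c(history, o), p0 * d0[o], p1 * d1[o])
      }
    }
  }
  recurse(integer(0), 1, 1)
  total
}

#' Worked two-coin example with wear
#'
#' A concrete two-outcome process pair (outcomes H = 1, T = 2) whose
#' conditional head probability drifts with the running head/tail
#' imbalance of the history — the coins wear as they are tossed, and the
#' wear rate differs between the two coin types. After the history
#' H, T, T, H, T, T (two heads, four tails) the conditionals are exactly
#' `(0.51, 0.49)` under hypothesis 0 and `(0.43, 0.57)` under hypothesis
#' 1, so the per-step l1 gap at that history is
#' `|0.51 - 0.43| + |0.49 - 0.57| = 0.16`.
#'
#' @return list with `pair` (a `process_pair`), the witness `history`
#'   (integer vector), and `gap` (its l1 gap).
#' @export
worn_coin_pair <- function() {
  base <- c(0.55, 0.51)   # head probability of a fresh coin, per hypothesis
  wear <- c(0.02, 0.04)   # drift per unit of (heads - tails) imbalance
  next_dist <- function(hyp, history) {
    imb <- sum(history == 1L) - sum(history == 2L)
    h <- min(max(base[hyp + 1L] + wear[hyp + 1L] * imb, 0.05), 0.95)
    c(h, 1 - h)
  }
  pair <- process_pair(next_dist, 2L, outcomes = c("H", "T"))
  history <- c(1L, 2L, 2L, 1L, 2L, 2L)
  gap <- l1_gap(pair$next_dist(0L, history), pair$next_dist(1L, history))
  list(pair = pair, history = history, gap = gap)
}
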