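#' The attracting-sink relay protocol
#'
#' For an odd alphabet of size k, sources always display the endpoint
#' symbol encoding the correct opinion (symbol 1 for opinion 0, symbol k
#' for opinion 1). Every other agent displays the middle symbol until it
#' first observes an endpoint, at which point it adopts the opinion that
#' endpoint encodes and displays that endpoint from then on. Under noise
#' that can only confuse consecutive symbols, endpoints are never produced
#' by noise acting on the default display, so the relayed opinion spreads
#' undisturbed; under fully uniform noise the endpoints observed carry no
#' information and the protocol fails.
#'
#' Before adopting, an agent outputs a fair coin drawn at initialisation
#' (this makes the error probability well defined at every round). By
#' default the first adoption is permanent; `adoption = "latest"` lets
#' later endpoint sightings overwrite it (sensitivity variant).
#'
#' @param k odd alphabet size >= 3.
#' @param adoption `"permanent"` (default) or `"latest"`.
#' @return a pull `spread_protocol`.
#' @examples
#' pr <- make_sink_protocol(5)
#' @export
make_sink_protocol <- function(k, adoption = c("permanent", "latest")) {
  adoption <- match.arg(adoption)
  k <- as.integer(k)
  if (k < 3L || k %% 2L == 0L) stop("sink protocol needs an odd k >= 3")
  mid <- (k + 1L) %/% 2L
  new_spread_protocol(
    name = sprintf("sink(k=%d)", k), model = "pull", k = k,
    init = function(n, source_ids, correct_opinion) {
      src <- seq_len(n) %in% source_ids
      disp <- rep(mid, n)
      disp[src] <- if (correct_opinion == 1L) k else 1L
      list(display = disp, adopted = src,
           opinion = ifelse(src, correct_opinion,
                            stats::rbinom(n, 1L, 0.5)),
           source = src)
    },
    display = function(state) state$display,
    update = function(state, obs) {
      for (j in seq_len(ncol(obs))) {
        o <- obs[, j]
        open <- !state$source &
          (if (adoption == "permanent") !state$adopted else TRUE)
        hit <- open & !is.na(o) & (o == 1L | o == k)
        if (any(hit)) {
          state$display[hit] <- o[hit]
          state$adopted[hit] <- TRUE
          state$opinion[hit] <- as.integer(o[hit] == k)
        }
      }
      state
    },
    output = function(state) state$opinion
  )
}

#' Static-display protocol
#'
#' Sources permanently display `opinion_symbols[correct_opinion + 1]`;
#' every other agent permanently displays `default`. No agent ever changes
#' state, which makes the induced observation process an i.i.d. mixture
#' and the exact Bayesian observer tractable (see [bayes_update()]).
#' Non-source outputs are a fair coin fixed at initialisation.
#'
#' @param default symbol index displayed by non-sources.
#' @param opinion_symbols length-2 integer vector: the symbols displayed
#'   by sources under correct opinion 0 and 1 (collisions with `default`
#'   are allowed).
#' @return a pull `spread_protocol`.
#' @export
make_static_display <- function(default, opinion_symbols) {
  default <- as.integer(default)
  opinion_symbols <- as.integer(opinion_symbols)
  stopifnot(length(opinion_symbols) == 2L)
  new_spread_protocol(
    name = "static-display", model = "pull",
    init = function(n, source_ids, correct_opinion) {
      src <- seq_len(n) %in% source_ids
      disp <- rep(default, n)
      disp[src] <- opinion_symbols[correct_opinion + 1L]
      list(display = disp, source = src,
           opinion = ifelse(src, correct_opinion,
                            stats::rbinom(n, 1L, 0.5)))
    },
    display = function(state) state$display,
    update = function(state, obs) state,
    output = function(state) state$opinion
  )
}

#' Per-step observation mixtures of the static-display broadcast process
#'
#' Under [run_broadcast_pull()] with the static-display protocol, each
#' observed symbol is an i.i.d. draw from the mixture
#' `Q_b = ((n-s)/n) P[default, ] + (s/n) P[opinion_b, ]` for hypothesis
#' b in \{0, 1\}. The hypotheses differ only through the rare (prob s/n)
#' event that the broadcast agent is a source, and only to the extent that
#' noise does not flatten the source's symbol, which is why the per-step
#' l1 gap equals `2 (s/n) (1 - delta k)` for the uniform noise matrix.
#'
#' @param n,s population and source counts.
#' @param P a `noise_matrix`.
#' @param default,opinion_symbols as in [make_static_display()].
#' @return list with components `q0` and `q1`, probability vectors over
#'   the alphabet.
#' @export
broadcast_mixture <- function(n, s, P, default, opinion_symbols) {
  check_noise_matrix(P)
  w <- s / n
  q <- function(b) {
    (1 - w) * unclass(P)[default, ] + w * unclass(P)[opinion_symbols[b + 1L], ]
  }
  list(q0 = unname(q(0L)), q1 = unname(q(1L)))
}

#' Observer beliefs and their exact Bayesian update
#'
#' `observer_belief()` creates a belief state (posterior probability that
#' the correct opinion is 1, plus an observation count). `bayes_update()`
#' applies one exact Bayes step for the static-display broadcast scenario,
#' where the observer knows n, s, the noise matrix and the display map:
#' `posterior <- prior q1(o) / (prior q1(o) + (1 - prior) q0(o))`.
#'
#' @param prior initial probability that the correct opinion is 1.
#' @param belief an `observer_belief`.
#' @param observed observed symbol index.
#' @param n,s,P,default,opinion_symbols scenario parameters (see
#'   [broadcast_mixture()]).
#' @return an updated `observer_belief`.
#' @examples
#' P <- build_confusion("uniform", 2, 0.3)
#' b <- bayes_update(observer_belief(), 2L, n = 10, s = 1, P = P,
#'                   default = 1L, opinion_symbols = c(1L, 2L))
#' b$posterior  # 0.53125
#' @export
observer_belief <- function(prior = 0.5) {
  stopifnot(prior >= 0, prior <= 1)
  structure(list(posterior = prior, count = 0L), class = "observer_belief")
}

#' @rdname observer_belief
#' @export
bayes_update <- function(belief, observed, n, s, P, default, opinion_symbols) {
  stopifnot(inherits(belief, "observer_belief"))
  mix <- broadcast_mixture(n, s, P, default, opinion_symbols)
  p1 <- belief$posterior * mix$q1[observed]
  p0 <- (1 - belief$posterior) * mix$q0[observed]
  if (p1 + p0 <= 0) {
    stop("observation has probability zero under both hypotheses")
  }
  structure(list(posterior = p1 / (p1 + p0), count = belief$count + 1L),
            class = "observer_belief")
}

#' Broadcast steps until an observer is confident of the correct opinion
#'
#' Simulates the static-display broadcast-PULL observation process under
#' the true hypothesis and returns the first step at which the exact
#' Bayesian posterior of the true hypothesis exceeds `threshold`. Because
#' the observations are i.i.d. mixture draws, the simulation runs the
#' log-posterior as a cumulative-sum first-passage problem in blocks,
#' which keeps large populations cheap.
#'
#' @inheritParams broadcast_mixture
#' @param correct_opinion the true hypothesis bit (default 1).
#' @param threshold confidence threshold in (1/2, 1); default 2/3.
#' @param prior prior probability of opinion 1.
#' @param max_steps give up after this many steps (returns `NA`).
#' @param seed optional seed.
#' @return integer step count, or `NA_integer_` if the threshold is never
#'   reached (e.g. when the mixtures coincide at delta = 1/k).
#' @export
certainty_time <- function(n, s, P, default = 1L,
                           opinion_symbols = c(1L, 2L),
                           correct_opinion = 1L, threshold = 2 / 3,
                           prior = 0.5, max_steps = 5e6, seed = NULL) {
  stopifnot(threshold > 0.5, threshold < 1)
  if (!is.null(seed)) set.seed(seed)
  mix <- broadcast_mixture(n, s, P, default, opinion_symbols)
  if (correct_opinion == 1L) {
    qt <- mix$q1; qf <- mix$q0; prior_true <- prior
  } else {
    qt <- mix$q0; qf <- mix$q1; prior_true <- 1 - prior
  }
  llr <- log(qt) - log(qf)
  if (all(abs(llr) < 1e-15)) return(NA_integer_)   # indistinguishable
  bar <- log(threshold / (1 - threshold)) -
    log(prior_true / (1 - prior_true))
  if (bar <= 0) return(0L)
  done <- 0L
  carry <- 0
  block <- 8192L
  while (done < max_steps) {
    m <- min(block, max_steps - done)
    o <- sample.int(length(qt), m, replace = TRUE, prob = qt)
    cum <- carry + cumsum(llr[o])
    hit <- which(cum > bar)
    if (length(hit)) return(done + hit[1L])
    done <- done + m
    carry <- cum[m]
    block <- min(block * 2L, 262144L)
  }
  NA_integer_
}

#' Two-stage push protocol with silence-gated spreading
#'
#' A simplified demonstrator of how active (push) communication escapes
#' the slow-spreading regime even when message content is noisy: the fact
#' that a message arrives at all is reliable, and agents exploit it by
#' staying silent until they have something to say.
#'
#' Stage 1 (`spread_rounds` rounds): with `warmup = "relay"` (default)
#' only informed agents (initially the sources) push their current guess,
#' and an uninformed agent that receives messages adopts their majority
#' value (ties broken by a fair coin) and becomes informed. With
#' `warmup = "source_only"` every non-source agent stays silent during
#' stage 1, so the stage-1 informed cohort consists purely of agents that
#' heard the source directly; this forgoes early growth but seeds stage 2
#' with high-quality guesses and makes the eventual consensus direction
#' far more reliable (relayed chains of noisy adoptions are barely better
#' than coin flips and can herd the whole population onto the wrong
#' opinion).
#'
#' Stage 2 (`boost_rounds` rounds): all informed agents push their guess
#' every round, and any agent that receives a message becomes informed.
#' Each agent accumulates every message received during the
#' stage in a running tally and resets its guess to the tally's majority
#' (`boost = "cumulative"`, the default) or to the majority of the current
#' round only (`boost = "round"`); ties leave the guess unchanged. The
#' cumulative variant is the one that actually amplifies the stage-1 bias:
#' per-round majorities keep discarding evidence and stall near chance.
#'
#' Agents that never receive a message output a fair coin drawn at
#' initialisation.
#'
#' @param spread_rounds,boost_rounds stage lengths (rounds, >= 1).
#' @param boost `"cumulative"` or `"round"` stage-2 aggregation.
#' @param warmup `"relay"` or `"source_only"` stage-1 spreading rule.
#' @return a push `spread_protocol` for [run_parallel_push()] with k = 2
#'   (symbol 1 encodes guess 0, symbol 2 encodes guess 1).
#' @export
make_push_boost <- function(spread_rounds, boost_rounds,
                            boost = c("cumulative", "round"),
                            warmup = c("relay", "source_only")) {
  boost <- match.arg(boost)
  warmup <- match.arg(warmup)
  stopifnot(spread_rounds >= 1, boost_rounds >= 1)
  count_votes <- function(inbox) {
    up <- vapply(inbox, function(v) sum(v == 2L), integer(1))
    down <- vapply(inbox, function(v) sum(v == 1L), integer(1))
    up - down
  }
  new_spread_protocol(
    name = sprintf("push-boost(%d+%d,%s,%s)", spread_rounds, boost_rounds,
                   boost, warmup),
    model = "push", k = 2L,
    init = function(n, source_ids, correct_opinion) {
      src <- seq_len(n) %in% source_ids
      list(source = src, informed = src,
           guess = ifelse(src, correct_opinion, stats::rbinom(n, 1L, 0.5)),
           tally = numeric(n), round = 0L)
    },
    display = function(state) {
      push <- if (warmup == "source_only" && state$round < spread_rounds) {
        state$source
      } else {
        state$informed
      }
      ifelse(push, state$guess + 1L, NA_integer_)
    },
    update = function(state, inbox) {
      state$round <- state$round + 1L
      votes <- count_votes(inbox)
      got <- lengths(inbox) > 0L
      if (state$round <= spread_rounds) {
        adopt <- got & !state$informed
        if (any(adopt)) {
          g <- as.integer(votes[adopt] > 0L)
          tie <- votes[adopt] == 0L
          if (any(tie)) g[tie] <- stats::rbinom(sum(tie), 1L, 0.5)
          state$guess[adopt] <- g
          state$informed[adopt] <- TRUE
          state$ever_informed[adopt] <- TRUE
        }
      } else {
        state$informed <- state$informed | got
        if (boost == "cumulative") {
          state$tally <- state$tally + votes
          dec <- !state$source & state$tally != 0
          state$guess[dec] <- as.integer(state$tally[dec] > 0)
        } else {
          dec <- !state$source & got & votes != 0
          state$guess[dec] <- as.integer(votes[dec] > 0)
        }
      }
      state
    },
    output = function(state) state$guess
  )
}
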