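#' Protocol contract
#'
#' A spread protocol is a set of population-level functions operated by the
#' interaction engines. All functions act on the whole population at once
#' (vectors of length n) — semantically each agent still only sees its own
#' state and observations.
#'
#' * `init(n, source_ids, correct_opinion)` builds the internal state.
#'   Non-source entries of the state must not depend on `correct_opinion`.
#' * `display(state)` returns an integer vector of displayed symbol
#'   indices. `NA` means silent and is only legal under the push engine.
#' * `update(state, obs)` consumes one round of observations. Under the
#'   pull engines `obs` is an integer matrix (n rows, one column per
#'   observation in the round; `NA` = no observation delivered to that
#'   agent). Under the push engine `obs` is a list of n integer vectors
#'   (the multiset of noisy messages received).
#' * `output(state)` returns each agent's current opinion bit (0/1).
#'
#' All protocol randomness must come from R's RNG so that a seeded run is
#' reproducible.
#'
#' @param name protocol label stored in traces.
#' @param init,display,update,output the contract functions (see above).
#' @param model `"pull"` or `"push"`.
#' @param k alphabet size the protocol expects (informational).
#' @return an object of class `spread_protocol`.
#' @export
new_spread_protocol <- function(name, init, display, update, output,
                                model = c("pull", "push"), k = NULL) {
  model <- match.arg(model)
  structure(
    list(name = name, init = init, display = display, update = update,
         output = output, model = model, k = k),
    class = "spread_protocol"
  )
}

#' @export
print.spread_protocol <- function(x, ...) {
  cat("spread protocol:", x$name, sprintf("(%s model)\n", x$model))
  invisible(x)
}

#' Population configuration
#'
#' @param n population size.
#' @param source_ids integer identities (in 1..n) of the source agents,
#'   which know the correct opinion.
#' @param correct_opinion the bit (0/1) shared by all sources.
#' @return a validated list of class `population_config`.
#' @export
population_config <- function(n, source_ids = 1L, correct_opinion = 1L) {
  n <- as.integer(n)
  source_ids <- sort(unique(as.integer(source_ids)))
  stopifnot(n >= 2, length(source_ids) >= 1, length(source_ids) < n,
            all(source_ids >= 1L), all(source_ids <= n),
            correct_opinion %in% c(0L, 1L))
  structure(list(n = n, source_ids = source_ids, s = length(source_ids),
                 correct_opinion = as.integer(correct_opinion)),
            class = "population_config")
}

new_trace <- function(model, cfg, protocol, displays, outputs, seed) {
  structure(
    list(model = model, n = cfg$n, source_ids = cfg$source_ids,
         correct_opinion = cfg$correct_opinion, protocol = protocol$name,
         displays = displays, outputs = outputs, seed = seed,
         rounds_run = nrow(displays)),
    class = "spread_trace"
  )
}

#' @export
print.spread_trace <- function(x, ...) {
  cat(sprintf("spread trace: %s, n = %d, s = %d, %d %s recorded\n",
              x$model, x$n, length(x$source_ids), x$rounds_run,
              if (x$model %in% c("parallel-pull", "parallel-push")) "rounds" else "steps"))
  invisible(x)
}

all_correct_now <- function(outputs, cfg) {
  ns <- setdiff(seq_len(cfg$n), cfg$source_ids)
  all(outputs[ns] == cfg$correct_opinion)
}

sample_targets <- function(n, m, include_self, self_ids) {
  if (include_self) {
    sample.int(n, m, replace = TRUE)
  } else {
    t <- sample.int(n - 1L, m, replace = TRUE)
    t + (t >= self_ids)
  }
}

run_engine_checks <- function(protocol, cfg, P, horizon) {
  stopifnot(inherits(protocol, "spread_protocol"),
            inherits(cfg, "population_config"), horizon >= 1)
  check_noise_matrix(P)
}

#' Run a synchronous parallel-PULL round model
#'
#' In every round each agent observes the message displayed (at the start
#' of the round) by `obs_per_round` agents chosen independently and
#' uniformly at random; each observation passes independently through the
#' noise matrix. All agents then update simultaneously.
#'
#' @param protocol a pull `spread_protocol`.
#' @param cfg a `population_config`.
#' @param P a `noise_matrix`.
#' @param max_rounds maximum number of rounds (default `50 * n`).
#' @param obs_per_round observations per agent per round (default 1).
#' @param include_self whether the uniform target choice includes the
#'   observer itself (default TRUE: uniform over all n agents).
#' @param stop `"none"` or `"all_correct"` (truncate once every non-source
#'   agent outputs the correct opinion).
#' @param seed optional integer seed (set before initialisation).
#' @return a `spread_trace` with per-round `displays` and `outputs`
#'   matrices (rows = rounds recorded after each update).
#' @export
run_parallel_pull <- function(protocol, cfg, P, max_rounds = 50L * cfg$n,
                              obs_per_round = 1L, include_self = TRUE,
                              stop = c("none", "all_correct"), seed = NULL) {
  stop <- match.arg(stop)
  run_engine_checks(protocol, cfg, P, max_rounds)
  if (protocol$model != "pull") stop("protocol is not a pull protocol")
  if (!is.null(seed)) set.seed(seed)
  n <- cfg$n
  self <- rep(seq_len(n), obs_per_round)
  state <- protocol$init(n, cfg$source_ids, cfg$correct_opinion)
  displays <- matrix(NA_integer_, max_rounds, n)
  outputs <- matrix(NA_integer_, max_rounds, n)
  rounds <- 0L
  for (r in seq_len(max_rounds)) {
    disp <- protocol$display(state)
    if (anyNA(disp)) stop("SILENT display is not allowed under pull engines")
    targets <- sample_targets(n, n * obs_per_round, include_self, self)
    obs <- matrix(sample_symbol_idx(P, disp[targets]), n, obs_per_round)
    state <- protocol$update(state, obs)
    rounds <- r
    displays[r, ] <- protocol$display(state)
    out <- protocol$output(state)
    outputs[r, ] <- out
    if (stop == "all_correct" && all_correct_now(out, cfg)) break
  }
  new_trace("parallel-pull", cfg, protocol,
            displays[seq_len(rounds), , drop = FALSE],
            outputs[seq_len(rounds), , drop = FALSE], seed)
}

#' Run the broadcast-PULL step model
#'
#' At each time step one agent is chosen uniformly at random, a single
#' noisy sample of its displayed message is drawn, and every agent
#' receives that same sample.
#'
#' @inheritParams run_parallel_pull
#' @param max_steps maximum number of steps.
#' @return a `spread_trace` with one row per step.
#' @export
run_broadcast_pull <- function(protocol, cfg, P, max_steps = 50L * cfg$n^2,
                               stop = c("none", "all_correct"), seed = NULL) {
  stop <- match.arg(stop)
  run_engine_checks(protocol, cfg, P, max_steps)
  if (protocol$model != "pull") stop("protocol is not a pull protocol")
  if (!is.null(seed)) set.seed(seed)
  n <- cfg$n
  state <- protocol$init(n, cfg$source_ids, cfg$correct_opinion)
  displays <- matrix(NA_integer_, max_steps, n)
  outputs <- matrix(NA_integer_, max_steps, n)
  steps <- 0L
  for (t in seq_len(max_steps)) {
    disp <- protocol$display(state)
    if (anyNA(disp)) stop("SILENT display is not allowed under pull engines")
    v <- sample.int(n, 1L)
    o <- sample_symbol_idx(P, disp[v])
    state <- protocol$update(state, matrix(o, n, 1L))
    steps <- t
    displays[t, ] <- protocol$display(state)
    out <- protocol$output(state)
    outputs[t, ] <- out
    if (stop == "all_correct" && all_correct_now(out, cfg)) break
  }
  new_trace("broadcast-pull", cfg, protocol,
            displays[seq_len(steps), , drop = FALSE],
            outputs[seq_len(steps), , drop = FALSE], seed)
}

#' Run the sequential-PULL step model
#'
#' At each step an ordered pair (u, v) is chosen uniformly at random and
#' only u observes (a noisy sample of) v's display.
#'
#' @inheritParams run_broadcast_pull
#' @param include_self whether v may equal u.
#' @return a `spread_trace` with one row per step.
#' @export
run_sequential_pull <- function(protocol, cfg, P, max_steps = 50L * cfg$n^2,
                                include_self = TRUE,
                                stop = c("none", "all_correct"), seed = NULL) {
  stop <- match.arg(stop)
  run_engine_checks(protocol, cfg, P, max_steps)
  if (protocol$model != "pull") stop("protocol is not a pull protocol")
  if (!is.null(seed)) set.seed(seed)
  n <- cfg$n
  state <- protocol$init(n, cfg$source_ids, cfg$correct_opinion)
  displays <- matrix(NA_integer_, max_steps, n)
  outputs <- matrix(NA_integer_, max_steps, n)
  steps <- 0L
  for (t in seq_len(max_steps)) {
    disp <- protocol$display(state)
    if (anyNA(disp)) stop("SILENT display is not allowed under pull engines")
    u <- sample.int(n, 1L)
    v <- sample_targets(n, 1L, include_self, u)
    obs <- matrix(NA_integer_, n, 1L)
    obs[u, 1L] <- sample_symbol_idx(P, disp[v])
    state <- protocol$update(state, obs)
    steps <- t
    displays[t, ] <- protocol$display(state)
    out <- protocol$output(state)
    outputs[t, ] <- out
    if (stop == "all_correct" && all_correct_now(out, cfg)) break
  }
  new_trace("sequential-pull", cfg, protocol,
            displays[seq_len(steps), , drop = FALSE],
            outputs[seq_len(steps), , drop = FALSE], seed)
}

#' Run the synchronous parallel-PUSH round model
#'
#' In every round each non-silent agent's displayed message is delivered,
#' independently noised through `P`, to one uniformly chosen target agent.
#' Silence (an `NA` display) is delivered reliably as the absence of a
#' message — this is the facet of push communication that noise cannot
#' touch. Each agent then updates on the multiset of messages it received.
#'
#' @inheritParams run_parallel_pull
#' @param protocol a push `spread_protocol` (display may return `NA` for
#'   silent agents).
#' @return a `spread_trace`; silent displays are recorded as `NA`.
#' @export
run_parallel_push <- function(protocol, cfg, P, max_rounds = 50L * cfg$n,
                              include_self = TRUE,
                              stop = c("none", "all_correct"), seed = NULL) {
  stop <- match.arg(stop)
  run_engine_checks(protocol, cfg, P, max_rounds)
  if (protocol$model != "push") stop("protocol is not a push protocol")
  if (!is.null(seed)) set.seed(seed)
  n <- cfg$n
  state <- protocol$init(n, cfg$source_ids, cfg$correct_opinion)
  displays <- matrix(NA_integer_, max_rounds, n)
  outputs <- matrix(NA_integer_, max_rounds, n)
  rounds <- 0L
  empty <- lapply(seq_len(n), function(i) integer(0))
  for (r in seq_len(max_rounds)) {
    disp <- protocol$display(state)
    pushers <- which(!is.na(disp))
    inbox <- empty
    if (length(pushers)) {
      targets <- sample_targets(n, length(pushers), include_self, pushers)
      noisy <- sample_symbol_idx(P, disp[pushers])
      got <- split(noisy, targets)
      inbox[as.integer(names(got))] <- got
    }
    state <- protocol$update(state, inbox)
    rounds <- r
    displays[r, ] <- protocol$display(state)
    out <- protocol$output(state)
    outputs[r, ] <- out
    if (stop == "all_correct" && all_correct_now(out, cfg)) break
  }
  new_trace("parallel-push", cfg, protocol,
            displays[seq_len(rounds), , drop = FALSE],
            outputs[seq_len(rounds), , drop = FALSE], seed)
}

#' Lift a parallel-PULL protocol to the broadcast-PULL model
#'
#' Wraps a parallel protocol so that it runs under [run_broadcast_pull()]:
#' broadcast steps are grouped into rounds of exactly n steps; during the
#' i-th step of a round only agent `(i mod n) + 1` keeps the broadcast
#' sample (everyone else ignores it), and all stored samples are processed
#' through the wrapped protocol's update only when the round completes.
#' Each simulated round is therefore distributed exactly as one round of
#' the parallel model: every agent processes one independent uniform
#' sample of the previous round's configuration.
#'
#' @param protocol a parallel-PULL `spread_protocol`.
#' @param n population size (the wrapper needs it to schedule keepers).
#' @return a pull `spread_protocol` usable under [run_broadcast_pull()].
#' @export
lift_to_parallel <- function(protocol, n) {
  if (protocol$model != "pull") stop("only pull protocols can be lifted")
  n <- as.integer(n)
  new_spread_protocol(
    name = paste0(protocol$name, " [lifted, n=", n, "]"),
    model = "pull", k = protocol$k,
    init = function(n_, source_ids, correct_opinion) {
      stopifnot(n_ == n)
      list(inner = protocol$init(n_, source_ids, correct_opinion),
           stored = rep(NA_integer_, n), step = 0L)
    },
    display = function(state) protocol$display(state$inner),
    update = function(state, obs) {
      state$step <- state$step + 1L
      i <- ((state$step - 1L) %% n) + 1L          # in-round step index, 1..n
      keeper <- (i %% n) + 1L
      state$stored[keeper] <- obs[keeper, 1L]
      if (i == n) {                                # round complete: process
        state$inner <- protocol$update(state$inner,
                                       matrix(state$stored, n, 1L))
        state$stored <- rep(NA_integer_, n)
      }
      state
    },
    output = function(state) protocol$output(state$inner)
  )
}

#' In-round keeper arithmetic for the broadcast lift
#'
#' Maps a global broadcast step to its round, in-round step, and the agent
#' that keeps the observation (`(i mod n) + 1` for in-round step i).
#'
#' @param step global 1-based broadcast step.
#' @param n population size.
#' @return list with `round`, `in_round_step`, `keeper`.
#' @export
lift_keeper <- function(step, n) {
  step <- as.integer(step); n <- as.integer(n)
  i <- ((step - 1L) %% n) + 1L
  list(round = ((step - 1L) %/% n) + 1L, in_round_step = i,
       keeper = (i %% n) + 1L)
}

#' First round at which a trace satisfies a convergence criterion
#'
#' @param trace a `spread_trace`.
#' @param criterion `"all_correct"`: every non-source agent outputs the
#'   correct opinion; `"any_belief_above"`: any non-source belief exceeds
#'   `threshold` (requires `beliefs`).
#' @param threshold belief threshold, default 2/3.
#' @param beliefs optional rounds x n matrix of posterior beliefs in the
#'   correct opinion.
#' @return the 1-based round (or step) index, or `NA_integer_` if the
#'   criterion never holds within the trace.
#' @export
convergence_round <- function(trace, criterion = c("all_correct", "any_belief_above"),
                              threshold = 2 / 3, beliefs = NULL) {
  criterion <- match.arg(criterion)
  ns <- setdiff(seq_len(trace$n), trace$source_ids)
  if (criterion == "all_correct") {
    ok <- apply(trace$outputs[, ns, drop = FALSE] == trace$correct_opinion,
                1L, all)
  } else {
    if (is.null(beliefs)) stop("belief criterion needs a beliefs matrix")
    ok <- apply(beliefs[, ns, drop = FALSE] > threshold, 1L, any)
  }
  hit <- which(ok)
  if (length(hit)) hit[1L] else NA_integer_
}
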