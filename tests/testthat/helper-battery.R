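# Randomised battery of history-dependent process pairs. The conditional
# distributions depend on the outcome counts and the last outcome, floored
# away from zero so delta > 0 and all KL quantities stay finite.
random_pair_battery <- function(n_pairs = 12L, seed = 20260927L) {
  set.seed(seed)
  lapply(seq_len(n_pairs), function(i) {
    k <- sample(2:3, 1L)
    w0 <- matrix(stats::runif(k * (k + 2L), -0.5, 0.5), nrow = k)
    w1 <- w0 + matrix(stats::runif(k * (k + 2L), -0.15, 0.15), nrow = k)
    floor_p <- stats::runif(1, 0.05, 0.15)
    mk <- function(w) {
      force(w)
      function(history) {
        counts <- tabulate(history, nbins = k)
        last <- if (length(history)) history[length(history)] else 0L
        feat <- c(1, counts / 4, last / k)
        z <- exp(pmin(as.vector(w %*% feat), 20))
        p <- z / sum(z)
        p <- pmax(p, floor_p)
        p / sum(p)
      }
    }
    f0 <- mk(w0); f1 <- mk(w1)
    process_pair(function(hyp, history) {
      if (hyp == 0L) f0(history) else f1(history)
    }, k)
  })
}

# Exact Bernoulli(a)-vs-Bernoulli(b) memoryless pair used across tests.
bernoulli_pair <- function(a, b) memoryless_pair(c(a, 1 - a), c(b, 1 - b))

# Minimal push protocol: sources push a fixed symbol every round, everyone
# else stays silent; each agent remembers the messages of the last round.
beacon_push_protocol <- function(symbol = 1L) {
  new_spread_protocol(
    name = "beacon", model = "push",
    init = function(n, source_ids, correct_opinion) {
      list(source = seq_len(n) %in% source_ids,
           last = lapply(seq_len(n), function(i) integer(0)))
    },
    display = function(state) ifelse(state$source, symbol, NA_integer_),
    update = function(state, inbox) { state$last <- inbox; state },
    output = function(state) rep(0L, length(state$source))
  )
}
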