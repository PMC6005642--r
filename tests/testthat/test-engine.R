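test_that("parallel-PULL traces respect the shape contract", {
  P <- build_confusion("neighbor", 5, 0.25)
  cfg <- population_config(12, source_ids = 3L, correct_opinion = 1L)
  tr <- run_parallel_pull(make_sink_protocol(5), cfg, P, max_rounds = 7,
                          seed = 1)
  expect_s3_class(tr, "spread_trace")
  expect_equal(dim(tr$displays), c(7, 12))
  expect_equal(dim(tr$outputs), c(7, 12))
  expect_true(all(tr$displays %in% 1:5))
  expect_true(all(tr$outputs %in% 0:1))
  # truncation with a stop criterion never exceeds max_rounds
  tr2 <- run_parallel_pull(make_sink_protocol(5), cfg, P, max_rounds = 500,
                           stop = "all_correct", seed = 2)
  expect_lte(tr2$rounds_run, 500)
})

test_that("identical (config, protocol, noise, seed) reproduce traces exactly", {
  P <- build_confusion("uniform", 5, 0.1)
  cfg <- population_config(20, 1L, 1L)
  pr <- make_sink_protocol(5)
  runs <- lapply(1:2, function(i) {
    run_parallel_pull(pr, cfg, P, max_rounds = 25, seed = 77)
  })
  expect_identical(runs[[1]]$displays, runs[[2]]$displays)
  expect_identical(runs[[1]]$outputs, runs[[2]]$outputs)
  expect_identical(serialize(runs[[1]], NULL), serialize(runs[[2]], NULL))

  seqs <- lapply(1:2, function(i) {
    run_sequential_pull(pr, cfg, P, max_steps = 60, seed = 5)
  })
  expect_identical(seqs[[1]]$displays, seqs[[2]]$displays)
})

test_that("time to meet the source directly is geometric with mean n", {
  # n = 2, one source, noiseless: the non-source adopts exactly when its
  # uniform draw (self included) hits the source, so the adoption round is
  # geometric with success probability 1/2 and mean 2.
  P <- as_noise_matrix(diag(3))
  cfg <- population_config(2, 1L, 1L)
  pr <- make_sink_protocol(3)
  set.seed(101)
  rounds <- vapply(1:1000, function(i) {
    tr <- run_parallel_pull(pr, cfg, P, max_rounds = 100)
    which(tr$displays[, 2] == 3L)[1]   # first round displaying the endpoint
  }, integer(1))
  expect_false(anyNA(rounds))
  se <- sqrt(2) / sqrt(1000)          # geometric sd at p = 1/2
  expect_lt(abs(mean(rounds) - 2), 3 * se)
})

test_that("broadcast-PULL delivers one shared sample per step", {
  # a recording protocol checks every agent got the same sample each step
  log <- new.env(); log$rows_constant <- logical(0)
  recorder <- new_spread_protocol(
    name = "recorder", model = "pull",
    init = function(n, source_ids, correct_opinion) list(n = n),
    display = function(state) rep(1L, state$n),
    update = function(state, obs) {
      log$rows_constant <- c(log$rows_constant,
                             length(unique(obs[, 1L])) == 1L)
      state
    },
    output = function(state) rep(0L, state$n)
  )
  P <- build_confusion("uniform", 2, 0.3)
  cfg <- population_config(3, 1L, 1L)
  tr <- run_broadcast_pull(recorder, cfg, P, max_steps = 40, seed = 9)
  expect_equal(tr$rounds_run, 40)
  expect_true(all(log$rows_constant))
  # under a noiseless sink run the shared sample makes everyone adopt at once
  sink3 <- make_sink_protocol(3)
  P0 <- as_noise_matrix(diag(3))
  trs <- run_broadcast_pull(sink3, population_config(4, 1L, 1L), P0,
                            max_steps = 50, stop = "all_correct", seed = 2)
  adopted <- trs$displays[trs$rounds_run, ]
  expect_true(all(adopted == 3L))     # everyone saw the same source sample
})

test_that("sequential-PULL updates exactly one agent per step", {
  # with a sink protocol and noiseless endpoint displays, adoption count
  # can grow by at most one per step
  P0 <- as_noise_matrix(diag(3))
  cfg <- population_config(6, 1L, 1L)
  tr <- run_sequential_pull(make_sink_protocol(3), cfg, P0, max_steps = 300,
                            stop = "all_correct", seed = 12)
  adopters <- rowSums(tr$displays[, -1, drop = FALSE] == 3L)
  expect_true(all(diff(adopters) %in% c(0L, 1L)))
  expect_gt(max(adopters), 0)
})

test_that("push delivers noised content, and silence is reliable absence", {
  P <- build_confusion("uniform", 2, 0.3)
  cfg <- population_config(10, 1L, 1L)
  # all agents silent: nothing ever delivered, no state change
  silent <- new_spread_protocol(
    name = "mute", model = "push",
    init = function(n, source_ids, correct_opinion) {
      list(n = n, got = 0L)
    },
    display = function(state) rep(NA_integer_, state$n),
    update = function(state, inbox) {
      state$got <- state$got + sum(lengths(inbox)); state
    },
    output = function(state) rep(0L, state$n)
  )
  tr <- run_parallel_push(silent, cfg, P, max_rounds = 5, seed = 1)
  expect_true(all(is.na(tr$displays)))

  # single pusher displaying symbol 1: receivers see symbol 2 with freq ~0.3
  log <- new.env()
  log$seen <- integer(0)
  recorder <- new_spread_protocol(
    name = "push-recorder", model = "push",
    init = function(n, source_ids, correct_opinion) {
      list(n = n, source = seq_len(n) %in% source_ids)
    },
    display = function(state) ifelse(state$source, 1L, NA_integer_),
    update = function(state, inbox) {
      log$seen <- c(log$seen, unlist(inbox)); state
    },
    output = function(state) rep(0L, state$n)
  )
  run_parallel_push(recorder, cfg, P, max_rounds = 6000, seed = 31)
  expect_equal(length(log$seen), 6000)   # one delivery per round
  expect_lt(abs(mean(log$seen == 2L) - 0.3), 3 * sqrt(0.3 * 0.7 / 6000))

  # a pull engine refuses a push protocol outright
  expect_error(run_parallel_pull(silent, cfg, P, max_rounds = 2, seed = 1),
               "not a pull protocol")
})

test_that("broadcast lift keeps observations with the stated schedule", {
  expect_equal(lift_keeper(1, 3)$keeper, 2L)
  expect_equal(lift_keeper(2, 3)$keeper, 3L)
  expect_equal(lift_keeper(3, 3)$keeper, 1L)
  k7 <- lift_keeper(7, 3)
  expect_equal(k7$round, 3L)
  expect_equal(k7$in_round_step, 1L)
  expect_equal(k7$keeper, 2L)
  # every agent keeps exactly one observation per round
  keepers <- vapply(1:12, function(s) lift_keeper(s, 4)$keeper, integer(1))
  expect_equal(sort(keepers[1:4]), 1:4)
  expect_equal(sort(keepers[5:8]), 1:4)

  # lifted protocol only changes outputs at round boundaries
  pr <- make_sink_protocol(3)
  lifted <- lift_to_parallel(pr, 5)
  P0 <- as_noise_matrix(diag(3))
  tr <- run_broadcast_pull(lifted, population_config(5, 1L, 1L), P0,
                           max_steps = 40, seed = 8)
  for (r in 1:7) {
    block <- tr$outputs[((r - 1) * 5 + 1):(r * 5 - 1), , drop = FALSE]
    expect_true(all(apply(block, 2, function(x) length(unique(x)) == 1L)))
  }
})

test_that("more observations per round speed up sink convergence", {
  P <- build_confusion("neighbor", 5, 0.25)
  cfg <- population_config(40, 1L, 1L)
  pr <- make_sink_protocol(5)
  mean_rounds <- function(kobs, seed) {
    set.seed(seed)
    mean(vapply(1:60, function(i) {
      tr <- run_parallel_pull(pr, cfg, P, max_rounds = 400,
                              obs_per_round = kobs, stop = "all_correct")
      convergence_round(tr)
    }, integer(1)))
  }
  m1 <- mean_rounds(1L, 21)
  m3 <- mean_rounds(3L, 22)
  expect_lt(m3, m1)
})

test_that("convergence_round finds the first satisfying round", {
  tr <- structure(list(
    n = 3L, source_ids = 1L, correct_opinion = 1L,
    outputs = rbind(c(1, 0, 0), c(1, 0, 1), c(1, 1, 1), c(1, 1, 1)),
    displays = matrix(1L, 4, 3), rounds_run = 4L),
    class = "spread_trace")
  expect_equal(convergence_round(tr), 3L)
  tr$outputs <- rbind(c(1, 0, 0), c(1, 0, 1))
  expect_true(is.na(convergence_round(tr)))
  beliefs <- rbind(c(1, 0.2, 0.1), c(1, 0.5, 0.69), c(1, 0.9, 0.1))
  tr$outputs <- matrix(0L, 3, 3); tr$rounds_run <- 3L
  expect_equal(convergence_round(tr, "any_belief_above", beliefs = beliefs),
               2L)
})
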