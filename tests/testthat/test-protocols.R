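test_that("sink protocol adopts endpoints and keeps the first adoption", {
  pr <- make_sink_protocol(5)
  st <- pr$init(3, 1L, 1L)                 # agent 1 source, opinion 1
  expect_equal(st$display, c(5L, 3L, 3L))
  # agent 2 observes the upper endpoint: adopts opinion 1 and displays it
  st2 <- pr$update(st, matrix(c(NA, 5L, NA), 3, 1))
  expect_equal(st2$display[2], 5L)
  expect_equal(st2$opinion[2], 1L)
  # a later conflicting endpoint is ignored under permanent adoption
  st3 <- pr$update(st2, matrix(c(NA, 1L, NA), 3, 1))
  expect_equal(st3$display[2], 5L)
  # ... but replaces it under the latest-wins variant
  prl <- make_sink_protocol(5, adoption = "latest")
  stl <- prl$init(3, 1L, 1L)
  stl <- prl$update(stl, matrix(c(NA, 5L, NA), 3, 1))
  stl <- prl$update(stl, matrix(c(NA, 1L, NA), 3, 1))
  expect_equal(stl$display[2], 1L)
  expect_equal(stl$opinion[2], 0L)
  # middle-symbol observations never trigger adoption
  st4 <- pr$update(st, matrix(c(NA, 3L, 4L), 3, 1))
  expect_equal(st4$display, st$display)
  expect_error(make_sink_protocol(4), "odd")
})

test_that("sink relay converges fast under structured noise at n = 100", {
  P <- build_confusion("neighbor", 5, 0.25)
  cfg <- population_config(100, 1L, 1L)
  pr <- make_sink_protocol(5)
  budget <- ceiling(10 * log2(100))
  set.seed(17)
  ok <- vapply(1:60, function(i) {
    tr <- run_parallel_pull(pr, cfg, P, max_rounds = budget,
                            stop = "all_correct")
    !is.na(convergence_round(tr))
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("static display induces the expected broadcast mixtures", {
  P <- build_confusion("uniform", 2, 0.3)
  mix <- broadcast_mixture(10, 1, P, default = 1L, opinion_symbols = c(1L, 2L))
  expect_equal(mix$q0, c(0.7, 0.3), tolerance = 1e-12)
  expect_equal(mix$q1, c(0.66, 0.34), tolerance = 1e-12)
  # l1 gap identity: 2 * (s/n) * (1 - delta k)
  expect_equal(l1_gap(mix$q0, mix$q1), 2 * (1 / 10) * (1 - 0.3 * 2),
               tolerance = 1e-12)
  # flattening noise: hypotheses coincide
  Pf <- build_confusion("uniform", 2, 0.5)
  mixf <- broadcast_mixture(10, 1, Pf, 1L, c(1L, 2L))
  expect_equal(mixf$q0, mixf$q1)
  # protocol itself never changes state
  pr <- make_static_display(1L, c(1L, 2L))
  st <- pr$init(5, 2L, 1L)
  expect_identical(pr$update(st, matrix(2L, 5, 1))$display, st$display)
})

test_that("bayes_update matches hand arithmetic and full-joint enumeration", {
  P <- build_confusion("uniform", 2, 0.3)
  args <- list(n = 10, s = 1, P = P, default = 1L,
               opinion_symbols = c(1L, 2L))
  b1 <- do.call(bayes_update, c(list(observer_belief(), 2L), args))
  expect_equal(b1$posterior, 0.34 / (0.30 + 0.34), tolerance = 1e-12)
  b0 <- do.call(bayes_update, c(list(observer_belief(), 1L), args))
  expect_equal(b0$posterior, 0.66 / (0.70 + 0.66), tolerance = 1e-9)

  # enumeration oracle: posterior from the explicit joint over sequences
  mix <- broadcast_mixture(10, 1, P, 1L, c(1L, 2L))
  for (len in 1:6) {
    seqs <- as.matrix(expand.grid(rep(list(1:2), len)))
    for (r in sample(nrow(seqs), min(8, nrow(seqs)))) {
      s <- seqs[r, ]
      p1 <- 0.5 * prod(mix$q1[s]); p0 <- 0.5 * prod(mix$q0[s])
      oracle <- p1 / (p1 + p0)
      b <- observer_belief()
      for (o in s) b <- do.call(bayes_update, c(list(b, o), args))
      expect_lt(abs(b$posterior - oracle), 1e-12)
    }
  }
  # zero-information noise pins the posterior at the prior
  Pf <- build_confusion("uniform", 2, 0.5)
  bf <- bayes_update(observer_belief(0.37), 2L, 10, 1, Pf, 1L, c(1L, 2L))
  expect_equal(bf$posterior, 0.37, tolerance = 1e-12)
})

test_that("certainty_time hits the threshold only when information flows", {
  Pf <- build_confusion("uniform", 2, 0.5)
  expect_true(is.na(certainty_time(20, 1, Pf, seed = 1)))
  P <- build_confusion("uniform", 2, 0.3)
  t1 <- certainty_time(20, 1, P, seed = 42)
  t2 <- certainty_time(20, 1, P, seed = 42)
  expect_identical(t1, t2)
  expect_gt(t1, 0)
  # mean certainty time grows with population size
  set.seed(8)
  means <- vapply(c(20, 80), function(n) {
    mean(vapply(1:150, function(i) as.numeric(certainty_time(n, 1, P)),
                numeric(1)))
  }, numeric(1))
  expect_lt(means[1], means[2])
})

test_that("push booster converges under a generous budget; never-contacted agents flip coins", {
  pr <- make_push_boost(3, 3)
  st <- pr$init(4, 1L, 1L)
  empty <- lapply(1:4, function(i) integer(0))
  for (r in 1:6) st <- pr$update(st, empty)
  expect_equal(st$informed, c(TRUE, FALSE, FALSE, FALSE))
  expect_true(all(st$guess %in% 0:1))   # uninformed output = initial coin

  # noiseless spread: all correct with high probability once boosted
  P0 <- as_noise_matrix(diag(2))
  cfg <- population_config(200, 1L, 1L)
  pr2 <- make_push_boost(ceiling(log2(200)), 25)
  set.seed(13)
  ok <- vapply(1:20, function(i) {
    tr <- run_parallel_push(pr2, cfg, P0, max_rounds = 33)
    all(tr$outputs[33, -1] == 1L)
  }, logical(1))
  expect_gte(mean(ok), 0.9)

  # noisy regime with source-only warmup and a long boost stage
  P <- build_confusion("uniform", 2, 0.1)
  cfg2 <- population_config(500, 1L, 1L)
  pr3 <- make_push_boost(9, 45, warmup = "source_only")
  set.seed(14)
  ok2 <- vapply(1:12, function(i) {
    tr <- run_parallel_push(pr3, cfg2, P, max_rounds = 54)
    all(tr$outputs[54, -1] == 1L)
  }, logical(1))
  expect_gte(mean(ok2), 0.9)
})
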