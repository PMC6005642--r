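fake_records <- function(init_speed, post_speed = NULL, pre_speed = NULL,
                         experiment = "e1") {
  n <- length(init_speed)
  data.frame(
    experiment_id = rep(experiment, n), time_s = seq_len(n),
    initiator_id = rep("A", n), receiver_id = rep("B", n),
    initiator_speed_cm_s = init_speed,
    receiver_pre_speed_cm_s = pre_speed %||% rep(0.2, n),
    receiver_post_speed_cm_s = post_speed %||% rep(5, n),
    stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("speed binning follows the half-open message ranges", {
  rec <- fake_records(c(5, 15, 25, 10, 20, 0.5, 1))
  lab <- assign_messages(rec)
  expect_equal(as.character(lab$message),
               c("a", "b", "c", "b", "c", NA, "a"))
  expect_error(assign_messages(fake_records(-1)), "negative")
})

test_that("confusion estimator reproduces the worked two-message overlap", {
  est <- estimate_confusion(cbind(m1 = c(0.8, 0.2), m2 = c(0.4, 0.6)))
  expect_equal(unname(est$overlap),
               matrix(c(7, 5, 5, 7) / 12, 2), tolerance = 1e-12)
  expect_equal(est$delta, 5 / 12, tolerance = 1e-12)
  expect_equal(unname(colSums(est$overlap)), c(1, 1), tolerance = 1e-9)

  # identical responses: total confusion 1/k everywhere
  same <- matrix(c(0.5, 0.3, 0.2), 3, 3)
  colnames(same) <- c("a", "b", "c")
  ei <- estimate_confusion(same)
  expect_true(all(abs(ei$overlap - 1 / 3) < 1e-12))
  # disjoint supports: perfect separability
  ed <- estimate_confusion(diag(3))
  expect_equal(unname(ed$overlap), diag(3))
  expect_equal(ed$delta, 0)
})

test_that("overlap columns always sum to one and survive bin permutations", {
  set.seed(5)
  for (i in 1:8) {
    nb <- sample(3:6, 1); nm <- sample(2:4, 1)
    prob <- matrix(stats::rexp(nb * nm), nb, nm)
    prob <- sweep(prob, 2, colSums(prob), "/")
    colnames(prob) <- paste0("m", seq_len(nm))
    est <- estimate_confusion(prob)
    expect_true(all(abs(colSums(est$overlap) - 1) < 1e-9))
    perm <- sample(nb)
    expect_equal(estimate_confusion(prob[perm, , drop = FALSE])$delta,
                 est$delta, tolerance = 1e-12)
  }
  # zero-mass response bins are dropped, not divided by
  prob0 <- rbind(c(0.8, 0.4), c(0, 0), c(0.2, 0.6))
  colnames(prob0) <- c("m1", "m2")
  expect_equal(estimate_confusion(prob0)$delta, 5 / 12, tolerance = 1e-12)
})

test_that("response_table uses only initially stationary receivers", {
  rec <- fake_records(c(5, 5, 15, 15), post_speed = c(5, 15, 15, 25),
                      pre_speed = c(0.1, 5, 0.1, 0.2))
  lab <- assign_messages(rec, speed_bins = c(1, 10), labels = c("a", "b"))
  tab <- response_table(lab, response_bins = c(0, 1, 10, 20))
  expect_equal(tab$n_used, 3L)            # the pre-speed 5 record excluded
  expect_equal(sum(tab$counts[, "a"]), 1L)
  expect_error(response_table(assign_messages(fake_records(c(5, 5)))[
    c(), , drop = FALSE]), "message")
})

test_that("separation tests reject shifted classes and pass identical ones", {
  set.seed(99)
  # same-distribution null: p-values are not systematically small
  pnull <- replicate(40, {
    rec <- fake_records(c(runif(120, 1, 10), runif(120, 10, 20)),
                        post_speed = pmax(rnorm(240, 12, 3), 0))
    p <- message_separation_tests(assign_messages(rec))
    p["a", "b"]
  })
  expect_gt(median(pnull), 0.2)
  # classes shifted by 3 sd: overwhelmingly detected
  ppow <- replicate(40, {
    post <- c(rnorm(50, 10, 2), rnorm(50, 16, 2))
    rec <- fake_records(c(runif(50, 1, 10), runif(50, 10, 20)),
                        post_speed = pmax(post, 0))
    message_separation_tests(assign_messages(rec))["a", "b"]
  })
  expect_gte(mean(ppow < 0.01), 0.95)
})

test_that("interaction rate counts both participants", {
  rec <- fake_records(rep(5, 6))
  expect_equal(interaction_rate(rec, group_size = 3, duration_min = 2), 2)
  expect_equal(interaction_rate(rec[0, ], 3, 2), 0)
  expect_equal(interaction_rate(rec, 3, 4),
               interaction_rate(rec, 3, 2) / 2)
  expect_error(interaction_rate(rec, 3, 0), "positive")
})

test_that("re-meeting intervals match the geometric uniform-mixing law", {
  # theoretical law: g = 6, next-interaction re-meet mass 1/5
  truth <- behavioral_truth(group_size = 6)
  rec <- gen_interactions(truth, 10000, seed = 123)
  out <- return_time_pdf(rec, group_size = 6)
  expect_equal(out$theoretical[["1"]], 0.2, tolerance = 1e-12)
  expect_equal(sum(out$theoretical), 1, tolerance = 1e-9)
  tv <- 0.5 * sum(abs(out$empirical - out$theoretical))
  expect_lt(tv, 0.03)
  expect_error(return_time_pdf(rec, group_size = 2), "at least 3")
})

test_that("recruitment times subtract entry from the second exit and are censored sensibly", {
  ev <- data.frame(experiment_id = c("x", "x", "x", "y"),
                   group_size = c(3, 3, 3, 8),
                   informed_entry_time_s = c(10, 10, 10, 0),
                   exit_time_s = c(40, 100, 200, 50))
  out <- suppressWarnings(recruitment_times(ev))
  expect_equal(out$times$time_s[out$times$experiment_id == "x"], 90)
  expect_equal(out$censored, "y")

  # power at the configured effect size over 24 experiments
  set.seed(1234)
  truth <- behavioral_truth()
  rej <- replicate(40, {
    log <- gen_recruitment_log(truth, 24)
    suppressWarnings(recruitment_times(log)$p_value) < 0.05
  })
  expect_gte(mean(rej), 0.8)
  # larger groups are slower under the default ground truth
  log <- gen_recruitment_log(truth, 200, seed = 9)
  out2 <- recruitment_times(log)
  expect_gt(out2$mean_large, out2$mean_small)

  # all experiments censored when no exits are generated
  log0 <- gen_recruitment_log(truth, 5, exits_per_experiment = 0, seed = 2)
  out0 <- suppressWarnings(recruitment_times(log0))
  expect_equal(length(out0$censored), 5L)
  expect_true(is.na(out0$p_value))
})

test_that("oversplit speed bins give statistically indistinguishable responses", {
  # data generated from 3 true classes, analysed with each bin split in two:
  # adjacent half-bins share the same response law, so the tests should not
  # reject
  truth <- behavioral_truth()
  rec <- gen_interactions(truth, 6000, seed = 77)
  lab <- assign_messages(rec, speed_bins = c(1, 5.5, 10, 15, 20, 25),
                         labels = c("a1", "a2", "b1", "b2", "c1", "c2"))
  p <- message_separation_tests(lab)
  expect_gt(p["a1", "a2"], 0.05)
  expect_gt(p["b1", "b2"], 0.05)
  expect_gt(p["c1", "c2"], 0.05)
})
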