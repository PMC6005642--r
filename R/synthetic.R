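#' Ground truth for synthetic behavioural data
#'
#' Collects the quantities the interaction generator emulates: the exact
#' response-speed distributions per message, message frequencies, group
#' size, the per-ant interaction rate, the probability that a receiver is
#' initially stationary, and the recruitment-delay distributions for two
#' group-size ranges. Defaults describe a small confined group with
#' near-uniform mixing, an interaction rate of 0.82 per ant per minute,
#' and message responses overlapping enough that the analytic confusion
#' level sits near 0.3.
#'
#' @param response_dists bins x messages column-stochastic matrix of exact
#'   response distributions p(v | j); rows are the response-speed bins
#'   below `response_bins` edges.
#' @param response_bins lower edges of the response-speed bins (cm/s).
#' @param message_weights message frequencies (normalised internally).
#' @param group_size ants per experiment.
#' @param rate_per_ant_min interactions per ant per minute.
#' @param stationary_prob probability a receiver is initially stationary.
#' @param speed_bins lower edges of the initiator-speed message bins.
#' @param speed_max upper cap for generated speeds (cm/s).
#' @param recruit_meanlog_small,recruit_meanlog_large,recruit_sdlog
#'   lognormal parameters (seconds) of nest-mate exit delays for the small
#'   and large group-size ranges.
#' @param small_range,large_range inclusive group-size ranges.
#' @return list of class `behavioral_truth`.
#' @export
behavioral_truth <- function(
    response_dists = default_response_dists(),
    response_bins = c(0, 1, 10, 20),
    message_weights = NULL,
    group_size = 6L,
    rate_per_ant_min = 0.82,
    stationary_prob = 0.8,
    speed_bins = c(1, 10, 20),
    speed_max = 30,
    recruit_meanlog_small = log(60),
    recruit_meanlog_large = log(130),
    recruit_sdlog = 0.45,
    small_range = c(2, 5), large_range = c(6, 10)) {
  response_dists <- as.matrix(response_dists)
  if (any(abs(colSums(response_dists) - 1) > 1e-9)) {
    stop("response distributions must each sum to 1")
  }
  if (is.null(message_weights)) {
    message_weights <- rep(1, ncol(response_dists))
  }
  message_weights <- message_weights / sum(message_weights)
  stopifnot(rate_per_ant_min > 0, group_size >= 3,
            nrow(response_dists) == length(response_bins),
            length(message_weights) == ncol(response_dists))
  structure(
    list(response_dists = response_dists, response_bins = response_bins,
         message_weights = message_weights, group_size = as.integer(group_size),
         rate_per_ant_min = rate_per_ant_min,
         stationary_prob = stationary_prob, speed_bins = speed_bins,
         speed_max = speed_max,
         recruit_meanlog_small = recruit_meanlog_small,
         recruit_meanlog_large = recruit_meanlog_large,
         recruit_sdlog = recruit_sdlog,
         small_range = small_range, large_range = large_range),
    class = "behavioral_truth")
}

#' @rdname behavioral_truth
#' @export
default_response_dists <- function() {
  cbind(a = c(0.46, 0.30, 0.17, 0.07),
        b = c(0.34, 0.29, 0.22, 0.15),
        c = c(0.23, 0.26, 0.28, 0.23))
}

#' Infinite-data confusion overlap of a ground truth
#'
#' Applies the overlap estimator's formulas to the exact response
#' distributions instead of empirical ones: the value
#' [estimate_confusion()] converges to as the number of records grows.
#'
#' @param truth a `behavioral_truth`.
#' @return a `confusion_estimate`.
#' @export
analytic_confusion <- function(truth) {
  stopifnot(inherits(truth, "behavioral_truth"))
  estimate_confusion(truth$response_dists)
}

runif_in_bin <- function(m, edges, idx, top) {
  lo <- edges[idx]
  hi <- c(edges[-1L], top)[idx]
  stats::runif(m, lo, hi)
}

#' Generate synthetic interaction records
#'
#' Emulates the statistical structure of recruitment-chamber interaction
#' data with known ground truth: partners are chosen uniformly at random
#' within each group (uniform mixing), interaction times follow a Poisson
#' clock matching the configured per-ant rate, initiator speeds are drawn
#' uniformly inside the bin of a message sampled from the configured
#' weights, and initially-stationary receivers respond with a speed drawn
#' from the exact p(v | message). Non-stationary receivers get unrelated
#' speeds and are ignored by the estimator, as in the real analysis.
#'
#' @param truth a `behavioral_truth`.
#' @param n number of interaction records (>= 1).
#' @param n_experiments how many experiments to spread the records over.
#' @param seed optional seed; the generated table is a pure function of
#'   (truth, n, n_experiments, seed).
#' @return interaction data.frame in the standard column schema, plus a
#'   `message_true` column with the generating message label.
#' @export
gen_interactions <- function(truth, n, n_experiments = 1L, seed = NULL) {
  stopifnot(inherits(truth, "behavioral_truth"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  g <- truth$group_size
  k <- ncol(truth$response_dists)
  msgs <- colnames(truth$response_dists)
  exp_id <- sort(rep_len(seq_len(n_experiments), n))
  # Poisson clock: per-ant rate r => pair-interaction rate g*r/2 per minute
  dt <- stats::rexp(n, rate = truth$rate_per_ant_min * g / 2 / 60)
  time_s <- stats::ave(dt, exp_id, FUN = cumsum)
  initiator <- sample.int(g, n, replace = TRUE)
  receiver <- sample.int(g - 1L, n, replace = TRUE)
  receiver <- receiver + (receiver >= initiator)
  msg <- sample.int(k, n, replace = TRUE, prob = truth$message_weights)
  init_speed <- runif_in_bin(n, truth$speed_bins, msg, truth$speed_max)
  stationary <- stats::runif(n) < truth$stationary_prob
  pre <- ifelse(stationary, stats::runif(n, 0, 1),
                stats::runif(n, 1, truth$speed_max))
  # response bin per record: inverse-CDF draw from p(. | msg)
  cum <- apply(truth$response_dists, 2L, cumsum)
  u <- stats::runif(n)
  vbin <- colSums(cum[, msg, drop = FALSE] < rep(u, each = nrow(cum))) + 1L
  vbin <- pmin(vbin, nrow(truth$response_dists))
  post_resp <- runif_in_bin(n, truth$response_bins, vbin, truth$speed_max)
  post <- ifelse(stationary, post_resp, stats::runif(n, 1, truth$speed_max))
  data.frame(
    experiment_id = paste0("synth", exp_id),
    time_s = time_s,
    initiator_id = paste0("ant", exp_id, "_", initiator),
    receiver_id = paste0("ant", exp_id, "_", receiver),
    initiator_speed_cm_s = init_speed,
    receiver_pre_speed_cm_s = pre,
    receiver_post_speed_cm_s = post,
    message_true = msgs[msg],
    stringsAsFactors = FALSE)
}

#' Generate a synthetic recruitment event log
#'
#' Per experiment: a group size drawn from the configured ranges, an
#' informed-ant nest entry time, and one exit time per nest-mate with
#' lognormal delays whose scale depends on the group-size range (larger
#' groups slower by default).
#'
#' @param truth a `behavioral_truth`.
#' @param n_experiments number of experiments (>= 1).
#' @param exits_per_experiment nest-mate exits recorded per experiment
#'   (0 makes every experiment censored).
#' @param seed optional seed.
#' @return event data.frame: `experiment_id`, `group_size`,
#'   `informed_entry_time_s`, `exit_time_s` (one row per exit).
#' @export
gen_recruitment_log <- function(truth, n_experiments, exits_per_experiment = 3L,
                                seed = NULL) {
  stopifnot(inherits(truth, "behavioral_truth"), n_experiments >= 1)
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  sizes <- c(seq(truth$small_range[1], truth$small_range[2]),
             seq(truth$large_range[1], truth$large_range[2]))
  for (e in seq_len(n_experiments)) {
    gs <- sample(sizes, 1L)
    small <- gs <= truth$small_range[2]
    entry <- stats::runif(1, 0, 30)
    if (exits_per_experiment >= 1L) {
      delays <- stats::rlnorm(exits_per_experiment,
                              meanlog = if (small) truth$recruit_meanlog_small
                                        else truth$recruit_meanlog_large,
                              sdlog = truth$recruit_sdlog)
      rows[[e]] <- data.frame(
        experiment_id = paste0("rec", e), group_size = gs,
        informed_entry_time_s = entry, exit_time_s = entry + sort(delays))
    } else {
      # no exits observed: keep the experiment visible so it is censored
      rows[[e]] <- data.frame(
        experiment_id = paste0("rec", e), group_size = gs,
        informed_entry_time_s = entry, exit_time_s = NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
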