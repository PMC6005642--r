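interaction_cols <- c("experiment_id", "time_s", "initiator_id",
                      "receiver_id", "initiator_speed_cm_s",
                      "receiver_pre_speed_cm_s", "receiver_post_speed_cm_s")

check_interactions <- function(records) {
  miss <- setdiff(interaction_cols, names(records))
  if (length(miss)) {
    stop("interaction table is missing columns: ", paste(miss, collapse = ", "))
  }
  sp <- c(records$initiator_speed_cm_s, records$receiver_pre_speed_cm_s,
          records$receiver_post_speed_cm_s)
  if (any(sp < 0, na.rm = TRUE)) stop("negative speeds in interaction data")
  if (any(records$initiator_id == records$receiver_id)) {
    stop("initiator and receiver must differ")
  }
  invisible(records)
}

#' Label interactions by the initiator's speed message
#'
#' Bins each interaction's initiator speed into a discrete message. The
#' default bins are the half-open ranges 'a': \[1, 10), 'b': \[10, 20),
#' 'c': \[20, Inf) cm/s; initiators slower than the first edge carry no
#' message (`NA`) and are excluded from confusion estimation.
#'
#' @param records interaction data.frame (see [read_interactions()] for
#'   the column schema).
#' @param speed_bins increasing numeric vector of lower bin edges; the
#'   last bin is unbounded above.
#' @param labels message labels, one per bin.
#' @return `records` with an added factor column `message`.
#' @export
assign_messages <- function(records, speed_bins = c(1, 10, 20),
                            labels = c("a", "b", "c")) {
  check_interactions(records)
  stopifnot(!is.unsorted(speed_bins, strictly = TRUE),
            length(labels) == length(speed_bins))
  idx <- findInterval(records$initiator_speed_cm_s, speed_bins)
  records$message <- factor(ifelse(idx >= 1L, labels[idx], NA),
                            levels = labels)
  records
}

#' Empirical response-speed distributions per message
#'
#' Builds, for each message j, the empirical distribution p(v | j) of the
#' receiver's post-interaction speed over discrete response bins, using
#' only interactions whose receiver was initially stationary (pre-speed
#' below `stationary_max`). The default response discretisation is the
#' message bins plus a "remained stationary" bin below 1 cm/s.
#'
#' @param labeled output of [assign_messages()].
#' @param response_bins increasing lower edges of the response-speed bins
#'   (the first bin starts at 0).
#' @param stationary_max receivers with pre-speed below this are
#'   considered initially stationary (default 1 cm/s).
#' @return object of class `response_table`: list with `prob` (bins x
#'   messages column-stochastic matrix), `counts`, `response_bins`,
#'   `n_used`.
#' @export
response_table <- function(labeled, response_bins = c(0, 1, 10, 20),
                           stationary_max = 1) {
  stopifnot("message" %in% names(labeled),
            !is.unsorted(response_bins, strictly = TRUE))
  use <- !is.na(labeled$message) &
    labeled$receiver_pre_speed_cm_s < stationary_max
  d <- labeled[use, , drop = FALSE]
  msgs <- levels(labeled$message)
  bin <- findInterval(d$receiver_post_speed_cm_s, response_bins)
  bin[bin < 1L] <- 1L
  counts <- table(factor(bin, levels = seq_along(response_bins)),
                  factor(d$message, levels = msgs))
  counts <- matrix(as.integer(counts), nrow = length(response_bins),
                   dimnames = list(response_bin = paste0("v", seq_along(response_bins)),
                                   message = msgs))
  tot <- colSums(counts)
  if (any(tot == 0)) {
    stop("no stationary-receiver observations for message class: ",
         paste(msgs[tot == 0], collapse = ", "))
  }
  prob <- sweep(counts, 2L, tot, "/")
  structure(list(prob = prob, counts = counts,
                 response_bins = response_bins, n_used = sum(counts)),
            class = "response_table")
}

confusion_from_prob <- function(prob, n_used = NA_integer_) {
  msgs <- colnames(prob)
  keep <- rowSums(prob) > 0           # response bins with any mass
  p <- prob[keep, , drop = FALSE]
  # posterior over messages per response bin, equal priors
  post <- sweep(p, 1L, rowSums(p), "/")
  overlap <- t(post) %*% p            # overlap[i, j] = sum_v p(v|j) p_i(v)
  dimnames(overlap) <- list(perceived = msgs, displayed = msgs)
  structure(list(overlap = overlap, delta = min(overlap), n_used = n_used),
            class = "confusion_estimate")
}

#' Estimate the message-confusion overlap from responses
#'
#' Implements the equal-prior overlap estimator: per response bin v the
#' posterior that the message was i is `p_i(v) = p(v|i) / sum_k p(v|k)`;
#' the probability that message j is perceived as message i is the
#' response-weighted posterior `overlap(i, j) = sum_v p(v|j) p_i(v)`; and
#' the noise level is `delta = min(overlap)`. Response bins with zero mass
#' under every message are dropped (they contribute nothing and would
#' divide by zero). Each column of the overlap matrix sums to 1 by
#' construction.
#'
#' @param table a `response_table`, or a column-stochastic bins x messages
#'   probability matrix.
#' @return object of class `confusion_estimate`: list with `overlap`
#'   (perceived x displayed matrix), `delta` (its minimum entry) and
#'   `n_used`.
#' @examples
#' prob <- cbind(m1 = c(0.8, 0.2), m2 = c(0.4, 0.6))
#' estimate_confusion(prob)$delta  # 5/12
#' @export
estimate_confusion <- function(table) {
  if (inherits(table, "response_table")) {
    confusion_from_prob(table$prob, table$n_used)
  } else {
    prob <- as.matrix(table)
    if (is.null(colnames(prob))) colnames(prob) <- paste0("m", seq_len(ncol(prob)))
    if (any(abs(colSums(prob) - 1) > 1e-9)) {
      stop("response distributions must sum to 1 per message")
    }
    confusion_from_prob(prob)
  }
}

#' @export
print.confusion_estimate <- function(x, ...) {
  cat("confusion overlap estimate; delta =", format(x$delta, digits = 4),
      if (!is.na(x$n_used)) sprintf("(N = %d)", x$n_used) else "", "\n")
  print(round(x$overlap, 4))
  invisible(x)
}

#' Pairwise tests that messages evoke different responses
#'
#' Two-sample location tests (Wilcoxon rank-sum by default) of the
#' receiver's post-interaction speed between every pair of message
#' classes, the check that the chosen alphabet is not an artificial
#' division of a continuous signal: distinct messages should give
#' significantly different responses, while oversplit bins should not.
#'
#' @param labeled output of [assign_messages()].
#' @param stationary_max receivers considered initially stationary.
#' @param test `"wilcox"` or `"t"`.
#' @return symmetric matrix of p-values (NA on the diagonal and for
#'   classes with fewer than 2 observations).
#' @export
message_separation_tests <- function(labeled, stationary_max = 1,
                                     test = c("wilcox", "t")) {
  test <- match.arg(test)
  use <- !is.na(labeled$message) &
    labeled$receiver_pre_speed_cm_s < stationary_max
  d <- labeled[use, , drop = FALSE]
  msgs <- levels(labeled$message)
  p <- matrix(NA_real_, length(msgs), length(msgs),
              dimnames = list(msgs, msgs))
  for (i in seq_along(msgs)) {
    for (j in seq_along(msgs)) {
      if (j <= i) next
      x <- d$receiver_post_speed_cm_s[d$message == msgs[i]]
      y <- d$receiver_post_speed_cm_s[d$message == msgs[j]]
      if (length(x) < 2 || length(y) < 2) next
      pv <- if (test == "wilcox") {
        suppressWarnings(stats::wilcox.test(x, y)$p.value)
      } else {
        stats::t.test(x, y)$p.value
      }
      p[i, j] <- p[j, i] <- pv
    }
  }
  p
}

#' Interaction rate per ant per minute
#'
#' Each interaction involves two participants, so the per-ant rate counts
#' every interaction twice: `2 * interactions / (group_size * minutes)`.
#' (Counting each interaction once for the initiating side only would
#' halve the value; the convention is stated because it scales results by
#' a factor 2.)
#'
#' @param records interaction data.frame (or anything with one row per
#'   interaction).
#' @param group_size number of ants present.
#' @param duration_min observation time in minutes (> 0).
#' @return interactions per ant per minute.
#' @export
interaction_rate <- function(records, group_size, duration_min) {
  if (duration_min <= 0) stop("duration must be positive")
  2 * nrow(records) / (group_size * duration_min)
}

#' Re-meeting interval distribution versus uniform mixing
#'
#' For every ant, orders its interactions in time and records, for each
#' partner met again, the number of interactions the ant experienced
#' between the two meetings (1 = the very next interaction was with the
#' same partner). Under uniform random mixing in a group of size g this
#' interval is geometric: `P(m) = ((g-2)/(g-1))^(m-1) / (g-1)`.
#'
#' @param records interaction data.frame.
#' @param group_size group size g (>= 3 for the theoretical law).
#' @param m_max largest interval tabulated.
#' @return list with `empirical` (named probability vector over 1..m_max,
#'   tail pooled), `theoretical` (same support), `intervals` (raw
#'   intervals), `n`.
#' @export
return_time_pdf <- function(records, group_size, m_max = 30L) {
  check_interactions(records)
  if (group_size < 3) stop("group size must be at least 3")
  intervals <- integer(0)
  for (ex in unique(records$experiment_id)) {
    d <- records[records$experiment_id == ex, , drop = FALSE]
    d <- d[order(d$time_s), , drop = FALSE]
    ants <- unique(c(d$initiator_id, d$receiver_id))
    for (a in ants) {
      mine <- d$initiator_id == a | d$receiver_id == a
      partner <- ifelse(d$initiator_id[mine] == a,
                        d$receiver_id[mine], d$initiator_id[mine])
      last_seen <- list()
      for (pos in seq_along(partner)) {
        key <- as.character(partner[pos])
        if (!is.null(last_seen[[key]])) {
          intervals <- c(intervals, pos - last_seen[[key]])
        }
        last_seen[[key]] <- pos
      }
    }
  }
  mm <- pmin(intervals, m_max)
  emp <- tabulate(mm, nbins = m_max)
  emp <- emp / max(1L, length(mm))
  g <- group_size
  theo <- ((g - 2) / (g - 1))^(seq_len(m_max) - 1) / (g - 1)
  theo[m_max] <- theo[m_max] + 1 - sum(theo)   # pool the tail mass
  names(emp) <- names(theo) <- seq_len(m_max)
  list(empirical = emp, theoretical = theo, intervals = intervals,
       n = length(intervals))
}

#' Time to recruit two nest-mates, compared across group sizes
#'
#' For each experiment, the recruitment time is the second nest-mate exit
#' time minus the informed ant's nest entry time; experiments with fewer
#' than two exits are censored and excluded with a warning. Experiments
#' are split into two group-size ranges and compared with a two-sample
#' Kolmogorov-Smirnov test.
#'
#' @param events data.frame with columns `experiment_id`, `group_size`,
#'   `informed_entry_time_s`, `exit_time_s` (one row per nest-mate exit).
#' @param small_range,large_range inclusive group-size ranges (defaults
#'   2-5 and 6-10).
#' @return list with `times` (per-experiment data.frame: experiment_id,
#'   group_size, group, time_s), `censored` (experiment ids), `p_value`,
#'   and the two group means.
#' @export
recruitment_times <- function(events, small_range = c(2, 5),
                              large_range = c(6, 10)) {
  need <- c("experiment_id", "group_size", "informed_entry_time_s",
            "exit_time_s")
  miss <- setdiff(need, names(events))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  out <- list(); censored <- character(0)
  for (ex in unique(events$experiment_id)) {
    d <- events[events$experiment_id == ex, , drop = FALSE]
    exits <- sort(d$exit_time_s)   # sort() drops NA exits
    if (length(exits) < 2L) {
      censored <- c(censored, as.character(ex))
      next
    }
    out[[length(out) + 1L]] <- data.frame(
      experiment_id = ex, group_size = d$group_size[1L],
      time_s = exits[2L] - d$informed_entry_time_s[1L])
  }
  if (length(censored)) {
    warning("censored experiments (fewer than two exits): ",
            paste(censored, collapse = ", "))
  }
  times <- do.call(rbind, out)
  if (is.null(times)) {
    return(list(times = NULL, censored = censored, p_value = NA_real_,
                mean_small = NA_real_, mean_large = NA_real_))
  }
  in_range <- function(g, r) g >= r[1] & g <= r[2]
  times$group <- ifelse(in_range(times$group_size, small_range), "small",
                        ifelse(in_range(times$group_size, large_range),
                               "large", NA))
  a <- times$time_s[times$group == "small" & !is.na(times$group)]
  b <- times$time_s[times$group == "large" & !is.na(times$group)]
  pv <- if (length(a) >= 2 && length(b) >= 2) {
    suppressWarnings(stats::ks.test(a, b)$p.value)
  } else {
    NA_real_
  }
  list(times = times, censored = censored, p_value = pv,
       mean_small = mean(a), mean_large = mean(b))
}
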