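#' Read and write interaction record tables
#'
#' The interaction CSV schema (versioned by its header) is:
#' `experiment_id,time_s,initiator_id,receiver_id,initiator_speed_cm_s,
#' receiver_pre_speed_cm_s,receiver_post_speed_cm_s`. Extra columns are
#' preserved. Validation checks non-negative speeds, distinct initiator
#' and receiver, and non-decreasing times within each experiment.
#'
#' @param path CSV file path.
#' @param records interaction data.frame.
#' @return `read_interactions` returns the validated data.frame;
#'   `write_interactions` returns `path` invisibly.
#' @export
read_interactions <- function(path) {
  records <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_interactions(records)
  for (ex in unique(records$experiment_id)) {
    tt <- records$time_s[records$experiment_id == ex]
    if (is.unsorted(tt)) {
      stop("times must be non-decreasing within experiment ", ex)
    }
  }
  records
}

#' @rdname read_interactions
#' @export
write_interactions <- function(records, path) {
  check_interactions(records)
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Read recruitment event logs
#'
#' Schema: `experiment_id,group_size,informed_entry_time_s,exit_time_s`,
#' one row per nest-mate exit (an `NA` exit time marks an experiment with
#' no observed exits).
#'
#' @param path CSV file path.
#' @param events event data.frame.
#' @return the event data.frame / `path` invisibly.
#' @export
read_recruitment <- function(path) {
  events <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("experiment_id", "group_size", "informed_entry_time_s",
            "exit_time_s")
  miss <- setdiff(need, names(events))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  events
}

#' @rdname read_recruitment
#' @export
write_recruitment <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE)
  invisible(path)
}

#' Read interaction records from a spreadsheet with a column mapping
#'
#' Loads an XLSX sheet (via the readxl package) and renames its columns to
#' the standard interaction schema through an explicit mapping, since
#' deposited spreadsheets rarely document their internal layout.
#'
#' @param path XLSX file path.
#' @param mapping named character vector: names are the standard schema
#'   columns, values are the spreadsheet's column names.
#' @param sheet sheet name or index (default first).
#' @return a validated interaction data.frame.
#' @export
read_interactions_xlsx <- function(path, mapping, sheet = 1) {
  if (!requireNamespace("readxl", quietly = TRUE)) {
    stop("read_interactions_xlsx requires the 'readxl' package")
  }
  raw <- as.data.frame(readxl::read_excel(path, sheet = sheet))
  miss <- setdiff(unname(mapping), names(raw))
  if (length(miss)) {
    stop("spreadsheet lacks mapped columns: ", paste(miss, collapse = ", "))
  }
  out <- raw[, unname(mapping), drop = FALSE]
  names(out) <- names(mapping)
  check_interactions(out)
  out
}

#' Simulation run configuration
#'
#' Reads a YAML (or JSON) run configuration, validates it, and executes
#' the run. Recognised fields: `model` (parallel_pull, broadcast_pull,
#' sequential_pull, parallel_push), `protocol` (`sink`, `static`,
#' `push_boost`) with `protocol_params`, `n`, `source_ids`,
#' `correct_opinion`, `noise` (list: `kind` + `k` + `param`, or
#' `csv` path), `max_rounds`/`max_steps`, `stop`, `seed`.
#'
#' @param path config file path (`.yaml`/`.yml` or `.json`).
#' @return `read_run_config`: the validated config list (class
#'   `run_config`); `run_from_config`: a `spread_trace`.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  # YAML 1.1 reads a bare `n` key as boolean FALSE; map it back
  names(cfg)[names(cfg) == "FALSE"] <- "n"
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  need <- c("model", "protocol", "n", "noise")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) stop("config is missing fields: ", paste(miss, collapse = ", "))
  cfg$model <- match.arg(cfg$model, c("parallel_pull", "broadcast_pull",
                                      "sequential_pull", "parallel_push"))
  cfg$protocol <- match.arg(cfg$protocol, c("sink", "static", "push_boost"))
  if (is.null(cfg$source_ids)) cfg$source_ids <- 1L
  if (is.null(cfg$correct_opinion)) cfg$correct_opinion <- 1L
  if (is.null(cfg$stop)) cfg$stop <- "none"
  structure(cfg, class = c("run_config", "list"))
}

config_noise <- function(noise) {
  if (!is.null(noise$csv)) {
    read_noise_csv(noise$csv)
  } else {
    build_confusion(noise$kind, noise$k, noise$param)
  }
}

config_protocol <- function(cfg, k) {
  pp <- cfg$protocol_params
  switch(cfg$protocol,
    sink = make_sink_protocol(k),
    static = make_static_display(
      default = pp$default %||% 1L,
      opinion_symbols = pp$opinion_symbols %||% c(1L, 2L)),
    push_boost = make_push_boost(
      spread_rounds = pp$spread_rounds %||% ceiling(log2(cfg$n)),
      boost_rounds = pp$boost_rounds %||% 20L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_run_config
#' @param cfg a `run_config` (or path passed through [read_run_config()]).
#' @export
run_from_config <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  P <- config_noise(cfg$noise)
  pop <- population_config(cfg$n, cfg$source_ids, cfg$correct_opinion)
  protocol <- config_protocol(cfg, ncol(P))
  seed <- cfg$seed %||% NULL
  switch(cfg$model,
    parallel_pull = run_parallel_pull(
      protocol, pop, P, max_rounds = cfg$max_rounds %||% (50L * pop$n),
      stop = cfg$stop, seed = seed),
    broadcast_pull = run_broadcast_pull(
      protocol, pop, P, max_steps = cfg$max_steps %||% (50L * pop$n^2),
      stop = cfg$stop, seed = seed),
    sequential_pull = run_sequential_pull(
      protocol, pop, P, max_steps = cfg$max_steps %||% (50L * pop$n^2),
      stop = cfg$stop, seed = seed),
    parallel_push = run_parallel_push(
      protocol, pop, P, max_rounds = cfg$max_rounds %||% (50L * pop$n),
      stop = cfg$stop, seed = seed))
}

#' Summarise a trace as a per-round data.frame
#'
#' One row per recorded round/step: the number of non-source agents whose
#' output matches the correct opinion, and the counts of each displayed
#' symbol.
#'
#' @param trace a `spread_trace`.
#' @param k alphabet size (inferred from displays if missing).
#' @return a data.frame with columns `round`, `correct_nonsource`, and one
#'   `disp_*` column per symbol.
#' @export
trace_summary <- function(trace, k = NULL) {
  if (is.null(k)) k <- max(trace$displays, na.rm = TRUE)
  ns <- setdiff(seq_len(trace$n), trace$source_ids)
  correct <- rowSums(trace$outputs[, ns, drop = FALSE] ==
                       trace$correct_opinion)
  disp <- t(apply(trace$displays, 1L, function(r) {
    tabulate(r[!is.na(r)], nbins = k)
  }))
  colnames(disp) <- paste0("disp_m", seq_len(k))
  data.frame(round = seq_len(trace$rounds_run),
             correct_nonsource = correct, disp)
}
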