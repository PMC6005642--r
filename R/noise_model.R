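#' Message alphabets
#'
#' An alphabet is an ordered set of distinct message labels. Symbols are
#' referred to everywhere else by their 1-based index into this ordering.
#'
#' @param k alphabet size (>= 2), or ignored when `labels` is given.
#' @param labels optional character vector of distinct labels; defaults to
#'   `"m1" ... "mk"`.
#' @return an object of class `msg_alphabet`: a character vector of labels.
#' @examples
#' msg_alphabet(5)
#' @export
msg_alphabet <- function(k, labels = NULL) {
  if (is.null(labels)) {
    stopifnot(length(k) == 1L, k >= 2, k == as.integer(k))
    labels <- paste0("m", seq_len(k))
  }
  labels <- as.character(labels)
  if (length(labels) < 2L) stop("alphabet needs at least 2 symbols")
  if (anyDuplicated(labels)) stop("alphabet labels must be distinct")
  structure(labels, class = "msg_alphabet")
}

#' @export
print.msg_alphabet <- function(x, ...) {
  cat("message alphabet, k =", length(x), ":", paste(unclass(x), collapse = " "), "\n")
  invisible(x)
}

row_sum_tol <- 1e-9

new_noise_matrix <- function(entries, labels) {
  entries <- as.matrix(entries)
  dimnames(entries) <- list(displayed = labels, observed = labels)
  structure(entries, class = c("noise_matrix", "matrix"))
}

#' Construct a confusion (noise) matrix over a message alphabet
#'
#' The entry in row `m`, column `m'` is the probability that a displayed
#' symbol `m` is observed as `m'`; rows are probability distributions.
#' Two stock constructions are provided:
#'
#' * `"uniform"`: every off-diagonal entry equals `param` (the uniformity
#'   level delta) and the diagonal is `1 - param * (k - 1)`. Requires
#'   `0 < param <= 1/k`; at `param = 1/k` all rows are identical and
#'   observations carry no information about the displayed symbol.
#' * `"neighbor"`: confusion only between consecutive symbols. Interior
#'   rows put `param` on each neighbour and `1 - 2*param` on the diagonal;
#'   the two boundary rows put `param` on their single neighbour. Requires
#'   `0 < param <= 1/2`. Entries off the tridiagonal are exactly zero, so
#'   this matrix is not delta-uniform for any positive delta.
#'
#' @param kind `"uniform"` or `"neighbor"`.
#' @param k alphabet size.
#' @param param uniform: the off-diagonal probability delta; neighbor: the
#'   per-neighbour leak probability.
#' @param alphabet optional `msg_alphabet`; defaults to `msg_alphabet(k)`.
#' @return a `noise_matrix`: a row-stochastic k x k matrix with the
#'   alphabet labels as dimnames.
#' @examples
#' build_confusion("uniform", k = 2, param = 0.3)
#' build_confusion("neighbor", k = 5, param = 0.25)
#' @export
build_confusion <- function(kind = c("uniform", "neighbor"), k, param,
                            alphabet = NULL) {
  kind <- match.arg(kind)
  stopifnot(length(k) == 1L, k == as.integer(k))
  if (k < 2) stop("alphabet size k must be at least 2")
  if (is.null(alphabet)) alphabet <- msg_alphabet(k)
  stopifnot(length(alphabet) == k)
  if (kind == "uniform") {
    if (!(param > 0 && param <= 1 / k)) {
      stop("uniform kind requires 0 < param <= 1/k (param is delta)")
    }
    entries <- matrix(param, k, k)
    diag(entries) <- 1 - param * (k - 1)
  } else {
    if (!(param > 0 && param <= 1 / 2)) {
      stop("neighbor kind requires 0 < param <= 1/2")
    }
    entries <- matrix(0, k, k)
    for (m in seq_len(k)) {
      nb <- intersect(c(m - 1L, m + 1L), seq_len(k))
      entries[m, nb] <- param
      entries[m, m] <- 1 - param * length(nb)
    }
  }
  new_noise_matrix(entries, unclass(alphabet))
}

#' Coerce a plain matrix to a validated noise matrix
#'
#' @param entries square numeric matrix of probabilities.
#' @param labels optional symbol labels (defaults to existing rownames or
#'   `"m1"...`).
#' @return a `noise_matrix`.
#' @export
as_noise_matrix <- function(entries, labels = NULL) {
  entries <- as.matrix(entries)
  if (nrow(entries) != ncol(entries)) stop("noise matrix must be square")
  if (is.null(labels)) {
    labels <- rownames(entries)
    if (is.null(labels)) labels <- paste0("m", seq_len(nrow(entries)))
  }
  P <- new_noise_matrix(entries, labels)
  check_noise_matrix(P)
  P
}

check_noise_matrix <- function(P) {
  if (any(P < -row_sum_tol) || any(P > 1 + row_sum_tol)) {
    stop("noise matrix entries must lie in [0, 1]")
  }
  if (any(abs(rowSums(P) - 1) > row_sum_tol)) {
    stop("noise matrix rows must each sum to 1 (tolerance 1e-9)")
  }
  invisible(P)
}

#' Smallest entry of a noise matrix
#'
#' @param P a `noise_matrix`.
#' @return the minimum entry, i.e. the largest delta for which the matrix
#'   is delta-uniform (0 when some confusion never happens).
#' @export
delta_min <- function(P) {
  check_noise_matrix(P)
  min(P)
}

#' Test delta-uniformity of a noise matrix
#'
#' The noise is delta-uniform when every displayed symbol can be observed
#' as every symbol with probability at least delta. The achievable range is
#' `0 < delta <= 1/k`. A warning threshold records the regime restriction
#' `s/n < delta` under which the convergence-time bounds are informative
#' (the theory requires `c*s/n < delta` for a sufficiently large constant;
#' the check here uses c = 1 and only warns).
#'
#' @param P a `noise_matrix`.
#' @param delta requested uniformity level, in (0, 1].
#' @param n,s optional population and source counts; when both are given a
#'   warning is emitted if `s/n >= delta`.
#' @return a list with `uniform` (logical) and `delta_min` (the actual
#'   minimum entry).
#' @examples
#' P <- build_confusion("uniform", 2, 0.3)
#' validate_delta_uniform(P, 0.3)
#' @export
validate_delta_uniform <- function(P, delta, n = NULL, s = NULL) {
  check_noise_matrix(P)
  stopifnot(delta > 0)
  dm <- min(P)
  if (!is.null(n) && !is.null(s) && s / n >= delta) {
    warning("regime check: s/n >= delta; the lower bounds assume s/n < delta")
  }
  list(uniform = dm >= delta, delta_min = dm)
}

# Row-wise inverse-CDF sampling; consumes exactly one uniform per draw so
# that paired-seed runs stay aligned across different displayed symbols.
sample_symbol_idx <- function(P, displayed) {
  k <- ncol(P)
  cum <- t(apply(unclass(P), 1L, cumsum))
  u <- stats::runif(length(displayed))
  idx <- rowSums(cum[displayed, , drop = FALSE] < u) + 1L
  pmin.int(idx, k)
}

#' Sample noisy observations of displayed symbols
#'
#' Draws, for each displayed symbol, the symbol actually observed, with
#' probabilities given by the corresponding row of `P`.
#'
#' @param P a `noise_matrix`.
#' @param displayed integer vector of displayed symbol indices (1-based),
#'   or a character vector of labels.
#' @return integer vector of observed symbol indices, same length as
#'   `displayed`.
#' @examples
#' P <- build_confusion("uniform", 2, 0.3)
#' set.seed(1); sample_symbol(P, c(1L, 1L, 2L))
#' @export
sample_symbol <- function(P, displayed) {
  check_noise_matrix(P)
  if (is.character(displayed)) {
    displayed <- match(displayed, rownames(P))
  }
  displayed <- as.integer(displayed)
  if (anyNA(displayed) || any(displayed < 1L) || any(displayed > nrow(P))) {
    stop("unknown displayed symbol")
  }
  sample_symbol_idx(P, displayed)
}

#' Read / write a noise matrix as CSV
#'
#' Layout: a header row of symbol labels followed by the k probability
#' rows. Values are written with 12 significant digits, so a write/read
#' round trip reproduces the matrix to that precision.
#'
#' @param P a `noise_matrix`.
#' @param path file path.
#' @return `read_noise_csv` returns a `noise_matrix`; `write_noise_csv`
#'   returns `path` invisibly.
#' @export
write_noise_csv <- function(P, path) {
  check_noise_matrix(P)
  lines <- c(
    paste(rownames(P), collapse = ","),
    apply(unclass(P), 1L, function(r) {
      paste(formatC(r, digits = 12, format = "g"), collapse = ",")
    })
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_noise_csv
#' @export
read_noise_csv <- function(path) {
  lines <- readLines(path)
  labels <- strsplit(lines[1L], ",", fixed = TRUE)[[1L]]
  rows <- lapply(lines[-1L], function(l) {
    as.numeric(strsplit(l, ",", fixed = TRUE)[[1L]])
  })
  entries <- do.call(rbind, rows)
  as_noise_matrix(entries, labels)
}

#' @export
print.noise_matrix <- function(x, ...) {
  cat("noise matrix over", ncol(x), "symbols; delta_min =",
      format(min(x), digits = 4), "\n")
  print(unclass(x), ...)
  invisible(x)
}
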