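#' Validate and construct a CTMC rate matrix
#'
#' A rate matrix (generator) `Q` of a continuous-time Markov chain has
#' non-negative off-diagonal entries `q_cd` (the instantaneous rate of
#' jumping from state `c` to state `d`) and rows summing to zero, so that
#' the diagonal holds the negative exit rates `q_cc = -q_c`.
#'
#' @param M a square numeric matrix.
#' @param labels optional character vector of state names; defaults to the
#'   row names of `M` or `"s1", "s2", ...`.
#' @param tol row-sum tolerance, relative to `max(abs(M))`. User-supplied
#'   matrices often carry rounding error; rows within `tol * max|Q|` of zero
#'   are accepted and re-centred exactly.
#' @return an object of class `rate_matrix`: the validated matrix with
#'   `dimnames` set to the state labels.
#' @examples
#' Q <- jc_rate_matrix(4)
#' validate_rate_matrix(unclass(Q))
#' @export
validate_rate_matrix <- function(M, labels = NULL, tol = 1e-12) {
  if (!is.matrix(M) || !is.numeric(M)) stop("M must be a numeric matrix")
  n <- nrow(M)
  if (ncol(M) != n) stop("M must be square")
  if (n < 2L) stop("a rate matrix needs at least 2 states")
  off <- M
  diag(off) <- 0
  if (any(off < 0)) {
    bad <- which(apply(off < 0, 1L, any))
    stop("negative off-diagonal entry in row(s) ", paste(bad, collapse = ", "))
  }
  scale <- max(abs(M), 1e-300)
  rs <- rowSums(M)
  if (any(abs(rs) > tol * scale)) {
    bad <- which(abs(rs) > tol * scale)
    stop("row(s) not summing to zero: ", paste(bad, collapse = ", "))
  }
  diag(M) <- -rowSums(off)            # re-centre exactly
  if (is.null(labels)) labels <- rownames(M)
  if (is.null(labels)) labels <- paste0("s", seq_len(n))
  if (length(labels) != n) stop("labels must have length ", n)
  dimnames(M) <- list(labels, labels)
  class(M) <- c("rate_matrix", class(matrix()))
  M
}

#' @export
print.rate_matrix <- function(x, ...) {
  cat("CTMC rate matrix with", nrow(x), "states\n")
  print(unclass(x), ...)
  invisible(x)
}

#' Number of states of a rate matrix
#' @param Q a `rate_matrix`.
#' @return integer state count.
#' @export
n_states <- function(Q) nrow(Q)

#' State labels of a rate matrix
#' @param Q a `rate_matrix`.
#' @return character vector of state names.
#' @export
state_labels <- function(Q) rownames(Q)

.as_state_index <- function(state, Q) {
  if (is.character(state)) {
    i <- match(state, state_labels(Q))
    if (anyNA(i)) stop("unknown state label: ", state[is.na(i)][1L])
    i
  } else as.integer(state)
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' Computed by scaling-and-squaring with Pade approximation and balancing
#' (the Higham08 algorithm of \code{\link[Matrix]{expm}}).
#'
#' @param Q a `rate_matrix`.
#' @param t elapsed time, `t >= 0` (same units as `1/Q`).
#' @return a stochastic matrix of class `transition_matrix` with attribute
#'   `t`; rows sum to one.
#' @export
transition_probabilities <- function(Q, t) {
  stopifnot(t >= 0)
  n <- nrow(Q)
  P <- if (t == 0) diag(n) else as.matrix(Matrix::expm(unclass(Q) * t))
  P[P < 0 & P > -1e-12] <- 0          # clip Pade round-off
  dimnames(P) <- dimnames(Q)
  structure(P, t = t, class = c("transition_matrix", class(matrix())))
}

#' Stationary distribution of an irreducible CTMC
#'
#' Solves `pi Q = 0`, `sum(pi) = 1` via the singular value decomposition of
#' `t(Q)`. A null space of dimension greater than one indicates a reducible
#' chain and is an error.
#'
#' @param Q a `rate_matrix`.
#' @param tol singular values below `tol * max(d)` count as zero.
#' @return a probability vector named by the state labels.
#' @export
stationary_distribution <- function(Q, tol = 1e-9) {
  sv <- svd(t(unclass(Q)))
  null_dim <- sum(sv$d < tol * max(sv$d))
  if (null_dim == 0L) stop("no stationary distribution found (numerical rank full)")
  if (null_dim > 1L) stop("reducible chain: null space of t(Q) has dimension ", null_dim)
  v <- sv$v[, ncol(Q)]          # right null vector of t(Q), i.e. pi Q = 0
  pi <- v / sum(v)
  if (any(pi < -1e-12)) stop("stationary vector has negative entries; chain may be reducible")
  pi <- pmax(pi, 0)
  pi <- pi / sum(pi)
  names(pi) <- state_labels(Q)
  pi
}

#' Test detailed balance (reversibility) of a rate matrix
#'
#' A CTMC is reversible with respect to its stationary distribution when
#' `pi_a q_ab = pi_b q_ba` for all state pairs.
#'
#' @param Q a `rate_matrix`.
#' @param pi stationary distribution; computed from `Q` if omitted.
#' @param tol tolerance relative to `max(abs(Q))`.
#' @return `TRUE` iff the maximal detailed-balance violation is within
#'   `tol * max|Q|`.
#' @export
is_reversible <- function(Q, pi = NULL, tol = 1e-10) {
  if (is.null(pi)) pi <- stationary_distribution(Q)
  F <- pi * unclass(Q)                # F_ab = pi_a q_ab (row scaling)
  max(abs(F - t(F))) <= tol * max(abs(Q))
}

#' Read a matrix from headered CSV or whitespace-delimited text
#'
#' @param path file path. Files ending in `.csv` are read as headered CSV
#'   with state labels in the first column and header row; anything else is
#'   read as whitespace-delimited plain text (no labels).
#' @return a numeric matrix (with dimnames when the file carries labels).
#' @export
read_matrix <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
    as.matrix(df)
  } else {
    as.matrix(utils::read.table(path))
  }
}

#' Write a matrix as headered CSV
#'
#' Inverse of [read_matrix()] for the CSV branch; labels go in the header
#' row and first column.
#'
#' @param M a numeric matrix.
#' @param path output path.
#' @export
write_matrix <- function(M, path) {
  M <- unclass(M)
  if (is.null(rownames(M))) dimnames(M) <- list(paste0("s", seq_len(nrow(M))),
                                                paste0("s", seq_len(ncol(M))))
  utils::write.csv(as.data.frame(M), path, row.names = TRUE)
  invisible(path)
}
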