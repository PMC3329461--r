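#' General time-reversible (GTR) nucleotide rate matrix
#'
#' State order **A, G, C, T**; six exchangeabilities `r = (r1..r6)` pair
#' with the target base frequencies as
#' `q_AG = r1 pi_G, q_AC = r2 pi_C, q_AT = r3 pi_T, q_GC = r4 pi_C,
#'  q_GT = r5 pi_T, q_CT = r6 pi_T` (and symmetrically below the diagonal),
#' which is reversible with respect to `pi` by construction.
#'
#' @param r the six exchangeability rates, all positive.
#' @param pi stationary distribution over (A, G, C, T).
#' @return a `rate_matrix` labeled A, G, C, T.
#' @export
gtr_rate_matrix <- function(r = c(0.5, 0.3, 0.6, 0.2, 0.3, 0.2),
                            pi = c(0.2, 0.2, 0.3, 0.3)) {
  if (length(r) != 6 || any(r <= 0)) stop("r must be 6 positive rates")
  if (length(pi) != 4 || any(pi <= 0) || abs(sum(pi) - 1) > 1e-8)
    stop("pi must be a length-4 probability vector")
  piA <- pi[1]; piG <- pi[2]; piC <- pi[3]; piT <- pi[4]
  M <- rbind(c(0,           r[1] * piG, r[2] * piC, r[3] * piT),
             c(r[1] * piA,  0,          r[4] * piC, r[5] * piT),
             c(r[2] * piA,  r[4] * piG, 0,          r[6] * piT),
             c(r[3] * piA,  r[5] * piG, r[6] * piC, 0))
  diag(M) <- -rowSums(M)
  Q <- validate_rate_matrix(M, labels = c("A", "G", "C", "T"))
  attr(Q, "pi") <- stats::setNames(pi, c("A", "G", "C", "T"))
  Q
}

#' Label sets of ordered state pairs
#'
#' A labeling picks out the jumps to be counted: a set of ordered state
#' pairs with no self-pairs. Presets: `"to-from:X"` (every jump into or out
#' of state `X`), `"transitions"` (A<->G and C<->T), `"all"` (every ordered
#' pair).
#'
#' @param spec a preset string, or a two-column matrix/data.frame of ordered
#'   pairs (indices or labels).
#' @param Q the `rate_matrix` the labels refer to (for state names and
#'   count).
#' @return integer matrix with columns `from`, `to`.
#' @export
label_set <- function(spec, Q) {
  n <- nrow(Q)
  labs <- state_labels(Q)
  if (is.character(spec) && length(spec) == 1L) {
    if (spec == "all") {
      pairs <- expand.grid(from = seq_len(n), to = seq_len(n))
      pairs <- as.matrix(pairs[pairs$from != pairs$to, ])
    } else if (spec == "transitions") {
      idx <- match(c("A", "G", "C", "T"), labs)
      if (anyNA(idx)) stop("'transitions' preset needs states A, G, C, T")
      pairs <- rbind(idx[c(1, 2)], idx[c(2, 1)], idx[c(3, 4)], idx[c(4, 3)])
    } else if (grepl("^to-from:", spec)) {
      x <- .as_state_index(sub("^to-from:", "", spec), Q)
      all_pairs <- expand.grid(from = seq_len(n), to = seq_len(n))
      keep <- (all_pairs$from == x | all_pairs$to == x) & all_pairs$from != all_pairs$to
      pairs <- as.matrix(all_pairs[keep, ])
    } else stop("unknown label-set preset: ", spec)
  } else {
    pairs <- as.matrix(as.data.frame(spec))
    if (ncol(pairs) != 2L) stop("label set must have two columns (from, to)")
    pairs <- cbind(.as_state_index(pairs[, 1L], Q), .as_state_index(pairs[, 2L], Q))
    if (any(pairs[, 1L] == pairs[, 2L])) stop("label set must not contain self-pairs")
    if (any(pairs < 1L | pairs > n)) stop("label set contains invalid state indices")
  }
  dimnames(pairs) <- list(NULL, c("from", "to"))
  pairs
}

#' Count-weight matrix of a label set
#'
#' `C_ij = q_ij` for `(i, j)` in the label set, zero elsewhere (including
#' the diagonal), so that `Sigma(C; a, b, t) / p_ab(t)` is the expected
#' number of labeled jumps given the endpoints.
#'
#' @param Q a `rate_matrix`.
#' @param L a label set (see [label_set()]).
#' @return a numeric weight matrix.
#' @export
label_weight_from_rates <- function(Q, L) {
  n <- nrow(Q)
  C <- matrix(0, n, n, dimnames = dimnames(Q))
  if (nrow(L)) C[L] <- unclass(Q)[L]
  C
}

#' Robust labeled evolutionary distance
#'
#' The labeled distance between two aligned sequences is the per-site
#' average of the expected number of labeled substitutions, conditioned on
#' each site's observed endpoint pair at unit divergence (`t = 1`; the data
#' only identify `Qt`). Averaging over the *empirical* site-pattern
#' distribution -- rather than the model's theoretical one -- is what makes
#' the estimate robust to model misspecification. One `Sigma(C;1)`
#' evaluation serves all sites.
#'
#' @param aln a `nucleotide_alignment` with exactly two sequences (or a
#'   2-row integer matrix of state indices).
#' @param Q the assumed `rate_matrix`.
#' @param L a label set (see [label_set()]).
#' @param method backend for `Sigma(C;t)`.
#' @return the estimated labeled distance (substitutions per site).
#' @export
robust_labeled_distance <- function(aln, Q, L, method = "uni") {
  states <- if (inherits(aln, "nucleotide_alignment")) aln$states else as.matrix(aln)
  if (nrow(states) != 2L) stop("robust distance needs exactly two sequences")
  m <- ncol(states)
  if (m == 0L) stop("alignment has no retained sites")
  C <- label_weight_from_rates(Q, L)
  res <- ctmc_statistics(Q, C, 1, method = method)
  E <- res$Sigma / res$P                 # E[N_L | 1, a, b] per endpoint pair
  if (any(!is.finite(E[cbind(states[1L, ], states[2L, ])]))) {
    bad <- which(!is.finite(E[cbind(states[1L, ], states[2L, ])]))[1L]
    stop("unreachable endpoint pair at site ", bad)
  }
  mean(E[cbind(states[1L, ], states[2L, ])])
}

#' Maximum-likelihood GTR estimation from a pairwise alignment
#'
#' Base frequencies are the pooled empirical frequencies of the two
#' sequences; the six exchangeabilities maximize the pairwise likelihood
#' `sum_s log(pi_{y1s} p_{y1s, y2s}(1))` at fixed divergence `t = 1` (the
#' scale of `Q` is identified by the unit-time constraint), by quasi-Newton
#' optimization over log-rates.
#'
#' @param aln a `nucleotide_alignment` with two sequences.
#' @param r_init starting exchangeabilities.
#' @return list with `r`, `pi`, `loglik`, `converged`, and `Q` (the fitted
#'   `rate_matrix`).
#' @export
estimate_gtr <- function(aln, r_init = rep(0.3, 6)) {
  states <- if (inherits(aln, "nucleotide_alignment")) aln$states else as.matrix(aln)
  if (nrow(states) != 2L) stop("GTR estimation needs exactly two sequences")
  pi <- tabulate(as.integer(states), nbins = 4L)
  if (any(pi == 0)) stop("all four bases must be observed")
  pi <- pi / sum(pi)
  counts <- table(factor(states[1L, ], levels = 1:4),
                  factor(states[2L, ], levels = 1:4))
  counts <- matrix(as.numeric(counts), 4L, 4L)
  negll <- function(logr) {
    Q <- gtr_rate_matrix(exp(logr), pi)
    P <- transition_probabilities(Q, 1)
    if (any(P[counts > 0] <= 0)) return(1e10)
    -sum(counts * log(pmax(matrix(pi, 4, 4) * P, 1e-300)))
  }
  fit <- stats::optim(log(r_init), negll, method = "L-BFGS-B",
                      lower = -12, upper = 12,
                      control = list(maxit = 500, factr = 1e4))
  r <- exp(fit$par)
  list(r = r, pi = stats::setNames(pi, c("A", "G", "C", "T")),
       loglik = -fit$value, converged = fit$convergence == 0L,
       Q = gtr_rate_matrix(r, pi))
}
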