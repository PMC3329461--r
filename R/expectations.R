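#' @title Endpoint-conditioned expectations of CTMC sufficient statistics
#' @description
#' For a CTMC with rate matrix `Q`, the conditional expectations of the
#' sufficient statistics given the endpoints `X(0) = a`, `X(t) = b` are
#' \deqn{E[T_c | t,a,b] = I^{ab}_{cc}(t) / p_{ab}(t), \qquad
#'       E[N_{cd} | t,a,b] = q_{cd} I^{ab}_{cd}(t) / p_{ab}(t),}
#' where \eqn{I^{ab}_{cd}(t) = \int_0^t p_{ac}(u) p_{db}(t-u) du}.
#' Linear combinations of such statistics are captured by a weight matrix
#' `C`: the package computes the matrix
#' \deqn{\Sigma(C;t)_{ab} = \sum_{c,d} C_{cd} I^{ab}_{cd}(t)}
#' in O(n^3) by one of three backends: eigenvalue decomposition (`evd`),
#' uniformization (`uni`), or the auxiliary block-matrix exponential
#' (`expm`).
#' @name ctmc-expectations
NULL

.expectation_result <- function(Sigma, P, t, method, Q) {
  dimnames(Sigma) <- dimnames(Q)
  structure(list(Sigma = Sigma, P = P, t = t, method = method),
            class = "ctmc_expectation")
}

#' @export
print.ctmc_expectation <- function(x, ...) {
  cat("Sigma(C;t) via", x$method, "at t =", x$t, "\n")
  print(x$Sigma, ...)
  invisible(x)
}

# ---------------------------------------------------------------- EVD ------

.eigen_system <- function(Q, force_general = FALSE, cond_max = 1e12) {
  Qm <- unclass(Q)
  n <- nrow(Qm)
  symmetrized <- FALSE
  if (!force_general) {
    pi <- tryCatch(stationary_distribution(Q), error = function(e) NULL)
    if (!is.null(pi) && all(pi > 0) && is_reversible(Q, pi)) {
      # reversible route: S = Pi^{1/2} Q Pi^{-1/2} is symmetric
      sq <- sqrt(pi)
      S <- (sq * Qm) %*% diag(1 / sq)   # row-scale then column-scale
      S <- (S + t(S)) / 2
      es <- eigen(S, symmetric = TRUE)
      U <- diag(1 / sq) %*% es$vectors
      U_inv <- t(es$vectors) %*% diag(sq)
      return(list(values = es$values, U = U, U_inv = U_inv, symmetrized = TRUE))
    }
  }
  es <- eigen(Qm)
  U <- es$vectors
  kappa <- tryCatch({
    sv <- svd(U, nu = 0, nv = 0)$d
    max(sv) / min(sv)
  }, error = function(e) Inf)
  if (!is.finite(kappa) || kappa > cond_max)
    stop("eigenvector matrix ill-conditioned (condition number ",
         signif(kappa, 3), "); the rate matrix may be non-diagonalizable -- ",
         "use the 'expm' backend instead")
  list(values = es$values, U = U, U_inv = solve(U), symmetrized = FALSE)
}

#' Auxiliary J matrix of divided exponential differences
#'
#' `J_ij(t) = t e^{lambda_i t}` when `lambda_i = lambda_j` and
#' `(e^{lambda_i t} - e^{lambda_j t}) / (lambda_i - lambda_j)` otherwise.
#' Eigenvalue pairs closer than `degeneracy_tol * max|lambda|` take the
#' degenerate branch to avoid catastrophic cancellation.
#'
#' @param values eigenvalues (possibly complex).
#' @param t time, `t >= 0`.
#' @param degeneracy_tol relative threshold for treating two eigenvalues as
#'   equal.
#' @return the n x n (possibly complex) J matrix.
#' @export
build_j_matrix <- function(values, t, degeneracy_tol = 1e-9) {
  n <- length(values)
  e <- exp(values * t)
  li <- matrix(values, n, n)
  lj <- t(li)
  dl <- li - lj
  scale <- max(Mod(values), 1)
  degen <- Mod(dl) <= degeneracy_tol * scale
  J <- matrix(0, n, n)
  if (is.complex(values)) J <- matrix(complex(real = 0), n, n)
  ei <- matrix(e, n, n)
  ej <- t(ei)
  J[!degen] <- (ei[!degen] - ej[!degen]) / dl[!degen]
  J[degen] <- t * ei[degen]
  J
}

#' Sigma(C;t) by eigenvalue decomposition
#'
#' Diagonalizes `Q = U diag(lambda) U^{-1}` (through the symmetrized form
#' `Pi^{1/2} Q Pi^{-1/2}` when the chain is reversible) and evaluates
#' `Sigma(C;t) = U [J(t) o (U^{-1} C U)] U^{-1}` with `o` the entrywise
#' product. Complex arithmetic is carried throughout and the imaginary
#' residue (always a cancellation artifact of conjugate eigenvalue pairs) is
#' checked to be below `1e-8 * max|Sigma|` before being dropped.
#'
#' @param Q a `rate_matrix` (must be diagonalizable).
#' @param C numeric weight matrix, same dimension as `Q`.
#' @param t time, `t >= 0`.
#' @param force_general skip the reversible symmetrization even when `Q`
#'   passes the detailed-balance test.
#' @param degeneracy_tol passed to [build_j_matrix()].
#' @return a `ctmc_expectation`: list with `Sigma`, `P` (the transition
#'   matrix at `t`), `t` and `method`.
#' @export
evd_statistics <- function(Q, C, t, force_general = FALSE,
                           degeneracy_tol = 1e-9) {
  stopifnot(t >= 0, nrow(C) == nrow(Q), ncol(C) == nrow(Q))
  es <- .eigen_system(Q, force_general = force_general)
  J <- build_j_matrix(es$values, t, degeneracy_tol)
  M <- es$U_inv %*% C %*% es$U
  Sigma <- es$U %*% (J * M) %*% es$U_inv
  P <- es$U %*% (exp(es$values * t) * es$U_inv)
  if (is.complex(Sigma)) {
    resid <- max(Mod(Im(Sigma)))
    if (resid > 1e-8 * max(Mod(Sigma), 1e-300))
      stop("imaginary residue ", signif(resid, 3), " too large; decomposition unreliable")
    Sigma <- Re(Sigma)
    P <- Re(P)
  }
  P[P < 0 & P > -1e-10] <- 0
  dimnames(P) <- dimnames(Q)
  .expectation_result(Sigma, P, t, "evd", Q)
}

# ---------------------------------------------------------------- UNI ------

#' Poisson truncation point for uniformization
#'
#' Number of terms of the uniformized series to retain so that the neglected
#' Poisson tail at mean `lam` is below `tail_bound`. The default rule is the
#' conservative closed form `ceiling(4 + 6*sqrt(lambda) + lambda)`,
#' calibrated for a tail bound of `1e-8`; `exact = TRUE` instead searches
#' for the smallest `s` with `P(Pois(lam) >= s) <= tail_bound`.
#'
#' @param lam Poisson mean `lambda = mu * t`, `lam >= 0`.
#' @param tail_bound tail mass bound (only used by the exact search).
#' @param exact use the exact quantile search instead of the closed form.
#' @return integer truncation point `s(lambda)`.
#' @export
truncation_point <- function(lam, tail_bound = 1e-8, exact = FALSE) {
  if (lam < 0) stop("lam must be non-negative")
  if (!exact) return(as.integer(ceiling(4 + 6 * sqrt(lam) + lam)))
  # smallest s with upper tail P(X >= s) <= tail_bound
  s <- as.integer(stats::qpois(1 - tail_bound, lam))
  while (stats::ppois(s - 1L, lam, lower.tail = FALSE) > tail_bound) s <- s + 1L
  while (s > 0L && stats::ppois(s - 2L, lam, lower.tail = FALSE) <= tail_bound) s <- s - 1L
  s
}

#' Sigma(C;t) by uniformization
#'
#' Writes `P(t)` as a Poisson mixture of powers of `R = Q/mu + I` with
#' `mu = max_i q_i`, giving
#' `Sigma(C;t) = (1/mu) sum_m Pois(m+1; mu t) sum_{l<=m} R^l C R^{m-l}`.
#' The inner sums `A(m)` are built once by the recursion
#' `A(m+1) = A(m) R + R^{m+1} C` up to the truncation point of the largest
#' requested time, so a batch of time points shares one precomputation.
#'
#' @param Q a `rate_matrix`.
#' @param C numeric weight matrix.
#' @param times one or more time points, all `>= 0`.
#' @param tail_bound Poisson tail bound controlling the truncation.
#' @param exact_truncation use the exact quantile search for the truncation
#'   point rather than the conservative closed form.
#' @return a `ctmc_expectation` for a single time point, or a list of them
#'   (one per time) when `length(times) > 1`.
#' @export
uni_statistics <- function(Q, C, times, tail_bound = 1e-8,
                           exact_truncation = FALSE) {
  stopifnot(all(times >= 0), nrow(C) == nrow(Q), ncol(C) == nrow(Q))
  n <- nrow(Q)
  Qm <- unclass(Q)
  mu <- max(-diag(Qm))
  single <- length(times) == 1L
  if (mu == 0) {
    # degenerate Q = 0: P(u) = I, so I_cd^ab(t) = t 1(a=c) 1(b=d) and
    # Sigma(C;t) = t * C entrywise
    out <- lapply(times, function(t)
      .expectation_result(t * C, structure(diag(n), dimnames = dimnames(Q)),
                          t, "uni", Q))
    return(if (single) out[[1L]] else out)
  }
  R <- Qm / mu + diag(n)
  s_max <- truncation_point(mu * max(times), tail_bound, exact = exact_truncation)
  # R^m for m = 0..s_max and the partial sums A(m) = sum_{l<=m} R^l C R^{m-l}
  Rpow <- vector("list", s_max + 1L)
  A <- vector("list", s_max + 1L)
  Rpow[[1L]] <- diag(n)
  A[[1L]] <- C
  for (m in seq_len(s_max)) {
    Rpow[[m + 1L]] <- Rpow[[m]] %*% R
    A[[m + 1L]] <- A[[m]] %*% R + Rpow[[m + 1L]] %*% C
  }
  out <- lapply(times, function(t) {
    lam <- mu * t
    s_t <- min(truncation_point(lam, tail_bound, exact = exact_truncation), s_max)
    m <- 0:s_t
    wP <- stats::dpois(m, lam)           # Pois(m; mu t) for P(t)
    wS <- stats::dpois(m + 1L, lam)      # Pois(m+1; mu t) for Sigma
    Sigma <- matrix(0, n, n)
    P <- matrix(0, n, n)
    for (k in seq_along(m)) {
      Sigma <- Sigma + wS[k] * A[[k]]
      P <- P + wP[k] * Rpow[[k]]
    }
    Sigma <- Sigma / mu
    dimnames(P) <- dimnames(Q)
    .expectation_result(Sigma, P, t, "uni", Q)
  })
  if (single) out[[1L]] else out
}

# --------------------------------------------------------------- EXPM ------

#' Sigma(C;t) by the auxiliary block-matrix exponential
#'
#' The integral `int_0^t e^{Qu} C e^{Q(t-u)} du` equals the upper-right
#' n x n block of `exp(At)` for the 2n x 2n auxiliary matrix
#' `A = [[Q, C], [0, Q]]` (Van Loan's construction). The lower-right block
#' is `P(t)` and is reused rather than recomputed.
#'
#' @param Q a `rate_matrix`.
#' @param C numeric weight matrix.
#' @param t time, `t >= 0`.
#' @return a `ctmc_expectation`.
#' @export
expm_statistics <- function(Q, C, t) {
  stopifnot(t >= 0, nrow(C) == nrow(Q), ncol(C) == nrow(Q))
  n <- nrow(Q)
  Qm <- unclass(Q)
  A <- rbind(cbind(Qm, C), cbind(matrix(0, n, n), Qm))
  E <- if (t == 0) diag(2L * n) else as.matrix(Matrix::expm(A * t))
  Sigma <- E[seq_len(n), n + seq_len(n), drop = FALSE]
  P <- E[n + seq_len(n), n + seq_len(n), drop = FALSE]
  P[P < 0 & P > -1e-12] <- 0
  dimnames(P) <- dimnames(Q)
  .expectation_result(Sigma, P, t, "expm", Q)
}

# ---------------------------------------------------------- dispatcher -----

#' Sigma(C;t) with backend selection
#'
#' Thin dispatcher over [evd_statistics()], [uni_statistics()] and
#' [expm_statistics()]. Uniformization is the default: its precomputation is
#' shared across time points and it is typically the fastest of the three.
#'
#' @param Q a `rate_matrix`.
#' @param C numeric weight matrix.
#' @param times one or more time points.
#' @param method backend: `"uni"`, `"evd"` or `"expm"`.
#' @param ... passed to the backend.
#' @return a `ctmc_expectation` or list of them (one per time point).
#' @export
ctmc_statistics <- function(Q, C, times, method = c("uni", "evd", "expm"), ...) {
  method <- match.arg(method)
  if (method == "uni") return(uni_statistics(Q, C, times, ...))
  out <- lapply(times, function(t)
    switch(method,
           evd = evd_statistics(Q, C, t, ...),
           expm = expm_statistics(Q, C, t, ...)))
  if (length(times) == 1L) out[[1L]] else out
}

#' Expected dwell time in a state, given the endpoints
#'
#' `E[T_c | t, a, b] = Sigma(1_cc; a, b, t) / p_ab(t)` where `1_cc` is the
#' single-entry indicator weight matrix.
#'
#' @param Q a `rate_matrix`.
#' @param t time.
#' @param c state whose occupancy time is wanted.
#' @param a,b endpoint states.
#' @param method backend.
#' @return expected time spent in `c` on `[0, t]` given `X(0)=a, X(t)=b`.
#' @export
conditional_dwell_time <- function(Q, t, c, a, b, method = "uni") {
  n <- nrow(Q)
  c <- .as_state_index(c, Q); a <- .as_state_index(a, Q); b <- .as_state_index(b, Q)
  C <- matrix(0, n, n); C[c, c] <- 1
  res <- ctmc_statistics(Q, C, t, method = method)
  p <- res$P[a, b]
  if (p <= 0) stop("endpoint pair unreachable: p_ab(t) = 0")
  res$Sigma[a, b] / p
}

#' Expected number of jumps between two states, given the endpoints
#'
#' `E[N_cd | t, a, b] = q_cd Sigma(1_cd; a, b, t) / p_ab(t)`.
#'
#' @param Q a `rate_matrix`.
#' @param t time.
#' @param c,d ordered jump pair, `c != d`.
#' @param a,b endpoint states.
#' @param method backend.
#' @return expected number of `c -> d` jumps on `[0, t]` given the endpoints.
#' @export
conditional_jump_count <- function(Q, t, c, d, a, b, method = "uni") {
  n <- nrow(Q)
  c <- .as_state_index(c, Q); d <- .as_state_index(d, Q)
  a <- .as_state_index(a, Q); b <- .as_state_index(b, Q)
  if (c == d) stop("jump count requires c != d")
  q <- unclass(Q)[c, d]
  if (q == 0) return(0)
  C <- matrix(0, n, n); C[c, d] <- 1
  res <- ctmc_statistics(Q, C, t, method = method)
  p <- res$P[a, b]
  if (p <= 0) stop("endpoint pair unreachable: p_ab(t) = 0")
  max(q * res$Sigma[a, b] / p, 0)
}
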