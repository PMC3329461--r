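#' Jukes-Cantor rate matrix on n states
#'
#' Uniform rates: `q_ii = -1`, `q_ij = 1/(n-1)`. The eigenvalues are 0
#' (multiplicity 1) and `-n/(n-1)` (multiplicity n-1), which gives closed
#' forms for the transition probabilities and the convolution integrals
#' used as ground truth for the numerical backends.
#'
#' @param n state count, `n >= 2`.
#' @return a `rate_matrix`.
#' @export
jc_rate_matrix <- function(n) {
  if (n < 2) stop("n must be at least 2")
  M <- matrix(1 / (n - 1), n, n)
  diag(M) <- -1
  validate_rate_matrix(M)
}

#' Closed-form Jukes-Cantor transition probability
#'
#' `p_ij(t) = 1/n + ((n-1)/n) exp(-nt/(n-1))` on the diagonal and
#' `1/n - (1/n) exp(-nt/(n-1))` off it.
#'
#' @param n state count.
#' @param t time.
#' @param i,j states (indices).
#' @return the transition probability.
#' @export
jc_transition_closed_form <- function(n, t, i, j) {
  e <- exp(-n * t / (n - 1))
  ifelse(i == j, 1 / n + (n - 1) / n * e, 1 / n - e / n)
}

#' Closed-form Jukes-Cantor convolution integral
#'
#' The integral `I_cd^ab(t) = int_0^t p_ac(u) p_db(t-u) du` under the
#' n-state Jukes-Cantor model, in its three cases: (`a != c, d != b`),
#' (`a = c, d = b`), and otherwise.
#'
#' @param n state count.
#' @param t time.
#' @param a,b endpoint states; `c,d` inner states.
#' @param c,d states of the integrand.
#' @return the integral value.
#' @export
jc_integral_closed_form <- function(n, t, a, b, c, d) {
  e <- exp(-n * t / (n - 1))
  g <- (1 - e)                       # recurring factor
  both <- (a == c) & (d == b)
  neither <- (a != c) & (d != b)
  val <- ifelse(both,
                t + (n - 1)^2 * t * e + 2 * (n - 1)^2 / n * g,
         ifelse(neither,
                t + t * e - 2 * (n - 1) / n * g,
                t - (n - 1) * t * e + (n - 2) * (n - 1) / n * g))
  val / n^2
}

# Closed-form Sigma(C;t) for JC: per endpoint pair (a,b) the integral value
# depends only on which of the three cases (c,d) falls in, so Sigma is a
# combination of C's total, row and column sums.
.jc_sigma_closed_form <- function(n, t, C) {
  e <- exp(-n * t / (n - 1))
  g <- 1 - e
  I2 <- (t + (n - 1)^2 * t * e + 2 * (n - 1)^2 / n * g) / n^2
  I1 <- (t + t * e - 2 * (n - 1) / n * g) / n^2
  I3 <- (t - (n - 1) * t * e + (n - 2) * (n - 1) / n * g) / n^2
  tot <- sum(C)
  rs <- rowSums(C)                   # indexed by a (= c)
  cs <- colSums(C)                   # indexed by b (= d)
  RS <- matrix(rs, n, n)
  CS <- matrix(cs, n, n, byrow = TRUE)
  Cab <- C
  I2 * Cab + I1 * (tot - RS - CS + Cab) + I3 * (RS + CS - 2 * Cab)
}

#' HKY85 rate matrix
#'
#' Four-state nucleotide model in state order **A, G, C, T** with
#' transitions (A<->G, C<->T) scaled by `kappa`:
#' row `i` has entry `kappa * pi_j` when `i -> j` is a transition and
#' `pi_j` when it is a transversion.
#'
#' @param pi stationary distribution over (A, G, C, T).
#' @param kappa transition/transversion rate ratio, `> 0`.
#' @return a `rate_matrix` with labels A, G, C, T.
#' @export
hky_rate_matrix <- function(pi = c(0.2, 0.2, 0.3, 0.3), kappa = 2.15) {
  if (length(pi) != 4 || any(pi <= 0) || abs(sum(pi) - 1) > 1e-8)
    stop("pi must be a length-4 probability vector")
  if (kappa <= 0) stop("kappa must be positive")
  piA <- pi[1]; piG <- pi[2]; piC <- pi[3]; piT <- pi[4]
  M <- rbind(c(0,          kappa * piG, piC,         piT),
             c(kappa * piA, 0,          piC,         piT),
             c(piA,         piG,        0,           kappa * piT),
             c(piA,         piG,        kappa * piC, 0))
  diag(M) <- -rowSums(M)
  validate_rate_matrix(M, labels = c("A", "G", "C", "T"))
}

#' Closed-form eigensystem of the HKY85 rate matrix
#'
#' Eigenvalues `(0, -1, -pi_Y kappa - pi_R, -pi_R kappa - pi_Y)` with
#' `pi_R = pi_A + pi_G`, `pi_Y = pi_C + pi_T`, and the matching analytic
#' right-eigenvector matrix `U` and its inverse. `U diag(lambda) U^{-1}`
#' reconstructs the rate matrix to full precision.
#'
#' @param pi stationary distribution over (A, G, C, T).
#' @param kappa transition/transversion ratio.
#' @return list with `values`, `U`, `U_inv`.
#' @export
hky_eigensystem_closed_form <- function(pi = c(0.2, 0.2, 0.3, 0.3), kappa = 2.15) {
  piA <- pi[1]; piG <- pi[2]; piC <- pi[3]; piT <- pi[4]
  piR <- piA + piG
  piY <- piC + piT
  values <- c(0, -1, -piY * kappa - piR, -piR * kappa - piY)
  U <- cbind(c(1, 1, 1, 1),
             c(-piY / piR, -piY / piR, 1, 1),
             c(0, 0, -piT / piC, 1),
             c(-piG / piA, 1, 0, 0))
  U_inv <- rbind(c(piA, piG, piC, piT),
                 c(-piA, -piG, piC * piR / piY, piT * piR / piY),
                 c(0, 0, -piC / piY, piC / piY),
                 c(-piA / piR, piA / piR, 0, 0))
  list(values = values, U = U, U_inv = U_inv)
}

# Closed-form Sigma(C;t) for HKY assembled from the analytic eigensystem.
.hky_sigma_closed_form <- function(pi, kappa, C, t) {
  es <- hky_eigensystem_closed_form(pi, kappa)
  J <- build_j_matrix(es$values, t, degeneracy_tol = 0)
  es$U %*% (J * (es$U_inv %*% C %*% es$U)) %*% es$U_inv
}

#' Random reversible rate matrix
#'
#' Draws a stationary distribution from the flat Dirichlet, lower-triangle
#' rates from Exp(1), fills the upper triangle by detailed balance
#' `q_ij = pi_j q_ji / pi_i`, and fixes the diagonal from the row sums.
#' The generating stationary distribution is attached as attribute `"pi"`.
#'
#' @param n state count.
#' @param seed optional RNG seed for reproducibility.
#' @return a `rate_matrix`, reversible with respect to `attr(, "pi")`.
#' @export
random_reversible_matrix <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- stats::rgamma(n, 1)
  pi <- g / sum(g)
  M <- matrix(0, n, n)
  low <- lower.tri(M)
  M[low] <- stats::rexp(sum(low))
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    M[i, j] <- pi[j] * M[j, i] / pi[i]
  diag(M) <- -rowSums(M)
  Q <- validate_rate_matrix(M)
  attr(Q, "pi") <- stats::setNames(pi, state_labels(Q))
  Q
}

# Random binary weight matrix, entries 1 with probability p; the all-zero
# draw is resampled (it has no informative deviation).
.random_binary_C <- function(n, p = 0.5) {
  repeat {
    C <- matrix(stats::rbinom(n * n, 1L, p), n, n)
    if (any(C != 0)) return(C)
  }
}

#' Accuracy experiment against the JC / HKY closed forms
#'
#' Recomputes `Sigma(C;t)` with each backend on models with analytic ground
#' truth and reports the normalized deviation
#' `|Sigma_hat - Sigma| / Sigma`, averaged over the endpoint pairs `(a, b)`
#' and over `reps` random binary weight matrices per setting (entries equal
#' to one with probability `binary_prob`; entries whose true value is zero
#' are excluded from the average).
#'
#' @param model `"jc"` (varying state count at fixed `t`) or `"hky"`
#'   (fixed 4-state model at varying `t`).
#' @param ns state counts for the JC runs.
#' @param ts time points (JC default 0.1; HKY default 10 log-spaced points
#'   in `[0.01, 10]`).
#' @param reps number of random binary weight matrices per setting.
#' @param binary_prob Bernoulli probability of a weight entry being one.
#' @param seed RNG seed.
#' @param methods backends to test.
#' @param pi,kappa HKY parameters.
#' @return a data.frame with columns `model`, `n`, `t`, `method`,
#'   `normalized_deviation`.
#' @export
run_accuracy_experiment <- function(model = c("jc", "hky"),
                                    ns = seq(5, 100, by = 5),
                                    ts = NULL,
                                    reps = 5, binary_prob = 0.5, seed = 1,
                                    methods = c("evd", "uni", "expm"),
                                    pi = c(0.2, 0.2, 0.3, 0.3), kappa = 2.15) {
  model <- match.arg(model)
  set.seed(seed)
  if (model == "jc") {
    if (is.null(ts)) ts <- 0.1
    grid <- expand.grid(n = ns, t = ts)
  } else {
    if (is.null(ts)) ts <- exp(seq(log(0.01), log(10), length.out = 10))
    grid <- expand.grid(n = 4L, t = ts)
  }
  rows <- list()
  for (k in seq_len(nrow(grid))) {
    n <- grid$n[k]; t <- grid$t[k]
    Q <- if (model == "jc") jc_rate_matrix(n) else hky_rate_matrix(pi, kappa)
    Cs <- lapply(seq_len(reps), function(i) .random_binary_C(n, binary_prob))
    truths <- lapply(Cs, function(C)
      if (model == "jc") .jc_sigma_closed_form(n, t, C)
      else .hky_sigma_closed_form(pi, kappa, C, t))
    for (method in methods) {
      devs <- numeric(0)
      for (i in seq_len(reps)) {
        est <- ctmc_statistics(Q, Cs[[i]], t, method = method)$Sigma
        tr <- truths[[i]]
        keep <- tr != 0
        devs <- c(devs, abs(est[keep] - tr[keep]) / abs(tr[keep]))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        model = model, n = n, t = t, method = method,
        normalized_deviation = mean(devs))
    }
  }
  do.call(rbind, rows)
}
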