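# ---- pattern handling ------------------------------------------------------

# collapse alignment columns to unique site patterns with multiplicities
.site_patterns <- function(states) {
  key <- apply(states, 2L, paste, collapse = ",")
  u <- !duplicated(key)
  idx <- match(key, key[u])
  list(patterns = states[, u, drop = FALSE],
       weight = as.vector(table(factor(idx, levels = seq_len(sum(u))))),
       site_of = idx)
}

# ---- peeling (inside/outside) ----------------------------------------------

# Inside (post-order partial likelihoods) and outside (pre-order) passes over
# a rooted tree, vectorized across site patterns, with per-pattern
# log-scaling against underflow. P_edges is a list of transition matrices
# indexed by edge row. leaf_states is an ntip x npat integer matrix ordered
# as tree$tip.label.
.peel <- function(tree, P_edges, leaf_states, root_dist) {
  n <- nrow(P_edges[[1L]])
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  npat <- ncol(leaf_states)
  edge <- tree$edge
  L <- vector("list", nnode)
  logs <- matrix(0, nnode, npat)
  for (v in seq_len(ntip)) {
    Lv <- matrix(0, n, npat)
    Lv[cbind(leaf_states[v, ], seq_len(npat))] <- 1
    L[[v]] <- Lv
  }
  post_edges <- rev(.preorder_edges(tree))
  Msg <- vector("list", nrow(edge))       # message through each edge, to parent
  for (e in post_edges) {
    par <- edge[e, 1L]; child <- edge[e, 2L]
    Msg[[e]] <- P_edges[[e]] %*% L[[child]]
    if (is.null(L[[par]])) {
      L[[par]] <- Msg[[e]]
      logs[par, ] <- logs[child, ]
    } else {
      L[[par]] <- L[[par]] * Msg[[e]]
      logs[par, ] <- logs[par, ] + logs[child, ]
    }
    sc <- apply(L[[par]], 2L, max)
    sc[sc == 0] <- 1
    L[[par]] <- sweep(L[[par]], 2L, sc, "/")
    logs[par, ] <- logs[par, ] + log(sc)
  }
  site_lik <- colSums(root_dist * L[[root]])
  if (any(site_lik <= 0))
    stop("zero likelihood at site pattern(s) ",
         paste(which(site_lik <= 0), collapse = ", "))
  loglik <- log(site_lik) + logs[root, ]
  # outside pass
  A <- vector("list", nnode)
  logsA <- matrix(0, nnode, npat)
  A[[root]] <- matrix(root_dist, n, npat)
  for (e in .preorder_edges(tree)) {
    par <- edge[e, 1L]; child <- edge[e, 2L]
    # contribution of everything except the subtree below this edge
    F_e <- A[[par]] * L[[par]] / Msg[[e]]
    logsF <- logsA[par, ] + logs[par, ] - logs[child, ]
    A[[child]] <- crossprod(P_edges[[e]], F_e)
    sc <- apply(A[[child]], 2L, max)
    sc[sc == 0] <- 1
    A[[child]] <- sweep(A[[child]], 2L, sc, "/")
    logsA[child, ] <- logsF + log(sc)
    attr(A[[child]], "logsF") <- logsF   # kept for the joint posteriors
  }
  list(L = L, logs = logs, A = A, logsA = logsA, loglik = loglik, Msg = Msg)
}

# per-edge endpoint outer weights: W0_e(a, b) = sum_s w_s F_e(a, s) L_v(b, s)
# * exp(scale_s - loglik_s). The joint endpoint posterior for pattern s is
# F_e(a, s) p_ab L_v(b, s) exp(scale_s - loglik_s), i.e. W0 with the p_ab
# factor; keeping W0 (without p_ab) lets expectation sums cancel the
# division by p_ab analytically.
.edge_outer_weights <- function(tree, peeled, pattern_weight) {
  edge <- tree$edge
  lapply(seq_len(nrow(edge)), function(e) {
    par <- edge[e, 1L]; child <- edge[e, 2L]
    Fe <- peeled$A[[par]] * peeled$L[[par]] / peeled$Msg[[e]]
    logsF <- peeled$logsA[par, ] + peeled$logs[par, ] - peeled$logs[child, ]
    w <- pattern_weight * exp(logsF + peeled$logs[child, ] - peeled$loglik)
    (Fe * rep(w, each = nrow(Fe))) %*% t(peeled$L[[child]])
  })
}

.aln_states <- function(aln) {
  if (inherits(aln, "codon_alignment")) aln$codons
  else if (inherits(aln, "nucleotide_alignment")) aln$states
  else stop("aln must be a codon_alignment or nucleotide_alignment")
}

.check_tree_aln <- function(tree, aln) {
  states <- .aln_states(aln)
  i <- match(tree$tip.label, rownames(states))
  if (anyNA(i))
    stop("tree leaves absent from the alignment: ",
         paste(tree$tip.label[is.na(i)], collapse = ", "))
  states[i, , drop = FALSE]
}

.edge_transitions <- function(tree, Q) {
  ts <- tree$edge.length
  ut <- sort(unique(ts))
  Ps <- lapply(ut, function(t) transition_probabilities(Q, t))
  Ps[match(ts, ut)]
}

# ---- exported operations ---------------------------------------------------

#' Joint posterior of branch endpoint states
#'
#' For every branch `k` (with parent-side node state `a` and child-side
#' state `b`) and every alignment site, computes
#' `P(state above = a, state below = b | data, t_k)` by the peeling
#' algorithm: an inside (post-order) pass of partial likelihoods and an
#' outside (pre-order) pass.
#'
#' @param tree `phylo` with branch lengths.
#' @param Q a `rate_matrix` on the alignment's state space.
#' @param aln a `codon_alignment` or `nucleotide_alignment`.
#' @param root_dist root distribution; defaults to the stationary
#'   distribution of `Q`.
#' @return list over edges (rows of `tree$edge`) of `n x n x n_sites`
#'   arrays; each site slice is non-negative and sums to one.
#' @export
branch_endpoint_posteriors <- function(tree, Q, aln, root_dist = NULL) {
  if (is.null(root_dist)) root_dist <- stationary_distribution(Q)
  states <- .check_tree_aln(tree, aln)
  pat <- .site_patterns(states)
  P_edges <- .edge_transitions(tree, Q)
  peeled <- .peel(tree, P_edges, pat$patterns, root_dist)
  n <- nrow(Q)
  edge <- tree$edge
  lapply(seq_len(nrow(edge)), function(e) {
    par <- edge[e, 1L]; child <- edge[e, 2L]
    Fe <- peeled$A[[par]] * peeled$L[[par]] / peeled$Msg[[e]]
    logsF <- peeled$logsA[par, ] + peeled$logs[par, ] - peeled$logs[child, ]
    scale <- exp(logsF + peeled$logs[child, ] - peeled$loglik)
    out <- array(0, c(n, n, length(pat$site_of)))
    for (s in seq_along(pat$site_of)) {
      p <- pat$site_of[s]
      out[, , s] <- (Fe[, p] %o% peeled$L[[child]][, p]) * P_edges[[e]] * scale[p]
    }
    out
  })
}

#' Observed-data log-likelihood on a fixed tree
#'
#' Standard pruning likelihood: the sum over sites of the log probability of
#' the leaf states under the CTMC with rate matrix `Q` and the given root
#' distribution.
#'
#' @inheritParams branch_endpoint_posteriors
#' @return the log-likelihood (a scalar).
#' @export
observed_log_likelihood <- function(tree, Q, aln, root_dist = NULL) {
  if (is.null(root_dist)) root_dist <- stationary_distribution(Q)
  states <- .check_tree_aln(tree, aln)
  pat <- .site_patterns(states)
  P_edges <- .edge_transitions(tree, Q)
  peeled <- .peel(tree, P_edges, pat$patterns, root_dist)
  sum(pat$weight * peeled$loglik)
}

#' E-step: expected Goldman-Yang sufficient statistics
#'
#' Sums, over branches, sites and endpoint pairs, the posterior-weighted
#' conditional expectations of the label-restricted dwell times and jump
#' counts. Conditional expectations come from `Sigma(C;t)` with the weight
#' matrices of [label_weight_matrices()]; uniformization serves all branch
#' lengths from one precomputation per weight matrix.
#'
#' @inheritParams branch_endpoint_posteriors
#' @param C_matrices output of [label_weight_matrices()] for the current
#'   `Q`.
#' @param method backend for `Sigma(C;t)`.
#' @return list of expected statistics: dwell times `Ls_ts`, `Ls_tv`,
#'   `Lns_ts`, `Lns_tv`; jump counts `N`, `N_ts`, `N_ns`; plus `loglik`, the
#'   observed-data log-likelihood at the current parameters.
#' @export
e_step <- function(tree, Q, aln, C_matrices, root_dist = NULL, method = "uni") {
  if (is.null(root_dist)) root_dist <- stationary_distribution(Q)
  states <- .check_tree_aln(tree, aln)
  pat <- .site_patterns(states)
  P_edges <- .edge_transitions(tree, Q)
  peeled <- .peel(tree, P_edges, pat$patterns, root_dist)
  W0 <- .edge_outer_weights(tree, peeled, pat$weight)
  ts <- tree$edge.length
  ut <- sort(unique(ts))
  t_of_edge <- match(ts, ut)
  Cs <- c(C_matrices$time, C_matrices$count)
  names(Cs) <- c("Ls_ts", "Ls_tv", "Lns_ts", "Lns_tv", "N_ts", "N_ns", "N")
  Cs <- Cs[c("Ls_ts", "Ls_tv", "Lns_ts", "Lns_tv", "N", "N_ts", "N_ns")]
  stats <- lapply(Cs, function(C) {
    res <- ctmc_statistics(Q, C, ut, method = method)
    if (length(ut) == 1L) res <- list(res)
    tot <- 0
    for (e in seq_along(W0))
      tot <- tot + sum(W0[[e]] * res[[t_of_edge[e]]]$Sigma)
    tot
  })
  stats$loglik <- sum(pat$weight * peeled$loglik)
  stats
}

#' M-step: closed-form update of the Goldman-Yang parameters
#'
#' Maximizes the expected complete-data log-likelihood in the
#' reparametrization `beta = alpha * kappa`:
#' `omega_hat` is the positive root of the quadratic
#' `a w^2 + b w + c = 0` with `a = -Lns_tv Lns_ts N_s`,
#' `b = Lns_tv Ls_ts (N_ns - N_tv) + Lns_ts Ls_tv (N_ns - N_ts)`,
#' `c = Ls_tv Ls_ts N_ns`; then `alpha_hat = N_tv / (Ls_tv + omega_hat
#' Lns_tv)`, `beta_hat = N_ts / (Ls_ts + omega_hat Lns_ts)` and
#' `kappa_hat = beta_hat / alpha_hat`. Here `N_tv = N - N_ts` and
#' `N_s = N - N_ns`.
#'
#' @param stats expected sufficient statistics from [e_step()] (or the
#'   realized complete-data statistics of a simulation).
#' @return a [gy_params()] object (without `pi`).
#' @export
m_step <- function(stats) {
  for (nm in c("Ls_ts", "Ls_tv", "Lns_ts", "Lns_tv", "N", "N_ts", "N_ns"))
    if (is.null(stats[[nm]]) || stats[[nm]] <= 0)
      stop("degenerate statistics: ", nm, " must be positive")
  N_tv <- stats$N - stats$N_ts
  N_s <- stats$N - stats$N_ns
  a <- -stats$Lns_tv * stats$Lns_ts * N_s
  b <- stats$Lns_tv * stats$Ls_ts * (stats$N_ns - N_tv) +
       stats$Lns_ts * stats$Ls_tv * (stats$N_ns - stats$N_ts)
  cc <- stats$Ls_tv * stats$Ls_ts * stats$N_ns
  disc <- b^2 - 4 * a * cc
  if (disc < 0) stop("degenerate statistics: negative discriminant in the omega update")
  # a < 0 and c > 0 whenever the statistics are positive, so the quadratic
  # has exactly one positive root; take it
  roots <- (-b + c(1, -1) * sqrt(disc)) / (2 * a)
  omega <- roots[roots > 0][1L]
  if (is.na(omega) || !is.finite(omega))
    stop("degenerate statistics: non-positive omega root")
  alpha <- N_tv / (stats$Ls_tv + omega * stats$Lns_tv)
  beta <- stats$N_ts / (stats$Ls_ts + omega * stats$Lns_ts)
  gy_params(alpha = alpha, kappa = beta / alpha, omega = omega)
}

#' EM estimation of the Goldman-Yang model on a fixed tree
#'
#' Alternates [e_step()] and [m_step()] starting from `init`, holding the
#' tree, branch lengths and codon frequencies fixed. The codon stationary
#' distribution is the observed codon frequency estimate (with a small
#' pseudo-count for unobserved codons) and also serves as the root
#' distribution -- the model is reversible, so the likelihood is invariant
#' to root placement.
#'
#' @param aln a `codon_alignment`.
#' @param tree `phylo` with branch lengths; tips must match the alignment.
#' @param init initial [gy_params()].
#' @param tol convergence: maximal relative parameter change below `tol`.
#' @param max_iter iteration cap; hitting it flags `converged = FALSE`.
#' @param code a [genetic_code()].
#' @param method backend for the E-step expectations.
#' @param pseudo_count for [codon_frequencies()].
#' @return list with `params` (final [gy_params()] including `pi`), `trace`
#'   (data.frame of `iter`, `alpha`, `kappa`, `omega`, `loglik` -- the
#'   log-likelihood at that iteration's parameters), and `converged`.
#' @export
em_fit <- function(aln, tree, init = gy_params(1, 2, 0.5), tol = 1e-6,
                   max_iter = 200L, code = genetic_code(), method = "uni",
                   pseudo_count = 0.1) {
  pi <- codon_frequencies(aln, code, pseudo_count)
  theta <- c(init$alpha, init$kappa, init$omega)
  trace <- data.frame(iter = integer(0), alpha = numeric(0),
                      kappa = numeric(0), omega = numeric(0),
                      loglik = numeric(0))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    params <- gy_params(theta[1], theta[2], theta[3], pi)
    Q <- gy_rate_matrix(params, code)
    Cs <- label_weight_matrices(code, pi, Q)
    stats <- e_step(tree, Q, aln, Cs, root_dist = pi, method = method)
    trace <- rbind(trace, data.frame(iter = it, alpha = theta[1],
                                     kappa = theta[2], omega = theta[3],
                                     loglik = stats$loglik))
    upd <- m_step(stats)
    new_theta <- c(upd$alpha, upd$kappa, upd$omega)
    rel <- max(abs(new_theta - theta) / pmax(abs(theta), 1e-12))
    theta <- new_theta
    if (rel < tol) { converged <- TRUE; break }
  }
  params <- gy_params(theta[1], theta[2], theta[3], pi)
  if (!converged)
    warning("EM did not reach tol = ", tol, " within ", max_iter, " iterations")
  list(params = params, trace = trace, converged = converged)
}
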