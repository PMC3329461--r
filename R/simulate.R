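#' Simulate a CTMC sample path (Gillespie)
#'
#' Draws a full trajectory of the chain from state `a` over `[0, t]`:
#' exponential holding times with the state's exit rate, jump targets
#' proportional to the off-diagonal rates.
#'
#' @param Q a `rate_matrix`.
#' @param a starting state (index or label).
#' @param t duration, `t >= 0`.
#' @return an object of class `sampled_path`: a list with `states` (visited
#'   state indices), `jump_times` (strictly increasing, in `(0, t)`),
#'   `dwell` (time spent per state, summing exactly to `t`), `counts`
#'   (n x n jump-count matrix), and `t`.
#' @export
simulate_path <- function(Q, a, t) {
  stopifnot(t >= 0)
  n <- nrow(Q)
  a <- .as_state_index(a, Q)
  Qm <- unclass(Q)
  rates <- -diag(Qm)
  states <- a
  jump_times <- numeric(0)
  dwell <- numeric(n)
  counts <- matrix(0, n, n, dimnames = dimnames(Q))
  now <- 0
  cur <- a
  repeat {
    wait <- if (rates[cur] > 0) stats::rexp(1L, rates[cur]) else Inf
    if (now + wait >= t) {
      dwell[cur] <- dwell[cur] + (t - now)
      break
    }
    now <- now + wait
    dwell[cur] <- dwell[cur] + wait
    nxt <- sample.int(n, 1L, prob = pmax(Qm[cur, ], 0) * (seq_len(n) != cur))
    counts[cur, nxt] <- counts[cur, nxt] + 1
    jump_times <- c(jump_times, now)
    states <- c(states, nxt)
    cur <- nxt
  }
  names(dwell) <- state_labels(Q)
  structure(list(states = states, jump_times = jump_times,
                 dwell = dwell, counts = counts, t = t),
            class = "sampled_path")
}

#' @export
print.sampled_path <- function(x, ...) {
  cat("CTMC path: duration", x$t, "with", length(x$jump_times), "jumps\n")
  invisible(x)
}

# Vectorized bulk simulator: evolves `length(start)` independent chains for
# duration t. Returns end states plus per-path dwell times (npath x n) and
# jump counts (npath x n^2, column-major over (from, to)).
.simulate_bulk <- function(Q, start, t, keep_stats = TRUE) {
  Qm <- unclass(Q)
  n <- nrow(Qm)
  rates <- -diag(Qm)
  npath <- length(start)
  cur <- as.integer(start)
  now <- numeric(npath)
  active <- rep(TRUE, npath)
  dwell <- if (keep_stats) matrix(0, npath, n) else NULL
  counts <- if (keep_stats) matrix(0, npath, n * n) else NULL
  while (any(active)) {
    idx <- which(active)
    r <- rates[cur[idx]]
    wait <- ifelse(r > 0, stats::rexp(length(idx), pmax(r, 1e-300)), Inf)
    done <- now[idx] + wait >= t
    fin <- idx[done]
    if (length(fin)) {
      if (keep_stats)
        dwell[cbind(fin, cur[fin])] <- dwell[cbind(fin, cur[fin])] + (t - now[fin])
      active[fin] <- FALSE
    }
    jmp <- idx[!done]
    if (length(jmp)) {
      w <- wait[!done]
      if (keep_stats)
        dwell[cbind(jmp, cur[jmp])] <- dwell[cbind(jmp, cur[jmp])] + w
      now[jmp] <- now[jmp] + w
      # sample jump targets grouped by current state (snapshot: cur mutates
      # as groups are processed)
      from <- cur[jmp]
      for (s in unique(from)) {
        grp <- jmp[from == s]
        p <- pmax(Qm[s, ], 0)
        p[s] <- 0
        nxt <- sample.int(n, length(grp), replace = TRUE, prob = p)
        if (keep_stats) {
          k <- (nxt - 1L) * n + s     # column k: (from = s, to = nxt), so
                                      # array(counts, c(npath, n, n))[i, from, to]
          for (u in seq_along(grp)) counts[grp[u], k[u]] <- counts[grp[u], k[u]] + 1
        }
        cur[grp] <- nxt
      }
    }
  }
  list(end = cur, dwell = dwell, counts = counts)
}

#' Endpoint-conditioned path sampling by rejection
#'
#' Simulates unconditional paths from state `a` over `[0, t]` and retains
#' those ending in state `b`, yielding unbiased draws from the
#' endpoint-conditioned path distribution. This is the Monte-Carlo oracle
#' for the analytic conditional expectations of dwell times and jump counts.
#'
#' @param Q a `rate_matrix`.
#' @param a,b start and end states (index or label).
#' @param t duration.
#' @param n_samples number of accepted paths required.
#' @param min_acceptance abort if the acceptance probability `p_ab(t)` is
#'   below this floor (rejection sampling would be hopeless; use a smaller
#'   problem).
#' @return an object of class `conditioned_paths`: list with `dwell`
#'   (`n_samples` x n matrix of per-state dwell times), `counts`
#'   (`n_samples` x n x n array of jump counts), `t`, `a`, `b`, and
#'   `acceptance` (empirical acceptance rate).
#' @export
simulate_endpoint_conditioned <- function(Q, a, b, t, n_samples = 1000L,
                                          min_acceptance = 1e-6) {
  n <- nrow(Q)
  a <- .as_state_index(a, Q); b <- .as_state_index(b, Q)
  p <- transition_probabilities(Q, t)[a, b]
  if (p <= min_acceptance)
    stop("acceptance probability p_ab(t) = ", signif(p, 3),
         " below floor; use a smaller problem or different endpoints")
  dwell <- matrix(0, 0L, n)
  counts <- matrix(0, 0L, n * n)
  tried <- 0L
  while (nrow(dwell) < n_samples) {
    batch <- max(1000L, ceiling((n_samples - nrow(dwell)) / p * 1.1))
    sim <- .simulate_bulk(Q, rep(a, batch), t)
    tried <- tried + batch
    keep <- sim$end == b
    dwell <- rbind(dwell, sim$dwell[keep, , drop = FALSE])
    counts <- rbind(counts, sim$counts[keep, , drop = FALSE])
  }
  dwell <- dwell[seq_len(n_samples), , drop = FALSE]
  counts <- counts[seq_len(n_samples), , drop = FALSE]
  colnames(dwell) <- state_labels(Q)
  structure(list(dwell = dwell,
                 counts = array(counts, c(n_samples, n, n)),
                 t = t, a = a, b = b,
                 acceptance = n_samples / tried),
            class = "conditioned_paths")
}

#' @export
print.conditioned_paths <- function(x, ...) {
  cat("Endpoint-conditioned CTMC sample:", nrow(x$dwell), "paths,",
      "t =", x$t, ", acceptance", signif(x$acceptance, 3), "\n")
  cat("mean dwell times:\n")
  print(colMeans(x$dwell))
  invisible(x)
}
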