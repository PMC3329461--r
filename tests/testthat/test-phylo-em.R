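make_star_aln <- function(states) {
  nuc_alignment(matrix(states, length(states), 1,
                       dimnames = list(c("A", "B", "C")[seq_along(states)], NULL)))
}

test_that("branch endpoint posteriors match exhaustive enumeration on a star tree", {
  tree <- ape::read.tree(text = "(A:0.2,B:0.3,C:0.15);")
  Q <- jc_rate_matrix(4)
  y <- c(1L, 2L, 2L)
  aln <- make_star_aln(y)
  post <- branch_endpoint_posteriors(tree, Q, aln)

  pi <- rep(0.25, 4)
  Ps <- lapply(c(0.2, 0.3, 0.15), function(t) transition_probabilities(Q, t))
  lik <- sum(sapply(1:4, function(x)
    pi[x] * Ps[[1]][x, y[1]] * Ps[[2]][x, y[2]] * Ps[[3]][x, y[3]]))
  for (e in 1:3) {
    brute <- matrix(0, 4, 4)
    for (x in 1:4)
      brute[x, y[e]] <- pi[x] * Ps[[1]][x, y[1]] * Ps[[2]][x, y[2]] *
        Ps[[3]][x, y[3]] / lik
    expect_lt(max(abs(post[[e]][, , 1] - brute)), 1e-12)
    expect_equal(sum(post[[e]][, , 1]), 1, tolerance = 1e-10)
    # child side of a leaf branch is the observed state with probability one
    expect_equal(sum(post[[e]][, y[e], 1]), 1, tolerance = 1e-12)
  }
})

test_that("two-leaf posteriors are a point mass at the observed pair", {
  tree <- ape::read.tree(text = "(A:0.4,B:0.3);")
  Q <- hky_rate_matrix()
  aln <- nuc_alignment(matrix(c(1L, 3L), 2, 1, dimnames = list(c("A", "B"), NULL)))
  post <- branch_endpoint_posteriors(tree, Q, aln)
  # the root here is the 2-degree node: each branch joins root and a leaf,
  # and the joint of (root state, leaf state) puts all leaf-side mass on the
  # observed state
  expect_equal(sum(post[[1]][, 1, 1]), 1, tolerance = 1e-12)
  expect_equal(sum(post[[2]][, 3, 1]), 1, tolerance = 1e-12)
})

test_that("pruning likelihood matches the pairwise closed form and flags impossible sites", {
  tree <- ape::read.tree(text = "(A:0.4,B:0.3);")
  Q <- jc_rate_matrix(4)
  states <- matrix(c(1L, 1L, 2L, 4L, 3L, 3L), 2, 3,
                   dimnames = list(c("A", "B"), NULL))
  aln <- nuc_alignment(states)
  ll <- observed_log_likelihood(tree, Q, aln)
  closed <- sum(log(0.25 * jc_transition_closed_form(4, 0.7, states[1, ], states[2, ])))
  expect_equal(ll, closed, tolerance = 1e-10)

  # a reducible chain makes some patterns impossible
  blk <- matrix(0, 4, 4)
  blk[1, 2] <- blk[2, 1] <- blk[3, 4] <- blk[4, 3] <- 1
  diag(blk) <- -1
  Qb <- validate_rate_matrix(blk)
  expect_error(
    observed_log_likelihood(tree, Qb, aln, root_dist = rep(0.25, 4)),
    "zero likelihood")
})

test_that("E-step with identity time weights recovers total tree length per site", {
  tree <- ape::read.tree(text = "((A:0.2,B:0.1):0.15,C:0.3);")
  Q <- jc_rate_matrix(4)
  set.seed(4)
  m <- 50L
  sim <- simulate_alignment(tree, Q, m, seed = 4)
  aln <- as_alignment(sim, "nucleotide")
  zero <- matrix(0, 4, 4)
  Cs <- list(time = list(s_ts = diag(4), s_tv = zero, ns_ts = zero, ns_tv = zero),
             count = list(ts = zero, ns = zero, all = zero))
  stats <- e_step(tree, Q, aln, Cs)
  expect_equal(stats$Ls_ts, sum(tree$edge.length) * m, tolerance = 1e-8)
})

test_that("E-step expectations are consistent with realized complete-data statistics", {
  code <- genetic_code()
  pi <- rep(1 / 61, 61)
  Q <- gy_rate_matrix(gy_params(10.5, 4.27, 0.6, pi), code)
  tree <- ape::read.tree(text = "((A:0.1,B:0.1):0.05,(C:0.1,D:0.1):0.05);")
  sim <- simulate_alignment(tree, Q, 500, root_dist = pi, seed = 21)
  aln <- as_alignment(sim, "codon")
  Cs <- label_weight_matrices(code, pi, Q)
  est <- e_step(tree, Q, aln, Cs, root_dist = pi)

  cls <- code$class
  realized <- list(
    N = sum(sim$counts),
    N_ts = sum(sim$counts[cls %in% c("s_ts", "ns_ts")]),
    N_ns = sum(sim$counts[cls %in% c("ns_ts", "ns_tv")]))
  # E[N|y] and the realized N estimate the same total; conditional noise is
  # O(sqrt(N)), so agreement is loose but scale-free
  for (nm in names(realized)) {
    expect_gt(est[[nm]], 0)
    expect_lt(abs(est[[nm]] - realized[[nm]]) / realized[[nm]], 0.2)
  }
  # dwell statistics: total dwell time is the tree length per site
  PI <- matrix(pi, 61, 61, byrow = TRUE)
  dwell_truth <- sapply(c("s_ts", "s_tv", "ns_ts", "ns_tv"), function(lab)
    sum(sim$dwell * rowSums(PI * (cls == lab))))
  est_dwell <- unlist(est[c("Ls_ts", "Ls_tv", "Lns_ts", "Lns_tv")])
  expect_lt(max(abs(est_dwell - dwell_truth) / dwell_truth), 0.1)
})

test_that("M-step solves the complete-data score equations", {
  stats <- list(Ls_ts = 3.2, Ls_tv = 5.1, Lns_ts = 2.2, Lns_tv = 4.4,
                N = 120, N_ts = 55, N_ns = 40)
  p <- m_step(stats)
  ll <- function(th)
    -th[1] * stats$Ls_tv - th[1] * th[3] * stats$Lns_tv -
     th[1] * th[2] * stats$Ls_ts - th[1] * th[2] * th[3] * stats$Lns_ts +
     stats$N * log(th[1]) + stats$N_ts * log(th[2]) + stats$N_ns * log(th[3])
  opt <- optim(c(1, 1, 1), function(th) -ll(th), method = "L-BFGS-B",
               lower = 1e-6, control = list(factr = 10))
  expect_equal(c(p$alpha, p$kappa, p$omega), opt$par, tolerance = 1e-5)
  # gradient vanishes at the estimate
  grad <- sapply(1:3, function(i) {
    h <- 1e-6 * max(1, abs(c(p$alpha, p$kappa, p$omega)[i]))
    e <- numeric(3); e[i] <- h
    (ll(c(p$alpha, p$kappa, p$omega) + e) - ll(c(p$alpha, p$kappa, p$omega) - e)) / (2 * h)
  })
  expect_lt(max(abs(grad)), 1e-5)

  # homogeneity: doubling the dwell statistics halves alpha and beta only
  stats2 <- stats
  for (nm in c("Ls_ts", "Ls_tv", "Lns_ts", "Lns_tv")) stats2[[nm]] <- 2 * stats2[[nm]]
  p2 <- m_step(stats2)
  expect_equal(p2$alpha, p$alpha / 2, tolerance = 1e-12)
  expect_equal(p2$kappa, p$kappa, tolerance = 1e-12)
  expect_equal(p2$omega, p$omega, tolerance = 1e-12)

  # statistics built from an omega = 1 complete-data expectation return omega = 1
  code <- genetic_code()
  pi <- rep(1 / 61, 61)
  Q1 <- gy_rate_matrix(gy_params(2, 3, 1, pi), code)
  cls <- code$class
  PI <- matrix(pi, 61, 61, byrow = TRUE)
  Ttot <- 10
  Ti <- Ttot * pi  # stationary occupancy
  s1 <- list(
    Ls_ts = sum(Ti * rowSums(PI * (cls == "s_ts"))),
    Ls_tv = sum(Ti * rowSums(PI * (cls == "s_tv"))),
    Lns_ts = sum(Ti * rowSums(PI * (cls == "ns_ts"))),
    Lns_tv = sum(Ti * rowSums(PI * (cls == "ns_tv"))))
  EN <- function(lab) sum((pi * unclass(Q1))[cls %in% lab])
  s1$N <- EN(c("s_ts", "s_tv", "ns_ts", "ns_tv")) * Ttot
  s1$N_ts <- EN(c("s_ts", "ns_ts")) * Ttot
  s1$N_ns <- EN(c("ns_ts", "ns_tv")) * Ttot
  p1 <- m_step(s1)
  expect_equal(p1$omega, 1, tolerance = 1e-10)
  expect_equal(p1$kappa, 3, tolerance = 1e-10)
  expect_equal(p1$alpha, 2, tolerance = 1e-10)

  s_bad <- stats; s_bad$N_ns <- 0
  expect_error(m_step(s_bad), "degenerate")
})

test_that("EM increases the likelihood and is stationary at the optimum", {
  code <- genetic_code()
  pi <- rep(1 / 61, 61)
  truth <- gy_params(10.5, 4.27, 0.6, pi)
  Q <- gy_rate_matrix(truth, code)
  tree <- ape::read.tree(text = "((A:0.1,B:0.1):0.05,(C:0.1,D:0.1):0.05);")
  sim <- simulate_alignment(tree, Q, 400, root_dist = pi, seed = 31)
  aln <- as_alignment(sim, "codon")

  fit <- em_fit(aln, tree, tol = 1e-4, max_iter = 30)
  expect_true(all(diff(fit$trace$loglik) > -1e-8))
  expect_true(fit$converged)
  expect_s3_class(fit$params, "gy_params")

  # near the optimum at large m the first M-step barely moves the parameters
  sim2 <- simulate_alignment(tree, Q, 2000, root_dist = pi, seed = 32)
  aln2 <- as_alignment(sim2, "codon")
  fit1 <- suppressWarnings(em_fit(aln2, tree, init = truth, tol = 0, max_iter = 2))
  th0 <- c(10.5, 4.27, 0.6)
  th1 <- unlist(fit1$trace[2, c("alpha", "kappa", "omega")])
  expect_lt(max(abs(th1 - th0) / th0), 0.05)
})
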