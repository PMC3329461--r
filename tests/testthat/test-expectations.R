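test_that("truncation point follows the conservative rule and bounds the Poisson tail", {
  expect_identical(truncation_point(0), 4L)
  expect_identical(truncation_point(2.6684), 17L)
  expect_identical(truncation_point(0.2668), 8L)
  expect_error(truncation_point(-1), "non-negative")

  # tail beyond s(lambda) stays at the bound across a wide lambda grid; the
  # closed-form rule overshoots the exact 1e-8 quantile by at most one term
  # (near lambda = 1 its tail is 1.005e-8, within half a percent of the bound)
  for (lam in c(0.001, 0.01, 0.1, 1, 5, 10, 50, 100)) {
    s <- truncation_point(lam)
    expect_lte(ppois(s - 1, lam, lower.tail = FALSE), 1.05e-8)
    s_exact <- truncation_point(lam, exact = TRUE)
    expect_lte(ppois(s_exact - 1, lam, lower.tail = FALSE), 1e-8)
    expect_lte(s_exact, s + 1L)
  }
})

test_that("J matrix handles degenerate and near-degenerate eigenvalues", {
  expect_equal(build_j_matrix(c(0, 0), 0.7), matrix(0.7, 2, 2))

  # JC n = 4 eigenvalues: 0 and -4/3 (x3)
  lam <- c(0, rep(-4 / 3, 3))
  t <- 0.3
  J <- build_j_matrix(lam, t)
  expect_equal(J[1, 2], (1 - exp(-4 * t / 3)) / (4 / 3), tolerance = 1e-12)
  expect_equal(J[2, 3], t * exp(-4 * t / 3), tolerance = 1e-12)
  expect_equal(diag(J), t * exp(lam * t), tolerance = 1e-12)

  # continuity at the degeneracy branch point
  J1 <- build_j_matrix(c(-1, -1 + 1e-14), t)
  J2 <- build_j_matrix(c(-1, -1), t)
  expect_lt(max(abs(J1 - J2)), 1e-9)
})

test_that("all backends are linear in C, vanish at C = 0, and conserve Sigma(I;t) = t P(t)", {
  set.seed(10)
  for (seed in 1:6) {
    n <- sample(3:7, 1)
    Q <- random_reversible_matrix(n, seed = seed)
    t <- runif(1, 0.05, 2)
    C1 <- matrix(rnorm(n * n), n, n)
    C2 <- matrix(rnorm(n * n), n, n)
    for (m in c("evd", "uni", "expm")) {
      z <- ctmc_statistics(Q, matrix(0, n, n), t, method = m)
      expect_equal(max(abs(z$Sigma)), 0, tolerance = 1e-12)
      s1 <- ctmc_statistics(Q, C1, t, method = m)$Sigma
      s2 <- ctmc_statistics(Q, C2, t, method = m)$Sigma
      s12 <- ctmc_statistics(Q, C1 + C2, t, method = m)$Sigma
      expect_lt(max(abs(s12 - s1 - s2)), 1e-10 * max(1, max(abs(s12))))
      ri <- ctmc_statistics(Q, diag(n), t, method = m)
      expect_lt(max(abs(ri$Sigma - t * ri$P)), 1e-9)
    }
  }
})

test_that("EVD takes the symmetric route for reversible chains and errors usefully otherwise", {
  Q <- gtr_rate_matrix()
  es <- ctmcexp:::.eigen_system(Q)
  expect_true(es$symmetrized)
  expect_lt(max(Mod(es$U %*% diag(es$values) %*% es$U_inv - unclass(Q))),
            1e-9 * max(abs(Q)))

  # non-reversible matrix with complex eigensystem: general route, real output
  Qu <- unr_rate_matrix()
  esu <- ctmcexp:::.eigen_system(Qu)
  expect_false(esu$symmetrized)
  expect_true(is.complex(esu$values))
  C <- matrix(runif(16), 4, 4)
  r_evd <- evd_statistics(Qu, C, 0.8)
  r_expm <- expm_statistics(Qu, C, 0.8)
  expect_false(is.complex(r_evd$Sigma))
  expect_lt(max(abs(r_evd$Sigma - r_expm$Sigma)), 1e-9 * max(abs(r_expm$Sigma)))
})

test_that("uniformization batches over time points without changing values", {
  Q <- hky_rate_matrix()
  C <- matrix(rbinom(16, 1, 0.5), 4, 4)
  single <- uni_statistics(Q, C, 0.4)
  batched <- uni_statistics(Q, C, c(0.4, 0.8))
  expect_lt(max(abs(single$Sigma - batched[[1]]$Sigma)), 1e-12)
  expect_lt(max(abs(single$P - batched[[1]]$P)), 1e-12)
})

test_that("the zero generator yields the degenerate Sigma = t*C", {
  Q0 <- validate_rate_matrix(matrix(0, 3, 3))
  C <- matrix(rnorm(9), 3, 3)
  res <- uni_statistics(Q0, C, 1.7)
  expect_equal(res$Sigma, 1.7 * C, ignore_attr = TRUE)
  expect_equal(unclass(res$P), diag(3), ignore_attr = TRUE)
  # cross-check against the block-matrix route, which needs no special case
  expect_equal(res$Sigma, expm_statistics(Q0, C, 1.7)$Sigma, ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("single-entry weights reduce to quadrature of the convolution integral", {
  set.seed(5)
  for (seed in c(2, 9)) {
    Q <- random_reversible_matrix(4, seed = seed)
    t <- runif(1, 0.2, 1.5)
    cd <- sample(4, 2)
    C <- matrix(0, 4, 4); C[cd[1], cd[2]] <- 1
    truth <- outer(1:4, 1:4, Vectorize(function(a, b)
      quadrature_integral(Q, t, a, b, cd[1], cd[2])))
    for (m in c("evd", "uni", "expm")) {
      est <- ctmc_statistics(Q, C, t, method = m)$Sigma
      expect_lt(max(abs(est - truth)), 1e-8)
    }
  }
})

test_that("conditional dwell times and jump counts follow the endpoint formulas", {
  Q <- jc_rate_matrix(4)
  t <- 0.5
  # conservation: dwell times over all states sum to t for every endpoint pair
  for (a in 1:2) for (b in 1:3) {
    tot <- sum(sapply(1:4, function(c) conditional_dwell_time(Q, t, c, a, b)))
    expect_equal(tot, t, tolerance = 1e-9)
  }
  # q_cd = 0 means no jumps counted
  gy <- gy_rate_matrix(gy_params(1, 2, 0.5))
  multi <- which(unclass(gy) == 0 & row(gy) != col(gy), arr.ind = TRUE)[1, ]
  expect_equal(conditional_jump_count(gy, 0.3, multi[1], multi[2], 1, 1), 0)
  # two-state chain, a = b, small t: double jumps are second order in t
  Q2 <- validate_rate_matrix(matrix(c(-1, 1, 1, -1), 2, 2))
  expect_lt(conditional_jump_count(Q2, 1e-3, 1, 2, 1, 1), 1e-5)
  # unreachable endpoints are an error
  blk <- matrix(0, 4, 4)
  blk[1, 2] <- blk[2, 1] <- blk[3, 4] <- blk[4, 3] <- 1
  diag(blk) <- -1
  Qb <- validate_rate_matrix(blk)
  expect_error(conditional_dwell_time(Qb, 0.5, 1, 1, 3), "unreachable")
})
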