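r_true <- c(0.5, 0.3, 0.6, 0.2, 0.3, 0.2)
pi_true <- c(0.2, 0.2, 0.3, 0.3)

test_that("GTR construction nests JC, matches the printed parameters, and is reversible", {
  Qjc <- gtr_rate_matrix(rep(1, 6), rep(0.25, 4))
  expect_equal(unclass(Qjc), 0.75 * unclass(jc_rate_matrix(4)), ignore_attr = TRUE)

  Q <- gtr_rate_matrix(r_true, pi_true)
  expect_true(is_reversible(Q))
  # detailed balance is exact analytically
  F <- pi_true * unclass(Q)
  expect_lt(max(abs(F - t(F))), 1e-16)
  expect_equal(unclass(Q)["A", "G"], 0.5 * 0.2)
  expect_equal(unclass(Q)["C", "T"], 0.2 * 0.3)
  expect_error(gtr_rate_matrix(c(1, 2), pi_true), "6 positive rates")
})

test_that("label sets and their weight matrices follow the rate restriction", {
  Q <- gtr_rate_matrix(r_true, pi_true)
  empty <- label_set(matrix(integer(0), 0, 2), Q)
  expect_equal(label_weight_from_rates(Q, empty), matrix(0, 4, 4),
               ignore_attr = TRUE)

  all_pairs <- label_set("all", Q)
  C_all <- label_weight_from_rates(Q, all_pairs)
  expect_equal(C_all[row(C_all) != col(C_all)],
               unclass(Q)[row(C_all) != col(C_all)])
  expect_true(all(diag(C_all) == 0))

  LA <- label_set("to-from:A", Q)
  expect_equal(nrow(LA), 6L)
  CA <- label_weight_from_rates(Q, LA)
  iA <- match("A", state_labels(Q))
  expect_true(all(CA[-iA, -iA] == 0))
  expect_equal(CA[iA, -iA], unclass(Q)[iA, -iA])

  expect_error(label_set(cbind(1, 1), Q), "self-pairs")
})

test_that("robust labeled distance reduces correctly at the edges", {
  Q <- gtr_rate_matrix(r_true, pi_true)
  empty <- label_set(matrix(integer(0), 0, 2), Q)
  same <- matrix(c(1L, 1L, 2L, 2L), 2, 2)
  expect_equal(robust_labeled_distance(same, Q, empty), 0)

  # one site reduces to the summed conditional jump counts for that pattern
  L <- label_set("to-from:A", Q)
  one <- matrix(c(1L, 3L), 2, 1)
  d1 <- robust_labeled_distance(one, Q, L)
  direct <- sum(sapply(seq_len(nrow(L)), function(k)
    conditional_jump_count(Q, 1, L[k, 1], L[k, 2], 1, 3)))
  expect_equal(d1, direct, tolerance = 1e-10)

  # additivity over disjoint label sets
  set.seed(12)
  states <- rbind(sample.int(4, 40, TRUE), sample.int(4, 40, TRUE))
  L1 <- label_set(rbind(c(1, 2), c(2, 1)), Q)
  L2 <- label_set(rbind(c(3, 4), c(4, 3)), Q)
  L12 <- label_set(rbind(c(1, 2), c(2, 1), c(3, 4), c(4, 3)), Q)
  expect_equal(robust_labeled_distance(states, Q, L12),
               robust_labeled_distance(states, Q, L1) +
               robust_labeled_distance(states, Q, L2), tolerance = 1e-10)
})

test_that("labeled distance converges to the stationary labeled rate", {
  Q <- gtr_rate_matrix(r_true, pi_true)
  L <- label_set("to-from:A", Q)
  truth <- sum(pi_true[L[, 1]] * unclass(Q)[L])
  tree <- ape::read.tree(text = "(x:0.5,y:0.5);")  # divergence 1
  m <- 2e4
  sim <- simulate_alignment(tree, Q, m, seed = 13)
  aln <- as_alignment(sim, "nucleotide")
  d <- robust_labeled_distance(aln, Q, L)
  C <- label_weight_from_rates(Q, L)
  res <- ctmc_statistics(Q, C, 1)
  E <- res$Sigma / res$P
  se <- sd(E[cbind(aln$states[1, ], aln$states[2, ])]) / sqrt(m)
  expect_lt(abs(d - truth), 3 * se)
})

test_that("pairwise ML recovers the GTR parameters", {
  Q <- gtr_rate_matrix(r_true, pi_true)
  tree <- ape::read.tree(text = "(x:0.5,y:0.5);")
  sim <- simulate_alignment(tree, Q, 2000, seed = 14)
  aln <- as_alignment(sim, "nucleotide")
  fit <- estimate_gtr(aln)
  expect_true(fit$converged)
  # base frequencies are exactly the pooled empirical frequencies
  emp <- tabulate(as.integer(aln$states), 4) / (2 * ncol(aln$states))
  expect_equal(unname(fit$pi), emp)
  expect_lt(max(abs(fit$r - r_true) / r_true), 0.25)

  # likelihood at the estimate beats the truth on the same data
  counts <- table(factor(aln$states[1, ], levels = 1:4),
                  factor(aln$states[2, ], levels = 1:4))
  llik <- function(Qx, pix) {
    P <- transition_probabilities(Qx, 1)
    sum(counts * log(matrix(pix, 4, 4) * P))
  }
  expect_gte(fit$loglik + 1e-6, llik(gtr_rate_matrix(r_true, fit$pi), fit$pi))
})
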