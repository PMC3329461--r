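# Independent oracles used across the suite.

# Adaptive quadrature of the convolution integral
# I_cd^ab(t) = int_0^t p_ac(u) p_db(t-u) du.
quadrature_integral <- function(Q, t, a, b, c, d, rel.tol = 1e-10) {
  stats::integrate(function(u) sapply(u, function(v)
    transition_probabilities(Q, v)[a, c] * transition_probabilities(Q, t - v)[d, b]),
    lower = 0, upper = t, rel.tol = rel.tol)$value
}

# Sigma(C;t) assembled entry by entry from quadrature (tiny n only).
sigma_by_quadrature <- function(Q, C, t) {
  n <- nrow(Q)
  S <- matrix(0, n, n)
  nz <- which(C != 0, arr.ind = TRUE)
  for (a in seq_len(n)) for (b in seq_len(n))
    for (k in seq_len(nrow(nz)))
      S[a, b] <- S[a, b] + C[nz[k, 1], nz[k, 2]] *
        quadrature_integral(Q, t, a, b, nz[k, 1], nz[k, 2])
  S
}

# in-memory nucleotide alignment from an integer state matrix
nuc_alignment <- function(states, labels = rownames(states)) {
  if (is.null(labels)) labels <- paste0("seq", seq_len(nrow(states)))
  rownames(states) <- labels
  structure(list(states = states, labels = labels,
                 state_names = c("A", "G", "C", "T"), n_masked = 0L),
            class = "nucleotide_alignment")
}

# fixed non-reversible 4-state rate matrix with a complex eigensystem
unr_rate_matrix <- function() {
  validate_rate_matrix(matrix(c(-4, 2, 1, 1,
                                 0, -3, 2, 1,
                                 1, 0, -3, 2,
                                 2, 1, 1, -4), 4, 4, byrow = TRUE))
}
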