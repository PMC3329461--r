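---
title: "Endpoint-conditioned expectations for CTMCs: models, algorithms and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Endpoint-conditioned expectations for CTMCs: models, algorithms and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctmcexp)
```

## The problem

A continuous-time Markov chain (CTMC) with rate matrix $Q = (q_{cd})$ on $n$
states is the standard model of sequence evolution at the nucleotide, amino
acid or codon level. Its sufficient statistics are the time $T_c$ spent in
each state and the number of jumps $N_{cd}$ between each ordered pair of
states: given a completely observed path, the log-likelihood is a linear
function of $(T_c)$ and $(\log q_{cd}\text{-weighted } N_{cd})$, and maximum
likelihood estimation is immediate.

Real sequence data are observed only at the ends of a branch. What is needed
is the conditional expectation of the sufficient statistics given the chain's
endpoints,

$$
E[T_c \mid t,a,b] = \frac{I^{ab}_{cc}(t)}{p_{ab}(t)}, \qquad
E[N_{cd} \mid t,a,b] = q_{cd}\,\frac{I^{ab}_{cd}(t)}{p_{ab}(t)},
$$

where $P(t) = e^{Qt}$ and $I^{ab}_{cd}(t) = \int_0^t p_{ac}(u)\,
p_{db}(t-u)\, du$. Applications almost always need *linear combinations* of
these — numbers of transitions, transversions, synonymous or labeled
substitutions — so the package's central object is the matrix

$$
\Sigma(C;t)_{ab} \;=\; \sum_{c,d} C_{cd}\, I^{ab}_{cd}(t)
$$

for an arbitrary weight matrix $C$. Dwell-time statistics use diagonal
weights, jump-count statistics use off-diagonal weights $C_{cd} = q_{cd}
\mathbf{1}((c,d)\in\mathcal{L})$. All three backends compute the full
$n \times n$ matrix in $O(n^3)$.

## The three backends

**EVD** (`evd_statistics`). With $Q = U \Lambda U^{-1}$,
$\Sigma(C;t) = U\,[J(t) \circ (U^{-1} C U)]\,U^{-1}$, where
$J_{ij}(t) = (e^{\lambda_i t} - e^{\lambda_j t})/(\lambda_i - \lambda_j)$
and $J_{ii} = t e^{\lambda_i t}$. For reversible chains the decomposition is
taken on the symmetric matrix $\Pi^{1/2} Q \Pi^{-1/2}$ (faster, more
robust); otherwise the general, possibly complex, decomposition is used and
the imaginary residue — a cancellation artifact of conjugate pairs — is
asserted to be below $10^{-8}\max|\Sigma|$ before being dropped. Eigenvalue
pairs closer than $10^{-9}\max_i|\lambda_i|$ take the degenerate branch of
$J$; the divided difference would otherwise cancel catastrophically. A
non-diagonalizable or ill-conditioned eigensystem (condition number above
$10^{12}$) is an explicit error directing the user to the `expm` backend.

**UNI** (`uni_statistics`). With $\mu = \max_i q_i$ and
$R = Q/\mu + I$,

$$
\Sigma(C;t) = \frac1\mu \sum_{m \ge 0} \mathrm{Pois}(m+1;\mu t)
\sum_{l=0}^{m} R^l C R^{m-l},
$$

truncated at $s(\lambda)$ terms, $\lambda = \mu t$. The inner sums satisfy
$A(m+1) = A(m)R + R^{m+1}C$ and are computed once at the *largest* requested
time, so a batch of time points costs one precomputation plus an $O(s n^2)$
weighted sum per extra time. Poisson weights come from `dpois`, which is
itself evaluated in log space and is safe for any $\mu t$. The default
truncation is the closed-form rule $s(\lambda) = \lceil 4 + 6\sqrt{\lambda}
+ \lambda\rceil$, calibrated to a tail bound of $10^{-8}$ (the standard
normal quantile at $1 - 10^{-8}$ is $5.6$, giving the leading
$\lambda + 5.6\sqrt\lambda$ behaviour; the constants are a conservative
round-up). The rule is conservative to within one term: near $\lambda = 1$
its Poisson tail is $1.005 \times 10^{-8}$, half a percent over the nominal
bound, and everywhere else on the grid $10^{-3} \le \lambda \le 100$ it is
below it. `truncation_point(..., exact = TRUE)` instead searches for the
smallest $s$ with tail $\le b$ and is used to verify the rule. The
degenerate generator $Q = 0$ (so $\mu = 0$) returns $\Sigma = tC$, which is
the exact value of the defining integral when $P(u) \equiv I$.

**EXPM** (`expm_statistics`). Van Loan's construction: the exponential of
the $2n \times 2n$ block matrix $A = \begin{pmatrix} Q & C \\ 0 & Q
\end{pmatrix}$ has $\Sigma(C;t)$ in its upper-right block and $P(t)$ in its
diagonal blocks; $P(t)$ is read off rather than recomputed. The matrix
exponential is `Matrix::expm`'s Higham08 scaling-and-squaring Padé with
balancing. No precomputation is shared across time points, which is why this
backend is the reference for accuracy rather than the default for speed.

`ctmc_statistics()` dispatches between the three; uniformization is the
default because its precomputation amortizes over the many branch lengths an
EM iteration needs.

### Numerical cross-checks

Three independent ground truths back the backends, all exercised in the test
suite and the acceptance script:

* the $n$-state Jukes–Cantor model, whose two-eigenvalue structure gives
  closed forms for $p_{ij}(t)$ and all three cases of $I^{ab}_{cd}(t)$;
* the HKY model with $\pi = (0.2, 0.2, 0.3, 0.3)$, $\kappa = 2.15$, whose
  eigensystem is analytic (eigenvalues $0, -1, -\pi_Y\kappa - \pi_R,
  -\pi_R\kappa - \pi_Y$);
* adaptive quadrature of the defining integral for single-entry $C$, and
  rejection-sampled endpoint-conditioned paths for the conditional
  expectations themselves.

On the accuracy regime (JC at $n = 5..100$, $t = 0.1$; HKY at ten log-spaced
times in $[0.01, 10]$; five random binary $C$ per setting) the normalized
deviation $|\hat\Sigma - \Sigma| / \Sigma$, averaged over endpoint pairs and
replicates, stays below $3 \times 10^{-9}$ for every backend, with EXPM the
most and UNI the least precise in the experiment-wide median. On random
reversible matrices (stationary law from a flat Dirichlet, lower-triangle
rates Exp(1), upper triangle by detailed balance) the three backends agree
to a relative $10^{-5}$.

Entries with $\Sigma = 0$ are excluded from the normalized-deviation average
(0/0), and all-zero binary weight draws are resampled.

## Application 1: EM for the Goldman–Yang codon model

The Goldman–Yang model puts a CTMC on the 61 sense codons (standard code;
stops TAA, TAG, TGA excluded; codons ordered lexicographically over
A, C, G, T — the code table ships as a plain-text TSV and can be overridden):

$$
q_{ij} = \begin{cases}
0 & \text{more than one position differs} \\
\alpha\kappa\pi_j & \text{synonymous transition} \\
\alpha\pi_j & \text{synonymous transversion} \\
\alpha\omega\kappa\pi_j & \text{non-synonymous transition} \\
\alpha\omega\pi_j & \text{non-synonymous transversion.}
\end{cases}
$$

Transitions are A$\leftrightarrow$G and C$\leftrightarrow$T. $\pi$ is fixed
at the observed codon frequencies (pseudo-count 0.1 on unobserved codons so
$Q$ stays irreducible); $\theta = (\alpha, \kappa, \omega)$ is estimated by
EM on a fixed tree with fixed branch lengths.

The complete-data log-likelihood is linear in four label-restricted dwell
statistics and three jump counts, so the E-step is exactly seven
$\Sigma(C;t)$ evaluations per distinct branch length: diagonal weights
$C_{ii} = \sum_j \pi_j \mathbf{1}((i,j) \in L)$ for the dwell statistics and
off-diagonal $C_{ij} = q_{ij}\mathbf{1}((i,j)\in L)$ for the counts. Joint
endpoint posteriors per branch and site come from the peeling algorithm: an
inside pass of partial likelihoods and an outside pass, both vectorized over
unique site patterns with per-pattern log-scaling. Because the joint
posterior of a branch's endpoints carries a factor $p_{ab}(t_k)$ that the
conditional expectation divides back out, the implementation cancels it
analytically and never forms the ratio, so unreachable endpoint pairs cannot
produce 0/0.

The M-step is closed-form in the reparametrization $\beta = \alpha\kappa$:
$\hat\omega$ solves a quadratic with exactly one positive root (the
implementation selects the positive root; writing the root as
$(-b + \sqrt{b^2 - 4ac})/(2a)$ with $a = -L_{ns,tv} L_{ns,ts} N_s < 0$
picks the negative one, a sign trap verified against direct numerical
maximization of the complete-data likelihood), then
$\hat\alpha = N_{tv}/(L_{s,tv} + \hat\omega L_{ns,tv})$,
$\hat\beta = N_{ts}/(L_{s,ts} + \hat\omega L_{ns,ts})$,
$\hat\kappa = \hat\beta/\hat\alpha$.

Design choices where the procedure is genuinely open:

* **Rooting and root distribution.** Input trees are used as read; the root
  distribution defaults to $\hat\pi$. The model is reversible, so the
  likelihood and all expectations are invariant to root placement.
* **Convergence.** Maximal relative change of $(\alpha,\kappa,\omega)$ below
  $10^{-6}$, capped at 200 iterations; both are user-settable, and
  non-convergence is a warning, not an error.
* **Initialization.** $\alpha = 1$, $\kappa = 2$, $\omega = 0.5$ unless
  supplied.
* **Site patterns** are collapsed to unique columns with multiplicities —
  mathematically neutral, large constant-factor savings.
* **Batching.** All distinct branch lengths are served by one uniformization
  precomputation per weight matrix at the largest branch length.

The EM trace records $\theta$ and the observed-data log-likelihood per
iteration; monotonicity of the trace (the EM guarantee) is asserted in the
tests to within $10^{-8}$ slack.

## Application 2: robust labeled distances

For a pairwise alignment $\mathbf{y} = (\mathbf{y}_1, \mathbf{y}_2)$ of
length $m$ under an assumed (typically GTR) model — divergence fixed at
$t = 1$ since only $Qt$ is identified — the labeled distance for a pair set
$\mathcal{L}$ is

$$
\hat d_{\mathcal{L}} = \frac1m \sum_{s=1}^m
E\Big[\textstyle\sum_{(i,j)\in\mathcal{L}} N_{ij} \,\Big|\, 1,
y_{1s}, y_{2s}\Big].
$$

Averaging over the *empirical* site-pattern distribution rather than the
model's theoretical one is what buys robustness to model misspecification.
One $\Sigma(C;1)$ evaluation (16 endpoint pairs for nucleotides) serves all
$m$ sites. Label sets are available as presets (`to-from:A`,
`transitions`, `all`) or explicit pair lists, and the distance is additive
over disjoint label sets.

GTR parameters are estimated by pairwise maximum likelihood at $t = 1$:
base frequencies are the pooled empirical frequencies, and all six
exchangeabilities are optimized freely over log-rates (with $t$ fixed, all
six are identifiable from the 16 pattern probabilities). Simulation at the
reference parameter values $r = (0.5, 0.3, 0.6, 0.2, 0.3, 0.2)$,
$\pi = (0.2, 0.2, 0.3, 0.3)$, $m = 2000$ recovers the rates to well within
25%.

## The simulator and what passing tests do (and do not) show

`simulate_alignment()` draws root states from the stationary law and runs
exact (Gillespie) simulation down every branch, returning both the leaf
alignment and the complete-data sufficient statistics of the hidden paths,
so every simulation doubles as ground truth. `simulate_endpoint_conditioned()`
is a rejection sampler — the simplest provably correct endpoint-conditioned
sampler — and refuses problems whose acceptance probability is below
$10^{-6}$.

The study conditions for the estimation experiments are fixed in the test
suite: EM recovery uses the reference parameters $\alpha = 10.5$,
$\kappa = 4.27$, $\omega = 0.6$ on a balanced four-leaf tree
`((A:0.1,B:0.1):0.05,(C:0.1,D:0.1):0.05)` with uniform codon frequencies and
2000 sites — sizes at which the recovery bias is comfortably within 15% —
and the robust-distance consistency check uses $10^5$ sites at unit
divergence. The simulator emulates i.i.d. sites evolving under a single
homogeneous, stationary process on a known tree. Real data violate most of
this — among-site rate variation, selection heterogeneity along the
sequence, alignment error, non-stationarity of base composition, and tree
misspecification are all absent — so passing recovery tests demonstrate the
correctness of the estimator under its own model, not its adequacy for any
particular dataset. The robust distance is specifically designed to degrade
gracefully under such misspecification, but the tests only verify its
behaviour under the correctly specified model.

## Degenerate inputs and tie-breaks

* Row sums of user matrices must vanish within $10^{-12}\max|Q|$
  (configurable); validated rows are re-centred exactly.
* Reversibility is declared at detailed-balance violations below
  $10^{-10}\max|Q|$; the symmetrized EVD route can be disabled with
  `force_general = TRUE`.
* Reducible chains are detected via the null-space dimension of $Q^\top$
  (SVD) and rejected by `stationary_distribution`.
* `p_{ab}(t) = 0` endpoints are an explicit "unreachable" error in the
  conditional expectations, and a named-site error in the likelihood and
  distance code paths.
* Negative transition-probability round-off (below $10^{-10}$ in magnitude)
  is clipped to zero.

## Limitations

* EVD requires a diagonalizable generator; the Jordan-form extension is not
  implemented (the `expm` backend covers those cases).
* No derivatives of $\Sigma(C;t)$, no variances of the sufficient
  statistics — first moments only.
* The EM estimates $(\alpha, \kappa, \omega)$ on a *fixed* tree: no branch
  length or topology estimation, no among-site rate variation.
* Time-homogeneous chains only.
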