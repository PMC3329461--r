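.pkg_cache <- new.env(parent = emptyenv())

#' The genetic code and codon state space
#'
#' Loads a codon -> amino-acid table and derives the codon state space used
#' by the Goldman-Yang model: the sense codons (61 under the standard code),
#' ordered lexicographically over the alphabet A, C, G, T, with stop codons
#' excluded. Also precomputes the substitution classification of every
#' ordered codon pair (see [classify_substitution()]).
#'
#' @param table_path path to a tab-separated table with columns `codon` and
#'   `amino_acid` (stops marked `*`); defaults to the standard code shipped
#'   with the package.
#' @return an object of class `genetic_code`: list with `codons` (sense
#'   codons in order), `amino_acid` (named map), `stop_codons`, and `class`
#'   (61 x 61 character matrix of substitution categories).
#' @export
genetic_code <- function(table_path = NULL) {
  default <- is.null(table_path)
  if (default && !is.null(.pkg_cache$genetic_code)) return(.pkg_cache$genetic_code)
  if (default)
    table_path <- system.file("extdata", "standard_genetic_code.tsv",
                              package = "ctmcexp", mustWork = TRUE)
  tab <- utils::read.table(table_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  aa <- stats::setNames(tab$amino_acid, toupper(tab$codon))
  stops <- names(aa)[aa == "*"]
  codons <- sort(names(aa)[aa != "*"])    # lexicographic over A, C, G, T
  code <- list(codons = codons, amino_acid = aa[codons], stop_codons = stops)
  code$class <- .classify_all(code)
  class(code) <- "genetic_code"
  if (default) .pkg_cache$genetic_code <- code
  code
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("Genetic code:", length(x$codons), "sense codons;",
      length(x$stop_codons), "stop codons (",
      paste(x$stop_codons, collapse = ", "), ")\n")
  invisible(x)
}

.is_transition_pair <- function(x, y) {
  (x == "A" & y == "G") | (x == "G" & y == "A") |
  (x == "C" & y == "T") | (x == "T" & y == "C")
}

# classification matrix over all ordered sense-codon pairs
.classify_all <- function(code) {
  codons <- code$codons
  k <- length(codons)
  pos <- do.call(rbind, strsplit(codons, ""))
  cls <- matrix("multi", k, k, dimnames = list(codons, codons))
  ndiff <- matrix(0L, k, k)
  for (p in 1:3) ndiff <- ndiff + outer(pos[, p], pos[, p], "!=")
  same_aa <- outer(code$amino_acid, code$amino_acid, "==")
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) { cls[i, j] <- "identical"; next }
    if (ndiff[i, j] != 1L) next           # stays "multi"
    p <- which(pos[i, ] != pos[j, ])
    ts <- .is_transition_pair(pos[i, p], pos[j, p])
    cls[i, j] <- paste0(if (same_aa[i, j]) "s_" else "ns_",
                        if (ts) "ts" else "tv")
  }
  cls
}

#' Classify a codon substitution
#'
#' An ordered pair of sense codons is `identical` (no change), `multi` (more
#' than one nucleotide position differs; instantaneous rate zero under the
#' Goldman-Yang model), or one of the four single-step categories:
#' synonymous/non-synonymous crossed with transition/transversion. A
#' transition is a purine<->purine (A<->G) or pyrimidine<->pyrimidine
#' (C<->T) change; a substitution is synonymous when both codons encode the
#' same amino acid.
#'
#' @param i,j codon strings (e.g. `"AAA"`).
#' @param code a [genetic_code()] object.
#' @return one of `"identical"`, `"multi"`, `"s_ts"`, `"s_tv"`, `"ns_ts"`,
#'   `"ns_tv"`.
#' @export
classify_substitution <- function(i, j, code = genetic_code()) {
  i <- toupper(i); j <- toupper(j)
  if (!(i %in% code$codons)) stop("not a sense codon: ", i)
  if (!(j %in% code$codons)) stop("not a sense codon: ", j)
  code$class[i, j]
}

#' Goldman-Yang codon model parameters
#'
#' @param alpha overall scaling factor (`> 0`); units of substitutions per
#'   unit branch length, absorbed into the rates.
#' @param kappa transition/transversion rate ratio (`> 0`).
#' @param omega non-synonymous/synonymous rate ratio (`> 0`); `omega < 1`
#'   indicates purifying selection.
#' @param pi stationary codon distribution (length 61 for the standard
#'   code); defaults to uniform.
#' @return an object of class `gy_params` with fields `alpha`, `kappa`,
#'   `omega`, `pi` and the derived `beta = alpha * kappa`.
#' @export
gy_params <- function(alpha, kappa, omega, pi = NULL) {
  stopifnot(alpha > 0, kappa > 0, omega > 0)
  if (!is.null(pi)) {
    if (any(pi < 0) || abs(sum(pi) - 1) > 1e-8)
      stop("pi must be a probability vector")
  }
  structure(list(alpha = alpha, kappa = kappa, omega = omega, pi = pi,
                 beta = alpha * kappa),
            class = "gy_params")
}

#' @export
print.gy_params <- function(x, ...) {
  cat(sprintf("GY codon model: alpha = %.4g, kappa = %.4g, omega = %.4g\n",
              x$alpha, x$kappa, x$omega))
  invisible(x)
}

#' Goldman-Yang codon rate matrix
#'
#' The 61 x 61 rate matrix (stop codons excluded) with
#' `q_ij = alpha kappa pi_j` (synonymous transition), `alpha pi_j`
#' (synonymous transversion), `alpha omega kappa pi_j` (non-synonymous
#' transition), `alpha omega pi_j` (non-synonymous transversion), and zero
#' for codon pairs differing at more than one position.
#'
#' @param params a [gy_params()] object (a missing `pi` defaults to
#'   uniform over the sense codons).
#' @param code a [genetic_code()] object.
#' @return a `rate_matrix` labeled by codons, reversible with respect to
#'   `pi`.
#' @export
gy_rate_matrix <- function(params, code = genetic_code()) {
  k <- length(code$codons)
  pi <- params$pi
  if (is.null(pi)) pi <- rep(1 / k, k)
  if (length(pi) != k) stop("pi must have length ", k)
  cls <- code$class
  fac <- matrix(0, k, k)
  fac[cls == "s_ts"] <- params$alpha * params$kappa
  fac[cls == "s_tv"] <- params$alpha
  fac[cls == "ns_ts"] <- params$alpha * params$omega * params$kappa
  fac[cls == "ns_tv"] <- params$alpha * params$omega
  M <- fac * matrix(pi, k, k, byrow = TRUE)   # q_ij proportional to pi_j
  diag(M) <- -rowSums(M)
  Q <- validate_rate_matrix(M, labels = code$codons)
  attr(Q, "pi") <- stats::setNames(pi, code$codons)
  Q
}

#' Weight matrices for the Goldman-Yang sufficient statistics
#'
#' The E-step of the EM algorithm needs expectations of four
#' label-restricted dwell-time statistics and three jump-count statistics.
#' Each is a linear combination `Sigma(C;t)`: the dwell statistics use
#' diagonal weights `C_ii = sum_j pi_j 1((i,j) in L)` for `L` one of the
#' synonymous/non-synonymous x transition/transversion pair sets; the count
#' statistics use off-diagonal weights `C_ij = q_ij 1((i,j) in L)` for the
#' transition, non-synonymous, and all-single-step pair sets.
#'
#' @param code a [genetic_code()] object.
#' @param pi stationary codon distribution.
#' @param Q the Goldman-Yang `rate_matrix` the counts refer to.
#' @return list with elements `time` (list `s_ts`, `s_tv`, `ns_ts`,
#'   `ns_tv` of diagonal matrices) and `count` (list `ts`, `ns`, `all` of
#'   zero-diagonal matrices).
#' @export
label_weight_matrices <- function(code, pi, Q) {
  k <- length(code$codons)
  cls <- code$class
  Qm <- unclass(Q)
  PI <- matrix(pi, k, k, byrow = TRUE)
  time <- lapply(c(s_ts = "s_ts", s_tv = "s_tv", ns_ts = "ns_ts", ns_tv = "ns_tv"),
                 function(lab) diag(rowSums(PI * (cls == lab)), k))
  single <- cls %in% c("s_ts", "s_tv", "ns_ts", "ns_tv")
  dim(single) <- dim(cls)
  count <- list(
    ts  = Qm * (cls %in% c("s_ts", "ns_ts")),
    ns  = Qm * (cls %in% c("ns_ts", "ns_tv")),
    all = Qm * single)
  count <- lapply(count, function(C) { dim(C) <- dim(cls); diag(C) <- 0; C })
  list(time = time, count = count)
}

#' Observed codon frequencies of an alignment
#'
#' Empirical frequencies of the sense codons across all sequences and
#' retained sites, with a pseudo-count keeping unobserved codons at positive
#' frequency (so the Goldman-Yang matrix stays irreducible).
#'
#' @param aln a `codon_alignment` (see [read_alignment()]).
#' @param code a [genetic_code()] object.
#' @param pseudo_count added to each codon's count before normalizing.
#' @return probability vector over the sense codons.
#' @export
codon_frequencies <- function(aln, code = genetic_code(), pseudo_count = 0.1) {
  k <- length(code$codons)
  counts <- tabulate(as.integer(aln$codons), nbins = k) + pseudo_count
  stats::setNames(counts / sum(counts), code$codons)
}
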