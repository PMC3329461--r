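#' Read a FASTA alignment
#'
#' Parses a multiple FASTA alignment and validates it for downstream use.
#' Columns containing gaps (`-`, `.`) or ambiguity codes (IUPAC letters such
#' as `N`, `R`, `Y`) are masked out; characters outside the IUPAC alphabet
#' are an error. Nucleotide states are indexed in the order **A, G, C, T**
#' (the convention of the HKY/GTR matrix layouts, where the `kappa` entries
#' pair A<->G and C<->T).
#'
#' @param path FASTA file.
#' @param alphabet `"codon"` (sequences read as consecutive triplets in
#'   frame 1; a codon column is masked when any of its three nucleotide
#'   columns is masked in any sequence, or when it contains a stop codon)
#'   or `"nucleotide"`.
#' @param code a [genetic_code()] object (codon mode).
#' @return for `"codon"`: a `codon_alignment` (list with `codons`, an
#'   `n_seq x n_site` matrix of indices into `code$codons`; `labels`;
#'   `n_masked`). For `"nucleotide"`: a `nucleotide_alignment` (list with
#'   `states`, indices into A, G, C, T; `labels`; `n_masked`).
#' @export
read_alignment <- function(path, alphabet = c("codon", "nucleotide"),
                           code = genetic_code()) {
  alphabet <- match.arg(alphabet)
  seqs <- ape::read.FASTA(path)
  chars <- lapply(as.character(seqs), toupper)
  lens <- lengths(chars)
  if (length(unique(lens)) != 1L)
    stop("ragged alignment: sequence lengths ", paste(unique(lens), collapse = ", "))
  mat <- do.call(rbind, chars)
  rownames(mat) <- names(seqs)
  .alignment_from_matrix(mat, alphabet, code)
}

.iupac_ambiguous <- c("N", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V",
                      "-", ".", "?")

.alignment_from_matrix <- function(mat, alphabet, code = genetic_code()) {
  nuc_order <- c("A", "G", "C", "T")
  mat[mat == "U"] <- "T"
  known <- mat %in% c(nuc_order, .iupac_ambiguous)
  if (!all(known))
    stop("unknown symbol(s) in alignment: ",
         paste(unique(mat[!known]), collapse = ", "))
  ambiguous_col <- apply(matrix(!(mat %in% nuc_order), nrow(mat)), 2L, any)
  if (alphabet == "nucleotide") {
    keep <- !ambiguous_col
    states <- matrix(match(mat[, keep, drop = FALSE], nuc_order), nrow(mat))
    rownames(states) <- rownames(mat)
    return(structure(list(states = states, labels = rownames(mat),
                          state_names = nuc_order, n_masked = sum(!keep)),
                     class = "nucleotide_alignment"))
  }
  len <- ncol(mat)
  if (len %% 3L != 0L)
    stop("codon mode requires length divisible by 3 (got ", len, ")")
  n_cod <- len %/% 3L
  col_of <- rep(seq_len(n_cod), each = 3L)
  bad <- tapply(ambiguous_col, col_of, any)
  codon_strings <- matrix("", nrow(mat), n_cod)
  for (s in seq_len(n_cod)) {
    cols <- (3L * s - 2L):(3L * s)
    codon_strings[, s] <- apply(mat[, cols, drop = FALSE], 1L, paste, collapse = "")
  }
  idx <- matrix(match(codon_strings, code$codons), nrow(mat))
  bad <- bad | apply(is.na(idx), 2L, any)     # stop codons in gap-free columns
  idx <- idx[, !bad, drop = FALSE]
  rownames(idx) <- rownames(mat)
  structure(list(codons = idx, labels = rownames(mat),
                 state_names = code$codons, n_masked = sum(bad)),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("Codon alignment:", nrow(x$codons), "sequences,", ncol(x$codons),
      "sites (", x$n_masked, "masked )\n")
  invisible(x)
}

#' @export
print.nucleotide_alignment <- function(x, ...) {
  cat("Nucleotide alignment:", nrow(x$states), "sequences,", ncol(x$states),
      "sites (", x$n_masked, "masked )\n")
  invisible(x)
}

#' Write an alignment to FASTA
#'
#' @param aln a `codon_alignment`, `nucleotide_alignment`, or a character
#'   matrix of sequence letters with row names.
#' @param path output path.
#' @export
write_alignment <- function(aln, path) {
  if (inherits(aln, "codon_alignment")) {
    seqs <- apply(aln$codons, 1L, function(i) paste(aln$state_names[i], collapse = ""))
  } else if (inherits(aln, "nucleotide_alignment")) {
    seqs <- apply(aln$states, 1L, function(i) paste(aln$state_names[i], collapse = ""))
  } else {
    seqs <- apply(aln, 1L, paste, collapse = "")
  }
  out <- character(2L * length(seqs))
  out[c(TRUE, FALSE)] <- paste0(">", names(seqs))
  out[c(FALSE, TRUE)] <- seqs
  writeLines(out, path)
  invisible(path)
}

#' Read a Newick tree
#'
#' @param path Newick file; every branch must carry a length.
#' @param leaf_names optional character vector the tip labels must match
#'   (e.g. alignment sequence names).
#' @return an `ape` `phylo` object.
#' @export
read_tree <- function(path, leaf_names = NULL) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick file ", path)
  if (is.null(tree$edge.length) || length(tree$edge.length) != nrow(tree$edge))
    stop("tree must have branch lengths on every branch")
  if (any(tree$edge.length <= 0))
    stop("branch lengths must be positive")
  if (!is.null(leaf_names)) {
    missing <- setdiff(tree$tip.label, leaf_names)
    if (length(missing))
      stop("tree leaves absent from the alignment: ", paste(missing, collapse = ", "))
    extra <- setdiff(leaf_names, tree$tip.label)
    if (length(extra))
      stop("alignment sequences absent from the tree: ", paste(extra, collapse = ", "))
  }
  tree
}

#' Simulate an alignment along a tree
#'
#' Draws root states from `root_dist`, evolves them down every branch by
#' exact stochastic simulation of the CTMC, and returns both the leaf
#' alignment and the complete-data sufficient statistics of the hidden
#' paths (total dwell times and jump counts, overall and per branch), so
#' simulations double as ground truth for complete-data checks.
#'
#' @param tree an `ape` `phylo` with branch lengths.
#' @param Q a `rate_matrix` (any state space: nucleotides or codons).
#' @param m number of sites.
#' @param root_dist root state distribution; defaults to the stationary
#'   distribution of `Q`.
#' @param seed optional RNG seed.
#' @return a `simulated_alignment`: list with `alignment` (tips x m matrix
#'   of state indices, rownames = tip labels), `dwell` (length-n total dwell
#'   times over all branches and sites), `counts` (n x n total jump counts),
#'   `per_branch` (list of per-edge dwell/count totals), `tree`, `labels`.
#' @export
simulate_alignment <- function(tree, Q, m, root_dist = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(Q)
  if (is.null(root_dist)) root_dist <- stationary_distribution(Q)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  states <- matrix(NA_integer_, nnode, m)
  states[root, ] <- sample.int(n, m, replace = TRUE, prob = root_dist)
  dwell <- numeric(n)
  counts <- matrix(0, n, n, dimnames = dimnames(Q))
  per_branch <- vector("list", nrow(tree$edge))
  ord <- .preorder_edges(tree)
  for (e in ord) {
    par <- tree$edge[e, 1L]; child <- tree$edge[e, 2L]
    sim <- .simulate_bulk(Q, states[par, ], tree$edge.length[e])
    states[child, ] <- sim$end
    d <- colSums(sim$dwell)
    cnt <- matrix(colSums(sim$counts), n, n)
    dwell <- dwell + d
    counts <- counts + cnt
    per_branch[[e]] <- list(dwell = d, counts = cnt)
  }
  aln <- states[seq_len(ntip), , drop = FALSE]
  rownames(aln) <- tree$tip.label
  names(dwell) <- state_labels(Q)
  structure(list(alignment = aln, dwell = dwell, counts = counts,
                 per_branch = per_branch, tree = tree,
                 labels = state_labels(Q)),
            class = "simulated_alignment")
}

#' @export
print.simulated_alignment <- function(x, ...) {
  cat("Simulated alignment:", nrow(x$alignment), "leaves,",
      ncol(x$alignment), "sites;", sum(x$counts), "substitutions in total\n")
  invisible(x)
}

# edges ordered so that every parent is visited before its children
.preorder_edges <- function(tree) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  out <- integer(0)
  stack <- root
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  while (length(stack)) {
    node <- stack[[1L]]
    stack <- stack[-1L]
    es <- kids[[as.character(node)]]
    if (is.null(es)) next
    out <- c(out, es)
    stack <- c(tree$edge[es, 2L], stack)
  }
  out
}

#' Convert a simulated alignment to an in-memory alignment object
#'
#' @param sim a `simulated_alignment`.
#' @param alphabet `"codon"` or `"nucleotide"` -- must match the state space
#'   of the rate matrix used for simulation.
#' @return a `codon_alignment` or `nucleotide_alignment`.
#' @export
as_alignment <- function(sim, alphabet = c("codon", "nucleotide")) {
  alphabet <- match.arg(alphabet)
  if (alphabet == "codon")
    structure(list(codons = sim$alignment, labels = rownames(sim$alignment),
                   state_names = sim$labels, n_masked = 0L),
              class = "codon_alignment")
  else
    structure(list(states = sim$alignment, labels = rownames(sim$alignment),
                   state_names = sim$labels, n_masked = 0L),
              class = "nucleotide_alignment")
}
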