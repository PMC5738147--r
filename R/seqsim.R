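## Vectorised site evolution across a batch of gene trees.
##
## states are propagated root-to-tips; because gene-tree node ids from the
## coalescent engine increase with coalescence order, visiting nodes in
## decreasing id order guarantees each node's parent state is available,
## even though topologies differ across rows.
##
## parent, blen: n x (2*ntip-1) matrices (mutation-scale lengths);
## rate: per-site (per-row) rate multiplier. Returns an n x ntip integer
## state matrix (1..4 = A,C,G,T).
.evolve_states <- function(parent, blen, model, rate) {
  n <- nrow(parent)
  nnode <- ncol(parent)
  ntip <- (nnode + 1L) / 2L
  states <- matrix(0L, n, nnode)
  states[, nnode] <- sample.int(4L, n, replace = TRUE, prob = model$freqs)
  rows <- seq_len(n)
  Lm <- model$L
  Rm <- model$R
  lambda <- model$lambda
  for (v in (nnode - 1L):1L) {
    ps <- states[cbind(rows, parent[, v])]
    E <- exp(outer(blen[, v] * rate, lambda))       # n x 4
    probs <- (Lm[ps, , drop = FALSE] * E) %*% t(Rm)  # n x 4, rows ~ P(t)[ps, ]
    probs[probs < 0] <- 0
    cum1 <- probs[, 1L]
    cum2 <- cum1 + probs[, 2L]
    cum3 <- cum2 + probs[, 3L]
    tot <- cum3 + probs[, 4L]
    u <- stats::runif(n) * tot
    states[, v] <- 1L + (u > cum1) + (u > cum2) + (u > cum3)
  }
  states[, seq_len(ntip), drop = FALSE]
}

#' Evolve sites along simulated gene trees
#'
#' Simulates one or more alignment columns on each gene tree of a
#' `gene_tree_set`: the root state is drawn from the model's stationary
#' frequencies and propagated along each branch with transition
#' probabilities `exp(Q b r)`, where `r` is the site's rate multiplier
#' (see [site_rates()]), drawn once per site and shared across the tree.
#'
#' @param gts a [simulate_gene_trees()] result (mutation-scale lengths are
#'   used).
#' @param model a [substitution_model()].
#' @param sites_per_tree columns simulated per gene tree (1 for coalescent
#'   independent sites; the locus length for multilocus data).
#' @return character alignment matrix, `ntip` rows (taxa) by
#'   `n_trees * sites_per_tree` columns, with attribute `provenance`
#'   giving each column's gene-tree index.
#' @export
evolve_sites <- function(gts, model, sites_per_tree = 1L) {
  stopifnot(inherits(gts, "gene_tree_set"),
            inherits(model, "substitution_model"), sites_per_tree >= 1L)
  idx <- rep(seq_len(nrow(gts$parent)), each = sites_per_tree)
  parent <- gts$parent[idx, , drop = FALSE]
  blen <- gts$blen_mut[idx, , drop = FALSE]
  rate <- site_rates(model, length(idx))
  states <- .evolve_states(parent, blen, model, rate)
  aln <- matrix(NUC[t(states)], nrow = gts$ntip,
                dimnames = list(gts$taxa, NULL))
  attr(aln, "provenance") <- idx
  aln
}

#' Simulate a single site on a gene tree
#'
#' @param gt a `phylo` gene tree with mutation-scale branch lengths.
#' @param model a [substitution_model()].
#' @return named character vector, one nucleotide per tip.
#' @export
evolve_site <- function(gt, model) {
  stopifnot(inherits(gt, "phylo"))
  ntip <- ape::Ntip(gt)
  nnode <- ntip + gt$Nnode
  states <- integer(nnode)
  root <- ntip + 1L
  states[root] <- sample.int(4L, 1L, prob = model$freqs)
  ord <- rev(ape::postorder(gt))
  for (e in ord) {
    p <- gt$edge[e, 1L]; ch <- gt$edge[e, 2L]
    P <- transition_matrix(model, gt$edge.length[e])
    states[ch] <- sample.int(4L, 1L, prob = P[states[p], ])
  }
  stats::setNames(NUC[states[seq_len(ntip)]], gt$tip.label)
}

#' Simulate coalescent independent sites
#'
#' Each alignment column gets its own coalescent gene tree: `n_sites`
#' genealogies are drawn from the species-tree model and one site is
#' evolved on each. Columns are exchangeable and recombine freely.
#'
#' @param model a [species_tree_model()].
#' @param subst a [substitution_model()].
#' @param n_sites number of sites (>= 1).
#' @return character alignment matrix (taxa x sites) with a `provenance`
#'   attribute; see [evolve_sites()].
#' @examples
#' aln <- simulate_cis(preset_species_tree("long_asym"),
#'                     substitution_model("JC69"), 1000)
#' quartet_root_test(aln)
#' @export
simulate_cis <- function(model, subst, n_sites) {
  if (n_sites < 1) stop("n_sites must be >= 1")
  gts <- simulate_gene_trees(model, n_sites)
  evolve_sites(gts, subst, 1L)
}

#' Simulate multilocus sequence data
#'
#' One coalescent gene tree per locus; all `locus_length` sites of a locus
#' evolve on that tree (independently given the tree). Loci are
#' concatenated into a single alignment.
#'
#' @param model a [species_tree_model()].
#' @param subst a [substitution_model()].
#' @param n_genes number of loci.
#' @param locus_length sites per locus (default 500).
#' @return character alignment matrix (taxa x `n_genes * locus_length`)
#'   with a per-column `provenance` attribute (locus index).
#' @export
simulate_multilocus <- function(model, subst, n_genes, locus_length = 500L) {
  if (n_genes < 1) stop("n_genes must be >= 1")
  if (locus_length < 1) stop("locus_length must be >= 1")
  gts <- simulate_gene_trees(model, n_genes)
  evolve_sites(gts, subst, as.integer(locus_length))
}
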