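#' Species-tree model for coalescent simulation
#'
#' Bundles a rooted species tree whose branch lengths are in coalescent
#' units (1 unit = 2 Ne generations; a pair of lineages in one population
#' coalesces at rate 1 per unit) with the population-scaled mutation rate
#' theta = 4 Ne mu used to convert coalescent lengths to expected
#' substitutions per site (a coalescent length t becomes t * theta / 2
#' substitutions), and optional per-tip pendant extensions that model
#' clock violation by adding extra substitution opportunity to a tip's
#' mutation-scale path after the coalescent draw.
#'
#' @param tree rooted tree: an `ape` `phylo` object or a Newick string.
#'   Polytomies are allowed (a star phylogeny is a root with >2 children).
#' @param theta population-scaled mutation rate (default 0.05).
#' @param tip_extension optional named numeric vector, tip label -> extra
#'   coalescent-unit length added to that tip's pendant mutation path.
#' @return object of class `species_tree_model`.
#' @seealso [preset_species_tree()] for the built-in study trees.
#' @export
species_tree_model <- function(tree, theta = 0.05, tip_extension = NULL) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (!inherits(tree, "phylo")) stop("tree must be a phylo object or Newick string")
  if (is.null(tree$edge.length)) stop("species tree needs branch lengths (coalescent units)")
  if (any(tree$edge.length < 0)) stop("branch lengths must be non-negative")
  # the basal node is taken as the root divergence; a basal polytomy models
  # simultaneous divergence (e.g. the star phylogeny), so ape::is.rooted's
  # degree-2 requirement is deliberately not enforced
  if (theta < 0) stop("theta must be non-negative")
  if (!is.null(tip_extension)) {
    if (is.null(names(tip_extension)) ||
        !all(names(tip_extension) %in% tree$tip.label))
      stop("tip_extension must be named by tip labels present in the tree")
    if (any(tip_extension < 0)) stop("tip extensions must be non-negative")
  }
  structure(list(tree = tree, theta = theta, tip_extension = tip_extension),
            class = "species_tree_model")
}

#' @export
print.species_tree_model <- function(x, ...) {
  cat("Species tree model (", length(x$tree$tip.label), " tips, theta = ",
      x$theta, ")\n", sep = "")
  cat("  ", ape::write.tree(x$tree), "\n", sep = "")
  if (!is.null(x$tip_extension))
    cat("  pendant extensions (coalescent units): ",
        paste(names(x$tip_extension), x$tip_extension,
              sep = "+", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Built-in four-taxon study trees
#'
#' The clock species trees used throughout the simulation studies, plus a
#' star phylogeny. `long_asym` is the caterpillar
#' `(A:3.0,(B:2.0,(C:1.0,D:1.0):1.0));` (root on tip A's branch, position
#' 1), `long_sym` is the balanced `((A:0.8,B:0.8):2.2,(C:1.2,D:1.2):1.8);`
#' (symmetric rooting, position 5); the `short_*` variants have every
#' branch length halved. `star` is a simultaneous divergence of the four
#' tips at depth 1.0 with no root branch to identify.
#'
#' @param name one of `"long_asym"`, `"long_sym"`, `"short_asym"`,
#'   `"short_sym"`, `"star"`.
#' @param theta population-scaled mutation rate (default 0.05).
#' @param tip_extension see [species_tree_model()].
#' @return a `species_tree_model`.
#' @export
preset_species_tree <- function(name = c("long_asym", "long_sym",
                                         "short_asym", "short_sym", "star"),
                                theta = 0.05, tip_extension = NULL) {
  name <- match.arg(name)
  nwk <- switch(name,
    long_asym  = "(A:3.0,(B:2.0,(C:1.0,D:1.0):1.0):1.0);",
    long_sym   = "((A:0.8,B:0.8):2.2,(C:1.2,D:1.2):1.8);",
    short_asym = "(A:1.5,(B:1.0,(C:0.5,D:0.5):0.5):0.5);",
    short_sym  = "((A:0.4,B:0.4):1.1,(C:0.6,D:0.6):0.9);",
    star       = "(A:1.0,B:1.0,C:1.0,D:1.0);")
  species_tree_model(nwk, theta = theta, tip_extension = tip_extension)
}

## Node ages (time before present) for a rooted phylo. Tips of an
## ultrametric tree get age 0; for safety, ages are measured from the
## deepest tip.
.node_ages <- function(tree) {
  n_all <- ape::Ntip(tree) + tree$Nnode
  depth <- numeric(n_all)
  root <- ape::Ntip(tree) + 1L
  # preorder: parents before children
  ord <- rev(ape::postorder(tree))
  for (e in ord) {
    depth[tree$edge[e, 2L]] <- depth[tree$edge[e, 1L]] + tree$edge.length[e]
  }
  max(depth[seq_len(ape::Ntip(tree))]) - depth
}

## Vectorised multispecies-coalescent engine.
##
## Simulates nsim independent gene genealogies for one haploid lineage per
## species along a rooted species tree with branch lengths in coalescent
## units. Populations (species-tree branches) are visited tips-to-root;
## within a population, each pair of lineages coalesces at rate 1, i.e.
## with k lineages the waiting time to the next event is Exp(k(k-1)/2);
## lineages surviving at the top of a branch enter the parent population;
## all remaining lineages coalesce in the root population.
##
## Gene-tree nodes are numbered 1..ntip for tips and ntip+1 .. 2*ntip-1 in
## order of coalescence (the root is always 2*ntip-1), so every parent has
## a larger index than its children.
##
## Returns list(parent, blen, age): nsim x (2*ntip-1) matrices; parent of
## the root is 0; blen is in coalescent units.
.msc_engine <- function(tree, nsim) {
  ntip <- ape::Ntip(tree)
  nnode_g <- 2L * ntip - 1L
  ages <- .node_ages(tree)
  parent_sp <- integer(ntip + tree$Nnode)
  parent_sp[tree$edge[, 2L]] <- tree$edge[, 1L]
  root_sp <- ape::Ntip(tree) + 1L

  P <- matrix(0L, nsim, nnode_g)
  B <- matrix(0, nsim, nnode_g)
  birth <- matrix(0, nsim, nnode_g)
  for (tp in seq_len(ntip)) birth[, tp] <- ages[tp]
  nextid <- rep.int(ntip + 1L, nsim)

  # surviving lineages leaving each species node's population
  surv <- vector("list", ntip + tree$Nnode)

  # process species nodes children-before-parents
  node_order <- unique(tree$edge[ape::postorder(tree), 2L])
  node_order <- c(node_order, root_sp)
  for (v in node_order) {
    if (v <= ntip) {
      L <- matrix(v, nsim, 1L)
    } else {
      kids <- tree$edge[tree$edge[, 1L] == v, 2L]
      L <- do.call(cbind, surv[kids])
      surv[kids] <- list(NULL)
      # compact non-NA entries to the left of each row
      if (anyNA(L)) {
        idx <- which(!is.na(L), arr.ind = TRUE)
        o <- order(idx[, 1L], idx[, 2L])
        r <- idx[o, 1L]
        cnt <- tabulate(r, nbins = nsim)
        Lc <- matrix(NA_integer_, nsim, max(cnt))
        Lc[cbind(r, sequence(cnt[cnt > 0L]))] <- L[idx[o, , drop = FALSE]]
        L <- Lc
      }
    }
    k <- rowSums(!is.na(L))
    tcur <- rep.int(ages[v], nsim)
    tend <- if (v == root_sp) Inf else ages[parent_sp[v]]
    repeat {
      act <- which(k >= 2L & tcur < tend)
      if (!length(act)) break
      ka <- k[act]
      tnew <- tcur[act] + stats::rexp(length(act)) / (ka * (ka - 1) / 2)
      coal <- tnew < tend
      ic <- act[coal]
      if (length(ic)) {
        kc <- k[ic]
        tc <- tnew[coal]
        # uniform unordered pair among the first kc lineage slots
        a <- 1L + floor(stats::runif(length(ic)) * kc)
        b <- 1L + floor(stats::runif(length(ic)) * (kc - 1L))
        b <- b + (b >= a)
        lo <- pmin(a, b); hi <- pmax(a, b)
        id <- nextid[ic]
        nextid[ic] <- id + 1L
        ca <- L[cbind(ic, lo)]; cb <- L[cbind(ic, hi)]
        P[cbind(ic, ca)] <- id
        P[cbind(ic, cb)] <- id
        B[cbind(ic, ca)] <- tc - birth[cbind(ic, ca)]
        B[cbind(ic, cb)] <- tc - birth[cbind(ic, cb)]
        birth[cbind(ic, id)] <- tc
        lastv <- L[cbind(ic, kc)]
        L[cbind(ic, lo)] <- id
        L[cbind(ic, hi)] <- lastv
        L[cbind(ic, kc)] <- NA_integer_
        k[ic] <- kc - 1L
        tcur[ic] <- tc
      }
      ino <- act[!coal]
      if (length(ino)) tcur[ino] <- tend
    }
    # lineages surviving to the top of this branch enter the parent
    # population; their branch lengths are closed only at coalescence
    # (B = coalescence time - birth time), so nothing accrues here
    if (is.finite(tend)) surv[[v]] <- L
  }
  list(parent = P, blen = B, age = birth, ntip = ntip)
}

#' Simulate gene trees under the multispecies coalescent
#'
#' Draws `n` independent gene genealogies (one haploid lineage per species)
#' along the model's species tree, and converts branch lengths to the
#' mutation scale (`coalescent length * theta / 2`, plus any pendant tip
#' extensions).
#'
#' @param model a [species_tree_model()].
#' @param n number of gene trees.
#' @return object of class `gene_tree_set`: matrices `parent` and `blen`
#'   (coalescent units) and `blen_mut` (mutation scale), each `n` rows by
#'   `2*ntip - 1` gene-tree nodes, plus `taxa` and the `model`. Individual
#'   trees are extracted with [gene_tree()].
#' @examples
#' gts <- simulate_gene_trees(preset_species_tree("long_sym"), 10)
#' gene_tree(gts, 1)
#' @export
simulate_gene_trees <- function(model, n) {
  stopifnot(inherits(model, "species_tree_model"), n >= 1)
  sim <- .msc_engine(model$tree, as.integer(n))
  out <- list(parent = sim$parent, blen = sim$blen,
              blen_mut = to_mutation_scale_matrix(sim$blen, model),
              ntip = sim$ntip, taxa = model$tree$tip.label, model = model)
  class(out) <- "gene_tree_set"
  out
}

## mutation-scale branch lengths: x theta/2, plus tip extensions on pendant
## branches (extension is in coalescent units, converted the same way).
to_mutation_scale_matrix <- function(blen, model) {
  m <- blen * model$theta / 2
  if (!is.null(model$tip_extension)) {
    tips <- match(names(model$tip_extension), model$tree$tip.label)
    for (i in seq_along(tips))
      m[, tips[i]] <- m[, tips[i]] + model$tip_extension[i] * model$theta / 2
  }
  m
}

#' Convert a gene tree (set) to the mutation scale
#'
#' Multiplies coalescent-unit branch lengths by `theta / 2` and adds any
#' pendant tip extensions. `gene_tree_set` objects already carry both
#' scales; this recomputes `blen_mut` (e.g. after changing `theta`).
#'
#' @param gts a `gene_tree_set`.
#' @param model a `species_tree_model` supplying `theta` and extensions
#'   (defaults to the set's own model).
#' @return the `gene_tree_set` with updated `blen_mut`.
#' @export
to_mutation_scale <- function(gts, model = gts$model) {
  stopifnot(inherits(gts, "gene_tree_set"))
  gts$blen_mut <- to_mutation_scale_matrix(gts$blen, model)
  gts$model <- model
  gts
}

#' Extract one gene tree as a phylo object
#'
#' @param gts a `gene_tree_set`.
#' @param i index of the gene tree.
#' @param scale `"coalescent"` or `"mutation"` branch lengths.
#' @return an `ape` `phylo`.
#' @export
gene_tree <- function(gts, i = 1L, scale = c("coalescent", "mutation")) {
  stopifnot(inherits(gts, "gene_tree_set"))
  scale <- match.arg(scale)
  ntip <- gts$ntip
  nnode_g <- 2L * ntip - 1L
  par <- gts$parent[i, ]
  bl <- if (scale == "coalescent") gts$blen[i, ] else gts$blen_mut[i, ]
  # remap internal ids so the root is ntip+1 (ape convention)
  remap <- function(x) ifelse(x > ntip, 3L * ntip - x, x)
  child <- seq_len(nnode_g - 1L)
  edge <- cbind(remap(par[child]), remap(child))
  phy <- list(edge = edge, edge.length = bl[child],
              tip.label = gts$taxa, Nnode = ntip - 1L)
  class(phy) <- "phylo"
  ape::reorder.phylo(phy, "cladewise")
}

#' Simulate a single gene tree
#'
#' Convenience wrapper around [simulate_gene_trees()] returning one `phylo`.
#'
#' @inheritParams simulate_gene_trees
#' @param scale branch-length scale of the returned tree.
#' @return an `ape` `phylo`.
#' @export
simulate_gene_tree <- function(model, scale = c("coalescent", "mutation")) {
  gene_tree(simulate_gene_trees(model, 1L), 1L, scale = match.arg(scale))
}

#' @export
print.gene_tree_set <- function(x, ...) {
  cat("Gene tree set:", nrow(x$parent), "coalescent genealogies,",
      x$ntip, "tips\n")
  cat("  taxa:", paste(x$taxa, collapse = ", "),
      "| theta =", x$model$theta, "\n")
  invisible(x)
}

#' Write gene trees to a Newick file
#'
#' @param gts a `gene_tree_set`.
#' @param file output path (or `""` for stdout).
#' @param scale branch-length scale.
#' @return invisibly, the Newick strings.
#' @export
write_gene_trees <- function(gts, file = "",
                             scale = c("coalescent", "mutation")) {
  scale <- match.arg(scale)
  nwk <- vapply(seq_len(nrow(gts$parent)),
                function(i) ape::write.tree(gene_tree(gts, i, scale)),
                character(1))
  if (!identical(file, "")) writeLines(nwk, file) else cat(nwk, sep = "\n")
  invisible(nwk)
}

#' Simulate from a species-tree model
#'
#' `simulate()` method drawing gene trees (default) or a
#' coalescent-independent-sites alignment from the model.
#'
#' @param object a `species_tree_model`.
#' @param nsim number of gene trees or sites.
#' @param seed optional seed, applied with `set.seed()`.
#' @param what `"gene_trees"` or `"cis"`.
#' @param subst substitution model for `what = "cis"`
#'   (default JC69).
#' @param ... unused.
#' @return a `gene_tree_set` or an alignment matrix (see [simulate_cis()]).
#' @export
simulate.species_tree_model <- function(object, nsim = 1, seed = NULL,
                                        what = c("gene_trees", "cis"),
                                        subst = substitution_model("JC69"),
                                        ...) {
  if (!is.null(seed)) set.seed(seed)
  what <- match.arg(what)
  switch(what,
         gene_trees = simulate_gene_trees(object, nsim),
         cis = simulate_cis(object, subst, nsim))
}
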