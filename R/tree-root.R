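#' Code the branches of an unrooted species tree
#'
#' Wraps an unrooted topology with a deterministic code per branch so that
#' root scores are comparable across runs. Each branch is identified by its
#' tip bipartition; the canonical side of a bipartition is the side *not*
#' containing the alphabetically first tip, and branches are coded `b01`,
#' `b02`, ... in order of (canonical-side size, labels). Rooted input is
#' unrooted first; polytomies are kept.
#'
#' @param tree a `phylo`, a `coded_tree` (returned unchanged), or a Newick
#'   string.
#' @return object of class `coded_tree`: the unrooted `phylo`, per-edge
#'   `codes` and `bipartitions` (aligned with `phylo$edge` rows), and an
#'   adjacency index for path queries.
#' @export
coded_tree <- function(tree) {
  if (inherits(tree, "coded_tree")) return(tree)
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  stopifnot(inherits(tree, "phylo"))
  if (ape::Ntip(tree) < 4L) stop("need at least 4 tips")
  if (ape::is.rooted(tree)) tree <- ape::unroot(tree)
  tree <- ape::collapse.singles(tree)
  ntip <- ape::Ntip(tree)
  nedge <- nrow(tree$edge)
  labels <- tree$tip.label
  ref <- labels[order(labels)][1L]

  # tip set below each edge (child side), via postorder accumulation
  below <- vector("list", ntip + tree$Nnode)
  for (tp in seq_len(ntip)) below[[tp]] <- tp
  for (e in ape::postorder(tree)) {
    p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  bip <- character(nedge)
  for (e in seq_len(nedge)) {
    side <- sort(labels[below[[tree$edge[e, 2L]]]])
    if (ref %in% side) side <- sort(setdiff(labels, side))
    bip[e] <- paste(side, collapse = "+")
  }
  sz <- lengths(strsplit(bip, "+", fixed = TRUE))
  ord <- order(sz, bip)
  codes <- character(nedge)
  codes[ord] <- sprintf("b%02d", seq_len(nedge))

  # adjacency: per node, matrix of (neighbour, edge index)
  n_all <- ntip + tree$Nnode
  adj <- vector("list", n_all)
  for (e in seq_len(nedge)) {
    a <- tree$edge[e, 1L]; b <- tree$edge[e, 2L]
    adj[[a]] <- rbind(adj[[a]], c(b, e))
    adj[[b]] <- rbind(adj[[b]], c(a, e))
  }
  structure(list(phylo = tree, codes = codes, bipartitions = bip, adj = adj),
            class = "coded_tree")
}

#' @export
print.coded_tree <- function(x, ...) {
  cat("Coded unrooted tree:", ape::Ntip(x$phylo), "tips,",
      nrow(x$phylo$edge), "branches\n")
  df <- data.frame(code = x$codes, bipartition = x$bipartitions)
  print(df[order(df$code), ], row.names = FALSE)
  invisible(x)
}

## node path between two nodes (BFS); returns the node sequence from x to y
.node_path <- function(ct, x, y) {
  if (x == y) return(x)
  prev <- integer(length(ct$adj))
  prev[x] <- -1L
  queue <- x
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    nb <- ct$adj[[v]]
    for (i in seq_len(nrow(nb))) {
      w <- nb[i, 1L]
      if (prev[w] == 0L) {
        prev[w] <- v
        if (w == y) {
          path <- w
          while (path[1L] != x) path <- c(prev[path[1L]], path)
          return(path)
        }
        queue <- c(queue, w)
      }
    }
  }
  stop("nodes not connected")
}

## edge indices along a node path
.path_edges <- function(ct, path) {
  if (length(path) < 2L) return(integer(0))
  out <- integer(length(path) - 1L)
  for (i in seq_len(length(path) - 1L)) {
    nb <- ct$adj[[path[i]]]
    out[i] <- nb[match(path[i + 1L], nb[, 1L]), 2L]
  }
  out
}

#' Enumerate (or sample) species quartets
#'
#' All `choose(n, 4)` four-tip subsets, or a uniform random sample without
#' replacement of `max_quartets` of them.
#'
#' @param tree a `coded_tree`, `phylo`, or Newick string.
#' @param max_quartets `NULL` (exhaustive) or a sample size.
#' @param seed optional seed for reproducible sampling.
#' @return list of character 4-vectors (sorted tip labels).
#' @export
enumerate_quartets <- function(tree, max_quartets = NULL, seed = NULL) {
  ct <- coded_tree(tree)
  tips <- sort(ct$phylo$tip.label)
  n <- length(tips)
  if (n < 4L) stop("need at least 4 tips")
  all_q <- utils::combn(tips, 4L, simplify = FALSE)
  if (!is.null(max_quartets) && max_quartets < length(all_q)) {
    if (!is.null(seed)) set.seed(seed)
    all_q <- all_q[sample.int(length(all_q), max_quartets)]
  }
  all_q
}

#' Map a quartet's five branches onto the full tree
#'
#' The subtree spanned by four tips consists of five paths: one from each
#' tip to its junction node, and one internal path between the two
#' junctions. This resolves the induced quartet split, orients the tips as
#' (a, b, c, d) with split \{a,b\}|\{c,d\} (alphabetical within and between
#' pairs), and returns the full-tree branch codes lying on each of the five
#' paths, in root-position order (pendant a, b, c, d, internal).
#'
#' @param tree a `coded_tree` (or coercible).
#' @param quartet character vector of 4 distinct tip labels.
#' @return list with `taxa` (the oriented a, b, c, d), `sets` (list of 5
#'   code vectors), `n` (set sizes), `resolved` (FALSE when the quartet is
#'   unresolved, e.g. at a polytomy, in which case `sets` is `NULL`).
#' @export
map_quartet_branches <- function(tree, quartet) {
  ct <- coded_tree(tree)
  if (length(quartet) != 4L || anyDuplicated(quartet))
    stop("quartet must be 4 distinct tip labels")
  idx <- match(quartet, ct$phylo$tip.label)
  if (anyNA(idx))
    stop("tips not in tree: ",
         paste(quartet[is.na(idx)], collapse = ", "))
  quartet <- sort(quartet)
  idx <- match(quartet, ct$phylo$tip.label)
  pairings <- list(c(1L, 2L, 3L, 4L), c(1L, 3L, 2L, 4L), c(1L, 4L, 2L, 3L))
  paths <- list()
  split <- NULL
  for (pg in pairings) {
    p1 <- .node_path(ct, idx[pg[1L]], idx[pg[2L]])
    p2 <- .node_path(ct, idx[pg[3L]], idx[pg[4L]])
    e1 <- .path_edges(ct, p1); e2 <- .path_edges(ct, p2)
    if (!length(intersect(e1, e2))) {
      if (!is.null(split)) return(list(taxa = quartet, sets = NULL,
                                       n = NULL, resolved = FALSE))
      split <- pg
    }
  }
  if (is.null(split)) return(list(taxa = quartet, sets = NULL,
                                  n = NULL, resolved = FALSE))
  a <- idx[split[1L]]; b <- idx[split[2L]]
  c_ <- idx[split[3L]]; d <- idx[split[4L]]
  # junction u joins a,b; junction v joins c,d
  p_ab <- .node_path(ct, a, b)
  p_ac <- .node_path(ct, a, c_)
  common <- p_ab[p_ab %in% p_ac]
  u <- common[length(common)]
  p_cd <- .node_path(ct, c_, d)
  p_ca <- rev(p_ac)
  common2 <- p_cd[p_cd %in% p_ca]
  v <- common2[length(common2)]
  seg <- function(x, y) ct$codes[.path_edges(ct, .node_path(ct, x, y))]
  sets <- list(seg(a, u), seg(b, u), seg(c_, v), seg(d, v), seg(u, v))
  list(taxa = ct$phylo$tip.label[c(a, b, c_, d)], sets = sets,
       n = lengths(sets), resolved = TRUE)
}

#' Per-branch score increments for one tested quartet
#'
#' A conclusive quartet places the root on one of its five branches; every
#' full-tree branch on that path receives `1 / n_i` (so the quartet
#' contributes total score 1), all other branches 0. Inconclusive results
#' contribute nothing.
#'
#' @param map a [map_quartet_branches()] result (must be resolved).
#' @param result a `quartet_root_test` fitted with rows ordered as
#'   `map$taxa`.
#' @return named numeric vector of increments (only non-zero entries).
#' @export
score_quartet <- function(map, result) {
  stopifnot(isTRUE(map$resolved))
  pos <- if (inherits(result, "quartet_root_test")) result$position else result
  if (is.na(pos)) return(stats::setNames(numeric(0), character(0)))
  codes <- map$sets[[pos]]
  if (!length(codes)) return(stats::setNames(numeric(0), character(0)))
  stats::setNames(rep.int(1 / length(codes), length(codes)), codes)
}

#' Bonferroni-corrected per-test significance level
#'
#' Dividing each test's level by the number of quartets evaluated controls
#' the familywise error rate over the correlated quartet tests.
#'
#' @param alpha per-test level before correction.
#' @param n_quartets number of quartets actually evaluated.
#' @return `alpha / n_quartets`.
#' @export
bonferroni_level <- function(alpha, n_quartets) {
  stopifnot(n_quartets >= 1)
  alpha / n_quartets
}

#' Root an unrooted species tree from site pattern frequencies
#'
#' Evaluates the quartet rooting test on every sampled four-tip subset of
#' the tree, accumulates weighted branch scores (see [score_quartet()]),
#' and selects the branch with the highest total score as the root branch.
#' The returned rooted tree places the root at the midpoint of the winning
#' branch. With `bonferroni = TRUE` (default) each test runs at level
#' `alpha_k / n_quartets`.
#'
#' @param aln alignment: character matrix (taxa x sites) or a file path
#'   readable by [read_alignment()]. Must cover all tree tips.
#' @param tree unrooted species tree: `coded_tree`, `phylo`, Newick string
#'   or file path.
#' @param alpha1,alpha2 per-test levels before Bonferroni correction.
#' @param bonferroni apply the correction (default `TRUE`).
#' @param max_quartets `NULL` for all `choose(n, 4)` quartets, or a sample
#'   size.
#' @param seed seed for quartet sampling.
#' @return object of class `coalroot`: branch score table (`scores`),
#'   `selected_codes`, `status` (`"rooted"`, `"ambiguous"` on score ties,
#'   `"inconclusive"` when no quartet was conclusive), the `rooted_tree`
#'   (`phylo`, `NULL` unless status is `"rooted"`), per-quartet records,
#'   and the settings used.
#' @examples
#' m <- preset_species_tree("long_asym")
#' aln <- simulate_cis(m, substitution_model("JC69"), 2000)
#' fit <- root_tree(aln, "(A,(B,(C,D)));")
#' fit
#' @export
root_tree <- function(aln, tree, alpha1 = 0.025, alpha2 = 0.025,
                      bonferroni = TRUE, max_quartets = NULL, seed = NULL) {
  if (is.character(aln) && length(aln) == 1L) aln <- read_alignment(aln)
  if (is.character(tree) && length(tree) == 1L && file.exists(tree))
    tree <- read_species_tree(tree)
  ct <- coded_tree(tree)
  tips <- ct$phylo$tip.label
  miss <- setdiff(tips, rownames(aln))
  if (length(miss))
    stop("tree tips missing from alignment: ", paste(miss, collapse = ", "))

  quartets <- enumerate_quartets(ct, max_quartets = max_quartets, seed = seed)
  nq <- length(quartets)
  a1 <- if (bonferroni) bonferroni_level(alpha1, nq) else alpha1
  a2 <- if (bonferroni) bonferroni_level(alpha2, nq) else alpha2

  scores <- stats::setNames(numeric(length(ct$codes)), ct$codes)
  records <- vector("list", nq)
  n_conclusive <- n_inconclusive <- n_skipped <- 0L
  for (i in seq_len(nq)) {
    map <- map_quartet_branches(ct, quartets[[i]])
    if (!map$resolved) {
      n_skipped <- n_skipped + 1L
      records[[i]] <- list(taxa = quartets[[i]], status = "unresolved",
                           position = NA_integer_)
      next
    }
    tst <- quartet_root_test(aln[map$taxa, , drop = FALSE],
                             alpha1 = a1, alpha2 = a2)
    if (tst$status == "conclusive") {
      inc <- score_quartet(map, tst)
      scores[names(inc)] <- scores[names(inc)] + inc
      n_conclusive <- n_conclusive + 1L
    } else {
      n_inconclusive <- n_inconclusive + 1L
    }
    records[[i]] <- list(taxa = map$taxa, status = tst$status,
                         position = tst$position,
                         z1 = tst$z1, z2 = tst$z2)
  }

  top <- max(scores)
  selected <- if (top > 0) names(scores)[scores == top] else character(0)
  status <- if (!length(selected)) "inconclusive"
    else if (length(selected) > 1L) "ambiguous" else "rooted"
  rooted <- if (status == "rooted") .reroot_on_code(ct, selected) else NULL

  score_df <- data.frame(branch_code = ct$codes,
                         bipartition = ct$bipartitions,
                         score = unname(scores[ct$codes]))
  score_df <- score_df[order(score_df$branch_code), ]
  rownames(score_df) <- NULL

  structure(list(scores = score_df, selected_codes = selected,
                 status = status, rooted_tree = rooted,
                 quartets = records,
                 n_quartets = nq, n_conclusive = n_conclusive,
                 n_inconclusive = n_inconclusive, n_skipped = n_skipped,
                 alpha = c(alpha1 = alpha1, alpha2 = alpha2),
                 alpha_corrected = c(alpha1 = a1, alpha2 = a2),
                 bonferroni = bonferroni, seed = seed,
                 coded_tree = ct),
            class = "coalroot")
}

## root the coded tree at the midpoint of the branch with the given code
.reroot_on_code <- function(ct, code) {
  e <- match(code, ct$codes)
  phy <- ct$phylo
  if (is.null(phy$edge.length)) {
    phy$edge.length <- rep.int(1, nrow(phy$edge))
  }
  child <- phy$edge[e, 2L]
  phytools::reroot(phy, node.number = child,
                   position = phy$edge.length[e] / 2)
}

#' @export
print.coalroot <- function(x, ...) {
  cat("\n\tCoalescent rooting of an unrooted species tree\n\n")
  cat("quartets evaluated:", x$n_quartets,
      "| conclusive:", x$n_conclusive,
      "| inconclusive:", x$n_inconclusive,
      if (x$n_skipped > 0) paste("| unresolved:", x$n_skipped), "\n")
  cat(sprintf("per-test levels: %.3g / %.3g%s\n",
              x$alpha_corrected[1], x$alpha_corrected[2],
              if (x$bonferroni) " (Bonferroni-corrected)" else ""))
  if (x$status == "rooted") {
    sel <- x$scores[x$scores$branch_code == x$selected_codes, ]
    cat(sprintf("root branch: %s (%s), score %.3f of %d\n",
                sel$branch_code, sel$bipartition, sel$score, x$n_conclusive))
  } else if (x$status == "ambiguous") {
    cat("ambiguous root: tied branches",
        paste(x$selected_codes, collapse = ", "), "\n")
  } else {
    cat("no conclusive quartets; root undetermined\n")
  }
  invisible(x)
}

#' @export
summary.coalroot <- function(object, ...) {
  out <- object
  class(out) <- c("summary.coalroot", class(object))
  out
}

#' @export
print.summary.coalroot <- function(x, ...) {
  print.coalroot(x, ...)
  cat("\nBranch score table:\n")
  print(x$scores, row.names = FALSE)
  if (!is.null(x$rooted_tree))
    cat("\nrooted tree:", ape::write.tree(x$rooted_tree), "\n")
  invisible(x)
}

#' Plot a rooting fit
#'
#' Draws the unrooted input tree with each branch labelled by its
#' accumulated root score; the selected root branch is highlighted.
#'
#' @param x a `coalroot` fit.
#' @param ... passed to [ape::plot.phylo()].
#' @return `x`, invisibly.
#' @export
plot.coalroot <- function(x, ...) {
  phy <- x$coded_tree$phylo
  sc <- stats::setNames(x$scores$score, x$scores$branch_code)
  edge_scores <- sc[x$coded_tree$codes]
  col <- ifelse(x$coded_tree$codes %in% x$selected_codes, "red", "black")
  ape::plot.phylo(phy, type = "unrooted", edge.color = col, ...)
  ape::edgelabels(text = sprintf("%.2f", edge_scores), frame = "none",
                  col = col, cex = 0.7)
  invisible(x)
}

#' Write the branch score table to TSV
#'
#' Columns: `branch_code`, `bipartition`, `score`.
#'
#' @param fit a `coalroot` fit.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_score_table <- function(fit, path) {
  stopifnot(inherits(fit, "coalroot"))
  utils::write.table(fit$scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
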