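## true generating root position of a 4-taxon species tree model, in the
## tip-label (A,B,C,D) orientation: a single tip on one side of the root
## gives that tip's pendant position; a 2-2 split (or a star) gives the
## symmetric position 5.
true_root_position <- function(model) {
  tree <- model$tree
  ntip <- ape::Ntip(tree)
  stopifnot(ntip == 4L)
  root <- ntip + 1L
  kids <- tree$edge[tree$edge[, 1L] == root, 2L]
  if (length(kids) > 2L) return(5L)  # star / root polytomy
  tip_kids <- kids[kids <= ntip]
  if (length(tip_kids) == 1L)
    return(match(tree$tip.label[tip_kids], sort(tree$tip.label)))
  5L
}

#' Power study for quartet rooting
#'
#' Repeatedly simulates four-taxon data from a species-tree model, applies
#' [quartet_root_test()], and records the proportion of replicates calling
#' the generating root position (position 5 for star trees). Conditions
#' are crossed over data sizes (and, via [nonclock_power_curve()], pendant
#' branch extensions).
#'
#' @param model a 4-taxon [species_tree_model()] (or a preset name for
#'   [preset_species_tree()]).
#' @param subst a [substitution_model()] (default JC69).
#' @param sizes vector of data sizes: number of coalescent independent
#'   sites (`mode = "cis"`) or number of loci (`mode = "multilocus"`).
#' @param mode `"cis"` or `"multilocus"`.
#' @param locus_length sites per locus for multilocus mode (default 500).
#' @param reps replicates per condition (default 500).
#' @param alpha1,alpha2 per-test significance levels.
#' @param seed optional seed.
#' @return object of class `power_study`: a data.frame with one row per
#'   condition (`size`, `n_correct`, `n_reps`, `power`, binomial 95%
#'   confidence limits `ci_lo`, `ci_hi`) plus the settings as attributes.
#' @examples
#' run_power_study("long_asym", sizes = 2000, reps = 20, seed = 1)
#' @export
run_power_study <- function(model, subst = substitution_model("JC69"),
                            sizes = c(5000, 10000, 20000, 100000),
                            mode = c("cis", "multilocus"),
                            locus_length = 500L, reps = 500L,
                            alpha1 = 0.025, alpha2 = 0.025, seed = NULL) {
  if (is.character(model)) model <- preset_species_tree(model)
  stopifnot(inherits(model, "species_tree_model"), reps >= 1, all(sizes >= 1))
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  truth <- true_root_position(model)
  # alignment rows must be in the canonical A,B,C,D label order
  row_order <- order(model$tree$tip.label)

  res <- lapply(sizes, function(sz) {
    correct <- 0L
    for (r in seq_len(reps)) {
      aln <- if (mode == "cis") simulate_cis(model, subst, sz)
             else simulate_multilocus(model, subst, sz, locus_length)
      tst <- quartet_root_test(aln[row_order, , drop = FALSE],
                               alpha1 = alpha1, alpha2 = alpha2)
      if (!is.na(tst$position) && tst$position == truth)
        correct <- correct + 1L
    }
    ci <- stats::binom.test(correct, reps)$conf.int
    data.frame(size = sz, n_correct = correct, n_reps = reps,
               power = correct / reps, ci_lo = ci[1L], ci_hi = ci[2L])
  })
  out <- do.call(rbind, res)
  attr(out, "mode") <- mode
  attr(out, "truth") <- truth
  attr(out, "alpha") <- c(alpha1, alpha2)
  attr(out, "locus_length") <- if (mode == "multilocus") locus_length else NA
  class(out) <- c("power_study", class(out))
  out
}

#' @export
print.power_study <- function(x, ...) {
  cat("Rooting power study (", attr(x, "mode"), " mode, true position ",
      attr(x, "truth"), ")\n", sep = "")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Power under molecular-clock violation
#'
#' Extends the pendant branch of one tip (on the mutation scale, after the
#' coalescent draw) and measures rooting power at each extension level.
#' An `extension` value `e` lengthens the tip's path by `e - 1` coalescent
#' units, so `e = 1` reproduces the clock scenario; the study levels are
#' 1.1 to 1.5.
#'
#' @param model 4-taxon clock [species_tree_model()] or preset name.
#' @param tip label of the tip whose branch is extended (e.g. `"A"` or
#'   `"C"`).
#' @param extensions extension levels (default `seq(1.1, 1.5, by = 0.1)`).
#' @inheritParams run_power_study
#' @return a `power_study` data.frame with one row per
#'   size-by-extension condition (extra column `extension`).
#' @export
nonclock_power_curve <- function(model, tip = "A",
                                 extensions = seq(1.1, 1.5, by = 0.1),
                                 subst = substitution_model("JC69"),
                                 sizes = c(5000, 10000, 20000, 100000),
                                 reps = 500L, alpha1 = 0.025, alpha2 = 0.025,
                                 seed = NULL) {
  if (is.character(model)) model <- preset_species_tree(model)
  stopifnot(all(extensions >= 1))
  if (!is.null(seed)) set.seed(seed)
  res <- lapply(extensions, function(e) {
    m <- species_tree_model(model$tree, theta = model$theta,
                            tip_extension =
                              if (e > 1) stats::setNames(e - 1, tip) else NULL)
    tab <- run_power_study(m, subst = subst, sizes = sizes, mode = "cis",
                           reps = reps, alpha1 = alpha1, alpha2 = alpha2)
    tab$extension <- e
    tab
  })
  out <- do.call(rbind, res)
  attr(out, "mode") <- "cis"
  attr(out, "truth") <- true_root_position(model)
  attr(out, "tip") <- tip
  class(out) <- c("power_study", "data.frame")
  out
}
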