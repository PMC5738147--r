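test_that("coded trees expose deterministic branch codes", {
  ct <- coded_tree("(A,(B,(C,D)));")
  expect_identical(ape::Ntip(ct$phylo), 4L)
  expect_identical(nrow(ct$phylo$edge), 5L)  # 4 pendant + 1 internal
  expect_identical(sort(ct$codes), sprintf("b%02d", 1:5))
  # codes are stable under a different newick rotation of the same topology
  ct2 <- coded_tree("(((D,C),B),A);")
  expect_identical(sort(ct2$bipartitions), sort(ct$bipartitions))
  m1 <- setNames(ct$codes, ct$bipartitions)
  m2 <- setNames(ct2$codes, ct2$bipartitions)
  expect_identical(m1[sort(names(m1))], m2[sort(names(m2))])
})

test_that("newick round trip preserves the bipartition set", {
  nwk <- "((A:1,B:1):1,(C:1,(D:1,E:1):1):1);"
  tmp <- tempfile(fileext = ".nwk")
  ct <- read_species_tree(text = nwk)
  write_species_tree(ct, tmp)
  ct2 <- read_species_tree(tmp)
  expect_identical(sort(ct$bipartitions), sort(ct2$bipartitions))
  expect_error(suppressWarnings(read_species_tree(text = "(A,(B,C")))
})

test_that("quartet enumeration is exhaustive or a seeded uniform sample", {
  t8 <- ape::rtree(8, tip.label = LETTERS[1:8])
  expect_identical(length(enumerate_quartets(t8)), 70L)
  t6 <- ape::rtree(6, tip.label = LETTERS[1:6])
  expect_identical(length(enumerate_quartets(t6)), 15L)
  expect_identical(length(enumerate_quartets("(A,(B,(C,D)));")), 1L)
  s1 <- enumerate_quartets(t8, max_quartets = 10, seed = 7)
  s2 <- enumerate_quartets(t8, max_quartets = 10, seed = 7)
  expect_identical(s1, s2)
  expect_identical(length(s1), 10L)
  all_q <- enumerate_quartets(t8)
  expect_true(all(s1 %in% all_q))
})

test_that("quartet branch maps are disjoint paths covering the spanned subtree", {
  # 4-taxon tree: identity mapping, every set a single code
  ct4 <- coded_tree("(A,(B,(C,D)));")
  mp <- map_quartet_branches(ct4, c("A", "B", "C", "D"))
  expect_true(mp$resolved)
  expect_identical(mp$taxa, c("A", "B", "C", "D"))
  expect_identical(unname(mp$n), rep(1L, 5))
  expect_identical(sort(unlist(mp$sets)), sort(ct4$codes))

  # caterpillar: quartet {A,B,D,E} routes its internal path through C's node
  ct5 <- coded_tree("((((A,B),C),D),E);")
  mp5 <- map_quartet_branches(ct5, c("A", "B", "D", "E"))
  expect_true(mp5$resolved)
  expect_identical(mp5$taxa, c("A", "B", "D", "E"))
  expect_identical(unname(mp5$n), c(1L, 1L, 1L, 1L, 2L))
  expect_identical(length(unique(unlist(mp5$sets))), 6L)  # disjoint

  set.seed(51)
  for (r in 1:10) {
    tr <- ape::rtree(9, tip.label = LETTERS[1:9])
    ct <- coded_tree(tr)
    q <- sort(sample(LETTERS[1:9], 4))
    mp <- map_quartet_branches(ct, q)
    expect_true(mp$resolved)
    all_codes <- unlist(mp$sets)
    expect_identical(anyDuplicated(all_codes), 0L)  # disjoint sets
    expect_identical(unname(mp$n), unname(lengths(mp$sets)))
  }
  expect_error(map_quartet_branches(ct4, c("A", "A", "B", "C")), "distinct")
  expect_error(map_quartet_branches(ct4, c("A", "B", "C", "Z")), "not in tree")
})

test_that("quartet scores spread one unit over the selected path", {
  ct5 <- coded_tree("((((A,B),C),D),E);")
  mp5 <- map_quartet_branches(ct5, c("A", "B", "D", "E"))
  inc <- score_quartet(mp5, 5L)  # internal path: 2 codes at 0.5 each
  expect_identical(length(inc), 2L)
  expect_true(all(inc == 0.5))
  inc1 <- score_quartet(mp5, 1L)  # single pendant code scores 1
  expect_identical(length(inc1), 1L)
  expect_equal(unname(inc1), 1)
  expect_length(score_quartet(mp5, NA_integer_), 0)  # inconclusive
})

test_that("Bonferroni levels divide alpha by the number of quartets", {
  expect_equal(bonferroni_level(0.025, 70), 0.025 / 70)
  expect_equal(bonferroni_level(0.025, 1), 0.025)
  lv <- sapply(1:20, bonferroni_level, alpha = 0.025)
  expect_true(all(diff(lv) < 0))
  expect_error(bonferroni_level(0.025, 0))
})

test_that("rooting a quartet tree reduces to the single quartet test", {
  set.seed(52)
  m <- preset_species_tree("long_asym")
  aln <- simulate_cis(m, substitution_model("JC69"), 8000)
  fit <- root_tree(aln, "(A,(B,(C,D)));")
  tst <- quartet_root_test(aln)
  expect_identical(fit$n_quartets, 1L)
  expect_identical(fit$status, "rooted")
  # position 1 = pendant branch of A = bipartition B+C+D
  expect_identical(tst$position, 1L)
  sel <- fit$scores[fit$scores$branch_code == fit$selected_codes, ]
  expect_identical(sel$bipartition, "B+C+D")
})

test_that("total branch score equals the number of conclusive quartets", {
  set.seed(53)
  for (r in 1:3) {
    tr <- ape::rtree(6, tip.label = LETTERS[1:6])
    aln <- matrix(sample(c("A", "C", "G", "T"), 6 * 300, replace = TRUE),
                  nrow = 6, dimnames = list(LETTERS[1:6], NULL))
    fit <- root_tree(aln, tr, bonferroni = FALSE)
    expect_equal(sum(fit$scores$score), fit$n_conclusive)
    expect_identical(fit$n_conclusive + fit$n_inconclusive + fit$n_skipped,
                     fit$n_quartets)
  }
})

test_that("rerooting on the selected branch preserves the unrooted topology", {
  set.seed(54)
  m <- preset_species_tree("long_asym")
  aln <- simulate_cis(m, substitution_model("JC69"), 8000)
  fit <- root_tree(aln, "(A:3,(B:2,(C:1,D:1):1):1);")
  expect_identical(fit$status, "rooted")
  expect_true(ape::is.rooted(fit$rooted_tree))
  expect_equal(ape::dist.topo(ape::unroot(fit$rooted_tree),
                              ape::unroot(ape::read.tree(text = "(A,(B,(C,D)));"))),
               0, ignore_attr = TRUE)
})

test_that("simulated data recover the known root branch of an 8-taxon tree", {
  set.seed(55)
  nwk <- "(A:7,(B:6,(C:5,(D:4,(E:3,(F:2,(G:1,H:1):1):1):1):1):1):1);"
  m <- species_tree_model(nwk, theta = 0.05)
  aln <- simulate_cis(m, substitution_model("JC69"), 10000)
  fit <- root_tree(aln, ape::unroot(m$tree))
  expect_identical(fit$status, "rooted")
  sel <- fit$scores[fit$scores$branch_code == fit$selected_codes, ]
  # the true root lies on A's pendant branch (all other taxa on one side)
  expect_identical(sel$bipartition, "B+C+D+E+F+G+H")
  expect_equal(sum(fit$scores$score), fit$n_conclusive)
})

test_that("missing taxa are reported by name", {
  aln <- matrix("A", 3, 10, dimnames = list(c("A", "B", "C"), NULL))
  expect_error(root_tree(aln, "(A,(B,(C,D)));"), "D")
})

test_that("score tables are written as TSV", {
  set.seed(56)
  aln <- random_quartet_aln(500)
  fit <- root_tree(aln, "(A,(B,(C,D)));", bonferroni = FALSE)
  tmp <- tempfile(fileext = ".tsv")
  write_score_table(fit, tmp)
  tab <- read.delim(tmp)
  expect_identical(names(tab), c("branch_code", "bipartition", "score"))
  expect_identical(nrow(tab), 5L)
})
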