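test_that("category probabilities are observed frequencies", {
  expect_equal(unname(estimate_category_probs(c(10, 5, 0, 0, 85))),
               c(0.10, 0.05, 0, 0, 0.85))
  expect_equal(unname(estimate_category_probs(c(0, 0, 0, 0, 50))),
               c(0, 0, 0, 0, 1))
  set.seed(21)
  for (i in 1:5) {
    X <- rmultinom(1, 500, c(0.1, 0.1, 0.1, 0.1, 0.6))[, 1]
    expect_equal(sum(estimate_category_probs(X)), 1)
  }
  expect_error(estimate_category_probs(c(0, 0, 0, 0, 0)), "M = 0")
})

test_that("Z statistics match direct arithmetic on the variance formula", {
  z <- z_statistics(c(10, 5, 40, 30, 15))
  expect_equal(unname(z[1]), 0.05 / sqrt(0.1475 / 100), tolerance = 1e-12)
  z2 <- z_statistics(c(0, 0, 20, 0, 80))
  expect_equal(unname(z2[2]), 5)
  expect_equal(unname(z_statistics(c(7, 7, 3, 9, 74))[1]), 0)
  # both-zero convention
  expect_equal(unname(z_statistics(c(0, 0, 0, 0, 50))), c(0, 0))
})

test_that("Z statistics agree with the multinomial-covariance oracle to 1e-12", {
  set.seed(22)
  for (i in 1:50) {
    X <- rmultinom(1, sample(50:5000, 1),
                   c(0.12, 0.1, 0.11, 0.09, 0.58))[, 1]
    expect_equal(unname(z_statistics(X)), unname(oracle_z(X)),
                 tolerance = 1e-12)
  }
})

test_that("the decision table maps test outcomes to root positions", {
  cases <- list(
    list(z1 = 3.0, z2 = 0.5, pos = 1L),
    list(z1 = -3.0, z2 = 0.4, pos = 2L),
    list(z1 = 0.3, z2 = 3.0, pos = 3L),
    list(z1 = -0.3, z2 = -3.0, pos = 4L),
    list(z1 = 0.1, z2 = 0.2, pos = 5L),
    list(z1 = 3.0, z2 = -3.0, pos = NA_integer_))
  for (cs in cases) {
    r <- infer_root_position(cs$z1, cs$z2)
    expect_identical(r$position, cs$pos)
    expect_identical(r$status,
                     if (is.na(cs$pos)) "inconclusive" else "conclusive")
  }
  # two-sided critical value at alpha = 0.025
  r <- infer_root_position(0, 0)
  expect_equal(r$crit1, qnorm(1 - 0.025 / 2), tolerance = 1e-12)
})

test_that("every (z1, z2) pair yields exactly one outcome", {
  zs <- c(-5, -2.3, -1, 0, 1, 2.3, 5)
  for (z1 in zs) for (z2 in zs) {
    r <- infer_root_position(z1, z2)
    legal <- (r$reject1 && !r$reject2 && r$position %in% 1:2) ||
             (!r$reject1 && r$reject2 && r$position %in% 3:4) ||
             (!r$reject1 && !r$reject2 && identical(r$position, 5L)) ||
             (r$reject1 && r$reject2 && is.na(r$position))
    expect_true(legal)
    if (!is.na(r$position) && r$position == 1L) expect_gt(z1, 0)
    if (!is.na(r$position) && r$position == 2L) expect_lt(z1, 0)
    if (!is.na(r$position) && r$position == 3L) expect_gt(z2, 0)
    if (!is.na(r$position) && r$position == 4L) expect_lt(z2, 0)
  }
})

test_that("significance levels are configurable per test", {
  r <- infer_root_position(2.0, 2.0, alpha1 = 0.2, alpha2 = 0.001)
  expect_true(r$reject1)
  expect_false(r$reject2)
  expect_identical(r$position, 1L)
})

test_that("quartet_root_test composes counting, statistics and decision", {
  mk <- function(X) {
    cols <- c(rep(list(c("G", "A", "A", "A")), X[1]),
              rep(list(c("A", "G", "A", "A")), X[2]),
              rep(list(c("A", "A", "G", "A")), X[3]),
              rep(list(c("A", "A", "A", "G")), X[4]),
              rep(list(c("A", "A", "A", "A")), X[5]))
    m <- do.call(cbind, cols)
    rownames(m) <- c("A", "B", "C", "D")
    m
  }
  t1 <- quartet_root_test(mk(c(60, 0, 0, 0, 40)))
  expect_true(t1$reject1)
  expect_gt(t1$z1, 0)
  expect_false(t1$reject2)
  expect_identical(t1$position, 1L)

  t5 <- quartet_root_test(mk(c(0, 0, 0, 0, 100)))
  expect_equal(t5$z1, 0)
  expect_equal(t5$z2, 0)
  expect_identical(t5$position, 5L)

  t3 <- quartet_root_test(mk(c(0, 0, 30, 0, 70)))
  expect_identical(t3$position, 3L)
  expect_equal(t3$z2, 0.3 / sqrt(0.3 * 0.7 / 100), tolerance = 1e-12)
})

test_that("taxon swaps negate the matching Z statistic", {
  set.seed(23)
  for (i in 1:5) {
    aln <- random_quartet_aln(400)
    t0 <- quartet_root_test(aln)
    t12 <- quartet_root_test(reorder_taxa(aln, c(2L, 1L, 3L, 4L)))
    expect_equal(t12$z1, -t0$z1, tolerance = 1e-12)
    expect_equal(t12$z2, t0$z2, tolerance = 1e-12)
    t34 <- quartet_root_test(reorder_taxa(aln, c(1L, 2L, 4L, 3L)))
    expect_equal(t34$z2, -t0$z2, tolerance = 1e-12)
    expect_equal(t34$z1, t0$z1, tolerance = 1e-12)
  }
})

test_that("type-I error of each test is near its nominal level under the null", {
  set.seed(24)
  M <- 10000
  reps <- 20000
  q <- c(0.1, 0.1, 0.05, 0.05, 0.7)
  X <- rmultinom(reps, M, q)
  crit <- qnorm(1 - 0.025 / 2)
  zz <- apply(X, 2, z_statistics)
  for (k in 1:2) {
    rate <- mean(abs(zz[k, ]) > crit)
    tol <- 3 * sqrt(0.025 * 0.975 / reps)
    expect_lt(abs(rate - 0.025), tol + 0.002)
  }
})

test_that("results serialise to JSON with decisions and statistics", {
  set.seed(25)
  tst <- quartet_root_test(random_quartet_aln(200))
  js <- jsonlite::fromJSON(as_json(tst))
  expect_equal(js$M, tst$M)
  expect_equal(js$z1, tst$z1)
  expect_length(js$q_hat, 5)
  expect_identical(js$status, tst$status)
})

test_that("print and coef methods expose the fit", {
  set.seed(26)
  tst <- quartet_root_test(random_quartet_aln(300))
  expect_output(print(tst), "Quartet rooting test")
  expect_output(print(summary(tst)), "category probabilities")
  expect_equal(coef(tst), tst$q_hat)
})
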