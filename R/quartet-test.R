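#' Estimated site-pattern category probabilities
#'
#' The category counts of a quartet alignment are multinomial(M, q); the
#' plug-in estimate is the observed frequency `q_hat[s] = X[s] / M`.
#'
#' @param counts a `pattern_counts` object from [count_patterns()], or an
#'   integer vector of 5 category counts.
#' @return numeric vector of 5 probabilities summing to 1.
#' @export
estimate_category_probs <- function(counts) {
  X <- .counts_vector(counts)
  M <- sum(X)
  if (M < 1L) stop("M = 0: no sites to estimate category probabilities from")
  stats::setNames(X / M, c("yxxx", "xyxx", "xxyx", "xxxy", "other"))
}

.counts_vector <- function(counts) {
  if (inherits(counts, "pattern_counts")) counts <- counts$X
  counts <- as.numeric(counts)
  if (length(counts) != 5L || any(counts < 0))
    stop("counts must be 5 non-negative category counts")
  counts
}

#' Z statistics for the two rooting hypothesis tests
#'
#' Test 1 contrasts the frequencies of categories `yxxx` and `xyxx`
#' (is tip a or tip b the odd one out?); Test 2 contrasts `xxyx` and
#' `xxxy`. Each statistic is the frequency difference divided by its
#' estimated multinomial standard error,
#' \deqn{Z_1 = (\hat q_1 - \hat q_2) \big/
#'   \sqrt{[\hat q_1(1-\hat q_1) + \hat q_2(1-\hat q_2) +
#'   2\hat q_1 \hat q_2]/M},}
#' and analogously for \eqn{Z_2} with \eqn{\hat q_3, \hat q_4}. Under the
#' corresponding null (equal category probabilities) each is asymptotically
#' standard normal. If both counts entering a statistic are zero the
#' statistic is defined as 0 (no evidence of asymmetry).
#'
#' @param counts a `pattern_counts` object or 5-vector of category counts.
#' @return named numeric vector `c(z1, z2)`.
#' @export
z_statistics <- function(counts) {
  X <- .counts_vector(counts)
  M <- sum(X)
  if (M < 1L) stop("M = 0: no sites")
  q <- X / M
  z_pair <- function(qi, qj) {
    if (qi == 0 && qj == 0) return(0)
    (qi - qj) / sqrt((qi * (1 - qi) + qj * (1 - qj) + 2 * qi * qj) / M)
  }
  c(z1 = z_pair(q[1L], q[2L]), z2 = z_pair(q[3L], q[4L]))
}

#' Map the two test decisions to a root position
#'
#' Each test rejects when `|Z| > qnorm(1 - alpha/2)` (two-sided). The
#' decisions combine to a root call: rejecting Test 1 only places the root
#' on tip a's branch (position 1) if `Z1 > 0`, on tip b's (position 2) if
#' `Z1 < 0`; rejecting Test 2 only gives position 3 (`Z2 > 0`) or 4
#' (`Z2 < 0`); accepting both gives the symmetric rooting on the internal
#' branch (position 5); rejecting both is inconclusive.
#'
#' @param z1,z2 the two test statistics.
#' @param alpha1,alpha2 per-test significance levels (defaults 0.025 each,
#'   so the familywise level is 0.05 by Bonferroni).
#' @return list with `reject1`, `reject2`, `crit1`, `crit2`, `position`
#'   (integer 1..5, or `NA` when inconclusive), and `status`
#'   (`"conclusive"` or `"inconclusive"`).
#' @export
infer_root_position <- function(z1, z2, alpha1 = 0.025, alpha2 = 0.025) {
  stopifnot(is.finite(z1), is.finite(z2),
            alpha1 > 0, alpha1 < 1, alpha2 > 0, alpha2 < 1)
  crit1 <- stats::qnorm(1 - alpha1 / 2)
  crit2 <- stats::qnorm(1 - alpha2 / 2)
  reject1 <- abs(z1) > crit1
  reject2 <- abs(z2) > crit2
  position <-
    if (reject1 && !reject2) if (z1 > 0) 1L else 2L
    else if (!reject1 && reject2) if (z2 > 0) 3L else 4L
    else if (!reject1 && !reject2) 5L
    else NA_integer_
  list(reject1 = reject1, reject2 = reject2, crit1 = crit1, crit2 = crit2,
       position = position,
       status = if (is.na(position)) "inconclusive" else "conclusive")
}

#' Root a four-taxon quartet from site pattern frequencies
#'
#' Fits the quartet rooting test to an alignment: tallies the five site
#' pattern categories, computes the two Z statistics, and applies the
#' decision rule of [infer_root_position()]. Row order is significant: rows
#' are tips (a, b, c, d) of the unrooted quartet with split \{a,b\}|\{c,d\},
#' and the returned position indexes the five branches (pendant a, b, c, d;
#' internal).
#'
#' @param aln quartet alignment (4-row character matrix or
#'   [quartet_alignment()] object) or a precomputed `pattern_counts` object.
#' @param alpha1,alpha2 per-test significance levels; see
#'   [infer_root_position()].
#' @return object of class `quartet_root_test`: the counts, `q_hat`, `z1`,
#'   `z2`, critical values, decisions, `position` and `status`.
#' @examples
#' m <- preset_species_tree("long_asym")
#' a <- simulate_cis(m, substitution_model("JC69"), 5000)
#' quartet_root_test(a)
#' @export
quartet_root_test <- function(aln, alpha1 = 0.025, alpha2 = 0.025) {
  counts <- if (inherits(aln, "pattern_counts")) aln else count_patterns(aln)
  q_hat <- estimate_category_probs(counts)
  z <- z_statistics(counts)
  dec <- infer_root_position(z[["z1"]], z[["z2"]], alpha1, alpha2)
  structure(
    list(counts = counts, M = counts$M, q_hat = q_hat,
         z1 = z[["z1"]], z2 = z[["z2"]],
         alpha1 = alpha1, alpha2 = alpha2,
         crit1 = dec$crit1, crit2 = dec$crit2,
         reject1 = dec$reject1, reject2 = dec$reject2,
         position = dec$position, status = dec$status,
         taxa = counts$taxa),
    class = "quartet_root_test")
}

#' @export
print.quartet_root_test <- function(x, digits = 4, ...) {
  cat("\n\tQuartet rooting test (site pattern frequencies)\n\n")
  cat("taxa (a,b,c,d):", paste(x$taxa, collapse = ", "), "\n")
  cat("sites retained M =", x$M, "\n")
  cat(sprintf("Test 1 (yxxx vs xyxx): Z1 = %.*f, |crit| = %.*f -> %s\n",
              digits, x$z1, digits, x$crit1,
              if (x$reject1) "reject" else "accept"))
  cat(sprintf("Test 2 (xxyx vs xxxy): Z2 = %.*f, |crit| = %.*f -> %s\n",
              digits, x$z2, digits, x$crit2,
              if (x$reject2) "reject" else "accept"))
  if (x$status == "conclusive") {
    lab <- c("pendant branch of tip a", "pendant branch of tip b",
             "pendant branch of tip c", "pendant branch of tip d",
             "internal branch (symmetric rooting)")[x$position]
    cat("inferred root position:", x$position, "-", lab, "\n")
  } else {
    cat("inferred root position: inconclusive (both tests reject)\n")
  }
  invisible(x)
}

#' @export
summary.quartet_root_test <- function(object, ...) {
  out <- object
  class(out) <- c("summary.quartet_root_test", class(object))
  out
}

#' @export
print.summary.quartet_root_test <- function(x, ...) {
  print.quartet_root_test(x, ...)
  cat("\nEstimated category probabilities:\n")
  print(round(x$q_hat, 5))
  cat("category counts:\n")
  print(x$counts$X)
  invisible(x)
}

#' @export
coef.quartet_root_test <- function(object, ...) object$q_hat

#' Serialize a quartet test result to JSON
#'
#' @param x a `quartet_root_test`.
#' @param ... passed to [jsonlite::toJSON()].
#' @return a JSON string.
#' @export
as_json <- function(x, ...) UseMethod("as_json")

#' @export
as_json.quartet_root_test <- function(x, ...) {
  jsonlite::toJSON(list(
    taxa = x$taxa, M = x$M, X = unname(x$counts$X),
    q_hat = unname(round(x$q_hat, 10)),
    z1 = x$z1, z2 = x$z2,
    alpha = c(x$alpha1, x$alpha2), crit = c(x$crit1, x$crit2),
    reject = c(x$reject1, x$reject2),
    position = if (is.na(x$position)) "inconclusive" else x$position,
    status = x$status), auto_unbox = TRUE, digits = NA, ...)
}
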