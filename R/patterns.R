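NUC <- c("A", "C", "G", "T")

## Map a character vector of nucleotides to integer states 1..4 (NA for
## anything that is not A/C/G/T after upper-casing; U is treated as T).
.nuc_to_int <- function(x) {
  x <- toupper(x)
  x[x == "U"] <- "T"
  match(x, NUC)
}

#' Classify an ordered four-taxon site pattern
#'
#' A site pattern over an ordered quartet (a, b, c, d) falls into one of five
#' categories according to which single tip carries a state different from the
#' shared state of the other three: `yxxx` (tip a differs, category 1),
#' `xyxx` (2), `xxyx` (3), `xxxy` (4), or "other" (5: constant sites,
#' two-two splits, and patterns with three or four states).
#'
#' @param pattern character vector of length 4 giving the nucleotides at the
#'   ordered tips (a, b, c, d). Lower case is accepted; `U` is read as `T`.
#' @return integer in 1..5, the category index.
#' @examples
#' classify_pattern(c("G", "A", "A", "A"))  # 1
#' classify_pattern(c("A", "A", "A", "A"))  # 5
#' @export
classify_pattern <- function(pattern) {
  if (length(pattern) != 4L)
    stop("a site pattern is an ordered 4-tuple, got length ", length(pattern))
  s <- .nuc_to_int(pattern)
  if (anyNA(s)) {
    bad <- unique(pattern[is.na(s)])
    stop("invalid nucleotide state(s): ", paste(bad, collapse = ", "))
  }
  .classify_int(matrix(s, nrow = 4L))[1L]
}

## Vectorised classification of integer-coded columns (4 x M matrix, states
## 1..4, no NAs). Returns an integer vector of categories 1..5.
.classify_int <- function(s) {
  a <- s[1L, ]; b <- s[2L, ]; c <- s[3L, ]; d <- s[4L, ]
  cat <- rep.int(5L, ncol(s))
  cat[b == c & c == d & a != b] <- 1L
  cat[a == c & c == d & b != a] <- 2L
  cat[a == b & b == d & c != a] <- 3L
  cat[a == b & b == c & d != a] <- 4L
  cat
}

#' Census of the 256 ordered site patterns by category
#'
#' Enumerates all `4^4 = 256` ordered nucleotide 4-tuples, classifies each
#' with [classify_pattern()]'s rule, and returns the per-category tallies.
#' Each one-off category contains the 12 patterns `jiii` (etc.) with
#' `j != i`; the remaining 208 patterns are "other".
#'
#' @return integer vector of length 5 (categories 1..5), summing to 256.
#' @export
category_sizes <- function() {
  g <- as.matrix(expand.grid(d = 1:4, c = 1:4, b = 1:4, a = 1:4))
  s <- t(g[, c("a", "b", "c", "d")])
  tabulate(.classify_int(s), nbins = 5L)
}

#' Census of site-pattern probability classes under a clock
#'
#' Under a molecular clock and an exchangeable substitution model, the
#' probability of a site pattern depends only on which tips share states,
#' i.e. on the set partition of the four ordered tip positions induced by
#' state identity (`xxxy`, `xyxy`, `xyzw`, ...). This enumerates all 256
#' ordered patterns, reduces each to its canonical partition signature, and
#' counts the distinct classes.
#'
#' @return a named integer vector: one element per signature (e.g. `"xxxy"`),
#'   giving the number of ordered patterns carrying it.
#' @export
pattern_signature_census <- function() {
  g <- as.matrix(expand.grid(d = 1:4, c = 1:4, b = 1:4, a = 1:4))
  s <- g[, c("a", "b", "c", "d"), drop = FALSE]
  sig <- apply(s, 1L, function(p) {
    # relabel states by first appearance: x, y, z, w
    paste(c("x", "y", "z", "w")[match(p, unique(p))], collapse = "")
  })
  table_ <- table(sig)
  out <- as.integer(table_)
  names(out) <- names(table_)
  out
}

#' Tally site-pattern categories in a quartet alignment
#'
#' Classifies every alignment column whose four states are all in
#' `{A, C, G, T}` and tallies the five categories. Columns containing a gap,
#' an ambiguity code, or any other symbol are excluded (complete-case sites);
#' the number excluded is recorded. The full 256-pattern tally is kept for
#' diagnostics.
#'
#' @param aln a quartet alignment: character matrix with 4 rows (taxa, in the
#'   rooted-tree order a, b, c, d) and one column per site, or an object
#'   created by [quartet_alignment()].
#' @return an object of class `pattern_counts`: list with `X` (integer vector
#'   of 5 category counts), `M` (retained sites), `n_excluded`, `raw` (named
#'   256-pattern tally over retained sites), and `taxa`.
#' @examples
#' aln <- rbind(A = c("A", "A"), B = c("C", "A"),
#'              C = c("C", "A"), D = c("C", "T"))
#' count_patterns(aln)
#' @export
count_patterns <- function(aln) {
  aln <- quartet_alignment(aln)
  s <- matrix(.nuc_to_int(aln$sites), nrow = 4L)
  keep <- colSums(is.na(s)) == 0L
  n_excluded <- sum(!keep)
  s <- s[, keep, drop = FALSE]
  M <- ncol(s)
  if (M == 0L) stop("no usable sites: every column contains a gap or ambiguity")
  X <- tabulate(.classify_int(s), nbins = 5L)
  idx <- (s[1L, ] - 1L) * 64L + (s[2L, ] - 1L) * 16L + (s[3L, ] - 1L) * 4L + s[4L, ]
  raw <- tabulate(idx, nbins = 256L)
  names(raw) <- .pattern_names()
  structure(
    list(X = stats::setNames(X, c("yxxx", "xyxx", "xxyx", "xxxy", "other")),
         M = M, n_excluded = n_excluded, raw = raw, taxa = aln$taxon_labels),
    class = "pattern_counts")
}

.pattern_names <- function() {
  g <- expand.grid(d = NUC, c = NUC, b = NUC, a = NUC, stringsAsFactors = FALSE)
  paste0(g$a, g$b, g$c, g$d)
}

#' @export
print.pattern_counts <- function(x, ...) {
  cat("Site pattern category counts (", x$M, " sites",
      if (x$n_excluded > 0L) paste0(", ", x$n_excluded, " excluded"), ")\n",
      sep = "")
  cat("  taxa:", paste(x$taxa, collapse = ", "), "\n")
  print(x$X)
  invisible(x)
}

#' Construct or validate a quartet alignment
#'
#' A quartet alignment is a character matrix of nucleotide states with
#' exactly four rows, one per taxon, in a significant order: row 1 is tip
#' `a`, ... row 4 is tip `d` of the rooted four-taxon tree convention used
#' throughout (root positions 1-4 are the pendant branches of a-d, position
#' 5 the internal branch).
#'
#' @param x character matrix with 4 rows (rownames taken as taxon labels),
#'   or an existing `quartet_alignment`.
#' @param taxon_labels optional character vector of 4 labels, overriding
#'   rownames.
#' @return object of class `quartet_alignment`: list with `taxon_labels`,
#'   `sites` (4 x M character matrix), `n_sites_raw`.
#' @export
quartet_alignment <- function(x, taxon_labels = NULL) {
  if (inherits(x, "quartet_alignment")) {
    if (!is.null(taxon_labels)) x$taxon_labels <- taxon_labels
    return(x)
  }
  if (!is.matrix(x) || !is.character(x))
    stop("a quartet alignment must be a character matrix")
  if (nrow(x) != 4L)
    stop("a quartet alignment has exactly 4 rows, got ", nrow(x))
  labels <- taxon_labels %||% rownames(x) %||% paste0("t", 1:4)
  if (length(labels) != 4L || anyDuplicated(labels))
    stop("taxon labels must be 4 distinct names")
  rownames(x) <- labels
  structure(list(taxon_labels = labels, sites = x, n_sites_raw = ncol(x)),
            class = "quartet_alignment")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reorder the taxa of a quartet alignment
#'
#' Row order is significant for pattern classification, so reordering swaps
#' pattern categories predictably (e.g. exchanging rows 1 and 2 exchanges
#' the `yxxx` and `xyxx` tallies).
#'
#' @param aln a quartet alignment (see [quartet_alignment()]).
#' @param new_order permutation of the taxon labels (character) or of 1..4
#'   (integer).
#' @return the reordered `quartet_alignment`.
#' @export
reorder_taxa <- function(aln, new_order) {
  aln <- quartet_alignment(aln)
  if (is.character(new_order)) {
    idx <- match(new_order, aln$taxon_labels)
    if (anyNA(idx) || length(idx) != 4L)
      stop("new_order must be a permutation of: ",
           paste(aln$taxon_labels, collapse = ", "))
  } else {
    idx <- as.integer(new_order)
    if (length(idx) != 4L || !setequal(idx, 1:4))
      stop("new_order must be a permutation of 1:4")
  }
  quartet_alignment(aln$sites[idx, , drop = FALSE],
                    taxon_labels = aln$taxon_labels[idx])
}

#' @export
print.quartet_alignment <- function(x, ...) {
  cat("Quartet alignment:", x$n_sites_raw, "sites\n")
  cat("  taxa (order a,b,c,d):", paste(x$taxon_labels, collapse = ", "), "\n")
  invisible(x)
}
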