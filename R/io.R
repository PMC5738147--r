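#' Read a multiple sequence alignment
#'
#' Reads FASTA, relaxed PHYLIP (sequential or interleaved) or NEXUS data
#' blocks into a character matrix, one row per taxon. Sequences are
#' upper-cased and `U` is mapped to `T`; gap and ambiguity symbols are kept
#' as-is (they are excluded site-wise by [count_patterns()]).
#'
#' @param path input file.
#' @param format `"auto"` (sniff the first non-blank line), `"fasta"`,
#'   `"phylip"` or `"nexus"`.
#' @param taxa optional character vector selecting (and ordering) a subset
#'   of taxa by name.
#' @return character matrix, taxa x sites, rownames = taxon labels.
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "phylip", "nexus"),
                           taxa = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    head_lines <- readLines(path, n = 50L, warn = FALSE)
    head_lines <- head_lines[nzchar(trimws(head_lines))]
    if (!length(head_lines)) stop("empty alignment file: ", path)
    first <- trimws(head_lines[1L])
    format <- if (startsWith(first, ">")) "fasta"
      else if (toupper(substr(first, 1, 6)) == "#NEXUS") "nexus"
      else "phylip"
  }
  seqs <- switch(format,
    fasta = {
      x <- as.character(ape::read.FASTA(path))
      lapply(x, toupper)
    },
    phylip = {
      x <- tryCatch(ape::read.dna(path, format = "sequential",
                                  as.character = TRUE),
                    error = function(e)
                      ape::read.dna(path, format = "interleaved",
                                    as.character = TRUE))
      lapply(seq_len(nrow(x)), function(i) toupper(x[i, ])) |>
        stats::setNames(rownames(x))
    },
    nexus = {
      x <- ape::read.nexus.data(path)
      lapply(x, toupper)
    })
  if (!length(seqs)) stop("no sequences in ", path)
  if (anyDuplicated(names(seqs)))
    stop("duplicate taxon names: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  lens <- lengths(seqs)
  if (length(unique(lens)) != 1L)
    stop("sequences have unequal lengths (", paste(unique(lens), collapse = ", "), ")")
  aln <- do.call(rbind, seqs)
  aln[aln == "U"] <- "T"
  rownames(aln) <- names(seqs)
  if (!is.null(taxa)) {
    miss <- setdiff(taxa, rownames(aln))
    if (length(miss))
      stop("taxa not in alignment: ", paste(miss, collapse = ", "))
    aln <- aln[taxa, , drop = FALSE]
  }
  aln
}

#' Write an alignment to FASTA or PHYLIP
#'
#' @param aln character alignment matrix (taxa x sites).
#' @param path output file.
#' @param format `"fasta"` or `"phylip"`.
#' @return invisibly, `path`.
#' @export
write_alignment <- function(aln, path, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  if (format == "fasta") {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(aln))) {
      writeLines(paste0(">", rownames(aln)[i]), con)
      writeLines(paste(aln[i, ], collapse = ""), con)
    }
  } else {
    lines <- c(paste(nrow(aln), ncol(aln)),
               paste(rownames(aln),
                     apply(aln, 1L, paste, collapse = "")))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read an unrooted species tree with stable branch codes
#'
#' Parses a Newick file (or string), unroots the topology, and assigns
#' deterministic branch codes; see [coded_tree()].
#'
#' @param path file path, or a Newick string via `text`.
#' @param text optional Newick string (overrides `path`).
#' @return a `coded_tree`.
#' @export
read_species_tree <- function(path = NULL, text = NULL) {
  tr <- if (!is.null(text)) ape::read.tree(text = text) else ape::read.tree(path)
  if (is.null(tr)) stop("could not parse Newick input")
  coded_tree(tr)
}

#' Write a tree to Newick
#'
#' @param tree a `phylo` or `coded_tree`.
#' @param path output file, or `""` for a returned string.
#' @return the Newick string, invisibly when written to file.
#' @export
write_species_tree <- function(tree, path = "") {
  if (inherits(tree, "coded_tree")) tree <- tree$phylo
  nwk <- ape::write.tree(tree)
  if (!identical(path, "")) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}
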