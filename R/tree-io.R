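## Tree and alignment input/output. Trees are ape "phylo" objects throughout;
## alignments are upper-case character matrices (rows = taxa, cols = sites).

#' Read a rooted Newick tree
#'
#' Thin wrapper around \code{\link[ape]{read.tree}} that additionally accepts
#' single-quoted node labels (as written by \code{\link{annotate_tree}}, whose
#' labels contain parentheses) and validates the result: exactly one root,
#' non-negative branch lengths, unique tip labels.
#'
#' @param text Newick string, or \code{NULL} if \code{file} is given.
#' @param file Path to a Newick file.
#' @return An object of class \code{"phylo"}.
#' @export
read_newick <- function(text = NULL, file = NULL) {
  if (is.null(text)) {
    stopifnot(!is.null(file))
    text <- paste(readLines(file, warn = FALSE), collapse = "")
  }
  text <- trimws(text)
  ## protect single-quoted labels (may contain parentheses/commas)
  quoted <- regmatches(text, gregexpr("'[^']*'", text))[[1]]
  restore <- character(0)
  if (length(quoted)) {
    keys <- sprintf("QLBL%06dX", seq_along(quoted))
    restore <- structure(substr(quoted, 2, nchar(quoted) - 1), names = keys)
    for (i in seq_along(quoted))
      text <- sub(quoted[i], keys[i], text, fixed = TRUE)
  }
  if (!grepl(";\\s*$", text))
    stop("Newick parse error: missing terminating ';'")
  n_open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  n_close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (n_open != n_close)
    stop(sprintf("Newick parse error: %d '(' vs %d ')'", n_open, n_close))
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) stop("Newick parse error: ",
                                          conditionMessage(e)))
  if (is.null(tr)) stop("Newick parse error: unreadable tree string")
  if (length(restore)) {
    tr$tip.label <- .restore_labels(tr$tip.label, restore)
    if (!is.null(tr$node.label))
      tr$node.label <- .restore_labels(tr$node.label, restore)
  }
  if (anyDuplicated(tr$tip.label))
    stop("duplicate taxon labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0))
    stop("negative branch lengths are not allowed")
  tr
}

.restore_labels <- function(lab, restore) {
  hit <- lab %in% names(restore)
  lab[hit] <- restore[lab[hit]]
  lab
}

#' Write a tree as Newick
#'
#' Node labels containing Newick metacharacters are single-quoted. Branch
#' lengths are written with full (15 significant digit) precision.
#'
#' @param tree A \code{"phylo"} object.
#' @param file Optional path; if omitted the Newick string is returned.
#' @return The Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, file = NULL) {
  ntip <- length(tree$tip.label)
  qu <- function(x) {
    if (!nzchar(x)) return(x)
    if (grepl("[][(),:;' ]", x))
      paste0("'", gsub("'", "''", x), "'")
    else x
  }
  label <- function(v)
    if (v <= ntip) qu(tree$tip.label[v])
    else if (!is.null(tree$node.label))
      qu(tree$node.label[v - ntip]) else ""
  edge_to <- integer(ntip + tree$Nnode)
  edge_to[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  render <- function(v) {
    kids <- tree$edge[tree$edge[, 1] == v, 2]
    core <- if (length(kids) == 0L) label(v)
            else paste0("(", paste(vapply(kids, render, ""),
                                   collapse = ","), ")", label(v))
    e <- edge_to[v]
    if (e > 0L && !is.null(tree$edge.length))
      core <- paste0(core, ":", sprintf("%.15g", tree$edge.length[e]))
    core
  }
  s <- paste0(render(ntip + 1L), ";")
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(s)
}

#' Read a nucleotide alignment from FASTA
#'
#' Sequences are upper-cased; \code{U} is converted to \code{T}. Records must
#' have equal length. The gap policy removes every column containing a gap
#' (\code{-} or \code{.}) in any sequence, so sites stay aligned across taxa;
#' ambiguity codes (N, R, Y, ...) are retained and treated as missing data by
#' the likelihood machinery.
#'
#' @param file FASTA path.
#' @param strip_gaps If \code{TRUE} (default), drop gap-containing columns.
#' @return Character matrix, rows named by taxon.
#' @export
read_alignment <- function(file, strip_gaps = TRUE) {
  dna <- seqinr::read.fasta(file, seqtype = "DNA",
                            forceDNAtolower = FALSE, set.attributes = FALSE)
  chr <- lapply(dna, toupper)
  len <- lengths(chr)
  if (length(unique(len)) > 1L) {
    bad <- names(chr)[len != stats::median(len)]
    stop("unequal sequence lengths for: ", paste(bad, collapse = ", "))
  }
  aln <- do.call(rbind, chr)
  rownames(aln) <- names(chr)
  aln[aln == "U"] <- "T"
  if (strip_gaps) {
    gap_col <- apply(aln == "-" | aln == ".", 2, any)
    aln <- aln[, !gap_col, drop = FALSE]
  }
  if (ncol(aln) == 0L) stop("alignment has no sites after gap removal")
  aln
}

#' Write an alignment to FASTA (60-column wrap)
#' @param aln Character matrix as from \code{\link{read_alignment}}.
#' @param file Output path.
#' @export
write_alignment <- function(aln, file) {
  con <- file(file, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(aln))) {
    s <- paste(aln[i, ], collapse = "")
    writeLines(paste0(">", rownames(aln)[i]), con)
    writeLines(substring(s, seq(1, nchar(s), 60),
                         pmin(seq(1, nchar(s), 60) + 59, nchar(s))), con)
  }
  invisible(file)
}

#' Read clade definitions from a two-column TSV
#'
#' @param file TSV with header columns \code{clade} and \code{taxon}.
#' @return Named list of character vectors of taxa, in first-appearance order.
#' @export
read_clades <- function(file) {
  d <- utils::read.delim(file, stringsAsFactors = FALSE)
  stopifnot(all(c("clade", "taxon") %in% names(d)))
  split(d$taxon, factor(d$clade, levels = unique(d$clade)))
}
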