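## Branch-class maps: every edge of the rooted tree is assigned to exactly one
## class; each class carries its own equilibrium GC (theta) in the
## non-homogeneous model.

#' Assign branches of a tree to model classes
#'
#' Three schemes cover the hierarchical model ladder: \code{"homogeneous"}
#' (one class for the whole tree), \code{"clades"} (one class per named taxon
#' group; covers the M1, M2 and terminal-clades levels, which differ only in
#' the clade definitions supplied) and \code{"per_branch"} (every branch its
#' own class).
#'
#' Under \code{"clades"} every taxon must belong to exactly one clade and each
#' clade must be monophyletic. The branch subtending a clade's most recent
#' common ancestor belongs to that clade's class; a backbone branch whose
#' descendant tips span several clades takes the class of the earliest-listed
#' clade among them, which classifies every branch deterministically.
#'
#' @param tree Rooted \code{"phylo"} tree.
#' @param scheme \code{"homogeneous"}, \code{"clades"} or \code{"per_branch"}.
#' @param clades Named list of character vectors of taxa (required for
#'   \code{"clades"}), e.g. from \code{\link{read_clades}}.
#' @return Object of class \code{"branch_classes"}: integer vector
#'   \code{class} along \code{tree$edge}, class \code{labels}, and the scheme.
#' @examples
#' tr <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
#' branch_classes(tr, "clades", list(left = c("A", "B"), right = c("C", "D")))
#' @export
branch_classes <- function(tree,
                           scheme = c("homogeneous", "clades", "per_branch"),
                           clades = NULL) {
  scheme <- match.arg(scheme)
  ne <- nrow(tree$edge)
  if (scheme == "homogeneous") {
    out <- list(class = rep(1L, ne), labels = "all", scheme = scheme)
  } else if (scheme == "per_branch") {
    out <- list(class = seq_len(ne),
                labels = paste0("branch", seq_len(ne)), scheme = scheme)
  } else {
    stopifnot(is.list(clades), !is.null(names(clades)))
    tips <- tree$tip.label
    flat <- unlist(clades, use.names = FALSE)
    if (anyDuplicated(flat))
      stop("taxa listed in more than one clade: ",
           paste(unique(flat[duplicated(flat)]), collapse = ", "))
    missing <- setdiff(tips, flat)
    if (length(missing))
      stop("taxa not covered by any clade: ", paste(missing, collapse = ", "))
    unknown <- setdiff(flat, tips)
    if (length(unknown))
      stop("clade taxa absent from tree: ", paste(unknown, collapse = ", "))
    desc <- edge_tip_sets(tree)
    ## monophyly: some edge's descendant tip set must equal the clade
    ## (or the clade is the full tip set, i.e. the root)
    edge_keys <- vapply(desc, function(s) paste(sort(s), collapse = "\r"),
                        "")
    for (cl in names(clades)) {
      want <- sort(clades[[cl]])
      if (length(want) == length(tips)) next
      if (length(want) == 1L) next  # single tips are trivially monophyletic
      if (!paste(want, collapse = "\r") %in% edge_keys) {
        mr <- ape::getMRCA(tree, clades[[cl]])
        span <- tips[descendant_tips_of_node(tree, mr)]
        stop(sprintf("clade '%s' is not monophyletic; its MRCA also spans: %s",
                     cl, paste(setdiff(span, clades[[cl]]), collapse = ", ")))
      }
    }
    clade_of_tip <- integer(length(tips))
    for (i in seq_along(clades))
      clade_of_tip[match(clades[[i]], tips)] <- i
    cls <- vapply(desc, function(s) {
      present <- unique(clade_of_tip[match(s, tips)])
      min(present)   # earliest-listed clade among descendants
    }, 0L)
    out <- list(class = as.integer(cls), labels = names(clades),
                scheme = scheme)
  }
  structure(out, class = "branch_classes")
}

#' @export
print.branch_classes <- function(x, ...) {
  cat(sprintf("Branch-class map (%s): %d branches, %d classes\n",
              x$scheme, length(x$class), length(x$labels)))
  print(stats::setNames(tabulate(x$class, length(x$labels)), x$labels))
  invisible(x)
}

#' Number of classes in a branch-class map
#' @param map A \code{"branch_classes"} object.
#' @return Integer class count.
#' @export
n_classes <- function(map) length(map$labels)

## Descendant tip labels of the child node of each edge, postorder accumulation.
edge_tip_sets <- function(tree) {
  ne <- nrow(tree$edge)
  ntip <- length(tree$tip.label)
  node_tips <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) node_tips[[i]] <- tree$tip.label[i]
  ord <- reorder_postorder(tree)
  for (e in ord) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    node_tips[[p]] <- c(node_tips[[p]], node_tips[[ch]])
  }
  lapply(seq_len(ne), function(e) node_tips[[tree$edge[e, 2]]])
}

## Edge indices in postorder (children before parents).
reorder_postorder <- function(tree) {
  tr <- ape::reorder.phylo(tree, "postorder")
  match(paste(tr$edge[, 1], tr$edge[, 2]),
        paste(tree$edge[, 1], tree$edge[, 2]))
}

## descendant tip indices of a node
descendant_tips_of_node <- function(tree, node) {
  ntip <- length(tree$tip.label)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    if (v <= ntip) out <- c(out, v)
    else stack <- c(stack, tree$edge[tree$edge[, 1] == v, 2])
  }
  out
}
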