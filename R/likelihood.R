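## Felsenstein pruning for the non-homogeneous, non-stationary T92 model:
## branch-specific transition matrices (class theta, shared kappa), a free
## root composition, discrete-gamma rate mixture and optional invariant sites.

## IUPAC nucleotide codes -> conditional likelihood rows (A, C, G, T).
## Ambiguity codes contribute a partial likelihood of 1 on every compatible
## state (missing-data treatment).
iupac_matrix <- function() {
  codes <- list(
    A = "A", C = "C", G = "G", T = "T",
    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
    K = c("G", "T"), M = c("A", "C"),
    B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
    V = c("A", "C", "G"), N = c("A", "C", "G", "T"),
    "?" = c("A", "C", "G", "T"), "-" = c("A", "C", "G", "T"))
  m <- matrix(0, length(codes), 4,
              dimnames = list(names(codes), NUC))
  for (i in seq_along(codes)) m[i, codes[[i]]] <- 1
  m
}

## Compress an alignment into site patterns and per-tip conditional
## likelihood arrays, ordered to match tree$tip.label.
prepare_alignment <- function(aln, tree) {
  if (is.null(rownames(aln))) stop("alignment rows must be named by taxon")
  missing <- setdiff(tree$tip.label, rownames(aln))
  extra <- setdiff(rownames(aln), tree$tip.label)
  if (length(missing))
    stop("tree tips without sequences: ", paste(missing, collapse = ", "))
  if (length(extra))
    stop("sequences not in tree: ", paste(extra, collapse = ", "))
  if (ncol(aln) == 0L) stop("alignment has zero sites")
  aln <- aln[tree$tip.label, , drop = FALSE]
  key <- apply(aln, 2, paste, collapse = "")
  pat <- !duplicated(key)
  weights <- as.vector(table(factor(key, levels = key[pat])))
  sub <- aln[, pat, drop = FALSE]
  iu <- iupac_matrix()
  bad <- setdiff(unique(as.vector(sub)), rownames(iu))
  if (length(bad))
    stop("unrecognized residue codes: ", paste(bad, collapse = ", "))
  tipcond <- lapply(seq_len(nrow(sub)), function(i) t(iu[sub[i, ], ,
                                                         drop = FALSE]))
  list(tipcond = tipcond, weights = weights, n_sites = ncol(aln),
       n_patterns = sum(pat), pattern_index = match(key, key[pat]))
}

## Core pruning pass for one rate multiplier. Returns per-pattern
## log site likelihoods.
prune_one_rate <- function(prep, tree, post_edges, edge_theta, kappa, rate,
                           root_freq, eig_cache) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  partial <- vector("list", nn)
  for (e in post_edges) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    th <- edge_theta[e]
    key <- format(th, digits = 17)
    eig <- eig_cache[[key]]
    if (is.null(eig)) {
      eig <- t92_eigen(th, kappa)
      eig_cache[[key]] <- eig
    }
    t_eff <- tree$edge.length[e] * rate
    P <- eig$right %*% (exp(eig$values * t_eff) * eig$left)
    P[P < 0] <- 0
    Lch <- if (ch <= ntip) prep$tipcond[[ch]] else partial[[ch]]
    contrib <- P %*% Lch
    partial[[p]] <- if (is.null(partial[[p]])) contrib
                    else partial[[p]] * contrib
  }
  root <- ntip + 1L
  sitelik <- colSums(root_freq * partial[[root]])
  log(sitelik)
}

#' Log-likelihood of an alignment under the non-homogeneous T92 model
#'
#' Felsenstein pruning on the fixed rooted tree. Each branch uses the
#' transition matrix of its class's theta with the shared kappa; the root is
#' summed against a free root composition (GC content \code{theta_root});
#' per-site rates follow a k-category discrete gamma, optionally mixed with a
#' proportion of invariant sites.
#'
#' @param aln Character matrix alignment (rows named by taxon).
#' @param tree Rooted \code{"phylo"} tree with branch lengths.
#' @param classes \code{"branch_classes"} map for \code{tree}.
#' @param theta Numeric vector of equilibrium GC values, one per class.
#' @param theta_root Root GC content in (0, 1).
#' @param kappa Transition/transversion ratio, > 0.
#' @param alpha Gamma shape (> 0); ignored when \code{k = 1}.
#' @param k Number of gamma categories (default 4).
#' @param p_inv Proportion of invariant sites in [0, 1), default 0.
#' @return The log-likelihood (a negative number); its negation is the
#'   -lnL reported by \code{\link{gc_fit}}.
#' @export
gc_loglik <- function(aln, tree, classes, theta, theta_root, kappa,
                      alpha = 1, k = 4L, p_inv = 0) {
  prep <- prepare_alignment(aln, tree)
  gc_loglik_prepared(prep, tree, classes, theta, theta_root, kappa,
                     alpha, k, p_inv)
}

gc_loglik_prepared <- function(prep, tree, classes, theta, theta_root,
                               kappa, alpha = 1, k = 4L, p_inv = 0) {
  stopifnot(length(theta) == length(classes$labels))
  if (any(theta <= 0 | theta >= 1) || theta_root <= 0 || theta_root >= 1 ||
      kappa <= 0 || p_inv < 0 || p_inv >= 1)
    stop("parameters out of domain")
  if (length(classes$class) != nrow(tree$edge))
    stop("branch-class map does not match the tree")
  edge_theta <- theta[classes$class]
  root_freq <- t92_frequencies(theta_root)
  g <- discrete_gamma_rates(alpha, k)
  post_edges <- reorder_postorder(tree)
  eig_cache <- new.env(parent = emptyenv())
  percat <- lapply(g$rates, function(r)
    prune_one_rate(prep, tree, post_edges, edge_theta, kappa, r, root_freq,
                   eig_cache))
  M <- do.call(cbind, percat)          # npat x k, log site likelihoods
  mx <- apply(M, 1, max)
  mix <- exp(mx) * as.vector(exp(M - mx) %*% g$weights)
  if (p_inv > 0) {
    const_lik <- prune_one_rate(prep, tree, post_edges, edge_theta, kappa, 0,
                                root_freq, eig_cache)
    mix <- (1 - p_inv) * mix + p_inv * exp(const_lik)
  }
  sum(prep$weights * log(mix))
}
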