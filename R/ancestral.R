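## Ancestral GC content at nodes and GC* along branches.
## Primary mode: model-expected composition, propagated from the root
## composition through each branch's transition matrix (deterministic given
## the fit). Cross-check mode: per-site marginal posterior state
## distributions from the standard two-pass algorithm.

#' Reconstruct ancestral GC content and branch GC*
#'
#' @param fit A converged \code{"gc_fit"}.
#' @param method \code{"expected"} (default): propagate the root composition
#'   through the fitted branch matrices, averaging over gamma categories
#'   (and the invariant class, if fitted). \code{"marginal"}: average, over
#'   sites, the marginal posterior probability of G or C at each node given
#'   the alignment (requires \code{aln}).
#' @param aln Alignment, required for \code{method = "marginal"}.
#' @param force Reconstruct even from an unconverged fit (default
#'   \code{FALSE}).
#' @return Object of class \code{"gc_ancestral"}: \code{node_gc} (named,
#'   tips then internal nodes, in tree node order), \code{branch_gc_star}
#'   (per edge: the fitted theta of the branch's class), \code{tree},
#'   \code{method}.
#' @export
ancestral_gc <- function(fit, method = c("expected", "marginal"),
                         aln = NULL, force = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(fit, "gc_fit"))
  if (!fit$convergence && !force)
    stop("fit did not converge; pass force = TRUE to reconstruct anyway")
  tree <- fit$tree
  node_gc <- if (method == "expected") node_gc_expected(fit)
             else node_gc_marginal(fit, aln)
  structure(list(node_gc = node_gc,
                 branch_gc_star = unname(fit$theta[fit$classes$class]),
                 tree = tree, method = method),
            class = "gc_ancestral")
}

#' @export
print.gc_ancestral <- function(x, ...) {
  ntip <- length(x$tree$tip.label)
  cat(sprintf("Ancestral GC reconstruction (%s), %d nodes\n",
              x$method, length(x$node_gc)))
  cat(sprintf("  root GC %.4f; internal-node GC range [%.4f, %.4f]\n",
              x$node_gc[ntip + 1],
              min(x$node_gc[(ntip + 1):length(x$node_gc)]),
              max(x$node_gc[(ntip + 1):length(x$node_gc)])))
  invisible(x)
}

## Expected composition at every node: per gamma category, comp(child) =
## comp(parent) P_branch(length * rate); report GC averaged over categories.
node_gc_expected <- function(fit) {
  tree <- fit$tree
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  g <- discrete_gamma_rates(if (fit$k > 1L) fit$alpha else 1, fit$k)
  rates <- g$rates; weights <- g$weights
  if (fit$p_inv > 0) {
    rates <- c(rates, 0)
    weights <- c(weights * (1 - fit$p_inv), fit$p_inv)
  }
  pre <- rev(reorder_postorder(tree))
  root_freq <- t92_frequencies(fit$theta_root)
  gc <- numeric(nn)
  for (ci in seq_along(rates)) {
    comp <- matrix(NA_real_, nn, 4)
    comp[ntip + 1L, ] <- root_freq
    for (e in pre) {
      p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      th <- fit$theta[fit$classes$class[e]]
      P <- t92_transition_prob(th, fit$kappa,
                               tree$edge.length[e] * rates[ci])
      comp[ch, ] <- as.vector(comp[p, ] %*% P)
    }
    gc <- gc + weights[ci] * rowSums(comp[, .GC_STATES, drop = FALSE])
  }
  stats::setNames(gc, c(tree$tip.label, ntip + seq_len(tree$Nnode)))
}

## Marginal posterior GC at every node: standard inside/outside two-pass with
## branch-specific matrices and the free root prior; mixture over gamma
## categories weighted by each category's per-site likelihood.
node_gc_marginal <- function(fit, aln) {
  if (is.null(aln)) stop("method = 'marginal' needs the alignment")
  tree <- fit$tree
  prep <- prepare_alignment(aln, tree)
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  root <- ntip + 1L
  npat <- prep$n_patterns
  g <- discrete_gamma_rates(if (fit$k > 1L) fit$alpha else 1, fit$k)
  rates <- g$rates; weights <- g$weights
  if (fit$p_inv > 0) {
    rates <- c(rates, 0)
    weights <- c(weights * (1 - fit$p_inv), fit$p_inv)
  }
  post_edges <- reorder_postorder(tree)
  root_freq <- t92_frequencies(fit$theta_root)
  edge_theta <- fit$theta[fit$classes$class]

  gc_num <- matrix(0, nn, npat)   # sum over cats of w * P(node in GC, data)
  site_den <- numeric(npat)       # sum over cats of w * P(data)
  for (ci in seq_along(rates)) {
    Pm <- lapply(seq_len(nrow(tree$edge)), function(e)
      t92_transition_prob(edge_theta[e], fit$kappa,
                          tree$edge.length[e] * rates[ci]))
    ## inside pass
    partial <- vector("list", nn)
    edge_contrib <- vector("list", nrow(tree$edge))
    for (e in post_edges) {
      p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      Lch <- if (ch <= ntip) prep$tipcond[[ch]] else partial[[ch]]
      edge_contrib[[e]] <- Pm[[e]] %*% Lch
      partial[[p]] <- if (is.null(partial[[p]])) edge_contrib[[e]]
                      else partial[[p]] * edge_contrib[[e]]
    }
    ## outside pass
    outside <- vector("list", nn)
    outside[[root]] <- matrix(root_freq, 4, npat)
    for (e in rev(post_edges)) {
      p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      sibs <- setdiff(which(tree$edge[, 1] == p), e)
      above <- outside[[p]]
      for (s in sibs) above <- above * edge_contrib[[s]]
      outside[[ch]] <- crossprod(Pm[[e]], above)
    }
    for (v in seq_len(nn)) {
      Lv <- if (v <= ntip) prep$tipcond[[v]]
            else if (v == root) partial[[v]]
            else partial[[v]]
      joint <- outside[[v]] * Lv
      gc_num[v, ] <- gc_num[v, ] +
        weights[ci] * colSums(joint[.GC_STATES, , drop = FALSE])
      if (v == root)
        site_den <- site_den + weights[ci] * colSums(joint)
    }
  }
  post_gc <- sweep(gc_num, 2, site_den, "/")
  gc <- as.vector(post_gc %*% prep$weights) / prep$n_sites
  stats::setNames(gc, c(tree$tip.label, ntip + seq_len(tree$Nnode)))
}

#' Site-bootstrap spread of the ancestral GC reconstruction
#'
#' Nonparametric bootstrap over alignment columns; per replicate the
#' per-class thetas and root GC are re-estimated with kappa and alpha held
#' at the point estimates, and the expected node GC recomputed.
#'
#' @param fit \code{"gc_fit"}.
#' @param aln The alignment the fit used.
#' @param B Number of bootstrap replicates (default 100).
#' @param seed Integer seed.
#' @return List: \code{boot_mean}, \code{boot_sd} (per node), \code{theta_sd}
#'   (per class), \code{B}.
#' @export
gc_bootstrap <- function(fit, aln, B = 100L, seed = 0L) {
  tree <- fit$tree
  aln <- aln[tree$tip.label, , drop = FALSE]
  n_class <- n_classes(fit$classes)
  set.seed(seed)
  node_mat <- NULL
  theta_mat <- matrix(NA_real_, B, n_class)
  for (b in seq_len(B)) {
    idx <- sample.int(ncol(aln), ncol(aln), replace = TRUE)
    prep <- prepare_alignment(aln[, idx, drop = FALSE], tree)
    obj <- function(x) {
      th <- inv_logit(x[-1]); tr <- inv_logit(x[1])
      -gc_loglik_prepared(prep, tree, fit$classes, th, tr, fit$kappa,
                          if (fit$k > 1L) fit$alpha else 1, fit$k,
                          fit$p_inv)
    }
    x0 <- c(logit(fit$theta_root), logit(pmin(pmax(fit$theta, .02), .98)))
    o <- stats::optim(x0, obj, method = "L-BFGS-B", lower = -12, upper = 12,
                      control = list(factr = 1e9))
    theta_mat[b, ] <- inv_logit(o$par[-1])
    bfit <- fit
    bfit$theta <- stats::setNames(inv_logit(o$par[-1]), names(fit$theta))
    bfit$theta_root <- inv_logit(o$par[1])
    ngc <- node_gc_expected(bfit)
    if (is.null(node_mat)) node_mat <- matrix(NA_real_, B, length(ngc),
                                              dimnames = list(NULL,
                                                              names(ngc)))
    node_mat[b, ] <- ngc
  }
  list(boot_mean = colMeans(node_mat),
       boot_sd = apply(node_mat, 2, stats::sd),
       theta_sd = apply(theta_mat, 2, stats::sd), B = B)
}

#' Annotate a tree with ancestral GC and GC* labels
#'
#' Internal nodes are labelled \code{"GC(GC*)"} to two decimals (GC* of the
#' branch subtending the node; the root, which has no branch, is labelled
#' with its GC alone). With \code{tips = TRUE} tip labels become
#' \code{"taxon|GC(GC*)"}. Labels contain parentheses and are single-quoted
#' in the output, which \code{\link{read_newick}} parses back.
#'
#' @param rec \code{"gc_ancestral"} object.
#' @param tips Also annotate tip labels (default \code{FALSE}).
#' @param file Optional output path.
#' @return Newick string (invisibly if written to \code{file}).
#' @export
annotate_tree <- function(rec, tips = FALSE, file = NULL) {
  stopifnot(inherits(rec, "gc_ancestral"))
  tree <- rec$tree
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  if (length(rec$node_gc) != nn)
    stop("reconstruction does not cover all nodes")
  ## GC* of the branch above each node
  star <- rep(NA_real_, nn)
  star[tree$edge[, 2]] <- rec$branch_gc_star
  lab <- function(v) {
    if (is.na(star[v])) sprintf("%.2f", rec$node_gc[v])
    else sprintf("%.2f(%.2f)", rec$node_gc[v], star[v])
  }
  tr <- tree
  tr$node.label <- vapply(ntip + seq_len(tree$Nnode), lab, "")
  if (tips)
    tr$tip.label <- paste0(tree$tip.label, "|",
                           vapply(seq_len(ntip), lab, ""))
  write_newick(tr, file = file)
}

#' Write a per-node reconstruction table as TSV
#'
#' Columns: node id (taxon label for tips), GC, GC* of the subtending branch,
#' and, if a bootstrap is supplied, bootstrap mean and sd.
#'
#' @param rec \code{"gc_ancestral"}.
#' @param file Output path.
#' @param boot Optional result of \code{\link{gc_bootstrap}}.
#' @export
write_ancestral_table <- function(rec, file, boot = NULL) {
  tree <- rec$tree
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  star <- rep(NA_real_, nn)
  star[tree$edge[, 2]] <- rec$branch_gc_star
  d <- data.frame(node = names(rec$node_gc), gc = unname(rec$node_gc),
                  gc_star = star)
  if (!is.null(boot)) {
    d$boot_mean <- unname(boot$boot_mean)
    d$boot_sd <- unname(boot$boot_sd)
  }
  utils::write.table(d, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
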