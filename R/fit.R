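## ML fitting of the non-homogeneous T92 model on a fixed tree.
## Optimization runs in transformed coordinates (logit for theta, theta_root
## and p_inv; log for kappa and alpha) with L-BFGS-B and multiple starts.

#' Optimizer control for \code{\link{gc_fit}}
#'
#' @param n_starts Number of optimization starts (default 3: a neutral start,
#'   an empirical-composition start, and a perturbation of the best so far).
#' @param maxit Maximum L-BFGS-B iterations per start.
#' @param factr L-BFGS-B convergence factor (precision ~ \code{factr * 1e-16}
#'   on the objective).
#' @param perturb_sd Standard deviation of the Gaussian jitter, in transformed
#'   coordinates, used for restart starts.
#' @return List of control settings.
#' @export
gc_control <- function(n_starts = 3L, maxit = 1000L, factr = 1e7,
                       perturb_sd = 0.4) {
  list(n_starts = as.integer(n_starts), maxit = as.integer(maxit),
       factr = factr, perturb_sd = perturb_sd)
}

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

## pack/unpack parameter vectors; layout:
## [theta_root, theta_1..C, log kappa, log alpha?, logit p_inv?]
pack_params <- function(theta, theta_root, kappa, alpha, p_inv, k,
                        use_pinv) {
  x <- c(logit(theta_root), logit(theta), log(kappa))
  if (k > 1L) x <- c(x, log(alpha))
  if (use_pinv) x <- c(x, logit(max(p_inv, 1e-4)))
  x
}

unpack_params <- function(x, n_class, k, use_pinv) {
  theta_root <- inv_logit(x[1])
  theta <- inv_logit(x[2:(1 + n_class)])
  i <- 2 + n_class
  kappa <- exp(x[i]); i <- i + 1
  alpha <- if (k > 1L) { a <- exp(x[i]); i <- i + 1; a } else 1
  p_inv <- if (use_pinv) inv_logit(x[i]) else 0
  list(theta = theta, theta_root = theta_root, kappa = kappa,
       alpha = alpha, p_inv = p_inv)
}

## Empirical GC of the tips descending from each class's branches.
empirical_class_gc <- function(aln, tree, classes) {
  tipsets <- edge_tip_sets(tree)
  gc_of <- function(taxa) {
    s <- as.vector(aln[taxa, , drop = FALSE])
    n_gc <- sum(s == "G" | s == "C"); n_at <- sum(s == "A" | s == "T")
    if (n_gc + n_at == 0) return(0.5)
    n_gc / (n_gc + n_at)
  }
  vapply(seq_along(classes$labels), function(ci) {
    taxa <- unique(unlist(tipsets[classes$class == ci]))
    gc_of(taxa)
  }, 0)
}

#' Fit the non-homogeneous, non-stationary T92 model
#'
#' Maximum-likelihood estimation of one equilibrium GC (theta = GC*) per
#' branch class, a free root GC, and shared kappa and gamma shape, on a fixed
#' rooted tree. This is the non-stationary setting: the root composition is a
#' free parameter, so ancestral and present-day GC may differ, and the
#' non-homogeneous setting: branch classes may have different GC*.
#'
#' @param aln Character matrix alignment (taxa x sites), e.g. from
#'   \code{\link{read_alignment}} or \code{\link{simulate_alignment}}.
#' @param tree Rooted \code{"phylo"} tree with branch lengths, fixed during
#'   fitting.
#' @param scheme Branch-class scheme passed to \code{\link{branch_classes}},
#'   or an existing \code{"branch_classes"} object.
#' @param clades Clade definitions (for \code{scheme = "clades"}).
#' @param k Number of discrete-gamma categories (default 4; \code{k = 1}
#'   disables rate heterogeneity and drops alpha from the model).
#' @param p_inv Logical: include a proportion of invariant sites (default
#'   \code{FALSE}).
#' @param control See \code{\link{gc_control}}.
#' @param seed Seed for the stochastic restart jitter (default 0).
#' @param init Optional warm start: list with \code{theta} (per class),
#'   \code{theta_root}, \code{kappa}, \code{alpha}, \code{p_inv}; used as the
#'   first optimization start (how the model ladder chains its fits).
#' @return Object of class \code{"gc_fit"} with components \code{theta}
#'   (named per-class GC*), \code{theta_root}, \code{kappa}, \code{alpha},
#'   \code{p_inv}, \code{minus_lnL}, \code{df} (free parameter count),
#'   \code{convergence} and the class map. Methods: \code{print},
#'   \code{summary}, \code{coef}, \code{logLik}, \code{simulate},
#'   \code{predict} (ancestral node GC), \code{plot}.
#' @examples
#' tr <- read_newick("((A:0.3,B:0.3):0.2,(C:0.3,D:0.3):0.2);")
#' sim <- simulate_alignment(tr, n_sites = 300, theta = 0.6, seed = 1)
#' fit <- gc_fit(sim$alignment, tr, "homogeneous", k = 1)
#' coef(fit)
#' @export
gc_fit <- function(aln, tree, scheme = "homogeneous", clades = NULL,
                   k = 4L, p_inv = FALSE, control = gc_control(),
                   seed = 0L, init = NULL) {
  cl_map <- if (inherits(scheme, "branch_classes")) scheme
            else branch_classes(tree, scheme, clades)
  prep <- prepare_alignment(aln, tree)
  n_class <- n_classes(cl_map)
  k <- as.integer(k)
  use_pinv <- isTRUE(p_inv)

  negll <- function(x) {
    p <- unpack_params(x, n_class, k, use_pinv)
    ll <- tryCatch(
      gc_loglik_prepared(prep, tree, cl_map, p$theta, p$theta_root,
                         p$kappa, p$alpha, k, p$p_inv),
      error = function(e) -Inf)
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  emp <- empirical_class_gc(aln, tree, cl_map)
  emp <- pmin(pmax(emp, 0.02), 0.98)
  gc_all <- {
    s <- as.vector(aln)
    n_gc <- sum(s == "G" | s == "C"); n_at <- sum(s == "A" | s == "T")
    min(max(n_gc / max(n_gc + n_at, 1), 0.02), 0.98)
  }
  starts <- list(
    pack_params(emp, gc_all, 2, 1, 0.05, k, use_pinv),
    pack_params(rep(0.5, n_class), 0.5, 2, 1, 0.05, k, use_pinv))
  if (!is.null(init)) {
    th0 <- pmin(pmax(rep_len(init$theta, n_class), 0.02), 0.98)
    starts <- c(list(pack_params(
      th0, min(max(init$theta_root, 0.02), 0.98), init$kappa,
      if (is.null(init$alpha) || is.na(init$alpha)) 1 else init$alpha,
      if (is.null(init$p_inv)) 0.05 else max(init$p_inv, 1e-3),
      k, use_pinv)), starts)
  }

  oldseed <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                          globalenv())
  on.exit(if (!is.null(oldseed)) assign(".Random.seed", oldseed, globalenv()))
  set.seed(seed)

  best <- NULL
  n_starts <- max(1L, control$n_starts)
  for (i in seq_len(n_starts)) {
    x0 <- if (i <= length(starts)) starts[[i]]
          else best$par + stats::rnorm(length(best$par),
                                       sd = control$perturb_sd)
    o <- stats::optim(x0, negll, method = "L-BFGS-B",
                      lower = rep(-12, length(x0)),
                      upper = rep(12, length(x0)),
                      control = list(maxit = control$maxit,
                                     factr = control$factr))
    if (is.null(best) || o$value < best$value - 1e-9) best <- o
  }

  p <- unpack_params(best$par, n_class, k, use_pinv)
  names(p$theta) <- cl_map$labels
  df <- n_class + 1L + 1L + (k > 1L) + use_pinv
  structure(list(
    call = match.call(),
    theta = p$theta, theta_root = p$theta_root, kappa = p$kappa,
    alpha = if (k > 1L) p$alpha else NA_real_,
    p_inv = if (use_pinv) p$p_inv else 0,
    k = k, use_pinv = use_pinv,
    minus_lnL = best$value, df = df,
    convergence = best$convergence == 0L,
    optim_message = best$message, n_starts = n_starts,
    classes = cl_map, tree = tree,
    n_sites = prep$n_sites, n_patterns = prep$n_patterns,
    taxa = tree$tip.label), class = "gc_fit")
}

#' @export
print.gc_fit <- function(x, ...) {
  cat("Non-homogeneous T92 fit (", x$classes$scheme, " scheme, ",
      n_classes(x$classes), " branch class",
      if (n_classes(x$classes) > 1) "es", ")\n", sep = "")
  cat(sprintf("  -lnL: %.4f   free parameters: %d   sites: %d\n",
              x$minus_lnL, x$df, x$n_sites))
  cat(sprintf("  root GC: %.4f   kappa: %.3f", x$theta_root, x$kappa))
  if (x$k > 1L) cat(sprintf("   gamma alpha: %.3f", x$alpha))
  if (x$use_pinv) cat(sprintf("   p_inv: %.3f", x$p_inv))
  cat("\n  GC* per class:\n")
  print(round(x$theta, 4))
  if (!x$convergence)
    cat("  WARNING: optimizer did not report convergence\n")
  invisible(x)
}

#' @export
summary.gc_fit <- function(object, ...) {
  out <- list(fit = object,
              theta_table = data.frame(
                class = names(object$theta),
                n_branches = tabulate(object$classes$class,
                                      n_classes(object$classes)),
                gc_star = unname(object$theta)))
  class(out) <- "summary.gc_fit"
  out
}

#' @export
print.summary.gc_fit <- function(x, ...) {
  print(x$fit)
  cat("\nBranches per class:\n")
  print(x$theta_table, row.names = FALSE)
  invisible(x)
}

#' @export
coef.gc_fit <- function(object, ...) {
  out <- c(stats::setNames(object$theta,
                           paste0("theta.", names(object$theta))),
           theta_root = object$theta_root, kappa = object$kappa)
  if (object$k > 1L) out <- c(out, alpha = object$alpha)
  if (object$use_pinv) out <- c(out, p_inv = object$p_inv)
  out
}

#' @export
logLik.gc_fit <- function(object, ...) {
  structure(-object$minus_lnL, df = object$df, nobs = object$n_sites,
            class = "logLik")
}

#' @export
simulate.gc_fit <- function(object, nsim = 1, seed = 0L, n_sites = NULL,
                            ...) {
  n_sites <- if (is.null(n_sites)) object$n_sites else n_sites
  sims <- lapply(seq_len(nsim), function(i)
    simulate_alignment(object$tree, classes = object$classes,
                       theta = object$theta,
                       theta_root = object$theta_root,
                       kappa = object$kappa, alpha = object$alpha,
                       k = object$k, p_inv = object$p_inv,
                       n_sites = n_sites, seed = seed + i - 1L))
  if (nsim == 1L) sims[[1]] else sims
}

#' @export
predict.gc_fit <- function(object, type = c("node_gc", "branch_gc_star"),
                           ...) {
  type <- match.arg(type)
  if (type == "branch_gc_star") return(object$theta[object$classes$class])
  ancestral_gc(object)$node_gc
}

#' @export
plot.gc_fit <- function(x, ...) {
  rec <- ancestral_gc(x)
  tr <- x$tree
  ape::plot.phylo(tr, ...)
  ntip <- length(tr$tip.label)
  ape::nodelabels(sprintf("%.2f", rec$node_gc[(ntip + 1):length(rec$node_gc)]),
                  frame = "none", adj = c(1.1, -0.3), cex = 0.7)
  invisible(x)
}
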