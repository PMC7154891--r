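## Phylogenetically independent contrasts ("crunch"), PGLS under Brownian
## motion, Baron-Kenny mediation on contrasts, and Bonferroni flags.

#' Standardized phylogenetically independent contrasts
#'
#' Felsenstein's contrasts via \code{\link[ape]{pic}}: at each internal node
#' the difference of daughter values divided by the square root of the sum of
#' their (augmented) branch lengths. Polytomies are resolved arbitrarily
#' into zero-length branches plus a small epsilon so the algorithm and the
#' Brownian covariance stay defined.
#'
#' @param tree Rooted \code{"phylo"} with branch lengths.
#' @param trait Named numeric vector (names = tip labels), complete.
#' @return Numeric vector of n_tips - 1 standardized contrasts.
#' @export
pic_contrasts <- function(tree, trait) {
  tree <- resolve_polytomies(tree)
  trait <- check_trait(tree, trait)
  ape::pic(trait, tree, scaled = TRUE)
}

resolve_polytomies <- function(tree, eps = 1e-8) {
  if (!ape::is.binary(tree)) {
    tree <- ape::multi2di(tree, random = FALSE)
    tree$edge.length[tree$edge.length == 0] <- eps
  }
  if (any(tree$edge.length <= 0))
    stop("contrasts need positive branch lengths")
  tree
}

check_trait <- function(tree, trait) {
  if (is.null(names(trait))) stop("trait vector must be named by taxon")
  miss <- setdiff(tree$tip.label, names(trait))
  if (length(miss))
    stop("trait missing for: ", paste(miss, collapse = ", "))
  v <- trait[tree$tip.label]
  if (anyNA(v)) stop("trait contains missing values")
  v
}

#' Through-origin regression of contrasts ("crunch")
#'
#' Least squares with no intercept, as contrasts have arbitrary sign; the
#' slope t-test uses n - 1 degrees of freedom.
#'
#' @param cx,cy Equal-length contrast vectors (x and y).
#' @return List: \code{slope}, \code{se}, \code{t}, \code{p}, \code{r2},
#'   \code{n} (number of contrasts).
#' @export
crunch_regression <- function(cx, cy) {
  stopifnot(length(cx) == length(cy), length(cx) >= 3)
  if (all(cx == 0)) stop("undefined slope: all x contrasts are zero")
  fit <- stats::lm(cy ~ cx + 0)
  s <- summary(fit)
  list(slope = unname(stats::coef(fit)[1]),
       se = s$coefficients[1, 2],
       t = s$coefficients[1, 3],
       p = s$coefficients[1, 4],
       r2 = s$r.squared,
       n = length(cx))
}

#' Crunch analysis of two traits on a tree
#'
#' Contrasts for both traits followed by \code{\link{crunch_regression}}.
#'
#' @param tree Rooted tree.
#' @param x,y Named trait vectors.
#' @return As \code{\link{crunch_regression}}.
#' @export
crunch <- function(tree, x, y) {
  crunch_regression(pic_contrasts(tree, x), pic_contrasts(tree, y))
}

#' Phylogenetic generalized least squares under Brownian motion
#'
#' GLS of \code{y} on \code{x} with residual covariance proportional to the
#' shared path length matrix (\code{\link[ape]{vcv}}), i.e. the Brownian
#' motion expectation. With an intercept (the default) the slope is
#' algebraically identical to the through-origin crunch slope on contrasts.
#'
#' @param tree Rooted tree with branch lengths.
#' @param x,y Named trait vectors.
#' @param intercept Include an intercept (default \code{TRUE}).
#' @return List: \code{slope}, \code{intercept}, \code{se}, \code{t},
#'   \code{p}, \code{r2} (on the GLS-whitened scale), \code{n}.
#' @export
pgls <- function(tree, x, y, intercept = TRUE) {
  ## polytomies need no resolution here: the BM covariance is defined on
  ## multifurcating trees directly
  x <- check_trait(tree, x); y <- check_trait(tree, y)
  V <- ape::vcv(tree)
  L <- tryCatch(chol(V), error = function(e)
    stop("singular Brownian covariance (duplicate zero-length tips?)"))
  ## whiten: solve L' z = v
  wh <- function(v) backsolve(L, v, transpose = TRUE)
  X <- if (intercept) cbind(`(Intercept)` = 1, x = x) else cbind(x = x)
  Xw <- apply(X, 2, wh); yw <- wh(y)
  fit <- stats::lm(yw ~ Xw + 0)
  s <- summary(fit)
  i_x <- ncol(X)
  res <- s$coefficients
  list(slope = unname(res[i_x, 1]),
       intercept = if (intercept) unname(res[1, 1]) else 0,
       se = res[i_x, 2], t = res[i_x, 3], p = res[i_x, 4],
       r2 = s$r.squared, n = length(y))
}

#' Baron-Kenny mediation test on contrasts
#'
#' All three regressions run through the origin on standardized contrasts:
#' (i) y ~ x, (ii) mediator ~ x, (iii) y ~ x + mediator. The verdict is
#' \code{"mediated"} (full mediation) when (i) and (ii) are significant at
#' \code{alpha} but x's coefficient in (iii) is not; \code{"not mediated"}
#' otherwise. A Sobel z for the indirect path is reported as supplementary
#' output. When the mediator's contrasts are nearly collinear with x's
#' (|r| > 0.999) no verdict is given.
#'
#' @param tree Rooted tree.
#' @param x,mediator,y Named trait vectors.
#' @param alpha Significance level for the component tests (default 0.05).
#' @return Object of class \code{"gc_mediation"}: the three regressions,
#'   \code{direct_p} (x in (iii)), \code{indirect} (product of path
#'   estimates), \code{sobel_z}, \code{sobel_p}, \code{verdict}.
#' @export
mediation_test <- function(tree, x, mediator, y, alpha = 0.05) {
  cx <- pic_contrasts(tree, x)
  cm <- pic_contrasts(tree, mediator)
  cy <- pic_contrasts(tree, y)
  if (abs(stats::cor(cx, cm)) > 0.999)
    return(structure(list(verdict = NA_character_,
                          flag = "mediator collinear with x"),
                     class = "gc_mediation"))
  step1 <- crunch_regression(cx, cy)
  step2 <- crunch_regression(cx, cm)
  m3 <- stats::lm(cy ~ cx + cm + 0)
  s3 <- summary(m3)$coefficients
  direct_p <- s3["cx", 4]
  b_med <- s3["cm", 1]; se_med <- s3["cm", 2]
  a <- step2$slope; sa <- step2$se
  sobel_z <- (a * b_med) / sqrt(b_med^2 * sa^2 + a^2 * se_med^2)
  verdict <- if (step1$p < alpha && step2$p < alpha &&
                 direct_p >= alpha) "mediated" else "not mediated"
  structure(list(step_total = step1, step_x_to_m = step2,
                 direct_slope = s3["cx", 1], direct_p = direct_p,
                 mediator_slope = b_med, mediator_p = s3["cm", 4],
                 indirect = a * b_med,
                 sobel_z = sobel_z,
                 sobel_p = 2 * stats::pnorm(-abs(sobel_z)),
                 alpha = alpha, verdict = verdict, flag = NULL),
            class = "gc_mediation")
}

#' @export
print.gc_mediation <- function(x, ...) {
  if (!is.null(x$flag)) {
    cat("Mediation test: no verdict (", x$flag, ")\n", sep = "")
    return(invisible(x))
  }
  cat("Mediation test (contrasts, through-origin)\n")
  cat(sprintf("  total effect  p = %.4g\n", x$step_total$p))
  cat(sprintf("  x -> mediator p = %.4g\n", x$step_x_to_m$p))
  cat(sprintf("  direct effect p = %.4g (controlling for mediator)\n",
              x$direct_p))
  cat(sprintf("  indirect effect = %.4g (Sobel p = %.4g)\n",
              x$indirect, x$sobel_p))
  cat("  verdict:", x$verdict, "\n")
  invisible(x)
}

#' Strict Bonferroni significance flags
#'
#' Flags are \code{p < alpha_corrected}, a strict inequality (a p-value equal
#' to the corrected threshold is not significant). The comparative analyses
#' use 0.005 for the genome-feature arm and 0.008 for the six-way
#' concomitance arm.
#'
#' @param p_values Numeric vector in [0, 1].
#' @param alpha_corrected Corrected threshold.
#' @return Logical vector.
#' @export
bonferroni_flag <- function(p_values, alpha_corrected) {
  stopifnot(all(p_values >= 0 & p_values <= 1))
  p_values < alpha_corrected
}

#' Concomitance tests of GC content between data sets
#'
#' For each pair of GC tables (e.g. ribosomal subunits of different genetic
#' compartments) runs crunch and PGLS on the species shared by the pair,
#' under three topologies: the first set's tree, the second set's tree, and
#' a fixed topology with all branch lengths set to one. Significance uses a
#' strict Bonferroni threshold.
#'
#' @param gc_tables Named list of named numeric vectors (GC per species).
#' @param trees Named list of \code{"phylo"} trees, same names.
#' @param pairs List of length-2 character vectors naming table pairs;
#'   default: all pairwise combinations.
#' @param alpha Bonferroni-corrected threshold (default 0.008, i.e. 0.05
#'   over six comparisons, rounded as commonly reported).
#' @return Data frame: \code{pair}, \code{topology}, \code{method},
#'   \code{n}, \code{slope}, \code{r2}, \code{p}, \code{significant}.
#'   Pairs with fewer than 3 shared species are skipped with a warning.
#' @export
concomitance_suite <- function(gc_tables, trees, pairs = NULL,
                               alpha = 0.008) {
  stopifnot(identical(sort(names(gc_tables)), sort(names(trees))))
  if (is.null(pairs)) {
    nm <- names(gc_tables)
    pairs <- utils::combn(nm, 2, simplify = FALSE)
  }
  rows <- list()
  for (pr in pairs) {
    a <- pr[1]; b <- pr[2]
    shared <- intersect(names(gc_tables[[a]]), names(gc_tables[[b]]))
    if (length(shared) < 3L) {
      warning(sprintf("pair %s-%s: only %d shared species, skipped",
                      a, b, length(shared)))
      next
    }
    x <- gc_tables[[a]][shared]; y <- gc_tables[[b]][shared]
    topo <- list()
    topo[[paste0("tree_", a)]] <- ape::keep.tip(trees[[a]], shared)
    topo[[paste0("tree_", b)]] <- ape::keep.tip(trees[[b]], shared)
    unit <- topo[[1]]
    unit$edge.length <- rep(1, nrow(unit$edge))
    topo$unit_lengths <- unit
    for (tn in names(topo)) {
      cr <- crunch(topo[[tn]], x, y)
      pg <- pgls(topo[[tn]], x, y)
      rows[[length(rows) + 1L]] <- data.frame(
        pair = paste(a, b, sep = "-"), topology = tn,
        method = c("crunch", "pgls"),
        n = length(shared),
        slope = c(cr$slope, pg$slope),
        r2 = c(cr$r2, pg$r2),
        p = c(cr$p, pg$p))
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(NULL)
  out$significant <- bonferroni_flag(out$p, alpha)
  rownames(out) <- NULL
  out
}
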