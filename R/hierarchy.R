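## The hierarchical model ladder and likelihood-ratio tests.
## Five nested levels: homogeneous < clade level(s) (M1, M2, terminal
## clades) < one GC* per branch, each refining the branch-class partition of
## the previous one.

#' Published model-ladder reference values for five ribosomal data sets
#'
#' The -lnL values, deviances, degrees of freedom and p-values of the
#' five-level hierarchical ladder as published for the mitochondrial,
#' nuclear and plastid ribosomal subunit alignments of the Streptophyta
#' study this package models (mtLSU, mtSSU, nSSU, cpLSU, cpSSU). Used to
#' validate the package's LRT arithmetic against an external result: the
#' deviance and p-value columns are recomputable from the -lnL and df
#' columns alone.
#'
#' @return Data frame: \code{dataset}, \code{model}, \code{minus_lnL},
#'   \code{printed_deviance}, \code{printed_df}, \code{printed_p}.
#' @export
ribosomal_ladder <- function() {
  utils::read.delim(system.file("extdata", "ribosomal_ladder.tsv",
                                package = "gcstar"),
                    stringsAsFactors = FALSE)
}

#' Upper tail of the chi-square distribution
#'
#' The LRT p-value: \eqn{Q(df/2, x/2)}, computed by \code{pchisq} with
#' \code{lower.tail = FALSE}, which stays accurate deep in the far tail.
#'
#' @param x Deviance (>= 0).
#' @param df Degrees of freedom (>= 1).
#' @return Upper-tail probability.
#' @examples
#' chi2_upper_tail(16.58, 3)
#' @export
chi2_upper_tail <- function(x, df) {
  stopifnot(all(x >= 0), all(df >= 1))
  stats::pchisq(x, df, lower.tail = FALSE)
}

## Does the partition of `fine` refine the partition of `coarse`?
refines <- function(coarse, fine) {
  if (length(coarse$class) != length(fine$class)) return(FALSE)
  all(vapply(split(coarse$class, fine$class),
             function(v) length(unique(v)) == 1L, TRUE))
}

#' Likelihood-ratio test between two nested fits
#'
#' @param simple \code{"gc_fit"} under the coarser branch-class scheme.
#' @param complex \code{"gc_fit"} under a scheme refining the simpler one.
#' @return Object of class \code{"gc_lrt"}: \code{deviance}
#'   (\eqn{2(\ln L_c - \ln L_s)}), \code{df} (difference in free parameter
#'   count) and \code{p_value} (chi-square upper tail).
#' @examples
#' # deviance arithmetic on two -lnL values
#' 2 * (22486.50 - 22438.91)
#' @export
gc_lrt <- function(simple, complex) {
  stopifnot(inherits(simple, "gc_fit"), inherits(complex, "gc_fit"))
  if (!refines(simple$classes, complex$classes))
    stop("models are not nested: the complex scheme must refine the simple one")
  dev <- 2 * (simple$minus_lnL - complex$minus_lnL)
  if (dev < -1e-4)
    warning(sprintf(
      "negative deviance (%.4g): the complex fit did not reach the simple optimum",
      dev))
  df <- complex$df - simple$df
  if (df < 1L) stop("complex model adds no free parameters")
  structure(list(deviance = dev, df = df,
                 p_value = chi2_upper_tail(max(dev, 0), df),
                 simple = simple$classes$scheme,
                 complex = complex$classes$scheme),
            class = "gc_lrt")
}

#' @export
print.gc_lrt <- function(x, ...) {
  cat(sprintf("LRT %s vs %s: deviance %.2f on %d df, p = %.4g\n",
              x$simple, x$complex, x$deviance, x$df, x$p_value))
  invisible(x)
}

#' Fit the hierarchical ladder of branch-class models
#'
#' Fits, in order: the homogeneous model, one model per supplied clade level
#' (each level must refine the previous one), and the one-GC*-per-branch
#' model. Every fit is warm-started from the previous (coarser) level's
#' estimates; consecutive levels are compared by likelihood-ratio tests.
#'
#' @param aln Alignment matrix.
#' @param tree Rooted \code{"phylo"} tree.
#' @param clade_levels Named list of clade definitions, coarse to fine, e.g.
#'   \code{list(M1 = ..., M2 = ..., terminal_clades = ...)}; each element as
#'   accepted by \code{\link{branch_classes}(scheme = "clades")}. May be
#'   empty.
#' @param per_branch Include the per-branch top level (default \code{TRUE}).
#' @param k,p_inv,control,seed Passed to \code{\link{gc_fit}}.
#' @return Object of class \code{"gc_hierarchy"}: \code{fits} (named list of
#'   \code{"gc_fit"}), \code{table} (data.frame with columns \code{model},
#'   \code{minus_lnL}, \code{deviance}, \code{df}, \code{p_value}; deviance
#'   and p of each row test it against the row above), \code{lrt} (list of
#'   \code{"gc_lrt"}).
#' @export
gc_hierarchy <- function(aln, tree, clade_levels = list(),
                         per_branch = TRUE, k = 4L, p_inv = FALSE,
                         control = gc_control(), seed = 0L) {
  maps <- list(homogeneous = branch_classes(tree, "homogeneous"))
  for (nm in names(clade_levels))
    maps[[nm]] <- branch_classes(tree, "clades", clade_levels[[nm]])
  if (per_branch)
    maps$per_branch <- branch_classes(tree, "per_branch")
  if (length(maps) < 2L)
    stop("the ladder needs at least two levels")
  for (i in seq_along(maps)[-1])
    if (!refines(maps[[i - 1L]], maps[[i]]))
      stop(sprintf("level '%s' does not refine level '%s'",
                   names(maps)[i], names(maps)[i - 1L]))

  fits <- vector("list", length(maps))
  names(fits) <- names(maps)
  prev <- NULL
  for (i in seq_along(maps)) {
    init <- if (!is.null(prev)) {
      ## map coarse thetas onto the finer classes via the edge assignment
      th <- vapply(seq_len(n_classes(maps[[i]])), function(ci) {
        edges <- which(maps[[i]]$class == ci)
        mean(prev$theta[prev$classes$class[edges]])
      }, 0)
      list(theta = th, theta_root = prev$theta_root, kappa = prev$kappa,
           alpha = prev$alpha, p_inv = prev$p_inv)
    }
    fits[[i]] <- gc_fit(aln, tree, maps[[i]], k = k, p_inv = p_inv,
                        control = control, seed = seed, init = init)
    prev <- fits[[i]]
  }

  lrts <- vector("list", length(fits) - 1L)
  for (i in seq_along(lrts))
    lrts[[i]] <- gc_lrt(fits[[i]], fits[[i + 1L]])
  tab <- data.frame(
    model = names(fits),
    minus_lnL = vapply(fits, `[[`, 0, "minus_lnL"),
    deviance = c(NA, vapply(lrts, `[[`, 0, "deviance")),
    df = c(NA, vapply(lrts, `[[`, 0L, "df")),
    p_value = c(NA, vapply(lrts, `[[`, 0, "p_value")),
    row.names = NULL)
  structure(list(fits = fits, table = tab, lrt = lrts),
            class = "gc_hierarchy")
}

#' @export
print.gc_hierarchy <- function(x, digits = 4, ...) {
  cat("Hierarchical non-homogeneous model ladder\n")
  tab <- x$table
  tab$minus_lnL <- sprintf("%.2f", tab$minus_lnL)
  tab$deviance <- ifelse(is.na(tab$deviance), "",
                         sprintf("%.2f", tab$deviance))
  tab$df <- ifelse(is.na(tab$df), "", as.character(tab$df))
  tab$p_value <- ifelse(is.na(tab$p_value), "",
                        format(signif(tab$p_value, digits)))
  names(tab) <- c("model", "-lnL", "deviance", "df", "p")
  print(tab, row.names = FALSE, right = FALSE)
  invisible(x)
}

#' Write a ladder table as TSV
#' @param x \code{"gc_hierarchy"} object.
#' @param file Output path.
#' @export
write_hierarchy_table <- function(x, file) {
  utils::write.table(x$table, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
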