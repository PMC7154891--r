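## End-to-end orchestration: the genome-feature arm (features + contrasts +
## mediation) and the GC-model arm (model ladder + LRTs + ancestral
## reconstruction), with optional TSV/Newick output.

#' Run the genome-feature arm
#'
#' Builds the per-species feature table, derives the analysis traits
#' (log GL, pct_GC, pct_NC, log NRS; the two log transforms linearize the
#' strongly skewed length and count variables), then tests every trait pair
#' with three methods side by side: ordinary least squares on species
#' values, PGLS, and crunch on contrasts. The mediation chain
#' log NRS -> pct_NC -> pct_GC and the chain log NRS -> pct_NC -> log GL are
#' tested on contrasts.
#'
#' @param genomes Named list of genomes (see
#'   \code{\link{build_feature_table}}).
#' @param tree Rooted tree over the same species.
#' @param min_len Minimum repeat length (default 20).
#' @param alpha Bonferroni-corrected threshold for the feature arm
#'   (default 0.005).
#' @param out_dir Optional directory for TSV output.
#' @return List: \code{features} (table), \code{traits}, \code{regressions}
#'   (pair x method data.frame with slope, p, significance flag),
#'   \code{mediation} (named list of \code{"gc_mediation"}).
#' @export
run_features <- function(genomes, tree, min_len = 20L, alpha = 0.005,
                         out_dir = NULL) {
  miss <- setdiff(tree$tip.label, names(genomes))
  extra <- setdiff(names(genomes), tree$tip.label)
  if (length(miss) || length(extra))
    stop("species/tree mismatch; missing genomes: ",
         paste(miss, collapse = ", "), "; extra genomes: ",
         paste(extra, collapse = ", "))
  tab <- build_feature_table(genomes, min_len = min_len)
  keep <- tab$NRS > 0
  traits <- data.frame(log_gl = log(tab$GL), pct_gc = tab$pct_GC,
                       pct_nc = tab$pct_NC,
                       log_nrs = ifelse(keep, log(pmax(tab$NRS, 1)), NA),
                       row.names = rownames(tab))
  use <- rownames(traits)[stats::complete.cases(traits)]
  if (length(use) < 4L)
    stop("too few species with complete traits (need >= 4)")
  tr_use <- ape::keep.tip(tree, use)
  tv <- lapply(traits[use, ], function(col) stats::setNames(col, use))

  prs <- utils::combn(names(tv), 2, simplify = FALSE)
  rows <- list()
  for (pr in prs) {
    x <- tv[[pr[1]]]; y <- tv[[pr[2]]]
    ols <- summary(stats::lm(y ~ x))
    cr <- crunch(tr_use, x, y)
    pg <- pgls(tr_use, x, y)
    rows[[length(rows) + 1L]] <- data.frame(
      pair = paste(pr[1], pr[2], sep = "~"),
      method = c("ols", "pgls", "crunch"),
      slope = c(ols$coefficients[2, 1], pg$slope, cr$slope),
      r2 = c(ols$r.squared, pg$r2, cr$r2),
      p = c(ols$coefficients[2, 4], pg$p, cr$p))
  }
  reg <- do.call(rbind, rows)
  reg$significant <- bonferroni_flag(reg$p, alpha)
  rownames(reg) <- NULL

  med <- list(
    gc_via_nc = mediation_test(tr_use, tv$log_nrs, tv$pct_nc, tv$pct_gc,
                               alpha = alpha),
    gl_via_nc = mediation_test(tr_use, tv$log_nrs, tv$pct_nc, tv$log_gl,
                               alpha = alpha))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_feature_table(tab, file.path(out_dir, "features.tsv"))
    utils::write.table(reg, file.path(out_dir, "regressions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(features = tab, traits = traits, regressions = reg, mediation = med)
}

#' Run the GC-model arm
#'
#' Fits the hierarchical model ladder with LRTs between consecutive levels,
#' then reconstructs ancestral GC and branch GC* from the finest clade-level
#' fit (the terminal-clades model when supplied; otherwise the finest level
#' fitted) and emits the annotated tree.
#'
#' @param aln Alignment matrix.
#' @param tree Rooted tree.
#' @param clade_levels As in \code{\link{gc_hierarchy}}.
#' @param k,p_inv,control,seed Passed to the fits.
#' @param per_branch Include the per-branch ladder top (default \code{TRUE}).
#' @param out_dir Optional directory for the ladder TSV and annotated
#'   Newick.
#' @return List: \code{hierarchy} (\code{"gc_hierarchy"}),
#'   \code{reconstruction} (\code{"gc_ancestral"}), \code{newick}
#'   (annotated tree string).
#' @export
run_gc_models <- function(aln, tree, clade_levels = list(), k = 4L,
                          p_inv = FALSE, control = gc_control(),
                          seed = 0L, per_branch = TRUE, out_dir = NULL) {
  h <- gc_hierarchy(aln, tree, clade_levels, per_branch = per_branch,
                    k = k, p_inv = p_inv, control = control, seed = seed)
  rec_fit <- if (length(clade_levels))
    h$fits[[utils::tail(names(clade_levels), 1)]]
  else h$fits[[length(h$fits)]]
  rec <- ancestral_gc(rec_fit, force = TRUE)
  nw <- annotate_tree(rec)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_hierarchy_table(h, file.path(out_dir, "model_ladder.tsv"))
    writeLines(nw, file.path(out_dir, "ancestral_gc.nwk"))
    write_ancestral_table(rec, file.path(out_dir, "ancestral_gc.tsv"))
  }
  list(hierarchy = h, reconstruction = rec, newick = nw)
}
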