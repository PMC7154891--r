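## Synthetic-data generators: sequence alignments evolved under the
## branch-class T92 model, Brownian-motion trait sets with a planted
## mediation chain, and annotated genomes with planted repeats.

#' Simulate an alignment under the non-homogeneous T92 model
#'
#' Root states are drawn from the root composition (GC = \code{theta_root});
#' each site draws a discrete-gamma rate category (and, with probability
#' \code{p_inv}, evolves at rate zero); states then evolve down the tree with
#' the branch-specific transition matrices implied by each branch class's
#' theta and the shared kappa.
#'
#' @param tree Rooted \code{"phylo"} tree with branch lengths.
#' @param classes \code{"branch_classes"} map (default: homogeneous).
#' @param theta Per-class equilibrium GC (recycled to the class count).
#' @param theta_root Root GC content (default 0.5).
#' @param kappa Transition/transversion ratio (default 2).
#' @param alpha Gamma shape (default 1).
#' @param k Gamma categories (default 4; 1 disables heterogeneity).
#' @param p_inv Invariant-site proportion (default 0).
#' @param n_sites Number of sites.
#' @param seed Integer seed; the generator is a pure function of it.
#' @return List: \code{alignment} (character matrix), \code{params} (the true
#'   generating parameters), \code{site_rates} (per-site rate multipliers).
#' @export
simulate_alignment <- function(tree, classes = NULL, theta = 0.5,
                               theta_root = 0.5, kappa = 2, alpha = 1,
                               k = 4L, p_inv = 0, n_sites = 1000L,
                               seed = 0L) {
  if (is.null(classes)) classes <- branch_classes(tree, "homogeneous")
  n_class <- n_classes(classes)
  theta <- rep_len(theta, n_class)
  if (is.na(alpha)) { alpha <- 1; k <- 1L }
  set.seed(seed)
  g <- discrete_gamma_rates(alpha, k)
  cat_idx <- sample.int(k, n_sites, replace = TRUE, prob = g$weights)
  rates <- g$rates[cat_idx]
  if (p_inv > 0)
    rates[stats::runif(n_sites) < p_inv] <- 0
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  root <- ntip + 1L
  pi_root <- t92_frequencies(theta_root)
  states <- matrix(0L, nn, n_sites)
  states[root, ] <- sample.int(4L, n_sites, replace = TRUE, prob = pi_root)
  pre <- rev(reorder_postorder(tree))     # parents before children
  eig_cache <- list()
  urate <- sort(unique(rates))
  for (e in pre) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    th <- theta[classes$class[e]]
    key <- format(th, digits = 17)
    if (is.null(eig_cache[[key]])) eig_cache[[key]] <- t92_eigen(th, kappa)
    eig <- eig_cache[[key]]
    for (r in urate) {
      idx <- which(rates == r)
      if (!length(idx)) next
      P <- eig$right %*% (exp(eig$values * tree$edge.length[e] * r) *
                          eig$left)
      P[P < 0] <- 0
      P <- P / rowSums(P)
      ps <- states[p, idx]
      for (s in 1:4) {
        sel <- idx[ps == s]
        if (length(sel))
          states[ch, sel] <- sample.int(4L, length(sel), replace = TRUE,
                                        prob = P[s, ])
      }
    }
  }
  aln <- matrix(NUC[states[seq_len(ntip), , drop = FALSE]], ntip, n_sites,
                dimnames = list(tree$tip.label, NULL))
  list(alignment = aln,
       params = list(theta = theta, theta_root = theta_root, kappa = kappa,
                     alpha = alpha, k = k, p_inv = p_inv, seed = seed),
       site_rates = rates)
}

#' Simulate Brownian-motion traits with a planted mediation chain
#'
#' Generates per-species traits on the tree: an exogenous trait evolves by
#' Brownian motion (BM); downstream traits are linear functions of their
#' parents in the chain \code{log_nrs -> pct_nc -> pct_gc} plus independent
#' BM noise, and \code{pct_nc -> log_gl}. Setting a path coefficient to zero
#' removes that arrow, which is how null data sets are produced.
#'
#' @param tree Rooted \code{"phylo"} with positive branch lengths.
#' @param b_nrs_nc Path coefficient log_nrs -> pct_nc (default 1).
#' @param b_nc_gc Path coefficient pct_nc -> pct_gc (default 1).
#' @param b_nrs_gc Direct path log_nrs -> pct_gc (default 0: full mediation
#'   through pct_nc).
#' @param b_nc_gl Path coefficient pct_nc -> log_gl (default 1).
#' @param rate BM rate of the exogenous trait (variance per unit branch
#'   length, default 1).
#' @param noise BM rate of the independent noise added to each downstream
#'   trait (default 0.25).
#' @param seed Integer seed.
#' @return List: \code{traits} (data.frame, rows = species: \code{log_nrs},
#'   \code{pct_nc}, \code{pct_gc}, \code{log_gl}), \code{effects} (the true
#'   path coefficients).
#' @export
simulate_bm_traits <- function(tree, b_nrs_nc = 1, b_nc_gc = 1,
                               b_nrs_gc = 0, b_nc_gl = 1, rate = 1,
                               noise = 0.25, seed = 0L) {
  set.seed(seed)
  bm <- function(sigma2) rbm_tips(tree, sigma2)
  x <- bm(rate)                                  # log NRS
  m <- b_nrs_nc * x + bm(noise)                  # pct NC
  y <- b_nc_gc * m + b_nrs_gc * x + bm(noise)    # pct GC
  gl <- b_nc_gl * m + bm(noise)                  # log GL
  traits <- data.frame(log_nrs = x, pct_nc = m, pct_gc = y, log_gl = gl,
                       row.names = tree$tip.label)
  list(traits = traits,
       effects = list(b_nrs_nc = b_nrs_nc, b_nc_gc = b_nc_gc,
                      b_nrs_gc = b_nrs_gc, b_nc_gl = b_nc_gl,
                      rate = rate, noise = noise, seed = seed))
}

## One BM realization at the tips: independent Gaussian increments along
## branches, variance = sigma2 * branch length; root value 0.
rbm_tips <- function(tree, sigma2) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  val <- numeric(nn)
  pre <- rev(reorder_postorder(tree))
  for (e in pre) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    val[ch] <- val[p] + stats::rnorm(1, 0,
                                     sqrt(sigma2 * tree$edge.length[e]))
  }
  stats::setNames(val[seq_len(ntip)], tree$tip.label)
}

#' Generate a synthetic annotated genome with planted repeats
#'
#' Background sequence is i.i.d. at the target GC; exact repeat copies of the
#' requested lengths and orientations are planted at non-overlapping
#' positions; gene intervals covering the requested coding fraction are
#' written as GFF3. Spurious maximal repeats of planted-repeat length in
#' i.i.d. background are astronomically unlikely at these sizes, so the truth
#' record can be compared directly with detector output.
#'
#' @param length Genome length (bp).
#' @param gc Target GC fraction in (0, 1).
#' @param coding_fraction Fraction of the genome covered by gene features.
#' @param repeat_plan Data frame with columns \code{len} and \code{kind}
#'   (\code{"forward"}, \code{"reverse"}, \code{"complement"} or
#'   \code{"reverse_complement"}); one planted pair per row. \code{NULL} for
#'   none.
#' @param n_genes Number of gene intervals (default 5).
#' @param seed Integer seed.
#' @param fasta,gff Optional output paths; written when non-NULL.
#' @return List: \code{sequence} (character scalar), \code{annotations}
#'   (GFF3-style data.frame), \code{truth} (planted repeat table with
#'   positions, exact noncoding fraction, gene count).
#' @export
synth_genome <- function(length, gc = 0.5, coding_fraction = 0.5,
                         repeat_plan = NULL, n_genes = 5L, seed = 0L,
                         fasta = NULL, gff = NULL) {
  stopifnot(gc > 0, gc < 1, coding_fraction >= 0, coding_fraction <= 1)
  set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqv <- sample(NUC, length, replace = TRUE, prob = p)

  planted <- NULL
  if (!is.null(repeat_plan) && nrow(repeat_plan)) {
    need <- 2 * sum(repeat_plan$len)
    if (need > length * 0.8)
      stop("repeat plan infeasible: planted copies exceed 80% of the genome")
    ## carve non-overlapping slots, separated by >= 2 bp of background
    slots <- list()
    cursor <- 1L
    lens <- rep(repeat_plan$len, each = 2L)
    gap_total <- length - sum(lens)
    gaps <- floor(gap_total * diff(c(0, sort(stats::runif(base::length(lens))))))
    gaps <- pmax(gaps, 2L)
    for (i in seq_along(lens)) {
      cursor <- cursor + gaps[i]
      if (cursor + lens[i] - 1L > length)
        stop("repeat plan infeasible: copies do not fit in the genome")
      slots[[i]] <- c(cursor, cursor + lens[i] - 1L)
      cursor <- cursor + lens[i]
    }
    planted <- repeat_plan
    planted$start1 <- planted$start2 <- NA_integer_
    for (j in seq_len(nrow(repeat_plan))) {
      s1 <- slots[[2L * j - 1L]]; s2 <- slots[[2L * j]]
      unit <- sample(NUC, repeat_plan$len[j], replace = TRUE, prob = p)
      seqv[s1[1]:s1[2]] <- unit
      copy <- switch(repeat_plan$kind[j],
        forward = unit,
        reverse = rev(unit),
        complement = dna_complement(unit),
        reverse_complement = rev(dna_complement(unit)),
        stop("unknown repeat kind: ", repeat_plan$kind[j]))
      seqv[s2[1]:s2[2]] <- copy
      planted$start1[j] <- s1[1]; planted$start2[j] <- s2[1]
    }
  }
  sequence <- paste(seqv, collapse = "")

  ann <- NULL
  coding_bp <- round(length * coding_fraction)
  if (coding_bp > 0) {
    n_genes <- max(1L, min(as.integer(n_genes), coding_bp))
    glen <- diff(round(seq(0, coding_bp, length.out = n_genes + 1L)))
    spare <- length - coding_bp
    offsets <- diff(round(seq(0, spare, length.out = n_genes + 1L)))
    starts <- integer(n_genes); pos <- 1L
    for (i in seq_len(n_genes)) {
      pos <- pos + offsets[i]
      starts[i] <- pos
      pos <- pos + glen[i]
    }
    ann <- data.frame(
      seqid = "synthetic_genome", source = "gcstar", type = "gene",
      start = starts, end = starts + glen - 1L, score = ".",
      strand = rep_len(c("+", "-"), n_genes), phase = ".",
      attributes = sprintf("ID=gene%02d", seq_len(n_genes)))
    cds <- ann
    cds$type <- "CDS"
    cds$phase <- "0"
    cds$attributes <- sprintf("ID=cds%02d;Parent=gene%02d",
                              seq_len(n_genes), seq_len(n_genes))
    ann <- rbind(ann, cds)
    ann <- ann[order(ann$start, ann$type, decreasing = FALSE), ]
  }
  truth <- list(planted_repeats = planted,
                noncoding_fraction = 1 - coding_bp / length,
                n_genes = if (is.null(ann)) 0L
                          else sum(ann$type == "gene"),
                gc_target = gc, seed = seed)
  if (!is.null(fasta)) {
    m <- matrix(seqv, 1, dimnames = list("synthetic_genome", NULL))
    write_alignment(m, fasta)
  }
  if (!is.null(gff)) write_gff3(ann, gff)
  list(sequence = sequence, annotations = ann, truth = truth)
}

dna_complement <- function(x) chartr("ACGT", "TGCA", x)

#' Write gene annotations as GFF3
#' @param ann Data frame with the nine GFF3 columns.
#' @param file Output path.
#' @export
write_gff3 <- function(ann, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (!is.null(ann) && nrow(ann))
    utils::write.table(ann, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  invisible(file)
}
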