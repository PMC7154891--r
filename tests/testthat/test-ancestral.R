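## A hand-built converged-looking fit object, for tests that need exact
## parameter control without running the optimizer.
manual_fit <- function(tree, classes, theta, theta_root, kappa = 2,
                       alpha = 1, k = 4L, p_inv = 0) {
  structure(list(theta = setNames(theta, classes$labels),
                 theta_root = theta_root, kappa = kappa, alpha = alpha,
                 p_inv = p_inv, k = k, use_pinv = p_inv > 0,
                 minus_lnL = 0, df = length(theta) + 3L,
                 convergence = TRUE, classes = classes, tree = tree,
                 n_sites = 0L, n_patterns = 0L, taxa = tree$tip.label),
            class = "gc_fit")
}

test_that("expected node GC obeys the propagation limits", {
  tr <- read_newick("((A:0,B:2):500,C:1);")
  cl <- branch_classes(tr, "per_branch")
  ## edge order follows tree$edge; identify edges by child
  theta <- rep(0.8, 4)
  fit <- manual_fit(tr, cl, theta, theta_root = 0.3, k = 1L)
  gc <- gcstar:::node_gc_expected(fit)
  ntip <- 3
  expect_equal(unname(gc[ntip + 1]), 0.3)        # root = theta_root
  ## zero-length branch: child equals parent
  zero_edge <- which(tr$edge.length == 0)
  child0 <- tr$edge[zero_edge, 2]
  parent0 <- tr$edge[zero_edge, 1]
  expect_equal(gc[child0], gc[parent0], ignore_attr = TRUE)
  ## very long branch: child at the branch equilibrium
  long_edge <- which(tr$edge.length == 500)
  expect_equal(unname(gc[tr$edge[long_edge, 2]]), 0.8, tolerance = 1e-6)
})

test_that("node GC moves monotonically from parent toward branch theta", {
  cl_theta <- 0.9
  for (t_len in c(0.1, 0.5, 1, 3, 10)) {
    tr <- read_newick(sprintf("(A:%g,B:1);", t_len))
    cl <- branch_classes(tr, "homogeneous")
    fit <- manual_fit(tr, cl, cl_theta, theta_root = 0.2, k = 1L)
    gc <- gcstar:::node_gc_expected(fit)
    expect_gte(gc[["A"]], 0.2 - 1e-12)
    expect_lte(gc[["A"]], cl_theta + 1e-12)
  }
  ## longer branches get closer to theta
  gc_at <- vapply(c(0.1, 1, 5), function(t_len) {
    tr <- read_newick(sprintf("(A:%g,B:1);", t_len))
    fit <- manual_fit(tr, branch_classes(tr, "homogeneous"), 0.9, 0.2,
                      k = 1L)
    gcstar:::node_gc_expected(fit)[["A"]]
  }, 0)
  expect_true(all(diff(gc_at) > 0))
})

test_that("expected GC matches simulation along a single branch", {
  tr <- read_newick("(A:0.8,B:0.1);")
  cl <- branch_classes(tr, "homogeneous")
  fit <- manual_fit(tr, cl, 0.75, theta_root = 0.35, kappa = 2, k = 1L)
  gc <- gcstar:::node_gc_expected(fit)
  sim <- simulate_alignment(tr, cl, theta = 0.75, theta_root = 0.35,
                            kappa = 2, k = 1L, n_sites = 1e5, seed = 50)
  gc_sim <- mean(sim$alignment["A", ] %in% c("G", "C"))
  expect_equal(gc[["A"]], gc_sim, tolerance = 0.01)
})

test_that("marginal reconstruction is exact on a 2-taxon single site", {
  tr <- read_newick("(A:0.4,B:0.7);")
  cl <- branch_classes(tr, "per_branch")
  theta <- c(0.3, 0.8); kappa <- 2.5; theta_root <- 0.45
  fit <- manual_fit(tr, cl, theta, theta_root, kappa, k = 1L)
  aln <- matrix(c("G", "T"), 2, 1, dimnames = list(c("A", "B"), NULL))
  ## hand Bayes: posterior over root states given leaves
  th_A <- theta[cl$class[tr$edge[, 2] == 1]]
  th_B <- theta[cl$class[tr$edge[, 2] == 2]]
  PA <- t92_transition_prob(th_A, kappa, 0.4)
  PB <- t92_transition_prob(th_B, kappa, 0.7)
  pi_r <- t92_frequencies(theta_root)
  joint <- pi_r * PA[, "G"] * PB[, "T"]
  hand_root_gc <- sum((joint / sum(joint))[c("C", "G")])
  gc <- gcstar:::node_gc_marginal(fit, aln)
  expect_equal(unname(gc[3]), hand_root_gc, tolerance = 1e-12)
  ## leaves: the posterior is the observation
  expect_equal(unname(gc[c("A", "B")]), c(1, 0))
})

test_that("marginal reconstruction at leaves returns observed GC", {
  tr <- two_clade_tree()
  sim <- simulate_alignment(tr, theta = 0.6, n_sites = 400, seed = 51)
  fit <- manual_fit(tr, branch_classes(tr, "homogeneous"), 0.6, 0.5)
  gc <- gcstar:::node_gc_marginal(fit, sim$alignment)
  obs <- apply(sim$alignment, 1, function(r) mean(r %in% c("G", "C")))
  expect_equal(gc[names(obs)], obs, tolerance = 1e-12)
})

test_that("expected and marginal reconstructions agree on ample data", {
  tr <- four_clade_tree()
  cl <- branch_classes(tr, "clades", four_clade_defs())
  sim <- simulate_alignment(tr, cl, theta = c(0.3, 0.5, 0.6, 0.8),
                            theta_root = 0.45, n_sites = 2000, seed = 52)
  fit <- gc_fit(sim$alignment, tr, cl, control = gc_control(n_starts = 2),
                seed = 52)
  e <- ancestral_gc(fit)$node_gc
  m <- ancestral_gc(fit, "marginal", aln = sim$alignment)$node_gc
  ntip <- length(tr$tip.label)
  internal <- (ntip + 1):length(e)
  expect_lt(max(abs(e[internal] - m[internal])), 0.02)
})

test_that("branch GC* equals the fitted theta of the branch's class", {
  tr <- four_clade_tree()
  cl <- branch_classes(tr, "clades", four_clade_defs())
  fit <- manual_fit(tr, cl, c(0.2, 0.4, 0.6, 0.8), 0.5)
  rec <- ancestral_gc(fit)
  expect_equal(rec$branch_gc_star,
               unname(fit$theta[cl$class]))
})

test_that("annotated newick uses fixed two-decimal GC(GC*) labels", {
  tr <- read_newick("(A:1,B:1);")
  cl <- branch_classes(tr, "homogeneous")
  fit <- manual_fit(tr, cl, 0.48123, 0.5, k = 1L)
  rec <- ancestral_gc(fit)
  nw <- annotate_tree(rec, tips = TRUE)
  ## root label is its GC at 2 dp; 0.5 formats as "0.50"
  expect_match(nw, "0.50;", fixed = TRUE)
  expect_match(nw, "(0.48)", fixed = TRUE)
  ## round trip recovers the numbers
  tr2 <- read_newick(nw)
  expect_equal(tr2$node.label, "0.50")
  vals <- regmatches(tr2$tip.label,
                     regexpr("[0-9.]+\\(0\\.48\\)", tr2$tip.label))
  expect_length(vals, 2)
  ## incomplete reconstruction is refused
  rec_bad <- rec
  rec_bad$node_gc <- rec_bad$node_gc[-1]
  expect_error(annotate_tree(rec_bad), "cover")
})

test_that("site bootstrap spread brackets the point estimate", {
  tr <- two_clade_tree()
  cl <- branch_classes(tr, "clades", two_clade_defs())
  sim <- simulate_alignment(tr, cl, theta = c(0.35, 0.65), n_sites = 500,
                            seed = 53)
  fit <- gc_fit(sim$alignment, tr, cl, control = gc_control(n_starts = 1),
                seed = 53)
  boot <- gc_bootstrap(fit, sim$alignment, B = 30, seed = 53)
  rec <- ancestral_gc(fit)
  expect_equal(boot$B, 30)
  ## bootstrap mean within 2 SE of the point estimate at every node
  se <- boot$boot_sd / sqrt(boot$B)
  ok <- abs(boot$boot_mean - rec$node_gc) <= 2 * pmax(se, 1e-6) + 0.02
  expect_true(all(ok))
  expect_true(all(boot$theta_sd >= 0))
})

test_that("unconverged fits are refused unless forced", {
  tr <- two_clade_tree()
  fit <- manual_fit(tr, branch_classes(tr, "homogeneous"), 0.5, 0.5)
  fit$convergence <- FALSE
  expect_error(ancestral_gc(fit), "force")
  expect_s3_class(ancestral_gc(fit, force = TRUE), "gc_ancestral")
})
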