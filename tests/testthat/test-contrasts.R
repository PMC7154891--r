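test_that("contrast formula on a two-taxon tree", {
  tr <- read_newick("(A:1,B:1);")
  expect_equal(unname(pic_contrasts(tr, c(A = 3, B = 1))), sqrt(2))
  expect_equal(unname(pic_contrasts(tr, c(A = 5, B = 5))), 0)
})

test_that("contrasts are linear in the trait", {
  set.seed(70)
  tr <- random_rooted_tree(15)
  x <- setNames(rnorm(15), tr$tip.label)
  y <- setNames(rnorm(15), tr$tip.label)
  cxy <- pic_contrasts(tr, 2 * x - 3 * y)
  expect_equal(cxy, 2 * pic_contrasts(tr, x) - 3 * pic_contrasts(tr, y),
               tolerance = 1e-12)
})

test_that("BM-simulated contrasts are properly standardized", {
  set.seed(71)
  tr <- ape::rcoal(50)
  tr$tip.label <- paste0("s", 1:50)
  sim <- simulate_bm_traits(tr, seed = 71)
  x <- setNames(sim$traits$log_nrs, rownames(sim$traits))
  cx <- pic_contrasts(tr, x)
  ## no trend of |contrast| with node height under correct standardization
  ntip <- 50
  heights <- ape::node.depth.edgelength(tr)[(ntip + 1):(2 * ntip - 1)]
  r <- cor(abs(cx), heights[as.integer(names(cx)) - ntip])
  expect_lt(abs(r), 0.3)
})

test_that("crunch regression is exact on deterministic contrasts", {
  set.seed(72)
  cx <- rnorm(20)
  ## exact linear data: lm warns about a perfect fit, which is the point
  res <- suppressWarnings(crunch_regression(cx, 2 * cx))
  expect_equal(res$slope, 2)
  expect_equal(res$r2, 1)
  expect_lt(res$p, 1e-20)
  expect_error(crunch_regression(rep(0, 10), rnorm(10)), "undefined")
})

test_that("crunch slope equals the PGLS slope under BM covariance", {
  set.seed(73)
  for (i in 1:10) {
    tr <- random_rooted_tree(sample(10:30, 1))
    x <- setNames(rnorm(length(tr$tip.label)), tr$tip.label)
    y <- setNames(rnorm(length(tr$tip.label)), tr$tip.label)
    cr <- crunch(tr, x, y)
    pg <- pgls(tr, x, y)
    expect_equal(cr$slope, pg$slope, tolerance = 1e-8)
  }
})

test_that("pgls agrees with an independent GLS implementation", {
  skip_if_not_installed("nlme")
  set.seed(74)
  ## ultrametric tree: corBrownian is then exactly the BM covariance shape
  tr <- ape::rcoal(25)
  tr$tip.label <- paste0("s", 1:25)
  sim <- simulate_bm_traits(tr, seed = 74)
  x <- setNames(sim$traits$pct_nc, rownames(sim$traits))
  y <- setNames(sim$traits$pct_gc, rownames(sim$traits))
  pg <- pgls(tr, x, y)
  d <- data.frame(x = x, y = y, sp = names(x))
  g <- nlme::gls(y ~ x, data = d,
                 correlation = ape::corBrownian(1, tr, form = ~sp))
  expect_equal(pg$slope, unname(coef(g)[2]), tolerance = 1e-6)
  expect_equal(pg$p, summary(g)$tTable[2, 4], tolerance = 1e-5)
})

test_that("on a star tree with unit branches pgls reduces to OLS", {
  tr <- ape::stree(8, "star")
  tr$tip.label <- paste0("s", 1:8)
  tr$edge.length <- rep(1, nrow(tr$edge))
  set.seed(75)
  x <- setNames(rnorm(8), tr$tip.label)
  y <- setNames(rnorm(8), tr$tip.label)
  pg <- pgls(tr, x, y)
  ols <- lm(y ~ x)
  expect_equal(pg$slope, unname(coef(ols)[2]), tolerance = 1e-10)
  expect_equal(pg$p, summary(ols)$coefficients[2, 4], tolerance = 1e-10)
})

test_that("null contrasts give calibrated p-values", {
  set.seed(76)
  tr <- ape::rcoal(40)
  tr$tip.label <- paste0("s", 1:40)
  hits <- 0
  for (i in 1:200) {
    x <- gcstar:::rbm_tips(tr, 1)
    y <- gcstar:::rbm_tips(tr, 1)
    if (crunch(tr, x, y)$p < 0.05) hits <- hits + 1
  }
  expect_gte(hits / 200, 0.02)
  expect_lte(hits / 200, 0.09)
})

test_that("pgls recovers a planted slope", {
  set.seed(77)
  cover <- 0
  for (i in 1:50) {
    tr <- ape::rcoal(40)
    tr$tip.label <- paste0("s", 1:40)
    x <- gcstar:::rbm_tips(tr, 1)
    y <- 3 * x + gcstar:::rbm_tips(tr, 0.5)
    pg <- pgls(tr, x, y)
    if (abs(pg$slope - 3) <= 2 * pg$se) cover <- cover + 1
  }
  expect_gte(cover / 50, 0.9)
})

test_that("mediation verdicts match the generating structure", {
  set.seed(78)
  tr <- ape::rcoal(40)
  tr$tip.label <- paste0("s", 1:40)
  tv <- function(sim, nm) setNames(sim$traits[[nm]], rownames(sim$traits))
  ## planted full mediation chain
  sim <- simulate_bm_traits(tr, b_nrs_nc = 1, b_nc_gc = 1, b_nrs_gc = 0,
                            seed = 78)
  mt <- mediation_test(tr, tv(sim, "log_nrs"), tv(sim, "pct_nc"),
                       tv(sim, "pct_gc"))
  expect_equal(mt$verdict, "mediated")
  ## mediator unrelated to x and y
  simn <- simulate_bm_traits(tr, b_nrs_nc = 0, b_nc_gc = 0, b_nrs_gc = 0,
                             seed = 79)
  mtn <- mediation_test(tr, tv(simn, "log_nrs"), tv(simn, "pct_nc"),
                        tv(simn, "pct_gc"))
  expect_equal(mtn$verdict, "not mediated")
  ## deterministic direct path is retained
  x <- gcstar:::rbm_tips(tr, 1)
  m <- gcstar:::rbm_tips(tr, 1)
  mtd <- suppressWarnings(mediation_test(tr, x, m, x))
  expect_equal(mtd$verdict, "not mediated")
  expect_lt(mtd$direct_p, 1e-10)
  ## collinear mediator: flagged, no verdict
  mtc <- mediation_test(tr, x, x * (1 + 1e-9), m)
  expect_true(is.na(mtc$verdict))
})

test_that("bonferroni flags use a strict inequality", {
  expect_true(bonferroni_flag(0.004, 0.005))
  expect_true(bonferroni_flag(0.0079, 0.008))
  expect_false(bonferroni_flag(0.008, 0.008))
  expect_equal(bonferroni_flag(numeric(0), 0.005), logical(0))
  expect_error(bonferroni_flag(1.2, 0.005))
})

test_that("concomitance suite produces the full pair/topology/method grid", {
  set.seed(80)
  subunits <- c("mtSSU", "mtLSU", "cpSSU", "cpLSU")
  trees <- list(); gcs <- list()
  for (s in subunits) {
    tr <- ape::rcoal(12)
    tr$tip.label <- paste0("sp", 1:12)
    trees[[s]] <- tr
    gcs[[s]] <- gcstar:::rbm_tips(tr, 1)
  }
  pairs <- list(c("mtSSU", "mtLSU"), c("cpSSU", "cpLSU"),
                c("mtLSU", "cpLSU"), c("mtSSU", "cpSSU"))
  out <- concomitance_suite(gcs, trees, pairs = pairs)
  expect_equal(nrow(out), 4 * 3 * 2)
  expect_setequal(unique(out$method), c("crunch", "pgls"))
  ## one topology per subunit tree plus the shared unit-lengths mode
  expect_equal(length(unique(out$topology)), 5)
  ## identical GC vectors: slope 1, r2 1, significant
  gcs2 <- gcs; gcs2$mtLSU <- gcs$mtSSU
  out2 <- suppressWarnings(
    concomitance_suite(gcs2, trees, pairs = list(c("mtSSU", "mtLSU"))))
  expect_equal(out2$slope, rep(1, 6), tolerance = 1e-9)
  expect_true(all(out2$significant))
  ## too few shared species: skipped with a warning
  gcs3 <- gcs
  names(gcs3$mtLSU) <- paste0("other", 1:12)
  expect_warning(
    out3 <- concomitance_suite(gcs3, trees,
                               pairs = list(c("mtSSU", "mtLSU"))),
    "shared")
  expect_null(out3)
})
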