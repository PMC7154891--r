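test_that("gc_content handles plain and ambiguous sequences", {
  expect_equal(gc_content("GGCC"), 1)
  expect_equal(gc_content("ATAT"), 0)
  expect_equal(gc_content("ACGT"), 0.5)
  ## ambiguity codes excluded from numerator and denominator
  expect_equal(gc_content("ACGTNNNN"), 0.5)
  expect_error(gc_content("NNN"), "undefined")
})

test_that("noncoding fraction is a per-base union of gene intervals", {
  genes <- function(...) {
    iv <- list(...)
    data.frame(start = vapply(iv, `[`, 0, 1), end = vapply(iv, `[`, 0, 2))
  }
  expect_equal(noncoding_fraction(100, genes(c(1, 100))), 0)
  expect_equal(noncoding_fraction(100, NULL), 1)
  ## overlapping genes counted once: 1 - 150/200
  expect_equal(noncoding_fraction(200, genes(c(1, 100), c(51, 150))), 0.25)
  ## brute-force per-base oracle on random interval sets
  set.seed(60)
  for (i in 1:20) {
    n <- sample(1:6, 1)
    st <- sample(1:180, n, TRUE)
    en <- pmin(st + sample(0:40, n, TRUE), 200)
    covered <- logical(200)
    for (j in seq_len(n)) covered[st[j]:en[j]] <- TRUE
    expect_equal(noncoding_fraction(200, data.frame(start = st, end = en)),
                 1 - mean(covered))
  }
  ## invariant to order and to splitting a feature into adjacent parts
  a <- genes(c(10, 50), c(60, 80))
  b <- genes(c(60, 80), c(10, 30), c(31, 50))
  expect_equal(noncoding_fraction(100, a), noncoding_fraction(100, b))
  expect_error(noncoding_fraction(100, genes(c(90, 120))), "out of bounds")
  ## circular: origin-spanning feature split across the origin
  expect_equal(noncoding_fraction(100, genes(c(91, 110)), circular = TRUE),
               1 - 20 / 100)
})

test_that("maximal repeats agree exactly with brute force on all kinds", {
  set.seed(61)
  kinds <- c("forward", "reverse", "complement", "reverse_complement")
  for (rep in 1:10) {
    n <- sample(80:200, 1)
    v <- sample(c("A", "C", "G", "T"), n, TRUE, prob = runif(4, 0.5, 1.5))
    if (rep %% 2 == 0) {   # plant a repeat of a random kind
      L <- sample(10:18, 1)
      u <- v[2:(L + 1)]
      p <- sample(seq(L + 4, n - L), 1)
      v[p:(p + L - 1)] <- gcstar:::transform_seq(u, sample(kinds, 1))
    }
    for (ml in c(3, 5, 8)) {
      got <- find_maximal_repeats(v, ml, kinds)
      want <- brute_force_repeats(v, ml, kinds)
      expect_equal(got, want)
    }
  }
})

test_that("reported hits are maximal: extending one base breaks the match", {
  set.seed(62)
  v <- sample(c("A", "C", "G", "T"), 150, TRUE)
  v[30:44] <- v[90:104]   # force a forward repeat
  hits <- find_maximal_repeats(v, 6)
  expect_gt(nrow(hits), 0)
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    b <- gcstar:::transform_seq(v, h$kind)
    i1 <- h$start1; i2 <- h$start2; L <- h$length
    expect_true(all(v[i1:(i1 + L - 1)] == b[i2:(i2 + L - 1)]))
    if (i1 > 1 && i2 > 1) expect_false(v[i1 - 1] == b[i2 - 1])
    if (i1 + L <= length(v) && i2 + L <= length(b))
      expect_false(v[i1 + L] == b[i2 + L])
  }
})

test_that("a planted 20-mer pair is found as exactly one forward hit", {
  set.seed(63)
  repeat {
    x <- sample(c("A", "C", "G", "T"), 420, TRUE)
    u <- sample(c("A", "C", "G", "T"), 20, TRUE)
    s <- c(x[1:140], u, x[141:280], u, x[281:420])
    ## re-draw if flanks extend the planted match
    h <- find_maximal_repeats(s, 20, "forward")
    if (nrow(h) == 1 && h$length == 20) break
  }
  expect_equal(h$start2 - h$start1, 160L)
  ## a high-complexity random sequence has no 20 bp repeats
  r <- sample(c("A", "C", "G", "T"), 1000, TRUE)
  expect_equal(nrow(find_maximal_repeats(r, 20)), 0)
})

test_that("repeat_stats counts pairs and unions bases", {
  expect_equal(repeat_stats(NULL, "ACGT"),
               list(NRS = 0L, RSL = 0L, gc_in_repeats = NA_real_))
  ## one disjoint forward pair of length 30: union is 60 bases
  set.seed(64)
  x <- sample(c("A", "C", "G", "T"), 300, TRUE)
  u <- sample(c("A", "C", "G", "T"), 30, TRUE)
  s <- c(x[1:100], u, x[101:200], u, x[201:300])
  h <- find_maximal_repeats(s, 25, "forward")
  st <- repeat_stats(h, s)
  expect_equal(st$NRS, nrow(h))
  ## union length from a per-base marking oracle
  covered <- logical(length(s))
  b <- s
  for (i in seq_len(nrow(h))) {
    covered[h$start1[i]:(h$start1[i] + h$length[i] - 1)] <- TRUE
    covered[h$start2[i]:(h$start2[i] + h$length[i] - 1)] <- TRUE
  }
  expect_equal(st$RSL, sum(covered))
  expect_equal(st$gc_in_repeats, gc_content(s[covered]))
})

test_that("overlapping and nested hits are not double-counted in RSL", {
  ## tandem array: AB AB AB -> overlapping maximal hits
  unit <- strsplit("ACGGTTACGG", "")[[1]]
  s <- c(rep(unit, 4), strsplit("TTTTGGGACCCA", "")[[1]])
  h <- find_maximal_repeats(s, 8, "forward")
  st <- repeat_stats(h, s)
  covered <- logical(length(s))
  b <- s
  for (i in seq_len(nrow(h))) {
    covered[h$start1[i]:(h$start1[i] + h$length[i] - 1)] <- TRUE
    covered[h$start2[i]:(h$start2[i] + h$length[i] - 1)] <- TRUE
  }
  expect_equal(st$RSL, sum(covered))
  expect_lte(st$RSL, length(s))
})

test_that("feature tables carry all variables for synthetic genomes", {
  plan <- data.frame(len = c(60, 50), kind = c("forward",
                                               "reverse_complement"))
  gs <- list(
    sp1 = synth_genome(3000, gc = 0.35, coding_fraction = 0.6,
                       repeat_plan = plan, seed = 1),
    sp2 = synth_genome(2500, gc = 0.55, coding_fraction = 0.4, seed = 2),
    sp3 = synth_genome(2000, gc = 0.45, coding_fraction = 0, seed = 3))
  genomes <- lapply(gs, function(g)
    list(sequence = g$sequence, annotations = g$annotations))
  tab <- build_feature_table(genomes, min_len = 20)
  expect_equal(rownames(tab), c("sp1", "sp2", "sp3"))
  expect_named(tab, c("GL", "pct_GC", "pct_NC", "NPG", "NRS", "RSL",
                      "gc_in_repeats"))
  expect_equal(tab$GL, c(3000, 2500, 2000))
  ## noncoding fraction is exact by construction
  expect_equal(tab$pct_NC, c(0.4, 0.6, 1), tolerance = 1e-9)
  ## planted repeats are detected
  expect_gte(tab["sp1", "NRS"], 2)
  expect_equal(tab["sp2", "NRS"], 0)
  ## log transforms finite where NRS > 0
  expect_true(is.finite(log(tab["sp1", "NRS"])))
  expect_error(build_feature_table(genomes[c(1, 1)]), "duplicate")
})

test_that("gff3 written by the generator reads back via ape", {
  g <- synth_genome(1500, gc = 0.5, coding_fraction = 0.5, n_genes = 3,
                    seed = 4)
  fa <- withr::local_tempfile(fileext = ".fasta")
  gf <- withr::local_tempfile(fileext = ".gff3")
  g <- synth_genome(1500, gc = 0.5, coding_fraction = 0.5, n_genes = 3,
                    seed = 4, fasta = fa, gff = gf)
  ann <- read_gff3(gf)
  expect_equal(sum(ann$type == "gene"), 3)
  expect_equal(sum(ann$type == "CDS"), 3)
  tab <- build_feature_table(list(sp = list(fasta = fa, gff = gf)))
  expect_equal(tab$NPG, 3)
  expect_equal(tab$pct_NC, 0.5, tolerance = 1e-9)
})
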