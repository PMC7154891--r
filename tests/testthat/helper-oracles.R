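## Independent oracles used across the suite. These deliberately avoid the
## package's own algorithms: exhaustive enumeration for the likelihood, an
## O(n^4)-style pair scan for repeats, a hand-written recursive-descent
## Newick parser for tree round trips.

## --- exhaustive ancestral-state enumeration likelihood ---------------------
brute_force_loglik <- function(aln, tree, classes, theta, theta_root,
                               kappa, alpha = 1, k = 4) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  g <- discrete_gamma_rates(alpha, k)
  pi_r <- c((1 - theta_root) / 2, theta_root / 2, theta_root / 2,
            (1 - theta_root) / 2)
  aln <- aln[tree$tip.label, , drop = FALSE]
  code <- list(A = 1, C = 2, G = 3, T = 4,
               N = 1:4, R = c(1, 3), Y = c(2, 4))
  tot <- 0
  grid <- as.matrix(expand.grid(rep(list(1:4), tree$Nnode)))
  for (s in seq_len(ncol(aln))) {
    sl <- 0
    for (ci in seq_len(k)) {
      P <- lapply(seq_len(nrow(tree$edge)), function(e)
        t92_transition_prob(theta[classes$class[e]], kappa,
                            tree$edge.length[e] * g$rates[ci]))
      lik <- 0
      for (r in seq_len(nrow(grid))) {
        states <- integer(nn)
        states[(ntip + 1):nn] <- grid[r, ]
        term <- pi_r[states[ntip + 1]]
        for (e in seq_len(nrow(tree$edge))) {
          p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
          term <- term * if (ch <= ntip)
            sum(P[[e]][states[p], code[[aln[ch, s]]]])
          else P[[e]][states[p], states[ch]]
        }
        lik <- lik + term
      }
      sl <- sl + g$weights[ci] * lik
    }
    tot <- tot + log(sl)
  }
  tot
}

## --- brute-force maximal repeat enumeration --------------------------------
brute_force_repeats <- function(seq, min_len, kinds) {
  v <- gcstar:::as_base_vector(seq)
  n <- length(v)
  out <- list()
  for (kd in kinds) {
    b <- gcstar:::transform_seq(v, kd)
    m <- length(b)
    for (i in 1:(n - min_len + 1)) for (j in 1:(m - min_len + 1)) {
      if (kd == "forward" && j <= i) next
      L <- 0
      while (i + L <= n && j + L <= m && v[i + L] == b[j + L]) L <- L + 1
      if (L < min_len) next
      if (!(i == 1 || j == 1 || v[i - 1] != b[j - 1])) next  # left-maximal
      out[[length(out) + 1]] <- data.frame(start1 = i, start2 = j,
                                           length = L, kind = kd)
    }
  }
  if (!length(out))
    return(data.frame(start1 = integer(), start2 = integer(),
                      length = integer(), kind = character()))
  res <- do.call(rbind, out)
  res <- res[order(match(res$kind, kinds), res$start1, res$start2), ]
  rownames(res) <- NULL
  res
}

## --- independent recursive-descent Newick parser ---------------------------
## Returns a set of (sorted taxon set, branch length) pairs, one per edge,
## which identifies a rooted tree up to child order.
hand_parse_newick <- function(s) {
  s <- sub(";\\s*$", "", trimws(s))
  pos <- 1
  chars <- strsplit(s, "")[[1]]
  peek <- function() if (pos <= length(chars)) chars[pos] else ""
  advance <- function() { ch <- chars[pos]; pos <<- pos + 1; ch }
  edges <- list()
  parse_clade <- function() {
    taxa <- character(0)
    if (peek() == "(") {
      advance()
      repeat {
        taxa <- c(taxa, parse_clade())
        if (peek() == ",") { advance(); next }
        if (peek() == ")") { advance(); break }
        stop("parse failure at ", pos)
      }
      ## optional internal label
      while (!peek() %in% c(":", ",", ")", "")) advance()
    } else {
      lab <- character(0)
      while (!peek() %in% c(":", ",", ")", "")) lab <- c(lab, advance())
      taxa <- paste(lab, collapse = "")
    }
    len <- NA_real_
    if (peek() == ":") {
      advance()
      num <- character(0)
      while (grepl("[-0-9.eE+]", peek())) num <- c(num, advance())
      len <- as.numeric(paste(num, collapse = ""))
    }
    edges[[length(edges) + 1]] <<- list(taxa = sort(taxa), length = len)
    taxa
  }
  all_taxa <- parse_clade()
  list(edges = edges, taxa = sort(all_taxa))
}

fmt_len <- function(L) if (is.na(L)) "NA" else formatC(L, digits = 12,
                                                       format = "g")

edge_signature <- function(parsed) {
  sig <- vapply(parsed$edges, function(e)
    paste(paste(e$taxa, collapse = "|"), fmt_len(e$length), sep = "@"), "")
  sort(sig)
}

## signature of a phylo object in the same format
phylo_signature <- function(tree) {
  tips <- edge_tip_sets_for_test(tree)
  sig <- vapply(seq_len(nrow(tree$edge)), function(e)
    paste(paste(sort(tips[[e]]), collapse = "|"),
          fmt_len(tree$edge.length[e]), sep = "@"), "")
  ## the root also appears in hand_parse output (length NA)
  root_sig <- paste(paste(sort(tree$tip.label), collapse = "|"), "NA",
                    sep = "@")
  sort(c(sig, root_sig))
}

edge_tip_sets_for_test <- function(tree) {
  ntip <- length(tree$tip.label)
  pp <- ape::prop.part(tree)
  lapply(seq_len(nrow(tree$edge)), function(e) {
    ch <- tree$edge[e, 2]
    if (ch <= ntip) tree$tip.label[ch]
    else tree$tip.label[pp[[ch - ntip]]]
  })
}

## --- fixture builders ------------------------------------------------------
four_clade_tree <- function() {
  read_newick(paste0(
    "(((A1:0.2,A2:0.2):0.1,A3:0.3):0.5,((B1:0.2,B2:0.2):0.1,B3:0.3):0.5,",
    "(((C1:0.2,C2:0.2):0.1,C3:0.3):0.4,((D1:0.2,D2:0.2):0.1,D3:0.3):0.4)",
    ":0.3);"))
}

four_clade_defs <- function() {
  list(A = paste0("A", 1:3), B = paste0("B", 1:3),
       C = paste0("C", 1:3), D = paste0("D", 1:3))
}

two_clade_tree <- function() {
  read_newick(paste0(
    "(((E1:0.3,E2:0.3):0.2,(E3:0.3,E4:0.3):0.2):0.3,",
    "((F1:0.3,F2:0.3):0.2,(F3:0.3,F4:0.3):0.2):0.3);"))
}

two_clade_defs <- function() {
  list(E = paste0("E", 1:4), F = paste0("F", 1:4))
}

random_rooted_tree <- function(n, scale = 1) {
  tr <- ape::rtree(n, rooted = TRUE)
  tr$tip.label <- paste0("t", seq_len(n))
  tr$edge.length <- tr$edge.length * scale
  tr
}
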