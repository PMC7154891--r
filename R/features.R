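## Per-genome variables: genome length, GC content, non-coding fraction,
## protein-coding gene count, and maximal exact repeats (number, total
## length, GC within repeats) in the four orientations a repeat can take.

#' GC content of a nucleotide sequence
#'
#' Ambiguity codes are excluded from both numerator and denominator.
#'
#' @param seq Character scalar (a sequence string) or character vector of
#'   single bases.
#' @return (G + C) / (A + C + G + T), a fraction in [0, 1].
#' @examples
#' gc_content("GGCC")  # 1
#' gc_content("ACGT")  # 0.5
#' @export
gc_content <- function(seq) {
  v <- as_base_vector(seq)
  n_gc <- sum(v == "G" | v == "C")
  n_at <- sum(v == "A" | v == "T")
  if (n_gc + n_at == 0L)
    stop("GC content undefined: no unambiguous A/C/G/T bases")
  n_gc / (n_gc + n_at)
}

as_base_vector <- function(seq) {
  if (length(seq) == 1L && nchar(seq[1]) > 1L)
    seq <- strsplit(seq, "", fixed = TRUE)[[1]]
  toupper(seq)
}

#' Non-coding fraction of a genome
#'
#' One minus the fraction of bases covered by the union of the supplied gene
#' intervals; overlapping or book-ended features are counted once, so the
#' result is invariant to annotation order and to splitting a feature into
#' adjacent pieces. On a circular genome a feature may run past the end
#' (\code{end > genome_len}); it is split across the origin.
#'
#' @param genome_len Genome length in bp.
#' @param annotations Data frame with \code{start} and \code{end} (1-based,
#'   inclusive); typically the \code{type == "gene"} rows of a GFF3 table.
#' @param circular Allow origin-spanning features (default \code{FALSE}).
#' @return Fraction in [0, 1].
#' @export
noncoding_fraction <- function(genome_len, annotations, circular = FALSE) {
  if (is.null(annotations) || nrow(annotations) == 0L) return(1)
  st <- annotations$start; en <- annotations$end
  ids <- if (!is.null(annotations$attributes)) annotations$attributes
         else as.character(seq_along(st))
  bad <- which(st < 1 | st > genome_len | en < st |
               (!circular & en > genome_len) |
               (circular & en > 2 * genome_len))
  if (length(bad))
    stop("annotation interval out of bounds: ", ids[bad[1]])
  if (circular && any(en > genome_len)) {
    wrap <- en > genome_len
    st <- c(st[!wrap], st[wrap], rep(1L, sum(wrap)))
    en <- c(en[!wrap], rep(genome_len, sum(wrap)), en[wrap] - genome_len)
  }
  cov <- interval_union_length(st, en)
  1 - cov / genome_len
}

## total length of the union of closed integer intervals
interval_union_length <- function(start, end) {
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  tot <- 0; cur_s <- start[1]; cur_e <- end[1]
  for (i in seq_along(start)[-1]) {
    if (start[i] <= cur_e + 1) cur_e <- max(cur_e, end[i])
    else { tot <- tot + cur_e - cur_s + 1; cur_s <- start[i]; cur_e <- end[i] }
  }
  tot + cur_e - cur_s + 1
}

REPEAT_KINDS <- c("forward", "reverse", "complement", "reverse_complement")

transform_seq <- function(v, kind) {
  switch(kind,
         forward = v,
         reverse = rev(v),
         complement = dna_complement(v),
         reverse_complement = rev(dna_complement(v)),
         stop("unknown repeat kind: ", kind))
}

#' Find maximal exact repeats
#'
#' Reports every maximal exact repeat pair of length >= \code{min_len}
#' between the sequence and each requested transform of itself: forward
#' (within-sequence), reverse, complement and reverse-complement. A pair is
#' maximal when extending it by one base on either side breaks the match.
#' \code{start1} indexes the original sequence; \code{start2} indexes the
#' transformed copy (for forward repeats both index the original and
#' \code{start1 < start2}). Matches are located by seeding shared
#' \code{min_len}-mers and scanning the full match run on each seeded
#' diagonal, which yields exactly the maximal runs.
#'
#' @param seq Sequence string (or character vector of bases).
#' @param min_len Minimum repeat length in bp (>= 2). Practical settings for
#'   organellar genomes: 20 generally, 50-100 for highly repetitive ones.
#' @param kinds Subset of \code{"forward"}, \code{"reverse"},
#'   \code{"complement"}, \code{"reverse_complement"}.
#' @return Data frame: \code{start1}, \code{start2} (1-based), \code{length},
#'   \code{kind}; ordered by kind (in the order given), start1, start2.
#' @export
find_maximal_repeats <- function(seq, min_len = 20L,
                                 kinds = REPEAT_KINDS) {
  stopifnot(min_len >= 2L)
  kinds <- match.arg(kinds, REPEAT_KINDS, several.ok = TRUE)
  v <- as_base_vector(seq)
  out <- lapply(kinds, function(kd)
    maximal_matches(v, transform_seq(v, kd), min_len,
                    self = identical(kd, "forward"), kind = kd))
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(start1 = integer(), start2 = integer(),
                      length = integer(), kind = character())
  rownames(res) <- NULL
  res
}

## Maximal exact matches of length >= k between base vectors a and b.
## self = TRUE restricts to pairs with start1 < start2 (within-sequence
## repeats, excluding the trivial self-diagonal).
maximal_matches <- function(a, b, k, self, kind) {
  n <- length(a); m <- length(b)
  if (n < k || m < k) return(NULL)
  sa <- paste(a, collapse = ""); sb <- paste(b, collapse = "")
  ka <- substring(sa, 1:(n - k + 1), k:n)
  kb <- if (self) ka else substring(sb, 1:(m - k + 1), k:m)
  shared <- if (self) unique(ka[duplicated(ka)]) else intersect(ka, kb)
  if (!length(shared)) return(NULL)
  ia <- split(seq_along(ka), ka)[shared]
  ib <- if (self) ia else split(seq_along(kb), kb)[shared]
  diags <- unique(unlist(Map(function(p, q) {
    d <- as.vector(outer(q, p, "-"))
    if (self) d[d > 0] else d
  }, ia, ib)))
  hits <- list()
  for (d in diags) {
    ## positions p in a aligned with p + d in b
    lo <- max(1L, 1L - d); hi <- min(n, m - d)
    if (hi - lo + 1L < k) next
    run <- a[lo:hi] == b[(lo + d):(hi + d)]
    r <- rle(run)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    ok <- which(r$values & r$lengths >= k)
    for (j in ok)
      hits[[length(hits) + 1L]] <-
        c(lo + starts[j] - 1L, lo + starts[j] - 1L + d,
          r$lengths[j])
  }
  if (!length(hits)) return(NULL)
  h <- do.call(rbind, hits)
  res <- data.frame(start1 = h[, 1], start2 = h[, 2], length = h[, 3],
                    kind = kind)
  res[order(res$start1, res$start2), , drop = FALSE]
}

## Map a hit's second copy back to coordinates on the original sequence.
second_copy_interval <- function(start2, len, kind, n) {
  switch(kind,
         forward = c(start2, start2 + len - 1L),
         complement = c(start2, start2 + len - 1L),
         reverse = c(n - (start2 + len - 1L) + 1L, n - start2 + 1L),
         reverse_complement = c(n - (start2 + len - 1L) + 1L,
                                n - start2 + 1L))
}

#' Repeat summary statistics
#'
#' \code{NRS} counts maximal repeat pairs; \code{RSL} is the number of bases
#' of the original sequence covered by at least one repeat copy (a per-base
#' union, so overlapping and nested hits are not double-counted);
#' \code{gc_in_repeats} is the GC fraction over those bases.
#'
#' @param hits Data frame from \code{\link{find_maximal_repeats}}.
#' @param seq The sequence the hits refer to.
#' @return List with \code{NRS}, \code{RSL}, \code{gc_in_repeats}
#'   (\code{NA} when there are no hits).
#' @export
repeat_stats <- function(hits, seq) {
  v <- as_base_vector(seq)
  n <- length(v)
  if (is.null(hits) || nrow(hits) == 0L)
    return(list(NRS = 0L, RSL = 0L, gc_in_repeats = NA_real_))
  covered <- logical(n)
  for (i in seq_len(nrow(hits))) {
    covered[hits$start1[i]:(hits$start1[i] + hits$length[i] - 1L)] <- TRUE
    iv <- second_copy_interval(hits$start2[i], hits$length[i],
                               hits$kind[i], n)
    covered[iv[1]:iv[2]] <- TRUE
  }
  list(NRS = nrow(hits), RSL = sum(covered),
       gc_in_repeats = gc_content(v[covered]))
}

#' Read gene annotations from GFF3
#'
#' Wrapper around \code{\link[ape]{read.gff}} keeping the nine standard
#' columns.
#'
#' @param file GFF3 path.
#' @return Data frame with columns \code{seqid}, \code{source}, \code{type},
#'   \code{start}, \code{end}, \code{score}, \code{strand}, \code{phase},
#'   \code{attributes}.
#' @export
read_gff3 <- function(file) {
  g <- ape::read.gff(file, GFF3 = TRUE)
  names(g)[1] <- "seqid"
  g$type <- as.character(g$type)
  g$attributes <- as.character(g$attributes)
  g
}

## protein-coding genes: gene features with at least one CDS child
count_protein_genes <- function(ann) {
  if (is.null(ann) || nrow(ann) == 0L) return(0L)
  genes <- ann[ann$type == "gene", , drop = FALSE]
  if (!nrow(genes)) return(0L)
  gid <- sub(".*ID=([^;]+).*", "\\1", genes$attributes)
  cds_parent <- sub(".*Parent=([^;]+).*", "\\1",
                    ann$attributes[ann$type == "CDS"])
  sum(gid %in% cds_parent)
}

#' Per-genome feature table
#'
#' Computes, for each species, the genome variables used by the comparative
#' analyses: GL (genome length), pct_GC, pct_NC (non-coding fraction), NPG
#' (protein-coding gene count), NRS and RSL (maximal-repeat count and total
#' repeat-covered length), and the GC fraction within repeats.
#'
#' @param genomes Named list (one element per species); each element a list
#'   with either \code{fasta}/\code{gff} paths or \code{sequence} (string)
#'   and \code{annotations} (GFF3-style data.frame).
#' @param min_len Minimum repeat length for the repeat search (default 20).
#' @param kinds Repeat orientations to search (default all four).
#' @return Data frame keyed by species (rownames) with columns \code{GL},
#'   \code{pct_GC}, \code{pct_NC}, \code{NPG}, \code{NRS}, \code{RSL},
#'   \code{gc_in_repeats}.
#' @export
build_feature_table <- function(genomes, min_len = 20L,
                                kinds = REPEAT_KINDS) {
  if (anyDuplicated(names(genomes)))
    stop("duplicate species: ",
         paste(unique(names(genomes)[duplicated(names(genomes))]),
               collapse = ", "))
  rows <- lapply(names(genomes), function(sp) {
    g <- genomes[[sp]]
    seqv <- if (!is.null(g$sequence)) as_base_vector(g$sequence)
            else {
              a <- read_alignment(g$fasta, strip_gaps = FALSE)
              as.vector(a[1, ])
            }
    ann <- if (!is.null(g$annotations)) g$annotations
           else if (!is.null(g$gff)) read_gff3(g$gff)
    genes <- if (!is.null(ann)) ann[ann$type == "gene", , drop = FALSE]
    hits <- find_maximal_repeats(seqv, min_len = min_len, kinds = kinds)
    rs <- repeat_stats(hits, seqv)
    data.frame(GL = length(seqv),
               pct_GC = gc_content(seqv),
               pct_NC = noncoding_fraction(length(seqv), genes),
               NPG = count_protein_genes(ann),
               NRS = rs$NRS, RSL = rs$RSL,
               gc_in_repeats = rs$gc_in_repeats,
               row.names = sp)
  })
  do.call(rbind, rows)
}

#' Write a feature table as TSV
#' @param tab Data frame from \code{\link{build_feature_table}}.
#' @param file Output path.
#' @export
write_feature_table <- function(tab, file) {
  utils::write.table(cbind(species = rownames(tab), tab), file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file)
}
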