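---
title: "Modelling non-stationary GC evolution: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling non-stationary GC evolution: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcstar)
```

## The substitution model

The core of the package is a Tamura-92-type nucleotide model with two
parameters per process: the equilibrium GC content $\theta \in (0,1)$ and the
transition/transversion ratio $\kappa > 0$. Off-diagonal rates are
$q_{ij} = \kappa \pi_j$ for transitions and $q_{ij} = \pi_j$ for
transversions, with $\pi_G = \pi_C = \theta/2$ and
$\pi_A = \pi_T = (1-\theta)/2$. Each generator is scaled so that one unit of
branch length equals one expected substitution per site *at that generator's
own equilibrium*.

Two departures from the textbook stationary setting define the method:

* **Non-stationarity.** The root composition is a free parameter
  $\theta_{root}$, distinct from any branch's $\theta$. Ancestral and
  present-day GC may therefore differ, which is the phenomenon of interest.
* **Non-homogeneity.** Branches are partitioned into classes
  (`branch_classes()`), each with its own $\theta$; $\kappa$, the gamma
  shape $\alpha$ and $\theta_{root}$ are shared across the tree.

Within a branch the process is reversible (T92 satisfies detailed balance);
all non-stationary behaviour enters through the free root and the parameter
changes between branch classes.

The equilibrium GC frequency GC\* is defined from the class-switching rates:
$$\mathrm{GC}^* = \frac{r_{AT \to GC}}{r_{AT \to GC} + r_{GC \to AT}},$$
where $r_{AT \to GC}$ is the substitution rate from an A or T base into
$\{G, C\}$ and $r_{GC \to AT}$ the reverse. For the T92 generator these rates
are $\theta(1+\kappa)/2$ and $(1-\theta)(1+\kappa)/2$, so GC\* equals
$\theta$ identically — this is the identity that lets the fitted
$\theta$ of a branch class be reported directly as that branch's GC\*. (Note
that the *equilibrium flux* between the two classes is symmetric by detailed
balance; the definition above is a ratio of per-state rates, not of
stationary fluxes.)

Rate heterogeneity uses the standard discrete-gamma approximation with
$k = 4$ equal-weight categories whose rates are the conditional *means* of
the quantile bands (renormalised to average exactly one), plus an optional
proportion of invariant sites $p_{inv}$ fitted as a mixture component. The
choice of category means over medians follows the dominant convention in
likelihood phylogenetics; the mean-1 constraint keeps branch lengths
interpretable.

## Likelihood, fitting, and the model ladder

`gc_loglik()` runs Felsenstein pruning with a branch-specific transition
matrix per branch (its class $\theta$, the shared $\kappa$, branch length
times the category rate), sums the root partial likelihoods against the free
root composition, averages over gamma categories per site and sums site
logs. Transition matrices come from the spectral decomposition of the
symmetrised generator, which is exact and cheap for a 4-state reversible
matrix; the test suite pins it against an independent scaling-and-squaring
matrix exponential at $10^{-10}$.

`gc_fit()` maximises the likelihood in transformed coordinates (logit for
$\theta$, $\theta_{root}$, $p_{inv}$; log for $\kappa$, $\alpha$) with
L-BFGS-B. Three starts are used by default: an empirical start (per-class
observed GC of descendant tips), a neutral start
($\theta = 0.5, \kappa = 2, \alpha = 1$), and a Gaussian perturbation of the
best solution so far (sd 0.4 in transformed coordinates). Ladder fits warm
start from the next-coarser model's estimates mapped onto the finer
partition. Convergence is L-BFGS-B's relative criterion at
`factr = 1e7` (~1e-9 on the objective), comfortably inside the 1e-6
intended resolution on $-\ln L$; ties between starts are broken by the lower
$-\ln L$. A fit that never reports convergence is returned flagged, never
silently.

`gc_hierarchy()` fits the nested ladder — homogeneous, one or more named
clade levels (the coarse ten-group scheme, the same scheme with mosses and
liverworts split, a terminal-clades scheme), and one GC\* per branch — and
compares consecutive levels with likelihood-ratio tests: deviance
$2(\ln L_{complex} - \ln L_{simple})$ against $\chi^2$ with degrees of
freedom equal to the difference in free parameter count. Because $\kappa$,
$\alpha$ and $\theta_{root}$ are shared within a ladder, the df reduce to
the class-count difference. Published df values for such ladders depend on
which clades a particular data set contains; the package derives df from
the partitions it is actually given rather than hard-coding any table.

Branch-class schemes need a rule for backbone branches that lie between
named groups, which published descriptions leave open. The rule here: the
stem branch above a clade's MRCA belongs to that clade; a branch whose
descendant tips span several clades takes the earliest-listed of them.
Every branch is classified deterministically, and the assignment depends
only on the clade list order, not on the internal child order of the tree.

## Ancestral reconstruction

The primary reconstruction (`ancestral_gc()`, method `"expected"`) is
parametric: the root composition is propagated through each branch's
transition matrix, per gamma category, and the node GC is the
category-weighted G+C mass. It is deterministic given a fit, monotone along
each branch (GC moves from the parent value toward the branch's $\theta$,
never past it), and matches stochastic simulation along single branches.

As a cross-check, method `"marginal"` computes per-site marginal posterior
state distributions at every node with the standard inside/outside two-pass
algorithm (run with the same branch-specific matrices and root prior, with
category posteriors weighted per site) and averages the posterior G+C mass
over sites. At leaves this returns the observed GC by construction. On
simulated data of realistic length the two reconstructions agree to about
0.01-0.02; they answer slightly different questions (model expectation vs
data-conditioned posterior), and published figures do not say which one an
NHML-style analysis reports, so both are exposed.

The "pseudo-bootstrap" spread reported alongside reconstructions is a
nonparametric site bootstrap: resample alignment columns, re-estimate the
$\theta$ vector and $\theta_{root}$ with $\kappa$ and $\alpha$ fixed at
their point estimates, recompute node GC; B = 100 by default. The procedure
is named but not defined in the literature this package follows, so this
concrete definition was chosen for being cheap and honest about composition
uncertainty only.

`annotate_tree()` writes node labels `GC(GC*)` at two decimals, e.g.
`0.51(0.48)`. Such labels contain parentheses, so they are single-quoted in
the Newick output, and `read_newick()` accepts quoted labels back. This is
why the package carries its own small Newick writer: the standard writer in
ape sanitises label punctuation instead of quoting it.

## Genome features and the repeat finder

`build_feature_table()` computes, per genome: length (GL), GC fraction
(ambiguity codes excluded from numerator and denominator), non-coding
fraction (one minus the per-base union of annotated gene intervals, so
overlapping and split annotations count once), the number of
protein-coding genes (GFF3 `gene` features with a CDS child; rRNA/tRNA
genes are annotated separately and not counted), and repeat statistics.

The repeat finder reports **maximal exact repeat pairs** in the four
orientations a repeat can take: forward, reverse, complement and
reverse-complement — a pair is maximal when a one-base extension on either
side breaks the match. Matches are located by seeding shared
`min_len`-mers and scanning each seeded diagonal's full match run, which
yields exactly the maximal runs; the suite verifies exact agreement with a
brute-force enumerator over all position pairs on all four kinds.
Coordinates: `start1` indexes the original sequence; `start2` indexes the
transformed copy (for forward repeats both index the original, with
`start1 < start2`).

Two definitional choices deserve note, since the variables NRS and RSL are
used downstream without a precise published definition. NRS counts maximal
pairs (the natural output unit of a REPuter-style finder). RSL is the
number of bases covered by at least one repeat copy — a per-base union
mapped back to original coordinates — so nested and overlapping hits are
never double-counted and RSL can never exceed GL. Genomes are treated as
linear by default; a `circular` option lets origin-spanning gene features
be split across the origin. Practical minimum repeat lengths for organellar
genomes are 20 bp in general and 50-100 bp for highly repetitive ones.

## Comparative analyses

The feature arm relates the genome variables with three methods side by
side: ordinary least squares on species values, PGLS with Brownian-motion
covariance (shared path length), and "crunch" — through-origin regression
on standardized independent contrasts. GL and NRS are log-transformed
before analysis for linearity. The through-origin crunch slope and the
PGLS slope are algebraically identical under the Brownian model; the suite
checks the identity numerically at $10^{-8}$, which is also a strong
end-to-end check of both implementations.

Mediation follows Baron-Kenny on contrasts: (i) y ~ x, (ii) m ~ x,
(iii) y ~ x + m, all through the origin; "full mediation" requires (i) and
(ii) significant with x non-significant in (iii). A Sobel z accompanies the
verdict as supplementary output. A mediator nearly collinear with x
(|r| > 0.999) yields a flagged no-verdict rather than a misleading one.

Multiple testing uses fixed, strict Bonferroni thresholds: p < 0.005 in the
feature arm and p < 0.008 in the six-comparison concomitance arm (a p equal
to the threshold is not significant). The concomitance suite runs each
subunit pair under three topologies — each member's own tree and a
unit-branch-length topology — with both crunch and PGLS, on the species
shared by the pair.

Polytomies are resolved arbitrarily into zero-length branches plus an
epsilon of 1e-8 before contrasts are computed; PGLS needs no resolution
because the Brownian covariance is defined on multifurcating trees
directly.

## Synthetic data: what it emulates and what it does not

`simulate_alignment()` draws root states from the root composition, a gamma
category (and possibly an invariant flag) per site, and evolves states down
the tree with the exact branch transition matrices — the same regime the
estimator assumes, which is what parameter-recovery and calibration
claims require. `simulate_bm_traits()` generates the trait chain
log NRS → %NC → %GC (and %NC → log GL) as Brownian motion plus planted
linear effects, so mediation detection can be scored against ground truth.
`synth_genome()` plants exact repeat pairs in i.i.d. background sequence at
a target GC; at the lengths used, spurious maximal repeats of planted size
are vanishingly unlikely, so detector output can be compared to the truth
record directly. All generators are pure functions of their seed.

None of this reproduces the texture of real organellar data: no codon
structure, no RNA editing, no gene-order evolution, no alignment error, no
among-site compositional heterogeneity beyond the gamma mixture. Passing
tests therefore demonstrate correctness of the algorithms under the model's
own assumptions, not robustness to their violation.

## Validation problem sizes

The suite validates: pruning against exhaustive ancestral-state enumeration
on trees of 3-5 leaves (20 random instances, tolerance 1e-8); the
stationary special case against an independent stationary T92+$\Gamma$
implementation (phangorn) at 1e-8; clade-$\theta$ recovery on a 12-taxon,
4-clade tree with $\theta \in \{0.2, 0.4, 0.6, 0.8\}$ at 2000 sites
(20 replicates, MAE well under 0.05); LRT type-I error under a homogeneous
null on an 8-taxon tree at 1000 sites (50 replicates, rate within
[0.01, 0.12] at $\alpha = 0.05$); mediation detection on 40-leaf coalescent
trees (50 replicates, detection above 80%); and repeat finding against
brute force on sequences up to 200 bp for all four kinds and
`min_len` of 3, 5 and 8. These sizes were chosen so each property is
measured with adequate replication while the whole suite stays quick to
run on one core.

## Known limitations

* Branch lengths are taken as given (the intended workflow re-optimises
  them upstream); joint branch-length estimation is not implemented.
* The ladder's df accounting assumes $\kappa$ and $\alpha$ shared across
  levels; software that re-estimates them per level would print different
  df for the same comparisons.
* The repeat finder is exact-match only; degenerate (mismatch-tolerant)
  repeats and E-value statistics are out of scope.
* GC reconstruction assumes the T92 composition symmetry (A = T, G = C
  within a class); strand-asymmetric processes are not representable.
```{r session}
sessionInfo()
```
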