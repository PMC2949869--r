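---
title: "Methods: mtDNA phylogeography with mtphylogeo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mtDNA phylogeography with mtphylogeo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtphylogeo)
```

`mtphylogeo` implements the analysis chain of a single-locus mtDNA
phylogeography study of a widespread, geographically structured species:
summarize sequence variation, quantify how molecular variance is
apportioned across nested geographic levels, test for departures from
demographic equilibrium, visualize haplotype relationships as a network,
and confront explicit biogeographic hypotheses with the genealogy through
coalescent simulation. The worked system throughout is a continent-wide
cytochrome-b survey of the lowland tapir (*Tapirus terrestris*): 45
haploid sequences of 1,068 unambiguous sites from 12 sampling sites in 4
geographic regions (plus 3 mountain-tapir sequences), and that survey's
sampling design is the package's default synthetic configuration.

## Sequence summaries and haplotypes

All site-based statistics use **complete deletion**: any column containing
a gap, `N`, or IUPAC ambiguity code in any sequence is removed before
counting, and haplotype identity is evaluated on the retained columns
only. This makes counts reproducible from "unambiguous bases" and means a
single ambiguous read cannot split a haplotype class. Polymorphic sites
are classified per column: biallelic sites are transitions ({A,G} or
{C,T}) or transversions; sites with three or more observed bases are
tallied separately as multiallelic, so `S = ti + tv + multiallelic` holds
by construction.

Gene diversity is Nei's unbiased estimator
$H_d = \frac{n}{n-1}\bigl(1 - \sum_i p_i^2\bigr)$, whose value on the
survey's published haplotype table reproduces the printed group values
(0.988 overall, 1.000 western Amazonia, 0.923 north Amazonia, ...).
Nucleotide diversity is the uncorrected per-site mean pairwise difference
$\pi = \bar k / L$ with $\bar k$ computed from haplotype counts
($\sum_{i<j} c_i c_j d_{ij} / \binom{n}{2}$); no multiple-hit correction
is applied because the target quantity is the descriptive per-site mean.
Standard deviations follow Nei's (1987) variance formulas, the convention
of DnaSP/Arlequin; they are reported as context, not tested quantities,
because the variance estimator convention differs across programs.

## AMOVA, pairwise Phi, SAMOVA

The molecular variance analysis treats the pairwise number of nucleotide
differences as a squared distance (the Arlequin default for haplotype
data; no model correction). Variance components for the two-level
hierarchy (groups / populations / samples) come from the standard sums of
squared deviations with the usual unequal-sample-size coefficients, and
the fixation indices are
$\Phi_{CT} = \sigma^2_a/\sigma^2_T$,
$\Phi_{SC} = \sigma^2_b/(\sigma^2_b+\sigma^2_c)$,
$\Phi_{ST} = (\sigma^2_a+\sigma^2_b)/\sigma^2_T$. Negative estimates are
reported unclamped — they are legitimate outcomes of the
method-of-moments estimators on weakly structured data. Permutation
schemes differ per statistic (samples among populations for
$\Phi_{ST}$; samples among populations within groups for $\Phi_{SC}$;
whole populations among groups for $\Phi_{CT}$), and p-values carry a +1
pseudo-count. The default of 10,000 permutations matches common practice;
tests in this package run far fewer because they check calibration, not
publication-grade significance.

SAMOVA searches for the partition of sampling sites into `K` groups
maximizing $\Phi_{CT}$, constrained to geographic contiguity on the
Delaunay triangulation of site coordinates. Coordinates are treated as
planar (a flagged approximation at continental scale; the original
construction is planar as well, and at K of a few the graph topology, not
metric detail, is what matters). The triangulation is computed by the
direct empty-circumcircle test — at a dozen sites the quartic cost is
irrelevant and the implementation is transparent; collinear degeneracies
fall back to a Euclidean minimum spanning tree so the adjacency graph is
always connected. Annealing uses geometric cooling (T0 = 1, ratio 0.9,
10 moves per temperature, stop below 1e-3) and independent restarts
(default 100), each chain proposing single-site moves that keep both
source and target groups connected; the best partition across chains
wins, ties to the first found under the seeded RNG.

## Neutrality tests

Tajima's D uses the textbook constants; Fu's Fs is computed from the
Ewens sampling formula with $\theta$ estimated by $\bar k$:
$S' = P(K \ge k_{obs})$ evaluated through unsigned Stirling numbers of
the first kind in log space (log-sum-exp recursion), which stays finite
for samples of a few hundred. Significance comes from constant-size
neutral coalescent simulation conditioned on the observed sample size and
on $\theta = \bar k$ — the "simulate given theta" convention of the
Arlequin lineage — with a fixed-S option; both statistics use lower-tail
p-values because significantly negative values are the expansion signal
of interest. Each simulated dataset re-estimates its own $S$, $\bar k$,
and haplotype count from the infinite-sites mutations, so the null
distribution reflects estimation noise as the real test does.

## Gene trees

The observed genealogy for the migration-count test is a UPGMA tree on
F84 distances with one tip per (haplotype, sampling site) occurrence —
shared haplotypes contribute one tip per site of occurrence, so the
geography character is well defined at every tip. F84 distances come from
`ape` (empirical base frequencies, complete deletion); saturated pairs
are flagged and by default replaced by the largest finite distance with a
warning, which keeps the clustering usable while making the pathology
visible. UPGMA sorts labels lexicographically before clustering so tied
agglomerations resolve deterministically. Whether the published s = 4 was
computed on this distance tree or on a Bayesian tree is not recoverable;
the package computes it on the UPGMA genealogy and exposes every step so
the sensitivity is easy to probe.

## Structured coalescent and the migration-count test

`simulate_gene_tree()` implements the structured coalescent without
migration on a population tree: within a population of haploid size
`Ne`, k lineages coalesce at rate $k(k-1)/(2N_e)$ per generation;
lineage sets merge at divergence times; the root population always
coalesces the remainder. mtDNA is haploid and maternally inherited, so
all `Ne` values are haploid (female effective) sizes — the scenario grid
values 10,000 and 1,000,000 are read this way.

The Slatkin–Maddison statistic s is the Fitch parsimony count of the
unordered deme character on the genealogy. Polytomies are resolved at
random under a seed and the minimum over resolutions reported; an
optional step-matrix (Sankoff) mode takes inter-deme costs, e.g. path
lengths on a hypothesis tree, but the default is the unordered count —
the standard Mesquite behaviour, and the reading under which both
alternative hypotheses imply the same four regional character states. The
null of allopatric fragmentation is modeled as a simultaneous four-way
split of the regional demes at the stated time, ancestral size equal to
the per-deme size — the hypothesis fixes no internal topology, so the
least-committal model is used, and this under-specification is the main
reason simulated null means can shift by a few units between
implementations while the test outcome (observed s far below the null's
0.5th percentile) is robust. The test's p-value is the lower-tail
fraction $P(s_{null} \le s_{obs})$, and the 99% interval is the
empirical 0.5–99.5 percentile range of attained null values. The
published generation counts for the scenario grid (1,250 and 375,000)
are used verbatim even though they are not the quotient of the stated
calendar times by the 10-year generation time; they are the scenario
definitions, not derived quantities.

Internal divergence times of the two structured hypotheses (gradient
first / river first) are evenly spaced at 2/3 and 1/3 of the root time:
the hypotheses specify branching order only, and even spacing adds no
extra structure.

## The synthetic generator

`generate_study()` draws one structured-coalescent genealogy over the 12
sampling sites (each site a deme; sites of a region split from their
regional ancestor 250 generations back, a within-region depth chosen
shallow relative to the regional split so that region-level structure
dominates) and evolves sequences along it under HKY. Defaults are the
survey conditions: 45 samples split 6/2/2/6/2/13/3/3/2/1/1/4 across
sites, L = 1,068, base frequencies A 0.298, C 0.286, G 0.130, T 0.286
(the observed composition with its bias against guanine), kappa = 20
(reflecting the observed 61:3 transition:transversion ratio), mutation
rate 2.5e-7 substitutions/site/generation (the internally calibrated
2.5e-2 substitutions/site/My at a 10-year generation), and the
allopatric tree at 1,250 generations with Ne = 10,000. Under these
conditions realized nucleotide diversity averages ~0.005–0.006 with
haplotype diversity ~0.93 — inside the survey's regime (within ±50% of
π = 0.009, H_d high) though below its point estimates, as expected when
the shallow-split scenario is taken at face value.

Substitution is simulated exactly: the HKY rate matrix is scaled so the
stationary substitution rate equals `mu`, and each site's end-of-branch
base is drawn from $e^{Qt}$ via the symmetrized eigendecomposition. This
is equivalent in distribution to event-by-event simulation but exact for
long branches and fast for 1,068 sites. Rate heterogeneity (Gamma or
invariant sites) is deliberately omitted: it would blur the analytic
checks (stationarity, divergence linearity) the generator is tested
against, and none of the downstream statistics require it. The generator
does not emulate sequencing error, indels, heteroplasmy, or nuclear
copies — so green tests say the estimators work on clean alignments of
the study's shape, not that they are robust to those artifacts.

## Problem sizes and determinism

Every stochastic routine takes a seed and is bit-reproducible given one.
The shipped checks use sizes chosen to make each property decisive yet
quick: exhaustive Fitch-vs-brute-force on all rooted 4- and 5-tip shapes
(with sampled 6-tip cases), brute-force AMOVA components at up to 20
samples, 10,000-replicate TMRCA calibration at n = 2/5/10,
2,000-replicate Tajima's D null, 10-dataset SAMOVA recovery with 5
restarts each, and a 1,000-replicate migration-count null at the survey's
sample sizes.

## Limitations

Single locus, modest n: all the usual caveats of one-gene phylogeography
apply, and the package quantifies only what the locus can show. The
Bayesian machinery of the original workflow (divergence dating, skyline
plots, model selection, ML/MP tree search) is out of scope by design —
the distance genealogy is used where a tree is needed. SAMOVA p-values
permute whole sites among groups and are coarse when sites are few; and
with 12 sites the partition space at small K is small enough that the
annealing is effectively exhaustive, which is a feature at survey scale
but says nothing about hundreds of demes.
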