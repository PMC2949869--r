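# mtphylogeo

Mitochondrial-DNA phylogeography for geographically structured
populations, in one tested R package. `mtphylogeo` is aimed at population
geneticists analysing single-locus surveys of widespread species: it
covers haplotype summaries and diversity, hierarchical population
structure, demographic-equilibrium tests, haplotype networks, distance
genealogies, and coalescent-simulation tests of biogeographic hypotheses.
Its running example — and default synthetic configuration — is a
continent-wide cytochrome-b survey of the lowland tapir (*Tapirus
terrestris*): 45 haploid sequences of 1,068 sites from 12 sampling sites
in 4 geographic regions.

What it computes:

- **Sequence variation** — haplotype collapsing under complete deletion of
  ambiguous columns; segregating sites classified into transitions,
  transversions, and multiallelic sites; pooled base composition.
- **Diversity** — Nei's unbiased gene diversity
  `H_d = n/(n-1) (1 - Σ p_i²)` and nucleotide diversity `π = k̄/L` with
  Nei (1987) standard deviations, per any grouping of samples.
- **Structure** — AMOVA variance components with `Φ_CT`, `Φ_SC`, `Φ_ST`
  and scheme-specific permutation tests; pairwise `Φ_ST`; SAMOVA, a
  simulated-annealing search for the geographically contiguous K-group
  partition of sampling sites maximizing `Φ_CT` (Delaunay contiguity).
- **Demography** — Tajima's D and Fu's Fs (Ewens sampling formula via
  log-space Stirling numbers), with p-values from neutral coalescent
  simulation conditioned on the observed θ.
- **Networks & trees** — median-joining haplotype networks (minimum
  spanning networks plus consensus median vectors), F84 distances, UPGMA
  genealogies, newick I/O.
- **Hypothesis testing** — a structured-coalescent simulator (no
  migration) on annotated population trees, and the Slatkin–Maddison
  minimum-migration statistic s (Fitch parsimony) with simulated null
  distributions for testing allopatric-fragmentation scenarios.
- **Synthetic data** — `generate_study()` simulates survey-shaped datasets
  (FASTA + population map + truth record) with known genealogy and
  partition, so every stage is testable without any downloads.

## Worked example

```r
library(mtphylogeo)

## published haplotype table: gene diversity of one geographic group
counts <- tapir_haplotype_counts("group")
gd <- gene_diversity(counts[["Andean Foothill"]])
cat(sprintf("Andean Foothill: H_d = %.3f +/- %.3f (n = %d)\n",
            gd$H_d, gd$sd, gd$n))
#> Andean Foothill: H_d = 0.977 +/- 0.023 (n = 19)

## a synthetic survey with known truth, analysed end to end
st <- generate_study(synthetic_study_config(), seed = 7)
h  <- collapse_haplotypes(st$aln, st$map)
h
#> haplotype_table: 16 haplotypes, n = 45 samples, 12 demes, 1068 sites
classify_sites(st$aln)
#> site_summary: S = 24 (23 transitions, 1 transversions, 0 multiallelic) over 1068 sites
#>  base composition: A: 31.08%, C: 28.58%, G: 13.49%, T: 26.85%

d   <- pairwise_difference_matrix(h)
res <- amova(d, setNames(st$map$site_id, st$map$sample_id),
             groups = setNames(st$map$group[!duplicated(st$map$site_id)],
                               st$map$site_id[!duplicated(st$map$site_id)]),
             permutations = 1000, seed = 7)
res
#> AMOVA
#>  among groups:              sigma2 =   0.3039 ( 13.8%)  Phi_CT =  0.138 (p = 0.02697)
#>  among pops within groups:  sigma2 =  -0.2785 (-12.6%)  Phi_SC = -0.147 (p = 0.7243)
#>  within pops:               sigma2 =   2.1768 ( 98.9%)  Phi_ST =  0.011 (p = 0.4136)

## Slatkin-Maddison test of allopatric fragmentation
pt <- hypothesis_tree("null", tmrca = 1250, Ne = 10000)
sm <- sm_hypothesis_test(pt, s_observed = 4, reps = 1000, seed = 7)
sm
#> Slatkin-Maddison test: observed s = 4, null mean s = 14.07 (99% CI 9 - 19), p = 0
```

Reading the output: the synthetic survey (generated under a shallow
four-way split) shows most variance within sites with a modest among-region
component, and an observed genealogy needing only 4 changes of the region
character is far below anything the allopatric null produces — the same
rejection logic applied to the real survey. Negative variance components,
as in `Φ_SC` above, are legitimate method-of-moments outcomes on weakly
structured levels and are reported unclamped.

Three annotated-newick hypothesis trees
(`inst/extdata/fig4-{null,ii,iii}.nwk`) and the site-coordinate table
(`inst/extdata/survey_sites.tsv`) ship as fixtures; see the methods
vignette (`vignettes/mtphylogeo-methods.Rmd`) for the models, parameter
defaults, and design decisions.

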