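---
title: "Methods: models, parameters and design choices in phylosym"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in phylosym}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylosym)
```

`phylosym` implements the downstream half of a comparative skin-microbiome
survey: given an OTU count table, sample metadata, a bacterial phylogeny
and a host phylogeny, it quantifies how locality, host species,
microhabitat and host relatedness shape bacterial community composition
(presence/absence) and structure (relative abundance). This vignette is
the package's own account of the methods: what each stage computes, which
parameters matter and why their defaults are what they are, what the
synthetic generator does and does not emulate, and where genuinely open
design choices were resolved.

## The analysis model

**Composition versus structure.** Throughout the package, *composition*
means the set of taxa present and is measured with unweighted UniFrac;
*structure* additionally weighs taxa by relative abundance and is measured
with weighted UniFrac. The two can disagree — a factor can govern which
bacteria colonize a host while a different factor governs which of them
thrive — so every inferential stage is run on both metrics and reported
separately.

**UniFrac.** Both variants are computed per branch of the bacterial tree.
For samples $A, B$ and branch $i$ with length $b_i$, let $p_i^X$ be the
fraction of sample $X$'s reads descending from branch $i$. Unweighted
UniFrac is the unique-to-one-sample branch length over the union branch
length; weighted UniFrac is $\sum_i b_i\,|p_i^A - p_i^B|$, reported
unnormalized by default with a `normalized` flag dividing by
$\sum_i b_i (p_i^A + p_i^B)$. Which variant a published analysis used is
often unstated, so both are available and labeled; they differ by a
factor that depends on tree depth, not by ordering, for most comparisons.
The implementation accumulates branch masses once per table in postorder;
tests verify it against a naive per-branch oracle to $10^{-10}$.

**Faith's PD** is root-inclusive: the PD of a single tip is its
root-to-tip path length. This convention makes single-tip PD well-defined
and matches the common pipeline behavior (`picante::pd` with
`include.root = TRUE`, cross-checked in the tests). **Shannon** uses
log base 2 by default; the base is an explicit argument because the
reported value is base-dependent.

**Permutation inference.** ANOSIM ranks all $M = n(n-1)/2$ pairwise
distances once and compares mean between- versus within-group ranks,
$R = (\bar r_B - \bar r_W)/(M/2) \in [-1, 1]$. PERMANOVA partitions the
Gower-centered squared-distance matrix; on univariate Euclidean input the
pseudo-$F$ equals the classical one-way ANOVA $F$ exactly, which the
tests assert to $10^{-10}$. The sequential model
`d ~ locality + microhabitat + species` uses Type-I (order-dependent)
sums of squares, because host species is nested in both other factors:
whatever enters first absorbs the shared variation, and the term order is
part of the scientific claim, not a nuisance. Terms fully aliased by
earlier ones are reported with zero degrees of freedom and no test. All
permutation p-values use the add-one rule $(b+1)/(m+1)$ — unbiased and
never zero — with free permutation of observations (no strata): at the
survey's sample sizes the simpler scheme is adequately calibrated, which
the acceptance suite checks directly (rejection rate within
$[0.02, 0.09]$ at $\alpha = 0.05$ over 200 null replicates, 199
permutations each).

**Decontamination.** The rule operationalizes "more prevalent and equally
or significantly more abundant in controls" as: flag OTU $o$ (present in
at least one control) iff
$\mathrm{prev}_c(o) \ge \mathrm{prev}_s(o)$ **and**
($\overline{\mathrm{rel}}_c(o) \ge \overline{\mathrm{rel}}_s(o)$ **or**
Kruskal–Wallis on per-sample relative abundances is significant at
$\alpha$ with the control mean rank higher). Relative abundance is
computed per sample before averaging because the KW test operates on
per-sample observations. OTUs absent from all controls are never
candidates: cross-contamination from true samples into controls is
common, so control presence alone is not evidence. Each flagged OTU
records its `reason` (`prevalence+abundance` or `prevalence+kw`) for
audit. Whether the KW arm should be one- or two-sided is not a settled
convention; the directional check at $\alpha = 0.05$ is this package's
choice and is exposed as a parameter.

**Filter order** is organelle removal, then the rare-OTU filter (strictly
less than 0.001% of the grand total, computed on the pre-rarefaction
table over all sample types jointly), then decontamination, then
rarefaction. Rarefaction subsamples without replacement to exactly the
target depth (default 3,000) and drops shallower samples.

**Discriminant taxa.** The LEfSe-style stage is a documented simplified
reimplementation: a per-OTU Kruskal–Wallis screen at $\alpha$, then, for
survivors, the effect size is the mean over 30 bootstrap resamples of
$\log_{10}$ of the spread of class means of the OTU's relative abundance
scaled by $10^6$ (so the conventional threshold 3.0 corresponds to a
~1,000-per-million spread). There is no subclass/Wilcoxon stage because
the targeted designs have a single class factor per run, and for a single
feature the linear discriminant axis is the feature itself. The `> 3.0`
cutoff is strict. On null data the discriminant set is bounded by the KW
screen's false-positive rate — the LDA stage only shrinks it.

**Phylosymbiosis.** OTU tables are collapsed to one row per host group as
the *mean of per-sample relative-abundance vectors* (equal weight per
individual; pooling counts would weight deep samples more). UPGMA places
each merge at half the average inter-cluster distance, so cophenetic
distances reproduce an ultrametric input exactly; ties are broken by
lexicographic label order to keep topologies deterministic. Congruence
with the host tree uses the *rooted* clade-based normalized
Robinson–Foulds distance — the symmetric difference of nontrivial clade
sets over their total — because UPGMA dendrograms are rooted; for binary
trees on $n$ tips the denominator is $2(n-2)$, which makes values like
$4/6 \approx 0.67$ attainable on 5-tip comparisons. The null draws
rooted binary topologies uniformly (each new tip attaches to one of the
$2k-1$ positions), the least-informative choice given that a "random
tree" null is otherwise underspecified; branch lengths of null trees are
irrelevant because nRF uses topology only. The null p-value is the
add-one fraction of random trees at least as congruent. Jackknife
supports rebuild the dendrogram 100 times at 75% of the rarefaction
depth — the replicate count is standard, the depth fraction is the
conventional default and is exposed as a parameter. The partial Mantel
test correlates host patristic distances with group-level UniFrac
distances controlling for a binary same/different-locality matrix
(one-sided, positive association), and PVR decomposes the dendrogram's
double-centered cophenetic matrix into eigenvectors (positive
eigenvalues, up to 95% variance and at most $n - \ell - 1$ axes for an
$\ell$-level factor) tested factor-by-factor with Pillai's trace. The
Pillai statistic and its F approximation are computed from the SSCP
matrices directly so that axes perfectly explained by a factor (singular
residuals) remain testable; with one retained axis the statistic reduces
to the one-way ANOVA F.

## The synthetic generator

The generator emulates the survey design at the OTU-table level (no
sequence simulation): eight host units across two localities — five at
the first including one population of a widespread generalist, three at
the second including a rock/cave specialist and the generalist's second
population — with four microhabitats, 12 skin samples per host unit
(the emulated design ranges 9–15), 40 environmental samples split across
localities, and 8 negative controls. Host units are tips of a Yule tree
rescaled to unit height; each unit maps to exactly one locality and
microhabitat (the two populations of the generalist are separate tips),
so species is nested in both factors, as in the emulated design.

Expected skin relative abundances are a per-OTU log-normal baseline
(σ = 1) multiplied by three effect layers:

* `locality_effect` — that fraction of skin OTUs is presence-restricted
  to a randomly assigned home locality (a pure composition effect);
* `species_effect` — per-species log-normal abundance multipliers with
  this log-sd (a pure structure effect);
* `phylosymbiosis_strength` — Brownian-motion offsets evolved on the
  host tree, applied on log abundance to a designated OTU subset
  (`phylo_fraction`, default half). Setting `phylo_presence_threshold`
  additionally zeroes an OTU for species whose offset falls below the
  threshold, injecting the phylogenetic signal into composition as well
  as structure — the two channels are separately recoverable.

Counts are multinomial draws at per-sample depths that are
gamma-mixed Poisson (negative binomial, dispersion 5, mean 5,000):
a pure Poisson at any realistic mean essentially never produces
low-coverage samples, whereas the overdispersed depths drop roughly a
fifth of samples at the 3,000-read rarefaction depth, exercising the
sample-dropping path the way real surveys do. Environment samples draw
from a pool with 120 extra OTUs (under an independent baseline), so
environmental richness and PD exceed skin values by construction.
Controls draw from a near-empty base (total weight 2% of the community)
plus `n_contaminants` OTUs boosted 50-fold over the mean base weight;
contaminants leak into every skin sample at 10% of their control
relative abundance — the partial-leakage case is deliberately the hard
one for the prevalence comparison. Control depths are Poisson at mean
100: blank-sample read depth is set by the sequencer and loading, not by
the biomass overdispersion that drives sample-to-sample depth variation
in real specimens, and low-biomass blanks sequencing shallow is exactly
what makes negative controls informative.

What the generator does **not** emulate: sequencing error and chimeras
(upstream of the covered pipeline), compositional correlations among
taxa, overdispersion beyond the multinomial within a sample,
spatial/temporal autocorrelation within a locality, and any genuine
ecological process behind the effect layers. Passing tests therefore
demonstrate that the statistics recover effects *of the injected form
and magnitude* — not that real communities carry such effects.

## Numerical choices and degenerate inputs

* Permutation p-values are add-one everywhere; a constant distance
  matrix yields ANOSIM `R = 0`, `p = 1` and PERMANOVA `F = 0`, `p = 1`.
* The rare-OTU filter is strict (`< 0.001%`); the core-microbiota
  prevalence is inclusive (`>= 90%`); the LDA cutoff is strict
  (`> 3.0`). All three follow the rule text they implement.
* UPGMA ties break lexicographically; tolerance $10^{-12}$ on distance
  comparisons.
* PCoA reports negative eigenvalues rather than dropping them, clamps
  requested axes at $n - 1$ with a warning, and uses only positive
  eigenvalues for coordinates.
* Zero-total samples are rejected by weighted UniFrac and Shannon;
  empty presence sets by Faith's PD; rarefaction may return a
  zero-sample table when nothing reaches depth.
* All randomness flows through per-call seeds that save and restore the
  caller's RNG state, so pipeline runs are byte-reproducible and the
  global stream is never disturbed.

## Verification strategy and problem sizes

The test suite verifies each statistic against an independent route:
brute-force per-branch UniFrac, classical ANOVA for PERMANOVA,
exhaustive label enumeration for ANOSIM and the permutation t-test,
exhaustive topology enumeration (15 and 105 rooted trees on 4 and 5
tips) for the random-tree null, the closed three-correlation form for
the partial Mantel statistic, and `vegan`/`picante` as external
cross-checks. Calibration and power runs use deliberately small survey
shapes — 4–8 host units, 4–6 samples per group, 60–150 OTUs, depths of
500–1,500 reads, 199 permutations, 200 null replicates — sizes at which
the whole suite completes in well under a minute per property while the
binomial error bands remain informative. The study-scale configuration
(12 samples per unit, 430 OTUs, depth 5,000, 999 permutations, 1,000
random trees) is exercised end to end by `scripts/acceptance.R`.

Known limitations: sequential PERMANOVA permutes raw observations rather
than residuals, which can be slightly liberal for later terms in highly
unbalanced designs; no strata-restricted permutations or random-effect
df corrections are provided (group-level alpha-diversity structure is
tested nonparametrically instead); the LEfSe-style stage is
intentionally simpler than the published tool and its scores should be
compared across runs of *this* implementation only; and the nRF null is
conservative at small tip counts because the distance is highly
discrete — with eight tips many topologies tie, so null rejection rates
sit at or below the nominal level.
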