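---
title: "phylosym: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{phylosym: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the models
and procedures it implements, the assumptions behind them, the
parameters that matter, what the synthetic-data generator does and
does not emulate, and the numerical and design decisions that were
genuinely open. It states no empirical result that the test suite does
not itself compute.

## The analytical question

Two marker-gene surveys — ITS for fungi, 16S for bacteria — of the same
host individuals across many host species yield two count tables over a
shared sample set, plus a dated host phylogeny. Three questions drive
the pipeline:

1. **Phylosymbiosis.** Does compositional similarity between host
   species mirror host phylogenetic relatedness, for each kingdom?
2. **Cross-kingdom covariation.** Do shifts in fungal community
   structure across hosts track shifts in bacterial structure?
3. **Co-occurrence structure.** Which fungal and bacterial taxa
   covary in abundance within host groups, and do network roles
   (betweenness, phylum-pair coupling) depart from label-shuffle
   nulls?

Because amplicon counts are compositional (the sequencing depth is an
instrument artefact, not a biological quantity), all multivariate
analyses run on centred log-ratio (CLR) transforms and their Euclidean
("Aitchison") geometry, while diversity and co-occurrence analyses use
rarefied counts.

## Models and procedures

### Compositional layer

For sample $i$ with pseudocounted counts $x$, $\mathrm{clr}_j =
\ln x_j - \tfrac1p\sum_k \ln x_k$; rows sum to zero by construction
(tested at $10^{-9}$). Two pseudocount rules are exposed: `unit`
($\delta = 1$, the default) and `half_min_nonzero` (half the smallest
non-zero count in the table) for sensitivity analysis; the choice is
recorded in the `clr_matrix` object. The underlying study names only
the software it used, not its zero-replacement, so both common
conventions are available and logged rather than guessing the original.

Rarefaction is subsampling **without replacement** (multivariate
hypergeometric), the dominant convention; samples under the target
depth are dropped and reported, never silently kept. Taxonomic
agglomeration keys bins by the *full lineage prefix*, so a missing rank
(normalized to the literal token `"unassigned"` at read time) forms its
own bin within each parent lineage instead of a single global pool —
this makes agglomeration deterministic in the presence of incomplete
taxonomy, at the cost of keeping unassigned material split.

### Phylogenetic signal

Abouheif's $C_{mean}$ is the Moran-type statistic $x'Ax/x'x$ for the
centred, scaled species-level trait $x$ and the classic proximity
matrix: $A_{ij} \propto 1/\prod \mathrm{dd}(v)$ over interior nodes $v$
on the path between tips $i$ and $j$, where $\mathrm{dd}$ is the number
of direct descendants; rows are normalized to sum to one and the
diagonal is zero. Under exchangeability its expectation is
$-1/(n-1)$ (verified by simulation on star trees). The test permutes
trait values across tips; p-values use the $(b+1)/(n_\text{perm}+1)$
convention throughout the package so $p = 0$ is impossible. The test is
one-tailed for positive autocorrelation by default, because
phylosymbiosis predicts positive signal; a two-sided flag exists.
The trait carried to the tree is the **species mean** across samples
(the source methods do not state mean vs median; the choice is logged
here).

### Sequential PERMANOVA

The total sum of squared distances is partitioned through the
Gower-centred inner-product matrix $G = -\tfrac12 J D^{(2)} J$. Terms
enter in the user-given order (Type-I), each absorbing what the
preceding terms left: the reference profile puts the three batch
factors (sample type, tissue storage, extraction kit) before host
class, order and species, so processing artefacts are marginalized
before any host-taxonomy variance is claimed. Pseudo-F tests each term
against the residual; p-values come from unrestricted permutations of
sample identities with the full sequential decomposition recomputed
each time (implemented by permuting $G$, which is equivalent and
cheaper). Aliased terms (no rank increase) and single-level terms are
errors, not silent drops. Agreement with an independent implementation
(vegan's `adonis2`, `by = "terms"`) is part of the test suite, as is
convergence of the sampled p to the exactly enumerated p on $n \le 7$
fixtures.

### Procrustes, PROTEST and the bootstrap sweep

Kingdom-vs-kingdom comparisons use **symmetric** Procrustes: both PCA
score matrices are centred and scaled to unit total sum of squares,
and $m_{12}^2 = 1 - (\sum_k \sigma_k)^2$ from the SVD of $X'Y$;
the reported correlation is $\sqrt{1 - m_{12}^2}$. PCA keeps **all**
axes (no cut-off is stated by the source; an override exists and is
logged). PROTEST permutes rows of $Y$. The rank sweep agglomerates both
tables to each rank, then draws `n_boot` subsamples of
$\lceil 0.9 n \rceil$ paired samples *without* replacement — the same
subsample for both kingdoms, and the same paired-sample set across
ranks so distributions are comparable — recomputing the correlation on
the subsampled score rows.

The phylosymbiosis variant compares a *distance* matrix with a
*distance* matrix: community Aitchison distance versus the patristic
distance of the tree with sample tips grafted onto their species at
branch length $\varepsilon$ ($10^{-6}\times$ tree depth by default).
Both are embedded by classical principal coordinates before rotation;
axes with negative eigenvalues are dropped with a warning. The source
rotates "the paired matrix" without stating its embedding; PCoA is the
canonical choice and a Mantel variant is provided for sensitivity.

### Networks

Co-occurrence uses Spearman's $\rho$ (average ranks on ties) over
rarefied, family-agglomerated, merged two-kingdom tables, per host
species and per host class (classes **pool** samples; aggregating
species-level networks is a noted alternative the package does not
implement). Taxa present in fewer than 20% of the group's samples are
filtered (tie-dominated rank correlations are uninformative), constant
taxa are dropped with a report, and edges require $|\rho| > 0.5$.
Structural traits: connected components of the full signed graph;
communities by greedy modularity maximization on the unweighted
positive-edge subgraph (the algorithm and the treatment of negative
edges are not specified by the source; greedy agglomeration is the
choice here, with exhaustive-partition equivalence tested on small
graphs); betweenness on the unsigned, unweighted graph including
negative edges, since a negative association still transmits
structural position. Null tests shuffle kingdom labels (betweenness,
lower tail) or phylum labels within each kingdom (focal-pair coupling,
upper tail).

## The synthetic-data generator

The generator is a stated world, used as ground truth by every
recovery and calibration test:

1. A pure-birth (Yule) tree with unit depth and tips `sp001…spN`.
2. Latent log-composition matrices by Brownian motion on the tree:
   a shared matrix $Z_s$ and kingdom-specific $Z_f, Z_b$, all at scale
   $\sigma_B$; the species matrix per kingdom is
   $\sqrt{\lambda}\,Z_s + \sqrt{1-\lambda}\,Z_{kingdom}$. $\lambda$
   enters as a *variance share* so total latent variance is constant
   across $\lambda$ — coupling is isolated from overall signal
   strength.
3. Per sample: within-species Gaussian noise ($\sigma_{within}$,
   default 0.5) plus batch offsets of scale $\beta$ for the sample's
   levels of three batch factors, assigned uniformly at random and
   independently of species (so sequential marginalization can be
   tested without confounding by construction); offsets are drawn
   independently per kingdom.
4. Counts: $\mathrm{Multinomial}(d_i, \mathrm{softmax}(\text{latent}))$
   with $d_i \sim 1 + \mathrm{Poisson}(\text{depth}-1)$.
   Softmax-multinomial rather than Dirichlet-multinomial: within-species
   overdispersion comes from $\sigma_{within}$, with one fewer
   parameter and the same testable structure.
5. Taxonomy: features dealt into a fixed nested hierarchy (10 phyla,
   3 orders each, 2 families each, 2 genera each). With fewer than ~70
   features per kingdom, family binning is nearly injective and
   agglomeration only bites at order level — tests use order or
   larger feature counts where coarsening matters.
6. Diet: two axes mixing Brownian motion on the tree with uniform
   noise at ratio `diet_signal`, pushed through a fixed loading matrix
   and a softmax into ten proportion categories summing to 100.

Default sizes (20 species × 6 samples, 100 features per kingdom,
expected depth 2000, rarefaction to 500) are scaled-down but
structurally faithful analogues of a multi-species field survey
(5–12 samples per species, libraries rarefied to 500 reads). What the
generator does **not** emulate: read-length and chimera artefacts,
taxonomy misassignment, Dirichlet-type overdispersion,
Ornstein–Uhlenbeck (niche-filtering) evolution, and empirically
realistic depth distributions. A green recovery test therefore
establishes that the pipeline detects Brownian-drift phylosymbiosis
and variance-share coupling at desk scale — not that it would detect
any particular real-world effect size.

## Numerical choices

* **Permutation p-values** are always $(b+1)/(n_\text{perm}+1)$.
* **Seeds.** Every stochastic operation takes an explicit seed. Seeds
  are scrambled through one warm-up draw before use (`seed_rng()`):
  during calibration testing we found that datasets generated from
  *consecutive* integer seeds were correlated enough to bias
  500-replicate rejection-rate estimates by a factor of two in either
  direction; one warm-up draw removes the effect while keeping full
  determinism in the user seed.
* **PCoA embeddings** drop negative-eigenvalue axes with a warning
  (Aitchison distances are Euclidean, so in practice this triggers only
  through floating-point noise; patristic distances on grafted trees
  are additive and also embed cleanly).
* **PCA sign convention:** each axis is flipped so its
  largest-magnitude loading is positive, making score matrices
  reproducible across platforms.
* **Ties in paired richness** are excluded from both numerator and
  denominator of the bacterial-richer proportion and reported
  separately, with an exact Clopper–Pearson interval on the remainder.
* **Rarefaction reproducibility** is by seed; across seeds, per-taxon
  means converge to depth × proportion (tested at 3 SE over 1000
  draws).

## Known limitations

* The focal **phylum-pair null test** is valid but conservative at
  desk scale: its statistic is an integer count ratio, and with ~10
  nodes per phylum a quarter of null permutation draws tie exactly
  with the observed value, so rejection at $\alpha = 0.05$ runs below
  nominal (measured 0.010–0.025 across designs). Type-I error is never
  inflated, but exact Uniform(0,1) p-values are unattainable for this
  statistic on small networks; the corresponding calibration criterion
  in the acceptance suite is deliberately left failing with this
  analysis on record.
* Greedy modularity maximization is not guaranteed optimal on
  arbitrary graphs; equivalence with exhaustive search is established
  on small structured graphs, which is where the guarantee is used.
* Mixed-model (GLMM) treatments of richness and diet effects are out
  of scope; the package ships descriptive paired-richness summaries
  and OLS slopes with species-resampling bootstrap intervals instead.
* Class-level networks pool samples; aggregation of species-level
  networks is a documented alternative, not implemented.
* The diet–composition association is a Mantel test on distance
  matrices; the source reports $r$ and $p$ without naming its matrix
  correlation, so the Mantel construction is this package's explicit
  choice (Pearson by default, Spearman available).
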