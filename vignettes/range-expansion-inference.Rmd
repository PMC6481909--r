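---
title: "Inferring range-expansion origins from polarized SNP directionality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring range-expansion origins from polarized SNP directionality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(expansionr)
```

## The model

A species that expands its range through serial founder events leaves a
spatial signature in neutral variation. Each newly colonized deme is founded
by a small group drawn from an established neighbour; the repeated
bottlenecks let some derived alleles "surf" the wave front to high
frequency while others are lost. Two consequences drive everything in this
package:

* derived-allele frequencies form clines away from the origin, so for two
  populations the mean difference in derived-allele frequency — the
  directionality index ψ — is positive when the second population is
  farther from the origin;
* ψ grows approximately linearly with the difference in distance from the
  origin, so the origin can be located like a sound source in
  time-difference-of-arrival (TDOA) localization: find the point whose
  distance differences to the sampled populations best explain the observed
  ψ matrix.

The null model against which an expansion must be tested is equilibrium
isolation by distance (IBD): differentiation that grows with distance but
has no directionality. ψ is designed to be insensitive to pure IBD because
it conditions on *shared derived* polymorphisms: sites where the derived
allele is present in both populations and not fixed in both. Under an
expansion-free exchangeable history the frequency difference at such sites
has mean zero; under an expansion it does not.

### ψ, exactly as computed

For populations $i, j$ and a site with derived counts $k_i$ of $n_i$ and
$k_j$ of $n_j$ chromosomes, the site enters the comparison when
$n_i \ge m$ and $n_j \ge m$ (the projection size, below), and is
*informative* when $k_i > 0$, $k_j > 0$ and not ($k_i = n_i$ and
$k_j = n_j$). Then

$$\psi_{ij} = \operatorname{mean}_{\text{informative sites}}
  \left(\frac{k_j}{n_j} - \frac{k_i}{n_i}\right),$$

which is antisymmetric by construction; a pair with no informative sites is
flagged undefined and excluded from the TDOA fit rather than imputed.
Uncertainty comes from a site bootstrap (resampling informative sites with
replacement).

GBS matrices are patchy, so sample sizes differ across sites and
populations. Where a common chromosome count is needed, the package uses
the deterministic hypergeometric projection
$P(j) = \binom{k}{j}\binom{n-k}{m-j}\big/\binom{n}{m}$ rather than
Monte-Carlo downsampling: it is exact, noise-free and leaves the expected
frequency $k/n$ unchanged — which is why ψ itself is computed from the
unprojected frequencies, with $m$ acting only as a per-site sample-size
gate.

### TDOA origin search and the IBD test

For a candidate origin $o$, each defined pair contributes
$\Delta d_{ij} = d(o, j) - d(o, i)$ (haversine great-circle distance,
Earth radius 6371.0088 km), and the model $\psi_{ij} = q\,\Delta d_{ij}$
is fitted by least squares *through the origin*: ψ of a population with
itself is zero at $\Delta d = 0$ by construction, so an intercept has no
meaning. The candidate grid covers the populations' bounding box expanded
by half its span on each side — origins near or beyond the edge of the
sampled area are detectable, though with reduced accuracy (see
Limitations). The inferred origin is the grid cell minimizing the residual
sum of squares; with fixed total sum of squares this is also the cell
maximizing $r^2$.

Significance against IBD uses a permutation test: the observed statistic is
the best cell's $r^2$; the null distribution is obtained by permuting the
population→coordinate assignment while holding ψ fixed, which destroys
geography but preserves the ψ distribution, and
$p = (1 + \#\{T_\text{perm} \ge T_\text{obs}\}) / (1 + n_\text{perm})$.
Permutations are drawn in sorted-population-label order so the p-value does
not depend on input ordering.

### Structure and heterozygosity

Before trusting a single-origin model, samples are examined for geographic
grouping with classical PCoA: genotypes coded 0/1/2 copies of the
non-reference allele, pairwise Euclidean distances with pairwise-deletion
scaling $d = \sqrt{(P/M)\sum(g_1-g_2)^2}$ ($P$ sites total, $M$ mutually
non-missing for the pair), then eigendecomposition of the double-centred
$-D^2/2$. Group labels are user-supplied (grouping in the motivating
analyses was assigned visually); a k-means helper on the leading axes is
provided for automation but nothing in the pipeline depends on it. Distinct
groups can be re-analysed separately via the group filter. Per-population
observed heterozygosity (mean fraction of heterozygous calls per sample)
supports the usual map shading of populations.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `min_samples_per_snp` | 4 | samples | standard GBS retention threshold; "present" means any non-missing call |
| `require_outgroup_presence` | on | — | polarization needs at least one outgroup call per site |
| `snp_choice_mode` | random | — | one SNP per locus; `rare_allele_bias` restricts to SNPs with minor-allele copies ≥ 2 (hard filter with fallback, not a soft weighting) |
| `m` (projection size) | 2 | chromosomes | smallest size compatible with one individual per population; larger m discards sites with fewer calls |
| `B` | 0 (off) | resamples | site bootstrap for ψ standard errors; ≥ 100 when used |
| `spacing_deg` | 0.25 | degrees | grid resolution; ~27 km, well below one lattice/population spacing |
| `padding_fraction` | 0.5 | of bbox span | broadened search area for edge/outside origins |
| `n_perm` | 199 | permutations | resolves p to 1/200; use 999 when the strict p < 0.01 call matters |

Every stochastic step (SNP choice, sample subsetting, bootstrap,
permutation, simulation) consumes an explicit integer seed recorded in the
outputs; there is no wall-clock seeding.

## The synthetic world

`simulate_expansion()` is a forward-time binomial Wright–Fisher model, one
unlinked SNP per locus (matching the analysis's one-SNP-per-locus
independence assumption), on a lattice of demes:

* standing variation starts in the origin deme with derived frequencies
  drawn from a discretized 1/f law conditioned on polymorphism — a
  neutral-SFS-like spectrum so "derived" has realistic frequencies;
* the colonization wave advances at constant speed in space: demes are
  colonized in order of Euclidean distance from the origin (unit-distance
  rings), each founded by `founder_size` diploids drawn binomially from an
  established previous-ring neighbour (king moves), so the founder-chain
  length — and hence accumulated founder drift — grows in proportion to
  distance from the origin, which is precisely the regime in which ψ grows
  linearly with distance. An earlier draft advanced the wave by 4-neighbour
  graph distance; that makes arrival time scale with Manhattan rather than
  great-circle distance and biases the TDOA scan toward far-field origins
  on the lattice diagonal, an artifact of the lattice, not of the biology
  being emulated;
* established demes hold `deme_size` diploids and exchange a fraction
  `migration_rate` of their gene pool with lattice neighbours each
  generation;
* sampling emits diploid genotype calls with per-call missingness, an
  outgroup fixed for the ancestral allele (optionally mispolarized at a
  configurable fraction of sites), population metadata on a configurable
  km-per-step geographic anchor (placed in arid Australia purely for
  realistic-looking maps), and a truth record (origin coordinates,
  colonization ring per population, per-site derived allele) sufficient to
  score recovery without re-reading the configuration.

Default sampled populations form a deterministic near-uniform sub-grid
(peripheral cells kept when trimming), the way field sampling tends to
cover a species' range.

`simulate_ibd()` shares the machinery but starts every deme occupied at
full size from one ancestral pool and burns in migration–drift for
`burn_in_generations` (≥ 10 × `deme_size` recommended); there is no origin
and no colonization order. `plant_linear_psi()` bypasses genetics entirely
and writes an exactly linear (optionally noisy) ψ field around a known
origin, for exact TDOA oracle tests.

What the generator does **not** emulate: linkage, selection, habitat
heterogeneity through time, uneven population sizes, allele-sharing with
the outgroup, or sequencing/genotyping error beyond missingness and
symmetric mispolarization. A green test therefore establishes that the
pipeline recovers what this idealized world encodes — not that real GBS
data meet the model's assumptions.

## Numerical choices

* Polarization uses a strict unanimity rule (every non-missing outgroup
  call homozygous for the same in-alphabet allele); conflicted sites are
  dropped, and alternative outgroup taxa are handled by re-running with a
  different `outgroup_taxon`, mirroring how the motivating study varied
  outgroups. Monomorphic-after-polarization sites are dropped.
* `rare_allele_bias` is a hard candidate filter (minor copies ≥ 2, counted
  over all non-missing calls including the outgroup, since the filter runs
  before polarization) with fallback to all SNPs of the locus.
* The TDOA fit clamps tiny negative residual sums (floating-point
  cancellation at perfect fits) to zero; cells equidistant from all
  populations have an undefined fit and are recorded as worst (infinite
  RSS). Ties for the best cell are broken by the first cell in row-major
  order and logged; a best cell on the grid boundary raises a flag.
* An all-zero ψ matrix yields a flat surface (RSS = 0, $r^2$ defined as 0
  everywhere) and a permutation p-value of 1.
* Degenerate inputs fail loudly: fewer than two populations, all
  populations at one coordinate, sample pairs with no mutually non-missing
  sites, fewer than three defined ψ pairs for a single-point fit.

## Limitations

* **Single origin.** The scan assumes one origin; with strong geographic
  structure, analyse groups separately via the group filter.
* **Edge-of-range origins.** When the true origin sits at the edge or
  corner of the sampled area, the RSS surface is nearly flat outward of the
  edge: migration during the expansion partially equilibrates
  early-colonized demes, flattening ψ for small distance differences, and
  the through-origin fit then prefers candidate origins displaced outward
  by one to a few lattice spacings. The package raises the boundary flag in
  this regime; the acceptance suite documents a measured recovery rate just
  below the nominal 80 % target for a corner origin under migration 0.05,
  entirely due to such outward near-misses (the fitted direction remains
  correct). Interpret edge origins as directions, not points.
* **Habitat history.** Heterogeneous habitat availability through time can
  mimic or distort expansion signals; nothing here corrects for it.
* **Tetraploids.** Handled only as a population-level inclusion/exclusion
  flag on diploid-coded calls, matching how GBS callers emit genotypes; no
  tetraploid allele dosages are modelled.

## A complete run

```{r example, eval = FALSE}
sim <- simulate_expansion(expansion_sim_config(seed = 1))
cfg <- run_config(
  selection = selection_config(per_population_scheme = "downsample_to_common",
                               seed = 1),
  n_perm = 199, seed = 1, out_dir = "results")
res <- run_pipeline(cfg, table = sim$table, info = sim$info)
res$summary$best_origin
res$summary$pvalue

# consistency across analysis choices, as a settings matrix
run_matrix(cfg,
           axes = list("selection.snp_choice_mode" =
                         c("random", "rare_allele_bias"),
                       "m" = c(2L, 4L)),
           table = sim$table, info = sim$info)
```
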