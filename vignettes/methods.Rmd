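---
title: "Methods: soil quality, multifunctionality and microbiome analysis for organic-replacement trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: soil quality, multifunctionality and microbiome analysis for organic-replacement trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(milletsoil)
```

## The study design the package models

The package targets a common agronomic design: a mineral NPK control and
three treatments in which 50% of fertilizer nitrogen is replaced by
composted cow (CM), pig (PM) or sheep (SM) manure at equal total
N-P₂O₅-K₂O rates (225, 135 and 112.5 kg/ha), grown over two seasons with
three replicate plots per treatment. Measurements per plot: ten
physicochemical indicators (pH, total porosity SP, total C/N/P/K,
ammonium, nitrate, available P and K), six enzyme activities (catalase,
invertase, β-N-acetylglucosaminidase, urease, alkaline phosphatase,
glutaminase), grain yield at the 13% moisture convention, and shotgun
profiles of the bacterial, fungal and archaeal communities.

## Soil quality index

`compute_sqi()` uses the total-dataset approach: every indicator is
linearly rescored over a pool,

$$S_{L}=\frac{x-L}{H-L},$$

and the index is the radar-polygon area $0.5\,\sum_i S_{Li}^2
\sin(2\pi/n)$. Design choices that were genuinely open:

* **Scoring pool.** H and L default to the samples of the same year
  (`pool = "per_year"`). The published per-year treatment means of EMF
  sum to zero within each year (−1.2 + 0.32 + 0.65 + 0.23 ≈ 0.00, and
  likewise in year two), which identifies per-year standardization for
  EMF; SQI follows the same convention for coherence. Both accept
  `pool = "global"`.
* **Directions.** All ten indicators default to more-is-better,
  including pH. On these alkaline soils (pH 8.0–8.7) the mineral control
  keeps the highest pH yet also the highest published share of its SQI
  attributable to pH: reproducing the published control SQI requires a
  positive pH contribution. On acidic soils a user should flip pH to
  `less_is_better`; directions are per-indicator configuration.
* **Degeneracies.** $n \le 2$ is rejected ($\sin(2\pi/n) \le 0$ makes the
  area formula meaningless). A constant indicator (H = L) scores 0.5
  with a warning by default; `constant = "error"` makes it fatal.
* **Replicates vs means.** SQI is computed per replicate and summarised
  afterwards. When only published group means exist,
  `summary_to_samples()` turns them into pseudo-replicates and the means
  act as the pool; recomputed index *levels* then differ from published
  ones (which used unavailable replicate-level pools), but fold changes
  between treatments — the quantities the trial reports — are
  reproduced exactly from the published index rows themselves.

## Ecological multifunctionality

`compute_emf()` is the averaged-z construction: per function,
$z = (x - \bar x_{pool})/s_{pool}$ with sample SD (n − 1), then the mean
of the function z-scores. Within each pool the EMF average is zero by
construction. Zero-variance functions are dropped with a warning. The
construction reproduces the published 2022 values (CM 0.32; control
−1.18 against a printed −1.2 ± 0.15) from the published enzyme means
alone.

## Nitrogen-use efficiency

`compute_pfp()` and `compute_aen()` implement $PFP_N = Y_T/F_N$ and
$AE_N = (Y_T - Y_0)/F_N$. The unfertilized-control yield $Y_0$ is never
published for this trial; the generator exposes it as `y0_frac` (default
0.6 of the control baseline, a typical unfertilized fraction for
intensively cropped loess soils). $AE_N$ levels therefore depend on an
assumption and only their treatment contrasts should be compared across
studies.

## What the synthetic generator emulates — and what it does not

`simulate_soil()` draws each variable independently as
Normal(mean, SE·√3), truncated at zero (pH kept inside (0, 14)): the
SE-to-SD conversion matches the published dispersion for n = 3.
`simulate_yields()` uses a multiplicative model around a 4200 kg/ha
control baseline with the published PM folds (+4.81% and +7.87% by year)
and CM/SM interpolated at 1/3 and 2/3 of the PM gain, preserving the
published ordering PM > SM > CM > control; plot noise has a 2% CV.

`simulate_communities()` nests species inside phyla (geometric weights,
ratio 0.75), applies per-treatment phylum concentration multipliers
encoding the reported shifts (Proteobacteria, Gemmatimonadetes and
Crenarchaeota up under CM; Bacteroidetes and Ascomycota up under PM;
Acidobacteria, Chloroflexi, Basidiomycota, Thaumarchaeota highest under
the control), then draws per-sample compositions from a Dirichlet and
counts from a multinomial. Two noise knobs matter:

* `overdispersion` (default 2e-3): the inverse Dirichlet precision;
  compositions converge to the profile means as it approaches 0.
* `phylum_sigma` (default 0.7): the SD of a per-sample lognormal
  activity factor shared by all species of a phylum. This factor is what
  generates co-occurrence: species of one phylum rise and fall together
  across samples, so networks show within-phylum correlation blocks and
  modules that align with phyla. With the defaults a 20-sample treatment
  network retains roughly 50 nodes and 100–200 edges at |ρ| ≥ 0.6 —
  the scale of the trial's reported networks.

The generator defaults to 10 community replicates per treatment-year
rather than the field trial's 3, because rank correlations over 3–6
samples are not estimable at conventional thresholds; this divergence is
deliberate and documented here. What the generator does **not** emulate:
real phylogenetic correlation beyond phylum blocks, cross-kingdom
coupling, abundance-soil covariation (communities are simulated
independently of the soil table), sequencing artifacts, or
functional-gene content. Tests passing on synthetic data therefore
validate the estimators' arithmetic and calibration, not any biological
claim about real soils.

## Community analyses

Alpha diversity reimplements the standard estimators: observed species,
Shannon ($-\sum p \ln p$, natural log by default since the upstream
pipeline's base is unstated), and Chao1 in the bias-corrected form
$S_{obs} + F_1(F_1-1)/(2(F_2+1))$ (classic $S_{obs} + F_1^2/(2F_2)$
selectable, falling back to bias-corrected when $F_2 = 0$). Bray-Curtis,
PCoA and PERMANOVA are implemented directly and cross-checked in the
test suite against vegan (`vegdist`, `adonis2`) as independent oracles.
PCoA reports negative eigenvalues with a flag rather than applying a
Lingoes/Cailliez correction. PERMANOVA uses Anderson's one-way
partitioning of squared distances with
$p = (1 + \#\{F_{perm} \ge F_{obs}\})/(1 + n_{perm})$, a mandatory seed,
and an exhaustive-enumeration mode for small n used by the tests.

## Co-occurrence networks and keystones

The upstream web tools used for the trial's networks publish neither
their correlation threshold nor their multiplicity correction, so the
edge rule here is the field convention and fully configurable: Spearman
|ρ| ≥ 0.6 with BH-FDR < 0.05, signs retained as metadata, taxa
pre-filtered at mean relative abundance > 0.5% (bacteria/fungi) or
> 0.01% (archaea). Edge p-values use the t approximation on ranks;
its far-tail accuracy limits family-wise calibration for grids beyond a
few hundred pairs (see *Numerical choices*). Modules come from Louvain
modularity maximization on absolute weights (modularity is defined for
non-negative weights); Zi–Pi follows the conventional thresholds
(module hub Zi > 2.5, connector Pi > 0.62), with Zi = 0 where a module's
within-degree SD is zero and isolated nodes classed peripheral.

In a thresholded co-occurrence network, an abundance enrichment
manifests mainly through *node recruitment*: more of the enriched
phylum's species pass the abundance filter, enlarging its module and its
total connectivity. The directional sanity check in the tests therefore
aggregates node counts and summed degree over replicate simulations
rather than asserting a per-seed mean-degree ordering, which the
generator's sampling noise does not support.

## Treatment statistics

Duncan's multiple range test computes least significant ranges from
studentized-range quantiles at the protection level
$\gamma_p = (1-\alpha)^{p-1}$ — `qtukey(γ_p, p, df)` reproduces the
classical published table values (e.g. 3.151/3.293/3.376 at df = 10) —
with letters assigned by the standard descending-means sweep and a
harmonic-mean group size for unbalanced designs. With zero residual
variance (pseudo-replicated group means) letters group by exact
equality. Orthogonal contrasts use the ANOVA MSE with
$t = \sum c_g \bar y_g / \sqrt{MSE \sum c_g^2/n_g}$. The Spearman grid
adjusts p-values across the *entire* grid (not per row) — conservative,
and configurable by subsetting. Variance partitioning fits every subset
of predictor groups by multivariate least squares on the
Hellinger-transformed composition (the standard transform for
compositional responses; the trial's tool does not state one), adjusts
R² by the Ezekiel formula, and isolates unique/shared fractions by
Möbius inversion over subsets; small negative fractions are reported
as-is, and `unique + shared + residual = 1` exactly.

## Numerical choices and known limitations

* Reported ratios and differences round half-up at two decimals,
  matching the printed style; an epsilon of 1e-9 absorbs binary
  representation error at .5 boundaries.
* Spearman edge p-values use the t approximation, which is accurate near
  conventional levels (the per-pair type-I error is nominal in the
  calibration tests) but too coarse in the extreme tails that dominate
  family-wise behavior over thousands of simultaneous pairs. At the
  default |ρ| ≥ 0.6 threshold this is immaterial — the magnitude filter,
  not the p-value, is binding at realistic sample sizes.
* Compositions are closed: Dirichlet-multinomial data carry small
  negative correlations between dominant taxa (closure), so a
  compositional generator cannot produce an exact zero-correlation null.
  Independence nulls in the tests permute each taxon across samples
  instead.
* PERMANOVA permutes raw labels; with tiny, perfectly separated groups
  the original partition can recur among sampled permutations, so the
  attainable minimum p is slightly above $1/(n_{perm}+1)$ for very small
  groups.
* Missing values are rejected rather than imputed (the design is
  complete-case); enzyme units are carried opaquely (the per-dry-mass vs
  per-fresh-mass convention is not stated upstream).
* Problem sizes in the test suite (e.g. 200-simulation calibration runs
  at 30–60 taxa, depth 10⁴–10⁵, PERMANOVA with 99 permutations) were
  chosen as the smallest designs at which the checked statistics are
  stable; all scale up through configuration.

## Scope

Sequencing-scale results — read QC/assembly, gene catalogs, KEGG/GO/CAZy
enrichment, biomarker discovery, random-forest importance and path
models — are outside this package's scope; it begins at taxa-by-sample
abundance tables and replicate-level soil measurements.
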