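---
title: "Models and methods behind triohet"
author: "triohet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind triohet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triohet)
```

# The scientific problem

Heterosis (hybrid vigour) is the superiority of an F1 hybrid over its
parents for some trait — in the motivating system, leaf nicotine content of
a tobacco cross between a high-nicotine flue-cured line and a low-nicotine
oriental line, measured before (BT) and after (AT) topping. A matching
RNA-seq experiment on the trio (maternal parent, paternal parent, F1) asks
*how* the hybrid's transcriptome departs from its parents: per gene, is the
F1 at the mid-parent level (additive), indistinguishable from one parent
(dominant), or outside the parental range (overdominant / transgressive)?
`triohet` implements the full desk-scale analysis: trait-level heterosis
indices, trio differential expression, the twelve-pattern inheritance
classification, gene-set over-representation, and qPCR concordance,
together with a simulator that plants known inheritance modes so the whole
chain is testable without sequencing data.

# Heterosis indices

For a trait value $F_1$ and parents with per-cell high value $HP$, low
value $LP$ and mid-parent $MP = (P_1 + P_2)/2$:

$$\mathrm{OPH} = \frac{F_1 - HP}{HP} \times 100,\qquad
  \mathrm{MPH} = \frac{F_1 - MP}{MP} \times 100,\qquad
  \mathrm{BPH} = \frac{F_1 - LP}{LP} \times 100.$$

HP/LP rank is assigned per measurement cell (a parent may switch rank
between years or stages), and BPH is the *signed* low-parent index: a
positive value simply means the F1 exceeds the low parent. Because all
three indices are ratios of the same four quantities, eliminating $F_1$,
$HP$ and $LP$ leaves an exact identity,

$$\mathrm{MPH} = \left(\frac{2}{\dfrac{1}{1+\mathrm{OPH}/100} +
  \dfrac{1}{1+\mathrm{BPH}/100}} - 1\right)\times 100,$$

a harmonic-mean combination implemented as `mph_from_oph_bph()`. It lets a
published (MPH, OPH, BPH) triple be checked for internal consistency
without the underlying means; since published indices are rounded (here to
two decimals), the implied MPH carries up to about ±0.01 of propagated
rounding error, which is the tolerance our consistency checks use.

```{r}
heterosis_indices(f1 = 2.0, parent1 = 1.0, parent2 = 1.5)
mph_from_oph_bph(24.65, 46.18)   # implied mid-parent index
```

The ordering $\mathrm{OPH} \le \mathrm{MPH} \le \mathrm{BPH}$ holds for any
positive inputs (the numerators decrease and denominators increase with the
parent value), and `heterosis_indices()` followed by `mph_from_oph_bph()`
round-trips to floating precision — both are property-tested.

# Quantification and the expression filter

`compute_fpkm()` implements
$\mathrm{FPKM}_{gs} = c_{gs} \cdot 10^9 / (\ell_g \cdot T_s)$ with
$\ell_g$ the gene length in bp and $T_s$ by default the column sum of the
supplied count matrix; a `totals` argument accepts externally determined
per-million denominators (e.g. uniquely mapped read counts) where those
differ from the matrix column sums. The analysis universe is the set of
genes with FPKM strictly above 1 in at least one sample
(`filter_expressed()`, strict inequality). Per sample,
$\sum_g \mathrm{FPKM}_{gs}\,\ell_g = 10^9$ exactly when the totals are the
column sums — a conservation identity used as a unit test. FPKM is a
*within-sample* relative measure: if a large fraction of the transcriptome
genuinely shifts in one genotype, per-sample renormalization absorbs part
of that shift (library-composition effect). That is a property of FPKM
itself, not of this implementation; the cross-sample inference below
therefore works on size-factor-normalized counts, not FPKM.

# Differential expression without (and with) replicates

Counts are modelled as negative binomial with
$\mathrm{Var} = \mu + \alpha\mu^2$; $\alpha = 0$ degenerates to Poisson.

**Normalization.** `estimate_size_factors()` is the median-of-ratios
estimator: each sample's factor is the median over genes observed in every
sample of $c_{gs} / \mathrm{geomean}_g$. The median is taken on the ratio
scale, so an even number of usable genes interpolates arithmetically. A
`pseudo_reference` flag handles matrices without any all-positive gene, and
a `normalize` flag rescales factors to geometric mean one.

**Dispersion.** Per gene, a method-of-moments estimate from normalized
counts ($\hat s^2 = \bar q\,\overline{1/sf} + \alpha \bar q^{\,2}$ solved
for $\alpha$), either within the contrast groups (`per_group`, needs
replicates) or pooled across all samples of the matrix (`blind_pooled`).
Blind pooling treats genotypes as replicates, so genuinely differential
genes absorb their signal into the dispersion — over-conservative, never
anti-conservative, and the only option in the one-library-per-genotype
design. Raw estimates are shrunk toward a global trend
$\alpha(\mu) = a_0 + a_1/\mu$ fitted by trimmed least squares across genes.
The shrinkage weight defaults to 1 (trend only) at ten or fewer residual
degrees of freedom, because a per-gene moment estimate with $d$ degrees of
freedom has relative error of order $\sqrt{2/d}$ — at $d \le 10$ it is
mostly noise — and 0.5 otherwise. A fixed numeric dispersion (including 0)
is also accepted.

**Test.** A Wald $z$ on the difference of log normalized group means, with
$$\mathrm{se}^2 = \sum_{j \in \{1,2\}} \frac{1}{n_j}\left(
   \frac{\overline{1/sf}_j}{\bar q_j + \varepsilon} + \alpha\right),$$
two-sided normal $p$, and
$\log_2\mathrm{FC} = \log_2\!\big((\bar q_2+\varepsilon)/(\bar q_1+\varepsilon)\big)$
with pseudo-count $\varepsilon = 0.5$ on the normalized scale, keeping fold
changes finite for zero-count genes. In the Poisson case with single
samples this reduces to the classical rate-ratio Wald test and agrees with
the exact conditional binomial test to within $|\Delta p| \lesssim 0.01$ in
the informative regime (it drifts to ~0.02 for near-null, high-count pairs,
where no decision depends on it). Empirical type-I error at nominal 0.05
under a simulated null (n = 3 vs 3, $\alpha = 0.1$) is ~0.05.

**Calls.** `call_deg()` applies the joint criterion: `up` when significant
with $\log_2\mathrm{FC} \ge \log_2(\text{min\_fold})$, `down`
symmetrically, else `ns`; significance uses the BH-adjusted $q$ by default
(`use_adjusted = FALSE` switches to raw $p$). The reported DEG tables use
the classical $q \le 0.05$ and fold $\ge 2$ definition. With
`min_fold = 1` a significant gene with a log fold change of exactly zero
stays `ns` (no direction to report).

# The twelve inheritance patterns

Three contrasts are tested per gene: parent vs parent, F1 vs maternal
parent, F1 vs paternal parent. The resulting call triple
$(\text{pp}, \text{f1f}, \text{f1m})$ lives in a closed
$3 \times 3 \times 3$ space, and `classify_pattern()` is a *total* function
on it:

| pattern | pp | F1 vs ♀ | F1 vs ♂ | rollup |
|---|---|---|---|---|
| P1 | f_higher | down | up | additive |
| P2 | m_higher | up | down | additive |
| P3 | m_higher | up | ns | HPD |
| P4 | f_higher | ns | up | HPD |
| P5 | f_higher | down | ns | LPD |
| P6 | m_higher | ns | down | LPD |
| P7/P8/P9 | f_higher / m_higher / ns | up | up | UOD |
| P10/P11/P12 | f_higher / m_higher / ns | down | down | DOD |

Additive genes sit strictly between significantly different parents;
dominant genes track one parent (higher-parent dominance P3–P4,
lower-parent dominance P5–P6, with P3 and P5 the paternal variants);
overdominant genes exceed (P7–P9) or undercut (P10–P12) both parents,
sub-indexed by the parental relation. The remaining 15 cells carry
conflicting or incomplete evidence and map to NC — never forced into a
pattern. The sub-pattern indexing within the overdominant triples (which
parental relation gets P7 vs P8, etc.) is a documented package convention;
the rollup classes do not depend on it. `build_rollup_sets()` returns the
four non-additive gene sets (HPDG, LPDG, UODG, DODG), which are pairwise
disjoint by construction.

**Calibration of the classifier's calls.** A gene's label rests on all
three calls simultaneously, so the natural error unit is "any false call on
this gene". The default (`pattern_call = "fwer"`) therefore tests each
contrast at raw $p \le \alpha/3$, controlling that per-gene family-wise
rate at $\alpha$. Two alternatives are provided: per-contrast BH at
$\alpha$ (`"bh"`) and raw $p$ at $\alpha$ (`"raw"`). The choice matters
because the additive/dominant boundary is intrinsically hard: an F1 at the
exact mid-parent of a 4-fold parental split is only 1.6-fold away from the
high parent, while a dominant gene's F1 is exactly *at* that parent — the
two hypotheses are a few standard errors apart at realistic depth and
dispersion, and any calibration trades missed additive genes against
dominance false positives. The FWER default sits near the optimum of that
trade-off in our simulations. For the same reason, the classifier's calls
apply **no fold-change gate** by default (`pattern_min_fold = 1`): a
fold-≥2 requirement on the F1 contrasts would make additive patterns
mathematically unreachable ($2e/(e+1) < 2$ for any parental ratio $e$),
while the published DEG tables keep their fold gate.

# Over-representation

`hypergeom_enrich()` computes, per term, the upper-tail hypergeometric
$P(X \ge \text{count})$ with the population as the urn, BH-adjusted across
tested terms. The population defaults in the pipeline to the genes passing
the expression filter — not the whole annotation universe — so that terms
full of unexpressed genes cannot masquerade as depleted background
(detection-bias guard). Terms with fewer than two in-population members are
not tested; untestable singletons would only inflate the BH denominator.
Only over-representation is tested. GMT input is parsed strictly (duplicate
term ids and sub-3-field lines are errors with line numbers; duplicate
members deduplicate).

# qPCR quantification and concordance

`ddct_relative_expression()` implements the Livak $2^{-\Delta\Delta C_t}$
method with amplification efficiency fixed at 2: technical replicates are
averaged on the cycle scale, $\Delta C_t$ subtracts the reference gene
(a single chosen reference, Actin-2-style), $\Delta\Delta C_t$ subtracts
the calibrator genotype, and the calibrator's fold is 1 by construction.
Fold changes are invariant to global cycle shifts. Efficiency-corrected
(Pfaffl) quantification and multi-reference geometric normalization are out
of scope. `concordance()` regresses qPCR $\log_2$ fold changes on RNA-seq
$\log_2$ fold changes (OLS) and reports the squared Pearson correlation;
$r^2$ is invariant to affine rescaling of either axis. `simulate_ct()` is
the exact inverse of the quantification at zero noise, which gives the
round-trip identity used in testing; concordance against a *real*
instrument also absorbs primer efficiency and biological resampling, so the
simulated $r^2 = 1$ is a correctness check, not a claim about achievable
experimental concordance.

# The synthetic-data generator

`simulate_trio_counts()` draws per-gene baseline means from a log-normal
distribution, sets the three genotype means according to a planted class,
and samples NB counts:

* **classes** — additive (F1 at the arithmetic mid-parent, one parent
  shifted by the effect size), higher-/lower-parent dominance (F1 equal to
  the named parent), up-/down-overdominance (F1 one effect-multiple above
  the higher or below the lower parent; spread round-robin over the three
  parental sub-patterns), and null;
* **defaults** — 2,000 genes; 70% null with the non-null mass spread over
  all eight classes; one library per genotype (the motivating study's
  design — `n_replicates` exposes replicated designs too); log-normal
  baseline around 100 counts (meanlog $\log 100$, sdlog 1.2, a typical
  bulk-RNA-seq spread at desk scale); dispersion 0.1 (biological CV
  $\approx$ 0.3, typical for field-grown material); effect size 2 on the
  $\log_2$ scale (4-fold, comfortably above the fold-2 reporting gate);
  gene lengths uniform on 200–5000 bp, independent of expression so FPKM
  arithmetic is not confounded;
* **reproducibility** — one integer seed, split into fixed per-operation
  substreams; the caller's RNG state is restored afterwards.

Each simulation returns a truth table (class, sub-pattern, true means and
fold changes) against which recovery is measured. What the generator does
*not* emulate: GC/length count bias, positional artifacts, correlated genes,
dispersion heterogeneity beyond the mean trend, outlier samples, and
library-composition imbalance (size factors are planted explicitly). A
passing recovery test therefore demonstrates the statistical machinery, not
robustness to those real-data pathologies.

`simulate_phenotype()` adds Gaussian replicate noise to configured
genotype × stage means (field default three replicates);
`nicotine_study_means()` reconstructs the motivating study's genotype means
from its published index table, anchoring the low parent at stage-typical
nicotine contents (1.6% dry weight before topping, 2.6% after) and taking
the maternal flue-cured parent as the high-nicotine parent.

# Problem sizes, numerical choices, degenerate inputs

The test and acceptance simulations use 2,000 genes, chosen so every
distributional check (type-I error, planted-pattern recovery) has a few
hundred genes per stratum while a full run stays in seconds. Recovery is
evaluated under 5 replicates per genotype, dispersion 0.05, 4-fold effects;
null calibration under 3 replicates, dispersion 0.1. Under those conditions
planted-pattern recovery is ~95% and the false non-additive rate on null
genes is well under $2\alpha$; as discussed above, the additive/dominant
boundary leaves the rollup recovery near 95% by information content, so
seed-to-seed it fluctuates by about ±1 percentage point around that value.

Numerical conventions worth knowing: percent heterosis requires positive
parent values (errors otherwise), and per-gene expression heterosis flags
rather than drops genes with a zero parental mean; `mph_from_oph_bph`
requires both indices above −100; BH adjustment rejects NaN inputs by
index; identical group means give $p = 1$ exactly; all-zero genes have
FPKM 0 and never pass the filter; the empty count matrix, missing genotype
roles, non-integer counts, unknown role tokens, and absent gene lengths are
all rejected with the offending entity named.

# Interfaces

Everything is plain, diffable text: counts TSV with
`sample:genotype:replicate` headers, two-column gene-length TSV, long
phenotype and Ct TSVs, GMT term files, YAML pipeline configuration, JSON
manifests. `fit_trio()` is the in-memory entry point (a classed fit with
`print`, `summary`, `coef`, `plot` methods); `run_pipeline()` wraps it for
file-based runs, writes every intermediate, and records input/output md5
hashes plus parameters in `manifest.json`, so identical inputs yield
byte-identical outputs. There is no shell executable: the exported
functions and this vignette are the interface, and every pipeline stage is
an ordinary R call.

# Known limitations

* The no-replicate mode cannot separate biological variability from
  genotype effect; its blind dispersion is deliberately conservative, and
  single-library results should be read as ranking, not inference.
* FPKM inherits library-composition distortion; cross-sample statements are
  made on normalized counts.
* The Wald test is asymptotic; for counts below ~10 its $p$-values are
  approximate (the Poisson oracle comparison quantifies this).
* Pattern sub-indices beyond the rollup classes are a convention; compare
  rollups, not sub-patterns, across tools.
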