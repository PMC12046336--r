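---
title: "Methods: germline-somatic driver QTL analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: germline-somatic driver QTL analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dqtltools)
```

## The problem

Tumors acquire recurrent somatic driver mutations — copy-number losses
and gains (with clonal "trunk" vs subclonal "branch" timing), SNV
hotspots, gene fusions — and patients differ in which drivers their
tumors acquire. A *driver QTL* (dQTL) is a germline SNP whose genotype is
associated with the presence of a specific somatic driver. Cohorts with
matched germline and somatic profiling are small (hundreds of patients),
so a genome-wide scan is underpowered; the package instead implements
four targeted search spaces per driver, each with its own
multiple-testing unit, plus the replication, meta-analysis, power and
characterization layers needed to interpret what such a scan can and
cannot see.

## The association model

Every scan fits, per SNP and driver, a logistic regression of the binary
driver on additive allele dosage, adjusting for the first five genetic
principal components, age, and a somatic mutation burden matched to the
driver type: PGA (proportion of the genome altered) for CNA and fusion
drivers, SNV density for SNV drivers. The burden covariate matters
because mutation burdens are mutually correlated and confound
driver-presence with overall instability. Missing genotypes are dropped
complete-case (the handling of post-joint-genotyping missingness is not
externally specified; complete-case is the package's choice and the
generator exposes `missing_rate` to stress it). Additive coding is used
for all scans; dominant/recessive/codominant codings appear only in the
clinical-association module, where the minimum-AIC model is reported.

Rare drivers crossed with rare alleles separate at these sample sizes, so
complete separation is detected and refit with a Firth-type penalized
likelihood, flagged in the output (`separation_flag`); a flagged estimate
is finite but should be treated as descriptive.

## Search spaces and multiple testing

* **risk**: a supplied risk-SNP list crossed with all eligible drivers
  (frequency ≥ 5%); Benjamini–Hochberg over the full SNP × driver grid,
  significance Q < 0.1. The full-grid adjustment is the conservative
  reading of an underdetermined description and is config-exposed.
* **linear**: SNPs with cohort MAF > 0.05 within ±500 kbp of the driver
  region.
* **spatial**: partner anchors of chromatin loops (e.g. RNAPII / RAD21
  ChIA-PET) touching the driver region, required in ≥ 2 distinct cell
  lines after merging overlapping partners, minus the linear window.
  "Interacts with the event region" is interpreted as ≥ 1 bp anchor
  overlap; no overlap fraction is imposed.
* **enhancer**: partner anchors of HiChIP H3K27ac loops with exactly one
  anchor in the driver region; a single cell line suffices.

Local strategies correct over *haplotype blocks*, not SNPs: the per-SNP
threshold is α / n_blocks with α = 0.1 (a deliberately permissive
family-wise level, counterbalanced by mandatory replication). Blocks
follow the Gabriel confidence-interval definition: pairwise |D′| is
estimated by EM from unphased 3×3 genotype tables, a 90% profile
likelihood interval for |D′| is computed on a grid with allele
frequencies fixed at their margin-determined MLEs, pairs are "strong LD"
(CI low ≥ 0.70, high ≥ 0.98) or "strong recombination" (high < 0.90), and
a contiguous run is a block when ≥ 95% of its informative pairs are
strong LD. Pairs with fewer than 20 complete genotypes are uninformative
(stabilizes small cohorts). Overlapping candidates are resolved greedily,
longest first, ties to the leftmost start; leftover SNPs are singleton
blocks. All thresholds are arguments. The greedy tie-break and the grid
resolution (0.005 on |D′|) are the only numerical choices; both are
config-exposed.

One tag SNP represents each significant block: the minimum-p SNP, ties
broken by smaller genomic position (a deterministic, documented rule).

## Replication, meta-analysis, screening

A discovered dQTL *replicates* when its replication-cohort refit (same
covariate model) is sign-concordant and BH-adjusted Q < 0.1 over the
discovered set. Replication cohorts without subclonal timing test the
collapsed CNA (timing dropped). Tag SNPs with concordant effects are then
screened against *all* drivers in a candidate grid (BH within grid,
originating pairs excluded) to find distal/pleiotropic candidates.

Cross-cohort pooling uses a random-effects model
β_i ~ N(µ, se_i² + τ²) with τ² estimated by REML via Fisher scoring with
nonnegativity projection (tolerance 1e-8, max 100 iterations) — the test
suite proves it equals a restricted-likelihood grid maximizer to 1e-4 and
collapses to the closed-form fixed-effect estimate at τ² = 0. Cohorts
contribute per dQTL only where the driver is callable (availability is
expressed simply by which rows exist in the estimates table).

## Power and extrapolation

Analytic power uses the non-centrality parameter of the 1-df allelic χ²
test: case/control allele frequencies are solved exactly from the
per-allele OR and the population MAF (a quadratic in the control
frequency), and NCP = (p_case − p_control)² / [p̄(1−p̄)(1/(2n_case) +
1/(2n_control))]. The fitted scan is genotype-based logistic, so this is
an approximation; a Monte Carlo oracle in the acceptance suite bounds the
gap at ±0.02 on a 3×3×3 grid. The α entering the power grid is a free
parameter (the source analysis does not state it); the acceptance suite
uses the printed per-SNP discovery bound 3.7×10⁻⁴ where a discovery
threshold is needed. Undiscovered-dQTL extrapolation bins discoveries on
(MAF, OR, driver frequency), divides observed counts by mean bin power,
and floors at zero per bin; bins under a 0.01 power floor are excluded to
avoid explosion.

## Co-occurrence and mutual exclusivity

Driver pairs present in ≥ 15 patients are tested with inclusive
hypergeometric tails (upper for co-occurrence, lower for exclusivity —
inclusive tails are the conservative convention where the source is
silent), BH-adjusted per direction (a joint-adjustment flag exists), and
classified at Q < 0.05. Each pair carries its minimum achievable p (the
all-overlap or zero-overlap extreme given the margins) as a power
annotation, and `min_cohort_for_exclusivity()` inverts that extreme case
to the smallest cohort where exclusivity is detectable at all.

## Characterization

Molecular QTLs (methylation, expression, protein) are linear models of
trait on dosage with PCs, age, and latent factors. The external
latent-factor tool used in the source analysis is replaced by the top-10
principal components of the covariate-residualized trait matrix: both are
variance-capture devices, the PC substitute is dependency-free, and the
count is config-exposed. Expression traits are rank inverse-normal
transformed (making results invariant to monotone transforms);
methylation beta values stay on their native scale. Tumor specificity of
a QTL is Q_tumor < 0.1 and (Q_reference > 0.1 or opposite signs) — a pure
function of (q, q, sign, sign) tested exhaustively.

Ancestry VAF bias reconstructs allele counts from published population
VAFs by rounding vaf × 2n (only VAFs and panel sizes are published) and
applies two-sided Fisher exact tests against the reference population,
FDR per comparison. The "fraction of an ancestral somatic difference
explained by a dQTL" sentence underdetermines its formula; the package
exposes a variant family (per-genome Δdosage — the default, per-allele Δ,
attributable-fraction scale) and stamps every output with the variant
used, rather than asserting any published range.

Distribution diagnostics: a permutation skew test reruns the full
per-driver scan under label permutation (which preserves driver frequency
exactly) and compares −log₁₀ p skewness; the study's estimator
#\{perm > obs\}/n is reproduced with an add-one option. π₀ is estimated by
the Storey λ-grid estimator with cubic-spline extrapolation to λ → 1,
falling back to λ = 0.5 under 20 p-values.

## The synthetic cohort: what it does and does not emulate

Defaults state the modeled world: 427 patients (discovery) with 17
drivers spanning frequencies 5.1%–57.3%; haplotype blocks with ~7 SNPs
(1 + Poisson(6)); covariates (5 PCs, age ~ N(65, 7), Beta/log-normal
burdens, ISUP grade group, T category, PSA); an independent replication
draw (optionally without timing); Balding–Nichols ancestry panels
(European/African/East-Asian sizes 7,718 / 4,359 / 780, Fst ≈ 0.11–0.12
for the non-reference panels).

Genotypes are block-structured: each block has an ancestral haplotype
pool (default 3 haplotypes, Dirichlet-weighted, alleles on random proper
subsets), individual haplotypes copy a pool member with per-SNP flip rate
`ld_decay` (default 0.005, chosen so the Gabriel estimator recovers the
planted partition at n ≈ 500), and diploids pair consecutive haplotypes.
A pool of ≤ 3 haplotypes guarantees |D′| = 1 within blocks at zero decay;
blocks are mutually independent. Drivers are drawn from the same logistic
law the scan fits, with the intercept bisection-solved to hit the target
marginal frequency to ±0.5%, and `confounded_by` planted effects shift a
covariate by genotype to create genuine confounding.

Not emulated: recombination-map realism, allele-frequency spectra from
demography, imputation uncertainty, somatic calling noise, population
substructure within a cohort. A green test therefore establishes that the
*statistics* behave as claimed on data satisfying their assumptions — not
that any biological conclusion transfers.

## Known limitations

* The block-Bonferroni's validity rests on blocks capturing the true
  correlation units; the null-calibration acceptance test checks this
  only in the generator's idealized LD world.
* Firth fallback estimates are flagged but still enter BH grids; with
  many separated cells, FDR calibration on those rows is approximate.
* Power extrapolation inherits the allelic-vs-logistic approximation and
  winner's-curse in the plug-in (MAF, OR) of discovered dQTLs; the
  acceptance criterion (±25% on a planted universe) bounds the combined
  effect at the stated scale only.
* The CLI exposes `simulate`, `run`, `cooccur`, `power`; the remaining
  stages run inside `run` via strategy toggles rather than as separate
  subcommands.
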