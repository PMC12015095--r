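---
title: "Models and methods: hormone response elements and sexual size dimorphism"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: hormone response elements and sexual size dimorphism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: the statistical
model, the counting conventions, the synthetic-data generator, and the
numerical and design choices made where more than one convention would have
been defensible. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The question and the model

Sexual size dimorphism is measured as `SSD = ln(male mass / female mass)`
(positive = male-larger, antisymmetric under swapping the sexes), and body
size as the arithmetic mean of the two masses. The hypothesis under test is
that SSD scales with the number of hormone response elements near genes, so
the species-level model is

$$\mathrm{SSD}_i = \beta_0 + \beta_1 \ln(\mathrm{HRE}_i) +
\beta_2 \ln(\mathrm{body}_i) + \varepsilon_i,\qquad
\varepsilon \sim \mathcal{N}(0,\ \sigma^2 V(\lambda)),$$

where HRE is the per-species ARE or ERE count in a TSS-flanking window and
body size enters because of Rensch's Rule (in male-larger clades, SSD tends
to increase with size, so size must be controlled). $V(\lambda)$ is the
phylogenetic variance–covariance matrix $C$ — $C_{ij}$ the shared
root-to-ancestor branch length of species $i$ and $j$ — with off-diagonal
entries multiplied by Pagel's $\lambda \in [0,1]$: $\lambda = 1$ is Brownian
motion, $\lambda = 0$ removes phylogenetic signal entirely.

Because SSD varies on very different scales across mammalian orders, orders
are analyzed as independent fits on subset tables (with a configurable
minimum of 20 species), never with order as a covariate.

## Motif scanning semantics

The two canonical motifs are the ARE `AGAACANNNTGTTCT` and the ERE
`GGTCANNNTGACC`; additional AREs from the literature vary in sequence and
binding specificity and can be supplied through the motif TSV (the package
ships only the two canonical sequences, since the extended set is not fixed
by a single printed source). Scanning rules, each of which is load-bearing
for the counts:

* **Overlaps.** Every valid start position is a hit, so overlapping
  occurrences all count — the semantics of position-by-position pattern
  counting.
* **Spacer `N` vs assembly `N`.** A motif `N` matches A/C/G/T only. An
  assembly gap character can never produce a motif hit; otherwise
  unresolved regions would manufacture counts out of artifacts.
* **Palindromes.** A degenerate motif equal to its own reverse complement is
  flagged palindromic and scanned on the forward strand only, since a
  reverse-complement scan would duplicate every occurrence. Non-palindromic
  motifs are scanned as given (strand `+`) and as their reverse complement
  (strand `-`, start reported in forward coordinates), and the two counts
  add.
* **Case.** Input is uppercased; soft-masked (lowercase) bases are scanned
  like any others, as no masking rule is part of the counting definition.
* **Coordinates.** 0-based, half-open everywhere internally; BED output uses
  the same convention, so hits and windows export without shifting.

The scanner is validated against an independent regular-expression oracle
(lookahead matching, so overlaps are preserved) on randomized sequences, and
against genomes with planted motif instances where the exact hit set is
known by construction.

## Window construction and the two counting modes

Each gene contributes the interval
$[\max(0, t - f),\ \min(L, t + f + 1))$ around its TSS $t$ on a contig of
length $L$ — a symmetric window of $f$ bases either side plus the TSS base
itself. Windows are symmetric regardless of gene strand ("upstream/
downstream" covers both sides); the $+1$ makes the window closed at the TSS,
a one-base convention that is immaterial at the flank sizes used
(10 kb–1 Mb) but fixed and tested. Only `Intact` and `ParalogousProjection`
genes enter by default: those are the categories whose TSS is trustworthy,
and duplicated genes are kept because the question concerns sex-biased
regulation of whatever is in the genome, duplicated or not.

* **Merged mode** unions all windows per contig (touching intervals merge)
  and counts a hit if its start position falls in the union — each genomic
  occurrence counts at most once no matter how many genes it sits near. The
  union's total length is reported as interrogated bp.
* **Per-gene mode** credits a hit to every gene whose window contains its
  start — the convention for the gene-centric scan, where the same
  occurrence may legitimately matter to several genes.

Membership is decided by the motif's start position, not full containment:
unambiguous for motifs spanning a window edge, and the difference is a few
bases against flanks of tens of kilobases. Merged counts are monotone
non-decreasing in the flank and bounded above by the per-gene sum, with
equality exactly when no two windows share a counted hit; both properties
are asserted in the suite.

## PGLS with maximum-likelihood Pagel's lambda

At fixed $\lambda$, writing $V = V(\lambda)$, the GLS solution is analytic:

$$\hat\beta = (X^\top V^{-1} X)^{-1} X^\top V^{-1} y,\qquad
\hat\sigma^2 = \frac{r^\top V^{-1} r}{n}\ \text{(ML)},$$

computed by Cholesky whitening rather than explicit inversion. $\lambda$ is
profiled out by bounded one-dimensional optimization of the profile
log-likelihood on $[0,1]$ (tolerance $10^{-8}$), with both endpoints
evaluated explicitly so boundary maxima are never lost to the golden-section
bracket. ML rather than REML mirrors the defaults of the phylogenetic
regression packages this analysis pattern comes from. Standard errors carry
the small-sample factor $n/(n-p)$ and p-values use a $t$ distribution on
$n-p$ degrees of freedom; both choices were confirmed, along with the
coefficients, likelihood and $\hat\lambda$, against `nlme::gls` with
`ape::corPagel` as an independent implementation.

The reported $R^2$ is the GLS deviance ratio
$1 - (r^\top V^{-1} r)/(r_0^\top V^{-1} r_0)$, with $r_0$ the residuals of
the GLS intercept-only fit under the same $V$ — "proportion of variance in
SSD explained, phylogenetically controlled". It reduces to the ordinary
OLS $R^2$ at $\lambda = 0$ and is guaranteed to lie in $[0,1]$ when the
design contains an intercept. Other definitions exist; this one is fixed
and tested.

Degenerate inputs are refused rather than repaired: trees without branch
lengths, negative branches, or zero-length terminal branches fail at load
(a tip at zero distance from its parent makes $C$ singular); a
non-positive-definite $V$ raises an error, with an explicit opt-in
`jitter` argument adding $10^{-10}\cdot\overline{\mathrm{diag}}$ for users
who want ridging; singular designs (e.g. a constant count column) error
rather than silently dropping columns.

Rescaling all branch lengths by a constant leaves $\hat\beta$, $t$, $p$,
$\hat\lambda$ and $R^2$ unchanged ($\hat\sigma^2$ absorbs the scale), so
trees need not be in any particular time unit.

## Phylogenetic PCA

Per-motif counts are $\log_{10}$-transformed (zero counts are refused, not
offset — a motif column with zeros should be dropped or handled upstream),
centered on the GLS phylogenetic mean
$a = (\mathbf 1^\top C^{-1}\mathbf 1)^{-1}\mathbf 1^\top C^{-1}X$, and
decomposed along the eigenvectors of the evolutionary covariance
$R = (X-\mathbf 1 a)^\top C^{-1}(X-\mathbf 1 a)/(n-1)$. Scores are the
centered data projected on those eigenvectors; their GLS mean is zero and
their GLS covariance is diagonal with the eigenvalues on the diagonal.
Brownian motion ($\lambda = 1$) is the default correlation structure — the
convention of the standard phylogenetic PCA implementations — with a fixed
$\lambda$ available as an option; whether to estimate $\lambda$ here is a
genuinely open choice and estimating it per decomposition was deliberately
not made the default. Eigenvector signs are fixed so each component's
largest-magnitude loading is positive. The decomposition is cross-checked
against `phytools::phyl.pca` and against ordinary PCA on a star phylogeny.

## The gene-centric scan

Each gene is tested separately with
`SSD ~ ln(count + 1) + ln(body size)` on the species that carry it.
Conventions:

* **Eligibility:** at least 10 species carry the gene and their counts take
  at least two distinct values ("variability" operationalized as ≥ 2
  distinct values).
* **Missing vs zero:** a species in which the gene is not annotated is
  missing data for that gene, not a zero — absence of an annotation is not
  evidence of zero regulatory elements. Observed zeros, however, are real,
  which is why this model (unlike the species-level one, where zero totals
  are excluded as degenerate) uses the $\ln(\mathrm{count}+1)$ offset.
* **Lambda:** re-estimated by ML per gene, with a fixed override available;
  fixing a single genome-wide $\lambda$ for all genes would be the main
  alternative and is one keystroke away.
* **Summaries:** the direction summary is the proportion of successfully
  fitted genes with a positive effect, significance not required. The
  significant-gene export applies `effect > 0` and uncorrected `p < 0.05` —
  deliberately uncorrected, as the export feeds enrichment tools that
  handle their own error control — while a Benjamini–Hochberg q-value
  column is emitted alongside for direct users. Failed fits are retained
  in the records with a status flag and excluded from summaries.

## The synthetic-data generator

The generator exists so that every stage has inputs with known ground
truth. What it emulates: a clock-like phylogeny (Yule tree rescaled to unit
depth); per-species motif abundances whose log rate evolves by Brownian
motion, with an optional monophyletic clade whose ARE rate is multiplied
(default 4×) to emulate a lineage-specific ARE explosion; genomes in which
every motif occurrence is planted at a known position near a known gene;
body mass evolving as ln-Brownian motion; and SSD generated from the
analysis model run forward, with phylogenetically structured residuals, so
male and female masses back-solve exactly to the generated SSD and body
size.

Generator defaults, chosen once as the conditions for all statistical
checks:

| parameter | default | rationale |
|---|---|---|
| `n_species` | 128 | large enough for stable ML $\lambda$, small enough for hundreds of replicates |
| `root_log_rate` | ln 50 | per-gene ARE rate; with 20 genes, totals ≈ 10³, so Poisson noise is small against BM spread |
| `rate_bm_var` | 0.25 | tip spread of ln counts (sd ≈ 0.5) comparable to real mammal ARE tables |
| `ere_root_log_rate` | ln 2 | EREs roughly 25× rarer than AREs, as in real genomes |
| `beta_are`, `beta_body` | 0.3, 0.3 | effect sizes detectable but not overwhelming at n = 128 |
| `lambda` | 0.5 | intermediate phylogenetic signal, the hardest case for $\lambda$ estimation |
| `resid_sd` | 0.2 | residual SSD noise on the scale of real interspecific SSD spread |
| `body_bm_var` | 1.0 | several-fold mass range across a unit-depth tree, 1 kg root |
| `burst_multiplier` | 4 | the documented fold-increase of a clade-specific ARE explosion |

What the generator does **not** emulate — and hence what passing tests do
not establish about real data: realistic genome composition (repeats,
isochores, GC structure), multiple contigs and assembly fragmentation,
annotation error, TSS uncertainty, correlated evolution of ARE and ERE
counts, measurement error in literature body masses, and real taxon
sampling. Counts are Poisson by default (negative binomial by option) at
regular TSS spacing on one contig per species: window clamping and merging
are exercised by dedicated fixtures rather than by genome realism. With
`clean_background` the background is rejection-resampled (capped at 1,000
passes) until the scanner finds exactly the planted occurrences; planted
spans are protected and kept at least one motif-length apart so junction
artifacts cannot arise.

All randomness in a run flows from one integer seed with fixed per-stage
offsets, making every dataset byte-reproducible.

## Problem sizes of the shipped checks

The statistical checks run at deliberately chosen scales: the recovery grid
$\lambda \in \{0, 0.5, 1\} \times n \in \{64, 256\}$ with 50 replicates per
cell; null calibration with 500 replicates at n = 128; the burst scenario
with 50 power replicates and 200 null replicates at n = 128; gene-centric
direction checks pooling 100 genes from each of three independent worlds
per condition (a single-world binomial band check on 100 genes fails about
one run in twenty by construction, so the band is applied at the pooled
size); scanner-oracle agreement on 100 random sequences up to 10 kb for
five motifs. The whole suite completes in a few minutes on one CPU.

## Known limitations

* **ML $\lambda$ with clade-structured predictors is anticonservative.**
  The burst scenario makes the ARE predictor carry a single deep clade
  shift. With $\lambda$ fixed at its generative value the null rejection
  rate of the ARE effect is nominal, but re-estimating $\lambda$ per fit —
  exactly what the species-level pipeline does — inflates it measurably
  (the acceptance script reports both rates side by side, and the effect
  grows as n shrinks toward per-order sample sizes of 20–40, where
  $\hat\lambda$ is very noisy). Conclusions that hinge on a significant
  effect of a predictor dominated by one clade contrast deserve a
  fixed-$\lambda$ or clade-indicator sensitivity check.
* **Zero totals are excluded, not modeled.** A species with a zero ARE or
  ERE total cannot enter the ln-scale species-level model and is dropped
  with a warning; a count model (e.g. negative-binomial regression) would
  be the principled alternative if zeros were common.
* **Motif counts are a proxy.** The scanner counts sequence matches;
  binding, chromatin accessibility and regulatory effect are out of scope,
  as is position-weight-matrix scoring. Only the two canonical motifs ship
  with the package; extended ARE sets must be supplied by the user.
* **The GFF3 adapter trusts the `gene` features' 5' ends** as TSSs and
  defaults the annotation category to `Intact` when no status attribute is
  present — adequate for TOGA-style annotations, not for arbitrary GFF3.
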