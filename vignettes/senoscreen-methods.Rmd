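---
title: "Methods: models, scores and design choices in senoscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, scores and design choices in senoscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`senoscreen` analyses drug-sensitivity screens of neuroblastoma model
cohorts spanning the mesenchymal-to-adrenergic identity spectrum. This
vignette documents each statistical component, its assumptions, the
parameters that matter, and the choices made where the design was genuinely
open. Nothing here states an empirical result beyond what the package's test
suite and `scripts/acceptance.R` themselves compute.

## Dose–response model and DSS

Viability is normalized per plate by the **median of the solvent-control
wells** (median rather than mean to resist single aberrant control wells)
and clipped to [0, 2] to bound the leverage of outlier wells. Each
line × drug series is fitted with the five-parameter asymmetric logistic

$$y(x) = L + \frac{U - L}{\left(1 + (x/\mathrm{EC}_{50})^{h}\right)^{s}},$$

on log10 dose, where $L, U$ are the lower/upper viability plateaus, $h > 0$
the Hill slope and $s > 0$ the asymmetry ($s = 1$ recovers the symmetric
4PL). Fitting uses Levenberg–Marquardt least squares with **multi-start
initialization** (EC50 grid over the observed dose range, $h \in \{0.5, 1,
2\}$, $s \in \{0.5, 1, 2\}$) and box constraints $L \in [0,1]$,
$U \in [0.5, 1.5]$, $s \in [0.1, 10]$; the start with the best residual sum
of squares wins. Multi-start matters because the asymmetric likelihood
surface is multimodal when the tested range only brackets one plateau.
Near-constant series (SD below $10^{-6}$) and total optimizer failure fall
back to a flat curve flagged `converged = FALSE` — scoring never aborts a
plate because one well series is degenerate.

The drug sensitivity score integrates thresholded inhibition
$i(x) = 100\,(1 - y(x))$ over the log10-dose window:

$$\mathrm{DSS} = \frac{100 \int_{x_\min}^{x_\max} \max(i(x) - t,\, 0)\,dx}
{(100 - t)(x_\max - x_\min)},$$

with activity threshold $t = 10\%$ by default, evaluated by adaptive
quadrature (relative tolerance $10^{-8}$; the suite checks agreement with a
dense trapezoid oracle to 0.1 DSS units). The score is 0 when inhibition
never exceeds $t$ and 100 for complete inhibition across the window, and is
invariant to dose-unit relabeling when the window is transformed
consistently. The window defaults to each series' tested range; a fixed
absolute window can be supplied for cross-drug comparability — the tested
range is the safer default when dose ranges are drug-specific, which is the
norm for libraries assembled around clinically relevant concentrations.

## Cohort quantile ranking

For one drug, a line's quantile rank over the $n$ lines with non-missing
DSS is the midrank empirical CDF

$$q = \frac{\#\{j : \mathrm{DSS}_j < \mathrm{DSS}_\ell\} +
\tfrac12 \#\{j \ne \ell : \mathrm{DSS}_j = \mathrm{DSS}_\ell\}}{n}.$$

A rank *strictly* above 0.75 is a hit, strictly above 0.95 a top hit. Two
reading notes. First, the verbal rule this implements is sometimes phrased
as "the sum of DSS below the line divided by the number of lines"; a literal
sum of DSS values is not a quantile, so the count interpretation (the
empirical CDF) is used. Second, strict inequalities mean a cohort of $n$
lines can never produce a rank above $(n - \tfrac12)/n$ for tied values or
$(n-1)/n$ for a unique maximum — top-hit calls therefore need $n > 20$.
Missing DSS values are excluded per drug rather than imputed, because
screening cohorts are heterogeneous across assay batches. Subtype groups
are compared on per-line mean DSS with a two-sided Wilcoxon rank-sum test,
exact when both groups have ≤ 10 lines and no ties.

## Single-sample gene-set scores

`ssgsea` ranks each sample's genes by decreasing expression (ties broken
deterministically by gene identifier) and walks the list accumulating two
ECDFs: in-set genes step by their rank weight $r^{\alpha}$ (top gene has
$r = N$) normalized over the in-set genes, out-of-set genes step uniformly
by $1/(N - m)$. The enrichment score is the **integrated difference**
$\sum_p (\mathrm{ECDF}_{\mathrm{in}} - \mathrm{ECDF}_{\mathrm{out}})$ — the
single-sample variant, not the max-deviation statistic — with
$\alpha = 0.25$ as default. Being rank-based, the score is invariant to any
per-sample monotone transform of expression; the suite verifies exact
agreement with a brute-force enumeration on 500 random small matrices.

The mesenchymal/adrenergic score is the ssGSEA enrichment of one
mesenchymal super-enhancer signature, min–max normalized to [0, 1] across
the cohort (higher = more mesenchymal). A genuinely open question was
whether to subtract an adrenergic signature to form one axis; the package
scores the mesenchymal set alone, since the identity is described by the
mesenchymal super-enhancer program and a second set can always be scored
separately and combined downstream. Cohort min–max normalization means the
score is only defined for ≥ 2 samples and is relative to the cohort at
hand. MPAS is $\sum_i z_i / \sqrt{k}$ over the $k$ MAPK target genes
present (absent genes dropped with a warning); a MEKi-sensitivity signature
can be scored as a plain ssGSEA set.

## Lysosomal phenotyping

Nuclei are segmented by Gaussian smoothing, global Otsu threshold, hole
filling and watershed on the distance transform (minimum area 30 px);
cells by seeded watershed propagation of the nuclei over the cell-mask
intensity restricted to its Otsu foreground — one cell per nucleus by
construction. Puncta are detected as local maxima of the
Laplacian-of-Gaussian response at spot scale $\sigma = 1.5$ px, thresholded
at $k = 5$ times the robust (MAD) background SD of the response; the
threshold is background-relative, so global intensity rescaling does not
change counts. Per-image aggregation uses foci per nucleus
($n_{\mathrm{foci}} / n_{\mathrm{nuclei}}$) even when cell segmentation is
available, keeping per-cell count distributions for display only.

The **combined basal lysosomal score** normalizes each stain's
foci-per-cell value to the reference line (default `GI-M-EN`) on the *same
plate* — cancelling plate-wide staining efficiency exactly — then averages
the normalized values per stain across plates and sums the three stain
means (LAMP1, LAMP2, Lysotracker). The reference line scores 1 per stain,
hence combined = 3. Normalizing before averaging (rather than the reverse)
is deliberate: it makes the score invariant to plate-wide multiplicative
effects, which is the point of carrying a reference line on every plate.
The **adaptation score** for a treated dose series is
$\sum_c (\mathrm{ratio}_c - 1)$ over the DMSO-normalized values; five doses
are the design target, fewer produce a warning, and a zero DMSO control is
an error rather than an infinity.

Marker-positive/negative cell classification (e.g. YAP1 status) uses mean
nuclear marker intensity against an Otsu threshold of the per-cell
intensity distribution, or a fixed configured threshold. This deterministic
policy replaces interactive machine-learning nucleus classification: it is
reproducible without training data, and the interface accepts an externally
derived threshold where a trained classifier's operating point is
available. A spread-free intensity distribution is flagged degenerate and
yields a single class rather than an arbitrary split.

## Synergy on full and reduced designs

The combination surface stores a $(K_1 + 1) \times (K_2 + 1)$ inhibition
matrix whose first row/column are the monotherapy edges. Each edge is
fitted with a symmetric logistic, and every interior well's ZIP delta is
$\delta_{ij} = y^{\mathrm{obs}}_{ij} - (\hat y_{1i} + \hat y_{2j} -
\hat y_{1i}\hat y_{2j})$; the summary is $100 \times$ the mean interior
delta, classified synergy/additive/antagonism-trend at ±10. Observed
interior inhibition is compared directly against fitted-edge expectations
— no two-way re-fitting of interior response curves — a deliberate
simplification: reduced designs leave too few interior points per row or
column for stable re-fitting.

For the **diagonal minimal-sampling design** (edges + equal-dose-rank
diagonal measured), the diagonal deltas $d_k$ are linearly interpolated
over dose rank at $k^* = (i + j)/2$ (clamped to $[1, K]$) and added to the
ZIP expectation, clipping to [0, 1]. This rank-index interpolation is exact
for constant-delta surfaces and for any delta profile that varies linearly
along the anti-diagonal direction; the suite checks that on smoothly
varying profiles the reduced-design mean ZIP lands within 2 units of the
full-matrix value in ≥ 95% of 200 random surfaces. Edges can never be
imputed — a missing edge is a hard error.

CSS fixes each partner at the tested dose nearest (log scale) its fitted
IC50, fits the resulting combination dose–response, and integrates it with
the DSS formula at threshold $t = 0$ — CSS measures effect magnitude, not
a hit call, so no activity floor is subtracted. The reported CSS is the
mean of the two directions, making it invariant to drug-label exchange;
values above 40 are classed high-effect. An IC50 outside the tested range
falls back to the nearest edge dose with a warning flag. Sequential vs
co-treatment schedules are compared as paired per-(line, combination)
differences of CSS and mean ZIP with a paired Wilcoxon signed-rank test
(p = 1 returned directly for all-zero differences, where the test statistic
is undefined).

## Xenograft response

Percent volume change $100\,(v_{72} - v_{24})/v_{24}$ is classified with
inclusive boundaries: PR at ≤ −30%, PD at ≥ +20%, SD otherwise. Volumes
are accepted in any consistent unit (the call is scale-invariant); volume
measurement itself is upstream of the package. Arms are compared with a
two-sided Mann–Whitney test on the percent changes of *all* embryos — SD
embryos are not excluded, since the percent change itself, not the
category, carries the information. The exact null is used when the smaller
arm has ≤ 8 embryos and no ties.

## What the synthetic cohort emulates — and what it does not

The generator is first-class, tested code; its defaults *are* the study
conditions for validation:

* 20 lines with latent mesenchymal scores evenly spanning [0, 1]; the
  mid-spectrum line is named `GI-M-EN` and serves as imaging reference, so
  reference normalization never divides by a near-zero rate.
* Five log-spaced concentrations (1 nM – 10 µM); concentration ranges per
  drug are configurable, with no claim of matching any particular library.
* MEKi EC50 shifts $\times 10^{1.5(0.5 - \mathrm{mes})}$ (potency rises
  with mesenchymal score), chemotherapy $\times 10^{1.0(\mathrm{mes} -
  0.5)}$ (resistance rises), other drugs neutral.
* Multiplicative log-normal viability noise with unit mean (CV 0.05
  default): plate luminescence is positive and CV-stable, which a
  log-normal reproduces and an additive Gaussian does not.
* Signature genes shifted by `effect_size` × mes score (scaled 1 / 0.8 /
  0.6 for MES / MPAS / SASP so all three are identity-linked but
  distinguishable) over iid backgrounds; expression noise SD 0.5.
* Lysosome puncta rate 4 + 12 × mes per cell; rendered images place
  non-overlapping disk cells by rejection sampling and Poisson puncta as
  Gaussian spots (σ = 1.5 px) with amplitude 6 × the background SD, and a
  **minimum 4 px separation between puncta within a cell**: spots closer
  than ~2σ are physically unresolvable as distinct local maxima, and
  lysosomes are solid organelles that do not coincide.
* Combination surfaces with interaction delta 0.15 × mes (stronger
  MEKi-senolytic interaction in mesenchymal lines), noise CV ≤ 0.02.
* Xenograft log volume ratios Normal(0.22 − group × 0.34, 0.35), i.e.
  untreated tumors grow ~25% at the median while the treated arm is
  centered near −11%; these values place the arms' partial-response rates
  in the vicinity of one quarter (treated) and a few percent (control),
  the regime reported for zebrafish embryo xenograft trials of this
  combination, with 40 embryos per arm.
* All randomness flows through named substreams of one base seed, so
  adding a generator never perturbs another table's draws, and identical
  configurations are bitwise-reproducible.

Not emulated: spheroid 3D geometry and optical sectioning, mixed
subtype populations within one culture, cell-shape features beyond disks,
spatially correlated imaging noise, dose–response model misspecification,
or single-cell expression counts. Passing tests therefore demonstrate that
the algorithms recover the structure they assume, *not* that real screens
satisfy those assumptions — segmentation accuracy on textured, overlapping
real cells in particular will be lower than on the rendered disks.

## Numerical conventions and degenerate inputs

* Expression gene identifiers are whitespace-trimmed and matched
  case-sensitively; duplicates are rejected at load.
* ssGSEA expression ties break by gene identifier, making scores
  deterministic under row permutation.
* Quadrature: `stats::integrate` with rel.tol 1e-8; curve fitting:
  `minpack.lm::nlsLM`, max 200 iterations per start.
* Zero-variance z-score columns map to zeros (not NaN); zero-overlap gene
  sets, missing reference lines, zero DMSO controls, non-positive volumes
  and invalid windows are errors that name the offending object.
* Problem sizes in the test suite — 100 noiseless curves, 1000 ranking
  vectors, 500 ssGSEA matrices, one 50-cell image, 200 synergy surfaces, a
  20-line end-to-end cohort — were chosen as the smallest sizes at which
  each property is a meaningful statistical statement.

## Known limitations

* The DSS family has several published variants; the normalized
  thresholded-area definition used here is bounded, reduces correctly in
  the trivial limits, and is applied to the asymmetric fit, but absolute
  values are not interchangeable with other implementations' scores.
* ZIP here scores observed-minus-expected against fitted edges only; full
  two-way ZIP re-fitting (as in dense-matrix synergy tools) is out of
  scope for reduced designs.
* The imaging pipeline assumes one nucleus per cell and roughly convex
  cells; multinucleated or overlapping cells will be mis-segmented.
* Cohort min–max normalization of signature scores makes cross-cohort
  comparison of normalized values meaningless; compare raw enrichment
  scores instead.
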