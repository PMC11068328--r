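---
title: "Quantifying somatic CAG-repeat instability: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying somatic CAG-repeat instability: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repquant)
library(dplyr)
```

repquant quantifies somatic instability of expanded CAG repeats from
capillary-electrophoresis fragment analysis, together with three companion
analyses that arise in the same experimental designs: cohort-level
multivariate statistics of the repeat-profile panel, per-gene classification
of transcriptional rescue, and threshold-based quantification of aggregate
immunostaining. This vignette is the package's own account of the models it
implements, the conventions it fixes where the field's informal practice is
ambiguous, and what its synthetic-data generators do and do not emulate.

## The instability index

A fragment-analysis trace of a PCR across an expanded CAG tract is a set of
peaks, one per observed repeat length, whose heights reflect the abundance
of template molecules of that length in the tissue sample. Let the retained
peaks of a sample have repeat lengths $x_i$ and heights $h_i$. repquant
normalizes heights to probabilities $p_i = h_i / \sum_j h_j$ after
discarding peaks below a *relative height threshold*: peaks with
$h_i < \tau \cdot \max_j h_j$ are treated as stutter ladder or baseline
noise. The default is $\tau = 0.10$; it is recorded in every output row
because the published descriptions of this family of analyses do not print
the threshold, and results are mildly sensitive to it.

With a reference modal allele $m$ (the tallest peak of the same animal's
early-life ear biopsy), the displacement of peak $i$ is $d_i = x_i - m$ and

$$\mathrm{II} = \sum_i p_i d_i, \qquad
  \mathrm{EI} = \sum_{d_i > 0} p_i d_i, \qquad
  \mathrm{CI} = \sum_{d_i < 0} p_i |d_i|,$$

so that $\mathrm{II} = \mathrm{EI} - \mathrm{CI}$ exactly. Probabilities are
normalized over *all* retained peaks, not renormalized within each side;
this convention is what makes the decomposition an identity rather than an
approximation.

The per-sample panel assembled by `instability_metrics()` additionally
baselines each component against the reference trace itself: the reported
instability, expansion and contraction are the sample's components minus the
reference profile's own components about its mode. A profile compared with
itself therefore scores exactly zero, and trace breadth shared between
sample and reference — including the PCR stutter ladder, which is common to
both reactions — cancels instead of inflating every tissue's apparent
instability. The cost of this choice is that a baselined expansion or
contraction column can go slightly negative when a tissue trace is narrower
than its reference; we consider this more informative than clamping at
zero.

Two anchoring modes are provided. The default anchors displacements at the
reference (ear) mode, matching how tissue panels are normalized to the
P12 ear sample in this literature. `ref_mode_source = "self"` anchors each
sample at its own mode, which is occasionally wanted for cross-study
comparisons where no early-life reference exists; the change in mode is
always reported against the reference.

### Weighted summary statistics

The cohort multivariate panel uses probability-weighted moments: mean,
variance $\sum p_i (x_i - \mu)^2$, skewness $m_3 / m_2^{3/2}$ and *excess*
kurtosis $m_4 / m_2^2 - 3$ (a Gaussian profile scores 0; published loading
plots list "kurtosis" without fixing the convention). Quartiles are computed
by linear interpolation on the cumulative probability over the sorted
repeat support, clamped at the support ends; a discrete
largest-repeat-below convention was considered and rejected because it
makes the IQR jump by whole repeat units under infinitesimal height
changes. Log columns are $\log_{10}(v + 10^{-6})$; the small guard keeps
degenerate single-peak profiles finite, and such profiles report skewness
and kurtosis 0 with an explicit `degenerate` flag rather than `NaN`.

### Sizing arithmetic

When input arrives as fragment sizes rather than repeat counts, sizes are
mapped to the repeat lattice as
$\mathrm{round}((\mathrm{bp} - \mathrm{offset}) / 3)$ with half-repeat ties
rounded away from zero. The flanking-sequence offset has no safe default —
it depends on the primer design — so it must be calibrated explicitly from
a sample of known repeat length (`calibrate_offset()`); the package refuses
to guess. Raw-trace support (plain TSV or ABIF containers) sizes peaks by
piecewise-linear interpolation through the internal size-standard points,
i.e. local sizing rather than a global mobility regression; positions
outside the standard range are extrapolated and flagged rather than
silently trusted. Triplicate instrument runs are merged by averaging
per-replicate-normalized heights so that run-to-run amplification
differences carry no weight.

## Cohort statistics

The PCA of the summary-statistic panel operates on the correlation matrix:
the panel mixes repeat units, log-variances and dimensionless shape
statistics, so unstandardized covariance PCA would be dominated by whichever
variable happens to have the largest numeric range (usually `n`, the summed
peak height). Components are ordered by eigenvalue and signed so that the
largest-magnitude loading of each component is positive, making score plots
reproducible across platforms. Samples with any missing metric are dropped
with a message; a constant column is an error naming the column, not a
silent degeneracy.

Because a genetic intervention also shifts the reference tissue itself, a
tissue metric normalized to the ear can inherit baseline variability. The
ANCOVA stage therefore fits ordinary least squares of each response on
genotype (treatment-coded) plus the same animal's ear value of that
response as a covariate, and reports least-squares means per genotype
evaluated at the covariate grand mean with $t$-based 95% intervals on the
residual degrees of freedom. Variance-type responses are fitted on the
$\log_{10}$ scale and back-transformed, so their least-squares means are
geometric means. The genotype effect is a partial $F$-test against the
covariate-only model. Passing `covariate = NULL` reduces the fit to a plain
one-way analysis — in that case the genotype $F$ equals `aov()`'s one-way
$F$ exactly, which the test suite asserts. Mixed-effects refits, post hoc
multiple comparisons and outlier screening are deliberately out of scope;
standard packages (`lme4`, `emmeans`, `multcomp`) apply directly to the
exported per-sample table.

## Transcriptional rescue

Given a disease-vs-control contrast ($\beta_{\mathrm{HD}}$ per gene) and a
rescue-genotype contrast in the disease background
($\beta_{\mathrm{KO}}$, both in $\log_2$), the rescue of each gene is
summarized by the multiplier $\alpha = \beta_{\mathrm{KO}} /
\beta_{\mathrm{HD}}$: $\alpha = -1$ means the knockout pushed the gene
exactly back to control levels, $\alpha < 0$ any reversal, $\alpha > 0$
exacerbation. Genes enter the analysis if they pass the signature filter
(adjusted $p < 0.05$ and at least a 20% fold change in either direction,
i.e. $|\beta_{\mathrm{HD}}| \ge \log_2 1.2$). The class bands are
super-reversal ($\alpha < -1.3$), full ($-1.3$ to $-0.7$), partial ($-0.7$
to $-0.3$), negligible ($-0.3$ to $0.3$) and exacerbation
($\alpha > 0.3$). The printed band definitions use strict inequalities on
both sides and so leave the boundary points undefined; repquant assigns
each boundary to the class nearer zero, which is conservative against
claiming rescue, and exposes the cut points as configuration.

The $\alpha$ standard error follows by first-order error propagation
assuming independent contrast errors,
$\mathrm{se}_\alpha^2 = (\mathrm{se}_{\mathrm{KO}} /
\beta_{\mathrm{HD}})^2 + (\alpha\, \mathrm{se}_{\mathrm{HD}} /
\beta_{\mathrm{HD}})^2$, a form that stays finite at
$\beta_{\mathrm{KO}} = 0$. Whether the two contrasts are really
independent depends on the design (shared control samples induce
correlation); the summary output flags the probability method as a Gaussian
approximation with independent errors. Class-membership probabilities are
Monte-Carlo fractions over $10{,}000$ seeded draws from
$\mathcal N(\alpha, \mathrm{se}_\alpha^2)$; the draws are seeded per gene
so results do not depend on gene order, and the test suite checks the
fractions against analytic Gaussian tail differences. The overall reversal
probability is $P(\alpha < -0.3)$, the exact sum of the three reversal-class
probabilities. Genes with $|\beta_{\mathrm{HD}}| < 0.05$ (log2) are marked
not evaluable rather than classified: the ratio is numerically unstable and
scientifically meaningless for a flat disease effect. Summaries report the
percent rescued both including super-reversal and as full+partial only, so
either reading of "rescued" is recoverable.

## Aggregate imaging

Immunostained sections are quantified on 8-bit grayscale images with the
field's two-parameter rule: a pixel is positive if its intensity strictly
exceeds a threshold, positive pixels are grouped into connected components,
and components below a pixel gate are discarded. The two standard parameter
pairs — threshold 190 with an 80-pixel gate for stained objects, threshold
150 with a 2-pixel gate for inclusions — run as two independent
segmentations of the same image. Connectivity defaults to 8-connected
("pixels in contact" read to include diagonal contact) with 4-connected
available. Whether stained material is bright or dark on the image depends
on the acquisition (DAB bright-field images are dark-positive), and an
8-bit threshold does not disambiguate; polarity is therefore an explicit
argument, never guessed, and dark-positive images are inverted as
$255 - v$ before thresholding. The percent image area is computed over
retained-object pixels, with the raw-mask percentage also reported. One
caveat worth knowing: raising the intensity threshold always shrinks the
stained area, but can occasionally *split* a dumbbell-shaped component into
two retained objects, so the object count is only guaranteed monotone in
the gate, and in the threshold for convex (disk-like) objects.

The labeller itself is a two-pass run-merging union-find over row runs,
written in R because no installed package exposes both connectivities on
plain matrices with a stable labelling order; it is validated against a
brute-force flood fill in the tests.

## The synthetic-data generators

No animal data ships with the package. Instead, seeded generators produce
every input the pipeline consumes, with planted ground truth, and the
acceptance checks run against them. The somatic process is a deliberately
minimal per-cell birth/death model: over $t$ months a cell accumulates
expansion events at rate $\lambda_e \cdot f \cdot d$ per month (base rate
$\lambda_e$, tissue factor $f$, Msh3 dosage $d \in \{0, 0.5, 1\}$ scaling
expansion linearly and *only* expansion) and contraction events at
$\lambda_c \cdot f$, independent of dosage; event counts are Poisson, jump
sizes geometric (unit jumps by default), lengths floored at one repeat.
This mirrors the core observations the model must emulate: expansion
proportional to MSH3 dosage, contraction unaffected by it, and
tissue-specific overall activity. It does not attempt mechanism — no
cell-type mixtures, no length-dependent acceleration of the expansion rate
(a hook exists, off by default), no replication timing.

Defaults are chosen once to make a striatum-like tissue gain about six
repeats in six months from an inherited repeat of 185 (base expansion rate
1.0 events/cell/month at tissue factor 1, a visible multi-repeat mode shift
of the kind seen in highly unstable tissues), a heart-like tissue stay flat
(factor 0.02), and a pituitary-like tissue drift downward at every dosage
(factor 0.4 with contraction rate 1.5/month, i.e. contraction-dominant).
The ear reference is simulated with both rates scaled by 0.02 — nearly but
not perfectly stable, since real early-life ear traces have visible
breadth.

The observation process models bulk-PCR stutter as a minus ladder: a
molecule of length $L$ contributes normalized mass $(1-s)s^k$ at $L-k$.
The default $s = 0.15$ is a placeholder calibrated only for test
stability — a realistic stutter fraction for a ~185-repeat CAG PCR is not
derivable from published trace figures — and a plus ladder is available
behind a parameter (default 0, since CAG stutter is predominantly
contraction). Heights are Poisson-jittered and peaks below 1% of the
tallest are dropped, emulating the detection floor. Two known biases of
real bulk PCR are deliberately reproduced rather than corrected: stutter
shifts the measured instability index below the population truth
(monotonically in $s$, asserted in the tests), and no correction is
attempted for preferential amplification of shorter alleles — the
generators do not model that bias at all, so passing tests say nothing
about it.

DE-table generation plants a reversal class per gene, draws
$|\beta_{\mathrm{HD}}|$ uniform on $[0.3, 2]$ for signature genes and a
true $\alpha$ uniform within the class band, then adds Gaussian
observation noise (default se 0.05 per contrast) and assigns adjusted
p-values small for signature genes and uniform for nulls. Staining scenes
place non-overlapping constant-intensity disks (nuclei above the object
gate, inclusions above the inclusion gate) over Gaussian background, so
the planted counts are exact ground truth for the segmentation. All
generators derive per-stream seeds from the global seed with a fixed
counter scheme, so adding a tissue or an image never perturbs another
stream's draws, and identical configuration plus seed gives byte-identical
outputs.

## Problem sizes and numerical conventions

The test suite and acceptance script run at desk scale, chosen as the
smallest sizes at which the stochastic assertions have comfortable margins:
1,000 random profiles for the index oracle; 5,000 cells per sample and 8
mice per dosage arm for the end-to-end dosage-linearity check; 1,000 genes
at noise se 0.05 (averaged over three replicate cohorts) for planted-class
recovery; $10^4$ Monte-Carlo draws per gene for class probabilities;
$32^2$ random masks against the flood-fill oracle. Monte-Carlo assertions
use three-standard-error bands. Other fixed conventions: modal ties break
to the smallest repeat; fractional repeats round half away from zero;
probability vectors are validated to sum to one within $10^{-9}$.

## Known limitations

Everything the generators omit is a limitation of what the tests can show:
real traces carry length-dependent amplification bias, baseline drift and
occasional off-ladder peaks; real DE contrasts have correlated errors and
heavy-tailed effect distributions; real sections have uneven illumination
and touching nuclei. The instability index itself is known to
underestimate expansion for long repeats because capillary electrophoresis
of bulk PCR preferentially detects shorter tracts; repquant reports what
the trace shows and leaves small-pool PCR or no-amplification sequencing
designs out of scope.
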