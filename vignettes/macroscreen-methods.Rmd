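---
title: "Models and methods behind macroscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind macroscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(macroscreen)
```

`macroscreen` implements the analysis pipeline of a cell-shape phenotypic
screen for macrophage polarization, plus the transcriptional analyses used
downstream of such a screen. This vignette explains the models, the
parameters that matter, what the synthetic generators emulate (and do not),
and the numerical and design choices that were genuinely open.

## The morphology model

Primary human macrophages round up under pro-inflammatory (M1) stimulation
and elongate under anti-inflammatory (M2) stimulation. The package models a
well's cell population as a two-state mixture: a "round" subpopulation and
an "elongated" one, with a baseline elongated fraction of 0.20 — the
typical non-activated (M0) culture. Per-cell eccentricity within each state
follows a beta distribution parameterized by its mode and a shared
concentration parameter $\kappa$, which keeps all values in $[0,1)$, the
natural range of eccentricity.

Defaults: round mode 0.45, elongated mode 0.88, $\kappa = 40$. These were
chosen once to give clearly separated but overlapping shape distributions,
comparable to segmented single-cell shape data from adherent macrophage
cultures: spread macrophages are rarely perfect discs (hence a round mode
well above 0), and elongated cells approach but do not reach a line. The
distributional form itself is a modelling choice — only the baseline
elongated fraction and the per-well imaging scale (~1000 cells, six fields)
are empirical anchors.

Compound action is modelled as *state switching*, not per-cell stretching:
a compound at concentration $c$ shifts the elongated fraction by
$\Delta_{\max}\, c/(K_m + c)$, clamped to $[0,1]$. M1 actives have
$\Delta_{\max} < 0$, M2 actives $> 0$, inert compounds $0$. This matches
the biology of polarization as a population-level phenotype change and
makes the dose dependence of the plate statistic inherit the saturating
Michaelis-Menten form.

## The plate Z-score

A 384-well plate has 16 rows by 24 columns; columns 1, 2, 23 and 24 of each
row carry DMSO and are pooled as that row's control. The screen statistic
is the Welch two-sample $t$ on per-cell eccentricities,

$$Z = \frac{\bar e_t - \bar e_c}{\sqrt{s_t^2/n_t + s_c^2/n_c}},$$

positive when treated cells are more elongated. "Calculated by T-test"
admits either the pooled-variance or the Welch form; the Welch statistic
was chosen because at ~1000 cells per well the two are numerically close
and Welch needs no equal-variance assumption between wells. Cells from the
six fields of a well are pooled before testing; positive-control wells are
scored against the same row pool as treatments; cutoff comparisons are
inclusive ($\le$/$\ge$), documented because either convention is
defensible. Rows without usable controls are skipped with a warning rather
than failing a whole plate.

Hit-calling cutoffs are calibrated as the mean Z of wells carrying
classical M1 and M2 stimuli. The synthetic stimuli are solved analytically
(via the closed-form mixture moments, `expected_zscore` /
`shift_for_target_z`) so that their asymptotic plate Z equals $-4$ and $+6$
— the calibration regime of the screen this package models. With ten
positive wells per class and Poisson(1000) cells per well, realized
calibrations land within a fraction of a Z-unit of those targets.

## Dose response and effective concentration

Z versus concentration is fitted as $z(c) = z_{\max} c/(K_m + c)$ with no
intercept: DMSO defines $Z = 0$ by construction, so the curve passes
through the origin. $z_{\max}$ is free in sign. For fixed $K_m$ the model
is linear in $z_{\max}$, so the fit profiles $z_{\max}$ out and minimizes
over $\log K_m$ on a fixed 121-point grid spanning two decades beyond the
tested concentrations, followed by 1-D refinement (`optimize`, tolerance
$10^{-12}$). This is deterministic — no random starts — and recovers
noiseless parameters to $10^{-6}$.

The effective concentration solves $z(EC) = \text{cutoff}$:
$EC = K_m \cdot \text{cutoff}/(z_{\max} - \text{cutoff})$, defined only
when the asymptote exceeds the cutoff in magnitude with matching sign.
When the curve never reaches the cutoff the EC is explicitly undefined
(`NA`) rather than extrapolated; that matches the EC's verbal definition as
a cutoff-reaching concentration, and such fits are classified as lacking a
strong dosage effect.

## Mutual-information networks

Gene-pair dependence is scored by a rank-based binned mutual information:
both profiles are rank-transformed, discretized into
$B = \lfloor\sqrt{n}\rfloor$ equal-frequency bins, and the plug-in MI
$\sum_{ij} \hat p_{ij}\ln(\hat p_{ij}/\hat p_i\hat p_j)$ is evaluated in
nats. The raw plug-in estimator carries a large positive bias at this bin
count (approximately $(B-1)^2/2n$ nats — about 0.48 at $n = 5000$), so by
default the Miller-Madow first-order correction is subtracted and the
result clamped at zero. The corrected estimator is within 15% of the
Gaussian closed form $-\tfrac12\ln(1-\rho^2)$ at $\rho = 0.8$, $n = 5000$;
`bias_correction = FALSE` exposes the raw plug-in, for which two identical
tie-free vectors attain exactly $\ln B$.

Significance at extreme levels (the screen's $\alpha = 10^{-7}$ per pair)
cannot be reached by direct permutation. The threshold is obtained by
peaks-over-threshold extrapolation: an exponential tail is fitted to the
null MI exceedances over the 95th percentile and the $(1-\alpha)$ quantile
is extrapolated from it; moderate $\alpha$ uses the empirical quantile
directly.

Indirect edges are pruned with the data processing inequality: in every
network triangle the weakest edge is marked when its MI falls below
$(1 - \text{tol})$ times the smaller of the other two ($\text{tol} = 0.1$),
and all marked edges are removed simultaneously after scanning all
triangles. Simultaneous (not sequential) removal is the published ARACNe
convention; it makes the operation order-independent and idempotent in a
single pass. "Connectivity" for hub ranking is the node degree, with ties
broken by summed edge MI and then by identifier; the hub count is
$\mathrm{round}(0.10\times n_{\text{nodes}})$ with half rounded away from
zero, so a 12,549-node network yields exactly 1255 hubs.

## The expression generator and its compositional trap

`simulate_expression` plants hubs whose latent activity drives a set of
target genes linearly on the log scale, with per-target noise, and draws
negative-binomial counts. Targets alternate between activation and
repression. That balance is not cosmetic: if a hub's whole regulon moves
up together, the library size co-varies with hub activity, and after CPM
normalization the shared denominator induces correlation between *all*
genes — at larger sample sizes this floods the network with
background-background edges and buries the planted hubs. Balanced regulons
keep the library stable, which is also the realistic regime: transcriptome
wide, compound perturbations redistribute rather than inflate the library.

Defaults (250 genes, 120 samples, 5 hubs x 20 targets, effect 1.5 on the
natural-log scale, target noise SD 0.7, NB size 50, base log-mean 5) are
the regime in which the pipeline achieves 100% planted-hub recall across
ten seeds. Target noise matters for an interesting reason: with *no*
target noise, hub-target and target-target dependencies are equally strong
and the DPI cannot identify the hub as the common cause; moderate noise
creates the Markov structure (target - hub - target) that the DPI exploits.
The full-transcriptome scale of a real analysis (~12,500 genes, hundreds of
millions of pairs) is far beyond a package test suite; the stated sizes are
the package's own scaled-down study design, and the hub-decile arithmetic
is checked separately at the full 12,549-node size.

## DEG calling and the FDR formula

Differential expression between two groups is called on pseudocounted
(0.5) CPM: log2 fold change of group means, with p-values from a normal
approximation whose variance is pooled across genes of similar abundance
(20 equal-count abundance bins). This deliberately does *not* reimplement
negative-binomial dispersion machinery; acceptance is defined by recovery
on synthetic data (planted four-fold changes at $n = 3$ vs 3: recall
$\ge 0.9$, false positives $< 1\%$), not by matching any particular
package's output. With duplicate-free designs a robust spread of the fold
changes within each abundance bin substitutes for the within-group
variance.

The FDR adjustment is the literal rank formula $q_i = p_i\, n / i$ applied
to ascending p-values, capped at 1 — by default *without* the step-up
cumulative-minimum pass, because that is the formula as stated; a
`monotone = TRUE` flag applies the classical correction, under which the
output is identical to Benjamini-Hochberg adjustment. The two differ only
on non-monotone q sequences.

Preranked enrichment uses the weighted Kolmogorov-Smirnov running sum with
weight exponent 1 (the classical default), signed maximal deviation as ES,
and a gene-label permutation null (sample permutation does not exist for
preranked input). NES divides ES by the mean absolute null ES of matching
sign; set-level q-values reuse the FDR formula above.

## Imaging choices

Segmentation follows the standard high-content recipe: Otsu threshold on
the nucleus channel, distance-transform watershed to split touching nuclei,
then nucleus-seeded region growing across the Otsu cytoskeleton foreground
(EBImage's `propagate`), so each cell contains exactly one nucleus and
unreachable foreground is dropped. Defaults that are package choices, not
data-derived: minimum region area 100 px, border cells kept, coordinates
(row, col) from the top-left. Eccentricity is computed from the pixel
covariance eigenvalues — the equivalent-second-moment-ellipse definition
used by high-content tools — with single-pixel regions defined as 0.

The renderer places non-overlapping ellipses whose moment eccentricity
equals the requested value before noise, with centers snapped to integer
pixels: subpixel placement adds quantization anisotropy that inflates
measured eccentricity near 0 (the eccentricity of a near-disc scales like
the square root of the relative eigenvalue perturbation). At the default
cell area (2500 px) the noiseless measurement round-trip is accurate to
0.02 across the full eccentricity range. The renderer does not attempt
photorealism: no point-spread function, no uneven illumination, no
touching/clumped cells. Consequently, passing imaging tests demonstrate
the correctness of the measurement chain, not robustness to the full
difficulty of real microscopy.

## What the synthetic screens do and do not show

The generators reproduce the *structure* of the screen — plate geometry,
row-matched controls, per-well cell counts (Poisson around 1000; the
variance is a module choice, only the mean is anchored), six pooled fields,
saturating dose dependence, positive-control calibration — with all
latent states recorded. Passing tests therefore demonstrate that the
statistics are implemented correctly and are well calibrated under the
stated model: null wells cross the $-4$ cutoff at the analytic $t$-tail
rate; planted actives with $|\Delta_{\max}| \ge 0.3$ and $K_m \le 5\,\mu M$
are recovered with sensitivity $\ge 0.95$. They do not demonstrate
robustness to plate-position (edge) effects, batch effects between plates,
donor-to-donor morphology differences, or segmentation errors on crowded
images — none of which the generators emulate, and the first two of which
the pipeline deliberately does not correct for (no B-scoring, no
multi-plate normalization).

## Problem sizes used by the test suite

Unit and acceptance checks run at deliberately modest sizes chosen as the
package's own study design: 10,000 null wells of 1000 cells for tail
calibration; 200 noisy dose series of 24 points for $K_m$ recovery;
250-gene x 120-sample expression matrices for hub recovery (ten seeds);
five full 384-well plates for the end-to-end screen; 100 random blobs for
the eccentricity oracle. Each is large enough to make its tolerance
statistically meaningful and small enough to keep the whole suite in the
low minutes on one CPU.
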