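---
title: "Methods: peptide-microarray autoantibody screening with pepscreen"
author: "pepscreen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: peptide-microarray autoantibody screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Scope

`pepscreen` implements the analysis side of a serological screen in which
sera from a case group (here: glioma patients) and a control group (healthy
donors) are hybridized to microarrays carrying short overlapping peptides
tiled across a candidate tumor antigen (here: the DNA-repair protein MGMT).
The wet-lab side — peptide synthesis, array printing, serum incubation,
chemiluminescence imaging, spot segmentation — is out of scope; the
pipeline starts from per-spot median intensities, the standard output of
spot-quantification software.

## Antigen tiling

An antigen of length $L$ is decomposed into peptides of length $\ell$
(default 20) whose starts advance by an offset $o$ (default 10), so
consecutive peptides overlap by $\ell - o$ residues. The number of tiles is
$n = \lceil (L-\ell)/o \rceil + 1$ and tile $i$ spans
$[1+(i-1)o,\; \min(1+(i-1)o+\ell-1, L)]$. The final tile is *truncated* at
$L$, never back-shifted onto the grid and never extended: this reproduces
published panels whose terminal peptide is shorter than $\ell$. With
$\ell = 2o$ every interior residue is covered by exactly two peptides; for
$\ell < 2o$ singly covered gaps appear between overlap bands, which is why
`tile_protein()` rejects $o > \ell$ outright and the double-coverage
guarantee is only claimed for the half-overlap design.

`assemble_from_tiles()` inverts the operation from a table of (start,
sequence) pairs, verifying residue agreement in every overlap. It derives
each peptide's end from its sequence length rather than trusting a printed
end column; the shipped MGMT panel table contains two typographical span
irregularities (a 19-mer labelled with a 19-residue span starting off-grid,
and an 18-position span holding 19 residues) that the assembler absorbs
this way, yielding a consistent 206-residue antigen.

## Spot quantification

Each 9×9 subarray carries the peptide probes, four positive-control spots
(printed human IgG), one negative-control spot (printing buffer) and eight
blank positions. The background $b$ of a block is the arithmetic mean of
its blank intensities — a *local* background, because blanks are printed
within each block; a blank count other than eight is reported as a warning.
Spot reactivity is the dimensionless signal-to-noise ratio

$$\mathrm{SNR} = \frac{s - b}{b},$$

which is invariant under global intensity rescaling. Negative values
(spots dimmer than the blanks) are retained unclipped so the downstream
threshold search sees the full distribution. Array-level QC passes an
array when all positive-control SNRs reach `min_pos_snr` (default 2) and
the negative control stays at or below `max_neg_snr` (default 1); the
source protocol states no acceptance rule, so these are package defaults,
both configurable. A serum's profile is the per-peptide arithmetic mean
over its QC-passing replicate arrays (two arrays per serum in the emulated
design; the combination rule is not stated in the source protocol and the
mean was chosen for symmetry). A serum with no passing replicate is
carried as explicitly missing. No inter-array normalization is applied
before thresholding: published cut-offs for this assay are on the raw SNR
scale, and normalization in the source study was used only for heatmap
display.

## Seropositivity cut-offs

The cut-off $c_p$ of peptide $p$ maximizes the difference in positive
response rate between cases and controls,

$$c_p = \arg\max_c\; \frac{\#\{i \in \text{case}: \mathrm{SNR}_{ip} \ge c\}}{n_\text{case}}
      - \frac{\#\{j \in \text{ctrl}: \mathrm{SNR}_{jp} \ge c\}}{n_\text{ctrl}},$$

with sera at exactly the cut-off counted positive (the boundary-inclusive
$\ge$ rule). The objective is piecewise constant between observed values,
so the candidate set is the sorted unique pooled SNR values and the search
is exact; a fixed-step grid mode (default step 0.1) is available for
sensitivity analysis but can never exceed the observed-value optimum. Ties
are broken toward the *smallest* maximizing candidate, which maximizes
sensitivity at equal discrimination. Internally the objective is computed
as an integer cross-product
$a \cdot n_\text{ctrl} - c \cdot n_\text{case}$ on the common denominator
$n_\text{case} n_\text{ctrl}$: floating-point rate differences can split
mathematically tied candidates by one ulp and make the tie-break
irreproducible.

Two properties of this estimator matter for interpretation. First, it is
optimistically biased in-sample: with identical case and control
distributions the maximized difference *is* the one-sided two-sample
Kolmogorov–Smirnov statistic, whose expectation at $n = m = 200$ is
$\sqrt{\pi/8}/10 \approx 0.063$, not zero — the test suite asserts this
equivalence exactly per seed. Second, for peptides with little true
contrast the selected cut-off can land in the bulk of the negative
distribution wherever sampling noise is largest; significance must
therefore come from the Fisher test with multiplicity correction, not from
the achieved difference itself.

## Group comparison

Per peptide, classified calls form a 2×2 table (case/control ×
positive/negative). The two-sided Fisher exact p sums hypergeometric
probabilities of all tables with the observed margins whose probability
does not exceed the observed one (minimum-likelihood convention, matching
`stats::fisher.test`); the implementation evaluates the support with
`dhyper` and is validated against a from-scratch log-factorial enumeration
over every table with $n \le 40$. Bonferroni adjustment multiplies by the
*panel size* $m$ (default 20), not by the number of tests actually run, so
screening a subset cannot silently weaken the correction; raw p-values are
reported alongside, in the style of published screening tables. Rates are
rendered as whole percent using round-half-away-from-zero (the convention
of the commercial statistics packages such tables come from; R's own
`round()` is half-to-even). The "highly responsive" peptides are those
with adjusted $p < 0.05$, ranked by rate difference, top $k = 5$ by
default — the source reports the outcome of this selection but not its
rule, so the rule is a documented package choice.

## Coverage and longitudinal tracking

Coverage of a peptide in a serum set is the seropositive fraction. For
longitudinal designs the preoperative cut-offs stay fixed and coverage is
tabulated per (peptide, group, timepoint); patients measured at several
timepoints additionally yield SNR trajectories with status transitions
(seroreversion, seroconversion, stable). Antigen removal at resection is
expected to lower autoantibody levels by day 30 and recurrence to restore
them, and the synthetic generator encodes exactly that structure.

## Serostatus–IHC association

IHC percentages are dichotomized with strict thresholds: MGMT positive
when more than 10% of nuclei stain, Ki-67 high when more than 20% do
(boundary values fall in the lower class). A subject is "seropositive" for
the association when positive for at least one of the selected peptides —
the pooled rule; a single-peptide mode is available because the pooled
rule saturates when many peptides are prevalent, which flattens the
association. The association is the midrank Spearman coefficient, which
for two binary variables equals the phi coefficient
$(ad-bc)/\sqrt{(a{+}b)(c{+}d)(a{+}c)(b{+}d)}$. The two-sided p uses the
t-approximation $t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ df; an exact
permutation p is available (combination enumeration for binary vectors,
full permutations up to $n = 8$ otherwise). The permutation null for
binary data is strongly discrete — a few attainable $|r|$ values with
large atoms — so exact and approximate p can differ by 0.1 or more at
these sample sizes; the approximation is the default only because it is
the convention of the field's software at $n \approx 21$.

## Recurrence-free survival

RFS runs from surgery to recurrence (event) or last follow-up (censored).
Kaplan–Meier curves, the two-group log-rank test and Cox
proportional-hazards fits go through the `survival` package with Breslow
tie handling by default (the default of the commercial package such
analyses are usually run in; Efron is available). Wald intervals are
$\exp(\hat\beta \pm 1.96\,\mathrm{SE})$. Monotone partial likelihood
(perfect separation) is flagged as non-converged instead of reporting a
runaway coefficient. Forward selection starts from the null model and
repeatedly enters the candidate with the smallest likelihood-ratio p below
0.05 (no removal step), breaking ties by candidate order so the procedure
is deterministic. Independent oracles in the test suite — a hand-written
product-limit estimator and a grid/refine maximizer of the hand-written
Breslow partial likelihood — validate these routes on small instances;
instances whose likelihood is monotone have no finite maximizer and are
excluded by the oracle itself.

## Synthetic data generator

The generator emulates the study design so that every stage is testable
without any real sera: a case-control cohort (presets: 100/300 by default;
67/311 with five elevated peptides at the published preoperative rates for
the "study" shape; 20/60 for fast demos), two replicate arrays per serum,
9×9 blocks with the 4+1+8 control/blank structure. True serostatus is
Bernoulli per serum and peptide; latent SNR comes from a two-component
log-normal mixture (seronegative median 0.5, sdlog 0.6; seropositive
median 6, sdlog 0.4 — SNR is a positive-skewed ratio, and the seropositive
median sits at the scale of the strongest published cut-off). Spot
intensities are $b\,(1+\mathrm{SNR})(1+\varepsilon)$ with block-level
log-normal background (mean 500, CV 0.1) and spot noise CV 0.08. Day-30
samples decay the latent SNR by a factor 0.3; recurrence samples restore
truly seropositive peptides to the preoperative level (factor 1.0) and
leave seronegative peptides unchanged. Event times are exponential with
hazard $h_0 e^{\beta z}$ ($h_0 = 1/365$ per day, default true HR 2 for the
target-peptide serostatus), with independent exponential censoring
calibrated to a 30% censored fraction. Everything derives from one integer
seed (longitudinal and survival stages use offset seed streams so adding
them never perturbs the preoperative draw), and identical seeds give
byte-identical files.

What the generator does **not** emulate: spatial artifacts, batch and
plate effects, isotype structure, heavy-tailed outliers, or any real
antigen-specific biology. Passing tests therefore demonstrate that the
*analysis machinery* is correct and that parameters are recoverable under
the stated statistical model — not that the biological findings of any
particular study replicate.

## Problem sizes and runtime choices

The test suite and the analysis scripts choose sizes that keep each run in
seconds to a couple of minutes while leaving sampling error well below the
asserted margins: end-to-end recovery at 100/300 sera, parameter-recovery
and type-I sweeps at 200 seeded replicates, the brute-force Fisher
validation over all tables with $n \le 40$, Cox oracle equivalence on 250
small instances, and the byte-reproducibility check on the 20/60 demo
preset. The analysis drivers use the 67/311 "study" shape.

## Known limitations

* Cut-offs are selected and evaluated on the same sample; no
  cross-validation or held-out calibration is provided (deliberately, to
  mirror the published procedure).
* Only Bonferroni multiplicity control is offered.
* The association module handles binary-binary data exactly; ordinal IHC
  scores (H-scores) are out of scope.
* Survival modelling assumes proportional hazards and right censoring;
  no time-dependent covariates or competing risks.
* Published per-patient survival tables cannot be reproduced numerically
  without the underlying cohort data; the survival module's correctness
  claims rest on oracle equivalence and parameter recovery instead.
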