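---
title: "Combinatorial biodiversity–ecosystem functioning analysis with befmix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combinatorial biodiversity–ecosystem functioning analysis with befmix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(befmix)
library(dplyr)
```

## The problem

Bioaugmentation — seeding an engineered treatment system with selected
bacteria — usually deploys single strains. The biodiversity–ecosystem
functioning (BEF) literature suggests mixed consortia should do better, via
two distinct mechanisms: a *selection effect* (diverse mixtures are more
likely to contain a high-performing species) and a *complementarity effect*
(species partition resources or facilitate each other). `befmix` implements
the analysis chain of a combinatorial biodiversity experiment that separates
these signals for defined consortia of up to k bacterial isolates degrading
organic matter in synthetic wastewater, with soluble chemical oxygen demand
removal efficiency (sCOD-RE, mg removed per mg introduced) and OD600 biomass
gross yield as the function responses.

## The experimental design

Assembling every subset of k species is \(2^k\) communities; a two-level
half fraction keeps the design practical while preserving inference. Species
presence is a factor at levels +1/−1 and the retained runs satisfy the
defining relation \(I = -X_1 X_2 \cdots X_k\) (the negative generator sign):

```{r design}
d <- half_fraction_design(6)
table(d$richness)
nrow(alias_structure(d))
```

For k = 6 the 32 retained runs are exactly the communities of odd richness —
6 monocultures, 20 tricultures, 6 pentacultures — and the alias report is
empty up to two-factor interactions (resolution VI), so species main effects
are cleanly estimable. `augment_design()` adds the hexaculture and abiotic
controls; with five control conditions in triplicate the layout reaches
`3 × (32 + 1 + 5) = 114` ecosystems. The decomposition of the augmented
layout into 32 + 1 + 5 conditions is a package choice (only the total is
conventionally reported); `n_controls` exposes it. Runs are ordered
lexicographically over level patterns purely for determinism.

## Diversity metrics

Two phylogenetic metrics are computed on a rooted tree (read from newick, or
built by `upgma_tree()` from a 16S distance matrix — sequence alignment is
out of scope):

* **FPD** (Faith): the branch-length sum of the subtree connecting a
  community's species. We default to the *include-root* convention
  (`include_root = TRUE`), the common rooted-tree behaviour in community
  phylogenetics software, so a monoculture scores its root-to-tip distance;
  the flag exposes the exclude-root alternative since conventions differ
  between implementations.
* **MPD**: the mean pairwise distance over the community's species. A
  monoculture has no pairs; we return `NA` rather than 0, and such rows are
  dropped (and counted) before any MPD regression.

The trait-side metrics start from carbon-source utilisation plates (31
substrates read at 590 nm). Blank-corrected absorbances are clipped at zero
(no negative activity), divided by the substrate's electron equivalents so
substrates of different reductance are comparable, and normalised by the
plate average — which makes each species' profile mean exactly 1 and renders
the profile invariant to any common rescaling of the eeq table. Electron
equivalents are chemistry the user must supply (`eeq` input); the package
never invents them silently — the synthetic pool generator draws plausible
values in the 4–40 range typical of plate substrates.

* **FDis**: mean pairwise Euclidean distance between member profiles. We use
  the mean — the richness-independent dissimilarity — as the default because
  FDis serves precisely as the SR-decorrelated functional axis; the pairwise
  sum is available via `agg = "sum"` for comparability with
  sum-over-pairs reports.
* **dFD**: branch-length sum on the functional dendrogram, built **once over
  the full pool** (never per community, which would break monotonicity in
  the member set). Average linkage is the default — consistent with the
  UPGMA phylogeny — with complete linkage available, since hierarchical
  clustering defaults vary between tools and the linkage is recorded in the
  report. For dFD we default to *exclude-root*, so a monoculture scores 0
  and dFD vanishes exactly when all member profiles coincide.

Internally dFD is `faith_pd()` applied to the dendrogram — one spanning-
subtree routine serves both trees, which the tests exploit as a consistency
check.

## Overyielding and inference

For each polyculture replicate and response,

\[
\bar{LR}_m = \ln\frac{y_{poly}}{\overline{y}_{mono}}, \qquad
\hat{LR}_m = \ln\frac{y_{poly}}{\max y_{mono}},
\]

where the monoculture references are the **replicate means** of the member
species' monocultures. Ratioing each polyculture replicate (rather than the
polyculture mean) preserves replicate-level variance for the one-sample
tests; means-vs-means is available via `mono_stat`. \(\bar{LR}_m > 0\) is
non-transgressive overyielding (better than the average member);
\(\hat{LR}_m > 0\) is transgressive overyielding (better than the *best*
member), and \(\hat{LR}_m \le \bar{LR}_m\) always. Nonpositive responses
make a log ratio undefined; such rows are excluded with an explicit count,
never silently.

Group comparisons follow the conventional routing: residual normality gates
ordinary one-way ANOVA (Tukey HSD post hoc) versus Kruskal–Wallis (pairwise
Wilcoxon, Holm-adjusted), with Welch's ANOVA (pairwise Welch t, Holm)
available by request. We gate on Shapiro–Wilk applied to group-centred
residuals: it is the standard omnibus normality test available in base R,
and the choice is configurable by passing `family` explicitly. Significance
is reported at α = 0.05 throughout (configurable).

The species main-effects screen fits the response on all k presence columns
plus intercept and reports each species' estimate, SE and **t-ratio**
(estimate/SE) against the two-sided 95% t threshold — the standard screen
for selection-effect species in factorial BEF designs. On the orthogonal
fraction, noiseless additive responses are recovered to machine precision
(a test asserts this). Only factorial runs enter the screen by default
(n = 96 for the triplicated 6-species fraction); augmented rows are excluded
because they are off-fraction.

Diversity–function regressions are ordinary least squares, fitted over all
communities and again within intermediate richness subsets (default
SR ∈ {3, 5}) where the phylogenetic/functional axes vary while richness is
held narrow; subset fits are exact refits of the filtered rows. A constant
response is reported as \(R^2 = 0\), F = 0 rather than NaN.

## The synthetic generator

Per-ecosystem measurements of such experiments are rarely redistributable,
so the generator is first-class, tested code rather than a fixture.

**Calibrated mode** draws each biotic ecosystem's responses from per-
richness-level normal distributions; its default calibration table is, for
sCOD-RE, mean ± SD of 0.266 ± 0.146, 0.542 ± 0.155, 0.742 ± 0.136,
0.822 ± 0.019 at SR = 1, 3, 5, 6, and for OD600 0.065 ± 0.052,
0.132 ± 0.046, 0.173 ± 0.049, 0.216 ± 0.019, with initial sCOD
540 ± 21 mg O₂ L⁻¹ — the study conditions of a six-isolate psychrophilic
consortium experiment, treating the printed SDs as total variance (the
within/between-replicate decomposition is not public). Draws are clipped to
valid ranges ([0,1] for RE, ≥0 for OD) rather than resampled: simpler, and
the truncation bias is negligible at these SDs except for monoculture OD600
(mean/SD = 1.25), where the group mean is inflated by roughly 5% — tolerable
for a generator whose monoculture OD is never an acceptance quantity.
Abiotic controls receive near-zero removal (σ = 0.005) and OD.

**Mechanistic mode** makes the two BEF mechanisms explicit knobs:

\[
\mathrm{logit}(RE_c) = \beta_0 + \overline{a}_{i \in c} + \gamma \ln SR_c +
\varepsilon, \quad \varepsilon \sim N(0, \sigma^2).
\]

With \(\gamma = 0, \sigma = 0\) the model collapses: a polyculture's
logit-RE is the mean of its members', so \(\hat{LR}_m < 0\) whenever
identity effects differ — no transgressive overyielding without
complementarity. Raising \(\gamma\) lifts mixtures above their best member.
The logit link keeps RE in (0,1) mechanistically; an identity link is
available for linear-theory checks. OD600 is generated as a fixed fraction
(0.26) of RE, the ratio implied by the calibrated hexaculture means.

Random streams are keyed per (ecosystem, replicate) from the master seed, so
adding rows to a design never perturbs existing draws; equal seeds give
byte-identical outputs. OD600 time series follow a saturating curve scaled
so the 144 h reading equals the drawn response value — the response
extraction defaults to 144 h OD and endpoint (192 h) sCOD, both
configurable. The OD-derived responses carry a metadata flag marking them as
morphology-biased: optical density conflates cell volume with cell count,
and cell volumes shrink during growth, so OD-based yield conclusions need
that caveat.

What passing tests on synthetic data do *not* show: the generator draws
independent normals per ecosystem, with no plate effects, no within-plate
correlation, no time-resolved sCOD decay, no species-abundance dynamics —
real data could violate any of these. What they do show is that the
statistical machinery recovers known structure: calibrated group means
converge at the \(1/\sqrt{n}\) rate; a species whose identity effect is 3
noise SDs tops the |t-ratio| screen in ≥95% of runs (the literal, testable
core of identifying a best-performing species); and the transgressive
overyielding test fires reliably once \(\gamma\) is large.

## Numerical choices and problem sizes

* UPGMA (and the functional dendrogram) delegate to average-linkage
  `hclust()`; labels are sorted first so tied merge heights resolve to the
  lexicographically smallest set, and the hand-worked examples in the test
  suite pin the height conventions (cophenetic distance = input distance
  scale).
* Tolerances: profile row means and ultrametricity are asserted at 1e−9;
  exact-recovery identities (orthogonal screens, F = t²) at machine
  precision via the default `testthat` tolerance.
* Monte-Carlo sizes were chosen to make the checks sharp but quick: 500
  seeds for screen top-ranking, 25 seeds × 20 tricultures per
  complementarity level for the \(\gamma\) monotonicity check, 100 seeds for
  detection rates, 200 replicates for calibrated group means.
* Degenerate inputs fail loudly: all-zero plate profiles, rank-deficient
  screens (collinear columns are named), zero-variance regression metrics,
  nonpositive initial sCOD.

## Limitations

The pipeline treats the tree and the trait table as inputs; building them
(alignment, substitution models, assay kinetics) is upstream. Additive
partitioning of complementarity vs selection requires per-species
densities in mixture, which endpoint OD/sCOD designs cannot deliver; the
mechanistic generator's \(\gamma\)/\(a_i\) knobs serve as the
simulator-side diagnostic instead. MPD and FDis are undefined for
monocultures by construction, so monoculture rows never inform those two
regression axes.
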