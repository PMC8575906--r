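---
title: "Quantifying de novo oocyte recruitment: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying de novo oocyte recruitment: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(ovodyn)
library(dplyr)
```

## The scientific problem

Whether a teleost's annual fecundity is fixed before spawning (determinate) or
topped up by *de novo* oocyte recruitment during spawning (indeterminate)
decides which egg production method is appropriate for estimating spawning
stock biomass. The classical diagnostic — presence or absence of a hiatus in
the oocyte size frequency distribution (OSFD) — is unreliable. `ovodyn`
implements a quantitative alternative built from two ingredients:

1. **Stereological oocyte packing density (OPD)**: phase-specific numbers of
   oocytes per gram of ovary, estimated from Weibel-grid point counts on
   histological sections via the Delesse principle, combined with
   volume-based mean diameters, prolate-spheroid shape factors, shrinkage
   correction and ovary specific gravity.
2. **Ultrametric spawning-stage classification (ORC)**: each female's "stage
   of spawning" from the ratio of previtellogenic (PVO) to developing
   (CA + VO + FOM) oocytes in wholemount images, classified into five rule
   categories (ORC0 prespawning through ORC4 spent).

Standardising phase-specific relative fecundity (RF, oocytes per gram of body
weight) by ORC turns a cross-sectional sample into a reconstruction of the
season's oocyte flow. The depletion of the final previtellogenic phase
(PVO4c) between ORC0 and ORC4 is the direct measurement of de novo
recruitment: positive depletion means the maturing pool was replenished
during spawning, the signature of indeterminate fecundity.

## The packing-density model

Oocytes are modelled as prolate spheroids with axes $(L, S, S)$. Writing the
profile diameter $OD = (L+S)/2$ and the shape factor $k = L/S \ge 1$, a
single oocyte occupies $(\pi/6)\,\frac{8k}{(1+k)^3}\,OD^3$ cubic micrometres.
Inverting this against the Delesse volume fraction $V_V$ and the ovary
specific gravity $\rho_o$ gives, in base-10 logs,

$$\log_{10} OPD = \log_{10}\!\left[V_V \cdot \frac{1}{\rho_o} \cdot
  \frac{(1+k)^3}{8k}\right] + C - 3\log_{10}(cOD_v),$$

where $cOD_v$ is the shrinkage-corrected, volume-based (cubic-mean) diameter
and $C = \log_{10}\!\big((6/\pi)\cdot 10^{12}\big) = 12.281\ldots$ converts
$\mu m^3$ to $cm^3$. Published applications print $C$ rounded to 12.28;
`opd()` exposes both (`constant_mode = "printed"` reproduces published
densities exactly, `"exact"` is used by the oracle tests; the two differ by a
fixed 0.23% factor). The log base is forced to 10 by the value of the
constant. For a sphere ($k=1$) the shape term is exactly 1 and the equation
reduces to packing spheres into the occupied volume per gram.

Key numerical conventions:

* the **cubic-mean** diameter $\left[\sum OD^3/n\right]^{1/3}$ weights each
  measured oocyte by its volume; it is never below the arithmetic mean
  (power-mean inequality), with equality only for identical oocytes;
* $k$ is computed per measured oocyte, then averaged within phase (rather
  than from averaged axes);
* phases with zero grid hits get $OPD = 0$ (with a $-\infty$ log sentinel),
  so spent ovaries process cleanly instead of erroring;
* PVO1 is excluded from OPD (too few grid hits to quantify) and so is HYD
  (irregular shape after histological dehydration);
* the shrinkage factor default is **1.11** (about 10% linear shrinkage,
  typical for resin histology). This is a documented stand-in: the correct
  value is protocol-specific and should be overridden when a laboratory
  calibration exists. Specific gravity defaults are 1.020 g cm$^{-3}$ for
  maturing females (stages 3–5) and 1.047 g cm$^{-3}$ for spawning/spent/
  resting females (stages 6–8), from whole-ovary submersion calibrations.

## The spawning-stage rules

The oocyte ratio is $OR = \#\{d \le 230\,\mu m\} / \#\{d > 230\,\mu m\}$ on
cleaned wholemount diameters (window 100–1100 µm; below 100 µm the smallest
oocytes wash out unreliably, above ~1150 µm the follicle layer detaches).
Class bounds are closed on the upper end: ORC1 $OR \le 1$, ORC2
$1 < OR \le 3$, ORC3 $3 < OR \le 15$, ORC4 $OR > 15$ (including $+\infty$
when no developing oocytes remain). ORC0 has no OR range: prespawning status
is metadata (e.g. females sampled in winter, in primary vitellogenesis) and
the `prespawning_flag` is authoritative. Cortical alveoli oocytes count on
the developing side; in wholemount data the split is by diameter, not
cytology.

The rule system is validated the way it was validated in the field: on
synthetic populations the median GSI$_{TL}$ ($10^4 \times OW/TL^{3.13}$)
declines strictly from ORC1 to ORC4 (`test-pipeline.R`).

## The diameter-threshold mixture

The PVO/developing diameter boundary can also be estimated statistically: a
two-component mixture $w\,\Gamma(d) + (1-w)\,\mathcal N(d)$ is fitted to a
female's diameters by EM (gamma = right-skewed PVO mode, normal = developing
mode), and the threshold is the smallest posterior-0.5 crossing between the
two component modes. Fitting is per female, then averaged across females
with a t-interval, since the cohort-level uncertainty is dominated by
between-female variation.

Numerical choices: deterministic multi-start initialisation (the empirical
density minimum between 150 and 400 µm plus fixed candidate split points;
method-of-moments on each side; the run with the best final log-likelihood
wins), tolerance $10^{-6}$ on the log-likelihood, at most 500 iterations,
non-convergence reported rather than raised, degenerate weights
($w \to 0/1$) treated as unimodal data and raised. The gamma M-step solves
the weighted likelihood equations by Newton iteration on the shape. The
log-likelihood trace is stored and asserted non-decreasing.

One modelling caveat discovered during validation and worth stating plainly:
on realistic multi-phase samples the upper component is misspecified — the
developing band (CA through GVBD, roughly 250–1000 µm) is multimodal, and a
single Gaussian cannot represent it. Fitted on the full diameter range, the
best-likelihood solution degenerates (the gamma absorbs everything up to
~600 µm). `run_pipeline()` therefore fits the mixture on diameters up to
`mixture_max_d = 500` µm, the range actually relevant to the PVO/early-
developing boundary. Even so, the two-component crossing tracks the deepest
density dip — between the abundant small PVOs and everything later — which
sits *below* the histologically defined PVO4c landmark. This mirrors the
field behaviour of the method (mixture estimates near 190 µm versus a
230 µm histological boundary) and is why the histological landmark, not the
mixture output, is the recommended enumeration threshold. The mixture
estimator itself is verified on data that satisfy its assumptions: 50
seeded gamma+normal cohorts recover the true density crossing to within
±15 µm in 100% of replicates (`test-acceptance.R`).

## The recruitment calculus

Per female and phase, $NO = OPD \times OW$, $RF = NO/W$,
$RF_{TL} = 100 \times NO / TL^{3.13}$ (the exponent defaults to the pooled
length–weight slope). Cell summaries by phase × ORC × year use
normal-approximation 95% CIs (mean ± 1.96 SE); single-female cells are
flagged, not bootstrapped. Then:

* **influx** = mean RF$_{PVO4c}$(ORC0) − mean RF$_{PVO4c}$(ORC4), SEs
  combined in quadrature. Negative estimates are reported with a warning,
  never clamped, so a determinate spawner remains detectable;
* **total potential RF** = ORC0 aggregate (PVO4c–GVBD) + influx; dividing by
  a batch fecundity gives the number of batches (unrounded ratio reported
  alongside the nearest integer). The ORC0 aggregate is the mean over
  females of per-female phase sums; the sum of per-phase means is reported
  alongside, as the two differ in unbalanced data;
* **threshold sensitivity**: per female, RF summed over PVO4a–GVBD (the
  historical 185 µm window) versus PVO4c–GVBD (the revised 230 µm window);
  percent reduction $100(1 - \Sigma_c/\Sigma_a)$ averaged within year.
  Per-female sums come first, then the year mean, matching the paired
  design; females with nothing left in the narrow window drop out of the
  pairing and are counted;
* **atresia is not subtracted** from the influx: no correction formula is
  established, and previtellogenic atresia occurs essentially outside the
  spawning season. The structure-prevalence summary surfaces the fractions
  needed to judge whether this matters for a given data set.

## What the synthetic generator emulates

The generator (`sim_config()`, `simulate_dataset()`) is first-class, tested
code: it produces populations with *known* ground truth so every estimator
has an oracle. Each female carries a latent spawning-progress stage 0–4.
Defaults (all overridable) define the study conditions:

* 150 females allocated (0.30, 0.14, 0.13, 0.13, 0.30) over stages 0–4 —
  prespawning and spent females oversampled, since those two stages pin down
  the influx;
* true RF trajectories per phase: early PVOs flat and large (PVO2 2500,
  PVO3 2000 oocytes g$^{-1}$), late PVOs a few hundred, PVO4c declining
  linearly from 200 to 40 (programmed influx 160 oocytes g$^{-1}$; a
  `pvo4c_influx = 0` null is one argument away), a dome-shaped developing
  pool peaking at stage 1 with a prespawning PVO4c–GVBD aggregate of ~528;
* phase diameter means 70–950 µm on the formalin scale, anchored at the
  185 µm (PVO4a) and 230 µm (PVO4c upper edge) landmarks. PVO4c is drawn
  from N(218, 10): the phase is defined as the last one at or below the
  230 µm split, so its distribution sits just under the boundary (a
  centred-at-230 choice would label half of every undepleted PVO4c pool as
  developing and make a determinate-null spent female unclassifiable);
* GSI$_{TL}$ by stage (1.5, 6, 5, 3, 0.9): prespawning females in primary
  vitellogenesis and spent females genuinely carry small ovaries; the
  decline from ORC1 on is what the validation property checks. Ovary weight
  has a physical floor — it must at least hold the female's oocytes at no
  more than 80% volume occupancy — so implied volume fractions can never
  exceed 1;
* wholemount observation: 600 measured oocytes per female, multinomial over
  phases weighted by true RF × detection probability. Detection is far below
  1 for PVOs (0.05–0.5, rising with size; 0.95 for developing phases),
  emulating small oocytes hiding under large ones; the probabilities were
  calibrated analytically so each latent stage's expected observed OR falls
  inside that stage's rule band (0.66, 2.3, 8.9, 25 for stages 1–4);
* histology observation: 500-point multinomial grid counts over expected
  volume fractions computed by inverting the OPD equation with the exact
  normal third moment $E[D^3] = m^3 + 3m\sigma^2$ (so the generator is
  consistent with the pipeline's cubic-mean estimator), stage-dependent
  POF/atresia fractions, an OTHERS bucket absorbing the remainder; three
  axis profiles per phase at histology scale (formalin / 1.11) with random
  prolate shape factors ($k = 1 + |N(0.12, 0.05)|$);
* biological scatter: lognormal, median-centred, truncated at ±2σ (GSI) and
  ±3σ (per-phase RF) — bounded within-stage variation, and unbounded tails
  would occasionally imply physically impossible ovaries.

Identical configuration and seed give byte-identical tables.

What the generator does **not** emulate: spatial section geometry (grid
counts are multinomial, i.e. section heterogeneity beyond counting noise is
absent), oocytes shared across section boundaries, measurement error in
axis reading, a second sampling year, real seasonal covariates (stage
stands in for calendar time), and atresia dynamics beyond simple
stage-dependent presence. Passing closed-loop tests therefore demonstrates
estimator correctness under the stated observation models, not robustness
to every field artefact.

## Problem sizes and verification

The test suite verifies, among others: the sphere-packing oracle for the
OPD equation (direct counting vs the equation, exact mode, within 0.5% for
$k \in \{1, 1.3, 2\}$); Delesse unbiasedness over 250–300 random 500-point
grids with variance scaling ~1/n; mixture recovery on 50 seeded cohorts of
n = 2000; end-to-end influx recovery on a 150-female population (within 10%
of the programmed 160, and a null whose CI covers 0); and the boundary
behaviour of every rule. These sizes were chosen so the whole suite runs in
well under a minute per file while keeping Monte-Carlo tolerances
meaningful.

## Interface notes

All user-facing functions take data frames first and return tibbles, so
stages chain with the pipe; fitted objects (`length_weight_fit`,
`gg_mixture`) have `tidy()`/`glance()` methods and the mixture an
`autoplot()`. The package is driven from R — `run_pipeline()` plus the
`read_*`/`write_*` functions are the orchestration layer; there is no shell
entry point, as the intended users work in R.

```{r example}
ds <- simulate_dataset(sim_config(n_females = 60, seed = 7))
res <- run_pipeline(ds$females, ds$wholemount, ds$histology_hits,
                    ds$histology_axes, fit_mixture = FALSE)
res$influx
```

## Known limitations

* The mixture threshold on real multi-phase data estimates a density dip,
  not the histological recruitment boundary (see above); use it as
  corroborating evidence, not as the enumeration threshold.
* The shrinkage default (1.11) is generic; results scale with its cube, so
  a protocol-specific calibration matters (~3% density error per 1% of
  shrinkage-factor error).
* Single-year cells with one female get no CI; the influx needs populated
  ORC0 and ORC4 cells and errors otherwise.
* The ORC0 class is metadata-driven; mislabelled prespawning flags
  propagate directly into the influx.
* Inferential hypothesis testing between groups (ANOVA-style comparisons)
  is out of scope by design; the package reports estimates and intervals.
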