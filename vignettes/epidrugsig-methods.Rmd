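---
title: "Methods: immunomodulation signatures of epigenetic drugs"
author: "epidrugsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: immunomodulation signatures of epigenetic drugs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epidrugsig)
```

# The analysis problem

Epigenetic drugs de-repress or silence large immune-related gene
programs in tumor cells. Characterising that activity comparatively —
across drug classes, across cell lines, and onward into clinical
biopsies and survival data — requires a chain of analyses, each simple
on its own but easy to get subtly wrong in combination:

* threshold-based **modulation calls** on paired treated/control panel
  counts,
* two **class-level metrics** summarising how much and in which
  direction each functional gene class moves,
* **drug-specific signatures** from cross-cell-line call frequency,
* **upstream-regulator (UR) activation** inferred from a signed causal
  network,
* **pre-ranked GSEA** of a signature along a biopsy timecourse,
* a per-gene **proportional-hazards screen**.

`epidrugsig` implements this chain together with a synthetic-data
generator that plants known effects at every stage, so the pipeline's
behaviour is verified by recovery of the planted truth rather than by
eyeballing.

# Modulation calls and class metrics

Counts are normalized per sample so that the geometric mean of the
housekeeping genes equals the cohort-wide geometric mean of those
genes (`normalize_counts()`). A sample in which any housekeeping gene
reads zero cannot be scaled and is excluded with a warning rather than
silently imputed.

For each gene, cell line and drug, the treated/control ratio $r$ is
called **up** when $r > \tau$ and **down** when $r < 1/\tau$, with
$\tau = 1.5$ by default. The rule is deliberately symmetric on the log
scale, so relabelling treated and control maps every up-call to a
down-call exactly. Two numerical conventions matter:

* **Zeros.** When either member of a pair is zero, a pseudocount of 1
  is added to both members and the gene is flagged
  (`zero_adjusted`). Panel counts are never negative, so this is the
  only degenerate ratio case.
* **Low-expression floor.** Genes whose *smaller* pair member falls
  below 20 normalized counts (configurable, `min_control`) are set to
  `none` rather than dropped. Applying the floor to the pair minimum —
  rather than to the control alone — preserves the treated/control
  symmetry above and keeps the null up/down call rates equal; a
  control-only floor biases calls downward for genes near the floor,
  because conditioning on a detectable control pushes the ratio down.

Class metrics condense the calls: per (class, drug, cell line),
`frac_modulated` $= (n_{up}+n_{down})/n_{genes}$ and the direction
index $d = (n_{up}-n_{down})/(n_{up}+n_{down})$, defined as 0 when no
gene moves. $d = +1$ means every modulated gene went up.

The MTT working-dose rule (`select_working_dose()`) picks the highest
tested dose whose viability strictly exceeds 60 % of control, so that
expression changes reflect drug pharmacology rather than toxicity.

# Drug signatures

A gene enters a drug's signature when the fraction of evaluable cell
lines sharing its majority call direction reaches `min_support`
(default 0.5), with ties excluded. The 0.5 default mirrors the
"more than half of cell lines" rule used for aggregating regulator
calls; signature sizes are sensitive to it, and it is exposed as an
argument rather than fixed. Raising `min_support` can only shrink a
signature (tested as a monotonicity property), and derivation is
invariant to input row order.

`venn_partition()` counts genes per membership pattern for 2–6 drug
sets (regions ordered singles-first, then pairs, and so on);
`signature_overlap()` reports the count and percent (one decimal) of
evaluable signature genes found in an external up-regulated gene
list. The evaluable denominator is supplied by the caller because
measurability in an external study cannot be inferred from the
signature itself.

# Upstream-regulator scoring

Given a signed regulator→target edge list, a signed DE gene list, and
the measured gene universe, each regulator is scored by:

* an **overlap p-value**: the upper-tail hypergeometric probability of
  observing at least the seen number of DE targets among its measured
  targets (via `stats::phyper`; the exact tail, not an approximation);
* an **activation z-score**
  $z = \sum_e w_e c_e \big/ \sqrt{\sum_e w_e^2}$ over the overlapping
  edges, where $c_e = +1$ when edge sign × DE direction is consistent
  with regulator *activation* and $-1$ otherwise. With unit weights
  (the default — the network model here carries no edge confidences)
  this is $(N_{cons}-N_{incons})/\sqrt{N}$, bounded by $\pm\sqrt{N}$.

A state call (*activated* / *inhibited*) requires **both** $|z| > 2$
and overlap $p < 0.05$: a regulator whose targets are everywhere (the
overlap is unsurprising) is not called however consistent its signs.
Raw p-values gate the call by default; `adjust = TRUE` switches to
Benjamini–Hochberg. Regulators are scored only against the measured
universe, which prevents bias from unmeasured targets, and regulators
with no measured targets are omitted with a message rather than
scored at zero.

Aggregation across cell lines (`aggregate_ur_signature()`) admits a
regulator with direction *activated* when it is called activated in at
least `min_lines` lines (default 6, i.e. more than half of a 10-line
panel), symmetrically for inhibited; a regulator qualifying in both
directions is excluded and logged. `compare_drugs()` assigns each
shared regulator to a scatter quadrant (both activated, both
inhibited, opposite, or non-significant).

## Responder discrimination

`responder_discrimination()` runs, at each biopsy timepoint, a
responder vs non-responder log2-fold-change ranking, thresholds it
into a signed DE list at $|log_2 FC| > \log_2 1.5$ (the same threshold
as the modulation rule), scores the network against it, and restricts
the result to a UR signature. Entries with $z > 2$ are flagged
significant — the reporting convention for this analysis, where the
question is progressive *activation* on treatment.
`timepoint_z_correlation()` is a plain Pearson correlation of paired z
vectors (≥ 3 shared regulators; zero-variance input is reported as
undefined rather than as a number).

# Pre-ranked GSEA

`rank_genes()` offers two ranking statistics — log2 fold change of
group means with pseudocount (default) and a signed Welch t on log2
counts — because the appropriate choice depends on replication depth;
both are deterministic, with ties broken by gene identifier
(enrichment scores are tie-sensitive, so the order must be fixed).

`running_es()` is the classic weighted Kolmogorov–Smirnov running sum:
set members increment by $|s|^p$ normalized by total hit mass
(default $p = 1$), non-members decrement by $1/(N-N_{hit})$; the ES is
the signed extremum. Numerical conventions:

* **Extremum ties.** The positive and negative excursions can tie in
  magnitude exactly (the increments are rationals). The contract is:
  the earliest position within $10^{-9}$ of the maximal $|$running
  sum$|$ wins. The brute-force oracle in the test suite applies the
  same rule, so implementation and oracle agree bit-for-bit elsewhere.
* **Degenerate sets.** A set spanning the whole universe leaves no
  misses to decrement; the ES is defined as 0 with a warning rather
  than an error. An all-zero ranking (identical groups) has zero hit
  mass; hits then increment equally, as in the unweighted statistic.

`gsea_pvalue()` uses a **gene-permutation null** (random same-size
gene sets), matching the pre-ranked setting where the ranking comes
from a DE analysis and sample permutation is unavailable. The p-value
is one-sided in the direction of the observed ES with the add-one
convention, $p = (1 + \#\{ES_{null} \ge ES\})/(1 + n_{perm})$ for
positive ES (mirrored for negative), so the minimum attainable p at
$n_{perm}$ permutations is $1/(n_{perm}+1)$. Because the side is
chosen by the observed sign, the null distribution of this p is close
to uniform on $(0, 0.5)$ — roughly twice the nominal mass falls below
any small $\alpha$ — which the calibration tests assert explicitly.
NES divides the ES by the mean $|ES_{null}|$ of the same sign.

# Survival screen

`cox_screen()` fits one univariate proportional-hazards model per gene
on internally standardized expression (Efron tie handling, the
`survival` default and the right choice for registry data with tied
times). Degenerate covariates and non-convergent fits are reported as
non-estimable rows, never dropped. No covariate adjustment is
attempted — external screens of this kind sometimes adjust for immune
infiltration estimates, but reconstructing unknown adjustments would
fake precision; the univariate model is the documented unit, and
`signature_prognostic_fraction()` reports the share of signature genes
that are significant (raw $p < 0.05$, matching how such fractions are
conventionally reported; BH-adjusted p-values are also emitted per
gene) and the share that additionally confer reduced risk ($z < 0$).

# The synthetic-data generator

The generator emulates the study design end to end; its defaults *are*
the study conditions, chosen once and documented here.

**Panel.** 731 genes assigned round-robin to 21 functional classes
(sizes differ by ≤ 1), plus 20 housekeeping genes. Housekeeping
baselines are drawn log-normal(log 500, sd 0.25) — reference genes are
selected for abundant, stable expression, and normalization relies on
their detection in every sample — while panel genes draw from
log-normal(log 200, sd 1).

**Cell-line counts.** One control and one treated sample per
(cell line, drug): panel-style experiments are typically run without
replicates, which is exactly why the downstream rules lean on
cross-cell-line consistency. Counts are negative binomial with
dispersion 0.01 (paired counts of the same line under identical
culture are technically tight; this puts the null false-call rate of
the 1.5-fold rule at a realistic few percent) and a log-normal
per-sample size factor (sigma 0.2) that normalization must undo. Each
drug's planted effect occupies 2 functional classes, touches 80 % of
their genes in 80 % of cell lines, with log2 fold changes of mean 1.2
(sd 0.25) and a drug-specific predominant direction (down for
BET-inhibitor-style drugs, up otherwise).

**Network.** 60 regulators; 8 planted per drug draw 15–30 targets
from that drug's planted genes with edge signs agreeing with the
planted direction at consistency 0.9 (recovery is then reliable but
not forced); decoys draw uniform targets with random signs.

**Cohort.** 24 patients × (w0, w4, w12), responder fraction 0.4, NB
dispersion 0.15 (between-patient biological variability). Responder
induction applies a monotone log2-fold-change profile to a 50-gene
subset of the trial drug's up-planted genes, in responders only. Two
named scenarios are used:

* *default* `induction_log2fc = c(0, 1.0, 1.8)`: the between-arm
  contrast is detectable already at w4, the regime in which
  responder discrimination is exercised;
* *weak-early* `c(0, 0.02, 1.2)`: the w4 induction sits inside
  noise, producing the timecourse enrichment pattern "significant at
  w12 vs w0 and w12 vs w4, not yet at w4 vs w0". The w4 value is a
  calibrated effect size for that qualitative pattern, fixed here
  once.

**Survival.** 500 subjects; 10 protective genes (drawn from the trial
drug's up-planted genes) with per-SD log hazard −0.8 acting jointly on
an exponential baseline (hazard 0.1); independent exponential
censoring tuned to a 30 % censoring fraction; 10 null genes ride along
for calibration.

**Seeding.** A single master seed fans out as `seed * 101 + stage`
(stages 1–6: baselines, planted effects, panel counts, network,
cohort, survival), so any stage can be re-run independently and
identical configurations are byte-identical.

## What the generator does *not* emulate

No probe-level artifacts, batch structure, GC content, cross-class
correlation, or network feedback; genes are conditionally independent
given their planted means, and survival covariates are Gaussian rather
than expression-derived. Passing the recovery suites therefore shows
that the *statistical machinery* is correct and calibrated under the
declared noise model — it does not certify performance on real data,
where class structure, normalization artifacts and confounding are
richer.

# Problem sizes in the test and acceptance suites

The recovery suites run the full study geometry (731 × 10 × drugs) over
10–20 seeds per stage, oracle-equivalence sweeps cover all gene-set
subsets of ranked lists up to length 9 (sampled at lengths 10–12) and
300 random small networks, and GSEA calibration uses 200–1000
permutations. Unit tests use a reduced 60-gene/6-class configuration
where study scale adds nothing to the property under test.

One calibration caveat is asserted rather than hidden: calls within a
treated/control pair share estimated normalization factors, so the
spread of `n_up − n_down` on null data slightly exceeds the
independent-binomial bound; the null-calibration tests account for
this.

# Known limitations

* The causal network here is synthetic; applying the UR machinery to
  real data requires an external curated signed network, and results
  inherit its biases.
* The activation z assumes unit edge weights and no correction for
  network bias toward well-studied regulators.
* The GSEA p-value is sign-directed (see above); users comparing many
  gene sets should apply their own multiplicity control — none is
  built in because the intended use tests one signature.
* Percentages from external-cohort overlap and prognostic fractions
  depend on denominators (evaluable genes, estimable fits) that the
  caller controls; the functions log exclusions but cannot validate
  external measurability claims.
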