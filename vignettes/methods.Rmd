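---
title: "Inferring signed miRNA regulatory influence from paired tumor/normal cohorts"
author: "mirInfluence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring signed miRNA regulatory influence from paired tumor/normal cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirInfluence)
```

## The model and its assumptions

A gene's expression is treated as a function of the miRNAs that target
it. Linearizing that function around the normal state, the
tumor-minus-normal change of gene *j* decomposes into contributions of
its regulators, each proportional to the regulator's own change. Three
consequences drive the whole design:

* **Patients are the unit of correlation.** Every quantity is built
  from per-patient paired differences Δr_i(p), Δg_j(p) of
  RPM-normalized expression (tumor minus matched normal from the same
  patient). This is why the data model requires an explicit pairing
  sheet and at least 3 patients, and why both expression matrices are
  restricted to their shared patients before anything else.
* **Apportionment.** A miRNA's change Δr_i is split over its effective
  target set in proportion to each target's share of the total absolute
  gene change, giving Δr_ij. The regulation sign is the Pearson
  correlation ρ_ij between Δr_ij and Δg_j across patients — positive is
  up-regulation, negative repression. The unknown proportionality
  constant between correlation and regulatory slope is the same for all
  pairs and cancels in the local-influence normalization, so it is
  never exposed as a parameter.
* **Two-level scoring.** Local influence I_ij normalizes ρ_ij·|Δr̄_ij|
  per *gene* over its regulators (so Σ|I_ij| = 1 on every informative
  gene); global influence I_i sums |I_ij| weighted by PPI-degree
  importance d_j/d_max per *miRNA*. A miRNA is critical when it
  dominates the regulation of many well-connected dysregulated genes.

The linearization is the model's central assumption: no saturation, no
combinatorial interaction between regulators, no direction of causality
beyond the targeting relation taken from the interaction table.
Correlation on raw RPM differences (no log transform) keeps the
apportionment and the correlation on the same scale; we deliberately do
not fit a multivariate regression of a gene on all its regulators —
the apportionment *is* the model of shared responsibility.

## The pipeline stages and their tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `de_method` | `nb_wald` | paired DE test; `paired_wilcoxon`, `paired_t` selectable |
| `de_alpha` | 0.05 | BH-adjusted FDR threshold for DE flagging |
| `gate_influence` | `TRUE` | restrict influence to edges with both endpoints DE |
| `apportion_mode` | `per_patient` | apportionment weights per patient or from cohort means |
| `ppi_min_score` | 150 | strict (>) combined-score filter on PPI edges |
| `rho_threshold` | 0.3 | cut-off for the ρ distribution summary |
| `top_k` | 20 | length of the ranked miRNA table extract |
| `n_top_intervention` | 5 | miRNAs summarized in the binned intervention table |

**Differential expression.** The DE stage is a gate, not the core
statistic, so it is kept self-contained: the default is a
negative-binomial Wald test on raw counts with log library-size
offsets, fitted by vectorized IRLS with a per-feature method-of-moments
dispersion floored at 1e-8 (near-Poisson) and capped at 100. On 1000
null features at 20 patients the raw p-values are close to uniform
(~5.5% below 0.05) and BH flagging under the global null is rare
(≪ 1%). The direction (`over`/`under`) is always taken from the sign of
the mean RPM difference — not from the GLM coefficient — so it is
defined identically for all three test methods, and a tie resolves to
`under`. Zero-variance features under the paired tests get p = 1 rather
than an error, because a cohort can legitimately contain flat features.

**Apportionment mode.** The per-patient mode is the literal sample-wise
reading of the weight formula and is the default. In `cohort_mean` mode
the weight is one positive constant per gene, which makes ρ_ij collapse
exactly to the plain Pearson correlation of Δr_i with Δg_j; it is
offered as a sensitivity analysis (the equivalence is property-tested).
A patient in which every target of a miRNA is unchanged gets weight 0
for that miRNA rather than 0/0.

**DE gating.** Influence is computed on the target-map subset where
both the miRNA and the gene are flagged, mirroring the staged design
(DE first, influence second); the effective target set used in the
apportionment denominator is therefore the analyzable, DE-gated one.
The switch is exposed because the ungated variant is occasionally
useful for diagnostics.

**PPI handling.** The network is undirected; self-loops and duplicate
edges are removed (degree is otherwise ill-defined); the score filter
is strict (> 150). Genes absent from the filtered network get
importance 0 — the formula offers no fallback and zero is the
conservative reading — and a miRNA whose every target is outside the
PPI keeps score 0 but stays in the output, so "no PPI evidence" is
distinguishable from "not analyzed". The PPI file must already use the
same gene identifiers as the expression data; identifier mapping is out
of scope.

## Numerical choices and degenerate inputs

* Zero-variance edges get ρ = 0 and genes with an all-zero
  normalization denominator get I = 0 for all regulators (flagged
  uninformative); downstream sums stay finite by construction.
* A zero-total library stays all-zero after RPM with a warning instead
  of producing NaN.
* Ranking ties are broken lexicographically by miRNA identifier;
  intervention bins are left-closed width-0.1 intervals with the top
  bin closed (`[0.9, 1.0]`), which is exhaustive and disjoint.
* Intervention calls require a nonzero ρ and two flagged endpoints;
  anything else is `undefined` and excluded (with a reported count)
  from the binned summary, since the sign rules only cover the four
  defined patterns.

## A property the per-gene normalization does *not* have

ρ_ij is invariant under rescaling any miRNA's deltas by a positive
constant (Pearson is scale-free), and all influences are invariant
under rescaling *all* miRNAs by one constant. But rescaling a *single*
miRNA changes its |Δr̄_ij| terms inside the per-gene denominators it
shares with other regulators, so I_ij on multi-regulator genes is not
invariant under single-miRNA rescaling — invariance there would require
a per-miRNA normalization, which would break the per-gene conservation
Σ|I_ij| = 1. We keep the per-gene form (conservation is the property
the ranking relies on) and test both the true invariances and,
deliberately, the stricter untrue one, which fails on shared-regulator
instances; comparisons of I across miRNAs therefore assume all features
are on a common expression scale, which RPM provides.

## What the synthetic generator emulates

`simulateRegulation()` produces the shapes of the intended inputs: a
paired cohort (default 50 patients, matching cohorts of ~50–100
patients this method targets), a target table, a scored PPI, and ground
truth. Per patient, each miRNA has a Gaussian latent delta
(SD = 0.5·baseline); planted features additionally get a DE shift
(0.6·baseline, random sign). Each planted gene responds to exactly one
regulator with the planted sign; deltas are injected symmetrically into
the NB means (tumor +d/2, normal −d/2, dispersion 0.02 around baseline
1000), which keeps means positive even for down-shifted features. The
latent correlation is pre-compensated analytically for NB counting
noise — λ = a/√(a² + ν) with ν = 2b + α(2b² + s²/2 + a²/2) per side —
so the *observed* delta correlation lands on `effect_rho`; empirically
the mean planted-edge correlation at 1000 patients is within ±0.01 of
targets 0.3/0.5/0.8. A target the noise cannot support (required latent
correlation > 0.995) is refused as infeasible rather than silently
attenuated.

Restricting planted genes to a single regulator is a modelling
necessity, not a convenience: a gene driven by k independent regulators
can correlate with each at no more than 1/√k of the shared slope, so a
per-edge population correlation of 0.8 is unattainable for k ≥ 2.
Multi-regulator genes still occur via decoy (null) target-map edges, so
the per-gene normalization is exercised. The generator does **not**
mimic TCGA library-size variation, batch effects, dispersion trends,
correlated co-regulation programs, or realistic miRNA naming — passing
tests on it demonstrates correctness of the computation and
recoverability under the stated noise model, not performance on real
cohorts.

The hub configuration (`hub_spec`) plants one miRNA with 20
strong-effect targets whose genes receive extra PPI neighbors, against
background miRNAs with 2 weak low-degree targets each; it exists to
verify that the global score ranks the hub first.

## Problem sizes used in the validation

The shipped validation uses cohorts of 50 patients with 100 miRNAs ×
400 genes (sign recovery, 100–200 replicates), 30 miRNAs × 200 genes
for hub recovery (50–100 replicates), 100-feature × 20-patient
two-group sets for the DE stage (100–200 replicates), and random
instances of ≤ 5 miRNAs × 8 genes × 10 patients against nested-loop
oracle implementations. These sizes give stable rates in a few minutes
on one core; the statistics scale to full cohorts without algorithmic
change (everything is vectorized per feature or per edge).

## Known limitations

* The Taylor linearization ignores regulator interactions; strongly
  cooperative or saturating regulation will be mis-apportioned.
* Correlation is not causation: a confounded miRNA–gene pair with
  correlated deltas is indistinguishable from regulation. The target
  map is the only causal prior.
* Gating at FDR 0.05 makes the analyzable edge set depend on cohort
  size; small cohorts lose weakly shifted regulators before influence
  is ever computed.
* Degree centrality is the only importance measure, as the global
  score defines; well-connected genes dominate regardless of the
  biological context of their connections.
* RPM normalization is composition-sensitive; a few extremely abundant
  features can distort the deltas of everything else.
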