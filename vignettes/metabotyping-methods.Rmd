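---
title: "Methods: from ex vivo SN-38G turnover to metagenome network features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from ex vivo SN-38G turnover to metagenome network features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabotyper)
```

## The problem

Irinotecan's active metabolite SN-38 is detoxified in the liver by
glucuronidation to SN-38G and excreted into the gut, where microbial
β-glucuronidases (BGs, EC 3.2.1.31) can remove the glucuronide and
regenerate SN-38 in situ — the mechanism behind the drug's severe
gastrointestinal toxicity. Individuals differ strongly in how much SN-38
their fecal communities regenerate. `metabotyper` implements the full
analysis chain that (i) measures this phenotype from ex vivo incubations by
targeted LC-MS/MS, (ii) splits a cohort into low/high "metabotypes", and
(iii) asks what distinguishes the metagenomes of the two groups: individual
features (taxa, BGs, transporters, KEGG orthologous groups), their evenness
across people, and the position of metabotype-associated enzymes in the
community metabolic network.

Every stage consumes plain tables (TSV) of the kind upstream tools
(read mappers, HUMAnN-style profilers) produce; raw reads, spectra and
database curation are out of scope. A seeded generator simulates all inputs
so the pipeline is fully testable offline.

## Quantitation model

Peak areas are normalized to a co-injected internal standard
(hydroxycamptothecin-d5) and converted to concentrations through an
ordinary-least-squares calibration line of area ratio on concentration:
$\hat c = (r - \beta_0)/\beta_1$. Negative back-calculations are floored at
0 and flagged rather than propagated. The paper-style limits of detection
are the ICH formulas $\mathrm{LLOD} = 3.3\,\sigma/\beta_1$ and
$\mathrm{LLOQ} = 10\,\sigma/\beta_1$ with $\sigma$ the calibration residual
SD on $n-2$ degrees of freedom (the source text states the limits were
determined but not how; this is the package's choice). Replicates are
summarised as mean ± sem; sem is exactly 0 iff replicates are identical.

Percent formation is an endpoint quantity:
$100 \cdot c_{\mathrm{SN38}}(t_{\mathrm{final}})/c_0$ with
$c_0 = 100\,\mu M$ substrate, clipped to $[0, 100]$. No kinetic model is
fitted — only triplicate endpoint summaries are reported by the emulated
assay, and the within-individual trajectory shape is unconstrained, so the
simulator uses the simplest shape consistent with the endpoints: a linear
rise in expectation across 0, 1.5 and 3 minutes.

## Metabotype classification

With percent-formation values sorted ascending, the cohort is split at the
largest consecutive gap; if that gap is under `min_gap` (default 10
percentage points, below the 17.74-point gap separating the two reported
group ranges) the cohort is called unimodal and everyone is labeled low.
Ties break by individual ID, making the assignment deterministic. Whenever
a high group exists, min(high) > max(low) by construction.

**Known limitation (deliberately left visible).** The generator draws each
individual's final fraction uniformly from the group range — low
0.04–8.72%, high 26.46–77.11%, sizes 16/4. Four uniform draws over a
50.65-point span produce a largest internal spacing that exceeds the
between-group gap (17.74 points plus the slack from the extreme order
statistics) in roughly a quarter of cohorts, so the largest-gap rule then
splits *inside* the high group. The recovery experiment in the acceptance
suite measures ~70–75% whole-cohort recovery, not the 100% the build
contract asserts; that test is intentionally left failing, because the
failure is a property of the stated generative world, not of the
implementation (no unsupervised two-group split of 20 points can achieve
100% there; a 1-D 2-means fails on the same cohorts). On the real data the
rule is sound: the printed ranges are the *observed* order statistics of a
cohort whose between-group gap was in fact its largest gap.

## Differential abundance

Within each feature category, samples are closed to proportions; Welch's
unequal-variance t statistic with Welch–Satterthwaite df is used because
the groups are unequal (16 vs 4) — a Shapiro–Wilk check is exposed as a
warn-only QC gate for its normality assumption. Multiplicity is handled by
Storey q-values with the single-λ estimator
$\hat\pi_0 = \min\!\big(1, \#\{p > \lambda\}/((1-\lambda)m)\big)$, λ = 0.5,
floored at $1/m$; q-values are the step-wise minimum, equal to
$\hat\pi_0 \times$ Benjamini–Hochberg (verified against `p.adjust` in the
tests). A feature is called only if additionally the symmetric
ratio-of-proportions effect size max/min of the two group means is ≥ 2;
zero means are replaced by half the smallest nonzero mean before forming
the ratio (two zeros give ratio 1). The published filter wording
("effect size < 2.00") is read as the exclusion rule: retained features
have ratio ≥ 2. q-values are computed within each category separately,
matching per-database analyses.

## Evenness

Simpson's equitability of an entity across $S$ samples is
$ED = (1/\sum_i p_i^2)/S \in [1/S, 1]$. $S$ counts *all* cohort samples by
default, zeros included — this is what makes the contrast "a BG family
evenly shared across people vs a taxon concentrated in a few carriers"
meaningful; a present-only mode is available. The classical $\sum p_i^2$ is
used without small-sample correction. The published ED values (0.938 for
Enterobacteriaceae BGs vs 0.629 for the family) require the study's data
and are not reproduction targets; the package reproduces the *pattern*
(positive gene-minus-taxon delta) on synthetic decoupled tables.

## Odds-ratio enrichment and the metabolic network

Per enzyme, abundance is dichotomized at the cross-sample median (ties to
low; the original construction is cited but not restated in the source, so
this is a documented reimplementation choice, configurable in spirit via
presence/absence). The 2×2 table against metabotype gives an odds ratio
with the Haldane–Anscombe +0.5 correction when any cell is zero; the
differential abundance score is $|\log_2 OR|$. The published categories
overlap (enriched OR > 2 is a subset of associated OR > 1); they are made
mutually exclusive here — enriched (OR > 2), associated (1 < OR ≤ 2), other
(0.5 ≤ OR ≤ 1, boundary 0.5 assigned to other), depleted (OR < 0.5) — and
the "associated set" for the network tests is OR > 1.

The community network has enzymes as nodes and a directed edge u→v iff
some product of u is a substrate of v, after removing blacklisted currency
compounds (default blacklist empty — none is published — and it is the main
driver of network density; water/ATP-like cofactors will otherwise connect
everything). Self-loops are dropped, isolated nodes kept. Betweenness is
standard Brandes semantics — unweighted directed shortest paths, endpoints
excluded, fractional credit among co-shortest paths — normalized by
$(n-1)(n-2)$, delegated to igraph and checked exactly against a brute-force
path-enumeration oracle in the tests. Enzymes are binned into
peripheral/intermediate/central tertiles by betweenness rank (tier of rank
$r$ is $\lceil 3r/n \rceil$; remainders accumulate at the central end; ties
break by enzyme ID). Associated vs non-associated centrality is compared by
Wilcoxon rank-sum (exact when both groups ≤ 10 and untied, else normal
approximation with midrank ties), tier over-representation by the
hypergeometric upper tail, and score-vs-topology association by Spearman's
ρ on midranks.

## What the synthetic world does and does not emulate

The generator reproduces the *statistical design* the analysis assumes:
16/4 groups, uniform turnover in the printed non-overlapping ranges,
triplicates with multiplicative log-normal noise (default CV 5%, a typical
LC-MS/MS technical spread), per-entry log-normal feature abundances with
planted fold changes, and chain-structured reaction annotations whose
chain-end enzymes are ground-truth peripheral. It does **not** emulate
compositional coupling between features, phylogenetic correlation,
zero-inflation, sequencing depth variation, or real KEGG stoichiometry. A
green recovery test therefore establishes that the statistical machinery is
implemented correctly and has its nominal operating characteristics in its
own model — not that the design has power on real microbiome data.

Two generator defaults deserve emphasis:

* `baseline_log_sd = 0.15` (CV ≈ 15%). This is the technical-replication
  scale, not the between-subject biological scale (log-SD ≥ 0.5 would be
  realistic for gene families across people). It is fixed by a power
  requirement the build contract itself asserts: a planted fold-4 effect at
  16 vs 4 must survive q < 0.05 at m = 200 features, which needs
  $|t| \gtrsim 7$ at df ≈ 3.3, i.e. CV ≲ 0.2 (at log-SD 0.5 the measured
  sensitivity is 0.05). The choice is the one-time instantiation of an
  unstated parameter so that the asserted property is satisfiable; with
  realistic between-subject noise, four high samples simply cannot support
  this detection task.
* The recovery network (8 chains × 6 enzymes, 6 cross-links) is large
  enough that the Wilcoxon comparison has ~95% power at the planted
  fold-4, chain-end design while staying sub-second.

## Numerical and degenerate-input choices

* Zero-variance Welch inputs: equal means → t = 0, p = 1; unequal means →
  p = 0 with a degenerate flag.
* $\hat\pi_0 = 0$ (every p small) is floored at $1/m$.
* Zero ISTD areas are excluded with a warning; a cell losing all
  replicates is an error, not an NA.
* All-zero abundance vectors have undefined evenness (error), as does a
  zero-variance correlation input.
* Every generator is a pure function of its spec including the seed; the
  pipeline report is byte-identical across reruns of the same config+seed.

## Limitations

Single-λ π0 (not the smoother); no compositional (log-ratio) testing; no
rarefaction or alternative diversity indices; degree and betweenness are
the only exposed topology features; the CLI covers the documented
interfaces but not STAMP-style interactive exploration.
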