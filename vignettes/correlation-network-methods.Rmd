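---
title: "Methods: sample correlation networks for LC-MS fingerprinting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sample correlation networks for LC-MS fingerprinting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sampleCorrNet)
```

## The problem and the model

Untargeted LC-MS profiling of food samples (the motivating system is cocoa:
beans at the unfermented, fermented and liquor processing stages, sourced from
several countries) yields, per sample, peak areas for thousands of compound
features. Classical ordination methods separate samples well along the
dominant source of variance — the processing stage — but the finer grouping by
country of origin is typically buried beneath it.

This package analyses such tables through the *family of sample correlation
networks*. Each sample $\alpha$ is a node; its profile is the vector
$l^\alpha$ of compound peak areas, normalized so that each sample sums to 100
(relative percent). The Pearson correlation between two samples is

$$r_{\alpha\beta} = \frac{\mathrm{cov}(l^\alpha, l^\beta)}
  {\sigma_{l^\alpha}\,\sigma_{l^\beta}},$$

and the Spearman correlation $\tilde r_{\alpha\beta}$ is the same quantity on
the rank-transformed profiles (ties receive average ranks). Spearman is the
default throughout because peak areas are heavy-tailed and zero-inflated, and
rank correlation is invariant to monotone distortions of intensity. The
population-vs-sample covariance convention cancels in the ratio.

A network at threshold $t \in [0, 1]$ has an edge between $\alpha$ and
$\beta$ exactly when $\tilde r_{\alpha\beta} \ge t$ **and**
$\tilde r_{\alpha\beta} > 0$. The strict-positivity clause makes the
threshold-0 network the graph of all positive correlations (negative
correlations never form edges). Edge sets are nested along any increasing
threshold grid. Sweeping $t$ from 0 towards 1 exposes a *nested* group
structure: modules first form by the coarse attribute (processing stage) and,
at higher thresholds, fragment into modules enriched in the fine attribute
(origin).

## Statistics across the sweep

Four quantities are computed per threshold:

* **Edge similarity** (`edgeSimilarity`, `similarityCurves`): the fraction of
  edges whose endpoints share an attribute value. It is defined per edge,
  never over visual clusters. With no edges it is *undefined* and reported as
  `NA` — never 0, which would fake perfect dissimilarity.
* **Null ensemble** (`nullEnsemble`): control networks obtained by permuting
  the multiset of positive edge weights over the positive pairs, preserving
  the weight distribution exactly, then re-thresholding. Because the
  permuted network at threshold $t$ is a uniformly random $k$-subset of the
  positive pairs, the expected null similarity at *every* threshold equals
  the full-network similarity $s_0$ — the mechanism behind the flat null
  line in similarity plots. The ensemble default is 100 replicates; mean and
  standard deviation are reported per threshold. A variant permuting over
  all $n(n-1)/2$ pairs is available (`scope = "all-pairs"`) for sensitivity
  analysis; the positive-pairs reading is the default because it keeps the
  control network's correlation distribution identical to the original's.
* **Ideal-network accuracy** (`idealNetwork`, `accuracyCurve`): the ideal
  network of an attribute links exactly the same-attribute pairs. Comparing
  the thresholded network with it classifies all $\binom{n}{2}$ pairs into
  TP/TN/FP/FN, and the accuracy $\alpha = (TP + TN)/\binom{n}{2}$ measures
  how closely the network realises that grouping. The four counts always sum
  to $\binom{n}{2}$.
* **Majority-vote inference** (`majorityVote`, `predictionGrid`,
  `meanPredictionScore`): each node's attribute is predicted, leave-one-out,
  as the most frequent label among its neighbours (optionally neighbours at
  distance $\le 2$, each counted once). Zero voters or a tied top count give
  an *undefined* outcome; the per-threshold mean score is the correct
  fraction among defined outcomes only. Ties are reported as undefined
  rather than resolved by coin flip so the pipeline stays deterministic; an
  optional correlation-weighted vote (`weighted = TRUE`) reduces ties and is
  off by default.

## The synthetic generator

`simulatePeakTable()` emulates the data the analysis assumes: `nSamples`
(default 140) samples allocated over 3 stages and 8 origins — allocation is a
deterministic largest-remainder split of the product weights, with the
default origin weights making the largest origin about four times the
smallest — and `nCompounds` (default 1000) nonnegative features per sample,
normalized to a per-sample sum of 100 and sorted by descending mean peak
area.

Profiles are exponentiated Gaussians over a latent layer
$x_\alpha = b + a\,u_s + c\,w_{s,o} + \sigma\,\varepsilon_\alpha$ with a
shared baseline $b$ ($\sigma_b$, default 1), one vector $u_s$ per stage
(scale $a$ = `stageEffect`, default 1), one vector $w_{s,o}$ per
stage-origin cell (scale $c$ = `originEffect`, default 0.6; nesting origins
within stages is what makes the fine structure appear *inside* the coarse
one), and i.i.d. noise ($\sigma$ = `noiseSd`, default 0.8). The log-normal
form guarantees nonnegative, heavy-tailed intensities, and since $\exp$ is
strictly increasing, Spearman correlations equal those of the latent layer,
where the expected correlation between two samples is

$$\frac{\sigma_b^2 + a^2\,[\text{same stage}] + c^2\,[\text{same origin}]}
  {\sigma_b^2 + a^2 + c^2 + \sigma^2}.$$

With the defaults this puts cross-stage pairs near 0.33, same-stage
cross-origin pairs near 0.65 and same-origin pairs near 0.78, so the stage
similarity curve saturates around threshold 0.4–0.5 while the origin curve
stays near its null value until about 0.6 and then rises — the qualitative
ordering the analysis is designed to reveal, with the coarse effect
preceding the fine one. The defaults were chosen once from this closed form
to reproduce that ordering; they are study conditions, not tuning knobs.

What the generator does **not** emulate: chromatography, m/z values and
retention times (features are anonymous), compound identities, batch or
acquisition-date effects, origin-specific variance structure, and the
occasional negative correlations real tables show (all simulated
correlations are positive in expectation). Passing tests on synthetic data
therefore demonstrate the machinery and the nested-recovery property, not
the numerical values any particular real dataset would give.

## Numerical and design choices

* Threshold comparison is an exact `>=` on stored values, no epsilon:
  thresholds are user-supplied round numbers.
* Ties in ranking use average ranks (midranks), the standard Spearman
  convention, which matters for the many tied zero entries of sparse tables.
* Missing compound cells on input are read as 0 ("not detected") and
  counted in a message; negative entries and non-numeric cells are errors
  with coordinates.
* Samples with constant profiles have undefined correlations and are
  rejected by name rather than propagated as `NA`.
* Isolated nodes are never removed from the data structure; isolation is a
  flag, and only the reported size-curve counts "drop" them, so
  classification denominators stay explicit.
* Component lists are ordered largest-first with ties broken by the
  earliest member in node order, making outputs deterministic.
* All randomness flows from explicit seeds through a local RNG (the
  caller's stream is saved and restored). `runPipeline` derives substreams
  documented as: generator = `seed`, null ensemble = `seed + 1`.
* Undefined statistics (no edges, no defined votes) are written to output
  files as empty cells, never 0.

## Problem sizes

The reference study conditions used by the test-suite recovery checks and by
`scripts/acceptance.R` are 140 samples by 1000 compounds over a 10-point
threshold grid (0 to 0.9 in steps of 0.1), with 20 generator seeds for the
seed-robustness checks and 100-replicate null ensembles (10,000 replicates
on a 6-node toy for the closed-form ensemble check). These sizes were chosen
so a full run completes in seconds to a few minutes on a single core while
keeping the Monte-Carlo error of every checked quantity well below its
assertion margin.

## Known limitations

* XLSX input is supported (via readxl) but output is CSV-only; there is no
  XLSX writer backend among the package's dependencies.
* Graph layout, interactive visualisation and movie rendering are out of
  scope; networks are exported as SIF/edge-list CSV plus node-attribute CSV
  for Cytoscape.
* No p-values are attached to correlations; the analysis uses magnitudes
  and permutation nulls only.
* The majority-vote classifier has no probabilistic calibration and no
  train/validation split; it is a leave-one-out read-out of network
  structure, not a tuned classifier.

## A worked miniature

```{r example}
pt <- simulatePeakTable(nSamples = 30, nCompounds = 200, seed = 2)
cm <- correlationMatrix(pt)           # Spearman by default
th <- seq(0, 0.9, 0.1)
sim <- similarityCurves(cm, list(sample_type = sampleType(pt),
                                 origin = origin(pt)), th)
subset(sim, threshold %in% c(0.3, 0.5, 0.7))
```

The coarse attribute's similarity saturates first; the fine attribute's
follows at higher thresholds.
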