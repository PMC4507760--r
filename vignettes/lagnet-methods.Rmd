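---
title: "Inferring regulatory hubs from lagged correlation networks"
author: "lagnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring regulatory hubs from lagged correlation networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lagnet)
```

## The problem

When a microalgal culture is shifted to nitrogen-free medium it rewires its
metabolism over hours: photosynthesis and chlorophyll synthesis are wound
down, nitrogen assimilation and carbon storage are ramped up, and neutral
storage lipid (triacylglycerol, TAG) accumulates from roughly 4–6 h onward.
Which transcription factors (TFs) and transcriptional regulators (TRs)
coordinate this program is the question this package addresses. The
available evidence is observational: a short, unevenly sampled multi-omics
time course (transcripts, proteins, metabolites, typically at 0, 0.5, 1, 2,
4, 6, 12, 24 and 48 h with duplicate samples), with no perturbation of
individual regulators. `lagnet` implements the standard correlation-network
reading of such data: regulators whose expression trajectories track — or
precede by one sampling step — the trajectories of many metabolic genes or
metabolites are candidate points of control.

## The model

All series are first reduced to fold changes against the time-zero control:
for entity $e$ at time $t$, replicates are averaged and
$\mathrm{fc}(e,t) = \bar{x}(e,t) / \bar{x}(e,0)$, analysed as
$\log_2 \mathrm{fc}$. Entities with a zero baseline cannot be expressed this
way and are reported in an exclusion table rather than silently dropped.

An entity *responds* when $|\log_2 \mathrm{fc}|$ reaches $\log_2 2 = 1$ at
some point of the analysis window (0.5–24 h; the 48 h point is excluded by
default, and down-regulation is the symmetric condition fc $\le 1/2$). The
first such time is the *onset*. Onsets in (0, 4] h are *early* (BTS,
"before TAG synthesis"); onsets in [6, 24] h are *late* (ATS, "after TAG
synthesis initiation"). The 4–6 h split is where TAG accumulation begins in
this experimental system.

For every responding regulator $x$ and every responding metabolic gene,
protein or metabolite $y$, the package computes the time-lagged Pearson
correlation: for each lag $\ell$ in the configured set (default
$\{0, +1\}$ sampling steps, regulator leading), $x_i$ is paired with
$y_{i+\ell}$ and the lag maximising $|r|$ is kept. Lags count grid
positions, not hours: on a grid that is dense early and sparse late, a
fixed-hour lag would be either invisible early or absurd late, so a
one-step lag is the natural unit. The p-value is the usual two-sided $t$
transform, $t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ degrees of freedom. An
edge is retained when $|r| \ge 0.9$ **and** $p \le 0.05$ — deliberately
stringent, and applied to raw p-values; a Benjamini–Hochberg column is
written alongside the audit table for reference but takes no part in the
filter, because the filter is part of the method being reproduced, not a
claim of per-edge significance.

Retained edges form an undirected signed graph that is bipartite by
construction (regulator versus non-regulator; regulator–regulator and
gene–gene correlations are never computed). Nodes carry one of ten
metabolic-process labels (lipid, Calvin cycle, nitrogen, photosynthesis,
photorespiration, oxidative pentose phosphate pathway, citrate/glyoxylate,
sucrose/starch, amino acid, chlorophyll), giving ten process subnetworks:
each keeps every regulator plus the nodes annotated with that process.

### Motifs and hubs

A *single-input motif* (SIM) is a regulator together with at least two
targets whose only regulator neighbour is that regulator; merging all SIMs
gives the SIM subnetwork. *Hubs* are the regulators in the top 5% of
regulator degrees — `ceiling(0.05 * m)` of the `m` connected regulators,
with all ties at the boundary degree included so the call is deterministic
and indifferent to node labels — in **both** the whole network and at least
one process subnetwork (`hub_rule = "any"`; requiring all subnetworks is a
configuration switch).

Hubs are then typed by the response phase of their partners. Using the
edges whose phase is clear, a hub with only early-phase edges is
*BTS-specific*, only late-phase edges *ATS-specific*, both *permanent*;
phase-specific hubs must additionally drive a SIM whose exclusive targets
span at least two biological processes, otherwise they stay unclassified.

### Edge phase: a design decision

Two schemes for giving an edge a phase are implemented. The default,
`"target"`, uses the target's onset window (requiring the regulator to
respond at all). The stricter `"both_endpoints"` scheme demands that both
endpoints' onsets fall in the same window and otherwise calls the edge
mixed. We made `"target"` the default after observing a structural
consequence of the strict rule: an edge exists only when the two profiles
are nearly affine ($|r| \ge 0.9$), and a regulator has exactly one onset,
so under the strict rule every clear-phase edge of a regulator inherits the
regulator's own window — no hub can ever have clear edges in both windows,
and the *permanent* class becomes unreachable. Phase-specific versus
permanent regulation is, however, a statement about *when the targets
respond* (a permanent hub drives targets irrespective of the phase), which
is exactly what the target-onset scheme measures. Both schemes are exposed
through `lagnet_config(phase_scheme = ...)` and `assign_edge_phase()`.

## Normality diagnostics

Before correlating, the per-time-point distributions are profiled:
Shapiro–Wilk $W$ and $p$, adjusted skewness $G_1$ and excess kurtosis $G_2$
(the SPSS convention, computed via `e1071` type 2) with the exact
small-sample standard errors
$\mathrm{SE}_{skew} = \sqrt{6n(n-1)/((n-2)(n+1)(n+3))}$ and
$\mathrm{SE}_{kurt} = 2\,\mathrm{SE}_{skew}\sqrt{(n^2-1)/((n-3)(n+5))}$,
and the ratios $z = \text{statistic}/\mathrm{SE}$. This report is a
diagnostic gate in the tradition of this analysis, not a hard filter: the
pipeline records it and proceeds, and the z-values are reported as
computed, without any judgement call about what "approximately normal"
should mean.

## Scale-free diagnostics

Correlation networks of this kind are routinely described as scale-free:
many low-degree regulators, few high-degree hubs. `degree_stats()` reports
the degree histograms and a power-law exponent fitted by least squares on
logarithmically binned log-log counts (bin edges at powers of two, counts
normalised by bin width — plain per-degree counts systematically
underestimate the exponent on the sparse tail). The boolean
`scale_free_like` requires an exponent in $[1, 4]$ and $R^2 \ge 0.8$ with
at least four occupied bins; it is a conservative descriptive flag, not a
statistical test of power-law behaviour.

## The synthetic benchmark

Because the method is a pipeline of filters, every stage is validated
against data with known structure. `generate_dataset()` plants:

* **three major hubs** — one early (BTS), one late (ATS), one both-phase —
  with ten targets each (genes and metabolites, alternating). The
  both-phase hub's profile crosses the 2-fold threshold exactly at 4 h, so
  its lag-0 targets respond early while its lag-1 targets (shifted one
  grid step, to 6 h) respond late: a permanent hub arises from lag
  structure, not from incoherent profiles;
* **45 minor regulators** with one exclusive target each. These are not
  decoration: `ceiling(0.05 m)` only reaches 3 when $m > 40$ regulators
  are connected, so the long tail is what makes the top-5% rule a real
  test, and it reproduces the field's qualitative claim of many weak
  regulators and few strong ones;
* **background responders** (30% of the remaining entities) that cross the
  threshold but partner with nobody, and **non-responders** fluctuating
  within ±0.3 log2 units.

Planted targets are exact lag-shifted, sign-scaled copies of their
regulator's log2 profile, so at zero noise every planted pair has
$|r| = 1$ at its planted lag. Replicate noise is multiplicative
log-normal, $\exp N(0, \sigma^2)$ with $\sigma = 0.15$ by default on two
replicates. Regulator profiles are drawn as random "wiggly" directions
scaled to a maximum amplitude of 2.5 log2 units, greedily accepted (and
refined) so that every regulator-versus-regulator correlation — at every
shift/lag combination the analysis will test — stays near or below 0.8.
This encodes the premise that distinct regulons follow distinct temporal
programs and makes the planted truth identifiable by construction: at zero
noise the retained edge set *equals* the planted edge set. Truth topology
and profiles depend only on the configuration's `truth_seed`, so
simulation seeds vary measurement noise around a fixed ground truth.

What the generator does **not** emulate: smooth mechanistic kinetics
(profiles are piecewise-random, not ODE solutions), realistic
mass-spectrometry noise (heteroscedasticity, missingness, batch effects),
correlated replicate error, and regulons that genuinely share temporal
programs. The last point matters most for interpretation: in real data,
co-responding but unrelated entities produce correlated profiles and hence
false edges that no threshold can remove; the benchmark quantifies the
pipeline's behaviour when the identifiability premise holds, not the
biological false-discovery rate. Residual profile correlations near the
0.8 cap do produce a small false-edge rate at the default noise level
(edge precision is typically 0.85–0.9, with hub precision/recall at 1.0),
which is the honest behaviour of a hard threshold near its boundary.

## Numerical choices and degenerate inputs

* Replicates are averaged (arithmetic mean) before fold change; missing
  replicates are absent, not zero, and pairs with fewer than `min_overlap`
  (default 5) complete observations yield no correlation.
* Correlations are computed on log2 fold changes, where the planted
  regulator–target relation is affine and up/down responses are symmetric.
* Lag ties (equal $|r|$) resolve toward the smaller absolute lag, then the
  smaller lag, so lag 0 wins over ±1 when nothing distinguishes them.
* Exactly collinear pairs ($1 - r^2 \le 0$ in floating point) get $p = 0$.
* Constant series raise a "zero variance" error in `lagged_pearson()`; in
  the all-pairs sweep such pairs are simply not evaluable and appear in no
  table.
* Duplicate edges per node pair collapse to the strongest $|r|$;
  self-loops and regulator–regulator edges are structural errors.
* A trailing 48 h sample is carried by the data model but excluded from
  the default analysis window, matching the designs this method is used
  on; the grid is data-driven, so other designs work unchanged.
* The problem sizes used in the package's tests and acceptance script —
  150 entities, seven window time points, two replicates, 20 simulation
  seeds — mirror the scale of the experimental designs this analysis
  targets, and run in well under a minute each.

## Known limitations

Correlation networks are not causal claims: an edge is a co-response, the
regulator-leads lag convention is a reading aid, and hub degree measures
coordination, not necessity. The stringent $|r| \ge 0.9$ filter on seven
points retains only near-affine profiles, which is why phase typing can
lean on onsets alone. The p-value threshold at $n = 7$ is nearly redundant
next to $|r| \ge 0.9$ (the $t$ transform crosses $p = 0.05$ near
$|r| = 0.75$); it becomes binding on shorter overlaps. Raw (uncorrected)
p-values are used by design, to reproduce the method faithfully; users
wanting error control should consult the `p_adj` column of the audit table
and treat the network as exploratory.
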