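---
title: "Detecting lateral gene transfer from gene-tree incongruence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting lateral gene transfer from gene-tree incongruence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lgtsurvey)
```

## The model

A set of protein markers shares one species history but each marker has
its own gene tree. If a marker's gene was transferred between a
prokaryotic lineage and the stem of a focal clade (here written as
Eukarya, but any focal clade works), its gene tree departs from the
species tree in a characteristic way, and those departures — not any one
tree — are the evidence this package quantifies.

Three transfer signatures are modelled, all as gene-replacement events:

* **Transfer into a prokaryotic lineage.** The recipient lineage's copy
  is replaced by the focal clade's gene, so in that marker's tree the
  recipient branches *with the focal clade at the focal clade's
  position*: the two are sister groups (nodal distance 1), while all
  other lineages of the recipient's group stay far away. This is why the
  simulator realises this event by regrafting the recipient lineage onto
  the focal clade's stem — the relocated sequence is the recipient's.
* **Transfer into the focal clade.** The focal clade's copy is replaced
  by a lineage's gene, so the focal clade appears *nested inside* that
  lineage's clade, with recipient-lineage leaves on both sides.
* **Prokaryote-to-prokaryote replacement.** A lineage's copy is replaced
  from an unrelated donor group, relocating the lineage next to the
  donor (the affinity census below counts these).

The central statistic is the **nodal distance** between two clades: with
`a = MRCA(focal)` and `b = MRCA(target)` on the rooted tree, the value is
the number of internal nodes strictly between `a` and `b`
(edges on the path minus one), so sister clades score 1 and a polytomy
node on the path counts once. When one MRCA is an ancestor of the other
the pair is flagged *nested* rather than given a small distance, because
nesting is a qualitatively different (into-the-focal-clade) signal.

Across markers, the distances to one target form an occurrence
histogram. Under no transfer the histogram is unimodal around the
species-tree distance; under a minority of transfers it is bimodal: a
near peak at 1–2 plus the far bulk. Since "looks bimodal" is not a
test, the package operationalises it as a **near-excess test**: the
observed count of markers at distance `<= d_near` is compared with the
same count in `n >= 100` matched no-transfer simulations, with the
add-one-smoothed exceedance probability
`p = (1 + #{null >= obs}) / (1 + n_null)`. A profile is `bimodal_lgt`
when `p < alpha` *and* the mode exceeds `d_near` (ties in the mode are
broken toward the larger distance, i.e. toward the bulk, so a tie never
manufactures a bimodal call); `sister_like` when the mode itself is
`<= d_near`; `unrelated_like` when the near count is null-consistent.

A simulated null — rather than an analytic one — is essential because
the null distance distribution depends strongly on taxon-sampling
imbalance: when half of all prokaryotic leaves belong to one group, an
unplaceable focal clade drifts toward that group at a rate set by the
sampling, not by history.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `min_support` | 50 | collapse internal edges below this support (same scale as the input's node labels) |
| `min_length` | 0.005 subst/site | collapse internal edges shorter than this; refused (not silently skipped) when a tree has no real lengths |
| `min_focal` | 4 | fewer focal leaves than this gives verdict `absent`; trees with 2–3 focal leaves are too thin to place |
| `min_lineage_leaves` | 2 | a lineage needs this many leaves to be scored; single stray leaves are likelier mis-annotation |
| `rooting_policy` | DPANN, then Euryarchaeota | outgroup rooting order; these groups are distant from both the focal clade and the Asgard lineages under either competing placement hypothesis, minimising bias in the focal region; midpoint fallback is always recorded |
| `major_share` | 0.2 | a lineage must hold this share of a sibling clade's classified leaves to appear in a sister label |
| `d_near` | 2 | "close" distances (sister = 1, near-sister = 2) |
| `d_far` | 4 | a direction call requires every other same-group lineage beyond this; the trough between the near peak and the far bulk sits at 3–4 under the default design |
| `alpha` | 0.05 | near-excess significance level |
| `tabulation` | strict | `loose` also credits unresolved trees whose nearest target lies within `d_near` — exposed because "sister or more closely related" censuses can be read either way |

Collapse thresholds operationalise the visual judgement that a node is
unresolved; they are deliberately configurable and the survey's
sensitivity to them is part of the test suite (collapsing more can only
move verdicts toward `unresolved`, never conjure a sister).

## The simulator and what it does (not) emulate

`simulate_gene_trees()` draws, per marker: transfer events (Bernoulli
per recipient, or exact counts via `k_lgt_focal_to_lineage`, at most one
focal-placement event per marker), a random coalescent expansion of each
lineage tip into its configured leaf count, SPR regrafts realising the
events, `nni_noise` (default 3) random NNI moves excluding edges
adjacent to event regraft points, optional deletion of the focal clade
(`p_focal_missing`, default 4/113), and log-normal branch lengths
(mean 0.06, sd 0.06 substitutions/site). A single master seed drives
everything; per-marker seeds are drawn once under it, so runs are
byte-identical for a given config.

Defaults are the study conditions the package is designed around:
56 markers; 345 leaves per tree with 175 Asgard leaves split over 14
lineages (about half of the archaeal sample), 72 TACK (Crenarchaeota +
Korarchaeota + a BAT cluster), 41 DPANN, 43 Euryarchaeota and a 14-leaf
focal clade; the focal clade's true position outside the archaeal
radiation (configurable, to test the within-Archaea alternative); and
roughly 10% of markers per focal–target pair carrying a transfer
(5/56 and 6/56 for the two Heimdallarchaeia-like defaults). Three NNI
moves per tree leave the null distance histogram unimodal with its mode
in the 5–8 node range under the default topology, matching the shape
expected for an unrelated clade.

What the simulator does **not** emulate — and therefore what passing
tests do not demonstrate about real data: sequence evolution (events are
purely topological, so alignment-level artefacts like compositional
attraction are out of scope), incomplete lineage sorting, correlated
noise between markers, support values (simulated trees carry none, so
support-based collapsing is exercised only on hand-built and real
trees), and annotation error beyond what the lineage map's override
mechanism handles. Real deposits also mix Newick dialects and contain
genuinely mislabelled leaves; the map's exact-override-beats-prefix rule
is the intended fix for those, keeping curation in data rather than
code.

## Numerical and design choices

* **Monophyly is bipartition-based and tested unrooted**, so verdicts
  are invariant under rerooting; the witness edge is the one whose
  removal separates query from rest. Singleton queries are monophyletic
  by convention.
* **Distances are measured on the collapsed, rooted tree** (that is the
  unresolved-aware reading), while **monophyly censuses use the
  uncollapsed topology**, since collapsing can only destroy, never
  create, the witnessing bipartition.
* **Nested beats small**: ancestor/descendant MRCA pairs get a flag, not
  a 0, and never enter histograms.
* **Sister labels**: a sibling clade dominated by one lineage gives a
  plain sister call; two lineages each above `major_share` give a joined
  label ("A/B"); three or more, or a mixed-group polytomy at the focal
  MRCA's parent, give `unresolved`. A sibling that is a *strict subset*
  of one lineage whose smallest containing clade also contains the focal
  MRCA's parent is the nested case.
* **Direction requires context**: `to_prokaryote` needs at least one
  other same-group lineage with a defined distance (all of them beyond
  `d_far`); with no scored companion lineage the call stays `ambiguous`
  rather than guessing.
* **Per-target p-values are not cross-target corrected by default**; the
  number of targets tested is always reported and a Bonferroni option
  exists. The survey's two default targets are interpreted jointly, so
  a correction policy is a reader's choice, not a hidden default.
* **Ties in midpoint rooting** are delegated to phangorn's deterministic
  implementation; outgroup rooting is attempted first in policy order,
  and every fallback is recorded in the per-tree report.
* **Degenerate inputs**: collapsing all internal edges yields a valid
  star tree; unknown leaf labels classify as `Unknown` and are excluded
  from lineage shares but retained in trees and counted per tree;
  unreadable tree files are logged and skipped, never fatal.

## Problem sizes used in the tests

The acceptance suite runs entirely on simulated data at the default
345-leaf design: 101 no-transfer replicate sets of 56 markers for null
calibration of the near-excess test (each replicate scored leave-one-out
against the other 100, which keeps observed and null draws exchangeable
while reusing one bank); 10 replicate sets with exactly 5 planted
transfers for recovery; 6 sets totalling over 200 planted events for
direction accuracy; 100 planted-insertion fixtures for the scanner; all
brute-force oracle comparisons run on every unrooted 6-leaf topology and
500 random 30-leaf trees. The exact-count option
(`k_lgt_focal_to_lineage`) exists precisely so that recovery experiments
condition on a known number of events instead of a Bernoulli draw.

## Known limitations

* The near-excess test assumes the null simulator's design is matched to
  the observed set (`matched_null_config()` estimates per-lineage leaf
  counts by medians; markers with wildly varying taxon sampling dilute
  the match).
* Nodal distances are topology-only by design; two clades separated by
  one node across a very long branch and by one node across a tiny one
  count the same.
* The sister classifier reads one rooted tree at a time; it does not
  attempt reconciliation-style joint inference across markers, which is
  a different (model-based) methodology altogether.
* Insertion scanning needs the insertion's flanks to be alignable and
  conserved (`min_flank_cons`); insertions inside fast-evolving regions
  will not pass the flank filter, and thresholds for presence/absence
  are exposed rather than claimed universal.
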