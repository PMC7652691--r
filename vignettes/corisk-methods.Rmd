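---
title: "Methods: comorbidity co-occurrence risk networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comorbidity co-occurrence risk networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`corisknet` implements an integrated supervised/unsupervised analysis of how
pre-existing comorbidities relate to 30-day hospital readmission in a 1:1
matched case-control cohort. The input is a binary patient x comorbidity
matrix with a case/control outcome per patient. Three stages build on each
other:

1. **Pairwise combinatorial risk (supervised).** Every unordered comorbidity
   pair is tested for association with readmission, significant pairs get
   directionality tests, and results are replicated against a second,
   independent cohort.
2. **Bipartite biclustering (unsupervised).** The replicated high-risk
   comorbidities and the case patients carrying them form a bipartite
   network; patient-comorbidity biclusters are found by maximizing Barber's
   bipartite modularity and validated against a permutation null.
   Cross-cohort agreement of the comorbidity partition is quantified by the
   Rand index.
3. **CoRisk integration.** The directed risk relations are superimposed on
   the bicluster network; patients are classified as inner/outer, bicluster
   heterogeneity is tested by chi-square, asymmetrical risk hubs are
   detected, and an exploded layout separates the biclusters visually.

A seeded synthetic cohort generator with planted effects stands in for the
restricted claims data the design targets, so the whole pipeline is testable
end to end.

# The synthetic cohort generator

## Generative model

Each candidate patient receives a binary comorbidity vector $x$ and a
readmission probability from a logistic model with pairwise interactions:

$$\operatorname{logit} P(\text{case} \mid x) \;=\; \alpha + \sum_k \beta_k x_k
  + \sum_{i<j} \gamma_{ij}\, x_i x_j .$$

Comorbidity presence is a mixture: a configurable fraction of *case-side*
candidates belongs to one of a set of planted blocks and carries the block's
comorbidities with probability `p_in` (background `p_out` elsewhere);
control-side candidates use the background model everywhere. The
case-control design is reproduced by rejection: case-side candidates are
accepted as cases with probability $P(\text{case}\mid x)$, control-side
candidates as controls with the complementary probability, until the
requested counts are reached (a cap of `max_draw_factor` times the requested
total turns an unreachable configuration into an explicit error naming the
deficit). A single seeded random stream is consumed in a fixed order (block
assignment, then presence, then outcome; case side before control side), so
identical configurations generate bit-identical cohorts.

Two consequences of this design are worth stating explicitly:

* With no blocks, a planted interaction $\gamma_{ij}$ is recovered exactly
  by the marginal cross-product odds ratio: all strata other than the
  doubly-exposed one share the same acceptance odds, so
  $\mathrm{OR}_{ij} = e^{\gamma_{ij}}$. This is the calibration the
  generator tests rely on.
* Blocks exist only among cases, deliberately: biclusters of readmitted
  patients are themselves a case-control signal. Any pair involving a block
  comorbidity therefore genuinely carries risk in the generated world, and
  the pairwise tests will (correctly) report such pairs even when no
  $\gamma$ was planted on them. Null-calibration checks consequently use
  configurations without blocks.

## Presets and default parameters

`synth_config_medicare_like()` freezes a cohort shape that mimics a large
1:1 matched readmission extract over K = 37 retained comorbidity
indicators (the count left after a 1% prevalence filter removes 32 of 69):

* background presence `p_out = 0.043` per comorbidity, giving roughly a 20%
  zero-comorbidity rate and a **median of 2 comorbidities** among patients
  retained after zero-row removal — the two marginal facts the emulated
  extract reports;
* 7 planted case blocks over the first 8 comorbidities (`p_in = 0.3`,
  fraction 0.04 each), the seventh holding two comorbidities — emulating the
  observed structure in which six biclusters are anchored by a single
  comorbidity and one by a pair;
* 11 planted pairs at $\gamma = \log 2$ among those 8 comorbidities, main
  effects $\beta = \log 2$ on them, and intercept
  $\alpha = \operatorname{logit}(0.1)$, i.e. a 10% base readmission rate.

The intercept and main effects deserve a note. A base rate near 10% is
realistic for 30-day readmission, and it keeps the logistic model in a
near-linear regime: with $\alpha = 0$ a candidate carrying two
main-effect comorbidities plus an interaction would be accepted as a control
with probability $1/9$, crushing the control counts of exactly the cells
the directionality tests divide by. Main effects on the high-risk
comorbidities mirror the analyzed setting, where single comorbidities carry
their own odds ratios, and give the directionality strata realistic
occupancy. `synth_config_block_recovery()` is the same structure at recovery
scale: `p_out = 0.02`, block fraction 0.10 (2,500 cases per block at the
default 25,000 cases), used by the validation suite and the acceptance
script.

## What the generator does not emulate

No claims codes, admission dates, episode windows, comorbidity hierarchies,
or matching covariates (age/sex/race): matching manifests only as the 1:1
count. Prevalence is exchangeable across background comorbidities rather
than following an empirical frequency spectrum. Passing recovery tests
therefore shows the statistical machinery is correct under the stated
generative assumptions — not that real claims data satisfy those
assumptions.

# Pairwise risk statistics

**Filters.** Patients with no comorbidity are removed first; then
comorbidities with prevalence below 1% are dropped and newly-emptied
patients removed. The 1% rule is read per-comorbidity by default; a
`combined` mode instead removes the largest low-prevalence set whose *union*
covers less than the threshold, for users who prefer the literal "together
occurred in less than 1%" reading. The two modes agree when rare
comorbidities rarely co-occur.

**Overall test.** For pair (A, B), exposure is carrying both, the reference
is everyone else, and the 2x2 table against case/control status gives the
cross-product odds ratio. When any cell is zero, 0.5 is added to every cell
(Haldane-Anscombe) for the OR and CI. The 95% CI is the Woolf logit
interval $\exp(\ln \mathrm{OR} \pm z_{0.975}\sqrt{1/a + 1/b + 1/c + 1/d})$;
the p-value is the two-sided Fisher exact probability on the uncorrected
counts. Fisher's exact test is used because pair strata are sparse; the
analyzed design names no test, and the exact choice is the conservative one.
Benjamini-Hochberg adjustment runs over the family of all testable pairs;
pairs with a degenerate margin are flagged untestable and excluded from the
family rather than absorbing rank mass.

**Directionality.** For each overall-significant pair, test (1) contrasts
A-and-B against A-and-not-B, test (2) against B-and-not-A. The reference
excludes the doubly-exposed so exposure and reference are disjoint; a nested
reference ("all A") would place the exposed inside the reference and bias
the OR toward 1. FDR correction is applied separately within each sub-test
family, matching a design in which each directionality test is its own
multiple-testing family. The resulting pattern (`both`, `a_only`, `b_only`,
`neither`) records which sub-tests are significant at the adjusted 0.05
level.

**Replication.** A pair is retained when it is overall-significant in both
cohorts with an identical, non-`neither` pattern (orientation is
canonicalized by label order first). The union of retained pairs' members is
the comorbidity node set for the network stages.

# Bipartite biclustering

**Modularity.** For a bipartite graph with incidence $A$, patient degrees
$k_i$, comorbidity degrees $d_j$ and $m$ edges, Barber's modularity of a
joint partition $g$ is

$$Q_B = \frac{1}{m} \sum_{i \in \text{patients}}\;\sum_{j \in \text{comorb.}}
 \left(A_{ij} - \frac{k_i d_j}{m}\right)\delta(g_i, g_j) \in [-1, 1],$$

zero for the all-in-one partition, and $(c-1)/c$ for $c$ equal disjoint
bicliques split into their components.

**Optimizer (BRIM).** Alternating exact reassignment: with comorbidity
labels fixed, each patient independently joins the community maximizing its
own modularity contribution (ties break toward the lowest community index);
then roles swap. Each half-step is monotone in $Q_B$, so iteration reaches a
fixed point. Two implementation details matter for optimality:

* two spare, initially-empty community slots are carried so that a node
  whose best populated community scores negative can escape to a
  zero-contribution singleton — without this, fixed points can trap nodes in
  communities that hurt them;
* the optimization restarts from random comorbidity assignments for every
  initial community count in `1..max_communities` (default: the number of
  connected comorbidity nodes), with the first restart a deterministic
  round-robin spread — at the top of the sweep this is the all-singletons
  initialization that separates disjoint bicliques which random initial
  labels merge with high probability.

The best partition wins by $Q_B$; ties prefer fewer communities, then the
lexicographically smallest canonical labeling (communities numbered by first
appearance over patients-then-comorbidities), making the result
deterministic given the seed. Degree-zero nodes are excluded from the
optimization and appended as singleton communities. On graphs of up to 10
nodes the optimizer is verified against an independent exhaustive search
(enumerate all comorbidity-set partitions; given one, the optimal patient
assignment is computable exactly because the objective only couples nodes of
opposite type).

**Permutation significance.** The null preserves network size and density
only: `m` edges are re-sampled uniformly over the full patient x comorbidity
grid (degrees are *not* preserved — this is the stated null of the emulated
design, and a degree-preserving alternative would test a different
question). Each permuted graph is re-optimized with the same optimizer
settings as the observed graph, and
$p = (1 + \#\{Q_{\text{perm}} \ge Q_{\text{obs}}\})/(R + 1)$, so 1000
permutations can report $p < .001$ at best. Because observed and permuted
graphs share one optimizer configuration, a capped community sweep
(`max_communities`) may be used to keep large permutation runs affordable
without breaking exchangeability; the capped statistic is then "best
modularity with at most C communities" on both sides of the comparison.

**Rand index.** Cross-cohort agreement compares the *comorbidity* partitions
only (patient sets differ between cohorts):
$\mathrm{RI} = \text{(agreeing pairs)}/\binom{n}{2}$, where a pair agrees if
co-clustered in both or separated in both partitions. Significance shuffles
one labeling across elements, preserving its cluster sizes — the simplest
exchangeable null; an independent-randomization null is available behind an
argument. The adjusted Rand index is offered as a convenience output, not
the headline statistic.

# CoRisk integration

**Arrow semantics.** Each significant replicated directionality sub-test
becomes one directed risk edge pointing *toward* the comorbidity against
which the pair adds significant risk alone: "(A&B) vs B" significant puts
the arrow from A to B (the pair is riskier than B alone), and a `both`
pattern yields two opposing arrows. A comorbidity with more incoming than
outgoing risk edges is an *asymmetrical hub*: many pairs add risk relative
to it alone, the signature of a systemic comorbidity whose co-occurrence
exacerbates organ-specific conditions.

**Inner/outer heterogeneity.** Patients with bipartite degree 1 sit on the
outer rim of their bicluster, degree > 1 inside. The 2 x C table of
outer/inner tallies per bicluster is tested by Pearson chi-square without
continuity correction (df = C - 1; the Yates correction applies to 2x2
tables only and would not reproduce the published statistic on the
reference 2x7 table).

**Exploded layout.** A seeded Fruchterman-Reingold layout of the bipartite
graph is post-processed by translating every community rigidly along the
unit vector from the global centroid to the community centroid, by
`explode_factor` times the layout radius. Pure translation preserves
within-community geometry exactly and monotonically separates community
centroids; a factor of 0 returns the base layout. The original cluster
separation algorithm's exact displacement rule is not published; this
centroid-translation rule is this package's chosen approximation with the
same goal (reduced visual overlap) and deterministic behavior.

# Numerical and validation choices

* p-values from `fisher.test` are clamped to `[0, 1]` (the exact-sum can
  overshoot 1 by machine epsilon).
* Permutation p-values use $\ge$ with a $10^{-12}$ slack so exact ties count
  as at-least-as-extreme.
* The validation suite checks, among others: seeded determinism everywhere;
  BH against the brute-force step-up definition for every family size up to
  12; the optimizer against exhaustive search on 100 random graphs of at
  most 10 nodes; null calibration of both permutation tests (200 null runs
  at R = 99 each, on 20x5 graphs with 30 edges and on 8-element
  partitions); type-I control of the pairwise pipeline under a planted null
  (50 seeds, cohorts of 5,000, K = 10); and full-pipeline recovery on two
  50,000-patient cohorts with the planted 7-block / 11-pair structure
  (planted pairs recovered as significant-replicated with the symmetric
  `both` direction; planted comorbidity partition recovered at
  RI $\ge$ 0.95). These sizes were chosen to exercise the asymptotics the
  statistics rely on while remaining routine on a single CPU.

# Known limitations

* BRIM with restarts is a heuristic; global optimality is only guaranteed
  where the exhaustive oracle can check it. On large graphs the sweep over
  community counts dominates runtime, which is why permutation tests accept
  a community-count cap.
* The pairwise tests measure marginal case-control association; they do not
  separate interaction effects from main effects, and with case-only block
  structure many block-adjacent pairs are genuinely associated. Interpreting
  a directed edge as synergy requires the directionality tests, not the
  overall test alone.
* The Rand index over 8 comorbidity nodes has a coarse permutation
  distribution; exact agreement (RI = 1) against 999 shuffles is the
  typical significant outcome at that scale.
* The generator's exchangeable background prevalence understates the
  heavy-tailed frequency spectrum of real comorbidity data; prevalence
  filters are exercised by construction, not by realistic rarity patterns.
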