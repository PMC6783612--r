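---
title: "Group analysis of FA-weighted structural connectomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Group analysis of FA-weighted structural connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Diffusion tractography reduces a subject's white matter to a weighted
graph: nodes are parcellated brain regions (we default to the 164 regions
of the Destrieux atlas), an edge exists wherever streamlines connect two
regions, and the edge weight is the mean fractional anisotropy (FA) of
those streamlines — a 0-to-1 proxy for tract integrity. Group studies in
neurodegenerative disease (the motivating application is amyotrophic
lateral sclerosis, ALS, versus healthy controls) then ask three
questions at three scales:

1. **Global**: is network integration reduced? (global efficiency, mean
   degree)
2. **Nodal**: which regions lose connectivity? (per-node degree, local
   efficiency, betweenness centrality, tested at two significance tiers)
3. **Network**: is there a connected subnetwork of weakened edges, and is
   the disease hub-centered? (network-based statistics, hub disruption
   index)

`connectokit` implements the full pipeline plus a synthetic cohort
generator so that every stage can be validated against planted ground
truth without access to imaging data.

## Graph metrics and their conventions

For a symmetric weighted adjacency `W` with zero diagonal:

- **degree** $k_i$ — the count of nonzero off-diagonal entries in row
  $i$. Degree is always the binary edge count, even in weighted mode:
  it answers "how many connections", not "how strong".
- **shortest paths** — in weighted mode an edge of weight $w$ has length
  $1/w$ (stronger tracts are shorter), the usual convention for
  FA-weighted connectomes; binary mode uses unit lengths. Disconnected
  pairs have infinite distance.
- **global efficiency** $E_{glob} = \frac{1}{n(n-1)} \sum_{i \ne j}
  1/d_{ij}$ with $1/\infty = 0$. Bounded by 1 on binary graphs.
- **local efficiency** $E_{loc}(i)$ — the global efficiency of the
  subgraph induced by $i$'s neighbors ($i$ excluded); nodes with fewer
  than two neighbors score 0.
- **betweenness centrality** $BC(v) = \sum_{s<t,\,s\ne v\ne t}
  \sigma_{st}(v) / \sigma_{st}$ — Brandes accumulation over unordered
  pairs, unnormalized, with equal-length ties shared via path counting.

Shortest-path machinery and betweenness are delegated to `igraph`; the
efficiency computations run on a dense Floyd–Warshall kernel in compiled
code because each subject requires 164 all-pairs problems over ~110-node
neighborhoods. The test suite checks both routes against an independent
exhaustive-enumeration oracle (all simple paths) on random graphs with up
to 8 nodes, to 1e-9.

Whether the original analyses of this kind run on weighted or binary
graphs, and whether betweenness is normalized, is typically not stated in
publications; both are exposed as `mode` options, with weighted,
unnormalized defaults.

## Hubs and the hub disruption index

A **hub** is a node whose group-mean degree lies strictly more than one
standard deviation above the across-node mean of group-mean degrees (we
use the sample SD; both the mean and the SD are over nodes, not
subjects — the rule compares a region with the spread of regions).

The **hub disruption index** $\kappa$ asks whether the most connected
regions are preferentially hit: regress the per-node difference
(subject − control-mean) on the control-mean profile across nodes; the
OLS slope is $\kappa$. A subject identical to the reference has
$\kappa = 0$; a subject scaled to $a \cdot$ reference has
$\kappa = a - 1$ exactly; uniform loss concentrated on high-degree nodes
drives $\kappa$ negative. Patients are scored against the control-group
mean profile; each control is scored against the leave-one-out mean of
the remaining controls, because regressing a subject on a reference that
contains it biases $\kappa$ toward zero. Groups are compared with a
two-sided rank-sum test.

## Network-based statistics (NBS)

With 164 nodes there are $164 \times 163 = 26732$ directed connections —
mass-univariate edge testing with Bonferroni correction has essentially
no power. NBS instead: (1) computes a two-sample statistic on every
tested edge (pooled-variance t by default, oriented control − patient so
positive values flag FA reductions in patients, one-sided by default);
(2) keeps edges with statistic ≥ a primary threshold (default 3.0,
conventional NBS practice) and finds connected components of that graph;
(3) builds a permutation null by shuffling group labels (default 5000
permutations) and recording each permutation's maximal component extent
(edge count); (4) assigns each observed component
$p_{FWER} = (1 + \#\{\text{null} \ge \text{extent}\}) / (n_{perm} + 1)$,
which is positive and valid by construction. For small cohorts the
permutation distribution can be enumerated exactly
(`method = "exact"`). An edge enters testing only if its weight is
nonzero in every subject (`edge_mask_rule = 1`), so group FA means are
always computed over identical support; the rule is relaxable.

Edges with zero pooled variance get statistic 0 when the group means
agree, and ±Inf (always supra-threshold) when constant groups differ.

For each significant component, the per-subject **NBS FA sum** — the sum
of the subject's FA over the component's edges, with absent edges
contributing 0 — is compared between groups with a rank-sum test.

Note that extent-based permutation inference is discrete: the null
maximal extent takes few integer values, so the realized family-wise
error rate sits at or below the nominal level (we observe ~0.03 at
$\alpha = 0.05$ across simulated null cohorts).

## Group and clinical statistics

Group comparisons use the unpaired Wilcoxon rank-sum test (exact for
small tie-free samples, tie-corrected normal approximation otherwise).
Nodal tests are reported at two tiers: Bonferroni $\alpha/n = 0.05/164
\approx 0.0003$ and the exploratory $1/n \approx 0.006$ threshold.
Demographics use Kruskal–Wallis (continuous) and chi-squared without
Yates correction (categorical). Clinical coupling uses the ALS
functional rating scale (ALSFRS-R, 0–48, higher = less disability) and
the disease progression rate $(48 - \text{ALSFRS-R}) / \text{duration}$
(per month). Correlations are Spearman, with fixed correction levels of
0.0125 for the two global metrics and 0.004 for nodal follow-up tests.

## The synthetic cohort generator

The generator emulates the study conditions the pipeline is meant for:
25 patients and 26 controls, 164-node symmetric FA-weighted matrices
with weights in (0, 1) and mean nodal degree ≈ 110.

**Topology.** Each node receives a connection propensity $f_i$ from a
truncated normal with mean `base_density` (110/163) and SD
`degree_spread` (0.18), and pair $(i,j)$ is connected with probability
$\min(1, f_i f_j / \text{base\_density})$, rescaled so the expected
density equals `base_density` exactly. Expected nodal degree is then
$f_i (n-1)$: mean ≈ 110 with an across-node SD ≈ 29, matching the degree
dispersion of dense tractography connectomes. A homogeneous random graph
(`degree_spread = 0`) would make hub analysis vacuous — with a flat
expected-degree profile the $\kappa$ regression has no x-variance and
hub sets are driven purely by noise — so the heterogeneous profile is the
default and the homogeneous model remains available as the degenerate
setting.

**Shared skeleton plus private edges.** Edge *presence* decomposes into
a cohort-level skeleton, drawn once and shared by all subjects
(subjects share anatomy), and a small set of *subject-private* edges:
each subject independently adds, from the non-skeleton pair pool, enough
random connections to contribute about `private_edge_rate` (default 10)
edges per node. FA *weights* are drawn independently per subject from a
truncated normal (mean 0.40, SD 0.08 — typical white-matter FA) on every
present edge. The split serves two needs at once. A fully shared
topology would make nodal degree constant within groups, so any
systematic patient effect — even a single deleted edge — would test as
arbitrarily significant against a zero-variance control group; the
private edges give degree a realistic between-subject SD of about
$\sqrt{\text{private\_edge\_rate}} \approx 3$. Conversely, a fully
independent topology at density 0.68 would leave essentially no edge
present in all 51 subjects, emptying the default NBS mask; private edges
never recur across subjects, so the mask still resolves to the skeleton.
Real cohorts of course vary topologically in richer ways — passing the
calibration tests here shows the statistics behave correctly under the
generator's assumptions, not that they were verified on realistic
anatomical variability.

**Planted effects** (all controlled by `simulation_config()`):

- *Weakened subnetwork*: a 10-edge star spanning 11 nodes (the shape of
  subnetworks typically reported by NBS analyses) whose edges lose
  `fa_effect` (default 0.15) FA in patients; these edges are forced
  present in every subject so the mask cannot exclude them.
- *Degree deficits*: each edge incident to the 6 configured deficit
  nodes is deleted with probability `edge_removal_prob` (0.15) in
  patients.
- *Hub-disruption slope*: `kappa_target` < 0 deletes every patient edge
  with probability $-\kappa$; targets > 0 add absent edges with odds
  $\kappa p / (1-p)$. Both rescale the *expected* degree profile to
  $(1+\kappa) \times$ baseline, so the planted slope is an
  expected-value construction recovered by the $\kappa$ regression.
- *Clinical coupling*: patient progression rates follow a truncated
  lognormal (mean 0.9, SD 0.9, range 0.05–4 per month) coupled to a
  configured nodal metric through a Gaussian copula. The latent
  correlation is calibrated so the *expected sample* Spearman at the
  configured group size matches `clinical_rho` (default −0.54): the
  large-sample identity $r = 2\sin(\pi\rho/6)$ is replaced by the
  normal-theory small-sample expectation of the Spearman coefficient,
  divided by the tie-correction factor of the observed (integer-valued)
  metric. ALSFRS-R is drawn as an integer from a truncated normal
  (39 ± 6, range 23–47) and the duration solved from the two, clamped to
  1–120 months.

**Randomness.** One master seed expands into named substreams (topology,
one per subject, clinical) via a 32-bit FNV-1a hash, so regeneration is
bit-identical and adding subjects never reshuffles existing ones.

## Numerical choices and degenerate inputs

- Symmetry violations up to 1e-9 are averaged away on read; larger ones
  are integrity errors, as are negative weights and nonzero diagonals.
- A constant reference profile makes $\kappa$ undefined (error), as does
  a fully tied rank-sum comparison; per-node failures inside the nodal
  table are recorded as `NA` rows rather than aborting the table.
- Hub thresholds use strict inequality, so an exactly-at-threshold node
  is not a hub and degenerate all-equal profiles yield no hubs.
- The permutation p-value estimator adds 1 to numerator and denominator;
  p = 0 is impossible and the test remains valid at any permutation
  count.
- Spearman p-values use the t approximation (`exact = FALSE`)
  throughout, appropriate at the cohort sizes involved and stable under
  ties.

## Problem sizes used by the validation suite

The test suite validates at the study's own scale (164 nodes, 25 + 26
subjects): 100 replicate cohorts per planted $\kappa$ target (recovery
within ±0.1), 200 null cohorts for the NBS family-wise error rate (500
permutations each), 50 replicates for planted-subnetwork recovery, 20
cohorts for each half of the nodal two-tier calibration, and 200
replicates for the clinical correlation. Metric implementations are
checked against the exhaustive oracle on 50 random graphs of up to 8
nodes, where enumeration of all simple paths is feasible.

## Limitations

- The generator plants effects on an otherwise exchangeable baseline; it
  does not model distance-dependent connectivity, modular/small-world
  structure, streamline counts, or acquisition artifacts.
- Printed group summaries from real cohorts constrain only the first two
  moments the generator is tuned to (density, degree dispersion, FA
  level); higher moments are unconstrained.
- The NBS primary threshold and permutation count are conventional
  defaults, not values recovered from any particular prior study; both
  are exposed in `nbs_config()`.
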