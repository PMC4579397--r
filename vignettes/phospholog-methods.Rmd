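---
title: "Boolean network training from perturbation phosphoproteomics: models, parameters and design choices"
author: "PhosphoLogic maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Boolean network training from perturbation phosphoproteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind PhosphoLogic, the
meaning and defaults of its tunable parameters, the numerical conventions
the implementation fixes where the underlying method leaves room, and what
the synthetic benchmark does and does not demonstrate.

## 1. From intensities to Boolean evidence

The pipeline assumes a perturbation screen: a panel of treatments (kinase
inhibitors, one hour scale) against a shared control, measured as
phosphopeptide ion intensities over biological and technical replicates.

**Normalization and effects.** Intensities are log2-transformed and
quantile normalized over non-missing entries (`normalizeIntensities()`).
Technical replicates are averaged within (condition, biological
replicate) — they are treated as exchangeable observations of the same
biological unit, a simplification of a duplicate-correlation adjustment
that preserves the expectation of the estimates. A linear model with a
condition factor and a biological-replicate factor is fitted across all
peptides (limma), each drug is contrasted against the control, and the
standard errors are moderated by empirical-Bayes shrinkage,
$s^2_{\text{post}} = (d_0 s_0^2 + d s^2)/(d_0 + d)$, with the prior
$(d_0, s_0^2)$ estimated across peptides from the residual variances.
P-values are Benjamini–Hochberg adjusted within each condition. A
peptide/condition estimate is kept only with at least `minObs = 2` raw
observations; peptides whose control intensity cannot be estimated are
excluded entirely.

**Booleanization.** Per peptide, univariate Gaussian mixtures with 1–9
components are fitted to the vector of per-condition effects (the control
enters as an exact zero) and the component count is selected by BIC,
using mclust's equal- and unequal-variance parameterizations. Two guards
apply:

* the component count is additionally capped at $\lfloor n/2 \rfloor$
  (but at least 2) so that no component is supported by fewer than two
  observations on average — at the 21 conditions of a full screen this
  coincides with the 9-component cap, while at a 5-condition panel it
  prevents degenerate one-point components;
* component variances are floored at `varFloor = 1e-4` (log2-FC units
  squared) as a numerical minimum, and — by default
  (`seFloor = TRUE` in `booleanizeEffects()`) — at the squared median
  moderated standard error of the peptide's effects. A fitted population
  narrower than the measurement noise is an overfitting artifact; with
  the floor in place the overlap filter removes such splits instead of
  mistaking them for well-separated states.

A peptide is *Boolean-compliant* when the selected model has exactly two
components, the control value lies in one of them, and the two densities
overlap by at most `overlapMax = 0.10`. The overlap is
$\int \min(\pi_1 f_1, \pi_2 f_2)\,dx$ by adaptive quadrature over
$\mu \pm 8\sigma$. Whether that integral should be normalized is not
fixed by the method's description; the package defaults to the *mass*
convention (divide by $\min(\pi_1, \pi_2)$, so two identical components
overlap by exactly 1 regardless of their weights) and exposes the raw
*area* convention as an option.

Each measurement of a compliant peptide receives
$S_{ij} = \log_{10} P_{ij}(C_i)/P_{ij}(P_i)$. The membership
probabilities are posterior responsibilities (mixture weights included);
a weight-free density ratio is available via `useWeights = FALSE`, since
the method's description does not fix this convention either. Scores are
clamped to $\pm 10$ against underflow. $S < -0.5$ calls the measurement
perturbed, $S > 0.5$ control, the rest undetermined; peptides mapping to
the same site ("UPID.RESPOS") sum their scores as independent evidence.

## 2. Background network

`loadKps()` filters the merged K/P-S resource: predicted interactions
need motif and context scores of at least 0.5, a configurable enzyme
blocklist removes promiscuous predictions, and duplicates collapse with
experimental evidence winning. `buildBackground()` then applies the
two-stage path construction with node-count limits of 7 (paths between
drug targets) and 5 (paths from the target component to the enzymes that
phosphorylate perturbed sites). Two conventions had to be fixed:

* "paths of up to $N$ nodes" counts protein-level nodes including both
  endpoints; the limits are arguments (`pathLimits()`) so other readings
  are reproducible;
* the construction's third step is implemented as: connect the proteins
  retained in the target stage to the enzymes with a direct K/P-S edge
  onto a perturbed data site, under the 5-node limit. (The alternative —
  a symmetric closure among those enzymes — is a strictly larger network;
  the implemented reading keeps the construction directional from drugs
  to data.)

Retained protein steps are re-expanded to sites, integrator edges bridge
each site to its host protein, and perturbed measured sites attach as
data sites. Nodes unreachable from every target are pruned; unreachable
perturbed sites are reported, and their evidence still counts as missed
perturbations during scoring, which keeps scores comparable across
backgrounds of different connectivity (this matters for the
randomized-network control below).

## 3. Sampling, simulation, scoring, weight correction

Node roles follow the network structure: drug targets are clamped roots;
measured sites without outgoing edges are sinks (exactly one upstream
kinase per model); protein nodes are integrators (one site, all sites
under an AND, or no input); remaining site nodes are intermediates
(independent per-edge inclusion, then an AND/OR gate over the included
subset — gates apply to the chosen subset, not to all background edges).
The initial bins are uniform: $1/m$ per sink input, $1/(m+2)$ per
integrator combination, inclusion probability 0.5 per intermediate edge
and 0.5 for the AND gate. For intermediates with more than two edges the
initial inclusion probability is not prescribed anywhere; the package
keeps 0.5 per edge (`interInit = "half"`), with $1/m$ as an option.

Simulation starts from the target set of a condition and sweeps
synchronously; states flip only $0 \to 1$, so all update functions are
monotone, the fixpoint is the unique least fixpoint, and synchronous and
asynchronous orders agree (property-tested on random instances).
Conditions sharing a target set share one simulation. The score of a
model sums, over conditions mapped to the simulated target set and over
measured sites: $S_{ij}$ if the site is predicted perturbed, $-S_{ij}$
if a negative-$S$ site is missed, nothing otherwise — true negatives are
deliberately ignored because discovery data are expected to be dominated
by unperturbed measurements. `sizeP` adds an additive penalty of
`sizeP` per selected edge; the method's description prints the values 0
and 1 for this setting without defining its functional form, so the
per-edge additive reading is a declared interpretation.

The best family is $\{m : s_m \le s^* + \text{tol} \cdot |s^*|\}$ — a
fractional band around the best score $s^*$, which can be negative; an
absolute-offset variant would be trivial to substitute. Weight
correction recomputes counts from the current generation's best-family
frequencies, `count = 1 + freq × cap`, normalized per node; the AND-gate
probability is averaged with its best-family frequency. The
non-compounding form exactly reproduces both published worked updates
((2/6, 1/6, 2/6, 1/6) for the integrator and (0.75, 0.25) for the sink at
cap 2); a compounding mode (`compound = TRUE`) accumulates counts across
generations instead. Note a structural consequence of non-compounding
updates: a two-option node's top sampling frequency equilibrates at
$(1+\text{cap})/(2+\text{cap})$, never at 1 — concentration is bounded
by the cap, which is exactly its role.

Training stops when the population mean score moves by less than
$0.01 \cdot |s^*|$ *and* every population edge frequency by less than
0.01 for three consecutive generations, or at the generation cap
(default 50, by which published runs had stabilized). Independent runs
(default 3) use sub-seeds derived deterministically from the master seed,
so results are independent of execution order; their final-population
frequencies are averaged, and the consensus network keeps, per node, all
input combinations within `consensus_tol` (default 20%) of the node's
maximum frequency — `tol = 0` is the majority-voting model with
deterministic tie-breaking by node id then combination key.

### Parameter defaults

| parameter | default | meaning |
|---|---|---|
| `n` | 5000 | models sampled per generation |
| `cap` | 5 (alt. printed setting: 20) | virtual-copy ceiling per unit frequency |
| `tolBest` | 0.30 (alt.: 0.15) | fractional best-family band |
| `sizeP` | 1 (alt.: 0) | per-edge size penalty |
| `generations` | 50 | generation cap |
| `nRuns` | 3 | independent optimizations combined |
| `consensusTol` | 0.20 | consensus frequency band |
| overlap ceiling | 0.10 | Boolean-compliance filter |
| $S$ cut | 0.5 | perturbed/control dead zone |
| prediction score cut | 0.5 | NetworKIN-style motif/context filter |
| path limits | 7 / 5 nodes | background construction |

## 4. The synthetic benchmark

`generateTruth()` builds a random K/P-S resource (each site draws 1–5
candidate upstream kinases; hosts are kinases with probability 0.25,
matching the minority of phosphosites that sit on kinases/phosphatases in
curated resources, substrate-only proteins otherwise; cycles allowed),
plants a logic model, assigns one hub-biased target per drug (inhibitor
panels target well-connected kinases; targets are drawn with
out-degree-squared weights), and derives each drug's perturbed sites by
simulating the planted model. Three deliberate choices:

* **Planted model style.** By default every non-root node receives a
  single uniformly chosen input (`truthStyle = "single"`). Drawing the
  truth from the untrained sampler instead (`"sampler"`) plants inactive
  nodes and many-input gates; single-perturbation designs provably cannot
  discriminate most of those (complex gates rarely concentrate without
  combination treatments), so the single-input truth represents the
  dominant-kinase regulation that this experimental design can actually
  identify. The sampler mode remains available and is used where the
  analytic random-consensus baseline $\sum_c p_c^2$ is wanted exactly.
* **Detectable footprints.** The planted model is redrawn (bounded
  retries, then target resampling) until every drug perturbs at least
  `minSitesPerDrug = 5` sites. The benchmark emulates inhibitors with a
  clearly detectable effect — the regime in which network training is
  scientifically meaningful; a drug that moves nothing constrains
  nothing.
* **Background bulk.** `simulateDataset()` adds `nBackground = 400`
  never-perturbed peptides on proteins outside the resource. A discovery
  screen measures mostly-unaffected peptides; without this bulk,
  quantile normalization at 50 peptides would be visibly distorted by
  the perturbed minority. Replicate noise decomposes as biological sd =
  2 × technical sd with total `sigma = 0.3` (log2 units); the planted
  shift is `delta = 5` downward (inhibition decreases phosphorylation;
  the sign is configurable).

What the generator does *not* emulate: intensity-dependent missingness
and undersampling (only a uniform missing-at-random rate), correlated
off-target drug effects, multiply-phosphorylated peptide ions, and
kinase-activity rewiring beyond Boolean propagation. Passing benchmarks
therefore demonstrate the correctness and identifiability behaviour of
the algorithmic pipeline under its own model assumptions, not performance
on real screens.

**Recovery metric.** `recoveryMetrics()` scores, per node, whether the
maximum-frequency input combination recovers the planted one. Two
combinations that propagate perturbations identically under every
assayed condition (two kinases active under exactly the same drugs; an
AND over always-co-active sites) cannot be distinguished by any method
from these data. The default metric therefore counts a top input as
recovered when substituting it into the planted model leaves every
condition's prediction unchanged — recovery up to observational
equivalence, the resolution limit of the design, analogous to scoring
structure learning up to Markov equivalence. Strict key equality is
reported alongside (`strictAccuracy`) and available via
`equivalence = FALSE`.

**Target-discrimination control.** `targetControlExperiment()` retrains
the same evidence with (i) the true network and target, (ii) enzyme-
shuffled networks (substrate side and degree structure untouched), and
(iii) the true network with a *viable decoy* target — an enzyme that can
still reach at least 80% of the focal sites' direct kinases but is
maximally distant from them, mirroring the published control in which the
decoy explained the data only through paths roughly twice as long.
Settings whose background construction fails score as the empty model
(full false-negative penalty). When no viable decoy exists the experiment
is refused as ill-posed rather than run against an unreachable strawman.

## 5. Problem sizes and budgets used in the shipped tests

The shipped test suite runs the full benchmark at 20 kinases / 50 sites /
4 drugs with populations of 500 models for 20 generations and 3 combined
runs — small enough to re-run interactively, large enough for the
selection dynamics to concentrate — and
the control experiment on the first drug of the same panel; exhaustive
enumeration oracles run on backgrounds with at most 12 candidate
combinations. The training engine itself is vectorized over the sampled
population (one state matrix per target set per sweep), which is what
makes these sizes interactive; full-scale runs (n = 5000, 50 generations,
hundreds of nodes) use the same code path.

## 6. Known limitations

* Inhibitory logic and multi-level states (control/up/down) are out of
  scope; evidence direction enters only through $S_{ij}$.
* At few conditions (4–5 effect values per peptide) mixture selection is
  weakly determined even with the safeguards above; expect a minority of
  spurious or missed compliance calls, which the evidence weighting
  partially absorbs.
* Non-identifiable regions of dense backgrounds remain mixed in the
  consensus (that is a feature of the output, made visible by the
  tolerance band, not resolved by the trainer).
* The intermediate-node inclusion update normalizes counts across a
  node's edges; for single-edge intermediates this drives the inclusion
  probability to 1 after the first correction, removing the "no edge"
  option — consistent with the published two-edge update rule, but worth
  knowing when interpreting single-edge relay frequencies.
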