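# PhosphoLogic

Boolean logic models of signal propagation trained on discovery
phosphoproteomics perturbation screens.

## The problem

Shotgun phospho-MS screens measure thousands of phosphopeptides across a
panel of kinase-inhibitor treatments, but the output is a flat list of
regulated sites. PhosphoLogic reconstructs *how* each inhibition reaches
each site: it places the data in the context of known and predicted
kinase/phosphatase–substrate (K/P-S) interactions, builds the network of
knowledge-compatible paths from the drug targets to the perturbed sites,
and trains Boolean logic models of perturbation flow against the data.
It is aimed at computational biologists analysing perturbation
phosphoproteomics panels (inhibitor screens, ligand stimulations) who want
mechanistic, site-resolved hypotheses rather than hit lists.

## The method

1. **Perturbation scoring.** Raw peak heights are log2-transformed and
   quantile normalized; a linear model with empirical-Bayes moderated
   standard errors (limma) estimates each treatment's log fold change per
   peptide, with Benjamini–Hochberg correction per condition. A Gaussian
   mixture model (mclust, 1–9 components, BIC-selected) is fitted per
   peptide across conditions; peptides best described by two populations —
   a control and a perturbed state, overlapping by at most 10% — are kept,
   and each measurement receives the evidence score

   *S*<sub>ij</sub> = log₁₀ *P*<sub>ij</sub>(C<sub>i</sub>) / *P*<sub>ij</sub>(P<sub>i</sub>),

   the log-ratio of its control vs perturbed membership probability.
   *S*<sub>ij</sub> < −0.5 calls the site perturbed, > 0.5 control,
   in between undetermined. Peptides mapping to one site sum their scores
   as independent evidence.
2. **Background network.** The K/P-S resource (score-filtered predictions,
   de-duplicated, optional manual augmentation) is searched for
   protein-level paths connecting the drug targets (≤ 7 nodes) and linking
   the target component to the enzymes that phosphorylate perturbed sites
   (≤ 5 nodes). Retained protein steps are re-expanded to the site level,
   with *integrator edges* bridging each site to its host protein, and the
   perturbed sites attached as data sinks.
3. **Training.** Candidate models are sampled per node (sinks draw one
   kinase; integrators one site, all sites under an AND, or nothing;
   intermediate sites draw each edge independently plus an AND/OR gate),
   simulated to their monotone Boolean fixpoint under every distinct
   target set, and scored: predicted perturbations add *S*<sub>ij</sub>
   (negative = reward), missed perturbations add |*S*<sub>ij</sub>|, true
   negatives are ignored. A best-scoring family is selected within a
   tolerance of the optimum and the sampling weights are corrected by
   capped virtual copying (`count = 1 + frequency × cap`). Edge
   frequencies from several independent runs are averaged and reported as
   a consensus network in Cytoscape-ready flat files.

A synthetic-data module generates ground-truth networks, planted logic
models and replicated noisy screens with the same file schemas, enabling
end-to-end benchmarking (parameter recovery, target-discrimination
controls) without any external data.

## Worked example

A full run on a synthetic benchmark: 20 kinases, 50 phosphosites, a
4-inhibitor panel with planted ground truth, 2 biological × 3 technical
replicates.

```r
library(PhosphoLogic)

truth  <- generateTruth(nKp = 20, nSites = 50, nDrugs = 4, seed = 1)
screen <- normalizeIntensities(simulateDataset(truth, seed = 101))
effects <- fitEffects(screen)
bool    <- booleanizeEffects(effects)
bool$smatrix
#> SMatrix: 450 peptides x 5 conditions; 40 Boolean-compliant peptides
#>   sites: 40 | perturbed in >=1 condition: 40

kps <- loadKps(truth@kps)
bg  <- buildBackground(kps, targets = unique(unlist(truth@panel)),
                       perturbed = perturbedSites(bool$smatrix))
#> 2 perturbed site(s) unreachable from targets
bg
#> BackgroundNetwork: 55 nodes, 126 edges
#>    data_site: 38, kp: 11, site: 2, target_kp: 4
#>   targets: KP14, KP11, KP01, KP09

params <- trainingParams(n = 500, generations = 20, nRuns = 3,
                         cap = 20, tolBest = 0.15, sizeP = 0)
fit <- trainModels(bg, bool$smatrix, truth@panel, params, seed = 2024)
fit$runs[[1]]
#> TrainingResult: 20 generations (n = 500 models each)
#>   mean score: 318.07 -> -131.67 | best: -330.85

consensusNetwork(fit$freqs, bg, tol = 0.2)
#> ConsensusNetwork: 53 nodes, 50 edges (tolerance 0.2)

recoveryMetrics(fit$freqs, truth, bg)[c("accuracy", "precision", "recall")]
#> $accuracy   [1] 0.9411765
#> $precision  [1] 0.86
#> $recall     [1] 0.8431373
```

Reading the numbers: of 450 simulated peptide ions (50 planted sites plus
unaffected background), 40 show the two-population behaviour the Boolean
assumption requires and are scored. The background network connects the
four drug targets to 38 of the 40 perturbed sites. Training drives the
population mean score from +318 (uninformed) to −132; the consensus
network recovers the planted input of 94% of nodes (up to observational
equivalence), with edge precision 0.86 and recall 0.84 against the planted
model.

The same workflow runs from the command line over TSV/SIF flat files:

```sh
inst/scripts/phospholog synth --outdir run1 --seed 1
inst/scripts/phospholog all   --outdir run1 --seed 1
```

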