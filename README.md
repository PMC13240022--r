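# regfate

Linking terminal single-cell states to state-specific transcription-factor
regulatory networks — and carrying the state programs forward to
patient-level survival.

Tumours such as hepatocellular carcinoma contain malignant cells spread
along a differentiation continuum that converges on a few terminal states
(e.g. immune-activated, metabolic and proliferative hepatocytes). Given the
usual upstream artefacts — a normalized expression matrix, per-cell state
assignments with a 2-D embedding, regulon definitions (a TF with its target
genes), and per-fate fate-driving gene tables with FDR values — `regfate`
answers, with tested code: *which regulons are specifically active in each
terminal state, how are they organized into co-activity modules, which
regulatory nodes form the core of each state's network, and does the
aggressive state's TF signature predict survival in a bulk cohort?*

The package is organized as an analysis workflow: every computation lives in
exported functions under `R/`, and the numbered scripts under `analysis/`
are thin narrative drivers that run the stages in order and write their
tables under `results/`.

## What it computes

* **Activity** — per-cell gene-set scores as the area under the recovery
  curve of the set within the top fraction *f* (default 0.05) of each
  cell's expression ranking, normalized so 1 is attainable; rank-based and
  invariant to monotone transforms.
* **Regulon specificity (RSS)** — `1 − JSD(P^R ‖ P^C)` with base-2 logs,
  where `P^R` is the regulon's activity normalized over cells and `P^C`
  the uniform indicator of the state.
* **Co-activity specificity (CSI)** — for a pair (A, B), the fraction of
  the other N−2 regulons *i* with `PCC(A,i) < PCC(A,B)` or
  `PCC(B,i) < PCC(A,B)`; modules are cut (default 7) from average-linkage
  clustering on `1 − CSI`.
* **State-specific regulons** — per-cell z > 1.5 in the state plus
  one-sided rank-sum p < 0.05 versus the rest, one state per regulon.
* **Fate networks and CoreScore** — selected regulon targets intersected
  with sub-0.05-FDR fate drivers; in/out-degree, betweenness, closeness and
  clustering are z-scored and averaged into a CoreScore, with the top 30%
  of nodes flagged core.
* **Clinical signature** — mean gene-wise z-score of the fate network's
  TFs per patient; quartile stratification with a Q4-vs-Q1 log-rank test,
  and Cox proportional-hazards models (per-SD hazard ratios, optional
  stage + age adjustment).
* **Integration QC** — per-cell batch-mixing and tissue-separation scores
  from the 30 nearest embedding neighbours.
* **Synthetic data** — a generator that plants state-specific regulons,
  hub TFs, driver overlap and a survival effect, so every stage is tested
  against known truth.

## Worked example

The six analysis stages run in order from the repository root:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_integration_qc.R
Rscript analysis/03_regulon_activity.R
Rscript analysis/04_modules.R
Rscript analysis/05_state_networks.R
Rscript analysis/06_signature_survival.R
```

Printed output (abridged) and what it means:

```
cells: 3000  genes: 1000  regulons: 100 (planted 30)
mean batch mixing: 0.749 (well-mixed expectation 0.75)
most specific regulon per state:
  fate0: g0002 (RSS 0.969)
  fate1: g0011 (RSS 0.962)
  fate2: g0021 (RSS 0.954)
mean CSI within modules: 0.888; between modules: 0.600
selected state-specific regulons per state:
fate0 fate1 fate2
    0     0     8
precision vs planted truth: 1.000; recall: 0.267
fate2: 102 nodes, 128 edges, 31 core, top TFs: g0021
signature: 8 TFs (g0021, g0022, g0027, g0025...)
Q4 vs Q1 log-rank: chi-square 62.17, p = 3.14e-15
univariable HR per SD of signature: 1.85 (95% CI 1.62-2.10, p = 8.86e-21)
signature vs stage (Kruskal-Wallis): chi-square 0.57, p = 0.902
```

The batch-mixing mean sits at the (S−1)/S expectation for four well-mixed
samples; each planted regulon is most specific to its home state; CSI
blocks are tight within modules. Selection recovers only the smallest
state's regulons — that is a structural property, not a bug: the mean
per-cell z inside a state holding proportion *p* of cells cannot exceed
√((1−p)/p), so a 1.5 threshold is attainable only for states under ~31% of
cells (see the methods vignette). Everything selected is genuinely planted
(precision 1.0). The fate2 network's TF signature then recovers the
planted survival effect in the bulk cohort with an HR of 1.85 per SD and a
strongly separated Q4-vs-Q1 comparison, while showing no stage association
(none was planted).

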