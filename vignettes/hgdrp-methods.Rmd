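---
title: "Heterogeneous-graph drug response prediction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heterogeneous-graph drug response prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Phenotype-based screening measures how strongly a drug suppresses a cell
line (an lnIC50 value per drug-cell pair) without saying *why*; target-based
data (drug-target interactions, pathways, GO annotations, protein-protein
interactions) says what a drug touches without saying what happens to a
cell.  `hgdrp` joins the two worlds in a single heterogeneous biomedical
graph (the *BioHG*) over five node types -- drugs, proteins, cell lines,
pathways, GO terms -- and trains one multi-task graph neural network whose
learned representations serve four downstream tasks: drug response
prediction under warm and cold-start scenarios, drug-target
prioritization, zero-shot phenotypic screening, and mechanism-of-action
analysis.

# The graph

Five edge types are admitted, and only five:

| edge type         | endpoints              | weight |
|-------------------|------------------------|--------|
| `dti`             | drug -> protein        | none   |
| `ppi`             | protein -- protein     | none   |
| `protein_pathway` | protein -> pathway     | none   |
| `protein_go`      | protein -> GO term     | none   |
| `protein_cell`    | protein -> cell line   | expression value |

Two design rules carry the science.  First, **drugs and cell lines are
never adjacent**: every predictive path between a drug and a cell line is
forced through the protein layer, so the network information is what links
pharmacology to phenotype.  Second, protein-cell edges are **derived from
expression**: a cell line is connected to exactly those proteins whose
expression is *strictly greater* than that cell line's mean expression
(ties at the mean produce no edge; a constant expression row produces no
edges and a warning).  The expression value is stored as the edge weight,
but message passing never reads it -- the weights exist solely so that the
training-sample generator can pose expression-comparison questions.  A test
asserts that perturbing the weights leaves every embedding bit-identical.

PPI edges are undirected and stored once in a canonical orientation;
rebuilding a graph from the same tables is byte-identical, which the suite
checks on the serialized archive.  Gene-to-protein mapping is an explicit
two-column table; unmapped expression columns are dropped and counted.
Node IDs are opaque strings -- no identifier-namespace validation is
attempted.

# Message passing

Each layer updates protein, pathway and GO nodes as the **sum of
per-edge-type convolutions**.  For the `ppi`, `protein_pathway`,
`protein_go` and (reversed) `dti` relations the convolution is
GraphSAGE-style,

$$h'_v = \sigma\!\big(W \cdot \mathrm{CONCAT}(h_v,\;
  \mathrm{Aggregate}\{h_u : u \in N(v)\})\big),$$

with a mean aggregator by default (`sum` and elementwise-max `pool` are
available; `pool` is forward-only because the training engine restricts
itself to aggregators with sparse linear adjoints).  For the
expression-derived `protein_cell` relation the convolution is a GCN with
symmetric degree normalization,

$$h'_i = \sigma\Big(W \sum_{j \in N(i)}
  \tfrac{1}{\sqrt{\deg i \,\deg j}}\, h_j\Big).$$

An empty neighborhood aggregates to the zero vector, so the SAGE update
degenerates gracefully to a transform of the self embedding, and an
isolated GCN destination receives zero before the activation.  Both layer
types are verified against dense per-node loop oracles to 1e-6 on batteries
of random graphs.

Drug and cell-line nodes **emit messages but are never updated**.  A drug's
representation is a learned linear map of its 1024-bit circular
fingerprint, $h_{drug} = x_{drug} W_{drug}$ (no bias, no activation) --
this is the cold-start path: a compound with no edges anywhere in the graph
is still representable, and the suite scores such a drug end-to-end.  A
cell line's representation is a learned linear projection of its expression
profile; expression enters the encoder z-scored per gene (constant genes
map to zero), which keeps the projection's scale independent of the
original measurement units.  Drug-to-protein messages along `dti` edges are
on by default (`drug_messages = FALSE` disables them, confining drug
information to the interaction loss).

Because graph convolution, gather/scatter and the MLP heads all need exact
gradients and no deep-learning framework is part of this package's
dependency footprint, `hgdrp` carries a small reverse-mode automatic
differentiation engine over dense matrices (`R/tape.R`): nodes record a
value and a pullback closure, creation order is the topological order, and
sparse aggregation operators participate as constants with precomputed
transposes.  It supports exactly the operations the model needs and its
gradients are tested against central finite differences.

# Training samples

Two ideas shape the sample streams.

**Comparison instead of regression.**  Response and expression values vary
with assay conditions, so absolute values are unreliable labels.  Both
streams are therefore reformulated as within-context pairwise comparisons:
a triple (entity A, cell line, entity B) is labeled 1 exactly when A's
value strictly exceeds B's in that cell line.  Ties are excluded; the
expression stream additionally drops pairs closer than a margin (default
0.1 on the expression scale) to absorb assay noise, while response
comparisons use margin 0.  Labels are anti-symmetric by construction, which
is property-tested.

**Network-distance negative sampling.**  Binary classification streams for
drug-target and protein-pathway interactions take the existing edges as
positives.  Negatives for an anchor are partner proteins at shortest-path
distance at least `d_min` over the union of the pair's own edge type and
the PPI network; unreachable proteins qualify.  `d_min` defaults to 3,
which excludes direct partners and shared-neighbor proteins; since no
single radius is canonical for "far from the anchor", it is exposed as a
parameter.  Every sampled negative is checked against a Floyd-Warshall
oracle in the acceptance suite.  The negative:positive ratio defaults to
1:1.

Per-epoch stream sizes are hyperparameters.  By default the subsample is
drawn once per run; `resample_each_epoch = TRUE` redraws it every epoch,
which acts as a regularizer for the interaction heads and is what the
desk-scale configurations use.

# Optimization

Stage 1 minimizes
$w_{pc}\,\ell_{pc} + w_{dc}\,\ell_{dc} + w_{dpi}\,\ell_{dpi} +
w_{pro\_path}\,\ell_{pro\_path}$, all four terms numerically stabilized
mean binary cross-entropies, with Adam (weight decay folded into the
gradient).  All weights default to 1; they are tunable, and the
hyperparameter search space covers them.  Early stopping monitors the
validation rank
correlation (SCC) of the response task; during stage 1 the pairwise
comparator is turned into a per-pair score by its mean win probability
against a fixed panel of reference drugs.  A warm-up period
(`min_epochs`, default 50) keeps the noisy early phase of a full-batch run
from triggering the patience rule; the best checkpoint is still tracked
from epoch 1, and early stopping can never return a later-than-best
checkpoint.

Stage 2 freezes the embeddings and fits the scalar response head --
a regressor on the lnIC50 scale for evaluation, or a classifier on labels
`lnIC50 < -2` for screening.  The two-stage design resolves the tension
between training on comparisons and reporting RMSE on values; a `joint`
flag trains the regressor in-loop for ablation.  Hyperparameter search is
a seeded random search over a declared discrete space; the interface is
engine-agnostic (any sequential model-based optimizer can drive the same
objective), and the objective is the validation SCC.

Field-standard defaults are kept where this modeling family has settled
ones: learning rate 0.001, weight decay 1e-6, Adam, 20-fold
cross-validation.  The desk-scale runs in
the tests and the acceptance script use `lr = 0.01` with full-batch
updates, 150 epochs, and capped streams (2000 expression + 2500 response
comparisons) -- full-batch gradients are low-variance, so the larger step
is stable and reaches the same plateau in far fewer epochs.

# Evaluation scenarios

`make_splits()` builds 20-fold (default) cross-validation under four
scenarios: `warm` partitions the (drug, cell) pairs; `cold_cell` and
`cold_drug` partition the cell-line or drug IDs; `cold_both` partitions
both independently, takes as test the pairs with *both* coordinates held
out, excludes from training every pair touching a held-out ID, and uses the
remaining mixed pairs in neither role (a necessary consequence of the two
independent partitions).  Leakage checks run as assertions on every
generated fold set.  For cold evaluation the training graph is also
restricted: held-out drugs lose their `dti` edges and held-out cells their
`protein_cell` edges, so nothing about a cold entity reaches the model
except its fingerprint or expression profile.  Metrics are RMSE, Pearson
and Spearman correlation; zero-variance correlations are reported as
missing rather than zero.  Fold aggregation is mean plus standard error.

Target prioritization scores every candidate protein per drug with the DTI
head, ranks with a deterministic tie-break by protein ID, and reports
pooled recall at fractional cutoffs (3% and 10% by default); per-drug
macro recall sits behind a flag.  The external-cohort mode emulates a
xenograft transfer: unseen models drawn from the same generative process,
expression z-scored per gene, responses as log10 IC50 clamped to [-10, 10],
and PCC/SCC reported per cohort model and per drug with groups smaller
than 3 skipped.  Zero-shot screening selects drugs whose classifier score
exceeds 0.5 on *every* case sample and stays below 0.5 on *every* control
sample.

# Interpretation

Integrated gradients attribute a classifier output to input features via
the m-step left-point Riemann approximation of the path integral from a
baseline x' (all-zeros by default, feature-means optionally) to x.  The
completeness residual |sum(attributions) - (F(x) - F(x'))| is recorded on
every call; it is exactly zero for linear models and shrinks as m grows,
both of which are asserted, with the residual at m = 500 under 1% of the
output change on a trained classifier.

Mechanism analysis takes a drug's top-k predicted targets, builds the
subgraph induced by *all* shortest paths from any target to a sink gene
over the PPI and DTI networks, and ranks the interior nodes by exact
(Brandes) betweenness centrality -- unnormalized by default, matching the
raw definition, with ties broken by node ID.  GO-frequency tables count
`protein_go` annotations among the top targets; pathway tables rank
pathways by the mean biological-process-head score against those targets.

# The synthetic world

Real counterparts of the data this method was built for (drug-sensitivity
panels, interaction databases, pathway collections, xenograft cohorts) are
large external resources, so the package ships a seeded generator that
emulates their statistical structure with planted ground truth:

* proteins live in a latent function space clustered by pathway; GO terms
  are a second, coarser clustering;
* PPI edges preferentially connect latent-similar proteins;
* each drug anchors to a pathway and targets `dti_per_drug` (default 3)
  latent-coherent proteins near its anchor; its binary fingerprint is
  hashed from the anchor direction through a fixed random projection with
  2% bit noise, so fingerprints carry a learnable signal about targets --
  the property the cold-start transform depends on;
* cell expression is nonnegative per-cell pathway activity (Gamma(2,1))
  times a per-gene sensitivity, plus Gaussian noise (sd 0.3);
* the response of drug d in cell c is
  `-1.5 * mean(activity of the target pathways) + noise` on an lnIC50-like
  scale -- lower means more sensitive, matching screening-panel semantics.

The standard fixture is 50 drugs x 200 proteins x 30 cell lines x 10
pathways x 20 GO terms with response noise 0.3; at these settings the
per-cell Spearman correlation between planted overlap and generated
response exceeds 0.8 in magnitude in every cell, so learnable signal is
guaranteed without being trivial.  With zero noise the response is an exact
function of the planted structure and ranking by overlap reproduces ranking
by response.  An `infection` flag plants a perturbed cell subset (a
signature pathway shifted from near-zero activity to high activity) plus an
"antiviral" drug subset anchored to that pathway, which exercises the
zero-shot screening pipeline end to end; screened cells keep their
expression edges in the graph but contribute no response rows, mirroring
how an infected expression profile would be integrated.

What the generator does **not** emulate: heavy-tailed degree distributions
of curated interactomes, batch effects and dropout in expression assays,
measurement-scale disagreements between laboratories beyond a global
log-transform, or chemical-series structure among fingerprints.  Passing
tests on this world demonstrates that the machinery learns and ranks what
it was designed to learn and rank when the planted signal exists; it does
not certify effect sizes on any real panel.

# Problem sizes and numerical choices

The test suite and the acceptance script run everything at desk scale:
embedding width 16, two layers, head width 64, one evaluated fold per
scenario, five seeds for the stochastic checks, 150 (response) or 120
(screening) epochs.  Layer-oracle, metric and betweenness comparisons use
tolerances of 1e-6, 1e-10 and 1e-10 respectively; the autodiff engine is
checked against central finite differences at 1e-6.  Degenerate inputs have
defined behavior throughout: empty neighborhoods aggregate to zero,
constant expression rows yield no edges plus a warning, all-tied metric
inputs yield missing values, anchors without distant-enough negatives are
skipped with a warning, and a divergent loss aborts training naming the
offending stream and the last finite epoch.

# Known limitations

* The engine is CPU-only and full-batch; graphs beyond ~10^4 nodes would
  need minibatched neighborhoods and a compiled backend.
* `pool` aggregation has no training path.
* The stage-1 validation score (comparator win rate against a reference
  panel) is a proxy for the stage-2 regressor's SCC; with very few drugs
  per cell the proxy gets noisy, which is why the desk configurations keep
  a warm-up period before early stopping.
* Negative sampling treats the graph as ground truth: a true-but-unrecorded
  interaction at distance >= `d_min` can be drawn as a negative, exactly as
  with the real databases.
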