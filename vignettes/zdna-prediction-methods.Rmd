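---
title: "Methods: nucleotide-resolution Z-DNA prediction from sequence and omics tracks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nucleotide-resolution Z-DNA prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model and its assumptions

`zdnascan` treats Z-DNA prediction as per-nucleotide segmentation rather
than per-window classification. The assumption behind this framing is that
mapped Z-DNA elements are rare as *regions* but, at a mean length of
roughly 400 nt, plentiful as *nucleotides*: each region contributes
hundreds of minor-class examples, enough to train neural models, at the
cost of a nucleotide-level class imbalance of roughly 1 in 50. All
model selection and evaluation therefore uses imbalance-robust metrics
(ROC AUC by rank statistic with midrank ties, and F1).

The second assumption is that sequence alone under-determines functional
Z-DNA. The input representation therefore concatenates, per chromosome,
three channel families:

* **Sequence** — one-hot A/C/G/T (4 channels). Ambiguity codes (N and the
  other IUPAC letters) become all-zero columns rather than a fifth
  channel; this keeps the channel count fixed and treats unknown bases as
  uninformative.
* **Energetics** — a per-nucleotide dinucleotide B–Z transition-energy
  channel (position *i* carries the energy of step *(i, i+1)*, the final
  position repeats its predecessor) plus two constant channels carrying
  the B–Z and Z–Z junction energies. Steps containing an ambiguous base
  get the table maximum, i.e. the least Z-favourable energy. The energy
  table is a TSV configuration input
  (`inst/extdata/zhunt_energy.tsv`); the shipped values are
  literature-anchored defaults (alternating CG/GC 0.7 kcal/mol, CA/TG and
  AC/GT 1.3, TA 2.5, graded penalties out of alternation; junctions 5.0
  and 4.0 kcal/mol) and can be replaced wholesale by editing the file.
* **Markers** — one binary channel per omics marker (histone mark, TF,
  RNA polymerase, DNase), aggregated across tissues by set union
  ("present in any tissue"). An optional blacklist BED is subtracted
  from every marker before encoding.

Every channel is min–max scaled to [0, 1] per chromosome. A constant
channel maps to all zeros (the 0/0 case); note this means the two constant
junction channels are zero after scaling — they are carried for interface
completeness and become informative only when a user supplies per-region
energy tracks. Channels are stored as run-length encoded sparse tracks
(`sparse_track`), which is exact for binary and scaled tracks and keeps a
genome-scale 1000-channel matrix within memory; dense windows are
materialised on demand.

## Architectures and training

Models are assembled from a block grammar: an optional convolutional
block (1–2 layers of 1-d convolutions, kernel size and kernel count 1–17,
stride 1, `(k-1)/2` zero padding so length is preserved, a rectifier
between consecutive conv layers), an optional recurrent block (1–2 LSTM
layers, optionally bidirectional with concatenated directions), and
exactly one terminal dense block applied position-wise, with dropout
(default probability 0.5) on the input of every dense layer and a final
two-unit softmax whose class-1 probability is the reported score. Valid
orders are conv → recurrent → dense. The per-position max over kernels
("channel pooling") is available as an opt-in flag on the conv block but
is off by default: it collapses the block to one channel, and the
reference architectures we exercise are described without it. Length
pooling is never used — it would break the segmentation contract that
output length equals input length.

Training minimises per-nucleotide two-class cross-entropy with RMSprop
(decay 0.9, epsilon 1e-8), computing each gradient on a batch of whole
windows. The engine (forward, backward, and input gradients for all three
block types) is implemented in the package and verified against finite
differences in the test suite. Defaults are 40 epochs, batch 8 windows,
learning rate 2e-3: with desk-scale window sets (tens of windows) an
RMSprop-normalised step moves each weight by about the learning rate per
update, so a useful fit needs a few hundred updates; smaller batches and
slightly larger steps achieve that without changing the optimiser. All
three values are `zdna_control()` parameters. Randomness (initialisation,
shuffling, dropout, background-window sampling, splits and folds) flows
from explicit integer seeds, making fits bit-reproducible.

Optional L1 regularisation is implemented as a proximal soft-threshold
applied inside the RMSprop update (scaled like the step itself, weights
only, biases exempt) rather than as a loss subgradient. The proximal form
drives unnecessary weights to *exact* zero, which the feature-pruning
step of interpretation depends on; a subgradient implementation merely
oscillates weights near zero and never certifies a pruned feature.

## Windowing, splits, annotation

Chromosomes are tiled into fixed windows (default 5000 nt) whose
boundaries never depend on label positions; trailing partial windows are
dropped. The training universe is every window containing a labelled
nucleotide plus a background of label-free windows sampled genome-wide
without replacement at 3:1 (both defaults configurable). The train/test
split is stratified by (chromosome, label presence) at 4:1, with
per-stratum test size `round(n/5)` and strata smaller than two windows
going wholly to train. Cross-validation folds (default 5) are assigned
cyclically within each stratum with the cycle counter carried across
strata, so global fold sizes differ by at most one while each stratum
spreads as evenly as possible.

Whole-genome annotation trains one model per fold on the other folds'
windows, has every model predict the full genome, and averages the five
probability tracks arithmetically. The operating threshold is chosen from
the finite set of observed probability values as the F1 maximiser (ties
to the smallest candidate); candidates are evaluated with
`probability >= t`, while region assembly — following the strict reading
of "more than the threshold" — uses `probability > t`. For continuous
tracks the discrepancy is confined to exact ties at the threshold value
and is immaterial; the shipped default threshold 0.343 in `zdna_config()`
is the published genome-scale instance of this selection and applies when
no labels are available to re-select. Assembly then joins runs separated
by gaps strictly smaller than 11 bp and drops joined calls strictly
shorter than 11 bp — one helix turn; a gap of exactly 11 bp stays split
and a call of exactly 11 bp is kept. The length filter runs after
joining, so fragments that only jointly reach 11 bp survive. Two
annotations are combined by union, merging intervals closer than 10 bp.
Chromosome ends never join across chromosomes. Assembly is verified
against a dense O(L) interval-scan oracle and is idempotent on its own
re-encoded output.

Convolutional models are evaluated genome-wide in chunks with an overlap
equal to the receptive-field half-width, so chunked and single-pass
predictions are bit-identical; recurrent models have unbounded context
and are evaluated in a single pass per chromosome.

## Interpretation

Feature importance trains a CNN-only model (recurrent architectures are
rejected: their context is unbounded and their first layer carries no
per-feature locality) with the L1 pair (1e-3 on the first convolutional
layer, 1e-2 elsewhere; both configurable, either order runnable). Each
input channel is scored by its largest-magnitude first-layer weight, sign
preserved; channels whose first-layer weights are all exactly zero are
dropped as pruned. Scores are normalised per sign group — positives by
the largest positive weight, negatives by the magnitude of the most
negative — so each sign group tops out at ±1. This is one of two
defensible readings of per-sign normalisation; it keeps the two signs
separately comparable.

The saliency step maximises the predicted Z-DNA probability of the
central nucleotide of a trainable input patch whose width is the model's
receptive field (9 nt for the two kernel-5 layers: the outermost
second-layer tap reaches 2 positions, plus 2 more through the first
layer, on each side). The patch is ascended with RMSprop at learning rate
1e-2 and clipped to [−1, 1] after every iteration — the extended range
(data live in [0, 1]) lets negatively influencing features express
themselves. The best-so-far patch is returned with a convergence flag.

Sequence channels cannot be maximised independently (the four values at a
position jointly encode one base), so the motif is found by a separate
constrained maximisation over the sequence channels only: each position's
four values are restricted to the probability simplex, with non-sequence
channels held fixed at the unconstrained optimum (configurable to zero).
The solver is projected gradient ascent with steps normalised by the
largest gradient entry and exact Euclidean simplex projection after every
step. Two numerical points matter here: per-coordinate adaptive steps
(RMSprop-style) equalise coordinate magnitudes and can never separate
same-signed gradients on the simplex, so the step is normalised globally;
and the global normalisation cancels the common sigmoid saturation
factor, so progress does not stall as the objective approaches 1. On
linear models the solver provably reaches the per-column argmax vertex
exactly, which the tests assert; infeasible starts are corrected by
projection. The resulting 4×W matrix (columns summing to 1) is
exportable in MEME minimal format. The motif width is fixed by the
architecture — 9 nt for the interpretation stack — so longer sequence
preferences are outside its vision range by construction.

## The synthetic fixture

`synth_generate()` emulates the statistical structure the method assumes:
i.i.d. uniform background sequence over 3 chromosomes of 100 kb; 12
planted regions with Gamma-distributed lengths (mean 400 nt, sd 100 nt,
the mean matching the labelled-element scale above) carrying a tiled
alternating-GC motif; 4 informative binary tracks equal to the labels
with interval-level Bernoulli noise at 0.1 (whole peaks dropped, and a
matching number of spurious peaks added — mimicking ChIP-seq peak dropout
rather than per-base noise); and 6 noise tracks of matched interval count
and length distribution. Three chromosomes ensure stratified splitting
and folding are genuinely exercised. These defaults are the package's
study conditions; the problem sizes keep a full training run in tens of
seconds on one CPU.

What passing tests on this fixture do show: the full pipeline — encoding,
windowing, training, thresholding, assembly, importance, motif recovery —
is internally consistent and recovers planted structure (held-out AUC
above 0.9, informative tracks ranked above noise tracks, the planted GC
alternation recovered with high correlation). What they do not show:
performance on real genomes, where marker tracks are far noisier and
correlated with each other, Z-DNA labels are biased by the detecting
assay, sequence composition is not i.i.d., and the feature compendium is
three orders of magnitude wider. The published genome-scale headline
numbers require that compendium and are out of desk-scale reach by
design.

## Known limitations

* The engine is plain R matrix algebra: adequate at fixture scale and for
  methodological work, not for 3-Gb genomes with a 1000-channel
  compendium on one CPU.
* Recurrent models are excluded from interpretation and from seamless
  chunked prediction, as discussed above.
* The shipped energy table is a literature-derived default, not a claim
  about any specific published parameterisation; it is a config file
  precisely so users can substitute their own.
* Strand is not modelled: features are strand-symmetric and labels
  unstranded, as in the underlying data formats.
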