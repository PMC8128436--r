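---
title: "Designing hammerhead ribozyme switches with a structural convolutional regressor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing hammerhead ribozyme switches with a structural convolutional regressor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aptazyme)
```

## The design problem

The sTRSV hammerhead ribozyme self-cleaves when tertiary contacts form
between its two stem-loops. Placed in the 3' UTR of a reporter transcript,
cleavage destabilises the transcript, so cleavage activity is read out as
gene-regulatory activity: the log10 ratio of GFP to a constitutive mCherry
control. A ribozyme *switch* (aptazyme) replaces one loop with a
small-molecule aptamer; ligand binding disrupts the loop-loop contacts and
raises expression. The design task is therefore: given an aptamer grafted
onto loop I or II, find variable loops for the opposite side that give very
low expression in the absence of ligand.

`aptazyme` implements this workflow end to end: construct assembly and
secondary-structure parsing, a structure-aware binary encoding, a small 3D
convolutional regressor of basal activity with linear/kernel/forest
baselines, sort-seq (FACS-Seq) quantification of per-sequence activity,
exhaustive variable-loop enumeration with model-based ranking, evaluation
utilities (including structural-segment hold-out), motif summaries, and a
synthetic-data generator that stands in for the experimental training data.

## Scaffold, folding, and stem-loop parsing

The scaffold (fixed arms, catalytic core, spacers) ships as an editable
JSON fixture populated from the literature 52-nt sTRSV hammerhead; all code
reads the fixture rather than a hard-coded string. Loop inserts are placed
between the stem arms; stem I is 6 bp and stem II 4 bp by default.

Which nucleotides actually form the loop is decided by the predicted
secondary structure: insert bases adjacent to a stem that pair with each
other extend the stem, and long inserts can fold internal (branch) stems.
Two folding backends are provided behind one interface:

* **`rnafold`** (default for full constructs): the ViennaRNA
  minimum-free-energy predictor, invoked through its command-line
  interface. Backend identity and version change MFE details, so the
  backend is recorded alongside outputs.
* **`nussinov`**: a built-in maximum base-pairing folder (Watson-Crick +
  GU, minimum hairpin 3, deterministic tie-breaks), used for fast,
  dependency-free tests and loop-local folds.

Full-sequence structures whose scaffold stems are broken, or whose loop
bases pair outside their own stem-loop, are flagged *misfolded* and
excluded from encoding and training rather than force-parsed; the flag is
reported so the exclusion is auditable.

For large libraries the package folds each loop insert independently under
a *closed-stem approximation*: the scaffold stems are taken as formed and
only intra-insert pairing is predicted (`parse_stemloops(mode = "loop")`).
This is consistent with the hierarchical-folding view of RNA secondary
structure, is memoised per unique insert, and makes the 174,080-candidate
design run tractable on one CPU; the full-sequence fold remains the
validation path. A caveat: an insert-local fold cannot form pairs between
an insert and the spacers, so rare full-sequence misfolds are invisible to
the fast path (they are caught when constructs are re-annotated with
`annotate_constructs()`).

## The structural encoding

Each stem-loop becomes a binary grid: rows index positions along the
stem-loop, two columns distinguish the 5' and 3' strand sides, and 8
channels one-hot encode nucleotide identity crossed with pairing state.
Stem pairs occupy both sides of one row; loop nucleotides walk up the 5'
side to the apex and down the 3' side (a loop of n nucleotides puts
`ceiling(n/2)` on the 5' side — the figure convention leaves odd-length
handling open, so the apex nucleotide sits on the 5' side). Branch-stem
nucleotides stay in the walk but carry paired channels. The grids of
stem-loops I and II are stacked along a third axis, representing the
assumed spatial apposition of the two stem-loops; empty cells are all-zero.

Two row-anchoring conventions are provided:

* **stem-base anchoring** (default): row 1 is the outermost scaffold stem
  pair. This is the simplest convention and the package default.
* **loop-interface anchoring** (`stem_depth = k`): the innermost stem pair
  sits at fixed row `k`, so the loop walk always starts at row `k + 1`
  and apposed loop nucleotides of the two stem-loops share a row
  regardless of stem length or extensions.

Why both exist: the convolutional window is only two rows tall, so the
anchoring decides which cells a window can co-observe, and during
development we found the choice matters for what the model can learn (see
the closing section). `L_max` defaults to 16 rows, which fits the training
libraries (loops to 13 nt); design runs with grafted aptamers use taller
grids (the bundled aptamer inserts walk up to ~26 rows), and the grid
geometry travels with the model metadata so mismatches fail loudly.

## The regressor

The network follows the published architecture: a 2 x 2 x 2 convolution
with stride 1 and valid padding over (row, side, stem-loop) — each window
sees a group of eight adjacent nucleotide cells across all channels — then
25% dropout, flattening, a rectified-linear dense layer, 50% dropout, and
a final linear unit. Training minimises mean squared error with Adam over
100 epochs. No deep-learning framework is available in this R stack, so
the network is implemented directly with matrix algebra (the convolution
as an im2col product) and hand-derived backpropagation; the test suite
checks every gradient against finite differences, and a single integer
seed fixes initialisation, shuffling and dropout masks.

Unspecified hyperparameters default to 32 filters, 128 dense units, batch
size 128 and learning rate 1e-3 — a model small enough not to overfit the
~10^4--10^5-record training sets this package targets, and all
configurable. The convolution is linear by default (`conv_activation =
"linear"`), matching the published layer list in which the rectifier
appears only at the dense layer; a ReLU convolution is available as an
option. Inference disables dropout, so predictions are deterministic and
batch-size invariant.

Baselines (`train_baseline()`) operate on the flattened tensors: lasso
(`glmnet`, penalty by internal cross-validation), an RBF support vector
machine (`e1071`) and a random forest (`randomForest`).

## Sort-seq quantification

FACS-Seq sorts cells into 8 bins of log10(GFP/mCherry): six interior bins
of equal width between two extreme boundaries, with open-ended first and
last bins holding the distribution tails. Per-sequence bin counts are
normalised by total reads per bin and rescaled by the fraction of sorted
cells per bin (the computational counterpart of remixing bin amplicons in
proportion to sorted cell counts). The activity estimate is then the mean
of a normal distribution fitted to the normalised profile.

The fit is a weighted maximum likelihood of an interval-censored normal —
the extreme bins enter as open intervals, which is the principled way to
use them — with a least-squares-on-profiles alternative exposed for
comparison, since the original description does not pin the method down. A
sigma floor of 0.01 log10 units guards degenerate single-bin profiles; a
profile confined to one open extreme bin is not identifiable, and is
reported at the boundary (offset by the floor) with `converged = FALSE`.
Sequences with fewer than 20 reads are dropped (inclusive threshold:
exactly 20 reads are kept), with the removal count reported.

## Forward design

`derive_loop_insert()` removes the terminal closing helix of an annotated
aptamer (the stem that the ribozyme stem replaces) and keeps everything
from the ligand-binding bulge outward; retaining closing pairs is possible
via `retained_pairs` (default 0, since the source protocol removed the
stem entirely). The bundled aptamer file is a clearly-labelled synthetic
stand-in: five entries carrying the literature core motifs of the
theophylline, tetracycline, neomycin, chloramphenicol and folinic-acid
aptamers inside simplified closing-stem/bulge architectures. It is data,
not code — swap in full published sequences by editing the JSON.

`enumerate_library()` generates all variable loops of lengths 5--8 for
each allowed aptamer position (2 x (4^5 + 4^6 + 4^7 + 4^8) = 174,080
candidates); `design_library()` scores them in streamed batches against a
trained model, keeps a running best-k pool, and returns the k = 200
lowest-predicted-activity designs ranked ascending with ties broken
lexicographically by full sequence. Candidates whose encoding exceeds the
model's grid are excluded and counted. `top_n_designs()` takes the 15
top-ranked designs per aptamer, the number one would synthesise for
individual characterisation.

## Synthetic data: what it emulates and what it does not

The surrogate activity function stands in for the missing experimental
training set. It maps a loop pair to

```
base + w * zipper(loop1, loop2) + motif effects + penalty * total_length + noise
```

where `zipper` is the longest run of consecutive complementary positions
when loop I is apposed to the reverse of loop II (Watson-Crick or GU) — a
deliberate caricature of the antiparallel loop-loop docking that activates
cleavage. Because the term couples the two loops non-additively and
respects their spatial apposition, a model that sees the loops aligned in
one tensor holds a genuine advantage over flattened linear features, which
is exactly the property the model comparison tests exercise. We chose the
position-wise (zipper) reading of "complementary run" over a
free-offset longest-common-substring reading: the zipper matches the
docking picture, and a free-offset signal is invisible to spatially
aligned convolution windows, defeating the purpose of a structure-aware
encoding.

Defaults, chosen once: base 0.3 (near-inactive expression), -0.2 per
complementary nucleotide (a full 8-nt dock approaches the activity of an
efficient cleaver, around -1.3), a -0.3 loop-II UGGAG motif effect
(mirroring the scale of motif contrasts reported for trained designs),
+0.02 per loop nucleotide, and 0.05 log10 units of Gaussian noise
(replicate-level repeatability). Loop lengths default to N5--N10 uniform
on both loops, the design of the doubly-randomised training library.

`simulate_facs_reads()` distributes a fixed read depth per sequence over
the 8 bins by a multinomial draw with probabilities from a
Normal(activity, sigma) integrated over the bin intervals, with sigma =
0.4 log10 units of cell-to-cell spread as the default population width.

The generator does **not** emulate: real cleavage biophysics or its
sequence determinants, transformation bottlenecks, sorting impurity,
PCR/qPCR amplification bias, or aptamer-specific ligand responses. Tests
passing on this surrogate therefore certify the *pipeline* — encoding
fidelity, estimator calibration, selection correctness, model mechanics —
not biological accuracy on real libraries.

## Evaluation choices

"R-squared" is reported in both common senses — squared Pearson
correlation (affine-invariant) and coefficient of determination
(calibration-sensitive) — with squared Pearson as the headline, since a
best-fit-line reading matches how scatter accuracy is usually presented;
hold-out analyses can consult the stricter variant in the same report.
Splits are seeded shuffles with round-half-up training sizes (75/25 by
default). Structural-segment hold-out groups records by structure key
(stem lengths, loop lengths, branch flags), trains on all other segments
and evaluates on the held-out segment, once per qualifying segment;
segments below `min_segment_size` (default 50) are never test segments,
to avoid noise-dominated per-segment estimates. Switch measurements are
normalised to a non-cleaving control measured under the matching condition
and expressed in percent, and the activation ratio is normalised induced
over normalised basal.

## Numerical choices and scale

Problem sizes used by the automated checks were chosen to exercise every
path at desk scale: the synthetic closure runs at 20,000 loop pairs with
read depth 1,000; design runs enumerate all 174,080 candidates per aptamer
with loop-insert folds memoised across aptamers (87,040 unique variable
loops); the binned-normal recovery study uses 200 seeded replicates.
Nussinov folding backs the high-volume paths; RNAfold backs the
full-construct validation path. Ties in ranking are broken
lexicographically so reruns are byte-identical; all stochastic steps take
explicit integer seeds.

## Known limitations

The single-convolution architecture sees at most two adjacent rows of
both stem-loops at a time. Loop pairs of unequal length place parts of
the docking interface at varying row offsets, so length-heterogeneous
training mixes force the dense layer to enumerate length-dependent
feature conjunctions — a steep sample-complexity burden for a
combinatorial signal like the complementarity zipper. Accuracy on the
synthetic closure (reported by the acceptance script and the test suite)
reflects this: the convolutional model clearly outperforms the flattened
baselines on the interaction-bearing surrogate, but the absolute held-out
accuracy on the full N5--N10 mix is modest, and structure-stratified
hold-out is the honest way to quantify how far a trained model
extrapolates. Practical design runs should train on libraries whose
loop-length mix covers the intended designs.

Other limitations worth noting: the closed-stem approximation cannot see
insert-spacer misfolds (re-annotate final candidates with
`annotate_constructs()`); the Nussinov test folder maximises pairing and
is cruder than an MFE folder on long sequences; the surrogate certifies
the pipeline, not cleavage biology; and the model predicts only basal
activity — ligand responsiveness of a designed switch is outside its
scope.
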