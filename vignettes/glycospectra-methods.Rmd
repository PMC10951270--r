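---
title: "Predicting intact glycopeptide fragment spectra: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting intact glycopeptide fragment spectra: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Stepped-collision-energy HCD spectra of intact N-glycopeptides contain
two interleaved fragment populations: peptide backbone b/y ions (with
HexNAc-carrying and cross-ring variants around the glycosite), and glycan
fragments — Y ions that retain the peptide and successively lose
monosaccharides from the non-reducing end, and oxonium-type B ions from
the antennae. Relative fragment intensities are rich, reproducible
functions of the precursor (sequence, glycan topology, charge), but they
are not predictable from first principles. glycospectra learns this map
from annotated spectra and uses the predictions for two downstream tasks:
discriminating glycan structural isomers by rescoring against predicted
spectra, and building predicted spectral libraries for DIA.

## Model

A glycopeptide is split into its peptide and glycan moieties.

**Peptide encoder.** Residues are 20-dimensional one-hot vectors;
modifications contribute a 6-vector of elemental counts (H, C, N, O, S,
P), zero when absent. Two stacked bidirectional LSTM layers (hidden width
$h$, default 256) produce per-position features of width $2h$, followed
by dropout (rate 0.25, training only).

**Glycan encoder.** The glycan is a rooted tree with the reducing-end
HexNAc at the root and 5-dimensional one-hot monosaccharide node features
(Hex, HexNAc, NeuAc, NeuGc, Fuc). A *child-sum* tree LSTM traverses
bottom-up: the cell is a standard LSTM cell except that child hidden
states are summed (one forget gate per child). Summation makes the
encoding exactly invariant to branch order, which HCD identification
cannot determine anyway.

**Fusion.** The bottom-up root state is passed through a dense layer and
added to the peptide features at the glycosite; the concatenated final
states of the peptide stack are passed through a dense layer and added to
the root node's feature. A learned 2-dimensional embedding of the
precursor charge (charges 1–6) is concatenated at every peptide position
and every glycan node.

**Peptide head.** The fused peptide features pass through two further
BiLSTM layers, then a dense + ReLU head emits 4 values per backbone
cleavage: b and y intensities at charges 1+ and 2+. Observed intensities
of the b-N(1)/b\$ variants are summed into their parent b channel (and
likewise for y) to form the 4-channel training target; this resolves the
tension between the six annotated peptide ion series and the 4-channel
head by treating variant splitting as unmodelled detail.

**Glycan head.** A second tree LSTM traverses top-down over the
concatenation (one-hot, bottom-up feature, charge), so each node sees
monosaccharides below, above and in sibling branches. Every glycosidic
edge (plus the glycan–peptide attachment, the source of Y0) is a
cleavage site; attention-weighted sums of the top-down features of the
*lost* and *retained* node sets are concatenated into a $2h$-wide
cleavage vector (512 at defaults). A tripartite fragmentation graph
connects cleavages to structure-specific fragments to composition-level
fragments. Per structure fragment, an LSTM runs over its boundary-cleavage
vectors (shuffled during training because an LSTM is not symmetric;
canonically ordered in evaluation — ascending cleavage depth, ties broken
by the whole-tree canonical serialization with the cut edge marked, so
any remaining ties are automorphism-equivalent cleavages with identical
features), attention pools the
outputs, and a dense + ReLU head emits Y intensities at charges 1–3
(B ions: one value, charge 1+ only). Composition intensities are the sums
over their isomeric structure members; this conservation is exact by
construction and is asserted in the tests. The attention weights and
member proportions are retained on the graph for explanation
(`explain_candidate()`).

**Ratio head.** Attention-pooled peptide and glycan features are
concatenated and mapped through a dense + sigmoid layer to $r \in (0,1)$,
the peptide share of total fragment intensity. The full spectrum scales
the peptide part to $r$ and the glycan part (Y and B jointly) to $1-r$.

At the default width the model has ~7.2 million parameters (~5.3 M
peptide, ~1.9 M glycan); the unnamed dense layers are taken as
hidden→output, which reproduces that scale.

## Losses and training

Spectrum dissimilarity is the spectral angle
$\mathrm{SA} = \tfrac{2}{\pi}\arccos \mathrm{DP}$, where DP is the
normalized dot product; both are scale-invariant. The total loss is
$L = w_1\,\mathrm{SA}_{total} + w_2\,\mathrm{SA}_{peptide} +
w_3\,\mathrm{SA}_{glycan} + w_4\,\mathrm{MSE}_{ratio}$, extended by
$w_5\,\mathrm{SA}_B$ for the branch-fragment model. Weights follow the
dynamic weight average: $r_k = L_k(t-1)/L_k(t-2)$,
$w_k = K\exp(r_k/T)/\sum_j \exp(r_j/T)$, uniform for the first two
epochs. The temperature $T = 2$ is the convention of the original
dynamic-weight-average method. $\mathrm{MSE}_{ratio}$ is the batch mean
of per-spectrum squared errors (per-spectrum vs batch aggregation is a
design choice; the batch mean keeps all task losses on an epoch scale). A part with no observed ions has an undefined SA; that term is
skipped for that spectrum rather than given an arbitrary value — the
dataset filters (≥5 peptide, ≥5 Y, and for the B model ≥2 B matched
ions) make this rare.

Optimization is Adam, batch size 16. The learning rate warms up linearly
0→0.001 over 5 epochs, then follows cosine annealing with warm restarts
(intervals 15, 30, 60, …; floor 0). Finetuning starts at 0.001 without
warmup and multiplies by 0.1 when the validation loss has not improved by
more than 1e-4 for 5 epochs ("stopped improving" means min-mode on the
uniform-weight validation total loss, which is also the model-selection
statistic). The B model trains at 1e-4 with the warmup+cosine
schedule, with every non-B module frozen (asserted bit-wise), so Y and
peptide predictions are unchanged by B training. Datasets are split
3/5–1/5–1/5 at the precursor level.

Because neither R nor this Python environment provides torch/DGL, the
network and its backward pass are implemented from scratch (sequence-LSTM
and tree-LSTM kernels in C++ via Rcpp, the rest in R). All gradients are
verified against central finite differences in the test suite, and the
C++ tree-LSTM kernels are cross-checked against an independent pure-R
implementation.

## Fragment enumeration

Y structure fragments are the connected, root-containing proper subsets
of the glycan tree (the intact glycan is excluded — a fragment requires
at least one cleavage; Y0 arises from the peptide-attachment cleavage).
Their count obeys $f(v)=\prod_{c\in\mathrm{children}(v)}(1+f(c))$, used
as an independent oracle. B ions exist for complex/hybrid glycans only:
per antenna, every complete subtree rooted at a branch node, plus each
such subtree with the adjacent arm mannose. The adjacent-mannose variants
are composition-level constructs and need not be connected node sets
(e.g. mannose + terminal Gal of a GlcNAc-Gal antenna yields Hex(2)); we
follow that reading because it reproduces the worked examples, and note
it as a deliberate relaxation of "fragments are connected". Oligomannose
branches contribute no B ions; the bisecting HexNAc sits on the central
core mannose, not an arm, and is not treated as a branch. Cross-ring
b\$/y\$ ions add 83.03711 Da (C4H5NO), the prevailing 0,2-A convention
for GlcNAc in glycoproteomics search engines. Proton mass 1.007276 Da; monoisotopic masses
throughout; peptide fragments at charges 1–2, Y at 1–3, B at 1+.

## Spectrum processing

Peak matching assigns each theoretical fragment the closest peak within a
ppm tolerance (default 20 ppm, configurable), and each peak to at most
one fragment (smallest m/z error
wins). Individual-CE spectra merge by the arithmetic mean of aligned
intensities. Consensus spectra are the mean of per-part total-normalized
replicates, chosen for replicate-order and scale invariance (no
replicate weighting or outlier rejection). The peptide intensity fraction is
bookkept on total (sum) intensity and carried alongside the normalized
parts.

## The simulator: a stated world

The synthetic-data module stands in for the deposited training data. Its
ground-truth rule makes structure determine spectrum: a Y structure
fragment bounded by cleavages $c_1..c_k$ has intensity
$\exp(-\sum_i \lambda(c_i))$ with $\lambda_{core}=1.2$ for cleavages
inside the chitobiose/trimannosyl core (and the peptide attachment) and
$\lambda_{branch}=0.4$ for antenna cleavages — encoding the observation
that core cleavages are less likely at Y-preserving collision energies.
These propensities are free parameters of the simulator, not measured
values. B fragments decay with the depth of their shallowest node, with
a 5× oxonium boost for mono/disaccharides; Y intensity spreads over
charges 1–3 by a precursor-charge-dependent profile; peptide b/y follow
a smooth positional bell with 70/20/10% naked/HexNAc/cross-ring variant
shares; the peptide fraction is Beta-distributed with mean 0.25 and
concentration 20 (peptide fragments are usually much weaker than glycan
fragments in stepped-CE HCD); observed copies apply multiplicative
log-normal noise (CV 10%) and 5% ion dropout. Peptides are tryptic-like
(7–14 residues, C-terminal K/R) with one N-X-S/T sequon; glycans grow on
the canonical core to 7–12 nodes with a 60/20/20 complex/hybrid/
high-mannose mix, 30% core fucosylation and 20% bisecting HexNAc;
charges 2–4.

What a green test establishes: that the full pipeline — enumeration,
matching, multi-task optimization, rescoring — can recover a smooth,
topology-determined intensity rule at desk scale. What it does not
establish: performance on real HCD data, which has instrument- and
CE-dependent intensity structure, noise far from log-normal, co-isolated
precursors, and noncanonical fragments. Dataset-level results on real
repositories are out of reach without the deposited raw data and
full-scale training, and the package makes no claim about them.

## Numerical choices

- SA gradients clamp the dot product to $[-1+10^{-9}, 1-10^{-9}]$ to
  avoid the arccos singularity at identical vectors.
- ReLU intensity heads are initialized with bias 0.1 so that outputs are
  not uniformly zero (an all-zero part has undefined SA and no gradient).
- The evaluation-time cleavage ordering keys on the canonical
  serialization of the whole tree with the cut edge marked (not just the
  lost subtree): keying on the lost subtree alone leaves ties between
  cleavages in different contexts, which breaks branch-permutation
  invariance at the 1e-5 level. With the marked key, remaining ties are
  automorphism-equivalent and their features identical by child-sum
  symmetry. String sorts use radix order for locale independence.
- Candidate ranking breaks score ties by the canonical glycan string for
  determinism. When the model predicts no B ions, the score degrades to
  the renormalized Y term.
- Degenerate inputs: single-node glycans have only the attachment
  cleavage (Y0); glycans without the HexNAc-HexNAc-Hex prefix classify
  as `other` instead of erroring, keeping toy inputs usable; peptides
  must have length ≥ 2.

## Limitations

Topology-only glycans (no linkage or anomericity); single glycosite per
peptide; no c/z/a/x ions, neutral losses, or isotope envelopes; no
retention-time model (libraries accept supplied retention times or use a
clearly tagged hydropathy proxy); no instrument/CE metadata encoders.
The DIA search engine itself (scoring, FDR, glycoform inference) is an
external tool: this package stops at library generation, including
entrapment entries whose compositions are provably absent from the
library.
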