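---
title: "cpinet: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cpinet: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The prediction problem

cpinet predicts a continuous binding affinity (pKd, pKi or an integrated
score) for a pair (small molecule, protein). The inputs are a SMILES string
and an amino-acid sequence; the output is a single real number. Affinity
labels on the Kd scale are transformed with `kd_to_pkd()`,
$\mathrm{pKd} = -\log_{10}(K_d/10^9)$ with $K_d$ in nM, so that 10 µM maps
to 5 and 1 nM to 9.

## Model

The model fuses three encoders with nested cross-attention.

**Graph view of the compound.** The molecule is a directed graph: each
chemical bond becomes two directed bonds. Atom features are one-hot atomic
number, heavy-atom degree, formal charge, chirality tag, bonded-hydrogen
count, hybridization, an aromaticity flag and scaled atomic mass; bond
features are a bond-type one-hot (single/double/triple/aromatic),
conjugation, ring membership and a stereo one-hot. Hidden states live on
directed bonds, initialized as
$h^0_{vw} = \mathrm{ReLU}(W_{in}\,[x_v \,\|\, e_{vw}])$. Each step updates

$$m^{t+1}_{vw} = \sum_{k \in N(v)\setminus\{w\}}
  \tfrac{1}{3}\big(\tilde x_v + \tilde x_k + h^t_{kv}\big),
  \qquad
  h^{t+1}_{vw} = \mathrm{ReLU}\big(h^0_{vw} + W_m\, m^{t+1}_{vw}\big),$$

where $\tilde x = W_p x$ is a shared learned projection of atom features
into the hidden width. The element-wise mean ("average" aggregation) rather
than a sum keeps the update magnitude independent of vertex degree, and the
$k \ne w$ restriction means a message never flows straight back along its
reverse bond. Readout averages the incoming-bond hiddens per atom, then
averages over atoms, giving the graph-view embedding $O_{G}$.

**Fingerprint view of the compound.** A Morgan/ECFP fingerprint (radius 2,
2048 bits by default; OpenBabel's ECFP hashing folded by bitwise OR) passes
through a two-layer MLP to the embedding $O_{M}$.

**Fusion.** Both 1-D embeddings are reshaped into `n_tokens` contiguous
tokens. Cross-attention takes queries from the fingerprint view and keys
and values from the graph view:
$Q = f_Q(O_M),\ K = f_K(O_G),\ V = f_V(O_G)$, energies
$\mathrm{softmax}(QK^\top/\sqrt{C/d})$, output $f_0(\mathrm{energy}\cdot V)$.
A stack of latent self-attention blocks (attention + position-wise
feed-forward, both residual) refines the fused compound latents.

**Protein encoder.** Sequences are tokenized over a fixed 26-symbol
vocabulary (pad = 0, 20 canonical residues, B/Z/X/U, unknown), right-padded
or right-truncated to `max_len` (500 by default). An embedding lookup and a
stem convolution produce the initial representation; each of `prot_blocks`
residual blocks computes
$\mathrm{GLU}(\mathrm{LN}(\mathrm{Conv1D}(s) + \lambda\, [s \,\|\, s]))$,
where the convolution doubles the channel width, the input is duplicated
along channels so the residual is well-typed, and the gated linear unit
$a \odot \sigma(b)$ restores the width. Padding positions are zeroed before
the stem and after every block (`mask_pad`), so representations of real
residues never depend on pad content.

**Interaction and head.** A final cross-attention takes queries from the
compound latents and keys/values from the protein positions — the model asks
how the protein responds to the compound — and the attended output is
mean-pooled over the query tokens and passed through a small MLP head to the
scalar affinity.

## Training

The loss is mean squared error, optionally density-weighted
(`weight_rule()`): datasets whose labels pile up at one value (e.g. the
assay ceiling pKd = 5) would otherwise dominate the gradient, so squared
errors inside the high-density interval are multiplied by 0.5 and all others
by 5 (`weight_rule_davis()`, interval [0, 5] closed at both ends; a KIBA
preset uses [11.1, 12]).

The optimizer is LAMB: Adam-style bias-corrected moments give an update
direction $u$, and each parameter array is rescaled by the trust ratio
$r = \|w\| / \|u + \mathrm{wd}\cdot w\|$ before the step
$w \leftarrow w - \eta\, r\,(u + \mathrm{wd}\cdot w)$. Degenerate norms fall
back to $r = 1$. The default clips $r$ at 1: in this architecture several
output layers are small vectors whose trust ratios would otherwise amplify
steps and destabilize the end of training; capping at 1 preserves the
layer-wise slowdown that motivates the trust ratio while never amplifying.
Labels are centred on the training mean before optimization and the
offset is added back at prediction time (it is stored in the fit and in
checkpoints): the network starts near zero output, and pushing a large
constant through the ReLU stack to reach an uncentred label scale can
collapse the activations early in training. Training is deterministic given
the seed, retains the best-validation parameters and stops early after
`patience` epochs without improvement.

## Benchmark split protocols

Cold splits operate on entities, not records: `split_novel_compound()` and
`split_novel_protein()` partition compounds (proteins), so no test compound
(protein) is ever seen in training; `split_novel_pair()` partitions both and
drops records that straddle the partition (the count is logged). A
validation set is carved from the training records at the 80/20 convention.
`filter_hard()` additionally removes test records whose compound has
Tanimoto similarity ≥ 0.3 to any training compound **and** whose protein has
alignment similarity ≥ 0.3 to any training protein — the stricter "both
below threshold" reading of a hard split; an `either` mode is available.
Protein similarity is the number of identical aligned residues from a global
alignment (identity scoring, linear gap penalty 0.5) divided by the fixed
encoding length 500 and capped at 1, matching the fixed-length protein
input. `kfold_split()` rotates entity folds so each entity is tested exactly
once.

## Metrics

`mse()`, `concordance_index()` (0.5 credit for tied predictions, pairs with
tied targets excluded), `enrichment_factor()` and `bedroc()`. Two EF
definitions exist in the literature: the standard one (active recall in the
top fraction divided by the fraction; default) and a decoy-referenced one
(active recall at the score threshold where the given fraction of decoys is
retrieved). Both are implemented; `definition = "standard"` is the default.
BEDROC uses the Truchon–Bailey closed form with α = 80.5 as the screening
default, which concentrates the weight on roughly the top 2% of the ranked
list. Ranking ties are broken by stable input order with a one-time warning;
seeded random tie-breaking is available.

## Synthetic data

`generate_synthetic()` emulates the structure of public CPI benchmarks
without downloads: a sparse compound × protein matrix sampled without
replacement at a requested density; compounds from a packaged list of 50
drug-like molecules (extended with generated branched alkanes when more are
requested); proteins as random sequences of length 50–500 over the
20-residue alphabet. Labels are a planted sparse linear function —
an intercept of 5, eight fingerprint bits with coefficients of magnitude
0.4–1.2, and five residue-composition terms with coefficients of magnitude
2–6 — plus Gaussian noise (default sd 0.3). These choices give a label
spread of roughly one pKd unit around 5, comparable to public affinity
panels. A point-mass mode pins a configurable fraction of labels
(default 0.6964) to a constant (default 5) to mimic the skew of
assay-ceiling datasets. The planted coefficients are stored in the manifest
attribute, so noiseless labels are exactly reproducible and a linear probe
can verify identifiability.

What the generator does **not** emulate: real structure–activity
relationships (labels are linear in fingerprint bits, not a docking
energy), realistic protein families (sequences are i.i.d. uniform), assay
noise structure, or correlated missingness of real interaction matrices.
Passing tests on synthetic data therefore demonstrate that the
implementation is correct and can learn a planted signal — not that the
architecture reaches any particular accuracy on real benchmarks.

## Numerical choices and degenerate inputs

* Attention energy scaling follows the transformer convention
  $QK^\top/\sqrt{C/d}$; a literal $QK^\top \cdot C/d$ reading is available
  via `energy_scaling = "literal"`.
* 1-D compound embeddings are reshaped to `n_tokens = 6` tokens before
  attention so the energies are informative; `n_tokens = 1` reproduces the
  single-token reading in which the fingerprint view only influences the
  output through constant-energy queries. Six divides the default widths
  (300); the token count must divide both compound embedding lengths.
* Single-head attention is the default; multi-head is supported.
* Bond-less molecules (single heavy atoms) read out as the zero vector.
* Layer normalization uses ε = 1e−5; softmax subtracts the row maximum.
* The final cross-attention output is mean-pooled over query tokens.
* `f_0` (the output projection) is applied inside every attention block.
* Checkpoints store weights together with the generating configuration;
  loading under a different configuration is an error, never a reshape.

## Problem sizes used by the tests

The test suite and the acceptance script exercise the full architecture at
reduced widths chosen so the whole suite runs comfortably on a single CPU:
oracle comparisons use random graphs of ≤ 6 atoms with hidden width 6; the
overfitting check trains on a 64-record synthetic set (16 × 8 entities,
density 0.5, noise sd 0.2) at hidden widths 32–128 and protein length 120;
the generalization check trains on a 500-record set (50 × 20, density 0.5,
noise sd 0.3) with a held-out 20% validation split and protein length 80.
These are the package's own fixed study conditions; the default
configuration (`cpi_config()`) uses the full widths.

## Known limitations

* Stereochemistry perception is approximate: chirality comes from the
  parser's stereo parity, and double-bond cis/trans is classified from the
  2-D layout only when the geometry is defined; undefined stereo maps to an
  "either" slot.
* Conjugation and hybridization are derived from the kekulized heavy-atom
  graph with standard valence rules, which can disagree with a full
  perception toolkit on exotic species.
* The protein encoder sees at most `max_len` residues; longer proteins are
  right-truncated.
* Training is single-threaded R matrix algebra: practical for the packaged
  problem sizes and for method study, not for large-scale benchmark
  training.
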