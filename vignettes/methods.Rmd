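---
title: "Methods: representation learning, reconstruction and evolution in latentmol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: representation learning, reconstruction and evolution in latentmol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`latentmol` implements a desk-scale molecular foundational model with two
orthogonal halves sharing one latent space: a graph-neural **encoder** that
maps a molecule to a 1D representation vector, and an autoregressive
Transformer **decoder** that reconstructs the SMILES string from that
vector. The encoder is pre-trained by *similarity projection*: pairs of
representations are projected onto an 8-component inter-molecular
similarity label, five components of conformational-space pharmacophore
similarity (CSPS) and three fingerprint similarities. Because the two
halves are trained separately against the same representation space,
property heads and gradient-based molecular optimization can operate on
the vectors without disturbing reconstruction.

## The encoder

A molecule is a graph $G=(V,E)$ with atom features (element one-hot over
C/N/O/S/P/F/Cl/Br/I/other, hybridization, formal charge, chiral tag,
ring and aromatic flags; 22 columns) and bond features (conjugation, ring
membership, stereo mark; 4 columns). Hydrogens are implicit. Message
passing follows the Weisfeiler-Lehman network pattern: atoms are embedded
by a ReLU-activated linear layer, $h_v^{(0)}=\mathrm{ReLU}(W_{in}h_v+b)$;
each round forms bond messages
$m_{uv}=\mathrm{ReLU}(W_{contact}[h_u\,\|\,e_{uv}]+b)$, replaces the bond
state by the message, and updates atoms from the sum of incoming bond
states, $h_v\leftarrow\mathrm{ReLU}(W_{agg}[h_v\,\|\,\sum_{u\in N(v)}
e_{uv}]+b)$. Four rounds are the default. Because round one consumes raw
4-dimensional bond features while later rounds consume hidden states, the
raw bond features are first embedded to the hidden width by a mirror of
the atom embedding; this keeps one shared set of round weights.

The readout gates each atom against its neighbourhood with three
bias-free matrices, $h_v^{final}=W_{self}h_v\odot\sum_{u\in
N(v)}(W_{bond}e_{uv}\odot W_{atom}h_u)$; an isolated atom has an empty
neighbour sum and reads out as the zero vector. Pooling is global
attention: an MLP (widths $3d \to d/2 \to d/16 \times 3 \to 1$ at
representation width $d$; 6144/1024/128/128/128/1 at the default
$d=2048$) scores each atom, with a sigmoid after *every* linear layer
including the scalar output, then a softmax across the atoms of a
molecule. Applying a sigmoid before the softmax compresses the logits
into $(0,1)$ and therefore bounds how peaked the attention can be; it is
implemented exactly in that printed order. The representation is the
attention-weighted sum of final atom vectors, so it lives in the convex
hull of atom states — an *intensive* summary. The synthetic property
default (below) is chosen with that in mind.

Two projection heads consume representation pairs. Each side passes a
rectifier that expands to $5d$ (LeakyReLU + batch norm) and is
concatenated with itself, giving $6d$ per molecule and $12d$ per pair
(24576 at full width). Staged reductions $12d\to d\to d/4\times 3$ with
SiLU activations and batch normalization lead to a sigmoid output of
width 3 (fingerprint head) or 5 (CSPS head). Batch normalization always
runs in evaluation mode at inference, so encoding is batch-independent.

Initialization is Kaiming-uniform (fan-in) for rectifier-activated
layers and Xavier-uniform for sigmoid layers and the bias-free gates,
under a configuration seed.

## Similarity labels

For a molecule pair the label is
$(\mathrm{CSPS}_{w1..w4},\ \mathrm{CSPS}_{diff},\ \mathrm{ECFP4~Tanimoto},
\ \mathrm{MACCS~Tanimoto},\ \mathrm{AtomPairs~Tversky})$, all in $[0,1]$.

**Energy windows.** Four strain-energy windows are the rotatable-bond
count times 0.14806, 0.5060, 0.88836 and 1.4806 kcal/mol (near-lowest,
first-percentile, medium and mean ligand strain), floored at 0.1 kcal/mol
so rigid molecules retain a non-empty ensemble.

**Conformers.** Ensembles come from seeded distance-geometry embedding
(ETKDG, 50 embedding attempts per molecule by default) followed by MMFF94
minimization; strain energies are taken relative to the best conformer
found, redundant conformers are removed at a 0.5 Å optimal-superposition
RMSD cutoff, and each window keeps at most 8 lowest-energy conformers.
The ensembles are nested across windows by construction. This open
pipeline replaces the proprietary Monte-Carlo search/commercial force
field/pharmacophore-shape stack that the full-scale protocol uses; the
*structure* of the label (four windows, max over conformer pairs, plus a
max-minus-min flexibility component) is preserved exactly.

**Overlay score.** A conformer pair is superposed by principal axes (the
four proper sign combinations are tried) and scored by Gaussian kernel
overlap, $V_{AB}=\sum_{i\in A,j\in B}\exp(-d_{ij}^2/2\sigma^2)$ with
$\sigma=1.5$ Å, normalized Tanimoto-style to
$V_{AB}/(V_{AA}+V_{BB}-V_{AB})\in[0,1]$. The final score averages a plain
shape term over all heavy atoms with a pharmacophore term restricted to
atoms sharing a feature family; self-comparison scores 1 by construction.
Pharmacophore families (donor, acceptor, aromatic, hydrophobe, positive,
negative) are assigned by explicit structural rules on the annotated
graph (element, aromaticity, formal charge, hydrogen count); the
installed SMARTS engine reports only match counts, not atom indices, so
rule-based typing is used instead of SMARTS patterns — the families and
their intent are the same.

**Fingerprints.** ECFP4 and MACCS similarities are Tanimoto on toolkit
fingerprints; AtomPairs uses the asymmetric Tversky coefficient with the
reference molecule as prototype, $\alpha=0.9,\ \beta=0.1$ by default
(both configurable). The coefficients are computed by explicit set
arithmetic so the parameterization is transparent and testable.
CSPS window components are non-decreasing in the window index (nested
ensembles); the fifth component is clamped to $[0,1]$.

## Decoder

SMILES are tokenized by a byte-pair tokenizer: single characters from the
corpus plus greedy frequency merges up to a configurable budget (ties
broken lexicographically), with padding at index 0 and start/end
specials. A drug-like corpus with a merge budget of ~24 lands near the
43-token vocabulary of the full-scale model. The vocabulary is persisted
(JSON) with every checkpoint so decoding is reproducible.

The decoder is a Transformer (default 4 layers, 32 heads, model width
equal to the 2048 representation width; post-layer-norm, SiLU
feed-forward) with causal self-attention over rotary-encoded target
embeddings. The representation vector, projected to model width, is the
*single-position memory* for cross-attention. With one key the attention
softmax is identically 1, so cross-attention reduces exactly to adding
the value/output-projected memory at every position; the implementation
exploits this identity rather than materializing degenerate attention
maps. Rotary encoding is applied to target embeddings only. The output
head is a 3-layer MLP ($d\to 2d\to d/2\to |V|$; 4096/1024/43 at full
width).

**Loss.** Training uses teacher forcing with a frequency-weighted
cross-entropy: token $i$ receives weight $\min(N_{total}/f_i, 100)$
($f_i$ its batch frequency among valid tokens, weight 1 when absent);
padding and the start token are excluded, and the weighted sum is divided
by the valid-token count. The cap keeps rare tokens (ring-closure digits,
stereo marks) from dominating while still counteracting the heavy
carbon/aromatic-carbon imbalance of SMILES corpora.

**Sampling.** Decoding is Gumbel-max: add $g=-\log(-\log u+\epsilon)$
($\epsilon=10^{-10}$) to the temperature-scaled log-softmax and take the
argmax, which samples exactly from $\mathrm{softmax}(y/T)$. Validity of a
decoded string means the toolkit parses it and every atom respects
standard valence given its formal charge.

## Property heads and representation-space evolution

The property predictor is an MLP with an input dropout (rate 0.5) and
sigmoid expansion $d\to 4d$, concatenation with the input ($5d$), two
$5d$ linears bridged by a residual addition, reduction to $d/2$ and the
output width (8192/10240/10240/10240/1024/1 at full scale). Dropout is
active only in training mode. Projection mode trains on frozen
representations; fine-tuning mode clones the encoder before touching it,
so the encoder that the decoder understands is never mutated — mutating
it would silently sever the reconstruction pathway.

Evolution procedures operate on vectors only, with cosine similarity as
the representation similarity throughout:

* **Screening**: per reference set, the maximum cosine similarity over
  its references; scores below 0.5 are reset to 0; molecules are ranked
  by the sum over sets and the top 0.1% flagged. BEDROC
  ($\alpha = 160.9$, matching 1% early recognition), AUROC and
  enrichment factors are provided.
* **Stochastic propagation**: a random walk
  $E \leftarrow E + 0.05\,n \odot \sigma \odot m$ with standard-normal
  $n$, a Bernoulli(0.5) mask $m$, and $\sigma$ the per-dimension standard
  deviation of a recorded reference representation set; each step decodes
  at temperature 0.30. The walk is cumulative — noise compounds across
  steps, so similarity to the start decays in expectation.
* **Directed migration**: AdamW (learning rate $2\times10^{-5}$, 600
  steps) on the representation under
  $L=|J| \cdot 0.2\,|\,\mathrm{sim}_{start}-0.8| + \sum_j |c_j-f_j(E)|$;
  decoding at temperature 0.4. The 0.2 multiplier is read as scaling only
  the similarity term; a flag switches to the alternative precedence.
  Scaffold hopping minimizes $1-\mathrm{sim}_{target}$.
* **Chemical fusion**: AdamW (learning rate $3\times10^{-5}$, 1000
  steps) on $\min_r 1/(1+10000^{\,\mathrm{sim}(E_r,E)-0.6})$, a steep
  sigmoid switching at similarity 0.6. The exponential is evaluated in
  log space, and the gradient flows through the arg-min branch (a hard
  minimum, not a log-sum-exp softening).
* **Ligand efficiency**: $LE=\Delta G/(1+\ln N_{heavy})$, a logarithmic
  size penalty used to keep generated ligands from growing without bound.

**Input standardization.** The encoder's raw representation entries are
unbounded (the gated readout multiplies sums of hidden activations), so
the decoder and the property heads standardize incoming representations
per dimension with statistics fitted once on their training
representations and stored in the model. Without it, large-magnitude
inputs saturate the memory projection and the sigmoid expansion and
gradients vanish. The scaler is a fixed differentiable affine map; all
representation-space gradients (migration, fusion) flow through it.

## Training schedules

All loops use AdamW (base learning rate $5\times10^{-5}$, weight decay
0.01) with a linear warmup from 10% of the base rate over 10000 steps and
a cosine oscillation between the base rate and 50% of it (period 10000
for similarity learning, 4000 for reconstruction, 2000/1000 for property
training), continuous at the junction; the printed period is read as the
full oscillation period. Early stopping monitors validation every 200
steps and stops after 60 evaluations without strict improvement.
Similarity learning samples query-by-reference blocks (512 x 48 at full
scale) and freezes the graph-network parameters for the first 2000 steps;
property training sets the batch size from the training-set size
(96 above 5000 samples, 64 above 1000, else 48). Checkpoints carry
configuration, vocabulary, parameters, batch-norm statistics and
optimizer state, so training resumes bit-identically.

## Numerical engine

No deep-learning framework is assumed: all modules run on an in-package
reverse-mode automatic-differentiation engine over dense matrices (BLAS
underneath), with gather/scatter primitives for graph batching, grouped
softmax for attention pooling, fused stable log-softmax cross-entropy,
batch/layer normalization and rotary rotation. Every primitive is
verified against central finite differences in the test suite, and the
composed encoder is verified against an independent dense loop-based
recomputation on small random graphs.

## Desk-scale profile

The defaults above are the full-scale widths. Tests and the bundled
fixture use a proportional desk profile chosen once: representation width
128 (all head widths scale with it), 16 x 8 similarity blocks, a
2-layer/4-head decoder, base learning rates of $1-2\times10^{-3}$ with
warmup and cosine periods shrunk in proportion to the step counts, and
evaluation every 25-50 steps. Small-batch training at a few hundred steps
needs a proportionally larger learning rate than a 48-million-molecule
run; these values follow that standard scaling and were fixed as part of
the desk design. The fixture itself is a fragment-grammar library (ring
cores, linkers, terminal substituents): 120 training, 16 validation and
16 test molecules with 8 references drawn from the training split, split
so that every cross-split ECFP4 Tanimoto stays below 0.3
(non-homologous splits, enforced by `split_guard`).

The synthetic property default (`composition_score`) combines heteroatom
fraction, aromatic fraction and ring density — intensive quantities that
an attention-pooled (convex-combination) representation can express;
extensive rules such as raw heavy-atom counts are also registered but are
partly erased by the pooling normalization, which is itself a property of
the architecture, not of the fixture.

## What the fixture does and does not show

The grammar guarantees chemical validity, controllable similarity
structure and determinism, which makes the end-to-end contracts testable
offline: similarity learning generalizes across non-homologous splits,
the decoder memorizes and exactly reconstructs a small corpus at low
temperature, property heads recover a deterministic rule, and the
optimization procedures descend their losses. It does **not** emulate the
breadth of a 48-million-molecule library: vocabulary coverage is smaller,
conformational diversity is modest (50 embeddings vs 10000 Monte-Carlo
steps at full scale), macrocycles/charged species are rare, and
generalization numbers on the fixture say nothing quantitative about
benchmark performance on real screening decks. Paper-scale results
require the full corpus, the commercial conformer stack and GPU training,
all outside this package's scope.

## Numerical choices and degenerate inputs

* Rigid molecules (0 rotatable bonds) take the 0.1 kcal/mol window floor
  and a single conformer; self-CSPS is 1 and the flexibility component 0.
* The CSPS difference component and all label components are clamped to
  $[0,1]$.
* Empty graphs cannot be pooled (error); single-atom graphs read out as
  zero vectors and pool with weight 1.
* Gumbel $\epsilon=10^{-10}$; cosine similarity guards zero vectors with
  a $10^{-12}$ floor; the fusion exponential $10000^x$ is computed as
  $\exp(x\ln 10^4)$.
* AdamW near an optimum oscillates with amplitude of order the learning
  rate; monotonicity checks on migration therefore allow increases up to
  $10^{-3}$ of the initial loss, three orders of magnitude below the
  loss scale.
* Gradient norms are clipped at 5 in the training loops to guard the
  early high-learning-rate phase of the desk profile.
* Stereochemistry tokens are retained through canonicalization; the
  tokenizer treats them as ordinary characters.
* The perturbation noise is standard normal; the mask is Bernoulli(0.5).

## Known limitations

* The overlay scorer uses principal-axes alignment with four sign flips
  rather than continuous rotational optimization; scores for dissimilar
  shapes are conservative lower bounds.
* The bond stereo feature is a heuristic flag (directional marks present
  on an acyclic double bond), not a full E/Z perception.
* OpenBabel's permissive parser accepts some malformed SMILES (e.g.
  truncated branches); validity additionally enforces a standard-valence
  table, but exotic valence states may still slip through.
* Fine-tuning re-encodes every batch through the cloned encoder and is
  correspondingly slow at desk scale; projection mode is the default for
  a reason.
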