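---
title: "Methods: equivariant graph networks for interface-site prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: equivariant graph networks for interface-site prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Protein–protein interaction (PPI) sites are the residues of a chain that
contact a partner chain in a complex. *Partner-independent* prediction asks
which residues of an isolated monomer are interface sites, with no knowledge
of the partner. `equippis` casts this as node classification on a residue
graph and solves it with an E(3)-equivariant graph neural network (EGNN): a
message-passing architecture whose node embeddings are provably invariant
under rotations, translations and reflections of the input coordinates,
because coordinates enter the messages only through inter-residue distances.

## Graph representation

A parsed single chain (`parse_structure()`) becomes a graph whose nodes are
residues. Two residues are connected when

* their C$\alpha$ Euclidean distance is at most 14 Å (inclusive), and
* their sequence separation $|i-j|$ is at least 6 (inclusive),

so only longer-range spatial contacts form edges (`build_residue_graph()`).
Both boundaries are inclusive, matching the "no more than"/"minimum"
phrasing conventional for these cutoffs. Each edge carries the scalar

$$a_{ij} = \frac{\log |i-j|}{\lVert x_i - x_j \rVert},$$

coupling sequence separation with spatial proximity. The logarithm base is
not dictated by the formula; we use the natural log and expose the base as
an argument. Residues closer than 6 positions along the chain receive no
edge at all; such nodes can be isolated, which the layers handle (their
aggregated message is zero and the residual path carries the embedding).

## The 118-channel featurization

Each residue carries 118 channels in a fixed block order
(`node_features()`):

| block | channels | content |
|---|---|---|
| `aa_onehot` | 20 | residue identity, alphabet `ACDEFGHIKLMNPQRSTVWY`; `X` rows are all zero |
| `pssm` | 20 | sequence profile scores through a sigmoid, $(0,1)$ |
| `plm` | 33 | protein-language-model embedding through a sigmoid |
| `ss3`, `ss8` | 3 + 8 | one-hot secondary structure (8-state and its helix/strand/coil collapse) |
| `rsa2`, `rsa8` | 2 + 8 | burial at absolute accessibility 50 Å²; 30-Å²-wide bins up to >210 |
| `local_geom` | 11 | C=O bond-vector cosine (1), sin/cos of the C$\alpha$ virtual bond and torsion angles (4), sin/cos of $\phi,\psi,\omega$ (6) |
| `rel_pos` | 2 | $1/i$ and clamped inverse distance to the C$\alpha$ centroid |
| `orient` | 9 | forward, reverse and imputed C$\beta$ unit vectors in the local backbone frame |
| `hull_area` | 1 | inverse surface area of the residue's atomic convex hull |
| `contact_count` | 1 | C$\beta$ neighbors within 8 Å, divided by the chain maximum |

Sequence-based channels total 73, structure-based channels 45.

Several readings had to be fixed where the channel budget alone does not
determine them:

* **Accessibility is absolute.** A "relative" accessibility can never reach
  bins like 180–210, so the cutoff 50 and the 30-wide bins are interpreted
  as DSSP's absolute ACC in Å². The exposed/buried boundary is inclusive
  (ACC $\ge$ 50 is exposed).
* **The 11 local-geometry channels** are split 1 + 4 + 6 to exhaust the
  budget, with "normalized" backbone torsions realized as sin/cos pairs —
  bounded, continuous, and free of the $\pm 180^\circ$ wrap-around.
  Channels undefined at the termini are exactly 0.
* **Orientation vectors live in the local backbone frame.** Written in the
  global frame, the three unit vectors would rotate with the structure and
  the *features* — hence the end-to-end predictions — would not be rotation
  invariant, defeating the architecture's headline property. Expressing
  them in each residue's Gram–Schmidt frame (from the N–C$\alpha$ and
  C–C$\alpha$ bonds) preserves the information content (how chain and side
  chain are oriented relative to the local backbone) and makes the whole
  pipeline invariant. Termini keep zero vectors.
* **C$\beta$ imputation** uses the standard ideal tetrahedral construction
  from N, C$\alpha$, C; the imputed direction is used for the orientation
  block of every residue and for glycine in the contact count.
* **Contact counts** are normalized by the chain maximum (the convention
  "normalized" leaves open; the alternative, dividing by $L$, compresses
  the dynamic range on long chains). No sequence-separation filter is
  applied to contacts.
* **Convex hull areas** come from a facet-enumeration routine adequate for
  residue-sized point sets; degenerate sets (< 4 non-coplanar atoms) give
  feature 0.

When no external DSSP file is supplied, an internal fallback assigns
8-state codes from the $\phi/\psi$ basins and computes accessibility with a
Shrake–Rupley sphere method (92 points, probe 1.4 Å). The sphere directions
are anchored to the molecule's principal axes so that the discrete sampling
rotates with the structure and the areas are rotation invariant. This
fallback distinguishes only H/E/C — sufficient for synthetic fixtures; real
applications should supply `read_dssp()` records. Note that a *mirrored*
structure legitimately changes these features: reflection flips torsion
signs, and a D-protein is a different molecule to the featurizer, though
not to the network itself.

## The equivariant convolution stack

With node embeddings $h_i^l$ and coordinate embeddings $x_i^l$ (initialized
to a linear embedding of the features and the C$\alpha$ coordinates), one
layer computes, over the graph's directed edges,

$$m_{ij} = \phi_e\!\left(h_i^l, h_j^l, \lVert x_i^l - x_j^l \rVert^2, a_{ij}\right),
\qquad
x_i^{l+1} = x_i^l + C \sum_j (x_i^l - x_j^l)\, \phi_x(m_{ij}),$$

with $C = 1/(M-1)$ for $M$ graph nodes, followed by aggregation
$m_i = \sum_j m_{ij}$, an optional attention gate
$m_i \leftarrow \sigma(\phi_a(m_i)) \odot m_i$, and the node update
$h_i^{l+1} = h_i^l + \phi_h(h_i^l \,\Vert\, m_i)$. A linear squeeze and a
sigmoid on the last layer's embeddings give the per-residue interface
probability. The production configuration is 10 layers with hidden width
256; ablation variants are config flags (`update_coordinates = FALSE` for
the invariant network, `use_attention = FALSE` for the no-attention
network).

Choices the equations leave open, and how they are fixed here:

* **Message scope.** The sums formally run over $j \neq i$, but $a_{ij}$ is
  defined only for graph edges; we aggregate over the graph's edges, and a
  `fully_connected` flag implements the all-pairs reading (computing
  $a_{ij}$ for every pair, with $\log\max(|i-j|,1)$ so adjacent pairs are
  defined).
* **MLP shapes.** $\phi_e$, $\phi_h$ are two-layer perceptrons with SiLU;
  $\phi_x$ is a two-layer perceptron to a scalar; $\phi_a$ is linear +
  sigmoid with elementwise gate width equal to the hidden dimension. The
  attention gate acts on the *aggregated* per-node message, not per edge.
* **Residual connections** on $h$ and an initial 118$\to$hidden linear
  embedding are required for a trainable 10-layer stack.
* **Numerical conditioning.** Two fixed reparameterizations stabilize the
  stack without altering the model family: the coordinate-weight output
  layer is initialized at gain $10^{-3}$ (otherwise coordinate updates
  compound exponentially with depth and the forward pass saturates at
  initialization), and the squared distance entering $\phi_e$ is scaled by
  a constant $1/100$ so that this input is on the same order as the other
  unit-scale channels (absorbable into the first $\phi_e$ layer; without it
  the optimizer spends its budget unlearning the scale). An optional
  `clamp_coord` flag bounds the coordinate weights to $[-100, 100]$ for
  very deep stacks; it is off by default.

Because distances are the only coordinate functional in the messages, node
embeddings are invariant — and coordinate embeddings equivariant — under
the full E(3) group including reflections, to floating-point accuracy
(verified to $10^{-8}$ in double precision over 100 random rigid motions).

## Training

`train_model()` (or the `equippis_fit()` front end) optimizes the plain
unweighted binary cross-entropy over all residues, one labeled graph per
Adam step, with decoupled weight decay ($10^{-16}$ by default) and a cosine
annealing of the learning rate from its initial value to 0 over
`max_epochs` (no warm restarts). The checkpoint keeps the epoch with the
best pooled validation PR-AUC; training is bit-reproducible given the
seeds. An optional positive-class weight is exposed but off by default:
interface data is imbalanced (roughly 1:5), but plain BCE is the stated
loss and ranking metrics are unaffected by a monotone recalibration.

The production defaults (learning rate $10^{-4}$, up to 50 epochs, 10
layers $\times$ 256 hidden) correspond to full-scale training on hundreds
of real complexes. The package's desk-scale experiments — the test suite
and the acceptance script — use a 2-layer/32-hidden network on 20–30
synthetic complexes of 25–45 residues, trained for 20 epochs at learning
rate $5 \times 10^{-3}$: a small model trained for 400 steps needs a
proportionally larger rate, chosen once for this configuration.

## Metrics and the significance procedure

Thresholded metrics follow the standard confusion-matrix formulas, with
zero denominators reported as 0 (the usual MCC convention). ROC-AUC uses
the rank (Mann–Whitney) form with midrank tie-averaging; PR-AUC uses step
integration over recall increments with tied scores processed as one group
(the average-precision convention). Thresholds, when not given, maximize F1
with ties broken toward the lowest cutpoint.

The resampling significance procedure draws the same random 70 % of the
targets for two methods, pools the residues of the subset (per-target
averaging is exposed as an option), scores F1, MCC, ROC-AUC and PR-AUC,
and repeats 10 times. Per metric, normality of each method's scores is
assessed by the Anderson–Darling test at the 5 % level (both methods must
pass); normal pairs get a two-sided paired t-test. For the non-normal
branch the field's nomenclature commonly says "Wilcoxon rank sum" even for
paired designs; the statistically coherent test on paired scores is the
signed-rank test, which is the default here, with the rank-sum flavor
available via an argument. Identical scores in every resample give p = 1
by convention, with a warning.

## What the synthetic data does and does not emulate

`make_monomer()` builds backbones from ideal internal coordinates by
sequential NeRF placement: ideal $\alpha$-helices
($\phi=-57^\circ, \psi=-47^\circ$; consecutive C$\alpha$ 3.8 Å, rise
$\approx$ 1.5 Å, $\approx$ 100°/turn, radius $\approx$ 2.3 Å), perturbed
extended coils, or random alternations of the two. `make_labeled_complex()`
poses a second chain against the first and labels receptor residues with
any heavy atom within 8 Å of any ligand heavy atom — a stand-in geometry,
*not* the labeling convention of any published benchmark.

Two generator choices matter for interpreting the tests:

* **The docking site is receptor-intrinsic.** The ligand approaches along
  the receptor's centroid-to-N-terminus direction. With a uniformly random
  approach direction, which face the ligand touches would be independent
  of every partner-independent feature, capping the achievable ROC-AUC
  near 0.75 regardless of model quality; planting the interface at a
  reproducible geometric site makes the labels recoverable, so the
  parameter-recovery experiment measures the pipeline, not an impossible
  task. The ligand is kept compact (a quarter of the receptor length) so
  the contact patch depends only weakly on its random orientation.
* **Profiles and embeddings are noise.** The mock providers emit
  deterministic pseudo-random matrices keyed by (seed, sequence) — the
  right shapes and ranges, but no evolutionary or semantic signal. Passing
  tests therefore demonstrate correct mechanics and a learnable geometric
  signal; they say nothing about accuracy on real complexes with real
  PSSMs and language-model embeddings.

The pooled positive fraction is kept in [0.05, 0.40] (regenerating
otherwise) to mimic the roughly 16 % imbalance of real interface data.

## Known limitations

* The internal secondary-structure fallback is a $\phi/\psi$ heuristic; it
  never emits G/I/B/T/S codes. Supply real DSSP output where available.
* Single chains only: no complexes, nucleic acids, ligands, or assemblies.
* The fallback accessibility and the hull areas are exact only up to the
  92-point sphere discretization and the facet tolerance, respectively.
* Reflection invariance holds for the network given fixed features; a
  mirrored input structure re-featurizes differently (by design — torsion
  signs flip).
* PSI-BLAST and language-model inference are consumed through files or
  provider callables, never executed by the package.
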