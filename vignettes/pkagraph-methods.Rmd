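---
title: "Chemistry-guided graph attention for microscopic pKa: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chemistry-guided graph attention for microscopic pKa: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pkagraph)
```

# The problem

The microscopic pKa of an ionizable site — one specific atom gaining or
losing a proton in one specific protonation state — is governed by a small
set of effects every organic chemistry student learns: the electronegativity
of nearby atoms and the inductive pull they exert through bonds, resonance
stabilization of the conjugate base, the charge state of the center and of
the rest of the molecule, hybridization, ring strain, and the local hydrogen
count. `pkagraph` encodes these effects directly as atom and bond features
of a molecular graph and regresses pKa with a masked multi-head
graph-attention network, rather than leaving a generic model to rediscover
them from categorical atom types.

# The paired molecular graph

Every training or scoring example is a conjugate acid/base *pair* sharing
one heavy-atom skeleton (the two forms differ by exactly one proton, which
is implicit — hydrogens are counts on heavy atoms, never explicit nodes).
The ionization center is always atom 1. Per atom and per form the features
are:

| feature            | type      | normalization                         |
|--------------------|-----------|---------------------------------------|
| electronegativity  | interval  | min–max over the element registry     |
| hardness           | interval  | min–max over the element registry     |
| atomic diameter    | interval  | min–max over the element registry     |
| formal charge      | integer   | none (already small)                  |
| hybridization      | one-hot   | sp / sp2 / sp3 / other                |
| smallest ring size | interval  | capped at 8, 0 if acyclic, /8         |
| hydrogen count     | interval  | capped at 4, /4                       |
| element one-hot    | optional  | off by default                        |

The scalar properties come from a versioned registry (Pauling
electronegativities, Pearson absolute hardness in eV, diameters as twice
the single-bond covalent radius) shipped as CSV for H, B, C, N, O, F, Si,
P, S, Cl, Se, Br and I. Normalization bounds are fixed over that registry,
never recomputed per dataset, so a feature vector means the same thing at
training time and on an arbitrary unseen molecule. An element outside the
registry is a hard error, never a silent zero. Model checkpoints embed the
registry version and refuse to load under a different one.

Per bond and per form there are seven features: a bond-order one-hot
(single / delocalized-aromatic / double / triple), two conjugation
indicators, and one signed polarization scalar. Concatenating acid and base
blocks gives 14 bond features; the *focused* mode treats acid and base bond
orders as equivalent and drops the base-form one-hot, giving 10. The
14-and-10 totals are fixed contracts; the 4+2+1 partition per form is this
package's choice of how to fill them, and it is where the revised
conjugation block lives. Acid-only and base-only modes keep a single form's
atom and bond blocks.

Two *molecular* features — the net charge of the base form and the center's
formal charge — are deliberately kept out of the graph and appended after
pooling, since they modulate pKa globally rather than through any one bond
path. They are two scalar slots, not literal bits: charges exceed {0, 1}.

## Revised conjugation

Conventional conjugation perception marks a carboxylic acid and its
carboxylate identically conjugated, yet the delocalization that actually
stabilizes the anion exists only in the base form. The package therefore
uses its own two-part definition:

* **conjugated** — both endpoints of the bond are π-system atoms or
  lone-pair donors, and at least one is a π atom (alternating
  multiple-bond/donor paths, aromatic systems);
* **enhanced resonance** — the bond belongs to a delocalized anionic
  group: a single bond from a negatively charged N/O/S/Se donor to a
  π atom, together with that π atom's double bonds to heteroatoms.

Bonds flagged enhanced are treated as one symmetric delocalized group:
their bond order is reported in the delocalized (aromatic) slot and their
polarization is directed away from the group's π-core atom rather than away
from the ionization center. Within such a group a per-bond direction
relative to the center is ill-defined — in acetate the two C–O bonds are
chemically equivalent, and after symmetrization they are feature-identical,
while the neutral acid's C–O(H) bond differs from its C=O. This is the
designed discrimination between an acid and its conjugate base.

## Directed polarization

For a bond whose atoms sit at different graph distances from the center,
polarization is EN(farther) − EN(closer) in Pauling units: an
electron-withdrawing substituent "pulls" with a positive sign regardless of
which side of the molecule it sits on, and relocating the center across a
bond flips the sign. Atoms equidistant from the center (possible in odd
cycles) get 0 — no direction is defined, and zero is the symmetric choice.

# The regressor

The model is a GATv2-style attention network with edge features. For layer
$l$ with $K$ heads of width $d$, the attention logit of directed edge
$j \to i$ is

$$ e_{ij} = a^\top \,\mathrm{LeakyReLU}\!\left(W_s h_j + W_d h_i + W_e x_{ij} + b\right), $$

with the score vector applied *after* the nonlinearity (the dynamic-attention
correction). Softmax runs over each destination's in-neighborhood (self
loops included, with zero edge features), and messages are the
attention-weighted source transforms, concatenated across heads and passed
through an ELU. Dropout, when enabled, acts on the node embeddings between
layers during training only.

**Masked readout.** After $L$ layers, sum pooling runs only over atoms
within $m$ bonds of the center; more distant atoms participate in message
passing but are concealed from the readout. A pooled atom at distance $m$
has aggregated information from $L$ bonds further out, so the effective
receptive radius is exactly $L + m$: an edit $L+m+1$ bonds from the center
cannot change the prediction (bitwise — the unchanged floating-point
summations are identical), and this is tested. Masking the readout rather
than the message passing is the only semantics under which one layer plus a
mask of six accounts for atoms seven bonds away. Sum pooling (not mean) is
used so molecule size information survives.

The pooled embedding, with the two molecular features appended, passes
through two fully connected layers (ReLU between) to a single scalar.

**Training.** Adam on the L1 loss by default — the reported metric is MAE,
so the loss optimizes what is measured; MSE is available by configuration.
The learning rate follows cosine decay to zero over the fixed epoch budget
(no early stopping; with a validation set the best-validation weights are
kept). The output bias is initialized at the label mean so the network only
learns shifts. One seed determines initialization, shuffling and dropout,
making every training log bitwise reproducible. Replicate runs use three
seeds and report the median test MAE, so a lucky initialization never
carries a conclusion. Numerical details: Glorot-uniform initialization,
grouped softmax stabilized by per-destination maxima, gradients checked
against numerical differentiation in the test suite, NaN loss aborts with a
diagnostic. Defaults (4 heads, hidden width 64, dropout 0.1, the shipped
grid over learning rate {1e-3, 3e-4} × hidden {64, 128} × dropout
{0, 0.2} × batch {32, 64}) are ordinary choices where no principled value
exists; grid search is exhaustive with ties broken toward grid order.

# Ionizable sites and the iterative protocol

Site detection is a rule table of named substructure patterns (a SMARTS
subset: element/aromaticity/charge/H-count/degree/ring primitives, AND/OR
logic, recursive environments with negation), shipped as an editable TSV
and validated entirely at load time. The default taxonomy: carboxylic and
other oxyacids, phenols, thiols, sulfonamide and imide N–H, azole N–H
acidic; aliphatic amines, pyridine-type ring nitrogens, amidines/guanidines
and imines basic. Two deliberate exclusions mirror chemical practice:
simple alcohols on sp3 carbons (pKa typically above 14) and terminal amides
are not centers. Activated C–H acids (1,3-dicarbonyls) are matched only on
request, since many benchmark conventions exclude carbon centers.

The multi-center protocol starts from the fully deprotonated microstate and
iterates: every remaining unprotonated site is scored *in the current
microstate* (the state is the base form; that state plus one proton at the
site is the acid form), the highest-pKa site is protonated and its value
recorded, until all sites are protonated. Sites are deliberately rescored
every iteration — protonating one center shifts the microscopic pKa of the
others. Equal scores protonate the lowest atom index first, for
determinism. The recorded sequence is most-basic-first; with a
deterministic injective scorer it is strictly decreasing, while a learned
scorer can violate monotonicity within its own noise. The dominant state at
a pH (default 7.4, physiological, user-settable) protonates exactly the
sites whose recorded pKa exceeds the pH — glycine at pH 7 comes out as the
zwitterion.

# Data pipeline

**Similarity-capped splitting.** Molecules are fingerprinted with 2048-bit
circular fingerprints (radius 2) computed directly on the graph with
order-independent invariant hashing. Clusters are the connected components
of the "Tanimoto > cap" graph — single-linkage at the cap, i.e. the
transitive closure of sphere exclusion. This is the weakest clustering that
makes the guarantee exact: whole components assigned to one side means *no*
train/test pair can exceed the cap, which an unmerged sphere-exclusion
clustering does not guarantee. Components are assigned greedily (largest
first) to reach the requested test fraction; a deviation beyond five
percentage points aborts with the blocking cluster named. Every split's
report carries an exhaustively verified maximum cross-set similarity. A
seeded uniform random split is exposed alongside, because the gap between
the two split styles is itself a finding worth reproducing — random splits
flatter a model by letting it be tested on near-neighbors of its training
set.

**Augmentation.** Each graph yields 50 randomized isomorphs by default
(atom order permuted, center fixed at index 1, labels carried over),
generated once at dataset build for reproducibility rather than per epoch.

**Records.** CSV with `smiles`, `pka`, optional `center` and `split`.
Unparseable SMILES are collected into a rejects report, never silently
dropped; duplicate SMILES with conflicting labels keep the first occurrence
and log the conflict.

# The synthetic study

The generator emulates the one physical effect the model must demonstrably
learn: through-bond inductive attenuation. A linear chain carries one
ionizable head group (carboxylic acid, pKa0 4.8; primary amine, 10.6;
thiol, 10.5 — textbook-range base values) and at most one substituent
(F, Cl, Br, I, nitrile, methoxy, trifluoromethyl, methyl with shifts from
−3.3 to +0.3, the magnitudes of familiar α-substitutions), and the ground
truth is

$$ \mathrm{p}K_a = \mathrm{p}K_{a,0} + \Delta \cdot \rho^{\,d-1} + \varepsilon, $$

with attenuation ρ = 0.4 per bond, Gaussian noise σ = 0.1, and $d$ the
substituent–center bond distance minus one. Substituent distances 1–7 are
all realized, so receptive-field experiments can probe shifts at and beyond
the model's radius.

What this emulates: geometric inductive decay, head-group identity, the
acid/base charge bookkeeping. What it does not: resonance-rich scaffolds,
tautomerism, intramolecular hydrogen bonds, conformational effects,
heteroscedastic experimental error, and the sheer diversity of real
chemical space. A model passing the synthetic recovery study has
demonstrably learned distance-attenuated electronegativity effects through
graph attention; it has *not* been validated as a production pKa predictor
— that requires curated experimental data, which this package reads but
does not ship.

Problem sizes used by the shipped tests, chosen as a desk-scale study: the
parameter-recovery experiment trains the L = 3, m = 4 configuration on a
2000-molecule library (cluster-split at 0.65, three seeds, 60 epochs,
hidden width 64, batch 64, learning rate 3e-3 with cosine decay) and
requires median held-out MAE at or below 0.3 pKa units together with
monotone decay of the predicted shift magnitude across distances 1–7; the
overfit sanity check memorizes 50 noise-free molecules to under 0.1 MAE;
split soundness is scanned exhaustively on 500 molecules.

# Baselines

Random forest (500 trees) and gradient-boosted trees (300 rounds, depth 6,
learning rate 0.1), seeded and single-threaded, over Morgan fingerprints,
MACCS keys (OpenBabel, standard 166 keys), a documented set of 16
two-dimensional descriptors, and electrotopological-state fingerprints
(Kier–Hall intrinsic states perturbed by topological distance, aggregated
over an element × aromaticity × has-hydrogen type vocabulary — a documented
reduced typing rather than the historical 79-type table). Baselines predict
one macro value per molecule and are never fed per-site tasks; the harness
labels them as such. On the synthetic study they lose to the graph model
precisely because a fingerprint cannot represent the substituent-to-center
distance driving the planted decay.

# Known limitations

* Perception is native and organic-subset only: no stereochemistry, no
  isotopes, no tautomer enumeration, no aromatizing kekulization of
  alternating Kekulé input (aromatic rings should be written in aromatic
  SMILES), hybridization from bond patterns only.
* The conjugation definition is a documented stand-in constrained by the
  carboxylate/acid discrimination requirement; enhanced resonance covers
  anionic delocalization, not cationic (amidinium-type) symmetry.
* The site taxonomy is this package's default, editable by the user; it is
  smaller than exhaustive pharmaceutical rule sets.
* Macro-pKa aggregation across microstates and tautomer-consistent
  reconciliation are out of scope.
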