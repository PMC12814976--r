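---
title: "Methods: fragment-based dual conditional diffusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fragment-based dual conditional diffusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Structure-based drug design asks for 3D molecules that fit a protein
binding pocket. A drug-like molecule is not a uniform cloud of atoms: a
rigid **scaffold** fixes its global topology and binding pose, while
peripheral **R-groups** tune local physicochemical properties. `fragdiff`
models the two parts with two separately trained conditional denoising
diffusion processes:

1. **Scaffold stage.** Conditioned on the pocket `G^P`, a seed fragment
   `F` and its anchor atoms (the cleavage sites marking valid growth
   positions), the model denoises `n_new` atoms from Gaussian noise into a
   scaffold completion. The fragment and pocket coordinates are frozen
   throughout.
2. **R-group stage.** Conditioned on the pocket and the (generated or
   given) scaffold, the model denoises exactly 10 padded atom slots; a
   dedicated *virtual* type category absorbs unused slots, which are
   dropped at decoding. This is how a fixed-shape network generates
   variable-size R-groups.

Both stages share one forward model, the variance-preserving chain

&nbsp;&nbsp;`q(x_t | x_{t-1}) = N(sqrt(1 - beta_t) x_{t-1}, beta_t I)`,

with closed-form marginal `x_t = sqrt(abar_t) x0 + sqrt(1 - abar_t) eps`,
`abar_t = prod_s (1 - beta_s)`. States comprise both Cartesian coordinates
(Å) and continuous relaxations of the one-hot type channels; decoding
takes the arg-max category at `t = 0`. Training minimizes the L2 loss
between true and predicted noise over the generated atoms' coordinate and
type channels; the two stages never share parameters (decoupled training),
and gradients are clipped by global norm.

Schedules: the scaffold stage uses the standard linear schedule
(`beta` from 1e-4 to 0.02 inclusive); the R-group stage uses a polynomial
schedule `abar_t = (1 - (t/T)^p)^2` (default `p = 2`), with betas derived
from successive `abar` ratios and clipped to `[1e-5, 0.999]`. The
polynomial form follows the equivariant-diffusion lineage; whether the
scaffold stage could also use it is left configurable (`fd_make_schedule`).

## The equivariant denoiser

The noise predictor is a stack of E(3)-equivariant graph convolution
layers over the fully connected graph of context and noisy atoms. Messages
and feature updates consume only scalars — node features, squared
distances and a Gaussian radial-basis expansion of the distance
(`K = 16` centers uniform on `[0, d_max = 10 Å]`, bandwidth `d_max/K`) —
so they are invariant under rigid motions; coordinate updates are linear
in relative positions (`(r_i - r_j) / (d_ij + 1)` times a learned scalar),
so they are equivariant; and context atoms receive a hard zero coordinate
update at every layer. The predicted coordinate noise is the final minus
the initial coordinates of the noisy atoms. Two conventions fix the
translation gauge: the system is centered on the context centroid before
the network runs, and the input coordinates are subtracted from the
coordinate output.

Design choices where the architecture was genuinely open:

* **Time conditioning.** `t/T` plus sinusoidal features at frequencies
  1, 2, 4, 8 are appended to every node. A single scalar proved too weak
  for the network to resolve the strongly time-dependent noise scale.
* **Role flags.** Four one-hot roles (pocket / fragment / scaffold /
  generated) plus one anchor bit let a single architecture serve both
  stages' context kinds.
* **Clean-state parameterization.** Reading the raw output-minus-input
  difference directly as predicted noise forces the network to represent
  an amplification of `1 / sqrt(1 - abar_t)` — two orders of magnitude
  across `t` — which a desk-scale network cannot do smoothly. Instead the
  network's final coordinates (and the feature head) are read as the
  predicted clean state `x0hat`, and the noise follows analytically from
  the forward marginal, `eps = (x_t - sqrt(abar_t) x0hat) /
  sqrt(1 - abar_t)`. The two parameterizations are algebraically
  equivalent families; the clean-state form moves the hard
  time-dependent rescaling out of the learned function. The training
  objective is still exactly the L2 noise loss.
* **Optimizer.** Adam at the configured learning rate with global-norm
  clipping (default 1.0); checkpoints hold an exponential moving average
  of the weights (decay 0.995), which sampling and evaluation use —
  standard diffusion practice that stabilizes the noisy small-batch
  objective.
* **Batch normalization** in the feature update always uses the current
  graph's node statistics, at sampling time as well as in training. The
  alternative — frozen running statistics — systematically mis-normalizes
  the small-`t` regime, because activation scales are strongly
  time-dependent while the running average pools all `t`; on an overfit
  check it inflated the evaluated noise loss by two orders of magnitude.
* **Sampling guard.** Late polynomial-schedule steps divide by
  `sqrt(1 - beta_t)` with `beta_t` near 1; after each reverse step every
  generated atom is radially clamped to 15 Å of the initialization
  center (type channels to ±5) so an imperfect prediction cannot diverge.
  The radial form commutes with rotations, preserving the sampler's
  rigid-motion covariance.
* **Type-channel scale.** One-hot type channels are diffused at scale 4
  (decoding by arg-max is scale free). At unit scale the type signal
  drowns in unit Gaussian noise over most of the schedule and reverse
  trajectories under-commit — R-group samples collapsed to all-virtual;
  the larger channel magnitude lets slot types commit mid-trajectory.
  For the same reason the padded R-group slots, which are exchangeable,
  are randomly reordered at each training presentation, so the model
  learns the joint exactly-one-real structure rather than a privileged
  slot index.
* **Initialization frame.** New scaffold atoms start from noise centered
  on the anchors' centroid; R-group slots on the scaffold attachment atom
  (anchors are spatial growth sites, and pure origin-centering would
  ignore the pocket frame).

## Reaction-informed preprocessing

Training tuples `(pocket, seed, scaffold, R-group)` are produced by:

1. **Template slicing.** Each ligand is cut at single acyclic bonds
   matched by reaction templates (amide, ester, ethers, sulfonamide,
   amines, benzylic coupling, thioether, aryl halide). The larger
   component is the scaffold (ties break on a canonical graph signature).
   The shipped file holds a 10-template starter subset — the full curated
   set of 37 synthesis templates is not redistributable — with SMIRKS
   strings carried as documentation; matching itself is a typed rule
   engine over the molecular graph, since no general SMARTS interpreter
   is available in this toolchain.
2. **BRICS cutting** of each scaffold into candidate seed fragments. The
   16 link environments and their compatibility matrix are implemented as
   graph predicates; on a 169-molecule panel (the fixture catalog plus
   seeded random molecules) the cleaved-bond sets agree exactly with a
   reference implementation, and those expectations are frozen into the
   test suite.
3. **Rule-of-Three filtering** of seeds: MW < 300 Da, logP ≤ 3,
   ≤ 3 donors (N–H/O–H), ≤ 3 acceptors (N/O), TPSA ≤ 60 Å², zero
   rotatable bonds — the filter is exactly this six-way conjunction.
   Order of operations is slice → BRICS → filter. logP is the
   octanol–water estimate (atom contributions) and TPSA the topological
   method, both via OpenBabel; logD at pH 7.4 is not implemented (it
   would need pKa prediction). MW, donor/acceptor and rotatable-bond
   counts are computed natively on the heavy-atom graph with implicit
   hydrogens; anchor positions count as hydrogen-capped open valences.

## Bond reconstruction

Generated atoms carry no bonds. Candidate edges are all pairs within 3 Å;
an edge-focused iterative refiner (3 iterations: node-context
aggregation, edge update with distances, node update) classifies each
candidate over five classes — single, double, aromatic, triple, and
**none**. The fifth class is a deliberate addition: a four-way softmax
alone cannot reject the non-bonded 1–3 contacts that a 3 Å cutoff
necessarily admits. A deterministic fallback perceives bonds from
covalent radii (accept within 1.3× the radius sum, in distance order,
under per-element valence caps) and assigns orders by nearest tabulated
reference length (aromatic considered only for ring bonds), upgrading in
confidence order within residual valence. On the ideal-geometry catalog
the fallback reproduces every reference bond list exactly, which makes it
the refiner's training oracle; the refiner is trained with per-edge
cross-entropy under Gaussian coordinate jitter (σ = 0.1 Å) so it
tolerates distorted geometries.

## The evaluation battery

* **QED** — the published desirability-product over MW, logP, HBA, HBD,
  TPSA, rotatable bonds, aromatic rings and structural alerts, with the
  published weights. The alert term uses a compact, procedurally matched
  motif set (aldehyde, acyl/alkyl halide, nitro, azo, peroxide, thiol,
  N-halogen, Michael-type patterns), a reduced surrogate for the full
  published alert list.
* **Synthetic accessibility** — a native synthesis-complexity estimator on
  the 1 (easy) – 10 (hard) raw scale, normalized as `(10 - raw) / 9` so
  higher is easier: size, ring-fusion/spiro, macrocycle, heteroelement
  diversity and flexibility penalties. The classical fragment-contribution
  score needs an external ~25 MB empirical fragment database that cannot
  ship with the package; this estimator is the package's own and is
  labeled as such.
* **Lipinski compliance** — the number of Rule-of-Five criteria met
  (0–5: MW ≤ 500, logP ≤ 5, HBD ≤ 5, HBA ≤ 10, rotatable bonds ≤ 10).
* **R value** — non-carbon heavy atoms over heavy atoms (drug-like range
  0.05–0.50).
* **Similarity / diversity** — Tanimoto over 2048-bit circular
  (radius-2) fingerprints computed on element/degree/H-count/ring
  invariants; diversity is 1 − mean pairwise similarity, reference
  similarity the mean best match against a reference set.
* **Geometric distributions** — bond lengths (Å), bond angles and
  dihedrals (radians) for element patterns such as `C-O`, `C-O-C`,
  `C-C-C-C`, as normalized histograms on shared bins (64 uniform bins;
  lengths on [0.5, 3] Å, angles [0, π], dihedrals [−π, π]) compared by
  KL divergence with the second argument floored at 1e-10.

## Synthetic fixtures: what they emulate and what they do not

Nothing in the package requires external data. The fixture catalog builds
~19 small molecules (alkanes, alcohols, ethers, amines, carbonyls,
aromatics, a chair cyclohexane) from tabulated bond lengths and canonical
angles, each with a reference bond list consistent with its geometry
(bonded pairs < 1.9 Å, non-bonded heavy pairs > 2.2 Å) and a coherent
fragment ⊆ scaffold ⊂ molecule partition with anchors on the partition
boundary. Toy complexes surround a catalog ligand with a seeded shell of
16 pseudo-atoms at a configurable radius (default 8 Å in the demo; the
radius must exceed the ligand extent); a seeded random-molecule generator
assembles drug-like heavy-atom graphs from motif blocks for
fragmentation-scale tests.

These fixtures exercise the machinery — equivariance, conditioning,
partitioning, bond perception, filtering — at desk scale. They do not
emulate real binding-site chemistry: pocket pseudo-atoms have no residue
structure or physics, toy ligands are small and strain-free, and
overfit-recovery experiments (train on one complex, regenerate its held
target) demonstrate that the conditional machinery can concentrate mass
on a known answer, not that the model generalizes across pockets.
Conclusions about real-data performance would require the full corpus
training that is outside this package's scope.

## Problem sizes and numerical choices

Desk-scale defaults, chosen once for the bundled experiments: `T = 100`
steps for stage-level experiments (training configs default to
`T = 1000`, standard practice, configurable); denoiser with 3 layers and
hidden width 40–48 for overfit experiments (the full-scale default is 6
layers × 128, as configured); batch size 1 and ≤ 3000 Adam steps at
learning rate ~1e-3 for single-complex overfits; the demo pipeline uses 2
layers × 32, `T = 50`, 250 steps per stage on three toy complexes. The
bond refiner trains for ~150 epochs over the catalog with jitter
augmentation. Randomness is always routed through a seed argument;
repeated runs are bit-identical.

Known limitations: no stereochemistry (wedge/hash bonds, chirality), no
formal charges or protonation states, no mmCIF input, pockets are
represented by all heavy atoms (the alternative Cα or residue-type
representations were not implemented), and the joint generation of bonds
with coordinates is explicitly out of scope — bonds are reconstructed
after sampling, so the generator can emit geometries whose best bond
assignment is still chemically invalid; such records are flagged, never
silently dropped.
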