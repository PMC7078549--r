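---
title: "Methods: elastic-network dynamics comparison of GNAT-fold domains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: elastic-network dynamics comparison of GNAT-fold domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(natdyn)
```

This vignette is the package's account of its models, parameters and the
design choices that were genuinely open. It states no empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## The model

A protein chain is reduced to its Cα atoms (plus, optionally, an 11-bead
coarse-grained acetyl-CoA). Every pair of nodes is joined by a Hookean
spring at its crystallographic separation, so the crystal structure is
the energy minimum by construction. The pair potential is
$V_{ij} = \tfrac{k_{ij}}{2}(\lVert r_{ij}\rVert - \lVert r^0_{ij}\rVert)^2$
with the distance-dependent force constant

$$k_{ij} = \begin{cases} a\,r^0_{ij} - b & r^0_{ij} < d \\
c\,(r^0_{ij})^{-6} & r^0_{ij} \ge d \end{cases}$$

with defaults $a = 8.6\times10^5$ kJ mol⁻¹ nm⁻³, $b = 2.39\times10^5$
kJ mol⁻¹ nm⁻², $c = 128$ kJ mol⁻¹ nm⁴, $d = 0.4$ nm (all configurable in
`enm_constants()`). Three numerical points about this law as
implemented:

* **Units.** Coordinates are Å everywhere in the package (PDB files,
  RMSDs and tunnel areas are Å-based); distances are converted to nm
  only inside the force-constant and energy evaluations. Eigenvalues
  are therefore in kJ mol⁻¹ nm⁻².
* **The $b$ unit.** Dimensional consistency of $k_{ij}$ requires $b$ in
  kJ mol⁻¹ nm⁻², and that is how it is implemented.
* **Discontinuity and clamping.** The law is discontinuous at $d$
  ($a d - b = 1.05\times10^5$ vs $c d^{-6} \approx 3.1\times10^4$); the
  branch is chosen strictly by $r^0 < d$, exactly as printed. The
  short-range branch turns negative below $b/a \approx 0.278$ nm; such
  pairs (which do not occur in plausible Cα geometry) are clamped to
  zero with a warning.

No cutoff is applied by default — the $r^{-6}$ branch makes distant
pairs negligibly stiff on its own. A hard cutoff is available for
speed; measurements on the package's domain-sized synthetic folds put
the change in the six lowest internal eigenvalues at ~0.01% for a 4.0 nm
cutoff, ~0.8% at 3.5 nm and 2–3% at 2.5–3.0 nm, so 4.0 nm is the
documented recommendation.

Normal modes come from a dense symmetric eigendecomposition of the
3N×3N Hessian with uniform unit masses (no mass weighting: the model is
a Cα force field, and cofactor beads are treated like residue nodes).
Rigid-body modes are identified by count (six for any non-collinear
connected network, five for collinear toy systems) and verified to be
numerically zero; the stored rigid/internal separator is the geometric
mean of the last rigid and first internal eigenvalue, which is robust
even when the softest internal mode is itself small. Disconnected
networks are refused (components found on the spring graph).

Fluctuations are $F_i = \sum_{m\ge7} \lVert d_{mi}\rVert^2/\lambda_m$.
The published profile has no printed normalization; the package divides
by the mean (profile averages 1), which preserves shape and makes
cross-protein overlays comparable; the constant is returned alongside.
Correlations use the same inverse-eigenvalue weighting with the raw
$F_i$ in the denominator, giving $C_{ii}=1$ exactly.

## Dynamics similarity (Bhattacharyya)

Each structure's internal-mode covariance
$\Sigma = \sum_{m\ge7} v_m v_m^\top/\lambda_m$ (the Hessian
pseudo-inverse — an identity the tests verify against `MASS::ginv`) is
rotated into the common superposition frame and marginalized to the
aligned core. The Bhattacharyya coefficient between two zero-mean
Gaussians is evaluated in the principal subspace of $(A+B)/2$ retaining
95% of its variance (configurable). The projection regularizes the
determinant form, which is singular for rank-deficient covariances; the
absolute BC values depend on the retained fraction, so the analysis
surface is the *clustering topology* over the distance $1-\mathrm{BC}$,
not individual matrix cells. Average linkage is the default (the
linkage behind the original heatmaps is not documented; it is
configurable).

## Aligned cores

The primary path for real datasets is an externally produced
structure-based alignment (gapped FASTA): the core is the set of columns
with no gap in any record. So that the pipeline also runs with no
external tool, `iterative_core_align()` pairwise-aligns each structure
to a reference by iterated superposition + nearest-Cα correspondence
(4.0 Å cutoff, one-to-one, kept sequential via longest increasing
subsequence, max 50 iterations) and intersects the pairwise maps. It is
deterministic, but it is a stand-in: its core will generally differ
from a dedicated multiple structure aligner's.

## Conformers

`displace_along_mode()` uses the convention $x = x_0 + s\,A\,v_m$ with
$v_m$ unit-normalized over 3N and $A$ in Å, so the Cα RMSD to the parent
is exactly $A/\sqrt{N}$ — with the reference amplitude $A=15$ that is
1.2–1.4 Å for domain-sized proteins (N ≈ 120–180), comfortably within
the ≤2 Å regime in which mode-following is meaningful.

Relaxation minimizes the full anharmonic network energy over
coefficients of the six rigid modes plus the `k = 20` lowest internal
modes (BFGS with the analytic gradient, cap 500 iterations). Two
details matter:

* **The displaced mode is excluded from the basis** when relaxing a
  conformer. The elastic energy's global minimum is the parent
  structure, so minimizing over a basis containing the displaced mode
  simply undoes the displacement; excluding it holds the imposed
  deformation while the remaining soft modes release local strain.
* **Rigid gauge fixing.** The energy is exactly flat along rigid-body
  motion, so the optimizer's endpoint is superimposed back onto its
  input; this changes nothing energetic and makes reported RMSDs
  meaningful.

On the synthetic folds, soft modes are near-rotations of subdomains, so
their linear extrapolation strains stiff virtual bonds at second order
and relaxation releases a large fraction of that energy by moving
1.5–2.5× the imposed RMSD into other soft modes — noticeably more than
for crystal structures of real domains. The tests bound the drift at
2.5× on synthetic inputs for that reason. Physics-based refinement
(side-chain repacking, force-field relaxation) is out of scope; the
all-atom rebuild (per-residue rigid transforms from 3-residue sliding
Cα windows) is followed by a steric-clash report (heavy-atom pairs at
residue separation ≥ 2 closer than 2.4 Å) as the structural-quality
check.

## Tunnel cross-sections

The tunnel axis is defined by three anchor residues: their Cα plane's
normal through the centroid, extended ±15 Å, oriented so positive
offsets point toward the protein's centre of geometry. At each offset
(default step 0.5 Å, matching overlapping 1 Å spheres along the 30 Å
line), a 0.25 Å grid on the 6 Å-radius disc is classified free/occupied
against heavy-atom van der Waals radii (C 1.70, N 1.55, O 1.52, S 1.80
Å; no probe inflation by default since conformers are compared to each
other); only the connected free region containing (or nearest) the axis
point counts, and its area is the free fraction times $\pi r^2$. This
is a deliberate simplification of surface-extrusion cavity tools: the
analysis consumes only area-vs-offset curves, which the grid computes
directly. An outer-surface probe is unnecessary under this formulation
and is omitted. Absolute areas from extrusion tools are therefore not
comparable cell-for-cell; constriction existence, opening vs
constriction ordering, and mode-induced gain/loss patterns are the
meaningful outputs. Discretization error is bounded in the tests:
halving the grid changes areas by <5%, and hollow-channel phantoms of
known radius recover $\pi r^2$ within 10% (the residual bias is the
wall-atom corrugation of the phantom, not the grid).

## Synthetic data: what it emulates and what it does not

`make_fold()` packs ideal-geometry helices and strands on a three-layer
sandwich layout (sheet strands 4.8 Å apart, helices on either face,
arc-interpolated loops bowing outward), then enforces real Cα-trace
geometry: virtual bonds 3.8 ± 0.1 Å (keeping every bond on the
short-range branch of the force-constant law) and non-consecutive
contacts ≥ 3.8 Å. The default specification follows the GNAT element
succession (B1-H1-H2-B2-B3-B4-H3-B5-H4-B6, ~123 residues) with a longer
connector where the β6β7 hairpin sits. Resulting traces are compact
(radius of gyration ≈ 14.5 Å) with protein-like lowest internal
eigenvalues (~15–45 kJ mol⁻¹ nm⁻²). They are *not* real proteins: no
side chains, idealized secondary structure, loops smoother than real
ones, and (as noted above) stronger anharmonic mode coupling. Tests
passing on them validate the machinery — formulas, invariances,
determinism, geometry — not biological conclusions about any particular
family member.

Gaussian ensembles (`make_gaussian_ensemble()`) provide ground truth for
covariance estimation and BC recovery; channel phantoms
(`make_channel()`) provide analytic ground truth for areas. All
generators run under a temporarily seeded RNG and restore the caller's
stream.

## Problem sizes and determinism

The test suite and the acceptance script use networks of 2–10 nodes
where analytic or pseudo-inverse oracles are exact, 100–123-residue
folds for pipeline-scale checks, and $10^4$–$10^5$ Monte-Carlo samples
for covariance recovery — sizes chosen so each oracle comparison is
sharp at its stated tolerance. Dense eigendecomposition is used
throughout (3N ≤ ~600 here; the dense path is exact and simple). All
sampling is seed-controlled; `run_pipeline()` writes a manifest with
parameters, seeds and md5 checksums of every deterministic text
artifact, and rerunning a configuration reproduces those checksums
bit-for-bit.

## Known limitations

* The internal aligner is a convenience, not a replacement for a
  structure-based multiple aligner; on genuinely divergent folds it may
  find only a small incidental core (and says so).
* Absolute fluctuation scale and absolute BC values depend on
  normalization/regularization conventions and are not comparison
  surfaces; profiles' shapes and clustering topologies are.
* Mode-space relaxation bounds, measured here on synthetic folds, will
  be tighter on crystal structures; conversely force-field-grade
  refinement of rebuilt all-atom models is explicitly out of scope.
* The ENM knows nothing of ligands beyond the optional CoA beads;
  effects of bound substrate on dynamics are outside the model.
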