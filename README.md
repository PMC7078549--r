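# natdyn

Comparative intrinsic-dynamics analysis of GNAT-fold acetyltransferase
catalytic domains — and of any set of related protein structures — from
Cα elastic-network normal modes.

N-terminal acetyltransferases (NATs) share the GNAT fold: a three-layer
αβα sandwich whose β6β7 hairpin and α1α2 loop enclose a narrow tunnel
where acetyl-CoA and the substrate N-terminus meet. Their substrate
specificities differ drastically, and part of that story is dynamics:
which parts of the fold move, how those motions are shared across the
family, and how they reshape the ligand tunnel. `natdyn` implements that
analysis chain as a tested R package:

1. **Structure I/O** — single-chain Cα models from PDB files, altloc and
   missing-Cα handling, an 11-bead coarse-grained CoA cofactor model
   (atoms C, C3P, C6P, C9P, CCP, P1A, C4B, P3B, N9A, N6A, N3A).
2. **Elastic network + normal modes** — all-pair Hookean springs with the
   distance-dependent force constant

   ```
   k_ij = a r0 − b        (r0 < d)
        = c r0⁻⁶          (r0 ≥ d)
   a = 8.6×10⁵ kJ mol⁻¹ nm⁻³,  b = 2.39×10⁵ kJ mol⁻¹ nm⁻²,
   c = 128 kJ mol⁻¹ nm⁴,       d = 0.4 nm
   ```

   eigendecomposition of the 3N×3N Hessian (unit masses; six rigid
   modes), normalized fluctuations `F_i = Σ_{m≥7} ‖d_mi‖²/λ_m` and
   cross-correlation maps `C_ij = Σ_m v_mi·v_mj/λ_m / √(F_i F_j)`.
3. **Structural comparison** — Kabsch superposition, gap-free aligned-core
   extraction (from an external gapped-FASTA alignment or an internal
   iterative Cα aligner), pairwise RMSD matrices, average-linkage
   clustering with heatmap/Newick output.
4. **Dynamics comparison** — mode covariances reduced to the aligned core
   in a common frame, compared pairwise with the Bhattacharyya
   coefficient `BC = det(A)¼ det(B)¼ / det((A+B)/2)^½`, evaluated in the
   dominant principal subspace of the mean covariance.
5. **Conformers** — Cα displacement along single low-frequency modes
   (`x = x0 + s·A·v_m`, RMSD = A/√N exactly), elastic-energy relaxation
   in mode space holding the displaced mode, 3-residue sliding-window
   all-atom rebuilding, steric-clash reporting.
6. **Tunnel profiling** — an axis from three anchor residues (plane
   normal through their Cα centroid, ±15 Å), grid-sampled cross-section
   free areas out to 6 Å radius, per-mode gain/loss and the constriction.
7. **Synthetic data** — ideal-geometry αβα sandwich folds, Gaussian
   ensembles with prescribed covariance, hollow channels of known inner
   radius; the whole pipeline is testable offline.

## Worked example

The `analysis/` scripts run the full study on a synthetic dataset (nine
123-residue sandwich folds in three groups whose networks differ in
overall stiffness). Run them in order:

```sh
Rscript analysis/01_dataset.R
Rscript analysis/02_alignment_rmsd.R
Rscript analysis/03_modes_fluctuations.R
Rscript analysis/04_dynamics_similarity.R
Rscript analysis/05_conformers_tunnel.R
Rscript analysis/06_pipeline.R
```

Output of the comparison stages (abridged):

```
aligned core: 123 columns over 9 structures
pairwise RMSD: min 0.486, median 0.710, max 0.789 A
...
reference domains: intra max |C| 0.79 / 0.76, inter max |C| 0.57
...
          1 2 3
  inter   0 3 0
  main    3 0 0
  outlier 0 0 3
BC clustering separates the three stiffness families cleanly
```

The point these numbers make: the structural signal is flat (all RMSDs
≈ 0.7 Å — the structures share one fold), yet the Bhattacharyya
clustering recovers the three dynamics families exactly. This is the
same contrast the method is designed to expose in the NAT family, where
structure-based clustering and dynamics-based clustering group the
enzymes differently. The conformer/tunnel stage prints

```
conformers: displaced RMSD 1.35 A, relaxed RMSD 1.77-2.49 A
native constriction: 93.7 A^2 at offset 8.0 A
channel phantom r = 3 A: plateau 28.95 A^2 (pi r^2 = 28.27)
channel phantom r = 5 A: plateau 80.17 A^2 (pi r^2 = 78.54)
```

i.e. the amplitude-15 convention yields sub-2 Å Cα displacements for
domain-sized proteins, and the cross-section areas are quantitatively
validated against channel phantoms of known radius.

To analyse real structures, point a YAML config at local PDB files
(path, chain, group per entry; see `results/data/config.yaml` written by
`01_dataset.R`) and run `run_pipeline(read_config("config.yaml"), out)`,
optionally supplying an external structure-based alignment as gapped
FASTA.

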