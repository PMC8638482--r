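# ktjoint

Joint compressed-sensing + parallel-imaging reconstruction for accelerated
dynamic (cine) cardiac MRI, in R.

Dynamic MRI cannot fully sample k-space for every time frame. `ktjoint`
implements a two-stage framework that *decouples* the acceleration between
the two major reconstruction families. The acquisition keeps every
R<sub>1</sub>-th phase-encode line (a uniform lattice), then keeps only a
Gaussian-tapered random subset of those lines per frame (reduction
R<sub>2</sub>), plus a fully sampled block of ACS lines at the k-space
center:

    d_ur = M_r · M_u · d_full

Reconstruction inverts the two operators in sequence:

1. **k-t FOCUSS** (per coil): the aliased image series is sparse in x-f
   (space × temporal frequency), so the random subsetting `M_r` is inverted
   by solving `min ‖ρ‖₁ s.t. ‖d − Fρ‖₂ ≤ ε` via iteratively reweighted ℓ₂
   minimization — each round a conjugate-gradient ridge solve
   `min_q ‖d − FWq‖₂² + λ‖q‖₂²` followed by the weight update
   `W = diag(|ρ|^½)`.
2. **Nonlinear GRAPPA**: after a per-frame, per-coil complex scaling
   normalization (`d_recon = β·d_acq`, fit on the overlap of reconstruction
   and acquisition), the remaining lattice gaps `M_u` are filled by a
   truncated second-order polynomial kernel (constant, first-order sources
   across coils/blocks/columns, their squares, and adjacent/skip-one column
   products) calibrated on the ACS lines of all frames jointly.

Final images are root-sum-of-squares coil combinations; quality is measured
as frame-wise NMSE `‖I_ref − I_recon‖² / ‖I_ref‖²` with the net acceleration
accounted as `R = n_pe / (n_pe/(R1·R2) + n_acs)`.

A deterministic multi-coil beating-heart phantom (contracting ventricle,
orbiting blood pool, broadband tissue texture, smooth coil maps, complex
Gaussian k-space noise) makes every stage testable without scanner data.

## Worked example

```r
library(ktjoint)

spec <- phantom_spec(seed = 11)                     # 128x128, 12 frames, 4 coils
plan <- sampling_plan(128, 128, 12, r1 = 2, r2 = 3, n_acs = 32, seed = 11)
net_reduction_factor(128, 2, 3, 32)
#> [1] 2.4

ds  <- simulate_phantom_acquisition(spec, plan)     # masked k-t data + reference
ref <- reference_images(ds)

for (m in c("zero_filled", "cs_only", "proposed")) {
  rec <- run_reconstruction(ds, plan, recon_config(method = m))
  cat(m, "frame-mean NMSE:", signif(mean(nmse(ref, rec)), 3), "\n")
}
#> zero_filled frame-mean NMSE: 0.046
#> cs_only frame-mean NMSE: 0.00831
#> proposed frame-mean NMSE: 0.00629
```

Zero-filling leaves strong aliasing (NMSE 0.046). Coil-wise CS alone
(`cs_only`, the k-t FOCUSS baseline run on the full acquired mask) removes
most of it, and the two-stage method improves on that again by recovering
the off-lattice lines from coil encoding rather than asking sparsity to do
the whole job. `sweep_acceleration()` and `sweep_acs()` rerun the proposed
method across (R1, R2) splits or ACS counts at a fixed net R and tabulate
frame-wise NMSE; `write_nifti_series()` / `write_nmse_csv()` export results.

A thin command-line wrapper is installed as `exec/ktjoint`
(`simulate`, `mask`, `recon`, `sweep` verbs) for shell pipelines.

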