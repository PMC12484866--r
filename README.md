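# ivmatch

Image-varifold measures and diffeomorphic matching for spatial omics.

Spatial transcriptomics technologies (MERFISH, BARseq, cycleHCR and
relatives) detect molecules and cells at submicron resolution, while the
anatomical reference frames they must be registered to — CCFv3-style
labeled atlases — live at the millimeter scale and speak a different
feature language (region ontologies rather than genes or cell types).
`ivmatch` represents both kinds of data uniformly as **image varifolds**:
weighted particle measures

&nbsp;&nbsp;&nbsp;&nbsp; μ = Σᵢ wᵢ δ_{xᵢ} ⊗ pᵢ

where each particle carries a mass wᵢ at position xᵢ (mm) and a
distribution pᵢ over a feature space (genes, cell types, or region
labels).  Closeness is measured by a reproducing-kernel varifold norm

&nbsp;&nbsp;&nbsp;&nbsp; ⟨μ, ν⟩ = Σ_{ij} wᵢ wⱼ K_σ(xᵢ, xⱼ) Σ_{fg} K_F(f,g) pᵢ(f) pⱼ(g)

that couples spatial proximity (Gaussian kernel K_σ, possibly a sum of
bandwidths) with feature similarity (indicator kernel for discrete
labels).  On this representation the package provides, for people building
3D registrations of spatial-omics data to atlases:

- **Geodesic shooting (LDDMM)** — diffeomorphic matching parameterized by
  initial space and mass momenta (ρˣ, ρʷ) evolving under Hamiltonian
  particle dynamics, with the Jacobian determinant |Dφ| transported along
  the flow (`shoot()`, `match_single_modality()`).
- **Cross-modality matching** — the atlas is augmented with latent
  per-region feature laws p_ℓ estimated jointly with the deformation under
  a mass-weighted KL prior toward uniform (`match_cross_modality()`,
  `kl_prior()`).
- **Censored (partial-volume) matching** — a spatial support weight
  α^λ ∈ [0,1] (a two-plane tanh profile, or a small learned boundary
  classifier) masks the deforming atlas so that only the measured
  subvolume drives the loss; the transition bandwidth λ is estimated
  jointly under the penalty J_s(λ) (`planar_censor()`,
  `fit_boundary_classifier()`, `lambda_penalty()`).
- **Scale-space resampling** — optimization-based compression of a
  high-resolution measure onto a fixed particle budget by minimizing the
  varifold distance over positions, weights and laws, with K-means (Lloyd)
  and fixed-grid baselines (`resample_scale_space()`, `compare_schemes()`).
- **Mutual-information feature selection** — spatially variable genes are
  scored by the conditional mutual information between a random
  megasquare-split indicator and quantile-binned counts
  (`rasterize_counts()`, `mi_score()`, `rank_features()`).
- **Rigid stack alignment** — adjacent-section varifold distances drive
  per-section rotations and translations (`align_stack()`).

Every input class has a seeded generator (`make_three_region_toy()`,
`make_censored_slab()`, `make_striped_gene_field()`, ...), so the full
pipeline runs and is tested without external downloads.  Internal units
are millimeters throughout.

## Worked example

The toy cross-modality problem: a square atlas with three homogeneous
regions over {R, G, B} must be matched to a target of the same outline
whose two-feature (black/white) regions correspond to the atlas partition
under a half turn.  Sweeping a rigid rotation and re-estimating the
optimal per-region feature laws at each angle:

```r
library(ivmatch)

toy <- make_three_region_toy(n_side = 32)          # ~1k particles per measure
sw  <- rotation_sweep(toy$atlas, toy$target, space_kernel(0.08))
attr(sw, "argmin")
#> [1] 180
head(sw[order(sw$loss), ], 3)
#>     angle         loss
#> 181   180 6.938894e-18
#> 180   179 2.052207e-05
#> 182   181 2.052748e-05
```

The loss minimum sits exactly at the half turn: homogeneous regions align
with homogeneous regions, and the estimated laws make the matched
configuration essentially exact (loss ~1e-18).

Compressing a curvilinear phantom (particles on a thin arc) to a fixed
budget shows why optimizing particle placement in the varifold metric
beats clustering and regridding at the same budget:

```r
arc <- make_curvilinear_arc(seed = 1, n = 500)
compare_schemes(arc, resampling_config(sigma = 0.15, seed = 1))
#>      scheme particles        dist2
#> 1 optimized        48 2.876864e-05
#> 2    kmeans        48 2.521602e-04
#> 3      grid        48 1.686339e-02
```

And scoring a spatially striped gene against a uniform decoy with matched
totals:

```r
det <- make_striped_gene_field(seed = 1)
gc  <- rasterize_counts(det, sigma = 0.05, bbox = c(0, 1, 0, 1))
sc  <- mi_score(quantile_bin(gc, q = 10),
                megasquare_ensemble(dim(gc$counts)[1], dim(gc$counts)[2], K = 4))
round(sc, 4)
#> striped uniform
#>  0.1246  0.0823
```

The striped gene's conditional MI (nats, mean per megasquare) exceeds the
uniform gene's; `rank_features(sc)` puts it first.

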