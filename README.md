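# tractmorph

Whole-volume white-matter tract morphometry for R.

Averaging a fibre bundle's diffusion metrics down to one number, an
along-tract profile or a voxel-thin skeleton throws away everything that
varies orthogonally to the tract's core. `tractmorph` keeps the whole
volume: a fixed-topology hexahedral template mesh of a tract (by default
16 × 16 × 80 = **20 480 elements**) is morphed onto each subject's tract
geometry by free-form deformation (FFD), each element is assigned the
diffusion tensor metrics (FA, MD, AD, RD) of its nearest image voxel, and
the resulting subjects × 20 480 matrices — corresponded element-for-element
across the cohort — feed standard group statistics. The package is aimed at
neuroimaging researchers comparing cohorts (e.g. contact-sport athletes vs
controls) on tracts such as the corticospinal tract.

## Method in brief

**Fitting.** The template is embedded in a regular wrapper lattice with a
trilinear basis; each node has fixed material coordinates **u** ∈ [0,1]³ in
its lattice cell. Fitting iterates nearest-point correspondence of surface
nodes to the subject's tract surface cloud with an exact linear
least-squares update of the control points C:

    min_C  Σ_s ‖ W_s C − y_s ‖²  +  λ·h̄² ‖ L (C − C₀) ‖² ,

(W_s trilinear weights, L a control-grid Laplacian on displacements, h̄²
the mean squared lattice spacing). Internal nodes ride through the same
lattice, so relative node positions — and hence inter-subject element
correspondence — are preserved. Fit quality is the surface RMSE
(root-mean-square surface-node-to-nearest-cloud-point distance); on
synthetic subjects with 2 mm-scale smooth warps it is ≈ 0.15 mm, well under
the 1 mm working bound.

**Embedding.** Per element and metric, the value of the nearest masked
voxel centre (pure nearest neighbour, deterministic smallest-index
tie-break, distance cap for overhangs).

**Statistics.** Columns are centred/scaled; PCA is computed by SVD of the
subjects × features matrix; element-wise pooled/Welch/paired t-tests give
t- and p-fields over the template; group mean ± 1/± 2 SD pattern fields
visualise within-cohort variation; a descriptive report scores group
separation by the AUC of PC1 as a ranker of group membership.

## Worked example (synthetic cohort)

```r
library(tractmorph)

tpl <- build_template_tract_mesh(template_config(8, 8, 32))  # desk-scale
#> hex_mesh: 2673 nodes, 2048 elements, 1154 surface nodes

## 6 cases + 6 controls; cases get +1.5e-4 mm^2/s MD in the mid-tract
eff <- effect_spec(affected_metrics = "MD", region = c(0.35, 0.65),
                   delta = c(MD = 1.5e-4))
bundle <- generate_cohort(sim_config(n_case = 6, n_control = 6, seed = 42),
                          eff, template = tpl)

fit <- fit_to_point_cloud(tpl, bundle$subjects[[1]]$cloud)
#> ffd_fit: rmse 0.3373 mm after 15 iteration(s) (converged)

models <- morph_and_embed_cohort(bundle)          # fit + embed everyone
glab <- vapply(models, function(m) m$group_label, "")

cm  <- assemble_cohort_matrix(models, "MD")
pca <- run_pca(standardize(cm), 2)
#> pca_result: 2 components, variance ratios 0.298, 0.146
cluster_report(pca, glab)$auc_pc1
#> [1] 1
st <- elementwise_ttest(tractmorph:::subset_cohort(cm, glab == "case"),
                        tractmorph:::subset_cohort(cm, glab == "control"))
```

With this seed, 96.1% of elements inside the true effect region have
p < 0.05 against 2.6% outside it, and the case/control groups separate
perfectly on PC1 (AUC 1.0) — the metric signal is recovered while shape-only
PCA of the same cohort stays at chance.

The same pipeline runs from the command line on files:

```sh
inst/exec/tractmorph simulate --config study.yaml --out study/
inst/exec/tractmorph fit --template study/template.vtk \
    --cloud study/case01_cloud.xyz --out fits/case01
inst/exec/tractmorph embed --mesh fits/case01/fitted.vtk \
    --fa study/case01_FA.nii.gz --md study/case01_MD.nii.gz \
    --ad study/case01_AD.nii.gz --rd study/case01_RD.nii.gz \
    --out models/case01 --subject case01 --group case
inst/exec/tractmorph analyze --models models/ --groups study/groups.csv \
    --out results/
```

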