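# nasorecon

Virtual reconstruction of **full nasal defects** on 3D facial scans, for
researchers in craniofacial imaging, prosthetics CAD and surgical planning.

A full nasal defect leaves no healthy contralateral side to mirror, so the
missing anatomy has to come from a model of what the patient's intact face
would look like. `nasorecon` builds that model and uses it:

* **Structured meshes** — all faces share one fixed template topology, so a
  vertex index is an anatomical location (`read_obj()`, `face_mesh()`,
  `build_face_graph()`).
* **Graph-convolutional mesh autoencoder** — a dual-branch (global +
  local feature) encoder to a latent code `z` and a graph-conv decoder,
  trained with vertex-wise MSE plus a *spherical latent regularization*
  `(||z|| - 1)^2` weighted by `lambda = 0.01` (Adam, learning rate 0.001,
  17:2:1 train/validation/test split): `train_face_autoencoder()`.
* **Defect-guided latent/rigid fitting** — the encoder is discarded; the
  decoder generates a face `S2 = decode(z)` and
  `fit_trf()` solves

  ```
  R*, T*, z* = argmin  CD(S1, R S2 + T) + lambda (||z|| - 1)^2
  CD(S1, S2) = (1/|S1|) * sum_{x in S1} min_{y in S2} ||x - y||^2
  ```

  (unidirectional chamfer distance) against the defective face `S1`,
  yielding a personalized **3D target reference face** (3D-TRF).
* **Nose extraction** — the defect edge curve is projected onto the fitted
  face and the enclosed region is cut out as `Nose_Reconstruction`
  (`extract_nose()`, `project_curve()`, `select_region()`).
* **Evaluation** — morphological similarity (`surface_deviation()`: RMSD +
  maximum of point-to-surface distances, the maximum localized to one of
  the nine nasal subunits) and edge fitness (`curve_deviation()`: RMSD +
  maximum between arc-length-resampled edge curves), summarized as
  mean ± SD with a subunit tally (`summarize_deviations()`).
* **Synthetic study conditions** — clinical scan datasets are not
  redistributable, so `make_template()`, `population_model()`,
  `sample_population()` and `simulate_defect()` generate a seeded,
  fixed-topology face population with smooth low-rank shape variation and
  parametric full nasal defects, on which the entire pipeline is validated.

## Worked example

The end-to-end simulated experiment: generate a population, train the
autoencoder, give 20 unseen faces full nasal defects, fit a 3D-TRF to each,
extract the nose and score it against the deleted ground truth — plus a
mean-template baseline for comparison:

```r
library(nasorecon)
rep <- run_experiment(experiment_config(seed = 1), verbose = TRUE)
print(rep)
#> Simulated full-nasal-defect experiment: 20 cases (seed 1)
#>   3D surface deviation  1.08 +/- 0.36 mm (baseline 3.45 +/- 1.32)
#>   max surface deviation 2.19 +/- 0.81 mm
#>   curve deviation       4.36 +/- 0.32 mm, max 7.14 +/- 0.86 mm
#>   fitted beats baseline surface RMSD in 20/20 cases; test MSE 1.384 mm^2
#>   max-deviation subunits: nasal_dorsum=7, nasal_sidewall_L=1, nasal_sidewall_R=3,
#>     nasal_tip=4, nasal_columella=1, nasal_ala_L=3, nasal_ala_R=1
```

Reading the numbers: the personalized reconstruction deviates from the true
(deleted) nose by 1.08 mm RMSD on average, versus 3.45 mm if one simply
used the population mean face — the fitted model wins the paired comparison
in 20 of 20 cases, which is the personalization claim this pipeline exists
for. The curve deviation (edge fitness) is bounded below by the mesh
resolution of the vertex-based nose cut (about one edge length, ~4 mm at
the benchmark resolution); see the methods vignette. `test MSE` is the
autoencoder's held-out reconstruction error in mm².

Individual stages are ordinary functions with S3 methods:

```r
tpl   <- make_template(40)                       # 1601-vertex analytic face
pop   <- population_model(tpl, seed = 1)         # rank-8 smooth variation
faces <- sample_population(tpl, pop, 60, seed = 2)
model <- train_face_autoencoder(faces, latent_dim = 32, widths = c(8, 16, 32),
                                branch_width = 32)
summary(model); plot(model)                      # loss curves
def   <- simulate_defect(sample_population(tpl, pop, 1, seed = 9)[[1]], tpl)
fit   <- fit_trf(def, model, template = tpl)     # the 3D-TRF
nose  <- extract_nose(fit$trf, def$defect_curve)
surface_deviation(nose, def$nose_original,
                  subunits = attr(def$nose_original, "region_labels"))
```

A thin command-line wrapper with `make-data` / `train` / `fit` /
`reconstruct` / `evaluate` / `run-experiment` subcommands is installed at
`inst/cli/nasorecon.R`; all meshes are exchanged as Wavefront OBJ and
curves as XYZ text.

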