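---
title: "Counterfactual functional-connectivity analysis with fcvae"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counterfactual functional-connectivity analysis with fcvae}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the approach

Functional connectivity (FC) analysis asks how synchronized the BOLD
time series of different brain regions are, and how that synchrony differs
between a clinical group and a reference population.  Classical group
contrasts inherit every imbalance of the cohort — in autism cohorts most
notably the strong male skew — so an apparent group effect may in part be a
sex effect in disguise.

`fcvae` implements a *normative* (counterfactual) strategy.  A variational
autoencoder (VAE) is trained to reconstruct windowed parcel-by-time BOLD
matrices of the neurotypical (TD) population only.  Passing a
neurodivergent (ASD) window through the trained model yields a
"neurotypical-like" version of that scan: the decoder can only express
patterns it learned from the typical population.  Comparing network-level
connectivity of the inputs against their counterfactual reconstructions
with per-pair Welch t tests localizes under-connectivity (negative t) and
over-connectivity (positive t) between five canonical resting-state
networks: DMN, Limbic, Visual, Somatomotor, Salience.

The conditional variant (CVAE) additionally feeds a phenotype embedding —
age, sex, and diagnostic group — to both encoder and decoder.  The
counterfactual is then generated by *flipping only the group label to TD*
while retaining age and sex, so that input-versus-output differences are
attributable to the diagnosis rather than to phenotype covariates.  The
package quantifies how much this conditioning de-biases the analysis by the
cosine similarity between the male-only and female-only divergence maps:
if the detected pattern is a property of the condition rather than of sex,
the two maps should agree.

## Model families

Three encoder/decoder families are provided, selected with
`model_config(family = ...)`:

* **CNN** — three strided 3×3 convolutions (stride 2, padding 1) with 32,
  64, 128 filters, batch normalization and leaky-ReLU (slope 0.2), then
  dense heads for the latent mean and log-variance.  The decoder is an
  exact mirror: a dense layer into the innermost feature map followed by
  three transposed convolutions.  The transposed convolutions are
  parameterized as the adjoint of the "mirror" convolution computed from
  the *target* shape chain, so the decoder inverts the encoder geometry
  exactly for any input size and no output-padding bookkeeping is exposed.
* **RNN** — a three-layer unidirectional LSTM read along the time axis
  (each step sees one parcel-vector), with the final hidden state feeding
  the latent heads.  The decoder maps the latent vector to a context
  vector repeated at every time step of a second three-layer LSTM, with a
  shared per-step linear map back to parcel space.  The hidden width
  (default 256 at full scale, 32 in the desk-scale tests) is not dictated
  by the architecture and is exposed in the configuration.
* **HYBRID** — CNN and RNN encoders run in parallel.  Latent Gaussians are
  fused element-wise: means are multiplied, log-variances added (the
  product-of-independent-Gaussians heuristic).  Both decoders run and
  their outputs are averaged.  Whether a parallel hybrid should also
  decode in parallel is genuinely open; averaging is our documented
  choice, switchable in principle by using either branch's decoder alone.

All three families expose the same contracts: with conditioning the
embedding (length = window width) is stacked as one extra parcel row, so a
200×200 window becomes a 201×200 encoder input, and the decoder consumes
`latent_dim + embedding_dim` values (2200 at the full-scale settings
d = 2000, embedding 200).  The decoder reconstructs only the data rows,
never the embedding row, and squashes outputs into [0, 1] with a sigmoid.

A note on the embedding length: stacking the embedding as a parcel row
forces its length to equal the *window width*, not the parcel count; the
two coincide at full scale (both 200).  `model_config()` therefore
enforces `embedding_dim == window`.

The latent prior is the standard normal with the closed-form KL
divergence.  A mixture-of-Gaussians latent model would be a natural
extension, but with no component count or mixture objective to pin it
down we did not guess; the ELBO here is the plain Gaussian one.

## Training objective and the KL weight

Training minimizes the negative ELBO: a reconstruction term (sum of
squared errors / 2 by default; binary cross-entropy selectable) plus
`beta` times the KL term, optimized with Adam (learning rate 0.0001 at
full scale).  The implementation is self-contained R with analytic
backpropagation through every layer; the test suite validates all six
(family × conditioning) variants against central finite differences to
1e-4.

`beta` deserves a comment.  The Gaussian reconstruction term `SSE/2`
implicitly assumes unit observation noise, which is far too diffuse for
data min-max scaled into [0, 1]: at desk scale the KL pressure then wins
and the posterior collapses (the decoder ignores the latent code and
reproduces a population mean).  The desk-scale analyses in the tests and
the acceptance script therefore train with `beta = 0.01`, which is
equivalent to assuming an observation standard deviation of 0.1 on the
normalized scale — a realistic noise level for these windows.  `beta = 1`
remains the default in `model_config()` for full-scale settings.

## Preprocessing conventions

* **Windowing** — sliding windows of 200 time steps with step 10 at full
  scale (`sliding_windows()`), 0-based and half-open; a scan shorter than
  one window yields zero samples with a warning.  Augmentation happens
  *after* the subject-level split, so train and test windows never share a
  subject.
* **Normalization** — per-window min-max to [0, 1].  Global (whole-window)
  scaling is the default because it preserves relative amplitudes across
  parcels.  Per-parcel scaling (`per_parcel = TRUE`) is used by the
  model-level analyses in this package: Pearson correlations (and hence
  every FC quantity) are invariant to per-row affine maps, while global
  scaling couples the element-wise dispersion of a window to its
  cross-parcel dependence structure.  That coupling is a confound for
  reconstruction-error comparisons between groups that differ exactly in
  their dependence structure, and per-parcel scaling removes it by
  construction.
* **Atlas grouping** — Schaefer-convention labels are parsed into the five
  analysis networks; control (`Cont`) and dorsal-attention (`DorsAttn`)
  parcels are excluded.  A synthetic 200-label list in the standard format
  ships under `inst/extdata/` for tests and examples (clearly named
  synthetic; it mimics the per-network proportions of the published atlas
  but is not the published label list).
* **Split** — stratified by (group, sex) for reproducible class balance at
  desk scale; strata with fewer than two subjects fall back to
  training-set assignment with a warning.

## The synthetic cohort generator

Real parcellated BOLD with known ground-truth effects does not exist, so
`fc_sim_config()` / `generate_cohort()` emulate the statistical structure
the pipeline consumes:

* Five latent network signals follow a stationary AR(1) process
  (coefficient 0.4 ≈ BOLD autocorrelation at TR = 2000 ms) whose
  innovations carry a configurable cross-network correlation matrix.
* Each parcel observes its network's signal plus i.i.d. Gaussian noise
  (`noise_sd = 1` gives within-network parcel correlations of 0.5).
* Scan lengths vary per subject (variable site protocols), exercising the
  windowing logic.
* Group and sex effects perturb the coupling matrix only — connectivity is
  where the scientific claims live.  Perturbed matrices are repaired to
  the nearest correlation matrix by eigenvalue clipping at zero and
  rescaling to unit diagonal, adequate at 5×5.
* Sex is drawn Bernoulli with a configurable male:female ratio (default
  4:1, mirroring public autism cohorts); each diagnostic group receives
  `2 * n_subjects_per_cell` subjects.

What the generator deliberately does **not** emulate: scanner/site batch
effects, motion artifacts, hemodynamic response variation,
subject-specific coupling heterogeneity within a cell, and spatial parcel
geometry.  Passing tests on these cohorts demonstrates that the machinery
recovers known coupling effects under the stated noise model — not that it
would survive every artifact of real fMRI.

## Statistical design of the built-in checks

* **Null calibration.**  With no injected effect, TD and ASD cohorts are
  exchangeable, so pushing both groups' test windows through the *same*
  trained counterfactual pathway must produce significant Welch calls at
  the nominal rate.  Two honesty constraints matter.  First, the
  calibration compares the two groups' counterfactual connectivity rather
  than inputs against reconstructions: reconstruction bias is common to
  both sides and cancels, whereas an input-versus-reconstruction null is
  not a null for an imperfect model (see the limitations below).  Second,
  calibration replicates use *non-overlapping* windows (step = window):
  overlapping augmentation windows are fine for training but are strongly
  dependent, and a t test over them would not be calibrated at any level.
* **Effect recovery.**  An injected −0.4 DMN–Limbic coupling deficit must
  be recovered as a significant negative Welch t at 60 windows per side in
  at least 9 of 10 seeded runs.  A model-mediated variant (ASD inputs
  versus their counterfactuals from a TD-trained VAE) asserts the sign of
  the recovered effect, in both directions, over 5 seeds.
* **Reconstruction-error pattern.**  A VAE trained on the typical group
  only should reconstruct held-out atypical windows at least as badly as
  typical ones.  The effect is mediated by compressibility: the typical
  group is simulated with strong baseline coupling (0.6) and the atypical
  group with broad under-connectivity (−0.5 on every network pair), so
  atypical windows carry more independent signal than the bottleneck
  learned to compress.  The check asserts the direction in ≥ 4 of 5 seeds.
* **Conditioning and sex bias.**  Cohorts carry one diagnostic effect
  shared by both sexes (DMN–Limbic −0.4) plus a sex-linked baseline
  difference present in both groups (Salience–Limbic +0.3 in males,
  echoing male-specific salience–limbic over-connectivity reported in the
  literature).  An ideal analysis would find identical divergence maps for
  the sexes.  The sex-agnostic VAE cannot, because its counterfactuals
  regress toward a mixed-sex reference; the CVAE decodes with sex
  retained.  The check asserts that the median male/female map similarity
  over 5 seeds is at least as large for the CVAE as for the VAE.

The similarity metric itself is the cosine of the vectorized upper
triangles of the two divergence-t maps.  Two operand pairings are
conceivable — comparing a model's map against another model's, or a
cohort's male map against its female map; this package computes
male-versus-female per model, which is the pairing that directly measures
sex bias of a given model's result.

Problem sizes used by the tests and the acceptance script, chosen as
desk-scale stand-ins for the full-size study: 20 parcels, 5 networks,
windows of 40 time steps, latent dimension 16–64, cohorts of 16–56
subjects, 200 calibration replicates with roughly 200 windows per side.
The full-scale configuration (200 parcels, 200-step windows, d = 2000)
remains available through `model_config()` but is not exercised by tests.

## Evaluation conventions

* Cohort-level reconstruction metrics are means of per-window cosine,
  Pearson correlation and L1 (mean absolute error); per-window PCC is
  averaged rather than pooling all elements, because pooling would let a
  few high-amplitude windows dominate.
* The latent separation test reduces each window's posterior mean to its
  scalar average and applies a pooled two-sample t test — Welch is
  reserved for the FC stage, matching the named usage.  A per-dimension
  variant with Benjamini–Hochberg correction is available behind a flag.
* FC divergence uses raw p < 0.05 by default (no multiplicity correction)
  with a `BH` flag, unpaired Welch by default with a `paired` flag, and
  raw correlations by default with a `fisher_z` flag.  Windows, not
  subjects, are the sampling unit, mirroring the validation-sample usage
  the method was designed around; within-network (diagonal) tests are
  computed but chord diagrams draw only between-network pairs.

## Known limitations

* An input-versus-counterfactual comparison confounds the group effect
  with reconstruction bias whenever the model is imperfect; the package's
  calibration check is deliberately two-sided (both groups through the
  model).  Interpreting single-sided divergence maps on real data should
  always be accompanied by the same analysis on a typical held-out set.
* At desk scale the reconstruction fidelity is modest (held-out per-window
  PCC ≈ 0.3–0.4); all model-level guarantees are therefore directional,
  not quantitative.
* Welch tests over overlapping windows are anti-conservative; use
  non-overlapping windows for inference, overlapping ones for training
  augmentation only.
* The simulator's parcels within a network are exchangeable; atlas-driven
  spatial structure in the CNN's receptive fields is not modeled.
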