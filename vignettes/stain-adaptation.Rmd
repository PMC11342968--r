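---
title: "Energy-preserving stain domain adaptation: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energy-preserving stain domain adaptation: model, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stainsan)
```

## The problem and the model

H&E-stained tissue images carry their color in two dyes: hematoxylin
(blue-purple nuclei) and eosin (pink cytoplasm and stroma). A batch of
images — a lab, a scanner, a staining run — induces a probability
distribution over per-image stain characteristics; we call that
distribution the batch's *stain domain*. Classifiers trained on one domain
and evaluated on another lose accuracy in proportion to the gap between the
domains, which is why stain adaptation is a standard preprocessing step in
computational pathology.

Everything in this package operates in optical-density (OD) space. With
incident intensity $I_0$ (255 for 8-bit images), a pixel's OD vector is
$v = -\log(I / I_0)$, and dye contributions add linearly:

$$V = W H, \qquad V \in \mathbb{R}^{3 \times d},\;
W \in \mathbb{R}^{3 \times 2},\; H \in \mathbb{R}^{2 \times d},$$

where the unit columns of $W$ are the RGB-OD directions of the two dyes and
$H$ holds non-negative per-pixel concentrations. The package fixes $m = 2$
stains throughout; $m = 3$ inputs are rejected with a clear error, since
H&E carries exactly two dyes and the downstream target distribution is
parameterized accordingly.

Adaptation follows one template: extract $(W, H)$, choose a new $W'$ (and
possibly $H'$) from a method-specific target domain, reconstruct
$I' = I_0 \exp(-W' H')$. The methods differ only in the target domain:

| method        | training target for $W$                  | test target for $W$ |
|---------------|------------------------------------------|---------------------|
| normalization | point mass at a reference $W_0$          | point mass at $W_0$ |
| augmentation  | per-column uniform perturbation of $W$   | unchanged           |
| mix-up        | convex mix with the other batch's $W_k$  | same                |
| SAN           | $\mathcal{N}(\mathrm{vec}(W_0), \sigma^2 I)$ | point mass at $W_0$ |

## The energy-preserving target distribution

Given extracted matrices $W_1, \dots, W_n$ from a training batch,
`estimate_stain_distribution()` sets

* $W_0$ = element-wise median (robust: one outlying image moves the mean
  by far less than its own displacement),
* $\sigma^2$ so that the isotropic Gaussian carries exactly the batch's
  total variance: $3 m \sigma^2 = \mathrm{Trace}\,\mathrm{Cov}(\mathrm{vec}(W))$.

The trace of a covariance matrix is the sum of per-entry variances, so the
identity holds to machine precision by construction, not approximately.
"Energy preservation" means the adapted training domain is exactly as
diverse as the original one — augmentation without domain inflation — while
being centered and spherical, which is what guarantees the gap reduction:
both batches end up centered on the same $W_0$.

Training images draw $\mathrm{vec}(W') \sim \mathcal{N}(\mathrm{vec}(W_0),
\sigma^2 I_{3m})$ and a single global intensity factor $\alpha \sim
U(1-\varepsilon,\, 1+\varepsilon)$ applied to all of $H$; test images
receive $W' = W_0$ deterministically (a zero-variance resample) and keep
$H$ untouched. We do not perturb test intensities: the intensity
perturbation is a training-time augmentation device, and a random test-time
transform would make evaluation non-reproducible for no benefit.

Two deliberate choices about the sampled $W'$:

* it is **not** re-normalized to unit columns — re-normalization would
  project the Gaussian onto a sphere and destroy the energy identity;
* negative entries (possible in the Gaussian tails, unphysical as
  absorbances) are clipped to zero with a warning. With the packaged
  reference ($\sigma = 0.053$, smallest mean entry 0.141) this affects
  well under 1% of draws and is negligible for the energy budget.

## Extraction: the SVD plane-and-angle method

Background is masked first: any pixel whose OD norm is at or below 0.3 is
treated as unstained near-white background, excluded from estimation, and
restored verbatim in every reconstructed output. A pixel exactly at the
threshold counts as background (a deterministic tie rule of negligible
measure). Masking is idempotent and an all-background image is rejected at
extraction with a degenerate-input error.

On the foreground OD cloud, the top-2 singular directions define the stain
plane; each pixel gets an angle there; the 1st and 99th percentile angles
(the `angle_percentile = 1` default, the usual robust-extreme convention
for this family of methods) are mapped back to 3-space, sign-fixed into the
non-negative octant, normalized, and ordered hematoxylin-first. Identity of
the columns matters downstream, so the ordering rule is physical:
hematoxylin looks blue-purple because it absorbs red light, hence its OD
vector has the larger red-channel entry (0.544 vs 0.141 in the packaged
reference). A cloud that is collinear (single stain) has no plane and is
rejected with an error naming the condition, as is a foreground smaller
than `min_foreground` (default 100 pixels — a percentile of a sparser cloud
is not meaningful).

Intensities solve $\min_H \lVert V - W H\rVert$ for **all** pixels
(foreground and background) so reconstruction is defined everywhere. The
default solver is the unconstrained least-squares solution with negatives
clipped to zero — deterministic, vectorized, and exact whenever the true
$H$ is non-negative; `solver = "nnls"` solves the exact two-variable
non-negative problem in closed form (pin one coordinate at zero, keep the
better fit) for clouds with pixels outside the cone of $W$.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `epsilon`, `epsilon1`, `epsilon2` | 0.2 | unitless factors | the setting used for all methods in the original cross-dataset experiments; keeps $\alpha \in [0.8, 1.2]$ |
| `mask_threshold` | 0.3 | OD norm | separates unstained background from tissue |
| `incident_intensity` | 255 | 8-bit intensity | standard for 8-bit scans |
| `angle_percentile` | 1 | percent | robust extreme of the angle distribution |
| `percentile_rescale` | 99 | percent | row-wise $H$ alignment for normalization, applied only when reference percentiles are supplied |
| `clip_floor` | 1 | 8-bit intensity | keeps $-\log$ finite at zero pixels |

One printed formula required a decision: the augmentation offset is stated
in the literature as $\beta_i \sim U(1-\varepsilon_2, 1+\varepsilon_2)$,
an additive shift of roughly $+1$ in OD units — larger than a typical stain
vector entry and inconsistent with the method it cites. The default here
draws the zero-centered $\beta_i \sim U(-\varepsilon_2, +\varepsilon_2)$;
`augment_beta_as_printed = TRUE` reproduces the literal convention for
comparison.

Randomness policy: each image gets one realization of every random
quantity ($\alpha$, $\alpha_i$, $\beta_i$, $u$, sampled $W'$), drawn from a
sub-stream derived from the user seed and the image index (batch API) or a
stable filename hash (CLI), so adding images to a directory does not
perturb existing draws and fixed-seed runs are byte-identical.

## The phantom generator

`phantom_spec()` / `generate_two_domain_study()` emulate exactly the
features the estimators consume: per-image true stain matrices jittered
around two domain centers (default: the packaged reference center and the
same center rotated 12° toward red, mimicking the purple-vs-reddish
contrast between labs); an $H$ field made of flat-top disk "nuclei"
carrying stain channel 1 and smooth low-frequency "stroma" texture
carrying channel 2; and a white background band of zero OD. Disk cores are
purely channel 1 and stroma-only areas purely channel 2, so the OD cloud
densely covers the angular range between the stain rays — the geometry a
percentile-based extractor needs to be well-posed. Default jitter
(`domain_spread = 0.05`) matches the scale of the packaged reference sigma.

What the phantoms do *not* emulate: chromatin texture and realistic nuclear
morphology, scanner noise and JPEG artifacts, out-of-focus regions, folds,
pen marks, or intensity-domain (as opposed to color-domain) batch effects.
Passing phantom tests therefore demonstrates correctness of the estimators
and adapters under the generative model they assume — not robustness to
every artifact of real slides.

## Validation scale and numerical notes

The shipped tests and the acceptance script run at sizes chosen to exercise
the asymptotics that matter while staying quick on a laptop: 64×64 to
96×96-pixel phantoms, 200-image batches for parameter recovery, 10,000
draws for sampling-energy checks, 20 seeded replicates for the domain-gap
property. At these sizes extraction recovers noiseless ground-truth stain
vectors to well under 1° and fitting recovers the generating center to
within 0.005 per entry; the test tolerances (2°, 0.02) leave comfortable
margin rather than tracking the observed error.

Numerical conventions fixed for reproducibility: pixels flatten row-major
into channel-first $3 \times d$ matrices; vectorization of $W$ is
column-stacked (the trace is invariant to this, serialization is not); the
covariance uses the unbiased $n-1$ denominator (the population definition
is the natural infinite-batch object; the sample analogue is its standard
estimator); distribution JSON is written with 17 significant digits so the
binary64 round trip is exact; quantiles use R's default type 7.

## Limitations

* Two stains only; no support for IHC or three-dye separations.
* 8-bit RGB rasters only — no 16-bit, multispectral, or ICC-managed input.
* The percentile rescale of normalization needs reference percentiles
  stored at fit time; it is off unless you supply them.
* The Gaussian target is isotropic by design; elliptical or uniform target
  domains are out of scope.
* Whole-slide pyramids are not handled; the unit of work is a tile/patch
  batch in memory or a directory of files.
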