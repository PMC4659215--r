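---
title: "Registering hyperspectral microscopy images in stained tissue sections"
author: "rmireg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Registering hyperspectral microscopy images in stained tissue sections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rmireg)
```

## The problem

Spectral histopathology workflows measure one and the same tissue section
twice: first label-free under a vibrational microscope (FTIR or CARS), where
every pixel carries an absorption or emission spectrum, and then — after
Hematoxylin & Eosin staining — under a conventional light microscope as an
RGB image. Training or validating spectral classifiers requires that both
images be overlaid so that a position in the sample has the same pixel
coordinate in both. The spectral image usually covers only a small region of
interest of the whole slide, which makes this a *template matching* problem:
the spectral region (the **fixed** image, or template) must be located
within the much larger stained image (the **moving** image) under a rigid or
similarity transform.

The two modalities share no intensity relationship — an infrared spectrum
and a stain color respond to entirely different physics — so
correlation-style metrics fail. `rmireg` implements a three-part strategy:

1. **Presegmentation.** Both images are reduced to *index-color images*:
   per-pixel integer cluster labels from k-means (k-means++ seeding),
   label 0 reserved for background. Labels are categorical; only their
   co-occurrence carries information.
2. **Restricted mutual information (RMI)** scores a candidate transform from
   the joint label histogram of overlapping pixels, with background
   knowledge built in.
3. **Sparse coarse-to-fine search** over the transform lattice, with the
   initial grid radius estimated automatically by *self-registration* of
   the template.

## The metric

Let $X$ and $Y$ be the label sequences of the template and the resampled
moving image over the template grid, with joint probabilities $p(x,y)$
estimated from the $m$ overlapping pixels. Plain mutual information
$I(X,Y) = H(X) + H(Y) - H(X,Y)$ suffers from *background attraction*:
large empty regions produce concentrated joint histograms and spuriously
high scores. RMI keeps MI's invariance to label identity but injects the
one piece of prior knowledge we do have — label 0 means "no sample" in both
modalities. With adjustment factor $\alpha \in [0,1]$:

$$p_\alpha(x,0) = (1-\alpha)\,p(x,0) \quad (x \ne 0), \qquad
  p_\alpha(0,y) = (1-\alpha)\,p(0,y) \quad (y \ne 0),$$
$$p_\alpha(0,0) = (1-\alpha)\,p(0,0) + \alpha\,[P(X{=}0) + P(Y{=}0) - p(0,0)],$$

all foreground–foreground cells unchanged. The adjusted table still sums to
one for every $\alpha$ (the removed border mass reappears exactly at
$(0,0)$; the tests assert this to $10^{-12}$ on random tables). The score is

$$I_\alpha(X,Y) = H(X) + H(Y) - H_\alpha(X,Y), \qquad
  H_\alpha(X,Y) = -\sum_{x,y} p(x,y)\,\log p_\alpha(x,y).$$

$H_\alpha$ is a cross-entropy: the observed $p$ weights the log of the
adjusted $p_\alpha$, exactly as the defining formula reads. We deliberately
do not "repair" it to $-\sum p_\alpha \log p_\alpha$. Consequences worth
knowing:

* $I_0 = I$ exactly, and $I_\alpha \le I_0$ for all $\alpha$ (Gibbs'
  inequality), with background-to-foreground overlap penalized by up to
  $-\log(1-\alpha)$ per unit mass.
* At $\alpha = 1$ a cell with $p > 0$ but $p_\alpha = 0$ makes
  $I_1 = -\infty$; the optimizer treats that as "worst possible", which is
  the sensible reading of a transform that pairs observed sample with
  forbidden background.
* Scores can be slightly negative (an off-slide template scores
  $\approx \log_2(1-\alpha) \cdot (1 - P(X{=}0))$), which matters for the
  optimizer's normalization below.

Logarithms are base 2 (scores in bits) by default and configurable; the
choice only scales scores and never changes an argmax.

## Transform model and interpolation

A similarity transform $(t_x, t_y, \theta, s)$ maps template pixel $x$ (row
down, column right, 0-based pixel centers) to
$x' = s\,R(\theta)(x - c) + c_m + (t_x, t_y)$, rotating and scaling about
the template center $c$ and translating relative to the moving-image center
$c_m$. Anchoring rotation and scale at the template center keeps the four
parameter axes approximately independent, which the per-parameter grid
search relies on. Rigid motion is the subgroup $s = 1$; pure translation
fixes $\theta = 0$ as well.

Index colors are categorical, so the only meaningful interpolator is
nearest-neighbour: each template pixel takes the label at the rounded mapped
coordinate. Rounding is half-up (ties toward $+\infty$), fixed for
bit-reproducibility. Coordinates falling outside the moving image receive
label 0: off-slide means no sample, and it keeps $m$ constant across
transforms so scores stay comparable.

## The optimizer

**Grid units.** Translations step in pixels. One rotation unit is the angle
that displaces the farthest template pixel (corner radius $R$) by one
pixel, $2\arcsin(1/2R)$; one scale unit is $1/R$. A step of one unit in any
parameter therefore moves no pixel by more than about 1 px, which makes the
lattice isotropic in image space and defines the finest resolution the
search ever needs.

**Initial radius by self-registration.** Registering the template against
itself along one parameter yields a score profile peaking at the neutral
transform with value $H(X)$. For each enabled parameter the initial radius
$r_0$ is the largest contiguous displacement $d$ (swept in unit steps, both
directions) with $\mathrm{score}(d)/\mathrm{score}(0) \ge k_0$, clamped to
at least 1. Templates dominated by large uniform regions yield wide peaks
and coarse initial grids; pixel-scale texture collapses the peak and forces
$r_0 = 1$. (A strict two-color checkerboard is a fun counterexample: a 1-px
shift permutes the labels and MI is permutation-invariant, so its peak does
not collapse at all.)

**Sparse search.** Level 0 evaluates the full lattice at per-parameter
spacing $r_0$. Points are *retained* when their normalized score reaches
$\nu_{\mathrm{thresh}} = k_0\,\delta_k^{\ell}$ at level $\ell$ (defaults
$k_0 = 0.6$, $\delta_k = 0.5$, i.e. thresholds 0.6, 0.30, 0.15, 0.075 of
the running maximum). Each next level halves the spacing and evaluates only
unseen lattice points within one previous-level spacing (per-parameter
Chebyshev box) of a retained point; the search stops when every parameter
reaches spacing 1 and returns the argmax over everything evaluated, ties
broken lexicographically. An evaluation cache guarantees no point is scored
twice.

Two design choices here deserve explanation, because the refinement rule
can degenerate if either is taken differently:

* *Normalization.* The threshold is a fraction of the running **maximum**,
  with score 0 (no statistical dependence) as the floor; negative scores
  count as 0. Normalizing instead between the running minimum and maximum
  would anchor the scale at the strongly negative off-slide scores and let
  large flat background plateaus clear the threshold, after which the
  refinement degenerates toward exhaustive evaluation. Should every score
  be negative (degenerate inputs), the running minimum takes over as the
  floor so the search still proceeds.
* *Nested refinement.* Retention at level $\ell$ filters only the *active*
  set — the points spawned around the previous level's retained points
  (surviving parents included). A point rejected at an earlier, stricter
  level does not re-enter later merely because the threshold has decayed.
  The refinement region can therefore only shrink, mirroring the
  successively smaller search spaces of the coarse-to-fine schedule.

With both rules the cost is the coarse grid plus a bounded box around every
level-0 survivor, typically a few percent of the full lattice; the
65 × 65-translation benchmark in the acceptance tests evaluates ~13 % of
the grid while reproducing the exhaustive argmax.

## The pipeline

`register_images()` glues the stages together. For a hyperspectral cube:
per-pixel integral absorption (trapezoid over the wavenumber axis), Otsu's
256-bin threshold for the foreground mask, then k-means on the raw spectra
(defaults: $k = 8$ for template ROIs). For the stained image: background
color estimated as the mean of pixels whose luminance reaches the 90th
percentile, optical-density cast correction (base-10 OD with reference 255,
where subtracting the background color is per-channel division), snap of
near-white pixels (RGB distance < 15) to exact white, area-average
resampling to the spectral resolution, and k-means on RGB (default
$k = 10$ for whole slides). Default $\alpha = 0.25$; rigid transforms with
rotations limited to ±30° for template matching (±180° for full
registration) and scale limited to [0.8, 1.2] when enabled. Setting
$k = 1$ on both sides reproduces the binary foreground/background variant,
which is informative exactly when the substrate geometry is (tissue
microarray cores; ROIs overlapping the section border).

One guard extends the plain intensity cutoff: a region of interest may
contain no substrate at all, in which case a threshold would split the
tissue itself. Substrate absorbs far less than tissue across the whole
spectrum, so the Otsu split is accepted only when the lower class is dark
relative to the upper (mean ratio below 0.5, configurable); otherwise the
ROI is declared all-foreground. Both automatic cutoffs (intensity and
background color) are config-exposed since neither has a canonical rule.

Accuracy is summarized by `evaluate_registration()` as the mean and maximum
displacement of the four template corners between recovered and true
transform — an interpretable pixel-scale error that is zero iff the
transforms act identically on the template.

## What the phantom generator emulates — and what it does not

`phantom_scene()` / `render_pair()` generate co-registered pairs with known
ground truth, so every stage is testable without any external data. The
default scene is a 600 × 400 px slide and a 160 × 120 px spectral ROI, both
at 5 µm/px, with 6 tissue classes. Design choices, made once:

* **Tissue geometry.** Class compartments are argmaxes of Gaussian-smoothed
  random fields with correlation length ~14 px — the scale of glands and
  stroma bands at a few µm/px — inside a smooth tissue blob (~60 %
  coverage) with a hard substrate border. Coarser compartments would widen
  the registration basin but leave so few independent structures in a
  160 × 120 template that the MI estimate between *unrelated* positions
  rises to a substantial fraction of the true peak (small-sample MI bias
  scales inversely with the number of independent structures); finer ones
  collapse the self-registration peak and with it the coarse search grid.
* **Spectra and colors.** Each class gets one dominant Gaussian band at its
  own position in the 900–1800 cm⁻¹ fingerprint region plus random minor
  bands; colors come from an H&E-like palette. Class SNR ≈ 10
  (per-band noise σ = 0.05 against unit peak amplitude; 3 gray levels
  against ~20+ color separations).
* **Within-class texture.** Each modality is modulated by its own smooth
  multiplicative field: broad (σ = 25 px) "biochemical" gradients in the
  cube, fine (σ = 3 px) staining texture in the slide. Two consequences are
  intended: oversegmentation (k = 8/10 against 6 classes) splits classes
  into spatially coherent subclusters rather than salt-and-pepper, as it
  does on real tissue; and the fine stained-side texture raises the number
  of effectively independent samples, keeping the background score level
  low. The fields are independent between modalities — biochemical and
  staining-intensity gradients are not the same physical quantity — so
  cross-modal correspondence lives at the class scale, which is what the
  registration peak should rest on.
* **RGB noise σ = 3.** Stained slides are acquired at sub-micron resolution
  and area-averaged down to the spectral resolution, which suppresses
  sensor noise; rendering directly at 5 µm/px with large noise would defeat
  the white-snap background labeling in a way real downsampled slides do
  not.
* **Stain cast.** A global per-channel multiplicative cast (default
  (236, 224, 230)) with near-white substrate (252, 252, 252), so the cast
  estimator has honest work to do.

What passing phantom tests does **not** show: robustness to resonance Mie
scattering artifacts, to spatially varying (non-global) stain casts, to
morphology differences between serial sections, or to non-linear
deformation. None of these are modeled; the scope is a rigid/similarity
overlay of the *same* physical section.

## Numerical choices and degenerate inputs

* Half-up rounding everywhere a coordinate or gray level is discretized.
* k-means: 5 k-means++ restarts, best objective kept, Lloyd iterations
  capped at 300; empty clusters reseeded at the farthest point. Fitting is
  capped at 20 000 sampled pixels (whole slides have hundreds of
  thousands), then all pixels are assigned to the nearest fitted center.
  When the data hold at most $k$ distinct points the exact optimum is
  returned directly.
* Joint tables keep zero-count rows/columns, so label 0 remains background
  even when absent from the overlap.
* Degenerate inputs fail loudly: constant intensity images, templates that
  are entirely background, or self-registration scores ≤ 0 raise errors
  rather than returning meaningless transforms; an empty retained set
  falls back to the incumbent best point rather than dying.
* `exhaustive_search()` exists as the reference optimizer and refuses grids
  beyond a configurable cap — it is a validation tool, not the method.

## Problem sizes used in validation

The acceptance-level tests run: 1000 random joint tables for metric
exactness; 200 synthetic unimodal score maps (65 × 65 translations) for
optimizer-vs-exhaustive agreement and cost; 50 full-size phantoms (rigid,
|θ| ≤ 30°, default configuration) for end-to-end recovery within 2 px and
one rotation unit; a robustness sweep over α ∈ {0.2, 0.3, 0.4} and
template cluster counts {6, 8, 10} at 10 phantoms per setting, reusing the
rendered scenes and stained-image segmentations across the α sweep; and
preprocessing checks on the phantom's cast and substrate. The sweep size
and the acceptance script's 20-phantom study are the package's chosen
problem sizes: success rates stabilize well below these n, and each
additional full-size phantom costs a render, two k-means segmentations and
a few hundred thousand metric evaluations.

## Known limitations

* The method assumes the two images show the *same* section; serial
  sections with morphology differences need non-rigid models out of scope
  here.
* Self-registration estimates the basin width from the template's own
  structure; when within-template structure is much finer than the
  cross-modality correspondence scale, $r_0$ is conservative (small) and
  the coarse grid correspondingly large — correct, but slower.
* The retention threshold presumes the true peak dominates the background
  score level at the coarse grid already; heavily degraded segmentations
  can violate this, in which case more of the space is refined (the search
  stays correct but loses its speed advantage).
* CARS-style inputs without any identifiable background work only through
  the all-foreground path (binary mode is then uninformative, as it is for
  real CARS data).
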