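---
title: "Brainstem bundle segmentation: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brainstem bundle segmentation: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`bundleseg` segments eight bilateral brainstem white-matter bundles — the
caudal and rostral medial lemniscus (MLc/MLr), superior cerebellar peduncle
(SCP), lateral forebrain bundle (LFB), mesencephalic homeostatic bundle
(MHB), brachium of the inferior colliculus (Bic), medial longitudinal
fasciculus (MLF) and central tegmental tract (CTG) — directly from diffusion
MRI. This vignette explains the model underlying each stage, the parameters
that matter, and the choices made where the design was genuinely open. The
package is evaluated entirely on synthetic tube phantoms; the last section is
explicit about what that does and does not demonstrate.

## The pipeline

A scan passes through five stages:

1. **Diffusion features.** A single diffusion tensor is fit per voxel by
   ordinary least squares in log-signal space under
   $S_g = S_0\exp(-b\,g^\top D g)$, with all volumes (including $b=0$) in the
   design — for single-shell acquisitions the $b=0$ rows are what pins the
   intercept; without them the intercept is collinear with the squared
   direction columns and the normal equations are singular. Signals are
   floored at $10^{-6}S_0$ before the log. From the clamped eigenvalues
   $\lambda_1 \ge \lambda_2 \ge \lambda_3 \ge 0$ come FA, MD, AD, RD and the
   principal direction V1. OLS (rather than weighted or robust variants) is
   deliberate: it is deterministic, exact on noiseless data, and sufficient at
   phantom-scale SNR.
2. **Probabilistic fiber map (PFM).** Streamlines are seeded in both members
   of three anchor-ROI pairs — thalamus–medulla, cerebellar gray–ventral
   diencephalon, ventral diencephalon–medulla — tracked probabilistically,
   and retained only if they touch both ROIs of their pair. Distinct-
   streamline visitation counts are clipped at the 99th percentile of
   nonzero counts and divided by the clip value ("histogram normalization"),
   giving three channels in $[0,1]$. The PFM encodes *connectivity*, which is
   exactly the information that scalar contrast lacks: two tubes with
   identical FA can carry different channel signatures.
3. **Network.** A five-level 3D U-Net (features $24 \cdot 2^{n-1}$, two
   $3^3$ convolutions with ELU per level, max-pool halving) consumes the
   five-channel stack (low-b, FA, PFM1–3) in a $64^3$, 1 mm, pons-centered
   frame and emits 17-class softmax probabilities. An attention gate sits on
   the finest skip connection only:
   $$\Phi_{att} = F_{d1} \circ \sigma\!\big(\varphi_a \otimes \mathrm{relu}(F_{e1})
     + \textstyle\sum_{n=2}^{N-1} \varphi_n \otimes \tanh(U(F_{dn}))\big),$$
   with $1^3$ convolutions $\varphi$, trilinear upsampling $U$ to full
   resolution, and the coarsest decoder level excluded from the gating sum
   (its four-voxel grid is too blocky to carry useful spatial detail). Two
   readings deserve a flag: the $\tanh$ terms are summed with the encoder
   term *inside* the sigmoid, and the gate multiplies the incoming *decoder*
   tensor $F_{d1}$ — not the encoder features as in conventional attention
   U-Nets.
4. **CRF refinement.** The softmax field is refined by a fixed number of
   mean-field iterations of a semidense CRF (below), then labeled by
   per-voxel argmax with ties broken toward background.
5. **Native-space mapping.** The frame-space label map is pulled back onto
   the input grid by the inverse crop transform with nearest-neighbor
   sampling.

## The CRF: energy, solver, and the σb default

The composite energy combines a unary negative log-likelihood
$\psi_u = -\log S$, a pairwise potential realized by convolving the
probability field with a Gaussian $K_{\sigma_K}$
($\log\psi_p \approx -\|S_{\sigma_K}(i') - S_{\sigma_K}(i)\|^2 / (2\sigma_b\sigma_K)$),
and a foreground-only entropy term
$\psi_H(i) = -\sum_{v\neq bg} S(i,v)\log S(i,v)$ that sharpens foreground
probabilities without letting the background dominate. `crf_energy()`
evaluates the printed composite form exactly as stated — including its
$4\pi\sigma_b\sigma_K$ pairwise denominator and overall sign — over unordered
voxel pairs within a Chebyshev half-span (a cube is chosen over a Euclidean
ball for consistency with the separable convolution). It is a diagnostic:
the solver can be swapped without touching it, and a brute-force triple-loop
transcription agrees with it to $10^{-8}$ relative on random instances.

The mean-field update is the package's own construction (the energy alone
does not determine one). Per iteration, per voxel and label,
$$\mathrm{logit}(i,v) = w_u \log S(i,v)
  + \frac{(K_{\sigma_K} \otimes Q)(i,v)}{2\sigma_b\sigma_K}
  + \lambda\,1_{v\neq bg}\log Q(i,v),$$
followed by a per-voxel softmax; exactly `iters` iterations, no early
stopping, so cost is linear in `iters` and independent of content. Each term
is the coordinate-wise stationarity contribution of the corresponding energy
term, and the update satisfies the limits one can check by hand: with
pairwise off, $w_u = 1$, $\lambda = 0$ it is the identity, and a uniform
field stays spatially uniform with foreground labels exchangeable.

Parameter defaults and why:

| parameter | default | meaning / rationale |
|---|---|---|
| `sigma_k` | 5 voxels | smoothing width; sized to the $64^3$ frame |
| `nbhd` | 3 voxels | pairwise half-span (kept small for run time) |
| `wu` | 1.0 | unary weight |
| `lambda` | 0.1 | entropy weight; mild sharpening |
| `sigma_b` | 0.05 | pairwise bandwidth, probability scale |
| `iters` | 5 | fixed iteration count |

`sigma_b` deserves its own paragraph. In the update above the pairwise
coupling is $1/(2\sigma_b\sigma_K)$ in logit units. A logit budget fixes its
scale: to flip an isolated voxel whose unary log-odds toward the wrong label
are up to $\approx 1.4$, the coupling times the smoothed-support difference
(at most $\approx 0.5$ between two coherent regions) must exceed that, so the
coupling must be at least $\approx 3$; with $\sigma_K = 5$ this forces
$\sigma_b \lesssim 0.07$. Since the bandwidth acts on probability
differences, which live in $[0,1]$, a sub-0.1 value is also the natural
scale. The default is 0.05 (coupling 2.0 at $\sigma_K = 5$; 6.7 at the
$\sigma_K = 1.5$ used on small volumes). A bandwidth of order 1 would make
the refiner a near-no-op: coupling 0.1 cannot override any unary preference.

$\sigma_K$ scales with the frame. On a $16^3$ test volume a 5-voxel kernel's
truncated support covers essentially the whole grid, so the smoothed field
collapses toward its global mean and carries no spatial information; the
denoising checks therefore run at $\sigma_K = 1.5$ with regions at least
$3\sigma_K$ across, the same geometry-to-kernel ratio the $64^3$ default
presumes. Probabilities are floored at $10^{-12}$ before any logarithm.

## Training

Dice loss ($\epsilon = 10^{-5}$ smoothing, foreground labels only) is the
default training penalty, paired with a class-balanced cross-entropy term
with square-root inverse-frequency voxel weights
$\omega_v = \sqrt{n/(V(\,|g_v|+1))}$. The pairing is not cosmetic: the Dice
term alone has degenerate optima that gradient descent actually finds at
desk scale. Because no penalty attaches to the excluded background class,
the network can park all background probability mass in one arbitrary
foreground class (that class's own Dice term is the only cost, and the
hardest — connectivity-ambiguous — labels get abandoned to pay it);
conversely, folding background into an unweighted Dice mean lets the easy
background term dominate and the model collapses to predicting background
everywhere. The cross-entropy term supplies dense, per-voxel gradients to
every class, removing the first attractor; full inverse-frequency weights
overshoot into foreground over-segmentation, and the square root is the
tempering that balanced both at desk scale. The plain foreground-only
score (`dice_loss()`) remains the reported validation metric. A boundary
loss (mean $L_1$ distance between pre-softmax logits and
the *negated* signed distance maps — logits positive inside a structure) and
an $\alpha = 0.5$ hybrid are available. The signed distance map is zero on
boundary voxels, negative inside, positive outside; an absent label yields a
constant positive field at the frame diagonal. Optimization is Adam at
`lr = 1e-3`, batch size 1 (whole volumes), with an 80/20 train–validation
split. Augmentation applies, identically to all channels and (spatially) to
labels: random affine (±10° per axis, ±10% scale), a smooth elastic
displacement field, per-channel intensity jitter (±10%), and Rician noise
injection. Everything is deterministic given the seed, including the C++
tracking and sampling kernels, which draw from R's RNG.

## The phantom generator

The generator is the package's study population. Tubes are cubic splines
through jittered control points, rasterized by distance-to-curve with
contested voxels going to the nearest tube; left/right tubes are exact
mirror images, and labels follow the fixed scheme (left odd, right even, in
bundle order MLc, SCP, LFB, MHB, Bic, MLr, MLF, CTG). Per-voxel tensors are
axially symmetric, aligned with the tube tangent, with eigenvalues obtained
by closed-form inversion of the FA formula at fixed MD
($7\times10^{-4}\,\mathrm{mm^2/s}$); the background is near-isotropic
(FA 0.05) with random orientations. The DWI is synthesized on a
30-direction $b = 1000$ shell plus two $b=0$ volumes at $S_0 = 100$ with
tube low-b contrast 0.8, and Rician noise
($|S + \sigma S_0(\epsilon_1 + i\epsilon_2)|$) at $\sigma = 0.05$ — SNR
20 at $b=0$, a realistic in vivo figure. Default tube radii span 1.4–3.0 mm
across bundles, giving per-bundle volumes spanning roughly a five-fold
range so size-dependence of accuracy and reliability can be probed. Radii
scale with $\sqrt{\mathrm{frame}/64}$ so bundles remain several voxels
across at reduced frame sizes.

Two bundles — MLc (thalamus–medulla) and CTG (ventral
diencephalon–medulla) — share two interchangeable mid-course lanes, and
which bundle occupies which lane is randomized per phantom. Their FA, low-b
and calibers match, so nothing in the scalar channels or in absolute
position identifies them; only connectivity (hence the PFM) does. This is
the construction behind the fiber-map ablation analysis. An optional lesion
applies a Gaussian-falloff radial displacement (mass effect) plus a
hemorrhage-like core (dark, isotropic, background-labeled), emulating
displacement-without-disconnection.

## Desk-scale study conditions

The package's own evaluation runs at a reduced problem size, chosen once:

* frame $32^3$ at 1 mm; four bilateral bundles (MLc, SCP, LFB, CTG — one
  representative per ROI pairing plus the ambiguous lane pair);
* 20 phantoms (16 train / 4 held out), Rician $\sigma = 0.05$;
* network reduced to three levels, widths [6, 12, 24], trained 22 epochs
  (Adam, constant 1e-3, batch 1);
* tracking with 5 seeds per ROI voxel, $\kappa = 30$, 45° angle cap,
  0.5 mm steps;
* test–retest harness: 20 synthetic subjects, tube-caliber scale drawn from
  $U(0.85, 1.2)$, two independently noised sessions each.

These sizes keep the full suite (two trainings, forty segmentations, all
oracles) within a desk-scale compute envelope while leaving every mechanism
of the full-size method in play. The full-size architecture (five levels,
24–384 features, $64^3$) is still constructed and audited; it is only the
*trained* models that are reduced.

## What the phantom suite shows — and what it cannot

Passing phantoms demonstrates: the oracle-verified correctness of every
computational stage; that the network can learn connectivity-dependent
labels from the PFM channels and loses exactly that ability when they are
removed; that the CRF refiner reduces label noise it was designed to
reduce; and that the end-to-end pipeline is reproducible bit-for-bit from a
seed. It does not demonstrate performance on real dMRI: phantoms have no
crossing fibers, no partial voluming, no susceptibility distortion or
motion, simplified anatomy, and a noise model (stationary Rician) far
cleaner than scanner reality. Numbers obtained here (Dice, ICC) are
properties of the synthetic conditions, not claims about clinical data.

## Numerical details worth knowing

* Trilinear resampling uses voxel-center alignment with border clamping;
  constants are preserved exactly, and outputs never leave the source range.
* Gaussian smoothing truncates at $3\sigma$ and renormalizes at borders, so
  constants are preserved everywhere, not just in the interior.
* Tracking terminates on mask exit, angle failure (after 8 rejection
  attempts), or the 120 mm length cap; steps are 0.5 mm with direction drawn
  from a von Mises–Fisher distribution about the sign-aligned local V1
  ($\kappa = \infty$ is the exact deterministic limit).
* Visitation counts are per-streamline-unique: a streamline increments a
  voxel once no matter how many of its points land in it.
* Empty-mask conventions: Dice of two empty masks is 1 (absence correctly
  predicted), empty-vs-nonempty is 0; average Hausdorff of an empty mask is
  reported missing, never 0.
* ICC is the two-way mixed-effects, absolute-agreement, single-measurement
  form (ICC(A,1)) computed from ANOVA mean squares, with F-distribution
  confidence bounds; zero between-subject variance is reported as 0 with a
  degeneracy flag.
* The LDA classifier uses a pooled covariance with a ridge of
  $10^{-6}\,\mathrm{tr}(\Sigma)/k$ against singularity; AUC is the
  Mann–Whitney statistic of the held-out scores, making it invariant to any
  monotone transform of the scores.

## Known limitations

The tracker is tensor-based (single fiber per voxel): adequate for
non-crossing phantom geometry, wrong where fibers cross. The left/right
label encoding (odd/even) is a package convention; other tools may encode
sides differently. The mean-field solver is a fixed-point scheme chosen for
its testable limits, not a provably convergent optimizer of the printed
energy (whose pairwise sign rewards, rather than penalizes, smoothed-field
agreement as printed — one more reason it is kept diagnostic). Training at
desk scale uses batch size 1 and no learning-rate schedule; real-data
training would revisit both.
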