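---
title: "Multilevel Otsu thresholding with the improved coot optimizer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilevel Otsu thresholding with the improved coot optimizer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icootseg)
```

## The problem and the model

Multilevel thresholding segments a grayscale image by choosing $k$ cut
points $T_1 < \dots < T_k$ on the gray axis, partitioning the $L = 256$
levels into $k + 1$ intensity classes. Otsu's criterion scores a candidate
set by the **between-class variance** of the histogram,

$$\sigma_B^2(T) = \sum_{j} \omega_j\,(\mu_j - \mu)^2,$$

where $\omega_j$ and $\mu_j$ are the probability mass and mean gray level of
class $j$ and $\mu$ is the global mean; the optimal thresholds maximize
$\sigma_B^2$. The package also exposes the equivalent second-moment form
$\sum_j \omega_j \mu_j^2$, which differs by the constant $\mu^2$ and shares
the argmax. Exhaustive search is exact but grows as $L^k$; for $k \gtrsim 3$
a stochastic optimizer is the practical route, and `otsu_exhaustive()`
remains available (up to $k = 3$) as a ground-truth oracle for validation.

### The coot optimizer

`coot_optim()` maintains $N$ agents in a box $[lb, ub]^d$. After the initial
uniform sampling the $NL$ fittest agents become *leaders*; the rest are
*followers*. Each iteration the exploration coefficient
$B = 1 - t/I_{max}$ decays linearly, and

* each follower, with probability `p_follow`, orbits its leader:
  $x' = L + 2 r_2 \cos(2\pi r_3)(L - x)$ with $r_2 \in [0,1]$,
  $r_3 \in [-1,1]$;
* otherwise, with probability `p_chain`, it takes the **chain** step, the
  entrywise mean with its predecessor in the population (updates are
  sequential, so the chain propagates within an iteration — the disciplined
  single-file movement the metaphor describes);
* otherwise it makes a **random** move $x' = x + B\,r_1 (R - x)$ toward a
  uniform point $R$ of the box, the stagnation-escape component;
* each leader moves around the global best,
  $B r_4 \cos(2\pi r_3)(g - L) \pm g$, the sign flipping with probability
  one half.

The improved variant adds, per iteration, (a) a **Lévy-flight pass**: each
agent is perturbed with probability `p_levy` by a heavy-tailed Mantegna step
$0.01\,u\sigma(\beta)/|v|^{1/\beta}$ with $u, v \sim \mathcal N(0,1)$ and
$\beta = 1.5$, keeping the fitter of the pair; (b) a
**quasi-opposition pass**, gated per iteration by `jumping_rate`: every
agent is compared with a uniform draw between the box center and its mirror
point $ub + lb - x$, again keeping the fitter. The Lévy tail supplies
occasional long exploratory jumps; quasi-opposition adds diversity and
accelerates convergence toward central optima. The best-so-far solution is
retained elitistically, so the convergence trace is monotone by
construction.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `n_agents` | 30 | population size; 30 is the conventional swarm budget |
| `leader_frac` | 0.1 | fraction of agents that are leaders ($NL = \lceil 0.1 N\rceil$) |
| `max_iter` | 100 | iteration budget; 100–300 suffices for $k \le 5$ thresholding |
| `beta` | 1.5 | Lévy exponent (gray levels are unitless); 1.5 is the customary heavy-tail compromise |
| `alpha` | 1 | Lévy step scale |
| `p_follow`, `p_chain` | 0.5, 0.5 | follower behavior mix |
| `p_levy` | 0.5 | per-agent Lévy perturbation probability |
| `jumping_rate` | 0.3 | per-iteration probability of a quasi-opposition pass |

The follower mix and the two improvement gates are not prescribed by the
method's description, which presents the operators but not their schedule;
they are therefore explicit, documented knobs rather than hard-coded
constants, with defaults chosen so every operator is exercised regularly.

## Design choices where the design was open

* **Lévy application.** The literal update rule is an entrywise product of
  the position with the step, which annihilates positions whenever the step
  is near zero (its typical value, $\sim 0.007$). The default is the
  standard additive Lévy walk $x + \alpha \cdot \text{step}$;
  `levy_mode = "multiplicative"` preserves the literal reading.
* **Lévy variates.** Mantegna's $\sigma(\beta)$ only has its distributional
  meaning for Gaussian numerator/denominator draws, so the default is
  standard normal; `levy_draws = "uniform"` is available for comparison.
  The $\sigma$ expression's final factor is $2^{(\beta-1)/2}$.
* **Replacement rule.** Both improvement passes are greedy (keep the fitter
  of original and candidate), the standard opposition-based-learning
  selection.
* **Leader count.** $NL = \lceil 0.1 N \rceil$, the original convention for
  this optimizer family; configurable.
* **Boundary handling.** Clamp to the nearest bound after every public
  update — the simplest contract that keeps all evaluated points feasible.
* **Reduction invariant.** With `p_levy = 0` and `jumping_rate = 0` the
  improved variant draws no extra random numbers at all, so it reproduces
  the baseline trajectory bitwise at the same seed. This is a deliberate
  RNG-layout decision and is tested.
* **Threshold decoding.** Agents are continuous; at evaluation time each
  coordinate is rounded, clamped into $[1, L-1]$ and sorted, and duplicates
  are pushed to the next free integer (cascading down from $L-1$ on
  overflow). Keeping the search space continuous matches the optimizer's
  initialization law and keeps it generic.
* **Class convention.** A pixel with gray level $g$ belongs to class $j$
  iff $T_j \le g < T_{j+1}$ ($T_0 = 0$, $T_{k+1} = L$): labels equal the
  number of thresholds at or below the pixel. The same convention is used
  by the objective, the oracle, and the segmentation renderer. Empty
  classes are legal and contribute zero variance (the continuous limit of
  the criterion).
* **Rendering.** A segmented image replaces each pixel by its class's mean
  intensity (rounded); `render = "midpoint"` uses interval midpoints
  instead. Class-mean rendering is what the thresholding literature scores
  with PSNR/SSIM/FSIM against the original image, which is also the
  reference image used here.

## Quality metrics

`img_psnr()` is $20\log_{10}(255/\mathrm{RMSE})$ with RMSE the root mean
*squared* difference; identical images give an explicit `Inf` (serialized
as the string `"inf"` in JSON reports, never silently capped).

`img_ssim()` uses whole-image statistics by default — the single-window
formulation with $C_1 = 6.5025$, $C_2 = 58.52252$ — because that is the
formulation used when scoring thresholded segmentations; the familiar
11×11 sliding-window mean SSIM is available via `windowed = TRUE`.
Variances are population moments.

`img_fsim()` combines phase-congruency similarity and gradient-magnitude
similarity, weighted by the pointwise maximum phase congruency, with
$T_1 = 0.85$ and $T_2 = 160$ (the customary constants for 8-bit images;
they are recorded in every `metric_report()`). Gradients use the Scharr
stencil. Phase congruency is computed from a log-Gabor bank (4 scales, 4
orientations, minimum wavelength 6, multiplier 2, $\sigma_{onf} = 0.55$)
in the PC2 local-energy formulation **without** the Rayleigh
noise-compensation term: the synthetic images used for validation have no
sensor noise floor to estimate, and omitting it keeps the map a pure
filter-bank property. Published FSIM figures from other implementations
will therefore differ in the third decimal or so; all structural laws
(range, identity, symmetry, degradation under distortion) hold and are
tested. Two identical featureless images are defined to have FSIM 1;
differing featureless images raise an error rather than returning 0/0.

## The synthetic generator

`synth_multimodal_image()` emulates the material this method is evaluated
on: images whose histograms are mixtures of 2–6 Gaussian modes, like
natural scenes and chest CT slices with multiple tissue peaks. Pixels are
laid out in contiguous horizontal bands (one per mode, heights proportional
to weights) so a correct segmentation is visually checkable; the
three-mode reference spec (`three_mode_spec()`: means 60/128/200, sd 8,
equal weights, 128×128) gives a cleanly trimodal histogram whose exhaustive
optima are cheap to compute. `synth_two_delta_image()` is the exact-oracle
fixture: two spikes whose bilevel optimum is $(high - low)^2/4$ in closed
form. What these fixtures do **not** emulate: spatial texture, correlated
noise, illumination gradients, unbalanced class masses, or histogram skew —
so passing tests demonstrate correctness of the objective and optimizer,
not segmentation quality on arbitrary real photographs. Loaders for
user-supplied PNG/TIFF/PGM/JPEG images are provided (`read_gray_image()`,
with luma conversion and optional bilinear resize to the conventional
512×512 benchmark size via EBImage).

## Numerical choices and problem sizes

The objective precomputes the cumulative mass and first-moment sums once
per histogram, making each evaluation $O(k)$. The exhaustive oracle
enumerates lexicographically and replaces only on strict improvement, so it
returns the lexicographically smallest optimal tuple; the stochastic
optimizer is compared on fitness, not on threshold identity, since plateaus
of equivalent cuts are common. Validation in the test suite uses 64×64 to
128×128 fixtures, 30 agents, and 200–300 iterations with 20 seeds per
property — sizes at which the exhaustive oracle is exact and replicated
runs are cheap; the acceptance script uses the same conditions.

## Known limitations

* The optimizer is a stochastic heuristic: recovery of the exact optimum is
  a statistical property (validated at ≥95% across seeded runs for one and
  two thresholds), not a guarantee.
* Quasi-opposition biases sampling toward the box center, which is a known
  strength on centered optima (e.g. the sphere benchmark) and a weaker aid
  when optima hug the boundary.
* Only 8-bit single-channel data are supported; 16-bit inputs must be
  rescaled by the caller.
* The whole-image SSIM is not comparable in absolute value to windowed
  mean-SSIM figures from image-processing toolboxes (use
  `windowed = TRUE` for those comparisons).
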