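# avsmotion

Biological visual systems learn to perceive motion direction without
labelled data: direction-selective retinal ganglion cells respond to local
motion, and downstream neurons self-organize so that cells preferring the
same direction converge onto one macroscopic detector. `avsmotion` is an R
implementation of that idea as a complete, testable pipeline — an
*unsupervised artificial visual system* that takes a pair of consecutive
images and returns the global motion direction of the object in them. It
is intended for computational-neuroscience and biomimetic-vision work
where the question is how a population read-out of simple local detectors
can be organized by unsupervised learning.

## The model in brief

Two layers:

1. **Local motion detection neurons (LMDNs).** Eight per pixel, one per
   direction (0° = rightward, counterclockwise in 45° steps). Each
   combines a bipolar cell `BC = 1[|X(i,j,t) − X(i,j,t+Δt)| > L]`, a
   horizontal cell `HC = 1[|X(i,j,t) − X(i+α,j+β,t+Δt)| > L]` and a
   ganglion stage `BC · ¬HC`, so it fires only for one-pixel motion along
   its preferred offset `(α, β)`. An activated neuron emits a normalized
   16-dimensional *index vector* encoding its direction (which dimension
   pair is nonzero) and grid position (the values `(a+h, a+w)/c`).

2. **A Gaussian mixture model fitted by EM, written from scratch.** The
   index vectors of all `H·W·8` neurons (8192 for a 32 × 32 retina) are
   clustered into `K = 8` components via responsibilities
   `R_ik ∝ π_k N(I_i | μ_k, Σ_k)` and the standard weighted updates, with
   log-space densities, diagonal covariance regularization, random
   restarts and a log-likelihood-driven split-and-merge refinement.
   Component labels are calibrated to direction angles automatically from
   the component means, and a frame pair's global direction is the
   direction whose component receives the most activated neurons.

The synthetic stimulus generators reproduce the reference benchmark:
uniformly coloured random 4-connected objects on uniformly coloured
backgrounds, translated one pixel per frame step, corrupted by static
randomly coloured noise pixels that do not move with the object.

## Worked example

```r
library(avsmotion)

model <- avs(seed = 1)        # train on the full ideal set, 32 x 32 retina
model
#> unsupervised AVS: 32 x 32 retina, 8192 LMDNs
#> GMM trained on 8192 index vectors, log-likelihood 633477.47 (23 update(s), converged)
#> component sizes: 1024 1024 1024 1024 1024 1024 1024 1024
#> training purity: 1.0000
```

All 8192 neurons split into eight components of exactly 1024 — one
component per direction, each direction-pure. Which component stands for
which angle is arbitrary and is calibrated after every run:

```r
model$label_map
#>   label direction angle        name
#> 1     0         6   270        down
#> 2     1         2    90          up
#> 3     2         1    45 upper-right
#> ...
```

Detect the motion of a simulated 64-pixel object moving right under 5%
static noise:

```r
sim <- simulate(model, nsim = 1, seed = 7, size = 64,
                direction = 0, noise = 0.05)
predict(model, sim[[1]])
#> global motion direction: 0 (0 degrees, right)
#> activated neurons per direction (0..7): 30 22 13 5 3 5 8 17
```

The rightward detector receives 30 activated neurons — the number of
pixels whose change is consistent with rightward motion — while competing
directions receive fewer; the argmax is the answer. An accuracy sweep over
object size and noise level:

```r
accuracy_grid(model, sizes = c(4, 16, 64), noise_levels = c(0, 0.10),
              trials_per_cell = 80, seed = 3)
#> detection accuracy (80 trials per cell)
#>     noise
#> size 0%      10%
#>   4  100.00% 98.75%
#>   16 100.00% 100.00%
#>   64 100.00% 100.00%
```

Small objects under heavy noise occasionally lose their one-pixel margin
to an exact count tie; from eight pixels upward detection is essentially
perfect. Models serialize losslessly with `save_avs()` / `read_avs()`, and
`inst/cli/avsmotion.R` wraps simulate/train/detect/evaluate for shell use.

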