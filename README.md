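# gpfseg

Level-set segmentation of 2D grayscale images, driven by a **global
gradient-vector-interaction image feature** (the geometric potential
field) and regularized by a **nonparametric kernel-density shape prior**
over signed distance functions.

## Who this is for

Researchers segmenting anatomical structures from noisy, inhomogeneous
biomedical images — rings, cross-sections, organs with known shape
families — where purely local edge information fails: heavy noise, weak
or broken boundaries, occlusions, and intensity ramps.  The package is a
library plus a small command-line tool; synthetic phantom generators make
it fully testable without any external data.

## The model

Segmentation minimizes `E(φ) = E_image(φ) + ν·E_shape(φ)` over a level-set
function φ (positive inside).  The image term uses the interaction field

    G(x) = Σ_{x'≠x}  r̂_xx' / r_xx'^λ · ∇I(x'),        λ = 2,

the sum of all image gradient vectors projected onto the direction toward
x with inverse-power distance weighting.  G is global (every edge attracts
from anywhere), bidirectional (it changes sign across boundaries, so
cross-boundary initializations work), and robust to noise (randomly
oriented noise gradients cancel).  It is computed exactly as a zero-padded
FFT convolution, with an O(n²) brute-force path kept as the test oracle.
The evolution is

    ∂φ/∂t = δ_ε(φ) [ ρ div(g ∇φ/|∇φ|) − G ] + ν · shape flow,

with the edge-stopping function g = 1/(1+|∇I|).  The shape prior is a
kernel density estimate over training shapes φ_i (signed distance
functions, centroid-aligned):

    E_shape(φ) = −log (1/N) Σ_i exp(−d²(φ, φ_i) / 2σ²),

where d² is the squared indicator distance after translating φ so its
center of gravity matches the training alignment — invariant to object
location.  Its gradient flow pulls the contour toward each training shape
with softmax weights α_i, letting the model complete occluded parts and
ignore misleading image forces.

## Worked example

The bundled study reproduces the package's core claim end to end: two
annuli under a linear intensity ramp with 40% of all pixels replaced by
noise, segmented from a single circle crossing both objects, no prior:

```r
library(gpfseg)
st  <- study_noisy_annuli(1)                 # image, truth, init, config
res <- evolve(st$image, st$phi0, NULL, st$cfg)
res
#> Level-set segmentation: 128x128 grid, 660 iterations (converged)
#>   foreground pixels: 2007; nu = 0; contours: 4
accuracy_report(res$mask, st$truth)
#> FG 96.7%  BG 99.3%  overall 98.0%  Dice 0.9569
```

FG/BG are the percentages of true foreground/background pixels classified
correctly; *overall* is their unweighted mean (robust to the large
background class); Dice is the overlap coefficient.  Four contours =
outer + inner boundary of each ring: the inner boundaries were nucleated
by the initialization circle crossing the holes.

With a 20-shape prior the same machinery recovers a ring that is 70%
noise-corrupted *and* partially deleted by an occlusion
(`study_occluded_annuli()`), scored against the unoccluded truth.

## Command line

```sh
gpfseg simulate    --kind annulus --spec spec.yaml --out sim/
gpfseg build-prior --masks masks/ --out prior/
gpfseg segment     --image sim/image.png --init circle:64,64,32 \
                   --prior prior/ --config cfg.yaml --out run/
gpfseg evaluate    --pred run/mask.png --truth sim/truth.png --out report.json
```

Every run writes the final mask (PNG), φ (float TIFF), sub-pixel contour
polylines and the iteration trace (CSV), the fully resolved configuration
(including the numeric value an `"auto"` ν resolved to), and a manifest
with checksums.

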