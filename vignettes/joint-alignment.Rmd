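---
title: "Joint alignment and reconstruction of jittered tomographic projections"
author: "tomojoint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint alignment and reconstruction of jittered tomographic projections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tomojoint)
```

## The problem

In parallel-beam tomography a 3D object $f$ is observed through $S$
projection images $p_i$ taken at tilt angles $\theta_i$. At the nanoscale,
imperfections of the rotation stage (runout, thermal drift) translate each
projection by an unknown amount before it reaches the detector, so the
measurement model is

$$ p_i = T_i(h_i, v_i)\, W(\theta_i)\, f + e_i, $$

where $W(\theta_i)$ is the line-integral (Radon) projector, $T_i$
translates the 2D image by $h_i$ pixels transverse to the rotation axis
and $v_i$ pixels along it, and $e_i$ is additive noise. Unless the
$(h_i, v_i)$ are recovered, reconstructions are blurred and small features
are lost entirely.

`tomojoint` recovers both $f$ and the per-projection translations from the
jittered stack alone. Two drivers are provided:

* **Sequential** (`alignSequential()`): the conventional iterative
  reprojection schedule — run a block of $N$ reconstruction iterations,
  reproject, register each measured projection against its reprojection,
  correct, and repeat the whole block $M$ times ($N \times M$
  reconstruction updates for $M$ alignment refinements).
* **Joint** (`alignJoint()`): one registration pass after *every*
  reconstruction update. Alignment information flows back into the
  reconstruction immediately, so the combined estimate needs only $N$
  reconstruction updates total — $\mathcal{O}(N)$ instead of
  $\mathcal{O}(NM)$ — and in practice converges dramatically faster.

Each iteration of the joint driver is: (a) one reconstruction update on
the currently corrected stack; (b) reprojection of the new object at all
angles; (c) per-projection sub-pixel registration of the corrected stack
against the reprojection; (d) accumulation of the corrections. The
corrected stack is always re-derived by translating the *original*
measured images by the cumulative correction, so interpolation blur never
compounds across iterations.

## Operators and their discretization

The projector is voxel-driven: for each angle the in-plane grid is sampled
on a rotated unit lattice with bilinear interpolation and summed along the
ray direction. Axial rows are decoupled (each axial slice projects onto
one detector row), which both matches the physics of parallel beam and
makes the inner loops cache-friendly; the kernels live in C++.
`backProject()` is the exact matched transpose — the adjoint identity
$\langle Wf, p\rangle = \langle f, W^Tp\rangle$ holds to machine
precision, which the SIRT and MLEM convergence guarantees rely on. The
rotation axis is fixed at the grid centre and never re-estimated: the
back/re-projection operator anchors object updates at the centre of the
detector field of view, and residual centre errors appear as a constant
transverse shift, which the registration loop corrects like any other.

The translation operator is a real-space bilinear warp with zero fill,
not an FFT phase ramp: measured projections are compactly supported, and
circular wrap-around would inject spurious features at the opposite frame
edge for the large (up to ±10 px) shifts handled here. Integer shifts are
exact permutations on interior pixels; the zero-fill intensity leakage is
proportional to the content crossing the frame edge.

Angles are degrees at every interface and converted to radians once,
internally.

## Reconstruction kernels

* **SIRT** (`sirtUpdate()`): $f \leftarrow f + \lambda\, C\, W^T R\,
  (p - Wf)$ with ray-length ($R = 1/W\mathbf{1}$) and voxel-coverage
  ($C = 1/W^T\mathbf{1}$) normalizations, $\lambda = 1$. Rays and voxels
  with empty support are left untouched. On consistent data the residual
  decreases monotonically.
* **MLEM** (`mlemUpdate()`): $f \leftarrow f \cdot W^T(p / \max(Wf,
  \epsilon)) / W^T\mathbf{1}$. Multiplicative, hence nonnegativity
  preserving, with exact data as a fixed point. The null initialization is
  all ones (a multiplicative update cannot leave zero), and negative
  measured pixels — possible after additive Gaussian noise — are clipped
  to zero with a logged count. $\epsilon$ (default $10^{-12}$) floors
  empty rays.
* **FBP** (`fbp()`): frequency-domain ramp filtering followed by
  backprojection with $\pi/(2S)$ weighting. The discrete ramp is the DFT
  of the exact band-limited spatial kernel ($h(0) = 1/4$, $h(k) =
  -1/(\pi k)^2$ for odd $k$), not the naively sampled $|k|$, which would
  underestimate low frequencies and bias reconstructed densities by
  roughly 10%. FBP stands in for the direct Fourier class of methods
  (GridRec and relatives), which is only needed qualitatively here: the
  interesting result is that it performs poorly inside the alignment loop
  when the Crowther criterion is violated.

## Sub-pixel registration

`phaseCorrelate()` estimates the translation between a measured projection
and its reprojection from the peak of the inverse-transformed cross-power
spectrum, refined on a $1/\texttt{upsampleFactor}$-pixel grid (default
0.01 px) by evaluating the correlation surface in a ±0.75 px
neighbourhood of the integer peak with a local matrix-multiply DFT.

One design choice deserves emphasis. The textbook "phase correlation"
whitens the cross-power spectrum to unit magnitude, which produces a
delta-like peak for image pairs of comparable sharpness. Inside the joint
loop, however, the reference is the reprojection of a one-iteration
reconstruction — strongly low-pass. Whitening then amplifies
high-frequency bins that carry no coherent signal, and the peak is
swamped: in our measurements the estimated shifts decorrelate completely
from the truth and the loop never converges. The *un-normalized*
cross-power correlation (which is what the classic efficient sub-pixel
registration algorithm, and the library implementations built on it,
actually compute) is robust to the sharpness mismatch and is therefore
the default (`method = "cross"`); fully whitened correlation remains
available as `method = "phase"` for sharp, noise-matched pairs. An
optional Hann window (`window = "hann"`) suppresses frame-edge artifacts
in experimental data; it is off by default because the simulated
projections are compactly supported.

## The gauge: what alignment cannot recover

A global translation of the object is invisible to the data: displacing
$f$ by $(dx, dy, dz)$ produces exactly the consistent per-projection shift
family $h_i = dx\cos\theta_i + dy\sin\theta_i$, $v_i = dz$. Any member of
this family is an equally valid solution, so absolute shift recovery is
only defined up to this three-parameter gauge. Two consequences:

* By default the drivers *anchor* the cumulative correction after every
  registration pass (`anchorShifts = TRUE`): the least-squares
  cosine/sine component is removed from the transverse corrections and
  the mean from the axial corrections. This keeps the reconstruction
  centred on the grid instead of letting early registrations against
  blurry references select a displaced member of the family. A *constant*
  transverse offset is deliberately kept — it encodes a rotation-centre
  error, which the data do identify and the loop corrects.
* Residual errors against ground truth contain an irreducible component:
  the gauge part of the drawn jitter itself, of magnitude roughly
  $w\sqrt{2/(3S)}$ per transverse degree of freedom for jitter uniform on
  $\pm w$ across $S$ projections (just under a pixel at the benchmark's
  $w = 10$, $S = 100$).
  This is why convergence is measured with the *successive-iteration*
  relative MSE $\|x_k - x_{k-1}\|^2 / \|x_{k-1}\|^2$ (per axis, relative
  to the previous iterate) — a gauge-invariant quantity — while
  per-projection recovery against truth is judged against the one-pixel
  bound, which comfortably absorbs the gauge term.

## The simulation benchmark

`simulateDataset()` reproduces the reference study conditions: a
three-sphere phantom of unit density on an $n^3$ grid (radii $0.30n$,
$0.15n$, $0.06n$ at distinct off-axis positions — exact sphere parameters
are a package convention chosen so that the smallest sphere is resolvable
only after alignment, and so that every sphere stays inside the
reconstructable cylinder under ±10% field-of-view jitter), $S$ projections
uniformly over $[0°, 180°)$ (half-open: $0°$ and $180°$ are redundant in
parallel beam), per-projection translations drawn uniformly from
$\pm 10\%$ of the field of view on both axes, and additive zero-mean
Gaussian noise with standard deviation a fraction (0, 5, 10 or 20%) of the
*global* stack maximum (per-stack rather than per-projection, so all
projections share one noise floor). Jitter and noise take separate seeds
so the noise level can vary at a fixed jitter realization.

The reference scale is $n = 100$, $S = 100$. The package's own test and
acceptance runs use $n = 64$, $S = 60$, jitter $\pm 6.4$ px — the same
relative geometry at a desk-scale cost; all convergence claims are scale-
relative (ratios, iteration counts against thresholds, per-pixel bounds).

What the generator does *not* emulate: Poisson counting statistics,
detector point-spread and flat-field structure, in-plane rotation or
tilt-angle errors, beam hardening, or partially transparent sample
holders. Passing the benchmark therefore demonstrates correct recovery of
rigid per-projection translations under additive noise, not robustness to
every artifact of experimental data.

```{r benchmark, eval = FALSE}
ds <- simulateDataset(defaultPhantomSpec(64), benchmarkAngles(60),
                      jitterModel(6.4, seed = 11),
                      noiseModel(0, seed = 12))
res <- alignJoint(ds$projections,
                  alignmentConfig(reconConfig("sirt"),
                                  registrationConfig(), "joint",
                                  totalIters = 400),
                  truth = list(shifts = ds$shifts, volume = ds$volume))
tail(convergenceTrace(res))
```

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `totalIters` (joint) | 400 on the benchmark | reconstruction updates = registration passes |
| `innerIters`, `outerIters` (sequential) | 40, 10 | reconstruction block size and number of alignment passes |
| `upsampleFactor` | 100 | registration grid = 0.01 px; residuals on the benchmark are well below 0.1 px, so coarser grids limit final accuracy |
| `relaxation` (SIRT) | 1 | stable for the normalized update in $(0, 2)$ |
| `epsilon` (MLEM) | $10^{-12}$ | floor for empty forward-projection rays |
| `stopTol` | off | optional early stop when both axes' successive rel-MSE fall below it; the fixed 400-iteration schedule is the reference protocol |
| `anchorShifts` | TRUE | gauge anchoring, see above |
| `maxShift` | off | per-axis clamp on registration output; useful for very noisy experimental frames |

## Numerical choices and degenerate inputs

* Ties in the correlation peak are resolved to the first maximum in
  column-major order; identical images return exactly (0, 0).
* Constant images (zero spectrum) are rejected with a clear error rather
  than returning an arbitrary peak.
* Rays that miss the volume and voxels never touched by a ray are exactly
  zeroed in the SIRT/MLEM normalizations rather than divided through.
* The divergence guard aborts a run (classed condition
  `tomojointDivergence`) once the mean cumulative shift exceeds the
  detector width — the object has left the field of view and further
  iterations are meaningless.
* The successive relative MSE normalizes by the previous iterate; a
  zero-norm previous iterate yields `NA`, not an error.
* `objectMse()` compares raw voxel grids by default; `fitScale = TRUE`
  fits a global least-squares intensity scale first (iterative
  reconstructions can differ from truth by a scale, especially early).

## Design decisions that were genuinely open

* **Warm starting the sequential baseline.** The object estimate persists
  across its outer loops, so sequential ($40 \times 10$) and joint (400)
  consume identical total reconstruction work and the comparison isolates
  the *scheduling* of registration passes.
* **Registration reference.** The reprojection is always the fixed
  reference and the measured image the moving one; the returned
  correction is the translation to apply to the measured image. This
  fixes the sign convention end to end: `estimatedShifts()` (the negated
  correction) is directly comparable to the generator's ground truth.
* **Ramp-FBP inside the joint loop.** With the matched-geometry FBP
  implemented here and anchored corrections, the joint-FBP combination
  does not run away catastrophically; it aligns measurably worse than
  SIRT (several times the gauge-free registration scatter at the
  benchmark scale) rather than diverging. The catastrophic drift reported
  for gridding implementations appears to be tied to their specific
  centre handling; the package's divergence guard still covers that
  failure mode.
* **Iteration budget in tests.** Unit tests run at $16^3$–$32^3$; the
  acceptance suite runs the full protocol at $64^3$/60 angles. These
  sizes are the package's reproducibility protocol: they keep the whole
  suite desk-scale while preserving every relative claim.

## Known limitations

Only rigid per-projection translations are modelled: in-plane rotations,
tilt-angle errors and magnification drifts are out of scope, as are
cone/fan-beam and laminography geometries. Absolute object position is
unrecoverable in principle (the gauge above). Severely off-centre
rotation axes can defeat the joint loop before it stabilizes; dedicated
centre-finding can then be run beforehand. GridRec itself is not
reimplemented — ramp-FBP represents the direct Fourier class.
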