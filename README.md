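# made — Movement Artifact Direction Estimation from single frames

Motion during one exposure leaves a direction-dependent blur — a
*movement artifact* — in the captured frame. For image-quality assessment
(deciding whether a frame is usable, flagging re-acquisition, feeding
downstream deblurring) two numbers are needed from a **single** grayscale
frame, where no temporal information exists: the artifact's direction
θ (degrees) and its magnitude q (pixels). This package computes both with
a deterministic signal-processing pipeline, and ships a trajectory-based
simulator that generates ground-truthed blurred frames for validation. It
is aimed at people building imaging QA for medical or industrial capture
systems, and at anyone studying single-frame blur estimation.

## The method

The object's motion is modeled as a circular oscillation plus linear
drift,

    r(t) = (A cos ωt, A sin ωt) − v_px · t · (cos φ, sin φ),  t ∈ [0, T],

and the frame is the exposure integral of the object along r(t). The dwell
of the trajectory (one speed minimum per oscillation cycle) deposits
replica copies of the object spaced by the drift per cycle along φ — the
structure the estimator detects:

1. **MAPE** — per scanline, the normalized self-similarity profile
   r[l] = a[l]/γ (zero-padded autocorrelation over full-vector energies);
   the most prominent nonzero-lag peak (prominence = drop to the lowest
   contour line) locates the replica.
2. **ROPE** — per scanline, EMA smoothing and first differences; the
   maximum-|slope| index is the undistorted reference origin, kept only
   above a global threshold τ·max slope.
3. **MAQ** — signed displacement between origin and the closest replica
   candidate g ± l, with |q| > τ (half the analysis window) suppressed as
   implausible.
4. **MADE** — the four directional (horizontal / diagonal / vertical /
   antidiagonal) MAQ means and dispersions map to eight 3D points
   (mean displacement in x–y, swap-inverted reliability in z); the
   circularly adjacent triplet farthest from the origin is averaged into
   a center of mass whose four-quadrant angle is θ, and the θ-ray's
   intersection with the corresponding octagon edge gives q.

Angles use one shared convention: x right, y up, counterclockwise from
+x; estimates are bidirectional (θ and θ+180° denote the same orientation
class).

## A worked example

```r
library(made)
fr  <- renderObjectTrail(motionParameters(v = 0.24, phi = 30))
est <- estimateDirection(fr)
est
#> DirectionEstimate
#>   theta     = 24.05 deg (complement 204.05 deg)
#>   magnitude = 9.49 px
#>   triplet   = (1, 2, 3), segment 1
orientationError(theta(est), truthPhi(fr))
#> [1] 5.95345
```

The frame is a dark object drifting at 0.24 m/s along 30° (a 30 px trail
at the default 125 px/m calibration). The estimate lands 5.95° from the
truth: horizontal scanlines saw replica displacements of ~8.3 px and
diagonal ones ~6.7 px (`est@diagnostics$stats`), and the center of mass of
the dominant octagon triplet interpolates between those two axes. The
magnitude 9.49 px is the 3D distance to the octagon boundary along θ —
the replica spacing, i.e. drift per oscillation cycle, plus the
reliability component.

A command-line wrapper with `simulate`, `estimate`, `sweep` and `report`
subcommands lives at `system.file("cli", "made.R", package = "made")`.

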