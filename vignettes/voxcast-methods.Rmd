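---
title: "voxcast: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{voxcast: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

voxcast is a headless, scriptable volume renderer for multichannel 3-D
fluorescence microscopy stacks. This vignette records the model it
implements, the parameters that matter, the numerical conventions, and the
design decisions taken where more than one reasonable choice existed. It
states no empirical result that the test suite does not itself compute.

## The rendering model

### 8-bit volumes with per-channel linear normalization

Rendering operates on volumes quantized to 8 bits per channel (the regime of
GPU texture samplers, and a good match for 8–10-bit displays). Each
channel's intensity range $[\min_c, \max_c]$ is mapped linearly onto codes
$0..255$ with round-half-up; the inverse affine map (offset, scale) is kept
per channel, so raw intensities are recoverable to within half a code,
$(\max_c - \min_c)/510$. Normalization is **per channel**, not global: in
multichannel fluorescence the channels routinely differ in dynamic range by
orders of magnitude, and per-channel scaling maximizes code utilization for
each fluorophore. Constant channels map wholly to code 0 with scale 0.
Rounding is round-half-up (`floor(x + 0.5)`), not banker's rounding, so
tests can be exact.

### The transfer function

Each channel maps normalized voxel intensity $i_{in} \in [0,1]$ to emissive
intensity through a piecewise monotonic quadratic,

$$
i_{out} = \begin{cases}
0 & i_{in} \le i_{dark} \\
a\,i_{in}^2 + b\,i_{in} + c & i_{dark} < i_{in} < i_{bright} \\
1 & i_{in} \ge i_{bright},
\end{cases}
$$

with $a, b, c$ the unique solution of $f(i_{dark}) = 0$,
$f(i_{bright}) = 1$ and $f\!\left(\tfrac{i_{dark}+i_{bright}}{2}\right) =
i_{mid}$. In normalized coordinates $u = (i_{in} - i_{dark}) /
(i_{bright} - i_{dark})$ the quadratic is $A u^2 + B u$ with
$A = 2 - 4\,i_{mid}$ and $B = 4\,i_{mid} - 1$; the endpoint derivatives $B$
and $2A + B$ are both non-negative exactly when $i_{mid} \in [1/4, 3/4]$.
That interval is therefore the monotone region, and requested `mid` values
are **clamped** into it rather than rejected — slider semantics: dragging
past the limit pins the curve at the limit. $i_{mid} = 0.5$ gives $a = 0$
exactly (a linear map); $i_{mid} > 0.5$ is concave down (lifts dim
structure), $i_{mid} < 0.5$ concave up (suppresses haze). Each channel
additionally carries a global opacity `alpha`, a color, and a visibility
flag. Inputs outside $[0,1]$ are clamped with a warning rather than
rejected, since dequantized codes are normalized by construction.

### Raycasting and compositing

One perspective ray is cast per pixel. Within the volume box, samples are
taken at uniform world-space steps of `step_scale` × the **smallest**
world-space voxel extent — "voxel-sized" sampling is directionless in an
anisotropic volume, and the smallest extent guarantees the finest axis is
not undersampled. At each sample, channels are combined as

$$
a_c = i_{out,c} \cdot \alpha_c,\qquad
\alpha_s = 1 - \prod_c (1 - a_c),\qquad
c_{rgb} = \frac{\sum_c a_c\,\mathrm{color}_c}{\sum_c a_c},
$$

i.e. union opacity with an opacity-weighted color average (zero color when
nothing emits). Opacity couples to emission through the single transfer
curve, so "bright" is simultaneously fully emissive and fully opaque.
Samples accumulate front-to-back with the over-operator on premultiplied
color, $C \leftarrow C + (1-\alpha)\,\alpha_s\,c_{rgb}$,
$\alpha \leftarrow \alpha + (1-\alpha)\,\alpha_s$, terminating early once
$\alpha \ge$ `early_termination_alpha` (default 0.995 — "fully opaque"
needs a numeric threshold). The final pixel is $C + (1-\alpha)\,bg$. The
model is emission/absorption only: no lighting, no gradient shading, no
maximum-intensity mode. Outside the box the volume is zero-padded.

The exact multichannel blend and the termination threshold are this
package's documented choices; pixel-exact parity with any particular GPU
viewer is explicitly not a goal (camera constants of such viewers are
unpublished). What the tests establish instead is internal consistency: the
compiled ray marcher agrees with an independently written pure-R
straight-line integrator to 1e-9 per pixel.

### Camera, picking and the sampling plane

The volume's physical box (`dims` × `physical_voxel_size`, so anisotropy is
honored) is centered at the origin and scaled so its largest extent is 1
world unit. The camera sits at 2.5 world units, 30° vertical field of view,
near/far 0.01/10 — chosen so the unit box fills roughly 70% of the viewport
at zoom 1; no published values exist for these, so absolute screenshot
comparison is out of scope. Zoom scales the ray grid in view space
(dolly-free), and pan translates the volume in the view plane; neither
changes the picking math.

The sampling plane is always perpendicular to the view axis, at signed
depth `plane_depth` from the volume center, **positive toward the camera**.
Clip modes: `off` renders the full segment; `front` renders only the
sub-segment at or behind the plane (the classic cut-away: plane at the near
edge shows everything, moving it backwards eats into the volume); `plane`
takes a single sample exactly at the plane, yielding an oblique slice.
Picking intersects a pixel's ray with the plane and converts the hit to a
voxel index under a fixed convention: 0-based indices, half-open cells,
voxel centers at index + 0.5, continuous coordinates floored. The
projection/picking round-trip is exact on voxel centers (verified
exhaustively on small volumes); off-volume hits report `"outside"`.

Rotation state is kept orthonormal by snapping to the nearest rotation
(polar decomposition via SVD) after every composition, so thousand-frame
scripted movies cannot drift.

## Control API

A localhost httpuv server exposes the session: `POST /loadImage` (JSON
metadata in the `X-Volume-Meta` header, raw little-endian channel-major
bytes in the body; uint8 passes through as codes, uint16/float32/float64
are quantized on arrival), `GET/PUT /renderParams` and `/viewParams`
(partial documents allowed; absent fields unchanged; every GET serializes
through one canonical function so identical state yields identical bytes),
`PUT /uiParams` (overlay toggles), and `GET /captureImage` (deterministic
PNG). The wire format is this package's own documented convention — no
published one exists. Default port 8307; invalid requests never mutate
state; a client implementing only `loadImage` + `captureImage` gets a
complete default rendering (the piecemeal-API contract). The R client is a
thin pass-through and can auto-start a server subprocess.

## Movies

Stages interpolate one parameter linearly over `round(duration_s * fps)`
frames; rotations compose equal per-frame delta matrices rather than
slerping, matching scripted-delta semantics, with the endpoint equal to the
closed-form rotation to 1e-7. The packaged sample movie runs, at 10 fps:
a 1 s zoom (10 frames, zoom 1 → 1.5), a 5 s 180° y-rotation (50 frames), a
2 s front-clip plane move (20 frames) from the box edge to 10% of the
view-axis extent behind the center, a second 5 s 180° y-rotation returning
to the start view, and a 2 s slice fly-out toward the camera. The three
stage lengths 10/50/20 are the scripted values; the second rotation and the
fly-out have no published lengths and are set to 5 s and 2 s for symmetry —
documented, not asserted. "A little back from the volume center" is fixed
at 10% of the view-axis extent. The PNG sequence is the bit-exact,
reproducible surface; MP4 muxing is best-effort convenience only.

## Synthetic data

The generator stands in for real spheroid-nucleus stacks (e.g. H2B-labelled
MCF10A cells). `blobs` sums isotropic Gaussian spots with seeded random
centers, widths in `[min(dims)/16, min(dims)/9]` and amplitudes in
`[0.5, 1]` per channel — bright, roughly round, partially overlapping
objects of nucleus-like scale. Centers are rejection-sampled to at least
2.5× the maximum width apart, since distinct nuclei do not coincide; this
also makes "n blobs ⇒ n local maxima" structural rather than accidental.
`single_voxel` and `gradient` are exact probes for
projection/occlusion and intensity mapping. What the generator does **not**
emulate: photon noise, background autofluorescence, bleed-through, the
axial PSF elongation, or intensity attenuation with depth. A green test
therefore establishes geometric and compositing correctness, not
photometric realism on microscope data.

## Numerical conventions worth knowing

- Sampling positions along a clipped segment `[t0, t1]` are
  `t0 + (k + 0.5) * step` for `k < ceiling((t1 - t0)/step - 0.5)`; the
  independent test oracle follows this documented convention.
- Overlays (plane grid at 1/8 intervals of the plane's visible extent;
  coordinate readout of the viewport-center voxel) draw only while the
  plane is active (`clip_mode != "off"`). This keeps the default capture of
  an all-zero volume exactly equal to the background while letting the
  overlay toggles default to on.
- Degenerate inputs: constant channels quantize to code 0 with scale 0; an
  empty (NULL) volume renders a uniform background; a plane outside the box
  yields `"outside"` picks and background slices; `mid` outside the
  monotone interval clamps; non-rotation matrices are rejected at 1e-6
  orthonormality / 1e-3 determinant tolerance, then snapped.
- All movie/render determinism is bitwise for fixed inputs; the only
  entropy source anywhere is an explicit seed.

## Known limitations

Whole volumes live in memory (no tiling or multiresolution); TIFF support
is baseline uncompressed grayscale multi-page; there is no lighting model;
HTTP is localhost-only, single-session, unauthenticated by design.
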