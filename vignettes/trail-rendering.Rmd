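---
title: "How chronotrails turns locomotion videos into time-coded trails"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How chronotrails turns locomotion videos into time-coded trails}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronotrails)
```

## The problem

A plate of *C. elegans* under a wide-field camera produces minutes to hours
of video in which the interesting signal — where each animal went, and when
— is spread thinly across thousands of frames. `chronotrails` condenses such
a recording into trail images: every pixel a worm visited is lit and colored
by visit time, over the whole recording (a still) or over a trailing
temporal window (a video of recent paths). This vignette explains the model
behind each stage, the parameters that matter, and what the synthetic tests
do and do not establish about real recordings.

## Image model and preprocessing

We model a frame as

\[ I_t(x) = V(x)\,\big[ B(x) + W_t(x) \big] + \eta_t(x), \]

with \(B\) a static background (agar, lawn texture), \(W_t\) the moving
worms (positive in darkfield, negative in brightfield), \(V\) a smooth
multiplicative vignette from the optics and illumination, and \(\eta_t\)
sensor noise. All intensities live on a normalized \([0,1]\) scale
regardless of source bit depth, so gain and offset parameters mean the same
thing for 8- and 16-bit sources.

**Brightness normalization** (`normalize_brightness()`) multiplies each
frame by `target / mean(frame)`. It removes global flicker that would
otherwise masquerade as change during average subtraction. The default
target, the grand mean of per-frame means, preserves the recording's
overall exposure.

**Vignetting correction** (`estimate_vignette()`, `correct_vignette()`)
exploits a separation of spatial scales: worms are a few pixels wide,
vignetting varies over the whole field. Blurring the temporal average frame
with a Gaussian of `sigma_px` (default \(\min(H,W)/8\)) leaves essentially
only \(V\,B\)'s low-frequency structure; flooring at `epsilon`
(default \(10^{-3}\)) guards the division in dark regions off the plate,
and normalizing the field to spatial mean 1 makes the correction
brightness-preserving. Correction is optional — a well-built rig needs
little of it — and `preprocess_stack(vignette = FALSE)` skips it.

### Why the blur extrapolates at the frame edge

Boundary handling is usually a footnote; here it is not, because the blur
scale is an eighth of the frame. A mirror ("reflect") boundary flips the
sign of the illumination gradient at the edge, and smoothing that kink
biases the estimated field a full \(\sigma\) deep into the image. On a flat
scene degraded by a radial vignette of strength 0.4 the mirror rule leaves
a corrected coefficient of variation of about 1.9% (only a ~4x improvement),
and the bias is structural, not statistical. The default boundary therefore
extends the image antisymmetrically about each edge sample,
\(g(n+t) = 2g(n) - g(n-t)\): value- and slope-continuous, exact for linear
illumination ramps, and free of halos. With it the same construction
flattens to ~0.13% CV, a ~59x improvement (`gaussian_blur()` exposes both
rules). The trade-off: on *rough* inputs the extrapolation amplifies edge
noise, which is irrelevant here because the blur is only ever applied to
the temporal average frame, which is smooth by construction.

**Average subtraction** (`average_subtract()`) forms
\(S_t = |I_t - \bar I|\) with \(\bar I\) recomputed on the corrected stack.
Recomputing keeps the static-scene-to-zero identity exact; the absolute
value makes the pipeline agnostic to illumination polarity, since
\(|(1-I) - \overline{(1-I)}| = |I - \bar I|\). Every stage clips to
\([0,1]\), keeping the representation closed.

## Trail rendering

`enhance()` applies \(E = \mathrm{clip}(g S - o)\). The gain \(g\)
(default 10) lifts the faint subtracted signal toward full scale; the
offset \(o\) (default 0.05) is a hard noise floor — any pixel with
\(gS \le o\) renders exactly black, which is what keeps sensor noise out of
the trails. Raising \(o\) can only extinguish pixels, never recruit them.

`fade_weight()` implements the fade of old track segments: with window
length \(n\) and fade fraction \(f\) (default 0.2, capped at 0.5), the
oldest \(m = \mathrm{round}(fn)\) frames get weights \(0, 1/m, \dots,
(m-1)/m\) and everything newer gets 1. Only the old end fades — fading the
new end would hide the animal itself. Seen across successive output frames,
each track segment enters at full strength and dissolves gradually as it
ages out of the window.

`project_window()` is the core. Each frame in the window gets a scalar
weighted intensity \(E_t w_t\) per pixel; the frame with the per-pixel
maximum wins, and the output pixel is that frame's \(E w\) times the
colormap evaluated at its window-normalized time
\(u = (t - t_\text{first})/(t_\text{last} - t_\text{first})\). Two
deliberate choices:

* **Selection is scalar, color applied after.** A per-channel maximum
  would blend colors from different times into hues that correspond to no
  actual visit time.
* **Ties break toward the later frame.** When the same pixel is visited
  twice at equal intensity, its hue reports the more recent visit —
  consistent with the tool's emphasis on recent behavior. This is also the
  one asymmetry under time reversal: reversing the frame order and the
  colormap reproduces a still exactly except at exact-tie pixels (which
  have measure zero in real data but arise from clipping at high gain).

Stills normalize \(u\) over the whole recording; videos normalize within
each window by default (each output frame reads as "the last
`window_s` seconds, old to new"), with `global_time = TRUE` available when
a recording-wide clock is wanted. Window length in frames is
\(\mathrm{round}(\text{window}_s \cdot \text{fps})\); startup windows are
truncated, never padded, so no phantom black history dilutes early frames.

Colormaps are piecewise-linear in linear RGB between user-supplied control
points (`colormap_from_points()`, text files of `u r g b` rows). Linear RGB
keeps the product intensity-times-color interpretable; perceptual
uniformity is deliberately out of scope. Built-ins cover the common cases:
sequential `blue_red` and `cyan_magenta`, diverging `blue_white_red` for
pre/post-intervention encodings, and `constant_white`.

## I/O choices

All containers are lossless: multi-page TIFF (deflate) for movies, PNG for
stills and sequences, everything quantized to the 8-bit grid before
writing so a write/read round trip is bit-identical. Lossy codecs are
refused outright rather than discouraged — block-compression artifacts
change between frames and survive average subtraction, i.e. they look
exactly like signal. TIFF carries no frame-rate metadata, so `load_video()`
requires an explicit `fps` and synthesizes times as \((i-1)/\text{fps}\);
the per-run parameter sidecar is the canonical place where the frame rate
is preserved.

`check_acquisition()` encodes the sampling rule of thumb for continuous
trails: no worm should travel more than one body length between frames
(about 1 fps for adults at typical plate magnifications). It warns,
never blocks.

## The simulator: what it emulates, and what it does not

`sim_scene()` describes a field of `n_worms` agents following a two-state
Markov chain (roam/dwell, symmetric per-second switch probability converted
per frame as \(1-(1-p)^{\Delta t}\)), with heading a Gaussian random walk
(4x broader while dwelling), step length `speed / fps`, and mirror
reflection at the field edge. Rendering adds isotropic Gaussian blobs at
each centroid to a static background, multiplies by a radial-quadratic
vignette \(1 - s\,(r/r_\text{max})^2\) (\(r_\text{max}\) the
half-diagonal), adds Gaussian noise, and clips. Scene defaults mirror a
typical plate recording — 1200 x 1200 px at 1 fps, about 100 um per pixel,
a single worm roaming at ~2 px/s for 10 minutes; tests and examples pass
smaller `shape` / `duration_s` for speed (typically 48-160 px fields,
30-300 frames, chosen so the full suite runs in about a minute).

The simulator is deliberately minimal. It produces the *phenomena* the
pipeline must handle — two-speed locomotion, both polarities, vignetting,
noise, sub-worm resolution — with exact ground truth
(`ideal_trail_mask()` turns centroids into coverage oracles). It does
**not** model body posture, self-occlusion, omega turns, lawn-edge
behavior, collisions between animals, or chemotaxis drift. Passing tests
therefore establish the correctness of the *processing* (subtraction
identities, projection algebra, color assignment, coverage of visited
pixels), not that any biological conclusion drawn from a real trail image
is valid; artifacts real recordings bring — condensation, reflections,
vibrating rigs — are outside what the synthetic suite can certify.

## Numerical conventions and degenerate inputs

* Intensities, gains and offsets are dimensionless on the \([0,1]\) scale;
  times are seconds; `sigma_px`, speeds and lengths are pixels.
* Frames are indexed from 1 in R; times are 0-based seconds
  (\(t_i = (i-1)/\text{fps}\)).
* A window of one frame gets \(u = 1\) (it is the newest frame of its
  window); an all-zero window renders black rather than erroring.
* A video window longer than the recording degrades to a single
  full-recording projection with a warning.
* Single-frame recordings are rejected: an average over one frame would
  subtract every stack to zero by construction.
* Frames with zero mean cannot be brightness-normalized and are reported
  by index.
* The blur kernel is truncated at \(4\sigma\) and renormalized, so
  constants are exact fixed points; with the extrapolating boundary the
  truncation radius is additionally capped at \(n-1\).

## Known limitations

Processing is in-memory (a 10-minute 1200 x 1200 px recording at 1 fps is
~6.9 GB as doubles), so long or high-resolution recordings should be
tiled or down-sampled first. The moving-window renderer recomputes each
window from scratch rather than maintaining a running maximum, favoring
simplicity over speed. There is no worm tracking, identity assignment, or
quantitative readout — trails are an exploratory visualization, upstream
of tracking pipelines, and the package stops there on purpose.
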