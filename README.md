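# chronotrails

Wide-field recordings of *C. elegans* crawling on agar plates are usually
shared as raw video or reduced to summary plots, and neither is much help
when you first open a dataset and want to *see* what the animals did.
`chronotrails` post-processes such recordings — brightfield or darkfield —
into **trail stills and trail videos**: every pixel a worm visited is lit,
colored by *when* it was visited, in the spirit of multiflash photography
and long-exposure imaging. A single still makes roaming, dwelling,
dispersal and chemotaxis patterns jump out; a sliding-window video shows
each animal's *recent* path, with the oldest track segments fading away.

The package is for worm labs (and anyone imaging slow-moving animals on a
plate) who want fast, exploratory visualization upstream of quantitative
tracking pipelines.

## Method

For a recording \(I_t(x,y)\), \(t = 0 \dots T-1\):

1. **Brightness normalization** — each frame is rescaled so its mean
   intensity matches a common target (the grand mean by default),
   removing global flicker.
2. **Vignetting correction** — the temporal average frame is blurred with
   a Gaussian of \(\sigma = \min(H,W)/8\) px, floored at \(\varepsilon\),
   normalized to spatial mean 1, and divided out:
   low-frequency illumination structure is flattened while worm-scale
   detail is untouched.
3. **Average subtraction** — \(S_t = |I_t - \bar I|\) with \(\bar I\) the
   (recomputed) temporal mean. The absolute value makes dark-on-bright and
   bright-on-dark recordings equivalent; static scenes map to exactly zero.
4. **Trail projection** — each \(S_t\) is contrast-enhanced,
   \(E_t = \mathrm{clip}(g\,S_t - o)\), weighted by a fade ramp \(w_t\)
   over the oldest fraction of the window, and collapsed by a pixel-wise
   maximum over the full recording (stills) or a trailing window of
   \(n = \mathrm{round}(\text{window}_s \cdot \text{fps})\) frames
   (videos). The winning frame's normalized time \(u \in [0,1]\) selects
   an RGB color from a colormap (sequential `blue_red`, `cyan_magenta`;
   diverging `blue_white_red`; `constant_white`), and the output pixel is
   \(E\,w\,\cdot\mathrm{cmap}(u)\). Ties go to the later frame, so the
   most recent visit always sets a pixel's hue.

A seedable simulator (`sim_scene()` / `simulate_scene()`) generates
worm-like two-state roam/dwell random walks rendered as Gaussian blobs
with vignetting and sensor noise, plus per-frame ground-truth centroids,
so the whole pipeline is testable without any recordings.

I/O is lossless by design: multi-page TIFF movies and PNG sequences
(compressed containers would leave codec artifacts in the subtracted
frames).

## Worked example

```r
library(chronotrails)

# simulate 2 worms for 60 s at 1 fps on a 160 x 160 px field
sim <- simulate_scene(sim_scene(shape = c(160, 160), duration_s = 60,
                                n_worms = 2, seed = 42))
sim$stack
#> <frame_stack> 60 frames of 160 x 160 px, 1 fps, t = [0, 59] s, 8-bit source

# preprocess: normalize -> vignette correction -> average subtraction
pre <- preprocess_stack(sim$stack)
pre$vignette
#> <vignette_field> 160 x 160 px, sigma 20 px, range [0.823, 1.102], mean 1

# full-recording still, early path blue -> late path red
still <- render_still(pre$subtracted,
                      trail_params(window_s = "full", colormap = "blue_red"))
still
#> <trail_frame> 160 x 160 px, window [0, 59] s
write_image(still$image, "trails.png")

# sliding 20 s window video with fade-out of the oldest 20%
frames <- render_video(pre$subtracted, trail_params(window_s = 20))
length(frames)
#> [1] 60
write_video(lapply(frames, `[[`, "image"), "trails.tif", fps = 1)
```

The still's pixel colors read as a clock: blue marks positions occupied
near `t = 0 s`, red near `t = 59 s`, black was never visited. In the video,
each frame shows only the previous 20 s of movement, colored by recency
within that window.

The same runs from a shell via the thin CLI wrapper:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/chronotrails.R", package="chronotrails"))') \
    still --input rec.tif --fps 1 --output trails.png --colormap blue_red
```

Every run writes a `<output>.params.yaml` sidecar with all effective
parameters; re-running from the sidecar reproduces the output bit for bit.

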