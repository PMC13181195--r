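---
title: "ROI-aware compression of MR images: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ROI-aware compression of MR images: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rgsc)
```

`rgsc` couples an automatic region-of-interest (ROI) segmentation of
grayscale MR slices to a non-uniform wavelet codec: the diagnostically
informative region is coded at a high bit rate and the background at a low
one, and both embedded streams travel in one container together with the
mask. This vignette explains the model and every consequential design
choice; it states nothing that the package's tests and scripts do not
themselves compute.

## 1. The segmentation model (RG-FCM)

Plain fuzzy c-means (FCM) clusters pixels on intensity alone and degrades
quickly on noisy images because it ignores where pixels are. The approach
here injects spatial evidence from a cheap, deterministic pre-segmentation:

1. **Otsu threshold.** The 256-bin histogram threshold `t` maximising the
   between-class variance; pixels strictly above `t` are foreground. Ties
   are broken toward the smallest `t`, and a constant image is rejected
   (`DegenerateHistogram`-style classed error) since no two classes exist.
2. **Seed selection.** The foreground pixel whose intensity is closest to
   the mean foreground intensity (ties: smallest row-major index). On
   lesion-dominant foregrounds this lands inside the lesion.
3. **Region growing.** Breadth-first growth from the seed under
   8-connectivity with the fixed neighbour order N, S, W, E, NW, NE, SW,
   SE. A frontier pixel is admitted iff its intensity differs from the
   *running* region mean by at most `tol`, and the mean is updated after
   each admission; each pixel is tested once. The default tolerance is
   `0.15 × |mean(fg) − mean(bg)|`, i.e. a fixed fraction of the Otsu
   between-class contrast, so it adapts to the image's dynamic range
   without a free absolute parameter.
4. **Constrained FCM.** Every pixel becomes the 2-D feature
   `x_j = (I_j, λ·M_j)` with `M_j ∈ {0,1}` the region-growing indicator and
   `λ = 128` by default. The standard FCM objective and updates operate
   unchanged on these features; the region indicator simply becomes a
   second Euclidean coordinate. `λ` is half the 8-bit intensity range:
   large enough that region membership separates clusters even when
   intensities overlap, small enough that intensity is never overruled
   outright. Fuzzifier `p = 2`, `m = 2` clusters (informative vs rest),
   membership tolerance `1e-5`, at most 200 iterations, centroids
   initialised uniformly over the per-feature data range from a seeded RNG
   (so the whole pipeline is bit-reproducible). Points coinciding with a
   centroid receive full membership in the first such cluster.
5. **ROI extraction.** Pixels are assigned to their maximum-membership
   cluster; the ROI cluster is the one overlapping the grown region most
   (ties: higher-intensity centroid); holes are filled and only the largest
   8-connected component is kept.

How region-growing output should enter the FCM objective is genuinely
open — as a feature, a penalty term, or an initialisation. The feature
reading was chosen because it leaves the objective and both update formulas
exactly in their textbook form (the alternating-minimisation monotonicity
proof carries over untouched, and the tests check the objective trace is
non-increasing), while still letting spatial evidence act on every pixel.

## 2. The codec

**Transform.** The bior4.4 biorthogonal 9/7 pair, implemented as its
lifting factorisation with whole-sample symmetric boundary handling and
subbands scaled so the lowpass DC gain is √2 per stage (the conventional
bior4.4 normalisation; the lifting output is identical to direct
convolution against symmetrically extended signals, which is what the test
oracle computes). Lifting makes perfect reconstruction structural: the
inverse replays the same steps with negated coefficients, and the
round-trip error on 8-bit images is below 1e-8. The level count is
`L = min(floor(log2(min(H, W))) − 2, 6)`, which keeps the coarsest
approximation band at least 4×4 — the minimum the SPIHT trees need — and
caps the depth where further levels stop paying. Non-dyadic sizes are
symmetric-padded to a multiple of `2^(L+1)` (so the coarsest band stays
even-sized) and cropped after synthesis.

**Quantisation.** Coefficients are rounded half away from zero (sign
symmetry); magnitude-zero coefficients carry sign +1. SPIHT is lossless on
these integers, so "full-depth" coding recovers the quantised plane
exactly; the only irreversible step is the rounding itself, which bounds
the reconstruction error at one gray level after clipping. The tests
assert this ≤ 1 bound rather than strict equality: with a hard ROI mask
the half-images contain step edges whose many mid-sized coefficients each
round by up to 0.5, and those errors can add to just over half a gray
level at a pixel.

**SPIHT.** The original list dynamics: LIP/LIS/LSP, sorting pass (LIP
significance + sign; LIS set tests with type-A/type-B splitting) then
refinement pass, from `n = b_max = floor(log2 max|C|)` down to 0.
Single-coefficient subsets need no special case — the offspring/type-B
mechanics subsume them. Set significance is answered in O(1) from
bottom-up precomputed descendant maxima. Outside the coarsest LL band,
offspring are the standard coordinate-doubled 2×2 block; inside it, each
2×2 group has a rootless top-left member while the other three parent the
co-located 2×2 blocks of the coarsest HL/LH/HH bands. (Naive doubling
inside an LL larger than 2×2 would collide with the LL itself; this
generalisation coincides with doubling when the LL is 2×2 and partitions
every detail coefficient exactly once — a property the test suite checks
exhaustively on a 16×16 plane.) The encoder stops the moment the bit
budget is hit, mid-entry if necessary, so the emitted length is exactly
`min(bits to reach plane 0, budget)`; the decoder mirrors the lists,
reconstructs a newly significant coefficient at ±1.5·2ⁿ, halves the
uncertainty with each refinement bit, and stops gracefully at stream end.
An all-zero plane has `b_max = −1` and an empty payload.

**Entropy stage.** The SPIHT bits are packed MSB-first into bytes and
Huffman-coded with byte symbols — the stream's exact bit count travels in
the container, so the final pad bits are never misread. Tie-breaking in
the Huffman merge (lowest count; then smallest symbol; internal nodes by
creation order) and canonical code assignment make the packet byte-stable.
Since a fixed 8-bit code is itself a prefix code, the optimal table can
never inflate the payload beyond the input, so the cascade costs at most
the table header (≤ 2 + 2·256 + 4 bytes) — also a tested invariant.

**Container and accounting.** Big-endian framing: magic, version,
dimensions, levels, wavelet id, the two rates, the two `b_max` values, the
two exact SPIHT bit counts, the run-length-coded mask (u16 runs
alternating zeros/ones, row-major, 65535/0 continuation for long runs),
then the two Huffman packets with byte lengths `E_r` and `E_nr`. The mask
must be transmitted for decoding, so its bytes are charged to the
full-image figures: `CR_full = S/(E_r + E_nr + mask)` with `S = H·W`
bytes, and `bpp = 8/CR` throughout. A zero-length mask block marks the
uniform single-stream mode, whose SPIHT-only compression ratio
`8·S / stream bits` equals `8/bpp` exactly whenever the budget binds —
the package's rate-control check.

## 3. The phantom: what it emulates and what it does not

`phantom_spec()` renders an elliptical head over a dark background, one or
more elliptical lesions jointly covering a target 2–9 % of the frame
(matching the foreground-area range reported for real tumour data), a
smooth ±10 % multiplicative bias field, and additive noise (Gaussian by
default; Rician, the physically correct magnitude-MR model, behind a
flag). The returned mask is the exact lesion support, bit-identical per
seed.

The default plateau intensities are background 10, parenchyma 45, lesion
220 — a FLAIR/T2-like contrast in which the lesion is the hyperintense
structure. This choice is load-bearing: an Otsu threshold isolates the
class that dominates the between-class variance, and a short calculation
shows that with a mid-gray parenchyma (say 120) the variance peak falls
between background and head for any realistic area fractions, so the seed
would land in normal tissue and the pipeline would segment the whole head.
With a hypointense parenchyma the peak falls between the lesion and
everything else across the full design range (lesion areas 2–9 %, bias
±10 %, noise σ ≤ 15), the seed lands inside the lesion, and the method
behaves as intended. In other words, the phantom encodes the contrast
regime this segmentation method is *for*; on sequences where the lesion is
not the brightest structure, the method as specified would need an
inverted or windowed input.

Default noise is σ = 10 gray levels — a harsh but plausible acquisition.
On noise-free phantoms the pipeline recovers the lesion pixel-for-pixel;
across seeds 0–9 at σ = 10 the mean Jaccard stays above 0.90 (both are
acceptance-tested). What passing these tests does **not** show: real MR
slices have textured parenchyma, partial-volume boundaries and non-elliptic
lesions, so phantom Jaccard values are an upper bound on real-data
performance, and the compression figures on phantoms likewise benefit from
the piecewise-smooth content.

## 4. Numerical choices and degenerate inputs

* Otsu ties → smallest threshold; foreground is strictly-greater-than.
* Region growing tests each pixel once (no re-testing as the mean drifts):
  deterministic, single pass, and the FCM stage recovers pixels the drift
  rejected.
* FCM zero-distance rule gives full membership to the first matching
  cluster; identical-data input converges immediately with objective 0.
* Empty∩empty masks score Jaccard = Dice = 1 (two empty segmentations
  agree); 0/0 in precision/recall/F is reported as 0.
* The confidence-interval z values are the conventional rounded 1.65,
  1.96, 2.58 — not 1.6449 etc. — to match how such tables are reported.
* SSIM defaults to global statistics with C1 = (0.01·255)², C2 =
  (0.03·255)² (population variances); an 11×11 Gaussian sliding-window
  variant is available via `method = "window"`.
* Boundary-band precision/recall (band default 2 px, Chebyshev) is offered
  alongside pixel-wise counts because "boundary-based" evaluation admits
  several formalisations; pixel-wise is the default.
* Dice is computed from its own formula but always equals `2J/(1+J)`;
  published tables whose J and D violate this identity were evidently
  produced by independent pipelines — the identity is enforced here, and a
  property test keeps it that way.

## 5. Problem sizes used by the test suite

The suite runs entirely on generated data: 256×256 phantoms for the
segmentation and rate-control checks (10 noisy segmentations, a 5-seed ×
5-rate monotonicity sweep), 16×16 planes for the 100-seed SPIHT
round-trip property, alphabets of at most 8 symbols for the exhaustive
prefix-code optimality oracle, and 64×64 images for the transform
round-trip bundle. These sizes were chosen so each property is exercised
at full strength while the whole suite stays interactive (well under a
minute on one core).

## 6. Known limitations

* Full-depth coding is near-lossless (≤ 1 gray level), not lossless; a
  true lossless mode would need an integer-to-integer (5/3 lifting)
  transform, which is out of scope.
* Full-frame PSNR on noisy inputs saturates near the noise's own PSNR
  (≈ 29 dB at σ = 10) regardless of rate, because white noise is
  incompressible; the ROI-restricted PSNR is the informative fidelity
  measure in that regime.
* `m = 2` clusters suffice for lesion-vs-rest; multi-tissue use
  (WM/GM/lesion) is configurable but the ROI-cluster selection still
  returns a single region.
* No 3-D volumes, no multi-modal registration, no learned segmentation,
  no arithmetic-coded SPIHT, and no JPEG/JPEG2000 baselines.
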