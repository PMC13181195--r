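# rgsc — region-grown segmentation and ROI-aware compression of medical images

Medical images are archived and transmitted in bulk, but only a small part
of a typical MR slice — the lesion or other diagnostically informative
region — must survive compression at high fidelity. `rgsc` implements a
segmentation-driven, non-uniform codec for 8-bit grayscale images aimed at
exactly that workflow: it extracts the region of interest (ROI)
automatically, then codes ROI and background as separate embedded streams
at different bit rates and fuses them on decode. It is intended for
researchers working on telemedicine-oriented image coding and for anyone
who needs a fully scriptable, reproducible ROI codec with a matching
evaluation suite.

## What is inside

**RG-FCM segmentation.** An Otsu threshold `t = argmax σ²_B(t)` (256-bin
between-class variance, foreground = pixels > t) picks the hyperintense
structure; the foreground pixel closest to the foreground mean seeds a
breadth-first region grower that admits a neighbouring pixel `p` while
`|I(p) − mean(region)| ≤ tol`, with the running mean updated after every
admission. The grown region then constrains fuzzy c-means: every pixel is
clustered on the feature vector `x_j = (I_j, λ·M_j)`, where `M_j` is the
region indicator, by minimising

    J = Σ_i Σ_j U_ij^p ||x_j − V_i||²,   Σ_i U_ij = 1,

with the classical alternating updates
`U_ij = 1 / Σ_k (d_ij/d_kj)^(2/(p−1))` and
`V_i = Σ_j U_ij^p x_j / Σ_j U_ij^p`. The cluster overlapping the grown
region most becomes the ROI; holes are filled and the largest 8-connected
component is kept.

**Non-uniform codec.** Each half-image (ROI masked in, background masked
in) goes through an L-level bior4.4 (CDF 9/7) wavelet decomposition,
integer rounding of the coefficient plane, SPIHT bitplane coding with the
significance rule `S_n = 1 ⇔ max |C_ij| ≥ 2^n` truncated at exactly
`floor(bpp · H · W)` bits, and a canonical byte-wise Huffman stage. The ROI
stream gets the higher rate (default 1.0 bpp vs 0.25 bpp). Everything is
framed in a bit-exact `.rgsc` container (including the run-length-coded
mask), so `CR_full = S / (E_r + E_nr + mask bytes)` and `bpp = 8/CR` are
true end-to-end figures for `S = H·W` bytes.

**Evaluation suite.** Jaccard, Dice, foreground-area percentage,
precision/recall/F (pixel-wise or boundary-band), normal-approximation
confidence intervals (`mean ∓ z·sd/√N`, z = 1.65/1.96/2.58), MSE, PSNR
(`10·log10(255²/MSE)`), global and windowed SSIM, and full rate accounting.

**Phantom generator.** A seeded synthetic-MRI generator (elliptical head,
hyperintense lesion covering a configurable 2–9 % of the frame, smooth
multiplicative bias field, Gaussian or Rician noise) returns every image
with its exact ground-truth mask, so the whole pipeline is testable without
any external dataset.

## Worked example

```r
library(rgsc)

ph  <- generate_phantom(phantom_spec(seed = 1, noise_sigma = 10))
seg <- segment_roi(ph$image)
seg
#> RG-FCM segmentation: otsu=87 seed=(132,103) rg tol=27.59 roi=5.01% of frame

unlist(evaluate_segmentation(seg$roi_mask, ph$mask))
#>   jaccard      dice  area_pct precision    recall f_measure
#>  1.000000  1.000000  5.006409  1.000000  1.000000  1.000000

cont <- compress_image(ph$image, mask = seg$roi_mask,
                       bpp_roi = 1.0, bpp_bg = 0.25)
cont
#> RGSC container: 256x256, levels 6, roi 1.00 / bg 0.25 bpp,
#>   E_r=4917B E_nr=2307B mask=290B

rec <- decompress_image(cont)
r <- rate_report(cont)
q <- evaluate_compression(ph$image, rec, seg$roi_mask)
#> cr_full=8.72  cr_r=13.33  bpp_full=0.917
#> psnr=29.22  ssim=0.9802  psnr_roi=58.74  psnr_bg=29.00
```

The segmentation recovers the lesion exactly (Jaccard 1.0 on this
phantom). After coding, the ROI is reconstructed at 58.7 dB while the
noisy background — carrying no diagnostic content — is held at 29 dB,
and the whole frame fits in under 0.92 bpp including the mask. The
full-frame PSNR is dominated by the additive noise in the background,
which no codec can reproduce at these budgets.

A command-line wrapper with the same behaviour ships at
`inst/cli/rgsc` (subcommands `phantom`, `segment`, `compress`,
`decompress`, `evaluate`, `evaluate-seg`, `report`).

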