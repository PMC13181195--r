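test_that("split partitions the image exactly", {
  img <- rand_gray(20, 24, 24)
  mask <- rand_mask(21, 24, 24)
  halves <- split_by_mask(img, mask)
  expect_equal(halves$roi + halves$bg, img)
  expect_true(all(halves$roi[!mask] == 0L))
  expect_true(all(halves$bg[mask] == 0L))

  full <- split_by_mask(img, matrix(TRUE, 24, 24))
  expect_equal(full$roi, img)
  expect_true(all(full$bg == 0L))
  empty <- split_by_mask(img, matrix(FALSE, 24, 24))
  expect_equal(empty$bg, img)

  expect_error(split_by_mask(img, matrix(TRUE, 5, 5)),
               class = "rgsc_dim_mismatch")
})

test_that("full-depth coding is near-lossless and containers are bit-stable", {
  img <- matrix(as.integer(round(outer(1:16, 1:16,
                                       function(i, j) 60 + 3 * i + 2 * j))),
                16, 16)
  mask <- matrix(FALSE, 16, 16); mask[5:10, 6:12] <- TRUE
  cont <- compress_image(img, mask, bpp_roi = 8, bpp_bg = 8)
  rec <- decompress_image(cont)
  # SPIHT is lossless on the quantized coefficients; the residual is the
  # bior4.4 integer-rounding error, at most one gray level after clipping
  expect_lte(max(abs(rec - img)), 1L)
  expect_gt(img_psnr(img, rec), 45)

  # end-to-end determinism: identical inputs give byte-identical containers
  cont2 <- compress_image(img, mask, bpp_roi = 8, bpp_bg = 8)
  expect_identical(cont$raw, cont2$raw)
})

test_that("containers survive the file round trip and reject corruption", {
  ph <- generate_phantom(phantom_spec(seed = 9, noise_sigma = 5,
                                      dim = c(64L, 64L)))
  cont <- compress_image(ph$image, ph$mask, bpp_roi = 1.0, bpp_bg = 0.25)
  f <- tempfile(fileext = ".rgsc")
  write_rgsc(cont, f)
  back <- read_rgsc(f)
  expect_identical(back$raw, cont$raw)
  expect_equal(back$mask, cont$mask)
  expect_identical(decompress_image(back), decompress_image(cont))

  expect_error(decompress_image(cont$raw[1:40]),
               class = "rgsc_malformed_packet")
  bad <- cont$raw; bad[2] <- as.raw(0)
  expect_error(decompress_image(bad), class = "rgsc_malformed_packet")
})

test_that("an empty ROI mask produces a header-only ROI stream", {
  img <- rand_gray(5, 32, 32)
  cont <- compress_image(img, matrix(FALSE, 32, 32),
                         bpp_roi = 1, bpp_bg = 1)
  expect_equal(cont$b_max_roi, -1L)
  expect_equal(cont$nbits_roi, 0)
  rec <- decompress_image(cont)
  expect_equal(dim(rec), dim(img))
  # both streams header-only -> all-zero image
  z <- compress_image(matrix(0L, 32, 32), matrix(FALSE, 32, 32),
                      bpp_roi = 1, bpp_bg = 1)
  expect_true(all(decompress_image(z) == 0L))
})

test_that("mse/psnr/ssim match their defining formulas", {
  a <- rand_gray(30, 20, 20)
  expect_equal(img_mse(a, a), 0)
  expect_equal(img_psnr(a, a), Inf)
  expect_equal(img_mse(a, a + 1L), 1)
  expect_equal(img_ssim(a, a), 1, tolerance = 1e-12)

  b <- rand_gray(31, 20, 20)
  # naive double-loop oracle for MSE
  s <- 0
  for (r in 1:20) for (c in 1:20) s <- s + (a[r, c] - b[r, c])^2
  expect_equal(img_mse(a, b), s / 400)

  # direct evaluation of the global SSIM formula
  mu_a <- mean(a); mu_b <- mean(b)
  va <- mean((a - mu_a)^2); vb <- mean((b - mu_b)^2)
  cab <- mean((a - mu_a) * (b - mu_b))
  C1 <- (0.01 * 255)^2; C2 <- (0.03 * 255)^2
  expect_equal(img_ssim(a, b),
               ((2 * mu_a * mu_b + C1) * (2 * cab + C2)) /
                 ((mu_a^2 + mu_b^2 + C1) * (va + vb + C2)))

  # an image and its negative share a symmetric histogram but not structure
  sym <- matrix(rep(c(40L, 215L), each = 200), 20, 20)
  expect_lt(img_ssim(sym, 255L - sym), 1)

  # windowed variant stays in range and is 1 on identity
  expect_equal(img_ssim(a, a, method = "window"), 1, tolerance = 1e-9)
  expect_lt(img_ssim(a, b, method = "window"), 1)

  expect_error(img_mse(a, matrix(0L, 3, 3)), class = "rgsc_dim_mismatch")
})

test_that("published PSNR worked values follow from the MSE definition", {
  # 95 of 100 pixels differing by 4: MSE 15.2
  a <- matrix(0L, 10, 10)
  b <- a; b[1:95] <- 4L
  expect_equal(img_mse(a, b), 15.2)
  expect_equal(round(img_psnr(a, b), 2), 36.31)
  # 466 of 500 pixels differing by 3: MSE 8.388
  a <- matrix(0L, 20, 25)
  b <- a; b[1:466] <- 3L
  expect_equal(img_mse(a, b), 8.388)
  expect_equal(round(img_psnr(a, b), 2), 38.89)
  # 97 of 250 pixels differing by 4: MSE 6.208
  a <- matrix(0L, 10, 25)
  b <- a; b[1:97] <- 4L
  expect_equal(img_mse(a, b), 6.208)
  expect_equal(round(img_psnr(a, b), 1), 40.2)
})

test_that("rate accounting follows the byte-budget identities", {
  fake <- structure(list(H = 32L, W = 32L, uniform = FALSE,
                         E_r = 64, E_nr = 64, mask_bytes = 0,
                         nbits_roi = 512, nbits_bg = 512),
                    class = "rgsc_container")
  r <- rate_report(fake)
  expect_equal(r$cr_full, 8)           # S/(E_r+E_nr) = 1024/128
  expect_equal(r$cr_r, 16)
  expect_equal(r$bpp_full, 1)
  expect_equal(r$bpp_r, 0.5)

  # uniform mode at a binding budget: SPIHT-only CR is exactly 8/bpp
  ph <- generate_phantom(phantom_spec(seed = 3, noise_sigma = 15,
                                      dim = c(64L, 64L)))
  cont <- compress_image(ph$image, bpp_roi = 0.5, uniform = TRUE)
  rr <- rate_report(cont)
  expect_equal(rr$spiht_bits_roi, floor(0.5 * 64 * 64))
  expect_equal(rr$cr_spiht, 16)
})

test_that("the entropy stage never inflates a stream beyond its table header", {
  for (s in c(1, 2)) {
    ph <- generate_phantom(phantom_spec(seed = s, noise_sigma = 10,
                                        dim = c(64L, 64L)))
    cont <- compress_image(ph$image, ph$mask, bpp_roi = 1, bpp_bg = 0.25)
    header_bound <- 2 + 2 * 256 + 4
    expect_lte(cont$E_r, ceiling(cont$nbits_roi / 8) + header_bound)
    expect_lte(cont$E_nr, ceiling(cont$nbits_bg / 8) + header_bound)
  }
})

test_that("the ROI/background cascade reconstructs phantoms faithfully", {
  # noise-free phantom: high-fidelity reconstruction at the default rates
  ph0 <- generate_phantom(phantom_spec(seed = 9, noise_sigma = 0))
  rec0 <- decompress_image(compress_image(ph0$image, ph0$mask,
                                          bpp_roi = 1.0, bpp_bg = 0.25))
  expect_gt(img_psnr(ph0$image, rec0), 40)

  # moderate-noise phantom: the cascade still clears 30 dB
  ph5 <- generate_phantom(phantom_spec(seed = 9, noise_sigma = 5))
  rec5 <- decompress_image(compress_image(ph5$image, ph5$mask,
                                          bpp_roi = 1.0, bpp_bg = 0.25))
  expect_gt(img_psnr(ph5$image, rec5), 30)

  q <- evaluate_compression(ph5$image, rec5, ph5$mask)
  expect_gt(q$psnr_roi, q$psnr_bg)   # ROI coded at the higher rate
})
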