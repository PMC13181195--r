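test_that("otsu threshold matches the exhaustive between-class-variance scan", {
  expect_error(otsu_threshold(matrix(100L, 20, 20)),
               class = "rgsc_degenerate_histogram")

  # perfectly bimodal image: the threshold must separate the two classes
  v <- c(rep(50L, 600), rep(200L, 400))
  img <- matrix(v, 25, 40)
  t <- otsu_threshold(img)
  expect_true(t >= 50 && t < 200)
  expect_identical(img > t, img == 200L)

  for (s in c(0, 1, 2, 11)) {
    img <- rand_gray(s, 32, 32)
    expect_identical(otsu_threshold(img), oracle_otsu(img))
  }
})

test_that("seed selection finds the pixel closest to the foreground mean", {
  # all foreground pixels equal: first in row-major order wins
  img <- matrix(10L, 8, 8)
  img[3, 5] <- 180L; img[5, 2] <- 180L; img[3, 7] <- 180L
  expect_identical(select_seed(img, 100L), c(3L, 5L))

  # exact match with the mean exists
  img <- matrix(0L, 6, 6)
  img[2, 2] <- 100L; img[3, 3] <- 150L; img[4, 4] <- 200L
  expect_identical(select_seed(img, 50L), c(3L, 3L))

  expect_error(select_seed(matrix(5L, 4, 4), 10L),
               class = "rgsc_empty_foreground")

  for (s in c(1, 5, 9)) {
    img <- rand_gray(s, 32, 32)
    t <- otsu_threshold(img)
    expect_identical(select_seed(img, t), oracle_seed(img, t))
  }
})

test_that("region growing matches an independent BFS and stays connected", {
  # uniform image, tolerance 0: everything joins
  img <- matrix(77L, 12, 12)
  rg <- region_grow(img, c(4, 4), 0)
  expect_true(all(rg$mask))

  # isolated bright block on zero background
  img <- matrix(0L, 30, 30)
  img[11:20, 11:20] <- 200L
  rg <- region_grow(img, c(15, 15), 5)
  expect_identical(rg$mask, img == 200L)
  expect_equal(rg$region_mean, 200)

  expect_error(region_grow(img, c(0, 5), 3),
               class = "rgsc_seed_out_of_bounds")

  # random blob image versus the reference BFS
  set.seed(2)
  img <- matrix(30L, 24, 24)
  img <- img + matrix(sample(0:25, 24 * 24, TRUE), 24, 24)
  img[8:18, 6:16] <- img[8:18, 6:16] + 120L
  rg <- region_grow(img, c(12, 10), 12)
  expect_identical(rg$mask, oracle_region_grow(img, c(12, 10), 12))
  expect_true(rg$mask[12, 10])

  # single 8-connected component containing the seed
  lab <- EBImage::imageData(EBImage::bwlabel(rg$mask))
  expect_equal(max(lab), 1)
})

test_that("FCM obeys the membership/centroid update formulas", {
  expect_error(fcm_fit(cbind(1:4, 1:4), m = 2, p = 1),
               class = "rgsc_invalid_fuzzifier")

  # six hand-listed 2-D points against the straight-from-formula reference
  x <- rbind(c(0, 0), c(1, 0), c(0, 1), c(10, 10), c(11, 10), c(10, 11))
  V0 <- rbind(c(0.5, 0.5), c(9, 9))
  fit <- fcm_fit(x, m = 2, p = 2, tol = 1e-12, max_iter = 25L, init = V0)
  ref <- oracle_fcm(x, m = 2, p = 2, V0 = V0, iters = 25L)
  expect_lt(max(abs(fit$U - ref$U)), 1e-6)
  expect_lt(max(abs(fit$V - ref$V)), 1e-6)

  # identical data points: zero-distance rule, objective 0 immediately
  fit0 <- fcm_fit(matrix(3, 10, 2), m = 2, p = 2)
  expect_equal(fit0$objective_trace[1L], 0)
  expect_equal(rowSums(fit0$U), rep(1, 10))
})

test_that("FCM invariants hold on random data: row sums 1, objective non-increasing", {
  for (s in 1:5) {
    set.seed(s)
    x <- cbind(rnorm(60, sample(c(0, 8), 60, TRUE)), runif(60, 0, 4))
    fit <- fcm_fit(x, m = 3, p = 2, seed = s)
    expect_true(all(abs(rowSums(fit$U) - 1) < 1e-9))
    expect_true(all(diff(fit$objective_trace) <= 1e-9))
    expect_lte(fit$iterations, 200L)
  }
})

test_that("rg_fcm separates two perfectly distinct populations", {
  img <- matrix(0L, 16, 16)
  img[, 9:16] <- 255L
  rg <- region_grow(img, c(1, 16), 5)       # grows the bright half
  fit <- rg_fcm(img, rg, seed = 1)
  assign <- max.col(fit$U, ties.method = "first")
  bright_cluster <- assign[length(assign)]  # last pixel is bright
  expect_true(all(fit$U[cbind(seq_along(assign), assign)] >= 0.999))
  # centroid intensity components sit on the two population values
  expect_lt(abs(min(fit$V[, 1L]) - 0), 0.5)
  expect_lt(abs(max(fit$V[, 1L]) - 255), 0.5)

  roi <- extract_roi(fit, img, rg)
  expect_identical(roi, img == 255L)
})

test_that("extract_roi returns an empty mask when nothing overlaps the region", {
  img <- matrix(0L, 16, 16); img[1, 1] <- 10L
  rg <- structure(list(mask = matrix(FALSE, 16, 16), seed = c(1L, 1L),
                       region_mean = 0, tolerance = 0), class = "rgsc_region")
  fcm <- structure(list(U = matrix(0.5, 256, 2),
                        V = rbind(c(0, 0), c(10, 0)), p = 2, m = 2L,
                        objective_trace = 0, iterations = 1L,
                        converged = TRUE), class = "rgsc_fcm")
  # ties in membership assign to cluster 1; the ROI cluster (higher
  # intensity centroid on zero overlap) is cluster 2 -> empty mask
  expect_false(any(extract_roi(fcm, img, rg)))
})

test_that("segment_roi recovers the phantom lesion and is reproducible", {
  ph <- generate_phantom(phantom_spec(seed = 4, noise_sigma = 0))
  seg <- segment_roi(ph$image)
  expect_identical(seg$roi_mask, ph$mask)

  # bit-identical across runs under the same config seed
  seg2 <- segment_roi(ph$image)
  expect_identical(seg$roi_mask, seg2$roi_mask)
  expect_identical(seg$fcm$U, seg2$fcm$U)

  expect_error(segment_roi(matrix(9L, 32, 32)),
               class = "rgsc_degenerate_histogram")

  phn <- generate_phantom(phantom_spec(seed = 5, noise_sigma = 10))
  segn <- segment_roi(phn$image)
  expect_gte(jaccard_index(segn$roi_mask, phn$mask), 0.90)
})
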