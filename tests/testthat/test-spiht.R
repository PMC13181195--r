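test_that("max bitplane follows floor(log2) with the all-zero convention", {
  z <- matrix(0L, 16, 16)
  p9 <- z; p9[5, 5] <- 9L
  expect_equal(spiht_max_bitplane(make_plane(p9, 2L)), 3L)
  p1 <- z; p1[1, 1] <- 1L
  expect_equal(spiht_max_bitplane(make_plane(p1, 2L)), 0L)
  expect_equal(spiht_max_bitplane(make_plane(z, 2L)), -1L)
})

test_that("set significance equals an exhaustive magnitude scan", {
  v <- matrix(0L, 16, 16); v[2, 3] <- 5L
  pl <- make_plane(v, 2L)
  expect_equal(spiht_significant(rbind(c(2, 3)), 2, pl), 1L)   # 5 >= 4
  v2 <- matrix(0L, 16, 16); v2[2, 3] <- 3L
  expect_equal(spiht_significant(rbind(c(2, 3)), 2, make_plane(v2, 2L)), 0L)
  expect_equal(spiht_significant(NULL, 1, pl), 0L)

  set.seed(7)
  v3 <- matrix(sample(-9:9, 256, TRUE), 16, 16)
  pl3 <- make_plane(v3, 2L)
  coords <- cbind(sample(1:4, 8, TRUE), sample(1:4, 8, TRUE))
  expect_equal(spiht_significant(coords, 1, pl3),
               as.integer(max(abs(v3[coords])) >= 2))
})

test_that("spatial-orientation tree partitions the plane correctly", {
  dims <- c(16L, 16L); levels <- 2L        # coarsest LL is 4x4
  # top-left members of LL 2x2 groups are rootless
  expect_equal(nrow(spiht_offspring(1, 1, dims, levels)), 0L)
  expect_equal(nrow(spiht_offspring(3, 3, dims, levels)), 0L)
  # finest-level coordinates have no offspring
  expect_equal(nrow(spiht_offspring(16, 16, dims, levels)), 0L)
  expect_equal(nrow(spiht_offspring(3, 7, dims, levels)), 4L)
  # mid-level coordinate doubles: 1-based (5,3) ~ 0-based (4,2) -> rows 8:9, cols 4:5
  expect_equal(spiht_offspring(5, 3, dims, levels),
               cbind(c(9L, 9L, 10L, 10L), c(5L, 6L, 5L, 6L)))

  # every coordinate outside the rootless LL members appears exactly once
  # as someone's offspring (hand-checkable on the 16x16, 2-level case)
  seen <- matrix(0L, 16, 16)
  for (r in 1:16) for (c in 1:16) {
    off <- spiht_offspring(r, c, dims, levels)
    if (nrow(off)) seen[off] <- seen[off] + 1L
  }
  roots <- matrix(FALSE, 16, 16)
  roots[seq(1, 4, 2), seq(1, 4, 2)] <- TRUE   # rootless LL members
  ll <- matrix(FALSE, 16, 16); ll[1:4, 1:4] <- TRUE
  expect_true(all(seen[ll] == 0L))            # nothing parents the LL
  expect_true(all(seen[!ll] == 1L))           # each detail coeff has one parent
})

test_that("encode/decode round trip is lossless at unlimited budget", {
  # degenerate all-zero plane: empty payload
  bs0 <- spiht_encode(make_plane(matrix(0L, 16, 16), 2L), Inf)
  expect_equal(length(bs0$bits), 0L)
  expect_equal(bs0$b_max, -1L)
  expect_true(all(spiht_decode(bs0) == 0))

  # single large coefficient at an LL root position
  v <- matrix(0L, 8, 8); v[1, 2] <- 63L
  bs1 <- spiht_encode(make_plane(v, 1L), Inf)
  expect_equal(spiht_decode(bs1), matrix(as.numeric(v), 8, 8))

  # property: 100 random sparse planes, exact integer recovery
  for (s in 1:100) {
    set.seed(s)
    v <- matrix(0L, 16, 16)
    k <- sample(5:60, 1)
    idx <- sample(256, k)
    v[idx] <- sample(c(-200:-1, 1:200), k, TRUE)
    pl <- make_plane(v, 2L)
    dec <- spiht_decode(spiht_encode(pl, Inf))
    expect_identical(dec, matrix(as.numeric(v), 16, 16))
  }
})

test_that("bit budget truncates the stream at exactly the requested length", {
  set.seed(7)
  v <- matrix(0L, 16, 16)
  idx <- sample(256, 40)
  v[idx] <- sample(c(-120:-1, 1:120), 40, TRUE)
  pl <- make_plane(v, 2L)
  full <- spiht_encode(pl, Inf)
  expect_gt(length(full$bits), 100)

  b100 <- spiht_encode(pl, 100)
  expect_equal(length(b100$bits), 100L)
  expect_identical(b100$bits, full$bits[1:100])   # embedded prefix property

  # a budget beyond the needed length leaves the stream untouched
  big <- spiht_encode(pl, length(full$bits) + 5000)
  expect_identical(big$bits, full$bits)

  expect_equal(length(spiht_encode(pl, 0)$bits), 0L)
})

test_that("reconstruction error decreases monotonically with prefix length", {
  set.seed(12)
  v <- matrix(sample(-60:60, 256, TRUE), 16, 16)
  pl <- make_plane(v, 2L)
  full <- spiht_encode(pl, Inf)
  n <- length(full$bits)
  cuts <- unique(pmin(c(10, 50, 100, 250, 500, 1000, 2000, n), n))
  sse <- sapply(cuts, function(k) {
    rec <- spiht_decode(full$bits[seq_len(k)], dim = c(16, 16),
                        levels = 2, b_max = full$b_max)
    sum((rec - v)^2)
  })
  expect_true(all(diff(sse) <= 1e-9))
  expect_equal(sse[length(sse)], 0)
})

test_that("malformed headers are rejected", {
  expect_error(spiht_decode(raw(10), dim = c(15, 16), levels = 2, b_max = 3),
               class = "rgsc_malformed_stream")
  expect_error(spiht_decode(raw(10), dim = c(16, 16), levels = 2, b_max = 99),
               class = "rgsc_malformed_stream")
})
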