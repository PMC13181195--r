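# Independent reference implementations used as oracles.  These are written
# as plain scalar loops / exhaustive scans, deliberately avoiding the code
# paths they check.

rand_gray <- function(seed, H = 32L, W = H) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed(matrix(sample(0:255, H * W, replace = TRUE), H, W))
}

rand_mask <- function(seed, H = 16L, W = H, p = 0.4) {
  set.seed(seed)
  matrix(runif(H * W) < p, H, W)
}

# Otsu by explicit scan over all 256 candidate thresholds.
oracle_otsu <- function(img) {
  v <- as.vector(img)
  best_t <- NA_integer_
  best_s <- -Inf
  for (t in 0:255) {
    bg <- v[v <= t]
    fg <- v[v > t]
    if (length(bg) == 0L || length(fg) == 0L) next
    w0 <- length(bg) / length(v)
    w1 <- 1 - w0
    s <- w0 * w1 * (mean(bg) - mean(fg))^2
    if (s > best_s + 1e-12) {
      best_s <- s
      best_t <- t
    }
  }
  best_t
}

# Seed selection by exhaustive scan of foreground pixels in row-major order.
oracle_seed <- function(img, t) {
  m <- mean(img[img > t])
  best <- NULL
  best_d <- Inf
  for (r in seq_len(nrow(img))) {
    for (c in seq_len(ncol(img))) {
      if (img[r, c] > t) {
        d <- abs(img[r, c] - m)
        if (d < best_d - 1e-12) {
          best_d <- d
          best <- c(r, c)
        }
      }
    }
  }
  best
}

# Second, independent BFS region grower with the same admission rule:
# neighbours examined in N, S, W, E, NW, NE, SW, SE order when a pixel is
# dequeued; tested once; running mean updated after each admission.
oracle_region_grow <- function(img, seed, tol) {
  H <- nrow(img); W <- ncol(img)
  offs <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
               c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  seen <- matrix(FALSE, H, W)
  mask <- matrix(FALSE, H, W)
  queue <- list(seed)
  seen[seed[1], seed[2]] <- TRUE
  mask[seed[1], seed[2]] <- TRUE
  s <- as.numeric(img[seed[1], seed[2]])
  k <- 1
  head <- 1
  while (head <= length(queue)) {
    p <- queue[[head]]
    head <- head + 1
    for (o in offs) {
      r <- p[1] + o[1]; c <- p[2] + o[2]
      if (r < 1 || r > H || c < 1 || c > W || seen[r, c]) next
      seen[r, c] <- TRUE
      if (abs(img[r, c] - s / k) <= tol) {
        mask[r, c] <- TRUE
        s <- s + img[r, c]
        k <- k + 1
        queue[[length(queue) + 1]] <- c(r, c)
      }
    }
  }
  mask
}

# Straight-from-formula FCM iteration (scalar loops).
oracle_fcm <- function(x, m, p, V0, iters) {
  n <- nrow(x)
  V <- V0
  U <- matrix(0, n, m)
  for (step in seq_len(iters)) {
    for (j in seq_len(n)) {
      d <- sapply(seq_len(m), function(i) sqrt(sum((x[j, ] - V[i, ])^2)))
      if (any(d == 0)) {
        U[j, ] <- 0
        U[j, which(d == 0)[1]] <- 1
      } else {
        for (i in seq_len(m)) {
          U[j, i] <- 1 / sum((d[i] / d)^(2 / (p - 1)))
        }
      }
    }
    for (i in seq_len(m)) {
      w <- U[, i]^p
      V[i, ] <- colSums(w * x) / sum(w)
    }
  }
  list(U = U, V = V)
}

# Pixel-wise confusion counts by explicit double loop.
oracle_confusion <- function(pred, truth) {
  tp <- fp <- fn <- 0L
  for (r in seq_len(nrow(pred))) {
    for (c in seq_len(ncol(pred))) {
      if (pred[r, c] && truth[r, c]) tp <- tp + 1L
      else if (pred[r, c]) fp <- fp + 1L
      else if (truth[r, c]) fn <- fn + 1L
    }
  }
  c(tp = tp, fp = fp, fn = fn)
}

# bior4.4 analysis filters (9-tap lowpass, 7-tap highpass), frozen.
BIOR44_DEC_LO <- c(0.03782845550726404, -0.023849465019556843,
                   -0.11062440441843718, 0.37740285561283066,
                   0.8526986790088938, 0.37740285561283066,
                   -0.11062440441843718, -0.023849465019556843,
                   0.03782845550726404)
BIOR44_DEC_HI <- c(-0.06453888262869706, 0.04068941760916406,
                   0.41809227322161724, -0.7884856164055829,
                   0.41809227322161724, 0.04068941760916406,
                   -0.06453888262869706)

# Direct separable filter-bank convolution with whole-sample symmetric
# extension; one decomposition level of one vector.
oracle_dwt1d <- function(x) {
  n <- length(x)
  ext <- function(i) {            # 0-based index reflection
    p <- 2 * (n - 1)
    i <- i %% p
    if (i < 0) i <- i + p
    if (i < n) i + 1 else p - i + 1
  }
  a <- sapply(0:(n / 2 - 1), function(k) {
    sum(sapply(-4:4, function(m) BIOR44_DEC_LO[m + 5] * x[ext(2 * k + m)]))
  })
  d <- sapply(0:(n / 2 - 1), function(k) {
    sum(sapply(-3:3, function(m) BIOR44_DEC_HI[m + 4] * x[ext(2 * k + 1 + m)]))
  })
  c(a, d)
}

oracle_dwt2_level <- function(img) {
  tmp <- apply(img, 2, oracle_dwt1d)              # columns
  t(apply(tmp, 1, oracle_dwt1d))                  # then rows
}

# Minimum total cost over all complete prefix codes on k symbols: enumerate
# length multisets of full binary trees recursively, assign longest codes to
# rarest symbols.
oracle_optimal_prefix_cost <- function(counts) {
  k <- length(counts)
  if (k == 1L) return(counts)      # degenerate 1-bit convention
  sets <- list()
  recurse <- function(lens, remaining, kraft_left, min_len) {
    if (remaining == 0L) {
      if (abs(kraft_left) < 1e-12) sets[[length(sets) + 1L]] <<- lens
      return(invisible())
    }
    for (L in min_len:(k - 1L)) {
      if (2^(-L) > kraft_left + 1e-12) next
      # the rest use lengths >= L, contributing at most 2^-L each
      if (kraft_left - 2^(-L) > (remaining - 1L) * 2^(-L) + 1e-12) next
      recurse(c(lens, L), remaining - 1L, kraft_left - 2^(-L), L)
    }
  }
  recurse(integer(0), k, 1, 1L)
  sorted <- sort(counts, decreasing = TRUE)
  best <- Inf
  for (lens in sets) {
    best <- min(best, sum(sorted * sort(lens)))
  }
  best
}

# Build a plane object directly for SPIHT tests.
make_plane <- function(values, levels) {
  mag <- abs(values)
  sgn <- ifelse(values < 0, -1L, 1L)
  storage.mode(mag) <- "integer"
  storage.mode(sgn) <- "integer"
  structure(list(mag = mag, sign = sgn, levels = levels,
                 wavelet = "bior4.4", dim = dim(values),
                 pad_dim = dim(values)),
            class = "rgsc_plane")
}
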