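# Shared toy fixtures: everything is generated in code at test time.

# tiny backbone for unit tests: 32 px input, no stem pooling
tinyConfig <- function(widthScale = 0.0625, epochs = 5L, lr = 1e-3) {
  networkConfig(inputSize = 32L, stemPool = 1L, widthScale = widthScale,
                epochs = epochs, lr = lr)
}

# linearly separable two-class toy: bright vs dark 32x32 images
makeToy <- function(n, seed = 1L, noiseSd = 0.08, gap = 0.4) {
  withr::with_seed(seed, {
    x <- array(0, c(32, 32, 3, n))
    y <- rep(0:1, length.out = n)
    for (i in seq_len(n)) {
      base <- 0.3 + gap * y[i]
      x[, , , i] <- array(rep(matrix(rnorm(32 * 32, base, noiseSd), 32, 32), 3),
                          c(32, 32, 3))
    }
    list(x = x, y = y, id = sprintf("toy%04d", seq_len(n)))
  })
}

# toy with a bright blob at a known location vs flat background
makeBlobToy <- function(n, seed = 1L, center = c(10, 22), radius = 5) {
  withr::with_seed(seed, {
    x <- array(0, c(32, 32, 3, n))
    y <- rep(0:1, length.out = n)
    mask <- outer(seq_len(32), seq_len(32), function(i, j)
      (i - center[1L])^2 + (j - center[2L])^2 <= radius^2)
    for (i in seq_len(n)) {
      img <- matrix(rnorm(32 * 32, 0.2, 0.05), 32, 32)
      if (y[i] == 1L) img[mask] <- img[mask] + 0.6
      x[, , , i] <- array(rep(pmin(pmax(img, 0), 1), 3), c(32, 32, 3))
    }
    list(x = x, y = y, id = sprintf("blob%04d", seq_len(n)), mask = mask)
  })
}

# radius of the rendered nodule along rays, for boundary-shape oracles
radialProfile <- function(img, fovMm = 50, threshold = -400, nAngles = 180L) {
  n <- nrow(img)
  sc <- n / fovMm
  ctr <- (n + 1) / 2
  th <- seq(0, 2 * pi, length.out = nAngles + 1L)[-(nAngles + 1L)]
  vapply(th, function(a) {
    rr <- seq(0.5, fovMm / 2 - 1, by = 0.1)
    ii <- pmin(pmax(round(ctr + rr * sc * sin(a)), 1L), n)
    jj <- pmin(pmax(round(ctr + rr * sc * cos(a)), 1L), n)
    v <- img[cbind(ii, jj)]
    k <- which(v < threshold)[1L]
    if (is.na(k)) rr[length(rr)] else rr[k]
  }, numeric(1L))
}

# exact two-sided Mann-Whitney p by full enumeration of label assignments
enumMannWhitneyP <- function(x, y) {
  pool <- c(x, y)
  m <- length(x)
  uStat <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  u0 <- uStat(x, y)
  idx <- utils::combn(seq_along(pool), m)
  us <- apply(idx, 2L, function(i) uStat(pool[i], pool[-i]))
  min(1, 2 * min(mean(us <= u0 + 1e-9), mean(us >= u0 - 1e-9)))
}

# exact two-sided Fisher p for a 2x2 table by margin-fixed enumeration
enumFisherP <- function(tab) {
  r1 <- sum(tab[1L, ]); c1 <- sum(tab[, 1L]); n <- sum(tab)
  ks <- max(0L, c1 - (n - r1)):min(r1, c1)
  pr <- stats::dhyper(ks, r1, n - r1, c1)
  p0 <- stats::dhyper(tab[1L, 1L], r1, n - r1, c1)
  sum(pr[pr <= p0 * (1 + 1e-7)])
}

# exact 1-D Wasserstein oracle: expand both multisets to a common size
lcmW1 <- function(a, b) {
  g <- function(x, y) ifelse(y == 0, x, Recall(y, x %% y))
  l <- length(a) * length(b) / g(length(a), length(b))
  mean(abs(sort(rep(sort(a), each = l / length(a))) -
           sort(rep(sort(b), each = l / length(b)))))
}

bruteAuc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
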