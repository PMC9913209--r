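test_that("convolution forward/backward agree with finite differences", {
  withr::with_seed(4, {
    H <- 6L; C <- 2L; Co <- 3L; k <- 3L; st <- 2L; pad <- 1L
    x <- array(rnorm(H * H * C * 2), c(H, H, C, 2L))
    W <- matrix(rnorm(k * k * C * Co) * 0.3, k * k * C, Co)
    b <- rnorm(Co) * 0.1
    f <- function(x, W, b) sum(sin(noduleTLR:::cppConvForward(x, W, b, k, st, pad)))
    dy <- cos(noduleTLR:::cppConvForward(x, W, b, k, st, pad))
    bk <- noduleTLR:::cppConvBackward(x, dy, W, k, st, pad)
    eps <- 1e-6
    for (probe in 1:4) {
      i <- sample(length(x), 1L)
      xp <- x; xm <- x; xp[i] <- xp[i] + eps; xm[i] <- xm[i] - eps
      expect_lt(abs(bk$dx[i] - (f(xp, W, b) - f(xm, W, b)) / (2 * eps)), 1e-6)
      j <- sample(length(W), 1L)
      Wp <- W; Wm <- W; Wp[j] <- Wp[j] + eps; Wm[j] <- Wm[j] - eps
      expect_lt(abs(bk$dW[j] - (f(x, Wp, b) - f(x, Wm, b)) / (2 * eps)), 1e-6)
    }
  })
})

test_that("feature extraction conserves the configured width and row order", {
  for (ws in c(0.03125, 0.0625)) {
    cfg <- tinyConfig(widthScale = ws)
    net <- initNet(cfg, seed = 2)
    toy <- makeToy(6, seed = 3)
    fe <- featureMatrix(extractFeatures(net, toy$x))
    expect_identical(ncol(fe), featureWidth(cfg))
    expect_identical(ncol(fe), sum(scaledChannels(cfg)))
    # permuting input rows permutes output rows identically
    perm <- c(4L, 1L, 6L, 2L, 5L, 3L)
    fe2 <- featureMatrix(extractFeatures(net, toy$x[, , , perm, drop = FALSE]))
    expect_equal(fe2, fe[perm, ], tolerance = 1e-12, ignore_attr = TRUE)
    # bit-identical patches give bit-identical rows
    dup <- toy$x[, , , c(1L, 1L), drop = FALSE]
    fd <- featureMatrix(extractFeatures(net, dup))
    expect_identical(fd[1L, ], fd[2L, ])
  }
})

test_that("selection gates are sigmoid-bounded and monotone in their logits", {
  st <- newMetaState(c(4L, 6L), lambda = 1)
  feats <- list(matrix(rnorm(20), 5, 4), matrix(rnorm(30), 5, 6))
  g <- selectionGates(st, feats)
  expect_equal(lengths(g), c(4L, 6L))
  expect_true(all(unlist(g) == 0.5))          # all meta-parameters zero
  st@gateLogits[[1L]][2L] <- st@gateLogits[[1L]][2L] + 0.3
  g2 <- selectionGates(st, feats)
  expect_gt(g2[[1L]][2L], g[[1L]][2L])        # strictly increasing
  expect_error(selectionGates(st, list(matrix(0, 2, 5), feats[[2L]])),
               class = "tlrShapeError")
})

test_that("constraint loss matches its definition and vanishing conditions", {
  st <- newMetaState(2L, lambda = 1)
  tf <- list(matrix(c(2, sqrt(2)), 1, 2))
  sf <- list(matrix(0, 1, 2))
  st@gateLogits[[1L]] <- c(Inf, 0)            # gates (1, 0.5)
  expect_equal(transferConstraintLoss(tf, sf, st), (1 * 4 + 0.5 * 2) / 2)
  st0 <- newMetaState(2L, lambda = 0)
  expect_identical(transferConstraintLoss(tf, sf, st0), 0)
  stz <- newMetaState(2L, lambda = 1)
  stz@gateLogits[[1L]] <- c(-Inf, -Inf)       # all gates zero
  expect_equal(transferConstraintLoss(tf, sf, stz), 0)
  expect_equal(transferConstraintLoss(tf, tf, newMetaState(2L, lambda = 3)), 0)
})

test_that("source pretraining is deterministic, learns separable data, honours 0 epochs", {
  cfg <- networkConfig(inputSize = 32L, stemPool = 1L, widthScale = 0.25,
                       epochs = 20L)
  toy <- makeToy(40, seed = 1)
  r1 <- pretrainSource(toy, cfg, seed = 7)
  r2 <- pretrainSource(toy, cfg, seed = 7)
  expect_identical(tail(r1$history$taskLoss, 1L), tail(r2$history$taskLoss, 1L))
  expect_lte(tail(r1$history$taskLoss, 1L), r1$history$taskLoss[1L])
  pr <- noduleTLR:::softmaxRows(noduleTLR:::netForward(r1$net, toy$x)$logits)[, 2L]
  expect_gte(mean((pr > 0.5) == (toy$y == 1L)), 0.95)

  net0 <- pretrainSource(toy, cfg, seed = 7, epochs = 0L)$net
  expect_identical(net0@weights, initNet(cfg, nClasses = 2L, seed = 7, cin = 3L)@weights)
  one <- list(x = toy$x[, , , toy$y == 0, drop = FALSE], y = rep(0L, 20))
  expect_error(pretrainSource(one, cfg), class = "tlrDataError")
})

test_that("with lambda 0, frozen gates and a random start, transfer training equals the baseline", {
  cfg <- tinyConfig(epochs = 3L)
  toy <- makeToy(24, seed = 5)
  tr <- list(x = toy$x[, , , 1:16, drop = FALSE], y = toy$y[1:16], id = toy$id[1:16])
  va <- list(x = toy$x[, , , 17:24, drop = FALSE], y = toy$y[17:24], id = toy$id[17:24])
  src <- pretrainSource(tr, cfg, seed = 9, epochs = 1L)$net
  a <- trainTargetWithTransfer(tr, va, src, lambda = 0, seed = 11,
                               adaptGates = FALSE, initFromSource = FALSE)
  b <- trainNontransfer(tr, va, cfg, seed = 11)
  expect_equal(a$history$taskLoss, b$history$taskLoss, tolerance = 1e-12)
  expect_equal(a$history$valAuc, b$history$valAuc, tolerance = 1e-12)
})

test_that("overlapping patients between train and validation raise a leakage error", {
  cfg <- tinyConfig(epochs = 1L)
  toy <- makeToy(12, seed = 6)
  tr <- list(x = toy$x[, , , 1:8, drop = FALSE], y = toy$y[1:8], id = toy$id[1:8])
  va <- list(x = toy$x[, , , 5:12, drop = FALSE], y = toy$y[5:12], id = toy$id[5:12])
  expect_error(trainNontransfer(tr, va, cfg), class = "tlrLeakageError")
})

test_that("from-scratch training sits on the overfitting side on average", {
  cfg <- tinyConfig(widthScale = 0.0625, epochs = 6L)
  gaps <- vapply(1:10, function(s) {
    toy <- makeToy(100, seed = 200 + s, noiseSd = 0.35, gap = 0.25)
    tr <- list(x = toy$x[, , , 1:50, drop = FALSE], y = toy$y[1:50],
               id = toy$id[1:50])
    va <- list(x = toy$x[, , , 51:100, drop = FALSE], y = toy$y[51:100],
               id = toy$id[51:100])
    r <- trainNontransfer(tr, va, cfg, seed = s)
    pT <- noduleTLR:::softmaxRows(noduleTLR:::netForward(r$net, tr$x)$logits)[, 2L]
    auc(pT, tr$y) - tail(r$history$valAuc, 1L)
  }, numeric(1L))
  expect_gte(mean(gaps), 0)
})

test_that("validation-driven gate updates separate useful from noise source channels", {
  withr::with_seed(31, {
    nUse <- 6L; nNoise <- 10L
    y <- rep(0:1, each = 30)
    fUse <- sapply(seq_len(nUse), function(i) y * 1.5 + rnorm(60))
    fNoise <- matrix(rnorm(60 * nNoise), 60)
    st <- newMetaState(nUse + nNoise, lambda = 1)
    for (k in 1:5) st <- updateGates(st, list(cbind(fUse, fNoise)), y)
    g <- selectionGates(st, list(cbind(fUse, fNoise)))[[1L]]
    expect_lt(stats::wilcox.test(g[(nUse + 1):(nUse + nNoise)], g[1:nUse],
                                 alternative = "less")$p.value, 0.05)
    # pure-noise source: mean gate drifts below its 0.5 start
    stn <- newMetaState(nNoise, lambda = 1)
    for (k in 1:5) stn <- updateGates(stn, list(fNoise), y)
    expect_lt(mean(selectionGates(stn, list(fNoise))[[1L]]), 0.5)
  })
})

test_that("filter heatmaps are normalised, guarded and localise a bright blob", {
  cfg <- tinyConfig()
  net <- initNet(cfg, seed = 13)
  flat <- array(0.4, c(32, 32, 3, 1))
  # constant activation map: the normalisation guard returns a constant map
  net0 <- net
  net0@weights[[1L]]$W[] <- 0
  net0@weights[[2L]]$W[] <- 0
  hm0 <- filterResponseHeatmap(net0, flat, channel = 1L, stage = 2L)
  expect_equal(diff(range(hm0$heatmap)), 0)
  hm <- filterResponseHeatmap(net, flat, channel = 1L, stage = 2L)
  expect_true(all(is.finite(hm$heatmap)))
  expect_true(all(hm$heatmap >= 0 & hm$heatmap <= 1))
  expect_error(filterResponseHeatmap(net, flat, channel = 10000L),
               class = "tlrParamError")

  hits <- vapply(1:10, function(s) {
    toy <- makeBlobToy(2, seed = 40 + s)
    xb <- toy$x[, , , 2L, drop = FALSE]       # the blob-class image
    net <- initNet(cfg, seed = 40 + s)
    fw <- noduleTLR:::netForward(net, xb, keepActs = TRUE)
    ch <- which.max(colMeans(matrix(fw$acts[[2L]], ncol = dim(fw$acts[[2L]])[3L])))
    h <- filterResponseHeatmap(net, xb, channel = ch, stage = 2L)
    toy$mask[h$max[1L], h$max[2L]]
  }, logical(1L))
  expect_gte(sum(hits), 8L)
})
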