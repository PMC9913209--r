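test_that("1-D Wasserstein matches sorted matching and the expansion oracle", {
  expect_equal(w1Dist(c(3, 1, 2), c(2, 1, 3)), 0)
  expect_equal(w1Dist(0, 1), 1)
  expect_equal(w1Dist(c(0, 1), c(2, 5)), 3)
  withr::with_seed(9, {
    for (k in 1:20) {
      a <- rnorm(sample(2:7, 1L))
      b <- rnorm(sample(2:7, 1L))
      expect_equal(w1Dist(a, b), lcmW1(a, b), tolerance = 1e-10)
    }
  })
  expect_error(w1Dist(numeric(0), 1), class = "tlrDataError")
})

test_that("sliced distance is a symmetric, seeded pseudometric with the point-mass closed form", {
  withr::with_seed(10, {
    A <- matrix(rnorm(60), 20, 3)
    B <- matrix(rnorm(60) + 1, 20, 3)
    expect_equal(slicedW1(A, A, seed = 4), 0)
    expect_identical(slicedW1(A, B, seed = 4), slicedW1(B, A, seed = 4))
    expect_identical(slicedW1(A, B, seed = 4), slicedW1(A, B, seed = 4))
    expect_gte(slicedW1(A, B, seed = 4), 0)
    expect_error(slicedW1(A, matrix(0, 5, 4)), class = "tlrShapeError")

    # two point masses in R^3: E|<u, x-y>| = ||x-y|| * E|u1| = ||x-y|| / 2
    x <- c(1, -2, 0.5); y <- c(-0.5, 1, 2)
    d <- slicedW1(matrix(x, 1), matrix(y, 1), nProjections = 10000L, seed = 1)
    expect_lt(abs(d - sqrt(sum((x - y)^2)) / 2) / (sqrt(sum((x - y)^2)) / 2), 0.05)
  })
})

test_that("source ranking orders by distance with name tie-breaks and fingerprint checks", {
  withr::with_seed(12, {
    tgt <- matrix(rnorm(100), 25, 4)
    mk <- function(m, nm) new("DomainEmbedding", features = m, domain = nm,
                              fingerprint = "fp1")
    target <- mk(tgt, "target")
    same <- mk(tgt, "same")
    far <- mk(tgt + 3, "far")
    rk <- rankSources(list(same = same, far = far), target, nProjections = 32L)
    expect_identical(rk$source[1L], "same")
    expect_equal(rk$distance[1L], 0)
    expect_identical(attr(rk, "recommended"), "same")

    dupA <- mk(tgt + 1, "b"); dupB <- mk(tgt + 1, "a")
    rk2 <- rankSources(list(b = dupA, a = dupB), target, nProjections = 32L)
    expect_identical(rk2$source, c("a", "b"))          # equal distances: name order
    expect_equal(rk2$distance[1L], rk2$distance[2L])

    bad <- new("DomainEmbedding", features = tgt, domain = "x", fingerprint = "fp2")
    expect_error(rankSources(list(a = same, b = bad), target),
                 class = "tlrFingerprintError")
    expect_error(rankSources(list(a = same), target), class = "tlrParamError")
  })
})

test_that("embeddings carry matching fingerprints for like extractors", {
  cfg <- tinyConfig()
  net <- initNet(cfg, seed = 3)
  toy <- makeToy(6, seed = 2)
  e1 <- embedDomain(net, toy$x, domain = "a")
  e2 <- embedDomain(net, toy$x, domain = "b")
  expect_identical(e1@fingerprint, e2@fingerprint)
  expect_identical(ncol(e1@features), scaledChannels(cfg)[length(net@weights) - 1L])
  net2 <- initNet(cfg, seed = 4)
  expect_false(identical(embedDomain(net2, toy$x)@fingerprint, e1@fingerprint))
})
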