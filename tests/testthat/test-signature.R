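test_that("Mann-Whitney screening handles ties, small exact cases and transforms", {
  X <- cbind(f1 = c(1, 2, 3, 4), f2 = c(5, 5, 5, 5))
  y <- c(0L, 0L, 1L, 1L)
  sc <- mannWhitneyFilter(X, y, alpha = 0.05)
  expect_equal(unname(sc$p["f2"]), 1.0)        # all ties: excluded
  expect_false(sc$mask[["f2"]])
  expect_equal(unname(sc$p["f1"]), 1 / 3)      # exact two-sided p, U = 0

  wt <- wilcoxonRanksum(c(1, 2), c(3, 4))
  expect_equal(wt$p, 1 / 3)
  expect_equal(wilcoxonRanksum(c(1, 2, 3), c(2, 3, 1))$p, 1, tolerance = 1e-9)

  # strictly increasing transform leaves rank-based p unchanged
  withr::with_seed(8, {
    x <- rnorm(30); y2 <- rep(0:1, 15)
    p1 <- mannWhitneyFilter(cbind(a = x), y2)$p
    p2 <- mannWhitneyFilter(cbind(a = exp(3 * x) + 2), y2)$p
    expect_equal(unname(p1), unname(p2))
  })
  expect_error(mannWhitneyFilter(X, c(1L, 1L, 1L, 1L)), class = "tlrDataError")
})

test_that("SBELM keeps a separating feature, prunes noise, and scores sanely", {
  withr::with_seed(12, {
    n <- 200L
    y <- rep(0:1, each = n / 2)
    X <- cbind(sig = y + rnorm(n, 0, 0.3),
               matrix(rnorm(n * 30), n, dimnames = list(NULL, sprintf("n%02d", 1:30))))
    fit <- fitSbelm(X, y)
    expect_true("sig" %in% fit@featureIds)
    expect_lt(length(fit@featureIds), 10L)
    sc <- tlsScore(fit, X)
    expect_true(all(sc >= 0 & sc <= 1))
    expect_gt(auc(sc, y), 0.9)

    # permuted labels: essentially everything pruned
    fitNull <- fitSbelm(X, sample(y))
    expect_lte(length(fitNull@featureIds), 2L)

    # duplicating a retained feature barely moves training scores
    X2 <- cbind(X, sig2 = X[, "sig"])
    fit2 <- fitSbelm(X2, y)
    expect_lt(max(abs(tlsScore(fit2, X2) - sc)), 0.15)
  })
  expect_error(fitSbelm(matrix(rnorm(8), 4), c(0, 1, 0, 1)), class = "tlrDataError")
})

test_that("TLS scores are bounded, monotone and null-safe", {
  m <- new("SbelmModel", featureIds = "f1", weights = 2, intercept = 0,
           alpha = 1, center = c(f1 = 0), scale = c(f1 = 1), screened = "f1",
           converged = TRUE, iterations = 1L, nullModel = FALSE)
  x <- cbind(f1 = c(-2, 0, 2))
  sc <- tlsScore(m, x)
  expect_equal(sc[2L], 0.5)                    # zero feature, zero intercept
  expect_true(all(diff(sc) > 0))               # monotone in a positive weight
  expect_error(tlsScore(m, cbind(g = 1:3)), class = "tlrSchemaError")
})

test_that("signature models round-trip through JSON bit-exactly", {
  withr::with_seed(3, {
    X <- matrix(rnorm(200), 20, dimnames = list(NULL, sprintf("f%02d", 1:10)))
    y <- rep(0:1, 10)
    fit <- suppressWarnings(fitSbelm(X, y))
    f <- tempfile(fileext = ".json")
    writeSbelm(fit, f)
    back <- readSbelm(f)
    expect_identical(back@weights, fit@weights)
    expect_identical(back@center, fit@center)
    expect_identical(tlsScore(back, X), tlsScore(fit, X))
  })
})

test_that("screening strictly precedes the SBELM in buildTls", {
  withr::with_seed(5, {
    n <- 60L
    y <- rep(0:1, each = n / 2)
    X <- cbind(good = y + rnorm(n, 0, 0.4),
               matrix(rnorm(n * 20), n, dimnames = list(NULL, sprintf("z%02d", 1:20))))
    out <- buildTls(X, y)
    # the model never saw features the screen masked out
    expect_true(all(out$model@screened %in% names(which(out$screen$mask))))
    expect_true(all(out$model@featureIds %in% out$model@screened))
  })
})

test_that("scores are invariant to patient ordering", {
  withr::with_seed(6, {
    X <- matrix(rnorm(300), 30, dimnames = list(NULL, sprintf("f%02d", 1:10)))
    y <- rep(0:1, 15)
    fit <- suppressWarnings(fitSbelm(X, y))
    perm <- sample(30)
    expect_equal(tlsScore(fit, X[perm, ]), tlsScore(fit, X)[perm])
  })
})
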