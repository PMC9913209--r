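test_that("Cohen's kappa matches hand computation and flags degeneracy", {
  expect_equal(cohenKappa(c("a", "b", "a"), c("a", "b", "a"))$kappa, 1)
  # 2x2 agreement table [[20,5],[10,15]]: po 0.7, pe 0.5, kappa 0.4
  r1 <- rep(c("x", "x", "y", "y"), c(20, 5, 10, 15))
  r2 <- rep(c("x", "y", "x", "y"), c(20, 5, 10, 15))
  k <- cohenKappa(r1, r2)
  expect_equal(k$po, 0.7)
  expect_equal(k$pe, 0.5)
  expect_equal(k$kappa, 0.4)
  withr::with_seed(2, {
    a <- sample(letters[1:3], 10000, replace = TRUE)
    b <- sample(letters[1:3], 10000, replace = TRUE)
    expect_lt(abs(cohenKappa(a, b)$kappa), 0.05)
  })
  expect_true(cohenKappa(rep("a", 5), rep("a", 5))$undefined)
  expect_error(cohenKappa(1:3, 1:4), class = "tlrDataError")
})

test_that("Pearson chi-square has no continuity correction and correct nulls", {
  flat <- pearsonChi2(matrix(c(10, 10, 10, 10), 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p, 1)
  expect_equal(round(pearsonChi2(matrix(c(64, 50, 65, 89), 2))$p, 4), 0.0240)
  expect_error(pearsonChi2(matrix(c(0, 0, 5, 5), 2)), class = "tlrDataError")
  expect_error(pearsonChi2(matrix(c(1.5, 2, 3, 4), 2)), class = "tlrDataError")
})

test_that("Fisher's exact test matches full enumeration and its asymptotics", {
  tab <- matrix(c(1, 9, 9, 1), 2)
  expect_equal(fisherExact(tab), (2 * choose(10, 1) * choose(10, 9) + 2) /
                 choose(20, 10))
  expect_equal(fisherExact(matrix(c(6, 6, 4, 4), 2)), 1)
  big <- matrix(c(260, 240, 215, 285), 2)     # all expected counts > 50
  expect_lt(abs(fisherExact(big) - pearsonChi2(big)$p), 0.01)
  expect_error(fisherExact(matrix(1:18, 3)), class = "tlrParamError")
})

test_that("univariate screening dispatches by type and expected counts", {
  withr::with_seed(14, {
    n <- 300L
    co <- data.frame(
      label = rep(c("LGN", "LAC"), each = n / 2),
      age = rnorm(n, 55, 10) + 5 * rep(0:1, each = n / 2),
      rare = sample(c(rep("p", 6), rep("a", n - 6))),
      common = sample(c("u", "v"), n, TRUE),
      flat = "same")
    scr <- univariateScreen(co)
    expect_identical(scr$test[scr$variable == "age"], "wilcoxon")
    expect_identical(scr$test[scr$variable == "rare"], "fisher_exact")
    expect_identical(scr$test[scr$variable == "common"], "pearson_chi2")
    expect_true(scr$degenerate[scr$variable == "flat"])
    expect_equal(scr$p[scr$variable == "flat"], 1)
  })
  # printed clinical-cohort tables reproduce to 4 dp through the dispatcher
  expect_equal(round(pearsonChi2(matrix(c(21, 16, 52, 10), 2))$p, 4), 0.0030)
  expect_equal(round(pearsonChi2(matrix(c(20, 17, 18, 44), 2))$p, 4), 0.0133)
})

test_that("a covariate independent of the label stays non-significant", {
  hits <- vapply(1:20, function(s) {
    withr::with_seed(400 + s, {
      y <- rep(0:1, each = 2500)
      x <- sample(c("m", "w"), 5000, TRUE)
      pearsonChi2(table(x, y))$p > 0.05
    })
  }, logical(1L))
  expect_gte(sum(hits), 18L)
})

test_that("sparse Bayes LASSO recovers planted covariates and shrinks monotonically", {
  withr::with_seed(77, {
    n <- 1000L
    X <- matrix(rnorm(n * 10), n, dimnames = list(NULL, sprintf("c%02d", 1:10)))
    eta <- X[, 1] - 0.9 * X[, 2] + 0.8 * X[, 3]
    y <- rbinom(n, 1, plogis(eta))
    d <- data.frame(label = y, X)
    cand <- sprintf("c%02d", 1:10)
    colnames(d)[-1L] <- cand
    fit <- fitSparseBayesLasso(d, cand)
    expect_true(all(c("c01", "c02", "c03") %in% fit@terms))
    expect_lte(length(setdiff(fit@terms, c("c01", "c02", "c03"))), 2L)

    # pure noise: nothing retained
    dn <- d; dn$label <- sample(y)
    fitN <- fitSparseBayesLasso(dn, cand)
    expect_lte(length(fitN@terms), 1L)

    # retained-set size never grows as the prior rate doubles
    sizes <- vapply(2^(0:4), function(g)
      length(fitSparseBayesLasso(d, cand, priorScale = g)@terms), integer(1L))
    expect_true(all(diff(sizes) <= 0L))

    # invariance to covariate ordering
    fit2 <- fitSparseBayesLasso(d, rev(cand))
    expect_setequal(fit2@terms, fit@terms)
  })
})

test_that("TLRM scores are logistic, monotone and schema-checked", {
  m <- new("TlrmModel", terms = character(0), coefficients = numeric(0),
           intercept = 0, center = numeric(0), scale = numeric(0),
           candidates = character(0), priorScale = 1, evidence = 0)
  expect_equal(tlrmScore(m, data.frame(x = 1:3)), rep(0.5, 3))

  withr::with_seed(21, {
    n <- 400L
    d <- data.frame(label = rep(c("LGN", "LAC"), each = n / 2),
                    age = rnorm(n, 55, 10) + 6 * rep(0:1, each = n / 2),
                    tls = plogis(rnorm(n) + 1.5 * rep(0:1, each = n / 2)))
    fit <- fitSparseBayesLasso(d, c("age", "tls"))
    expect_true("tls" %in% fit@terms)
    probe <- d[rep(1L, 5L), ]
    probe$tls <- seq(0.1, 0.9, length.out = 5L)
    sc <- tlrmScore(fit, probe)
    expect_true(all(diff(sc) > 0))
    expect_lt(stats::wilcox.test(tlrmScore(fit, d[d$label == "LAC", ]),
                                 tlrmScore(fit, d[d$label == "LGN", ]),
                                 alternative = "greater")$p.value, 0.05)
    expect_error(tlrmScore(fit, data.frame(age = 1)), class = "tlrSchemaError")
  })
})

test_that("the clinical logistic comparator fits, recovers and degrades safely", {
  withr::with_seed(31, {
    n <- 5000L
    d <- data.frame(
      gender = sample(c("men", "women"), n, TRUE),
      age = rnorm(n),
      lobulated = sample(c("absence", "presence"), n, TRUE),
      spiculated = sample(c("absence", "presence"), n, TRUE))
    X <- noduleTLR:::fusionDesign(d, c("gender", "age", "lobulated", "spiculated"))
    beta <- c(0.5, -0.8, 1.0, 0.7)
    y <- rbinom(n, 1, plogis(drop(X %*% beta) - 0.3))
    d$label <- ifelse(y == 1, "LAC", "LGN")
    fit <- fitClinicalLogistic(d)
    est <- fit@coefficients[-1L]
    expect_true(all(abs(est - beta) < 3 * fit@se[-1L]))

    # a covariate equal to the label separates perfectly -> AUC 1 + fallback
    d2 <- d
    d2$age <- as.numeric(d2$label == "LAC")
    fit2 <- suppressWarnings(fitClinicalLogistic(d2))
    expect_equal(auc(clinicalScore(fit2, d2), y), 1)
  })

  nullAucs <- vapply(1:20, function(s) {
    withr::with_seed(500 + s, {
      n <- 500L
      d <- data.frame(
        gender = sample(c("men", "women"), n, TRUE), age = rnorm(n),
        lobulated = sample(c("absence", "presence"), n, TRUE),
        spiculated = sample(c("absence", "presence"), n, TRUE),
        label = sample(c("LGN", "LAC"), n, TRUE))
      fit <- suppressWarnings(fitClinicalLogistic(d))
      auc(clinicalScore(fit, d), noduleTLR:::asLabel01(d$label))
    })
  }, numeric(1L))
  expect_true(all(nullAucs >= 0.45 & nullAucs <= 0.60))
})
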