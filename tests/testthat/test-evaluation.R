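test_that("AUC is the Mann-Whitney probability with half-weight ties", {
  expect_equal(auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(auc(c(1, 2, 3, 10), c(0, 0, 1, 1)), 1)
  expect_equal(auc(rep(0.3, 6), rep(0:1, 3)), 0.5)
  expect_error(auc(1:4, rep(1, 4)), class = "tlrDataError")
})

test_that("DeLong machinery matches pROC and handles degenerate pairs", {
  withr::with_seed(15, {
    n <- 150L
    y <- rep(0:1, c(60, 90))
    a <- y + rnorm(n)
    b <- y * 0.5 + rnorm(n)
    dt <- delongTest(a, b, y)
    pr <- pROC::roc.test(pROC::roc(y, a, quiet = TRUE),
                         pROC::roc(y, b, quiet = TRUE),
                         method = "delong", paired = TRUE)
    expect_equal(dt$p, pr$p.value, tolerance = 1e-9)
    expect_equal(abs(dt$z), abs(unname(pr$statistic)), tolerance = 1e-9)

    ci <- delongCi(a, y)
    pci <- as.numeric(pROC::ci.auc(pROC::roc(y, a, quiet = TRUE), method = "delong"))
    expect_equal(c(ci$lower, ci$auc, ci$upper), pci, tolerance = 1e-9)
    expect_true(ci$lower <= ci$auc && ci$auc <= ci$upper)

    same <- delongTest(a, a, y)
    expect_identical(c(same$z, same$p), c(0, 1))
    expect_true(same$degenerate)
  })
})

test_that("confusion metrics and the Youden threshold behave as defined", {
  lab <- c(1, 1, 1, 0, 0)
  sc <- c(0.9, 0.8, 0.4, 0.3, 0.2)
  r <- confusionAt(sc, lab, 0.5)
  expect_equal(r$sensitivity, 2 / 3)
  expect_equal(r$specificity, 1)
  expect_equal(r$accuracy, 4 / 5)
  expect_equal(r$ppv, 1)
  expect_equal(r$npv, 2 / 3)
  expect_equal(r$tp + r$tn, 4L)
  expect_equal(confusionAt(sc, lab, 0)$sensitivity, 1)
  expect_error(confusionAt(sc, lab, 1.2), class = "tlrParamError")

  thr <- youdenThreshold(sc, lab)
  r2 <- confusionAt(sc, lab, thr)
  expect_equal(r2$sensitivity + r2$specificity, 2)   # perfectly separable here?
})

test_that("IDI matches its hand example and nulls out on identical inputs", {
  pOld <- c(0.6, 0.7, 0.4, 0.3)
  pNew <- c(0.8, 0.9, 0.2, 0.1)
  lab <- c(1, 1, 0, 0)
  expect_equal(idi(pOld, pNew, lab)$idi, 0.40)
  same <- idi(pOld, pOld, lab)
  expect_equal(c(same$idi, same$p), c(0, 1))
})

test_that("Hosmer-Lemeshow is zero for perfectly grouped probabilities and rejects inversion", {
  probs <- rep(seq(0.05, 0.95, by = 0.1), each = 20)
  withr::with_seed(18, {
    labs <- unlist(lapply(seq(0.05, 0.95, by = 0.1), function(p) {
      k <- round(20 * p)
      sample(rep(c(1, 0), c(k, 20 - k)))
    }))
  })
  hl <- hosmerLemeshow(probs, labs, g = 10L)
  expect_equal(hl$df, 8L)
  # per-group observed equals expected by construction
  expect_lt(hl$chisq, 1e-9)
  expect_equal(hl$p, 1)

  bad <- hosmerLemeshow(1 - labs, labs, g = 10L)
  expect_lt(bad$p, 0.001)
  expect_error(hosmerLemeshow(runif(10), rbinom(10, 1, 0.5), g = 10L),
               class = "tlrDataError")
})

test_that("decision curves honour the net-benefit identities", {
  dc <- decisionCurve(c(1, 0), c(1, 0), thresholds = 0.5)
  expect_equal(dc$netBenefit, 0.5)
  expect_equal(dc$treatAll, 0)
  expect_equal(dc$treatNone, 0)

  withr::with_seed(19, {
    y <- rbinom(80, 1, 0.4)
    p <- pmin(pmax(y * 0.8 + runif(80) * 0.2, 0), 1)
    dc2 <- decisionCurve(p, y)
    prev <- mean(y)
    ok <- !is.na(dc2$netBenefit)
    expect_true(all(dc2$netBenefit[ok] <= prev + 1e-12))
    expect_equal(dc2$treatAll[ok],
                 prev - (1 - prev) * dc2$threshold[ok] / (1 - dc2$threshold[ok]))
    expect_true(is.na(dc2$netBenefit[dc2$threshold == 1]))
    # perfect classifier: net benefit equals prevalence at every pt < 1
    dcp <- decisionCurve(y, y, thresholds = c(0.2, 0.5, 0.9))
    expect_true(all(abs(dcp$netBenefit - prev) < 1e-12))
  })
  expect_error(decisionCurve(0.5, 1, thresholds = numeric(0)),
               class = "tlrParamError")
})

test_that("stratified analysis reduces to the pooled AUC and skips degenerate strata", {
  withr::with_seed(20, {
    y <- rep(0:1, each = 40)
    s <- y * 0.8 + rnorm(80)
    one <- stratifiedAnalysis(s, y, rep("all", 80))
    expect_equal(one$auc, auc(s, y))
    expect_equal(one$delongP, 1)

    strata <- c(rep("a", 75), rep("b", 5))
    y2 <- c(rep(0:1, length.out = 75), rep(1, 5))
    expect_warning(res <- stratifiedAnalysis(s, y2, strata), "skipped")
    expect_true(res$skipped[res$stratum == "b"])
    expect_false(res$skipped[res$stratum == "a"])
  })
})

test_that("random strata of an exchangeable cohort rarely differ from pooled", {
  hits <- vapply(1:20, function(k) {
    withr::with_seed(600 + k, {
      y <- rep(0:1, each = 60)
      s <- y * 0.7 + rnorm(120)
      g <- sample(c("g1", "g2"), 120, TRUE)
      res <- stratifiedAnalysis(s, y, g)
      all(res$delongP[!res$skipped] > 0.05)
    })
  }, logical(1L))
  expect_gte(sum(hits), 18L)
})
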