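test_that("nodule renderer is deterministic and validates parameters", {
  p <- noduleParams(12, 2, 1, textureSeed = 42)
  expect_identical(renderNodule(p, size = 64), renderNodule(p, size = 64))
  expect_error(noduleParams(1.5), class = "tlrParamError")
  expect_error(noduleParams(35), class = "tlrParamError")
  expect_error(noduleParams(10, -1), class = "tlrParamError")
  expect_error(renderNodule(p, size = 16), class = "tlrParamError")
})

test_that("spicules roughen the boundary and diameter doubles the area", {
  smooth <- renderNodule(noduleParams(10, 0, 0, textureSeed = 7))
  spiky <- renderNodule(noduleParams(10, 0, 8, textureSeed = 7))
  cvS <- sd(radialProfile(smooth)) / mean(radialProfile(smooth))
  cvK <- sd(radialProfile(spiky)) / mean(radialProfile(spiky))
  expect_lt(cvS, cvK)

  a1 <- sum(renderNodule(noduleParams(10, 0, 0, textureSeed = 7)) > -400)
  a2 <- sum(renderNodule(noduleParams(20, 0, 0, textureSeed = 7)) > -400)
  expect_gte(a2 / a1, 3.5)
  expect_lte(a2 / a1, 4.5)
})

test_that("target cohorts allocate classes exactly and reproduce the cohort ages", {
  cl <- generateTargetCohort(cohortSpec(n = 200, prevalenceLac = 0.5, seed = 3),
                             images = FALSE)$clinical
  expect_identical(sum(cl$label == "LAC"), 100L)

  big <- generateTargetCohort(cohortSpec(n = 2000, seed = 17), images = FALSE)$clinical
  expect_lt(abs(mean(big$age[big$label == "LAC"]) - 60.13), 1.0)
  expect_lt(abs(mean(big$age[big$label == "LGN"]) - 53.42), 1.0)
  # association directions
  expect_gt(mean(big$nodule_size[big$label == "LAC"]),
            mean(big$nodule_size[big$label == "LGN"]))
  expect_gt(mean(big$lobulated[big$label == "LAC"] == "presence"),
            mean(big$lobulated[big$label == "LGN"] == "presence"))

  expect_error(cohortSpec(n = 100, ageSdLac = -1), class = "tlrParamError")
  expect_error(cohortSpec(n = 100, prevalenceLac = 1.2), class = "tlrParamError")
})

test_that("cohort generation is a pure function of its spec", {
  sp <- cohortSpec(n = 8, seed = 9, size = 64L)
  a <- generateTargetCohort(sp)
  b <- generateTargetCohort(sp)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$patches@pixels, b$patches@pixels)
})

test_that("source domains are balanced, deterministic and kind-checked", {
  sp <- sourceDomainSpec("wsi_like", nClasses = 3, n = 60, targetOverlap = 0.5,
                         size = 64L, seed = 5)
  d <- generateSourceDomain(sp)
  expect_equal(unname(table(patchPheno(d)$label)), rep(20L, 3L),
               ignore_attr = TRUE)
  expect_identical(generateSourceDomain(sp)@pixels, d@pixels)
  expect_error(sourceDomainSpec("histology", 2, 10, 0.5), class = "tlrParamError")
  expect_error(sourceDomainSpec("wsi_like", 2, 10, 1.5), class = "tlrParamError")
  expect_error(sourceDomainSpec("wsi_like", 5, 3, 0.5), class = "tlrParamError")
})

test_that("target overlap controls pixel-distribution similarity to target patches", {
  tgt <- generateTargetCohort(cohortSpec(n = 12, seed = 21, size = 64L))$patches
  tpix <- unlist(lapply(tgt@pixels, as.numeric))
  histDist <- function(ov) {
    d <- generateSourceDomain(sourceDomainSpec("wsi_like", 2, 12, ov,
                                               size = 64L, seed = 22))
    w1Dist(sample(unlist(lapply(d@pixels, as.numeric)), 5000),
           sample(tpix, 5000))
  }
  withr::with_seed(1, expect_lt(histDist(1), histDist(0)))
})

test_that("default effect sizes make the key covariates screen significant", {
  hits <- vapply(1:20, function(s) {
    cl <- generateTargetCohort(cohortSpec(n = 500, seed = 100 + s),
                               images = FALSE)$clinical
    scr <- univariateScreen(cl)
    all(scr$significant[scr$variable %in%
                          c("age", "nodule_size", "lobulated", "spiculated")])
  }, logical(1L))
  expect_gte(sum(hits), 18L)
})
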