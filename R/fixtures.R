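# Synthetic fixtures: nodule renderer, target cohorts, source domains.
# The generator's clinical defaults are a reference multicentre cohort
# summary (means/SDs/proportions); morphology is class-conditional
# via Poisson lobulation/spiculation counts and moment-matched log-normal
# diameters. Everything is a pure function of its spec (seed included).

#' Nodule rendering parameters
#'
#' Encodes the dichotomised subjective CT findings as renderable morphology:
#' lobulation adds low-frequency boundary undulations, spicules add narrow
#' radial spikes.
#'
#' @param diameterMm nodule diameter in mm, in (2, 30].
#' @param lobulationCount non-negative number of lobulation components.
#' @param spiculeCount non-negative number of radial spicules.
#' @param baseIntensity interior pseudo-HU value (solid nodules are ~ 30 HU).
#' @param textureSeed integer seed for the internal texture generator;
#'   identical params + seed render bit-identical images.
#' @param textureSd interior texture standard deviation in HU.
#' @param marginRoughness extra high-frequency boundary roughness in [0, 1]
#'   (0 = regular margin).
#' @return a validated parameter list of class `"NoduleParams"`.
#' @export
noduleParams <- function(diameterMm, lobulationCount = 0L, spiculeCount = 0L,
                         baseIntensity = 30, textureSeed = 1L,
                         textureSd = 20, marginRoughness = 0) {
  if (!is.finite(diameterMm) || diameterMm <= 2 || diameterMm > 30)
    stopParam("diameterMm must be in (2, 30]")
  lobulationCount <- as.integer(lobulationCount)
  spiculeCount <- as.integer(spiculeCount)
  if (is.na(lobulationCount) || lobulationCount < 0L ||
      is.na(spiculeCount) || spiculeCount < 0L)
    stopParam("lobulation/spicule counts must be non-negative integers")
  structure(list(diameterMm = diameterMm, lobulationCount = lobulationCount,
                 spiculeCount = spiculeCount, baseIntensity = baseIntensity,
                 textureSeed = as.integer(textureSeed), textureSd = textureSd,
                 marginRoughness = marginRoughness),
            class = "NoduleParams")
}

#' Render a synthetic nodule as a pseudo-HU grid
#'
#' Draws a centred soft-edged nodule on a lung-parenchyma background. The
#' boundary radius is `R0 * (1 + undulations + spikes + roughness)`; interior
#' texture is a deterministic sinusoid mixture seeded by `textureSeed`.
#'
#' @param params a [noduleParams()] object.
#' @param size output grid side in pixels (>= 32).
#' @param fovMm physical field of view in mm represented by the grid.
#' @param background parenchyma HU level.
#' @return `size` x `size` numeric matrix of pseudo-HU values.
#' @export
.gridCache <- new.env(parent = emptyenv())

# mm coordinate grids are identical across renders of one size/fov; memoise
renderGrid <- function(size, fovMm) {
  key <- paste0(size, ":", fovMm)
  g <- get0(key, envir = .gridCache)
  if (is.null(g)) {
    sc <- size / fovMm                        # px per mm
    ax <- (seq_len(size) - (size + 1) / 2) / sc
    x <- matrix(ax, size, size, byrow = TRUE)
    y <- matrix(ax, size, size)
    g <- list(x = x, y = y, r = sqrt(x^2 + y^2), th = atan2(y, x))
    assign(key, g, envir = .gridCache)
  }
  g
}

renderNodule <- function(params, size = 224L, fovMm = 50, background = -820) {
  stopifnot(inherits(params, "NoduleParams"))
  size <- as.integer(size)
  if (size < 32L) stopParam("size must be >= 32")
  withSeed(params$textureSeed, {
    R0 <- params$diameterMm / 2
    L <- params$lobulationCount
    lobFr <- if (L > 0L) as.numeric(sample(2:6, L, replace = TRUE)) else numeric(0)
    lobPh <- if (L > 0L) runif(L, 0, 2 * pi) else numeric(0)
    S <- params$spiculeCount
    spikeAng <- if (S > 0L) runif(S, 0, 2 * pi) else numeric(0)
    spikeLen <- if (S > 0L) runif(S, 0.45, 0.7) else numeric(0)
    roughPh <- if (params$marginRoughness > 0) runif(2, 0, 2 * pi) else c(0, 0)
    texW <- matrix(runif(8, 0.25, 1.1), 4, 2, byrow = TRUE)
    texPh <- runif(4, 0, 2 * pi)
    noise <- rnorm(size * size)
    cppRenderNodule(size, fovMm, R0, lobFr, lobPh, spikeAng, spikeLen,
                    params$marginRoughness, roughPh, texW, texPh,
                    params$textureSd, params$baseIntensity, background,
                    noise, 0.35)
  })
}

#' Synthetic target-cohort specification
#'
#' Defaults encode a reference multicentre SPSN cohort summary: LAC patients are older (60.13 +/- 10.08 vs 53.42 +/- 11.99
#' years), more often women, with larger (18.91 vs 12.45 mm), more lobulated
#' and more spiculated nodules. Lobulation/spiculation presence rates are
#' matched through the Poisson means (e.g. `1 - exp(-2.0) = 0.86` lobulated
#' LAC). `genderOdds` is the implied men-odds ratio LGN : LAC.
#'
#' @param n cohort size (>= 2).
#' @param prevalenceLac LAC prevalence in (0, 1); patients are allocated by
#'   exact count (`round(n * prevalenceLac)` LAC), not Bernoulli draws.
#' @param ageMeanLac,ageSdLac,ageMeanLgn,ageSdLgn age distributions (years).
#' @param pMenLac,pMenLgn probability of male gender per class.
#' @param sizeMeanLac,sizeSdLac,sizeMeanLgn,sizeSdLgn nodule diameter (mm);
#'   sampled log-normal (moment-matched) truncated to (2, 30].
#' @param lobLambda,spicLambda named Poisson means `c(lgn=, lac=)` for
#'   lobulation and spicule counts.
#' @param pIrregularLac,pIrregularLgn probability of an irregular margin.
#' @param locationProbs named multinomial over lobes (class-independent).
#' @param baseHu,baseHuSd interior attenuation and its between-patient SD.
#' @param textureSd named interior texture SD `c(lgn=, lac=)` (LAC lesions
#'   rendered more heterogeneous).
#' @param size patch side in pixels.
#' @param seed integer seed; generation is a pure function of the spec.
#' @return a validated spec list of class `"SyntheticCohortSpec"`.
#' @export
cohortSpec <- function(n, prevalenceLac = 411 / 573,
                       ageMeanLac = 60.13, ageSdLac = 10.08,
                       ageMeanLgn = 53.42, ageSdLgn = 11.99,
                       pMenLac = 201 / 411, pMenLgn = 102 / 162,
                       sizeMeanLac = 18.91, sizeSdLac = 7.65,
                       sizeMeanLgn = 12.45, sizeSdLgn = 6.66,
                       lobLambda = c(lgn = 0.5, lac = 2.0),
                       spicLambda = c(lgn = 0.2, lac = 0.73),
                       pIrregularLac = 372 / 411, pIrregularLgn = 93 / 162,
                       locationProbs = c(LUL = 146, LLL = 89, RUL = 178,
                                         RML = 59, RLL = 101) / 573,
                       baseHu = 32, baseHuSd = 8,
                       textureSd = c(lgn = 16, lac = 34),
                       size = 224L, seed = 1L) {
  if (n < 2L) stopParam("n must be >= 2")
  if (prevalenceLac <= 0 || prevalenceLac >= 1)
    stopParam("prevalenceLac must be in (0, 1)")
  if (ageSdLac <= 0 || ageSdLgn <= 0 || sizeSdLac <= 0 || sizeSdLgn <= 0)
    stopParam("standard deviations must be positive")
  structure(as.list(environment())[names(formals(cohortSpec))],
            genderOdds = (pMenLgn / (1 - pMenLgn)) / (pMenLac / (1 - pMenLac)),
            class = "SyntheticCohortSpec")
}

truncLnorm <- function(n, m, s, lo, hi) {
  sig2 <- log(1 + (s / m)^2)
  x <- rlnorm(n, log(m) - sig2 / 2, sqrt(sig2))
  pmin(pmax(x, lo), hi)
}

#' Generate a synthetic target cohort
#'
#' Jointly samples labels, clinical covariates and (optionally) rendered,
#' lung-windowed nodule patches whose morphology matches the covariates.
#'
#' @param spec a [cohortSpec()].
#' @param images render patches (set `FALSE` for a clinical-table-only
#'   cohort, e.g. for large-n statistical checks).
#' @param cohort cohort tag written into the metadata.
#' @return `list(patches = CtPatchSet | NULL, clinical = data.frame)`; the
#'   clinical table has columns patient_id, cohort, label, gender, age,
#'   nodule_size, location, margin, lobulated, spiculated.
#' @export
generateTargetCohort <- function(spec, images = TRUE, cohort = "synthetic") {
  stopifnot(inherits(spec, "SyntheticCohortSpec"))
  withSeed(spec$seed, {
    n <- as.integer(spec$n)
    nLac <- as.integer(round(n * spec$prevalenceLac))
    lab <- integer(n)
    lab[sample.int(n, nLac)] <- 1L
    isLac <- lab == 1L
    age <- ifelse(isLac, rnorm(n, spec$ageMeanLac, spec$ageSdLac),
                  rnorm(n, spec$ageMeanLgn, spec$ageSdLgn))
    age <- pmin(pmax(age, 16), 95)
    men <- rbinom(n, 1L, ifelse(isLac, spec$pMenLac, spec$pMenLgn))
    sz <- numeric(n)
    sz[isLac] <- truncLnorm(sum(isLac), spec$sizeMeanLac, spec$sizeSdLac, 2.5, 30)
    sz[!isLac] <- truncLnorm(sum(!isLac), spec$sizeMeanLgn, spec$sizeSdLgn, 2.5, 30)
    lob <- rpois(n, ifelse(isLac, spec$lobLambda[["lac"]], spec$lobLambda[["lgn"]]))
    spic <- rpois(n, ifelse(isLac, spec$spicLambda[["lac"]], spec$spicLambda[["lgn"]]))
    irr <- rbinom(n, 1L, ifelse(isLac, spec$pIrregularLac, spec$pIrregularLgn))
    loc <- sample(names(spec$locationProbs), n, replace = TRUE,
                  prob = spec$locationProbs)
    base <- rnorm(n, spec$baseHu, spec$baseHuSd)
    txSd <- ifelse(isLac, spec$textureSd[["lac"]], spec$textureSd[["lgn"]])
    txSeed <- sample.int(.Machine$integer.max - 1L, n)
    clinical <- data.frame(
      patient_id = sprintf("P%05d", seq_len(n)), cohort = cohort,
      label = ifelse(isLac, "LAC", "LGN"),
      gender = ifelse(men == 1L, "men", "women"),
      age = age, nodule_size = sz, location = loc,
      margin = ifelse(irr == 1L, "irregular", "regular"),
      lobulated = ifelse(lob > 0L, "presence", "absence"),
      spiculated = ifelse(spic > 0L, "presence", "absence"),
      stringsAsFactors = FALSE)
    patches <- NULL
    if (images) {
      w <- lungWindow()
      px <- vector("list", n)
      for (i in seq_len(n)) {
        p <- noduleParams(sz[i], lob[i], spic[i], base[i], txSeed[i],
                          textureSd = txSd[i],
                          marginRoughness = if (irr[i] == 1L) 0.3 else 0)
        px[[i]] <- applyWindow(renderNodule(p, size = spec$size), w)
      }
      patches <- newCtPatchSet(px, data.frame(
        patient_id = clinical$patient_id, cohort = cohort, label = lab,
        provenance = "synthetic-renderer", stringsAsFactors = FALSE), window = w)
    }
    list(patches = patches, clinical = clinical)
  })
}

#' Synthetic source-domain specification
#'
#' Emulates candidate pretraining domains (histology-tile-like, natural-
#' image-like, CT-nodule-like textures) whose distributional similarity to
#' the target patches is controlled by `targetOverlap`: each image is the
#' convex pixel blend `overlap * targetStyle + (1 - overlap) * kindStyle`,
#' so `targetOverlap = 1` draws from the same renderer family as target
#' patches and 0 is a fully independent generator.
#'
#' @param kind one of `"wsi_like"`, `"natural_like"`, `"ct_like"`.
#' @param nClasses number of classes (>= 2).
#' @param n number of images (>= nClasses); classes are balanced exactly.
#' @param targetOverlap similarity dial in `[0, 1]`.
#' @param size image side in pixels.
#' @param seed integer seed.
#' @export
sourceDomainSpec <- function(kind, nClasses = 2L, n = 100L, targetOverlap = 0.5,
                             size = 224L, seed = 1L) {
  kind <- as.character(kind)
  if (!kind %in% c("wsi_like", "natural_like", "ct_like"))
    stopParam("unknown source-domain kind: ", kind)
  if (nClasses < 2L) stopParam("nClasses must be >= 2")
  if (n < nClasses) stopParam("n must be >= nClasses")
  if (targetOverlap < 0 || targetOverlap > 1)
    stopParam("targetOverlap must be in [0, 1]")
  structure(list(kind = kind, nClasses = as.integer(nClasses), n = as.integer(n),
                 targetOverlap = targetOverlap, size = as.integer(size),
                 seed = as.integer(seed)), class = "SourceDomainSpec")
}

kindStyleImage <- function(kind, classFrac, size, fovMm = 50) {
  g <- renderGrid(size, fovMm)
  x <- g$x; y <- g$y
  if (kind == "wsi_like") {
    # blobby cellular texture from thresholded band-limited noise
    s <- matrix(0, size, size)
    f0 <- 0.5 + 0.7 * classFrac
    for (k in 1:6) {
      w <- runif(2, 0.6 * f0, 1.6 * f0)
      s <- s + sin(w[1L] * x + w[2L] * y + runif(1, 0, 2 * pi))
    }
    plogis((s - 0.8 + 0.6 * classFrac) / 0.4)
  } else if (kind == "natural_like") {
    om <- 0.25 + 1.2 * classFrac
    phi <- runif(1, 0, pi)
    g <- 0.5 + 0.5 * sin(om * (x * cos(phi) + y * sin(phi)) + runif(1, 0, 2 * pi))
    grad <- (x - min(x)) / (max(x) - min(x))
    pmin(pmax(0.7 * g + 0.3 * grad + rnorm(1, 0, 0.05), 0), 1)
  } else { # ct_like: concentric ring phantom
    r <- sqrt(x^2 + y^2)
    p <- 3 + 6 * classFrac
    v <- 0.5 + 0.35 * sin(2 * pi * r / p + runif(1, 0, 2 * pi))
    pmin(pmax(v + rnorm(length(v), 0, 0.03), 0), 1)
  }
}

#' Generate a labeled synthetic source domain
#'
#' @param spec a [sourceDomainSpec()].
#' @return a [CtPatchSet-class] whose labels are class codes
#'   `0 .. nClasses-1`, balanced exactly.
#' @export
generateSourceDomain <- function(spec) {
  stopifnot(inherits(spec, "SourceDomainSpec"))
  withSeed(spec$seed, {
    K <- spec$nClasses
    sizes <- rep(spec$n %/% K, K)
    extra <- spec$n - sum(sizes)
    if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    labels <- rep(seq_len(K) - 1L, times = sizes)
    w <- lungWindow()
    px <- vector("list", spec$n)
    for (i in seq_len(spec$n)) {
      cf <- if (K > 1L) labels[i] / (K - 1L) else 0
      tgt <- 0
      if (spec$targetOverlap > 0) {
        p <- noduleParams(diameterMm = 7 + 16 * cf,
                          lobulationCount = rpois(1L, 2.2 * cf),
                          spiculeCount = rpois(1L, 0.9 * cf),
                          baseIntensity = rnorm(1, 32, 8),
                          textureSeed = sample.int(.Machine$integer.max - 1L, 1L),
                          textureSd = 16 + 18 * cf,
                          marginRoughness = 0.3 * cf)
        tgt <- applyWindow(renderNodule(p, size = spec$size), w)
      }
      sty <- if (spec$targetOverlap < 1)
        kindStyleImage(spec$kind, cf, spec$size) else 0
      px[[i]] <- spec$targetOverlap * tgt + (1 - spec$targetOverlap) * sty
    }
    newCtPatchSet(px, data.frame(
      patient_id = sprintf("S%05d", seq_len(spec$n)),
      cohort = paste0("source:", spec$kind), label = labels,
      provenance = sprintf("synthetic-source overlap=%.2f", spec$targetOverlap),
      stringsAsFactors = FALSE), window = w)
  })
}
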