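# End-to-end orchestration: fixtures -> pretrain -> transfer-train ->
# features -> TLS -> fusion -> evaluation -> source ranking, from a single
# validated config, with per-stage caching and a hash manifest.

#' Default desk-scale run configuration
#'
#' One nested list drives the whole experiment. The three synthetic source
#' domains emulate the usual candidate pretraining corpora
#' (histology-tile-like, natural-image-like and CT-like) with target
#' overlaps 1.0 / 0.5 / 0.0, so the histology-like domain is the most
#' target-similar.
#'
#' @param seed global integer seed.
#' @return nested configuration list.
#' @export
defaultRunConfig <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    cohort = list(n = 300L, prevalenceLac = 411 / 573, size = 224L,
                  trainFraction = 0.5),
    sources = list(
      lw = list(kind = "wsi_like", targetOverlap = 1.0, n = 300L, nClasses = 4L),
      imagenet = list(kind = "natural_like", targetOverlap = 0.5, n = 300L,
                      nClasses = 4L),
      lidc = list(kind = "ct_like", targetOverlap = 0.0, n = 300L, nClasses = 4L)),
    network = list(stageChannels = c(64L, 128L, 256L, 512L, 1024L, 1920L),
                   declaredFeatureWidth = 3904L, widthScale = 0.25,
                   inputSize = 224L, stemPool = 4L, epochs = 15L,
                   pretrainEpochs = 3L, batchSize = 32L, lr = 1e-3),
    transfer = list(lambda = 0.1, adaptGates = TRUE, metaLr = 1),
    signature = list(alpha = 0.05, pruneThreshold = 1e4, tol = 1e-4,
                     maxIter = 200L),
    fusion = list(sparsityEps = 1e-3),
    similarity = list(nProjections = 64L, stage = 5L),
    evaluation = list(hlGroups = 10L))
}

#' Validate a run configuration
#'
#' Schema and cross-field checks; in particular the declared feature width
#' must equal the stage-channel sum and the constraint weight must be
#' non-negative.
#'
#' @param config a configuration list (see [defaultRunConfig()]).
#' @return `list(valid = logical, errors = character)`.
#' @export
validateConfig <- function(config) {
  errs <- character()
  need <- c("seed", "cohort", "sources", "network", "transfer", "signature",
            "fusion", "similarity", "evaluation")
  miss <- setdiff(need, names(config))
  if (length(miss)) errs <- c(errs, paste("missing sections:", paste(miss, collapse = ", ")))
  nw <- config$network
  if (!is.null(nw)) {
    if (!is.null(nw$stageChannels) && !is.null(nw$declaredFeatureWidth) &&
        sum(nw$stageChannels) != nw$declaredFeatureWidth)
      errs <- c(errs, sprintf("stage channels sum to %d but declared feature width is %d",
                              sum(nw$stageChannels), nw$declaredFeatureWidth))
    if (!is.null(nw$widthScale) && nw$widthScale <= 0)
      errs <- c(errs, "widthScale must be positive")
  }
  if (!is.null(config$transfer$lambda) && config$transfer$lambda < 0)
    errs <- c(errs, "constraint weight lambda must be >= 0")
  ch <- config$cohort
  if (!is.null(ch)) {
    if (!is.null(ch$prevalenceLac) &&
        (ch$prevalenceLac <= 0 || ch$prevalenceLac >= 1))
      errs <- c(errs, "prevalenceLac must be in (0, 1)")
    if (!is.null(ch$trainFraction) &&
        (ch$trainFraction <= 0 || ch$trainFraction >= 1))
      errs <- c(errs, "trainFraction must be in (0, 1)")
  }
  for (nm in names(config$sources)) {
    s <- config$sources[[nm]]
    if (!s$kind %in% c("wsi_like", "natural_like", "ct_like"))
      errs <- c(errs, paste0("source '", nm, "': unknown kind ", s$kind))
    if (s$targetOverlap < 0 || s$targetOverlap > 1)
      errs <- c(errs, paste0("source '", nm, "': targetOverlap outside [0, 1]"))
  }
  list(valid = length(errs) == 0L, errors = errs)
}

#' Load a run configuration from YAML
#'
#' Keys present in the file override [defaultRunConfig()] defaults.
#'
#' @param path YAML file.
#' @return configuration list.
#' @export
loadRunConfig <- function(path) {
  usr <- yaml::read_yaml(path)
  utils::modifyList(defaultRunConfig(if (is.null(usr$seed)) 1L else usr$seed), usr)
}

splitCohort <- function(clinical, patches, fraction, seed) {
  withSeed(seed, {
    ids <- clinical$patient_id
    nTr <- round(length(ids) * fraction)
    tr <- sort(sample.int(length(ids), nTr))
    list(trainIdx = tr, valIdx = setdiff(seq_along(ids), tr))
  })
}

#' Run the full pipeline from a configuration
#'
#' Executes fixtures, preprocessing, source pretraining, constrained target
#' training (plus the non-transfer baseline), feature extraction, TLS,
#' source ranking, TLRM and clinical fusion, and evaluation in dependency
#' order. Stage results are cached in `outDir/cache` keyed by a hash of the
#' stage inputs; a manifest of output-file hashes, seed and timings is
#' written alongside the reports. With no configured sources (or
#' `lambda = 0` and no source) the signature outputs are labelled
#' `Non-TLS`.
#'
#' @param config validated configuration list.
#' @param outDir output directory (created if needed); `NULL` skips all
#'   file output.
#' @return invisible list with reports, comparisons, ranking, models,
#'   scores, histories and the manifest.
#' @export
runPipeline <- function(config = defaultRunConfig(), outDir = NULL) {
  chk <- validateConfig(config)
  if (!chk$valid)
    stop(errorCondition(paste("invalid config:", paste(chk$errors, collapse = "; ")),
                        class = c("tlrConfigError", "error")))
  cache <- NULL
  if (!is.null(outDir)) {
    dir.create(file.path(outDir, "cache"), recursive = TRUE, showWarnings = FALSE)
    cache <- file.path(outDir, "cache")
  }
  t0 <- Sys.time()
  timings <- list()
  stage <- function(name, inputs, fn) {
    key <- objHash(list(name, inputs))
    f <- if (!is.null(cache)) file.path(cache, paste0(name, "-", key, ".rds")) else NULL
    tic <- Sys.time()
    out <- if (!is.null(f) && file.exists(f)) readRDS(f) else {
      r <- tryCatch(fn(), error = function(e)
        stop(errorCondition(paste0("stage '", name, "' failed: ", conditionMessage(e)),
                            class = c("tlrStageError", "error"))))
      if (!is.null(f)) saveRDS(r, f, version = 3L)
      r
    }
    timings[[name]] <<- as.numeric(difftime(Sys.time(), tic, units = "secs"))
    out
  }
  seed <- config$seed

  cohort <- stage("simulate", config[c("seed", "cohort")], function() {
    spec <- cohortSpec(n = config$cohort$n,
                       prevalenceLac = config$cohort$prevalenceLac,
                       size = config$cohort$size, seed = seed)
    generateTargetCohort(spec)
  })
  sp <- splitCohort(cohort$clinical, cohort$patches,
                    config$cohort$trainFraction, seed + 1L)
  trainPatch <- cohort$patches[sp$trainIdx]
  valPatch <- cohort$patches[sp$valIdx]
  trainClin <- cohort$clinical[sp$trainIdx, ]
  valClin <- cohort$clinical[sp$valIdx, ]
  yTr <- patchLabels(trainPatch)
  yVa <- patchLabels(valPatch)

  nw <- config$network
  cfg <- networkConfig(stageChannels = nw$stageChannels,
                       inputSize = nw$inputSize, stemPool = nw$stemPool,
                       widthScale = nw$widthScale, epochs = nw$epochs,
                       batchSize = nw$batchSize, lr = nw$lr)
  # apply the fixed pooling stem once; every training/extraction pass below
  # reuses the pooled arrays
  trainData <- list(x = poolInputsCfg(cfg, 3L, trainPatch), y = yTr,
                    id = trainClin$patient_id)
  valData <- list(x = poolInputsCfg(cfg, 3L, valPatch), y = yVa,
                  id = valClin$patient_id)

  sourceSets <- stage("sources", config[c("seed", "sources", "cohort")], function() {
    lapply(seq_along(config$sources), function(i) {
      s <- config$sources[[i]]
      generateSourceDomain(sourceDomainSpec(
        kind = s$kind, nClasses = s$nClasses, n = s$n,
        targetOverlap = s$targetOverlap, size = config$cohort$size,
        seed = seed + 10L + i))
    })
  })
  names(sourceSets) <- names(config$sources)
  sourcePooled <- lapply(sourceSets, function(s)
    list(x = poolInputsCfg(cfg, 3L, s), y = patchLabels(s),
         id = patchPheno(s)$patient_id))

  peEpochs <- if (is.null(nw$pretrainEpochs)) cfg@train$epochs else nw$pretrainEpochs
  sourceNets <- stage("pretrain", list(config, "pretrain"), function()
    lapply(seq_along(sourcePooled), function(i)
      pretrainSource(sourcePooled[[i]], cfg, seed = seed + 20L + i,
                     epochs = peEpochs)$net))
  names(sourceNets) <- names(sourceSets)

  lambda <- config$transfer$lambda
  useTransfer <- length(sourceNets) > 0L && lambda > 0
  histories <- list()

  nt <- stage("nontransfer", list(config, "nontransfer"), function()
    trainNontransfer(trainData, valData, cfg, seed = seed + 30L))
  histories[["Non-TLS"]] <- nt$history

  targetNets <- list()
  if (useTransfer) {
    targetNets <- stage("transfer", list(config, "transfer"), function()
      lapply(seq_along(sourceNets), function(i)
        trainTargetWithTransfer(trainData, valData, sourceNets[[i]],
                                lambda = lambda, seed = seed + 30L,
                                adaptGates = config$transfer$adaptGates,
                                metaLr = config$transfer$metaLr)))
    names(targetNets) <- names(sourceNets)
    for (nm in names(targetNets))
      histories[[paste0("TLS-", nm)]] <- targetNets[[nm]]$history
  }

  sig <- config$signature
  fitSig <- function(net) {
    feTr <- featureMatrix(extractFeatures(net, trainData$x))
    feVa <- featureMatrix(extractFeatures(net, valData$x))
    tls <- buildTls(feTr, yTr, alpha = sig$alpha,
                    pruneThreshold = sig$pruneThreshold, tol = sig$tol,
                    maxIter = sig$maxIter)
    list(model = tls$model,
         train = tlsScore(tls$model, feTr), val = tlsScore(tls$model, feVa))
  }
  sigs <- stage("tls", list(config, "tls"), function() {
    out <- list(`Non-TLS` = fitSig(nt$net))
    for (nm in names(targetNets))
      out[[paste0("TLS-", nm)]] <- fitSig(targetNets[[nm]]$net)
    out
  })

  ranking <- NULL
  if (length(sourceNets) >= 2L) {
    # one shared frozen embedder (the target-trained network's penultimate
    # stage) so source distances are computed in a common feature space
    ranking <- stage("rank", list(config, "rank"), function() {
      simCfg <- config$similarity
      embs <- lapply(names(sourceSets), function(nm)
        embedDomain(nt$net, sourcePooled[[nm]]$x, stage = simCfg$stage,
                    domain = nm))
      names(embs) <- names(sourceSets)
      rankSources(embs,
                  embedDomain(nt$net, trainData$x, stage = simCfg$stage,
                              domain = "target"),
                  nProjections = simCfg$nProjections, seed = seed + 40L)
    })
  }

  bestName <- if (useTransfer) {
    if (!is.null(ranking)) paste0("TLS-", ranking$source[1L])
    else paste0("TLS-", names(targetNets)[1L])
  } else "Non-TLS"
  bestSig <- sigs[[bestName]]

  screen <- univariateScreen(trainClin)
  sigVars <- intersect(screen$variable[screen$significant],
                       c("gender", "age", "nodule_size", "location", "margin",
                         "lobulated", "spiculated"))
  trainClin$tls <- bestSig$train
  valClin$tls <- bestSig$val
  tlrm <- fitSparseBayesLasso(trainClin, candidates = c(sigVars, "tls"),
                              sparsityEps = config$fusion$sparsityEps)
  clinical <- fitClinicalLogistic(trainClin)

  scores <- list()
  for (nm in names(sigs))
    scores[[nm]] <- list(train = sigs[[nm]]$train, val = sigs[[nm]]$val)
  scores[["TLRM"]] <- list(train = tlrmScore(tlrm, trainClin),
                           val = tlrmScore(tlrm, valClin))
  scores[["Clinical"]] <- list(train = clinicalScore(clinical, trainClin),
                               val = clinicalScore(clinical, valClin))

  reports <- do.call(rbind, lapply(names(scores), function(nm) {
    thr <- youdenThreshold(scores[[nm]]$train, yTr)
    rbind(cbind(model = nm, evalReport(scores[[nm]]$train, yTr, thr, "training")),
          cbind(model = nm, evalReport(scores[[nm]]$val, yVa, thr, "validation")))
  }))

  cmp <- list()
  if (bestName != "Non-TLS") {
    cmp$tlsVsNonTls <- c(delongTest(scores[[bestName]]$val, scores[["Non-TLS"]]$val, yVa),
                         idi = idi(scores[["Non-TLS"]]$val, scores[[bestName]]$val, yVa)$idi)
  }
  cmp$tlrmVsClinical <- c(delongTest(scores[["TLRM"]]$val, scores[["Clinical"]]$val, yVa),
                          idi = idi(scores[["Clinical"]]$val, scores[["TLRM"]]$val, yVa)$idi)
  cmp$tlrmVsBestTls <- c(delongTest(scores[["TLRM"]]$val, scores[[bestName]]$val, yVa),
                         idi = idi(scores[[bestName]]$val, scores[["TLRM"]]$val, yVa)$idi)
  hl <- hosmerLemeshow(scores[["TLRM"]]$val, yVa, g = config$evaluation$hlGroups)
  dca <- decisionCurve(scores[["TLRM"]]$val, yVa)
  strat <- stratifiedAnalysis(scores[["TLRM"]]$val, yVa, valClin$gender)

  manifest <- list(seed = seed, config = config,
                   package = as.character(utils::packageVersion("noduleTLR")),
                   started = format(t0), timings = timings, files = list())
  result <- list(reports = reports, comparisons = cmp, ranking = ranking,
                 hosmerLemeshow = hl[c("chisq", "df", "p")],
                 decisionCurve = dca, stratified = strat,
                 models = list(tlrm = tlrm, clinical = clinical,
                               tls = bestSig$model, bestSignature = bestName),
                 scores = scores, screen = screen, histories = histories,
                 labels = list(train = yTr, val = yVa),
                 clinical = list(train = trainClin, val = valClin),
                 manifest = manifest)

  if (!is.null(outDir)) {
    wf <- function(obj, file, writer) {
      p <- file.path(outDir, file)
      writer(obj, p)
      manifest$files[[file]] <<- unname(tools::md5sum(p))
    }
    wcsv <- function(o, p) write.csv(o, p, row.names = FALSE)
    wjson <- function(o, p) jsonlite::write_json(o, p, digits = NA,
                                                 auto_unbox = TRUE, force = TRUE)
    wf(rbind(trainClin, valClin), "cohort.csv", wcsv)
    wf(reports, "evaluation.csv", wcsv)
    wf(screen, "screening.csv", wcsv)
    wf(dca, "decision_curve.csv", wcsv)
    if (!is.null(ranking)) wf(ranking, "source_ranking.csv", wcsv)
    wf(cmp, "comparisons.json", wjson)
    wf(list(terms = tlrm@terms, coefficients = tlrm@coefficients,
            intercept = tlrm@intercept, priorScale = tlrm@priorScale),
       "tlrm.json", wjson)
    writeSbelm(bestSig$model, file.path(outDir, "tls_model.json"))
    manifest$files[["tls_model.json"]] <-
      unname(tools::md5sum(file.path(outDir, "tls_model.json")))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         digits = NA, auto_unbox = TRUE, force = TRUE)
    result$manifest <- manifest
  }
  invisible(result)
}
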