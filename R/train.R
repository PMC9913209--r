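# Training: cross-entropy task loss, optional meta-gated source-feature
# matching constraint, Adam optimiser, first-order validation-driven meta
# updates. All loops are deterministic given the seed.

softmaxRows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

adamInit <- function(params) {
  list(m = rapply(params, function(p) p * 0, how = "replace"),
       v = rapply(params, function(p) p * 0, how = "replace"), t = 0L)
}

adamStep <- function(params, grads, st, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  if (length(lr) == 1L) lr <- rep(lr, length(params))
  for (i in seq_along(params)) {
    for (nm in names(params[[i]])) {
      u <- cppAdamUpdate(params[[i]][[nm]], grads[[i]][[nm]],
                         st$m[[i]][[nm]], st$v[[i]][[nm]],
                         lr[i], b1, b2, eps, st$t)
      params[[i]][[nm]] <- u$p
      st$m[[i]][[nm]] <- u$m
      st$v[[i]][[nm]] <- u$v
    }
  }
  list(params = params, st = st)
}

#' Create a fresh meta-selection state
#'
#' Gates start at exactly 0.5 (all meta-parameters zero) and matching maps
#' at identity.
#'
#' @param channels integer vector of per-stage channel counts (use
#'   `scaledChannels(cfg)`).
#' @param lambda constraint weight (>= 0).
#' @param utilityRef reference utility: per-channel source features whose
#'   validation usefulness `|2 AUC - 1|` exceeds this level see their gates
#'   pushed up, others down. Default 0.2, just above the small-sample noise
#'   floor of the utility statistic.
#' @return a [MetaSelectionState-class].
#' @export
newMetaState <- function(channels, lambda = 1, utilityRef = 0.2) {
  z <- lapply(channels, numeric)
  new("MetaSelectionState", gateLogits = z, gateSlope = z,
      matchScale = lapply(channels, function(C) rep(1, C)),
      matchShift = z, lambda = lambda, utilityRef = utilityRef)
}

#' Per-stage selection gates of meta-network A
#'
#' `g_c = sigmoid(logit_c + slope_c * mean pooled source activation_c)`;
#' sigmoid-bounded and differentiable in the meta-parameters.
#'
#' @param state a [MetaSelectionState-class].
#' @param sourceStageFeatures list of per-stage pooled source features
#'   (n x channels matrices).
#' @return list of per-stage gate vectors in `[0, 1]`.
#' @export
selectionGates <- function(state, sourceStageFeatures) {
  stopifnot(is(state, "MetaSelectionState"))
  lapply(seq_along(sourceStageFeatures), function(s) {
    f <- sourceStageFeatures[[s]]
    if (!is.matrix(f)) f <- matrix(f, 1L)
    if (ncol(f) != length(state@gateLogits[[s]]))
      stopShape("stage ", s, ": feature channels do not match gate parameters")
    plogis(state@gateLogits[[s]] + state@gateSlope[[s]] * colMeans(f))
  })
}

perChannelMSD <- function(tf, sf, m, b) {
  if (is.matrix(tf)) {
    colMeans((sweep(sweep(tf, 2L, m, "*"), 2L, b, "+") - sf)^2)
  } else {
    d <- dim(tf)
    md <- sweep(sweep(tf, 3L, m, "*"), 3L, b, "+") - sf
    apply(md^2, 3L, mean)
  }
}

#' Gated source-feature matching constraint loss
#'
#' `lambda * sum_stages sum_c g_c * msd_c / n_channels`, where `msd_c` is the
#' mean squared difference between the matched target feature and the source
#' feature of channel `c` over all samples and pixels. Zero iff `lambda = 0`,
#' all gates are 0, or matched features equal source features.
#'
#' @param targetFeats,sourceFeats per-stage lists of pooled feature matrices
#'   (n x channels) or activation arrays (H x W x C x N).
#' @param state a [MetaSelectionState-class].
#' @return scalar `>= 0`.
#' @export
transferConstraintLoss <- function(targetFeats, sourceFeats, state) {
  if (state@lambda == 0) return(0)
  gates <- selectionGates(state, sourceFeats)
  tot <- 0
  for (s in seq_along(targetFeats)) {
    tf <- targetFeats[[s]]; sf <- sourceFeats[[s]]
    if (!all(is.finite(tf)) || !all(is.finite(sf)))
      stop(errorCondition("non-finite features in constraint",
                          class = c("tlrNumericError", "error")))
    msd <- perChannelMSD(tf, sf, state@matchScale[[s]], state@matchShift[[s]])
    tot <- tot + sum(gates[[s]] * msd) / length(msd)
  }
  state@lambda * tot
}

#' Validation-driven gate update (meta-network A)
#'
#' First-order rule: the usefulness of source channel `c` is
#' `u_c = |2 AUC(s_c, y) - 1|` of its frozen pooled source feature on the
#' validation labels; gate logits move by `metaLr * (u_c - utilityRef)`, so
#' channels no more useful than noise are down-weighted and predictive
#' channels are emphasised.
#'
#' @param state a [MetaSelectionState-class].
#' @param sourceVal per-stage list of pooled source features on the
#'   validation set (n x channels).
#' @param y binary validation labels.
#' @param metaLr meta learning rate.
#' @return the updated state.
#' @export
updateGates <- function(state, sourceVal, y, metaLr = 1) {
  for (s in seq_along(sourceVal)) {
    f <- sourceVal[[s]]
    u <- apply(f, 2L, function(v) {
      if (sd(v) < 1e-12) 0 else abs(2 * auc(v, y) - 1)
    })
    zc <- colMeans(f)
    zs <- sd(zc); if (!is.finite(zs) || zs < 1e-12) zs <- 1
    state@gateLogits[[s]] <- state@gateLogits[[s]] + metaLr * (u - state@utilityRef)
    state@gateSlope[[s]] <- state@gateSlope[[s]] +
      0.1 * metaLr * (u - state@utilityRef) * (zc - mean(zc)) / zs
  }
  state
}

# least-squares per-channel affine matching maps (meta-network B), moved a
# damped step towards the LS solution: a full refit every epoch would let
# the matching absorb all feature drift and null the constraint
updateMatching <- function(state, targetPooled, sourcePooled, rate = 0.2) {
  if (rate <= 0) return(state)
  for (s in seq_along(targetPooled)) {
    tp <- targetPooled[[s]]; sp <- sourcePooled[[s]]
    vt <- apply(tp, 2L, var); vt[!is.finite(vt)] <- 0
    cv <- vapply(seq_len(ncol(tp)), function(c)
      mean((tp[, c] - mean(tp[, c])) * (sp[, c] - mean(sp[, c]))), numeric(1L))
    m <- cv / (vt + 1e-8)
    b <- colMeans(sp) - m * colMeans(tp)
    state@matchScale[[s]] <- (1 - rate) * state@matchScale[[s]] + rate * m
    state@matchShift[[s]] <- (1 - rate) * state@matchShift[[s]] + rate * b
  }
  state
}

asTrainData <- function(d) {
  if (is(d, "CtPatchSet"))
    return(list(x = d, y = patchLabels(d), id = patchPheno(d)$patient_id))
  stopifnot(is.list(d), !is.null(d$x), !is.null(d$y))
  if (is.null(d$id)) d$id <- sprintf("anon%05d", seq_along(d$y))
  d
}

# shared training engine
trainCore <- function(net, train, val, epochs, lambda = 0, sourceNet = NULL,
                      state = NULL, adaptGates = TRUE, seed = 1L,
                      metaLr = 1, matchRate = 0.2, backboneLrMult = 1) {
  cfg <- net@config
  bs <- cfg@train$batchSize
  lr <- c(rep(cfg@train$lr * backboneLrMult, length(net@weights)), cfg@train$lr)
  y <- as.integer(train$y)
  classes <- sort(unique(y))
  nS <- length(net@weights)
  xPool <- prePoolInputs(net, train$x)
  valPool <- if (!is.null(val)) prePoolInputs(net, val$x) else NULL
  srcTrain <- srcVal <- NULL
  if (!is.null(sourceNet)) {
    srcTrain <- netForward(sourceNet, xPool, stemDone = TRUE)$pooled
    if (!is.null(val)) srcVal <- netForward(sourceNet, valPool, stemDone = TRUE)$pooled
  }
  params <- c(net@weights, list(head = net@head))
  hist <- data.frame(epoch = integer(), taskLoss = numeric(),
                     constraintLoss = numeric(), valAuc = numeric())
  withSeed(seed, {
    opt <- adamInit(params)
    n <- length(y)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / bs))
      epTask <- epCon <- 0
      accPooled <- NULL
      for (bi in batches) {
        xB <- xPool[, , , bi, drop = FALSE]
        yB <- y[bi]
        B <- length(bi)
        fw <- netForward(net, xB, keepActs = TRUE, stemDone = TRUE)
        pr <- softmaxRows(fw$logits)
        yc <- match(yB, classes)
        taskLossB <- -mean(log(pmax(pr[cbind(seq_len(B), yc)], 1e-12)))
        dlog <- pr
        dlog[cbind(seq_len(B), yc)] <- dlog[cbind(seq_len(B), yc)] - 1
        dlog <- dlog / B
        pooledL <- fw$pooled[[nS]]
        gHead <- list(W = crossprod(pooledL, dlog), b = colSums(dlog))
        dPooled <- vector("list", nS)
        dPooled[[nS]] <- dlog %*% t(net@head$W)
        conLossB <- 0
        if (lambda > 0 && !is.null(sourceNet)) {
          gates <- selectionGates(state, lapply(srcTrain, function(m) m[bi, , drop = FALSE]))
          for (s in seq_len(nS)) {
            tfs <- fw$pooled[[s]]
            sfs <- srcTrain[[s]][bi, , drop = FALSE]
            m <- state@matchScale[[s]]; b0 <- state@matchShift[[s]]
            diff <- sweep(sweep(tfs, 2L, m, "*"), 2L, b0, "+") - sfs
            C <- ncol(tfs)
            conLossB <- conLossB + lambda * sum(gates[[s]] * colMeans(diff^2)) / C
            gC <- lambda * 2 * sweep(diff, 2L, gates[[s]] * m, "*") / (C * B)
            dPooled[[s]] <- if (is.null(dPooled[[s]])) gC else dPooled[[s]] + gC
          }
        }
        grads <- vector("list", nS + 1L)
        names(grads) <- names(params)
        grads[[nS + 1L]] <- gHead
        dzNext <- NULL
        for (s in nS:1) {
          d <- dim(fw$acts[[s]])
          da <- if (is.null(dzNext)) array(0, d) else dzNext
          if (!is.null(dPooled[[s]])) {
            hw <- d[1L] * d[2L]
            da <- da + array(rep(t(dPooled[[s]]) / hw, each = hw), dim = d)
          }
          da[fw$acts[[s]] <= 0] <- 0
          below <- if (s > 1L) fw$acts[[s - 1L]] else fw$stemOut
          bk <- cppConvBackward(below, da, params[[s]]$W, cfg@kernel, cfg@stride, 1L)
          grads[[s]] <- list(W = bk$dW, b = bk$db)
          dzNext <- bk$dx
        }
        up <- adamStep(params, grads, opt, lr)
        params <- up$params
        opt <- up$st
        net@weights <- params[seq_len(nS)]
        net@head <- params$head
        epTask <- epTask + taskLossB * B / n
        epCon <- epCon + conLossB * B / n
        accPooled <- if (is.null(accPooled)) lapply(fw$pooled, function(p) p) else
          Map(rbind, accPooled, fw$pooled)
      }
      vAuc <- NA_real_
      if (!is.null(val) && length(classes) == 2L) {
        pv <- softmaxRows(netForward(net, valPool, stemDone = TRUE)$logits)[, 2L]
        vAuc <- auc(pv, as.integer(val$y))
      }
      hist <- rbind(hist, data.frame(epoch = ep, taskLoss = epTask,
                                     constraintLoss = epCon, valAuc = vAuc))
      if (!is.null(sourceNet) && lambda > 0) {
        if (adaptGates && !is.null(srcVal) && length(classes) == 2L)
          state <- updateGates(state, srcVal, as.integer(val$y), metaLr)
        state <- updateMatching(state, accPooled,
                                lapply(seq_len(nS), function(s)
                                  srcTrain[[s]][unlist(batches), , drop = FALSE]),
                                rate = matchRate)
      }
    }
  })
  attr(hist, "seed") <- as.integer(seed)
  attr(hist, "config") <- cfg
  list(net = net, state = state, history = hist)
}

checkDisjoint <- function(train, val) {
  if (is.null(val)) return(invisible(TRUE))
  ov <- intersect(train$id, val$id)
  if (length(ov))
    stop(errorCondition(paste("train/validation patients overlap:",
                              paste(head(ov, 3L), collapse = ", ")),
                        class = c("tlrLeakageError", "error")))
  invisible(TRUE)
}

#' Pretrain the source network
#'
#' Trains the backbone plus head on labelled source-domain images with
#' cross-entropy to construct the intermediate feature space used by the
#' transfer constraint.
#'
#' @param images a [CtPatchSet-class] (labels in metadata) or
#'   `list(x = array, y = labels)`.
#' @param cfg a [NetworkConfig-class].
#' @param seed integer seed (weight init + batch order).
#' @param epochs training epochs; 0 returns the initialisation unchanged.
#' @return `list(net, history)`.
#' @export
pretrainSource <- function(images, cfg, seed = 1L, epochs = cfg@train$epochs) {
  d <- asTrainData(images)
  tab <- table(d$y)
  if (length(tab) < 2L) stopData("source data must contain >= 2 classes")
  if (any(tab < 4L)) stopData("each source class needs >= 4 images")
  net <- initNet(cfg, nClasses = length(tab), seed = seed,
                 cin = if (is(d$x, "CtPatchSet")) d$x@channels else dim(d$x)[3L])
  if (epochs == 0L) return(list(net = net, history = NULL))
  trainCore(net, d, NULL, epochs = epochs, seed = seed)[c("net", "history")]
}

#' Train the target network without transfer
#'
#' Random initialisation, cross-entropy only: the non-transfer baseline
#' (Non-TLS) feature extractor.
#'
#' @param train,val training and validation data ([CtPatchSet-class] or
#'   `list(x, y, id)`); patients must be disjoint.
#' @param cfg a [NetworkConfig-class].
#' @param seed integer seed.
#' @param epochs training epochs.
#' @return `list(net, history)`.
#' @export
trainNontransfer <- function(train, val, cfg, seed = 1L, epochs = cfg@train$epochs) {
  tr <- asTrainData(train)
  vl <- if (is.null(val)) NULL else asTrainData(val)
  checkDisjoint(tr, vl)
  net <- initNet(cfg, nClasses = cfg@nTargetClasses, seed = seed,
                 cin = if (is(tr$x, "CtPatchSet")) tr$x@channels else dim(tr$x)[3L])
  trainCore(net, tr, vl, epochs = epochs, seed = seed)[c("net", "history")]
}

#' Train the target network under the adaptive transfer constraint
#'
#' Alternating optimisation: target weights minimise cross-entropy plus the
#' gated source-feature matching constraint on the training cohort; after
#' each epoch the meta-networks are updated first-order from the validation
#' cohort ([updateGates()]) and matching maps are refit by least squares.
#' By default the target network is initialised from the source weights
#' (pretraining with fine-tuning); set `initFromSource = FALSE` for a random
#' start, in which case `lambda = 0` with frozen gates reproduces
#' [trainNontransfer()] exactly.
#'
#' @param train,val target-cohort data; patient ids must be disjoint.
#' @param sourceNet the pretrained [ConvNet-class].
#' @param lambda constraint weight, `>= 0`.
#' @param seed integer seed.
#' @param epochs training epochs.
#' @param adaptGates update gates from validation data (FALSE freezes them
#'   at 0.5).
#' @param initFromSource initialise target weights from the source network.
#' @param metaLr meta-network learning rate.
#' @param matchRate damped step size of the matching-map (meta-network B)
#'   update towards its least-squares solution; 0 freezes identity maps.
#' @param backboneLrMult learning-rate multiplier for the convolution stages
#'   during fine-tuning (standard discounted-rate fine-tuning; applied only
#'   when `initFromSource = TRUE`).
#' @return `list(net, state, history)`.
#' @export
trainTargetWithTransfer <- function(train, val, sourceNet, lambda = 0.1,
                                    seed = 1L, epochs = sourceNet@config@train$epochs,
                                    adaptGates = TRUE, initFromSource = TRUE,
                                    metaLr = 1, matchRate = 0.2,
                                    backboneLrMult = 0.1) {
  if (lambda < 0) stopParam("lambda must be >= 0")
  tr <- asTrainData(train)
  vl <- if (is.null(val)) NULL else asTrainData(val)
  checkDisjoint(tr, vl)
  cfg <- sourceNet@config
  net <- initNet(cfg, nClasses = cfg@nTargetClasses, seed = seed, cin = sourceNet@cin)
  if (initFromSource) net@weights <- sourceNet@weights
  state <- newMetaState(scaledChannels(cfg), lambda = lambda)
  trainCore(net, tr, vl, epochs = epochs, lambda = lambda,
            sourceNet = sourceNet, state = state, adaptGates = adaptGates,
            seed = seed, metaLr = metaLr, matchRate = matchRate,
            backboneLrMult = if (initFromSource) backboneLrMult else 1)
}
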