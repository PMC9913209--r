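# Reference backbone: fixed average-pooling stem + six 3x3 stride-2
# convolution stages; global-average-pooled stage outputs concatenate to the
# transfer-learning feature vector (3904-dim at default widths).

#' Build a network configuration
#'
#' @param stageChannels per-stage output channels at `widthScale = 1`;
#'   the default sums to 3904, the transfer-learning feature width.
#' @param inputSize input spatial size (must be divisible by `stemPool`).
#' @param stemPool fixed average-pooling stem factor.
#' @param widthScale channel multiplier for desk-scale runs (actual widths
#'   are `max(1, round(stageChannels * widthScale))`).
#' @param nSourceClasses,nTargetClasses class counts.
#' @param epochs,batchSize,lr,valAucEvery training hyper-parameters
#'   (Adam optimiser; defaults documented in the methods vignette).
#' @return a [NetworkConfig-class].
#' @export
networkConfig <- function(stageChannels = c(64L, 128L, 256L, 512L, 1024L, 1920L),
                          inputSize = 224L, stemPool = 4L, widthScale = 1,
                          nSourceClasses = 2L, nTargetClasses = 2L,
                          epochs = 8L, batchSize = 32L, lr = 1e-3,
                          valAucEvery = 1L) {
  new("NetworkConfig", stageChannels = as.integer(stageChannels),
      inputSize = as.integer(inputSize), stemPool = as.integer(stemPool),
      kernel = 3L, stride = 2L, widthScale = widthScale,
      nSourceClasses = as.integer(nSourceClasses),
      nTargetClasses = as.integer(nTargetClasses),
      train = list(epochs = as.integer(epochs), batchSize = as.integer(batchSize),
                   lr = lr, valAucEvery = as.integer(valAucEvery)))
}

#' Realised per-stage channel widths
#' @param cfg a [NetworkConfig-class].
#' @export
scaledChannels <- function(cfg) pmax(1L, as.integer(round(cfg@stageChannels * cfg@widthScale)))

#' Transfer-learning feature width of a configuration
#' @param cfg a [NetworkConfig-class].
#' @export
featureWidth <- function(cfg) sum(scaledChannels(cfg))

#' Initialise network weights
#'
#' He-normal initialisation of every convolution stage plus a zero linear
#' head, fully determined by `seed`.
#'
#' @param cfg a [NetworkConfig-class].
#' @param nClasses output classes.
#' @param seed integer seed.
#' @param cin input channels (3 for replicated CT patches).
#' @return a [ConvNet-class].
#' @export
initNet <- function(cfg, nClasses = cfg@nTargetClasses, seed = 1L, cin = 3L) {
  ch <- scaledChannels(cfg)
  k <- cfg@kernel
  withSeed(seed, {
    weights <- vector("list", length(ch))
    prev <- as.integer(cin)
    for (s in seq_along(ch)) {
      fanIn <- k * k * prev
      weights[[s]] <- list(
        W = matrix(rnorm(fanIn * ch[s], 0, sqrt(2 / fanIn)), fanIn, ch[s]),
        b = numeric(ch[s]))
      prev <- ch[s]
    }
    head <- list(W = matrix(0, ch[length(ch)], nClasses), b = numeric(nClasses))
    new("ConvNet", config = cfg, weights = weights, head = head,
        nClasses = as.integer(nClasses), cin = as.integer(cin),
        seed = as.integer(seed))
  })
}

#' @export
setMethod("show", "ConvNet", function(object) {
  ch <- scaledChannels(object@config)
  cat(sprintf("ConvNet: %d stages [%s], %d-class head, %d pooled features\n",
              length(ch), paste(ch, collapse = ","), object@nClasses, sum(ch)))
})

# forward pass; returns logits, per-stage pooled features (N x C matrices)
# and, optionally, the post-ReLU activation arrays needed for backprop
netForward <- function(net, x, keepActs = FALSE, stemDone = FALSE) {
  cfg <- net@config
  stemDone <- stemDone || isTRUE(attr(x, "stemDone"))
  if (!stemDone && (dim(x)[1L] != cfg@inputSize || dim(x)[3L] != net@cin))
    stopShape("input array does not match network configuration")
  a <- if (!stemDone && cfg@stemPool > 1L) cppAvgPool(x, cfg@stemPool) else x
  stemOut <- if (keepActs) a else NULL
  pooled <- vector("list", length(net@weights))
  acts <- if (keepActs) vector("list", length(net@weights)) else NULL
  for (s in seq_along(net@weights)) {
    z <- cppConvForward(a, net@weights[[s]]$W, net@weights[[s]]$b,
                        cfg@kernel, cfg@stride, 1L)
    z[z < 0] <- 0
    d <- dim(z)
    pooled[[s]] <- t(matrix(.colMeans(matrix(z, d[1L] * d[2L]), d[1L] * d[2L],
                                      d[3L] * d[4L]), d[3L], d[4L]))
    if (keepActs) acts[[s]] <- z
    a <- z
  }
  p <- pooled[[length(pooled)]]
  logits <- sweep(p %*% net@head$W, 2L, net@head$b, "+")
  list(logits = logits, pooled = pooled, acts = acts, stemOut = stemOut)
}

# apply the fixed average-pooling stem to a whole data set once (chunked),
# so training epochs slice the pooled array instead of re-pooling
prePoolInputs <- function(net, patches, chunk = 50L) {
  poolInputsCfg(net@config, net@cin, patches, chunk)
}

poolInputsCfg <- function(cfg, cin, patches, chunk = 50L) {
  if (isTRUE(attr(patches, "stemDone"))) return(patches)
  n <- if (is(patches, "CtPatchSet")) length(patches) else dim(patches)[4L]
  f <- cfg@stemPool
  s0 <- cfg@inputSize %/% f
  out <- array(0, c(s0, s0, cin, n))
  for (b in split(seq_len(n), ceiling(seq_len(n) / chunk))) {
    xb <- asInputArray(patches, b)
    out[, , , b] <- if (f > 1L) cppAvgPool(xb, f) else xb
  }
  attr(out, "stemDone") <- TRUE
  out
}

asInputArray <- function(patches, i = NULL) {
  if (is(patches, "CtPatchSet")) {
    if (is.null(i)) i <- seq_len(length(patches))
    patchArray(patches, i)
  } else {
    stopifnot(is.array(patches), length(dim(patches)) == 4L)
    if (is.null(i)) return(patches)
    out <- patches[, , , i, drop = FALSE]
    if (isTRUE(attr(patches, "stemDone"))) attr(out, "stemDone") <- TRUE
    out
  }
}

#' Extract transfer-learning features
#'
#' Runs patches through a trained (or initialised) network and concatenates
#' the global-average-pooled per-stage activation maps in stage order; the
#' column count equals `featureWidth(cfg)` (3904 under the default
#' configuration). Rows align with input order.
#'
#' @param net a [ConvNet-class].
#' @param patches a [CtPatchSet-class] (or `H x W x C x N` array).
#' @param batchSize forward-pass batch size.
#' @return a [SummarizedExperiment::SummarizedExperiment] with one assay
#'   `"features"` (features x patients), rowData giving the originating
#'   stage, and the patch metadata as colData.
#' @export
extractFeatures <- function(net, patches, batchSize = 32L) {
  n <- if (is(patches, "CtPatchSet")) length(patches) else dim(patches)[4L]
  ch <- scaledChannels(net@config)
  out <- matrix(NA_real_, n, sum(ch))
  idx <- split(seq_len(n), ceiling(seq_len(n) / batchSize))
  for (b in idx) {
    fw <- netForward(net, asInputArray(patches, b))
    out[b, ] <- do.call(cbind, fw$pooled)
  }
  featIds <- sprintf("tlf_s%d_c%03d", rep(seq_along(ch), ch),
                     unlist(lapply(ch, seq_len)))
  colnames(out) <- featIds
  meta <- if (is(patches, "CtPatchSet")) patchPheno(patches) else
    data.frame(patient_id = sprintf("X%05d", seq_len(n)))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(features = t(out)),
    rowData = S4Vectors::DataFrame(stage = rep(seq_along(ch), ch),
                                   channel = unlist(lapply(ch, seq_len)),
                                   row.names = featIds),
    colData = S4Vectors::DataFrame(meta, row.names = make.unique(meta$patient_id)))
}

#' Patients-by-features matrix from an extraction result
#'
#' @param x a SummarizedExperiment from [extractFeatures()] or a plain
#'   patients x features matrix (returned unchanged).
#' @export
featureMatrix <- function(x) {
  if (is.matrix(x)) return(x)
  t(SummarizedExperiment::assay(x, "features"))
}

#' Filter response heatmap
#'
#' Upsampled activation map of one convolution channel, aligned to the
#' input patch and min-max normalised to `[0, 1]` (a constant activation map
#' stays constant at 0 under the normalisation guard).
#'
#' @param net a [ConvNet-class].
#' @param patch single patch: [CtPatchSet-class] of length 1 or
#'   `H x W x C x 1` array.
#' @param channel channel index within `stage`.
#' @param stage backbone stage of the filter (default 2, a mid-level map
#'   with usable spatial resolution).
#' @return `list(heatmap = H x W matrix in [0,1], max = c(row, col))`.
#' @export
filterResponseHeatmap <- function(net, patch, channel, stage = 2L) {
  ch <- scaledChannels(net@config)
  stage <- as.integer(stage)
  if (stage < 1L || stage > length(ch)) stopParam("invalid stage index")
  if (channel < 1L || channel > ch[stage]) stopParam("invalid channel index")
  x <- asInputArray(patch)
  if (dim(x)[4L] != 1L) stopParam("heatmaps are computed per single patch")
  fw <- netForward(net, x, keepActs = TRUE)
  act <- fw$acts[[stage]][, , channel, 1L]
  rng <- range(act)
  hm <- if (diff(rng) < 1e-12) matrix(0, nrow(act), ncol(act)) else
    (act - rng[1L]) / diff(rng)
  up <- bilinearResize(hm, dim(x)[1L])
  up <- pmin(pmax(up, 0), 1)
  mx <- which(up == max(up), arr.ind = TRUE)[1L, ]
  list(heatmap = up, max = unname(mx))
}
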