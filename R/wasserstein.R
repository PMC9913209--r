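# Domain similarity: exact 1-D 1-Wasserstein distance and its sliced
# extension over random projections, plus source-domain ranking.

#' Exact 1-D 1-Wasserstein distance
#'
#' Quantile matching: for equal sizes the mean absolute difference of the
#' sorted values, otherwise the exact integral of the inverse-CDF
#' difference over the merged quantile grid.
#'
#' @param a,b non-empty numeric multisets.
#' @return distance `>= 0`.
#' @export
w1Dist <- function(a, b) {
  if (!length(a) || !length(b)) stopData("empty sample in w1Dist")
  a <- sort(a); b <- sort(b)
  n <- length(a); m <- length(b)
  if (n == m) return(mean(abs(a - b)))
  p <- sort(unique(c(seq_len(n) / n, seq_len(m) / m)))
  widths <- diff(c(0, p))
  mid <- p - widths / 2
  sum(widths * abs(a[ceiling(mid * n)] - b[ceiling(mid * m)]))
}

#' Sliced 1-Wasserstein distance between embedded domains
#'
#' Mean of [w1Dist()] over uniformly random unit-vector projections of the
#' two point clouds; symmetric, non-negative, zero on identical clouds, and
#' deterministic given the seed. Domains larger than `maxPoints` are
#' sub-sampled (seeded) to bound runtime.
#'
#' @param A,B [DomainEmbedding-class] objects or plain n x d matrices of
#'   equal dimensionality.
#' @param nProjections number of random projections (>= 1; default 256).
#' @param seed integer seed for the projections (and any sub-sampling).
#' @param maxPoints per-domain sub-sampling cap.
#' @return distance `>= 0`.
#' @export
slicedW1 <- function(A, B, nProjections = 256L, seed = 1L, maxPoints = 2000L) {
  fa <- if (is(A, "DomainEmbedding")) A@features else as.matrix(A)
  fb <- if (is(B, "DomainEmbedding")) B@features else as.matrix(B)
  if (is(A, "DomainEmbedding") && is(B, "DomainEmbedding") &&
      A@fingerprint != B@fingerprint)
    stop(errorCondition("embeddings come from different extractors",
                        class = c("tlrFingerprintError", "error")))
  if (ncol(fa) != ncol(fb)) stopShape("embedding dimensionalities differ")
  if (nProjections < 1L) stopParam("nProjections must be >= 1")
  d <- ncol(fa)
  withSeed(seed, {
    if (nrow(fa) > maxPoints) fa <- fa[sample.int(nrow(fa), maxPoints), , drop = FALSE]
    if (nrow(fb) > maxPoints) fb <- fb[sample.int(nrow(fb), maxPoints), , drop = FALSE]
    U <- matrix(rnorm(d * nProjections), d, nProjections)
    U <- sweep(U, 2L, sqrt(colSums(U^2)), "/")
    pa <- fa %*% U
    pb <- fb %*% U
    mean(vapply(seq_len(nProjections), function(j) w1Dist(pa[, j], pb[, j]),
                numeric(1L)))
  })
}

#' Embed a domain with a frozen extractor
#'
#' Pooled activations of one backbone stage (default the penultimate stage)
#' applied to every image; the extractor fingerprint ties embeddings to the
#' weights and stage that produced them.
#'
#' @param net a [ConvNet-class] (typically the pretrained source network).
#' @param images a [CtPatchSet-class] or input array.
#' @param stage backbone stage to pool (default `nStages - 1`).
#' @param domain domain tag.
#' @param batchSize forward batch size.
#' @return a [DomainEmbedding-class].
#' @export
embedDomain <- function(net, images, stage = length(net@weights) - 1L,
                        domain = "domain", batchSize = 32L) {
  n <- if (is(images, "CtPatchSet")) length(images) else dim(images)[4L]
  ch <- scaledChannels(net@config)
  out <- matrix(NA_real_, n, ch[stage])
  for (b in split(seq_len(n), ceiling(seq_len(n) / batchSize)))
    out[b, ] <- netForward(net, asInputArray(images, b))$pooled[[stage]]
  new("DomainEmbedding", features = out, domain = domain,
      fingerprint = objHash(list(net@weights, stage)))
}

#' Rank candidate source domains by similarity to the target
#'
#' Sorts sources ascending by sliced 1-Wasserstein distance to the target
#' embedding (smaller = more similar = recommended for transfer); ties are
#' broken by name.
#'
#' @param sources named list of [DomainEmbedding-class] (>= 2).
#' @param target the target-domain [DomainEmbedding-class].
#' @param nProjections,seed passed to [slicedW1()].
#' @param scale `"target"` (default) z-scores every embedding by the
#'   target-domain per-dimension mean/SD before the distance, so distances
#'   are in units of target spread; `"none"` uses raw features.
#' @return data.frame (source, distance, rank) sorted by rank, with the
#'   recommended source as attribute `"recommended"`.
#' @export
rankSources <- function(sources, target, nProjections = 256L, seed = 1L,
                        scale = c("target", "none")) {
  scale <- match.arg(scale)
  if (length(sources) < 2L) stopParam("need at least two candidate sources")
  if (is.null(names(sources)) || any(names(sources) == ""))
    names(sources) <- vapply(sources, function(s) s@domain, character(1L))
  for (s in sources)
    if (s@fingerprint != target@fingerprint)
      stop(errorCondition("embeddings come from different extractors",
                          class = c("tlrFingerprintError", "error")))
  tf <- target@features
  zfun <- identity
  if (scale == "target") {
    mu <- colMeans(tf)
    sg <- apply(tf, 2L, sd)
    sg[sg < 1e-8] <- 1
    zfun <- function(m) sweep(sweep(m, 2L, mu, "-"), 2L, sg, "/")
  }
  tz <- zfun(tf)
  d <- vapply(sources, function(s)
    slicedW1(zfun(s@features), tz, nProjections = nProjections, seed = seed),
    numeric(1L))
  ord <- order(d, names(sources))
  out <- data.frame(source = names(sources)[ord], distance = unname(d[ord]),
                    rank = seq_along(ord), stringsAsFactors = FALSE)
  attr(out, "recommended") <- out$source[1L]
  out
}
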