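# Transfer learning signature (TLS): Mann-Whitney screening of the pooled
# transfer-learning features followed by a linear-kernel sparse Bayesian
# extreme learning machine (ARD Bayesian logistic regression) for final
# selection and scoring. Screening always strictly precedes the SBELM.

#' Mann-Whitney U screen of a feature matrix
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum p-value per feature: exact
#' enumeration when both groups have at most `exactMax` observations (and no
#' ties), otherwise the normal approximation with tie correction. No
#' multiplicity correction is applied; the screen keeps features with
#' `p < alpha`. Rank-based, hence invariant to strictly increasing
#' transforms of a feature.
#'
#' @param X patients x features matrix (or [extractFeatures()] result).
#' @param y binary labels (0/1).
#' @param alpha screening level (default 0.05, two-sided).
#' @param exactMax exact-enumeration cutoff per group size.
#' @return `list(mask = logical, p = numeric)` named by feature.
#' @export
mannWhitneyFilter <- function(X, y, alpha = 0.05, exactMax = 8L) {
  X <- featureMatrix(X)
  y <- as.integer(y)
  if (!isBinaryLabels(y)) stopData("both classes must be present")
  g1 <- y == 1L
  p <- vapply(seq_len(ncol(X)), function(j) {
    x <- X[, j]
    if (length(unique(x)) == 1L) return(1.0)   # all ties: uninformative
    useExact <- sum(g1) <= exactMax && sum(!g1) <= exactMax &&
      !anyDuplicated(x)
    suppressWarnings(
      wilcox.test(x[g1], x[!g1], exact = useExact, correct = FALSE)$p.value)
  }, numeric(1L))
  p <- pmin(p, 1)
  nm <- colnames(X)
  if (!is.null(nm)) names(p) <- nm
  list(mask = p < alpha, p = p)
}

#' Wilcoxon rank-sum test (re-export of the screening engine)
#'
#' Same engine as [mannWhitneyFilter()] applied to one variable: exact for
#' small untied groups, tie-corrected normal approximation otherwise.
#'
#' @param x,y numeric samples of the two groups.
#' @param exactMax exact-enumeration cutoff per group size.
#' @return `list(statistic = U, p = p.value)`.
#' @export
wilcoxonRanksum <- function(x, y, exactMax = 8L) {
  if (!length(x) || !length(y)) stopData("both samples must be non-empty")
  useExact <- length(x) <= exactMax && length(y) <= exactMax &&
    !anyDuplicated(c(x, y))
  wt <- suppressWarnings(wilcox.test(x, y, exact = useExact, correct = FALSE))
  list(statistic = unname(wt$statistic), p = min(wt$p.value, 1))
}

#' Fit the sparse Bayesian extreme learning machine
#'
#' Linear-kernel SBELM: Bernoulli-likelihood Bayesian logistic regression
#' with a per-weight automatic-relevance-determination (ARD) Gaussian prior.
#' Each outer iteration finds the posterior mode by Newton/IRLS (Laplace
#' approximation), then re-estimates the precisions with the MacKay update
#' `alpha_j = gamma_j / w_j^2`; weights whose precision exceeds
#' `pruneThreshold` are removed. Features are standardised on the training
#' cohort and the transform is frozen into the model.
#'
#' @param X patients x features matrix of screened features (or
#'   [extractFeatures()] result; screen first with [mannWhitneyFilter()]).
#' @param y binary labels (0/1).
#' @param pruneThreshold ARD precision above which a weight is pruned.
#' @param tol convergence tolerance on `max |delta log alpha|`.
#' @param maxIter maximum outer iterations (warning + `converged = FALSE`
#'   past it).
#' @param hidden optional random sigmoid hidden-layer width for the classic
#'   ELM variant (default `NULL` = linear kernel, which yields explicit
#'   input-feature selection).
#' @param seed seed for the random hidden layer (ignored for the linear
#'   kernel).
#' @return an [SbelmModel-class].
#' @export
fitSbelm <- function(X, y, pruneThreshold = 1e4, tol = 1e-4, maxIter = 200L,
                     hidden = NULL, seed = 1L) {
  X <- featureMatrix(X)
  y <- as.integer(y)
  if (length(y) != nrow(X)) stopShape("label length does not match rows of X")
  if (nrow(X) < 10L) stopData("SBELM needs n >= 10")
  if (!isBinaryLabels(y)) stopData("both classes must be present")
  if (ncol(X) < 1L) stopData("at least one screened feature is required")
  if (is.null(colnames(X))) colnames(X) <- sprintf("f%04d", seq_len(ncol(X)))
  if (!is.null(hidden)) {
    # classic ELM form: random sigmoid expansion, ARD prunes hidden units
    withSeed(seed, {
      Wh <- matrix(rnorm(ncol(X) * hidden), ncol(X), hidden)
      bh <- runif(hidden, -1, 1)
    })
    Xh <- plogis(sweep(scale(X) %*% Wh, 2L, bh, "+"))
    colnames(Xh) <- sprintf("h%03d", seq_len(hidden))
    fit <- fitSbelm(Xh, y, pruneThreshold, tol, maxIter, hidden = NULL)
    return(fit)
  }
  ctr <- colMeans(X)
  scl <- apply(X, 2L, sd)
  scl[scl < 1e-12] <- 1
  Z <- sweep(sweep(X, 2L, ctr, "-"), 2L, scl, "/")
  p <- ncol(Z)
  n <- nrow(Z)
  # constructive fast marginal-likelihood ARD (Faul-Tipping style, adapted
  # to the Bernoulli likelihood through IRLS): the model starts empty and a
  # feature enters only while its quality factor exceeds its sparsity
  # factor; in-model features failing the test are deleted
  active <- integer(0)
  alpha <- rep(Inf, p)
  w <- numeric(p)
  b <- qlogis(mean(pmin(pmax(y, 0.01), 0.99)))
  biasPrec <- 1e-6
  converged <- FALSE
  it <- 0L
  nDropped <- integer(p)   # re-entry bar against add/delete cycling
  while (it < maxIter) {
    it <- it + 1L
    Za <- cbind(Z[, active, drop = FALSE], 1)
    A <- c(alpha[active], biasPrec)
    wa <- c(w[active], b)
    for (k in seq_len(50L)) {              # Newton/IRLS to the posterior mode
      eta <- drop(Za %*% wa)
      mu <- plogis(eta)
      g <- crossprod(Za, mu - y) + A * wa
      r <- pmax(mu * (1 - mu), 1e-10)
      H <- crossprod(Za * r, Za)
      diag(H) <- diag(H) + A
      step <- solve(H, g)
      wa <- wa - step
      if (max(abs(step)) < 1e-8) break
    }
    eta <- drop(Za %*% wa)
    mu <- plogis(eta)
    r <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(Za * r, Za)
    diag(H) <- diag(H) + A
    Sigma <- chol2inv(chol(H))
    nAct <- length(active)
    w[] <- 0
    if (nAct) w[active] <- wa[seq_len(nAct)]
    b <- wa[nAct + 1L]
    # sparsity and quality factors of every candidate feature
    tbar <- eta + (y - mu) / r                 # IRLS working response
    Bt <- r * tbar
    Wm <- crossprod(Za * r, Z)                 # (nAct+1) x p
    Shat <- colSums(Z * (Z * r)) - colSums(Wm * (Sigma %*% Wm))
    Qhat <- drop(crossprod(Z, Bt)) - drop(crossprod(Wm, Sigma %*% crossprod(Za, Bt)))
    sj <- Shat; qj <- Qhat
    if (nAct) {
      den <- alpha[active] - Shat[active]
      den[abs(den) < 1e-12] <- 1e-12
      sj[active] <- alpha[active] * Shat[active] / den
      qj[active] <- alpha[active] * Qhat[active] / den
    }
    # entry/retention demands the evidence gain exceed the universal
    # threshold 2 log p: the bare q^2 > s rule admits ~32% of pure-noise
    # candidates (a one-sigma test), which at thousands of screened
    # features would swamp the signature
    kappa <- max(1, 2 * log(p))
    theta <- qj^2 - sj
    gate <- qj^2 - kappa * sj
    changed <- FALSE
    # delete at most one failing feature per sweep (the worst): collinear
    # pairs fail jointly and the survivor must be re-tested alone
    fail <- active[gate[active] <= 0]
    drop_ <- if (length(fail)) fail[which.min(gate[fail])] else integer(0)
    if (length(drop_)) {
      w[drop_] <- 0
      alpha[drop_] <- Inf
      nDropped[drop_] <- nDropped[drop_] + 1L
      active <- setdiff(active, drop_)
      changed <- TRUE
    }
    dl <- 0
    if (length(active)) {
      newA <- pmin(pmax(sj[active]^2 / theta[active], 1e-12), 1e12)
      dl <- max(abs(log(newA) - log(alpha[active])))
      alpha[active] <- newA
      over <- active[newA >= pruneThreshold]
      if (length(over)) {
        w[over] <- 0
        alpha[over] <- Inf
        active <- setdiff(active, over)
        changed <- TRUE
      }
    }
    cand <- setdiff(which(gate > 0 & nDropped < 2L), active)
    cand <- cand[sj[cand]^2 / theta[cand] < pruneThreshold]
    if (length(cand)) {
      add <- cand[which.max(theta[cand] / pmax(sj[cand], 1e-12))]
      alpha[add] <- sj[add]^2 / theta[add]
      active <- sort(c(active, add))
      changed <- TRUE
    }
    if (!changed && dl < tol) { converged <- TRUE; break }
  }
  if (!converged && it >= maxIter)
    warning("SBELM did not converge within maxIter")
  new("SbelmModel",
      featureIds = colnames(Z)[active],
      weights = w[active], intercept = b,
      alpha = alpha[active],
      center = ctr, scale = scl, screened = colnames(Z),
      converged = converged, iterations = it,
      nullModel = length(active) == 0L)
}

#' @export
setMethod("show", "SbelmModel", function(object) {
  cat(sprintf("SbelmModel: %d/%d features retained (%s, %d iterations)\n",
              length(object@featureIds), length(object@screened),
              if (object@converged) "converged" else "not converged",
              object@iterations))
  if (object@nullModel) cat("  null model: every feature pruned\n")
})

#' Transfer learning signature score
#'
#' Logistic-link score of the fitted SBELM on new patients, in `[0, 1]`;
#' deterministic given the model and features.
#'
#' @param model an [SbelmModel-class].
#' @param X patients x features matrix containing at least the model's
#'   retained features (by name), or an [extractFeatures()] result.
#' @return numeric score per patient.
#' @export
tlsScore <- function(model, X) {
  stopifnot(is(model, "SbelmModel"))
  X <- featureMatrix(X)
  if (model@nullModel) return(rep(plogis(model@intercept), nrow(X)))
  miss <- setdiff(model@featureIds, colnames(X))
  if (length(miss))
    stopSchema("features missing from X: ", paste(head(miss, 3L), collapse = ", "))
  ids <- model@featureIds
  Z <- sweep(sweep(X[, ids, drop = FALSE], 2L, model@center[ids], "-"),
             2L, model@scale[ids], "/")
  unname(plogis(drop(Z %*% model@weights) + model@intercept))
}

#' Serialise a signature model to JSON
#'
#' Full-precision JSON round-trip ([readSbelm()] restores a bit-identical
#' model).
#'
#' @param model an [SbelmModel-class].
#' @param path output file.
#' @export
writeSbelm <- function(model, path) {
  jsonlite::write_json(
    list(featureIds = model@featureIds, weights = model@weights,
         intercept = model@intercept, alpha = model@alpha,
         center = as.list(model@center), scale = as.list(model@scale),
         screened = model@screened, converged = model@converged,
         iterations = model@iterations, nullModel = model@nullModel),
    path, digits = I(17), auto_unbox = TRUE)   # 17 sig. digits: bit-exact doubles
  invisible(path)
}

#' @rdname writeSbelm
#' @export
readSbelm <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("SbelmModel", featureIds = as.character(j$featureIds),
      weights = as.numeric(j$weights), intercept = j$intercept,
      alpha = as.numeric(j$alpha), center = unlist(j$center),
      scale = unlist(j$scale), screened = as.character(j$screened),
      converged = j$converged, iterations = as.integer(j$iterations),
      nullModel = j$nullModel)
}

#' Screen-then-fit convenience wrapper
#'
#' Applies [mannWhitneyFilter()] and fits the SBELM on the surviving
#' features only (the SBELM never sees masked-out features). When nothing
#' survives the screen, the `alpha`-smallest `minKeep` features are used so
#' a signature always exists.
#'
#' @param X patients x features matrix or [extractFeatures()] result.
#' @param y binary labels.
#' @param alpha screening level.
#' @param minKeep fallback feature count when the screen returns empty.
#' @param ... passed to [fitSbelm()].
#' @return `list(model, screen)`.
#' @export
buildTls <- function(X, y, alpha = 0.05, minKeep = 5L, ...) {
  X <- featureMatrix(X)
  scr <- mannWhitneyFilter(X, y, alpha = alpha)
  keep <- which(scr$mask)
  if (!length(keep)) keep <- order(scr$p)[seq_len(min(minKeep, ncol(X)))]
  model <- fitSbelm(X[, keep, drop = FALSE], y, ...)
  list(model = model, screen = scr)
}
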