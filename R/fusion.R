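# Clinical statistics and multimodal fusion: Cohen's kappa, univariate
# screening with the chi-square / Fisher / Wilcoxon dispatch, the sparse
# Bayes LASSO fusion model (TLRM) and the multivariable-logistic clinical
# comparator.

#' Cohen's kappa for interreader agreement
#'
#' `kappa = (p_o - p_e) / (1 - p_e)`; 1 for perfect agreement. When both
#' readers are constant and equal (`p_e = 1`) the statistic is undefined and
#' flagged.
#'
#' @param reader1,reader2 categorical vectors of equal length.
#' @return `list(kappa, po, pe, undefined)`.
#' @export
cohenKappa <- function(reader1, reader2) {
  if (length(reader1) != length(reader2)) stopData("reader vectors differ in length")
  lev <- sort(unique(c(as.character(reader1), as.character(reader2))))
  t1 <- factor(reader1, levels = lev)
  t2 <- factor(reader2, levels = lev)
  tab <- table(t1, t2) / length(t1)
  po <- sum(diag(tab))
  pe <- sum(rowSums(tab) * colSums(tab))
  if (abs(1 - pe) < 1e-12)
    return(list(kappa = NA_real_, po = po, pe = pe, undefined = TRUE))
  list(kappa = (po - pe) / (1 - pe), po = po, pe = pe, undefined = FALSE)
}

#' Pearson chi-square test for a 2 x k table
#'
#' No continuity correction; `df = (r-1)(c-1)`.
#'
#' @param tab matrix of non-negative counts.
#' @return `list(statistic, df, p)`.
#' @export
pearsonChi2 <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab))) stopData("counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stopData("zero marginal in contingency table")
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = unname(ct$p.value))
}

#' Fisher's exact test for a 2 x k table
#'
#' Two-sided p by summing the probabilities of all margin-fixed tables as or
#' less probable than the observed one (network enumeration, `k <= 5`).
#'
#' @param tab matrix of non-negative counts (2 x k or k x 2, k <= 5).
#' @return two-sided p-value.
#' @export
fisherExact <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab))) stopData("counts must be non-negative integers")
  if (min(dim(tab)) > 2L || max(dim(tab)) > 5L)
    stopParam("table too large to enumerate (2 x k with k <= 5)")
  min(stats::fisher.test(tab)$p.value, 1)
}

#' Univariate screening of a clinical cohort table
#'
#' Dispatch per variable: continuous variables use the Wilcoxon rank-sum
#' test; categorical variables use Pearson's chi-square unless any expected
#' cell count is below 5, in which case Fisher's exact test is used.
#' Constant variables are reported with `p = 1` and a degenerate flag.
#'
#' @param cohort data.frame containing a `label` column plus covariates.
#' @param labelCol name of the class column.
#' @param alpha significance level for the `significant` flag.
#' @param exclude columns ignored (ids, tags).
#' @return data.frame with columns variable, test, statistic, p,
#'   significant, degenerate.
#' @export
univariateScreen <- function(cohort, labelCol = "label", alpha = 0.05,
                             exclude = c("patient_id", "cohort", "tls")) {
  if (!labelCol %in% names(cohort)) stopData("label column not found")
  y <- asLabel01(cohort[[labelCol]])
  if (!isBinaryLabels(y)) stopData("both classes must be present")
  vars <- setdiff(names(cohort), c(labelCol, exclude))
  rows <- lapply(vars, function(v) {
    x <- cohort[[v]]
    if (length(unique(x)) == 1L)
      return(data.frame(variable = v, test = "degenerate", statistic = NA_real_,
                        p = 1, significant = FALSE, degenerate = TRUE))
    if (is.numeric(x)) {
      wt <- wilcoxonRanksum(x[y == 1L], x[y == 0L])
      data.frame(variable = v, test = "wilcoxon", statistic = wt$statistic,
                 p = wt$p, significant = wt$p < alpha, degenerate = FALSE)
    } else {
      tab <- table(factor(x), y)
      exp <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(exp < 5)) {
        p <- fisherExact(tab)
        data.frame(variable = v, test = "fisher_exact", statistic = NA_real_,
                   p = p, significant = p < alpha, degenerate = FALSE)
      } else {
        ct <- pearsonChi2(tab)
        data.frame(variable = v, test = "pearson_chi2", statistic = ct$statistic,
                   p = ct$p, significant = ct$p < alpha, degenerate = FALSE)
      }
    }
  })
  do.call(rbind, rows)
}

# design matrix for fusion/clinical models: numeric kept (standardised
# later), two-level categoricals coded 0/1 (absence/presence, women=0/men=1)
fusionDesign <- function(data, terms) {
  cols <- lapply(terms, function(v) {
    x <- data[[v]]
    if (is.null(x)) stopSchema("covariate missing: ", v)
    if (is.numeric(x)) return(as.numeric(x))
    ch <- as.character(x)
    ref <- if (all(ch %in% c("absence", "presence"))) "presence"
           else if (all(ch %in% c("men", "women"))) "men"
           else if (all(ch %in% c("regular", "irregular"))) "irregular"
           else sort(unique(ch))[2L]
    as.numeric(ch == ref)
  })
  X <- do.call(cbind, cols)
  colnames(X) <- terms
  X
}

# EM adaptive-ridge MAP for a hierarchical-Laplace (scale-mixture) prior on
# standardised covariates; gamma is the Laplace rate per sqrt(n) -- the
# score of a standardised null covariate has sd ~ sqrt(n)/2, so scaling the
# rate keeps the selection behaviour stable across cohort sizes
laplaceMap <- function(Z, y, gamma, maxIter = 200L, tol = 1e-8) {
  p <- ncol(Z)
  gamma <- gamma * sqrt(nrow(Z))
  Za <- cbind(Z, 1)
  w <- rep(0.01, p + 1L)
  for (it in seq_len(maxIter)) {
    pen <- c(gamma / pmax(abs(w[seq_len(p)]), 1e-9), 1e-8)
    for (k in seq_len(30L)) {
      eta <- drop(Za %*% w)
      mu <- plogis(eta)
      g <- crossprod(Za, mu - y) + pen * w
      r <- pmax(mu * (1 - mu), 1e-10)
      H <- crossprod(Za * r, Za)
      diag(H) <- diag(H) + pen
      step <- solve(H, g)
      w <- w - step
      if (max(abs(step)) < 1e-9) break
    }
    if (it > 1L && max(abs(w - wPrev)) < tol) break
    wPrev <- w
  }
  eta <- drop(Za %*% w)
  ll <- sum(y * eta - log1p(exp(eta)))
  # Laplace-approximate evidence over the surviving dimensions only:
  # collapsed weights sit in a fully concentrated prior and contribute
  # neither parameters nor curvature
  act <- which(abs(w[seq_len(p)]) >= 1e-6)
  Zact <- cbind(Z[, act, drop = FALSE], 1)
  r <- pmax(plogis(eta) * (1 - plogis(eta)), 1e-10)
  H <- crossprod(Zact * r, Zact)
  diag(H) <- diag(H) + c(gamma / abs(w[act]), 1e-8)
  logEvid <- ll + length(act) * log(gamma / 2) - gamma * sum(abs(w[act])) -
    0.5 * determinant(H / (2 * pi), logarithm = TRUE)$modulus
  list(w = w[seq_len(p)], b = w[p + 1L], logEvid = as.numeric(logEvid))
}

#' Fit the sparse-Bayes-LASSO fusion model (TLRM)
#'
#' Bayesian logistic regression with a hierarchical Laplace (scale-mixture)
#' prior over standardised candidate covariates, solved by EM adaptive
#' ridge; the prior rate is chosen by BIC over the refit active sets of a
#' small grid unless given (the approximate evidence of each fit is also
#' computed and stored). Covariates whose posterior-mode weight falls below
#' `sparsityEps` are dropped and the survivors refit. Invariant to covariate
#' ordering.
#'
#' @param data data.frame of candidate covariates (typically the significant
#'   variables of [univariateScreen()] plus a `tls` column) and the label.
#' @param candidates character vector of candidate column names.
#' @param labelCol class column name.
#' @param priorScale Laplace prior rate per sqrt(n) (larger = stronger
#'   shrinkage); `NULL` selects it by BIC over `priorGrid`.
#' @param priorGrid grid for the evidence search.
#' @param sparsityEps hard threshold on standardised weights.
#' @return a [TlrmModel-class].
#' @export
fitSparseBayesLasso <- function(data, candidates, labelCol = "label",
                                priorScale = NULL,
                                priorGrid = 2^seq(-2, 4),
                                sparsityEps = 1e-3) {
  y <- asLabel01(data[[labelCol]])
  if (!isBinaryLabels(y)) stopData("both classes must be present")
  candidates <- sort(candidates)
  X <- fusionDesign(data, candidates)
  n <- nrow(X)
  if (n < 10L * ncol(X))
    warning(sprintf("n = %d is below the recommended 10 x %d candidates", n, ncol(X)))
  ctr <- colMeans(X)
  scl <- apply(X, 2L, sd)
  scl[scl < 1e-12] <- 1
  Z <- sweep(sweep(X, 2L, ctr, "-"), 2L, scl, "/")
  if (is.null(priorScale)) {
    # rate selection by BIC over the refit active sets: the Laplace
    # approximation to the evidence is unreliable at the non-smooth
    # posterior mode and over-rewards borderline covariates
    fits <- lapply(priorGrid, function(g) laplaceMap(Z, y, g))
    bic <- vapply(seq_along(fits), function(i) {
      act <- abs(fits[[i]]$w) >= sparsityEps
      eta <- if (any(act))
        drop(cbind(Z[, act, drop = FALSE], 1) %*%
               c(fits[[i]]$w[act], fits[[i]]$b)) else rep(fits[[i]]$b, n)
      ll <- sum(y * eta - log1p(exp(eta)))
      -2 * ll + (sum(act) + 1L) * log(n)
    }, numeric(1L))
    best <- which.min(bic)
    priorScale <- priorGrid[best]
    fit <- fits[[best]]
  } else fit <- laplaceMap(Z, y, priorScale)
  keep <- abs(fit$w) >= sparsityEps
  if (any(keep)) {
    ref <- laplaceMap(Z[, keep, drop = FALSE], y, priorScale)
    coefs <- ref$w
    names(coefs) <- candidates[keep]
    b <- ref$b
  } else {
    coefs <- numeric(0)
    b <- qlogis(mean(y))
  }
  if (max(abs(coefs), 0) > 15)
    warning("possible separation: coefficients remain prior-regularised")
  new("TlrmModel", terms = candidates[keep], coefficients = unname(coefs),
      intercept = b, center = ctr, scale = scl, candidates = candidates,
      priorScale = priorScale, evidence = fit$logEvid)
}

#' @export
setMethod("show", "TlrmModel", function(object) {
  cat(sprintf("TlrmModel: %d/%d covariates retained (prior rate %.3g)\n",
              length(object@terms), length(object@candidates), object@priorScale))
  if (length(object@terms))
    cat("  ", paste(sprintf("%s=%.3f", object@terms, object@coefficients),
                    collapse = ", "), "\n")
})

#' TLRM risk prediction value
#'
#' Deterministic logistic-link score in `[0, 1]` for new patient records
#' carrying the selected covariates (clinical factors, subjective CT
#' findings and the TLS score).
#'
#' @param model a [TlrmModel-class].
#' @param data data.frame with the model's selected covariates.
#' @return numeric risk per row.
#' @export
tlrmScore <- function(model, data) {
  stopifnot(is(model, "TlrmModel"))
  if (!length(model@terms)) return(rep(plogis(model@intercept), nrow(data)))
  X <- fusionDesign(data, model@terms)
  Z <- sweep(sweep(X, 2L, model@center[model@terms], "-"),
             2L, model@scale[model@terms], "/")
  unname(plogis(drop(Z %*% model@coefficients) + model@intercept))
}

#' Fit the clinical comparator model
#'
#' Maximum-likelihood multivariable logistic regression over gender, age,
#' lobulated shape and spiculated sign. Under quasi-separation the fit
#' falls back to a lightly ridge-penalised solution with a warning.
#'
#' @param cohort clinical data.frame with a `label` column.
#' @param terms covariates (default the four independent clinical factors).
#' @return a [ClinicalModel-class].
#' @export
fitClinicalLogistic <- function(cohort,
                                terms = c("gender", "age", "lobulated", "spiculated")) {
  y <- asLabel01(cohort$label)
  if (!isBinaryLabels(y)) stopData("both classes must be present")
  X <- fusionDesign(cohort, terms)
  df <- data.frame(y = y, X)
  fit <- suppressWarnings(glm(y ~ ., data = df, family = binomial()))
  sep <- !fit$converged || any(abs(coef(fit)[-1L]) > 15, na.rm = TRUE) ||
    anyNA(coef(fit))
  if (sep) {
    warning("quasi-separation detected; using ridge-penalised fallback")
    gn <- glmnet::glmnet(X, y, family = "binomial", alpha = 0, lambda = 1e-2,
                         standardize = TRUE)
    co <- c(as.numeric(gn$a0), as.numeric(gn$beta))
    names(co) <- c("(Intercept)", colnames(X))
    se <- rep(NA_real_, length(co))
  } else {
    co <- coef(fit)
    se <- sqrt(diag(vcov(fit)))
  }
  new("ClinicalModel", coefficients = co, se = se,
      terms = colnames(X), separation = sep, fit = fit)
}

#' @export
setMethod("show", "ClinicalModel", function(object) {
  cat("ClinicalModel (multivariable logistic):\n")
  print(round(rbind(coef = object@coefficients, se = object@se), 4))
})

#' Clinical model risk score
#'
#' @param model a [ClinicalModel-class].
#' @param data data.frame with the model's covariates.
#' @return fitted probability per row.
#' @export
clinicalScore <- function(model, data) {
  X <- fusionDesign(data, model@terms)
  eta <- drop(cbind(1, X) %*% model@coefficients)
  unname(plogis(eta))
}
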