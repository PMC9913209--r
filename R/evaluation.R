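# Evaluation stack: Mann-Whitney AUC, DeLong machinery (structural
# components), threshold metrics, IDI, Hosmer-Lemeshow calibration,
# decision curves and stratified analysis.

#' Area under the ROC curve (Mann-Whitney form)
#'
#' Probability that a random positive outscores a random negative, ties
#' counted one half.
#'
#' @param scores numeric scores.
#' @param labels binary labels (0/1); both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stopData("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# DeLong structural components: V10 per positive, V01 per negative
delongComponents <- function(scores, labels) {
  x <- scores[labels == 1L]
  y <- scores[labels == 0L]
  cmp <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(cmp), v01 = 1 - colMeans(cmp), auc = mean(cmp))
}

#' DeLong confidence interval for one AUC
#'
#' `AUC +/- z * SE` with the structural-components variance, truncated to
#' `[0, 1]`.
#'
#' @param scores,labels scores and binary labels.
#' @param level confidence level (default 0.95).
#' @return `list(auc, lower, upper, se)`.
#' @export
delongCi <- function(scores, labels, level = 0.95) {
  labels <- as.integer(labels)
  dc <- delongComponents(scores, labels)
  se <- sqrt(var(dc$v10) / length(dc$v10) + var(dc$v01) / length(dc$v01))
  z <- qnorm(1 - (1 - level) / 2)
  list(auc = dc$auc, lower = max(0, dc$auc - z * se),
       upper = min(1, dc$auc + z * se), se = se)
}

#' DeLong test between two correlated AUCs
#'
#' Paired comparison of two models scored on the same patients via the
#' structural-components covariance; two-sided normal p. A degenerate
#' zero-variance difference (e.g. identical score vectors) is flagged and
#' reported as `z = 0, p = 1`.
#'
#' @param scoresA,scoresB paired score vectors.
#' @param labels binary labels.
#' @return `list(aucA, aucB, z, p, degenerate)`.
#' @export
delongTest <- function(scoresA, scoresB, labels) {
  labels <- as.integer(labels)
  if (length(scoresA) != length(scoresB) || length(scoresA) != length(labels))
    stopShape("scores must be paired on identical patients")
  da <- delongComponents(scoresA, labels)
  db <- delongComponents(scoresB, labels)
  m <- length(da$v10); n <- length(da$v01)
  s10 <- cov(cbind(da$v10, db$v10))
  s01 <- cov(cbind(da$v01, db$v01))
  v <- (s10[1L, 1L] + s10[2L, 2L] - 2 * s10[1L, 2L]) / m +
       (s01[1L, 1L] + s01[2L, 2L] - 2 * s01[1L, 2L]) / n
  if (!is.finite(v) || v < 1e-14)
    return(list(aucA = da$auc, aucB = db$auc, z = 0, p = 1, degenerate = TRUE))
  z <- (da$auc - db$auc) / sqrt(v)
  list(aucA = da$auc, aucB = db$auc, z = z, p = 2 * pnorm(-abs(z)),
       degenerate = FALSE)
}

#' Unpaired DeLong comparison of two independent(ly scored) cohorts
#'
#' @param scoresA,labelsA first cohort.
#' @param scoresB,labelsB second cohort.
#' @return `list(aucA, aucB, z, p, degenerate)`.
#' @export
delongTestUnpaired <- function(scoresA, labelsA, scoresB, labelsB) {
  ca <- delongCi(scoresA, labelsA)
  cb <- delongCi(scoresB, labelsB)
  v <- ca$se^2 + cb$se^2
  if (!is.finite(v) || v < 1e-14)
    return(list(aucA = ca$auc, aucB = cb$auc, z = 0, p = 1, degenerate = TRUE))
  z <- (ca$auc - cb$auc) / sqrt(v)
  list(aucA = ca$auc, aucB = cb$auc, z = z, p = 2 * pnorm(-abs(z)),
       degenerate = FALSE)
}

#' Confusion-matrix metrics at a threshold
#'
#' `score >= threshold` is called positive; returns sensitivity,
#' specificity, accuracy, PPV and NPV with their numerator/denominator
#' counts.
#'
#' @param scores,labels scores and binary labels.
#' @param threshold operating threshold in `[0, 1]`.
#' @param cohort cohort tag carried into the report.
#' @return one-row data.frame.
#' @export
confusionAt <- function(scores, labels, threshold, cohort = "cohort") {
  if (!is.finite(threshold) || threshold < 0 || threshold > 1)
    stopParam("threshold must be in [0, 1]")
  labels <- as.integer(labels)
  pos <- scores >= threshold
  tp <- sum(pos & labels == 1L); fn <- sum(!pos & labels == 1L)
  fp <- sum(pos & labels == 0L); tn <- sum(!pos & labels == 0L)
  data.frame(cohort = cohort, threshold = threshold,
             sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
             accuracy = (tp + tn) / length(labels),
             ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
             npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
             tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Youden-index operating threshold
#'
#' Maximises sensitivity + specificity - 1 over the observed scores; ties
#' resolve to the lower threshold.
#'
#' @param scores,labels scores and binary labels.
#' @return threshold value.
#' @export
youdenThreshold <- function(scores, labels) {
  labels <- as.integer(labels)
  cand <- sort(unique(scores))
  j <- vapply(cand, function(t) {
    pos <- scores >= t
    sum(pos & labels == 1L) / sum(labels == 1L) +
      sum(!pos & labels == 0L) / sum(labels == 0L) - 1
  }, numeric(1L))
  cand[which.max(j)]   # which.max returns the first (lowest) maximiser
}

#' Full evaluation report for one model on one cohort
#'
#' AUC with DeLong 95% CI plus threshold metrics at a given (typically
#' training-cohort Youden) threshold.
#'
#' @param scores,labels scores and binary labels.
#' @param threshold operating threshold; default the cohort's own Youden.
#' @param cohort cohort tag.
#' @return one-row data.frame.
#' @export
evalReport <- function(scores, labels, threshold = NULL, cohort = "cohort") {
  if (is.null(threshold)) threshold <- youdenThreshold(scores, labels)
  ci <- delongCi(scores, labels)
  cbind(data.frame(auc = ci$auc, aucLower = ci$lower, aucUpper = ci$upper),
        confusionAt(scores, labels, threshold, cohort))
}

#' Integrated discrimination improvement
#'
#' `IDI = (mean p_new | cases - mean p_new | controls) -
#'        (mean p_old | cases - mean p_old | controls)`;
#' p-value from the paired-difference z-test on discrimination slopes.
#'
#' @param pOld,pNew paired predicted probabilities of the old and new model.
#' @param labels binary labels.
#' @return `list(idi, z, p)`.
#' @export
idi <- function(pOld, pNew, labels) {
  labels <- as.integer(labels)
  if (length(pOld) != length(pNew) || length(pOld) != length(labels))
    stopShape("probabilities must be paired")
  d <- pNew - pOld
  d1 <- d[labels == 1L]; d0 <- d[labels == 0L]
  est <- mean(d1) - mean(d0)
  se <- sqrt(var(d1) / length(d1) + var(d0) / length(d0))
  if (!is.finite(se) || se < 1e-14)
    return(list(idi = est, z = 0, p = 1))
  z <- est / se
  list(idi = est, z = z, p = 2 * pnorm(-abs(z)))
}

#' Hosmer-Lemeshow calibration test
#'
#' Equal-count risk groups (ties to the lower group),
#' `chi2 = sum (O - E)^2 / (E (1 - E/n_g))`, `df = g - 2`. Empty groups
#' after tying are merged with a warning.
#'
#' @param probs predicted probabilities.
#' @param labels binary labels.
#' @param g number of groups (default 10); requires `n >= 2g`.
#' @return `list(chisq, df, p, table)`.
#' @export
hosmerLemeshow <- function(probs, labels, g = 10L) {
  labels <- as.integer(labels)
  n <- length(probs)
  if (n < 2L * g) stopData("need n >= 2g observations")
  ord <- order(probs)
  grp <- integer(n)
  grp[ord] <- ceiling(seq_len(n) / n * g)
  O <- tapply(labels, grp, sum)
  E <- tapply(probs, grp, sum)
  ng <- tapply(labels, grp, length)
  if (any(ng == 0L) || length(O) < g) {
    warning("empty risk group; merging")
  }
  denom <- E * (1 - E / ng)
  denom[denom < 1e-10] <- 1e-10
  chisq <- sum((O - E)^2 / denom)
  df <- length(O) - 2L
  list(chisq = chisq, df = df, p = pchisq(chisq, df, lower.tail = FALSE),
       table = data.frame(group = as.integer(names(O)), n = as.integer(ng),
                          observed = as.integer(O), expected = as.numeric(E)))
}

#' Decision curve analysis
#'
#' Net benefit `NB(pt) = TP/n - FP/n * pt/(1-pt)` of the model, the
#' treat-all policy and treat-none (identically 0) across a threshold-
#' probability grid; `pt = 1` has an undefined weight and is reported `NA`.
#'
#' @param probs predicted probabilities in `[0, 1]`.
#' @param labels binary labels.
#' @param thresholds threshold-probability grid (default 0.01 to 1.00 in
#'   steps of 0.01).
#' @return data.frame (threshold, netBenefit, treatAll, treatNone).
#' @export
decisionCurve <- function(probs, labels, thresholds = seq(0.01, 1, by = 0.01)) {
  if (!length(thresholds)) stopParam("empty threshold grid")
  if (any(probs < 0 | probs > 1)) stopData("probs must be in [0, 1]")
  labels <- as.integer(labels)
  n <- length(labels)
  prev <- mean(labels)
  nb <- vapply(thresholds, function(pt) {
    if (pt >= 1) return(NA_real_)
    pos <- probs >= pt
    sum(pos & labels == 1L) / n - sum(pos & labels == 0L) / n * pt / (1 - pt)
  }, numeric(1L))
  ta <- ifelse(thresholds >= 1, NA_real_,
               prev - (1 - prev) * thresholds / (1 - thresholds))
  data.frame(threshold = thresholds, netBenefit = nb, treatAll = ta,
             treatNone = 0)
}

#' Stratified AUC analysis
#'
#' Per-stratum AUC with DeLong CI plus the unpaired DeLong comparison of
#' each stratum against the pooled cohort; strata missing a class are
#' skipped with a flag.
#'
#' @param scores,labels scores and binary labels.
#' @param strata factor/character stratum per patient.
#' @return data.frame (stratum, n, auc, lower, upper, delongP, skipped).
#' @export
stratifiedAnalysis <- function(scores, labels, strata) {
  labels <- as.integer(labels)
  rows <- lapply(unique(as.character(strata)), function(s) {
    i <- which(as.character(strata) == s)
    if (!length(i) || length(unique(labels[i])) < 2L) {
      warning("stratum '", s, "' skipped (missing class)")
      return(data.frame(stratum = s, n = length(i), auc = NA_real_,
                        lower = NA_real_, upper = NA_real_,
                        delongP = NA_real_, skipped = TRUE))
    }
    ci <- delongCi(scores[i], labels[i])
    dt <- if (length(i) == length(labels))
      list(p = 1) else
      delongTestUnpaired(scores[i], labels[i], scores, labels)
    data.frame(stratum = s, n = length(i), auc = ci$auc, lower = ci$lower,
               upper = ci$upper, delongP = dt$p, skipped = FALSE)
  })
  do.call(rbind, rows)
}
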