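#' Confusion-matrix performance metrics
#'
#' Sensitivity, specificity, PPV, NPV, prevalence and prevalence gain from
#' confusion counts. Counts may be non-integer (e.g. expected counts derived
#' from printed rates). The prevalence gain is the disease prevalence inside
#' the suspicious-called pool over the baseline prevalence,
#' `[tp/(tp+fp)] / [(tp+fn)/n]` — the enrichment a triage step achieves.
#' Ratios with zero denominators are `NA`, not 0.
#'
#' @param tp,fp,tn,fn Nonnegative confusion counts.
#' @return One-row tibble with the counts and derived metrics.
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  if (any(c(tp, fp, tn, fn) < 0)) abort("Confusion counts must be nonnegative.")
  rat <- function(a, b) if (b > 0) a / b else NA_real_
  n <- tp + fp + tn + fn
  prevalence <- rat(tp + fn, n)
  ppv <- rat(tp, tp + fp)
  tibble::tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = rat(tp, tp + fn),
    specificity = rat(tn, tn + fp),
    ppv = ppv,
    npv = rat(tn, tn + fn),
    prevalence = prevalence,
    prevalence_gain = if (is.na(ppv) || is.na(prevalence) || prevalence == 0)
      NA_real_ else ppv / prevalence
  )
}

#' Expected confusion report from printed rates and dataset composition
#'
#' Reconstructs the derived columns of a performance table (PPV, NPV,
#' prevalence gain, expected negatives removed) from a printed sensitivity
#' and specificity and the number of suspicious and normal images, using
#' expected (possibly non-integer) counts `tp = sens * n_s` etc.
#'
#' @param sensitivity,specificity Rates in `[0, 1]`.
#' @param n_suspicious,n_normal Positive class sizes.
#' @return One-row tibble as from [confusion_metrics()].
#' @export
expected_report <- function(sensitivity, specificity, n_suspicious, n_normal) {
  if (sensitivity < 0 || sensitivity > 1 || specificity < 0 || specificity > 1) {
    abort("Rates must lie in [0, 1].")
  }
  stopifnot(n_suspicious > 0, n_normal > 0)
  confusion_metrics(tp = sensitivity * n_suspicious,
                    fp = (1 - specificity) * n_normal,
                    tn = specificity * n_normal,
                    fn = (1 - sensitivity) * n_suspicious)
}

#' Area under the ROC curve by rank statistic
#'
#' `P(score_suspicious > score_normal) + 0.5 P(equal)`, computed with
#' midranks; identical to the trapezoidal area under the [roc_sweep()]
#' curve.
#'
#' @param scores Numeric scores (higher = more suspicious), or a tibble with
#'   `label` and `pp_suspicious`/`score` columns.
#' @param labels Labels when `scores` is a vector.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels = NULL) {
  sc <- extract_scores(scores, labels)
  check_two_classes(sc$label)
  is_s <- sc$label == "suspicious"
  n_s <- sum(is_s); n_n <- sum(!is_s)
  r <- rank(sc$score)
  (sum(r[is_s]) - n_s * (n_s + 1) / 2) / (n_s * n_n)
}

#' DeLong comparison of two ROC curves
#'
#' Estimates `var(AUC_a - AUC_b)` from the empirical placement values
#' (midrank handling of ties) and reports the normal z statistic and
#' two-sided p value. Paired comparison uses the placement covariance across
#' the two score sets on the same images; unpaired sums the two independent
#' AUC variances. `|z| < 1.96` indicates no significant difference at the
#' 5% level.
#'
#' @param scores_a,scores_b Score vectors.
#' @param labels_a Labels for `scores_a` (and for `scores_b` when paired).
#' @param labels_b Labels for `scores_b` when `paired = FALSE`.
#' @param paired Same images under both score sets (default `TRUE`).
#' @return One-row tibble: `auc_a`, `auc_b`, `delta`, `z`, `p_value`.
#' @export
delong_test <- function(scores_a, scores_b, labels_a, labels_b = NULL,
                        paired = TRUE) {
  if (paired) {
    if (length(scores_a) != length(scores_b)) {
      abort("Paired scores must have the same length.")
    }
    pa <- placements(scores_a, labels_a)
    pb <- placements(scores_b, labels_a)
    m <- length(pa$v10); n <- length(pa$v01)
    d10 <- pa$v10 - pb$v10
    d01 <- pa$v01 - pb$v01
    var_d <- cov2(d10, d10) / m + cov2(d01, d01) / n
    auc <- c(pa$auc, pb$auc)
  } else {
    labels_b <- labels_b %||% labels_a
    pa <- placements(scores_a, labels_a)
    pb <- placements(scores_b, labels_b)
    var_d <- var1(pa) + var1(pb)
    auc <- c(pa$auc, pb$auc)
  }
  delta <- auc[1] - auc[2]
  z <- if (delta == 0 && var_d <= 0) 0 else delta / sqrt(var_d)
  tibble::tibble(auc_a = auc[1], auc_b = auc[2], delta = delta, z = z,
                 p_value = 2 * pnorm(-abs(z)))
}

# Placement values: v10[i] = fraction of normals a suspicious score beats
# (ties count 1/2); v01[j] = fraction of suspicious scores a normal loses to.
placements <- function(scores, labels) {
  check_two_classes(labels)
  s <- scores[labels == "suspicious"]
  n <- scores[labels == "normal"]
  cmp <- outer(s, n, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(cmp), v01 = colMeans(cmp), auc = mean(cmp))
}

cov2 <- function(a, b) {
  # covariance of the paired placement vectors (single-curve case: variance)
  if (length(a) < 2) return(0)
  sum((a - mean(a)) * (b - mean(b))) / (length(a) - 1)
}

var1 <- function(p) cov2(p$v10, p$v10) / length(p$v10) +
  cov2(p$v01, p$v01) / length(p$v01)
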