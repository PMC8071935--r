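#' Mann-Whitney area under the ROC curve
#'
#' AUC computed as the proportion of (positive, negative) pairs in which
#' the positive value exceeds the negative, ties counted one half -- the
#' Mann-Whitney U identity with the area under the empirical ROC curve.
#' Orientation is auto-detected: if the raw proportion falls below 0.5 the
#' direction flips so the reported AUC is always >= 0.5.
#'
#' @param positives,negatives numeric vectors (non-empty); positives are
#'   the target class (conventionally the less-differentiated group).
#' @return list with \code{auc} in [0.5, 1] and \code{direction}
#'   (\code{"greater-is-positive"} or \code{"lesser-is-positive"}).
#' @examples
#' mann_whitney_auc(c(3, 5), c(1, 2, 4))  # 5/6 of the pairs ordered
#' @export
mann_whitney_auc <- function(positives, negatives) {
  if (!length(positives) || !length(negatives))
    stop("both groups must be non-empty")
  cmp <- outer(positives, negatives, ">") + 0.5 * outer(positives, negatives, "==")
  auc <- mean(cmp)
  if (auc >= 0.5) list(auc = auc, direction = "greater-is-positive")
  else list(auc = 1 - auc, direction = "lesser-is-positive")
}

#' Youden-index optimal cutoff
#'
#' Scans every candidate threshold (midpoints between adjacent sorted
#' unique values, plus sentinels outside the data range) and returns the
#' one maximizing Youden's J = sensitivity + specificity - 1. Ties are
#' broken toward higher specificity, then toward the lower cutoff.
#'
#' @param positives,negatives numeric vectors.
#' @param direction \code{"greater-is-positive"} (a value above the cutoff
#'   calls positive) or \code{"lesser-is-positive"}.
#' @return list with \code{cutoff}, \code{sensitivity}, \code{specificity},
#'   and \code{youden}.
#' @export
youden_cutoff <- function(positives, negatives,
                          direction = c("greater-is-positive", "lesser-is-positive")) {
  direction <- match.arg(direction)
  if (!length(positives) || !length(negatives))
    stop("both groups must be non-empty")
  v <- sort(unique(c(positives, negatives)))
  cand <- c(v[1L] - 1, if (length(v) > 1L) (v[-length(v)] + v[-1L]) / 2, v[length(v)] + 1)
  best <- NULL
  for (cut in cand) {
    if (direction == "greater-is-positive") {
      sens <- mean(positives > cut); spec <- mean(negatives <= cut)
    } else {
      sens <- mean(positives < cut); spec <- mean(negatives >= cut)
    }
    j <- sens + spec - 1
    if (is.null(best) || j > best$youden + 1e-12 ||
        (abs(j - best$youden) <= 1e-12 && (spec > best$specificity + 1e-12 ||
          (abs(spec - best$specificity) <= 1e-12 && cut < best$cutoff)))) {
      best <- list(cutoff = cut, sensitivity = sens, specificity = spec, youden = j)
    }
  }
  best
}

#' Closed-form binormal AUC
#'
#' For two normal populations the AUC has the closed form
#' \deqn{\Phi\!\left(\frac{\mu_+-\mu_-}{\sqrt{\sigma_+^2+\sigma_-^2}}\right),}
#' oriented so the result is >= 0.5. Useful as the theoretical center of
#' Monte-Carlo AUC estimates.
#'
#' @param mean_pos,sd_pos,mean_neg,sd_neg moments of the two populations;
#'   sds > 0.
#' @return AUC in [0.5, 1].
#' @export
binormal_auc <- function(mean_pos, sd_pos, mean_neg, sd_neg) {
  if (sd_pos <= 0 || sd_neg <= 0) stop("sds must be > 0")
  auc <- stats::pnorm((mean_pos - mean_neg) / sqrt(sd_pos^2 + sd_neg^2))
  max(auc, 1 - auc)
}

#' Diagnostic-value band of an AUC
#'
#' The conventional interpretation scale: [0.5, 0.7) low, [0.7, 0.9]
#' moderate, (0.9, 1] high diagnostic value (the boundary 0.9 itself is
#' "moderate"; "high" requires strictly greater than 0.9).
#'
#' @param auc numeric in [0.5, 1].
#' @return \code{"low"}, \code{"moderate"}, or \code{"high"}.
#' @export
classify_auc <- function(auc) {
  if (!is.finite(auc) || auc < 0.5 || auc > 1)
    stop("auc must lie in [0.5, 1]")
  if (auc > 0.9) "high" else if (auc >= 0.7) "moderate" else "low"
}

#' Pairwise ROC table across grade groups
#'
#' For each grade pair (PD vs WD, PD vs MD, MD vs WD) and each parameter,
#' computes the empirical AUC, the Youden-optimal cutoff, and its
#' sensitivity/specificity, with the less-differentiated group of the pair
#' as the positive class. With \code{select = "significant"} (default) a
#' row is emitted only when the parameter discriminates that pair in the
#' group comparison (significant omnibus test and, on the ANOVA path, a
#' significant pairwise LSD p); \code{select = "all"} emits every row.
#' Cutoffs for D and D* are reported in display units (10^-3 and 10^-2
#' mm^2/s).
#'
#' @param cohort an \code{\link{ivim_cohort}}.
#' @param parameters parameters to evaluate.
#' @param model_tags fitting models to evaluate.
#' @param select row-selection rule.
#' @param alpha significance level for the selection rule.
#' @return data.frame with columns \code{comparison, parameter, model,
#'   cutoff, auc, sensitivity, specificity, direction, band}.
#' @export
pairwise_roc_table <- function(cohort, parameters = c("D", "D_star", "f"),
                               model_tags = c("mono", "bi"),
                               select = c("significant", "all"),
                               alpha = 0.05) {
  select <- match.arg(select)
  unit_scale <- c(D = 1e3, D_star = 1e2, f = 1)
  pairs <- list(c(pos = "PD", neg = "WD"), c(pos = "PD", neg = "MD"),
                c(pos = "MD", neg = "WD"))
  rows <- list()
  for (model in model_tags) for (par in parameters) {
    cmp <- compare_parameter(cohort, par, model, alpha)
    groups <- grade_groups(cohort, par, model)
    for (pr in pairs) {
      label <- paste(pr[["pos"]], "vs", pr[["neg"]])
      if (select == "significant") {
        if (cmp$omnibus_p >= alpha) next
        pw <- cmp$pairwise_p[[label]]
        if (cmp$test == "ANOVA" && (is.na(pw) || pw >= alpha)) next
      }
      res <- mann_whitney_auc(groups[[pr[["pos"]]]], groups[[pr[["neg"]]]])
      yj <- youden_cutoff(groups[[pr[["pos"]]]], groups[[pr[["neg"]]]],
                          direction = res$direction)
      rows[[length(rows) + 1L]] <- data.frame(
        comparison = label, parameter = par, model = model,
        cutoff = yj$cutoff * unit_scale[[par]], auc = res$auc,
        sensitivity = yj$sensitivity, specificity = yj$specificity,
        direction = res$direction, band = classify_auc(res$auc),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}
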