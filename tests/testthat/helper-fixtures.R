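# Published per-grade group means used as generating truths throughout the
# suite (D and D* in mm^2/s, f dimensionless).
wd_mono <- ivim_params(D = 1.48e-3, D_star = 2.65e-2, f = 0.16)
md_mono <- ivim_params(D = 1.22e-3, D_star = 1.88e-2, f = 0.23)
pd_mono <- ivim_params(D = 1.05e-3, D_star = 1.25e-2, f = 0.32)
wd_bi   <- ivim_params(D = 1.33e-3, D_star = 2.82e-2, f = 0.18)
pd_bi   <- ivim_params(D = 0.91e-3, D_star = 1.67e-2, f = 0.35)

scheme10 <- default_scheme()

# independent trapezoidal ROC area: sweep thresholds over all observed
# values, accumulate (FPR, TPR) points, integrate
trapezoid_auc <- function(positives, negatives) {
  thr <- sort(unique(c(positives, negatives, -Inf, Inf)), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(positives >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(negatives >= t), numeric(1))
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

# brute-force Youden scan over every observed value and gap midpoint
youden_bruteforce <- function(positives, negatives, direction) {
  v <- sort(unique(c(positives, negatives)))
  cand <- sort(unique(c(v - 1e-9, v, v + 1e-9,
                        (v[-length(v)] + v[-1]) / 2, v[1] - 1, v[length(v)] + 1)))
  best_j <- -Inf
  for (cut in cand) {
    if (direction == "greater-is-positive") {
      j <- mean(positives > cut) + mean(negatives <= cut) - 1
    } else {
      j <- mean(positives < cut) + mean(negatives >= cut) - 1
    }
    if (j > best_j) best_j <- j
  }
  best_j
}
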