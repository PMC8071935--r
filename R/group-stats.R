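#' Shapiro-Wilk normality gate
#'
#' Thin wrapper used as the routing gate of the group comparison: each
#' grade group's parameter values are tested at alpha = 0.05; only when all
#' three groups pass is the parametric (ANOVA + LSD) path taken.
#' A zero-variance vector cannot be tested and is reported as a gate
#' failure (p = 0).
#'
#' @param values numeric vector, n >= 3.
#' @return the Shapiro-Wilk p-value.
#' @export
shapiro_normality <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 3L) stop("Shapiro-Wilk needs at least 3 observations")
  if (stats::sd(values) == 0) return(0)
  stats::shapiro.test(values)$p.value
}

#' One-way ANOVA across grade groups
#'
#' Classical equal-variance one-way analysis of variance. Degenerate input
#' (zero within- and between-group variance) returns F = 0, p = 1.
#'
#' @param groups list of numeric vectors, each n >= 2.
#' @return list with \code{F} and \code{p}.
#' @export
one_way_anova <- function(groups) {
  if (any(vapply(groups, length, integer(1)) < 2L))
    stop("each group needs at least 2 observations")
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  if (stats::sd(x) == 0) return(list(F = 0, p = 1))
  out <- stats::oneway.test(x ~ g, var.equal = TRUE)
  list(F = unname(out$statistic), p = unname(out$p.value))
}

#' Fisher's least-significant-difference post hoc
#'
#' Unadjusted pairwise t tests that reuse the pooled within-group mean
#' square error and error degrees of freedom of the three-group ANOVA --
#' the classical LSD procedure, with no multiplicity correction.
#'
#' @param groups named list of numeric vectors (names default to
#'   group1..k).
#' @return data.frame with columns \code{pair, t, p}, one row per
#'   unordered group pair.
#' @export
lsd_posthoc <- function(groups) {
  k <- length(groups)
  if (k < 2L) stop("need at least two groups")
  if (is.null(names(groups))) names(groups) <- paste0("group", seq_len(k))
  n <- vapply(groups, length, integer(1))
  if (any(n < 2L)) stop("each group needs at least 2 observations")
  means <- vapply(groups, mean, numeric(1))
  sse <- sum(vapply(groups, function(v) sum((v - mean(v))^2), numeric(1)))
  df_err <- sum(n) - k
  mse <- sse / df_err
  pairs <- utils::combn(k, 2L)
  rows <- apply(pairs, 2L, function(ij) {
    i <- ij[1L]; j <- ij[2L]
    se <- sqrt(mse * (1 / n[i] + 1 / n[j]))
    tstat <- if (se == 0) 0 else (means[i] - means[j]) / se
    data.frame(pair = paste(names(groups)[i], "vs", names(groups)[j]),
               t = tstat, p = 2 * stats::pt(-abs(tstat), df_err),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Kruskal-Wallis rank test
#'
#' Nonparametric fallback when any group fails the normality gate. All-tied
#' data returns H = 0, p = 1.
#'
#' @param groups list of numeric vectors, each n >= 2.
#' @return list with \code{H} and \code{p}.
#' @export
kruskal_wallis <- function(groups) {
  if (any(vapply(groups, length, integer(1)) < 2L))
    stop("each group needs at least 2 observations")
  x <- unlist(groups, use.names = FALSE)
  if (stats::sd(x) == 0) return(list(H = 0, p = 1))
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  out <- stats::kruskal.test(x, g)
  list(H = unname(out$statistic), p = unname(out$p.value))
}

grade_groups <- function(cohort, parameter, model_tag) {
  tab <- cohort_table(cohort)
  tab <- tab[tab$model == model_tag, , drop = FALSE]
  lapply(stats::setNames(nm = c("WD", "MD", "PD")),
         function(g) tab[[parameter]][tab$grade == g])
}

#' Compare one parameter across the three grade groups
#'
#' Applies the study's decision rule: Shapiro-Wilk on each group at
#' alpha = 0.05; if all three pass, one-way ANOVA with LSD post hoc;
#' otherwise Kruskal-Wallis with no post hoc. Pairwise p-values are
#' reported only on the ANOVA path and only when the omnibus test is
#' significant, mirroring the usual grading-table layout.
#'
#' @param cohort an \code{\link{ivim_cohort}}.
#' @param parameter \code{"D"}, \code{"D_star"}, or \code{"f"}.
#' @param model_tag \code{"mono"} or \code{"bi"}.
#' @param alpha significance level for the gate and the omnibus test.
#' @return list of class \code{group_comparison}: per-group mean/sd,
#'   normality p-values, omnibus test name and p, and pairwise p-values
#'   (PD vs WD, PD vs MD, MD vs WD) or NA.
#' @export
compare_parameter <- function(cohort, parameter = c("D", "D_star", "f"),
                              model_tag = c("mono", "bi"), alpha = 0.05) {
  parameter <- match.arg(parameter)
  model_tag <- match.arg(model_tag)
  groups <- grade_groups(cohort, parameter, model_tag)
  if (any(vapply(groups, length, integer(1)) == 0L))
    stop("cohort is missing a grade group")
  norm_p <- vapply(groups, shapiro_normality, numeric(1))
  normal <- all(norm_p > alpha)
  pairwise <- c("PD vs WD" = NA_real_, "PD vs MD" = NA_real_, "MD vs WD" = NA_real_)
  if (normal) {
    omni <- one_way_anova(groups)
    test <- "ANOVA"
    if (omni$p < alpha) {
      lsd <- lsd_posthoc(groups)
      get_p <- function(a, b) lsd$p[lsd$pair %in% c(paste(a, "vs", b), paste(b, "vs", a))]
      pairwise <- c("PD vs WD" = get_p("PD", "WD"),
                    "PD vs MD" = get_p("PD", "MD"),
                    "MD vs WD" = get_p("MD", "WD"))
    }
    omni_p <- omni$p
  } else {
    omni <- kruskal_wallis(groups)
    test <- "Kruskal-Wallis"
    omni_p <- omni$p
  }
  structure(list(parameter = parameter, model = model_tag,
                 group_mean = vapply(groups, mean, numeric(1)),
                 group_sd = vapply(groups, stats::sd, numeric(1)),
                 normality_p = norm_p, test = test, omnibus_p = omni_p,
                 pairwise_p = pairwise),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s (%s): %s p = %.4g\n", x$parameter, x$model, x$test, x$omnibus_p))
  invisible(x)
}

#' Spearman correlation of a parameter with grade
#'
#' Rank correlation between per-patient parameter values and an integer
#' grade coding. The default coding PD = 1 < MD = 2 < WD = 3 makes the
#' diffusion coefficient correlate positively with differentiation (D is
#' largest in well-differentiated tumors) and the perfusion fraction
#' negatively (f is largest in poorly differentiated tumors).
#'
#' @param cohort an \code{\link{ivim_cohort}}.
#' @param parameter \code{"D"}, \code{"D_star"}, or \code{"f"}.
#' @param model_tag \code{"mono"} or \code{"bi"}.
#' @param coding named integer vector mapping the three grades to distinct
#'   ranks.
#' @return list with \code{rho} and \code{p}.
#' @export
spearman_grade <- function(cohort, parameter = c("D", "D_star", "f"),
                           model_tag = c("mono", "bi"),
                           coding = c(PD = 1L, MD = 2L, WD = 3L)) {
  parameter <- match.arg(parameter)
  model_tag <- match.arg(model_tag)
  if (length(unique(coding[c("PD", "MD", "WD")])) != 3L)
    stop("coding must assign distinct integers to PD, MD, WD")
  tab <- cohort_table(cohort)
  tab <- tab[tab$model == model_tag, , drop = FALSE]
  x <- tab[[parameter]]
  if (stats::sd(x) == 0) stop("constant parameter vector: rho undefined")
  g <- as.numeric(coding[tab$grade])
  ct <- suppressWarnings(stats::cor.test(x, g, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = unname(ct$p.value))
}

#' Grading comparison table for all six parameters
#'
#' Runs \code{\link{compare_parameter}} for D, D*, f under both fitting
#' models and assembles the per-group summary table (display units:
#' D in 10^-3 mm^2/s, D* in 10^-2 mm^2/s, f dimensionless).
#'
#' @param cohort an \code{\link{ivim_cohort}}.
#' @param alpha significance level.
#' @return data.frame with one row per parameter-model combination.
#' @export
grading_table <- function(cohort, alpha = 0.05) {
  unit_scale <- c(D = 1e3, D_star = 1e2, f = 1)
  rows <- list()
  for (model in c("mono", "bi")) for (par in c("D", "D_star", "f")) {
    cmp <- compare_parameter(cohort, par, model, alpha)
    sc <- unit_scale[[par]]
    rows[[length(rows) + 1L]] <- data.frame(
      parameter = par, model = model,
      WD_mean = cmp$group_mean[["WD"]] * sc, WD_sd = cmp$group_sd[["WD"]] * sc,
      MD_mean = cmp$group_mean[["MD"]] * sc, MD_sd = cmp$group_sd[["MD"]] * sc,
      PD_mean = cmp$group_mean[["PD"]] * sc, PD_sd = cmp$group_sd[["PD"]] * sc,
      test = cmp$test, omnibus_p = cmp$omnibus_p,
      p_PD_WD = cmp$pairwise_p[["PD vs WD"]],
      p_PD_MD = cmp$pairwise_p[["PD vs MD"]],
      p_MD_WD = cmp$pairwise_p[["MD vs WD"]],
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Correlation table of every parameter with grade
#'
#' @param cohort an \code{\link{ivim_cohort}}.
#' @param coding grade coding passed to \code{\link{spearman_grade}}.
#' @return data.frame with columns \code{parameter, model, rho, p}.
#' @export
correlation_table <- function(cohort, coding = c(PD = 1L, MD = 2L, WD = 3L)) {
  rows <- list()
  for (model in c("mono", "bi")) for (par in c("D", "D_star", "f")) {
    ct <- spearman_grade(cohort, par, model, coding)
    rows[[length(rows) + 1L]] <- data.frame(parameter = par, model = model,
                                            rho = ct$rho, p = ct$p,
                                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
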