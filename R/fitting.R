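#' Fitting configuration
#'
#' Controls both estimation strategies. The b-value threshold splits the
#' scheme into a low part (b <= threshold) and a high part (b > threshold);
#' the conventional threshold is 200 s/mm^2, above which the perfusion term
#' f exp(-b D*) is negligible for D* >> D. Bounds bracket physiologically
#' plausible esophageal-tumor values with wide margins.
#'
#' @param b_threshold split point in s/mm^2 (default 200); the high set is
#'   b strictly greater than the threshold.
#' @param D_bounds,D_star_bounds,f_bounds closed parameter intervals,
#'   mm^2/s for the diffusivities.
#' @param max_iterations iteration cap for the full nonlinear fit.
#' @param convergence_tol relative tolerance on residual-sum-of-squares
#'   change declaring convergence.
#' @param init_strategy \code{"segmented-init"} (default: start the full fit
#'   from the segmented estimates) or \code{"fixed-init"} (geometric
#'   mid-bounds start).
#' @param dstar_b_range which b values enter the fixed-D,f pseudo-diffusion
#'   step: \code{"all"} (default) or \code{"low"}.
#' @return an object of class \code{fit_config}.
#' @export
fit_config <- function(b_threshold = 200,
                       D_bounds = c(1e-5, 5e-3),
                       D_star_bounds = c(1e-3, 0.5),
                       f_bounds = c(0, 1),
                       max_iterations = 500L,
                       convergence_tol = 1e-10,
                       init_strategy = c("segmented-init", "fixed-init"),
                       dstar_b_range = c("all", "low")) {
  chk <- function(b, nm) {
    if (length(b) != 2L || b[1L] >= b[2L]) stop(nm, " must be a (lower, upper) interval")
  }
  chk(D_bounds, "D_bounds"); chk(D_star_bounds, "D_star_bounds"); chk(f_bounds, "f_bounds")
  if (b_threshold <= 0) stop("b_threshold must be positive")
  structure(list(
    b_threshold = b_threshold,
    D_bounds = D_bounds, D_star_bounds = D_star_bounds, f_bounds = f_bounds,
    max_iterations = as.integer(max_iterations),
    convergence_tol = convergence_tol,
    init_strategy = match.arg(init_strategy),
    dstar_b_range = match.arg(dstar_b_range)
  ), class = "fit_config")
}

# threshold below which an estimated perfusion fraction leaves D*
# unidentifiable (the perfusion term carries no signal)
F_IDENTIFIABILITY_MIN <- 0.005

#' Split a scheme at the b-value threshold
#'
#' @param scheme a \code{\link{bvalue_scheme}}.
#' @param threshold split point in s/mm^2; high set is b > threshold,
#'   low set is b <= threshold.
#' @return list with integer index vectors \code{low} and \code{high}.
#'   At least three high-b points are required for the log-linear step.
#' @export
split_b <- function(scheme, threshold) {
  stopifnot(inherits(scheme, "bvalue_scheme"))
  if (threshold <= min(scheme$b_values) || threshold >= max(scheme$b_values))
    stop("threshold must lie strictly inside the scheme's b range")
  high <- which(scheme$b_values > threshold)
  low <- which(scheme$b_values <= threshold)
  if (length(high) < 3L)
    stop("fewer than 3 b values above the threshold: segmented fit infeasible")
  list(low = low, high = high)
}

#' High-b log-linear diffusion estimate
#'
#' Ordinary least squares of log(Sb/S0) on b over the high-b subset, where
#' the decay is mono-exponential: D is minus the slope and the extrapolated
#' b = 0 intercept (on the signal scale) estimates the diffusion-only
#' fraction 1 - f. An intercept above 1 is clamped to 1 (implying f = 0)
#' and flagged.
#'
#' @param curve a \code{\link{signal_curve}}.
#' @param config a \code{\link{fit_config}}.
#' @return list with \code{D}, \code{intercept}, and logical
#'   \code{intercept_clamped}.
#' @export
fit_high_b_linear <- function(curve, config = fit_config()) {
  stopifnot(inherits(curve, "signal_curve"))
  idx <- split_b(curve$scheme, config$b_threshold)$high
  s <- curve$signal[idx]
  if (any(s <= 0)) stop("non-positive signal in the high-b set: log fit undefined")
  b <- curve$scheme$b_values[idx]
  fit <- stats::lm.fit(cbind(1, b), log(s))
  D <- -fit$coefficients[[2L]]
  intercept <- exp(fit$coefficients[[1L]])
  clamped <- intercept > 1
  if (clamped) intercept <- 1
  list(D = D, intercept = intercept, intercept_clamped = clamped)
}

#' Pseudo-diffusion estimate with D and f held fixed
#'
#' One-dimensional bounded least squares of the bi-exponential model in
#' signal space: with D and f fixed at their segmented estimates, D* is the
#' minimizer of the squared residuals over the configured b range.
#'
#' @param curve a \code{\link{signal_curve}}.
#' @param D,f fixed diffusion coefficient (mm^2/s) and perfusion fraction;
#'   f must exceed the identifiability floor of 0.005.
#' @param config a \code{\link{fit_config}}; \code{dstar_b_range} selects
#'   all b values (default) or the low set only.
#' @return list with \code{D_star} and logical \code{boundary_hit}.
#' @export
fit_dstar_fixed <- function(curve, D, f, config = fit_config()) {
  stopifnot(inherits(curve, "signal_curve"))
  if (f <= F_IDENTIFIABILITY_MIN)
    stop("f too small: pseudo-diffusion coefficient is not identifiable")
  idx <- if (config$dstar_b_range == "low")
    split_b(curve$scheme, config$b_threshold)$low
  else seq_along(curve$scheme$b_values)
  b <- curve$scheme$b_values[idx]
  s <- curve$signal[idx]
  tissue <- (1 - f) * exp(-b * D)
  obj <- function(ds) sum((f * exp(-b * ds) + tissue - s)^2)
  lo <- config$D_star_bounds[1L]; hi <- config$D_star_bounds[2L]
  opt <- stats::optimize(obj, lower = lo, upper = hi, tol = 1e-12)
  ds <- opt$minimum
  # optimize() never returns the exact endpoints; treat near-boundary as a hit
  hit <- (ds - lo) < 1e-6 * (hi - lo) || (hi - ds) < 1e-6 * (hi - lo)
  list(D_star = ds, boundary_hit = hit)
}

new_fit_result <- function(params, model_tag, rss, converged, n_low, n_high,
                           iterations = NA_integer_, flags = character()) {
  structure(list(
    params = params, model_tag = model_tag, rss = rss, converged = converged,
    n_points_low = n_low, n_points_high = n_high,
    diagnostics = list(iterations = iterations, flags = flags)
  ), class = "ivim_fit")
}

#' @export
print.ivim_fit <- function(x, ...) {
  cat(sprintf("IVIM %s fit: D = %.4g x10^-3, D* = %.4g x10^-2 mm^2/s, f = %.3f (rss %.3g)\n",
              x$model_tag, x$params$D * 1e3, x$params$D_star * 1e2, x$params$f, x$rss))
  if (length(x$diagnostics$flags))
    cat("  flags:", paste(x$diagnostics$flags, collapse = ", "), "\n")
  invisible(x)
}

fit_rss <- function(curve, params) {
  sum((ivim_signal(params, curve$scheme$b_values) - curve$signal)^2)
}

#' Segmented mono-exponential IVIM fit
#'
#' The classical asymptotic three-step estimator: (1) D and the b = 0
#' intercept from the high-b log-linear fit (\code{\link{fit_high_b_linear}});
#' (2) f = 1 - intercept, the normalized form of (S0 - Sb)/S0 with the
#' extrapolated intercept standing in for the diffusion-only b = 0 signal;
#' (3) D* from the fixed-D,f one-dimensional step
#' (\code{\link{fit_dstar_fixed}}). If the estimated f is at or below the
#' identifiability floor, D* is reported at its lower bound and flagged.
#'
#' @param curve a \code{\link{signal_curve}}.
#' @param config a \code{\link{fit_config}}.
#' @return an \code{ivim_fit} object with \code{model_tag = "mono"}.
#' @examples
#' p <- ivim_params(1.05e-3, 1.25e-2, 0.32)
#' fit_mono_segmented(ivim_signal_curve(p, default_scheme()))
#' @export
fit_mono_segmented <- function(curve, config = fit_config()) {
  stopifnot(inherits(curve, "signal_curve"))
  parts <- split_b(curve$scheme, config$b_threshold)
  hb <- fit_high_b_linear(curve, config)
  flags <- character()
  if (hb$intercept_clamped) flags <- c(flags, "intercept_clamped")
  D <- min(max(hb$D, config$D_bounds[1L]), config$D_bounds[2L])
  if (D != hb$D) flags <- c(flags, "D_at_bound")
  f <- min(max(1 - hb$intercept, config$f_bounds[1L]), config$f_bounds[2L])
  if (f <= F_IDENTIFIABILITY_MIN) {
    ds <- config$D_star_bounds[1L]
    flags <- c(flags, "dstar_not_identifiable")
  } else {
    step <- fit_dstar_fixed(curve, D, f, config)
    ds <- step$D_star
    if (step$boundary_hit) flags <- c(flags, "dstar_at_bound")
  }
  params <- ivim_params(D, ds, f)
  new_fit_result(params, "mono", fit_rss(curve, params), TRUE,
                 length(parts$low), length(parts$high), flags = flags)
}

#' Full bi-exponential IVIM fit
#'
#' Simultaneous bounded nonlinear least squares of (D, D*, f) in the
#' bi-exponential model over all b values, using the Levenberg-Marquardt
#' algorithm (\code{minpack.lm}). By default the optimizer starts from the
#' segmented estimates; \code{init_strategy = "fixed-init"} starts from
#' geometric mid-bounds values instead. The full fit's residual sum of
#' squares never exceeds that of its starting point. If the optimum has
#' D* <= D the labels are ambiguous: when swapping (D, D*) and complementing
#' f leaves the residual unchanged the canonical ordering D <= D* is
#' restored, otherwise the fit is flagged.
#'
#' @param curve a \code{\link{signal_curve}} with at least 5 distinct
#'   b values.
#' @param config a \code{\link{fit_config}}.
#' @return an \code{ivim_fit} object with \code{model_tag = "bi"}.
#' @examples
#' p <- ivim_params(1.33e-3, 2.82e-2, 0.18)
#' fit_bi_full(ivim_signal_curve(p, default_scheme()))
#' @export
fit_bi_full <- function(curve, config = fit_config()) {
  stopifnot(inherits(curve, "signal_curve"))
  b <- curve$scheme$b_values
  if (length(unique(b)) < 5L) stop("full fit needs at least 5 distinct b values")
  s <- curve$signal
  flags <- character()

  if (config$init_strategy == "segmented-init") {
    seg <- fit_mono_segmented(curve, config)
    start <- c(D = seg$params$D,
               D_star = max(seg$params$D_star, config$D_star_bounds[1L] * 1.01),
               f = min(max(seg$params$f, 0.01), 0.99))
  } else {
    start <- c(D = exp(mean(log(config$D_bounds))),
               D_star = exp(mean(log(config$D_star_bounds))),
               f = 0.2)
  }
  lower <- c(config$D_bounds[1L], config$D_star_bounds[1L], config$f_bounds[1L])
  upper <- c(config$D_bounds[2L], config$D_star_bounds[2L], config$f_bounds[2L])
  start <- pmin(pmax(start, lower), upper)

  resid_fn <- function(p) p[3L] * exp(-b * p[2L]) + (1 - p[3L]) * exp(-b * p[1L]) - s
  ctrl <- minpack.lm::nls.lm.control(maxiter = config$max_iterations,
                                     ftol = config$convergence_tol,
                                     ptol = 1e-12)
  fit <- minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                            fn = resid_fn, control = ctrl)
  p <- pmin(pmax(unname(fit$par), lower), upper)
  rss <- sum(resid_fn(p)^2)
  start_rss <- sum(resid_fn(unname(start))^2)
  if (rss > start_rss) {           # optimizer never beat its start: keep start
    p <- unname(start); rss <- start_rss
    flags <- c(flags, "no_improvement")
  }
  converged <- fit$info %in% 1:4
  if (!converged) flags <- c(flags, "not_converged")
  if (any(abs(p - lower) < 1e-12) || any(abs(p - upper) < 1e-12))
    flags <- c(flags, "at_bound")
  if (p[3L] <= F_IDENTIFIABILITY_MIN) flags <- c(flags, "dstar_not_identifiable")

  if (p[2L] <= p[1L] && !"dstar_not_identifiable" %in% flags) {
    swapped <- c(p[2L], p[1L], 1 - p[3L])
    if (all(swapped >= lower & swapped <= upper) &&
        abs(sum(resid_fn(swapped)^2) - rss) <= 1e-12 + 1e-8 * rss) {
      p <- swapped
      flags <- c(flags, "labels_swapped")
    } else {
      flags <- c(flags, "dstar_below_D")
    }
  }

  parts <- split_b(curve$scheme, config$b_threshold)
  params <- ivim_params(max(p[1L], 1e-12), max(p[2L], 1e-12), p[3L])
  new_fit_result(params, "bi", rss, converged,
                 length(parts$low), length(parts$high),
                 iterations = fit$niter, flags = flags)
}

#' Fit a set of decay curves with one or both models
#'
#' Convenience wrapper producing the per-ROI parameter table used by the
#' pipeline and the command-line interface.
#'
#' @param curves a named list of \code{\link{signal_curve}} objects (names
#'   are ROI ids) or a single curve.
#' @param model \code{"both"} (default), \code{"mono"}, or \code{"bi"}.
#' @param config a \code{\link{fit_config}}.
#' @return data.frame with columns \code{roi_id, model, D, D_star, f, rss,
#'   converged, flags} (D and D* in mm^2/s).
#' @export
fit_curves <- function(curves, model = c("both", "mono", "bi"),
                       config = fit_config()) {
  model <- match.arg(model)
  if (inherits(curves, "signal_curve")) curves <- list(roi1 = curves)
  ids <- names(curves)
  if (is.null(ids)) ids <- paste0("roi", seq_along(curves))
  tags <- switch(model, both = c("mono", "bi"), mono = "mono", bi = "bi")
  rows <- list()
  for (i in seq_along(curves)) {
    for (tag in tags) {
      ft <- if (tag == "mono") fit_mono_segmented(curves[[i]], config)
            else fit_bi_full(curves[[i]], config)
      rows[[length(rows) + 1L]] <- data.frame(
        roi_id = ids[i], model = tag,
        D = ft$params$D, D_star = ft$params$D_star, f = ft$params$f,
        rss = ft$rss, converged = ft$converged,
        flags = paste(ft$diagnostics$flags, collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
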