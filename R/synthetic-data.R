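#' Grade-specific generating distribution
#'
#' Describes one differentiation-grade group of a simulated cohort: its
#' size and the means and standard deviations of the generating normal
#' distributions for (D, D*, f). Parameters are drawn independently and
#' truncated to their physical ranges.
#'
#' @param grade one of \code{"WD"}, \code{"MD"}, \code{"PD"} (well-,
#'   moderately-, poorly-differentiated).
#' @param n group size (> 0).
#' @param means,sds numeric length-3 vectors (D, D_star, f), diffusivities
#'   in mm^2/s; all sds > 0.
#' @return an object of class \code{grade_spec}.
#' @export
grade_spec <- function(grade = c("WD", "MD", "PD"), n, means, sds) {
  grade <- match.arg(grade)
  if (n <= 0) stop("group size must be positive")
  means <- as.numeric(means); sds <- as.numeric(sds)
  if (length(means) != 3L || length(sds) != 3L)
    stop("means and sds must have length 3 (D, D_star, f)")
  if (any(sds <= 0)) stop("all sds must be > 0")
  structure(list(grade = grade, n = as.integer(n),
                 means = stats::setNames(means, c("D", "D_star", "f")),
                 sds = stats::setNames(sds, c("D", "D_star", "f"))),
            class = "grade_spec")
}

#' Default grade distributions for an esophageal squamous-cell cohort
#'
#' Group sizes 20 (WD), 20 (MD), 14 (PD) with per-grade parameter means and
#' SDs reported for a three-grade esophageal-tumor cohort. The
#' \code{"mono"} set (default) carries the segmented-model summary values
#' (D decreasing, f increasing from WD to PD); \code{"bi"} carries the
#' full-fit summary values.
#'
#' @param model which published parameter set generates the truth:
#'   \code{"mono"} (default) or \code{"bi"}.
#' @return list of three \code{\link{grade_spec}} objects named WD, MD, PD.
#' @export
default_grade_specs <- function(model = c("mono", "bi")) {
  model <- match.arg(model)
  tab <- if (model == "mono") list(
    WD = list(m = c(1.48e-3, 2.65e-2, 0.16), s = c(0.51e-3, 1.96e-2, 0.05)),
    MD = list(m = c(1.22e-3, 1.88e-2, 0.23), s = c(0.39e-3, 1.26e-2, 0.08)),
    PD = list(m = c(1.05e-3, 1.25e-2, 0.32), s = c(0.44e-3, 0.56e-2, 0.07))
  ) else list(
    WD = list(m = c(1.33e-3, 2.82e-2, 0.18), s = c(0.54e-3, 1.63e-2, 0.07)),
    MD = list(m = c(1.17e-3, 2.21e-2, 0.26), s = c(0.51e-3, 1.41e-2, 0.10)),
    PD = list(m = c(0.91e-3, 1.67e-2, 0.35), s = c(0.45e-3, 0.78e-2, 0.08))
  )
  n <- c(WD = 20L, MD = 20L, PD = 14L)
  stats::setNames(lapply(names(tab), function(g)
    grade_spec(g, n[[g]], tab[[g]]$m, tab[[g]]$s)), names(tab))
}

#' Cohort simulation configuration
#'
#' @param grade_specs list of three \code{\link{grade_spec}} objects
#'   (default: \code{\link{default_grade_specs}()}).
#' @param scheme acquisition design (default: \code{\link{default_scheme}()}).
#' @param snr0 signal-to-noise ratio at b = 0 per single excitation
#'   (noise SD per channel is 1/snr0 on the normalized scale); \code{Inf}
#'   switches noise off. Default 50, typical of 3T body DWI.
#' @param rois_per_patient regions of interest per patient (default 9:
#'   three ROIs on each of three tumor sections).
#' @param voxels_per_roi voxels averaged into each ROI curve (default 25,
#'   a proxy for a ~54 mm^2 ROI).
#' @param seed master integer seed; all randomness derives from it.
#' @return an object of class \code{cohort_config}.
#' @export
cohort_config <- function(grade_specs = default_grade_specs(),
                          scheme = default_scheme(),
                          snr0 = 50, rois_per_patient = 9L,
                          voxels_per_roi = 25L, seed = 1L) {
  if (!all(vapply(grade_specs, inherits, logical(1), "grade_spec")))
    stop("grade_specs must be grade_spec objects")
  if (snr0 <= 0) stop("snr0 must be positive")
  if (rois_per_patient < 1L) stop("rois_per_patient must be >= 1")
  if (voxels_per_roi < 1L) stop("voxels_per_roi must be >= 1")
  structure(list(grade_specs = grade_specs, scheme = scheme, snr0 = snr0,
                 rois_per_patient = as.integer(rois_per_patient),
                 voxels_per_roi = as.integer(voxels_per_roi),
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# counter-based seed stream: patient/replicate k's seed depends only on the
# master seed and k, never on how many draws preceded it
derive_seed <- function(seed, counter) {
  as.integer((as.double(seed) * 48271 + as.double(counter) * 2654435) %% 2147483629) + 1L
}

#' Draw ground-truth parameters for one subject
#'
#' Independent truncated-normal draws per parameter: D truncated to
#' (0, Inf), D* to (D, Inf) so the pseudo-diffusion pool is always the
#' faster one (the model's physical ordering), and f to (0.01, 0.9);
#' resampling with a 1000-attempt cap per parameter.
#'
#' @param spec a \code{\link{grade_spec}}.
#' @return an \code{\link{ivim_params}} object.
#' @export
sample_truth <- function(spec) {
  stopifnot(inherits(spec, "grade_spec"))
  draw_trunc <- function(mean, sd, lo, hi) {
    for (i in seq_len(1000L)) {
      x <- stats::rnorm(1L, mean, sd)
      if (x > lo && x < hi) return(x)
    }
    stop("could not draw a valid parameter in 1000 attempts; check the grade_spec")
  }
  D <- draw_trunc(spec$means[["D"]], spec$sds[["D"]], 0, Inf)
  Ds <- draw_trunc(spec$means[["D_star"]], spec$sds[["D_star"]], D, Inf)
  f <- draw_trunc(spec$means[["f"]], spec$sds[["f"]], 0.01, 0.9)
  ivim_params(D, Ds, f)
}

#' Rician magnitude noise with excitation averaging
#'
#' Magnitude-MRI noise model: each excitation observes
#' sqrt((A + g1)^2 + g2^2) with g1, g2 ~ N(0, sigma) corrupting the two
#' receiver channels; the scanner averages \code{nex} excitations per
#' b value. Noise SD is constant across b values (thermal noise); NEX
#' averaging is the only b-dependent noise reduction.
#'
#' @param clean_signal numeric vector of noise-free relative intensities.
#' @param sigma per-excitation noise SD on the normalized scale
#'   (1/snr0); 0 returns the input unchanged.
#' @param nex integer vector of excitation counts, recycled along
#'   \code{clean_signal}.
#' @return numeric vector of noisy relative intensities.
#' @export
add_rician_noise <- function(clean_signal, sigma, nex = 1L) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (any(nex < 1L)) stop("nex must be >= 1")
  if (sigma == 0) return(clean_signal)
  nex <- rep_len(as.integer(nex), length(clean_signal))
  vapply(seq_along(clean_signal), function(i) {
    g1 <- stats::rnorm(nex[i], 0, sigma)
    g2 <- stats::rnorm(nex[i], 0, sigma)
    mean(sqrt((clean_signal[i] + g1)^2 + g2^2))
  }, numeric(1))
}

#' Simulate one patient
#'
#' Draws one ground truth, then for each region of interest generates
#' \code{voxels_per_roi} noisy voxel curves from that truth, averages the
#' voxel signals into one ROI curve, renormalizes it by its b = 0 value,
#' and fits the ROI curve with both estimation strategies. The patient's
#' reported parameters are the arithmetic means of the per-ROI fits,
#' mirroring the measure-then-average protocol of ROI-based IVIM studies.
#'
#' @param spec a \code{\link{grade_spec}}.
#' @param config a \code{\link{cohort_config}}.
#' @param fitcfg a \code{\link{fit_config}}.
#' @param patient_id identifier string.
#' @return a list of class \code{ivim_patient}.
#' @export
simulate_patient <- function(spec, config, fitcfg = fit_config(),
                             patient_id = "p1") {
  truth <- sample_truth(spec)
  clean <- ivim_signal(truth, config$scheme$b_values)
  sigma <- if (is.infinite(config$snr0)) 0 else 1 / config$snr0
  nb <- length(clean)

  roi_curves <- vector("list", config$rois_per_patient)
  mono_fits <- matrix(NA_real_, config$rois_per_patient, 3L)
  bi_fits <- matrix(NA_real_, config$rois_per_patient, 3L)
  excluded <- FALSE; reason <- NA_character_
  for (r in seq_len(config$rois_per_patient)) {
    vox <- matrix(NA_real_, config$voxels_per_roi, nb)
    for (v in seq_len(config$voxels_per_roi))
      vox[v, ] <- add_rician_noise(clean, sigma, config$scheme$nex)
    roi_signal <- colMeans(vox)
    curve <- signal_curve(config$scheme, roi_signal, normalize = TRUE)
    roi_curves[[r]] <- curve
    res <- tryCatch({
      m <- fit_mono_segmented(curve, fitcfg)
      b <- fit_bi_full(curve, fitcfg)
      list(m = m, b = b)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      excluded <- TRUE; reason <- conditionMessage(res)
      break
    }
    mono_fits[r, ] <- c(res$m$params$D, res$m$params$D_star, res$m$params$f)
    bi_fits[r, ] <- c(res$b$params$D, res$b$params$D_star, res$b$params$f)
  }

  mk <- function(m) if (excluded) NULL else {
    v <- colMeans(m); ivim_params(v[1L], v[2L], v[3L])
  }
  structure(list(patient_id = patient_id, grade = spec$grade,
                 true_params = truth, roi_curves = roi_curves,
                 fitted_mono = mk(mono_fits), fitted_bi = mk(bi_fits),
                 excluded = excluded, exclusion_reason = reason),
            class = "ivim_patient")
}

#' Simulate a full graded cohort
#'
#' Deterministic given the config's seed: each patient's random stream is
#' derived from the master seed and the patient's position, so simulations
#' are reproducible and patient k's data do not depend on group ordering.
#' A grade group in which more than 10\% of patients fail to fit aborts the
#' simulation; isolated failures are recorded on the patient and excluded
#' from analysis tables.
#'
#' @param config a \code{\link{cohort_config}}.
#' @param fitcfg a \code{\link{fit_config}}.
#' @return an object of class \code{ivim_cohort}.
#' @examples
#' \donttest{
#' coh <- simulate_cohort(cohort_config(seed = 7))
#' nrow(cohort_table(coh))
#' }
#' @export
simulate_cohort <- function(config = cohort_config(), fitcfg = fit_config()) {
  patients <- list()
  counter <- 0L
  for (g in names(config$grade_specs)) {
    spec <- config$grade_specs[[g]]
    fails <- 0L
    for (i in seq_len(spec$n)) {
      counter <- counter + 1L
      pid <- sprintf("%s%02d", g, i)
      old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
      set.seed(derive_seed(config$seed, counter))
      p <- simulate_patient(spec, config, fitcfg, patient_id = pid)
      if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
      if (p$excluded) fails <- fails + 1L
      patients[[length(patients) + 1L]] <- p
    }
    if (fails > 0.1 * spec$n)
      stop("more than 10% of group ", g, " failed to fit; check the configuration")
  }
  structure(list(patients = patients, config = config, seed = config$seed),
            class = "ivim_cohort")
}

#' @export
print.ivim_cohort <- function(x, ...) {
  tab <- table(vapply(x$patients, `[[`, character(1), "grade"))
  cat("Simulated IVIM cohort:", length(x$patients), "patients (",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "), seed", x$seed, "\n")
  invisible(x)
}

#' Per-patient fitted-parameter and ground-truth tables
#'
#' @param cohort an \code{\link{ivim_cohort}}.
#' @return \code{cohort_table}: data.frame with one row per patient per
#'   model (\code{patient_id, grade, model, D, D_star, f}; diffusivities in
#'   mm^2/s), excluded patients omitted. \code{truth_table}: one row per
#'   patient with the generating parameters.
#' @export
cohort_table <- function(cohort) {
  stopifnot(inherits(cohort, "ivim_cohort"))
  rows <- lapply(cohort$patients, function(p) {
    if (p$excluded) return(NULL)
    data.frame(patient_id = rep(p$patient_id, 2L), grade = rep(p$grade, 2L),
               model = c("mono", "bi"),
               D = c(p$fitted_mono$D, p$fitted_bi$D),
               D_star = c(p$fitted_mono$D_star, p$fitted_bi$D_star),
               f = c(p$fitted_mono$f, p$fitted_bi$f),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @rdname cohort_table
#' @export
truth_table <- function(cohort) {
  stopifnot(inherits(cohort, "ivim_cohort"))
  do.call(rbind, lapply(cohort$patients, function(p)
    data.frame(patient_id = p$patient_id, grade = p$grade,
               D = p$true_params$D, D_star = p$true_params$D_star,
               f = p$true_params$f, excluded = p$excluded,
               stringsAsFactors = FALSE)))
}
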