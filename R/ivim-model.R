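#' B-value acquisition scheme
#'
#' Describes a diffusion-weighted acquisition design: the ordered diffusion
#' weightings (b values, s/mm^2) and the number of excitations (NEX) averaged
#' at each b value. The default corresponds to a ten-b-value esophageal
#' protocol at 3T: b = 0, 30, 50, 80, 150, 200, 400, 600, 800, 1000 s/mm^2
#' with NEX 2, 2, 2, 2, 2, 2, 2, 4, 6, 8.
#'
#' @param b_values numeric vector of b values in s/mm^2, strictly increasing,
#'   starting at 0.
#' @param nex integer vector of excitation counts (>= 1), same length as
#'   \code{b_values}.
#' @return an object of class \code{bvalue_scheme}.
#' @examples
#' sch <- default_scheme()
#' sch$b_values
#' @export
bvalue_scheme <- function(b_values, nex = rep(1L, length(b_values))) {
  b_values <- as.numeric(b_values)
  nex <- as.integer(nex)
  if (length(b_values) != length(nex))
    stop("b_values and nex must have the same length")
  if (length(b_values) < 2L)
    stop("a scheme needs at least two b values")
  if (b_values[1L] != 0)
    stop("the first b value must be 0 (the unweighted reference)")
  if (any(diff(b_values) <= 0))
    stop("b_values must be strictly increasing")
  if (any(nex < 1L))
    stop("all nex must be >= 1")
  structure(list(b_values = b_values, nex = nex), class = "bvalue_scheme")
}

#' @rdname bvalue_scheme
#' @export
default_scheme <- function() {
  bvalue_scheme(
    b_values = c(0, 30, 50, 80, 150, 200, 400, 600, 800, 1000),
    nex      = c(2, 2, 2, 2, 2, 2, 2, 4, 6, 8)
  )
}

#' @export
print.bvalue_scheme <- function(x, ...) {
  cat("B-value scheme:", length(x$b_values), "b values (s/mm^2)\n")
  print(data.frame(b = x$b_values, nex = x$nex), row.names = FALSE)
  invisible(x)
}

#' IVIM model parameters
#'
#' The parameter triple of the two-compartment intravoxel incoherent motion
#' model: the true (tissue) diffusion coefficient D, the pseudo-diffusion
#' coefficient D* attributed to capillary perfusion, and the perfusion
#' fraction f. D and D* are stored in mm^2/s throughout; display-unit
#' conversion (10^-3 / 10^-2 mm^2/s) happens only in reporting tables.
#'
#' @param D true diffusion coefficient, mm^2/s; must be > 0.
#' @param D_star pseudo-diffusion coefficient, mm^2/s; must be > 0 and is
#'   typically an order of magnitude larger than D.
#' @param f perfusion fraction in [0, 1].
#' @return an object of class \code{ivim_params}.
#' @examples
#' ivim_params(D = 1.48e-3, D_star = 2.65e-2, f = 0.16)
#' @export
ivim_params <- function(D, D_star, f) {
  if (!is.finite(D) || D <= 0) stop("D must be a positive number (mm^2/s)")
  if (!is.finite(D_star) || D_star <= 0) stop("D_star must be a positive number (mm^2/s)")
  if (!is.finite(f) || f < 0 || f > 1) stop("f must lie in [0, 1]")
  structure(list(D = D, D_star = D_star, f = f), class = "ivim_params")
}

#' @export
print.ivim_params <- function(x, ...) {
  cat(sprintf("IVIM parameters: D = %.4g x10^-3 mm^2/s, D* = %.4g x10^-2 mm^2/s, f = %.3f\n",
              x$D * 1e3, x$D_star * 1e2, x$f))
  invisible(x)
}

#' Bi-exponential IVIM signal model
#'
#' Relative diffusion-weighted signal Sb/S0 of the two-compartment IVIM
#' model:
#' \deqn{S_b/S_0 = f\,e^{-b D^*} + (1-f)\,e^{-b D}.}
#' Equals 1 at b = 0 and decreases strictly with b.
#'
#' @param params an \code{\link{ivim_params}} object.
#' @param b numeric vector of b values, s/mm^2, all >= 0.
#' @return numeric vector of relative signals in (0, 1].
#' @examples
#' p <- ivim_params(1.48e-3, 2.65e-2, 0.16)
#' ivim_signal(p, c(0, 200, 1000))
#' @export
ivim_signal <- function(params, b) {
  stopifnot(inherits(params, "ivim_params"))
  b <- as.numeric(b)
  if (any(!is.finite(b)) || any(b < 0)) stop("b values must be finite and >= 0")
  params$f * exp(-b * params$D_star) + (1 - params$f) * exp(-b * params$D)
}

#' Diffusion-only (high-b asymptote) signal
#'
#' The mono-exponential simplification valid where the perfusion term has
#' fully decayed (in practice b > 200 s/mm^2 when D* >> D):
#' \deqn{S_b/S_0 = (1-f)\,e^{-b D}.}
#'
#' @param D true diffusion coefficient, mm^2/s.
#' @param f perfusion fraction in [0, 1].
#' @param b numeric vector of b values, s/mm^2.
#' @return numeric vector of relative signals.
#' @export
diffusion_only_signal <- function(D, f, b) {
  if (!is.finite(D) || D <= 0) stop("D must be a positive number (mm^2/s)")
  if (!is.finite(f) || f < 0 || f > 1) stop("f must lie in [0, 1]")
  b <- as.numeric(b)
  if (any(!is.finite(b)) || any(b < 0)) stop("b values must be finite and >= 0")
  (1 - f) * exp(-b * D)
}

#' Signal-decay curve on an acquisition scheme
#'
#' A normalized decay curve: relative signals Sb/S0 sampled at the scheme's
#' b values. \code{signal_curve()} wraps existing values (optionally
#' renormalizing by the b = 0 entry); \code{ivim_signal_curve()} evaluates
#' the noise-free forward model.
#'
#' @param scheme a \code{\link{bvalue_scheme}}.
#' @param signal numeric vector of relative intensities, same length as the
#'   scheme's b values, all > 0.
#' @param normalize if TRUE (default), divide by the b = 0 entry so the curve
#'   starts exactly at 1.
#' @return an object of class \code{signal_curve}.
#' @export
signal_curve <- function(scheme, signal, normalize = TRUE) {
  stopifnot(inherits(scheme, "bvalue_scheme"))
  signal <- as.numeric(signal)
  if (length(signal) != length(scheme$b_values))
    stop("signal length must match the scheme's b values")
  if (any(!is.finite(signal)) || any(signal <= 0))
    stop("all signal values must be finite and > 0")
  if (normalize) signal <- signal / signal[1L]
  structure(list(scheme = scheme, signal = signal), class = "signal_curve")
}

#' @param params an \code{\link{ivim_params}} object.
#' @rdname signal_curve
#' @export
ivim_signal_curve <- function(params, scheme) {
  signal_curve(scheme, ivim_signal(params, scheme$b_values), normalize = FALSE)
}

#' @export
print.signal_curve <- function(x, ...) {
  cat("IVIM signal curve (Sb/S0):\n")
  print(data.frame(b = x$scheme$b_values, signal = signif(x$signal, 5)),
        row.names = FALSE)
  invisible(x)
}

#' Read and write decay-curve tables
#'
#' Curves are exchanged as CSV with columns \code{b,signal} (and an optional
#' leading \code{roi_id} column when one file holds several ROIs). Signals
#' are normalized by each curve's b = 0 entry at ingestion, so raw
#' two-column (b, intensity) exports work unchanged.
#'
#' @param path CSV file path.
#' @param scheme optional \code{\link{bvalue_scheme}} to validate b values
#'   against; if NULL, a scheme with NEX 1 is built from the file's b column.
#' @return \code{read_signal_curves}: a named list of
#'   \code{\link{signal_curve}} objects (names are ROI ids).
#' @export
read_signal_curves <- function(path, scheme = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("b", "signal") %in% names(tab)))
    stop("curve CSV must have columns 'b' and 'signal'")
  if (!"roi_id" %in% names(tab)) tab$roi_id <- "roi1"
  split_tab <- split(tab, tab$roi_id)
  lapply(split_tab, function(d) {
    d <- d[order(d$b), , drop = FALSE]
    sch <- if (is.null(scheme)) bvalue_scheme(d$b) else scheme
    if (!isTRUE(all.equal(sch$b_values, d$b)))
      stop("b values in file do not match the scheme")
    signal_curve(sch, d$signal, normalize = TRUE)
  })
}

#' @param curves named list of \code{signal_curve} objects.
#' @rdname read_signal_curves
#' @export
write_signal_curves <- function(curves, path) {
  if (inherits(curves, "signal_curve")) curves <- list(roi1 = curves)
  ids <- names(curves)
  if (is.null(ids)) ids <- paste0("roi", seq_along(curves))
  tab <- do.call(rbind, lapply(seq_along(curves), function(i) {
    data.frame(roi_id = ids[i],
               b = curves[[i]]$scheme$b_values,
               signal = curves[[i]]$signal)
  }))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
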