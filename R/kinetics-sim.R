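#' Fluorescence observable model for simulated stopped-flow traces
#'
#' Maps the three state fractions to a FRET fluorescence signal:
#' \code{F(t) = F_base + cU*U + cB*B + cO*O + drift}. By default the bound
#' monomer and the oligomer contribute equally (\code{coeff_bound ==
#' coeff_oligomer}): acceptor-labelled lipids sense any membrane-bound
#' protein regardless of its oligomeric state. Drift phases are slow
#' additive exponentials \code{a * (1 - exp(-r t))} standing in for vesicle
#' aggregation during long acquisitions; they are phenomenological, not
#' mechanistic.
#'
#' @param F_base baseline fluorescence (a.u.)
#' @param coeff_unbound,coeff_bound,coeff_oligomer per-state fluorescence
#'   coefficients (a.u. per unit fraction)
#' @param drift_phases a list of \code{c(amplitude, rate)} pairs
#'   (a.u., s^-1) for additive slow components; empty list for none
#' @return an object of class \code{"observable_model"}
#' @export
observable_model <- function(F_base = 0.1, coeff_unbound = 0,
                             coeff_bound = 1, coeff_oligomer = coeff_bound,
                             drift_phases = list()) {
  co <- c(F_base, coeff_unbound, coeff_bound, coeff_oligomer)
  if (any(!is.finite(co))) stop("coefficients must be finite", call. = FALSE)
  for (ph in drift_phases) {
    if (length(ph) != 2 || !all(is.finite(ph)) || ph[2] < 0)
      stop("each drift phase must be c(amplitude, rate >= 0)", call. = FALSE)
  }
  structure(list(F_base = F_base, coeff_unbound = coeff_unbound,
                 coeff_bound = coeff_bound, coeff_oligomer = coeff_oligomer,
                 drift_phases = drift_phases),
            class = "observable_model")
}

#' Construct a stopped-flow fluorescence trace
#'
#' @param times times (s), strictly increasing, first >= 0, length >= 8
#' @param fluorescence fluorescence (a.u.), same length as \code{times}
#' @param condition a [lipid_condition()]
#' @param protein_uM protein concentration (micromolar)
#' @param seed seed used to generate the trace, if synthetic (metadata)
#' @return an object of class \code{"sf_trace"}
#' @export
sf_trace <- function(times, fluorescence, condition, protein_uM,
                     seed = NA_integer_) {
  if (length(times) != length(fluorescence))
    stop("times and fluorescence must have equal length", call. = FALSE)
  if (length(times) < 8)
    stop("a trace needs at least 8 points", call. = FALSE)
  if (times[1] < 0 || any(diff(times) <= 0))
    stop("times must be strictly increasing with first >= 0", call. = FALSE)
  stopifnot(inherits(condition, "lipid_condition"))
  # pseudo-first-order sanity: accessible lipid should dwarf protein
  acc_mM <- condition_accessible_lipid(condition)
  if (is.finite(protein_uM) && acc_mM > 0 &&
      acc_mM < 100 * protein_uM / 1000)
    warning("accessible lipid < 100 x protein concentration; ",
            "pseudo-first-order assumption may be violated", call. = FALSE)
  structure(list(times = as.numeric(times),
                 fluorescence = as.numeric(fluorescence),
                 condition = condition, protein_uM = protein_uM,
                 seed = seed),
            class = "sf_trace")
}

#' @export
print.sf_trace <- function(x, ...) {
  cat(sprintf(
    "Stopped-flow trace: %d points, %.4g-%.4g s, %.3g mM accessible lipid\n",
    length(x$times), x$times[1], x$times[length(x$times)],
    condition_accessible_lipid(x$condition)))
  if (nzchar(x$condition$label)) cat("  label:", x$condition$label, "\n")
  invisible(x)
}

#' @export
plot.sf_trace <- function(x, ...) {
  graphics::plot(x$times, x$fluorescence, type = "l",
                 xlab = "time (s)", ylab = "fluorescence (a.u.)", ...)
  invisible(x)
}

#' Simulate a stopped-flow FRET binding trace
#'
#' Integrates the two-step binding scheme in closed form (see
#' [state_fractions()]), maps states to fluorescence through the observable
#' model, adds any drift phases and i.i.d. Gaussian noise.
#'
#' @param params a [rate_params()] object
#' @param obs an [observable_model()]
#' @param cond a [lipid_condition()]
#' @param duration trace length (s)
#' @param n_points number of samples (>= 8), evenly spaced from 0
#' @param noise_sd Gaussian noise standard deviation (a.u.); 0 for noiseless
#' @param seed integer seed; the same seed reproduces the trace exactly
#' @param protein_uM protein concentration (micromolar), metadata
#' @return an [sf_trace()]
#' @examples
#' tr <- simulate_trace(rate_params(0.85, 0.66), observable_model(),
#'                      lipid_condition(0.5), duration = 10, n_points = 100,
#'                      noise_sd = 0, seed = 1)
#' @export
simulate_trace <- function(params, obs, cond, duration, n_points,
                           noise_sd = 0, seed = NULL, protein_uM = 0.25) {
  stopifnot(inherits(params, "rate_params"),
            inherits(obs, "observable_model"),
            inherits(cond, "lipid_condition"))
  if (duration <= 0) stop("duration must be > 0", call. = FALSE)
  if (n_points < 8) stop("n_points must be >= 8", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  times <- seq(0, duration, length.out = n_points)
  L <- condition_accessible_lipid(cond)
  st <- state_fractions(params, L, times)
  f <- obs$F_base + obs$coeff_unbound * st[, "U"] +
    obs$coeff_bound * st[, "B"] + obs$coeff_oligomer * st[, "O"]
  for (ph in obs$drift_phases)
    f <- f + ph[1] * (1 - exp(-ph[2] * times))
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    f <- f + stats::rnorm(n_points, sd = noise_sd)
  }
  sf_trace(times, f, cond, protein_uM,
           seed = if (is.null(seed)) NA_integer_ else seed)
}

#' Donor-quench readout
#'
#' Relative change of donor fluorescence upon liposome addition,
#' \code{(F_with - F_without) / F_without}. Negative values indicate donor
#' quenching, i.e. proximity of the labelled residue to the
#' acceptor-labelled membrane; the more negative, the closer.
#'
#' @param f_with_liposomes donor fluorescence with liposomes (a.u.)
#' @param f_without donor fluorescence without liposomes (a.u.), > 0
#' @return relative fluorescence change (unitless)
#' @examples
#' donor_quench(80, 100)   # -0.2
#' @export
donor_quench <- function(f_with_liposomes, f_without) {
  if (any(f_without <= 0))
    stop("reference fluorescence must be > 0", call. = FALSE)
  (f_with_liposomes - f_without) / f_without
}
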