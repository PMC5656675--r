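#' Kinetic rate constants of the two-step membrane-binding scheme
#'
#' Bundles the four rate constants of the scheme
#' \deqn{U + L \overset{k_{on}}{\underset{k_{off}}{\rightleftharpoons}} B
#'       \overset{k_{oli}}{\underset{k_{dis}}{\rightleftharpoons}} O}
#' where U is unbound protein, B is membrane-bound monomer and O is
#' membrane-bound oligomer. Under pseudo-first-order conditions (lipid in
#' large excess) the binding step is first order in protein with effective
#' rate \code{k_on * L + k_off}, L being the accessible lipid concentration.
#'
#' @param k_on association rate constant (mM^-1 s^-1)
#' @param k_off dissociation rate constant of the binding step (s^-1)
#' @param k_oli oligomerization rate of membrane-bound protein (s^-1)
#' @param k_dis oligomer disassembly rate (s^-1)
#' @return an object of class \code{"rate_params"}
#' @examples
#' rate_params(k_on = 0.85, k_off = 0.66)
#' @export
rate_params <- function(k_on, k_off, k_oli = 0, k_dis = 0) {
  v <- c(k_on = k_on, k_off = k_off, k_oli = k_oli, k_dis = k_dis)
  if (any(!is.finite(v)))
    stop("rate constants must be finite", call. = FALSE)
  if (any(v < 0))
    stop("rate constants must be non-negative, got ",
         paste(names(v)[v < 0], collapse = ", "), call. = FALSE)
  structure(as.list(v), class = "rate_params")
}

#' @export
print.rate_params <- function(x, ...) {
  cat("Two-step binding rate constants:\n")
  cat(sprintf("  k_on  = %g mM^-1 s^-1\n  k_off = %g s^-1\n", x$k_on, x$k_off))
  cat(sprintf("  k_oli = %g s^-1\n  k_dis = %g s^-1\n", x$k_oli, x$k_dis))
  cat(sprintf("  k_off,app = k_off + k_oli + k_dis = %g s^-1\n",
              koff_app_from_rates(x)))
  invisible(x)
}

#' Apparent dissociation rate constant of the two-step scheme
#'
#' The intercept of the pseudo-first-order line decomposes as
#' \code{k_off,app = k_off + k_oli + k_dis}: dissociation proper plus the
#' two membrane-bound interconversion rates, both of which deplete the
#' FRET-visible bound monomer pool on the observed timescale.
#'
#' @param params a [rate_params()] object
#' @return apparent dissociation rate constant (s^-1)
#' @examples
#' koff_app_from_rates(rate_params(0.85, 0.66))            # 0.66
#' koff_app_from_rates(rate_params(1, 0.5, 0.3, 0.2))      # 1.0
#' @export
koff_app_from_rates <- function(params) {
  stopifnot(inherits(params, "rate_params"))
  params$k_off + params$k_oli + params$k_dis
}

#' Accessible lipid concentration
#'
#' Only the outer-leaflet lipid of a unilamellar vesicle is available to a
#' peripheral protein; by the convention used throughout this package 60%
#' of the total lipid is taken as accessible.
#'
#' @param total_lipid total lipid concentration (mM)
#' @param fraction accessible fraction, in (0, 1]; default 0.6
#' @return accessible lipid concentration (mM)
#' @examples
#' accessible_lipid(1.0)        # 0.6
#' accessible_lipid(0.5, 1.0)   # 0.5
#' @export
accessible_lipid <- function(total_lipid, fraction = 0.6) {
  if (any(total_lipid < 0)) stop("total_lipid must be >= 0", call. = FALSE)
  if (any(!is.finite(fraction)) || any(fraction <= 0) || any(fraction > 1))
    stop("accessible fraction must lie in (0, 1]", call. = FALSE)
  total_lipid * fraction
}

#' Lipid condition metadata for a stopped-flow trace
#'
#' @param total_lipid total lipid concentration (mM)
#' @param accessible_fraction fraction of lipid accessible to protein,
#'   default 0.6
#' @param pip_mole_fraction PIP mole fraction of the vesicles (metadata only)
#' @param label free-text label, e.g. the FRET dye pair
#' @return an object of class \code{"lipid_condition"}
#' @export
lipid_condition <- function(total_lipid, accessible_fraction = 0.6,
                            pip_mole_fraction = NA_real_, label = "") {
  if (total_lipid < 0) stop("total_lipid must be >= 0", call. = FALSE)
  if (!is.finite(accessible_fraction) ||
      accessible_fraction <= 0 || accessible_fraction > 1)
    stop("accessible_fraction must lie in (0, 1]", call. = FALSE)
  structure(list(total_lipid = total_lipid,
                 accessible_fraction = accessible_fraction,
                 pip_mole_fraction = pip_mole_fraction,
                 label = label),
            class = "lipid_condition")
}

#' @rdname lipid_condition
#' @param cond a \code{lipid_condition}
#' @export
condition_accessible_lipid <- function(cond) {
  accessible_lipid(cond$total_lipid, cond$accessible_fraction)
}

# Rate matrix of the linear 3-state system d(U,B,O)/dt = A %*% (U,B,O),
# with L the (constant) accessible lipid concentration in mM.
rate_matrix <- function(params, L) {
  kb <- params$k_on * L
  matrix(c(-kb,            params$k_off,                  0,
            kb, -(params$k_off + params$k_oli), params$k_dis,
             0,            params$k_oli,       -params$k_dis),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("U", "B", "O"), c("U", "B", "O")))
}

#' State fractions of the two-step scheme at given times (closed form)
#'
#' Solves the linear three-state system
#' \deqn{dU/dt = -k_{on} L U + k_{off} B}
#' \deqn{dB/dt = k_{on} L U - (k_{off}+k_{oli}) B + k_{dis} O}
#' \deqn{dO/dt = k_{oli} B - k_{dis} O}
#' with U(0) = 1, by eigendecomposition of the rate matrix (the matrix
#' exponential in closed form). Falls back to a Pade matrix exponential per
#' time point if the eigenvector matrix is numerically singular (defective
#' parameter combinations).
#'
#' @param params a [rate_params()] object
#' @param L accessible lipid concentration (mM), held constant
#'   (pseudo-first-order assumption)
#' @param times numeric vector of times (s)
#' @return matrix with columns \code{U}, \code{B}, \code{O}; rows sum to 1
#' @export
state_fractions <- function(params, L, times) {
  stopifnot(inherits(params, "rate_params"), L >= 0, all(is.finite(times)))
  A <- rate_matrix(params, L)
  x0 <- c(1, 0, 0)
  eg <- eigen(A)
  ok <- FALSE
  if (Matrix::rcond(Matrix::Matrix(eg$vectors)) > 1e-10) {
    c0 <- solve(eg$vectors, x0)
    # x(t) = V diag(exp(lambda t)) V^-1 x0; rates are real but eigen() may
    # return complex for some parameter draws -- the imaginary parts cancel
    ex <- exp(outer(eg$values, times))           # 3 x n_t
    out <- Re(eg$vectors %*% (ex * c0))
    ok <- all(is.finite(out))
  }
  if (!ok) {
    out <- vapply(times, function(t)
      as.numeric(Matrix::expm(A * t) %*% x0), numeric(3))
  }
  out <- t(out)
  colnames(out) <- c("U", "B", "O")
  out
}
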