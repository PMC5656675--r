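#' Fit a sum of exponentials to a stopped-flow trace
#'
#' Fits \deqn{F(t) = F_0 + \sum_{i=1}^{n} A_{obs(i)} e^{-k_{obs(i)} t}}
#' by Levenberg-Marquardt least squares, where \eqn{F_0} is the final
#' fluorescence, \eqn{A_{obs(i)}} the amplitude and \eqn{k_{obs(i)}} the
#' observed rate of phase i. Up to three phases are supported; in practice
#' the fastest phase reports membrane binding while slower phases absorb
#' oligomerization and aggregation drift.
#'
#' Initialization uses log-spaced rate guesses spanning
#' \code{[1/duration, n_points/duration]} with amplitudes split from the
#' signal range; on failure the rates are rescaled through a fixed
#' multiplier schedule (1, 0.3, 3, 0.1, 10) before the fit is declared
#' unconverged. An unconverged fit is returned with \code{converged =
#' FALSE}, never as silent garbage.
#'
#' @param trace an [sf_trace()]
#' @param n_phases number of exponential phases, 1, 2 or 3
#' @return an object of class \code{"expfit"} with components \code{F0},
#'   \code{phases} (data frame with \code{A}, \code{k}, \code{se_A},
#'   \code{se_k}, sorted by descending rate), \code{se_F0}, \code{rss},
#'   \code{converged}
#' @examples
#' tr <- simulate_trace(rate_params(0.85, 0.66), observable_model(),
#'                      lipid_condition(0.5), 10, 100, 0)
#' fit_multiexponential(tr, 1)
#' @export
fit_multiexponential <- function(trace, n_phases = 1) {
  stopifnot(inherits(trace, "sf_trace"))
  if (!n_phases %in% 1:3)
    stop("n_phases must be 1, 2 or 3", call. = FALSE)
  t <- trace$times
  y <- trace$fluorescence
  dur <- max(t) - min(t)
  n <- n_phases

  # starting values: rates log-spaced across the resolvable window,
  # amplitudes from the observed signal range, F0 from the tail
  k0 <- exp(seq(log(1 / dur), log(length(t) / dur), length.out = n + 2))
  k0 <- k0[seq(2, n + 1)]
  a0 <- rep((y[1] - y[length(y)]) / n, n)
  if (all(a0 == 0)) a0 <- rep(diff(range(y)) / max(n, 1) + 1e-6, n)
  F0_0 <- mean(y[max(1, length(y) - 4):length(y)])

  model_fn <- function(p, t) {
    f <- rep(p[1], length(t))
    for (i in seq_len(n))
      f <- f + p[1 + i] * exp(-p[1 + n + i] * t)
    f
  }
  residual_fn <- function(p) y - model_fn(p, t)

  lower <- c(-Inf, rep(-Inf, n), rep(1e-12, n))
  schedule <- c(1, 0.3, 3, 0.1, 10)
  best <- NULL
  for (mult in schedule) {
    p0 <- c(F0_0, a0, k0 * mult)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, fn = residual_fn, lower = lower,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    conv <- fit$info %in% 1:4
    rss <- sum(fit$fvec^2)
    if (is.null(best) || (conv && !best$conv) ||
        (conv == best$conv && rss < best$rss))
      best <- list(fit = fit, conv = conv, rss = rss)
    if (conv && (rss <= 1e-20 || mult == 1)) break
  }

  if (is.null(best)) {
    return(structure(list(F0 = NA_real_, se_F0 = NA_real_,
                          phases = data.frame(A = numeric(), k = numeric(),
                                              se_A = numeric(),
                                              se_k = numeric()),
                          rss = NA_real_, n_phases = n, converged = FALSE,
                          times = t, fluorescence = y),
                     class = "expfit"))
  }

  p <- best$fit$par
  se <- tryCatch({
    covm <- chol2inv(chol(best$fit$hessian)) *
      best$rss / max(1, length(y) - length(p))
    sqrt(pmax(diag(covm), 0))
  }, error = function(e) rep(NA_real_, length(p)))

  phases <- data.frame(A = p[1 + seq_len(n)], k = p[1 + n + seq_len(n)],
                       se_A = se[1 + seq_len(n)], se_k = se[1 + n + seq_len(n)])
  phases <- phases[order(-phases$k), , drop = FALSE]
  rownames(phases) <- NULL

  structure(list(F0 = p[1], se_F0 = se[1], phases = phases,
                 rss = best$rss, n_phases = n, converged = best$conv,
                 times = t, fluorescence = y),
            class = "expfit")
}

#' @export
print.expfit <- function(x, ...) {
  cat(sprintf("Multi-exponential fit (%d phase%s)%s\n", x$n_phases,
              if (x$n_phases > 1) "s" else "",
              if (x$converged) "" else "  [NOT CONVERGED]"))
  if (x$converged || nrow(x$phases)) {
    cat(sprintf("  F0 = %.6g (se %.3g)\n", x$F0, x$se_F0))
    for (i in seq_len(nrow(x$phases)))
      cat(sprintf("  phase %d: A = %.6g (se %.3g), k_obs = %.6g s^-1 (se %.3g)\n",
                  i, x$phases$A[i], x$phases$se_A[i],
                  x$phases$k[i], x$phases$se_k[i]))
    cat(sprintf("  RSS = %.4g\n", x$rss))
  }
  invisible(x)
}

#' @export
coef.expfit <- function(object, ...) {
  ph <- object$phases
  n <- nrow(ph)
  out <- c(F0 = object$F0)
  if (n) {
    a <- ph$A; k <- ph$k
    names(a) <- paste0("A", seq_len(n)); names(k) <- paste0("k", seq_len(n))
    out <- c(out, a, k)
  }
  out
}

#' @export
predict.expfit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$times else
    if (is.list(newdata)) newdata$times else newdata
  f <- rep(object$F0, length(t))
  for (i in seq_len(nrow(object$phases)))
    f <- f + object$phases$A[i] * exp(-object$phases$k[i] * t)
  f
}

#' @export
residuals.expfit <- function(object, ...) {
  object$fluorescence - predict(object)
}

#' @export
plot.expfit <- function(x, ...) {
  graphics::plot(x$times, x$fluorescence, pch = 16, cex = 0.4,
                 xlab = "time (s)", ylab = "fluorescence (a.u.)", ...)
  graphics::lines(x$times, predict(x), col = "red", lwd = 2)
  invisible(x)
}

#' Select the binding-phase rate from a multi-exponential fit
#'
#' Keeps the fastest phase as k_obs1 (the membrane-binding relaxation) and
#' discards the slower phases, which under the conditions modelled here are
#' dominated by oligomerization and vesicle-aggregation drift. An
#' alternative rule keeps the largest-amplitude phase instead.
#'
#' @param fit a converged [fit_multiexponential()] result
#' @param cond the [lipid_condition()] of the fitted trace
#' @param rule \code{"fastest"} (default) or \code{"largest_amplitude"}
#' @return a one-row data frame of class \code{"kobs_point"} with columns
#'   \code{accessible_lipid} (mM), \code{kobs1} (s^-1), \code{se} (s^-1)
#' @export
select_kobs1 <- function(fit, cond, rule = c("fastest", "largest_amplitude")) {
  stopifnot(inherits(fit, "expfit"), inherits(cond, "lipid_condition"))
  rule <- match.arg(rule)
  if (!fit$converged)
    stop("cannot select k_obs1 from an unconverged fit", call. = FALSE)
  ph <- fit$phases
  i <- if (rule == "fastest") which.max(ph$k) else which.max(abs(ph$A))
  out <- data.frame(accessible_lipid = condition_accessible_lipid(cond),
                    kobs1 = ph$k[i],
                    se = if (is.na(ph$se_k[i])) 0 else ph$se_k[i])
  class(out) <- c("kobs_point", "data.frame")
  out
}

#' Pseudo-first-order analysis of observed binding rates
#'
#' Fits the weighted straight line
#' \deqn{k_{obs1} = k_{on} [\mathrm{accessible\ lipid}] + k_{off,app}}
#' across lipid concentrations, with weights \code{1/se^2}. If any point
#' has a zero (or missing) standard error the fit falls back to ordinary
#' least squares with equal unit weights, which is the appropriate choice
#' for noiseless fixtures. A negative fitted intercept is reported as-is
#' with \code{negative_intercept = TRUE}, never clamped.
#'
#' @param points a data frame with columns \code{accessible_lipid} (mM),
#'   \code{kobs1} (s^-1) and \code{se} (s^-1), e.g. row-bound
#'   [select_kobs1()] results
#' @return an object of class \code{"pfo_fit"} with \code{k_on},
#'   \code{k_on_se} (mM^-1 s^-1), \code{k_off_app}, \code{k_off_app_se}
#'   (s^-1), \code{r_squared}, \code{n_points}
#' @examples
#' pts <- data.frame(accessible_lipid = c(0.1, 0.3, 0.5),
#'                   kobs1 = 0.85 * c(0.1, 0.3, 0.5) + 0.66, se = 0)
#' fit_pseudo_first_order(pts)
#' @export
fit_pseudo_first_order <- function(points) {
  points <- as.data.frame(points)
  need <- c("accessible_lipid", "kobs1", "se")
  if (!all(need %in% names(points)))
    stop("points must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (length(unique(points$accessible_lipid)) < 2)
    stop("need >= 2 points with distinct accessible-lipid values",
         call. = FALSE)
  w <- if (any(!is.finite(points$se)) || any(points$se <= 0))
    rep(1, nrow(points)) else 1 / points$se^2
  fit <- stats::lm(kobs1 ~ accessible_lipid, data = points, weights = w)
  # noiseless fixtures fit exactly; that is expected, not suspicious
  sm <- withCallingHandlers(summary(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
  co <- sm$coefficients
  intercept <- co["(Intercept)", "Estimate"]
  out <- structure(list(
    k_on = co["accessible_lipid", "Estimate"],
    k_on_se = co["accessible_lipid", "Std. Error"],
    k_off_app = intercept,
    k_off_app_se = co["(Intercept)", "Std. Error"],
    r_squared = sm$r.squared,
    n_points = nrow(points),
    negative_intercept = intercept < 0,
    points = points, lm = fit), class = "pfo_fit")
  if (out$negative_intercept)
    warning("fitted k_off,app is negative; reported unclamped",
            call. = FALSE)
  out
}

#' @export
print.pfo_fit <- function(x, ...) {
  cat("Pseudo-first-order fit: k_obs1 = k_on * [accessible lipid] + k_off,app\n")
  cat(sprintf("  k_on      = %.4g +/- %.2g mM^-1 s^-1\n", x$k_on, x$k_on_se))
  cat(sprintf("  k_off,app = %.4g +/- %.2g s^-1%s\n", x$k_off_app,
              x$k_off_app_se,
              if (x$negative_intercept) "  [negative intercept]" else ""))
  cat(sprintf("  R^2 = %.6g over %d points\n", x$r_squared, x$n_points))
  invisible(x)
}

#' @export
coef.pfo_fit <- function(object, ...) {
  c(k_on = object$k_on, k_off_app = object$k_off_app)
}

#' @export
predict.pfo_fit <- function(object, newdata = NULL, ...) {
  L <- if (is.null(newdata)) object$points$accessible_lipid
       else if (is.list(newdata)) newdata$accessible_lipid else newdata
  object$k_on * L + object$k_off_app
}

#' @export
plot.pfo_fit <- function(x, ...) {
  graphics::plot(x$points$accessible_lipid, x$points$kobs1,
                 xlab = "accessible lipid (mM)",
                 ylab = expression(k[obs1] ~ (s^-1)), pch = 16, ...)
  graphics::abline(x$k_off_app, x$k_on, col = "red")
  invisible(x)
}
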