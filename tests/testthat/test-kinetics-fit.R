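make_trace <- function(times, f) {
  sf_trace(times, f, lipid_condition(0.5), 0.25)
}

test_that("a noiseless mono-exponential is recovered to machine-level accuracy", {
  t <- seq(0, 5, length.out = 60)
  fit <- fit_multiexponential(make_trace(t, 1 + 0.5 * exp(-2 * t)), 1)
  expect_true(fit$converged)
  expect_equal(fit$F0, 1, tolerance = 1e-6)
  expect_equal(fit$phases$A, 0.5, tolerance = 1e-6)
  expect_equal(fit$phases$k, 2, tolerance = 1e-6)
})

test_that("a noiseless bi-exponential round trip recovers all four parameters", {
  t <- seq(0, 20, length.out = 200)
  y <- 0.8 + 0.4 * exp(-3.0 * t) + 0.2 * exp(-0.3 * t)
  fit <- fit_multiexponential(make_trace(t, y), 2)
  expect_true(fit$converged)
  expect_equal(fit$phases$k, c(3.0, 0.3), tolerance = 1e-4)
  expect_equal(fit$phases$A, c(0.4, 0.2), tolerance = 1e-4)
  expect_equal(fit$F0, 0.8, tolerance = 1e-4)
  # phases come out sorted by descending rate
  expect_true(all(diff(fit$phases$k) <= 0))
})

test_that("three-phase fit of a two-step trace with drift finds the binding mode", {
  p <- rate_params(0.85, 0.66, 0.05, 0.01)
  obs <- observable_model(drift_phases = list(c(0.1, 0.02)))
  cond <- lipid_condition(1.0)  # accessible 0.6 mM
  tr <- simulate_trace(p, obs, cond, 40, 400, 0)
  fit <- fit_multiexponential(tr, 3)
  expect_true(fit$converged)
  ev <- eigen(proppinkit:::rate_matrix(p, 0.6))$values
  binding_rate <- max(-Re(ev))
  expect_equal(fit$phases$k[1], binding_rate, tolerance = 0.1)
})

test_that("an invalid phase count is rejected and fits report standard errors", {
  t <- seq(0, 5, length.out = 60)
  tr <- make_trace(t, 1 + 0.5 * exp(-2 * t))
  expect_error(fit_multiexponential(tr, 4), "n_phases")
  set.seed(5)
  fitn <- fit_multiexponential(make_trace(t, 1 + 0.5 * exp(-2 * t) +
                                            rnorm(60, sd = 0.01)), 1)
  expect_true(fitn$converged)
  expect_true(all(is.finite(fitn$phases$se_k)) && fitn$phases$se_k > 0)
})

test_that("expfit methods are mutually consistent", {
  t <- seq(0, 5, length.out = 60)
  tr <- make_trace(t, 1 + 0.5 * exp(-2 * t))
  fit <- fit_multiexponential(tr, 1)
  expect_equal(unname(coef(fit)), c(fit$F0, fit$phases$A, fit$phases$k))
  expect_equal(predict(fit) + residuals(fit), tr$fluorescence)
  expect_equal(sum(residuals(fit)^2), fit$rss, tolerance = 1e-12)
})

test_that("k_obs1 selection keeps the fastest phase and demands convergence", {
  fit <- structure(list(F0 = 1, se_F0 = 0,
                        phases = data.frame(A = c(0.1, 0.3), k = c(5.0, 0.2),
                                            se_A = c(0, 0),
                                            se_k = c(0.1, 0.01)),
                        rss = 0, n_phases = 2, converged = TRUE),
                   class = "expfit")
  cond <- lipid_condition(0.5)
  pt <- select_kobs1(fit, cond)
  expect_equal(pt$kobs1, 5.0)
  expect_equal(pt$accessible_lipid, 0.3)
  pt2 <- select_kobs1(fit, cond, rule = "largest_amplitude")
  expect_equal(pt2$kobs1, 0.2)
  single <- fit
  single$phases <- single$phases[2, ]
  expect_equal(select_kobs1(single, cond)$kobs1, 0.2)
  bad <- fit; bad$converged <- FALSE
  expect_error(select_kobs1(bad, cond), "unconverged")
})

test_that("noiseless single-step series puts k_obs1 on the k_on*L + k_off line", {
  p <- rate_params(0.85, 0.66)
  Ls <- seq(0.1, 0.6, length.out = 6)
  pts <- do.call(rbind, lapply(Ls, function(L) {
    cond <- lipid_condition(L / 0.6)
    tr <- simulate_trace(p, observable_model(), cond, 10, 150, 0)
    select_kobs1(fit_multiexponential(tr, 1), cond)
  }))
  expect_equal(pts$kobs1, 0.85 * Ls + 0.66, tolerance = 1e-3)
  fit <- fit_pseudo_first_order(pts)
  expect_gt(fit$r_squared, 0.9999)
  expect_equal(fit$k_on, 0.85, tolerance = 1e-3)
  expect_equal(fit$k_off_app, 0.66, tolerance = 1e-3)
})

test_that("pseudo-first-order fit reproduces exact input lines", {
  L <- c(0.1, 0.2, 0.35, 0.5, 0.6)
  pts <- data.frame(accessible_lipid = L, kobs1 = 0.85 * L + 0.66, se = 0)
  fit <- fit_pseudo_first_order(pts)
  expect_equal(fit$k_on, 0.85, tolerance = 1e-10)
  expect_equal(fit$k_off_app, 0.66, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  two <- data.frame(accessible_lipid = c(0, 1), kobs1 = c(1, 2), se = 0)
  fit2 <- fit_pseudo_first_order(two)
  expect_equal(unname(coef(fit2)), c(1, 1), tolerance = 1e-12)
})

test_that("weighting honours 1/se^2 and degrades gracefully to OLS", {
  L <- c(0.1, 0.3, 0.5, 0.7)
  pts <- data.frame(accessible_lipid = L, kobs1 = 2 * L + 0.5,
                    se = c(0.01, 0.01, 0.01, 0.01))
  pts$kobs1[4] <- pts$kobs1[4] + 0.5     # outlier
  pts$se[4] <- 10                        # ...with huge uncertainty
  wfit <- fit_pseudo_first_order(pts)
  pts_ols <- pts; pts_ols$se <- 0
  ofit <- fit_pseudo_first_order(pts_ols)
  # the weighted fit shrugs off the down-weighted outlier; OLS cannot
  expect_lt(abs(wfit$k_on - 2), 1e-3)
  expect_gt(abs(ofit$k_on - 2), 0.1)
})

test_that("degenerate and negative-intercept inputs are handled explicitly", {
  same <- data.frame(accessible_lipid = c(0.3, 0.3), kobs1 = c(1, 2), se = 0)
  expect_error(fit_pseudo_first_order(same), "distinct")
  L <- c(0.2, 0.4, 0.6)
  neg <- data.frame(accessible_lipid = L, kobs1 = 2 * L - 0.1, se = 0)
  expect_warning(fit <- fit_pseudo_first_order(neg), "negative")
  expect_true(fit$negative_intercept)
  expect_equal(fit$k_off_app, -0.1, tolerance = 1e-10)  # not clamped
})
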