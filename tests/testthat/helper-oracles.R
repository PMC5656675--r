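# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: matching by exhaustive scan, the kinetic ODE by
# numerical integration.

# O(n*m) exhaustive precursor matcher
brute_force_match <- function(observed, theo_masses, tol_ppm) {
  hits <- list()
  for (i in seq_along(observed)) {
    for (j in seq_along(theo_masses)) {
      ppm <- (observed[i] - theo_masses[j]) / theo_masses[j] * 1e6
      if (abs(ppm) <= tol_ppm)
        hits[[length(hits) + 1L]] <- c(obs = i, cand = j, ppm = ppm)
    }
  }
  if (!length(hits)) return(data.frame(obs = integer(), cand = integer(),
                                       ppm = numeric()))
  as.data.frame(do.call(rbind, hits))
}

# numerical integration of the three-state system (independent of the
# package's eigendecomposition path)
ode_states <- function(params, L, times) {
  rhs <- function(t, y, p) {
    U <- y[1]; B <- y[2]; O <- y[3]
    list(c(-p$k_on * L * U + p$k_off * B,
           p$k_on * L * U - (p$k_off + p$k_oli) * B + p$k_dis * O,
           p$k_oli * B - p$k_dis * O))
  }
  out <- deSolve::ode(c(U = 1, B = 0, O = 0), times, rhs, params,
                      rtol = 1e-10, atol = 1e-12)
  unname(out[, c("U", "B", "O")])
}

random_rates <- function() {
  rate_params(k_on = runif(1, 0.1, 5), k_off = runif(1, 0.05, 2),
              k_oli = runif(1, 0, 1), k_dis = runif(1, 0, 0.5))
}
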