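test_that("the charge-state relation and its inverse are exact", {
  expect_equal(mz_for(1, 10000, 10), 1001.007276, tolerance = 1e-9)
  expect_equal(mz_for(2, 30000, 15), mz_for(1, 60000, 15), tolerance = 1e-12)
  m <- mz_for(3, 61234.5, 17)
  expect_equal(17 * (m - 1.007276) / 3, 61234.5, tolerance = 1e-6)
  expect_error(mz_for(0, 100, 1), "order")
})

test_that("peaks generated at exact positions are fully assigned", {
  M <- 60000
  grid <- expand.grid(order = 1:4, charge = 12:18)
  mzs <- sort(mz_for(grid$order, M, grid$charge))
  pl <- peak_list(mzs, rep(100, length(mzs)))
  a <- assign_peaks(pl, M, n_max = 4, charge_range = 12:18, tol_ppm = 5)
  expect_true(all(!is.na(a$table$order)))
  # every assignment reproduces its generating (order, charge)
  back <- mz_for(a$table$order, M, a$table$charge)
  expect_equal(back, a$table$mz, tolerance = 1e-9)
  # degenerate collisions within this grid go to the smallest order
  # the (2,12)/(3,18) coincidence resolves to the smaller order, flagged
  col <- which(abs(a$table$mz - mz_for(2, M, 12)) < 1e-6)
  expect_true(all(a$table$order[col] == 2L))
  expect_true(all(a$table$ambiguous[col]))
})

test_that("a single peak with wide tolerance takes the smallest compatible order", {
  pl <- peak_list(mz_for(2, 60000, 12), 100)
  a <- assign_peaks(pl, 60000, n_max = 4, charge_range = 1:30,
                    tol_ppm = 100)
  expect_equal(a$table$order, 1L)   # (1, 6) degenerate with (2, 12)
  expect_true(a$table$ambiguous)
  expect_error(assign_peaks(peak_list(numeric(), numeric()), 60000),
               "equal length|empty")
})

test_that("oligomer intensities are reported relative to the monomer", {
  mzs <- c(mz_for(1, 60000, 15), mz_for(2, 60000, 15))
  a <- assign_peaks(peak_list(sort(mzs), c(100, 50)[order(mzs)]), 60000,
                    n_max = 2, charge_range = 12:18, tol_ppm = 5)
  res <- oligomer_intensities(a)
  expect_equal(res$rel_intensity[res$order == 1], 100)
  expect_equal(res$rel_intensity[res$order == 2], 50)
  # single order present -> 100%
  one <- assign_peaks(peak_list(mz_for(1, 60000, 15), 40), 60000,
                      n_max = 1, charge_range = 12:18, tol_ppm = 5)
  expect_equal(oligomer_intensities(one)$rel_intensity, 100)
})

test_that("with no monomer the reference falls back to the most abundant order", {
  mzs <- c(mz_for(2, 60000, 15), mz_for(3, 60000, 15))
  a <- assign_peaks(peak_list(sort(mzs), c(80, 20)[order(mzs)]), 60000,
                    n_max = 3, charge_range = 12:18, tol_ppm = 5)
  expect_warning(res <- oligomer_intensities(a), "monomer absent")
  expect_equal(attr(res, "normalized_to"), 2L)
  expect_equal(res$rel_intensity[res$order == 2], 100)
})

test_that("assigned plus unassigned intensity conserves the input total", {
  g <- gen_native_spectrum(seed = 5)
  a <- assign_peaks(g$peaks, 60000, n_max = 4, charge_range = 12:18,
                    tol_ppm = 200)
  expect_equal(sum(a$table$intensity), a$total_intensity, tolerance = 1e-12)
  picked <- pick_peaks(g$peaks)
  expect_equal(a$total_intensity, sum(picked$intensity), tolerance = 1e-12)
})

test_that("per-series mass spread stays within the assignment tolerance", {
  g <- gen_native_spectrum(noise_frac = 0, noise_floor = 0, seed = 1)
  a <- assign_peaks(g$peaks, 60000, n_max = 4, charge_range = 12:18,
                    tol_ppm = 200)
  res <- oligomer_intensities(a)
  for (i in seq_len(nrow(res))) {
    tol_da <- 2 * 200e-6 * res$mass[i]
    expect_lt(res$mass_sd[i], tol_da)
    expect_equal(res$mass[i], 60000 * res$order[i],
                 tolerance = 300e-6)  # grid-limited centroid accuracy
  }
})

test_that("mass and abundances round-trip across random seeds", {
  for (seed in 1:20) {
    g <- gen_native_spectrum(monomer_mass = 60000,
                             abundances = c(100, 50, 20, 10), seed = seed)
    a <- assign_peaks(g$peaks, 60000, n_max = 4,
                      charge_range = g$truth$charge_range, tol_ppm = 200)
    res <- oligomer_intensities(a)
    expect_setequal(res$order, 1:4)
    expect_true(all(abs(res$rel_intensity - c(100, 50, 20, 10)) <= 5))
  }
})

test_that("a mass window search locates the generating monomer mass", {
  g <- gen_native_spectrum(monomer_mass = 61500, noise_frac = 0,
                           noise_floor = 0, seed = 2)
  a <- assign_peaks(g$peaks, c(58000, 64000), n_max = 4,
                    charge_range = 12:18, tol_ppm = 150,
                    mass_grid_points = 1201)
  expect_equal(a$monomer_mass, 61500, tolerance = 1e-2)
})
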