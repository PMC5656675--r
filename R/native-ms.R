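#' m/z of an oligomer charge state
#'
#' Protonated native-ESI relation:
#' \code{(order * monomer_mass + charge * proton) / charge}.
#'
#' @param order oligomer order (1 = monomer), >= 1
#' @param monomer_mass monomer neutral mass (Da), > 0
#' @param charge charge state, >= 1
#' @return m/z (Th)
#' @examples
#' mz_for(1, 10000, 10)   # 1001.007276
#' @export
mz_for <- function(order, monomer_mass, charge) {
  if (any(order < 1) || any(charge < 1) || any(monomer_mass <= 0))
    stop("need order >= 1, charge >= 1, monomer_mass > 0", call. = FALSE)
  proton <- 1.007276
  (order * monomer_mass + charge * proton) / charge
}

#' Construct a native-MS peak list
#'
#' @param mz m/z values (Th), ascending, > 0
#' @param intensity intensities (a.u.), >= 0, same length
#' @return an object of class \code{"peak_list"}
#' @export
peak_list <- function(mz, intensity) {
  if (length(mz) != length(intensity))
    stop("mz and intensity must have equal length", call. = FALSE)
  if (any(mz <= 0) || any(diff(mz) < 0))
    stop("mz must be positive and ascending", call. = FALSE)
  if (any(intensity < 0))
    stop("intensities must be >= 0", call. = FALSE)
  structure(list(mz = as.numeric(mz), intensity = as.numeric(intensity)),
            class = "peak_list")
}

#' @export
print.peak_list <- function(x, ...) {
  cat(sprintf("Native-MS peak list: %d points, %.1f-%.1f Th\n",
              length(x$mz), min(x$mz), max(x$mz)))
  invisible(x)
}

#' Pick peaks from a profile spectrum
#'
#' Finds local maxima above a relative intensity floor (default 1% of the
#' base peak), then refines each to an intensity-weighted centroid over its
#' half-maximum region. The half-maximum region of each accepted peak is
#' claimed so that noise ripples riding on a flat peak top do not split one
#' physical peak into several; the reported intensity is the apex height.
#'
#' @param peaks a [peak_list()] (profile data)
#' @param floor_rel minimum intensity relative to the base peak
#' @return data frame with columns \code{mz} (centroid), \code{intensity}
#'   (apex), sorted by m/z
#' @export
pick_peaks <- function(peaks, floor_rel = 0.01) {
  stopifnot(inherits(peaks, "peak_list"))
  y <- peaks$intensity
  n <- length(y)
  if (n < 3 || max(y) <= 0) {
    i <- which(y >= floor_rel * max(y))
    return(data.frame(mz = peaks$mz[i], intensity = y[i]))
  }
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n],
              FALSE)
  cand <- which(is_max & y >= floor_rel * max(y))
  cand <- cand[order(-y[cand])]          # strongest apex claims first
  claimed <- logical(n)
  out_mz <- numeric(0)
  out_int <- numeric(0)
  for (i in cand) {
    if (claimed[i]) next                 # ripple on an accepted peak top
    half <- y[i] / 2
    lo <- i
    while (lo > 1 && y[lo - 1] >= half && !claimed[lo - 1]) lo <- lo - 1
    hi <- i
    while (hi < n && y[hi + 1] >= half && !claimed[hi + 1]) hi <- hi + 1
    claimed[lo:hi] <- TRUE
    seg <- lo:hi
    out_mz <- c(out_mz, sum(peaks$mz[seg] * y[seg]) / sum(y[seg]))
    out_int <- c(out_int, y[i])
  }
  o <- order(out_mz)
  data.frame(mz = out_mz[o], intensity = out_int[o])
}

#' Assign native-MS peaks to oligomer charge states
#'
#' Each picked peak is assigned to the (order, charge) pair minimizing the
#' ppm error against \code{mz_for(order, M, charge)}, provided that error
#' is within \code{tol_ppm}; otherwise the peak is left unassigned. Exact
#' (n, z) degeneracies -- an n-mer at charge z has the same m/z as a
#' 2n-mer at 2z -- are resolved toward the smallest order and flagged
#' \code{ambiguous}. If \code{monomer_mass} is a length-2 window, a grid
#' search picks the mass maximizing total assigned intensity.
#'
#' @param peaks a [peak_list()]; profile data are centroided with
#'   [pick_peaks()] first
#' @param monomer_mass monomer mass (Da), or a \code{c(lo, hi)} search
#'   window
#' @param n_max maximum oligomer order considered
#' @param charge_range integer vector of candidate charges
#' @param tol_ppm assignment tolerance (ppm)
#' @param floor_rel peak-picking floor, see [pick_peaks()]
#' @param mass_grid_points grid resolution for the window search
#' @return an object of class \code{"nms_assignments"}: a list with
#'   \code{table} (mz, intensity, order, charge, ppm, ambiguous; order NA
#'   if unassigned), \code{monomer_mass}, \code{tol_ppm}
#' @export
assign_peaks <- function(peaks, monomer_mass, n_max = 4,
                         charge_range = 10:25, tol_ppm = 200,
                         floor_rel = 0.01, mass_grid_points = 2001) {
  stopifnot(inherits(peaks, "peak_list"))
  if (!length(peaks$mz)) stop("empty peak list", call. = FALSE)
  if (n_max < 1 || tol_ppm <= 0)
    stop("need n_max >= 1 and tol_ppm > 0", call. = FALSE)
  picked <- pick_peaks(peaks, floor_rel)
  if (!nrow(picked)) {
    # no profile maxima: treat the input as an already-centroided list
    keep <- peaks$intensity >= floor_rel * max(peaks$intensity)
    picked <- data.frame(mz = peaks$mz[keep],
                         intensity = peaks$intensity[keep])
  }

  if (length(monomer_mass) == 2) {
    grid <- seq(monomer_mass[1], monomer_mass[2],
                length.out = mass_grid_points)
    score <- vapply(grid, function(M) {
      a <- assign_to_mass(picked, M, n_max, charge_range, tol_ppm)
      sum(a$intensity[!is.na(a$order)])
    }, 0)
    monomer_mass <- grid[which.max(score)]
  }
  tab <- assign_to_mass(picked, monomer_mass, n_max, charge_range, tol_ppm)
  structure(list(table = tab, monomer_mass = monomer_mass,
                 tol_ppm = tol_ppm,
                 total_intensity = sum(picked$intensity)),
            class = "nms_assignments")
}

# core assignment at a fixed monomer mass
assign_to_mass <- function(picked, M, n_max, charge_range, tol_ppm) {
  proton <- 1.007276
  grid <- expand.grid(order = seq_len(n_max), charge = charge_range)
  grid$mz <- mz_for(grid$order, M, grid$charge)
  # smallest order first so that the first minimum-|ppm| hit wins exact ties
  grid <- grid[order(grid$order, grid$charge), ]
  out <- data.frame(mz = picked$mz, intensity = picked$intensity,
                    order = NA_integer_, charge = NA_integer_,
                    ppm = NA_real_, neutral_mass = NA_real_,
                    ambiguous = FALSE)
  for (i in seq_len(nrow(out))) {
    ppm <- (out$mz[i] - grid$mz) / grid$mz * 1e6
    ok <- abs(ppm) <= tol_ppm
    if (!any(ok)) next
    j <- which(ok)[order(abs(ppm[ok]))]
    best <- j[1]
    out$order[i] <- grid$order[best]
    out$charge[i] <- grid$charge[best]
    out$ppm[i] <- ppm[best]
    out$neutral_mass[i] <- grid$charge[best] * (out$mz[i] - proton)
    # degenerate alternatives: same m/z within numerical tie but higher order
    ties <- j[abs(abs(ppm[j]) - abs(ppm[best])) < 1e-9 & j != best]
    out$ambiguous[i] <- length(ties) > 0
  }
  out
}

#' @export
print.nms_assignments <- function(x, ...) {
  n_ass <- sum(!is.na(x$table$order))
  cat(sprintf("Native-MS assignments: %d/%d peaks at monomer mass %.1f Da\n",
              n_ass, nrow(x$table), x$monomer_mass))
  invisible(x)
}

#' Per-oligomer mass and intensity summary
#'
#' Sums assigned peak intensities per oligomer order and reports intensity
#' relative to the monomer (monomer = 100%). The oligomer mass is the
#' intensity-weighted mean of the per-peak neutral masses with its SD
#' across charge states. If no monomer was assigned, intensities are
#' normalized to the most abundant order instead and the result is flagged.
#'
#' @param assignments an [assign_peaks()] result
#' @return data frame of class \code{"oligomer_result"} with columns
#'   \code{order}, \code{mass}, \code{mass_sd}, \code{n_peaks},
#'   \code{intensity}, \code{rel_intensity}; attribute
#'   \code{normalized_to} gives the reference order
#' @examples
#' # intensities 100 (monomer) and 50 (dimer) give dimer rel_intensity 50
#' @export
oligomer_intensities <- function(assignments) {
  stopifnot(inherits(assignments, "nms_assignments"))
  tab <- assignments$table[!is.na(assignments$table$order), ]
  if (!nrow(tab)) stop("no assigned peaks", call. = FALSE)
  orders <- sort(unique(tab$order))
  out <- data.frame(order = orders, mass = NA_real_, mass_sd = NA_real_,
                    n_peaks = NA_integer_, intensity = NA_real_)
  for (i in seq_along(orders)) {
    s <- tab[tab$order == orders[i], ]
    out$n_peaks[i] <- nrow(s)
    out$intensity[i] <- sum(s$intensity)
    out$mass[i] <- sum(s$neutral_mass * s$intensity) / sum(s$intensity)
    out$mass_sd[i] <- if (nrow(s) > 1) stats::sd(s$neutral_mass) else 0
  }
  ref <- if (1 %in% orders) 1L else orders[which.max(out$intensity)]
  if (ref != 1L)
    warning("monomer absent; relative intensities normalized to the ",
            "most abundant order (", ref, ")", call. = FALSE)
  out$rel_intensity <- 100 * out$intensity / out$intensity[out$order == ref]
  attr(out, "normalized_to") <- ref
  class(out) <- c("oligomer_result", "data.frame")
  out
}

#' @export
print.oligomer_result <- function(x, ...) {
  cat("Oligomer deconvolution summary:\n")
  df <- as.data.frame(x)
  df$mass <- round(df$mass, 1)
  df$mass_sd <- round(df$mass_sd, 1)
  df$rel_intensity <- round(df$rel_intensity, 1)
  print(df, row.names = FALSE)
  invisible(x)
}
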