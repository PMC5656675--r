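# Ground-truthed synthetic-data generators. Every generator is
# deterministic under a fixed seed and returns its ground truth alongside
# the data, so downstream recovery can be scored without instrument data.

new_truth <- function(generator, seed, ...) {
  structure(list(generator = generator, seed = seed, ...),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("Synthetic ground truth (", x$generator, ", seed ", x$seed, ")\n",
      sep = "")
  invisible(x)
}

#' Serialize / restore generator ground truth
#'
#' Ground truth is written as a YAML key-value sidecar so that every
#' generated dataset travels with its generating parameters.
#'
#' @param truth a \code{synthetic_truth}
#' @param path file path
#' @return \code{read_truth} returns the restored \code{synthetic_truth}
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  yaml::write_yaml(unclass(truth), path)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- yaml::read_yaml(path)
  structure(x, class = "synthetic_truth")
}

#' Generate a series of synthetic stopped-flow traces
#'
#' Emulates a stopped-flow titration: one trace per (accessible lipid
#' concentration, replicate), simulated from the two-step scheme with the
#' given observable model, i.i.d. Gaussian noise and optional aggregation
#' drift. The single returned truth object records the generating rates.
#'
#' Defaults mirror a typical titration of a ~0.25 uM labelled protein
#' against vesicles: 10 s acquisitions at 200 samples, noise at 1% of the
#' unit bound-state amplitude.
#'
#' @param params generating [rate_params()]
#' @param accessible_lipid accessible lipid concentrations (mM), >= 2
#'   values
#' @param obs an [observable_model()]
#' @param noise_sd Gaussian noise SD (a.u.)
#' @param replicates traces per concentration
#' @param seed integer seed (one stream for the whole series)
#' @param duration,n_points trace geometry
#' @param accessible_fraction used to back-compute the total lipid
#'   metadata
#' @param protein_uM protein concentration metadata
#' @return list with \code{traces} (list of [sf_trace()], ordered by
#'   concentration then replicate) and \code{truth}
#' @examples
#' g <- gen_trace_series(rate_params(0.85, 0.66),
#'                       accessible_lipid = c(0.1, 0.35, 0.6),
#'                       noise_sd = 0, replicates = 1, seed = 1)
#' length(g$traces)
#' @export
gen_trace_series <- function(params, accessible_lipid,
                             obs = observable_model(), noise_sd = 0.01,
                             replicates = 1, seed = 1, duration = 10,
                             n_points = 200, accessible_fraction = 0.6,
                             protein_uM = 0.25) {
  stopifnot(inherits(params, "rate_params"))
  if (length(accessible_lipid) < 2)
    stop("need at least 2 concentrations", call. = FALSE)
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  set.seed(seed)
  traces <- list()
  meta <- list()
  for (L in accessible_lipid) {
    cond <- lipid_condition(L / accessible_fraction, accessible_fraction)
    base <- simulate_trace(params, obs, cond, duration, n_points,
                           noise_sd = 0, protein_uM = protein_uM)
    for (r in seq_len(replicates)) {
      f <- base$fluorescence
      if (noise_sd > 0) f <- f + stats::rnorm(n_points, sd = noise_sd)
      traces[[length(traces) + 1L]] <-
        sf_trace(base$times, f, cond, protein_uM, seed = seed)
      meta[[length(meta) + 1L]] <- c(accessible_lipid = L, replicate = r)
    }
  }
  truth <- new_truth("trace_series", seed,
                     k_on = params$k_on, k_off = params$k_off,
                     k_oli = params$k_oli, k_dis = params$k_dis,
                     k_off_app = koff_app_from_rates(params),
                     accessible_lipid = accessible_lipid,
                     replicates = replicates, noise_sd = noise_sd,
                     duration = duration, n_points = n_points)
  list(traces = traces, layout = do.call(rbind, meta), truth = truth)
}

#' Generate a random protein sequence amenable to tryptic digestion
#'
#' Residues are drawn uniformly from the 20 standard amino acids (5% each,
#' so the combined K/R frequency of 10% clears the 8% floor needed to
#' guarantee plentiful tryptic peptides).
#'
#' @param n_residues sequence length
#' @param seed integer seed
#' @param id record id
#' @return a [protein_record()]
#' @export
gen_protein <- function(n_residues = 300, seed = 1, id = "synthetic") {
  set.seed(seed)
  aa <- names(residue_mass_table()$residues)
  protein_record(id, paste(sample(aa, n_residues, replace = TRUE),
                           collapse = ""))
}

#' Generate a synthetic cross-linking precursor dataset
#'
#' Digests the protein, enumerates lipid-adduct and di-peptide cross-link
#' candidates, picks the requested number of each as ground truth, and
#' emits their masses perturbed by Gaussian ppm noise together with decoy
#' masses drawn uniformly over the candidate mass range.
#'
#' @param protein a [protein_record()]; default a 300-residue random
#'   sequence derived from \code{seed}
#' @param true_lipid_sites number of true lipid-adduct masses
#' @param true_dipeptide_links number of true di-peptide link masses
#' @param ppm_noise_sd mass-error SD (ppm)
#' @param n_decoys number of uniform decoy masses
#' @param seed integer seed
#' @param lipid,linker chemistry, as elsewhere
#' @param max_missed,min_len,max_len digestion settings
#' @return list with \code{observed} (shuffled numeric masses, Da),
#'   \code{candidates} (classified candidate table), \code{truth}
#'   (records the selected candidate indices and their sites)
#' @export
gen_xl_dataset <- function(protein = NULL, true_lipid_sites = 20,
                           true_dipeptide_links = 5, ppm_noise_sd = 3,
                           n_decoys = 200, seed = 1,
                           lipid = xl_lipid(), linker = xl_linker(),
                           max_missed = 1, min_len = 4, max_len = 30) {
  set.seed(seed)
  if (is.null(protein)) protein <- gen_protein(300, seed = seed)
  peps <- digest(protein, max_missed = max_missed, min_len = min_len,
                 max_len = max_len)
  lip <- enumerate_lipid_candidates(peps, lipid, linker)
  dip <- enumerate_dipeptide_candidates(peps, linker)
  cand <- classify_candidates(rbind(lip, dip))
  n_lip <- nrow(lip)
  if (true_lipid_sites > n_lip)
    stop("requested ", true_lipid_sites, " lipid sites but only ", n_lip,
         " candidates exist", call. = FALSE)
  if (true_dipeptide_links > nrow(dip))
    stop("requested ", true_dipeptide_links, " di-peptide links but only ",
         nrow(dip), " candidates exist", call. = FALSE)
  true_idx <- c(sample(seq_len(n_lip), true_lipid_sites),
                n_lip + sample(seq_len(nrow(dip)), true_dipeptide_links))
  theo <- cand$theo_mass[true_idx]
  obs_true <- theo * (1 + stats::rnorm(length(theo)) * ppm_noise_sd * 1e-6)
  rng <- range(cand$theo_mass)
  decoys <- stats::runif(n_decoys, rng[1], rng[2])
  observed <- sample(c(obs_true, decoys))
  truth <- new_truth("xl_dataset", seed,
                     protein_id = protein$id,
                     true_idx = true_idx,
                     true_kind = cand$kind[true_idx],
                     true_site_a = cand$site_a[true_idx],
                     true_site_b = cand$site_b[true_idx],
                     true_mass = theo,
                     ppm_noise_sd = ppm_noise_sd, n_decoys = n_decoys)
  list(observed = observed, candidates = cand, protein = protein,
       truth = truth)
}

#' Generate a synthetic native mass spectrum of an oligomer series
#'
#' Gaussian peaks at the [mz_for()] positions of each oligomer order and
#' charge, with a shared Gaussian charge envelope, multiplicative
#' peak-height noise and an additive baseline. Charge envelope and peak
#' widths are shared across orders, so apex intensities preserve the
#' abundance ratios.
#'
#' @param monomer_mass monomer neutral mass (Da)
#' @param abundances per-order relative abundances (order 1, 2, ...);
#'   non-negative, at least one positive
#' @param charge_center,charge_spread Gaussian charge-envelope centre and
#'   SD
#' @param charge_range integer charges to emit; default
#'   \code{charge_center} +/- 2 SD
#' @param peak_width_th Gaussian peak SD (Th)
#' @param noise_frac multiplicative peak-height noise (fraction)
#' @param noise_floor additive baseline noise SD, relative to the base
#'   peak
#' @param mz_step profile grid spacing (Th)
#' @param seed integer seed
#' @return list with \code{peaks} (a [peak_list()] profile spectrum) and
#'   \code{truth}
#' @export
gen_native_spectrum <- function(monomer_mass = 60000,
                                abundances = c(100, 50, 20, 10),
                                charge_center = 15, charge_spread = 1.5,
                                charge_range = NULL, peak_width_th = 5,
                                noise_frac = 0.02, noise_floor = 0.001,
                                mz_step = 1, seed = 1) {
  if (any(abundances < 0) || !any(abundances > 0))
    stop("abundances must be non-negative with at least one positive",
         call. = FALSE)
  set.seed(seed)
  if (is.null(charge_range))
    charge_range <- seq(ceiling(charge_center - 2 * charge_spread),
                        floor(charge_center + 2 * charge_spread))
  env <- exp(-(charge_range - charge_center)^2 / (2 * charge_spread^2))
  centers <- list()
  heights <- list()
  for (n in seq_along(abundances)) {
    if (abundances[n] == 0) next
    centers[[length(centers) + 1L]] <- mz_for(n, monomer_mass, charge_range)
    heights[[length(heights) + 1L]] <- abundances[n] * env
  }
  centers <- unlist(centers)
  heights <- unlist(heights)
  if (noise_frac > 0)
    heights <- heights *
      pmax(0, 1 + stats::rnorm(length(heights)) * noise_frac)
  mz <- seq(min(centers) - 20 * peak_width_th,
            max(centers) + 20 * peak_width_th, by = mz_step)
  y <- numeric(length(mz))
  for (i in seq_along(centers))
    y <- y + heights[i] *
      exp(-(mz - centers[i])^2 / (2 * peak_width_th^2))
  if (noise_floor > 0)
    y <- pmax(0, y + stats::rnorm(length(y),
                                  sd = noise_floor * max(heights)))
  truth <- new_truth("native_spectrum", seed,
                     monomer_mass = monomer_mass, abundances = abundances,
                     charge_range = charge_range,
                     charge_center = charge_center,
                     charge_spread = charge_spread,
                     peak_width_th = peak_width_th,
                     noise_frac = noise_frac, noise_floor = noise_floor)
  list(peaks = peak_list(mz, y), truth = truth)
}
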