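# Flat run configuration shared by all pipeline stages.
# Precedence: explicit overrides > config file > built-in defaults.

config_defaults <- function() {
  list(
    # chemistry
    lipid_mass = 743.36, linker_mass = 140.074,
    # kinetics
    accessible_fraction = 0.6, n_phases = 1, duration = 10, n_points = 200,
    noise_sd = 0.01, replicates = 5,
    accessible_lipid = c(0.1, 0.225, 0.35, 0.475, 0.6),
    k_on = 0.85, k_off = 0.66, k_oli = 0, k_dis = 0,
    # cross-linking
    tol_ppm = 10, true_lipid_sites = 20, true_dipeptide_links = 5,
    ppm_noise_sd = 3, n_decoys = 200,
    # native MS
    monomer_mass = 60000, abundances = c(100, 50, 20, 10),
    charge_range = 12:18, nms_tol_ppm = 200, n_max = 4,
    # run control
    seed = 1, outdir = ".")
}

#' Resolve a run configuration
#'
#' Merges built-in defaults, an optional YAML config file and explicit
#' overrides (highest precedence). Unknown keys are rejected with an error
#' naming the key.
#'
#' @param path optional YAML file
#' @param overrides named list of overrides (e.g. from CLI flags)
#' @return an object of class \code{"run_config"} (a named list)
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- config_defaults()
  apply_layer <- function(cfg, layer, origin) {
    bad <- setdiff(names(layer), names(cfg))
    if (length(bad))
      stop("unknown configuration key", if (length(bad) > 1) "s", " in ",
           origin, ": ", paste(bad, collapse = ", "), call. = FALSE)
    cfg[names(layer)] <- layer
    cfg
  }
  if (!is.null(path)) {
    if (!file.exists(path)) stop("no such config file: ", path,
                                 call. = FALSE)
    cfg <- apply_layer(cfg, yaml::read_yaml(path), path)
  }
  cfg <- apply_layer(cfg, overrides, "overrides")
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("Run configuration:\n")
  for (k in names(x))
    cat(sprintf("  %s: %s\n", k, paste(format(x[[k]]), collapse = " ")))
  invisible(x)
}

pipeline_stages <- c("synth-traces", "fit-traces", "pfo-fit",
                     "synth-xl", "match-xl",
                     "synth-nativems", "nativems-deconv")

#' Run a multi-stage analysis pipeline
#'
#' Executes the named stages in order with file handoffs inside
#' \code{config$outdir}; each stage reads the previous stage's outputs.
#' The resolved configuration is written next to the outputs
#' (\code{resolved_config.yaml}) and per-stage wall times are logged to
#' standard error. Any stage failure propagates as an error.
#'
#' Stages: \code{synth-traces} (trace_NNN.csv + traces_truth.yaml),
#' \code{fit-traces} (kobs_table.csv), \code{pfo-fit} (pfo_fit.csv);
#' \code{synth-xl} (observed_masses.txt, xl_truth.yaml),
#' \code{match-xl} (matches.tsv); \code{synth-nativems} (spectrum.txt,
#' nativems_truth.yaml), \code{nativems-deconv} (oligomers.tsv).
#'
#' @param config a [read_run_config()] result
#' @param stages character vector of stage names, run in the given order
#' @return invisibly, 0 on success
#' @export
run_pipeline <- function(config, stages) {
  stopifnot(inherits(config, "run_config"))
  bad <- setdiff(stages, pipeline_stages)
  if (length(bad))
    stop("unknown stage(s): ", paste(bad, collapse = ", "),
         "; valid stages: ", paste(pipeline_stages, collapse = ", "),
         call. = FALSE)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(unclass(config),
                   file.path(config$outdir, "resolved_config.yaml"))
  for (st in stages) {
    t0 <- proc.time()[["elapsed"]]
    switch(st,
           "synth-traces" = stage_synth_traces(config),
           "fit-traces" = stage_fit_traces(config),
           "pfo-fit" = stage_pfo_fit(config),
           "synth-xl" = stage_synth_xl(config),
           "match-xl" = stage_match_xl(config),
           "synth-nativems" = stage_synth_nativems(config),
           "nativems-deconv" = stage_nativems_deconv(config))
    message(sprintf("[proppinkit] stage %s done in %.2f s (seed %d)",
                    st, proc.time()[["elapsed"]] - t0, config$seed))
  }
  invisible(0L)
}

stage_synth_traces <- function(cfg) {
  g <- gen_trace_series(
    rate_params(cfg$k_on, cfg$k_off, cfg$k_oli, cfg$k_dis),
    accessible_lipid = cfg$accessible_lipid, noise_sd = cfg$noise_sd,
    replicates = cfg$replicates, seed = cfg$seed, duration = cfg$duration,
    n_points = cfg$n_points, accessible_fraction = cfg$accessible_fraction)
  for (i in seq_along(g$traces))
    write_trace_csv(g$traces[[i]],
                    file.path(cfg$outdir, sprintf("trace_%03d.csv", i)))
  write_truth(g$truth, file.path(cfg$outdir, "traces_truth.yaml"))
}

stage_fit_traces <- function(cfg) {
  files <- sort(list.files(cfg$outdir, "^trace_[0-9]+\\.csv$",
                           full.names = TRUE))
  if (!length(files)) stop("fit-traces: no trace_*.csv in ", cfg$outdir,
                           call. = FALSE)
  pts <- do.call(rbind, lapply(files, function(f) {
    tr <- read_trace_csv(f)
    select_kobs1(fit_multiexponential(tr, cfg$n_phases), tr$condition)
  }))
  write_kobs_csv(pts, file.path(cfg$outdir, "kobs_table.csv"))
}

stage_pfo_fit <- function(cfg) {
  pts <- read_kobs_csv(file.path(cfg$outdir, "kobs_table.csv"))
  fit <- fit_pseudo_first_order(pts)
  out <- data.frame(parameter = c("k_on", "k_off_app", "r_squared"),
                    estimate = c(fit$k_on, fit$k_off_app, fit$r_squared),
                    se = c(fit$k_on_se, fit$k_off_app_se, NA))
  utils::write.csv(out, file.path(cfg$outdir, "pfo_fit.csv"),
                   row.names = FALSE, quote = FALSE)
}

stage_synth_xl <- function(cfg) {
  g <- gen_xl_dataset(true_lipid_sites = cfg$true_lipid_sites,
                      true_dipeptide_links = cfg$true_dipeptide_links,
                      ppm_noise_sd = cfg$ppm_noise_sd,
                      n_decoys = cfg$n_decoys, seed = cfg$seed,
                      lipid = xl_lipid(mass = cfg$lipid_mass),
                      linker = xl_linker(linker_mass = cfg$linker_mass))
  writeLines(sprintf("%.8f 1", g$observed),
             file.path(cfg$outdir, "observed_masses.txt"))
  write_fasta(list(g$protein), file.path(cfg$outdir, "protein.fasta"))
  write_truth(g$truth, file.path(cfg$outdir, "xl_truth.yaml"))
}

stage_match_xl <- function(cfg) {
  observed <- read_masses(file.path(cfg$outdir, "observed_masses.txt"))
  protein <- read_fasta(file.path(cfg$outdir, "protein.fasta"))[[1]]
  peps <- digest(protein, max_missed = 1, min_len = 4, max_len = 30)
  lipid <- xl_lipid(mass = cfg$lipid_mass)
  linker <- xl_linker(linker_mass = cfg$linker_mass)
  cand <- classify_candidates(
    rbind(enumerate_lipid_candidates(peps, lipid, linker),
          enumerate_dipeptide_candidates(peps, linker)))
  m <- match_precursors(observed, cand, cfg$tol_ppm)
  write_matches_tsv(m, cand, file.path(cfg$outdir, "matches.tsv"))
}

stage_synth_nativems <- function(cfg) {
  g <- gen_native_spectrum(monomer_mass = cfg$monomer_mass,
                           abundances = cfg$abundances,
                           charge_range = cfg$charge_range,
                           seed = cfg$seed)
  write_peaklist(g$peaks, file.path(cfg$outdir, "spectrum.txt"))
  write_truth(g$truth, file.path(cfg$outdir, "nativems_truth.yaml"))
}

stage_nativems_deconv <- function(cfg) {
  peaks <- read_peaklist(file.path(cfg$outdir, "spectrum.txt"))
  a <- assign_peaks(peaks, cfg$monomer_mass, n_max = cfg$n_max,
                    charge_range = cfg$charge_range,
                    tol_ppm = cfg$nms_tol_ppm)
  write_oligomer_tsv(oligomer_intensities(a),
                     file.path(cfg$outdir, "oligomers.tsv"))
}
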