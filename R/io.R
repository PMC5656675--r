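#' Read protein records from a FASTA file
#'
#' The first whitespace-delimited word of each header is the record id; an
#' optional \code{offset=N} key anywhere in the header sets the
#' \code{numbering_offset} (see [protein_record()]). Sequences are
#' upper-cased and validated against the 20 standard residues.
#'
#' @param path FASTA file
#' @return list of [protein_record()]s, in file order
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ss <- Biostrings::readAAStringSet(path)
  if (!length(ss)) stop("empty FASTA file: ", path, call. = FALSE)
  headers <- names(ss)
  ids <- vapply(strsplit(headers, "\\s+"), `[`, "", 1)
  if (anyDuplicated(ids))
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1], call. = FALSE)
  lapply(seq_along(ss), function(i) {
    off <- 1L
    m <- regmatches(headers[i],
                    regexpr("offset=-?[0-9]+", headers[i]))
    if (length(m)) off <- as.integer(sub("offset=", "", m))
    protein_record(ids[i], as.character(ss[[i]]), numbering_offset = off)
  })
}

#' Write protein records to a FASTA file
#'
#' @param records list of [protein_record()]s
#' @param path output file
#' @export
write_fasta <- function(records, path) {
  headers <- vapply(records, function(r) {
    if (r$numbering_offset != 1L)
      paste0(r$id, " offset=", r$numbering_offset) else r$id
  }, "")
  seqs <- Biostrings::AAStringSet(vapply(records, `[[`, "", "sequence"))
  names(seqs) <- headers
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

trace_meta_keys <- c("total_lipid_mM", "accessible_fraction", "protein_uM",
                     "label", "seed")

#' Write / read a stopped-flow trace CSV
#'
#' Dialect: metadata header lines \code{#key=value} (keys
#' \code{total_lipid_mM}, \code{accessible_fraction}, \code{protein_uM},
#' \code{label}, \code{seed}) followed by a \code{time_s,fluorescence_au}
#' table. Numbers are serialized with 10 significant digits so the round
#' trip is lossless at working precision.
#'
#' @param trace an [sf_trace()]
#' @param path file path
#' @return \code{read_trace_csv} returns the restored [sf_trace()]
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "sf_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  meta <- c(total_lipid_mM = sprintf("%.10g", trace$condition$total_lipid),
            accessible_fraction =
              sprintf("%.10g", trace$condition$accessible_fraction),
            protein_uM = sprintf("%.10g", trace$protein_uM),
            label = trace$condition$label,
            seed = as.character(trace$seed))
  writeLines(paste0("#", names(meta), "=", meta), con)
  writeLines("time_s,fluorescence_au", con)
  writeLines(sprintf("%.10g,%.10g", trace$times, trace$fluorescence), con)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  kv <- strsplit(sub("^#", "", meta_lines), "=", fixed = TRUE)
  meta <- stats::setNames(
    vapply(kv, function(x) paste(x[-1], collapse = "="), ""),
    vapply(kv, `[`, "", 1))
  missing <- setdiff(trace_meta_keys, names(meta))
  if (length(missing))
    stop("trace CSV missing metadata key(s): ",
         paste(paste0("#", missing), collapse = ", "), call. = FALSE)
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  if (body[1] != "time_s,fluorescence_au")
    stop("expected header 'time_s,fluorescence_au'", call. = FALSE)
  dat <- utils::read.csv(textConnection(body))
  if (any(diff(dat$time_s) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  seed <- suppressWarnings(as.integer(meta[["seed"]]))
  cond <- lipid_condition(as.numeric(meta[["total_lipid_mM"]]),
                          as.numeric(meta[["accessible_fraction"]]),
                          label = meta[["label"]])
  sf_trace(dat$time_s, dat$fluorescence_au, cond,
           as.numeric(meta[["protein_uM"]]),
           seed = if (is.na(seed)) NA_integer_ else seed)
}

#' Write / read a two-column m/z-intensity peak list
#'
#' Plain whitespace-delimited text, one \code{mz intensity} pair per line;
#' lines starting with \code{#} are comments.
#'
#' @param peaks a [peak_list()]
#' @param path file path
#' @return \code{read_peaklist} returns a [peak_list()]
#' @export
write_peaklist <- function(peaks, path) {
  stopifnot(inherits(peaks, "peak_list"))
  writeLines(sprintf("%.10g %.10g", peaks$mz, peaks$intensity), path)
  invisible(path)
}

#' @rdname write_peaklist
#' @export
read_peaklist <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  dat <- utils::read.table(path, comment.char = "#",
                           col.names = c("mz", "intensity"))
  peak_list(dat$mz, dat$intensity)
}

#' Read observed precursor masses
#'
#' Accepts either two-column \code{neutral_mass_da intensity} text or an
#' MGF file (detected by a \code{BEGIN IONS} block). MGF \code{PEPMASS}
#' and \code{CHARGE} lines are honoured: the neutral mass is
#' \code{pepmass * z - z * proton}.
#'
#' @param path input file
#' @return numeric vector of neutral masses (Da)
#' @export
read_masses <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  if (any(grepl("^BEGIN IONS", lines))) return(read_mgf_masses(lines))
  dat <- utils::read.table(text = lines[nzchar(lines) &
                                          !grepl("^#", lines)])
  dat[[1]]
}

read_mgf_masses <- function(lines) {
  proton <- 1.007276
  masses <- numeric()
  pepmass <- NA_real_
  charge <- 1L
  for (ln in lines) {
    if (startsWith(ln, "BEGIN IONS")) {
      pepmass <- NA_real_
      charge <- 1L
    } else if (startsWith(ln, "PEPMASS=")) {
      pepmass <- as.numeric(strsplit(sub("PEPMASS=", "", ln), "\\s+")[[1]][1])
    } else if (startsWith(ln, "CHARGE=")) {
      charge <- as.integer(gsub("[^0-9]", "", sub("CHARGE=", "", ln)))
    } else if (startsWith(ln, "END IONS")) {
      if (is.na(pepmass))
        stop("MGF block without PEPMASS", call. = FALSE)
      masses <- c(masses, pepmass * charge - charge * proton)
    }
  }
  masses
}

#' Write cross-link match results as TSV
#'
#' Columns: \code{kind}, \code{peptide_a}, \code{site_a},
#' \code{peptide_b_or_lipid}, \code{site_b}, \code{theo_mass_da},
#' \code{obs_mass_da}, \code{ppm}, \code{classification}.
#'
#' @param matches a [match_precursors()] result
#' @param candidates the candidate table that was matched against
#' @param path output file
#' @export
write_matches_tsv <- function(matches, candidates, path) {
  cand <- candidates[matches$cand_idx, , drop = FALSE]
  if (!"classification" %in% names(cand))
    cand <- classify_candidates(cand)
  out <- data.frame(kind = cand$kind,
                    peptide_a = cand$peptide_a,
                    site_a = cand$site_a,
                    peptide_b_or_lipid = cand$partner,
                    site_b = cand$site_b,
                    theo_mass_da = sprintf("%.6f", matches$theo_mass),
                    obs_mass_da = sprintf("%.6f", matches$obs_mass),
                    ppm = sprintf("%.3f", matches$ppm),
                    classification = cand$classification,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write an oligomer deconvolution summary as TSV
#'
#' Columns: \code{order}, \code{mass_da}, \code{sd_da}, \code{n_peaks},
#' \code{rel_intensity_pct}.
#'
#' @param result an [oligomer_intensities()] result
#' @param path output file
#' @export
write_oligomer_tsv <- function(result, path) {
  out <- data.frame(order = result$order,
                    mass_da = sprintf("%.2f", result$mass),
                    sd_da = sprintf("%.2f", result$mass_sd),
                    n_peaks = result$n_peaks,
                    rel_intensity_pct = sprintf("%.2f",
                                                result$rel_intensity))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write / read a k_obs table CSV
#'
#' Columns \code{accessible_lipid_mM}, \code{kobs1_per_s}, \code{se_per_s}.
#'
#' @param points data frame as used by [fit_pseudo_first_order()]
#' @param path file path
#' @export
write_kobs_csv <- function(points, path) {
  out <- data.frame(accessible_lipid_mM = points$accessible_lipid,
                    kobs1_per_s = points$kobs1, se_per_s = points$se)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_kobs_csv
#' @export
read_kobs_csv <- function(path) {
  dat <- utils::read.csv(path)
  data.frame(accessible_lipid = dat$accessible_lipid_mM,
             kobs1 = dat$kobs1_per_s, se = dat$se_per_s)
}
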