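#' Match observed precursor masses against cross-link candidates
#'
#' For each observed neutral mass, reports every candidate whose
#' theoretical mass lies within \code{tol_ppm} parts per million
#' (\code{|obs - theo| / theo * 1e6 <= tol_ppm}), sorted by absolute ppm
#' error and then by lower candidate mass. All matches within tolerance are
#' reported; none are dropped. Observations with no match produce no rows.
#'
#' @param observed numeric vector of observed neutral masses (Da), > 0
#' @param candidates an \code{xl_candidates} table (any kind)
#' @param tol_ppm matching tolerance (ppm), > 0
#' @return data frame with columns \code{obs_idx}, \code{obs_mass},
#'   \code{cand_idx}, \code{theo_mass}, \code{ppm}, \code{kind},
#'   \code{classification} (if present in \code{candidates})
#' @export
match_precursors <- function(observed, candidates, tol_ppm = 10) {
  if (tol_ppm <= 0) stop("tol_ppm must be > 0", call. = FALSE)
  if (any(!is.finite(observed)) || any(observed <= 0))
    stop("observed masses must be positive and finite", call. = FALSE)
  theo <- candidates$theo_mass
  ord <- order(theo)
  ts <- theo[ord]
  rows <- vector("list", length(observed))
  for (i in seq_along(observed)) {
    m <- observed[i]
    # window in the sorted candidate masses; tolerance is relative to theo,
    # widen slightly and filter exactly
    w <- m * tol_ppm * 1e-6 * (1 + 2 * tol_ppm * 1e-6)
    lo <- findInterval(m - w, ts) + 1L
    hi <- findInterval(m + w, ts)
    if (hi < lo) next
    j <- ord[lo:hi]
    ppm <- (m - theo[j]) / theo[j] * 1e6
    keep <- abs(ppm) <= tol_ppm
    if (!any(keep)) next
    j <- j[keep]; ppm <- ppm[keep]
    o <- order(abs(ppm), theo[j])
    j <- j[o]; ppm <- ppm[o]
    df <- data.frame(obs_idx = i, obs_mass = m, cand_idx = j,
                     theo_mass = theo[j], ppm = ppm,
                     kind = candidates$kind[j], stringsAsFactors = FALSE)
    if ("classification" %in% names(candidates))
      df$classification <- candidates$classification[j]
    rows[[i]] <- df
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(obs_idx = integer(), obs_mass = numeric(),
                      cand_idx = integer(), theo_mass = numeric(),
                      ppm = numeric(), kind = character(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' b/y fragment ion m/z values
#'
#' Standard b and y series: neutral b_i is the sum of the first i residue
#' masses; neutral y_i is the sum of the last i residue masses plus water;
#' m/z = (neutral + z * proton) / z. A cross-link is modelled as a fixed
#' mass delta on the linked residue (for a lipid adduct,
#' [lipid_adduct_delta()]; for a di-peptide link, the partner-chain mass
#' plus linker minus two protons), so every fragment containing the linked
#' position is shifted by \code{link_delta}.
#'
#' @param sequence peptide sequence
#' @param ion_types subset of \code{c("b", "y")}
#' @param max_charge maximum fragment charge (>= 1)
#' @param link_pos position (1-based within the peptide) carrying a
#'   cross-link delta, or NULL
#' @param link_delta neutral-mass delta carried at \code{link_pos} (Da)
#' @param table a [residue_mass_table()]
#' @return data frame with columns \code{ion} (e.g. "b2"), \code{charge},
#'   \code{mz}
#' @examples
#' fragment_masses("GK", ion_types = "y")   # y1 at 147.1128
#' @export
fragment_masses <- function(sequence, ion_types = c("b", "y"),
                            max_charge = 1L, link_pos = NULL,
                            link_delta = 0, table = residue_mass_table()) {
  if (max_charge < 1) stop("max_charge must be >= 1", call. = FALSE)
  bad <- setdiff(ion_types, c("b", "y"))
  if (length(bad))
    stop("unsupported ion type(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  aa <- strsplit(toupper(sequence), "")[[1]]
  if (any(!aa %in% names(table$residues)))
    stop("invalid residue in sequence", call. = FALSE)
  n <- length(aa)
  res <- unname(table$residues[aa])
  if (!is.null(link_pos)) {
    if (link_pos < 1 || link_pos > n)
      stop("link_pos outside peptide", call. = FALSE)
    res[link_pos] <- res[link_pos] + link_delta
  }
  rows <- list()
  for (z in seq_len(max_charge)) {
    if ("b" %in% ion_types) {
      neutral <- cumsum(res)[-n]                      # b1..b(n-1)
      rows[[length(rows) + 1L]] <- data.frame(
        ion = paste0("b", seq_len(n - 1)), charge = z,
        mz = (neutral + z * table$proton) / z, stringsAsFactors = FALSE)
    }
    if ("y" %in% ion_types) {
      neutral <- cumsum(rev(res))[-n] + table$water   # y1..y(n-1)
      rows[[length(rows) + 1L]] <- data.frame(
        ion = paste0("y", seq_len(n - 1)), charge = z,
        mz = (neutral + z * table$proton) / z, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fragment annotation for a cross-link candidate row
#'
#' Convenience wrapper around [fragment_masses()]: fragments one chain of a
#' candidate, carrying the partner (lipid, or the other peptide plus
#' linker) as a fixed delta on the linked residue.
#'
#' @param candidate one row of an \code{xl_candidates} table
#' @param chain \code{"a"} or \code{"b"} (di-peptide candidates only)
#' @param lipid,linker,table chemistry, as elsewhere
#' @param ... passed to [fragment_masses()]
#' @return data frame as from [fragment_masses()]
#' @export
xl_fragment_masses <- function(candidate, chain = c("a", "b"),
                               lipid = xl_lipid(), linker = xl_linker(),
                               table = residue_mass_table(), ...) {
  chain <- match.arg(chain)
  if (chain == "b" && candidate$kind != "dipeptide")
    stop("chain 'b' only exists for di-peptide candidates", call. = FALSE)
  if (candidate$kind == "lipid") {
    seqs <- candidate$peptide_a
    delta <- lipid_adduct_delta(lipid, linker, table)
    pos <- candidate$site_a - candidate$start_a + 1L
  } else {
    this <- if (chain == "a") "a" else "b"
    other <- if (chain == "a") "b" else "a"
    seqs <- candidate[[paste0("peptide_", this)]]
    partner_mass <- peptide_mass(candidate[[paste0("peptide_", other)]],
                                 table)
    delta <- partner_mass + linker$linker_mass - 2 * table$proton
    pos <- candidate[[paste0("site_", this)]] -
      candidate[[paste0("start_", this)]] + 1L
  }
  fragment_masses(seqs, link_pos = pos, link_delta = delta,
                  table = table, ...)
}
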