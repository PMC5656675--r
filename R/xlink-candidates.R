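#' Cross-linker definition
#'
#' Defaults describe BS3 (bis(sulfosuccinimidyl)suberate) with the bridge
#' mass accounted as 140.074 Da and one proton released per reacted amine
#' (two per completed bridge). Besides lysine, BS3 reacts at measurable
#' rates with serine, threonine and tyrosine hydroxyls and with the protein
#' N-terminus, so all of these are reactive by default.
#'
#' @param name linker name
#' @param linker_mass mass added by the intact bridge before proton
#'   accounting (Da)
#' @param reactive_residues residues accepted as link sites
#' @param nterm_reactive whether the protein N-terminus is a site
#' @return an object of class \code{"xl_linker"}
#' @export
xl_linker <- function(name = "BS3", linker_mass = 140.074,
                      reactive_residues = c("K", "S", "T", "Y"),
                      nterm_reactive = TRUE) {
  if (linker_mass <= 0) stop("linker_mass must be > 0", call. = FALSE)
  structure(list(name = name, linker_mass = linker_mass,
                 protons_released_per_bond = 1L,
                 reactive_residues = reactive_residues,
                 nterm_reactive = nterm_reactive),
            class = "xl_linker")
}

#' Cross-linkable lipid definition
#'
#' The default is DOPE (dioleoylphosphatidylethanolamine), the
#' amine-headgroup lipid reachable by an amine-reactive linker, at the
#' 743.36 Da mass accounting used in this workflow. The elemental
#' monoisotopic mass of DOPE (C41H78NO8P, ~743.55 Da) differs from this
#' value; which accounting applies is a configuration choice, so the mass
#' is a parameter, not a constant.
#'
#' @param name lipid name
#' @param mass neutral lipid mass (Da)
#' @return an object of class \code{"xl_lipid"}
#' @export
xl_lipid <- function(name = "DOPE", mass = 743.36) {
  if (!is.finite(mass) || mass <= 0)
    stop("lipid mass must be > 0", call. = FALSE)
  structure(list(name = name, mass = mass), class = "xl_lipid")
}

#' Net mass added to a peptide by a lipid-linker adduct
#'
#' One linker bridges a peptide amine (or hydroxyl) to the lipid headgroup
#' amine; one proton is released from each side, so the net neutral-mass
#' delta is \code{lipid + linker - 2 * proton}. With the default DOPE/BS3
#' accounting this is 881.42 Da.
#'
#' @param lipid an [xl_lipid()]
#' @param linker an [xl_linker()]
#' @param table a [residue_mass_table()] (source of the proton mass)
#' @return neutral mass delta (Da)
#' @examples
#' round(lipid_adduct_delta(), 2)   # 881.42
#' @export
lipid_adduct_delta <- function(lipid = xl_lipid(), linker = xl_linker(),
                               table = residue_mass_table()) {
  stopifnot(inherits(lipid, "xl_lipid"), inherits(linker, "xl_linker"))
  lipid$mass + linker$linker_mass - 2 * table$proton
}

# Valid link sites within one peptide row (from digest()).
# A lysine at the peptide's C-terminal cleavage site cannot carry a link:
# a cross-linked K is not cleaved by trypsin, so such a peptide would not
# exist -- unless the K is the protein C-terminus. S/T/Y sites and the
# protein N-terminus are unrestricted.
peptide_link_sites <- function(pep_row, linker) {
  aa <- strsplit(pep_row$sequence, "")[[1]]
  len <- length(aa)
  pos <- which(aa %in% linker$reactive_residues)
  drop <- pos == len & aa[pos] == "K" & !pep_row$is_cterm
  pos <- pos[!drop]
  res <- aa[pos]
  coord <- pep_row$start + pos - 1L
  if (linker$nterm_reactive && isTRUE(pep_row$is_nterm)) {
    coord <- c(pep_row$start, coord)
    res <- c("N-term", res)
  }
  data.frame(coord = coord, residue = res, stringsAsFactors = FALSE)
}

#' Enumerate lipid-adduct cross-link candidates
#'
#' One candidate per (peptide, reactive site) pair; the candidate's neutral
#' mass is the peptide mass plus [lipid_adduct_delta()].
#'
#' @param peptides a [digest()] result
#' @param lipid an [xl_lipid()]
#' @param linker an [xl_linker()]
#' @param table a [residue_mass_table()]
#' @return data frame of class \code{"xl_candidates"} with columns
#'   \code{kind} ("lipid"), \code{protein_a}, \code{peptide_a},
#'   \code{start_a}, \code{end_a}, \code{site_a}, \code{residue_a},
#'   \code{partner} (lipid name), \code{theo_mass}
#' @export
enumerate_lipid_candidates <- function(peptides, lipid = xl_lipid(),
                                       linker = xl_linker(),
                                       table = residue_mass_table()) {
  delta <- lipid_adduct_delta(lipid, linker, table)
  rows <- lapply(seq_len(nrow(peptides)), function(i) {
    p <- peptides[i, ]
    s <- peptide_link_sites(p, linker)
    if (!nrow(s)) return(NULL)
    data.frame(kind = "lipid", protein_a = p$protein_id,
               peptide_a = p$sequence, start_a = p$start, end_a = p$end,
               site_a = s$coord, residue_a = s$residue,
               partner = lipid$name,
               protein_b = NA_character_, peptide_b = NA_character_,
               start_b = NA_integer_, end_b = NA_integer_,
               site_b = NA_integer_, residue_b = NA_character_,
               theo_mass = p$mass + delta, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(empty_candidates())))
  rownames(out) <- NULL
  class(out) <- c("xl_candidates", "data.frame")
  out
}

empty_candidates <- function() {
  data.frame(kind = character(), protein_a = character(),
             peptide_a = character(), start_a = integer(),
             end_a = integer(), site_a = integer(), residue_a = character(),
             partner = character(), protein_b = character(),
             peptide_b = character(), start_b = integer(),
             end_b = integer(), site_b = integer(), residue_b = character(),
             theo_mass = numeric(), stringsAsFactors = FALSE)
}

#' Enumerate di-peptide cross-link candidates
#'
#' All unordered peptide pairs (including a peptide with itself, the
#' homodimeric case) in which each peptide carries at least one valid link
#' site. The candidate neutral mass is
#' \code{mass_a + mass_b + linker - 2 * proton}. Site coordinates are
#' reported for the first valid site of each peptide; the precursor mass is
#' site-independent.
#'
#' @param peptides a [digest()] result
#' @param linker an [xl_linker()]
#' @param mass_window optional \code{c(lo, hi)} neutral-mass filter (Da)
#' @param table a [residue_mass_table()]
#' @return data frame of class \code{"xl_candidates"}, \code{kind}
#'   "dipeptide"
#' @export
enumerate_dipeptide_candidates <- function(peptides, linker = xl_linker(),
                                           mass_window = NULL,
                                           table = residue_mass_table()) {
  n <- nrow(peptides)
  sites <- lapply(seq_len(n), function(i)
    peptide_link_sites(peptides[i, ], linker))
  has_site <- vapply(sites, nrow, 0L) > 0
  idx <- which(has_site)
  rows <- list()
  for (a in idx) for (b in idx[idx >= a]) {
    pa <- peptides[a, ]; pb <- peptides[b, ]
    m <- pa$mass + pb$mass + linker$linker_mass - 2 * table$proton
    if (!is.null(mass_window) && (m < mass_window[1] || m > mass_window[2]))
      next
    rows[[length(rows) + 1L]] <- data.frame(
      kind = "dipeptide", protein_a = pa$protein_id,
      peptide_a = pa$sequence, start_a = pa$start, end_a = pa$end,
      site_a = sites[[a]]$coord[1], residue_a = sites[[a]]$residue[1],
      partner = pb$sequence,
      protein_b = pb$protein_id, peptide_b = pb$sequence,
      start_b = pb$start, end_b = pb$end,
      site_b = sites[[b]]$coord[1], residue_b = sites[[b]]$residue[1],
      theo_mass = m, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(rows, list(empty_candidates())))
  rownames(out) <- NULL
  class(out) <- c("xl_candidates", "data.frame")
  out
}

#' Classify a di-peptide cross-link as intra- or intermolecular
#'
#' For a homo-oligomer, a link between two copies of the same or
#' coordinate-overlapping peptide can only arise between two protein
#' molecules and is therefore unambiguously intermolecular. Links between
#' disjoint peptides are ambiguous at the precursor level: intra- and
#' intermolecular links have identical mass. Peptides from different
#' proteins are labelled heteromeric. The classification is symmetric in
#' the two peptides.
#'
#' @param start_a,end_a,start_b,end_b peptide coordinate ranges (inclusive)
#' @param protein_a,protein_b protein identifiers
#' @return one of \code{"inter"}, \code{"ambiguous"}, \code{"heteromeric"}
#' @examples
#' classify_crosslink(100, 110, 105, 115)   # "inter"
#' classify_crosslink(50, 60, 200, 210)     # "ambiguous"
#' @export
classify_crosslink <- function(start_a, end_a, start_b, end_b,
                               protein_a = "p", protein_b = "p") {
  if (end_a < start_a || end_b < start_b)
    stop("peptide ranges must have end >= start", call. = FALSE)
  if (protein_a != protein_b) return("heteromeric")
  if (start_a <= end_b && start_b <= end_a) "inter" else "ambiguous"
}

#' Classify every di-peptide candidate in a candidate table
#'
#' @param candidates an [enumerate_dipeptide_candidates()] result (rows of
#'   other kinds get classification \code{"lipid"})
#' @return the table with a \code{classification} column appended
#' @export
classify_candidates <- function(candidates) {
  cl <- character(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    cl[i] <- if (candidates$kind[i] != "dipeptide") "lipid" else
      classify_crosslink(candidates$start_a[i], candidates$end_a[i],
                         candidates$start_b[i], candidates$end_b[i],
                         candidates$protein_a[i], candidates$protein_b[i])
  }
  candidates$classification <- cl
  candidates
}
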