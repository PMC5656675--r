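# Monoisotopic residue masses (Da) for the 20 standard amino acids, plus
# the constants used throughout the mass arithmetic.

#' Monoisotopic residue mass table
#'
#' Residue (i.e. dehydrated amino-acid) monoisotopic masses in Da, plus the
#' water and proton masses and the deltas of the two variable modifications
#' used in the search chemistry: carbamidomethylation of cysteine
#' (+57.021464 Da) and oxidation of methionine (+15.994915 Da).
#'
#' @param overrides named numeric vector of residue-mass overrides (Da)
#' @return an object of class \code{"residue_mass_table"}: a list with
#'   \code{residues} (named vector), \code{water}, \code{proton},
#'   \code{mods} (named vector of modification deltas)
#' @export
residue_mass_table <- function(overrides = NULL) {
  residues <- c(
    G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
    T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
    N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
    E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
    R = 156.10111, Y = 163.06333, W = 186.07931)
  if (!is.null(overrides)) {
    bad <- setdiff(names(overrides), names(residues))
    if (length(bad))
      stop("unknown residue(s) in overrides: ", paste(bad, collapse = ", "),
           call. = FALSE)
    residues[names(overrides)] <- overrides
  }
  if (any(residues <= 0)) stop("residue masses must be > 0", call. = FALSE)
  structure(list(residues = residues, water = 18.010565, proton = 1.007276,
                 mods = c(carbamidomethyl = 57.021464,
                          oxidation = 15.994915)),
            class = "residue_mass_table")
}

#' A protein sequence with coordinate numbering
#'
#' \code{numbering_offset} is the protein coordinate of sequence position 1
#' (default 1). Offsets <= 0 represent expression-tag residues so that
#' native-sequence site labels are preserved: e.g. with offset -4 the fifth
#' residue of the construct is coordinate 0 and the sixth is 1. Coordinate
#' 0 does not exist in this convention if the offset is positive.
#'
#' @param id protein identifier
#' @param sequence amino-acid sequence (upper-case one-letter codes)
#' @param numbering_offset protein coordinate of the first residue
#' @return an object of class \code{"protein_record"}
#' @export
protein_record <- function(id, sequence, numbering_offset = 1L) {
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stop("sequence must be non-empty", call. = FALSE)
  aa <- strsplit(sequence, "")[[1]]
  bad <- which(!aa %in% names(residue_mass_table()$residues))
  if (length(bad))
    stop("invalid residue '", aa[bad[1]], "' at position ", bad[1],
         " of ", id, call. = FALSE)
  structure(list(id = id, sequence = sequence,
                 numbering_offset = as.integer(numbering_offset)),
            class = "protein_record")
}

# sequence position (1-based) -> protein coordinate under the record's offset
position_to_coord <- function(protein, pos) {
  protein$numbering_offset + pos - 1L
}

#' In-silico tryptic digestion
#'
#' Cleaves C-terminal to K and R, except when the following residue is
#' proline. Returns all peptides with at most \code{max_missed} internal
#' missed cleavages whose length lies in \code{[min_len, max_len]}.
#' Peptide coordinates honour the record's \code{numbering_offset}.
#'
#' @param protein a [protein_record()]
#' @param max_missed maximum internal missed cleavages (>= 0)
#' @param min_len,max_len peptide length window
#' @return a data frame of class \code{"peptide_set"} with columns
#'   \code{protein_id}, \code{start}, \code{end} (protein coordinates,
#'   inclusive), \code{sequence}, \code{missed_cleavages}, \code{mass}
#'   (neutral monoisotopic, Da), \code{is_nterm}, \code{is_cterm}
#' @examples
#' p <- protein_record("demo", "AKRPGKG")
#' digest(p, max_missed = 0)$sequence   # "AK" "RPGK" "G"
#' @export
digest <- function(protein, max_missed = 0L, min_len = 1L, max_len = 100L) {
  stopifnot(inherits(protein, "protein_record"))
  if (max_missed < 0) stop("max_missed must be >= 0", call. = FALSE)
  if (min_len < 1 || min_len > max_len)
    stop("need 1 <= min_len <= max_len", call. = FALSE)
  aa <- strsplit(protein$sequence, "")[[1]]
  np <- length(aa)
  # cleavage sites: position i such that the bond after residue i is cut
  cut_after <- which(aa %in% c("K", "R"))
  cut_after <- cut_after[cut_after == np | aa[cut_after + 1] != "P"]
  bounds <- c(0L, cut_after, if (!np %in% cut_after) np)  # segment ends
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1]
  nseg <- length(starts)

  rows <- list()
  tab <- residue_mass_table()
  for (i in seq_len(nseg)) {
    for (j in i:min(nseg, i + max_missed)) {
      s <- starts[i]; e <- ends[j]
      len <- e - s + 1L
      if (len < min_len || len > max_len) next
      seqs <- paste(aa[s:e], collapse = "")
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = protein$id,
        start = position_to_coord(protein, s),
        end = position_to_coord(protein, e),
        sequence = seqs,
        missed_cleavages = j - i,
        mass = sum(tab$residues[aa[s:e]]) + tab$water,
        is_nterm = s == 1L,
        is_cterm = e == np,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(protein_id = character(), start = integer(), end = integer(),
               sequence = character(), missed_cleavages = integer(),
               mass = numeric(), is_nterm = logical(), is_cterm = logical())
  rownames(out) <- NULL
  class(out) <- c("peptide_set", "data.frame")
  out
}

#' Neutral monoisotopic peptide mass
#'
#' Sum of residue masses plus one water, plus any variable-modification
#' deltas. Modifications are given as counts, e.g.
#' \code{c(carbamidomethyl = 1)}; a modification is rejected if the peptide
#' lacks the residue it targets (C for carbamidomethylation, M for
#' oxidation).
#'
#' @param sequence peptide sequence (one-letter codes)
#' @param table a [residue_mass_table()]
#' @param mods named integer vector of modification counts, or NULL
#' @return neutral monoisotopic mass (Da)
#' @examples
#' peptide_mass("G")   # 75.032025
#' @export
peptide_mass <- function(sequence, table = residue_mass_table(),
                         mods = NULL) {
  if (!nzchar(sequence)) stop("empty peptide sequence", call. = FALSE)
  aa <- strsplit(toupper(sequence), "")[[1]]
  bad <- which(!aa %in% names(table$residues))
  if (length(bad))
    stop("invalid residue '", aa[bad[1]], "' at position ", bad[1],
         call. = FALSE)
  m <- sum(table$residues[aa]) + table$water
  if (!is.null(mods)) {
    target <- c(carbamidomethyl = "C", oxidation = "M")
    for (nm in names(mods)) {
      if (!nm %in% names(table$mods))
        stop("unknown modification: ", nm, call. = FALSE)
      if (mods[[nm]] > sum(aa == target[[nm]]))
        stop("modification '", nm, "' exceeds available ", target[[nm]],
             " residues", call. = FALSE)
      m <- m + mods[[nm]] * table$mods[[nm]]
    }
  }
  unname(m)
}
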