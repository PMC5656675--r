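test_that("tryptic digestion cleaves after K/R except before proline", {
  p <- protein_record("demo", "AKRPGKG")
  expect_equal(digest(p, max_missed = 0)$sequence, c("AK", "RPGK", "G"))
})

test_that("zero-missed-cleavage peptides tile the protein exactly once", {
  set.seed(19)
  for (i in 1:10) {
    prot <- gen_protein(sample(30:200, 1), seed = i, id = "r")
    peps <- digest(prot, max_missed = 0)
    expect_identical(paste(peps$sequence, collapse = ""), prot$sequence)
    expect_equal(peps$start[1], 1L)
    expect_equal(peps$end[nrow(peps)], nchar(prot$sequence))
  }
})

test_that("numbering offsets map tag residues to non-positive coordinates", {
  p <- protein_record("tagged", "GR", numbering_offset = -3L)
  d <- digest(p)
  expect_equal(d$start, -3L)
  expect_equal(d$end, -2L)
})

test_that("missed cleavages expand the peptide set as expected", {
  p <- protein_record("demo", "AKGKA")
  d0 <- digest(p, max_missed = 0)
  d1 <- digest(p, max_missed = 1)
  expect_equal(sort(d0$sequence), sort(c("AK", "GK", "A")))
  expect_setequal(d1$sequence, c("AK", "GK", "A", "AKGK", "GKA"))
  expect_equal(d1$missed_cleavages[d1$sequence == "AKGK"], 1L)
  expect_error(protein_record("bad", "AXK"), "position 2")
})

test_that("peptide masses are residue sums plus water plus modifications", {
  expect_equal(peptide_mass("G"), 57.02146 + 18.010565, tolerance = 1e-9)
  expect_equal(peptide_mass("C", mods = c(carbamidomethyl = 1)),
               peptide_mass("C") + 57.021464, tolerance = 1e-9)
  expect_equal(peptide_mass("MC", mods = c(oxidation = 1)),
               peptide_mass("MC") + 15.994915, tolerance = 1e-9)
  expect_error(peptide_mass(""), "empty")
  expect_error(peptide_mass("GG", mods = c(carbamidomethyl = 1)), "exceeds")
  # digest() masses agree with peptide_mass()
  d <- digest(protein_record("p", "AKRPGKG"))
  expect_equal(d$mass, vapply(d$sequence, peptide_mass, 0), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("the DOPE/BS3 adduct delta is 881.42 Da and peptide-independent", {
  delta <- lipid_adduct_delta()
  expect_equal(round(delta, 2), 881.42)
  expect_equal(delta, 743.36 + 140.074 - 2 * 1.007276, tolerance = 1e-9)
  expect_error(xl_lipid(mass = 0), "> 0")
  peps <- digest(protein_record("p", "AKRPGKG"))
  cand <- enumerate_lipid_candidates(peps)
  expect_equal(cand$theo_mass,
               peps$mass[match(cand$peptide_a, peps$sequence)] + delta,
               tolerance = 1e-9)
})

test_that("lipid candidate sites respect the blocked-cleavage rule for K", {
  # RGSTKA: K ends peptide GSTK at a cleavage site -> only S and T react
  peps <- digest(protein_record("p", "RGSTKA"))
  gstk <- enumerate_lipid_candidates(peps[peps$sequence == "GSTK", ])
  expect_setequal(gstk$residue_a, c("S", "T"))
  # a C-terminal protein K is a valid site
  pepK <- digest(protein_record("p", "RGAK"))
  ak <- enumerate_lipid_candidates(pepK[pepK$sequence == "GAK", ])
  expect_true("K" %in% ak$residue_a)
  # an internal missed-cleavage K is a valid site
  d1 <- digest(protein_record("p", "RAKGKA"), max_missed = 1)
  akgk <- enumerate_lipid_candidates(d1[d1$sequence == "AKGK", ])
  expect_equal(akgk$residue_a, "K")
  expect_equal(akgk$site_a, 3L)
  # no reactive residue, not protein N-terminal -> no candidates
  d <- digest(protein_record("p", "RGGAGGA"))
  none <- enumerate_lipid_candidates(d[d$sequence == "GGAGGA", ])
  expect_equal(nrow(none), 0L)
  # the protein N-terminus itself is a site
  nt <- enumerate_lipid_candidates(d[d$sequence == "R", ])
  expect_true("N-term" %in% nt$residue_a)
})

test_that("di-peptide candidates cover all unordered pairs incl. homodimers", {
  peps <- digest(protein_record("p", "SKTKYK"))  # SK, TK, YK: all have sites
  cand <- enumerate_dipeptide_candidates(peps)
  n <- nrow(peps)
  expect_equal(nrow(cand), n * (n + 1) / 2)
  expect_true(any(cand$peptide_a == cand$peptide_b &
                    cand$start_a == cand$start_b))
  tab <- residue_mass_table()
  i <- which(cand$peptide_a == "SK" & cand$peptide_b == "TK")
  expect_equal(cand$theo_mass[i],
               peptide_mass("SK") + peptide_mass("TK") + 140.074 -
                 2 * tab$proton, tolerance = 1e-9)
  # a mass window filters candidates
  win <- range(cand$theo_mass)
  narrowed <- enumerate_dipeptide_candidates(peps,
                                             mass_window = c(win[1], win[1]))
  expect_lt(nrow(narrowed), nrow(cand))
})

test_that("cross-link classification follows the overlap rule and is symmetric", {
  expect_equal(classify_crosslink(100, 110, 105, 115), "inter")
  expect_equal(classify_crosslink(390, 401, 390, 401), "inter")
  expect_equal(classify_crosslink(50, 60, 200, 210), "ambiguous")
  expect_equal(classify_crosslink(50, 60, 200, 210, "p1", "p2"),
               "heteromeric")
  set.seed(23)
  for (i in 1:25) {
    a <- sort(sample(1:300, 2)); b <- sort(sample(1:300, 2))
    expect_identical(classify_crosslink(a[1], a[2], b[1], b[2]),
                     classify_crosslink(b[1], b[2], a[1], a[2]))
  }
})

test_that("precursor matching agrees with an exhaustive scan oracle", {
  set.seed(31)
  g <- gen_xl_dataset(true_lipid_sites = 50, true_dipeptide_links = 0,
                      ppm_noise_sd = 3, n_decoys = 200, seed = 31)
  m <- match_precursors(g$observed, g$candidates, tol_ppm = 10)
  oracle <- brute_force_match(g$observed, g$candidates$theo_mass, 10)
  key <- function(o, c) paste(o, c)
  expect_setequal(key(m$obs_idx, m$cand_idx), key(oracle$obs, oracle$cand))
  # every true candidate is recovered at 10 ppm with 3 ppm noise
  expect_true(all(g$truth$true_idx %in% unique(m$cand_idx)))
})

test_that("matching respects tolerance boundaries and ordering", {
  peps <- digest(protein_record("p", "SKTKYK"))
  cand <- enumerate_lipid_candidates(peps)
  theo <- cand$theo_mass[1]
  exact <- match_precursors(theo, cand, 10)
  expect_equal(exact$ppm[1], 0)
  off <- match_precursors(theo * (1 + 20e-6), cand, 10)
  expect_equal(nrow(off[off$cand_idx == 1, ]), 0L)
  expect_error(match_precursors(-1, cand, 10), "positive")
  expect_error(match_precursors(theo, cand, 0), "tol_ppm")
  # within one observation, matches are sorted by |ppm|
  m <- match_precursors(theo * (1 + 2e-6), cand, 1000)
  expect_true(all(diff(abs(m$ppm)) >= 0))
})

test_that("b/y fragment masses follow the residue-sum arithmetic", {
  tab <- residue_mass_table()
  fr <- fragment_masses("GK", ion_types = "y")
  expect_equal(fr$mz[fr$ion == "y1"],
               128.09496 + tab$water + tab$proton, tolerance = 1e-6)
  # complement identity: b_i + y_(n-i) = peptide neutral + 2 protons
  seqs <- c("GASK", "PEPTIDER", "WLKYM")
  for (s in seqs) {
    fr <- fragment_masses(s)
    n <- nchar(s)
    b <- fr$mz[grepl("^b", fr$ion)]
    y <- fr$mz[grepl("^y", fr$ion)]
    expect_equal(b + rev(y), rep(peptide_mass(s) + 2 * tab$proton, n - 1),
                 tolerance = 1e-9)
  }
  expect_error(fragment_masses("GK", ion_types = "a"), "ion type")
})

test_that("a lipid adduct shifts fragments containing the linked site", {
  delta <- lipid_adduct_delta()
  plain <- fragment_masses("GASTK", ion_types = "y")
  linked <- fragment_masses("GASTK", ion_types = "y",
                            link_pos = 3, link_delta = delta)
  # y1, y2 (K, TK) exclude the S at position 3; y3, y4 include it
  expect_equal(linked$mz[1:2], plain$mz[1:2], tolerance = 1e-9)
  expect_equal(linked$mz[3:4], plain$mz[3:4] + delta, tolerance = 1e-9)
  # candidate-level wrapper carries the partner chain as a delta
  peps <- digest(protein_record("p", "SKTKYK"))
  dip <- enumerate_dipeptide_candidates(peps)
  i <- which(dip$peptide_a == "SK" & dip$peptide_b == "TK")[1]
  fr <- xl_fragment_masses(dip[i, ], chain = "a")
  tab <- residue_mass_table()
  partner_delta <- peptide_mass("TK") + 140.074 - 2 * tab$proton
  base <- fragment_masses("SK")
  expect_equal(fr$mz[fr$ion == "b1"],
               base$mz[base$ion == "b1"] + partner_delta, tolerance = 1e-9)
})
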