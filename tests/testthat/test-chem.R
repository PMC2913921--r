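# In-silico digestion and monoisotopic mass computation.

test_that("tryptic digestion follows the trypsin rule (after K/R, not before P)", {
  expect_equal(tryptic_digest("AKRPGKT"), c("AK", "RPGK", "T"))
  expect_equal(tryptic_digest("GGG"), "GGG")
  expect_equal(tryptic_digest("KKK"), c("K", "K", "K"))
  expect_equal(tryptic_digest(""), character(0))
  expect_error(tryptic_digest("AKZ"), "Z")
})

test_that("digestion partitions the protein and is stable under random inputs", {
  set.seed(11)
  for (i in 1:25) {
    protein <- paste(sample(canonical_residues(), sample(5:120, 1),
                            replace = TRUE), collapse = "")
    peps <- tryptic_digest(protein)
    expect_identical(paste(peps, collapse = ""), protein)
    # any internal K/R left in a fragment must be followed by P
    for (pep in peps) {
      ch <- strsplit(pep, "")[[1]]
      if (length(ch) > 1) {
        sites <- which(ch[-length(ch)] %in% c("K", "R"))
        expect_true(all(ch[sites + 1] == "P"))
      }
    }
  }
})

test_that("missed cleavages append joined adjacent fragments", {
  expect_setequal(tryptic_digest("AKGGKCCR", missed_cleavages = 1),
                  c("AK", "GGK", "CCR", "AKGGK", "GGKCCR"))
})

test_that("residue composition sums residue formulas plus one water", {
  expect_identical(residue_composition("G"),
                   c(C = 2L, H = 5L, N = 1L, O = 2L, S = 0L))
  expect_identical(residue_composition("GK"),
                   c(C = 8L, H = 17L, N = 3L, O = 3L, S = 0L))
  expect_identical(residue_composition("CM")[["S"]], 2L)
  expect_error(residue_composition("GXK"), "X")
  expect_error(residue_composition(""), "empty")
})

test_that("composition round-trips against per-residue summation", {
  set.seed(21)
  for (i in 1:20) {
    seq <- random_peptide(sample(2:30, 1))
    per_residue <- Reduce(`+`, lapply(strsplit(seq, "")[[1]], function(a) {
      residue_composition(a)
    }))
    # each single-residue call added one water; keep exactly one
    n <- nchar(seq)
    per_residue[["H"]] <- per_residue[["H"]] - 2L * (n - 1L)
    per_residue[["O"]] <- per_residue[["O"]] - (n - 1L)
    expect_identical(residue_composition(seq), per_residue)
  }
})

test_that("monoisotopic masses match the element-summation oracle", {
  gk <- residue_composition("GK")
  expect_equal(monoisotopic_mass(gk, 0), 203.126992, tolerance = 1e-9)
  expect_equal(monoisotopic_mass(gk, 100), 203.126992 + 8 * 1.003355,
               tolerance = 1e-9)
  expect_equal(monoisotopic_mass(gk, 0), unname(oracle_mass(gk)))
  # spec'd atomic inventory: MK is 277.146013 Da by direct summation
  expect_equal(peptide_mass("MK"), unname(oracle_mass(residue_composition("MK"))))
  expect_equal(peptide_mass("MK"), 277.146013, tolerance = 1e-9)
  expect_error(monoisotopic_mass(gk, -1), "\\[0, 100\\]")
  expect_error(monoisotopic_mass(gk, 101), "\\[0, 100\\]")
})

test_that("mass is linear in incorporation and shifts 1.003355 Da per carbon", {
  set.seed(31)
  for (i in 1:20) {
    seq <- random_peptide(sample(2:40, 1))
    el <- residue_composition(seq)
    m0 <- monoisotopic_mass(el, 0)
    m100 <- monoisotopic_mass(el, 100)
    expect_equal(m100 - m0, el[["C"]] * 1.003355, tolerance = 1e-12)
    for (p in c(25, 50, 75)) {
      expect_equal(monoisotopic_mass(el, p) - m0,
                   (p / 100) * el[["C"]] * 1.003355, tolerance = 1e-12)
    }
    expect_equal(monoisotopic_mass(el, 50), (m0 + m100) / 2,
                 tolerance = 1e-12)
  }
})

test_that("mass is additive over sequence concatenation up to one water", {
  set.seed(41)
  water <- 2 * 1.007825 + 15.994915
  for (i in 1:15) {
    a <- random_peptide(sample(2:15, 1))
    b <- random_peptide(sample(2:15, 1))
    expect_equal(peptide_mass(paste0(a, b)),
                 peptide_mass(a) + peptide_mass(b) - water,
                 tolerance = 1e-9)
  }
})

test_that("reference building filters by length and light mass, keeps duplicates", {
  # MKGK digests to MK (277.15 Da) and GK (203.13 Da): both below 300 Da
  expect_error(build_reference_peptides("MKGK"), "empty reference")
  # a length-41 peptide is excluded by the length filter
  long_pep <- paste(rep("A", 41), collapse = "")
  tab <- build_reference_peptides(c(paste0(long_pep, "K", "WWPEPTIDEK"),
                                    "WWPEPTIDEK"))
  expect_identical(tab$sequence, c("WWPEPTIDEK", "WWPEPTIDEK"))
  expect_equal(tab$length, c(10, 10))
  expect_equal(tab$mass_light,
               rep(peptide_mass("WWPEPTIDEK"), 2), tolerance = 1e-12)
  expect_equal(tab$mass_heavy - tab$mass_light,
               tab$n_carbon * 1.003355, tolerance = 1e-9)
  # tightening the window can empty the reference
  expect_error(build_reference_peptides("WWPEPTIDEK", mz_min = 5000),
               "empty reference")
})

test_that("FASTA input supports wrapped records and strips stop characters", {
  fa <- write_test_fasta(c(p1 = paste0(strrep("WPEPTIDES", 10), "K"),
                           p2 = "WWPEPTIDEK*"), width = 17)
  expect_warning(seqs <- read_fasta_proteins(fa), "\\*")
  expect_identical(unname(nchar(seqs)), c(91L, 10L))
  tab <- suppressWarnings(build_reference_peptides(fa))
  expect_true("WWPEPTIDEK" %in% tab$sequence)
  expect_error(read_fasta_proteins(tempfile()), "not found")
})

test_that("proteins with non-canonical residues are skipped with a warning", {
  expect_warning(
    tab <- build_reference_peptides(c("WWPEPTIDEK", "WWBADPROTEINX")),
    "skipped"
  )
  expect_identical(tab$sequence, "WWPEPTIDEK")
})

test_that("reference peptide tables round-trip through disk", {
  tab <- build_reference_peptides(c("WWPEPTIDEKAAAGGWWK", "LLNQWYRPK"))
  path <- tempfile(fileext = ".tsv")
  write_reference_peptides(tab, path)
  back <- read_reference_peptides(path)
  expect_identical(back$sequence, tab$sequence)
  expect_identical(back$mass_light, tab$mass_light)
  expect_identical(back$mass_heavy, tab$mass_heavy)
})
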