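Package: hdpr
Title: Partial 13C Incorporation into Peptides from the Half Decimal Place Rule
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates partial 13C incorporation (atom % 13C) into tryptic
    peptides from high-resolution, deconvoluted peptide mass lists, without
    requiring peptide identification. The method exploits the half decimal
    place rule (HDPR): the fractional part of a tryptic peptide's
    monoisotopic mass grows linearly with the mass, and the slope of that
    relationship increases in proportion to the amount of incorporated
    heavy carbon. The package calibrates 0 and 100 atom % reference slopes
    from an in-silico tryptic digest of any proteome, unwraps the periodic
    decimal-residual bands with k-means classification after a mass
    transformation, fits zero-intercept slopes by exact least squares or by
    robust iteratively re-weighted least squares, and converts a user mass
    list's slope into atom % 13C with a standard error. A synthetic
    tryptic-peptide generator and a subsampling accuracy experiment are
    included for validation at known incorporation levels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    grDevices,
    graphics,
    stats,
    utils
Suggests:
    MASS,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
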