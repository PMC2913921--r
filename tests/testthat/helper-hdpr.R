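# Shared fixtures and independent oracles for the hdpr test suite.

# Element masses retyped independently of the package internals, for
# oracle-style mass summation in tests.
ORACLE_MASS <- c(C = 12.000000, H = 1.007825, N = 14.003074,
                 O = 15.994915, S = 31.972071)

# Direct element-mass summation oracle: mass of an element-count vector
# at a given atom % 13C, written as plain arithmetic.
oracle_mass <- function(counts, incorporation = 0) {
  counts["C"] * ORACLE_MASS["C"] + counts["H"] * ORACLE_MASS["H"] +
    counts["N"] * ORACLE_MASS["N"] + counts["O"] * ORACLE_MASS["O"] +
    counts["S"] * ORACLE_MASS["S"] +
    (incorporation / 100) * counts["C"] * (13.003355 - 12.000000)
}

# Brute-force zero-intercept slope: minimise the error sum of squares
# over a slope grid, iteratively refined to 1e-9 resolution. Independent
# of the closed-form estimator it checks.
bruteforce_slope <- function(mass, residual, lower = 0, upper = 2e-3) {
  sse <- function(b) sum((residual - b * mass)^2)
  for (pass in 1:12) {
    grid <- seq(lower, upper, length.out = 101)
    vals <- vapply(grid, sse, numeric(1))
    best <- which.min(vals)
    step <- grid[2] - grid[1]
    lower <- grid[max(1, best - 1)]
    upper <- grid[min(length(grid), best + 1)]
    if (step < 1e-12) break
  }
  (lower + upper) / 2
}

# Random peptide-like sequence ending in K/R.
random_peptide <- function(len) {
  aas <- hdpr::canonical_residues()
  paste0(paste(sample(aas, len - 1, replace = TRUE), collapse = ""),
         sample(c("K", "R"), 1))
}

# Write a small FASTA file (wrapped at `width` columns) and return its path.
write_test_fasta <- function(seqs, path = tempfile(fileext = ".fasta"),
                             width = 60) {
  lines <- unlist(lapply(seq_along(seqs), function(i) {
    name <- if (!is.null(names(seqs))) names(seqs)[i] else paste0("prot", i)
    body <- gsub(sprintf("(.{1,%d})", width), "\\1\n", seqs[i])
    c(paste0(">", name), strsplit(body, "\n")[[1]])
  }))
  writeLines(lines, path)
  path
}

# Minimal hand-built reference model carrying the published calibration
# slopes, for arithmetic tests that need no proteome.
printed_reference <- function(b_12C = 5.1357e-4, b_13C = 6.3347e-4) {
  structure(
    list(b_12C = b_12C, b_13C = b_13C, fit_light = NULL, fit_heavy = NULL,
         n_peptides = NA_integer_, source = "printed slopes",
         filters = list(mz_min = 300, mz_max = 6000, len_min = 2,
                        len_max = 40),
         transform_constant = 1800,
         light_centers = c(0, 2000, 4000),
         heavy_centers = c(0, 1600, 3200, 4800)),
    class = "hdpr_reference"
  )
}

# Large shared fixture for the acceptance checks: 50,000 synthetic
# tryptic-like peptides and their calibration, built once per session.
.acceptance_cache <- new.env(parent = emptyenv())
acceptance_fixture <- function() {
  if (is.null(.acceptance_cache$ref)) {
    peps <- hdpr::generate_synthetic_peptides(50000, seed = 20100624)
    .acceptance_cache$peps <- peps
    .acceptance_cache$ref <- hdpr::calibrate(peps)
  }
  list(peptides = .acceptance_cache$peps, reference = .acceptance_cache$ref)
}
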