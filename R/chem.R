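# Peptide chemistry: in-silico tryptic digestion and exact monoisotopic
# masses at arbitrary 13C incorporation, by element counting.

# Monoisotopic element masses (Da).
ELEMENT_MASSES <- c(
  C = 12.000000,
  H = 1.007825,
  N = 14.003074,
  O = 15.994915,
  S = 31.972071
)

# Mass gained when one 12C is replaced by 13C (13.003355 - 12.000000 Da).
C13_SHIFT <- 1.003355

# Monoisotopic residue compositions (peptide-bond residues, i.e. amino acid
# minus one water) for the 20 canonical amino acids, one row per one-letter
# code, columns C/H/N/O/S.
RESIDUE_ELEMENTS <- matrix(
  c(
    # C   H   N  O  S
      3,  5,  1, 1, 0,  # A Ala
      6, 12,  4, 1, 0,  # R Arg
      4,  6,  2, 2, 0,  # N Asn
      4,  5,  1, 3, 0,  # D Asp
      3,  5,  1, 1, 1,  # C Cys
      5,  7,  1, 3, 0,  # E Glu
      5,  8,  2, 2, 0,  # Q Gln
      2,  3,  1, 1, 0,  # G Gly
      6,  7,  3, 1, 0,  # H His
      6, 11,  1, 1, 0,  # I Ile
      6, 11,  1, 1, 0,  # L Leu
      6, 12,  2, 1, 0,  # K Lys
      5,  9,  1, 1, 1,  # M Met
      9,  9,  1, 1, 0,  # F Phe
      5,  7,  1, 1, 0,  # P Pro
      3,  5,  1, 2, 0,  # S Ser
      4,  7,  1, 2, 0,  # T Thr
     11, 10,  2, 1, 0,  # W Trp
      9,  9,  1, 2, 0,  # Y Tyr
      5,  9,  1, 1, 0   # V Val
  ),
  ncol = 5, byrow = TRUE,
  dimnames = list(
    c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
      "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
    c("C", "H", "N", "O", "S")
  )
)

# Monoisotopic mass of each residue and of water, precomputed.
RESIDUE_MASSES <- drop(RESIDUE_ELEMENTS %*% ELEMENT_MASSES)
WATER_MASS <- 2 * ELEMENT_MASSES[["H"]] + ELEMENT_MASSES[["O"]]

#' Amino acids handled by the package
#'
#' @return Character vector of the 20 canonical one-letter amino-acid codes.
#' @export
canonical_residues <- function() rownames(RESIDUE_ELEMENTS)

.check_canonical <- function(sequence) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), rownames(RESIDUE_ELEMENTS))
  if (length(bad) > 0) {
    stop("non-canonical residue code(s) in sequence: ",
         paste(sQuote(bad), collapse = ", "), call. = FALSE)
  }
  chars
}

#' In-silico tryptic digestion of a protein sequence
#'
#' Cleaves C-terminal of lysine (K) and arginine (R), except when the
#' following residue is proline (P). With `missed_cleavages = 0` the returned
#' peptides partition the input: their concatenation reproduces the protein.
#'
#' @param sequence Protein sequence (canonical one-letter codes only).
#' @param missed_cleavages Maximum number of internal cleavage sites a
#'   reported peptide may retain. The default 0 reports fully cleaved
#'   peptides only.
#' @return Character vector of peptide sequences in N- to C-terminal order.
#'   Fully cleaved peptides come first (in order); peptides with 1, 2, ...
#'   missed cleavages follow when requested.
#' @examples
#' tryptic_digest("AKRPGKT")   # no cleavage after R: followed by P
#' @export
tryptic_digest <- function(sequence, missed_cleavages = 0L) {
  stopifnot(length(sequence) == 1, is.character(sequence))
  if (nchar(sequence) == 0) return(character(0))
  chars <- .check_canonical(sequence)
  n <- length(chars)
  is_kr <- chars %in% c("K", "R")
  next_p <- c(chars[-1] == "P", FALSE)
  cut_after <- which(is_kr & !next_p & seq_len(n) < n)
  starts <- c(1L, cut_after + 1L)
  ends <- c(cut_after, n)
  peptides <- substring(sequence, starts, ends)
  if (missed_cleavages > 0 && length(peptides) > 1) {
    k <- length(peptides)
    for (mc in seq_len(min(missed_cleavages, k - 1L))) {
      idx <- seq_len(k - mc)
      joined <- vapply(idx, function(i) {
        paste(peptides[i:(i + mc)], collapse = "")
      }, character(1))
      peptides <- c(peptides, joined)
    }
  }
  peptides
}

#' Elemental composition of an intact peptide
#'
#' Sums the standard monoisotopic residue formulas and adds one water
#' (H2, O1) for the intact peptide termini.
#'
#' @param sequence Peptide sequence (canonical one-letter codes only).
#' @return Named integer vector with components `C`, `H`, `N`, `O`, `S`.
#' @examples
#' residue_composition("GK")  # C8 H17 N3 O3
#' @export
residue_composition <- function(sequence) {
  stopifnot(length(sequence) == 1, is.character(sequence))
  if (nchar(sequence) == 0) stop("empty peptide sequence", call. = FALSE)
  chars <- .check_canonical(sequence)
  counts <- colSums(RESIDUE_ELEMENTS[chars, , drop = FALSE])
  counts[["H"]] <- counts[["H"]] + 2
  counts[["O"]] <- counts[["O"]] + 1
  storage.mode(counts) <- "integer"
  counts
}

# Vectorised composition for many peptides at once: returns an n x 5 matrix
# of element counts (including one water each). Used by the reference
# builder and the synthetic generator, where per-peptide calls would be slow.
composition_matrix <- function(sequences) {
  chars <- strsplit(sequences, "", fixed = TRUE)
  lens <- lengths(chars)
  flat <- unlist(chars, use.names = FALSE)
  idx <- match(flat, rownames(RESIDUE_ELEMENTS))
  if (anyNA(idx)) {
    stop("non-canonical residue code(s): ",
         paste(sQuote(unique(flat[is.na(idx)])), collapse = ", "),
         call. = FALSE)
  }
  group <- rep.int(seq_along(sequences), lens)
  counts <- rowsum(RESIDUE_ELEMENTS[idx, , drop = FALSE], group,
                   reorder = TRUE)
  counts[, "H"] <- counts[, "H"] + 2
  counts[, "O"] <- counts[, "O"] + 1
  counts
}

#' Monoisotopic peptide mass at a given 13C incorporation
#'
#' Computes the mass from element counts, linearly interpolating the carbon
#' mass between pure 12C (0 atom %) and pure 13C (100 atom %): each fully
#' substituted carbon adds exactly 1.003355 Da.
#'
#' @param elements Named numeric vector (or matrix with columns) `C`, `H`,
#'   `N`, `O`, `S`, as returned by [residue_composition()].
#' @param incorporation Atom % 13C in \[0, 100\].
#' @return Monoisotopic mass in Da (vector if `elements` is a matrix).
#' @examples
#' monoisotopic_mass(residue_composition("GK"))        # 203.126992
#' monoisotopic_mass(residue_composition("GK"), 100)   # + 8 * 1.003355
#' @export
monoisotopic_mass <- function(elements, incorporation = 0) {
  stopifnot(is.numeric(incorporation), length(incorporation) == 1)
  if (is.na(incorporation) || incorporation < 0 || incorporation > 100) {
    stop("incorporation must be in [0, 100] atom %", call. = FALSE)
  }
  if (is.matrix(elements)) {
    base <- drop(elements[, names(ELEMENT_MASSES), drop = FALSE] %*%
                   ELEMENT_MASSES)
    nC <- elements[, "C"]
  } else {
    base <- sum(elements[names(ELEMENT_MASSES)] * ELEMENT_MASSES)
    nC <- elements[["C"]]
  }
  base + (incorporation / 100) * nC * C13_SHIFT
}

#' Monoisotopic mass of a peptide sequence
#'
#' Convenience wrapper: composition then mass, vectorised over sequences.
#'
#' @param sequences Character vector of peptide sequences.
#' @inheritParams monoisotopic_mass
#' @return Numeric vector of masses in Da.
#' @export
peptide_mass <- function(sequences, incorporation = 0) {
  if (length(sequences) == 0) return(numeric(0))
  unname(monoisotopic_mass(composition_matrix(sequences), incorporation))
}

#' Read a protein FASTA file
#'
#' Wraps [Biostrings::readAAStringSet()]; multi-line wrapped sequences are
#' supported. Stop characters (`*`) are stripped with a warning. Sequences
#' are upper-cased.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of protein sequences.
#' @export
read_fasta_proteins <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0) stop("no FASTA records in ", path, call. = FALSE)
  seqs <- toupper(as.character(aa))
  if (any(grepl("*", seqs, fixed = TRUE))) {
    warning("stop characters '*' stripped from ",
            sum(grepl("*", seqs, fixed = TRUE)), " sequence(s)",
            call. = FALSE)
    seqs <- gsub("*", "", seqs, fixed = TRUE)
  }
  seqs
}

#' Build the reference peptide table from a proteome
#'
#' Digests every protein tryptically (no missed cleavages, no
#' modifications), then keeps peptides whose length lies in
#' `[len_min, len_max]` and whose light (0 atom % 13C) monoisotopic mass
#' lies in `[mz_min, mz_max]` (z = 1 throughout, so m/z is read as neutral
#' monoisotopic mass). Duplicate sequences arising from different proteins
#' are retained as separate entries. Proteins containing non-canonical
#' residue codes are skipped with a warning.
#'
#' @param proteins Path to a FASTA file, or a (optionally named) character
#'   vector of protein sequences.
#' @param mz_min,mz_max Light-mass window in Da (defaults 300 and 6000).
#' @param len_min,len_max Peptide length window in residues (defaults 2
#'   and 40).
#' @return A data frame with one row per retained peptide entry: `sequence`,
#'   `length`, `n_carbon`, `mass_light` (0 atom %) and `mass_heavy`
#'   (100 atom %).
#' @export
build_reference_peptides <- function(proteins, mz_min = 300, mz_max = 6000,
                                     len_min = 2, len_max = 40) {
  if (is.character(proteins) && length(proteins) == 1 &&
      file.exists(proteins)) {
    proteins <- read_fasta_proteins(proteins)
  }
  stopifnot(is.character(proteins))
  if (length(proteins) == 0) {
    stop("empty reference: no protein sequences provided", call. = FALSE)
  }
  ok <- !grepl(sprintf("[^%s]", paste(canonical_residues(), collapse = "")),
               proteins)
  if (any(!ok)) {
    warning(sum(!ok), " protein(s) skipped: non-canonical residue codes",
            call. = FALSE)
    proteins <- proteins[ok]
  }
  if (length(proteins) == 0) {
    stop("empty reference: no digestible proteins", call. = FALSE)
  }
  peptides <- unlist(lapply(proteins, tryptic_digest), use.names = FALSE)
  keep_len <- nchar(peptides) >= len_min & nchar(peptides) <= len_max
  peptides <- peptides[keep_len]
  if (length(peptides) == 0) {
    stop("empty reference: no peptide passes the length filter",
         call. = FALSE)
  }
  comp <- composition_matrix(peptides)
  mass_light <- monoisotopic_mass(comp, 0)
  keep_mass <- mass_light >= mz_min & mass_light <= mz_max
  if (!any(keep_mass)) {
    stop("empty reference: no peptide mass falls in [", mz_min, ", ",
         mz_max, "] Da", call. = FALSE)
  }
  data.frame(
    sequence = peptides[keep_mass],
    length = nchar(peptides[keep_mass]),
    n_carbon = as.integer(comp[keep_mass, "C"]),
    mass_light = mass_light[keep_mass],
    mass_heavy = mass_light[keep_mass] + comp[keep_mass, "C"] * C13_SHIFT,
    row.names = NULL
  )
}

#' Write a reference peptide table
#'
#' Tab-separated with columns sequence, length, C count, light and heavy
#' mass; full-precision decimal serialisation so a read-back is bit-exact.
#'
#' @param peptides Data frame from [build_reference_peptides()].
#' @param path Output file path.
#' @export
write_reference_peptides <- function(peptides, path) {
  out <- peptides
  out$mass_light <- sprintf("%.17g", out$mass_light)
  out$mass_heavy <- sprintf("%.17g", out$mass_heavy)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a reference peptide table written by [write_reference_peptides()]
#'
#' @param path Path to the tab-separated table.
#' @return Data frame with the same columns as [build_reference_peptides()].
#' @export
read_reference_peptides <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    colClasses = c("character", "integer", "integer",
                                   "numeric", "numeric"))
}
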