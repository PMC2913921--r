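# Synthetic tryptic-like peptides and the subsampling accuracy experiment:
# how the estimation error shrinks as more peptide masses are included.

# Amino-acid background frequencies (%) of the UniProtKB/Swiss-Prot
# average proteome composition; used to draw realistic random sequences.
AA_BACKGROUND <- c(
  A = 8.25, R = 5.53, N = 4.06, D = 5.46, C = 1.38,
  E = 6.72, Q = 3.93, G = 7.07, H = 2.27, I = 5.91,
  L = 9.65, K = 5.80, M = 2.41, F = 3.86, P = 4.74,
  S = 6.64, T = 5.35, W = 1.10, Y = 2.92, V = 6.86
)

#' Amino-acid background frequencies used by the generator
#'
#' @return Named numeric vector of relative frequencies (summing to 1)
#'   over the 20 canonical residues.
#' @export
aa_background_frequencies <- function() AA_BACKGROUND / sum(AA_BACKGROUND)

# Evaluate `code` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is untouched. seed = NULL runs on the current stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (!exists(".Random.seed", globalenv(), inherits = FALSE)) {
      set.seed(NULL)
    }
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  code
}

#' Generate synthetic tryptic-like peptides
#'
#' Draws random peptide sequences emulating a curated tryptic reference
#' set: residues are sampled from the Swiss-Prot background amino-acid
#' frequencies, the C-terminal residue is forced to lysine or arginine
#' (tryptic C-terminus), and candidates failing the length or light-mass
#' window are rejected and redrawn; generation aborts if the constraints
#' are infeasible.
#'
#' Two length distributions are offered. The default `"uniform"` draws
#' lengths flat over the length range, emulating a reference table that
#' represents all peptide lengths well — the situation after the
#' score-based curation typical of in-silico digest tools, which depletes
#' the very short fragments that dominate a raw digest. `"tryptic"`
#' instead uses the geometric fragment-length distribution of a raw
#' uncurated digest (cleavage probability = combined K/R background
#' frequency); it concentrates mass below ~1,500 Da, which roughly
#' doubles the spread of downstream incorporation estimates at a given
#' peptide count.
#'
#' @param n Number of peptides to generate.
#' @param seed Optional integer seed; the same `n` and `seed` always
#'   reproduce the same peptides, and the caller's RNG state is restored.
#' @param length_range Integer bounds on residue count (default 2-40).
#' @param mz_range Light monoisotopic mass window in Da (default
#'   300-6000).
#' @param length_dist `"uniform"` (flat over `length_range`, default) or
#'   `"tryptic"` (geometric, raw-digest-like).
#' @param max_batches Rejection-sampling cap; exceeded only for
#'   infeasible constraint combinations.
#' @return A reference peptide table as from [build_reference_peptides()]:
#'   columns `sequence`, `length`, `n_carbon`, `mass_light`, `mass_heavy`.
#' @export
generate_synthetic_peptides <- function(n, seed = NULL,
                                        length_range = c(2, 40),
                                        mz_range = c(300, 6000),
                                        length_dist = c("uniform",
                                                        "tryptic"),
                                        max_batches = 200) {
  stopifnot(n >= 1, length(length_range) == 2, length(mz_range) == 2,
            length_range[1] >= 2, length_range[1] <= length_range[2],
            mz_range[1] > 0, mz_range[1] < mz_range[2])
  length_dist <- match.arg(length_dist)
  freqs <- aa_background_frequencies()
  lengths_pool <- seq.int(length_range[1], length_range[2])
  p_cut <- sum(freqs[c("K", "R")])
  length_prob <- switch(
    length_dist,
    tryptic = stats::dgeom(lengths_pool - 1, prob = p_cut),
    uniform = rep.int(1, length(lengths_pool))
  )
  term_pool <- c("K", "R")
  term_prob <- freqs[term_pool] / sum(freqs[term_pool])

  draw_batch <- function(m) {
    len <- sample(lengths_pool, m, replace = TRUE, prob = length_prob)
    body_n <- sum(len) - m
    body <- sample(names(freqs), body_n, replace = TRUE, prob = freqs)
    term <- sample(term_pool, m, replace = TRUE, prob = term_prob)
    id <- rep.int(seq_len(m), len - 1L)
    seqs <- character(m)
    has_body <- len > 1L
    joined <- vapply(split(body, factor(id, levels = seq_len(m))),
                     paste, character(1), collapse = "")
    seqs[has_body] <- joined[has_body]
    paste0(seqs, term)
  }

  with_seed(seed, {
    accepted <- character(0)
    batches <- 0L
    while (length(accepted) < n) {
      batches <- batches + 1L
      if (batches > max_batches) {
        stop("could not generate ", n, " peptides in ", max_batches,
             " batches; the length/mass constraints look infeasible",
             call. = FALSE)
      }
      m <- max(1000L, 2L * (n - length(accepted)))
      cand <- draw_batch(m)
      mass <- peptide_mass(cand)
      ok <- mass >= mz_range[1] & mass <= mz_range[2]
      accepted <- c(accepted, cand[ok])
    }
    accepted <- accepted[seq_len(n)]
    comp <- composition_matrix(accepted)
    mass_light <- monoisotopic_mass(comp, 0)
    data.frame(
      sequence = accepted,
      length = nchar(accepted),
      n_carbon = as.integer(comp[, "C"]),
      mass_light = mass_light,
      mass_heavy = mass_light + comp[, "C"] * C13_SHIFT,
      row.names = NULL
    )
  })
}

#' Peptide masses at a given incorporation level
#'
#' Exact labeled masses for a reference peptide table. By default
#' (`mode = "integer"`) each peptide carries a whole number of heavy
#' carbons, `round(truth/100 * n_carbon)`, emulating what a deconvoluted
#' high-resolution measurement reports: the apex of the isotopologue
#' envelope sits an integer number of 1.003355 Da shifts above the light
#' monoisotopic mass. This keeps all peptides on a single
#' residual-vs-mass line at any incorporation level. `mode =
#' "continuous"` instead interpolates the carbon mass exactly
#' (`truth/100 * n_carbon * 1.003355` Da); note that at intermediate
#' truths this places odd-carbon peptides on a lattice shifted by half a
#' Dalton in residual — a structure no real measurement produces and one
#' the integer-Dalton band unwrapping cannot repair. Optionally adds
#' Gaussian ppm-scale measurement error (off by default; the in-silico
#' design is exact).
#'
#' @param peptides Reference peptide table.
#' @param truth Atom % 13C in \[0, 100\].
#' @param mode `"integer"` (whole substituted carbons, default) or
#'   `"continuous"` (exact interpolation).
#' @param ppm_error Standard deviation of mass error in parts per million
#'   (default 0 = exact masses).
#' @return Numeric vector of masses in Da.
#' @export
labeled_masses <- function(peptides, truth, mode = c("integer",
                                                     "continuous"),
                           ppm_error = 0) {
  stopifnot(truth >= 0, truth <= 100, ppm_error >= 0)
  mode <- match.arg(mode)
  n_heavy <- switch(
    mode,
    integer = round((truth / 100) * peptides$n_carbon),
    continuous = (truth / 100) * peptides$n_carbon
  )
  m <- peptides$mass_light + n_heavy * C13_SHIFT
  if (ppm_error > 0) {
    m <- m * (1 + stats::rnorm(length(m), sd = ppm_error * 1e-6))
  }
  m
}

#' Subsampling accuracy experiment
#'
#' Quantifies estimation error as a function of the number of peptide
#' masses. For each known truth and subsample size, peptides are drawn
#' from the reference without replacement, their exact labeled masses are
#' computed, and the full banding + robust-fit + interpolation pipeline
#' produces an estimate; this is repeated `replicates` times with fresh
#' draws.
#'
#' @param peptides Reference peptide table (must be larger than the
#'   largest subsample size; too-large sizes are skipped with a warning).
#' @param reference An `hdpr_reference`; calibrated from `peptides`
#'   itself if omitted.
#' @param truths Known atom % 13C levels (default 0, 50, 100).
#' @param sizes Subsample sizes (default the ladder 10-1000).
#' @param replicates Independent draws per cell (default 100).
#' @param seed Optional seed (RNG state restored afterwards).
#' @return A long data frame of class `hdpr_accuracy` with one row per
#'   replicate: `truth`, `size`, `replicate`, `estimate`, `se`,
#'   `converged`. Summarise per cell with [summary.hdpr_accuracy()].
#' @export
accuracy_experiment <- function(peptides, reference = NULL,
                                truths = c(0, 50, 100),
                                sizes = c(10, 20, 30, 40, 50, 60, 70, 80,
                                          90, 100, 200, 300, 500, 1000),
                                replicates = 100, seed = NULL) {
  stopifnot(is.data.frame(peptides), replicates >= 1)
  if (is.null(reference)) reference <- calibrate(peptides)
  feasible <- sizes <= nrow(peptides)
  if (any(!feasible)) {
    warning("subsample size(s) ", paste(sizes[!feasible], collapse = ", "),
            " exceed the reference size ", nrow(peptides), "; skipped",
            call. = FALSE)
    sizes <- sizes[feasible]
  }
  grid <- expand.grid(replicate = seq_len(replicates), size = sizes,
                      truth = truths)
  with_seed(seed, {
    res <- lapply(seq_len(nrow(grid)), function(i) {
      size <- grid$size[i]
      truth <- grid$truth[i]
      idx <- sample.int(nrow(peptides), size)
      masses <- labeled_masses(peptides[idx, , drop = FALSE], truth)
      est <- suppressWarnings(
        estimate_incorporation(masses, reference)
      )
      c(estimate = est$atom_percent, se = est$se,
        converged = as.numeric(est$slope_fit$converged))
    })
    res <- do.call(rbind, res)
    out <- data.frame(
      truth = grid$truth,
      size = grid$size,
      replicate = grid$replicate,
      estimate = res[, "estimate"],
      se = res[, "se"],
      converged = res[, "converged"] == 1
    )
    class(out) <- c("hdpr_accuracy", "data.frame")
    out
  })
}

#' Summarise an accuracy experiment per cell
#'
#' One row per (truth, size): median, quartiles, 2.5/97.5 percentile
#' envelope, envelope half-width around the truth (the default error
#' metric, matching a whisker reading of the replicate spread), the
#' median bias, and a parametric 95% confidence half-width of the median
#' for comparison.
#'
#' @param object An `hdpr_accuracy` from [accuracy_experiment()].
#' @param ... Unused.
#' @return Data frame with columns `truth`, `size`, `median`, `q25`,
#'   `q75`, `q025`, `q975`, `envelope_half_width`, `median_bias`,
#'   `median_ci_half_width`.
#' @export
summary.hdpr_accuracy <- function(object, ...) {
  cells <- split(object, list(object$truth, object$size), drop = TRUE)
  rows <- lapply(cells, function(cell) {
    q <- stats::quantile(cell$estimate,
                         c(0.025, 0.25, 0.5, 0.75, 0.975), names = FALSE)
    truth <- cell$truth[1]
    data.frame(
      truth = truth,
      size = cell$size[1],
      median = q[3],
      q25 = q[2],
      q75 = q[4],
      q025 = q[1],
      q975 = q[5],
      envelope_half_width = max(abs(q[c(1, 5)] - truth)),
      median_bias = q[3] - truth,
      median_ci_half_width = 1.96 * 1.2533 *
        stats::sd(cell$estimate) / sqrt(nrow(cell))
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$truth, out$size), ]
  row.names(out) <- NULL
  out
}

#' Box-and-whisker plot of an accuracy experiment
#'
#' One panel per truth; boxes are replicate quartiles, whiskers the
#' 2.5-97.5 percentile envelope; dashed lines mark truth +/- 5 atom %.
#'
#' @param x An `hdpr_accuracy`.
#' @param ... Passed to [graphics::boxplot()].
#' @export
plot.hdpr_accuracy <- function(x, ...) {
  truths <- sort(unique(x$truth))
  old <- graphics::par(mfrow = c(length(truths), 1),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (tr in truths) {
    sub <- x[x$truth == tr, ]
    graphics::boxplot(estimate ~ size, data = sub, range = 0,
                      xlab = "peptide masses per draw",
                      ylab = "estimated atom % 13C",
                      main = sprintf("truth = %g atom %%", tr), ...)
    graphics::abline(h = tr + c(-5, 0, 5), lty = c(2, 1, 2),
                     col = "grey40")
  }
  invisible(x)
}

#' Write an accuracy experiment table
#'
#' Long-format tab-separated file: truth, size, replicate, estimate, se.
#'
#' @param results An `hdpr_accuracy`.
#' @param path Output file path.
#' @export
write_accuracy_table <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Ground-truth integer band offsets
#'
#' For validation on data whose underlying slope is known (or estimable):
#' the true offset of a point is the integer `k` minimising
#' `|D_R + k - b * P_M|`, i.e. `round(b * P_M - D_R)` floored at zero.
#' When `refine = TRUE` the slope is polished by a short fixed-point
#' iteration (offsets from `b`, then `b` refit by exact least squares on
#' the unwrapped points) so only a coarse starting slope is needed.
#'
#' @param mass Peptide masses in Da.
#' @param b Slope (coarse guess is enough with `refine = TRUE`).
#' @param residual Decimal residuals; computed from `mass` if omitted.
#' @param refine Number of fixed-point refinement passes (default 3).
#' @return Integer vector of true band offsets.
#' @export
true_band_offsets <- function(mass, b, residual = decimal_residual(mass),
                              refine = 3) {
  stopifnot(b > 0)
  offsets <- pmax(0, round(b * mass - residual))
  for (i in seq_len(refine)) {
    b <- fit_slope_ols(mass, residual + offsets)$b
    offsets_new <- pmax(0, round(b * mass - residual))
    if (all(offsets_new == offsets)) break
    offsets <- offsets_new
  }
  as.integer(offsets)
}

#' Band misassignment rate against ground truth
#'
#' Classifies the masses with the standard transform + k-means pipeline
#' and compares each assigned offset with the ground-truth offset from
#' [true_band_offsets()].
#'
#' @param mass Peptide masses in Da.
#' @param config A [band_config()] for the classification under test.
#' @param b_true Known or coarsely estimated underlying slope.
#' @return Fraction of points whose assigned band differs from truth.
#' @export
band_misassignment <- function(mass, config, b_true) {
  assigned <- classify_bands(mass, config)
  truth <- true_band_offsets(mass, b_true)
  mean(assigned != truth)
}
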