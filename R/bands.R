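# Band classification and unwrapping: turn the periodic (mass, decimal
# residual) scatter into one continuous line through the origin.
#
# The decimal residual of a tryptic peptide grows linearly with its mass
# (half decimal place rule) but wraps back to 0 every time it passes 1,
# producing parallel diagonal bands. Unwrapping adds the band index in
# Daltons to each residual. Bands are separated by k-means on a transformed
# mass axis where each band is nearly vertical, seeded at preset centers.

#' Decimal residual of a mass
#'
#' The fractional part of the mass: the digits behind the decimal point.
#'
#' @param mass Positive mass (Da); vectorised.
#' @return Value(s) in \[0, 1).
#' @export
decimal_residual <- function(mass) {
  stopifnot(is.numeric(mass))
  if (any(!is.finite(mass)) || any(mass <= 0)) {
    stop("masses must be positive and finite", call. = FALSE)
  }
  mass - floor(mass)
}

#' Residual-dependent mass transformation
#'
#' Shifts each mass down by `transform_constant` times its decimal
#' residual: `P_M_trans = P_M - transform_constant * D_R`. Masses with
#' residuals near 0 barely move while those near 1 shift by almost the full
#' constant, which rotates each diagonal band into a near-vertical cluster.
#' At the default constant of 1800 Da the bands of unlabeled tryptic
#' peptides reach their steepest (most vertical) position; larger values
#' tilt them the opposite way.
#'
#' @param mass Peptide mass(es) in Da.
#' @param residual Decimal residual(s); computed from `mass` if omitted.
#' @param transform_constant Transformation constant in Da (default 1800).
#' @return Transformed mass(es); may be negative.
#' @export
transform_mass <- function(mass, residual = decimal_residual(mass),
                           transform_constant = 1800) {
  stopifnot(transform_constant > 0)
  if (any(residual < 0 | residual >= 1)) {
    stop("residuals must lie in [0, 1)", call. = FALSE)
  }
  mass - transform_constant * residual
}

#' Band configuration
#'
#' Bundles the settings of the band classification step.
#'
#' @param centers Strictly increasing preset cluster centers on the
#'   transformed mass axis, in Da. The defaults `c(0, 2000, 4000)` suit
#'   unlabeled peptides up to ~5,800 Da; fully labeled data use
#'   `c(0, 1600, 3200, 4800)`. Centers need not be accurate: k-means
#'   refines them from the data.
#' @param transform_constant Transformation constant in Da (default 1800).
#' @param add_dummy_points If `TRUE`, one synthetic point is placed at each
#'   preset center before clustering and removed afterwards, so that small
#'   data sets cannot leave a cluster empty. The dummies never enter the
#'   slope fit.
#' @return An object of class `band_config`.
#' @export
band_config <- function(centers = c(0, 2000, 4000),
                        transform_constant = 1800,
                        add_dummy_points = FALSE) {
  stopifnot(is.numeric(centers), length(centers) >= 1,
            !is.unsorted(centers, strictly = TRUE),
            is.numeric(transform_constant), transform_constant > 0)
  structure(
    list(centers = as.numeric(centers),
         transform_constant = as.numeric(transform_constant),
         add_dummy_points = isTRUE(add_dummy_points)),
    class = "band_config"
  )
}

#' Preset band centers for a given slope
#'
#' Derives k-means seed centers on the transformed mass axis from a coarse
#' slope guess: band `k` covers masses in `[k/b, (k+1)/b)`, and its
#' transformed midpoint is `(1 - tc*b) * (k + 0.5)/b + tc*k`. For the
#' unlabeled slope over masses up to ~5,800 Da this reproduces three
#' centers near 0/2,000/4,000 Da, and for the fully labeled slope four
#' centers near 0/1,600/3,200/4,800 Da.
#'
#' @param b_guess Coarse slope guess (residual Da per mass Da).
#' @param max_mass Largest mass to be classified, in Da.
#' @param transform_constant Transformation constant in Da.
#' @return Numeric vector of centers, one per expected band.
#' @export
band_centers <- function(b_guess, max_mass, transform_constant = 1800) {
  stopifnot(b_guess > 0, max_mass > 0)
  n_bands <- floor(max_mass * b_guess) + 1
  k <- seq_len(n_bands) - 1
  (1 - transform_constant * b_guess) * (k + 0.5) / b_guess +
    transform_constant * k
}

#' Classify masses into residual bands
#'
#' Runs one-dimensional k-means (Hartigan-Wong) on the transformed masses,
#' seeded exactly at the preset centers (single initialisation, no random
#' restarts, so the classification is reproducible bit for bit). Cluster
#' labels are then re-ordered by increasing final center so that band 0 is
#' always the lowest band. If a preset center would capture no point,
#' classification is retried with dummy points (one per center) and a
#' warning; the dummies are removed before the result is returned.
#'
#' @param mass Peptide masses in Da.
#' @param config A [band_config()].
#' @return Integer vector of 0-based band indices, one per mass.
#' @export
classify_bands <- function(mass, config = band_config()) {
  stopifnot(inherits(config, "band_config"))
  if (length(mass) < 1) stop("no masses to classify", call. = FALSE)
  residual <- decimal_residual(mass)
  x <- transform_mass(mass, residual, config$transform_constant)
  centers <- config$centers
  if (length(centers) == 1) {
    return(rep.int(0L, length(mass)))
  }
  run_kmeans <- function(values) {
    stats::kmeans(matrix(values, ncol = 1),
                  centers = matrix(centers, ncol = 1),
                  algorithm = "Hartigan-Wong", iter.max = 100)
  }
  n_real <- length(x)
  use_dummies <- config$add_dummy_points || n_real < length(centers)
  fit <- NULL
  if (!use_dummies) {
    fit <- tryCatch(run_kmeans(x), error = function(e) NULL)
    if (is.null(fit)) {
      warning("a preset center captured no point; retrying with dummy ",
              "points at the centers", call. = FALSE)
      use_dummies <- TRUE
    }
  }
  if (use_dummies) {
    fit <- run_kmeans(c(x, centers))
  }
  cluster <- fit$cluster[seq_len(n_real)]
  # relabel so that band indices increase with the final center mass
  ord <- order(fit$centers[, 1])
  band_of_cluster <- integer(length(ord))
  band_of_cluster[ord] <- seq_along(ord) - 1L
  band_of_cluster[cluster]
}

#' Unwrap decimal residuals by band
#'
#' Adds the integer band index (in Daltons) to each residual, stacking the
#' second band on top of the first, the third on top of the second, and so
#' on, so that all bands form one continuous line through the origin.
#'
#' @param residual Decimal residuals in \[0, 1).
#' @param band 0-based integer band indices, as from [classify_bands()].
#' @return Unwrapped residuals `residual + band`.
#' @export
unwrap_residuals <- function(residual, band) {
  stopifnot(length(residual) == length(band), all(band >= 0),
            all(band == floor(band)))
  residual + band
}

#' Band-classify a mass set into a fit-ready point table
#'
#' Full banding pipeline: residuals, transformation, k-means
#' classification, unwrapping.
#'
#' @inheritParams classify_bands
#' @return Data frame with columns `mass`, `residual`, `mass_trans`,
#'   `band`, `residual_unwrapped`.
#' @export
band_points <- function(mass, config = band_config()) {
  residual <- decimal_residual(mass)
  band <- classify_bands(mass, config)
  data.frame(
    mass = mass,
    residual = residual,
    mass_trans = transform_mass(mass, residual, config$transform_constant),
    band = band,
    residual_unwrapped = unwrap_residuals(residual, band)
  )
}

#' Write a banded point table
#'
#' Tab-separated columns mass, residual, transformed mass, band, unwrapped
#' residual — the coordinates needed to reproduce the classification
#' scatter plots.
#'
#' @param points Data frame from [band_points()].
#' @param path Output file path.
#' @export
write_banded_points <- function(points, path) {
  utils::write.table(points, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
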