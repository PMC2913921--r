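# Calibration of the 0 / 100 atom % reference slopes and conversion of a
# user mass list's slope into atom % 13C.

LIGHT_CENTERS <- c(0, 2000, 4000)
HEAVY_CENTERS <- c(0, 1600, 3200, 4800)

#' Calibrate reference slopes from a proteome
#'
#' End-to-end calibration: in-silico tryptic digest and filtering
#' ([build_reference_peptides()]), light (0 atom % 13C) and fully labeled
#' (100 atom %) mass sets, band classification and unwrapping for each,
#' and exact zero-intercept least-squares slopes. The two slopes anchor
#' all later incorporation estimates; they are kept at full precision
#' internally and displayed rounded to 6 significant digits.
#'
#' @param proteins FASTA path, character vector of protein sequences, or a
#'   prebuilt reference peptide table (data frame from
#'   [build_reference_peptides()] or [generate_synthetic_peptides()]).
#' @inheritParams build_reference_peptides
#' @param transform_constant Transformation constant in Da (default 1800).
#' @param light_centers,heavy_centers Preset k-means centers on the
#'   transformed mass axis for the light and heavy mass sets. The defaults
#'   (three centers 0/2000/4000 Da and four centers 0/1600/3200/4800 Da)
#'   suit the default 300-6000 Da window.
#' @param add_dummy_points Place one dummy point per preset center during
#'   classification (removed before fitting) so that sparse high-mass
#'   bands cannot leave a cluster empty. Has no measurable effect on the
#'   slopes of well-populated references.
#' @param source Label recorded in the model (defaults to the FASTA path
#'   or `"peptide table"`).
#' @return An object of class `hdpr_reference` with components `b_12C`,
#'   `b_13C`, the underlying `slope_fit`s (`fit_light`, `fit_heavy`),
#'   `n_peptides`, `source`, `filters` and the band settings.
#' @export
calibrate <- function(proteins, mz_min = 300, mz_max = 6000,
                      len_min = 2, len_max = 40,
                      transform_constant = 1800,
                      light_centers = LIGHT_CENTERS,
                      heavy_centers = HEAVY_CENTERS,
                      add_dummy_points = TRUE,
                      source = NULL) {
  if (is.data.frame(proteins)) {
    required <- c("mass_light", "mass_heavy")
    stopifnot(all(required %in% names(proteins)))
    peptides <- proteins
    if (is.null(source)) source <- "peptide table"
  } else {
    if (is.null(source)) {
      source <- if (length(proteins) == 1 && file.exists(proteins)) {
        basename(proteins)
      } else {
        "protein sequences"
      }
    }
    peptides <- build_reference_peptides(proteins, mz_min, mz_max,
                                         len_min, len_max)
  }
  cfg_light <- band_config(light_centers, transform_constant,
                           add_dummy_points)
  cfg_heavy <- band_config(heavy_centers, transform_constant,
                           add_dummy_points)
  pts_light <- band_points(peptides$mass_light, cfg_light)
  pts_heavy <- band_points(peptides$mass_heavy, cfg_heavy)
  fit_light <- fit_slope_ols(pts_light$mass, pts_light$residual_unwrapped)
  fit_heavy <- fit_slope_ols(pts_heavy$mass, pts_heavy$residual_unwrapped)
  if (fit_heavy$b <= fit_light$b) {
    stop("calibration failure: the fully labeled slope (",
         format(fit_heavy$b), ") is not larger than the unlabeled slope (",
         format(fit_light$b), "); band classification is suspect",
         call. = FALSE)
  }
  structure(
    list(
      b_12C = fit_light$b,
      b_13C = fit_heavy$b,
      fit_light = fit_light,
      fit_heavy = fit_heavy,
      n_peptides = nrow(peptides),
      source = source,
      filters = list(mz_min = mz_min, mz_max = mz_max,
                     len_min = len_min, len_max = len_max),
      transform_constant = transform_constant,
      light_centers = as.numeric(light_centers),
      heavy_centers = as.numeric(heavy_centers)
    ),
    class = "hdpr_reference"
  )
}

#' @export
print.hdpr_reference <- function(x, ...) {
  cat("HDPR reference model\n")
  cat("  source     :", x$source, "\n")
  cat("  peptides   :", x$n_peptides, "entries (length",
      x$filters$len_min, "-", x$filters$len_max, ", mass",
      x$filters$mz_min, "-", x$filters$mz_max, "Da)\n")
  cat(sprintf("  b_12C (0%%)   = %.6g\n", x$b_12C))
  cat(sprintf("  b_13C (100%%) = %.6g\n", x$b_13C))
  invisible(x)
}

#' Serialise a reference model to a key-value text file
#'
#' Slopes are written at full precision so estimates are reproducible
#' against a pinned calibration.
#'
#' @param reference An `hdpr_reference` from [calibrate()].
#' @param path Output file path.
#' @export
write_reference_model <- function(reference, path) {
  stopifnot(inherits(reference, "hdpr_reference"))
  lines <- c(
    "format=hdpr-reference-1",
    sprintf("b_12C=%.17g", reference$b_12C),
    sprintf("b_13C=%.17g", reference$b_13C),
    sprintf("n_peptides=%d", reference$n_peptides),
    sprintf("source=%s", reference$source),
    sprintf("mz_min=%.17g", reference$filters$mz_min),
    sprintf("mz_max=%.17g", reference$filters$mz_max),
    sprintf("len_min=%d", reference$filters$len_min),
    sprintf("len_max=%d", reference$filters$len_max),
    sprintf("transform_constant=%.17g", reference$transform_constant),
    sprintf("light_centers=%s",
            paste(sprintf("%.17g", reference$light_centers),
                  collapse = ",")),
    sprintf("heavy_centers=%s",
            paste(sprintf("%.17g", reference$heavy_centers),
                  collapse = ","))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a reference model written by [write_reference_model()]
#'
#' @param path Path to the key-value reference file.
#' @return An `hdpr_reference` (without the per-point fit objects).
#' @export
read_reference_model <- function(path) {
  if (!file.exists(path)) stop("reference file not found: ", path,
                               call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- vapply(kv, `[`, character(1), 2)
  get <- function(key) {
    i <- match(key, keys)
    if (is.na(i)) stop("reference file missing key: ", key, call. = FALSE)
    vals[i]
  }
  if (get("format") != "hdpr-reference-1") {
    stop("unrecognised reference file format", call. = FALSE)
  }
  structure(
    list(
      b_12C = as.numeric(get("b_12C")),
      b_13C = as.numeric(get("b_13C")),
      fit_light = NULL,
      fit_heavy = NULL,
      n_peptides = as.integer(get("n_peptides")),
      source = get("source"),
      filters = list(mz_min = as.numeric(get("mz_min")),
                     mz_max = as.numeric(get("mz_max")),
                     len_min = as.integer(get("len_min")),
                     len_max = as.integer(get("len_max"))),
      transform_constant = as.numeric(get("transform_constant")),
      light_centers = as.numeric(strsplit(get("light_centers"),
                                          ",")[[1]]),
      heavy_centers = as.numeric(strsplit(get("heavy_centers"),
                                          ",")[[1]])
    ),
    class = "hdpr_reference"
  )
}

#' Convert a fitted slope into atom % 13C
#'
#' Linear interpolation between the calibration anchors:
#' `atom % = (b_user - b_12C) / (b_13C - b_12C) * 100`.
#'
#' @param b_user Fitted zero-intercept slope of the user data.
#' @param reference An `hdpr_reference`.
#' @return Atom % 13C (may fall outside \[0, 100\] for noisy data).
#' @export
incorporation_from_slope <- function(b_user, reference) {
  stopifnot(inherits(reference, "hdpr_reference"))
  (b_user - reference$b_12C) / (reference$b_13C - reference$b_12C) * 100
}

#' Estimate atom % 13C incorporation from a peptide mass list
#'
#' Runs the full user-data pipeline: band classification with dummy-point
#' safeguard, residual unwrapping, robust zero-intercept slope fitting,
#' and conversion to atom % with a standard error.
#'
#' Because the band layout of partially labeled data is not known in
#' advance, classification is tried at both reference center sets (the
#' light and the heavy presets) and the unwrapping with the smaller
#' least-squares error sum of squares is kept before the robust fit.
#'
#' Estimates slightly outside \[0, 100\] are reported as-is with an
#' out-of-range flag (measurement noise can push a slope past the
#' calibration anchors); they are never clipped.
#'
#' @param masses Numeric vector of singly-charged, deconvoluted peptide
#'   masses in Da (at least 3).
#' @param reference An `hdpr_reference` from [calibrate()] or
#'   [read_reference_model()].
#' @param psi Robust weight function, see [fit_slope_robust()].
#' @param add_dummy_points Dummy-point safeguard for small sets
#'   (default `TRUE`).
#' @return An object of class `hdpr_estimate`: `atom_percent`, `se`,
#'   `slope_fit` (the robust fit), `n_masses`, `out_of_range`,
#'   `banding` (which center set won) and `points` (the banded table).
#' @export
estimate_incorporation <- function(masses, reference,
                                   psi = c("huber", "bisquare"),
                                   add_dummy_points = TRUE) {
  stopifnot(inherits(reference, "hdpr_reference"), is.numeric(masses))
  psi <- match.arg(psi)
  if (length(masses) < 3) {
    stop("at least 3 peptide masses are required for a slope estimate; ",
         "got ", length(masses), ". Collect more masses or fit manually ",
         "with fit_slope_ols().", call. = FALSE)
  }
  if (any(!is.finite(masses)) || any(masses <= 0)) {
    stop("masses must be positive and finite", call. = FALSE)
  }
  if (length(unique(masses)) == 1) {
    stop("degenerate input: all masses identical; a slope cannot be ",
         "estimated", call. = FALSE)
  }
  win <- c(reference$filters$mz_min, reference$filters$mz_max)
  outside <- masses < win[1] | masses > win[2]
  if (any(outside)) {
    warning(sum(outside), " mass(es) outside the reference window [",
            win[1], ", ", win[2], "] Da; kept", call. = FALSE)
  }
  trials <- list(
    light = band_config(reference$light_centers,
                        reference$transform_constant, add_dummy_points),
    heavy = band_config(reference$heavy_centers,
                        reference$transform_constant, add_dummy_points)
  )
  best <- NULL
  for (name in names(trials)) {
    pts <- band_points(masses, trials[[name]])
    ols <- fit_slope_ols(pts$mass, pts$residual_unwrapped)
    if (is.null(best) || ols$sse < best$sse) {
      best <- list(points = pts, sse = ols$sse, banding = name)
    }
  }
  fit <- fit_slope_robust(best$points$mass,
                          best$points$residual_unwrapped, psi = psi)
  span <- reference$b_13C - reference$b_12C
  atom_percent <- incorporation_from_slope(fit$b, reference)
  se <- if (is.na(fit$se_b)) NA_real_ else fit$se_b / span * 100
  structure(
    list(
      atom_percent = atom_percent,
      se = se,
      slope_fit = fit,
      n_masses = length(masses),
      out_of_range = atom_percent < 0 || atom_percent > 100,
      banding = best$banding,
      reference = reference,
      points = best$points
    ),
    class = "hdpr_estimate"
  )
}

#' @export
print.hdpr_estimate <- function(x, ...) {
  cat("13C incorporation estimate\n")
  cat(sprintf("  atom %% 13C = %.2f +/- %.2f (se)\n", x$atom_percent,
              x$se))
  cat(sprintf("  b_user     = %.6g (robust IWLS, %s)\n", x$slope_fit$b,
              if (x$slope_fit$converged) "converged" else "NOT converged"))
  cat("  n masses   =", x$n_masses, "\n")
  if (x$out_of_range) {
    cat("  NOTE: estimate outside [0, 100] atom % (kept unclipped)\n")
  }
  invisible(x)
}

#' Scatter plot of a user estimate against the reference lines
#'
#' Mirrors the standard diagnostic figure: user points in unwrapped
#' (mass, residual) coordinates, the 0 and 100 atom % reference lines,
#' the fitted user line, and the printed estimate.
#'
#' @param x An `hdpr_estimate`.
#' @param ... Further arguments passed to [graphics::plot()].
#' @export
plot.hdpr_estimate <- function(x, ...) {
  pts <- x$points
  ref <- x$reference
  xmax <- max(pts$mass) * 1.05
  ymax <- max(pts$residual_unwrapped, xmax * ref$b_13C) * 1.05
  graphics::plot(pts$mass, pts$residual_unwrapped,
                 xlim = c(0, xmax), ylim = c(0, ymax),
                 xlab = "peptide mass (Da)",
                 ylab = "unwrapped decimal residual (Da)",
                 pch = 19, col = "grey30", ...)
  graphics::abline(0, ref$b_12C, col = "grey60", lwd = 2)
  graphics::abline(0, ref$b_13C, col = "grey80", lwd = 2)
  graphics::abline(0, x$slope_fit$b, col = "black", lwd = 3)
  graphics::legend(
    "topleft", bty = "n",
    legend = c("0 atom % reference", "100 atom % reference",
               sprintf("user fit: %.2f +/- %.2f atom %%",
                       x$atom_percent, x$se)),
    col = c("grey60", "grey80", "black"), lwd = c(2, 2, 3)
  )
  invisible(x)
}

#' Write a plain-text estimate report
#'
#' One tab-separated row per estimate plus a human-readable header; used
#' by the command-line `estimate` subcommand for batch runs.
#'
#' @param estimates A single `hdpr_estimate` or a list of them.
#' @param path Output file path.
#' @param labels Optional row labels (e.g. input file names).
#' @export
write_estimate_report <- function(estimates, path, labels = NULL) {
  if (inherits(estimates, "hdpr_estimate")) estimates <- list(estimates)
  if (is.null(labels)) labels <- paste0("masslist", seq_along(estimates))
  rows <- data.frame(
    input = labels,
    n_masses = vapply(estimates, `[[`, numeric(1), "n_masses"),
    atom_percent = vapply(estimates, `[[`, numeric(1), "atom_percent"),
    se = vapply(estimates, `[[`, numeric(1), "se"),
    b_user = vapply(estimates, function(e) e$slope_fit$b, numeric(1)),
    converged = vapply(estimates, function(e) e$slope_fit$converged,
                       logical(1)),
    out_of_range = vapply(estimates, `[[`, logical(1), "out_of_range")
  )
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(rows)
}
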