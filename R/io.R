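# Mass-list file handling and the command-line interface.

#' Read a peptide mass list
#'
#' Plain-text ASCII format: one singly-charged (z = 1, deconvoluted)
#' peptide mass per line, no header and no row names. Both point and
#' comma decimal markers are accepted (detected per line), so European
#' exports parse to identical values. Blank lines are ignored.
#'
#' @param path Path to the mass-list file.
#' @return Numeric vector of masses in input order.
#' @export
read_mass_list <- function(path) {
  if (!file.exists(path)) stop("mass list not found: ", path,
                               call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lines <- trimws(lines[keep])
  if (length(lines) == 0) stop("mass list is empty: ", path,
                               call. = FALSE)
  line_no <- which(keep)
  normalised <- gsub(",", ".", lines, fixed = TRUE)
  masses <- suppressWarnings(as.numeric(normalised))
  if (anyNA(masses)) {
    bad <- which(is.na(masses))[1]
    stop("unparseable mass ", sQuote(lines[bad]), " at line ",
         line_no[bad], " of ", path,
         " (one numeric mass per line, no header)", call. = FALSE)
  }
  if (any(masses <= 0)) {
    bad <- which(masses <= 0)[1]
    stop("non-positive mass at line ", line_no[bad], " of ", path,
         call. = FALSE)
  }
  message(length(masses), " peptide mass(es) read from ", path)
  masses
}

#' Write a peptide mass list
#'
#' One mass per line, point decimal marker, full precision.
#'
#' @param masses Numeric vector of positive masses.
#' @param path Output file path.
#' @export
write_mass_list <- function(masses, path) {
  stopifnot(is.numeric(masses), all(masses > 0))
  writeLines(sprintf("%.17g", masses), path)
  invisible(path)
}

# --- command-line interface ------------------------------------------------
#
# Thin subcommand dispatcher used by the installed `exec/hdpr` script.
# Flags are simple `--key value` pairs (plus repeatable --masses).

.cli_usage <- function() {
  paste(
    "usage: hdpr <subcommand> [options]",
    "",
    "subcommands:",
    "  digest     --fasta FILE --out FILE [--mz-min N --mz-max N",
    "             --len-min N --len-max N]",
    "               write the filtered reference peptide table",
    "  calibrate  --fasta FILE --out FILE [filter options as above]",
    "               write a reference model (both slopes, full precision)",
    "  estimate   --masses FILE [--masses FILE ...] --reference FILE",
    "             [--out FILE] [--plot FILE.png]",
    "               estimate atom % 13C for each mass list",
    "  simulate   --truth P --n N --seed S --out FILE",
    "               emit a synthetic mass list at a known incorporation",
    "  accuracy   --n-reference N --seed S --out FILE",
    "             [--sizes 10,20,...] [--replicates N] [--truths 0,50,100]",
    "               run the subsampling accuracy experiment",
    sep = "\n"
  )
}

.cli_parse <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    arg <- args[i]
    if (!startsWith(arg, "--")) {
      stop("unexpected argument: ", arg, call. = FALSE)
    }
    key <- sub("^--", "", arg)
    if (i == length(args) || startsWith(args[i + 1L], "--")) {
      stop("flag --", key, " needs a value", call. = FALSE)
    }
    value <- args[i + 1L]
    if (key %in% names(opts)) {
      opts[[key]] <- c(opts[[key]], value)
    } else {
      opts[[key]] <- value
    }
    i <- i + 2L
  }
  opts
}

.cli_need <- function(opts, key) {
  if (is.null(opts[[key]])) {
    stop("missing required flag --", key, call. = FALSE)
  }
  opts[[key]]
}

.cli_num <- function(opts, key, default) {
  if (is.null(opts[[key]])) default else as.numeric(opts[[key]])
}

.cli_numvec <- function(opts, key, default) {
  if (is.null(opts[[key]])) {
    default
  } else {
    as.numeric(strsplit(opts[[key]], ",")[[1]])
  }
}

.cli_seed <- function(opts) {
  if (is.null(opts[["seed"]])) NULL else as.integer(opts[["seed"]])
}

#' Command-line entry point
#'
#' Dispatches the subcommands of the `hdpr` script installed under the
#' package's `exec` directory (locate it with
#' `file.path(system.file("exec", package = "hdpr"), "hdpr")` after
#' installation). Callable directly from R for testing:
#' `hdpr_cli(c("estimate", ...))`.
#'
#' @param args Character vector of command-line arguments (subcommand
#'   first), e.g. `commandArgs(trailingOnly = TRUE)`.
#' @return Integer exit status, invisibly: 0 on success, 1 on usage or
#'   runtime error.
#' @export
hdpr_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0 ||
      args[1] %in% c("-h", "--help", "help")) {
    message(.cli_usage())
    return(invisible(if (length(args) == 0) 1L else 0L))
  }
  subcommand <- args[1]
  status <- tryCatch({
    opts <- .cli_parse(args[-1])
    switch(
      subcommand,
      digest = {
        peptides <- build_reference_peptides(
          .cli_need(opts, "fasta"),
          mz_min = .cli_num(opts, "mz-min", 300),
          mz_max = .cli_num(opts, "mz-max", 6000),
          len_min = .cli_num(opts, "len-min", 2),
          len_max = .cli_num(opts, "len-max", 40)
        )
        write_reference_peptides(peptides, .cli_need(opts, "out"))
        message(nrow(peptides), " reference peptides written to ",
                opts$out)
        0L
      },
      calibrate = {
        ref <- calibrate(
          .cli_need(opts, "fasta"),
          mz_min = .cli_num(opts, "mz-min", 300),
          mz_max = .cli_num(opts, "mz-max", 6000),
          len_min = .cli_num(opts, "len-min", 2),
          len_max = .cli_num(opts, "len-max", 40),
          transform_constant = .cli_num(opts, "transform-constant", 1800)
        )
        write_reference_model(ref, .cli_need(opts, "out"))
        print(ref)
        0L
      },
      estimate = {
        ref <- read_reference_model(.cli_need(opts, "reference"))
        files <- .cli_need(opts, "masses")
        estimates <- lapply(files, function(f) {
          estimate_incorporation(read_mass_list(f), ref)
        })
        for (i in seq_along(files)) {
          message("== ", files[i])
          print(estimates[[i]])
        }
        if (!is.null(opts$out)) {
          write_estimate_report(estimates, opts$out, labels = files)
          message("report written to ", opts$out)
        }
        if (!is.null(opts$plot)) {
          grDevices::png(opts$plot, width = 800, height = 600)
          plot(estimates[[1]])
          grDevices::dev.off()
        }
        0L
      },
      simulate = {
        truth <- .cli_num(opts, "truth", 0)
        n <- as.integer(.cli_need(opts, "n"))
        peptides <- generate_synthetic_peptides(n, seed = .cli_seed(opts))
        write_mass_list(labeled_masses(peptides, truth),
                        .cli_need(opts, "out"))
        message(n, " synthetic masses at ", truth,
                " atom % written to ", opts$out)
        0L
      },
      accuracy = {
        peptides <- generate_synthetic_peptides(
          as.integer(.cli_num(opts, "n-reference", 50000)),
          seed = .cli_seed(opts)
        )
        results <- accuracy_experiment(
          peptides,
          truths = .cli_numvec(opts, "truths", c(0, 50, 100)),
          sizes = .cli_numvec(opts, "sizes",
                              c(10, 20, 30, 40, 50, 60, 70, 80, 90, 100,
                                200, 300, 500, 1000)),
          replicates = .cli_num(opts, "replicates", 100),
          seed = .cli_seed(opts)
        )
        write_accuracy_table(results, .cli_need(opts, "out"))
        print(summary(results))
        0L
      },
      {
        message("unknown subcommand: ", subcommand, "\n\n", .cli_usage())
        1L
      }
    )
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
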