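#' Pipeline run configuration
#'
#' Aggregates the fixed constants of a full run: the generator settings,
#' registration settings (50-iteration cap), the 2-degree clinical
#' cutoff and the 0.05 significance level.
#'
#' @param seed Global seed; per-stage, per-case sub-seeds are derived by
#'   [stable_seed()] so adding cases never reshuffles existing ones.
#' @param n_cases Number of synthetic patients (each contributes a
#'   mandibular and a maxillary arch).
#' @param out_dir Output directory.
#' @param jitter_sd,pose_max_deg,pose_max_mm Generator noise settings
#'   (see [generator_config()]).
#' @param max_iterations ICP iteration cap.
#' @param sample_size ICP moving-vertex subsample bound.
#' @param trim_fraction ICP trimming fraction.
#' @param cutoff_deg Prescription exclusion cutoff (deg).
#' @param alpha Significance level.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L, n_cases = 5L, out_dir = tempfile("run"),
                       jitter_sd = 0.05, pose_max_deg = 5,
                       pose_max_mm = 5, max_iterations = 50L,
                       sample_size = 5000L, trim_fraction = 0,
                       cutoff_deg = 2, alpha = 0.05) {
  stopifnot_scalar_number(n_cases, "n_cases", lower = 1)
  stopifnot_scalar_number(max_iterations, "max_iterations", lower = 1)
  stopifnot_scalar_number(cutoff_deg, "cutoff_deg", lower = 0)
  stopifnot_scalar_number(alpha, "alpha", lower = 1e-6, upper = 0.5)
  stopifnot_scalar_number(jitter_sd, "jitter_sd", lower = 0)
  structure(list(seed = as.integer(seed), n_cases = as.integer(n_cases),
                 out_dir = out_dir, jitter_sd = jitter_sd,
                 pose_max_deg = pose_max_deg, pose_max_mm = pose_max_mm,
                 max_iterations = as.integer(max_iterations),
                 sample_size = as.integer(sample_size),
                 trim_fraction = trim_fraction,
                 cutoff_deg = cutoff_deg, alpha = alpha),
            class = "run_config")
}

log_line <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full synthetic pipeline
#'
#' simulate -> align/measure -> records -> report, writing every stage's
#' artifacts under `config$out_dir`: per-case directories with
#' T0/T1/T2 STL and sidecars, `measurements.csv`, `records.csv`, the
#' four report tables, and `manifest.json` with MD5 hashes of every
#' artifact. Per-tooth measurement failures are logged and quarantined
#' in the manifest without aborting the run.
#'
#' @param config A [run_config()].
#' @return The run directory, invisibly.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) {
    abort("config must be a run_config", "rotometry_invalid_input")
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  measurements <- list()
  quarantine <- character(0L)
  for (i in seq_len(config$n_cases)) {
    case_id <- sprintf("case%03d", i)
    for (arch in c("mandibular", "maxillary")) {
      gc <- generator_config(
        arch = arch,
        seed = stable_seed(config$seed, "simulate", case_id, arch),
        jitter_sd = config$jitter_sd,
        pose_max_deg = config$pose_max_deg,
        pose_max_mm = config$pose_max_mm)
      sim <- generate_arch(gc, case_id = paste0(case_id, "_",
                                                substr(arch, 1L, 4L)))
      case_dir <- file.path(config$out_dir, "cases", sim$case$case_id)
      emit_case(sim$case, sim$truth, case_dir)
      log_line("simulate", "%s written", sim$case$case_id)

      m <- measure_case(sim$case,
                        max_iterations = config$max_iterations,
                        sample_size = config$sample_size,
                        trim_fraction = config$trim_fraction)
      errs <- attr(m, "errors")
      if (length(errs) > 0L) {
        quarantine <- c(quarantine,
                        paste(sim$case$case_id, errs, sep = ": "))
        log_line("measure", "%s: %d teeth quarantined",
                 sim$case$case_id, length(errs))
      }
      measurements[[length(measurements) + 1L]] <- m
      log_line("measure", "%s: %d teeth measured (global RMS %.3f/%.3f)",
               sim$case$case_id, nrow(m),
               attr(m, "global_rms")[["T1"]],
               attr(m, "global_rms")[["T2"]])
    }
  }
  meas <- do.call(rbind, measurements)
  meas_file <- file.path(config$out_dir, "measurements.csv")
  utils::write.csv(meas, meas_file, row.names = FALSE)

  records <- build_records(meas, cutoff_deg = config$cutoff_deg)
  rec_file <- file.path(config$out_dir, "records.csv")
  utils::write.csv(records, rec_file, row.names = FALSE)
  log_line("metrics", "%d records (%d excluded by %g deg cutoff)",
           nrow(records), sum(records$excluded), config$cutoff_deg)

  report_dir <- file.path(config$out_dir, "report")
  build_report(records, report_dir, alpha = config$alpha,
               seed = config$seed)

  artifacts <- list.files(config$out_dir, recursive = TRUE,
                          full.names = TRUE)
  artifacts <- artifacts[basename(artifacts) != "manifest.json"]
  manifest <- list(
    seed = config$seed, n_cases = config$n_cases,
    settings = unclass(config)[setdiff(names(unclass(config)),
                                       "out_dir")],
    quarantine = quarantine,
    files = as.list(stats::setNames(
      unname(tools::md5sum(artifacts)),
      sub(paste0("^", config$out_dir, "/?"), "", artifacts))))
  jsonlite::write_json(manifest, file.path(config$out_dir,
                                           "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(config$out_dir)
}

#' Command-line entry point
#'
#' Minimal subcommand interface: `simulate` (write case directories),
#' `run` (full pipeline), `metrics` (records + report from a
#' measurements CSV). Used by the `inst/cli/rotometry` launcher.
#'
#' @param args Character vector of command-line arguments.
#' @return Exit status, invisibly.
#' @export
rotometry_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: rotometry <simulate|run|metrics> [--seed N] [--out DIR]",
    "[--cases K] [--measurements FILE] [--cutoff DEG] [--alpha A]")
  if (length(args) < 1L) {
    message(usage)
    return(invisible(1L))
  }
  cmd <- args[1L]
  opt <- function(flag, default) {
    i <- which(args == flag)
    if (length(i) == 1L && i < length(args)) args[i + 1L] else default
  }
  seed <- as.integer(opt("--seed", "1"))
  out <- opt("--out", "rotometry_run")
  cases <- as.integer(opt("--cases", "5"))
  cutoff <- as.numeric(opt("--cutoff", "2"))
  alpha <- as.numeric(opt("--alpha", "0.05"))
  status <- 0L
  if (cmd == "simulate") {
    for (i in seq_len(cases)) {
      for (arch in c("mandibular", "maxillary")) {
        case_id <- sprintf("case%03d", i)
        gc <- generator_config(
          arch = arch, seed = stable_seed(seed, "simulate", case_id, arch))
        sim <- generate_arch(gc, paste0(case_id, "_",
                                        substr(arch, 1L, 4L)))
        emit_case(sim$case, sim$truth,
                  file.path(out, sim$case$case_id))
      }
    }
  } else if (cmd == "run") {
    run_pipeline(run_config(seed = seed, n_cases = cases, out_dir = out,
                            cutoff_deg = cutoff, alpha = alpha))
  } else if (cmd == "metrics") {
    mfile <- opt("--measurements", "measurements.csv")
    if (!file.exists(mfile)) {
      message("measurements file not found: ", mfile)
      return(invisible(1L))
    }
    meas <- utils::read.csv(mfile)
    records <- build_records(meas, cutoff_deg = cutoff)
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(records, file.path(out, "records.csv"),
                     row.names = FALSE)
    build_report(records, file.path(out, "report"), alpha = alpha,
                 seed = seed)
  } else {
    message(usage)
    status <- 1L
  }
  invisible(status)
}
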