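# Minimal TOML-subset reader: [section] tables and scalar `key = value`
# pairs (quoted strings, numbers, booleans). Comments start with `#` outside
# quotes. This covers the run-configuration grammar; it is not a general
# TOML implementation.
.parse_toml <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  section <- NULL
  strip_comment <- function(s) {
    in_q <- FALSE
    for (i in seq_len(nchar(s))) {
      ch <- substr(s, i, i)
      if (ch == '"') in_q <- !in_q
      if (ch == "#" && !in_q) return(substr(s, 1, i - 1))
    }
    s
  }
  for (k in seq_along(lines)) {
    ln <- trimws(strip_comment(lines[k]))
    if (ln == "") next
    if (grepl("^\\[.+\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      if (!is.null(out[[section]])) {
        stop(sprintf("line %d of %s: duplicate section [%s]", k, path,
                     section), call. = FALSE)
      }
      out[[section]] <- list()
      next
    }
    m <- regexec("^([A-Za-z0-9_.-]+)\\s*=\\s*(.+)$", ln)
    parts <- regmatches(ln, m)[[1]]
    if (length(parts) != 3L) {
      stop(sprintf("line %d of %s: cannot parse '%s'", k, path, ln),
           call. = FALSE)
    }
    key <- parts[2]
    raw <- trimws(parts[3])
    val <- if (grepl('^".*"$', raw)) {
      gsub('^"|"$', "", raw)
    } else if (raw %in% c("true", "false")) {
      raw == "true"
    } else {
      num <- suppressWarnings(as.numeric(raw))
      if (is.na(num)) {
        stop(sprintf("line %d of %s: unsupported value '%s'", k, path, raw),
             call. = FALSE)
      }
      num
    }
    if (is.null(section)) out[[key]] <- val else out[[section]][[key]] <- val
  }
  out
}

# per-section defaults applied by run_analysis
.run_defaults <- list(equilibration = 0.25, bin_width = 0.05, d0 = 1.0,
                      stride = 1L)

#' Read a run configuration
#'
#' The configuration is TOML: an optional `[run]` table with pipeline-wide
#' defaults (`outdir`, `equilibration`, `bin_width`, `d0`, `stride`,
#' `units`), then one table per lipid/temperature combination. Each lipid
#' table gives either input paths (`area` for the time series, `ztable` or
#' `coords` for phosphorus coordinates) or synthetic ground-truth parameters
#' (`seed` plus optional `ka`, `area0`, `thickness`, `sigma`, `rho`,
#' `n_frames`, `n_phosphorus`, `z_frames`), and a temperature as
#' `temperature_C` or `temperature_K`. Section labels must be unique (TOML
#' enforces this) and are used as lipid labels in reports.
#'
#' @param path Path to the TOML file.
#' @return A list with elements `run` (defaults, possibly empty) and
#'   `sections` (named list of lipid tables, validated).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  toml <- .parse_toml(path)
  tables <- Filter(is.list, toml)
  run <- if (!is.null(tables$run)) tables$run else list()
  sections <- tables[setdiff(names(tables), "run")]
  if (!length(sections)) stop("config has no lipid sections: ", path,
                              call. = FALSE)
  base <- dirname(path)
  for (lab in names(sections)) {
    s <- sections[[lab]]
    if (!is.null(s[["temperature_C"]])) {
      s[["temperature"]] <- celsius_to_kelvin(s[["temperature_C"]])
    } else if (!is.null(s[["temperature_K"]])) {
      s[["temperature"]] <- s[["temperature_K"]]
    } else {
      stop(sprintf("section [%s]: temperature_C or temperature_K required",
                   lab), call. = FALSE)
    }
    if (!is.finite(s[["temperature"]]) || s[["temperature"]] <= 0) {
      stop(sprintf("section [%s]: temperature must be positive", lab),
           call. = FALSE)
    }
    if (is.null(s[["seed"]]) &&
        (is.null(s[["area"]]) || (is.null(s[["ztable"]]) && is.null(s[["coords"]])))) {
      stop(sprintf(
        "section [%s]: give input paths (area and ztable/coords) or a seed for a synthetic run",
        lab), call. = FALSE)
    }
    for (p in c("area", "ztable", "coords")) {
      if (!is.null(s[[p]])) {
        full <- if (file.exists(s[[p]])) s[[p]] else file.path(base, s[[p]])
        if (!file.exists(full)) {
          stop(sprintf("section [%s]: %s file not found: %s", lab, p, s[[p]]),
               call. = FALSE)
        }
        s[[p]] <- full
      }
    }
    sections[[lab]] <- s
  }
  list(run = run, sections = sections)
}

#' Run the full elasticity pipeline from a configuration
#'
#' For every lipid section the pipeline obtains an area series and a
#' phosphorus z table (reading files, or generating a synthetic ensemble
#' when the section gives ground-truth parameters and a seed), applies the
#' equilibration cut, estimates K_A with a block-averaged standard error,
#' builds the phosphorus density profile, measures the peak-to-peak
#' thickness, computes the bending rigidity, and finally assembles the
#' cross-lipid comparative report. When `outdir` is given (in the call or
#' the `[run]` table), results are written there: `results.json`,
#' `report.csv`, `verdicts.csv`, `spread.csv`, per-lipid density profiles
#' and block-error curves, and a plain-text log recording the constants,
#' conversions, cuts and plateau choices behind every number.
#'
#' @param config Path to a TOML file or the result of [read_run_config()].
#' @param outdir Output directory; overrides the config. `NULL` writes
#'   nothing.
#' @return A list with `results` (named list of
#'   [elasticity_result][compute_bending_rigidity] objects) and `report`
#'   (a [comparative_report()]), invisibly.
#' @export
run_analysis <- function(config, outdir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  run <- utils::modifyList(.run_defaults, config$run)
  if (is.null(outdir) && !is.null(run$outdir)) outdir <- run$outdir
  log_lines <- c(
    sprintf("membelast run, kB = %.6e J/K", boltzmann_constant()),
    sprintf("defaults: equilibration = %s, bin_width = %g nm, d0 = %g nm, stride = %d",
            format(run$equilibration), run$bin_width, run$d0,
            as.integer(run$stride))
  )

  results <- list()
  profiles <- list()
  kas <- list()
  for (lab in names(config$sections)) {
    s <- utils::modifyList(run, config$sections[[lab]])
    Tk <- s[["temperature"]]

    spec <- if (!is.null(s[["seed"]])) {
      membrane_spec(
        area_modulus = if (is.null(s[["ka"]])) 240 else s[["ka"]],
        area0 = if (is.null(s[["area0"]])) 130 else s[["area0"]],
        temperature = Tk,
        n_frames = if (is.null(s[["n_frames"]])) 20000L else s[["n_frames"]],
        rho = if (is.null(s[["rho"]])) 0 else s[["rho"]],
        thickness = if (is.null(s[["thickness"]])) 3.8 else s[["thickness"]],
        peak_sigma = if (is.null(s[["sigma"]])) 0.35 else s[["sigma"]],
        n_phosphorus = if (is.null(s[["n_phosphorus"]])) 400L else s[["n_phosphorus"]],
        seed = s[["seed"]]
      )
    } else NULL
    series <- if (!is.null(s[["area"]])) {
      read_area_table(s[["area"]], temperature = Tk)
    } else {
      generate_area_series(spec)
    }
    series <- stride_series(series, s[["stride"]])
    series <- apply_equilibration_cut(series, s[["equilibration"]])
    ka <- estimate_area_modulus(series)

    ztab <- if (!is.null(s[["ztable"]])) {
      read_z_table(s[["ztable"]])
    } else if (!is.null(s[["coords"]])) {
      read_coordinates_z(s[["coords"]],
                         selection = if (is.null(s[["selection"]])) "P"
                                     else s[["selection"]])
    } else {
      generate_phosphorus_z(spec, n_frames = if (is.null(s[["z_frames"]])) 2000L
                                             else s[["z_frames"]])
    }
    prof <- build_density_profile(ztab, bin_width = s[["bin_width"]])
    th <- peak_to_peak_thickness(prof)

    res <- compute_bending_rigidity(ka, th, d0 = s[["d0"]], temperature = Tk,
                                    label = lab)
    results[[lab]] <- res
    profiles[[lab]] <- prof
    kas[[lab]] <- ka
    log_lines <- c(log_lines, sprintf(
      paste0("[%s] T = %.2f K; %d frames after cut of %d; ",
             "K_A = %.2f +/- %.2f mN/m (plateau block %d%s); ",
             "d = %.3f +/- %.3f nm; kappa = %.3f +/- %.3f kBT = %.4e J"),
      lab, Tk, ka$n, series$equilibration_cut, ka$area_modulus, ka$se,
      ka$block$plateau_block,
      if (ka$block$plateau_found) "" else ", no plateau",
      th$thickness, th$uncertainty, res$kappa_kBT, res$kappa_se_kBT,
      res$kappa_J))
  }

  report <- comparative_report(results)

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      lapply(results, function(r) r[!vapply(r, is.null, logical(1))]),
      file.path(outdir, "results.json"),
      auto_unbox = TRUE, digits = NA, na = "null"
    )
    utils::write.csv(report$table, file.path(outdir, "report.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(report$verdicts, file.path(outdir, "verdicts.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(report$spread, file.path(outdir, "spread.csv"),
                     row.names = FALSE, quote = FALSE)
    for (lab in names(profiles)) {
      write_density_profile(profiles[[lab]],
                            file.path(outdir, paste0(lab, "_profile.csv")))
      write_block_curve(kas[[lab]]$block,
                        file.path(outdir, paste0(lab, "_blocks.csv")))
    }
    writeLines(log_lines, file.path(outdir, "run.log"))
  }

  invisible(list(results = results, report = report, log = log_lines))
}
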