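#' Read an experimental time series from CSV
#'
#' Expects a header `time_min,value[,sd]`; lines starting with `#` are
#' comments, and comment lines of the form `# key: value` are collected into
#' the series metadata (the key `kind` sets the series kind).
#'
#' @param path CSV file path.
#' @param kind Series kind override; default: the `kind` metadata comment, or
#'   `"swelling_degree"`.
#' @return An [experimental_series()].
#' @export
read_series <- function(path, kind = NULL) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    mm <- regmatches(ln, regexec("^#\\s*([^:]+):\\s*(.+)$", ln))[[1]]
    if (length(mm) == 3) meta[[trimws(mm[2])]] <- trimws(mm[3])
  }
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  df <- tryCatch(
    read.csv(text = paste(body, collapse = "\n"), strip.white = TRUE),
    error = function(e) stop("malformed series file: ", conditionMessage(e),
                             call. = FALSE))
  if (!all(c("time_min", "value") %in% names(df)))
    stop("series file must have columns time_min, value[, sd]", call. = FALSE)
  if (anyDuplicated(df$time_min)) {
    i <- which(duplicated(df$time_min))[1]
    stop(sprintf("schema error at data row %d: duplicated time %.6g",
                 i, df$time_min[i]), call. = FALSE)
  }
  if (is.unsorted(df$time_min))
    stop("schema error: times must be increasing", call. = FALSE)
  if ("sd" %in% names(df) && any(df$sd < 0, na.rm = TRUE)) {
    i <- which(df$sd < 0)[1]
    stop(sprintf("schema error at data row %d: negative sd", i),
         call. = FALSE)
  }
  if (is.null(kind)) kind <- meta$kind %||% "swelling_degree"
  experimental_series(kind, df$time_min, df$value,
                      sd = if ("sd" %in% names(df)) df$sd else NULL,
                      metadata = meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an experimental series to CSV
#'
#' Inverse of [read_series()]: metadata entries become `# key: value` comment
#' lines followed by a `time_min,value,sd` table.
#'
#' @param series An [experimental_series()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "experimental_series"))
  meta <- c(list(kind = series$kind),
            Filter(function(x) is.character(x) || is.numeric(x),
                   series$metadata))
  hdr <- vapply(names(meta), function(k)
    sprintf("# %s: %s", k, paste(format(meta[[k]], digits = 12),
                                 collapse = " ")), "")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.csv(series$data, con, row.names = FALSE)
  invisible(path)
}

#' Write a release protocol to YAML
#'
#' @param protocol A [release_protocol()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "release_protocol"))
  doc <- list(
    formulation = list(
      name = protocol$formulation$name,
      dry_diameter_mm = protocol$formulation$dry_diameter_mm,
      dry_density = protocol$formulation$dry_density,
      drug_mass_fraction = protocol$formulation$drug_mass_fraction),
    drug = protocol$drug[!vapply(protocol$drug, is.null, TRUE)],
    sample_mass_mg = protocol$sample_mass_mg,
    stages = lapply(protocol$stages, function(st) list(
      medium = st$medium$name,
      solvent_density = st$medium$solvent_density,
      swelling = unclass(st$swelling),
      D_d_sg = st$D_d_sg, k_bg_sg = st$k_bg_sg,
      V_res_mL = st$V_res_mL, duration_min = st$duration_min,
      withdrawal_times_min = st$schedule$times_min,
      withdrawal_volume_mL = st$schedule$volume_mL)))
  yaml::write_yaml(doc, path, precision = 12)
  invisible(path)
}

#' Read a release protocol from YAML
#'
#' @param path YAML file written by [write_protocol()] (or hand-authored with
#'   the same keys).
#' @return A [release_protocol()].
#' @export
read_protocol <- function(path) {
  doc <- yaml::read_yaml(path)
  form <- bead_formulation(doc$formulation$name,
                           doc$formulation$dry_diameter_mm,
                           doc$formulation$dry_density,
                           drug_mass_fraction =
                             doc$formulation$drug_mass_fraction %||% 0)
  dr <- doc$drug
  drug <- drug_params(dr$D_d_sg, epsilon = dr$epsilon %||% 0,
                      k_bg_sg = dr$k_bg_sg %||% 0, c_d0 = dr$c_d0)
  stages <- lapply(doc$stages, function(sd) {
    sw <- sd$swelling
    release_stage(
      medium = medium(sd$medium, sd$solvent_density %||% 1.0),
      swelling = swelling_params(sw$D_s_sg, sw$phi_eq, beta = sw$beta,
                                 phi_G = sw$phi_G, phi_0 = sw$phi_0),
      D_d_sg = sd$D_d_sg, k_bg_sg = sd$k_bg_sg %||% 0,
      V_res_mL = sd$V_res_mL, duration_min = sd$duration_min,
      schedule = withdrawal_schedule(unlist(sd$withdrawal_times_min),
                                     sd$withdrawal_volume_mL %||% 1))
  })
  release_protocol(stages, form, drug, doc$sample_mass_mg %||% 15)
}

#' Export a release solution to CSV files
#'
#' Writes the reservoir trace (`trace.csv`: time_min, C_res_mg_per_mL,
#' event_flag, released_fraction, Mt_over_Minf) and the withdrawal ledger
#' (`ledger.csv`: t_w_min, C_w_mg_per_mL, mass_removed_mg).
#'
#' @param sol A `release_solution`.
#' @param dir Output directory (created if missing).
#' @return Character vector of the files written, invisibly.
#' @export
write_release_csv <- function(sol, dir) {
  stopifnot(inherits(sol, "release_solution"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  trace <- sol$curve
  names(trace)[names(trace) == "C_res"] <- "C_res_mg_per_mL"
  names(trace)[names(trace) == "event"] <- "event_flag"
  f1 <- file.path(dir, "trace.csv")
  write.csv(trace, f1, row.names = FALSE)
  led <- sol$ledger
  names(led)[names(led) == "C_w"] <- "C_w_mg_per_mL"
  f2 <- file.path(dir, "ledger.csv")
  write.csv(led, f2, row.names = FALSE)
  invisible(c(f1, f2))
}

#' Run a configured pipeline stage and write a manifest
#'
#' A light command layer over the package functions. `config` is a named list
#' (or YAML file path) with at least `command` and `out_dir`; other fields
#' depend on the command:
#' \describe{
#'   \item{`simulate-swelling`}{`formulation`, `medium` (fixture keys),
#'     `t_end_h` (default 24).}
#'   \item{`simulate-gi`}{`drug` (`tph`/`b12`), `formulation`
#'     (`gg`/`gg_lapo`).}
#'   \item{`gen-data`}{`kind` (`swelling`/`release`), `formulation`,
#'     `medium`, `drug` (release only), `noise_level`, `seed`.}
#'   \item{`fixtures`}{no extra fields; writes the registry as YAML.}
#' }
#' Every run writes `manifest.json` (command, config, outputs, package
#' version, seed) into `out_dir`.
#'
#' @param config Named list or path to a YAML config file.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$command) || is.null(config$out_dir))
    stop("config must name a `command` and an `out_dir`", call. = FALSE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character()
  cmd <- config$command
  if (cmd == "simulate-swelling") {
    key <- config$formulation %||% "gg"
    med <- config$medium %||% "SIF"
    sol <- solve_swelling(fixture_formulation(key), medium(med),
                          fixture_swelling(key, med),
                          t_end_s = (config$t_end_h %||% 24) * 3600)
    f <- file.path(config$out_dir, "swelling_curve.csv")
    write.csv(swelling_degree_curve(sol), f, row.names = FALSE)
    outputs <- f
  } else if (cmd == "simulate-gi") {
    if (is.null(config$drug) || is.null(config$formulation))
      stop("simulate-gi needs `drug` and `formulation`", call. = FALSE)
    sol <- simulate_gi_fixture(config$drug, config$formulation)
    outputs <- write_release_csv(sol, config$out_dir)
  } else if (cmd == "gen-data") {
    key <- config$formulation %||% "gg"
    med <- config$medium %||% "SGF"
    nm <- noise_model(level = config$noise_level %||% 0.02,
                      seed = config$seed %||% 1L)
    if ((config$kind %||% "swelling") == "swelling") {
      ser <- gen_swelling_series(fixture_formulation(key), medium(med),
                                 fixture_swelling(key, med), noise = nm)
      f <- file.path(config$out_dir, "swelling_series.csv")
      write_series(ser, f)
      outputs <- f
    } else {
      drug <- config$drug %||% "tph"
      dp <- fixture_drug(drug, key, med)
      st <- release_stage(medium(med), fixture_swelling(key, med),
                          D_d_sg = dp$D_d_sg, k_bg_sg = dp$k_bg_sg,
                          V_res_mL = config$V_res_mL %||% 100,
                          duration_min = 240)
      pr <- release_protocol(st, fixture_formulation(key, drug = drug), dp)
      gs <- gen_release_series(pr, noise = nm)
      f1 <- file.path(config$out_dir, "differential_series.csv")
      f2 <- file.path(config$out_dir, "integral_series.csv")
      write_series(gs$differential, f1)
      write_series(gs$integral, f2)
      outputs <- c(f1, f2)
    }
  } else if (cmd == "fixtures") {
    f <- file.path(config$out_dir, "fixtures.yaml")
    yaml::write_yaml(bead_fixtures(), f)
    outputs <- f
  } else {
    stop("unknown command: ", cmd, call. = FALSE)
  }
  manifest <- list(command = cmd, config = config, outputs = outputs,
                   package = "gelbead",
                   version = as.character(utils::packageVersion("gelbead")),
                   seed = config$seed %||% NA)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
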