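# File formats, run configuration and report generation.
#
# Time courses are CSV with '#'-prefixed metadata header lines, then
# 'time_s,absorbance'. Spectral series are CSV with a 'wavelength_nm'
# column followed by one column per acquisition time. Run configs are YAML
# (JSON accepted); reports are JSON with units annotated in key names.

.log_msg <- function(..., verbose = getOption("glbkin.verbose", FALSE)) {
  if (isTRUE(verbose)) {
    message(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), ...)
  }
}

# Order-invariant FNV-style hash of a config for report provenance.
.config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Write a time course to CSV
#'
#' @param tc a [timecourse()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_timecourse <- function(tc, path) {
  stopifnot(inherits(tc, "timecourse"))
  instr <- tc$instrument
  meta <- c(
    paste0("# instrument_kind: ", instr$kind),
    paste0("# dead_time_s: ", format(instr$dead_time, digits = 15)),
    paste0("# sampling_s: ", format(instr$sampling_interval, digits = 15)),
    paste0("# duration_s: ", format(instr$duration, digits = 15)),
    paste0("# noise_sd_au: ", format(instr$noise_sd, digits = 15)),
    paste0("# pathlength_cm: ", format(instr$pathlength, digits = 15)),
    paste0("# wavelength_nm: ", format(tc$wavelength, digits = 15)),
    paste0("# seed: ", tc$seed))
  truth <- tc$truth
  truth$noiseless <- NULL
  if (length(truth)) {
    meta <- c(meta, paste0("# truth: ",
                           jsonlite::toJSON(truth, auto_unbox = TRUE,
                                            digits = NA)))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  writeLines("time_s,absorbance", con)
  utils::write.table(
    data.frame(time_s = format(tc$times, digits = 15),
               absorbance = format(tc$signal, digits = 15)),
    con, sep = ",", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a time course from CSV
#'
#' @param path file written by [write_timecourse()].
#' @return A [timecourse()].
#' @export
read_timecourse <- function(path) {
  lines <- readLines(path)
  meta_idx <- grep("^#", lines)
  meta <- list()
  for (ln in lines[meta_idx]) {
    kv <- regmatches(ln, regexec("^#\\s*([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(kv) == 3) meta[[kv[2]]] <- kv[3]
  }
  header_idx <- grep("^time_s", lines)[1]
  if (is.na(header_idx) || header_idx == length(lines)) {
    stop("read_timecourse: no data rows in ", path, call. = FALSE)
  }
  body <- lines[(header_idx + 1L):length(lines)]
  body <- body[nzchar(body)]
  parts <- strsplit(body, ",", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) != 2L |
                 vapply(parts, function(p) {
                   anyNA(suppressWarnings(as.numeric(p)))
                 }, logical(1)))
  if (length(bad)) {
    stop("read_timecourse: malformed row(s) at line ",
         paste(bad + header_idx, collapse = ", "), " of ", path,
         call. = FALSE)
  }
  num <- vapply(parts, function(p) as.numeric(p), numeric(2))
  instr <- instrument_profile(
    kind = meta$instrument_kind %||% "stopped_flow",
    dead_time = as.numeric(meta$dead_time_s %||% 0),
    sampling_interval = as.numeric(meta$sampling_s %||% 1),
    duration = as.numeric(meta$duration_s %||% max(num[1, ])),
    noise_sd = as.numeric(meta$noise_sd_au %||% 0),
    pathlength = as.numeric(meta$pathlength_cm %||% 1))
  truth <- if (!is.null(meta$truth)) jsonlite::fromJSON(meta$truth) else NULL
  timecourse(num[1, ], num[2, ], instr,
             wavelength = as.numeric(meta$wavelength_nm %||% NA),
             seed = as.integer(meta$seed %||% NA), truth = truth)
}

#' Write a spectral series to CSV
#'
#' @param series a [spectrum_series()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_spectrum_series <- function(series, path) {
  stopifnot(inherits(series, "spectrum_series"))
  df <- data.frame(wavelength_nm = series$wavelengths,
                   series$absorbance, check.names = FALSE)
  names(df)[-1] <- format(series$times, digits = 15, trim = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# pathlength_cm: ",
                    format(series$pathlength, digits = 15)), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a spectral series from CSV
#'
#' @param path file written by [write_spectrum_series()].
#' @return A [spectrum_series()].
#' @export
read_spectrum_series <- function(path) {
  first <- readLines(path, n = 1)
  pathlength <- 1
  skip <- 0
  if (grepl("^#", first)) {
    pathlength <- as.numeric(sub("^#\\s*pathlength_cm:\\s*", "", first))
    skip <- 1
  }
  df <- utils::read.csv(path, skip = skip, check.names = FALSE)
  spectrum_series(df[[1]], as.numeric(names(df)[-1]),
                  as.matrix(df[, -1, drop = FALSE]), pathlength)
}

.cfg_get <- function(cfg, path_keys) {
  node <- cfg
  for (k in path_keys) {
    if (is.null(node[[k]])) {
      stop("read_run_config: missing required field '",
           paste(path_keys, collapse = "."), "'", call. = FALSE)
    }
    node <- node[[k]]
  }
  node
}

#' Read and validate a run configuration
#'
#' YAML (or JSON) with a `protein` block (name and per-site rate constants,
#' units s^-1 and M^-1 s^-1), one or more `assays` blocks (kind,
#' concentrations in M, pH), an optional `instrument` block and a `seed`.
#' Validation errors name the offending field path.
#'
#' @param path config file (`.yaml`, `.yml` or `.json`).
#' @return List with `protein` (a [protein_model()]), `assays` (list of
#'   [assay_conditions()] plus per-assay options), `instrument` overrides,
#'   `seed`, and the raw config in `$raw`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  prot_cfg <- .cfg_get(raw, "protein")
  name <- .cfg_get(raw, c("protein", "name"))
  sites_cfg <- .cfg_get(raw, c("protein", "sites"))
  rate_fields <- c("k_minus_H_per_s" = "k_minus_H", "k_H_per_s" = "k_H",
                   "k_prime_on_NO_per_M_s" = "k_prime_on_NO",
                   "k_on_O2_per_M_s" = "k_on_O2",
                   "k_off_O2_per_s" = "k_off_O2",
                   "k_on_CO_per_M_s" = "k_on_CO",
                   "k_NOD_per_M_s" = "k_NOD",
                   "k_NiR_pH7_per_M_s" = "k_NiR_pH7")
  sites <- lapply(seq_along(sites_cfg), function(i) {
    sc <- sites_cfg[[i]]
    args <- list(has_distal_his = isTRUE(sc$has_distal_his %||% TRUE))
    for (key in names(rate_fields)) {
      if (!is.null(sc[[key]])) args[[rate_fields[[key]]]] <- sc[[key]]
    }
    do.call(heme_site, args)
  })
  protein <- protein_model(name, sites)
  assays_cfg <- .cfg_get(raw, "assays")
  assays <- lapply(seq_along(assays_cfg), function(i) {
    ac <- assays_cfg[[i]]
    kind <- ac$kind
    if (is.null(kind) || !kind %in% assay_kinds()) {
      stop("read_run_config: assays[", i, "].kind must be one of ",
           paste(assay_kinds(), collapse = ", "), call. = FALSE)
    }
    cond <- assay_conditions(
      kind,
      protein_conc = ac$protein_conc_M %||% 2.5e-6,
      ligand_conc = ac$ligand_conc_M %||% 0,
      dithionite_conc = ac$dithionite_conc_M %||% 0,
      CO_conc = ac$CO_conc_M %||% 0,
      O2_conc = ac$O2_conc_M %||% 0,
      pH = ac$pH %||% 7)
    list(conditions = cond, vary = ac$vary %||% NULL,
         values = ac$values_M %||% NULL,
         n_replicates = ac$n_replicates %||% 1,
         label = ac$label %||% kind)
  })
  list(protein = protein, assays = assays,
       instrument = raw$instrument %||% list(),
       seed = raw$seed %||% 1, raw = raw)
}

#' Simulate every assay in a run configuration
#'
#' Writes one time-course CSV per (assay, varied value, replicate) into
#' `out_dir`, plus the resolved configuration, deterministically for a
#' given seed.
#'
#' @param config path to a config file or the result of
#'   [read_run_config()].
#' @param out_dir output directory (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
run_simulate <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  for (a in config$assays) {
    .log_msg("simulating assay ", a$label)
    traces <- generate_assay_dataset(
      config$protein, a$conditions, vary = a$vary, values = a$values,
      n_replicates = a$n_replicates, seed = config$seed)
    for (i in seq_along(traces)) {
      f <- file.path(out_dir, sprintf("%s_%03d.csv", a$label, i))
      write_timecourse(traces[[i]], f)
      written <- c(written, f)
    }
  }
  cfg_file <- file.path(out_dir, "resolved_config.json")
  jsonlite::write_json(config$raw, cfg_file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(written, cfg_file))
}

#' Analyse a simulated or recorded dataset
#'
#' Reads every time-course CSV in `dataset_dir`, groups traces by assay
#' (from their truth blocks), runs the fitting chain appropriate to each
#' assay, and writes a JSON report containing the fitted rates with
#' standard errors, phase counts, dependence verdicts, censoring bounds,
#' O2 affinity constants and reference comparisons, plus the seed, config
#' hash and package version.
#'
#' @param dataset_dir directory of CSVs from [run_simulate()].
#' @param config config path or [read_run_config()] result.
#' @param out_path output JSON path (default `report.json` inside
#'   `dataset_dir`).
#' @return The report list, invisibly; the JSON file is written as a side
#'   effect.
#' @export
run_analyze <- function(dataset_dir, config,
                        out_path = file.path(dataset_dir, "report.json")) {
  if (is.character(config)) config <- read_run_config(config)
  files <- list.files(dataset_dir, pattern = "\\.csv$", full.names = TRUE)
  if (!length(files)) {
    stop("run_analyze: no time-course CSV files in ", dataset_dir,
         call. = FALSE)
  }
  traces <- lapply(files, read_timecourse)
  assays <- vapply(traces, function(tc) tc$truth$assay %||% "unknown",
                   character(1))
  protein <- config$protein
  max_phases <- length(protein$sites)
  report <- list(
    seed = config$seed,
    config_hash = .config_hash(config$raw),
    package_version = as.character(utils::packageVersion("glbkin")),
    protein = protein$name,
    assays = list())
  for (kind in unique(assays)) {
    sub <- traces[assays == kind]
    .log_msg("analysing ", length(sub), " ", kind, " trace(s)")
    entry <- list(n_traces = length(sub))
    kobs <- .kobs_table(sub, max_phases = if (kind == "O2_dissociation_trap")
      max_phases else 1)
    entry$kobs_per_s <- kobs
    tab <- data.frame(conc = kobs$value, kobs = kobs$kobs)
    if (kind == "O2_dissociation_trap") {
      res <- trap_koff_experiment(protein, traces = sub)
      entry$k_off_per_s <- as.list(res$k_off)
      entry$n_phases <- res$n_phases_mode
      # affinity floor from the minimum observable k_on of the detector
      entry$affinity <- lapply(res$k_off, function(koff) {
        aff <- affinity_constants(5e8, koff)
        list(K_min_per_M = aff$K_2sf, Kd_max_M = aff$Kd_2sf)
      })
    } else if (kind == "NO_binding") {
      entry$verdict <- classify_dependence(tab)
      entry$k_NO_per_s <- mean(kobs$kobs)
    } else if (kind == "NiR") {
      so <- fit_second_order(tab)
      entry$k_NiR_per_heme_per_M_s <- so$second_order_k
      entry$k_NiR_per_molecule_per_M_s <-
        so$second_order_k * length(protein$sites)
      entry$verdict <- classify_dependence(tab)
      entry$reference_fold_changes <-
        as.list(compare_to_references(entry$k_NiR_per_molecule_per_M_s))
    }
    report$assays[[kind]] <- entry
  }
  jsonlite::write_json(report, out_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  .log_msg("report written to ", out_path)
  invisible(report)
}
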