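#' Write a trace to CSV
#'
#' Comma-separated, '.' decimal, mandatory header, UTF-8; times in ms.
#' Electrical traces use columns `time_ms,Vm_mV,Cai_uM,CaSR_mM,Cass_mM`;
#' mechanics traces `time_ms,tension_kPa,force_norm,ATP_norm,SL_um,eq_length`.
#' Values are written with 17 significant digits so a write/read round trip
#' reproduces the doubles exactly.
#'
#' @param trace an `ionic_trace`, `mech_trace`, or plain data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  df <- if (inherits(trace, c("ionic_trace", "mech_trace"))) trace$trace else trace
  if (inherits(trace, "ionic_trace"))
    df <- df[, c("time_ms", "Vm_mV", "Cai_uM", "CaSR_mM", "Cass_mM")]
  txt <- vapply(df, function(col) sprintf("%.17g", col), character(nrow(df)))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = ","), con)
  writeLines(do.call(paste, c(as.data.frame(txt, stringsAsFactors = FALSE),
                              sep = ",")), con)
  invisible(path)
}

#' Read a trace CSV written by [write_trace_csv()]
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_trace_csv <- function(path) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  df <- tryCatch(utils::read.csv(path, check.names = FALSE,
                                 colClasses = "numeric"),
                 error = function(e) stop("malformed CSV ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  if (!"time_ms" %in% names(df))
    stop("malformed trace CSV (no time_ms column): ", path)
  bad <- !vapply(df, is.numeric, TRUE)
  if (any(bad))
    stop("malformed trace CSV ", path, ": non-numeric column '",
         names(df)[bad][1], "'")
  df
}

#' Write the sweep summary CSV (Table-1-style columns)
#'
#' @param sweep a `sweep_result`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_summary_csv <- function(sweep, path) {
  utils::write.csv(sweep$metrics, path, row.names = FALSE)
  invisible(path)
}

#' Write the per-combination alternans flags as JSON
#'
#' @param sweep a `sweep_result`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_alternans_json <- function(sweep, path) {
  jsonlite::write_json(sweep$alternans, path, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read a sweep configuration from a YAML file
#'
#' Recognized keys mirror the arguments of [sweep_config()]; unknown keys
#' raise an error naming the field.
#'
#' @param path YAML file.
#' @return a [sweep_config()].
#' @export
read_sweep_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  known <- c("cell_variants", "bcl_list", "n_beats", "record_beats", "loads",
             "dt", "dt_out", "mech_dt", "mech_dt_out", "apd_fraction", "seed")
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown config field: ", paste(bad, collapse = ", "))
  y$cell_variants <- unlist(y$cell_variants)
  for (k in c("bcl_list", "record_beats", "loads"))
    if (!is.null(y[[k]])) y[[k]] <- as.numeric(unlist(y[[k]]))
  do.call(sweep_config, y)
}

# per-combination trace persistence used by run_sweep(out_dir = ...)
persist_cell <- function(res, out_dir, config) {
  files <- character(0)
  f <- sprintf("%s_bcl%g_electrical.csv", res$variant, res$bcl)
  write_trace_csv(res$electrical, file.path(out_dir, f))
  files <- c(files, f)
  for (li in seq_along(res$loads)) {
    fm <- sprintf("%s_bcl%g_load%g_mech.csv", res$variant, res$bcl,
                  load_kpa(res$loads[[li]]))
    write_trace_csv(res$mechanical[[li]], file.path(out_dir, fm))
    files <- c(files, fm)
  }
  files
}

#' Write the run manifest
#'
#' Records the configuration, package version, solver settings and the file
#' inventory (with MD5 checksums) so a run can be re-analyzed or reproduced.
#'
#' @param config the [sweep_config()] used.
#' @param files files written (relative to `out_dir`).
#' @param out_dir output directory.
#' @return manifest path, invisibly.
#' @export
write_manifest <- function(config, files, out_dir) {
  paths <- file.path(out_dir, files)
  inv <- data.frame(file = files,
                    md5 = unname(tools::md5sum(paths)),
                    stringsAsFactors = FALSE)
  cfg <- unclass(config)
  cfg$loads <- lapply(config$loads, unclass)
  man <- list(package_version = as.character(utils::packageVersion("cardalt")),
              config = cfg, files = inv)
  p <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(man, p, auto_unbox = TRUE, digits = NA)
  invisible(p)
}

#' Recompute the sweep summary from persisted trace files
#'
#' Reads the manifest and trace CSVs written by [run_sweep()] and recomputes
#' every per-beat metric from the files alone; by construction this
#' reproduces the inline summary exactly (traces round-trip losslessly).
#' Mechanics-only directories (e.g. synthetic-Ca runs) are analyzed without
#' electrical files.
#'
#' @param dir directory containing `manifest.json` and trace CSVs.
#' @return data.frame of per-beat metrics.
#' @export
analyze_traces <- function(dir) {
  if (!dir.exists(dir)) stop("no such directory: ", dir)
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json in ", dir)
  man <- jsonlite::read_json(mf, simplifyVector = TRUE)
  cfg <- man$config
  record_beats <- as.integer(unlist(cfg$record_beats))
  fraction <- as.numeric(cfg$apd_fraction)
  traces <- man$files$file
  elec_files <- grep("_electrical\\.csv$", traces, value = TRUE)
  if (!length(elec_files)) stop("no electrical traces listed in manifest")
  out <- list()
  for (ef in elec_files) {
    stem <- sub("_electrical\\.csv$", "", ef)
    parts <- regmatches(stem, regexec("^(.+)_bcl([0-9.]+)$", stem))[[1]]
    variant <- parts[2]
    bcl <- as.numeric(parts[3])
    edf <- read_trace_csv(file.path(dir, ef))
    dt_out <- edf$time_ms[2] - edf$time_ms[1]
    n_beats <- as.integer(cfg$n_beats)
    eobj <- list(trace = edf,
                 beat_start = as.integer((seq_len(n_beats) - 1) *
                                           round(bcl / dt_out) + 1))
    mech_files <- grep(sprintf("^%s_load.*_mech\\.csv$", stem), traces,
                       value = TRUE)
    for (mfile in mech_files) {
      lk <- as.numeric(sub(".*_load([0-9.]+)_mech\\.csv$", "\\1", mfile))
      mdf <- read_trace_csv(file.path(dir, mfile))
      mdt <- mdf$time_ms[2] - mdf$time_ms[1]
      mobj <- list(trace = mdf,
                   beat_start = as.integer((seq_len(n_beats) - 1) *
                                             round(bcl / mdt) + 1))
      rows <- do.call(rbind, lapply(record_beats, function(b)
        combined_beat_metrics(eobj, mobj, b, fraction)))
      out[[length(out) + 1]] <-
        cbind(data.frame(variant = variant, bcl = bcl, load_kPa = lk,
                         mode = "isotonic"), rows)
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
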