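#' Default BCL list of the study
#'
#' 1000 ms down to 200 ms in 30 ms decrements (the final step lands on
#' 200 ms), 28 values.
#' @return numeric vector of BCLs (ms).
#' @export
default_bcl_list <- function() c(seq(1000, 220, by = -30), 200)

#' Sweep configuration
#'
#' @param cell_variants subset of `c("endo", "mid", "epi")`.
#' @param bcl_list BCLs in ms (arbitrary lists allowed, min 150 ms).
#' @param n_beats stimuli per BCL (default 30).
#' @param record_beats beats whose metrics are recorded (default 29, 30).
#' @param loads numeric afterloads in kPa (isotonic mode; 1000 kPa acts as
#'   the pseudo-isometric condition) or a list of [load_condition()].
#' @param dt,dt_out electrical integration/output steps (ms).
#' @param mech_dt,mech_dt_out mechanical integration/output steps (ms).
#' @param apd_fraction repolarization fraction for APD.
#' @param thresholds [alternans_thresholds()].
#' @param seed reserved (the pipeline core is deterministic).
#' @return object of class `sweep_config`.
#' @export
sweep_config <- function(cell_variants = c("endo", "mid", "epi"),
                         bcl_list = default_bcl_list(), n_beats = 30,
                         record_beats = c(29, 30), loads = c(0.6, 10, 1000),
                         dt = 0.01, dt_out = 0.2, mech_dt = 0.1,
                         mech_dt_out = 0.5, apd_fraction = 0.9,
                         thresholds = alternans_thresholds(), seed = 1L) {
  cell_variants <- match.arg(cell_variants, several.ok = TRUE)
  stopifnot(min(bcl_list) >= 150, all(record_beats >= 1),
            all(record_beats <= n_beats))
  if (is.numeric(loads))
    loads <- lapply(loads, function(l) load_condition("isotonic", afterload = l))
  stopifnot(all(vapply(loads, inherits, TRUE, "load_condition")))
  structure(list(cell_variants = cell_variants, bcl_list = bcl_list,
                 n_beats = as.integer(n_beats),
                 record_beats = sort(as.integer(record_beats)), loads = loads,
                 dt = dt, dt_out = dt_out, mech_dt = mech_dt,
                 mech_dt_out = mech_dt_out, apd_fraction = apd_fraction,
                 thresholds = thresholds, seed = as.integer(seed)),
            class = "sweep_config")
}

load_kpa <- function(load)
  if (load$mode == "isometric_clamp") NA_real_ else load$afterload

# row indices of one beat's window in a uniformly sampled trace
beat_window_idx <- function(n_rows, beat_start, beat, closing = TRUE) {
  n_beats <- length(beat_start)
  stopifnot(beat >= 1, beat <= n_beats)
  i0 <- beat_start[beat]
  i1 <- if (beat < n_beats) beat_start[beat + 1] - 1L else n_rows
  if (closing && beat < n_beats) i1 <- i1 + 1L  # include next stimulus sample
  seq.int(i0, min(i1, n_rows))
}

#' Row indices of one beat's window in a run's trace
#'
#' @param run an `ionic_trace` or `mech_trace`.
#' @param beat beat index.
#' @return integer row indices spanning the beat (including the closing
#'   sample at the next stimulus).
#' @export
beat_window <- function(run, beat) {
  beat_window_idx(nrow(run$trace), run$beat_start, beat)
}

#' APD of one beat of a paced run
#'
#' @param run an `ionic_trace` from [run_paced()].
#' @param beat beat index.
#' @param fraction repolarization fraction.
#' @return list as returned by [apd()].
#' @export
beat_apd <- function(run, beat, fraction = 0.9) {
  idx <- beat_window_idx(nrow(run$trace), run$beat_start, beat)
  apd(run$trace$time_ms[idx], run$trace$Vm_mV[idx], fraction)
}

#' One-way coupled run of a single (variant, BCL, loads) combination
#'
#' The electrical stage runs first to completion; its cytosolic Ca transient
#' (uM) then drives the mechanics stage once per load condition over the
#' identical time base. Coupling is strictly one-way: mechanics never feeds
#' back on the ionic model.
#'
#' @param variant cell variant.
#' @param bcl basic cycle length (ms).
#' @param loads numeric afterloads (kPa) or list of [load_condition()].
#' @param config a [sweep_config()] providing solver settings and beat
#'   bookkeeping.
#' @param params optional explicit ionic parameters.
#' @param mech_par mechanics parameters.
#' @return object of class `cell_run`: list with `electrical` (ionic trace),
#'   `mechanical` (one `mech_trace` per load), `metrics` (one row per
#'   recorded beat x load), `alternans` (one report per load).
#' @export
run_cell <- function(variant, bcl, loads = c(0.6, 10, 1000),
                     config = sweep_config(), params = NULL,
                     mech_par = mech_params()) {
  if (is.numeric(loads))
    loads <- lapply(loads, function(l) load_condition("isotonic", afterload = l))
  prot <- stimulus_protocol(bcl, n_beats = config$n_beats)
  elec <- tryCatch(
    run_paced(variant, prot, params = params, dt = config$dt,
              dt_out = config$dt_out),
    error = function(e) stop("electrical stage failed (", variant, ", BCL ",
                             bcl, "): ", conditionMessage(e), call. = FALSE))
  ca <- ca_transient(elec)
  mech_runs <- lapply(loads, function(ld) {
    tryCatch(
      run_mechanics(ca, ld, mech_par, dt = config$mech_dt,
                    dt_out = config$mech_dt_out),
      error = function(e) stop("mechanical stage failed (", variant, ", BCL ",
                               bcl, ", load ",
                               load_kpa(ld), " kPa): ",
                               conditionMessage(e), call. = FALSE))
  })
  metrics <- list()
  alternans <- list()
  for (li in seq_along(loads)) {
    mt <- mech_runs[[li]]
    rows <- lapply(config$record_beats, function(b)
      combined_beat_metrics(elec, mt, b, config$apd_fraction))
    rows <- do.call(rbind, rows)
    rows <- cbind(data.frame(variant = variant, bcl = bcl,
                             load_kPa = load_kpa(loads[[li]]),
                             mode = loads[[li]]$mode), rows)
    metrics[[li]] <- rows
    if (length(config$record_beats) == 2) {
      alternans[[li]] <- detect_alternans(rows[1, ], rows[2, ],
                                          config$thresholds)
    }
  }
  structure(list(variant = variant, bcl = bcl, loads = loads,
                 electrical = elec, mechanical = mech_runs,
                 metrics = do.call(rbind, metrics), alternans = alternans),
            class = "cell_run")
}

# merge electrical-grid and mechanics-grid per-beat metrics into one row
combined_beat_metrics <- function(elec, mech, beat, fraction = 0.9) {
  ei <- beat_window_idx(nrow(elec$trace), elec$beat_start, beat)
  em <- beat_metrics(elec$trace$time_ms[ei], vm_mV = elec$trace$Vm_mV[ei],
                     ca_uM = elec$trace$Cai_uM[ei], fraction = fraction,
                     beat_index = beat)
  mi <- beat_window_idx(nrow(mech$trace), mech$beat_start, beat)
  mm <- beat_metrics(mech$trace$time_ms[mi],
                     tension_kPa = mech$trace$tension_kPa[mi],
                     atp = mech$trace$ATP_norm[mi],
                     eq_length = mech$trace$eq_length[mi],
                     beat_index = beat)
  em[, c("st", "dt", "tpt", "sl_sys", "dl", "tpl",
         "atp_peak", "atp_min", "tpa")] <-
    mm[, c("st", "dt", "tpt", "sl_sys", "dl", "tpl",
           "atp_peak", "atp_min", "tpa")]
  em
}

#' Run the full BCL sweep
#'
#' Executes every (cell variant x BCL x load) combination, each started
#' fresh from the resting state, so results are independent of execution
#' order. Per-combination failures are recorded and the sweep continues.
#' When `out_dir` is given, traces and the growing summary are persisted
#' after each combination together with a run manifest.
#'
#' @param config a [sweep_config()].
#' @param out_dir optional output directory.
#' @param mech_par mechanics parameters.
#' @param progress print per-combination progress lines.
#' @return object of class `sweep_result`: list with `metrics` (data.frame),
#'   `alternans` (data.frame of per-combination flags), `failures`,
#'   `config`.
#' @export
run_sweep <- function(config = sweep_config(), out_dir = NULL,
                      mech_par = mech_params(), progress = FALSE) {
  metrics <- list()
  alt <- list()
  failures <- list()
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (v in config$cell_variants) {
    for (bcl in config$bcl_list) {
      t0 <- proc.time()[["elapsed"]]
      res <- tryCatch(
        run_cell(v, bcl, config$loads, config, mech_par = mech_par),
        error = function(e) e)
      if (inherits(res, "error")) {
        failures[[length(failures) + 1]] <-
          data.frame(variant = v, bcl = bcl, message = conditionMessage(res))
        next
      }
      key <- sprintf("%s_bcl%g", v, bcl)
      metrics[[key]] <- res$metrics
      alt[[key]] <- alternans_rows(res)
      if (!is.null(out_dir)) files <- c(files, persist_cell(res, out_dir, config))
      if (progress)
        message(sprintf("%s BCL %g ms: done in %.1f s", v, bcl,
                        proc.time()[["elapsed"]] - t0))
    }
  }
  out <- structure(
    list(metrics = do.call(rbind, c(metrics, list(make.row.names = FALSE))),
         alternans = do.call(rbind, c(alt, list(make.row.names = FALSE))),
         failures = if (length(failures)) do.call(rbind, failures) else NULL,
         config = config),
    class = "sweep_result")
  if (!is.null(out_dir)) {
    write_summary_csv(out, file.path(out_dir, "summary.csv"))
    write_alternans_json(out, file.path(out_dir, "alternans.json"))
    write_manifest(config, c(files, "summary.csv", "alternans.json"), out_dir)
  }
  out
}

alternans_rows <- function(res) {
  rows <- lapply(seq_along(res$alternans), function(li) {
    a <- res$alternans[[li]]
    if (is.null(a)) return(NULL)
    data.frame(variant = res$variant, bcl = res$bcl,
               load_kPa = load_kpa(res$loads[[li]]), block = a$block,
               electrical = a$electrical$flag, delta_apd = a$electrical$delta_apd_ms,
               ca = a$ca$flag, delta_ca_max = a$ca$delta_ca_max_uM,
               mechanical = a$mechanical$flag, delta_st = a$mechanical$delta_st_kPa,
               discordant = a$discordant)
  })
  do.call(rbind, rows)
}

#' Refine the electrical alternans onset BCL by bisection
#'
#' Scans the coarse BCL list downward until the first alternans-positive BCL
#' (|APD(30) - APD(29)| above threshold, both beats captured), then bisects
#' between it and the last negative BCL down to the requested resolution.
#' Returns the largest BCL found alternans-positive.
#'
#' @param variant cell variant.
#' @param coarse_bcls coarse scan BCLs (descending; default study grid).
#' @param resolution bisection resolution (ms, default 2).
#' @param n_beats stimuli per BCL.
#' @param threshold_ms APD alternans threshold (ms).
#' @param params optional explicit ionic parameters.
#' @param dt,dt_out solver settings.
#' @param fraction APD repolarization fraction.
#' @return list with `onset_bcl` (NA when no alternans in range),
#'   `evaluated` (data.frame of every probed BCL), `n_runs`.
#' @export
refine_alternans_onset <- function(variant, coarse_bcls = default_bcl_list(),
                                   resolution = 2, n_beats = 30,
                                   threshold_ms = 2, params = NULL,
                                   dt = 0.01, dt_out = 0.2, fraction = 0.9) {
  coarse_bcls <- sort(coarse_bcls, decreasing = TRUE)
  evaluated <- list()
  probe <- function(bcl) {
    run <- run_paced(variant, stimulus_protocol(bcl, n_beats), params = params,
                     dt = dt, dt_out = dt_out)
    a29 <- beat_apd(run, n_beats - 1L, fraction)
    a30 <- beat_apd(run, n_beats, fraction)
    flag <- isTRUE(a29$captured) && isTRUE(a30$captured) &&
      !is.na(a29$apd_ms) && !is.na(a30$apd_ms) &&
      abs(a30$apd_ms - a29$apd_ms) > threshold_ms
    row <- data.frame(bcl = bcl, apd29 = a29$apd_ms, apd30 = a30$apd_ms,
                      captured = a29$captured && a30$captured,
                      alternans = flag)
    evaluated[[length(evaluated) + 1]] <<- row
    flag
  }
  hi_neg <- NA_real_
  lo_pos <- NA_real_
  for (bcl in coarse_bcls) {
    if (probe(bcl)) { lo_pos <- bcl; break }
    hi_neg <- bcl
  }
  if (is.na(lo_pos))
    return(list(onset_bcl = NA_real_,
                evaluated = do.call(rbind, evaluated),
                n_runs = length(evaluated)))
  if (!is.na(hi_neg)) {
    while (hi_neg - lo_pos > resolution) {
      mid <- round((hi_neg + lo_pos) / 2)
      if (probe(mid)) lo_pos <- mid else hi_neg <- mid
    }
  }
  list(onset_bcl = lo_pos, evaluated = do.call(rbind, evaluated),
       n_runs = length(evaluated))
}
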