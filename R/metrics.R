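#' Action potential duration of one beat
#'
#' Time from the maximum upstroke velocity (max dV/dt) to the crossing of
#' `V_rest + (1 - fraction) * (V_peak - V_rest)`, linearly interpolated
#' between samples. A beat whose peak never rises above 0 mV is treated as
#' not captured (stimulus blocked) and gets an undefined APD.
#'
#' @param time_ms,vm_mV sampled membrane potential over one beat window.
#' @param fraction repolarization fraction in (0, 1); 0.9 gives APD90.
#' @return list with `apd_ms`, `captured`, `t_upstroke_ms`, `v_peak`, `v_rest`.
#' @export
apd <- function(time_ms, vm_mV, fraction = 0.9) {
  stopifnot(length(time_ms) == length(vm_mV), length(time_ms) >= 3,
            fraction > 0, fraction < 1)
  v_rest <- vm_mV[1]
  ipk <- which.max(vm_mV)
  v_peak <- vm_mV[ipk]
  if (v_peak <= 0 || v_peak - v_rest < 10)
    return(list(apd_ms = NA_real_, captured = FALSE, t_upstroke_ms = NA_real_,
                v_peak = v_peak, v_rest = v_rest))
  dvdt <- diff(vm_mV) / diff(time_ms)
  iup <- which.max(dvdt)
  t_up <- (time_ms[iup] + time_ms[iup + 1]) / 2
  v_thr <- v_peak - fraction * (v_peak - v_rest)
  below <- which(vm_mV[(ipk + 1):length(vm_mV)] <= v_thr)
  if (!length(below))
    return(list(apd_ms = NA_real_, captured = TRUE, t_upstroke_ms = t_up,
                v_peak = v_peak, v_rest = v_rest))
  i2 <- ipk + below[1]
  i1 <- i2 - 1
  t_cross <- time_ms[i1] + (v_thr - vm_mV[i1]) /
    (vm_mV[i2] - vm_mV[i1]) * (time_ms[i2] - time_ms[i1])
  list(apd_ms = t_cross - t_up, captured = TRUE, t_upstroke_ms = t_up,
       v_peak = v_peak, v_rest = v_rest)
}

#' Scalar metrics of one beat
#'
#' Computes the per-beat summary used throughout the study: APD, calcium
#' transient extrema, systolic/diastolic tension and their timing, systolic
#' and diastolic equivalent cell length, and the ATP consumption rate
#' extrema. Times are reported relative to the beat's stimulus (the first
#' sample of the window). Diastolic tension and length are measured over the
#' final `diastolic_frac` of the beat window, just before the next stimulus.
#'
#' @param time_ms sample times of the beat window (first sample = stimulus).
#' @param vm_mV,ca_uM,tension_kPa,atp,eq_length optional aligned traces.
#' @param fraction APD repolarization fraction.
#' @param diastolic_frac final fraction of the window used for diastolic
#'   readouts.
#' @param beat_index bookkeeping index stored in the result.
#' @return one-row data.frame (class `beat_metrics`).
#' @export
beat_metrics <- function(time_ms, vm_mV = NULL, ca_uM = NULL,
                         tension_kPa = NULL, atp = NULL, eq_length = NULL,
                         fraction = 0.9, diastolic_frac = 0.05,
                         beat_index = NA_integer_) {
  n <- length(time_ms)
  stopifnot(n >= 3)
  t0 <- time_ms[1]
  out <- data.frame(beat = beat_index, captured = NA, apd = NA_real_,
                    ca_max = NA_real_, ca_min = NA_real_, st = NA_real_,
                    dt = NA_real_, tpt = NA_real_, sl_sys = NA_real_,
                    dl = NA_real_, tpl = NA_real_, atp_peak = NA_real_,
                    atp_min = NA_real_, tpa = NA_real_)
  idia <- seq.int(max(1L, n - max(1L, ceiling(diastolic_frac * n)) + 1L), n)
  if (!is.null(vm_mV)) {
    a <- apd(time_ms, vm_mV, fraction)
    out$captured <- a$captured
    out$apd <- a$apd_ms
  }
  if (!is.null(ca_uM)) {
    out$ca_max <- max(ca_uM)
    out$ca_min <- min(ca_uM)
  }
  if (!is.null(tension_kPa)) {
    out$st <- max(tension_kPa)
    out$dt <- min(tension_kPa[idia])
    out$tpt <- time_ms[which.max(tension_kPa)] - t0
  }
  if (!is.null(eq_length)) {
    out$sl_sys <- min(eq_length)
    out$dl <- eq_length[n]
    out$tpl <- time_ms[which.min(eq_length)] - t0
  }
  if (!is.null(atp)) {
    out$atp_peak <- max(atp)
    out$atp_min <- min(atp)
    out$tpa <- time_ms[which.max(atp)] - t0
  }
  class(out) <- c("beat_metrics", "data.frame")
  out
}

#' Alternans detection thresholds
#'
#' @param apd_ms absolute APD difference threshold (ms).
#' @param ca_rel Ca-peak difference threshold, relative to the mean transient
#'   amplitude of the two beats.
#' @param tension_rel tension-peak difference threshold, relative to the mean
#'   beat amplitude (ST - DT).
#' @return named list.
#' @export
alternans_thresholds <- function(apd_ms = 2, ca_rel = 0.02,
                                 tension_rel = 0.02) {
  stopifnot(apd_ms >= 0, ca_rel >= 0, tension_rel >= 0)
  list(apd_ms = apd_ms, ca_rel = ca_rel, tension_rel = tension_rel)
}

#' Detect beat-to-beat alternans between the two recorded steady-state beats
#'
#' Electrical alternans: `|APD(30) - APD(29)|` above the APD threshold;
#' calcium and mechanical (tension) alternans analogous with thresholds
#' relative to the respective beat amplitudes. Discordant alternans: the
#' long-APD beat of the pair carries the smaller Ca peak.
#'
#' @param m29,m30 [beat_metrics()] rows of beats 29 and 30.
#' @param thresholds an [alternans_thresholds()] list.
#' @return list (class `alternans_report`) with per-modality flags and
#'   deltas, `discordant`, and `block` (TRUE when either beat was not
#'   captured, in which case no alternans call is made).
#' @export
detect_alternans <- function(m29, m30, thresholds = alternans_thresholds()) {
  blocked <- isFALSE(m29$captured) || isFALSE(m30$captured)
  d_apd <- m30$apd - m29$apd
  d_ca <- m30$ca_max - m29$ca_max
  d_st <- m30$st - m29$st
  ca_amp <- mean(c(m29$ca_max - m29$ca_min, m30$ca_max - m30$ca_min))
  t_amp <- mean(c(m29$st - m29$dt, m30$st - m30$dt))
  el <- if (blocked || is.na(d_apd)) NA else abs(d_apd) > thresholds$apd_ms
  caf <- if (blocked || is.na(d_ca)) NA else
    abs(d_ca) > thresholds$ca_rel * ca_amp
  mech <- if (blocked || is.na(d_st)) NA else
    abs(d_st) > thresholds$tension_rel * t_amp
  disc <- if (isTRUE(el) && isTRUE(caf)) sign(d_apd) * sign(d_ca) < 0 else FALSE
  structure(list(block = blocked,
                 electrical = list(flag = el, delta_apd_ms = d_apd),
                 ca = list(flag = caf, delta_ca_max_uM = d_ca),
                 mechanical = list(flag = mech, delta_st_kPa = d_st),
                 discordant = disc, thresholds = thresholds),
            class = "alternans_report")
}

#' APD restitution table and maximum slope
#'
#' Tabulates the beat-29/30 APDs against BCL, computes the diastolic
#' interval preceding beat 30 (`DI = BCL - APD29`), and estimates the
#' restitution slope by finite differences of APD30 vs DI on the
#' pre-alternans branch (BCLs where the two recorded beats agree within the
#' APD threshold).
#'
#' @param tbl data.frame with columns `bcl`, `apd29`, `apd30`.
#' @param apd_threshold_ms pre-alternans branch criterion (ms).
#' @return list with the augmented `table` (adds `di`, `alternating`) and
#'   `max_slope`.
#' @export
restitution_curve <- function(tbl, apd_threshold_ms = 2) {
  stopifnot(all(c("bcl", "apd29", "apd30") %in% names(tbl)))
  tbl <- tbl[stats::complete.cases(tbl[, c("bcl", "apd29", "apd30")]), ]
  if (nrow(tbl) < 3) stop("restitution curve needs at least 3 captured BCLs")
  tbl <- tbl[order(tbl$bcl), ]
  tbl$di <- tbl$bcl - tbl$apd29
  tbl$alternating <- abs(tbl$apd30 - tbl$apd29) > apd_threshold_ms
  br <- tbl[!tbl$alternating, ]
  max_slope <- NA_real_
  if (nrow(br) >= 2) {
    br <- br[order(br$di), ]
    sl <- diff(br$apd30) / diff(br$di)
    max_slope <- max(sl)
  }
  list(table = tbl, max_slope = max_slope)
}

#' Tension amplitude and systolic peak versus BCL
#'
#' For the pseudo-isometric condition: per BCL, amplitude = `ST - DT` of
#' beat 30 (beat 29 reported alongside), plus the BCL maximizing the beat-30
#' amplitude.
#'
#' @param metrics sweep metrics data.frame (see [run_sweep()]) with columns
#'   `variant, bcl, load_kPa, beat, st, dt`.
#' @param load_kPa load condition to extract (default 1000, pseudo-isometric).
#' @param variant optional cell variant filter.
#' @return list with `table` (`bcl, amplitude29, amplitude30, peak30`) and
#'   `argmax_bcl`.
#' @export
tension_amplitude_curve <- function(metrics, load_kPa = 1000, variant = NULL) {
  stopifnot(all(c("bcl", "load_kPa", "beat", "st", "dt") %in% names(metrics)))
  m <- metrics[metrics$load_kPa == load_kPa, ]
  if (!is.null(variant)) m <- m[m$variant == variant, ]
  if (!nrow(m)) stop("no rows for the requested load/variant")
  b30 <- m[m$beat == max(m$beat), ]
  b29 <- m[m$beat == min(m$beat), ]
  tab <- data.frame(bcl = b30$bcl,
                    amplitude30 = b30$st - b30$dt,
                    peak30 = b30$st)
  tab$amplitude29 <- (b29$st - b29$dt)[match(tab$bcl, b29$bcl)]
  tab <- tab[order(-tab$bcl), c("bcl", "amplitude29", "amplitude30", "peak30")]
  list(table = tab, argmax_bcl = tab$bcl[which.max(tab$amplitude30)])
}
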