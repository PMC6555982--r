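# shared expensive runs, computed once per test session
.cache <- new.env(parent = emptyenv())

cached_run <- function(variant, bcl = 1000, n_beats = 30) {
  key <- sprintf("run_%s_%g_%d", variant, bcl, n_beats)
  if (is.null(.cache[[key]]))
    .cache[[key]] <- run_paced(variant, stimulus_protocol(bcl, n_beats))
  .cache[[key]]
}

cached_onset <- function(variant) {
  key <- paste0("onset_", variant)
  if (is.null(.cache[[key]]))
    .cache[[key]] <- refine_alternans_onset(variant)
  .cache[[key]]
}

cached_mech <- function(variant, afterload, bcl = 1000) {
  key <- sprintf("mech_%s_%g_%g", variant, afterload, bcl)
  if (is.null(.cache[[key]]))
    .cache[[key]] <- run_mechanics(ca_transient(cached_run(variant, bcl)),
                                   load_condition("isotonic", afterload = afterload))
  .cache[[key]]
}

beat_rows <- function(obj, beat) {
  tr <- obj$trace
  idx <- seq_along(tr$time_ms)
  n_beats <- length(obj$beat_start)
  i0 <- obj$beat_start[beat]
  i1 <- if (beat < n_beats) obj$beat_start[beat + 1] else nrow(tr)
  seq.int(i0, i1)
}
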