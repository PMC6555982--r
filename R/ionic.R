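#' Published resting state of the ionic model
#'
#' Initial conditions for the human ventricular myocyte model: resting
#' membrane potential with closed channels and diastolic ion concentrations.
#' Every pacing run starts fresh from this state unless another state is
#' supplied, so sweep results are order-independent.
#'
#' @return named numeric vector (19 states).
#' @export
ionic_initial_state <- function() {
  stats::setNames(
    c(-86.2, 0, 0.75, 0.75, 0, 1, 0, 0, 1, 0, 1, 1, 1, 1,
      0.00007, 1.3, 0.00007, 7.67, 138.3),
    ionic_state_names())
}

#' Pacing stimulus protocol
#'
#' @param bcl basic cycle length (ms).
#' @param n_beats number of stimuli (default 30; the last two beats are the
#'   conventional steady-state readout).
#' @param amplitude stimulus current in A/F; negative = depolarizing
#'   (twice-threshold convention, -52 A/F).
#' @param duration pulse width (ms).
#' @return object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(bcl, n_beats = 30, amplitude = -52, duration = 1) {
  stopifnot(bcl > duration, duration > 0, n_beats >= 1)
  structure(list(bcl = bcl, n_beats = as.integer(n_beats),
                 amplitude = amplitude, duration = duration),
            class = "stimulus_protocol")
}

validate_ionic_state <- function(state) {
  nm <- ionic_state_names()
  if (length(state) != length(nm))
    stop("ionic state must have ", length(nm), " elements")
  if (is.null(names(state))) names(state) <- nm
  state <- state[nm]
  if (anyNA(state)) stop("ionic state has missing/misnamed entries")
  gates <- state[2:14]
  if (any(gates < 0 | gates > 1)) stop("gating variables must lie in [0, 1]")
  if (any(state[c("Cai", "CaSR", "CaSS", "Nai", "Ki")] < 0))
    stop("ionic concentrations must be non-negative")
  state
}

#' Sarcoplasmic-reticulum calcium fluxes
#'
#' Leak, SERCA uptake, release (calcium-induced calcium release through the
#' open fraction `O`), and subspace-to-cytosol transfer, all in mM/ms.
#' The uptake flux tends to 0 as `Ca_i` tends to 0 (no division fault).
#'
#' @param state ionic state vector.
#' @param params ionic parameters, see [ionic_params()].
#' @return named numeric vector `c(I_leak, I_up, I_rel, I_xfer)`.
#' @export
sr_fluxes <- function(state, params) {
  state <- validate_ionic_state(state)
  cur <- .tt06_currents(state, params, check_finite = FALSE)
  c(I_leak = cur$Ileak, I_up = cur$Iup, I_rel = cur$Irel, I_xfer = cur$Ixfer)
}

#' Total transmembrane ionic current with per-current breakdown
#'
#' @inheritParams sr_fluxes
#' @return list with `total` (A/F) and named `breakdown` of the twelve
#'   sarcolemmal currents.
#' @export
total_ionic_current <- function(state, params) {
  state <- validate_ionic_state(state)
  cur <- .tt06_currents(state, params)
  nm <- c("INa", "IK1", "Ito", "IKr", "IKs", "ICaL", "INaCa", "INaK",
          "IpCa", "IpK", "IbCa", "IbNa")
  breakdown <- stats::setNames(vapply(nm, function(k) cur[[k]], 0), nm)
  list(total = cur$Iion, breakdown = breakdown)
}

#' Full right-hand side of the ionic model
#'
#' The stimulus is applied when `t mod BCL` falls inside the pulse window.
#'
#' @inheritParams sr_fluxes
#' @param t time since the first stimulus (ms).
#' @param protocol a [stimulus_protocol()] (or `NULL` for no stimulus).
#' @return list with `dstate` (d/dt of all 19 states) and `currents`.
#' @export
ionic_derivs <- function(state, t = 0, params, protocol = NULL) {
  state <- validate_ionic_state(state)
  istim <- 0
  if (!is.null(protocol)) {
    phase <- t %% protocol$bcl
    if (t >= 0 && t < protocol$bcl * protocol$n_beats &&
        phase < protocol$duration)
      istim <- protocol$amplitude
  }
  .tt06_derivs(state, istim, params)
}

#' Run a paced train of the ionic model
#'
#' Integrates `n_beats` stimuli at the protocol's BCL from the supplied
#' initial state. The production path is a fixed-step Heun
#' (predictor-corrector) integrator with Rush-Larsen exponential gate
#' updates (dt = 0.01 ms, chosen so one paced beat agrees with the adaptive
#' reference within 0.5 mV); an adaptive stiff solver (`deSolve::lsoda`)
#' over the identical right-hand side is available as reference
#' (`method = "adaptive"`).
#'
#' @param variant cell variant passed to [ionic_params()], or `NULL` when
#'   `params` given.
#' @param protocol a [stimulus_protocol()].
#' @param params optional explicit parameter vector (overrides `variant`).
#' @param dt integration step (ms, fixed-step method).
#' @param dt_out output sampling interval (ms).
#' @param method `"fixed"` (default) or `"adaptive"`.
#' @param state0 initial state (default [ionic_initial_state()]).
#' @param rtol,atol adaptive-solver tolerances.
#' @return object of class `ionic_trace`: list with `trace` (data.frame
#'   `time_ms, Vm_mV, Cai_uM, CaSR_mM, Cass_mM, O`), `beat_start` (row index
#'   of each beat's stimulus), `bcl`, `snapshots` (state at each beat
#'   boundary), `final_state`, `variant`.
#' @export
run_paced <- function(variant = "endo", protocol, params = NULL, dt = 0.01,
                      dt_out = 0.2, method = c("fixed", "adaptive"),
                      state0 = ionic_initial_state(), rtol = 1e-6,
                      atol = 1e-8) {
  method <- match.arg(method)
  stopifnot(inherits(protocol, "stimulus_protocol"))
  if (is.null(params)) params <- ionic_params(variant)
  state0 <- validate_ionic_state(state0)

  if (method == "fixed") {
    raw <- .tt06_run(state0, params, protocol$bcl, protocol$n_beats,
                     protocol$amplitude, protocol$duration, dt, dt_out)
    trace <- data.frame(time_ms = raw$time_ms, Vm_mV = raw$Vm_mV,
                        Cai_uM = raw$Cai_mM * 1000, CaSR_mM = raw$CaSR_mM,
                        Cass_mM = raw$Cass_mM, O = raw$O)
    beat_start <- raw$beat_start_idx
    snapshots <- raw$snapshots
    final_state <- raw$final_state
  } else {
    sol <- run_paced_adaptive(state0, params, protocol, dt_out, rtol, atol)
    trace <- sol$trace
    beat_start <- sol$beat_start
    snapshots <- sol$snapshots
    final_state <- sol$final_state
  }
  structure(list(trace = trace, beat_start = beat_start, bcl = protocol$bcl,
                 n_beats = protocol$n_beats, dt_out = dt_out,
                 snapshots = snapshots, final_state = final_state,
                 variant = attr(params, "cell_variant") %||% variant),
            class = "ionic_trace")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# adaptive reference integration, beat by beat (stimulus window integrated
# as its own segment so the solver never steps across the discontinuity)
run_paced_adaptive <- function(state0, params, protocol, dt_out, rtol, atol) {
  bcl <- protocol$bcl
  n_out_beat <- round(bcl / dt_out)
  times_beat <- seq(0, bcl, by = dt_out)
  snapshots <- matrix(NA_real_, protocol$n_beats + 1, length(state0),
                      dimnames = list(NULL, names(state0)))
  rows <- vector("list", protocol$n_beats)
  y <- state0
  f <- function(t, y, parms) {
    d <- .tt06_derivs(y, parms$istim, params)
    list(d$dstate)
  }
  for (b in seq_len(protocol$n_beats)) {
    snapshots[b, ] <- y
    t_stim <- c(0, protocol$duration)
    s1 <- deSolve::lsoda(y, times = unique(c(t_stim[1], times_beat[times_beat <= t_stim[2]], t_stim[2])),
                         func = f, parms = list(istim = protocol$amplitude),
                         rtol = rtol, atol = atol)
    y1 <- s1[nrow(s1), -1]
    t_rest <- unique(c(t_stim[2], times_beat[times_beat >= t_stim[2]], bcl))
    s2 <- deSolve::lsoda(y1, times = t_rest, func = f,
                         parms = list(istim = 0), rtol = rtol, atol = atol)
    y <- s2[nrow(s2), -1]
    # collect output on the dt_out grid (excluding the beat-end point, which
    # is the next beat's start)
    seg <- rbind(s1[s1[, 1] %in% times_beat, , drop = FALSE],
                 s2[s2[, 1] %in% times_beat & s2[, 1] > t_stim[2], , drop = FALSE])
    seg <- seg[seg[, 1] < bcl, , drop = FALSE]
    seg[, 1] <- seg[, 1] + (b - 1) * bcl
    rows[[b]] <- seg
  }
  snapshots[protocol$n_beats + 1, ] <- y
  out <- do.call(rbind, rows)
  # append final point
  out <- rbind(out, c(protocol$n_beats * bcl, y))
  st <- out[, -1, drop = FALSE]
  O <- vapply(seq_len(nrow(st)), function(i) {
    .tt06_currents(stats::setNames(st[i, ], names(state0)), params)$O
  }, 0)
  trace <- data.frame(time_ms = out[, 1], Vm_mV = st[, "V"],
                      Cai_uM = st[, "Cai"] * 1000, CaSR_mM = st[, "CaSR"],
                      Cass_mM = st[, "CaSS"], O = O)
  beat_start <- as.integer((seq_len(protocol$n_beats) - 1) * n_out_beat + 1)
  list(trace = trace, beat_start = beat_start, snapshots = snapshots,
       final_state = stats::setNames(as.numeric(y), names(state0)))
}

#' Extract the calcium transient handed to the mechanics stage
#'
#' @param run an `ionic_trace` from [run_paced()].
#' @return data.frame `time_ms, Cai_uM` with attributes `beat_start` and
#'   `bcl` (class `ca_transient`).
#' @export
ca_transient <- function(run) {
  stopifnot(inherits(run, "ionic_trace"))
  out <- data.frame(time_ms = run$trace$time_ms, Cai_uM = run$trace$Cai_uM)
  attr(out, "beat_start") <- run$beat_start
  attr(out, "bcl") <- run$bcl
  class(out) <- c("ca_transient", "data.frame")
  out
}
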