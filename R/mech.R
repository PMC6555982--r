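#' Load condition for the mechanics stage
#'
#' The study's "isometric" condition is isotonic contraction against a
#' 1000 kPa afterload, which pins the sarcomere at its rest length; a true
#' isosarcometric clamp (`dSL/dt == 0` exactly) is provided additionally.
#'
#' @param mode `"isotonic"` or `"isometric_clamp"`.
#' @param afterload afterload in kPa (must be > 0 for isotonic).
#' @param preload preload in kPa (default 0: the passive force at `SL0`,
#'   which is zero by construction since passive force is measured about
#'   the rest length).
#' @return object of class `load_condition`.
#' @export
load_condition <- function(mode = c("isotonic", "isometric_clamp"),
                           afterload = 10, preload = 0) {
  mode <- match.arg(mode)
  if (mode == "isotonic" && afterload <= 0)
    stop("isotonic afterload must be > 0 kPa")
  structure(list(mode = mode, afterload = afterload, preload = preload),
            class = "load_condition")
}

#' Initial (fully relaxed) mechanics state
#'
#' @param params mechanics parameters, see [mech_params()].
#' @param ca_dia_uM diastolic Ca level used to pre-equilibrate troponin (uM).
#' @return named numeric vector (9 states).
#' @export
mech_initial_state <- function(params = mech_params(), ca_dia_uM = 0.1) {
  tca <- params[["kon"]] * ca_dia_uM /
    (params[["kon"]] * ca_dia_uM + params[["koff"]])
  stats::setNames(c(0.99, 0.01, 0, 0, 0, params[["x0"]], tca,
                    params[["SL0"]], 0),
                  mech_state_names())
}

validate_mech_state <- function(state) {
  nm <- mech_state_names()
  if (length(state) != length(nm))
    stop("mechanics state must have ", length(nm), " elements")
  if (is.null(names(state))) names(state) <- nm
  state <- state[nm]
  if (anyNA(state)) stop("mechanics state has missing/misnamed entries")
  occ <- state[1:4]
  if (any(occ < -1e-9 | occ > 1 + 1e-9))
    stop("cross-bridge occupancies must lie in [0, 1]")
  if (abs(sum(occ) - 1) > 1e-6)
    stop("cross-bridge occupancies must sum to 1")
  state
}

#' Thick-filament single-overlap fraction
#'
#' Piecewise-linear fraction of myosin heads in the single-overlap region,
#' in [0, 1]; equals 1 at optimal sarcomere length.
#'
#' @param SL sarcomere length (um), within the model's SL bounds.
#' @param params mechanics parameters.
#' @return dimensionless fraction.
#' @export
single_overlap_fraction <- function(SL, params = mech_params()) {
  vapply(SL, function(s) .mech_sovf(s, params), 0)
}

#' Normalized active force and tension
#'
#' `F_active = SOVF_thick(SL) * (xXB_PreR*XB_PreR + xXB_PostR*XB_PostR) /
#' (x_0 * XB_PostR_Max)`; tension is `force_scale` times the normalized force.
#'
#' @param state mechanics state vector.
#' @param params mechanics parameters.
#' @return list with `force_norm` and `tension_kPa`.
#' @export
active_force <- function(state, params = mech_params()) {
  state <- validate_mech_state(state)
  duty <- .mech_duty_fractions(params)
  f <- single_overlap_fraction(state[["SL"]], params) *
    (state[["xXB_PreR"]] * state[["XB_PreR"]] +
     state[["xXB_PostR"]] * state[["XB_PostR"]]) /
    (params[["x0"]] * duty[["dutyPostR"]])
  list(force_norm = f, tension_kPa = params[["force_scale"]] * f)
}

#' Contractile ATP consumption rate
#'
#' `ATP = g_xbT * XB_PostR * SOVF_thick(SL)` (normalized, 1/ms), including
#' the strain dependence of the detachment rate; always non-negative.
#'
#' @inheritParams active_force
#' @return normalized ATP consumption rate (1/ms).
#' @export
atp_rate <- function(state, params = mech_params()) {
  state <- validate_mech_state(state)
  r <- .mech_rates(state, params)
  r$gxbT * state[["XB_PostR"]] * r$sovf
}

#' Strain- and activation-modified cross-bridge transition rates
#'
#' @inheritParams active_force
#' @return list of rates `knpT, kpnT, fappT, gappT, hfT, hbT, gxbT` (1/ms)
#'   and the current overlap fraction `sovf`.
#' @export
xb_rates <- function(state, params = mech_params()) {
  state <- validate_mech_state(state)
  .mech_rates(state, params)
}

#' Time derivatives of the cross-bridge chain, strains and troponin
#'
#' Four-state chain `N_xb <-> P_xb <-> XB_PreR <-> XB_PostR` with
#' permissiveness rates `K_np*(TCa_Tot)^7.5` / `K_pn*(TCa_Tot)^-7.5`
#' (smooth sigmoid form, capped as `TCa_Tot` approaches 0), attachment
#' `f_appT/g_appT`, rotation `h_fT/h_bT` and ATP-consuming detachment
#' `g_xbT`; plus mean-strain ODEs and troponin Ca binding.
#'
#' @inheritParams active_force
#' @param ca_uM cytosolic Ca (uM), >= 0.
#' @param dSLdt imposed sarcomere-length velocity (um/ms).
#' @return named vector of d(state)/dt.
#' @export
xb_transitions <- function(state, ca_uM, params = mech_params(), dSLdt = 0) {
  state <- validate_mech_state(state)
  if (ca_uM < 0) stop("Ca must be >= 0")
  .mech_derivs(state, ca_uM, dSLdt, params)
}

#' Sarcomere-length dynamics under a load condition
#'
#' `d(SL)/dt = (Integral_Force + (SL_0 - SL) * viscosity) / mass`, where the
#' force integral accumulates afterload + preload - active - passive
#' contributions; under the isosarcometric clamp the velocity is identically
#' zero.
#'
#' @inheritParams active_force
#' @param load a [load_condition()].
#' @return `dSL/dt` (um/ms).
#' @export
sl_dynamics <- function(state, load, params = mech_params()) {
  state <- validate_mech_state(state)
  stopifnot(inherits(load, "load_condition"))
  if (load$mode == "isometric_clamp") return(0)
  (state[["intf"]] + (params[["SL0"]] - state[["SL"]]) * params[["viscosity"]]) /
    params[["mass"]]
}

#' Run the mechanics stage over a calcium transient
#'
#' Integrates the cross-bridge model driven by linear interpolation of a
#' uniformly sampled cytosolic Ca transient (the electrical stage's output
#' or a synthetic waveform). Equivalent cell length is `SL / SL_0`
#' (1.0 = fully relaxed).
#'
#' @param ca a `ca_transient` data.frame (`time_ms, Cai_uM`, uniformly
#'   sampled) from [ca_transient()] or [generate_ca()].
#' @param load a [load_condition()].
#' @param params mechanics parameters.
#' @param dt integration step (ms).
#' @param dt_out output sampling interval (ms).
#' @param state0 initial mechanics state.
#' @return object of class `mech_trace`: list with `trace` (data.frame
#'   `time_ms, tension_kPa, force_norm, ATP_norm, SL_um, eq_length`),
#'   `occupancies`, `occupancy_sum`, `beat_start`, `bcl`, `final_state`.
#' @export
run_mechanics <- function(ca, load = load_condition(), params = mech_params(),
                          dt = 0.1, dt_out = 0.5, state0 = NULL) {
  stopifnot(inherits(load, "load_condition"))
  if (inherits(ca, "ionic_trace")) ca <- ca_transient(ca)
  if (!all(c("time_ms", "Cai_uM") %in% names(ca)))
    stop("ca must have columns time_ms and Cai_uM")
  tms <- ca$time_ms
  ca_dt <- tms[2] - tms[1]
  if (max(abs(diff(tms) - ca_dt)) > 1e-6)
    stop("ca must be uniformly sampled")
  if (is.null(state0))
    state0 <- mech_initial_state(params, ca_dia_uM = ca$Cai_uM[1])
  state0 <- validate_mech_state(state0)
  mode <- if (load$mode == "isometric_clamp") 1L else 0L
  raw <- .mech_run(state0, ca$Cai_uM, ca_dt, params, mode,
                   load$afterload, load$preload, dt, dt_out)
  trace <- data.frame(time_ms = raw$time_ms, tension_kPa = raw$tension_kPa,
                      force_norm = raw$force_norm, ATP_norm = raw$ATP_norm,
                      SL_um = raw$SL_um, eq_length = raw$eq_length)
  bcl <- attr(ca, "bcl")
  beat_start <- NULL
  if (!is.null(bcl))
    beat_start <- as.integer(round(seq(0, max(trace$time_ms) - bcl, by = bcl) /
                                     dt_out) + 1)
  structure(list(trace = trace, occupancies = raw$occupancies,
                 occupancy_sum = raw$occupancy_sum, beat_start = beat_start,
                 bcl = bcl, load = load, final_state = raw$final_state),
            class = "mech_trace")
}
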