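#' Specification of a parametric cytosolic calcium transient
#'
#' Emulates the electrical stage's output so the mechanics stage and metrics
#' are testable without running the ionic model. Per beat the waveform is a
#' double exponential `Ca_dia + A_k * (1 - exp(-t/tau_r)) * exp(-t/tau_decay)`
#' normalized so the beat peaks at `Ca_dia + A_k` at time ~`t_rise`; `A_k`
#' alternates between `Ca_amp` (odd beats) and `Ca_amp * alternation_ratio`
#' (even beats). Defaults emulate the endocardial steady-state transient at
#' BCL 1000 ms (diastolic 0.098 uM, peak 0.73 uM).
#'
#' @param bcl basic cycle length (ms).
#' @param n_beats number of beats.
#' @param ca_dia diastolic level (uM), >= 0.
#' @param ca_amp peak-minus-diastolic amplitude of odd beats (uM), > 0.
#' @param t_rise time to peak (ms).
#' @param tau_decay decay time constant (ms).
#' @param alternation_ratio even/odd beat amplitude ratio in (0, 1].
#' @param noise_sd additive Gaussian noise (uM), clipped at 0.
#' @param seed RNG seed for the noise.
#' @return object of class `ca_waveform_spec`.
#' @export
ca_waveform_spec <- function(bcl = 1000, n_beats = 2, ca_dia = 0.098,
                             ca_amp = 0.632, t_rise = 25, tau_decay = 70,
                             alternation_ratio = 1, noise_sd = 0, seed = 1L) {
  stopifnot(ca_dia >= 0, ca_amp > 0, t_rise > 0, tau_decay > 0,
            alternation_ratio > 0, alternation_ratio <= 1, noise_sd >= 0,
            bcl > 0, n_beats >= 1)
  structure(list(bcl = bcl, n_beats = as.integer(n_beats), ca_dia = ca_dia,
                 ca_amp = ca_amp, t_rise = t_rise, tau_decay = tau_decay,
                 alternation_ratio = alternation_ratio, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "ca_waveform_spec")
}

# rise constant such that (1-exp(-t/tau_r))*exp(-t/tau_d) peaks at t_rise:
# the peak sits at t* = tau_r * log(1 + tau_d/tau_r)
solve_tau_rise <- function(t_rise, tau_decay) {
  f <- function(tr) tr * log(1 + tau_decay / tr) - t_rise
  if (t_rise >= tau_decay * 0.99 * log(1e8))
    stop("t_rise too long for the given tau_decay")
  stats::uniroot(f, lower = 1e-6, upper = 1e6, tol = 1e-10)$root
}

#' Generate a synthetic calcium transient
#'
#' @param spec a [ca_waveform_spec()].
#' @param dt sampling interval (ms), must be < BCL.
#' @return `ca_transient` data.frame (`time_ms, Cai_uM`) with `beat_start`
#'   and `bcl` attributes; deterministic under the spec's seed.
#' @export
generate_ca <- function(spec, dt = 0.5) {
  stopifnot(inherits(spec, "ca_waveform_spec"))
  if (dt >= spec$bcl) stop("dt must be smaller than the BCL")
  tau_r <- solve_tau_rise(spec$t_rise, spec$tau_decay)
  shape <- function(t) (1 - exp(-t / tau_r)) * exp(-t / spec$tau_decay)
  peak <- shape(spec$t_rise)
  n_per <- round(spec$bcl / dt)
  t_beat <- seq(0, by = dt, length.out = n_per)
  amps <- ifelse(seq_len(spec$n_beats) %% 2 == 1, spec$ca_amp,
                 spec$ca_amp * spec$alternation_ratio)
  ca <- unlist(lapply(amps, function(a) spec$ca_dia + a * shape(t_beat) / peak))
  ca <- c(ca, spec$ca_dia)  # closing sample at the final beat boundary
  if (spec$noise_sd > 0) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(spec$seed)
    ca <- pmax(ca + stats::rnorm(length(ca), 0, spec$noise_sd), 0)
  }
  out <- data.frame(time_ms = seq(0, by = dt, length.out = length(ca)),
                    Cai_uM = ca)
  attr(out, "beat_start") <- as.integer((seq_len(spec$n_beats) - 1) * n_per + 1)
  attr(out, "bcl") <- spec$bcl
  class(out) <- c("ca_transient", "data.frame")
  out
}
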