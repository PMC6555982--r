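test_that("SR calcium fluxes follow their closed-form expressions", {
  p <- ionic_params("endo")
  s <- ionic_initial_state()

  # zero-gradient leak
  s["CaSR"] <- s["Cai"]
  expect_equal(unname(sr_fluxes(s, p)["I_leak"]), 0)

  # closed release channel
  s <- ionic_initial_state()
  s["Rbar"] <- 0  # open fraction O = k1*Cass^2*Rbar/(k3 + k1*Cass^2) = 0
  expect_equal(unname(sr_fluxes(s, p)["I_rel"]), 0)

  # scalar hand evaluation of the leak at a stated operating point
  s <- ionic_initial_state()
  s["CaSR"] <- 3.0
  s["Cai"] <- 0.0002
  expect_equal(unname(sr_fluxes(s, p)["I_leak"]), 3.6e-4 * 2.9998,
               tolerance = 1e-12)

  # uptake matches the saturating form, and its Cai -> 0 limit is 0
  s["Cai"] <- 0.0005
  expect_equal(unname(sr_fluxes(s, p)["I_up"]),
               p[["Vmaxup"]] / (1 + p[["Kup"]]^2 / 0.0005^2), tolerance = 1e-12)
  s["Cai"] <- 0
  expect_equal(unname(sr_fluxes(s, p)["I_up"]), 0)

  # transfer flux is proportional to the subspace-cytosol gradient
  s <- ionic_initial_state()
  s["CaSS"] <- 0.01
  fl <- sr_fluxes(s, p)
  expect_equal(unname(fl["I_xfer"]),
               p[["Vxfer"]] * (0.01 - s[["Cai"]]), tolerance = 1e-12)
})

test_that("per-current breakdown sums to the total ionic current", {
  p <- ionic_params("mid")
  set.seed(42)
  for (i in 1:20) {
    s <- ionic_initial_state()
    s["V"] <- runif(1, -90, 40)
    s[2:14] <- runif(13)
    s["Cai"] <- runif(1, 1e-5, 1e-3)
    s["CaSR"] <- runif(1, 0.5, 4)
    s["CaSS"] <- runif(1, 1e-5, 1e-2)
    cur <- total_ionic_current(s, p)
    expect_equal(sum(cur$breakdown), cur$total, tolerance = 1e-12)
  }

  # all conductances zero (and exchanger/pump scales) give zero current
  p0 <- p
  p0[c("GNa", "GK1", "Gto", "GKr", "GKs", "GCaL", "knaca", "knak",
       "GpCa", "GpK", "GbCa", "GbNa")] <- 0
  expect_equal(total_ionic_current(ionic_initial_state(), p0)$total, 0)
})

test_that("the resting state is a quasi-equilibrium of the model", {
  p <- ionic_params("endo")
  # let the published resting state settle without stimulation
  quiet <- stimulus_protocol(1000, n_beats = 3, amplitude = 0)
  r <- run_paced("endo", quiet, params = p)
  s <- r$final_state
  expect_lt(abs(total_ionic_current(s, p)$total), 0.1)
  d <- ionic_derivs(s, t = 0, params = p)$dstate
  expect_lt(abs(d[["V"]]), 0.01)          # mV/ms
  expect_lt(abs(d[["Cai"]]), 1e-6)        # mM/ms
})

test_that("gates stay bounded and concentrations positive while pacing", {
  r <- cached_run("endo")
  gates <- r$snapshots[, 2:14]
  expect_true(all(gates >= 0 & gates <= 1))
  concs <- r$snapshots[, c("Cai", "CaSR", "CaSS", "Nai", "Ki")]
  expect_true(all(concs > 0))
  expect_true(all(r$trace$Cai_uM > 0))
  expect_true(all(r$trace$CaSR_mM > 0))
  expect_true(all(r$trace$Cass_mM > 0))
  # subspace/SR gradient at rest
  expect_gt(r$snapshots[1, "CaSR"], r$snapshots[1, "CaSS"])
})

test_that("fixed-step Rush-Larsen and adaptive integration agree on a beat", {
  prot <- stimulus_protocol(1000, n_beats = 1)
  fx <- run_paced("endo", prot, dt_out = 1)
  ad <- run_paced("endo", prot, method = "adaptive", dt_out = 1)
  n <- min(nrow(fx$trace), nrow(ad$trace))
  expect_lt(max(abs(fx$trace$Vm_mV[1:n] - ad$trace$Vm_mV[1:n])), 0.5)
  ca_pk <- max(ad$trace$Cai_uM)
  expect_lt(max(abs(fx$trace$Cai_uM[1:n] - ad$trace$Cai_uM[1:n])), 0.02 * ca_pk)
})

test_that("pacing reaches steady state and preserves transmural APD order", {
  runs <- lapply(c(endo = "endo", mid = "mid", epi = "epi"), cached_run)
  apd30 <- vapply(runs, function(r) beat_apd(r, 30)$apd_ms, 0)
  apd29 <- vapply(runs, function(r) beat_apd(r, 29)$apd_ms, 0)
  # no alternans at BCL 1000: recorded beats agree to 1 ms
  expect_true(all(abs(apd30 - apd29) < 1))
  # mid > epi > endo
  expect_gt(apd30[["mid"]], apd30[["epi"]])
  expect_gt(apd30[["epi"]], apd30[["endo"]])
  # doubling the stimulus count leaves the steady-state APD within 2 ms
  r60 <- cached_run("endo", n_beats = 60)
  expect_lt(abs(beat_apd(r60, 60)$apd_ms - apd30[["endo"]]), 2)
})

test_that("net SR flux closes over a steady-state beat", {
  r <- cached_run("endo")
  p <- ionic_params("endo")
  i <- beat_rows(r, 30)
  tr <- r$trace[i, ]
  cai <- tr$Cai_uM / 1000
  ileak <- p[["Vleak"]] * (tr$CaSR_mM - cai)
  iup <- p[["Vmaxup"]] / (1 + p[["Kup"]]^2 / cai^2)
  irel <- p[["Vrel"]] * tr$O * (tr$CaSR_mM - tr$Cass_mM)
  dt <- diff(tr$time_ms)
  mid <- function(x) (x[-1] + x[-length(x)]) / 2
  net <- sum(mid(iup - ileak - irel) * dt)
  gross <- sum(mid(iup) * dt)
  expect_lt(abs(net), 0.01 * gross)
})

test_that("parameter sets are positive and differ only in the documented way", {
  ps <- lapply(c(endo = "endo", mid = "mid", epi = "epi"), ionic_params)
  for (p in ps)
    expect_true(all(p[c("GNa", "GK1", "Gto", "GKr", "GKs", "GCaL", "Vmaxup",
                        "Vrel", "Vleak", "Vxfer", "Vc", "Vsr", "Vss")] > 0))
  shared <- setdiff(names(ps$endo), c("Gto", "GKs", "s_endo"))
  expect_identical(ps$endo[shared], ps$mid[shared])
  expect_identical(ps$mid[shared], ps$epi[shared])
  expect_identical(attr(ps$endo, "restitution_variant"), "steep_slope_1.8")
  expect_error(ionic_params("endo", overrides = c(5)), "named")
})

test_that("the stimulus enters the voltage equation with the stated sign", {
  p <- ionic_params("endo")
  s <- ionic_initial_state()
  prot <- stimulus_protocol(1000, 1, amplitude = -52, duration = 1)
  d_on <- ionic_derivs(s, t = 0.5, params = p, protocol = prot)$dstate
  d_off <- ionic_derivs(s, t = 5, params = p, protocol = prot)$dstate
  # dV/dt at stimulus onset is -I_stim plus the small resting currents
  expect_equal(d_on[["V"]] - d_off[["V"]], 52, tolerance = 1e-9)
})
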