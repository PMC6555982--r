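mp <- mech_params()

test_that("single-overlap fraction matches the piecewise geometry", {
  # full overlap at optimal length
  expect_equal(single_overlap_fraction(2.3, mp), 1)
  # hand evaluation at the rest length (thick 1.65, thin 1.2, bare 0.1)
  sl <- mp[["SL0"]]
  ze <- min(1.65 / 2, sl / 2)
  cle <- max(sl / 2 - (sl - 1.2), 0.05)
  expect_equal(single_overlap_fraction(sl, mp), 2 * (ze - cle) / 1.55)
  # non-increasing above the optimum, bounded in [0, 1]
  xs <- seq(2.3, mp[["SLmax"]], by = 0.01)
  v <- single_overlap_fraction(xs, mp)
  expect_true(all(diff(v) <= 1e-12))
  v_all <- single_overlap_fraction(seq(mp[["SLmin"]], mp[["SLmax"]], 0.05), mp)
  expect_true(all(v_all >= 0 & v_all <= 1))
  expect_error(single_overlap_fraction(mp[["SLmax"]] + 0.1, mp), "bounds")
})

test_that("active force implements the normalized cross-bridge expression", {
  s <- mech_initial_state(mp)
  # no bound bridges, no force
  expect_equal(active_force(s, mp)$force_norm, 0)

  # normalization identity: post-rotated bridges at reference strain and
  # maximal duty, full overlap -> force exactly 1
  duty <- cardalt:::.mech_duty_fractions(mp)
  s1 <- s
  s1["SL"] <- 2.3
  s1["XB_PostR"] <- duty[["dutyPostR"]]
  s1["N_xb"] <- 1 - duty[["dutyPostR"]]
  s1["P_xb"] <- 0
  s1["XB_PreR"] <- 0
  s1["xXB_PostR"] <- mp[["x0"]]
  expect_equal(active_force(s1, mp)$force_norm, 1, tolerance = 1e-12)
  expect_equal(active_force(s1, mp)$tension_kPa, mp[["force_scale"]],
               tolerance = 1e-12)

  # linear in XB_PostR at fixed strains
  s2 <- s1
  s2["XB_PostR"] <- duty[["dutyPostR"]] / 2
  s2["N_xb"] <- 1 - s2["XB_PostR"]
  s2["P_xb"] <- 0
  expect_equal(active_force(s2, mp)$force_norm, 0.5, tolerance = 1e-12)
})

test_that("ATP rate is the detachment flux through the overlap fraction", {
  s <- mech_initial_state(mp)
  expect_equal(atp_rate(s, mp), 0)
  s["XB_PostR"] <- 0.3
  s["N_xb"] <- 0.7
  s["P_xb"] <- 0
  a1 <- atp_rate(s, mp)
  expect_gt(a1, 0)
  mp2 <- mech_params(c(gxb = 2 * mp[["gxb"]]))
  expect_equal(atp_rate(s, mp2), 2 * a1, tolerance = 1e-12)
})

test_that("occupancy derivatives conserve total state mass", {
  set.seed(7)
  for (i in 1:25) {
    occ <- runif(4); occ <- occ / sum(occ)
    s <- c(occ, runif(1, -0.01, 0.01), runif(1, 0, 0.02), runif(1),
           runif(1, 1.5, 2.3), 0)
    names(s) <- cardalt:::mech_state_names()
    d <- xb_transitions(s, ca_uM = runif(1, 0, 10), mp,
                        dSLdt = runif(1, -0.01, 0.01))
    expect_lt(abs(sum(d[1:4])), 1e-13)
  }
})

test_that("clamped-Ca equilibrium matches the rate-matrix null space", {
  # integrate to equilibrium under saturating Ca at fixed SL
  ca <- data.frame(time_ms = seq(0, 4000, by = 0.5), Cai_uM = 10)
  attr(ca, "bcl") <- NULL
  m <- run_mechanics(ca, load_condition("isometric_clamp"), mp)
  occ <- m$occupancies[nrow(m$occupancies), ]
  s_end <- m$final_state

  # independent algebraic steady state: null space of the transition matrix
  # evaluated at the settled strains/troponin
  r <- xb_rates(s_end, mp)
  A <- matrix(c(-r$knpT, r$kpnT, 0, 0,
                r$knpT, -(r$kpnT + r$fappT), r$gappT, r$gxbT,
                0, r$fappT, -(r$gappT + r$hfT), r$hbT,
                0, 0, r$hfT, -(r$hbT + r$gxbT)),
              4, 4, byrow = TRUE)
  ns <- svd(A)$v[, 4]
  ns <- ns / sum(ns)
  expect_lt(max(abs(unname(occ) - ns)), 1e-6)
  # saturating Ca turns most units permissive
  expect_lt(occ[["N_xb"]], 0.05)
})

test_that("diastolic Ca keeps the sarcomere relaxed", {
  ca <- data.frame(time_ms = seq(0, 3000, by = 0.5), Cai_uM = 0.1)
  m <- run_mechanics(ca, load_condition("isometric_clamp"), mp)
  n <- nrow(m$trace)
  expect_lt(m$occupancies[n, "XB_PostR"], 1e-3)
  expect_lt(m$trace$force_norm[n], 0.01)
  expect_equal(m$trace$eq_length[n], 1)
})

test_that("isosarcometric clamp holds SL at its initial value exactly", {
  ca <- generate_ca(ca_waveform_spec(bcl = 500, n_beats = 2), dt = 0.5)
  m <- run_mechanics(ca, load_condition("isometric_clamp"), mp)
  expect_true(all(m$trace$SL_um == mp[["SL0"]]))
  # sl_dynamics contract: clamp mode returns exactly zero velocity
  expect_identical(sl_dynamics(mech_initial_state(mp),
                               load_condition("isometric_clamp"), mp), 0)
})

test_that("a 1000 kPa afterload is pseudo-isometric", {
  ca <- generate_ca(ca_waveform_spec(bcl = 1000, n_beats = 2))
  m <- run_mechanics(ca, load_condition("isotonic", afterload = 1000), mp)
  expect_lt(max(abs(m$trace$SL_um - mp[["SL0"]])) / mp[["SL0"]], 0.01)
})

test_that("low afterload shortens the sarcomere at least as much as 10 kPa", {
  ca <- generate_ca(ca_waveform_spec(bcl = 1000, n_beats = 3, ca_amp = 1.0))
  m06 <- run_mechanics(ca, load_condition("isotonic", afterload = 0.6), mp)
  m10 <- run_mechanics(ca, load_condition("isotonic", afterload = 10), mp)
  expect_lte(min(m06$trace$eq_length), min(m10$trace$eq_length))
})

test_that("peak tension responds monotonically to the Ca drive", {
  base <- ca_waveform_spec(bcl = 1000, n_beats = 3)
  up <- ca_waveform_spec(bcl = 1000, n_beats = 3, ca_amp = base$ca_amp * 1.2)
  m1 <- run_mechanics(generate_ca(base), load_condition("isometric_clamp"), mp)
  m2 <- run_mechanics(generate_ca(up), load_condition("isometric_clamp"), mp)
  expect_gte(max(m2$trace$tension_kPa), max(m1$trace$tension_kPa))
})

test_that("traces conserve occupancy and keep tension and ATP non-negative", {
  ca <- generate_ca(ca_waveform_spec(bcl = 600, n_beats = 4,
                                     alternation_ratio = 0.7))
  for (ld in list(load_condition("isotonic", afterload = 10),
                  load_condition("isotonic", afterload = 1000),
                  load_condition("isometric_clamp"))) {
    m <- run_mechanics(ca, ld, mp)
    expect_lt(max(abs(m$occupancy_sum - 1)), 1e-9)
    expect_true(all(m$trace$tension_kPa >= 0))
    expect_true(all(m$trace$ATP_norm >= 0))
  }
})

test_that("an alternating Ca drive produces tension alternans in phase", {
  ca <- generate_ca(ca_waveform_spec(bcl = 500, n_beats = 6,
                                     alternation_ratio = 0.7))
  m <- run_mechanics(ca, load_condition("isometric_clamp"), mp)
  pk <- vapply(3:6, function(b) max(m$trace$tension_kPa[beat_rows(m, b)]), 0)
  # odd beats carry the large Ca amplitude -> larger peaks (beats 3, 5)
  expect_gt(pk[1], pk[2])
  expect_gt(pk[3], pk[4])
  # no alternation when the drive does not alternate
  ca1 <- generate_ca(ca_waveform_spec(bcl = 500, n_beats = 6))
  m1 <- run_mechanics(ca1, load_condition("isometric_clamp"), mp)
  pk1 <- vapply(5:6, function(b) max(m1$trace$tension_kPa[beat_rows(m1, b)]), 0)
  expect_lt(abs(pk1[1] - pk1[2]) / pk1[1], 0.02)
})
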