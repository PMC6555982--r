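test_that("APD of a square pulse equals the pulse width", {
  t <- seq(0, 400, by = 0.5)
  vm <- ifelse(t >= 10 & t < 160, 20, -85)
  a <- apd(t, vm, fraction = 0.9)
  expect_true(a$captured)
  expect_equal(a$apd_ms, 150, tolerance = 1)
  # APD50 of the same pulse is the same (instant repolarization)
  expect_equal(apd(t, vm, fraction = 0.5)$apd_ms, 150, tolerance = 1)
})

test_that("a beat without an upstroke is reported as not captured", {
  t <- seq(0, 300, by = 0.5)
  a <- apd(t, rep(-85, length(t)))
  expect_false(a$captured)
  expect_true(is.na(a$apd_ms))
  # small subthreshold deflection (stimulus artifact) is still no capture
  vm <- -85 + 40 * exp(-(t - 5)^2 / 4)
  expect_false(apd(t, vm)$captured)
})

test_that("beat metrics handle degenerate and synthetic waveforms", {
  t <- seq(0, 500, by = 0.5)
  m <- beat_metrics(t, tension_kPa = rep(3, length(t)),
                    ca_uM = rep(0.1, length(t)))
  expect_equal(m$st, m$dt)
  expect_equal(m$ca_max, m$ca_min)
  expect_equal(m$tpt, 0)  # peak-at-first-sample convention

  # sin^2 tension pulse peaking at 100 ms
  tens <- sin(pmin(pmax(t - 50, 0), 100) * pi / 200)^2 * 40
  m2 <- beat_metrics(t, tension_kPa = tens)
  expect_equal(m2$tpt, 150, tolerance = 1)   # 50 ms delay + 100 ms rise
  expect_equal(m2$st, 40, tolerance = 1e-6)

  # equivalent length dip at 120 ms
  eql <- 1 - 0.2 * exp(-(t - 120)^2 / 500)
  m3 <- beat_metrics(t, eq_length = eql)
  expect_equal(m3$tpl, 120, tolerance = 1)
  expect_equal(m3$sl_sys, 0.8, tolerance = 1e-6)
  expect_equal(m3$dl, eql[length(eql)])
})

test_that("alternans detection flags and thresholds behave as specified", {
  mk <- function(apd, camax, st) {
    m <- beat_metrics(seq(0, 300, 0.5), ca_uM = rep(camax, 601),
                      tension_kPa = rep(st, 601))
    m$apd <- apd; m$captured <- TRUE
    m$ca_min <- 0.1; m$dt <- 1
    m
  }
  # identical beats: no flags
  r0 <- detect_alternans(mk(280, 0.7, 20), mk(280, 0.7, 20))
  expect_false(r0$electrical$flag)
  expect_false(r0$ca$flag)
  expect_false(r0$mechanical$flag)
  expect_false(r0$discordant)

  # 50 ms APD split far above threshold
  r1 <- detect_alternans(mk(280, 0.7, 20), mk(230, 0.9, 28))
  expect_true(r1$electrical$flag)
  expect_true(r1$ca$flag)
  expect_true(r1$mechanical$flag)
  # long-APD beat (29) pairs with the small Ca peak -> discordant
  expect_true(r1$discordant)

  # concordant pairing is not discordant
  r2 <- detect_alternans(mk(280, 0.9, 28), mk(230, 0.7, 20))
  expect_true(r2$electrical$flag)
  expect_false(r2$discordant)

  # raising thresholds never turns a false flag true
  ths <- list(alternans_thresholds(),
              alternans_thresholds(apd_ms = 10, ca_rel = 0.1, tension_rel = 0.1),
              alternans_thresholds(apd_ms = 100, ca_rel = 1, tension_rel = 1))
  flags <- lapply(ths, function(th) detect_alternans(mk(280, 0.7, 20),
                                                     mk(275, 0.71, 20.5), th))
  for (i in 2:3) {
    expect_false(isTRUE(flags[[i]]$electrical$flag) &&
                   !isTRUE(flags[[i - 1]]$electrical$flag))
    expect_false(isTRUE(flags[[i]]$mechanical$flag) &&
                   !isTRUE(flags[[i - 1]]$mechanical$flag))
  }

  # a blocked beat yields a block report, no alternans call
  mb <- mk(NA, 0.7, 20); mb$captured <- FALSE
  rb <- detect_alternans(mb, mk(280, 0.7, 20))
  expect_true(rb$block)
  expect_true(is.na(rb$electrical$flag))
})

test_that("restitution slope recovers a linear APD(DI) relation", {
  di <- seq(20, 300, by = 40)
  apd_curve <- 100 + 0.6 * di
  bcl <- di + apd_curve  # so that DI = BCL - APD29 recovers di exactly
  tbl <- data.frame(bcl = bcl, apd29 = apd_curve, apd30 = apd_curve)
  rc <- restitution_curve(tbl)
  expect_equal(rc$table$di, sort(di))
  expect_equal(rc$max_slope, 0.6, tolerance = 1e-9)
  # flat curve has slope 0
  tbl0 <- data.frame(bcl = bcl, apd29 = 250, apd30 = 250)
  expect_equal(restitution_curve(tbl0)$max_slope, 0)
  expect_error(restitution_curve(tbl[1:2, ]), "3")
})

test_that("tension amplitude curve finds the constructed maximum", {
  bcls <- seq(1000, 400, by = -100)
  amp <- -(bcls - 700)^2 / 1e4 + 50
  m <- data.frame(variant = "endo", bcl = rep(bcls, each = 2),
                  load_kPa = 1000, beat = rep(c(29, 30), length(bcls)),
                  st = rep(amp, each = 2) + 5, dt = 5)
  tc <- tension_amplitude_curve(m, load_kPa = 1000)
  expect_equal(tc$argmax_bcl, 700)
  expect_true(all(tc$table$amplitude30 >= 0))
  expect_equal(tc$table$amplitude29, tc$table$amplitude30)
})
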