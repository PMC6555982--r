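# small configurations keep the coupled runs cheap
toy_config <- function(...) {
  sweep_config(cell_variants = "endo", bcl_list = c(340, 310), n_beats = 4,
               record_beats = c(3, 4), loads = c(10, 1000), ...)
}

test_that("beat segmentation is stimulus-aligned", {
  r <- cached_run("endo", bcl = 1000, n_beats = 30)
  expect_length(r$beat_start, 30)
  expect_equal(unique(diff(r$beat_start)), 1000 / r$dt_out)
  expect_equal(r$trace$time_ms[r$beat_start], seq(0, by = 1000, length.out = 30))
})

test_that("a coupled run is one electrical stage feeding each load", {
  cfg <- toy_config()
  res <- run_cell("endo", 340, loads = cfg$loads, config = cfg)
  expect_s3_class(res, "cell_run")
  expect_length(res$mechanical, 2)
  # identical time base across stages
  expect_equal(max(res$electrical$trace$time_ms),
               max(res$mechanical[[1]]$trace$time_ms))
  # metrics: 2 loads x 2 recorded beats
  expect_equal(nrow(res$metrics), 4)
  expect_true(all(res$metrics$st >= res$metrics$dt))
  expect_true(all(res$metrics$ca_max >= res$metrics$ca_min))
})

test_that("run order does not affect per-load or per-BCL results", {
  cfg <- toy_config()
  a <- run_cell("endo", 340, loads = c(10, 1000), config = cfg)
  b <- run_cell("endo", 340, loads = c(1000, 10), config = cfg)
  m_a <- a$metrics[order(a$metrics$load_kPa, a$metrics$beat), ]
  m_b <- b$metrics[order(b$metrics$load_kPa, b$metrics$beat), ]
  rownames(m_a) <- rownames(m_b) <- NULL
  expect_identical(m_a, m_b)
  # rerun is bit-identical (deterministic core)
  c2 <- run_cell("endo", 340, loads = c(10, 1000), config = cfg)
  expect_identical(a$metrics, c2$metrics)
  expect_identical(a$electrical$trace, c2$electrical$trace)
})

test_that("a sweep is the composition of independent cell runs", {
  cfg <- toy_config()
  sw <- run_sweep(cfg)
  expect_s3_class(sw, "sweep_result")
  # 1 variant x 2 BCLs x 2 loads x 2 beats
  expect_equal(nrow(sw$metrics), 8)
  expect_null(sw$failures)
  one <- run_cell("endo", 310, loads = cfg$loads, config = cfg)
  sw_rows <- sw$metrics[sw$metrics$bcl == 310, ]
  rownames(sw_rows) <- rownames(one$metrics) <- NULL
  expect_equal(sw_rows, one$metrics)
  # alternans table has one row per (BCL, load)
  expect_equal(nrow(sw$alternans), 4)
})

test_that("mechanics driven from a saved transient equals the inline run", {
  cfg <- toy_config()
  res <- run_cell("endo", 340, loads = 10, config = cfg)
  f <- tempfile(fileext = ".csv")
  write_trace_csv(res$electrical, f)
  back <- read_trace_csv(f)
  ca <- data.frame(time_ms = back$time_ms, Cai_uM = back$Cai_uM)
  attr(ca, "bcl") <- 340
  m2 <- run_mechanics(ca, load_condition("isotonic", afterload = 10),
                      mech_params(), dt = cfg$mech_dt, dt_out = cfg$mech_dt_out)
  expect_identical(m2$trace, res$mechanical[[1]]$trace)
  unlink(f)
})

test_that("onset refinement brackets and bisects the alternans boundary", {
  # the endocardial boundary sits between 280 and 250 under the default
  # protocol; a coarse grid spanning it must refine into that interval
  o <- refine_alternans_onset("endo", coarse_bcls = c(310, 280, 250),
                              resolution = 4)
  expect_true(!is.na(o$onset_bcl))
  expect_gte(o$onset_bcl, 250)
  expect_lte(o$onset_bcl, 280)
  expect_true(all(c("bcl", "apd29", "apd30", "alternans") %in%
                    names(o$evaluated)))
  # every probed BCL below the onset that was captured alternates
  ev <- o$evaluated[o$evaluated$captured & o$evaluated$bcl > o$onset_bcl, ]
  expect_true(all(!ev$alternans))
})

test_that("sweep configuration validates its fields", {
  expect_error(sweep_config(bcl_list = c(1000, 100)), "150")
  expect_error(sweep_config(record_beats = c(29, 31)))
  expect_error(sweep_config(cell_variants = "outer"))
  cfg <- sweep_config(loads = c(5))
  expect_equal(cfg$loads[[1]]$afterload, 5)
})

test_that("the coupled endocardial beat reproduces the reported peak-tension timing", {
  m <- cached_mech("endo", 1000)
  i <- beat_rows(m, 30)
  tpt <- m$trace$time_ms[i][which.max(m$trace$tension_kPa[i])] -
    m$trace$time_ms[i][1]
  expect_lt(abs(tpt - 228), 10)
})
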