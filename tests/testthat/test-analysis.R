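test_that("distribution report respects its invariants", {
  m2 <- build_model2()
  d <- complex_distribution(m2, lps = 100)
  expect_setequal(
    d$component,
    c("TLR4", "TIRAP", "MyD88", "IRAK1", "IRAK4", "TRAF6")
  )
  expect_true(all(d$pct_myddosome >= 0 & d$pct_independent >= 0))
  expect_true(all(d$pct_myddosome + d$pct_independent <= 100 + 1e-6))
  # the receptor's flux partition covers all engaged receptor
  tlr4 <- d[d$component == "TLR4", ]
  expect_equal(tlr4$pct_myddosome + tlr4$pct_independent, 100)

  d0 <- complex_distribution(m2, lps = 0)
  expect_true(all(d0$pct_myddosome == 0 & d0$pct_independent == 0))
  expect_error(complex_distribution(m2, lps = -1), "lps")
  expect_error(complex_distribution(m2, lps = 10, horizon_h = 0), "horizon")
})

test_that("recruitment accounting is cumulative: shares never shrink with horizon", {
  m2 <- build_model2()
  d5 <- complex_distribution(m2, lps = 50, horizon_h = 5)
  d10 <- complex_distribution(m2, lps = 50, horizon_h = 10)
  expect_true(all(d10$pct_myddosome >= d5$pct_myddosome - 1e-9))
  expect_true(all(d10$pct_independent >= d5$pct_independent - 1e-9))
})

test_that("Myddosome shares grow with LPS and thresholds are read off the scan", {
  m2 <- build_model2()
  scan <- dose_response_scan(m2, lps_grid = 10^seq(0, 4, by = 1))
  for (d in split(scan, scan$component)) {
    d <- d[order(d$lps), ]
    # non-decreasing within the reporting precision of these percentages
    # (1.5 points): past its saturation dose the MyD88 share drifts down by
    # about a point as the independent branch keeps competing
    expect_true(all(d$pct_myddosome >= cummax(d$pct_myddosome) - 1.5))
  }
  th <- dose_thresholds(scan)
  expect_setequal(th$component, unique(scan$component))
  # saturating components reach 95% of max well below the top dose
  expect_lte(th$threshold_lps[th$component == "TIRAP"], 100)

  one <- dose_response_scan(m2, lps_grid = 50)
  expect_identical(unique(one$lps), 50)
  expect_true(all(dose_thresholds(one)$threshold_lps == 50))
  expect_error(dose_response_scan(m2, lps_grid = numeric()), "positive")
})

test_that("stoichiometry ratios are anchored at TIRAP and defined only where TIRAP is bound", {
  m2 <- build_model2()
  r <- stoichiometry_ratios(m2, lps = 500, times = c(30, 60))
  expect_true(all(r$ratio_to_tirap[r$component == "TIRAP"] == 1))
  expect_true(all(r$ratio_to_tirap >= 0))
  # MyD88 is the most super-stoichiometric component at every time
  for (tt in c(30, 60)) {
    rt <- r[r$time_min == tt, ]
    expect_identical(
      rt$component[which.max(rt$ratio_to_tirap)],
      "MyD88"
    )
  }
  # TIRAP never recruited -> ratio undefined
  no_tirap <- set_network_values(m2, rate_constants = c("3" = 0))
  expect_error(
    stoichiometry_ratios(no_tirap, lps = 500, times = 30),
    "undefined"
  )
})

test_that("raising initial TIRAP fills the Myddosome and linearizes MyD88 assembly", {
  m2 <- build_model2()
  ts <- tirap_scan(m2, tirap_grid = 10^seq(1, 4, by = 1))
  expect_true(all(diff(ts$tirap_in_myddosome) > 0))
  expect_true(all(diff(ts$myd88_tirap_ratio) < 0))
  expect_lt(
    cor(ts$tirap_in_myddosome, ts$myd88_tirap_ratio, method = "spearman"),
    0
  )
  one <- tirap_scan(m2, tirap_grid = 100)
  expect_identical(nrow(one), 1L)
  expect_error(tirap_scan(m2, tirap_grid = c(-1, 10)), "positive")
})

test_that("the LPS axis partitions into three contiguous assembly phases", {
  m2 <- build_model2()
  scan <- assembly_scan(m2, lps_grid = 10^seq(0, 4, by = 0.5))
  expect_true(all(diff(scan$tirap_in_myddosome) > 0))
  expect_true(all(diff(scan$myd88_tirap_ratio) < 0))
  expect_lt(
    cor(scan$tirap_in_myddosome, scan$myd88_tirap_ratio,
      method = "spearman"
    ), 0
  )
  ph <- classify_phases(scan)
  expect_setequal(ph$phase, c("I", "II", "III"))
  # contiguous, ordered intervals along the LPS axis
  ord <- ph[match(c("I", "II", "III"), ph$phase), ]
  expect_true(ord$lps_max[1] < ord$lps_min[2])
  expect_true(ord$lps_max[2] < ord$lps_min[3])
  expect_identical(sum(ph$n_points), nrow(scan))
  # long chains under weak stimulation, short chains under strong
  expect_gt(ord$mean_ratio[1], ord$mean_ratio[3])

  flat <- scan
  flat$tirap_in_myddosome <- 1
  expect_error(classify_phases(flat), "constant")
  wiggly <- scan
  wiggly$tirap_in_myddosome <- rev(wiggly$tirap_in_myddosome)
  expect_error(classify_phases(wiggly), "monotone")
  expect_error(classify_phases(scan[scan$lps <= 100, ]), "three decades")
})
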