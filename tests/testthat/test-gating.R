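test_that("control-tube thresholds follow the chosen quantile", {
  dmso <- manual_tube(hx103 = 1:100, egfr_ab = 1:100)
  panel <- manual_panel(dmso)
  th <- derive_thresholds(panel, gate_config(control_quantile = 1.0))
  expect_equal(th$hx103_cut, 100)
  th2 <- derive_thresholds(panel, gate_config(control_quantile = 0.999))
  expect_equal(th2$hx103_cut, unname(quantile(1:100, 0.999)))  # 99.901
  # counts recorded along the derivation chain never increase
  expect_lte(th$n_events_after_cd45, th$n_events_after_scatter)
})

test_that("missing or thin control tubes are rejected", {
  dmso <- manual_tube(hx103 = 1:200)
  empty <- dmso[0, ]
  expect_error(derive_thresholds(manual_panel(empty, isotype = dmso)),
               "missing control tube")
  thin <- manual_tube(hx103 = 1:50)
  expect_error(derive_thresholds(manual_panel(thin)), "too few gated control")
})

test_that("quadrants partition events with ties going negative", {
  th <- structure(list(hx103_cut = 10, egfr_cut = 20, cd45_cut = 300,
                       n_events_after_scatter = 4, n_events_after_cd45 = 4),
                  class = "gate_thresholds")
  ev <- manual_tube(hx103 = c(5, 15, 15, 5), egfr_ab = c(25, 25, 5, 5))
  g <- apply_gates(ev, th)
  expect_equal(as.character(g$quadrant), c("Q1", "Q2", "Q3", "Q4"))

  # all events below both cuts: 100% Q4
  low <- manual_tube(hx103 = rep(1, 10), egfr_ab = rep(1, 10))
  expect_true(all(apply_gates(low, th)$quadrant == "Q4"))

  # equality with the cut is the negative side (strict positivity)
  tie <- manual_tube(hx103 = c(10, 10.0001), egfr_ab = c(20, 20.0001))
  expect_equal(as.character(apply_gates(tie, th)$quadrant), c("Q4", "Q2"))
})

test_that("empty gates raise errors naming the failing stage", {
  th <- structure(list(hx103_cut = 10, egfr_cut = 20, cd45_cut = 300,
                       n_events_after_scatter = 1, n_events_after_cd45 = 1),
                  class = "gate_thresholds")
  debris <- manual_tube(hx103 = 1:5, fsc = rep(10, 5), ssc = rep(10, 5))
  expect_error(apply_gates(debris, th), "scatter")
  leuk <- manual_tube(hx103 = 1:5, cd45 = rep(1e4, 5))
  expect_error(apply_gates(leuk, th), "CD45")
  expect_error(apply_gates(manual_tube(numeric(0)), th), "empty event table")
})

test_that("gate chain counts are monotone and quadrants close to 100%", {
  panel <- preset_panel("mutant_high", seed = 4, n_events = 5000)
  res <- quantify(panel)
  for (counts in res$gate_counts) {
    expect_true(all(diff(counts) <= 0))
  }
  for (tube in rownames(res$raw)) {
    gated <- apply_gates(panel$tubes[[tube]], res$thresholds)
    expect_equal(sum(table(gated$quadrant)) / nrow(gated) * 100, 100)
  }
  # raw double-positive never exceeds either marginal parameter
  expect_lte(res$raw["stained", "double_pos"], res$raw["stained", "egfr_pos"])
  expect_lte(res$raw["stained", "double_pos"], res$raw["stained", "hx103_pos"])
})

test_that("background correction is a plain subtraction and can go negative", {
  # with a sub-maximal control quantile the DMSO tube has its own positives
  dmso <- manual_tube(hx103 = c(rep(1, 180), rep(50, 20)),
                      egfr_ab = rep(1, 200))
  stained <- manual_tube(hx103 = c(rep(1, 186), rep(60, 14)),
                         egfr_ab = rep(1, 200))
  panel <- manual_panel(dmso, stained = stained)
  cfg <- gate_config(control_quantile = 0.9)
  res <- quantify(panel, cfg)
  raw_dmso <- res$raw["dmso_control", "hx103_pos"]
  raw_st <- res$raw["stained", "hx103_pos"]
  expect_gt(raw_dmso, 0)
  expect_equal(res$corrected[["hx103_pos"]], raw_st - raw_dmso)
  expect_lt(res$corrected[["hx103_pos"]], 0)  # 7% stained vs 10% control

  # stained identical to DMSO: every corrected parameter is exactly zero
  same <- quantify(manual_panel(dmso, stained = dmso), cfg)
  expect_equal(unname(same$corrected), c(0, 0, 0))
})

test_that("quantify is idempotent and flags non-evaluable blocking ratios", {
  panel <- preset_panel("mutant_high", seed = 6, n_events = 3000)
  r1 <- quantify(panel)
  r2 <- quantify(panel)
  expect_identical(as.data.frame(r1), as.data.frame(r2))

  # stained MFI at (below) the DMSO level: ratio undefined, not an error
  dmso <- manual_tube(hx103 = rep(c(10, 20), 100))
  stained <- manual_tube(hx103 = rep(c(5, 10), 100))
  res <- quantify(manual_panel(dmso, stained = stained, blocked = stained))
  expect_true(is.na(res$blocking_ratio))
  expect_true(is.na(res$specificity_pass))
})

test_that("gefitinib competition lowers double-positive labeling in every panel", {
  for (seed in 1:3) {
    panel <- preset_panel("mutant_high", seed = seed, n_events = 4000)
    res <- quantify(panel)
    corrected_blocked <- res$raw["gefitinib_blocked", "double_pos"] -
      res$raw["dmso_control", "double_pos"]
    expect_lt(corrected_blocked, res$corrected[["double_pos"]])
    expect_true(res$specificity_pass)
  }
})

test_that("the CD45 cut can be derived from a CD45-low reference quantile", {
  dmso <- manual_tube(hx103 = 1:200, cd45 = seq(0, 199))
  panel <- manual_panel(dmso)
  th <- derive_thresholds(panel, gate_config(cd45_cut = NULL,
                                             cd45_quantile = 0.5))
  expect_equal(th$cd45_cut, unname(quantile(seq(0, 199), 0.5)))
})
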