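test_that("identical seeds and specs reproduce panels bit-for-bit", {
  pops <- tumor_mixture_populations(0.7)
  p1 <- simulate_panel(pops, n_events = 500, seed = 99)
  p2 <- simulate_panel(pops, n_events = 500, seed = 99)
  expect_identical(p1$tubes, p2$tubes)
  p3 <- simulate_panel(pops, n_events = 500, seed = 100)
  expect_false(identical(p1$tubes$stained, p3$tubes$stained))
})

test_that("simulation leaves the caller's RNG stream untouched", {
  set.seed(123); before <- .Random.seed
  invisible(simulate_panel(tumor_mixture_populations(0.5), 200, seed = 1))
  expect_identical(.Random.seed, before)
})

test_that("malformed population specs are rejected", {
  bad <- list(pop_tumor_active(0.5), pop_debris(0.2))  # sums to 0.7
  expect_error(simulate_panel(bad, 500, seed = 1), "sum to 1")
  expect_error(simulate_panel(tumor_mixture_populations(0.5), 99, seed = 1),
               "at least 100")
  expect_error(population_spec("x", 0.5, 1, -1, 1, 1, 0, 4, 0.3, 0.5),
               ">= 0")
  expect_error(population_spec("x", 0.5, 1, 1, 1, 1, 0, 4, 0.3, 1.5),
               "active_fraction")
  expect_error(preset_panel("no_such_archetype", seed = 1), "unknown archetype")
})

test_that("every tube carries the designed signal structure", {
  panel <- simulate_panel(tumor_mixture_populations(1), n_events = 5000, seed = 5)
  tumor <- lapply(panel$tubes, function(tb) tb[tb$truth_active == 1, ])

  # DMSO tube: probe channel is autofluorescence only (mean near the floor)
  fl <- fluorophore_model()
  expect_lt(abs(mean(tumor$dmso_control$hx103) - fl$autofluorescence_mean), 5)
  # stained tube lights up far above it; blocked tube sits in between
  expect_gt(mean(tumor$stained$hx103), 10 * fl$autofluorescence_mean)
  expect_gt(mean(tumor$stained$hx103), mean(tumor$gefitinib_blocked$hx103))
  expect_gt(mean(tumor$gefitinib_blocked$hx103), mean(tumor$dmso_control$hx103))

  # isotype tube: antibody channel is background only
  expect_lt(mean(tumor$isotype_control$egfr_ab), 80)
  expect_gt(mean(tumor$stained$egfr_ab), 200)

  # all channels finite and non-negative
  for (tb in panel$tubes) {
    m <- as.matrix(tb[, c("fsc", "ssc", "cd45", "egfr_ab", "hx103")])
    expect_true(all(is.finite(m)) && all(m >= 0))
  }
})

test_that("a leukocyte-only suspension is almost entirely CD45-excluded", {
  panel <- simulate_panel(pop_leukocyte(1.0), n_events = 5000, seed = 8)
  cfg <- gate_config()
  ev <- panel$tubes$stained
  surv <- ev[ev$fsc >= cfg$fsc_min & ev$ssc >= cfg$ssc_min &
               ev$cd45 <= cfg$cd45_cut, ]
  expect_lt(nrow(surv) / nrow(ev), 0.01)
})

test_that("corrected double-positive tracks the simulated active-tumor share", {
  # mutant-dominant: 85% tumour, all of it active (share 1 of tumour cells)
  panel <- simulate_panel(tumor_mixture_populations(1), n_events = 2e4, seed = 1)
  res <- quantify(panel)
  gated <- apply_gates(panel$tubes$stained, res$thresholds)
  truth_share <- 100 * mean(gated$truth_active)
  expect_lt(abs(res$corrected[["double_pos"]] - truth_share), 5)
})

test_that("archetype presets land where their tissue of origin does", {
  q_mut <- quantify(preset_panel("mutant_high", seed = 2, n_events = 1e4))
  expect_gte(q_mut$corrected[["double_pos"]], 80)
  expect_gte(q_mut$blocking_ratio, 0.8)

  q_norm <- quantify(preset_panel("adjacent_normal", seed = 2, n_events = 1e4))
  expect_lte(q_norm$corrected[["double_pos"]], 13)
  expect_lte(q_norm$corrected[["hx103_pos"]], 13)

  q_wt <- quantify(preset_panel("wt_normal", seed = 2, n_events = 1e4))
  expect_true(all(q_wt$corrected <= 15))
})

test_that("panels round-trip through CSV + manifest unchanged", {
  dir <- withr::local_tempdir()
  panel <- preset_panel("wt_overexpressing", seed = 3, n_events = 300)
  write_panel(panel, dir)
  back <- read_panel(dir)
  expect_identical(back$specimen_id, panel$specimen_id)
  expect_identical(back$n_events, panel$n_events)
  for (tube in names(panel$tubes)) {
    expect_equal(back$tubes[[tube]]$hx103, panel$tubes[[tube]]$hx103,
                 tolerance = 1e-12)
    expect_identical(back$tubes[[tube]]$truth_population,
                     panel$tubes[[tube]]$truth_population)
  }
  expect_error(read_panel(file.path(dir, "nope")), "manifest")
})
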