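test_that("a degenerate configuration yields the hand-computed record", {
  cfg <- degenerate_config(baseline_hb = 12)
  p <- create_patient(1, cfg)
  rec <- run_patient(p, cfg)

  abt <- rec$outcomes$ABT
  expect_equal(abt$postop_hb, 8.7, tolerance = 1e-3)
  expect_false(abt$transfused)      # 8.7 >= trigger 8.5
  expect_equal(abt$los, 10)
  expect_equal(abt$total_cost, 3000)

  pad <- rec$outcomes$PAD
  expect_true(pad$pad_applicable)
  expect_equal(pad$preop_hb_adjusted, 10.8, tolerance = 1e-3)
  expect_equal(pad$postop_hb, 7.5, tolerance = 1e-3)
  expect_equal(pad$units_needed, 1L)
  expect_equal(pad$autologous_units, 1L)
  expect_equal(pad$allogeneic_units, 0L)
  expect_equal(pad$los, 12)
  expect_equal(pad$total_cost, 500 + 12 * 300)
  expect_gte(pad$final_hb, pad$effective_trigger)

  epo <- rec$outcomes$EPO
  expect_equal(epo$epo_doses_given, 2L)
  expect_equal(epo$preop_hb_adjusted, 14, tolerance = 1e-3)
  expect_false(epo$transfused)
  expect_equal(epo$total_cost, 2 * 200 + 3000)

  expect_identical(run_patient(p, cfg)$outcomes, rec$outcomes)
})

test_that("simulation runs are reproducible and clone-consistent", {
  cfg <- default_config(n_patients = 400, seed = 3)
  r1 <- run_simulation(cfg)
  r2 <- run_simulation(cfg)
  expect_identical(r1$patients, r2$patients)
  expect_identical(r1$outcomes, r2$outcomes)
  expect_equal(nrow(r1$patients), 400)
  expect_equal(nrow(r1$outcomes), 1200)

  # clone integrity: per-patient quantities driven by the shared profile
  # are identical across arms
  by_arm <- split(r1$outcomes, r1$outcomes$arm)
  for (arm in c("PAD", "EPO")) {
    o <- by_arm[[arm]][order(by_arm[[arm]]$patient_id), ]
    a <- by_arm$ABT[order(by_arm$ABT$patient_id), ]
    expect_identical(o$patient_id, a$patient_id)
    expect_identical(o$effective_trigger, a$effective_trigger)
  }
  # EPO dominance under cloning: preop Hb never below baseline, so demand
  # never exceeds the ABT arm's
  epo <- by_arm$EPO[order(by_arm$EPO$patient_id), ]
  abt <- by_arm$ABT[order(by_arm$ABT$patient_id), ]
  expect_true(all(epo$units_needed <= abt$units_needed))
})

test_that("band stratification is half-open with PAD suppressed below 11", {
  cfg <- degenerate_config(baseline_hb = 11.2, n_patients = 30, seed = 4)
  run <- run_simulation(cfg)
  s <- summary(run)
  df <- as.data.frame(s)
  counts <- unique(df[, c("band_lo", "n")])
  expect_equal(counts$n[counts$band_lo == 11.0], 30)
  expect_equal(sum(counts$n), 30)

  # exact boundary lands in the band whose lower edge it equals
  run2 <- run_simulation(degenerate_config(baseline_hb = 11.0,
                                           n_patients = 5, seed = 4))
  run2$patients$baseline_hb <- 11.0
  df2 <- as.data.frame(stratify_and_summarize(run2))
  c2 <- unique(df2[, c("band_lo", "n")])
  expect_equal(c2$n[c2$band_lo == 11.0], 5)
  expect_equal(c2$n[c2$band_lo == 10.5], 0)

  # PAD cells are missing markers below 11 g/dl
  low <- degenerate_config(baseline_hb = 10.2, n_patients = 20, seed = 4)
  dfl <- as.data.frame(summary(run_simulation(low)))
  pad_low <- dfl[dfl$group == "PAD" & dfl$band_lo == 10.0, ]
  expect_true(all(is.na(pad_low$mean)))
  inc_low <- dfl[dfl$group == "incremental" &
                 dfl$stat == "PAD_minus_EPO_total" & dfl$band_lo == 10.0, ]
  expect_true(all(is.na(inc_low$mean)))
  abt_low <- dfl[dfl$group == "ABT" & dfl$band_lo == 10.0, ]
  expect_false(any(is.na(abt_low$mean)))
})

test_that("summary SEs are SD/sqrt(n) and the overall band is available", {
  run <- run_simulation(default_config(n_patients = 600, seed = 5))
  df <- as.data.frame(stratify_and_summarize(run, include_overall = TRUE))
  filled <- df[!is.na(df$sd) & df$denom > 1, ]
  expect_true(all(abs(filled$se - filled$sd / sqrt(filled$denom)) < 1e-8))
  overall <- df[!is.finite(df$band_lo), ]
  expect_equal(unique(overall$n), 600)
})

test_that("reports round-trip through JSON and preserve missing cells", {
  run <- run_simulation(degenerate_config(baseline_hb = 11.2,
                                          n_patients = 25, seed = 6))
  s <- summary(run)
  d <- withr::local_tempdir()
  write_report(s, d)
  expect_true(file.exists(file.path(d, "base.csv")))
  back <- read_report(d)[["base"]]
  expect_equal(as.data.frame(back), as.data.frame(s), tolerance = 1e-12)
  expect_equal(attr(back, "scenario"), "base")
  # empty bands stay missing, not zero, in the arm and incremental cells
  empty_cells <- back$n == 0 & back$group != "baseline"
  expect_true(any(empty_cells))
  expect_true(all(is.na(back$mean[empty_cells])))
})

test_that("identical configurations produce byte-identical report files", {
  cfg <- default_config(n_patients = 300, seed = 8)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_report(summary(run_simulation(cfg)), d1)
  write_report(summary(run_simulation(cfg)), d2)
  expect_identical(readLines(file.path(d1, "report.json")),
                   readLines(file.path(d2, "report.json")))
  expect_identical(readLines(file.path(d1, "base.csv")),
                   readLines(file.path(d2, "base.csv")))
})

test_that("the scenario grid shares characteristics and responds as expected", {
  base <- default_config(n_patients = 1500, seed = 10)
  sc <- build_scenarios(base)
  grid <- run_scenario_grid(base, scenarios = sc[c("base", "trigger_9.0",
                                                   "cost_epo_up",
                                                   "zero_correlation")])
  gb <- as.data.frame(grid$base)
  g9 <- as.data.frame(grid$trigger_9.0)

  # a more liberal trigger never lowers per-band transfusion rates
  for (arm in c("ABT", "EPO")) {
    b <- gb$mean[gb$group == arm & gb$stat == "transfused_pct"]
    l <- g9$mean[g9$group == arm & g9$stat == "transfused_pct"]
    ok <- !is.na(b) & !is.na(l)
    expect_true(all(l[ok] >= b[ok]))
  }

  # a dearer EPO dose shrinks the savings of EPO in every band
  ge <- as.data.frame(grid$cost_epo_up)
  for (st in c("ABT_minus_EPO_total", "PAD_minus_EPO_total")) {
    b <- gb$mean[gb$group == "incremental" & gb$stat == st]
    u <- ge$mean[ge$group == "incremental" & ge$stat == st]
    ok <- !is.na(b) & !is.na(u)
    expect_true(all(u[ok] < b[ok]))
  }

  # zero correlation makes blood loss independent of the revision flag
  cfg0 <- apply_scenario(base, sc$zero_correlation)
  r0 <- run_simulation(cfg0)
  loss_rev <- r0$patients$blood_loss_hb[r0$patients$revision]
  loss_pri <- r0$patients$blood_loss_hb[!r0$patients$revision]
  expect_lt(abs(mean(loss_rev) - mean(loss_pri)), 0.25)

  # the revision-only subset restricts summaries to revision patients
  grid_rev <- run_scenario_grid(base, scenarios = sc["revision_only"])
  expect_equal(attr(grid_rev$revision_only, "n_total"),
               sum(run_simulation(apply_scenario(base,
                                                 sc$revision_only))$patients$revision))
})
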