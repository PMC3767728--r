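test_that("cell sampling follows table frequencies", {
  one <- degenerate_population()
  for (i in 1:5) expect_equal(sample_procedure_cell(one)$row_id, "cell1")

  two <- rbind(one, one)
  two$row_id <- c("a", "b")
  two$frequency <- c(0.7, 0.3)
  class(two) <- c("bloodsim_population", "data.frame")
  set.seed(401)
  draws <- replicate(1e5, sample_procedure_cell(two)$row_id)
  expect_equal(mean(draws == "a"), 0.7, tolerance = 0.01)
  # chi-square goodness of fit not rejected at alpha = 0.001
  expect_gt(chisq.test(table(draws), p = c(0.7, 0.3))$p.value, 0.001)
  # identical sequence under the same seed
  set.seed(401)
  expect_identical(replicate(1e5, sample_procedure_cell(two)$row_id), draws)

  expect_error(sample_procedure_cell(two[0, ]), "empty")
})

test_that("age is integer-uniform within its band", {
  expect_equal(sample_age_within_band(70, 70), 70)
  expect_error(sample_age_within_band(74, 65), "inverted")
  set.seed(402)
  ages <- replicate(1e5, sample_age_within_band(65, 74))
  expect_true(all(ages %in% 65:74))
  expect_true(all(abs(table(ages) / 1e5 - 0.1) < 0.01))
})

test_that("weight draws are normal with a floor", {
  expect_equal(sample_weight(80, 0), 80)
  set.seed(403)
  w <- replicate(1e4, sample_weight(75, 12))
  expect_equal(mean(w), 75, tolerance = 0.5)
  expect_true(all(replicate(200, sample_weight(30, 1)) >= 35))
})

test_that("estimated blood volume is the weight multiple", {
  expect_equal(estimated_blood_volume(70), 4550)
  expect_equal(estimated_blood_volume(100), 6500)
  expect_equal(estimated_blood_volume(80, 70), 5600)
  expect_error(estimated_blood_volume(0), "> 0")
  # linear and homogeneous in weight
  w <- c(50, 65, 90)
  expect_equal(estimated_blood_volume(2 * w), 2 * estimated_blood_volume(w))
  expect_equal(estimated_blood_volume(w[1] + w[2]),
               estimated_blood_volume(w[1]) + estimated_blood_volume(w[2]))
})

test_that("baseline Hb follows the configured Weibull", {
  cfg <- default_config()
  # concentration: huge shape collapses onto the scale
  cfg2 <- cfg
  cfg2$hb_weibull_female <- list(shape = 200, scale = 13, location = 0)
  set.seed(404)
  x <- sample_baseline_hb("female", cfg2, n = 1e4)
  expect_equal(mean(x), 13, tolerance = 0.02)
  expect_gt(mean(abs(x - 13) < 0.2), 0.9)
  # closed-form mean lambda * Gamma(1 + 1/k)
  set.seed(405)
  k <- cfg$hb_weibull_male$shape; lam <- cfg$hb_weibull_male$scale
  y <- sample_baseline_hb("male", cfg, n = 1e5)
  expect_equal(mean(y), lam * gamma(1 + 1 / k), tolerance = 0.01)
  expect_true(all(y >= 6 & y <= 18))
  set.seed(406)
  a <- sample_baseline_hb("female", cfg)
  set.seed(406)
  expect_identical(sample_baseline_hb("female", cfg), a)
  cfg$hb_weibull_female$shape <- -1
  expect_error(sample_baseline_hb("female", cfg), "Weibull")
})

test_that("comorbidity flags are Bernoulli at the configured risks", {
  cl <- default_config()$clinical
  cell0 <- degenerate_population()
  cl0 <- cl
  cl0$rheumatoid_risk_hip <- 0; cl0$cardiac_history_prob <- 0
  expect_equal(unname(assign_comorbidities(cell0[1, ], cl0)), rep(FALSE, 4))

  cell <- degenerate_population(revision_probability = 0.104,
                                asa_ge3_probability = 0.4)
  set.seed(407)
  draws <- t(replicate(2e4, assign_comorbidities(cell[1, ], cl)))
  expect_equal(mean(draws[, "cardiac_history"]), 0.15, tolerance = 0.05)
  expect_equal(mean(draws[, "revision"]), 0.104, tolerance = 0.05)
  expect_equal(mean(draws[, "asa_ge3"]), 0.40, tolerance = 0.03)
  expect_equal(mean(draws[, "rheumatoid"]), cl$rheumatoid_risk_hip,
               tolerance = 0.2)
})

test_that("blood-loss modifiers compose multiplicatively", {
  cl <- default_config()$clinical
  cl$blood_loss_sd <- 0
  expect_equal(sample_blood_loss("hip", 60, FALSE, FALSE, cl), 3.3)
  expect_equal(sample_blood_loss("knee", 60, FALSE, TRUE, cl), 3.5 * 1.25)
  # composed modifiers match the direct product
  expect_equal(sample_blood_loss("hip", 80, TRUE, TRUE, cl),
               3.3 * 1.05 * 1.05 * 1.25)
  # removing any flag never increases expected loss
  full <- sample_blood_loss("hip", 80, TRUE, TRUE, cl)
  expect_lte(sample_blood_loss("hip", 80, FALSE, TRUE, cl), full)
  expect_lte(sample_blood_loss("hip", 60, TRUE, TRUE, cl), full)
  expect_lte(sample_blood_loss("hip", 80, TRUE, FALSE, cl), full)
  # zero-correlation settings make loss independent of all flags
  cl0 <- cl
  cl0$asa_loss_factor <- 1; cl0$age_loss_factor <- 1
  cl0$revision_loss_factor <- 1
  expect_equal(sample_blood_loss("hip", 80, TRUE, TRUE, cl0),
               sample_blood_loss("hip", 60, FALSE, FALSE, cl0))
})

test_that("create_patient is deterministic and fully degenerate when asked", {
  cfg <- degenerate_config(baseline_hb = 12)
  p <- create_patient(1, cfg)
  expect_equal(p$procedure, "hip")
  expect_equal(p$age, 70)
  expect_equal(p$weight, 80)
  expect_equal(p$ebv, 5200)
  expect_equal(p$baseline_hb, 12, tolerance = 1e-3)
  expect_false(p$revision || p$asa_ge3 || p$rheumatoid || p$cardiac_history)
  expect_equal(p$blood_loss_hb, 3.3, tolerance = 1e-12)
  expect_identical(create_patient(1, cfg), p)
  expect_false(identical(create_patient(2, cfg)$baseline_hb, NULL))

  cfg2 <- default_config(seed = 5)
  q1 <- create_patient(17, cfg2)
  q2 <- create_patient(17, cfg2)
  expect_identical(q1, q2)
})

test_that("the synthetic fixture table is schema-valid with the intended mix", {
  pop <- generate_fixture_population()
  expect_no_error(validate_population(pop))
  expect_equal(sum(pop$frequency), 1)
  expect_equal(sum(pop$frequency[pop$procedure == "hip"]), 0.575)
  expect_equal(sum(pop$frequency[pop$sex == "female"]), 0.65)

  two <- generate_fixture_population(hip_share = 0.5, female_share = 0.5,
                                     age_bands = rbind(c(70, 70)),
                                     age_weights = 1)
  expect_equal(nrow(two), 4)
  expect_equal(sum(two$frequency), 1)

  set.seed(408)
  j1 <- generate_fixture_population(frequency_jitter_sd = 0.2)
  set.seed(408)
  j2 <- generate_fixture_population(frequency_jitter_sd = 0.2)
  expect_identical(j1, j2)
  expect_no_error(validate_population(j1))

  # CSV round trip
  f <- withr::local_tempfile(fileext = ".csv")
  write_population(pop, f)
  expect_equal(as.data.frame(read_population(f)), as.data.frame(pop),
               tolerance = 1e-12)
})

test_that("a simulated cohort reproduces the procedure mix", {
  run <- run_simulation(default_config(seed = 2), n_patients = 3000)
  hip <- mean(run$patients$procedure == "hip")
  expect_gt(hip, 0.54)
  expect_lt(hip, 0.61)
  # sampling frequencies converge to table frequencies (chi-square GoF)
  pop <- generate_fixture_population()
  key <- paste(pop$procedure, pop$sex, pop$age_lo)
  drawn <- table(factor(paste(run$patients$procedure, run$patients$sex,
                              findInterval(run$patients$age,
                                           sort(unique(pop$age_lo))) * 10 + 35),
                        levels = sort(unique(paste(pop$procedure, pop$sex,
                                                   pop$age_lo)))))
  expect_gt(chisq.test(as.vector(drawn),
                       p = pop$frequency[order(key)])$p.value, 0.001)
})
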