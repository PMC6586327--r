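test_that("generation is deterministic under a fixed seed and varies across seeds", {
  des <- study_designs(analyzable = TRUE)$choice_2d
  a <- simulate_experiment(generator_config(des, seed = 5))
  b <- simulate_experiment(generator_config(des, seed = 5))
  expect_identical(a, b)
  c_ <- simulate_experiment(generator_config(des, seed = 6))
  expect_false(identical(a, c_))
})

test_that("noise-free choice colonies hit the intake target exactly", {
  des <- study_designs(analyzable = TRUE)$choice_2d
  sim <- simulate_experiment(noise_free_config(des))
  sums <- summarize_intake(sim, diets_2d_standard())
  expect_equal(sums$protein_consumed, rep(20, 22), tolerance = 1e-9)
  expect_equal(sums$carb_consumed, rep(30, 22), tolerance = 1e-9)
  # nothing hoarded or scattered: consumed equals harvested
  expect_equal(sums$consumed_dry, sums$harvested_dry, tolerance = 1e-9)
  expect_true(all(sums$final_workers == 200))
})

test_that("choice mixing solves the two-diet system for the target draw", {
  # target (20, 30) split between 1:6 and 3:1 rails; verify the per-diet
  # harvests against the 2x2 linear system solved by hand substitution
  d <- diets_2d_standard()
  des <- experiment_design("choice_2d", list(list(d[["1:6"]], d[["3:1"]])),
                           replicates = 3)
  sim <- simulate_experiment(noise_free_config(des))
  s <- summarize_colony(sim[[1]], d)
  per <- s$per_diet
  m16 <- per$harvested_dry[per$diet_label == "1:6"]
  m31 <- per$harvested_dry[per$diet_label == "3:1"]
  expect_equal(m16 * 1 / 7 + m31 * 3 / 4, 20, tolerance = 1e-9)
  expect_equal(m16 * 6 / 7 + m31 * 1 / 4, 30, tolerance = 1e-9)
})

test_that("targets outside the cone of the two rails are rejected", {
  d <- diets_2d_standard()
  des <- experiment_design("choice_2d", list(list(d[["1:6"]], d[["3:1"]])),
                           replicates = 1)
  cfg <- noise_free_config(des, target = c(50, 1))
  expect_error(simulate_experiment(cfg), "infeasible target")
})

test_that("no-choice colonies follow the configured rule of compromise", {
  des <- study_designs()$nochoice_2d
  # equal distance, zero noise: identical total intake on every rail
  sim <- simulate_experiment(noise_free_config(des, rule = "equal_distance"))
  sums <- summarize_intake(sim, diets_2d_standard())
  totals <- sums$protein_consumed + sums$carb_consumed
  expect_equal(totals, rep(50, 40), tolerance = 1e-9)
  # closest distance, zero noise: 1:1 rail holds the projection (25, 25)
  simc <- simulate_experiment(noise_free_config(des, rule = "closest_distance"))
  sc <- summarize_intake(simc, diets_2d_standard())
  on11 <- sc[sc$treatment == "1:1", ]
  expect_equal(on11$protein_consumed, rep(25, 8), tolerance = 1e-9)
  expect_equal(on11$carb_consumed, rep(25, 8), tolerance = 1e-9)
  # zero hazard keeps every colony at full strength
  expect_true(all(sums$final_workers == 200))
})

test_that("3-D consumption follows the configured surface and mortality its hazard", {
  des <- study_designs()$nochoice_3d
  # intercept-only surface, no noise: equal consumption on all 7 diets
  cfg <- noise_free_config(des)
  cfg$surface_coeffs <- c(b0 = 40, bP = 0, bC = 0, bPP = 0, bCC = 0, bPC = 0)
  cfg$noise_sd <- 0
  sim <- simulate_rmt_experiment(cfg)
  sums <- summarize_intake(sim, diets_3d_standard())
  expect_equal(sums$consumed_dry, rep(40, 35), tolerance = 1e-9)

  # Monte-Carlo death rate matches the logistic hazard within 3 SE
  d3 <- diets_3d_standard()
  des2 <- experiment_design("nochoice_3d", d3["80:10:10"], replicates = 300,
                            n_workers = 200, n_days = 7)
  hz <- function(diet) stats::plogis(-4 + 0.01 * diet$p_frac - 0.01 * diet$c_frac)
  cfg2 <- generator_config(des2, death_hazard_fn = hz, bin_effect_sd = 0,
                           noise_sd = 0, seed = 99)
  cfg2$surface_coeffs <- c(b0 = 40, bP = 0, bC = 0, bPP = 0, bCC = 0, bPC = 0)
  sim2 <- simulate_rmt_experiment(cfg2)
  q <- hz(d3[["80:10:10"]])
  # survival after 7 days is (1 - q)^7 per worker
  surv <- vapply(sim2, `[[`, numeric(1), "final_workers") / 200
  p_surv <- (1 - q)^7
  se <- sqrt(p_surv * (1 - p_surv) / (300 * 200))
  expect_lt(abs(mean(surv) - p_surv), 3 * se)
})

test_that("mass balance holds by construction on noisy simulations", {
  cfg <- generator_config(study_designs()$nochoice_3d, seed = 31)
  sim <- suppressWarnings(simulate_experiment(cfg))
  sums <- summarize_intake(sim, diets_3d_standard())
  expect_equal(sums$consumed_dry,
               sums$harvested_dry - sums$hoarded_dry - sums$scattered_dry,
               tolerance = 1e-12)
  expect_true(all(sums$hoarded_dry + sums$scattered_dry <=
                    sums$harvested_dry + 1e-9))
})

test_that("fixtures round-trip losslessly and match the design arithmetic", {
  tmp <- withr::local_tempdir()
  cfg <- generator_config(study_designs()$nochoice_3d, seed = 13)
  sim <- suppressWarnings(simulate_experiment(cfg))
  write_fixture(sim, tmp, diets_3d_standard(), cfg)
  expect_true(file.exists(file.path(tmp, "truth.yaml")))
  back <- read_fixture(tmp)
  expect_equal(length(back$experiments), 35)
  # 35 colonies x 14 days, one cube per day
  expect_equal(sum(vapply(back$experiments, function(e) nrow(e$records),
                          numeric(1))), 490)
  for (i in c(1, 18, 35)) {
    expect_equal(back$experiments[[i]]$records, sim[[i]]$records,
                 tolerance = 1e-12)
    expect_equal(back$experiments[[i]]$hoarded_by_diet,
                 sim[[i]]$hoarded_by_diet, tolerance = 1e-12)
    expect_equal(back$experiments[[i]]$final_workers, sim[[i]]$final_workers)
  }
  truth <- yaml::read_yaml(file.path(tmp, "truth.yaml"))
  expect_equal(truth$hoard_frac, 0.10)

  # empty experiment list gives header-only files
  tmp2 <- withr::local_tempdir()
  write_fixture(list(), tmp2, diets_3d_standard())
  expect_equal(nrow(utils::read.csv(file.path(tmp2, "colony_days.csv"))), 0)
  expect_error(read_fixture(file.path(tmp2, "nowhere")), "not found")
})
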