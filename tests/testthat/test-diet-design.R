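test_that("2-D diets split the total concentration by ratio parts", {
  d <- diet_2d(1, 1, 100)
  expect_equal(c(d$p_conc, d$c_conc), c(50, 50))
  d <- diet_2d(1, 6, 100)
  expect_equal(d$p_conc, 100 / 7, tolerance = 1e-9)
  expect_equal(d$c_conc, 600 / 7, tolerance = 1e-9)
  m <- diet_2d(6, 1, 100)
  expect_equal(c(m$p_conc, m$c_conc), c(d$c_conc, d$p_conc))
  # concentration bookkeeping and ratio preservation
  for (parts in list(c(1, 6), c(1, 3), c(2, 5), c(7, 2))) {
    d <- diet_2d(parts[1], parts[2], 100)
    expect_equal(d$p_conc + d$c_conc, 100, tolerance = 1e-9)
    expect_equal(d$p_conc / d$c_conc, parts[1] / parts[2], tolerance = 1e-9)
  }
  expect_error(diet_2d(0, 0), "invalid ratio")
  expect_error(diet_2d(-1, 2), "nonnegative")
  expect_error(diet_2d(1, 1, total_conc = 0), "positive")
})

test_that("3-D diets partition total energy and apply the 2:1 lipid density", {
  d <- diet_3d(10, 10, 80, 675)
  expect_equal(unname(d$energy_per_nutrient), c(67.5, 67.5, 540))
  thirds <- diet_3d(100 / 3, 100 / 3, 100 / 3, 675)
  expect_equal(unname(thirds$energy_per_nutrient), rep(225, 3))
  corner <- diet_3d(100, 0, 0, 675)
  expect_equal(unname(corner$energy_per_nutrient), c(675, 0, 0))
  for (d in diets_3d_standard()) {
    expect_equal(d$p_frac + d$c_frac + d$l_frac, 100, tolerance = 1e-9)
    expect_equal(sum(d$energy_per_nutrient), d$total_energy, tolerance = 1e-9)
    # lipid carries twice the energy per mg
    expect_equal(d$mass_per_nutrient[["L"]] * 2 * d$energy_density,
                 d$energy_per_nutrient[["L"]], tolerance = 1e-9)
    expect_equal(d$mass_per_nutrient[["P"]] * d$energy_density,
                 d$energy_per_nutrient[["P"]], tolerance = 1e-9)
  }
  expect_error(diet_3d(40, 40, 10), "composition error")
  expect_error(diet_3d(-10, 60, 50), "nonnegative")
})

test_that("RMT coordinates place lipid on negative-slope isoclines and invert", {
  co <- rmt_coordinates(diet_3d(10, 10, 80))
  expect_equal(c(co$x, co$y, co$isocline_sum), c(10, 10, 20))
  expect_equal(unlist(rmt_coordinates(diet_3d(0, 0, 100))[c("x", "y")]),
               c(x = 0, y = 0))
  co <- rmt_coordinates(diet_3d(45, 45, 10))
  expect_equal(co$isocline_sum, 90)
  # invertibility: (x, y, 100 - x - y) recovers the composition
  for (d in diets_3d_standard()) {
    co <- rmt_coordinates(d)
    expect_equal(c(co$x, co$y, 100 - co$x - co$y),
                 c(d$p_frac, d$c_frac, d$l_frac), tolerance = 1e-9)
  }
})

test_that("nutritional rails are unit rays preserving the diet ratio", {
  r <- nutritional_rail(1, 1)
  expect_equal(unname(r$direction), rep(1 / sqrt(2), 2), tolerance = 1e-9)
  r <- nutritional_rail(1, 6)
  expect_equal(unname(r$direction), c(1, 6) / sqrt(37), tolerance = 1e-9)
  expect_error(nutritional_rail(0, 0), "invalid ratio")
  # any on-rail point has the diet's P:C ratio exactly
  for (parts in list(c(1, 6), c(3, 1), c(2, 7))) {
    r <- nutritional_rail(parts[1], parts[2])
    expect_equal(sqrt(sum(r$direction^2)), 1, tolerance = 1e-12)
    for (t in c(0.5, 3, 41)) {
      pt <- t * r$direction
      expect_equal(pt[1] / pt[2], parts[1] / parts[2], tolerance = 1e-12)
    }
  }
})

test_that("study designs reproduce the assembled and analyzable colony counts", {
  ds <- study_designs()
  expect_equal(n_colonies(ds$choice_2d), 24)
  expect_equal(n_colonies(ds$nochoice_2d), 40)
  expect_equal(n_colonies(ds$nochoice_3d), 35)
  expect_equal(ds$nochoice_3d$n_days, 14)
  expect_equal(ds$nochoice_3d$n_queens, 4)
  expect_equal(length(ds$nochoice_2d$treatments), 5)
  expect_equal(length(ds$nochoice_3d$treatments), 7)
  # dropping one colony per choice pairing leaves 22 analyzable
  expect_equal(n_colonies(study_designs(analyzable = TRUE)$choice_2d), 22)
  # choice treatments must pair distinct diets
  d <- diets_2d_standard()
  expect_error(
    experiment_design("choice_2d", list(list(d[["1:1"]], d[["1:1"]])), 2),
    "distinct")
})

test_that("diet recipe tables round-trip through delimited text", {
  tmp <- withr::local_tempdir()
  f2 <- file.path(tmp, "d2.csv")
  write_diets(diets_2d_standard(), f2)
  back <- read_diets(f2)
  expect_equal(names(back), names(diets_2d_standard()))
  expect_equal(back[["1:6"]]$p_conc, 100 / 7, tolerance = 1e-9)
  f3 <- file.path(tmp, "d3.csv")
  write_diets(diets_3d_standard(), f3)
  back3 <- read_diets(f3)
  expect_equal(back3[["10:10:80"]]$energy_per_nutrient,
               diets_3d_standard()[["10:10:80"]]$energy_per_nutrient,
               tolerance = 1e-9)
})
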