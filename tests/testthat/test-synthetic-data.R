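test_that("assembly preset reproduces the salt-dependence structure", {
  salts <- seq(20, 1000, by = 20)
  fr <- sapply(salts, function(s) scenario_abundances(s)$fractions)
  # normalization and the absent pentamer, everywhere
  expect_equal(colSums(fr), rep(1, length(salts)), tolerance = 1e-12)
  expect_true(all(fr["5", ] == 0))
  # hexamer dominant above 200 mM, above 70 percent past 700 mM
  above200 <- salts > 200
  expect_true(all(fr["6", above200] == apply(fr[, above200], 2, max)))
  expect_true(all(fr["6", salts > 700] > 0.70))
  # small-oligomer fractions decay monotonically with salt
  for (ord in c("1", "2", "3", "4"))
    expect_true(all(diff(fr[ord, ]) <= 1e-12))
  # low salt favours the small oligomers over the hexamer
  low <- scenario_abundances(20)$fractions
  expect_gt(low[["2"]], low[["6"]])
  expect_error(scenario_abundances(10), "salt")
  expect_error(scenario_abundances(300, preset = "nope"))
})

test_that("a single noiseless component renders as one Gaussian with the configured area", {
  sp <- data.frame(order = 6, mass = 92370, ccs = 4740)
  sc <- scenario_abundances(1000)
  sc$fractions[] <- 0
  sc$fractions["6"] <- 1
  cfg <- spectrum_config(mz_range = c(5000, 6500), mz_step = 1,
                         drift_range = c(1, 8), drift_step = 0.02,
                         adduct_lambda = 0, max_adducts = 0,
                         charge_spread = 0.1,  # single charge state
                         noise_sd = 0, total_intensity = 1000, seed = 1)
  ds <- simulate_dataset(sc, sp, cfg)
  expect_true(all(ds$intensity >= 0))
  cell <- (ds$mz[2] - ds$mz[1]) * (ds$drift[2] - ds$drift[1])
  expect_equal(sum(ds$intensity) * cell, 1000, tolerance = 0.005 * 1000)
  # dominant component sits at the predicted (m/z, drift) center
  main <- ds$ground_truth[which.max(ds$ground_truth$area), ]
  peak <- which(ds$intensity == max(ds$intensity), arr.ind = TRUE)
  expect_equal(ds$mz[peak[2]], main$mz, tolerance = 1)
  expect_equal(ds$drift[peak[1]], main$drift, tolerance = 0.02)
  # each isolated rendered component of non-negligible weight
  # integrates to its ground-truth area
  for (i in which(ds$ground_truth$area > 1e-6 * 1000)) {
    tr <- ds$ground_truth[i, ]
    win_d <- abs(ds$drift - tr$drift) <= 6 * cfg$drift_sigma
    win_m <- abs(ds$mz - tr$mz) <= 6 * cfg$mz_sigma
    expect_equal(sum(ds$intensity[win_d, win_m]) * cell, tr$area,
                 tolerance = 0.005 * tr$area)
  }
})

test_that("simulated datasets are seed-deterministic and conserve ground truth", {
  sc <- scenario_abundances(300)
  cfg <- spectrum_config(noise_sd = 0.002, seed = 9)
  d1 <- simulate_dataset(sc, config = cfg)
  d2 <- simulate_dataset(sc, config = cfg)
  expect_identical(d1$intensity, d2$intensity)
  expect_identical(d1$ground_truth, d2$ground_truth)
  d3 <- simulate_dataset(sc, config = spectrum_config(noise_sd = 0.002, seed = 10))
  expect_false(identical(d1$intensity, d3$intensity))
  # per-species injected areas sum to the total intensity
  expect_equal(sum(d1$ground_truth$area), cfg$total_intensity,
               tolerance = 1e-6 * cfg$total_intensity)
  # fractions of injected area match the scenario
  per_order <- tapply(d1$ground_truth$area, d1$ground_truth$order, sum)
  fr <- sc$fractions[sc$fractions > 0]
  expect_equal(as.numeric(per_order[names(fr)] / sum(per_order)),
               as.numeric(fr), tolerance = 1e-9)
})

test_that("degenerate simulation inputs are rejected", {
  sc <- scenario_abundances(300)
  no_ccs <- default_species_table()
  no_ccs$ccs[no_ccs$order == 6] <- NA
  expect_error(simulate_dataset(sc, no_ccs), "lacking a true CCS")
  empty <- sc
  empty$fractions[] <- 0
  expect_error(simulate_dataset(empty), "non-zero fraction")
  expect_error(simulate_calibrants(-1, 0.5), "A > 0")
})

test_that("dataset round-trips through the CSV + JSON sidecar container", {
  sc <- scenario_abundances(200)
  ds <- simulate_dataset(sc, config = spectrum_config(
    mz_range = c(2000, 7000), mz_step = 4, drift_range = c(1, 25),
    drift_step = 0.2, noise_sd = 0.001, seed = 4))
  dir <- tempfile()
  write_imms_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "intensity.csv")))
  expect_true(file.exists(file.path(dir, "metadata.json")))
  back <- read_imms_dataset(dir)
  expect_equal(back$mz, ds$mz)
  expect_equal(back$drift, ds$drift)
  expect_equal(back$intensity, ds$intensity, tolerance = 1e-6)
  expect_equal(back$ground_truth$area, ds$ground_truth$area, tolerance = 1e-9)
  expect_equal(back$calibration_truth$A, ds$calibration_truth$A)
  expect_equal(back$config$seed, 4)
})

test_that("surrogate strand set reproduces the design mass regime", {
  masses <- vapply(surrogate_strands(), strand_mass, 0)
  expect_length(masses, 6)
  expect_true(all(abs(masses - 15400) < 60))
  tab <- default_species_table()
  expect_equal(tab$mass[tab$order == 6], sum(masses))
  expect_equal(tab$ccs[tab$order == 1], 4457)
  expect_equal(tab$ccs[tab$order == 6], 4740)
  expect_equal(tab$ccs[tab$order == 12], 7545)
  expect_equal(tab$ccs[tab$order == 18], 9578)
})
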