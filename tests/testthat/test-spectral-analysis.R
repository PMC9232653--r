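# Small handmade grids go through the same imms_dataset structure the
# simulator emits.
make_grid_dataset <- function(mz, drift, intensity) {
  structure(list(mz = mz, drift = drift, intensity = intensity,
                 ground_truth = NULL, calibration_truth = NULL,
                 scenario = NULL,
                 config = spectrum_config(seed = 1)),
            class = "imms_dataset")
}

test_that("peak picking finds isolated Gaussians and integrates their area", {
  mz <- seq(1000, 1400, by = 1)
  dt <- seq(1, 10, by = 0.05)
  sig <- 500 * (dnorm(dt, 5, 0.2) %o% dnorm(mz, 1200, 4))
  pk <- pick_peaks(make_grid_dataset(mz, dt, sig))
  expect_equal(nrow(pk), 1)
  expect_equal(pk$mz, 1200, tolerance = 1)
  expect_equal(pk$drift, 5, tolerance = 0.05)
  expect_equal(pk$area, 500, tolerance = 0.01 * 500)
  # two Gaussians 10 sigma apart resolve into two peaks
  sig2 <- sig + 300 * (dnorm(dt, 5, 0.2) %o% dnorm(mz, 1240, 4))
  pk2 <- pick_peaks(make_grid_dataset(mz, dt, sig2))
  expect_equal(nrow(pk2), 2)
  # all-zero input gives an empty list, not an error
  expect_equal(nrow(pick_peaks(make_grid_dataset(mz, dt, sig * 0))), 0)
})

test_that("picked maxima match a brute-force local-maximum scan at SNR 20", {
  sc <- scenario_abundances(300)
  cfg <- spectrum_config(mz_range = c(2000, 7000), mz_step = 2,
                         drift_range = c(1, 25), drift_step = 0.1,
                         noise_sd = 15, seed = 31)
  ds <- simulate_dataset(sc, config = cfg)
  pk <- pick_peaks(ds)
  # oracle: exhaustive scan for 8-neighbourhood maxima over the same
  # threshold, greedily merged with the same radius
  int <- ds$intensity
  thr <- 8 * median(int[int > 0]) / 0.6745
  maxima <- list()
  for (i in 2:(nrow(int) - 1)) for (j in 2:(ncol(int) - 1)) {
    nb <- int[(i - 1):(i + 1), (j - 1):(j + 1)]
    if (int[i, j] >= thr && int[i, j] == max(nb))
      maxima[[length(maxima) + 1]] <- c(ds$drift[i], ds$mz[j], int[i, j])
  }
  om <- do.call(rbind, maxima)
  om <- om[order(-om[, 3]), , drop = FALSE]
  keep <- rep(TRUE, nrow(om))
  for (i in seq_len(nrow(om))) {
    if (!keep[i]) next
    later <- which(keep & seq_len(nrow(om)) > i)
    d2 <- ((om[later, 2] - om[i, 2]) / 12)^2 + ((om[later, 1] - om[i, 1]) / 0.4)^2
    keep[later[d2 < 1]] <- FALSE
  }
  oracle <- om[keep, , drop = FALSE]
  oracle <- oracle[order(oracle[, 2], oracle[, 1]), , drop = FALSE]
  got <- as.matrix(pk[order(pk$mz, pk$drift), c("drift", "mz", "height")])
  expect_equal(nrow(got), nrow(oracle))
  expect_equal(unname(got), unname(oracle), tolerance = 1e-9)
})

test_that("charge series deconvolve neutral masses to 0.01 percent at zero noise", {
  sp <- data.frame(order = 6, mass = 91000, ccs = 4740)
  sc <- scenario_abundances(1000)
  sc$fractions[] <- 0; sc$fractions["6"] <- 1
  cfg <- spectrum_config(mz_range = c(4500, 7000), mz_step = 1,
                         drift_range = c(1, 10), drift_step = 0.02,
                         adduct_lambda = 0, max_adducts = 0,
                         noise_sd = 0, seed = 2)
  ds <- simulate_dataset(sc, sp, cfg)
  pk <- pick_peaks(ds)
  sr <- detect_series(pk)
  real <- Filter(function(s) !s$ambiguous, sr)
  expect_length(real, 1)
  expect_equal(real[[1]]$neutral_mass, 91000, tolerance = 1e-4 * 91000)
  expect_equal(range(real[[1]]$members$z), c(14, 18))
  # deconvolution consistency: the deconvolved M re-predicts every
  # member m/z within the grid pitch
  for (k in seq_len(nrow(real[[1]]$members))) {
    m <- real[[1]]$members[k, ]
    expect_equal(mz_of(real[[1]]$neutral_mass, z = m$z), m$mz, tolerance = 1.5)
  }
  # an isolated peak becomes a flagged singleton
  lone <- pick_peaks(data.frame(mz = 5000, drift = 4, area = 10))
  s1 <- detect_series(lone)
  expect_length(s1, 1)
  expect_true(s1[[1]]$ambiguous)
})

test_that("interleaved series overlapping in m/z are separated by mobility", {
  # monomer z5 and dimer z10 fall within ~1 sigma in m/z by mass
  # doubling, but drift tells them apart
  sc <- scenario_abundances(100)
  ds <- simulate_dataset(sc, config = spectrum_config(noise_sd = 0, seed = 6))
  pk <- pick_peaks(ds)
  sr <- detect_series(pk)
  asg <- assign_species(sr, default_species_table())
  expect_true(all(c(1, 2) %in% asg$order))
  s_mono <- sr[[asg$series[asg$order == 1][1]]]
  s_di <- sr[[asg$series[asg$order == 2][1]]]
  # both series contain a member at essentially the same m/z
  overlap_m <- outer(s_mono$members$mz, s_di$members$mz,
                     function(a, b) abs(a - b))
  expect_lt(min(overlap_m), 8)
  # and those members are far apart in drift
  idx <- which(overlap_m == min(overlap_m), arr.ind = TRUE)[1, ]
  expect_gt(abs(s_mono$members$drift[idx[1]] - s_di$members$drift[idx[2]]), 2)
})

test_that("stoichiometry assignment reports ties instead of resolving them", {
  map <- connectivity_map()
  masses <- vapply(surrogate_strands(), strand_mass, 0)
  tab <- species_table(map, masses)
  # a deconvolved mass between the trimer variants matches several
  # compositions of order 3: full candidate set, one order
  fake <- list(structure(list(
    members = data.frame(idx = 1, z = 11, mz = mz_of(mean(tab$mass[tab$order == 3]), z = 11),
                         drift = 7, area = 100),
    neutral_mass = mean(tab$mass[tab$order == 3]), mass_sd = 0,
    polarity = "positive", ambiguous = FALSE), class = "charge_series"))
  asg <- assign_species(fake, tab, mass_tol = 60)
  expect_equal(asg$order, 3)
  expect_gte(asg$n_candidates, 2)
  # masses matching two different orders give a multi-assignment
  ambig <- tab[tab$order %in% c(1, 2), ]
  ambig$mass <- c(rep(20000, sum(tab$order == 1)), rep(20010, sum(tab$order == 2)))
  fake2 <- fake
  fake2[[1]]$neutral_mass <- 20005
  asg2 <- assign_species(fake2, ambig, mass_tol = 20)
  expect_true(is.na(asg2$order))
  expect_equal(asg2$n_orders, 2)
  expect_true(asg2$matched)
  # far-off masses stay unassigned but retained
  fake3 <- fake
  fake3[[1]]$neutral_mass <- 1e6
  asg3 <- assign_species(fake3, tab)
  expect_false(asg3$matched)
  expect_equal(nrow(asg3), 1)
})

test_that("abundances normalize to 100 and recover the injected fractions", {
  sc <- scenario_abundances(20)
  ds <- simulate_dataset(sc, config = spectrum_config(noise_sd = 0.002, seed = 12))
  pk <- pick_peaks(ds)
  sr <- detect_series(pk)
  asg <- assign_species(sr, default_species_table())
  ab <- quantify_abundances(asg, sr)
  expect_equal(sum(ab$table$percent), 100, tolerance = 1e-6)
  truth <- 100 * sc$fractions / sum(sc$fractions)
  for (k in ab$table$order) {
    expect_lt(abs(ab$table$percent[ab$table$order == k] -
                    truth[[as.character(k)]]), 5)
  }
  # per-charge contributions add up to each order's total
  for (k in ab$table$order) {
    expect_equal(sum(ab$by_charge$area[ab$by_charge$order == k]),
                 ab$table$area[ab$table$order == k], tolerance = 1e-9)
  }
  # a single assigned species is 100 percent by construction
  one <- asg[asg$order == 6, , drop = FALSE]
  ab1 <- quantify_abundances(one, sr)
  expect_equal(ab1$table$percent, 100)
})

test_that("species within 1 sigma in m/z but 4 sigma apart in drift quantify within 5 percent", {
  sp <- data.frame(order = c(2, 3), mass = c(30000, 45000), ccs = c(4600, 6200))
  # dimer z12 and trimer z18 land at m/z 2501.0 within a hundredth of a
  # Thomson of each other (3:2 mass and charge ratio), coincident in m/z
  sc <- scenario_abundances(300)
  sc$fractions[] <- 0
  sc$fractions["2"] <- 0.4; sc$fractions["3"] <- 0.6
  cfg <- spectrum_config(mz_range = c(1500, 5000), mz_step = 1,
                         drift_range = c(1, 20), drift_step = 0.02,
                         adduct_lambda = 0, max_adducts = 0,
                         noise_sd = 0, seed = 8)
  ds <- simulate_dataset(sc, sp, cfg)
  pk <- pick_peaks(ds)
  sr <- detect_series(pk)
  asg <- assign_species(sr, sp)
  ab <- quantify_abundances(asg, sr)
  expect_equal(ab$table$percent[ab$table$order == 2], 40, tolerance = 5)
  expect_equal(ab$table$percent[ab$table$order == 3], 60, tolerance = 5)
})

test_that("abundance recovery stays within 3 points MAE across 20 seeded runs", {
  errs <- c()
  for (seed in 1:20) {
    salt <- c(20, 100, 300, 700, 1000)[(seed %% 5) + 1]
    sc <- scenario_abundances(salt)
    ds <- simulate_dataset(sc, config = spectrum_config(
      mz_range = c(1500, 11000), mz_step = 2, drift_range = c(0.5, 30),
      drift_step = 0.1, noise_sd = 10, seed = seed))
    pk <- pick_peaks(ds)
    sr <- detect_series(pk)
    asg <- assign_species(sr, default_species_table())
    ab <- quantify_abundances(asg, sr)
    truth <- 100 * sc$fractions / sum(sc$fractions)
    for (k in names(truth)) {
      got <- ab$table$percent[ab$table$order == as.numeric(k)]
      if (length(got) == 0) got <- 0
      errs <- c(errs, abs(got - truth[[k]]))
    }
  }
  expect_lt(mean(errs), 3)
})

test_that("peak list CSV round trip preserves rows and order", {
  df <- data.frame(mz = c(3000, 1500, 2000), drift = c(3, 9, 6),
                   area = c(5, 10, 2))
  pk <- pick_peaks(df, min_separation = c(mz = 1, drift = 0.1))
  f <- tempfile(fileext = ".csv")
  write_peaklist(pk, f)
  back <- read_peaklist(f)
  expect_equal(back$mz, sort(df$mz))
  expect_s3_class(back, "peak_list")
})
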