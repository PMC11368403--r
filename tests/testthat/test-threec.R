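test_that("standard curves recover closed-form dilution series", {
  cal <- data.frame(relative_concentration = c(1, 0.1, 0.01),
                    ct = c(20, 23.3219, 26.6439))
  sc <- fit_standard_curve(cal)
  expect_equal(sc$slope, -3.3219, tolerance = 1e-3)
  expect_equal(sc$efficiency, 2, tolerance = 1e-3)
  cal2 <- data.frame(relative_concentration = c(1, 0.5, 0.25),
                     ct = c(20, 21, 22))    # one cycle per twofold dilution
  expect_equal(fit_standard_curve(cal2)$efficiency, 2, tolerance = 1e-9)
})

test_that("standard-curve fitting rejects unusable calibration data", {
  expect_error(fit_standard_curve(
    data.frame(relative_concentration = c(1, 0.1), ct = c(20, 23))),
    ">= 3")
  expect_error(fit_standard_curve(
    data.frame(relative_concentration = rep(1, 4), ct = c(20, 20, 21, 21))),
    "single concentration")
  expect_error(fit_standard_curve(
    data.frame(relative_concentration = c(1, 0.1, 0.01), ct = c(26, 23, 20))),
    "inverted dilution series")
})

test_that("quantify inverts the curve at its landmark points", {
  sc <- structure(list(locus_id = "x", intercept = 20, slope = -3.3219,
                       efficiency = 2, r_squared = 1),
                  class = "standard_curve")
  expect_equal(quantify(20, sc), 1)
  expect_equal(quantify(20 + 3.3219, sc), 0.1, tolerance = 1e-6)
  expect_equal(quantify(19, sc), 2, tolerance = 1e-3)
})

test_that("noiseless simulated Ct tables invert to the planted truth", {
  planted <- c(a = 1.0, b = 0.25, c = 0.05)
  tab <- simulate_3c(planted, efficiency = 1.9, ct_noise_sd = 0, seed = 1)
  prof <- interaction_frequency(tab)
  got <- stats::setNames(prof$profile$mean_if, prof$profile$locus_id)
  expect_equal(got[names(planted)], planted, tolerance = 1e-6)
  for (cv in prof$curves)
    expect_equal(cv$efficiency, 1.9, tolerance = 1e-6)
  # a flat planted profile comes back flat
  flat <- simulate_3c(c(a = 0.2, b = 0.2, c = 0.2), ct_noise_sd = 0,
                      seed = 2)
  pf <- interaction_frequency(flat)$profile
  expect_equal(pf$mean_if, rep(0.2, 3), tolerance = 1e-6)
  # doubling the planted frequencies doubles the recovered ones
  dbl <- simulate_3c(planted * 2, ct_noise_sd = 0, seed = 1)
  got2 <- interaction_frequency(dbl)$profile
  expect_equal(stats::setNames(got2$mean_if, got2$locus_id)[names(planted)],
               planted * 2, tolerance = 1e-6)
})

test_that("calibration spacing is one cycle for twofold dilutions at efficiency 2", {
  tab <- simulate_3c(c(a = 0.5), efficiency = 2, ct_noise_sd = 0,
                     dilution_steps = 4, dilution_factor = 2, seed = 3)
  cal <- tab$calibration[tab$calibration$locus_id == "a", ]
  expect_equal(diff(cal$ct), rep(1, 3), tolerance = 1e-9)
})

test_that("a global Ct shift within a replicate cancels through the bait", {
  planted <- c(a = 0.8, b = 0.1)
  tab <- simulate_3c(planted, efficiency = 1.9, ct_noise_sd = 0, seed = 4)
  base <- interaction_frequency(tab)$profile
  shifted <- tab
  one_rep <- shifted$samples$replicate == 2
  shifted$samples$ct[one_rep] <- shifted$samples$ct[one_rep] + 1.7
  got <- interaction_frequency(shifted)$profile
  expect_equal(got$mean_if, base$mean_if, tolerance = 1e-9)
})

test_that("missing bait replicates are dropped with a warning, all-missing errors", {
  tab <- simulate_3c(c(a = 0.5, b = 0.1), ct_noise_sd = 0, seed = 5)
  drop_one <- tab
  drop_one$samples <- drop_one$samples[
    !(drop_one$samples$locus_id == "bait" & drop_one$samples$replicate == 3), ]
  w <- testthat::capture_warnings(prof <- interaction_frequency(drop_one))
  expect_match(w, "without a bait", all = TRUE)
  expect_true(all(prof$profile$n_replicates == 2))
  drop_all <- tab
  drop_all$samples$sample_id[drop_all$samples$locus_id == "bait"] <- "other"
  expect_error(suppressWarnings(interaction_frequency(drop_all)),
               "no replicate")
})

test_that("ct_table validation catches structural problems", {
  s <- data.frame(locus_id = "a", sample_id = "s", replicate = 1, ct = 25)
  cal <- data.frame(locus_id = "a", relative_concentration = c(1, 0.1, 0.01),
                    ct = c(20, 23, 26))
  expect_error(ct_table(s, cal[1:2, ], "a"), "calibration points")
  expect_error(ct_table(s, cal, "bait"), "no sample records")
  s_bad <- s; s_bad$ct <- -1
  expect_error(ct_table(s_bad, cal, "a"), "positive")
  # TSV round trip
  tab <- simulate_3c(c(a = 0.5, b = 0.1), ct_noise_sd = 0.1, seed = 6)
  sp <- withr::local_tempfile(fileext = ".tsv")
  cp <- withr::local_tempfile(fileext = ".tsv")
  write_ct_table(tab, sp, cp)
  back <- read_ct_table(sp, cp, "bait")
  expect_equal(back$samples$ct, tab$samples$ct, tolerance = 1e-9)
  expect_equal(back$calibration, tab$calibration, tolerance = 1e-9)
})
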