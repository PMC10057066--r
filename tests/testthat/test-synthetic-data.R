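test_that("water trace records the true rate constant and asymptote", {
  tr <- generateWaterTrace(noiselessPreset(), 5, 500, seed = 1)
  expect_equal(tr$meta$k_w, 1.418, tolerance = 5e-4)
  expect_equal(tr$meta$v_inf, 0.8)   # 1.4 / 1.75
  expect_equal(tr$meta$P_f, 3.002e-3)
  # scatter mapping: signal starts at s0 and rises to s0 + s1 (1 - v_inf)
  expect_equal(tr$signal[1], 0.2, tolerance = 1e-9)
  expect_equal(tail(tr$signal, 1), 0.2 + 0.2, tolerance = 1e-3)
})

test_that("vanishing water permeability leaves the signal at the isotonic baseline", {
  pr <- noiselessPreset(P_f = 1e-10)
  tr <- generateWaterTrace(pr, 5, 100, seed = 1)
  expect_true(all(abs(tr$signal - tr$signal[1]) < 1e-6))
})

test_that("glycerol cascade is biphasic with full recovery", {
  pr <- noiselessPreset()
  k_g <- linearizedRate(pr$P_gly, pr$geometry, kind = "glycerol")
  tr <- generateGlycerolTrace(pr, 15 / k_g, 2000, seed = 1)
  v <- 1 - (tr$signal - 0.2)  # invert the scatter mapping
  expect_equal(v[1], 1)
  expect_equal(tail(v, 1), 1, tolerance = 1e-3)
  imin <- which.min(v)
  expect_gt(imin, 1)
  expect_lt(imin, length(v))
  # single interior minimum: decreasing before, increasing after
  expect_true(all(diff(v[1:imin]) < 0))
  expect_true(all(diff(v[imin:length(v)]) > 0))
  expect_equal(tr$meta$k_g, 0.0681, tolerance = 5e-3)
})

test_that("empty-vector preset reswells far slower than the hAQP3 preset", {
  pr_slow <- noiselessPreset(P_gly = 0.162e-6)
  tr <- generateGlycerolTrace(pr_slow, 100, 100, seed = 1)
  expect_equal(tr$meta$k_g, 0.00243, tolerance = 5e-3)
  expect_equal(tr$meta$k_g * 28, noiselessPreset()$P_gly / 6.67e-5,
               tolerance = 2e-3)
})

test_that("trace generation is deterministic in the seed", {
  pr <- noiselessPreset(noise_sd = 0.02)
  a <- generateWaterTrace(pr, 5, 200, seed = 11)
  b <- generateWaterTrace(pr, 5, 200, seed = 11)
  c <- generateWaterTrace(pr, 5, 200, seed = 12)
  expect_identical(a$signal, b$signal)
  expect_false(identical(a$signal, c$signal))
  # global RNG state is untouched
  set.seed(99); before <- .Random.seed
  generateWaterTrace(pr, 5, 200, seed = 11)
  expect_identical(before, .Random.seed)
})

test_that("shock sanity checks reject non-hyperosmotic or degenerate setups", {
  pr <- noiselessPreset()
  pr$shock_water <- shockConditions(1.75, 1.4)
  expect_error(generateWaterTrace(pr, 5, 100, seed = 1), "hyperosmotic")
  fast_gly <- noiselessPreset(P_f = 1e-6, P_gly = 1e-3)
  expect_error(generateGlycerolTrace(fast_gly, 5, 100, seed = 1),
               "faster")
  expect_error(generateGlycerolTrace(noiselessPreset(P_gly = 0), 5, 100,
                                     seed = 1), "P_gly")
})

test_that("dose-response sets scale the permeability by the Hill factor", {
  pr <- noiselessPreset(inhibition = list(
    P_gly = list(IC50 = 6.7, HillSlope = 3.5)))
  at_ic50 <- treatedPreset(pr, 6.7)
  expect_equal(at_ic50$P_gly / pr$P_gly, 0.5, tolerance = 1e-12)
  at_25 <- treatedPreset(pr, 25)
  expect_equal(1 - at_25$P_gly / pr$P_gly, 0.990, tolerance = 1e-3)

  set1 <- generateDoseResponseSet(pr, c(1, 6.7, 25), 2, seed = 5)
  set2 <- generateDoseResponseSet(pr, c(1, 6.7, 25), 2, seed = 5)
  expect_identical(
    lapply(set1, function(el) lapply(el$treated, `[[`, "signal")),
    lapply(set2, function(el) lapply(el$treated, `[[`, "signal")))
  expect_equal(set1[[2]]$true_inhibition, 50, tolerance = 1e-9)
  # replicates share conditions but differ in noise realization
  pr$noise_sd <- 0.02
  setn <- generateDoseResponseSet(pr, c(6.7), 3, seed = 5)
  sigs <- lapply(setn[[1]]$control, `[[`, "signal")
  expect_false(identical(sigs[[1]], sigs[[2]]))
  expect_error(generateDoseResponseSet(pr, c(6.7), 0, seed = 1),
               "replicates")
  expect_error(generateDoseResponseSet(pr, c(-1, 5), 2, seed = 1), "> 0")
})

test_that("baseline traces are flat apart from bleach drift", {
  pr <- noiselessPreset(modality = "fluorescence", bleach_rate = 1e-4)
  tr <- generateBaselineTrace(pr, 100, 200, seed = 1)
  drift <- stats::coef(stats::lm(tr$signal ~ tr$time))[2]
  expect_equal(unname(drift), -1e-4, tolerance = 1e-9)
})

test_that("CV mixture sampling concentrates at the designed modes", {
  one <- list(list(weight = 1, mean = c(2.0, 1.3), cov = 1e-4))
  s <- generateCVSamples(one, 300, seed = 2)
  expect_true(all(abs(s$d1 - 2.0) < 5 * 0.01))
  expect_true(all(abs(s$d2 - 1.3) < 5 * 0.01))
  expect_equal(colnames(s)[1:3], c("frame", "monomer", "replicate"))

  two <- list(list(weight = 0.5, mean = c(1, 1), cov = 1e-4),
              list(weight = 0.5, mean = c(3, 3), cov = 1e-4))
  s2 <- generateCVSamples(two, 1000, seed = 3)
  occ <- mean(s2$d1 < 2)
  # binomial 99.9% band around 0.5 at n = 1000
  expect_lt(abs(occ - 0.5), 3.3 * sqrt(0.25 / 1000))

  expect_error(generateCVSamples(one, 0, seed = 1), "n must")
  bad <- list(list(weight = 0.6, mean = c(1, 1), cov = 1e-4))
  expect_error(generateCVSamples(bad, 10, seed = 1), "sum to 1")
  npd <- list(list(weight = 1, mean = c(1, 1),
                   cov = matrix(c(1, 2, 2, 1), 2)))
  expect_error(generateCVSamples(npd, 10, seed = 1), "positive-definite")
})

test_that("toy complexes respect jitter, determinism and PDB round-trip", {
  layout <- list(list(resno = 150, pos = c(0, 0, 0), jitter = 0),
                 list(resno = 43, pos = c(1, 0, 0), jitter = 0))
  tc <- generateToyComplex(4, layout, c(0.3, 0, 0), seed = 1)
  expect_true(all(apply(tc$xyz, 2, function(col) length(unique(col)) == 1)))

  layout_j <- list(list(resno = 1, pos = c(0, 0, 0), jitter = 0.05))
  tj1 <- generateToyComplex(3, layout_j, c(1, 0, 0), seed = 7)
  tj2 <- generateToyComplex(3, layout_j, c(1, 0, 0), seed = 7)
  expect_identical(tj1$xyz, tj2$xyz)
  expect_false(all(tj1$xyz[1, ] == tj1$xyz[2, ]))

  path <- tempfile(fileext = ".pdb")
  writePdbFrames(tc, path)
  rd <- readPdbFrames(path)
  expect_equal(rd$xyz, tc$xyz, tolerance = 1e-3)   # PDB precision, Angstrom
  expect_equal(rd$atoms$resno, tc$atoms$resno)
  expect_equal(nrow(rd$xyz), 4)
})

test_that("presets round-trip through the YAML config exactly", {
  presets <- aqpPresets()
  path <- tempfile(fileext = ".yaml")
  writePresets(presets, path)
  back <- readPresets(path)
  expect_equal(back, presets)
  expect_error(readPresets(tempfile()), "not found")
})
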