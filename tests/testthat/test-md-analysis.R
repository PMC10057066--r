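kT298 <- 0.008314462618 * 298.15

test_that("loop definitions reject empty or overlapping ranges", {
  expect_silent(loopDefinition(c(52, 54), c(209, 211)))
  expect_error(loopDefinition(c(54, 52), c(209, 211)), "non-empty")
  expect_error(loopDefinition(c(52, 60), c(55, 70)), "overlap")
})

test_that("loop distances are centroid distances in nm", {
  # two single-residue loops 2 nm apart on z
  at <- caAtoms(c(1, 10))
  fr <- makeFrames(list(rbind(c(0, 0, 0), c(0, 0, 2))), at)
  cv <- computeLoopDistances(fr, loopDefinition(c(1, 1), c(10, 10)),
                             loopDefinition(c(1, 1), c(10, 10)))
  expect_equal(cv$d1, 2.0)

  # 3-residue loop with centroid at x = 1 vs a single CA at x = 4
  at2 <- caAtoms(c(1, 2, 3, 10))
  fr2 <- makeFrames(list(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                               c(4, 0, 0))), at2)
  cv2 <- computeLoopDistances(fr2, loopDefinition(c(1, 3), c(10, 10)),
                              loopDefinition(c(1, 3), c(10, 10)))
  expect_equal(cv2$d1, 3.0)

  # missing residue is reported by name
  expect_error(computeLoopDistances(
    fr2, loopDefinition(c(1, 4), c(10, 10)),
    loopDefinition(c(1, 3), c(10, 10))), "residue")
})

test_that("oscillating loops average to their designed separation", {
  at <- caAtoms(c(1, 10))
  frames <- lapply(1:60, function(f)
    rbind(c(0, 0, 0), c(1.5 + 0.1 * sin(f), 0, 0)))
  cv <- computeLoopDistances(makeFrames(frames, at),
                             loopDefinition(c(1, 1), c(10, 10)),
                             loopDefinition(c(1, 1), c(10, 10)))
  expect_equal(mean(cv$d1), 1.5, tolerance = 0.02 / 1.5)
})

test_that("free-energy landscape normalizes the occupied minimum to zero", {
  s <- generateCVSamples(list(list(weight = 1, mean = c(2, 1.3),
                                   cov = 0.01)), 5000, seed = 1)
  grid <- freeEnergyLandscape(s)
  expect_identical(min(grid$dG, na.rm = TRUE), 0)
  expect_true(all(is.na(grid$dG[grid$counts == 0])))
  expect_true(all(grid$dG[grid$counts > 0] >= 0))
  # minimum bin sits at the mode of a tight Gaussian (within the region
  # where Poisson bin noise can move the argmax, ~0.6 sigma)
  mn <- which(grid$dG == 0, arr.ind = TRUE)
  bw <- c(diff(grid$d1_edges[1:2]), diff(grid$d2_edges[1:2]))
  ctr <- c(grid$d1_edges[mn[1]] + bw[1] / 2, grid$d2_edges[mn[2]] + bw[2] / 2)
  expect_lte(abs(ctr[1] - 2), 0.6 * 0.1 + bw[1])
  expect_lte(abs(ctr[2] - 1.3), 0.6 * 0.1 + bw[2])
})

test_that("a half-count bin sits at kT ln 2 above the minimum", {
  # two point-mass locations with a 2:1 count ratio
  d <- data.frame(
    frame = 1:300, monomer = 1, replicate = 1, time_ns = 1:300,
    d1 = c(rep(1.0, 200), rep(2.0, 100)),
    d2 = c(rep(1.0, 200), rep(2.0, 100)))
  grid <- freeEnergyLandscape(d, n_bins = 10)
  vals <- sort(unique(grid$dG[!is.na(grid$dG)]))
  expect_equal(vals, c(0, kT298 * log(2)))
  expect_equal(kT298 * log(2), 1.718, tolerance = 1e-3)
})

test_that("uniform sampling yields an essentially flat landscape", {
  d <- withr::with_seed(5, data.frame(
    frame = 1:20000, monomer = 1, replicate = 1, time_ns = 1,
    d1 = stats::runif(20000, 1, 3), d2 = stats::runif(20000, 1, 2)))
  grid <- freeEnergyLandscape(d, n_bins = 10)
  expect_identical(min(grid$dG, na.rm = TRUE), 0)
  # only Poisson sampling noise (~200 counts/bin) plus partially-covered
  # padded edge bins: well under 1 kT of spread
  expect_lt(max(grid$dG, na.rm = TRUE), 2)
  # flat landscape with a cutoff above the noise: one basin covering the
  # occupied region
  b <- findBasins(grid, depth_cutoff = 2.5)
  expect_length(b, 1)
  expect_equal(nrow(b[[1]]$bins), sum(!is.na(grid$dG)))
})

test_that("well-separated mixture components appear as separate basins", {
  s <- generateCVSamples(threeBasinMixture(), 10000, seed = 3)
  grid <- freeEnergyLandscape(s)
  basins <- findBasins(grid)
  expect_length(basins, 3)
  # labels ascend in minimum free energy
  expect_true(!is.unsorted(vapply(basins, `[[`, 0, "min_dG")))
  # each minimum lies within one bin of a designed mode
  modes <- rbind(c(2.0, 1.3), c(2.4, 1.6), c(2.8, 1.3))
  bw <- c(diff(grid$d1_edges[1:2]), diff(grid$d2_edges[1:2]))
  for (b in basins) {
    dists <- apply(modes, 1, function(m) abs(m - b$min_location))
    expect_true(any(dists[1, ] <= 1.5 * bw[1] & dists[2, ] <= 1.5 * bw[2]))
  }
})

test_that("a tight cutoff reduces basins to single bins", {
  # three isolated point masses with equal counts: all at dG = 0
  d <- data.frame(
    frame = 1:300, monomer = 1, replicate = 1, time_ns = 1,
    d1 = rep(c(1, 2, 3), each = 100), d2 = rep(c(1, 2, 1), each = 100))
  grid <- freeEnergyLandscape(d, n_bins = 12)
  basins <- findBasins(grid, depth_cutoff = 0.1)
  expect_length(basins, 3)
  expect_true(all(vapply(basins, function(b) nrow(b$bins), 0L) == 1L))
  # no bin below an impossible cutoff: empty basin set, not an error
  expect_length(findBasins(grid, depth_cutoff = -1), 0)
})

test_that("binding-ready selection applies the open-loop thresholds", {
  mix <- list(list(weight = 0.4, mean = c(2.0, 1.3), cov = 1e-4),  # passes
              list(weight = 0.3, mean = c(1.5, 1.3), cov = 1e-4),  # fails d1
              list(weight = 0.3, mean = c(2.0, 1.0), cov = 1e-4))  # fails d2
  s <- generateCVSamples(mix, 5000, seed = 4)
  grid <- freeEnergyLandscape(s)
  basins <- findBasins(grid)
  expect_length(basins, 3)
  sel <- selectBindingReady(s, basins, seed = 1)
  expect_equal(unique(sel$basin), basins[[which(vapply(basins, function(b)
    b$min_location["d1"] > 1.9 && b$min_location["d2"] > 1.19,
    logical(1)))]]$label)
  expect_equal(nrow(sel), 5)
  expect_true(all(sel$d1 > 1.9 & sel$d2 > 1.19))
})

test_that("three qualifying basins with five draws give 15 conformers", {
  s <- generateCVSamples(threeBasinMixture(), 10000, seed = 3)
  basins <- findBasins(freeEnergyLandscape(s))
  sel <- selectBindingReady(s, basins, seed = 5)
  expect_equal(nrow(sel), 15)
  expect_equal(as.vector(table(sel$basin)), c(5, 5, 5))
  expect_false(any(duplicated(sel$frame)))
  # seeded selection contract
  expect_identical(sel, selectBindingReady(s, basins, seed = 5))
  expect_false(identical(sel, selectBindingReady(s, basins, seed = 6)))
  # qualifying set is a pure predicate: permuting samples changes nothing
  perm <- withr::with_seed(1, s[sample.int(nrow(s)), ])
  basins_p <- findBasins(freeEnergyLandscape(perm))
  sel_p <- selectBindingReady(perm, basins_p, seed = 5)
  expect_setequal(unique(sel_p$basin), unique(sel$basin))
})

test_that("selection errors when a qualifying basin is too small", {
  mix <- list(list(weight = 0.999, mean = c(2.0, 1.3), cov = 1e-4),
              list(weight = 0.001, mean = c(2.8, 1.6), cov = 1e-6))
  s <- generateCVSamples(mix, 3000, seed = 8)
  basins <- findBasins(freeEnergyLandscape(s), min_bins = 1)
  expect_error(selectBindingReady(s, basins, n_per_basin = 1e6, seed = 1),
               "qualifying samples")
})

test_that("contact counting applies a strict cutoff per residue", {
  at <- caAtoms(c(150, 43))
  at <- rbind(at, data.frame(serial = 3, elety = "C1", resid = "LIG",
                             chain = "B", resno = 9999))
  # ligand 0.35 nm from residue 150, 1.0 nm from residue 43
  fr <- makeFrames(list(rbind(c(0, 0, 0), c(1.0, 0.35, 0), c(0, 0.35, 0))),
                   at)
  cp <- contactCounts(fr, cutoff = 0.4)
  expect_equal(cp$resno, c(150, 43))
  expect_equal(cp$mean_contacts, c(1, 0))

  # a pair at exactly the cutoff distance is not a contact
  fr_edge <- makeFrames(list(rbind(c(0, 0, 0), c(1.0, 0.4, 0),
                                   c(0, 0.4, 0))), at)
  cp_edge <- contactCounts(fr_edge, cutoff = 0.4)
  expect_equal(sum(cp_edge$mean_contacts), 0)

  expect_error(contactCounts(fr, ligand_resid = "XXX"), "no ligand")
  expect_error(contactCounts(fr, window = c(50, 60)), "empty window")
})

test_that("toy-complex contact ranking follows the designed geometry", {
  layout <- list(list(resno = 150, pos = c(0, 0, 0), jitter = 0.01),
                 list(resno = 43, pos = c(1, 0, 0), jitter = 0.01),
                 list(resno = 208, pos = c(0.1, 0.3, 0), jitter = 0.01))
  tc <- generateToyComplex(20, layout, c(0.3, 0, 0), seed = 2)
  cp <- contactCounts(tc, cutoff = 0.4)
  expect_equal(cp$resno[1], 150)
  expect_equal(cp$mean_contacts[cp$resno == 43], 0)
})

test_that("contact counts equal a brute-force all-pairs oracle", {
  for (s in 1:5) {
    n_prot <- 40
    at <- caAtoms(sample.int(300, n_prot))
    at <- rbind(at, data.frame(serial = n_prot + 1:3, elety = "C1",
                               resid = "LIG", chain = "B", resno = 9999))
    frames <- withr::with_seed(s, lapply(1:4, function(f)
      matrix(stats::runif(3 * (n_prot + 3), 0, 1.2), ncol = 3)))
    fr <- makeFrames(frames, at)
    cp <- contactCounts(fr, cutoff = 0.4)

    # independent double-loop reference
    ref <- stats::setNames(numeric(n_prot), paste("A", at$resno[1:n_prot]))
    for (f in seq_along(frames)) {
      co <- frames[[f]]
      for (i in 1:n_prot) for (j in (n_prot + 1):(n_prot + 3)) {
        if (sqrt(sum((co[i, ] - co[j, ])^2)) < 0.4)
          ref[paste("A", at$resno[i])] <- ref[paste("A", at$resno[i])] + 1
      }
    }
    ref <- ref / length(frames)
    got <- stats::setNames(cp$mean_contacts, paste(cp$chain, cp$resno))
    expect_equal(got[names(ref)], ref)
  }
})

test_that("basin detection recovers the component count across seeds", {
  mix <- threeBasinMixture()
  ok <- vapply(1:100, function(s)
    length(findBasins(freeEnergyLandscape(
      generateCVSamples(mix, 10000, seed = s)))) == 3, logical(1))
  expect_gte(mean(ok), 0.95)
})
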