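test_that("buildSnpMap respects density, pitch and degenerate inputs", {
  # fixed pitch: markers at 1000, 2000, ..., 10000
  m <- buildSnpMap(c(c1 = 10000), spacing = "fixed", pitch = 1000)
  expect_equal(markers(m)$pos, seq(1000, 10000, by = 1000))

  # zero density: empty map
  expect_equal(nrow(markers(buildSnpMap(c(c1 = 1e5), snpDensity = 0))), 0L)

  # negative inputs rejected
  expect_error(buildSnpMap(c(c1 = -5)))
  expect_error(buildSnpMap(c(c1 = 1e5), snpDensity = -1))

  # genome-scale density: ~74,911 markers over ~12.07 Mb, within 5%
  counts <- vapply(1:3, function(s)
    nrow(markers(buildSnpMap(yeastChromLengths(), seed = s))), 0)
  expect_true(all(abs(counts - 74911) / 74911 < 0.05))

  # alleles always differ, positions strictly increasing
  mk <- markers(buildSnpMap(c(c1 = 2e5), seed = 7))
  expect_true(all(mk$alleleP1 != mk$alleleP2))
  expect_true(all(diff(mk$pos) > 0))
})

test_that("placeCrossovers is a stationary gamma-renewal process", {
  expect_equal(placeCrossovers(0, 2.3, 1e5), numeric())
  expect_error(placeCrossovers(1e6, 0, 1e5))
  expect_error(placeCrossovers(1e6, 2, -1))

  # shape 1 reduces to a Poisson process: E[count] = L / mean
  set.seed(21)
  n <- replicate(2000, length(placeCrossovers(1e6, 1, 3e5)))
  expect_lt(abs(mean(n) - 10 / 3), 3 * sd(n) / sqrt(length(n)))

  # gap mean and CV converge to mean and 1/sqrt(shape) (3 SE tolerance)
  set.seed(22)
  gaps <- unlist(replicate(300, diff(placeCrossovers(5e6, 2.3, 1e5)),
                           simplify = FALSE))
  expect_gt(length(gaps), 5000)
  seMean <- sd(gaps) / sqrt(length(gaps))
  expect_lt(abs(mean(gaps) - 1e5), 3 * seMean)
  cv <- sd(gaps) / mean(gaps)
  # delta-method SE of the CV of a gamma sample
  seCv <- cv * sqrt((1 + 2 * cv^2) / (2 * length(gaps)))
  expect_lt(abs(cv - 1 / sqrt(2.3)), 3 * seCv)

  # positions sorted within (0, L)
  p <- placeCrossovers(2e6, 2.3, 2e5, seed = 5)
  expect_true(all(diff(p) > 0) && all(p > 0) && all(p < 2e6))
})

test_that("simulateMeiosis without events yields a Mendelian octad", {
  map <- pitchMap(L = 20000, pitch = 500)
  p <- SimParams(chromLengths = c(chrA = 20000), ncoRate = 0,
                 meanInterCo = 1e12)
  for (seed in 1:4) {
    sim <- simulateMeiosis(map, p, seed = seed)
    prof <- segregationProfile(sim$octad)
    expect_true(all(prof$mendelian))
    expect_equal(nrow(sim$truth), 0L)
  }
})

test_that("ground truth reproduces the emitted matrix bit-for-bit", {
  map <- buildSnpMap(c(c1 = 6e5, c2 = 4e5), seed = 8)
  p <- SimParams(chromLengths = c(c1 = 6e5, c2 = 4e5))
  for (seed in c(1, 2)) {
    sim <- simulateMeiosis(map, p, seed = seed)
    expect_identical(calls(octadFromTruth(sim$truth, map)), calls(sim$octad))
  }
})

test_that("strand conservation holds at every marker", {
  map <- buildSnpMap(c(c1 = 4e5), seed = 3)
  sim <- simulateMeiosis(map, SimParams(chromLengths = c(c1 = 4e5)), seed = 9)
  prof <- segregationProfile(sim$octad)
  expect_true(all(prof$nP1 + prof$nP2 + prof$nMissing == 8L))
})

test_that("forced single NCO yields one discordant spore pair over the tract", {
  # msh2-deficient setting: a retained one-strand hDNA tract makes exactly
  # one spore's daughters disagree (5:3); everything else stays 4:4
  map <- pitchMap(L = 60000, pitch = 300)
  p <- SimParams(chromLengths = c(chrA = 60000), meanInterCo = 1e12,
                 ncoRate = 3e-5, pTransHdna = 0, pSymHdna = 0,
                 tractLenDist = list(dist = "fixed", median = 2000))
  sim <- NULL
  for (seed in 1:50) {
    s <- simulateMeiosis(map, p, seed = seed)
    if (nrow(s$truth) == 1L && s$truth$nMarkers > 0) { sim <- s; break }
  }
  expect_false(is.null(sim))
  st <- duplexStates(sim$octad)
  hetBySpore <- colSums(st == "HET")
  expect_equal(sum(hetBySpore > 0), 1L)
  expect_equal(unname(hetBySpore[as.integer(sim$truth$spores)]),
               sim$truth$nMarkers)
  prof <- segregationProfile(sim$octad)
  expect_true(all(prof$mendelian[-(sim$truth$firstMarker:sim$truth$lastMarker)]))
})

test_that("emitReadCounts models depth, error and missingness", {
  map <- pitchMap(L = 30000, pitch = 100)
  oct <- mendelianOctad(map)

  # zero depth: all counts zero
  rc0 <- emitReadCounts(oct, depth = 0, seed = 1)
  expect_true(all(rc0@nP1 == 0) && all(rc0@nP2 == 0))

  # error-free: the wrong allele never collects reads
  rc <- emitReadCounts(oct, depth = 70, errorRate = 0, seed = 2)
  expect_true(all(rc@nP2[, 1:4] == 0) && all(rc@nP1[, 5:8] == 0))

  # mean depth ~ Poisson(70)
  expect_lt(abs(mean(rc@nP1[, 1:4]) - 70), 0.5)

  # missing genotype yields zero informative reads
  cl <- calls(oct); cl[5, "s2a"] <- NA
  rcNA <- emitReadCounts(OctadMatrix(cl, map), depth = 70, seed = 3)
  expect_equal(unname(rcNA@nP1[5, "s2a"] + rcNA@nP2[5, "s2a"]), 0L)

  # pooled minor-allele fraction ~ error rate (binomial check)
  rcE <- emitReadCounts(oct, depth = 70, errorRate = 0.01, seed = 4)
  minor <- sum(rcE@nP2[, 1:4]) + sum(rcE@nP1[, 5:8])
  total <- sum(rcE@nP1) + sum(rcE@nP2)
  se <- sqrt(0.01 * 0.99 / total)
  expect_lt(abs(minor / total - 0.01), 4 * se)

  expect_error(emitReadCounts(oct, depth = -1))
  expect_error(emitReadCounts(oct, errorRate = 0.6))
})

test_that("simulated crossover count round-trips through event inference", {
  map <- buildSnpMap(c(c1 = 1e6), seed = 5)
  p <- SimParams(chromLengths = c(c1 = 1e6))
  sim <- simulateMeiosis(map, p, seed = 31)
  ev <- events(inferEvents(sim$octad))
  expect_equal(sum(ev$type == "CO"), sum(sim$truth$type == "CO"))
})
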