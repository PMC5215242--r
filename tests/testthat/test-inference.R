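# Constructed octads on a 50 kb chromosome with markers every 250 bp.

test_that("segregationProfile counts calls and flags non-Mendelian markers", {
  map <- pitchMap(L = 2500, pitch = 500)  # 5 markers
  cl <- mendelianCalls(map)
  cl <- setStrand(cl, 1, "a", 2)          # 5:3... P2 gains on spore 1
  cl[3, "s4b"] <- NA                       # 4:3 with one missing
  prof <- segregationProfile(OctadMatrix(cl, map))
  expect_equal(prof$nP1[1], 4); expect_equal(prof$nP2[1], 4)
  expect_true(prof$mendelian[1])
  expect_equal(prof$nP1[2], 3); expect_equal(prof$nP2[2], 5)
  expect_false(prof$mendelian[2])
  expect_equal(prof$nMissing[3], 1); expect_false(prof$mendelian[3])
})

test_that("duplexStates derives spore states from daughter strands", {
  map <- pitchMap(L = 2000, pitch = 500)
  cl <- mendelianCalls(map)
  cl <- setStrand(cl, 1, "a", 1)   # HET
  cl[2, "s2a"] <- NA               # PARTIAL_P1
  cl[3, c("s3a", "s3b")] <- NA     # MISSING
  st <- duplexStates(OctadMatrix(cl, map))
  expect_equal(unname(st[1, 1]), "HET")
  expect_equal(unname(st[2, 2]), "PARTIAL_P1")
  expect_equal(unname(st[3, 3]), "MISSING")
  expect_equal(unname(st[4, 4]), "HOMO_P2")
})

test_that("phase background: Mendelian octad has one block per spore", {
  map <- pitchMap()
  bg <- inferPhaseBackground(mendelianOctad(map))
  expect_equal(nrow(bg$switches), 0L)
  expect_equal(unique(bg$phase[, 1]), 1L)
  expect_equal(unique(bg$phase[, 4]), 2L)
  expect_equal(nrow(bg$uncallable), 0L)
})

test_that("phase background: a single crossover switches exactly the two partners", {
  map <- pitchMap()
  cl <- applyCoAt(mendelianCalls(map), c(1, 3), afterRow = 100)
  bg <- inferPhaseBackground(OctadMatrix(cl, map))
  sw <- bg$switches
  expect_setequal(sw$spore, c(1, 3))
  expect_equal(nrow(sw), 2L)
  # switch interval is the marker gap around the exchange (rows 100 -> 101)
  expect_true(all(sw$leftPos == 100 * 250 & sw$rightPos == 101 * 250))
  # a conversion tract (6:2) does not switch phase
  cl2 <- mendelianCalls(map)
  cl2 <- setStrand(setStrand(cl2, 2, "a", 60:65), 2, "b", 60:65)
  bg2 <- inferPhaseBackground(OctadMatrix(cl2, map))
  expect_equal(nrow(bg2$switches), 0L)
  tr <- detectRawTracts(OctadMatrix(cl2, map), bg2)
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$carriers, "222222")
})

test_that("spores without informative homoduplex markers are flagged uncallable", {
  map <- pitchMap(L = 5000, pitch = 500)
  cl <- mendelianCalls(map)
  cl[, c("s4a", "s4b")] <- NA
  bg <- inferPhaseBackground(OctadMatrix(cl, map))
  expect_equal(bg$uncallable$spore, 4L)
})

test_that("detectRawTracts finds maximal deviant runs and bridges missing markers", {
  map <- pitchMap()
  oct <- mendelianOctad(map)
  bg <- inferPhaseBackground(oct)
  expect_equal(nrow(detectRawTracts(oct, bg)), 0L)

  # one-spore HET over rows 12..19
  cl <- setStrand(mendelianCalls(map), 1, "a", 12:19)
  oct1 <- OctadMatrix(cl, map)
  tr <- detectRawTracts(oct1, inferPhaseBackground(oct1))
  expect_equal(nrow(tr), 1L)
  expect_equal(c(tr$firstMarker, tr$lastMarker, tr$spore), c(12, 19, 1))
  expect_equal(tr$carriers, "aaaaaaaa")

  # a single interrupting missing marker (<= maxMissingRun) is bridged
  cl2 <- cl; cl2[15, c("s1a", "s1b")] <- NA
  oct2 <- OctadMatrix(cl2, map)
  tr2 <- detectRawTracts(oct2, inferPhaseBackground(oct2))
  expect_equal(nrow(tr2), 1L)
  expect_equal(tr2$nDeviant, 7L)

  # a longer uninformative stretch splits the run
  cl3 <- cl; cl3[14:16, c("s1a", "s1b")] <- NA
  oct3 <- OctadMatrix(cl3, map)
  tr3 <- detectRawTracts(oct3, inferPhaseBackground(oct3),
                         InferenceConfig(maxMissingRun = 2))
  expect_equal(nrow(tr3), 2L)
})

test_that("mergeEvents combines items below the merge distance only", {
  mkTract <- function(first, last) {
    data.frame(spore = 1L, chrom = "chrA", firstMarker = NA_integer_,
               lastMarker = NA_integer_, firstPos = first, lastPos = last,
               nDeviant = 2L, carriers = "aa", stringsAsFactors = FALSE)
  }
  noSwitch <- data.frame(spore = integer(), chrom = character(),
                         leftPos = numeric(), rightPos = numeric(),
                         mid = numeric(), fromPhase = integer(),
                         toPhase = integer())
  cfg <- InferenceConfig(mergeGapBp = 1500)

  # 1,499 bp between nearest affected markers: one event
  near <- rbind(mkTract(10000, 10500), mkTract(11999, 12400))
  expect_length(mergeEvents(near, noSwitch, cfg), 1L)
  # 1,500 bp: two events (strict "less than")
  far <- rbind(mkTract(10000, 10500), mkTract(12000, 12400))
  expect_length(mergeEvents(far, noSwitch, cfg), 2L)
  # single tract unchanged; input order irrelevant
  expect_length(mergeEvents(mkTract(5000, 5600), noSwitch, cfg), 1L)
  expect_length(mergeEvents(near[2:1, ], noSwitch, cfg), 1L)
})

test_that("classification covers the crossover and heteroduplex categories", {
  map <- pitchMap()
  cl <- mendelianCalls(map)
  # trans hDNA on spore 2: donor strand switches sides at rows 80..89
  cl <- setStrand(cl, 2, "a", 80:84)
  cl <- setStrand(cl, 2, "b", 85:89)
  # crossover between spores 1 and 3 after row 100, adjacent hDNA tract
  cl <- applyCoAt(cl, c(1, 3), afterRow = 100)
  cl <- setStrand(cl, 1, "a", 101:106)
  # symmetric hDNA: complementary one-strand tracts on spores 1 and 3
  cl <- setStrand(cl, 1, "a", 120:126)
  cl <- setStrand(cl, 3, "a", 120:126)
  # full conversion (6:2) on spore 4
  cl <- setStrand(cl, 4, "a", 150:155)
  cl <- setStrand(cl, 4, "b", 150:155)

  ev <- events(inferEvents(OctadMatrix(cl, map)))
  expect_equal(nrow(ev), 4L)
  expect_equal(ev$type, c("NCO", "CO", "NCO", "NCO"))
  expect_equal(ev$category, c("trans_hDNA", "SDSA_like_hDNA",
                              "symmetric_hDNA", "full_conversion"))
  expect_equal(ev$spores[2], "1,3")
  expect_equal(ev$spores[3], "1,3")
  # crossover point sits between the flanking homoduplex markers (the hDNA
  # tract widens one partner's switch interval to its far edge)
  expect_gte(ev$coPos[2], 100 * 250); expect_lte(ev$coPos[2], 107 * 250)
})

test_that("tract lengths follow the min/mid/max conventions", {
  map <- SNPMap(chrom = rep("c", 4), pos = c(9800L, 10000L, 11000L, 11300L),
                alleleP1 = rep("A", 4), alleleP2 = rep("C", 4),
                chromLengths = c(c = 20000))
  expect_equal(tractLength(2, 3, map, "min"), 1001)
  expect_equal(tractLength(2, 3, map, "mid"), 1250)
  expect_equal(tractLength(2, 3, map, "max"), 1499)
  # single affected marker
  expect_equal(tractLength(2, 2, map, "min"), 1)
  # no flanking marker on the left: clamps to the chromosome start
  expect_equal(tractLength(1, 2, map, "max"), 11000 - 0 - 1)
})

test_that("event inference is deterministic and empty on Mendelian input", {
  map <- pitchMap()
  expect_equal(nEvents(inferEvents(mendelianOctad(map))), 0L)

  map2 <- buildSnpMap(c(c1 = 3e5), seed = 4)
  sim <- simulateMeiosis(map2, SimParams(chromLengths = c(c1 = 3e5)), seed = 6)
  e1 <- inferEvents(sim$octad)
  e2 <- inferEvents(sim$octad)
  expect_identical(events(e1), events(e2))
})

test_that("lower depth never creates phantom crossovers in event-free octads", {
  map <- buildSnpMap(c(c1 = 3e5), seed = 10)
  p <- SimParams(chromLengths = c(c1 = 3e5), ncoRate = 0, meanInterCo = 1e12)
  for (seed in 1:3) {
    sim <- simulateMeiosis(map, p, seed = seed)
    rc <- emitReadCounts(sim$octad, depth = 25, errorRate = 0,
                         seed = seed + 50)   # substantial missingness
    oct <- callMatrix(rc)
    expect_gt(mean(is.na(calls(oct))), 0.01)
    ev <- events(inferEvents(oct))
    expect_equal(sum(ev$type == "CO"), 0L)
  }
})

test_that("length conventions are ordered and bracket the true tract", {
  map <- buildSnpMap(c(c1 = 5e5, c2 = 3e5), seed = 12)
  p <- SimParams(chromLengths = c(c1 = 5e5, c2 = 3e5))
  for (seed in 1:3) {
    sim <- simulateMeiosis(map, p, seed = seed)
    evs <- inferEvents(sim$octad)
    ev <- events(evs)
    withLen <- ev[!is.na(ev$lenMin), ]
    expect_true(all(withLen$lenMin <= withLen$lenMid + 1e-9))
    expect_true(all(withLen$lenMid <= withLen$lenMax + 1e-9))

    m <- matchEventsToTruth(evs, sim$truth, map)
    mt <- m$matches
    iso <- which(mt$visible & mt$isolated & mt$recovered)
    for (i in iso) {
      tr <- sim$truth[i, ]
      hit <- ev[ev$chrom == tr$chrom & ev$start <= tr$tractEnd &
                  ev$end >= tr$tractStart & !is.na(ev$lenMin), ]
      if (nrow(hit) == 1L) {
        expect_lte(hit$lenMin, tr$tractLen)
        expect_gte(hit$lenMax, tr$tractLen)
      }
    }
  }
})
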