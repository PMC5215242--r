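test_that("callGenotype follows the read-count validity rule", {
  cfg <- GenotypeCallConfig()
  # single allele within [15, 150]
  expect_equal(callGenotype(70, 0, cfg), "P1")
  expect_equal(callGenotype(0, 70, cfg), "P2")
  # two alleles: major in [40, 150], minor below 5
  expect_equal(callGenotype(100, 4, cfg), "P1")
  expect_equal(callGenotype(4, 100, cfg), "P2")
  # boundary violations and ties are missing
  expect_true(is.na(callGenotype(14, 0, cfg)))
  expect_true(is.na(callGenotype(151, 0, cfg)))
  expect_true(is.na(callGenotype(100, 5, cfg)))
  expect_true(is.na(callGenotype(39, 3, cfg)))
  expect_true(is.na(callGenotype(6, 6, cfg)))
  # boundaries themselves are valid (inclusive reading)
  expect_equal(callGenotype(15, 0, cfg), "P1")
  expect_equal(callGenotype(150, 0, cfg), "P1")
  expect_equal(callGenotype(40, 4, cfg), "P1")
  expect_error(callGenotype(-1, 5, cfg))
})

test_that("callGenotype matches a literal transcription on the full count grid", {
  grid <- expand.grid(n1 = 0:200, n2 = 0:200)
  got <- callGenotype(grid$n1, grid$n2)
  want <- mapply(oracleGenotype, grid$n1, grid$n2)
  expect_identical(got, unname(want))
})

test_that("adding minor-allele reads never rescues a missing call", {
  grid <- expand.grid(n1 = 0:200, n2 = 0:199)
  keep <- grid$n1 >= grid$n2 + 1   # stay on the same side of the tie
  g <- grid[keep, ]
  before <- callGenotype(g$n1, g$n2)
  after <- callGenotype(g$n1, g$n2 + 1)
  expect_false(any(is.na(before) & !is.na(after)))
})

test_that("callGenotype is symmetric under allele swap", {
  grid <- expand.grid(n1 = 0:160, n2 = 0:160)
  fwd <- callGenotype(grid$n1, grid$n2)
  rev <- callGenotype(grid$n2, grid$n1)
  mirror <- ifelse(is.na(fwd), NA_character_,
                   ifelse(fwd == "P1", "P2", "P1"))
  expect_identical(rev, mirror)
})

test_that("callMatrix vectorises callGenotype and reports missingness", {
  map <- pitchMap(L = 2000, pitch = 500)  # 4 markers
  z <- matrix(0L, 4, 8, dimnames = list(NULL, octadStrandNames()))
  rc <- ReadCountTable(z, z, map)
  octAllMissing <- callMatrix(rc)
  expect_true(all(is.na(calls(octAllMissing))))
  expect_equal(unname(attr(calls(octAllMissing), "missingness")), rep(1, 8))

  # single-marker composition of the scalar examples
  nP1 <- z; nP2 <- z
  nP1[1, ] <- c(70, 14, 100, 6, 0, 0, 4, 39)
  nP2[1, ] <- c(0, 0, 4, 6, 70, 151, 100, 3)
  oct <- callMatrix(ReadCountTable(nP1, nP2, map))
  expect_identical(unname(calls(oct)[1, ]),
                   c("P1", NA, "P1", NA, "P2", NA, "P2", NA))

  # round trip: error-free simulated counts at depth 70 reproduce the octad
  map2 <- buildSnpMap(c(c1 = 2e5), seed = 2)
  sim <- simulateMeiosis(map2, SimParams(chromLengths = c(c1 = 2e5)), seed = 3)
  rc2 <- emitReadCounts(sim$octad, depth = 70, errorRate = 0, seed = 4)
  called <- callMatrix(rc2)
  tot <- rc2@nP1 + rc2@nP2
  inBounds <- tot >= 15 & tot <= 150
  expect_identical(calls(called)[inBounds], calls(sim$octad)[inBounds])
})
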