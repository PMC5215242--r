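test_that("interCoDistances pools successive midpoint differences", {
  ev <- emptyEventFrame()
  ev[1:5, ] <- list(
    c("c1", "c1", "c1", "c2", "c3"),
    c(1e5, 3e5, 6e5, 2e5, 4e5), c(1e5, 3e5, 6e5, 2e5, 4e5) + 100,
    paste0("e", 1:5), c("CO", "CO", "CO", "CO", "NCO"),
    c(rep("none", 4), "SDSA_like_hDNA"), "1",
    c(1e5, 3e5, 6e5, 2e5, NA), NA_real_, NA_real_, NA_real_,
    c(0L, 0L, 0L, 0L, 3L), "m1", "WT")
  gaps <- interCoDistances(EventSet(ev, c(c1 = 1e6, c2 = 1e6, c3 = 1e6)))
  # chromosome with <2 COs contributes nothing; NCOs never do
  expect_equal(sort(gaps$gap), c(2e5, 3e5))
  expect_true(all(gaps$chrom == "c1"))
})

test_that("fitGammaMle matches a grid-search oracle and recovers parameters", {
  set.seed(101)
  x <- rgamma(500, shape = 2.3, scale = 5e4)
  fit <- fitGammaMle(x)
  expect_true(fit@converged)
  expect_lt(abs(gammaShape(fit) - 2.3), 0.25)
  oracle <- oracleGammaGrid(x)
  expect_gte(fit@loglik, oracle$loglik - 1e-6)

  # exponential sample: shape near 1 (no interference)
  set.seed(102)
  e <- rexp(1000, rate = 1 / 300)
  expect_lt(abs(gammaShape(fitGammaMle(e)) - 1), 0.1)

  # independent optimiser agreement (MASS, on rescaled data for stability)
  fd <- MASS::fitdistr(x / 1e4, "gamma")
  expect_lt(abs(gammaShape(fitGammaMle(x / 1e4)) - fd$estimate[["shape"]]),
            5e-3)

  # degenerate inputs fail explicitly
  expect_error(fitGammaMle(numeric()))
  expect_error(fitGammaMle(5))
  expect_error(fitGammaMle(c(3, 3, 3)), "variance")
  expect_error(fitGammaMle(c(-1, 2, 3)))
})

test_that("gamma MLE is scale-invariant in shape and proportional in scale", {
  set.seed(103)
  x <- rgamma(300, shape = 1.7, scale = 1000)
  f1 <- fitGammaMle(x)
  f2 <- fitGammaMle(x * 137)
  expect_equal(gammaShape(f1), gammaShape(f2), tolerance = 1e-6)
  expect_equal(gammaScale(f2) / gammaScale(f1), 137, tolerance = 1e-6)
})

test_that("shape recovery across genotypes: median error below 0.2", {
  set.seed(104)
  shapes <- runif(50, 1, 4)
  err <- vapply(shapes, function(k) {
    g <- rgamma(300, shape = k, scale = 1e5 / k)
    abs(gammaShape(fitGammaMle(g)) - k)
  }, 0)
  expect_lt(median(err), 0.2)
})

test_that("KS comparison matches exact enumeration and the stats package", {
  expect_equal(compareInterference(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  expect_equal(compareInterference(c(1, 2, 3), c(10, 20, 30))$statistic, 1)
  expect_error(compareInterference(numeric(), 1:3))

  set.seed(105)
  cases <- list(
    list(a = rnorm(5), b = rnorm(7)),
    list(a = rnorm(8), b = rnorm(8, 1)),
    list(a = c(1, 2, 2, 3), b = c(2, 3, 3, 4, 5)),      # ties
    list(a = rexp(6), b = rexp(9, 0.3)),
    list(a = c(1, 1, 1), b = c(1, 1, 2)))               # heavy ties
  for (cs in cases) {
    got <- compareInterference(cs$a, cs$b)
    expect_equal(got$p.value, oracleKs(cs$a, cs$b), tolerance = 1e-12)
    if (!any(duplicated(c(cs$a, cs$b))))   # ks.test exact only without ties
      expect_equal(got$p.value, ks.test(cs$a, cs$b)$p.value, tolerance = 1e-9)
  }

  # asymptotic branch agrees with stats::ks.test
  set.seed(106)
  a <- rnorm(200); b <- rnorm(250, 0.15)
  expect_equal(compareInterference(a, b)$p.value,
               suppressWarnings(ks.test(a, b)$p.value), tolerance = 1e-6)
})

test_that("Wilcoxon comparison matches exact enumeration and the stats package", {
  r <- compareTractLengths(c(1, 2, 3), c(10, 20, 30), alternative = "less")
  expect_equal(r$statistic, 0)
  expect_equal(r$p.value, 1 / 20)   # 1 of the 20 orderings
  same <- compareTractLengths(c(4, 5, 6), c(4, 5, 6))
  expect_equal(same$statistic, 9 / 2)   # U = n1 n2 / 2 under symmetry
  expect_equal(same$p.value, 1)
  expect_error(compareTractLengths(numeric(), 1:3))

  set.seed(107)
  cases <- list(
    list(a = rnorm(5), b = rnorm(6)),
    list(a = rnorm(8), b = rnorm(10, 0.8)),
    list(a = c(1, 2, 2, 5), b = c(2, 2, 3)),            # ties
    list(a = rpois(7, 4), b = rpois(8, 6)))             # discrete ties
  for (cs in cases) {
    for (alt in c("two.sided", "less", "greater")) {
      got <- compareTractLengths(cs$a, cs$b, alternative = alt)
      expect_equal(got$p.value, oracleWilcox(cs$a, cs$b, alt),
                   tolerance = 1e-12)
    }
    if (!any(duplicated(c(cs$a, cs$b))))
      expect_equal(compareTractLengths(cs$a, cs$b)$p.value,
                   wilcox.test(cs$a, cs$b, exact = TRUE)$p.value,
                   tolerance = 1e-9)
  }

  # asymptotic branch agrees with wilcox.test (tie-corrected, no continuity)
  set.seed(108)
  a <- rnorm(200); b <- rnorm(180, 0.1)
  expect_equal(compareTractLengths(a, b)$p.value,
               wilcox.test(a, b, exact = FALSE, correct = FALSE)$p.value,
               tolerance = 1e-9)
})

test_that("a strong tract-length shift at study scale is highly significant", {
  # two genotypes with a twofold median shift at a few hundred events each
  set.seed(109)
  wt <- rexp(300, rate = log(2) / 1000)
  mut <- rexp(300, rate = log(2) / 2100)
  p <- compareTractLengths(wt, mut)$p.value
  expect_lt(p, 5e-5)
})

test_that("summarizeEvents computes medians, counts and symmetric tallies", {
  ev <- emptyEventFrame()
  ev[1:5, ] <- list(
    "c1", c(1, 1e4, 2e4, 3e4, 4e4), c(2000, 12000, 21000, 31000, 41000),
    paste0("e", 1:5), c("CO", "NCO", "CO", "NCO", "NCO"),
    c("SDSA_like_hDNA", "full_conversion", "none", "symmetric_hDNA",
      "SDSA_like_hDNA"),
    "1", c(1500, NA, 2.05e4, NA, NA),
    c(1200, 900, NA, 500, 700), c(1300, 1000, NA, 560, 800),
    c(1500, 1200, NA, 700, 900), c(6L, 4L, 0L, 3L, 4L),
    c("m1", "m1", "m2", "m2", "m2"), "WT")
  s <- summarizeEvents(EventSet(ev, c(c1 = 1e5)), convention = "mid")

  co <- s$tracts[s$tracts$type == "CO", ]
  expect_equal(co$n, 1L)            # the tract-less CO is excluded
  expect_equal(co$medianBp, 1300)
  nco <- s$tracts[s$tracts$type == "NCO", ]
  expect_equal(nco$n, 3L)
  expect_equal(nco$medianBp, 800)

  # counts per meiosis with SE across meioses: m1 has 1 CO, m2 has 1
  cnt <- s$counts[s$counts$type == "CO", ]
  expect_equal(cnt$meanPerMeiosis, 1)
  expect_equal(cnt$se, 0)
  expect_equal(s$symmetric$n, 1L)
  expect_equal(s$symmetric$meanBp, 560)

  # two meioses with 80 and 100 events: mean 90, SE 10
  ev2 <- emptyEventFrame()
  n <- 180
  ev2[1:n, ] <- list("c1", seq(1, by = 5000, length.out = n),
                     seq(2, by = 5000, length.out = n),
                     paste0("e", 1:n), "CO", "none", "1",
                     seq(1, by = 5000, length.out = n),
                     NA_real_, NA_real_, NA_real_, 0L,
                     rep(c("m1", "m2"), c(80, 100)), "WT")
  s2 <- summarizeEvents(EventSet(ev2, c(c1 = 1e7)))
  co2 <- s2$counts[s2$counts$type == "CO", ]
  expect_equal(co2$meanPerMeiosis, 90)
  expect_equal(co2$se, 10)
})

test_that("simulated tract medians match the configured 1 kb scale", {
  # The mid convention is close to unbiased for the drawn tract length, but
  # only when (a) the marker pitch is fine relative to the tolerance and
  # (b) events are sparse enough that the 1.5 kb positional merging rarely
  # fuses independent DSBs (merged clusters are genuinely longer). A 50 bp
  # pitch and the default (study-like) per-bp event rates on a long
  # chromosome give > 250 well-separated events.
  lens <- c(cA = 1.9e7)
  map <- buildSnpMap(lens, spacing = "fixed", pitch = 50)
  p <- SimParams(chromLengths = lens)
  sim <- simulateMeiosis(map, p, seed = 301)
  es <- inferEvents(sim$octad)
  expect_gte(nEvents(es), 250L)
  s <- summarizeEvents(es, convention = "mid")
  med <- stats::weighted.mean(s$tracts$medianBp, s$tracts$n)
  expect_lt(abs(med - 1000) / 1000, 0.15)

  # at the study's native marker density the conventions bracket the drawn
  # length, offset by about one spacing either way
  lens2 <- c(cB = 2e6)
  map2 <- buildSnpMap(lens2, seed = 78)
  sim2 <- simulateMeiosis(map2, SimParams(chromLengths = lens2), seed = 310)
  ev2 <- events(inferEvents(sim2$octad))
  w2 <- ev2[!is.na(ev2$lenMin) & ev2$nMarkers > 0, ]
  expect_lte(median(w2$lenMin), median(sim2$truth$tractLen))
  expect_gte(median(w2$lenMax), median(sim2$truth$tractLen))
})
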