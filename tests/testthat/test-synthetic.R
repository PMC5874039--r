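# Virtual paleoclimate and virtual species generator.

test_that("zero drift gives identical slices and seeds give determinism", {
  spec <- scenarioSpec(nrow = 10, ncol = 10, nSlices = 4,
                       drift = c(bio10 = 0, bio11 = 0, bio16 = 0, bio17 = 0))
  st <- generateClimateStack(spec, seed = 7)
  for (a in 1:3)
    for (v in varNames(st))
      expect_identical(getSlice(st, a)@variables[[v]],
                       getSlice(st, 0)@variables[[v]])
  st2 <- generateClimateStack(spec, seed = 7)
  expect_identical(st@slices, st2@slices)
  st3 <- generateClimateStack(spec, seed = 8)
  expect_false(identical(getSlice(st, 0)@variables$bio10,
                         getSlice(st3, 0)@variables$bio10))
})

test_that("slice means drift linearly at the configured rate", {
  # temperatures only, so the precipitation floor never truncates the shift
  spec <- scenarioSpec(nrow = 20, ncol = 20, nSlices = 5,
                       drift = c(bio10 = 0.5, bio11 = -0.25),
                       variableMeans = c(bio10 = 24, bio11 = 12),
                       variableSds = c(bio10 = 3, bio11 = 4),
                       precipVars = character(0))
  st <- generateClimateStack(spec, seed = 3)
  m0 <- mean(getSlice(st, 0)@variables$bio10)
  m4 <- mean(getSlice(st, 4)@variables$bio10)
  expect_equal(m4 - m0, 2.0, tolerance = 1e-6)
  for (k in 0:4) {
    expect_equal(mean(getSlice(st, k)@variables$bio10) - m0, k * 0.5,
                 tolerance = 1e-6)
    expect_equal(mean(getSlice(st, k)@variables$bio11) -
                   mean(getSlice(st, 0)@variables$bio11), -0.25 * k,
                 tolerance = 1e-6)
  }
})

test_that("realized inter-variable correlation matches the target", {
  for (rho in c(0, 0.4, 0.65)) {
    spec <- scenarioSpec(nrow = 50, ncol = 50,
                         interVariableCorrelation = rho,
                         precipVars = character(0))  # no clipping distortion
    g0 <- getSlice(generateClimateStack(spec, seed = 11), 0)
    R <- cor(vapply(g0@variables, as.vector, numeric(2500)))
    off <- R[upper.tri(R)]
    expect_true(all(abs(off - rho) < 0.15))
    expect_true(all(abs(off - rho) < 1e-8))  # construction is exact
  }
})

test_that("precipitation-like variables are never negative", {
  spec <- scenarioSpec(nrow = 15, ncol = 15, nSlices = 6,
                       drift = c(bio10 = -1, bio11 = -1, bio16 = -200,
                                 bio17 = -40))
  st <- generateClimateStack(spec, seed = 5)
  for (a in ages(st)) {
    g <- getSlice(st, a)
    expect_true(all(g@variables$bio16 >= 0, na.rm = TRUE))
    expect_true(all(g@variables$bio17 >= 0, na.rm = TRUE))
  }
})

test_that("invalid scenario specs are rejected", {
  expect_error(scenarioSpec(nrow = 0, ncol = 10), "positive")
  expect_error(scenarioSpec(nrow = 2, ncol = 1), "4 cells")
  expect_error(virtualSpecies("x", c(a = 1), c(a = -1)), "positive")
})

test_that("true suitability follows the Gaussian closed form", {
  sp <- virtualSpecies("v", c(a = 10, b = 100), c(a = 2, b = 20),
                       maxSuitability = 0.9)
  expect_equal(trueSuitability(sp, c(a = 10, b = 100)), 0.9)
  # one dimension displaced by exactly one width
  expect_equal(trueSuitability(sp, c(a = 12, b = 100)), 0.9 * exp(-0.5))
  expect_equal(trueSuitability(sp, c(a = 10, b = 80)), 0.9 * exp(-0.5))
  # random vectors against an independent re-evaluation of the formula
  set.seed(42)
  for (i in 1:25) {
    env <- c(a = rnorm(1, 10, 4), b = rnorm(1, 100, 40))
    oracle <- 0.9 * exp(-0.5 * (((env[["a"]] - 10) / 2)^2 +
                                ((env[["b"]] - 100) / 20)^2))
    expect_equal(trueSuitability(sp, env), oracle)
  }
  expect_error(trueSuitability(sp, c(a = 1)), "dimension")
})

test_that("occurrence sampling draws distinct suitable cells", {
  g <- tinyGrid(values = matrix(c(0, 0, 0, 0, 0, 0, 10, 10, 10, 10, 10, 10),
                                3, 4))
  # niche so narrow that value-0 cells have suitability exactly 0 (underflow)
  sp <- virtualSpecies("v", c(bio10 = 10), c(bio10 = 0.1))
  occ <- sampleOccurrences(sp, g, 6, seed = 1)
  expect_equal(nrow(occPoints(occ)), 6L)
  env <- extractEnv(occ, g)
  expect_true(all(env$bio10 == 10))           # zero-suitability cells never drawn
  expect_equal(anyDuplicated(occPoints(occ)), 0L)
  expect_error(sampleOccurrences(sp, g, 7, seed = 1), "positive suitability")
})

test_that("per-cell sampling frequency tracks true suitability", {
  spec <- scenarioSpec(nrow = 50, ncol = 50, precipVars = character(0))
  g0 <- getSlice(generateClimateStack(spec, seed = 2), 0)
  sp <- virtualSpecies("v", spec@variableMeans, spec@variableSds)
  s <- trueSuitability(sp, vapply(g0@variables, as.vector, numeric(2500)))
  counts <- numeric(2500)
  for (r in 1:50) {
    occ <- sampleOccurrences(sp, g0, 2000, seed = r)
    rc <- paleoSDM:::cellRowCol(g0@origin, g0@cellSize, dim(g0@mask),
                                occPoints(occ)$lon, occPoints(occ)$lat)
    idx <- paleoSDM:::cellLinear(dim(g0@mask), rc)
    counts[idx] <- counts[idx] + 1
  }
  expect_gt(cor(counts, s, method = "spearman"), 0.8)
})

test_that("planted fossils satisfy their suitability constraints", {
  spec <- demoScenario(1, seed = 9)
  st <- generateClimateStack(spec)
  sp <- spec@species[[1]]
  f <- plantFossil(sp, st, 5, requireOutsideCurrent = TRUE, seed = 3)
  envK <- extractEnv(data.frame(lon = f@lon, lat = f@lat), getSlice(st, 5))
  env0 <- extractEnv(data.frame(lon = f@lon, lat = f@lat), getSlice(st, 0))
  expect_gte(trueSuitability(sp, as.numeric(envK[names(sp@nicheCenter)])),
             0.5 * sp@maxSuitability)
  expect_lt(trueSuitability(sp, as.numeric(env0[names(sp@nicheCenter)])),
            0.1 * sp@maxSuitability)
  expect_equal(c(f@ageMinBP, f@ageMaxBP), c(4900, 5100))

  # without the outside-current requirement only the past constraint binds
  f2 <- plantFossil(sp, st, 5, requireOutsideCurrent = FALSE, seed = 3)
  envK2 <- extractEnv(data.frame(lon = f2@lon, lat = f2@lat), getSlice(st, 5))
  expect_gte(trueSuitability(sp, as.numeric(envK2[names(sp@nicheCenter)])),
             0.5 * sp@maxSuitability)

  # stationary climate cannot host a fossil outside the current range
  spec0 <- spec
  spec0@drift[] <- 0
  st0 <- generateClimateStack(spec0, seed = 9)
  expect_error(plantFossil(sp, st0, 5, requireOutsideCurrent = TRUE, seed = 3),
               "drift")
})
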