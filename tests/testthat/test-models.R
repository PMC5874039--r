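# The three suitability algorithms and the shared prediction surface.

test_that("maxent with no signal yields a near-constant surface", {
  set.seed(1)
  bg <- data.frame(a = rnorm(500), b = rnorm(500))
  pres <- data.frame(a = rnorm(100), b = rnorm(100))  # same distribution
  m <- fitMaxent(pres, bg)
  g <- randomGrid(seed = 2, nr = 10, nc = 10, vars = c("a", "b"))
  v <- mapValues(predictMap(m, g))
  expect_lt(max(v) - min(v), 0.1)
})

test_that("maxent tracks a monotone presence signal", {
  set.seed(2)
  bg <- data.frame(a = rnorm(800), b = rnorm(800))
  # presences concentrated at high a, b pure noise
  pres <- data.frame(a = rnorm(150, 1.6, 0.5), b = rnorm(150))
  m <- fitMaxent(pres, bg)
  scan <- data.frame(a = seq(quantile(bg$a, 0.05), quantile(bg$a, 0.95),
                             length.out = 40), b = 0)
  p <- predictSuitability(m, scan)
  expect_true(all(diff(p) > -1e-8))
  expect_gt(p[40], p[1])
})

test_that("stronger maxent regularization shrinks the weights", {
  set.seed(3)
  bg <- data.frame(a = rnorm(600), b = rnorm(600))
  pres <- data.frame(a = rnorm(120, 1, 0.6), b = rnorm(120, -0.5, 0.8))
  l1 <- function(mult) {
    m <- fitMaxent(pres, bg, maxentSettings(regularizationMultiplier = mult))
    sum(abs(m@fit$weights))
  }
  norms <- vapply(c(1, 3, 10), l1, numeric(1))
  expect_true(all(diff(norms) <= 1e-8))
})

test_that("maxent refits are bit-for-bit reproducible", {
  set.seed(4)
  bg <- data.frame(a = rnorm(300), b = rnorm(300))
  pres <- data.frame(a = rnorm(60, 1), b = rnorm(60))
  m1 <- fitMaxent(pres, bg)
  m2 <- fitMaxent(pres, bg)
  expect_identical(m1@fit$weights, m2@fit$weights)
  newEnv <- data.frame(a = seq(-3, 3, 0.5), b = seq(3, -3, -0.5))
  expect_identical(predictSuitability(m1, newEnv),
                   predictSuitability(m2, newEnv))
})

test_that("glm recovers known quadratic-logistic coefficients", {
  truth <- c(`(Intercept)` = 0.4, a = 0.9, `a^2` = -0.6, b = -0.7,
             `b^2` = 0.3)
  set.seed(11)
  x <- data.frame(a = rnorm(2000), b = rnorm(2000))
  eta <- truth[1] + truth[2] * x$a + truth[3] * x$a^2 + truth[4] * x$b +
    truth[5] * x$b^2
  y <- rbinom(2000, 1, plogis(eta))
  m <- fitGlm(x[y == 1, ], x[y == 0, ])
  est <- glmCoefficients(m, "original")[names(truth)]
  expect_true(all(abs(est - truth) < 0.15))
})

test_that("glm on identical class distributions predicts the prevalence", {
  set.seed(12)
  pres <- data.frame(a = rnorm(1200), b = rnorm(1200))
  abs_ <- data.frame(a = rnorm(1800), b = rnorm(1800))
  m <- fitGlm(pres, abs_)
  p <- predictSuitability(m, data.frame(a = rnorm(200), b = rnorm(200)))
  expect_lt(mean(abs(p - 0.4)), 0.05)
  expect_true(all(abs(p - 0.4) < 0.15))
})

test_that("glm ranks a presence site above distant pseudo-absences", {
  pres <- data.frame(a = rep(2, 30) + rnorm(30, 0, 1e-3))
  abs_ <- data.frame(a = rnorm(100, -2, 0.3))
  m <- suppressWarnings(fitGlm(pres, abs_))
  expect_gt(predictSuitability(m, data.frame(a = 2)),
            predictSuitability(m, data.frame(a = -2)))
})

test_that("glm separation triggers the ridge fallback, not failure", {
  pres <- data.frame(a = rnorm(50, 5, 0.1))
  abs_ <- data.frame(a = rnorm(50, -5, 0.1))
  expect_warning(m <- fitGlm(pres, abs_), "ridge")
  p <- predictSuitability(m, data.frame(a = c(-5, 5)))
  expect_true(all(is.finite(p)) && p[2] > p[1])
})

test_that("random forest separates a separable toy set and stabilizes", {
  set.seed(13)
  pres <- data.frame(a = rnorm(100, 3, 0.5), b = rnorm(100, 3, 0.5))
  abs_ <- data.frame(a = rnorm(100, -3, 0.5), b = rnorm(100, -3, 0.5))
  m <- fitRf(pres, abs_, nTrees = 500, seed = 5)
  expect_true(all(predictSuitability(m, pres) > 0.9))
  expect_true(all(predictSuitability(m, abs_) < 0.1))
  # same seed twice -> identical predictions
  m2 <- fitRf(pres, abs_, nTrees = 500, seed = 5)
  grid <- expand.grid(a = seq(-4, 4, 0.5), b = seq(-4, 4, 0.5))
  expect_identical(predictSuitability(m, grid), predictSuitability(m2, grid))
  # 500 vs 1000 trees: predictions have stabilized
  m3 <- fitRf(pres, abs_, nTrees = 1000, seed = 5)
  expect_lt(mean(abs(predictSuitability(m, grid) -
                     predictSuitability(m3, grid))), 0.05)
  expect_error(fitRf(pres, abs_, nTrees = 0), "nTrees")
})

test_that("all algorithms stay within [0,1] under extreme extrapolation", {
  set.seed(14)
  pres <- data.frame(a = rnorm(60, 1), b = rnorm(60))
  bg <- data.frame(a = rnorm(400), b = rnorm(400))
  extreme <- data.frame(a = c(-1e3, 1e3, 0), b = c(1e3, -1e3, 1e6))
  for (m in list(fitMaxent(pres, bg), fitGlm(pres, bg),
                 fitRf(pres, bg, 100, seed = 1))) {
    p <- predictSuitability(m, extreme, clamp = FALSE)
    expect_true(all(p >= 0 & p <= 1))
    pc <- predictSuitability(m, extreme, clamp = TRUE)
    expect_true(all(pc >= 0 & pc <= 1))
  }
})

test_that("map prediction equals looped point prediction and keeps nodata", {
  mask <- matrix(TRUE, 7, 7); mask[2, c(2, 5)] <- FALSE
  g <- randomGrid(seed = 15, nr = 7, nc = 7, vars = c("a", "b"), mask = mask)
  set.seed(15)
  pres <- data.frame(a = rnorm(40, 0.5), b = rnorm(40))
  bg <- data.frame(a = rnorm(200), b = rnorm(200))
  m <- fitMaxent(pres, bg)
  mp <- predictMap(m, g, speciesId = "x")
  expect_equal(sum(is.na(mapValues(mp))), 2L)
  valid <- which(g@mask, arr.ind = TRUE)
  for (i in sample(nrow(valid), 10)) {
    rc <- valid[i, ]
    lonlat <- data.frame(lon = g@origin[1] + (rc[2] - 0.5) * g@cellSize,
                         lat = g@origin[2] - (rc[1] - 0.5) * g@cellSize)
    expect_equal(mapValues(mp)[rc[1], rc[2]],
                 predictSuitability(m, extractEnv(lonlat, g)))
  }
  # constant-environment grid gives a constant map
  gc <- tinyGrid(values = matrix(0.3, 4, 4), varName = "a")
  gc@variables$b <- matrix(-0.2, 4, 4)
  expect_equal(length(unique(as.vector(mapValues(predictMap(m, gc))))), 1L)
  gx <- tinyGrid(values = matrix(1, 3, 3), varName = "a")
  expect_error(predictMap(m, gx), "lacks model variable")
})
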