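# Fossil-based validation and taxonomic assignment.

test_that("age intervals map to the slices spanning them", {
  expect_equal(slicesForAge(c(13898, 13941), 0:130), c(13L, 14L))
  expect_equal(slicesForAge(c(11068, 11211), 0:130), 11L)
  expect_equal(slicesForAge(c(19980, 20250), 0:130), c(19L, 20L))
  expect_equal(slicesForAge(c(5000, 5001), 0:130), 5L)
  # nearest-slice fallback when the span catches no available age
  expect_equal(slicesForAge(c(5200, 5400), c(0L, 10L, 20L)), 10L)
  expect_equal(slicesForAge(c(100, 300), c(5L, 9L)), 5L)
  expect_error(slicesForAge(c(100, 300), integer(0)), "no available")
  expect_error(slicesForAge(c(300, 100), 0:10))
})

test_that("minimum occurrence suitability is the floor of the predictions", {
  g <- randomGrid(seed = 40, nr = 8, nc = 8, vars = c("a", "b"))
  set.seed(40)
  pres <- data.frame(a = rnorm(30, 1), b = rnorm(30))
  m <- fitGlm(pres, data.frame(a = rnorm(100), b = rnorm(100)))
  occ <- new("OccurrenceSet", speciesId = "x",
             points = data.frame(lon = c(1.5, 3.5, 6.5), lat = c(2.5, 5.5, 7.5)),
             provenance = character(0))
  expect_equal(minOccurrenceSuitability(m, occ, g),
               min(predictSuitability(m, extractEnv(occ, g))))
  one <- new("OccurrenceSet", speciesId = "x",
             points = data.frame(lon = 1.5, lat = 2.5),
             provenance = character(0))
  expect_equal(minOccurrenceSuitability(m, one, g),
               predictSuitability(m, extractEnv(one, g)))
  empty <- new("OccurrenceSet", speciesId = "x",
               points = data.frame(lon = numeric(0), lat = numeric(0)),
               provenance = character(0))
  expect_error(minOccurrenceSuitability(m, empty, g), "empty")
})

test_that("fossil-cell suitability uses containing-cell lookup", {
  const <- new("SuitabilityMap", values = matrix(0.3, 5, 5),
               origin = c(0, 5), cellSize = 1, age = 2L, speciesId = "x",
               algorithm = "glm")
  f <- new("FossilRecord", fossilId = "f1", lon = 2.2, lat = 3.7,
           ageMinBP = 1900, ageMaxBP = 2100, candidates = character(0))
  expect_equal(unname(suitabilityAtFossil(list(const), f)), 0.3)
  vals <- matrix(runif(25), 5, 5)
  peak <- which(vals == max(vals), arr.ind = TRUE)
  mp <- new("SuitabilityMap", values = vals, origin = c(0, 5), cellSize = 1,
            age = 2L, speciesId = "x", algorithm = "glm")
  fp <- new("FossilRecord", fossilId = "f2",
            lon = peak[1, "col"] - 0.5, lat = 5 - peak[1, "row"] + 0.5,
            ageMinBP = 1900, ageMaxBP = 2100, candidates = character(0))
  expect_equal(unname(suitabilityAtFossil(list(mp), fp)), max(vals))
  offMap <- new("FossilRecord", fossilId = "f3", lon = 99, lat = 0.5,
                ageMinBP = 1900, ageMaxBP = 2100, candidates = character(0))
  expect_error(suitabilityAtFossil(list(mp), offMap), "off the")
})

test_that("assignment recovers a planted fossil and respects the rules", {
  fx <- assignmentFixture(seed = 51)
  fossil <- plantFossil(fx$spec@species[[1]], fx$stack, 5, TRUE, seed = 51,
                        candidates = names(fx$occ))
  cands <- candidatesFor(fx, "maxent", seed = 51)
  rep <- assignFossil(cands, fossil, fx$stack)
  expect_equal(headline(rep), "species_a")
  pc <- perCandidate(rep)
  expect_true(pc$plausible[pc$species == "species_a"])
  # plausibility is exactly S >= m
  expect_equal(pc$plausible, pc$S >= pc$minOccSuit)
  # a candidate with S < m is implausible regardless of its S rank
  expect_true(all(!pc$plausible[pc$S < pc$minOccSuit]))
  # ranking contains plausible candidates sorted by S
  expect_equal(rep@ranking,
               pc$species[pc$plausible][order(-pc$S[pc$plausible])])
  # diagnostics carry one row per candidate and slice
  expect_equal(nrow(rep@diagnostics),
               length(cands) * length(rep@slicesEvaluated))

  # permutation invariance of the evidence (up to row order)
  rep2 <- assignFossil(rev(cands), fossil, fx$stack)
  pc2 <- perCandidate(rep2)
  expect_equal(pc2[order(pc2$species), ], pc[order(pc$species), ],
               ignore_attr = TRUE)
  expect_equal(headline(rep2), headline(rep))

  # no cross-candidate coupling: dropping a candidate changes nothing else
  rep3 <- assignFossil(cands[-2], fossil, fx$stack)
  pc3 <- perCandidate(rep3)
  expect_equal(pc3, pc[pc$species != "species_b", ], ignore_attr = TRUE)
})

test_that("single-candidate assignment degenerates to validation", {
  fx <- assignmentFixture(seed = 52, nSpecies = 1L)
  fossil <- plantFossil(fx$spec@species[[1]], fx$stack, 5, TRUE, seed = 52,
                        candidates = "species_a")
  cand <- candidatesFor(fx, "glm", seed = 52)
  rep <- assignFossil(cand, fossil, fx$stack)
  fossilV <- fossil
  fossilV@candidates <- character(0)
  v <- validateAgainstFossil(cand[[1]]$model, fx$occ[[1]], fossilV, fx$stack)
  expect_equal(perCandidate(rep)$S, v$S)
  expect_equal(perCandidate(rep)$minOccSuit, v$m)
  expect_equal(perCandidate(rep)$plausible, v$pass)
  expect_equal(headline(rep) == "species_a", v$pass)
  expect_error(validateAgainstFossil(cand[[1]]$model, fx$occ[[1]], fossil,
                                     fx$stack), "known identity")
})

test_that("validation fails gracefully at a never-suitable cell", {
  fx <- assignmentFixture(seed = 53, nSpecies = 1L)
  sp <- fx$spec@species[[1]]
  s0 <- paleoSDM:::trueSuitabilityGrid(sp, fx$g0)
  s5 <- paleoSDM:::trueSuitabilityGrid(sp, getSlice(fx$stack, 5))
  worst <- which.min(pmax(s0, s5))
  rc <- paleoSDM:::linearToRowCol(dim(s0), worst)
  xy <- paleoSDM:::cellCenters(fx$g0@origin, fx$g0@cellSize, rc)
  bad <- new("FossilRecord", fossilId = "bad", lon = xy[1, "lon"],
             lat = xy[1, "lat"], ageMinBP = 4900, ageMaxBP = 5100,
             candidates = character(0))
  m <- fitFor(fx, "species_a", "maxent", seed = 53)
  v <- validateAgainstFossil(m, fx$occ[[1]], bad, fx$stack)
  expect_false(v$pass)          # a verdict, not an error
  expect_lt(v$S, v$m)
})
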