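# Synthetic geometry, rasterisation and cohort generation.

test_that("degenerate spec yields concentric circles, deterministically", {
  spec <- geometrySpec(outerRadius = 500, innerRadius = 300,
                       outerHarmonics = data.frame(order = integer(),
                                                   amplitude = numeric(),
                                                   phase = numeric()),
                       innerHarmonics = data.frame(order = integer(),
                                                   amplitude = numeric(),
                                                   phase = numeric()),
                       ridgeAmplitude = 0)
  b <- makeBaselineGeometry(spec, n = 200, register = FALSE)
  expect_equal(sqrt(rowSums(contourCoords(b$periosteal)^2)), rep(500, 200))
  expect_equal(sqrt(rowSums(contourCoords(b$endosteal)^2)), rep(300, 200))
  jit <- list(outerAmp = c(), innerAmp = c())
  b1 <- makeBaselineGeometry(geometrySpec(), n = 200)
  b2 <- makeBaselineGeometry(geometrySpec(), n = 200)
  expect_identical(contourCoords(b1$periosteal), contourCoords(b2$periosteal))
})

test_that("the ridge produces one localised curvature maximum", {
  spec <- geometrySpec(outerHarmonics = data.frame(order = integer(),
                                                   amplitude = numeric(),
                                                   phase = numeric()),
                       innerHarmonics = data.frame(order = integer(),
                                                   amplitude = numeric(),
                                                   phase = numeric()),
                       ridgeAmplitude = 80)
  b <- makeBaselineGeometry(spec, n = 400, register = FALSE)
  k <- polylineCurvature(contourCoords(b$periosteal))
  circleK <- 1 / spec$outerRadius
  high <- which(k > 1.5 * circleK)
  expect_gt(length(high), 0)
  # the high-curvature points form one contiguous arc around the ridge
  idx <- sort(high)
  gaps <- diff(idx)
  expect_lte(sum(gaps > 1), 1)   # at most one wrap-around break
  # and the arc sits at the ridge (bottom of the section)
  expect_true(all(contourCoords(b$periosteal)[high, 2L] < 0))
})

test_that("invalid geometry is rejected", {
  spec <- geometrySpec(outerRadius = 430, innerRadius = 400)
  expect_error(makeBaselineGeometry(spec, n = 100), "thickness")
  expect_error(makeBaselineGeometry(
    geometrySpec(), jitter = list(innerRadius = -500), n = 100), "radius|thickness")
})

test_that("rasterisation reproduces the analytic annulus area", {
  peri <- circleContour(500, "periosteal", 400)
  endo <- circleContour(300, "endosteal", 400)
  sl <- rasterizeSection(peri, endo, 9.56)
  est <- sum(sliceGrid(sl)) * 9.56^2
  truth <- pi * (500^2 - 300^2)
  expect_lt(abs(est - truth) / truth, 0.01)
  # refinement: halving the pixel strictly reduces the area error
  sl2 <- rasterizeSection(peri, endo, 4.78)
  est2 <- sum(sliceGrid(sl2)) * 4.78^2
  expect_lt(abs(est2 - truth), abs(est - truth))
  # degenerate: a contour inside one pixel is rejected
  tiny <- surfaceContour(0.5 * cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)),
                         "periosteal")
  expect_error(rasterizeSection(tiny, tiny, 9.56), "single pixel")
})

test_that("null adaptation makes loaded and mirrored control slices agree", {
  spec <- cohortSpec(nMice = 2, loadLevels = 6,
                     shapeJitterSD = 0, phaseJitterSD = 0,
                     contourNoiseSD = 0, rotationJitterSD = 0, seed = 4,
                     truthParams = mechanostatParams("M1", kPT = 0, kSN = 0,
                                                     epsHomP = 1e9,
                                                     epsHomE = 1e9),
                     nPoints = 200)
  ch <- makeCohort(spec)
  m <- ch$groups$F6$mice[[1L]]
  expect_false(m$flagged)
  back <- mirrorControl(m$left)
  # identical up to rasterisation: only boundary pixels may differ, from
  # floating-point ties in the point-in-polygon test under reflection
  differing <- sum(xor(sliceGrid(back), sliceGrid(m$right)))
  expect_lt(differing / sum(sliceGrid(m$right)), 0.005)
  # stationary surfaces: only sub-resolution arc-resampling drift remains
  expect_lt(max(abs(m$truth$deltaEtaP)), 0.1)
  expect_lt(max(abs(m$truth$deltaEtaE)), 0.1)
})

test_that("disuse-only cohorts carry the closed-form ground truth", {
  spec <- cohortSpec(nMice = 2, loadLevels = 0, shapeJitterSD = 3,
                     phaseJitterSD = 0.02, contourNoiseSD = 0,
                     rotationJitterSD = 0, seed = 9, nPoints = 250)
  ch <- makeCohort(spec)
  for (m in ch$groups$F0$mice) {
    # periosteum untouched; endosteum resorbed by kSN x 21 days everywhere,
    # up to the interpolation tolerance of the distance measurement
    expect_lt(max(abs(m$truth$deltaEtaP)), 0.5)
    expect_lt(max(abs(m$truth$deltaEtaE + 1.398 * 21)), 0.5)
  }
})

test_that("cohorts are pure functions of their spec", {
  spec <- cohortSpec(nMice = 2, loadLevels = c(0, 10), seed = 5,
                     nPoints = 120)
  c1 <- makeCohort(spec)
  c2 <- makeCohort(spec)
  expect_identical(
    sliceGrid(c1$groups$F10$mice[[2L]]$right),
    sliceGrid(c2$groups$F10$mice[[2L]]$right))
  expect_identical(c1$groups$F0$mice[[1L]]$truth, c2$groups$F0$mice[[1L]]$truth)
  # a different seed jitters the shapes but keeps the mean geometry
  c3 <- makeCohort(cohortSpec(nMice = 2, loadLevels = c(0, 10), seed = 6,
                              nPoints = 120))
  expect_false(identical(sliceGrid(c1$groups$F0$mice[[1L]]$left),
                         sliceGrid(c3$groups$F0$mice[[1L]]$left)))
})

test_that("mean baseline geometry is stable across seeds", {
  meanOuter <- function(seed, nm) {
    spec <- cohortSpec(nMice = nm, loadLevels = 0, contourNoiseSD = 0,
                       rotationJitterSD = 0, seed = seed, nPoints = 100)
    ch <- makeCohort(spec)
    mean(vapply(ch$groups$F0$mice, function(m)
      mean(sqrt(rowSums(contourCoords(m$baseline$periosteal)^2))),
      numeric(1)))
  }
  m1 <- meanOuter(1, 12); m2 <- meanOuter(2, 12)
  # shape jitter SD is 5 um; group means should agree within sampling error
  expect_lt(abs(m1 - m2), 3 * 5 / sqrt(12) * sqrt(2))
})

test_that("measured cohorts recover the stored ground truth within a pixel", {
  spec <- cohortSpec(nMice = 3, loadLevels = 10, shapeJitterSD = 2,
                     phaseJitterSD = 0.01, contourNoiseSD = 1,
                     rotationJitterSD = 1, seed = 21, nPoints = 250)
  ch <- makeCohort(spec)
  g <- ch$groups$F10
  gs <- measureGroup(lapply(g$mice, function(m) m[c("left", "right")]),
                     n = 250)
  truthP <- colMeans(do.call(rbind, lapply(g$mice, function(m) m$truth$deltaEtaP)))
  truthE <- colMeans(do.call(rbind, lapply(g$mice, function(m) m$truth$deltaEtaE)))
  okP <- mean(abs(fieldMean(gs$deltaEtaP) - truthP) <= 9.56)
  okE <- mean(abs(fieldMean(gs$deltaEtaE) - truthE) <= 9.56)
  expect_gte(okP, 0.95)
  expect_gte(okE, 0.95)
})
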