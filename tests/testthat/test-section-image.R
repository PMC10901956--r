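# Binarisation, cavity filling, contour extraction, registration,
# mirroring, fine alignment and resampling.

makeAnnulusGrid <- function(R = 500, r = 300, ps = 9.56, hi = 200, lo = 50) {
  half <- ceiling((R + 3 * ps) / ps)
  xs <- (-half:half) * ps
  d2 <- outer(xs^2, xs^2, `+`)
  g <- matrix(lo, length(xs), length(xs))
  g[d2 <= R^2 & d2 >= r^2] <- hi
  list(gray = g, origin = c(xs[1L], xs[1L]), ps = ps)
}

test_that("Otsu threshold separates a bimodal image and keeps binary input", {
  a <- makeAnnulusGrid()
  sl <- binarizeOtsu(a$gray, a$ps, a$origin)
  expect_identical(sliceGrid(sl), a$gray > 125)
  b <- matrix(c(0, 255, 255, 0), 2, 2)
  expect_identical(sliceGrid(binarizeOtsu(b)), b == 255)
  expect_error(binarizeOtsu(matrix(7, 4, 4)), "uniform")
})

test_that("Otsu binarisation is robust to moderate intensity noise", {
  a <- makeAnnulusGrid()
  clean <- sum(a$gray > 125)
  set.seed(7)
  noisy <- a$gray + rnorm(length(a$gray), 0, 10)
  got <- sum(sliceGrid(binarizeOtsu(noisy, a$ps, a$origin)))
  expect_lt(abs(got - clean) / clean, 0.02)
})

test_that("cavity filling removes cortical voids but keeps the marrow", {
  a <- makeAnnulusGrid()
  g <- a$gray > 125
  ctr <- (nrow(g) + 1) / 2
  mid <- round(400 / a$ps)              # radial offset well inside the cortex
  g2 <- g
  g2[ctr + mid + 0:1, ctr] <- FALSE     # three 2-pixel holes
  g2[ctr - mid - 0:1, ctr] <- FALSE
  g2[ctr, ctr + mid + 0:1] <- FALSE
  filled <- fillCavities(binarySlice(g2, a$ps, a$origin))
  expect_identical(sliceGrid(filled), g)
  # clean annulus is returned unchanged
  expect_identical(sliceGrid(fillCavities(binarySlice(g, a$ps, a$origin))), g)
  # exactly one interior background component remains
  lab <- EBImage::bwlabel(!sliceGrid(filled))
  border <- setdiff(unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1],
                             lab[, ncol(lab)])), 0)
  expect_length(setdiff(setdiff(unique(as.vector(lab)), 0), border), 1L)
  # a solid disc has no cavity at all
  half <- (nrow(g) - 1) / 2
  xs <- (-half:half) * a$ps
  disc <- outer(xs^2, xs^2, `+`) <= 500^2
  expect_warning(fillCavities(binarySlice(disc, a$ps, a$origin)),
                 "no interior cavity")
})

test_that("contour extraction recovers radii and areas of a known annulus", {
  a <- makeAnnulusGrid()
  sl <- binarizeOtsu(a$gray, a$ps, a$origin)
  ct <- extractContours(sl)
  rP <- sqrt(rowSums(contourCoords(ct$periosteal)^2))
  rE <- sqrt(rowSums(contourCoords(ct$endosteal)^2))
  expect_lt(abs(mean(rP) - 500), a$ps)
  expect_lt(abs(mean(rE) - 300), a$ps)
  expect_true(all(rE < min(rP)))
  # polygon area of the periosteal contour vs bone+marrow pixel area
  pixArea <- sum(sliceGrid(sl) | (outer(((seq_len(nrow(sliceGrid(sl))) - 1) * a$ps + a$origin[1L])^2,
                                        ((seq_len(ncol(sliceGrid(sl))) - 1) * a$ps + a$origin[2L])^2,
                                        `+`) < 300^2)) * a$ps^2
  polyArea <- abs(sum(contourCoords(ct$periosteal)[, 1L] *
                        c(contourCoords(ct$periosteal)[-1L, 2L],
                          contourCoords(ct$periosteal)[1L, 2L]) -
                      c(contourCoords(ct$periosteal)[-1L, 1L],
                        contourCoords(ct$periosteal)[1L, 1L]) *
                        contourCoords(ct$periosteal)[, 2L]) / 2)
  expect_lt(abs(polyArea - pixArea) / pixArea, 0.01)
})

test_that("registration aligns the minimal-inertia axis with y", {
  # elongated elliptical cortex rotated 30 degrees off axis
  th <- -pi / 2 - 2 * pi * (0:399) / 400
  a <- 500; b <- 320
  rot <- 30 * pi / 180
  R <- matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2)
  po <- cbind(a * cos(th), b * sin(th)) %*% t(R)
  pi_ <- cbind(0.6 * a * cos(th), 0.6 * b * sin(th)) %*% t(R)
  reg <- registerSection(surfaceContour(po, "periosteal"),
                         surfaceContour(pi_, "endosteal"))
  pr <- sectionProperties(reg$periosteal, reg$endosteal)
  I <- secondMoments(pr)
  expect_lt(abs(I["Ixy"]), 1e-6 * max(I["Ixx"], I["Iyy"]))
  # long axis along y: spread in y exceeds spread in x
  expect_gt(diff(range(contourCoords(reg$periosteal)[, 2L])),
            diff(range(contourCoords(reg$periosteal)[, 1L])))
  # marrow centroid at the origin
  ic <- MechanoCT:::.polygonCentroid(contourCoords(reg$endosteal))
  expect_lt(max(abs(ic)), 1e-9)
  # idempotence: re-registering is the identity up to numerical noise
  reg2 <- registerSection(reg$periosteal, reg$endosteal)
  expect_lt(abs(reg2$transform$rotation_deg) %% 180, 1e-6)
  expect_lt(max(abs(contourCoords(reg2$periosteal) -
                    contourCoords(reg$periosteal))), 1e-6)
})

test_that("mirroring is an involution that preserves orientation", {
  b <- makeBaselineGeometry(geometrySpec(), n = 200)
  m2 <- mirrorControl(mirrorControl(b$periosteal))
  expect_equal(contourCoords(m2), contourCoords(b$periosteal))
  m1 <- mirrorControl(b$periosteal)
  expect_lt(MechanoCT:::.signedArea(contourCoords(m1)), 0)  # still clockwise
  expect_identical(limbLabel(m1), "L")
  # an asymmetric feature flips sides
  pts <- contourCoords(b$periosteal)
  iR <- which.max(pts[, 1L])
  expect_equal(min(contourCoords(m1)[, 1L]), -max(pts[, 1L]))
  # slices mirror consistently with contours
  sl <- rasterizeSection(b$periosteal, b$endosteal)
  expect_identical(sliceGrid(mirrorControl(mirrorControl(sl))), sliceGrid(sl))
})

test_that("fine alignment recovers a known relative rotation", {
  b <- makeBaselineGeometry(geometrySpec(), n = 300)
  rot3 <- lapply(b, function(ct)
    surfaceContour(MechanoCT:::.rotatePts(contourCoords(ct), 3 * pi / 180),
                   surfaceLabel(ct)))
  fa <- fineAlign(b, rot3)
  expect_equal(fa$angleDeg, 3, tolerance = 0.1 / 3)
  # identical pairs need no rotation, and the optimum beats angle zero
  fa0 <- fineAlign(b, b)
  expect_equal(fa0$angleDeg, 0)
  expect_lte(fa$objective,
             MechanoCT:::.symmDiffArea(contourCoords(rot3$periosteal),
                                       contourCoords(rot3$endosteal),
                                       contourCoords(b$periosteal),
                                       contourCoords(b$endosteal)))
})

test_that("resampling enforces spacing, origin and orientation conventions", {
  peri <- circleContour(300, "periosteal", 500)
  pts <- contourCoords(peri)
  expect_equal(pts[1L, ], c(0, -300), tolerance = 1e-9)
  P <- positionGrid(peri)
  expect_equal(P, (0:499) / 500)
  seg <- sqrt(rowSums((pts[c(2:500, 1L), ] - pts)^2))
  expect_lt(diff(range(seg)) / mean(seg), 0.01)
  # P = 0.5 sits at the top of the circle under the clockwise convention
  expect_equal(pts[251L, ], c(0, 300),
               tolerance = 2 * pi * 300 / 500 / 300)
  expect_error(resampleContour(peri, 5), "at least 8")
})
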