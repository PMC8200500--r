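test_that("field edges are located with sub-pixel accuracy", {
  plan <- buildOpenFieldPlan(c(100, 100))
  img <- renderOpenField(plan, fastConfig(), noiseless())
  e <- detectFieldEdges(img)
  expect_all_near(e, c(X1 = -50, X2 = 50, Y1 = -50, Y2 = 50), 0.1)
  ## translation equivariance
  shifted <- buildOpenFieldPlan()
  for (b in seq_along(shifted@beams))
    for (i in 1:2) {
      shifted@beams[[b]]$control_points[[i]]$jaws[["X1"]] <- -47
      shifted@beams[[b]]$control_points[[i]]$jaws[["X2"]] <- 53
    }
  es <- detectFieldEdges(renderOpenField(shifted, fastConfig(), noiseless()))
  expect_all_near(es[c("X1", "X2")], c(-47, 53), 0.1)
  ## flat image: detection error
  flat <- EPIDImage(matrix(0.5, 64, 64), pixelSpacing = 1)
  expect_error(detectFieldEdges(flat), "detection error")
})

test_that("the junction statistic matches its closed form and invariances", {
  expect_equal(junctionStatistic(100, 10, 100), 0)
  expect_equal(junctionStatistic(10, 10, 100), -1)
  expect_equal(junctionStatistic(80, 10, 100), 70 / 90 - 1)
  expect_error(junctionStatistic(80, 100, 100), "degenerate")
  ## affine invariance: I -> g*I + c leaves the statistic unchanged
  set.seed(42)
  for (k in 1:25) {
    i <- sort(runif(3, 0, 100))  # bg < junc < rad
    g <- runif(1, 0.1, 10); c0 <- runif(1, -50, 50)
    expect_equal(
      junctionStatistic(g * i[2] + c0, g * i[1] + c0, g * i[3] + c0),
      junctionStatistic(i[2], i[1], i[3]), tolerance = 1e-9)
  }
})

test_that("junction analysis flags 4 mm gaps and overlaps but passes 0 mm", {
  plan <- buildJunctionPlan()
  cfg <- fastConfig()
  r0 <- analyzeJunction(renderJunctionImage(plan, cfg, noiseless()), plan)
  expect_lt(abs(r0@worst), 0.1)
  expect_true(isPass(r0))
  expect_named(r0@values, c("vertical", "horizontal"))
  rov <- analyzeJunction(
    renderJunctionImage(plan, cfg, noiseless(junctionError = -4)), plan)
  expect_gt(rov@worst, 0.3)
  expect_false(isPass(rov))
  rgp <- analyzeJunction(
    renderJunctionImage(plan, cfg, noiseless(junctionError = 4)), plan)
  expect_lt(rgp@worst, -0.3)
  expect_false(isPass(rgp))
  ## monotonicity: the statistic strictly decreases from overlap to gap
  vals <- vapply(seq(-4, 4, by = 2), function(e)
    analyzeJunction(renderJunctionImage(plan, cfg,
      noiseless(junctionError = e)), plan)@values[["vertical"]], numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("BB detection is accurate, shape-selective and edge-aware", {
  plan <- buildLightRadPlan()
  cfg <- studyConfig()
  img <- renderLightRadImage(plan, cfg, noiseless())
  bbs <- detectBBs(img)
  expect_equal(nrow(bbs), 8)
  expect_true(all(bbs$roundness > 0.9))
  ## a square attenuator of matching size is rejected by roundness
  base <- renderOpenField(buildOpenFieldPlan(c(100, 100)), cfg, noiseless())
  px <- pixelData(base)
  co <- isoCoords(base)
  sq <- outer(abs(co$y) < 4, abs(co$x - 20) < 4, "&")
  px[sq] <- px[sq] * 0.75
  sq_img <- EPIDImage(px, pixelSpacing(base), sid = base@sid, sad = base@sad)
  expect_equal(nrow(detectBBs(sq_img, expectedRadiusMm = 4.5)), 0)
  ## while a disk of the same size is kept
  px2 <- pixelData(base)
  disk <- sqrt(outer(co$y^2, (co$x - 20)^2, "+")) < 4.5
  px2[disk] <- px2[disk] * 0.75
  dk_img <- EPIDImage(px2, pixelSpacing(base), sid = base@sid, sad = base@sad)
  expect_equal(nrow(detectBBs(dk_img, expectedRadiusMm = 4.5)), 1)
  ## a BB straddling the field edge is not returned
  str <- renderLightRadImage(plan, cfg, noiseless(phantomShift = c(5, 0)))
  fs <- detectBBs(str)
  expect_equal(nrow(fs), 7)
  expect_true(all(fs$x < 49))
})

test_that("light-rad deviations follow the projection oracle", {
  plan <- buildLightRadPlan()
  cfg <- studyConfig()
  r <- analyzeLightRad(renderLightRadImage(plan, cfg, noiseless()), plan)
  expect_equal(r@detectedCount, 8L)
  expect_all_near(r@deviations, 0, 0.2)
  expect_true(isPass(r))
  ## SSD 1050: inner BBs project to 45 * sad/ssd from the axis, so the
  ## edge distance grows to 50 - 45*1000/1050 and the test fails at 2 mm
  rm <- analyzeLightRad(renderLightRadImage(plan, cfg, noiseless(ssd = 1050)),
                        plan)
  oracle <- (50 - 45 * 1000 / 1050) - 5
  expect_all_near(rm@deviations, oracle, 0.2)
  expect_false(isPass(rm))
  ## +2 mm phantom shift: right-side inner BB closes in, left side opens up
  rs <- analyzeLightRad(
    renderLightRadImage(plan, cfg, noiseless(phantomShift = c(2, 0))), plan)
  right <- rs@bbCenters$inner & rs@bbCenters$x > 40
  left <- rs@bbCenters$inner & rs@bbCenters$x < -40
  expect_all_near(rs@bbCenters$edge_distance_mm[right] - 5, -2, 0.2)
  expect_all_near(rs@bbCenters$edge_distance_mm[left] - 5, 2, 0.2)
})

test_that("picket-fence analysis recovers spacing and injected offsets", {
  plan <- buildPicketFencePlan()
  cfg <- studyConfig()
  r <- analyzePicketFence(renderPicketFenceImage(plan, cfg, noiseless()),
                          plan)
  expect_all_near(r@perGapSpacing, 15, 0.1)
  expect_equal(r@percentPassing, 100)
  expect_true(isPass(r))
  ## uniform +2 mm: deviation (expected - measured) is -2, nothing passes
  r2 <- analyzePicketFence(
    renderPicketFenceImage(plan, cfg,
      ErrorModel(leafOffset = 2, noiseSigma = 0.01, seed = 5)), plan)
  expect_all_near(mean(r2@deviation[r2@detected]), -2, 0.1)
  expect_equal(r2@percentPassing, 0)
  ## offset recovery across the error-injection grid at 1% noise
  for (o in c(-1.5, -0.5, 0.5, 1, 2)) {
    ri <- analyzePicketFence(
      renderPicketFenceImage(plan, cfg,
        ErrorModel(leafOffset = o, noiseSigma = 0.01, seed = 50 + o * 2)),
      plan)
    expect_lt(abs(mean(ri@deviation[ri@detected]) + o), 0.15)
  }
})

test_that("the VMAT band statistic matches hand arithmetic and is scale-free", {
  ## synthetic images realizing corrected readings (1, 1, 1.02, 0.98)
  rois <- lapply(0:3, function(b)
    c(x1 = -40 + b * 20 + 2, x2 = -40 + b * 20 + 18, y1 = -30, y2 = 30))
  mk <- function(vals) {
    px <- matrix(1, 128, 128)
    img <- EPIDImage(px, pixelSpacing = 1, sid = 1000, sad = 1000)
    co <- isoCoords(img)
    for (b in seq_along(vals)) {
      rows <- co$y >= rois[[b]][["y1"]] & co$y <= rois[[b]][["y2"]]
      cols <- co$x >= rois[[b]][["x1"]] & co$x <= rois[[b]][["x2"]]
      px[rows, cols] <- vals[b]
    }
    EPIDImage(px, pixelSpacing = 1, sid = 1000, sad = 1000)
  }
  open <- mk(c(1, 1, 1, 1))
  test <- mk(c(1, 1, 1.02, 0.98))
  r <- analyzeVmatBands(test, open, rois)
  expect_equal(r@corrected, c(1, 1, 1.02, 0.98))
  expect_equal(r@percentDiff, c(0, 0, 2, -2), tolerance = 1e-9)
  expect_equal(r@diffAbs, 1.0, tolerance = 1e-9)
  expect_false(isPass(r))  # 2% exceeds the 1.5% band tolerance
  ## identical bands pass with all-zero differences
  r0 <- analyzeVmatBands(open, open, rois)
  expect_equal(r0@percentDiff, rep(0, 4))
  expect_true(isPass(r0))
  ## invariance under separate global scalings of test and open image
  test2 <- EPIDImage(pixelData(test) * 1.07, pixelSpacing = 1,
                     sid = 1000, sad = 1000)
  open2 <- EPIDImage(pixelData(open) * 0.6, pixelSpacing = 1,
                     sid = 1000, sad = 1000)
  r2 <- analyzeVmatBands(test2, open2, rois)
  expect_equal(r2@percentDiff, r@percentDiff, tolerance = 1e-9)
  ## signed percent differences always average to zero
  expect_lt(abs(mean(r2@percentDiff)), 1e-9)
})

test_that("Winston-Lutz offsets are measured from field center to BB", {
  plan <- buildWinstonLutzPlan()
  cfg <- wlConfig()
  r0 <- analyzeWinstonLutz(renderWinstonLutzImage(plan, cfg, noiseless()))
  expect_lt(r0@magnitude, 0.1)
  r1 <- analyzeWinstonLutz(
    renderWinstonLutzImage(plan, cfg, noiseless(phantomShift = c(1, 0))))
  expect_all_near(r1@offset, c(1, 0), 0.1)
  expect_equal(r1@magnitude, sqrt(sum(r1@offset^2)))
  ## open field without a BB: detection error
  open <- renderOpenField(buildOpenFieldPlan(c(20, 20)), cfg, noiseless())
  expect_error(analyzeWinstonLutz(open), "detection error")
})
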