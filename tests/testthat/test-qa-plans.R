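test_that("MLC models validate their geometry", {
  mlc <- millennium120()
  expect_equal(nPairs(mlc), 60L)
  expect_equal(range(leafBoundaries(mlc)), c(-200, 200))
  ## 10 x 10 mm, 40 x 5 mm, 10 x 10 mm
  expect_equal(as.vector(table(diff(leafBoundaries(mlc)))), c(40L, 20L))
  expect_error(MLCModel(c(0, 0, 10)), "strictly increasing")
  expect_error(MLCModel(c(5, 0)), "strictly increasing|2 leaf pairs")
})

test_that("open-field builder produces symmetric static jaws", {
  plan <- buildOpenFieldPlan(c(100, 100))
  cps <- beams(plan)[[1]]$control_points
  expect_length(cps, 2)
  expect_equal(cps[[1]]$jaws, c(X1 = -50, X2 = 50, Y1 = -50, Y2 = 50))
  ## MLC fully retracted
  expect_true(all(cps[[1]]$mlc_a <= -200))
  expect_true(all(cps[[1]]$mlc_b >= 200))
  expect_error(buildOpenFieldPlan(c(0, 100)), "positive")
  expect_error(buildOpenFieldPlan(c(450, 100)), "200")
})

test_that("junction builder places abutting half fields with signed errors", {
  exact <- buildJunctionPlan(junctionError = 0)
  b <- beams(exact)
  ## vertical pair shares x = 0 exactly
  expect_equal(b[[1]]$control_points[[1]]$jaws[["X2"]], 0)
  expect_equal(b[[2]]$control_points[[1]]$jaws[["X1"]], 0)
  ## +2 mm: unirradiated 2 mm gap between the nominal edges
  gap <- beams(buildJunctionPlan(junctionError = 2))
  expect_equal(gap[[2]]$control_points[[1]]$jaws[["X1"]] -
               gap[[1]]$control_points[[1]]$jaws[["X2"]], 2)
  ## -4 mm: 4 mm double-exposed overlap
  ov <- beams(buildJunctionPlan(junctionError = -4))
  expect_equal(ov[[1]]$control_points[[1]]$jaws[["X2"]] -
               ov[[2]]$control_points[[1]]$jaws[["X1"]], 4)
  expect_error(buildJunctionPlan(junctionError = 12), "<= 10")
})

test_that("picket-fence builder: expected centers form an arithmetic sequence", {
  plan <- buildPicketFencePlan()
  pk <- planMeta(plan)$picket
  expect_length(pk$centers_mm, 9)
  expect_equal(diff(pk$centers_mm), rep(15, 8))
  ## delivered slit centers equal expected when no offset is injected
  cps <- beams(plan)[[1]]$control_points
  act <- seq.int(pk$active_pairs[1], pk$active_pairs[2])
  slit_centers <- vapply(seq(1, 17, by = 2), function(i)
    mean(c(cps[[i]]$mlc_a[act[1]], cps[[i]]$mlc_b[act[1]])), numeric(1))
  expect_equal(slit_centers, pk$centers_mm)
  ## uniform +2 mm offset moves every delivered slit, not the expectation
  off <- buildPicketFencePlan(leafOffsets = 2)
  cps2 <- beams(off)[[1]]$control_points
  slit2 <- vapply(seq(1, 17, by = 2), function(i)
    mean(c(cps2[[i]]$mlc_a[act[1]], cps2[[i]]$mlc_b[act[1]])), numeric(1))
  expect_equal(slit2, pk$centers_mm + 2)
  expect_equal(planMeta(off)$picket$centers_mm, pk$centers_mm)
  expect_error(buildPicketFencePlan(leafOffsets = c(1, 2, 3)), "length")
  expect_error(buildPicketFencePlan(PicketFenceSpec(nPickets = 9,
                                                    spacing = 50)),
               "jaw aperture")
})

test_that("Winston-Lutz builder emits one small field per angle combo", {
  plan <- buildWinstonLutzPlan()
  expect_length(beams(plan), 4)
  cp <- beams(plan)[[2]]$control_points[[1]]
  expect_equal(cp$gantry_deg, 90)
  expect_equal(cp$jaws, c(X1 = -10, X2 = 10, Y1 = -10, Y2 = 10))
  expect_error(
    buildWinstonLutzPlan(data.frame(gantry = 0, collimator = 0, couch = 370)),
    "\\[0, 360\\)")
  expect_error(buildWinstonLutzPlan(data.frame()), "at least one")
})

test_that("VMAT builders follow the cardinal-angle and band layout", {
  t1 <- buildVmatPlan("t1_static_dmlc")
  expect_length(beams(t1), 4)
  g <- vapply(beams(t1), function(b) b$control_points[[1]]$gantry_deg,
              numeric(1))
  expect_equal(g, c(0, 90, 180, 270))

  t2 <- buildVmatPlan("t2_doserate_gantry")
  rois <- planMeta(t2)$bands$rois
  expect_length(rois, 7)
  ## ROIs disjoint and ordered left to right across the aperture
  x1 <- vapply(rois, `[[`, numeric(1), "x1")
  x2 <- vapply(rois, `[[`, numeric(1), "x2")
  expect_true(all(x2[-7] <= x1[-1] + 1e-9))

  t3 <- buildVmatPlan("t3_mlc_speed")
  expect_length(planMeta(t3)$bands$rois, 4)
  expect_error(buildVmatPlan("t2_doserate_gantry", bandCount = 1), ">= 2")

  err <- buildVmatPlan("t1_rotating_picket", injectMlcErrors = TRUE)
  me <- planMeta(err)$mlc_error
  nominal <- beams(err)[[5]]$control_points[[1]]  # clean arc
  injected <- beams(err)[[me$beam]]$control_points[[1]]
  delta <- injected$mlc_a - nominal$mlc_a
  expect_equal(which(abs(delta) > 1e-9), me$pairs)
  expect_equal(unique(delta[me$pairs]), me$offset_mm)
})

test_that("control-point resampling bounds spacing and preserves nodes", {
  p <- buildOpenFieldPlan()
  p@beams[[1]]$control_points[[2]]$gantry_deg <- 180
  r <- resampleControlPoints(p, maxGantryDeg = 2)
  cps <- r@beams[[1]]$control_points
  expect_length(cps, 91)  # ceil(180/2) + 1
  g <- vapply(cps, `[[`, numeric(1), "gantry_deg")
  expect_true(all(diff(g) <= 2 + 1e-9))
  expect_equal(g[c(1, 91)], c(0, 180))
  ## idempotent once the bound is met
  r2 <- resampleControlPoints(r, maxGantryDeg = 2)
  expect_equal(r2, r)
  ## identity when the bound is already satisfied
  expect_equal(resampleControlPoints(p, maxGantryDeg = 400), p)
  ## interpolated leaf trajectories pass through the original values at
  ## the original meterset nodes (sliding beam: strictly increasing w)
  pf <- buildVmatPlan("t1_static_dmlc")
  rf <- resampleControlPoints(pf, maxWeight = 0.02)
  w0 <- vapply(beams(pf)[[1]]$control_points, `[[`, numeric(1),
               "meterset_weight")
  wr <- vapply(beams(rf)[[1]]$control_points, `[[`, numeric(1),
               "meterset_weight")
  for (i in seq_along(w0)) {
    j <- which(abs(wr - w0[i]) < 1e-9)
    expect_length(j, 1)
    expect_equal(beams(rf)[[1]]$control_points[[j]]$mlc_a,
                 beams(pf)[[1]]$control_points[[i]]$mlc_a, tolerance = 1e-9)
  }
})

test_that("plan validity rejects inconsistent control points", {
  p <- buildOpenFieldPlan()
  bad <- p
  bad@beams[[1]]$control_points[[1]]$meterset_weight <- 0.5
  expect_error(validObject(bad), "start at 0")
  bad2 <- p
  bad2@beams[[1]]$control_points[[1]]$mlc_a[3] <- 500
  expect_error(validObject(bad2), "bank A")
  bad3 <- p
  bad3@beams[[1]]$control_points[[2]]$jaws[["X1"]] <- 60
  expect_error(validObject(bad3), "X1 <= X2")
})
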