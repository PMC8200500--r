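test_that("open-field renders have unit plateau, erf edges and seeded noise", {
  plan <- buildOpenFieldPlan(c(100, 100))
  img <- renderOpenField(plan, fastConfig(), noiseless())
  co <- isoCoords(img)
  cax <- caxPixel(img)
  expect_equal(pixelData(img)[round(cax[1]), round(cax[2])], 1.0)
  ## 50% crossing sits on the jaw position
  prof <- pixelData(img)[round(cax[1]), ]
  thr <- 0.02 + 0.5 * (1 - 0.02)
  i <- max(which(prof >= thr))
  x50 <- approx(prof[c(i, i + 1)], co$x[c(i, i + 1)], xout = thr)$y
  expect_lt(abs(x50 - 50), 0.1)
  ## determinism per seed
  e <- ErrorModel(noiseSigma = 0.02, seed = 11)
  expect_identical(pixelData(renderOpenField(plan, fastConfig(), e)),
                   pixelData(renderOpenField(plan, fastConfig(), e)))
  e2 <- ErrorModel(noiseSigma = 0.02, seed = 12)
  expect_false(identical(pixelData(renderOpenField(plan, fastConfig(), e)),
                         pixelData(renderOpenField(plan, fastConfig(), e2))))
})

test_that("abutting junction fields are erf-complementary", {
  plan <- buildJunctionPlan(axes = "vertical", junctionError = 0)
  cfg <- fastConfig()
  img <- renderJunctionImage(plan, cfg, noiseless())
  co <- isoCoords(img)
  mid <- which(abs(co$y) < 20)
  prof <- colMeans(pixelData(img)[mid, ])
  plateau <- mean(prof[abs(co$x) > 15 & abs(co$x) < 45])
  junc <- prof[which.min(abs(co$x))]
  expect_lt(abs(junc - plateau) / plateau, 0.02)
  ## -4 mm overlap: double exposure at the junction (erf shoulders keep
  ## the peak just below the ideal 2x)
  ov <- renderJunctionImage(plan, cfg, noiseless(junctionError = -4))
  provf <- colMeans(pixelData(ov)[mid, ])
  expect_gt(provf[which.min(abs(co$x))], 1.7 * plateau)
  ## +4 mm gap drops below half the plateau
  gp <- renderJunctionImage(plan, cfg, noiseless(junctionError = 4))
  profg <- colMeans(pixelData(gp)[mid, ])
  expect_lt(profg[which.min(abs(co$x))], 0.5 * plateau)
})

test_that("light-rad renders put BBs at projected phantom positions", {
  plan <- buildLightRadPlan()
  cfg <- studyConfig()
  nominal <- planMeta(plan)$lightrad$bb
  img <- renderLightRadImage(plan, cfg, noiseless())
  found <- detectBBs(img)
  expect_equal(nrow(found), 8)
  for (i in seq_len(8)) {
    d <- sqrt((found$x - nominal$x[i])^2 + (found$y - nominal$y[i])^2)
    expect_lt(min(d), 0.2)
  }
  ## SSD 975 magnifies the BB pattern by sad/ssd, edges unmoved
  mag <- renderLightRadImage(plan, cfg, noiseless(ssd = 975))
  fm <- detectBBs(mag)
  r_nom <- sort(sqrt(found$x^2 + found$y^2))
  r_mag <- sort(sqrt(fm$x^2 + fm$y^2))
  expect_all_near(r_mag, r_nom * 1000 / 975, 0.25)
  expect_all_near(detectFieldEdges(mag), detectFieldEdges(img), 0.15)
  ## phantom shift moves the BBs, not the field
  sh <- renderLightRadImage(plan, cfg, noiseless(phantomShift = c(2, 0)))
  fs <- detectBBs(sh)
  expect_all_near(sort(fs$x), sort(found$x + 2), 0.2)
  expect_all_near(detectFieldEdges(sh), detectFieldEdges(img), 0.15)
})

test_that("picket-fence renders place stripes at delivered slit centers", {
  plan <- buildPicketFencePlan()
  cfg <- studyConfig()
  centers <- planMeta(plan)$picket$centers_mm
  img <- renderPicketFenceImage(plan, cfg, noiseless())
  co <- isoCoords(img)
  mid <- which(abs(co$y) < 30)
  prof <- colMeans(pixelData(img)[mid, ])
  for (ck in centers) {
    win <- which(abs(co$x - ck) <= 7)
    expect_lt(abs(co$x[win[which.max(prof[win])]] - ck), 0.5 + 1e-9)
  }
  ## uniform +2 mm leaf offset displaces every stripe by +2
  off <- renderPicketFenceImage(plan, cfg, noiseless(leafOffset = 2))
  profo <- colMeans(pixelData(off)[mid, ])
  for (ck in centers) {
    win <- which(abs(co$x - (ck + 2)) <= 7)
    expect_lt(abs(co$x[win[which.max(profo[win])]] - (ck + 2)), 0.5 + 1e-9)
  }
  ## per-pair offset moves only that pair's row band
  act <- planMeta(plan)$picket$active_pairs
  offs <- rep(0, act[2] - act[1] + 1); offs[10] <- 1.5
  one <- renderPicketFenceImage(plan, cfg, noiseless(leafOffset = offs))
  r <- analyzePicketFence(one, plan)
  moved <- which(rowMeans(abs(r@deviation)) > 0.5)
  expect_equal(r@pairs[moved], (act[1]:act[2])[10])
})

test_that("band renders scale each band by its perturbation only", {
  plan <- buildVmatPlan("t3_mlc_speed")
  cfg <- fastConfig()
  open <- renderOpenField(plan, cfg, noiseless())
  flat <- renderBandImage(plan, cfg, noiseless())
  r0 <- analyzeVmatBands(flat, open, plan)
  expect_all_near(r0@percentDiff, 0, 0.05)
  pert <- c(1, 1.02, 1, 1)
  bump <- renderBandImage(plan, cfg, noiseless(bandPerturbation = pert))
  r1 <- analyzeVmatBands(bump, open, plan)
  expect_gt(r1@corrected[2] / mean(r1@corrected[-2]), 1.019)
})
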